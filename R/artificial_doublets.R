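#' Droplets eligible for artificial doublet generation
#'
#' Returns the droplets whose library size lies within the given percentile
#' band (inclusive; quantiles by linear interpolation). Extreme droplets are
#' excluded from doublet generation so that artificial doublets are not
#' dominated by outlier library sizes.
#'
#' @param counts feature x droplet count matrix.
#' @param low,high percentile bounds, default the 5-95 band.
#' @return integer vector of droplet column indices.
#' @export
filter_by_libsize <- function(counts, low = 0.05, high = 0.95) {
  counts <- as_counts(counts)
  stopifnot(ncol(counts) >= 3, low >= 0, high <= 1, low < high)
  ls <- libsizes(counts)
  q <- quantile(ls, c(low, high), type = 7, names = FALSE)
  unname(which(ls >= q[1] & ls <= q[2]))
}

#' Generate artificial doublets
#'
#' Creates artificial doublets from random pairs of real droplets (restricted
#' to the 5-95 library-size percentile band). The majority (`prop_sum`, 75%
#' by default) are plain element-wise sums of the two source droplets. For
#' the remainder, the sum is halved and used as the element-wise mean of
#' Poisson sampling. When clusters are supplied, pairs are drawn from
#' *different* clusters (proportionally to cluster sizes), and half of the
#' Poisson remainder additionally re-weights the two sources: the target
#' contribution fraction of source 1 is the average of its actual
#' library-size fraction and its cluster's median-library-size fraction,
#' accounting for the possibility that observed library size is a poor proxy
#' for RNA content.
#'
#' @param counts feature x droplet count matrix (typically already reduced to
#'   the selected features).
#' @param n_artificial number of doublets to generate; defaults to the number
#'   of real droplets.
#' @param prop_sum proportion generated by the plain sum (default 0.75).
#' @param libsize_percentiles length-2 numeric, eligibility band.
#' @param clusters optional [fast_cluster()] result (or label vector); when
#'   present, generation is in between-cluster mode.
#' @param seed integer seed.
#' @return An object of class `dblkit_artificial`: list with `counts`
#'   (feature x doublet sparse matrix), `origins` (n x 2 matrix of source
#'   column indices), `origin_clusters` (n x 2 matrix or `NULL`), and
#'   `method` (per-doublet `"sum"`, `"poisson"` or `"reweighted"`).
#' @export
generate_artificial_doublets <- function(counts, n_artificial = ncol(counts),
                                         prop_sum = 0.75,
                                         libsize_percentiles = c(0.05, 0.95),
                                         clusters = NULL, seed = 42) {
  counts <- as_counts(counts)
  if (n_artificial < 1) abort("n_artificial must be >= 1")
  stopifnot(prop_sum >= 0, prop_sum <= 1)
  eligible <- filter_by_libsize(counts, libsize_percentiles[1],
                                libsize_percentiles[2])
  lab <- if (!is.null(clusters)) cluster_labels(clusters, ncol(counts))
  if (!is.null(lab)) {
    if (length(unique(lab[eligible])) < 2) {
      abort("between-cluster mode needs eligible droplets in >= 2 clusters")
    }
    med <- vapply(split(libsizes(counts), lab), median, numeric(1))
  } else if (length(eligible) < 2) {
    abort("need at least 2 eligible droplets")
  }

  n_sum <- ceiling(prop_sum * n_artificial)
  n_rest <- n_artificial - n_sum
  n_rw <- if (!is.null(lab)) floor(n_rest / 2) else 0L
  n_pois <- n_rest - n_rw
  method <- rep(c("sum", "poisson", "reweighted"), c(n_sum, n_pois, n_rw))

  with_seed(seed, {
    origins <- draw_pairs(n_artificial, eligible, lab)
    i1 <- origins[, 1]; i2 <- origins[, 2]
    out <- counts[, i1, drop = FALSE] + counts[, i2, drop = FALSE]
    rest <- which(method != "sum")
    if (length(rest)) {
      ls <- libsizes(counts)
      block <- matrix(0, nrow(counts), length(rest))
      for (j in seq_along(rest)) {
        d <- rest[j]
        c1 <- counts[, i1[d]]; c2 <- counts[, i2[d]]
        if (method[d] == "reweighted") {
          l1 <- ls[i1[d]]; l2 <- ls[i2[d]]
          m1 <- med[as.character(lab[i1[d]])]
          m2 <- med[as.character(lab[i2[d]])]
          f1 <- mean(c(l1 / (l1 + l2), m1 / (m1 + m2)))
          c1 <- c1 * (f1 * (l1 + l2) / l1)
          c2 <- c2 * ((1 - f1) * (l1 + l2) / l2)
        }
        block[, j] <- rpois(nrow(counts), (c1 + c2) / 2)
      }
      out <- as(as(out, "CsparseMatrix"), "dMatrix")
      out[, rest] <- block
    }
    out <- as(as(out, "CsparseMatrix"), "dMatrix")
    colnames(out) <- sprintf("artificial%d", seq_len(n_artificial))
    structure(list(
      counts = out,
      origins = origins,
      origin_clusters = if (!is.null(lab))
        cbind(lab[origins[, 1]], lab[origins[, 2]]),
      method = method
    ), class = "dblkit_artificial")
  })
}

# Draw n origin pairs among `eligible` droplets; distinct within a pair, and
# from different clusters when labels are given (rejection sampling keeps the
# pair distribution proportional to cluster sizes).
draw_pairs <- function(n, eligible, lab = NULL) {
  pick <- function(m) cbind(sample(eligible, m, replace = TRUE),
                            sample(eligible, m, replace = TRUE))
  out <- matrix(0L, 0, 2)
  while (nrow(out) < n) {
    cand <- pick(2L * (n - nrow(out)) + 10L)
    ok <- cand[, 1] != cand[, 2]
    if (!is.null(lab)) ok <- ok & lab[cand[, 1]] != lab[cand[, 2]]
    out <- rbind(out, cand[ok, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' @export
print.dblkit_artificial <- function(x, ...) {
  cat(sprintf("# %d artificial doublets over %d features (%s)\n",
              ncol(x$counts), nrow(x$counts),
              paste(sprintf("%s: %d", names(table(x$method)),
                            table(x$method)), collapse = ", ")))
  invisible(x)
}
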