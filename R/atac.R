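#' TF-IDF normalization for sparse accessibility matrices
#'
#' Term frequency - inverse document frequency, the standard normalization
#' for peak/site count matrices: `TF(i, j) = x(i, j) / colsum(j)` and
#' `IDF(i) = log(1 + N / n_i)` with `n_i` the number of droplets in which
#' feature `i` is detected. Features detected nowhere get a zero row;
#' all-zero droplets yield a zero column with a warning.
#'
#' @param counts feature x droplet count matrix.
#' @return sparse numeric TF-IDF matrix of the same dimensions.
#' @export
tfidf_normalize <- function(counts) {
  counts <- as_counts(counts)
  cs <- libsizes(counts)
  if (all(cs == 0)) abort("all droplets are empty")
  if (any(cs == 0)) warn("all-zero droplet column(s) map to zero")
  ni <- Matrix::rowSums(counts > 0)
  idf <- ifelse(ni > 0, log(1 + ncol(counts) / pmax(ni, 1)), 0)
  tf <- counts %*% Matrix::Diagonal(x = ifelse(cs > 0, 1 / cs, 0))
  out <- Matrix::Diagonal(x = idf) %*% tf
  out <- as(as(out, "CsparseMatrix"), "dMatrix")
  dimnames(out) <- dimnames(counts)
  out
}

#' Aggregate correlated features into meta-features
#'
#' scATAC reads are spread thinly across very many sites, so selecting a
#' subset of "top" features discards most of the signal. Instead, features
#' are clustered into a moderate number of meta-features — PCA on the TF-IDF
#' matrix with features as observations, then k-means — and the raw counts
#' are summed within each group. Total counts per droplet are conserved
#' exactly, and the meta-feature matrix feeds [detect_doublets()] directly
#' (with feature selection disabled).
#'
#' @param counts site x droplet count matrix.
#' @param n_meta number of meta-features (default 1000; must not exceed the
#'   number of features).
#' @param seed integer seed for PCA and k-means.
#' @param rank PCA rank for the feature coordinates (default 20).
#' @return meta-feature x droplet sparse count matrix with a
#'   `feature_groups` attribute (the integer group of each input feature).
#' @export
aggregate_features <- function(counts, n_meta = 1000, seed = 42, rank = 20) {
  counts <- as_counts(counts)
  if (n_meta > nrow(counts)) abort("n_meta exceeds the number of features")
  tfidf <- tfidf_normalize(counts)
  rank <- min(rank, nrow(counts) - 1, ncol(counts) - 1)
  groups <- with_seed(seed, {
    emb <- svd_embed(Matrix::t(tfidf), rank = rank, seed = seed)
    if (n_meta == nrow(counts)) seq_len(nrow(counts))
    else kmeans(emb, centers = n_meta, iter.max = 30, nstart = 1)$cluster
  })
  # indicator (meta x feature) %*% counts sums counts within groups
  ind <- sparseMatrix(i = groups, j = seq_len(nrow(counts)), x = 1,
                      dims = c(n_meta, nrow(counts)))
  out <- ind %*% counts
  out <- as(as(out, "CsparseMatrix"), "dMatrix")
  rownames(out) <- sprintf("meta%d", seq_len(n_meta))
  colnames(out) <- colnames(counts)
  attr(out, "feature_groups") <- groups
  out
}

#' Per-droplet count of loci covered by more than two fragments
#'
#' In a diploid cell a genomic position can be captured at most twice, so
#' loci where a single barcode's fragments stack more than two deep point to
#' a doublet. For each barcode and chromosome, a sweep-line over fragment
#' starts/ends finds the maximal runs where overlap depth exceeds 2; the
#' statistic is the number of such runs.
#'
#' @param fragments tibble from [read_fragments()] (`chrom`, `start`, `end`,
#'   `barcode`; 0-based half-open intervals).
#' @param exclude optional tibble of regions (`chrom`, `start`, `end`) to
#'   blacklist; fragments overlapping them are dropped before counting.
#' @return tibble with `barcode` and `n_loci_gt2`, one row per barcode seen
#'   in the input.
#' @export
amulet_counts <- function(fragments, exclude = NULL) {
  stopifnot(all(c("chrom", "start", "end", "barcode") %in%
                colnames(fragments)))
  if (!is.null(exclude) && nrow(exclude)) {
    drop <- rep(FALSE, nrow(fragments))
    for (r in seq_len(nrow(exclude))) {
      drop <- drop | (fragments$chrom == exclude$chrom[r] &
                        fragments$start < exclude$end[r] &
                        fragments$end > exclude$start[r])
    }
    fragments <- fragments[!drop, , drop = FALSE]
  }
  barcodes <- unique(fragments$barcode)
  counts <- vapply(split(fragments, fragments$barcode), function(fr) {
    sum(vapply(split(fr, fr$chrom), function(chr_fr) {
      count_deep_runs(chr_fr$start, chr_fr$end, depth = 2L)
    }, integer(1)))
  }, integer(1))
  tibble(barcode = barcodes,
         n_loci_gt2 = as.integer(counts[barcodes]))
}

# Number of maximal runs where interval overlap depth exceeds `depth`.
count_deep_runs <- function(start, end, depth = 2L) {
  if (length(start) <= depth) return(0L)
  pos <- c(start, end)
  delta <- rep(c(1L, -1L), each = length(start))
  # ends sort before starts at the same coordinate: half-open intervals
  ord <- order(pos, delta)
  cum <- cumsum(delta[ord])
  above <- cum > depth
  sum(above & !c(FALSE, above[-length(above)]))
}

#' Poisson upper-tail p-values for the fragment-overlap statistic
#'
#' The overlap counts of singlets form the null; its rate is estimated
#' robustly as the trimmed mean of counts within a quantile band, and each
#' droplet's p-value is the Poisson upper tail `P(X >= observed)`. The
#' statistic grows with library size, which is confounded with doublet
#' status; the per-barcode fragment totals are reported alongside as a
#' diagnostic, not corrected for.
#'
#' @param stats tibble from [amulet_counts()] (`barcode`, `n_loci_gt2`),
#'   optionally with an `n_fragments` column.
#' @param trim quantile band for the null-rate estimate (default
#'   `c(0.1, 0.9)`).
#' @return tibble with `barcode`, `n_loci_gt2`, `p_value`, `q_value`
#'   (Benjamini-Hochberg), and `n_fragments` when available.
#' @export
amulet_pvalues <- function(stats, trim = c(0.1, 0.9)) {
  x <- stats$n_loci_gt2
  stopifnot(length(x) >= 10)
  q <- quantile(x, trim, type = 7, names = FALSE)
  band <- x[x >= q[1] & x <= q[2]]
  lambda <- mean(band)
  if (lambda == 0) {
    warn("null rate is zero; using 1/n as the Poisson rate for nonzero counts")
    lambda <- 1 / length(x)
    p <- ifelse(x == 0, 1, ppois(x - 1, lambda, lower.tail = FALSE))
  } else {
    p <- ppois(x - 1, lambda, lower.tail = FALSE)
  }
  out <- stats
  out$p_value <- pmin(p, 1)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  attr(out, "lambda") <- lambda
  out
}

#' Combine two p-values with Fisher's method
#'
#' `X = -2 (ln p1 + ln p2)` is chi-square with 4 degrees of freedom under the
#' joint null; the combined p-value is its upper tail,
#' `(1 + X/2) * exp(-X/2)`. Used to merge the fragment-overlap p-value with
#' one minus the aggregated expression-based doublet score.
#'
#' @param p1,p2 p-values in `(0, 1]` (vectorised; zero or negative values are
#'   clamped to the smallest positive double with a warning).
#' @return combined p-value(s).
#' @export
fisher_combine <- function(p1, p2) {
  if (any(p1 <= 0) || any(p2 <= 0)) {
    warn("non-positive p-values clamped")
    p1 <- pmax(p1, .Machine$double.xmin)
    p2 <- pmax(p2, .Machine$double.xmin)
  }
  X <- -2 * (log(p1) + log(p2))
  pchisq(X, df = 4, lower.tail = FALSE)
}

#' Doublet detection for scATAC-seq
#'
#' Runs the expression pipeline on meta-features aggregated from the site
#' matrix, optionally computes the fragment-overlap statistic, and combines
#' the two with Fisher's method.
#'
#' @param counts site x droplet count matrix.
#' @param fragments optional fragment tibble for the overlap statistic.
#' @param n_meta number of meta-features (default 1000, capped at the number
#'   of sites).
#' @param combine `"none"` or `"fisher"`; `"fisher"` requires `fragments`.
#' @param seed integer seed.
#' @param ... further arguments to [detect_doublets()].
#' @return `dblkit_scores` tibble; with `combine = "fisher"`, extra columns
#'   `amulet_p`, `combined_p`.
#' @export
detect_doublets_atac <- function(counts, fragments = NULL, n_meta = 1000,
                                 combine = c("none", "fisher"), seed = 42,
                                 ...) {
  combine <- match.arg(combine)
  counts <- as_counts(counts)
  n_meta <- min(n_meta, nrow(counts))
  agg <- aggregate_features(counts, n_meta = n_meta, seed = seed)
  res <- detect_doublets(agg, n_features = nrow(agg), seed = seed, ...)
  if (!is.null(fragments)) {
    st <- amulet_counts(fragments)
    nf <- table(fragments$barcode)
    st$n_fragments <- as.integer(nf[st$barcode])
    st <- amulet_pvalues(st)
    keep_attrs <- attributes(res)[setdiff(names(attributes(res)),
                                          c("names", "row.names", "class"))]
    res <- left_join(res, st[, c("barcode", "n_loci_gt2", "p_value")],
                     by = c(droplet_id = "barcode"))
    names(res)[names(res) == "p_value"] <- "amulet_p"
    if (combine == "fisher") {
      res$combined_p <- fisher_combine(pmax(res$amulet_p, .Machine$double.xmin,
                                            na.rm = TRUE),
                                       pmax(1 - res$score,
                                            .Machine$double.xmin))
    }
    for (nm in names(keep_attrs)) attr(res, nm) <- keep_attrs[[nm]]
    class(res) <- c("dblkit_scores", class(tibble()))
  }
  res
}
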