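#' Infer the cluster origins of called doublets
#'
#' When artificial doublets are generated between clusters, each carries its
#' pair of source clusters; a called doublet's origin is inferred as the
#' modal origin pair among its k nearest artificial doublets in the joint
#' embedding. Ties are broken towards the pair whose tied neighbours are
#' closer (smaller summed distance). Origin inference is only partially
#' identifiable in practice — the dominant contributor is usually recovered,
#' the weaker one often not.
#'
#' @param scores `dblkit_scores` from a cluster-mode [detect_doublets()] run
#'   (the embedding and artificial-doublet origins travel as attributes).
#' @param k neighbours consulted (default 10).
#' @return tibble with `droplet_id`, `cluster_a`, `cluster_b` (ordered so
#'   `cluster_a <= cluster_b`) for each called doublet.
#' @export
infer_origins <- function(scores, k = 10) {
  embedding <- attr(scores, "embedding")
  art <- attr(scores, "artificial")
  if (is.null(embedding) || is.null(art) || is.null(art$origin_clusters)) {
    abort("origin inference needs a cluster-mode detect_doublets() result")
  }
  called <- which(scores$class == "doublet")
  if (!length(called)) {
    return(tibble(droplet_id = character(), cluster_a = integer(),
                  cluster_b = integer()))
  }
  is_art <- embedding$label == "artificial"
  art_emb <- embedding$embedding[is_art, , drop = FALSE]
  real_emb <- embedding$embedding[!is_art, , drop = FALSE]
  k <- min(k, nrow(art_emb))
  nn <- RANN::nn2(art_emb, query = real_emb[called, , drop = FALSE], k = k)
  oc <- art$origin_clusters
  pair_key <- paste(pmin(oc[, 1], oc[, 2]), pmax(oc[, 1], oc[, 2]), sep = "_")
  res <- vapply(seq_along(called), function(i) {
    keys <- pair_key[nn$nn.idx[i, ]]
    d <- nn$nn.dists[i, ]
    tab <- table(keys)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1) {
      sums <- vapply(top, function(kk) sum(d[keys == kk]), numeric(1))
      top <- top[which.min(sums)]
    }
    top
  }, character(1))
  parts <- do.call(rbind, strsplit(res, "_", fixed = TRUE))
  tibble(droplet_id = scores$droplet_id[called],
         cluster_a = as.integer(parts[, 1]),
         cluster_b = as.integer(parts[, 2]))
}

#' Expected doublet counts per cluster combination
#'
#' Under random pairing, a heterotypic doublet joins clusters `a` and `b`
#' with probability proportional to `2 p_a p_b`; renormalising over the
#' heterotypic pairs (dividing by `1 - sum(p_k^2)`) and scaling by the
#' doublet count gives the expectation for each combination.
#'
#' @param clusters [fast_cluster()] result or label vector.
#' @param n_doublets total (heterotypic) doublets to distribute.
#' @return tibble with `cluster_a`, `cluster_b` (`cluster_a < cluster_b`) and
#'   `expected`; expectations sum to `n_doublets`.
#' @export
expected_combination_counts <- function(clusters, n_doublets) {
  lab <- cluster_labels(clusters)
  p <- table(lab) / length(lab)
  ks <- as.integer(names(p))
  if (length(ks) < 2) abort("need at least 2 clusters")
  pairs <- utils::combn(seq_along(ks), 2)
  w <- 2 * p[pairs[1, ]] * p[pairs[2, ]]
  tibble(cluster_a = ks[pairs[1, ]],
         cluster_b = ks[pairs[2, ]],
         expected = n_doublets * as.numeric(w) / (1 - sum(p^2)))
}

#' Build the doublet-type enrichment table
#'
#' Combines the inferred origins of called doublets with the random-pairing
#' expectation and each origin's identification difficulty (the
#' misclassification rate, at the final threshold, of the artificial
#' doublets of that origin, with a continuity correction so the covariate
#' stays strictly inside (0, 1)).
#'
#' @param scores cluster-mode `dblkit_scores`.
#' @param origins optional precomputed [infer_origins()] result.
#' @param k neighbours for origin inference.
#' @return tibble of class `dblkit_enrichment`: `cluster_a`, `cluster_b`,
#'   `observed`, `expected`, `difficulty`.
#' @export
enrichment_table <- function(scores, origins = NULL, k = 10) {
  if (is.null(origins)) origins <- infer_origins(scores, k = k)
  cl <- attr(scores, "clusters")
  if (is.null(cl)) abort("scores carry no clusters")
  exp_tab <- expected_combination_counts(cl, nrow(origins))
  obs <- table(paste(origins$cluster_a, origins$cluster_b, sep = "_"))
  key <- paste(exp_tab$cluster_a, exp_tab$cluster_b, sep = "_")
  exp_tab$observed <- as.integer(ifelse(key %in% names(obs), obs[key], 0))
  art <- attr(scores, "artificial")
  art_scores <- attr(scores, "artificial_scores")
  thr <- attr(scores, "threshold")
  oc <- art$origin_clusters
  akey <- paste(pmin(oc[, 1], oc[, 2]), pmax(oc[, 1], oc[, 2]), sep = "_")
  exp_tab$difficulty <- vapply(key, function(kk) {
    i <- akey == kk
    if (!any(i)) return(NA_real_)
    (sum(art_scores[i] < thr) + 0.5) / (sum(i) + 1)
  }, numeric(1))
  out <- exp_tab[, c("cluster_a", "cluster_b", "observed", "expected",
                     "difficulty")]
  class(out) <- c("dblkit_enrichment", class(out))
  out
}

# 0/1 cluster-membership indicator matrix for combination rows.
combination_indicators <- function(table) {
  ks <- sort(unique(c(table$cluster_a, table$cluster_b)))
  ind <- vapply(ks, function(k)
    as.integer(table$cluster_a == k | table$cluster_b == k),
    integer(nrow(table)))
  ind <- matrix(ind, nrow = nrow(table),
                dimnames = list(NULL, sprintf("cluster_%s", ks)))
  ind
}

#' Test clusters for doublet stickiness
#'
#' Fits one generalized linear model over all doublet combinations: the
#' observed abundance of each combination against its random-pairing
#' expectation (as offset), cluster-membership indicators, and optionally
#' the log identification difficulty. A cluster coefficient significantly
#' above zero means that cluster joins doublets more often than random
#' pairing predicts — it is "sticky".
#'
#' For the (quasi-)binomial families the response is
#' `observed / (observed + expected)` on the logit scale, weighted by the
#' mean of observed and expected counts; for Poisson and negative binomial
#' the response is the observed count with `log(expected)` as offset.
#'
#' @param table `dblkit_enrichment` tibble (columns `cluster_a`, `cluster_b`,
#'   `observed`, `expected`, optional `difficulty`).
#' @param family `"quasibinomial"` (default, the best calibrated of the
#'   candidates), `"binomial"`, `"poisson"`, or `"nb"`.
#' @param min_clusters_for_difficulty include the difficulty covariate only
#'   when at least this many clusters are present (default 7).
#' @return object of class `dblkit_stickiness` with [tidy()] and [glance()]
#'   methods; `tidy()` gives per-cluster estimates, standard errors and
#'   p-values.
#' @export
stickiness_test <- function(table,
                            family = c("quasibinomial", "binomial",
                                       "poisson", "nb"),
                            min_clusters_for_difficulty = 7) {
  family <- match.arg(family)
  stopifnot(all(c("cluster_a", "cluster_b", "observed", "expected") %in%
                colnames(table)))
  ind <- combination_indicators(table)
  n_clusters <- ncol(ind)
  if (n_clusters < 3) {
    abort(paste("stickiness is not identifiable with fewer than 3 clusters",
                "(each row involves two of them)"))
  }
  use_difficulty <- n_clusters >= min_clusters_for_difficulty &&
    !is.null(table$difficulty) && !anyNA(table$difficulty)
  df <- as.data.frame(ind)
  if (use_difficulty)
    df$log_difficulty <- log(pmin(pmax(table$difficulty, 1e-4), 1))
  if (family %in% c("binomial", "quasibinomial")) {
    df$y <- table$observed / (table$observed + table$expected)
    wts <- (table$observed + table$expected) / 2
    fit <- suppressWarnings(
      glm(y ~ 0 + ., data = df, weights = wts,
          family = if (family == "binomial") binomial() else
            stats::quasibinomial()))
  } else {
    df$observed <- table$observed
    df$off <- log(pmax(table$expected, 1e-8))
    fml <- observed ~ 0 + . - off + offset(off)
    fit <- if (family == "poisson") {
      glm(fml, data = df, family = poisson())
    } else {
      suppressWarnings(MASS::glm.nb(fml, data = df))
    }
  }
  sm <- summary(fit)
  co <- as.data.frame(sm$coefficients)
  names(co) <- c("estimate", "std.error", "statistic", "p.value")
  co$term <- rownames(co)
  structure(list(
    fit = fit,
    family = family,
    dispersion = if (family == "nb") 1 / fit$theta else
      sm$dispersion %||% 1,
    coefficients = as_tibble(co[, c("term", "estimate", "std.error",
                                    "statistic", "p.value")]),
    used_difficulty = use_difficulty,
    n_clusters = n_clusters
  ), class = "dblkit_stickiness")
}

#' @export
tidy.dblkit_stickiness <- function(x, ...) x$coefficients

#' @export
glance.dblkit_stickiness <- function(x, ...) {
  tibble(family = x$family, dispersion = x$dispersion,
         n_clusters = x$n_clusters, used_difficulty = x$used_difficulty,
         deviance = x$fit$deviance, df.residual = x$fit$df.residual)
}

#' @export
print.dblkit_stickiness <- function(x, ...) {
  cat(sprintf("# Cluster stickiness (%s family, %d clusters%s)\n",
              x$family, x$n_clusters,
              if (x$used_difficulty) ", difficulty-adjusted" else ""))
  print(x$coefficients)
  invisible(x)
}

#' Test for enrichment of specific doublet combinations
#'
#' First fits a global model of observed counts against the random-pairing
#' expectation (offset) and log difficulty — absorbing the overall calling
#' efficiency — then treats the fitted values as adjusted expectations and
#' computes, for each combination, the upper-tail probability of its
#' observed count under that expectation. For the negative binomial family
#' the global over-dispersion estimated in the first step is reused for the
#' tails.
#'
#' @param table `dblkit_enrichment` tibble.
#' @param family `"nb"` (default) or `"poisson"`.
#' @return the table with added `fitted`, `p_value` and `q_value`
#'   (Benjamini-Hochberg) columns; the global fit is attached as attribute
#'   `fit`.
#' @export
combination_test <- function(table, family = c("nb", "poisson")) {
  family <- match.arg(family)
  stopifnot(nrow(table) >= 3)
  out <- as_tibble(table)
  if (all(table$observed == 0)) {
    warn("no observed doublets; all p-values are 1")
    out$fitted <- 0
    out$p_value <- 1
    out$q_value <- 1
    return(out)
  }
  df <- data.frame(observed = table$observed,
                   off = log(pmax(table$expected, 1e-8)))
  use_difficulty <- !is.null(table$difficulty) && !anyNA(table$difficulty) &&
    length(unique(table$difficulty)) > 1
  fml <- if (use_difficulty) {
    df$log_difficulty <- log(pmin(pmax(table$difficulty, 1e-4), 1))
    observed ~ log_difficulty + offset(off)
  } else observed ~ offset(off)
  if (family == "poisson") {
    fit <- glm(fml, data = df, family = poisson())
    mu <- fitted(fit)
    p <- ppois(table$observed - 1, mu, lower.tail = FALSE)
  } else {
    # under-dispersed data sends the theta estimate to infinity, where the
    # negative binomial degenerates to its Poisson limit
    fit <- tryCatch(suppressWarnings(MASS::glm.nb(fml, data = df)),
                    error = function(e) NULL)
    if (is.null(fit)) {
      fit <- glm(fml, data = df, family = poisson())
      mu <- fitted(fit)
      p <- ppois(table$observed - 1, mu, lower.tail = FALSE)
    } else {
      mu <- fitted(fit)
      p <- pnbinom(table$observed - 1, mu = mu, size = fit$theta,
                   lower.tail = FALSE)
    }
  }
  out$fitted <- as.numeric(mu)
  out$p_value <- pmin(p, 1)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  attr(out, "fit") <- fit
  out
}
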