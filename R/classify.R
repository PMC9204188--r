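#' Expected doublet count and heterotypic bounds
#'
#' The expected doublet rate scales with the number of droplets captured
#' (roughly 1% per 1000 cells): by default `dbr = n * 1e-5`, so the expected
#' doublet count is `e = dbr * n = n^2 * 1e-5`. The rate carries an
#' uncertainty `dbr_sd`, and the bounds are restricted to *heterotypic*
#' doublets via `het_fraction`, since homotypic doublets are essentially
#' undetectable and should not be demanded of the threshold.
#'
#' @param n number of droplets.
#' @param dbr expected doublet rate; `NULL` for the `n * 1e-5` default.
#' @param dbr_sd uncertainty on the rate (default 0.015).
#' @param het_fraction fraction of doublets expected to be heterotypic, in
#'   `(0, 1]`.
#' @return list of class `dblkit_rate` with fields `n`, `dbr`, `dbr_sd`,
#'   `e`, `e_low`, `e_high`, `het_fraction`.
#' @export
expected_doublet_count <- function(n, dbr = NULL, dbr_sd = 0.015,
                                   het_fraction = 1) {
  stopifnot(n >= 1, het_fraction > 0, het_fraction <= 1)
  if (is.null(dbr)) dbr <- n * 1e-5
  if (dbr < 0 || dbr > 1) {
    warn("doublet rate clamped into [0, 1]")
    dbr <- min(max(dbr, 0), 1)
  }
  lo <- dbr - dbr_sd
  hi <- dbr + dbr_sd
  if (lo < 0 || hi > 1) {
    warn("dbr +/- dbr_sd clamped into [0, 1]")
    lo <- max(lo, 0); hi <- min(hi, 1)
  }
  structure(list(n = n, dbr = dbr, dbr_sd = dbr_sd,
                 e = dbr * n,
                 e_low = max(0, lo * n * het_fraction),
                 e_high = hi * n * het_fraction,
                 het_fraction = het_fraction),
            class = "dblkit_rate")
}

#' Deviation of observed doublet calls from the expected count
#'
#' Zero when the observed number of called doublets `o_t` lies inside the
#' expected heterotypic interval, otherwise the distance to the nearest bound
#' scaled by the interval midpoint sum:
#' `2 * min(|o_t - e_low|, |o_t - e_high|) / (e_low + e_high)`.
#'
#' @param o_t observed doublet calls at a threshold (vectorised).
#' @param e_low,e_high expected-count bounds, `e_low <= e_high`,
#'   `e_low + e_high > 0`.
#' @return non-negative numeric, same length as `o_t`.
#' @export
threshold_deviation <- function(o_t, e_low, e_high) {
  stopifnot(e_low <= e_high, e_low + e_high > 0)
  inside <- o_t >= e_low & o_t <= e_high
  dev <- 2 * pmin(abs(o_t - e_low), abs(o_t - e_high)) / (e_low + e_high)
  ifelse(inside, 0, dev)
}

#' Doublet-calling threshold by combined cost minimisation
#'
#' Scans every candidate threshold (all unique scores plus 0 and just above
#' 1) and minimises `cost_t = FNR_t + FPR_t + deviation_t^2`, where `FNR_t`
#' is the fraction of artificial doublets scored below `t` (misclassified as
#' singlets), `FPR_t` the fraction of eligible real droplets scored at or
#' above `t`, and the deviation term penalises call counts outside the
#' expected heterotypic doublet interval. Ties are broken towards the larger
#' threshold (fewer calls).
#'
#' @param scores_real,scores_artificial score vectors in `[0, 1]`.
#' @param rate `dblkit_rate` from [expected_doublet_count()].
#' @param exclude logical or index vector over the real droplets: droplets
#'   already called doublet in a previous round, ignored in the FPR (they
#'   still count towards `o_t`).
#' @return list with `threshold` and `context`, a tibble of the full scan
#'   (`t`, `o_t`, `fnr`, `fpr`, `deviation`, `cost`) whose attribute
#'   `chosen` is the selected row.
#' @export
find_threshold <- function(scores_real, scores_artificial, rate,
                           exclude = NULL) {
  stopifnot(length(scores_real) > 0, length(scores_artificial) > 0)
  eligible <- rep(TRUE, length(scores_real))
  if (!is.null(exclude)) {
    if (is.logical(exclude)) eligible <- !exclude else eligible[exclude] <- FALSE
  }
  cand <- sort(unique(c(0, scores_real, scores_artificial,
                        1 + .Machine$double.eps)))
  sr <- sort(scores_real)
  se <- sort(scores_real[eligible])
  sa <- sort(scores_artificial)
  n_ge <- function(sorted, t) length(sorted) - findInterval(t, sorted,
                                                            left.open = TRUE)
  o_t <- vapply(cand, function(t) n_ge(sr, t), numeric(1))
  fpr <- vapply(cand, function(t) n_ge(se, t), numeric(1)) /
    max(1, length(se))
  fnr <- 1 - vapply(cand, function(t) n_ge(sa, t), numeric(1)) /
    length(sa)
  dev <- threshold_deviation(o_t, rate$e_low, rate$e_high)
  cost <- fnr + fpr + dev^2
  ctx <- tibble(t = cand, o_t = o_t, fnr = fnr, fpr = fpr,
                deviation = dev, cost = cost)
  best <- which(cost == min(cost))
  chosen <- best[length(best)]  # largest t among minima
  attr(ctx, "chosen") <- ctx[chosen, ]
  list(threshold = cand[chosen], context = ctx)
}

#' Iteratively train the doublet classifier
#'
#' Trains gradient-boosted trees to separate artificial doublets from real
#' droplets, scoring every droplet out-of-fold (5-fold cross-fitting) so that
#' no droplet is scored by a model that saw it. Because some real droplets
#' are in fact doublets mislabelled as singlets, training is iterative: after
#' each round's thresholding, real droplets called doublet are removed from
#' the next round's training set (they are still scored). With
#' `exclude_unidentifiable = TRUE` (random-pair doublet generation),
#' artificial doublets scoring below the threshold — likely homotypic-like
#' and unidentifiable — are removed from training too.
#'
#' @param predictors `dblkit_predictors` tibble from [build_predictors()] (or
#'   any tibble with a `label` column, predictor columns, and
#'   `include_in_training`).
#' @param rate `dblkit_rate`; when `het_fraction` was left at 1 and
#'   `estimate_het` is `TRUE`, the heterotypic fraction is re-estimated each
#'   round as the fraction of artificial doublets scoring above the median
#'   real droplet (an identifiability proxy used in random mode).
#' @param iterations training rounds (default 3).
#' @param seed integer seed; runs are deterministic given the seed.
#' @param max_depth,nrounds,eta,subsample gradient-boosting hyperparameters
#'   (defaults 4, 250, 0.1, 0.75).
#' @param nfolds folds for out-of-fold scoring (default 5).
#' @param exclude_unidentifiable drop low-scoring artificial doublets from
#'   training (random mode).
#' @param estimate_het re-estimate the heterotypic fraction each round.
#' @return `dblkit_scores` tibble over the *real* droplets, with attributes
#'   `threshold`, `context` (threshold scan), `artificial_scores`, and
#'   `iterations_run`.
#' @export
train_iterative <- function(predictors, rate, iterations = 3, seed = 42,
                            max_depth = 4, nrounds = 250, eta = 0.1,
                            subsample = 0.75, nfolds = 5,
                            exclude_unidentifiable = FALSE,
                            estimate_het = FALSE) {
  stopifnot(iterations >= 1)
  cols <- predictor_columns(predictors)
  X <- as.matrix(predictors[, cols])
  mode(X) <- "double"
  y <- as.integer(predictors$label == "artificial")
  if (length(unique(y)) < 2) abort("need both real and artificial rows")
  is_real <- y == 0
  include <- rep(TRUE, nrow(X))
  called <- rep(FALSE, sum(is_real))
  scores <- numeric(nrow(X))
  thr <- NULL
  iterations_run <- 0L
  for (it in seq_len(iterations)) {
    train <- include
    if (length(unique(y[train])) < 2) {
      warn("training set degenerated to a single class; stopping early")
      break
    }
    scores <- with_seed(seed + it, {
      crossfit_xgb(X, y, train, nfolds = nfolds, max_depth = max_depth,
                   nrounds = nrounds, eta = eta, subsample = subsample,
                   seed = seed + it)
    })
    iterations_run <- it
    r <- rate
    if (estimate_het) {
      hf <- mean(scores[!is_real] > median(scores[is_real]))
      hf <- min(max(hf, 0.05), 1)
      r <- expected_doublet_count(rate$n, dbr = rate$dbr,
                                  dbr_sd = rate$dbr_sd, het_fraction = hf)
    }
    ft <- find_threshold(scores[is_real], scores[!is_real], r,
                         exclude = called)
    thr <- ft
    if (it < iterations) {
      called_now <- scores[is_real] >= ft$threshold
      include[is_real][called_now] <- FALSE
      called <- called | called_now
      if (exclude_unidentifiable) {
        include[!is_real][scores[!is_real] < ft$threshold] <- FALSE
      }
    }
  }
  if (is.null(thr)) abort("classifier never trained (degenerate input)")
  ids <- if (!is.null(predictors$droplet_id)) {
    predictors$droplet_id[is_real]
  } else sprintf("droplet%d", seq_len(sum(is_real)))
  out <- score_table(ids, scores[is_real], thr$threshold,
                     context = thr$context,
                     artificial_scores = scores[!is_real],
                     iterations_run = iterations_run)
  out
}

# Out-of-fold gradient-boosting scores. Training rows are scored by the fold
# model that held them out; non-training rows by the average over fold
# models. Stratified folds keep both classes in every training split.
crossfit_xgb <- function(X, y, train, nfolds, max_depth, nrounds, eta,
                         subsample, seed) {
  tr_idx <- which(train)
  fold <- integer(length(tr_idx))
  for (cls in unique(y[tr_idx])) {
    i <- which(y[tr_idx] == cls)
    fold[i] <- sample(rep(seq_len(nfolds), length.out = length(i)))
  }
  scores <- numeric(nrow(X))
  out_idx <- which(!train)
  acc <- numeric(length(out_idx))
  params <- list(objective = "binary:logistic", max_depth = max_depth,
                 eta = eta, subsample = subsample, nthread = 1, seed = seed)
  for (f in seq_len(nfolds)) {
    fit_rows <- tr_idx[fold != f]
    oof_rows <- tr_idx[fold == f]
    dtrain <- xgboost::xgb.DMatrix(X[fit_rows, , drop = FALSE],
                                   label = y[fit_rows])
    m <- xgboost::xgb.train(params = params, data = dtrain,
                            nrounds = nrounds, verbose = 0)
    scores[oof_rows] <- predict(m, xgboost::xgb.DMatrix(
      X[oof_rows, , drop = FALSE]))
    if (length(out_idx)) {
      acc <- acc + predict(m, xgboost::xgb.DMatrix(
        X[out_idx, , drop = FALSE]))
    }
  }
  if (length(out_idx)) scores[out_idx] <- acc / nfolds
  pmin(pmax(scores, 0), 1)
}

#' Detect doublets in a count matrix
#'
#' The full pipeline: select the top expressed features, cluster (in cluster
#' mode), generate artificial doublets, embed real and artificial droplets
#' together, build the multi-scale kNN predictor table, train the iterative
#' gradient-boosted classifier, and call doublets with the combined
#' misclassification/expected-rate threshold.
#'
#' @param counts feature x droplet count matrix (genes/features as rows).
#' @param clusters optional precomputed clusters ([fast_cluster()] result or
#'   label vector); computed when `NULL` in cluster mode.
#' @param mode `"cluster"` (between-cluster artificial doublets, the default)
#'   or `"random"` (random pairs plus exclusion of unidentifiable artificial
#'   doublets during iteration).
#' @param dbr,dbr_sd expected doublet rate and its uncertainty (see
#'   [expected_doublet_count()]).
#' @param n_features number of top features (default 1000).
#' @param n_artificial artificial doublets (default: number of droplets).
#' @param prop_sum fraction of artificial doublets made by plain summing.
#' @param dims embedding dimensionality (default 20).
#' @param k_list kNN neighbourhood sizes.
#' @param iterations classifier training rounds (default 3).
#' @param seed integer seed; the run is deterministic given the seed.
#' @param return_predictors attach the predictor table to the result.
#' @return `dblkit_scores` tibble (droplet_id, score, class) with attributes
#'   `threshold`, `context`, `clusters`, `artificial`, `rate`, and optionally
#'   `predictors` and `embedding`.
#' @examples
#' sim <- simulate_scrnaseq(n_clusters = 3, n_cells = 300, n_genes = 150,
#'                          doublet_rate = 0.1, seed = 1)
#' res <- detect_doublets(sim$counts, seed = 1, n_features = 100)
#' table(res$class)
#' @export
detect_doublets <- function(counts, clusters = NULL,
                            mode = c("cluster", "random"),
                            dbr = NULL, dbr_sd = 0.015,
                            n_features = 1000,
                            n_artificial = NULL, prop_sum = 0.75,
                            dims = 20, k_list = c(5, 10, 20),
                            iterations = 3, seed = 42,
                            return_predictors = FALSE) {
  mode <- match.arg(mode)
  counts <- validate_counts(counts)
  n <- ncol(counts)
  if (n < 50) warn("fewer than 50 droplets: likely too little data to train")
  if (is.null(n_artificial)) n_artificial <- n
  if (mode == "cluster" && is.null(clusters)) {
    clusters <- fast_cluster(counts, seed = seed)
    if (clusters$k < 2) {
      inform("single cluster found; falling back to random-pair doublets")
      mode <- "random"; clusters <- NULL
    }
  }
  lab <- if (mode == "cluster") cluster_labels(clusters, n)
  sel <- select_top_features(counts, n = n_features, clusters = lab)
  sub <- counts[sel, , drop = FALSE]
  art <- generate_artificial_doublets(sub, n_artificial = n_artificial,
                                      prop_sum = prop_sum,
                                      clusters = lab, seed = seed)
  embedding <- embed_union(sub, art, dims = dims, seed = seed)
  predictors <- build_predictors(sub, art, embedding = embedding,
                                 k_list = k_list, seed = seed)
  if (mode == "cluster") {
    p <- table(lab) / n
    het <- max(1 - sum(p^2), 1e-3)
    rate <- expected_doublet_count(n, dbr = dbr, dbr_sd = dbr_sd,
                                   het_fraction = het)
    estimate_het <- FALSE
  } else {
    rate <- expected_doublet_count(n, dbr = dbr, dbr_sd = dbr_sd)
    estimate_het <- TRUE
  }
  res <- train_iterative(predictors, rate, iterations = iterations,
                         seed = seed,
                         exclude_unidentifiable = (mode == "random"),
                         estimate_het = estimate_het)
  attr(res, "clusters") <- clusters
  attr(res, "artificial") <- art[c("origins", "origin_clusters", "method")]
  attr(res, "rate") <- rate
  attr(res, "mode") <- mode
  attr(res, "embedding") <- embedding
  if (return_predictors) attr(res, "predictors") <- predictors
  res
}

#' Direct classification on the expression matrix
#'
#' A variant that skips the dimension-reduction and kNN summarisation and
#' trains the gradient-boosted classifier directly on the normalized
#' expression of the selected features (tree depth raised to 6 for the
#' higher-dimensional predictors). Doublet generation, iterative training
#' and thresholding are identical to [detect_doublets()]. Mostly useful to
#' demonstrate that kNN summarisation mitigates overfitting to the
#' artificial-vs-real problem.
#'
#' @inheritParams detect_doublets
#' @return `dblkit_scores`, same schema as [detect_doublets()].
#' @export
direct_classify <- function(counts, clusters = NULL,
                            mode = c("cluster", "random"),
                            dbr = NULL, dbr_sd = 0.015,
                            n_features = 1000, n_artificial = NULL,
                            prop_sum = 0.75, iterations = 3, seed = 42) {
  mode <- match.arg(mode)
  counts <- validate_counts(counts)
  n <- ncol(counts)
  if (is.null(n_artificial)) n_artificial <- n
  if (mode == "cluster" && is.null(clusters)) {
    clusters <- fast_cluster(counts, seed = seed)
    if (clusters$k < 2) { mode <- "random"; clusters <- NULL }
  }
  lab <- if (mode == "cluster") cluster_labels(clusters, n)
  sel <- select_top_features(counts, n = n_features, clusters = lab)
  sub <- counts[sel, , drop = FALSE]
  art <- generate_artificial_doublets(sub, n_artificial = n_artificial,
                                      prop_sum = prop_sum,
                                      clusters = lab, seed = seed)
  target <- median(libsizes(sub)[libsizes(sub) > 0])
  norm <- cbind(normalize_log(sub, target = target),
                normalize_log(art$counts, target = target))
  predictors <- as_tibble(as.matrix(Matrix::t(norm)), .name_repair = "minimal")
  colnames(predictors) <- sprintf("f%d", seq_len(ncol(predictors)))
  predictors$droplet_id <- colnames(norm)
  predictors$label <- factor(rep(c("real", "artificial"),
                                 c(n, ncol(art$counts))),
                             levels = c("real", "artificial"))
  predictors$include_in_training <- TRUE
  if (mode == "cluster") {
    p <- table(lab) / n
    rate <- expected_doublet_count(n, dbr = dbr, dbr_sd = dbr_sd,
                                   het_fraction = max(1 - sum(p^2), 1e-3))
    estimate_het <- FALSE
  } else {
    rate <- expected_doublet_count(n, dbr = dbr, dbr_sd = dbr_sd)
    estimate_het <- TRUE
  }
  res <- train_iterative(predictors, rate, iterations = iterations,
                         seed = seed, max_depth = 6,
                         exclude_unidentifiable = (mode == "random"),
                         estimate_het = estimate_het)
  attr(res, "mode") <- mode
  attr(res, "rate") <- rate
  res
}

#' Doublet detection across multiple captures
#'
#' Doublets form within a capture, so the expected doublet count for pooled
#' captures is the sum of per-capture expectations, not the expectation at
#' the pooled size. `"split"` runs the pipeline independently per sample and
#' concatenates the scores; `"combined"` runs once on all droplets with the
#' per-sample-derived expected rate.
#'
#' @param counts feature x droplet count matrix over all captures.
#' @param sample_of per-droplet sample/capture identifier.
#' @param strategy `"split"` or `"combined"`.
#' @param ... further arguments to [detect_doublets()].
#' @return `dblkit_scores` over all droplets (in input order).
#' @export
detect_doublets_multisample <- function(counts, sample_of,
                                        strategy = c("split", "combined"),
                                        dbr = NULL, ...) {
  strategy <- match.arg(strategy)
  counts <- as_counts(counts)
  stopifnot(length(sample_of) == ncol(counts))
  sample_of <- as.character(sample_of)
  if (strategy == "split") {
    parts <- lapply(unique(sample_of), function(s) {
      idx <- which(sample_of == s)
      if (length(idx) < 50)
        warn(sprintf("sample '%s' has fewer than 50 droplets", s))
      r <- detect_doublets(counts[, idx, drop = FALSE], dbr = dbr, ...)
      r$sample <- s
      r
    })
    thr <- vapply(parts, function(p) attr(p, "threshold"), numeric(1))
    out <- bind_rows(lapply(parts, as_tibble))
    out <- out[match(colnames(counts), out$droplet_id), ]
    res <- score_table(out$droplet_id, out$score, NA_real_)
    # classes were decided per-sample at per-sample thresholds
    res$class <- factor(out$class, levels = c("singlet", "doublet"))
    res$sample <- out$sample
    attr(res, "threshold") <- setNames(thr, unique(sample_of))
    res
  } else {
    if (is.null(dbr)) {
      # doublets form per capture: sum per-sample expectations
      ns <- table(sample_of)
      dbr <- sum(as.numeric(ns)^2 * 1e-5) / ncol(counts)
    }
    res <- detect_doublets(counts, dbr = dbr, ...)
    res$sample <- sample_of
    res
  }
}
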