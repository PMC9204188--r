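#' Jointly embed real droplets and artificial doublets
#'
#' Normalizes the artificial doublets exactly as the real droplets (scaling
#' to the real droplets' median library size before `log1p`), then fits a
#' single truncated PCA on the union, so that real and artificial droplets
#' share a coordinate system for the kNN features.
#'
#' @param real_counts feature x droplet counts over the selected features.
#' @param artificial `dblkit_artificial` from [generate_artificial_doublets()],
#'   over the same features.
#' @param dims number of components (default 20; must be >= 2).
#' @param seed integer seed (PCA initialisation).
#' @return An object of class `dblkit_embedding`: list with `embedding`
#'   (rows = real droplets then artificial doublets), `label` (factor
#'   real/artificial), and `droplet_id`.
#' @export
embed_union <- function(real_counts, artificial, dims = 20, seed = 42) {
  if (dims < 2) abort("dims must be >= 2")
  real_counts <- as_counts(real_counts)
  stopifnot(nrow(real_counts) == nrow(artificial$counts))
  target <- median(libsizes(real_counts)[libsizes(real_counts) > 0])
  norm_real <- normalize_log(real_counts, target = target)
  norm_art <- normalize_log(artificial$counts, target = target)
  union <- cbind(norm_real, norm_art)
  if (ncol(union) <= dims) abort("union must have more droplets than dims")
  emb <- svd_embed(union, rank = dims, seed = seed)
  structure(list(
    embedding = emb,
    label = factor(rep(c("real", "artificial"),
                       c(ncol(norm_real), ncol(norm_art))),
                   levels = c("real", "artificial")),
    droplet_id = c(colnames(real_counts), colnames(artificial$counts))
  ), class = "dblkit_embedding")
}

#' Multi-scale kNN artificial-neighbour ratios
#'
#' For every droplet (real or artificial) and every neighbourhood size in
#' `k_list`, computes the fraction of its k nearest neighbours (self
#' excluded, exact search) that are artificial doublets. Gathering the ratio
#' at several k lets the downstream classifier pick the most informative
#' scale. A distance-weighted ratio at the largest k (weights `1/(d + eps)`)
#' is added.
#'
#' @param embedding `dblkit_embedding` from [embed_union()].
#' @param k_list neighbourhood sizes, default `c(5, 10, 20)`.
#' @param eps stabiliser in the inverse-distance weights (default 1e-8).
#' @return tibble with one row per embedded droplet: `droplet_id`, `label`,
#'   one `art_ratio_k<k>` column per k, and `weighted_ratio`.
#' @export
knn_predictors <- function(embedding, k_list = c(5, 10, 20), eps = 1e-8) {
  emb <- embedding$embedding
  lab <- embedding$label == "artificial"
  n <- nrow(emb)
  kmax <- max(k_list)
  stopifnot(kmax < n)
  nn <- RANN::nn2(emb, k = kmax + 1)
  idx <- nn$nn.idx
  d <- nn$nn.dists
  # drop self from each neighbourhood (usually column 1; under exact distance
  # ties it can appear later)
  self_col <- max.col(-abs(idx - seq_len(n)), ties.method = "first")
  idx2 <- matrix(0L, n, kmax)
  d2 <- matrix(0, n, kmax)
  for (i in seq_len(n)) {
    keep <- setdiff(seq_len(kmax + 1), self_col[i])
    idx2[i, ] <- idx[i, keep]
    d2[i, ] <- d[i, keep]
  }
  is_art <- matrix(lab[idx2], n, kmax)
  out <- tibble(droplet_id = embedding$droplet_id,
                label = embedding$label)
  for (k in sort(k_list)) {
    out[[sprintf("art_ratio_k%d", k)]] <-
      rowMeans(is_art[, seq_len(k), drop = FALSE])
  }
  w <- 1 / (d2 + eps)
  out$weighted_ratio <- rowSums(w * is_art) / rowSums(w)
  out
}

#' Co-expression doublet score
#'
#' A variation on the co-expression strategy: find feature pairs that are
#' expressed less often together than independence predicts (mutually
#' exclusive markers), then score each droplet by how many of those top pairs
#' it nevertheless co-expresses. Doublets combine two transcriptional states
#' and therefore co-express normally exclusive pairs.
#'
#' Counts are binarized at `> 0`, the `n_top_features` most expressed
#' features are considered, and pairs are ranked by the standardized deficit
#' of observed co-occurrence below `n * p1 * p2`. Scores are scaled to
#' `[0, 1]` by the maximum.
#'
#' @param counts feature x droplet count matrix.
#' @param n_top_pairs number of mutually-exclusive pairs to use (default 500;
#'   fewer if fewer candidates exist).
#' @param n_top_features candidate features, by total count (default 500).
#' @return numeric vector, one score in `[0, 1]` per droplet.
#' @export
cxds_score <- function(counts, n_top_pairs = 500, n_top_features = 500) {
  counts <- as_counts(counts)
  stopifnot(nrow(counts) >= 2, ncol(counts) >= 2)
  n <- ncol(counts)
  keep <- select_top_features(counts, n = min(n_top_features, nrow(counts)))
  B <- counts[keep, , drop = FALSE]
  B@x <- rep(1, length(B@x))
  p <- Matrix::rowSums(B) / n
  expressed <- which(p > 0 & p < 1)
  if (length(expressed) < 2) return(setNames(rep(0, n), colnames(counts)))
  B <- as.matrix(B[expressed, , drop = FALSE])
  p <- p[expressed]
  O <- tcrossprod(B)
  E <- n * outer(p, p)
  V <- n * outer(p, p) * (1 - outer(p, p))
  z <- (O - E) / sqrt(pmax(V, .Machine$double.eps))
  z[upper.tri(z, diag = TRUE)] <- Inf
  ord <- order(z)
  m <- min(n_top_pairs, sum(is.finite(z)))
  pairs <- arrayInd(ord[seq_len(m)], dim(z))
  s <- colSums(B[pairs[, 1], , drop = FALSE] * B[pairs[, 2], , drop = FALSE])
  if (max(s) > 0) s <- s / max(s)
  setNames(s, colnames(counts))
}

#' Assemble the per-droplet predictor table
#'
#' Builds the feature matrix handed to the classifier: the multi-scale kNN
#' artificial ratios and weighted ratio, projections on the first principal
#' components, library size, number of detected features, and the
#' co-expression score, with the real/artificial label.
#'
#' @param real_counts selected-feature counts of the real droplets.
#' @param artificial `dblkit_artificial` over the same features.
#' @param embedding `dblkit_embedding`; computed if `NULL`.
#' @param k_list kNN neighbourhood sizes.
#' @param n_pcs number of PC-projection predictors (default `min(10, dims)`).
#' @param seed integer seed.
#' @return tibble of class `dblkit_predictors`: one row per real droplet and
#'   artificial doublet, predictor columns, `label`, and
#'   `include_in_training` (all `TRUE` initially).
#' @export
build_predictors <- function(real_counts, artificial, embedding = NULL,
                             k_list = c(5, 10, 20), n_pcs = 10, seed = 42) {
  real_counts <- as_counts(real_counts)
  if (is.null(embedding))
    embedding <- embed_union(real_counts, artificial, seed = seed)
  out <- knn_predictors(embedding, k_list = k_list)
  d <- ncol(embedding$embedding)
  for (j in seq_len(min(n_pcs, d))) {
    out[[sprintf("pc_%d", j)]] <- embedding$embedding[, j]
  }
  union_counts <- cbind(real_counts, artificial$counts)
  out$libsize <- as.numeric(libsizes(union_counts))
  out$n_detected <- as.numeric(Matrix::colSums(union_counts > 0))
  out$cxds_score <- as.numeric(cxds_score(union_counts))
  out$include_in_training <- TRUE
  class(out) <- c("dblkit_predictors", class(out))
  out
}

predictor_columns <- function(predictors) {
  setdiff(colnames(predictors),
          c("droplet_id", "label", "include_in_training"))
}
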