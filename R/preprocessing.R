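#' Select the most expressed features
#'
#' Reduces the matrix to its top expressed features before doublet generation
#' and embedding. Without clusters, the `n` features with the largest total
#' count are kept (ties broken towards the lower feature index). With
#' clusters, the union of each cluster's top `ceiling(n / k)` features is
#' taken instead, so that cluster-specific markers survive selection; the
#' union is ordered by overall expression and truncated to at most `n`.
#'
#' @param counts feature x droplet count matrix.
#' @param n number of features to keep (default 1000). Values larger than the
#'   number of features select everything.
#' @param clusters optional cluster labels (see [fast_cluster()]).
#' @return integer vector of selected row indices.
#' @export
select_top_features <- function(counts, n = 1000, clusters = NULL) {
  counts <- as_counts(counts)
  stopifnot(n >= 1)
  totals <- Matrix::rowSums(counts)
  if (is.null(clusters)) {
    ord <- order(-totals, seq_along(totals))
    return(sort(ord[seq_len(min(n, length(totals)))]))
  }
  lab <- cluster_labels(clusters, ncol(counts))
  k <- length(unique(lab))
  per <- ceiling(n / k)
  sel <- integer(0)
  for (cl in sort(unique(lab))) {
    tot_cl <- Matrix::rowSums(counts[, lab == cl, drop = FALSE])
    ord <- order(-tot_cl, seq_along(tot_cl))
    sel <- union(sel, ord[seq_len(min(per, length(ord)))])
  }
  sel <- sel[order(-totals[sel], sel)]
  sort(sel[seq_len(min(n, length(sel)))])
}

#' Library-size normalize and log-transform counts
#'
#' Each droplet's counts are scaled to the median library size of the dataset
#' and then `log1p`-transformed. All-zero droplets map to zero vectors. The
#' zero pattern is preserved, so sparse input stays sparse.
#'
#' @param counts feature x droplet count matrix.
#' @param target scaling target; defaults to the median library size of the
#'   non-empty droplets. Passing the target explicitly lets artificial
#'   doublets be normalized identically to the real droplets.
#' @return sparse numeric matrix of normalized log-expression.
#' @export
normalize_log <- function(counts, target = NULL) {
  counts <- as_counts(counts)
  ls <- libsizes(counts)
  if (all(ls == 0)) abort("all droplets are empty")
  if (is.null(target)) target <- median(ls[ls > 0])
  sf <- ifelse(ls > 0, target / ls, 0)
  out <- counts %*% Matrix::Diagonal(x = sf)
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(counts)
  out
}

#' Fast graph-based clustering of droplets
#'
#' Clusters droplets for between-cluster doublet generation: truncated SVD of
#' the normalized matrix, an exact kNN graph on the embedding, and Louvain
#' community detection. For datasets larger than `meta_cell_threshold`
#' droplets, a first k-means step groups droplets into meta-cells, Louvain
#' runs on the meta-cell centroids, and labels are propagated back —
#' trading a little resolution for a large constant-factor speedup.
#'
#' Singleton communities are merged into the cluster with the nearest
#' centroid so that no cluster is too small to form between-cluster doublet
#' pairs.
#'
#' @param counts feature x droplet count matrix.
#' @param meta_cell_threshold droplet count above which the meta-cell path is
#'   used (default 1000).
#' @param seed integer seed; the result is deterministic given the seed.
#' @param rank SVD rank (default 20, reduced with a warning when the data
#'   cannot support it).
#' @param knn_k neighbourhood size for the graph (default 10).
#' @param resolution Louvain resolution (default 1).
#' @param n_meta number of meta-cells (default `min(n/10, 500)`).
#' @return An object of class `dblkit_clusters`: a list with `labels`
#'   (integer cluster per droplet, named by droplet id), `k` (number of
#'   clusters) and `median_libsize` (per-cluster median library size).
#' @export
fast_cluster <- function(counts, meta_cell_threshold = 1000, seed = 42,
                         rank = 20, knn_k = 10, resolution = 1,
                         n_meta = NULL) {
  counts <- as_counts(counts)
  n <- ncol(counts)
  stopifnot(n >= 2)
  norm <- normalize_log(counts)
  emb <- svd_embed(norm, rank = rank, seed = seed)
  lab <- with_seed(seed, {
    if (n > meta_cell_threshold) {
      if (is.null(n_meta)) n_meta <- min(floor(n / 10), 500)
      km <- kmeans(emb, centers = n_meta, iter.max = 30, nstart = 1)
      meta_lab <- louvain_graph(km$centers,
                                k = min(knn_k, nrow(km$centers) - 1),
                                resolution = resolution)
      meta_lab[km$cluster]
    } else {
      louvain_graph(emb, k = min(knn_k, n - 1), resolution = resolution)
    }
  })
  lab <- merge_singletons(lab, emb)
  lab <- as.integer(as.factor(lab))
  names(lab) <- colnames(counts)
  ls <- libsizes(counts)
  med <- vapply(split(ls, lab), median, numeric(1))
  structure(list(labels = lab, k = length(unique(lab)),
                 median_libsize = med),
            class = "dblkit_clusters")
}

# Truncated SVD embedding (droplets x rank) of a normalized matrix, with
# column centering. Rank is reduced when the matrix cannot support it.
svd_embed <- function(norm, rank = 20, seed = 42) {
  n <- ncol(norm)
  max_rank <- min(n, nrow(norm)) - 1L
  if (rank > max_rank) {
    warn(sprintf("SVD rank reduced from %d to %d (matrix is %d x %d)",
                 rank, max_rank, nrow(norm), n))
    rank <- max_rank
  }
  x <- Matrix::t(norm)
  centers <- Matrix::colSums(x) / n
  if (rank >= 0.5 * min(dim(x))) {
    # irlba is inefficient near full rank; use the exact decomposition
    xc <- sweep(as.matrix(x), 2, centers)
    s <- svd(xc, nu = rank, nv = 0)
    return(s$u %*% diag(s$d[seq_len(rank)], nrow = rank))
  }
  with_seed(seed, {
    s <- irlba::irlba(x, nv = rank, center = centers)
    emb <- s$u %*% diag(s$d, nrow = rank)
  })
}

louvain_graph <- function(emb, k, resolution = 1) {
  n <- nrow(emb)
  if (n <= 2) return(rep(1L, n))
  nn <- RANN::nn2(emb, k = min(k + 1, n))
  from <- rep(seq_len(n), ncol(nn$nn.idx) - 1)
  to <- as.vector(nn$nn.idx[, -1])
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::simplify(g)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  as.integer(igraph::membership(comm))
}

merge_singletons <- function(lab, emb) {
  tab <- table(lab)
  single <- as.integer(names(tab)[tab == 1])
  if (!length(single) || length(tab) == length(single)) return(lab)
  keep <- as.integer(names(tab)[tab > 1])
  cent <- vapply(keep, function(cl)
    colMeans(emb[lab == cl, , drop = FALSE]), numeric(ncol(emb)))
  for (cl in single) {
    i <- which(lab == cl)
    d <- colSums((cent - as.numeric(emb[i, ]))^2)
    lab[i] <- keep[which.min(d)]
  }
  lab
}

#' @export
print.dblkit_clusters <- function(x, ...) {
  cat(sprintf("# %d clusters over %d droplets; sizes: %s\n", x$k,
              length(x$labels),
              paste(table(x$labels), collapse = ", ")))
  invisible(x)
}

#' @export
as_tibble.dblkit_clusters <- function(x, ...) {
  tibble(droplet_id = names(x$labels), cluster = unname(x$labels))
}
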