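#' Simulate cluster-structured scRNA-seq counts with planted doublets
#'
#' Generates negative-binomial counts for a requested number of clusters,
#' each marked by a disjoint block of over-expressed genes, plus planted
#' planted doublets. A doublet is *not* simulated as the sum of two realized
#' cells: the library preparation samples once from the pooled mRNA of the
#' two cells, so doublet counts are a single negative-binomial draw from the
#' combined (and partially captured) parent mean profiles. Captured doublet
#' libraries are also systematically smaller than the sum of the composing
#' cells' libraries (the two cells compete for capture), modelled by a
#' per-doublet capture fraction. Both choices matter: summing two realized
#' droplets is exactly how *artificial* doublets are made, and simulated
#' real doublets built the same way would share their noise signature and
#' make the artificial-vs-real training problem unrealistically identical to
#' the real one. Parent clusters are drawn independently with the cluster
#' frequencies, so the homotypic fraction among doublets follows the
#' random-pairing law `sum(p_k^2)`.
#'
#' @param n_clusters number of clusters (>= 2).
#' @param n_cells total droplets, doublets included.
#' @param n_genes number of genes.
#' @param doublet_rate fraction of droplets that are doublets (in `[0, 0.5)`);
#'   the doublet count is `round(doublet_rate * n_cells)` exactly.
#' @param cluster_freqs cluster frequencies (default equal).
#' @param marker_fc fold-change of cluster markers (default 10).
#' @param marker_frac fraction of genes marking each cluster (default 0.05).
#' @param dispersion negative-binomial size parameter (default 10; smaller is
#'   noisier).
#' @param target_libsize expected singlet library size (default 2000).
#' @param libsize_sd log-normal sd of the per-cell library-size factor
#'   (default 0.3).
#' @param doublet_capture range of the per-doublet capture fraction applied
#'   to the pooled parent mean, drawn uniformly per doublet (default
#'   `c(0.55, 0.9)`).
#' @param heterotypic_only plant only cross-cluster doublets (default
#'   `FALSE`: parent clusters drawn independently, giving homotypic doublets
#'   at the random-expectation rate).
#' @param seed integer seed; output is reproducible bit-for-bit.
#' @return list with `counts` (gene x droplet sparse matrix, doublet columns
#'   shuffled among singlets) and `truth`, a tibble with `droplet_id`,
#'   `type` (`singlet`/`heterotypic_doublet`/`homotypic_doublet`), `cluster`
#'   (singlets), and `origin_a`/`origin_b` (doublet parent clusters).
#' @export
simulate_scrnaseq <- function(n_clusters = 5, n_cells = 2000, n_genes = 500,
                              doublet_rate = 0.1, cluster_freqs = NULL,
                              marker_fc = 10, marker_frac = 0.05,
                              dispersion = 10, target_libsize = 2000,
                              libsize_sd = 0.3,
                              doublet_capture = c(0.55, 0.9),
                              heterotypic_only = FALSE, seed = 42) {
  stopifnot(n_clusters >= 2, doublet_rate >= 0, doublet_rate < 0.5)
  if (is.null(cluster_freqs)) cluster_freqs <- rep(1 / n_clusters, n_clusters)
  cluster_freqs <- cluster_freqs / sum(cluster_freqs)
  with_seed(seed, {
    base <- rlnorm(n_genes, meanlog = 1, sdlog = 1)
    n_mark <- max(1, round(marker_frac * n_genes))
    profiles <- sapply(seq_len(n_clusters), function(k) {
      mu <- base
      lo <- (k - 1) * n_mark + 1
      hi <- min(k * n_mark, n_genes)
      if (lo <= n_genes) mu[lo:hi] <- mu[lo:hi] * marker_fc
      mu / sum(mu) * target_libsize
    })
    sim_cell <- function(k) {
      lf <- rlnorm(1, 0, libsize_sd)
      rnbinom(n_genes, mu = profiles[, k] * lf, size = dispersion)
    }
    sim_doublet <- function(k1, k2) {
      mu <- profiles[, k1] * rlnorm(1, 0, libsize_sd) +
        profiles[, k2] * rlnorm(1, 0, libsize_sd)
      keep <- runif(1, doublet_capture[1], doublet_capture[2])
      rnbinom(n_genes, mu = mu * keep, size = dispersion)
    }
    n_dbl <- round(doublet_rate * n_cells)
    n_sing <- n_cells - n_dbl
    sing_cl <- sample.int(n_clusters, n_sing, replace = TRUE,
                          prob = cluster_freqs)
    cols <- lapply(sing_cl, sim_cell)
    origin <- cbind(sample.int(n_clusters, n_dbl, TRUE, prob = cluster_freqs),
                    sample.int(n_clusters, n_dbl, TRUE, prob = cluster_freqs))
    if (heterotypic_only && n_dbl) {
      for (i in which(origin[, 1] == origin[, 2])) {
        others <- setdiff(seq_len(n_clusters), origin[i, 1])
        origin[i, 2] <- if (length(others) == 1) others else
          sample(others, 1, prob = cluster_freqs[others])
      }
    }
    dbl_cols <- lapply(seq_len(n_dbl), function(i)
      sim_doublet(origin[i, 1], origin[i, 2]))
    m <- do.call(cbind, c(cols, dbl_cols))
    type <- c(rep("singlet", n_sing),
              ifelse(origin[, 1] == origin[, 2],
                     "homotypic_doublet", "heterotypic_doublet"))
    truth <- tibble(
      droplet_id = sprintf("cell%d", seq_len(n_cells)),
      type = type,
      cluster = c(sing_cl, rep(NA_integer_, n_dbl)),
      origin_a = c(rep(NA_integer_, n_sing), pmin(origin[, 1], origin[, 2])),
      origin_b = c(rep(NA_integer_, n_sing), pmax(origin[, 1], origin[, 2]))
    )
    perm <- sample.int(n_cells)
    m <- m[, perm, drop = FALSE]
    truth <- truth[perm, ]
    truth$droplet_id <- sprintf("cell%d", seq_len(n_cells))
    counts <- as(as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix"),
                 "dMatrix")
    dimnames(counts) <- list(sprintf("gene%d", seq_len(n_genes)),
                             truth$droplet_id)
    list(counts = counts, truth = truth)
  })
}

#' Simulate scATAC fragments with planted doublets
#'
#' Places fragments at cluster-specific accessible sites, at most two
#' overlapping fragments per site per cell (the diploid ceiling), so that
#' singlet barcodes have zero loci with more-than-two coverage by
#' construction. Doublets merge the fragments of two parent cells from
#' *different* clusters; at sites both parents cover twice the overlap depth
#' reaches four, producing the deep loci that the fragment-overlap statistic
#' detects. Only cross-cluster doublets are planted: homotypic fragment
#' doublets carry no accessibility signal beyond library size and are the
#' overlap statistic's job, not the embedding pipeline's.
#'
#' @param n_cells total droplets, doublets included.
#' @param n_sites number of genomic sites (1 kb apart on one chromosome).
#' @param doublet_rate fraction of droplets that are doublets.
#' @param n_clusters number of cell populations (default 3).
#' @param site_frac fraction of the cluster-specific sites accessible per
#'   cluster (default 0.6).
#' @param shared_frac fraction of sites accessible in every cluster at high
#'   rate (default 1/3) — the "housekeeping" accessibility that dominates
#'   naive most-expressed feature selection while carrying no cluster
#'   signal.
#' @param seed integer seed.
#' @return list with `fragments` (tibble: chrom, start, end, barcode),
#'   `counts` (site x droplet fragment counts), and `truth` as in
#'   [simulate_scrnaseq()].
#' @export
simulate_fragments <- function(n_cells = 400, n_sites = 2000,
                               doublet_rate = 0.1, n_clusters = 3,
                               site_frac = 0.6, shared_frac = 0.1,
                               seed = 42) {
  stopifnot(n_clusters >= 2, doublet_rate >= 0, doublet_rate < 0.5)
  with_seed(seed, {
    site_start <- (seq_len(n_sites) - 1L) * 1000L
    shared <- seq_len(round(shared_frac * n_sites))
    access <- sapply(seq_len(n_clusters), function(k)
      runif(n_sites) < site_frac)
    access[shared, ] <- TRUE
    sim_cell_frags <- function(k) {
      open <- which(access[, k])
      # shared sites are captured at high rate, specific sites sparsely;
      # a per-cell capture efficiency gives the wide library-size spread of
      # real ATAC libraries (and confounds library size with doublet status)
      eff <- min(rlnorm(1, meanlog = -0.2, sdlog = 0.5), 1.25)
      hot <- open %in% shared
      p <- ifelse(hot, 0.5, 0.12) * eff
      copies <- rbinom(length(open), 2, pmin(p, 1))
      sites <- rep(open, copies)
      if (!length(sites)) return(NULL)
      start <- site_start[sites] + sample.int(100, length(sites), TRUE)
      tibble(chrom = "chr1", start = start, end = start + 300L,
             site = sites)
    }
    n_dbl <- round(doublet_rate * n_cells)
    n_sing <- n_cells - n_dbl
    sing_cl <- sample.int(n_clusters, n_sing, replace = TRUE)
    o1 <- sample.int(n_clusters, n_dbl, TRUE)
    o2 <- vapply(o1, function(a)
      sample(setdiff(seq_len(n_clusters), a), 1), integer(1))
    origin <- cbind(o1, o2)
    frag_list <- c(
      lapply(sing_cl, sim_cell_frags),
      lapply(seq_len(n_dbl), function(i)
        bind_rows(sim_cell_frags(origin[i, 1]), sim_cell_frags(origin[i, 2])))
    )
    type <- c(rep("singlet", n_sing),
              ifelse(origin[, 1] == origin[, 2],
                     "homotypic_doublet", "heterotypic_doublet"))
    perm <- sample.int(n_cells)
    frag_list <- frag_list[perm]
    type <- type[perm]
    cl <- c(sing_cl, rep(NA_integer_, n_dbl))[perm]
    oa <- c(rep(NA_integer_, n_sing), pmin(origin[, 1], origin[, 2]))[perm]
    ob <- c(rep(NA_integer_, n_sing), pmax(origin[, 1], origin[, 2]))[perm]
    ids <- sprintf("bc%d", seq_len(n_cells))
    fragments <- bind_rows(lapply(seq_len(n_cells), function(i) {
      f <- frag_list[[i]]
      if (is.null(f)) return(NULL)
      f$barcode <- ids[i]
      f
    }))
    counts <- sparseMatrix(
      i = fragments$site,
      j = match(fragments$barcode, ids),
      x = 1, dims = c(n_sites, n_cells),
      dimnames = list(sprintf("site%d", seq_len(n_sites)), ids))
    counts <- as(as(counts, "CsparseMatrix"), "dMatrix")
    truth <- tibble(droplet_id = ids, type = type, cluster = cl,
                    origin_a = oa, origin_b = ob)
    list(fragments = fragments[, c("chrom", "start", "end", "barcode")],
         counts = counts, truth = truth)
  })
}

#' Simulate doublet-type count tables for the enrichment tests
#'
#' Draws observed doublet counts per cluster combination from a negative
#' binomial around the random-pairing expectation, optionally inflated by
#' per-cluster stickiness factors and per-pair enrichment factors
#' (renormalised so the total expectation stays at `n_doublets`).
#'
#' @param cluster_freqs cluster frequencies (normalised internally).
#' @param n_doublets total expected doublets.
#' @param stickiness per-cluster multiplicative factors (default 1).
#' @param combo_enrichment optional per-pair factors, in the row order of the
#'   output (pairs sorted by `cluster_a` then `cluster_b`).
#' @param dispersion negative-binomial size; `Inf` gives the Poisson limit.
#' @param seed integer seed.
#' @return `dblkit_enrichment` tibble (`cluster_a`, `cluster_b`, `observed`,
#'   `expected`, `difficulty` = 0.5) with attribute `mu` (the true means).
#' @export
simulate_doublet_table <- function(cluster_freqs, n_doublets,
                                   stickiness = NULL, combo_enrichment = NULL,
                                   dispersion = 5, seed = 42) {
  p <- cluster_freqs / sum(cluster_freqs)
  k <- length(p)
  stopifnot(k >= 2)
  if (is.null(stickiness)) stickiness <- rep(1, k)
  stopifnot(all(stickiness > 0), length(stickiness) == k)
  pairs <- utils::combn(k, 2)
  base <- n_doublets * 2 * p[pairs[1, ]] * p[pairs[2, ]] / (1 - sum(p^2))
  mu <- base * stickiness[pairs[1, ]] * stickiness[pairs[2, ]]
  if (!is.null(combo_enrichment)) {
    stopifnot(length(combo_enrichment) == ncol(pairs),
              all(combo_enrichment > 0))
    mu <- mu * combo_enrichment
  }
  mu <- mu * n_doublets / sum(mu)
  obs <- with_seed(seed, {
    if (is.infinite(dispersion)) rpois(length(mu), mu)
    else rnbinom(length(mu), mu = mu, size = dispersion)
  })
  out <- tibble(cluster_a = pairs[1, ], cluster_b = pairs[2, ],
                observed = as.integer(obs), expected = base,
                difficulty = 0.5)
  attr(out, "mu") <- mu
  class(out) <- c("dblkit_enrichment", class(out))
  out
}

#' Precision-recall and ROC metrics
#'
#' AUROC from the rank statistic (ties get average ranks); AUPRC by step
#' interpolation over the unique score thresholds (precision held constant
#' between thresholds). Both curves are returned as tibbles of points.
#'
#' @param scores numeric scores, larger meaning more doublet-like.
#' @param truth logical (or 0/1) true doublet labels; both classes must be
#'   present.
#' @return list with `auprc`, `auroc`, `pr` (threshold, recall, precision)
#'   and `roc` (threshold, fpr, tpr) tibbles.
#' @export
pr_roc_metrics <- function(scores, truth) {
  truth <- as.logical(truth)
  stopifnot(length(scores) == length(truth))
  np <- sum(truth); nn <- sum(!truth)
  if (np == 0 || nn == 0) abort("both classes must be present")
  r <- rank(scores)
  auroc <- (sum(r[truth]) - np * (np + 1) / 2) / (np * nn)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(s, fromLast = TRUE)  # one point per unique threshold
  tp <- tp[last]; fp <- fp[last]; thr <- s[last]
  recall <- tp / np
  precision <- tp / (tp + fp)
  tpr <- recall
  fpr <- fp / nn
  auprc <- sum(diff(c(0, recall)) * precision)
  structure(list(auprc = auprc, auroc = auroc,
                 pr = tibble(threshold = thr, recall = recall,
                             precision = precision),
                 roc = tibble(threshold = thr, fpr = fpr, tpr = tpr)),
            class = "dblkit_metrics")
}

#' AUPRC adjusted for doublet misannotation
#'
#' When ground truth comes from genotype demultiplexing, within-individual
#' heterotypic doublets are wrongly labelled singlets (inflating the
#' apparent FDR) and between-individual homotypic doublets are essentially
#' undetectable (capping the apparent TPR). The adjustment linearly rescales
#' so that an observed FDR equal to the expected within-individual
#' proportion maps to 0 and an observed TPR of one minus the expected
#' homotypic proportion maps to 1, both clamped to `[0, 1]`, and integrates
#' the rescaled precision over the rescaled TPR by the trapezoid rule.
#'
#' @param scores,truth as in [pr_roc_metrics()].
#' @param p_within_het expected proportion of within-individual (mislabelled)
#'   doublets among apparent false positives, in `[0, 1)`.
#' @param p_homo expected proportion of homotypic doublets, in `[0, 1)`.
#' @return adjusted area under the PR curve.
#' @export
adjusted_auprc <- function(scores, truth, p_within_het = 0, p_homo = 0) {
  stopifnot(p_within_het >= 0, p_within_het < 1, p_homo >= 0, p_homo < 1)
  m <- pr_roc_metrics(scores, truth)
  fdr <- 1 - m$pr$precision
  tpr <- m$pr$recall
  fdr_adj <- pmin(pmax((fdr - p_within_het) / (1 - p_within_het), 0), 1)
  tpr_adj <- pmin(pmax(tpr / (1 - p_homo), 0), 1)
  prec_adj <- 1 - fdr_adj
  x <- c(0, tpr_adj)
  y <- c(prec_adj[1], prec_adj)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Expected homotypic doublet fraction from cluster frequencies
#'
#' Under random pairing the probability that the two cells of a doublet come
#' from the same cluster is `sum(p_k^2)`.
#'
#' @param clusters [fast_cluster()] result or label vector.
#' @return numeric in `(0, 1]`.
#' @export
homotypic_fraction <- function(clusters) {
  lab <- cluster_labels(clusters)
  p <- table(lab) / length(lab)
  sum(p^2)
}

#' Fraction of doublets invisible to genotype demultiplexing
#'
#' Pooling `k` genetically distinct samples lets demultiplexing flag only
#' doublets whose two cells come from different samples; with equal pools a
#' fraction `1/k` of doublets pairs cells of the same sample and stays
#' invisible. The closed form is returned together with an optional
#' Monte-Carlo estimate from random pairings.
#'
#' @param n_samples number of equally sized pooled samples.
#' @param n_pairs Monte-Carlo pairings to draw (`0` to skip).
#' @param seed integer seed for the simulation.
#' @return list with `analytic`, and when simulated `monte_carlo` and `se`
#'   (binomial standard error).
#' @export
demux_missed_fraction <- function(n_samples, n_pairs = 0, seed = 42) {
  stopifnot(n_samples >= 1)
  out <- list(analytic = 1 / n_samples)
  if (n_pairs > 0) {
    mc <- with_seed(seed, {
      s1 <- sample.int(n_samples, n_pairs, replace = TRUE)
      s2 <- sample.int(n_samples, n_pairs, replace = TRUE)
      mean(s1 == s2)
    })
    out$monte_carlo <- mc
    out$se <- sqrt(mc * (1 - mc) / n_pairs)
  }
  out
}

#' Evaluate doublet detection on simulated data
#'
#' Runs [detect_doublets()] on a simulation for each seed and averages the
#' metrics over the runs (two seeds by default, smoothing run-to-run
#' classifier variability).
#'
#' @param sim a [simulate_scrnaseq()] result (or any list with `counts` and
#'   `truth`).
#' @param seeds integer seeds (default `c(1, 2)`).
#' @param ... further arguments to [detect_doublets()].
#' @return tibble with one row per seed plus the mean row: `seed`, `auprc`,
#'   `auroc`, `called_fraction`, `true_fraction`.
#' @export
evaluate_detection <- function(sim, seeds = c(1, 2), ...) {
  is_dbl <- sim$truth$type != "singlet"
  rows <- lapply(seeds, function(s) {
    res <- detect_doublets(sim$counts, seed = s, ...)
    m <- pr_roc_metrics(res$score, is_dbl)
    tibble(seed = s, auprc = m$auprc, auroc = m$auroc,
           called_fraction = mean(res$class == "doublet"),
           true_fraction = mean(is_dbl))
  })
  out <- bind_rows(rows)
  bind_rows(out, summarise(out, seed = NA_integer_,
                           across(c("auprc", "auroc", "called_fraction",
                                    "true_fraction"), mean)))
}
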