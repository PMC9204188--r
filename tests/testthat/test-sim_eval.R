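test_that("simulators are seed-reproducible and honour the doublet rate", {
  s1 <- simulate_scrnaseq(n_clusters = 3, n_cells = 300, n_genes = 100,
                          doublet_rate = 0.1, seed = 5)
  s2 <- simulate_scrnaseq(n_clusters = 3, n_cells = 300, n_genes = 100,
                          doublet_rate = 0.1, seed = 5)
  expect_identical(as.matrix(s1$counts), as.matrix(s2$counts))
  expect_identical(s1$truth, s2$truth)
  expect_equal(sum(s1$truth$type != "singlet"), 30)

  f1 <- simulate_fragments(n_cells = 100, n_sites = 300, seed = 7)
  f2 <- simulate_fragments(n_cells = 100, n_sites = 300, seed = 7)
  expect_identical(f1$fragments, f2$fragments)

  t1 <- simulate_doublet_table(rep(0.25, 4), 200, dispersion = 5, seed = 3)
  t2 <- simulate_doublet_table(rep(0.25, 4), 200, dispersion = 5, seed = 3)
  expect_identical(t1$observed, t2$observed)
})

test_that("homotypic fraction among planted doublets follows sum(p^2)", {
  sim <- simulate_scrnaseq(n_clusters = 4, n_cells = 4000, n_genes = 30,
                           doublet_rate = 0.45, marker_fc = 2, seed = 11)
  dbl <- sim$truth[sim$truth$type != "singlet", ]
  p_homo <- mean(dbl$type == "homotypic_doublet")
  # equal clusters: expectation 1/4; binomial CI on 1800 doublets
  se <- sqrt(0.25 * 0.75 / nrow(dbl))
  expect_lt(abs(p_homo - 0.25), 4 * se)
})

test_that("fragment doublets merging covered sites produce deep loci", {
  sim <- default_atac_sim()
  st <- amulet_counts(sim$fragments)
  truth <- sim$truth$type[match(st$barcode, sim$truth$droplet_id)]
  expect_true(all(st$n_loci_gt2[truth == "singlet"] == 0))
  expect_gt(mean(st$n_loci_gt2[truth != "singlet"] >= 1), 0.95)
})

test_that("doublet-table expectations respect stickiness construction", {
  p <- rep(1 / 4, 4)
  base <- simulate_doublet_table(p, 300, dispersion = Inf, seed = 1)
  sticky <- simulate_doublet_table(p, 300, stickiness = c(3, 1, 1, 1),
                                   dispersion = Inf, seed = 1)
  mu_b <- attr(base, "mu"); mu_s <- attr(sticky, "mu")
  has1 <- base$cluster_a == 1 | base$cluster_b == 1
  # before renormalization pairs with cluster 1 are inflated x3; after
  # renormalization their share triples relative to the others
  ratio <- (mu_s / mu_b)[has1] / (mu_s / mu_b)[!has1]
  expect_equal(ratio, rep(3, sum(has1)), tolerance = 1e-12)
})

test_that("Poisson-limit doublet tables concentrate at the expectation", {
  p <- c(0.4, 0.3, 0.3)
  ratios <- replicate(1000, {
    tab <- simulate_doublet_table(p, 600, dispersion = Inf,
                                  seed = sample.int(1e6, 1))
    sum(tab$observed) / sum(tab$expected)
  })
  expect_lt(abs(mean(ratios) - 1), 0.01)
})

test_that("rank AUROC and hand AUPRC match small oracles", {
  # scores .9 .8 .7 .6, labels 1 0 1 0 -> AUROC 0.75
  m <- pr_roc_metrics(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))
  expect_equal(m$auroc, 0.75)
  # perfect separation
  mp <- pr_roc_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(mp$auprc, 1)
  expect_equal(mp$auroc, 1)
  # random scores, balanced classes: AUROC near 1/2
  set.seed(2)
  sc <- runif(1000); lb <- rep(c(0, 1), 500)
  se <- sqrt(1 / 12) / sqrt(250)  # loose bound on the rank statistic sd
  expect_lt(abs(pr_roc_metrics(sc, lb)$auroc - 0.5), 3 * se)
  expect_error(pr_roc_metrics(1:3, c(1, 1, 1)), "both classes")
})

test_that("stepwise AUPRC equals a brute-force prefix oracle", {
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(5:20, 1)
    sc <- round(runif(n), 1)  # force ties
    lb <- rbinom(n, 1, 0.5)
    if (length(unique(lb)) < 2) next
    m <- pr_roc_metrics(sc, lb)
    ths <- sort(unique(sc), decreasing = TRUE)
    rec <- prec <- numeric(length(ths))
    for (i in seq_along(ths)) {
      called <- sc >= ths[i]
      rec[i] <- sum(lb == 1 & called) / sum(lb == 1)
      prec[i] <- sum(lb == 1 & called) / sum(called)
    }
    expect_equal(m$auprc, sum(diff(c(0, rec)) * prec), tolerance = 1e-12)
  }
})

test_that("adjusted AUPRC reduces to the trapezoid area at (0, 0)", {
  set.seed(14)
  sc <- runif(40); lb <- rbinom(40, 1, 0.4)
  m <- pr_roc_metrics(sc, lb)
  # independent trapezoid computation over the PR points
  x <- c(0, m$pr$recall); y <- c(m$pr$precision[1], m$pr$precision)
  trap <- sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  expect_equal(adjusted_auprc(sc, lb, 0, 0), trap, tolerance = 1e-12)
  # perfect classifier stays 1 under any valid rescaling
  expect_equal(adjusted_auprc(c(.9, .8, .1), c(1, 1, 0), 0.2, 0.5), 1)
})

test_that("adjusted AUPRC matches a hand-computed rescaled curve", {
  # 4 droplets, scores .9 .8 .7 .6, labels 1 1 0 1; p_within=0.2, p_homo=0.5
  sc <- c(0.9, 0.8, 0.7, 0.6); lb <- c(1, 1, 0, 1)
  m <- pr_roc_metrics(sc, lb)
  fdr <- 1 - m$pr$precision
  tpr <- m$pr$recall
  fdr_a <- pmin(pmax((fdr - 0.2) / 0.8, 0), 1)
  tpr_a <- pmin(tpr / 0.5, 1)
  pa <- 1 - fdr_a
  x <- c(0, tpr_a); y <- c(pa[1], pa)
  expect_equal(adjusted_auprc(sc, lb, 0.2, 0.5),
               sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2),
               tolerance = 1e-12)
})

test_that("homotypic fraction equals sum of squared frequencies", {
  expect_equal(homotypic_fraction(rep(1, 10)), 1)
  expect_equal(homotypic_fraction(rep(1:2, each = 5)), 0.5)
  expect_equal(homotypic_fraction(rep(1:3, c(5, 3, 2))), 0.38)
})

test_that("demultiplexing miss rate is 1/k analytically and by simulation", {
  d <- demux_missed_fraction(10, n_pairs = 1e5, seed = 1)
  expect_equal(d$analytic, 0.1)
  expect_lt(abs(d$monte_carlo - 0.1), 3 * d$se)
})

test_that("two-seed evaluation averages detection metrics", {
  sim <- simulate_scrnaseq(n_clusters = 3, n_cells = 300, n_genes = 150,
                           doublet_rate = 0.1, heterotypic_only = TRUE,
                           seed = 8)
  ev <- suppressWarnings(
    evaluate_detection(sim, seeds = c(1, 2), dbr = 0.1, n_features = 100))
  expect_equal(nrow(ev), 3)
  expect_equal(ev$auprc[3], mean(ev$auprc[1:2]))
  expect_equal(ev$true_fraction[1], 0.1)
  expect_true(all(ev$auprc >= 0 & ev$auprc <= 1))
})
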