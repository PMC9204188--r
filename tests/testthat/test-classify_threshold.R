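test_that("expected doublet count follows the rate-per-droplet scaling", {
  r <- expected_doublet_count(10000, het_fraction = 1)
  expect_equal(r$dbr, 0.1)
  expect_equal(r$e, 1000)
  expect_equal(r$e_low, 850)   # (0.1 - 0.015) * 10000
  expect_equal(r$e_high, 1150)
  # two equal clusters: heterotypic fraction 1 - 2 * 0.5^2 = 0.5
  r2 <- expected_doublet_count(10000, het_fraction = 0.5)
  expect_equal(r2$e, 1000)
  expect_equal(r2$e_high, 575)
  expect_equal(r2$dbr * r2$n * r2$het_fraction, 500)
  expect_warning(expected_doublet_count(100, dbr = 0.005, dbr_sd = 0.015),
                 "clamped")
})

test_that("deviation is zero inside the interval and scaled outside", {
  expect_equal(threshold_deviation(15, 10, 20), 0)
  expect_equal(threshold_deviation(10, 10, 20), 0)
  expect_equal(threshold_deviation(20, 10, 20), 0)
  expect_equal(threshold_deviation(0, 10, 20), 2 * 10 / 30)
  expect_equal(threshold_deviation(35, 10, 20), 2 * 15 / 30)
  expect_equal(threshold_deviation(c(0, 15, 35), 10, 20),
               c(2 / 3, 0, 1))
})

test_that("perfectly separated scores give zero cost at any threshold", {
  # e-interval reaching down to zero calls: [0, 40]
  rate <- expected_doublet_count(100, dbr = 0.2, dbr_sd = 0.2)
  ft <- find_threshold(rep(0, 60), rep(1, 40), rate)
  expect_lte(ft$threshold, 1)
  chosen <- attr(ft$context, "chosen")
  expect_equal(chosen$fnr, 0)
  expect_equal(chosen$fpr, 0)
  expect_equal(chosen$cost, 0)
})

test_that("threshold scan equals an exhaustive brute-force oracle", {
  set.seed(77)
  for (rep in 1:200) {
    nr <- sample(5:40, 1); na <- sample(5:40, 1)
    sr <- round(runif(nr), 2)
    sa <- round(runif(na), 2)
    e_mid <- runif(1, 0, nr)
    e_lo <- max(0, e_mid - runif(1, 0, 5))
    e_hi <- e_mid + runif(1, 0, 5)
    rate <- list(e_low = e_lo, e_high = e_hi)
    ft <- find_threshold(sr, sa, rate)
    # oracle: recompute cost at every candidate independently
    cand <- sort(unique(c(0, sr, sa, 1 + 1e-9)))
    cost <- vapply(cand, function(t) {
      fnr <- mean(sa < t)
      fpr <- mean(sr >= t)
      o_t <- sum(sr >= t)
      dev <- if (o_t >= e_lo && o_t <= e_hi) 0 else
        2 * min(abs(o_t - e_lo), abs(o_t - e_hi)) / (e_lo + e_hi)
      fnr + fpr + dev^2
    }, numeric(1))
    expect_equal(min(ft$context$cost), min(cost), tolerance = 1e-12)
    chosen <- attr(ft$context, "chosen")
    # cost decomposition holds exactly at the chosen threshold
    expect_equal(chosen$cost,
                 chosen$fnr + chosen$fpr + chosen$deviation^2)
  }
})

test_that("deviation term can overrule misclassification pressure", {
  # 50 planted real doublets at 0.99 and a matching expected interval:
  # calling them costs FPR but zeroes the deviation
  sr <- c(rep(0, 950), rep(0.99, 50))
  sa <- rep(0.99, 1000)
  rate <- list(e_low = 40, e_high = 60)
  ft <- find_threshold(sr, sa, rate)
  expect_lte(ft$threshold, 0.99)
  expect_equal(sum(sr >= ft$threshold), 50)
})

test_that("FPR ignores droplets called in a previous round", {
  sr <- c(rep(0.95, 10), rep(0.1, 90))
  sa <- rep(0.9, 50)
  rate <- list(e_low = 8, e_high = 12)
  prior <- c(rep(TRUE, 10), rep(FALSE, 90))
  ft <- find_threshold(sr, sa, rate, exclude = prior)
  chosen <- attr(ft$context, "chosen")
  # at the chosen threshold (<= 0.9) all excluded droplets score above it,
  # yet FPR counts only the 90 eligible droplets
  expect_equal(chosen$fpr, mean(sr[!prior] >= ft$threshold))
  # o_t still counts everyone
  expect_equal(chosen$o_t, sum(sr >= ft$threshold))
})

test_that("iterative training separates a perfectly informative predictor", {
  set.seed(30)
  n <- 200
  pt <- tibble::tibble(
    droplet_id = sprintf("d%d", 1:(2 * n)),
    label = factor(rep(c("real", "artificial"), each = n),
                   levels = c("real", "artificial")),
    signal = c(rnorm(n, 0), rnorm(n, 6)),
    noise = rnorm(2 * n),
    include_in_training = TRUE
  )
  rate <- expected_doublet_count(n, dbr = 0.05)
  res <- train_iterative(pt, rate, iterations = 1, seed = 1)
  m <- pr_roc_metrics(c(res$score, attr(res, "artificial_scores")),
                      rep(c(FALSE, TRUE), each = n))
  expect_gte(m$auroc, 0.999)
})

test_that("training runs are reproducible and score within [0, 1]", {
  sim <- default_rna_sim()
  sub <- sim$counts[, 1:400]
  r1 <- detect_doublets(sub, dbr = 0.1, n_features = 200, iterations = 2,
                        seed = 7)
  r2 <- detect_doublets(sub, dbr = 0.1, n_features = 200, iterations = 2,
                        seed = 7)
  expect_identical(r1$score, r2$score)
  expect_identical(attr(r1, "threshold"), attr(r2, "threshold"))
  expect_true(all(r1$score >= 0 & r1$score <= 1))
})

test_that("iterative relabelling removes planted doublets from training", {
  sim <- default_rna_sim()
  res <- default_rna_run()
  pred <- detect_doublets(sim$counts[, 1:800], dbr = 0.1, iterations = 3,
                          n_features = 300, seed = 3,
                          return_predictors = TRUE)
  # artificial scores exceed real scores on average (calibration direction)
  expect_gt(mean(attr(pred, "artificial_scores")), mean(pred$score))
})

test_that("zero planted doublets yields calls bounded by the rate band", {
  clean <- simulate_scrnaseq(n_clusters = 3, n_cells = 500, n_genes = 300,
                             doublet_rate = 0, seed = 17)
  # the clamp warning for dbr - dbr_sd < 0 is expected here
  res <- suppressWarnings(
    detect_doublets(clean$counts, dbr = 0.01, dbr_sd = 0.015, seed = 17))
  expect_lte(mean(res$class == "doublet"), 0.01 + 2 * 0.015)
})

test_that("multi-sample strategies agree on identical captures", {
  sim <- default_rna_sim()
  sub <- sim$counts[, 1:600]
  sample_of <- rep(c("s1", "s2"), each = 300)
  split <- detect_doublets_multisample(sub, sample_of, "split",
                                       dbr = 0.1, n_features = 200, seed = 5)
  comb <- detect_doublets_multisample(sub, sample_of, "combined",
                                      dbr = 0.1, n_features = 200, seed = 5)
  expect_equal(nrow(split), 600)
  expect_equal(split$droplet_id, colnames(sub))
  truth <- sim$truth$type[1:600] != "singlet"
  a_split <- pr_roc_metrics(split$score, truth)$auprc
  a_comb <- pr_roc_metrics(comb$score, truth)$auprc
  expect_lt(abs(a_split - a_comb), 0.1)
})

test_that("combined-mode expected doublets sum per capture", {
  # two captures of 5000 droplets: e = 2 * 5000^2 * 1e-5 = 500, not 1000
  ns <- c(5000, 5000)
  e_total <- sum(ns^2 * 1e-5)
  expect_equal(e_total, 500)
  dbr <- e_total / sum(ns)
  r <- expected_doublet_count(sum(ns), dbr = dbr)
  expect_equal(r$e, 500)
})
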