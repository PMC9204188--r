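test_that("expected combination counts follow 2 p_a p_b renormalization", {
  # three equal clusters, 300 doublets: each of the 3 pairs expects 100
  lab <- rep(1:3, each = 50)
  tab <- expected_combination_counts(lab, 300)
  expect_equal(tab$expected, rep(100, 3))
  # frequencies (0.5, 0.25, 0.25): weights 0.25, 0.25, 0.125 -> 120/120/60
  lab2 <- rep(1:3, c(100, 50, 50))
  tab2 <- expected_combination_counts(lab2, 300)
  expect_equal(sort(tab2$expected, decreasing = TRUE), c(120, 120, 60))
  expect_equal(sum(tab2$expected), 300)
  expect_error(expected_combination_counts(rep(1, 10), 5), "2 clusters")
})

test_that("origin inference recovers planted cross-cluster pairs", {
  sim <- cached("origin_sim", simulate_scrnaseq(n_clusters = 4,
                                                n_cells = 1200,
                                                n_genes = 400,
                                                doublet_rate = 0.1,
                                                seed = 5))
  res <- cached("origin_run", detect_doublets(sim$counts, dbr = 0.1,
                                              seed = 5))
  ori <- infer_origins(res)
  expect_gt(nrow(ori), 20)
  truth <- sim$truth[match(ori$droplet_id, sim$truth$droplet_id), ]
  het <- truth$type == "heterotypic_doublet" & !is.na(truth$origin_a)
  # map detected cluster ids to generating clusters by singlet majority
  cl <- attr(res, "clusters")
  sing <- sim$truth$cluster[match(names(cl$labels), sim$truth$droplet_id)]
  map <- vapply(split(sing, cl$labels), function(x)
    as.integer(names(sort(table(x), decreasing = TRUE))[1]), integer(1))
  ia <- map[as.character(ori$cluster_a)]
  ib <- map[as.character(ori$cluster_b)]
  at_least_one <- (ia == truth$origin_a | ia == truth$origin_b |
                     ib == truth$origin_a | ib == truth$origin_b)
  expect_gte(mean(at_least_one[het], na.rm = TRUE), 0.5)
})

test_that("null stickiness fits give near-zero coefficients", {
  tab <- simulate_doublet_table(rep(1 / 5, 5), 500, dispersion = 5, seed = 1)
  tab$observed <- as.integer(round(tab$expected))
  fit <- stickiness_test(tab, family = "quasibinomial")
  expect_true(all(abs(tidy(fit)$estimate[
    grepl("^cluster", tidy(fit)$term)]) < 0.05))
  g <- glance(fit)
  expect_equal(g$family, "quasibinomial")
  expect_equal(g$n_clusters, 5L)
})

test_that("stickiness power: an inflated cluster is flagged reliably", {
  hits <- 0
  for (r in 1:50) {
    tab <- simulate_doublet_table(rep(1 / 6, 6), 500,
                                  stickiness = c(3, rep(1, 5)),
                                  dispersion = 5, seed = 1000 + r)
    td <- tidy(stickiness_test(tab, family = "quasibinomial"))
    row <- td[td$term == "cluster_1", ]
    hits <- hits + (row$p.value < 0.05 && row$estimate > 0)
  }
  expect_gte(hits / 50, 0.8)
})

test_that("parametric stickiness families run hot on over-dispersed null", {
  rate_for <- function(fam) {
    fp <- 0; tot <- 0
    for (r in 1:50) {
      tab <- simulate_doublet_table(rep(1 / 6, 6), 500, dispersion = 3,
                                    seed = 2000 + r)
      td <- tidy(stickiness_test(tab, family = fam))
      cl <- td[grepl("^cluster", td$term), ]
      fp <- fp + sum(cl$p.value < 0.05)
      tot <- tot + nrow(cl)
    }
    fp / tot
  }
  fp_nb <- rate_for("nb")
  fp_qb <- rate_for("quasibinomial")
  expect_gt(fp_nb, 0.05)
  # the quasi-binomial absorbs the extra variance best (the family ranking)
  expect_lt(fp_qb, fp_nb)
})

test_that("power is monotone in the stickiness factor", {
  power_at <- function(f) {
    hits <- 0
    for (r in 1:40) {
      tab <- simulate_doublet_table(rep(1 / 6, 6), 500,
                                    stickiness = c(f, rep(1, 5)),
                                    dispersion = 5, seed = 3000 + r)
      td <- tidy(stickiness_test(tab, family = "quasibinomial"))
      row <- td[td$term == "cluster_1", ]
      hits <- hits + (row$p.value < 0.05 && row$estimate > 0)
    }
    hits / 40
  }
  pw <- vapply(c(1, 1.5, 2, 3), power_at, numeric(1))
  expect_lt(pw[1], 0.35)          # near the nominal level at factor 1
  expect_gte(pw[4], pw[2] - 0.05) # increasing trend, small MC slack
  expect_gte(pw[4], 0.8)
})

test_that("combination test pinpoints an inflated pair", {
  ce <- rep(1, 10); ce[4] <- 5
  tab <- simulate_doublet_table(rep(1 / 5, 5), 500, combo_enrichment = ce,
                                dispersion = 5, seed = 9)
  ct <- combination_test(tab, family = "nb")
  expect_equal(which.min(ct$p_value), 4L)
  expect_true(all(ct$q_value >= ct$p_value - 1e-12))
})

test_that("combination test at the fitted mean gives large p-values", {
  tab <- simulate_doublet_table(rep(1 / 5, 5), 500, dispersion = 5, seed = 3)
  tab$observed <- as.integer(round(tab$expected))
  ct <- combination_test(tab, family = "nb")
  expect_true(all(ct$p_value >= 0.4))
})

test_that("combination NB variant is anti-conservative on over-dispersed null", {
  fp <- 0; tot <- 0
  for (r in 1:50) {
    tab <- simulate_doublet_table(rep(1 / 6, 6), 600, dispersion = 3,
                                  seed = 4000 + r)
    ct <- combination_test(tab, family = "nb")
    fp <- fp + sum(ct$p_value < 0.05)
    tot <- tot + nrow(ct)
  }
  expect_gt(fp / tot, 0.05)
})

test_that("degenerate enrichment inputs are handled", {
  tab <- simulate_doublet_table(rep(1 / 4, 4), 100, dispersion = 5, seed = 2)
  tab$observed <- 0L
  expect_warning(ct <- combination_test(tab), "no observed")
  expect_true(all(ct$p_value == 1))
  two <- simulate_doublet_table(c(0.5, 0.5), 100, dispersion = 5, seed = 2)
  expect_error(stickiness_test(two), "3 clusters")
})
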