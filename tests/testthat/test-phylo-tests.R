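test_that("the internal F and Wilks statistics match base R fits", {
  set.seed(1)
  x <- rnorm(24)
  g <- factor(rep(letters[1:3], each = 8))
  f_fast <- furculashape:::.fast_f(matrix(x), g)
  f_aov <- anova(stats::lm(x ~ g))$`F value`[1]
  expect_equal(unname(f_fast), f_aov, tolerance = 1e-10)

  X <- matrix(rnorm(24 * 3), 24, 3)
  w_fast <- furculashape:::.wilks(X, g)
  w_man <- summary(stats::manova(X ~ g), test = "Wilks")$stats[1, "Wilks"]
  expect_equal(w_fast, unname(w_man), tolerance = 1e-8)
})

test_that("phylogenetic ANOVA handles degenerate and deterministic cases", {
  tr <- random_tree(12, seed = 2)
  # identical group distributions (same values in both groups): F = 0
  x <- stats::setNames(rep(0:5, each = 2), tr$tip.label)
  g <- stats::setNames(rep(c("a", "b"), 6), tr$tip.label)
  res <- phyl_anova(x, g, tr, n_sim = 99, seed = 1)
  expect_equal(res$statistic, 0, tolerance = 1e-10)
  expect_gt(res$p_phylogenetic, 0.95)

  # identical seeds give identical p-values
  y <- drop(simulate_bm(tr, 1, 0, seed = 3))
  r1 <- phyl_anova(y, g, tr, n_sim = 199, seed = 9)
  r2 <- phyl_anova(y, g, tr, n_sim = 199, seed = 9)
  expect_identical(r1$p_phylogenetic, r2$p_phylogenetic)

  expect_error(phyl_anova(y, stats::setNames(c("a", rep("b", 11)),
                                             tr$tip.label), tr),
               "fewer than 2")
  expect_warning(phyl_anova(y, g, tr, n_sim = 50, seed = 1), "n_sim")
})

test_that("on a star tree the simulation null converges to the classical F test", {
  star <- star_tree(20)
  x <- stats::setNames(rnorm(20), star$tip.label)
  set.seed(4)
  g <- stats::setNames(sample(rep(c("a", "b"), each = 10)),
                       star$tip.label)
  res <- phyl_anova(x, g, star, n_sim = 4999, seed = 5)
  expect_equal(res$p_phylogenetic, res$p_ahistorical, tolerance = 0.03)
})

test_that("clade-structured BM traits inflate the ahistorical p-value", {
  tr <- balanced_tree(16)
  g <- stats::setNames(rep(c("a", "b"), each = 8), tr$tip.label)
  res <- vapply(1:25, function(i) {
    x <- drop(simulate_bm(tr, 1, 0, seed = 500 + i))
    r <- phyl_anova(x, g, tr, n_sim = 199, seed = 600 + i)
    r$p_ahistorical < r$p_phylogenetic
  }, logical(1))
  expect_gte(mean(res), 0.8)
})

test_that("the multivariate phylogenetic MANOVA is calibrated", {
  tr <- random_tree(16, seed = 6)
  set.seed(7)
  rej <- vapply(1:100, function(i) {
    X <- simulate_bm(tr, 1, 0, n_traits = 3, seed = 700 + i)
    g <- stats::setNames(sample(rep(c("a", "b"), each = 8)),
                         tr$tip.label)
    phyl_anova(X, g, tr, n_sim = 199, seed = 800 + i)$p_phylogenetic <=
      0.05
  }, logical(1))
  expect_gte(mean(rej), 0.01)
  expect_lte(mean(rej), 0.11)
})

test_that("phylogenetic Tukey HSD enumerates pairs and flags real shifts", {
  tr <- random_tree(24, seed = 8)
  x <- drop(simulate_bm(tr, 1, 0, seed = 9))
  g <- stats::setNames(rep(c("a", "b", "c", "d"), each = 6), tr$tip.label)
  tk <- phyl_tukey_hsd(x, g, tr, n_sim = 199, seed = 1)
  expect_equal(nrow(tk), 6)  # C(4, 2)

  # a 10-SD mean shift in one group flags all three of its pairs
  x2 <- x
  x2[g == "d"] <- x2[g == "d"] + 10 * stats::sd(x)
  tk2 <- phyl_tukey_hsd(x2, g, tr, n_sim = 199, seed = 1)
  d_pairs <- tk2$group1 == "d" | tk2$group2 == "d"
  expect_true(all(tk2$significant[d_pairs]))

  grid <- tukey_grid(tk2)
  expect_equal(dim(grid), c(4, 4))
  expect_equal(grid["a", "d"], "X")
  expect_equal(grid["a", "a"], "-")
})

test_that("Tukey flags stay near the family-wise rate under the null", {
  tr <- random_tree(16, seed = 10)
  g <- stats::setNames(rep(c("a", "b", "c", "d"), each = 4), tr$tip.label)
  flagged <- vapply(1:40, function(i) {
    x <- drop(simulate_bm(tr, 1, 0, seed = 1000 + i))
    mean(phyl_tukey_hsd(x, g, tr, n_sim = 99, seed = 2000 + i)$significant)
  }, numeric(1))
  expect_lte(mean(flagged), 0.1)
})

test_that("AICc identity holds exactly and models are recovered", {
  # closed form: k = 2, n = 10, logL = -5
  expect_equal(-2 * (-5) + 2 * 2 + 2 * 2 * 3 / (10 - 2 - 1), 15.7143,
               tolerance = 1e-4)
  tr <- random_tree(20, seed = 11)
  x <- drop(simulate_bm(tr, 1, 0, seed = 12))
  tab <- fit_evo_models(x, tr)
  n <- 20
  for (i in seq_len(nrow(tab))) {
    k <- tab$k[i]
    expect_equal(tab$AICc[i],
                 -2 * tab$logL[i] + 2 * k + 2 * k * (k + 1) / (n - k - 1),
                 tolerance = 1e-10)
  }
  expect_equal(tab$dAICc[1], 0)

  # white-noise recovery
  set.seed(13)
  wn_best <- vapply(1:50, function(i) {
    y <- stats::setNames(rnorm(20), tr$tip.label)
    fit_evo_models(y, tr)$model[1] == "WN"
  }, logical(1))
  expect_gte(mean(wn_best), 0.8)

  # Brownian recovery on a deep balanced tree
  bt <- balanced_tree(32)
  bm_best <- vapply(1:50, function(i) {
    y <- drop(simulate_bm(bt, 1, 0, seed = 3000 + i))
    tab <- fit_evo_models(y, bt)
    tab$dAICc[tab$model == "BM"] == 0
  }, logical(1))
  expect_gte(mean(bm_best), 0.7)
})

test_that("phylogenetic RMA has the exact-line and symmetry properties", {
  tr <- random_tree(16, seed = 14)
  x <- drop(simulate_bm(tr, 1, 0, seed = 15))
  y <- 2 * x
  fit <- phyl_rma(x, y, tr)
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  y2 <- y + drop(simulate_bm(tr, 0.5, 0, seed = 16))
  f12 <- phyl_rma(x, y2, tr)
  f21 <- phyl_rma(y2, x, tr)
  expect_equal(f21$slope, 1 / f12$slope, tolerance = 1e-10)

  expect_error(phyl_rma(stats::setNames(rep(1, 16), tr$tip.label), y2,
                        tr), "zero GLS variance")
})

test_that("RMA reduces to the ordinary estimator on a star tree", {
  star <- star_tree(20)
  set.seed(17)
  x <- stats::setNames(rnorm(20), star$tip.label)
  y <- stats::setNames(1.3 * x + rnorm(20, 0, 0.4), star$tip.label)
  fit <- phyl_rma(x, y, star)
  slope_ols <- sign(stats::cov(x, y)) * stats::sd(y) / stats::sd(x)
  expect_equal(fit$slope, slope_ols, tolerance = 1e-8)
  expect_equal(fit$r_squared, stats::cor(x, y)^2, tolerance = 1e-8)
})

test_that("RMA agrees with the phytools implementation", {
  skip_if_not_installed("phytools")
  tr <- random_tree(18, seed = 18)
  x <- drop(simulate_bm(tr, 1, 0, seed = 19))
  y <- 0.5 * x + drop(simulate_bm(tr, 1, 0, seed = 20))
  mine <- phyl_rma(x, y, tr)
  ph <- suppressWarnings(phytools::phyl.RMA(x[tr$tip.label],
                                            y[tr$tip.label], tr,
                                            method = "BM"))
  expect_equal(mine$slope, unname(ph$RMA.beta[2]), tolerance = 1e-6)
  expect_equal(mine$intercept, unname(ph$RMA.beta[1]), tolerance = 1e-6)
})

test_that("assumption diagnostics report the expected tests", {
  set.seed(21)
  X <- matrix(rnorm(60 * 3), 60, 3)
  g <- rep(c("a", "b", "c"), each = 20)
  d <- assumption_diagnostics(X, g)
  expect_setequal(d$test, c("mardia_skewness", "mardia_kurtosis", "box_m"))
  expect_true(all(d$p_value >= 0 & d$p_value <= 1))
})
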