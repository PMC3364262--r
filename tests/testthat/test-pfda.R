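test_that("the whitener satisfies its contract on the training covariance", {
  tr <- random_tree(15, seed = 1)
  sc <- simulate_bm(tr, 1, 0, n_traits = 2, seed = 2)
  g <- stats::setNames(rep(c("A", "B", "C"), each = 5), tr$tip.label)
  for (lam in c(0, 0.5, 1)) {
    m <- pfda_train(sc, g, tr, lam)
    V <- vcv_with_lambda(tr, lam)$V[m$training_ids, m$training_ids]
    expect_lt(max(abs(m$whitener %*% V %*% t(m$whitener) - diag(15))),
              1e-6)
  }
})

test_that("pFDA at lambda 0 on a star tree matches ordinary LDA", {
  skip_if_not_installed("MASS")
  for (s in 1:20) {
    set.seed(s)
    star <- star_tree(30)
    sc <- matrix(rnorm(60), 30, 2,
                 dimnames = list(star$tip.label, c("v1", "v2")))
    sc[1:15, 1] <- sc[1:15, 1] + 2
    g <- stats::setNames(rep(c("A", "B"), each = 15), star$tip.label)
    train <- 1:20
    fit <- pfda_train(sc[train, ], g[train], star, lambda = 0)
    pred <- pfda_predict(fit, sc[-train, ], star)
    ld <- MASS::lda(sc[train, ], grouping = g[train], prior = c(0.5, 0.5))
    po <- stats::predict(ld, sc[-train, ])
    expect_identical(pred$predicted, as.character(po$class))
    expect_equal(pred$posterior, apply(po$posterior, 1, max),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("lambda optimization recovers phylogenetic structure", {
  # single-value grid returns that value
  tr <- random_tree(20, seed = 3)
  sc <- simulate_bm(tr, 1, 0, n_traits = 2, seed = 4)
  g <- stats::setNames(rep(c("A", "B"), each = 10), tr$tip.label)
  one <- optimize_lambda(sc, g, tr, grid = 0.37)
  expect_equal(one$lambda_opt, 0.37)

  # clade-clustered classes with BM traits push lambda high
  bt <- balanced_tree(32)
  hits <- vapply(1:10, function(i) {
    X <- simulate_bm(bt, 1, 0, n_traits = 2, seed = 100 + i)
    gl <- stats::setNames(rep(c("A", "B"), each = 16), bt$tip.label)
    optimize_lambda(X, gl, bt)$lambda_opt >= 0.7
  }, logical(1))
  expect_gte(mean(hits), 0.6)

  # star tree: flat profile flagged
  star <- star_tree(16)
  set.seed(5)
  scs <- matrix(rnorm(32), 16, 2, dimnames = list(star$tip.label, NULL))
  gs <- stats::setNames(rep(c("A", "B"), each = 8), star$tip.label)
  flat <- optimize_lambda(scs, gs, star, grid = seq(0, 1, by = 0.1))
  expect_true(flat$flat_profile)
})

test_that("training behaves on separable, duplicated and degenerate input", {
  star <- star_tree(20)
  sc <- matrix(c(rnorm(10, -4, 0.3), rnorm(10, 4, 0.3), rnorm(20)),
               20, 2, dimnames = list(star$tip.label, c("a", "b")))
  g <- stats::setNames(rep(c("A", "B"), each = 10), star$tip.label)
  fit <- pfda_train(sc, g, star, 0)
  resub <- pfda_predict(fit, sc, star)
  expect_equal(mean(resub$predicted == as.character(g[resub$tip])), 1)

  # duplicated training set keeps the discriminant directions
  star2 <- star_tree(40)
  sc2 <- rbind(sc, sc)
  rownames(sc2) <- star2$tip.label
  g2 <- stats::setNames(rep(as.character(g), 2), star2$tip.label)
  fit2 <- pfda_train(sc2, g2, star2, 0)
  d1 <- fit$directions[, 1] / sqrt(sum(fit$directions[, 1]^2))
  d2 <- fit2$directions[, 1] / sqrt(sum(fit2$directions[, 1]^2))
  expect_lt(min(max(abs(d1 - d2)), max(abs(d1 + d2))), 1e-6)

  expect_error(pfda_train(sc[1:11, ], g[1:11], star, 0), "fewer than 2")
})

test_that("prediction honours phylogenetic position and flags outliers", {
  tr <- random_tree(21, seed = 6)
  sc <- simulate_bm(tr, 1, 0, n_traits = 2, seed = 7)
  sc[1:7, 1] <- sc[1:7, 1] + 4
  g <- stats::setNames(rep(c("A", "B", "C"), each = 7), tr$tip.label)
  train_tips <- tr$tip.label[-21]
  fit <- pfda_train(sc[train_tips, ], g[train_tips], tr, 0.5)

  # an unknown identical in scores and position to a training tip gets
  # that tip's class
  twin_tree <- tr
  twin_tree$tip.label[21] <- "twin"
  twin_scores <- sc[21, , drop = FALSE]
  rownames(twin_scores) <- "twin"
  ref <- pfda_predict(fit, sc[21, , drop = FALSE], tr)
  twin <- pfda_predict(fit, twin_scores, twin_tree)
  expect_identical(twin$predicted, ref$predicted)

  # far outliers are flagged atypical
  out_scores <- matrix(c(60, -60), 1, 2,
                       dimnames = list(tr$tip.label[21], NULL))
  far <- pfda_predict(fit, out_scores, tr)
  expect_true(far$atypical)

  expect_error(pfda_predict(fit, matrix(0, 1, 2,
                                        dimnames = list("ghost", NULL)),
                            tr), "missing from tree")
})

test_that("lambda sweep measures prediction stability", {
  tfl <- parse_newick(
    "(((u:1,a1:1):1,(a2:1,a3:1):1):3,((b1:1,b2:1):1,(b3:1,b4:1):1):3);")
  sc <- matrix(c(-1, -1.1, -0.9, 1, 1.1, 0.9), ncol = 1,
               dimnames = list(c("a1", "a2", "a3", "b1", "b2", "b3"),
                               "ES1"))
  g <- stats::setNames(rep(c("A", "B"), each = 3), rownames(sc))

  # single-lambda grid gives a single column
  stable_unknown <- matrix(-0.95, 1, 1, dimnames = list("u", "ES1"))
  one <- lambda_sweep(sc, g, stable_unknown, tfl, grid = 0.5)
  expect_equal(ncol(one$table), 1)
  full <- lambda_sweep(sc, g, stable_unknown, tfl,
                       grid = seq(0, 1, by = 0.25))
  expect_equal(unname(full$stability["u"]), 1)

  # constructed boundary case: classified A ahistorically but B once the
  # phylogenetic expectation (sister to an A tip) is removed
  boundary <- matrix(-0.05, 1, 1, dimnames = list("u", "ES1"))
  sw <- lambda_sweep(sc, g, boundary, tfl, grid = seq(0, 1, by = 0.1))
  expect_lt(unname(sw$stability["u"]), 1)
  expect_equal(unname(unlist(sw$table["u", 1])), "A")
})

test_that("confusion summaries are exact on degenerate inputs", {
  ident <- confusion_summary(rep(c("x", "y"), 5), rep(c("x", "y"), 5))
  expect_equal(unname(ident$percent_correct), c(100, 100))
  expect_equal(ident$error_rate, 0)

  wrong <- confusion_summary(rep(c("x", "y"), each = 5),
                             rep(c("y", "x"), each = 5))
  expect_equal(unname(wrong$percent_correct), c(0, 0))
  expect_equal(wrong$error_rate, 1)

  expect_error(confusion_summary(c("x", "y"), c("x")), "equal length")

  # column sums equal the true class counts
  set.seed(8)
  tl <- sample(c("p", "q", "r"), 50, replace = TRUE)
  pl <- sample(c("p", "q", "r"), 50, replace = TRUE)
  cm <- confusion_summary(tl, pl)
  expect_equal(unname(colSums(cm$counts)), unname(table(tl)[colnames(cm$counts)]),
               ignore_attr = TRUE)
})

test_that("five synthetic flight modes are recovered by leave-one-out pFDA", {
  ds <- simulate_dataset(c(CF = 12, FG = 12, IB = 12, S = 12, PF = 12),
                         seed = 11)
  prepped <- lapply(ds$profile_curves, function(cv) {
    resample_equal_arclength(orient_standard(cv), 100)
  })
  model <- eigenshape_fit(lapply(prepped, phi_transform))
  sc <- model$scores[, 1:3]
  g <- stats::setNames(ds$metadata$flight_mode, ds$metadata$specimen_id)
  opt <- optimize_lambda(sc, g, ds$tree)
  loo <- pfda_loo(sc, g, ds$tree, opt$lambda_opt)
  expect_gte(loo$accuracy, 0.6)
})
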