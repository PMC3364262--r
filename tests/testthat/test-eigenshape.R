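test_that("phi transform matches analytic turning angles", {
  # collinear points turn nowhere
  line <- cbind(0:4, 0)
  expect_equal(phi_transform(line)$phi, rep(0, 3))
  # a single right-angle corner, counterclockwise positive
  corner <- rbind(c(0, 0), c(1, 0), c(1, 1))
  expect_equal(phi_transform(corner)$phi, pi / 2)
  # semicircular arc of n points: each turning angle pi/(n-1), total
  # turning (n-2)/(n-1)*pi
  th <- seq(0, pi, length.out = 100)
  arc <- cbind(cos(th), sin(th))
  p <- phi_transform(arc)$phi
  expect_lt(diff(range(p)), 1e-12)            # near-constant
  expect_equal(sum(p), 98 / 99 * pi, tolerance = 1e-12)
  # zero-length segment reported by index
  expect_error(phi_transform(rbind(c(0, 0), c(1, 0), c(1, 0), c(2, 0))),
               "zero-length segment at index 2")
})

test_that("phi is invariant to translation, rotation and scale", {
  pts <- random_polyline(30, seed = 11)
  p0 <- phi_transform(pts)$phi
  th <- 0.7
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  p1 <- phi_transform(3.2 * pts %*% t(Rm) +
                        matrix(c(5, -2), 30, 2, byrow = TRUE))$phi
  expect_equal(p1, p0, tolerance = 1e-10)
})

test_that("eigenshape_fit matches a dense eigendecomposition oracle", {
  set.seed(7)
  X <- matrix(rnorm(10 * 98), 10, 98)
  rownames(X) <- paste0("s", 1:10)
  m <- eigenshape_fit(X, use_correlation = TRUE)
  # oracle: eigendecomposition of the standardized covariance
  Xs <- scale(X, center = TRUE, scale = apply(X, 2, sd))
  e <- eigen(stats::cov(Xs), symmetric = TRUE)
  k <- ncol(m$axes)
  for (j in seq_len(k)) {
    err <- min(max(abs(m$axes[, j] - e$vectors[, j])),
               max(abs(m$axes[, j] + e$vectors[, j])))
    expect_lt(err, 1e-8)
  }
  pos <- e$values[e$values > max(e$values) * 1e-10]
  expect_equal(m$variance_fraction, (pos / sum(pos))[seq_len(k)],
               tolerance = 1e-10)
  # scores equal projections of the standardized data (up to axis sign,
  # already fixed identically on both sides here)
  expect_equal(unname(m$scores), unname(Xs %*% m$axes), tolerance = 1e-8)
})

test_that("eigenshape model satisfies its structural invariants", {
  set.seed(8)
  X <- matrix(rnorm(12 * 40), 12, 40)
  m <- eigenshape_fit(X)
  expect_lt(max(abs(crossprod(m$axes) - diag(ncol(m$axes)))), 1e-8)
  expect_equal(sum(m$variance_fraction), 1, tolerance = 1e-9)
  expect_true(all(diff(m$variance_fraction) <= 1e-12))
  expect_lt(max(abs(colMeans(m$scores))), 1e-10)  # mean specimen at origin

  # two distinct specimens span a single axis carrying all variance
  m2 <- eigenshape_fit(X[1:2, ])
  expect_equal(ncol(m2$axes), 1)
  expect_equal(m2$variance_fraction, 1)

  # duplicating every specimen changes neither axes nor variance fractions
  md <- eigenshape_fit(rbind(X, X))
  expect_equal(md$variance_fraction, m$variance_fraction, tolerance = 1e-9)
  expect_equal(abs(md$axes), abs(m$axes), tolerance = 1e-8)

  expect_error(eigenshape_fit(X[1, , drop = FALSE]), "at least 2")
  expect_error(eigenshape_fit(rbind(X[1, ], X[1, ])), "degenerate")
})

test_that("scores are invariant to rigid motion and scaling of all outlines", {
  curves <- angle_sweep_curves(seq(40, 120, length.out = 8))
  phis <- lapply(curves, phi_transform)
  m0 <- suppressWarnings(eigenshape_fit(phis))
  th <- 1.1
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- lapply(curves, function(cv) {
    cv$points <- 2.5 * cv$points %*% t(Rm) +
      matrix(c(-3, 7), nrow(cv$points), 2, byrow = TRUE)
    cv
  })
  m1 <- suppressWarnings(eigenshape_fit(lapply(moved, phi_transform)))
  expect_lt(max(abs(m1$scores - m0$scores)), 1e-8)
})

test_that("reconstruction inverts the decomposition", {
  set.seed(9)
  X <- matrix(rnorm(8 * 58), 8, 58)
  rownames(X) <- paste0("s", 1:8)
  m <- eigenshape_fit(X)
  # zero scores give the mean shape
  mean_rec <- reconstruct_outline(m)
  expect_equal(phi_transform(mean_rec$points)$phi, unname(m$mean_phi),
               tolerance = 1e-10)
  # full score vector reproduces each specimen's phi
  for (i in c(1, 5)) {
    rec <- reconstruct_outline(m, m$scores[i, ])
    expect_equal(phi_transform(rec$points)$phi, unname(X[i, ]),
                 tolerance = 1e-8)
  }
  expect_error(reconstruct_outline(m, rep(0, ncol(m$axes) + 1)),
               "beyond axis count")
})

test_that("sweeping axis 1 sweeps the measured interclavicular angle", {
  angles <- seq(35, 125, length.out = 20)
  curves <- angle_sweep_curves(angles)
  m <- eigenshape_fit(lapply(curves, phi_transform),
                      use_correlation = FALSE)
  sd1 <- stats::sd(m$scores[, 1])
  sweep_scores <- seq(-2 * sd1, 2 * sd1, length.out = 7)
  measured <- vapply(sweep_scores, function(s) {
    rec <- reconstruct_outline(m, c(ES1 = s))
    measure_interclavicular_angle(rec)
  }, numeric(1))
  expect_true(all(diff(measured) > 0) || all(diff(measured) < 0))
})

test_that("extended eigenshape reduces to the standard fit without landmarks", {
  curves <- angle_sweep_curves(seq(50, 110, length.out = 6))
  m_std <- suppressWarnings(eigenshape_fit(lapply(curves, phi_transform)))
  m_ext <- suppressWarnings(extended_eigenshape_fit(curves))
  expect_equal(m_ext$scores, m_std$scores, tolerance = 1e-10)
  expect_equal(m_ext$variance_fraction, m_std$variance_fraction,
               tolerance = 1e-10)
})

test_that("extended eigenshape separates classes differing in epicleideum bend", {
  # curves differ only in the epicleideum bend: clearly distinct class
  # means plus modest within-class spread
  mk <- function(fl, id) {
    cv <- make_furcula_outline(furcula_params(70, 0.4, 0.05, fl, 0.4),
                               "lateral", specimen_id = id)
    resample_equal_arclength(cv, 100)
  }
  set.seed(401)
  fls_a <- rnorm(10, -0.2, 0.03)
  fls_b <- rnorm(10, 0.25, 0.03)
  curves <- c(lapply(1:10, function(i) mk(fls_a[i], paste0("a", i))),
              lapply(1:10, function(i) mk(fls_b[i], paste0("b", i))))
  m <- suppressWarnings(suppressMessages(extended_eigenshape_fit(curves)))
  s1 <- m$scores[1:10, 1]
  s2 <- m$scores[11:20, 1]
  expect_lt(stats::t.test(s1, s2)$p.value, 1e-4)

  bad <- curves
  bad[[1]]$landmark_indices <- integer(0)
  expect_error(extended_eigenshape_fit(bad), "mismatched landmark counts")
})

test_that("combine_views fuses score blocks like PCA of the joint matrix", {
  set.seed(2)
  A <- matrix(rnorm(20 * 3), 20, 3)
  B <- matrix(rnorm(20 * 2), 20, 2)
  f <- combine_views(A, B)
  Z <- scale(cbind(A, B))
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  expect_lt(max(abs(abs(f$scores) - abs(pc$x[, seq_len(ncol(f$scores))]))),
            1e-8)

  # duplicate blocks: fused subspace equals that of one block
  fAA <- combine_views(A, A)
  qa <- qr.Q(qr(scale(A)))
  qf <- qr.Q(qr(fAA$scores[, 1:3]))
  principal_cos <- svd(crossprod(qa, qf))$d
  expect_equal(principal_cos, rep(1, 3), tolerance = 1e-8)

  # two orthogonal unit-variance columns fuse symmetrically
  a <- matrix(rep(c(1, -1), 10), ncol = 1)
  b <- matrix(rep(c(1, 1, -1, -1), 5), ncol = 1)
  f2 <- combine_views(a, b)
  expect_equal(f2$variance_fraction, c(0.5, 0.5), tolerance = 1e-10)

  expect_error(combine_views(A, B[1:10, ]), "different numbers")
})

test_that("curve sensitivity ranks the definition carrying the class signal first", {
  tr <- random_tree(20, seed = 21)
  groups <- stats::setNames(rep(c("g1", "g2"), each = 10), tr$tip.label)
  set.seed(22)
  # signal definition: angles differ by group; null definition: shared
  sig <- lapply(seq_len(20), function(i) {
    ang <- if (i <= 10) 50 else 100
    cv <- make_furcula_outline(furcula_params(ang + rnorm(1, 0, 3),
                                              0.4, 0.05, 0, 0.4),
                               "profile", noise_sd = 0.01, seed = 900 + i,
                               specimen_id = tr$tip.label[i])
    resample_equal_arclength(orient_standard(cv), 60)
  })
  null <- lapply(seq_len(20), function(i) {
    cv <- make_furcula_outline(furcula_params(75 + rnorm(1, 0, 3),
                                              0.4, 0.05, 0, 0.4),
                               "profile", noise_sd = 0.01, seed = 950 + i,
                               specimen_id = tr$tip.label[i])
    resample_equal_arclength(orient_standard(cv), 60)
  })
  rank_tab <- curve_sensitivity(list(outside = sig, inside = null),
                                groups, tr, n_sim = 99, seed = 5)
  expect_equal(rank_tab$definition[1], "outside")
  expect_equal(rank_tab$rank, 1:2)

  one <- curve_sensitivity(list(inside = null), groups, tr,
                           n_sim = 99, seed = 5)
  expect_equal(nrow(one), 1)

  # identical data under two names: deterministic name-order tie-break
  tie <- curve_sensitivity(list(b_def = null, a_def = null), groups, tr,
                           n_sim = 99, seed = 5)
  expect_equal(tie$definition, c("a_def", "b_def"))

  expect_error(curve_sensitivity(list(a = sig, b = null[1:10]), groups, tr),
               "missing specimens")
})
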