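# Simulation-null phylogenetic (M)ANOVA, phylogenetic Tukey HSD,
# evolutionary model comparison by AICc, and phylogenetic RMA regression.

# classical one-way F for one or many trait columns simultaneously
# (x: n x m matrix, one F per column)
.fast_f <- function(x, g) {
  x <- as.matrix(x)
  n <- nrow(x)
  G <- stats::model.matrix(~ g - 1)
  ng <- colSums(G)
  k <- length(ng)
  gm <- (t(G) %*% x) / ng            # group means, k x m
  grand <- colMeans(x)
  ssb <- colSums(ng * (sweep(gm, 2L, grand))^2)
  sst <- colSums(sweep(x, 2L, grand)^2)
  ssw <- sst - ssb
  (ssb / (k - 1)) / (ssw / (n - k))
}

# Wilks' lambda (and Pillai trace) for a multivariate one-way design
.wilks <- function(X, g, stat = "wilks") {
  X <- as.matrix(X)
  G <- stats::model.matrix(~ g - 1)
  ng <- colSums(G)
  gm <- (t(G) %*% X) / ng
  Xc <- X - G %*% gm                  # within-group residuals
  W <- crossprod(Xc)
  Tm <- crossprod(sweep(X, 2L, colMeans(X)))
  B <- Tm - W
  if (stat == "pillai") {
    sum(diag(solve(Tm, B)))
  } else {
    det(W) / det(Tm)
  }
}

# Rao's F approximation for Wilks' lambda
.wilks_f <- function(lambda, p, k, n) {
  q <- k - 1
  vh <- q
  ve <- n - k
  s <- sqrt(ifelse(p^2 + vh^2 - 5 > 0,
                   (p^2 * vh^2 - 4) / (p^2 + vh^2 - 5), 1))
  m <- ve + vh - (p + vh + 1) / 2
  df1 <- p * vh
  df2 <- m * s - p * vh / 2 + 1
  lam_s <- lambda^(1 / s)
  f <- (1 - lam_s) / lam_s * df2 / df1
  list(f = f, df1 = df1, df2 = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# GLS evolutionary rate (matrix) of traits under V
.gls_rate <- function(X, R) {
  X <- as.matrix(X)
  a <- .gls_root(R, X)
  Xc <- sweep(X, 2L, a)
  crossprod(.chol_solve(R, Xc), Xc) / (nrow(X) - 1)
}

#' Simulation-null phylogenetic ANOVA / MANOVA
#'
#' Computes the classical one-way statistic (F for a single trait; Wilks'
#' lambda, reported with Rao's F approximation, for several) and derives a
#' phylogenetic p-value by simulating Brownian-motion traits on the tree --
#' rate (matrix) estimated from the observed data by GLS -- and recomputing
#' the statistic for each replicate. Interrelated species violate the
#' independence assumption of the ahistorical test and inflate its type I
#' error; the simulation null restores calibration. The ahistorical
#' parametric p-value is also reported for comparison.
#'
#' @param traits named vector, or matrix with tip-label rownames.
#' @param groups factor (or vector) of group labels named by tip; every
#'   group needs at least 2 members.
#' @param tree a `phylo` with branch lengths covering the tips.
#' @param n_sim simulation replicates (default 999; fewer than 99 warns).
#' @param seed RNG seed.
#' @param stat multivariate statistic: `"wilks"` (default) or `"pillai"`.
#' @return a `group_test_result`: `statistic_name`, `statistic`,
#'   `statistic_f` (F or Rao's F), `p_ahistorical`, `p_phylogenetic`,
#'   `n_sim`, `seed`.
#' @export
phyl_anova <- function(traits, groups, tree, n_sim = 999L, seed = 1L,
                       stat = c("wilks", "pillai")) {
  stat <- match.arg(stat)
  X <- if (is.matrix(traits) || is.data.frame(traits)) as.matrix(traits)
       else matrix(traits, dimnames = list(names(traits), "trait"))
  .stopifnot_tips(X, tree)
  X <- .match_tips(X, tree)
  if (is.null(names(groups))) {
    stopifnot(length(groups) == nrow(X))
    names(groups) <- rownames(X)
  }
  g <- factor(groups[rownames(X)])
  tab <- table(g)
  if (length(tab) < 2) stop("need at least 2 groups")
  if (any(tab < 2)) {
    stop("group(s) with fewer than 2 members: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  if (n_sim < 99) warning("n_sim < 99 gives a coarse phylogenetic p-value")
  n <- nrow(X)
  m <- ncol(X)
  k <- nlevels(g)
  V <- vcv_with_lambda(tree, 1)$V
  R <- .chol_safe(V)
  L <- t(R)
  set.seed(seed)
  if (m == 1L) {
    obs <- .fast_f(X, g)
    rate <- .gls_rate(X, R)[1L, 1L]
    Z <- L %*% matrix(stats::rnorm(n * n_sim), n) * sqrt(rate)
    null_f <- .fast_f(Z, g)
    res <- list(statistic_name = "F", statistic = unname(obs),
                statistic_f = unname(obs),
                p_ahistorical = unname(stats::pf(obs, k - 1, n - k,
                                                 lower.tail = FALSE)),
                p_phylogenetic = .perm_p(sum(null_f >= obs), n_sim),
                n_sim = n_sim, seed = seed)
  } else {
    obs <- .wilks(X, g, stat)
    rate <- .gls_rate(X, R)
    Lr <- tryCatch(chol(rate), error = function(e)
      chol(rate + diag(1e-10 * mean(diag(rate)), m)))
    null_s <- vapply(seq_len(n_sim), function(i) {
      Z <- (L %*% matrix(stats::rnorm(n * m), n)) %*% Lr
      .wilks(Z, g, stat)
    }, numeric(1))
    extreme <- if (stat == "wilks") sum(null_s <= obs) else
      sum(null_s >= obs)
    rao <- .wilks_f(if (stat == "wilks") obs else NA, m, k, n)
    res <- list(statistic_name = if (stat == "wilks") "Wilks" else "Pillai",
                statistic = obs,
                statistic_f = if (stat == "wilks") rao$f else NA_real_,
                p_ahistorical = if (stat == "wilks") rao$p else NA_real_,
                p_phylogenetic = .perm_p(extreme, n_sim),
                n_sim = n_sim, seed = seed)
  }
  structure(res, class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  cat("<group_test_result> ", x$statistic_name, " = ",
      signif(x$statistic, 5), "; p (ahistorical) = ",
      signif(x$p_ahistorical, 4), "; p (phylogenetic, ", x$n_sim,
      " sims) = ", signif(x$p_phylogenetic, 4), "\n", sep = "")
  invisible(x)
}

#' Phylogenetic Tukey HSD
#'
#' Post-hoc pairwise comparisons between groups after a phylogenetic ANOVA.
#' The studentized-range statistic
#' `q = |mean_i - mean_j| / sqrt(MSW/2 * (1/n_i + 1/n_j))` is computed per
#' pair; the family-wise null distribution of the maximum q comes from the
#' same Brownian simulation machinery as [phyl_anova()], so each pair's
#' p-value is the fraction of simulated maxima at least as large.
#'
#' @inheritParams phyl_anova
#' @param trait named numeric vector by tip.
#' @param alpha significance level for the `significant` flag.
#' @return data.frame with one row per group pair: `group1`, `group2`,
#'   `diff`, `q`, `p_phylogenetic`, `significant`.
#' @export
phyl_tukey_hsd <- function(trait, groups, tree, n_sim = 999L, seed = 1L,
                           alpha = 0.05) {
  .stopifnot_tips(trait, tree)
  x <- .match_tips(trait, tree)
  g <- factor(groups[names(x)])
  tab <- table(g)
  if (length(tab) < 2 || any(tab < 2)) {
    stop("every group needs at least 2 members")
  }
  n <- length(x)
  k <- nlevels(g)
  pair_q <- function(x) {
    mu <- tapply(x, g, mean)
    msw <- sum(tapply(x, g, function(v) sum((v - mean(v))^2))) / (n - k)
    combs <- utils::combn(levels(g), 2)
    q <- apply(combs, 2L, function(pr) {
      se <- sqrt(msw / 2 * (1 / tab[pr[1L]] + 1 / tab[pr[2L]]))
      abs(mu[pr[1L]] - mu[pr[2L]]) / se
    })
    list(q = q, combs = combs, mu = mu)
  }
  obs <- pair_q(x)
  V <- vcv_with_lambda(tree, 1)$V
  R <- .chol_safe(V)
  rate <- .gls_rate(x, R)[1L, 1L]
  set.seed(seed)
  L <- t(R)
  null_max <- vapply(seq_len(n_sim), function(i) {
    z <- drop(L %*% stats::rnorm(n)) * sqrt(rate)
    max(pair_q(z)$q)
  }, numeric(1))
  p <- vapply(obs$q, function(q) .perm_p(sum(null_max >= q), n_sim),
              numeric(1))
  out <- data.frame(group1 = obs$combs[1L, ], group2 = obs$combs[2L, ],
                    diff = obs$mu[obs$combs[1L, ]] - obs$mu[obs$combs[2L, ]],
                    q = obs$q, p_phylogenetic = p,
                    significant = p <= alpha)
  rownames(out) <- NULL
  out
}

#' Pairwise significance grid
#'
#' Reshapes one or more pairwise tables into the symmetric X/- grid layout
#' used for reporting post-hoc comparisons (rows/columns = groups, `X` =
#' significant pair).
#'
#' @param pairs a data.frame from [phyl_tukey_hsd()].
#' @return character matrix with `X`/`-` cells.
#' @export
tukey_grid <- function(pairs) {
  lev <- sort(unique(c(pairs$group1, pairs$group2)))
  M <- matrix("-", length(lev), length(lev), dimnames = list(lev, lev))
  for (i in seq_len(nrow(pairs))) {
    mark <- if (isTRUE(pairs$significant[i])) "X" else "-"
    M[pairs$group1[i], pairs$group2[i]] <- mark
    M[pairs$group2[i], pairs$group1[i]] <- mark
  }
  diag(M) <- "-"
  M
}

# correlation structures for the candidate evolutionary models ------------

.ou_corr <- function(tree, alpha) {
  V <- vcv_with_lambda(tree, 1)$V
  d <- diag(V)
  Dpat <- outer(d, d, "+") - 2 * V      # patristic distances
  (1 / (2 * alpha)) * exp(-alpha * Dpat) * (1 - exp(-2 * alpha * V))
}

.eb_corr <- function(tree, a) {
  V <- vcv_with_lambda(tree, 1)$V
  (exp(a * V) - 1) / a
}

#' Evolutionary model comparison by AICc
#'
#' Fits Brownian motion, Ornstein-Uhlenbeck, Early Burst and white-noise
#' models to a continuous trait by maximum likelihood (rate and root state
#' profiled analytically; the OU strength and EB decay optimized
#' numerically) and ranks them by the small-sample corrected AICc,
#' `AICc = -2 logL + 2k + 2k(k+1)/(n-k-1)`.
#'
#' @param trait named numeric vector by tip (n >= 6).
#' @param tree a `phylo` with branch lengths.
#' @return a `model_fit_table` data.frame: one row per model with
#'   `model`, `logL`, `k`, `AICc`, `dAICc`, `param` (alpha or a),
#'   `sigma2`, `converged`, sorted by AICc.
#' @export
fit_evo_models <- function(trait, tree) {
  .stopifnot_tips(trait, tree)
  if (length(trait) < 6) stop("model comparison needs at least 6 tips")
  x <- .match_tips(trait, tree)
  n <- length(x)
  V <- vcv_with_lambda(tree, 1)$V
  T_depth <- max(diag(V))

  fit_fixed <- function(C) {
    R <- .chol_safe(C)
    a <- .gls_root(R, x)
    r <- x - a
    s2 <- sum(.chol_solve(R, r) * r) / n
    ll <- -0.5 * (n * log(2 * pi) + n * log(s2) + .logdet_chol(R) + n)
    list(logL = ll, sigma2 = s2)
  }

  rows <- list()
  add_row <- function(model, logL, k, param, sigma2, converged = TRUE) {
    aicc <- -2 * logL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
    rows[[length(rows) + 1L]] <<-
      data.frame(model = model, logL = logL, k = k, AICc = aicc,
                 param = param, sigma2 = sigma2, converged = converged)
  }

  bm <- fit_fixed(V)
  add_row("BM", bm$logL, 2L, NA_real_, bm$sigma2)

  wn <- fit_fixed(diag(n))
  add_row("WN", wn$logL, 2L, NA_real_, wn$sigma2)

  ou_ll <- function(la) fit_fixed(.ou_corr(tree, exp(la)))$logL
  ou <- tryCatch({
    o <- stats::optimize(ou_ll, log(c(1e-6 / T_depth, 100 / T_depth)),
                         maximum = TRUE, tol = 1e-6)
    alpha <- exp(o$maximum)
    add_row("OU", o$objective, 3L, alpha,
            fit_fixed(.ou_corr(tree, alpha))$sigma2)
    TRUE
  }, error = function(e) {
    add_row("OU", NA_real_, 3L, NA_real_, NA_real_, converged = FALSE)
    FALSE
  })

  eb_ll <- function(la) fit_fixed(.eb_corr(tree, -exp(la)))$logL
  eb <- tryCatch({
    o <- stats::optimize(eb_ll, log(c(1e-6 / T_depth, 10 / T_depth)),
                         maximum = TRUE, tol = 1e-6)
    a_hat <- -exp(o$maximum)
    add_row("EB", o$objective, 3L, a_hat,
            fit_fixed(.eb_corr(tree, a_hat))$sigma2)
    TRUE
  }, error = function(e) {
    add_row("EB", NA_real_, 3L, NA_real_, NA_real_, converged = FALSE)
    FALSE
  })

  out <- do.call(rbind, rows)
  out$dAICc <- out$AICc - min(out$AICc, na.rm = TRUE)
  out <- out[order(out$AICc), ]
  rownames(out) <- NULL
  class(out) <- c("model_fit_table", class(out))
  out
}

#' Phylogenetic reduced major axis regression
#'
#' RMA (standardized major axis) regression with the (co)variances
#' estimated by GLS under the Brownian covariance of the tree:
#' `slope = sign(cov_xy) * sqrt(var_y / var_x)`, intercept through the GLS
#' root means, R-squared from the squared GLS correlation, and p from the
#' t-test on that correlation.
#'
#' @param x,y named numeric vectors by tip (complete pairs).
#' @param tree a `phylo` with branch lengths.
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
phyl_rma <- function(x, y, tree) {
  .stopifnot_tips(x, tree)
  .stopifnot_tips(y, tree)
  x <- .match_tips(x, tree)
  y <- .match_tips(y, tree)
  if (anyNA(x) || anyNA(y)) stop("x and y must be complete")
  n <- length(x)
  V <- vcv_with_lambda(tree, 1)$V
  R <- .chol_safe(V)
  ax <- .gls_root(R, x)
  ay <- .gls_root(R, y)
  xc <- x - ax
  yc <- y - ay
  Sxx <- sum(.chol_solve(R, xc) * xc) / (n - 1)
  Syy <- sum(.chol_solve(R, yc) * yc) / (n - 1)
  Sxy <- sum(.chol_solve(R, xc) * yc) / (n - 1)
  if (Sxx < 1e-14) stop("zero GLS variance in x")
  r <- Sxy / sqrt(Sxx * Syy)
  slope <- sign(Sxy) * sqrt(Syy / Sxx)
  if (slope == 0) slope <- sqrt(Syy / Sxx)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, 1e-14))
  p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  list(slope = unname(slope), intercept = unname(ay - slope * ax),
       r_squared = unname(r^2), p_value = unname(p), n = n)
}

#' Multivariate normality and homoscedasticity diagnostics
#'
#' Diagnostic report (not a gate) for the assumptions behind the
#' group-comparison tests: Mardia's multivariate skewness and kurtosis
#' tests, and Box's M test of equality of group covariance matrices.
#'
#' @param X specimens x traits matrix.
#' @param groups factor of group labels (for Box's M; optional).
#' @return data.frame with `test`, `statistic`, `p_value`.
#' @export
assumption_diagnostics <- function(X, groups = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  Xc <- sweep(X, 2L, colMeans(X))
  S <- crossprod(Xc) / n
  Sinv <- solve(S + diag(1e-12, p))
  D <- Xc %*% Sinv %*% t(Xc)
  b1 <- sum(D^3) / n^2
  b2 <- mean(diag(D)^2)
  skew_stat <- n * b1 / 6
  skew_df <- p * (p + 1) * (p + 2) / 6
  kurt_stat <- (b2 - p * (p + 2)) / sqrt(8 * p * (p + 2) / n)
  out <- data.frame(
    test = c("mardia_skewness", "mardia_kurtosis"),
    statistic = c(skew_stat, kurt_stat),
    p_value = c(stats::pchisq(skew_stat, skew_df, lower.tail = FALSE),
                2 * stats::pnorm(abs(kurt_stat), lower.tail = FALSE)))
  if (!is.null(groups)) {
    g <- factor(groups)
    ng <- table(g)
    k <- nlevels(g)
    Sp <- matrix(0, p, p)
    logdets <- numeric(k)
    for (i in seq_len(k)) {
      Xi <- X[g == levels(g)[i], , drop = FALSE]
      Si <- stats::cov(Xi)
      Sp <- Sp + (ng[i] - 1) * Si
      logdets[i] <- determinant(Si + diag(1e-12, p))$modulus
    }
    Sp <- Sp / (n - k)
    M <- (n - k) * determinant(Sp + diag(1e-12, p))$modulus -
      sum((ng - 1) * logdets)
    c1 <- (2 * p^2 + 3 * p - 1) / (6 * (p + 1) * (k - 1)) *
      (sum(1 / (ng - 1)) - 1 / (n - k))
    stat <- M * (1 - c1)
    df <- p * (p + 1) * (k - 1) / 2
    out <- rbind(out, data.frame(
      test = "box_m", statistic = as.numeric(stat),
      p_value = stats::pchisq(as.numeric(stat), df, lower.tail = FALSE)))
  }
  out
}
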