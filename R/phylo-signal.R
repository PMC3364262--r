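#' Phylogenetic signal statistics
#'
#' @name phylo_signal
#' @description
#' Four complementary measures of phylogenetic signal in a continuous
#' trait (typically an eigenshape score): Blomberg's K (ratio statistic,
#' K = 1 expected under Brownian motion, permutation test on the variance of
#' independent contrasts), Abouheif's C (Moran-type autocorrelation with the
#' test for serial independence proximity), Pagel's lambda (maximum
#' likelihood, likelihood-ratio test against lambda = 0), and phylogenetic
#' eigenvector regression (PVR, trait regressed on principal coordinates of
#' the patristic distance matrix selected by the broken-stick rule or
#' stepwise AIC). All return a `signal_result`.
NULL

.signal_result <- function(method, statistic, p_value, n_perm = NA_integer_,
                           extras = list()) {
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 n_perm = n_perm, extras = extras),
            class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  cat("<signal_result> ", x$method, ": statistic = ",
      signif(x$statistic, 5), ", p = ", signif(x$p_value, 4),
      if (!is.na(x$n_perm)) paste0(" (", x$n_perm, " permutations)"),
      "\n", sep = "")
  invisible(x)
}

#' Blomberg's K
#'
#' K compares the observed ratio of the ahistorical mean squared error to
#' the phylogenetically corrected one against its Brownian expectation:
#' with GLS root estimate a, `MSE0 = (x-a)'(x-a)/(n-1)`,
#' `MSE = (x-a)'V^-1(x-a)/(n-1)` and expected ratio
#' `(tr V - n/(1'V^-1 1))/(n-1)`. K = 1 under Brownian motion; K > 1 means
#' stronger, K < 1 weaker signal. Significance comes from permuting tip
#' labels and comparing the variance of phylogenetically independent
#' contrasts (signal = observed variance lower than permuted).
#'
#' @param trait named numeric vector by tip (n >= 4).
#' @param tree a `phylo` with branch lengths.
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed.
#' @return a `signal_result` with `method = "K"`.
#' @export
blomberg_k <- function(trait, tree, n_perm = 999L, seed = 1L) {
  .stopifnot_tips(trait, tree)
  if (length(trait) < 4) stop("Blomberg's K needs at least 4 tips")
  x <- .match_tips(trait, tree)
  if (stats::sd(x) < 1e-14) stop("trait has zero variance")
  n <- length(x)
  V <- vcv_with_lambda(tree, 1)$V
  R <- tryCatch(chol(V), error = function(e) {
    stop("singular phylogenetic covariance; consider flooring zero-length ",
         "branches")
  })
  one <- rep(1, n)
  Vi1 <- .chol_solve(R, one)
  a <- sum(Vi1 * x) / sum(Vi1)
  r <- x - a
  mse0 <- sum(r^2) / (n - 1)
  mse <- sum(.chol_solve(R, r) * r) / (n - 1)
  expected <- (sum(diag(V)) - n / sum(Vi1)) / (n - 1)
  K <- (mse0 / mse) / expected
  set.seed(seed)
  obs_vpic <- stats::var(ape::pic(x, tree))
  perm <- replicate(n_perm, {
    xp <- stats::setNames(sample(x), names(x))
    stats::var(ape::pic(xp, tree))
  })
  p <- .perm_p(sum(perm <= obs_vpic), n_perm)
  .signal_result("K", K, p, n_perm,
                 extras = list(mse0 = mse0, mse = mse,
                               expected_ratio = expected,
                               pic_variance = obs_vpic))
}

# Abouheif proximity matrix: A[i, j] = 1 / prod of direct-descendant counts
# of the internal nodes on the path between tips i and j (mrca included);
# diagonal 0.
.abouheif_proximity <- function(tree) {
  n <- length(tree$tip.label)
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  dd <- tabulate(tree$edge[, 1], nbins = n + tree$Nnode)
  anc_path <- lapply(seq_len(n), function(i) {
    path <- integer(0)
    u <- i
    while (parent[u] != 0L) {
      u <- parent[u]
      path <- c(path, u)
    }
    path
  })
  A <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pi_ <- anc_path[[i]]
      pj <- anc_path[[j]]
      mrca <- pi_[match(TRUE, pi_ %in% pj)]
      nodes <- c(pi_[seq_len(which(pi_ == mrca))],
                 pj[seq_len(which(pj == mrca) - 1L)])
      A[i, j] <- A[j, i] <- 1 / prod(dd[nodes])
    }
  }
  A
}

#' Abouheif's C (test for serial independence)
#'
#' Moran-type autocorrelation of the trait under Abouheif's
#' topology-derived proximities (row-normalized), tested by permutation
#' (greater tail).
#'
#' @inheritParams blomberg_k
#' @return a `signal_result` with `method = "abouheif_C"`.
#' @export
abouheif_cmean <- function(trait, tree, n_perm = 999L, seed = 1L) {
  .stopifnot_tips(trait, tree)
  x <- .match_tips(trait, tree)
  if (stats::sd(x) < 1e-14) {
    stop("trait has zero variance: Abouheif's C undefined")
  }
  W <- .abouheif_proximity(tree)
  W <- W / rowSums(W)
  z <- x - mean(x)
  cstat <- function(z) sum(z * (W %*% z)) / sum(z^2)
  obs <- cstat(z)
  set.seed(seed)
  perm <- replicate(n_perm, cstat(sample(z)))
  p <- .perm_p(sum(perm >= obs), n_perm)
  .signal_result("abouheif_C", obs, p, n_perm)
}

#' Pagel's lambda by maximum likelihood
#'
#' Profiles the Brownian rate and root state analytically and maximizes the
#' multivariate-normal log-likelihood over lambda in [0, 1], where lambda
#' scales the off-diagonal phylogenetic covariance. The p-value is a
#' likelihood-ratio test against lambda = 0 using the 50:50
#' chi-squared(0):chi-squared(1) boundary mixture. On a star tree the
#' profile is flat and the result is flagged unidentifiable.
#'
#' @inheritParams blomberg_k
#' @return a `signal_result` with `method = "pagel_lambda"`; `extras`
#'   carries `logL`, `logL0` and `unidentifiable`.
#' @export
pagel_lambda_ml <- function(trait, tree) {
  .stopifnot_tips(trait, tree)
  if (length(trait) < 4) stop("needs at least 4 tips")
  x <- .match_tips(trait, tree)
  V1 <- vcv_with_lambda(tree, 1)$V
  d <- diag(V1)
  ll <- function(lam) {
    V <- V1 * lam
    diag(V) <- d
    .bm_loglik(x, V)
  }
  opt <- stats::optimize(ll, c(0, 1), maximum = TRUE, tol = 1e-6)
  ll0 <- ll(0)
  ll1 <- ll(1)
  flat <- max(opt$objective, ll0, ll1) - min(opt$objective, ll0, ll1) < 1e-6
  lam_hat <- if (opt$objective >= max(ll0, ll1)) opt$maximum else
    if (ll1 > ll0) 1 else 0
  llhat <- max(opt$objective, ll0, ll1)
  lrt <- 2 * (llhat - ll0)
  p <- if (lrt <= 0) 1 else 0.5 * stats::pchisq(lrt, df = 1,
                                                lower.tail = FALSE)
  .signal_result("pagel_lambda", lam_hat, p,
                 extras = list(logL = llhat, logL0 = ll0,
                               unidentifiable = flat))
}

#' Broken-stick expectations
#'
#' Expected ordered eigenvalue fractions under the broken-stick null:
#' `b_k = (1/n) * sum_{i=k}^{n} 1/i`.
#'
#' @param n number of pieces.
#' @return numeric vector of length `n`.
#' @export
broken_stick <- function(n) {
  rev(cumsum(1 / rev(seq_len(n)))) / n
}

#' Phylogenetic eigenvector regression (PVR)
#'
#' Principal-coordinate eigenvectors of the double-centred patristic
#' distance matrix serve as predictors for the trait. Eigenvectors are
#' retained either where their eigenvalue fraction exceeds the broken-stick
#' expectation (leading run) or by stepwise AIC over the leading candidate
#' set. Reports the OLS R-squared, overall F-test p-value, retained
#' eigenvector ids and the cumulative eigenvalue fraction they represent
#' (the "phylogenetic variance explained").
#'
#' @param trait named numeric vector by tip (n >= 5).
#' @param tree a `phylo` with branch lengths.
#' @param selection `"broken_stick"` (default) or `"aic_step"`.
#' @return a `signal_result` with `method = "PVR"`, statistic = R-squared.
#' @export
pvr <- function(trait, tree, selection = c("broken_stick", "aic_step")) {
  selection <- match.arg(selection)
  .stopifnot_tips(trait, tree)
  if (length(trait) < 5) stop("PVR needs at least 5 tips")
  x <- .match_tips(trait, tree)
  n <- length(x)
  D <- ape::cophenetic.phylo(tree)[names(x), names(x)]
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% (D^2) %*% J
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  pos <- which(e$values > max(e$values) * 1e-10)
  vals <- e$values[pos]
  vecs <- e$vectors[, pos, drop = FALSE]
  frac <- vals / sum(vals)
  m <- length(pos)
  if (selection == "broken_stick") {
    bs <- broken_stick(m)
    run <- which(frac <= bs)
    keep <- if (length(run) && run[1L] == 1L) integer(0) else
      seq_len(if (length(run)) run[1L] - 1L else m)
  } else {
    cand <- seq_len(min(m, n - 2L))
    df <- data.frame(x = x, vecs[, cand, drop = FALSE])
    names(df) <- c("x", paste0("V", cand))
    full <- stats::lm(x ~ ., data = df)
    sel <- stats::step(full, direction = "both", trace = 0)
    keep <- as.integer(sub("^V", "", names(stats::coef(sel))[-1L]))
  }
  if (!length(keep)) {
    return(.signal_result("PVR", 0, 1,
                          extras = list(retained = integer(0),
                                        note = "no eigenvector retained",
                                        phylo_variance = 0)))
  }
  fit <- stats::lm(x ~ vecs[, keep, drop = FALSE])
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p <- stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)
  .signal_result("PVR", sm$r.squared, unname(p),
                 extras = list(retained = keep,
                               adj_r_squared = sm$adj.r.squared,
                               phylo_variance = sum(frac[keep]),
                               aic = stats::AIC(fit)))
}

#' Tabulate signal tests across traits
#'
#' Runs Blomberg's K, Abouheif's C, Pagel's lambda and PVR for every column
#' of a score matrix and returns one tidy row per trait x method.
#'
#' @param scores specimens x traits matrix with tip-label rownames.
#' @param tree a `phylo`.
#' @param n_perm permutations for K and C.
#' @param seed RNG seed.
#' @return data.frame with columns `trait`, `method`, `statistic`, `p`,
#'   `n_perm`.
#' @export
signal_table <- function(scores, tree, n_perm = 999L, seed = 1L) {
  scores <- as.matrix(scores)
  rows <- list()
  for (j in seq_len(ncol(scores))) {
    x <- stats::setNames(scores[, j], rownames(scores))
    trait <- colnames(scores)[j]
    if (is.null(trait)) trait <- paste0("trait", j)
    fits <- list(blomberg_k(x, tree, n_perm, seed + j),
                 abouheif_cmean(x, tree, n_perm, seed + j),
                 pagel_lambda_ml(x, tree),
                 pvr(x, tree))
    for (f in fits) {
      rows[[length(rows) + 1L]] <-
        data.frame(trait = trait, method = f$method, statistic = f$statistic,
                   p = f$p_value, n_perm = f$n_perm)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
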