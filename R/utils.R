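# Internal numerical helpers shared across modules.

# Cholesky with a small diagonal jitter fallback; V must be PSD up to
# round-off.  Jitter never exceeds 1e-10 * mean(diag).
.chol_safe <- function(V) {
  out <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(out)) {
    eps <- 1e-10 * mean(diag(V))
    out <- chol(V + diag(eps, nrow(V)))
  }
  out
}

# Solve V x = b through the Cholesky factor.
.chol_solve <- function(R, b) {
  backsolve(R, forwardsolve(t(R), b))
}

# GLS estimate of the phylogenetic (root) mean: a = (1'V^-1 1)^-1 1'V^-1 x.
# `R` is chol(V); x may be a vector or a matrix (one column per trait).
.gls_root <- function(R, x) {
  x <- as.matrix(x)
  one <- matrix(1, nrow(x), 1)
  Vi1 <- .chol_solve(R, one)
  drop(crossprod(Vi1, x) / drop(crossprod(one, Vi1)))
}

# log|V| from the Cholesky factor.
.logdet_chol <- function(R) 2 * sum(log(diag(R)))

# Symmetric inverse square root by eigendecomposition (unique symmetric
# root; small eigenvalues clamped).
.sym_inv_sqrt <- function(M, tol = 1e-12) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, tol * max(e$values))
  e$vectors %*% (t(e$vectors) / sqrt(lam))
}

# Largest-remainder apportionment of `total` into parts proportional to
# `weights`, each part at least `minimum`.  Deterministic: ties broken by
# index order.
.largest_remainder <- function(weights, total, minimum = 0L) {
  k <- length(weights)
  if (total < k * minimum) {
    stop("cannot apportion ", total, " into ", k,
         " parts with minimum ", minimum)
  }
  quota <- weights / sum(weights) * total
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    frac <- quota - base
    ord <- order(-frac, seq_len(k))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  # enforce the minimum by taking from the largest parts
  while (any(base < minimum)) {
    i <- which(base < minimum)[1L]
    j <- which.max(base)
    base[i] <- base[i] + 1
    base[j] <- base[j] - 1
  }
  as.integer(base)
}

# (r + 1) / (n + 1) permutation p-value convention.
.perm_p <- function(n_extreme, n_perm) (n_extreme + 1) / (n_perm + 1)

.stopifnot_tips <- function(x, tree) {
  nm <- if (is.matrix(x) || is.data.frame(x)) rownames(x) else names(x)
  if (is.null(nm)) {
    stop("trait data must be named by tip label")
  }
  missing <- setdiff(nm, tree$tip.label)
  if (length(missing)) {
    stop("tips absent from tree: ", paste(missing, collapse = ", "))
  }
  if (length(nm) != length(tree$tip.label)) {
    stop("trait data must cover every tip of the tree")
  }
  invisible(TRUE)
}

# Reorder a named vector/matrix to the tree tip order.
.match_tips <- function(x, tree) {
  if (is.matrix(x) || is.data.frame(x)) {
    as.matrix(x)[tree$tip.label, , drop = FALSE]
  } else {
    x[tree$tip.label]
  }
}
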