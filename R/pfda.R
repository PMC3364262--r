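# Phylogenetic flexible discriminant analysis: lambda-whitened linear
# discriminants, profile-likelihood lambda optimization, prediction of
# unknown tips, lambda sweeps and confusion summaries.

# C(lambda)^(-1/2) over a set of tips (symmetric eigendecomposition root)
.whitener <- function(tree, tips, lambda) {
  sub <- if (length(setdiff(tree$tip.label, tips))) {
    ape::keep.tip(tree, tips)
  } else {
    tree
  }
  V <- vcv_with_lambda(sub, lambda)$V[tips, tips]
  .sym_inv_sqrt(V)
}

# log-likelihood of the multivariate linear regression of the whitened
# class-indicator matrix on the whitened predictors (Gaussian residuals,
# covariance profiled out)
.fit_loglik <- function(Xw, Yw) {
  n <- nrow(Xw)
  q <- ncol(Yw)
  fit <- stats::lm.fit(cbind(1, Xw), Yw)
  E <- as.matrix(fit$residuals)
  S <- crossprod(E) / n
  ld <- determinant(S + diag(1e-12 * max(diag(S), 1e-300), q))$modulus
  -0.5 * n * (q * log(2 * pi) + as.numeric(ld) + q)
}

#' Optimize Pagel's lambda for phylogenetic discrimination
#'
#' Profiles the discriminant fit over lambda: for each candidate the
#' predictors and the class-indicator matrix are whitened by
#' `C(lambda)^(-1/2)` (C = phylogenetic covariance of the training tips)
#' and the log-likelihood of the multivariate linear regression of
#' whitened indicators on whitened predictors is evaluated. A grid search
#' (step 0.01 by default) is refined by golden-section optimization around
#' the best grid point.
#'
#' @param scores training specimens x traits matrix, rownames = tip labels.
#' @param labels factor (or vector) of class labels named by tip.
#' @param tree a `phylo` containing at least the training tips.
#' @param grid candidate lambda values in [0, 1].
#' @return list with `lambda_opt`, `logL`, `profile` (data.frame `lambda`,
#'   `logL`) and `flat_profile` flag (TRUE when the profile varies by less
#'   than 1e-6, e.g. on a star tree).
#' @export
optimize_lambda <- function(scores, labels, tree,
                            grid = seq(0, 1, by = 0.01)) {
  scores <- as.matrix(scores)
  tips <- rownames(scores)
  if (is.null(tips)) stop("scores must have tip-label rownames")
  g <- factor(labels[tips])
  Y <- stats::model.matrix(~ g)[, -1L, drop = FALSE]
  if (any(grid < 0 | grid > 1)) stop("lambda grid must lie in [0, 1]")
  ll_at <- function(lam) {
    W <- .whitener(tree, tips, lam)
    .fit_loglik(W %*% scores, W %*% Y)
  }
  prof <- vapply(grid, ll_at, numeric(1))
  best <- which.max(prof)
  lambda_opt <- grid[best]
  logL <- prof[best]
  flat <- diff(range(prof)) < 1e-6
  if (!flat && length(grid) > 1L) {
    lo <- grid[max(1L, best - 1L)]
    hi <- grid[min(length(grid), best + 1L)]
    if (hi > lo) {
      o <- stats::optimize(ll_at, c(lo, hi), maximum = TRUE, tol = 1e-5)
      if (o$objective > logL) {
        lambda_opt <- o$maximum
        logL <- o$objective
      }
    }
  }
  list(lambda_opt = lambda_opt, logL = logL,
       profile = data.frame(lambda = grid, logL = prof),
       flat_profile = flat)
}

# linear discriminant machinery on (already whitened) predictors ----------

.lda_fit <- function(X, g, prior = NULL, ridge = 1e-8) {
  k <- nlevels(g)
  p <- ncol(X)
  if (is.null(prior)) prior <- rep(1 / k, k)
  means <- do.call(rbind, lapply(levels(g), function(lv) {
    colMeans(X[g == lv, , drop = FALSE])
  }))
  rownames(means) <- levels(g)
  Xc <- X - means[as.integer(g), , drop = FALSE]
  Sw <- crossprod(Xc) / (nrow(X) - k)
  if (rcond(Sw) < 1e-10) {
    message("pfda: collinear whitened predictors; applying ridge ", ridge)
    Sw <- Sw + diag(ridge * max(diag(Sw), 1), p)
  }
  list(means = means, Sw = Sw, Sw_inv = solve(Sw), prior = prior,
       classes = levels(g))
}

.lda_posterior <- function(fit, X) {
  X <- as.matrix(X)
  k <- nrow(fit$means)
  disc <- sapply(seq_len(k), function(i) {
    mu <- fit$means[i, ]
    drop(X %*% (fit$Sw_inv %*% mu)) -
      0.5 * drop(t(mu) %*% fit$Sw_inv %*% mu) + log(fit$prior[i])
  })
  disc <- matrix(disc, nrow = nrow(X),
                 dimnames = list(rownames(X), fit$classes))
  post <- exp(disc - apply(disc, 1L, max))
  post / rowSums(post)
}

# squared Mahalanobis distance to the nearest class centroid
.lda_mahal_min <- function(fit, X) {
  X <- as.matrix(X)
  d2 <- sapply(seq_len(nrow(fit$means)), function(i) {
    Z <- sweep(X, 2L, fit$means[i, ])
    rowSums((Z %*% fit$Sw_inv) * Z)
  })
  apply(matrix(d2, nrow = nrow(X)), 1L, min)
}

# discriminant variates (canonical directions of Sw^-1 Sb)
.lda_variates <- function(fit, g, X) {
  gm <- fit$means
  grand <- colMeans(X)
  ng <- as.numeric(table(g))
  Sb <- crossprod(sweep(gm, 2L, grand) * sqrt(ng))
  M <- fit$Sw_inv %*% Sb
  e <- eigen(M)
  k <- min(nrow(gm) - 1L, ncol(X))
  dirs <- Re(e$vectors[, seq_len(k), drop = FALSE])
  # deterministic signs
  for (j in seq_len(k)) {
    i <- which.max(abs(dirs[, j]))
    if (dirs[i, j] < 0) dirs[, j] <- -dirs[, j]
  }
  dirs
}

#' Train a phylogenetic flexible discriminant model
#'
#' Whitens the training predictors by `C(lambda)^(-1/2)` -- removing the
#' phylogenetic autocorrelation implied by Brownian motion at strength
#' lambda -- and fits Gaussian linear discriminant functions (pooled
#' within-class covariance, uniform class priors by default) on the
#' whitened data. Predictors are centred on the GLS root estimate before
#' whitening.
#'
#' @param scores training specimens x traits matrix, tip-label rownames.
#' @param labels class labels named by tip; every class needs >= 2 members.
#' @param tree a `phylo` containing the training tips.
#' @param lambda Pagel's lambda in [0, 1] (typically from
#'   [optimize_lambda()]).
#' @param prior `"uniform"` (default) or `"proportional"` class priors.
#' @return a `pfda_model`: `lambda`, `whitener`, `discriminant`,
#'   `classes`, `training_ids`, `scores`, `labels`, `variates`
#'   (training discriminant coordinates), `tree`.
#' @export
pfda_train <- function(scores, labels, tree, lambda,
                       prior = c("uniform", "proportional")) {
  prior <- match.arg(prior)
  scores <- as.matrix(scores)
  tips <- rownames(scores)
  g <- factor(labels[tips])
  tab <- table(g)
  if (nlevels(g) < 2) stop("need at least 2 classes")
  if (any(tab < 2)) {
    stop("class(es) with fewer than 2 training tips: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  W <- .whitener(tree, tips, lambda)
  sub <- if (length(setdiff(tree$tip.label, tips)))
    ape::keep.tip(tree, tips) else tree
  V <- vcv_with_lambda(sub, lambda)$V[tips, tips]
  R <- .chol_safe(V)
  root <- .gls_root(R, scores)
  Xw <- W %*% sweep(scores, 2L, root)
  rownames(Xw) <- tips
  pr <- if (prior == "uniform") NULL else as.numeric(tab) / sum(tab)
  fit <- .lda_fit(Xw, g, prior = pr)
  dirs <- .lda_variates(fit, g, Xw)
  structure(list(lambda = lambda, whitener = W, root = root,
                 discriminant = fit, classes = levels(g),
                 training_ids = tips, scores = scores, labels = g,
                 variates = Xw %*% dirs, directions = dirs, tree = tree,
                 prior = prior),
            class = "pfda_model")
}

#' @export
print.pfda_model <- function(x, ...) {
  cat("<pfda_model> ", length(x$training_ids), " training tips, ",
      length(x$classes), " classes, lambda = ", signif(x$lambda, 4),
      "\n", sep = "")
  invisible(x)
}

#' Predict flight mode for unknown tips
#'
#' Whitens the combined (training + unknown) predictor matrix with
#' `C(lambda)^(-1/2)` built over the full tip set -- so an unknown tip's
#' transform reflects its phylogenetic position -- refits the discriminant
#' on the whitened training rows, and classifies the unknown rows.
#' Predictions far outside the training morphospace are flagged: the
#' typicality p-value is the chi-squared tail of the squared Mahalanobis
#' distance to the nearest class centroid.
#'
#' @param model a `pfda_model`.
#' @param scores_unknown unknown specimens x traits matrix, tip-label
#'   rownames; columns must match the training scores.
#' @param tree_full a `phylo` covering training and unknown tips (defaults
#'   to the tree stored in the model).
#' @param typicality_alpha threshold below which the `atypical` flag is set.
#' @return data.frame with `tip`, `predicted`, `posterior` (max), one
#'   posterior column per class, `typicality`, `atypical`; discriminant
#'   coordinates attached as attribute `"variates"`.
#' @export
pfda_predict <- function(model, scores_unknown, tree_full = model$tree,
                         typicality_alpha = 0.01) {
  stopifnot(inherits(model, "pfda_model"))
  scores_unknown <- as.matrix(scores_unknown)
  unknown <- rownames(scores_unknown)
  if (is.null(unknown)) stop("scores_unknown must have tip-label rownames")
  missing <- setdiff(unknown, tree_full$tip.label)
  if (length(missing)) {
    stop("unknown tip(s) missing from tree: ",
         paste(missing, collapse = ", "))
  }
  tips_all <- c(model$training_ids, unknown)
  W <- .whitener(tree_full, tips_all, model$lambda)
  X_all <- rbind(model$scores, scores_unknown)
  Xw <- W %*% sweep(X_all, 2L, model$root)
  rownames(Xw) <- tips_all
  idx_tr <- seq_along(model$training_ids)
  pr <- if (model$prior == "uniform") NULL else
    as.numeric(table(model$labels)) / length(model$labels)
  fit <- .lda_fit(Xw[idx_tr, , drop = FALSE], model$labels, prior = pr)
  Xu <- Xw[-idx_tr, , drop = FALSE]
  post <- .lda_posterior(fit, Xu)
  d2 <- .lda_mahal_min(fit, Xu)
  typ <- stats::pchisq(d2, df = ncol(Xu), lower.tail = FALSE)
  pred <- fit$classes[max.col(post, ties.method = "first")]
  out <- data.frame(tip = unknown, predicted = pred,
                    posterior = apply(post, 1L, max),
                    typicality = typ,
                    atypical = typ < typicality_alpha,
                    row.names = NULL)
  out <- cbind(out, as.data.frame(post))
  dirs <- .lda_variates(fit, model$labels, Xw[idx_tr, , drop = FALSE])
  attr(out, "variates") <- Xu %*% dirs
  out
}

#' Prediction stability across a lambda sweep
#'
#' Re-trains and re-predicts at every lambda on a grid and tabulates the
#' predicted class of each unknown tip, plus a stability score (fraction of
#' grid values agreeing with the modal class).
#'
#' @inheritParams pfda_train
#' @param scores_unknown unknown specimens x traits matrix.
#' @param grid lambda grid within [0, 1].
#' @return list with `table` (unknown x lambda data.frame of classes) and
#'   `stability` (named numeric vector).
#' @export
lambda_sweep <- function(scores, labels, scores_unknown, tree,
                         grid = seq(0, 1, by = 0.1)) {
  if (any(grid < 0 | grid > 1)) stop("lambda grid must lie in [0, 1]")
  preds <- sapply(grid, function(lam) {
    m <- pfda_train(scores, labels, tree, lam)
    pfda_predict(m, scores_unknown, tree)$predicted
  })
  preds <- matrix(preds, nrow = nrow(scores_unknown),
                  dimnames = list(rownames(scores_unknown),
                                  paste0("lambda_", format(grid))))
  stability <- apply(preds, 1L, function(r) max(table(r)) / length(r))
  list(table = as.data.frame(preds), stability = stability)
}

#' Confusion matrix summary
#'
#' Cross-classification counts with true classes in columns and predicted
#' classes in rows, per-class percent correct (rounded to whole percent,
#' matching the conventional display) and the overall error rate
#' `1 - trace/total`.
#'
#' @param true_labels,predicted_labels equal-length vectors over a shared
#'   class set, or a pre-tabulated square count matrix passed as
#'   `true_labels` (columns = true).
#' @return a `confusion_matrix`: list with `counts`, `percent_correct`,
#'   `error_rate`, `n`.
#' @export
confusion_summary <- function(true_labels, predicted_labels = NULL) {
  if (is.matrix(true_labels) && is.null(predicted_labels)) {
    counts <- as.matrix(true_labels)
    if (nrow(counts) != ncol(counts)) stop("count matrix must be square")
  } else {
    classes <- sort(unique(c(as.character(true_labels),
                             as.character(predicted_labels))))
    if (length(true_labels) != length(predicted_labels)) {
      stop("label vectors must have equal length")
    }
    counts <- table(factor(predicted_labels, levels = classes),
                    factor(true_labels, levels = classes))
    counts <- unclass(as.matrix(counts))
    names(dimnames(counts)) <- NULL
  }
  total <- sum(counts)
  colsum <- colSums(counts)
  pct <- floor(100 * diag(counts) / colsum + 0.5)  # half rounds up
  structure(list(counts = counts,
                 percent_correct = stats::setNames(pct, colnames(counts)),
                 error_rate = 1 - sum(diag(counts)) / total,
                 n = total),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  M <- rbind(x$counts, `% Correct` = paste0(x$percent_correct, "%"))
  print(M, quote = FALSE)
  cat("overall error rate: ", signif(x$error_rate, 4), " (n = ", x$n,
      ")\n", sep = "")
  invisible(x)
}

#' Leave-one-out cross-validated pFDA accuracy
#'
#' Drops each training tip in turn, retrains at the given lambda and
#' predicts the held-out tip from its phylogenetic position and scores.
#'
#' @inheritParams pfda_train
#' @return list with `accuracy`, `predicted` (named vector) and
#'   `confusion` (a `confusion_matrix`).
#' @export
pfda_loo <- function(scores, labels, tree, lambda) {
  scores <- as.matrix(scores)
  tips <- rownames(scores)
  g <- factor(labels[tips])
  preds <- character(length(tips))
  for (i in seq_along(tips)) {
    m <- pfda_train(scores[-i, , drop = FALSE],
                    stats::setNames(as.character(g[-i]), tips[-i]),
                    tree, lambda)
    preds[i] <- pfda_predict(m, scores[i, , drop = FALSE], tree)$predicted
  }
  names(preds) <- tips
  cm <- confusion_summary(as.character(g), preds)
  list(accuracy = mean(preds == as.character(g)), predicted = preds,
       confusion = cm)
}
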