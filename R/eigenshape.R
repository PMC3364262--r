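#' Tangent-angle (phi) transform of a pseudolandmark curve
#'
#' Converts an open curve of n points to its turning-angle function: the
#' signed angle between successive chord segments, wrapped to (-pi, pi].
#' Counterclockwise turns are positive. The transform removes position,
#' rotation and size, leaving pure shape; this is the open-curve form of the
#' Zahn-Roskies representation (no closed-curve ramp subtraction).
#'
#' @param points a `pseudolandmarks`/`outline_curve` object or an n x 2
#'   coordinate matrix (n >= 3).
#' @return An object of class `phi_vector`: list with `specimen_id`, `phi`
#'   (length n - 2) and, when the input carries landmarks, `segment_breaks`.
#' @export
phi_transform <- function(points) {
  sid <- "specimen"
  lm <- integer(0)
  if (inherits(points, "outline_curve")) {
    sid <- points$specimen_id
    lm <- points$landmark_indices
    points <- points$points
  }
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 3) stop("phi transform needs at least 3 points")
  d <- diff(points)
  len2 <- rowSums(d * d)
  if (any(len2 == 0)) {
    stop("zero-length segment at index ", which(len2 == 0)[1L])
  }
  a <- d[-nrow(d), , drop = FALSE]
  b <- d[-1L, , drop = FALSE]
  phi <- atan2(a[, 1] * b[, 2] - a[, 2] * b[, 1],
               a[, 1] * b[, 1] + a[, 2] * b[, 2])
  structure(list(specimen_id = sid, phi = phi, landmark_indices = lm),
            class = "phi_vector")
}

# point count of each landmark-bounded segment (shared landmarks counted
# in both neighbours)
.segment_budgets <- function(curve) {
  p <- curve$points
  lm <- curve$landmark_indices
  lm <- lm[lm > 1L & lm < nrow(p)]
  bounds <- c(1L, lm, nrow(p))
  as.integer(diff(bounds) + 1L)
}

# re-resample each landmark-bounded segment to an explicit point budget
.resample_to_budgets <- function(curve, budgets) {
  p <- curve$points
  lm <- curve$landmark_indices
  lm <- lm[lm > 1L & lm < nrow(p)]
  bounds <- c(1L, lm, nrow(p))
  if (length(budgets) != length(bounds) - 1L) {
    stop("specimen '", curve$specimen_id,
         "' has a different landmark count")
  }
  out <- matrix(NA_real_, 0, 2)
  lm_out <- integer(0)
  for (s in seq_along(budgets)) {
    q <- p[bounds[s]:bounds[s + 1L], , drop = FALSE]
    cl <- c(0, cumsum(sqrt(rowSums(diff(q)^2))))
    tt <- seq(0, cl[length(cl)], length.out = budgets[s])
    seg <- cbind(stats::approx(cl, q[, 1], xout = tt, ties = "ordered")$y,
                 stats::approx(cl, q[, 2], xout = tt, ties = "ordered")$y)
    if (s > 1L) seg <- seg[-1L, , drop = FALSE]
    out <- rbind(out, seg)
    if (s < length(budgets)) lm_out <- c(lm_out, nrow(out))
  }
  res <- outline_curve(out, specimen_id = curve$specimen_id,
                       view = curve$view, landmark_indices = lm_out,
                       curve_definition = curve$curve_definition)
  class(res) <- c("pseudolandmarks", class(res))
  res$n_points <- nrow(out)
  res
}

# Per-segment phi for landmarked curves: turning angles are computed inside
# each landmark-bounded segment only (angles spanning a landmark are
# excluded), then concatenated. Returns list(phi, seg_lengths).
.phi_segments <- function(curve) {
  stopifnot(inherits(curve, "outline_curve"))
  p <- curve$points
  lm <- curve$landmark_indices
  lm <- lm[lm > 1L & lm < nrow(p)]
  bounds <- c(1L, lm, nrow(p))
  phis <- list()
  for (s in seq_len(length(bounds) - 1L)) {
    q <- p[bounds[s]:bounds[s + 1L], , drop = FALSE]
    phis[[s]] <- phi_transform(q)$phi
  }
  list(phi = unlist(phis), seg_lengths = lengths(phis))
}

#' Eigenshape decomposition of phi functions
#'
#' Assembles the specimens x variables matrix of turning angles, mean
#' centres each specimen row against the mean shape, optionally standardizes
#' each phi variable to unit variance (the correlation-matrix option, the
#' default since digitizations may lack scale), and decomposes by SVD.
#' Eigenshape axes are the right singular vectors; specimen scores are
#' `U %*% diag(d)`; variance fractions come from the squared singular
#' values. Axis signs are fixed by requiring the largest-magnitude loading
#' of each axis to be positive.
#'
#' @param phis list of `phi_vector` objects (or a specimens x variables
#'   numeric matrix) with equal phi lengths; at least 2 specimens.
#' @param use_correlation standardize each phi variable to unit variance
#'   (default `TRUE`). Zero-variance variables are dropped with a warning
#'   and recorded in the model.
#' @param open_curve flag stored on the model (the analysis itself is the
#'   open-curve form).
#' @return An `eigenshape_model`: `mean_phi`, `axes` (variables x axes,
#'   orthonormal), `variance_fraction` (non-increasing, sums to 1),
#'   `scores` (specimens x axes), `standardization` (per-variable scale
#'   factors), `dropped` (indices of constant variables), `n_points`,
#'   `open_curve`, `segment_lengths` (extended analyses only).
#' @export
eigenshape_fit <- function(phis, use_correlation = TRUE, open_curve = TRUE) {
  X <- .phi_matrix(phis)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 2) stop("eigenshape analysis needs at least 2 specimens")
  mean_phi <- colMeans(X)
  Xc <- sweep(X, 2L, mean_phi)
  if (max(abs(Xc)) < 1e-12) stop("all specimens identical: degenerate model")
  scale_fac <- rep(1, p)
  dropped <- integer(0)
  if (use_correlation) {
    sds <- apply(X, 2L, stats::sd)
    dropped <- which(sds < 1e-12)
    if (length(dropped)) {
      warning(length(dropped), " constant phi variable(s) dropped from the ",
              "correlation-matrix decomposition")
    }
    scale_fac <- sds
  }
  keep <- setdiff(seq_len(p), dropped)
  Xs <- sweep(Xc[, keep, drop = FALSE], 2L, scale_fac[keep], "/")
  sv <- svd(Xs)
  tol <- max(sv$d) * 1e-10
  k <- sum(sv$d > tol)
  if (k == 0) stop("all specimens identical: degenerate model")
  d <- sv$d[seq_len(k)]
  axes <- sv$v[, seq_len(k), drop = FALSE]
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(d, k)
  # deterministic axis signs
  for (j in seq_len(k)) {
    i <- which.max(abs(axes[, j]))
    if (axes[i, j] < 0) {
      axes[, j] <- -axes[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ids <- rownames(X)
  dimnames(scores) <- list(ids, paste0("ES", seq_len(k)))
  colnames(axes) <- paste0("ES", seq_len(k))
  structure(list(mean_phi = mean_phi, axes = axes,
                 variance_fraction = d^2 / sum(d^2), scores = scores,
                 standardization = scale_fac, dropped = dropped,
                 kept = keep, n_points = p + 2L, open_curve = open_curve,
                 use_correlation = use_correlation,
                 segment_lengths = NULL),
            class = "eigenshape_model")
}

.phi_matrix <- function(phis) {
  if (is.matrix(phis)) {
    if (is.null(rownames(phis))) {
      rownames(phis) <- paste0("specimen", seq_len(nrow(phis)))
    }
    return(phis)
  }
  stopifnot(is.list(phis), length(phis) >= 1)
  lens <- vapply(phis, function(p) length(p$phi), integer(1))
  if (length(unique(lens)) != 1) {
    stop("phi vectors have unequal lengths: ",
         paste(unique(lens), collapse = ", "))
  }
  X <- do.call(rbind, lapply(phis, `[[`, "phi"))
  rownames(X) <- vapply(phis, `[[`, character(1), "specimen_id")
  X
}

#' @export
print.eigenshape_model <- function(x, ...) {
  k <- ncol(x$axes)
  cat("<eigenshape_model> ", nrow(x$scores), " specimens, ", k,
      " axes (", if (x$use_correlation) "correlation" else "covariance",
      " matrix)\n", sep = "")
  vf <- round(100 * x$variance_fraction[seq_len(min(3, k))], 1)
  cat("  variance: ", paste0("ES", seq_along(vf), " ", vf, "%",
                             collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Extended eigenshape decomposition with homologous landmarks
#'
#' For landmarked curves (e.g. lateral views with the ramus/epicleideum
#' interface marked) the turning angles are computed within each
#' landmark-bounded segment and concatenated, so homologous segments occupy
#' homologous variable blocks. With zero landmarks this reduces exactly to
#' [eigenshape_fit()].
#'
#' @param curves list of `pseudolandmarks` objects sharing a landmark count.
#' @inheritParams eigenshape_fit
#' @return An `eigenshape_model` carrying `segment_lengths`.
#' @export
extended_eigenshape_fit <- function(curves, use_correlation = TRUE,
                                    open_curve = TRUE) {
  stopifnot(is.list(curves), length(curves) >= 2)
  n_lm <- vapply(curves, function(cv) length(cv$landmark_indices), integer(1))
  if (length(unique(n_lm)) != 1) {
    stop("specimens have mismatched landmark counts: ",
         paste(unique(n_lm), collapse = ", "))
  }
  # homologous segments must occupy homologous variable blocks: when the
  # per-specimen proportional budgets differ (segment arc lengths vary
  # across specimens), every curve is re-resampled to the budgets of the
  # first specimen
  budgets <- .segment_budgets(curves[[1L]])
  same <- vapply(curves, function(cv) {
    identical(.segment_budgets(cv), budgets)
  }, logical(1))
  if (!all(same)) {
    message("extended_eigenshape_fit: aligning ", sum(!same),
            " specimen(s) to the first specimen's segment budgets")
    curves[!same] <- lapply(curves[!same], .resample_to_budgets, budgets)
  }
  segs <- lapply(curves, .phi_segments)
  seg_lengths <- segs[[1L]]$seg_lengths
  X <- do.call(rbind, lapply(segs, `[[`, "phi"))
  rownames(X) <- vapply(curves, `[[`, character(1), "specimen_id")
  model <- eigenshape_fit(X, use_correlation = use_correlation,
                          open_curve = open_curve)
  model$segment_lengths <- seg_lengths
  model$n_points <- nrow(curves[[1L]]$points)
  model
}

#' Reconstruct outline coordinates from eigenshape scores
#'
#' Rebuilds a phi function as `mean_phi + standardization * (axes %*%
#' scores)` (unspecified axes contribute 0) and integrates it to
#' coordinates: the curve starts at the origin heading along +x with a fixed
#' segment length.
#'
#' @param model an `eigenshape_model`.
#' @param scores numeric vector of axis scores; may be shorter than the
#'   number of axes (remaining axes 0) or named (`ES1`, ...).
#' @param segment_length chord length between consecutive points.
#' @return a `pseudolandmarks` object for the modelled shape.
#' @export
reconstruct_outline <- function(model, scores = numeric(0),
                                segment_length = 1) {
  stopifnot(inherits(model, "eigenshape_model"))
  k <- ncol(model$axes)
  s <- numeric(k)
  if (length(scores)) {
    if (!is.null(names(scores))) {
      idx <- match(names(scores), colnames(model$axes))
      if (anyNA(idx)) stop("unknown axis name: ",
                           names(scores)[which(is.na(idx))[1L]])
      s[idx] <- scores
    } else {
      if (length(scores) > k) {
        stop("score index ", length(scores), " beyond axis count ", k)
      }
      s[seq_along(scores)] <- scores
    }
  }
  p_full <- length(model$mean_phi)
  phi <- model$mean_phi
  contrib <- drop(model$axes %*% s) * model$standardization[model$kept]
  phi[model$kept] <- phi[model$kept] + contrib
  # integrate turning angles to coordinates
  headings <- cumsum(c(0, phi))
  steps <- segment_length * cbind(cos(headings), sin(headings))
  pts <- rbind(c(0, 0), apply(steps, 2L, cumsum))
  res <- outline_curve(pts, specimen_id = "reconstruction")
  class(res) <- c("pseudolandmarks", class(res))
  res$n_points <- nrow(pts)
  res
}

#' Fuse eigenshape scores from two views by SVD
#'
#' Column-standardizes the concatenated score blocks from two analyses of
#' the same specimens (e.g. profile and lateral views) and decomposes the
#' joint matrix by SVD, yielding a single fused score space.
#'
#' @param scores_a,scores_b specimens x axes matrices with identical row
#'   order (rownames checked when present).
#' @return list with `scores` (fused), `axes`, `variance_fraction`.
#' @export
combine_views <- function(scores_a, scores_b) {
  scores_a <- as.matrix(scores_a)
  scores_b <- as.matrix(scores_b)
  if (nrow(scores_a) != nrow(scores_b)) {
    stop("score matrices have different numbers of specimens")
  }
  if (!is.null(rownames(scores_a)) && !is.null(rownames(scores_b)) &&
      !identical(rownames(scores_a), rownames(scores_b))) {
    stop("score matrices have mismatched specimen order")
  }
  Z <- cbind(scores_a, scores_b)
  sds <- apply(Z, 2L, stats::sd)
  Z <- Z[, sds > 1e-12, drop = FALSE]
  if (!ncol(Z)) stop("all score columns are constant")
  Z <- scale(Z, center = TRUE, scale = TRUE)
  sv <- svd(Z)
  tol <- max(sv$d) * 1e-10
  k <- sum(sv$d > tol)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  rownames(scores) <- rownames(scores_a)
  colnames(scores) <- paste0("F", seq_len(k))
  list(scores = scores, axes = sv$v[, seq_len(k), drop = FALSE],
       variance_fraction = sv$d[seq_len(k)]^2 / sum(sv$d[seq_len(k)]^2))
}

#' Curve-definition sensitivity analysis
#'
#' Ranks alternative curve definitions (inside, inside without the
#' hypocleideum, outside, full outline, ...) by how well their eigenshape
#' scores separate the locomotor groups: for each definition the curves are
#' decomposed, the leading axes retained, and a simulation-null phylogenetic
#' MANOVA run; definitions are ranked by the MANOVA separation statistic
#' (ties broken by definition name).
#'
#' @param datasets named list; each element is a list of `pseudolandmarks`
#'   objects for the same specimens under one curve definition.
#' @param groups factor of group labels named by specimen id.
#' @param tree a phylo covering the specimens.
#' @param n_axes number of leading eigenshape axes retained (default 3).
#' @param n_sim simulation replicates for the phylogenetic p-value.
#' @param seed RNG seed for the simulation null.
#' @return data.frame with one row per definition: `definition`,
#'   `statistic` (approximate F from Wilks' lambda), `p_phylogenetic`,
#'   `p_ahistorical`, `rank`.
#' @export
curve_sensitivity <- function(datasets, groups, tree, n_axes = 3L,
                              n_sim = 199L, seed = 1L) {
  stopifnot(is.list(datasets), !is.null(names(datasets)))
  ids <- sort(vapply(datasets[[1L]], `[[`, character(1), "specimen_id"))
  for (nm in names(datasets)) {
    have <- sort(vapply(datasets[[nm]], `[[`, character(1), "specimen_id"))
    if (!identical(have, ids)) {
      stop("definition '", nm, "' missing specimens: ",
           paste(setdiff(ids, have), collapse = ", "))
    }
  }
  rows <- lapply(names(datasets), function(nm) {
    curves <- datasets[[nm]]
    phis <- lapply(curves, phi_transform)
    model <- eigenshape_fit(phis)
    k <- min(n_axes, ncol(model$scores))
    sc <- model$scores[, seq_len(k), drop = FALSE]
    g <- groups[rownames(sc)]
    res <- phyl_anova(sc, g, tree, n_sim = n_sim, seed = seed)
    data.frame(definition = nm, statistic = res$statistic_f,
               p_phylogenetic = res$p_phylogenetic,
               p_ahistorical = res$p_ahistorical)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$statistic, out$definition), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Write eigenshape scores and variance table to CSV
#'
#' @param model an `eigenshape_model`.
#' @param scores_path,variance_path output CSV paths (either may be `NULL`).
#' @export
write_eigenshape_csv <- function(model, scores_path = NULL,
                                 variance_path = NULL) {
  if (!is.null(scores_path)) {
    df <- data.frame(specimen_id = rownames(model$scores), model$scores,
                     check.names = FALSE)
    utils::write.csv(df, scores_path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  }
  if (!is.null(variance_path)) {
    df <- data.frame(axis = colnames(model$axes),
                     variance_fraction = model$variance_fraction,
                     cumulative = cumsum(model$variance_fraction))
    utils::write.csv(df, variance_path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  }
  invisible(model)
}
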