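# Class-conditional synthetic furcula outlines with phylogenetic
# covariance. The generator stands in for undeposited specimen
# photographs: it emits clean parametric curves whose controllable
# features (interclavicular angle, U-vs-V ramus curvature, hypocleideum
# development, omal flare, anteroposterior bowing) mirror the aspects of
# shape the eigenshape axes are interpreted to capture.

#' Furcula shape parameters
#'
#' @param interclavicular_angle_deg angle between the clavicular rami in
#'   profile view, degrees, in (10, 170).
#' @param ramus_curvature 0 = straight (V-shaped) rami, 1 = circular-arc
#'   (U-shaped); in [0, 1].
#' @param hypocleideum_frac length of the midline hypocleideum process as a
#'   fraction of ramus length; in [0, 0.6].
#' @param omal_flare lateral (+) or medial (-) deflection of the omal
#'   (shoulder) ends; in [-0.3, 0.3].
#' @param lateral_curvature anteroposterior bowing of the anterior edge in
#'   lateral view; in [0, 1].
#' @return a `furcula_params` list.
#' @export
furcula_params <- function(interclavicular_angle_deg = 70,
                           ramus_curvature = 0.4,
                           hypocleideum_frac = 0.05,
                           omal_flare = 0,
                           lateral_curvature = 0.4) {
  chk <- function(x, lo, hi, nm, open = FALSE) {
    bad <- if (open) x <= lo || x >= hi else x < lo || x > hi
    if (bad) stop(nm, " = ", x, " outside ",
                  if (open) "(" else "[", lo, ", ", hi,
                  if (open) ")" else "]")
  }
  chk(interclavicular_angle_deg, 10, 170, "interclavicular_angle_deg",
      open = TRUE)
  chk(ramus_curvature, 0, 1, "ramus_curvature")
  chk(hypocleideum_frac, 0, 0.6, "hypocleideum_frac")
  chk(omal_flare, -0.3, 0.3, "omal_flare")
  chk(lateral_curvature, 0, 1, "lateral_curvature")
  structure(list(interclavicular_angle_deg = interclavicular_angle_deg,
                 ramus_curvature = ramus_curvature,
                 hypocleideum_frac = hypocleideum_frac,
                 omal_flare = omal_flare,
                 lateral_curvature = lateral_curvature),
            class = "furcula_params")
}

# circular arc from A to B with sagitta s bulging along unit vector u
# (perpendicular to the chord at its midpoint); m points including both
# endpoints. s = 0 gives a straight line.
.arc_points <- function(A, B, s, u, m) {
  if (abs(s) < 1e-12) {
    t <- seq(0, 1, length.out = m)
    return(cbind(A[1] + t * (B[1] - A[1]), A[2] + t * (B[2] - A[2])))
  }
  c_len <- sqrt(sum((B - A)^2))
  Rr <- (c_len^2 / 4 + s^2) / (2 * s)
  M <- (A + B) / 2
  centre <- M + u * (s - Rr)
  a0 <- atan2(A[2] - centre[2], A[1] - centre[1])
  a1 <- atan2(B[2] - centre[2], B[1] - centre[1])
  # sweep the short way round that passes through the sagitta point
  d <- a1 - a0
  d <- d - 2 * pi * round(d / (2 * pi))
  ang <- a0 + seq(0, 1, length.out = m) * d
  cbind(centre[1] + Rr * cos(ang), centre[2] + Rr * sin(ang))
}

# smooth perpendicular deviation along point normals: a low-frequency
# random field (first 8 Fourier modes, 1/k amplitude decay) emulating
# surface irregularity and tracing error, which vary smoothly along a
# digitized outline rather than point to point
.jitter_curve <- function(pts, sd, modes = 8L) {
  if (sd <= 0) return(pts)
  n <- nrow(pts)
  tang <- rbind(pts[2, ] - pts[1, ],
                pts[3:n, ] - pts[1:(n - 2), ],
                pts[n, ] - pts[n - 1, ])
  tang <- tang / sqrt(rowSums(tang^2))
  normal <- cbind(-tang[, 2], tang[, 1])
  t01 <- seq(0, 1, length.out = n)
  f <- numeric(n)
  for (k in seq_len(modes)) {
    f <- f + stats::rnorm(1) / k * sin(pi * k * t01 + stats::runif(1, 0, 2 * pi))
  }
  f <- f / sqrt(sum(1 / (1:modes)^2) / 2)  # unit marginal sd
  pts + normal * (sd * f)
}

#' Generate a synthetic furcula outline
#'
#' Profile view: two clavicular rami of unit length meeting at the
#' symphysis, separated by the interclavicular angle; ramus curvature sets
#' the arc sagitta (0 = V, 1 = U), the hypocleideum adds a midline process
#' at the symphysis, and omal flare deflects the shoulder ends. Lateral
#' view: the anterior edge as an arc bowed by `lateral_curvature`, with a
#' short epicleideum segment beyond a landmark at the ramus/articular
#' interface whose bend tracks `omal_flare`. Optional Gaussian noise is
#' applied perpendicular to the local tangent, sd = `noise_sd` x ramus
#' length.
#'
#' @param params a [furcula_params()] object.
#' @param view `"profile"` or `"lateral"`.
#' @param n_points number of raw digitized points to emit.
#' @param noise_sd perpendicular noise, as a fraction of ramus length.
#' @param seed RNG seed; required when `noise_sd > 0`.
#' @param specimen_id id stored on the curve.
#' @param curve_definition profile trace variant: `"inside"` (default,
#'   hypocleideum included), `"inside_no_hypocleideum"`, `"outside"` (the
#'   inside trace offset outward by the bone thickness) or
#'   `"full_outline"` (outside then inside, traced as one open curve).
#' @return an [outline_curve()].
#' @export
make_furcula_outline <- function(params, view = c("profile", "lateral"),
                                 n_points = 120L, noise_sd = 0,
                                 seed = NULL, specimen_id = "synthetic",
                                 curve_definition = "inside") {
  stopifnot(inherits(params, "furcula_params"))
  view <- match.arg(view)
  if (noise_sd > 0 && is.null(seed)) {
    stop("seed is required when noise_sd > 0")
  }
  if (!is.null(seed)) set.seed(seed)
  if (view == "profile") {
    pts <- .profile_outline(params, n_points, curve_definition)
    lm <- integer(0)
  } else {
    made <- .lateral_outline(params, n_points)
    pts <- made$pts
    lm <- made$landmark
    curve_definition <- "anterior_edge"
  }
  pts <- .jitter_curve(pts, noise_sd)
  outline_curve(pts, specimen_id = specimen_id, view = view,
                landmark_indices = lm, curve_definition = curve_definition)
}

.profile_ramus <- function(params, side, m) {
  h <- params$interclavicular_angle_deg * pi / 360  # half angle from midline
  E <- c(side * sin(h), cos(h))                      # omal end, unit ramus
  S <- c(0, 0)
  chord <- S - E
  u <- c(chord[2], -chord[1]) / sqrt(sum(chord^2))   # perpendicular
  if (side * u[1] < 0) u <- -u                       # bulge away from midline
  s <- params$ramus_curvature * 0.5
  pts <- .arc_points(E, S, s, u, m)                  # omal -> symphysis
  # omal flare: deflect the shoulder-most 20% of the ramus
  fl <- params$omal_flare
  if (abs(fl) > 0) {
    t <- seq(0, 1, length.out = m)                   # 0 at omal end
    w <- pmax(0, (0.2 - t) / 0.2)^2
    pts[, 1] <- pts[, 1] + side * fl * w
  }
  pts
}

.profile_outline <- function(params, n_points, curve_definition) {
  # the left half is built explicitly and mirrored, so the noiseless
  # outline is exactly symmetric about the midline
  m <- max(20L, floor(n_points / 2))
  left <- .profile_ramus(params, -1, m)               # omal -> symphysis
  f <- params$hypocleideum_frac
  if (curve_definition == "inside_no_hypocleideum") f <- 0
  if (f > 0) {
    k <- max(4L, floor(n_points / 12))
    # trace dips around the midline hypocleideum process: shift the ramus
    # end to (-w, 0) and descend to the process tip at (0, -f)
    w <- 0.02
    left[m, ] <- c(-w, 0)
    down <- cbind(seq(-w, 0, length.out = k), seq(0, -f, length.out = k))
    left <- rbind(left, down[-1, , drop = FALSE])
  }
  mirror <- cbind(-left[, 1], left[, 2])
  pts <- rbind(left, mirror[(nrow(left) - 1L):1, , drop = FALSE])
  if (curve_definition %in% c("outside", "full_outline")) {
    outer_pts <- .offset_outward(pts, 0.05)
    pts <- if (curve_definition == "outside") outer_pts else
      rbind(outer_pts, pts[nrow(pts):1, ])
  }
  pts
}

# offset a profile trace outward (away from the interior of the U/V)
.offset_outward <- function(pts, d) {
  n <- nrow(pts)
  tang <- rbind(pts[2, ] - pts[1, ],
                pts[3:n, ] - pts[1:(n - 2), ],
                pts[n, ] - pts[n - 1, ])
  tang <- tang / sqrt(rowSums(tang^2))
  normal <- cbind(-tang[, 2], tang[, 1])
  centroid <- colMeans(pts)
  out_dir <- sweep(pts, 2L, centroid)
  flip <- rowSums(normal * out_dir) < 0
  normal[flip, ] <- -normal[flip, ]
  pts + d * normal
}

.lateral_outline <- function(params, n_points) {
  m1 <- max(20L, floor(n_points * 0.8))
  m2 <- max(8L, n_points - m1 + 1L)
  s <- params$lateral_curvature * 0.5
  ramus <- .arc_points(c(0, 0), c(1, 0), s, c(0, 1), m1)
  # epicleideum: short articular segment beyond the landmark, bending by
  # an angle tracking omal flare
  tang <- ramus[m1, ] - ramus[m1 - 1L, ]
  tang <- tang / sqrt(sum(tang^2))
  bend <- 0.4 + params$omal_flare
  tt <- seq(0, 1, length.out = m2)
  ang0 <- atan2(tang[2], tang[1])
  ang <- ang0 + bend * tt
  step <- 0.2 / (m2 - 1)
  epi <- matrix(NA_real_, m2, 2)
  epi[1, ] <- ramus[m1, ]
  for (i in 2:m2) {
    epi[i, ] <- epi[i - 1, ] + step * c(cos(ang[i]), sin(ang[i]))
  }
  list(pts = rbind(ramus, epi[-1, , drop = FALSE]), landmark = m1)
}

#' Measure the interclavicular angle of a profile outline
#'
#' Locates the symphysis as the interior point farthest from the chord
#' joining the two omal ends (rotation and translation invariant) and
#' measures the angle between the chords running from it to the two curve
#' ends, in degrees.
#'
#' @param curve an [outline_curve()] or an n x 2 coordinate matrix in
#'   profile view.
#' @return angle in degrees.
#' @export
measure_interclavicular_angle <- function(curve) {
  pts <- if (inherits(curve, "outline_curve")) curve$points else curve
  n <- nrow(pts)
  A <- pts[1, ]
  B <- pts[n, ]
  d <- B - A
  d <- d / sqrt(sum(d * d))
  rel <- sweep(pts, 2L, A)
  dist <- abs(rel[, 1] * d[2] - rel[, 2] * d[1])
  sym <- pts[which.max(dist[2:(n - 1)]) + 1L, ]
  v1 <- A - sym
  v2 <- B - sym
  ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))
  ang * 180 / pi
}

#' Flight-mode parameter profile
#'
#' Default class-conditional means and standard deviations for the shape
#' parameters, a qualitative translation of how the flight modes are
#' understood to differ: soaring birds have wide interclavicular angles and
#' U-shaped (strongly curved) rami; intermittent bounders narrow angles and
#' straight rami; subaqueous (wing-propelled diving) birds strong
#' anteroposterior curvature; poor/burst-adapted fliers minimal
#' anteroposterior curvature and a developed hypocleideum; non-avian
#' theropod-grade ("preflight") furculae are wide-open and nearly straight.
#' The magnitudes are synthetic defaults, not fitted values.
#'
#' @param clustering strength in [0, 1] with which classes cluster into
#'   clades on a simulated tree (1 = perfectly clade-wise).
#' @return a `flight_mode_profile` data.frame (one row per class, columns
#'   `<param>_mean` and `<param>_sd`) with attribute `clustering`.
#' @export
flight_mode_profile <- function(clustering = 0.8) {
  classes <- c("CF", "FG", "IB", "S", "PF", "SUB", "preflight")
  df <- data.frame(
    class = classes,
    interclavicular_angle_deg_mean = c(65, 80, 35, 115, 55, 50, 140),
    ramus_curvature_mean = c(0.45, 0.55, 0.08, 0.85, 0.30, 0.35, 0.15),
    hypocleideum_frac_mean = c(0.05, 0.05, 0.10, 0.02, 0.20, 0.05, 0.00),
    omal_flare_mean = c(0.00, 0.05, -0.05, 0.10, -0.10, 0.00, 0.00),
    lateral_curvature_mean = c(0.45, 0.50, 0.35, 0.40, 0.08, 0.90, 0.10),
    interclavicular_angle_deg_sd = 6,
    ramus_curvature_sd = 0.06,
    hypocleideum_frac_sd = 0.03,
    omal_flare_sd = 0.04,
    lateral_curvature_sd = 0.08)
  attr(df, "clustering") <- clustering
  class(df) <- c("flight_mode_profile", class(df))
  df
}

.param_ranges <- list(
  interclavicular_angle_deg = c(10.5, 169.5),
  ramus_curvature = c(0, 1),
  hypocleideum_frac = c(0, 0.6),
  omal_flare = c(-0.3, 0.3),
  lateral_curvature = c(0, 1))

#' Simulate a class-conditional outline dataset on a phylogeny
#'
#' Draws per-specimen shape parameters as class mean + a mixture of a
#' Brownian-motion deviation on the tree (weight `bm_fraction`) and an
#' i.i.d. deviation (weight `1 - bm_fraction`), both scaled to the class
#' standard deviation and clipped to the valid parameter ranges, then emits
#' profile and lateral outlines per specimen, a metadata table (including a
#' log body-mass column positively correlated with interclavicular angle)
#' and the tree. Classes are assigned clade-wise with the profile's
#' clustering strength. If no tree is given a pure-birth tree is simulated.
#'
#' @param n_per_class named integer vector, e.g. `c(CF = 10, S = 10)`;
#'   every class needs >= 2.
#' @param profile a [flight_mode_profile()].
#' @param tree optional `phylo` with as many tips as specimens.
#' @param bm_fraction weight of the phylogenetic (Brownian) component of
#'   parameter deviations, in [0, 1].
#' @param noise_sd digitization noise passed to [make_furcula_outline()].
#' @param seed RNG seed (required; drives tree, parameters and noise).
#' @return list with `profile_curves`, `lateral_curves` (lists of
#'   [outline_curve()]), `params` (data.frame), `metadata` (data.frame with
#'   `specimen_id`, `flight_mode`, `log_mass`), `tree`.
#' @export
simulate_dataset <- function(n_per_class, profile = flight_mode_profile(),
                             tree = NULL, bm_fraction = 0.5,
                             noise_sd = 0.01, seed) {
  if (missing(seed)) stop("seed is required")
  if (any(n_per_class < 2)) stop("n_per_class must be at least 2 per class")
  classes <- names(n_per_class)
  if (is.null(classes) || !all(classes %in% profile$class)) {
    stop("n_per_class must be named by classes present in the profile")
  }
  if (bm_fraction < 0 || bm_fraction > 1) {
    stop("bm_fraction must lie in [0, 1]")
  }
  n <- sum(n_per_class)
  set.seed(seed)
  if (is.null(tree)) {
    tree <- ape::rphylo(n, birth = 1, death = 0)
    tree$tip.label <- sprintf("sp%03d", seq_len(n))
  }
  if (length(tree$tip.label) != n) {
    stop("tree must have exactly ", n, " tips")
  }
  # clade-wise class assignment: contiguous blocks in cladewise tip order,
  # then a fraction (1 - clustering) of tips shuffled among themselves
  edge <- reorder(tree, "cladewise")$edge
  tip_order <- edge[edge[, 2] <= n, 2]
  labels <- rep(classes, n_per_class)
  assign <- character(n)
  assign[tip_order] <- labels
  s <- attr(profile, "clustering")
  if (is.null(s)) s <- 0.8
  n_shuffle <- round((1 - s) * n)
  if (n_shuffle >= 2) {
    idx <- sample(n, n_shuffle)
    assign[idx] <- assign[sample(idx)]
  }
  names(assign) <- tree$tip.label
  # per-parameter deviations: BM component + iid component
  pnames <- names(.param_ranges)
  prof <- profile[match(assign, profile$class), ]
  params <- matrix(NA_real_, n, length(pnames),
                   dimnames = list(tree$tip.label, pnames))
  for (j in seq_along(pnames)) {
    bm <- drop(simulate_bm(tree, sigma2 = 1, seed = seed + 100 * j))
    bm <- bm / max(stats::sd(bm), 1e-12)
    iid <- stats::rnorm(n)
    dev <- bm_fraction * bm + (1 - bm_fraction) * iid
    mu <- prof[[paste0(pnames[j], "_mean")]]
    sdv <- prof[[paste0(pnames[j], "_sd")]]
    val <- mu + sdv * dev
    rng <- .param_ranges[[pnames[j]]]
    params[, j] <- pmin(pmax(val, rng[1]), rng[2])
  }
  log_mass <- 1.5 + 0.015 * (params[, "interclavicular_angle_deg"] - 70) +
    stats::rnorm(n, 0, 0.25)
  prof_curves <- vector("list", n)
  lat_curves <- vector("list", n)
  for (i in seq_len(n)) {
    fp <- do.call(furcula_params, as.list(params[i, ]))
    prof_curves[[i]] <- make_furcula_outline(
      fp, "profile", noise_sd = noise_sd, seed = seed + 7 * i,
      specimen_id = tree$tip.label[i])
    lat_curves[[i]] <- make_furcula_outline(
      fp, "lateral", noise_sd = noise_sd, seed = seed + 7 * i + 3,
      specimen_id = tree$tip.label[i])
  }
  list(profile_curves = prof_curves, lateral_curves = lat_curves,
       params = as.data.frame(params),
       metadata = data.frame(specimen_id = tree$tip.label,
                             flight_mode = unname(assign),
                             log_mass = unname(log_mass)),
       tree = tree)
}

#' Write a simulated dataset to a directory
#'
#' Emits a self-contained dataset: `outlines_profile.csv`,
#' `outlines_lateral.csv` (long point format), `metadata.csv`,
#' `tree.nwk` and a `config.txt` echo of the generation settings.
#'
#' @param dataset result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @param config optional named list echoed to `config.txt`.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, config = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_outline_csv(dataset$profile_curves,
                    file.path(dir, "outlines_profile.csv"))
  write_outline_csv(dataset$lateral_curves,
                    file.path(dir, "outlines_lateral.csv"))
  utils::write.csv(dataset$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  writeLines(write_newick(dataset$tree), file.path(dir, "tree.nwk"))
  cfg <- c(sprintf("n_specimens=%d", nrow(dataset$metadata)),
           vapply(names(config), function(k) {
             sprintf("%s=%s", k, format(config[[k]]))
           }, character(1)))
  writeLines(cfg, file.path(dir, "config.txt"))
  invisible(dir)
}
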