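#' Digitized outline curve
#'
#' Container for one digitized outline of a furcula (or any open 2D curve):
#' an ordered point sequence in arbitrary image units, optionally with
#' interior landmarks marking homologous segment boundaries (used by the
#' extended eigenshape analysis), and a curve-definition tag recording which
#' edge of the bone was traced.
#'
#' @param points numeric matrix (n x 2) of ordered (x, y) coordinates.
#' @param specimen_id character scalar identifying the specimen.
#' @param view `"profile"` (anterior view of both rami) or `"lateral"`.
#' @param landmark_indices strictly increasing integer indices into the rows
#'   of `points` marking interior landmarks; may be empty.
#' @param curve_definition which curve was traced; one of `"inside"`,
#'   `"inside_no_hypocleideum"`, `"outside"`, `"full_outline"`,
#'   `"anterior_edge"`.
#' @return An object of class `outline_curve`.
#' @export
outline_curve <- function(points, specimen_id = "specimen",
                          view = c("profile", "lateral"),
                          landmark_indices = integer(0),
                          curve_definition = c("inside",
                                               "inside_no_hypocleideum",
                                               "outside", "full_outline",
                                               "anterior_edge")) {
  view <- match.arg(view)
  curve_definition <- match.arg(curve_definition)
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2) {
    stop("points must be a numeric n x 2 matrix")
  }
  if (nrow(points) < 3) stop("an outline curve needs at least 3 points")
  d <- diff(points)
  if (any(rowSums(d * d) == 0)) {
    stop("consecutive duplicate points at index ",
         which(rowSums(d * d) == 0)[1L])
  }
  landmark_indices <- as.integer(landmark_indices)
  if (length(landmark_indices)) {
    if (is.unsorted(landmark_indices, strictly = TRUE) ||
        min(landmark_indices) < 1 || max(landmark_indices) > nrow(points)) {
      stop("landmark_indices must be strictly increasing and in range")
    }
  }
  dimnames(points) <- list(NULL, c("x", "y"))
  structure(list(specimen_id = as.character(specimen_id), view = view,
                 points = points, landmark_indices = landmark_indices,
                 curve_definition = curve_definition),
            class = "outline_curve")
}

#' @export
print.outline_curve <- function(x, ...) {
  cat("<outline_curve> ", x$specimen_id, " [", x$view, ", ",
      x$curve_definition, "]: ", nrow(x$points), " points, ",
      length(x$landmark_indices), " landmarks\n", sep = "")
  invisible(x)
}

#' Read a TPS digitization file
#'
#' Parses the tpsDig dialect of the TPS format: records start with `LM=n`
#' followed by `n` whitespace-separated coordinate lines; optional
#' `CURVES=k` / `POINTS=m` blocks append further digitized points; `ID=`,
#' `IMAGE=` and `SCALE=` lines are recognised. Scale factors are ignored:
#' the downstream tangent-angle transform is scale free. Specimen ids come
#' from `ID=`, falling back to `IMAGE=` and then to the record index.
#'
#' @param path path to a TPS file.
#' @param view,curve_definition tags applied to every curve read.
#' @param flip_y if `TRUE`, negate y to convert image-origin (y-down)
#'   coordinates to the mathematical y-up convention used throughout;
#'   default off.
#' @return list of [outline_curve()] objects in file order.
#' @export
read_tps <- function(path, view = "profile", curve_definition = "inside",
                     flip_y = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty TPS file: ", path)
  starts <- grep("^LM\\s*=", lines, ignore.case = TRUE)
  if (!length(starts)) stop("no LM= records found in ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  curves <- vector("list", length(starts))
  for (r in seq_along(starts)) {
    block <- lines[starts[r]:ends[r]]
    n_lm <- as.integer(sub("^LM\\s*=\\s*", "", block[1L], ignore.case = TRUE))
    coords <- list()
    id <- NA_character_
    image <- NA_character_
    declared <- n_lm
    i <- 2L
    expect <- n_lm
    while (i <= length(block)) {
      ln <- block[i]
      if (grepl("^POINTS\\s*=", ln, ignore.case = TRUE)) {
        m <- as.integer(sub("^POINTS\\s*=\\s*", "", ln, ignore.case = TRUE))
        declared <- declared + m
        expect <- expect + m
      } else if (grepl("^CURVES\\s*=", ln, ignore.case = TRUE)) {
        # number of appended curve blocks; their POINTS= lines carry counts
      } else if (grepl("^ID\\s*=", ln, ignore.case = TRUE)) {
        id <- sub("^ID\\s*=\\s*", "", ln, ignore.case = TRUE)
      } else if (grepl("^IMAGE\\s*=", ln, ignore.case = TRUE)) {
        image <- sub("^IMAGE\\s*=\\s*", "", ln, ignore.case = TRUE)
      } else if (grepl("^SCALE\\s*=", ln, ignore.case = TRUE)) {
        # scale discarded: shape analysis is size free
      } else {
        xy <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1L]]))
        if (length(xy) != 2 || anyNA(xy)) {
          stop("unparseable line in TPS record ", r, ": '", ln, "'")
        }
        coords[[length(coords) + 1L]] <- xy
      }
      i <- i + 1L
    }
    if (length(coords) != declared) {
      stop("TPS record ", r, if (!is.na(id)) paste0(" ('", id, "')"),
           ": declared ", declared, " points but parsed ", length(coords))
    }
    pts <- do.call(rbind, coords)
    if (flip_y) {
      pts[, 2] <- -pts[, 2]
      message("read_tps: flipped y axis for record ", r)
    }
    sid <- if (!is.na(id)) id else if (!is.na(image)) image else as.character(r)
    curves[[r]] <- outline_curve(pts, specimen_id = sid, view = view,
                                 curve_definition = curve_definition)
  }
  curves
}

#' Standardize curve orientation to left-to-right
#'
#' Furcula traces run from the left omal end to the right; a curve digitized
#' right-to-left is reversed (landmark indices remapped `i -> n + 1 - i`).
#' Translation and rotation are untouched. A vertically degenerate curve
#' (equal first/last x) is oriented bottom-to-top by y, with a message.
#'
#' @param curve an [outline_curve()].
#' @param tol tolerance for the x tie.
#' @return an [outline_curve()] running left to right.
#' @export
orient_standard <- function(curve, tol = 1e-12) {
  stopifnot(inherits(curve, "outline_curve"))
  p <- curve$points
  n <- nrow(p)
  dx <- p[n, 1] - p[1, 1]
  reverse <- if (abs(dx) <= tol) {
    message("orient_standard: vertical curve '", curve$specimen_id,
            "', orienting by y")
    p[n, 2] < p[1, 2]
  } else {
    dx < 0
  }
  if (reverse) {
    curve$points <- p[n:1, , drop = FALSE]
    if (length(curve$landmark_indices)) {
      curve$landmark_indices <- sort(n + 1L - curve$landmark_indices)
    }
  }
  curve
}

#' Resample a curve to equally spaced pseudolandmarks
#'
#' Interpolates `n_points` points at equal arc-length spacing along the
#' piecewise-linear curve (the standard semilandmark treatment; 100 points
#' capture furcular outlines well). Interior landmarks are retained exactly
#' and each landmark-bounded segment receives a point budget proportional to
#' its arc length (largest-remainder rounding, minimum 2 points per
#' segment), so spacing is equal within each segment.
#'
#' @param curve an [outline_curve()].
#' @param n_points total number of output points (default 100).
#' @return An object of class `pseudolandmarks`: like an outline curve but
#'   with exactly `n_points` points and remapped `landmark_indices`.
#' @export
resample_equal_arclength <- function(curve, n_points = 100L) {
  stopifnot(inherits(curve, "outline_curve"))
  n_points <- as.integer(n_points)
  if (n_points < 3) stop("n_points must be at least 3")
  p <- curve$points
  lm <- curve$landmark_indices
  lm <- lm[lm > 1L & lm < nrow(p)]  # endpoints are implicit boundaries
  bounds <- c(1L, lm, nrow(p))
  n_seg <- length(bounds) - 1L
  seg_len <- numeric(n_seg)
  for (s in seq_len(n_seg)) {
    q <- p[bounds[s]:bounds[s + 1L], , drop = FALSE]
    seg_len[s] <- sum(sqrt(rowSums(diff(q)^2)))
  }
  if (sum(seg_len) <= 0) stop("curve has zero total arc length")
  # shared interior landmarks are counted once
  budget <- .largest_remainder(seg_len, n_points + n_seg - 1L, minimum = 2L)
  out <- matrix(NA_real_, 0, 2)
  lm_out <- integer(0)
  for (s in seq_len(n_seg)) {
    q <- p[bounds[s]:bounds[s + 1L], , drop = FALSE]
    cl <- c(0, cumsum(sqrt(rowSums(diff(q)^2))))
    tt <- seq(0, cl[length(cl)], length.out = budget[s])
    xs <- stats::approx(cl, q[, 1], xout = tt, ties = "ordered")$y
    ys <- stats::approx(cl, q[, 2], xout = tt, ties = "ordered")$y
    seg_pts <- cbind(xs, ys)
    if (s > 1L) seg_pts <- seg_pts[-1L, , drop = FALSE]  # shared landmark
    out <- rbind(out, seg_pts)
    if (s < n_seg) lm_out <- c(lm_out, nrow(out))
  }
  stopifnot(nrow(out) == n_points)
  res <- outline_curve(out, specimen_id = curve$specimen_id,
                       view = curve$view,
                       landmark_indices = lm_out,
                       curve_definition = curve$curve_definition)
  class(res) <- c("pseudolandmarks", class(res))
  res$n_points <- n_points
  res
}

#' Write outline curves to CSV
#'
#' Long format, one row per point, with the exact header
#' `specimen_id,view,point_index,x,y,is_landmark`.
#'
#' @param curves list of [outline_curve()] objects.
#' @param path output file.
#' @export
write_outline_csv <- function(curves, path) {
  if (inherits(curves, "outline_curve")) curves <- list(curves)
  rows <- lapply(curves, function(cv) {
    n <- nrow(cv$points)
    data.frame(specimen_id = cv$specimen_id, view = cv$view,
               point_index = seq_len(n),
               x = cv$points[, 1], y = cv$points[, 2],
               is_landmark = as.integer(seq_len(n) %in% cv$landmark_indices))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read outline curves from CSV
#'
#' Inverse of [write_outline_csv()]; curves are grouped by
#' `(specimen_id, view)` and points ordered by `point_index`.
#'
#' @param path CSV file with header
#'   `specimen_id,view,point_index,x,y,is_landmark`.
#' @param curve_definition tag applied to every curve read.
#' @return list of [outline_curve()] objects.
#' @export
read_outline_csv <- function(path, curve_definition = "inside") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("specimen_id", "view", "point_index", "x", "y", "is_landmark")
  if (!identical(names(df)[seq_along(need)], need)) {
    stop("outline CSV must have header: ", paste(need, collapse = ","))
  }
  key <- interaction(df$specimen_id, df$view, drop = TRUE)
  lapply(split(df, key), function(g) {
    g <- g[order(g$point_index), ]
    outline_curve(cbind(g$x, g$y), specimen_id = g$specimen_id[1L],
                  view = g$view[1L],
                  landmark_indices = which(g$is_landmark == 1),
                  curve_definition = curve_definition)
  })
}
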