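test_that("read_tps parses minimal records and preserves file order", {
  path <- write_tps_fixture("LM=3\n0 0\n1 0\n2 1\nID=spec1")
  curves <- read_tps(path)
  expect_length(curves, 1)
  expect_equal(curves[[1]]$specimen_id, "spec1")
  expect_equal(nrow(curves[[1]]$points), 3)
  expect_equal(curves[[1]]$points[, "x"], c(0, 1, 2))

  path2 <- write_tps_fixture(
    "LM=3\n0 0\n1 0\n2 1\nID=a\nLM=4\n0 0\n1 1\n2 0\n3 1\nID=b")
  curves2 <- read_tps(path2)
  expect_length(curves2, 2)
  expect_equal(vapply(curves2, `[[`, character(1), "specimen_id"),
               c("a", "b"))
})

test_that("read_tps falls back to IMAGE= and the record index for ids", {
  path <- write_tps_fixture(
    "LM=3\n0 0\n1 0\n2 1\nIMAGE=img.jpg\nLM=3\n0 0\n1 1\n2 0")
  curves <- read_tps(path)
  expect_equal(curves[[1]]$specimen_id, "img.jpg")
  expect_equal(curves[[2]]$specimen_id, "2")
})

test_that("read_tps rejects count mismatches and empty files", {
  path <- write_tps_fixture("LM=4\n0 0\n1 0\n2 1\nID=bad")
  expect_error(read_tps(path), "declared 4.*parsed 3")
  empty <- write_tps_fixture(character(0))
  expect_error(read_tps(empty), "empty")
})

test_that("outline_curve validates its invariants", {
  expect_error(outline_curve(rbind(c(0, 0), c(1, 1))), "at least 3")
  expect_error(outline_curve(rbind(c(0, 0), c(0, 0), c(1, 1))),
               "duplicate")
  expect_error(outline_curve(rbind(c(0, 0), c(1, 0), c(2, 0)),
                             landmark_indices = c(2, 2)),
               "strictly increasing")
})

test_that("orient_standard reverses right-to-left traces and remaps landmarks", {
  pts <- rbind(c(2, 1), c(1, 0.5), c(0, 0))
  cv <- outline_curve(pts, landmark_indices = 2L)
  out <- orient_standard(cv)
  expect_equal(out$points, pts[3:1, ], ignore_attr = TRUE)
  expect_equal(out$landmark_indices, 2L)  # n + 1 - 2 = 2 for n = 3
  cv4 <- outline_curve(rbind(c(3, 0), c(2, 1), c(1, 1), c(0, 0)),
                       landmark_indices = 2L)
  expect_equal(orient_standard(cv4)$landmark_indices, 3L)

  # already left-to-right: identity; applying twice changes nothing
  lr <- outline_curve(rbind(c(0, 0), c(1, 1), c(2, 0)))
  expect_identical(orient_standard(lr), lr)
  expect_identical(orient_standard(orient_standard(cv)),
                   orient_standard(cv))
})

test_that("vertically degenerate curves orient bottom-to-top by y", {
  cv <- outline_curve(rbind(c(0, 2), c(0.5, 1), c(0, 0)))
  expect_message(out <- orient_standard(cv), "vertical")
  expect_equal(unname(out$points[1, 2]), 0)
})

test_that("resampling places points at analytic equal-arc positions", {
  seg <- outline_curve(rbind(c(0, 0), c(0.4, 0), c(1, 0)))
  ps <- resample_equal_arclength(seg, 5)
  expect_equal(ps$points[, 1], c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(ps$points[, 2], rep(0, 5))

  elbow <- outline_curve(rbind(c(0, 0), c(1, 0), c(1, 1)))
  ps3 <- resample_equal_arclength(elbow, 3)
  expect_equal(ps3$points, rbind(c(0, 0), c(1, 0), c(1, 1)),
               ignore_attr = TRUE)
})

test_that("default configuration emits exactly 100 pseudolandmarks", {
  cv <- make_furcula_outline(furcula_params(), "profile")
  ps <- resample_equal_arclength(cv)
  expect_equal(nrow(ps$points), 100)
  expect_equal(ps$n_points, 100)
})

test_that("resampled points sit at equal arc length along the source curve", {
  # property: over many random polylines, the cumulative source arc length
  # at the output points is uniform within each landmark segment
  for (s in 1:100) {
    pts <- random_polyline(sample(5:20, 1), seed = s)
    cv <- outline_curve(pts)
    n_out <- sample(10:60, 1)
    ps <- resample_equal_arclength(cv, n_out)
    cl <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
    # locate each output point's arc position on the source polyline
    pos <- vapply(seq_len(n_out), function(i) {
      p <- ps$points[i, ]
      best <- Inf
      best_pos <- NA_real_
      for (k in seq_len(nrow(pts) - 1)) {
        d <- pts[k + 1, ] - pts[k, ]
        t <- sum((p - pts[k, ]) * d) / sum(d * d)
        t <- min(max(t, 0), 1)
        q <- pts[k, ] + t * d
        dist <- sum((p - q)^2)
        if (dist < best) {
          best <- dist
          best_pos <- cl[k] + t * sqrt(sum(d * d))
        }
      }
      best_pos
    }, numeric(1))
    expect_lt(max(abs(diff(pos) - cl[length(cl)] / (n_out - 1))), 1e-8)
  }
})

test_that("resampling an equally spaced curve is idempotent", {
  line <- outline_curve(cbind(seq(0, 1, length.out = 37), 0))
  ps <- resample_equal_arclength(line, 37)
  expect_lt(max(abs(ps$points - line$points)), 1e-9)
})

test_that("landmarks are retained exactly with proportional point budgets", {
  pts <- rbind(c(0, 0), c(1, 0), c(1, 2))  # segments of length 1 and 2
  cv <- outline_curve(pts, landmark_indices = 2L)
  ps <- resample_equal_arclength(cv, 10)
  expect_equal(nrow(ps$points), 10)
  lm <- ps$landmark_indices
  expect_length(lm, 1)
  expect_equal(ps$points[lm, ], c(1, 0), ignore_attr = TRUE)
  # budgets by largest remainder over 11 shared points: 4 and 7
  expect_equal(lm, 4L)
  # spacing equal within each segment
  d1 <- sqrt(rowSums(diff(ps$points[1:lm, , drop = FALSE])^2))
  d2 <- sqrt(rowSums(diff(ps$points[lm:10, , drop = FALSE])^2))
  expect_lt(diff(range(d1)), 1e-9)
  expect_lt(diff(range(d2)), 1e-9)
})

test_that("outline CSV round trips", {
  cv1 <- make_furcula_outline(furcula_params(), "profile",
                              specimen_id = "sp1")
  cv2 <- make_furcula_outline(furcula_params(100, 0.8, 0, 0, 0.2),
                              "lateral", specimen_id = "sp2")
  path <- tempfile(fileext = ".csv")
  write_outline_csv(list(cv1, cv2), path)
  back <- read_outline_csv(path)
  expect_length(back, 2)
  ids <- vapply(back, `[[`, character(1), "specimen_id")
  got1 <- back[[which(ids == "sp1")]]
  expect_equal(got1$points, cv1$points, tolerance = 1e-12)
  got2 <- back[[which(ids == "sp2")]]
  expect_equal(got2$landmark_indices, cv2$landmark_indices)
})
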