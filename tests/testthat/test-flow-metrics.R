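test_that("top band selection follows the magnitude rule", {
  f <- make_plane_field("uniform")
  expect_equal(length(top_band(f)), nrow(f$cells))
  # single dominant cell: 0.5 < 0.85 * 1.0
  cells <- data.frame(x = 1:3, y = 0, z = 0, area = 1,
                      speed = c(1, 0.5, 0.5))
  f2 <- plane_velocity_field(cells)
  expect_equal(top_band(f2), 1L)
  expect_error(top_band(plane_velocity_field(
    data.frame(x = 1, y = 0, z = 0, area = 1, speed = 0))), "zero")
})

test_that("linear ramp band agrees with an exhaustive scan oracle", {
  cells <- data.frame(x = seq(0, 1, length.out = 101), y = 0, z = 0,
                      area = 1, speed = seq(0, 2, length.out = 101))
  f <- plane_velocity_field(cells)
  idx <- top_band(f, 0.15)
  oracle <- which(vapply(seq_len(101), function(i)
    cells$speed[i] >= 0.85 * max(cells$speed), logical(1)))
  expect_equal(idx, oracle)
})

test_that("quantile band mode takes the requested area fraction", {
  cells <- data.frame(x = 1:100, y = 0, z = 0, area = 1,
                      speed = seq(0.01, 1, length.out = 100))
  f <- plane_velocity_field(cells)
  idx <- top_band(f, 0.15, mode = "quantile")
  expect_equal(length(idx), 15)
  expect_true(all(cells$speed[idx] >= sort(cells$speed, decreasing = TRUE)[15]))
})

test_that("flow asymmetry is zero for centred patterns, planted for jets", {
  expect_equal(flow_asymmetry(make_plane_field("centered_parabolic")), 0,
               tolerance = 1e-9)
  expect_equal(flow_asymmetry(make_plane_field("uniform")), 0,
               tolerance = 1e-9)
  # jet planted at half the equivalent radius
  R <- 0.01
  f <- make_plane_field("offset_jet", R = R, n_cells = 301,
                        offset = c(0.5 * sqrt(pi * R^2 / pi), 0),
                        sigma = 0.15 * R)
  gt <- attr(f, "ground_truth")
  expect_equal(flow_asymmetry(f), gt$fA, tolerance = 0.02)
  expect_gt(gt$fA, 49); expect_lt(gt$fA, 51)
})

test_that("flow dispersion measures band area fraction", {
  expect_equal(flow_dispersion(make_plane_field("uniform")), 100)
  # one qualifying cell of area a on a plane of area A
  cells <- data.frame(x = 1:10, y = 0, z = 0, area = c(2, rep(1, 9)),
                      speed = c(1, rep(0.1, 9)))
  expect_equal(flow_dispersion(plane_velocity_field(cells)), 100 * 2 / 11)
  # Gaussian jet vs analytic 85%-contour area
  f <- make_plane_field("offset_jet", n_cells = 301,
                        offset = c(0.002, 0), sigma = 0.002)
  expect_equal(flow_dispersion(f), attr(f, "ground_truth")$fD,
               tolerance = 0.02)
  # centered parabolic: band is the disc r <= R sqrt(0.15)
  f2 <- make_plane_field("centered_parabolic", n_cells = 301)
  expect_equal(flow_dispersion(f2), attr(f2, "ground_truth")$fD,
               tolerance = 0.02)
})

test_that("metrics are invariant under rigid motion and speed rescaling", {
  f <- make_plane_field("offset_jet", n_cells = 151, offset = c(0.003, 0.001),
                        sigma = 0.002)
  fa0 <- flow_asymmetry(f); fd0 <- flow_dispersion(f)
  expect_gte(fa0, 0); expect_gt(fd0, 0); expect_lte(fd0, 100)
  th <- 0.6
  rot <- f$cells
  xr <- cos(th) * rot$x - sin(th) * rot$y + 5
  yr <- sin(th) * rot$x + cos(th) * rot$y - 3
  rot$x <- xr; rot$y <- yr; rot$z <- rot$z + 2
  rot$speed <- 4.2 * rot$speed
  f2 <- plane_velocity_field(rot)
  expect_equal(flow_asymmetry(f2), fa0, tolerance = 1e-9)
  expect_equal(flow_dispersion(f2), fd0, tolerance = 1e-12)
})

test_that("tessellation refinement changes smooth-jet metrics by < 1%", {
  mk <- function(n) make_plane_field("offset_jet", n_cells = n,
                                     offset = c(0.002, 0), sigma = 0.003)
  f1 <- mk(201); f2 <- mk(402)
  expect_lt(abs(flow_asymmetry(f2) - flow_asymmetry(f1)) /
              flow_asymmetry(f1), 0.01)
  expect_lt(abs(flow_dispersion(f2) - flow_dispersion(f1)) /
              flow_dispersion(f1), 0.01)
})

test_that("plane field derives Req and centroid from its cells", {
  f <- make_plane_field("uniform", R = 0.01, n_cells = 201)
  A <- sum(f$cells$area)
  expect_equal(f$Req, sqrt(A / pi), tolerance = 1e-12)
  expect_equal(unname(f$centroid[1:2]), c(0, 0), tolerance = 1e-9)
  expect_error(plane_velocity_field(data.frame(x = 1, y = 1)), "columns")
})
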