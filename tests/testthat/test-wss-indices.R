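test_that("constant fields give TAWSS = magnitude, OSI = 0, finite RRT", {
  f <- make_wss_field(4, steady = 0.5, amplitude = 0)
  expect_equal(tawss(f), rep(0.5, 4))
  expect_equal(osi(f), rep(0, 4))
  expect_equal(rrt(tawss(f), osi(f)), rep(2, 4))
})

test_that("pure sinusoidal loading matches the analytic |sin| integrals", {
  f <- make_wss_field(1, steady = 0, amplitude = 1, n_times = 2000)
  expect_equal(tawss(f), 2 / pi, tolerance = 1e-6)
  expect_equal(osi(f), 0.5)
  # fixed-direction positive magnitude: |integral| equals integral of | |
  f2 <- make_wss_field(1, steady = 2, amplitude = 1, n_times = 2000)
  expect_equal(tawss(f2), 2, tolerance = 1e-9)
  expect_equal(osi(f2), 0)
})

test_that("zero fields are flagged undefined, not maximally oscillatory", {
  f <- make_wss_field(2, steady = 0, amplitude = 0)
  expect_equal(tawss(f), c(0, 0))
  expect_true(all(is.na(osi(f))))
  expect_true(all(is.na(rrt(c(0, 0), c(0, 0)))))
})

test_that("RRT identities hold and OSI = 0.5 flags infinity", {
  expect_equal(rrt(0.5, 0), 2)
  expect_equal(rrt(1, 0.25), 2)
  expect_true(is.infinite(rrt(1, 0.5)))
  expect_error(rrt(1, c(0, 0.5)), "equal length")
})

test_that("index maps match generator ground truth across regimes", {
  m <- c(0, 0.3, 1, 2, 5)
  a <- c(1, 1, 1, 1, 1)
  f <- make_wss_field(5, steady = m, amplitude = a, n_times = 4000)
  gt <- attr(f, "ground_truth")
  maps <- wss_indices(f)
  expect_equal(maps$tawss, gt$tawss, tolerance = 1e-5)
  expect_equal(maps$osi, gt$osi, tolerance = 1e-4)
})

test_that("scaling WSS by c scales TAWSS by c, fixes OSI, scales RRT by 1/c", {
  f <- random_wss_field(20, seed = 7)
  f2 <- surface_wss_field(3 * f$wss, f$areas, f$times, f$period)
  expect_equal(tawss(f2), 3 * tawss(f))
  expect_equal(osi(f2), osi(f))
  expect_equal(rrt(tawss(f2), osi(f2)), rrt(tawss(f), osi(f)) / 3)
})

test_that("OSI stays within [0, 0.5] over random vector series", {
  for (s in 1:5) {
    f <- random_wss_field(200, n_times = 16, seed = s)
    o <- osi(f)
    expect_true(all(o >= 0 & o <= 0.5))
  }
})

test_that("time-grid refinement leaves band-limited indices unchanged", {
  mk <- function(n) make_wss_field(6, steady = c(0, 0.2, 0.5, 1, 2, 4),
                                   amplitude = 1, phase = 0.7, n_times = n)
  m200 <- wss_indices(mk(200)); m400 <- wss_indices(mk(400))
  expect_lt(max(abs(m400$tawss - m200$tawss) / m200$tawss), 1e-3)
  expect_lt(max(abs(m400$osi - m200$osi)), 1e-3)
})

test_that("thrombus-prone percentages are area-weighted with strict thresholds", {
  maps <- data.frame(area = c(1, 1), tawss = c(0.3, 0.3),
                     osi = c(0.4, 0.1), rrt = c(1, 1))
  pct <- threshold_percentages(maps)
  expect_equal(unname(pct), c(100, 50, 0))
  # boundary values are NOT prone (strict inequalities)
  maps2 <- data.frame(area = 1, tawss = 0.4, osi = 0.3, rrt = 10)
  expect_equal(unname(threshold_percentages(maps2)), c(0, 0, 0))
  # infinite RRT counts as above threshold
  maps3 <- data.frame(area = c(2, 2), tawss = c(1, 1), osi = c(0, 0.5),
                      rrt = c(1, Inf))
  expect_equal(unname(threshold_percentages(maps3))[3], 50)
  expect_error(threshold_percentages(data.frame(area = 1)), "columns")
})

test_that("planted thrombus-prone fractions are recovered exactly", {
  # 40% of area steady at 0.2 Pa (prone), the rest steady at 1 Pa
  f <- make_wss_field(10, steady = c(rep(0.2, 4), rep(1, 6)),
                      amplitude = 0)
  pct <- threshold_percentages(wss_indices(f))
  expect_equal(unname(pct[1]), 40)
})

test_that("summaries agree with a brute-force loop oracle", {
  f <- random_wss_field(100, seed = 11)
  maps <- wss_indices(f)
  s <- summarize_indices(maps)
  expect_equal(unname(s$tawss["ave"]),
               brute_weighted_mean(maps$tawss, maps$area))
  expect_equal(unname(s$rrt["ave"]),
               brute_weighted_mean(maps$rrt, maps$area))
  expect_equal(unname(s$osi[c("min", "max")]),
               c(min(maps$osi), max(maps$osi)))
  expect_true(s$tawss["min"] <= s$tawss["ave"] &&
                s$tawss["ave"] <= s$tawss["max"])
  # uniform map: ave = min = max
  fu <- make_wss_field(5, steady = 0.7, amplitude = 0)
  su <- summarize_indices(wss_indices(fu))
  expect_equal(unname(su$tawss), rep(0.7, 3))
  # two elements, areas 1 and 3: weighted average
  maps2 <- data.frame(area = c(1, 3), tawss = c(0, 1), osi = c(0, 0),
                      rrt = c(Inf, 1))
  s2 <- summarize_indices(maps2)
  expect_equal(unname(s2$tawss["ave"]), 0.75)
  expect_true(s2$rrt_has_inf)
  expect_equal(unname(s2$rrt["ave"]), 1)  # infinite RRT excluded
  # unweighted mode for sensitivity checks
  expect_equal(unname(summarize_indices(maps2, weighted = FALSE)$tawss["ave"]),
               0.5)
})
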