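test_that("trimmed mean drops floor(trim*n) per tail and resists outliers", {
  expect_equal(trimmed_mean(1:10, 0.2), 5.5)      # mean of 3..8
  expect_equal(trimmed_mean(c(3, 1, 2), 0), 2)    # trim 0 = mean
  expect_equal(trimmed_mean(c(1:9, 1e6), 0.2), 5.5)
  expect_error(trimmed_mean(numeric(0)), "empty")
  expect_error(trimmed_mean(1:5, 0.5), "0.5")
  # cross-check against the base implementation on random samples
  set.seed(3)
  for (i in 1:20) {
    x <- rnorm(sample(5:40, 1))
    tr <- runif(1, 0, 0.45)
    expect_equal(trimmed_mean(x, tr), mean(x, trim = tr))
  }
})

test_that("winsorized variance matches a brute-force winsorize-then-var oracle", {
  expect_equal(winsorized_variance(rep(4, 9)), 0)
  x <- c(2.3, 1.1, 5.2, 0.4)
  expect_equal(winsorized_variance(x, 0), var(x))
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(sample(5:30, 1))
    expect_equal(winsorized_variance(x, 0.2), brute_winvar(x, 0.2))
  }
})

test_that("Hochberg step-up adjustment follows its definition", {
  expect_equal(hochberg_adjust(0.03), 0.03)
  expect_equal(hochberg_adjust(c(0.01, 0.03, 0.04)), c(0.03, 0.04, 0.04))
  # all-equal p: the largest is compared at level alpha/1, so nothing
  # is inflated
  expect_equal(hochberg_adjust(rep(0.02, 4)), rep(0.02, 4))
  set.seed(9)
  for (i in 1:20) {
    p <- runif(sample(2:12, 1))
    adj <- hochberg_adjust(p)
    expect_equal(adj, p.adjust(p, method = "hochberg"))
    expect_true(all(adj >= p))
  }
  expect_error(hochberg_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("evidence labels split at 0.005 and 0.05", {
  expect_equal(evidence_label(c(0.001, 0.0049, 0.005, 0.012, 0.05, 0.5)),
               c("strong", "strong", "weak", "weak", "weak", "none"))
  expect_error(evidence_label(-0.1), "\\[0, 1\\]")
})

test_that("Yuen test with trim 0 reduces to the Welch two-sample t-test", {
  set.seed(21)
  for (i in 1:10) {
    x <- rnorm(12); y <- rnorm(15, sd = 3)
    yt <- yuen_test(x, y, trim = 0)
    tt <- t.test(x, y)
    expect_equal(yt$estimate, unname(diff(rev(tt$estimate))))
    expect_equal(yt$df, unname(tt$parameter))
    expect_equal(yt$p.value, tt$p.value)
  }
})

test_that("robust ANOVA validates the design", {
  tab <- make_factorial_table(seed = 2)
  expect_error(robust_two_way_anova(tab[-1, ]), "balanced")
  expect_error(robust_two_way_anova(tab, value = "nope"), "not found")
  small <- make_factorial_table(n_per_cell = 3, seed = 2)
  expect_error(robust_two_way_anova(small), "at least 4")
})

test_that("constant tables carry no evidence against any null", {
  tab <- make_factorial_table(grand_mean = 5, seed = 1)
  tab$value <- 5
  fit <- robust_two_way_anova(tab)
  for (e in c("factorA", "factorB", "interaction")) {
    expect_equal(fit[[e]]$Q, 0)
    expect_equal(fit[[e]]$p.value, 0.999)
  }
})

test_that("trim 0 reduces the ANOVA to a mean-based heteroscedastic test", {
  set.seed(33)
  for (rep in 1:5) {
    tab <- make_factorial_table(grand_mean = 1,
                                factorA_effects = c(1, -1, 0.5, -0.5, 0),
                                factorB_effects = c(0.3, -0.3, 0),
                                noise_scales = 1, n_per_cell = 8,
                                seed = 100 + rep)
    fit <- robust_two_way_anova(tab, trim = 0)
    cells <- split(tab$value,
                   list(factor(tab$rheology), factor(tab$inlet)))
    cons <- con_5x3()
    for (pair in list(c("factorA", "A"), c("factorB", "B"),
                      c("interaction", "AB"))) {
      oracle <- brute_johansen_means(cells, cons[[pair[2]]])
      expect_equal(fit[[pair[1]]]$Q, oracle$Q, tolerance = 1e-10)
    }
  }
})

test_that("ANOVA detects planted main effects and ignores absent interaction", {
  tab <- make_factorial_table(grand_mean = 10,
                              factorA_effects = c(4, -4, 2, -2, 0),
                              factorB_effects = c(0, 0, 0),
                              noise_scales = 1, seed = 7)
  fit <- robust_two_way_anova(tab)
  expect_lt(fit$factorA$p.value, 0.005)
  # planted interaction is zero: no strong evidence should emerge
  expect_gt(fit$interaction$p.value, 0.005)
})

test_that("pooled post hoc contrasts recover planted level differences", {
  tab <- make_factorial_table(grand_mean = 0,
                              factorA_effects = c(0, 0, 0, 0, 0),
                              factorB_effects = c(3, -3, 0),
                              noise_scales = 0.5, n_per_cell = 30,
                              seed = 12)
  cr <- posthoc_contrasts(tab, "inlet")
  # Parabolic - Plug planted at +6
  row <- cr[cr$level1 == "Parabolic" & cr$level2 == "Plug", ]
  expect_equal(row$estimate, 6, tolerance = 0.2)
  expect_equal(row$evidence, "strong")
  expect_true(all(cr$ci_lower <= cr$estimate & cr$estimate <= cr$ci_upper))
  expect_true(all(cr$p.adjusted >= cr$p.value))
})

test_that("identical groups yield zero contrasts with no evidence", {
  tab <- make_factorial_table(grand_mean = 2, noise_scales = 1, seed = 4)
  # recycle one inlet block so all three inlet groups are identical
  tab <- tab[order(tab$inlet), ]
  tab$value <- rep(tab$value[tab$inlet == "Parabolic"], 3)
  cr <- posthoc_contrasts(tab, "inlet")
  expect_equal(cr$estimate, rep(0, 3))
  expect_equal(cr$p.adjusted, rep(1, 3))
})

test_that("cellwise pooling mode differs slightly from pooled estimates", {
  t5 <- subset(load_reference_table("T5"), variable == "FD_pct")
  pooled <- posthoc_contrasts(t5, "inlet")
  cellw <- posthoc_contrasts(t5, "inlet", pooling = "cellwise",
                             other_factor = "rheology")
  expect_false(isTRUE(all.equal(pooled$estimate, cellw$estimate)))
  expect_lt(max(abs(pooled$estimate - cellw$estimate)), 1)
})
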