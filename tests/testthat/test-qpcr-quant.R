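test_that("fit_standard_curve: perfect doubling and degenerate input", {
  tab <- simulate_qpcr(2.0, 20, 2^-(0:5), noise_sd = 0, seed = 1)
  cv <- fit_standard_curve(tab)
  expect_equal(cv$slope, -1 / log10(2), tolerance = 1e-9)
  expect_equal(cv$efficiency, 2.0, tolerance = 1e-9)
  expect_equal(cv$r_squared, 1, tolerance = 1e-9)

  flat <- data.frame(log10_input = c(0, -1, -2), cq = c(20, 20, 20))
  expect_error(fit_standard_curve(flat), "degenerate")
  expect_error(
    fit_standard_curve(data.frame(log10_input = c(0, -1), cq = c(20, 23))),
    "3 dilution"
  )
})

test_that("noiseless round-trip recovers the published efficiencies to
           machine precision", {
  for (E in c(1.76, 1.82, 1.90, 2.0)) {
    tab <- simulate_qpcr(E, 22, 2^-(0:6), noise_sd = 0, seed = 4)
    cv <- fit_standard_curve(tab)
    expect_equal(cv$efficiency, E, tolerance = 1e-9)
  }
})

test_that("noisy triplicate series recover efficiency within 0.05 on
           average", {
  # 6 two-fold dilutions, triplicates, Cq noise sd 0.1, 100 seeds
  e_hat <- vapply(1:100, function(s) {
    tab <- simulate_qpcr(1.90, 21, 2^-(0:5), noise_sd = 0.1, seed = s,
                         replicates = 3)
    fit_standard_curve(tab)$efficiency
  }, numeric(1))
  expect_lt(abs(mean(e_hat) - 1.90), 0.05)
})

test_that("scale equivariance: input rescaling moves only the intercept", {
  tab <- simulate_qpcr(1.85, 20, 2^-(0:5), noise_sd = 0, seed = 2)
  cv1 <- fit_standard_curve(tab)
  tab$log10_input <- tab$log10_input + log10(7)  # multiply inputs by 7
  cv2 <- fit_standard_curve(tab)
  expect_equal(cv1$slope, cv2$slope, tolerance = 1e-9)
  expect_equal(cv1$efficiency, cv2$efficiency, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(cv1$intercept, cv2$intercept)))
})

test_that("standard_copies converts mass to copy number", {
  # 1 ng/uL at 1000 bp: 1e-9 / 660000 * 6.022e23 copies/uL
  expect_equal(standard_copies(1, 1000), 1e-9 / 660000 * 6.022e23)
  expect_equal(standard_copies(1, 1000) / standard_copies(1, 2000), 2)
  expect_error(standard_copies(0, 1000), "positive")
})

test_that("quantify_sample scales to copies per gram and is monotone", {
  tab <- simulate_qpcr(2.0, 20, 2^-(0:5), noise_sd = 0, seed = 1)
  # calibrate in log10 copies per ng: relabel inputs as 1e4 copies at top
  tab$log10_input <- tab$log10_input + 4
  cv <- fit_standard_curve(tab)
  # a sample whose mean Cq sits exactly at the top standard
  q <- quantify_sample(cv, rep(20, 3), dna_ng_per_g = 6230,
                       extraction_eff = 0.30)
  expect_equal(q$copies_per_ng, 1e4, tolerance = 1e-6)
  expect_equal(q$copies_per_g, 1e4 * 6230 / 0.30, tolerance = 1e-6)
  expect_equal(q$copies_per_g, 2.0767e8, tolerance = 1e-4)
  expect_false(q$below_detection)
  # extraction efficiency 1: no correction
  q2 <- quantify_sample(cv, rep(20, 3), dna_ng_per_g = 6230,
                        extraction_eff = 1)
  expect_equal(q2$copies_per_g, q2$copies_per_ng * 6230)
  # monotone decreasing in Cq
  qs <- vapply(c(19, 21, 23, 25), function(cq) {
    suppressWarnings(quantify_sample(cv, cq)$copies_per_ng)
  }, numeric(1))
  expect_true(all(diff(qs) < 0))
  # extrapolation warning outside the calibrated range
  expect_warning(quantify_sample(cv, 35), "extrapolat")
})

test_that("round-trip quantification recovers known copies within 5% at
           noise 0.1", {
  tab <- simulate_qpcr(1.9, 21, 2^-(0:5), noise_sd = 0, seed = 3,
                       replicates = 3)
  tab$log10_input <- tab$log10_input + 5  # standards: 1e5 copies at top
  cv <- fit_standard_curve(tab)
  set.seed(101)
  rel_err <- vapply(1:11, function(i) {
    true_copies <- 10^runif(1, 3, 5)
    true_cq <- 21 - (log10(true_copies) - 5) / log10(1.9)
    cqs <- true_cq + rnorm(3, 0, 0.1)
    q <- suppressWarnings(quantify_sample(cv, cqs))
    abs(q$copies_per_ng - true_copies) / true_copies
  }, numeric(1))
  expect_lt(median(rel_err), 0.05)
})

test_that("compare_groups: identical groups, two-group F oracle, letters", {
  y <- rep(1e8, 8)
  g <- rep(c("a", "b"), each = 4)
  out <- compare_groups(y, g)
  expect_true(is.na(out$anova$F) || out$anova$F < 1e-10)
  expect_equal(unname(out$letters["a"]), unname(out$letters["b"]))

  # separated groups at log10 means 8.0 vs 8.5, sd 0.05, n = 4
  set.seed(11)
  y2 <- 10^c(rnorm(4, 8.0, 0.05), rnorm(4, 8.5, 0.05))
  out2 <- compare_groups(y2, g, alpha = 0.01)
  expect_lt(out2$anova$p, 0.01)
  expect_false(out2$letters["a"] == out2$letters["b"])
  # F statistic equals the closed-form two-group expression
  l <- log10(y2)
  expect_equal(out2$anova$F, two_group_f(l[1:4], l[5:8]),
               tolerance = 1e-9)

  expect_error(compare_groups(y, rep("a", 8)), "2 groups")
  expect_error(compare_groups(y[1:3], c("a", "a", "b")), "replicates")
})

test_that("ANOVA type-I error is near nominal under a planted null", {
  set.seed(13)
  rejections <- vapply(1:400, function(i) {
    y <- 10^rnorm(12, 8, 0.3)
    g <- rep(c("a", "b", "c"), each = 4)
    compare_groups(y, g)$anova$p < 0.05
  }, logical(1))
  p_hat <- mean(rejections)
  expect_lt(abs(p_hat - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("regress_rate_on_logcopies: exact fit and degenerate input", {
  copies <- 10^seq(7, 9, length.out = 12)
  rate <- 2 + 3 * log10(copies)
  out <- regress_rate_on_logcopies(rate, copies)
  expect_equal(out$r_squared, 1, tolerance = 1e-12)
  expect_equal(out$slope, 3, tolerance = 1e-9)
  expect_equal(out$n, 12)
  expect_error(regress_rate_on_logcopies(rate, rep(1e8, 12)),
               "degenerate")
  expect_error(regress_rate_on_logcopies(rate[1:2], copies[1:2]), "3")
})

test_that("regression recovers an R2 ~ 0.6 regime on average", {
  # emulate n = 12 with signal/noise tuned to R2 = 0.6
  r2s <- vapply(1:200, function(s) {
    set.seed(s)
    x <- rnorm(12, 8, 0.5)
    # slope 1, noise chosen so R2 = var(bx)/(var(bx)+var(e)) = 0.6
    y <- x + rnorm(12, 0, 0.5 * sqrt(0.4 / 0.6))
    regress_rate_on_logcopies(y, 10^x)$r_squared
  }, numeric(1))
  expect_lt(abs(mean(r2s) - 0.6), 0.15)
})
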