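# Beta-binomial model: closed forms, limits, fitting, purity rescaling.

test_that("zero-count closed form matches the Beta-function identity", {
  # B(1, beta + n) / B(1, beta) = beta / (beta + n); concentration 200
  fit <- resiphy:::new_bb_fit(mu = 1 / 200, rho = 1 / 201, 2L, 1L)
  expect_equal(fit$alpha, 1, tolerance = 1e-12)
  expect_equal(fit$beta, 199, tolerance = 1e-12)
  expect_equal(absence_pvalue(fit, 100, 0), 199 / 299, tolerance = 1e-12)
})

test_that("beta-binomial pmf is a proper distribution and nests the binomial", {
  n <- 40
  p <- dbetabinom(0:n, n, mu = 0.3, rho = 0.05)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(dbetabinom(0:n, n, 0.3, 0),
               dbinom(0:n, n, 0.3), tolerance = 1e-12)
})

test_that("expected VAF follows the purity/copy-number dilution curve", {
  expect_equal(expected_vaf(0.01, 1, 2, 2), 0.005)
  expect_equal(expected_vaf(1, 1, 2, 2), 0.5)
  expect_equal(expected_vaf(0), 0)
  # LOH locus: one tumour copy, mutated
  expect_equal(expected_vaf(0.5, 1, 1, 2), 0.5 / 1.5)
  expect_error(expected_vaf(1, 1, 0, 2), "no DNA")
})

test_that("absence p-value handles edge cases and is monotone in depth", {
  fit <- binom_fit(mu = 0.005, purity = 0.01)
  expect_equal(absence_pvalue(fit, 0, 0), 1)
  depths <- c(10, 100, 500, 1000, 4000)
  p <- absence_pvalue(fit, depths, 0)
  expect_true(all(diff(p) < 0))
  # same monotonicity with overdispersion
  od <- resiphy:::new_bb_fit(0.005, 0.001, 2L, 1L)
  pod <- sapply(depths, function(n) absence_pvalue(od, n, 0))
  expect_true(all(diff(pod) < 0))
  expect_error(absence_pvalue(fit, 10, 11), "alt_observed")
})

test_that("p-value tends to 1 as worst-case purity tends to 0", {
  fit0 <- binom_fit(mu = 0.3, purity = 0.6)
  p <- sapply(c(0.01, 1e-3, 1e-4, 1e-6), function(ps)
    absence_pvalue(rescale_fit(fit0, ps), 4000, 0))
  expect_true(all(diff(p) > 0))
  expect_gt(p[4], 0.99)
})

test_that("ML fit recovers simulated mean and overdispersion", {
  set.seed(11)
  depth <- rep(150L, 500)
  alt <- rbetabinom(500, depth, 0.30, 0.01)
  fit <- resiphy:::fit_bb_mle(alt, depth)
  expect_lt(abs(fit$mu - 0.30) / 0.30, 0.05)
  expect_gt(fit$rho, 0.005)
  expect_lt(fit$rho, 0.02)
})

test_that("dispersion-free counts drive the overdispersion estimate to zero", {
  fit <- resiphy:::fit_bb_mle(rep(30L, 60), rep(100L, 60))
  expect_equal(fit$mu, 0.3, tolerance = 1e-3)
  expect_lt(fit$rho, 1e-4)
})

test_that("fit_betabinomial groups by CN state and pools small groups", {
  set.seed(3)
  counts <- data.frame(
    alt_count = c(rbetabinom(40, 150, 0.3, 0.01), rbetabinom(3, 150, 0.4, 0.01)),
    depth = 150L,
    total_cn = c(rep(2L, 40), rep(3L, 3)),
    major_cn = c(rep(1L, 40), rep(2L, 3)))
  fits <- fit_betabinomial(counts, sample_id = "T1", purity = 0.6,
                           min_training = 10)
  sm <- fits$state_map
  expect_true(sm$pooled[sm$total_cn == 3])
  expect_false(sm$pooled[sm$total_cn == 2])
  pooled_fit <- lookup_fit(fits, 3, 2)
  expect_equal(pooled_fit$n_training, 43L)
  expect_error(fit_betabinomial(data.frame(alt_count = 0L, depth = 100L)),
               "zero")
})

test_that("rescaling is the identity at the training purity and keeps rho = 0", {
  set.seed(5)
  counts <- data.frame(alt_count = rbetabinom(200, 150, 0.3, 0.01),
                       depth = 150L)
  fits <- fit_betabinomial(counts, sample_id = "T1", purity = 0.6)
  f <- lookup_fit(fits, 2, 1)
  same <- rescale_fit(f, 0.6)
  expect_equal(same$mu, f$mu, tolerance = 1e-12)
  expect_equal(same$rho, f$rho, tolerance = 1e-12)
  # diploid het trained at 0.6 with mean exactly 0.3 -> 0.005 at 1% purity
  f2 <- binom_fit(mu = 0.3, purity = 0.6)
  r2 <- rescale_fit(f2, 0.01)
  expect_equal(r2$mu, 0.005, tolerance = 1e-12)
  expect_identical(r2$rho, 0)
  expect_error(rescale_fit(f2, 0), "purity")
})

test_that("rescaling shrinks overdispersion with the mean", {
  f <- resiphy:::new_bb_fit(0.3, 0.01, 2L, 1L, purity = 0.6,
                            multiplicity = 1L)
  r <- rescale_fit(f, 0.01)
  expect_equal(r$mu, 0.005, tolerance = 1e-12)
  expect_equal(r$alpha, f$alpha, tolerance = 1e-9)
  expect_lt(r$rho, f$rho)
})
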