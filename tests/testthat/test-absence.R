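# Candidate identification and the absence test itself.

test_that("detection rule and its undetected bound are consistent", {
  r <- detection_rule()
  expect_false(is_detected(1, 150, r))
  expect_true(is_detected(2, 150, r))
  expect_true(is_detected(5, 100, r))
  # at depth 4000 the floor is ceiling(2.0) = 2 reads -> bound 2... the
  # fractional part matters: 4000 * 5e-4 = 2, so 2 reads detect
  expect_equal(resiphy:::max_undetected(150, r), 1L)
  expect_equal(resiphy:::max_undetected(4000, r), 1L)
  expect_equal(resiphy:::max_undetected(10000, r), 4L)
})

test_that("missing-SNV candidates are chosen per assay coverage", {
  tr <- tiny_truncal(c("chr1:1:A>T", "chr1:2:A>T", "chr1:3:A>T"))
  obs <- rbind(
    # undetected everywhere -> candidate, tested on deepest assay (TES1)
    obs_row("chr1:1:A>T", "M1", "WES", 150, 0),
    obs_row("chr1:1:A>T", "M1", "TES1", 4000, 1),
    obs_row("chr1:1:A>T", "M1", "TES2", 1100, 0),
    # detected by TES2 -> not a candidate
    obs_row("chr1:2:A>T", "M1", "TES2", 100, 5),
    # covered only by WES with zero reads -> candidate on WES
    obs_row("chr1:3:A>T", "M1", "WES", 120, 0))
  cand <- identify_missing(obs, tr, "M1")
  expect_equal(cand$status, c("CANDIDATE", "DETECTED", "CANDIDATE"))
  expect_equal(cand$assay_used[1], "TES1")
  expect_equal(cand$depth[1], 4000L)
  expect_equal(cand$assay_used[3], "WES")
  # truncal SNV with no coverage at all
  tr2 <- tiny_truncal("chr9:9:A>T")
  expect_equal(identify_missing(obs, tr2, "M1")$status, "NO_COVERAGE")
})

test_that("testability fixed point is conservative and deterministic", {
  # all candidates comfortably testable
  r <- resiphy:::resolve_testable(rep(1e-9, 20), 0.05)
  expect_equal(r$n_tests, 20L)
  # none testable
  r2 <- resiphy:::resolve_testable(rep(0.5, 20), 0.05)
  expect_equal(r2$n_tests, 0L)
  # borderline set shrinks to a fixed point
  r3 <- resiphy:::resolve_testable(c(rep(1e-9, 5), rep(0.02, 10)), 0.05)
  expect_equal(r3$n_tests, 5L)
  expect_equal(sum(r3$testable), 5L)
})

test_that("deep coverage yields ABSENT, shallow stays UNDETERMINED", {
  ids <- sprintf("chr1:%d:A>T", 1:50)
  tr <- tiny_truncal(ids)
  fits <- structure(list(
    fits = list("2/1" = binom_fit(mu = 0.3, purity = 0.6)),
    state_map = data.frame(total_cn = 2L, major_cn = 1L, fit = "2/1",
                           pooled = FALSE, n_state = 100L),
    sample_id = "T1", purity = 0.6, normal_cn = 2, min_training = 10),
    class = "bb_fits")
  sheet <- tiny_sheet(n_t = 2)
  deep <- do.call(rbind, lapply(ids, function(v)
    obs_row(v, "M1", "TES1", 4000, 0)))
  res <- run_absence_test(deep, tr, fits, sheet, target_samples = "M1")
  expect_equal(nrow(res), 50)
  expect_true(all(res$decision == "ABSENT"))
  expect_equal(res$null_vaf[1], 0.005, tolerance = 1e-12)
  # p_raw = (1 - 0.005)^4000, Bonferroni over the 50 testable candidates
  expect_equal(res$p_raw[1], 0.995^4000, tolerance = 1e-9)
  expect_equal(res$n_tests[1], 50L)
  expect_equal(res$p_adjusted, pmin(1, res$p_raw * 50), tolerance = 1e-12)

  shallow <- do.call(rbind, lapply(ids[1:2], function(v)
    obs_row(v, "M1", "WES", 150, 0)))
  expect_warning(
    res2 <- run_absence_test(shallow, tiny_truncal(ids[1:2]), fits, sheet,
                             target_samples = "M1"),
    "no testable")
  expect_true(all(res2$decision == "UNDETERMINED"))
  expect_false(any(res2$testable))
  expect_equal(res2$p_raw[1], 0.995^150, tolerance = 1e-9)
})

test_that("detected truncal SNVs pass through as DETECTED rows", {
  tr <- tiny_truncal(c("chr1:1:A>T", "chr1:2:A>T"))
  fits <- structure(list(
    fits = list("2/1" = binom_fit()),
    state_map = data.frame(total_cn = 2L, major_cn = 1L, fit = "2/1",
                           pooled = FALSE, n_state = 100L),
    sample_id = "T1", purity = 0.6, normal_cn = 2, min_training = 10),
    class = "bb_fits")
  obs <- rbind(obs_row("chr1:1:A>T", "M1", "TES1", 4000, 110),
               obs_row("chr1:2:A>T", "M1", "TES1", 4000, 0))
  res <- run_absence_test(obs, tr, fits, tiny_sheet(), target_samples = "M1")
  expect_equal(res$decision[res$variant_id == "chr1:1:A>T"], "DETECTED")
  expect_equal(res$decision[res$variant_id == "chr1:2:A>T"], "ABSENT")
})

test_that("invalid test parameters are rejected before any compute", {
  fits <- structure(list(fits = list(), state_map = NULL, sample_id = "T1",
                         purity = 0.6, normal_cn = 2, min_training = 10),
                    class = "bb_fits")
  expect_error(run_absence_test(resiphy:::empty_observations(), tiny_truncal("a"),
                                fits, tiny_sheet(), pi_star = 0))
})
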