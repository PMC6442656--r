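# The absence test: decide whether putative truncal SNVs that are
# undetected in a low-purity margin/SVZ sample are truly absent, or merely
# missed for lack of power. The null hypothesis is that the mutation is
# truly truncal -- present in the target sample at worst-case purity
# pi_star -- and the one-sided lower tail of the purity-rescaled
# beta-binomial gives the p-value. Bonferroni correction is applied within
# each target sample.

#' Detection rule for "not detected"
#'
#' A mutation counts as detected in one assay when
#' `alt_count >= max(min_alt, depth * min_frac)`. The defaults (2 reads or
#' 0.05% of depth, whichever is larger) reproduce a caller-like detection
#' floor in a way that is exactly reproducible.
#'
#' @param min_alt Minimum variant reads, default 2.
#' @param min_frac Minimum variant fraction of depth, default 5e-4.
#' @return A `detection_rule` object.
#' @export
detection_rule <- function(min_alt = 2, min_frac = 5e-4) {
  stopifnot(min_alt >= 1, min_frac >= 0)
  structure(list(min_alt = min_alt, min_frac = min_frac),
            class = "detection_rule")
}

#' @rdname detection_rule
#' @param alt_count,depth Read counts (vectorised).
#' @param rule A `detection_rule`.
#' @export
is_detected <- function(alt_count, depth, rule = detection_rule()) {
  alt_count >= pmax(rule$min_alt, depth * rule$min_frac)
}

# Largest alt count that still counts as "not detected" at this depth.
max_undetected <- function(depth, rule = detection_rule()) {
  pmax(as.integer(ceiling(pmax(rule$min_alt, depth * rule$min_frac))) - 1L, 0L)
}

#' Identify truncal SNVs missing from a target sample
#'
#' A putative truncal SNV is a *candidate* for the absence test when it is
#' not detected in the target margin/SVZ sample by any assay with coverage;
#' the assay with the deepest coverage at the locus is chosen for testing.
#' SNVs with no coverage in any assay are flagged `NO_COVERAGE`; SNVs
#' detected by at least one assay are reported as `DETECTED`.
#'
#' @param observations Observation table covering the target sample.
#' @param truncal_set A `truncal_set` from [select_putative_truncal()].
#' @param target_sample Sample id of the margin or SVZ sample.
#' @param rule Detection rule.
#' @return Data frame: `variant_id`, `status`
#'   (CANDIDATE/DETECTED/NO_COVERAGE), `assay_used`, `depth`, `alt_count`.
#' @export
identify_missing <- function(observations, truncal_set, target_sample,
                             rule = detection_rule()) {
  obs <- observations[observations$sample_id == target_sample &
                        observations$variant_id %in% truncal_set$variant_id, ,
                      drop = FALSE]
  out <- lapply(truncal_set$variant_id, function(v) {
    o <- obs[obs$variant_id == v & obs$depth > 0, , drop = FALSE]
    if (nrow(o) == 0)
      return(data.frame(variant_id = v, status = "NO_COVERAGE",
                        assay_used = NA_character_, depth = 0L,
                        alt_count = 0L, stringsAsFactors = FALSE))
    det <- is_detected(o$alt_count, o$depth, rule)
    i <- which.max(o$depth)
    data.frame(variant_id = v,
               status = if (any(det)) "DETECTED" else "CANDIDATE",
               assay_used = o$assay[i], depth = o$depth[i],
               alt_count = o$alt_count[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Resolve which candidates are testable together with the Bonferroni family
# size. A candidate is testable when even the largest p attainable while
# still undetected, P(X <= detection bound | depth), falls below
# alpha / n_tests. Since n_tests is itself the number of testable
# candidates, the pair is resolved by fixed-point iteration from
# n_tests = #candidates; if the iteration enters a 2-cycle the larger
# (more conservative) family size is kept.
resolve_testable <- function(p_bound, alpha) {
  n <- length(p_bound)
  if (n == 0) return(list(testable = logical(0), n_tests = 0L))
  k <- n
  seen <- integer(0)
  repeat {
    testable <- p_bound < alpha / max(k, 1L)
    k_new <- sum(testable)
    if (k_new == k || k_new == 0) break
    if (k_new %in% seen) {
      k <- max(k, k_new)
      testable <- p_bound < alpha / max(k, 1L)
      break
    }
    seen <- c(seen, k)
    k <- k_new
  }
  list(testable = testable, n_tests = as.integer(sum(testable)))
}

#' Run the truncal-absence test on margin/SVZ samples
#'
#' For every putative truncal SNV undetected in a target sample, the
#' beta-binomial model of its copy-number state (trained on a high-purity
#' tumour-mass sample) is rescaled to the worst-case purity `pi_star` and
#' the lower-tail p-value of the observed count is Bonferroni-corrected
#' across the testable candidates of that sample. Decisions: `ABSENT`
#' (testable and adjusted p < alpha), `UNDETERMINED` (untestable, or
#' testable but not significant, or no coverage), `DETECTED`.
#'
#' @param observations Observation table (all assays).
#' @param truncal_set From [select_putative_truncal()].
#' @param fits `bb_fits` trained with [fit_betabinomial()] on the
#'   highest-purity tumour-mass sample.
#' @param sample_sheet Sample metadata.
#' @param cn_map Optional copy-number annotation for the *target* samples;
#'   when `NULL` the training copy-number state of each SNV is assumed at
#'   the target locus.
#' @param target_samples Margin/SVZ sample ids; default every M and SVZ
#'   sample in the sheet.
#' @param pi_star Worst-case purity under the null, default 0.01.
#' @param alpha Significance level before Bonferroni, default 0.05.
#' @param rule Detection rule.
#' @param normal_cn Germline copy number.
#' @return Data frame, one row per truncal SNV per target sample:
#'   `variant_id`, `target_sample_id`, `assay_used`, `depth`,
#'   `alt_observed`, `null_vaf`, `pi_star`, `p_raw`, `p_adjusted`,
#'   `n_tests`, `testable`, `decision`, `flag`.
#' @export
run_absence_test <- function(observations, truncal_set, fits, sample_sheet,
                             cn_map = NULL, target_samples = NULL,
                             pi_star = 0.01, alpha = 0.05,
                             rule = detection_rule(), normal_cn = 2) {
  stopifnot(inherits(fits, "bb_fits"), pi_star > 0, pi_star <= 1,
            alpha > 0, alpha < 1)
  if (is.null(target_samples))
    target_samples <- sample_sheet$sample_id[
      sample_sheet$region_class %in% c("M", "SVZ")]
  res <- list()
  for (ts in target_samples) {
    cand <- identify_missing(observations, truncal_set, ts, rule)
    if (nrow(cand) == 0) next
    cand$target_sample_id <- ts
    idx <- match(cand$variant_id, truncal_set$variant_id)
    cn_t <- truncal_set$total_cn[idx]
    cn_m <- truncal_set$major_cn[idx]
    if (!is.null(cn_map)) {
      cm <- cn_map[cn_map$sample_id == ts, , drop = FALSE]
      j <- match(cand$variant_id, cm$variant_id)
      cn_t <- ifelse(!is.na(j), cm$total_cn[j], cn_t)
      cn_m <- ifelse(!is.na(j), cm$major_cn[j], cn_m)
    }
    is_c <- cand$status == "CANDIDATE"
    null_vaf <- rep(NA_real_, nrow(cand))
    p_bound <- rep(NA_real_, nrow(cand))
    p_raw <- rep(NA_real_, nrow(cand))
    rfits <- vector("list", nrow(cand))
    for (i in which(is_c)) {
      f0 <- lookup_fit(fits, truncal_set$total_cn[idx[i]],
                       truncal_set$major_cn[idx[i]])
      rf <- rescale_fit(f0, pi_star, cn_t[i], cn_m[i], normal_cn)
      rfits[[i]] <- rf
      null_vaf[i] <- rf$mu
      p_bound[i] <- absence_pvalue(rf, cand$depth[i],
                                   max_undetected(cand$depth[i], rule))
      p_raw[i] <- absence_pvalue(rf, cand$depth[i], cand$alt_count[i])
    }
    tst <- resolve_testable(p_bound[is_c], alpha)
    testable <- rep(FALSE, nrow(cand))
    testable[is_c] <- tst$testable
    n_tests <- tst$n_tests
    if (n_tests == 0 && any(is_c))
      warning("no testable candidates in sample ", ts)
    p_adj <- ifelse(is_c, pmin(1, p_raw * max(n_tests, 1L)), NA_real_)
    decision <- ifelse(cand$status == "DETECTED", "DETECTED", "UNDETERMINED")
    decision[is_c & testable & !is.na(p_adj) & p_adj < alpha] <- "ABSENT"
    res[[ts]] <- data.frame(
      variant_id = cand$variant_id, target_sample_id = ts,
      assay_used = cand$assay_used, depth = cand$depth,
      alt_observed = cand$alt_count, null_vaf = null_vaf,
      pi_star = pi_star, p_raw = p_raw, p_adjusted = p_adj,
      n_tests = ifelse(is_c, n_tests, NA_integer_),
      testable = testable, decision = decision,
      flag = ifelse(cand$status == "NO_COVERAGE", "NO_COVERAGE", ""),
      stringsAsFactors = FALSE)
  }
  if (length(res) == 0)
    return(data.frame(variant_id = character(), target_sample_id = character(),
                      assay_used = character(), depth = integer(),
                      alt_observed = integer(), null_vaf = numeric(),
                      pi_star = numeric(), p_raw = numeric(),
                      p_adjusted = numeric(), n_tests = integer(),
                      testable = logical(), decision = character(),
                      flag = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Train truncal VAF models for every tumour-mass sample
#'
#' Fits [fit_betabinomial()] models from the putative truncal SNVs of each
#' tumour-mass sample (WES counts), excluding SNVs whose copy-number state
#' fell back to the default. Returns all fits; the one from the
#' highest-purity sample (`$best`) is the recommended model for rescaling,
#' as the highest purity gives the tightest truncal VAF estimate.
#'
#' @param observations Observation table.
#' @param truncal_set From [select_putative_truncal()].
#' @param sample_sheet Sample metadata.
#' @param assay Training assay, default WES.
#' @param min_training Minimum SNVs per copy-number state.
#' @param normal_cn Germline copy number.
#' @return List with `per_sample` (named list of `bb_fits`) and `best`.
#' @export
train_vaf_models <- function(observations, truncal_set, sample_sheet,
                             assay = "WES", min_training = 10,
                             normal_cn = 2) {
  tum <- sample_sheet[sample_sheet$region_class == "T", , drop = FALSE]
  keep <- truncal_set[!truncal_set$cn_default, , drop = FALSE]
  if (nrow(keep) == 0)
    stop("no truncal SNVs with called copy number to train on")
  per <- list()
  for (i in seq_len(nrow(tum))) {
    sid <- tum$sample_id[i]
    o <- observations[observations$sample_id == sid &
                        observations$assay == assay &
                        observations$variant_id %in% keep$variant_id &
                        observations$depth > 0, , drop = FALSE]
    j <- match(o$variant_id, keep$variant_id)
    counts <- data.frame(alt_count = o$alt_count, depth = o$depth,
                         total_cn = keep$total_cn[j],
                         major_cn = keep$major_cn[j])
    per[[sid]] <- fit_betabinomial(counts, sample_id = sid,
                                   purity = tum$purity[i],
                                   normal_cn = normal_cn,
                                   min_training = min_training)
  }
  best <- per[[tum$sample_id[which.max(tum$purity)]]]
  list(per_sample = per, best = best)
}
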