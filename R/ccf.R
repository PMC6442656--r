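# Cancer cell fractions and putative-truncal SNV selection.

#' Estimate mutation multiplicity
#'
#' Number of mutated allele copies per tumour cell implied by an observed
#' VAF, given purity and local copy number:
#' `m = clamp(round(vaf * (pi*CNt + (1-pi)*CNn) / pi), 1, major_cn)`.
#'
#' @param vaf Observed variant allele fraction (vectorised).
#' @param purity Tumour purity in (0, 1].
#' @param total_cn Tumour total copy number at the locus.
#' @param normal_cn Germline copy number (2 for autosomes).
#' @param major_cn Major allele copy number; upper clamp for `m`.
#' @return Integer multiplicities, clamped to `[1, max(1, major_cn)]`.
#' @export
estimate_multiplicity <- function(vaf, purity, total_cn, normal_cn = 2,
                                  major_cn = 1) {
  n <- max(length(vaf), length(purity), length(total_cn), length(normal_cn),
           length(major_cn))
  vaf <- rep_len(vaf, n); purity <- rep_len(purity, n)
  total_cn <- rep_len(total_cn, n); normal_cn <- rep_len(normal_cn, n)
  major_cn <- rep_len(major_cn, n)
  if (any(purity <= 0)) stop("purity must be > 0 to estimate multiplicity")
  m <- round(vaf * (purity * total_cn + (1 - purity) * normal_cn) / purity)
  as.integer(pmin(pmax(m, 1), pmax(1, major_cn)))
}

#' Cancer cell fraction of a mutation
#'
#' Purity- and copy-number-corrected fraction of tumour cells carrying a
#' mutation:
#' `ccf = vaf * (pi*CNt + (1-pi)*CNn) / (pi * m)`,
#' capped at 1; raw values above 1 (supraclonal, usually noise or a wrong
#' multiplicity) are flagged. When `multiplicity` is `NULL` it is estimated
#' with [estimate_multiplicity()].
#'
#' @param alt_count,depth Variant and total read counts (vectorised).
#' @param purity Tumour purity in (0, 1].
#' @param total_cn,normal_cn,multiplicity Local copy-number state.
#' @param major_cn Used only when estimating multiplicity.
#' @return Data frame with `vaf`, `multiplicity`, `ccf`,
#'   `flagged_supraclonal`.
#' @export
compute_ccf <- function(alt_count, depth, purity, total_cn = 2,
                        normal_cn = 2, multiplicity = NULL, major_cn = 1) {
  n <- max(length(alt_count), length(depth), length(purity),
           length(total_cn), length(normal_cn), length(major_cn))
  alt_count <- rep_len(alt_count, n); depth <- rep_len(depth, n)
  purity <- rep_len(purity, n); total_cn <- rep_len(total_cn, n)
  normal_cn <- rep_len(normal_cn, n); major_cn <- rep_len(major_cn, n)
  if (any(depth == 0)) stop("CCF undefined at zero depth")
  if (any(purity <= 0)) stop("CCF undefined at purity 0")
  if (any(alt_count > depth)) stop("alt_count exceeds depth")
  vaf <- alt_count / depth
  if (is.null(multiplicity))
    multiplicity <- estimate_multiplicity(vaf, purity, total_cn, normal_cn,
                                          major_cn)
  multiplicity <- rep_len(as.integer(multiplicity), n)
  raw <- vaf * (purity * total_cn + (1 - purity) * normal_cn) /
    (purity * multiplicity)
  data.frame(vaf = vaf, multiplicity = multiplicity,
             ccf = pmin(raw, 1), flagged_supraclonal = raw > 1)
}

#' CCF table for all variants in the tumour-mass samples
#'
#' Joins observations (one assay, default WES as truncal selection precedes
#' the targeted panels), sample purities and per-sample copy-number states
#' into one CCF estimate per variant per tumour-mass (region class `T`)
#' sample.
#'
#' @param observations Observation table (see [read_multisample_vcf()]).
#' @param sample_sheet Sample metadata (see [read_sample_sheet()]).
#' @param cn_map Output of [annotate_copy_number()].
#' @param assay Assay whose counts feed the CCF (default `"WES"`).
#' @param normal_cn Germline copy number.
#' @return Data frame: `variant_id`, `sample_id`, `vaf`, `multiplicity`,
#'   `ccf`, `flagged_supraclonal`, `total_cn`, `major_cn`, `cn_default`.
#' @export
compute_ccf_table <- function(observations, sample_sheet, cn_map,
                              assay = "WES", normal_cn = 2) {
  tum <- sample_sheet$sample_id[sample_sheet$region_class == "T"]
  obs <- observations[observations$assay == assay &
                        observations$sample_id %in% tum, , drop = FALSE]
  obs <- obs[obs$depth > 0, , drop = FALSE]
  obs <- merge(obs, sample_sheet[, c("sample_id", "purity")], by = "sample_id")
  obs <- merge(obs, cn_map, by = c("variant_id", "sample_id"))
  if (nrow(obs) == 0)
    return(data.frame(variant_id = character(), sample_id = character(),
                      vaf = numeric(), multiplicity = integer(),
                      ccf = numeric(), flagged_supraclonal = logical(),
                      total_cn = integer(), major_cn = integer(),
                      cn_default = logical()))
  est <- compute_ccf(obs$alt_count, obs$depth, obs$purity, obs$total_cn,
                     normal_cn, NULL, obs$major_cn)
  out <- cbind(obs[, c("variant_id", "sample_id")], est,
               obs[, c("total_cn", "major_cn", "cn_default")])
  out[order(out$variant_id, out$sample_id), , drop = FALSE]
}

#' Select putative truncal SNVs
#'
#' Keeps SNVs whose CCF reaches `threshold` in *every* tumour-mass sample
#' and whose copy-number state `(total_cn, major_cn)` is identical across
#' all of them. Margin, SVZ and blood samples play no role here.
#'
#' @param ccf_table Output of [compute_ccf_table()].
#' @param tumour_samples Character vector of tumour-mass sample ids
#'   (at least 2; truncality is undefined for a single region).
#' @param threshold CCF cut-off, default 0.8.
#' @return A `truncal_set`: data frame with `variant_id`, shared `total_cn`
#'   and `major_cn`, `cn_default` (any sample fell back to the default
#'   diploid state), `min_ccf`; the threshold is kept as an attribute.
#' @export
select_putative_truncal <- function(ccf_table, tumour_samples,
                                    threshold = 0.8) {
  if (length(tumour_samples) < 2)
    stop("truncality is undefined with fewer than 2 tumour-mass samples")
  tab <- ccf_table[ccf_table$sample_id %in% tumour_samples, , drop = FALSE]
  keep <- vapply(split(tab, tab$variant_id), function(d) {
    all(tumour_samples %in% d$sample_id) &&
      all(d$ccf >= threshold) &&
      nrow(unique(d[, c("total_cn", "major_cn")])) == 1
  }, logical(1))
  ids <- names(keep)[keep]
  rows <- tab[!duplicated(tab$variant_id) & tab$variant_id %in% ids, ,
              drop = FALSE]
  flg <- vapply(split(tab$cn_default, tab$variant_id), any, logical(1))
  mn <- vapply(split(tab$ccf, tab$variant_id), min, numeric(1))
  out <- data.frame(variant_id = rows$variant_id,
                    total_cn = rows$total_cn, major_cn = rows$major_cn,
                    cn_default = flg[rows$variant_id],
                    min_ccf = mn[rows$variant_id],
                    stringsAsFactors = FALSE)
  out <- out[order(out$variant_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, ccf_threshold = threshold,
            tumour_samples = tumour_samples,
            class = c("truncal_set", "data.frame"))
}
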