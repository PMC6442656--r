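# Readers and writers for the formats the pipeline touches:
# multi-sample VCF (WES), TSV read-count tables (targeted panels),
# 1-based closed copy-number segment TSV, sample sheet, Newick.
#
# Observations are held in one long data frame with columns
# variant_id, chrom, pos, ref, alt, sample_id, assay, depth, alt_count;
# variant ids follow the chrom:pos:ref>alt convention.

REGION_CLASSES <- c("T", "M", "SVZ", "BLOOD")
ASSAYS <- c("WES", "TES1", "TES2")

variant_id <- function(chrom, pos, ref, alt) {
  paste0(chrom, ":", pos, ":", ref, ">", alt)
}

parse_variant_id <- function(id) {
  m <- regmatches(id, regexec("^([^:]+):([0-9]+):([ACGT])>([ACGT])$", id))
  bad <- vapply(m, length, integer(1)) != 5
  if (any(bad))
    stop("malformed variant_id (expected chrom:pos:ref>alt): ",
         paste(utils::head(id[bad], 3), collapse = ", "))
  data.frame(chrom = vapply(m, `[`, "", 2),
             pos = as.integer(vapply(m, `[`, "", 3)),
             ref = vapply(m, `[`, "", 4),
             alt = vapply(m, `[`, "", 5),
             stringsAsFactors = FALSE)
}

empty_observations <- function() {
  data.frame(variant_id = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), sample_id = character(),
             assay = character(), depth = integer(), alt_count = integer(),
             stringsAsFactors = FALSE)
}

validate_observations <- function(obs) {
  need <- names(empty_observations())
  miss <- setdiff(need, names(obs))
  if (length(miss) > 0)
    stop("observation table lacks columns: ", paste(miss, collapse = ", "))
  if (any(obs$alt_count > obs$depth))
    stop("alt_count > depth for ",
         obs$variant_id[which(obs$alt_count > obs$depth)[1]])
  if (any(obs$pos < 1)) stop("positions must be 1-based (pos >= 1)")
  if (any(obs$ref == obs$alt)) stop("ref and alt must differ")
  invisible(obs)
}

#' Read somatic SNVs from a multi-sample VCF
#'
#' Parses a VCF v4.x with per-sample allele depths into the long
#' observation table used throughout the package. Every sample column
#' becomes one observation per SNV, tagged `assay = "WES"`. Multi-allelic
#' rows are split into one record per alternate allele; indel alleles are
#' skipped and counted in a message. Depth is the sum of the per-sample
#' allele depths (`AD`); when `AD` is absent the depth falls back to
#' `DP` and the variant reads to `round(DP * AF)`.
#'
#' @param path VCF file.
#' @param sample_sheet Optional sample sheet; if given, VCF samples absent
#'   from it raise an error.
#' @param assay Assay tag for the observations, default `"WES"`.
#' @return Observation data frame (see [empty_observations()] columns).
#' @export
read_multisample_vcf <- function(path, sample_sheet = NULL, assay = "WES") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (!is.matrix(fix)) fix <- t(fix)  # single-record VCFs drop to a vector
  if (nrow(fix) == 0) return(empty_observations())
  samples <- colnames(v@gt)[-1]
  if (!is.null(sample_sheet)) {
    unknown <- setdiff(samples, sample_sheet$sample_id)
    if (length(unknown) > 0)
      stop("VCF sample(s) absent from sample sheet: ",
           paste(unknown, collapse = ", "))
  }
  fmt <- strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)
  has_ad <- vapply(fmt, function(f) "AD" %in% f, logical(1))

  ad <- if (any(has_ad)) vcfR::extract.gt(v, element = "AD") else NULL
  dp <- if (!all(has_ad)) vcfR::extract.gt(v, element = "DP",
                                           as.numeric = TRUE) else NULL
  af <- if (!all(has_ad)) vcfR::extract.gt(v, element = "AF",
                                           as.numeric = TRUE) else NULL

  out <- vector("list", nrow(fix))
  n_skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    chrom <- unname(fix[i, "CHROM"])
    pos <- unname(fix[i, "POS"])
    ref <- unname(fix[i, "REF"])
    alts <- strsplit(unname(fix[i, "ALT"]), ",", fixed = TRUE)[[1]]
    is_snv <- nchar(ref) == 1 & nchar(alts) == 1 & alts != ref & alts != "*"
    n_skipped <- n_skipped + sum(!is_snv)
    if (!any(is_snv)) next
    rec_id <- paste0(chrom, ":", pos)
    if (has_ad[i]) {
      ads <- strsplit(ad[i, ], ",", fixed = TRUE)
      bad <- vapply(ads, function(a) any(is.na(a)) ||
                      length(a) != length(alts) + 1, logical(1))
      if (any(bad))
        stop("missing or malformed AD field at ", rec_id, " for sample ",
             samples[which(bad)[1]])
      adm <- vapply(ads, function(a) as.integer(a), integer(length(alts) + 1))
      depth <- colSums(adm)
    } else {
      if (is.null(dp) || any(is.na(dp[i, ])) ||
          is.null(af) || any(is.na(af[i, ])))
        stop("no AD field and no usable DP/AF fallback at ", rec_id)
      depth <- as.integer(dp[i, ])
    }
    depth <- unname(depth)
    for (k in which(is_snv)) {
      altc <- if (has_ad[i]) unname(adm[k + 1, ]) else
        as.integer(round(depth * unname(af[i, ])))
      out[[length(out) + 1L]] <- data.frame(
        variant_id = variant_id(chrom, pos, ref, alts[k]),
        chrom = chrom, pos = as.integer(pos),
        ref = ref, alt = alts[k], sample_id = samples,
        assay = assay, depth = as.integer(depth), alt_count = altc,
        stringsAsFactors = FALSE)
    }
  }
  if (n_skipped > 0)
    message(n_skipped, " non-SNV allele(s) skipped")
  obs <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(obs)) obs <- empty_observations()
  rownames(obs) <- NULL
  validate_observations(obs)
}

#' Read a targeted-panel read-count table
#'
#' TSV with columns `variant_id`, `sample_id`, `depth`, `alt_count`
#' (chrom/pos/ref/alt are recovered from the variant id). Rows are tagged
#' with the given assay; merging with WES observations is by exact
#' variant id (see [merge_observations()]).
#'
#' @param path TSV file.
#' @param assay One of `"WES"`, `"TES1"`, `"TES2"`.
#' @return Observation data frame.
#' @export
read_readcount_table <- function(path, assay) {
  assay <- match.arg(assay, ASSAYS)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant_id", "sample_id", "depth", "alt_count")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("read-count table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(tab) == 0) {
    warning("empty read-count table: ", path)
    return(empty_observations())
  }
  bad <- which(is.na(tab$depth) | is.na(tab$alt_count) |
                 tab$depth < 0 | tab$alt_count < 0)
  if (length(bad) > 0)
    stop("malformed read-count row at line ", bad[1] + 1L, " of ", path)
  over <- which(tab$alt_count > tab$depth)
  if (length(over) > 0)
    stop("alt_count > depth at line ", over[1] + 1L, " of ", path)
  loc <- parse_variant_id(tab$variant_id)
  obs <- data.frame(variant_id = tab$variant_id, loc,
                    sample_id = tab$sample_id, assay = assay,
                    depth = as.integer(tab$depth),
                    alt_count = as.integer(tab$alt_count),
                    stringsAsFactors = FALSE)
  validate_observations(obs)
}

#' Combine observation tables from several assays
#'
#' Row-binds observation tables (e.g. WES plus TES1/TES2) after checking
#' that no (variant, sample, assay) observation appears twice.
#'
#' @param ... Observation data frames.
#' @return One observation data frame.
#' @export
merge_observations <- function(...) {
  obs <- do.call(rbind, list(...))
  key <- paste(obs$variant_id, obs$sample_id, obs$assay)
  if (anyDuplicated(key))
    stop("duplicate observation for ", key[duplicated(key)][1])
  rownames(obs) <- NULL
  validate_observations(obs)
}

#' Write an observation table as a read-count TSV
#'
#' Inverse of [read_readcount_table()]; requires a single assay so the
#' reader can round-trip the table bit-exactly.
#'
#' @param observations Observation data frame with one assay.
#' @param path Output TSV.
#' @export
write_readcount_table <- function(observations, path) {
  if (length(unique(observations$assay)) > 1)
    stop("write one assay per read-count table")
  utils::write.table(
    observations[, c("variant_id", "sample_id", "depth", "alt_count")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the sample sheet
#'
#' TSV with columns `sample_id`, `patient_id`, `region_class`
#' (T/M/SVZ/BLOOD), `timepoint` (primary/recurrence), `purity`, `assays`
#' (semicolon-separated). Enforces: purity in \[0, 1\], blood purity 0,
#' exactly one blood sample per patient.
#'
#' @param path TSV file.
#' @return Data frame of sample metadata.
#' @export
read_sample_sheet <- function(path) {
  s <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_sheet(s)
}

validate_sample_sheet <- function(s) {
  need <- c("sample_id", "patient_id", "region_class", "timepoint",
            "purity", "assays")
  miss <- setdiff(need, names(s))
  if (length(miss) > 0)
    stop("sample sheet lacks columns: ", paste(miss, collapse = ", "))
  if (!all(s$region_class %in% REGION_CLASSES))
    stop("region_class must be one of ", paste(REGION_CLASSES, collapse = "/"))
  if (!all(s$timepoint %in% c("primary", "recurrence")))
    stop("timepoint must be primary or recurrence")
  if (any(s$purity < 0 | s$purity > 1)) stop("purity must lie in [0, 1]")
  if (any(s$purity[s$region_class == "BLOOD"] != 0))
    stop("blood samples must have purity 0")
  nb <- table(s$patient_id[s$region_class == "BLOOD"])
  pats <- unique(s$patient_id)
  if (!setequal(names(nb), pats) || any(nb != 1))
    stop("each patient needs exactly one BLOOD sample")
  if (anyDuplicated(s$sample_id)) stop("duplicate sample_id in sample sheet")
  s
}

#' Read copy-number segments
#'
#' TSV with columns `sample_id`, `chrom`, `start`, `end`, `total_cn`,
#' `major_cn`. Intervals are 1-based and closed (both ends included),
#' matching VCF positions; segments of one sample must not overlap within
#' a chromosome.
#'
#' @param path TSV file.
#' @return Data frame of segments.
#' @export
read_copy_number <- function(path) {
  seg <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "chrom", "start", "end", "total_cn", "major_cn")
  miss <- setdiff(need, names(seg))
  if (length(miss) > 0)
    stop("copy-number table lacks columns: ", paste(miss, collapse = ", "))
  if (any(seg$start > seg$end)) stop("segment start > end")
  if (any(seg$major_cn > seg$total_cn)) stop("major_cn > total_cn")
  if (any(seg$total_cn < 0)) stop("negative copy number")
  for (key in split(seg, paste(seg$sample_id, seg$chrom))) {
    key <- key[order(key$start), , drop = FALSE]
    if (nrow(key) > 1 && any(key$start[-1] <= key$end[-nrow(key)]))
      stop("overlapping copy-number segments for sample ",
           key$sample_id[1], " on ", key$chrom[1])
  }
  seg
}

#' Annotate variant positions with copy-number state per sample
#'
#' Maps every (variant, sample) pair to its unique overlapping segment.
#' Positions covered by no segment fall back to a default state (diploid
#' heterozygous, `total_cn = 2`, `major_cn = 1`) and are flagged with
#' `cn_default = TRUE`; flagged variants are excluded from beta-binomial
#' training but may still be tested.
#'
#' @param variants Data frame with `variant_id`, `chrom`, `pos` (an
#'   observation table works; rows are de-duplicated by variant).
#' @param segments Segment table from [read_copy_number()].
#' @param samples Sample ids to annotate; default all in `segments`.
#' @param default_total,default_major Fallback state.
#' @return Data frame `variant_id`, `sample_id`, `total_cn`, `major_cn`,
#'   `cn_default`.
#' @export
annotate_copy_number <- function(variants, segments,
                                 samples = unique(segments$sample_id),
                                 default_total = 2L, default_major = 1L) {
  vv <- unique(variants[, c("variant_id", "chrom", "pos")])
  out <- vector("list", length(samples))
  for (si in seq_along(samples)) {
    s <- samples[si]
    res <- data.frame(variant_id = vv$variant_id, sample_id = s,
                      total_cn = as.integer(default_total),
                      major_cn = as.integer(default_major),
                      cn_default = TRUE, stringsAsFactors = FALSE)
    segs <- segments[segments$sample_id == s, , drop = FALSE]
    for (ch in unique(vv$chrom)) {
      sc <- segs[segs$chrom == ch, , drop = FALSE]
      if (nrow(sc) == 0) next
      sc <- sc[order(sc$start), , drop = FALSE]
      idx <- which(vv$chrom == ch)
      hit <- findInterval(vv$pos[idx], sc$start)
      ok <- hit > 0 & ifelse(hit > 0, vv$pos[idx] <= sc$end[pmax(hit, 1)], FALSE)
      # closed intervals: pos == end is inside; findInterval handles start
      res$total_cn[idx[ok]] <- as.integer(sc$total_cn[hit[ok]])
      res$major_cn[idx[ok]] <- as.integer(sc$major_cn[hit[ok]])
      res$cn_default[idx[ok]] <- FALSE
    }
    out[[si]] <- res
  }
  do.call(rbind, out)
}

#' Write a rooted tree with bootstrap supports as Newick
#'
#' Internal-node bootstrap supports (0--100) are written as integer node
#' labels; unrooted trees are refused.
#'
#' @param tree A rooted `phylo`, e.g. from [bootstrap_support()].
#' @param path Output file.
#' @export
write_newick <- function(tree, path) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted (germline outgroup)")
  if (!is.null(tree$node.label)) {
    lab <- suppressWarnings(as.numeric(tree$node.label))
    tree$node.label <- ifelse(is.na(lab), "", as.character(as.integer(round(lab))))
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a results table as TSV
#'
#' Generic TSV writer used for truncal sets, absence-test results and
#' per-branch mutation lists; an empty table yields a header-only file.
#'
#' @param results Data frame.
#' @param path Output file.
#' @export
write_results_table <- function(results, path) {
  utils::write.table(as.data.frame(results), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a presence matrix as TSV
#'
#' Cells are written as the words PRESENT/ABSENT/UNKNOWN with samples in
#' rows; [read_presence_matrix()] inverts it.
#'
#' @param pmat Integer matrix (1/0/NA) from [build_presence_matrix()].
#' @param path Output file.
#' @export
write_presence_matrix <- function(pmat, path) {
  words <- matrix(c("ABSENT", "PRESENT")[pmat + 1L], nrow = nrow(pmat),
                  dimnames = dimnames(pmat))
  words[is.na(pmat)] <- "UNKNOWN"
  df <- data.frame(sample_id = rownames(pmat), words, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_presence_matrix
#' @export
read_presence_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  out <- matrix(NA_integer_, nrow(m), ncol(m),
                dimnames = list(df$sample_id, colnames(m)))
  out[m == "PRESENT"] <- 1L
  out[m == "ABSENT"] <- 0L
  out
}
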