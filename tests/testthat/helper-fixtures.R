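# Shared builders for tiny in-code fixtures.

tiny_sheet <- function(n_t = 3, m = TRUE, svz = FALSE) {
  ids <- c(paste0("T", seq_len(n_t)), if (m) "M1", if (svz) "SVZ1", "BLOOD")
  cls <- c(rep("T", n_t), if (m) "M", if (svz) "SVZ", "BLOOD")
  data.frame(sample_id = ids, patient_id = "P1", region_class = cls,
             timepoint = "primary",
             purity = c(rep(0.6, n_t), if (m) 0.07, if (svz) 0.22, 0),
             assays = ifelse(cls %in% c("M", "SVZ"), "WES;TES1;TES2", "WES"),
             stringsAsFactors = FALSE)
}

obs_row <- function(vid, sample, assay, depth, alt) {
  loc <- resiphy:::parse_variant_id(vid)
  data.frame(variant_id = vid, loc, sample_id = sample, assay = assay,
             depth = as.integer(depth), alt_count = as.integer(alt),
             stringsAsFactors = FALSE)
}

tiny_truncal <- function(ids, total_cn = 2L, major_cn = 1L) {
  data.frame(variant_id = ids, total_cn = total_cn, major_cn = major_cn,
             cn_default = FALSE, min_ccf = 1, stringsAsFactors = FALSE)
}

# Binomial-limit fit trained at a known purity (diploid heterozygous).
binom_fit <- function(mu = 0.3, purity = 0.6) {
  resiphy:::new_bb_fit(mu, 0, 2L, 1L, sample_id = "T1", purity = purity,
                       multiplicity = 1L, n_training = 100L)
}

# A small multi-sample VCF written as text; counts is a list keyed by
# "chrom:pos" of per-sample "ref,alt" AD strings.
write_tiny_vcf <- function(path, rows, samples) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, rows), path)
  path
}

# All rooted topologies with `outgroup` as root-adjacent leaf: every
# unrooted topology on the taxon set, rooted on the outgroup. Independent
# of the branch-and-bound search path.
all_rooted_trees <- function(taxa, outgroup) {
  trees <- phangorn::allTrees(length(taxa), rooted = FALSE, tip.label = taxa)
  lapply(trees, function(t) ape::root(t, outgroup, resolve.root = TRUE))
}

# Exhaustive minimum parsimony score over all topologies.
exhaustive_min_score <- function(pmat, outgroup) {
  trees <- all_rooted_trees(rownames(pmat), outgroup)
  min(vapply(trees, fitch_score, integer(1), pmat = pmat))
}
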