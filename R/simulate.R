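# Seeded clonal-evolution simulator emulating the study design this
# package is built for: a multi-region glioblastoma with 4-6 high-purity
# tumour-mass samples (purity around 0.59), an SVZ sample around 0.22, an
# infiltrative margin at 5-10% purity, and a germline blood sample;
# whole-exome depth around x157 and targeted panels around x4050 (TES1)
# and x1128 (TES2). Read counts are beta-binomial around the true VAF so
# the noise model matches the one the absence test assumes; absent
# mutations draw zero variant reads (no sequencing-error reads -- see the
# methods vignette for what that does and does not exercise).

#' Simulation configuration
#'
#' Defaults encode the sampling design described above. `n_clones` counts
#' the germline root, so `n_clones = 2` is a single-trunk tumour. With
#' `ancestral_margin = TRUE` the margin's dominant clone is the first
#' tumour clone (the trunk), every tumour-mass dominant clone descends
#' from a later shared ancestor, and the margin sample contains *only* its
#' dominant clone, making the trunk-to-ancestor mutations truly absent
#' there.
#'
#' @param n_clones Number of clones including the germline root.
#' @param mut_rate Poisson mean of mutations per clone-tree edge.
#' @param mut_counts Optional exact per-edge mutation counts (named by
#'   child clone, `"2"` upward); overrides `mut_rate`.
#' @param ancestral_margin Encode the early-diverging-margin scenario?
#' @param n_t,n_m,n_svz Numbers of tumour-mass, margin and SVZ samples.
#' @param t_purity,m_purity,svz_purity Purity ranges (uniform draws).
#' @param depths Named mean depths per assay.
#' @param depth_size Negative-binomial size (dispersion) of depths;
#'   `Inf` gives fixed depths at the assay means.
#' @param t_assays,m_assays,svz_assays Semicolon-separated assay lists.
#' @param rho Beta-binomial overdispersion of simulated read counts.
#' @param dominance,base_conc Dirichlet concentration on the dominant
#'   clone and on the others.
#' @param pure If `TRUE` every sample contains only its dominant clone.
#' @param diploid_frac Fraction of mutations in diploid regions; the rest
#'   sit in clonal altered segments (a 3/2 gain and a 1/1 loss), with a
#'   small `uncovered_frac` on a chromosome with no segment at all to
#'   exercise the default-state fallback.
#' @param uncovered_frac See above.
#' @param patient_id Patient label in the sample sheet.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_clones = 6, mut_rate = 25, mut_counts = NULL,
                       ancestral_margin = TRUE,
                       n_t = 4, n_m = 1, n_svz = 1,
                       t_purity = c(0.45, 0.75),
                       m_purity = c(0.05, 0.10),
                       svz_purity = c(0.15, 0.30),
                       depths = c(WES = 157, TES1 = 4050, TES2 = 1128),
                       depth_size = 10,
                       t_assays = "WES;TES1",
                       m_assays = "WES;TES1;TES2",
                       svz_assays = "WES;TES1;TES2",
                       rho = 0.005, dominance = 30, base_conc = 0.3,
                       pure = FALSE, diploid_frac = 0.8,
                       uncovered_frac = 0.03, patient_id = "SIM01") {
  stopifnot(n_clones >= 2, n_t >= 2, all(depths > 0), rho >= 0, rho < 1,
            all(c(t_purity, m_purity, svz_purity) >= 0),
            all(c(t_purity, m_purity, svz_purity) <= 1))
  structure(as.list(environment()), class = "sim_config")
}

# Altered copy-number states used by the simulator (clonal).
.SIM_CN <- data.frame(
  chrom = c("chr19", "chr20"), start = 1L, end = 50000000L,
  total_cn = c(3L, 1L), major_cn = c(2L, 1L), multiplicity = c(2L, 1L),
  stringsAsFactors = FALSE)

#' Simulate a clone tree with mutations on its edges
#'
#' Clone 1 is the germline root; clone 2 attaches to it (the trunk) and
#' later clones attach by sequential uniform attachment (restricted to
#' descendants of clone 3 in the ancestral-margin scenario, so that clone
#' 2 remains ancestral to every tumour-mass dominant). Edge mutation
#' counts are Poisson; chromosome placement fixes each mutation's
#' copy-number state and multiplicity.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed; identical seeds give identical truth.
#' @return List of class `tumour_sim` (partially filled): `parent` vector,
#'   `mutations` data frame, `cn_states`.
#' @export
simulate_clone_tree <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  n <- config$n_clones
  parent <- c(NA_integer_, 1L)
  if (n >= 3) parent <- c(parent, 2L)
  if (n >= 4) {
    lo <- if (config$ancestral_margin) 3L else 2L
    for (k in 4:n) {
      cand <- lo:(k - 1)
      parent[k] <- cand[sample.int(length(cand), 1)]
    }
  }
  edges <- 2:n
  if (!is.null(config$mut_counts)) {
    cnt <- config$mut_counts[as.character(edges)]
    stopifnot(!any(is.na(cnt)))
  } else {
    cnt <- stats::rpois(length(edges), config$mut_rate)
  }
  total <- sum(cnt)
  clone <- rep(edges, cnt)
  u <- stats::runif(total)
  state <- ifelse(u < config$uncovered_frac, 0L,
                  ifelse(u < config$uncovered_frac + (1 - config$diploid_frac),
                         1L + (seq_len(total) %% 2L), 99L))
  chrom <- character(total); mult <- integer(total)
  tot_cn <- integer(total); maj_cn <- integer(total)
  diploid <- state == 99L
  chrom[diploid] <- paste0("chr", sample.int(17, sum(diploid), replace = TRUE))
  tot_cn[diploid] <- 2L; maj_cn[diploid] <- 1L; mult[diploid] <- 1L
  uncov <- state == 0L
  chrom[uncov] <- "chr21"
  tot_cn[uncov] <- 2L; maj_cn[uncov] <- 1L; mult[uncov] <- 1L
  for (k in 1:2) {
    sel <- state == k
    chrom[sel] <- .SIM_CN$chrom[k]
    tot_cn[sel] <- .SIM_CN$total_cn[k]
    maj_cn[sel] <- .SIM_CN$major_cn[k]
    mult[sel] <- .SIM_CN$multiplicity[k]
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, total, replace = TRUE)
  alt <- unname(vapply(ref, function(r) sample(setdiff(bases, r), 1),
                       character(1)))
  pos <- sample.int(49000000L, total)
  mut <- data.frame(
    mutation = sprintf("m%04d", seq_len(total)), clone = clone,
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    total_cn = tot_cn, major_cn = maj_cn, multiplicity = mult,
    cn_covered = !uncov, stringsAsFactors = FALSE)
  mut$variant_id <- variant_id(mut$chrom, mut$pos, mut$ref, mut$alt)
  structure(list(config = config, seed = seed, parent = parent,
                 mutations = mut),
            class = "tumour_sim")
}

# Clones carrying a mutation on the edge above `clone`: itself plus all
# descendants.
.carriers <- function(parent, clone) {
  n <- length(parent)
  carry <- clone
  repeat {
    add <- which(parent %in% carry & !(seq_len(n) %in% carry))
    if (length(add) == 0) break
    carry <- c(carry, add)
  }
  sort(carry)
}

#' Compose samples as clone mixtures
#'
#' Draws per-sample clone-mixture weights (Dirichlet concentrated on each
#' sample's dominant clone) and purities, producing the sample sheet and
#' the per-mutation, per-sample true VAF implied by purity, copy number,
#' multiplicity and the mixture.
#'
#' @param sim Output of [simulate_clone_tree()] (continues its RNG stream;
#'   call right after it for reproducibility, or reseed).
#' @return The `tumour_sim` with `samples`, `weights` (samples x clones)
#'   and `true_vaf` (mutations x samples) filled in.
#' @export
compose_samples <- function(sim) {
  cfg <- sim$config
  n <- cfg$n_clones
  tumour_clones <- 2:n
  t_cand <- if (cfg$ancestral_margin && n >= 3) 3:n else 2:n
  t_dom <- rep_len(t_cand, cfg$n_t)
  rows <- list(); wts <- list()
  mk <- function(sid, cls, purity, dom, present, assays) {
    w <- stats::setNames(numeric(length(tumour_clones)),
                         tumour_clones)
    if (length(present) == 0) {
      # blood: no tumour clones
    } else if (cfg$pure || length(present) == 1) {
      w[as.character(dom)] <- 1
    } else {
      conc <- stats::setNames(rep(cfg$base_conc, length(present)),
                              present)
      conc[as.character(dom)] <- cfg$dominance
      g <- stats::rgamma(length(present), shape = conc)
      w[as.character(present)] <- g / sum(g)
    }
    rows[[length(rows) + 1]] <<- data.frame(
      sample_id = sid, patient_id = cfg$patient_id, region_class = cls,
      timepoint = "primary", purity = purity, assays = assays,
      dominant_clone = dom, stringsAsFactors = FALSE)
    wts[[length(wts) + 1]] <<- w
  }
  for (i in seq_len(cfg$n_t))
    mk(paste0("T", i), "T", stats::runif(1, cfg$t_purity[1], cfg$t_purity[2]),
       t_dom[i], tumour_clones, cfg$t_assays)
  for (i in seq_len(cfg$n_m)) {
    dom <- if (cfg$ancestral_margin) 2L else
      tumour_clones[sample.int(length(tumour_clones), 1)]
    present <- if (cfg$ancestral_margin) dom else tumour_clones
    mk(paste0("M", i), "M", stats::runif(1, cfg$m_purity[1], cfg$m_purity[2]),
       dom, present, cfg$m_assays)
  }
  for (i in seq_len(cfg$n_svz)) {
    dom <- if (n >= 3) 3L else 2L
    mk(paste0("SVZ", i), "SVZ",
       stats::runif(1, cfg$svz_purity[1], cfg$svz_purity[2]),
       dom, tumour_clones, cfg$svz_assays)
  }
  mk("BLOOD", "BLOOD", 0, NA_integer_, integer(0), "WES")
  samples <- do.call(rbind, rows)
  weights <- do.call(rbind, wts)
  rownames(weights) <- samples$sample_id
  mut <- sim$mutations
  vaf <- matrix(0, nrow(mut), nrow(samples),
                dimnames = list(mut$variant_id, samples$sample_id))
  carry <- lapply(tumour_clones, function(cl) .carriers(sim$parent, cl))
  names(carry) <- tumour_clones
  for (s in seq_len(nrow(samples))) {
    pi_s <- samples$purity[s]
    if (pi_s == 0) next
    for (j in seq_len(nrow(mut))) {
      w <- sum(weights[s, as.character(
        intersect(carry[[as.character(mut$clone[j])]], tumour_clones))])
      vaf[j, s] <- pi_s * mut$multiplicity[j] * w /
        (pi_s * mut$total_cn[j] + (1 - pi_s) * 2)
    }
  }
  sim$samples <- samples
  sim$weights <- weights
  sim$true_vaf <- vaf
  sim
}

#' Draw read counts for every sample, assay and mutation
#'
#' Depths are negative-binomial around each assay's mean; variant reads
#' are beta-binomial around the true VAF with overdispersion `rho`.
#' Mutations absent from a sample (true VAF 0) draw zero variant reads.
#'
#' @param sim Output of [compose_samples()].
#' @return The `tumour_sim` with `observations` and `cn_segments` filled.
#' @export
simulate_read_counts <- function(sim) {
  cfg <- sim$config
  mut <- sim$mutations
  obs <- list()
  for (s in seq_len(nrow(sim$samples))) {
    sid <- sim$samples$sample_id[s]
    for (assay in strsplit(sim$samples$assays[s], ";", fixed = TRUE)[[1]]) {
      depth <- if (is.finite(cfg$depth_size))
        stats::rnbinom(nrow(mut), mu = cfg$depths[[assay]],
                       size = cfg$depth_size)
      else rep(as.integer(round(cfg$depths[[assay]])), nrow(mut))
      alt <- integer(nrow(mut))
      v <- sim$true_vaf[, sid]
      pos <- which(v > 0 & depth > 0)
      if (cfg$rho > 0) {
        sh <- bb_shapes(v[pos], cfg$rho)
        p <- stats::rbeta(length(pos), sh$alpha, sh$beta)
        alt[pos] <- stats::rbinom(length(pos), depth[pos], p)
      } else {
        alt[pos] <- stats::rbinom(length(pos), depth[pos], v[pos])
      }
      obs[[length(obs) + 1]] <- data.frame(
        variant_id = mut$variant_id, chrom = mut$chrom, pos = mut$pos,
        ref = mut$ref, alt = mut$alt, sample_id = sid, assay = assay,
        depth = depth, alt_count = alt, stringsAsFactors = FALSE)
    }
  }
  sim$observations <- do.call(rbind, obs)
  rownames(sim$observations) <- NULL
  tum <- sim$samples$sample_id[sim$samples$region_class != "BLOOD"]
  base <- rbind(
    data.frame(chrom = paste0("chr", 1:17), start = 1L, end = 250000000L,
               total_cn = 2L, major_cn = 1L, stringsAsFactors = FALSE),
    .SIM_CN[, c("chrom", "start", "end", "total_cn", "major_cn")])
  sim$cn_segments <- do.call(rbind, lapply(tum, function(s)
    cbind(sample_id = s, base, stringsAsFactors = FALSE)))
  rownames(sim$cn_segments) <- NULL
  sim
}

#' Simulate a complete patient dataset
#'
#' Convenience wrapper: clone tree, sample composition and read counts in
#' one seeded call.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed; all draws flow from it.
#' @return A complete `tumour_sim`.
#' @export
simulate_patient <- function(config = sim_config(), seed = 1) {
  simulate_read_counts(compose_samples(simulate_clone_tree(config, seed)))
}

#' Expected sample phylogeny of a simulated patient
#'
#' Builds the sample tree implied by the clone tree and each sample's
#' dominant clone: samples hang from their dominant clone, clone nodes
#' with fewer than two children are suppressed, and the blood sample roots
#' the tree.
#'
#' @param sim A `tumour_sim` with samples composed.
#' @return A rooted `phylo`.
#' @export
true_sample_tree <- function(sim) {
  kids <- split(seq_along(sim$parent), sim$parent)
  att <- split(sim$samples$sample_id[!is.na(sim$samples$dominant_clone)],
               sim$samples$dominant_clone[!is.na(sim$samples$dominant_clone)])
  rec <- function(clone) {
    items <- c(unlist(lapply(kids[[as.character(clone)]], rec)),
               att[[as.character(clone)]])
    items <- items[!is.na(items) & nzchar(items)]
    if (length(items) == 0) return(character(0))
    if (length(items) == 1) return(items)
    paste0("(", paste(sort(items), collapse = ","), ")")
  }
  core <- rec(2L)
  blood <- sim$samples$sample_id[sim$samples$region_class == "BLOOD"]
  ape::read.tree(text = paste0("(", blood, ",", core, ");"))
}

#' Write a simulated dataset in the pipeline's input dialects
#'
#' Emits a multi-sample VCF of the WES counts, TES1/TES2 read-count
#' tables, the copy-number segment table, the sample sheet, and truth
#' files (mutation-to-clone map, clone mixtures, expected sample tree) in
#' a directory.
#'
#' @param sim A complete `tumour_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_patient_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wes <- sim$observations[sim$observations$assay == "WES", , drop = FALSE]
  write_simulated_vcf(wes, file.path(dir, "wes.vcf"))
  for (a in c("TES1", "TES2")) {
    t <- sim$observations[sim$observations$assay == a, , drop = FALSE]
    if (nrow(t) > 0)
      write_readcount_table(t, file.path(dir, paste0(tolower(a), ".tsv")))
  }
  write_results_table(sim$cn_segments, file.path(dir, "cn.tsv"))
  write_results_table(
    sim$samples[, c("sample_id", "patient_id", "region_class", "timepoint",
                    "purity", "assays")],
    file.path(dir, "samples.tsv"))
  write_results_table(
    sim$mutations[, c("variant_id", "mutation", "clone", "total_cn",
                      "major_cn", "multiplicity")],
    file.path(dir, "truth_mutations.tsv"))
  wt <- data.frame(sample_id = rownames(sim$weights), sim$weights,
                   check.names = FALSE)
  write_results_table(wt, file.path(dir, "truth_weights.tsv"))
  ape::write.tree(true_sample_tree(sim), file.path(dir, "truth_tree.nwk"))
  invisible(dir)
}

# Minimal fixed-dialect VCF emitter for simulated WES counts (GT:AD:DP,
# one ALT per row). Read back with read_multisample_vcf().
write_simulated_vcf <- function(observations, path) {
  obs <- observations
  samples <- sort(unique(obs$sample_id))
  vars <- unique(obs[, c("variant_id", "chrom", "pos", "ref", "alt")])
  vars <- vars[order(vars$chrom, vars$pos), , drop = FALSE]
  hdr <- c("##fileformat=VCFv4.2",
           "##source=resiphy-simulator",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  key <- paste(obs$variant_id, obs$sample_id)
  rows <- vapply(seq_len(nrow(vars)), function(i) {
    cells <- vapply(samples, function(s) {
      j <- match(paste(vars$variant_id[i], s), key)
      if (is.na(j)) return("./.:.,.:.")
      d <- obs$depth[j]; a <- obs$alt_count[j]
      sprintf("%s:%d,%d:%d", if (a > 0) "0/1" else "0/0", d - a, a, d)
    }, character(1))
    paste(c(vars$chrom[i], vars$pos[i], ".", vars$ref[i], vars$alt[i], ".",
            "PASS", ".", "GT:AD:DP", cells), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
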