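# Per-patient orchestration: load -> annotate copy number -> CCF ->
# truncal selection -> beta-binomial fits -> absence test -> presence
# matrix -> parsimony tree -> bootstrap. Each patient is analysed
# independently; multi-patient cohorts are a loop over run_patient().

#' Pipeline parameters
#'
#' Validated bundle of the tunable parameters, with the defaults used
#' throughout: CCF threshold 0.8 for truncal selection, worst-case purity
#' 0.01 for the absence test, alpha 0.05 with Bonferroni correction, 1000
#' bootstrap replicates, 10 training SNVs per copy-number state, and the
#' 2-read / 0.05% detection floor.
#'
#' @param ccf_threshold,pi_star,alpha,n_bootstrap,min_training Numeric
#'   parameters (see above).
#' @param min_alt,min_frac Detection-rule parameters ([detection_rule()]).
#' @param normal_cn Germline copy number.
#' @param seed RNG seed for the bootstrap.
#' @return A list of class `pipeline_params`.
#' @export
pipeline_params <- function(ccf_threshold = 0.8, pi_star = 0.01,
                            alpha = 0.05, n_bootstrap = 1000,
                            min_training = 10, min_alt = 2,
                            min_frac = 5e-4, normal_cn = 2, seed = 1) {
  if (!(ccf_threshold > 0 && ccf_threshold <= 1))
    stop("ccf_threshold must lie in (0, 1]")
  if (!(pi_star > 0 && pi_star <= 1))
    stop("pi_star must lie in (0, 1]")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (n_bootstrap < 0) stop("n_bootstrap must be >= 0")
  if (min_training < 2) stop("min_training must be >= 2")
  structure(list(ccf_threshold = ccf_threshold, pi_star = pi_star,
                 alpha = alpha, n_bootstrap = n_bootstrap,
                 min_training = min_training,
                 rule = detection_rule(min_alt, min_frac),
                 normal_cn = normal_cn, seed = seed),
            class = "pipeline_params")
}

#' Analyse one patient in memory
#'
#' Runs the full statistical chain on already-loaded tables. Stage order:
#' copy-number annotation, CCF, truncal selection, beta-binomial training
#' (highest-purity tumour-mass sample), absence test on every margin/SVZ
#' sample, presence matrix, exact parsimony tree, bootstrap (skipped when
#' `n_bootstrap = 0`).
#'
#' @param observations Observation table (all assays).
#' @param sample_sheet Sample metadata for one patient.
#' @param segments Copy-number segments.
#' @param params A [pipeline_params()].
#' @return List: `cn_map`, `ccf`, `truncal`, `fits`, `absence`, `pmat`,
#'   `tree`, `params`.
#' @export
analyse_patient <- function(observations, sample_sheet, segments,
                            params = pipeline_params()) {
  stopifnot(inherits(params, "pipeline_params"))
  validate_sample_sheet(sample_sheet)
  validate_observations(observations)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  cn_map <- stage("annotate_cn", annotate_copy_number(
    observations, segments, samples = sample_sheet$sample_id))
  ccf <- stage("ccf", compute_ccf_table(
    observations, sample_sheet, cn_map, normal_cn = params$normal_cn))
  tum <- sample_sheet$sample_id[sample_sheet$region_class == "T"]
  truncal <- stage("truncal_selection", select_putative_truncal(
    ccf, tum, params$ccf_threshold))
  fits <- stage("betabinomial_fit", train_vaf_models(
    observations, truncal, sample_sheet, min_training = params$min_training,
    normal_cn = params$normal_cn))
  absence <- stage("absence_test", run_absence_test(
    observations, truncal, fits$best, sample_sheet, cn_map = cn_map,
    pi_star = params$pi_star, alpha = params$alpha, rule = params$rule,
    normal_cn = params$normal_cn))
  pmat <- stage("presence_matrix", build_presence_matrix(
    observations, sample_sheet, absence, rule = params$rule))
  blood <- sample_sheet$sample_id[sample_sheet$region_class == "BLOOD"]
  tree <- stage("parsimony_tree",
    if (params$n_bootstrap > 0)
      bootstrap_support(pmat, blood, params$n_bootstrap, seed = params$seed)
    else parsimony_tree(pmat, blood))
  list(cn_map = cn_map, ccf = ccf, truncal = truncal, fits = fits,
       absence = absence, pmat = pmat, tree = tree, params = params)
}

#' Run the per-patient pipeline from files
#'
#' Reads the inputs named in `config`, calls [analyse_patient()] and
#' writes the result tables: `truncal.tsv`, `absence_test.tsv`,
#' `presence_matrix.tsv`, `tree.nwk`, `branch_mutations.tsv` and a
#' parameter-echoing `run_log.txt`. Outputs are deterministic: the same
#' config produces byte-identical files.
#'
#' @param config List with `paths` (named: `vcf`, optional `tes1`/`tes2`
#'   read-count tables, `cn`, `sample_sheet`), `out_dir` and optional
#'   `params` (a [pipeline_params()] or a list of its arguments).
#' @return The [analyse_patient()] result, invisibly.
#' @export
run_patient <- function(config) {
  stopifnot(is.list(config), !is.null(config$paths), !is.null(config$out_dir))
  params <- config$params
  if (is.null(params)) params <- pipeline_params()
  if (!inherits(params, "pipeline_params"))
    params <- do.call(pipeline_params, params)
  p <- config$paths
  sheet <- read_sample_sheet(p$sample_sheet)
  obs <- read_multisample_vcf(p$vcf, sheet)
  for (a in c("tes1", "tes2"))
    if (!is.null(p[[a]]))
      obs <- merge_observations(obs, read_readcount_table(p[[a]], toupper(a)))
  segments <- read_copy_number(p$cn)

  res <- analyse_patient(obs, sheet, segments, params)

  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_results_table(as.data.frame(res$truncal),
                      file.path(out, "truncal.tsv"))
  write_results_table(res$absence, file.path(out, "absence_test.tsv"))
  write_presence_matrix(res$pmat, file.path(out, "presence_matrix.tsv"))
  write_newick(res$tree, file.path(out, "tree.nwk"))
  write_results_table(branch_mutations(res$tree),
                      file.path(out, "branch_mutations.tsv"))
  log <- c(
    "resiphy run log",
    paste0("inputs: ", paste(names(p), unlist(p), sep = "=", collapse = " ")),
    paste0("parameters: ccf_threshold=", params$ccf_threshold,
           " pi_star=", params$pi_star, " alpha=", params$alpha,
           " n_bootstrap=", params$n_bootstrap,
           " min_training=", params$min_training,
           " detection=", params$rule$min_alt, "/", params$rule$min_frac,
           " normal_cn=", params$normal_cn, " seed=", params$seed),
    paste0("observations: ", nrow(obs)),
    paste0("truncal SNVs: ", nrow(res$truncal)),
    paste0("absence calls: ",
           sum(res$absence$decision == "ABSENT"), " ABSENT, ",
           sum(res$absence$decision == "UNDETERMINED"), " UNDETERMINED, ",
           sum(res$absence$decision == "DETECTED"), " DETECTED"),
    paste0("parsimony score: ", attr(res$tree, "parsimony_score")))
  writeLines(log, file.path(out, "run_log.txt"))
  invisible(res)
}

#' Simulate a patient and write it as a pipeline-ready fixture
#'
#' Thin wrapper over [simulate_patient()] and [write_patient_dataset()]
#' that also returns a [run_patient()] config pointing at the files.
#'
#' @param dir Fixture directory.
#' @param config A [sim_config()].
#' @param seed RNG seed.
#' @param params Optional [pipeline_params()] for the returned config.
#' @return A `run_patient()`-ready config list, invisibly.
#' @export
simulate_patient_files <- function(dir, config = sim_config(), seed = 1,
                                   params = pipeline_params()) {
  sim <- simulate_patient(config, seed)
  write_patient_dataset(sim, dir)
  cfg <- list(paths = list(vcf = file.path(dir, "wes.vcf"),
                           tes1 = file.path(dir, "tes1.tsv"),
                           tes2 = file.path(dir, "tes2.tsv"),
                           cn = file.path(dir, "cn.tsv"),
                           sample_sheet = file.path(dir, "samples.tsv")),
              out_dir = file.path(dir, "results"),
              params = params)
  for (a in c("tes1", "tes2"))
    if (!file.exists(cfg$paths[[a]])) cfg$paths[[a]] <- NULL
  invisible(cfg)
}
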