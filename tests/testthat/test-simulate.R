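# Clonal-evolution simulator: determinism, composition, noise model.

test_that("the same seed reproduces the dataset bit-exactly", {
  a <- simulate_patient(sim_config(n_clones = 4), seed = 13)
  b <- simulate_patient(sim_config(n_clones = 4), seed = 13)
  expect_identical(a$observations, b$observations)
  expect_identical(a$weights, b$weights)
  c <- simulate_patient(sim_config(n_clones = 4), seed = 14)
  expect_false(identical(a$observations$alt_count, c$observations$alt_count))
})

test_that("a two-clone tumour is all-truncal and blood is clean", {
  sim <- simulate_patient(sim_config(n_clones = 2), seed = 2)
  expect_true(all(sim$mutations$clone == 2))
  blood <- sim$observations[sim$observations$sample_id == "BLOOD", ]
  expect_true(all(blood$alt_count == 0))
  expect_true(all(abs(rowSums(sim$weights[sim$samples$purity > 0, ,
                                          drop = FALSE]) - 1) < 1e-12))
})

test_that("ancestral margin carries a subset of every tumour sample's clone", {
  sim <- simulate_patient(sim_config(), seed = 5)
  margin_dom <- sim$samples$dominant_clone[sim$samples$region_class == "M"]
  expect_equal(margin_dom, 2L)
  # margin contains only its dominant clone
  w <- sim$weights["M1", ]
  expect_equal(unname(w[as.character(margin_dom)]), 1)
  # every tumour dominant clone descends from clone 3, hence carries the
  # trunk mutations of clone 2 but not vice versa
  t_dom <- sim$samples$dominant_clone[sim$samples$region_class == "T"]
  expect_true(all(t_dom %in% resiphy:::.carriers(sim$parent, 3L)))
  expect_false(2L %in% resiphy:::.carriers(sim$parent, 3L))
})

test_that("fixed depth model and the large-depth VAF law of large numbers", {
  cfg <- sim_config(n_clones = 3, depth_size = Inf,
                    depths = c(WES = 100, TES1 = 4050, TES2 = 1128),
                    t_assays = "WES", m_assays = "WES", svz_assays = "WES")
  sim <- simulate_patient(cfg, seed = 8)
  wes <- sim$observations[sim$observations$assay == "WES", ]
  expect_true(all(wes$depth == 100L))
  # rho -> 0, deep coverage: empirical VAF within 1% of truth
  cfg2 <- sim_config(n_clones = 3, rho = 0, depth_size = Inf,
                     depths = c(WES = 200000, TES1 = 4050, TES2 = 1128),
                     t_assays = "WES", m_assays = "WES", svz_assays = "WES",
                     pure = TRUE)
  sim2 <- simulate_patient(cfg2, seed = 8)
  o <- sim2$observations[sim2$observations$assay == "WES", ]
  v <- sim2$true_vaf[cbind(o$variant_id, o$sample_id)]
  expect_lt(max(abs(o$alt_count / o$depth - v)), 0.01)
})

test_that("simulated files round-trip through the package readers", {
  dir <- tempfile("fixture")
  sim <- simulate_patient(sim_config(n_clones = 4, n_t = 2), seed = 3)
  write_patient_dataset(sim, dir)
  sheet <- read_sample_sheet(file.path(dir, "samples.tsv"))
  expect_equal(sheet$sample_id, sim$samples$sample_id)
  wes <- read_multisample_vcf(file.path(dir, "wes.vcf"), sheet)
  orig <- sim$observations[sim$observations$assay == "WES", ]
  key <- function(d) d[order(d$variant_id, d$sample_id),
                       c("variant_id", "sample_id", "depth", "alt_count")]
  ow <- key(orig); rownames(ow) <- NULL
  bw <- key(wes); rownames(bw) <- NULL
  expect_equal(bw, ow)
  tes1 <- read_readcount_table(file.path(dir, "tes1.tsv"), "TES1")
  ot <- key(sim$observations[sim$observations$assay == "TES1", ])
  rownames(ot) <- NULL
  bt <- key(tes1); rownames(bt) <- NULL
  expect_equal(bt, ot)
  segs <- read_copy_number(file.path(dir, "cn.tsv"))
  expect_true(all(c("chr19", "chr20") %in% segs$chrom))
})

test_that("noiseless high-depth data recover exactly the trunk as truncal", {
  cfg <- sim_config(n_clones = 5, ancestral_margin = FALSE, n_t = 4,
                    rho = 0, depth_size = Inf,
                    depths = c(WES = 5000, TES1 = 4050, TES2 = 1128),
                    uncovered_frac = 0)
  sim <- simulate_patient(cfg, seed = 17)
  # dominant clones cover 2..5, so only trunk mutations are shared
  expect_setequal(sim$samples$dominant_clone[sim$samples$region_class == "T"],
                  2:5)
  sheet <- sim$samples[, 1:6]
  cn <- annotate_copy_number(sim$observations, sim$cn_segments)
  ccf <- compute_ccf_table(sim$observations, sheet, cn)
  sel <- select_putative_truncal(ccf, paste0("T", 1:4))
  trunk <- sim$mutations$variant_id[sim$mutations$clone == 2]
  expect_setequal(sel$variant_id, trunk)
})
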