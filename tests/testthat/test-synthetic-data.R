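small_cfg <- function(...) {
  sim_config(chrom_lengths = c(chr1 = 10e6, chr2 = 10e6), tad_mean_bp = 1e6,
             n_genes = 40, n_markers = 60, n_peaks = 80, n_samples = 40, ...)
}

test_that("identical config and seed give identical datasets", {
  d1 <- generate_genome(small_cfg(), seed = 1)
  d2 <- generate_genome(small_cfg(), seed = 1)
  expect_identical(d1, d2)
  d3 <- plant_models(d1, truth_spec(), seed = 2)
  d4 <- plant_models(d2, truth_spec(), seed = 2)
  expect_identical(d3, d4)
  d5 <- generate_genome(small_cfg(), seed = 99)
  expect_false(identical(d1$dosage, d5$dosage))
})

test_that("TADs stay inside chromosome bounds and never overlap", {
  ds <- generate_genome(small_cfg(), seed = 3)
  for (ch in ds$genome$chrom) {
    tt <- ds$tads[ds$tads$chrom == ch, ]
    tt <- tt[order(tt$start), ]
    L <- ds$genome$length[ds$genome$chrom == ch]
    expect_true(all(tt$start >= 0 & tt$end <= L))
    expect_true(all(tt$end > tt$start))
    if (nrow(tt) > 1)
      expect_true(all(tt$start[-1] >= tt$end[-nrow(tt)]))
  }
  expect_gt(mean(ds$tads$end - ds$tads$start), 5e5)
})

test_that("dosage frequencies track their planted allele frequencies", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 50e6), n_genes = 5,
                    n_markers = 1000, n_peaks = 5, n_samples = 176,
                    maf_range = c(0.2, 0.8))
  ds <- generate_genome(cfg, seed = 4)
  f <- ds$markers$maf
  mean_dos <- rowMeans(ds$dosage)
  sd3 <- 3 * sqrt(2 * f * (1 - f) / 176)
  expect_gte(mean(abs(mean_dos - 2 * f) <= sd3), 0.99)
})

test_that("noiseless planting reproduces the generative formula exactly", {
  ds <- generate_genome(small_cfg(), seed = 5)
  ds <- plant_models(ds, truth_spec(class_props = c(interacting = 1),
                                    noise_sd = 0), seed = 6)
  tr <- ds$truth
  for (i in sample(nrow(tr), 10)) {
    g <- ds$dosage[tr$variant_id[i], ]
    a <- ds$atac[tr$peak_id[i], ]
    y_expect <- tr$b0[i] + tr$b1[i] * g + tr$b2[i] * a + tr$b3[i] * g * a
    expect_equal(unname(ds$expression[tr$gene_id[i], ]), unname(y_expect),
                 tolerance = 1e-12)
  }
})

test_that("truth classes respect their coefficient zero patterns", {
  ds <- generate_genome(small_cfg(), seed = 7)
  ds <- plant_models(ds, truth_spec(), seed = 8)
  tr <- ds$truth
  expect_true(all(tr$b3[tr$true_class != "interacting"] == 0))
  expect_true(all(tr$b1[tr$true_class %in% c("null", "atac_only")] == 0))
  expect_true(all(tr$b2[tr$true_class %in% c("null", "genotype_only")] == 0))
  expect_true(all(tr$b1[tr$true_class == "additive"] != 0 &
                    tr$b2[tr$true_class == "additive"] != 0))
  expect_true(all(tr$b1[tr$true_class == "interacting"] != 0 &
                    tr$b2[tr$true_class == "interacting"] != 0 &
                    tr$b3[tr$true_class == "interacting"] != 0))
})

test_that("noiseless fits recover every planted coefficient set", {
  ds <- generate_genome(small_cfg(), seed = 9)
  ds <- plant_models(ds, truth_spec(noise_sd = 0), seed = 10)
  sc <- fit_truth_trios(ds)
  mo <- merge(sc$models, ds$truth, by = c("gene_id", "variant_id", "peak_id"))
  expect_equal(mo$beta0, mo$b0, tolerance = 1e-6)
  expect_equal(mo$beta1, mo$b1, tolerance = 1e-6)
  expect_equal(mo$beta2, mo$b2, tolerance = 1e-6)
  expect_equal(mo$beta3, mo$b3, tolerance = 1e-6)
})

test_that("forced intra-TAD placement marks every truth record", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 20e6), tad_mean_bp = 2e6,
                    gap_prob = 0, n_genes = 30, n_markers = 300,
                    n_peaks = 300, n_samples = 30)
  ds <- generate_genome(cfg, seed = 11)
  ds <- plant_models(ds, truth_spec(intra_tad_prob = 1), seed = 12)
  expect_true(all(ds$truth$causal_intra_tad))
})

test_that("impossible configurations raise explicit errors", {
  expect_error(generate_genome(sim_config(chrom_lengths = c(chr1 = 100),
                                          n_genes = 200, n_markers = 200,
                                          n_peaks = 200), seed = 1),
               "sizing error")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  ds <- generate_genome(small_cfg(), seed = 13)
  expect_error(plant_ctcf_world(ds, snp_rate = 1.5, seed = 1),
               "snp_rate")
})

test_that("dataset round-trips through its text writers", {
  ds <- generate_genome(small_cfg(), seed = 14)
  ds <- plant_models(ds, truth_spec(), seed = 15)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(all(file.exists(file.path(dir,
    c("genes.bed", "markers.bed", "peaks.bed", "tads.bed", "dosage.tsv",
      "atac.tsv", "expression.tsv", "truth.tsv", "config.json")))))
  dos <- read_matrix_tsv(file.path(dir, "dosage.tsv"))
  expect_equal(dos, ds$dosage)
  bed <- read_bed(file.path(dir, "tads.bed"))
  expect_equal(bed$start, ds$tads$start)
  expect_equal(bed$end, ds$tads$end)
})

test_that("the planted CTCF world mirrors the replicate design", {
  ds <- generate_genome(small_cfg(), seed = 16)
  w <- plant_ctcf_world(ds, n_sites = 50, seed = 17)
  # 4 strains x 3 replicates minus 2 dropped samples
  expect_equal(ncol(w$chip$fe), 10L)
  expect_equal(sort(unique(unname(w$chip$sample_strain))),
               sort(c("B6", "CAST", "PWK", "WSB")))
  expect_equal(sum(w$chip$sample_strain == "PWK"), 2L)
  expect_equal(sum(w$chip$sample_strain == "WSB"), 2L)
  # embedded consensus recoverable from the sequences
  pw <- ctcf_pwm()
  hits <- scan_pwm(w$sequences, pw, p_threshold = 1e-6)
  snp_free <- w$sites[!w$sites$has_snp, ]
  found <- paste(hits$chrom, hits$start)
  expect_true(all(paste(snp_free$chrom, snp_free$start) %in% found))
})

test_that("allele intensity multiplier separates strain group means", {
  ds <- generate_genome(small_cfg(), seed = 18)
  w <- plant_ctcf_world(ds, n_sites = 120, snp_rate = 1, seed = 19,
                        share_probs = c("4" = 1), effect_prob = 1,
                        effect_multiplier = 0.2, noise_sd = 0.05)
  ratios <- vapply(seq_len(nrow(w$sites)), function(i) {
    fe <- w$chip$fe[i, ]
    al <- w$allele_matrix[i, ]
    mean(fe[al == 0]) / mean(fe[al == 1])
  }, numeric(1))
  expect_equal(median(ratios), 5, tolerance = 0.15)
})
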