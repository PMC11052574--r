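test_that("TAD membership handles half-open boundaries and gaps", {
  tads <- data.frame(chrom = "chr1", start = c(0, 1200), end = c(1000, 2000),
                     tad_id = c("t1", "t2"))
  out <- assign_to_tads(data.frame(chrom = "chr1", pos = c(500, 1000, 1150,
                                                           1200, 1999)),
                        tads)
  expect_equal(out$tad_id, c("t1", NA, NA, "t2", "t2"))
  expect_equal(out$intra_tad, c(TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_error(assign_to_tads(data.frame(chrom = "chrX", pos = 1), tads),
               "chrX")
})

test_that("membership matches a brute-force linear scan", {
  set.seed(30)
  tads <- data.frame(chrom = "chr1",
                     start = sort(sample(seq(0, 9.5e6, by = 1e5), 50)))
  tads$end <- tads$start + 60000
  tads$tad_id <- paste0("t", seq_len(nrow(tads)))
  pos <- sample.int(1e7, 1e4) - 1
  out <- assign_to_tads(data.frame(chrom = "chr1", pos = pos), tads)
  brute <- vapply(pos, function(p) {
    hit <- which(p >= tads$start & p < tads$end)
    if (length(hit)) tads$tad_id[hit] else NA_character_
  }, character(1))
  expect_equal(out$tad_id, brute)
})

test_that("loop distance is the two-arc minimum, capped at L/2", {
  tad <- list(start = 0, end = 1000)
  expect_equal(loop_distance(100, 900, tad), 200)
  expect_equal(loop_distance(100, 600, tad), 500)
  expect_error(loop_distance(100, 1500, tad), "inside the TAD")
  set.seed(31)
  a <- sample.int(1000, 200) - 1
  b <- sample.int(1000, 200) - 1
  d <- loop_distance(a, b, tad)
  expect_equal(d, mapply(two_arc_oracle, a, b, 0, 1000))
  expect_true(all(d <= 500))
  # metric properties on the circle
  expect_equal(loop_distance(a, b, tad), loop_distance(b, a, tad))
  cpos <- sample.int(1000, 200) - 1
  expect_true(all(loop_distance(a, b, tad) <=
                    loop_distance(a, cpos, tad) +
                    loop_distance(cpos, b, tad) + 1e-9))
})

test_that("enrichment odds ratio and Fisher p match exact enumeration", {
  # construct a model table realising the contingency (30, 10, 10, 30)
  tads <- data.frame(chrom = "chr1", start = 0, end = 1e6, tad_id = "t1")
  genes <- data.frame(chrom = "chr1", start = 5e5, end = 5e5 + 100,
                      strand = "+", tss = 5e5, gene_id = "g1")
  n_pk <- 80
  # 40 intra-TAD (mid inside t1, > 200 kb from its boundaries),
  # 40 outside (all far from boundaries so no exclusion)
  mids <- c(seq(300000, 660000, length.out = 40),
            seq(1300000, 1900000, length.out = 40))
  peaks <- data.frame(chrom = "chr1", start = mids - 50, end = mids + 50,
                      peak_id = paste0("p", 1:n_pk), mid = mids)
  interacting <- c(rep(TRUE, 30), rep(FALSE, 10),   # intra: 30 yes, 10 no
                   rep(TRUE, 10), rep(FALSE, 30))   # extra: 10 yes, 30 no
  models <- data.frame(gene_id = "g1", peak_id = peaks$peak_id,
                       model_class = ifelse(interacting, "interacting",
                                            "additive"),
                       significant = TRUE)
  enr <- boundary_window_enrichment(models, genes, peaks, tads)
  expect_equal(unname(as.vector(enr$contingency)), c(30, 10, 10, 30))
  expect_equal(enr$odds_ratio, 9.0)
  expect_equal(enr$p_value, fisher_enum_oracle(enr$contingency),
               tolerance = 1e-9)
  expect_false(enr$haldane)
})

test_that("equal interacting rates inside and outside give OR near 1", {
  tads <- data.frame(chrom = "chr1", start = 0, end = 1e6, tad_id = "t1")
  genes <- data.frame(chrom = "chr1", start = 5e5, end = 5e5 + 100,
                      strand = "+", tss = 5e5, gene_id = "g1")
  mids <- c(seq(300000, 660000, length.out = 20),
            seq(1300000, 1900000, length.out = 20))
  peaks <- data.frame(chrom = "chr1", start = mids - 50, end = mids + 50,
                      peak_id = paste0("p", 1:40), mid = mids)
  models <- data.frame(gene_id = "g1", peak_id = peaks$peak_id,
                       model_class = rep(c("interacting", "additive"), 20),
                       significant = TRUE)
  enr <- boundary_window_enrichment(models, genes, peaks, tads)
  expect_equal(enr$odds_ratio, 1.0)
})

test_that("standardised loop coordinates behave at the anchors", {
  tads <- data.frame(chrom = "chr1", start = 0, end = 1000, tad_id = "t1")
  genes <- data.frame(chrom = "chr1", start = 200, end = 300, strand = "+",
                      tss = 200, gene_id = "g1")
  mk <- function(mid) data.frame(chrom = "chr1", start = mid, end = mid + 1,
                                 peak_id = "p1", mid = mid)
  base <- data.frame(gene_id = "g1", peak_id = "p1",
                     model_class = "interacting", significant = TRUE)
  at <- function(mid)
    standardize_tad_coords(base, genes, mk(mid), tads)$offset
  expect_equal(at(200), 0)
  expect_equal(at(700), 0.5)   # diametrically opposite on the loop
  expect_equal(at(100), -0.1)  # upstream in linear sequence
  expect_equal(at(900), 0.3)   # wraps the boundary: loop distance 300
})

test_that("capture window equals sort-based quantiles of planted offsets", {
  set.seed(32)
  n <- 200
  genes <- data.frame(chrom = "chr1", start = 5e6, end = 5e6 + 100,
                      strand = "+", tss = 5e6, gene_id = "g1")
  off_pk <- round(c(rnorm(n / 2, -3e5, 1e5), rnorm(n / 2, 4e5, 2e5)))
  off_mk <- round(rnorm(n, 0, 2e5))
  markers <- data.frame(chrom = "chr1", pos = 5e6 + off_mk,
                        variant_id = paste0("m", 1:n))
  peaks <- data.frame(chrom = "chr1", start = 5e6 + off_pk,
                      end = 5e6 + off_pk + 1,
                      peak_id = paste0("p", 1:n), mid = 5e6 + off_pk)
  models <- data.frame(gene_id = "g1", variant_id = markers$variant_id,
                       peak_id = peaks$peak_id,
                       model_class = "interacting", significant = TRUE)
  cw <- capture_window(models, genes, markers, peaks, q = 0.95)
  up <- pmax(0, -pmin(off_mk, off_pk))
  dn <- pmax(0, pmax(off_mk, off_pk))
  sort_q <- function(x, q) sort(x)[ceiling(q * length(x))]
  expect_equal(unname(cw["upstream_bp"]), sort_q(up, 0.95))
  expect_equal(unname(cw["downstream_bp"]), sort_q(dn, 0.95))
  cw1 <- capture_window(models, genes, markers, peaks, q = 1)
  expect_equal(unname(cw1["upstream_bp"]), max(up))
  expect_equal(unname(cw1["downstream_bp"]), max(dn))
  expect_error(capture_window(models[1:10, ], genes, markers, peaks),
               "fewer than 20")
})

test_that("search profiles conserve counts and zero out without hits", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 20e6), n_genes = 10,
                    n_markers = 20, n_peaks = 50, n_samples = 20)
  ds <- generate_genome(cfg, seed = 33)
  ds <- plant_models(ds, truth_spec(class_props = c(null = 1)), seed = 34)
  empty <- data.frame(gene_id = character(0), peak_id = character(0),
                      model_class = character(0), significant = logical(0))
  prof <- search_efficiency_profiles(ds, empty, max_radius = 2.5e6,
                                     bin_bp = 5e5)
  expect_true(all(prof$pct_interacting == 0))
  # conservation: TAD-mode bin counts sum to the (gene, intra-TAD peak)
  # pairs within the radius
  g_asg <- assign_to_tads(data.frame(chrom = ds$genes$chrom,
                                     pos = ds$genes$tss), ds$tads)
  p_asg <- assign_to_tads(data.frame(chrom = ds$peaks$chrom,
                                     pos = ds$peaks$mid), ds$tads)
  pairs <- 0
  for (i in seq_len(nrow(ds$genes))) {
    same <- !is.na(g_asg$tad_id[i]) & !is.na(p_asg$tad_id) &
      p_asg$tad_id == g_asg$tad_id[i]
    off <- (ds$peaks$mid - ds$genes$tss[i]) *
      (if (ds$genes$strand[i] == "+") 1 else -1)
    pairs <- pairs + sum(same & off >= -2.5e6 & off < 2.5e6 &
                           ds$peaks$chrom == ds$genes$chrom[i])
  }
  expect_equal(sum(prof$n_peaks[prof$mode == "tad"]), pairs)
  expect_error(search_efficiency_profiles(ds, empty, bin_bp = 0),
               "bin_bp")
})

test_that("gene-boundary proximity is strand-aware and vanishes at zero", {
  tads <- data.frame(chrom = "chr1", start = c(0, 120000),
                     end = c(100000, 200000), tad_id = c("t1", "t2"))
  genes <- data.frame(chrom = "chr1",
                      tss = c(130000, 130000, 60000),
                      strand = c("+", "-", "+"),
                      gene_id = c("gA", "gB", "gC"))
  # gA: boundary 120000 lies 10 kb upstream (+) -> flagged at 50 kb
  res <- gene_boundary_proximity(genes, tads, 50000)
  expect_equal(res$flags, c(TRUE, FALSE, FALSE))
  expect_equal(res$fraction, 1 / 3)
  expect_equal(gene_boundary_proximity(genes, tads, 0)$fraction, 0)
})
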