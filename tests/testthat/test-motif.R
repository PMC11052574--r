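test_that("PWM validation enforces probability rows", {
  m <- matrix(0.25, 6, 4)
  expect_s3_class(pwm(m), "pwm")
  bad <- m; bad[1, 1] <- 0.5
  expect_error(pwm(bad), "sum to 1")
  expect_error(pwm(m[, 1:3]), "4 columns")
  expect_error(pwm(m, background = c(0.5, 0.5, 0.2, 0.2)), "background")
})

test_that("PWM text format round-trips", {
  pw <- ctcf_pwm()
  path <- withr::local_tempfile(fileext = ".pwm")
  write_pwm(pw, path)
  back <- read_pwm(path)
  expect_equal(back$matrix, pw$matrix, tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_equal(back$name, pw$name)
})

test_that("the consensus sequence scores highest with minimal p", {
  pw <- ctcf_pwm()
  cons <- pwm_consensus(pw)
  h <- scan_pwm(cons, pw, p_threshold = 1)
  fwd <- h[h$strand == "+", ]
  expect_equal(nrow(fwd), 1L)
  expect_equal(fwd$score, sum(apply(pwm_score_matrix(pw), 1, max)))
  expect_equal(fwd$p_value, min(h$p_value))
})

test_that("hexamer p-values match exhaustive window enumeration", {
  set.seed(50)
  m <- matrix(runif(24, 0.05, 1), 6, 4)
  m <- m / rowSums(m)
  pw <- pwm(m, name = "hex")
  bases <- c("A", "C", "G", "T")
  all_hex <- do.call(expand.grid,
                     rep(list(bases), 6))[, 6:1, drop = FALSE]
  seqs <- apply(all_hex, 1, paste, collapse = "")
  # package scores/p-values, one window each (forward strand)
  got <- do.call(rbind, lapply(seqs, function(s) {
    h <- scan_pwm(s, pw, p_threshold = 1)
    h[h$strand == "+", c("score", "p_value")]
  }))
  # oracle: same discretisation grid, p by direct enumeration over all
  # 4096 windows under the uniform background
  lo <- pwm_score_matrix(pw)
  rmin <- apply(lo, 1, min)
  w <- (sum(apply(lo, 1, max)) - sum(rmin)) / 1000
  D <- round(sweep(lo, 1, rmin) / w)
  code <- lapply(strsplit(seqs, ""), match, bases)
  ti <- vapply(code, function(cc) sum(D[cbind(1:6, cc)]), numeric(1))
  p_oracle <- vapply(ti, function(t0) mean(ti >= t0), numeric(1))
  expect_equal(got$p_value, p_oracle, tolerance = 1e-9)
  # continuous scores match direct summation
  sc_oracle <- vapply(code, function(cc) sum(lo[cbind(1:6, cc)]), numeric(1))
  expect_equal(got$score, sc_oracle, tolerance = 1e-10)
})

test_that("a reverse-complemented motif is found on the minus strand", {
  pw <- ctcf_pwm()
  cons <- pwm_consensus(pw)
  set.seed(51)
  flank <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                    replace = TRUE), collapse = "")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(cons)))
  s <- paste0(flank(100), rc, flank(100))
  h <- scan_pwm(s, pw, p_threshold = 1e-6)
  hit <- h[h$start == 100, ]
  expect_equal(hit$strand, "-")
  expect_equal(hit$end, 100 + nchar(cons))
  expect_equal(hit$score, sum(apply(pwm_score_matrix(pw), 1, max)))
})

test_that("windows containing N are skipped", {
  pw <- ctcf_pwm()
  s <- paste0(pwm_consensus(pw), "N", pwm_consensus(pw))
  h <- scan_pwm(s, pw, p_threshold = 1)
  expect_false(any(h$start > 0 & h$start < 15))
  expect_true(all(c(0, 15) %in% h$start))
})

test_that("SNP offsets within motif hits are strand-aware", {
  hits <- data.frame(chrom = "s", start = 100, end = 110, strand = "+")
  res <- snp_motif_density(hits, data.frame(chrom = "s", pos = 103))
  expect_equal(which(res$position_counts == 1) - 1, 3)
  hits$strand <- "-"
  res2 <- snp_motif_density(hits, data.frame(chrom = "s", pos = 103))
  expect_equal(which(res2$position_counts == 1) - 1, 6)
  expect_equal(res2$fraction_hits_with_snp, 1)
})

test_that("uniformly planted SNPs give an approximately flat profile", {
  set.seed(52)
  n_hits <- 300
  starts <- seq(0, by = 50, length.out = n_hits)
  hits <- data.frame(chrom = "s", start = starts, end = starts + 10,
                     strand = sample(c("+", "-"), n_hits, replace = TRUE))
  snp_pos <- starts + sample(0:9, n_hits, replace = TRUE)
  res <- snp_motif_density(hits, data.frame(chrom = "s", pos = snp_pos))
  expect_equal(sum(res$position_counts), n_hits)
  expect_gt(chisq.test(res$position_counts)$p.value, 0.001)
})

test_that("peak annotation follows the midpoint rule over categories", {
  peaks <- data.frame(chrom = "chr1", start = c(100, 1000, 5000),
                      end = c(300, 1200, 5400),
                      peak_id = c("p1", "p2", "p3"))
  genes <- data.frame(chrom = "chr1", start = 150, end = 260)
  promoters <- data.frame(chrom = "chr1", start = c(190, 1050),
                          end = c(250, 1150))
  res <- annotate_peaks(peaks, list(gene_bodies = genes,
                                    promoters = promoters,
                                    enhancers = data.frame(
                                      chrom = character(0),
                                      start = numeric(0),
                                      end = numeric(0))))
  expect_equal(unname(res$percent["gene_bodies"]), 100 / 3)
  expect_equal(unname(res$percent["promoters"]), 200 / 3)
  expect_equal(unname(res$percent["enhancers"]), 0)
  expect_warning(annotate_peaks(peaks, list(genes = genes, exons = NULL)),
                 "exons")
  # percentages are invariant to interval order
  res2 <- annotate_peaks(peaks, list(promoters = promoters[2:1, ]))
  expect_equal(unname(res2$percent["promoters"]), 200 / 3)
})

test_that("planted annotation fractions are recovered exactly", {
  set.seed(53)
  n <- 100
  mids <- seq(1000, by = 1000, length.out = n)
  peaks <- data.frame(chrom = "chr1", start = mids - 100, end = mids + 100,
                      peak_id = paste0("p", 1:n))
  in_gene <- seq_len(60)
  genes <- data.frame(chrom = "chr1", start = mids[in_gene] - 10,
                      end = mids[in_gene] + 10)
  in_prom <- 41:60
  promoters <- data.frame(chrom = "chr1", start = mids[in_prom] - 10,
                          end = mids[in_prom] + 10)
  res <- annotate_peaks(peaks, list(gene_bodies = genes,
                                    promoters = promoters))
  expect_equal(unname(res$percent), c(60, 20))
})

test_that("negative effector peaks honour both thresholds", {
  mk <- function(peak, n, n_neg) {
    data.frame(gene_id = paste0("g", seq_len(n)), peak_id = peak,
               beta1 = 1, beta2 = c(rep(-0.5, n_neg), rep(0.5, n - n_neg)),
               beta3 = 0.5, retained = "x1,x2,x1x2",
               model_class = "interacting", significant = TRUE,
               stringsAsFactors = FALSE)
  }
  mo <- rbind(mk("pA", 12, 7),   # 12 models, 7 negative -> negative
              mk("pB", 9, 9),    # below min_models -> excluded
              mk("pC", 15, 3))   # majority positive -> positive
  eff <- negative_effector_peaks(mo)
  expect_equal(eff$negative, "pA")
  expect_equal(eff$positive, "pC")
  expect_false("pB" %in% eff$table$peak_id)
})
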