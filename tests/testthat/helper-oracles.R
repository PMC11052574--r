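# Independent oracles used across the suite. All deliberately use
# different computational routes than the package internals (explicit
# normal equations rather than QR, exhaustive enumeration rather than
# greedy search, closed forms rather than stats wrappers).

# OLS via explicit normal equations: betas, RSS
ne_ols <- function(y, X) {
  XtX <- t(X) %*% X
  b <- solve(XtX, t(X) %*% y)
  r <- y - X %*% b
  list(betas = as.numeric(b), rss = sum(r^2))
}

# Full trio fit oracle: betas, F statistic and p for the interaction term
ne_trio_oracle <- function(y, g, a) {
  X4 <- cbind(1, g, a, g * a)
  X3 <- X4[, 1:3]
  full <- ne_ols(y, X4)
  null <- ne_ols(y, X3)
  n <- length(y)
  f <- (null$rss - full$rss) / (full$rss / (n - 4))
  p <- 1 - pf(f, 1, n - 4)
  list(betas = full$betas, rss_full = full$rss, rss_null = null$rss,
       f = f, p = p)
}

# AIC of a hierarchical submodel, same convention as the package
# (n log(RSS/n) + 2k, RSS floored) but with RSS from the normal equations.
ne_submodel_aics <- function(y, g, a) {
  design <- list(
    "x1,x2,x1x2" = cbind(1, g, a, g * a),
    "x1,x2"      = cbind(1, g, a),
    "x1"         = cbind(1, g),
    "x2"         = cbind(1, a),
    "(none)"     = matrix(1, length(y), 1))
  n <- length(y)
  floor <- 1e-12 * max(1, sum(y * y))
  vapply(design, function(X)
    n * log(max(ne_ols(y, X)$rss, floor) / n) + 2 * ncol(X), numeric(1))
}

# Reachable-minimum backward path over the exhaustive AIC table:
# full -> additive -> {x1}/{x2} -> {}, taking each step only if it lowers
# AIC, with the package's tie-break (interaction first, else x2).
ne_backward_optimum <- function(y, g, a) {
  aics <- ne_submodel_aics(y, g, a)
  cur <- "x1,x2,x1x2"
  repeat {
    next_of <- switch(cur,
      "x1,x2,x1x2" = "x1,x2",
      "x1,x2"      = c("x1", "x2"),
      "x1"         = "(none)",
      "x2"         = "(none)",
      "(none)"     = NULL)
    if (is.null(next_of)) break
    cand <- aics[next_of]
    ord <- order(cand)
    pick <- next_of[ord[1]]
    if (length(cand) > 1 && abs(cand[ord[1]] - cand[ord[2]]) < 1e-12)
      pick <- "x1"  # dropping x2 preferred => remaining model is x1
    if (aics[pick] < aics[cur]) cur <- pick else break
  }
  switch(cur,
    "x1,x2,x1x2" = c("x1", "x2", "x1x2"),
    "x1,x2" = c("x1", "x2"),
    "x1" = "x1", "x2" = "x2", "(none)" = character(0))
}

# Welch two-sample t closed form
welch_oracle <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  v1 <- var(x1); v2 <- var(x2)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x1) - mean(x2)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Two-arc circular distance oracle
two_arc_oracle <- function(a, b, start, end) {
  L <- end - start
  d1 <- abs(a - b)
  d2 <- L - d1
  min(d1, d2)
}

# Fisher exact two-sided p by hypergeometric enumeration for a 2x2 table
fisher_enum_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c_ + d; k <- a + c_
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Small fully-specified dataset for scan enumeration tests
toy_dataset <- function() {
  genes <- data.frame(chrom = "chr1", start = c(1000, 5000),
                      end = c(3000, 8000), strand = c("+", "-"),
                      tss = c(1000, 7999),
                      gene_id = c("gene_1", "gene_2"),
                      stringsAsFactors = FALSE)
  markers <- data.frame(chrom = "chr1", start = c(500, 4000, 9000),
                        end = c(501, 4001, 9001),
                        variant_id = paste0("marker_", 1:3),
                        pos = c(500, 4000, 9000), monomorphic = FALSE,
                        stringsAsFactors = FALSE)
  peaks <- data.frame(chrom = "chr1", start = c(1500, 6000, 9500),
                      end = c(1900, 6400, 9900),
                      peak_id = paste0("peak_", 1:3),
                      mid = c(1700, 6200, 9700), stringsAsFactors = FALSE)
  set.seed(99)
  n <- 12
  samples <- sprintf("S%02d", 1:n)
  dosage <- matrix(rbinom(3 * n, 2, 0.5), 3, n,
                   dimnames = list(markers$variant_id, samples))
  dosage[1, 1:2] <- c(0, 1)  # ensure polymorphic
  atac <- matrix(rlnorm(3 * n, 1, 0.5), 3, n,
                 dimnames = list(peaks$peak_id, samples))
  expr <- matrix(rnorm(2 * n, 5, 1), 2, n,
                 dimnames = list(genes$gene_id, samples))
  tads <- data.frame(chrom = "chr1", start = c(0, 4500),
                     end = c(4000, 10000),
                     tad_id = c("tad_chr1_1", "tad_chr1_2"),
                     stringsAsFactors = FALSE)
  list(genome = data.frame(chrom = "chr1", length = 12000),
       tads = tads, genes = genes, markers = markers, peaks = peaks,
       dosage = dosage, atac = atac, expression = expr,
       samples = samples)
}

# A constructed ChIP fixture: 4 strains x 3 reps minus 2 dropped samples,
# detection patterns chosen per test.
chip_fixture <- function(fe, strains = c("B6", "CAST", "PWK", "WSB")) {
  samples <- colnames(fe)
  sample_strain <- setNames(sub("_r[0-9]+$", "", samples), samples)
  peaks <- data.frame(chrom = "seq1", start = seq_len(nrow(fe)) * 100,
                      end = seq_len(nrow(fe)) * 100 + 50,
                      peak_id = paste0("site_", seq_len(nrow(fe))),
                      stringsAsFactors = FALSE)
  chip_peak_matrix(peaks, fe, sample_strain)
}

ten_samples <- function() {
  c(paste0("B6_r", 1:3), paste0("CAST_r", 1:3), paste0("PWK_r", 1:2),
    paste0("WSB_r", 1:2))
}
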