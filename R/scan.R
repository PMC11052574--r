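#' Scan plan
#'
#' Describes which gene-variant-peak trios a scan visits. Random mode
#' samples distinct intrachromosomal trios uniformly (seeded); TAD mode
#' deterministically enumerates, for every gene, all variants and peaks
#' whose anchor lies in the gene's TAD or the nearest flanking TAD /
#' inter-TAD region on each side.
#'
#' @param mode \code{"random_intrachromosomal"} or \code{"tad_constrained"}.
#' @param n_models number of trios to sample (random mode).
#' @param seed RNG seed (required in random mode).
#' @return list of class \code{"gei_scan_plan"}.
#' @export
scan_plan <- function(mode = c("random_intrachromosomal", "tad_constrained"),
                      n_models = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "random_intrachromosomal") {
    if (is.null(seed)) stop("random mode requires a seed")
    if (is.null(n_models) || n_models < 1) stop("random mode requires n_models >= 1")
  }
  structure(list(mode = mode, n_models = n_models, seed = seed),
            class = "gei_scan_plan")
}

#' Run a genome-wide trio regression scan
#'
#' Fits the genotype-by-accessibility interaction model for every planned
#' trio, selects retained terms by backward AIC, classifies each model,
#' computes the interaction F-test, and Bonferroni-adjusts raw p-values
#' over the family of attempted fits. Trios with a monomorphic marker or a
#' zero-variance peak in the analysed samples are skipped and counted, not
#' fit; rank-deficient designs are emitted flagged with \code{f_stat = NA}.
#'
#' @param dataset a \code{gei_dataset} with expression planted, or any list
#'   with sample-aligned \code{expression}, \code{dosage}, \code{atac}
#'   matrices plus \code{genes}, \code{markers}, \code{peaks} (and
#'   \code{tads} for TAD mode) tables.
#' @param plan a [scan_plan()].
#' @param alpha adjusted-p significance cutoff (default 1e-7).
#' @return Object of class \code{"gei_scan"}: list with \code{models} (one
#'   row per fitted trio: ids, \code{beta0..beta3}, \code{retained},
#'   \code{rss_full}, \code{rss_null}, \code{f_stat}, \code{p_raw},
#'   \code{p_adj}, \code{model_class}, \code{significant}, \code{n}) and
#'   \code{manifest} (plan, seed, family size, skip counts, alpha).
#' @export
run_scan <- function(dataset, plan, alpha = 1e-7) {
  stopifnot(inherits(plan, "gei_scan_plan"))
  if (is.null(dataset$expression))
    stop("dataset has no expression matrix; run plant_models() first")
  sam <- colnames(dataset$expression)
  if (!identical(sam, colnames(dataset$dosage)) ||
      !identical(sam, colnames(dataset$atac)))
    stop("expression, dosage and atac matrices must share the same sample columns")

  trios <- if (plan$mode == "random_intrachromosomal")
    .enumerate_random_trios(dataset, plan$n_models, plan$seed)
  else
    .enumerate_tad_trios(dataset)

  n_trios <- nrow(trios)
  if (n_trios == 0L) stop("scan plan produced no trios")

  expr <- dataset$expression
  dos <- dataset$dosage
  atc <- dataset$atac

  beta <- matrix(NA_real_, n_trios, 4)
  rssf <- rssn <- fst <- pr <- rep(NA_real_, n_trios)
  retained <- character(n_trios)
  cls <- character(n_trios)
  ok <- rep(TRUE, n_trios)
  skip_mono <- skip_flat <- collinear_n <- 0L
  nsam <- length(sam)

  for (k in seq_len(n_trios)) {
    y <- expr[trios$gi[k], ]
    g <- dos[trios$mi[k], ]
    a <- atc[trios$pi[k], ]
    if (all(g == g[1])) { ok[k] <- FALSE; skip_mono <- skip_mono + 1L; next }
    if (all(a == a[1])) { ok[k] <- FALSE; skip_flat <- skip_flat + 1L; next }
    core <- .fit_trio_core(y, g, a)
    beta[k, ] <- core$betas
    rssf[k] <- core$rss_full; rssn[k] <- core$rss_null
    fst[k] <- core$f_stat; pr[k] <- core$p_raw
    if (core$collinear) {
      collinear_n <- collinear_n + 1L
      retained[k] <- NA_character_; cls[k] <- NA_character_
      next
    }
    ret <- .stepwise_core(y, g, a, rss_full = core$rss_full,
                          rss_add = core$rss_null)$retained
    retained[k] <- paste(ret, collapse = ",")
    cls[k] <- classify_model(ret)
  }

  keep <- ok
  m_family <- sum(keep & !is.na(pr))
  models <- data.frame(
    gene_id = dataset$genes$gene_id[trios$gi],
    variant_id = dataset$markers$variant_id[trios$mi],
    peak_id = dataset$peaks$peak_id[trios$pi],
    beta0 = beta[, 1], beta1 = beta[, 2], beta2 = beta[, 3], beta3 = beta[, 4],
    retained = retained, rss_full = rssf, rss_null = rssn,
    f_stat = fst, p_raw = pr, model_class = cls, n = nsam,
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(models) <- NULL
  models$p_adj <- NA_real_
  fitted_ok <- !is.na(models$p_raw)
  models$p_adj[fitted_ok] <- bonferroni_adjust(models$p_raw[fitted_ok], m_family)
  models$significant <- !is.na(models$p_adj) & models$p_adj < alpha

  structure(list(models = models,
                 manifest = list(mode = plan$mode, seed = plan$seed,
                                 n_requested = plan$n_models,
                                 family_size = m_family,
                                 alpha = alpha,
                                 skipped_monomorphic = skip_mono,
                                 skipped_zero_variance = skip_flat,
                                 collinear = collinear_n)),
            class = "gei_scan")
}

# Uniform sample of distinct same-chromosome (gene, marker, peak) trios.
.enumerate_random_trios <- function(dataset, n_models, seed) {
  set.seed(seed)
  chroms <- unique(dataset$genes$chrom)
  per <- lapply(chroms, function(ch) {
    list(gi = which(dataset$genes$chrom == ch),
         mi = which(dataset$markers$chrom == ch),
         pi = which(dataset$peaks$chrom == ch))
  })
  sizes <- vapply(per, function(p)
    as.numeric(length(p$gi)) * length(p$mi) * length(p$pi), numeric(1))
  total <- sum(sizes)
  if (total < 1) stop("no intrachromosomal trios available")
  n_take <- min(n_models, total)
  idx <- if (n_take == total) seq_len(total) else sample(total, n_take)
  cum <- c(0, cumsum(sizes))
  out <- vector("list", length(per))
  for (ci in seq_along(per)) {
    local_idx <- idx[idx > cum[ci] & idx <= cum[ci + 1]] - cum[ci] - 1
    if (length(local_idx) == 0L) next
    p <- per[[ci]]
    nm <- length(p$mi); np <- length(p$pi)
    gi <- local_idx %/% (nm * np)
    rem <- local_idx %% (nm * np)
    mi <- rem %/% np
    pk <- rem %% np
    out[[ci]] <- data.frame(gi = p$gi[gi + 1], mi = p$mi[mi + 1],
                            pi = p$pi[pk + 1])
  }
  do.call(rbind, out)
}

# For each gene: variants/peaks anchored in the gene's TAD/inter-TAD region
# or the region immediately up- or downstream of it.
.enumerate_tad_trios <- function(dataset) {
  if (is.null(dataset$tads)) stop("TAD mode requires dataset$tads")
  out <- vector("list", nrow(dataset$genes))
  for (ch in unique(dataset$genes$chrom)) {
    reg <- tad_regions(dataset$tads[dataset$tads$chrom == ch, , drop = FALSE],
                       chrom_length = dataset$genome$length[
                         dataset$genome$chrom == ch])
    gsel <- which(dataset$genes$chrom == ch)
    msel <- which(dataset$markers$chrom == ch)
    psel <- which(dataset$peaks$chrom == ch)
    g_reg <- findInterval(dataset$genes$tss[gsel], reg$start)
    m_reg <- findInterval(dataset$markers$pos[msel], reg$start)
    p_reg <- findInterval(dataset$peaks$mid[psel], reg$start)
    for (j in seq_along(gsel)) {
      r <- g_reg[j]
      span <- (r - 1):(r + 1)
      mi <- msel[m_reg %in% span]
      pk <- psel[p_reg %in% span]
      if (length(mi) == 0L || length(pk) == 0L) next  # gene logged by count
      out[[gsel[j]]] <- expand.grid(gi = gsel[j], mi = mi, pi = pk,
                                    KEEP.OUT.ATTRS = FALSE)
    }
  }
  do.call(rbind, out)
}

#' @export
print.gei_scan <- function(x, ...) {
  m <- x$manifest
  cat("Genotype-by-accessibility scan (", m$mode, ")\n", sep = "")
  cat("  fitted trios: ", nrow(x$models), " (family size ", m$family_size,
      "); skipped ", m$skipped_monomorphic, " monomorphic, ",
      m$skipped_zero_variance, " zero-variance; ", m$collinear,
      " collinear\n", sep = "")
  cat("  significant (adj. p < ", format(m$alpha), "): ",
      sum(x$models$significant), "\n", sep = "")
  tab <- table(x$models$model_class)
  if (length(tab)) {
    cat("  model classes:\n")
    print(tab)
  }
  invisible(x)
}

#' Summarise a scan: class counts and unique participants
#'
#' @param object a \code{gei_scan}.
#' @param ... unused.
#' @return list of class \code{"summary.gei_scan"} with per-class counts of
#'   models and of unique genes / variants / peaks, overall and among
#'   significant models.
#' @export
summary.gei_scan <- function(object, ...) {
  mo <- object$models
  by_class <- function(df) {
    cls <- unique(stats::na.omit(df$model_class))
    do.call(rbind, lapply(cls, function(cc) {
      sub <- df[!is.na(df$model_class) & df$model_class == cc, ]
      data.frame(model_class = cc, n_models = nrow(sub),
                 n_genes = length(unique(sub$gene_id)),
                 n_variants = length(unique(sub$variant_id)),
                 n_peaks = length(unique(sub$peak_id)),
                 stringsAsFactors = FALSE)
    }))
  }
  out <- list(all = by_class(mo),
              significant = by_class(mo[mo$significant, , drop = FALSE]),
              n_models = nrow(mo),
              n_significant = sum(mo$significant),
              pct_significant = 100 * mean(mo$significant),
              manifest = object$manifest)
  class(out) <- "summary.gei_scan"
  out
}

#' @export
print.summary.gei_scan <- function(x, ...) {
  cat("Scan summary: ", x$n_models, " models, ", x$n_significant,
      " significant (", format(x$pct_significant, digits = 3), "%)\n",
      sep = "")
  cat("\nAll models by class:\n"); print(x$all, row.names = FALSE)
  if (!is.null(x$significant) && nrow(x$significant)) {
    cat("\nSignificant models by class:\n")
    print(x$significant, row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.gei_scan <- function(x, ...) {
  p <- x$models$p_adj[!is.na(x$models$p_adj)]
  graphics::hist(p, breaks = 50, main = "Adjusted p-values",
                 xlab = "Bonferroni-adjusted p", ...)
  invisible(x)
}

#' Significant models of a scan
#'
#' @param scan a \code{gei_scan}.
#' @param class optional model class filter (e.g. \code{"interacting"}).
#' @return data frame of significant model rows.
#' @export
significant_models <- function(scan, class = NULL) {
  mo <- scan$models[scan$models$significant, , drop = FALSE]
  if (!is.null(class))
    mo <- mo[!is.na(mo$model_class) & mo$model_class %in% class, , drop = FALSE]
  mo
}

#' Fit the planted causal trio of every gene
#'
#' Convenience driver for synthetic datasets: fits the gene's true
#' (planted) variant and peak from the truth ledger, selects and
#' classifies terms, and Bonferroni-adjusts over the attempted fits. This
#' is the power/recovery counterpart of [run_scan()], which searches over
#' candidate trios.
#'
#' @param dataset a \code{gei_dataset} with \code{truth} filled by
#'   [plant_models()].
#' @param alpha adjusted-p significance cutoff (default 1e-7).
#' @param m family size for the Bonferroni adjustment; defaults to the
#'   number of attempted fits.
#' @return a \code{gei_scan} object (one model per fittable gene).
#' @export
fit_truth_trios <- function(dataset, alpha = 1e-7, m = NULL) {
  if (is.null(dataset$truth)) stop("dataset has no truth ledger")
  tr <- dataset$truth
  rows <- vector("list", nrow(tr))
  skip_mono <- skip_flat <- 0L
  for (i in seq_len(nrow(tr))) {
    y <- dataset$expression[tr$gene_id[i], ]
    g <- dataset$dosage[tr$variant_id[i], ]
    a <- dataset$atac[tr$peak_id[i], ]
    if (all(g == g[1])) { skip_mono <- skip_mono + 1L; next }
    if (all(a == a[1])) { skip_flat <- skip_flat + 1L; next }
    core <- .fit_trio_core(y, g, a)
    ret <- if (core$collinear) NA_character_ else
      paste(.stepwise_core(y, g, a, rss_full = core$rss_full,
                           rss_add = core$rss_null)$retained,
            collapse = ",")
    rows[[i]] <- data.frame(
      gene_id = tr$gene_id[i], variant_id = tr$variant_id[i],
      peak_id = tr$peak_id[i],
      beta0 = core$betas[1], beta1 = core$betas[2],
      beta2 = core$betas[3], beta3 = core$betas[4],
      se0 = core$se[1], se1 = core$se[2], se2 = core$se[3],
      se3 = core$se[4],
      retained = ret, rss_full = core$rss_full, rss_null = core$rss_null,
      f_stat = core$f_stat, p_raw = core$p_raw,
      model_class = if (is.na(ret)) NA_character_ else
        classify_model(strsplit(ret, ",", fixed = TRUE)[[1]]),
      n = core$n, stringsAsFactors = FALSE, row.names = NULL)
  }
  models <- do.call(rbind, rows)
  fam <- if (is.null(m)) sum(!is.na(models$p_raw)) else m
  models$p_adj <- NA_real_
  okp <- !is.na(models$p_raw)
  models$p_adj[okp] <- bonferroni_adjust(models$p_raw[okp], fam)
  models$significant <- !is.na(models$p_adj) & models$p_adj < alpha
  structure(list(models = models,
                 manifest = list(mode = "truth_trios", seed = dataset$seed,
                                 n_requested = nrow(tr), family_size = fam,
                                 alpha = alpha,
                                 skipped_monomorphic = skip_mono,
                                 skipped_zero_variance = skip_flat,
                                 collinear = sum(is.na(models$retained)))),
            class = "gei_scan")
}
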