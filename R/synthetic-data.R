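#' Simulation configuration
#'
#' Collects the knobs of the synthetic genome generator. Defaults emulate
#' the study design the analysis assumes: 176 samples, TADs averaging
#' ~1.1 Mb, dosage genotypes with balanced allele frequencies, TMM-like
#' non-negative peak intensities, and residual noise of 0.5 log2 TPM.
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param tad_mean_bp mean TAD length; lengths are log-normal around this.
#' @param tad_sdlog log-scale SD of TAD lengths.
#' @param gap_prob probability of an inter-TAD gap after each TAD.
#' @param gap_mean_bp mean inter-TAD gap length (exponential).
#' @param n_genes,n_markers,n_peaks feature counts.
#' @param n_samples number of samples (columns of all matrices).
#' @param maf_range range of per-marker allele frequencies; dosages are
#'   binomial(2, f).
#' @param atac_meanlog,atac_sdlog log-normal parameters of peak intensity.
#' @param peak_width_meanlog,peak_width_sdlog log-normal peak widths.
#' @param gene_width_meanlog,gene_width_sdlog log-normal gene body widths.
#' @param noise_sd residual SD of expression (log2 TPM).
#' @return A list of class \code{"gei_config"}.
#' @export
sim_config <- function(chrom_lengths = c(chr1 = 60e6, chr2 = 60e6),
                       tad_mean_bp = 1.1e6, tad_sdlog = 0.35,
                       gap_prob = 0.3, gap_mean_bp = 8e4,
                       n_genes = 200, n_markers = 200, n_peaks = 300,
                       n_samples = 176, maf_range = c(0.2, 0.8),
                       atac_meanlog = 1, atac_sdlog = 0.5,
                       peak_width_meanlog = log(400), peak_width_sdlog = 0.4,
                       gene_width_meanlog = log(2e4), gene_width_sdlog = 0.6,
                       noise_sd = 0.5) {
  if (is.null(names(chrom_lengths)) || anyDuplicated(names(chrom_lengths)))
    stop("chrom_lengths must have unique names")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  if (maf_range[1] <= 0 || maf_range[2] >= 1 || maf_range[1] > maf_range[2])
    stop("maf_range must lie strictly inside (0, 1)")
  structure(as.list(environment()), class = "gei_config")
}

#' Generate a synthetic genome with TADs, genes, markers and peaks
#'
#' Tiles each chromosome with non-overlapping TADs (log-normal lengths,
#' optional exponential inter-TAD gaps), places genes, markers and peaks at
#' recorded 0-based half-open coordinates, draws dosage genotypes per
#' marker from binomial(2, f) with f uniform in \code{maf_range}, and peak
#' intensities from a per-peak log-normal. Expression is left unset until
#' [plant_models()] fills it from a planted-truth specification.
#'
#' The same (config, seed) pair always yields an identical dataset.
#'
#' @param config a [sim_config()] list.
#' @param seed integer RNG seed (mandatory; sets the session RNG).
#' @return An object of class \code{"gei_dataset"}: a list with elements
#'   \code{genome}, \code{tads}, \code{genes}, \code{markers}, \code{peaks}
#'   (data frames, 0-based half-open coordinates), \code{dosage},
#'   \code{atac} (feature x sample matrices), \code{expression}
#'   (\code{NULL} until planted), \code{truth} (\code{NULL}),
#'   \code{samples}, \code{config}, \code{seed}.
#' @export
generate_genome <- function(config = sim_config(), seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  cl <- config$chrom_lengths
  total_bp <- sum(cl)
  n_feat <- config$n_genes + config$n_markers + config$n_peaks
  if (total_bp < n_feat)
    stop("sizing error: ", n_feat, " features cannot fit in a ",
         total_bp, " bp genome")

  # --- TADs: tile each chromosome ---
  tad_list <- lapply(names(cl), function(ch) {
    L <- cl[[ch]]
    starts <- ends <- numeric(0)
    pos <- 0
    mu <- log(config$tad_mean_bp) - config$tad_sdlog^2 / 2
    while (pos < L) {
      len <- round(stats::rlnorm(1, mu, config$tad_sdlog))
      if (pos + len > L) {
        if (L - pos >= config$tad_mean_bp / 5) len <- L - pos else break
      }
      starts <- c(starts, pos); ends <- c(ends, pos + len)
      pos <- pos + len
      if (stats::runif(1) < config$gap_prob && pos < L)
        pos <- pos + min(round(stats::rexp(1, 1 / config$gap_mean_bp)), L - pos)
    }
    data.frame(chrom = ch, start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  tads <- do.call(rbind, tad_list)
  tads$tad_id <- sprintf("tad_%s_%d", tads$chrom,
                         stats::ave(seq_len(nrow(tads)), tads$chrom,
                                    FUN = seq_along))

  place <- function(n, width = NULL) {
    ch <- sample(names(cl), n, replace = TRUE, prob = cl / total_bp)
    w <- if (is.null(width)) rep(1L, n) else pmax(1L, round(width))
    start <- floor(stats::runif(n) * pmax(1, cl[ch] - w))
    data.frame(chrom = ch, start = start, end = start + w,
               stringsAsFactors = FALSE, row.names = NULL)
  }

  genes <- place(config$n_genes,
                 stats::rlnorm(config$n_genes, config$gene_width_meanlog,
                               config$gene_width_sdlog))
  genes$strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes$gene_id <- sprintf("gene_%d", seq_len(config$n_genes))

  markers <- place(config$n_markers)
  markers$variant_id <- sprintf("marker_%d", seq_len(config$n_markers))
  markers$pos <- markers$start
  markers$maf <- stats::runif(config$n_markers, config$maf_range[1],
                              config$maf_range[2])

  peaks <- place(config$n_peaks,
                 stats::rlnorm(config$n_peaks, config$peak_width_meanlog,
                               config$peak_width_sdlog))
  peaks$peak_id <- sprintf("peak_%d", seq_len(config$n_peaks))
  peaks$mid <- floor((peaks$start + peaks$end) / 2)

  samples <- sprintf("S%03d", seq_len(config$n_samples))

  dosage <- t(vapply(markers$maf,
                     function(f) stats::rbinom(config$n_samples, 2, f),
                     integer(config$n_samples)))
  dimnames(dosage) <- list(markers$variant_id, samples)
  monomorphic <- apply(dosage, 1, function(r) length(unique(r)) < 2)
  markers$monomorphic <- unname(monomorphic)

  peak_mu <- stats::rnorm(config$n_peaks, config$atac_meanlog, 0.3)
  atac <- t(vapply(peak_mu,
                   function(m) stats::rlnorm(config$n_samples, m, config$atac_sdlog),
                   numeric(config$n_samples)))
  dimnames(atac) <- list(peaks$peak_id, samples)

  structure(list(genome = data.frame(chrom = names(cl),
                                     length = as.numeric(cl),
                                     stringsAsFactors = FALSE),
                 tads = tads, genes = genes, markers = markers, peaks = peaks,
                 dosage = dosage, atac = atac, expression = NULL,
                 truth = NULL, samples = samples, config = config,
                 seed = seed),
            class = "gei_dataset")
}

#' @export
print.gei_dataset <- function(x, ...) {
  cat("Synthetic genetic-epigenetic dataset (seed ", x$seed, ")\n", sep = "")
  cat("  genome: ", nrow(x$genome), " chromosome(s), ",
      format(sum(x$genome$length), big.mark = ","), " bp, ",
      nrow(x$tads), " TADs\n", sep = "")
  cat("  features: ", nrow(x$genes), " genes, ", nrow(x$markers),
      " markers, ", nrow(x$peaks), " peaks; ", length(x$samples),
      " samples\n", sep = "")
  cat("  expression: ",
      if (is.null(x$expression)) "not planted" else
        paste0(nrow(x$expression), " genes planted (",
               paste(names(table(x$truth$true_class)), collapse = "/"), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Planted-truth specification
#'
#' @param class_props named proportions over model classes
#'   \code{null}, \code{genotype_only}, \code{atac_only}, \code{additive},
#'   \code{interacting}; normalised to sum to 1.
#' @param b0_range intercept range (log2 TPM).
#' @param b1_range,b2_range,b3_range magnitude ranges of the genotype,
#'   accessibility and interaction effects; signs are drawn independently
#'   with \code{prob_negative}.
#' @param prob_negative probability each drawn effect is negative.
#' @param intra_tad_prob probability the causal marker and peak are chosen
#'   inside the gene's TAD.
#' @param noise_sd residual SD; \code{NULL} uses the dataset config value.
#' @return list of class \code{"gei_truth_spec"}.
#' @export
truth_spec <- function(class_props = c(null = 0.2, genotype_only = 0.2,
                                       atac_only = 0.2, additive = 0.2,
                                       interacting = 0.2),
                       b0_range = c(2, 8),
                       b1_range = c(0.3, 1.5),
                       b2_range = c(0.1, 0.8),
                       b3_range = c(0.2, 1.0),
                       prob_negative = 0.5,
                       intra_tad_prob = 0.9,
                       noise_sd = NULL) {
  valid <- c("null", "genotype_only", "atac_only", "additive", "interacting")
  if (!all(names(class_props) %in% valid))
    stop("unknown model class in class_props")
  if (any(class_props < 0) || sum(class_props) <= 0)
    stop("class_props must be non-negative and sum to a positive value")
  class_props <- class_props / sum(class_props)
  structure(list(class_props = class_props, b0_range = b0_range,
                 b1_range = b1_range, b2_range = b2_range,
                 b3_range = b3_range, prob_negative = prob_negative,
                 intra_tad_prob = intra_tad_prob, noise_sd = noise_sd),
            class = "gei_truth_spec")
}

#' Plant generative models and fill the expression matrix
#'
#' For each gene draws a true model class, a causal marker and peak
#' (intra-TAD with the configured probability), and coefficients with the
#' class's zero pattern, then generates expression as
#' \eqn{y = \beta_0 + \beta_1 g + \beta_2 a + \beta_3 g a + \varepsilon}
#' with \eqn{\varepsilon \sim N(0, \sigma)} per sample.
#'
#' @param dataset a [generate_genome()] result.
#' @param spec a [truth_spec()].
#' @param seed integer RNG seed.
#' @return The dataset with \code{expression} filled and \code{truth} set to
#'   the planted-truth ledger (one row per gene: ids, class, true betas,
#'   \code{causal_intra_tad}).
#' @export
plant_models <- function(dataset, spec = truth_spec(), seed) {
  stopifnot(inherits(dataset, "gei_dataset"))
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  sigma <- if (is.null(spec$noise_sd)) dataset$config$noise_sd else spec$noise_sd

  genes <- dataset$genes
  markers <- dataset$markers
  peaks <- dataset$peaks
  tads <- dataset$tads
  ns <- length(dataset$samples)
  ng <- nrow(genes)

  gene_tad <- .locate_in_tads(genes$chrom, genes$tss, tads)

  cls_names <- names(spec$class_props)
  classes <- sample(cls_names, ng, replace = TRUE, prob = spec$class_props)

  draw_mag <- function(rg) stats::runif(1, rg[1], rg[2]) *
    ifelse(stats::runif(1) < spec$prob_negative, -1, 1)

  expr <- matrix(NA_real_, ng, ns, dimnames = list(genes$gene_id,
                                                   dataset$samples))
  truth <- vector("list", ng)
  for (i in seq_len(ng)) {
    ch <- genes$chrom[i]
    tid <- gene_tad[i]
    want_intra <- stats::runif(1) < spec$intra_tad_prob
    mk_intra <- if (!is.na(tid)) which(markers$chrom == ch &
      .in_tad(markers$pos, tads, tid)) else integer(0)
    pk_intra <- if (!is.na(tid)) which(peaks$chrom == ch &
      .in_tad(peaks$mid, tads, tid)) else integer(0)
    mk_all <- which(markers$chrom == ch & !markers$monomorphic)
    pk_all <- which(peaks$chrom == ch)
    mk_intra <- intersect(mk_intra, mk_all)
    if (length(mk_all) == 0L || length(pk_all) == 0L)
      stop("gene ", genes$gene_id[i], " has no markers or peaks on its chromosome")
    intra_ok <- length(mk_intra) > 0L && length(pk_intra) > 0L
    if (want_intra && !intra_ok) {
      if (spec$intra_tad_prob >= 1)
        stop("intra-TAD placement forced but gene ", genes$gene_id[i],
             " has no intra-TAD marker/peak")
      want_intra <- FALSE
    }
    mi <- if (want_intra) mk_intra[sample.int(length(mk_intra), 1)] else
      mk_all[sample.int(length(mk_all), 1)]
    pi <- if (want_intra) pk_intra[sample.int(length(pk_intra), 1)] else
      pk_all[sample.int(length(pk_all), 1)]

    cls <- classes[i]
    b0 <- stats::runif(1, spec$b0_range[1], spec$b0_range[2])
    b1 <- if (cls %in% c("genotype_only", "additive", "interacting"))
      draw_mag(spec$b1_range) else 0
    b2 <- if (cls %in% c("atac_only", "additive", "interacting"))
      draw_mag(spec$b2_range) else 0
    b3 <- if (cls == "interacting") draw_mag(spec$b3_range) else 0

    gvec <- dataset$dosage[mi, ]
    avec <- dataset$atac[pi, ]
    expr[i, ] <- b0 + b1 * gvec + b2 * avec + b3 * gvec * avec +
      stats::rnorm(ns, 0, sigma)
    truth[[i]] <- data.frame(gene_id = genes$gene_id[i],
                             variant_id = markers$variant_id[mi],
                             peak_id = peaks$peak_id[pi],
                             true_class = cls,
                             b0 = b0, b1 = b1, b2 = b2, b3 = b3,
                             causal_intra_tad = want_intra,
                             stringsAsFactors = FALSE)
  }
  dataset$expression <- expr
  dataset$truth <- do.call(rbind, truth)
  dataset
}

# tad id containing each position (NA if in a gap); positions 0-based.
.locate_in_tads <- function(chrom, pos, tads) {
  out <- rep(NA_character_, length(pos))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    tt <- tads[tads$chrom == ch, , drop = FALSE]
    if (nrow(tt) == 0L) next
    for (j in seq_len(nrow(tt))) {
      hit <- idx[pos[idx] >= tt$start[j] & pos[idx] < tt$end[j]]
      out[hit] <- tt$tad_id[j]
    }
  }
  out
}

.in_tad <- function(pos, tads, tad_id) {
  row <- tads[tads$tad_id == tad_id, ]
  pos >= row$start & pos < row$end
}
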