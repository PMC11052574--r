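#' ChIP peak matrix constructor
#'
#' Fold-enrichment values of peak intervals across replicate samples, with
#' a sample-to-strain mapping.
#'
#' @param peaks data frame \code{chrom}, \code{start}, \code{end},
#'   \code{peak_id}.
#' @param fold_enrichment numeric matrix, peaks x samples, non-negative.
#' @param sample_strain named character vector mapping each sample
#'   (column) to exactly one strain.
#' @param detection_floor a peak counts as detected in a sample when its
#'   fold enrichment exceeds this (default 1).
#' @return object of class \code{"chip_peak_matrix"}.
#' @export
chip_peak_matrix <- function(peaks, fold_enrichment, sample_strain,
                             detection_floor = 1) {
  fold_enrichment <- as.matrix(fold_enrichment)
  if (nrow(fold_enrichment) != nrow(peaks))
    stop("fold_enrichment must have one row per peak")
  if (any(fold_enrichment < 0)) stop("fold enrichment must be non-negative")
  sam <- colnames(fold_enrichment)
  if (is.null(sam)) stop("fold_enrichment needs sample column names")
  if (!all(sam %in% names(sample_strain)))
    stop("every sample must map to exactly one strain")
  structure(list(peaks = peaks, fe = fold_enrichment,
                 sample_strain = sample_strain[sam],
                 detection_floor = detection_floor,
                 consensus = NULL, n_strains_found = NULL),
            class = "chip_peak_matrix")
}

#' @export
print.chip_peak_matrix <- function(x, ...) {
  cat("ChIP peak matrix: ", nrow(x$fe), " peaks x ", ncol(x$fe),
      " samples (", length(unique(x$sample_strain)), " strains)\n", sep = "")
  if (!is.null(x$consensus))
    cat("  consensus peaks: ", sum(x$consensus), " (",
        format(100 * mean(x$consensus), digits = 4), "%)\n", sep = "")
  invisible(x)
}

#' Call consensus peaks across replicate strains
#'
#' A peak passes consensus when it is detected (fold enrichment above the
#' detection floor) in at least \code{min_samples} samples of at least one
#' strain. Also reports, per peak, the number of strains in which it meets
#' the same within-strain rule, giving the strain-sharing distribution.
#' Strains with fewer than \code{min_samples} samples cannot by themselves
#' confer consensus; they are listed in the result.
#'
#' @param chip a [chip_peak_matrix()].
#' @param min_samples within-strain detection count required (default 2).
#' @return The matrix with \code{consensus} and \code{n_strains_found}
#'   filled, plus attributes \code{sharing_counts} (peaks found in 0..K
#'   strains) and \code{underpowered_strains}.
#' @export
consensus_peaks <- function(chip, min_samples = 2) {
  stopifnot(inherits(chip, "chip_peak_matrix"))
  strains <- unique(chip$sample_strain)
  det <- chip$fe > chip$detection_floor
  per_strain <- vapply(strains, function(st) {
    rowSums(det[, chip$sample_strain == st, drop = FALSE])
  }, numeric(nrow(chip$fe)))
  strain_n <- vapply(strains, function(st) sum(chip$sample_strain == st),
                     numeric(1))
  underpowered <- strains[strain_n < min_samples]
  found <- per_strain >= min_samples
  chip$n_strains_found <- rowSums(found)
  chip$consensus <- chip$n_strains_found >= 1
  attr(chip, "sharing_counts") <-
    table(factor(chip$n_strains_found, levels = 0:length(strains)))
  attr(chip, "underpowered_strains") <- underpowered
  chip
}

#' Per-peak variance of binding fold enrichment
#'
#' Sample variance (n - 1 denominator) across all samples per peak, its
#' log10, and the fraction of peaks exceeding a variance threshold.
#'
#' @param chip a [chip_peak_matrix()] with at least 3 samples.
#' @param threshold variance threshold for the summary fraction (default
#'   10).
#' @return list: \code{per_peak} (data frame \code{peak_id},
#'   \code{variance}, \code{log10_variance}), \code{fraction_gt_threshold}.
#' @export
fold_variance <- function(chip, threshold = 10) {
  stopifnot(inherits(chip, "chip_peak_matrix"))
  if (ncol(chip$fe) < 3) stop("at least 3 samples required")
  v <- apply(chip$fe, 1, stats::var)
  list(per_peak = data.frame(peak_id = chip$peaks$peak_id,
                             variance = v, log10_variance = log10(v),
                             stringsAsFactors = FALSE),
       fraction_gt_threshold = mean(v > threshold))
}

#' Associate SNP genotype with binding intensity at one peak
#'
#' Two-sample t-test of per-sample fold enrichment grouped by allele.
#' Welch's unequal-variance test is the default (\code{var_equal = TRUE}
#' switches to pooled-variance Student). Groups with fewer than 2 samples
#' on either allele make the result untestable, flagged.
#'
#' @param intensity numeric vector of fold enrichment per sample.
#' @param alleles per-sample allele labels (2 distinct values expected).
#' @param var_equal pooled-variance Student instead of Welch.
#' @return list: \code{t}, \code{p}, \code{df}, \code{n1}, \code{n2},
#'   \code{testable}.
#' @export
genotype_binding_association <- function(intensity, alleles,
                                         var_equal = FALSE) {
  alleles <- as.factor(alleles)
  lv <- levels(droplevels(alleles))
  if (length(lv) != 2)
    return(list(t = NA_real_, p = NA_real_, df = NA_real_,
                n1 = sum(alleles == lv[1]),
                n2 = if (length(lv) > 1) sum(alleles == lv[2]) else 0L,
                testable = FALSE))
  g1 <- intensity[alleles == lv[1]]
  g2 <- intensity[alleles == lv[2]]
  if (length(g1) < 2 || length(g2) < 2 ||
      (stats::var(g1) == 0 && stats::var(g2) == 0))
    return(list(t = NA_real_, p = NA_real_, df = NA_real_,
                n1 = length(g1), n2 = length(g2), testable = FALSE))
  tt <- stats::t.test(g1, g2, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), n1 = length(g1), n2 = length(g2),
       testable = TRUE)
}

#' Genotype-binding association across all peaks
#'
#' @param chip a [chip_peak_matrix()].
#' @param allele_matrix peaks x samples matrix of allele labels (e.g. 0/1
#'   alt-allele carriage per strain).
#' @param var_equal see [genotype_binding_association()].
#' @return data frame, one row per peak: \code{peak_id}, \code{t},
#'   \code{p}, \code{n1}, \code{n2}, \code{testable}.
#' @export
associate_binding <- function(chip, allele_matrix, var_equal = FALSE) {
  stopifnot(inherits(chip, "chip_peak_matrix"))
  stopifnot(nrow(allele_matrix) == nrow(chip$fe),
            ncol(allele_matrix) == ncol(chip$fe))
  out <- lapply(seq_len(nrow(chip$fe)), function(i) {
    r <- genotype_binding_association(chip$fe[i, ], allele_matrix[i, ],
                                      var_equal)
    data.frame(peak_id = chip$peaks$peak_id[i], t = r$t, p = r$p,
               n1 = r$n1, n2 = r$n2, testable = r$testable,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Significance rates across peak subsets
#'
#' Proportion of testable associations with \code{p < alpha} in each named
#' peak subset. Empty subsets report \code{n = 0} and an undefined rate.
#'
#' @param associations result of [associate_binding()].
#' @param subsets named list of peak-id vectors (must be subsets of the
#'   tested peaks).
#' @param alpha significance level (default 0.05).
#' @return data frame \code{subset}, \code{n}, \code{n_sig}, \code{rate}.
#' @export
subset_significance_rates <- function(associations, subsets, alpha = 0.05) {
  out <- lapply(names(subsets), function(nm) {
    ids <- subsets[[nm]]
    extra <- setdiff(ids, associations$peak_id)
    if (length(extra))
      stop("subset '", nm, "' contains untested peaks")
    sub <- associations[associations$peak_id %in% ids &
                          associations$testable, , drop = FALSE]
    data.frame(subset = nm, n = nrow(sub), n_sig = sum(sub$p < alpha),
               rate = if (nrow(sub)) mean(sub$p < alpha) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Standard model-defined ChIP peak subsets
#'
#' Builds the named subsets compared in the binding-association analysis:
#' all tested peaks, peaks under ATAC peaks, peaks in additive models,
#' peaks in interacting models, negative and positive effectors, and
#' peaks in densely modelled TADs (TADs holding more significant models
#' than the genome-wide mean).
#'
#' @param associations result of [associate_binding()].
#' @param peak_map named character vector mapping ChIP peak ids to ATAC
#'   peak ids (\code{NA} = no overlapping ATAC peak); names are ChIP peak
#'   ids.
#' @param models scan model table (or \code{gei_scan}); optional.
#' @param effectors result of [negative_effector_peaks()]; optional.
#' @param chip_tads optional character vector (same length/order as
#'   tested peaks) giving each ChIP peak's TAD id, for the dense-region
#'   subset.
#' @param genes,tads with \code{models}, used to count significant models
#'   per TAD when \code{chip_tads} is given.
#' @return named list of ChIP peak-id vectors.
#' @export
standard_chip_subsets <- function(associations, peak_map, models = NULL,
                                  effectors = NULL, chip_tads = NULL,
                                  genes = NULL, tads = NULL) {
  ids <- associations$peak_id
  subsets <- list(all = ids)
  mapped <- peak_map[ids]
  subsets$under_atac <- ids[!is.na(mapped)]
  if (!is.null(models)) {
    mo <- .as_model_table(models)
    sig <- mo[mo$significant, , drop = FALSE]
    add_pk <- unique(sig$peak_id[sig$model_class == "additive"])
    int_pk <- unique(sig$peak_id[sig$model_class == "interacting"])
    subsets$additive <- ids[!is.na(mapped) & mapped %in% add_pk]
    subsets$interacting <- ids[!is.na(mapped) & mapped %in% int_pk]
  }
  if (!is.null(effectors)) {
    subsets$negative <- ids[!is.na(mapped) & mapped %in% effectors$negative]
    subsets$positive <- ids[!is.na(mapped) & mapped %in% effectors$positive]
  }
  if (!is.null(chip_tads) && !is.null(models) && !is.null(genes) &&
      !is.null(tads)) {
    mo <- .as_model_table(models)
    sig <- mo[mo$significant, , drop = FALSE]
    g_asg <- assign_to_tads(data.frame(chrom = genes$chrom, pos = genes$tss),
                            tads)
    tad_of_gene <- stats::setNames(g_asg$tad_id, genes$gene_id)
    per_tad <- table(stats::na.omit(tad_of_gene[sig$gene_id]))
    dense <- names(per_tad)[per_tad > mean(per_tad)]
    subsets$dense_region <- ids[!is.na(chip_tads) & chip_tads %in% dense]
  }
  subsets
}

#' Plant a CTCF binding world with strain-specific intensities
#'
#' Generates background sequences (one per chromosome of the dataset),
#' embeds motif-consensus instances at recorded loci, injects biallelic
#' SNPs into a fraction of sites with per-strain alleles, and simulates
#' ChIP fold enrichment per replicate as base intensity times an
#' allele-dependent multiplier plus noise. Which sites are
#' genotype-dependent is recorded as ground truth.
#'
#' The default design mirrors four inbred strains with three replicates
#' each and two dropped samples (10 columns).
#'
#' @param dataset a \code{gei_dataset} (chromosome names are reused).
#' @param pwm motif to embed (length >= 6).
#' @param n_sites number of motif instances.
#' @param snp_rate fraction of sites carrying a SNP, in [0, 1].
#' @param effect_prob fraction of SNP-carrying sites whose alleles
#'   actually modulate binding intensity (the rest carry silent SNPs).
#' @param strains strain names (>= 2).
#' @param reps_per_strain replicates per strain.
#' @param seed integer RNG seed.
#' @param seq_bp background sequence length per chromosome.
#' @param share_probs distribution of the number of strains a site is
#'   present in (names = strain counts).
#' @param effect_multiplier intensity multiplier for alt-allele strains at
#'   SNP sites.
#' @param noise_sd additive intensity noise SD.
#' @param base_meanlog,base_sdlog log-normal base intensity parameters.
#' @param dropped_samples sample names (\code{"<strain>_r<k>"}) removed
#'   from the design; defaults to one replicate of each of the third and
#'   fourth strain when four strains with three replicates are simulated.
#' @return list of class \code{"ctcf_world"}: \code{sequences}
#'   (\code{DNAStringSet}), \code{sites} (site table with SNP and truth
#'   columns), \code{chip} (a [chip_peak_matrix()]), \code{allele_matrix}
#'   (sites x samples alt-carriage 0/1), \code{snps} (\code{chrom},
#'   \code{pos}).
#' @export
plant_ctcf_world <- function(dataset, pwm = ctcf_pwm(), n_sites = 200,
                             snp_rate = 0.5,
                             strains = c("B6", "CAST", "PWK", "WSB"),
                             reps_per_strain = 3, seed,
                             seq_bp = 50000,
                             share_probs = c("4" = 0.52, "3" = 0.16,
                                             "2" = 0.16, "1" = 0.16),
                             effect_prob = 0.5,
                             effect_multiplier = 0.2, noise_sd = 0.5,
                             base_meanlog = log(8), base_sdlog = 0.4,
                             dropped_samples = NULL) {
  stopifnot(inherits(pwm, "pwm"))
  if (nrow(pwm$matrix) < 6) stop("motif length must be at least 6")
  if (length(strains) < 2) stop("at least 2 strains required")
  if (snp_rate < 0 || snp_rate > 1) stop("snp_rate must lie in [0, 1]")
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)

  L <- nrow(pwm$matrix)
  chroms <- dataset$genome$chrom
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(chroms, function(ch)
    paste(sample(bases, seq_bp, replace = TRUE), collapse = ""),
    character(1))

  cons <- strsplit(pwm_consensus(pwm), "")[[1]]
  # non-overlapping site placement across sequences
  per_chrom <- table(sample(chroms, n_sites, replace = TRUE))
  sites <- list()
  for (ch in names(per_chrom)) {
    k <- per_chrom[[ch]]
    slots <- floor(seq_bp / (2 * L))
    if (k > slots)
      stop("sizing error: ", k, " sites do not fit on ", ch,
           " at length ", seq_bp)
    starts <- sort(sample.int(slots, k)) * 2L * L - 2L * L
    sites[[ch]] <- data.frame(chrom = ch, start = starts,
                              end = starts + L,
                              strand = sample(c("+", "-"), k, replace = TRUE),
                              stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, sites)
  rownames(sites) <- NULL
  sites$site_id <- sprintf("site_%d", seq_len(nrow(sites)))

  # embed consensus (reverse-complemented on minus-strand sites)
  seq_chars <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  for (i in seq_len(nrow(sites))) {
    ins <- if (sites$strand[i] == "+") cons else
      rev(chartr("ACGT", "TGCA", cons))
    seq_chars[[sites$chrom[i]]][(sites$start[i] + 1):(sites$end[i])] <- ins
  }

  # SNPs: offset within the motif, alt allele, carrier strains
  has_snp <- stats::runif(nrow(sites)) < snp_rate
  sites$has_snp <- has_snp
  sites$snp_offset <- NA_integer_
  sites$alt_strains <- NA_character_
  snp_rows <- which(has_snp)
  alt_carrier <- matrix(FALSE, nrow(sites), length(strains),
                        dimnames = list(sites$site_id, strains))
  for (i in snp_rows) {
    off <- sample.int(L, 1) - 1L
    sites$snp_offset[i] <- off
    n_alt <- sample.int(length(strains) - 1L, 1)
    carriers <- sample(strains, n_alt)
    alt_carrier[i, carriers] <- TRUE
    sites$alt_strains[i] <- paste(sort(carriers), collapse = ",")
  }
  sites$genotype_dependent <- has_snp & stats::runif(nrow(sites)) < effect_prob

  # presence pattern per site and strain
  lvls <- as.integer(names(share_probs))
  n_present <- lvls[sample.int(length(lvls), nrow(sites), replace = TRUE,
                               prob = share_probs)]
  n_present <- pmin(n_present, length(strains))
  present <- matrix(FALSE, nrow(sites), length(strains),
                    dimnames = list(sites$site_id, strains))
  for (i in seq_len(nrow(sites)))
    present[i, sample(strains, n_present[i])] <- TRUE

  samples <- as.vector(t(outer(strains, seq_len(reps_per_strain),
                               function(s, r) paste0(s, "_r", r))))
  if (is.null(dropped_samples) && length(strains) == 4 &&
      reps_per_strain == 3)
    dropped_samples <- paste0(strains[3:4], "_r3")
  samples <- setdiff(samples, dropped_samples)
  sample_strain <- stats::setNames(sub("_r[0-9]+$", "", samples), samples)

  base <- stats::rlnorm(nrow(sites), base_meanlog, base_sdlog)
  fe <- matrix(0, nrow(sites), length(samples),
               dimnames = list(sites$site_id, samples))
  allele_matrix <- matrix(0L, nrow(sites), length(samples),
                          dimnames = list(sites$site_id, samples))
  floor_ <- 1
  for (j in seq_along(samples)) {
    st <- sample_strain[j]
    mult <- ifelse(sites$genotype_dependent & alt_carrier[, st],
                   effect_multiplier, 1)
    mu <- ifelse(present[, st], base * mult, stats::runif(nrow(sites), 0,
                                                          0.8 * floor_))
    fe[, j] <- pmax(0, mu + stats::rnorm(nrow(sites), 0, noise_sd))
    allele_matrix[, j] <- as.integer(alt_carrier[, st])
  }

  snps <- sites[has_snp, c("chrom", "start", "snp_offset", "strand")]
  snp_pos <- ifelse(snps$strand == "+", snps$start + snps$snp_offset,
                    snps$start + (L - 1L) - snps$snp_offset)
  snp_tab <- data.frame(chrom = snps$chrom, pos = snp_pos,
                        stringsAsFactors = FALSE)

  chip <- chip_peak_matrix(
    data.frame(chrom = sites$chrom, start = sites$start, end = sites$end,
               peak_id = sites$site_id, stringsAsFactors = FALSE),
    fe, sample_strain, detection_floor = floor_)

  structure(list(sequences = Biostrings::DNAStringSet(
                   stats::setNames(vapply(seq_chars, paste, character(1),
                                          collapse = ""), chroms)),
                 sites = sites, chip = chip,
                 allele_matrix = allele_matrix, snps = snp_tab,
                 present = present),
            class = "ctcf_world")
}

#' @export
print.ctcf_world <- function(x, ...) {
  cat("Synthetic CTCF binding world: ", nrow(x$sites), " sites, ",
      ncol(x$chip$fe), " ChIP samples, ",
      sum(x$sites$has_snp), " SNP-carrying sites\n", sep = "")
  invisible(x)
}
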