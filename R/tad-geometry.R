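#' Region decomposition of a chromosome into TADs and inter-TAD gaps
#'
#' Builds an ordered, non-overlapping tiling of one chromosome from its TAD
#' intervals: each TAD is a region, and every gap between (or flanking)
#' TADs is an inter-TAD region. Coordinates are 0-based half-open.
#'
#' @param tads data frame with \code{chrom}, \code{start}, \code{end} (and
#'   optionally \code{tad_id}) for a single chromosome.
#' @param chrom_length chromosome length; \code{NA} leaves the final flank
#'   unbounded.
#' @return data frame \code{start}, \code{end}, \code{type}
#'   (\code{"tad"}/\code{"inter"}), \code{region_id}, ordered by start and
#'   tiling \code{[0, chrom_length)}.
#' @export
tad_regions <- function(tads, chrom_length = NA) {
  if (length(unique(tads$chrom)) > 1)
    stop("tad_regions() expects TADs from a single chromosome")
  tads <- tads[order(tads$start), , drop = FALSE]
  if (any(tads$end <= tads$start)) stop("TADs must satisfy end > start")
  if (nrow(tads) > 1 && any(tads$start[-1] < tads$end[-nrow(tads)]))
    stop("TADs on a chromosome must not overlap")
  if (is.null(tads$tad_id))
    tads$tad_id <- sprintf("tad_%s_%d", tads$chrom[1], seq_len(nrow(tads)))
  ch <- if (nrow(tads)) tads$chrom[1] else NA_character_
  L <- if (is.na(chrom_length) || length(chrom_length) == 0) Inf else chrom_length

  starts <- ends <- numeric(0); type <- id <- character(0)
  cursor <- 0
  k_gap <- 0
  for (j in seq_len(nrow(tads))) {
    if (tads$start[j] > cursor) {
      k_gap <- k_gap + 1
      starts <- c(starts, cursor); ends <- c(ends, tads$start[j])
      type <- c(type, "inter"); id <- c(id, sprintf("inter_%s_%d", ch, k_gap))
    }
    starts <- c(starts, tads$start[j]); ends <- c(ends, tads$end[j])
    type <- c(type, "tad"); id <- c(id, tads$tad_id[j])
    cursor <- tads$end[j]
  }
  if (cursor < L) {
    k_gap <- k_gap + 1
    starts <- c(starts, cursor); ends <- c(ends, L)
    type <- c(type, "inter"); id <- c(id, sprintf("inter_%s_%d", ch, k_gap))
  }
  data.frame(start = starts, end = ends, type = type, region_id = id,
             stringsAsFactors = FALSE)
}

#' Assign features to TADs or inter-TAD regions
#'
#' A feature whose anchor lies in \code{[start, end)} of a TAD belongs to
#' that TAD; otherwise it belongs to the inter-TAD region bounded by the
#' neighbouring TADs (chromosome flanks included). Inter-TAD regions are
#' first-class membership targets.
#'
#' @param features data frame with \code{chrom} and \code{pos} (anchor, bp).
#' @param tads data frame of TAD intervals (\code{chrom}, \code{start},
#'   \code{end}, optional \code{tad_id}).
#' @param chrom_lengths optional named vector bounding the final flank.
#' @return \code{features} with added columns \code{region_id},
#'   \code{intra_tad} (logical), \code{tad_id} (\code{NA} for inter-TAD).
#' @export
assign_to_tads <- function(features, tads, chrom_lengths = NULL) {
  unknown <- setdiff(unique(features$chrom), unique(tads$chrom))
  if (length(unknown))
    stop("features on chromosomes without TADs: ",
         paste(unknown, collapse = ", "))
  features$region_id <- NA_character_
  features$intra_tad <- NA
  features$tad_id <- NA_character_
  for (ch in unique(features$chrom)) {
    L <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths))
      chrom_lengths[[ch]] else NA
    reg <- tad_regions(tads[tads$chrom == ch, , drop = FALSE], L)
    sel <- which(features$chrom == ch)
    ri <- findInterval(features$pos[sel], reg$start)
    if (any(ri < 1) || any(features$pos[sel] >= reg$end[ri]))
      stop("feature positions outside the region tiling on ", ch)
    features$region_id[sel] <- reg$region_id[ri]
    features$intra_tad[sel] <- reg$type[ri] == "tad"
    features$tad_id[sel] <- ifelse(reg$type[ri] == "tad",
                                   reg$region_id[ri], NA_character_)
  }
  features
}

#' Intra-TAD enrichment of significant interacting models
#'
#' Forms a 2x2 contingency table over gene-peak pairs of the model table:
#' rows intra-TAD (peak midpoint in the same TAD as the gene's TSS) vs
#' not, columns significant-interacting vs other, and tests enrichment
#' with a two-sided Fisher exact test. The stored odds ratio is the sample
#' ratio \eqn{(ad)/(bc)}; an empty cell triggers the Haldane-Anscombe 0.5
#' correction, flagged in the result.
#'
#' Peaks whose midpoint lies within \code{window_bp} of a TAD boundary are
#' tagged boundary-proximal; by default they are excluded from the table
#' (both variants are reported).
#'
#' @param models scan model table (or \code{gei_scan}).
#' @param genes,peaks,tads dataset feature tables.
#' @param window_bp boundary window, default 200 kb.
#' @param exclude_boundary_proximal drop boundary-proximal pairs from the
#'   default table.
#' @return list of class \code{"gei_enrichment"}: \code{contingency} (2x2),
#'   \code{odds_ratio}, \code{p_value}, \code{haldane} flag,
#'   \code{n_boundary_proximal}, and \code{including_proximal} (the same
#'   statistics without the exclusion).
#' @export
boundary_window_enrichment <- function(models, genes, peaks, tads,
                                       window_bp = 200000,
                                       exclude_boundary_proximal = TRUE) {
  models <- .as_model_table(models)
  gi <- match(models$gene_id, genes$gene_id)
  pj <- match(models$peak_id, peaks$peak_id)
  if (anyNA(gi) || anyNA(pj))
    stop("model table references genes/peaks absent from the feature tables")

  g_asg <- assign_to_tads(data.frame(chrom = genes$chrom, pos = genes$tss),
                          tads)
  p_asg <- assign_to_tads(data.frame(chrom = peaks$chrom, pos = peaks$mid),
                          tads)
  same_tad <- !is.na(g_asg$tad_id[gi]) & !is.na(p_asg$tad_id[pj]) &
    g_asg$tad_id[gi] == p_asg$tad_id[pj]
  inter_sig <- !is.na(models$model_class) &
    models$model_class == "interacting" & models$significant

  bp_dist <- .boundary_distance(peaks$chrom[pj], peaks$mid[pj], tads)
  proximal <- bp_dist <= window_bp

  tab_of <- function(keep) {
    a <- sum(keep & same_tad & inter_sig)
    b <- sum(keep & !same_tad & inter_sig)
    c_ <- sum(keep & same_tad & !inter_sig)
    d <- sum(keep & !same_tad & !inter_sig)
    m <- matrix(c(a, b, c_, d), 2, 2,
                dimnames = list(c("intra_tad", "extra_tad"),
                                c("interacting", "other")))
    haldane <- any(m == 0)
    mm <- if (haldane) m + 0.5 else m
    or <- (mm[1, 1] * mm[2, 2]) / (mm[1, 2] * mm[2, 1])
    p <- stats::fisher.test(m)$p.value
    list(contingency = m, odds_ratio = or, p_value = p, haldane = haldane)
  }

  keep <- if (exclude_boundary_proximal) !proximal else rep(TRUE, nrow(models))
  out <- tab_of(keep)
  out$n_boundary_proximal <- sum(proximal)
  out$including_proximal <- tab_of(rep(TRUE, nrow(models)))
  class(out) <- "gei_enrichment"
  out
}

#' @export
print.gei_enrichment <- function(x, ...) {
  cat("Intra-TAD enrichment of significant interacting models\n")
  print(x$contingency)
  cat("odds ratio = ", format(x$odds_ratio, digits = 4),
      if (x$haldane) " (Haldane-Anscombe corrected)" else "",
      ", Fisher p = ", format(x$p_value, digits = 4), "\n", sep = "")
  cat(x$n_boundary_proximal, "boundary-proximal pairs",
      "(excluded from the default table)\n")
  invisible(x)
}

# distance from each position to the nearest TAD boundary on its chromosome
.boundary_distance <- function(chrom, pos, tads) {
  out <- rep(Inf, length(pos))
  for (ch in unique(chrom)) {
    b <- sort(unique(c(tads$start[tads$chrom == ch],
                       tads$end[tads$chrom == ch])))
    if (length(b) == 0) next
    sel <- which(chrom == ch)
    i <- findInterval(pos[sel], b)
    lo <- ifelse(i >= 1, pos[sel] - b[pmax(i, 1)], Inf)
    hi <- ifelse(i < length(b), b[pmin(i + 1, length(b))] - pos[sel], Inf)
    out[sel] <- pmin(lo, hi)
  }
  out
}

#' Loop distance between two intra-TAD positions
#'
#' Circular metric on the TAD loop formed by joining the two boundaries:
#' \code{min(|a - b|, L - |a - b|)} with \code{L} the TAD length. The
#' maximum attainable value is \code{L / 2}, reached halfway around the
#' loop.
#'
#' @param pos_a,pos_b positions (bp), vectorised; both must lie inside the
#'   TAD.
#' @param tad a one-row TAD (list or data frame with \code{start},
#'   \code{end}).
#' @return numeric distances in bp.
#' @export
loop_distance <- function(pos_a, pos_b, tad) {
  L <- tad$end - tad$start
  if (any(pos_a < tad$start | pos_a >= tad$end) ||
      any(pos_b < tad$start | pos_b >= tad$end))
    stop("positions must lie inside the TAD [start, end)")
  d <- abs(pos_a - pos_b)
  pmin(d, L - d)
}

#' Standardised loop coordinates of interacting peaks
#'
#' For every significant interacting model whose gene TSS and peak midpoint
#' share a TAD, computes the gene-relative loop offset divided by TAD
#' length: sign is the linear-sequence direction from the TSS (positive =
#' downstream), magnitude is \code{loop_distance / L}, so values lie in
#' [-0.5, 0.5]. Aggregating across TADs yields the gene-centred loop
#' density profile.
#'
#' @inheritParams boundary_window_enrichment
#' @return data frame \code{gene_id}, \code{peak_id}, \code{tad_id},
#'   \code{offset}; attribute \code{n_excluded} counts models whose gene
#'   and peak do not share a TAD.
#' @export
standardize_tad_coords <- function(models, genes, peaks, tads) {
  models <- .as_model_table(models)
  sub <- models[!is.na(models$model_class) &
                  models$model_class == "interacting" & models$significant, ,
                drop = FALSE]
  gi <- match(sub$gene_id, genes$gene_id)
  pj <- match(sub$peak_id, peaks$peak_id)
  g_asg <- assign_to_tads(data.frame(chrom = genes$chrom, pos = genes$tss),
                          tads)
  p_asg <- assign_to_tads(data.frame(chrom = peaks$chrom, pos = peaks$mid),
                          tads)
  shared <- !is.na(g_asg$tad_id[gi]) & !is.na(p_asg$tad_id[pj]) &
    g_asg$tad_id[gi] == p_asg$tad_id[pj]
  n_excluded <- sum(!shared)
  sub <- sub[shared, , drop = FALSE]
  gi <- gi[shared]; pj <- pj[shared]
  tid <- g_asg$tad_id[gi]
  ti <- match(tid, tads$tad_id)
  L <- tads$end[ti] - tads$start[ti]
  tss <- genes$tss[gi]; mid <- peaks$mid[pj]
  d <- abs(tss - mid)
  loop <- pmin(d, L - d)
  offset <- sign(mid - tss) * loop / L
  out <- data.frame(gene_id = sub$gene_id, peak_id = sub$peak_id,
                    tad_id = tid, offset = offset,
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' TSS-relative capture window for significant interactions
#'
#' Finds the smallest upstream and downstream distances from the TSS such
#' that a fraction \code{q} of significant interacting models have all
#' their elements (causal variant and peak) inside. Computed as marginal
#' type-1 quantiles of the per-model most-upstream and most-downstream
#' element offsets (strand-aware).
#'
#' @param models scan model table (or \code{gei_scan}).
#' @param genes,markers,peaks dataset feature tables.
#' @param q coverage fraction, default 0.95.
#' @return named numeric \code{c(upstream_bp, downstream_bp)}.
#' @export
capture_window <- function(models, genes, markers, peaks, q = 0.95) {
  models <- .as_model_table(models)
  sub <- models[!is.na(models$model_class) &
                  models$model_class == "interacting" & models$significant, ,
                drop = FALSE]
  if (nrow(sub) < 20)
    stop("fewer than 20 significant interacting models; quantile unstable")
  gi <- match(sub$gene_id, genes$gene_id)
  mi <- match(sub$variant_id, markers$variant_id)
  pj <- match(sub$peak_id, peaks$peak_id)
  sgn <- ifelse(genes$strand[gi] == "+", 1, -1)
  off_var <- (markers$pos[mi] - genes$tss[gi]) * sgn
  off_peak <- (peaks$mid[pj] - genes$tss[gi]) * sgn
  up <- pmax(0, -pmin(off_var, off_peak))
  down <- pmax(0, pmax(off_var, off_peak))
  c(upstream_bp = unname(stats::quantile(up, q, type = 1)),
    downstream_bp = unname(stats::quantile(down, q, type = 1)))
}

#' TAD-based vs linear search efficiency profiles
#'
#' For every gene, bins peaks by signed strand-aware TSS offset out to
#' \code{max_radius}. Linear mode counts all same-chromosome peaks per
#' bin; TAD mode counts only peaks sharing the gene's TAD. A peak counts
#' as interacting for a gene if the model table holds a significant
#' interacting model of that gene-peak pair.
#'
#' @param dataset a \code{gei_dataset} (or list with \code{genes},
#'   \code{peaks}, \code{tads}).
#' @param models scan model table (or \code{gei_scan}).
#' @param max_radius maximum |offset| from the TSS (default 2.5 Mb).
#' @param bin_bp bin width (must be positive).
#' @return data frame \code{mode}, \code{bin_start}, \code{bin_end}
#'   (TSS-relative bp), \code{n_peaks}, \code{n_interacting},
#'   \code{pct_interacting} (0 where the bin is empty).
#' @export
search_efficiency_profiles <- function(dataset, models, max_radius = 2.5e6,
                                       bin_bp = 1e5) {
  if (bin_bp <= 0) stop("bin_bp must be positive")
  models <- .as_model_table(models)
  genes <- dataset$genes; peaks <- dataset$peaks; tads <- dataset$tads
  inter <- models[!is.na(models$model_class) &
                    models$model_class == "interacting" & models$significant, ,
                  drop = FALSE]
  inter_key <- paste(inter$gene_id, inter$peak_id)
  g_asg <- assign_to_tads(data.frame(chrom = genes$chrom, pos = genes$tss),
                          tads)
  p_asg <- assign_to_tads(data.frame(chrom = peaks$chrom, pos = peaks$mid),
                          tads)
  breaks <- seq(-max_radius, max_radius, by = bin_bp)
  nb <- length(breaks) - 1
  cnt <- list(linear = numeric(nb), tad = numeric(nb))
  hit <- list(linear = numeric(nb), tad = numeric(nb))
  for (i in seq_len(nrow(genes))) {
    sel <- which(peaks$chrom == genes$chrom[i])
    if (!length(sel)) next
    sgn <- if (genes$strand[i] == "+") 1 else -1
    off <- (peaks$mid[sel] - genes$tss[i]) * sgn
    inside <- off >= -max_radius & off < max_radius
    sel <- sel[inside]; off <- off[inside]
    if (!length(sel)) next
    b <- findInterval(off, breaks, rightmost.closed = FALSE)
    is_int <- paste(genes$gene_id[i], peaks$peak_id[sel]) %in% inter_key
    same_tad <- !is.na(g_asg$tad_id[i]) & !is.na(p_asg$tad_id[sel]) &
      p_asg$tad_id[sel] == g_asg$tad_id[i]
    tb <- tabulate(b, nb)
    cnt$linear <- cnt$linear + tb
    hit$linear <- hit$linear + tabulate(b[is_int], nb)
    cnt$tad <- cnt$tad + tabulate(b[same_tad], nb)
    hit$tad <- hit$tad + tabulate(b[same_tad & is_int], nb)
  }
  out <- do.call(rbind, lapply(c("linear", "tad"), function(md) {
    data.frame(mode = md, bin_start = breaks[-length(breaks)],
               bin_end = breaks[-1], n_peaks = cnt[[md]],
               n_interacting = hit[[md]],
               pct_interacting = ifelse(cnt[[md]] > 0,
                                        100 * hit[[md]] / cnt[[md]], 0),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Fraction of genes with a TAD boundary close upstream of the TSS
#'
#' Strand-aware: a gene is flagged when some TAD boundary lies strictly
#' upstream of its TSS within \code{near_bp}.
#'
#' @param genes gene table with \code{chrom}, \code{tss}, \code{strand}.
#' @param tads TAD intervals.
#' @param near_bp window size in bp.
#' @return list: \code{fraction}, \code{flags} (per-gene logical).
#' @export
gene_boundary_proximity <- function(genes, tads, near_bp) {
  if (near_bp < 0) stop("near_bp must be non-negative")
  flags <- logical(nrow(genes))
  for (ch in unique(genes$chrom)) {
    b <- sort(unique(c(tads$start[tads$chrom == ch],
                       tads$end[tads$chrom == ch])))
    sel <- which(genes$chrom == ch)
    if (!length(b)) next
    for (j in sel) {
      tss <- genes$tss[j]
      d <- if (genes$strand[j] == "+") tss - b else b - tss
      flags[j] <- any(d > 0 & d <= near_bp)
    }
  }
  list(fraction = mean(flags), flags = flags)
}

# Accept either a gei_scan or a bare model table.
.as_model_table <- function(models) {
  if (inherits(models, "gei_scan")) models$models else as.data.frame(models)
}
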