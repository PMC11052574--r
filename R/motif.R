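#' Position weight matrix constructor
#'
#' @param matrix numeric matrix, motif positions x 4 base probabilities
#'   (columns A, C, G, T); each row must sum to 1 within 1e-6.
#' @param background length-4 base probabilities (default uniform).
#' @param name motif name.
#' @return object of class \code{"pwm"}.
#' @export
pwm <- function(matrix, background = rep(0.25, 4), name = "motif") {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 4) stop("PWM must have 4 columns (A, C, G, T)")
  if (any(matrix < 0)) stop("PWM probabilities must be non-negative")
  if (any(abs(rowSums(matrix) - 1) > 1e-6))
    stop("each PWM row must sum to 1 (tolerance 1e-6)")
  if (length(background) != 4 || abs(sum(background) - 1) > 1e-6)
    stop("background must be 4 probabilities summing to 1")
  colnames(matrix) <- c("A", "C", "G", "T")
  structure(list(matrix = matrix, background = as.numeric(background),
                 name = name), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM '", x$name, "' (", nrow(x$matrix), " bp), consensus ",
      pwm_consensus(x), "\n", sep = "")
  invisible(x)
}

#' Consensus sequence of a PWM
#' @param x a [pwm()].
#' @return character consensus string.
#' @export
pwm_consensus <- function(x) {
  paste(c("A", "C", "G", "T")[apply(x$matrix, 1, which.max)], collapse = "")
}

#' Log-odds score matrix of a PWM
#'
#' \code{log2(p / background)} per position and base, with a 1e-4 floor on
#' probabilities so zero entries stay finite (standard pseudocount
#' practice).
#'
#' @param x a [pwm()].
#' @return numeric matrix, positions x 4.
#' @export
pwm_score_matrix <- function(x) {
  log2(pmax(x$matrix, 1e-4) / rep(pmax(x$background, 1e-4),
                                  each = nrow(x$matrix)))
}

#' Built-in CTCF-like motif
#'
#' A synthetic position-probability matrix shaped like the CTCF core
#' binding motif (strong CCxxxAGxxGGC core with degenerate edges). It is a
#' stand-in defined in code for simulation and testing, not a database
#' matrix.
#'
#' @return a [pwm()] of length 14.
#' @export
ctcf_pwm <- function() {
  cons <- strsplit("CCACCAGGTGGCAG", "")[[1]]
  # edge positions more degenerate than the core
  strength <- c(0.7, 0.8, 0.85, 0.95, 0.95, 0.9, 0.95, 0.95, 0.85,
                0.95, 0.95, 0.9, 0.8, 0.7)
  m <- t(vapply(seq_along(cons), function(i) {
    p <- rep((1 - strength[i]) / 3, 4)
    p[match(cons[i], c("A", "C", "G", "T"))] <- strength[i]
    p
  }, numeric(4)))
  pwm(m, name = "CTCF_like_synthetic")
}

#' Scan a sequence for PWM hits with exact score p-values
#'
#' Scores every window on both strands with the log2 odds of PWM vs
#' background. Score p-values come from the exact distribution of
#' discretised window scores over all \code{4^L} windows under the
#' background model, computed by dynamic programming (position-wise
#' convolution over \code{n_bins} integer score levels). Windows
#' containing N are skipped.
#'
#' @param sequence character string, \code{Biostrings::DNAString}, or a
#'   named \code{DNAStringSet} (scanned per sequence).
#' @param pwm a [pwm()] (length 6-20 supported).
#' @param p_threshold report hits with p-value at or below this (default
#'   1e-4; use 1 to score every window).
#' @param n_bins score-discretisation bins for the p-value DP.
#' @return data frame of hits sorted by position: \code{chrom},
#'   \code{start}, \code{end} (0-based half-open), \code{strand},
#'   \code{score} (log2 odds), \code{p_value}.
#' @export
scan_pwm <- function(sequence, pwm, p_threshold = 1e-4, n_bins = 1000) {
  stopifnot(inherits(pwm, "pwm"))
  L <- nrow(pwm$matrix)
  if (L < 2 || L > 20) stop("motif length must be between 2 and 20")
  if (inherits(sequence, "DNAStringSet")) {
    nm <- if (is.null(names(sequence))) as.character(seq_along(sequence))
          else names(sequence)
    out <- do.call(rbind, lapply(seq_along(sequence), function(i) {
      h <- scan_pwm(as.character(sequence[[i]]), pwm, p_threshold, n_bins)
      if (nrow(h)) h$chrom <- nm[i]
      h
    }))
    return(out)
  }
  if (inherits(sequence, "DNAString")) sequence <- as.character(sequence)
  sequence <- toupper(sequence)

  lo <- pwm_score_matrix(pwm)
  disc <- .discretize_scores(lo, pwm$background, n_bins)

  fwd <- .strand_hits(sequence, lo, disc, L)
  rc <- .revcomp(sequence)
  rev <- .strand_hits(rc, lo, disc, L)
  n <- nchar(sequence)
  if (nrow(rev)) {
    # mirror minus-strand coordinates back to the forward sequence
    rev$start <- n - rev$start - L
    rev$strand <- "-"
  }
  hits <- rbind(fwd, rev)
  hits <- hits[hits$p_value <= p_threshold, , drop = FALSE]
  if (nrow(hits) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      score = numeric(0), p_value = numeric(0),
                      stringsAsFactors = FALSE))
  hits$end <- hits$start + L
  hits$chrom <- NA_character_
  hits <- hits[order(hits$start, hits$strand), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits[, c("chrom", "start", "end", "strand", "score", "p_value")]
}

# Integer discretisation of a log-odds matrix plus the exact tail
# distribution of total discretised scores under the background model.
.discretize_scores <- function(lo, background, n_bins) {
  rmin <- apply(lo, 1, min)
  rng <- sum(apply(lo, 1, max)) - sum(rmin)
  w <- if (rng > 0) rng / n_bins else 1
  D <- round(sweep(lo, 1, rmin) / w)  # L x 4, non-negative integers
  maxT <- sum(apply(D, 1, max))
  dist <- numeric(maxT + 1); dist[1] <- 1
  for (i in seq_len(nrow(D))) {
    nd <- numeric(maxT + 1)
    for (b in 1:4) {
      s <- D[i, b]
      nd[(s + 1):(maxT + 1)] <- nd[(s + 1):(maxT + 1)] +
        background[b] * dist[1:(maxT + 1 - s)]
    }
    dist <- nd
  }
  tail_p <- rev(cumsum(rev(dist)))  # P(T >= t), index t+1
  list(D = D, tail_p = pmin(tail_p, 1), w = w)
}

# windows on one strand: continuous score, integer score, p-value
.strand_hits <- function(sequence, lo, disc, L) {
  code <- match(strsplit(sequence, "", fixed = TRUE)[[1]],
                c("A", "C", "G", "T"))
  n <- length(code)
  if (n < L)
    return(data.frame(start = integer(0), strand = character(0),
                      score = numeric(0), p_value = numeric(0),
                      stringsAsFactors = FALSE))
  nw <- n - L + 1
  sc <- numeric(nw); ti <- integer(nw); bad <- logical(nw)
  for (j in seq_len(L)) {
    cj <- code[j:(j + nw - 1)]
    nas <- is.na(cj)
    bad <- bad | nas
    cj[nas] <- 1L
    sc <- sc + lo[j, cj]
    ti <- ti + disc$D[j, cj]
  }
  keep <- !bad
  data.frame(start = which(keep) - 1L, strand = "+",
             score = sc[keep], p_value = disc$tail_p[ti[keep] + 1L],
             stringsAsFactors = FALSE)
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' SNP density by motif position
#'
#' Bins SNPs inside motif hits by strand-aware offset within the motif
#' (offset 0 is the motif's first base on its own strand).
#'
#' @param hits hit table from [scan_pwm()] (needs \code{chrom},
#'   \code{start}, \code{end}, \code{strand}).
#' @param snps data frame with \code{chrom}, \code{pos} (point
#'   coordinates), or a numeric position vector when all hits share one
#'   sequence.
#' @return list: \code{position_counts} (SNP count per motif offset),
#'   \code{fraction_hits_with_snp}, \code{n_hits}.
#' @export
snp_motif_density <- function(hits, snps) {
  if (is.numeric(snps))
    snps <- data.frame(chrom = hits$chrom[1], pos = snps)
  L <- if (nrow(hits)) hits$end[1] - hits$start[1] else 0
  counts <- numeric(L)
  has_snp <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    sel <- (is.na(hits$chrom[i]) | snps$chrom == hits$chrom[i]) &
      snps$pos >= hits$start[i] & snps$pos < hits$end[i]
    if (!any(sel)) next
    has_snp[i] <- TRUE
    off <- if (hits$strand[i] == "+") snps$pos[sel] - hits$start[i]
           else (hits$end[i] - 1) - snps$pos[sel]
    for (o in off) counts[o + 1] <- counts[o + 1] + 1
  }
  list(position_counts = counts,
       fraction_hits_with_snp = if (nrow(hits)) mean(has_snp) else NA_real_,
       n_hits = nrow(hits))
}

#' Annotate peaks against genomic feature categories
#'
#' A peak counts for a category when its midpoint lies inside any interval
#' of that category (midpoint rule; categories are not exclusive).
#'
#' @param peaks peak table with \code{chrom}, \code{start}, \code{end}
#'   (midpoint derived if no \code{mid} column).
#' @param annotations named list of interval tables (\code{chrom},
#'   \code{start}, \code{end}), e.g. gene bodies, exons, promoters,
#'   enhancers. \code{NULL} entries are skipped with a warning.
#' @return list: \code{percent} (named, over the peak set), \code{flags}
#'   (peaks x categories logical matrix).
#' @export
annotate_peaks <- function(peaks, annotations) {
  if (is.null(peaks$mid)) peaks$mid <- floor((peaks$start + peaks$end) / 2)
  keep <- !vapply(annotations, is.null, logical(1))
  if (any(!keep))
    warning("skipping missing annotation categories: ",
            paste(names(annotations)[!keep], collapse = ", "))
  annotations <- annotations[keep]
  flags <- matrix(FALSE, nrow(peaks), length(annotations),
                  dimnames = list(peaks$peak_id, names(annotations)))
  for (k in seq_along(annotations)) {
    ann <- annotations[[k]]
    for (ch in unique(peaks$chrom)) {
      psel <- which(peaks$chrom == ch)
      asel <- ann$chrom == ch
      if (!any(asel) || !length(psel)) next
      q <- IRanges::IRanges(start = peaks$mid[psel] + 1L, width = 1L)
      s <- IRanges::IRanges(start = ann$start[asel] + 1L,
                            end = ann$end[asel])
      ov <- IRanges::overlapsAny(q, s)
      flags[psel, k] <- ov
    }
  }
  list(percent = 100 * colMeans(flags), flags = flags)
}

#' Identify negative-effector peaks
#'
#' Peaks participating in at least \code{min_models} significant
#' interacting models, of which at least \code{min_negative_fraction} have
#' a negative accessibility effect (\code{b2 < 0}), form the negative
#' effector subset. Qualifying peaks that miss the negative-fraction bar
#' form the complementary positive effector subset.
#'
#' @param models scan model table (or \code{gei_scan}).
#' @param min_models minimum significant interacting models per peak.
#' @param min_negative_fraction minimum fraction with \code{b2 < 0}.
#' @return list: \code{negative}, \code{positive} (peak id vectors),
#'   \code{table} (per-qualifying-peak counts and negative fractions).
#' @export
negative_effector_peaks <- function(models, min_models = 10,
                                    min_negative_fraction = 0.5) {
  mo <- .as_model_table(models)
  mo <- mo[!is.na(mo$model_class) & mo$model_class == "interacting" &
             mo$significant, , drop = FALSE]
  if (nrow(mo) == 0)
    return(list(negative = character(0), positive = character(0),
                table = data.frame(peak_id = character(0),
                                   n_models = integer(0),
                                   frac_negative = numeric(0))))
  n_mod <- tapply(mo$beta2, mo$peak_id, length)
  f_neg <- tapply(mo$beta2, mo$peak_id, function(b) mean(b < 0))
  tab <- data.frame(peak_id = names(n_mod),
                    n_models = as.integer(n_mod),
                    frac_negative = as.numeric(f_neg),
                    stringsAsFactors = FALSE)
  tab <- tab[tab$n_models >= min_models, , drop = FALSE]
  neg <- tab$peak_id[tab$frac_negative >= min_negative_fraction]
  pos <- setdiff(tab$peak_id, neg)
  list(negative = neg, positive = pos, table = tab)
}
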