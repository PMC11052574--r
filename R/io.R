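#' Write intervals as BED
#'
#' Internal coordinates are 0-based half-open, matching BED, so intervals
#' are emitted as-is. Columns beyond chrom/start/end (name, score, strand)
#' are included when present.
#'
#' @param x data frame with \code{chrom}, \code{start}, \code{end} and
#'   optionally \code{name}/id, \code{score}, \code{strand}.
#' @param path output file.
#' @export
write_bed <- function(x, path) {
  name_col <- intersect(c("name", "gene_id", "variant_id", "peak_id",
                          "tad_id", "site_id"), names(x))[1]
  out <- data.frame(chrom = x$chrom, start = x$start, end = x$end)
  if (!is.na(name_col)) {
    out$name <- x[[name_col]]
    out$score <- if ("score" %in% names(x)) x$score else 0
    out$strand <- if ("strand" %in% names(x)) x$strand else "."
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file
#'
#' @param path BED file (3-6 columns, no header).
#' @return data frame \code{chrom}, \code{start}, \code{end} and, when
#'   present, \code{name}, \code{score}, \code{strand} (0-based half-open,
#'   as stored).
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  names(x) <- c("chrom", "start", "end", "name", "score",
                "strand")[seq_len(ncol(x))]
  x
}

#' Write a feature x sample matrix as TSV
#'
#' First column \code{feature_id}, then one column per sample.
#'
#' @param m numeric matrix with dimnames.
#' @param path output file.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature x sample TSV matrix
#'
#' @param path file written by [write_matrix_tsv()].
#' @return numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a synthetic dataset to a directory
#'
#' Emits genes/peaks/TADs/markers as BED, the three sample matrices and
#' the truth ledger as TSV, and the configuration (seed included) as JSON.
#'
#' @param dataset a \code{gei_dataset}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bed(dataset$genes, file.path(dir, "genes.bed"))
  write_bed(dataset$markers, file.path(dir, "markers.bed"))
  write_bed(dataset$peaks, file.path(dir, "peaks.bed"))
  write_bed(dataset$tads, file.path(dir, "tads.bed"))
  write_matrix_tsv(dataset$dosage, file.path(dir, "dosage.tsv"))
  write_matrix_tsv(dataset$atac, file.path(dir, "atac.tsv"))
  if (!is.null(dataset$expression))
    write_matrix_tsv(dataset$expression, file.path(dir, "expression.tsv"))
  if (!is.null(dataset$truth))
    utils::write.table(dataset$truth, file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- unclass(dataset$config)
  cfg$seed <- dataset$seed
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a scan model table and run manifest
#'
#' @param scan a \code{gei_scan}.
#' @param dir output directory.
#' @export
write_scan <- function(scan, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(scan$models, file.path(dir, "models.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(scan$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a PWM in the package's position-probability text format
#'
#' Format: comment lines \code{# name:} and \code{# background:}, then one
#' line of four probabilities (A C G T) per motif position. Matrices in
#' other dialects (counts, MEME minimal) convert by normalising rows to
#' probabilities before writing.
#'
#' @param x a [pwm()].
#' @param path output file.
#' @export
write_pwm <- function(x, path) {
  lines <- c(paste0("# name: ", x$name),
             paste0("# background: ",
                    paste(format(x$background, digits = 6), collapse = " ")),
             apply(x$matrix, 1, function(r)
               paste(format(r, digits = 6), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a PWM from the position-probability text format
#'
#' @param path file written by [write_pwm()].
#' @return a [pwm()].
#' @export
read_pwm <- function(path) {
  lines <- readLines(path)
  nm <- sub("^# name: *", "", grep("^# name:", lines, value = TRUE)[1])
  bg_line <- grep("^# background:", lines, value = TRUE)
  bg <- if (length(bg_line))
    as.numeric(strsplit(sub("^# background: *", "", bg_line[1]),
                        " +")[[1]])
  else rep(0.25, 4)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  m <- do.call(rbind, lapply(strsplit(trimws(body), " +"), as.numeric))
  pwm(m, background = bg, name = if (is.na(nm)) "motif" else nm)
}

#' Write sequences as FASTA
#'
#' @param sequences named character vector or \code{DNAStringSet}.
#' @param path output file.
#' @export
write_fasta <- function(sequences, path) {
  if (!inherits(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(sequences, path)
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return a \code{Biostrings::DNAStringSet}.
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)
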