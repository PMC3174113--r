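#' Write a probe track as bedGraph
#'
#' Tab-delimited `chrom start end log2ratio`, 0-based half-open, one
#' file per replicate per mark.
#'
#' @param track A [probe_track()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_probe_track <- function(track, path) {
  stopifnot(inherits(track, "probe_track"))
  df <- data.frame(chrom = track$chrom,
                   start = format(track$start, scientific = FALSE,
                                  trim = TRUE),
                   end = format(track$start + track$probe_length,
                                scientific = FALSE, trim = TRUE),
                   ratio = track$ratio)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph probe track
#'
#' @param path A bedGraph file written by [write_probe_track()] (or any
#'   4-column bedGraph covering one chromosome with equal-width
#'   intervals).
#' @return A [probe_track()].
#' @export
read_probe_track <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "ratio"),
                          colClasses = c("character", "numeric", "numeric",
                                         "numeric"))
  if (length(unique(df$chrom)) != 1L) {
    stop("a probe track covers exactly one chromosome")
  }
  probe_track(df$chrom[1], df$start, df$ratio,
              probe_length = df$end[1] - df$start[1])
}

#' Write peaks as BED6+ (height, FPR, support)
#'
#' Columns: `chrom start end name height strand fpr support`; 0-based
#' half-open.  Missing `fpr`/`support` columns are written as NA/1.
#'
#' @param peaks A peak [GenomicRanges::GRanges] (1-based internally).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  mc <- S4Vectors::mcols(peaks)
  n <- length(peaks)
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(peaks)),
    start = GenomicRanges::start(peaks) - 1L,
    end = GenomicRanges::end(peaks),
    name = sprintf("peak_%05d", seq_len(n)),
    height = if (!is.null(mc$height)) round(mc$height, 4) else NA,
    strand = ".",
    fpr = if (!is.null(mc$fpr)) signif(mc$fpr, 6) else NA,
    support = if (!is.null(mc$support)) mc$support else 1L
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6+ peak file written by [write_peaks()]
#'
#' @param path Input file path.
#' @return A [GenomicRanges::GRanges] with `name`, `height`, `fpr`,
#'   `support` metadata.
#' @export
read_peaks <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "height", "strand", "fpr",
                                        "support"))
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    name = df$name, height = df$height, fpr = df$fpr,
    support = df$support
  )
}

#' Write gene models as BED6 or GFF3
#'
#' @param genes [GenomicRanges::GRanges] with `name` metadata and
#'   strand.
#' @param path Output path.
#' @param format "bed" or "gff3".
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  g <- genes
  if (is.null(S4Vectors::mcols(g)$name)) {
    S4Vectors::mcols(g)$name <- sprintf("gene_%04d", seq_along(g))
  }
  if (format == "bed") {
    S4Vectors::mcols(g)$score <- 0L
    rtracklayer::export(g, path, format = "BED")
  } else {
    S4Vectors::mcols(g)$type <- "gene"
    S4Vectors::mcols(g)$ID <- S4Vectors::mcols(g)$name
    rtracklayer::export(g, path, format = "GFF3")
  }
  invisible(path)
}

#' Read gene models from BED or GFF3
#'
#' @param path Input path; format inferred from the extension.
#' @return A [GenomicRanges::GRanges] with a `name` column.
#' @export
read_gene_models <- function(path) {
  g <- rtracklayer::import(path)
  mc <- S4Vectors::mcols(g)
  nm <- if (!is.null(mc$name)) mc$name
        else if (!is.null(mc$ID)) mc$ID
        else sprintf("gene_%04d", seq_along(g))
  S4Vectors::mcols(g) <- S4Vectors::DataFrame(name = nm)
  g
}

#' Write / read ground-truth sidecar JSON
#'
#' Serialises a simulation's truth (intervals as data frames, numeric
#' vectors as-is) so fractions and probabilities round-trip at full
#' double precision.
#'
#' @param truth A list (GRanges members are converted to data frames).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  enc <- lapply(truth, function(x) {
    if (inherits(x, "GRanges")) {
      data.frame(chrom = as.character(GenomeInfoDb::seqnames(x)),
                 start = GenomicRanges::start(x),
                 end = GenomicRanges::end(x),
                 strand = as.character(GenomicRanges::strand(x)),
                 S4Vectors::mcols(x))
    } else x
  })
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write / read bisulfite call matrices and allelic assay tables
#'
#' Plain CSV round-trips for the two tabular interchange formats: read
#' call matrices (rows = reads, `cpg_*` columns with M/U/NA) and
#' allelic assay tables (`sample, known_fraction, signal_A, signal_B,
#' replicate`).
#'
#' @param x The data.frame to write.
#' @param path File path.
#' @return `path` (writers, invisibly) or a data.frame (readers).
#' @export
write_bisulfite_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bisulfite_csv
#' @export
read_bisulfite_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  df$conversion_rate <- as.numeric(df$conversion_rate)
  df
}

#' @rdname write_bisulfite_csv
#' @export
write_assay_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bisulfite_csv
#' @export
read_assay_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
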