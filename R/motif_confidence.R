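#' Chain overlapping motif reads into clusters
#'
#' Reads overlapping by >= 1 bp chain into clusters (book-ended reads do
#' not join).  Each cluster's depth is the maximum number of mutually
#' overlapping reads — the height of the read stack, computed as the
#' maximum of the per-base coverage inside the cluster.  Optionally only
#' clusters intersecting a set of enriched loci are kept.
#'
#' @param reads [GenomicRanges::GRanges] of mapped motif reads.
#' @param loci Optional [GenomicRanges::GRanges]; when supplied, only
#'   clusters overlapping a locus are returned.
#' @return A [GenomicRanges::GRanges] of clusters with an integer
#'   `depth` metadata column.
#' @export
cluster_reads <- function(reads, loci = NULL) {
  if (length(reads) == 0L) {
    return(GenomicRanges::GRanges(depth = integer(0)))
  }
  clusters <- GenomicRanges::reduce(reads, min.gapwidth = 0L)
  cvg <- GenomicRanges::coverage(reads)
  depth <- integer(length(clusters))
  for (ch in GenomeInfoDb::seqlevels(clusters)) {
    idx <- which(as.character(GenomeInfoDb::seqnames(clusters)) == ch)
    if (length(idx) == 0L) next
    v <- IRanges::Views(cvg[[ch]],
                        IRanges::IRanges(GenomicRanges::start(clusters)[idx],
                                         GenomicRanges::end(clusters)[idx]))
    depth[idx] <- as.integer(IRanges::viewMaxs(v))
  }
  S4Vectors::mcols(clusters)$depth <- depth
  if (!is.null(loci)) {
    clusters <- clusters[IRanges::overlapsAny(clusters, loci)]
  }
  clusters
}

#' Depth spectrum of read clusters with power-law fit
#'
#' Tabulates the exact cluster-depth histogram and fits an unweighted
#' least-squares line to the log10 count versus log10 depth points over
#' depths 1..`threshold` with nonzero counts.  The reported exponent is
#' the negative slope; it is `NA` when fewer than two such depths exist.
#'
#' @param clusters A [GenomicRanges::GRanges] with a `depth` column, or
#'   an integer vector of depths.
#' @param threshold Largest depth included in the fit (default 10).
#' @return A list of class `depth_spectrum`: `counts` (named integer
#'   vector over observed depths), `exponent`, `intercept` (log10
#'   scale), `threshold`, `n_clusters`.
#' @export
depth_spectrum <- function(clusters, threshold = 10L) {
  depths <- if (inherits(clusters, "GRanges")) {
    S4Vectors::mcols(clusters)$depth
  } else {
    as.integer(clusters)
  }
  if (length(depths) == 0L) stop("no clusters supplied")
  stopifnot(threshold >= 1L, all(depths >= 1L))
  tab <- table(depths)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  h <- as.integer(names(tab))
  keep <- h <= threshold & counts > 0L
  if (sum(keep) < 2L) {
    exponent <- NA_real_
    intercept <- NA_real_
  } else {
    fit <- stats::lm(log10(counts[keep]) ~ log10(h[keep]))
    exponent <- -unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
  }
  structure(list(counts = counts, exponent = exponent,
                 intercept = intercept, threshold = as.integer(threshold),
                 n_clusters = length(depths)),
            class = "depth_spectrum")
}

#' @export
print.depth_spectrum <- function(x, ...) {
  cat(sprintf("depth_spectrum: %d clusters, depths %s-%s\n",
              x$n_clusters, names(x$counts)[1],
              names(x$counts)[length(x$counts)]))
  if (is.na(x$exponent)) {
    cat("  power-law fit over depths <=", x$threshold, ": undefined\n")
  } else {
    cat(sprintf("  power-law exponent over depths <= %d: %.3f\n",
                x$threshold, x$exponent))
  }
  invisible(x)
}

#' Partition clusters into confidence classes
#'
#' Clusters with depth strictly greater than the threshold are
#' high-confidence; depth at or below it (including exactly the
#' threshold) is low-confidence, matching the reading of the excess
#' component as heights above the threshold.
#'
#' @param clusters A [GenomicRanges::GRanges] with a `depth` column.
#' @param threshold Depth threshold (default 10).
#' @return The input with a `confidence` metadata column
#'   ("high"/"low"); the high/low counts are attached as the
#'   `"counts"` attribute.
#' @export
partition_confidence <- function(clusters, threshold = 10L) {
  stopifnot(threshold >= 1L)
  depth <- S4Vectors::mcols(clusters)$depth
  if (is.null(depth)) stop("'clusters' must carry a 'depth' column")
  conf <- ifelse(depth > threshold, "high", "low")
  S4Vectors::mcols(clusters)$confidence <- conf
  attr(clusters, "counts") <- c(high = sum(conf == "high"),
                                low = sum(conf == "low"))
  clusters
}
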