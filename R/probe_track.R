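#' Construct a probe track
#'
#' A probe track holds one chromosome's tiling-array probes: ordered probe
#' start coordinates (0-based), a common probe length, and one log2 IP:input
#' ratio per probe.  It is the unit the peak caller operates on, mirroring
#' the per-chromosome treatment of cutoffs and permutations.
#'
#' @param chrom Chromosome identifier (scalar character).
#' @param start Integer vector of probe start coordinates (0-based),
#'   strictly increasing.
#' @param ratio Numeric vector of log2 IP:input ratios, same length as
#'   `start`, all finite.
#' @param probe_length Probe length in bp (default 50).
#'
#' @return An object of class `probe_track`: a list with elements `chrom`,
#'   `start`, `ratio`, `probe_length`.
#' @examples
#' pt <- probe_track("chr1", seq(0, 900, by = 100), rnorm(10))
#' pt
#' @export
probe_track <- function(chrom, start, ratio, probe_length = 50L) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  start <- as.numeric(start)
  ratio <- as.numeric(ratio)
  if (length(start) < 1L) {
    stop("a probe track needs at least one probe")
  }
  if (length(start) != length(ratio)) {
    stop("'start' and 'ratio' must have equal length")
  }
  if (any(diff(start) <= 0)) {
    stop("probe start coordinates must be strictly increasing")
  }
  if (!all(is.finite(ratio))) {
    stop("all log2 ratios must be finite")
  }
  if (probe_length <= 0) {
    stop("'probe_length' must be positive")
  }
  structure(
    list(chrom = chrom, start = start, ratio = ratio,
         probe_length = as.integer(probe_length)),
    class = "probe_track"
  )
}

#' @export
print.probe_track <- function(x, ...) {
  cat(sprintf("probe_track: %s, %d probes of %d bp, span %d-%d\n",
              x$chrom, length(x$start), x$probe_length,
              min(x$start), max(x$start) + x$probe_length))
  cat(sprintf("  log2 ratio: mean %.3f, sd %.3f, max %.3f\n",
              mean(x$ratio),
              if (length(x$ratio) > 1) stats::sd(x$ratio) else NA_real_,
              max(x$ratio)))
  invisible(x)
}

#' @export
length.probe_track <- function(x) length(x$start)

#' Convert a probe track to a GRanges
#'
#' @param track A [probe_track()].
#' @return A [GenomicRanges::GRanges] (1-based) with a `ratio` metadata
#'   column.
#' @export
track_as_granges <- function(track) {
  stopifnot(inherits(track, "probe_track"))
  GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(start = track$start + 1L,
                              width = track$probe_length),
    ratio = track$ratio
  )
}
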