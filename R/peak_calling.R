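#' Per-chromosome enrichment cutoff
#'
#' The threshold applied to probe log2 ratios is a percentage `P` of the
#' chromosome-wide value `mean + 6 * SD` of all probe ratios, recomputed
#' per chromosome (and per replicate).  SD is the sample standard
#' deviation (n - 1 denominator).
#'
#' @param track A [probe_track()].
#' @param p Cutoff percentage in (0, 100].
#' @return Threshold in log2 units.
#' @examples
#' pt <- probe_track("chr1", seq(0, 500, 100), c(0, 0, 0, 0, 2, 2))
#' compute_cutoff(pt, 50)
#' @export
compute_cutoff <- function(track, p) {
  stopifnot(inherits(track, "probe_track"))
  if (!(p > 0 && p <= 100)) stop("'p' must be in (0, 100]")
  if (length(track$ratio) < 2L) {
    stop("insufficient probes: standard deviation undefined")
  }
  (p / 100) * (mean(track$ratio) + 6 * stats::sd(track$ratio))
}

# Vectorized core of the window rule.  A probe seeds a detection when the
# closed window [start - flank, start + flank] contains >= min_probes
# probe starts whose ratio exceeds the threshold.  Qualifying seed
# windows that overlap or are book-ended are merged; each merged region
# yields one peak spanning its above-threshold probes.
# Returns a data.frame(start, end, height, n_above) in 0-based
# half-open coordinates, or a zero-row frame.
.peak_intervals <- function(start, ratio, probe_length, threshold,
                            min_probes, flank) {
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      height = numeric(0), n_above = integer(0))
  above <- ratio > threshold
  if (!any(above)) return(empty)
  cs <- cumsum(above)
  hi <- findInterval(start + flank, start)
  lo <- findInterval(start - flank - 0.5, start) + 1L
  cnt <- cs[hi] - ifelse(lo > 1L, cs[pmax(lo - 1L, 1L)], 0L)
  seeds <- which(cnt >= min_probes)
  if (length(seeds) == 0L) return(empty)
  ss <- start[seeds]
  # closed integer windows [s - flank, s + flank] overlap or touch when
  # consecutive seed starts differ by at most 2 * flank + 1
  grp <- cumsum(c(TRUE, diff(ss) > 2 * flank + 1))
  first <- tapply(ss, grp, min)
  last <- tapply(ss, grp, max)
  out <- lapply(seq_along(first), function(g) {
    wlo <- first[[g]] - flank
    whi <- last[[g]] + flank
    i1 <- findInterval(wlo - 0.5, start) + 1L
    i2 <- findInterval(whi, start)
    idx <- seq.int(i1, i2)
    idx <- idx[above[idx]]
    if (length(idx) == 0L) return(NULL)
    c(min(start[idx]), max(start[idx]) + probe_length,
      max(ratio[idx]), length(idx))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  data.frame(start = out[, 1], end = out[, 2], height = out[, 3],
             n_above = as.integer(out[, 4]))
}

# peak count only (hot path for permutations)
.peak_count <- function(start, ratio, probe_length, threshold,
                        min_probes, flank) {
  nrow(.peak_intervals(start, ratio, probe_length, threshold,
                       min_probes, flank))
}

#' Detect enriched peaks on a probe track
#'
#' A probe seeds a possible binding site when, among the probe itself and
#' its flanking probes within a window covering `flank` bp on both sides,
#' at least `min_probes` probes have log2 ratio above `threshold`.
#' Overlapping or book-ended qualifying windows are merged into one peak
#' spanning their above-threshold probes; peak height is the maximum
#' ratio inside.  Window membership is judged on probe start coordinates
#' and the window is closed at both ends.
#'
#' @param track A [probe_track()].
#' @param threshold Log2-ratio cutoff (see [compute_cutoff()]).
#' @param min_probes Minimum above-threshold probes per window (default 4).
#' @param flank Window half-width in bp (default 250).
#' @return A [GenomicRanges::GRanges] (1-based) with metadata columns
#'   `height` (max probe ratio) and `n_above`.  Empty when nothing
#'   qualifies.
#' @export
detect_peaks <- function(track, threshold, min_probes = 4L, flank = 250L) {
  stopifnot(inherits(track, "probe_track"), is.finite(threshold))
  pk <- .peak_intervals(track$start, track$ratio, track$probe_length,
                        threshold, min_probes, flank)
  GenomicRanges::GRanges(
    seqnames = rep(track$chrom, nrow(pk)),
    ranges = IRanges::IRanges(start = pk$start + 1, end = pk$end),
    height = pk$height,
    n_above = pk$n_above
  )
}

#' Scramble probe ratios to build a null track
#'
#' Coordinates are untouched; the multiset of log2 ratios is preserved
#' exactly and reassigned to probes in uniformly random order.  This is
#' the randomization behind the permutation false-positive rate.
#'
#' @param track A [probe_track()].
#' @param seed Optional integer seed for reproducibility.
#' @return A new [probe_track()] with permuted ratios.
#' @export
permute_track <- function(track, seed = NULL) {
  stopifnot(inherits(track, "probe_track"))
  if (!is.null(seed)) set.seed(seed)
  # index-based shuffle: sample(x) on a length-1 numeric would resample 1:x
  perm <- sample.int(length(track$ratio))
  probe_track(track$chrom, track$start, track$ratio[perm],
              track$probe_length)
}

#' Permutation plan
#'
#' Number of randomized data sets built per chromosome (default 20) and
#' the master seed from which per-chromosome sub-seeds are derived.
#'
#' @param n_permutations Randomized data sets per chromosome.
#' @param seed Master integer seed.
#' @return A list of class `permutation_plan`.
#' @export
permutation_plan <- function(n_permutations = 20L, seed = 1L) {
  stopifnot(n_permutations >= 1L)
  structure(list(n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "permutation_plan")
}

# deterministic sub-seed per chromosome, kept inside 32-bit range
.chrom_subseed <- function(seed, chrom) {
  h <- sum(utf8ToInt(chrom) * seq_along(utf8ToInt(chrom)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483587)
}

#' Cutoff-percentage schedule
#'
#' Descending sweep of cutoff percentages, most stringent first.  The
#' default spans 100% down to 20% in steps of 5.
#'
#' @param from,to,by Sweep bounds and step (percent).
#' @return Numeric vector of percentages, strictly descending.
#' @export
cutoff_schedule <- function(from = 100, to = 20, by = 5) {
  p <- seq(from, to, by = -abs(by))
  if (any(p <= 0) || any(p > 100) || any(diff(p) >= 0)) {
    stop("schedule percentages must be strictly descending in (0, 100]")
  }
  p
}

#' Estimate the false-positive rate at one cutoff
#'
#' The FPR at cutoff percentage `p` is the mean peak count over the
#' plan's ratio-scrambled tracks, divided by the peak count on the
#' observed track, both at the same threshold.  A zero observed count
#' yields `NA` (undefined), never a division error.  The ratio is not
#' capped at 1.
#'
#' @param track A [probe_track()].
#' @param p Cutoff percentage.
#' @param plan A [permutation_plan()].
#' @param min_probes,flank Window rule parameters, as in [detect_peaks()].
#' @return A single numeric FPR, or `NA_real_` when no peak is observed.
#' @export
estimate_fpr <- function(track, p, plan = permutation_plan(),
                         min_probes = 4L, flank = 250L) {
  stopifnot(inherits(track, "probe_track"),
            inherits(plan, "permutation_plan"))
  thr <- compute_cutoff(track, p)
  obs <- .peak_count(track$start, track$ratio, track$probe_length, thr,
                     min_probes, flank)
  set.seed(.chrom_subseed(plan$seed, track$chrom))
  perm <- vapply(seq_len(plan$n_permutations), function(i) {
    r <- sample(track$ratio)
    .peak_count(track$start, r, track$probe_length, thr, min_probes, flank)
  }, numeric(1))
  if (obs == 0L) return(NA_real_)
  mean(perm) / obs
}

#' Sweep cutoffs and assign each peak its first-detection FPR
#'
#' Runs the detector over a descending cutoff schedule.  One set of
#' permuted ratio vectors is generated per chromosome (sub-seeded from
#' the plan's master seed) and reused at every cutoff, giving a per-level
#' FPR = mean permuted peak count / observed peak count.  Each peak in
#' the final (least stringent) peak set is assigned the FPR of the most
#' stringent cutoff at which a peak overlapping it is detected — its
#' first detection, since lowering the cutoff only widens and adds
#' peaks.
#'
#' @param track A [probe_track()].
#' @param schedule Percentages from [cutoff_schedule()], descending.
#' @param plan A [permutation_plan()].
#' @param min_probes,flank Window rule parameters.
#' @return A [GenomicRanges::GRanges] of peaks with metadata columns
#'   `height`, `first_p` (cutoff percentage of first detection) and
#'   `fpr`.
#' @export
assign_peak_fpr <- function(track, schedule = cutoff_schedule(),
                            plan = permutation_plan(),
                            min_probes = 4L, flank = 250L) {
  stopifnot(inherits(track, "probe_track"),
            inherits(plan, "permutation_plan"))
  if (any(diff(schedule) >= 0)) stop("schedule must be strictly descending")
  thresholds <- vapply(schedule, function(p) compute_cutoff(track, p),
                       numeric(1))
  set.seed(.chrom_subseed(plan$seed, track$chrom))
  perms <- replicate(plan$n_permutations, sample(track$ratio),
                     simplify = FALSE)

  levels <- lapply(seq_along(schedule), function(i) {
    pk <- .peak_intervals(track$start, track$ratio, track$probe_length,
                          thresholds[i], min_probes, flank)
    perm_counts <- vapply(perms, function(r) {
      .peak_count(track$start, r, track$probe_length, thresholds[i],
                  min_probes, flank)
    }, numeric(1))
    fpr <- if (nrow(pk) == 0L) NA_real_ else mean(perm_counts) / nrow(pk)
    list(peaks = pk, fpr = fpr)
  })

  final <- levels[[length(levels)]]$peaks
  n <- nrow(final)
  if (n == 0L) {
    return(GenomicRanges::GRanges(height = numeric(0),
                                  first_p = numeric(0),
                                  fpr = numeric(0)))
  }
  first_idx <- rep(NA_integer_, n)
  assigned <- rep(FALSE, n)
  for (i in seq_along(levels)) {       # most stringent first
    pk <- levels[[i]]$peaks
    if (nrow(pk) == 0L) next
    todo <- which(!assigned)
    if (length(todo) == 0L) break
    ov <- IRanges::overlapsAny(
      IRanges::IRanges(final$start[todo] + 1, final$end[todo]),
      IRanges::IRanges(pk$start + 1, pk$end)
    )
    first_idx[todo[ov]] <- i
    assigned[todo[ov]] <- TRUE
  }
  GenomicRanges::GRanges(
    seqnames = rep(track$chrom, n),
    ranges = IRanges::IRanges(start = final$start + 1, end = final$end),
    height = final$height,
    first_p = schedule[first_idx],
    fpr = vapply(first_idx, function(i) levels[[i]]$fpr, numeric(1))
  )
}

#' Three-replicate consensus filter
#'
#' High-confidence peaks must be present in all required biological
#' replicates and carry a first-detection FPR below `max_fpr`.  Peaks
#' failing the FPR cut are removed per replicate first; a consensus
#' interval is then emitted wherever peaks from at least
#' `required_support` replicates mutually overlap by >= 1 bp (for
#' intervals on a line, pairwise overlap implies a common intersection).
#' The consensus interval is the region covered by all contributors; its
#' height is the mean of the contributing peaks' heights and its FPR the
#' maximum among contributors.
#'
#' @param peak_sets List of per-replicate peak [GenomicRanges::GRanges]
#'   with `fpr` and `height` metadata (as from [assign_peak_fpr()]).
#' @param required_support Number of replicates a peak must appear in
#'   (default 3).
#' @param max_fpr FPR cutoff, exclusive (default 0.05).
#' @return A [GenomicRanges::GRanges] of consensus peaks with `height`,
#'   `fpr` (max over contributors) and `support` metadata.
#' @export
intersect_replicates <- function(peak_sets, required_support = 3L,
                                 max_fpr = 0.05) {
  if (length(peak_sets) < required_support) {
    stop("fewer replicate peak sets than 'required_support'")
  }
  keep <- lapply(peak_sets, function(g) {
    f <- S4Vectors::mcols(g)$fpr
    g[!is.na(f) & f < max_fpr]
  })
  all_levels <- unique(unlist(lapply(keep, GenomeInfoDb::seqlevels)))
  if (length(all_levels) == 0L || all(vapply(keep, length, 1L) == 0L)) {
    return(GenomicRanges::GRanges(height = numeric(0), fpr = numeric(0),
                                  support = integer(0)))
  }
  keep <- lapply(keep, function(g) {
    GenomeInfoDb::seqlevels(g) <- all_levels
    g
  })
  width_by_chr <- vapply(all_levels, function(ch) {
    m <- unlist(lapply(keep, function(g) {
      gg <- g[GenomeInfoDb::seqnames(g) == ch]
      if (length(gg) == 0L) 0L else max(GenomicRanges::end(gg))
    }))
    max(m) + 1L
  }, numeric(1))
  cvg <- Reduce(`+`, lapply(keep, function(g) {
    GenomicRanges::coverage(GenomicRanges::reduce(g), width = width_by_chr)
  }))
  sl <- IRanges::slice(cvg, lower = required_support, rangesOnly = TRUE)
  cons <- GenomicRanges::GRanges(sl)
  if (length(cons) == 0L) {
    return(GenomicRanges::GRanges(height = numeric(0), fpr = numeric(0),
                                  support = integer(0)))
  }
  contrib <- lapply(keep, function(g) {
    GenomicRanges::findOverlaps(cons, g)
  })
  height <- numeric(length(cons))
  fpr <- numeric(length(cons))
  support <- integer(length(cons))
  for (i in seq_along(cons)) {
    hs <- numeric(0); fs <- numeric(0); nrep <- 0L
    for (r in seq_along(keep)) {
      j <- S4Vectors::subjectHits(contrib[[r]])[
        S4Vectors::queryHits(contrib[[r]]) == i]
      if (length(j) > 0L) {
        nrep <- nrep + 1L
        hs <- c(hs, S4Vectors::mcols(keep[[r]])$height[j])
        fs <- c(fs, S4Vectors::mcols(keep[[r]])$fpr[j])
      }
    }
    height[i] <- mean(hs)
    fpr[i] <- max(fs)
    support[i] <- nrep
  }
  S4Vectors::mcols(cons) <- S4Vectors::DataFrame(height = height,
                                                 fpr = fpr,
                                                 support = support)
  cons
}

#' Full peak-calling chain on a simulated or loaded experiment
#'
#' Convenience wrapper: for every replicate and chromosome, sweeps the
#' cutoff schedule with [assign_peak_fpr()], pools chromosomes per
#' replicate, and applies the consensus filter.
#'
#' @param tracks A list of replicates, each a list of [probe_track()]
#'   objects (one per chromosome), as returned in
#'   `simulate_tiling_experiment()$tracks`.
#' @param schedule,plan,min_probes,flank See [assign_peak_fpr()].
#' @param required_support,max_fpr See [intersect_replicates()].
#' @return A list with `replicate_peaks` (list of GRanges) and
#'   `consensus` (GRanges).
#' @export
call_consensus_peaks <- function(tracks, schedule = cutoff_schedule(),
                                 plan = permutation_plan(),
                                 min_probes = 4L, flank = 250L,
                                 required_support = length(tracks),
                                 max_fpr = 0.05) {
  all_chroms <- unique(unlist(lapply(tracks, names)))
  rep_peaks <- lapply(tracks, function(chroms) {
    per_chrom <- lapply(chroms, assign_peak_fpr, schedule = schedule,
                        plan = plan, min_probes = min_probes,
                        flank = flank)
    per_chrom <- lapply(per_chrom, function(g) {
      GenomeInfoDb::seqlevels(g) <- all_chroms
      g
    })
    do.call(c, unname(per_chrom))
  })
  list(replicate_peaks = rep_peaks,
       consensus = intersect_replicates(rep_peaks,
                                        required_support = required_support,
                                        max_fpr = max_fpr))
}
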