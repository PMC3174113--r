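# Independent brute-force oracles, written as plain loops so they share
# no code path with the package implementations they check.

# Windowed peak detection by exhaustive enumeration of every probe's
# closed +/- flank window.  Returns data.frame(start, end, height) in
# 0-based half-open coordinates.
oracle_detect_peaks <- function(start, ratio, probe_length, threshold,
                                min_probes = 4, flank = 250) {
  n <- length(start)
  seed_ok <- logical(n)
  for (i in seq_len(n)) {
    cnt <- 0
    for (j in seq_len(n)) {
      if (start[j] >= start[i] - flank && start[j] <= start[i] + flank &&
          ratio[j] > threshold) {
        cnt <- cnt + 1
      }
    }
    seed_ok[i] <- cnt >= min_probes
  }
  seeds <- which(seed_ok)
  if (length(seeds) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      height = numeric(0)))
  }
  # merge overlapping/book-ended closed windows [s - flank, s + flank]
  win_lo <- start[seeds] - flank
  win_hi <- start[seeds] + flank
  merged <- list()
  cur_lo <- win_lo[1]; cur_hi <- win_hi[1]
  for (k in seq_along(seeds)[-1]) {
    if (win_lo[k] <= cur_hi + 1) {
      cur_hi <- max(cur_hi, win_hi[k])
    } else {
      merged[[length(merged) + 1]] <- c(cur_lo, cur_hi)
      cur_lo <- win_lo[k]; cur_hi <- win_hi[k]
    }
  }
  merged[[length(merged) + 1]] <- c(cur_lo, cur_hi)
  out <- list()
  for (m in merged) {
    idx <- which(start >= m[1] & start <= m[2] & ratio > threshold)
    if (length(idx) == 0) next
    out[[length(out) + 1]] <- data.frame(
      start = min(start[idx]),
      end = max(start[idx]) + probe_length,
      height = max(ratio[idx]))
  }
  do.call(rbind, out)
}

# Greedy nearest-first one-to-one matching by repeated scan of the full
# distance matrix (midpoint metric, strict max_distance).
oracle_colocalize <- function(mid_a, mid_b, max_distance = 500) {
  d <- abs(outer(mid_a, mid_b, "-"))
  pairs <- list()
  repeat {
    if (all(!is.finite(d)) || min(d, na.rm = TRUE) >= max_distance) break
    k <- which(d == min(d), arr.ind = TRUE)
    k <- k[order(k[, 1], k[, 2]), , drop = FALSE][1, ]
    pairs[[length(pairs) + 1]] <- c(a = k[1], b = k[2],
                                    dist = d[k[1], k[2]])
    d[k[1], ] <- Inf
    d[, k[2]] <- Inf
  }
  if (length(pairs) == 0) {
    return(data.frame(a = integer(0), b = integer(0), dist = numeric(0)))
  }
  as.data.frame(do.call(rbind, pairs))
}

# Cluster depths from an explicit per-base coverage array (1-based
# closed read intervals on one chromosome).  Clusters chain reads that
# overlap by >= 1 bp (book-ended reads stay separate); each cluster's
# depth is the maximum of the coverage function inside it.
oracle_cluster_depths <- function(read_start, read_end) {
  L <- max(read_end)
  cov <- integer(L)
  for (i in seq_along(read_start)) {
    idx <- read_start[i]:read_end[i]
    cov[idx] <- cov[idx] + 1L
  }
  o <- order(read_start, read_end)
  rs <- read_start[o]
  re <- read_end[o]
  starts <- integer(0)
  ends <- integer(0)
  cur_s <- rs[1]
  cur_e <- re[1]
  for (i in seq_along(rs)[-1]) {
    if (rs[i] <= cur_e) {               # strict overlap in closed coords
      cur_e <- max(cur_e, re[i])
    } else {
      starts <- c(starts, cur_s)
      ends <- c(ends, cur_e)
      cur_s <- rs[i]
      cur_e <- re[i]
    }
  }
  starts <- c(starts, cur_s)
  ends <- c(ends, cur_e)
  depths <- integer(length(starts))
  for (k in seq_along(starts)) {
    depths[k] <- max(cov[starts[k]:ends[k]])
  }
  data.frame(start = starts, depth = depths)
}

# Nearest-feature context classification by per-gene linear scan.
oracle_classify <- function(pos, g_start, g_end, g_strand,
                            promoter_up = 2000, promoter_down = 500) {
  tss <- ifelse(g_strand == "-", g_end, g_start)
  in_prom <- FALSE
  in_body <- FALSE
  for (j in seq_along(g_start)) {
    lo <- if (g_strand[j] == "-") tss[j] - promoter_down else
      tss[j] - promoter_up
    hi <- if (g_strand[j] == "-") tss[j] + promoter_up else
      tss[j] + promoter_down
    if (pos >= lo && pos <= hi) in_prom <- TRUE
    if (pos >= g_start[j] && pos <= g_end[j]) in_body <- TRUE
  }
  if (in_prom) "promoter" else if (in_body) "intragenic" else "intergenic"
}

# Small random probe track for property tests.
random_track <- function(n, seed, spacing = 100, sd = 1,
                         chrom = "chrT") {
  set.seed(seed)
  probe_track(chrom, (seq_len(n) - 1) * spacing, rnorm(n, 0, sd))
}
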