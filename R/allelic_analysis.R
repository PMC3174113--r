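#' Score per-CpG methylation from bisulfite read calls
#'
#' Reads whose non-CpG cytosine conversion rate falls below
#' `min_conversion` are discarded as incompletely converted; the
#' per-site methylation fraction is then M / (M + U) over the retained
#' reads.  Sites with no retained informative call get `NA`.
#'
#' @param calls A data.frame or matrix of read calls: rows are reads,
#'   `cpg_*` columns hold "M", "U" or NA.  A `conversion_rate` column,
#'   if present, supplies the per-read QC statistic; alternatively pass
#'   `conversion_rates`.
#' @param conversion_rates Optional numeric vector, one per read.
#' @param min_conversion Minimum conversion rate to retain a read
#'   (default 0.9).
#' @return A data.frame of class `methylation_profile`: `site` (column
#'   label), `fraction` in \[0, 1\] or NA, `depth` (informative reads).
#' @examples
#' m <- simulate_bisulfite_reads(50, c(a = 1, b = 0.5), seed = 3)
#' score_methylation(m)
#' @export
score_methylation <- function(calls, conversion_rates = NULL,
                              min_conversion = 0.9) {
  calls <- as.data.frame(calls, stringsAsFactors = FALSE)
  if (nrow(calls) == 0L) stop("empty call matrix")
  if (is.null(conversion_rates) && "conversion_rate" %in% names(calls)) {
    conversion_rates <- calls$conversion_rate
  }
  site_cols <- setdiff(names(calls), c("read_id", "conversion_rate"))
  if (length(site_cols) == 0L) stop("no CpG site columns found")
  bad <- unlist(calls[site_cols])
  bad <- bad[!is.na(bad)]
  if (length(bad) && !all(bad %in% c("M", "U"))) {
    stop("calls must be 'M', 'U' or NA")
  }
  keep <- rep(TRUE, nrow(calls))
  if (!is.null(conversion_rates)) {
    stopifnot(length(conversion_rates) == nrow(calls))
    keep <- conversion_rates >= min_conversion
  }
  retained <- calls[keep, site_cols, drop = FALSE]
  frac <- vapply(site_cols, function(s) {
    x <- retained[[s]]
    m <- sum(x == "M", na.rm = TRUE)
    u <- sum(x == "U", na.rm = TRUE)
    if (m + u == 0L) NA_real_ else m / (m + u)
  }, numeric(1))
  depth <- vapply(site_cols, function(s) {
    sum(!is.na(retained[[s]]))
  }, integer(1))
  out <- data.frame(site = site_cols, fraction = unname(frac),
                    depth = unname(depth), stringsAsFactors = FALSE)
  class(out) <- c("methylation_profile", "data.frame")
  out
}

#' Fit allelic-mixture calibration curves
#'
#' Ordinary least squares of each channel's signal against the known
#' allele-A mixture fraction.  Requires at least three distinct
#' fractions with nonzero variance.  A constant signal yields slope 0
#' with R-squared defined as 0.
#'
#' @param assay A data.frame with `known_fraction`, `signal_A`,
#'   `signal_B` (as from [simulate_allelic_mixtures()]).
#' @return A list of class `calibration_curves` with elements `A` and
#'   `B`, each a list `slope`, `intercept`, `r_squared`, plus
#'   `fraction_range`.
#' @export
fit_calibration <- function(assay) {
  needed <- c("known_fraction", "signal_A", "signal_B")
  if (!all(needed %in% names(assay))) {
    stop("assay table must contain: ", paste(needed, collapse = ", "))
  }
  f <- assay$known_fraction
  if (length(unique(f)) < 3L) {
    stop("need at least 3 distinct mixture fractions")
  }
  if (stats::var(f) == 0) stop("mixture fractions have zero variance")
  fit_one <- function(y) {
    fit <- stats::lm(y ~ f)
    # noiseless data fits exactly; the lm summary warning is expected
    r2 <- if (stats::var(y) == 0) 0 else
      suppressWarnings(summary(fit)$r.squared)
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2)
  }
  structure(list(A = fit_one(assay$signal_A),
                 B = fit_one(assay$signal_B),
                 fraction_range = range(f)),
            class = "calibration_curves")
}

#' @export
print.calibration_curves <- function(x, ...) {
  for (ch in c("A", "B")) {
    cat(sprintf("channel %s: y = %.4f x + %.4f   (R^2 = %.5f)\n",
                ch, x[[ch]]$slope, x[[ch]]$intercept, x[[ch]]$r_squared))
  }
  invisible(x)
}

#' Estimate the allele-A fraction from two-channel signals
#'
#' Inverts each channel's calibration line, averages the two per-channel
#' estimates, and clamps to \[0, 1\].  A channel with near-zero slope is
#' excluded with a warning; with no usable channel an error is raised.
#'
#' @param signal_a,signal_b Numeric signal vectors (same length).
#' @param curves A `calibration_curves` object from [fit_calibration()].
#' @param slope_tol Minimum absolute slope for a channel to be used.
#' @return Numeric vector of estimated allele-A fractions in \[0, 1\].
#' @export
estimate_allelic_fraction <- function(signal_a, signal_b, curves,
                                      slope_tol = 1e-8) {
  stopifnot(inherits(curves, "calibration_curves"),
            length(signal_a) == length(signal_b))
  est <- list()
  for (ch in c("A", "B")) {
    sig <- if (ch == "A") signal_a else signal_b
    cv <- curves[[ch]]
    if (abs(cv$slope) < slope_tol) {
      warning("channel ", ch, " has a near-zero slope; excluded")
      next
    }
    est[[ch]] <- (sig - cv$intercept) / cv$slope
  }
  if (length(est) == 0L) stop("no channel with a usable slope")
  pmin(pmax(Reduce(`+`, est) / length(est), 0), 1)
}

#' Classify genotype clusters by nearest control centroid
#'
#' Two-channel endpoint signals are assigned to the nearest centroid
#' among the control groups (typically AA, AB, BB and a no-template
#' control).  A point whose second-nearest centroid is less than
#' `margin` times farther than its nearest is labelled "undetermined".
#'
#' @param points A data.frame/matrix with columns `signal_A`,
#'   `signal_B` (one row per sample).
#' @param controls A data.frame with `label`, `signal_A`, `signal_B`;
#'   centroids are the per-label means.
#' @param margin Ambiguity ratio (second-nearest / nearest distance
#'   below this is undetermined; default 1.05).
#' @return Character vector of labels.
#' @export
classify_genotypes <- function(points, controls, margin = 1.05) {
  if (missing(controls) || is.null(controls) || nrow(controls) == 0L) {
    stop("control samples (or centroid table) are required")
  }
  pts <- as.data.frame(points)
  stopifnot(all(c("signal_A", "signal_B") %in% names(pts)),
            all(c("label", "signal_A", "signal_B") %in% names(controls)))
  cen <- stats::aggregate(controls[c("signal_A", "signal_B")],
                          by = list(label = controls$label), FUN = mean)
  d <- vapply(seq_len(nrow(cen)), function(k) {
    sqrt((pts$signal_A - cen$signal_A[k])^2 +
         (pts$signal_B - cen$signal_B[k])^2)
  }, numeric(nrow(pts)))
  d <- matrix(d, nrow = nrow(pts))
  out <- vapply(seq_len(nrow(pts)), function(i) {
    o <- order(d[i, ])
    if (nrow(cen) > 1L) {
      d1 <- d[i, o[1]]; d2 <- d[i, o[2]]
      if (d1 > 0 && d2 / d1 < margin) return("undetermined")
    }
    as.character(cen$label[o[1]])
  }, character(1))
  out
}

#' Call mono- versus biallelic expression
#'
#' A homozygous genomic genotype is uninformative: with one allele in the
#' genome, allele-specific expression cannot be defined.  For
#' heterozygous samples, the cDNA minor-allele fraction below
#' `minor_cut` is called monoallelic, otherwise biallelic.  The default
#' cut of 1/6 corresponds to a 1:5 allelic ratio, the smallest imbalance
#' the calibration assay is demonstrated to resolve.
#'
#' @param genotype Character vector of gDNA genotypes ("AA", "AB",
#'   "BB").
#' @param cdna_fraction Numeric vector of cDNA allele-A fractions in
#'   \[0, 1\].
#' @param minor_cut Minor-allele-fraction threshold (default 1/6,
#'   exclusive).
#' @return A data.frame with `genotype`, `minor_fraction` (NA for
#'   homozygotes) and `verdict` ("monoallelic"/"biallelic"/
#'   "uninformative").
#' @export
call_monoallelic <- function(genotype, cdna_fraction, minor_cut = 1 / 6) {
  stopifnot(length(genotype) == length(cdna_fraction),
            all(genotype %in% c("AA", "AB", "BB")),
            all(is.na(cdna_fraction) |
                  (cdna_fraction >= 0 & cdna_fraction <= 1)))
  het <- genotype == "AB"
  minor <- ifelse(het, pmin(cdna_fraction, 1 - cdna_fraction), NA_real_)
  verdict <- ifelse(!het, "uninformative",
                    ifelse(minor < minor_cut, "monoallelic", "biallelic"))
  data.frame(genotype = genotype, minor_fraction = minor,
             verdict = verdict, stringsAsFactors = FALSE)
}
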