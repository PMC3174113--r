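test_that("score_methylation computes per-site M fractions", {
  calls <- data.frame(read_id = paste0("r", 1:4),
                      cpg_100 = c("M", "M", "M", "U"),
                      cpg_150 = c("M", "M", "M", "M"),
                      stringsAsFactors = FALSE)
  prof <- score_methylation(calls)
  expect_equal(prof$fraction[prof$site == "cpg_100"], 0.75)
  expect_equal(prof$fraction[prof$site == "cpg_150"], 1.0)
  expect_equal(prof$depth, c(4L, 4L))
})

test_that("score_methylation filters poorly converted reads and handles NA", {
  calls <- data.frame(read_id = paste0("r", 1:4),
                      conversion_rate = c(1, 1, 0.5, 0.5),
                      cpg_1 = c("U", "U", "M", "M"),
                      cpg_2 = c(NA, NA, NA, NA),
                      stringsAsFactors = FALSE)
  prof <- score_methylation(calls, min_conversion = 0.9)
  # the two badly converted reads (which carried the M calls) are dropped
  expect_equal(prof$fraction[prof$site == "cpg_1"], 0)
  expect_equal(prof$depth[prof$site == "cpg_1"], 2L)
  # NA-only site never produces a number
  expect_true(is.na(prof$fraction[prof$site == "cpg_2"]))
  expect_equal(prof$depth[prof$site == "cpg_2"], 0L)

  expect_error(score_methylation(calls[0, ]), "empty")
  bad <- data.frame(cpg_1 = c("M", "X"))
  expect_error(score_methylation(bad), "must be")
})

test_that("simulated methylation fractions land within binomial bounds", {
  m <- simulate_bisulfite_reads(1000, c(s = 0.3),
                                conversion_failure_rate = 0, seed = 21)
  prof <- score_methylation(m)
  expect_lt(abs(prof$fraction - 0.3), 0.05)
})

test_that("fit_calibration is exact on noiseless linear data", {
  ax <- simulate_allelic_mixtures(noise_sd = 0, seed = 1)
  cv <- fit_calibration(ax)
  expect_equal(cv$A$slope, 1.02, tolerance = 1e-10)
  expect_equal(cv$A$intercept, 0.0415, tolerance = 1e-10)
  expect_equal(cv$A$r_squared, 1)
  expect_equal(cv$B$slope, -0.85, tolerance = 1e-10)
  expect_equal(cv$B$r_squared, 1)
})

test_that("fit_calibration handles degenerate inputs per contract", {
  # constant signal: slope 0, R^2 defined as 0
  ax <- data.frame(known_fraction = c(0, 0.5, 1),
                   signal_A = c(2, 2, 2), signal_B = c(1, 2, 3))
  cv <- fit_calibration(ax)
  expect_equal(cv$A$slope, 0)
  expect_equal(cv$A$r_squared, 0)

  too_few <- data.frame(known_fraction = c(0, 1),
                        signal_A = 1:2, signal_B = 2:1)
  expect_error(fit_calibration(too_few), "3 distinct")
  expect_error(fit_calibration(data.frame(known_fraction = 1)),
               "must contain")
})

test_that("calibration parameters are recovered from noisy mixtures", {
  ax <- simulate_allelic_mixtures(slope_a = 1.02, intercept_a = 0.0415,
                                  noise_sd = 0.02, replicates = 5,
                                  seed = 33)
  cv <- fit_calibration(ax)
  expect_lt(abs(cv$A$slope - 1.02), 0.05)
  expect_lt(abs(cv$A$intercept - 0.0415), 0.03)
  expect_gt(cv$A$r_squared, 0.95)
})

test_that("estimate_allelic_fraction inverts the calibration lines", {
  ax <- simulate_allelic_mixtures(noise_sd = 0, seed = 1)
  cv <- fit_calibration(ax)
  # signal at the intercept maps to fraction 0; slope + intercept to 1
  expect_equal(estimate_allelic_fraction(0.0415, 0.9796, cv), 0)
  expect_equal(estimate_allelic_fraction(0.0415 + 1.02, 0.9796 - 0.85, cv),
               1)
  # noiseless round trip is exact across the whole range
  for (f in seq(0, 1, 0.125)) {
    est <- estimate_allelic_fraction(0.0415 + 1.02 * f,
                                     0.9796 - 0.85 * f, cv)
    expect_equal(est, f, tolerance = 1e-10)
  }
  # estimates are clamped to [0, 1]
  expect_equal(estimate_allelic_fraction(-1, 2, cv), 0)
})

test_that("a flat channel is excluded with a warning", {
  ax <- data.frame(known_fraction = rep(c(0, 0.5, 1), each = 2),
                   signal_A = rep(c(0, 0.5, 1), each = 2),
                   signal_B = rep(2, 6))
  cv <- fit_calibration(ax)
  expect_warning(est <- estimate_allelic_fraction(0.5, 2, cv),
                 "near-zero slope")
  expect_equal(est, 0.5)
  # both channels flat: no usable inversion
  ax$signal_A <- 1
  cv2 <- fit_calibration(ax)
  expect_error(suppressWarnings(estimate_allelic_fraction(1, 2, cv2)),
               "no channel")
})

test_that("classify_genotypes assigns nearest control centroid", {
  controls <- data.frame(
    label = rep(c("AA", "AB", "BB", "NTC"), each = 2),
    signal_A = c(1, 1.1, 0.5, 0.55, 0.05, 0.08, 0, 0.01),
    signal_B = c(0.05, 0.08, 0.5, 0.55, 1, 1.1, 0, 0.01))
  cen_aa <- c(mean(c(1, 1.1)), mean(c(0.05, 0.08)))
  pts <- data.frame(signal_A = c(cen_aa[1], 0), signal_B = c(cen_aa[2], 0))
  lab <- classify_genotypes(pts, controls)
  expect_equal(lab, c("AA", "NTC"))
  expect_error(classify_genotypes(pts, NULL), "required")
  # equidistant point between two centroids is undetermined
  mid_ab_bb <- c((0.525 + 0.065) / 2, (0.525 + 1.05) / 2)
  lab <- classify_genotypes(data.frame(signal_A = mid_ab_bb[1],
                                       signal_B = mid_ab_bb[2]), controls)
  expect_equal(lab, "undetermined")
})

test_that("genotype classification is accurate and order-invariant", {
  set.seed(8)
  centroids <- data.frame(label = c("AA", "AB", "BB", "NTC"),
                          signal_A = c(1, 0.5, 0.05, 0),
                          signal_B = c(0.05, 0.5, 1, 0))
  n <- 400
  truth <- sample(centroids$label, n, replace = TRUE)
  idx <- match(truth, centroids$label)
  sep <- 0.5                      # smallest centre-to-centre separation
  pts <- data.frame(
    signal_A = centroids$signal_A[idx] + rnorm(n, 0, 0.1 * sep),
    signal_B = centroids$signal_B[idx] + rnorm(n, 0, 0.1 * sep))
  lab <- classify_genotypes(pts, centroids, margin = 1)
  expect_gte(mean(lab == truth), 0.99)

  perm <- sample.int(n)
  lab_perm <- classify_genotypes(pts[perm, ], centroids, margin = 1)
  expect_equal(lab_perm, lab[perm])
})

test_that("call_monoallelic partitions verdicts by genotype and fraction", {
  res <- call_monoallelic(c("AA", "BB", "AB", "AB", "AB"),
                          c(0.9, 0.1, 0.5, 0.02, 0.98))
  expect_equal(res$verdict,
               c("uninformative", "uninformative", "biallelic",
                 "monoallelic", "monoallelic"))
  # homozygous verdicts carry no minor fraction
  expect_true(all(is.na(res$minor_fraction[1:2])))
  # minor fraction is symmetric in the two alleles
  expect_equal(res$minor_fraction[4], res$minor_fraction[5])

  # boundary: minor fraction exactly at the cut is biallelic (strict <)
  at_cut <- call_monoallelic("AB", 1 / 6)
  expect_equal(at_cut$verdict, "biallelic")

  # verdict partition: uninformative iff homozygous
  set.seed(3)
  g <- sample(c("AA", "AB", "BB"), 100, replace = TRUE)
  f <- runif(100)
  res <- call_monoallelic(g, f)
  expect_true(all(res$verdict %in%
                    c("monoallelic", "biallelic", "uninformative")))
  expect_equal(res$verdict == "uninformative", g != "AB")
})

test_that("mixture estimates feed mono/biallelic calls end to end", {
  ax <- simulate_allelic_mixtures(noise_sd = 0.02, seed = 44)
  cv <- fit_calibration(ax)
  set.seed(45)
  # heterozygote expressing both alleles evenly vs one dominated by A
  sig_even <- c(0.0415 + 1.02 * 0.5, 0.9796 - 0.85 * 0.5) +
    rnorm(2, 0, 0.02)
  sig_mono <- c(0.0415 + 1.02 * 0.97, 0.9796 - 0.85 * 0.97) +
    rnorm(2, 0, 0.02)
  f_even <- estimate_allelic_fraction(sig_even[1], sig_even[2], cv)
  f_mono <- estimate_allelic_fraction(sig_mono[1], sig_mono[2], cv)
  res <- call_monoallelic(c("AB", "AB"), c(f_even, f_mono))
  expect_equal(res$verdict, c("biallelic", "monoallelic"))
})
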