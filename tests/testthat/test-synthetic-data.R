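test_that("simulators are deterministic under a fixed seed", {
  cfg <- tiling_sim_config(chrom_lengths = c(chr1 = 5e4, chr2 = 3e4),
                           n_sites = 2, seed = 13)
  s1 <- simulate_tiling_experiment(cfg)
  s2 <- simulate_tiling_experiment(cfg)
  expect_identical(s1$tracks, s2$tracks)
  expect_identical(s1$truth, s2$truth)

  d1 <- simulate_dual_mark(cfg, 0.5, 50)
  d2 <- simulate_dual_mark(cfg, 0.5, 50)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$mark_b$tracks, d2$mark_b$tracks)

  expect_identical(simulate_gene_annotation(20, c(chr1 = 1e6), seed = 4),
                   simulate_gene_annotation(20, c(chr1 = 1e6), seed = 4))
  expect_identical(simulate_motif_clusters(100, seed = 8),
                   simulate_motif_clusters(100, seed = 8))
  expect_identical(simulate_bisulfite_reads(20, c(0.2, 0.8), seed = 5),
                   simulate_bisulfite_reads(20, c(0.2, 0.8), seed = 5))
  expect_identical(simulate_allelic_mixtures(seed = 6),
                   simulate_allelic_mixtures(seed = 6))
})

test_that("probe grids conserve floor(length / spacing) probes", {
  cfg <- tiling_sim_config(chrom_lengths = c(chr1 = 100350, chr2 = 99999),
                           spacing = 100, n_sites = 0, seed = 1)
  sim <- simulate_tiling_experiment(cfg)
  expect_length(sim$tracks[[1]]$chr1$start, 1003L)
  expect_length(sim$tracks[[1]]$chr2$start, 999L)
  expect_length(sim$tracks, 3L)
})

test_that("zero effect size leaves tracks at background while truth lists sites", {
  cfg <- tiling_sim_config(chrom_lengths = c(chr1 = 5e5), n_sites = 5,
                           effect_size = 0, seed = 3)
  sim <- simulate_tiling_experiment(cfg)
  expect_length(sim$truth, 5)
  r <- sim$tracks[[1]]$chr1$ratio
  expect_lt(abs(mean(r)), 0.02)          # background mean 0
  expect_lt(abs(sd(r) - 0.5), 0.02)      # background SD 0.5
})

test_that("spiked probes carry the additive effect in every replicate", {
  cfg <- tiling_sim_config(chrom_lengths = c(chr1 = 1e5), n_sites = 1,
                           effect_size = 4, bg_sd = 0.1, seed = 9)
  sim <- simulate_tiling_experiment(cfg)
  site <- sim$truth[1]
  for (r in 1:3) {
    trk <- sim$tracks[[r]]$chr1
    inside <- trk$start + 1 >= GenomicRanges::start(site) &
      trk$start + 1 <= GenomicRanges::end(site)
    expect_equal(sum(inside), 8)          # default site width in probes
    expect_true(all(trk$ratio[inside] > 3))
    expect_true(all(abs(trk$ratio[!inside]) < 1))
  }
})

test_that("site placement is rejected when wider than any chromosome", {
  expect_error(
    tiling_sim_config(chrom_lengths = c(chr1 = 500), spacing = 100,
                      n_sites = 1, site_width = 50),
    "exceeds"
  )
})

test_that("dual-mark truth honours the colocalized fraction at the extremes", {
  cfg <- tiling_sim_config(chrom_lengths = c(chr1 = 1e6), n_sites = 20,
                           seed = 5)
  none <- simulate_dual_mark(cfg, 0)
  expect_false(any(none$truth$shared))
  expect_length(none$truth$sites_b, 0)

  all_shared <- simulate_dual_mark(cfg, 1, offset_sd = 0)
  expect_true(all(all_shared$truth$shared))
  mid <- function(g) (GenomicRanges::start(g) + GenomicRanges::end(g)) / 2
  expect_equal(mid(all_shared$truth$sites_b),
               mid(all_shared$truth$sites_a))
})

test_that("gene annotation covers the degenerate and dense regimes", {
  empty <- simulate_gene_annotation(0, c(chr1 = 1e6), seed = 1)
  expect_length(empty, 0)
  cls <- classify_locus("chr1", 5e5, empty)
  expect_equal(cls$context, "intergenic")
  expect_equal(cls$dist_to_tss, Inf)

  genes <- simulate_gene_annotation(400, c(chr1 = 2e6), seed = 2,
                                    width_range = c(1000, 4000))
  expect_true(all(GenomicRanges::width(genes) >= 200))
  # non-overlapping by construction
  expect_equal(length(GenomicRanges::reduce(genes)), length(genes))

  # densely tiled genes: no locus farther than 10 kb from a 5' end
  dense <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(seq(1, 1e6, 5000), width = 2000),
    strand = "+", name = sprintf("g%03d", 1:200))
  q <- seq(1, 1e6, 777)
  cls <- classify_locus(rep("chr1", length(q)), q, dense)
  expect_true(all(cls$dist_to_tss <= 10000))
})

test_that("motif cluster depths follow the planted spectrum", {
  pure <- simulate_motif_clusters(5000, power_exponent = 2,
                                  excess_count = 0, seed = 11)
  cnt <- table(pure$clusters$depth)
  # monotone decreasing frequency (up to sampling noise at the tail)
  expect_true(all(diff(as.integer(cnt[1:5])) < 0))
  expect_true(max(pure$clusters$depth) <= 10)

  exc <- simulate_motif_clusters(100, excess_count = 50,
                                 excess_depth_range = c(15, 40), seed = 2)
  labelled <- partition_confidence(exc$clusters, threshold = 10)
  expect_equal(sum(labelled$confidence == "high"), 50)
})

test_that("bisulfite simulation respects the per-site probabilities", {
  all_m <- simulate_bisulfite_reads(200, c(site1 = 1), seed = 1)
  expect_true(all(all_m$cpg_site1 == "M"))

  all_u <- simulate_bisulfite_reads(200, c(a = 0, b = 0),
                                    conversion_failure_rate = 0, seed = 2)
  expect_true(all(all_u$cpg_a == "U") && all(all_u$cpg_b == "U"))
  expect_true(all(all_u$conversion_rate == 1))
})

test_that("allelic mixture labels translate to explicit fractions", {
  ax <- simulate_allelic_mixtures(noise_sd = 0, replicates = 1, seed = 1)
  expect_equal(ax$known_fraction,
               c(0, 0.2, 0.4, 0.5, 20 / 60, 0.8, 1))
  # pure-B sample: allele-A signal equals the channel intercept
  expect_equal(ax$signal_A[ax$known_fraction == 0], 0.0415)
  expect_error(simulate_allelic_mixtures(ratios = c("bad")), "malformed")
})

test_that("tracks, peaks, annotations and tables round-trip through files", {
  tmp <- withr::local_tempdir()
  trk <- random_track(30, seed = 4)
  f <- file.path(tmp, "rep1.bedGraph")
  write_probe_track(trk, f)
  back <- read_probe_track(f)
  expect_equal(back$start, trk$start)
  expect_equal(back$ratio, trk$ratio, tolerance = 1e-6)
  expect_equal(back$probe_length, trk$probe_length)

  pk <- GenomicRanges::GRanges("chr2", IRanges::IRanges(101, 400),
                               height = 2.5, fpr = 0.01, support = 3L)
  f <- file.path(tmp, "peaks.bed")
  write_peaks(pk, f)
  back <- read_peaks(f)
  expect_equal(GenomicRanges::start(back), 101)
  expect_equal(back$fpr, 0.01)
  expect_equal(back$support, 3L)

  genes <- simulate_gene_annotation(10, c(chr1 = 1e5), seed = 6)
  for (fmt in c("bed", "gff3")) {
    f <- file.path(tmp, paste0("genes.", fmt))
    write_gene_models(genes, f, format = fmt)
    back <- read_gene_models(f)
    expect_equal(GenomicRanges::start(back), GenomicRanges::start(genes))
    expect_equal(as.character(GenomicRanges::strand(back)),
                 as.character(GenomicRanges::strand(genes)))
    expect_equal(back$name, genes$name)
  }

  calls <- simulate_bisulfite_reads(15, c(0.4, 0.9), seed = 7)
  f <- file.path(tmp, "calls.csv")
  write_bisulfite_csv(calls, f)
  back <- read_bisulfite_csv(f)
  expect_equal(back$cpg_50, calls$cpg_50)
  expect_equal(back$conversion_rate, calls$conversion_rate)

  ax <- simulate_allelic_mixtures(seed = 8)
  f <- file.path(tmp, "assay.csv")
  write_assay_csv(ax, f)
  back <- read_assay_csv(f)
  expect_equal(back$known_fraction, ax$known_fraction)
  expect_equal(back$signal_A, ax$signal_A, tolerance = 1e-12)

  f <- file.path(tmp, "truth.json")
  write_truth_json(list(sites = GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(5, 10)), fractions = c(0.25, 0.5)), f)
  back <- read_truth_json(f)
  expect_equal(back$sites$start, 5)
  expect_equal(back$fractions, c(0.25, 0.5))
})
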