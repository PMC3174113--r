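#' Configuration for a simulated tiling-array experiment
#'
#' Defaults emulate the study design the pipeline targets: probes spaced
#' 100 bp apart (50-mers), three biological replicates, and a handful of
#' enriched sites shared by all replicates.  Background log2 IP:input
#' ratios are i.i.d. Gaussian per probe; an enriched site adds a constant
#' effect (in log2 units) to every probe it covers, in every replicate.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param spacing Probe spacing in bp (> 0).
#' @param probe_length Probe length in bp.
#' @param n_replicates Number of biological replicates (>= 1).
#' @param bg_mean,bg_sd Mean and SD of the Gaussian background log2 ratio.
#' @param n_sites Number of spiked enriched sites.
#' @param site_width Width of each site in probes.
#' @param effect_size Log2 enrichment added at spiked probes (>= 0).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A list of class `tiling_sim_config`.
#' @export
tiling_sim_config <- function(chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
                              spacing = 100L, probe_length = 50L,
                              n_replicates = 3L, bg_mean = 0,
                              bg_sd = 0.5, n_sites = 10L,
                              site_width = 8L, effect_size = 3,
                              seed = 1L) {
  if (is.null(names(chrom_lengths)) || any(names(chrom_lengths) == "")) {
    stop("'chrom_lengths' must be a named vector")
  }
  stopifnot(spacing > 0, probe_length > 0, n_replicates >= 1,
            bg_sd >= 0, n_sites >= 0, site_width >= 1, effect_size >= 0)
  n_probes <- floor(chrom_lengths / spacing)
  if (n_sites > 0 && any(site_width > max(n_probes))) {
    stop("spiked site width exceeds every chromosome's probe count")
  }
  structure(list(chrom_lengths = chrom_lengths,
                 spacing = as.integer(spacing),
                 probe_length = as.integer(probe_length),
                 n_replicates = as.integer(n_replicates),
                 bg_mean = bg_mean, bg_sd = bg_sd,
                 n_sites = as.integer(n_sites),
                 site_width = as.integer(site_width),
                 effect_size = effect_size,
                 seed = as.integer(seed)),
            class = "tiling_sim_config")
}

# place n non-overlapping sites of `width` probes on chromosomes with
# `n_probes[chrom]` probes; returns data.frame(chrom, first_probe)
.place_sites <- function(n_sites, n_probes, width) {
  if (n_sites == 0L) {
    return(data.frame(chrom = character(0), first_probe = integer(0)))
  }
  eligible <- names(n_probes)[n_probes >= width]
  if (length(eligible) == 0L) {
    stop("spiked sites exceed chromosome bounds: no chromosome can hold ",
         width, " probes")
  }
  w <- n_probes[eligible] / sum(n_probes[eligible])
  placed <- data.frame(chrom = character(0), first_probe = integer(0))
  tries <- 0L
  while (nrow(placed) < n_sites) {
    tries <- tries + 1L
    if (tries > 1000L * n_sites) {
      stop("could not place ", n_sites,
           " non-overlapping spiked sites; reduce count or width")
    }
    ch <- sample(eligible, 1L, prob = w)
    fp <- sample.int(n_probes[[ch]] - width + 1L, 1L)
    clash <- placed$chrom == ch &
      abs(placed$first_probe - fp) < width
    if (!any(clash)) {
      placed <- rbind(placed, data.frame(chrom = ch, first_probe = fp))
    }
  }
  placed[order(placed$chrom, placed$first_probe), , drop = FALSE]
}

#' Simulate a replicated tiling-array experiment with known truth
#'
#' Builds per-chromosome probe grids, draws i.i.d. Gaussian background
#' log2 ratios independently per probe and replicate, and adds the
#' configured effect size to every probe covered by a spiked site.  Site
#' positions are identical across replicates (biological replicates share
#' biology); only the noise differs.
#'
#' @param config A [tiling_sim_config()].
#' @return A list with elements:
#'   * `tracks`: list of `n_replicates` elements, each a named list of
#'     [probe_track()] objects (one per chromosome);
#'   * `truth`: [GenomicRanges::GRanges] (1-based) of spiked sites with
#'     `site_id` metadata;
#'   * `config`: the input configuration.
#' @examples
#' sim <- simulate_tiling_experiment(
#'   tiling_sim_config(chrom_lengths = c(chr1 = 1e5), n_sites = 2, seed = 7))
#' length(sim$truth)
#' @export
simulate_tiling_experiment <- function(config) {
  stopifnot(inherits(config, "tiling_sim_config"))
  set.seed(config$seed)
  n_probes <- vapply(config$chrom_lengths,
                     function(L) as.integer(floor(L / config$spacing)),
                     integer(1))
  starts <- lapply(n_probes, function(n) (seq_len(n) - 1L) * config$spacing)
  sites <- .place_sites(config$n_sites, n_probes, config$site_width)

  truth <- GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(
      start = (sites$first_probe - 1L) * config$spacing + 1L,
      end = (sites$first_probe + config$site_width - 2L) * config$spacing +
        config$probe_length
    ),
    site_id = if (nrow(sites)) paste0("site_", seq_len(nrow(sites)))
              else character(0)
  )

  tracks <- lapply(seq_len(config$n_replicates), function(r) {
    per_chrom <- lapply(names(n_probes), function(ch) {
      ratio <- stats::rnorm(n_probes[[ch]], config$bg_mean, config$bg_sd)
      hit <- sites[sites$chrom == ch, , drop = FALSE]
      for (k in seq_len(nrow(hit))) {
        idx <- hit$first_probe[k]:(hit$first_probe[k] + config$site_width - 1L)
        ratio[idx] <- ratio[idx] + config$effect_size
      }
      probe_track(ch, starts[[ch]], ratio, config$probe_length)
    })
    names(per_chrom) <- names(n_probes)
    per_chrom
  })
  list(tracks = tracks, truth = truth, config = config)
}

#' Simulate a dual-chromatin-mark experiment
#'
#' Generates a mark-A experiment from `config`, then gives a Bernoulli
#' fraction of A sites a mark-B partner whose centre is jittered by a
#' zero-mean Gaussian of SD `offset_sd`; remaining A sites stay
#' A-exclusive.  Optionally adds B-exclusive sites placed away from A
#' sites.  Mark-B replicate tracks are generated on the same probe grid
#' with the same background model.
#'
#' @param config A [tiling_sim_config()]; its `n_sites` is the mark-A
#'   site count.
#' @param colocalized_fraction Probability an A site is also a B site,
#'   in \[0, 1\].
#' @param offset_sd SD (bp) of the B-site centre jitter.
#' @param n_b_only Number of additional B-exclusive sites (default 0).
#' @return A list with `mark_a` and `mark_b` (each as returned by
#'   [simulate_tiling_experiment()], sharing one grid), and `truth`: a
#'   list with `sites_a`, `sites_b` (GRanges) and `shared` (logical per
#'   A site).
#' @export
simulate_dual_mark <- function(config, colocalized_fraction,
                               offset_sd = 100, n_b_only = 0L) {
  stopifnot(inherits(config, "tiling_sim_config"),
            colocalized_fraction >= 0, colocalized_fraction <= 1,
            offset_sd >= 0)
  exp_a <- simulate_tiling_experiment(config)
  sites_a <- exp_a$truth
  set.seed(.chrom_subseed(config$seed, "dual_mark_B"))

  shared <- if (length(sites_a)) {
    stats::runif(length(sites_a)) < colocalized_fraction
  } else logical(0)

  site_w <- (config$site_width - 1L) * config$spacing + config$probe_length
  b_list <- GenomicRanges::GRanges()
  if (any(shared)) {
    a_start <- GenomicRanges::start(sites_a[shared])
    b_start <- a_start + round(stats::rnorm(sum(shared), 0, offset_sd))
    chr_len <- config$chrom_lengths[
      as.character(GenomeInfoDb::seqnames(sites_a[shared]))]
    b_start <- pmin(pmax(b_start, 1), chr_len - site_w + 1)
    b_list <- GenomicRanges::GRanges(
      seqnames = GenomeInfoDb::seqnames(sites_a[shared]),
      ranges = IRanges::IRanges(start = b_start, width = site_w)
    )
  }
  if (n_b_only > 0L) {
    ch <- sample(names(config$chrom_lengths), n_b_only, replace = TRUE,
                 prob = config$chrom_lengths / sum(config$chrom_lengths))
    st <- vapply(ch, function(c1) {
      round(stats::runif(1, 1, config$chrom_lengths[[c1]] - site_w + 1))
    }, numeric(1))
    b_list <- c(b_list, GenomicRanges::GRanges(
      seqnames = ch,
      ranges = IRanges::IRanges(start = st, width = site_w)
    ))
  }
  if (length(b_list)) {
    S4Vectors::mcols(b_list)$site_id <- paste0("bsite_", seq_along(b_list))
  }

  # mark-B probe tracks on the same grid
  n_probes <- vapply(config$chrom_lengths,
                     function(L) as.integer(floor(L / config$spacing)),
                     integer(1))
  tracks_b <- lapply(seq_len(config$n_replicates), function(r) {
    per_chrom <- lapply(names(n_probes), function(chn) {
      st <- (seq_len(n_probes[[chn]]) - 1L) * config$spacing
      ratio <- stats::rnorm(n_probes[[chn]], config$bg_mean, config$bg_sd)
      bs <- b_list[GenomeInfoDb::seqnames(b_list) == chn]
      for (k in seq_along(bs)) {
        cover <- which(st + config$probe_length >=
                         GenomicRanges::start(bs)[k] - 1 &
                       st < GenomicRanges::end(bs)[k])
        ratio[cover] <- ratio[cover] + config$effect_size
      }
      probe_track(chn, st, ratio, config$probe_length)
    })
    names(per_chrom) <- names(n_probes)
    per_chrom
  })

  list(mark_a = exp_a,
       mark_b = list(tracks = tracks_b, truth = b_list, config = config),
       truth = list(sites_a = sites_a, sites_b = b_list, shared = shared))
}

#' Simulate a gene annotation
#'
#' Draws non-overlapping gene bodies with random strand on each
#' chromosome, allocated proportionally to chromosome length.  Intended
#' for testing genomic-context classification, not for realism of exon
#' structure.
#'
#' @param n_genes Total number of genes (>= 0).
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param seed Integer seed.
#' @param width_range Min/max gene body width (bp).
#' @return A [GenomicRanges::GRanges] with `name` metadata and strand.
#' @export
simulate_gene_annotation <- function(n_genes, chrom_lengths, seed = 1L,
                                     width_range = c(2000, 50000)) {
  stopifnot(n_genes >= 0, all(chrom_lengths > 0))
  set.seed(seed)
  if (n_genes == 0L) {
    return(GenomicRanges::GRanges(name = character(0)))
  }
  per_chrom <- table(sample(names(chrom_lengths), n_genes, replace = TRUE,
                            prob = chrom_lengths / sum(chrom_lengths)))
  out <- lapply(names(per_chrom), function(ch) {
    k <- per_chrom[[ch]]
    L <- chrom_lengths[[ch]]
    anchors <- sort(sample.int(L - 1L, k))
    gap_to_next <- c(diff(anchors), L - anchors[k])
    # trim each body to its gap; drop genes squeezed below 200 bp
    w <- pmin(round(stats::runif(k, width_range[1], width_range[2])),
              gap_to_next - 1)
    g <- GenomicRanges::GRanges(
      seqnames = ch,
      ranges = IRanges::IRanges(start = anchors, width = pmax(w, 1)),
      strand = sample(c("+", "-"), k, replace = TRUE)
    )
    g[w >= 200]
  })
  gr <- do.call(c, out)
  S4Vectors::mcols(gr)$name <- sprintf("gene_%04d", seq_along(gr))
  gr
}

#' Simulate motif-read clusters with a power-law depth spectrum
#'
#' Cluster depths (maximum read-stack heights) are drawn from a discrete
#' power law on a finite support (default 1..10) by inverse-CDF
#' sampling, plus an excess component of high-depth clusters uniform
#' over `excess_depth_range`.  Each simulated cluster is realised as
#' `depth` identical reads, so re-clustering the reads recovers the
#' planted depths exactly.
#'
#' @param n_clusters Number of power-law clusters.
#' @param power_exponent Power-law exponent alpha > 0
#'   (P(depth = h) proportional to h^-alpha).
#' @param excess_count Number of excess high-depth clusters.
#' @param excess_depth_range Integer range of excess depths
#'   (default 15..40).
#' @param seed Integer seed.
#' @param support_max Upper bound of the power-law support (default 10).
#' @param read_length Read length in bp (default 36).
#' @param chrom Chromosome name for the synthetic placements.
#' @return A list with `clusters` (GRanges with `depth`) and `reads`
#'   (GRanges).
#' @export
simulate_motif_clusters <- function(n_clusters, power_exponent = 1.8,
                                    excess_count = 0L,
                                    excess_depth_range = c(15L, 40L),
                                    seed = 1L, support_max = 10L,
                                    read_length = 36L, chrom = "chrS") {
  stopifnot(power_exponent > 0, n_clusters >= 0, excess_count >= 0,
            support_max >= 1)
  set.seed(seed)
  support <- seq_len(support_max)
  p <- support^(-power_exponent)
  p <- p / sum(p)
  depths <- c(
    if (n_clusters > 0) sample(support, n_clusters, replace = TRUE, prob = p),
    if (excess_count > 0)
      sample(seq(excess_depth_range[1], excess_depth_range[2]),
             excess_count, replace = TRUE)
  )
  n <- length(depths)
  if (n == 0L) {
    return(list(clusters = GenomicRanges::GRanges(depth = integer(0)),
                reads = GenomicRanges::GRanges()))
  }
  gap <- 2L * read_length           # clusters never touch
  starts <- cumsum(rep(read_length + gap, n)) - read_length
  clusters <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = starts, width = read_length),
    depth = as.integer(depths)
  )
  reads <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = rep(starts, depths),
                              width = read_length)
  )
  list(clusters = clusters, reads = reads)
}

#' Simulate bisulfite read calls
#'
#' Each read's call at each CpG site is Bernoulli with the site's
#' methylation probability ("M" methylated, "U" unmethylated).  Each
#' read also carries a non-CpG cytosine conversion rate: failures are
#' binomial at `conversion_failure_rate` over `n_noncpg` non-CpG
#' cytosines, giving the QC statistic used to discard incompletely
#' converted reads.
#'
#' @param n_reads Number of reads.
#' @param methylation_probs Numeric vector of per-CpG methylation
#'   probabilities in \[0, 1\]; names (or positions 1..k scaled by 50 bp)
#'   become site coordinates.
#' @param conversion_failure_rate Per-cytosine failure probability.
#' @param seed Integer seed.
#' @param n_noncpg Non-CpG cytosines per read used for the conversion
#'   rate (default 20).
#' @param na_rate Probability a call is missing (default 0).
#' @return A data.frame with `read_id`, `conversion_rate`, and one
#'   `cpg_<pos>` column per site holding "M"/"U"/NA.
#' @export
simulate_bisulfite_reads <- function(n_reads, methylation_probs,
                                     conversion_failure_rate = 0.02,
                                     seed = 1L, n_noncpg = 20L,
                                     na_rate = 0) {
  stopifnot(n_reads >= 1, all(methylation_probs >= 0),
            all(methylation_probs <= 1),
            conversion_failure_rate >= 0, conversion_failure_rate <= 1)
  set.seed(seed)
  k <- length(methylation_probs)
  pos <- names(methylation_probs)
  if (is.null(pos)) pos <- as.character(seq_len(k) * 50L)
  calls <- vapply(seq_len(k), function(j) {
    x <- ifelse(stats::runif(n_reads) < methylation_probs[j], "M", "U")
    if (na_rate > 0) x[stats::runif(n_reads) < na_rate] <- NA_character_
    x
  }, character(n_reads))
  calls <- matrix(calls, nrow = n_reads)
  colnames(calls) <- paste0("cpg_", pos)
  fails <- stats::rbinom(n_reads, n_noncpg, conversion_failure_rate)
  out <- data.frame(read_id = sprintf("read_%05d", seq_len(n_reads)),
                    conversion_rate = 1 - fails / n_noncpg,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(calls, stringsAsFactors = FALSE))
}

# "B:A" mixture labels -> fraction of allele A, normalised by the pair sum
.ratio_label_to_fraction <- function(labels) {
  vapply(labels, function(s) {
    parts <- suppressWarnings(
      as.numeric(strsplit(s, ":", fixed = TRUE)[[1]]))
    if (length(parts) != 2L || any(is.na(parts)) || sum(parts) <= 0) {
      stop("malformed mixture label: ", s)
    }
    parts[2] / sum(parts)
  }, numeric(1))
}

#' Simulate two-channel allelic mixture assays
#'
#' Emulates endpoint-fluorescence genotyping of DNA mixtures: per-channel
#' signal is linear in the allele-A fraction plus Gaussian noise.  The
#' default mixture series covers the classic dilution ladder from pure
#' allele B to pure allele A; character labels are interpreted as B:A
#' ratios and normalised by their sum, so uneven labels are handled
#' explicitly.
#'
#' @param ratios Numeric allele-A fractions in \[0, 1\], or character
#'   "B:A" labels (default the seven-step ladder
#'   `100:0 ... 0:100`).
#' @param slope_a,intercept_a Allele-A channel response (signal vs
#'   fraction of A).
#' @param slope_b,intercept_b Allele-B channel response (decreasing in
#'   the A fraction).
#' @param noise_sd Gaussian signal noise SD (same units as signal).
#' @param replicates Technical replicates per mixture (default 3).
#' @param seed Integer seed.
#' @return A data.frame `sample, known_fraction, signal_A, signal_B,
#'   replicate` with the generating truth in `known_fraction`.
#' @export
simulate_allelic_mixtures <- function(ratios = c("100:0", "80:20", "60:40",
                                                 "50:50", "40:20", "20:80",
                                                 "0:100"),
                                      slope_a = 1.02, intercept_a = 0.0415,
                                      slope_b = -0.85, intercept_b = 0.9796,
                                      noise_sd = 0.02, replicates = 3L,
                                      seed = 1L) {
  if (is.character(ratios)) {
    labels <- ratios
    frac <- .ratio_label_to_fraction(ratios)
  } else {
    stopifnot(all(ratios >= 0), all(ratios <= 1))
    frac <- as.numeric(ratios)
    labels <- sprintf("%g:%g", round(100 * (1 - frac)), round(100 * frac))
  }
  stopifnot(noise_sd >= 0, replicates >= 1)
  set.seed(seed)
  n <- length(frac) * replicates
  f <- rep(frac, each = replicates)
  data.frame(
    sample = rep(labels, each = replicates),
    known_fraction = f,
    signal_A = intercept_a + slope_a * f + stats::rnorm(n, 0, noise_sd),
    signal_B = intercept_b + slope_b * f + stats::rnorm(n, 0, noise_sd),
    replicate = rep(seq_len(replicates), times = length(frac)),
    stringsAsFactors = FALSE
  )
}
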