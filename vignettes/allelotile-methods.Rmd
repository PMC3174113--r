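---
title: "Methods: tiling-array peak calling and allele-specific analytics"
author: "allelotile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tiling-array peak calling and allele-specific analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allelotile)
```

# Overview

`allelotile` implements a ChIP-chip analysis chain for tiling
microarrays — probes spaced ~100 bp apart, each reporting a log2
IP:input ratio — together with the downstream allele-specific analytics
used to study loci that carry both CTCF binding and the repressive
H3K9me3 mark. Every stage consumes inputs that the package's
synthetic-data module can generate with known ground truth, so the
whole chain is testable end to end without any external data set.

# Peak detection and the permutation false-positive rate

## The window rule

A probe *seeds* a possible binding site when, among the probe itself
and the flanking probes within a window covering 250 bp on both sides
of it, at least four probes have log2 ratios above the cutoff.
Overlapping or book-ended qualifying windows merge into one peak that
spans their above-threshold probes; peak height is the maximum probe
ratio inside.

Two conventions here were genuinely open and are fixed as follows,
each exercised explicitly by a test:

* window membership is judged on **probe start coordinates**, and the
  window `[seed - 250, seed + 250]` is **closed** at both ends. At
  100-bp spacing this makes a window hold five to six probes;
* the seed probe itself counts toward the four only when it is above
  the threshold (it is part of the candidate set, not exempt from the
  cutoff).

## The cutoff schedule

The cutoff applied to a chromosome is a percentage *P* of the value
`mean + 6 * SD` of all that chromosome's probe ratios, recomputed per
chromosome and per replicate; SD is the sample standard deviation
(n − 1), a convention the method leaves open. The sweep runs *P* from
100% down to 20% in steps of 5 (17 levels, most stringent first). The
step grid itself is a package choice: it spans stringent-to-permissive
while keeping 17 levels x 20 permutations cheap on a desktop.

## Permutation FPR and first detection

For each chromosome, the log2 ratios are scrambled across probes — the
coordinate grid is untouched, the ratio multiset is preserved exactly —
20 times. The FPR at a cutoff is the mean peak count over the scrambled
tracks divided by the observed peak count at the same cutoff. The FPR
is a ratio of counts, not a probability, and is deliberately **not
capped at 1**; an observed count of zero yields `NA` rather than a
division error.

Each peak is assigned the FPR of the cutoff at which it is *first
detected*. Because lowering the cutoff only widens existing peaks and
adds new ones (a monotonicity property the tests assert), "first" is
read as the most stringent level in the descending sweep at which any
peak overlaps it; peak identity across levels is tracked by genomic
overlap. One set of permuted tracks per chromosome is generated from a
per-chromosome sub-seed and reused across all 17 levels, which keeps
runs reproducible and avoids re-drawing 340 permutations.

## Replicate consensus

High-confidence calls must be present in all three biological
replicates and carry FPR < 0.05 (strict). Peaks failing the FPR cut are
removed per replicate first; a consensus interval is then emitted
wherever FPR-passing peaks from all replicates mutually overlap by at
least 1 bp — for intervals on a line, pairwise overlap guarantees a
common intersection, so the consensus interval is simply the region
covered by all contributors. No reciprocal-overlap fraction is
required, since the design constraint is presence, not extent.
Consensus height is the mean of contributors; consensus FPR is the
maximum (most pessimistic) contributor FPR, so the < 0.05 postcondition
is inherited.

# What the tiling simulator emulates — and what it does not

The generator builds per-chromosome probe grids at 100-bp spacing
(50-mer probes, `floor(length / spacing)` probes per chromosome), draws
background log2 ratios i.i.d. Gaussian per probe and replicate, and
adds a constant effect to every probe covered by a spiked site. Site
positions are shared across replicates — biological replicates share
biology; only the noise differs.

Defaults: two 1-Mb chromosomes, background mean 0 and SD 0.5, ten
spiked sites of eight probes each, effect size 3.0 (six background
SDs). No public record states the original arrays' noise
characteristics or enrichment magnitudes, so these are calibrated
operating conditions for exploring the pipeline's behaviour, not a
reconstruction: the background was chosen so the `mean + 6 SD` base
cutoff sits near 3 log2 units, and the six-SD effect is the regime in
which the consensus filter should reach sensitivity 1.0 — which the
acceptance tests then verify it does.

The simulator deliberately omits dye bias, GC effects, spatial artefacts
and probe-response heterogeneity. Passing tests therefore demonstrate
the algorithmic contract (window rule, FPR calibration on exchangeable
nulls, consensus postcondition), not robustness to real-array
systematics, which upstream normalisation is assumed to have handled.

# Dual-mark colocalization and genomic context

Two peak sets are paired by midpoint-to-midpoint distance, strictly
below 500 bp. Distances use interval **midpoints** (width-robust and
symmetric; edge-to-edge is available as an option), and matching is
one-to-one, greedy nearest-first, so no peak is double-counted; the
pairing outcome is symmetric in the two mark roles. The dual-mark
simulator gives each mark-A site a Bernoulli chance of carrying a
mark-B partner whose centre is jittered by a zero-mean Gaussian
(default SD 100 bp), which makes the recovered pair count a binomial
quantity with known tolerance.

Paired loci are classified with precedence promoter > intragenic >
intergenic. The promoter window defaults to 2,000 bp upstream to 500 bp
downstream of the strand-appropriate 5' end — a common convention
adopted because the underlying method never defines "promoter region";
it is fully configurable. Intergenic loci farther than 10 kb from the
nearest 5' end are flagged distal. Overlap against an external gene
list counts loci whose midpoint falls within a configurable window of a
listed gene's span; the window is exposed rather than fixed because the
comparable published comparisons do not state whether gene bodies,
promoters, or padded spans were used.

# Motif-read clusters and confidence partitioning

Reads overlapping by at least 1 bp chain into clusters (book-ended
reads do not join); a cluster's depth is the **maximum number of
simultaneously overlapping reads** — the height of the stack, computed
as the max of the per-base coverage — rather than the total read
count, so depth is invariant to cluster width.

The depth histogram of such clusters is bimodal in the regime the
pipeline targets: a power law at low depths plus an excess of deep
clusters. The exponent is fitted by unweighted least squares on
log10–log10 points over depths 1..10 with nonzero counts (the standard
treatment for visually assessed power laws; an MLE fit would also be
defensible but is not the default). Fewer than two usable depths yields
an `NA` exponent rather than an error. Clusters with depth **strictly
greater than 10** are high-confidence; depth exactly 10 is
low-confidence, because the excess component is described as heights
*above* the threshold. The cluster simulator samples the low-depth
component by inverse-CDF from a discrete power law on support 1..10 and
the excess uniformly over a configurable high range (default 15..40),
reproducing the bimodal shape without asserting an unstated generative
law.

# Allele-specific analytics

## Bisulfite methylation scoring

The scorer consumes pre-extracted per-read CpG calls (M/U/NA). Reads
whose non-CpG cytosine conversion rate falls below 0.9 are discarded as
incompletely converted — the standard QC for bisulfite completeness —
and the per-site percentage methylation is M / (M + U) over retained
reads; zero-coverage sites give `NA`, never a number. This is a
deliberately minimal scorer: trace alignment and base calling belong to
dedicated bisulfite software and are out of scope; the scored quantity
(per-site percent methylation) is what downstream claims consume.

## Allelic-mixture calibration and expression calls

Endpoint two-channel genotyping signals are modelled as linear in the
allele-A fraction. Calibration is ordinary least squares per channel
(requiring three distinct mixture fractions; a constant channel gets
slope 0 with R² defined as 0), and an unknown sample's fraction is
estimated by inverting each channel's line and averaging the two
estimates — no combination rule is established practice here, and the
mean is transparent and testable; a channel with near-zero slope is
excluded with a warning. Estimates are clamped to [0, 1].

The default simulator responses (A: slope 1.02, intercept 0.0415; B:
slope −0.85, intercept 0.9796; noise SD 0.02) represent a realistic
two-fluorophore endpoint assay whose dilution ladder runs 100:0 to
0:100. Mixture labels are parsed as B:A pairs and normalised by their
pair sum, so an uneven label like 40:20 is treated explicitly as a
fraction of 1/3 rather than silently corrected.

Genotypes are classified by nearest control centroid (AA, AB, BB,
no-template control), with a point whose second-nearest centroid is
less than 1.05x farther than its nearest labelled undetermined.
Mono/biallelic calls: a homozygous genomic genotype is uninformative by
definition — with one allele there is nothing allele-specific to
measure; a heterozygote whose cDNA minor-allele fraction is below 1/6
is monoallelic, otherwise biallelic. The 1/6 default operationalises
"expressed primarily from one allele" at the 1:5 ratio, the smallest
imbalance the calibration assay is demonstrated to resolve; it is a
documented package choice, not an established threshold, and is
configurable.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open in all files (BED/bedGraph
  semantics) and 1-based closed inside R (`GRanges` semantics).
* A single-probe track has no sample SD; `compute_cutoff` errors with
  "insufficient probes" rather than returning `NaN`.
* `permute_track` shuffles by index, so a single-probe track maps to
  itself.
* Greedy pairing breaks distance ties by input order, making results
  deterministic.
* Per-chromosome permutation sub-seeds are derived from the master seed
  by a fixed integer hash of the chromosome name, kept below 2^31.
* Sites spiked wider than any chromosome's probe count are rejected at
  configuration time with a clear message.

# Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen
so the full suite completes in well under a minute of compute: 2 x 1 Mb
chromosomes (20,000 probes) for the consensus experiment, 200 random
tracks of up to 500 probes for the window-rule oracle, 10,000 sampled
clusters for exponent recovery, and 1,000 reads for methylation
scoring. These sizes give the binomial and regression tolerances quoted
in the tests; nothing in the implementation depends on them.

# Known limitations

* The FPR denominator is the observed peak count at the same cutoff, so
  on spike-in data the null calibration statement (mean FPR near 1)
  holds only for background-only tracks.
* Consensus re-estimation of FPR on the merged intervals is not
  performed; filtering is per replicate, and the consensus inherits the
  worst contributor FPR.
* The context classifier assumes a flat gene model (no exon structure,
  no alternative TSSs).
* The power-law fit is descriptive; it does not test goodness of fit
  against alternatives.
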