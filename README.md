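# allelotile

Tiling-array ChIP-chip peak calling with permutation false-positive
rates, dual-chromatin-mark colocalization, motif-cluster confidence
partitioning, and allele-specific expression analytics — with a
synthetic-data module that generates every input with known ground
truth.

## The scientific problem

Loci that carry both CTCF binding and the repressive H3K9me3 histone
mark — the chromatin signature of imprinting control regions — are
candidates for allele-specific regulation. Finding them from tiling
microarrays (probes every ~100 bp, each reporting a log2 IP:input
ratio) requires a peak caller whose error rate can be estimated without
a parametric noise model, a way to pair peaks from two independent
ChIP experiments, and downstream assays that decide whether a candidate
gene is actually expressed from one allele: bisulfite methylation
scoring and two-channel allelic-discrimination calibration.

`allelotile` is aimed at analysts who want that whole chain as
composable, tested R functions over Bioconductor containers
(`GRanges`, plain data frames), plus generators that produce realistic
inputs with planted truth so every stage's operating characteristics
can be measured.

## The method

**Peak calling.** A probe seeds a possible binding site when at least
4 probes within a closed ±250 bp window around it exceed a cutoff; the
cutoff is a percentage *P* of the per-chromosome value
mean + 6·SD of all probe log2 ratios. Sweeping *P* from 100% down to
20%, the false-positive rate at each level is

FPR(P) = (mean peak count over 20 ratio-scrambled tracks) / (observed peak count),

computed per chromosome. Each peak carries the FPR of the most
stringent *P* at which it is first detected, and consensus peaks must
appear in all three biological replicates with FPR < 0.05.

**Colocalization.** Peaks from two marks pair when their midpoints lie
strictly within 500 bp (greedy one-to-one nearest matching); paired
loci are classified promoter / intragenic / intergenic against a gene
annotation, with intergenic loci >10 kb from the nearest 5' end flagged
distal.

**Motif clusters.** Overlapping motif reads chain into clusters whose
depth is the maximum read-stack height; the depth spectrum is fitted by
a log–log least-squares power law over depths ≤ 10, and clusters with
depth > 10 form the high-confidence class.

**Allelic analytics.** Per-CpG methylation is M/(M+U) over
bisulfite reads passing a 90% non-CpG conversion filter. Two-channel
allelic assays are calibrated by per-channel OLS of signal against
known mixture fraction; unknown samples are estimated by inverting both
channels and averaging, and heterozygotes with a cDNA minor-allele
fraction below 1/6 (a 1:5 ratio) are called monoallelic.

## Worked example

```r
library(allelotile)

# a 500-kb chromosome, 3 replicates, 4 spiked sites at 6 background SDs
cfg <- tiling_sim_config(chrom_lengths = c(chr1 = 5e5), n_sites = 4,
                         seed = 42)
sim <- simulate_tiling_experiment(cfg)
res <- call_consensus_peaks(sim$tracks, plan = permutation_plan(20, 7))
res$consensus
#> GRanges object with 4 ranges and 3 metadata columns:
#>       seqnames        ranges strand |    height       fpr   support
#>          <Rle>     <IRanges>  <Rle> | <numeric> <numeric> <integer>
#>   [1]     chr1   63301-64050      * |   3.55273         0         3
#>   [2]     chr1 109701-110450      * |   3.64252         0         3
#>   [3]     chr1 391001-391750      * |   3.57192         0         3
#>   [4]     chr1 406801-407550      * |   4.17776         0         3
```

All four planted sites are recovered, each supported by all three
replicates, with permutation FPR 0: at six background SDs the spikes
are first detected at cutoffs where scrambled tracks produce no peaks
at all.

```r
# motif clusters: power law + excess, fitted back from the reads
mc <- simulate_motif_clusters(5000, power_exponent = 1.8,
                              excess_count = 150, seed = 1)
depth_spectrum(cluster_reads(mc$reads))
#> depth_spectrum: 5150 clusters, depths 1-40
#>   power-law exponent over depths <= 10: 1.754

# allelic calibration and a mono/biallelic call
cv <- fit_calibration(simulate_allelic_mixtures(seed = 3))
cv
#> channel A: y = 1.0250 x + 0.0355   (R^2 = 0.99791)
#> channel B: y = -0.8303 x + 0.9725   (R^2 = 0.99643)
f <- estimate_allelic_fraction(0.20, 0.85, cv)   # one cDNA sample
round(f, 3)
#> [1] 0.154
call_monoallelic("AB", f)
#>   genotype minor_fraction     verdict
#> 1       AB      0.1540545 monoallelic
```

The fitted exponent (1.754) recovers the generating value 1.8 from
5,000 sampled clusters; the cDNA sample's estimated allele-A fraction
0.154 lies below the 1/6 minor-allele cut, so a heterozygous individual
with these signals is called monoallelic.

A thin command-line front end over the same functions ships in
`inst/scripts/allelotile` (subcommands `callpeaks`, `colocalize`,
`motifconf`, `methylation`, `allelic`).

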