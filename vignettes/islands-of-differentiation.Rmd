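---
title: "Mapping islands of differentiation between hybridizing populations"
author: "diffscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping islands of differentiation between hybridizing populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Two populations connected by gene flow across a hybrid zone differentiate
unevenly: neutral regions are homogenized by migration and retain shared
ancestral variation, while loci contributing to reproductive isolation
resist introgression and accumulate differentiation — up to fixed
differences — in narrow genomic islands. `diffscan` locates such islands
from modest samples (a handful of diploids per population, one outgroup
individual) typed at bi-allelic SNPs, and asks the complementary
model-based question: *could the observed genome-wide excess of fixed
differences have arisen under neutral isolation-with-migration at all?*

The package assumes bi-allelic SNPs with per-population allele counts,
diploid genotypes with missingness handled by reducing the called sample
size (never imputed), and an outgroup used only for polarization and for
outgroup divergence; phasing is never required, because every statistic is
computed from allele frequencies.

## Statistics

**Per-SNP F\_ST.** The two-population Weir–Cockerham variance-components
estimator, treating called chromosomes as the sampling unit: with sample
sizes $n_i$ and frequencies $p_i$, the among- and within-population mean
squares give $\hat\theta = (MSP - MSG)/(MSP + (n_c - 1)MSG)$. The
estimator may be negative; it is undefined (NA) when both populations are
monomorphic or fewer than two chromosomes were called in either. Window
aggregation uses the *mean of per-SNP values*, not the ratio of sums —
a deliberate choice matching the scan design this package implements;
the per-SNP values remain available for any other aggregation.

**Site classes.** Each SNP is *fixed* (alternate alleles at frequencies 1
vs 0), *shared* (segregating in both populations), *exclusive* to one, or
*monomorphic*. The classification is exhaustive for bi-allelic sites with
at least one called chromosome per population.

**Spectra and neutrality tests.** Per fragment and population, the
folded spectrum yields π, Watterson's $\theta_W = S/(a_n L)$ and Tajima's
*D*; the unfolded spectrum (outgroup-polarized sites only) yields Fay &
Wu's $H = \pi - \theta_H$, sensitive to high-frequency derived alleles.
Sites whose called sample size exceeds the reference $n$ are projected
down hypergeometrically; smaller ones are dropped.

**Divergence and RND.** $D_{xy}$ is the mean pairwise difference per
site computed from allele frequencies; RND divides ingroup $D_{xy}$ by
$D_{xy}$ to the outgroup, cancelling locus-specific mutation rates. RND
is reported only for fragments with at least `min_outgroup_span`
(default 1000 bp) of aligned outgroup sequence — short alignments make
the denominator too noisy to be meaningful.

## The scan

| parameter | default | units | rationale |
| --- | --- | --- | --- |
| `window_size` | 100 000 | bp | resolution/variance compromise for sparse targeted data |
| `step` | 10 000 | bp | 10× overlap smooths island edges |
| `maf` | 0.10 | pooled frequency | removes singletons/doubletons at 24 chromosomes, the classes most affected by genotyping error and most biasing for F\_ST |
| `min_snps` | 5 | SNPs/window | windows below it are never significant |
| `z_threshold` | 3 | SD | "far outside the background" cutoff |
| `fisher_p` | 0.01 | p | raw threshold, no multiplicity correction (see below) |
| `merge_gap` | 50 000 | bp | significant windows closer than this are one island |

Z-scores are centered on the **median** of defined windows (mean is an
option) and scaled by the plain standard deviation. The Fisher exact test
contrasts each window's fixed/shared counts against the genome-wide
totals (the focal window included in the totals; the 2×2 table is window
vs rest-of-genome). The MAF filter is applied *before* both the
F\_ST averaging and the fixed/shared counting by default — fixed
differences always pass a pooled-MAF filter, shared polymorphisms need
not, and using one table for both keeps the two criteria comparable; an
option takes the class counts from the unfiltered table instead.
Fragment-level statistics (π, θ, D, H, D\_xy, RND) are always computed on
the *pre-MAF* table: rare variants and ingroup-monomorphic divergence
sites carry most of their information.

No multiple-testing correction is applied to window Fisher p-values: the
scan is a screening procedure whose final calls require *both* criteria
and whose global significance is assessed by permutation, not per-window
error control.

The permutation clustering test shuffles per-SNP (F\_ST, class) tuples
across SNP positions, recomputes the track, and counts windows with
z ≥ 3; the p-value uses the add-one estimator
$(1 + \#\{perm \ge obs\})/(1 + n_{perm})$, which cannot return 0.

Islands are called per criterion, merged across gaps < 50 kb (gap
comparison is strict, so abutting or overlapping windows always merge;
island count is non-increasing in the merge gap), and intersected:
"both"-criterion islands are unions of overlapping z and Fisher islands
(≥ 1 bp overlap under the half-open convention).

## The isolation-with-migration null

The simulator is a continuous-time structured coalescent for two demes of
diploid sizes $N_1, N_2$ exchanging lineages backwards at per-lineage
rates $m_{12} = M_{12}/2N_1$, $m_{21} = M_{21}/2N_2$ (inputs are the
population rates $2Nm$), merging at $T_{split}$ generations into an
ancestral deme of size $N_{anc}$; mutations follow the infinite-sites
model as a Poisson process on branches, with no intralocus recombination
and loci independent. The core is compiled (Rcpp) and draws all
randomness from R's RNG, so `set.seed()` reproduces every dataset
exactly.

The bundled demography (`im_model_rabbit()`) is the history inferred for
the hybridizing rabbit subspecies that motivate the package's worked
examples: $N_1 = 1.6\times10^6$, $N_2 = 7.8\times10^5$,
$N_{anc} = 4.7\times10^5$, a split $1.8\times10^6$ generations ago
(one-year generations), autosomal $2Nm$ of 1.69 and 0.83 (X: 0.38 and
0.26, with all sizes multiplied by ¾). The mutation rate is not part of
that inference; the default $\mu = 1.25\times10^{-9}$ per site per
generation makes $4N_1\mu = 0.008$ per site, the system's intronic
diversity scale. The fixed:shared ratio is fairly insensitive to $\mu$
(both counts scale with it), which `im_null()` users can verify by
sweeping `mu`.

A replicate dataset is 4,749 independent 1.2 kb loci at 12 chromosomes
per population; its pooled fixed:shared ratio forms the null
distribution. Replicates with fixed differences but no shared
polymorphism count as exceeding any finite observed ratio; replicates
with no variation at all cannot exceed a positive observation.

Engine calibration is part of the test suite: pair-TMRCA of $2N$
generations, $E[S] = \theta a_{n-1}$ and $E[\pi] = \theta$ in a single
deme, the large-sample TMRCA limits $4N(1-1/n)$ (autosomal) and their
¾ X-scaling, and a frozen cross-simulator comparison of the IM-model
mean $D_{xy}$ against an independent coalescent simulator run at
identical parameters.

## Synthetic genomes

`generate_genome()` emulates the structure of a sparse targeted-capture
study: 1.2 kb fragments every 268 kb on three 12 Mb chromosomes, six
diploids per population, one haploid outgroup call per site (sampled from
a lineage isolated for $1.2\times10^7$ generations, putting background
RND near 0.2), genes on a regular grid, centromeres at chromosome
midpoints. Each fragment is an independent coalescent locus simulated
under the background demography above.

Planted islands need a mechanism that produces *fixed differences*,
because under the background demography neutral gene flow makes them
vanishingly rare — that scarcity is precisely what the IM null
quantifies. Islands are therefore simulated as loci resisting
introgression under selection: migration zero inside the island *and*
local effective sizes multiplied by `ne_scale` (default 0.05), a
sweep-mimic representing recurrent selection that accelerates local
lineage sorting. Island loci then sort completely within each
population and accumulate mutations on the two internodal branches
(about $2T\mu L \approx 5$ fixed differences per 1.2 kb locus), while
staying at background divergence to the outgroup — reproducing elevated
RND inside islands.

What passing tests on these genomes do show: the full pipeline recovers
planted islands (two-criterion recall ≥ 90% over 20 seeded genomes with
zero false "both" calls) and stays quiet on island-free genomes (well
under 5% of windows at Fisher p < 0.01). What they do not show: power
against real selective architectures (actual sweeps, polygenic barriers,
recombination-gradient effects), robustness to genotyping error,
coverage or alignment artifacts — the generator has no read-level error
model, emits complete genotypes, and simulates free recombination
between fragments and none within.

## Numerical and degenerate-input conventions

* Statistics that are not estimable are `NA`, never 0: F\_ST with both
  populations monomorphic or fewer than 2 called chromosomes; Tajima's
  *D* at $S = 0$; RND with zero outgroup divergence or a short outgroup
  alignment; enrichment p with zero islands; contrasts with a stratum
  smaller than 2.
* Intervals are 0-based half-open internally; VCF positions convert on
  I/O; BED output is half-open. Abutting islands share no base and do
  not intersect.
* Identical values in both strata of a contrast give p = 1 (the rank
  test's variance vanishes).
* Windows are emitted only if fully contained in the chromosome;
  chromosomes shorter than one window contribute none, with a warning.
* All outputs (including the VCF and JSON report) are written without
  timestamps; a rerun of any seeded pipeline is byte-identical, which
  the test suite verifies by hashing.

## Problem sizes used by the test suite

The acceptance checks run the IM null at 1,000 replicates of 4,749 loci,
TMRCA calibration at 10,000 replicates, oracle-equivalence on 100–1,000
random instances per statistic (tolerance $10^{-10}$; $10^{-12}$ for the
Fisher test), and 20 seeded genomes each for island recovery and neutral
calibration — sizes chosen so the whole suite completes in a few minutes
while keeping Monte-Carlo error well below the tested effects.

## Known limitations

* **Tajima's D is not mean-zero at small samples.** At $n = 12$
  chromosomes and $\theta_{locus} \approx 10$, the expectation of *D*
  under the strict neutral panmictic null is ≈ −0.08 (confirmed against
  an independent coalescent simulator), because the variance
  normalization only asymptotically centres the statistic. Averaging
  thousands of fragments resolves this intrinsic offset at many standard
  errors, so "mean D ≈ 0" should not be used as an engine check at high
  precision; the suite's spectrum checks account for π, θ and the exact
  spectrum instead, and the D centering check is reported at its honest
  value.
* **SNP-level permutation is mildly anti-conservative here.** Permuting
  per-SNP values destroys the genealogical correlation of SNPs within a
  1.2 kb fragment; with one fragment per 100 kb window, observed window
  means are heavier-tailed than the permutation null, inflating the
  false-positive rate to roughly 15% at α = 0.05 on island-free genomes.
  A fragment-level block permutation would be calibrated, but with
  sparse fragments it is nearly powerless for within-window
  concentration, so the package keeps the SNP-level test and documents
  the caveat: treat small permutation p-values on sparse designs as
  evidence of *concentration of differentiation*, not spatial clustering
  alone.
* Within-population spectra under migration are skewed (background-model
  *D* around −0.4): neutrality tests computed inside connected demes
  must be compared against a structured null, not against 0.
* No intralocus recombination, no missing-data or error model in the
  generator, at most 64 sampled chromosomes per locus, and the island
  mechanism is a selection *mimic* — none of which affect the analysis
  functions, only the synthetic benchmarks.
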