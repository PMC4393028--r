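---
title: "Inbreeding, effective population size and selection scans in bottlenecked populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inbreeding, effective population size and selection scans in bottlenecked populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohsel)
```

rohsel analyses SNP-array genotypes from small, strongly bottlenecked
diploid populations — numerically tiny livestock and dog breeds, island
populations, zoo pedigrees. Three questions drive the design: how large was
the population over the recent past (the effective-size trajectory from
linkage disequilibrium), how inbred is each animal (runs of homozygosity,
genomic and pedigree inbreeding coefficients), and which genome regions
were recently under positive selection (the long-range haplotype test).
This vignette documents the models behind each step, the tunable
parameters, the numerical conventions, and the design choices that were
genuinely open.

## Coordinates and containers

All positions are 1-based physical bp; every interval is closed
`[start_bp, end_bp]` and its length is `end_bp - start_bp`, so reported Mb
lengths are position differences, as PLINK reports them. BED output
converts to 0-based half-open on the way out. Genotypes live in a
`genotype_dataset` (samples x SNPs matrix of minor-allele counts, `NA` for
missing — never conflated with the homozygous code 0) and phased data in a
`haplotype_set` (two 0/1 rows per sample). Minor-allele orientation is
recomputed per dataset after import; a tie at frequency 0.5 is broken
towards the lexicographically later allele label so that text and binary
PLINK readers agree exactly. Monomorphic SNPs carry 0 copies of the
(absent) minor allele. Half-missing binary genotypes are rejected rather
than imputed: a genotype is either fully called or missing.

## LD decay and the effective-size trajectory

Within-chromosome r² is computed for all SNP pairs in a distance window
(default 1 kb–50 Mb). With phased input, r² = D²/(p₁q₁p₂q₂), which equals
the squared Pearson correlation of the 0/1 haplotype indicators; with
genotypes it is the complete-case squared correlation of genotype codes
(composite LD) — no phasing step is performed by this package. Pairs are
grouped into half-open distance bins `[kw, (k+1)w)` (default w = 0.1 Mb; a
pair exactly on a boundary goes to the upper bin) and averaged, unweighted,
per bin.

Physical distance maps to genetic distance through a uniform
`recomb_scale` of 1e-8 Morgan/bp (100 Mb = 1 Morgan), using the bin
*midpoint* — deterministic and consistent with fixed-width binning. Each
bin is then inverted through the Sved equilibrium relation

  r² = 1 / (1 + 4 Ne c)   ⇒   Ne = (1 − r²) / (4 c r²),

assigned to a time horizon g = round(1/(2c)) generations in the past (IBD
segments inherited from an ancestor g generations back have mean length
1/(2g) Morgan), and annotated with the per-generation inbreeding increase
ΔF = 1/(2 Ne). Several bins can round to the same g; the trajectory
reports the pair-count-weighted mean Ne per generation. Bins whose mean r²
is exactly 0 or 1 are flagged non-estimable rather than extrapolated.

Two caveats the estimates inherit from the method itself: sample r² is
inflated by roughly 1/(2n) for n sampled chromosomes, which biases Ne
downward at long distances, and a recent admixture pulse creates
long-range admixture LD that masquerades as a very small recent Ne. Both
effects are visible on the synthetic cohorts and are why validation
focuses on the bin range probing generations 5–50 of constant-size
simulations.

## Runs of homozygosity

A ROH is a maximal stretch of consecutive autosomal SNPs in one individual
with **zero** heterozygous calls, at most `max_missing` (default 5)
missing calls, and homozygous calls at both ends — missing SNPs never
anchor a segment, because segment endpoints must be evidence-backed. The
scan is run-based and exact: it enumerates every maximal window satisfying
the constraints (two overlapping maximal windows can coexist when more
missing calls than the budget are interspersed), rather than approximating
through PLINK's proportion-of-window heuristic. A window is reported iff
it spans at least `min_snps` SNPs (the count includes interior missing
sites) **and** at least `min_length_bp` (default 1,000 kb). The unit tests
hold this scan against an independent exhaustive all-substring oracle on
hundreds of randomized fixtures.

The classic `min_snps` choices are 50 and 65; a data-derived alternative
controls the expected number of chance (identity-by-state) runs across the
whole dataset at an error rate α:

  l = log(α / (n_SNP × n_ind)) / log(hom),

rounded to the nearest integer, where `hom` is the mean per-SNP
homozygosity and `n_SNP` the mean genotyped SNPs per individual. For a
cohort of 28 individuals with 168,467 SNPs each and hom = 0.95 at α = 0.05
this gives l = 358. The threshold grows steeply as hom → 1: the more
homozygous the population, the longer a run must be before it is evidence
of autozygosity rather than chance.

Consensus ROHs are computed on SNP support: a SNP is covered for a sample
if it lies inside one of that sample's segments, and consensus intervals
are maximal runs of SNPs covered in *every* sample. No minimum length is
applied to a consensus ROH, and its endpoints are SNP positions.

F_ROH is the summed segment length over a denominator genome size. The
default denominator is the SNP-covered autosome length of the dataset
(sum over chromosomes of last-minus-first mapped position); a fixed
assembly constant (e.g. 2.29e9 bp for the CanFam3.1 dog autosomes) is a
documented override for whole-genome fractions. Restricting to segments of
at least L bp focuses F_ROH on the last round(1/(2 L s)) generations: 500
kb ↔ 100, 780 kb ↔ 64, 4.3 Mb ↔ 12 generations at the default scale.

F_IS for individual i is (O_i − E_i)/(n_i − E_i): observed homozygous
count against the random-mating expectation
E_i = Σ_j (1 − 2 p_j q_j · 2N_j/(2N_j − 1)) over the SNPs genotyped in i,
with the small-sample factor 2N/(2N−1) on expected heterozygosity
(toggleable to the uncorrected form). SNPs called in fewer than two
samples are excluded from both counts.

## Pedigree inbreeding

F is half the additive relationship of the parents, computed by the
tabular method on the pedigree truncated `max_depth` meioses above the
focal animal; ancestors at the horizon keep their identity but lose their
parents, becoming unknown, unrelated, non-inbred founders. This matches
the "last k generations" window semantics of mate-planning software.
Validation pins the textbook anchors (full-sib 0.25, half-sib 0.125,
parent-offspring 0.25) and full agreement with an independent recursive
path-counting implementation. Pedigree completeness is the MacCluer
index — the mean over generations g = 1..d of the fraction of the 2^g
ancestor slots that are filled — chosen because it is the standard measure
where no formula is otherwise specified. The per-generation rate derived
from a mean pedigree F takes its divisor explicitly
(`delta_f_from_fped(mean, k)` = mean/k) because the depth-vs-depth-minus-one
convention varies between studies.

## The long-range haplotype test

Chromosomes are tiled into non-overlapping cores of `core_snps`
consecutive SNPs (default 10; the trailing remainder is dropped). The
distinct allele strings over a core are its core haplotypes. For a core
haplotype with n_h carriers, EHH at distance d in one direction is the
fraction of carrier pairs identical at every SNP from the core edge out to
the last SNP within d:

  EHH = Σ_groups C(n_g, 2) / C(n_h, 2),

1 at distance zero, monotonically non-increasing in d (pairs break, never
re-form), and 0 by convention for single carriers. REHH divides the tested
haplotype's EHH by the pair-count-weighted mean EHH of all *other*
haplotypes at the same core, normalising out local recombination-rate
variation; it is undefined (and excluded from scoring) when the others
contribute no pairs.

Both directions are evaluated at a fixed physical test distance and the
reported REHH is the larger of the two, each direction also being written
out. Scores come from grouping haplotypes into 20 equal-width frequency
bins over (0, 1], standardising ln REHH within each bin, and converting
the z-score to a one-sided upper-tail normal P (selection inflates REHH;
reported as −log10 P). Bins with fewer than two defined members or zero
spread leave their members unscored; haplotypes below frequency 0.1 are
flagged, since the test has little power for rare haplotypes. Candidate
regions pass a core-haplotype frequency floor (default 0.50) and a
−log10 P threshold (default 3), and are exported as BED with a
0.5 Mb flank per side; overlapping extended regions are deliberately not
merged, because adjacent cores may represent one sweep but are evidence
from different windows.

Two open choices are documented rather than asserted: the fixed-distance
evaluation (an EHH-integral would be an alternative; default 1 Mb for
dense real data, but the matching distance scales with the genome — see
below), and the one-sided P (the transform-and-standardise recipe does not
itself fix the tail).

## The Wright–Fisher generator

The simulator breeds discrete generations of a monoecious diploid
population (selfing excluded, as appropriate for dogs) with per-meiosis
Poisson crossovers at `recomb_morgan_per_bp`, recording full parentage and
per-generation expected heterozygosity. Founders carry standing variation
at `n_founder_sites` positions with Beta(0.5, 0.5) allele frequencies.
Infinite-sites mutation is implemented on a pre-allocated reserve of
unused positions, activated one per mutation event; the reserve is sized
to ~1.5x the expectation and exhaustion raises a warning. A single seeded
RNG stream drives every draw, so a fixed seed reproduces results byte for
byte.

Chip-like ascertainment mirrors an array designed on an outbred reference
pool: sites are selected for even physical spacing subject to a *panel*
minor-allele-frequency floor (default 0.05), so sites fixed in the
bottlenecked sample stay on the chip — exactly the mechanism that makes
mean SNP homozygosity approach 0.95 in a severely bottlenecked cohort
while the array remains polymorphic across breeds.

An admixture pulse replaces each gamete of one generation with probability
`fraction` by a migrant gamete drawn site-wise from a migrant
allele-frequency pool (frequencies drawn once per run). We model the
migrant pool by its allele frequencies rather than simulating a second
large population forward in time: at migrant-pool sizes in the hundreds or
more, drift and within-pool LD over the relevant timescale are negligible,
and the pool's identity enters only through the gametes it donates.
Migrant parents appear in the pedigree as unknown-parent founders.

Selection is additive (fitness 1, 1 + s/2, 1 + s) through weighted parent
sampling, in two modes. `standing` selects on the segregating site nearest
the requested position with frequency in 0.2–0.4 — a soft sweep from
intermediate standing variation, suitable for allele-frequency-trajectory
properties but nearly invisible to haplotype tests, because founder sites
start at linkage equilibrium and the allele rides many backgrounds.
`de_novo` introduces a single derived allele on one random chromosome and
conditions the sweep on survival — and optionally on a final frequency
band — by rewinding to the onset generation on failure, the standard
conditioning used in forward simulators. This is the hard sweep with a
single haplotype background that the long-range haplotype test is designed
to detect.

### Bundled fixtures and what they do (and do not) emulate

* `tiny_toy` — 3 samples, ≤10 SNPs, hand-checkable plumbing fixture.
* `bottleneck28` — 28 diploids after 20 generations at size 50, 50 at
  size 12 and a recovery to 30 for the final 5, with a 1/16 admixture
  pulse 5 generations back; 3,000 chip-ascertained SNPs on 3 chromosomes
  of 50 Mb. The genome is scaled down ~50x from a 38-autosome array
  design while keeping a realistic SNP density (20/Mb); the bottleneck
  length was chosen so that mean SNP homozygosity lands near 0.95, the
  regime of interest, giving mean F_ROH around 0.8 and r² above 0.5 in
  the shortest distance bin.
* `sweep_demo` — 28 diploids from a constant size-50 population with a
  de-novo additive sweep (s = 0.8) over the last 12 generations,
  conditioned to finish at frequency 0.5–0.95. The moderate background is
  deliberate: in a severely bottlenecked genome the long-haplotype noise
  floor drowns the REHH signal — a genuine limitation of the test, which
  its original authors noted is designed for large recombining
  populations.

The generator emulates drift, recombination, admixture and selection, but
not: variable recombination maps (the Morgan/bp scale is uniform, so REHH's
raison d'être — rate variation — is absent and REHH ≈ calibrated EHH),
genotyping error (missing calls must be injected downstream), overlapping
generations, or sex chromosomes. Tests passing on these cohorts therefore
validate the estimators' arithmetic and their behavior under idealised
inheritance, not robustness to array artefacts.

### Scaling the scan distance

Haplotype-length scales stretch with the simulated genome. A sweep of age
t generations extends ~1/(2t) Morgan; at the default 1e-8 Morgan/bp a
12-generation sweep spans several Mb, while the neutral background of a
size-50 population founded 40 generations ago decorrelates over ~1 Mb. The
sweep-demo analyses therefore evaluate EHH at 8 Mb, where the background
has decayed but the swept haplotype has not; on a real dense array with
deep coalescent background the matching distance is sub-Mb (the 1 Mb
default). Recovery is assessed at region level — a top-ranked core whose
scan window spans the selected site — because EHH localises selection to a
window, not a point; the core sitting exactly on the locus is in fact
systematically under-scored, as its REHH denominator is the rapidly
coalescing non-swept complement class.

## Validation problem sizes

The test suite validates each stochastic claim at sizes chosen to keep the
whole suite a few minutes long while leaving the checks well-powered: ROH
calling against the exhaustive oracle on 200 random 25–80-SNP fixtures;
drift-law recovery from 8 replicate 50-generation runs (single-trajectory
OLS standard errors are anti-conservative because drift is a random walk,
so the slope is averaged over replicates); constant-N recovery for
N ∈ {25, 50} over 20 seeds each, with the median across bins probing
generations 5–50 required within ±25%; scan power over 25 sweep seeds
(top-5% region recovery in at least 80%) and false-positive calibration
(at most 1% of scored haplotypes beyond −log10 P = 3) over 8 neutral
seeds.

## Known limitations

* The Sved inversion assumes equilibrium; recent admixture or growth
  distorts the most recent generations of the trajectory (visible on
  `bottleneck28`, where admixture LD pushes apparent recent Ne down).
* r² carries an ~1/(2n) sample-size inflation that is not corrected,
  matching the plain estimator the analysis is built around.
* REHH in very small or severely bottlenecked populations has little
  discriminatory power; the package reports scores regardless, and the
  demo fixtures quantify the contrast between regimes.
* The −log10 P > 3 convention for "top 5%" presumes tens of thousands of
  scored core haplotypes with heavy-tailed ln REHH; on small synthetic
  genomes the empirical top-5% cutoff sits far lower, so ranking, not the
  absolute threshold, is the meaningful quantity.
* Pedigree F is only as good as pedigree depth: truncation turns unknown
  coancestry into zeros, biasing F_Ped downwards relative to genomic
  measures in closed populations.

## A worked mini-analysis

```{r example, eval = FALSE}
dir <- tempfile()
fx <- make_fixture("bottleneck28", dir, seed = 1)

cfg <- pipeline_config(list(
  input = list(ped = paste0(fx$prefix, ".ped"),
               map = paste0(fx$prefix, ".map"),
               haps = paste0(fx$prefix, "_haps.tsv"),
               pedigree = paste0(fx$prefix, "_pedigree.csv")),
  roh = list(min_snps = list(50, 65, "auto")),
  scan = list(distance_bp = 8e6),
  pedigree = list(depths = list(5, 11), monoecious = TRUE),
  out_dir = file.path(dir, "out"), seed = 1))

report <- run_pipeline(cfg)
report$table1
plot_ne_trajectory(report$ne_trajectory)
plot_rehh_scores(report$scan)
```
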