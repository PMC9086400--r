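---
title: "Runs of homozygosity, inbreeding and selection scans with rohscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Runs of homozygosity, inbreeding and selection scans with rohscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohscan)
library(dplyr)
```

rohscan analyzes diploid SNP-array genotypes for the footprints that
inbreeding and balancing selection leave on a genome: runs of homozygosity
(ROH) and heterozygosity (ROHet), genomic inbreeding coefficients, the
burden of deleterious variation and its concentration inside ROH, population
hotspots of both run types, and windowed Tajima's D and a folded β statistic
for balancing selection. A pedigree gene-dropping simulator with exact
identity-by-descent (IBD) tracking supplies ground truth for every stage, so
the whole pipeline is testable without any external data. This vignette
explains the methods, the tunable parameters, and the design choices made
where conventions differ between tools.

## The run caller (consecutive method)

Runs are detected by a linear scan of each individual's genotypes along the
marker map, not by sliding windows. A candidate run starts on a *conforming*
genotype (homozygous for ROH, heterozygous for ROHet) and extends SNP by SNP
while three allowance budgets hold:

* at most `max_opposite` interior opposite genotypes (default 1 heterozygote
  in an ROH, 3 homozygotes in an ROHet) — absorbing occasional genotyping
  errors;
* at most `max_missing` interior missing calls (default 2);
* no gap between adjacent SNPs larger than `max_gap_bp` (default 1 Mb).

When a constraint is violated the candidate closes, is trimmed so both
endpoints are conforming calls, and is emitted if it spans at least
`min_snps` SNPs (default 15) and `min_length_bp` base pairs (default 500 kb,
endpoints inclusive, so `length = end - start + 1`). Defaults follow the
standard medium-density chip parameterization for both run types.

Three details are dialect choices on which published tools differ, and are
therefore explicit, documented and tested here:

* **Trimming.** Allowed opposite/missing genotypes are interior only; a run
  never starts or ends on one. This prevents allowance SNPs from inflating
  run length.
* **SNP counting.** `n_snps` counts every SNP the run spans (conforming plus
  allowed); `min_snps` is tested against that count. The conforming-only
  alternative is available via `conforming_only_min_snps = TRUE`.
* **Restart rule.** After a violation, scanning restarts at the SNP after
  the violator. A gap violation is a property of the interval rather than of
  a genotype, so scanning restarts *at* the right-hand SNP of the gap, which
  is not itself faulty. This gives a deterministic linear-time scan; runs of
  one individual never overlap.

The test suite holds the caller against an independent exhaustive scanner
(whole-window recounts via cumulative sums) on hundreds of random panels
across the full parameter range, and against simulated cohorts where every
IBD tract of at least 1 Mb must be covered ≥ 90% by an emitted ROH.

ROH lengths are classified into 0.5–2, 2–4, 4–8, 8–16 and > 16 Mb bins and
ROHet lengths into 0.5–1, 1–1.5, 1.5–2 and > 2 Mb bins, all half-open
`[lo, hi)`, so a 2.0 Mb ROH belongs to 2–4 Mb.

## Inbreeding coefficients

Two estimators are computed per individual:

* `F_HOM = (H_O - H_E) / (L - H_E)` from SNP-by-SNP excess homozygosity.
  `L` counts the individual's non-missing autosomal genotypes — the natural
  reading of "genotyped SNPs" when samples differ in missingness. `H_E`
  sums `1 - 2 p (1 - p) \cdot 2N_s/(2N_s - 1)` over those SNPs, with `p` the
  cohort allele frequency and `N_s` the non-missing genotype count at the
  SNP; the `2N_s/(2N_s - 1)` factor is the usual small-sample correction of
  the method-of-moments estimator and can be switched off.
* `F_ROH = L_ROH / L_auto`, the fraction of the autosomal genome inside
  ROH. `L_auto` always comes from a `genome_build()` (2.46 Gb for the goat
  autosomes; simulated genomes supply their own), never from a hard-wired
  constant, so synthetic and real genomes scale alike. The per-length-class
  decomposition restricts the numerator to one class and sums exactly to the
  total.

Run length also dates the inbreeding event: a segment inherited intact from
an ancestor `g` generations back has expected length `100/(2g)` cM, so
`g = 100 / (2 L cM)` with the 1 cM ≈ 1 Mb livestock map scale. A 16 Mb ROH
points to ~3 whole generations, an 8 Mb ROH to ~6. The simulator reproduces
this expectation: mean recorded IBD tract lengths for full-sib (g = 2) and
first-cousin (g = 3) matings match 25 Mb and 16.7 Mb within 25% on a 200 Mb
chromosome (shorter chromosomes truncate long tracts and bias the mean
down, which is why that check uses a long chromosome).

Parameter recovery is part of the acceptance suite: across 200 gene-dropped
offspring, mean F_ROH lands in [0.20, 0.30] for full-sib matings
(expectation 0.25) and [0.035, 0.095] for first-cousin matings (expectation
0.0625), and F_ROH correlates with pedigree F at r > 0.8 on a mixed
pedigree. The mixed-pedigree check runs on a 10 × 100 Mb map: realized
autozygosity has substantial Mendelian sampling variance, which shrinks with
map length, and a livestock-scale genome is the regime the estimator is used
in. F_HOM centers on zero (|mean| < 0.02) in randomly mating cohorts and
correlates strongly with F_ROH when inbreeding varies. The recovery
experiments likewise run on multi-chromosome maps (10 × 50 Mb): on a
1-Morgan toy genome the per-offspring sd of realized autozygosity (~0.22)
would dominate the recovery bands, which would then test the luck of the
seed rather than the estimator.

## Genetic load and its concentration in ROH

Alleles are polarized against a wild outgroup: the ancestral allele is the
one with outgroup frequency above 0.5; an exact tie or an uncovered SNP
stays unpolarized and is excluded from every count rather than guessed.
Missense variants with SIFT ≤ 0.05 (inclusive) are *deleterious*, the union
with loss-of-function variants is *damaging*; SNPs annotated with several
consequences collapse to the most severe (LOF > missense > synonymous >
other). Per individual, the load ratios are

* `load_het = n_del_het / n_syn_het`,
* `load_hom = n_del_hom / n_syn_hom` (homozygous for the *derived* allele),
* `load_total = (n_del_het + 2 n_del_hom) / (n_syn_het + 2 n_syn_hom)`,

with zero denominators flagged undefined. For the ROH-enrichment analysis,
ROH are split into medium (A: 0.5–4 Mb) and long (B: ≥ 4 Mb) classes; per
individual `G_j = L_j / L_g` is the genome fraction in class j (R = A ∪ B,
N = outside, so `G_A + G_B = G_R` and `G_R + G_N = 1`), every damaging
derived homozygote is assigned to A, B or N by position (run endpoints
inclusive), and the damaging fraction per class is correlated with `G_j`
across individuals.

One property of these correlations deserves emphasis because it shaped the
validation design: the fraction of an individual's damaging homozygotes in
class j tracks `G_j` *mechanically* — ROH concentrate homozygotes of every
kind, and long-ROH coverage varies most between individuals — so r for long
ROH exceeds r for medium ROH even when damaging labels are placed uniformly
at random. The correlation contrast (here typically ~0.9 vs ~0.45 on
mixed-inbreeding cohorts) therefore demonstrates the genome-coverage
geometry, while *preferential placement* is a statement about variants and
is verified at the variant level: the damaging share among derived
homozygotes inside long tracts versus outside (a two-proportion test),
which is significant exactly when the generator plants enrichment and
non-significant under uniform placement.

## Hotspots

Per population and SNP, incidence is the percentage of individuals whose
runs cover the position — the denominator is the whole population,
including run-free individuals. The hotspot threshold is the value at the
`ceiling((1 - f) n)`-th ascending order statistic of the incidence
distribution over *all* panel SNPs, zeros included (the zeros materially
lower percentile cutoffs, and breed-specific cutoffs are the point of a
percentile rule); `f` defaults to 0.005 for ROH and 0.001 for ROHet. SNPs
at or above the threshold are selected — ties included — and merged into
maximal regions only across SNPs adjacent in map order, which keeps region
counts deterministic. Candidate genes are collected in 100 kb windows (± 50
kb) around hotspot SNPs, clipped at position 1 and the chromosome end, and
hotspot sets from several populations can be intersected genomically to
report shared islands.

## Balancing-selection scan

Both statistics run on non-overlapping 250 kb tiles by default ("sliding"
with step = width; the step is exposed if overlapping windows are wanted).

**Tajima's D** per window uses the classical constants at `n = 2 ×`
samples: `π` sums per-site `2 j (n_s - j) / (n_s (n_s - 1))` with `j` the
alternate-allele count and `n_s` the non-missing chromosome count (missing
calls enter through `n_s`), `θ_W = S/a1`, and
`D = (π - θ_W) / sqrt(e1 S + e2 S(S-1))`. Windows with `S = 0` are flagged
undefined. The implementation is pinned to a hand-computed value at
(n = 10, S = 5, π = 2.0) to 10⁻⁶.

**The β statistic** is a folded allele-frequency-correlation score: for a
core SNP with folded frequency `f_c` (cores need `f_c ≥ min_core_maf`,
default 0.05), each supporting SNP is weighted by
`w_i = ((0.5 - |f_i - f_c|)/0.5)^p` with `p = 2` by default. The weighted
site count becomes a θ estimate by dividing by the weight expected per unit
θ under the neutral folded frequency spectrum,
`D_norm = Σ_j w(j/n) (1/j + 1/(n-j)) / (1 + [j = n-j])`, and
`β(core) = Σ w_i / D_norm - S / a1`; the window score is the mean over
cores. Three properties are the contract, all tested: β is identically zero
in the flat-weight limit (`p = 0`, where `D_norm = a1`); β is positive and
top-ranked where intermediate-frequency variants cluster (the planted
balanced region ranks in the top 5% of windows in 20/20 seeded replicates);
and β is exactly invariant to allele-label swaps because it sees only
folded frequencies. Exact numerical equivalence with any external β
implementation is not claimed.

Z-scores standardize each statistic over all defined windows genome-wide,
and p-values are upper-tail normal probabilities — a positive D or β is the
balancing-selection signal, so the upper tail is the interesting one —
with `p < 0.05` flagging extreme windows.

## The synthetic cohort generator

`sim_config()` describes a chip-like panel; the desk default is 2
chromosomes × 50 Mb at 25 kb spacing (4,000 SNPs), a scaled-down stand-in
for a ~50K panel that keeps test runtimes in seconds while staying dense
enough that every run of interest spans dozens of SNPs. Founder B-allele
frequencies are uniform on [0.05, 0.95]; founder haplotypes are drawn
independently per SNP, so there is *no background linkage disequilibrium* —
runs and frequency statistics behave correctly, but LD-based analyses would
not, and passing tests say nothing about LD structure in real data.
Balanced regions are the exception: there, haplotypes come from two
divergent allelic classes (B-allele probabilities 0.9/0.1 per SNP, 2% flip
noise) held at an equilibrium frequency, which creates the excess of
intermediate frequencies and heterozygous clusters that long-term balancing
selection maintains.

Gene dropping uses Haldane (no-interference) crossovers at 1 cM/Mb —
matching the dating formula's map scale — with Poisson crossover counts and
uniform breakpoints. Descent labels are carried per SNP alongside alleles,
so autozygous tracts are recorded *exactly* as maximal runs of SNPs whose
two labels agree, and pedigree F comes from the tabular (path-counting)
method. Genotyping noise is applied per call (symmetric errors, then
missingness). The true ancestral allele is the founding major allele
(random side at an exact tie); the outgroup (n = 24, emulating a wild
reference panel) draws its per-SNP ancestral-allele frequency from
Beta(9, 1) — near fixation with drift noise — realized as binomial
haplotype sampling, so polarization accuracy is high but imperfect and
testable (≥ 95% correct where the outgroup frequency is ≥ 0.7).

Damaging-annotation placement has two modes. `uniform` labels SNPs at
random. `enriched_in_recent_haplotypes` weights the label draw by the
*concentration* of a SNP's derived homozygotes inside long (≥ 4 Mb) true
tracts — concentration rather than count, since counts would simply favor
high-frequency SNPs — planting the biological situation where recent
deleterious mutations ride the haplotypes that long ROH expose. Annotation
class proportions default to 10% synonymous, 6% missense (30% of them
SIFT-deleterious) and 0.5% LOF: deliberately generous relative to a real
chip so load counts are informative at desk scale.

All generator randomness derives from one seed (stage-offset seeds for the
founder pool, the gene drop and the noise/annotation layer), making every
emitted dataset bit-reproducible.

## Numerical and degenerate-input conventions

* Positions are 1-based inclusive internally; every BED export converts to
  0-based half-open.
* QC runs in a fixed single-pass order — non-autosomal SNPs, sample call
  rate, SNP call rate, MAF — each step computed on the survivors of the
  previous one, with no Hardy–Weinberg filter (inbreeding is a cause of HWE
  deviation, not an artifact to remove). A sample sitting exactly at the
  call-rate margin can, after SNP removal, fall below threshold on a second
  application; strict idempotence is guaranteed only away from the margin,
  which is where real cohorts live.
* Undefined quantities are flagged, never silently dropped: allele
  frequencies with no calls, F_HOM on a monomorphic panel, correlations
  with < 3 pairs or zero variance, D with S = 0, β without supporting SNPs,
  CV of populations of size 1, load ratios with zero denominators.
* Pearson correlations use the exact t-transform with n − 2 degrees of
  freedom for two-sided p-values.
* The problem sizes used by the validation suite — 100 random panels for
  the caller oracle, 200 offspring per mating design, 20 balancing-scan
  replicates, 2,000-SNP hotspot panels — were chosen as the smallest scales
  at which the statistics under test are stable, and are stated in the test
  code.

## Known limitations

* No background LD in the generator (a block-copying hook would be the
  natural extension); no coalescent demography; no selection dynamics
  beyond the static balanced-region construction.
* The run caller is the consecutive method only — no sliding-window or
  HMM-based calling, and no sequencing-depth input.
* β here is a reconstruction governed by its stated properties, not a
  re-implementation of any specific external tool; its absolute values are
  not comparable across tools.
* Text PED/MAP and VCF (GT only) are the supported formats; binary
  PLINK files, phasing, imputation and liftover are out of scope.
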