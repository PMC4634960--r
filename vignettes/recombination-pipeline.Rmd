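---
title: "Mapping sex-specific recombination from SNP pedigrees"
author: "recpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping sex-specific recombination from SNP pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recpipe)
```

## The problem

Meiotic crossovers can be observed directly in genotyped livestock
pedigrees.  In a three-generation family — an offspring, its sire and dam,
and the grandparents — the grandparental genotypes let each parental
haplotype be labeled as grand-paternal or grand-maternal.  A crossover in
the gamete a parent transmitted then shows up as a switch of grandparental
origin along the offspring's inherited haplotype.  Because dairy-cattle
pedigrees contain both sire/offspring and dam/offspring pairs, the same
machinery yields *male and female* recombination maps on an equal footing,
something sperm-typing or sire-only designs cannot do.

`recpipe` implements that full analysis as composable stages:

1. **simulate** a genotyped pedigree with known crossovers (`sim_config()`,
   `simulate_pedigree()`),
2. **extract** analyzable three-generation families (`extract_families()`),
3. **phase** each trio by Mendelian rules (`phase_families()`),
4. **call** crossovers from origin switches (`call_crossover_set()`),
5. **fit** per-interval recombination rates by EM (`em_fit()`),
6. **call hotspots** and per-animal hotspot usage (`call_hotspots()`,
   `hotspot_usage()`),
7. **scan** for loci associated with recombination phenotypes under a
   weighted linear mixed model (`fit_null()`, `lmm_scan()`),
8. **diagnose** positional profiles, time trends and suspicious SNPs
   (`position_profile()`, `time_trend()`, `ld_screen()`).

`run_pipeline()` chains the stages from a single (YAML or list)
configuration and writes headered, deterministic TSVs plus a manifest.

## Phasing rules

Within a family, a homozygous genotype phases trivially; a heterozygous
genotype phases whenever the two parents are *not both heterozygous* (the
unique transmission consistent with Mendelian inheritance is then forced).
Parents are phased the same way against the grandparents; when the granddam
is not genotyped, a heterozygous parent site is phased only if the grandsire
is homozygous, his allele defining the parent's paternal haplotype.  Three
deliberate choices where the rules leave room:

* a site with a missing genotype in any required member is left unphased for
  that rule (conservative; homozygous sites still phase trivially),
* Mendelian-inconsistent sites are masked — never "corrected" — and counted;
  families with more than 2% inconsistent sites are flagged,
* no LD and no multi-offspring information is used, so paternal and maternal
  meioses are treated identically and bulls with hundreds of progeny get no
  extra phasing power.

A site is *informative* for a meiosis when the transmitting parent is
heterozygous with known phase and the offspring's transmitted allele is
assigned; roughly a quarter to a third of SNPs are informative per meiosis
under chip-like allele frequencies.

## Crossover calling

A crossover is called at each switch of grandparental origin supported by at
least `min_support = 3` consecutive informative SNPs on both flanks.  Runs
shorter than the support threshold are treated as *unresolved*: they neither
produce calls nor break the flanking runs, so an isolated discordant SNP
(typically a genotyping error) is ignored, and a genuine double crossover
inside a short run is missed — the calls are deliberately *observed*
crossovers, a slight undercount of true ones.  "Consecutive" is read as
consecutive among informative sites; `require_adjacent = TRUE` switches to
the stricter reading (no interleaved uninformative SNPs), which we default
off because informative sites are interleaved with uninformative ones
everywhere on real chips.  The called region spans from the last supporting
SNP of the left run to the first supporting SNP of the right run; the m
adjacent-SNP intervals between them (half-open `(pos_i, pos_{i+1}]`,
1-based) are the region's support for map fitting.  No map function is
applied at calling time: at chip densities the inter-SNP distances are a few
hundredths of a centimorgan, where rate and distance coincide numerically.

## The EM map

Each called region localizes one crossover to m intervals.  The EM starts by
assigning 1/m expected counts to each interval of every region; the M-step
divides each interval's total expected count by the number of meioses n to
get the rate estimate, and the E-step re-allocates each region's single
event over its intervals proportionally to the current rates.  Two exact
invariants hold at every iteration and are property-tested: the total
fitted mass times n equals the number of regions, and the observed-region
log-likelihood never decreases.  On instances small enough for brute force,
the fixed point agrees with a grid-search multinomial MLE.

Numerical choices: convergence at a maximum absolute rate change below
`tol = 1e-8` with `max_iter = 5000`; intervals never covered by a region
stay at exactly zero (the EM's natural absorbing state — no floor is
applied); a region whose intervals all carry zero mass re-seeds uniformly.
Rates are reported as expected crossovers per meiosis (Morgans); Haldane
lengths (`-log(1 - 2c)/2` per interval, computed with `log1p`) are offered
as an alternative output and always dominate the raw lengths.

Meioses on sparser chips reveal fewer crossovers, so scalar crossover-count
phenotypes are rescaled per chip category to the all-50K reference mean
(`chip_correct()`); maps themselves should be fitted from the densest-panel
meioses only.

## Hotspots and usage

Hotspots are intervals whose rate strictly exceeds the genome-wide mean plus
`k_sd = 2.5` standard deviations, computed over all autosomal intervals
without distance weighting (cutoffs 2–10 are supported for sensitivity
sweeps).  A distance-standardized variant divides rates by interval length,
drops intervals under 500 bp, and uses a 0.6-SD cutoff, since
standardization compresses the scale.  Hotspot *usage* — the proportion of
an animal's crossovers falling in hotspots — allocates each region's single
event across its intervals proportionally to the fitted rates (the EM
posterior of the event's location); a hard majority-assignment alternative
is available via `method = "hard"`.  Usage is averaged per animal over its
meioses with at least one crossover, and the meiosis count becomes the
LMM weight.

## The weighted mixed model

Animal-level phenotypes are means over repeated meioses, so their residual
variance shrinks with the number of measurements w.  The scan model is

$$y = Xg + Za + e, \qquad a \sim N(0, A\sigma_a^2), \qquad
  e \sim N(0, R\sigma_e^2), \quad R = \mathrm{diag}(1/w),$$

with A the VanRaden method-1 genomic relationship matrix from observed
allele frequencies (mean-imputed missing dosages, `1e-8` diagonal ridge).
Variance components are REML-estimated once on the null model by profiling
the ratio $\lambda = \sigma_a^2/\sigma_e^2$ on the spectrum of the
weight-standardized A, then held fixed for all SNPs — the standard
single-fit approximation that makes genome-wide scans tractable; an exact
fit is just `fit_null()` re-run with the SNP as a covariate.  Per SNP the
test is generalized least squares with a re-estimated residual scale, i.e.
an exact t-test given the correlation structure; with unit weights and
A = I the scan therefore reproduces ordinary regression to machine
precision, which is tested.  Conditional scans add chosen SNPs as fixed
covariates; `lmm_joint()` fits all significant SNPs simultaneously.  The
default significance threshold is Bonferroni 0.05 divided by the number of
tests actually run.  Pre-scan filtering drops SNPs with MAF < 0.001 and
greedily prunes pairs with |r| > 0.95 within a 50-SNP sliding window
(duplicates always go); the window-greedy procedure is our concretization of
a redundancy rule usually stated without an algorithm.

## Diagnostics

Positional profiles put interval midpoints on a relative 0–1 scale per
chromosome, trim 2 Mb from each end (where sparse coverage depresses
detection power), and fit `smooth.spline` with 5 degrees of freedom —
pooled across autosomes and optionally per chromosome or per
single/double-crossover stratum.  Time trends adjust meiosis-level counts by
OLS for chip categories, inbreeding and informative-SNP counts before
smoothing on birth year, and report the inbreeding coefficient's effect.
The two-point screen computes, against every same-chromosome SNP, the
recombinant fraction among phase-known meioses (capped at 0.5) and
LOD = log10 L(r̂)/L(0.5) with L(r) = r^R (1−r)^(N−R); a SNP is flagged
*suspicious* when its LOD argmax sits more than 10 Mb from its mapped
position or the 5-Mb-binned LOD profile fails to decay monotonically (5%
tolerance of the peak).  The published screens of this kind are visual;
the argmax-distance and monotone-decay rules are our explicit,
reproducible proxy, and the thresholds are exposed as arguments.

## What the simulator does and does not emulate

The generator reproduces the features that matter for validating this
pipeline: a multi-generation pedigree with sires shared across families
(AI-bull structure) and full-sib dam groups; grandsires always genotyped and
each granddam genotyped with probability 0.5695 (an expected 1.14 genotyped
granddams per family, matching large dairy pedigrees; independence across
granddams is a simplification — the real 2/1/0 mix is slightly
overdispersed relative to it); 29 autosomes totalling 2,516 Mb with ~54,000
SNPs allocated proportionally to length; chip-SNP MAF drawn
Uniform(0.05, 0.5); sex-specific genetic lengths of 25.5 and 23.2 Morgans
allocated proportionally to physical length; Poisson crossovers by default
(gamma-renewal spacing with shape ν > 1 available for interference, thinned
chiasma model); optional designated hotspot intervals carrying a chosen
share of map mass; nested chip panels masked after truth is recorded; and
uniform dosage-flip genotyping error.  Error and missingness rates of real
chips are not published, so they default to zero and are meant to be
sensitivity-swept.

Founders are linkage-equilibrium draws: there is **no background LD**, no
selection, no mutation and no sex chromosomes.  Family-rule phasing uses no
LD, so this does not flatter the pipeline, but it does mean passing tests
say nothing about LD-dependent steps (none are implemented) or about real
assembly errors, which the LD screen can only be shown to catch in the
constructed-misplacement sense.  Each chromosome consumes its own seeded RNG
stream, so simulating a chromosome subset reproduces the corresponding slice
of a full-genome run bit for bit — which is how the genome-wide power study
keeps its memory footprint at one chromosome.

## Validation scales

The test suite validates at sizes chosen to separate signal from Monte-Carlo
noise while staying desk-sized: the power study uses 500 families (≈24,000
true crossovers, binomial SE ≈ 0.1 pp) at full 54K density; EM recovery uses
50,000 meioses on a 2.5-Morgan chromosome with 2,000 SNPs; phasing
exactness uses 5,000 families (10,000 meioses) on two chromosomes; GWAS
calibration uses 2,000 animals × 5,000 SNPs; hotspot-usage recovery uses
20,000 meioses against a designed 3%-of-bp / 25%-of-mass hotspot map.
Region-level validation (`simulate_crossover_regions()`) draws observed
regions directly from a genetic map through a random informative-SNP mask —
double crossovers inside one uninformative gap cancel, as in real data —
which exercises the EM and usage machinery without the cost of full family
simulation.

## Known limitations

* Observed crossovers undercount true crossovers when multiples land between
  the same informative SNPs; the EM fits the observed process.
* The chip correction is a mean-matching rescale of scalar counts; it does
  not redistribute events positionally, so low-density meioses should not
  contribute to maps.
* The LMM holds variance components at their null estimates per scan
  (EMMAX-style); for traits with very large single-SNP effects the per-SNP
  exact fit is the fallback.
* `extract_families()` requires both grandsires genotyped, mirroring the
  three-generation design; families informative on one side only are
  discarded rather than half-used.
* Cattle autosomes are acrocentric, so "subtelomeric" means the terminal
  15% of each chromosome by physical length; for metacentric karyotypes the
  definition would need both ends.

## A small end-to-end run

```{r example, eval = FALSE}
cfg <- pipeline_config(
  sim = list(n_chromosomes = 2, chrom_lengths_bp = c(8e7, 6e7),
             n_snps = 2000, total_male_morgans = 1.6,
             total_female_morgans = 1.4),
  n_families = 120, seed = 500)
res <- run_pipeline(cfg, "run1")
res$shared$n_shared            # hotspots shared between the sexes
map_summary(res$maps$M, res$maps$F)$genome
```
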