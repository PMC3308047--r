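---
title: "Population-genetic analysis of exome variant call sets: models and methods"
author: "ExomePopGen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-genetic analysis of exome variant call sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ExomePopGen)
library(SummarizedExperiment)
```

## Scope

ExomePopGen implements the downstream, population-genetic half of a deep
exome-capture resequencing study: everything that happens after reads have
been mapped and genotypes called. Its inputs are variant call sets (VCF),
capture target regions (BED), a sample panel mapping samples to populations
and continents, gene models, and a reference sequence. Its outputs are
filtered and intersected call sets with QC summaries, functional site
annotations, per-base diversity estimates, allele frequency spectra,
cross-population allele-sharing estimates, frequency-binned functional
enrichment tests, and validation-assay arithmetic. Read mapping, duplicate
marking, base-quality recalibration and the Bayesian genotype callers
themselves are out of scope; the package consumes their outputs.

Because the real study data are large and external, the package ships a
first-class synthetic cohort generator with known ground truth. Every
analysis stage is exercised, and its statistical behaviour verified, on
simulated cohorts.

## The synthetic cohort generator

`simulateCohort()` draws polymorphic sites per functional class (silent,
missense, nonsense by default) under a neutral infinite-sites model:

* **Ancestral frequencies** follow the density proportional to $1/x$ on
  $(\varepsilon, 1)$ with $\varepsilon = 1/(2N_e)$ and an effective
  population size $N_e = 10{,}000$ by default. This is the stationary
  frequency density of neutral polymorphism, and it makes the expected
  unfolded sample spectrum proportional to $\theta/i$ for derived allele
  count $i$. The truncation point matters: flooring frequencies at one copy
  *in the sample* (i.e. $\varepsilon = 1/n$) would deplete the singleton bin
  by a factor $(1-1/n)^n \approx e^{-1}$ and break the $\theta/x$ null that
  the acceptance checks verify; with $\varepsilon = 1/(2N_e)$ the distortion
  of the singleton bin is below one percent for the sample sizes used here.

* **Population structure** follows a two-level Balding–Nichols model: a
  continent-level frequency is drawn from a Beta distribution with mean
  equal to the ancestral frequency and variance $F \, p(1-p)$, then each
  population's frequency is drawn the same way around its continent value.
  Each level carries $F = f_{st}/2$, so populations within a continent
  resemble each other more than populations across continents — the pattern
  real panels show. Default $f_{st} = 0.08$.

* **Selection** is a single knob: ancestral frequencies of the selected
  classes (missense and nonsense by default) are multiplied by
  `selectionSkew` (default 0.5; acceptance power checks use 0.25) and
  re-truncated (clamped) at $\varepsilon$. This enriches rare alleles in
  amino-acid-changing classes the way purifying selection does, without
  modelling fitness explicitly.

* **Genotypes** are Hardy–Weinberg binomial draws per sample. Only sites
  polymorphic in the realized sample are kept (exactly `nSites` per class);
  the number of rejected monomorphic draws is recorded and converted to an
  implied surveyed length $L = \text{draws}/(\theta \ln(1/\varepsilon))$ per
  class, stored as `classBases` in the truth metadata. This is the
  denominator that lets Watterson's $\theta_W = S/(a_{n-1} L)$ and per-base
  heterozygosity recover the configured $\theta$ — a genuine consistency
  property of the generator, not a bookkeeping identity. Sites monomorphic
  *after* down-sampling, projection or sample subsetting still arise and are
  handled by the analysis code.

* **Coverage** is a shared per-target log-normal effect (default
  $\sigma_{\log} = 0.7$, reproducing strong target-to-target heterogeneity)
  times a per-sample gamma effect (shape 10) times the mean depth (default
  48×, the study-scale average). Genotypes at zero-depth sample-sites are
  missing. Site quality, QD, genotype qualities and allele depths are filled
  in at levels consistent with the depths so that the filtering stages run
  end to end on simulated data; they are plumbing, not a sequencing-error
  model.

* The default panel is seven populations in three continental groups with
  sample sizes 112/108/109/107/105/90/66 — the scale of a deep multi-panel
  exon study. Smaller panels are used in tests purely to keep runtimes
  short; the vignette and tests state the sizes they use.

What the generator does **not** emulate: linkage disequilibrium and
recombination (sites are independent), demographic history beyond the skew
knob (no growth, so the real data's extra excess of rare variants is not
reproduced), read-level errors, and capture dropout correlated with
sequence content. Passing tests therefore demonstrate the correctness and
calibration of the estimators under a clean neutral-plus-structure model,
not agreement with any particular real cohort.

Determinism: one root seed; fixed offsets derive substreams for site
drawing, depths and genotype corruption, so stages can be re-run
independently and whole runs are byte-identical under the same config.

## Site filters and call-set QC

Two filter suites mirror the two calling pipelines whose intersection forms
a release call set:

* the joint-calling pipeline's quality rule: site quality $\ge 40$ and at
  least one sample carrying a non-reference genotype with genotype quality
  $\ge 10$;
* the per-population pipeline's covariate rules: QD (site quality over
  covered depth) $\ge 5$ **passes** — the other covariates are failure
  conditions: adjacent allele-sharing homopolymer run (HRun) $> 3$, mean
  reference allele balance over heterozygotes $\ge 0.75$, and membership in
  a cluster of $\ge 3$ variants spanning $\le 10$ bases. HRun is the longer
  of the two runs flanking the variant (the convention when "adjacent" is
  otherwise ambiguous); sites with no heterozygotes pass the AB rule, whose
  target is het-site artifacts.

`intersectCallsets()` partitions two call sets by (chrom, pos, ref, alt);
`summarizeCallset()` reports size, percent known (against a user-supplied
known-sites list) and Ts/Tv, the standard QC trio in which a shared, known,
transition-rich call set signals quality. Indels are merged across call
sets by clustering same-type events within 5 bp transitively; each cluster
emits the leftmost position with the alleles of its highest-AC member.
Indel site filters drop sites lacking a sample with $\ge 2$ variant reads
and 1-bp singletons.

## Annotation

Degeneracy of a coding position counts, strand-aware under the standard
genetic code, how many of the three possible substitutions are synonymous
(0/1/2/3 → non-degenerate/two-/three-/four-fold). Amino-acid effect is
silent/missense/nonsense; stop-loss is folded into missense because the
three-way scheme has no separate category. Positions in several transcripts
are classified once per transcript context and de-duplicated within a
class. SIFT and PolyPhen-2 predictions are consumed as labels and combined
under either of two selectable rules: the three-class rule (matched
severities, or a single prediction, give their class; any conflict lands in
"possibly damaging" — the convention used when comparing against disease
databases; a lone middle-severity prediction also lands there), or the
"severest wins" ordinal rule used for frequency-spectrum displays.

## Diversity and spectra

Per-site heterozygosity is the differing-pair fraction
$2j(n-j)/(n(n-1))$; per-base estimates divide the sum over callable variant
sites of a class by the class's callable base count, and are displayed
scaled by $10^4$ (raw values are always returned, since the unit convention
is display-only). A base is callable when at least 100 chromosomes (2 per
sample) have $\ge 10\times$ depth. Chromosome counts per site use
non-missing genotypes only.

Spectra are built unfolded (derived allele, requiring an ancestral base
that matches one of the two alleles; others are excluded) or folded (minor
allele). Sites whose non-missing chromosome count exceeds the target $n$
are projected down per site with the hypergeometric expectation
$$c'_i = \sum_j c_j \binom{j}{i}\binom{n-j}{m-i}\Big/\binom{n}{m},$$
which is also exposed as `projectAFS()` for whole spectra. Projected counts
stay fractional; mass landing in bins $0$ and $m$ is tracked separately so
segregating-site totals remain interpretable. Projection is linear and
composition-consistent (projecting via an intermediate size changes nothing
beyond $10^{-10}$), and no correction for ancestral misidentification is
applied. Watterson's $\theta_W = S/a_{n-1}$ and the neutral expectation
$\theta/i$ complete the module.

## Allele sharing

The sharing statistic asks: given two minor alleles drawn at random without
replacement from all minor alleles at a site, what is the probability they
come from the same population, different populations of one continent, or
different continents? For per-population minor counts $c_p$ with
$C = \sum c_p \ge 2$ these are exact ratios of ordered pair counts
(singletons cannot be shared and are removed). The panmictic expectation
substitutes panel chromosome counts for allele counts and is independent of
allele frequency — which is why departures of the rare bin from it are
informative.

Because panels differ in size, each population is down-sampled to a common
target (by convention 90% of the smallest panel) by independent
hypergeometric reduction. Per site the statistic is averaged over
down-sampling outcomes conditional on $\ge 2$ surviving minor alleles, and
sites are combined weighted by that survival probability. The conditional
expectation is computed by exact joint enumeration when $C \le 12$ (the
joint hypergeometric support is small) and by seeded Monte Carlo otherwise;
the two routes agree within Monte Carlo error and the threshold is
configurable. The minor-allele label is fixed from the full sample before
down-sampling — re-polarizing per draw would make the site-level label
ill-defined. Confidence intervals are percentile bootstrap over variant
sites, deterministic under the seed. Estimates are reported per minor-AF
bin (< 0.01, 0.01–0.1, 0.1–0.5).

## Enrichment

Sites are binned by minor allele frequency into low (< 1%), intermediate
(1–10%, both ends included — matching the printed labels "<0.01" and
">0.1") and common (> 10%). Class contrasts use a chi-square test of
homogeneity on the 2×3 class-by-bin table, reporting also the per-class
low-bin fraction. Per-bin variant error rates (for example 6.2% / 3.2% /
3.4% for low/intermediate/common — the assignment of printed rates to bins
follows the order in which the bins are discussed and is an interpretive
choice) deflate counts to expected true positives, $c'_b = c_b(1-e_b)$;
the chi-square on these fractional counts is used as a score with the same
reference distribution. Calibration is checked by simulation: across 1,000
null cohorts the 5% rejection rate stays within (0.03, 0.07), and at
`selectionSkew = 0.25` with 5,000 sites power exceeds 0.95 at
$\alpha = 0.01$.

## Validation arithmetic

`planSeries()` draws stratified validation samples without replacement,
warning on shortfall. `validationRate()` is conclusive-assay arithmetic
(inconclusive assays never enter denominators; display rounds to one
decimal, full precision is kept). `genotypeAccuracy()` reads a 3×3
called-vs-assayed table: per-called-class accuracy (diagonal over row
total), overall accuracy (trace over total), the variant-genotype false
discovery rate, the missed-variant rate, and per-true-class miscall rates —
the last recover the error matrix used by `corruptGenotypes()`, closing the
loop between the simulator and the report.

## Numerical and design choices

* Coordinates: VCF positions are 1-based; BED is 0-based half-open on disk
  and converted on read; all interval arithmetic runs on `GRanges`.
* Multi-allelic records are split per alternate allele on read; statistics
  are per alternate allele throughout (Ts/Tv counts split records once per
  alternate).
* Consensus targets intersect the overlap-normalized designs with each
  other and with the exon set, so the result is never longer than any
  input.
* Missing genotypes are excluded from numerators and denominators of every
  frequency computation.
* Degenerate cases are signalled, not silently patched: zero transversions
  report `Inf`, no heterozygotes yield `NA` allele balance (and pass the
  filter), empty strata warn, singleton sites are refused by the sharing
  statistic.
* Bootstrap CIs need $B \ge 100$; all randomized routines take explicit
  seeds and restore the caller's RNG state.

## Problem sizes in the test suite

Module tests run on cohorts of tens to hundreds of sites. The
simulation-based checks use 100 replicates of 600-site single-population
cohorts ($\theta$ and heterozygosity-ratio recovery within 3 SE), 200
replicates of 250-site cohorts (unfolded spectrum versus $\theta/i$ per
bin), 1,000 null cohorts of 600 sites (type-I error), 100 cohorts of 5,000
sites (power), and 100 three-population cohorts of 1,000 sites (bootstrap
coverage of the panmictic expectation, checked per AF bin at $\ge 93/100$
against the nominal 95%). These sizes were chosen to make the Monte Carlo
error small relative to each tolerance while keeping the default suite
quick to run.

## Known limitations

The generator's clamped selection skew changes the shape, not just the
scale, of the selected classes' spectrum, so it should be read as "an
excess-rare class" rather than any specific fitness model. The
error-rate-corrected chi-square is a score with a well-calibrated null in
our checks, but its distribution under fractional counts is approximate.
The sharing estimator fixes the minor-allele label before down-sampling;
sites whose minor allele flips in the reduced sample are rare at the panel
sizes used but not impossible. Heterozygosity display units follow the
$\times 10^4$ convention; consumers should use the raw values for
arithmetic.
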