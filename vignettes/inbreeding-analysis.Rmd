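---
title: "Quantifying inbreeding and its phenotypic cost: methods and design"
author: "InbreedKit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying inbreeding and its phenotypic cost}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(InbreedKit)
```

InbreedKit estimates how inbred the animals of a pedigreed, genotyped
livestock population are — by six different definitions of "inbred" — and
what that inbreeding costs in phenotype. This vignette explains the models
behind each stage, the parameters that matter, the numerical choices made
where the design was genuinely open, and what the simulation-based
validation does and does not demonstrate about real data.

## The six inbreeding coefficients

An inbreeding coefficient F is, conceptually, the probability that the two
alleles an individual carries at a locus are identical by descent (IBD), or
equivalently the correlation between the gametes that united to form it.
The six estimators differ in what they condition on.

**Pedigree-based** (`computeFPed()`). F_PED is the diagonal of the additive
(numerator) relationship matrix **A** minus one: F_i = A_ii − 1. We compute
it with the Meuwissen–Luo recursion, which reconstructs each animal's row of
the Cholesky factor of **A** over its ancestor closure; `buildAMatrix()`
implements the tabular method independently, and the identity
A_ii = 1 + F_i is asserted in the tests. Founders are assumed unrelated and
non-inbred, and an unknown parent contributes as an unrelated founder; an
animal with an unknown parent therefore has F = 0. This is the standard
livestock convention; it matters only for pedigrees with substantial
missing parentage.

**Frequency-based genomic** (`genomicInbreeding()`). With x the
reference-allele dosage of a SNP and p its population frequency:

* F_GRM = G_ii − 1, with G_ii = Σ(x − 2p)² / Σ2p(1 − p): the individual's
  self-relationship on the VanRaden genomic relationship matrix. Weighted
  by 1/p(1−p), so homozygosity for rare alleles moves it a lot.
* F_HOM1 = (E_het − O_het)/E_het: shortfall of observed heterozygosity
  relative to its Hardy–Weinberg expectation.
* F_HOM2 = 1 − Σx(2 − x) / Σ2p(1 − p): heterozygote count against the
  expected heterozygosity denominator (x(2 − x) = 1 exactly at x = 1).
* F_UNI = Σ[x² − (1 + 2p)x + 2p²] / Σ2p(1 − p): the correlation between
  uniting gametes, less sensitive to frequency mis-specification.

Three design choices were open and are fixed as follows. (1) *Missing
genotypes* are excluded per individual from numerator and denominator
alike, so each coefficient stays a self-consistent ratio over the markers
actually observed; with no missingness F_HOM1 and F_HOM2 coincide exactly,
and any divergence is attributable to missingness handling (asserted in
tests). (2) *Frequencies* are estimated once from the post-QC cohort; no
external reference population is used. This induces the usual small
negative bias of order −1/(2n − 1) in the cohort means, which is well
inside the Monte-Carlo bands used in validation. (3) The "homozygosity"
ambiguity in F_HOM1 is resolved on the heterozygosity scale so that
positive values always mean "more homozygous than expected", making the
sign convention uniform across all six metrics.

**ROH-based** (`detectRoh()`, `fRoh()`). Runs of homozygosity are
contiguous homozygous stretches; their length is inversely related to the
age of the inbreeding event that created them (long runs = recent
inbreeding, because recombination has not yet broken them). F_ROH is the
fraction of the autosomal genome covered by runs, overall and within the
length classes <2, 2–4, 4–8, 8–16 and >16 Mb.

## The ROH scanner, precisely

The detector follows the PLINK sliding-window scheme with the standard
50K-panel settings (all overridable through `rohParams()`):

* window of 50 SNPs, hitting when it has ≤1 heterozygous and ≤1 missing
  call;
* a SNP is a run candidate when ≥5% of the windows containing it hit;
* maximal candidate stretches are split at inter-SNP gaps >1,000 kb and
  kept when they have ≥30 SNPs, span ≥500 kb, and average ≤50 kb per SNP.

Details that affect marginal cases, fixed here deliberately: segment length
is end − start + 1 bp; length classes are half-open [lower, upper), so a
run of exactly 2.0 Mb is "2–4 Mb"; near chromosome ends the hit fraction is
taken over the windows that actually contain the SNP, and a chromosome
shorter than the window is scanned with one truncated window; the
autosomal genome length in the F_ROH denominator is the sum over
chromosomes of the largest mapped position — derived from the same map
used for detection, never a hard-coded assembly constant, so the
coefficient is well-defined on synthetic maps.

Because window-era bookkeeping is where scanner implementations diverge,
the package ships `bruteForceRoh()`, an exhaustive re-implementation that
inspects every (window, SNP) pair directly. The test suite requires
segment-for-segment identity between the two on hundreds of seeded random
chromosomes and on handcrafted fixtures either side of every threshold
(29 vs 30 SNPs, 499 vs 500 kb, 999 vs 1,001 kb gaps, 1 vs 2 heterozygotes
per window). Equivalence is guaranteed against this internal oracle, not
against any particular PLINK binary, whose end-of-chromosome handling has
varied across versions. One consequence of the window rule worth knowing:
a homozygous run shorter than the window embedded in a heterozygous
background cannot become a candidate (every covering window fails), so
isolated sub-window runs are undetectable by construction.

## Quality control

Two regimes mirror how the analyses are used downstream: ROH detection
keeps every marker and animal with call rate strictly above 95%; the
frequency-based metrics additionally require MAF ≥ 0.05 and a
Hardy–Weinberg exact-test p ≥ 10⁻⁶. The HWE test is the exact conditional
two-sided test (not mid-p), computed by the stable recurrence over
heterozygote counts; tests pin it to a direct log-gamma enumeration. Filter
order — individuals, then marker call rate, then MAF, then HWE — is fixed
and logged in the `QcReport`, because the order affects marginal markers.

## The inbreeding-depression model

The cost of inbreeding is estimated one covariate at a time by regressing
phenotypes on an inbreeding coefficient inside a pedigree animal model:

y = 1μ + Xb + βF + Za + (Wm + C·mpe | W·pe) + e

with contemporary group, sex, dam age and animal age (linear and
quadratic) as fixed effects, a ~ N(0, **A**σ²ₐ) the additive genetic
effect, and optionally a maternal genetic effect m ~ N(0, **A**σ²ₘ) with a
maternal permanent-environment term (for weaning-age traits) or an animal
permanent-environment term (for repeated records such as tick counts).
Maternal and direct effects are taken as uncorrelated, matching the model
statement's independent distributions. β is the depression slope in trait
units per unit F; the reported "percent depression per 1% inbreeding" is
100 × (β × 0.01) / mean, with the mean taken over the records actually
analysed (post-filter), a choice the output records explicitly. A 95%
confidence interval β ± 1.96·se decides significance.

Phenotype editing before fitting: count traits are transformed
log10(y + 1.001) (so a zero count maps to log10(1.001) ≈ 0.000434);
continuous records beyond 3.5 SD of their contemporary-group mean are
dropped, with the z-score computed with the candidate record included, an
n−1 denominator, and ties at exactly 3.5 kept ("exceeding"); groups with
fewer than three records, and zero-variance groups for score traits, are
removed.

### AI-REML on sparse mixed-model equations

Variance components are estimated by average-information REML on the
mixed-model equations, with **A**⁻¹ built directly by Henderson's rules
accounting for inbreeding (the Mendelian-sampling variance of each animal
uses its parents' F). The coefficient matrix is kept in variance-ratio
form and refactorised numerically each iteration on a fixed symbolic
pattern. The trace terms tr(K⁻¹C^{uu}) that EM updates and the REML score
require are computed exactly: the fixed-effect block is absorbed through a
Schur complement, a Takahashi selected inverse (compiled) yields the
entries of the random-block inverse on the Cholesky pattern, and a rank-p
Woodbury correction accounts for the absorbed fixed effects. This also
gives exact GLS standard errors for β from the Schur complement inverse.

Numerical policy: the first 3 iterations are EM (guaranteed ascent, robust
far from the optimum), then Newton steps with the average-information
matrix; a step proposing a negative component is first damped and, if
still infeasible, that component is pinned at a floor of 10⁻⁸ times the
phenotypic variance and flagged as a boundary estimate. Convergence
requires a maximum relative parameter change below 10⁻⁸ within 200
iterations; non-convergence is an error carrying the iteration trace, not
a silent result. All of these are arguments to `aiReml()`. Two exact
reductions anchor correctness: with no random terms the fit equals
ordinary least squares to 10⁻¹⁰, and on balanced sire designs the REML
components equal the closed-form ANOVA estimators to 10⁻⁶. A constant
inbreeding covariate is refused outright (it is confounded with the
intercept), never silently dropped.

## The synthetic cohort generator

Because the motivating data (a half-million-animal pedigree with ~14k
genotyped animals) are access-restricted, every stage is validated on
simulated data with known truth, and the generator is itself first-class,
tested code.

**Pedigree** (`simulatePedigree()`): discrete generations, litters of two
(so full sibs always exist); with probability `consanguinityRate` a mating
is drawn from a menu of full-sib, half-sib and parent–offspring pairings
(expected offspring F of 0.25, 0.125 and 0.25), otherwise a pair sharing
no parent is drawn. Birth year is the generation index.

**Genotypes** (`geneDrop()`): founders get unique haplotype labels and
biallelic SNP states from a configurable founder-frequency distribution;
each meiosis places Poisson(L in Morgans) crossovers uniformly at a
uniform 1 cM/Mb (no interference) — the simplest map that produces
length-graded ROH, mirroring the inverse relationship between run length
and inbreeding age; setting `cMPerMb = 0` makes autozygous tracts span
whole chromosomes, a useful degenerate check. Realized IBD is computed on
the exact segment structure (not the SNP grid), so the comparison of
F_ROH against realized autozygosity is not confounded by marker density.

**Phenotypes** (`simulatePhenotypes()`): breeding values follow
a_i = (a_s + a_d)/2 + m_i with Mendelian-sampling variance d_i·σ²ₐ using
parental inbreeding, so the simulated covariance is exactly σ²ₐ**A** — the
same **A** the estimator assumes. Fixed effects, maternal/permanent terms
and the depression slope β enter exactly as in the fitted model equation.

Validation problem sizes (chosen to make each check sharp at desk scale,
and stated here as the package's own study conditions): oracle equivalence
on all random pedigrees up to 8 animals; ROH equivalence on 200 random
chromosomes up to 5,000 SNPs; metric oracles on 50 × 200 matrices at
10⁻¹²; null calibration at n = 500 individuals × 5,000 markers (means
within 3 SE of zero); full-sib realized IBD over 500 gene-dropping
replicates (within 3 SE of 0.25); depression recovery at n = 2,000
records, h² = 0.3 and β = −20, where the 95% CI must cover the truth in at
least 90 of 100 seeded replicates. For the per-length-class slopes, a
deep pedigree (15 generations) on a dense map (6 × 80 Mb at 15 kb
spacing) populates all five classes; the class-specific true slopes
(+600, −300, −150, −75, −30 trait units per unit class-F) are scaled
inversely to each class's variance so that every class carries a
detectable signal, with the short-class slope favourable and long-class
slopes unfavourable, mirroring the old-versus-recent-inbreeding contrast.

What passing these checks does *not* show about real data: the generator
has no selection, migration, genotyping error, imputation artefacts, or
pedigree errors; founder frequencies are drawn independently per locus (no
ancestral LD beyond what the pedigree creates); contemporary groups are
random rather than confounded with genetic merit. Results on real
populations inherit none of these guarantees — in particular, imputation
error inflates short-ROH noise, and pedigree errors bias F_PED downward in
ways no internal check can detect.

## Known limitations

* The scanner is a detector of *genotypic* runs; it does not model
  phased/HMM autozygosity, and very short runs are invisible below the
  window size by construction.
* One inbreeding covariate per fit, mirroring per-metric reporting;
  joint models over classes, genomic BLUP, multi-trait models and
  dominance are out of scope.
* Dense pedigree blocks (e.g., long full-sib loops) increase Cholesky
  fill-in; the selected inverse handles the tested sizes in milliseconds,
  but half-million-animal pedigrees would warrant supernodal handling.
* The .ped/.map format carries no allele identities, so the reference
  allele is taken as the first allele observed per marker (with a
  warning); dosages can be relabelled (x → 2 − x) relative to a VCF of the
  same cohort, which leaves every metric unchanged.
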