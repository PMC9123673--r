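---
title: "Measuring and analysing individual recombination rate with xoverscan"
author: "xoverscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and analysing individual recombination rate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xoverscan)
```

## The measurement problem

Meiotic recombination shuffles parental haplotypes; how often it happens is
itself a quantitative trait. In pedigreed livestock populations the trait can
be measured directly: when a parent (the *focal individual*, FID), its own
two parents and at least one offspring are all SNP-genotyped, the FID's two
chromosome copies can be labelled by grandparental origin and each gamete the
FID transmitted can be read as a mosaic of the two. Every switch of
grandparental origin along a chromosome is a crossover, and the total over
all autosomes is the gamete's *autosomal crossover count* (ACC) — one
phenotype per meiosis, with repeated measures per FID.

`xoverscan` implements the full chain:

1. marker QC (MAF, call rate, Hardy–Weinberg, segregation distortion,
   two-point-LOD linkage-group membership);
2. three-generation full-sib family construction around (sire, dam) pairs;
3. Mendelian phasing of each FID and per-gamete crossover calling;
4. sex-specific linkage maps (Haldane mapping function) and cM/Mb
   landscapes;
5. heritability of ACC by an AI-REML repeatability animal model on the
   pedigree relationship matrix;
6. a mixed-model association scan of mean ACC per FID with a sparsified
   genomic relationship matrix (GRM) and per-SNP variance explained (PVE).

Because real datasets of this kind are proprietary, the package ships a
generative simulator whose ground truth (every crossover position, every
breeding value) exercises each stage end to end.

## The simulator and what it does (and does not) emulate

`simConfig()` fixes the study conditions. Defaults describe a commercial
pig-style population: 18 autosomes with realistic physical lengths; female
and male genome map totals of 2300 and 1800 cM (ratio 1.278, the
female-biased heterochiasmy typical of this species); mean ACC of 23
(female) and 18 (male), consistent with those totals; ACC variance
components `varA = 2`, `varPe = 1`, `varE = 17` (phenotypic variance 20,
h² = 0.10, SD ≈ 4.5 crossovers — the scale reported for commercial pig
lines); a polygynous pedigree with few sires and many dams; founder allele
frequencies uniform on [0.1, 0.5] in linkage equilibrium.

The generative model, stage by stage:

* **Breeding values.** Founders draw `a ~ N(0, varA)`; descendants get the
  parent average plus a Mendelian-sampling deviation
  `N(0, varA/2 · (1 − (F_s + F_d)/2))` with F the pedigree inbreeding
  coefficient. Permanent-environment effects are `N(0, varPe)` per
  individual.
* **Crossover counts.** Each meiosis has a latent Gaussian target
  `T = mu_sex + betaAge·age + betaHet·F + a + pe + e`, `e ~ N(0, varE)`,
  realised as `round(max(T, 0))`. Rounding a Gaussian rather than drawing a
  Poisson keeps `varE` interpretable as the gamete-level residual variance
  of the repeatability model that is fitted downstream; the rounding bias on
  the mean is below 0.1 crossovers for SD ≥ 3. In obligate mode the floor
  is one crossover per chromosome and clamping is recorded.
* **Placement.** Counts distribute over chromosomes in proportion to the
  sex-specific map lengths; positions within a chromosome come from
  normalised gamma-renewal spacings with shape `interferenceNu`. Shape 1
  reproduces uniform order statistics (no interference); the default of 8
  is a typical mammalian interference strength and spaces crossovers
  evenly, which is also what makes exact ACC recovery testable (close
  double crossovers that no marker panel could separate are essentially
  absent). With a fixed count, strong interference also pushes crossovers
  away from chromosome ends — real pig maps instead show elevated
  recombination near telomeres. The cM/Mb *landscape* of the simulator is
  therefore not realistic, only its totals and counts; landscape-shape
  claims should not be validated against it.
* **Observation model.** Genotyping error is a per-call random allele swap;
  missingness is per-call uniform. Both are applied after the truth tables
  are recorded. Founder haplotypes are in linkage equilibrium, so LD exists
  only through family descent — sufficient for family-based phasing, not
  for population-LD methods.
* **Ages.** Each mating event carries one age class (1–4) shared by sire
  and dam — the data model records a single `age` per offspring, a
  deliberate simplification of parity structure.

A single integer seed drives everything; identical configurations write
byte-identical datasets.

## Phasing and crossover calling

Phasing is deterministic Mendelian logic, not a probabilistic model: at
markers where the FID is heterozygous, a homozygous father (or failing
that, a homozygous mother) forces the allele onto the paternal (maternal)
haplotype. Both parents heterozygous leaves the marker unphased;
Mendelian-inconsistent trios are counted and excluded above a configurable
error ceiling (default 5%).

Transmission states are read per offspring: a homozygous offspring reveals
the transmitted allele directly; a heterozygous offspring is resolved
through a homozygous mate and is otherwise unknown. Crossovers are switches
between consecutive informative states, localised to the half-open bp
interval between them. Runs of fewer than `minSupport = 2` consecutive
identical states are treated as genotyping error and reverted before
counting — a single mistyped marker would otherwise fabricate two
crossovers. The price is that genuine double crossovers flanking one
isolated informative marker are merged away; with realistic interference
these are rare, and the package asserts `called ACC ≤ true ACC` as an
invariant. Leading and trailing unknown runs contribute nothing. Double
crossovers inside runs of homozygosity are undetectable by construction;
this surfaces downstream as a negative regression of ACC on the genomic
inbreeding coefficient rather than being imputed away.

Gametes with ACC below 6 or above 50 are flagged (`qcPass`), boundaries
retained.

## Linkage maps

Marker order is fixed to physical position. Per-interval distances are
estimated from each gamete's *spans* between consecutive informative
markers: every observed switch is one crossover whose location within its
span is latent, and an EM allocates switches to marker intervals in
proportion to the current interval rates, normalised by the number of spans
covering each interval. The per-interval crossover fraction is then
converted to cM with the Haldane mapping function, so for a single
two-marker interval the estimate reduces exactly to the Haldane transform
of the recombinant fraction.

Why not the textbook two-point estimate per adjacent marker pair? At
realistic informativeness (~25% of markers per gamete) two problems appear.
First, intervals with a handful of doubly-informative gametes produce wild
recombination fractions whose Haldane transform explodes. Second, and more
subtly, resolving transmission through offspring homozygosity makes a
gamete's informativeness at the two flanking markers *depend on whether it
recombined between them* (the recombinant haplotype matches the mate's
transmitted alleles differently), which biases naive pairwise counts
downward by several percent. Span-based estimation is immune to both: a
switch is observed whatever the span width, and the selection acts on
localisation, not on detection. Recombination fractions are capped at 0.49
before the Haldane transform so sampling noise can never produce an
infinite distance.

Chromosome totals are the last marker's cumulative position; the cM/Mb
landscape spreads each interval's cM uniformly over its bp span into
fixed-width windows (default 1 Mb). Two-point LOD scores
(`LOD = log10[r̂^R (1−r̂)^(N−R) / 0.5^N]`) support a linkage-group
membership filter (drop markers whose best LOD against nearby markers is
below 5); note that 17 fully linked gametes are needed before a marker
*can* pass, so the filter is meant for datasets of realistic size.

## The repeatability animal model

Variance components of ACC are estimated from

`y_ij = intercept + b1·age_i + b2·F_i + a_i + pe_i + e_ij`

with `a ~ N(0, A·varA)` on the pedigree relationship matrix, a
permanent-environment effect per FID, and heritability
`h² = varA / (varA + varPe + varE)`. Sexes are fitted separately by
default (`fitAccModel(sex = "F")`), matching how per-sex phenotypic and
error variances are usually reported; a pooled fit with a sex fixed effect
is available (`sex = "joint"`).

The engine maximises the REML log-likelihood through the sparse
mixed-model equations (A⁻¹ by Henderson's rules with inbreeding from the
recursive kinship coefficients; log|A| tracked analytically). Updates are
average-information steps with exact analytic scores obtained from the
trace identities `tr(P Z A Z') = q/σ² − tr(A⁻¹ C^{uu})/σ⁴`; steps that
leave the parameter space or decrease the likelihood fall back to
step-halving and then to EM updates, so accepted iterations are monotone.
Convergence is a change in −2 log-likelihood below 1e−8 (default);
variances are floored at `1e−8 · var(y)` and boundary pinning is flagged.
Starting values split `var(y)` as (0.4, 0.1, 0.5) over (varA, varPe,
varE). Standard errors come from the inverse average-information matrix,
with a delta-method SE for h². With unrelated individuals (`A = I`) only
`varA + varPe` is identifiable — the likelihood is flat along that ridge —
and the balanced case coincides with the one-way ANOVA method-of-moments
decomposition, which the tests exploit as an independent oracle alongside
a brute-force dense-covariance REML.

The genomic inbreeding covariate uses the method-of-moments coefficient
`F = (Ohom − Ehom)/(L − Ehom)`; the small-sample correction of the
expected-homozygosity term is off by default and available as a switch.

## The association scan

The response is the mean QC-passing ACC per FID — one value per individual
regardless of gamete count. The GRM is VanRaden method 1 (mean-imputed
missing genotypes, monomorphic markers skipped; optional base-population
allele frequencies, since sample frequencies deflate relationships in a
pedigreed sample). Sparsification zeroes off-diagonals strictly below 0.05.
The null covariance `V = G_sparse·σg² + I·σe²` is estimated once by REML
through the eigendecomposition of the sparse GRM; each SNP is then tested
by generalised least squares of the response on intercept, `nPcs = 10`
principal components of the dense GRM, and the SNP dosage, holding the
covariance *shape* fixed while re-estimating the overall scale from the
per-SNP GLS residuals with `n − p − 1` degrees of freedom and a t
reference. That last choice means the scan collapses exactly onto ordinary
least squares when the GRM is the identity — a property the tests assert to
1e−8 — at the cost of a minor departure from scans that keep a single
global variance for every SNP. Significance is Bonferroni at `0.05/M`, and
the per-SNP variance explained is
`PVE = 2β̂²q(1−q) / (2β̂²q(1−q) + SE(β̂)²·2Nq(1−q))`, reported in percent.

## Validation experiments and their sizes

The acceptance suite (also re-run by `scripts/acceptance.R`) uses these
problem sizes, chosen to keep each experiment's sampling error well inside
its tolerance:

* caller oracle: 1000 fully informative gametes (150 markers/chromosome),
  error-free and at 0.2% genotyping error;
* map recovery: 25 sires × 500 dams × 4 offspring (2000 gametes per sex),
  250 markers/chromosome;
* heritability: 2000 focal females × 5 gametes on a 50-sire pedigree, plus
  a 500-individual balanced unrelated design for the ANOVA identity;
* association: 800 × 5000 null scan, 2000 × 2000 planted-locus scan
  (true PVE 7% at MAF 0.3), 300 × 50 OLS-equivalence check.

## Known limitations

* Phasing is single-family Mendelian logic; half-sib information outside
  the three-generation family is not used, and no probabilistic (HMM)
  phasing with per-genotype error likelihoods is attempted.
* The map estimator assumes crossovers are located uniformly within a
  span given the interval rates; interval-level resolution is bounded by
  informative-marker spacing.
* The simulator's recombination landscape is flat within chromosomes (no
  telomeric elevation, no hotspots) and its founders carry no LD.
* Sex chromosomes are out of scope throughout.
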