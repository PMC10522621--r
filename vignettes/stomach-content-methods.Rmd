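---
title: "Methods: stomach-content diet analysis and foraging-depth estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stomach-content diet analysis and foraging-depth estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deepdiet)
```

## The problem

Midtrophic deep-sea fishes — hammerjaws, juvenile fangtooths, juvenile
lancetfishes — are mobile enough to avoid nets and camera platforms, so
almost nothing is known about how they divide shared prey resources.
A large pelagic predator can act as a biological sampler: specimens
recovered from its stomach arrive in good enough condition for full diet
analysis. `deepdiet` implements the quantitative machinery such a study
needs: composition indices over prey groups, overlap and permutation
statistics on diet profiles, coverage-based diversity estimation over prey
families, allometric models of prey size and number, and a per-stomach
foraging-depth estimator that converts a stomach's contents into an
estimate of where in the water column the predator fed. A synthetic
generator with known ground truth makes every stage testable without any
survey data.

## Data model

The unit of enumeration is the **prey group**: all individuals of one
taxon at one digestion state (1 = intact … 4 = heavily digested) in one
stomach, with a count, a total wet mass, and measurements for at most a
subset of individuals. Stomachs (predator specimens) carry species,
standard length, whole and content mass; predator mass is whole minus
content mass unless supplied directly, and a negative derived mass is
flagged and set missing rather than clamped. Empty stomachs are first-class
records: vacuity is itself a result. Only digestion states 1–3 are treated
as measurable; state-4 groups contribute totals but never individual-mass
statistics.

Datasets are exchanged as canonical long-format CSVs (one prey group per
row, measurements packed into a `mass:length:type;…` sub-field) with a
`schema` mapping to adapt foreign column names. A separate CSV edge list
supplies the taxonomy. Four coarse groups — the hyperiid superfamily
Platysceloidea (absorbing Brachyscelidae and Lycaeidae), crustacean
megalopa, fish leptocephali, and ceratioid anglerfishes — are sanctioned as
family-level analysis units because each is mutually exclusive with every
true family in the data.

## Prey-size imputation

Within a measured prey group, unmeasured individuals take the median mass
and length of the measured ones (even counts: mean of the two central
values); wholly unmeasured groups split their total mass evenly. Family
length–mass models are fit per (family, length type) — standard length for
fishes, mantle length for cephalopods, total length for crustaceans — and
never pooled across length conventions. The prediction map is a monotone
smooth on the log–log scale: a penalized spline fit, evaluated on a fine
grid, isotonized by pool-adjacent-violators, and interpolated. Monotonicity
is imposed because the map must be invertible to predict lengths from
masses; an unconstrained smooth can wiggle. Below 8 pairs the map falls
back to a log–log power law, whose coefficients are recorded in every
model as a diagnostic (the closed-form inverse is
`L = (m/a)^(1/b)`). Masses outside `[0.5x, 2x]` of the fitted range return
extrapolated values with a warning.

## Composition indices and filters

For each predator species, over its prey-containing stomachs:

* `%N̄`, `%M̄` — mean per-stomach proportional count/mass of a category, ×100;
* `%FO` — percent of stomachs containing the category;
* `%M̄ps` — mean proportional mass over only the containing stomachs;
* `IRI = (%N̄ + %M̄) × %FO`.

These satisfy `%M̄ = %M̄ps × %FO / 100` exactly, which the tests assert.
The `%FO` denominator is the number of prey-containing stomachs (the
per-stomach proportional metrics are only defined there); a flag switches
to all stomachs examined. A 50 `%M̄ps` threshold separates specialist from
generalist feeding on a category and a 50 `%FO` threshold separates
population-level from individual-level patterns; exact ties at 50 classify
as generalist/individual because the specialist side is defined strictly
(`> 50`).

Similarity analyses are restricted to predators between 1 and 100 g
(window closed on both ends, configurable) so that unequal size
distributions do not masquerade as diet differences, and to prey families
that contribute more than 1 `%M̄` for at least one species and occur in
more than one stomach — rare categories dominate abundance-based distance
metrics out of proportion to their importance. Unidentified material is
excluded from similarity and diversity but retained in totals and
occurrence tables.

## Overlap statistics

All distance-based procedures run on `1 − Cmh`, where
`Cmh = 2Σpq / (Σp² + Σq²)` is the Morisita–Horn similarity of two
renormalized profiles; the conversion to a dissimilarity is the package's
choice, made explicit and tested. The permutation statistics are
implemented from first principles:

* **ANOSIM**: `R = (r̄B − r̄W) / (M/2)` on the ranks of the `M = n(n−1)/2`
  pairwise dissimilarities, so `R = 1` under complete separation and 0
  under none. (Some summaries print the divisor as `M/4`; that
  normalization lets `R` reach 2 and is not used here — the `M/2` divisor
  is what makes the perfect-separation case equal exactly 1, which the
  tests pin down.)
* **PERMANOVA**: one-way pseudo-F from direct within/total sums of squared
  dissimilarities; a zero within-group sum returns an infinite statistic
  with a degeneracy flag rather than a silent number.
* **PERMDISP**: principal-coordinate embedding (Lingoes correction — add
  `−2λmin` to squared off-diagonal dissimilarities — when negative
  eigenvalues arise), distances to group mean centroids, ANOVA F on those
  distances, labels permuted over distances.

P-values enumerate all distinct labelings exactly when their number is at
most 100 000, otherwise Monte-Carlo permutation with the observed labeling
counted (`p ≥ 1/(n_perm + 1)`). Tests verify exact enumeration against an
independent brute-force oracle, agreement of the statistics with
`vegan::anosim`/`adonis2`/`betadisper(type = "centroid")`, invariance of
`R` under monotone transforms, and a null rejection rate of 5% ± 2% under
exchangeable Dirichlet profiles (1000 replicates, 199 permutations each).

**NMDS** minimizes Kruskal stress-1 by iterative majorization with
monotone regression (pool-adjacent-violators). Disparities are rescaled to
the configuration's sum of squares each iteration — stress-1 is scale
free, and without this normalization the Guttman update contracts the
configuration toward a point. The first start is the principal-coordinate
configuration, the rest random; 50 restarts by default. Solutions are
reported centered and are unique only up to rotation/reflection, which the
order-invariance test accounts for via a Procrustes gap.

## Diversity over prey families

Each stomach is a sampling unit and each family an incidence category
(the incidence framing matches reporting effort in "samples"; an abundance
reading of the same estimators would use individuals). Observed diversity
is the Hill number of order 1, `exp` of the Shannon entropy of relative
incidence frequencies. The asymptotic estimator applies the digamma-series
bias correction with a tail term driven by the unique (`Q1`) and duplicate
(`Q2`) categories; when `Q2 = 0` the tail coefficient uses the usual
bias-corrected fallback `2/((n−1)(Q1−1)+2)` so estimates stay finite.
Standard errors bootstrap the sampling units (200 replicates by default).
Sample coverage uses the matching `Q1`/`Q2` estimator; the coverage–effort
curve interpolates hypergeometrically below the reference effort and
extrapolates geometrically beyond it, and `t95` is the smallest effort
whose estimated coverage reaches 95%, searched up to 4× the reference
effort (a configurable cap — diffuse diets can need extrapolation far
beyond the sample, so the cap is generous) with a beyond-cap sentinel.

## Foraging depth

Each prey taxon resolves to a median depth of occurrence: direct reference
entry first (diel vertical migrators get the day/night mean;
length-specific rules apply when a length is known, with fragile taxa
pinned to a single depth by a `fixed_depth` flag), then genus/family
averaging over member species in the reference, with the members logged.
Within a stomach, proportional masses are recalculated over only the
depth-resolvable prey (the retained fraction is reported as
`mass_coverage`), restricted to families contributing at least 1 `%M̄` for
some species — computed on the full, unwindowed dataset, since analyses
that model predator mass explicitly need no size restriction. The
foraging-depth estimator is then the mass-weighted mean of taxon median
depths, `Zf = Σ zi · adjM̄i`. Although such estimators are sometimes
described as weighted medians, the defining formula is the weighted sum
and that is what is implemented: `Zf` is convex (always inside the range
of the prey depths used) and invariant to rescaling all masses.

One consequence worth stating: the *population* mass-share depth (weights
= mixture weight × typical prey mass, aggregated over all stomachs) and
the *mean of per-stomach* `Zf` differ when prey sizes are very unequal — a
rare but heavy deep-living prey raises the former more than the latter.
The generator's `ground_truth()` reports the population quantity;
recovery tests of the per-stomach mean therefore use equal-mass two-layer
configurations, where the two coincide and the mean `Zf` converges to
`z_shallow + w·(z_deep − z_shallow)`.

Depth trends over predator mass are penalized-spline fits
(`Zf ~ species + s(log10 mass, by = species)`, GCV smoothing); fewer than
10 estimates for any species drops the smooth for plain species means.
Occurrence trends are binomial GLMs of per-stomach presence on log10
mass, with a small-ridge IRLS fallback under complete separation.

## Allometric models

Individual prey mass and total prey mass per stomach are log10-transformed
and prey counts log2-transformed (the field's conventional bases, keeping
slopes comparable across studies) and fit by OLS against
`log10(predator mass) × species`, with Wald-t confidence intervals and
type-III ANCOVA via sum-contrast refits. Prey-type proportion trends use a
quasi-likelihood logit-link smooth of the per-stomach proportion on log10
mass; when more than 90% of responses are exactly 0 or 1 the smooth is
refit as a binomial model on the binarized response — the same fallback a
beta-likelihood model needs when dominated by zeros and ones, triggered
deterministically.

## The synthetic generator

The generator emulates a three-species survey: a generalist
(`Alepisaurus ferox`, n = 138, 16-taxon tapering mixture), a shallow
specialist (`Anoplogaster cornuta`, n = 91, half its mixture on one
hyperiid amphipod), and a deep specialist (`Omosudis lowii`, n = 79, twothirds
on hatchetfishes). Vacuity is 0.16/0.11/0.49 — deep-sea sit-and-wait
predators are often found with empty stomachs — and predator masses are
lognormal with means/sds matched to the cohort the design emulates
(28.2 ± 82.6, 6.3 ± 4.0, 13.3 ± 17.6 g). The taxon catalog's resolved
depths are bimodal (modes near 180 m and 675 m, matching the two acoustic
scattering layers of the central North Pacific) and include the standard
depth anchors: hatchetfishes at 675 m, *Phrosina semilunata* at 185.38 m,
Lycaeidae at 87.5 m, *Platyscelus armatus* at 185 m, *Gempylus serpens* at
237 m.

Per stomach: a vacuity draw; `1 + Poisson(λ)` prey-group draws from the
species mixture with digestion states drawn per group (same taxon and
state merge, as the prey-group definition requires); counts from a
zero-truncated negative binomial whose log mean rises with log predator
mass; individual masses lognormal around the taxon's typical mass scaled
allometrically with predator mass (`γ` per species); lengths back-computed
through the taxon's length–mass law. Measurement mimics the bench
protocol: groups of at most three measurable individuals are fully
measured (with a measurement probability), larger groups contribute their
minimum, median and maximum individuals only; state-4 groups are never
measured.

What it deliberately does **not** emulate: spatial or temporal structure,
taxonomic misidentification, digestion-driven mass loss across states,
and prey-size-dependent depth shifts. Green recovery tests therefore
demonstrate correctness of the estimators under a known sampling process,
not robustness to those real-data complications.

### Recovery expectations

For a mixture `p` estimated from `N` effective draws, the expected
total-variation error is approximately
`0.5 · sqrt(2/(πN)) · Σi sqrt(pi(1−pi))`. The 16-taxon generalist mixture
has `Σ√(pq) ≈ 3.7`, so at the default study conditions (~4 prey groups per
stomach, overdispersed counts, 200 stomachs) the expected TV error sits
right at 0.05–0.06 — dominated by sampling noise, not estimator error. The
TV recovery check therefore runs the densely sampled noiseless
configuration (~10 groups per stomach, near-deterministic counts,
`σ_log = 0`, full measurement), where the formula predicts ≈ 0.038 for the
generalist and less for the specialists; the observed errors match.
Because same-taxon groups merge, mixtures are estimated from individual
counts (counts are drawn independently of taxon identity, so count shares
are consistent) rather than group frequencies, which are biased low for
dominant taxa. Allometric recovery controls for taxon, since the taxon's
typical mass acts as a group-level random effect that OLS standard errors
on pooled individuals understate.

## Numerical choices and problem sizes

* Permutations default to 9999 in analyses (999 in the packaged drivers);
  exact enumeration below 100 000 arrangements; every stochastic stage
  takes an explicit seed and the pipeline manifest records it.
* NMDS: 50 restarts default, stress change `< 1e-7` to converge.
* The test suite's stochastic checks use: 1000 replicates × 199
  permutations for ANOSIM calibration; 1000 replicates for Wald-CI
  coverage; 500 sampling units for diversity recovery; 200 stomachs per
  species for mixture and depth recovery — sizes chosen so each check's
  Monte-Carlo error is several times smaller than the tolerance it
  asserts.
* Ties at exactly 50 in feeding-strategy thresholds → generalist /
  individual; the 1–100 g window is closed on both ends; both are
  configurable.

## Known limitations

* The beta-likelihood proportion model is deliberately replaced by a
  quasi-likelihood logit smooth with a deterministic binomial fallback;
  coefficients are not comparable to a beta GAM's at printed precision.
* Smoothing-parameter selection uses GCV; exact equivalence with
  REML-selected smooths from other software is not promised.
* The asymptotic diversity estimator is asymptotically unbiased under the
  incidence model but can be noisy at very small `n` with many uniques
  (its bootstrap se says so).
* Family-mean depth resolution averages all reference entries under the
  family; with strongly depth-stratified families this is a coarse
  default, and the resolution path of every assignment is recorded for
  audit.
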