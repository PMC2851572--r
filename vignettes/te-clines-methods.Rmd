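---
title: "Models and methods: detecting climate-adaptive TE insertions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: detecting climate-adaptive TE insertions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teclines)
```

## The scientific problem

*Drosophila melanogaster* is tropical by origin and colonised temperate
latitudes only recently.  A transposable-element (TE) insertion that helps
flies cope with temperate conditions should therefore be rare or absent in
ancestral African populations, common in derived populations, and — crucially
— more common at the temperate end of a latitudinal cline than at the
tropical end, on more than one continent.  `teclines` implements the full
inference chain behind this argument: estimating insertion frequencies from
strain genotypes, testing frequency heterogeneity between population pairs,
deciding which TE *families* are under purifying selection (so that their
rare high-frequency members stand out as candidate adaptive insertions),
screening candidates, correcting for multiple testing, and regressing
frequencies on latitude and climate.

Every stage is paired with a synthetic-data generator that reproduces the
statistical structure the stage assumes, so the whole pipeline is testable
without any external data.

## Insertion-frequency likelihood and the heterogeneity test

Strains are treated as effectively containing two haploid genomes drawn from
a panmictic population, so at insertion frequency $p$ a strain is homozygous
present / heterozygous / homozygous absent with Hardy–Weinberg probabilities
$p^2$, $2p(1-p)$, $(1-p)^2$.  For counts $(n_1, n_2, n_3)$ the
log-likelihood is the corresponding multinomial sum, maximised exactly at
the sample allele frequency $\hat p = (2n_1 + n_2)/(2n)$
(`mle_frequency()`).  We use the convention $0\log 0 = 0$ and handle the
boundary frequencies exactly — never by epsilon-clipping — so fixed and
absent samples are legal inputs.  Missing genotype calls are dropped per TE
per population, so strain totals may differ across TEs.

Heterogeneity between two populations is a likelihood-ratio test
(`heterogeneity_test()`): $\Delta L$ is the gain in maximised log-likelihood
from giving each population its own frequency rather than a shared one.
Because the heterozygote multiplicity terms cancel between the two models,
$\Delta L$ depends only on the allele counts and $2\Delta L$ is exactly the
G statistic of the 2×2 allele-count table; the tests verify this identity
against an independent 2×2 implementation.  P-values refer $2\Delta L$ to
$\chi^2_1$.  Two decision conventions circulate for this test — comparing
$2\Delta L$ or $\Delta L$ itself against the 3.84 critical value — and they
disagree for $\Delta L$ between 1.92 and 3.84, so the result object reports
both flags (`significant_lrt`, `significant_deltaL_rule`); p-values always
come from $2\Delta L$, the calibrated choice.

```{r}
north <- genotype_counts(0, 0, 24)   # 0 of 48 presence alleles
south <- genotype_counts(6, 5, 11)   # 17 of 44, p_hat = 0.386
heterogeneity_test(north, south)
```

## Family selection coefficients under mutation–selection balance

TE insertions are modelled with codominant fitness: homozygote $1+s$,
heterozygote $1+s/2$.  For a panmictic diploid population of constant size
$N$, the stationary frequency spectrum on the grid
$x \in \{1/(2N), \dots, (2N-1)/(2N)\}$ is the Wright–Fisher diffusion
result for additive selection,
$$\rho(x \mid s, N) \;=\; c\,\frac{1 - e^{-2Ns(1-x)}}{x(1-x)},$$
normalised by $c$ over the grid.  Three structural checks guard this form
in the test suite: the neutral limit is the $1/x$ spectrum, purifying
selection strictly lowers the mean frequency, and (after ascertainment,
below) the neutral spectrum becomes exactly uniform.  Evaluation is in log
space so $|Ns|$ up to $10^3$ stays finite.  The likelihood depends on $s$
and $N$ essentially through $Ns$, so fitting fixes $N = 10^4$ (19,999 grid
points) and searches $Ns \in [-500, 50]$; a configurable smaller $N$ is
used in tests and brute-force oracles.

Because all TEs in the analysed set were discovered in a single sequenced
genome, discovery probability scales with $x$; `ascertained_distribution()`
size-biases the spectrum accordingly.

**Observation model.**  Frequencies are observed only through pooled PCR on
pools of $k$ strains ($2k$ genomes; the panel this model was built for used
8–12 strains per pool, summarised as $k = 11$).  Before errors, a pool is
absent with probability $(1-x)^{2k}$, fixed with $x^{2k}$, else
polymorphic; truly polymorphic pools are misread as absent with rate
$e_1 = 0.042$ and as fixed with rate $e_2 = 0.010$.  An element's data are
pool counts $m_1,\dots,m_6$ (absent / polymorphic / fixed /
absent-or-polymorphic / polymorphic-or-fixed / no usable assay).  The
likelihood of an observation integrates the class probabilities over the
ascertained spectrum, with a multinomial coefficient over the perfectly
classified pools $m_1..m_3$ only: the partial classes overlap the primary
ones, so they enter as plain powers (giving them a share of the coefficient
would push the total above one — the package's version is verified against
a brute-force double loop at $N = 50$ to relative $10^{-8}$).  $m_6$ pools
contribute a factor of one; an element with only $m_6$ pools has
probability exactly 1, and a family of such elements is reported
`indeterminate`.  Which pools end up partial or unusable is taken to be a
property of the assay, independent of frequency, so it carries no
likelihood information.

**Fitting.**  `fit_family()` maximises the family log-likelihood (elements
independent) by simulated annealing — geometric cooling over 400
evaluations, Gaussian proposals shrinking with temperature — followed by a
deterministic golden-section refinement in a bracket around the annealing
optimum.  The refinement makes the reported estimate insensitive to the
annealing seed, which is the property the tests check.  Confidence bounds
solve $\log L(\widehat{Ns}) - \log L(Ns) = 2.512$ on each side by root
finding; bounds that hit the search range are clipped and flagged.  The
2.512 drop follows the convention this model was published with even though
the textbook $\chi^2_1$ 95% profile drop is 1.92; the conventional constant
is available via `ci_const = qchisq(0.95, 1)/2`, and since 2.512 > 1.92 the
default intervals are conservative (observed coverage for neutral families
in the acceptance suite exceeds the nominal 95%).  Families are classified
`putatively_neutral` when the interval contains zero,
`putatively_adaptive_family` when the upper bound is negative (the family
is purged by selection, so its high-frequency members are candidate
adaptive insertions), and `indeterminate` when the profile is flat or the
family has fewer than `min_family_size = 3` elements — and indeterminate
families are treated as *possibly adaptive* downstream (`classify_te()`),
since there is no evidence of their neutrality.

## Candidate screening

`screen_candidates()` applies four conjunctive filters: present in all six
North American pools (present = polymorphic or fixed; counting the
ambiguous absent-or-polymorphic class is a documented override), not fixed
in the African pool, recombination rate strictly above 0 cM/Mb (1 cM/Mb as
the robustness alternative), and African strain frequency strictly below
30% (a TE exactly at the cutoff is removed).  The final set is
order-invariant; the per-stage tallies are logged and written out because
they, not the final set, are what changes when cutoffs move.

## Differentiation, FDR and direction

TEs inside clinal inversions whose confounding cannot be excluded are
dropped (`exclude_inversion_tes()`), and strains carrying scored inversions
are removed before frequency estimation (`drop_inversion_strains()`).

Multiple testing is corrected within each comparison column separately
(m = number of TEs tested, 28 in the packaged table).  Two quantities are
deliberately distinguished:

* `bh_adjust_plain()` reports $q_i = p_i\,m/\mathrm{rank}_i$ without
  monotonicity enforcement — the form many published tables print, which
  can be non-monotone in $p$ (the packaged table contains such a pair:
  raw 0.0016 → 0.0087 vs raw 0.0017 → 0.0080);
* `bh_significant()` makes the actual step-up decisions
  ($i^* = \max\{i: p_{(i)} \le i\alpha/m\}$), cross-checked in the tests
  against `stats::p.adjust(method = "BH")` and a brute-force threshold
  search.

Direction is labelled per TE per pair relative to the pair's *temperate
pole* — south in Australia, north in North America; exact frequency ties
are `tie` and never count as expected-direction.  `summarize_candidates()`
reports unique significant TEs, their adaptive/neutral split, and how many
are temperate-higher in at least one significant comparison.

`direction_gtest()` tests direction counts against 1:1 within each class
and class×direction independence (2×2 G-test).  This is one defensible
contingency construction ("interpretation A"); published directionality
p-values for data of this shape are not generally reproducible from
frequency tables alone, so the function is a qualitative companion, not a
numeric target.

## Cline regression

Frequencies are angular transformed ($\arcsin\sqrt p$) and regressed by OLS
on latitude (absolute degrees, so hemispheres share an axis), mean maximum
temperature, mean minimum temperature, or rainfall, one population per data
point and long-term (20-year) climate averages — selection coefficients are
small, so long-term conditions are the relevant ones.  A quadratic term is
checked alongside and reported only as a flag; linear fits are what the
output surfaces.  P-values are two-sided t tests on the slope with $n-2$
df; values above 0.05 print as ">0.05" while full precision is kept.

## The synthetic-data generator

`simulate_study()` draws, from one bundle seed (stage sub-seeds derived
deterministically), everything the pipeline reads: element frequencies from
the ascertained family spectra, pooled panels with the $e_1/e_2$
misclassification, Hardy–Weinberg genotype tables, and population metadata.
Defaults are the study conditions the models assume: six pools of 11
strains, error rates 0.042/0.010, 22–24 strains per population, four
populations spanning 17–37° latitude, and a family table spanning strong
purifying selection ($Ns = -100$) to neutrality with a few elements per
family.  The cline generator is *linear on the angular scale*
($x_i = \sin^2(a + b\,\mathrm{lat}_i)$, with $a + b\,\mathrm{lat}$
required to stay in $[0, \pi/2]$), so the regression model is exactly
recoverable; a logistic-on-latitude alternative exists for misspecification
experiments.

What the generator does *not* emulate — and therefore what passing
recovery tests do not establish about field data: linkage between TEs
(elements are drawn independently), demographic departures from the
panmictic constant-size equilibrium (bottlenecks during colonisation,
admixture, laboratory evolution between collection and assay), shared
strains across pools, and locus-specific error rates.  Recovery results
validate the estimators under their own assumptions, no more.

## Numerical choices and problem sizes

* Grid likelihoods are computed in log space with a stable
  $\log|e^z - 1|$; per-element observation factors are precomputed once
  per family (they do not depend on $Ns$), so each likelihood evaluation
  costs one log-sum-exp per element over the grid.
* Profile CI roots are found by `uniroot` to $10^{-4}$; flat profiles
  (log-likelihood range $< 10^{-6}$ over the search range) short-circuit
  to `indeterminate`.
* The validation suite uses 50 replicate deleterious families and 20
  neutral families of 30 elements at the full $N = 10^4$ grid, 500
  cline-recovery replicates at 20 populations, 2000 null replicates for
  the type-I calibration of the heterogeneity test, and $10^5$-replicate
  Monte-Carlo checks of the pool observation model — sizes chosen so each
  recovery property is measured with binomial noise well below its margin.
* Cline-recovery calibration compares slope errors to the estimator's
  *true* sampling SE, available analytically because the angular
  transform is variance-stabilising (var $= 1/(4m)$ per population for
  $m$ genomes); the per-fit estimated SE would make the check a test of
  the $t_{n-2}$ tail instead ($\pm 2\,\widehat{SE}$ covers only ~94% at
  $n = 20$).

## Known limitations

* The selection model assumes a stationary panmictic population;
  estimated $Ns$ absorbs any demographic misfit.
* Pools are summarised at $k = 11$ strains; true per-pool sizes (8–12)
  would sharpen the likelihood slightly and could be supported by making
  `k` per-observation.
* The directionality G-tests are interpretation-dependent (above).
* The packaged 28-TE table carries frequencies and p-values at printed
  precision only; checks against it respect last-digit rounding.
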