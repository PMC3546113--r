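---
title: "Collapsed family-based association tests for rare variants: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collapsed family-based association tests for rare variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvfbat)
```

## The testing problem

Sequencing a candidate region in families yields many variants whose minor
alleles are too rare for single-marker association tests to have any power.
The standard remedy in population samples is to *collapse*: sum the rare
allele counts over the region and test the aggregate burden.  In family
samples the natural single-marker test is the FBAT: for family $i$ and
marker $j$, with offspring minor-allele count $X_{ij}$ and coded trait
$T_i = Y_i - \mu$ (offset $\mu$), the score

$$u_{ij} = T_i\,(X_{ij} - E[X_{ij} \mid C_i])$$

is a covariance between trait and transmitted genotype, where the
conditional expectation is computed under the null from Mendel's laws given
the parental genotypes $C_i$ (or, when parents are untyped, given the
sufficient statistics for them).  Because the conditioning fixes everything
ancestral, the test is immune to population stratification by construction.

`rvfbat` collapses these single-marker scores over a region:

$$W \;=\; \sum_{j \in S} w_j \sum_i u_{ij},
  \qquad Z = W / \sqrt{\widehat{\mathrm{Var}}(W)},$$

with three interchangeable choices of the marker set $S$ and weights $w$:

* **unweighted, no threshold** — $w_j = 1$, all markers;
* **fixed threshold** — $S = \{j : \hat p_j < t\}$ with $t$ conventionally
  0.005, 0.01 or 0.05, estimated frequencies strictly below the cutoff;
* **frequency weights** — $w_j = 1/\sqrt{n \hat p_j (1-\hat p_j)}$
  (inverse null standard deviation of the allele count, the
  Madsen–Browning-style choice), or $w_j = 1/\sqrt{n_j^{\text{inf}}}$ with
  $n_j^{\text{inf}}$ the number of informative families.

All weights and thresholds are functions of parental genotypes only
(parents for trios; all siblings for sibpairs without parents), never of
the transmissions being tested, so they cannot bias the null distribution.

## Variance of the collapsed statistic

Marker scores within a family are correlated (linkage disequilibrium, and
in our simulations complete cosegregation of haplotypes), so the variance
of $W$ cannot be the sum of the per-marker variances.  The package follows
the multimarker-FBAT construction: the empirical covariance
$V_E[j,k] = \sum_i u_{ij} u_{ik}$ captures the between-marker correlation,
and the *adjusted* covariance replaces its diagonal with the exact
model-based variances $D_j$ while keeping the empirical correlations,

$$V_A[j,k] = \sqrt{D_j D_k}\;
  \frac{V_E[j,k]}{\sqrt{V_E[j,j]\,V_E[k,k]}}.$$

Then $\widehat{\mathrm{Var}}(W) = w^\top V_A w$, which for unit weights is
exactly the sum of all elements of $V_A$.  The same bundle powers the
multimarker chi-square test $T = S^\top V_A^{-} S$ with degrees of freedom
equal to the numerical rank of $V_A$ (generalized inverse, relative
singular-value cutoff $10^{-8}$ — rare variants make $V_A$ near-singular
routinely).  The off-diagonal rescaling formula is a reconstruction from
the verbal definition of the adjusted matrix ("replace the empirical
variances with the exact ones"); it is isolated in
`adjusted_covariance()` so an alternative convention is a one-line change.
The quadratic form $w^\top V_A w$ for weighted statistics is the exact
generalization of the stated unweighted case and reduces to it at
$w \equiv 1$.

Asymptotic reference distributions are $N(0,1)$ for $Z$ (two-sided
throughout; the alternatives of interest are symmetric and the reported
nominal levels are central) and $\chi^2_{\mathrm{rank}}$ for $T$.  The
normality of $W$ only needs many informative families in aggregate, which
is why the collapsed test remains calibrated where the multimarker test —
which needs each marker's own statistic to be normal — turns conservative.

## Conditioning details

* **Trios and multi-offspring families with typed parents.**  Transmission
  distributions come from Mendel's laws; with several offspring the
  transmissions are treated as conditionally independent given parents,
  which is the correct null when testing "no association and no linkage".
* **Sibpairs without parents.**  Conditioning on the sufficient statistics
  of the unobserved parental genotypes reduces, for exactly two offspring,
  to exchangeability of the observed genotype pair: two orderings with
  probability one half each (point mass if the genotypes coincide).  The
  family score is $u = (T_1 - T_2)(X_1 - X_2)/2$ with null variance $u^2$
  under the ordering distribution.  Sibships of other sizes without
  parents, and families with exactly one typed parent, are rejected rather
  than approximated: the general sufficient-statistic machinery for
  arbitrary missing-parent configurations is out of scope, and the
  discordant-sibpair design needs only this case.
* **Offsets.**  $\mu = 0$ for affected-only trios (unaffected offspring
  then contribute nothing) and for discordant sibpairs, where any offset
  cancels in $T_1 - T_2$.  The offset is configurable for other sampling
  schemes.
* **Missing genotypes.**  A family is dropped from marker $j$ only, when
  any member used in the conditioning is missing at $j$.  This choice is
  ours; per-marker exclusion keeps the remaining markers' conditioning
  intact and is the least aggressive option.
* **Informative families.**  A family is informative at a marker when its
  conditional variance is positive — for trios, at least one heterozygous
  parent.  Markers informative in no family carry a score identically zero
  and are dropped before any covariance work (they cannot be rescaled).

## Population-based comparators

Two case-control tests serve as the population-based reference points,
with variant frequencies estimated from cases and controls pooled:

* a **burden score test**: the Rao score test of the burden sum
  $B_i = \sum_{j \in S} X_{ij}$ in an intercept-only logistic model,
  $U = \sum_i (Y_i - \bar Y) B_i$,
  $V = \bar Y(1-\bar Y) \sum_i (B_i - \bar B)^2$ — the simplest member of
  the general score-test family for pooled rare variants, matching the
  fixed-threshold unweighted analysis on the family side;
* a **modified Madsen–Browning weighted sum**: individual scores
  $\gamma_i = \sum_j X_{ij}/\sqrt{n\hat q_j(1-\hat q_j)}$ with smoothed
  pooled frequencies $\hat q_j = (m_j+1)/(2n+2)$, case rank sum with
  midranks, standardized by the tie-corrected Wilcoxon moments.  We use
  the asymptotic normal reference because the published type-I errors use
  normal cutoffs; a Monte-Carlo permutation p-value is available via
  `n_perm` for verification.  The rank-sum form (rather than a weighted
  burden z) is retained because the comparator is described as *the*
  weighted-sum statistic with a changed frequency source.

## What the simulator emulates

The generator reproduces the study conditions under which the published
tables were computed:

* **Frequencies.**  Each of 50 variants draws its population frequency
  from Wright's equilibrium density
  $\propto q^{\beta_1-1}(1-q)^{\beta_2-1}e^{\sigma(1-q)}$ with
  $\beta_1=\beta_2=0.001$, $\sigma=12$, truncated to
  $(10^{-5}, 0.999)$ — weak purifying selection, most mass below 1%.
  Sampling is inverse-CDF on a dense log-spaced grid; the boundary
  singularities are integrable and the grid resolves them (the sampler is
  checked against direct quadrature of the density).
* **Effects.**  10 or 20 DSVs are drawn uniformly among sub-1% variants;
  disease risk is $f_0 \prod_s RR_s^{X_s}$, capped at 1 (the product can
  exceed 1 for multi-copy carriers; the cap is the minimal fix).  Equal
  effects set one common relative risk; the varying-effect option solves
  $RR(p) = a e^{-bp}$ so the rarest selected DSV gets the top of the
  requested range and the commonest the bottom.
* **Families.**  Parental haplotypes are independent Bernoulli draws per
  variant (no linkage disequilibrium between variants, as assumed);
  offspring inherit one whole haplotype from each parent (no
  recombination).  Trios are ascertained on an affected offspring until
  the target count; sibpairs on discordance; the case-control sample takes
  the affected offspring as cases and an equal number of unaffected
  offspring from *different* families as controls (one offspring per
  family makes this automatic).  Generation totals are recorded so the
  prevalence can be estimated as affected/generated — the only reading
  under which prevalence is estimable at all in an ascertained design.
* **Stratification.**  Two subpopulations, mixed 50/50 by default (the
  mixture is not identified by the published description; it is
  configurable), with baseline risks 0.05 and 0.01 and subpopulation-2
  frequencies drawn from the Balding–Nichols model
  $\mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$ at $F_{ST} = 0.01$.  Whether
  the frequency shift applies to the DSVs only or to all markers is
  genuinely ambiguous in the source description.  We resolved it by the
  observable consequence: perturbing only sub-1% DSV frequencies moves
  case-control allele frequencies by amounts of order
  $\sqrt{F\,p(1-p)} \approx 3\times10^{-3}$ per DSV and produces *no*
  detectable inflation of the population-based tests, contradicting the
  strong inflation the stratified comparison is meant to exhibit.  The
  stratified experiment scenarios therefore shift all 50 markers
  (`shift_all = TRUE`); `build_effect_profile()` keeps the DSV-only
  default, with the flag as the switch.  Null stratified runs still
  designate 10 DSVs so the shift has markers to act on.
* **Coding.**  Ascertained datasets are recoded to the sample minor allele
  (judged from the design's founders), so written PED files, frequency
  estimates and thresholds are consistently minor-allele based.

What the generator does **not** emulate: linkage disequilibrium between
variants, recombination, genotyping or sequencing error, de-novo
mutation, and quantitative traits.  Calibration results under this
generator therefore speak to ascertainment, rarity and stratification —
not to error-prone calls or LD-induced covariance beyond what complete
cosegregation already produces.

## Prevalence and attributable risk summaries

Per replicate, prevalence is estimated as affected/generated offspring
during ascertainment of 500 cases.  Total attributable risk of the region
is the sum over the true DSVs of Levin's formula
$f(\widehat{OR}-1)/(1+f(\widehat{OR}-1))$, with $\widehat{OR}$ the allelic
odds ratio from the 500-case/500-control sample (0.5 continuity correction
on every cell) and $f$ the variant's minor-allele frequency among
controls.  The published per-variant formula is not recoverable from the
source, so this estimator is a reconstruction; we use the allele as the
exposure unit (rather than carrier status) because the resulting totals —
roughly the sum of DSV frequencies times $(RR-1)$ — are the ones
consistent with the published summary table, while carrier-based exposure
doubles them.  Sums are not truncated at zero, so null regions average to
approximately zero.

## Numerical and design choices

* Pseudo-inverse cutoff $10^{-8}$ (relative); rank is the number of
  singular values above it.
* Frequency-threshold comparisons are strict (`<`), matching the verbal
  definition of the rare subset.
* Markers with $\hat p \in \{0, 1\}$ or zero informative families are
  excluded from weighted analyses; a marker with positive model variance
  but all-zero observed scores cannot be correlation-rescaled and is
  dropped with a warning.
* Ties in founder allele counts during PED writing are emitted so that a
  reader's lexical tie-break reproduces the genotype counts exactly;
  round-trip identity on counts, ids and phenotypes is a tested contract.
* Per-replicate seeds are spawned from the master seed up front, so
  experiments are reproducible and methods are compared on identical data
  within each replicate.  Untestable replicates (empty rare subset, zero
  variance) are excluded from that method's denominator and reported.
* Replicate counts default to 500 and the experiment harness is vectorized
  over families and markers; the full set of replication runs (two
  prevalence scenarios, an unstratified and a stratified null, 500
  replicates of 500 trios each) completes in a few minutes on one core.
  Non-DSV marker columns are generated only for ascertained families —
  distributionally identical to full generation because unkept families'
  non-DSV genotypes influence nothing.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
profile <- build_effect_profile(n_dsv = 10, effect = list(type = "equal", rr = 2))
study <- simulate_ascertained_sample(profile, "trio", n = 500,
                                     with_case_control = TRUE)
fams <- extract_nuclear_families(study$dataset)
fbat_rare(fams, weights = "frequency")          # weighted, no threshold
fbat_rare(fams, threshold = 0.01)               # unweighted, fixed threshold
fbat_rare(fams, method = "mm", threshold = 0.01)
estimate_total_par(study$case_control, profile$dsv_indices)
```

## Known limitations

* All collapsed statistics assume effects in one direction; mixed
  protective/deleterious regions will lose power (the multimarker test is
  less affected).  Sign-split statistics are not implemented.
* Additive coding only; no X-chromosome handling; no multi-generation
  pedigree traversal beyond decomposition into nuclear families; no
  imputation of missing genotypes.
* The adjusted-covariance off-diagonal convention and the attributable-risk
  estimator are documented reconstructions (see above); both are isolated
  in single functions.
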