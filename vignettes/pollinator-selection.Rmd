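---
title: "Partitioning phenotypic selection among co-occurring pollinators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning phenotypic selection among co-occurring pollinators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Most plants are visited by several pollinator species that differ in
abundance and in pollination efficiency, yet classical phenotypic selection
analysis collapses all of them into a single fitness measure. `pollselect`
implements a partitioning approach for alfalfa-like systems: every plant's
seed set is divided among the visiting bee species in proportion to the
flowers each species visited on that plant (or, better, the flowers it
*tripped* -- in alfalfa a flower sets seed only after a visitor releases the
staminal column, and tripping rates differ strongly among bee species).
Relative fitness can then be computed *within* each pollinator species on
the same set of plants, and standard selection estimators applied per
species, per attribution basis, and for all pollinators combined.

## Fitness attribution

For plant $i$ and species $s$ with flower-visit count $v_{is}$ and tripping
rate $t_s$:

* tripped flowers: $\tau_{is} = v_{is} \, t_s$;
* shares: $p_{is} = \tau_{is} / \sum_{s'} \tau_{is'}$ (the `tripped` basis)
  or $v_{is} / \sum_{s'} v_{is'}$ (the `visited` basis);
* attributed seeds: $y_{is} = p_{is} \, y_i$, where $y_i$ is the plant's
  total seed set.

Attributed seeds are kept fractional: they are proportional expectations,
not integer realisations, and per-plant seed totals in this kind of study
are themselves fractional (products of per-stem and per-pod averages).
Attribution conserves seed set exactly: $\sum_s y_{is} = y_i$ for every
visited plant. Plants never observed being visited by species $s$ enter
that species' analysis with $y_{is} = 0$ rather than being dropped, so the
plant sample is identical in every analysis; plants with no recorded visits
at all still contribute their full seed set to the all-pollinator analysis.

Relative fitness within a group is $w_i = y_i / \bar y$, mean 1 by
construction; the opportunity for selection is $I = \mathrm{var}(w)$
(sample variance, $n-1$).

## Selection estimators

Traits are variance-standardized ($z = (x - \bar x)/s_x$, $n-1$ SD), so all
coefficients are in per-SD fitness units. With relative fitness $w$:

* the directional selection differential $S_j$ is the slope of $w$ on
  $z_j$ alone (equivalently $\mathrm{cov}(w, z_j)$) and includes indirect
  selection through correlated traits;
* the directional gradient $\beta_j$ is the partial coefficient of the
  multiple linear regression on all traits (direct selection);
* the quadratic differential $C_{jj}$ comes from the one-trait
  linear-plus-quadratic fit, and the quadratic gradient $\gamma_{jj}$ and
  correlational gradient $\gamma_{jk}$ from the full second-order model
  with all squared and cross-product terms;
* quadratic coefficients are reported as *twice* the raw regression
  coefficient, the convention that makes them estimate fitness-surface
  curvature. The doubling of $\gamma_{jj}$ is standard; whether to double
  $C_{jj}$ as well is interpretive, so both are controlled by switches
  (`double_gamma`, `double_C`, both default `TRUE`). Cross-product
  coefficients are never doubled.

Point estimates always come from regressions on *untransformed* $w$.
Because fitness residuals are typically skewed, p-values come from refits
with response $\log(w + c)$: the transform improves residual behaviour for
inference while leaving the estimates untouched. The offset $c$ defaults
to 1 when a block contains zero-fitness plants and 0 otherwise. For
heavily zero-inflated species (in the motivating system, the rare
leafcutting bee left 107 of 153 plants unvisited) even the transformed
model fits poorly; the log model can then be disabled per species
(`log_model`), leaving bootstrap-only inference.

Confidence intervals are case-resampling bootstrap percentiles (default
B = 1000, level 95%). Within every replicate the resampled plants are
re-relativized and re-standardized before re-estimation, mirroring the full
pipeline; replicates that collapse (a zero-variance trait, all-zero
fitness, a rank-deficient design) are redrawn, at most 100 times each. A
coefficient is flagged significant when its interval excludes zero.
Percentile intervals (not BCa) are used deliberately: they are what plain
bootstrap reporting in this literature means. They are mildly
anti-conservative with heavy-tailed fitness at $n \approx 150$; our null
calibration places non-coverage near 6% rather than 5%.

## Distributional selection differentials

Directional and quadratic coefficients see only the first two moments of
the fitness-weighted trait distribution. The distributional selection
differential takes the whole distribution: with post-selection weights
$w_i / \sum w_i$,

$$\mathrm{DSD} = \int \left| F(z) - F_w(z) \right| \, dz,$$

the 1-D optimal-transport (earth mover's) distance between the unweighted
and fitness-weighted empirical CDFs, computed exactly as the area between
the two step functions over merged sorted breakpoints. It decomposes as
$\mathrm{DSD} = d_D + d_N$ with $d_D = \left| \sum w_i z_i / \sum w_i -
\bar z \right|$ the mean-shift (directional) component and $d_N \ge 0$ the
residual shape change; the transport bound guarantees
$\mathrm{DSD} \ge d_D$. Note $d_D$ is population-weighted, so under
sample-SD standardization $d_D = |S| \, (n-1)/n$, a deliberate,
documented hair's difference from the regression $S$ -- the two labels are
often conflated.

The probability columns use a permutation test (fitness shuffled across
plants, default B = 1999, $p = (1 + \#\{\text{perm} \ge \text{obs}\}) /
(B+1)$): the upstream literature does not specify its inference procedure,
so we chose the simplest exchangeability-based one and say so. The related
"distributional gradients" are defined in an external reference and are
out of scope here.

## The synthetic-data generator

No per-plant raw data are deposited for the motivating field study, so the
package ships a generator calibrated to the study's printed summary
statistics; it is first-class, tested code and the basis of the power and
calibration suites.

* **Traits.** Six floral traits (stems/plant, racemes/stem, open
  flowers/raceme, hue, chroma, reflectivity) are truncated normals whose
  underlying location and scale are *solved numerically* so the realised
  post-truncation mean and SD equal the printed ones (30.65 ± 16.4 stems,
  4.93 ± 3.41 racemes/stem, 7.53 ± 2.44 flowers/raceme, −0.012 ± 0.476
  hue, 1.29 ± 0.76 chroma, 3.76 ± 1.11 reflectivity). Naive truncation of
  a normal with those moments would inflate, e.g., racemes/stem to ≈ 5.44.
  Correlation enters through a Gaussian copula, leaving marginals exact;
  the default correlation is the identity because field inter-trait
  correlations are not published -- a stated assumption, not an estimate.
  Stems are integer, floor 1.
* **Visits.** Per plant × species counts are Poisson (negative binomial
  behind a switch) with log-linear intensity in the standardized traits --
  intercepts, linear, quadratic and pairwise interaction terms per species
  -- rescaled so the expected grand total is 8,727 visits. Default
  intercepts reproduce the observed 52.3/45.0/2.7% bumble/honey/leafcutting
  mix. Standardization uses the generated sample's own moments so
  preference coefficients live on the analysis scale: a linear preference
  of 0.6 on stems induces a directional gradient near 0.6.
* **Seeds.** Expected seed set is $\sum_s v_{is} t_s \kappa$ with tripping
  rates 0.55/0.25/0.80 (bumble/honey/leafcutting). κ = 31.4 seeds per
  tripped flower and negative-binomial dispersion θ = 0.6 are the two
  free constants; they were solved once from the printed seed-set moments
  (754.67 ± 986.90 at 8,727 visits over 153 plants): κ sets the mean and
  absorbs visitation outside the two-week observation window, θ sets the
  variance. These defaults imply an overall opportunity for selection of
  ≈ 1.7, incidentally close to the study's 1.74. With `noise = FALSE`
  seed set equals its expectation exactly and the tripped-basis
  attribution recovers each species' generative contribution to machine
  precision -- the conservation oracle for the whole chain.

What a green simulation test does *not* establish: the generator has no
spatial foraging, no temporal structure, no trait correlations by default,
and Poisson visits under-disperse relative to real bee revisitation
sequences (the real study saw 70% of plants unvisited by leafcutting bees;
Poisson at the same mean gives fewer zeros). Power numbers transfer to
field data only qualitatively.

## Numerical choices and degenerate inputs

* All randomness flows from one master seed; each stage (plants, visits,
  seeds, bootstrap, permutations) derives its own stream via a documented
  label-hash split, so runs are reproducible and stages independent.
* Conservation and estimator identities are asserted at 1e-9; exact
  algebraic facts (doubling, mean-1 relativization) at 1e-12.
* Zero-variance traits, all-zero fitness vectors and rank-deficient
  designs raise typed errors naming the offending columns; the 2-level
  factorial design, whose squared terms alias the intercept, is rejected
  rather than silently dropped.
* `n` must exceed 28 (the full second-order parameter count for six
  traits) for gradient estimation; the pipeline refuses smaller samples.

## Open design decisions taken

* Whether the original analysis doubled $C_{jj}$ is not stated; we double
  by default and expose the switch.
* How zero-fitness plants entered the original log model is not stated; we
  default to offset 1 in their presence and expose `log_offset`.
* Whether bootstrap replicates re-standardized traits is not stated; we do
  (it mirrors the estimation pipeline end to end) and expose
  `restandardize`.
* The DSD probability procedure is not described upstream; we use
  permutation inference as documented above.

## Limitations

Attribution assumes seeds follow visit (or tripped-visit) proportions
exactly -- no pollen carry-over, no pollinator-specific per-visit seed
quality beyond tripping rate, no male-function fitness. The bootstrap and
permutation procedures assume exchangeable plants (no spatial
autocorrelation). Gradient comparisons *across* species are qualitative;
no formal test of gradient differences is provided.
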