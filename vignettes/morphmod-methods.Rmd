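---
title: "Methods: modularity, integration and evolvability of a 14-trait body"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modularity, integration and evolvability of a 14-trait body}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphmod)
```

## The problem and the model

`morphmod` analyses variational modularity — the tendency of some trait
sets to covary more strongly with each other than with the rest of the
body — in tables of linear body measurements grouped by sex, age class and
habitat. The canonical layout is 14 traits: head length, neck length and
neck diameter (head/neck region), trunk length, chest width and chest
depth (trunk), four forelimb and four hindlimb dimensions. All inference
runs on per-group trait association matrices, so the pipeline is, at its
core, careful bookkeeping around three matrix statistics: Pearson
correlation structure, its eigenvalue dispersion, and its behaviour under
simulated selection.

The stages and the choices behind them are described below in pipeline
order. Every empirical statement in this vignette is computed by the
package's tests or by `scripts/acceptance.R`; nothing is quoted from
external data.

## Synthetic data: what the generator emulates

No raw field data ship with the package, so a seeded generator
(`sim_config()`, `simulate_traits()`) produces tables with the structure
the analysis assumes:

* a shared lognormal **body-size factor** per individual,
  `s ~ N(mean_log_size, sd_log_size)`, entering each log-trait through a
  per-trait allometric exponent `b_t`;
* additive **population offsets** on the log scale (two localities per
  habitat by default), which the preprocessing stage must remove;
* **block-modular residuals**: multivariate normal with correlation
  `rho_within` inside the modules of a generating partition and
  `rho_between` elsewhere, scaled by `residual_sd`.

Generation happens on the log scale and is exponentiated, so traits are
strictly positive and the power-law allometric model used downstream is
*exactly* correct for generated data — parameter recovery is an exact
test, not an approximation. The default design is 8 sex/age/habitat groups
of 70 individuals (560 rows), echoing a field study's scale of a few
hundred animals over a handful of localities without copying any real
sample table. Trait baselines (e.g. trunk length ≈ 92 cm) are plausible
ungulate magnitudes, explicitly non-empirical. Default group differences
encode the gradients the analysis should detect: adults larger than
subadults, residual integration higher in subadults, in closed habitats
and (slightly) in females. The generating partition is
trunk+forelimbs+hindlimbs with `rho_within = 0.40`, `rho_between = 0.10`,
`residual_sd = 0.05`, `sd_log_size = 0.12`.

What the generator does **not** emulate: measurement rounding (real tapes
read to 1 cm), age-estimation error, missing data, non-normal residuals,
and any geographic or temporal autocorrelation. Passing tests therefore
demonstrate correctness of the statistical machinery under its own
assumptions, not robustness to those field artefacts.

Randomness discipline: one root seed, deterministic child streams per
group (`seed * 7919 + 104729 * i mod 2^31 - 1`), so any group can be
regenerated independently and the full table is bit-identical across runs.

## Preprocessing

**Population adjustment** shifts every population's values, per trait and
per group, up to the maximum population mean. With two populations this is
literally "add the difference in means to the population with the smaller
mean"; the maximum-mean generalisation to three or more populations keeps
that behaviour as a special case and keeps values positive. Shifts are
additive, so within-population covariance matrices are untouched and the
operation is idempotent.

**Allometric correction** uses the geometric mean (GM) of the 14 traits as
the overall size measure and the power law `Y* = Y (X0/X)^b`. Two points
were genuinely open and are resolved as follows:

* *The regression covariate.* A regression of log-traits onto a
  group-average size would regress on a constant, which is undefined; the
  covariate is therefore the **per-individual** log GM, and `X0` is the
  group-level geometric mean of those individual sizes. Because `b` is
  estimated by OLS of log *Y* on log *X*, the corrected log-trait is the
  regression residual plus a constant — the trait–size correlation after
  correction is zero to machine precision within each group by
  construction.
* *Scaling to body size 1.* After correction every trait is divided by
  `X0`, putting all individuals of all groups at a common theoretical size
  of 1. The mechanism is recorded in the output flags
  (`adjustment_flags()`), and can be disabled
  (`rescale_to_unit_size = FALSE`).

Partial-correlation analysis deliberately receives population-adjusted but
**not** allometry-adjusted data: conditioning on all other traits already
holds shared size constant, and removing it twice distorts the conditional
structure. All other matrix analyses use fully adjusted data.

## Correlation matrices and Mantel machinery

Matrix correlation is Pearson correlation over the 91 off-diagonal
lower-triangle elements. Diagonals are excluded for every matrix type:
they carry no information in correlation matrices and would dominate
covariance comparisons. The Mantel test permutes the trait labels of the
second matrix (rows and columns jointly) and reports the one-tailed
`p = (#\{r_perm >= r_obs\} + 1) / (n_perm + 1)`; the +1 correction
guarantees `p > 0` and makes "exceeds 95% of the permutation distribution"
the exact rejection rule at the default 999 permutations. A constant
(equicorrelated) matrix has zero off-diagonal variance and raises an error
rather than returning a vacuous correlation.

Repeatability is Cheverud-style self-similarity: rows are bootstrapped,
the matrix re-estimated, and `t` is the **mean** matrix correlation
between bootstrap and observed matrices (the mean, not the median, is the
recorded aggregation choice). Between-group correlations are reported raw;
the noise-adjusted variant `r / sqrt(t1 t2)` is deliberately not applied
anywhere.

## Modularity hypotheses and likelihood comparison

The eleven a priori hypotheses are fixed partitions of the 14 traits
(`builtin_hypotheses()`); `connectivity_matrix()` encodes each as a binary
matrix with ones for within-module pairs. Hypotheses are screened by
Mantel tests, then compared by likelihood (`emmli_fit()`): each observed
correlation `r_ij` is modelled via Fisher's `z` as normal with variance
`1/(n-3)`, with one pooled parameter per within-module class and **one**
pooled parameter for all remaining pairs. The closed-form MLE per class is
`tanh(mean z)`. Models are ranked by
`AICc = -2 lnL + 2k + 2k(k+1)/(m-k-1)` with `m = 91`, and by Akaike
weights as posterior probabilities. Richer between-class structures (one
parameter per module pair) are intentionally out of scope, but the class
assignment is isolated in one internal function and straightforward to
extend.

`k` counts every estimated correlation class, including the pooled
between-module class — a three-module hypothesis has `k = 4`, the null
(one pooled correlation) `k = 1`. The likelihood-ratio gate for comparing
two screened hypotheses is `2 |lnL1 - lnL2| > 3.841`, the χ² critical
value with 1 d.f. at α = 0.05, computed (not hard-coded) via `qchisq`.
The null model is included in the comparison set by default
(`include_null = TRUE`) and can be dropped to compare only the a priori
hypotheses.

## Conditional-independence graphs

Full partial correlations come from the precision matrix,
`partial_r(i,j) = -W_ij / sqrt(W_ii W_jj)`, conditioning each pair on all
12 remaining traits — the Gaussian graphical-model convention. Edges are
kept when the edge-exclusion deviance `EED = -N ln(1 - partial_r^2)`
reaches the χ²₁ critical value at `alpha` (3.841 at 0.05); `N` is the
group sample size, used exactly as the formula states (no degrees-of-
freedom correction). A correlation matrix with smallest eigenvalue below
1e-10 is treated as singular and refused, since inverse-based partials are
then numerically meaningless.

"Strong" edges — the visually emphasised subset in conditional-independence
graph figures — have no standard numeric definition; here they are the top
decile of |partial r| among significant edges (`strong_quantile = 0.90`,
configurable), recorded as an interpretation. Per-trait connectivity
(incident significant edges), per-trait mean |partial r|, average
connectivity `2E/14` and the fraction of the 91 potential edges present
are exported in tidy tables; the factorial ANOVA/GLM on those metrics is
deliberately not re-implemented — any stats package consumes the exported
table directly.

## Integration index

`VE` is the variance of the correlation-matrix eigenvalues around their
known mean of 1, computed as a population variance (divide by `N = 14`).
Under that convention the maximum — attained by the all-ones matrix — is
exactly `N - 1`, so `VE_SD = VE/(N-1)` is exactly 1 at maximal integration
and exactly `rho^2` for an equicorrelated matrix, a closed form the tests
assert at 1e-12. Dividing by `N - 1` inside `VE` instead would break both
identities; that is why the population variance is the only convention
used.

The bootstrap comparison of two groups resamples each group's rows,
recomputes `VE_SD` per iteration, labels the group with the smaller point
estimate, and reports the fraction of iterations in which the smaller
group's bootstrap value reaches or exceeds the larger group's. The
iteration pairing was ambiguous in the underlying verbal rule ("the number
of times the smaller group's VE exceeds the bootstrapped values of the
larger"): both a paired-by-iteration and an all-vs-all reading are
implemented (`pairing = "paired"` / `"all"`); paired is the default for
determinism and O(iterations) cost. Under the null this p-value is
approximately uniform on (0, 0.5] (the smaller group is selected
two-sidedly), giving a ~10% rejection rate at the 0.05 threshold — the
calibration the acceptance tests check.

## Evolvability indices

Selection vectors are isotropic unit Gaussians (`random_skewers()`), the
standard random-skewers choice. With the phenotypic covariance matrix `P`
substituting for `G` in the breeder's equation `dz = P beta`:

* **evolvability (flexibility)** — mean cosine between `beta` and
  `P beta`; 1 for isotropic `P`, decreasing with anisotropy;
* **conditional evolvability** — mean of `1/(beta' P^-1 beta)`, the
  response available along `beta` under stabilising selection on all
  orthogonal directions; per-skewer it never exceeds the directional
  evolvability `beta' P beta` (asserted vector-by-vector in tests);
* **constraints** — mean |cos| between the **response** vector and PC1 of
  `P`. Whether selection or response should be compared to PC1 is not
  derivable from the verbal definition; the response-vector convention is
  adopted and flagged here.

Scale laws anchor the units: evolvability and constraints are invariant
under `P -> cP`, conditional evolvability scales by `c`. Conditional
evolvability is therefore reported in squared trait units (tiny numbers,
~1e-5, for size-standardised traits near 1) and only scale-free properties
are asserted about it. One shared skewer set is used across groups in a
comparison batch so between-group differences are not skewer noise.

## Ordination

Group distances are `1 - matrix_correlation` between covariance matrices,
using the same off-diagonal lower-triangle convention as everywhere else
(covariance diagonals could arguably be included; consistency won).
Classical scaling is delegated to `stats::cmdscale` — the canonical
implementation of double-centred eigendecomposition, cross-checked in the
tests against an explicit `-1/2 J D^2 J` oracle. Negative eigenvalues are
reported untouched (no Cailliez/Lingoes correction): with eight points the
ordination is descriptive.

## Numerical choices and degenerate inputs

* PSD gate for generated correlation matrices: smallest eigenvalue
  ≥ −1e-10; the generator uses a symmetric eigen square root (negative
  round-off eigenvalues clamped to zero), so zero-noise and boundary-PSD
  configs are handled exactly.
* Fisher transform: |r| = 1 is clipped to 0.9999 with a warning.
* Pearson matrices require ≥ 3 individuals and no constant trait (named in
  the error); bootstrap draws that produce a constant trait are redrawn.
* Mantel requires ≥ 100 permutations; p can never be 0 by the +1 rule.
* Groups smaller than 15 individuals trigger a pipeline warning
  (Fisher-z variance and precision-matrix inversion degrade; with n ≤ 14
  the 14-trait correlation matrix is singular and the graph stage refuses
  it).

## Test problem sizes

The suite exercises exact identities at machine tolerance and statistical
properties by simulation: slope/size-removal recovery at n = 2000,
residual-correlation recovery at n = 4000–8000 (where the ±0.05 recovery
bands sit comfortably outside pure Pearson sampling noise), model recovery
and Mantel power at n = 150 over 100 seeded replicates, null calibrations
over 100–200 replicates with 199–200 permutations/iterations each, and a
full-pipeline structural run on the default 560-row design. These sizes
were chosen so each property's expected sampling noise is several times
smaller than the asserted margin.

## Known limitations

* The likelihood comparison uses the simplest between-module pooling; data
  generated with strongly heterogeneous between-module correlations will
  fit all eleven hypotheses imperfectly.
* The EED test uses `N` as printed, not an effective sample size; for
  n close to the trait count it is anticonservative.
* Bootstrap group comparisons are approximate-level tests (see the
  calibration analysis above), not exact permutation tests.
* The generator's groups share one residual partition per config; studies
  of between-group *pattern* differences should combine configs with
  different generating partitions, as the ordination tests do.
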