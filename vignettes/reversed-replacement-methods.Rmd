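---
title: "Reconstructing honest responses from fake-good data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing honest responses from fake-good data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsgr)
```

## The problem

Self-report questionnaires are vulnerable to *fake-good* distortion:
respondents under social pressure (job applicants, students graded on
attitudes, patients seeking a diagnosis or avoiding one) shift their
answers upward. The honest data matrix D is never observed; only a
suspected-fake matrix F is. `rsgr` treats reconstruction as a probabilistic
sensitivity analysis: instead of claiming to recover D, it samples many
candidate D matrices under explicit, parameterized hypotheses about *how*
the faking happened, and reports how each hypothesis moves the statistics a
researcher cares about.

## The reversing distribution

Fake-good responding is assumed strictly upward: every honest value is less
than or equal to its observed counterpart. Reconstruction therefore only
lowers entries. An observed value k is kept with probability 1 − π and
otherwise replaced by a draw from a discrete generalized beta (DG)
distribution on {1, …, k − 1}; the value 1 is absorbing (it cannot have
been inflated into). The DG mass at h on support {a, …, b} is proportional
to (h − a + 1)^(γ−1)(b − h + 1)^(δ−1), normalized over the support. The
literature that introduced this family does not print a normalization
constant; normalizing over the integer support makes every proportional
variant identical, so nothing is lost.

Three canonical shape pairs are built in:

* **uninformative** (γ = δ = 1): uniform replacement — use when nothing is
  known about the faking mechanism;
* **slight** (γ = 4, δ = 1.5): mass piles up adjacent to k — small
  distortions are most likely;
* **extreme** (γ = 1.5, δ = 4): mass piles up far below k — gross
  distortions are most likely.

The labels follow the shapes' behavior, which the package verifies as a
property test: the slight pmf is strictly increasing toward k over
{1, …, k − 1}, the extreme pmf strictly decreasing.

### The forward (corruption) model

Only the reverse model is needed for reconstruction, but simulation
studies need the *generating* direction too: corrupting a known honest D
into a fake F so recovery can be measured. The forward model is defined as
the exact value reflection of the reverse model — perturbing X forward is
distributionally identical to q + 1 minus the reverse perturbation of
q + 1 − X — with the (γ, δ) pair swapped, so a scenario name means the same
thing in both directions ("slight" = small shifts). The reflection identity
is asserted analytically in the tests, and again empirically by a
goodness-of-fit test on sampled draws.

### Interpretation of π

π is a *per-entry* replacement probability: each eligible entry is
independently replaced with probability π, so a fraction π of eligible
entries is replaced in expectation, not exactly. The alternative reading —
selecting an exact π-fraction of cells without replacement — is defensible,
but the conditional-distribution form of the model is inherently
per-entry, and the independent version is what the package implements
throughout. Per-respondent or per-item heterogeneous π is out of scope.

### Determinism

`perturb_matrix` consumes one uniform draw per entry in row-major order and
inverts the entry's conditional CDF, so a (matrix, parameters, seed) triple
fixes the output exactly. The grid runner derives every replicate seed from
the master seed by an integer hash kept inside the 32-bit range; rerunning
a grid reproduces the replicate table bit-for-bit.

## The generator of honest data

Study-style simulations need honest matrices with a stated statistical
structure: 5-point items, binomial-shaped marginals with parameter 0.5
(symmetric around 3), and a uniform medium inter-item correlation near
0.25 induced by a single factor. The generating mechanism behind those
three properties was open; the package uses the simplest one that satisfies
them jointly, a Gaussian-copula latent one-factor model:

1. each latent item is √ρ_latent · common factor + √(1 − ρ_latent) · noise,
   giving unit variances and equicorrelation ρ_latent;
2. each column is discretized through thresholds
   c_v = Φ⁻¹(F_B(v − 1)), where F_B is the Binomial(q − 1, p) CDF, which
   makes the marginal distribution *exactly* binomial-shaped;
3. discretization attenuates correlation, so ρ_latent is calibrated by
   monotone bisection until the observed-scale Pearson correlation of the
   discretized pair hits the target (default tolerance 1e-4, contract
   0.005). For a target of 0.25 with q = 5, p = 0.5 the calibrated latent
   value is about 0.275.

The bivariate-normal rectangle probabilities used by the calibration are
computed by adaptive quadrature of the classical single-integral identity
for Φ₂ (derivative with respect to the correlation); no bivariate-normal
package is required, and the quadrature was validated against a
five-million-draw Monte-Carlo estimate (agreement within 4e-4, the MC
standard error).

What the generator deliberately does **not** emulate: item-specific
marginals, multi-factor or hierarchical structure, respondent
heterogeneity, and missing data. A green recovery test therefore
establishes that the method works *when the world matches the stated
generative model*, nothing stronger.

## The one-factor CFA

The grid records factor loadings and fit indices per reconstructed matrix,
from a one-factor confirmatory model Σ = λλᵀ + diag(ψ) fit by maximum
likelihood on the Pearson covariance of the integer scores:

* discrepancy F = log|Σ| − log|S| + tr(SΣ⁻¹) − m, minimized by BFGS with
  the analytic gradient; χ² = (n − 1)·F at the optimum;
* start values: first principal-component pattern v₁√e₁, with
  ψ₀ = diag(S) − λ₀² floored at 5% of the item variance;
* ψ is **unconstrained**, so Heywood cases (negative error variances) can
  and do occur; they are flagged improper — along with |λ| > 10 — rather
  than prevented, because the Monte-Carlo pipeline's exclusion counts are
  part of the output;
* loading signs are fixed by forcing a nonnegative mean loading;
* convergence: optimizer success or gradient norm below 1e-6 within 500
  iterations; a degenerate baseline (zero baseline χ², e.g. an identity
  covariance) leaves the incremental indices undefined and marks the
  replicate non-converged so it is excluded like any other failure.

Fit indices use the standard definitions against the independence baseline
(χ²_b = −(n − 1)·log|R|, df m(m − 1)/2): NFI, CFI, NNFI/TLI (which can
exceed 1), and RMSEA.

A deliberate design choice: ordinal-data CFA is classically estimated by
diagonally weighted least squares on polychoric correlations. This package
uses plain ML on Pearson covariances instead. The pipeline's purpose is
*comparative* — the same estimator is applied to every reconstructed matrix
and to the control, and only relative bias is interpreted — so the simpler
estimator is adequate; absolute index values from a DWLS analysis of the
same data would differ, and no numeric equality with published
DWLS results is claimed.

## The experiment grid and ARB

For each scenario × π cell (defaults: three scenarios × π ∈
{0.25, 0.5, 0.75, 1}, B = 2000 replicates), the runner reconstructs B
matrices and records marginal means, loadings and fit indices. Replicates
that fail to converge or are improper are excluded, and the books
(used + excluded = B) are reported per cell. The summary statistic is the
average relative bias

ARB = 100 · (1/B) Σ_b (1/V) Σ_v (θ̂_bv − θ_v)/θ_v,

computed per statistic family against injectable control statistics: an
honest control group's matrix, generative-model values, or a π = 0
self-fit. Averaging within replicate first and then across replicates
follows the formula literally; with equal V per replicate it coincides
with pooling all terms. ARB is undefined when any control value is zero —
the error is raised, not patched — and loadings are paired to controls in
item order, the only order-preserving choice. Conventional reading:
|ARB| < 5% trivial, 5–10% moderate, > 10% substantial.

## Numerical choices and degenerate inputs

* DG weights are computed on the log scale to survive large shapes or
  supports; a single-point support returns a point mass; k = 2 under
  reverse needs no special casing (the DG support is {1}).
* Replacement pmfs are closed at the top of the CDF to absorb roundoff, so
  inverse-CDF sampling can never emit an out-of-range category.
* Matrices with missing, non-integer, or out-of-range cells are rejected
  at ingest with the offending row and column named; nothing is imputed.
* `rho_target` is capped below 0.95 and the calibration reports an
  explicit error if the discretization ceiling makes a target unreachable.

## Known limitations

* Scenario plausibility is judged through |ARB| on a finite grid; the true
  faking process may sit between grid points or outside the DG family.
* The ML-on-Pearson CFA treats ordinal scores as interval; fit indices are
  comparative tools here, not absolute model assessments.
* Reconstruction assumes all distortion is upward; mixed faking
  (good and bad in one sample) is not modeled.
* Reported recovery rates come from the package's own generative world
  (equicorrelated single factor, homogeneous π); real questionnaires
  violate some of those assumptions.
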