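---
title: "Entropy-based factor contributions and canonical factor analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-based factor contributions and canonical factor analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canfa)
```

## The model and its assumptions

`canfa` works on a *fitted* common-factor model for p standardized
manifest variables and m common factors,

$$X_i = \sum_{j=1}^m \lambda_{ij}\,\xi_j + \varepsilon_i,\qquad
\mathrm{Var}(\xi_j)=1,\ \mathrm{Cov}(\xi_k,\xi_l)=\phi_{kl},\
\mathrm{Var}(\varepsilon_i)=\omega_i^2>0,$$

with mutually uncorrelated unique factors (Ω diagonal — correlated
uniquenesses are out of scope) and Gaussian errors for the entropy
interpretation. All quantities in the package are population functions of
(Λ, Φ, ω²); estimating these parameters from data, and rotation criteria
such as varimax or oblimin, are deliberately not part of the package: any
factor-analysis fit can supply the inputs.

**Uniqueness convention.** Published loading tables usually print
uniquenesses rounded to two decimals, while their loadings imply
ω² = 1 − communality at full precision. Chained rounding of ω² is the
dominant error source in small worked examples (a uniqueness of 0.0447
printed as 0.04 shifts a contribution of ~20 by ~10%). `factorModel()`
therefore honors user-supplied ω² but offers
`recomputeUniqueness = TRUE`, which the built-in example models use; when
both are supplied the flag wins, with a warning.

## The contribution measure

The contribution of ξ to X is the symmetrized Kullback–Leibler
information between the conditional law of X given ξ and its marginal.
For the Gaussian model it has the closed form

$$KL(X,\xi) \;=\; \sum_{i=1}^p
\frac{(\Lambda\Phi\Lambda^\mathsf{T})_{ii}}{\omega_i^2},$$

a signal-to-noise ratio that is additive over variables and over any
partition of X into subvectors (`klContribution`,
`variableContributions`). The entropy coefficient of determination
`ECD = KL/(KL+1)` maps it to [0, 1) as an entropy analogue of R².

**Single-factor contributions.** For a factor η = fᵀξ the package uses
the marginal form

$$C(\eta \to X) = \sum_i
\frac{\mathrm{Cov}(X_i,\eta)^2}{\omega_i^2\,\mathrm{Var}(\eta)},\qquad
\mathrm{Cov}(X,\eta) = \Lambda\Phi f,\ \mathrm{Var}(\eta)=f^\mathsf{T}\Phi f.$$

The definitional route is conditional: C(η→X) = KL(X,ξ) minus the
conditional information given η. Under the Gaussian joint distribution the
two coincide, because conditioning on η reduces each Cov(X_i, θ_i) by
exactly Cov(X_i, η)²/Var(η); `conditionalKL()` implements the conditional
route independently, and the equivalence is asserted to 1e-8 across random
models in the test suite rather than assumed. The marginal form is the
implementation because it is direct, O(pm) and manifestly scale-invariant
in f.

For correlated (oblique) factors the relative contributions RC = C/KL of
a set of factors may sum above one; this is a property of the measure, not
an artifact, and no renormalization is applied.

## Canonical factor analysis

Canonical correlation analysis between a manifest subvector X(a) and ξ,
computed from model-implied covariances, decomposes the subvector's
contribution exactly:

$$KL(X_{(a)},\xi) = \sum_{j=1}^{m_{(a)}}
\frac{\rho_{(a)j}^2}{1-\rho_{(a)j}^2},\qquad
m_{(a)} = \min\{\dim X_{(a)},\, m\},$$

and importance order of the canonical common factors is the order of the
canonical correlations. The analysis is invariant under nonsingular
transforms of X or ξ, so its output does not depend on the initial
rotation of the fit — the property that makes it usable as a rotation-free
interpretability tool.

**Numerical route.** The contributions ρ²/(1−ρ²) are the eigenvalues of
AΦ with A = Λₐᵀ Ωₐ⁻¹ Λₐ, via the symmetric eigenproblem on Tᵀ A T where
Φ = TTᵀ is the Cholesky factorization. This follows from
ΛₐᵀΣₐ⁻¹ΛₐΦ = AΦ(I + AΦ)⁻¹: the textbook CCA eigenvalues are
ρ² = a/(1+a). The route never inverts Σₐ for the eigenvalues and stays
accurate when uniquenesses are small — the regime where the measure is
most interesting. Manifest-side coefficients are recovered as
b ∝ Σₐ⁻¹ΛₐΦf, normalized to unit variance.

**Conventions and edge cases.**

* *Sign*: each factor coefficient vector is oriented so its
  largest-magnitude entry is positive; manifest coefficients then make
  corr(V_j, η_j) = +ρ_j.
* *Ties*: equal eigenvalues (within 1e-12) are ordered lexicographically
  on the oriented coefficient vectors, for reproducible output.
* *Degeneracy*: positive definiteness of Φ and Σ is required with a
  relative eigenvalue tolerance of 1e-10, and transforms are rejected
  above condition number 1e12 — conventional numerical safety margins. If
  1 − ρ² falls below 1e-12 (uniqueness at machine level) the pair is
  flagged `capped` with a warning instead of overflowing.
* Manifest-side canonical coefficients are normalized to unit *variance*
  (bᵀΣₐb = 1). Published tables sometimes normalize to unit Euclidean
  norm instead; only the normalization differs, not the variate.

## Derived interpretable factors

Given m substantive groups of variables (for example liberal-arts versus
science scores), `selectLeadingFactors()` stacks each group's leading
canonical factor coefficients into an m×m matrix G, and
`deriveFactorSystem()` re-expresses the model on η = Gξ: loadings
Λ* = ΛG⁻¹, factor correlations GΦGᵀ, uniquenesses unchanged. The
re-parametrization is exact (Λ*G = Λ, implied Σ preserved, total KL
preserved), so nothing is lost — the model is merely rotated, obliquely,
into interpretable axes.

Design choices made here, where the design was genuinely open:

* *Square G only for loadings.* Λ* = ΛG⁻¹ needs a full-rank square
  system, so re-expressed loadings require exactly m groups; the error
  message says so. Contributions of any number of derived factors remain
  available through `factorContribution()`, and systems with more derived
  factors than dimensions are handled per factor-pair (any square
  selection is accepted).
* *Row normalization.* Rows of G are rescaled to unit variance under Φ
  before inversion, keeping Var(η_k) = 1 so that GΦGᵀ is a correlation
  matrix and loadings are comparable across systems.
* *Ordering.* Derived factors keep the user's group order; no automatic
  reassignment is attempted (and no search over groupings — groups are
  substantive inputs, not tuning targets).

## The synthetic generator and the oracles

`simulateFactorModel()` emulates the simple-structure pattern of rotated
solutions: one dominant loading per variable (default range 0.5–0.9,
typical of well-identified scales), small cross-loadings (±0.2), a factor
correlation matrix interpolating between identity and a random correlation
matrix, and uniquenesses 1 − communality floored at 0.1 by row rescaling.
These defaults generate the kind of model the method targets; property
tests sweep p ∈ 3–8, m ∈ 1–3 and orthogonal through strongly correlated
factors (200 models per invariant; 50 random transforms for the
invariance checks).

Two independent oracles guard the closed forms:

* `mcKLEstimate()` evaluates both directed integrals of the symmetrized
  divergence by Monte Carlo with exact Gaussian log-densities — the
  density-level definition, sharing no code path with the moment formula —
  and agrees with `klContribution()` within 3 standard errors (10⁶ draws
  for the example models, 5×10⁴ in the random-model sweep).
* Sample CCA (`stats::cancor`) on 10⁶ simulated observations recovers the
  model-implied canonical correlations within 3 asymptotic standard
  errors.

What the generator does **not** emulate: non-Gaussian errors (the moment
formulas are distribution-free, but the KL interpretation is validated
only in the Gaussian case), Heywood-adjacent fits (communalities ≥ 1 are
rejected, not repaired), correlated uniquenesses, and sampling variability
of the loading estimates themselves. Passing tests therefore certify the
population algebra and the numerics, not the behaviour of the pipeline
under estimation noise in Λ.

## Limitations

* All quantities are population-level; no standard errors or inference
  for canonical correlations or contributions.
* Conditional contributions given more than one factor simultaneously are
  not provided.
* Internally everything is double precision; printed output rounds to 3
  decimals. Comparisons against hand-rounded published tables should
  expect ~1% drift from their chained rounding, which is why the built-in
  examples recompute uniquenesses.
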