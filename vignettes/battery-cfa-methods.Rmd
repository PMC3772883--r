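---
title: "Covariance-structure models for cognitive test batteries: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariance-structure models for cognitive test batteries: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfabattery)
```

## The problem

A cognitive battery such as the WAIS-IV reports 15 subtest scores whose
pairwise correlations are summarized, per age band, in published manual
tables. Competing structural accounts of those correlations differ in how
latent abilities map onto subtests: *simple structure* models give each
subtest a single group factor, with the factors tied together either by a
second-order general factor (hierarchical) or by free factor correlations
(oblique); *multidimensional* models instead let several orthogonal
factors — including a general factor entered directly as a "nested"
(bifactor-style) column — load on every subtest. `cfabattery` implements
the full comparison pipeline: pooling correlation tables, maximum-likelihood
fitting of all four structure kinds, the classic fit indices, stepwise
modification driven by Lagrange-multiplier and Wald projections, and
fixed-loading cross-validation to new populations.

The actual WAIS-IV standardization correlations are proprietary and are not
included or reproduced. Everything in the package runs on synthetic
surrogates with known ground truth, or on user-supplied matrices.

## Model and estimation

A model for $p$ observed variables with $m$ factors is
$$\Sigma(\theta) \;=\; \Lambda \Phi \Lambda^\top + \Theta,$$
with $\Lambda$ ($p \times m$) the loading matrix (each cell free or fixed,
almost always fixed at 0), $\Theta$ diagonal (the uniquenesses), and $\Phi$
given by the structure kind:

* **orthonormal / nested** — $\Phi = I$. A nested model is an orthonormal
  model whose pattern includes one general column loading on every subtest.
* **oblique** — $\mathrm{diag}(\Phi) = 1$, off-diagonals free (bounded in
  $(-0.995, 0.995)$).
* **second-order** — $\Phi = \Gamma\Gamma^\top + \mathrm{diag}(\Psi)$ with
  the $m$ second-order loadings $\Gamma$ free, the disturbances $\Psi$ free
  with lower bound 0, and the general factor's variance fixed at 1.

All first-order latent variances are fixed at 1 except under the
second-order structure, where a group factor's variance is
$\gamma_j^2 + \psi_j$ and its scale is carried by $\Gamma$ and $\Psi$ with
no reference loadings. As parameterized this leaves one scale indeterminacy
per group factor ($\Lambda_j \to c\Lambda_j$, $\gamma_j \to \gamma_j/c$,
$\psi_j \to \psi_j/c^2$ leaves $\Sigma$ unchanged): the implied matrix,
discrepancy, $\chi^2$ and every fit index are unaffected, the optimizer
simply lands somewhere on the solution manifold, and the conventional df
bookkeeping (which counts $\Gamma$ and $\Psi$ as free) is what the
comparison tables use. Parameter-recovery guarantees are therefore stated
for the identified structures (orthonormal, nested, oblique).

Estimation minimizes the Wishart maximum-likelihood discrepancy
$$F(S, \Sigma) = \ln|\Sigma| + \mathrm{tr}(S\Sigma^{-1}) - \ln|S| - p,$$
with $\chi^2 = (N-1)\,F_{\min}$. The input correlation matrix is analyzed
as if it were a covariance matrix — the convention of SAS CALIS and LISREL
for matrix input, and the convention under which the published index
arithmetic (RMSEA, CFI, the Akaike column) reproduces exactly. The known
caveat applies: standard errors computed this way do not account for the
diagonal being fixed by standardization; the package reports them for
projection purposes (LM/Wald ranking), not as calibrated confidence
intervals.

### Numerical choices

* **Optimizer.** Bound-constrained quasi-Newton (`optim` L-BFGS-B) with the
  analytic gradient ($\partial F/\partial \Sigma = \Sigma^{-1}(\Sigma -
  S)\Sigma^{-1}$, chained through $\Lambda$, $\Phi$, $\Theta$); convergence
  control `factr = 1e2`, `pgtol = 1e-7`, at most 2000 iterations; a fit is
  flagged converged when the free-parameter gradient (off active bounds) is
  below `1e-4`. No random numbers are used anywhere in estimation:
  determinism given `(spec, sample, start)` is a contract.
* **Starting values.** Free loadings start at 0.5 *plus a small fixed
  cell-dependent offset* (at most $\pm 0.02$, a deterministic arithmetic
  formula of the cell's row and column). The offset exists because a flat
  start makes the columns of a full-loading pattern exactly exchangeable:
  the gradient is then identical across columns and a quasi-Newton
  iteration can never break the symmetry, stalling on a saddle. Factor
  correlations start at 0.2, second-order loadings at 0.5, disturbances at
  0.3, uniquenesses at 0.5. All starts are overridable.
* **Bounds and Heywood cases.** All variance parameters (uniquenesses,
  disturbances) are bounded below by 0 by default. This global guard
  reproduces the published handling of the one disturbance that went
  negative — on surrogate batteries the fluid-factor disturbance of the
  five-factor hierarchical model routinely lands on this bound — and the
  active-bound set is always reported on the fit object.
* **Positive definiteness.** If a trial point leaves the
  positive-definite cone (indefinite $\Sigma$, or indefinite $\Phi$ in an
  oblique model), the objective returns a large penalty value and the line
  search backs off. Indefinite matrices in *data* are rejected outright at
  validation, never smoothed: silently repairing an input would change
  every downstream statistic.
* **Information matrix.** The observed information is the numerically
  differentiated (central differences of the analytic gradient) Hessian of
  $(N-1)/2 \cdot F$, symmetrized; if indefinite, its eigenvalues are
  floored at a small positive multiple of the largest with a warning.
* **Sign convention.** Factor columns are sign-indeterminate. Raw
  estimates are kept unflipped; at report time each column is flipped so
  its largest-magnitude loading is positive (with matching flips applied
  to $\Phi$ or $\Gamma$, leaving $\Sigma$ unchanged). Published loading
  tables deliberately contain mixed signs, so the flip must be — and is —
  exact and reversible.

## Fit indices

For a fitted model and the uniqueness-only null model (df
$= p(p+1)/2 - p = 105$ at $p = 15$) on the same sample:

* $\mathrm{GFI} = 1 - \mathrm{tr}[(\Sigma^{-1}S - I)^2] /
  \mathrm{tr}[(\Sigma^{-1}S)^2]$ (ML metric);
* $\mathrm{AGFI} = 1 - \frac{p(p+1)/2}{df}(1 - \mathrm{GFI})$;
* $\mathrm{CFI} = 1 - \max(\chi^2 - df,\,0) / \max(\chi^2_0 - df_0,\,
  \chi^2 - df,\,0)$;
* $\mathrm{RMSEA} = \sqrt{\max(\chi^2 - df,\,0) / (df\,(N-1))}$;
* the "Akaike" column of the comparison tables is the legacy CALIS form
  $\chi^2 - 2\,df$ — the table arithmetic identifies it unambiguously
  (e.g. the null row: $8697.69 - 210 = 8487.69$) — and is named
  `aic_calis` to avoid confusion with the $-2\ln L + 2k$ textbook AIC.

With df $= 0$, AGFI and RMSEA are undefined and reported `NA`; anomalies
(model better than its df, null worse than the model) are absorbed by the
`max` clamps. Indices print at 4 decimals in tables and carry full
precision in structured output.

## Stepwise modification

Candidates are fixed-zero loading cells only — no error covariances and no
factor-correlation candidates, matching the loading-only layout of the
published modified models. Each step changes a single weight:

1. compute score (LM) projections for all candidates — squared score over
   information, partialed for all currently free, non-active-bound
   parameters; if the largest is significant at $\alpha$ (default 0.05,
   per step, uncorrected), free that cell;
2. otherwise compute Wald projections $(\hat\lambda/\mathrm{se})^2$ for all
   free loadings; if the smallest is *not* significant, fix that cell to 0;
3. refit after every step; the *actual* $\Delta\chi^2$ must meet the same
   criterion (significant for an addition, non-significant for a drop) — a
   step that fails it is rolled back and the search stops, reading the
   source procedure's continuation clause as a global stopping rule.

Ties in either ranking break lexicographically by subtest then factor
order; determinism wins over any substantive tie-break argument. An
oscillation guard terminates the search if a cell is added and dropped
twice. Score and Wald projections are quadratic, *local* approximations:
on constructed fixtures they track the actual refit $\Delta\chi^2$ within
about 15% for planted loadings near 0.1, but can be off by a factor of
several for a planted 0.4, which is far outside the local regime. The
package's projection-accuracy tests therefore operate in the small-effect
regime; rank order and exact recovery of a planted modification hold well
beyond it.

## Fixed-loading cross-validation

A fitted structure is carried to a new population by freezing *all*
structural parameters ($\Lambda$, $\Phi$, $\Gamma$, $\Psi$) at their
estimates and re-estimating only the $p$ uniquenesses, so every
cross-validated model — including the null model, whose only parameters
already are uniquenesses — has df $= p(p+1)/2 - p$. With equal df and N,
every index is a monotone transform of $\chi^2$, so all indices produce
the same ranking within a generalization table. Internally the frozen part
is carried as the fully fixed matrix $\Lambda\,\mathrm{chol}(\Phi)^\top$
with orthonormal factors, which leaves the implied matrix identical and
makes the cross-validated $\chi^2$ invariant to sign flips of the source
fit. The new sample's N — never the estimation sample's — scales the
cross-validated $\chi^2$.

Correlation tables are pooled on the Fisher-$z$ scale (unweighted mean of
$\mathrm{atanh}\,r$, then $\tanh$), which presumes equal per-table N — the
situation of the per-age-band manual tables (200 each) — and the pooled N
(1000/400/400 in the study's frame) is an explicit caller input: how an
averaged table should scale the $\chi^2$ multiplier is not derivable from
the inputs, so the package never guesses it.

## The synthetic-data generator

`wais_like_battery()` emulates the study's sampling frame: an estimation
band "ages 20-54" (N = 1000) and generalization bands "ages 16-19" and
"ages 55-69" (N = 400 each) over the 15 subtests, generated from the
modified-CHC parameter set — the study's most completely published loading
matrix; the modified six-independent-factors set is available as an
alternative ground truth. Sampling draws N multivariate-normal vectors per
band and takes Pearson correlations. For the two outer bands each free
loading receives additive Gaussian noise (sd 0.03 by default) and the
uniquenesses are re-completed to unit diagonal; 0.03 produces
cross-validation degradation of the same order as the published
generalization tables relative to the estimation table — a qualitative
emulation, chosen once, not a calibration to any printed number.
Perturbation draws are rejection-sampled to the feasible region: around
the published values the highest-communality subtest (Vocabulary, 0.858)
occasionally exceeds unit structural variance at sd 0.03, so the
perturbation distribution is read as truncated to valid correlation
structures. Every sampling operation seeds a private RNG stream and
restores the caller's generator state.

What the surrogates do *not* emulate: the real standardization
correlations themselves (proprietary), non-normal score distributions,
item-level structure, or age trends beyond random loading drift. Passing
tests on surrogates therefore demonstrate correctness of the machinery and
the internal consistency of the published arithmetic, not any new claim
about WAIS-IV data.

`six_equal_factor_sim()` generates the exchangeable population with six
orthogonal factors loading equally ($\lambda$) on all tests: all
off-diagonals equal $6\lambda^2$. One identifiability caveat discovered
while testing it is worth recording: that population equals
$6\lambda^2 J + (1 - 6\lambda^2) I$, and any $\Lambda\Lambda^\top =
6\lambda^2 J + \Delta$ with small diagonal $\Delta$ (rank at most 6) fits
*exactly*, with the uniquenesses absorbing $-\Delta$ — so per-test
communality in the full free model is identified only up to that diagonal
slack, and recovery checks on this fixture use a correspondingly realistic
tolerance.

## Catalog assumptions and df bookkeeping

The model catalog encodes the published comparison models. Where the
sources underdetermine a pattern, the choice is recorded on the object:

* the single Benson/Ward cross-loading is placed on Arithmetic (fluid
  reasoning and short-term memory), overridable via
  `build_catalog(cross_subtest = )` or a serialized config;
* the four-group-factor manual model carries two cross-loadings
  (Arithmetic on verbal comprehension, Figure Weights on working memory),
  which reconciles its published df of 80;
* the published df of the five-factor hierarchical (80), five-factor
  oblique (78) and modified six-independent (47) models cannot be
  reconciled with any structure derivable from the published patterns
  alone — this package counts 79, 79 and 49 — and those catalog entries
  carry a `df_unverified` attribute rather than a guessed hidden
  parameter. For the modified six-independent model the published loading
  table's 56 nonblank cells plus 15 uniquenesses fix the count at 49.
* where the running text and a loading table disagree about which cells
  are nonblank, the table is authoritative.

## Problem sizes used by the test suite

The packaged checks run at sizes chosen to make the statistical properties
sharp yet quick on a single CPU: $\chi^2$ calibration uses 200 replicates
at N = 500 (mean $\chi^2$ within 10% of df); the generalization sweep fits
the full 12-model catalog on 50 surrogate batteries and requires the
generating model to win the summed cross-validated $\chi^2$ in at least
45; Monte-Carlo convergence of the sampler is checked at N = $10^6$. The
end-to-end worked example in the README completes in seconds.

## Known limitations

* GLS/ULS discrepancies, mean structures, multi-group simultaneous
  estimation, measurement-invariance hierarchies, SRMR/TLI/BIC and RMSEA
  confidence intervals are out of scope.
* Standard errors inherit the correlation-as-covariance caveat above.
* Full-loading orthonormal models are rotationally indeterminate; df
  bookkeeping follows the conventional count and does not subtract
  rotational freedom, matching the published tables.
* The stepwise search is greedy with single-parameter steps and a global
  stop; it is a faithful implementation of the published procedure, not a
  model-search recommendation.
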