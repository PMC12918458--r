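---
title: "Measurement equivalence of short Likert inventories: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement equivalence of short Likert inventories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nomoscan)
```

# The problem

Two self-report inventories that both claim to measure Machiavellianism,
narcissism and psychopathy need not measure the same constructs — the
jingle-jangle problem. `nomoscan` quantifies equivalence on two fronts:
*structurally*, with a multitrait–multimethod (MTMM) confirmatory factor
analysis of the ordinal items, and *nomologically*, by comparing how the
two inventories' trait scores relate to an external criterion battery.
This vignette records the models, every tunable parameter that matters,
what the synthetic-data generator does and does not emulate, the numerical
choices, and the places where the design was genuinely open.

# The measurement model

Each item loads on exactly one trait × method factor (simple structure, no
cross-loadings); with three traits and two methods this gives the
six-factor model. Factor variances are fixed at 1, all loadings and factor
correlations are free. For standardized loadings $\lambda$ and factor
correlation matrix $\Phi$, the implied item correlation is
$\rho_{ij} = \lambda_i \Phi_{f(i)f(j)} \lambda_j$ for $i \ne j$.

Because the items are ordered categories, Pearson correlations of the raw
responses would be attenuated and category-dependent. The analysis instead
assumes a standard-normal latent response behind each item, cut at
thresholds $\tau$, and estimates **polychoric correlations** pairwise in
two steps: thresholds from the inverse-normal cumulative marginals, then a
one-dimensional likelihood maximisation over $\rho \in (-0.999, 0.999)$
using bivariate-normal cell probabilities. The estimate is clipped at
$\pm 0.999$; a degenerate all-on-the-diagonal table therefore returns the
clip value rather than diverging. Pairwise estimates need not be jointly
positive semidefinite, so the assembled matrix is smoothed by eigenvalue
clipping (floor at $10^{-8}$) and rescaled to unit diagonal.

**Estimation.** The model is fitted by diagonally weighted least squares,
$$F(\theta) = \sum_{i<j} w_{ij}^{-1}\,(s_{ij} - \sigma_{ij}(\theta))^2,$$
where $w_{ij}$ is the estimated asymptotic variance of
$\sqrt{n}(s_{ij}-\sigma_{ij})$, obtained from the observed information of
the pairwise profile likelihood (numerical second derivative at the
estimate) times $n$. A unit-weight (ULS) fallback is available.
Optimisation is quasi-Newton (L-BFGS-B) with the analytic gradient, box
constraints at $\pm 0.999$, a deterministic start (all loadings 0.5, all
correlations 0.3) and up to three seeded jittered restarts on failure.
Fitting the model-implied matrix of any valid parameter set returns those
parameters with discrepancy below $10^{-8}$ — the key self-consistency
property the test suite enforces on the full 39-item design.

**Test statistic and fit indices.** The package reports the naive statistic
$T = (N-1)F_{\min}$ with $df = p(p-1)/2 - (\text{free parameters})$, and
CFI, TLI, RMSEA and SRMR computed from $T$ against the independence
baseline (closed form: all correlations zero). Published applications of
DWLS usually report mean- or mean-and-variance-adjusted ("scaled") test
statistics; those corrections are deliberately not reproduced, so $T$ and
RMSEA here will differ from scaled values computed by full SEM software on
the same data. The df arithmetic, the nested $\Delta\chi^2$ mechanics and
the descriptive indices are unaffected by this choice.

**Constrained comparisons.** Convergence of identically-labelled factors is
tested by fixing the cross-method correlation at 1.00 (parameter
substitution of that single $\Phi$ entry, so $\Delta df = 1$) and comparing
$\Delta\chi^2 = T_c - T_f$ against $\chi^2_{\Delta df}$. A constrained fit
with a *smaller* statistic than the free fit is flagged as an estimation
anomaly rather than given a p-value.

**Validity statistics.** AVE is the mean squared standardized loading of a
factor's items; the Fornell–Larcker criterion passes a factor only when
$\sqrt{AVE}$ *strictly* exceeds its absolute correlation with every other
factor (ties fail — a deliberate, documented tie-break). HTMT is computed
on the polychoric item matrix (Pearson optional): the mean between-set
correlation divided by either the arithmetic mean of the two within-set
mean correlations (default) or their geometric mean (the common
formalisation in the partial-least-squares literature). The verbal
definitions circulating in applied work are ambiguous between the two, so
both are exposed and the rule used is recorded in the output; when all
correlations are equal both give the limiting value 1.

# The consistency framework

Profiles of trait–criterion correlations for the two methods are compared
per criterion set:

* $\Delta\bar r$ — mean absolute difference of the profiles. The default
  averages $|z_A - z_B|$ on the Fisher-z scale and back-transforms with
  $\tanh$; a raw-correlation rule is available. The conventional cutoff
  (.10) lives on the correlation metric, which is why the z-scale mean is
  transformed back. Since reference values for full correlation matrices
  are not available in print, neither rule can be validated against a
  published number; both are first-class options and the rule is recorded.
* $\Delta\bar R^2$ — the absolute difference of the two *mean* regression
  $R^2$ values (difference of means, not mean of differences). This
  convention exactly reproduces all four reference-table values bundled
  with the package, which is what fixed the ambiguity.
* $r_{ICC}$ — profile similarity per trait. Default: Pearson correlation of
  the double-entered pair vectors $[(a,b);(b,a)]$ on Fisher-z values, which
  penalises both shape and level differences; a two-way absolute-agreement
  single-measure ICC and a raw-r option are available. Published per-trait
  values could not adjudicate between variants (the underlying matrices are
  unpublished), so these are options rather than competing claims.
* Pairwise Fisher z tests,
  $z = (\mathrm{atanh}\,r_A - \mathrm{atanh}\,r_B)\big/\sqrt{1/(n_A-3) + 1/(n_B-3)}$.
  Both profiles come from one sample, so the independent-samples test is
  conservative (the estimates are positively correlated); it is used anyway
  because it replicates the published procedure. No multiplicity correction
  is applied, also by replication.
* JZS Bayes factors. $BF_{10}$ of a $p$-predictor regression against the
  intercept-only model is the one-dimensional integral over the
  Zellner–Siow mixing parameter $g$ of
  $(1+g)^{(n-p-1)/2}\,(1+g(1-R^2))^{-(n-1)/2}$ against an
  inverse-gamma$(1/2,\, n r^2/2)$ density. The omitted-predictor
  $BF_{01}$ is reduced-over-full: $BF_{10}(R^2_{reduced}, p-1) /
  BF_{10}(R^2_{full}, p)$, so low values mark the omitted trait as
  important. Prior scale $r$ defaults to $\sqrt{2}/4$ ("medium" for
  regression) and is configurable because the published analyses do not
  state theirs — for the same reason the bundled $BF_{01}$ table is treated
  as a classification input, not as a reproduction target for the BF
  engine. Evidence categories use closed boundaries: $\ge 3$ favors
  omission, $\le 1/3$ favors inclusion, strictly between is inconclusive.

The five cutoffs ($\Delta\bar r \le .10$, $\Delta\bar R^2 \le .05$,
$r_{ICC} \ge .80$, all $p \ge .05$, agreement $\ge 80\%$) are applied with
closed inequalities exactly as stated; boundary values pass. A missing
component makes its flag not-evaluable and the set verdict NA — never a
silent pass.

# Numerical choices

* **Bivariate-normal cell probabilities**: fixed 64-node Gauss–Legendre
  quadrature of $\int \phi(x)[\Phi(\cdot)-\Phi(\cdot)]\,dx$ per cell,
  infinite tails truncated at $\pm 8.5$ SD; verified against adaptive
  quadrature to $10^{-7}$ including $|\rho| = 0.99$.
* **JZS integral**: log-scale integrand, mode located on the $\log g$ axis,
  change of variables $t = g/(1+g)$, adaptive quadrature at relative
  tolerance $10^{-10}$; verified against a $10^6$-point trapezoid oracle to
  $10^{-6}$ relative, and during development against an independent
  reference implementation to $\sim 10^{-10}$. $BF_{01}$ values that
  underflow `exp()` at very large $n$ are floored at the smallest positive
  double for classification (log values are retained).
* **Constant input** to descriptives yields sd 0 with shape statistics
  flagged undefined, not an exception; skewness/kurtosis use the
  sample-adjusted $G_1$/$G_2$ formulas (the published screen states only
  the $\pm 2$ band, not the estimator, so the choice is fixed here and
  documented).
* **Profile ICC** accepts two-point profiles: the reversed two-point
  profile is the canonical check that double entry yields $-1$ (an
  operation-level precondition of three criteria was relaxed to two for
  this reason).

# The synthetic-data generator

The generator states a world and sticks to it: multivariate-normal factor
scores with correlation $\Phi$, single-factor items
$x_i = \lambda_i F_{f(i)} + \sqrt{1-\lambda_i^2}\,\varepsilon_i$
discretised at fixed thresholds, criteria $y = F w + e$. Sub-seeds are
derived deterministically per operation from one master seed, so adding a
stage never changes another stage's draws.

The `"sd3dd"` preset mirrors the published design: 27 five-point items
(9 per trait) and 12 seven-point items (4 per trait); cross-method
same-trait correlations .927, .718, .876 as published. Full heterotrait
correlations are not published; they are fixed once at .65 within the
27-item method (its weak discriminant validity is the published finding),
.45 within the 12-item method, and .50 across (positive-definiteness
verified at construction). Loadings are spread evenly over the published
per-subscale ranges. Thresholds are equiprobable normal cuts shifted by
+0.3, giving the mild right skew typical of dark-trait items in community
samples while staying far inside the ±2 screen. Criterion weights are the
reference table's standardized betas placed on the first method's factors
("the chosen reference scale"), plus a social-desirability criterion with
modest negative weights — desirability is modelled as an ordinary
correlated criterion, not as a response-distortion process. Response
styles, acquiescence and differential item functioning are likewise *not*
modelled, and criteria derive from factor scores, not item scores.

Two engineered worlds exercise the verdict logic: `"equivalent"` (both
methods' items load on the same trait factors with identical loadings,
counts and formats, so every consistency metric has its ideal population
value) and `"sd3dd_divergent"` (each criterion mixes the two methods'
published beta sets half-and-half on the two methods' factors, so profiles
diverge exactly where the published betas diverge). A green equivalence
test therefore establishes that the metrics converge to ideal values in a
world built to be equivalent — not that any real pair of inventories is
equivalent; conversely the divergent world shows the report flags
inconsistency when it is truly present.

# What the worked examples do and do not establish

The raw participant data behind the reference tables were never deposited,
so the exactly reproducible quantities are those computable from printed
summaries: the four $\Delta\bar R^2$ values, the four agreement
percentages, and the design's degrees of freedom (687 = 741 − 54). The
printed fit indices, latent correlations, HTMT values, $\Delta\bar r$ and
$r_{ICC}$ values depend on the raw data and are covered instead by
property-based checks (exact fixed points, parameter recovery at n = 5000
within ±.05, polychoric bias < .02 at n = 50000, oracle agreement for the
Bayes-factor quadrature, ideal-world convergence). Where a published value
was near but not exactly recoverable under the naive statistic (RMSEA from
an apparently scaled $T$), the divergence is documented above rather than
patched.

# Known limitations

* Naive DWLS $T$ only; no robust/scaled corrections, no modification
  indices, no method-factor (CT-CM) or bifactor models, no multi-group CFA.
* Polychoric correlations only; criteria are treated as continuous once
  aggregated (no polyserial).
* The independent-samples z test is conservative for within-sample profile
  comparisons; a dependent-correlations test is provided as an option but
  is not used for replication output.
* Listwise deletion is the default missing-data policy (pairwise optional);
  the replicated analyses' policy is unstated.
* Scale scores are item means (not sums) of reverse-coded responses; range
  invariance motivated the choice, also unstated in the replicated work.
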