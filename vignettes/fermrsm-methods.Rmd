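---
title: "Methods: response-surface optimization and unstructured batch kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: response-surface optimization and unstructured batch kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermrsm)
```

`fermrsm` covers the two statistical workhorses of small-scale fermentation
development: locating the culture conditions that maximize a measured
response over several interacting factors, and describing the time evolution
of a batch culture with a small unstructured kinetic model. This vignette
records the models, the estimation choices, and the places where a design
decision was genuinely open.

## Face-centered composite designs and coded factors

A full central composite design on $n$ factors contains $2^n$ factorial
points, $2n$ axial points and $n_c$ replicated center points, $N = 2^n + 2n
+ n_c$ runs in all; with five factors and eight center replicates this is
the familiar 50-run plan. The face-centered variant places the axial points
at the faces of the factor cube (axial distance 1), so every factor is
exercised at exactly three levels — the natural choice when a rotatable
design would push settings (say, pH or temperature) outside the
instrumentally sensible range. Rotatable and inscribed variants, fractional
cores and blocking are deliberately out of scope.

All modelling happens on *coded* factors: the linear map that sends the
low/center/high settings to $-1/0/+1$,
$x = (u - u_{\mathrm{center}})/\tfrac{1}{2}(u_{\mathrm{high}} -
u_{\mathrm{low}})$. Coding makes coefficients comparable across factors with
wildly different units and keeps the design matrix well conditioned. The
center is normally the midpoint of the range; `factor_spec()` tolerates an
off-center value (the map stays linear in the half-range) but warns, since
three *equispaced* levels are what make the coded design orthogonal in its
factorial block.

```{r}
sp <- design_spec(list(
  factor_spec("time_d", 10, 12), factor_spec("pH", 7, 9),
  factor_spec("temp_C", 25, 35), factor_spec("sucrose_pct", 1, 3),
  factor_spec("soya_pct", 0.5, 1.5)), n_center = 8)
nrow(generate_ccfd(sp))
```

Canonical run order is factorial, axial, then center block; randomization is
opt-in with a mandatory seed, because a reproducible canonical order is what
downstream tests and file diffs need, while physical experiments should
randomize.

## The second-order response surface

The response is modelled as the full quadratic polynomial on coded factors

$$Y = \beta_0 + \sum_i \beta_i x_i + \sum_{i<j} \beta_{ij} x_i x_j +
\sum_i \beta_{ii} x_i^2,$$

$1 + n + \binom{n}{2} + n$ terms (21 for $n = 5$). Fitting is ordinary least
squares via `lm` on the expanded model matrix; term order (intercept,
linear, lexicographic pairs, squares) is fixed in one place and shared by
fitting and prediction. At the all-zero coded point the prediction is the
intercept exactly — a property the test-suite asserts for random models, and
the basis of the worked examples below.

Reported alongside the coefficients:

* **ANOVA** with per-term *partial* (type III) sums of squares,
  $SS_j = t_j^2 \, MS_{\mathrm{res}}$ for 1-df terms — the layout
  commercial DoE software prints. On the orthogonal blocks of a CCFD the
  linear and interaction rows coincide with sequential sums of squares.
* **Lack of fit**: the residual is split into pure error (within-replicate
  variation at identically coded runs — the center replicates in a standard
  CCD) and lack of fit, with $F = (SS_{\mathrm{lof}}/df_{\mathrm{lof}}) /
  (SS_{\mathrm{pe}}/df_{\mathrm{pe}})$. With no replicates the test is
  reported as not computable rather than silently skipped; identical
  replicate responses (pure error exactly zero) flag the F as undefined.
* **Fit summary**: $R^2$, adjusted $R^2$, predicted $R^2$ from PRESS using
  the hat-matrix identity $\mathrm{PRESS} = \sum_i (e_i/(1-h_i))^2$ (a
  brute-force leave-one-out loop serves as the test oracle, never the
  implementation), $\mathrm{CV}\% = 100\sqrt{MS_{\mathrm{res}}}/\bar y$,
  $\mathrm{RMSE} = \sqrt{SS_{\mathrm{res}}/n}$, and
  $\mathrm{AAD}\% = (100/n)\sum_i |y_i - \hat y_i| / y_i$. AAD is undefined
  when any observation is zero and is then reported missing with a warning.
* **Sequential model comparison** across the nested tiers mean, linear,
  2FI, quadratic, cubic, each tier's incremental SS tested against the
  larger model's residual mean square. On a three-level design the pure
  cubics $x_i^3$ are exactly aliased with $x_i$ (all coded values are in
  $\{-1,0,1\}$); the cubic tier therefore keeps only the estimable mixed
  terms $x_i x_j^2$, and dropped columns are reported rather than erroring.
  Rank is decided by QR pivoting.

No multiple-testing adjustment is applied to the per-term p-values; each row
is the usual marginal F test.

### Optima and surface views

`optimum_on_cube()` solves $\nabla Y = 0$; when the Hessian is negative
definite and the stationary point lies inside $[-1,1]^n$ that point is the
optimum. Otherwise the surface is maximized over the cube by multi-start
L-BFGS-B (center, cube corners, the projected stationary point, and 20
seeded random starts), labelled `boundary max` or `saddle-adjusted`. Among
numerically tied maximizers the lexicographically smallest coded point is
returned, so results are deterministic. A two-stage grid search (step 0.1
over the cube, then 0.01 around the incumbent) is used as an independent
oracle in the tests. `surface_grid()` evaluates the fitted polynomial over a
coded $[-1,1]^2$ grid for any factor pair with the others held fixed — the
numerical content of the usual 3-D surface plots; rendering is left to the
caller.

```{r}
fx <- reference_fixtures()
predict(fx$models$saureus, rep(0, 5))       # center-point prediction
optimum_on_cube(fx$models$saureus)$value
```

## Unstructured batch kinetics

Biomass $X$ (g/L) follows the logistic law
$\mathrm{d}X/\mathrm{d}t = \mu_{\max} X (1 - X/X_m)$ with closed form

$$X(t) = \frac{X_0 e^{\mu_{\max} t}}
{1 - (X_0/X_m)\left(1 - e^{\mu_{\max} t}\right)},$$

product (here an agar-diffusion inhibition zone in mm, the bioactivity
proxy) follows the Luedeking–Piret partition into growth-associated and
non-growth-associated formation,
$\mathrm{d}P/\mathrm{d}t = \alpha\,\mathrm{d}X/\mathrm{d}t + \beta X$, and
substrate consumption its modified form
$-\mathrm{d}S/\mathrm{d}t = \gamma\,\mathrm{d}X/\mathrm{d}t + \eta X$.
Substituting the logistic solution and integrating gives closed forms built
from one logarithmic kernel, $\ln L(t)$ with
$L(t) = 1 + (X_0/X_m)(e^{\mu_{\max} t} - 1) \ge 1$:

$$P(t) = P_0 + \alpha\,(X(t) - X_0) +
\frac{\beta X_m}{\mu_{\max}} \ln L(t), \qquad
S(t) = S_0 - \gamma\,(X(t) - X_0) -
\frac{\eta X_m}{\mu_{\max}} \ln L(t),$$

since $(X_m/\mu_{\max})\ln L(t) = \int_0^t X\,\mathrm{d}u$. Note both
substrate terms carry a minus sign: the kernel is non-negative, so both the
growth-associated and the non-growth-associated contributions *consume*
substrate — writing the logarithmic term with a plus sign would make the
medium spontaneously gain sugar. The test suite pins all three closed forms
against adaptive ODE integration (`deSolve`, tolerances $10^{-10}/10^{-12}$)
over 200 random valid parameter sets on $t \in [0, 15]$ d to $10^{-6}$
relative.

Numerical care: both $X(t)$ and $\ln L(t)$ are evaluated in overflow-safe
forms ($X = X_m/(1 + \frac{X_m - X_0}{X_0} e^{-\mu t})$ and
$\ln L = \mu t + \ln(X_0/X_m) + \mathrm{log1p}(\frac{X_m - X_0}{X_0}
e^{-\mu t})$), so `lilp_P(1e4, p)` is as safe as `lilp_P(1, p)`. For large
$\mu_{\max} t$ the product curve grows linearly with slope $\beta X_m$ — the
stationary-phase culture producing at its non-growth-associated rate — which
is also where the one-line identities
$\eta = -(\mathrm{d}S/\mathrm{d}t)_{\mathrm{stat}}/X_{\max}$ and
$\beta = (\mathrm{d}P/\mathrm{d}t)_{\mathrm{stat}}/X_{\max}$ come from
(`eta_from_stationary()`, `beta_from_stationary()`, with
`stationary_slope()` supplying the windowed OLS slope; the default window of
days 5–11 covers the reference strain's stationary phase and is
user-overridable).

Time is in days throughout ($\mu_{\max}$ in day$^{-1}$; the reference
fermentations run 11 days, and day 11 is the canonical evaluation time for
maximum-zone predictions). Defaults when unstated: $P_0 = 0$ mm (no
inhibition zone exists at inoculation) and $S_0 = 20$ g/L (a 2 % w/v sucrose
medium).

```{r}
p <- fx$kinetics$xcampestris
lilp_P(11, p)   # model-fitted maximum zone, day 11
```

### Parameter estimation

Estimation is sequential, mirroring the model structure. The logistic
parameters $(\mu_{\max}, X_0, X_m)$ are fitted to the biomass series by
bounded nonlinear least squares (`minpack.lm::nlsLM`, tolerances
$10^{-15}$), with data-driven starts ($X_0$ from the first observation,
$X_m$ from the series maximum, $\mu_{\max}$ from the log-linear slope of the
first half of the series) perturbed over a five-point deterministic
multi-start grid; the best converged fit wins, and total failure raises an
error carrying the optimizer diagnostics. A constant biomass series is
rejected up front as unidentifiable.

Conditional on the growth fit, the product and substrate closed forms are
*linear* in $(\alpha, \beta)$ and $(\gamma, \eta)$ — both are combinations
of the same two regressors $f_1 = X(t) - X_0$ and
$f_2 = (X_m/\mu_{\max})\ln L(t)$ — so those steps are solved exactly by
non-negative linear least squares (`pracma::lsqnonneg`); no iteration, no
starting values, and the non-negativity constraints of the rate law are
honoured at the boundary rather than by post-hoc clipping. A joint refit of
all seven parameters would add nothing here: the conditional problems are
already solved to machine precision, and the growth parameters are informed
only by the biomass series.

The anchor values $P_0$ and $S_0$ default to the first observations of
their series, but `fit_lilp()`, `fit_limlp()` and `fit_kinetics()` accept
explicit values. Supplying the known initial conditions is the right call
whenever the protocol sets them (a formulated medium's sugar load; the zero
zone at inoculation): anchoring on a single noisy $t = 0$ assay injects that
one measurement's error into both coefficients, and for the weakly
identified $\gamma$ this is the dominant error source at realistic noise
(see the simulation design below).

## The synthetic-data generator

The generator exists so that every stage is testable without external data,
and it generates exactly the structure the estimators assume:

* `gen_ccd_responses()`: the quadratic surface evaluated at the design
  points plus i.i.d. homoscedastic Gaussian noise — the OLS error model.
* `gen_timecourse()`: the three closed-form curves plus additive Gaussian
  noise per series (biomass clipped at zero). With `relative = TRUE` the
  noise is multiplicative ($\sigma$ proportional to the local signal), the
  error model of many plate/HPLC assays.

Everything is seeded and reproducible; the same seed yields byte-identical
tables. `reference_fixtures()` packages the worked-example inputs — the
five-factor spec (with both reported temperature-range variants, 25/30/35
and 20/25/30 °C; the package takes whichever the user supplies and does not
arbitrate), five fitted coefficient sets for the indicator organisms
(*S. aureus*, *B. subtilis*, *X. campestris*, *P. aeruginosa*,
*C. albicans*), and the fitted kinetic parameter sets (one shared growth and
substrate set; organism-specific $\alpha, \beta$).

**Recovery-study design.** The packaged simulation studies use 13 daily
samples over a 12-day batch. Noise for the headline recovery study is
additive at 2 % of each series' *amplitude* — the informative span of the
trajectory: growth range $X_m - X_0$, substrate consumed $S_0 - S(12)$,
final zone $P(12) - P_0$. The amplitude convention matters and is worth
stating: scaling substrate noise to the 20 g/L *baseline* instead gives
$\sigma_S \approx 0.4$ g/L against a $\gamma$-signal of barely 1 g/L, and
$\gamma$ then cannot be recovered to useful precision at $n = 13$ by any
estimator — an identifiability fact about the data, not a solver failure.
Under the amplitude convention, with known initials, all seven parameters
are recovered with median relative error under 15 % across 50 seeded
replicates, and noise-free data are recovered to $10^{-6}$. A separate
study checks near-unbiasedness under 5 % multiplicative noise. Study sizes
(50 seeds for recovery, 200 parameter sets for the ODE equivalence, 100
fixtures for the ANOVA identities, 500 null simulations for the F-test
calibration) were chosen once as comfortable for the properties being
demonstrated.

What passing these tests does *not* show about real fermentations: real
biomass error is rarely homoscedastic Gaussian, inhibition-zone diameters
respond nonlinearly to metabolite concentration, substrate and product
inhibition are assumed absent, and the generator draws every series from
the very model family being fitted — so the studies demonstrate estimator
correctness and identifiability, not model adequacy for any particular
organism.

## Degenerate inputs and edge policies

* Constant response → intercept-only surface, $R^2$ reported as 0, with a
  warning; fewer runs than terms, missing responses, dimension mismatches →
  errors.
* Rank-deficient model matrices name the dependent columns.
* Predicted substrate below zero is returned as computed but flagged with a
  substrate-exhaustion warning (the unstructured model has no substrate
  limitation term).
* Ties in the cube optimum break lexicographically; aliased cubic columns
  are dropped and reported.

## Command-line layer

`exec/fermrsm` exposes `design`, `simulate`, `fit-rsm`, `fit-kinetics` and
`report` as thin wrappers over the same functions documented here, driven by
one YAML config; numeric reports are fixed at four decimals while the CSV
exports keep full precision, and every report header records the package
version, a config hash and the seed. Exit codes: 0 success, 2 validation
error, 3 convergence failure.
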