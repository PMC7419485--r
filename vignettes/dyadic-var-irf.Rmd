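---
title: "Modeling bidirectional mother–infant influence with pooled VAR and orthogonalized impulse responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling bidirectional mother-infant influence with pooled VAR and orthogonalized impulse responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadVAR)
```

## The scientific problem

Developmental interaction is bidirectional: an infant's emerging motor
repertoire changes what the mother does, and maternal behavior feeds back
into what the infant does next. Classical tools (ANOVA, ordinary
regression) force one side into the role of predictor. Vector
autoregression (VAR) instead treats every behavior as endogenous: with
$m$ behavior codes observed monthly, the lag-$p$ model is

$$x(t) = c + B_1\,x(t-1) + \dots + B_p\,x(t-p) + \varepsilon(t),$$

where $x(t)$ is the $m$-vector of monthly behavior totals, the $B_k$ are
$m \times m$ coefficient matrices (so a 26-code lag-1 system carries
$26^2 = 676$ lagged coefficients), and $\varepsilon(t)$ is an i.i.d.
innovation with covariance $\Sigma$. Prior changes in one code improving
the prediction of another code's later values — beyond that code's own
history — is the Granger-style notion of influence this package
quantifies.

Rather than reading 676 coefficients, influence is summarized by
orthogonalized impulse-response functions (IRFs): the projected
trajectory of every code after a one-time, one-standard-error shock to a
single code's innovation, followed over a 10-month horizon and collapsed
into sign tables of significant early responses.

## From event logs to monthly panels

The input is a session-level behavioral coding log: one row per (dyad,
month-of-age, session, code) with a duration in seconds and an
occurrence count. Codes come from a fixed 26-name vocabulary (15 infant,
11 maternal; `behavior_codes()`). Each behavior is analyzed under two
encodings — total seconds and number of events — because the two can
dissociate (many brief events vs. one long one).

`aggregate_monthly()` pools a month's sessions into one cell per (dyad,
month, code). Pooling is a **sum** by default: sessions are fixed
5-minute windows, so with a fixed number of sessions per month sums and
means differ only by a constant factor that the linear model absorbs;
`stat = "mean"` is available. Months with no event for a code are
explicit zeros. A dyad missing an *entire* month is a hard error, not an
imputation target: VAR validity rests on equally spaced, cotemporaneous
series, so a gap invalidates the lag structure rather than one cell.

## Pooled estimation across dyads

The study design has many short series (one 10-month series per dyad)
rather than one long one. The package pools them the minimal way:
lagged predictor rows are constructed **within** each dyad — no
(x(t), x(t-1)) pair ever spans two dyads — and the per-dyad rows are
stacked into one least-squares design with a single common intercept per
equation. Per-equation ordinary least squares on this stacked design is
equivalent to multivariate least squares for an unrestricted VAR. Two
consequences worth knowing:

* a one-dyad panel reduces exactly to textbook single-series VAR;
* all dyads in a group share one coefficient set — there is no
  hierarchical/per-dyad layer, matching a pooled "across all infants"
  analysis. (Per-dyad or multilevel VAR is a deliberate non-goal; the
  pooling layer isolates where it would plug in.)

The residual covariance uses the degrees-of-freedom-adjusted denominator
$n - mp - 1$. Series are not centered or rescaled by default (raw
monthly values; `center = TRUE` exists). A constant column is an error
naming the offending code, with `drop_degenerate = TRUE` as an explicit
escape hatch, because silently dropping a behavior would change the
system being modeled.

## Residual requirements and lag selection

A VAR is only a judicious model when its residuals are (i) serially
uncorrelated, (ii) homoscedastic, and (iii) the companion matrix of the
$B_k$ has all eigenvalues strictly inside the unit circle. The package
operationalizes the first two with standard multivariate tests, both
built on within-dyad lagged products only:

* **Portmanteau** (`portmanteau_test()`): small-sample-weighted
  multivariate Ljung–Box $Q$ over residual autocovariances up to lag
  $h$ (default $\min(8, n/2)$), $\chi^2$ with $m^2(h-p)$ df. The
  $\chi^2$ approximation degrades badly once those degrees of freedom
  approach the number of residual rows (at $m = 26$ with 135 rows, even
  one lag costs 676 df, and the naive test falsely rejects on truly
  lag-1 data more than 80% of the time). `var_diagnostics()` therefore
  caps $h$ so that $m^2(h-p) \le n/2$ and, when no lag fits, falls back
  to per-equation Ljung–Box tests combined by Bonferroni across the
  $m$ equations — conservative but valid at any dimension. The form
  used is recorded in the report.
* **ARCH-LM** (`arch_lm_test()`): regression of
  $\mathrm{vech}(u_t u_t')$ on $q = 4$ of its own lags,
  $\chi^2$ with $q\,m^2(m+1)^2/4$ df. When the vech regression is not
  identified — its regressand has $m(m+1)/2$ dimensions, which exceeds
  the usable rows for a 26-variable model on a 10-month cohort — the
  diagnostics fall back to an **aggregate** form on the scalar squared
  Mahalanobis norm $u_t' C_0^{-1} u_t$ ($\chi^2$, $q$ df), and record
  which form was used.

Monte-Carlo calibration on null VAR(1) data (length 500, $m = 2$, 1000
replicates) puts both tests' type-I error at 0.04–0.06 at
$\alpha = 0.05$; the test suite and acceptance script recompute this.

`select_lag()` implements the prescribed loop: start at $p = 1$ and
increase until the fitted model passes both residual tests and the
stability check, returning the full per-$p$ audit trail. On cohorts that
are truly lag-1 the selection lands on $p = 1$; planted second-lag
coupling drives it to $p = 2$.

## Orthogonalized impulse responses

Innovations of behaviorally coupled codes are correlated, so a raw
one-variable shock is not attributable to that variable. The package
uses the Cholesky factorization $\Sigma = P P'$ ($P$ lower triangular,
positive diagonal) under a chosen variable entry order: $P$'s first
column carries the first-entered variable's residual SD and its
covariances scaled by it, and each later column is tempered by all
previously entered variables. The IRF is

$$\Theta_0 = P, \qquad \Theta_h = \sum_{k=1}^{\min(h,p)} B_k\,\Theta_{h-k},$$

so for a VAR(1), $\Theta_h = B_1^h P$. Column $j$ of $\Theta_h$ is the
$h$-months-later response of every code to a one-SD orthogonalized shock
of code $j$. Two independent oracles verify the implementation in the
test suite: the closed form $B_1^h P$, and a shocked-minus-baseline
pair of noise-free forward simulations through `simulate_var()`; both
agree with `compute_irf()` to $10^{-10}$ or better. Stable models are
required (IRFs of an unstable VAR diverge), and responses decay to zero
geometrically.

### The conservative entered-last sweep

VAR coefficients are exactly invariant to variable entry order; the
Cholesky attribution is not. The most conservative estimate of a
variable's *impulse* effects puts that variable last, so its shocks are
credited only with variance unexplained by all other codes.
`conservative_irf_sweep()` re-runs the orthogonalization once per
variable ($m$ orderings for an $m$-variable model; 26 for the full
vocabulary) and reports each variable's impulse column exclusively from
its own entered-last run. The sweep also *verifies* coefficient
order-invariance by refitting under every ordering (agreement to
$10^{-8}$ demanded; $10^{-15}$ typical).

Because replicate re-estimation is itself order-invariant, the sweep
shares one set of bootstrap replicates across all orderings and repeats
only the factorization per ordering. This is statistically identical to
running the bootstrap per ordering with common draws, and about $m$
times faster.

### Bootstrap bands and significance

Confidence bands come from a residual bootstrap
(`bootstrap_irf_ci()`; defaults 100 replicates, 95% level, horizon 10):
residual rows are resampled with replacement from the pooled residual
pool (rows are exchangeable under the pooled model; per-dyad pools of 9
rows would be too coarse), pseudo-series are rebuilt per dyad from each
dyad's observed initial values through the fitted coefficients, the VAR
is re-estimated, and IRFs are recomputed. Bands are pointwise Efron
percentile intervals — simple, not bias-corrected — and a horizon is
flagged significant when its band excludes zero. Replicates that fail
re-estimation are dropped with a warning; more than 20% dropped aborts.
Coverage for a true-zero response entry measures 92–95% over 200
seeded experiments, within the expected neighborhood of the nominal
95%.

## Sign tables

`build_sign_table()` collapses the banded curves into the compact
reporting matrix: a cell (response code × impulse code) is blank unless
some horizon in the significance window — default months 1–3 after the
shock, the "1 to 3 months beforehand" convention read from the
reporting side — has a band excluding zero; otherwise it shows the sign
of the point curve at the *first* significant horizon. A curve
significant with both signs inside the window keeps the first sign and
logs a mixed-sign warning, since the binary rendering has no richer
cell to offer. No multiple-testing correction is applied across cells
(per-cell 5% tests); this is deliberate and documented rather than
hidden, and p-adjustment belongs upstream of tabulation if wanted.
`render_sign_matrix()` combines groups and encodings into the bracket
dialect (`+B[-G]`: durations outside brackets, occurrences inside,
letters naming groups).

`run_study()` wires the whole design together: split dyads by group,
run each encoding, fix or select the lag, fit, diagnose, sweep,
tabulate — with two groups and two encodings, four independent models.
Groups are modeled separately by design: no gender/sex dummy inside a
single model, so group differences surface as differences between
tables rather than as one coefficient. `write_report()` writes models
(JSON), IRF curves (CSV), sign tables (CSV) and an MD5 manifest, and
refuses to overwrite a non-empty directory without `force = TRUE`.

## The synthetic cohort generator

Real dyadic coding data are rarely shareable, so validation rests on
`generator_config()` / `generate_cohort()`: each dyad's latent monthly
vector follows its group's stationary VAR(1)
$x(t) = c + A x(t-1) + \eta$, $\eta \sim N(0, \Sigma)$, after a 50-step
burn-in so recorded windows start at stationarity. Defaults emulate the
target study design: 15 dyads per group (30 total), months 3–12, two
5-minute sessions per month (20 sessions aggregating to 10 monthly
rows), all 26 codes, and group-specific couplings (e.g. a
mother-responds-to-independent-standing link positive for boys and
negative for girls). Spectral radius < 1 and positive-definite $\Sigma$
are enforced at configuration time. Dyads are i.i.d. given their group.

Two emissions serve two purposes:

* `gaussian_latent` — the panel *is* the latent draw. The model class
  matches the estimator exactly, so it supports sharp checks: on
  4-variable, 40-dyad, 40-month cohorts every entry of $A$ is recovered
  within ±0.1 essentially always.
* `poisson_counts` — monthly occurrence counts are Poisson with a log
  link on the latent (stationary mean `log(3)` ≈ 3 events/month),
  split over sessions, with durations as sums of exponential event
  lengths (mean 2 s). This yields realistic non-negative integer data
  and session-level event logs whose monthly aggregation reproduces the
  panels exactly — but the linear VAR is now misspecified on purpose,
  so recovery is approximate and duration models can legitimately fail
  homoscedasticity diagnostics.

`ground_truth_irf()` returns the closed-form orthogonalized IRFs of the
planted system ($\Theta_0 = \mathrm{chol}(\Sigma)$,
$\Theta_h = A \Theta_{h-1}$), the recoverable truth for every
downstream stage.

What the generator does *not* emulate: real behavioral coding is
zero-inflated and bounded by session length, codes are mutually
exclusive within posture families, coders disagree, and real dyads are
heterogeneous. Passing tests therefore demonstrate that the estimation
machinery is correct and calibrated under the study's design geometry —
not that a linear VAR is an adequate model of any particular real
cohort.

## Numerical and design choices

* Estimation is QR-based least squares; rank deficiency is an error
  naming the offending column, never a silent pseudo-inverse.
* An exactly-zero residual covariance (deterministic input) degrades to
  a zero shock factor — zero point IRF with zero-width bands — while
  the user-facing `cholesky_factor()` treats non-positive-definite
  input as an error.
* Monthly panels admit a third encoding label, `gaussian_latent`, for
  synthetic latent-scale panels; non-negativity is enforced only for
  the two data encodings.
* Lag-1 autocorrelation weights are sample correlations of overlapping
  lagged pairs (so a perfectly alternating series has lag-1 weight
  exactly −1); at extreme lags where a segment has zero variance the
  weight is `NA` rather than a fabricated number.
* Determinism: every stochastic step takes a seed; `run_study()`
  derives per-model seeds from its master seed, so identical configs
  give byte-identical reports.
* Validation problem sizes (used in the test suite and acceptance
  script): 1000 null replicates of length 500 for test calibration;
  200 experiments × 100 bootstrap replicates for coverage; 20-seed
  batteries for recovery and for planted group-specific effects; the
  full-vocabulary sweep smoke-tested at 25 replicates per ordering.

## Limitations

Structural VAR, vector error correction, fractional integration,
multilevel/per-dyad models, and generalized (ordering-free) IRFs are
out of scope. The sign table inherits every caveat of Granger-style
inference: short-lag, linear, in-sample association — not mechanism.
With 26 codes the per-group design (135 usable rows for 27 parameters
per equation) estimates 676 coefficients; individual coefficients are
noisy, which is precisely why reporting flows through conservative
orthogonalized IRFs with bootstrap bands rather than raw coefficients.
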