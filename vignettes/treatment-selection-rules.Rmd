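---
title: "Constructing and evaluating treatment selection rules from an estimated effect function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing and evaluating treatment selection rules from an estimated effect function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A randomized controlled trial with a continuous biomarker $X \in [0,1]$, a
treatment indicator $T \in \{0,1\}$ (randomized 1:1) and a continuous outcome
$Y$ lets us estimate the *treatment effect function*

$$\theta(x) = E(Y \mid X=x, T=1) - E(Y \mid X=x, T=0),$$

the expected benefit of the new treatment over the standard at marker value
$x$. A *treatment selection rule* is a subset $C \subseteq [0,1]$: future
patients with $x \in C$ receive the new treatment. Estimating $\theta$ does
not by itself say how to get from $\hat\theta$ to a concrete $C$ — the open
question is how stochastic uncertainty in $\hat\theta$ should enter the rule.
This package implements and compares four construction principles, each
applied after a gatekeeping interaction pretest:

| rule | definition |
|------|------------|
| EST | $\{x : \hat\theta(x) \ge 0\}$ |
| POI | $\{x : l_p(x) \ge 0\}$, $l_p$ the lower bound of a pointwise $1-\gamma$ band |
| SIM | $\{x : l_s(x) \ge 0\}$, $l_s$ the lower bound of a simultaneous $1-\gamma$ band |
| CIR | $\{x : \hat\theta(x) \ge 0\} \setminus \bigcup_{x_r} \mathrm{CI}(x_r)$, removing confidence intervals around every root $x_r$ of $\hat\theta$ |

POI and CIR are conceptually linked: a pointwise band read *horizontally* at
height 0 is a $1-\gamma$ confidence set for $\theta^{-1}(0)$
(`invert_band_horizontally()`), so POI can itself be seen as a CIR-type rule.
They remain distinct implementations here — CIR uses delta-method intervals —
mirroring the fact that the delta method for a root (a *ratio* of
coefficients in the linear model) can behave differently from band inversion.

## Models and inference

The analysis model is a linear-regression interaction model, fitted by
ordinary least squares (`fit_interaction_model()`):

* linear: $Y = \alpha_0 + \alpha_1 X + (\beta_0 + \beta_1 X)T + \varepsilon$
* quadratic: $Y = \alpha_0 + \alpha_1 X + \alpha_2 X^2 + (\beta_0 + \beta_1 X + \beta_2 X^2)T + \varepsilon$

The treatment block $g = (\beta_0, \beta_1[,\beta_2])$ and its covariance
submatrix $\Sigma$ give $\hat\theta(x) = a(x)'g$ with $a(x) = (1, x[, x^2])$
and $\mathrm{se}(x) = \sqrt{a(x)'\Sigma a(x)}$.

**Pretest.** Rules are only constructed if the interaction F-test
($H_0: \beta_1 = 0$, or $\beta_1 = \beta_2 = 0$) rejects at the 5% level;
otherwise every candidate set is empty. For the linear model the F statistic
equals the squared t statistic of the single interaction coefficient; F is
used for both degrees so the joint quadratic null is handled identically.

**Pointwise band.** $\hat\theta(x) \mp t_{\mathrm{df},1-\gamma/2}\,\mathrm{se}(x)$ —
exact under the normal error model.

**Simultaneous band.** The critical value $c$ solves
$P(\sup_x |\hat\theta(x)-\theta(x)|/\mathrm{se}(x) \le c) = 1-\gamma$ over the
bounded marker domain (which is why the design restricts markers to bounded
supports). The reference backend is *sup-t Monte Carlo*: draw
$Z \sim N(0, \Sigma)$, evaluate $\sup_x |a(x)'Z|/\mathrm{se}(x)$ on a
201-point grid, and take the $1-\gamma$ quantile of the sups. An analytic
*tube-formula* backend is also provided
($P(\sup|t|>c) \approx \frac{\kappa}{\pi}e^{-c^2/2} + 2(1-\Phi(c))$ with
$\kappa$ the length of the standardized regression curve on the sphere); the
two agree to a few hundredths at the usual levels and the Monte Carlo backend
is validated by empirical coverage in the test suite. Numerical choices:

* `simultaneous_critical_value()` defaults to $10^5$ draws; the simulation
  engine uses 20,000 draws per replicate (`band_draws`), whose Monte Carlo
  error on the critical value ($\approx 0.015$ at level 0.95) is negligible
  against the band width while keeping full studies fast.
* The sup-t draws use the plug-in normal approximation (z-style) while the
  pointwise band uses the t quantile; at the design's $n = 1500$ the df
  correction is immaterial, and the returned critical value is floored at the
  pointwise t quantile so the nesting $l_s(x) \le l_p(x)$ — and hence
  $C_\mathrm{SIM} \subseteq C_\mathrm{POI}$ — holds for any residual df.
* Band-rule boundaries solve the polynomial equation
  $(a(x)'g)^2 = c^2\,a(x)'\Sigma a(x)$ (degree $\le 4$) by companion-matrix
  root finding with bisection refinement, then midpoints of the induced
  partition are sign-classified. All sets use the closed ($\ge$) convention of
  the rule definitions; measure-zero touch points are kept.

**Root intervals.** Roots of $\hat\theta$ come from the closed-form
linear/quadratic formulas; each root $r$ in the domain gets a symmetric
normal-quantile interval with the delta-method standard error from the
gradient $\partial r/\partial g_k = -r^k/\hat\theta'(r)$. A vanishing
derivative at a root (double root, or a constant effect) leaves the root
unidentified to first order; `root_cis_delta()` flags this and `rule_cir()`
responds maximally conservatively with an empty selection, counting the event
in the engine's logs rather than hiding it.

## Performance functionals

For a set $C$ and a known scenario, with $X^*$ a future patient's marker
drawn from the same distribution as $X$:

* sensitivity $= P(X^* \in C \mid \theta(X^*) \ge 0)$,
* specificity $= P(X^* \notin C \mid \theta(X^*) < 0)$,
* overall gain $= E(\theta(X^*) 1_{X^* \in C})$, the change in the population
  mean outcome under the rule, bounded by the maximal gain
  $E(\theta(X^*)1_{\theta(X^*) \ge 0})$,
* power $= P(\mathcal{C} \ne \emptyset)$ across replicates — the chance the
  investigation recommends the new treatment to anyone at all.

These are computed by integration against the true scenario — conditional
masses from the exact marker CDF, the gain by adaptive quadrature (absolute
tolerance $10^{-9}$, split at the triangular density's knot) — never by
resampling future patients, which removes one layer of Monte Carlo noise. The
test suite checks the quadrature against independently coded closed-form
polynomial integrals to $10^{-8}$. Edge conventions: an empty set has
sensitivity 0, specificity 1 and gain 0; at $\beta = 0$ there are no
negative-effect patients and specificity is defined as 1 (the study never
evaluates metrics there, so this only stabilizes edge cases and null cells).

## The synthetic data generator

`sample_trial()` *is* the study condition, not a tuning knob: marker uniform
on $[0,1]$ or triangular $\mathcal{T}(0,1,1/3)$ (inverse-CDF sampling — exact,
reproducible, no rejection step), arms Bernoulli(0.5), outcome
$\alpha(X) + \theta(X)T + \varepsilon$ with $\varepsilon \sim N(0,1)$ and
$\alpha \equiv 0$ by default. The four canonical scenarios
(`scenario_from_id()`): linear/uniform, linear/triangular, concave/uniform,
convex/uniform, with shapes $\beta(x-0.5)$, $\beta(0.3-0.9(x-1)^2)$,
$\beta(-0.3+0.9x^2)$. Setting $\alpha \equiv 0$ is without loss of generality
for correctly specified analysis models, whose treatment-block estimates are
invariant under $Y' = Y + \alpha(X)$ — a property the tests verify on shared
noise streams. A `noise_sd` hook (default 1) exists purely for
exact-recovery tests.

What the generator does *not* emulate: unbounded or normally distributed
markers (the simultaneous-band theory used here needs a bounded domain),
non-normal or heteroscedastic errors, binary/survival outcomes, model classes
outside linear/quadratic, and thresholds other than 0. Passing tests
therefore speak to the behaviour of the construction principles under a
correctly specified (or deliberately misspecified polynomial) model, not to
robustness against arbitrary real-world violations.

## The simulation engine

`run_study()` replicates the full pipeline — sample, fit, pretest, construct
EST/POI/SIM/CIR, score — across a $\beta$ grid, and `run_level_sweep()`
across a grid of confidence levels. Defaults mirror the study design:
$n = 1500$ (sized so SIM retains $\ge 90\%$ power in the linear/uniform
scenario at $\beta = 0.8$, where a quarter of patients have effects above
0.2), 2500 replicates (SE 0.6% for a power of 90%, `power_se(0.9, 2500)`),
$\beta \in \{0.4, 0.6, 0.8, 1, 1.2\}$, level 0.95, pretest level 0.05, and
the "correct" model pairing (linear truth → linear model, curved truth →
quadratic) unless a misspecified pairing is requested.

Design choices made where the design was genuinely open:

* **Common random numbers.** Within a replicate all four rules share the
  trial; across levels in a sweep each replicate reuses its trial and its
  sup-t draws (quantiles at each level come from one set of sups), so EST is
  *exactly* constant across levels and level comparisons are paired.
* **Seed policy.** A master seed spawns one substream per replicate via a
  deterministic counter mix, so results are independent of execution order
  and replicate counts can be extended without changing earlier replicates.
  Singular fits (possible only for degenerate marker samples) are redrawn on
  a derived substream and counted; at $n = 1500$ the count is zero in
  practice.
* **Degenerate roots** are counted per replicate and reported in
  `counts$degenerate_roots` rather than silently absorbed, since how often
  they occur is itself informative about the delta-method rule.

Problem sizes used in the shipped checks are the package's own choices:
the full-scale operating characteristics (power, specificity, gain
shortfalls, level-0.80 sweep) use $n = 1500$ with 1000–2000 replicates —
binomial SE at most 1.1 points on a 90% power — and the distributional
calibration checks (band coverage, pretest size) use smaller trials
($n = 100$–300, 400–2000 replicates) where the t-based theory is exact at any
sample size.

## Known limitations

* The simultaneous band is defined through its coverage contract and
  validated empirically; numerical identity with any particular published
  band construction is not guaranteed.
* Delta-method root intervals are first-order; for the linear model the root
  is a coefficient ratio and the interval can be poorly calibrated when the
  interaction is weak — visible as POI/CIR discrepancies, which are by design
  reported, not corrected. Fieller-type intervals are out of scope.
* Only the threshold 0 is implemented for the rules; clinical-relevance
  variants $\hat\theta(x) > c$ and the "unmet gain" of overlooked
  beneficiaries are not.
* Metrics are exact integrals against the *assumed* scenario; applying them
  to a real trial requires believing the scenario, which is why this is a
  simulation framework and not an estimation tool for field data.

## A worked example

```{r, eval = FALSE}
library(trtselect)

cfg <- study_config(scenario_id = 1, beta_grid = 0.8, n = 1500,
                    replicates = 500, seed = 11)
res <- run_study(cfg)
subset(res$results, metric %in% c("power", "specificity") & rule %in% c("EST", "SIM"))
res$benchmarks
```

With 500 replicates this reproduces the qualitative picture: EST has the
highest power and a specificity near 95%, the band/CI rules push specificity
toward 100% at a price in sensitivity and gain, and the price is largest for
SIM and in the triangular-marker scenario. Lowering the level from 0.95 to
0.80 (`run_level_sweep()`) recovers much of the gain while keeping
specificity above 0.98 — the argument for 80% bands as a first step toward
gain-oriented rule construction.
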