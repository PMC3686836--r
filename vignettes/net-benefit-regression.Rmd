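---
title: "Robust net-benefit regression: model, estimators and the contamination study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust net-benefit regression: model, estimators and the contamination study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbreg)
```

## The model

A two-arm cost-effectiveness study records, for each subject $i$, an
effectiveness value $E_i$, a cost $C_i$, a treatment indicator
$T_i \in \{0, 1\}$ and covariates $x_{i1}, \dots, x_{is}$. Given a
willingness-to-pay $\lambda$ per unit of effectiveness, the per-subject
net benefit is

$$nb_i = \lambda E_i - C_i,$$

the monetary value of the subject's effectiveness at price $\lambda$,
net of what their care actually cost. Net-benefit regression (NBR) is
the linear model

$$nb_i = \beta_0 + \beta_T T_i + \beta_1 x_{i1} + \cdots + \beta_s x_{is} + \varepsilon_i.$$

The coefficient $\beta_T$ is the covariate-adjusted *incremental net
benefit* (INB) of the intervention arm: the intervention is
cost-effective at $\lambda$ exactly when $\beta_T > 0$. Sampling
uncertainty is handled by the one-sided test of $H_0: \beta_T \le 0$
against $H_1: \beta_T > 0$; `nbreg` refers the t-statistic
$\hat\beta_T / \widehat{se}(\hat\beta_T)$ to a $t_{n-p}$ distribution
(standard small-sample practice; indistinguishable from the normal
reference at the sample sizes of interest). The probability of
cost-effectiveness reported alongside is $1 - p$, and the
cost-effectiveness acceptability curve (CEAC) traces that probability
over a grid of $\lambda$ values (`ceac()`, `autoplot()`).

Cost data are notoriously heavy-tailed: a handful of catastrophically
expensive patients can dominate a least-squares fit, bias
$\hat\beta_T$ toward the outliers and destroy the power of the test.
`fit_nbr()` therefore exposes, besides OLS, five outlier-resistant
estimators of the same regression.

## The estimators

All six estimators operate on the design matrix
$[1 \mid T \mid x_1 \cdots x_s]$ built by `fit_nbr()`; they differ only
in how coefficients, scale and standard errors are computed.

**M-estimation** (`huber`, `hampel`, `tukey`) minimizes
$\sum_i \rho\!\left((nb_i - X_i\beta)/\hat\sigma\right)$ for a symmetric
loss $\rho$, solved by iteratively reweighted least squares (IRLS) from
an OLS start, with the residual scale $\hat\sigma$ re-estimated at every
iteration by the Gaussian-consistent MAD,
$\mathrm{median}|r - \mathrm{median}(r)| / 0.6745$. The losses are the
canonical published forms:

* Huber: quadratic inside $|r| \le k$, linear outside ($k = 1.345$,
  95% Gaussian efficiency). Bounded influence, but large outliers keep
  a constant pull.
* Hampel three-part redescending ($a, b, c = 1.7, 3.4, 8.5$): influence
  decays linearly to zero beyond $b$, so residuals past $c$ are ignored
  entirely.
* Tukey bisquare ($c = 4.685$, 95% efficiency): smooth redescending
  loss, zero weight beyond $c$.

Standard errors use the M-estimation asymptotic covariance
$\hat\sigma^2 \,\frac{\sum \psi^2/(n-p)}{(\overline{\psi'})^2}\,
(X^\top X)^{-1}$ with Huber's finite-sample correction
$K = 1 + \frac{p}{n}\frac{\mathrm{var}(\psi')}{(\overline{\psi'})^2}$ —
the same construction mainstream robust-regression software uses, which
keeps the resulting t-statistics pivotal for the one-sided test.

**MM-estimation** (`mm`) first computes an S-estimator: the
coefficients minimizing the bisquare M-scale of the residuals, tuned to
a 50% breakdown point ($c_0 = 1.548$, found by a random $p$-subset
search with weighted-least-squares refinement, in compiled code). The
final stage is a bisquare IRLS step tuned to 95% Gaussian efficiency
($c_1 = 4.685$), started at the S-coefficients with the scale *fixed*
at the S-scale — never updated — which is what preserves the 50%
breakdown point while recovering high efficiency. Both tuning constants
are solved from their defining Gaussian integrals at run time
(`bisquare_bdp_constant()`, `bisquare_efficiency_constant()`), so
non-default breakdown points and efficiencies are first-class.

**Least trimmed squares** (`lts`) minimizes the sum of the $h$ smallest
squared residuals, by the concentration algorithm: 500 random
$p$-subset starts, 10 C-steps each (every C-step refits least squares
on the $h$ currently best-fitting points and provably never increases
the objective), then the 10 best candidates are concentrated to
convergence. Default coverage is $h = \lfloor 3n/4 \rfloor$, bounded
below by $\lfloor (n+p+1)/2 \rfloor$ — comfortably above the 30%
contamination ceiling studied here. The reported fit is the
least-squares refit on the covered subset (weights exactly 0/1); its
residual scale carries the Gaussian consistency factor
$\alpha / (\alpha - 2c\,\phi(c))$ with $\alpha = h/n$,
$c = \Phi^{-1}((1+\alpha)/2)$, and standard errors come from the
covered-subset covariance with that corrected scale. Ties in the
ordered squared residuals are broken by row index, so a seeded search
is fully deterministic.

Non-convergent IRLS fits are flagged (`converged = FALSE`), never
raised as errors; the simulation harness counts them as non-rejections
rather than dropping them, which would bias rejection rates.

### Outlier reporting and the bootstrap

Robust fits report the share of observations whose final weight falls
below 0.5 (`outlier_proportion()`); for LTS this is exactly the trimmed
fraction. The 0.5 cut-off is a reporting convention — it labels points
the estimator has at least half-discounted — and is flagged as such in
the documentation; it plays no role in estimation. The bootstrap
probability of cost-effectiveness (`prob_ce_bootstrap()`) resamples
*subjects* (cases) with replacement, B = 1000 by default, refits, and
reports the fraction of replicates with positive INB; replicates that
lose an arm are redrawn and counted. Case resampling was chosen over
residual resampling because it is valid under the very
heteroscedasticity and contamination that motivate the robust fits.

## The synthetic-data generator

`sim_config()` / `sim_nbr_data()` define the contamination study that
doubles as the package's synthetic-data generator. Effect and cost are
bivariate normal conditional on `arm ~ Bernoulli(0.5)` and a covariate
`x ~ N(2, 0.5^2)`, with means

$$E = 1 + 1\cdot arm + 1\cdot x + e_1,\qquad
  C = 50 + 10\cdot arm + 1\cdot x + e_2,$$

so the intervention buys one unit of effect for 10 extra currency
units, and the true INB at willingness-to-pay $\lambda$ is
$\lambda - 10$: negative at $\lambda \in \{7, 8\}$ (size cells),
positive at $\{12, 13\}$ (power cells). Contamination replaces the cost
of the *last* $\lfloor \pi n \rfloor$ subjects with draws from
$N(150, 1)$ (scenario I), $N(200, 1)$ (scenario II) or an equal-odds
mixture of the two (scenario III), for
$\pi \in \{0.05, 0.1, 0.2, 0.3\}$ — outliers live in the cost variable
only, in both arms, exactly as cost outliers arise in claims data.

**Error covariance.** The generator's error covariance is
`diag(0.64, 4)`: effect and cost error SDs 0.8 and 2.0, uncorrelated.
This is the package's calibration of the study conditions, fixed once
before the acceptance checks were written: the net-benefit error SD it
implies, $\sqrt{\lambda^2 \cdot 0.64 + 4} \approx 9.8$ at
$\lambda = 12$, is the value recovered by inverting the reference
experiment's power cells through the normal-approximation power
identity $q \approx \Phi(z_{0.95}^{-} + INB/se)$, and simulation under
it reproduces the reference OLS, Huber, bisquare and LTS cells
simultaneously (e.g. OLS $n{=}100$: 0.12; Huber $n{=}500$: 0.65). A
unit-variance choice cannot: it matches the OLS cells (which are
dominated by the contamination variance) but predicts robust powers
~0.15 too low. Both the covariance and the treatment probability are
exposed as configuration knobs.

**Seeding.** Every replicate seed is derived deterministically from the
cell seed (a 48271-multiplier counter kept inside 32-bit range), so any
cell is independently reproducible and all estimators see *identical*
datasets within a replicate. The LTS/S subset searches run on their own
seeded `mt19937` streams; when no seed is passed they draw one from the
session RNG, so a single upstream `set.seed()` still fixes every
result.

`empirical_q()` reports the rejection fraction $q$ of the one-sided
test at level 0.05 with its binomial Monte-Carlo standard error
$\sqrt{q(1-q)/reps}$; `run_sim_table()` drives a grid of cells and
keeps going past per-cell failures.

### What the generator does and does not emulate

The generator reproduces the mechanism that matters for the question —
grossly right-shifted cost values embedded in an otherwise
well-behaved linear model — under Gaussian errors and a fixed outlier
magnitude. Real claims costs are skewed even without outliers
(log-normal- or gamma-like), effects may be censored, and real outliers
are not all drawn 10-15 residual SDs from the mean. Passing the
simulation checks therefore demonstrates correct behaviour of the
estimators and the test under the stated contamination model, not
performance guarantees on arbitrary real data. Effect-side outliers,
skewed cost models and censoring are out of scope.

## Numerical choices

* IRLS convergence: every coefficient change below
  $10^{-8}(1 + |\beta|)$, at most 100 iterations.
* Degenerate scale (MAD = 0, i.e. an exact fit of more than half the
  data): the fit returns immediately with scale 0 and zero residual
  report instead of dividing by zero; `mad_scale()` itself treats an
  all-identical residual vector as an error signalling an exact fit.
* The MM IRLS loop includes a descent safeguard: a step that would
  increase $\sum \rho(r/\hat\sigma_S)$ is rejected, so the objective
  trace is non-increasing by construction.
* S-stage search effort: 200 random subsets with 2 refinement steps
  each, best 10 polished to convergence — ample at the design's sample
  sizes; configurable via `n_starts`/`k_steps`.
* Problem sizes in the shipped checks: simulation cells run at 200
  replicates in the test suite and 500 in `scripts/acceptance.R`
  (matching the reference design); the parameter-recovery check uses
  200 replicates at $n = 5000$ with lightened subset searches, which on
  clean data lose nothing.

## Limitations

* Standard errors for the robust fits are asymptotic; at $n \ll 100$
  the one-sided test can be conservative (the simulated sizes at
  $n = 100$ are well below 0.05, matching the reference study).
* The LTS covered-subset standard error is known to be optimistic
  relative to the raw LTS sampling variance; it is the construction
  that reproduces the reference experiment's behaviour, and the
  bootstrap probability is available as the assumption-free
  alternative.
* ICER confidence intervals (Fieller-type or otherwise) are explicitly
  out of scope; the package's inferential object is the INB at a given
  willingness-to-pay.
* With contamination above the LTS trimming fraction or the M
  breakdown point (e.g. 30% with default $h$), no estimator here is
  guaranteed stable — consistent with the reference study, where the
  monotone-influence M-estimators degrade at $\pi = 0.3$ while MM and
  LTS persist.
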