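---
title: "Serial t-tests for N-of-1 trials: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serial t-tests for N-of-1 trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nof1serial)
```

## The problem

An N-of-1 trial draws inference about two treatments from a single
individual's repeated measurements. Those measurements are serially
correlated — tomorrow's pain score resembles today's — yet the analyses
most often reported for such trials are plain paired or two-sample
t-tests that assume independence. Under positive serial correlation the
classical tests understate the standard error *and* overstate the
information content of the series, so they reject too often and produce
intervals that are too narrow. Methods that do handle serial correlation
(bootstrap schemes, simulation-based modelling, likelihood iterations)
demand computation and expertise that practitioners of these small
trials rarely deploy.

This package implements the closed-form middle road: keep the ordinary
least squares estimates everyone understands, and fix the *reference
distribution* for AR(1) correlation.

## Model and test statistics

A single series of $m$ equally spaced observations is modelled as
$Y \sim N(X\beta,\, R\sigma^2)$ with $R_{jk} = \rho^{|j-k|}$. Two mean
structures are supported per series:

* **level-change**: $X = \mathbf{1}_m$ ($p = 1$ location parameter);
* **rate-change**: $X = [\mathbf{1}_m, x]$ with the centered time index
  $x = (1,\dots,m) - (m+1)/2$ ($p = 2$). All slopes are per unit of this
  index, i.e. per time step.

OLS gives $\hat\beta$ and the residual variance $s^2$. Under the AR(1)
model, $\mathrm{Var}(\hat\beta) = c(\rho)\sigma^2$ and
$E(s^2) = b(\rho)\sigma^2$, where $c(\rho)$ comes from the sandwich
$(X'X)^{-1}X'RX(X'X)^{-1}$ and $b(\rho)$ from
$\{m - \mathrm{tr}(P_X R)\}/(m - p)$. Both admit closed forms for the
two designs (`c_level()`, `b_level()`, `c_rate()`, `b_rate()`), verified
in the test suite against a dense matrix-algebra oracle
(`ar1_matrix_oracle()`) to a relative error of $10^{-10}$ over
$m \le 30$ and $|\rho| \le 0.9$. The effective sample size
$m' = m / \{m - (m-1)b\}$ (level) or $2m / \{m - (m-2)b\}$ (rate)
re-expresses the information loss; for positive $\rho$, $m' < m$.

The serial t-statistic is
$$ t \;=\; \frac{\hat\beta}{\sqrt{c(\rho)\, s^2 / b(\rho)}} $$
referred to a Student-t distribution with fractional degrees of freedom
$m' - p$ (for 2-sample tests: $m'_A + m'_B - 2p$, with the pooled $s^2$
over summed residual df). Four tests result: paired and 2-sample, level
and rate, with size minima $m \ge 4$; $m_i \ge 3,\ \Sigma m \ge 7$;
$m \ge 5$; and $m_i \ge 4,\ \Sigma m \ge 9$, respectively — each the
smallest series able to support the parameters estimated. With
$\rho = 0$ every kernel collapses to its classical value and each serial
test reproduces its usual analogue *exactly*; the suite asserts this to
$10^{-12}$, and the classical analogues are themselves cross-checked
against `stats::t.test()` and `stats::lm()`.

## Estimating the correlation

$\rho$ enters through its estimate. From the design's residuals
(series minus mean, or minus the intercept+slope fit), the simplified
maximum-likelihood estimator is
$\hat\rho = \sum_{j\ge2} e_j e_{j-1} / \sum_j e_j^2$; its small-sample
bias ($\approx -2\rho/(m-1)$) is severe at N-of-1 lengths, so Fuller's
correction $r = \hat\rho + (1-\hat\rho^2)/(m-1)$ is applied — the
estimator with the best small-sample track record among the standard
lag-1 candidates. Two-sample designs estimate $r$ per arm and pool by
length, $\bar r = (m_A r_A + m_B r_B)/(m_A + m_B)$, then evaluate both
arms' kernels at $\bar r$.

Numerical guards, chosen here because the formulas are silent about
edge cases:

* $r$ is clamped to $[-0.999, 0.999]$ (the kernels are singular at
  $\rho = 1$); clamping is flagged in the result. Powers $\rho^m$ are
  evaluated directly in double precision, which loses fewer than six
  significant digits for $m \le 200$, well inside every tolerance used.
* A series with zero residual variance is an **error**, not $r = 0$:
  $s^2 = 0$ leaves the t-statistic undefined, and silently continuing
  would fabricate certainty. (Real data hit this: constant response
  series must be excluded, not analyzed.)
* Estimated correlations extreme enough to drive $m' - p \le 0$ raise an
  error advising more observations; $0 <$ df $< 1$ is legal, computed,
  and flagged (`df_lt_1`), since the t distribution is defined for any
  positive real df.
* Estimates are carried at full precision everywhere; only printed
  output and table-matching tests round (half away from zero, matching
  how the reference tables were typeset).

One worked-example wrinkle is worth recording. On the packaged pre/post
discounting fixture our formula chain reproduces the published $s$ and
$r$ columns and the level-change statistics exactly, but the published
rate-change df subscripts (2.94 and 3.98) correspond to $r$ values of
0.3254 and 0.4712 — which would have *printed* as 0.33 and 0.47, not the
0.32 and 0.46 actually printed alongside them. The published table is
internally inconsistent at that precision; this package follows the
formulas (giving df 2.96 and 4.11), and the acceptance suite leaves the
corresponding assertions red rather than bending the estimator.

## Planning calculators

`expected_margin()` returns the plug-in half-width
$t_{DF,\alpha/2}\sqrt{c(\rho)\sigma^2/b(\rho)}$ (two-sample:
$\sqrt{\sigma^2(c_A/b_A + c_B/b_B)}$) at the $\rho$-implied fractional
df. Defaults — $\alpha = 0.10$ (a 90% interval, i.e. a 95% one-sided
limit) and $\sigma^2 = 1$ — mirror the published planning tables, all 90
cells of which are reproduced at two decimals except the four or five
extreme cells at $\rho = 0.8$, $m \le 7$, where our values (cross-checked
independently against R's and SciPy's t quantile routines, which agree to
four decimals at df $\approx 0.29$) differ from the printed ones by up to
0.2% — quantile-precision artifacts in the source tables, left as red
assertions in the acceptance suite.

`detectable_effect_size()` maps any of the four designs onto a
one-sample noncentral-t calculator: set the calculator's sample size
$m_{(C)} = DF + 1$ (fractional), solve its power equation
$P\{T_{m_{(C)}-1}(\delta_{(C)}\sqrt{m_{(C)}}) > t_{1-\alpha}\} =$ power
for $\delta_{(C)}$ by `uniroot` on $(10^{-8}, 10^4)$ at tolerance
$10^{-10}$, and convert back via
$\delta = \delta_{(C)}\sqrt{m_{(C)}\, c(\rho)}$. For 2-sample designs the
same recipe applies with $c = c_A + c_B$ — an extension chosen here, as
the published five-step recipe is written for the one-sample calculator;
it follows from matching noncentrality parameters, and the round-trip
property (direct power evaluation at the returned $\delta$ recovers the
requested power to $10^{-6}$) holds for all four designs.

## The Monte Carlo harness and its stated world

`generate_ar1()` draws stationary series — first deviation at full
marginal variance, innovations at $\sigma^2(1-\rho^2)$ — so every finite
stretch has exactly the model covariance; no burn-in approximation.
`generate_paired_ar1()` produces two arms sharing $\rho$ with jointly
Gaussian innovations calibrated so the contemporaneous cross-correlation
equals $\rho_{pair}$; the within-pair difference is then *exactly* AR(1)
with parameter $\rho$ and variance $2\sigma^2(1-\rho_{pair})$, matching
the paired tests' model. This is the simplest process consistent with
every property the evaluation design states; whether $\rho_{pair}$ should
enter as contemporaneous or innovation correlation is unstated there, and
under this construction (common $\rho$) the two coincide.

Experiment defaults are the evaluation study's stated conditions:
$\sigma^2 = 1$, one-sided 5% tests, $\rho \in \{-0.33, 0, 0.33, 0.67\}$
as typical grid values, $\rho_{pair} \in \{0.33, 0.67\}$ for paired
designs (0 for 2-sample), 10,000 replicates (binomial half-width
$\le 0.01$). Replicates with degenerate estimates are excluded from
rejection denominators and counted (`n_excluded`) — the source is silent
on this; excluding-and-reporting is the only option that neither
fabricates a test result nor hides the exclusion.

Two non-obvious choices:

* **Margin-factor yardstick.** The factor compares the mean *realized*
  margin (t-quantile at the estimated df times the estimated SE) to a
  theoretical margin at the true $\rho$. For the yardstick we use
  $t_{DF,\alpha/2}\sqrt{c(\rho)\sigma^2}$ — *without* the $1/b$
  division — because that division exists to de-bias an estimated $s^2$,
  and the yardstick contains no $s^2$: indeed
  $E(\widehat{SE}^2) = c(\rho)\sigma^2$ exactly. This choice also
  reproduces the published factor table at $m \in \{8, 12\}$ for both
  serial and usual rows, which the $\sqrt{c/b}$ yardstick does not.
  (The published 1.00 entries for the usual test at $\rho = 0$ are
  idealized: any mean-of-margins definition gives $E(s) < 1$ there.)
  The planning function `expected_margin()` keeps the $\sqrt{c/b}$ form,
  which is what reproduces the planning tables.
* **Paired margin/power simulations generate the difference series
  directly** at variance $\sigma^2$, so realized and theoretical margins
  share a scale; Type I simulations generate the raw arms with
  $\rho_{pair}$ (the tests are scale-invariant, so this choice cannot
  affect rejection rates).

### What a green simulation test does and does not establish

The generator emulates stationary Gaussian AR(1) data with a constant
(or linearly trending) mean and common variance across arms. Real N-of-1
data can be non-Gaussian, heteroscedastic, non-stationary, unequally
spaced, affected by carryover between treatment periods, or correlated
beyond lag 1 — none of which the harness emulates, so green tests
establish correctness *under the model*, not robustness beyond it. Two
properties measured by the harness temper even the in-model story: at
high $\rho$ the serial tests' Type I error stays above nominal until
$m \approx 50$ (about 0.069 at $\rho = 0.67$, $m = 50$, against a
one-sided 0.05), and the rate-change tests inherit a strong negative
bias in the estimated correlation. The acceptance suite runs the
$\rho = 0.67$ check at 200,000 replicates because the true rate sits
0.019 from nominal against a 0.02 tolerance; at 10,000 replicates the
verdict would be decided by Monte Carlo noise.

## Limitations

* No carryover-effect adjustment; design trials to wash out carryover.
* No missing data or unequal spacing — both are hard errors.
* Common $\sigma^2$ across arms is assumed, as in most t-test practice.
* At the minimum sizes ($m = 4$ or 5) the correlation estimate is poor,
  fractional df can fall below 1, and inference is fragile; the package
  computes honestly and flags, but more observations are the only cure.
* Rate-change tests at small $m$ reject above nominal even for
  $\rho = 0$; treat them as descriptive below $m \approx 9$.
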