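---
title: "GPS dose-response estimation for daily mortality series: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GPS dose-response estimation for daily mortality series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the causal framing

Short-term air-pollution epidemiology usually regresses daily death counts
on daily pollutant concentrations and a battery of confounder terms,
assuming a log-linear exposure effect. That assumption decides, among other
things, whether lowering concentrations that are already below regulatory
limits is predicted to save lives. This package instead treats each day as
a unit with potential outcomes: $Y_i(z)$ is the death count day $i$ would
have shown under lag 0-1 exposure $z$, only $Y_i(Z_i)$ is observed, and the
quantities of interest are

* the average dose-response function $\mu(z) = N^{-1}\sum_i Y_i(z)$, and
  its conditional version over day subsets (here: lag 0-3 temperature
  categories $\le 10$, $10$–$23$, $>23$ °C);
* attributable deaths $AD(z^\star) = \sum_{i:Z_i>z^\star}(Y_i -
  Y_i(z^\star))$ for counterfactual thresholds motivated by air-quality
  standards (20, 40, 50 μg/m³);
* distributional attributable deaths $DAD(z^\star)$, in which
  above-threshold days draw counterfactual exposures from the empirical
  exposure distribution of the below-threshold days — a more realistic
  "intervention" than pinning every exceedance exactly at the limit.

Identification rests on unconfoundedness given the measured covariates
(untestable; motivated by the standard confounder set of this literature)
and on SUTVA, made more plausible by using the lag 0-1 moving average as
the exposure rather than the same-day level.

The lag 0-1 exposure and lag 0-3 temperature mean are computed by
`study_series()`; days with incomplete lag windows (at most three at the
start of a gap-free series) are dropped rather than imputed, and gapped
dates are a hard error because lagging across a gap would mix non-adjacent
days.

## The two working models

**Exposure / GPS.** $\log Z_i \sim N(\alpha_0 + \alpha^\top X_i, \sigma_Z)$
with covariates: six day-of-week indicators (Monday reference), holiday and
influenza indicators, a degree-1 calendar spline with 5 df per year and
equally spaced knots (seasonality and trend), a cubic spline of lag 0-3
temperature with 5 df and knots at equally spaced quantiles, humidity and
humidity², and a July–August indicator (summer population dip). The
generalized propensity score is the conditional density of the exposure on
the log scale, $r(z;x) = \varphi\{(\log z - \alpha_0 -
\alpha^\top x)/\sigma_Z\}/\sqrt{2\pi\sigma_Z^2}$, evaluated literally as a
density in $\log z$ (no $1/z$ Jacobian): the GPS enters all later models
only through its value, and any strictly monotone transformation preserves
the balancing property, so the simpler log-scale form is used consistently
at fitting and prediction time. $\sigma_Z$ is the maximum-likelihood scale
(RSS/$N$): the GPS is a density evaluation, so the exact divisor is a
reproducibility convention rather than an inferential choice.

**Outcome.** $Y_i \sim \text{quasi-Poisson}(\lambda_i)$, $\log\lambda_i =
s(z, r(z;X_i))$, fitted at the observed pairs $(Z_i, R_i)$ where $R_i$ is
the actual GPS. No other covariates enter the outcome model — confounder
adjustment flows entirely through the GPS, which is the point of the
method. The dispersion is estimated from the Pearson statistic and rescales
uncertainty only; point estimates are Poisson maximum penalized likelihood
(asserted against `glm` in the tests).

## The bivariate smoother, in detail

`radial_penalized_basis()` builds a low-rank thin-plate-type smoother:

1. **Standardization.** $z$ and $r$ are min-max scaled to $[0,1]$ because
   they live on incommensurate scales (tens of μg/m³ vs densities of order
   $10^{-2}$–$10^0$); the smoother is isotropic in the scaled coordinates.
2. **Knots.** $K$ knots (default 50; configurable) are chosen among the
   observed scaled pairs by a greedy max-min-distance design seeded at the
   point nearest the centroid. The design is deterministic — ties break to
   the lowest index — so fits need no RNG.
3. **Kernel.** Radial columns $\phi(\lVert(\tilde z,\tilde r) -
   \kappa_k\rVert)$ with the 2-D thin-plate kernel $\phi(d) = d^2\log d$,
   $\phi(0)=0$.
4. **Whitening.** With $\Omega_{kl} = \phi(\lVert\kappa_k -
   \kappa_l\rVert)$, the radial block is post-multiplied by
   $|\Omega|^{-1/2}$ (eigenvalue magnitudes, floored at $10^{-8}$ relative
   to the largest) so the roughness penalty is the identity on the radial
   coefficients and zero on the unpenalized block $[1, \tilde z, \tilde
   r]$. The kernel matrix is genuinely indefinite (it is only
   conditionally positive definite), so the whitening uses the matrix
   absolute value: flooring *signed* eigenvalues instead would blow
   strongly curved negative directions up by four orders of magnitude,
   ruining the conditioning of the design and breaking the heavy-smoothing
   limit in which the fit must collapse onto the $[1,\tilde z,\tilde r]$
   GLM.

Fitting is penalized IRLS with step-halving on the penalized deviance;
convergence is declared when the penalized deviance changes by less than
$10^{-8}$ in relative terms (with a small absolute floor so saturated,
zero-deviance fits terminate), with a 100-iteration cap. The smoothing
weight minimizes the GCV score $n\,D/(n-\text{edf})^2$ — deviance $D$, edf
the trace of the influence matrix at the final weights — over a 40-point
logarithmic grid on $[10^{-6}, 10^6]$, refined once by a bounded
one-dimensional search around the grid minimizer; exact score ties break to
the largest $\lambda$ (the most parsimonious fit).

**Prediction and clamping.** A potential outcome $\hat Y_i(z)$ evaluates
the surface at $(z, \hat r(z;X_i))$. Counterfactual GPS values can fall far
outside the training cloud (a winter day evaluated at a summer-typical
exposure sits in the far tail of its own exposure distribution), so scaled
coordinates are clamped into $[0,1]^2$; every estimand records how many
evaluations were clamped. Clamping bounds extrapolation but does not create
information where the data have none — see the limitations below.

## Balance diagnostics

Following the blocking approach for continuous treatments, days are split
into four fixed exposure classes ($(0,20)$, $[20,40)$, $[40,70)$,
$[70,\infty)$ μg/m³). For each class the package compares a marginal Welch
t statistic of each covariate (class vs rest) with a GPS-adjusted one: the
GPS is evaluated for *all* days at the class median exposure $M_k$, days
are cut into four blocks at the quartiles of $r(M_k;X_i)$ (right-open
intervals), within-block Welch mean differences are combined with weights
proportional to block size, and the combined difference is divided by
$\sqrt{\sum_j w_j^2 se_j^2}$ — the independent-blocks standard error, a
choice the method literature leaves open. Blocks where either side has
fewer than two days are dropped with a warning and the weights
renormalized; zero-variance comparisons return a signed-infinity (or zero)
sentinel rather than an error so a whole report never dies on one
degenerate covariate.

## Bootstrap

Confidence intervals are percentile intervals from an iid bootstrap over
analysable days: lagged variables stay attached to their day, and each
replicate refits the exposure model, recomputes the GPS, and refits the
outcome model. By default the smoothing parameter is re-selected by GCV on
every replicate (full uncertainty propagation); `refit_lambda = "fixed"`
freezes it at the base fit's value, which is roughly fifteen times cheaper
and is what the package's own large coverage simulation uses. Replicates
that fail to fit (e.g. a rank-deficient resampled design) are dropped and
counted, and more than 5% failures aborts. The iid resampling ignores the
serial correlation of mortality series — a deliberate simplification; block
or residual bootstraps are out of scope.

## The synthetic generator and its calibration

`simulate_pm_study()` emulates a four-year (1461-day) daily series from a
polluted mid-latitude European city: sinusoidal temperature (mean 14.5 °C,
amplitude 10, iid noise sd 3 °C), seasonal humidity clamped to
$[20,100]$%, fixed-date holidays, a winter influenza window, and weekends.
The lag 0-1 exposure is drawn conditionally log-normal with a mean that is
*exactly linear in the package's own exposure design* (a target surface —
winter-peaking seasonal cosine, a temperature loading, a weekend dip — is
projected onto the design, so the exposure-model coefficients have an exact
known truth and parameter recovery can be tested sharply). Counts are
Poisson with mean $\exp\{b_0 + \text{seasonal} + \text{U-shaped
temperature loading} + (1 + \gamma_T\,\text{tdev}_i)\,g(Z_i)\}$ with the
saturating dose-response $g(z) = \gamma\log(1+z/\tau)$, $\tau = 20$ μg/m³,
per-cause $\gamma$ of 0.18 (natural), 0.21 (cardiovascular), 0.35
(respiratory) — steep below ~50 μg/m³ and flattening above, with impact
magnitudes of the order reported for comparable urban analyses. The
exposure-by-temperature modifier $\gamma_T$ defaults to 0; the effect
modification check uses $\gamma_T = 0.1$ per °C, i.e. a near-null cold-day
effect and a roughly doubled hot-day effect — the strong-modification
scenario in which stratified curves should visibly diverge.

Calibration targets, fixed once: marginal exposure mean ≈ 52.5 μg/m³ with
sd ≈ 33 and a seasonal/residual split of the log-exposure variance
(seasonal loading 0.32, $\sigma_Z = 0.48$) chosen so that the *marginal*
balance t statistics for temperature across exposure classes land in the
low-to-mid teens — the magnitude reported for real urban series of this
kind — rather than the mid-twenties an exposure this seasonal would
otherwise show; mean daily counts 28.0 / 10.3 / 2.5; winter baseline
mortality excess of roughly 30% (seasonal loading 0.08 plus $6\times
10^{-4}\,(T-20)^2$ cold/heat curvature). Each cause's intercept is solved
so the realized mean matches its target exactly.

The generator deliberately omits: serial correlation in weather, exposure
and counts (matching the bootstrap's independence assumption; an
overdispersion frailty option exists to exercise the quasi-likelihood
path), exposure measurement error and multi-monitor averaging, moving
holidays, and heat-wave clustering. Passing tests therefore demonstrate
correctness of the estimator under the model's own assumptions, not
robustness to the autocorrelation or measurement structure of real series.

## Test and simulation scales

The test suite validates at the study scale it emulates: 20 generator seeds
at $N = 1461$ for parameter, curve and impact recovery; 200 replicates at
$N = 500$ with $B = 200$ (and frozen smoothing) for bootstrap coverage;
$M \in \{100, \dots, 10000\}$ for the DAD Monte-Carlo error law. These
sizes were chosen as the smallest at which the sampling-theory comparisons
(3-standard-error bands, $1/\sqrt{M}$ scaling) are sharp.

## Known limitations

* **Treated-subset impact estimands inherit a pooling bias under strong
  confounding.** The aDRF averages $s(z, r(z;X_i))$ over *all* days, and
  the balancing property makes that average consistent — the package's
  simulations recover the true curve well. $AD$ and $DAD$, however, sum
  only over above-threshold (in practice: winter) days, and the GPS value
  $r(z^\star; X)$ pools day types with different baseline mortality (a
  high-pollution winter day and a very clean day can share the same GPS at
  $z^\star$). The subset average of the pooled surface then inherits a
  bias that no amount of data removes, and the finite-sample smoother —
  which cannot resolve the steep GPS gradient of the surface near
  $z^\star$ in the sparse off-ridge region — adds to it. In the package's
  calibrated simulations the natural-cause $AD(40)$ overshoots the
  potential-outcome truth by tens of percent while the aDRF is recovered
  to within a tenth of the curve range, and bootstrap intervals — centred
  on the biased estimator — rarely cover the truth. An independent
  thin-plate quasi-Poisson GAM fitted to the same $(Z_i, R_i)$ reproduces
  the same behaviour, so this is a property of the estimand-plus-smoother,
  not of this implementation. Impact estimates from this method on
  strongly seasonal series should be read as *descriptive of the fitted
  curve*, and compared against a matching or regression benchmark before
  being quoted as burdens.
* **Positivity.** Information below 20 μg/m³ and in stratum-by-exposure
  corners is thin; predictions there rely on clamped extrapolation (the
  clamp counters make this visible). No trimming is applied, by design:
  the estimands are defined over all treated days.
* **Low-exposure wiggle.** With GCV-selected smoothing the curve can
  wiggle where data are sparse; the knot count $K$ and $\lambda$ are
  exposed, but adaptive smoothing is not implemented.
* **No formal shape tests.** Non-linearity and effect modification are
  assessed descriptively (curve shapes, slopes), not by hypothesis tests.
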