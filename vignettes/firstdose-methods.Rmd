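---
title: "Methods: first-dose beta-lactam exposure and target attainment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: first-dose beta-lactam exposure and target attainment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firstdose)
```

## The problem

Meropenem and piperacillin are time-dependent antibiotics: efficacy tracks
the fraction of the dosing interval during which the free plasma
concentration stays above the pathogen's minimum inhibitory concentration
(%fT>MIC). In critically ill patients, the first hours of treatment matter
most, yet first-dose exposure is rarely measured. A common aggressive
regimen starts with a loading dose infused over 0.5 h followed immediately
by a 3 h extended infusion, repeated every 6-12 h. Whether this achieves
100% fT>MIC during the *first* dosing interval depends strongly on renal
function: patients with augmented renal clearance (ARC, conventionally
CrCL > 130 mL/min) eliminate beta-lactams so fast that even this regimen
can leave the trough below target.

`firstdose` implements the full analysis chain for this question:

1. **Renal assessment** — CKD-EPI 2021 eGFR (with Du Bois BSA for the
   absolute scale), Cockcroft-Gault CrCL, an ARC risk score, the
   suspected-ARC rule, and KDIGO AKI criteria.
2. **Pharmacokinetics** — a two-compartment infusion model evaluated in
   closed form under superposition of infusion events.
3. **Individual (MAP Bayesian) estimation** from the sparse three-sample
   schedule used for therapeutic drug monitoring.
4. **Exposure metrics** — %fT>MIC over the first interval and first 24 h,
   predicted troughs, attainment flags, dose-normalised Cmin/Cmax ratios,
   terminal half-lives.
5. **Cohort statistics** — exact Wilcoxon rank-sum comparisons with
   Hodges-Lehmann shift intervals, ROC/Youden cutoff analysis, ECDF-based
   cumulative distribution analysis.
6. **A synthetic cohort generator** that emulates the study conditions so
   the entire pipeline is testable without patient data.

## Structural PK model

Drug amounts in the central (A1) and peripheral (A2) compartments follow

$$\frac{dA_1}{dt} = R(t) - (k_{10} + k_{12})A_1 + k_{21}A_2,
  \qquad \frac{dA_2}{dt} = k_{12}A_1 - k_{21}A_2,$$

with $k_{10} = CL/V_1$, $k_{12} = Q/V_1$, $k_{21} = Q/V_2$ and total plasma
concentration $C = A_1/V_1$. $R(t)$ is piecewise constant over the infusion
events. Because the system is linear, `concentration_at()` evaluates the
profile as a closed-form biexponential superposition over events; the
disposition exponents $\alpha > \beta$ are the roots of
$\lambda^2 - (k_{10}+k_{12}+k_{21})\lambda + k_{10}k_{21} = 0$ and the
terminal half-life is $\ln 2/\beta$. The one-compartment limit $Q = 0$ is
handled exactly. A stiff ODE integration serves as an independent oracle in
the test suite (agreement to relative error $10^{-6}$); the closed form is
the production evaluator because it is exact and orders of magnitude
faster.

The dosing-interval clock is anchored at the start of the first extended
infusion: with a 0.5 h loading dose, maintenance infusions start at
$0.5 + k\tau$ and the first dosing interval is $[0, 0.5 + \tau]$. This
matches the convention of substituting the model-predicted concentration
"$\tau$ hours after the start of the extended infusion" for mistimed
troughs.

## Population model and configuration

Individual parameters are
$\theta_i = \theta_{\mathrm{typ}} \cdot m_i(\mathrm{cov}) \cdot e^{\eta_i}$
with log-normal random effects $\eta \sim N(0, \Omega)$ (diagonal) and
covariate multipliers of power form $(x/x_{\mathrm{ref}})^{c}$ or
proportional form $1 + c(x - x_{\mathrm{ref}})$. Residual error is the
combined model $g = a + b f$.

The bundled defaults (`inst/models/*.yml`, editable without touching code)
follow the structure used in first-dose ICU analyses: meropenem is a
two-compartment model with Cockcroft-Gault CrCL and age as power covariates
on CL and body weight on V1; piperacillin is a covariate-free
two-compartment model with wider between-subject variability. The numeric
values are package defaults calibrated so that the default synthetic cohort
reproduces the observable first-dose exposure pattern of a general ICU
population: median meropenem Cmax near 57 mg/L after a 1 g / 0.5 h load and
trough near 2.7 mg/L on 1 g q8h; median piperacillin Cmax near 230 mg/L
after 4 g and trough near 29 mg/L on 4 g q6h; terminal half-lives around
1.4 h (meropenem, normal-to-high eGFR) to ~2-3 h (reduced eGFR). All tests
are parameter-agnostic: they assert structural and statistical properties,
not specific typical values, so users can substitute any published model
through the configuration file.

## MAP Bayesian estimation

For each patient the conditional (posterior) log-density of $\eta$ given
the population prior and the observations is

$$\log p(\eta \mid y) = \sum_j \log\phi\!\big(y_j;\, f(t_j;\eta),\,
  g(f)\big) + \log\phi(\eta;\, 0,\, \Omega) + \mathrm{const},$$

and the estimator is its mode (`map_fit()`), found by derivative-free
Nelder-Mead descent followed by a BFGS polish, multi-started from
$\eta = 0$ and $\pm 1$ prior SD on each coordinate. With no usable
observations the mode is exactly $\eta = 0$ (the covariate-adjusted typical
subject). A random-walk Metropolis-Hastings sampler
(`conditional_mode_mh()`) targeting the same conditional distribution is
kept as a stochastic cross-check: its proposal scale adapts toward ~30%
acceptance during burn-in and anneals downward over the final third of the
chain so that the best state visited converges on the mode; the two
estimators agree in objective value to within 0.1 on sparse-data fits.

Observations below the 0.1 mg/L quantification limit are excluded with a
warning rather than treated by a censored likelihood: at the doses studied
no BLQ samples are expected within the first interval, and the exclusion is
logged so that it can never pass silently.

## Exposure metrics

MIC targets are EUCAST epidemiological cut-offs for *P. aeruginosa*:
2 mg/L for meropenem (protein binding negligible, $f_u = 1$) and 16 mg/L
for piperacillin with assumed 20% binding, giving the 20 mg/L total
target via $\mathrm{threshold} = m \cdot \mathrm{MIC}/f_u$ ($m = 1$ or 4).
%fT>MIC is computed on the total-concentration profile against this
adjusted threshold, which is mathematically identical to comparing the free
concentration against $m \cdot \mathrm{MIC}$ under constant binding.

Threshold crossings are bracketed on a fine grid within each inter-knot
segment of the profile and refined by root finding to $10^{-7}$ h; the
measure of time above the threshold is then assembled exactly from the
crossing times. The 24 h window assumes the maintenance regimen continues
unchanged.

One numerical subtlety is documented rather than hidden: the profile starts
at $C(0) = 0$, so a short sub-threshold ramp (typically 0.01-0.03 h while
the loading infusion runs up) always exists and the literal measure is
below 100% even for clear attainers — the conventional "100% fT>MIC"
labels are integer-rounded. The package therefore defines first-interval
attainment by the trough rule — `predicted_trough() > threshold`, which is
also the clinical equivalence used for observed troughs (strict inequality;
a trough of exactly 2.0/20.0 mg/L is non-attained) — and the test suite
asserts the equivalence "trough above threshold $\iff$ no sub-threshold
excursion after the initial up-crossing" on randomly drawn patients.

Cmin/Cmax ratios are dose-normalised to reference doses (1 g meropenem,
4 g piperacillin): Cmax reflects the loading dose and Cmin the maintenance
dose, so each is scaled by its own dose before the ratio is formed; with
equal amounts this is plain Cmin/Cmax.

## Cohort statistics

Group comparisons use the exact two-sided Wilcoxon rank-sum distribution
(through `stats::wilcox.test`) for combined $n \le 25$ without ties, and
the tie-corrected normal approximation otherwise, with Hodges-Lehmann shift
estimates and exact-inversion 95% confidence intervals. The test suite
validates the exact p-values against full enumeration of all two-group
partitions up to combined $n = 8$.

ROC analysis treats a *low* Cmin/Cmax ratio as the positive (ARC) call:
candidate cutoffs are midpoints between adjacent sorted unique ratios, and
the reported cutoff maximises Youden's $J$; ties are broken toward higher
specificity, then the smaller cutoff (the underlying study reported only
"optimal cut-offs according to ROC analysis", so the criterion and
tie-breaks had to be fixed here — Youden's $J$ is the standard default).
The ECDF-based cumulative distribution analysis locates the maximal
vertical distance between the per-group ECDFs, which coincides with the
Youden cutoff for this construction.

## Synthetic cohort generator

The generator emulates the study conditions at their reported anchors:

* **Covariates** per drug arm: truncated-normal age and height,
  log-normal weight and creatinine, with medians/IQRs anchored to the
  study's characteristics tables (e.g. meropenem arm: age 58 (46-69) y,
  weight 83 (68-94) kg, creatinine 58 (46-78) umol/L); IQR widths are
  converted to scales via $\mathrm{SD} = \mathrm{IQR}/(2 \Phi^{-1}(0.75))$
  on the natural or log scale as appropriate. Sex (73% male), trauma
  admission (41%/17%) and an integer SOFA draw complete the record.
  Covariates are drawn independently (the source tables carry no joint
  distributions) except for the renal linkage below.
* **Regimens** from the reported mixes: meropenem 1+1 g q8h (50%),
  2+2 g (27%), 1+2 g (14%), 0.5+1 g (9%), all q8h; piperacillin 4+4 g q6h
  (71%), q8h (19%), and a 2+2 g q12h "other" stratum (10%) standing in for
  the heterogeneous reduced-dose regimens.
* **Sampling schedule**: end of loading dose (0.5 h), uniform in the last
  15 min of the extended infusion, and a trough at the interval end plus
  truncated-normal timing jitter (SD 0.25 h, truncated at the observed
  extreme band of +/- 1 h; the default SD puts ~95% of troughs within
  +/- 0.5 h, consistent with the reported 82%). Actual times are recorded
  — a late trough deliberately reads into the next infusion, reproducing
  the mistimed-sample discordance the model-based trough corrects.
* **Noise**: $y = f(1 + b\varepsilon_2) + a\varepsilon_1$ with the model's
  residual coefficients; non-positive draws are resampled and values below
  0.1 mg/L are flagged BLQ.
* **ARC linkage**: the meropenem model links clearance to CrCL through its
  covariate; the covariate-free piperacillin model is given a configurable
  correlation (default 0.6) between $\eta_{CL}$ and the patient's
  standardised log-CrCL, so that the eGFR-trough association and the
  ARC-ratio separation emerge in synthetic data too. An optional
  `arc_fraction` steers ARC prevalence by covariate resampling.

What the generator does *not* emulate: joint covariate correlations beyond
the renal linkage, within-patient creatinine dynamics, renal replacement
therapy (excluded in the study design), infusion-rate deviations, or any
link between exposure and outcome. Passing tests on synthetic cohorts
therefore validate the computational pipeline under the assumed
data-generating model, not the clinical conclusions on real patients.

## Numerical and design choices

* Creatinine is stored in umol/L and converted with the factor 88.42
  umol/L per mg/dL; Cockcroft-Gault uses actual body weight.
* The ARC score awards 6 points for age <= 50 y, 3 for trauma admission,
  1 for SOFA <= 4 (maximum 10); suspected ARC is CrCL > 130 mL/min or
  CrCL > 90 mL/min with a score > 6.
* eGFR grouping splits at 90 mL/min/1.73 m^2 (">90" vs "<=90").
* KDIGO baseline creatinine defaults to the earliest available value.
* Profile knots (infusion starts/ends) are inserted into every evaluation
  grid exactly; crossing times are refined to well below the 1e-4 h
  contract.
* Optimisation tolerances: `optim` relative tolerance 1e-10, multi-start
  as described; non-convergence from all starts is reported explicitly and
  such patients are counted and excluded from model-based summaries, never
  dropped silently.
* Problem sizes in the shipped test-suite: 100 random parameter/regimen
  draws for the ODE-oracle contract, 200 simulated patients for the
  sparse-design recovery study, 500 for the attainment-equivalence
  property, 70 (22 + 48) for the end-to-end reproducibility run — sizes
  chosen to exercise the pipeline at the study's own scale.

## Known limitations

* The shipped model parameter values are calibrated defaults, not
  estimates from patient data; any serious application should substitute a
  published, externally evaluated population model via the configuration
  file.
* BLQ handling is exclusion, not censored likelihood.
* $\Omega$ is diagonal; correlated random effects are not supported.
* The MH sampler is a cross-check of the mode, not a posterior-uncertainty
  engine; no credible intervals are reported.
* Tazobactam, three-compartment kinetics, nonlinear clearance and renal
  replacement therapy are out of scope.
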