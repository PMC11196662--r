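---
title: "Modelling abnormal body temperature probability in dairy cattle"
author: "abtp package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling abnormal body temperature probability in dairy cattle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical methods: the
models, their assumptions, the tunable parameters, what the synthetic
herd generator does and does not emulate, and the numerical and design
choices that were genuinely open.

## The problem

Dairy cattle under combined heat and humidity load show elevated body
temperatures, with welfare and production consequences. The package
models the probability that an animal's body temperature is *abnormal*
(above a reference level) as a smooth, monotone function of a single
quantitative heat-stress factor. The default factor is the
temperature–humidity index,

$$\mathrm{THI} = (1.8\,T + 32) - (0.55 - 0.0055\,RH)(1.8\,T - 26),$$

with $T$ in °C and $RH$ in percent. Two closed-form anchors are useful
for sanity checks and are exercised in the tests: at $RH = 100$ the
humidity correction vanishes (THI is the Fahrenheit temperature), and
at $T = 26/1.8$ °C the index is 58 regardless of humidity. THI is
strictly increasing in $T$ everywhere on $RH \in [0, 100]$ and
increasing in $RH$ whenever $T > 26/1.8$.

## The four ABTP curve families

All four families are two-parameter sigmoids in the factor $n$, with a
location $T\!n_{50}$ — the factor value at 50 % probability — and one
shape parameter:

* **LKB (probit)**: $P = \Phi(u)$, $u = (n - T\!n_{50}) / (m\,T\!n_{50})$.
  The shape $m$ is a *relative* width: the transition spans roughly
  $\pm 2 m\,T\!n_{50}$ around the location.
* **Logistic**: $P = 1/(1 + e^{-(\beta_0 + \beta_1 n)})$, with
  $T\!n_{50} = -\beta_0/\beta_1$. For display the package also derives
  the normalised slope at the midpoint, $\gamma_{50} = \beta_1\,
  \mathrm{TT}_{50}/4$.
* **Schultheiss (log-logistic)**: $P = 1/(1 + (T\!n_{50}/n)^k)$,
  defined for $n > 0$; computed as a logistic in $\log n$ for
  numerical stability.
* **Poisson tolerance curve**: $P = 2^{-\exp(e\,\gamma\,(1 - n/T\!n_{50}))}$.
  The constant $e$ is used at full machine precision, not a truncated
  decimal: only then does the curve pass through exactly $2^{-1} = 1/2$
  at $n = T\!n_{50}$, which is what defines the location parameter.
  This identity — each family passes through exactly 1/2 at its
  $T\!n_{50}$ — is enforced by tests across random parameter draws.

Fitting maximises the Bernoulli log-likelihood
$\sum_i y_i \log p_i + (1 - y_i)\log(1 - p_i)$ over the two free
parameters. The assumptions are the usual ones for univariate
dose-response work: independent animals, a correctly measured factor,
and monotone response; no covariates beyond the single factor are
fitted, because the workflow first *selects* that factor explicitly.

### Optimisation and numerical choices

The optimiser is deliberately deterministic: a $50 \times 50$ coarse
grid — location over the observed factor range, shape log-spaced over a
documented box ($m \in [0.005, 2]$, $\beta_1 \in [0.005, 5]$,
$k \in [0.1, 200]$, $\gamma \in [0.05, 20]$) — followed by Nelder–Mead
refinement from the best grid point (relative tolerance $10^{-8}$ on
the log-likelihood). The refined optimum is never accepted if it falls
below the best grid value, so the reported log-likelihood is
monotonically at least the grid search's, a property the tests assert.
Probabilities are clipped to $[\varepsilon, 1-\varepsilon]$ with
$\varepsilon = 10^{-12}$ before logs; the clipping constant is an
exposed argument. On separable data (a noiseless step in the factor)
the likelihood pushes the shape to the steep edge of its box; the LKB
slope then sits at the documented lower bound $m = 0.005$ rather than
diverging — degenerate data are reported, not chased.

Quantile inversion (`abtp_ttq()`) uses closed forms for LKB
($T\!n_{50}(1 + m\,\Phi^{-1}(q))$, with an explicit error when
$1 + m\,\Phi^{-1}(q) \le 0$), logistic and Schultheiss, and bracketed
root-finding for the Poisson curve; round-trips are tested to
$10^{-6}$.

## Labelling and triage

The binary outcome defaults to a one-sided rule: an animal is abnormal
when its eye-socket temperature strictly exceeds the dataset mean
(configurable offset, or a fixed threshold instead). One-sided and
upward because heat stress elevates temperature; whether a two-sided
deviation or an offset would be preferable is a genuinely open choice,
so both reference and offset are exposed in `label_rule()`.

Triage bands are constructed, not free parameters: the observation
ceiling is the critical temperature inflated by the thermal imager's
relative accuracy, `round(normal_below * (1 + instrument_margin), 2)`;
with the defaults 38.32 °C and 2 % this gives 39.09 °C. Both band
boundaries are inclusive on the hotter side, and the environmental
alert fires strictly above THI 75.

## The synthetic herd generator

The generator exists so every downstream stage is testable without any
data download. It emulates the *marginal* structure of a 320-animal
study herd: eye-socket temperature 38.3 ± 1.40 °C, air temperature
25.13 ± 4.55 °C, relative humidity 83.79 ± 7.90 %, age 49 ± 27 months,
days in milk 194 ± 132, parity 2 ± 1, body weight 599.76 ± 81.07 kg,
milk yield 22.27 ± 6.87 l. Choices where the joint structure was
unspecified:

* Gaussian marginals throughout; humidity truncated to $[0, 100]$;
  age, days in milk and parity truncated at zero and rounded to
  integers.
* One explicit dependence: air temperature and humidity are drawn from
  a bivariate Gaussian with correlation $-0.3$ (typical diurnal
  anticorrelation); all other variables are independent. THI is never
  drawn — it is computed from the generated temperature and humidity,
  and the implied THI distribution lands close to the reported
  75.37 ± 7.11 (a first-order variance propagation with the default
  correlation gives an SD near 7.2).
* Eye temperature follows a piecewise-linear "knee" response to THI:
  baseline 38.1 °C (the reported farm-average orbital temperature),
  flat below THI 70 (orbital temperatures are reported to rise sharply
  above that level), slope 0.032 °C per THI unit above it, plus
  Gaussian noise with SD 1.39 °C. The slope and noise are *calibrated,
  not free*: with the baseline and knee fixed, matching the marginal
  eye-temperature mean of 38.3 pins the slope near 0.032
  (E[(THI−70)⁺] ≈ 6.3 under the default THI distribution), and
  matching the marginal SD of 1.40 then pins the noise SD near 1.39.

Two consequences of this calibration are worth stating plainly,
because they bound what passing tests show about real data. First,
the THI→eye-temperature signal (SD ≈ 0.19 °C) is small relative to the
noise (1.39 °C), so mean-rule labels on the default herd are
noise-dominated and the in-sample discrimination of the fitted curves
is modest; published discrimination figures on the real herd are
substantially higher, which the marginal moments alone cannot
reproduce — presumably the real labels reflect tighter within-period
coupling than independent Gaussian noise. Second, THI and air
temperature are ~0.99 correlated by construction, so at $n = 320$ the
*first-entry* variable between the two in a LASSO path is genuinely
noise-dominated; ranking experiments that want attributable importance
must decouple the companion factors (the tests permute them),
and on the correlated herd the top-ranked factor varies by seed. The
pipeline follows the data-driven ranking and reports a stage-named
error if a selected factor is outside a family's domain (e.g. zeros
under a log-scale family).

The generator does *not* emulate: repeated measures or diurnal cycles
(rows are independent animals), seasonal structure, instrument error
beyond the noise term, or any breed/farm heterogeneity.

A second labelling mode, `bernoulli_direct`, draws outcomes from a
*known* ABTP curve evaluated at the generated THI. This is the
ground-truth mode used for parameter-recovery experiments: with a
logistic truth whose 50 % point is THI 75 ($\beta_0 = -22.5$,
$\beta_1 = 0.30$), the mean fitted TT50 over 100 herd-sized replicates
recovers 75 within one THI unit (this is what `scripts/acceptance.R`
recomputes).

## LASSO factor ranking

The eight candidate factors are standardised to zero mean and unit
variance and an L1-penalised binomial path is fitted over 100
log-spaced penalties from $\lambda_{max}$ (empty support) down to
$\lambda_{max}/10^4$ — the conventional grid. Importance is the *entry
order* along the path (the penalty at which a coefficient first
becomes non-zero), which matches the coefficient-convergence reading
of such paths; ties are broken by coefficient magnitude at the
selected penalty, then by column order. The penalty is selected by
stratified K-fold cross-validation of binomial deviance with an
explicit fold loop (which also permits the 2-fold case) under a fixed
seed. Standardisation and the selection rule are exposed because
neither is forced by the method. On orthonormal designs the
single-penalty solution must equal analytic soft-thresholding of the
unpenalised estimates; the tests verify this equivalence, which
guards the entire path machinery.

## The effective-index model

The effective-index model couples the factor with body temperature
through a power law: the tolerated factor level declines with body
temperature as $T\!n_{50}(temp) = T\!n_{50}(1)\,temp^{-c}$, $c > 0$,
and an observed factor value $n_i$ maps the observed temperature onto
an effective temperature $Temp_{e\!f\!f} = Temp_i\,(n_i/n_{ref})^{-c}$
(exactly the identity when $n_i = n_{ref}$). The abnormality
probability is the LKB probit

$$u = \frac{\nu - T\!n_{50}(1)\,Temp_{e\!f\!f}^{-c}}
           {m\,T\!n_{50}(1)\,Temp_{e\!f\!f}^{-c}},$$

with the numerator term $\nu$ configurable: `"reference"` uses
$n_{ref}$ (the form implemented by default), `"observed"` uses $n_i$
(the standard radiotherapy-style form). The distinction matters: with
the reference numerator the surface *decreases* in the factor at fixed
temperature, whereas the observed numerator gives the orientation
under which probability rises with the factor and the 20 % contour
lies at lower THI than the 50 % one — the orientation a heat-stress
triage chart displays. Both variants are implemented and tested; the
default is the reference form, and contour-orientation properties are
tested under the monotone (observed) variant.

$n_{ref}$ defaults to the mean observed factor (the herd-mean
condition); it is an exposed argument since no canonical reference
exists.

### Estimation and the identifiability of $c$

$(T\!n_{50}(1), c, m)$ are estimated by joint MLE with the same
grid-then-Nelder–Mead scheme, but internally the location is
reparameterised as $t_{50,ref} = T\!n_{50}(1)\,temp_{ref}^{-c}$ — the
50 % level *at the mean body temperature* — because $T\!n_{50}(1)$
itself is an extrapolation to 1 °C and any error in $c$ is amplified
into it by a factor $\ln temp_{ref} \approx 3.6$. That amplification
also drives the design of the recovery experiment: with weakly curved
truths (small $c$) the three parameters are not separately
identifiable at realistic sample sizes, because the likelihood only
constrains $t_{50,ref}$ and the ratio $c/m$. The recovery tests
therefore use a deliberately informative synthetic design — truth
$c = 0.8$, $m = 0.04$, $T\!n_{50}(1) = 75 \cdot 38.3^{0.8}$,
$n_{ref} = 75$, THI uniform on [55, 95] and body temperature uniform
on [33, 45], $n = 5000$ — chosen by a design-stage power analysis so
that each parameter is recoverable within 10 % relative error in the
large majority of replicates. This is a statement about the
*estimator* under an identifiable design, not about typical field
data, where body temperatures span a far narrower range and $c$ would
be correspondingly harder to pin down.

Iso-probability contours are found per temperature grid point by
bracketed root-finding on the factor axis (tolerance $10^{-8}$);
points where the level is unreachable inside the bracket are flagged
per point rather than failing the whole contour. Contour round-trips
(re-evaluating the surface on the returned polyline) are tested to
$10^{-6}$, and contours for different levels cannot cross because the
surface is monotone in the factor for either numerator convention.

One caveat the pipeline inherits: when labels are *derived from* the
same eye temperature that enters the effective-index model as a
covariate (the annual-mean rule), outcome and covariate are
deterministically linked, the likelihood favours a step-like surface
and the slope $m$ runs to the steep edge of its search box. That is
the correct MLE for such data, but parameter values from that regime
should not be interpreted physiologically.

## Model evaluation

The comparison battery reports, per model: AUC as Mann–Whitney
concordance with ties credited 1/2 and an analytic DeLong 95 % CI
(deterministic, unlike a bootstrap); accuracy with the strict
`p > 0.5` convention; AIC $= 2k - 2\ell$ with $k = 2$ for every
family, and ΔAIC against the LKB baseline (rendered as a dash for the
baseline itself); the Brier score; the Hosmer–Lemeshow test; and a
calibration curve summarised by a count-weighted least-squares slope
and intercept plus the weighted correlation between bin-observed and
bin-predicted rates. A single published scalar "calibration" value has
no stated definition, so the package reports all three summaries
rather than guessing.

Hosmer–Lemeshow uses 10 equal-frequency bins (stable under ties) and
$\chi^2 = \sum_g (O_g - E_g)^2 / (E_g(1 - E_g/n_g))$ on
$\text{bins} - 2$ degrees of freedom — the convention for probabilities
fitted on the same data. Two subtleties are documented because they
are easy to trip over. First, degenerate bins (expected count 0 or
$n_g$) are merged into a neighbour with a message, and fewer than
three usable bins is an explicit error (degrees of freedom would
vanish). Second, the $\text{bins}-2$ convention applied to *external*
probabilities (not fitted to the data at hand) is mildly
anti-conservative — the statistic then behaves like $\chi^2$ on
roughly `bins` degrees of freedom, so the null rejection rate at the
0.05 level is nearer 10 % than 5 %. Within this package probabilities
are always fitted, which is the regime the convention matches; the
tests exercise both regimes.

The evaluation is in-sample, matching how such comparison tables are
usually produced for these models; no cross-validated performance
estimation or threshold optimisation is attempted.

## Reproducibility and problem sizes

Everything stochastic flows from explicit integer seeds: the herd
generator, label simulation, fold assignment, and the pipeline's
single global seed, which determines every output byte (artifacts are
stamped with a config hash and the seed). The simulation sizes used by
the test suite and the acceptance script — herds of 320 (the study
scale), recovery experiments at 5000, and 100-replicate batteries —
were chosen so the relevant sampling distributions are tight enough
for the stated tolerances while the whole suite stays comfortably
fast on a single CPU.

## Known limitations

* Rows are independent animals; no repeated-measures or temporal
  correlation structure is modelled or generated.
* Only the one THI formula is implemented; the literature has several.
* The marginal-moment calibration of the generator cannot reproduce
  published discrimination levels on the real herd (see above); tests
  against the generator validate the machinery, not field performance.
* The effective-index exponent $c$ is weakly identified on narrow
  body-temperature ranges; treat fitted values on field-like data as
  descriptive.
* The four families are compared in-sample; AIC differences of a few
  units should be read as "indistinguishable", which is also the
  expected outcome when all four sigmoids approximate the same
  underlying response.
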