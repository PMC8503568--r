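---
title: "Spectral DCM and hierarchical group inference: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral DCM and hierarchical group inference: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spdcmr)
```

## The scientific problem

Resting-state fMRI correlations between a subcortical component (basal
ganglia and thalamus) and the primary sensory cortices are elevated in
autism spectrum disorder (ASD). Correlation is symmetric, so it cannot say
whether this reflects a stronger bottom-up drive of sensory cortex by
subcortical activity, a stronger top-down modulation, or reduced
self-inhibition (functional segregation) of the regions involved. This
package estimates those *directed* quantities with a spectral dynamic
causal model (spDCM) of a five-region hub-and-spoke network — one
subcortical hub (`SubC`) plus ventral and dorsal somatosensory (`vS1`,
`dS1`), auditory (`A1`) and visual (`V1`) cortex — and then asks, with a
hierarchical Bayesian model over subjects, how age, diagnostic group,
their interaction, head motion and acquisition site shape each
connection, and how connection strengths relate to symptom severity
(total SRS score).

## The generative model

Latent neuronal activity obeys a linear stochastic differential equation

$$\dot x(t) = A\,x(t) + v(t),$$

where the coupling matrix $A$ (units: Hz) is constrained hub-and-spoke:
$2(R-1)$ off-diagonal couplings (bottom-up `SubC -> cortex`, top-down
`cortex -> SubC`) and $R$ self-connections; direct cortico-cortical
connections between primary sensory areas are anatomically implausible
and are fixed at zero, which also reduces the number of estimated
parameters (13 coupling parameters at $R = 5$). Diagonal entries are
parameterized as $A_{rr} = -\tfrac12 e^{s_r}$, so a *positive* self
parameter $s_r$ means *stronger* self-inhibition, i.e. greater functional
segregation of that region.

Neuronal fluctuations $v$ and observation noise have power-law spectra
$\alpha\,\omega^{-\beta}$ with log-amplitude parameters and exponents
constrained to $(0, 2)$ by a scaled logistic; one $(\alpha, \beta)$ pair
is shared across regions for each noise source. Each region's BOLD
response is a linearized two-pole hemodynamic kernel

$$h_r(\omega) = \frac{\kappa_r}{(i\omega + \kappa_r)(i\omega + \gamma_r)},
\qquad \kappa_r = 0.64\,e^{d_r},\ \gamma_r = 0.32\,e^{t_r},$$

a low-pass surrogate for the nonlinear balloon model with two free
log-scales per region. Note that $\gamma_r$ sets the low-frequency gain
($|h_r(0)| = 1/\gamma_r$), which is what lets the model absorb moderate
region-to-region amplitude differences. The predicted cross-spectral
density at frequency $f$ ($\omega = 2\pi f$) is

$$S(f) = H(\omega)\,T(\omega)\,G_v(\omega)\,T^*(\omega)\,H^*(\omega)
       + \alpha_e\,\omega^{-\beta_e} I,
\qquad T(\omega) = (i\omega I - A)^{-1}.$$

Because subjects' spectra are estimated from *sampled* series, the
fitted feature map folds alias images at multiples of the sampling rate,
$S_\mathrm{obs}(f) = \sum_k S(f + k/\mathrm{TR})$ (`predict_csd_sampled()`,
two images per side by default). Without folding, prediction errors
concentrate near the Nyquist edge and bias the couplings; with it, the
analytic spectrum matches Welch estimates of long simulations across the
whole grid (the acceptance suite checks 10% relative error).

## Data features

Each subject's series is detrended (linear by default) and rescaled by
one *global* factor (the geometric mean of the region SDs). Per-region
unit-variance scaling is available (`standardize_series(scale =
"column")`) but is not used in the fitting path: rescaling region $j$ by
its own SD transforms the effective coupling matrix as $D A D^{-1}$ and
therefore distorts the couplings the data reflect, while a shared factor
leaves them untouched. The spectra themselves come from a
ridge-regularized multivariate autoregression (`fit_mar()`, default
order 8 for scan-length data; validation studies on long synthetic
series use order 16–24) evaluated on 32 linearly spaced frequencies in
$[1/128, 0.25]$ Hz — the resting-state BOLD band, bounded away from zero
so power-law forms stay finite. A Hann-tapered Welch estimator
(`csd_welch()`) serves as an independent nonparametric check; it is never
part of the fitting path. Before inversion the data spectra are rescaled
once so their mean diagonal power matches the prior-mean model
(`scale_data = TRUE`): the tight log-amplitude priors below presume this
common scale, and the factor does not touch the coupling parameters.

## Inversion

`invert_subject()` implements a variational-Laplace scheme: Gauss-Newton
ascent on the free energy $F$ (accuracy minus KL complexity) with
Levenberg-Marquardt damping (initial 1/32, doubled on rejection, halved
on acceptance), central finite-difference Jacobians (step $10^{-4}$), and
joint Newton updates of one residual log-precision per region-pair data
mode (prior $\mathcal N(0, 1)$). Steps are accepted only if $F$ does not
decrease and the implied $A$ stays stable; convergence requires
$|\Delta F| < 10^{-2}$ nats on three consecutive accepted steps (cap 128
iterations). Non-convergence is flagged, never used to exclude a
subject. Priors are weakly informative diagonal Gaussians centred at
zero: couplings $\mathcal N(0, 1/16)$ Hz$^2$, self and noise log-scales
$\mathcal N(0, 1/64)$, hemodynamic log-scales $\mathcal N(0, 1/256)$ —
so a priori the network sits near its leak-dominated default
$A = -\tfrac12 I$. These variances were validated by the recovery
studies below, not fitted to any particular dataset.

## Hierarchical group model

With first-level posteriors $\mathcal N(m_i, C_i)$ over the coupling
block, the second level is the empirical-Bayes GLM
$\theta_i = X_i \beta + \varepsilon_i$: each $m_i$ is a noisy observation
of $\theta_i$ with covariance $C_i$ (first-level uncertainty propagates),
$\varepsilon_i$ has isotropic precision $e^\lambda$ with
$\lambda \sim \mathcal N(0,1)$, and $\beta \sim \mathcal N(0, 1/16)$
per entry. $\lambda$ is profiled by one-dimensional free-energy
maximization; $\beta$'s Gaussian posterior is then exact.

The design codes age z-scored, group as ASD $= +0.5$ / TD $= -0.5$ (so
the interaction column reads as the ASD-minus-TD difference in age
slope), their product, z-scored mean framewise displacement, and —
optionally — centred site dummies (one fewer than the number of sites,
reference = most populous site). A second design models age separately
within each group (`build_within_group_age_design()`), and a third
variant replaces group by SRS for the symptom stage.

Nested models that switch off subsets of (connection x covariate)
effects are scored by Bayesian model reduction — the closed-form
Gaussian identity, exact to numerical precision against conjugate
refits — and averaged: model weights are the softmax of log evidences,
an effect's posterior probability is the summed weight of models that
retain it, and its moments are those of the spike-and-slab mixture. The
search prunes in waves (all evidence-favoured removals per sweep, with a
best-single fallback) and then enumerates the $2^{\min(8, n)}$
neighbourhood of the most evidence-ambiguous effects; exhaustive
enumeration exists for small spaces and agrees with the search on toys.
An effect is *significant* when its posterior probability exceeds 0.90,
a *trend* in $(0.80, 0.90]$ (the trend band is a reporting convention of
this package), *null* otherwise. Two summaries are reported side by
side: `effect_mean`/`effect_sd` are moments of the full spike-and-slab
mixture (the shrinkage display, where pruned effects pull toward zero),
while the 90% credible interval is mean $\pm\,1.6449\,$sd of the
*conditional* average over the models that retain the effect — the
error bar of the estimated effect given that it exists, which is what
zero-crossing is read against. For a retained, well-supported effect
this interval excludes zero; the probability rule is primary, and the
mutual consistency of rule, interval and retention probability is
asserted on every computed report row rather than assumed, because for
marginally retained effects the equivalence is not a logical necessity.

## Site confounds

When mean age differs across sites, raw site dummies and age compete for
shared variance: the age effect keeps only its unique part, standard
errors inflate, and true effects can drop below the 0.90 rule. Site
handling is therefore a first-class, three-valued choice (`none`,
`dummies`, `orthogonalized`) reported side by side. Orthogonalized mode
residualizes each dummy on the span of the age regressors and the
previously processed dummies: the design's column span — hence fitted
values — is unchanged (projection matrices agree to $10^{-10}$), only
the attribution of shared variance moves back to age. The synthetic
generator reproduces the situation on demand
(`make_confounded_sites(spec, severity)`): severity 0 makes sites
exchangeable; severity 1 (site mean-age offsets spanning $\pm 4$ years)
makes a one-way age-on-site ANOVA significant at $p < 0.001$ at the
default cohort size; the validation studies use severity 2 with
realistic short-scan first-level noise so the age effect sits near the
decision threshold, where the collinearity cost is visible.

## Symptom association

The two-step route fits, per connection, a linear mixed model of the
posterior-mean strength on z-scored SRS, age, their interaction and mean
FD with a site random intercept, estimated by REML with the variance
ratio profiled in one dimension (site-block structure gives closed-form
determinants). Wald t tests use between-within denominator degrees of
freedom; p-values are Benjamini-Hochberg adjusted across connections
within each term (the FDR family, documented in the output). Subjects
without SRS are excluded from this stage only. Because the two-step
route ignores first-level uncertainty, a PEB variant with design
[mean, SRS, age, SRS x age, FD, site dummies] runs alongside
(`peb_srs_interaction()`). For presentation, subjects are stratified at
the mean $\pm 1$ SD of the analysed subsample's SRS (boundaries
inclusive to mid); stratification is never used for inference.

## The synthetic cohort generator

`cohort_spec()` defaults emulate the study conditions: 166 ASD + 193 TD
over 8 sites; ages 17.6 (7.6) years in [7, 50] (ASD) and 16.9 (6.6) in
[6.5, 39.4] (TD) with site-dependent mean age; lognormal mean FD
(median 0.12 mm) that multiplies observation noise ($1 + 0.5\,$FD),
making the motion nuisance column genuinely necessary; SRS drawn per
group (ASD 89.4 (32.4), TD 22.2 (18.1)) and observed for 67% / 56% of
subjects. The default ground-truth effects follow the qualitative
findings the pipeline is meant to recover: per SD of age,
self-inhibition rises (+0.10 in TD) and bottom-up coupling falls
(-0.08 in TD), both attenuated to 25% in ASD; baseline couplings are
+0.20 Hz bottom-up and +0.10 Hz top-down with 0.05 Hz between-subject
SD, resampled under a stability check. BOLD is generated by Euler
integration of the latent SDE at dt = TR/16 with power-law-filtered
Gaussian input, convolved with the prior-mean hemodynamic kernel,
downsampled to the TR, with white observation noise at 25% of signal SD
and a 60 s burn-in discarded.

What the generator does *not* emulate: spatial structure, scanner
drifts beyond polynomial trends, spike artifacts, non-Gaussian noise,
inter-regional hemodynamic delays, or any task structure. Passing the
validation studies therefore shows that the estimation machinery is
correct and calibrated under the model's own assumptions — not that
those assumptions hold in any particular empirical dataset.

## Problem sizes for validation, and what short scans can support

The package's validation studies run at reduced network size and
deliberately *long* synthetic acquisitions:

* single-subject recovery: 3 regions, couplings up to $\pm0.4$ Hz,
  4096 volumes at TR 2 s, MAR order 24, 20 seeds — pooled truth-estimate
  correlation $\ge 0.7$ and median absolute error $\le 0.1$ Hz;
* hierarchical recovery: 4 regions, N = 120 (60 per group, 4 sites),
  4096 volumes, a true age-by-group interaction of 0.1 Hz/SD on the
  bottom-up couplings (TD slope $-0.125$/SD, ASD attenuated to
  $-0.025$/SD), 10 replicate cohorts;
* end-to-end recovery: one N = 120 three-region cohort under the
  default generator truths at 8192 volumes (MAR order 32), where
  first-level error is subdominant — subject-level coupling correlation
  $\ge 0.7$ and recovery of all group-level age-effect signs;
* calibration and site-confound studies draw first-level posteriors
  directly around the ground truth (`simulate_first_level_posteriors()`),
  isolating the design/reduction machinery from first-level cost.

The long acquisitions are a deliberate design choice, not an oversight.
At typical resting-state scan lengths (about 200 volumes) the
first-level posterior error of this MAR-feature route is roughly
0.15–0.25 Hz per coupling — several times the 0.05 Hz between-subject
variation of the default cohorts — so a 0.1 Hz/SD interaction is below
the single-cohort detection floor regardless of how well the group
machinery works. Testing the hierarchy in that regime would measure
first-level noise, not the property under test. The flip side is a
genuine scientific caveat: at empirical scan lengths, group-level
findings lean heavily on the hierarchical shrinkage across hundreds of
subjects, and per-subject coupling estimates should not be interpreted
individually.

## Numerical choices and degenerate inputs

* Stability is enforced everywhere: candidate inversion steps with an
  unstable $A$ are rejected (damping doubles); the generator resamples
  subject noise up to 100 times before giving up with advice to reduce
  effect sizes.
* "Switched off" in model reduction means reduced prior variance
  $10^{-8}$ with mean zero; non-positive-definite reductions score
  $-\infty$ evidence and drop out of the average.
* The Welch and MAR estimators refuse series that cannot resolve the
  requested band; frequency grids truncate to $[1/(T\cdot TR),
  0.5/TR]$.
* Zero-variance regions, non-finite samples, duplicate ids, unknown
  group labels and rank-deficient designs are hard errors that name the
  offending region, coordinate, row or column.
* The mixed model profiles the variance ratio on $\log\phi \in
  [-12, 8]$ and checks the $\phi = 0$ boundary explicitly;
  `site_variance = "zero"` reproduces OLS exactly.
* All randomness descends from a single root seed; per-subject
  simulation seeds are derived arithmetically, kept below $2^{31}$, and
  re-running any stage with the same configuration is bit-reproducible.

## Known limitations

* Linear one-state neuronal dynamics and a linearized two-pole
  hemodynamic kernel; no bilinear (task-modulated) terms and no full
  balloon model.
* Shared power-law noise parameters across regions; per-region noise
  amplitudes are only absorbed indirectly.
* The estimator is consistent in scan length but materially biased at
  short scans; we quantify this rather than hide it (see above).
* P(M|Y) here is the BMA retention probability of an effect. An
  alternative reading — the posterior odds of a single with-vs-without
  comparison — would generally be more extreme; the retention
  probability is the more conservative convention and is the one that
  ties to the credible-interval rule.
* The trend band (0.80, 0.90] is a reporting convention; only the 0.90
  threshold carries inferential weight.
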