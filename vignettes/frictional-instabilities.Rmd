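---
title: "Classifying frictional instabilities and linking them to tactile discrimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying frictional instabilities and linking them to tactile discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frinstab)
```

## Overview

`frinstab` implements a pipeline for sliding-friction psychophysics: it
classifies tangential-force traces from a finger–surface rig into three
instability phenotypes, maps their frequency over an applied-mass by
driving-velocity grid, scores surface pairs by differential instability
frequency, computes competing surface descriptors from AFM height maps
and contact-angle tables, and fits mixed models of three-alternative
forced-choice (3-AFC) performance against those predictors. Because
instrument data are not bundled, every input has a first-class generator
whose statistical structure matches what the analysis assumes. This
vignette records the models, the tunable parameters, the numerical
choices, and the places where the design was genuinely open.

## The spring–block trace model

A pull is modelled as a single-degree-of-freedom spring–block system. A
block of effective mass $m$ (the finger pad plus applied mass, in kg) is
dragged through a spring of stiffness $k$ (default 13\,900 N/m, the
force-sensor/loading stiffness) by a stage moving at velocity $v$. The
measured force is the spring force $F = k(X - x)$, where $X$ is stage
position and $x$ block position. Friction combines two ingredients:

* **contact aging** — while the block is stuck its static threshold grows
  with the stationary-contact age $\theta$:
  $\mu_s = \mu_{k0} + \Delta\mu + b\,\log(1 + \theta/\theta_0)$, with
  $\theta$ initialised to the pre-slide dwell $t_0$ and reset to zero at
  every re-stick;
* **velocity weakening** — while sliding the kinetic coefficient decays
  with slip speed: $\mu(\dot x) = \mu_{k0} + \Delta\mu\,e^{-\dot x/v_c}$.

This is a deliberately minimal aging + weakening law rather than a full
rate-and-state formulation: it is the simplest model that spans all three
observed phenotypes, and the phenotypes — not the dynamics — are what the
downstream analysis consumes.

* $b = \Delta\mu = 0$ gives **steady sliding**: the force ramps at exactly
  $dF/dX = k$ (the block is stuck), slips at $\mu_{k0} N$ and settles
  there.
* Large $b$ with a long dwell ($t_0 = 2$ s, $\theta_0 = 10$ ms) and
  $\Delta\mu = 0$ gives a **stiction spike**: one large peak at onset
  (the template aims the first peak at 1.6× the steady force), then
  steady sliding.
* Large $\Delta\mu$ with $v_c = v$ and light damping sustains a
  stick-slip **limit cycle**: slow frictional waves. The force drop per
  cycle saturates near $2\Delta\mu N$, so the template chooses
  $\Delta\mu = k v / (2 N f_w)$ to put the reload (cycle) frequency at a
  target $f_w$.

Two physical details matter for realistic traces. First, the stage
accelerates linearly over `accel_time` (default 60 ms) before reaching
$v$, as a real motorised stage does; since slip typically starts while
the stage is still slow, this keeps the inertial overshoot at slip onset
small — with an instantaneous-velocity stage the overshoot
$\sim v\sqrt{km}$ would itself register as a spurious spike at high
velocity. Second, damping acts on the velocity of the block *relative to
the stage* (a viscoelastic pad), so it shapes transients without biasing
the steady-sliding force, which remains exactly $\mu_{k0} N$. The damping
ratio is a template property: steady sliding and stiction spikes are the
dissipative phenotypes (ratio 5), while slow waves require underdamping
(ratio 1) for the weakening instability to survive.

### Numerical scheme

Fixed-step semi-implicit Euler at `oversample` (default 10) times the
output rate of 550 Hz, with the damping term handled implicitly
(unconditionally stable at large ratios). The stuck→slip transition is
clamped to the exact threshold: the within-step force excess (up to
$k v\,dt$) is a discretisation artifact, so the block is placed exactly at
$x = X - \mu_s N / k$ when slip begins. The output is the spring force
decimated to 550 Hz plus Gaussian sensor noise (SD 0.013 N, chosen so
~3σ peak-to-peak matches the ~0.04 N electronic noise floor; the floor,
not the SD, is what an instrument datasheet quotes). A force magnitude
above $10^6$ N aborts with an integration error naming the parameter set.

### What the generator does and does not emulate

It reproduces: the loading ramp with slope $k$, the three phenotypes and
their coexistence (a spike followed by steady sliding or waves), the 4 mm
pull at each of 16 (mass, velocity) conditions with 9 retained pulls, and
sensor noise. It does not model fingerprint ridges, 2-D contact-area
evolution, or finite-element pad mechanics; and at 45 mm/s a 4 mm pull at
550 Hz is simply too short to resolve two sub-50 Hz wave cycles, so the
slow-wave guarantee holds for drive velocities up to 25 mm/s — faster
pulls realise as spike-type traces. Tests passing on these fixtures show
the pipeline's logic is correct under the stated assumptions; they do not
certify behaviour on real traces with drift, fouling, or non-stationary
noise.

## Trace classification

`detect_onset()` low-pass filters the force (zero-phase Butterworth,
cutoff the lower of 50 Hz and 10 cycles per drive duration, with
odd-reflection padding to suppress boundary transients) and returns the
first *prominent* local maximum — prominence at least the larger of twice
the noise floor and 5% of the filtered range. Monotone-to-plateau traces
(steady sliding) have no such maximum; the onset is then the first index
where the smoothed slope (5-sample moving average) falls below 10% of
$k v$, after the ramp has been seen at half that slope. If the sampling
cannot resolve the ramp at all (light loads at high velocity), onset
falls back to the first sample above half the plateau. A trace entirely
inside the noise floor raises a no-slide error.

`extract_features()` computes the first peak (raw maximum within
$w = 5$ samples of onset), the steady mean (mean beyond onset $+ 3w$),
and the slow-wave amplitude and count: the post-peak segment is
band-limited by FFT masking to frequencies below 50 Hz and above two
cycles per segment, and local maxima at least half the noise floor high
are counted, their mean height being the baseline-to-peak wave amplitude.
The friction coefficient is the steady mean divided by the normal force
$(M + 6\,\mathrm{g}) \times 9.81\,\mathrm{m/s^2}$. Segments shorter than
$3w$ past the onset window are a feature error.

`classify_trace()` applies the heuristic rules in a fixed order with ties
at exact equality going to the spike/wave: waves are present when at
least 2 peaks of mean amplitude at least twice the noise floor were
detected; a first peak at least 40% above the wave envelope level
(steady mean + wave amplitude) is a spike over waves; with no waves, a
first peak at least 10% above the steady mean is a spike over steady
sliding; otherwise the label is SFW or SS. Both spike branches
additionally require the peak's excess over its reference level to reach
the noise floor — at the lightest load, 10% of the steady force is below
electronic noise, and a "spike" smaller than noise carries no evidence.
Because the guard is expressed in noise-floor units, classification is
equivariant under joint rescaling of force and noise floor, and raising
the first peak alone can only move a label toward Sp.

Open points resolved here: the 40% rule's reference amplitude is not
uniquely determined by its verbal statement; we compare against the wave
envelope level (steady mean plus band-limited mean crest height). The
thresholds are configuration values (`classifier_thresholds()`) because
the scheme is explicitly heuristic. First pulls of each slide set are
flagged and excluded at ingest (contact aging from setup), matching the
protocol of collecting four slides and retaining three.

## Friction-coefficient summary

The average coefficient $\bar\mu$ is the mean of the 16 per-condition
means (each over its 9 retained pulls); the interquartile range is
Q3 − Q1 over all per-pull coefficients with the linear-interpolation
quantile definition (R type 7). The aggregation order is a design choice:
averaging conditions first keeps $\bar\mu$ balanced across the grid,
while the IQR over pulls captures the cross-condition spread of friction
on a single surface, which is the quantity of interest when arguing that
within-surface variability rivals between-surface differences.

## Phase maps and pair scores

`count_phases()` tallies primary labels per grid node (exactly 9 per
node, totals summing to 144) — coexisting spikes are recorded as a flag
on the trace, not double-counted, so these tallies are not directly
comparable to protocols that count a spike-over-waves trace in two
categories. `interpolate_map()` renders frequencies (count/9) by
bilinear interpolation on *linear* mass and velocity axes (tensor-product
1-D interpolation, exact at the nodes, bounded in [0, 1]).
`pair_difference()` takes, per label, the absolute difference of the two
surfaces' totals — not the sum of per-node absolute differences — as a
count of the 144 maximum pulls and as a percentage rounded to three
significant figures; the absolute value matches a discrimination task
blind to sample order.

## Surface descriptors

Height maps are flattened by least-squares removal of a full 2-D
polynomial of total degree 3 (10 monomials, coordinates scaled to
[−1, 1] for conditioning), then per-row (fast-scan line) median
subtraction — which also serves as the scan-line correction — and
recentring; aggregates are not masked. The operation is idempotent to
rounding error, and a constant map returns a zero map with a warning.
Ra is the mean absolute height and Rrms the rms height about the mean.

The Hurst exponent comes from the line-averaged 1-D power spectral
density: Hann-windowed periodograms of each fast-scan line are averaged,
and the log–log slope $\beta$ is fit over the central band, excluding the
lowest 3 wavenumber bins (flattening leaks there) and the highest 25%
(noise, pixelation, and the finite transverse bandwidth of line scans
steepen the spectrum there). For a self-affine profile the 1-D PSD scales
as $q^{-(1+2H)}$, so $H = (|\beta| - 1)/2$, clipped to [0, 1] with a flag
— white noise, for instance, clips to 0. A line-spectrum method was
chosen over a variogram because the AFM workflow is line-oriented and
because it is the exact inverse of the generator's spectral synthesis
(Fourier amplitudes $\propto |q|^{-(1+H)}$ in 2-D, random phases,
rescaled to an exact target rms), making generator/estimator consistency
a meaningful test. Fits need at least 8 usable bins. With 512² maps the
estimator recovers H ∈ {0.2, 0.5, 0.8} within ±0.1 across seeds; the
residual positive bias of a few hundredths comes from the truncated
transverse integration inherent in line scans.

Contact-angle hysteresis is per-droplet advancing minus receding, with
the mean advancing and receding angles, mean hysteresis and its sample SD
reported (typically 5 droplets). A droplet with receding above advancing
is physically suspect and is kept but flagged. Published tables in this
area sometimes print the two mean angles rather than their difference;
the summary therefore reports both means alongside the difference.

## Behavioural statistics

Trials are 3-AFC records (subject, pair, odd position, chosen position,
correctness recomputed from the positions, response time). Accuracy is
tested against the chance level 1/3 by a two-sided one-sample t-test per
pair, with a degenerate branch for zero-variance samples. Pairwise
comparisons use a two-sided Wilcoxon rank-sum on subject-level accuracies
with mid-ranks; for combined samples up to 20 the null distribution of
the rank sum is enumerated exactly over all assignments (valid under
ties), otherwise a normal approximation with tie and continuity
corrections is used. Subject-level (not trial-level) units were chosen
for the rank test because subjects, not trials, are exchangeable.

The accuracy model is a trial-level Bernoulli GLMM with logit link, a
fixed slope on the chosen per-pair predictor and a subject random
intercept, fit by Laplace maximum likelihood (`lme4::glmer`); slope
inference is Wald. Response times are strictly positive and right-skewed,
so they are modelled as Gaussian on the log scale with the same random
structure (`lme4::lmer`, ML). Aggregated binomial fits were rejected in
favour of trial-level outcomes so that subject-by-pair imbalance is
handled naturally. Since a correlation coefficient is not defined for a
GLMM, each fit also reports a *descriptive* Pearson r between the six
pair-level mean outcomes and the predictor — the analogue of the r
usually quoted beside such scatter plots — alongside the model p-value.
Multi-term fits are supported, but single-term is the default report, and
no multiple-testing correction is applied (raw p-values are reported).

The behavioural generator draws a subject intercept
$u \sim N(0, \sigma^2)$, trial success with probability
$\mathrm{logit}^{-1}(\beta_0 + \beta_1 x + u)$, the odd position uniform
on {1, 2, 3}, an incorrect choice uniform over the two remaining
positions, and log-normal response times with log-mean linear in a second
predictor plus its own subject intercept.

## Pipeline, determinism, problem sizes

`run_pipeline()` chains the stages on a single flat configuration (R list
or YAML) and writes `classified.csv`, per-surface counts, per-pair
scores, fits and a plain-text summary whose every number comes from a
stage output. All randomness derives from one logged master seed, with
per-surface and per-pull child seeds derived by counter, so reruns are
byte-identical. The default demo uses six synthetic surfaces whose
slow-wave boundary and spike propensity are shifted per surface, which
yields a spread of differential-instability scores; behavioural trials
are generated with accuracy following |dSS|% (slope 0.1 per percentage
point on the logit scale) and log response time following |dSp|% (slope
−0.03), effect sizes in the range the discrimination literature reports.

Simulation-based checks run at the study scale where that is cheap
(10 subjects × 6 pairs × 10 trials for the mixed models; 50 replicates
for CI coverage, 200 for type-I error; 512² pixels × 10 seeds × 3
exponents for Hurst recovery) and at reduced grids (2 × 2 × 3 pulls)
where only the plumbing is under test.

## Known limitations

* The slow-wave cycle frequency has no canonical band separating it from
  motor or microscopic stick-slip timescales; the generator's target
  band (8–36 Hz, velocity-adaptive) and the classifier's sub-50 Hz
  analysis band are package conventions, consistent with each other.
* At 45 mm/s, slow waves are unresolvable in a 4 mm pull (see above).
* The classifier is the stated two-threshold heuristic; human raters'
  judgments may have used additional cues that are not reproduced.
* The Hurst estimator's conventions (windowing, fit band, 1-D line
  average) are self-consistent with the generator but not guaranteed to
  match other instruments' software.
* The GLMM descriptive r is a plotting-level summary, not a model
  parameter; it is reported only for single-term fits.
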