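---
title: "Models and methods behind fepsp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fepsp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fepsp)
```

## The experimental design this package analyses

Optic-tract stimulation of a superior colliculus slice evokes a field
EPSP (fEPSP) in the superficial grey layer: a negative-going voltage
deflection of a few tenths of a millivolt, peaking about 2 ms after the
stimulus. The recording session has three pharmacological epochs:

1. **baseline** — normal medium. GABAergic inhibition truncates the
   response after a few milliseconds.
2. **gaba_block** — picrotoxin + CGP55845 block all GABA receptor
   classes. The *disinhibited* response is revealed: a composite of
   non-NMDA and NMDA glutamatergic components lasting tens of
   milliseconds.
3. **gaba_nmda_block** — D-AP5 is added. The NMDA component is removed,
   leaving the non-NMDA component.

Stimuli are single 0.1 ms pulses every 20 s; responses are waveform
averaged in blocks of three consecutive sweeps (one minute of
recording), and each epoch is quantified over its last three minutes
(nine sweeps, i.e. three averaging blocks whose feature values are
averaged).

Four features are measured on each averaged response, all relative to
the pre-stimulus baseline level: peak amplitude (mV, negative), latency
to peak (ms from the stimulus), response duration (ms), and the
late-phase area under the curve (AUC, mV·ms) from the fEPSP peak to
100 ms after the stimulus.

The two headline statistics are per-slice receptor contributions built
from the condition AUCs:

$$\mathrm{GABA\%} = 100\,\frac{A_{gb} - A_{base}}{A_{gb}},\qquad
  \mathrm{NMDA\%} = 100\,\frac{A_{gb} - A_{full}}{A_{gb}},$$

where $A_{base}$, $A_{gb}$, $A_{full}$ are the AUCs under baseline, GABA
blockade, and GABA+NMDA blockade. The denominator is the disinhibited
AUC in both cases; this is the only simple algebra consistent with the
published worked examples (a slice whose baseline AUC is 15% of its
disinhibited AUC has an 85% GABA contribution; a D-AP5 residual of 46%
gives a 54% NMDA contribution). Out-of-range values (e.g. a drug that
*reduced* the response) are reported with a QC flag, never clamped.

Group-level inference mirrors the original analysis: paired *t*-tests
for within-slice drug effects, and one-way ANOVA with Tukey HSD
(Tukey–Kramer for unequal group sizes) for between-group comparisons,
two-sided at $\alpha = 0.05$. `anova_from_summary()` reconstructs the
identical ANOVA and Tukey results from per-group (n, mean, SEM) alone —
within-group variance is recovered as $s_i^2 = \mathrm{SEM}_i^2 n_i$ —
so published summary tables can be re-analysed directly; a property
test holds it to exact agreement with the raw-data route.

## The synthetic waveform model

No raw recordings are available, so the package ships a generative
stand-in whose *measured* properties are calibrated to the published
values. The noise-free sweep is

$$V(t) = -\bigl[A_f\,K_{f}(t) + A_n\,K_{n}(t)\bigr]\,G(t),$$

with $t$ measured from the stimulus. $K_f$ and $K_n$ are peak-normalized
biexponential kernels (fast non-NMDA and slow NMDA components). $G$ is a
monotone logistic *gating envelope* falling from 1 to `gate_floor`
around `gate_time_ms` — a phenomenological stand-in for feed-forward
GABAergic inhibition. Gating is active only at baseline; D-AP5 sets
$A_n = 0$. Disinhibition therefore *reveals* the late phase rather than
adding one, matching the pharmacology: multiplicative gating was chosen
over an additive inhibitory component for exactly this reason.

Key parameters (see `synth_params()`):

| parameter | default | meaning |
|---|---|---|
| `a_fast_mV`, `a_nmda_mV` | 0.7, 0.3 | component peak scales (mV) |
| `tau_rise_fast_ms`/`tau_decay_fast_ms` | 0.5 / 2 | fast kernel (ms) |
| `tau_rise_nmda_ms`/`tau_decay_nmda_ms` | 2 / 40 | NMDA kernel (ms) |
| `gate_time_ms`, `gate_width_ms`, `gate_floor` | 3, 1, 0.05 | inhibition onset, 10–90% transition, late leak |
| `noise_sd_mV` | 0.02 | per-sample Gaussian recording noise |
| `trial_cv` | 0.05 | trial-to-trial amplitude CV |
| `slice_cv_fast` | 0.2 | between-slice amplitude CV (common factor) |
| `slice_cv_nmda` | 0.3 | between-slice NMDA-balance CV |

The sweep-noise SD and trial CV are stated assumptions — the source
tables report no sweep-level variability — chosen at magnitudes typical
of interface-chamber field recordings (noise ~3% of the peak; a few
percent trial jitter). Records are sampled at 10 kHz with the stimulus
at 10 ms and 120 ms of post-stimulus record, so the 100 ms AUC window
always fits.

### Three variability tiers

* **Sweep noise** — i.i.d. Gaussian per sample.
* **Trial jitter** — independent mean-one lognormal factors on the two
  component amplitudes per sweep.
* **Slice tier** — drawn once per slice: a mean-one lognormal *common
  amplitude factor* (CV `slice_cv_fast`, matching the spread of
  published peak amplitudes), and a lognormal *NMDA-to-fast balance
  ratio*. Because every AUC is 1-homogeneous in the joint amplitude,
  the contribution percentages depend on the balance ratio alone.

For calibrated presets the balance law is not simply mean-one: the
contribution is a saturating nonlinear function $h$ of the balance
ratio, so any skewed mean-one amplitude law shifts the *mean*
contribution away from the generating value once the between-slice
spread is large. `preset_params()` therefore measures $h$ from the
pipeline itself on a ratio grid and solves the lognormal's location and
scale by quadrature so that the slice-level contribution distribution
has **exactly** the preset's mean and the published between-slice SD
($\mathrm{SEM}\sqrt{n}$, e.g. $3\sqrt{14}\approx11$ points for the
32-week operated-eye group). The location parameter is stored as
`slice_nmda_meanlog`.

## Calibrating presets to published values

`calibrate_preset()` solves generator parameters so that the package's
*own measurements* of noise-free output reproduce a target set: baseline
peak amplitude and latency, baseline and disinhibited durations, GABA%
and NMDA%. One preset exists for each published group (two models ×
three timepoints × two hemispheres/eyes), plus the two single-slice
worked examples; `fepsp_presets()` lists the targets.

The solve is a cycle of nested 1-D root finds, each parameter against
the measurement it dominates:

* fast decay ↔ latency, on a 1 µs-grid continuous surrogate (the 0.1 ms
  acquisition grid quantizes the measured latency, so the solve runs on
  the underlying waveform and the sampled measurement is verified
  after);
* NMDA/fast amplitude ratio ↔ NMDA% (re-solved inside the latency and
  duration solves, since it moves both);
* NMDA decay ↔ disinhibited duration;
* gate time ↔ baseline duration, with the gate floor re-solved for
  GABA% at every trial value;
* gate floor ↔ GABA%;
* a final exact amplitude scaling for the peak (every other measurement
  is scale-invariant).

Duration measurements move in 0.1 ms sample steps, so those solves use
*plateau bisection*: they locate a parameter value at which the
quantized measurement equals the printed value exactly. Two shape
subtleties surfaced during development and are handled automatically:

* Baseline duration vs gate time is V-shaped — an early gate shrinks
  the peak and with it the 5%-of-peak duration threshold, inflating the
  measurement — so the solve is restricted to the physical rising
  branch, and the gate's 10–90% width is narrowed (1 → 0.25 ms) when
  the duration target lies below the width-limited valley.
* A 0.5 ms fast rise forces a very slow fast decay to place the peak at
  ~2 ms, which raises the achievable baseline-duration floor; the
  calibration therefore tries fast rise times 1.0, 1.5, 0.5 ms in turn
  and keeps the first that closes. Closure is 2% relative on waveform
  features and 0.5% on the contribution percentages (which admit exact
  1-D solves); failure to close raises a calibration error reporting
  the worst residual.

## Numerical and procedural choices

* **AUC integrand.** The AUC is the signed trapezoidal integral of
  (baseline − V) from the peak to 100 ms post-stimulus. A rectified
  variant (`rectified = TRUE`) exists but is not the default: rectifying
  adds $\mathbb{E}\max(-\varepsilon,0)=\sigma/\sqrt{2\pi}$ per sample
  wherever the signal sits near baseline, which inflates the small
  D-AP5 AUC relatively more than the disinhibited one and biases the
  estimated NMDA contribution downward by several points at realistic
  noise levels. The two are identical on noise-free monotone
  deflections. The AUC window end ("100 ms after stimulation") follows
  the procedural description of the measurement; it is configurable via
  `protocol_spec(auc_end_ms=)`.
* **Duration rule.** The source describes no operational duration
  definition, so the package declares one: threshold
  $\theta = \max(3\,\hat\sigma_{noise},\,0.05\,|\mathrm{peak}|)$, onset
  at the first post-stimulus crossing, offset at the first post-peak
  time staying below $\theta$ for ≥1 ms (or the record end). Presets
  are calibrated *under this rule*, so printed durations are
  reproduced exactly by construction.
* **Peak search** is restricted to 0.5–10 ms post-stimulus to exclude
  any stimulus-adjacent transient (the stimulus artifact itself is not
  modelled); ties break to the earliest sample.
* **Analysis window**: "last 3 min" = the last 9 sweeps at the 20 s
  interval, processed as three 3-sweep averages whose features are
  averaged — mirroring the session's averaging unit.
* **Comparison family.** The published 32-week group comparison quotes
  the control value pooled across hemispheres, so the power analysis
  uses the three-group family {operated-eye input, unoperated-eye
  input, pooled controls}; the pipeline's report tables also emit the
  full pairwise Tukey set across whatever cohorts are present.
* **Seeds.** A cohort's master seed derives per-slice seeds as
  $(1009\,s + 7919\,i) \bmod 2147483629$; `run_experiment()` derives
  per-cohort seeds from its single top-level seed the same way. All
  draws use R's default Mersenne–Twister stream.
* **Degenerate inputs.** Flat traces yield amplitude 0, latency at the
  window start, duration 0, and a `no_response` QC flag; zero
  disinhibited AUC raises an error rather than returning an undefined
  contribution; zero-variance paired differences return p = 1 (all
  zero) or a degeneracy flag.

## What the generator does and does not emulate

It emulates: the negative-going fEPSP shape and its published feature
values per group; the epoch structure and stimulation schedule; sweep
noise and trial jitter; between-slice spread calibrated so group SEMs
match the published tables; and the group contrasts (the 32-week
operated-eye NMDA elevation).

It does not emulate: stimulus artifacts or fiber volleys; multi-peaked
or polysynaptic responses; slow drift, electrode instability, or
within-epoch drug-washin kinetics (epochs are stationary, so the "last
3 min" selection is statistically equivalent to any other window —
real washin dynamics are exactly what that selection exists for);
receptive-field structure or any in vivo visual response; and RGC-loss
dynamics underlying the group differences (groups differ only through
their calibrated parameter sets). Passing tests therefore validate the
measurement and inference machinery and the internal consistency of
the published values — not the biology of any particular slice.

## Problem sizes used in the shipped checks

Deterministic checks (worked examples, control features) use noise-free
single slices. Cohort-recovery checks simulate the full recording
protocol (60 + 60 + 30 sweeps per slice) at the published group sizes
(14, 12, 15 + 13 slices). The power analysis runs 50 seed replicates of
the four cohorts with 3-minute epochs — only the last-3-minute analysis
window ever enters the computation, so epoch length changes the random
stream but not the estimator's distribution. The paired *t* type-I
check uses 10,000 null replicates at n = 8. These sizes keep the whole
suite within a few minutes on one core.

## Known limitations

* The contribution algebra is inferred from worked-example values, not
  from a printed formula; both operations are isolated so an
  alternative denominator convention is a two-line change.
* Calibration matches six scalar targets, not waveform shape; many
  parameter sets are observationally equivalent under these six
  numbers, and the fitted kernels should not be read as biophysical
  time constants.
* The between-slice model is a two-factor lognormal; real slices may
  covary in ways (e.g. amplitude–contribution correlation) the tables
  cannot constrain.
* `anova_from_summary()` assumes the summary SEMs are sample SEMs with
  the $n-1$ convention; published tables that used population SDs would
  reconstruct slightly inflated within-group variance.
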