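---
title: "Methods: gaze-stabilization and spike-regularity quantification with gazelab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gaze-stabilization and spike-regularity quantification with gazelab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazelab)
```

## Scope

gazelab quantifies gaze-stabilizing reflexes and cerebellar spike-train
regularity in sinusoidal rotation experiments of the kind used to phenotype
mouse models of cerebellar disease (here: an SCA6-like knock-in line versus
wild-type littermates). The measured quantities are:

* **slow-phase gain and phase** of the vestibulo-ocular reflex in darkness
  (VORd) and light (VORl) and of the optokinetic reflex (OKR), per stimulus
  frequency;
* **quick-phase kinematics** (the "main sequence": peak velocity versus
  amplitude of the fast, resetting eye movements of vestibular nystagmus);
* **VOR motor learning**, as the percent change in gain after gain-down
  training;
* **simple-spike regularity** of Purkinje cells: firing rate, CV and CV2 of
  the inter-spike intervals (ISIs);
* the accompanying **group statistics**: two-way mixed-design ANOVA with
  Bonferroni post hoc contrasts, the extra sum-of-squares F test for slope
  equality, and the Mann-Whitney U test.

Because raw recordings from such studies are rarely deposited, the package
ships a synthetic cohort generator with ground-truth logging; every analysis
stage is validated against data whose true parameters are known.

## Slow-phase gain and phase

The stimulus is a turntable (or surround) velocity $h(t) = A\sin(2\pi f t)$
with $f \in \{0.2, 0.4, 0.8, 1, 2\}$ Hz and $A = 16$ °/s, sampled at 1 kHz
after 125 Hz low-pass filtering. For each recording the package fits, by the
closed-form least-squares (normal-equations) solution,

$$ s(t) \approx a\sin(2\pi f t) + b\cos(2\pi f t) + c $$

to the head trace (all samples) and to the eye-velocity trace (quick-phase
samples excluded). Gain is the ratio of fitted eye to head amplitudes,
$\sqrt{a^2+b^2}$. Phase is reported relative to the *ideal* response: for
compensatory conditions the ideal eye is $-$head, so
phase $= \phi_{eye} - \phi_{head} - 180°$ (wrapped to $(-180°, 180°]$);
for the OKR the ideal eye follows the surround and the $180°$ term is
dropped. Positive phase means the eye leads the ideal response. The sign
convention is applied uniformly across VORd/OKR/VORl, selected by the
recording's condition metadata. On whole-cycle windows this fit coincides
with the discrete Fourier projection at $f$ (tested to $10^{-8}$); on
arbitrary windows and with masked samples the least-squares form remains
exact, which is why it is the canonical estimator here.

The whole trace is fitted at once rather than cycle-by-cycle: with
stationary sinusoidal stimulation the whole-trace fit is the lower-variance
estimator, and the desaccading mask removes the only systematic
contamination.

## Quick-phase detection (desaccading)

Quick phases ride on the slow-phase sinusoid, so the detector works on the
residual around the current sinusoid fit and iterates to a fixed point:

1. fit the sinusoid to the eye velocity under the current mask (initially
   empty);
2. compute the residual $r$ and the robust SD
   $1.4826 \cdot \mathrm{median}|r - \mathrm{median}\,r|$;
3. mark samples with $|r| > \max(\text{velocity\_floor}, k \cdot
   \text{robust SD})$;
4. discard marked runs shorter than `min_duration`, then dilate the
   survivors by `margin_before`/`margin_after`;
5. repeat until the mask stops changing (or `max_iter`).

Defaults: $k = 3$, `velocity_floor` = 10 °/s, margins 20 ms before / 40 ms
after, `min_duration` = 5 ms, `max_iter` = 10. The floor keeps the threshold
off the noise floor of clean traces (a residual SD of 2 °/s would otherwise
put the threshold at 6 °/s, well inside physiological slow-phase
variability); the minimum-duration rule removes isolated supra-threshold
noise excursions, which for 125 Hz band-limited noise last one or two
samples, while murine quick phases last tens of milliseconds; the asymmetric
margins reflect that detection triggers on the rising edge of the velocity
pulse while the decaying tail is longer. A mask covering more than 80 % of
the trace aborts the analysis: such a trace is saccade-dominated or the
threshold is mis-set, and a gain fitted through it would be meaningless.

Each contiguous masked run becomes one event with amplitude
$\int r\,dt$ (degrees) and peak velocity $\max |r|$. On synthetic traces
whose injected pulses exceed five noise SDs, the detector finds at least
95 % of them with no spurious events, and recovered amplitudes are within
10 % of truth (median).

## Main sequence and slope comparison

Events are pooled across animals within genotype (events, not per-animal
means, are plotted and regressed in this paradigm), rectified, and fitted
with ordinary least squares: peak velocity on amplitude. Two genotypes are
compared with the extra sum-of-squares F test between nested linear models:

* reduced: common slope, group-specific intercepts;
* full: group-specific slopes and intercepts;
* $F = \frac{(SSE_{red} - SSE_{full})/(df_{red} - df_{full})}{SSE_{full}/df_{full}}$, with numerator df 1.

The reduced model deliberately keeps separate intercepts so a vertical
offset between groups cannot masquerade as a slope difference. The test is
algebraically identical to the squared t of the interaction coefficient in
the pooled regression (asserted in the tests), and its type-I error is
calibrated by simulation.

## VOR learning

Gain-down training (visual surround rotating with the head, target gain 0;
training stimulus 2 Hz, 16 °/s) is quantified only through its outcome:
percent change $= 100\,(g_{pre} - g_{post})/g_{pre}$, positive for a gain
decrease. Pre/post recordings are paired per animal and frequency; unmatched
pairs are an error, not silently dropped. No trial-by-trial plasticity model
is implemented — the generator encodes learning as a reduced post-training
gain.

## Spike-train metrics

For sorted spike times $t_1 < t_2 < \dots$ with ISIs $I_n$:

* firing rate $= (N-1)/(t_N - t_1)$, the reciprocal mean ISI over the
  spiking span — robust to silent padding at the record edges (the
  spikes-per-recording-duration variant is exposed as an option);
* $CV = \sigma_{ISI}/\mu_{ISI}$ with the *population* SD (denominator $n$).
  At the ISI counts of interest ($10^3$–$10^4$) the population/sample
  distinction is far below measurement noise, but the convention is fixed
  and tested;
* $CV2 = \mathrm{mean}_n \left( 2|I_{n+1} - I_n| / (I_{n+1} + I_n) \right)$,
  bounded in $[0, 2]$, equal to 1 in expectation for a Poisson process, and
  insensitive to slow rate drifts that inflate CV (a property the tests
  verify on rate-ramped trains). This is the standard local-regularity
  definition from the spike-train literature; the source describing this
  analysis prints the formula with a typographically garbled
  numerator/denominator, so the standard definition is adopted explicitly.

## Synthetic cohorts

`gen_cohort()` writes trace CSVs, spike files, a manifest and a ground-truth
JSON. Its defaults are the study conditions: 0.2–2 Hz at 16 °/s for 60 s per
recording (trial durations are not reported in this paradigm; 60 s is a
typical session segment and is configurable), 7 WT / 8 SCA6 animals for the
reflex cohorts, 6 / 7 for learning, anesthetized populations of 32 / 38
cells and awake populations of 32 / 30, with group rates and CVs set to the
reported values (e.g. anesthetized WT 30.49 sp/s, CV 0.41; SCA6 38.83 sp/s,
CV 0.68; awake SCA6 24.22 sp/s, CV 1.06). Where per-frequency gains are not
numerically reported, the defaults are plausible murine profiles anchored by
the quantified 28 % VORd deficit at 2 Hz (WT 0.800 vs SCA6 0.576).

The eye model adds: (i) Gaussian noise low-passed at 125 Hz with a 4th-order
zero-phase Butterworth filter, rescaled so the post-filter SD equals
`noise_sd` — mirroring the acquisition chain; (ii) quick phases as
raised-cosine velocity pulses. A raised cosine of peak $P$ and width $w$
integrates to $Pw/2$, so fixing both the amplitude $A$ (uniform in 2–10°)
and the main-sequence peak $P = \text{slope}\cdot A + \text{intercept}$
determines the width $w = 2A/P$ per pulse; the nominal `qp_duration` sets
the refractory spacing ($\ge 2 \times$) between pulses. Quick-phase
direction resets against the ongoing slow phase, as in physiological
nystagmus (configurable off). Pulses that would overlap the end of the
trace are discarded.

Spike trains are renewal processes: `gamma_renewal` draws i.i.d. gamma ISIs
with shape $k = 1/CV^2$ and scale $CV^2/\text{rate}$, covering regular
($CV \ll 1$) through supra-Poisson ($CV > 1$, $k < 1$) regimes; whether
awake irregularity in this preparation is bursty or merely a higher-CV
renewal process is not established, so a `burst_pause` alternative
(two-state alternation of high-rate gamma bursts and long gamma pauses,
with the burst rate solved numerically to hit the target mixture CV) is
provided, with `gamma_renewal` as the default. Target CVs below $10^{-3}$
(gamma shape $> 10^6$) are clamped to an exactly regular train with a
warning.

Determinism: every file draws from its own RNG stream seeded by a
polynomial hash of (master seed, file key), so identical (config, seed)
runs are byte-identical and any single file can be regenerated in
isolation.

What the generator does *not* emulate: eccentric-gaze and torsional
components, video-oculography calibration error, electrode drift,
complex-spike/simple-spike interactions, and nonstationary stimuli. Passing
recovery tests on synthetic cohorts therefore demonstrates correctness of
the estimators under the stated signal model, not robustness to every
artifact of real recordings.

## Statistics layer

The mixed-design ANOVA (between: genotype; within: frequency; subject:
animal) uses the standard error strata — genotype against
subject-within-group, frequency and interaction against subject ×
frequency — and requires a complete design (missing cells are an error; no
imputation). No sphericity correction is applied by default, matching common
practice in this literature. Post hoc, genotypes are compared per frequency
with independent two-sample t tests, Bonferroni-multiplied by the number of
frequencies (5 at the study design); per-frequency contrasts were chosen
over pooled-error contrasts for transparency, at a small cost in power. The
ANOVA F values are validated against a from-scratch sums-of-squares oracle,
and the between-factor type-I error is calibrated by simulation.

The Mann-Whitney U statistic counts $x_i > y_j$ pairs (half for ties); the
p-value is exact for tie-free pooled samples up to $n_1 + n_2 = 40$ and the
tie-corrected normal approximation with continuity correction otherwise. The
exact path is verified against full enumeration of group assignments. All
tests are two-sided.

## Problem sizes and numerical choices

The package's own validation uses: 60 s, 1 kHz traces for the
parameter-recovery checks (the study-scale condition); 20-seed batches of
20 s traces for detector sensitivity/specificity; gamma populations at the
reported group sizes (38/32/30 cells, 120–300 s trains) for the spike
calibration; and 600–1000 null replicates for the type-I calibration of each
test, chosen to keep binomial uncertainty around 1 % while running in
seconds. Unit tests use further-reduced cohorts (short traces, two
frequencies) since they probe plumbing, not statistical precision.

Tie-breaking and degenerate inputs: rank-deficient main-sequence designs
(all amplitudes equal), sub-minimum event counts, non-monotone spike times,
absent stimulus (head amplitude < 1 °/s) and saccade-dominated traces all
raise informative errors rather than returning numbers.

## Known limitations

* Horizontal channel only, as in the paradigm being modelled.
* The per-frequency generator gain profiles away from 2 Hz are plausible
  defaults, not reported values; analyses relying on them (e.g. the shape of
  the frequency-response curve) characterise the pipeline, not the biology.
* The burst-pause generator is a statistical stand-in, not a biophysical
  Purkinje-cell model.
* Repeated-measures ANOVA software options differ across packages
  (contrast coding, sphericity handling); p-values on real data are
  comparable only when those options match.
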