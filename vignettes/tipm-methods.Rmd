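---
title: "Quantifying tilt responses with tipm: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tilt responses with tipm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tipm)
```

# The measurement problem

Tilt-in-place microscopy (TIPM) images calcium activity in neurons of an
animal mounted on a platform that can rotate to an eccentric roll angle
within milliseconds and return just as fast. Because the imaging plane is
only in focus at horizontal, fluorescence is recorded before the step
(baseline) and immediately after the return. A slow indicator such as
GCaMP6s decays over seconds, so the fluorescence in the first second after
the return is a faithful proxy for the neuron's steady-state activity at the
eccentric angle — that is the core trick this package quantifies. Two
stimulus classes separate response components:

* **step** — rapid rotation to ±10/20/30°, a 15 s hold, rapid return.
  Probes tonic (static tilt) encoding; the post-return response mixes the
  held steady state with any phasic response to the return itself.
* **impulse** — out and back within ~13 ms, leaving no steady-state
  component. Probes phasic (angular acceleration/velocity) encoding.

The package implements the full analysis chain — ΔF/F normalization, peak
extraction, responsiveness, directional and magnitude tuning, longitudinal
change classification, and imaging/mounting QC — together with a forward
simulator that generates every input with known ground truth, so each
estimator can be validated end to end.

# The forward model

## Stimulus kinematics

`generate_waveform()` produces idealized trajectories on a fine grid
(default 1 kHz): a linear ramp of `transition_ms`, the hold, a ramp back,
and a response window, repeated `repeats_per_trial` times after a single
shared baseline. Ramp durations default to measured platform kinematics
(2.2/3.9/5.3 ms for 10/20/30° steps; impulse excursions of 5.0–13.0 ms with
sub-millisecond dwells), interpolated for other magnitudes. Ipsilateral
angles are positive, contralateral negative.

## Neural drive

`simulate_drive()` maps a trajectory onto a cell's instantaneous drive, in
ΔF/F-equivalent units:

* **tonic**: `utricle_scale · gain_ipsi · max(angle, 0) + gain_contra ·
  max(−angle, 0)`. During the hold, *plateau* cells sustain this level;
  *fast-decay* cells ramp it down linearly at `hold_decay_rate` (ΔF/F per
  second), floored at zero. `utricle_scale` multiplies only the
  ipsilateral tonic term, emulating loss of the utricular otolith, which
  spares contralateral and phasic drive.
* **phasic**: a delta at the end of every rapid transition (angular speed
  above 1000°/s), identical for all magnitudes and directions. The delta's
  area is `phasic_gain / k_max`, so the rendered transient peaks at
  `phasic_gain`. An impulse contains two near-coincident transitions and
  therefore peaks near `2 · phasic_gain`.

## Indicator kernel and rendering

`render_fluorescence()` convolves the drive with a causal double-exponential
kernel normalized to unit area,

$$k(t) = \frac{e^{-t/\tau_d} - e^{-t/\tau_r}}{\tau_d - \tau_r},$$

so a sustained drive `c` converges to a ΔF/F plateau of exactly `c`.
Defaults are $\tau_r = 0.18$ s and $\tau_d = 1.8$ s — literature-typical
GCaMP6s values, configurable per cell, and *not* measured quantities of any
particular dataset. Convolution uses two exact first-order recursions
(zero-order hold), so there is no quadrature error accumulation; steps are
simulated on a 5 ms grid and impulses on a 0.5 ms grid (the grid must
resolve the transition to place phasic events correctly). Fluorescence is
`baseline_F · (1 + dff)`, resampled at the volume rate (default 2.2
volumes/s), plus additive Gaussian noise of SD `noise_sd · baseline_F` per
sampled volume. Shot-noise/Poisson statistics are not modeled.

## Readout attenuation and implied ground truth

Because the indicator decays after the return, the mean ΔF/F over the first
post-return second is an attenuated version of the held steady state. For a
constant drive held for `hold_s`, the attenuation has the closed form
implemented in `readout_factor()` (≈ 0.83 for the default kernel and a 15 s
hold; the 2.2 Hz discretization of the window lowers the effective factor to
≈ 0.76, depending on sample phase). Two consequences:

* `simulate_neurons()` is parameterized in **measured-slope units** (the
  ΔF/F-per-degree slope of the post-return peak response, the unit in which
  roll sensitivity is reported) and divides by the analytic factor to set
  drive gains.
* `simulate_experiment()` pushes the *noise-free* forward model through the
  same normalization and window readout and reports the result as **implied
  ground truth** (per-cell implied peaks, slopes, directionality index).
  Estimator validation always compares against these implied values, which
  is exact regardless of discretization, decay class, or drive floors.

## Seeding

A single master seed fans out to per-(cell, protocol, trial) substreams via
a multiplicative hash (`mix_seed()`), so a fixed seed gives bit-identical
traces, and adding trials or protocols never reshuffles existing ones. This
also means that two simulations differing only in a drive parameter (for
example `utricle_scale`) see *identical* noise, enabling exact paired
comparisons.

## Default population, and what it emulates

Defaults were chosen once, from the study conditions the simulator emulates,
and then frozen: ipsilateral sensitivity slopes N(0.07, 0.06) truncated at
0.003, contralateral N(0.02, 0.02); half-normal phasic gains (SD 0.35 ΔF/F);
half plateau and half fast-decay cells; 3 trials per step size with 2
stimulus repeats per trial at 2.2 volumes/s; a 10 s baseline, 15 s hold, and
10 s response window. `noise_sd = 0.35` was calibrated with the forward
model so that the trial-to-trial coefficient of variation of 30° step peaks
is ≈ 0.18–0.19, the variability scale reported for real recordings. Strongly
phasic cells are placed ventrally (z ≈ −3.6 ± 7 µm versus +2.2 ± 11 µm),
mirroring the reported topography of impulse-responsive somata.

Fast-decay cells draw their hold-decay rate scaled to their own 10°
ipsilateral drive (losing 20–80% of it over a full hold) rather than from a
fixed absolute range. A fixed range would drive weak cells' tonic input to
the zero floor and abolish their post-return responses entirely,
contradicting the strong eccentric-versus-return correlation seen in real
populations; scaling keeps decay visible at every gain without annihilating
responses.

`develop_neurons()` builds the older-age population: ipsilateral changes are
unconditional and asymmetric (20% increase by 0.15 ΔF/F/°, ~4% decrease),
while contralateral changes follow the conditional structure observed in
longitudinal recordings — only the most contralaterally tuned third of cells
may lose their tuning, and only non-tuned cells may gain it.

What the generator does **not** emulate: optics (no point-spread function,
scattering, or bleaching), motion artifacts within trials, correlated
biological state fluctuations across cells, ROI segmentation error, and
frame drops. Passing tests therefore validate the estimators' statistical
behavior under the declared response model, not robustness to every failure
mode of real imaging data.

# Trace processing

**Normalization.** `normalize_traces()` computes ΔF/F = (F − F₀)/F₀ under
two schemes. `trial_baseline` uses the mean F over the *last 5 s* of the
trial's own baseline (requiring a baseline of at least 5 s) and is the
default when all imaging happens at horizontal. `anesthetized_baseline`
divides by a per-cell F₀ from a matched anesthetized recording at the same
angle; it is required whenever responses at different orientations are
compared, because the light path (and hence apparent baseline brightness)
changes with orientation. Non-positive F₀ values and missing cells are hard
errors naming the trial or cell.

**Peak responses.** `extract_peaks()` takes the arithmetic mean of ΔF/F over
a half-open 1 s window `[start, start + 1)` of sample timestamps, keyed to
the *stimulus log* (the protocol's event times), never to trace features:
`post_return_first_1s` for the standard paradigm, `eccentric_last_1s` for
recordings made at the eccentric angle. At 2.2 volumes/s the window holds
2–3 samples. Each stimulus repeat contributes one row; the mean ΔF/F over
the first second of the trial's baseline rides along as the paired
reference. Missing samples are excluded, not interpolated.

**Responsiveness.** A cell responds to a stimulus if its peak responses are
significantly higher than its own first-second baseline values (one-tailed
t test, α = 0.05). Repeats are averaged within trial before pairing: the
two repeats of a trial share the trial's estimated F₀, so repeat-level
pairs would be positively correlated and inflate the test size, while
trial-level pairs are independent and the test holds its nominal 5% size
(verified on 1000 null cells in the acceptance suite). An unpaired
two-sample variant is available (`paired = FALSE`). Cells with fewer than
two trials are flagged untestable.

**Hold dynamics.** `eccentric_dynamics()` summarizes recordings made at the
eccentric angle: time-to-peak (argmax of ΔF/F within the hold) and the
least-squares decay slope from that peak to the end of the hold. The fit
starts at the peak, not at hold onset, because peak-then-decay morphology
would otherwise bias slopes toward zero. Note that kernel smoothing delays
the ΔF/F peak of a linearly declining drive by several seconds and leaves
some curvature, so recovered slopes match the drive's decline rate only to
within ~15–20%.

# Tuning metrics

The **directionality index** is `(R_ipsi − R_contra)/(R_ipsi + R_contra)`
over mean 30° step peaks: +1 for purely ipsilateral-preferring cells. A
non-positive denominator leaves the index undefined; the cell is flagged
(`di_defined = FALSE`) rather than clamped, since a sign-flipped ratio is
meaningless. Negative mean peaks are allowed in the numerator.

The **roll-sensitivity slope** is an ordinary least-squares line (slope and
free intercept) through the individual per-trial peaks pooled across all
step magnitudes in one direction, in ΔF/F per degree. Pooling individual
trials rather than per-magnitude means weights magnitudes by their trial
counts and propagates trial-level variance into the standard error.
Baseline (0°) points are not included. Fits use a closed-form helper
(`slope_fit()`), identical to `lm()` to 1e−10 but cheap enough for the
millions of refits the permutation null needs; the test suite compares it
against an independent normal-equations oracle and against `lm()`.

# Longitudinal change classification

For each cell and direction, the observed statistic is the slope difference
between the two ages. The null is built by permutation: pool the cell's
trials from both ages, randomly reassign *age labels to whole trials*
(preserving per-age trial counts, each trial's magnitude/peak pairing, and
the grouping of repeats within a trial), refit a slope per pseudo-age, and
record the difference. Permuting whole trials matters: repeats within a
trial share the trial's F₀ estimate and are therefore correlated, and a
row-level shuffle would underestimate the null SD (about 12% false-change
calls on no-change simulations versus ~4% for the trial-level shuffle).

The significance cutoff is **mean ± 2 SD of the shuffled differences pooled
across cells** within a direction — one cutoff pair per direction for the
whole population (`cutoff = "population"`, the default). The pooled cutoff
is the form in which a single significance band can be drawn over the
population's distribution of changes, and it is the only form with useful
per-cell power at these trial counts: with three trials per magnitude, a
cell that changes strongly inflates *its own* permutation null (pseudo-ages
become magnitude-specific mixtures of the two true ages), so a per-cell
cutoff grows faster than the observed difference and large changes become
undetectable by construction. The per-cell variant is retained
(`cutoff = "per_cell"`) for diagnostics, and each cell's own null mean/SD is
always reported. The acceptance suite verifies both calibration (~95% of
no-change cells inside the band, symmetric errors) and power (≥90%
detection of a +0.07 ΔF/F/° gain increase).

**Early-tuned labels** use the analogous within-age null: permute the
trial→magnitude assignment among the first age's trials, refit slopes, and
call a cell early-tuned in a direction when its observed slope exceeds the
pooled mean + 2 SD. The rule is defined for the contralateral direction
(Early Contra Responders) and applied symmetrically to the ipsilateral
split; the exact single-age shuffle is an interpretation, documented here,
since only the two-age shuffle is fully specified by the source procedure.
Group differences in the change distributions are tested with a two-sample
Kolmogorov–Smirnov test, and the ipsi/contra coupling of per-cell changes
with a Pearson correlation — both delegated to `stats`.

# Imaging and mounting QC

`frame_shift()` estimates the field-of-view displacement between a
pre-stimulus and post-stimulus frame by normalized cross-correlation over
integer pixel lags (zero-mean, unit-variance per overlap region), reporting
the argmax lag (ties broken toward the smallest lag magnitude), the
correlation at zero lag, and a low-confidence flag when the peak correlation
is below 0.3. Lags are limited to 50% overlap; there is no subpixel
interpolation, matching the matrix-argmax definition of the estimate.
Constant frames make the correlation undefined and are flagged rather than
guessed. Micron conversion requires a user-supplied pixel size.

`roll_angle()` estimates mounting roll as `atan(Δz / 171.8 µm)` in degrees,
where Δz is the depth difference between the left and right Mauthner lateral
dendrite tips and 171.8 µm is the population-average mediolateral distance
between them. Cell positions are referenced per hemisphere to the Mauthner
landmark (+x lateral, +y rostral, +z dorsal; ventral cells have negative z),
and `position_group_compare()` contrasts responsive versus nonresponsive
somata per axis with unpaired t tests, skipping degenerate groups.

# Pipeline and reproducibility

`run_all()` orchestrates simulate → extract → tune → longitudinal → qc with
plain CSV/JSON files between stages, so every stage can be re-run and tested
from files. The manifest records the resolved configuration's MD5, each
stage's outputs and row counts, and every excluded cell with its reason. No
timestamps are written: a fixed seed makes the entire output directory
byte-identical across runs. A thin command-line wrapper
(`inst/cli/tipm`) exposes the stages as subcommands; the package functions
are the primary interface.

# Validation design and problem sizes

The test suite validates each formula against independent oracles (direct
formula evaluation, normal equations, a brute-force lag scan) and each
estimator against the simulator's implied ground truth at these sizes,
chosen to make the statistical assertions stable: slope recovery on 500
cells with gains uniform in [0.02, 0.12] ΔF/F/° (bias < 0.005, ≥90% within
3 SE); classifier calibration on 1000 no-change cells; classifier power on
populations of 300 cells of which 5% truly increase by {0, 0.03, 0.05,
0.07} ΔF/F/° at a fixed moderate noise of 0.2 — the small changer fraction
matches the single-changing-cell framing of the power question and keeps
the pooled cutoff at its base level; responsiveness size on 1000 zero-gain
cells; and the utricle-null contrast on 100 plateau cells. Plateau cells
isolate the multiplicative `utricle_scale` effect from hold-decay
flooring; with shared noise substreams the contralateral slopes are
*identical* between the intact and attenuated runs, and impulse responses
agree to within a few tenths of a percent (the residual being the brief
tonic drive during the 13 ms excursion), so the paired comparison is an
equivalence check rather than a significance test.

# Known limitations

* The tonic drive follows the platform angle instantaneously; sensory and
  synaptic dynamics shorter than the kernel are absorbed into the phasic
  term. The brief tonic drive during an impulse excursion leaks a small
  (<1%) magnitude- and utricle-dependent component into impulse responses.
* The readout attenuation factor is continuous-time; the 2.2 Hz window
  discretization shifts the effective factor by up to ~10% depending on
  sample phase. Implied ground truth accounts for this exactly; the
  population-mean parameterization is approximate at that level.
* Only two ages are supported in the longitudinal design; no trajectory
  modeling.
* The shuffle classifier's population cutoff assumes cells within a
  direction share a common null scale; with strongly heterogeneous noise
  levels across cells the per-cell variant may be preferable.
* Frame-shift estimation is integer-pixel only and 2-D; volumetric
  registration and slow drift correction are out of scope.
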