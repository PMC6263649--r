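---
title: "Walk detection and step counting: models, parameters and evaluation methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Walk detection and step counting: models, parameters and evaluation methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitbench)
```

# Scope

`gaitbench` implements two algorithm families for body-worn tri-axial
accelerometers — frame-level walk detection (WD) and event-level step
counting (SC) — together with the strict per-gait-cycle ROC methodology
used to score counters and a context-impact framework that measures how
placement, orientation knowledge, personalization, window size and
sampling rate move each algorithm's accuracy. Because suitable annotated
recordings are rarely shareable, the package ships a synthetic gait
simulator that produces labelled sessions with per-cycle ground truth;
every algorithm and metric in the package runs end to end on it.

# The signal model behind the simulator

A walking bout at stride frequency $f$ (drawn uniformly from
$[0.8, 1.2]$ Hz unless fixed; the canonical walk band is
$[0.66, 1.66]$ Hz) is generated in the body frame as

$$a_z(t) = 1 + s \sum_{h=1}^{H} A_h \cos\!\big(2\pi h f_{\mathrm{obs}} (t - t_0)\big)
           - s\,I \sum_k e^{-(t - t_k)^2 / 2w^2} + \varepsilon(t),$$

with gravity kept in (a static sensor reads 1 g), default harmonic
amplitudes $A = (0.35, 0.15, 0.08)$ g, subject amplitude factor $s$,
heel-strike impulses of depth $I = 0.4$ g and width $w = 30$ ms, and
white Gaussian noise $\varepsilon$ (default s.d. 0.02 g). The horizontal
channels carry attenuated copies in quadrature. The observed fundamental
is $f_{\mathrm{obs}} = f$ for Group I placements (Foot, FrontPocket,
BackPocket, Hand), which see one signal period per gait cycle of the
instrumented leg, and $f_{\mathrm{obs}} = 2f$ for Group II (UpPocket),
which also picks up the contralateral leg. Hand sits on the group
boundary; it defaults to Group I with an override. The body-frame signal
is rotated by a proper rotation drawn uniformly from SO(3) (free
orientation) or the identity (orientation known), and each axis gets
independent noise.

Two modelling choices deserve emphasis:

* **Harmonics are phase-locked.** All harmonics share one random phase
  offset $t_0$ per bout rather than independent phases. Walking
  acceleration is an impact-driven oscillation: its harmonics are locked
  to the gait event, and the magnitude shows one dominant peak per
  period. Independently-phased harmonics produce waveforms with two
  comparable peaks per period — a shape no peak-scoring counter can
  threshold apart, and not one that walking produces.
* **Cycle annotations are event-aligned.** Ground-truth cycle boundaries
  are placed relative to $t_0$, between one cycle's heel impulse and the
  previous cycle's harmonic peak, the way a human annotator marking heel
  strikes would segment the record. Anchoring boundaries at absolute
  multiples of $1/f$ instead makes strict scores depend on the arbitrary
  phase of the bout: detections near a boundary flip between adjacent
  cycles and a perfect counter can appear to fail. At zero noise the
  bout still contains exactly $\lfloor \mathrm{duration} \times f \rfloor$
  cycles.

Non-walk activities reuse the same harmonic machinery with
activity-specific fundamentals and amplitudes — stairs (0.70/0.75 Hz,
with impulses), running (2.6 Hz, large), riding (4 Hz vibration, small),
tooth-brushing (1.3 Hz — deliberately inside the walk band),
vehicle sway (0.3–0.4 Hz), static postures (gravity + noise), and
irregular bursts ("other"). Per-subject variation is one amplitude
factor (log-uniform on $[0.6, 1.8]$) and one stride frequency, drawn once
per subject id.

What the simulator does *not* model: terrain and slope, turning,
cadence drift within a bout, gyroscopic channels, soft-tissue artefacts,
or genuinely diverse hand movement (an extra low-frequency jitter term
stands in for the Hand placement without claiming fidelity). Results on
the benchmark therefore demonstrate algorithmic correctness and
*relative* behaviour under controlled context changes, not absolute
field performance.

# Preprocessing

All orientation-agnostic processing starts from the magnitude
$d_t = \sqrt{x_t^2 + y_t^2 + z_t^2}$, which is exactly invariant to
sensor rotation. For WD the magnitude is low-passed at 15 Hz; the filter
family is a 4th-order Butterworth applied forward–backward, preserving
peak timing (zero phase) with unit DC gain. `signal::filtfilt` starts
from zero state, so the implementation wraps it in odd-reflection
padding with the mean removed; without this a constant signal acquires
O(1) edge transients. Cutoffs at or above Nyquist (possible at low rates
for the 15 Hz WD filter and the 50 Hz Pan-Tompkins filter) are clipped
to $0.45 \times$ rate with a warning.

Frames are `W` seconds with overlap `W/6` (the one-sixth rule; the
default 3 s window gives the canonical 0.5 s overlap), trailing partial
frames discarded, each frame labelled by the majority activity of its
samples with ties broken against walk (conservative for WD). Whether the
15 Hz filter precedes or follows the magnitude is an open choice; the
package filters the magnitude (one channel instead of three), and the
band content of interest is unaffected.

For SC the magnitude is variance-normalized (mean removed, unit
variance), making FSM thresholds comparable across subjects and
placements; normalization deliberately includes mean removal so
peak/valley thresholds sit symmetrically around zero. Rate changes are
Fourier resampling — spectrum truncation at the new Nyquist — which
keeps in-band sinusoid amplitudes within fractions of a percent, where a
polyphase FIR implementation showed ~2.5% ripple.

# Walk detectors

The three signal-statistic detectors reduce each frame to one number —
variance (`thr`), one-sided spectral energy in the closed band
$[0.66, 1.66]$ Hz (`stft`), or the frame mean of the 1 s-smoothed squared
db10 detail coefficients of levels 7–8 (`dwt`) — and threshold it.
The threshold is fitted by exhaustive scan: candidates are the extremes
and all midpoints between consecutive distinct training values, accuracy
of "walk iff statistic ≥ t" is evaluated at each, ties go to the
smallest threshold. A brute-force oracle in the test suite confirms the
scan is exactly optimal over that candidate set.

The ML detectors use the full feature vector per frame: mean, variance,
min, max, energy (defined as the mean of squares so that
$\mathrm{rms}^2 = \mathrm{energy}$), population skewness and excess
kurtosis (zero by convention on constant frames), mean-crossing rate
(sign changes of $x - \bar{x}$ per second, plateaus counted once), RMS,
and the first $K = 32$ one-sided Hann-windowed FFT amplitude bins after
DC, scaled $2|X_k|/N$ so they are rate-independent at fixed window
duration. $K$ is configurable; 32 bins reach ≈10.7 Hz at a 3 s window,
comfortably covering gait harmonics. k-NN uses $k = 5$; the SVM uses an
RBF kernel with cost and gamma chosen by a small inner grid
($C \in \{1, 10\}$, $\gamma \in \{1, 4\}/d$) on each training fold.

Evaluation is stratified 10-fold cross-validation on a 1:1
class-balanced, seed-shuffled dataset; features are standardized per
training fold; accuracy is the pooled fraction of correct frames.
Threshold detectors are refitted per fold so all five detectors are
scored by the same protocol.

Context variants: orientation known evaluates the body-frame axes
(three-axis feature concatenation for ML; per-axis statistic with the
best axis kept, ties to the gravity axis, for the threshold detectors);
personalization known trains and tests within each subject and averages;
placement known restricts to one placement; rate and window sweeps
resample and re-frame the same sessions.

# Step counters

All counters share `detect_peaks()`: plateau-aware local maxima filtered
by minimum height, minimum prominence (default $0.1 \times$ IQR of the
transformed signal) and the decision threshold, then greedily pruned by
minimum distance (default 0.25 s) visiting candidates in decreasing
height with ties to the earlier index. An exhaustive $O(n^2)$ oracle in
the tests reproduces the implementation exactly on fuzz signals. Because
greedy pruning by descending height commutes with score thresholding,
the ROC sweep can filter the unthresholded event list by score — and
event counts are provably monotone in the threshold, which makes every
ROC curve monotone by construction.

The FSM topology is IDLE → RISING ($x > t_2$) → PEAK ($x > t_1$) →
FALLING ($x < t_3$) → VALLEY ($x < t_4$), emitting one event at the
PEAK-phase maximum on valley confirmation; incomplete traversals emit
nothing. The four thresholds are grid-searched (default
$5 \times 3 \times 3 \times 3$ lattice) on an annotated training bout,
maximizing strict TPR subject to FPR ≤ 0.05, ties to larger $t_1$.

The Pan-Tompkins chain runs FIR low-pass (order 200, 50 Hz, symmetric so
it is zero-phase when centred), first difference, squaring, and a 0.5 s
moving-sum integrator; one integrator maximum is one step. Squaring
makes event positions invariant to amplitude scaling (scores scale by
the square).

The spectral counter keeps the largest-magnitude FFT coefficients
(conjugate pairs together) until their cumulative energy reaches 20% of
the total, inverse-transforms, differentiates and detects peaks. Its
input is the variance-normalized magnitude: with the mean retained, the
DC coefficient alone exceeds the 20% budget and the reconstruction is
constant. The alternative reading — keep coefficients from the
low-frequency end to the same budget — is implemented behind
`mode = "lowfreq"`; magnitude order is the default.

The wavelet counters reconstruct from db10 detail levels {6,7,8}
(≈0.39–3.125 Hz at 200 Hz) or {2,3} (≈12.5–50 Hz). Stated levels assume
the 200 Hz reference rate and shift by $\mathrm{round}(\log_2(200/r))$
at rate $r$. The DWT itself is implemented in the package (periodized
pyramid with odd-length padding recorded per level), reconstructs
exactly to machine precision, and level 1 is the finest scale.

Group II placements produce two observed periods per gait cycle, so a
counter tuned to one event per period over-reports by 2×; the package
halves the event stream (keeping every other event) before strict
matching. "Step" throughout means one annotated gait cycle of the
instrumented side; bilateral totals are out of scope.

# Evaluation methodology

Strict matching scores each cycle independently: $n > 0$ events inside a
cycle give one true positive and $n - 1$ false positives; empty cycles
are misses; events outside every cycle are false positives (the strict
definition exists to penalize spurious detections, so stray events must
count). $\mathrm{TPR} = C_{tp}/C_{gt}$, $\mathrm{FPR} = C_{fp}/C_{gt}$
(which may exceed 1), and conservation $C_{tp} + \mathrm{misses} =
C_{gt}$ holds identically. The loose signed error
$(C_{est} - C_{gt})/C_{gt} \times 100\%$ is reported alongside; the
README's worked example shows a bout where the loose error is exactly
zero while strict scoring exposes one miss and one false positive.

Operating points are chosen on the ROC grid as the point with FPR
nearest the target (3% for context tables, 5% for error-source
distributions), ties to the lower FPR and then the higher TPR — the last
tie-break matters on clean data where long stretches of the curve sit at
FPR 0. Error sources report each placement's share of total false
positives at a common operating point. Context reports tabulate each
context's accuracy (WD) or operating-point TPR (SC) as a delta against
the pooled baseline (200 Hz, 3 s window, orientation/personalization
unknown), with multi-valued axes (placement, rate, window) reported as
[min, max] delta ranges.

# The benchmark and its study conditions

The default benchmark is 6 subjects × {FrontPocket, Hand}, each a 185 s
session mixing three walking bouts with stairs, running, tooth-brushing,
riding, standing and driving, at 200 Hz with 0.02 g noise — sized so the
full cross-validated evaluation of all five detectors runs in tens of
seconds on one core. Two constructions make the benchmark informative
rather than saturated:

* Tooth-brushing (1.3 Hz) lies inside the walk band, and stairs lie
  near it, so variance and band-energy statistics cannot fully separate
  the classes — which is exactly why the ML detectors, which see the
  harmonic pattern, dominate them.
* Stair bouts are generated from the *walking* model at the cadence and
  amplitude of a different subject on the roster (next subject for
  stairs up, previous for stairs down). Pooled across subjects the walk
  and stair classes collide; within one subject they separate. This is
  the regime in which personalization genuinely pays: per-subject
  training raises ML accuracy above the pooled baseline, while at the
  same time keeping the pooled baseline honest (below ceiling).

Session generation is fully deterministic given the study seed: subject
profiles derive from `seed × 1000 + subject`, sessions from a hash of
seed, subject and placement, and every consumer (balancing, fold
assignment, SVM tuning) seeds its own RNG use, so identical
configurations give byte-identical outputs.

# Numerical choices and degenerate inputs

* Sample indexing in files is 0-based with half-open segments and
  cycles; R-side accessors convert internally.
* Variance normalization refuses (near-)constant signals — step counting
  on a constant signal is meaningless — and feature extraction maps
  zero-variance frames to zero skewness/kurtosis/crossing-rate instead.
* The spectral counter errors on an all-zero spectrum; wavelet depth is
  reduced with a warning when the signal is too short, and counters
  error only when the requested detail levels become unavailable.
* Threshold fits require both classes; balancing requires both classes
  non-empty; FSM grid search warns and returns the lowest-FPR
  configuration if nothing meets the FPR budget.
* Numeric CSV I/O prints 15 significant digits; round-trips are exact to
  well below the 1e-9 contract used in the tests.

# Known limitations

The benchmark's absolute accuracies have no claim to field validity —
they characterize the implementation under a controlled, favourable
signal model. Cross-subject generalization is emulated by two scalar
factors, not by real kinematic diversity; the Hand placement's jitter
term is a placeholder; and the context framework reports deltas on the
synthetic roster, which is the mirror of a study design, not of a
deployment. The package's claims are therefore structural: oracle-exact
matching and pruning, monotone ROCs, rotation invariance, determinism,
and the qualitative orderings (ML over single-statistic WD,
personalization gains, rate robustness above the low-rate transition)
that survive any reasonable parameterization of the simulator.
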