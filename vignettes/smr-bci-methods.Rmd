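---
title: "Methods: a sensorimotor-rhythm BCI pipeline with synthetic ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a sensorimotor-rhythm BCI pipeline with synthetic ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(smrbci)
```

This vignette documents the models, the tunable parameters, the numerical
choices and the limitations of the package, in the order the data flow
through it.  Every empirical statement below is one the test suite or
`scripts/acceptance.R` computes; nothing is quoted from elsewhere.

## The signal model behind the generator

Motor and mental imagery modulate idling oscillations over task-specific
cortical areas: mu (≈8–13 Hz) and beta (≈16–30 Hz) rhythms
*desynchronize* — lose power — while the corresponding task is performed.
The generator reproduces exactly the statistical structure this implies and
nothing more:

* **Background.** Per channel, independent Gaussian noise whose power
  spectrum falls as 1/f^`background_slope` (default slope 1, `noise_sd`
  5 μV at 512 Hz).  It is synthesized by spectral shaping in the Fourier
  domain, so the realized slope is exact up to estimation error; a
  periodogram fit on a source-free channel recovers it within ±20% in the
  tests.
* **Sources.** Band-limited Gaussian processes (4th-order zero-phase
  Butterworth-filtered white noise, unit variance, scaled by `amp` μV) with
  one mu and one beta source per non-rest class, each projected onto the
  scalp by a row of the mixing matrix (weight 1 at a class-specific center
  channel — C3 for right-hand imagery, Cz for feet, Pz for mental
  subtraction — and 0.4 at its 2.5 cm neighbours).  Linear instantaneous
  mixing is the standard EEG volume-conduction approximation; no leadfield
  is computed (an explicit non-goal).
* **ERD.** During imagery of class *k* the amplitude of its sources is
  multiplied by `sqrt(1 + d)` with `d = erd_depth[[k]][source]`, so band
  *power* scales by `1 + d`.  Defaults are −0.5 (mu) and −0.3 (beta):
  a deep but physiologically plausible desynchronization for a trained
  subject, and the regime in which the acceptance criteria operate.  The
  envelope ramps over 250 ms (raised cosine) to avoid spectral splatter and
  spurious artifact-gate triggers; `d > -1` is enforced because power
  cannot become negative.
* **Sessions.** Calibration sessions follow the Graz-style timing: fixation
  3 s before the visual cue, 5 s of imagery from the cue, inter-trial
  breaks drawn uniformly from 2–3 s (the protocol states the range only;
  uniform is the least-informative choice), classes pseudorandomized with
  exact per-class counts, and an artifact-free resting segment (default
  30 s) at the session start for normalization and gate statistics.  Race
  streams alternate 5 s of pad-class imagery and 5 s of rest per pad; rest
  pads are never modulated.
* **Artifacts.** Blinks are 200 μV-scale Gaussian-envelope transients
  (σ = 80 ms, spectrum below 10 Hz) maximal at AFz with 0.4 weight on other
  frontal channels; steps are sustained baseline shifts on chosen channels.
  Ground-truth intervals are returned so detection rates can be scored.

What the generator does **not** emulate: non-stationary background drift,
volume-conducted EMG/ECG, electrode impedance changes, inter-subject
variability, or feedback-induced feature drift.  Green tests therefore show
the pipeline is *correct* (it recovers what was planted, and stays calibrated
on null data), not that any accuracy number transfers to real subjects.

## Preprocessing

Filtering is per-channel IIR Butterworth (`signal::butter`), causal
(forward-only, what an online system can compute) or zero-phase
(forward–backward, effective order doubled, offline maps only).  The notch
is a 2nd-order biquad at 50 Hz with Q = 35.  The ±100 μV amplitude
criterion for trial rejection is applied to the segmented (already
band-limited) trials: on broadband data, slow drift would dominate the
threshold.  "Abnormal joint probability" is implemented as the per-trial
Gaussian log-likelihood under per-channel fits pooled across trials,
z-scored across trials; both it and the kurtosis criterion use two-sided
4 SD thresholds, evaluated in a single pass on the original set so that the
criteria do not interact.

## ERD/ERS maps

Per frequency bin (2 Hz-wide bands stepped by 1 Hz over 2–40 Hz by
default): causal band filter, squaring, 250 ms moving average, average over
trials, and percent change `100 (A − R)/R` against the mean power `R` in a
pre-cue reference interval (default −2 to −1 s).  Two numerical choices
matter.  First, each epoch is reflection-padded by one second before the
causal filter, and the first half second of the map is dropped: without
this, the filter's settling transient masquerades as deep ERD at the epoch
edge.  Second, significance uses a t-percentile (studentized) bootstrap of
the across-trial mean of per-trial percent-change values, resampling trials
with replacement (default 1000 resamples, seeded); a bin is significant iff
the interval excludes zero.  On white-noise trials the flagged fraction
stays at the nominal level within Monte-Carlo tolerance; an injected −50%
modulation is recovered within ±10 points and flagged at the injected bin.

## CSP and band-power features

Per class pair and band, trial covariances over the fit window (default
1–3 s post-cue) are trace-normalized, averaged per class, and shrunk toward
scaled identity.  Shrinkage `"auto"` uses the analytic estimator
`γ = Σ Var(S_ij) / Σ (S_ij − T_ij)²` over the per-trial covariance
dispersion, clipped to [0, 1] — zero extra tuning parameters.  The filters
come from a symmetric whitening of Σ̂A + Σ̂B followed by an eigendecomposition,
with a deterministic sign convention (largest-magnitude coefficient
positive) so that serialized models reproduce bit-identically.  Trace
normalization is the field's standard guard against inter-trial amplitude
drift, but it breaks the exact invariance of eigenvalues under invertible
channel mixings; `trace_norm = FALSE` restores the exact invariance and is
what the invariance property test uses.  Features are the natural log of a
trailing one-second moving average of the squared projections, computed at
every sample; the first second uses a growing window and is flagged as
burn-in.  A floor of 1e-12 keeps silent channels finite.

## Classification and evaluation

The sLDA classifier shrinks the pooled within-class covariance toward
scaled identity (same analytic `γ` on centered observations) and uses equal
priors — calibration designs are balanced by construction, and equal priors
avoid frequency-driven bias.  Posteriors are the softmax of the linear
discriminant scores, which is exact for the Gaussian equal-covariance
model; at `γ = 0` decisions coincide with classical LDA (verified against
an independent implementation).

Cross-validation is repeated and stratified; CSP and sLDA are fitted
strictly inside training folds, and a `fit_on_full` request is refused
outright rather than silently honored.  Accuracy is reported over time
(default every 16th sample), as trial-majority accuracy (strictly more than
half of in-window predictions correct; ties count as errors), and as a
row-normalized percent confusion matrix.  The chance bound is the upper end
of the adjusted-Wald (Agresti–Coull) interval for a 1/k-success binomial —
within one point of a 10⁶-draw Monte-Carlo quantile in the tests.  Note the
bound applies to a single accuracy number; the *peak* of an accuracy curve
is a maximum over correlated tests and exceeds it slightly more often, which
is why the calibration check evaluates accuracy at one fixed latency.

Task-combination ranking runs the full cross-validation for every k-subset
of the task pool (70 subsets for 8 tasks, k = 4) and sorts by peak accuracy,
with the median accuracy over 1–4 s as a stability column.

## Online decisions and artifact gating

Class probabilities are averaged over a trailing second and compared to
class-specific thresholds at 16 decisions per second (512/32 samples; the
emission rate is configurable).  Among classes above threshold the highest
average wins; exact ties emit nothing, and predictions of the rest class
emit nothing by design — in the game, rest means "send no command".
Thresholds come from out-of-fold probability statistics (5×5 CV): the
suggested threshold per class is its mean off-class probability + 2 SD, a
reproducible starting point standing in for a technician's manual tuning
(manual override is a plain argument).  In the default generator the
unmodulated REST class sits centrally in feature space, attracts off-class
probability mass, and receives the strictest suggested threshold — the bias
phenomenon the estimator exists to expose.

The blink gate compares 250 ms windowed 1–10 Hz power at AFz against the
resting mean + 3 SD.  Because windowed power is right-skewed, this blocks
roughly 0.5–3% of clean resting samples rather than a Gaussian 0.1%; the
tests bound it at 5%.  The AR gate fits order-10 autoregressive models per
channel on resting EEG (Yule-Walker), predicts each sample from the
previous ten, and blocks when any channel's prediction error exceeds 3
error-SDs.  On clean unblocked samples the error variance and (slowly, via
normalized LMS) the coefficients are updated by exponential forgetting with
a 30 s time constant, which keeps the false-block rate stable under a ×2
amplitude drift over ten minutes.  A sustained step keeps the gate blocked
until adaptation absorbs it — intended behavior, since the data remain
non-resting-like.

## The race simulator

Pads are 11.25 distance units long at unit base speed, so a passive
traversal takes 11.25 s and satisfies the 10 s training-paradigm minimum;
boost and slow factors are 2.0 and 0.5.  These constants are free
parameters of the real game and are not published; they were fixed once so
that a 16-pad no-command run takes 180 s and a perfect run half that,
bracketing the scale of competitive runtimes, and all of them are
configurable.  A command's effect lasts one decision tick (1/16 s).  The
avatar integrator is event-driven within ticks — speed changes at pad
crossings are handled exactly, so closed-form runtimes for pure policies
are met to machine precision, and an independent 1 ms brute-force
re-simulation agrees within 1%.  The significance baseline is the median
runtime over ≥100 races driven by per-tick uniform random commands
(rest draws emit nothing); a decoder trained at ERD depth −0.5 beats it in
well over 95% of seeded races in the acceptance suite.

One structural simplification: race streams are generated open-loop with
the training paradigm's fixed 10 s-per-pad timing, while the avatar's pad
at each tick determines command correctness.  A fast avatar therefore
receives briefly stale commands after pad transitions, which *lowers* the
measured performance relative to a truly co-adaptive pilot — the
conservative direction for the baseline comparison.

## Problem sizes and formats

The test and acceptance runs use scaled-down study conditions chosen for
routine execution: 128 Hz, a 6-channel montage around C3/Cz/C4/Pz/AFz/O1,
5–10 trials per class, 50 permutation seeds, 100 closed-loop races, and a
64 Hz 4-channel setting for the 30+30 calibration-transfer assembly.  The
full-scale defaults (512 Hz, 32 channels, 8-task screening pools) run
through the identical code paths.  Recordings interchange as EDF (16-bit,
one-second records, zero-padded final record) with a TSV event sidecar;
sessions and decoders serialize to RDS; run configurations are
schema-validated YAML that rejects unknown keys and super-Nyquist band
edges at load time.

## Known limitations

* Synthetic validation only: no claim about real-subject accuracy
  transfers from these tests.
* The generator's stationarity means session-to-session transfer
  (30 + 30 trial merging with per-session variance normalization) is
  exercised mechanically, not under realistic drift.
* The blink detector has no refractory period beyond the threshold
  crossing itself.
* The AR gate's coefficient adaptation is a small-step NLMS, adequate for
  slow drifts but not for abrupt montage changes.
* EDF support covers the continuous equal-rate layout this package writes,
  not the full zoo of EDF+ annotations.
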