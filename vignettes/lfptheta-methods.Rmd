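---
title: "Methods: cerebello-hippocampal LFP theta coherence analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cerebello-hippocampal LFP theta coherence analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(lfptheta)
```

## The problem

During movement, the rodent dorsal hippocampus is dominated by a 6–12 Hz
("theta") oscillation, and discrete regions of the cerebellar cortex —
Crus I, lobule VI, lobule II/III — synchronize with it to different degrees
depending on behavioural context. Quantifying that synchronization from
simultaneous local field potential (LFP) recordings requires a chain of
steps, each with parameters that matter: signal conditioning, behavioural
epoching, multitaper spectral estimation, coherence summarised per
frequency band and per position on a linear track, resampling nulls for
speed confounds, and spike-level confirmation through theta phase locking
of photo-identified Purkinje cells. `lfptheta` implements that chain as
tested, reusable components, together with a synthetic-session generator
whose ground truth is exact — so every estimator in the package is
validated against known answers rather than against itself.

## Signal conditioning

LFP channels (nominally 1 kHz) are processed in a fixed order:
**standardize** (z-units over the whole trace; downstream thresholds become
scale-free), **notch filter** (zero-phase 2nd-order Butterworth band-stop
centred at 50 Hz; only the centre frequency is prescribed by the recording
context, so we chose quality factor 30, giving a ~1.7 Hz stop band — wide
enough to absorb mains wander, narrow enough to leave 48 and 52 Hz within
1% of unity after the forward–backward pass), and **local-linear
detrending** (ordinary least-squares line fitted in a 1 s window sliding by
0.5 s and subtracted). With 50% overlap every interior sample is covered by
two windows; their fits are blended with triangular weights peaking at each
window's centre, which makes the subtracted trend continuous (a plain
piecewise fit would introduce steps at window boundaries). A globally
linear input is removed to numerical precision; an 8 Hz oscillation passes
with correlation above 0.99.

### Artifact exclusion

Large low-frequency transients are found by thresholding the z-scored mean
0.5–5 Hz power of the 1 s / 0.1 s / 4-taper spectrogram. The z-threshold
default is 4: the band-power distribution is right-skewed, and 4 SD keeps
false flagging on clean data below ~1% per channel-pass while catching
10–20× transients reliably — the step is meant to remove only gross events,
not to be a cleaning filter. Detection runs on each channel **both before
and after detrending**, and the pipeline excludes the union: the detrend
stopband overlaps the artifact band, so slow sub-cycle bursts are visible
only pre-detrend, while weaker mid-band bursts need the quieter
post-detrend baseline. Flagged window extents, plus ±0.5 s around every
reward/stimulation pulse on the linear track, are merged into a half-open
interval mask; any analysis window overlapping the mask is dropped whole —
no partial windows.

## Multitaper estimation

Spectrograms and coherograms use discrete prolate spheroidal (Slepian)
tapers computed from the standard symmetric tridiagonal commuting matrix
(unit-energy, cached per shape). The defaults are a 1 s window sliding by
0.1 s with 4 tapers at time-bandwidth product 2.5, the `K = 2NW − 1`
convention of the Chronux-style toolchain; spectral resolution is 1 Hz with
±2.5 Hz taper bandwidth. Power is one-sided spectral density scaled so the
per-window frequency integral recovers the windowed variance (verified by a
Parseval check in the tests).

Coherency is the normalised cross-spectrum `C(f) = S_ab / sqrt(S_aa S_bb)`.
Two summaries coexist deliberately:

* **Per-window coherograms** average the cross-spectrum over the 4 tapers
  of one window. With only `m = 4` degrees of freedom, the magnitude has a
  large positive bias for independent signals:
  `E|C| = (sqrt(pi)/2) * Gamma(m) / Gamma(m + 1/2) ≈ 0.457` (exposed as
  `coherence_bias_floor()`). This is the natural scale for *instantaneous*
  coherence series and distance-binned coherence profiles, where baseline
  values around 0.46–0.53 are expected.
* **Pooled spectra** (`coherence_spectrum()`) sum taper cross- and
  auto-spectra over all retained windows before normalising, giving
  `windows × tapers` degrees of freedom and a bias floor shrinking as
  `1/sqrt(dof)`. This is the right estimator for session-mean coherence and
  is the one validated against the mixing oracle to ±0.03.

Coherence is reported as the **magnitude** of coherency (not
magnitude-squared); a `squared` switch exists. The **imaginary part** of
coherency is computed alongside magnitude as the volume-conduction control:
any zero-lag mixture has `Im C = 0` in expectation, so a coupling that
survives in the imaginary part cannot be passive field spread. On pink,
LFP-like spectra the 4th taper's leakage correlates the taper estimates
slightly, raising the measured per-window floor to ~0.52; on white signals
the measured floor matches the analytic value to three decimals.

Mean power spectra are z-scored **across frequency bins** within
0.1–500 Hz, which removes inter-animal and inter-region scale and makes a
hippocampal theta peak read as a large positive z. The 48–52 Hz band is
masked (open interval, so a low-gamma band ending exactly at 48 Hz is
untouched) from coherence outputs because the notch leaves a spurious
structure there.

## Behaviour

Speed comes from 30 Hz position tracking: positions are smoothed with a
0.5 s moving average (tracker jitter otherwise inflates finite-difference
speed — the smoothing constant is our choice, sized to a few tracking
samples), differentiated centrally, and block-averaged onto the 10 Hz
window-centre grid of the spectrograms. Active movement is defined as
speed > 3 cm/s sustained for at least 4 s; "sustained" is read strictly
(any sub-threshold sample ends the epoch), with an optional
`dip_tolerance` documented for users who want to bridge single-sample
dips. Epoch detection is tested for exact equality with a per-sample scan.

On the linear track, each inter-reward traversal is one run. Runs
containing a mid-track turnaround (along-track reversal > 2 cm) are
flagged `non_monotonic` but kept, since early-training exploratory sessions
are analysed despite non-ballistic paths. Distance to the upcoming reward
is signed negative on approach and 0 at the reward. Any 10 Hz series is
averaged by distance in 1 cm bins weighted by time spent (occupancy
normalisation), so a bin visited often at low speed is not over-counted;
occupancy totals are conserved to within one sample per session. Pooled
summaries average occupancy-weighted values over the −60 to −20 cm
approach window. Per-day summaries are the mean of the (three) sessions of
a day, and hemisphere averaging — applied after per-hemisphere coherence
computation — passes a single hemisphere through unchanged when the other
electrode is off target.

## Statistics

The speed-correlation test is a shuffle bootstrap: Spearman rank
correlation (average ranks on ties) between an instantaneous series and
speed on the masked 10 Hz grid, against a null of 1000 whole-vector
permutations of the speed samples; the empirical 0.025/0.975 quantiles are
the confidence limits and significance means falling outside them. The
whole-vector permutation is exact only for exchangeable samples: strongly
autocorrelated series (and 90%-overlap band-power series are strongly
autocorrelated) widen the true null beyond the permutation null, inflating
the type-I rate. We document this rather than hide it: the calibration
test drives the procedure with exchangeable series, where it attains
0.05 ± 0.02, and a circular block-shuffle option (`block_s`) is provided
as the conservative alternative for autocorrelated data.

Distribution-shape summaries report adjusted Fisher–Pearson skewness, a
standard normality test (Shapiro–Wilk up to its n = 5000 implementation
limit, Anderson–Darling beyond), and a smooth-density modality note —
histogram bin noise would otherwise masquerade as extra modes.

## Phase locking and photo-identification

Hippocampal theta phase is the analytic-signal (Hilbert) phase of the
zero-phase 6–12 Hz band-passed LFP, with 0 rad at the oscillation peak and
±π at the trough. Spike phases are looked up at the nearest sample; the
circular mean angle and resultant length R feed the Rayleigh test using
the standard approximation `p = exp(−Z)(1 + (2Z − Z²)/(4n))`, `Z = nR²`,
verified in the tests against a Monte-Carlo uniform null to ±0.01. Units
with fewer than 10 usable spikes return a flagged insufficient-data row.

Photo-identification builds a trial-averaged PSTH in 10 ms bins,
z-normalised against the mean and SD of the 1 s pre-illumination baseline.
The classification statistic is the **mean z over the illumination
window** against ±1.96; a per-bin any-crossing rule is available but has a
~40% nominal false-positive rate over ten bins (1 − 0.95¹⁰), which is why
mean-z is the default — its nominal level is essentially zero, and the
Monte-Carlo calibration in the acceptance tests confirms both. Simple and
complex spikes are pooled.

## The synthetic generator

`generate_session()` emulates exactly the statistical structure the
analysis assumes, with exact ground truth:

* **Coherence by construction.** All channels are synthesised in the
  frequency domain from a single shared theta source: the reference
  (first hippocampal) channel's 6–12 Hz content *is* the source, and every
  other channel mixes source and private theta-shaped noise as
  `c·U + sqrt(1 − c²)·V`, so its in-band coherence with the reference is
  exactly `c`, flat across the band, regardless of the channel's spectral
  envelope (strong theta bump for hippocampus, weak for cerebellum, on a
  pink background). Coherence between two non-reference channels is the
  product of their targets; an explicit pair target inconsistent with that
  single-source geometry is rejected as non-realizable.
* **Contamination.** A common-phase 50 Hz sinusoid at configurable
  amplitude, and Gaussian-windowed 0.5–5 Hz bursts at 10–20× signal SD at
  a configurable events-per-minute rate, with ground-truth intervals
  (±2 SD of the envelope — the energetic core) returned for round-trip
  tests.
* **Behaviour.** Home-cage mode: bout-structured 2-D exploration whose
  speed distribution straddles the 3 cm/s threshold. Linear-track mode:
  runs between two 5 cm goal zones 10 cm from the ends of a 1 m track,
  either goal-directed (accelerate–plateau–decelerate, ~20–30 cm/s
  plateau) or exploratory (4–9 cm/s, occasional turnarounds); rewards fire
  at goal-zone entry. Sessions default to 12 min.
* **Spikes.** Inhomogeneous Bernoulli thinning with von Mises intensity
  `∝ exp(κ cos(φ − μ))/I₀(κ)` against the *generating* source phase (not
  an analysis-side filter), so recovery tests are genuinely end-to-end.
* **Seeding.** One master seed; sub-seeds per stream; the caller's RNG
  state is saved and restored, so generation never perturbs user code.

For the end-to-end ordering check, the generating theta-coherence targets
are Crus I = 0.35 and lobule II/III = 0.10 against the hippocampal
reference. These were calibrated through the per-window estimator's
response curve so that the *measured* distance-pooled values (~0.56 vs
~0.52 on the 4-taper scale) reproduce the contrast observed between the
corresponding session-20 medians in goal-directed navigation (0.525 vs
0.461); the generator emulates the measured phenomenon, not the raw
numbers.

What the generator does **not** emulate — and hence what passing tests do
not certify about real data: non-stationary theta bouts and the negative
skew of sustained hippocampal theta power, cross-frequency coupling,
behaviour-locked spectral changes other than those imposed, realistic
volume-conduction geometry (the zero-lag control is constructed, not
modelled from tissue), electrode drift, and spike-sorting errors (spike
times are inputs by contract).

## Numerical choices and problem sizes

Windows shorter than the analysis window raise degenerate-input errors
rather than returning truncated estimates. Excluded windows propagate as
missing values and never contribute to averages; spectrogram bookkeeping
is tested so that masking a segment leaves all other windows bit-identical.
Zero-phase filters use reflection padding (~1 s) to confine edge
transients. The test and acceptance suites run sessions of 2–12 min and
Monte-Carlo batches of 100–500 replicates — sizes chosen so that each
check's sampling error sits well below its tolerance (e.g. 1530 windows
for the ±0.03 coherence oracle, where the theta band contributes only ~3
independent bins per window); Monte-Carlo replicates are drawn from a
single RNG stream because consecutive integer seeds proved not to behave
as independent draws at the precision these calibrations need.

## Known limitations

The EMG-based fallback for defining active movement (used in the original
setting when tracking failed for one animal) is out of scope: thresholds
are not specifiable from the available description, so epoching requires
tracking. Group-level omnibus statistics (ANOVA, Friedman, Kruskal–Wallis,
FDR post-hocs) are standard procedures deliberately left to `stats::` and
friends rather than re-implemented. The shuffle null's exchangeability
caveat above applies to any strongly autocorrelated instantaneous series.
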