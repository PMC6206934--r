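---
title: "Phase-synchrony connectivity and motor-imagery decoding with plvbci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-synchrony connectivity and motor-imagery decoding with plvbci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(plvbci)
```

## The problem

Motor-imagery (MI) brain–computer interfaces decode which limb movement a
user is imagining from their EEG. Most decoders rely on amplitude features
(sensorimotor-rhythm desynchronization, common spatial patterns). `plvbci`
implements an alternative built entirely on *phase synchrony*: the degree to
which the instantaneous phases of two recording sites keep a systematic
relation over time. The working hypothesis is that imagery of a left versus
right hand movement transiently reorganizes the cortical network, and that
this reorganization is visible as band-specific, pair-specific phase
locking in the sensor space — particularly strongly in users whose motor
system has undergone long-term reorganization, such as patients with
neuromuscular disease.

The package covers the full stack: preprocessing, static and time-resolved
phase locking value (PLV) connectivity, weighted-graph network metrics,
permutation-thresholded screening of discriminative couplings, a bank of
latency-specific linear SVM decoders combined into a time-lagged ensemble,
a radial-basis "switch" that detects MI events in the streaming ensemble
readout without an external trigger, and cohort-contrast statistics. A
seeded synthetic-data generator plants known couplings so every stage can
be validated without access to patient recordings.

## The connectivity model

For a pair of band-limited signals $x_k(t)$, $x_r(t)$ with Hilbert phases
$\varphi_k(t)$, $\varphi_r(t)$, the phase locking value over an integration
window of $n$ samples is

$$\mathrm{PLV}(x_k, x_r) \;=\; \frac{1}{n}\,
  \Bigl|\sum_{t} e^{\,i(\varphi_k(t) - \varphi_r(t))}\Bigr| ,$$

the modulus of the time-averaged unit phasor of the phase difference: 1 for
perfect locking, near 0 for independence (the null expectation for $n$
independent phases is $\sqrt{\pi}/(2\sqrt{n})$, the Rayleigh resultant).
`plvMatrix()` computes all $N(N-1)/2$ pairs in one pass by accumulating the
outer product of per-sample unit phasors; `vecW()` exposes the row-major
upper triangle ("vec(W)"), the feature space for all decoding. For 61 good
sensors that is 1830 couplings.

Time-resolved connectivity (`slidingConnectivity()`) confines the
integration to overlapping windows whose width follows the *cycle
criterion*: 3 cycles of the band's lowest frequency (0.75 s for theta,
0.375 s for lower alpha). Windows advance by 350 ms for cued decoding and
by 20 ms for streaming analyses; the phase is extracted once per epoch and
the windows slice the accumulated phasor series, so no per-window Hilbert
edge effects arise. Since windows advance by whole samples, the effective
step (stored on the object) is `round(step*fs)/fs`.

Preprocessing follows the conventional chain: zero-phase third-order
Butterworth filtering of the *continuous* recording (wideband 0.5–45 Hz,
then one of seven rhythms: delta 1–4, theta 4–8, alpha1 8–10, alpha2
10–13, beta1 13–20, beta2 20–30, gamma 30–45 Hz), average re-referencing
over the good channels once on the wideband signal, then band-splitting and
epoching. Zero-phase filtering uses odd-reflect padding of three filter
lengths to suppress edge transients. Artifact removal by independent
component analysis is out of scope: the package accepts pre-cleaned input
and a bad-channel list (a variance-based flagger is provided as a
convenience, not an authority).

## Network metrics

`nodeStrength()`, `globalEfficiency()` and `localEfficiency()` characterize
a PLV graph as a weighted network. Couplings are turned into distances
$d = 1 - w$ (weights capped at $1 - 10^{-6}$ so a perfect coupling cannot
produce a zero distance) and shortest paths are computed with Dijkstra's
algorithm. Global efficiency is the mean inverse shortest-path length over
ordered pairs; disconnected pairs contribute zero. Local efficiency
restricts the computation to each node's neighbourhood subgraph (intra-
subgraph edges only, the Latora–Marchiori formulation) and averages over
nodes; nodes with fewer than two neighbours contribute zero. PLV graphs are
dense, so no weight thresholding is applied.

## Screening temporally consistent couplings

The discriminative power of each coupling is the absolute standardized
two-sample rank-sum statistic $|z|$ (Wilcoxon criterion), computed per
latency of the stepping window (`timeIndexedScores()`). Because the number
of candidate features (pairs × latencies) vastly exceeds the number of
trials, selection is conservative and three-fold:

1. **Permutation threshold.** Class labels are shuffled `nRand = 100`
   times; the pooled distribution of null scores over all pairs, latencies
   and permutations defines the 99.9th-percentile threshold
   (p < 0.001). Pooling is global rather than per-latency: one threshold
   for the whole score field. One hundred permutations give a stable
   pooled 99.9th percentile because the pool is features × latencies ×
   permutations, typically millions of values.
2. **Temporal consistency.** The supra-threshold mask is sieved row-wise
   with a running median whose half-width spans at least 100 ms (11 taps
   at the 20 ms step, 3 at 350 ms), eliminating couplings that flicker
   above threshold for shorter than that. The per-pair profile is the
   latency count of the sieved mask.
3. **Bootstrap aggregation.** Trials are resampled with replacement within
   class `nBoot = 30` times; each resample's profile is computed with the
   same threshold and the profiles are averaged. A pair enters the final
   fixed feature set if its average profile exceeds the selection floor.

The selection floor deserves a note. The profile is a latency *count*
(0 .. $N_\tau$), so the floor is expressed in the same units:
`max(0.5*(medianWindow+1)/2, 0.1*N_tau)` — a pair must persist, in the
bootstrap-averaged sense, for at least a tenth of the trial's latencies
(and never less than half a minimal sieve-surviving run). We found that a
small constant floor admits *marginal* couplings that flicker above the
threshold for a few percent of latencies; beyond diluting the decoders,
such an unbalanced feature set biases the streaming readout on baseline
data (a rest pattern then sits firmly on one side of the member
hyperplanes), which inflates false alarms in self-paced operation. The 10%
floor operationalizes "stable" and keeps the selection balanced; on
calibrated synthetic data it returns exactly the planted couplings.

The threshold is computed once from the training set and reused across
bootstrap resamples; the resampling quantifies the stability of the score
field, not of the threshold, and re-permuting inside every resample would
multiply the cost thirtyfold for no change in the selected set on our
validation data. If the selection comes back empty (pure-noise input), the
function warns and falls back to the static top-k ranking.

## Decoding

**Static scenario.** One vec(W) per trial, integrated over the full
imagery window. `loocvStaticAccuracy()` runs leave-one-out
cross-validation over the $2N_{trials}$ trials; the top-10 coupling
selection is *re-run inside every fold* on the remaining
$2N_{trials}-1$ trials, so the held-out trial never influences its own
feature set. The per-fold selections are returned for leak auditing.

**Time-indexed scenario.** The fixed coupling set from the bootstrap
screening (selected once, outside the LOOCV, because these features must
be consistent in time) feeds one "instantaneous" linear SVM per latency
(`timeResolvedSvms()`), each validated by LOOCV; the result is an accuracy
curve over latency plus a calibrated classifier bank.

Classifiers are maximum-margin linear separators with fixed regularization
C = 1 and per-fold feature standardization; no hyperparameter tuning, so
results are deterministic. Signed confidence is calibrated as
$2p(\text{right}) - 1 \in [-1, 1]$: a sigmoid (Platt, with regularized
targets so perfect separation still yields finite coefficients) is fitted
to *leave-one-out decision values* of the training fold. Calibrating on
held-out rather than in-sample decision values matters: in-sample
calibration saturates, and a saturated member emits confident nonsense on
baseline (off-manifold) input, which poisons the streaming readout
downstream.

## The SVM-ensemble and the self-paced switch

Members of the ensemble (`buildEnsemble()`) are local maxima of the
accuracy curve within 90% of its maximum, visited in decreasing accuracy
order and kept greedily subject to (a) pairwise lag separation of at least
one window width — members must not "collide" on overlapping integration
windows — and (b) hyperplane dissimilarity: a candidate whose normal has
|cosine| ≥ 0.95 with a kept member duplicates it and is dropped. Member
lags can additionally be confined to the early part of the trial
(`maxLagSeconds`, default 2 s in the self-paced trainer): the streaming
trace is truncated by the largest lag, and late members smear partial
alignment into the pre-onset region, so early members both keep the trace
long and the response speedy.

The streaming readout (`ensembleReadout()`) evaluates every member at
every latency of the incoming vec(W[τ]) stream and combines them as

$$z_{\mathrm{ensemble}}(t) \;=\; \frac{1}{M}\sum_{i=1}^{M}
   z^{i}(t + \tau_{\mathrm{sel}_i}),$$

the mean of the member confidences read at their own lags: near a true
event onset all members align with their trained latencies and agree;
elsewhere they decorrelate and the average shrinks roughly as
$M^{-1/2}$.

The switch (`trainSwitch()`) is a radial-basis-kernel binary SVM over
0.5 s segments of the readout trace. MI-event segments are drawn from the
designated post-onset interval (default 0.2–2.0 s, five per trial → 100
from 20 trials); an equal number of baseline-state segments is drawn half
from the rest traces (anywhere) and half from the pre-cue fixation of the
MI traces, so the switch sees the baseline state both in isolation and as
it appears immediately before an event (including the partial-alignment
ramp). `streamDecode()` slides segments along a test trace, merges
consecutive supra-threshold positions into one detection (direction = sign
of the classification index at the confidence peak), and discards
supra-threshold flickers shorter than one segment width — a genuine
imagery event holds the readout pattern for on the order of a second, and
this persistence rule is the same principle the screening applies at the
feature level. `monteCarloSelfPaced()` repeats the entire two-stage
pipeline over randomized 10-per-class train/test partitions and averages
per-trial false-positive and false-negative rates across splits.

## Group statistics

`compareCouplings()` contrasts subject-averaged connectivity patterns
between two cohorts with per-coupling Wilcoxon rank-sum tests,
Benjamini–Hochberg FDR correction at α = 0.05, and a median-difference
map whose sign encodes the direction. Patterns must first be confined to
the sensors good in *all* subjects (`commonGoodSensors()`).
`compareNetworkMetrics()` does the analogous contrast for trial-averaged
strength/GE/LE triads with Bonferroni correction across the whole
metric × band × condition family (the family definition is a documented
default; the underlying tests are exposed so other families can be
assembled). `rankSumCompare()` is the generic two-group utility with a
one-tailed option.

## What the synthetic generator emulates — and what it does not

`simulateRecording()` reproduces the study design the pipeline targets: 61
channels (10–10 montage) at 256 Hz, 40 cued trials (20 per class; 3 s
fixation + 5 s imagery) and a 3-minute rest recording cut into 20
non-overlapping 8 s baseline trials. Each channel carries one narrowband
component per rhythm — a *band-limited complex Gaussian process*
synthesized in the frequency domain, so its spectrum is exactly confined
to the band and its Hilbert phase is well defined — plus 1/f background
noise at a configurable SNR (default 10 dB total oscillation-to-noise).
A scheduled coupling replaces both channels' band component during the
scheduled window by the unit-power mixture

$$A = \frac{(1-\kappa)\,A_{\mathrm{own}} + \kappa\,A_{\mathrm{latent}}
      e^{i\varepsilon}}{\sqrt{(1-\kappa)^2 + \kappa^2}},$$

with a shared latent process, per-channel Gaussian phase jitter
$\varepsilon$ and mixing weight $\kappa \in [0,1]$; windows are entered
and left through 0.1 s raised-cosine ramps. κ = 1 with zero jitter gives
PLV ≈ 1; κ = 0 leaves channels independent. The unit-power normalization
is essential: without it a coupling would also dip the channel's band
amplitude, making every pair touching a coupled channel class-informative
— an artifact, not phase coupling.

We deliberately chose this process over a frequency-modulated cosine with
a random-walk phase. A random-walk oscillator at the band's centre
frequency leaves *uncoupled* same-band pairs phase-locked over
multi-second windows (their phases drift too slowly apart); per-channel
detuning fixes that on average but creates persistent near-collision
pairs, and stronger phase diffusion broadens the spectrum beyond the band.
The Gaussian process has an exchangeable null — about 0.3 for a 2 Hz
bandwidth over a 4 s window, exactly the $\approx\!1/\sqrt{B T}$ behaviour
theory predicts — with no privileged pairs.

What the generator does *not* emulate: volume conduction and a head model
(couplings are planted directly between sensors), eye/muscle artifacts,
non-stationary background, inter-subject variability of montage quality.
Passing recovery tests therefore demonstrates that the algorithms do what
they claim on data with a known ground truth; it does not certify
performance on real recordings.

A note on band choice for validation. Within one window the phase of any
band-limited process decorrelates at a rate set by its relative bandwidth;
with the cycle-criterion window of $3/f_{\mathrm{low}}$ the number of
independent phase segments per window is $3\,B/f_{\mathrm{low}}$. For
lower alpha that is 0.75 — the per-window null PLV is high for *any* pair
and single-window contrast is weak — while for theta it is 3. The
validation subject therefore plants theta-band couplings (five per class
on disjoint sensor pairs, κ = 0.8, jitter 0.02 rad, active 0.3–4.5 s
after the cue, on a 20-channel montage); real users show their best rhythm
subject-specifically, and the package treats the band as a free parameter
throughout.

## Numerical choices and degenerate inputs

* Rank-sum scores: ties handled by midranks with the tie-corrected
  variance; all-tied features score 0. The vectorized implementation is
  tested against exhaustive permutation-distribution moments.
* Static top-k ties break by ascending pair index (stable selection).
* PLV is clipped to [0, 1] against floating-point overshoot; the matrix is
  symmetrized and given a unit diagonal.
* Weight cap $1-10^{-6}$ before the distance transform; disconnected
  pairs contribute 0 to efficiency; sub-two-node neighbourhoods give
  LE(k) = 0.
* Constant channels have undefined phase and are flagged with a warning.
* Sliding windows are truncated at the trial end (no partial windows);
  steps are rounded to whole samples and the effective step is stored.
* All randomness flows from one master seed through per-trial sub-streams
  (`sample.int` derived, kept below 2^31); identical configuration and
  seed give bit-identical recordings and pipeline artifacts.

## Problem sizes used for validation

The shipped tests validate the stack at desk scale, chosen once: the
20-channel separable subject described above for recovery checks (static
LOOCV, screening recovery, latency localization at the 350 ms step), two
Monte-Carlo splits of the full two-stage self-paced pipeline at the 20 ms
step, and an 8-channel subject with a 60 ms streaming step for end-to-end
determinism. Statistical calibration checks use pure-noise pattern sets
with 9000 feature–latency cells and 100 permutations. The generator's
*defaults* remain the full study design (61 channels, 20 trials per
class); nothing in the code depends on the reduced sizes.

## Known limitations

* Sensor-space PLV is blind to volume conduction; zero-lag leakage
  inflates couplings between neighbouring sensors on real data. Leakage-
  robust estimators (PLI, wPLI, orthogonalized envelopes) are out of
  scope.
* The self-paced evaluation treats epoched rest trials as stand-ins for
  continuous idle streaming — a proof-of-concept protocol, not a live
  system.
* LOOCV on 40 trials has high variance; per-latency accuracy curves are
  noisy and the ensemble's peak picking inherits that noise.
* The switch's per-segment decisions are temporally correlated (window
  overlap), so per-trial false-alarm rates, not per-segment ones, are the
  meaningful unit.
* Classic EDF carries no annotations; events travel in a JSON sidecar.
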