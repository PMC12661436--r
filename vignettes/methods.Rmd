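---
title: "Models and methods behind optoentrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind optoentrain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optoentrain)
```

optoentrain analyses electrophysiological sessions recorded during
pulsatile optogenetic stimulation and operant behavior: spike-phase
locking to a pulse-train clock, spike-triggered averages and normalized
spike-field coherence, firing-rate modulation classification, LFP gamma
band-power comparisons across behavioral states, and
discrimination-learning statistics. A synthetic session generator with
known ground truth backs every stage, so each analysis can be validated
by parameter recovery rather than by eyeballing real recordings. This
vignette documents the models, the defaults and their units, the
numerical choices, and the limits of what the synthetic validation can
show.

## Session model

All data live in a `session`: continuous signals (LFP channels with a
sampling rate and region tag), sorted spike trains, stimulation pulse
trains (on/off intervals plus nominal frequency and duty cycle),
behavioral trial blocks, and press/reward events. Every timestamp is in
seconds on a single session clock with origin at the start of the
recording; a single clock avoids the alignment bugs that plague
multi-stream analyses. Bundles on disk are language-neutral and
bit-exact: a JSON manifest, tab-delimited event tables, and signals as
little-endian float64 binary with the dtype and sample count declared in
the manifest. Spike times closer than 1 microsecond — a spike-sorter
artifact, not physiology — collapse to one event with a warning rather
than crashing downstream stages.

## Spike-phase locking

Spike phases relative to pulsatile stimulation at frequency $f$ are

$$\varphi = 2\pi f\,(t_{sp} - t_0) \bmod 2\pi,$$

with the origin $t_0$ at the first pulse onset of the analyzed
stimulation train and phases computed only within stimulation epochs,
because the formula is meaningful only on the stimulus clock. With a 50%
duty cycle the light-on interval maps to $[0, \pi)$, so a circular mean
below 180 degrees marks a unit driven while the laser is on and a mean
at or above 180 degrees marks light-off (rebound) firing; the boundary
is excluded from light-on by the half-open convention used everywhere in
the package. Uniformity is tested with the Rayleigh statistic
$Z = nR^2$, where $R$ is the resultant length, using the standard
small-sample-corrected approximation
$p = \exp\!\big(\sqrt{1 + 4n + 4(n^2 - R_n^2)} - (1 + 2n)\big)$ with
$R_n = nR$. The suite verifies this approximation against a Monte-Carlo
permutation null and confirms that its p-values are uniform under
uniform phases. Phase histograms default to 18 bins (20-degree bins,
the granularity of a typical rose plot); locking is assessed per
frequency condition with no pooling across frequencies.

## Spike-triggered average and spike-field coherence

The STA is the pointwise mean of 200 ms LFP epochs centered on each
spike (spikes without full coverage are dropped and counted). The
spike-field coherence divides the power spectrum of the STA by the mean
of the epochs' power spectra on the same grid:

$$\mathrm{SFC}(f) = \frac{P_{\mathrm{STA}}(f)}{\bar P(f)}.$$

Because averaging attenuates any component not phase-locked to the
spikes, this ratio is bounded in $[0, 1]$: 1 means perfect locking, and
independence gives an expected value of about $1/n_{\mathrm{epochs}}$.
Two numerical choices matter here. First, the "power of the STA" reading
(rather than amplitude) is what makes the ratio bounded and
scale-invariant, yielding testable invariants; the suite fuzz-tests the
bounds and the invariance to global amplitude scaling. Second, epochs
carry $2\,\mathrm{round}(h r) + 1$ samples for half-window $h$ and rate
$r$ (an odd count, centered on the spike), while spectra are computed on
the first $2\,\mathrm{round}(h r)$ samples so the frequency grid is
exactly $k/2h$ — 5 Hz steps for 200 ms epochs — and the 35 Hz control
frequency lies on the grid with no interpolation. Epochs are
rectangular-windowed (no taper), keeping the estimator as bare as the
procedure it implements. Target-versus-control comparisons (40 vs 35 Hz)
split a unit's spikes into contiguous equal-spike-count segments
(default 10, equalizing estimator variance across segments), compute the
SFC per segment, and apply the normality-gated paired test; a population
test applies the Wilcoxon signed-rank to per-site mean differences.
Spikes and LFP may come from the same electrode vicinity; no
spike-removal or interpolation is applied to the LFP, so bleed-through
of spike energy into the field is a known caveat.

## Modulation classification and the gated test

Pulses are grouped into stimulation trains (a gap longer than 1.5
periods starts a new train); the train is the pairing unit. Rates during
each train are paired with rates in an equal-duration window immediately
preceding it — matched duration removes rate-estimator bias, since the
procedure itself only fixes "baseline". The comparison applies both the
Lilliefors and Anderson–Darling tests to the paired differences at level
0.05 (the gate's level is fixed by convention, independent of the test
level); only if both fail to reject normality is a paired t-test used,
otherwise the Wilcoxon signed-rank. The Anderson–Darling implementation
requires at least 8 observations; with 5–7 pairs the gate falls back to
Lilliefors alone. A unit is `excited` or `inhibited` only when the test
is significant, with the direction taken from the mean rates. The
transient classifier applies the same machinery to only the first 100 ms
of each train, capturing the transient-inhibition-then-excitation
profile typical of targets of GABAergic pallidal input. Type-I error of
the whole pipeline on unmodulated Poisson units is verified at the
nominal 5% within ±1.5 points over 2000 simulated units. Counts of
response classes are compared with a plain Pearson chi-square
goodness-of-fit without continuity correction; depth profiles bin
stimulation sites into half-open 0.5 mm bins anchored at the shallowest
site rounded down, then run a one-way ANOVA of evoked rate increase on
bin.

## LFP band power

Signals are decimated to 200 Hz through multistage zero-phase
Butterworth filtering (order 6 per stage, forward–backward, cutoff at
0.8 of each stage's output Nyquist, reflection padding against edge
transients), giving a final passband edge of 80 Hz — comfortably above
the 40–60 Hz gamma band and below the 100 Hz output Nyquist. Only
integer decimation factors are supported; the canonical 25 kHz
acquisition rate divides evenly. The decimated signal is cut into
non-overlapping 1 s epochs (trailing remainder dropped). An epoch is
rejected when any sample deviates from the signal median by more than 6
robust SDs (1.4826 × MAD) or contains three or more consecutive
identical extreme values (amplifier saturation); median/MAD statistics
keep large artifacts from masking their own detection. Per-epoch
periodograms are computed on demeaned epochs and normalized so the sum
of the spectrum over the grid equals the epoch variance (Parseval,
verified to 1e-6 relative); at 1 s epochs and 200 Hz the grid is 0–100
Hz in 1 Hz steps, and band power is the mean spectral value over the
inclusive 40–60 Hz band. High and low lever-pressing epochs are defined
by a 10 s window centered on each epoch: at least 2 presses is high,
zero presses is low, and anything between is excluded — the criterion
itself is not fixed by the procedure this package implements, so the
parameters are explicit and the exclusion band keeps the contrast
conservative. Comparisons use the test that matches the design:
epoch-level high-versus-low by Wilcoxon rank-sum, session-level paired
contrasts by signed-rank, and region-by-schedule families by sign tests
with Bonferroni correction over the family size. Trial-block (S+ versus
S−) analyses assign each kept epoch to the block containing its center.

## Operant behavior and learning statistics

The schedule engine implements CRF (every press rewarded), FR($k$)
(every $k$-th press), and VI(mean, jitter): an interval drawn uniformly
from mean ± jitter arms the schedule — the first draw at $t = 0$, each
subsequent draw at the preceding reward — and the first press after
arming is rewarded. The VI30 protocol uses mean 30 s, jitter 5 s; the
uniform reading of "± jitter" is the simplest bounded interpretation of
an interval stated as a center and range. Cumulative records step at
each press and reset after 50 presses, so the local slope reads out
press rate. Discrimination performance is percent correct
$100\,S^+/(S^+ + S^-)$ computed independently per condition set from raw
press counts (block durations are equalized by design; a rate-based
variant is available). Learning stages are the first, middle, and last 7
training days, the middle stage centered on the median day.

Stage-level inference is a two-way repeated-measures ANOVA for condition
(opto vs control) and training day. The replication unit is explicit:
the default `unit = "day"` averages over subjects and fits the 2 × 7
table without replication, matching the F(1, 6) degrees of freedom such
designs report, at the cost of an inestimable interaction; `unit =
"subject"` fits the full within-subject model with both factors and
their interaction. No sphericity correction is applied by default.
Conditional residuals are checked with a Lilliefors test, reported
alongside the F statistics. The F values of both branches are verified
against brute-force sums-of-squares oracles computed from the
definitional formulas, and the null rejection rate of the condition
effect is calibrated at 5% ± 1.5 over 2000 simulated null learning
curves.

## The synthetic session generator

Every generator is a pure function of its parameters and a seed
(bit-identical on repeat), and returns its ground-truth components
alongside the composite so recovery tests never re-derive truth from the
mixture.

Spikes are inhomogeneous Poisson processes sampled by thinning, which is
exact for any bounded rate function. Archetypes: `excited_on` (elevated
during light-on), `inhibited` (baseline scaled by 1 − suppression during
light-on), `rebound` (suppressed during light-on, an added rebound rate
for a window after each light offset), `md_biphasic` (suppressed for the
first 100 ms of each train, elevated for the remainder), and
`unmodulated`. The excited gain follows a normalized exponential
onset-adaptation profile within each pulse (time constant 0.25 of the
on-width; the normalization keeps the mean on-rate at exactly baseline +
gain). This shape was chosen deliberately over a flat on-rate: real
light-driven units fire onset-locked, adapting volleys, and the choice
is not cosmetic — a perfectly flat on-rate makes the spike-phase
density a half-cycle boxcar whose spectrum has an exact null at $2f$, so
the first SFC harmonic of the stimulation frequency (80 Hz under 40 Hz
drive) would vanish from the spike-triggered average no matter what the
LFP contains. `onset_shape = "flat"` restores the idealized profile.

The synthetic LFP sums 1/f-amplitude Gaussian noise, a pulse-locked
oscillation at the stimulation frequency with harmonics at $2f$ and $3f$
at $1/k$ amplitude (the evoked deflection of a square light pulse has
distinct onset and offset transients, hence energy at every multiple of
$f$), behavior-gated gamma (default 50 Hz, within the 40–60 Hz band)
whose amplitude is multiplied per behavioral state, and sparse
high-amplitude impulse artifacts. A 2:1 amplitude gate therefore
produces a 4:1 band-power contrast, which the suite verifies.

Operant sessions draw presses from a Poisson policy (press-rate
magnitudes on interval schedules are free parameters — no canonical
value exists for them) and pass them through the schedule engine. Trial
sequences enforce equal counts per type, no type more than 3 in a row
(by rejection sampling, so violations are impossible), durations uniform
on 60 ± 3 s with the same duration multiset assigned to every type
(equalizing total time per type exactly), and inter-trial intervals
uniform on 1–4 s — an ITI stated elsewhere as "1 ± 3 s" would allow
negative durations, so the package uses the positive reading. Learning
curves rise logistically from chance (50%) to an asymptote with
Gaussian session noise; an opto condition adds a stage-specific effect
in percentage points, clipped to [0, 100].

What the generator does not emulate: refractoriness or bursting
statistics beyond the rebound window, spike-waveform or sorting noise,
non-stationary baselines, volume-conducted artifacts correlated across
channels, phase-amplitude coupling, or any acoustic property of the
discrimination stimuli. Recovery tests passing on these synthetics
therefore certify the analysis code — its estimators, conventions, and
calibration — not the biological claims one might draw from real
recordings.

## Problem sizes and determinism

The validation suite runs at desk scale on one CPU: 2000 replicates for
the type-I calibrations of modulation classification, the rm-ANOVA
condition effect, the band-power comparison, and the Rayleigh p
uniformity check; 500 replicates for the unmodulated phase-locking null;
200 seeds for the end-to-end gated-gamma and stage-specific learning
recoveries (at least 90% and 80% recovery respectively); and 120 s
sessions with ≥ 500 spikes for spike-field coherence peak recovery.
Master seeds derive per-stage sub-seeds through a fixed counter scheme
(`derive_seed`), so any stage can be rerun independently and full
pipeline runs are byte-identical under a repeated seed.

## Known limitations

The SFC estimator inherits the bias of small epoch counts (expected
value ~ 1/n under independence), so comparisons across conditions should
hold epoch counts comparable — the equal-spike-count segmentation exists
for exactly this reason. The artifact detector targets impulse and
saturation artifacts; slow drifts pass through and should be handled by
the decimation filter's high-pass companion if present in real data (no
high-pass is applied here because the band of interest sits well above
DC). The day-replication ANOVA treats subject-averaged values as
exchangeable across days; with strong subject-by-condition
heterogeneity the subject-replication branch is the safer choice. The
rank-based tests use normal approximations with continuity correction
rather than exact distributions, which is standard at the epoch counts
involved but slightly conservative for very small samples.
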