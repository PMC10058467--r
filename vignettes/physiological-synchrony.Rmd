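---
title: "Measuring physiological synchrony with physync: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring physiological synchrony with physync}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physync)
```

## The problem

When a group of people watches the same movie, heart rate (HR) and
electrodermal activity (EDA) fluctuate in partial lockstep: arousing moments
of the narrative drive transient responses in everyone who is paying
attention. *Physiological synchrony* — the degree to which one person's
signal correlates with the others' — is therefore used as an implicit,
wearable-friendly marker of shared attentional engagement. The practical
questions physync addresses are:

1. how to quantify synchrony from noisy wearable recordings
   (inter-subject correlation, ISC);
2. how to decide whether a participant's synchrony exceeds chance
   (a circular-shuffle permutation test); and
3. how much data — stimulus minutes and participants — is needed before
   that decision becomes robust.

Because real recordings are not required for any of this machinery to be
exercised, the package ships a synthetic cohort generator whose ground truth
(coupling gains, event times, quiz-score linkage) is known exactly, so every
downstream stage can be tested end to end.

## Signal models

### Phasic EDA

A participant's phasic skin conductance during one movie is modeled as

$$
y_i(t) = g_i \, (e_{\mathrm{shared}} * k)(t) + (e_i * k)(t)
       + A\,k(t) + \sigma\,\tilde\varepsilon(t), \qquad y_i(t) \ge 0,
$$

where $k$ is the Bateman-form SCR kernel
$k(t) \propto e^{-t/\tau_d} - e^{-t/\tau_r}$ (unit peak; defaults
$\tau_r = 0.75$ s, $\tau_d = 2$ s, the standard shape of a single
skin-conductance response), $e_{\mathrm{shared}}$ is a homogeneous Poisson
train of stimulus-driven arousal events common to the whole cohort (default
6/min), $e_i$ is an idiosyncratic train (default 3/min), $g_i \ge 0$ is
participant $i$'s coupling gain, and $\tilde\varepsilon$ is white Gaussian
noise smoothed with the same kernel (so the noise is SCR-like rather than
broadband) and rescaled to standard deviation $\sigma$ (default 0.05 µS).
The term $A\,k(t)$ at $t = 0$ (default $A = 2$ µS) reproduces the large
conductance burst at the start of every stimulus, followed by a sharp drop —
the "something new" arousal response routinely seen when a movie begins.
EDA is generated at 32 Hz, matching wrist-worn devices.

### Heart rate

HR is generated at 1 Hz with 1 bpm resolution, matching chest-strap output:

$$
h_i(t) = \mathrm{round}\!\big(b_i + g_i\,\gamma\, d(t) + \eta_i(t)\big),
$$

where $d$ is the shared event train binned at 1 Hz and smoothed with a 10 s
moving average (HR synchrony lives at slower timescales than EDA), $b_i$ is
a resting baseline in [40, 100] bpm, $\gamma$ (`hr_gain_bpm`) converts drive
to bpm, and $\eta_i$ is AR(1) noise with coefficient 0.9 and stationary SD 2
bpm — heart rate is strongly autocorrelated, and the circular-shuffle null
is designed exactly to respect such autocorrelation.

With the default $\gamma = 10$ and unit gains, the mean dyadic HR ISC of a
20-participant, 10-minute epoch is approximately 0.2. That constant was
calibrated once, by simulation, to place the default cohort in the
moderate-synchrony regime that the robustness analyses are meant to probe,
and is not revisited.

### What the generator does and does not emulate

The generator reproduces the statistical structure the analysis relies on —
a shared stimulus-locked component with per-participant gains, SCR-shaped
phasic responses, the onset transient, integer-quantized autocorrelated HR,
and injectable wearable artifacts (electrode signal loss, out-of-range
values, implausible jumps, stuck sensors). It does **not** emulate tonic
EDA drift realism beyond what the phasic-extraction test needs, beat-level
cardiac dynamics, movie-specific content differences, or heterogeneous
attentional states. Consequently, green tests demonstrate that the
*machinery* is correct and calibrated under the stated assumptions; they do
not certify effect sizes on any particular real dataset, where synchrony is
weaker, movie-dependent and less homogeneous across participants.

## Preprocessing rules

All artifact handling is mask-only: values are never altered except by
smoothing and tonic/phasic decomposition.

* **Smoothing** — 3 s Savitzky–Golay filter, polynomial order 2 (order is a
  package decision; it preserves constants and ramps exactly and attenuates
  one-sample quantization spikes).
* **EDA signal loss** — runs below 0.01 µS lasting ≥ 5 s are masked; both
  thresholds are declared, configurable defaults.
* **Phasic extraction** — the tonic level is a 10 s running minimum,
  smoothed with a 10 s moving average; the phasic component is the clipped
  remainder. Full continuous-decomposition (nonnegative deconvolution with
  fitted SCR parameters) is deliberately out of scope: downstream ISC needs
  fast stimulus-locked fluctuations, not SCR parameterization, and the
  running-minimum stand-in is deterministic and cheap to test.
* **HR range rule** — samples above 200 or below 30 bpm are masked (bounds
  inclusive on the plausible side).
* **HR jump rule** — samples differing by more than 25% from the *most
  recent usable* sample are masked. Comparing to the last usable sample
  rather than blindly to $t-1$ stops a single bad sample from cascading.
* **Stuck sensor** — a recording whose consecutive-sample repeats are more
  than 50× as prevalent as changes is excluded outright (all-equal series:
  ratio $+\infty$).
* **Exclusion** — a recording with strictly more than 30% of samples masked
  is excluded entirely ("more than 30%": exactly 30% is retained).
* **Epoching** — movies are half-open windows $[\mathrm{onset},
  \mathrm{onset} + \mathrm{duration})$ on a shared clock; sample $i$
  (1-based) of a rate-$f$ segment sits at $t = (i-1)/f$.

Masked samples propagate into ISC windows as missing values and are never
interpolated — interpolation would manufacture synchrony.

## Inter-subject correlation

For each dyad, Pearson correlations are computed in 15 s windows sliding at
1 s increments over the epoch and averaged (plain mean; Fisher-z averaging
is available behind `iscParams(fisher = TRUE)` but is not the default, and
no lag search is performed — with a common stimulus there is no asymmetry
to capture). Conventions:

* Both modalities are analyzed at 1 Hz; EDA is mean-decimated block-wise
  (a decimated sample is missing when fewer than half its block is usable).
  This gives both modalities identical 15-sample windows.
* Windows are aligned to the epoch start; a trailing partial window is
  dropped. A 60-sample epoch with window 15 and step 1 yields exactly 46
  windows.
* A window is dropped when fewer than 80% of its sample pairs are usable
  (`min_valid_fraction`) or fewer than 3 pairs remain.
* Zero-variance windows yield missing, never 0: a constant signal carries
  no synchrony evidence. Numerically, a window is "zero variance" when its
  centered sum of squares is below $10^{-9}$ of its uncentered magnitude,
  which absorbs the catastrophic cancellation possible with large-mean
  integer HR values.
* The epoch-level ISC is missing when fewer than `min_windows` (default 10)
  windows are valid.
* The N×N matrix computes each of the $N(N-1)/2$ unique dyads once and
  mirrors them; the participant-to-group ISC is the off-diagonal row mean.

The implementation uses rolling cumulative sums ($O(L)$ per dyad rather
than $O(LW)$), which is what makes the 50-shuffle null and the resampling
surfaces affordable; the test suite pins it to a naive double-loop oracle
at $10^{-12}$.

## The circular-shuffle significance test

Under the null hypothesis that a participant's signal is not locked to the
stimulus, rotating it in time changes nothing statistically. Each shuffle
draws an independent shift uniformly from $\{1, \dots, L-1\}$ for every
participant (the identity shift is excluded so true synchrony cannot leak
into the null), rotates all series, and recomputes the full ISC matrix.
After 50 shuffles (the default), participant $i$'s null sample pools their
$N-1$ dyadic values across shuffles; their actual sample is their $N-1$
observed dyadic values. A one-sided Welch $t$-test (actual > null,
$\alpha = 0.05$) flags significant synchrony. Welch rather than pooled
variance because the sample sizes differ by a factor of 50; pooled dyads
rather than participant-to-group scalars because at 50 shuffles the scalar
null would have only 50 points.

Pooled dyads sharing a participant are not fully independent, so exact
nominal calibration is not guaranteed a priori. Measured on 200 uncoupled
synthetic cohorts (20 participants, 10 min, 1 Hz), the long-run fraction of
significant participants is ≈ 5.5% — close to the nominal 5% and well
within the 2α operational bound the test suite asserts; the acceptance
script recomputes this number on every run.

## Robustness to stimulus duration and group size

To ask "how much data is enough", the cohort's six 10-minute movies are
concatenated into 60-minute streams in six counterbalanced orders (the rows
of a 6×6 Latin square; all 720 orders exist behind `allMovieOrders()`, the
Latin-square subset matches standard counterbalanced designs and keeps the
grid tractable), truncated to the first $x$ minutes on the grid {0.5, 1, 3,
5, …, 19, 24, 28, …, 60} (the gap between 19 and 24 is part of the design),
and analyzed in 50 random participant subsets per group size (all distinct
subsets when fewer exist). Each (order × duration × size × subset) cell
reports the percentage of testable participants with significant ISC;
summaries average over orders and subsets and attach the cell's *total
minutes* (group size × duration). Shuffle seeds are derived per cell from
the root seed via `mixSeed`, so cells are independent but individually
reproducible. Participants missing any movie of an order are dropped for
that order, keeping concatenation well-defined.

On homogeneous coupled cohorts this machinery reproduces the qualitative
robustness pattern: the fraction of significant participants is
non-decreasing in both duration and group size, dispersion across subsets
shrinks as groups grow, and — the key collapse property — cells with equal
total minutes agree regardless of whether the minutes came from more people
or longer stimuli.

## Problem sizes used in the shipped checks

The package's own test suite and acceptance script run, as their standard
configuration: 200 null cohorts (20 participants, one 10-minute movie, HR)
for type-I calibration; one coupled cohort (20 participants, six 10-minute
movies) analyzed over durations {1, 5, 20, 40, 60} min × sizes {5, 10, 20}
× 2 orders × 2 subsets at 50 shuffles for power, monotonicity and collapse;
and a heterogeneous-gain cohort (gains 0.4–1.6) for quiz-linkage recovery.
These sizes were chosen as the smallest grids on which the monotone and
collapse properties are meaningfully testable; the full default grid
(6 orders × 21 durations × sizes 2–N × 50 subsets) remains available
through `robustnessSurface()`'s defaults.

## Numerical and degenerate-input conventions

* All randomness flows from one root seed through documented substreams
  (`mixSeed(root, purpose, indices…)`); identical configuration and seed
  give bit-identical outputs, including across the CSV round trip.
* Correlations are clamped to $[-1, 1]$ after the rolling-sum formula to
  absorb floating-point overshoot.
* `testParticipant` returns an explicit untestable result (with a reason)
  when either sample has fewer than 2 values — never a silent pass.
* Constant series: stuck-ratio $+\infty$ and exclusion for HR; missing ISC
  (zero variance) for correlation machinery.
* The quiz linkage clips scores to the 0–10 range of a ten-question recall
  quiz, so extreme gains saturate rather than escape the scale.

## Known limitations

* The phasic extraction is a running-minimum stand-in, adequate for
  ISC-style analyses but not for studies of SCR shape or amplitude.
* The pooled-dyad null trades exact independence for sample size; its
  measured calibration is excellent at the shipped problem sizes, but users
  applying very small cohorts (N ≤ 4) should expect coarser p-values.
* Synthetic cohorts are homogeneous and stationary; real movie data show
  movie-dependent synchrony and onset-transient artifacts that can make
  very short stimulus segments *more* significant than slightly longer
  ones, a pattern the generator reproduces only through its onset term.
* Clock synchronization across devices is out of scope: recordings are
  assumed to sit on one shared clock.
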