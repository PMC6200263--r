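---
title: "Estimating working-memory load and probe-tone ERP modulation in simultaneous interpreting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating working-memory load and probe-tone ERP modulation in simultaneous interpreting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decalage)
```

## The problem

During simultaneous interpreting (SI) the interpreter lags behind the
speaker by a few words — the *décalage* or ear-voice span.  Everything heard
but not yet translated sits in working memory (WM), and the effort of
holding and transforming that buffer competes with the effort of listening.
A standard way to probe the listening side is to embed short, task-irrelevant
pure tones in the speech stream and measure the early auditory evoked
potentials they elicit (P1 around 60 ms, N1 around 100–160 ms): their
amplitude shifts with the attention allocated to the auditory channel.  If
WM load and attention draw on one limited pool, epochs recorded under a
heavy buffer should differ systematically from epochs under a light one.

`decalage` implements that analysis end to end: WM-load estimation from
time-coded transcripts, alignment of the load series to probe onsets,
quantile-based condition labeling, a minimal ERP chain, and the matching
statistics — plus a forward simulator with known ground truth, so every
stage can be validated without access to any recording.

## The load model

Let source word $i$ end at time $o_i$ and let its translation chunk (all
target words sharing its alignment id) end at time $c_i$.  The word is
considered buffered on $[o_i, c_i)$ and contributes a weight $w_i$ there.
Instantaneous load is

$$L(t) = \sum_i w_i \, \mathbf{1}\{o_i \le t < c_i\},$$

with three weighting schemes:

* **CW** — $w_i = 1$ for content words, 0 for function words;
* **CL** — content words weighted by the min–max normalized log corpus
  frequency of their lemma,
  $$\hat f = \frac{\log f - \log F_{min}}{\log F_{max} - \log F_{min}},$$
  where $F_{min}$ and $F_{max}$ are the smallest and largest absolute
  frequency in the reference table;
* **SYL** — every word weighted by its syllable count.

Breakpoints are emitted at each entry/clear event (simultaneous events are
coalesced to their net load) and load at arbitrary times — in particular at
probe onsets, which fall between word offsets — is obtained by linear
interpolation between breakpoints, clamped to the endpoint values outside
the covered range.  Two readings of the event process coexist in the
literature on such piecewise descriptions: a step function that holds its
value between events, and the linearly interpolated series used here for
probe-onset estimation.  The package stores the event-time breakpoints, so
both views are recoverable (`breakpoints()` gives the exact event values);
all probe-onset estimation uses linear interpolation.

Design choices worth knowing:

* **Clear time** is the offset of the *last* target word of the aligned
  chunk — the only observable proxy.  Self-monitoring (a chunk lingering
  after overt translation) and anticipation (translation completed early)
  make any transcript-based estimate noisy; neither is modeled.
* **Never-translated source words** have no observable clear time.  They
  are excluded from the series and counted in the `coverage` attribute;
  keeping them buffered forever would eventually dominate the series.
* **Word scope.** By default CL weights content words only and SYL weights
  all words.  `wordScope = "alternate"` swaps the two scopes, which is the
  other defensible reading of how the three estimators partition words.
* **CL direction.** As defined above, a *more* frequent word contributes
  *more* load, which sits oddly with the motivation that frequent words
  clear faster.  The default implements the definition literally;
  `invertClWeight = TRUE` substitutes $1 - \hat f$.
* **Out-of-vocabulary lemmas** are assigned $F_{min}$ (maximal
  unfamiliarity, $\hat f = 0$) with a warning.
* **Function-word lists** are shipped as explicit text files (English:
  articles, prepositions, auxiliary verbs, "and"; Russian: prepositions,
  "и") and are user-overridable; classification lowercases
  and strips edge punctuation first.  Hyphenated and numeral tokens count
  as content words.
* **Syllables.** Russian syllable count equals the Cyrillic vowel-letter
  count, which is exact.  English uses vowel-group counting with a single
  terminal-silent-e rule, floored at one; it is a heuristic (it undercounts
  e.g. consonant-le words) and `countSyllables(counter = ...)` accepts a
  dictionary-based replacement.

## Condition labeling

Within one subject and one direction of interpretation, a probe epoch is
*low* if its interpolated load falls strictly below the 10% sample quantile
of that session pair's load distribution, *high* if strictly above the 90%
quantile, otherwise *medium*.  Quantiles use the linear-interpolation
estimator (R's default type 7).  The asymmetric 10/80/10 split reflects
that interpreters hold a comfort zone most of the time, so the extremes are
where a load effect is best visible; the boundaries are per subject ×
direction because load distributions differ strongly across both.  Labels
are invariant under any strictly monotone transform of the loads.

## ERP chain

The preprocessing deliberately mirrors a conventional auditory-ERP
pipeline and nothing more: resample to 250 Hz, re-reference to linked
mastoids (TP9/TP10 average), remove per-channel DC, and apply a zero-phase
windowed-sinc FIR band-pass of 0.1–30 Hz.  The filter length follows the
`3.3 / transition-bandwidth` Hamming rule (8251 taps at 250 Hz, i.e. a
±16.5 s settling span), with cutoffs half a transition band outside the
pass band; `firBandpass()` exposes the design and `firResponse()` its
frequency response (50 Hz is attenuated by roughly 100 dB, DC by the
demeaning step).

Epochs cover the half-open window $[-100, 400)$ ms around probe onset —
exactly 125 samples at 250 Hz — and are baseline-corrected over
$[-100, 0)$ ms.  An alternative reading of "500 ms post-stimulus plus
100 ms baseline" as a 600 ms epoch is available through `tmin`/`tmax`.
Artifact handling is a single optional peak-to-peak threshold (default
150 µV in the pipeline): the simulator produces artifact-light data by
design, so ICA/ASR stages are deliberately out of scope, and this is a
documented divergence from what a real-data pipeline would need.

Component measures follow the narrow-window convention: window-mean
amplitude over 40–80 ms (P1, positive) and 120–160 ms (N1, negative),
inclusive at both ends, and peak latency as the extremum inside the window
with ties resolved to the earliest sample (a flat window warns and returns
the earliest sample).  Analyses run on a fixed 21-channel fronto-central
subset; the Anteriority (Front/Center/Back) × Laterality
(Left/Middle/Right) map is a shipped 7/7/7 and 9/3/9 partition of those
channels (`topoMap()`), overridable by a TSV, since no canonical partition
exists.

## Statistics

* **Exact Wilcoxon signed-rank** (`wilcoxonExact`): two-sided, zeros
  dropped; for ≤ 25 untied pairs the p-value comes from the complete null
  distribution of the positive-rank sum over all $2^n$ sign assignments
  (computed by convolution counting, which is exact).  Ties or larger n
  fall back to the tie-corrected normal approximation with continuity
  correction, with a warning.  With nine subjects, all differences in one
  direction give $V = 45$, $p = 2/512 = 0.003906$.
* **Repeated-measures ANOVA** (`rmAnova`): full factorial within-subject
  decomposition with one error term per effect (the effect × subject
  interaction).  Sphericity is handled by the Greenhouse–Geisser epsilon
  estimated from the covariance of orthonormalized within-subject
  contrasts; the table reports uncorrected and corrected dfs and p-values
  side by side, plus partial eta squared.  The corrected test is known to
  be conservative near sphericity in small samples, so calibration
  statements in the test-suite use the uncorrected F (exact under
  sphericity); inference on real effects should quote the corrected
  values.  Missing subject-by-cell values are imputed by the cell mean
  over the remaining subjects, with a warning.  No multiplicity correction
  is applied across the three load estimators.
* **Jackknife** (`jackknifeSubjects`): the analysis is repeated on every
  leave-one-subject-out subset and the monitored effect must be
  significant in all resamples for a `consistent` verdict; per-resample
  failures are recorded, not fatal.

## The simulator

`simConfig()` fixes the study conditions; the defaults are the conditions
the pipeline is validated under, not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| word rate | 105 wpm | the delivery rate of the emulated design |
| probe ISI | U(450, 750) ms | jittered probing, mean 600 ms |
| tone | 440 Hz, 52 ms | probe metadata |
| content fraction | 0.60 | typical running-text content share |
| Zipf exponent | 1.1 | frequency–rank slope of the synthetic lexicon |
| lag process | base 3 words, reflected mean-centred lognormal steps (sdlog 0.6), reversion ρ = 0.9 | stationary, right-skewed, hugging a comfort zone |
| direction offset δ | +1.5 words in L1→L2 | larger buffered lag when working into L2 |
| P1 template | +2 µV, 60 ms peak, 12 ms sd | positive fronto-central bump |
| N1 template | −3 µV, 140 ms peak, 18 ms sd | negative bump |
| modulation | +0.3 / −0.5 µV per load z-unit; +4 ms latency per z | desk-scale effect sizes (the emulated design reports none in µV) |
| noise | 1/f (γ = 1) at 4 µV RMS + 10 Hz alpha at 2 µV RMS per channel | clean, artifact-free background after band-limiting |

Mechanics and rationale:

* **Transcripts.**  Source words sit on a fixed grid (so a 10-minute
  session has exactly 1050 words at 105 wpm).  Content lemmas are drawn
  from a Zipf-distributed 400-lemma vocabulary; surfaces are
  consonant–vowel pseudo-words whose spelled syllable count is exact by
  construction, and function words are sampled from the shipped lists, so
  classification and syllable counting behave on synthetic text exactly as
  on real text.  Each source word's one-word translation chunk is emitted
  after the current lag, making target offsets the observable clear times
  with alignment ids consistent by construction.
* **Lag process.** Mean-centred lognormal steps give right-skewed
  excursions; reflection at zero keeps the lag positive; the reversion
  coefficient keeps the process stationary.  A free random walk would let
  the session median wander with $\sqrt{n}$ and drown the direction
  offset; reversion bounds it, which is also the behaviorally sensible
  model of an interpreter steering back to a comfortable lag.  The load
  distributions this induces are right-skewed in both directions, and the
  +δ offset orders every simulated subject's median CW load by direction,
  reproducing the all-positive signed-rank configuration.
* **EEG forward model.** Each probe adds Gaussian P1/N1 bumps whose
  amplitude is `base + slope · z(load)` and latency `peak + shift ·
  z(load)`, where z-scoring is per session so slope units are comparable
  across methods and sessions.  A fixed gain vector peaking at Fz/Cz
  projects the templates across channels; TP9/TP10 carry noise only, so
  linked-mastoid re-referencing does not subtract signal.  Noise is
  spectrally shaped Gaussian noise (power ∝ 1/f^γ plus a narrow 10 Hz
  alpha bump), independent across channels.
* **What the simulator does *not* emulate:** ocular/muscle artifacts (so
  passing tests say nothing about artifact robustness), spatially
  correlated noise or volume conduction, chunking, anticipation and
  self-monitoring dynamics in the lag, overlapping-ERP distortions beyond
  what the 450–750 ms ISI produces, and acoustic properties of speech or
  probes.  Results on simulated data validate the *computational* chain,
  not the physiological assumptions.

A methodological detail that matters when validating recovery: the
window-mean measure integrates the Gaussian template over a fixed window,
so the slope of the *window mean* with respect to load z is the generative
amplitude slope attenuated by the window-averaging factor (about 0.85 for
the default N1 template) times the channel gain.  Recovery checks
therefore compare the regression estimate against the analytic window-mean
slope derived from `noiselessEpoch()`, not against the raw template
parameter.

## Numerical conventions

* Epoch window half-open, 0 ms = probe-onset sample; baseline indices are
  those with $-100 \le t < 0$ ms.
* Simultaneous load events coalesce into one breakpoint at the net load;
  loads within $10^{-12}$ of zero are snapped to zero.
* Peak-latency ties break to the earliest sample; flat windows warn.
* Quantile labeling uses strict inequalities, so a degenerate (constant)
  load distribution yields all-medium labels rather than arbitrary splits.
* All randomness flows from explicit seeds; one seed regenerates
  transcripts, probe trains and EEG bit-identically, and the pipeline
  manifest records the seed and the MD5 of every output.

## Problem sizes used in the test-suite

The validation suite runs entirely on simulated data at desk scale, chosen
as the package's own verification conditions: sessions of 40–310 s for
unit and recovery tests (about 60–500 probes), 100 seeded sessions for the
N1-recovery check, 500 nine-subject cohorts of 60 s sessions for the
null-calibration check, and 10,000+ ISI draws for generator fidelity.  The
emulated design itself is larger (about 54 minutes of material per
subject); nothing in the code depends on the smaller sizes.

## Known limitations

* The English syllable counter is a heuristic; swap in a dictionary
  counter for serious SYL-based analyses.
* The clear-time policy is the only supported bookkeeping; transcripts
  with heavy reordering or omissions will produce conservative coverage
  (omitted words are dropped, and chunks that finish before their source
  word's offset contribute nothing).
* `rmAnova` expects a balanced within-subject design and imputes rather
  than models missing cells; heavily incomplete designs deserve a
  mixed-effects treatment instead.
* BrainVision is the only EEG interchange format implemented (float32 and
  int16, multiplexed); EDF is not supported.
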