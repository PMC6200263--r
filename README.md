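# decalage

Working-memory (WM) load estimation and probe-tone ERP analysis for
simultaneous interpreting (SI).

## What it is for

When interpreters translate continuous speech in real time, everything
they have heard but not yet translated — the *décalage* or ear-voice span —
sits in working memory. If memory and listening compete for one attentional
pool, the early auditory potentials (P1 ~60 ms, N1 ~120–160 ms) evoked by
task-irrelevant probe tones embedded in the speech should vary with the
momentary WM load. `decalage` is a research pipeline for exactly that
question, aimed at psycholinguists and cognitive neuroscientists working
with time-coded interpreting corpora and probe-tone EEG:

1. **Load estimation.** From aligned source/target transcripts, the
   instantaneous load is
   `L(t) = Σ_i w_i · 1{o_i ≤ t < c_i}`,
   where word *i* is buffered from its own offset `o_i` until the offset
   `c_i` of its translation chunk, with weights `w_i` given by one of three
   schemes: content-word counting (**CW**), content words weighted by
   min–max normalized log corpus frequency
   `f̂ = (log f − log F_min) / (log F_max − log F_min)` (**CL**), or
   syllable-weighted words (**SYL**). Load at probe onsets is linearly
   interpolated between event-time breakpoints.
2. **Condition labeling.** Per subject and direction of interpretation,
   probe epochs are labeled *low* / *medium* / *high* by the 10% and 90%
   quantiles of the load distribution.
3. **ERP chain.** Resampling to 250 Hz, linked-mastoid re-reference,
   zero-phase 0.1–30 Hz FIR, 125-sample epochs over [−100, 400) ms with
   [−100, 0) ms baseline, optional peak-to-peak rejection, window-mean
   amplitudes (P1: 40–80 ms; N1: 120–160 ms) and peak latencies on a
   21-channel fronto-central subset.
4. **Statistics.** Exact Wilcoxon signed-rank test (full enumeration of
   the sign-assignment null), 4-way repeated-measures ANOVA
   (Direction × Load × Anteriority × Laterality) with Greenhouse–Geisser
   correction and partial η², and a leave-one-subject-out jackknife.
5. **Synthetic data.** A forward simulator generates transcripts with a
   right-skewed, direction-offset lag process, uniform 450–750 ms probe
   trains, and EEG in which P1/N1 amplitude and latency are linear in
   z-scored load, in 1/f + alpha noise — with the ground truth returned,
   so the whole chain is testable without any recording.

See `vignettes/decalage-methods.Rmd` for the model, the design decisions
and the simulator's scope.

## Worked example

Simulate a 9-subject cohort (two directions each), run the full pipeline,
and inspect the behavioral contrast and the N1 load effect:

```r
library(decalage)

rep <- runPipeline(list(seed = 1, out_dir = "demo-run",
                        sim = list(nSubjects = 9, duration = 120)))

head(rep$medians, 4)
#>   subject direction method median_load
#> 1     s01    L1toL2     CW    3.354091
#> 2     s01    L1toL2     CL    1.814640
#> 3     s01    L1toL2    SYL   10.353113
#> 4     s01    L2toL1     CW    2.646121

rep$wilcoxon$CW
#> CW: V = 45, p = 0.00390625 (n = 9, exact)
```

Every subject's median CW load is larger in the L1→L2 direction (the
simulator's +1.5-word lag offset), so the signed-rank statistic takes its
maximum `V = 45` with the exact two-sided `p = 2/512 = 0.0039`. The N1
amplitude ANOVA shows the load effect and no direction effect:

```r
a <- rep$anova$N1_CW_amplitude
a[a$effect %in% c("direction", "load", "direction:load"), ]
#>          effect df_num df_den      F        p gg_epsilon     p_gg    pes
#>       direction      1      8  0.131 7.27e-01      1.000 7.27e-01 0.0161
#>            load      2     16 48.402 1.64e-07      0.784 2.77e-06 0.8582
#>  direction:load      2     16  0.990 3.93e-01      0.754 3.76e-01 0.1101

rep$jackknife
#> Leave-one-out jackknife over 9 subjects (alpha = 0.05)
#> ...
#> Effect significant in every resample.
```

The `load` row says: with the simulator's −0.5 µV/z N1 slope, epochs
labeled *high* are reliably more negative-shifted than *low* epochs
(partial η² = 0.86 at this session length), the Greenhouse–Geisser epsilon
deflates the 2/16 dfs to 1.57/12.5, and the effect survives in all nine
leave-one-out resamples. `demo-run/` contains the median-load table,
Wilcoxon and ANOVA CSVs, the ERP summary, the jackknife report and a
`manifest.json` with the seed and an MD5 for every file; re-running with
the same config reproduces the files bit-identically.

A thin command-line wrapper is installed at
`inst/scripts/run-pipeline.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/run-pipeline.R", package="decalage"))')" \
    --seed 1 --out demo-run --method CW,CL
```

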