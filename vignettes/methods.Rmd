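---
title: "Multimodal fusion embeddings, subset ablation and Shapley attribution: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal fusion embeddings, subset ablation and Shapley attribution: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ehrfusion` asks a simple question of a multimodal patient record: how
much predictive value does each data source, and each modality,
contribute to a clinical prediction task? This vignette documents the
modelling choices, the parameters that matter, and the limits of what
the synthetic-cohort tests demonstrate.

## Patient representation and time windows

A `patient_file` collects one admission: demographics, per-source event
tables of irregular `(signal, time, value)` observations, time-stamped
free-text notes, image studies, exit timestamps, and optional 4-state
pathology codes. All within-record times are real-valued **hours since
admission**; an admission must carry at least one image study, because
samples are anchored at imaging time points.

Windows are **boundary-inclusive**: `window_events(pf, t)` keeps
everything with `time <= t`. An observation stamped exactly at the
inference time is treated as available — an imaging procedure carries
its own report — and windowing is monotone and idempotent, which the
suite asserts as properties. For operational tasks an `end_of_day`
anchor maps each study time to the next multiple of 24 h at or after
it; studies sharing a timestamp collapse into a single sample (one
sample per time point). These boundary conventions are package choices:
several readings are defensible, so we fixed the ones above and test
them explicitly. The on-disk container is a plain directory (JSON
manifest, CSV event tables, text notes, 8-bit grayscale PNGs) with
canonical key ordering, so `save → load` is field-identical and
`save → load → save` is byte-identical; an archive variant would be
straightforward but is not provided.

## Per-source embeddings

**Tabular.** Six demographics, min–max normalised to [0, 1] with
declared ranges; missing values embed as 0 and out-of-range values clip
with a warning.

**Time series.** Each signal contributes 11 statistics: count, max,
min, mean, median, population SD, population variance, number of strict
local maxima, the mean per-step slope Δv/Δt, the mean piece-wise change
magnitude |Δv|/Δt, and the overall trend (v_last − v_first)/(t_last −
t_first). Population (not sample) moments are used so the statistics
are defined at n = 1; a peak is a strict local maximum so plateaus are
unambiguous; steps with zero time gap are skipped in the slope terms;
an empty series embeds as zeros and a single observation as
`[1, v, v, v, v, 0, …, 0]`. The chart-event list has nine signals —
heart rate, systolic and diastolic non-invasive blood pressure,
respiratory rate, SpO₂, the three Glasgow coma subscales, and
temperature (the ninth is a schema choice of this package: the
embedding dimension of 99 requires nine signals while common signal
inventories name eight unambiguously). The laboratory list holds 22
unique analytes and the procedure list 10 event types, giving source
dimensions 99, 242 and 110. An independent brute-force statistics
oracle checks the extractor on hundreds of random series to 1e-9.

**Text.** All notes of a source are concatenated in time order,
tokenised (whitespace by default; real encoder plug-ins bring their own
tokeniser), split greedily into the minimal number of ≤512-token
chunks, encoded chunk-wise to 768-d vectors, and averaged unweighted.
No notes, or empty text, embeds as the zero vector so the fusion
layout never changes; a per-source presence flag preserves
auditability of which blocks were real.

**Image.** Images are resampled to 224 × 224 by pixel-area relations —
each output pixel is the overlap-weighted average of the input pixels
it covers, implemented as two dense weight-matrix products. Area
resampling preserves the global mean and never leaves the input's
intensity range, which the tests exploit as a conservation oracle. The
single-image stream embeds the most recent image (18 class
probabilities + 1024 dense features); the multi-image stream averages
those vectors over *all* images in the window, planes and past studies
included.

Encoders are contracts, not dependencies: any function with the right
signature and output dimensions can stand behind the text or image
stream. The shipped stubs are deterministic hash-and-project maps whose
first components are smooth functions of input summary statistics —
that smooth channel is what lets synthetic cohorts pass signal through
them — plus a small content-keyed pseudo-random component that makes
distinct inputs produce distinct outputs. They are not language or
vision models and make no claim of realism.

## Fusion and normalisation

Per-source embeddings concatenate in a fixed canonical order
(`de, ce, le, pe, radn, ecgn, econ, vp, vd, vmp, vmd`; 4845 dimensions
in total). Subsets are recorded as fixed-width bitmask strings over
that order. Normalisation is a per-feature z-score with population
scaling, fitted on the training rows of each experiment and only ever
*applied* to test rows; zero-variance features pass through as zeros.
Fitting per training split (rather than globally) is deliberate: it
makes train/test leakage through the normaliser impossible, and a
mutation test asserts that corrupting test rows cannot change what the
model sees at training time.

## Tasks and labels

Pathology tasks use 4-state ground-truth codes: confirmed present (1)
and confirmed absent (0) are kept; inconclusive (−1) and not-explored
(missing) samples are dropped. The radiology-note source is excluded
from pathology inputs since the ground truth derives from those notes.
The operational labels use a **(t, t + 48 h]** window: the event must
occur strictly after the sampling time (an event exactly at *t* is
past) and at or before *t* + 48 (boundary-inclusive); death at any time
forces the length-of-stay label to 0. This is the only reading that
keeps labels causal, and monotonicity of the mortality label in *t* is
property-tested. No exclusion is applied to samples within 48 h of a
censored record end.

## Experiment engine

All `2^k − 1` subsets of the allowed sources are enumerated and
annotated with source and modality counts. For the 10-source pathology
configuration the modality-count groups have sizes 26/196/486/315,
verified against a brute-force subset scan. (A side note: the
11-source per-modality counts sometimes quoted as 52/392/972/630 sum
to 2046, not 2047, and equal exactly double the 10-source counts; this
package reports the brute-force-derived group sizes instead.)

Splits are 5 repetitions of 80/20 partitions at **patient-id**
granularity — no patient contributes samples to both sides — with
optional label stratification implemented as grouped shuffling within
patient-majority-label classes. The classifier backend is a contract
(`fit`, `predict_prob`); gradient-boosted trees (xgboost,
single-threaded for determinism) are the production default with a
24-cell grid (depth 5–8, 200/300 estimators, learning rate
0.05/0.1/0.3) searched by fivefold patient-grouped CV inside each
training split, ties breaking to the first cell in lexicographic
order. A ridge-penalised logistic backend (glmnet, fixed small λ)
ignores the grid and exists for speed in tests; penalisation keeps it
defined when the fusion dimension exceeds the sample count. Degenerate
single-class inner folds skip their grid cell with a warning; the test
split is touched exactly once per repetition, for the reported AUROC
(computed by pROC). Subset runs are order-independent and resumable
through a checkpoint CSV.

`summarize_auroc()` reports mean AUROC per (modality-count,
source-count) cell and the percent change of every multi-source model
against the single-source baseline — by default the *mean* over all
single-source models, with the best-single-source alternative also
available.

## Shapley attribution

The completed AUROC table defines a cooperative game over sources with
`v(S)` the 5-repetition mean AUROC and `v(∅) = 0.5` (a model with no
data is chance). `shapley_sources()` evaluates the exact summation
formula; an independent all-orderings permutation oracle (k ≤ 8) agrees
to 1e-10, and efficiency, dummy, symmetry and additivity are
property-tested. Exact enumeration is capped at 15 sources; the package
deliberately does not implement sampling approximations.

Modality-level attribution is emitted in two labelled readings, because
"aggregated modality values" is genuinely ambiguous: (a) the sum of
member-source Shapley values, which inherits efficiency exactly and is
the primary output; and (b) a 4-player game over modalities whose value
function averages the AUROCs of all subsets with exactly that modality
coverage — the generalisation of valuing a modality by the average
AUROC of its sources' models. The two need not agree; both are written
side by side.

## Synthetic cohorts: what they do and do not show

The generator gives every stage a testable input without credentialed
clinical data. Each patient has a standard-normal latent risk `z`; each
source `s` has `u_s = rho * z + (1 - rho) * eps_s`, so `rho` is an
explicit inter-source redundancy knob; observed data drift with
`beta_s * u_s`; the outcome risk score is the standardised
`sum(beta_s * u_s)`. Death times are placed inside the 48 h window
after the anchor image with a logistic link whose intercept is solved
numerically so the realised mortality-48h prevalence matches the
configured target; a `threshold` link instead kills the top prevalence
fraction by risk and pushes each class's latents away from the decision
boundary, yielding a separable cohort for sanity tests. The four image
sources share their pixel data, so a single latent drives the whole
image group.

Defaults were chosen once as plausible desk-scale conditions and are
not tuned: 200 patients, one stay each, all `beta = 1`, `rho = 0.3`,
0.05 events per signal-hour (a few observations per signal over a
multi-day stay), 120-token notes, 48 × 48 images, prevalence 0.3.
Values are rounded to fixed precision (times to 1e-6 h, pixels to the
8-bit grid) purely so containers round-trip exactly.

What passing tests show: the pipeline recovers signal planted in any
modality; chance-level AUROC on null cohorts (all `beta = 0`); perfect
discrimination on separable cohorts; AUROC non-decreasing in modality
count with positive full-fusion gains on informative cohorts; and
shrinking returns from added sources as `rho` approaches 1. What they
do **not** show: anything about real vital-sign dynamics, clinical
language, or radiographs — the stubs and the generator are statistical
scaffolding, and absolute AUROCs on real multimodal EHR data are out
of reach of any synthetic check.

## Problem sizes and numerical choices

The suite runs its statistical checks at deliberate desk scale: the
null-cohort check uses 2000 patients with 3 split repetitions, the
qualitative-gain check a 6-source cohort (63 subsets × 5 splits,
~320 patients) with the logistic backend, and the redundancy
comparison two 4-source cohorts (15 subsets × 3 splits) at
`rho = 0.2` and `0.95`. Tolerances follow the object being checked:
1e-9 against the statistics oracle, 1e-10 for Shapley identities,
±0.05 around chance for null AUROCs, ±0.02 for prevalence at n = 5000,
and sign-level assertions for the qualitative multimodality claims.
Stub randomness uses a Lehmer generator with Schrage decomposition so
no call ever touches R's global RNG state; cohort generation is a pure
function of `(config, seed)` via a preserved-seed wrapper.

## Known limitations

Exact Shapley enumeration is exponential and capped at 15 sources. The
experiment engine is single-process (cells are independent, so outer
parallelisation is trivial, but none is built in). The container
supports grayscale PNG only — no DICOM, no zip archives. Label
stratification is approximate at patient granularity by construction.
The modality game's coalition values average over unequal subset
counts; interpret it as the labelled alternative it is.
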