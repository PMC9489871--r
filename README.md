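# ehrfusion

Multimodal patient records — demographics, irregular clinical time
series, free-text notes, and imaging — rarely enter a predictive model
together. `ehrfusion` implements a *late-fusion* pipeline for exactly
that setting, aimed at clinical-informatics researchers who want to
quantify what each data source and modality is worth for a prediction
task: every source is embedded independently into a fixed-dimensional
vector, the vectors are concatenated into one fusion embedding per
patient-admission time point, a classifier is trained on **every**
non-empty subset of sources, and the resulting test AUROCs are
attributed back to sources and modalities with exact Shapley values.

## The model

One hospital admission is a `patient_file`: demographics, per-source
event tables of `(signal, time, value)` observations, time-stamped
notes, image studies, outcome timestamps, and optional per-pathology
ground-truth codes. At an inference time *t* (one sample per chest
X-ray time point), everything up to *t* is embedded per source:

| modality    | sources            | embedding                                   | dim       |
|-------------|--------------------|---------------------------------------------|-----------|
| tabular     | `de`               | min–max normalised demographics             | 6         |
| time-series | `ce`, `le`, `pe`   | 11 statistics × (9 / 22 / 10 signals)       | 99/242/110|
| text        | `radn`,`ecgn`,`econ`| chunk-averaged 768-d encoder vectors       | 768 each  |
| image       | `vp`,`vd`,`vmp`,`vmd`| class-probability + dense-layer vectors, latest and averaged-over-all images | 18/1024/18/1024 |

The 11 statistics per clinical signal are count, max, min, mean,
median, population SD, population variance, strict-local-maximum count,
mean slope Δv/Δt, mean piece-wise change |Δv|/Δt, and the overall trend
(v_last − v_first)/(t_last − t_first). Concatenating all 11 sources in
canonical order gives a 4845-dimensional fusion embedding. Text and
image encoders are pluggable contracts (tokens → 768-vector; 224 × 224
array → (18, 1024) vectors); deterministic stub encoders ship with the
package so that the whole pipeline runs without pretrained weights.

For a task with *k* allowed sources, all `2^k − 1` subsets are
enumerated (2047 for the 11-source registry; 1023 when radiology notes
are excluded for pathology tasks) and each is scored by the mean test
AUROC over 5 patient-stratified 80/20 splits, with an optional
cross-validated hyperparameter grid (tree depth 5–8, 200/300
estimators, learning rate 0.05/0.1/0.3) searched inside each training
split. The completed table is a cooperative game: player *i*'s Shapley
value is

    phi_i = sum over S ⊆ N\{i} of |S|! (k−|S|−1)! / k! · [v(S ∪ {i}) − v(S)]

with `v(S)` the subset's mean AUROC and `v(∅) = 0.5` (chance). Modality
attributions are the sums of their member sources' values, so
`sum(phi) = v(full) − 0.5` exactly.

## Worked example

A synthetic four-source cohort (one source per modality), the full
15-subset ablation with the fast logistic backend, and the attribution:

```r
library(ehrfusion)
library(dplyr)

cfg <- sim_config(n_patients = 150, sources = c("de", "ce", "econ", "vp"),
                  beta = 1.2, rho = 0.3)
cohort <- simulate_cohort(cfg, seed = 42)
samples <- cohort_samples(cohort, task_spec("mortality48", "mortality48"))
registry <- source_registry() |> filter(source %in% cfg$sources)
emb <- embed_cohort(cohort, samples, registry = registry)

results <- run_experiment(
  emb$x, emb$layout, samples,
  enumerate_source_subsets(registry),
  make_splits(samples, n_rep = 5, seed = 42),
  backend = backend_logistic(), task = "mortality48")

summarize_auroc(results)
#> <ehrf_auroc_summary> baseline (mean single-source) = 0.6686
#> # A tibble: 4 × 5
#>   n_modalities n_sources auroc_mean auroc_sd n_subsets
#>          <int>     <dbl>      <dbl>    <dbl>     <int>
#> 1            1         1      0.669   0.0483         4
#> 2            2         2      0.692   0.0324         6
#> 3            3         3      0.732   0.0295         4
#> 4            4         4      0.778  NA              1

shapley_sources(results)
#> <ehrf_attribution>  v(full) = 0.7776, v(empty) = 0.5, efficiency residual = -5.55e-17
#> # A tibble: 4 × 3
#>   source modality       phi
#> 1 de     tabular     0.0647
#> 2 ce     time-series 0.0771
#> 3 econ   text        0.0407
#> 4 vp     image       0.0952
```

Mean AUROC rises monotonically from 0.669 (single sources) to 0.778
(full fusion), and every modality receives a positive Shapley share of
the 0.278 AUROC above chance — with imaging worth the most on this
cohort. `autoplot()` on the attribution draws the waterfall;
`tidy()`/`glance()` return the numbers as tibbles.

A command-line pipeline (`simulate` → `embed` → `run` → `summarize` /
`shapley`) over the same functions ships in `inst/cli/ehrfusion`; every
stage writes a manifest with its seed and config hash.

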