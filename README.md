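# patsim

Patient similarity from mixed-type health-record data: build
lower-dimensional patient representations with four competing data
processing pipelines, measure which features actually drive the resulting
similarity, and evaluate the consequences for cluster analysis.

## The problem

Phenotype-discovery studies cluster patients on routinely collected
features of mixed type — numeric (age, BMI, FEV1 % predicted, eosinophil
%), ordinal (inhaled-therapy line), and binary (sex, smoking, diagnosis
flags). Before any clustering algorithm runs, the data must be collapsed
into a single numeric space where Euclidean distances make sense, and every
way of doing that (binning, one-hot encoding, scaling, dimensionality
reduction) silently reweights the features. `patsim` implements a framework
for making that reweighting visible and for choosing a pipeline
deliberately.

Four pipelines produce an m × c coordinate matrix per patient:

| name          | stages |
|---------------|--------|
| `MCA`         | bin numerics → one-hot all 16 features → multiple correspondence analysis |
| `MCA/PCA`     | MCA on discrete features ∥ PCA on numerics → concatenate components |
| `MCA/PCA/PCA` | as above → second (standardized) PCA over the concatenation |
| `AE`          | scale numerics + one-hot discrete → feed-forward autoencoder → 6-unit bottleneck |

Each linear stage keeps the smallest leading component set reaching 75 % of
the explained variance (PCA) or principal inertia (MCA). All transform
state is fitted on a training split only and applied unchanged to held-out
data.

## The evaluation metrics

**Relative variability (RV).** For feature *x*, cohort-level variability is
`q_cohort = median_{i<j} |x_i − x_j|` (numeric), the mean absolute pairwise
rank difference (ordinal), or the proportion of disagreeing pairs
(categorical). The same statistic computed over each patient's N = 20
nearest neighbours in the representation, averaged over patients, gives
`q_sample,N`, and

```
RV = 100 · q_sample,N / q_cohort      (p_sample,N / p_cohort for categorical)
```

RV ≈ 0 means the representation makes neighbours share that feature (the
feature drives similarity); RV ≈ 100 means the feature is ignored. **MRV**
is the mean RV per feature-type group and overall — a cost-function-style
summary of a representation.

**Cluster tendency.** The Hopkins index (exponent-*d* formulation, sampling
window = bounding box of the data): ≈ 0.5 for spatially random data, → 1
for clustered data, → 0 for regular grids.

**Congruity.** k-means (identical seeded initialisations, k ∈ 2..5) is run
on every representation; the percentage of patients co-assigned under the
overlap-maximising cluster matching quantifies how much the pipeline choice
alone changes clustering results. The diagonal holds each pipeline's
bootstrap pair-stability (20 × 10 % subsample re-clustering).

**Expert rating support.** Blinded clinical-vignette export (reference
patient + best non-identical match per pipeline), rating-file validation,
raw and best/worst-binarized agreement, and Cohen's kappa with large-sample
confidence intervals.

Because the original cohort is license-bound, the package ships a synthetic
cohort generator (`copd_cohort_spec()`, `generate_cohort()`) that emulates
a reference COPD feature set — 4 truncated-normal numerics, a 4-level therapy
line, 11 binary prevalences — with optional planted cluster structure for
parameter-recovery testing.

## Worked example

```r
library(patsim)

co <- generate_cohort(copd_cohort_spec(m = 1000, seed = 42))
sp <- split_train_test(co, seed = 42)     # default fraction 0.7516
rep <- evaluate_all(sp, ks = 2:3, bootstrap_repeats = 10, seed = 42)
print(rep)
#> <evaluation_report> 4 pipelines, N = 20, k in {2, 3}
#>   MCA          c = 18 Hopkins = 0.999 MRV overall = 52.8
#>   MCA/PCA      c = 13 Hopkins = 1.000 MRV overall = 63.3
#>   MCA/PCA/PCA  c = 10 Hopkins = 0.998 MRV overall = 52.7
#>   AE           c = 6  Hopkins = 0.999 MRV overall = 85.4
```

`c` is the retained representation width. Hopkins ≈ 1 here because
predominantly discrete data yields many (near-)duplicate coordinates. The
MRV says the second PCA of `MCA/PCA/PCA` produced one of the most
feature-homogeneous neighbourhoods overall on this cohort, while the AE
representation concentrated on few features.

```r
head(as.data.frame(rep$pipelines$MCA$rv_table), 5)
#>  rank       feature  dtype       rv
#>     1           crs binary 17.12088
#>     2       anxiety binary 41.11089
#>     3 heart_failure binary 42.12836
#>     4    depression binary 43.85315
#>     5          gerd binary 44.73647
```

Under the MCA pipeline, similarity on this cohort is driven mostly by
binary diagnosis flags — rank 1 (chronic rhinosinusitis, RV 17 %) means
that among each patient's 20 nearest neighbours the share of disagreeing
pairs on CRS drops to 17 % of its cohort-wide value.

```r
round(rep$congruity[["2"]], 1)
#>              MCA MCA/PCA MCA/PCA/PCA   AE
#> MCA         54.3    54.3        60.2 54.8
#> MCA/PCA     54.3    53.7        50.7 84.6
#> MCA/PCA/PCA 60.2    50.7        59.2 52.0
#> AE          54.8    84.6        52.0 91.0
```

With k = 2, only 50–85 % of patients end up in matching clusters across
pipelines (off-diagonal) — pipeline choice alone relabels up to half the
cohort. The diagonal is each pipeline's own bootstrap pair-stability.

`write_report(rep, "out/")` serialises everything (JSON + CSV tables). A
command-line interface covering generation, pipeline runs, RV, Hopkins,
congruity, agreement and the full report is available via
`Rscript inst/cli/patsim.R <subcommand> [--option value ...]` (see
`?patsim_cli`).

## Further reading

`vignettes/patient-similarity-methods.Rmd` documents the model choices:
pipeline composition, the RV/MRV statistics and their known biases, the
Hopkins/k-means/congruity conventions, autoencoder training details, what
the synthetic generator does and does not emulate, and every place where a
genuinely open design decision was pinned.
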