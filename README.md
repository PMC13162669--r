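# spatprox

Spatial proximity analysis of PD-L1(+) tumor-associated macrophages (TAMs)
and CD8(+) T cells in multiplex-IHC cell maps, with the downstream
survival / ROC / bootstrap-validation chain used to evaluate the resulting
biomarker.

## The problem

Responses to PD-L1-blocking combination therapy in hepatocellular carcinoma
are heterogeneous, and the *abundance* of immune cells in pretreatment
biopsies predicts them poorly. What appears to matter is spatial
organization: whether CD8(+) T cells actually sit next to PD-L1(+) TAMs,
close enough for checkpoint engagement and short-range paracrine signaling.
`spatprox` is for analysts working with cell-segmentation tables exported
from multiplex immunofluorescence platforms (inForm/phenoptr-style: one row
per cell with x/y centroids in µm and marker positivity flags) who want to
quantify that proximity and test it as a prognostic biomarker.

## The statistic

For one imaged region with `n_tam` PD-L1(+) TAMs and `n_cd8` CD8(+) T cells,
count the distinct CD8 cells lying within radius *r* (default 25 µm, about
one to two cell diameters) of at least one PD-L1(+) TAM, and normalize:

```
iv(r) = 100 · n_within(r) / (n_cd8 + n_tam)
```

The normalization makes the score reflect the *relative frequency of
interacting cells*: doubling either population in place, or adding any
number of other cells, leaves it unchanged. Around this core the package
provides nearest-neighbor distance profiles (5 µm bins), patient-level
aggregation across biopsy cores, radius-sensitivity analysis (15/30/50 µm,
Spearman agreement with the 25 µm reference), median dichotomization,
Kaplan–Meier / log-rank / Cox screening (univariate → multivariate at
p < 0.05), ROC discrimination of 1-year PFS with Youden-index cutoffs,
1000-iteration bootstrap optimism correction of the AUC and Harrell
C-index, and the ALBI/mALBI liver-function score. A marked point-pattern
simulator (Thomas-like parent–offspring attraction) generates cohorts with
known ground truth for end-to-end validation.

## Worked example

Simulate four patients whose CD8 cells are increasingly attracted to TAMs,
then score them:

```r
library(spatprox)

set.seed(7)
cfg <- simulation_config(seed = 7)
cohort <- simulate_cohort(cfg, n_patients = 4,
                          attraction_values = c(0.1, 0.4, 0.7, 1.0))

regions <- lapply(cohort$regions, assign_phenotypes)
by_patient <- split(regions, vapply(regions, function(r) r$patient_id, ""))
scores <- do.call(rbind, lapply(by_patient, aggregate_patient_iv))
scores[, c("patient_id", "n_cd8", "n_tam", "n_cd8_within", "iv")]
#> # A tibble: 4 × 5
#>   patient_id n_cd8 n_tam n_cd8_within    iv
#>   <chr>      <int> <int>        <int> <dbl>
#> 1 P001         192   173           88  24.1
#> 2 P002         196   166          107  29.6
#> 3 P003         221   132          166  47.0
#> 4 P004         203   162          194  53.2

d <- nearest_neighbor_distances(regions[[12]], "PDL1_TAM", "CD8_T")
median_nn_distance(d)   # strongest-attraction patient: 12.3 µm
d1 <- nearest_neighbor_distances(regions[[1]], "PDL1_TAM", "CD8_T")
median_nn_distance(d1)  # weakest-attraction patient: 26.5 µm
```

Cell counts are nearly identical across patients — only the *placement* of
CD8 cells differs — yet the interaction variable rises monotonically with
the attraction strength (24.1 → 53.2) and the median TAM-to-nearest-CD8
distance halves (26.5 µm → 12.3 µm). That is the density-decoupling the
score is designed for.

## Analysis workflow

The `analysis/` directory holds the pipeline as numbered drivers over the
package, writing tables to `results/`:

| script | role |
|---|---|
| `analysis/01_simulate_cohort.R` | synthetic 23-patient cohort: cell maps + clinical table |
| `analysis/02_spatial_scoring.R` | per-region/per-patient iv, NN distances, radius sensitivity |
| `analysis/03_survival.R` | KM curves, log-rank, Table-style Cox screening |
| `analysis/04_validation.R` | ROC for 1-year PFS, Youden cutoff, bootstrap optimism correction |

Each step reads only the previous step's files, so step 2 onward works
unchanged on real cell-segmentation exports with the documented columns
(`patient_id, region_id, cell_id, x_um, y_um, CD8, CD68, CD163, PDL1, GZMB,
TIM3`).

See `vignettes/spatial-proximity-methods.Rmd` for the model, parameter
rationale, numerical conventions and known limitations.

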