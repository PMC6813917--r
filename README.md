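# stromaplex

Quantitative multiplex-immunohistochemistry (mIHC) analysis of the
prostate-cancer stromal compartment, for computational pathologists and
biostatisticians who need a reproducible path from multi-channel
tissue-microarray (TMA) core images to survival statistics.

The tumour stroma is a mixture of fibroblasts, myofibroblasts, smooth
muscle, vessels and immune cells; a fibroblast-rich, smooth-muscle-poor
stroma marks aggressive disease. `stromaplex` implements the whole
analysis chain:

* **Compartments** — tissue / epithelium / stroma masks from the DAPI and
  PanEpi (pooled pan-cytokeratin + E-cadherin) channels; stroma is defined
  as tissue ∖ epithelium, so the partition is exact.
* **Stromal classification** — the marker truth table, at pixel level or
  anchored on segmented nuclei:

  | class | VIM | aSMA | CAV2 |
  |---|---|---|---|
  | fibroblast | + | − | − |
  | myofibroblast | + | + | − |
  | smooth muscle | − | + | − |
  | endothelium (excluded from the above) | any | any | + |

* **Quantification** — cross-core intensity normalization (99th-percentile
  scale, cohort-median anchor), relative class areas / cell counts within
  stroma, per-patient averages, immune score (`<1%` low, `1–5%` medium,
  `>5%` high of stromal area).
* **Phenotyping** — quartile categories and hierarchical phenotype
  clustering (patients: Euclidean distance, average linkage; classes:
  correlation distance, average linkage).
* **Survival** — Cox proportional hazards on `proportion × 10` (hazard
  ratios read *per 10-percentage-point change*), Kaplan–Meier + log-rank,
  Schoenfeld proportional-hazards check, Benjamini–Hochberg control at
  20% FDR, and the usual group-comparison tests.
* **Synthetic TMA simulator** — renders multi-channel cores with
  pixel-level ground truth and cohorts whose survival follows a known
  proportional-hazards law, so every stage above is verifiable.

## Worked example

Simulate a 40-patient cohort (one 256×256 px core each, true hazard ratio
2.0 per 10 percentage points of fibroblast stroma), run the full pipeline
in memory, and look at the fibroblast effect:

```r
library(stromaplex)

coh <- generate_cohort(40, 1,
                       surv = survival_sim_params(baseline_hazard = 0.001),
                       seed = 60101,
                       image_params = list(width = 256, height = 256,
                                           noise_sd = 5))
run <- analyze_cohort(lapply(coh$cores, `[[`, "core"), coh$clinical,
                      pipeline_config())
print(run)
#> <stromaplex_run> 40 cores, 40 patients (0 excluded)
#> multivariate Cox:
#> <stromal_cox> n = 40, events = 17 (0 excluded, efron ties)
#>              term         HR (95% CI)        p
#>      fib_frac_x10 2.264 (1.469-3.487) 0.000211
#>  gleason_groupeq7 0.553 (0.127-2.415) 0.431000
#>  gleason_grouplt7 0.889 (0.281-2.814) 0.841000
#>               age 0.962 (0.881-1.050) 0.387000

run$survival$univariate$fib_frac
#> <stromal_cox> n = 40, events = 17 (0 excluded, efron ties)
#>          term         HR (95% CI)        p
#>  fib_frac_x10 2.267 (1.483-3.465) 0.000158
```

The univariate hazard ratio 2.27 (95% CI 1.48–3.47) recovers the
simulated truth of 2.0: a patient with ten percentage points more
fibroblast stroma has roughly twice the cancer-specific mortality hazard,
and the effect survives adjustment for Gleason group (reference ">7") and
age. The per-patient table carries the composition estimates, quartile
categories and phenotype cluster:

```r
head(run$patients[, c("patient_id", "fib_frac", "smc_frac",
                      "fib_quartile", "cluster", "time", "event")])
#>   patient_id fib_frac smc_frac fib_quartile cluster   time event
#> 1      P0001   0.3523    0.182            4       1   5.16     1
#> 2      P0002   0.3550    0.327            4       1  23.91     1
#> 3      P0003   0.0807    0.410            1       1 120.00     0
#> ...
```

Kaplan–Meier by fibroblast quartile gives log-rank χ² = 21.5,
p = 8.2e-05; the Schoenfeld test finds no proportional-hazards violation
(all p > 0.5).

The same analysis runs from disk (TIFF cores + CSV clinical table) via
`write_cohort()` / `run_pipeline()`, or from a shell through the thin CLI:

```sh
Rscript inst/cli/stromaplex.R simulate --n-patients 40 --seed 1 --out-dir cohort/
Rscript inst/cli/stromaplex.R run --in-dir cohort/ --out-dir cohort/out
```

`run_pipeline()` caches per-stage intermediates (compartment and class
label rasters, metric tables) so `segment`, `classify`, `quantify`,
`phenotype` and `survive` can each be re-run alone, and writes a manifest
recording the config hash, seed, and every excluded core or patient with
its reason.

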