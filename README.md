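# hepafunc

Estimating liver functional reserve from routine multiphase hepatic CT.

Before major hepatectomy, severe liver dysfunction — conventionally
ICG-R15 ≥ 20%, the indocyanine green retention at 15 minutes — must be ruled
out. `hepafunc` implements a CT-based alternative to dedicated function
tests: it computes iodine-uptake biomarkers from per-phase hepatic and
aortic enhancements,

```
ECV = E_liver,DP × (100 − Hct) / E_aorta,DP            (extracellular volume fraction, %)
IWR = (E_liver,PVP − E_liver,DP) / E_liver,PVP × 100   (iodine washout rate, %)
```

body-surface-area-normalized liver and spleen volumes (LV/BSA, SpV/BSA with
Mosteller BSA = √(wt·ht/3600)), the ⁹⁹ᵐTc-GSA scintigraphy indices HH15 and
LHL15, and the MELD score; evaluates each against the ICG-R15 ≥ 20% endpoint
(Welch/Fisher group comparison, Spearman correlations with Fisher-z CIs,
empirical ROC with Youden cutoffs, DeLong AUC variance and paired
comparisons, Clopper–Pearson sensitivity/specificity CIs, ICC(2,1)
inter-reader agreement); and applies the frozen published combined model

```
P = 1 / (1 + exp(−(11.869 − 0.1119·IWR + 0.0118·SpV/BSA − 0.0139·LV/BSA)))
```

classifying severe dysfunction when P > 0.472, alongside a from-scratch IRLS
logistic refit. A seeded synthetic-cohort generator (Gaussian copula over
group-conditional truncated normals) and an ellipsoidal voxel-phantom/ROI
stage make the whole pipeline testable without patient data. Intended users
are imaging researchers validating CT-derived liver-function markers and
methodologists who need the full evaluation machinery in one place.

## Worked example

```r
library(hepafunc)
library(dplyr)

spec <- cohort_spec()                 # 96 ICG-R15 < 20% + 22 >= 20% subjects
rep  <- run_pipeline(spec, seed = 1)  # sample, derive biomarkers, analyze

rep$roc_table |>
  select(marker, auc, auc_low, auc_high, threshold, threshold_direction, sens, spec)
#> # A tibble: 7 × 8
#>   marker     auc auc_low auc_high threshold threshold_direction  sens  spec
#>   <chr>    <dbl>   <dbl>    <dbl>     <dbl> <chr>               <dbl> <dbl>
#> 1 ecv      0.607   0.477    0.736    26.5   >                   0.864 0.417
#> 2 iwr      0.885   0.787    0.983    17.9   <=                  0.773 0.958
#> 3 lv_bsa   0.768   0.662    0.874   735.    <=                  0.727 0.75
#> 4 spv_bsa  0.702   0.550    0.855   201.    >                   0.545 0.917
#> 5 hh15     0.887   0.810    0.963     0.671 >                   0.864 0.781
#> 6 lhl15    0.936   0.854    1        0.872  <=                  0.909 0.927
#> 7 combined 0.905   0.825    0.984    0.441  >                   0.864 0.823
```

Each row is one marker's ROC against ICG-R15 ≥ 20% on this synthetic draw:
the Mann–Whitney AUC with its DeLong 95% CI, the Youden-optimal cutoff with
its direction (`<=` for markers that fall with dysfunction), and
sensitivity/specificity at that cutoff. IWR separates the groups far better
than ECV or volumetry alone, and the combined row — every patient scored
with the frozen published model — sits near the top, the same ordering the
printed study tables report. The refit on this draw recovers odds ratios
close to the published 0.894 / 0.986 / 1.012:

```r
tidy(rep$logistic_fit) |> select(term, odds.ratio, conf.low, conf.high)
#> # A tibble: 4 × 4
#>   term        odds.ratio conf.low conf.high
#>   <chr>            <dbl>    <dbl>     <dbl>
#> 1 (Intercept)     30.0      0.509  1770.
#> 2 iwr              0.902    0.858     0.948
#> 3 lv_bsa           0.996    0.991     1.00
#> 4 spv_bsa          1.01     1.00      1.02
```

Scoring the two published group-mean profiles with the frozen model gives
P = 0.047 (preserved function) and P = 0.857 (severe dysfunction) — the
closed-form binormal AUC from the IWR group summaries,
`binormal_auc(43.0, 12.4, 18.8, 20.2)` = 0.846, matches the published IWR
AUC of 0.845.

Other entry points: `sample_cohort()` / `add_biomarkers()` for
measurement-level synthetic data, `generate_phantom()` /
`auto_place_rois()` / `measure_hepatic_mean()` for the voxel stage,
`roc_analysis()` / `delong_compare()` / `fit_logistic()` for standalone
statistics, `autoplot()` on ROC results and reports, and
`inst/scripts/hepafunc.R` as a command-line wrapper
(`simulate` / `analyze` subcommands). The cohort CSV schema is documented
in `inst/extdata/cohort_dictionary.csv`.

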