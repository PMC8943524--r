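# faimscv

Compensation-voltage prediction and SEC-aware FAIMS scheduling for
cross-linked peptides.

## The problem

Field asymmetric waveform ion-mobility spectrometry (FAIMS) transmits only
the ions whose differential mobility matches the applied compensation
voltage (CV). For cross-linking mass spectrometry this is a double-edged
sword: the gas-phase filter enriches the rare cross-linked species, but a
badly chosen CV throws them away. Two practical questions follow:

1. **Can the optimal CV of a cross-linked peptide pair be predicted from
   its sequence?** `faimscv` featurizes each cross-link spectrum match
   (CSM) into 32 physicochemical descriptors — m/z, cross-linked mass,
   chain lengths, precursor charge, the Henderson–Hasselbalch solution
   charge at pH 2.7, Kyte–Doolittle hydropathy, residue-class composition —
   and fits a gradient-boosted tree regression of the applied CV, explained
   by TreeSHAP attributions.
2. **Which two CVs should be combined per size-exclusion chromatography
   (SEC) fraction?** Because cross-linked peptides are large, they elute
   early from SEC, and because analyte size also steers FAIMS transmission,
   the optimal CV drifts with the fraction number. `faimscv` counts unique
   residue pairs (URPs — distinct protein-level linked positions) per CV
   and fraction, exhaustively evaluates every two-CV combination
   (union yield and percentage overlap), and quantifies the gain of
   fraction-specific over global CV pairs and of top-k pair merging over
   replicate acquisition without FAIMS.

For training data at the keyboard, the package ships a fully seeded
synthetic generator: tryptic cross-linked pairs from random proteins,
mass-coupled SEC fractions, a true optimal CV `cv* = β0 + β1·(m/z) +
β2·size + ε`, and Bernoulli detection through a Gaussian transmission
window `p = p_max · exp(−(CV − cv*)² / 2σ²)` on a 5 V grid.

## The core quantities

* leakage-free deduplication: one CSM per (alpha sequence, beta sequence,
  charge), highest score wins, so link-site variants of the same pair
  cannot straddle a train/validation split;
* regression metrics: Pearson r, MSE, and the fractions of predictions
  within ±5 V and ±10 V of the applied CV;
* two-CV yield: `URPs(a ∪ b)` with Jaccard overlap
  `100·|A∩B| / |A∪B|`;
* fraction gain: `100·(URPs_fraction-pair − URPs_global-pair) /
  URPs_global-pair`.

## Worked example

```r
library(faimscv)

cfg <- synthetic_config(seed = 1)        # 3000 cross-linked analytes
ml  <- simulate_ml_dataset(cfg)          # survey, prefilter, dedup, featurize
sp  <- split_train_validation(cbind(ml$features, cv = ml$labels), seed = 1)
fn  <- names(ml$features)

model   <- train_cv_regressor(sp$train[, fn], sp$train$cv, seed = 1)
metrics <- evaluate_cv_model(model, sp$validation[, fn], sp$validation$cv)
str(metrics)
#> $ pearson       : num 0.857
#> $ mse           : num 56.1
#> $ frac_within_5 : num 0.482
#> $ frac_within_10: num 0.842
#> $ n             : int 575

head(shap_importance(model, sp$validation[, fn])$importance, 3)
#>   feature        mean_abs_shap
#> 1 mz                     8.90
#> 2 charge_density         1.13
#> 3 mass                   1.00
```

Half the held-out CSMs are predicted within one 5 V grid step and 84 %
within two; m/z dominates the attribution, exactly the dependence the
generator encodes. The schedule analysis on the same configuration:

```r
sim   <- simulate_sec_experiment(cfg)
faims <- subset(sim$csms, !is.na(cv))

best_pair(faims, cfg$cv_grid, fraction = 7)
#>   cv_a  cv_b urps_a urps_b urps_union overlap_pct
#>  -55   -60     283    291        437        31.4

fraction_gain(faims, cfg$cv_grid)$per_fraction
#>   sec_fraction best_cv_a best_cv_b urps_best urps_global gain_pct
#>              5       -35       -45       422         183  131.
#>              6       -45       -60       417         342   21.9
#>              7       -55       -60       437         405    7.90
#>              8       -60       -65       430         427    0.703
#>              9       -60       -70       450         402   11.9
#>             10       -75       -80       487         287   69.7
```

The fraction-optimal pairs march to more negative CVs as the analytes get
smaller (fraction 5 → 10), and the fractions farthest from the global
optimum (−55/−70 V here) gain the most from fraction-specific pairs —
over +60 % in the last fraction.

A thin command-line wrapper (`inst/cli/faimscv`) exposes the same chains
as `simulate`, `featurize`, `train`, `evaluate`, `explain`, `schedule`
and `report` subcommands; each run writes a `manifest.json` with input
hashes, seed and package version.

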