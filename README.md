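# kinomescreen

Kinome-wide screening of kinase inhibition against adverse events with
random survival forests.

## The problem

Small-molecule kinase inhibitors (SMKIs) inhibit many kinases beyond their
nominal targets, and both on-target and off-target inhibition can cause
adverse events (AEs). Attributing an AE to a specific kinase from clinical
data is confounded by the drug identity (every patient gets a whole
inhibition profile) and by large inter-individual variability in drug
exposure. `kinomescreen` implements a pipeline that removes the drug label
from the analysis: for patient *i* on drug *j*, inhibition of kinase *k* is
summarised by the dimensionless ratio

```
x_ik = C_ave,ss(i) / K_d(j, k)
```

of the patient's steady-state average plasma concentration to the drug's
dissociation constant (both nM; missing K_d entries imputed as 1e4 nM).
Patients from many drugs can then be pooled, and the time from treatment
start to the first occurrence of each (consolidated) AE term is modelled
with a random survival forest — log-rank node splitting, Nelson–Aalen
terminal-node cumulative hazards, out-of-bag bookkeeping. Kinase–AE
associations are ranked by permutation variable importance (with minimal
depth alongside), stratified ensemble survival curves visualise
exposure-dependent onset, and predictive performance is evaluated by
Harrell's C under bootstrap and leave-one-out cross-validation, external
validation at an incidence threshold, and reporting odds ratios.

Because clinical trial datasets of this kind are confidential, the package
ships a synthetic-data generator with configurable causal structure
(kinome panel sparsity, per-drug exposures, proportional-hazards outcomes
driven by designated causal kinases), so the entire pipeline is testable
end to end with known ground truth.

## Worked example

Simulate the versioned benchmark study (600 patients on 8 drugs, 200
kinases, one AE term with 5 causal kinases at hazard ratio 2.5 per SD of
the log feature), screen the kinome, and cross-validate:

```r
library(kinomescreen)

cfg <- benchmark_config()
ds  <- simulate_dataset(cfg, seed = 42)
#> Synthetic kinome-AE dataset: 600 patients, 8 drugs, 200 kinases, 1 AE term(s), seed 42

tbl <- screen_ae(ds$features, ds$outcomes, "ae_1", n_trees = 500, seed = 42)
head(top_predictors(tbl), 8)
#> # A tibble: 8 × 6
#>   ae_term predictor    vimp minimal_depth  rank fitted
#>   <chr>   <chr>       <dbl>         <dbl> <int> <lgl>
#> 1 ae_1    KIN009    0.0181           12.3     1 TRUE
#> 2 ae_1    KIN108    0.00959          13.9     2 TRUE
#> 3 ae_1    KIN040    0.00952          13.9     3 TRUE
#> 4 ae_1    KIN107    0.00951          13.1     4 TRUE
#> 5 ae_1    KIN129    0.00889          13.4     5 TRUE
#> 6 ae_1    KIN037    0.00885          14.5     6 TRUE
#> 7 ae_1    KIN103    0.00861          13.6     7 TRUE
#> 8 ae_1    KIN112    0.00855          13.5     8 TRUE

ds$ground_truth$ae_1$causal_kinases
#> [1] "KIN009" "KIN027" "KIN052" "KIN071" "KIN145"

cv <- bootstrap_cv(ds$features, ds$outcomes, "ae_1", B = 50, n_trees = 25,
                   seed = 42)
cv
#> Bootstrap cross-validation for 'ae_1' (B = 50, train 80%)
#>   C-index 0.820 (90% interval 0.777, 0.855)
```

The importance ranking puts the designed causal kinase `KIN009` first
(the VIMP value 0.018 is the increase in out-of-bag prediction error when
its values are permuted), and held-out concordance of 0.82 says the
forest's mortality score orders patients' event times far better than
chance (0.5). Kinases whose panel columns are nearly collinear with a
causal kinase's column share its importance, so the list identifies
equivalence classes of candidate kinases for follow-up rather than unique
culprits — the honest resolution limit of a pooled screen over eight
drugs.

The whole workflow (simulate or read data, integrate, screen, stratify,
cross-validate, manifest) is also available as one call:

```r
run_pipeline(list(simulation = list(), screen = list(n_trees = 500)),
             out_dir = "run1", seed = 1)
report_summary("run1")
```

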