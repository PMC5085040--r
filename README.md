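# txinit

Inference of the rate-limiting steps of bacterial transcription initiation
from censored single-cell RNA-production intervals.

## The problem

Time-lapse microscopy with RNA tagging yields, per cell, the durations
between consecutive RNA production events. Those intervals carry the
signature of the initiation machinery: a promoter toggling between an
inactive and an active state (telegraph switching) composed with a short
cascade of sequential steps,

    P_off <=[k_on/k_off]=> P_on --k1--> I1 --k2--> I2 --k3--> P_on + E

where `k1` is the effective forward rate of an active gene (polymerase
abundance times the per-polymerase closed-complex rate). The interval
between productions is the absorption time of this chain — a phase-type
distribution. Which steps are rate limiting, whether switching matters,
and which parameter carries the temperature response of a promoter are
model-selection questions over this family.

The catch is the data: movies are finite, sampled on a 60 s grid, and each
cell is observed only for its own lifetime. Every interval is therefore
grid-censored (known to a lower/upper bound) or right-censored (still open
at the end of observation). `txinit` provides the full pipeline for this
setting, for anyone analyzing single-cell interval data of this kind:

- phase-type densities, moments, and analytic noise bounds of the
  initiation scheme (`initiation_model`, `interval_moments`,
  `precommit_cv_sq_range`, `cv_sq_lower_bound`, `burst_statistics`);
- censoring-aware maximum likelihood with delta-method uncertainty
  (`censored_loglik`, `fit_model`, `fit_censored_gamma`,
  `delta_method_interval`);
- BIC model selection with censored samples worth 0.5 exact samples and a
  worst-case Delta-BIC lower bound (`bic`, `delta_bic_with_lb`,
  `select_structure`);
- polynomial inverse-rate temperature laws fitted jointly across
  conditions, including a shared shape-up-to-scale variant and an
  RNA-polymerase-abundance-constrained variant (`fit_joint_temperature`,
  `select_temperature_model`, `fit_shared_shape`, `fit_rnap_constrained`);
- parametric-bootstrap goodness of fit (`parametric_bootstrap`);
- the pre/post-commit split from activity-vs-polymerase measurements via
  Lineweaver-Burk extrapolation (`lineweaver_burk_split`,
  `postcommit_assignments`, `reconcile_split`);
- a synthetic-data generator reproducing the observation design
  (`generate_study`, `simulate_records`), and readers/writers for the
  study CSV schemas (`read_study`, `write_study`, `run_pipeline`).

## Worked example

```r
library(txinit)

# a bursty promoter: rare activation, small bursts, one rate-limiting step
gen <- initiation_model(1/350, k_on = 1/500, k_off = 1/50)
interval_moments(gen)
#> interval moments: mean 3850 s, sd 4280 s, cv 1.112, median/mean 0.6484

# observe it the way the microscope would: 120-min movies, 60 s frames
des  <- observation_design(movie_length = 7200, sampling_interval = 60,
                           n_cells = 200)
set.seed(42)
recs <- simulate_records(gen, des, "C1")
table(is.finite(recs$ub_s))
#> FALSE  TRUE
#>   200   420    # every cell ends with one right-censored interval

# which architecture does BIC select?
cmp <- select_structure(recs, n_starts = 4, seed = 1)
cmp
#> model comparison (BIC, censored weight 0.5)
#>         structure df    loglik      bic delta_bic delta_bic_lb evidence
#> 1 on/off + 1-step  3 -2046.873 4112.508     0.000        0.000     <NA>
#> 2 on/off + 2-step  4 -2046.650 4118.316     5.808        5.594 positive
#> 3 on/off + 3-step  5 -2046.578 4124.425    11.916       11.489   strong
#> 4          1-step  1 -2117.988 4242.231   129.722      129.370   strong
#> 5          2-step  2 -2118.076 4248.661   136.152      135.976   strong
#> 6          3-step  3 -2118.165 4255.091   142.582      142.582   strong
#> best: on/off + 1-step (Delta-BIC 5.81 vs second best, LB 5.59, positive evidence)

fit <- cmp$candidates[[cmp$best]]
coef_canonical(fit$model)
#>        k_on       k_off          k1
#> 0.002043115 0.022157003 0.003265440   # truth: 0.002, 0.02, 0.00286

# does the data fit the model as well as data simulated from it?
parametric_bootstrap(recs, fit, rounds = 500, seed = 1, design = des)
#> parametric bootstrap: p_fraction 0.702 over 500 rounds (empirical loglik -2046.87)
```

The selected architecture retains the on/off switch with one sequential
step (the switching-free alternatives trail by >129 BIC units), the
recovered rates sit close to the generating values, and the bootstrap
p-fraction well above the 0.01 rejection threshold says the data are
typical of the fitted model.

## The analysis workflow

The `analysis/` scripts run the full study on synthetic data emulating the
measured design (three induction schemes x six temperatures of a lac/ara
hybrid promoter; a two-temperature tetA dataset), writing tables under
`results/`:

| script | what it does |
|---|---|
| `01_simulate_study.R` | generate the interval tables (study CSV schema) |
| `02_interval_moments.R` | censored-gamma mean/sd/cv per condition |
| `03_structure_selection.R` | on/off and step-count selection per condition |
| `04_temperature_laws.R` | law selection, shared-shape and RNAP-constrained fits |
| `05_commit_split.R` | step ambiguity + Lineweaver-Burk reconciliation |
| `06_goodness_of_fit.R` | parametric bootstrap per scheme and combined |

Run them in order from the repository root, e.g.
`Rscript analysis/01_simulate_study.R`.

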