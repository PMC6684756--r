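# xerograd

NTCP (normal tissue complication probability) modelling of
moderate-to-severe (CTCAE grade >= 2) xerostomia after head-and-neck
IMRT, for radiotherapy outcome researchers. Highly conformal plans keep
parotid mean doses low and homogeneous across patients — so the mean
dose alone predicts poorly — while their steep lateral dose gradients
make the *delivered* dose sensitive to the medial drift of the parotid
glands as patients lose weight during treatment. `xerograd` implements
the full analysis around that mechanism:

* **Dose features** from a 3D dose grid + structure mask: mean dose
  `MD` (Gy) and the average lateral dose gradient `GRADX` (Gy/mm,
  medial-positive), plus delivered-dose accumulation over a migrating
  mask (first-order law `delivered − planned ≈ GRADX · PGM / 2`).
* **Migration proxy** from serial external-contour volumes at the C2
  vertebra: `ΔVC2 = 100 (VC2_c − VC2_1)/VC2_1` [%],
  `PGM_c = −0.413 · ΔVC2` [mm], linearly extrapolated in time to the
  end of treatment.
* **Endpoint** pooling of 6–24-month CTCAE follow-up reports (mean
  grade, halves rounding up; positive = pooled grade >= 2).
* **Three nested logistic models** — `MD`, `MD + GRADX + MD:GRADX`,
  `+ PGM` — evaluated by leave-pair-out cross-validated AUC with BCa
  bootstrap confidence intervals, partial dependence profiles with
  percentile rugs, median-GRADX stratification (with the `1 − AUC`
  directional flip), and a Kendall-tau ipsi/contra concordance screen.
* **Synthetic phantoms and cohorts** reproducing the published summary
  statistics, so the entire pipeline is testable without clinical data.

## Worked example

```r
library(xerograd)

sim <- simulate_cohort(cohort_sim_config(seed = 1))
sim
#> <cohort_sim> 88 patients, 12 (13.6%) G2-positive, 388 reports

fit <- ntcp_fit(sim$cohort, model = "md_gradx_pgm", ridge_lambda = 0.05)
fit
#> Logistic NTCP model: label ~ md + gradx + md:gradx + pgm
#> n = 88 (12 events), ridge lambda = 0.05
#> Coefficients (standardized scale):
#> (Intercept)          md       gradx    md:gradx         pgm
#>     -2.1538      0.4024      0.5524      0.2423      0.6268

ntcp_evaluate(sim$cohort, "md_gradx_pgm", ridge_lambda = 0.05,
              n_bootstrap = 200, seed = 1)
#> Model label ~ md + gradx + md:gradx + pgm
#> LPO-CV AUC = 0.793  (95% BCa CI 0.525-0.876, B = 200)
#> pairs: 12 positive x 76 negative

stratify_by_median(sim$cohort, "gradx")
#> Median split on gradx (median = 1.263)
#>   low  stratum: n = 44 (1 events), AUC(md, higher-risk) = 0.907
#>   high stratum: n = 44 (11 events), AUC(md, higher-risk) = 0.658
```

Reading the output: the simulated cohort reproduces the intended
structure (88 patients, ~11% prevalence in expectation, a median
contralateral GRADX near 1.27 Gy/mm). All slopes of the full model are
positive on the standardized scale — risk rises with planned dose,
lateral gradient, and medial migration — and its leave-pair-out AUC of
0.79 sits at the level the mechanism was calibrated to. The migration
proxy itself is tiny but interpretable:

```r
pgm_at_control(-2)            # a 2% C2 contour shrinkage ...
#> [1] 0.826                   # ... maps to 0.83 mm medial migration
extrapolate_pgm(0.826, 32, 40)
#> [1] 1.0325                  # ... and 1.03 mm by treatment end
```

A full reproducible run (cohort, migration, endpoint, all three model
evaluations, partial dependence grids, stratification report, md5
manifest) is one call:

```r
run_pipeline(pipeline_config(seed = 42), "out/")
```

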