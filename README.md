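# stimmap

Where does deep brain stimulation (DBS) help? `stimmap` builds the two
standard population-level answers from a cohort of stimulated patients
and validates them on an independent cohort:

* **Sweet-spot model (R-map).** For voxels covered by at least
  `min_n = 3` patients' electric fields above 0.2 V/mm, the voxel value
  is the across-patient Spearman correlation between local E-field
  magnitude `e_iv` and clinical improvement `y_i`:
  `R(v) = Spearman_i(e_iv, y_i)`. A held-out patient's **Sweet Spot
  Score** is the spatial Spearman correlation between their magnitudes
  and `R(v)` over the voxels their own field activates.
* **Fiber-filtering model.** Each tract-atlas streamline `s` receives a
  **Fiber-R-Score** `r_s = Spearman_i(p_is, y_i)`, where `p_is` is the
  peak interpolated E-field magnitude along the streamline. A held-out
  patient is summarised by the **Weighted Mean of Fiber R-Scores**
  `W = sum(m_s * r_s) / sum(m_s)` over the streamlines their field
  intersects (`p_s > 0.2 V/mm`), with `m_s` the mean magnitude along
  the streamline.

Cohort-level validation correlates either score with clinical
improvement (UPDRS-III change scores or percent change, normalised to
improvement polarity) and reports Spearman's R with asymptotic and
permutation p-values.

The package targets methodologists and DBS imaging researchers who want
a transparent, fully testable implementation: E-fields come from a
declared point-source model (`|E| = A·k/max(r, r_min)²`) rather than a
finite-element solver, and a synthetic two-cohort generator plants a
known sweet spot and on/off-target fiber bundles so that every stage
can be verified against ground truth. See the methods vignette
(`vignettes/stimmap-methods.Rmd`) for models, assumptions, and design
choices.

## Worked example

```r
library(stimmap)

# a full synthetic study: 14-patient training cohort, 29-patient
# validation cohort, planted target at (12, -13, -6) mm
report <- run_full_study(synth_config(seed = 42), verbose = FALSE)
report
#> <study_report> seed 42
#>   sweet-spot arm: R = 0.469, perm p = 0.0130 (n = 29)
#>   fiber arm:      R = 0.609, perm p = 0.0020 (n = 29)
#>   sweet-spot peak (mm): 12, -13.5, -8.5
```

The sweet-spot map recovered the planted target to within 2.5 mm
(peak at (12, −13.5, −8.5) vs truth (12, −13, −6)), and both
out-of-sample scores correlate significantly with the validation
cohort's percent improvements. Per-patient scores and the
responder-threshold sweep are in the report:

```r
head(report$sweetspot_scores, 3)
#>   patient_id         rho n_voxels defined
#> 1        V01  0.04441423      614    TRUE
#> 2        V02  0.51684807     1317    TRUE
#> 3        V03 -0.42221909      456    TRUE

report$threshold_sweep[3:4, 1:5]
#>   threshold n_top n_remaining mean_distance_top mean_distance_remaining
#> 3         5     4          10          2.104601                4.697479
#> 4         8     6           8          2.309406                5.192095
```

Top-responder contacts (progression-score cuts of 5 and 8 points) sit
roughly half as far from the recovered sweet spot as the remaining
patients' contacts. `run_full_study(..., out_dir = "out")` additionally
persists every table, the model volumes (NIfTI + JSON sidecar), the
scored tractogram, and a markdown report; outputs are byte-reproducible
under a fixed seed.

Individual stages are available as plain functions:
`compute_efield()`, `mirror_to_hemisphere()`, `build_support_mask()`,
`map_sweet_spot()`, `sweet_spot_score()`, `fit_fiber_r()`,
`weighted_fiber_score()`, `validate_cohort()`, `responder_partition()`,
plus I/O (`read_volume()`, `read_tractogram()`, `read_cohort_table()`,
`read_stims()`) and outcome derivations (`progression_score()`,
`percent_improvement()`, `ledd()`).

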