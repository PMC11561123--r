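# Shared synthetic-study machinery for the heavier simulation tests.
# The 20-seed sweep is computed once per test run and cached.

.study_cache <- new.env(parent = emptyenv())

# fit both models on one seed's training cohort and score the validation
# cohort; returns the headline quantities
run_one_study <- function(seed) {
  cfg <- synth_config(seed = seed)
  st <- generate_study(cfg)
  grid <- st$grid
  ef_tr <- cohort_efields(mirror_to_hemisphere(st$train$stims, "right"), grid)
  ef_va <- cohort_efields(mirror_to_hemisphere(st$valid$stims, "right"), grid)
  imp <- cohort_improvement(st$train$cohort, "progression")
  model <- map_sweet_spot(ef_tr, imp)
  peak <- sweet_spot_peak(model)
  scored <- fit_fiber_r(ef_tr, imp, st$tractogram)
  ss <- sweet_spot_score_cohort(ef_va, model)
  fib <- weighted_fiber_score_cohort(ef_va, scored)
  rho_ss <- validate_cohort(ss, st$valid$cohort, outcome_type = "percent",
                            n_perm = 199, seed = seed * 101 + 4)$rho
  rho_fib <- validate_cohort(fib, st$valid$cohort, outcome_type = "percent",
                             n_perm = 199, seed = seed * 101 + 5)$rho
  list(peak_dist = sqrt(sum((peak - cfg$target_center)^2)),
       rho_ss = rho_ss, rho_fib = rho_fib)
}

study_sweep <- function(seeds = 1:20) {
  key <- paste0("sweep_", paste(range(seeds), collapse = "_"))
  if (is.null(.study_cache[[key]]))
    .study_cache[[key]] <- lapply(seeds, run_one_study)
  .study_cache[[key]]
}
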