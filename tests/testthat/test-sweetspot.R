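test_that("support mask counts strict threshold exceedances", {
  fields <- constant_fields(c(0.3, 0.3, 0.3))
  m <- build_support_mask(fields, threshold = 0.2, min_n = 3)
  expect_true(all(m$data == 1))              # 3 fields > 0.2 everywhere

  fields2 <- constant_fields(c(0.3, 0.3, 0.1))
  expect_true(all(build_support_mask(fields2, 0.2, 3)$data == 0))

  # exactly 0.2 does not count (strict >)
  fields3 <- constant_fields(c(0.2, 0.2, 0.2))
  expect_true(all(build_support_mask(fields3, 0.2, 3)$data == 0))

  expect_error(build_support_mask(list()), "empty")
  bad <- c(constant_fields(0.3), list(make_grid(c(5, 5, 5), 1)))
  expect_error(build_support_mask(bad, 0.2, 1), "geometry")
})

test_that("support mask matches the brute-force count on random cohorts", {
  set.seed(41)
  for (rep in 1:5) {
    fields <- lapply(1:5, function(i) random_volume(c(10, 10, 10)))
    # plant exact-threshold values to exercise the boundary
    fields[[1]]$data[1:3, 1, 1] <- 0.2
    m <- build_support_mask(fields, 0.2, 3)
    want <- brute_support_mask(lapply(fields, `[[`, "data"), 0.2, 3)
    expect_identical(m$data, want)
  }
})

test_that("rmap is the across-patient correlation at each support voxel", {
  # 4 patients; at every voxel magnitudes [0.1 .. 0.4] track improvements
  fields <- constant_fields(c(0.25, 0.3, 0.35, 0.4), dim = c(3, 3, 3))
  mask <- build_support_mask(fields, 0.2, 3)
  model <- map_sweet_spot(fields, outcomes = c(1, 2, 3, 4), mask = mask)
  expect_true(all(abs(model$rmap$data - 1) < 1e-12))  # perfect monotone
  model2 <- map_sweet_spot(fields, outcomes = c(4, 3, 2, 1), mask = mask)
  expect_true(all(abs(model2$rmap$data + 1) < 1e-12))

  # zero variance in magnitudes -> 0 by convention
  const <- constant_fields(c(0.3, 0.3, 0.3, 0.3), dim = c(3, 3, 3))
  m3 <- map_sweet_spot(const, outcomes = c(1, 2, 3, 4),
                       mask = build_support_mask(const, 0.2, 3))
  expect_true(all(m3$rmap$data == 0))
})

test_that("rmap values stay in [-1, 1] and ignore patient order", {
  set.seed(42)
  fields <- lapply(1:6, function(i) random_volume(c(6, 6, 6)))
  outcomes <- rnorm(6)
  model <- map_sweet_spot(fields, outcomes, efield_threshold = 0.3)
  expect_true(all(abs(model$rmap$data) <= 1 + 1e-12))
  perm <- sample(6)
  model_p <- map_sweet_spot(fields[perm], outcomes[perm],
                            efield_threshold = 0.3)
  expect_equal(model_p$rmap$data, model$rmap$data)
  # rmap is zero outside the mask
  expect_true(all(model$rmap$data[model$mask$data == 0] == 0))
})

test_that("score is +1 for a field increasing in rmap and NA off-support", {
  set.seed(43)
  fields <- lapply(1:6, function(i) random_volume(c(6, 6, 6)))
  model <- map_sweet_spot(fields, rnorm(6), efield_threshold = 0.3)
  stopifnot(sum(model$mask$data) >= 10)
  # build a patient whose magnitude is a strictly increasing function of rmap
  ef <- make_grid(c(6, 6, 6), 1)
  ef$data[] <- model$efield_threshold / 2
  idx <- which(model$mask$data == 1)
  r <- model$rmap$data[idx]
  ef$data[idx] <- model$efield_threshold + exp(r)   # monotone in rmap
  sc <- sweet_spot_score(ef, model, patient_id = "X")
  expect_equal(sc$rho, 1)
  expect_equal(sc$n_voxels, length(idx))

  # entirely below threshold inside the mask -> undefined marker
  low <- make_grid(c(6, 6, 6), 1)
  low$data[] <- model$efield_threshold / 10
  sc2 <- sweet_spot_score(low, model)
  expect_true(is.na(sc2$rho))
  expect_false(sc2$defined)
})

test_that("score is invariant under strictly increasing transforms", {
  set.seed(44)
  fields <- lapply(1:6, function(i) random_volume(c(6, 6, 6)))
  model <- map_sweet_spot(fields, rnorm(6), efield_threshold = 0.3)
  ef <- random_volume(c(6, 6, 6))
  base <- sweet_spot_score(ef, model)
  cube <- ef; cube$data <- ef$data^3
  model_c <- model; model_c$efield_threshold <- model$efield_threshold^3
  expect_identical(sweet_spot_score(cube, model_c)$rho, base$rho)
})

test_that("sweet-spot models persist as NIfTI + JSON sidecar", {
  set.seed(45)
  fields <- lapply(1:5, function(i) random_volume(c(5, 5, 5)))
  model <- map_sweet_spot(fields, rnorm(5), efield_threshold = 0.4)
  d <- tempfile()
  write_sweetspot_model(model, d)
  m2 <- read_sweetspot_model(d)
  expect_equal(m2$rmap$data, model$rmap$data, tolerance = 1e-6)
  expect_identical(m2$mask$data, model$mask$data)
  expect_equal(m2$efield_threshold, 0.4)
  expect_equal(m2$statistic, "spearman")
})
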