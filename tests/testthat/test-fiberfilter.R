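test_that("peak magnitude along a streamline is the interpolated maximum", {
  set.seed(51)
  v <- random_volume(c(8, 8, 8))
  # streamline through the global maximum voxel centre
  mx <- arrayInd(which.max(v$data), dim(v$data)) - 1L
  sl <- rbind(c(0, 0, 0), as.numeric(mx), c(7, 7, 7))
  sl <- voxel_to_world(v, sl)
  expect_equal(peak_magnitude_along(sl, v), max(v$data))

  # entirely outside the grid -> 0
  far <- rbind(c(100, 100, 100), c(110, 100, 100))
  expect_equal(peak_magnitude_along(far, v), 0)

  # 20-point streamline equals the brute-force point-wise maximum
  pts <- matrix(runif(60, 0, 7), ncol = 3)
  want <- max(vapply(seq_len(20), function(i)
    brute_trilinear(v$data, pts[i, ]), numeric(1)))
  expect_equal(peak_magnitude_along(voxel_to_world(v, pts), v), want,
               tolerance = 1e-10)
})

test_that("fiber scores are the across-patient exposure/outcome correlation", {
  # constant fields make every streamline's peak equal the field level
  fields <- constant_fields(c(0.3, 0.4, 0.5, 0.6))
  sl <- list(rbind(c(1, 1, 1), c(2, 2, 2)))
  trk <- new_tractogram(sl)
  scored <- fit_fiber_r(fields, outcomes = c(1, 2, 3, 4), trk)
  expect_equal(scored$fiber_r, 1)
  expect_false(scored$unscored)

  scored_rev <- fit_fiber_r(fields, outcomes = c(4, 3, 2, 1), trk)
  expect_equal(scored_rev$fiber_r, -1)

  # identical peaks across patients -> unscored, fiber_r = 0
  const <- constant_fields(c(0.5, 0.5, 0.5, 0.5))
  s2 <- fit_fiber_r(const, c(1, 2, 3, 4), trk)
  expect_true(s2$unscored)
  expect_equal(s2$fiber_r, 0)

  # exposure below min_exposed -> unscored
  weak <- constant_fields(c(0.3, 0.1, 0.1, 0.1))
  s3 <- fit_fiber_r(weak, c(1, 2, 3, 4), trk)
  expect_true(s3$unscored)

  expect_error(fit_fiber_r(fields[1:2], c(1, 2), trk), "cohort size")
})

test_that("fiber fitting ignores patient order", {
  set.seed(52)
  fields <- lapply(1:6, function(i) random_volume(c(6, 6, 6)))
  outcomes <- rnorm(6)
  sl <- lapply(1:4, function(i)
    voxel_to_world(fields[[1]], matrix(runif(12, 0, 5), ncol = 3)))
  trk <- new_tractogram(sl)
  a <- fit_fiber_r(fields, outcomes, trk)
  perm <- sample(6)
  b <- fit_fiber_r(fields[perm], outcomes[perm], trk)
  expect_equal(a$fiber_r, b$fiber_r)
})

test_that("weighted mean of fiber scores normalises as a convex mean", {
  v <- constant_fields(0.5)[[1]]
  sl1 <- list(rbind(c(1, 1, 1), c(2, 2, 2)))
  one <- new_tractogram(sl1, fiber_r = 0.5)
  sc <- weighted_fiber_score(v, one)
  expect_equal(sc$weighted_mean_r, 0.5)      # single fiber: mean = its score
  expect_equal(sc$n_intersected, 1)

  sl2 <- list(rbind(c(1, 1, 1), c(2, 2, 2)), rbind(c(1, 2, 1), c(2, 1, 2)))
  two <- new_tractogram(sl2, fiber_r = c(1, -1))
  expect_equal(weighted_fiber_score(v, two)$weighted_mean_r, 0)  # symmetry

  # below threshold everywhere -> undefined marker
  low <- constant_fields(0.05)[[1]]
  und <- weighted_fiber_score(low, one)
  expect_true(is.na(und$weighted_mean_r))
  expect_equal(und$n_intersected, 0)

  expect_error(weighted_fiber_score(v, new_tractogram(sl1)), "fiber_r")
})

test_that("weighted score matches a brute-force recomputation", {
  set.seed(53)
  v <- random_volume(c(10, 10, 10))
  sl <- lapply(1:50, function(i) {
    n <- sample(3:10, 1)
    voxel_to_world(v, matrix(runif(3 * n, 0, 9), ncol = 3))
  })
  trk <- new_tractogram(sl, fiber_r = runif(50, -1, 1))
  got <- weighted_fiber_score(v, trk, fiber_score_params(0.2, 3))
  want <- brute_weighted_fiber(v, trk, 0.2)
  expect_equal(got$weighted_mean_r, want$wmean, tolerance = 1e-12)
  expect_equal(got$n_intersected, want$n)
  # convexity: within the range of intersected fiber scores
  expect_gte(got$weighted_mean_r, min(trk$fiber_r))
  expect_lte(got$weighted_mean_r, max(trk$fiber_r))
})

test_that("uniform field rescaling with a matched threshold leaves the score", {
  set.seed(54)
  v <- random_volume(c(8, 8, 8))
  sl <- lapply(1:10, function(i)
    voxel_to_world(v, matrix(runif(12, 0, 7), ncol = 3)))
  trk <- new_tractogram(sl, fiber_r = runif(10, -1, 1))
  base <- weighted_fiber_score(v, trk, fiber_score_params(0.2, 3))
  v2 <- v; v2$data <- v$data * 3.7
  scaled <- weighted_fiber_score(v2, trk, fiber_score_params(0.2 * 3.7, 3))
  expect_equal(scaled$weighted_mean_r, base$weighted_mean_r,
               tolerance = 1e-12)
  expect_equal(scaled$n_intersected, base$n_intersected)
})
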