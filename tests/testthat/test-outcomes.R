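test_that("progression and percent change scores follow their definitions", {
  expect_equal(progression_score(28, 28), 0)
  expect_equal(progression_score(30, 28), -2)   # improvement of two points
  expect_true(is.na(progression_score(NA, 28)))

  expect_equal(percent_improvement(20, 10), 50)
  expect_equal(percent_improvement(20, 20), 0)
  expect_equal(percent_improvement(20, 30), -50)
  expect_true(is.na(percent_improvement(0, 10)))

  tab <- as_cohort_table(data.frame(patient_id = c("a", "b"),
                                    updrs3_pre = c(30, 20),
                                    updrs3_post = c(28, 30)))
  expect_equal(cohort_improvement(tab, "progression"), c(2, -10))
  expect_equal(cohort_improvement(tab, "percent"), c(100 * 2 / 30, -50))
})

test_that("LEDD sums dose times factor over the conversion table", {
  expect_equal(ledd(data.frame(drug = "levodopa", daily_dose_mg = 300)), 300)
  expect_equal(ledd(data.frame(drug = character(), daily_dose_mg = numeric())),
               0)
  custom <- data.frame(drug = c("a", "b"), factor = c(1.0, 0.25))
  expect_equal(ledd(data.frame(drug = c("a", "b"),
                               daily_dose_mg = c(100, 200)), custom), 150)
  expect_error(ledd(data.frame(drug = "unobtainium", daily_dose_mg = 1)),
               "unobtainium")
  # shipped table has the reference agents
  ft <- ledd_factors()
  expect_true(all(c("levodopa", "pramipexole", "rasagiline") %in% ft$drug))
  expect_equal(ft$factor[ft$drug == "levodopa"], 1)
})

test_that("spearman_rho matches the brute-force rank-then-Pearson oracle", {
  expect_equal(spearman_rho(1:3, c(10, 20, 30))$rho, 1)
  expect_equal(spearman_rho(1:3, c(3, 2, 1))$rho, -1)
  x <- c(1, 2, 2, 4); y <- c(1, 3, 2, 4)
  expect_equal(spearman_rho(x, y)$rho, brute_spearman(x, y),
               tolerance = 1e-15)
  expect_true(is.na(spearman_rho(c(1, 1, 1), 1:3)$rho))

  set.seed(61)
  for (rep in 1:50) {
    n <- sample(3:30, 1)
    a <- sample(1:8, n, replace = TRUE)   # plenty of ties
    b <- rnorm(n)
    got <- spearman_rho(a, b)
    if (!is.na(got$rho))
      expect_equal(got$rho, brute_spearman(a, b), tolerance = 1e-12)
  }
})

test_that("asymptotic p agrees with the t approximation", {
  set.seed(62)
  x <- rnorm(12); y <- x + rnorm(12)
  got <- spearman_rho(x, y)
  tstat <- got$rho * sqrt((12 - 2) / (1 - got$rho^2))
  expect_equal(got$p, 2 * pt(-abs(tstat), 10))
})

test_that("permutation p is reproducible and small for perfect correlation", {
  x <- 1:8; y <- 2 * (1:8)
  p1 <- permutation_p(x, y, n_perm = 999, seed = 7)
  p2 <- permutation_p(x, y, n_perm = 999, seed = 7)
  expect_identical(p1$p, p2$p)
  expect_lte(p1$p, 0.01)
  expect_error(permutation_p(x, y, n_perm = 50), "n_perm")
})

test_that("validate_cohort joins, excludes undefined scores, and counts", {
  tab <- as_cohort_table(data.frame(
    patient_id = sprintf("P%02d", 1:10),
    updrs3_pre = rep(20, 10),
    updrs3_post = 20 - (1:10)))          # improvement 5%..50%
  sc <- data.frame(patient_id = sprintf("P%02d", 1:10),
                   rho = (1:10) / 10, defined = TRUE)
  v <- validate_cohort(sc, tab, outcome_type = "percent", n_perm = 199,
                       seed = 3)
  expect_equal(v$rho, 1)                  # scores equal improvements in rank
  expect_equal(v$n_used, 10)
  expect_equal(v$n_undefined_excluded, 0)

  sc$rho[4] <- NA
  v2 <- validate_cohort(sc, tab, outcome_type = "percent", n_perm = 199,
                        seed = 3)
  expect_equal(v2$n_used, 9)
  expect_equal(v2$n_undefined_excluded, 1)

  sc_small <- sc[1:4, ]
  expect_error(validate_cohort(sc_small, tab[1:4, ], n_perm = 199),
               "sample-size")
})

test_that("responder partition thresholds, distances, and nesting behave", {
  tab <- as_cohort_table(data.frame(
    patient_id = sprintf("P%d", 1:6),
    updrs3_pre = rep(30, 6),
    updrs3_post = c(28, 29.5, 30, 30.7, 35, 38),  # progression -2..8
    ledd_pre = rep(400, 6), ledd_post = rep(500, 6)))
  contacts <- do.call(bind_stims, lapply(1:6, function(i)
    electrode_stim(sprintf("P%d", i), c(12 + i - 1, -13, -6), 1.9)))
  ref <- c(12, -13, -6)

  # threshold at the minimum score isolates the best patient
  p <- responder_partition(tab, contacts, threshold = -2, reference_mm = ref)
  expect_equal(sum(p$patients$group == "top"), 1)
  expect_equal(p$patients$distance_mm[p$patients$patient_id == "P1"], 0)

  # threshold 0: all stable-or-better patients (n = 4 here: -2,-0.5,0,0.7<=0?)
  p0 <- responder_partition(tab, contacts, threshold = 0, reference_mm = ref)
  expect_equal(sum(p0$patients$group == "top"), 3)
  expect_equal(sort(p0$patients$patient_id[p0$patients$group == "top"]),
               c("P1", "P2", "P3"))
  expect_true(all(c("top", "remaining") %in% p0$group_stats$group))

  # nesting across decreasing thresholds
  tops <- lapply(c(8, 5, 0, -2), function(th) {
    q <- responder_partition(tab, contacts, th, ref)$patients
    q$patient_id[q$group == "top"]
  })
  for (i in 2:4) expect_true(all(tops[[i]] %in% tops[[i - 1]]))
})

test_that("threshold sweep tabulates group sizes and distances consistently", {
  tab <- as_cohort_table(data.frame(
    patient_id = sprintf("P%d", 1:6),
    updrs3_pre = rep(30, 6),
    updrs3_post = c(28, 29, 30, 31, 35, 38)))
  contacts <- do.call(bind_stims, lapply(1:6, function(i)
    electrode_stim(sprintf("P%d", i), c(12 + (i - 1) / 2, -13, -6), 1.9)))
  ref <- c(12, -13, -6)
  sw <- threshold_sweep(tab, contacts, c(-2, 0, 5), ref)
  expect_equal(nrow(sw), 3)
  expect_true(all(diff(sw$n_top) >= 0))   # monotone nondecreasing
  # each sweep row agrees with a direct partition
  p0 <- responder_partition(tab, contacts, 0, ref)
  expect_equal(sw$n_top[sw$threshold == 0],
               sum(p0$patients$group == "top"))
  expect_equal(sw$mean_distance_top[sw$threshold == 0],
               mean(p0$patients$distance_mm[p0$patients$group == "top"]))
  expect_error(threshold_sweep(tab, contacts, 0, ref), "2 thresholds")
})
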