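#' Configuration for the synthetic two-cohort study generator
#'
#' Generates data emulating the structure of a two-cohort stimulation
#' mapping study: a small training cohort with washout change-score
#' outcomes, a larger validation cohort with long-term percent-change
#' outcomes, electrode contacts scattered around a planted target, and
#' streamline bundles that do or do not traverse the target. The planted
#' outcome model is linear in contact-to-target distance:
#' `improvement = a - b * distance + N(0, sd)`.
#'
#' @param seed integer seed; the full dataset is a deterministic
#'   function of it. Training and validation cohorts use independent
#'   substreams, so changing `n_valid` never alters the training data.
#' @param grid_shape,voxel_mm,grid_origin grid geometry (default a 24 mm
#'   box at 0.5 mm isotropic around the target region).
#' @param target_center planted sweet-spot coordinate, template mm.
#' @param target_sigma spatial scale (mm) of the target; on-target
#'   bundles pass within it, off-target bundles stay > 4x away.
#' @param n_train,n_valid cohort sizes (defaults 14 and 29).
#' @param contact_scatter_sigma sd (mm) of isotropic Gaussian contact
#'   scatter around the target, truncated at `contact_scatter_max`.
#' @param contact_scatter_max truncation radius (mm).
#' @param train_amp,valid_amp_v amplitude mean/sd in V for the training
#'   cohort and the voltage-controlled part of the validation cohort.
#' @param valid_amp_ma amplitude mean/sd in mA for the
#'   current-controlled validation patients.
#' @param n_valid_ma how many validation patients are current-controlled
#'   (default 8 of 29).
#' @param train_effect list `a` (points), `b` (points/mm), `sd` (points)
#'   of the training outcome model; `b = 0` gives a null cohort.
#' @param valid_effect list `a` (%), `b` (%/mm), `sd` (%) for the
#'   validation outcome model.
#' @param train_updrs_pre,valid_updrs_pre mean/sd of baseline UPDRS-III.
#' @param bundles list of bundle specs: `name`, `on_target` flag,
#'   `offset_mm` from the target, unit `direction`, `n_streamlines`,
#'   `half_length_mm`, `jitter_mm`, `n_points`.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed = 1,
                         grid_shape = c(48, 48, 48),
                         voxel_mm = 0.5,
                         grid_origin = c(0, -25, -18),
                         target_center = c(12, -13, -6),
                         target_sigma = 1,
                         n_train = 14,
                         n_valid = 29,
                         contact_scatter_sigma = 2,
                         contact_scatter_max = 5,
                         train_amp = c(mean = 1.9, sd = 0.3),
                         valid_amp_v = c(mean = 2.9, sd = 0.9),
                         valid_amp_ma = c(mean = 3.0, sd = 0.6),
                         n_valid_ma = 8,
                         train_effect = list(a = 2, b = 3, sd = 1.5),
                         valid_effect = list(a = 30, b = 12, sd = 12),
                         train_updrs_pre = c(mean = 28.0, sd = 10.2),
                         valid_updrs_pre = c(mean = 20.6, sd = 9.3),
                         bundles = default_bundles()) {
  if (target_sigma <= 0 || contact_scatter_sigma <= 0)
    stop("config error: sigmas must be > 0")
  if (n_train < 5 || n_valid < 5)
    stop("config error: cohorts must have at least 5 patients")
  if (any(grid_shape < 2) || voxel_mm <= 0)
    stop("config error: degenerate grid")
  structure(as.list(environment()), class = "synth_config")
}

#' Default streamline bundle specification
#'
#' Three on-target bundles traverse the planted target along different
#' axes (analogues of the beneficial motor-cortex pathways converging on
#' the sensorimotor target); five off-target bundles surround it at 5 mm
#' in the lateral, medial, anterior, posterior and dorsal directions,
#' close enough that displaced stimulation reaches them (analogues of
#' detrimental neighbouring pathways). On-target bundles are kept short
#' (6 mm half-length) so that stimulation exposure falls off with
#' displacement in every direction, not only transverse to the bundle.
#'
#' @return list of bundle specs for [synth_config()].
#' @export
default_bundles <- function() {
  on_b <- function(name, direction)
    list(name = name, on_target = TRUE, offset_mm = c(0, 0, 0),
         direction = direction, n_streamlines = 25,
         half_length_mm = 6, jitter_mm = 0.6, n_points = 30)
  off_b <- function(name, offset_mm, direction, half_length_mm = 8)
    list(name = name, on_target = FALSE, offset_mm = offset_mm,
         direction = direction, n_streamlines = 25,
         half_length_mm = half_length_mm, jitter_mm = 0.6, n_points = 30)
  list(
    on_b("on_target_a", c(0, 1, 0.5)),
    on_b("on_target_b", c(0.3, 1, -0.2)),
    on_b("on_target_c", c(0.2, 0.4, 1)),
    off_b("off_lateral",   c(5, 0, 0),  c(0, 1, 0)),
    off_b("off_medial",    c(-5, 0, 0), c(0, 1, 0)),
    off_b("off_anterior",  c(0, 5, 0),  c(1, 0, 0.2)),
    off_b("off_posterior", c(0, -5, 0), c(1, 0, -0.2)),
    off_b("off_dorsal",    c(0, 0, 5),  c(0, 1, 0)))
}

#' Empty volume over the configured grid
#'
#' @param config `synth_config`.
#' @return `stim_volume` of zeros.
#' @export
synth_grid <- function(config) {
  make_grid(config$grid_shape, config$voxel_mm, config$grid_origin)
}

# truncated isotropic Gaussian scatter around the origin
scatter_points <- function(n, sigma, rmax) {
  out <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    repeat {
      p <- stats::rnorm(3, 0, sigma)
      if (sqrt(sum(p^2)) <= rmax) break
    }
    out[i, ] <- p
  }
  out
}

#' Generate one synthetic cohort with planted ground truth
#'
#' Contacts are scattered around the planted target (half the patients
#' on the mirrored left side); outcomes follow the configured
#' linear-in-distance model. Training outcomes are emitted as a washout
#' pre/post pair (change score = post - pre), validation outcomes as a
#' pre/post pair realising the drawn percent improvement. UPDRS values
#' are clipped at 0.
#'
#' @param config `synth_config`.
#' @param which `"train"` or `"valid"`.
#' @return list: `stims` (`electrode_stims`), `cohort` (`cohort_table`),
#'   `truth` (target, per-patient distances and noiseless outcomes).
#' @export
generate_cohort <- function(config, which = c("train", "valid")) {
  which <- match.arg(which)
  set.seed(config$seed * 101 + if (which == "train") 1L else 2L)
  n <- if (which == "train") config$n_train else config$n_valid
  eff <- if (which == "train") config$train_effect else config$valid_effect
  pre_par <- if (which == "train") config$train_updrs_pre
             else config$valid_updrs_pre

  offs <- scatter_points(n, config$contact_scatter_sigma,
                         config$contact_scatter_max)
  contact_right <- sweep(offs, 2, config$target_center, `+`)
  dist <- sqrt(rowSums(offs^2))
  hemi <- rep(c("right", "left"), length.out = n)
  contact <- contact_right
  contact[hemi == "left", 1] <- -contact_right[hemi == "left", 1]

  if (which == "train") {
    amp <- pmax(stats::rnorm(n, config$train_amp["mean"],
                             config$train_amp["sd"]), 0.5)
    unit <- rep("V", n)
  } else {
    n_ma <- min(config$n_valid_ma, n)
    amp <- c(pmax(stats::rnorm(n - n_ma, config$valid_amp_v["mean"],
                               config$valid_amp_v["sd"]), 0.5),
             pmax(stats::rnorm(n_ma, config$valid_amp_ma["mean"],
                               config$valid_amp_ma["sd"]), 0.5))
    unit <- c(rep("V", n - n_ma), rep("mA", n_ma))
  }

  imp_true <- eff$a - eff$b * dist
  imp_obs <- imp_true + stats::rnorm(n, 0, eff$sd)
  pre <- pmax(stats::rnorm(n, pre_par["mean"], pre_par["sd"]), 5)
  if (which == "train") {
    post <- pmax(pre - imp_obs, 0)          # change score = post - pre
  } else {
    post <- pmax(pre * (1 - imp_obs / 100), 0)  # percent improvement
  }
  ledd_pre <- pmax(stats::rnorm(n, if (which == "train") 430 else 1378,
                                if (which == "train") 314 else 583), 0)
  ledd_post <- pmax(ledd_pre +
                      stats::rnorm(n, if (which == "train") 100 else -600,
                                   150), 0)
  ids <- sprintf("%s%02d", if (which == "train") "T" else "V", seq_len(n))

  stims <- do.call(bind_stims, lapply(seq_len(n), function(i)
    electrode_stim(ids[i], contact[i, ], amp[i], unit[i],
                   pulse_width_us = if (which == "train") 60 else 75,
                   frequency_hz = 130, hemisphere = hemi[i])))
  cohort <- as_cohort_table(data.frame(
    patient_id = ids, updrs3_pre = pre, updrs3_post = post,
    ledd_pre = ledd_pre, ledd_post = ledd_post,
    followup_years = if (which == "train") 2 else
      round(pmax(stats::rnorm(n, 5.4, 2.0), 2), 1),
    cohort_label = if (which == "train") "early" else "advanced",
    arm = "DBS", stringsAsFactors = FALSE))
  truth <- list(target_center = config$target_center,
                patient_id = ids, distance_mm = dist,
                improvement_true = imp_true,
                improvement_observed = imp_obs)
  list(stims = stims, cohort = cohort, truth = truth)
}

#' Generate a synthetic tractogram with on- and off-target bundles
#'
#' Streamlines are smooth spline interpolations of jittered control
#' points along each bundle's axis. On-target bundles are guaranteed to
#' pass within `target_sigma` of the target; off-target bundles to stay
#' more than `4 * target_sigma` away (violating draws are rejected and
#' redrawn).
#'
#' @param config `synth_config`.
#' @return `tractogram`; bundle membership is attached as attribute
#'   `bundle` (integer index) and `bundle_names`.
#' @export
generate_tractogram <- function(config) {
  set.seed(config$seed * 101 + 3L)
  if (!any(vapply(config$bundles, `[[`, TRUE, "on_target")) ||
      !all(vapply(config$bundles, function(b) is.logical(b$on_target), TRUE)))
    stop("config error: need at least one on-target bundle")
  if (all(vapply(config$bundles, `[[`, TRUE, "on_target")))
    stop("config error: need at least one off-target bundle")
  grid <- synth_grid(config)
  lo <- drop(voxel_to_world(grid, c(0, 0, 0)))
  hi <- drop(voxel_to_world(grid, dim(grid$data) - 1L))
  sl <- list()
  bundle_of <- integer(0)
  for (bi in seq_along(config$bundles)) {
    b <- config$bundles[[bi]]
    dir <- b$direction / sqrt(sum(b$direction^2))
    centre <- config$target_center + b$offset_mm
    t_ctrl <- seq(-b$half_length_mm, b$half_length_mm, length.out = 5)
    base <- outer(t_ctrl, dir) + matrix(centre, 5, 3, byrow = TRUE)
    if (any(base < matrix(lo, 5, 3, byrow = TRUE)) ||
        any(base > matrix(hi, 5, 3, byrow = TRUE)))
      stop("config error: bundle '", b$name, "' exceeds the grid")
    for (s in seq_len(b$n_streamlines)) {
      for (try in 1:100) {
        ctrl <- base + matrix(stats::rnorm(15, 0, b$jitter_mm), 5, 3)
        if (b$on_target) {
          # clamp the middle control point to guarantee target passage
          mid_off <- ctrl[3, ] - config$target_center
          nrm <- sqrt(sum(mid_off^2))
          if (nrm > 0.5 * config$target_sigma)
            ctrl[3, ] <- config$target_center +
              mid_off * 0.5 * config$target_sigma / nrm
        }
        pts <- vapply(1:3, function(c)
          stats::spline(t_ctrl, ctrl[, c],
                        xout = seq(min(t_ctrl), max(t_ctrl),
                                   length.out = b$n_points))$y,
          numeric(b$n_points))
        d <- sqrt(colSums((t(pts) - config$target_center)^2))
        ok <- if (b$on_target) min(d) < config$target_sigma
              else min(d) > 4 * config$target_sigma
        if (ok) break
      }
      if (!ok) stop("config error: bundle '", b$name,
                    "' cannot satisfy its target-distance constraint")
      sl[[length(sl) + 1L]] <- pts
      bundle_of <- c(bundle_of, bi)
    }
  }
  trk <- new_tractogram(sl)
  attr(trk, "bundle") <- bundle_of
  attr(trk, "bundle_names") <- vapply(config$bundles, `[[`, "", "name")
  attr(trk, "on_target") <- vapply(config$bundles, `[[`, TRUE, "on_target")
  trk
}

#' Generate the full synthetic study
#'
#' @param config `synth_config`.
#' @return list: `config`, `grid`, `train`, `valid` (each as from
#'   [generate_cohort()]), `tractogram`.
#' @export
generate_study <- function(config = synth_config()) {
  list(config = config,
       grid = synth_grid(config),
       train = generate_cohort(config, "train"),
       valid = generate_cohort(config, "valid"),
       tractogram = generate_tractogram(config))
}
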