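#' Parameters for streamline scoring
#'
#' @param efield_threshold magnitude (V/mm) above which a streamline
#'   counts as stimulated ("intersected") by a patient's field; shared
#'   default with the sweet-spot model (0.2).
#' @param min_exposed minimum number of patients whose fields reach a
#'   streamline for it to receive a score (default 3, must be >= 2).
#' @return list of class `fiber_score_params`.
#' @export
fiber_score_params <- function(efield_threshold = 0.2, min_exposed = 3) {
  if (efield_threshold <= 0) stop("efield_threshold must be > 0")
  if (min_exposed < 2) stop("min_exposed must be >= 2")
  structure(list(efield_threshold = efield_threshold,
                 min_exposed = min_exposed),
            class = "fiber_score_params")
}

#' Peak E-field magnitude along a streamline
#'
#' Maximum of the trilinearly interpolated field over the streamline's
#' points; points outside the grid read as 0.
#'
#' @param streamline n x 3 matrix of mm coordinates.
#' @param efield `stim_volume`.
#' @return scalar V/mm.
#' @export
peak_magnitude_along <- function(streamline, efield) {
  max(interp_volume(efield, rbind_points(streamline)))
}

#' Mean E-field magnitude along a streamline
#'
#' @inheritParams peak_magnitude_along
#' @return scalar V/mm.
#' @export
mean_magnitude_along <- function(streamline, efield) {
  mean(interp_volume(efield, rbind_points(streamline)))
}

# n_streamlines x n_patients matrix of a summary statistic along fibers
fiber_exposure_matrix <- function(tractogram, efields, stat = c("peak", "mean")) {
  stat <- match.arg(stat)
  f <- switch(stat, peak = max, mean = mean)
  vapply(efields, function(ef) {
    vapply(tractogram$streamlines,
           function(sl) f(interp_volume(ef, sl)), numeric(1))
  }, numeric(length(tractogram$streamlines)))
}

#' Assign Fiber-R-Scores to a tractogram from a training cohort
#'
#' Each streamline's score is the across-patient Spearman correlation
#' between the peak E-field magnitude along the streamline and the
#' clinical outcome (improvement polarity). Streamlines whose peak
#' exceeds the threshold in fewer than `min_exposed` patients, or whose
#' peaks have zero variance, are flagged unscored with `fiber_r = 0`.
#'
#' @param efields list of `stim_volume`, one per patient.
#' @param outcomes numeric vector aligned with `efields` (higher =
#'   better).
#' @param tractogram `tractogram` to score.
#' @param params `fiber_score_params`.
#' @return `tractogram` with `fiber_r` and `unscored` filled in.
#' @export
fit_fiber_r <- function(efields, outcomes, tractogram,
                        params = fiber_score_params()) {
  n <- length(efields)
  if (n < 3L) stop("input error: cohort size < 3")
  if (length(outcomes) != n)
    stop("input error: outcomes not aligned with efields")
  peaks <- fiber_exposure_matrix(tractogram, efields, "peak")
  if (!is.matrix(peaks)) peaks <- matrix(peaks, ncol = n)
  yr <- rank(outcomes)
  ns <- nrow(peaks)
  fiber_r <- numeric(ns)
  unscored <- logical(ns)
  for (s in seq_len(ns)) {
    x <- peaks[s, ]
    if (sum(x > params$efield_threshold) < params$min_exposed ||
        stats::sd(x) == 0) {
      unscored[s] <- TRUE
    } else {
      fiber_r[s] <- stats::cor(rank(x), yr)
    }
  }
  new_tractogram(tractogram$streamlines, fiber_r = fiber_r,
                 unscored = unscored)
}

#' Weighted mean of Fiber-R-Scores for one patient
#'
#' Streamlines intersected by the patient's field (peak magnitude above
#' the threshold) contribute their Fiber-R-Score weighted by the mean
#' interpolated magnitude along the streamline:
#' `weighted_mean_r = sum(m_s * r_s) / sum(m_s)`. The unnormalised
#' weighted sum is also reported. No intersected streamline yields an
#' undefined score.
#'
#' @param efield patient `stim_volume`.
#' @param scored_tractogram `tractogram` with `fiber_r` (from
#'   [fit_fiber_r()]).
#' @param params `fiber_score_params`.
#' @param patient_id optional id carried into the result.
#' @return one-row data.frame: `patient_id`, `weighted_mean_r`,
#'   `weighted_sum_r`, `n_intersected`, `defined`.
#' @export
weighted_fiber_score <- function(efield, scored_tractogram,
                                 params = fiber_score_params(),
                                 patient_id = NA_character_) {
  if (is.null(scored_tractogram$fiber_r))
    stop("state error: tractogram has no fiber_r (run fit_fiber_r first)")
  sl <- scored_tractogram$streamlines
  vals <- lapply(sl, function(s) interp_volume(efield, s))
  peak <- vapply(vals, max, numeric(1))
  hit <- peak > params$efield_threshold
  n_int <- sum(hit)
  wmean <- NA_real_
  wsum <- NA_real_
  if (n_int > 0L) {
    m <- vapply(vals[hit], mean, numeric(1))
    r <- scored_tractogram$fiber_r[hit]
    wsum <- sum(m * r)
    wmean <- wsum / sum(m)
  }
  data.frame(patient_id = patient_id, weighted_mean_r = wmean,
             weighted_sum_r = wsum, n_intersected = n_int,
             defined = n_int > 0L, stringsAsFactors = FALSE)
}

#' Weighted fiber scores for a cohort
#'
#' @param efields named list of `stim_volume`.
#' @inheritParams weighted_fiber_score
#' @return data.frame, one row per patient.
#' @export
weighted_fiber_score_cohort <- function(efields, scored_tractogram,
                                        params = fiber_score_params()) {
  ids <- names(efields)
  if (is.null(ids)) ids <- as.character(seq_along(efields))
  do.call(rbind, lapply(seq_along(efields), function(i)
    weighted_fiber_score(efields[[i]], scored_tractogram, params,
                         patient_id = ids[i])))
}

#' Export per-streamline scores as a data.frame
#'
#' @param scored_tractogram `tractogram` with `fiber_r`.
#' @return data.frame: `streamline_index`, `fiber_r`, `unscored`.
#' @export
fiber_r_table <- function(scored_tractogram) {
  if (is.null(scored_tractogram$fiber_r))
    stop("state error: tractogram has no fiber_r")
  data.frame(streamline_index = seq_along(scored_tractogram$streamlines),
             fiber_r = scored_tractogram$fiber_r,
             unscored = scored_tractogram$unscored)
}
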