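#' Parameters of the point-source E-field model
#'
#' The stimulation volume is modelled as an isotropic point source:
#' `magnitude(r) = amplitude * k_cal / max(r, r_min)^2` in V/mm, with the
#' singularity clamped inside `r_min`. Any smooth monotone radial field
#' preserves the rank-based statistics downstream; with `k_cal = 1` mm a
#' 2 V stimulation crosses the conventional 0.2 V/mm activation
#' threshold at sqrt(10) ~ 3.2 mm, a plausible stimulation extent.
#'
#' @param k_cal calibration constant in mm (> 0).
#' @param r_min clamp radius in mm (> 0); the field inside equals the
#'   field at `r_min`.
#' @param ma_to_v conversion factor applied to current-controlled (mA)
#'   amplitudes to place them on the model's V scale.
#' @return list of class `field_model_params`.
#' @export
field_model_params <- function(k_cal = 1.0, r_min = 0.5, ma_to_v = 1.0) {
  if (k_cal <= 0) stop("k_cal must be > 0")
  if (r_min <= 0) stop("r_min must be > 0")
  if (ma_to_v <= 0) stop("ma_to_v must be > 0")
  structure(list(k_cal = k_cal, r_min = r_min, ma_to_v = ma_to_v),
            class = "field_model_params")
}

# effective amplitude on the V scale
effective_amplitude <- function(amplitude, unit, params) {
  switch(unit,
         V = amplitude,
         mA = amplitude * params$ma_to_v,
         stop("unit error: unknown amplitude unit '", unit,
              "' (expected V or mA)"))
}

#' Compute a patient's E-field magnitude volume
#'
#' Evaluates the point-source model at every voxel centre of `grid`.
#'
#' @param stim one-row `electrode_stims` record.
#' @param grid `stim_volume` supplying the target geometry (its data are
#'   ignored).
#' @param params `field_model_params`.
#' @return `stim_volume` of magnitudes in V/mm.
#' @export
compute_efield <- function(stim, grid, params = field_model_params()) {
  stopifnot(nrow(stim) == 1L)
  amp <- effective_amplitude(stim$amplitude, stim$amplitude_unit, params)
  xyz <- grid_world_coords(grid)
  contact <- c(stim$contact_x, stim$contact_y, stim$contact_z)
  r <- sqrt((xyz[, 1] - contact[1])^2 + (xyz[, 2] - contact[2])^2 +
            (xyz[, 3] - contact[3])^2)
  mag <- amp * params$k_cal / pmax(r, params$r_min)^2
  new_volume(array(mag, dim = dim(grid$data)), grid$affine, grid$frame)
}

#' Radius of an E-field isocontour under the point-source model
#'
#' Solves `amplitude * k_cal / r^2 = threshold` for `r`.
#'
#' @param amplitude effective amplitude (V).
#' @param threshold magnitude threshold (V/mm).
#' @param params `field_model_params`.
#' @return radius in mm (at least `r_min`).
#' @export
efield_isocontour_radius <- function(amplitude, threshold,
                                     params = field_model_params()) {
  max(sqrt(amplitude * params$k_cal / threshold), params$r_min)
}

#' Mirror a stimulation record across the midsagittal plane
#'
#' Reflects the active-contact x-coordinate about `x = plane_x_mm`,
#' flips the hemisphere label, and leaves all stimulation parameters
#' unchanged. Used to pool bilateral implants in one common hemisphere.
#'
#' @param stim `electrode_stims` data.frame (any number of rows).
#' @param plane_x_mm x-position of the mirror plane (default 0).
#' @return mirrored `electrode_stims`.
#' @export
mirror_stim <- function(stim, plane_x_mm = 0) {
  out <- stim
  out$contact_x <- 2 * plane_x_mm - stim$contact_x
  out$hemisphere <- ifelse(stim$hemisphere == "left", "right", "left")
  out
}

#' Mirror stims into a single hemisphere
#'
#' Contacts on the far side of the mirror plane from the target
#' hemisphere are reflected; the rest pass through.
#'
#' @param stims `electrode_stims`.
#' @param to `"right"` (x > plane) or `"left"`.
#' @param plane_x_mm mirror plane.
#' @return `electrode_stims` with all contacts in the target hemisphere.
#' @export
mirror_to_hemisphere <- function(stims, to = "right", plane_x_mm = 0) {
  to <- match.arg(to, c("right", "left"))
  flip <- if (to == "right") stims$contact_x < plane_x_mm
          else stims$contact_x > plane_x_mm
  if (any(flip)) stims[flip, ] <- mirror_stim(stims[flip, ], plane_x_mm)
  stims
}

#' Pool two E-fields of one patient into a single volume
#'
#' @param efield_a,efield_b `stim_volume` E-fields on one grid.
#' @param mode `"max"` (voxel-wise maximum: stimulation reaches the voxel
#'   from either side) or `"mean"`.
#' @return pooled `stim_volume`.
#' @export
pool_bilateral <- function(efield_a, efield_b, mode = c("max", "mean")) {
  mode <- match.arg(mode)
  if (!same_grid(efield_a, efield_b))
    stop("geometry error: E-fields are not on the same grid")
  dat <- switch(mode,
                max = pmax(efield_a$data, efield_b$data),
                mean = (efield_a$data + efield_b$data) / 2)
  new_volume(dat, efield_a$affine, efield_a$frame)
}

#' Compute E-fields for a cohort of stimulation records
#'
#' @param stims `electrode_stims`, one row per patient (mirror first if
#'   pooling hemispheres).
#' @param grid `stim_volume` geometry.
#' @param params `field_model_params`.
#' @return named list of `stim_volume`, one per `patient_id`.
#' @export
cohort_efields <- function(stims, grid, params = field_model_params()) {
  fields <- lapply(seq_len(nrow(stims)), function(i)
    compute_efield(stims[i, ], grid, params))
  names(fields) <- stims$patient_id
  fields
}
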