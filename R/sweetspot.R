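#' Build the sweet-spot support mask from a cohort of E-fields
#'
#' A voxel enters the support when strictly more than `threshold` V/mm is
#' reached there by at least `min_n` patients' E-fields (magnitudes equal
#' to the threshold do not count).
#'
#' @param efields list of `stim_volume` E-fields on a common grid.
#' @param threshold E-field magnitude threshold in V/mm (default 0.2).
#' @param min_n minimum number of patients covering a voxel (default 3).
#' @return binary `stim_volume` mask.
#' @export
build_support_mask <- function(efields, threshold = 0.2, min_n = 3) {
  if (length(efields) == 0L) stop("input error: empty cohort of E-fields")
  check_common_grid(efields)
  counts <- Reduce(`+`, lapply(efields, function(v) (v$data > threshold) * 1L))
  g <- efields[[1]]
  new_volume(array(as.numeric(counts >= min_n), dim = dim(g$data)),
             g$affine, g$frame)
}

check_common_grid <- function(efields) {
  g <- efields[[1]]
  for (v in efields[-1])
    if (!same_grid(g, v))
      stop("geometry error: E-fields are not on a common grid")
  invisible(TRUE)
}

#' Map the sweet spot: voxel-wise outcome correlation over the support
#'
#' At every support-mask voxel the across-patient Spearman correlation
#' between local E-field magnitude and the clinical outcome is computed.
#' Outcomes must be passed in improvement polarity (higher = clinically
#' better), so positive map values always mean stimulation here
#' associates with better outcomes. Voxels where the magnitudes have
#' zero variance across patients get a value of 0.
#'
#' @param efields list of `stim_volume` on one grid, one per patient.
#' @param outcomes numeric vector aligned with `efields`, improvement
#'   polarity.
#' @param mask binary support `stim_volume` from [build_support_mask()],
#'   or `NULL` to build it with the defaults.
#' @param statistic `"spearman"` (default) or `"pearson"`.
#' @param efield_threshold,min_n stored in the model and used when `mask`
#'   is `NULL`.
#' @return object of class `sweetspot_model`: list with `rmap` and
#'   `mask` volumes, `efield_threshold`, `min_n`, `statistic`.
#' @export
map_sweet_spot <- function(efields, outcomes, mask = NULL,
                           statistic = c("spearman", "pearson"),
                           efield_threshold = 0.2, min_n = 3) {
  statistic <- match.arg(statistic)
  n <- length(efields)
  if (n < min_n)
    stop("input error: fewer than min_n = ", min_n, " patients")
  if (length(outcomes) != n)
    stop("input error: outcomes not aligned with efields")
  check_common_grid(efields)
  if (is.null(mask))
    mask <- build_support_mask(efields, efield_threshold, min_n)
  g <- efields[[1]]
  if (!same_grid(g, mask))
    stop("geometry error: mask not on the E-field grid")
  idx <- which(mask$data == 1)
  rvals <- numeric(length(idx))
  if (length(idx)) {
    mat <- vapply(efields, function(v) v$data[idx], numeric(length(idx)))
    if (!is.matrix(mat)) mat <- matrix(mat, nrow = length(idx))
    # mat: n_voxels x n_patients
    y <- if (statistic == "spearman") rank(outcomes) else outcomes
    xr <- if (statistic == "spearman") t(apply(mat, 1L, rank)) else mat
    if (length(idx) == 1L) xr <- matrix(xr, nrow = 1L)
    xc <- xr - rowMeans(xr)
    yc <- y - mean(y)
    sx <- sqrt(rowSums(xc^2))
    sy <- sqrt(sum(yc^2))
    ok <- sx > 0 & sy > 0
    rvals[ok] <- (xc %*% yc)[ok] / (sx[ok] * sy)
  }
  rmap <- array(0, dim = dim(g$data))
  rmap[idx] <- rvals
  structure(list(rmap = new_volume(rmap, g$affine, g$frame),
                 mask = mask,
                 efield_threshold = efield_threshold,
                 min_n = min_n,
                 statistic = statistic),
            class = "sweetspot_model")
}

#' @export
print.sweetspot_model <- function(x, ...) {
  nv <- sum(x$mask$data)
  cat("<sweetspot_model> support:", nv, "voxels; statistic:",
      x$statistic, "\n")
  if (nv > 0)
    cat("  rmap range:", paste(signif(range(x$rmap$data[x$mask$data == 1]), 3),
                               collapse = " .. "), "\n")
  invisible(x)
}

#' World coordinate of the sweet-spot peak
#'
#' @param model `sweetspot_model`.
#' @return length-3 mm coordinate of the maximum rmap value (first voxel
#'   in array order on ties).
#' @export
sweet_spot_peak <- function(model) {
  idx <- which(model$mask$data == 1)
  if (!length(idx)) stop("sweet-spot model has an empty support mask")
  best <- idx[which.max(model$rmap$data[idx])]
  ijk <- arrayInd(best, dim(model$rmap$data)) - 1L
  drop(voxel_to_world(model$rmap, ijk))
}

#' Score a patient's E-field against a sweet-spot model
#'
#' The patient's magnitudes are Spearman-correlated with the model's
#' rmap values over the voxel support. The default support is the model
#' mask restricted to voxels where the patient's own field exceeds the
#' model's E-field threshold; rank correlation makes the score invariant
#' to any strictly increasing transform of the magnitudes. Supports
#' smaller than `min_support` voxels yield an undefined score (`NA`
#' rho), reported rather than silently zeroed.
#'
#' @param efield patient `stim_volume` on the model grid.
#' @param model `sweetspot_model`.
#' @param support `"thresholded"` (default), `"mask"` (full model mask),
#'   or `"nonzero"` (mask voxels where the patient field is > 0).
#' @param min_support minimum number of support voxels for a defined
#'   score (default 10).
#' @param patient_id optional id carried into the result.
#' @return one-row data.frame: `patient_id`, `rho`, `n_voxels`,
#'   `defined`.
#' @export
sweet_spot_score <- function(efield, model,
                             support = c("thresholded", "mask", "nonzero"),
                             min_support = 10, patient_id = NA_character_) {
  support <- match.arg(support)
  if (!same_grid(efield, model$rmap))
    stop("geometry error: E-field not on the model grid")
  idx <- which(model$mask$data == 1)
  sel <- switch(support,
                thresholded = idx[efield$data[idx] > model$efield_threshold],
                mask = idx,
                nonzero = idx[efield$data[idx] > 0])
  n_vox <- length(sel)
  rho <- NA_real_
  if (n_vox >= min_support) {
    x <- efield$data[sel]
    y <- model$rmap$data[sel]
    if (stats::sd(x) > 0 && stats::sd(y) > 0)
      rho <- stats::cor(rank(x), rank(y))
  }
  data.frame(patient_id = patient_id, rho = rho, n_voxels = n_vox,
             defined = !is.na(rho), stringsAsFactors = FALSE)
}

#' Score a cohort of E-fields against a sweet-spot model
#'
#' @param efields named list of `stim_volume` (names = patient ids).
#' @inheritParams sweet_spot_score
#' @return data.frame with one row per patient.
#' @export
sweet_spot_score_cohort <- function(efields, model, support = "thresholded",
                                    min_support = 10) {
  ids <- names(efields)
  if (is.null(ids)) ids <- as.character(seq_along(efields))
  do.call(rbind, lapply(seq_along(efields), function(i)
    sweet_spot_score(efields[[i]], model, support = support,
                     min_support = min_support, patient_id = ids[i])))
}

#' Persist a sweet-spot model as NIfTI volumes plus a JSON sidecar
#'
#' @param model `sweetspot_model`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sweetspot_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(model$rmap, file.path(dir, "rmap.nii.gz"))
  write_volume(model$mask, file.path(dir, "mask.nii.gz"))
  jsonlite::write_json(list(efield_threshold = model$efield_threshold,
                            min_n = model$min_n,
                            statistic = model$statistic),
                       file.path(dir, "model.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Load a persisted sweet-spot model
#'
#' @param dir directory written by [write_sweetspot_model()].
#' @return `sweetspot_model`.
#' @export
read_sweetspot_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  mask <- read_volume(file.path(dir, "mask.nii.gz"))
  mask$data <- array(as.numeric(mask$data > 0.5), dim = dim(mask$data))
  structure(list(rmap = read_volume(file.path(dir, "rmap.nii.gz")),
                 mask = mask,
                 efield_threshold = meta$efield_threshold,
                 min_n = meta$min_n,
                 statistic = meta$statistic),
            class = "sweetspot_model")
}
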