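#' Spatial volume: 3D scalar grid plus voxel-to-world affine
#'
#' A `stim_volume` holds a 3D numeric array together with a 4x4 affine
#' matrix mapping 0-based voxel indices `(i, j, k)` to template-space
#' millimetre coordinates, and a free-text label for the template frame.
#' All spatial quantities in this package (E-field magnitudes in V/mm,
#' correlation maps, binary masks) live in this container; the affine is
#' the single source of truth for geometry.
#'
#' @param data 3D numeric array.
#' @param affine 4x4 numeric matrix, voxel (0-based) to mm. Must be
#'   invertible.
#' @param frame character label of the template space.
#' @return An object of class `stim_volume` with fields `data`, `affine`,
#'   `frame`.
#' @export
new_volume <- function(data, affine, frame = "MNI-like synthetic") {
  if (!is.array(data) || length(dim(data)) != 3L || any(dim(data) < 1L))
    stop("volume data must be a 3D array with positive dimensions")
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  if (abs(det(affine)) < .Machine$double.eps * 100)
    stop("affine is not invertible (determinant ~ 0)")
  structure(list(data = data, affine = affine, frame = frame),
            class = "stim_volume")
}

#' @export
print.stim_volume <- function(x, ...) {
  cat("<stim_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, frame '", x$frame, "'\n", sep = "")
  cat("  voxel size (mm):",
      paste(signif(sqrt(colSums(x$affine[1:3, 1:3]^2)), 4), collapse = " x "),
      "\n")
  invisible(x)
}

#' Construct an empty volume over a regular grid
#'
#' @param shape integer 3-vector of voxel counts.
#' @param voxel_mm scalar or 3-vector voxel edge length in mm.
#' @param origin_mm mm coordinate of voxel (0,0,0).
#' @param frame template frame label.
#' @return `stim_volume` of zeros.
#' @export
make_grid <- function(shape, voxel_mm = 0.5, origin_mm = c(0, 0, 0),
                      frame = "MNI-like synthetic") {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape > 0L))
  voxel_mm <- rep_len(as.numeric(voxel_mm), 3L)
  affine <- diag(4)
  diag(affine)[1:3] <- voxel_mm
  affine[1:3, 4] <- as.numeric(origin_mm)
  new_volume(array(0, dim = shape), affine, frame)
}

#' Convert 0-based voxel indices to world mm coordinates
#'
#' @param vol a `stim_volume`.
#' @param ijk n x 3 matrix (or length-3 vector) of 0-based voxel indices,
#'   possibly fractional.
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_to_world <- function(vol, ijk) {
  ijk <- rbind_points(ijk)
  t(vol$affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
}

#' Convert world mm coordinates to 0-based (fractional) voxel indices
#'
#' @inheritParams voxel_to_world
#' @param xyz n x 3 matrix (or length-3 vector) of mm coordinates.
#' @return n x 3 matrix of continuous 0-based voxel indices.
#' @export
world_to_voxel <- function(vol, xyz) {
  xyz <- rbind_points(xyz)
  t(solve(vol$affine) %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]
}

# coerce a 3-vector or n x 3 matrix to matrix form
rbind_points <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3L, byrow = TRUE)
  storage.mode(p) <- "double"
  if (ncol(p) != 3L) stop("points must be a length-3 vector or n x 3 matrix")
  p
}

#' World mm coordinates of every voxel centre
#'
#' @param vol a `stim_volume`.
#' @return (prod(dim) x 3) matrix, voxels in R's column-major array order.
#' @export
grid_world_coords <- function(vol) {
  d <- dim(vol$data)
  ijk <- as.matrix(expand.grid(i = 0:(d[1] - 1L), j = 0:(d[2] - 1L),
                               k = 0:(d[3] - 1L)))
  voxel_to_world(vol, ijk)
}

#' Check that two volumes share a grid (shape and affine)
#'
#' @param a,b `stim_volume` objects.
#' @param tol numeric tolerance on affine entries.
#' @return TRUE/FALSE.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$affine - b$affine)) <= tol
}

#' Read a NIfTI-1 volume
#'
#' Wraps [RNifti::readNifti()]; the returned affine is the file's
#' sform/qform (0-based voxel to mm, the NIfTI convention).
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param frame template frame label to attach.
#' @return `stim_volume`.
#' @export
read_volume <- function(path, frame = "MNI-like synthetic") {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("malformed NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  affine <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  affine <- matrix(as.numeric(affine), 4, 4)
  if (abs(det(affine)) < .Machine$double.eps * 100)
    stop("malformed NIfTI file '", path,
         "': header field sform/qform affine is not invertible")
  dd <- dim(img)
  if (length(dd) > 3L) {
    if (prod(dd[-(1:3)]) != 1L)
      stop("malformed NIfTI file '", path,
           "': header field dim describes >3 non-singleton dimensions")
    dd <- dd[1:3]
  }
  new_volume(array(as.numeric(img), dim = dd), affine, frame)
}

#' Write a volume as NIfTI-1
#'
#' @param vol `stim_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Trilinear interpolation of a volume at world mm points
#'
#' Points outside the grid read as 0 (the out-of-bounds convention used
#' for E-fields, whose magnitudes decay to zero far from the contact).
#'
#' @param vol `stim_volume`.
#' @param xyz n x 3 matrix (or 3-vector) of mm coordinates.
#' @return numeric vector of interpolated values.
#' @export
interp_volume <- function(vol, xyz) {
  p <- world_to_voxel(vol, xyz)            # continuous 0-based indices
  d <- dim(vol$data)
  n <- nrow(p)
  out <- numeric(n)
  inb <- p[, 1] >= 0 & p[, 1] <= d[1] - 1 &
         p[, 2] >= 0 & p[, 2] <= d[2] - 1 &
         p[, 3] >= 0 & p[, 3] <= d[3] - 1
  if (!any(inb)) return(out)
  q <- p[inb, , drop = FALSE]
  f0 <- pmin(floor(q), rep(d - 2L, each = nrow(q)))  # keep upper corner legal
  f0 <- pmax(f0, 0)
  fr <- q - f0
  i0 <- f0[, 1] + 1L; j0 <- f0[, 2] + 1L; k0 <- f0[, 3] + 1L  # 1-based
  arr <- vol$data
  v <- numeric(nrow(q))
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    w <- (if (di) fr[, 1] else 1 - fr[, 1]) *
         (if (dj) fr[, 2] else 1 - fr[, 2]) *
         (if (dk) fr[, 3] else 1 - fr[, 3])
    v <- v + w * arr[cbind(i0 + di, j0 + dj, k0 + dk)]
  }
  out[inb] <- v
  out
}
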