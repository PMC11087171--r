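#' Axis-aligned volume geometry
#'
#' Shared geometry of every grid in a study: voxel counts, voxel spacing in
#' mm, and the position (mm, LPS patient coordinates) of the center of voxel
#' `[1, 1, 1]`. All structure masks and dose grids carry one of these and
#' operations require them to match.
#'
#' @param shape Integer length-3 voxel counts `(nx, ny, nz)`.
#' @param spacing Numeric length-3 voxel spacing, mm; all positive.
#' @param origin Numeric length-3 center of the first voxel, mm; default 0.
#' @return An object of class `volume_geometry`.
#' @export
volume_geometry <- function(shape, spacing, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(shape) == 3, all(shape >= 1),
            length(spacing) == 3, all(spacing > 0),
            length(origin) == 3, all(is.finite(origin)))
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "volume_geometry")
}

#' @export
print.volume_geometry <- function(x, ...) {
  cat(sprintf("<volume_geometry> %dx%dx%d voxels @ %gx%gx%g mm, origin (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

same_geometry <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_geometry_mismatch <- function(a, b) {
  if (!same_geometry(a, b)) stop("volumes do not share a geometry")
  invisible(TRUE)
}

#' Volume of one voxel in cubic centimetres
#'
#' @param geometry A `volume_geometry`.
#' @return Scalar, cc.
#' @export
voxel_volume_cc <- function(geometry) {
  prod(geometry$spacing) / 1000
}

#' Voxel-center coordinates along one axis
#' @keywords internal
axis_coords <- function(geometry, axis) {
  geometry$origin[axis] + (seq_len(geometry$shape[axis]) - 1) * geometry$spacing[axis]
}

#' Binary structure mask on a volume geometry
#'
#' @param occupancy Logical 3D array matching `geometry$shape`.
#' @param geometry A `volume_geometry`.
#' @param name Structure name.
#' @param role One of `"TARGET_CTV"`, `"TARGET_PTV"`, `"OAR"`, `"BODY"`,
#'   `"RING"`, `"BOLUS"`.
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(occupancy, geometry, name = "structure",
                           role = c("OAR", "TARGET_CTV", "TARGET_PTV",
                                    "BODY", "RING", "BOLUS")) {
  role <- match.arg(role)
  stopifnot(is.logical(occupancy), inherits(geometry, "volume_geometry"))
  if (!identical(dim(occupancy), geometry$shape)) {
    stop("occupancy shape does not match geometry")
  }
  structure(list(occupancy = occupancy, geometry = geometry,
                 name = name, role = role),
            class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask> '%s' (%s): %d voxels, %.2f cc\n",
              x$name, x$role, sum(x$occupancy),
              sum(x$occupancy) * voxel_volume_cc(x$geometry)))
  invisible(x)
}

#' Total structure volume in cc
#' @param mask A `structure_mask`.
#' @return Scalar, cc.
#' @export
mask_volume_cc <- function(mask) {
  sum(mask$occupancy) * voxel_volume_cc(mask$geometry)
}

#' 3D dose grid in Gy on a volume geometry
#'
#' @param dose Numeric 3D array, Gy, non-negative and finite.
#' @param geometry A `volume_geometry`.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(dose, geometry) {
  stopifnot(is.numeric(dose), inherits(geometry, "volume_geometry"))
  if (!identical(dim(dose), geometry$shape)) stop("dose shape does not match geometry")
  if (any(!is.finite(dose)) || any(dose < 0)) stop("dose must be finite and >= 0")
  structure(list(dose = dose, geometry = geometry), class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %dx%dx%d, max %.2f Gy, mean %.2f Gy\n",
              x$geometry$shape[1], x$geometry$shape[2], x$geometry$shape[3],
              max(x$dose), mean(x$dose)))
  invisible(x)
}
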