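#' Relative gantry offsets of the standardized multi-field arrangement
#'
#' The arrangement is built outward from the medial tangent field in
#' "lateral-sign units": positive offsets rotate laterally (over the
#' ipsilateral hemithorax), negative offsets medially. Starting from the
#' medial tangent (offset 0) the sequence adds two fields in 8-degree steps
#' laterally, two more in 16-degree steps, jumps 96 degrees to the first
#' lateral field, adds two more 16-degree steps, five more 8-degree steps,
#' and finally a posterior-axillary-boost (PAB) field 24 degrees past the
#' final lateral field (adjustable by +/- 8 degrees). Up to four optional
#' extra fields may be prepended medially in 8-degree steps.
#'
#' The resulting partial ring of fixed fields mimics a volumetric arc while
#' remaining a static-field IMRT delivery, and by construction contains no
#' directly opposed beam pair.
#'
#' @param n_medial_extra Integer in `0:4`, number of additional medial fields.
#' @param pab_offset_adjust PAB offset adjustment in degrees, one of
#'   `-8`, `0`, `8`.
#' @return Numeric vector of signed offsets (degrees, lateral-sign units),
#'   strictly increasing, of length `14 + n_medial_extra`.
#' @examples
#' relative_offsets(1)          # the default 15-field sequence
#' length(relative_offsets(3))  # 17 fields
#' @export
relative_offsets <- function(n_medial_extra = 1L, pab_offset_adjust = 0L) {
  if (!is.numeric(n_medial_extra) || length(n_medial_extra) != 1 ||
      n_medial_extra != as.integer(n_medial_extra) ||
      n_medial_extra < 0 || n_medial_extra > 4) {
    stop("`n_medial_extra` must be an integer in 0..4")
  }
  if (!pab_offset_adjust %in% c(-8, 0, 8)) {
    stop("`pab_offset_adjust` must be one of -8, 0, 8")
  }
  n_medial_extra <- as.integer(n_medial_extra)
  medial <- if (n_medial_extra > 0) -8 * seq(n_medial_extra, 1) else numeric(0)
  c(
    medial,
    0,                        # medial tangent
    8, 16,                    # two fields, 8-degree steps
    32, 48,                   # two fields, 16-degree steps
    144,                      # first lateral field, 96 degrees on
    160, 176,                 # two fields, 16-degree steps
    184, 192, 200, 208, 216,  # five fields, 8-degree steps
    240 + pab_offset_adjust   # PAB, 24 degrees past the final lateral field
  )
}

field_role_for_offset <- function(offset, is_last) {
  if (is_last) return("PAB")
  if (offset < 0) return("MEDIAL_EXTRA")
  if (offset == 0) return("MEDIAL_TANGENT")
  if (offset <= 48) return("MEDIAL_ARC")
  "LATERAL_ARC"
}

#' Generate the standardized beam arrangement from a medial tangent angle
#'
#' Places the full 14-18 field arrangement (default 15 fields) given the
#' single planner choice that drives everything else: the medial tangent
#' gantry angle. Every other field is derived by [relative_offsets()], with
#' the rotation direction set by the target laterality
#' (see [lateral_sign()]). Fields are returned ordered from the most medial
#' field to the PAB.
#'
#' The function verifies that no two fields are directly opposed (minimum
#' over pairs of `||delta gantry| - 180|` of at least 4 degrees, half the
#' smallest placement increment) and aborts otherwise, since opposed beams
#' degrade plan quality and signal a pathological tangent choice.
#'
#' @param medial_tangent Medial tangent gantry angle, degrees, IEC 61217.
#' @param laterality `"LEFT"` or `"RIGHT"`.
#' @param n_medial_extra Integer in `0:4`; default 1 gives 15 fields.
#' @param pab_offset_adjust PAB adjustment in degrees, one of `-8`, `0`, `8`.
#' @param isocenter Numeric length-3 isocenter position, mm, patient (LPS)
#'   coordinates.
#' @return An object of class `beam_arrangement`: a list with `laterality`,
#'   `medial_tangent`, `n_medial_extra`, `pab_offset_adjust`, `isocenter`
#'   and `fields`, a data frame with columns `id`, `role`, `offset_deg`,
#'   `gantry_deg`.
#' @examples
#' arr <- generate_arrangement(310, "LEFT")
#' nrow(arr$fields)  # 15
#' subset(arr$fields, role == "PAB")$gantry_deg  # 190
#' @export
generate_arrangement <- function(medial_tangent, laterality,
                                 n_medial_extra = 1L, pab_offset_adjust = 0L,
                                 isocenter = c(0, 0, 0)) {
  stopifnot(is.numeric(medial_tangent), length(medial_tangent) == 1,
            is.finite(medial_tangent),
            is.numeric(isocenter), length(isocenter) == 3)
  side <- match.arg(toupper(laterality), c("LEFT", "RIGHT"))
  offsets <- relative_offsets(n_medial_extra, pab_offset_adjust)
  sgn <- lateral_sign(side)
  gantry <- normalize_angle(medial_tangent + sgn * offsets)

  n <- length(offsets)
  roles <- vapply(seq_len(n), function(i) {
    field_role_for_offset(offsets[i], i == n)
  }, character(1))
  ids <- sprintf("F%02d_%s", seq_len(n), roles)

  fields <- data.frame(
    id = ids, role = roles, offset_deg = offsets, gantry_deg = gantry,
    stringsAsFactors = FALSE
  )

  opp <- opposition_margin(gantry)
  if (opp < 4) {
    stop(sprintf(
      "arrangement contains a (nearly) opposed beam pair (margin %.2f deg < 4 deg); choose a different medial tangent",
      opp
    ))
  }

  structure(
    list(
      laterality = side,
      medial_tangent = normalize_angle(medial_tangent),
      n_medial_extra = as.integer(n_medial_extra),
      pab_offset_adjust = as.integer(pab_offset_adjust),
      isocenter = as.numeric(isocenter),
      fields = fields
    ),
    class = "beam_arrangement"
  )
}

#' Minimum opposition margin over all field pairs
#'
#' @param gantry_deg Vector of gantry angles, degrees.
#' @return `min` over unordered pairs of `||delta| - 180|`, degrees;
#'   `Inf` for fewer than two fields.
#' @keywords internal
opposition_margin <- function(gantry_deg) {
  n <- length(gantry_deg)
  if (n < 2) return(Inf)
  pairs <- utils::combn(n, 2)
  sep <- angle_separation(gantry_deg[pairs[1, ]], gantry_deg[pairs[2, ]])
  min(abs(sep - 180))
}

#' @export
print.beam_arrangement <- function(x, ...) {
  cat(sprintf(
    "<beam_arrangement> %s-sided, %d fields, medial tangent %.1f deg, PAB adjust %+d\n",
    x$laterality, nrow(x$fields), x$medial_tangent, x$pab_offset_adjust
  ))
  print(x$fields, row.names = FALSE)
  invisible(x)
}

#' Reduce an arrangement to a smaller number of fields
#'
#' Keeps the medial tangent and the PAB and thins the remaining fields as
#' evenly as possible across the partial ring. Used to study how plan quality
#' degrades as fields are removed from the standard arrangement.
#'
#' @param arrangement A `beam_arrangement`.
#' @param n_fields Target field count, between 3 and the current count.
#' @return A `beam_arrangement` with `n_fields` fields.
#' @export
reduce_arrangement <- function(arrangement, n_fields) {
  stopifnot(inherits(arrangement, "beam_arrangement"))
  n <- nrow(arrangement$fields)
  if (n_fields < 3 || n_fields > n) {
    stop(sprintf("`n_fields` must be in 3..%d", n))
  }
  tangent_i <- which(arrangement$fields$role == "MEDIAL_TANGENT")
  keep <- unique(c(tangent_i, round(seq(1, n, length.out = n_fields))))
  # evenly spaced subset; force the tangent in, then trim from the interior
  while (length(keep) > n_fields) {
    interior <- setdiff(keep, c(1, tangent_i, n))
    keep <- setdiff(keep, interior[ceiling(length(interior) / 2)])
  }
  out <- arrangement
  out$fields <- arrangement$fields[sort(keep), , drop = FALSE]
  rownames(out$fields) <- NULL
  out
}

#' Check clearance of patient points against the machine bore
#'
#' Ring-gantry machines have a closed bore (default radius 500 mm for a
#' 100 cm diameter bore); any part of the patient - most commonly the
#' contralateral elbow, which is usually outside the CT field of view - must
#' clear it with a safety margin. Each clearance point is localized by two
#' measurements taken at simulation: lateral distance from the patient
#' midline and vertical height above the couch top. The point's radial
#' distance from the rotation axis (which runs longitudinally through the
#' isocenter) is compared against `bore_radius_mm - margin_mm`.
#'
#' @param arrangement A `beam_arrangement` (provides the isocenter).
#' @param clearance_points Data frame with columns `label`,
#'   `lateral_offset_mm`, `vertical_offset_mm` (both non-negative), or `NULL`.
#' @param bore_radius_mm Bore radius, mm; default 500.
#' @param margin_mm Required clearance margin, mm; default 10.
#' @param iso_lateral_mm,iso_vertical_mm Isocenter position in the same
#'   midline/couch-top frame as the measurements, mm; default 0 (isocenter on
#'   the midline at couch height), override when the isocenter is shifted.
#' @return Data frame with columns `label`, `radial_mm`, `limit_mm`, `pass`.
#' @examples
#' arr <- generate_arrangement(310, "LEFT")
#' pts <- data.frame(label = "contralateral elbow",
#'                   lateral_offset_mm = 300, vertical_offset_mm = 150)
#' check_bore_clearance(arr, pts)
#' @export
check_bore_clearance <- function(arrangement, clearance_points,
                                 bore_radius_mm = 500, margin_mm = 10,
                                 iso_lateral_mm = 0, iso_vertical_mm = 0) {
  stopifnot(bore_radius_mm > 0, margin_mm >= 0)
  empty <- data.frame(label = character(0), radial_mm = numeric(0),
                      limit_mm = numeric(0), pass = logical(0))
  if (is.null(clearance_points) || nrow(clearance_points) == 0) return(empty)
  req <- c("label", "lateral_offset_mm", "vertical_offset_mm")
  if (!all(req %in% names(clearance_points))) {
    stop("clearance_points needs columns: ", paste(req, collapse = ", "))
  }
  if (any(clearance_points$lateral_offset_mm < 0) ||
      any(clearance_points$vertical_offset_mm < 0)) {
    stop("clearance offsets must be >= 0")
  }
  radial <- sqrt((clearance_points$lateral_offset_mm - iso_lateral_mm)^2 +
                 (clearance_points$vertical_offset_mm - iso_vertical_mm)^2)
  limit <- bore_radius_mm - margin_mm
  data.frame(
    label = clearance_points$label,
    radial_mm = radial,
    limit_mm = limit,
    pass = radial <= limit,
    stringsAsFactors = FALSE
  )
}
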