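#' Margin policy for planning-volume construction
#'
#' Bundles the institutional margin rules applied when building planning
#' volumes from clinical target volumes: a 5 mm CTV-to-PTV expansion (0 mm
#' for the internal mammary chain, i.e. CTV = PTV there), skin pullback of
#' 5 mm for intact-breast cases and 2 mm for post-mastectomy cases, a 3 mm
#' planning-risk-volume (PRV) margin on the esophagus used to crop the
#' supraclavicular PTV, a 5 mm margin around the total PTV when carving the
#' conformity ring out of the body, and a 5 mm virtual bolus shell thickness.
#'
#' @param ptv_margin_mm CTV-to-PTV margin, mm.
#' @param imn_ptv_margin_mm Margin for the internal mammary node CTV, mm.
#' @param skin_pullback_breast_mm Skin pullback for intact breast, mm.
#' @param skin_pullback_pmrt_mm Skin pullback post-mastectomy, mm.
#' @param esophagus_prv_mm Esophagus PRV margin, mm.
#' @param ring_margin_mm PTV margin excluded from the conformity ring, mm.
#' @param bolus_thickness_mm Virtual bolus shell thickness, mm.
#' @return A `margin_policy` list.
#' @export
margin_policy <- function(ptv_margin_mm = 5, imn_ptv_margin_mm = 0,
                          skin_pullback_breast_mm = 5,
                          skin_pullback_pmrt_mm = 2,
                          esophagus_prv_mm = 3, ring_margin_mm = 5,
                          bolus_thickness_mm = 5) {
  p <- list(ptv_margin_mm = ptv_margin_mm,
            imn_ptv_margin_mm = imn_ptv_margin_mm,
            skin_pullback_breast_mm = skin_pullback_breast_mm,
            skin_pullback_pmrt_mm = skin_pullback_pmrt_mm,
            esophagus_prv_mm = esophagus_prv_mm,
            ring_margin_mm = ring_margin_mm,
            bolus_thickness_mm = bolus_thickness_mm)
  if (any(unlist(p) < 0)) stop("all margins must be >= 0")
  structure(p, class = "margin_policy")
}

# Integer voxel offsets whose center-to-center Euclidean distance is within
# radius_mm, respecting anisotropic spacing. Offsets are exact: the distance
# between voxel centers (i, j) is |(i - j) * spacing|.
ball_offsets <- function(spacing, radius_mm) {
  r <- radius_mm + 1e-9
  reach <- floor(r / spacing)
  dx <- seq(-reach[1], reach[1])
  dy <- seq(-reach[2], reach[2])
  dz <- seq(-reach[3], reach[3])
  g <- expand.grid(dx = dx, dy = dy, dz = dz)
  d2 <- (g$dx * spacing[1])^2 + (g$dy * spacing[2])^2 + (g$dz * spacing[3])^2
  as.matrix(g[d2 <= r^2, , drop = FALSE])
}

# Binary dilation of a logical 3D array by an explicit offset set
# (shift-and-OR); voxels shifted beyond the grid are dropped.
dilate_occupancy <- function(occ, offsets) {
  dm <- dim(occ)
  out <- array(FALSE, dm)
  for (k in seq_len(nrow(offsets))) {
    dx <- offsets[k, 1]; dy <- offsets[k, 2]; dz <- offsets[k, 3]
    xlo <- max(1, 1 - dx); xhi <- min(dm[1], dm[1] - dx)
    ylo <- max(1, 1 - dy); yhi <- min(dm[2], dm[2] - dy)
    zlo <- max(1, 1 - dz); zhi <- min(dm[3], dm[3] - dz)
    if (xlo > xhi || ylo > yhi || zlo > zhi) next
    sx <- xlo:xhi; sy <- ylo:yhi; sz <- zlo:zhi
    out[sx + dx, sy + dy, sz + dz] <-
      out[sx + dx, sy + dy, sz + dz] | occ[sx, sy, sz]
  }
  out
}

#' Expand a structure mask by a Euclidean margin
#'
#' An output voxel is occupied iff its center lies within `radius_mm`
#' (Euclidean distance, anisotropic spacing respected) of the center of some
#' occupied input voxel. This is the voxel-center-exact 3D dilation used for
#' all margin rules (CTV-to-PTV expansion, PRV margins, ring margins).
#'
#' @param mask A `structure_mask`.
#' @param radius_mm Margin radius, mm, `>= 0`. Radius 0 returns the mask
#'   unchanged.
#' @param name Optional name for the result; default appends the margin.
#' @return A `structure_mask` on the same geometry.
#' @export
expand_mask <- function(mask, radius_mm, name = NULL) {
  stopifnot(inherits(mask, "structure_mask"))
  if (radius_mm < 0) stop("`radius_mm` must be >= 0")
  if (is.null(name)) name <- sprintf("%s+%gmm", mask$name, radius_mm)
  if (radius_mm == 0 || !any(mask$occupancy)) {
    return(structure_mask(mask$occupancy, mask$geometry, name, mask$role))
  }
  offs <- ball_offsets(mask$geometry$spacing, radius_mm)
  structure_mask(dilate_occupancy(mask$occupancy, offs),
                 mask$geometry, name, mask$role)
}

#' Pull a PTV back from the body surface
#'
#' Removes from the PTV every voxel whose center lies within `depth_mm`
#' (Euclidean) of the body's exterior, implementing the skin pullback applied
#' to planning volumes (5 mm for intact breast, 2 mm post-mastectomy).
#' Voxels outside the grid are not treated as exterior, so a body touching
#' the grid boundary does not erode the PTV from that face.
#'
#' @param ptv,body `structure_mask`s on a shared geometry with
#'   `ptv` contained in `body`.
#' @param depth_mm Pullback depth, mm, `>= 0`.
#' @return A `structure_mask`, subset of `ptv`.
#' @export
pull_back_from_surface <- function(ptv, body, depth_mm) {
  stopifnot(inherits(ptv, "structure_mask"), inherits(body, "structure_mask"),
            depth_mm >= 0)
  stop_if_geometry_mismatch(ptv$geometry, body$geometry)
  if (any(ptv$occupancy & !body$occupancy)) {
    stop("`ptv` must be contained in `body`")
  }
  exterior <- structure_mask(!body$occupancy, body$geometry, "exterior", "OAR")
  near_surface <- expand_mask(exterior, depth_mm)
  structure_mask(ptv$occupancy & !near_surface$occupancy, ptv$geometry,
                 sprintf("%s-pullback%gmm", ptv$name, depth_mm), ptv$role)
}

#' Crop a PTV off an organ-at-risk PRV expansion
#'
#' Returns `ptv` minus the OAR expanded by the PRV margin, e.g. cropping the
#' supraclavicular PTV off the esophagus expanded by 3 mm.
#'
#' @param ptv,oar `structure_mask`s on a shared geometry.
#' @param prv_margin_mm PRV margin, mm, `>= 0`.
#' @return A `structure_mask`, subset of `ptv`.
#' @export
crop_with_prv <- function(ptv, oar, prv_margin_mm) {
  stopifnot(inherits(ptv, "structure_mask"), inherits(oar, "structure_mask"),
            prv_margin_mm >= 0)
  stop_if_geometry_mismatch(ptv$geometry, oar$geometry)
  prv <- expand_mask(oar, prv_margin_mm)
  structure_mask(ptv$occupancy & !prv$occupancy, ptv$geometry,
                 sprintf("%s-crop(%s+%gmm)", ptv$name, oar$name, prv_margin_mm),
                 ptv$role)
}

#' Conformity ring: body excluding the PTV plus margin
#'
#' Builds the normal-tissue ring used to score dose conformity: the body
#' minus the total PTV expanded by `margin_mm` (default policy: 5 mm). The
#' near-maximum dose in this ring measures dose spill outside the target.
#'
#' @param body,ptv_total `structure_mask`s on a shared geometry with
#'   `ptv_total` contained in `body`.
#' @param margin_mm Excluded margin around the PTV, mm.
#' @return A `structure_mask` with role `"RING"`.
#' @export
make_ring <- function(body, ptv_total, margin_mm = 5) {
  stopifnot(inherits(body, "structure_mask"),
            inherits(ptv_total, "structure_mask"), margin_mm >= 0)
  stop_if_geometry_mismatch(body$geometry, ptv_total$geometry)
  if (any(ptv_total$occupancy & !body$occupancy)) {
    stop("`ptv_total` must be contained in `body`")
  }
  expanded <- expand_mask(ptv_total, margin_mm)
  structure_mask(body$occupancy & !expanded$occupancy, body$geometry,
                 "ring", "RING")
}

#' Virtual bolus shell over a chest-wall PTV
#'
#' Builds the tissue-equivalent shell used for post-mastectomy cases: voxels
#' outside the body, within `thickness_mm` of the body surface, restricted to
#' the outward neighbourhood of the chest-wall PTV's surface patch. The shell
#' never intersects the body.
#'
#' @param body,chestwall_ptv `structure_mask`s on a shared geometry.
#' @param thickness_mm Shell thickness, mm, `> 0`; default 5 (a 0.5 cm bolus).
#' @param proximity_mm How far (along the surface) beyond the PTV's outward
#'   projection the shell may extend, mm; default 5.
#' @return A `structure_mask` with role `"BOLUS"`, disjoint from `body`.
#' @export
make_bolus_shell <- function(body, chestwall_ptv, thickness_mm = 5,
                             proximity_mm = 5) {
  stopifnot(inherits(body, "structure_mask"),
            inherits(chestwall_ptv, "structure_mask"), thickness_mm > 0)
  stop_if_geometry_mismatch(body$geometry, chestwall_ptv$geometry)
  if (!any(chestwall_ptv$occupancy)) {
    return(structure_mask(array(FALSE, body$geometry$shape), body$geometry,
                          "bolus", "BOLUS"))
  }
  outer <- expand_mask(body, thickness_mm)
  near_ptv <- expand_mask(chestwall_ptv, thickness_mm + proximity_mm)
  shell <- outer$occupancy & !body$occupancy & near_ptv$occupancy
  structure_mask(shell, body$geometry, "bolus", "BOLUS")
}
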