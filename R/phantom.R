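#' Parametric thorax phantom specification
#'
#' Describes a synthetic thorax used to exercise the full planning pipeline
#' without clinical data: a half-elliptical body on a flat couch, an
#' ipsilateral breast half-ellipsoid with a clinical target volume (CTV)
#' seated 5 mm under the skin, supraclavicular and axillary (three-level)
#' node spheres, an internal mammary node (IMN) chain along the sternum, a
#' heart sphere offset to the ipsilateral-for-left side, two lung ellipsoids,
#' an esophagus tube and a contralateral breast. Geometry is defined for a
#' left-sided target and mirrored in x for right-sided ones.
#'
#' Coordinates are LPS (x toward patient left, y posterior, z superior), mm,
#' with the grid centered on the rotation axis. The `seed` drives small
#' anatomical jitter (solid centers and semi-axes) emulating inter-patient
#' variation; `jitter_sd_mm = 0` gives the nominal anatomy.
#'
#' @param laterality `"LEFT"` or `"RIGHT"`.
#' @param shape Grid voxel counts; default `c(128, 128, 96)`.
#' @param spacing Voxel spacing, mm; default `c(2, 2, 2)`.
#' @param seed Integer seed for the anatomical jitter.
#' @param jitter_sd_mm Standard deviation of the anatomical jitter, mm.
#' @return A `phantom_spec` list of solid parameters.
#' @export
phantom_spec <- function(laterality = "LEFT", shape = c(128, 128, 96),
                         spacing = c(2, 2, 2), seed = 1L, jitter_sd_mm = 0) {
  side <- match.arg(toupper(laterality), c("LEFT", "RIGHT"))
  stopifnot(length(shape) == 3, length(spacing) == 3, all(spacing > 0),
            jitter_sd_mm >= 0)
  j <- local_jitter(seed, jitter_sd_mm)
  spec <- list(
    laterality = side, shape = as.integer(shape), spacing = as.numeric(spacing),
    seed = as.integer(seed), jitter_sd_mm = jitter_sd_mm,
    # body: half-ellipse cross-section, flat posterior at couch level
    body_semi_xy = c(110, 100), body_flat_y = 70,
    # breast solid and its CTV (5 mm inside the skin surface)
    breast_center = c(50 + j(1), -19 + j(2), -20 + j(3)),
    breast_semi = pmax(c(45, 40, 45) + j(4:6), 25),
    breast_ctv_shrink_mm = 5,
    # nodal targets
    sclav_center = c(25 + j(7), 10, 70), sclav_radius = max(18 + j(8), 10),
    axilla_centers = rbind(c(55, 15, 50), c(45, 8, 58), c(35, 5, 64)),
    axilla_radii = c(15, 13, 12),
    imn_x = 12, imn_y = -15 + j(9), imn_z = seq(-10, 40, by = 10),
    imn_radius = 6,
    # organs at risk
    heart_center = c(20, 20, -30), heart_radius = max(35 + j(10), 25),
    lung_center_x = 45, lung_center = c(25, 10), lung_semi = c(38, 48, 75),
    esophagus_xy = c(0, 35), esophagus_radius = 6,
    contra_breast_center = c(-50, -19, -20), contra_breast_semi = c(40, 32, 40),
    lung_density = 0.3
  )
  structure(spec, class = "phantom_spec")
}

# deterministic jitter stream that does not disturb the caller's RNG state
local_jitter <- function(seed, sd_mm) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  draws <- stats::rnorm(32, 0, sd_mm)
  function(i) draws[i]
}

phantom_geometry <- function(spec) {
  volume_geometry(spec$shape, spec$spacing,
                  origin = -(spec$shape - 1) * spec$spacing / 2)
}

# solid rasterizers: vectorized via outer sums of per-axis quadratic terms
ellipsoid_occ <- function(geometry, center, semi) {
  t1 <- ((axis_coords(geometry, 1) - center[1]) / semi[1])^2
  t2 <- ((axis_coords(geometry, 2) - center[2]) / semi[2])^2
  t3 <- ((axis_coords(geometry, 3) - center[3]) / semi[3])^2
  outer(outer(t1, t2, `+`), t3, `+`) <= 1
}

sphere_occ <- function(geometry, center, radius) {
  ellipsoid_occ(geometry, center, rep(radius, 3))
}

ztube_occ <- function(geometry, xy, radius, zlim = NULL) {
  t1 <- (axis_coords(geometry, 1) - xy[1])^2
  t2 <- (axis_coords(geometry, 2) - xy[2])^2
  disc <- outer(t1, t2, `+`) <= radius^2
  zs <- axis_coords(geometry, 3)
  inz <- if (is.null(zlim)) rep(TRUE, length(zs)) else zs >= zlim[1] & zs <= zlim[2]
  outer(disc, inz, `&`)
}

#' Build the phantom structure set and density grid
#'
#' Rasterizes the solids of a [phantom_spec()] into structure masks, derives
#' the planning volumes through the margin-morphology operations (5 mm
#' CTV-to-PTV expansion cropped to the body, skin pullback, esophagus PRV
#' crop for the supraclavicular PTV, 0 mm margin for the IMN chain), builds
#' the total-PTV conformity ring, and assembles a density grid (tissue 1.0,
#' lung 0.3, air 0). Right-sided phantoms are exact x-mirrors of the
#' left-sided geometry. Deterministic given the spec (and its seed).
#'
#' @param spec A `phantom_spec`.
#' @param policy A [margin_policy()]; defaults to the standard margins.
#' @return List with `structures` (named list of `structure_mask`s including
#'   `Body`, `BreastCTV`, `BreastPTV`, `SclavCTV`, `SclavPTV`, `AxillaCTV`,
#'   `AxillaPTV`, `IMNCTV`, `IMNPTV`, `PTVTotal`, `Ring`, `Heart`, `IpsiLung`,
#'   `ContraLung`, `Esophagus`, `ContraBreast`), `density` (3D array),
#'   `geometry` and `spec`.
#' @export
build_phantom <- function(spec, policy = margin_policy()) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- phantom_geometry(spec)
  xs <- axis_coords(g, 1); ys <- axis_coords(g, 2)

  # trunk: half-ellipse cross-section, flat at the couch (posterior) side
  t1 <- (xs / spec$body_semi_xy[1])^2
  t2 <- ((ys - spec$body_flat_y) / spec$body_semi_xy[2])^2
  disc <- outer(t1, t2, `+`) <= 1 & outer(rep(TRUE, length(xs)), ys <= spec$body_flat_y, `&`)
  trunk <- outer(disc, rep(TRUE, g$shape[3]), `&`)

  breast <- ellipsoid_occ(g, spec$breast_center, spec$breast_semi)
  body_occ <- trunk | breast

  ctv_breast <- ellipsoid_occ(g, spec$breast_center,
                              pmax(spec$breast_semi - spec$breast_ctv_shrink_mm, 1))
  sclav <- sphere_occ(g, spec$sclav_center, spec$sclav_radius)
  axilla <- Reduce(`|`, lapply(seq_len(nrow(spec$axilla_centers)), function(i) {
    sphere_occ(g, spec$axilla_centers[i, ], spec$axilla_radii[i])
  }))
  imn <- Reduce(`|`, lapply(spec$imn_z, function(z) {
    sphere_occ(g, c(spec$imn_x, spec$imn_y, z), spec$imn_radius)
  }))
  heart <- sphere_occ(g, spec$heart_center, spec$heart_radius)
  lung_ipsi <- ellipsoid_occ(g, c(spec$lung_center_x, spec$lung_center, 10),
                             spec$lung_semi) & !heart
  lung_contra <- ellipsoid_occ(g, c(-spec$lung_center_x, spec$lung_center, 10),
                               spec$lung_semi) & !heart
  esoph <- ztube_occ(g, spec$esophagus_xy, spec$esophagus_radius)
  contra_breast <- ellipsoid_occ(g, spec$contra_breast_center,
                                 spec$contra_breast_semi)
  body_occ <- body_occ | contra_breast

  occs <- list(Body = body_occ, BreastCTV = ctv_breast, SclavCTV = sclav,
               AxillaCTV = axilla, IMNCTV = imn, Heart = heart,
               IpsiLung = lung_ipsi, ContraLung = lung_contra,
               Esophagus = esoph, ContraBreast = contra_breast)
  # clip everything to the body; targets must live inside it
  for (nm in setdiff(names(occs), "Body")) occs[[nm]] <- occs[[nm]] & body_occ

  if (spec$laterality == "RIGHT") {
    occs <- lapply(occs, function(o) o[rev(seq_len(g$shape[1])), , , drop = FALSE])
  }

  role_of <- c(Body = "BODY", BreastCTV = "TARGET_CTV", SclavCTV = "TARGET_CTV",
               AxillaCTV = "TARGET_CTV", IMNCTV = "TARGET_CTV",
               Heart = "OAR", IpsiLung = "OAR", ContraLung = "OAR",
               Esophagus = "OAR", ContraBreast = "OAR")
  structures <- lapply(names(occs), function(nm) {
    structure_mask(occs[[nm]], g, nm, role_of[[nm]])
  })
  names(structures) <- names(occs)

  # planning volumes via the margin-morphology rules
  body <- structures$Body
  clip_to_body <- function(m) {
    structure_mask(m$occupancy & body$occupancy, g, m$name, "TARGET_PTV")
  }
  raw_ptv <- function(ctv, margin) clip_to_body(expand_mask(ctv, margin))
  breast_ptv <- pull_back_from_surface(
    raw_ptv(structures$BreastCTV, policy$ptv_margin_mm), body,
    policy$skin_pullback_breast_mm)
  sclav_ptv <- crop_with_prv(
    pull_back_from_surface(raw_ptv(structures$SclavCTV, policy$ptv_margin_mm),
                           body, policy$skin_pullback_breast_mm),
    structures$Esophagus, policy$esophagus_prv_mm)
  axilla_ptv <- pull_back_from_surface(
    raw_ptv(structures$AxillaCTV, policy$ptv_margin_mm), body,
    policy$skin_pullback_breast_mm)
  imn_ptv <- raw_ptv(structures$IMNCTV, policy$imn_ptv_margin_mm)

  ptv_total_occ <- breast_ptv$occupancy | sclav_ptv$occupancy |
    axilla_ptv$occupancy | imn_ptv$occupancy
  ptv_total <- structure_mask(ptv_total_occ, g, "PTVTotal", "TARGET_PTV")
  ring <- make_ring(body, ptv_total, policy$ring_margin_mm)

  structures$BreastPTV <- structure_mask(breast_ptv$occupancy, g, "BreastPTV", "TARGET_PTV")
  structures$SclavPTV <- structure_mask(sclav_ptv$occupancy, g, "SclavPTV", "TARGET_PTV")
  structures$AxillaPTV <- structure_mask(axilla_ptv$occupancy, g, "AxillaPTV", "TARGET_PTV")
  structures$IMNPTV <- structure_mask(imn_ptv$occupancy, g, "IMNPTV", "TARGET_PTV")
  structures$PTVTotal <- ptv_total
  structures$Ring <- ring

  density <- array(0, g$shape)
  density[structures$Body$occupancy] <- 1
  density[structures$IpsiLung$occupancy | structures$ContraLung$occupancy] <-
    spec$lung_density

  list(structures = structures, density = density, geometry = g, spec = spec)
}

#' Dose-engine parameters for the phantom simulator
#'
#' The simulator is a deliberately simple geometric engine (parallel rays,
#' exponential attenuation of radiological depth, Gaussian lateral penumbra),
#' not a clinical dose algorithm: it preserves the geometric plan properties
#' the downstream modules exercise (coverage, conformity, laterality) at
#' trivial computational cost.
#'
#' @param mu_per_mm Linear attenuation coefficient, 1/mm (water-equivalent).
#' @param penumbra_sigma_mm Gaussian penumbra sigma, mm.
#' @param aperture_margin_mm Aperture margin around the beam's-eye-view
#'   target projection, mm; stands in for the skin-flash fluence extension.
#' @param prescription_gy Breast/chest-wall prescription, Gy.
#' @param fractions Number of fractions.
#' @param nodal_prescription_gy Regional-node prescription, Gy.
#' @param ray_step_mm Marching step for radiological depth, mm (`NULL`:
#'   the smallest voxel spacing).
#' @return A `beam_dose_params` list.
#' @export
beam_dose_params <- function(mu_per_mm = 0.005, penumbra_sigma_mm = 4,
                             aperture_margin_mm = 7, prescription_gy = 50,
                             fractions = 25, nodal_prescription_gy = 45,
                             ray_step_mm = NULL) {
  stopifnot(mu_per_mm > 0, penumbra_sigma_mm > 0, aperture_margin_mm >= 0,
            prescription_gy > 0, fractions > 0, nodal_prescription_gy > 0)
  structure(list(mu_per_mm = mu_per_mm, penumbra_sigma_mm = penumbra_sigma_mm,
                 aperture_margin_mm = aperture_margin_mm,
                 prescription_gy = prescription_gy, fractions = fractions,
                 nodal_prescription_gy = nodal_prescription_gy,
                 ray_step_mm = ray_step_mm),
            class = "beam_dose_params")
}

# 2D fluence map in beam's-eye-view coordinates (u = in-plane transverse,
# v = longitudinal): dilated target projection with Gaussian penumbra.
bev_fluence <- function(u_t, v_t, u_axis, v_axis, margin_mm, sigma_mm, bin_mm) {
  iu <- pmin(pmax(round((u_t - u_axis[1]) / bin_mm) + 1, 1), length(u_axis))
  iv <- pmin(pmax(round((v_t - v_axis[1]) / bin_mm) + 1, 1), length(v_axis))
  ap <- matrix(FALSE, length(u_axis), length(v_axis))
  ap[cbind(iu, iv)] <- TRUE
  # dilate by the aperture margin
  r <- floor(margin_mm / bin_mm + 1e-9)
  if (r > 0) {
    offs <- expand.grid(du = -r:r, dv = -r:r)
    offs <- offs[(offs$du^2 + offs$dv^2) * bin_mm^2 <= margin_mm^2 + 1e-9, ]
    dil <- matrix(FALSE, nrow(ap), ncol(ap))
    for (k in seq_len(nrow(offs))) {
      du <- offs$du[k]; dv <- offs$dv[k]
      ulo <- max(1, 1 - du); uhi <- min(nrow(ap), nrow(ap) - du)
      vlo <- max(1, 1 - dv); vhi <- min(ncol(ap), ncol(ap) - dv)
      if (ulo > uhi || vlo > vhi) next
      su <- ulo:uhi; sv <- vlo:vhi
      dil[su + du, sv + dv] <- dil[su + du, sv + dv] | ap[su, sv]
    }
    ap <- dil
  }
  # separable Gaussian blur -> penumbra
  half <- max(1, ceiling(3 * sigma_mm / bin_mm))
  kern <- stats::dnorm(seq(-half, half) * bin_mm, sd = sigma_mm)
  kern <- kern / sum(kern)
  f <- apply(ap * 1, 2, function(col) as.numeric(stats::filter(col, kern, sides = 2)))
  f[is.na(f)] <- 0
  f <- t(apply(f, 1, function(row) as.numeric(stats::filter(row, kern, sides = 2))))
  f[is.na(f)] <- 0
  f
}

#' Simulate a dose distribution for a beam arrangement on the phantom
#'
#' Each field deposits dose along parallel rays in its gantry direction:
#' exponential attenuation of the density-scaled radiological depth, confined
#' to the beam's-eye-view projection of its aperture target expanded by the
#' aperture margin, with a Gaussian lateral penumbra. Field doses are summed
#' with the given weights and the total is normalized so that the median dose
#' in `normalize_to` (by default the breast/chest-wall PTV) equals the
#' prescription.
#'
#' @param arrangement A `beam_arrangement`.
#' @param phantom Output of [build_phantom()].
#' @param params A [beam_dose_params()].
#' @param weights Non-negative per-field weights (length = field count,
#'   not all zero); default uniform.
#' @param aperture_targets Optional list (length = field count) of
#'   `structure_mask`s shaping each field's aperture; default: the total PTV
#'   for every field.
#' @param normalize_to Mask whose median dose is set to the prescription;
#'   default `phantom$structures$BreastPTV`.
#' @param modulate If `TRUE` (default), per-ray fluence is compensated for
#'   the radiological depth of the field's target along that ray, so each
#'   field delivers a uniform dose at its target — the simulator's stand-in
#'   for inverse-optimized fluence modulation. `FALSE` gives flat (open
#'   field) fluence.
#' @return A `dose_grid`.
#' @export
simulate_dose <- function(arrangement, phantom, params = beam_dose_params(),
                          weights = NULL, aperture_targets = NULL,
                          normalize_to = NULL, modulate = TRUE) {
  stopifnot(inherits(arrangement, "beam_arrangement"),
            inherits(params, "beam_dose_params"))
  g <- phantom$geometry
  nf <- nrow(arrangement$fields)
  if (is.null(weights)) weights <- rep(1, nf)
  stopifnot(length(weights) == nf, all(weights >= 0))
  if (all(weights == 0)) stop("all field weights are zero")
  if (is.null(aperture_targets)) {
    aperture_targets <- rep(list(phantom$structures$PTVTotal), nf)
  }
  stopifnot(length(aperture_targets) == nf)
  if (is.null(normalize_to)) normalize_to <- phantom$structures$BreastPTV

  xs <- axis_coords(g, 1); ys <- axis_coords(g, 2); zs <- axis_coords(g, 3)
  body <- phantom$structures$Body$occupancy
  body_lin <- which(body)
  sub <- arrayInd(body_lin, g$shape)
  px <- xs[sub[, 1]]; py <- ys[sub[, 2]]; pz <- zs[sub[, 3]]

  step <- if (is.null(params$ray_step_mm)) min(g$spacing) else params$ray_step_mm
  bin <- min(g$spacing[1:2])
  n_steps <- ceiling(sqrt(sum((g$shape * g$spacing)^2)) / step)
  dens <- phantom$density

  total <- numeric(length(body_lin))
  for (i in seq_len(nf)) {
    if (weights[i] == 0) next
    th <- arrangement$fields$gantry_deg[i] * pi / 180
    sdir <- c(sin(th), -cos(th), 0)       # toward the source
    e1 <- c(cos(th), sin(th), 0)          # BEV transverse axis

    tgt <- aperture_targets[[i]]$occupancy
    tl <- which(tgt)
    if (length(tl) == 0) next
    ts <- arrayInd(tl, g$shape)
    tu <- xs[ts[, 1]] * e1[1] + ys[ts[, 2]] * e1[2]
    tv <- zs[ts[, 3]]
    pad <- params$aperture_margin_mm + 3 * params$penumbra_sigma_mm + 2 * bin
    u_axis <- seq(min(tu) - pad, max(tu) + pad, by = bin)
    v_axis <- seq(min(tv) - pad, max(tv) + pad, by = bin)
    flu <- bev_fluence(tu, tv, u_axis, v_axis, params$aperture_margin_mm,
                       params$penumbra_sigma_mm, bin)

    pu <- px * e1[1] + py * e1[2]
    iu <- round((pu - u_axis[1]) / bin) + 1
    iv <- round((pz - v_axis[1]) / bin) + 1
    inside <- iu >= 1 & iu <= length(u_axis) & iv >= 1 & iv <= length(v_axis)
    fl <- numeric(length(body_lin))
    fl[inside] <- flu[cbind(iu[inside], iv[inside])]
    active <- which(fl > 1e-3)
    if (length(active) == 0) next

    # radiological depth by ray marching toward the source
    depth <- numeric(length(active))
    ax <- px[active]; ay <- py[active]; az <- pz[active]
    iz <- round((az - g$origin[3]) / g$spacing[3]) + 1
    for (k in seq_len(n_steps)) {
      qx <- ax + k * step * sdir[1]
      qy <- ay + k * step * sdir[2]
      ix <- round((qx - g$origin[1]) / g$spacing[1]) + 1
      iy <- round((qy - g$origin[2]) / g$spacing[2]) + 1
      ok <- ix >= 1 & ix <= g$shape[1] & iy >= 1 & iy <= g$shape[2]
      if (!any(ok)) break
      lin <- ix[ok] + (iy[ok] - 1) * g$shape[1] +
        (iz[ok] - 1) * g$shape[1] * g$shape[2]
      depth[ok] <- depth[ok] + dens[lin] * step
    }

    # compensator-style modulation: reference each ray's exponential to the
    # mean radiological depth of the field's target in that BEV bin, so the
    # field delivers a uniform dose across its target
    comp <- 0
    if (modulate) {
      bin_a <- iu[active] + (iv[active] - 1) * length(u_axis)
      in_tgt <- tgt[body_lin[active]]
      if (any(in_tgt)) {
        td <- tapply(depth[in_tgt], bin_a[in_tgt], mean)
        comp <- td[as.character(bin_a)]
        comp[is.na(comp)] <- mean(depth[in_tgt])
        comp <- as.numeric(comp)
      }
    }
    total[active] <- total[active] +
      weights[i] * fl[active] * exp(-params$mu_per_mm * (depth - comp))
  }

  norm_sel <- normalize_to$occupancy[body_lin]
  med <- stats::median(total[norm_sel])
  if (!is.finite(med) || med <= 0) stop("normalization volume received no dose")
  dose <- array(0, g$shape)
  dose[body_lin] <- total * (params$prescription_gy / med)
  dose_grid(dose, g)
}

#' Default medial tangent angle for a phantom laterality
#' @param laterality `"LEFT"` or `"RIGHT"`.
#' @return Gantry angle, degrees.
#' @export
default_medial_tangent <- function(laterality) {
  if (match.arg(toupper(laterality), c("LEFT", "RIGHT")) == "LEFT") 310 else 50
}

#' Simplified two-tangent-plus-nodal comparison arrangement
#'
#' Builds the comparator technique's beam set on the phantom: a medial/lateral
#' tangent pair on the breast (184 degrees apart, just clear of direct
#' opposition), an anterior nodal field and a posterior axillary boost.
#'
#' @param medial_tangent Medial tangent angle, degrees.
#' @param laterality `"LEFT"` or `"RIGHT"`.
#' @param isocenter Isocenter, mm.
#' @return A `beam_arrangement` with 4 fields.
#' @export
tangent_nodal_arrangement <- function(medial_tangent, laterality,
                                      isocenter = c(0, 0, 0)) {
  side <- match.arg(toupper(laterality), c("LEFT", "RIGHT"))
  sgn <- lateral_sign(side)
  gantry <- normalize_angle(medial_tangent + sgn * c(0, 184, 8, 240))
  fields <- data.frame(
    id = c("T1_MED", "T2_LAT", "N1_ANT", "N2_PAB"),
    role = c("MEDIAL_TANGENT", "LATERAL_ARC", "MEDIAL_ARC", "PAB"),
    offset_deg = c(0, 184, 8, 240),
    gantry_deg = gantry,
    stringsAsFactors = FALSE
  )
  structure(list(laterality = side,
                 medial_tangent = normalize_angle(medial_tangent),
                 n_medial_extra = 0L, pab_offset_adjust = 0L,
                 isocenter = as.numeric(isocenter), fields = fields),
            class = "beam_arrangement")
}

#' Metric panel used for cohort comparisons
#' @return Data frame of `structure`, `metric` specs (CTV-oriented panel).
#' @export
comparison_metric_panel <- function() {
  data.frame(
    structure = c("BreastCTV", "BreastCTV", "SclavCTV", "AxillaCTV", "IMNCTV",
                  "Heart", "Heart", "IpsiLung", "IpsiLung", "ContraLung",
                  "Esophagus", "ContraBreast"),
    metric = c("V47.5Gy[%]", "V50Gy[%]", "V45Gy[%]", "V45Gy[%]", "V45Gy[%]",
               "Mean[Gy]", "D0.03cc[Gy]", "V20Gy[%]", "V5Gy[%]", "V5Gy[%]",
               "D0.03cc[Gy]", "V5Gy[%]"),
    stringsAsFactors = FALSE
  )
}

#' Generate a paired cohort of comparator and multi-field IMRT phantom plans
#'
#' For each pair, an anatomically jittered phantom is built and planned both
#' ways: with the simplified tangent-plus-nodal comparator arrangement (the
#' tangent pair shaped to the breast PTV, the nodal fields to the nodal PTVs)
#' and with the full multi-field IMRT arrangement (all fields shaped to the
#' total PTV). The comparison metric panel is evaluated on both doses and
#' returned as per-metric paired samples (group A = comparator, group B =
#' multi-field IMRT), ready for [compare_cohorts()].
#'
#' @param n_pairs Number of phantom pairs (`>= 1`).
#' @param seed Integer seed; drives the anatomical jitter.
#' @param laterality Phantom laterality.
#' @param shape,spacing Phantom grid (smaller grids are markedly faster).
#' @param params A [beam_dose_params()].
#' @param jitter_sd_mm Anatomical jitter SD, mm.
#' @return List with `samples` (list of `metric_samples`), `metrics_a`,
#'   `metrics_b` (per-plan metric tables, one list element per pair).
#' @export
make_cohort <- function(n_pairs = 5, seed = 1L, laterality = "LEFT",
                        shape = c(64, 64, 48), spacing = c(4, 4, 4),
                        params = beam_dose_params(), jitter_sd_mm = 3) {
  stopifnot(n_pairs >= 1)
  panel <- comparison_metric_panel()
  tabs_a <- vector("list", n_pairs)
  tabs_b <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    spec <- phantom_spec(laterality, shape, spacing,
                         seed = seed + i - 1L, jitter_sd_mm = jitter_sd_mm)
    ph <- build_phantom(spec)
    mt <- default_medial_tangent(laterality)
    imrt <- generate_arrangement(mt, laterality)
    dose_imrt <- simulate_dose(imrt, ph, params)

    comp <- tangent_nodal_arrangement(mt, laterality)
    nodal_occ <- ph$structures$SclavPTV$occupancy |
      ph$structures$AxillaPTV$occupancy | ph$structures$IMNPTV$occupancy
    nodal <- structure_mask(nodal_occ, ph$geometry, "NodalPTV", "TARGET_PTV")
    ap <- list(ph$structures$BreastPTV, ph$structures$BreastPTV, nodal, nodal)
    dose_comp <- simulate_dose(comp, ph, params, aperture_targets = ap)

    tabs_a[[i]] <- metrics_table(dose_comp, ph$structures, panel)
    tabs_b[[i]] <- metrics_table(dose_imrt, ph$structures, panel)
  }
  samples <- lapply(seq_len(nrow(panel)), function(r) {
    metric_samples(panel$metric[r], panel$structure[r],
                   vapply(tabs_a, function(t) t$value[r], 1),
                   vapply(tabs_b, function(t) t$value[r], 1),
                   labels = c("comparator", "imrt"))
  })
  list(samples = samples, metrics_a = tabs_a, metrics_b = tabs_b)
}
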