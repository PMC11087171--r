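#' Gamma-analysis parameters
#'
#' Defaults follow the common patient-specific QA criteria: 3 percent global
#' dose difference, 2 mm distance-to-agreement (DTA), with points below 10
#' percent of the normalization dose excluded from analysis. Global
#' normalization uses the maximum of the reference distribution unless a
#' prescribed normalization dose is supplied.
#'
#' @param dose_tol_pct Dose-difference tolerance, percent of the
#'   normalization dose.
#' @param dta_mm Distance-to-agreement tolerance, mm.
#' @param low_dose_threshold_pct Reference points below this percentage of
#'   the normalization dose are not evaluated.
#' @param normalization `"GLOBAL_MAX_REFERENCE"` or `"PRESCRIBED"`.
#' @param prescribed_gy Normalization dose when `normalization` is
#'   `"PRESCRIBED"`, Gy.
#' @param search_radius_mm Spatial search radius; default `3 * dta_mm`.
#' @param interp_step_mm Evaluated-dose interpolation step; default
#'   `dta_mm / 10`, must be at most `dta_mm / 2`.
#' @return A `gamma_params` list.
#' @export
gamma_params <- function(dose_tol_pct = 3, dta_mm = 2,
                         low_dose_threshold_pct = 10,
                         normalization = c("GLOBAL_MAX_REFERENCE", "PRESCRIBED"),
                         prescribed_gy = NULL,
                         search_radius_mm = 3 * dta_mm,
                         interp_step_mm = dta_mm / 10) {
  normalization <- match.arg(normalization)
  stopifnot(dose_tol_pct > 0, dta_mm > 0, low_dose_threshold_pct > 0,
            search_radius_mm > 0, interp_step_mm > 0)
  if (interp_step_mm > dta_mm / 2 + 1e-12) {
    stop("`interp_step_mm` must be <= dta_mm / 2")
  }
  if (normalization == "PRESCRIBED" &&
      (is.null(prescribed_gy) || prescribed_gy <= 0)) {
    stop("PRESCRIBED normalization requires a positive `prescribed_gy`")
  }
  structure(list(dose_tol_pct = dose_tol_pct, dta_mm = dta_mm,
                 low_dose_threshold_pct = low_dose_threshold_pct,
                 normalization = normalization, prescribed_gy = prescribed_gy,
                 search_radius_mm = search_radius_mm,
                 interp_step_mm = interp_step_mm),
            class = "gamma_params")
}

# Upsample an array (2D or 3D) onto a grid with step `step_mm` by separable
# linear interpolation. Returns list(values, coords): coords are per-axis
# physical positions (mm) sharing the coarse grid's origin and extent.
interp_fine_grid <- function(arr, spacing_mm, step_mm) {
  dm <- dim(arr)
  nd <- length(dm)
  coords <- lapply(seq_len(nd), function(ax) {
    extent <- (dm[ax] - 1) * spacing_mm[ax]
    if (extent == 0) return(0)
    seq(0, extent, by = step_mm)
  })
  out <- arr
  for (ax in seq_len(nd)) {
    if (dm[ax] == 1) next
    src_pos <- (seq_len(dim(out)[ax]) - 1) * spacing_mm[ax]
    tgt <- coords[[ax]]
    lo <- findInterval(tgt, src_pos, rightmost.closed = TRUE)
    lo <- pmin(pmax(lo, 1), length(src_pos) - 1)
    w <- (tgt - src_pos[lo]) / (src_pos[lo + 1] - src_pos[lo])
    # linear blend of slabs lo and lo+1 along axis ax
    take <- function(a, idx, axis) {
      args <- rep(list(quote(expr = )), length(dim(a)))
      args[[axis]] <- idx
      do.call(`[`, c(list(a), args, list(drop = FALSE)))
    }
    a_lo <- take(out, lo, ax)
    a_hi <- take(out, lo + 1, ax)
    wshape <- rep(1, length(dim(out)))
    wshape[ax] <- length(tgt)
    warr <- array(rep(w, each = prod(dim(a_lo)[seq_len(ax - 1)])),
                  dim = replace(dim(a_lo), ax, length(tgt)))
    out <- a_lo * (1 - warr) + a_hi * warr
  }
  list(values = out, coords = coords)
}

#' Gamma-index comparison of two dose distributions
#'
#' For each reference point above the low-dose threshold, the gamma index is
#' the minimum over evaluated positions `e` within the search radius of
#' `sqrt((dD/dose_tol)^2 + (|r - e|/dta)^2)`, where `dD` is the dose
#' difference between the reference point and the evaluated dose linearly
#' interpolated at `e`. A point passes when gamma is at most 1. Both 2D
#' planes (the usual QA geometry) and 3D grids are supported; the two
#' distributions must share a geometry.
#'
#' @param reference,evaluated `dose_grid`s on the same geometry, or plain
#'   numeric arrays (2D or 3D) with `spacing_mm` supplied.
#' @param params A [gamma_params()].
#' @param spacing_mm Voxel spacing, mm (required for plain arrays; taken
#'   from the geometry for `dose_grid`s).
#' @return A `gamma_result`: `gamma_map` (array, `NA` below threshold),
#'   `evaluated_mask`, `pass_rate_pct`, `n_evaluated`, `params`.
#' @examples
#' ref <- matrix(100, 8, 8)
#' res <- gamma_index(ref, ref * 1.03, gamma_params(), spacing_mm = c(2, 2))
#' res$pass_rate_pct  # 100: a uniform +3% offset sits exactly at gamma 1
#' @export
gamma_index <- function(reference, evaluated, params = gamma_params(),
                        spacing_mm = NULL) {
  if (inherits(reference, "dose_grid")) {
    spacing_mm <- reference$geometry$spacing
    reference <- reference$dose
  }
  if (inherits(evaluated, "dose_grid")) evaluated <- evaluated$dose
  if (is.null(dim(reference))) reference <- as.matrix(reference)
  if (is.null(dim(evaluated))) evaluated <- as.matrix(evaluated)
  if (!identical(dim(reference), dim(evaluated))) {
    stop("reference and evaluated must share a grid")
  }
  nd <- length(dim(reference))
  if (is.null(spacing_mm)) stop("`spacing_mm` required for plain arrays")
  spacing_mm <- rep_len(as.numeric(spacing_mm), nd)

  norm_dose <- switch(params$normalization,
                      GLOBAL_MAX_REFERENCE = max(reference),
                      PRESCRIBED = params$prescribed_gy)
  if (norm_dose <= 0) stop("reference maximum (normalization dose) must be > 0")
  dose_tol <- params$dose_tol_pct / 100 * norm_dose
  thresh <- params$low_dose_threshold_pct / 100 * norm_dose

  eval_mask <- reference >= thresh
  if (!any(eval_mask)) stop("no reference points above the low-dose threshold")

  step <- params$interp_step_mm
  fine <- interp_fine_grid(evaluated, spacing_mm, step)
  fdim <- vapply(fine$coords, length, 1L)
  fvals <- fine$values

  # reference voxel centers on the fine lattice (may fall between fine
  # nodes; snap to the nearest node, an error bounded by step/2)
  ref_idx_axes <- lapply(seq_len(nd), function(ax) {
    pos <- (seq_len(dim(reference)[ax]) - 1) * spacing_mm[ax]
    pmin(pmax(round(pos / step) + 1, 1), fdim[ax])
  })

  # fine-lattice offsets within the search radius
  reach <- floor(params$search_radius_mm / step)
  offs <- do.call(expand.grid, lapply(seq_len(nd), function(ax) {
    if (fdim[ax] == 1) 0 else seq(-reach, reach)
  }))
  off_dist2 <- rowSums((as.matrix(offs) * step)^2)
  keep <- off_dist2 <= params$search_radius_mm^2 + 1e-9
  offs <- as.matrix(offs)[keep, , drop = FALSE]
  off_dist2 <- off_dist2[keep]
  # visit near offsets first so the running minimum tightens quickly
  o <- order(off_dist2)
  offs <- offs[o, , drop = FALSE]
  off_dist2 <- off_dist2[o]

  ref_lin <- which(eval_mask)
  ref_sub <- arrayInd(ref_lin, dim(reference))
  ref_fine <- matrix(0L, nrow(ref_sub), nd)
  for (ax in seq_len(nd)) ref_fine[, ax] <- ref_idx_axes[[ax]][ref_sub[, ax]]
  ref_dose <- reference[ref_lin]

  fmul <- cumprod(c(1, fdim[-nd]))
  best <- rep(Inf, length(ref_lin))
  dta2 <- params$dta_mm^2
  for (k in seq_len(nrow(offs))) {
    geom_term <- off_dist2[k] / dta2
    # offsets are sorted by distance: once the geometric term alone exceeds
    # every running minimum, no later offset can improve any point
    if (k > 1 && geom_term >= max(best)) break
    idx <- ref_fine[, 1] + offs[k, 1]
    ok <- idx >= 1 & idx <= fdim[1]
    lin <- idx
    for (ax in seq_len(nd)[-1]) {
      idx <- ref_fine[, ax] + offs[k, ax]
      ok <- ok & idx >= 1 & idx <= fdim[ax]
      lin <- lin + (idx - 1) * fmul[ax]
    }
    if (!any(ok)) next
    g2 <- rep(Inf, length(ref_lin))
    dd <- fvals[lin[ok]] - ref_dose[ok]
    g2[ok] <- (dd / dose_tol)^2 + geom_term
    best <- pmin(best, g2)
  }

  gamma_map <- array(NA_real_, dim(reference))
  gamma_map[ref_lin] <- sqrt(best)
  pass_rate <- 100 * mean(best <= 1 + 1e-9)
  structure(list(gamma_map = gamma_map, evaluated_mask = eval_mask,
                 pass_rate_pct = pass_rate, n_evaluated = length(ref_lin),
                 params = params),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %d points evaluated, pass rate %.1f%% (%g%%/%g mm, %g%% threshold)\n",
              x$n_evaluated, x$pass_rate_pct, x$params$dose_tol_pct,
              x$params$dta_mm, x$params$low_dose_threshold_pct))
  invisible(x)
}

#' Compare a gamma pass rate against an institutional minimum
#'
#' @param result A `gamma_result`.
#' @param min_pass_pct Minimum acceptable pass rate, percent (0-100);
#'   the boundary is inclusive.
#' @return `TRUE` iff `pass_rate_pct >= min_pass_pct`.
#' @export
pass_against_threshold <- function(result, min_pass_pct = 95) {
  stopifnot(inherits(result, "gamma_result"),
            min_pass_pct >= 0, min_pass_pct <= 100)
  result$pass_rate_pct >= min_pass_pct
}
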