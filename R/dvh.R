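#' Parse a plan-quality metric string
#'
#' Canonical metric strings follow clinical DVH shorthand:
#' * `"V50Gy[%]"` — percent of the structure receiving at least 50 Gy;
#' * `"V20Gy[cc]"` — absolute volume (cc) receiving at least 20 Gy;
#' * `"D0.03cc[Gy]"` — minimum dose to the hottest 0.03 cc (near-maximum);
#' * `"D2%[Gy]"` — minimum dose to the hottest 2 percent of the volume;
#' * `"Mean[Gy]"`, `"Max[Gy]"` — volume-weighted mean and maximum dose.
#'
#' @param text Metric string.
#' @return A `metric_spec` list with `kind`
#'   (`V_DOSE_PCT`, `V_DOSE_CC`, `D_CC`, `D_PCT`, `MEAN`, `MAX`),
#'   `threshold` and the canonical `text`.
#' @examples
#' parse_metric("V50Gy[%]")
#' parse_metric("D0.03cc[Gy]")
#' @export
parse_metric <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  s <- gsub("\\s+", "", text)
  num <- "([0-9]*\\.?[0-9]+)"
  spec <- if (grepl(sprintf("^V%sGy\\[%%\\]$", num), s)) {
    list(kind = "V_DOSE_PCT",
         threshold = as.numeric(sub(sprintf("^V%sGy\\[%%\\]$", num), "\\1", s)))
  } else if (grepl(sprintf("^V%sGy\\[cc\\]$", num), s)) {
    list(kind = "V_DOSE_CC",
         threshold = as.numeric(sub(sprintf("^V%sGy\\[cc\\]$", num), "\\1", s)))
  } else if (grepl(sprintf("^D%scc\\[Gy\\]$", num), s)) {
    list(kind = "D_CC",
         threshold = as.numeric(sub(sprintf("^D%scc\\[Gy\\]$", num), "\\1", s)))
  } else if (grepl(sprintf("^D%s%%\\[Gy\\]$", num), s)) {
    list(kind = "D_PCT",
         threshold = as.numeric(sub(sprintf("^D%s%%\\[Gy\\]$", num), "\\1", s)))
  } else if (identical(s, "Mean[Gy]")) {
    list(kind = "MEAN", threshold = 0)
  } else if (identical(s, "Max[Gy]")) {
    list(kind = "MAX", threshold = 0)
  } else {
    stop("cannot parse metric string: ", text)
  }
  if (spec$threshold < 0) stop("metric threshold must be >= 0")
  structure(c(spec, list(text = format_metric(spec$kind, spec$threshold))),
            class = "metric_spec")
}

#' Canonical string form of a metric
#' @param kind Metric kind (see [parse_metric()]).
#' @param threshold Threshold (Gy, cc or percent depending on kind).
#' @return Canonical metric string.
#' @export
format_metric <- function(kind, threshold = 0) {
  switch(kind,
         V_DOSE_PCT = sprintf("V%gGy[%%]", threshold),
         V_DOSE_CC  = sprintf("V%gGy[cc]", threshold),
         D_CC       = sprintf("D%gcc[Gy]", threshold),
         D_PCT      = sprintf("D%g%%[Gy]", threshold),
         MEAN       = "Mean[Gy]",
         MAX        = "Max[Gy]",
         stop("unknown metric kind: ", kind))
}

as_metric_spec <- function(x) {
  if (inherits(x, "metric_spec")) x else parse_metric(x)
}

#' Cumulative dose-volume histogram of a structure
#'
#' @param dose A `dose_grid`.
#' @param mask A nonempty `structure_mask` sharing the dose geometry.
#' @param bin_width_gy Dose bin width for the curve, Gy; default 0.05.
#' @return A `dvh_curve` list: `structure`, `dose_edges_gy` (increasing,
#'   starting at 0), `cum_volume_fraction` (nonincreasing, starts at 1:
#'   fraction of the structure receiving at least each edge dose) and
#'   `total_volume_cc`.
#' @export
compute_dvh <- function(dose, mask, bin_width_gy = 0.05) {
  stopifnot(inherits(dose, "dose_grid"), inherits(mask, "structure_mask"),
            bin_width_gy > 0)
  stop_if_geometry_mismatch(dose$geometry, mask$geometry)
  d <- dose$dose[mask$occupancy]
  if (length(d) == 0) stop("mask is empty")
  edges <- seq(0, max(d) + bin_width_gy, by = bin_width_gy)
  # fraction with dose >= edge; findInterval on the sorted sample
  ds <- sort(d)
  n_below <- findInterval(edges - 1e-12, ds)
  frac <- 1 - n_below / length(d)
  structure(list(structure = mask$name,
                 dose_edges_gy = edges,
                 cum_volume_fraction = frac,
                 total_volume_cc = length(d) * voxel_volume_cc(mask$geometry)),
            class = "dvh_curve")
}

# Minimum dose to the hottest `cc` of the sorted voxel doses.
# Anchor points are (k * voxel_cc, d_(k)) on the descending sort with linear
# interpolation between anchors; volumes at or below one voxel clamp to the
# hottest voxel's dose (within-voxel interpolation cannot go above Dmax).
dose_at_hottest_cc <- function(d_sorted_desc, voxel_cc, cc) {
  n <- length(d_sorted_desc)
  total <- n * voxel_cc
  if (cc > total + 1e-9) stop("requested volume exceeds structure volume")
  if (cc <= voxel_cc) return(d_sorted_desc[1])
  k <- cc / voxel_cc           # fractional voxel count
  k_lo <- floor(k)
  if (k_lo >= n) return(d_sorted_desc[n])
  frac <- k - k_lo
  d_lo <- d_sorted_desc[k_lo]
  d_hi <- d_sorted_desc[k_lo + 1]
  d_lo + (d_hi - d_lo) * frac
}

#' Evaluate a plan-quality metric on a dose grid
#'
#' Metrics are computed from the raw voxel doses (not a binned curve), with
#' whole-voxel membership. `VxGy` metrics count voxels with dose at or above
#' the threshold; `Dcc` metrics sort doses descending, accumulate volume and
#' interpolate linearly within the voxel that crosses the requested volume
#' (volumes smaller than one voxel return the hottest voxel's dose).
#'
#' @param dose A `dose_grid`.
#' @param mask A nonempty `structure_mask` on the same geometry.
#' @param spec A `metric_spec` or canonical metric string.
#' @return The metric value (percent for `V..[%]`, cc for `V..[cc]`,
#'   Gy for `D`/`Mean`/`Max`).
#' @examples
#' g <- volume_geometry(c(2, 1, 1), c(10, 10, 10))
#' dg <- dose_grid(array(c(10, 50), c(2, 1, 1)), g)
#' m <- structure_mask(array(TRUE, c(2, 1, 1)), g, "s")
#' evaluate_metric(dg, m, "V20Gy[%]")  # 50
#' @export
evaluate_metric <- function(dose, mask, spec) {
  spec <- as_metric_spec(spec)
  stopifnot(inherits(dose, "dose_grid"), inherits(mask, "structure_mask"))
  stop_if_geometry_mismatch(dose$geometry, mask$geometry)
  d <- dose$dose[mask$occupancy]
  if (length(d) == 0) stop("mask is empty")
  vv <- voxel_volume_cc(mask$geometry)
  switch(spec$kind,
    V_DOSE_PCT = 100 * mean(d >= spec$threshold - 1e-12),
    V_DOSE_CC  = sum(d >= spec$threshold - 1e-12) * vv,
    D_CC       = dose_at_hottest_cc(sort(d, decreasing = TRUE), vv, spec$threshold),
    D_PCT      = dose_at_hottest_cc(sort(d, decreasing = TRUE), vv,
                                    spec$threshold / 100 * length(d) * vv),
    MEAN       = mean(d),
    MAX        = max(d),
    stop("unknown metric kind")
  )
}

#' Tabulate plan-quality metrics over a structure set
#'
#' @param dose A `dose_grid`.
#' @param structure_set Named list of `structure_mask`s.
#' @param specs Data frame with columns `structure` and `metric` (canonical
#'   metric strings), or a character vector `"Structure:Metric"`.
#' @return Data frame with columns `structure`, `metric`, `value`; one row
#'   per requested spec. Writable as CSV.
#' @export
metrics_table <- function(dose, structure_set, specs) {
  if (is.character(specs)) {
    parts <- strsplit(specs, ":", fixed = TRUE)
    specs <- data.frame(structure = vapply(parts, `[`, "", 1),
                        metric = vapply(parts, `[`, "", 2),
                        stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(specs), all(c("structure", "metric") %in% names(specs)))
  if (nrow(specs) == 0) {
    return(data.frame(structure = character(0), metric = character(0),
                      value = numeric(0)))
  }
  vals <- vapply(seq_len(nrow(specs)), function(i) {
    sname <- specs$structure[i]
    if (!sname %in% names(structure_set)) {
      stop("unknown structure in metric spec: ", sname)
    }
    evaluate_metric(dose, structure_set[[sname]], specs$metric[i])
  }, numeric(1))
  data.frame(structure = specs$structure, metric = specs$metric, value = vals,
             stringsAsFactors = FALSE)
}
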