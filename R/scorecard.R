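#' Piecewise-linear score function for one plan-quality metric
#'
#' A score function maps a measured DVH metric to points. Its breakpoints run
#' from the failing value (0 points) through optional intermediate anchors
#' (typically the expected or historically achieved value) up to the maximum,
#' deliberately unachievable, point value. Metric values beyond either
#' terminal breakpoint clamp to that terminal's points. Bands translate the
#' achieved points into the usual color semantics: red (fail) below the
#' acceptable range, yellow (acceptable), green (clinical benchmark), blue
#' reserved for the unachievable maximum.
#'
#' @param structure Structure name the metric applies to.
#' @param metric Canonical metric string (see [parse_metric()]).
#' @param breakpoints Data frame with numeric columns `value` (metric value,
#'   strictly monotone) and `points` (`>= 0`, exactly one terminal at 0,
#'   maximum at the other terminal).
#' @param benchmark_points Points at or above which the band is
#'   `BENCHMARK_green`; defaults to 80 percent of the maximum.
#' @return A `score_function`.
#' @export
score_function <- function(structure, metric, breakpoints,
                           benchmark_points = NULL) {
  stopifnot(is.data.frame(breakpoints),
            all(c("value", "points") %in% names(breakpoints)),
            nrow(breakpoints) >= 2)
  v <- breakpoints$value
  p <- breakpoints$points
  dv <- diff(v)
  if (!(all(dv > 0) || all(dv < 0))) {
    stop("breakpoint values must be strictly monotone")
  }
  if (any(p < 0)) stop("points must be >= 0")
  if (min(p[c(1, length(p))]) != 0) {
    stop("one terminal breakpoint must carry 0 points (the failing end)")
  }
  if (max(p) != max(p[c(1, length(p))])) {
    stop("maximum points must sit at a terminal breakpoint")
  }
  max_points <- max(p)
  if (is.null(benchmark_points)) benchmark_points <- 0.8 * max_points
  structure(list(structure = structure,
                 metric = as_metric_spec(metric)$text,
                 breakpoints = data.frame(value = v, points = p),
                 max_points = max_points,
                 benchmark_points = benchmark_points),
            class = "score_function")
}

#' Score a measured metric value against a score function
#'
#' Linear interpolation between the bracketing breakpoints, clamped at the
#' terminal breakpoints.
#'
#' @param fn A `score_function`.
#' @param value Measured metric value (finite).
#' @return List with `points` and `band` (one of `"FAIL_red"`,
#'   `"ACCEPTABLE_yellow"`, `"BENCHMARK_green"`, `"UNACHIEVABLE_blue"`).
#' @examples
#' fn <- score_function("Lung", "V20Gy[%]",
#'                      data.frame(value = c(35, 30, 20), points = c(0, 5, 10)))
#' score_metric(fn, 25)  # 7.5 points
#' @export
score_metric <- function(fn, value) {
  stopifnot(inherits(fn, "score_function"))
  if (!is.finite(value)) stop("metric value must be finite")
  bp <- fn$breakpoints
  # approx() needs increasing x; flip decreasing functions
  o <- order(bp$value)
  pts <- stats::approx(bp$value[o], bp$points[o], xout = value, rule = 2)$y
  band <- if (pts >= fn$max_points) "UNACHIEVABLE_blue"
          else if (pts >= fn$benchmark_points) "BENCHMARK_green"
          else if (pts > 0) "ACCEPTABLE_yellow"
          else "FAIL_red"
  list(points = pts, band = band)
}

#' Assemble a dosimetric scorecard
#'
#' @param name Card name.
#' @param side `"LEFT"`, `"RIGHT"` or `"COMPARISON"`.
#' @param functions List of `score_function`s.
#' @return A `score_card` with `max_total` equal to the sum of per-function
#'   maxima.
#' @export
score_card <- function(name, side, functions) {
  side <- match.arg(toupper(side), c("LEFT", "RIGHT", "COMPARISON"))
  stopifnot(length(functions) >= 1,
            all(vapply(functions, inherits, TRUE, "score_function")))
  structure(list(name = name, side = side, functions = functions,
                 max_total = sum(vapply(functions, `[[`, 1, "max_points"))),
            class = "score_card")
}

#' @export
print.score_card <- function(x, ...) {
  cat(sprintf("<score_card> '%s' (%s): %d metrics, max total %g points\n",
              x$name, x$side, length(x$functions), x$max_total))
  invisible(x)
}

#' Score a plan's metrics table against a card
#'
#' @param card A `score_card`.
#' @param metrics A metrics table as produced by [metrics_table()]
#'   (columns `structure`, `metric`, `value`); every card metric must be
#'   present.
#' @return A `score_report`: data frame `rows` (structure, metric, value,
#'   points, max_points, band) plus `total` and `max_total`.
#' @export
score_plan <- function(card, metrics) {
  stopifnot(inherits(card, "score_card"), is.data.frame(metrics))
  rows <- lapply(card$functions, function(fn) {
    hit <- metrics$structure == fn$structure & metrics$metric == fn$metric
    if (!any(hit)) {
      stop(sprintf("metric '%s' for structure '%s' missing from metrics table",
                   fn$metric, fn$structure))
    }
    value <- metrics$value[which(hit)[1]]
    sc <- score_metric(fn, value)
    data.frame(structure = fn$structure, metric = fn$metric, value = value,
               points = sc$points, max_points = fn$max_points, band = sc$band,
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  structure(list(card = card$name, side = card$side, rows = rows,
                 total = sum(rows$points), max_total = card$max_total),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("<score_report> card '%s' (%s)\n", x$card, x$side))
  print(x$rows, row.names = FALSE, digits = 4)
  cat(sprintf("TOTAL: %.1f / %g\n", x$total, x$max_total))
  invisible(x)
}

#' Write a score report in a plain-text row layout
#' @param report A `score_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_score_report <- function(report, path) {
  stopifnot(inherits(report, "score_report"))
  utils::write.csv(report$rows, path, row.names = FALSE)
  invisible(path)
}

card_to_list <- function(card) {
  list(
    name = card$name, side = card$side,
    functions = lapply(card$functions, function(fn) {
      list(structure = fn$structure, metric = fn$metric,
           breakpoints = fn$breakpoints,
           benchmark_points = fn$benchmark_points)
    })
  )
}

card_from_list <- function(x) {
  need <- c("name", "side", "functions")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("card schema violation: missing field(s) ",
                         paste(miss, collapse = ", "))
  fns <- lapply(seq_along(x$functions), function(i) {
    f <- x$functions[[i]]
    fmiss <- setdiff(c("structure", "metric", "breakpoints"), names(f))
    if (length(fmiss)) {
      stop(sprintf("card schema violation: functions[%d] missing %s",
                   i, paste(fmiss, collapse = ", ")))
    }
    bp <- data.frame(value = as.numeric(unlist(f$breakpoints$value)),
                     points = as.numeric(unlist(f$breakpoints$points)))
    score_function(f$structure, f$metric, bp,
                   benchmark_points = f$benchmark_points)
  })
  score_card(x$name, x$side, fns)
}

#' Save / load a scorecard as JSON
#'
#' The JSON schema holds the card name, side, and for each metric its
#' structure, canonical metric string, breakpoints (value/points pairs) and
#' benchmark points. Round-trips losslessly.
#'
#' @param card A `score_card`.
#' @param path JSON file path.
#' @return `save_card` returns `path` invisibly; `load_card` returns the
#'   `score_card`.
#' @export
save_card <- function(card, path) {
  stopifnot(inherits(card, "score_card"))
  jsonlite::write_json(card_to_list(card), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "columns")
  invisible(path)
}

#' @rdname save_card
#' @export
load_card <- function(path) {
  card_from_list(jsonlite::read_json(path, simplifyVector = FALSE))
}
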