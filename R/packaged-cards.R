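#' Packaged dosimetric scorecards
#'
#' Three cards ship with the package. The left- and right-sided IMRT cards
#' (200-point maximum each) score the full institutional metric panel for
#' breast/chest wall plus regional-node plans: target coverage at the
#' prescription and near-prescription levels (V50Gy / V52.5Gy for the breast,
#' V45Gy / V47.25Gy for the nodal volumes), heart mean and near-maximum dose,
#' ipsilateral lung V20Gy/V5Gy, contralateral lung V5Gy, esophagus and
#' contralateral breast near-maximum dose, plus the two conformity rows that
#' dominate field-number comparisons: near-maximum dose to the conformity
#' ring (body minus PTV plus 5 mm) and to the body. The comparison card (153-point
#' maximum) uses a relaxed, CTV-based metric panel intended for comparing
#' planning techniques that target CTV rather than PTV coverage.
#'
#' For each metric the failing breakpoint (0 points) sits at the clinical
#' criterion bound (e.g. ipsilateral lung V20Gy fails above 35 percent, heart
#' mean dose above 5 Gy), the green benchmark anchor at the institutional
#' expected value, and the maximum points at a deliberately unachievable
#' terminal (complete coverage, zero organ dose). Coverage metrics carry the
#' largest weights, then heart, lung, and contralateral structures; the
#' per-metric weights sum exactly to the card maxima.
#'
#' Structure names used by the cards: `BreastCTV`, `BreastPTV`, `SclavCTV`,
#' `SclavPTV`, `AxillaCTV`, `AxillaPTV`, `IMNCTV`, `Heart`, `IpsiLung`,
#' `ContraLung`, `Esophagus`, `ContraBreast` (and `Ring` for conformity
#' reporting outside the cards).
#'
#' @param which One of `"left"`, `"right"`, `"comparison"`.
#' @return A `score_card` (max total 200 for left/right, 153 for comparison).
#' @examples
#' packaged_card("left")$max_total  # 200
#' @export
packaged_card <- function(which = c("left", "right", "comparison")) {
  which <- match.arg(which)
  sf <- function(structure, metric, values, points, benchmark_points = NULL) {
    score_function(structure, metric,
                   data.frame(value = values, points = points),
                   benchmark_points = benchmark_points)
  }
  if (which %in% c("left", "right")) {
    heart_mean_anchor <- if (which == "left") 3.0 else 1.6
    fns <- list(
      # target coverage: fail at 90% coverage, benchmark at expected value,
      # maximum at (unachievable) complete coverage
      sf("BreastCTV", "V50Gy[%]",   c(90, 97.9, 100), c(0, 14, 18), 14),
      sf("BreastCTV", "V52.5Gy[%]", c(20, 5, 0),      c(0, 4, 5),   4),
      sf("BreastPTV", "V50Gy[%]",   c(90, 95.7, 100), c(0, 10, 13), 10),
      sf("BreastPTV", "V52.5Gy[%]", c(20, 5, 0),      c(0, 4, 5),   4),
      sf("SclavCTV",  "V45Gy[%]",   c(90, 100),       c(0, 13),     10.4),
      sf("SclavCTV",  "V47.25Gy[%]", c(90, 99.8, 100), c(0, 3, 4),  3),
      sf("SclavPTV",  "V45Gy[%]",   c(90, 95.5, 100), c(0, 7, 9),   7),
      sf("SclavPTV",  "V47.25Gy[%]", c(80, 85.6, 100), c(0, 3, 4),  3),
      sf("AxillaCTV", "V45Gy[%]",   c(90, 100),       c(0, 13),     10.4),
      sf("AxillaCTV", "V47.25Gy[%]", c(90, 99.6, 100), c(0, 3, 4),  3),
      sf("AxillaPTV", "V45Gy[%]",   c(90, 97.1, 100), c(0, 7, 9),   7),
      sf("AxillaPTV", "V47.25Gy[%]", c(85, 92.5, 100), c(0, 3, 4),  3),
      sf("IMNCTV",    "V45Gy[%]",   c(90, 99.2, 100), c(0, 10, 13), 10),
      sf("IMNCTV",    "V47.25Gy[%]", c(80, 96.5, 100), c(0, 3, 4),  3),
      # organs at risk: fail at the clinical criterion bound
      sf("Heart", "Mean[Gy]",    c(5, heart_mean_anchor, 0), c(0, 14, 18), 14),
      sf("Heart", "D0.03cc[Gy]", c(53, 23.6, 0),  c(0, 8, 10),  8),
      sf("IpsiLung", "V20Gy[%]", c(35, 19.3, 0),  c(0, 11, 14), 11),
      sf("IpsiLung", "V5Gy[%]",  c(55, 51, 0),    c(0, 4, 5),   4),
      sf("ContraLung", "V5Gy[%]", c(15, 0.2, 0),  c(0, 4, 5),   4),
      sf("Esophagus", "D0.03cc[Gy]", c(50, 18.6, 0), c(0, 4, 5), 4),
      sf("ContraBreast", "D0.03cc[Gy]", c(4.96, 3.7, 0), c(0, 4, 5), 4),
      # hotspot / conformity rows: fail at 110% of the 50 Gy prescription,
      # benchmark at 105%, maximum at an unachievable 90%
      sf("Ring", "D0.03cc[Gy]", c(55, 52.5, 45), c(0, 9.6, 12), 9.6),
      sf("Body", "D0.03cc[Gy]", c(55, 52.5, 45), c(0, 6.4, 8),  6.4)
    )
    return(score_card(sprintf("%s-sided IMRT scorecard", which),
                      toupper(which), fns))
  }
  # comparison card: relaxed, CTV-coverage-oriented panel, 153 points
  fns <- list(
    sf("BreastCTV", "V47.5Gy[%]", c(90, 99, 100),   c(0, 16, 20), 16),
    sf("BreastCTV", "V50Gy[%]",   c(60, 98.3, 100), c(0, 16, 20), 16),
    sf("SclavCTV",  "V45Gy[%]",   c(90, 99.9, 100), c(0, 14, 18), 14),
    sf("AxillaCTV", "V45Gy[%]",   c(90, 100),       c(0, 15),     12),
    sf("IMNCTV",    "V45Gy[%]",   c(75, 99.6, 100), c(0, 16, 20), 16),
    sf("Heart", "Mean[Gy]",       c(5, 2, 0),       c(0, 12, 15), 12),
    sf("Heart", "D0.03cc[Gy]",    c(53, 20, 0),     c(0, 8, 10),  8),
    sf("IpsiLung", "V20Gy[%]",    c(35, 19.6, 0),   c(0, 12, 15), 12),
    sf("IpsiLung", "V5Gy[%]",     c(55, 50, 0),     c(0, 4, 5),   4),
    sf("ContraLung", "V5Gy[%]",   c(15, 0.1, 0),    c(0, 4, 5),   4),
    sf("Esophagus", "D0.03cc[Gy]", c(50, 17, 0),    c(0, 4, 5),   4),
    sf("ContraBreast", "V5Gy[%]", c(10, 1.7, 0),    c(0, 4, 5),   4)
  )
  score_card("technique comparison scorecard", "COMPARISON", fns)
}

#' Path to a packaged card's JSON file
#' @param which One of `"left"`, `"right"`, `"comparison"`.
#' @return File path inside the installed package.
#' @export
packaged_card_path <- function(which = c("left", "right", "comparison")) {
  which <- match.arg(which)
  system.file("extdata", "cards", paste0(which, "_imrt.json"),
              package = "ringplan", mustWork = TRUE)
}
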