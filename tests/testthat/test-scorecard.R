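lung_fn <- function() {
  score_function("IpsiLung", "V20Gy[%]",
                 data.frame(value = c(35, 30, 20), points = c(0, 5, 10)),
                 benchmark_points = 8)
}

test_that("piecewise-linear scoring interpolates and clamps", {
  fn <- lung_fn()
  expect_equal(score_metric(fn, 35)$points, 0)
  expect_equal(score_metric(fn, 30)$points, 5)
  expect_equal(score_metric(fn, 20)$points, 10)
  # hand interpolation: 5 + 5 * (30 - 25) / 10
  expect_equal(score_metric(fn, 25)$points, 7.5)
  expect_equal(score_metric(fn, 40)$points, 0)    # clamp beyond failing end
  expect_equal(score_metric(fn, 5)$points, 10)    # clamp beyond best end
  expect_error(score_metric(fn, NaN), "finite")

  # continuity / monotonicity along the stated direction
  vals <- seq(15, 40, by = 0.25)
  pts <- vapply(vals, function(v) score_metric(fn, v)$points, numeric(1))
  expect_true(all(diff(pts) <= 1e-12))
  # continuity: increments bounded by steepest slope (1 pt/unit) times step
  expect_true(max(abs(diff(pts))) <= 0.25 + 1e-12)

  expect_error(score_function("s", "Mean[Gy]",
                              data.frame(value = c(1, 1), points = c(0, 5))),
               "monotone")
  expect_error(score_function("s", "Mean[Gy]",
                              data.frame(value = c(5, 1), points = c(2, 5))),
               "0 points")
})

test_that("bands follow the red/yellow/green/blue semantics", {
  fn <- lung_fn()
  expect_equal(score_metric(fn, 36)$band, "FAIL_red")
  expect_equal(score_metric(fn, 32)$band, "ACCEPTABLE_yellow")
  expect_equal(score_metric(fn, 24)$band, "BENCHMARK_green")
  expect_equal(score_metric(fn, 20)$band, "UNACHIEVABLE_blue")
})

test_that("plan scoring sums rows and hits the card bounds", {
  card <- score_card("toy", "LEFT", list(
    lung_fn(),
    score_function("Heart", "Mean[Gy]",
                   data.frame(value = c(5, 0), points = c(0, 20)))
  ))
  expect_equal(card$max_total, 30)
  best <- data.frame(structure = c("IpsiLung", "Heart"),
                     metric = c("V20Gy[%]", "Mean[Gy]"), value = c(20, 0))
  worst <- transform(best, value = c(35, 5))
  expect_equal(score_plan(card, best)$total, 30)
  expect_equal(score_plan(card, worst)$total, 0)
  r1 <- score_plan(card, best); r2 <- score_plan(card, best)
  expect_identical(r1$rows, r2$rows)
  missing <- best[1, , drop = FALSE]
  expect_error(score_plan(card, missing), "Mean\\[Gy\\].*Heart")
})

test_that("improving one metric never lowers the total", {
  card <- packaged_card("left")
  base <- do.call(rbind, lapply(card$functions, function(fn) {
    data.frame(structure = fn$structure, metric = fn$metric,
               value = mean(fn$breakpoints$value))
  }))
  t0 <- score_plan(card, base)$total
  for (i in seq_along(card$functions)) {
    fn <- card$functions[[i]]
    better <- base
    best_value <- fn$breakpoints$value[which.max(fn$breakpoints$points)]
    better$value[i] <- best_value
    expect_gte(score_plan(card, better)$total, t0 - 1e-9)
  }
})

test_that("packaged cards carry the published maxima and metric panels", {
  left <- packaged_card("left")
  right <- packaged_card("right")
  comp <- packaged_card("comparison")
  expect_equal(left$max_total, 200)
  expect_equal(right$max_total, 200)
  expect_equal(comp$max_total, 153)

  key <- function(card) vapply(card$functions,
                               function(f) paste(f$structure, f$metric),
                               character(1))
  # the institutional metric panel is fully represented
  panel <- c("BreastCTV V50Gy[%]", "BreastCTV V52.5Gy[%]",
             "BreastPTV V50Gy[%]", "BreastPTV V52.5Gy[%]",
             "SclavCTV V45Gy[%]", "SclavPTV V45Gy[%]",
             "AxillaCTV V45Gy[%]", "AxillaPTV V45Gy[%]", "IMNCTV V45Gy[%]",
             "Heart Mean[Gy]", "Heart D0.03cc[Gy]",
             "IpsiLung V20Gy[%]", "IpsiLung V5Gy[%]", "ContraLung V5Gy[%]",
             "Esophagus D0.03cc[Gy]", "ContraBreast D0.03cc[Gy]")
  expect_true(all(panel %in% key(left)))
  expect_true(all(panel %in% key(right)))
  cpanel <- paste(comparison_metric_panel()$structure,
                  comparison_metric_panel()$metric)
  expect_true(all(cpanel %in% key(comp)))

  # failing breakpoints sit at the clinical criteria bounds
  fail_value <- function(card, structure, metric) {
    fn <- card$functions[[which(key(card) == paste(structure, metric))]]
    fn$breakpoints$value[fn$breakpoints$points == 0]
  }
  expect_equal(fail_value(left, "IpsiLung", "V20Gy[%]"), 35)
  expect_equal(fail_value(left, "Heart", "Mean[Gy]"), 5)
  expect_equal(fail_value(left, "Heart", "D0.03cc[Gy]"), 53)
  expect_equal(fail_value(comp, "IpsiLung", "V20Gy[%]"), 35)
})

test_that("cards round-trip through JSON and ship with the package", {
  card <- packaged_card("left")
  path <- tempfile(fileext = ".json")
  save_card(card, path)
  back <- load_card(path)
  expect_equal(back$max_total, card$max_total)
  expect_equal(length(back$functions), length(card$functions))
  for (i in seq_along(card$functions)) {
    expect_equal(back$functions[[i]]$breakpoints,
                 card$functions[[i]]$breakpoints)
    expect_identical(back$functions[[i]]$metric, card$functions[[i]]$metric)
  }
  for (w in c("left", "right", "comparison")) {
    shipped <- load_card(packaged_card_path(w))
    expect_equal(shipped$max_total, packaged_card(w)$max_total)
    expect_identical(key_shipped <- vapply(shipped$functions,
                                           function(f) paste(f$structure, f$metric),
                                           character(1)),
                     vapply(packaged_card(w)$functions,
                            function(f) paste(f$structure, f$metric),
                            character(1)))
  }
  # schema violations name the offending field
  bad <- tempfile(fileext = ".json")
  writeLines('{"name": "x", "side": "LEFT"}', bad)
  expect_error(load_card(bad), "functions")
})
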