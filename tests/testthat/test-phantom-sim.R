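small_spec <- function(side = "LEFT", seed = 1, jitter = 0) {
  phantom_spec(side, c(48, 48, 32), c(5, 5, 5), seed = seed,
               jitter_sd_mm = jitter)
}

test_that("phantom construction is deterministic and anatomically consistent", {
  ph1 <- build_phantom(small_spec(seed = 7, jitter = 3))
  ph2 <- build_phantom(small_spec(seed = 7, jitter = 3))
  for (nm in names(ph1$structures)) {
    expect_identical(ph1$structures[[nm]]$occupancy,
                     ph2$structures[[nm]]$occupancy)
  }
  expect_identical(ph1$density, ph2$density)
  ph3 <- build_phantom(small_spec(seed = 8, jitter = 3))
  expect_false(identical(ph1$structures$BreastCTV$occupancy,
                         ph3$structures$BreastCTV$occupancy))

  # every target is inside the body
  body <- ph1$structures$Body$occupancy
  for (nm in c("BreastCTV", "SclavCTV", "AxillaCTV", "IMNCTV",
               "BreastPTV", "SclavPTV", "AxillaPTV", "IMNPTV", "PTVTotal")) {
    occ <- ph1$structures[[nm]]$occupancy
    expect_true(any(occ))
    expect_false(any(occ & !body))
  }
  # lungs are less dense than soft tissue
  lungs <- ph1$structures$IpsiLung$occupancy
  expect_true(all(ph1$density[lungs] < 1))
  expect_true(all(ph1$density[body & !lungs &
                              !ph1$structures$ContraLung$occupancy] == 1))
})

test_that("left phantoms carry the heart on the left; mirrors reflect", {
  pl <- build_phantom(small_spec("LEFT"))
  g <- pl$geometry
  xs <- g$origin[1] + (seq_len(g$shape[1]) - 1) * g$spacing[1]
  hx <- which(pl$structures$Heart$occupancy, arr.ind = TRUE)[, 1]
  expect_gt(mean(xs[hx]), 0)   # +x is the patient's left in LPS

  pr <- build_phantom(small_spec("RIGHT"))
  for (nm in names(pl$structures)) {
    flipped <- pl$structures[[nm]]$occupancy[rev(seq_len(g$shape[1])), , ]
    expect_identical(pr$structures[[nm]]$occupancy, flipped)
  }
})

test_that("dose falls off with depth for a single unmodulated field", {
  ph <- build_phantom(small_spec())
  arr <- generate_arrangement(310, "LEFT")
  arr$fields <- arr$fields[arr$fields$offset_deg == 0, , drop = FALSE]
  arr$fields$gantry_deg <- 0   # single anterior field
  d <- simulate_dose(arr, ph, weights = 1, modulate = FALSE,
                     aperture_targets = list(ph$structures$BreastPTV))
  g <- ph$geometry
  # walk one beam-axis column through the breast center, anterior to
  # posterior, inside the body: dose must be nonincreasing with depth
  ix <- which.min(abs((g$origin[1] + (seq_len(g$shape[1]) - 1) * g$spacing[1]) - 50))
  iz <- which.min(abs((g$origin[3] + (seq_len(g$shape[3]) - 1) * g$spacing[3]) - (-20)))
  col <- d$dose[ix, , iz]
  inside <- ph$structures$Body$occupancy[ix, , iz] & col > 0
  prof <- col[inside]
  expect_gt(length(prof), 5)
  expect_true(all(diff(prof) <= 1e-9))
})

test_that("dose is nonnegative, normalized, and scale-invariant in weights", {
  ph <- shared_phantom()
  arr <- generate_arrangement(310, "LEFT")
  d1 <- simulate_dose(arr, ph)
  expect_true(all(d1$dose >= 0))
  expect_equal(stats::median(d1$dose[ph$structures$BreastPTV$occupancy]), 50)
  # normalization makes the result invariant to a global weight rescale
  d2 <- simulate_dose(arr, ph, weights = rep(2, nrow(arr$fields)))
  expect_equal(d1$dose, d2$dose, tolerance = 1e-12)
  expect_error(simulate_dose(arr, ph, weights = rep(0, nrow(arr$fields))),
               "zero")
})

test_that("a wider aperture margin never reduces target coverage", {
  ph <- build_phantom(small_spec())
  arr <- generate_arrangement(310, "LEFT")
  v50 <- vapply(c(4, 7, 10), function(m) {
    d <- simulate_dose(arr, ph, beam_dose_params(aperture_margin_mm = m))
    evaluate_metric(d, ph$structures$BreastPTV, "V47.5Gy[%]")
  }, numeric(1))
  expect_true(all(diff(v50) >= -1e-9))
})

test_that("the multi-field plan is more conformal than a tangent pair", {
  ph <- shared_phantom()
  arr15 <- generate_arrangement(310, "LEFT")
  d15 <- simulate_dose(arr15, ph)
  tang <- tangent_nodal_arrangement(310, "LEFT")
  d2 <- simulate_dose(tang, ph, weights = c(1, 1, 0, 0),
                      aperture_targets = rep(list(ph$structures$PTVTotal), 4))
  ring <- ph$structures$Ring
  expect_lt(evaluate_metric(d15, ring, "D0.03cc[Gy]"),
            evaluate_metric(d2, ring, "D0.03cc[Gy]"))
})

test_that("paired cohorts are reproducible and separation yields 2/252", {
  ch1 <- make_cohort(n_pairs = 3, seed = 5, shape = c(48, 48, 32),
                     spacing = c(5, 5, 5))
  ch2 <- make_cohort(n_pairs = 3, seed = 5, shape = c(48, 48, 32),
                     spacing = c(5, 5, 5))
  expect_identical(ch1$metrics_a, ch2$metrics_a)
  expect_identical(ch1$metrics_b, ch2$metrics_b)
  expect_length(ch1$samples, nrow(comparison_metric_panel()))
  for (s in ch1$samples) {
    expect_length(s$group_a, 3)
    expect_length(s$group_b, 3)
  }
  tab <- compare_cohorts(ch1$samples)
  separated <- vapply(ch1$samples, function(s) {
    max(s$group_a) < min(s$group_b) || max(s$group_b) < min(s$group_a)
  }, logical(1))
  expect_true(any(separated))   # the techniques differ measurably
  expect_equal(tab$p_two_sided[separated],
               rep(2 / choose(6, 3), sum(separated)))
})
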