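make_dose_mask <- function(values, spacing = c(10, 10, 10)) {
  # one voxel per value; 10 mm isotropic spacing gives 1 cc voxels
  n <- length(values)
  g <- volume_geometry(c(n, 1, 1), spacing)
  list(dose = dose_grid(array(values, c(n, 1, 1)), g),
       mask = structure_mask(array(TRUE, c(n, 1, 1)), g, "s"),
       geometry = g)
}

test_that("metric strings parse to canonical specs and round-trip", {
  s <- parse_metric("V20Gy[%]")
  expect_equal(s$kind, "V_DOSE_PCT"); expect_equal(s$threshold, 20)
  expect_equal(parse_metric("D0.03cc[Gy]")$kind, "D_CC")
  expect_equal(parse_metric("D0.03cc[Gy]")$threshold, 0.03)
  expect_equal(parse_metric("D2%[Gy]")$kind, "D_PCT")
  expect_equal(parse_metric("Mean[Gy]")$kind, "MEAN")
  for (txt in c("V50Gy[%]", "V5Gy[cc]", "D0.03cc[Gy]", "D2%[Gy]",
                "Mean[Gy]", "Max[Gy]")) {
    p <- parse_metric(txt)
    expect_identical(format_metric(p$kind, p$threshold), txt)
  }
  expect_error(parse_metric("Q13[Gy]"), "cannot parse")
})

test_that("cumulative DVH curves start at 1 and step at voxel doses", {
  u <- make_dose_mask(rep(50, 8))
  c1 <- compute_dvh(u$dose, u$mask, bin_width_gy = 0.5)
  expect_equal(c1$cum_volume_fraction[1], 1)
  expect_true(all(diff(c1$cum_volume_fraction) <= 0))
  expect_true(all(c1$cum_volume_fraction[c1$dose_edges_gy <= 50] == 1))
  expect_true(all(c1$cum_volume_fraction[c1$dose_edges_gy > 50] == 0))

  two <- make_dose_mask(c(10, 50))
  c2 <- compute_dvh(two$dose, two$mask, bin_width_gy = 0.5)
  expect_equal(c2$cum_volume_fraction[c2$dose_edges_gy == 20], 0.5)
  expect_equal(c2$total_volume_cc, 2)

  empty <- structure_mask(array(FALSE, c(8, 1, 1)), u$geometry, "e")
  expect_error(compute_dvh(u$dose, empty), "empty")
})

test_that("V, D, Mean metrics match hand-computed cases", {
  u <- make_dose_mask(rep(50, 4))
  expect_equal(evaluate_metric(u$dose, u$mask, "V45Gy[%]"), 100)
  two <- make_dose_mask(c(10, 50))
  expect_equal(evaluate_metric(two$dose, two$mask, "V20Gy[%]"), 50)
  expect_equal(evaluate_metric(two$dose, two$mask, "V20Gy[cc]"), 1)
  # hottest 0.03 cc sits inside the 50 Gy voxel (1 cc voxels)
  expect_equal(evaluate_metric(two$dose, two$mask, "D0.03cc[Gy]"), 50)
  expect_equal(evaluate_metric(two$dose, two$mask, "Mean[Gy]"), 30)
  expect_equal(evaluate_metric(two$dose, two$mask, "Max[Gy]"), 50)
  # D for a volume spanning both voxels interpolates between their doses
  expect_equal(evaluate_metric(two$dose, two$mask, "D1.5cc[Gy]"), 30)
  expect_error(evaluate_metric(two$dose, two$mask, "D5cc[Gy]"), "exceeds")
})

test_that("metrics agree with voxel-enumeration oracles on random grids", {
  set.seed(101)
  for (rep in 1:4) {
    shape <- sample(3:20, 3, replace = TRUE)
    g <- volume_geometry(shape, c(2, 2, 1.5))
    vals <- array(stats::runif(prod(shape), 0, 60), shape)
    dg <- dose_grid(vals, g)
    occ <- array(stats::runif(prod(shape)) < 0.5, shape)
    if (!any(occ)) occ[1] <- TRUE
    m <- structure_mask(occ, g, "s")
    d <- vals[occ]
    vv <- voxel_volume_cc(g)

    for (thr in c(5, 20, 45)) {
      expect_identical(evaluate_metric(dg, m, sprintf("V%dGy[%%]", thr)),
                       bf_v_pct(d, thr))
    }
    expect_identical(evaluate_metric(dg, m, "Mean[Gy]"), mean(d))
    expect_identical(evaluate_metric(dg, m, "Max[Gy]"), max(d))

    for (cc in c(0.03, 0.5, 2)) {
      if (cc > length(d) * vv) next
      got <- evaluate_metric(dg, m, sprintf("D%gcc[Gy]", cc))
      bounds <- bf_dcc_bounds(d, vv, cc)
      expect_gte(got, bounds["lower"] - 1e-12)
      expect_lte(got, bounds["upper"] + 1e-12)
    }
  }
})

test_that("V is nonincreasing in threshold and Dcc nonincreasing in volume", {
  set.seed(5)
  x <- make_dose_mask(stats::runif(30, 0, 55))
  v <- vapply(seq(0, 55, by = 5),
              function(t) evaluate_metric(x$dose, x$mask, sprintf("V%gGy[%%]", t)),
              numeric(1))
  expect_true(all(diff(v) <= 0))
  dcc <- vapply(c(0.2, 1, 5, 10, 25),
                function(cc) evaluate_metric(x$dose, x$mask, sprintf("D%gcc[Gy]", cc)),
                numeric(1))
  expect_true(all(diff(dcc) <= 0))
})

test_that("mean dose equals the integral of the cumulative DVH", {
  set.seed(9)
  x <- make_dose_mask(stats::runif(50, 0, 60))
  bw <- 0.05
  curve <- compute_dvh(x$dose, x$mask, bin_width_gy = bw)
  integral <- sum(curve$cum_volume_fraction) * bw  # rectangle rule on edges
  expect_equal(evaluate_metric(x$dose, x$mask, "Mean[Gy]"), integral,
               tolerance = bw)
})

test_that("metrics tables are deterministic and validate structure names", {
  ph <- shared_phantom()
  dose <- simulate_dose(generate_arrangement(310, "LEFT"), ph)
  expect_equal(nrow(metrics_table(dose, ph$structures,
                                  data.frame(structure = character(0),
                                             metric = character(0)))), 0)
  panel <- data.frame(
    structure = c(rep("BreastCTV", 2), rep("BreastPTV", 2), rep("SclavCTV", 2),
                  rep("SclavPTV", 2), rep("AxillaCTV", 2), rep("AxillaPTV", 2),
                  rep("IMNCTV", 2), "Heart", "Heart"),
    metric = c(rep(c("V50Gy[%]", "V52.5Gy[%]"), 2),
               rep(c("V45Gy[%]", "V47.25Gy[%]"), 5), "Mean[Gy]", "D0.03cc[Gy]"))
  tab <- metrics_table(dose, ph$structures, panel)
  expect_equal(nrow(tab), 16)
  tab2 <- metrics_table(dose, ph$structures, panel)
  expect_identical(tab, tab2)
  expect_error(metrics_table(dose, ph$structures,
                             data.frame(structure = "Nope", metric = "Mean[Gy]")),
               "Nope")
})
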