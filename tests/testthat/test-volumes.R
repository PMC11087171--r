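test_that("expansion matches the brute-force Euclidean oracle", {
  # single voxel, isotropic 1 mm grid, radius 5: exact Euclidean ball
  g <- volume_geometry(c(13, 13, 13), c(1, 1, 1))
  occ <- array(FALSE, g$shape); occ[7, 7, 7] <- TRUE
  m <- structure_mask(occ, g, "seed")
  got <- expand_mask(m, 5)
  want <- bf_expand(m, 5)
  expect_identical(got$occupancy, want$occupancy)

  # anisotropic spacing and random masks
  set.seed(42)
  for (rep in 1:3) {
    g2 <- tiny_geometry(c(9, 8, 7), c(1, 2, 1.5))
    m2 <- random_mask(g2, p = 0.08)
    for (r in c(0, 1.4, 3)) {
      expect_identical(expand_mask(m2, r)$occupancy, bf_expand(m2, r)$occupancy)
    }
  }
})

test_that("expansion is monotone, identity at zero, and empty-preserving", {
  set.seed(7)
  g <- tiny_geometry()
  m <- random_mask(g, p = 0.1)
  expect_identical(expand_mask(m, 0)$occupancy, m$occupancy)
  e1 <- expand_mask(m, 2); e2 <- expand_mask(m, 4)
  expect_true(all(e1$occupancy[m$occupancy]))      # contains the input
  expect_true(all(e2$occupancy[e1$occupancy]))     # monotone in radius
  sub <- structure_mask(m$occupancy & random_mask(g, 0.5)$occupancy, g, "sub")
  expect_true(all(expand_mask(m, 3)$occupancy[expand_mask(sub, 3)$occupancy]))
  empty <- structure_mask(array(FALSE, g$shape), g, "empty")
  expect_false(any(expand_mask(empty, 5)$occupancy))
  expect_error(expand_mask(m, -1), ">= 0")
  # composition: two-step expansion stays within the one-step expansion
  # (triangle inequality; equality can fail on a voxel lattice because the
  # intermediate point need not be a voxel center)
  ab <- expand_mask(expand_mask(m, 2), 1.5)$occupancy
  once <- expand_mask(m, 3.5)$occupancy
  expect_true(all(once[ab]))
})

test_that("skin pullback equals the exterior-expansion set algebra", {
  set.seed(11)
  g <- tiny_geometry(c(12, 12, 8), c(1, 1, 1.5))
  body_occ <- array(FALSE, g$shape)
  body_occ[3:10, 3:10, 2:7] <- TRUE
  body <- structure_mask(body_occ, g, "body", "BODY")
  ptv_occ <- array(FALSE, g$shape)
  ptv_occ[4:9, 4:9, 3:6] <- TRUE
  ptv <- structure_mask(ptv_occ, g, "ptv", "TARGET_PTV")

  expect_identical(pull_back_from_surface(ptv, body, 0)$occupancy, ptv$occupancy)
  got <- pull_back_from_surface(ptv, body, 2)
  ext <- structure_mask(!body$occupancy, g, "ext")
  want <- ptv$occupancy & !bf_expand(ext, 2)$occupancy
  expect_identical(got$occupancy, want)
  expect_true(all(ptv$occupancy[got$occupancy]))   # result within the input

  # a PTV already deeper than the pullback is untouched
  deep_occ <- array(FALSE, g$shape); deep_occ[6:7, 6:7, 4:5] <- TRUE
  deep <- structure_mask(deep_occ, g, "deep", "TARGET_PTV")
  expect_identical(pull_back_from_surface(deep, body, 2)$occupancy, deep$occupancy)

  outside <- structure_mask(array(TRUE, g$shape), g, "all")
  expect_error(pull_back_from_surface(outside, body, 2), "contained")
})

test_that("PRV cropping and ring construction match set-algebra oracles", {
  set.seed(3)
  g <- tiny_geometry(c(10, 10, 8), c(1.5, 1.5, 1.5))
  ptv <- random_mask(g, 0.2, "ptv", "TARGET_PTV")
  oar <- random_mask(g, 0.1, "oar")
  got <- crop_with_prv(ptv, oar, 3)
  want <- ptv$occupancy & !bf_expand(oar, 3)$occupancy
  expect_identical(got$occupancy, want)

  disjoint <- structure_mask(ptv$occupancy & !oar$occupancy, g, "p2", "TARGET_PTV")
  expect_identical(crop_with_prv(disjoint, oar, 0)$occupancy, disjoint$occupancy)
  swallowed <- structure_mask(oar$occupancy, g, "p3", "TARGET_PTV")
  expect_false(any(crop_with_prv(swallowed, oar, 3)$occupancy))

  body_occ <- array(TRUE, g$shape)
  body <- structure_mask(body_occ, g, "body", "BODY")
  ring <- make_ring(body, ptv, 3)
  expect_identical(ring$occupancy, body$occupancy & !bf_expand(ptv, 3)$occupancy)
  expect_identical(make_ring(body, ptv, 0)$occupancy,
                   body$occupancy & !ptv$occupancy)
  expect_false(any(make_ring(body, body, 0)$occupancy))

  g_other <- volume_geometry(g$shape, c(1, 1, 1))
  oar_other <- structure_mask(oar$occupancy, g_other, "oar")
  expect_error(crop_with_prv(ptv, oar_other, 3), "geometry")
})

test_that("bolus shell sits outside the body at the requested thickness", {
  g <- volume_geometry(c(16, 16, 10), c(1, 1, 1))
  body_occ <- array(FALSE, g$shape)
  body_occ[, 8:16, ] <- TRUE                      # flat anterior surface at y=8
  body <- structure_mask(body_occ, g, "body", "BODY")
  cw_occ <- array(FALSE, g$shape)
  cw_occ[6:10, 8:10, 4:7] <- TRUE
  cw <- structure_mask(cw_occ, g, "chestwall", "TARGET_PTV")

  shell <- make_bolus_shell(body, cw, thickness_mm = 5)
  expect_false(any(shell$occupancy & body$occupancy))
  expect_true(any(shell$occupancy))
  # every shell voxel within 5 mm of the body (distance-transform check)
  expect_false(any(shell$occupancy & !bf_expand(body, 5)$occupancy))
  # and within the outward neighbourhood of the chest-wall patch
  expect_false(any(shell$occupancy & !bf_expand(cw, 10)$occupancy))
  # on the flat surface the shell is exactly 5 voxels (5 mm) thick
  col <- shell$occupancy[8, , 5]
  expect_equal(sum(col), 5)

  empty <- structure_mask(array(FALSE, g$shape), g, "none", "TARGET_PTV")
  expect_false(any(make_bolus_shell(body, empty, 5)$occupancy))
})

test_that("morphology outputs preserve the input geometry bit-for-bit", {
  g <- tiny_geometry(c(7, 7, 5), c(0.97, 1.21, 1.5))
  m <- random_mask(g, 0.2)
  out <- expand_mask(m, 2.3)
  expect_identical(out$geometry$shape, g$shape)
  expect_identical(out$geometry$spacing, g$spacing)
  expect_identical(out$geometry$origin, g$origin)
})

test_that("margin policy rejects negative margins", {
  p <- margin_policy()
  expect_equal(p$ptv_margin_mm, 5)
  expect_equal(p$imn_ptv_margin_mm, 0)
  expect_equal(p$skin_pullback_pmrt_mm, 2)
  expect_equal(p$esophagus_prv_mm, 3)
  expect_error(margin_policy(ptv_margin_mm = -1), ">= 0")
})
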