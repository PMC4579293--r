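test_that("lesion reports follow the slice-coverage definition", {
  g <- cylinder_mask(c(11, 8, 11), x0 = 6, z0 = 6, radius = 2)
  sm <- streamline_mask(g)

  far <- array(FALSE, dim(g)); far[1, 1, 1] <- TRUE
  rep0 <- intersect_lesion(sm, far)
  expect_false(rep0$interrupted)
  expect_equal(rep0$overlap_voxels, 0)

  # lesion covering the full cross-section in one slice
  slab <- array(FALSE, dim(g)); slab[, 4, ] <- TRUE
  rep1 <- intersect_lesion(sm, slab)
  expect_true(rep1$interrupted)
  expect_equal(max(rep1$coverage$coverage), 1)

  # partial coverage is below the default threshold but interrupts at
  # a lower one; interruption at t = 1 implies it at every t <= 1
  half <- array(FALSE, dim(g)); half[1:6, 4, ] <- TRUE
  rep2 <- intersect_lesion(sm, half)
  expect_false(rep2$interrupted)
  expect_true(intersect_lesion(sm, half, coverage_threshold = 0.3)$interrupted)
  for (t in c(0.25, 0.5, 1)) {
    expect_true(intersect_lesion(sm, slab, coverage_threshold = t)$interrupted)
  }

  expect_error(intersect_lesion(streamline_mask(array(FALSE, dim(g))), slab),
               "empty streamline")
})

test_that("phantom lesions interrupt on-path and spare off-path", {
  spec <- small_arc_spec()
  occ <- simulate_phantom(spec, small_scheme(12))$truth$bundles$arc$mask
  sm <- streamline_mask(occ)
  expect_true(intersect_lesion(sm, make_lesion(spec, "arc", TRUE))$interrupted)
  expect_false(intersect_lesion(sm,
                                make_lesion(spec, "arc", FALSE))$interrupted)
})

test_that("dilating a lesion never rescinds an interruption", {
  set.seed(14)
  for (rep in 1:20) {
    ctrl <- cbind(runif(3, 4, 16), c(3, 10, 17), runif(3, 4, 16))
    spec <- phantom_spec(grid_shape = c(20, 20, 20),
                         bundles = list(bundle_spec("b", ctrl,
                                                    radius = 1.5)))
    occ <- phantom_occupancy(spec, "b")
    sm <- streamline_mask(occ)
    les <- make_lesion(spec, "b", on_path = TRUE)
    expect_true(intersect_lesion(sm, les)$interrupted)
    grown <- dilate3(les$grid)
    expect_true(intersect_lesion(sm, grown)$interrupted)
  }
})
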