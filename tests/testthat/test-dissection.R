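fake_vmap <- function(counts, voxel_size = c(1, 1, 1)) {
  structure(list(counts = counts, n_seed_samples = sum(counts),
                 n_retained = max(counts), voxel_size = voxel_size,
                 config = tracker_config()),
            class = "visitation_map")
}

test_that("threshold keeps exactly the at-least-10%-of-maximum voxels", {
  counts <- array(0L, c(4, 1, 1))
  counts[1:4] <- c(100L, 10L, 9L, 0L)
  kept <- threshold_map(fake_vmap(counts), 0.10)$grid
  expect_equal(as.logical(kept), c(TRUE, TRUE, FALSE, FALSE))

  # fraction 1: only the argmax survives
  expect_equal(which(threshold_map(fake_vmap(counts), 1)$grid), 1L)

  # uniform map: every voxel ties the maximum
  u <- array(7L, c(3, 2, 2))
  expect_true(all(threshold_map(fake_vmap(u), 0.999)$grid))

  zero <- array(0L, c(2, 2, 2))
  expect_error(threshold_map(fake_vmap(zero)), "empty tractogram")

  # monotone in the fraction
  counts2 <- array(sample(0:50, 60, replace = TRUE), c(5, 4, 3))
  m1 <- threshold_map(fake_vmap(counts2), 0.1)$grid
  m2 <- threshold_map(fake_vmap(counts2), 0.4)$grid
  expect_true(all(!m2 | m1))
})

test_that("bidirectional overlap is the sum-equals-two rule", {
  c1 <- array(0L, c(6, 3, 1)); c1[1:4, , 1] <- 5L
  c2 <- array(0L, c(6, 3, 1)); c2[3:6, , 1] <- 2L
  ra <- array(FALSE, c(6, 3, 1)); ra[3, 1, 1] <- TRUE
  rb <- array(FALSE, c(6, 3, 1)); rb[4, 3, 1] <- TRUE
  ov <- overlap_bidirectional(fake_vmap(c1), fake_vmap(c2),
                              roi_mask(ra, "seed"), roi_mask(rb, "seed"))
  expect_equal(which(apply(ov$mask$grid, 1, any)), 3:4)
  expect_true(ov$continuous)

  # idempotence: overlap of a map with itself is its binarisation
  ov2 <- overlap_bidirectional(fake_vmap(c1), fake_vmap(c1),
                               roi_mask(ra, "seed"), roi_mask(rb, "seed"))
  expect_equal(ov2$mask$grid, c1 > 0)

  # disjoint maps: empty overlap, not continuous
  c3 <- array(0L, c(6, 3, 1)); c3[6, 3, 1] <- 1L
  c4 <- array(0L, c(6, 3, 1)); c4[1, 1, 1] <- 1L
  ov3 <- overlap_bidirectional(fake_vmap(c3), fake_vmap(c4),
                               roi_mask(ra, "seed"), roi_mask(rb, "seed"))
  expect_equal(sum(ov3$mask$grid), 0)
  expect_false(ov3$continuous)

  expect_error(
    overlap_bidirectional(fake_vmap(c1), fake_vmap(array(0L, c(2, 2, 2))),
                          roi_mask(ra, "seed"), roi_mask(rb, "seed")),
    "grid mismatch")
})

test_that("continuity uses 26-connectivity, against a brute-force oracle", {
  # diagonal chain: connected under 26-connectivity only
  m <- array(FALSE, c(4, 4, 4))
  for (i in 1:4) m[i, i, i] <- TRUE
  lab <- label_components(m)
  expect_equal(max(lab), 1)

  # independent oracle: repeated neighbourhood expansion in plain R
  flood <- function(mask) {
    comp <- array(FALSE, dim(mask))
    comp[which(mask)[1]] <- TRUE
    repeat {
      grown <- dilate3(comp) & mask
      if (identical(grown, comp)) return(comp)
      comp <- grown
    }
  }
  set.seed(2)
  for (rep in 1:5) {
    m <- array(runif(5 * 5 * 5) < 0.3, c(5, 5, 5))
    if (!any(m)) next
    lab <- label_components(m)
    first <- lab == lab[which(m)[1]]
    expect_identical(first & m, flood(m))
  }
})

test_that("composite implements at-least-N-of-M participant rules", {
  base <- array(FALSE, c(5, 2, 2))
  base[1:3, , ] <- TRUE
  identical12 <- replicate(12, streamline_mask(base), simplify = FALSE)
  expect_equal(composite(identical12, 0.75)$grid, base)

  # a voxel present in exactly 9 of 12 is kept at both 75% and 8/12;
  # one present in 7 is dropped at 8/12
  masks <- lapply(1:12, function(j) {
    g <- array(FALSE, c(3, 1, 1))
    g[1, 1, 1] <- j <= 9
    g[2, 1, 1] <- j <= 7
    g[3, 1, 1] <- TRUE
    streamline_mask(g)
  })
  at75 <- composite(masks, 0.75)$grid
  at8of12 <- composite(masks, 8 / 12)$grid
  expect_true(at75[1, 1, 1]);  expect_true(at8of12[1, 1, 1])
  expect_false(at75[2, 1, 1]); expect_false(at8of12[2, 1, 1])
  expect_true(at75[3, 1, 1])

  # single subject: identity at any fraction
  expect_equal(composite(masks[1], 0.3)$grid, masks[[1]]$grid)

  # monotone in min_fraction
  set.seed(3)
  rnd <- replicate(6, streamline_mask(array(runif(27) < 0.5, c(3, 3, 3))),
                   simplify = FALSE)
  lo <- composite(rnd, 0.3)$grid
  hi <- composite(rnd, 0.9)$grid
  expect_true(all(!hi | lo))

  expect_error(composite(list(streamline_mask(base),
                              streamline_mask(array(FALSE, c(2, 2, 2))))),
               "grid mismatch")
})

test_that("the full dissection protocol runs on the ground-truth field", {
  sim <- simulate_phantom(sc_amygdala_phantom(two_bundle = TRUE),
                          small_scheme(12))
  tr <- sim$truth
  field <- gt_orientation_field(tr)
  cfg <- tracker_config(samples_per_seed_voxel = 60, rng_seed = 7)
  dr <- dissect_pathway(field, tr$rois, config = cfg, bidirectional = TRUE)
  main <- tr$bundles$sc_amygdala$mask

  expect_s3_class(dr, "dissection_result")
  expect_true(dr$stria_excluded)
  expect_gte(dice_coefficient(dr$sc_amygdala_raw, main), 0.5)
  expect_true(dr$continuous)
  # exclusion soundness: the cleaned map is voxelwise <= the raw map
  expect_true(all(dr$maps$main_excl$counts <= dr$maps$main_raw$counts))

  # omitting the pulvinar waypoint has little effect on the topography
  dr2 <- dissect_pathway(field, tr$rois, config = cfg,
                         use_pulvinar_waypoint = FALSE)
  expect_gte(dice_coefficient(dr$sc_amygdala_raw, dr2$sc_amygdala_raw), 0.8)

  expect_error(dissect_pathway(field, tr$rois[c("sc", "pulvinar")]),
               "missing masks")
})

test_that("a pathway-free phantom skips the exclusion step with a warning", {
  sim <- simulate_phantom(sc_amygdala_phantom(two_bundle = FALSE),
                          small_scheme(12))
  field <- gt_orientation_field(sim$truth)
  expect_warning(
    dr <- dissect_pathway(field, sim$truth$rois,
                          config = tracker_config(samples_per_seed_voxel = 40,
                                                  rng_seed = 2)),
    "exclusion step skipped")
  expect_false(dr$stria_excluded)
  expect_null(dr$maps$main_excl)
})
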