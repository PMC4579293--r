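test_that("a uniform field yields a straight line to the boundary", {
  f <- orientation_field(c(0, 1, 0), dim = c(9, 30, 9))
  p <- propagate_one(f, start = c(4, 14, 4), config = tracker_config())
  expect_identical(p$reason, "exited")
  expect_equal(sd(p$points[, 1]), 0)
  expect_equal(sd(p$points[, 3]), 0)
  expect_gt(max(p$points[, 2]), 28)
  expect_error(propagate_one(f, start = c(50, 0, 0)), "outside")
})

test_that("orientation interfaces enforce the curvature threshold", {
  dim3 <- c(11, 21, 11)
  v90 <- array(0, c(3, dim3))
  v90[2, , 1:10, ] <- 1    # +y posterior half
  v90[1, , 11:21, ] <- 1   # +x anterior half: 90 degrees, cos 0 < 0.2
  p90 <- propagate_one(orientation_field(v90), c(5, 2, 5),
                       tracker_config(rng_seed = 4))
  expect_identical(p90$reason, "curvature")
  expect_lt(max(p90$points[, 2]), 10.6)  # stopped at the interface

  v60 <- array(0, c(3, dim3))
  v60[2, , 1:10, ] <- 1
  v60[1, , 11:21, ] <- sin(pi / 3)  # 60 degrees, cos 0.5 >= 0.2
  v60[2, , 11:21, ] <- cos(pi / 3)
  p60 <- propagate_one(orientation_field(v60), c(5, 2, 5),
                       tracker_config(rng_seed = 4))
  expect_identical(p60$reason, "exited")
  expect_gt(max(p60$points[, 2]), 11)   # crossed the interface
})

sim_gt <- simulate_phantom(small_arc_spec(), small_scheme(12))
field_gt <- gt_orientation_field(sim_gt$truth)
rois <- sim_gt$truth$rois

test_that("streamlines follow a curved bundle end to end", {
  seed1 <- array(FALSE, field_gt$dim)
  seed1[7, 5, 7] <- TRUE
  vm <- track(field_gt, roi_mask(seed1, "seed"),
              waypoints = list(rois$c),
              config = tracker_config(samples_per_seed_voxel = 100,
                                      rng_seed = 3))
  expect_gte(vm$n_retained / 100, 0.95)
})

test_that("mask roles behave as the dissection protocol requires", {
  cfg <- tracker_config(samples_per_seed_voxel = 30, rng_seed = 5)
  all_excl <- roi_mask(array(TRUE, field_gt$dim), "exclusion")
  vm <- track(field_gt, rois$a, exclusions = list(all_excl), config = cfg)
  expect_equal(vm$n_retained, 0)
  expect_equal(max(vm$counts), 0)

  far <- array(FALSE, field_gt$dim)
  far[1, 35, 24] <- TRUE
  vm2 <- track(field_gt, rois$a, waypoints = list(roi_mask(far, "waypoint")),
               config = cfg)
  expect_equal(max(vm2$counts), 0)

  empty <- roi_mask(array(FALSE, field_gt$dim), "seed")
  expect_error(track(field_gt, empty), "empty seed")
  expect_error(
    track(field_gt, rois$a, waypoints = list(rois$mid),
          exclusions = list(rois$mid), config = cfg),
    "contradictory mask roles")
})

test_that("count bookkeeping and mask monotonicity hold", {
  cfg <- tracker_config(samples_per_seed_voxel = 50, rng_seed = 6)
  vm <- track(field_gt, rois$a, waypoints = list(rois$mid),
              termination = rois$c, config = cfg)
  expect_lte(max(vm$counts), vm$n_retained)
  expect_gte(sum(vm$counts), vm$n_retained)
  expect_equal(vm$n_seed_samples, 50 * sum(rois$a$grid))

  # same seed, extra exclusion: counts can only drop
  block <- array(FALSE, field_gt$dim)
  block[12:14, 15:20, ] <- TRUE
  vm_excl <- track(field_gt, rois$a, waypoints = list(rois$mid),
                   termination = rois$c,
                   exclusions = list(roi_mask(block, "exclusion")),
                   config = cfg)
  expect_true(all(vm_excl$counts <= vm$counts))

  # adding a waypoint can only drop counts too
  vm_nowp <- track(field_gt, rois$a, termination = rois$c, config = cfg)
  expect_true(all(vm$counts <= vm_nowp$counts))

  # determinism
  vm_b <- track(field_gt, rois$a, waypoints = list(rois$mid),
                termination = rois$c, config = cfg)
  expect_identical(vm$counts, vm_b$counts)
})

test_that("reversing seed and termination preserves the topography", {
  cfg <- tracker_config(samples_per_seed_voxel = 200, rng_seed = 5)
  m_ac <- track(field_gt, rois$a, waypoints = list(rois$mid),
                termination = rois$c, config = cfg)
  m_ca <- track(field_gt, set_role(rois$c, "seed"),
                waypoints = list(rois$mid),
                termination = set_role(rois$a, "termination"), config = cfg)
  expect_gte(dice_coefficient(threshold_map(m_ac, 0.1),
                              threshold_map(m_ca, 0.1)), 0.5)
})
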