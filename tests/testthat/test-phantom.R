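test_that("noiseless forward model: b0, voids and stick anisotropy", {
  sch <- small_scheme()
  spec <- sc_amygdala_phantom(two_bundle = FALSE)
  sim <- simulate_phantom(spec, sch)
  b0 <- sim$dwv$data[, , , which(sch$bvals == 0)[1]]
  expect_true(all(b0[sim$truth$void] == 0))
  expect_true(all(abs(b0[!sim$truth$void] - 100) < 1e-9))

  # inside the bundle, signal along the tangent is attenuated more than
  # signal across it
  tr <- sim$truth$bundles$sc_amygdala
  vox <- which(tr$mask, arr.ind = TRUE)[50, ]
  tg <- matrix(tr$tangent, 3, prod(dim(tr$mask)))[,
    (vox[3] - 1) * prod(dim(tr$mask)[1:2]) +
      (vox[2] - 1) * dim(tr$mask)[1] + vox[1]]
  dw <- which(sch$bvals > 0)
  align <- abs(sch$bvecs[dw, ] %*% tg)
  sig <- sim$dwv$data[vox[1], vox[2], vox[3], dw]
  expect_lt(sig[which.max(align)], sig[which.min(align)])

  # isotropic voxels: identical signal across same-b volumes
  bg <- which(!sim$truth$void &
                !Reduce(`|`, lapply(sim$truth$bundles, `[[`, "mask")))[1]
  flat <- matrix(sim$dwv$data, prod(spec$grid_shape),
                 sch$n_volumes)[bg, dw]
  expect_lt(diff(range(flat)), 1e-10)
})

test_that("Rician noise matches the analytic moments at SNR 20", {
  sch <- small_scheme()
  sim <- simulate_phantom(sc_amygdala_phantom(two_bundle = FALSE, snr = 20,
                                              rng_seed = 3), sch)
  bundles <- Reduce(`|`, lapply(sim$truth$bundles, `[[`, "mask"))
  bg <- sim$truth$brain_mask & !bundles
  b0 <- sim$dwv$data[, , , 1][bg]
  expect_gt(length(b0), 10000)
  expect_gte(mean(b0) / 100, 1.0)   # Rice mean exceeds the clean signal
  expect_lte(mean(b0) / 100, 1.01)
  expect_gte(sd(b0) / 100, 0.045)
  expect_lte(sd(b0) / 100, 0.055)
})

test_that("phantoms are bit-reproducible and validate their geometry", {
  sch <- small_scheme()
  a <- simulate_phantom(small_arc_spec(snr = 15, rng_seed = 9), sch)
  b <- simulate_phantom(small_arc_spec(snr = 15, rng_seed = 9), sch)
  expect_identical(a$dwv$data, b$dwv$data)
  expect_identical(a$truth$bundles$arc$mask, b$truth$bundles$arc$mask)
  cc <- simulate_phantom(small_arc_spec(snr = 15, rng_seed = 10), sch)
  expect_false(identical(a$dwv$data, cc$dwv$data))

  expect_error(
    phantom_spec(grid_shape = c(10, 10, 10),
                 bundles = list(bundle_spec("runaway",
                                            rbind(c(0, 0, 0), c(30, 0, 0)),
                                            radius = 2))),
    "runaway")
  bad <- small_arc_spec()
  bad$voids <- list(list(type = "sphere", center = c(6, 4, 6), radius = 3))
  expect_error(simulate_phantom(bad, sch), "overlaps a void")
})

test_that("two-bundle phantom realises the crossing confound", {
  sch <- small_scheme()
  tr <- simulate_phantom(sc_amygdala_phantom(two_bundle = TRUE), sch)$truth
  main <- tr$bundles$sc_amygdala$mask
  st <- tr$bundles$stria$mask
  expect_gt(sum(main & st), 0)        # shared voxels exist
  expect_gt(sum(st & !main), 0)       # and so does stria-only territory
  # the two attachments sit at well-separated poles of the amygdala
  amyg <- tr$rois$amygdala$grid
  pole <- function(m) colMeans(which(m & amyg, arr.ind = TRUE))
  expect_gt(sqrt(sum((pole(main) - pole(st))^2)), 3)
})

test_that("lesions are placed on or off the bundle path as requested", {
  spec <- sc_amygdala_phantom(two_bundle = FALSE)
  sch <- small_scheme()
  occ <- simulate_phantom(spec, sch)$truth$bundles$sc_amygdala$mask

  on <- make_lesion(spec, "sc_amygdala", on_path = TRUE)
  covered <- vapply(seq_len(dim(occ)[2]), function(y) {
    n <- sum(occ[, y, ])
    n > 0 && all(on$grid[, y, ][occ[, y, ]])
  }, TRUE)
  expect_true(any(covered))  # a slice where the lesion spans the bundle

  off <- make_lesion(spec, "sc_amygdala", on_path = FALSE)
  expect_equal(sum(off$grid & occ), 0)
  expect_error(make_lesion(spec, "nonesuch"), "no bundle named")
})
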