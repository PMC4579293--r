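sch60 <- make_scheme(60, 1000, n_b0 = 11, rng_seed = 2)

test_that("noiseless single-stick voxels are recovered almost exactly", {
  set.seed(4)
  for (i in 1:3) {
    v0 <- rnorm(3); v0 <- v0 / sqrt(sum(v0^2))
    ft <- fit_voxel(bs_signal(sch60, v0, f = 0.7), sch60, K = 10,
                    rng_seed = i)
    ang <- acos(min(1, abs(sum(ft$v_hat * v0)))) * 180 / pi
    expect_lt(ang, 1)
    expect_lt(abs(ft$f_hat - 0.7), 0.01)
    expect_lt(abs(ft$d - 1.2e-3) / 1.2e-3, 0.01)
  }
})

test_that("isotropic voxels leave the orientation unidentified", {
  sig <- 100 * exp(-sch60$bvals * 1.2e-3)  # f = 0
  ft <- fit_voxel(sig, sch60, K = 200, rng_seed = 7)
  sv <- ft$v_samples
  sgn <- sign(colSums(sv * sv[, 1])); sgn[sgn == 0] <- 1
  resultant <- sqrt(sum(rowMeans(sweep(sv, 2, sgn, "*"))^2))
  # a diffuse orientation posterior: sign-aligned draws from a uniform
  # sphere have resultant ~0.5, against ~1 for an identified stick
  expect_lt(resultant, 0.7)
  aniso <- fit_voxel(bs_signal(sch60, c(0, 0, 1), f = 0.7), sch60, K = 200,
                     rng_seed = 7)
  sv2 <- aniso$v_samples
  sgn2 <- sign(colSums(sv2 * sv2[, 1])); sgn2[sgn2 == 0] <- 1
  expect_gt(sqrt(sum(rowMeans(sweep(sv2, 2, sgn2, "*"))^2)), 0.99)
})

test_that("all-zero signal is flagged background, bad input errors", {
  expect_true(fit_voxel(rep(0, sch60$n_volumes), sch60, K = 5)$background)
  expect_error(fit_voxel(rep(1, 5), sch60), "does not match")
  expect_error(fit_voxel(rep(-1, sch60$n_volumes), sch60), "non-negative")
})

test_that("posterior spread shrinks with SNR", {
  disp <- function(snr) {
    set.seed(11)
    mean(vapply(1:25, function(i) {
      v0 <- rnorm(3); v0 <- v0 / sqrt(sum(v0^2))
      noisy <- rician(bs_signal(sch60, v0), 100 / snr)
      ft <- fit_voxel(noisy, sch60, K = 50, rng_seed = i)
      sv <- ft$v_samples
      sgn <- sign(colSums(sv * sv[, 1])); sgn[sgn == 0] <- 1
      1 - sqrt(sum(rowMeans(sweep(sv, 2, sgn, "*"))^2))
    }, 0))
  }
  expect_lt(disp(40), disp(10))
})

test_that("volume fits are deterministic, mask-aware and accurate", {
  sim <- simulate_phantom(small_arc_spec(snr = 30, rng_seed = 8), sch60)
  occ <- sim$truth$bundles$arc$mask

  empty <- fit_ball_stick(sim$dwv, array(FALSE, dim(occ)), K = 5)
  expect_length(empty$voxels, 0)

  f1 <- fit_ball_stick(sim$dwv, occ, K = 10, rng_seed = 4)
  f2 <- fit_ball_stick(sim$dwv, occ, K = 10, rng_seed = 4)
  expect_identical(f1$v_samples, f2$v_samples)
  expect_identical(f1$f_samples, f2$f_samples)

  tg <- matrix(sim$truth$bundles$arc$tangent, 3, prod(f1$dim))[, f1$voxels]
  mo <- mean_orientation(f1)
  ang <- acos(pmin(1, abs(colSums(tg * mo$mean_v)))) * 180 / pi
  expect_lte(median(ang), 10)

  expect_error(fit_ball_stick(sim$dwv, array(TRUE, c(2, 2, 2))),
               "grid mismatch")
})

test_that("the fitted model predicts the signal it was fit to", {
  sim <- simulate_phantom(small_arc_spec(), small_scheme(12))
  occ <- sim$truth$bundles$arc$mask
  fit <- fit_ball_stick(sim$dwv, occ, K = 5, rng_seed = 1)
  vox <- fit$voxels[7]
  pred <- predict(fit, sim$dwv$scheme, voxels = vox)
  obs <- matrix(sim$dwv$data, prod(fit$dim), ncol = 13)[vox, ]
  expect_equal(as.numeric(pred), obs, tolerance = 1e-4)
  expect_equal(colnames(coef(fit))[1:4], c("voxel", "S0", "d", "f"))
})
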