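test_that("per-slice CoG equals hand-computed centroids", {
  g <- array(FALSE, c(9, 4, 9))
  g[3, 2, 5] <- TRUE                     # single voxel
  g[c(2, 6), 3, 4] <- TRUE               # symmetric pair in x
  m <- streamline_mask(g, voxel_size = c(2, 2, 2))
  p <- cog_profile(m, slices = 2:3)
  expect_equal(p$x_mm[1], (3 - 1) * 2)
  expect_equal(p$z_mm[1], (5 - 1) * 2)
  expect_equal(p$x_mm[2], (4 - 1) * 2)   # midpoint of voxels 2 and 6
  expect_error(cog_profile(m, slices = 1:3), "slice 1")
})

test_that("cylinder CoG tracks the analytic centerline and translation", {
  g <- cylinder_mask(c(15, 10, 15), x0 = 7, z0 = 9, radius = 2)
  m <- streamline_mask(g, voxel_size = c(1, 1, 1))
  p <- cog_profile(m, slices = 1:10)
  expect_true(all(abs(p$x_mm - 6) < 0.5))   # centerline x = (7-1)*1 mm
  expect_true(all(abs(p$z_mm - 8) < 0.5))

  # translation equivariance is exact
  g2 <- array(FALSE, dim(g))
  g2[, , 2:15] <- g[, , 1:14]  # shift +1 voxel in z
  p2 <- cog_profile(streamline_mask(g2), slices = 1:10)
  expect_equal(p2$z_mm, p$z_mm + 1)
  expect_equal(p2$x_mm, p$x_mm)

  # weighted centroid responds to the weights
  w <- array(0, dim(g)); w[g] <- 1; w[9:15, , ] <- w[9:15, , ] * 9
  pw <- cog_profile(m, slices = 1:10, weights = w)
  expect_true(all(pw$x_mm > p$x_mm))
})

test_that("CoG of a phantom bundle matches its analytic centerline", {
  sim <- simulate_phantom(small_arc_spec(), small_scheme(12))
  tr <- sim$truth$bundles$arc
  sl <- 10:24
  p <- cog_profile(streamline_mask(tr$mask), slices = sl)
  truth <- tr$per_slice[match(sl, tr$per_slice$slice), ]
  expect_true(all(abs(p$x_mm - truth$x_mm) < 0.5))
  expect_true(all(abs(p$z_mm - truth$z_mm) < 0.5))
})

test_that("variability tables reproduce closed-form SDs", {
  p0 <- sim_profiles(2, noise = 0)
  p0[[2]]$x_mm <- p0[[2]]$x_mm + 2       # exactly 2 mm apart
  vt <- variability_table(p0)
  expect_equal(vt$sd_x, rep(sqrt(2), 8))  # sd of {a, a+2} is sqrt(2)
  expect_equal(vt$sd_z, rep(0, 8))

  ident <- sim_profiles(5, noise = 0)
  expect_true(all(variability_table(ident)$sd_x == 0))
  expect_error(variability_table(ident[1]), "at least 2")

  set.seed(21)
  p12 <- sim_profiles(12, noise = 1)
  vt12 <- variability_table(p12)
  expect_gte(attr(vt12, "summary")["Mean", "sd_x"], 0.7)
  expect_lte(attr(vt12, "summary")["Mean", "sd_x"], 1.3)

  # permutation invariance in subject order
  vt_perm <- variability_table(p12[sample(12)])
  expect_equal(vt_perm$sd_x, vt12$sd_x)

  # voxel units divide by the voxel size
  vt_vox <- variability_table(p12, units = "voxels")
  expect_equal(vt_vox$sd_x, vt12$sd_x)  # 1 mm voxels here
})

test_that("offset comparison handles identity and pure shifts", {
  set.seed(5)
  a <- sim_profiles(6, noise = 1)
  same <- compare_offsets(a, a, "x")
  expect_equal(same$mean_offset, 0)
  expect_equal(same$F, 0)

  b <- lapply(a, function(p) { p$x_mm <- p$x_mm + 3; p })
  sh <- compare_offsets(a, b, "x")
  expect_equal(sh$mean_offset, -3)
  expect_true(sh$degenerate)        # zero interaction variance
  expect_identical(sh$F, Inf)

  expect_error(compare_offsets(a, a[1:3], "x"), "subject sets differ")
  bad <- a; bad[[2]]$slice <- bad[[2]]$slice + 1
  expect_error(compare_offsets(bad, a, "x"), "common slice")
})

test_that("the streamline-effect F agrees with a brute-force oracle", {
  # independent oracle: explicit sums of squares for the two-factor layout
  brute_F <- function(pa, pb, col) {
    val <- function(ps) t(vapply(ps, function(p) p[[col]],
                                 numeric(nrow(pa[[1]]))))
    A <- val(pa); B <- val(pb)            # subjects x slices
    n_s <- nrow(A); n_l <- ncol(A)
    grand <- mean(c(A, B))
    m_stream <- c(mean(A), mean(B))
    m_subj <- (rowMeans(A) + rowMeans(B)) / 2
    cell <- cbind(rowMeans(A), rowMeans(B))  # subject x stream means
    ss_stream <- n_s * n_l * sum((m_stream - grand)^2)
    ss_inter <- n_l * sum((cell - outer(m_subj, rep(1, 2)) -
                             outer(rep(1, n_s), m_stream) + grand)^2)
    (ss_stream / 1) / (ss_inter / (n_s - 1))
  }
  set.seed(9)
  for (rep in 1:4) {
    n_sub <- sample(3:5, 1); n_sl <- sample(2:4, 1)
    pa <- sim_profiles(n_sub, slices = seq_len(n_sl), noise = 1)
    pb <- sim_profiles(n_sub, slices = seq_len(n_sl), offset = 2, noise = 1)
    oc <- compare_offsets(pa, pb, "x")
    expect_equal(oc$F, brute_F(pa, pb, "x_mm"), tolerance = 1e-8)
    expect_equal(oc$df, c(1, n_sub - 1))
  }
})
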