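# Shared fixtures, all generated in code.

# Small curved-bundle phantom: an arc through three ROI spheres on a
# 24 x 36 x 24 grid. Cheap enough for per-test simulation.
small_arc_spec <- function(snr = Inf, rng_seed = 1, two_roi_radius = 2.5) {
  phantom_spec(
    grid_shape = c(24, 36, 24), voxel_size = c(1, 1, 1),
    bundles = list(bundle_spec(
      "arc", rbind(c(6, 4, 6), c(10, 12, 12), c(16, 22, 14), c(18, 30, 10)),
      radius = 2)),
    rois = list(
      a = list(center = c(6, 4, 6), radius = two_roi_radius, role = "seed"),
      mid = list(center = c(16, 22, 14), radius = two_roi_radius,
                 role = "waypoint"),
      c = list(center = c(18, 30, 10), radius = two_roi_radius,
               role = "termination")),
    snr = snr, rng_seed = rng_seed)
}

small_scheme <- function(n_dir = 12, bval = 1000, n_b0 = 1, seed = 1) {
  make_scheme(n_dir, bval, n_b0 = n_b0, rng_seed = seed)
}

# straight cylinder mask of given radius around x = x0, z = z0 (voxel idx)
cylinder_mask <- function(dim3, x0, z0, radius) {
  g <- array(FALSE, dim3)
  for (i in seq_len(dim3[1])) for (k in seq_len(dim3[3])) {
    if ((i - x0)^2 + (k - z0)^2 <= radius^2) g[i, , k] <- TRUE
  }
  g
}

# 3^3 binary dilation, base R
dilate3 <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    xs <- pmin(pmax(seq_len(d[1]) + dx, 1), d[1])
    ys <- pmin(pmax(seq_len(d[2]) + dy, 1), d[2])
    zs <- pmin(pmax(seq_len(d[3]) + dz, 1), d[3])
    out <- out | mask[xs, ys, zs]
  }
  out
}

# simulated centre-of-gravity profiles for n subjects: truth + N(0, noise)
sim_profiles <- function(n_subjects = 12, slices = 1:8, x0 = 10, z0 = 5,
                         offset = 0, noise = 1) {
  lapply(seq_len(n_subjects), function(j) {
    df <- data.frame(slice = slices,
                     x_mm = x0 + offset + rnorm(length(slices), sd = noise),
                     z_mm = z0 + rnorm(length(slices), sd = noise))
    structure(df, class = c("cog_profile", "data.frame"),
              voxel_size = c(1, 1, 1), subject = j, hemisphere = "L",
              label = "sim")
  })
}

# add Rician noise to a clean signal vector
rician <- function(sig, sigma) {
  sqrt((sig + rnorm(length(sig), sd = sigma))^2 +
         rnorm(length(sig), sd = sigma)^2)
}

# clean ball-and-stick signal for one voxel
bs_signal <- function(scheme, v, f = 0.6, d = 1.2e-3, S0 = 100) {
  gv <- scheme$bvecs %*% v
  S0 * ((1 - f) * exp(-scheme$bvals * d) +
          f * exp(-scheme$bvals * d * gv^2))
}
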