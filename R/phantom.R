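#' Specify a fiber bundle for the phantom
#'
#' A bundle is a tube of constant radius around a smooth centerline
#' (Catmull-Rom spline through the control points). Within the tube the
#' diffusion signal follows a ball-and-stick forward model with anisotropic
#' fraction `f` and diffusivity `d`, the stick oriented along the local
#' centerline tangent.
#'
#' @param name bundle label (used in error messages and ground truth).
#' @param centerline numeric matrix (>= 2 rows x 3 columns) of control
#'   points in world mm.
#' @param radius tube radius in mm.
#' @param f anisotropic (stick) volume fraction in `[0, 1]`.
#' @param d diffusivity in mm^2/s.
#' @return An object of class `bundle_spec`.
#' @export
bundle_spec <- function(name, centerline, radius = 2.5, f = 0.7,
                        d = 1.2e-3) {
  centerline <- as.matrix(centerline)
  stopifnot(nrow(centerline) >= 2, ncol(centerline) == 3,
            radius > 0, f >= 0, f <= 1, d > 0)
  structure(list(name = name, centerline = centerline, radius = radius,
                 f = f, d = d),
            class = "bundle_spec")
}

#' Specify a synthetic diffusion phantom
#'
#' Collects the geometry of a phantom: grid, bundles, signal-void cavities
#' (e.g. a ventricle's temporal horn, where the MR signal is essentially
#' absent), named ROI placements with tracking roles, lesion cavities, and
#' the noise level.
#'
#' @param grid_shape integer vector of 3 positive extents.
#' @param voxel_size voxel edge lengths in mm.
#' @param bundles list of [bundle_spec()] objects.
#' @param voids list of cavity shapes; each element is a list with `type`
#'   (`"ellipsoid"` or `"box"`), `center` (mm) and `semiaxes`/`halfwidth`.
#' @param rois named list of ROI placements; each element a list with
#'   `center`, `radius` and `role`.
#' @param lesions named list of lesion placements (same shape grammar as
#'   `voids`).
#' @param snr b = 0 signal-to-noise ratio; `Inf` disables noise.
#' @param S0 non-diffusion-weighted signal amplitude.
#' @param d_background diffusivity of isotropic background tissue (mm^2/s).
#' @param rng_seed integer seed controlling the Rician noise draw.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(40, 60, 40), voxel_size = c(1, 1, 1),
                         bundles = list(), voids = list(), rois = list(),
                         lesions = list(), snr = Inf, S0 = 100,
                         d_background = 1.2e-3, rng_seed = 1) {
  grid_shape <- as.integer(grid_shape)
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  stopifnot(length(grid_shape) == 3, all(grid_shape > 0),
            all(voxel_size > 0), snr > 0, S0 > 0, d_background > 0)
  spec <- structure(list(grid_shape = grid_shape, voxel_size = voxel_size,
                         bundles = bundles, voids = voids, rois = rois,
                         lesions = lesions, snr = snr, S0 = S0,
                         d_background = d_background,
                         rng_seed = as.integer(rng_seed)),
                    class = "phantom_spec")
  world_max <- (grid_shape - 1) * voxel_size
  for (b in bundles) {
    if (!inherits(b, "bundle_spec")) stop("bundles must be bundle_spec")
    reach_lo <- apply(b$centerline, 2, min) - b$radius
    reach_hi <- apply(b$centerline, 2, max) + b$radius
    if (any(reach_lo < -voxel_size / 2) ||
        any(reach_hi > world_max + voxel_size / 2)) {
      stop(sprintf("bundle '%s' leaves the phantom grid", b$name),
           call. = FALSE)
    }
  }
  for (nm in names(rois)) {
    r <- rois[[nm]]
    if (any(r$center < 0) || any(r$center > world_max)) {
      stop(sprintf("ROI '%s' placed outside the grid", nm), call. = FALSE)
    }
  }
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("Diffusion phantom spec: %s grid at %s mm, S0 = %g, SNR = %s\n",
              paste(x$grid_shape, collapse = "x"),
              paste(x$voxel_size, collapse = "x"), x$S0,
              format(x$snr)))
  cat(sprintf("  %d bundle(s): %s\n", length(x$bundles),
              paste(vapply(x$bundles, `[[`, "", "name"), collapse = ", ")))
  cat(sprintf("  %d void(s), %d ROI(s), %d lesion(s)\n",
              length(x$voids), length(x$rois), length(x$lesions)))
  invisible(x)
}

# Catmull-Rom spline through control points, sampled at ~`spacing` mm,
# with unit tangents from centered finite differences.
interpolate_centerline <- function(ctrl, spacing = 0.25) {
  n <- nrow(ctrl)
  ext <- rbind(2 * ctrl[1, ] - ctrl[2, ], ctrl, 2 * ctrl[n, ] - ctrl[n - 1, ])
  pts <- list()
  for (i in seq_len(n - 1)) {
    p0 <- ext[i, ]; p1 <- ext[i + 1, ]; p2 <- ext[i + 2, ]; p3 <- ext[i + 3, ]
    seg_len <- sqrt(sum((p2 - p1)^2))
    m <- max(2L, ceiling(seg_len / spacing))
    t <- seq(0, 1, length.out = m + 1)
    if (i < n - 1) t <- t[-length(t)]
    t2 <- t^2; t3 <- t^3
    # standard Catmull-Rom basis
    seg <- 0.5 * (cbind(2 * t3 - 3 * t2 + 1) %*% rbind(2 * p1) +
                  cbind(t3 - 2 * t2 + t) %*% rbind(p2 - p0) +
                  cbind(-2 * t3 + 3 * t2) %*% rbind(2 * p2) +
                  cbind(t3 - t2) %*% rbind(p3 - p1))
    pts[[i]] <- seg
  }
  pts <- do.call(rbind, pts)
  m <- nrow(pts)
  tang <- rbind(pts[2, ] - pts[1, ],
                pts[3:m, ] - pts[1:(m - 2), ],
                pts[m, ] - pts[m - 1, ])
  tang <- tang / pmax(sqrt(rowSums(tang^2)), 1e-12)
  list(points = pts, tangents = tang)
}

shape_grid <- function(shape, dim3, voxel_size) {
  if (identical(shape$type, "box")) {
    box_mask_grid(dim3, voxel_size, shape$center, shape$halfwidth)
  } else if (identical(shape$type, "ellipsoid")) {
    ellipsoid_mask_grid(dim3, voxel_size, shape$center, shape$semiaxes)
  } else if (identical(shape$type, "sphere")) {
    sphere_mask_grid(dim3, voxel_size, shape$center, shape$radius)
  } else {
    stop("unknown shape type: ", shape$type, call. = FALSE)
  }
}

# Voxelise every bundle: occupancy mask, per-voxel unit tangent, nearest
# centerline sample index, plus the dense analytic centerline.
phantom_geometry <- function(spec) {
  lapply(spec$bundles, function(b) {
    cl <- interpolate_centerline(b$centerline)
    occ <- cpp_tube_occupancy(spec$grid_shape, spec$voxel_size,
                              cl$points, cl$tangents, b$radius)
    list(name = b$name, f = b$f, d = b$d, radius = b$radius,
         mask = array(occ$mask, spec$grid_shape),
         tangent = occ$tangent,
         centerline = cl$points)
  })
}

# Analytic per-coronal-slice centerline (mean of dense centerline points
# falling inside each y slab), the oracle for CoG statistics.
per_slice_centerline <- function(points, voxel_size, n_slices) {
  hy <- voxel_size[2]
  slice <- round(points[, 2] / hy) + 1
  keep <- slice >= 1 & slice <= n_slices
  slice <- slice[keep]
  pts <- points[keep, , drop = FALSE]
  out <- do.call(rbind, lapply(sort(unique(slice)), function(s) {
    p <- pts[slice == s, , drop = FALSE]
    c(slice = s, x_mm = mean(p[, 1]), z_mm = mean(p[, 3]))
  }))
  as.data.frame(out)
}

#' Simulate a diffusion-weighted phantom
#'
#' Evaluates the ball-and-stick forward model on the phantom grid for every
#' volume of the acquisition scheme. Per voxel the noiseless signal is
#' `S(g, b) = S0 * ((1 - f) * exp(-b d) + f * exp(-b d (g . v)^2))` with `v`
#' the local bundle tangent; voxels outside all bundles are isotropic
#' (`f = 0`), voxels inside two bundles split the stick fraction equally
#' between the two tangents, and void cavities carry zero signal. With a
#' finite `snr`, Rician noise is applied: the magnitude of
#' `(S + e1, e2)` with `e ~ Normal(0, S0 / snr)`.
#'
#' @param spec a [phantom_spec()].
#' @param scheme an [make_scheme()] acquisition scheme.
#' @return A list with `dwv` (class `dw_volume`: 4D `data`, the `scheme`,
#'   `voxel_size`) and `truth` (class `phantom_truth`: per-bundle occupancy
#'   masks, tangent fields, analytic per-slice centerlines, named ROI and
#'   lesion masks and the brain mask).
#' @export
simulate_phantom <- function(spec, scheme) {
  validate_scheme(scheme)
  dim3 <- spec$grid_shape
  nvol <- scheme$n_volumes
  geoms <- phantom_geometry(spec)

  void <- array(FALSE, dim3)
  for (v in spec$voids) void <- void | shape_grid(v, dim3, spec$voxel_size)

  rois <- lapply(names(spec$rois), function(nm) {
    r <- spec$rois[[nm]]
    g <- sphere_mask_grid(dim3, spec$voxel_size, r$center, r$radius)
    if (any(g & void)) {
      stop(sprintf("ROI '%s' overlaps a void region", nm), call. = FALSE)
    }
    roi_mask(g, r$role, nm, spec$voxel_size)
  })
  names(rois) <- names(spec$rois)

  lesions <- lapply(names(spec$lesions), function(nm) {
    roi_mask(shape_grid(spec$lesions[[nm]], dim3, spec$voxel_size),
             "exclusion", nm, spec$voxel_size)
  })
  names(lesions) <- names(spec$lesions)

  # per-voxel tissue composition
  n_in <- array(0L, dim3)
  for (g in geoms) n_in <- n_in + g$mask
  if (any(n_in > 2)) {
    stop("more than two bundles overlap in one voxel; unsupported mixture",
         call. = FALSE)
  }

  nvox <- prod(dim3)
  signal <- matrix(0, nvox, nvol)
  b <- scheme$bvals
  gdir <- scheme$bvecs

  bg_idx <- which(!void & n_in == 0L)
  signal[bg_idx, ] <- rep(spec$S0 * exp(-b * spec$d_background),
                          each = length(bg_idx))

  one_idx <- which(n_in == 1L & !void)
  if (length(one_idx)) {
    for (g in geoms) {
      idx <- intersect(which(g$mask), one_idx)
      if (!length(idx)) next
      tg <- matrix(g$tangent, 3, nvox)[, idx, drop = FALSE]  # 3 x m
      gv <- gdir %*% tg                                      # nvol x m
      iso <- exp(-b * g$d)
      att <- (1 - g$f) * iso + g$f * exp(-(b * g$d) * gv^2)
      signal[idx, ] <- spec$S0 * t(att)
    }
  }

  two_idx <- which(n_in == 2L & !void)
  if (length(two_idx)) {
    pair <- utils::combn(length(geoms), 2)
    for (p in seq_len(ncol(pair))) {
      g1 <- geoms[[pair[1, p]]]; g2 <- geoms[[pair[2, p]]]
      idx <- intersect(which(g1$mask & g2$mask), two_idx)
      if (!length(idx)) next
      f <- mean(c(g1$f, g2$f)); d <- mean(c(g1$d, g2$d))
      t1 <- matrix(g1$tangent, 3, nvox)[, idx, drop = FALSE]
      t2 <- matrix(g2$tangent, 3, nvox)[, idx, drop = FALSE]
      gv1 <- gdir %*% t1; gv2 <- gdir %*% t2
      att <- (1 - f) * exp(-b * d) +
        (f / 2) * exp(-(b * d) * gv1^2) + (f / 2) * exp(-(b * d) * gv2^2)
      signal[idx, ] <- spec$S0 * t(att)
    }
  }

  signal[void, ] <- 0

  if (is.finite(spec$snr)) {
    sigma <- spec$S0 / spec$snr
    signal <- with_seed(spec$rng_seed, {
      e1 <- matrix(stats::rnorm(length(signal), sd = sigma), nrow(signal))
      e2 <- matrix(stats::rnorm(length(signal), sd = sigma), nrow(signal))
      sqrt((signal + e1)^2 + e2^2)
    })
  }

  dwv <- structure(list(data = array(signal, c(dim3, nvol)), scheme = scheme,
                        voxel_size = spec$voxel_size, S0 = spec$S0),
                   class = "dw_volume")
  truth <- structure(list(
    bundles = lapply(geoms, function(g) {
      list(name = g$name, mask = g$mask, tangent = g$tangent,
           centerline = g$centerline,
           per_slice = per_slice_centerline(g$centerline, spec$voxel_size,
                                            dim3[2]))
    }),
    rois = rois, lesions = lesions, void = void,
    brain_mask = !void,
    voxel_size = spec$voxel_size), class = "phantom_truth")
  names(truth$bundles) <- vapply(geoms, `[[`, "", "name")
  list(dwv = dwv, truth = truth)
}

#' @export
print.dw_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Diffusion-weighted volume: %dx%dx%d grid, %d volumes, %s mm\n",
              d[1], d[2], d[3], d[4], paste(x$voxel_size, collapse = "x")))
  invisible(x)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("Phantom ground truth:",
      length(x$bundles), "bundle(s),",
      length(x$rois), "ROI(s),",
      length(x$lesions), "lesion(s)\n")
  invisible(x)
}

#' Ground-truth occupancy mask of one bundle
#'
#' Voxelises a bundle of a phantom spec without simulating any signal.
#'
#' @param spec a [phantom_spec()].
#' @param bundle bundle name.
#' @return Logical array on the phantom grid.
#' @export
phantom_occupancy <- function(spec, bundle) {
  names_b <- vapply(spec$bundles, `[[`, "", "name")
  if (!bundle %in% names_b) {
    stop(sprintf("no bundle named '%s' in the phantom spec", bundle),
         call. = FALSE)
  }
  phantom_geometry(spec)[[match(bundle, names_b)]]$mask
}

#' Construct a lesion cavity on or off a bundle's path
#'
#' An on-path lesion is a box that fully covers the bundle's cross-section
#' in at least one coronal slice (so any streamline following the bundle
#' must traverse it); an off-path lesion is a sphere placed with zero
#' overlap with the bundle's occupancy.
#'
#' @param spec a [phantom_spec()].
#' @param target_bundle name of a bundle in `spec`.
#' @param on_path logical; place the lesion on (TRUE) or off (FALSE) the
#'   bundle's path.
#' @param radius off-path sphere radius in mm.
#' @return An `roi_mask` (role `"exclusion"`).
#' @export
make_lesion <- function(spec, target_bundle, on_path = TRUE, radius = 3) {
  names_b <- vapply(spec$bundles, `[[`, "", "name")
  if (!target_bundle %in% names_b) {
    stop(sprintf("no bundle named '%s' in the phantom spec", target_bundle),
         call. = FALSE)
  }
  geoms <- phantom_geometry(spec)
  g <- geoms[[match(target_bundle, names_b)]]
  dim3 <- spec$grid_shape
  if (on_path) {
    ys <- which(apply(g$mask, 2, any))
    # try mid-bundle slices first
    for (y in ys[order(abs(ys - stats::median(ys)))]) {
      sl <- g$mask[, y, ]
      ij <- which(sl, arr.ind = TRUE)
      x_rng <- range(ij[, 1]); z_rng <- range(ij[, 2])
      x_lo <- x_rng[1] - 1; x_hi <- x_rng[2] + 1
      z_lo <- z_rng[1] - 1; z_hi <- z_rng[2] + 1
      y_lo <- max(1, y - 1); y_hi <- min(dim3[2], y + 1)
      if (x_lo < 1 || z_lo < 1 || x_hi > dim3[1] || z_hi > dim3[3]) next
      les <- array(FALSE, dim3)
      les[x_lo:x_hi, y_lo:y_hi, z_lo:z_hi] <- TRUE
      return(roi_mask(les, "exclusion",
                      paste0("lesion_on_", target_bundle), spec$voxel_size))
    }
    stop("no coronal slice admits an on-path lesion inside the grid",
         call. = FALSE)
  }
  # off path: deterministic scan over a coarse grid of sphere centres
  world_max <- (dim3 - 1) * spec$voxel_size
  cand <- expand.grid(x = seq(radius, world_max[1] - radius, by = 4),
                      y = seq(radius, world_max[2] - radius, by = 4),
                      z = seq(radius, world_max[3] - radius, by = 4))
  for (i in seq_len(nrow(cand))) {
    sph <- sphere_mask_grid(dim3, spec$voxel_size,
                            as.numeric(cand[i, ]), radius)
    if (!any(sph & g$mask)) {
      return(roi_mask(sph, "exclusion",
                      paste0("lesion_off_", target_bundle), spec$voxel_size))
    }
  }
  stop("no placement satisfies the off-path constraint within the grid",
       call. = FALSE)
}
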