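#' Fit the ball-and-stick model in one voxel
#'
#' Estimates a single-stick ball-and-stick model
#' `S(g, b) = S0 * ((1 - f) exp(-b d) + f exp(-b d (g . v)^2))` from the
#' per-volume signal magnitudes of one voxel. A nonlinear least-squares
#' point fit (Levenberg-Marquardt from a log-linear tensor initialisation)
#' provides point estimates of `S0`, `d`, `f` and the orientation `v`;
#' Metropolis sampling under a Gaussian likelihood (noise level fixed from
#' the point-fit residuals, proposal scales adapted toward ~40% acceptance
#' during burn-in only) then yields `K` posterior draws of `(v, f)`.
#' Orientations are identified only up to sign.
#'
#' @param signal non-negative numeric vector, one magnitude per volume.
#' @param scheme the [make_scheme()] acquisition scheme.
#' @param K number of posterior samples to keep.
#' @param rng_seed integer seed; the fit is deterministic given the seed.
#' @param burn_in,thin Metropolis burn-in iterations and thinning interval.
#' @return A list with `v_samples` (3 x K), `f_samples` (K), point
#'   estimates `v_hat`, `f_hat`, `S0`, `d`, the residual `sigma`, the
#'   Metropolis `accept_rate` and a `background` flag. All-zero signal is
#'   flagged `background = TRUE` with no samples.
#' @export
fit_voxel <- function(signal, scheme, K = 50, rng_seed = 1,
                      burn_in = 200, thin = 2) {
  validate_scheme(scheme)
  if (length(signal) != scheme$n_volumes) {
    stop("signal length does not match the acquisition scheme", call. = FALSE)
  }
  if (any(signal < 0)) stop("signal must be non-negative", call. = FALSE)
  cpp_fit_voxel(as.numeric(signal), scheme$bvals, scheme$bvecs,
                as.integer(K), as.integer(burn_in), as.integer(thin),
                as.double(rng_seed))
}

#' Fit the ball-and-stick model over a volume
#'
#' Applies [fit_voxel()] to every in-mask voxel of a diffusion-weighted
#' volume. Per-voxel seeds are derived deterministically from `rng_seed`
#' and the voxel's linear index, so results do not depend on iteration
#' order. Voxels whose signal is identically zero are flagged background
#' and excluded from the fitted field.
#'
#' @param dwv a `dw_volume` (see [simulate_phantom()] or [read_dwi()]).
#' @param brain_mask logical array or `roi_mask` on the same grid; default
#'   keeps voxels whose mean b = 0 signal is positive.
#' @param K posterior samples per voxel.
#' @param rng_seed integer seed.
#' @param burn_in,thin Metropolis settings (see [fit_voxel()]).
#' @return An object of class `ball_stick_field`: per-voxel orientation and
#'   fraction samples plus point estimates, with `print`, `summary`,
#'   `coef` and `predict` methods.
#' @export
fit_ball_stick <- function(dwv, brain_mask = NULL, K = 50, rng_seed = 1,
                           burn_in = 200, thin = 2) {
  stopifnot(inherits(dwv, "dw_volume"))
  dim3 <- dim(dwv$data)[1:3]
  nvol <- dim(dwv$data)[4]
  if (is.null(brain_mask)) {
    b0 <- dwv$scheme$bvals == 0
    mb0 <- apply(dwv$data[, , , b0, drop = FALSE], 1:3, mean)
    brain_mask <- mb0 > 0
  } else {
    brain_mask <- as_binary_grid(brain_mask)
    stop_if_grid_mismatch(dim(brain_mask), dim3, "brain mask and volume")
  }
  idx <- which(brain_mask)
  if (length(idx) == 0) {
    return(new_ball_stick_field(dim3, dwv$voxel_size, K, integer(0),
                                array(0, c(3, K, 0)), matrix(0, K, 0),
                                numeric(0), numeric(0), numeric(0),
                                matrix(0, 3, 0),
                                list(burn_in = burn_in, thin = thin,
                                     rng_seed = rng_seed)))
  }
  sig <- t(matrix(dwv$data, prod(dim3), nvol)[idx, , drop = FALSE])
  fit <- cpp_fit_volume(sig, dwv$scheme$bvals, dwv$scheme$bvecs,
                        as.integer(idx), as.integer(K), as.integer(burn_in),
                        as.integer(thin), as.double(rng_seed))
  keep <- !fit$background
  idx <- idx[keep]
  new_ball_stick_field(
    dim3, dwv$voxel_size, K, idx,
    array(fit$v_samples[, , keep, drop = FALSE], c(3, K, sum(keep))),
    fit$f_samples[, keep, drop = FALSE],
    fit$S0[keep], fit$d[keep], fit$f_hat[keep],
    fit$v_hat[, keep, drop = FALSE],
    list(burn_in = burn_in, thin = thin, rng_seed = rng_seed,
         accept_rate = mean(fit$accept_rate[keep])))
}

new_ball_stick_field <- function(dim3, voxel_size, K, idx, v_samples,
                                 f_samples, S0, d, f_hat, v_hat, settings) {
  index <- array(-1L, dim3)
  index[idx] <- seq_along(idx) - 1L  # 0-based row for the C++ tracker
  structure(list(dim = as.integer(dim3),
                 voxel_size = rep_len(as.numeric(voxel_size), 3),
                 K = as.integer(K), index = index,
                 voxels = as.integer(idx),
                 v_samples = v_samples, f_samples = f_samples,
                 S0 = S0, d = d, f_hat = f_hat, v_hat = v_hat,
                 settings = settings),
            class = c("ball_stick_field", "orientation_field"))
}

#' Construct an orientation field from known orientations
#'
#' Builds a degenerate (K = 1) orientation field directly from per-voxel
#' orientations, e.g. to probe the tracker with an analytically known
#' substrate.
#'
#' @param orientations either a length-3 vector (one orientation
#'   everywhere) or an array of dimension `c(3, dim)` of per-voxel unit
#'   vectors.
#' @param mask logical array of voxels carrying samples; defaults to all.
#' @param dim grid extents; required when `orientations` is a single
#'   vector and `mask` is missing.
#' @param voxel_size mm per axis.
#' @param f anisotropic fraction recorded for every voxel.
#' @return An `orientation_field`.
#' @export
orientation_field <- function(orientations, mask = NULL, dim = NULL,
                              voxel_size = c(1, 1, 1), f = 0.7) {
  if (is.null(base::dim(orientations)) || length(orientations) == 3) {
    if (is.null(dim) && is.null(mask)) {
      stop("supply `dim` or `mask` with a constant orientation",
           call. = FALSE)
    }
    dim3 <- if (is.null(dim)) base::dim(mask) else as.integer(dim)
    v0 <- orientations / sqrt(sum(orientations^2))
    orientations <- array(v0, c(3, dim3))
  } else {
    dim3 <- base::dim(orientations)[-1]
  }
  if (is.null(mask)) mask <- array(TRUE, dim3)
  idx <- which(mask)
  vmat <- matrix(orientations, 3, prod(dim3))[, idx, drop = FALSE]
  vmat <- sweep(vmat, 2, sqrt(colSums(vmat^2)), "/")
  new_ball_stick_field(dim3, voxel_size, 1L, idx,
                       array(vmat, c(3, 1, length(idx))),
                       matrix(f, 1, length(idx)),
                       rep(1, length(idx)), rep(1.2e-3, length(idx)),
                       rep(f, length(idx)), vmat,
                       list(constructed = TRUE))
}

#' Ground-truth orientation field of a phantom
#'
#' Converts the analytic bundle geometry of a phantom into an orientation
#' field: inside a bundle every posterior sample equals the local centerline
#' tangent (both tangents, sampled equiprobably, where two bundles
#' overlap); the brain mask is the union of bundle occupancies plus any
#' ROI spheres supplied. Useful as a noise-free tracking substrate and as
#' an oracle in simulation studies.
#'
#' @param truth a `phantom_truth` (from [simulate_phantom()]).
#' @param f anisotropic fraction assigned to in-bundle voxels.
#' @return An `orientation_field` with `K = 2`.
#' @export
gt_orientation_field <- function(truth, f = 0.7) {
  dim3 <- dim(truth$brain_mask)
  nvox <- prod(dim3)
  occ <- lapply(truth$bundles, `[[`, "mask")
  union_mask <- Reduce(`|`, occ)
  idx <- which(union_mask)
  K <- 2L
  v <- array(0, c(3, K, length(idx)))
  fs <- matrix(f, K, length(idx))
  filled <- logical(length(idx))
  for (b in truth$bundles) {
    tb <- matrix(b$tangent, 3, nvox)
    pos <- match(which(b$mask), idx)
    pos <- pos[!is.na(pos)]
    for (p in pos) {
      li <- idx[p]
      if (!filled[p]) {
        v[, 1, p] <- tb[, li]
        v[, 2, p] <- tb[, li]
        filled[p] <- TRUE
      } else {
        v[, 2, p] <- tb[, li]  # second bundle: 50/50 two-stick mixture
      }
    }
  }
  new_ball_stick_field(dim3, truth$voxel_size, K, idx, v, fs,
                       rep(1, length(idx)), rep(1.2e-3, length(idx)),
                       rep(f, length(idx)), v[, 1, , drop = TRUE],
                       list(ground_truth = TRUE))
}

#' @export
print.orientation_field <- function(x, ...) {
  cat(sprintf(
    "Orientation field: %s grid, %d fitted voxel(s), K = %d samples/voxel\n",
    paste(x$dim, collapse = "x"), length(x$voxels), x$K))
  invisible(x)
}

#' @export
summary.ball_stick_field <- function(object, ...) {
  out <- list(n_voxels = length(object$voxels), K = object$K,
              f = summary(object$f_hat), d = summary(object$d),
              S0 = summary(object$S0),
              accept_rate = object$settings$accept_rate)
  class(out) <- "summary.ball_stick_field"
  out
}

#' @export
print.summary.ball_stick_field <- function(x, ...) {
  cat("Ball-and-stick fit over", x$n_voxels, "voxels, K =", x$K, "\n")
  cat("anisotropic fraction f:\n"); print(x$f)
  cat("diffusivity d (mm^2/s):\n"); print(x$d)
  if (!is.null(x$accept_rate)) {
    cat(sprintf("mean Metropolis acceptance: %.2f\n", x$accept_rate))
  }
  invisible(x)
}

#' @export
coef.ball_stick_field <- function(object, ...) {
  cbind(voxel = object$voxels, S0 = object$S0, d = object$d,
        f = object$f_hat, vx = object$v_hat[1, ], vy = object$v_hat[2, ],
        vz = object$v_hat[3, ])
}

#' Predicted mean signal from a fitted ball-and-stick field
#'
#' @param object a `ball_stick_field`.
#' @param scheme acquisition scheme to predict for.
#' @param voxels linear voxel indices (defaults to all fitted voxels).
#' @param ... unused.
#' @return Matrix `n_volumes x length(voxels)` of model-mean signals from
#'   the point estimates.
#' @export
predict.ball_stick_field <- function(object, scheme, voxels = NULL, ...) {
  validate_scheme(scheme)
  if (is.null(voxels)) voxels <- object$voxels
  rows <- object$index[voxels] + 1L
  if (any(rows < 1)) stop("voxel not in the fitted field", call. = FALSE)
  b <- scheme$bvals
  g <- scheme$bvecs
  vapply(rows, function(r) {
    gv <- g %*% object$v_hat[, r]
    object$S0[r] * ((1 - object$f_hat[r]) * exp(-b * object$d[r]) +
                    object$f_hat[r] * exp(-b * object$d[r] * gv^2))
  }, numeric(length(b)))
}

# Mean orientation of the posterior samples in one voxel (sign-aligned to
# the first sample), plus the resultant length as a dispersion measure.
#' Posterior mean orientation per voxel
#'
#' Sign-aligns each voxel's orientation samples to its first sample,
#' averages and renormalises. The resultant length (norm of the average of
#' the sign-aligned unit vectors) quantifies concentration: 1 for a
#' degenerate posterior, near 0 for an isotropic one.
#'
#' @param field an `orientation_field`.
#' @param voxels linear voxel indices (defaults to all fitted voxels).
#' @return List with `mean_v` (3 x n) and `resultant_length` (n).
#' @export
mean_orientation <- function(field, voxels = NULL) {
  if (is.null(voxels)) voxels <- field$voxels
  rows <- field$index[voxels] + 1L
  if (any(rows < 1)) stop("voxel not in the fitted field", call. = FALSE)
  mv <- matrix(0, 3, length(rows))
  rl <- numeric(length(rows))
  for (i in seq_along(rows)) {
    s <- field$v_samples[, , rows[i], drop = FALSE]
    dim(s) <- c(3, field$K)
    sgn <- sign(colSums(s * s[, 1]))
    sgn[sgn == 0] <- 1
    s <- sweep(s, 2, sgn, "*")
    m <- rowMeans(s)
    rl[i] <- sqrt(sum(m^2))
    mv[, i] <- if (rl[i] > 0) m / rl[i] else c(1, 0, 0)
  }
  list(mean_v = mv, resultant_length = rl)
}
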