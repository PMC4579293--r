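#' Tracker configuration
#'
#' Settings for probabilistic streamline propagation. The curvature
#' threshold is the minimum cosine of the angle between successive step
#' directions; a draw below it terminates the streamline. The defaults
#' (curvature threshold 0.2, 5000 samples per seed voxel) follow the
#' standard probabilistic-tractography settings for this kind of
#' dissection.
#'
#' @param curvature_threshold minimum cosine between successive steps, in
#'   `[-1, 1]`.
#' @param samples_per_seed_voxel streamlines launched per seed voxel.
#' @param step_size step length in mm; default half the smallest voxel
#'   dimension (resolved at tracking time when `NULL`).
#' @param max_steps maximum steps per propagation direction.
#' @param rng_seed integer seed; per-streamline RNG streams are derived
#'   from `(rng_seed, seed-voxel index, sample index)`, so results are
#'   independent of iteration order.
#' @return An object of class `tracker_config`.
#' @export
tracker_config <- function(curvature_threshold = 0.2,
                           samples_per_seed_voxel = 5000,
                           step_size = NULL, max_steps = 2000,
                           rng_seed = 1) {
  stopifnot(curvature_threshold >= -1, curvature_threshold <= 1,
            samples_per_seed_voxel >= 1,
            is.null(step_size) || step_size > 0, max_steps >= 1)
  structure(list(curvature_threshold = curvature_threshold,
                 samples_per_seed_voxel = as.integer(samples_per_seed_voxel),
                 step_size = step_size, max_steps = as.integer(max_steps),
                 rng_seed = as.integer(rng_seed)),
            class = "tracker_config")
}

resolve_step <- function(config, voxel_size) {
  if (is.null(config$step_size)) 0.5 * min(voxel_size) else config$step_size
}

#' Propagate a single streamline
#'
#' Propagates one streamline from `start` (world mm) through an
#' orientation field: at each step one orientation sample is drawn from
#' the current voxel's posterior (nearest-voxel lookup), sign-aligned with
#' the previous direction, and the position advanced by the step size.
#' Propagation ends when the curvature threshold is violated, the
#' streamline leaves the brain mask or grid, a termination mask is
#' entered, or `max_steps` is reached. The first direction is drawn
#' without a curvature constraint. Unidirectional; [track()] propagates
#' both ways from each seed.
#'
#' @param field an `orientation_field`.
#' @param start numeric length-3 world position (mm).
#' @param config a [tracker_config()].
#' @param termination optional `roi_mask` that stops propagation.
#' @param stream_id integer folded into the RNG stream, so repeated calls
#'   can draw distinct streamlines reproducibly.
#' @return List with `points` (n x 3 matrix of mm positions, starting at
#'   `start`) and `reason` (one of `"exited"`, `"curvature"`,
#'   `"termination"`, `"max_steps"`).
#' @export
propagate_one <- function(field, start, config = tracker_config(),
                          termination = NULL, stream_id = 0) {
  vx <- round(start / field$voxel_size)
  if (any(vx < 0) || any(vx > field$dim - 1)) {
    stop("start point outside the field grid", call. = FALSE)
  }
  term <- if (is.null(termination)) integer(0) else {
    stop_if_grid_mismatch(dim(termination$grid), field$dim)
    as.integer(termination$grid)
  }
  cpp_propagate_one(field$dim, field$voxel_size, field$index,
                    field$v_samples, field$K, term, as.numeric(start),
                    config$curvature_threshold,
                    resolve_step(config, field$voxel_size),
                    config$max_steps,
                    as.double(config$rng_seed * 2654435761 + stream_id))
}

#' Probabilistic tractography between ROI masks
#'
#' Launches `samples_per_seed_voxel` streamlines from the centre of every
#' seed voxel, propagating in both directions from the initial point and
#' concatenating the two halves. A streamline is discarded if it enters
#' any exclusion mask and retained only if it visits every waypoint mask;
#' entering the termination mask ends propagation on that side and keeps
#' the streamline (still subject to the waypoint check). Each retained
#' streamline increments every voxel it visits exactly once; the value of
#' each voxel of the result is the number of retained streamlines passing
#' through it.
#'
#' @param field an `orientation_field`.
#' @param seed `roi_mask` of seed voxels (non-empty).
#' @param waypoints list of `roi_mask` objects that must all be visited.
#' @param termination optional `roi_mask`.
#' @param exclusions list of `roi_mask` objects (or binary arrays).
#' @param config a [tracker_config()].
#' @return An object of class `visitation_map`: integer `counts` array,
#'   `n_seed_samples`, `n_retained` and the `config` snapshot.
#' @export
track <- function(field, seed, waypoints = list(), termination = NULL,
                  exclusions = list(), config = tracker_config()) {
  stopifnot(inherits(field, "orientation_field"))
  seed_grid <- as_binary_grid(seed)
  stop_if_grid_mismatch(dim(seed_grid), field$dim, "seed mask and field")
  seed_idx <- which(seed_grid)
  if (length(seed_idx) == 0) stop("empty seed mask", call. = FALSE)
  if (length(waypoints) > 31) stop("at most 31 waypoint masks supported")

  wp_bits <- array(0L, field$dim)
  for (i in seq_along(waypoints)) {
    g <- as_binary_grid(waypoints[[i]])
    stop_if_grid_mismatch(dim(g), field$dim, "waypoint mask and field")
    wp_bits <- wp_bits + bitwShiftL(1L, i - 1L) * g
  }
  excl <- array(FALSE, field$dim)
  for (e in exclusions) {
    g <- as_binary_grid(e)
    stop_if_grid_mismatch(dim(g), field$dim, "exclusion mask and field")
    excl <- excl | g
  }
  if (any(excl & wp_bits > 0)) {
    stop("contradictory mask roles: a waypoint voxel is also excluded",
         call. = FALSE)
  }
  term <- if (is.null(termination)) {
    array(0L, field$dim)
  } else {
    g <- as_binary_grid(termination)
    stop_if_grid_mismatch(dim(g), field$dim, "termination mask and field")
    array(as.integer(g), field$dim)
  }

  res <- cpp_track(field$dim, field$voxel_size, field$index, field$v_samples,
                   field$K, as.integer(seed_idx) - 1L,
                   as.integer(wp_bits), as.integer(term), as.integer(excl),
                   length(waypoints), config$samples_per_seed_voxel,
                   config$curvature_threshold,
                   resolve_step(config, field$voxel_size), config$max_steps,
                   as.double(config$rng_seed))

  structure(list(counts = array(res$counts, field$dim),
                 n_seed_samples = res$n_launched,
                 n_retained = res$n_retained,
                 voxel_size = field$voxel_size,
                 config = config),
            class = "visitation_map")
}

#' @export
print.visitation_map <- function(x, ...) {
  cat(sprintf(paste0(
    "Visitation map: %s grid; %s streamlines launched, %s retained; ",
    "max count %d over %d visited voxel(s)\n"),
    paste(dim(x$counts), collapse = "x"),
    format(x$n_seed_samples, big.mark = ","),
    format(x$n_retained, big.mark = ","),
    max(x$counts), sum(x$counts > 0)))
  invisible(x)
}

#' @export
plot.visitation_map <- function(x, slice = NULL, axis = 2, ...) {
  counts <- x$counts
  if (is.null(slice)) {
    proj <- apply(counts, setdiff(1:3, axis), max)
  } else {
    proj <- switch(axis, counts[slice, , ], counts[, slice, ],
                   counts[, , slice])
  }
  graphics::image(proj, col = grDevices::hcl.colors(64, "inferno"),
                  useRaster = TRUE, ...)
  invisible(x)
}
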