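#' Threshold a visitation map
#'
#' Keeps exactly the voxels containing at least `fraction` of the maximum
#' number of retained streamlines found in any voxel (boundary inclusive).
#' The 10% default is the fraction reported to best reflect tracer anatomy
#' in validation studies of probabilistic tractography.
#'
#' @param vmap a `visitation_map` with at least one nonzero voxel.
#' @param fraction threshold fraction in `(0, 1]`.
#' @return An object of class `streamline_mask`: binary `grid` plus
#'   provenance (source map diagnostics and the threshold used).
#' @export
threshold_map <- function(vmap, fraction = 0.10) {
  stopifnot(inherits(vmap, "visitation_map"), fraction > 0, fraction <= 1)
  mx <- max(vmap$counts)
  if (mx == 0) stop("empty tractogram", call. = FALSE)
  streamline_mask(vmap$counts >= fraction * mx,
                  provenance = list(threshold = fraction, max_count = mx,
                                    n_retained = vmap$n_retained),
                  voxel_size = vmap$voxel_size)
}

#' Binarize a visitation map without thresholding
#'
#' All voxels visited by at least one retained streamline (the
#' "unthresholded streamline" of the dissection protocol, used e.g. as an
#' exclusion mask).
#'
#' @inheritParams threshold_map
#' @export
binarize_map <- function(vmap) {
  stopifnot(inherits(vmap, "visitation_map"))
  streamline_mask(vmap$counts > 0,
                  provenance = list(threshold = 0,
                                    n_retained = vmap$n_retained),
                  voxel_size = vmap$voxel_size)
}

#' Streamline mask container
#'
#' @param grid logical 3D array.
#' @param provenance list describing the source (thresholds, map ids).
#' @param voxel_size mm per axis.
#' @param subject,hemisphere,label optional annotations.
#' @return An object of class `streamline_mask`.
#' @export
streamline_mask <- function(grid, provenance = list(),
                            voxel_size = c(1, 1, 1), subject = NA,
                            hemisphere = NA, label = NA) {
  structure(list(grid = as_binary_grid(grid), provenance = provenance,
                 voxel_size = rep_len(as.numeric(voxel_size), 3),
                 subject = subject, hemisphere = hemisphere, label = label),
            class = "streamline_mask")
}

#' @export
print.streamline_mask <- function(x, ...) {
  cat(sprintf("Streamline mask: %d voxels on a %s grid", sum(x$grid),
              paste(dim(x$grid), collapse = "x")))
  if (!is.null(x$provenance$threshold)) {
    cat(sprintf(" (threshold %.0f%%)", 100 * x$provenance$threshold))
  }
  cat("\n")
  invisible(x)
}

#' Bidirectional overlap of two opposing dissections
#'
#' Combines the A-to-B and B-to-A visitation maps by binarizing each,
#' adding them, and keeping voxels present in both (sum = 2). The result
#' is flagged `continuous` when a single 26-connected component of the
#' overlap intersects both endpoint ROIs.
#'
#' @param map_ab,map_ba `visitation_map`s tracked in opposite directions.
#' @param roi_a,roi_b the endpoint `roi_mask`s.
#' @return List with `mask` (`streamline_mask`) and `continuous` (logical).
#' @export
overlap_bidirectional <- function(map_ab, map_ba, roi_a, roi_b) {
  stopifnot(inherits(map_ab, "visitation_map"),
            inherits(map_ba, "visitation_map"))
  stop_if_grid_mismatch(dim(map_ab$counts), dim(map_ba$counts))
  ga <- as_binary_grid(roi_a); gb <- as_binary_grid(roi_b)
  stop_if_grid_mismatch(dim(ga), dim(map_ab$counts))
  stop_if_grid_mismatch(dim(gb), dim(map_ab$counts))
  overlap <- (map_ab$counts > 0) & (map_ba$counts > 0)
  lab <- label_components(overlap)
  touching <- intersect(setdiff(unique(lab[ga]), 0L),
                        setdiff(unique(lab[gb]), 0L))
  list(mask = streamline_mask(overlap,
                              provenance = list(op = "bidirectional_overlap"),
                              voxel_size = map_ab$voxel_size),
       continuous = length(touching) > 0)
}

#' Cross-subject composite streamline
#'
#' Keeps voxels present in at least `ceil(min_fraction * n)` of the `n`
#' input masks ("at least N% of participants"; the at-least-8-of-12 rule
#' is `min_fraction = 8/12`).
#'
#' @param masks list of `streamline_mask`s (or binary arrays) on a common
#'   grid.
#' @param min_fraction fraction in `(0, 1]`.
#' @return A `streamline_mask`.
#' @export
composite <- function(masks, min_fraction = 0.75) {
  stopifnot(length(masks) >= 1, min_fraction > 0, min_fraction <= 1)
  grids <- lapply(masks, as_binary_grid)
  for (g in grids[-1]) stop_if_grid_mismatch(dim(g), dim(grids[[1]]))
  n <- length(grids)
  count <- Reduce(`+`, grids)
  # guard the ceiling against floating fuzz (8/12 * 12 slightly above 8)
  need <- ceiling(min_fraction * n - 1e-9)
  vs <- if (is.list(masks[[1]]) && !is.null(masks[[1]]$voxel_size)) {
    masks[[1]]$voxel_size
  } else c(1, 1, 1)
  streamline_mask(count >= need,
                  provenance = list(op = "composite", n_subjects = n,
                                    min_fraction = min_fraction,
                                    min_count = need),
                  voxel_size = vs)
}

#' Virtual dissection of the SC-pulvinar-amygdala pathway
#'
#' Runs the full dissection protocol on an orientation field:
#' \enumerate{
#'   \item track the stria terminalis (amygdala seed, frontal-horn
#'     waypoint, BNST termination);
#'   \item track SC to amygdala (SC seed, optional pulvinar waypoint,
#'     amygdala waypoint + termination);
#'   \item re-track SC to amygdala using the \emph{unthresholded} stria
#'     visitation map, binarized, as an exclusion mask (the protocol's
#'     own ROI masks are subtracted from the exclusion so the seed and
#'     termination regions stay reachable);
#'   \item threshold both dissections at 10% of the per-map maximum;
#'   \item optionally repeat the dissection in the reverse direction and
#'     form the bidirectional overlap.
#' }
#' If the stria run fails to produce a streamline -- fewer than
#' `min_stria_fraction` of its launched samples retained, i.e. only stray
#' walkers rather than a reproducible connection -- step 3 is skipped with
#' a warning and the unexcluded dissection is carried forward.
#'
#' @param field an `orientation_field`.
#' @param masks named list of `roi_mask`s: `sc`, `pulvinar`, `amygdala`,
#'   `stria_frontal`, `bnst`.
#' @param config a [tracker_config()].
#' @param use_pulvinar_waypoint include the pulvinar waypoint in the
#'   SC-amygdala runs.
#' @param extra_exclusions list of additional exclusion masks (e.g. a
#'   coronal exclusion plane) applied to every run.
#' @param bidirectional also run amygdala-to-SC and compute the overlap.
#' @param threshold visitation threshold fraction for step 4.
#' @param min_stria_fraction minimum retained fraction of launched stria
#'   samples for the stria map to count as a streamline and be used as an
#'   exclusion mask.
#' @return An object of class `dissection_result` with thresholded
#'   `sc_amygdala` (exclusion-cleaned when available), `sc_amygdala_raw`
#'   (no stria exclusion), `stria` masks, the underlying visitation maps,
#'   the `overlap` mask and `continuous` flag when `bidirectional`, a
#'   `stria_excluded` flag and per-run diagnostics.
#' @export
dissect_pathway <- function(field, masks, config = tracker_config(),
                            use_pulvinar_waypoint = TRUE,
                            extra_exclusions = list(),
                            bidirectional = FALSE, threshold = 0.10,
                            min_stria_fraction = 1e-3) {
  needed <- c("sc", "pulvinar", "amygdala", "stria_frontal", "bnst")
  missing <- setdiff(needed, names(masks))
  if (length(missing)) {
    stop("missing masks: ", paste(missing, collapse = ", "), call. = FALSE)
  }

  # The SC and pulvinar are excluded from the stria dissection: because the
  # stria map is about to be used as an exclusion mask, it must contain only
  # genuine amygdalofugal stria streamlines, not amygdala-seeded streamlines
  # that ride the SC pathway (which pass through the pulvinar, where real
  # stria fibers never run).
  stria_map <- track(field, seed = set_role(masks$amygdala, "seed"),
                     waypoints = list(set_role(masks$stria_frontal,
                                               "waypoint")),
                     termination = set_role(masks$bnst, "termination"),
                     exclusions = c(extra_exclusions,
                                    list(set_role(masks$sc, "exclusion"),
                                         set_role(masks$pulvinar,
                                                  "exclusion"))),
                     config = config)

  wps <- list(set_role(masks$amygdala, "waypoint"))
  if (use_pulvinar_waypoint) {
    wps <- c(list(set_role(masks$pulvinar, "waypoint")), wps)
  }
  main_raw <- track(field, seed = set_role(masks$sc, "seed"),
                    waypoints = wps,
                    termination = set_role(masks$amygdala, "termination"),
                    exclusions = extra_exclusions, config = config)

  stria_excluded <- stria_map$n_retained >=
    max(1, min_stria_fraction * stria_map$n_seed_samples)
  stria_excl_mask <- NULL
  if (stria_excluded) {
    protocol_rois <- masks$sc$grid | masks$pulvinar$grid | masks$amygdala$grid
    stria_excl_mask <- (stria_map$counts > 0) & !protocol_rois
    main_excl <- track(field, seed = set_role(masks$sc, "seed"),
                       waypoints = wps,
                       termination = set_role(masks$amygdala, "termination"),
                       exclusions = c(extra_exclusions,
                                      list(stria_excl_mask)),
                       config = config)
  } else {
    warning(sprintf(
      "stria run retained no streamline (%d of %s samples); exclusion step skipped",
      stria_map$n_retained, format(stria_map$n_seed_samples)))
    main_excl <- NULL
  }

  chosen_map <- if (stria_excluded) main_excl else main_raw
  overlap <- NULL
  continuous <- NA
  reverse_map <- NULL
  if (bidirectional) {
    rev_wps <- list(set_role(masks$sc, "waypoint"))
    if (use_pulvinar_waypoint) {
      rev_wps <- c(list(set_role(masks$pulvinar, "waypoint")), rev_wps)
    }
    rev_excl <- extra_exclusions
    if (stria_excluded) rev_excl <- c(rev_excl, list(stria_excl_mask))
    reverse_map <- track(field, seed = set_role(masks$amygdala, "seed"),
                         waypoints = rev_wps,
                         termination = set_role(masks$sc, "termination"),
                         exclusions = rev_excl, config = config)
    ov <- overlap_bidirectional(chosen_map, reverse_map, masks$sc,
                                masks$amygdala)
    overlap <- ov$mask
    continuous <- ov$continuous
  }

  structure(list(
    sc_amygdala = threshold_map(chosen_map, threshold),
    sc_amygdala_raw = threshold_map(main_raw, threshold),
    stria = if (stria_excluded) threshold_map(stria_map, threshold) else NULL,
    maps = list(stria = stria_map, main_raw = main_raw,
                main_excl = main_excl, reverse = reverse_map),
    overlap = overlap, continuous = continuous,
    stria_excluded = stria_excluded,
    diagnostics = list(
      n_retained = c(stria = stria_map$n_retained,
                     main_raw = main_raw$n_retained,
                     main_excl = if (is.null(main_excl)) NA else
                       main_excl$n_retained,
                     reverse = if (is.null(reverse_map)) NA else
                       reverse_map$n_retained)),
    options = list(use_pulvinar_waypoint = use_pulvinar_waypoint,
                   threshold = threshold, bidirectional = bidirectional)),
    class = "dissection_result")
}

#' @export
print.dissection_result <- function(x, ...) {
  cat("Virtual dissection result\n")
  nr <- x$diagnostics$n_retained
  cat(sprintf("  stria run:        %s retained\n", format(nr[["stria"]])))
  cat(sprintf("  SC-amygdala:      %s retained (no exclusion)\n",
              format(nr[["main_raw"]])))
  if (x$stria_excluded) {
    cat(sprintf("  SC-amygdala:      %s retained (stria excluded)\n",
                format(nr[["main_excl"]])))
  } else {
    cat("  stria exclusion step skipped (no stria streamlines)\n")
  }
  cat(sprintf("  thresholded pathway: %d voxels\n", sum(x$sc_amygdala$grid)))
  if (!is.na(x$continuous)) {
    cat(sprintf("  bidirectional overlap continuous: %s\n", x$continuous))
  }
  invisible(x)
}
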