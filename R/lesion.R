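#' Would a lesion interrupt a streamline?
#'
#' Slices the streamline mask along its principal (coronal, y) axis and
#' computes, for every slice in which the streamline is present, the
#' fraction of its voxels falling inside the lesion. The streamline is
#' deemed interrupted when any slice's coverage reaches
#' `coverage_threshold`: at the default of 1.0 the lesion must cover the
#' streamline's complete cross-section in at least one slice, the
#' reproducible criterion this package imposes for "the lesion would
#' likely have interrupted the streamline".
#'
#' @param streamline a `streamline_mask` (non-empty).
#' @param lesion an `roi_mask` or binary array on the same grid.
#' @param coverage_threshold per-slice coverage fraction in `(0, 1]`
#'   declaring interruption.
#' @param axis slice axis (1 = x, 2 = y coronal, 3 = z); coronal by
#'   default.
#' @return An object of class `lesion_report`: `interrupted`,
#'   `overlap_voxels`, a per-slice `coverage` data frame and the threshold
#'   used.
#' @export
intersect_lesion <- function(streamline, lesion, coverage_threshold = 1.0,
                             axis = 2) {
  s <- as_binary_grid(streamline)
  l <- as_binary_grid(lesion)
  stop_if_grid_mismatch(dim(s), dim(l), "streamline and lesion")
  stopifnot(coverage_threshold > 0, coverage_threshold <= 1,
            axis %in% 1:3)
  if (!any(s)) stop("empty streamline mask", call. = FALSE)

  n_stream <- apply(s, axis, sum)
  n_hit <- apply(s & l, axis, sum)
  present <- which(n_stream > 0)
  coverage <- data.frame(slice = present,
                         streamline_voxels = n_stream[present],
                         lesion_voxels = n_hit[present],
                         coverage = n_hit[present] / n_stream[present])
  structure(list(interrupted = any(coverage$coverage >=
                                     coverage_threshold),
                 overlap_voxels = sum(s & l),
                 coverage = coverage,
                 coverage_threshold = coverage_threshold,
                 axis = axis),
            class = "lesion_report")
}

#' @export
print.lesion_report <- function(x, ...) {
  cat(sprintf(
    "Lesion report: %s (overlap %d voxel(s); max slice coverage %.2f; threshold %.2f)\n",
    if (x$interrupted) "streamline INTERRUPTED" else "streamline spared",
    x$overlap_voxels, max(x$coverage$coverage), x$coverage_threshold))
  invisible(x)
}
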