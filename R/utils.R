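# Internal helpers shared across modules.

# Evaluate `expr` with R's RNG seeded to `seed`, restoring the caller's
# RNG state afterwards so library calls never disturb user-level streams.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stop_if_grid_mismatch <- function(a_dim, b_dim, what = "volumes") {
  if (!identical(as.integer(a_dim), as.integer(b_dim))) {
    stop(sprintf("grid mismatch between %s: %s vs %s", what,
                 paste(a_dim, collapse = "x"), paste(b_dim, collapse = "x")),
         call. = FALSE)
  }
  invisible(TRUE)
}

# 1-based voxel indices -> world mm (voxel centre)
voxel_to_world <- function(idx, voxel_size) {
  sweep(idx - 1, 2, voxel_size, "*")
}

#' Dice coefficient between two binary volumes
#'
#' `2 |A & B| / (|A| + |B|)`; returns `NaN` when both volumes are empty.
#'
#' @param a,b logical arrays (or objects with a `$grid` element) on a
#'   common grid.
#' @return A number in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  a <- as_binary_grid(a)
  b <- as_binary_grid(b)
  stop_if_grid_mismatch(dim(a), dim(b))
  2 * sum(a & b) / (sum(a) + sum(b))
}

# Accept logical arrays, roi_mask, streamline_mask or visitation_map.
as_binary_grid <- function(x) {
  if (is.array(x) || is.vector(x)) return(x != 0)
  if (inherits(x, "visitation_map")) return(x$counts > 0)
  if (!is.null(x$grid)) return(x$grid != 0)
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a binary volume", call. = FALSE)
}

#' Label 26-connected components of a binary volume
#'
#' @param mask a logical 3D array (or mask object).
#' @return An integer array of the same shape; 0 marks background, components
#'   are numbered from 1.
#' @export
label_components <- function(mask) {
  g <- as_binary_grid(mask)
  lab <- cpp_label26(as.logical(g), as.integer(dim(g)))
  array(lab, dim(g))
}
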