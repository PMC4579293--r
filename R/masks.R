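#' Region-of-interest masks with a dissection role
#'
#' A binary volume plus the role it plays in a tractography run: `"seed"`
#' (streamlines are launched from every nonzero voxel), `"waypoint"`
#' (streamlines must visit the mask to be retained), `"termination"`
#' (entering the mask ends propagation on that side; the streamline is
#' kept), or `"exclusion"` (entering the mask discards the streamline).
#' Lesion cavities reuse the same container with role `"exclusion"`.
#'
#' @param grid logical/0-1 3D array.
#' @param role one of `"seed"`, `"waypoint"`, `"termination"`, `"exclusion"`.
#' @param name label used in printed output and error messages.
#' @param voxel_size voxel edge lengths in mm (length 3 or scalar).
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(grid, role = c("seed", "waypoint", "termination",
                                    "exclusion"),
                     name = "roi", voxel_size = c(1, 1, 1)) {
  role <- match.arg(role)
  grid <- as_binary_grid(grid)
  if (length(dim(grid)) != 3) stop("mask must be a 3D array", call. = FALSE)
  structure(list(grid = grid, role = role, name = name,
                 voxel_size = rep_len(as.numeric(voxel_size), 3)),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("ROI mask '%s' (role: %s): %d voxels on a %s grid\n",
              x$name, x$role, sum(x$grid),
              paste(dim(x$grid), collapse = "x")))
  invisible(x)
}

#' Re-role an ROI mask
#'
#' The dissection protocol reuses the same anatomical mask under different
#' roles (the amygdala is a waypoint, a termination mask and the stria seed).
#'
#' @inheritParams roi_mask
#' @param mask an `roi_mask`.
#' @export
set_role <- function(mask, role) {
  roi_mask(mask$grid, role, mask$name, mask$voxel_size)
}

# Spherical mask; centre in world mm, radius in mm.
sphere_mask_grid <- function(dim3, voxel_size, center, radius) {
  cx <- (seq_len(dim3[1]) - 1) * voxel_size[1]
  cy <- (seq_len(dim3[2]) - 1) * voxel_size[2]
  cz <- (seq_len(dim3[3]) - 1) * voxel_size[3]
  dx2 <- (cx - center[1])^2
  dy2 <- (cy - center[2])^2
  dz2 <- (cz - center[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+") <= radius^2
}

# Axis-aligned box in world mm: center +/- halfwidth.
box_mask_grid <- function(dim3, voxel_size, center, halfwidth) {
  inside_axis <- function(n, h, c0, w) {
    x <- (seq_len(n) - 1) * h
    x >= c0 - w & x <= c0 + w
  }
  ix <- inside_axis(dim3[1], voxel_size[1], center[1], halfwidth[1])
  iy <- inside_axis(dim3[2], voxel_size[2], center[2], halfwidth[2])
  iz <- inside_axis(dim3[3], voxel_size[3], center[3], halfwidth[3])
  outer(outer(ix, iy, "&"), iz, "&")
}

ellipsoid_mask_grid <- function(dim3, voxel_size, center, semiaxes) {
  cx <- ((seq_len(dim3[1]) - 1) * voxel_size[1] - center[1]) / semiaxes[1]
  cy <- ((seq_len(dim3[2]) - 1) * voxel_size[2] - center[2]) / semiaxes[2]
  cz <- ((seq_len(dim3[3]) - 1) * voxel_size[3] - center[3]) / semiaxes[3]
  outer(outer(cx^2, cy^2, "+"), cz^2, "+") <= 1
}
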