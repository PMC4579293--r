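# NIfTI-1 + FSL gradient-table serialisation for the pipeline's containers.

#' Write and read a diffusion-weighted volume
#'
#' Serialises a `dw_volume` as a 4D NIfTI-1 file (voxel sizes in the
#' header, RAS world convention with voxel centre `index * voxel_size`)
#' plus FSL-dialect `bvals`/`bvecs` text files.
#'
#' @param dwv a `dw_volume`.
#' @param dir output directory (created if needed).
#' @param basename file stem; writes `<basename>.nii.gz`, `<basename>.bval`
#'   and `<basename>.bvec`.
#' @return `write_dwi` returns the paths invisibly; `read_dwi` a
#'   `dw_volume`.
#' @export
write_dwi <- function(dwv, dir, basename = "dwi") {
  stopifnot(inherits(dwv, "dw_volume"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nii <- file.path(dir, paste0(basename, ".nii.gz"))
  img <- RNifti::asNifti(dwv$data)
  RNifti::pixdim(img) <- dwv$voxel_size
  RNifti::writeNifti(img, nii)
  write_fsl_gradients(dwv$scheme,
                      file.path(dir, paste0(basename, ".bval")),
                      file.path(dir, paste0(basename, ".bvec")))
  invisible(c(nii, file.path(dir, paste0(basename, c(".bval", ".bvec")))))
}

#' @rdname write_dwi
#' @param nii_path,bvals_path,bvecs_path input paths for `read_dwi`.
#' @export
read_dwi <- function(nii_path, bvals_path, bvecs_path) {
  img <- RNifti::readNifti(nii_path)
  scheme <- read_fsl_gradients(bvals_path, bvecs_path)
  data <- array(as.numeric(img), dim(img))
  if (dim(data)[4] != scheme$n_volumes) {
    stop("volume count does not match the gradient table", call. = FALSE)
  }
  structure(list(data = data, scheme = scheme,
                 voxel_size = RNifti::pixdim(img)[1:3],
                 S0 = NA),
            class = "dw_volume")
}

#' Write and read binary masks as uint8 NIfTI-1
#'
#' @param mask an `roi_mask`, `streamline_mask` or logical array.
#' @param path output `.nii.gz` path.
#' @param voxel_size used when `mask` is a bare array.
#' @export
write_mask <- function(mask, path, voxel_size = NULL) {
  g <- as_binary_grid(mask)
  if (is.null(voxel_size)) {
    voxel_size <- if (is.list(mask) && !is.null(mask$voxel_size)) {
      mask$voxel_size
    } else c(1, 1, 1)
  }
  img <- RNifti::asNifti(array(as.integer(g), dim(g)))
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname write_mask
#' @param role,name passed to [roi_mask()] on read.
#' @export
read_mask <- function(path, role = "waypoint", name = NULL) {
  img <- RNifti::readNifti(path)
  roi_mask(array(as.numeric(img) != 0, dim(img)), role = role,
           name = if (is.null(name)) basename(path) else name,
           voxel_size = RNifti::pixdim(img)[1:3])
}

#' Write and read a visitation map
#'
#' Writes the counts as int32 NIfTI-1 plus a JSON sidecar holding the
#' launch/retention diagnostics and the tracker configuration.
#'
#' @param vmap a `visitation_map`.
#' @param path output `.nii.gz` path; the sidecar replaces the extension
#'   with `.json`.
#' @export
write_visitation <- function(vmap, path) {
  stopifnot(inherits(vmap, "visitation_map"))
  img <- RNifti::asNifti(vmap$counts)
  RNifti::pixdim(img) <- vmap$voxel_size
  RNifti::writeNifti(img, path, datatype = "int32")
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  cfg <- vmap$config
  cfg$step_size <- resolve_step(cfg, vmap$voxel_size)
  jsonlite::write_json(
    list(n_seed_samples = vmap$n_seed_samples,
         n_retained = vmap$n_retained,
         config = cfg[c("curvature_threshold", "samples_per_seed_voxel",
                        "step_size", "max_steps", "rng_seed")]),
    side, auto_unbox = TRUE, digits = NA)
  invisible(c(path, side))
}

#' @rdname write_visitation
#' @export
read_visitation <- function(path) {
  img <- RNifti::readNifti(path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  cfg <- tracker_config(
    curvature_threshold = meta$config$curvature_threshold,
    samples_per_seed_voxel = meta$config$samples_per_seed_voxel,
    step_size = meta$config$step_size,
    max_steps = meta$config$max_steps,
    rng_seed = meta$config$rng_seed)
  structure(list(counts = array(as.integer(img), dim(img)),
                 n_seed_samples = meta$n_seed_samples,
                 n_retained = meta$n_retained,
                 voxel_size = RNifti::pixdim(img)[1:3],
                 config = cfg),
            class = "visitation_map")
}
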