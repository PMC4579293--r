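#' Build a diffusion acquisition scheme
#'
#' Generates an acquisition scheme of `n_b0` non-diffusion-weighted volumes
#' followed by `n_directions` diffusion-encoding directions at a single
#' b-value. Directions are quasi-uniform on the hemisphere, obtained by
#' electrostatic-repulsion relaxation of a seeded random configuration with
#' antipodal symmetry (each direction repels both images of every other
#' direction), the standard construction for "isotropically distributed"
#' gradient tables.
#'
#' @param n_directions number of diffusion-weighted directions (at least 6,
#'   the minimum for orientation fitting).
#' @param bvalue diffusion weighting in s/mm^2 (positive).
#' @param n_b0 number of b = 0 volumes, at least 1.
#' @param rng_seed integer seed; the scheme is deterministic given the seed.
#' @return An object of class `acquisition_scheme`: a list with `bvals`
#'   (length-n vector, s/mm^2), `bvecs` (n x 3 matrix of unit vectors, zero
#'   rows for b = 0 volumes) and `n_volumes`.
#' @examples
#' sch <- make_scheme(32, 800, n_b0 = 4, rng_seed = 1)
#' sch$n_volumes  # 36
#' @export
make_scheme <- function(n_directions, bvalue, n_b0 = 1, rng_seed = 1) {
  if (n_directions < 6) {
    stop("insufficient directions for orientation fitting", call. = FALSE)
  }
  stopifnot(bvalue > 0, n_b0 >= 1)
  v <- repulsion_directions(n_directions, rng_seed)
  scheme <- structure(
    list(bvals = c(rep(0, n_b0), rep(bvalue, n_directions)),
         bvecs = rbind(matrix(0, n_b0, 3), v),
         n_volumes = as.integer(n_b0 + n_directions)),
    class = "acquisition_scheme")
  validate_scheme(scheme)
  scheme
}

validate_scheme <- function(scheme) {
  stopifnot(length(scheme$bvals) == scheme$n_volumes,
            nrow(scheme$bvecs) == scheme$n_volumes)
  dw <- scheme$bvals > 0
  if (!any(!dw)) stop("scheme needs at least one b = 0 volume", call. = FALSE)
  nrm <- sqrt(rowSums(scheme$bvecs[dw, , drop = FALSE]^2))
  if (any(abs(nrm - 1) > 1e-6)) {
    stop("diffusion-weighted b-vectors must be unit length", call. = FALSE)
  }
  invisible(scheme)
}

# Electrostatic repulsion on the sphere with antipodal symmetry; gradient
# descent with a slowly annealed step, deterministic given the seed.
repulsion_directions <- function(n, seed) {
  with_seed(seed, {
    v <- matrix(stats::rnorm(3 * n), n, 3)
    v <- v / sqrt(rowSums(v^2))
    step <- 0.05
    for (it in seq_len(600)) {
      force <- matrix(0, n, 3)
      for (i in seq_len(n)) {
        d1 <- sweep(v[-i, , drop = FALSE], 2, v[i, ], "-")
        d2 <- sweep(-v[-i, , drop = FALSE], 2, v[i, ], "-")
        r1 <- pmax(sqrt(rowSums(d1^2)), 1e-6)
        r2 <- pmax(sqrt(rowSums(d2^2)), 1e-6)
        force[i, ] <- -colSums(d1 / r1^3) - colSums(d2 / r2^3)
      }
      force <- force - v * rowSums(force * v)  # tangential component
      vmax <- max(sqrt(rowSums(force^2)), 1e-9)
      v <- v + step * force / vmax
      v <- v / sqrt(rowSums(v^2))
      step <- step * 0.997
    }
    flip <- v[, 3] < 0 | (v[, 3] == 0 & v[, 1] < 0)
    v[flip, ] <- -v[flip, ]
    v
  })
}

#' @export
print.acquisition_scheme <- function(x, ...) {
  shells <- table(round(x$bvals))
  cat("Diffusion acquisition scheme:", x$n_volumes, "volumes\n")
  for (b in names(shells)) {
    cat(sprintf("  b = %s s/mm^2: %d volume(s)\n", b, shells[[b]]))
  }
  invisible(x)
}

#' Write and read FSL-dialect gradient tables
#'
#' `bvals`/`bvecs` text files in the layout used by the FSL diffusion tools:
#' `bvals` is a single whitespace-separated row, `bvecs` has three rows (one
#' per axis), one column per volume.
#'
#' @param scheme an `acquisition_scheme`.
#' @param bvals_path,bvecs_path file paths.
#' @return `write_fsl_gradients` returns the paths invisibly;
#'   `read_fsl_gradients` returns an `acquisition_scheme`.
#' @export
write_fsl_gradients <- function(scheme, bvals_path, bvecs_path) {
  validate_scheme(scheme)
  writeLines(paste(format(scheme$bvals, trim = TRUE), collapse = " "),
             bvals_path)
  rows <- apply(t(scheme$bvecs), 1, function(r) {
    paste(format(r, trim = TRUE, digits = 15), collapse = " ")
  })
  writeLines(rows, bvecs_path)
  invisible(c(bvals_path, bvecs_path))
}

#' @rdname write_fsl_gradients
#' @export
read_fsl_gradients <- function(bvals_path, bvecs_path) {
  bvals <- scan(bvals_path, quiet = TRUE)
  bv <- do.call(rbind, lapply(readLines(bvecs_path), function(l) {
    as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]])
  }))
  if (nrow(bv) != 3) stop("bvecs file must have exactly 3 rows", call. = FALSE)
  scheme <- structure(
    list(bvals = bvals, bvecs = t(bv), n_volumes = length(bvals)),
    class = "acquisition_scheme")
  validate_scheme(scheme)
  scheme
}
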