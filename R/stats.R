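#' Per-slice centre of gravity of a streamline mask
#'
#' For each coronal (y) slice in `slices`, computes the in-plane centroid
#' of the mask voxels, mapped to world mm. By default the centroid is
#' unweighted (binary mask); supply `weights` (e.g. a visitation map's
#' counts) for a count-weighted centroid.
#'
#' @param mask a `streamline_mask`, `roi_mask` or logical array.
#' @param slices integer vector of 1-based coronal slice indices; every
#'   slice must contain at least one mask voxel (callers restrict the
#'   range to a segment where the tract runs perpendicular to the coronal
#'   plane).
#' @param affine optional 4 x 4 voxel-to-world matrix (0-based voxel
#'   indices); defaults to `diag(voxel_size)` with zero origin.
#' @param voxel_size used when `mask` is a bare array.
#' @param weights optional non-negative array of per-voxel weights.
#' @param subject,hemisphere,label annotations carried into the profile.
#' @return An object of class `cog_profile`: a data frame with columns
#'   `slice`, `x_mm`, `z_mm`.
#' @export
cog_profile <- function(mask, slices, affine = NULL, voxel_size = NULL,
                        weights = NULL, subject = NA, hemisphere = NA,
                        label = NA) {
  g <- as_binary_grid(mask)
  if (is.null(voxel_size)) {
    voxel_size <- if (is.list(mask) && !is.null(mask$voxel_size)) {
      mask$voxel_size
    } else c(1, 1, 1)
  }
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  stopifnot(all(slices >= 1), all(slices <= dim(g)[2]))
  if (!is.null(weights)) stop_if_grid_mismatch(dim(weights), dim(g))

  rows <- lapply(slices, function(y) {
    sl <- g[, y, ]
    ij <- which(sl, arr.ind = TRUE)
    if (nrow(ij) == 0) {
      stop(sprintf("no streamline voxels in coronal slice %d", y),
           call. = FALSE)
    }
    w <- if (is.null(weights)) rep(1, nrow(ij)) else {
      weights[cbind(ij[, 1], y, ij[, 2])]
    }
    w <- w / sum(w)
    vox <- cbind(sum(ij[, 1] * w), y, sum(ij[, 2] * w))  # 1-based, fractional
    world <- cbind(vox - 1, 1) %*% t(affine)
    c(slice = y, x_mm = world[1, 1], z_mm = world[1, 3])
  })
  out <- as.data.frame(do.call(rbind, rows))
  structure(out, class = c("cog_profile", "data.frame"),
            subject = subject, hemisphere = hemisphere, label = label,
            voxel_size = voxel_size)
}

#' @export
print.cog_profile <- function(x, ...) {
  lbl <- attr(x, "label")
  cat("Per-slice centre-of-gravity profile",
      if (!is.na(lbl)) paste0("(", lbl, ")"), "\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Cross-subject variability of centre-of-gravity profiles
#'
#' For each coronal slice, the across-subject standard deviation
#' (denominator n - 1) of the x and z centre-of-gravity coordinates, plus
#' a `Mean` row (column means over slices) and an `SD` row (standard
#' deviation of the per-slice values) in the layout of the study's
#' variability tables.
#'
#' @param profiles list of [cog_profile()]s, one per subject, sharing a
#'   common slice set (at least 2 subjects).
#' @param slices slice subset; defaults to the slices common to all
#'   profiles.
#' @param units `"mm"` or `"voxels"`; voxel units divide by `voxel_size`
#'   (isotropic in-plane voxels assumed for the voxel-unit table).
#' @return An object of class `variability_table`: a data frame with
#'   columns `slice`, `sd_x`, `sd_z` and attributes `summary` (Mean/SD
#'   rows) and `units`.
#' @export
variability_table <- function(profiles, slices = NULL, units = c("mm",
                                                                 "voxels")) {
  units <- match.arg(units)
  if (length(profiles) < 2) {
    stop("variability requires at least 2 subjects", call. = FALSE)
  }
  if (is.null(slices)) {
    slices <- Reduce(intersect, lapply(profiles, function(p) p$slice))
  }
  if (length(slices) == 0) stop("no common slices", call. = FALSE)
  scale <- if (units == "voxels") {
    vs <- attr(profiles[[1]], "voxel_size")
    if (is.null(vs)) c(1, 1) else c(vs[1], vs[3])
  } else c(1, 1)

  per_slice <- t(vapply(slices, function(s) {
    xs <- vapply(profiles, function(p) p$x_mm[match(s, p$slice)], 0)
    zs <- vapply(profiles, function(p) p$z_mm[match(s, p$slice)], 0)
    if (anyNA(xs) || anyNA(zs)) {
      stop(sprintf("slice %d missing from some profiles", s), call. = FALSE)
    }
    c(sd_x = sd(xs) / scale[1], sd_z = sd(zs) / scale[2])
  }, c(sd_x = 0, sd_z = 0)))

  out <- data.frame(slice = slices, sd_x = per_slice[, "sd_x"],
                    sd_z = per_slice[, "sd_z"])
  structure(out, class = c("variability_table", "data.frame"),
            summary = rbind(Mean = colMeans(per_slice),
                            SD = apply(per_slice, 2, sd)),
            units = units, n_subjects = length(profiles))
}

#' @export
print.variability_table <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Across-subject SD of the centre of gravity (n = %d subjects, %s)\n",
    attr(x, "n_subjects"), attr(x, "units")))
  tab <- rbind(as.matrix(data.frame(sd_x = x$sd_x, sd_z = x$sd_z,
                                    row.names = x$slice)),
               attr(x, "summary"))
  print(round(tab, digits))
  invisible(x)
}

#' Compare the centre-of-gravity offset between two streamlines
#'
#' Tests whether two streamlines (e.g. the SC-amygdala pathway and the
#' stria terminalis) occupy reliably different in-plane positions. The
#' per-slice centre-of-gravity values of both streamlines are submitted to
#' a two-factor ANOVA (streamline identity x participant); the streamline
#' effect is tested against the streamline-by-participant interaction,
#' giving `F(1, n_subjects - 1)`. The mean A - B offset and its standard
#' error across subjects are reported alongside.
#'
#' @param profiles_a,profiles_b lists of [cog_profile()]s for the same
#'   subjects and slices (same order).
#' @param axis `"x"` (left-right) or `"z"` (superior-inferior).
#' @return An object of class `offset_comparison`: `mean_offset` (mm),
#'   `se`, `F`, `df`, `p`, and a `degenerate` flag (zero interaction
#'   variance, F unbounded).
#' @export
compare_offsets <- function(profiles_a, profiles_b, axis = c("x", "z")) {
  axis <- match.arg(axis)
  if (length(profiles_a) != length(profiles_b)) {
    stop("subject sets differ between the two streamlines", call. = FALSE)
  }
  n_sub <- length(profiles_a)
  col <- paste0(axis, "_mm")
  slices <- profiles_a[[1]]$slice
  long <- do.call(rbind, lapply(seq_len(n_sub), function(j) {
    a <- profiles_a[[j]]; b <- profiles_b[[j]]
    if (!identical(a$slice, slices) || !identical(b$slice, slices)) {
      stop("profiles must share a common slice set", call. = FALSE)
    }
    rbind(data.frame(subject = j, slice = a$slice, stream = "A",
                     value = a[[col]]),
          data.frame(subject = j, slice = b$slice, stream = "B",
                     value = b[[col]]))
  }))
  long$subject <- factor(long$subject)
  long$stream <- factor(long$stream)

  fit <- aov(value ~ stream * subject, data = long)
  tab <- summary(fit)[[1]]
  rn <- trimws(rownames(tab))
  ms_stream <- tab[match("stream", rn), "Mean Sq"]
  ms_inter <- tab[match("stream:subject", rn), "Mean Sq"]
  df1 <- tab[match("stream", rn), "Df"]
  df2 <- tab[match("stream:subject", rn), "Df"]
  degenerate <- !is.finite(ms_inter) || ms_inter < 1e-12
  Fval <- if (degenerate) Inf else ms_stream / ms_inter
  pval <- if (degenerate) 0 else pf(Fval, df1, df2, lower.tail = FALSE)
  if (ms_stream < 1e-12) {  # identical streamlines: F is exactly 0
    Fval <- 0; pval <- 1; degenerate <- FALSE
  }

  d_j <- vapply(seq_len(n_sub), function(j) {
    mean(profiles_a[[j]][[col]]) - mean(profiles_b[[j]][[col]])
  }, 0)

  structure(list(axis = axis, mean_offset = mean(d_j),
                 se = sd(d_j) / sqrt(n_sub),
                 F = Fval, df = c(df1, df2), p = pval,
                 degenerate = degenerate, n_subjects = n_sub,
                 per_subject_offset = d_j),
            class = "offset_comparison")
}

#' @export
print.offset_comparison <- function(x, ...) {
  cat(sprintf("Centre-of-gravity offset (%s axis, n = %d subjects)\n",
              x$axis, x$n_subjects))
  cat(sprintf("  mean A - B offset: %.3f mm (SE %.3f)\n", x$mean_offset,
              x$se))
  if (x$degenerate) {
    cat("  streamline effect: F unbounded (zero interaction variance)\n")
  } else {
    cat(sprintf("  streamline effect: F(%d, %d) = %.2f, p = %.3g\n",
                x$df[1], x$df[2], x$F, x$p))
  }
  invisible(x)
}
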