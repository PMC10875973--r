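# Analysis grid: a regular voxel lattice over a brain-envelope mask.

# Canonical ellipsoidal brain envelope (mm, MNI-style axes). Centre and
# semi-axes bound the adult cortex generously without an external template;
# the same envelope is the default ALE mask and the synthetic generator's
# background support.
ENVELOPE_CENTER <- c(0, -18, 18)
ENVELOPE_SEMIAXES <- c(70, 86, 78)

#' Is a coordinate inside the default brain envelope?
#' @param xyz numeric matrix (n x 3) or length-3 vector of mm coordinates.
#' @return logical vector.
#' @export
inside_envelope <- function(xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3L)
  u <- sweep(xyz, 2L, ENVELOPE_CENTER)
  u <- sweep(u, 2L, ENVELOPE_SEMIAXES, "/")
  rowSums(u^2) <= 1
}

#' Construct an analysis grid
#'
#' A regular isotropic voxel lattice with an optional boolean analysis mask.
#' The default covers the package's ellipsoidal brain envelope at 2 mm
#' spacing with the envelope itself as the mask. Voxel centres sit at
#' `origin + (index - 1) * spacing` on each axis; every focus maps to the
#' nearest voxel centre.
#'
#' @param spacing voxel edge length in mm (> 0).
#' @param mask `"envelope"` for the default ellipsoid, `"none"` for an
#'   all-TRUE mask, or a logical array matching the grid dimensions.
#' @param lower,upper mm coordinates of the grid's bounding box (length 3);
#'   defaults cover the envelope.
#' @return an object of class `brain_grid` with fields `dim`, `spacing`,
#'   `origin` (mm of voxel `[1,1,1]`), and `mask` (logical array).
#' @export
brain_grid <- function(spacing = 2, mask = "envelope",
                       lower = ENVELOPE_CENTER - ENVELOPE_SEMIAXES,
                       upper = ENVELOPE_CENTER + ENVELOPE_SEMIAXES) {
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("spacing must be a single positive number", call. = FALSE)
  lower <- spacing * floor(lower / spacing)
  upper <- spacing * ceiling(upper / spacing)
  dims <- as.integer(round((upper - lower) / spacing)) + 1L
  g <- structure(list(dim = dims, spacing = spacing, origin = lower),
                 class = "brain_grid")
  if (is.character(mask)) {
    mask <- match.arg(mask, c("envelope", "none"))
    g$mask <- if (mask == "none") array(TRUE, dims)
              else array(inside_envelope(voxel_coordinates(g)), dims)
  } else {
    if (!is.logical(mask) || !identical(dim(mask), dims))
      stop("mask must be a logical array matching the grid dimensions",
           call. = FALSE)
    g$mask <- mask
  }
  if (!any(g$mask)) stop("empty mask", call. = FALSE)
  g
}

#' @export
print.brain_grid <- function(x, ...) {
  cat(sprintf("Brain grid: %d x %d x %d voxels at %g mm (%d in mask)\n",
              x$dim[1L], x$dim[2L], x$dim[3L], x$spacing, sum(x$mask)))
  invisible(x)
}

# mm coordinates of every voxel centre, grid (column-major) order; n_vox x 3.
#' @keywords internal
voxel_coordinates <- function(grid) {
  ax <- lapply(1:3, function(k)
    grid$origin[k] + (seq_len(grid$dim[k]) - 1L) * grid$spacing)
  nx <- grid$dim[1L]; ny <- grid$dim[2L]; nz <- grid$dim[3L]
  cbind(rep(ax[[1L]], times = ny * nz),
        rep(rep(ax[[2L]], each = nx), times = nz),
        rep(ax[[3L]], each = nx * ny))
}

# Nearest-voxel index (n x 3 integer) for mm coordinates; errors if outside.
#' @keywords internal
mm_to_voxel <- function(grid, xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3L)
  idx <- round(sweep(xyz, 2L, grid$origin) / grid$spacing) + 1
  bad <- idx < 1 | sweep(idx, 2L, grid$dim, ">")
  if (any(bad))
    stop("focus outside grid: (",
         paste(xyz[which(rowSums(bad) > 0)[1L], ], collapse = ", "), ")",
         call. = FALSE)
  storage.mode(idx) <- "integer"
  idx
}

#' @keywords internal
voxel_to_mm <- function(grid, idx) {
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 3L)
  sweep((idx - 1) * grid$spacing, 2L, grid$origin, "+")
}

#' @keywords internal
voxel_volume <- function(grid) grid$spacing^3

# 4x4 affine (voxel index, 1-based -> mm) for NIfTI export.
#' @keywords internal
grid_affine <- function(grid) {
  aff <- diag(c(rep(grid$spacing, 3L), 1))
  aff[1:3, 4L] <- grid$origin  # NIfTI voxel indices are 0-based
  aff
}
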