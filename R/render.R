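#' Render a synthetic 3D nuclei image
#'
#' Places one Gaussian blob per nucleus position into an intensity stack,
#' emulating diffraction-limited nuclear signal (sigma defaults to the
#' 4 um nominal nuclear diameter divided by 2.355, the FWHM-to-sigma
#' factor).  Optional Poisson shot noise.  Provides rendered test input for
#' the spot detector together with the ground-truth centre list.
#'
#' @param positions n x 3 matrix of nucleus centres (micrometres).
#' @param voxel_size Length-3 voxel size in micrometres (x, y, z); a scalar
#'   is recycled.
#' @param fov Length-3 field of view in micrometres; defaults to the
#'   position bounding box plus a 6 um margin.  Positions must lie inside.
#' @param origin Length-3 world coordinate of the stack corner.
#' @param psf_sigma Blob sigma in micrometres (isotropic).
#' @param amplitude Peak intensity per blob (photons).
#' @param background Constant background level.
#' @param noise `"none"` or `"poisson"`.
#' @return List with `stack` (3D array indexed x, y, z), `centers`,
#'   `voxel_size`, `origin`.
#' @export
render_nuclei_image <- function(positions, voxel_size = c(1, 1, 1),
                                fov = NULL, origin = NULL,
                                psf_sigma = 4 / 2.355,
                                amplitude = 100, background = 0,
                                noise = c("none", "poisson")) {
  noise <- match.arg(noise)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (any(voxel_size <= 0)) stop("voxel size must be positive")
  positions <- matrix(as.numeric(positions), ncol = 3L)
  if (is.null(origin)) {
    origin <- if (nrow(positions)) apply(positions, 2, min) - 6 else c(0, 0, 0)
  }
  if (is.null(fov)) {
    fov <- if (nrow(positions)) apply(positions, 2, max) - origin + 6 else c(20, 20, 20)
  }
  dims <- pmax(2L, ceiling(fov / voxel_size))
  if (nrow(positions)) {
    rel <- sweep(positions, 2, origin)
    if (any(rel < 0) || any(sweep(rel, 2, fov) >= 0))
      stop("positions must lie within the field of view")
  }
  stack <- array(background, dim = dims)
  # voxel centre coordinate along axis a: origin[a] + (i - 0.5) * voxel[a]
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 0.5) * voxel_size[a])
  for (i in seq_len(nrow(positions))) {
    p <- positions[i, ]
    g <- lapply(1:3, function(a) {
      idx <- which(abs(ax[[a]] - p[a]) <= 4 * psf_sigma)
      list(idx = idx, w = exp(-(ax[[a]][idx] - p[a])^2 / (2 * psf_sigma^2)))
    })
    if (any(vapply(g, function(e) length(e$idx) == 0L, logical(1)))) next
    blob <- amplitude * (g[[1]]$w %o% g[[2]]$w %o% g[[3]]$w)
    stack[g[[1]]$idx, g[[2]]$idx, g[[3]]$idx] <-
      stack[g[[1]]$idx, g[[2]]$idx, g[[3]]$idx] + blob
  }
  if (noise == "poisson") {
    stack <- array(stats::rpois(length(stack), lambda = stack), dim = dims)
  }
  list(stack = stack, centers = positions, voxel_size = voxel_size,
       origin = origin)
}

#' Write / read a 3D stack as multi-page TIFF
#'
#' Pages are z-planes; intensities are scaled to [0, 1] on write (the
#' scale factor is returned as an attribute on read, intensities being
#' relative in this pipeline).
#'
#' @param stack 3D array (x, y, z).
#' @param path File path.
#' @export
write_stack_tiff <- function(stack, path) {
  mx <- max(stack, 1e-12)
  pages <- lapply(seq_len(dim(stack)[3]), function(k) t(stack[, , k]) / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages))
  stack <- array(0, dim = dims)
  for (k in seq_along(pages)) stack[, , k] <- t(pages[[k]])
  stack
}
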