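# Separable Gaussian smoothing of a 3D array; sigma in voxels per axis.
gauss_smooth3 <- function(stack, sigma) {
  dims <- dim(stack)
  for (a in 1:3) {
    s <- sigma[a]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2))
    k <- k / sum(k)
    n <- dims[a]
    # dense band matrix applied along axis a (replicate-edge padding)
    K <- matrix(0, n, n)
    for (o in seq(-r, r)) {
      idx <- seq_len(n)
      src <- pmin(pmax(idx + o, 1L), n)
      K[cbind(idx, src)] <- K[cbind(idx, src)] + k[o + r + 1L]
    }
    perm <- c(a, setdiff(1:3, a))
    m <- matrix(aperm(stack, perm), nrow = dims[a])
    m <- K %*% m
    stack <- aperm(array(m, dim = dims[perm]), order(perm))
  }
  stack
}

# Second difference along an axis (replicate-edge), scaled by 1/h^2.
second_diff3 <- function(stack, a, h) {
  dims <- dim(stack)
  n <- dims[a]
  up <- pmin(seq_len(n) + 1L, n)
  dn <- pmax(seq_len(n) - 1L, 1L)
  ix <- function(ord) {
    idx <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
    idx[[a]] <- ord
    do.call(`[`, c(list(stack), idx, list(drop = FALSE)))
  }
  (ix(up) - 2 * stack + ix(dn)) / h^2
}

#' Detect nuclear spots in a 3D image stack
#'
#' Blob detection at a single scale: the stack is smoothed with a Gaussian
#' of sigma = `diameter` / 2.355 (per axis, in voxels, so anisotropic
#' voxels are handled), the scale-normalised negative Laplacian response is
#' computed, and strict local maxima over the 26-neighbourhood whose
#' smoothed intensity exceeds `min_intensity` become spots.  Spot centres
#' are refined to sub-voxel precision by a 3-point quadratic fit per axis
#' on the response.
#'
#' The defaults (4 um estimated cell diameter, zero minimum intensity) are
#' the detection settings that give accurate PSM nuclear counts; blobs
#' closer together than about the diameter merge into one detection.
#'
#' @param stack 3D intensity array (x, y, z) or the list returned by
#'   [render_nuclei_image()].
#' @param voxel_size Length-3 (or scalar) voxel size in micrometres.
#' @param diameter Estimated nuclear diameter in micrometres.
#' @param min_intensity Minimum smoothed fluorescence intensity.
#' @param origin World coordinate of the stack corner (micrometres).
#' @return A spot table: `spot_id, frame, x_um, y_um, z_um, intensity`.
#' @export
detect_spots <- function(stack, voxel_size = c(1, 1, 1), diameter = 4,
                         min_intensity = 0, origin = c(0, 0, 0)) {
  if (is.list(stack)) {
    voxel_size <- stack$voxel_size
    origin <- stack$origin
    stack <- stack$stack
  }
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (any(voxel_size <= 0)) stop("voxel size must be positive")
  empty <- data.frame(spot_id = integer(0), frame = integer(0),
                      x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                      intensity = numeric(0))
  if (length(stack) == 0 || max(stack) == min(stack)) return(empty)

  sigma_um <- diameter / 2.355
  sm <- gauss_smooth3(stack, sigma_um / voxel_size)
  resp <- -(second_diff3(sm, 1, voxel_size[1]) +
              second_diff3(sm, 2, voxel_size[2]) +
              second_diff3(sm, 3, voxel_size[3])) * sigma_um^2

  dims <- dim(resp)
  # strict local maxima over the 26-neighbourhood (interior voxels)
  shift <- function(arr, d) {
    idx <- lapply(1:3, function(a) {
      i <- seq_len(dims[a]) + d[a]
      pmin(pmax(i, 1L), dims[a])
    })
    do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  }
  # ties on exact plateaus are broken toward the lower voxel index: the
  # comparison is >= toward lexicographically positive offsets, > otherwise
  is_max <- array(TRUE, dims)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    lex_pos <- dx > 0 || (dx == 0 && (dy > 0 || (dy == 0 && dz > 0)))
    sh <- shift(resp, c(dx, dy, dz))
    is_max <- is_max & if (lex_pos) resp >= sh else resp > sh
  }
  # exclude border voxels (edge padding makes their neighbourhood degenerate)
  border <- array(FALSE, dims)
  border[c(1, dims[1]), , ] <- TRUE
  border[, c(1, dims[2]), ] <- TRUE
  border[, , c(1, dims[3])] <- TRUE
  cand <- which(is_max & !border & resp > 0 & sm >= min_intensity, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)

  # sub-voxel refinement: 3-point quadratic per axis on the response
  centers <- matrix(NA_real_, nrow(cand), 3L)
  for (r in seq_len(nrow(cand))) {
    v <- cand[r, ]
    for (a in 1:3) {
      im <- v; ip <- v
      im[a] <- v[a] - 1L; ip[a] <- v[a] + 1L
      fm <- resp[matrix(im, 1)]; f0 <- resp[matrix(v, 1)]; fp <- resp[matrix(ip, 1)]
      denom <- fm - 2 * f0 + fp
      off <- if (denom < 0) 0.5 * (fm - fp) / denom else 0
      off <- max(-0.5, min(0.5, off))
      centers[r, a] <- origin[a] + (v[a] - 0.5 + off) * voxel_size[a]
    }
  }
  ord <- order(centers[, 1], centers[, 2], centers[, 3])
  data.frame(spot_id = seq_len(nrow(cand)), frame = 0L,
             x_um = centers[ord, 1], y_um = centers[ord, 2],
             z_um = centers[ord, 3],
             intensity = sm[cand[ord, , drop = FALSE]])
}
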