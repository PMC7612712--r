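#' Construct a contour stack
#'
#' A contour stack describes one tissue or one cell surface as planar
#' polygons drawn at successive z positions (the manual-contour surface
#' representation).  Volumes are obtained by integrating polygon area over
#' z, see [contour_volume()].
#'
#' @param slices List of slices, each a list with elements `z` (micrometres)
#'   and `xy` (an n x 2 matrix of polygon vertices in micrometres).
#' @param tissue_label Optional label ("psm", "somite", "cell", ...).
#' @param stage Somite stage the stack was measured at.
#' @return An object of class `contour_stack`.
#' @export
contour_stack <- function(slices, tissue_label = "", stage = NA_real_) {
  if (length(slices) < 2L) stop("a contour stack needs at least 2 slices")
  z <- vapply(slices, function(s) as.numeric(s$z), numeric(1))
  if (any(diff(z) <= 0)) stop("slice z positions must be strictly increasing")
  for (s in slices) {
    xy <- s$xy
    if (!is.matrix(xy) || ncol(xy) != 2L || nrow(xy) < 3L)
      stop("each polygon needs >= 3 (x, y) vertices")
    if (!polygon_is_simple(xy))
      stop(sprintf("self-intersecting polygon at z = %g", s$z))
  }
  structure(list(tissue_label = tissue_label, stage = stage, slices = slices),
            class = "contour_stack")
}

#' Shoelace area of a planar polygon
#'
#' @param xy n x 2 vertex matrix (closing edge implicit).
#' @return Unsigned area.
#' @export
polygon_area <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  j <- c(seq_len(nrow(xy))[-1L], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Simple-polygon test: no two non-adjacent edges intersect.
polygon_is_simple <- function(xy) {
  n <- nrow(xy)
  if (n < 3L) return(FALSE)
  a <- xy
  b <- xy[c(2:n, 1L), , drop = FALSE]
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
    d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
    d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2L)) {
    jj <- (i + 2L):n
    jj <- jj[!(i == 1L & jj == n)]  # skip adjacent (closing) edge
    for (j in jj) {
      if (seg_int(a[i, ], b[i, ], a[j, ], b[j, ])) return(FALSE)
    }
  }
  TRUE
}

#' Volume of a contour stack
#'
#' Trapezoidal integration of polygon area over z:
#' `sum((A_i + A_{i+1}) / 2 * (z_{i+1} - z_i))`, with areas from the
#' shoelace formula.  Exact for prisms; approximates smooth surfaces as
#' sampled by sparse contours.
#'
#' @param stack A [contour_stack()].
#' @return Volume in cubic micrometres.
#' @export
contour_volume <- function(stack) {
  stopifnot(inherits(stack, "contour_stack"))
  z <- vapply(stack$slices, `[[`, numeric(1), "z")
  A <- vapply(stack$slices, function(s) polygon_area(s$xy), numeric(1))
  n <- length(z)
  sum((A[-n] + A[-1L]) / 2 * diff(z))
}

#' Curved midline length through ordered waypoints
#'
#' Sum of Euclidean segment lengths through the waypoints; used for
#' two-segment curved tissue lengths (posterior medial face -> progenitor
#' boundary -> anterior PSM face).  Duplicate consecutive points contribute
#' zero length.
#'
#' @param waypoints n x 3 matrix of 3D points (micrometres), n >= 2.
#' @return Length in micrometres.
#' @export
midline_length <- function(waypoints) {
  waypoints <- as.matrix(waypoints)
  if (nrow(waypoints) < 2L) stop("need at least 2 waypoints")
  sum(sqrt(rowSums(diff(waypoints)^2)))
}

#' Cross-section height and width of a contour stack
#'
#' Measures the dorsoventral (height) and mediolateral (width) extent of
#' the tissue cross-section at the anteroposterior midpoint of a region,
#' along supplied local anatomical axes.  Contour vertices are transformed
#' into the local frame; vertices within a band around the region's AP
#' midpoint form the cross-section.
#'
#' @param stack A [contour_stack()].  Slice vertices `(x, y)` at height `z`
#'   are treated as world points `(x, y, z)`.
#' @param region_bounds Length-2 AP interval (local frame coordinates).
#' @param frame List with `origin` (length-3) and `axes` (3 x 3 matrix whose
#'   columns are the AP, DV and ML unit vectors).  Defaults to the identity
#'   frame (AP = x, DV = y, ML = z).
#' @param band_frac Half-width of the sampling band as a fraction of the
#'   region extent.
#' @return Named numeric vector `c(height =, width =)` in micrometres.
#' @export
region_dimensions <- function(stack, region_bounds,
                              frame = list(origin = c(0, 0, 0), axes = diag(3)),
                              band_frac = 0.05) {
  stopifnot(inherits(stack, "contour_stack"), length(region_bounds) == 2L)
  pts <- do.call(rbind, lapply(stack$slices, function(s)
    cbind(s$xy, s$z)))
  loc <- t(t(frame$axes) %*% (t(pts) - frame$origin))
  mid <- mean(region_bounds)
  half <- band_frac * abs(diff(region_bounds))
  sel <- abs(loc[, 1L] - mid) <= half
  if (!any(sel)) stop("empty cross-section: no contour vertices near the region midpoint")
  c(height = diff(range(loc[sel, 2L])), width = diff(range(loc[sel, 3L])))
}

#' Read / write contour stacks as JSON
#'
#' @param path File path.
#' @param stacks A list of [contour_stack()] objects.
#' @return `read_contours_json` returns a list of contour stacks.
#' @export
write_contours_json <- function(stacks, path) {
  payload <- lapply(stacks, function(st) list(
    tissue_label = st$tissue_label, stage = st$stage,
    slices = lapply(st$slices, function(s)
      list(z = s$z, x = s$xy[, 1L], y = s$xy[, 2L]))
  ))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_contours_json
#' @export
read_contours_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  lapply(payload, function(st) contour_stack(
    slices = lapply(st$slices, function(s)
      list(z = s$z, xy = cbind(s$x, s$y))),
    tissue_label = st$tissue_label,
    stage = if (is.null(st$stage)) NA_real_ else st$stage
  ))
}
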