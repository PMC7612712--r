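#' k-nearest-neighbour set of a cell at one frame
#'
#' The k cells with the smallest Euclidean distance to the target; distance
#' ties resolve to the lower cell id.
#'
#' @param positions Data.frame or matrix with columns `id, x, y, z` (any
#'   coordinate column names of length 3 after the id).
#' @param target_id Id of the focal cell.
#' @param k Neighbourhood size (>= 1); at least k + 1 cells must be present.
#' @return Vector of k neighbour ids.
#' @export
knn_neighbourhood <- function(positions, target_id, k) {
  positions <- as.data.frame(positions)
  ids <- positions[[1L]]
  P <- as.matrix(positions[, 2:4])
  if (nrow(P) < k + 1L) stop("need at least k + 1 cells")
  ti <- which(ids == target_id)
  if (length(ti) != 1L) stop("target id not present exactly once")
  d <- sqrt(colSums((t(P) - P[ti, ])^2))
  ord <- order(d, ids)
  ord <- ord[ord != ti]
  ids[ord[seq_len(k)]]
}

# kNN id sets for many targets at one frame; D computed blockwise.
knn_sets_frame <- function(ids, P, target_idx, k) {
  n <- nrow(P)
  out <- vector("list", length(target_idx))
  for (m in seq_along(target_idx)) {
    i <- target_idx[m]
    d <- sqrt(colSums((t(P) - P[i, ])^2))
    ord <- order(d, ids)
    ord <- ord[ord != i]
    out[[m]] <- ids[ord[seq_len(k)]]
  }
  out
}

#' Neighbourhood-exchange counts (tissue fluidity)
#'
#' For each evaluated cell, counts the new cells entering its
#' k-nearest-neighbour set over a time window -- a proxy for local tissue
#' fluidity / cell mixing.  Two counting modes:
#' \describe{
#'   \item{cumulative_entrants (default)}{distinct ids appearing in the
#'     kNN set at any frame in `(t0, t0 + window]` that were absent at t0
#'     (cells that transit the neighbourhood and leave again still count);}
#'   \item{endpoint_difference}{ids in the kNN set at `t0 + window` absent
#'     at t0.}
#' }
#' Cells not observed over their full window are excluded and reported in
#' the `excluded` attribute.
#'
#' @param tracks A [track_set()] in tissue-frame (or local) coordinates.
#' @param k Neighbourhood size.
#' @param window_min Window length in minutes.
#' @param frame_interval Minutes per frame.
#' @param mode Counting mode, see above.
#' @param start_frame `"first"` (each cell evaluated from its first
#'   observed frame) or an integer frame applying to all cells.
#' @param cells Optional subset of cell ids to evaluate.
#' @return Data.frame `(track_id, start_ap, count)`; `start_ap` is the
#'   cell's AP (`x_um`) position at its evaluation start.
#' @export
neighbour_exchange <- function(tracks, k = 10, window_min = 60,
                               frame_interval = 1,
                               mode = c("cumulative_entrants",
                                        "endpoint_difference"),
                               start_frame = "first", cells = NULL) {
  mode <- match.arg(mode)
  wf <- round(window_min / frame_interval)
  if (wf < 1L) stop("window shorter than one frame")
  by_frame <- split(tracks[, c("track_id", "x_um", "y_um", "z_um")],
                    tracks$frame)
  frames_avail <- as.integer(names(by_frame))

  first_frame <- tapply(tracks$frame, tracks$track_id, min)
  ids_all <- names(first_frame)
  eval_ids <- if (is.null(cells)) ids_all else as.character(cells)
  t0s <- if (identical(start_frame, "first"))
    as.integer(first_frame[eval_ids]) else rep(as.integer(start_frame),
                                               length(eval_ids))

  res <- vector("list", length(eval_ids)); excl <- character(0)
  for (m in seq_along(eval_ids)) {
    id <- eval_ids[m]; t0 <- t0s[m]
    fr_needed <- t0:(t0 + wf)
    ok <- all(fr_needed %in% frames_avail)
    if (ok) {
      present <- vapply(as.character(fr_needed), function(f)
        id %in% by_frame[[f]]$track_id, logical(1))
      ok <- all(present)
    }
    if (!ok) { excl <- c(excl, id); next }
    knn_at <- function(f) {
      df <- by_frame[[as.character(f)]]
      knn_neighbourhood(df, id, k)
    }
    base <- knn_at(t0)
    newc <- if (mode == "endpoint_difference") {
      setdiff(knn_at(t0 + wf), base)
    } else {
      seen <- character(0)
      for (f in (t0 + 1L):(t0 + wf)) seen <- union(seen, knn_at(f))
      setdiff(seen, base)
    }
    df0 <- by_frame[[as.character(t0)]]
    res[[m]] <- data.frame(track_id = id,
                           start_ap = df0$x_um[df0$track_id == id],
                           count = length(newc))
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(track_id = character(0), start_ap = numeric(0),
                      count = integer(0))
  attr(out, "excluded") <- excl
  out
}

#' Signed elevation angle of a cell pair relative to the AP axis
#'
#' The angle between the pair vector and the transverse (DV-ML) plane:
#' +/-90 degrees for separation purely along the AP axis (the pair lies
#' parallel to the AP axis), 0 degrees for separation within the
#' transverse plane (perpendicular to the AP axis).  Magnitude is
#' `asin(|AP component| / norm)`; the sign is carried by the DV component
#' of the pair vector (an arbitrary but fixed convention -- only absolute
#' angle changes enter downstream comparisons).
#'
#' @param p_a,p_b Points in local AP/DV/ML coordinates (length 3, or n x 3
#'   matrices for vectorised use).
#' @return Signed angle(s) in degrees, in [-90, 90].
#' @export
pair_elevation_angle <- function(p_a, p_b) {
  A <- matrix(as.numeric(p_a), ncol = 3L)
  B <- matrix(as.numeric(p_b), ncol = 3L)
  v <- B - A
  nrm <- sqrt(rowSums(v^2))
  if (any(nrm == 0)) stop("zero-length pair vector")
  ang <- asin(pmin(1, abs(v[, 1L]) / nrm)) * 180 / pi
  ang * ifelse(v[, 2L] < 0, -1, 1)
}

# Projected pair angle in the AP-DV plane, folded to (-90, 90] so it is
# independent of pair orientation.  num/den select the numerator/denominator
# components: (dv, ap) gives the "DV angle" (0 = parallel to the AP axis),
# (ap, dv) the "AP angle" (0 = perpendicular, i.e. along DV).
projected_pair_angle <- function(v, num, den) {
  a <- atan2(v[, num], v[, den]) * 180 / pi
  a[a > 90] <- a[a > 90] - 180
  a[a <= -90] <- a[a <= -90] + 180
  a
}

wrap_half_turn <- function(d) {
  ((d + 90) %% 180) - 90
}

#' Neighbour-pair angle-change analysis
#'
#' For each cell present at the start frame, takes its nearest neighbour
#' and follows the orientation of the pair vector over the window
#' (regardless of whether the two cells are still neighbours at the end).
#' Pairs are deduplicated as unordered pairs.
#'
#' Two angle parametrizations of the pair vector projected into the AP-DV
#' plane are used, each appropriate to one class of pairs:
#' \describe{
#'   \item{DV angle}{`atan2(DV, AP)`, 0 degrees = pair parallel to the AP
#'     axis.  Pairs with |DV angle| < 45 at the start are the *parallel*
#'     class and their `change` is the (wrapped) change of this angle.}
#'   \item{AP angle}{`atan2(AP, DV)`, 0 degrees = pair perpendicular to
#'     the AP axis (lying along DV).  Pairs with |AP angle| < 45 at the
#'     start are the *perpendicular* class and their `change` is the
#'     change of this angle.}
#' }
#' The two parametrizations are exact mirror images, so each class is
#' measured as the deviation from its own reference orientation.  This
#' makes the null (non-directional rearrangement) well calibrated: under
#' isotropic motion the two change distributions are symmetric by the
#' AP-DV mirror, whereas a single shared angle would compare
#' near-pole pairs with near-plane pairs, whose change distributions
#' differ for purely geometric reasons.  Under directional intercalation
#' perpendicular pairs reorient toward the AP axis (large AP-angle
#' changes) while parallel pairs stay put -- the two distributions then
#' separate.  |DV angle| = 45 exactly is excluded.
#'
#' The 3D elevation angle of each pair ([pair_elevation_angle()]) is also
#' reported at both timepoints (columns `angle_t0`, `angle_t1`;
#' +/-90 = parallel to AP, 0 = transverse).
#'
#' @param tracks A [track_set()] in local AP/DV/ML coordinates.
#' @param window_min Window in minutes.
#' @param frame_interval Minutes per frame.
#' @param start_frame Frame at which neighbours are defined (default: the
#'   first frame present).
#' @return Data.frame of pair records: `id_a, id_b, angle_t0, angle_t1,
#'   dv_angle_t0, ap_angle_t0, change, initial_class`.
#' @export
angle_change_analysis <- function(tracks, window_min = 60, frame_interval = 1,
                                  start_frame = NULL) {
  wf <- round(window_min / frame_interval)
  t0 <- if (is.null(start_frame)) min(tracks$frame) else start_frame
  t1 <- t0 + wf
  at0 <- tracks[tracks$frame == t0, ]
  at1 <- tracks[tracks$frame == t1, ]
  common <- intersect(at0$track_id, at1$track_id)
  if (length(common) < 2L) {
    warning("no pairs survive the window")
    return(data.frame(id_a = character(0), id_b = character(0),
                      angle_t0 = numeric(0), angle_t1 = numeric(0),
                      dv_angle_t0 = numeric(0), ap_angle_t0 = numeric(0),
                      change = numeric(0), initial_class = character(0)))
  }
  at0 <- at0[at0$track_id %in% common, ]
  at1 <- at1[match(at0$track_id, at1$track_id), ]
  P0 <- as.matrix(at0[, c("x_um", "y_um", "z_um")])
  P1 <- as.matrix(at1[, c("x_um", "y_um", "z_um")])
  ids <- at0$track_id

  pairs <- matrix(NA_integer_, length(ids), 2L)
  for (i in seq_along(ids)) {
    d <- sqrt(colSums((t(P0) - P0[i, ])^2))
    ord <- order(d, ids)
    j <- ord[ord != i][1L]
    pairs[i, ] <- c(i, j)
  }
  key <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  pairs <- pairs[!duplicated(key), , drop = FALSE]

  v0 <- P0[pairs[, 2], , drop = FALSE] - P0[pairs[, 1], , drop = FALSE]
  v1 <- P1[pairs[, 2], , drop = FALSE] - P1[pairs[, 1], , drop = FALSE]
  a0 <- pair_elevation_angle(P0[pairs[, 1], , drop = FALSE],
                             P0[pairs[, 2], , drop = FALSE])
  a1 <- pair_elevation_angle(P1[pairs[, 1], , drop = FALSE],
                             P1[pairs[, 2], , drop = FALSE])
  dv0 <- projected_pair_angle(v0, 2L, 1L)
  dv1 <- projected_pair_angle(v1, 2L, 1L)
  ap0 <- projected_pair_angle(v0, 1L, 2L)
  ap1 <- projected_pair_angle(v1, 1L, 2L)
  cls <- ifelse(abs(dv0) < 45, "parallel",
                ifelse(abs(dv0) > 45, "perpendicular", "excluded"))
  ch <- ifelse(cls == "parallel", wrap_half_turn(dv1 - dv0),
               wrap_half_turn(ap1 - ap0))
  data.frame(id_a = ids[pairs[, 1]], id_b = ids[pairs[, 2]],
             angle_t0 = a0, angle_t1 = a1,
             dv_angle_t0 = dv0, ap_angle_t0 = ap0,
             change = ch, initial_class = cls)
}

# Asymptotic two-sided Kolmogorov p-value: Q(lambda) = 2 sum (-1)^(k-1) exp(-2 k^2 lambda^2)
kolmogorov_p <- function(d, n_eff) {
  lam <- sqrt(n_eff) * d
  if (lam < 1e-8) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lam^2))
  min(1, max(0, p))
}

#' Two-sample Kolmogorov-Smirnov comparison of angle-change distributions
#'
#' Compares the absolute angle-change distributions of the initially
#' parallel and initially perpendicular pair classes.  D is the maximum
#' absolute difference of the two empirical CDFs; the two-sided p-value
#' comes from the asymptotic Kolmogorov distribution with effective sample
#' size `n_a * n_b / (n_a + n_b)`.
#'
#' @param records Output of [angle_change_analysis()], or a list with
#'   numeric elements `a` and `b` to compare directly.
#' @return List of class `ks_result`: `d`, `p`, `n_a`, `n_b`.
#' @export
compare_angle_distributions <- function(records) {
  if (is.data.frame(records)) {
    a <- abs(records$change[records$initial_class == "parallel"])
    b <- abs(records$change[records$initial_class == "perpendicular"])
  } else {
    a <- records$a; b <- records$b
  }
  if (length(a) == 0L || length(b) == 0L)
    stop("both classes must be non-empty")
  n_a <- length(a); n_b <- length(b)
  grid <- sort(unique(c(a, b)))
  Fa <- vapply(grid, function(t) mean(a <= t), numeric(1))
  Fb <- vapply(grid, function(t) mean(b <= t), numeric(1))
  d <- max(abs(Fa - Fb))
  structure(list(d = d, p = kolmogorov_p(d, n_a * n_b / (n_a + n_b)),
                 n_a = n_a, n_b = n_b),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("Two-sample KS: D = %.6g, p = %.4g (n_a = %d, n_b = %d)\n",
              x$d, x$p, x$n_a, x$n_b))
  invisible(x)
}

#' Convergence regression of displacement on start position
#'
#' Ordinary least squares of per-track displacement along the DV or ML
#' axis over a window against the track's start position along the same
#' axis (positions relative to the midline, tailbud-tip reference frame).
#' A negative slope means convergence: cells on either side of the midline
#' displace toward it.
#'
#' @param tracks A [track_set()] in local AP/DV/ML coordinates.
#' @param axis `"DV"` or `"ML"`.
#' @param window_min Window in minutes (120 by default).
#' @param frame_interval Minutes per frame.
#' @param ap_range Optional length-2 AP interval; only tracks starting
#'   inside it qualify (posterior-PSM selection).
#' @return List of class `regression_fit`: `slope`, `intercept`, `r2`, `n`.
#' @export
convergence_regression <- function(tracks, axis = c("DV", "ML"),
                                   window_min = 120, frame_interval = 1,
                                   ap_range = NULL) {
  axis <- match.arg(axis)
  ax <- c(DV = "y_um", ML = "z_um")[[axis]]
  wf <- round(window_min / frame_interval)
  rows <- lapply(split(tracks, tracks$track_id), function(tr) {
    f0 <- min(tr$frame); f1 <- f0 + wf
    if (!(f1 %in% tr$frame)) return(NULL)
    if (!is.null(ap_range)) {
      ap0 <- tr$x_um[tr$frame == f0]
      if (ap0 < ap_range[1] || ap0 > ap_range[2]) return(NULL)
    }
    data.frame(start = tr[[ax]][tr$frame == f0],
               disp = tr[[ax]][tr$frame == f1] - tr[[ax]][tr$frame == f0])
  })
  d <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(d) || nrow(d) < 3L)
    stop("fewer than 3 tracks span the window")
  fit <- stats::lm(disp ~ start, data = d)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((d$disp - mean(d$disp))^2)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r2 = if (tss > 0) 1 - rss / tss else NA_real_,
                 n = nrow(d)),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("y = %.4g*x + %.4g (R2 = %.3g, n = %d)\n",
              x$slope, x$intercept, x$r2, x$n))
  invisible(x)
}
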