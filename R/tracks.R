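#' Construct a track set
#'
#' Tracks are id-linked time-indexed 3D points.  The canonical schema is
#' `track_id, frame, t_min, x_um, y_um, z_um` plus an optional `region`
#' column; frames within a track are strictly increasing and may contain
#' gaps (closed by the tracker up to its configured gap size).
#'
#' @param df Data.frame with at least `track_id, frame, x_um, y_um, z_um`.
#' @param frame_interval Minutes per frame; used to fill `t_min` if absent.
#' @return The data.frame, validated, with class `track_set` prepended.
#' @export
track_set <- function(df, frame_interval = NA_real_) {
  need <- c("track_id", "frame", "x_um", "y_um", "z_um")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing track columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(as.matrix(df[, c("x_um", "y_um", "z_um")]))))
    stop("track coordinates must be finite")
  df <- df[order(df$track_id, df$frame), , drop = FALSE]
  if (any(stats::ave(df$frame, df$track_id, FUN = function(f) c(1, diff(f))) <= 0))
    stop("frames must be strictly increasing within each track")
  if (!"t_min" %in% names(df) && !is.na(frame_interval))
    df$t_min <- df$frame * frame_interval
  rownames(df) <- NULL
  class(df) <- unique(c("track_set", class(df)))
  df
}

#' Read / write tracks as CSV
#'
#' Schema: `track_id, frame, t_min, x_um, y_um, z_um, region` (the last two
#' optional on read).
#'
#' @param tracks A [track_set()].
#' @param path File path.
#' @export
write_tracks_csv <- function(tracks, path) {
  utils::write.csv(as.data.frame(tracks), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  track_set(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Select paraxial-mesoderm tracks
#'
#' Drops tracks that ever cross the embryo midline or enter a named
#' exclusion region (notochord, neural tube).  The test is strict-interior:
#' a track point lying exactly on a mask surface or on the midline plane is
#' retained.
#'
#' @param tracks A [track_set()].
#' @param midline_plane List with `point` (length 3) and `normal`
#'   (length 3); positions with `dot(p - point, normal) > 0` are past the
#'   midline.  `NULL` to skip.
#' @param exclusion_masks List of masks, each a list with `type = "box"`,
#'   `min`, `max` (length-3 corners) and optional `frames = c(first, last)`
#'   restricting when the mask applies.
#' @return The retained tracks; excluded track ids in the `excluded`
#'   attribute.
#' @export
select_paraxial_tracks <- function(tracks, midline_plane = NULL,
                                   exclusion_masks = list()) {
  P <- as.matrix(tracks[, c("x_um", "y_um", "z_um")])
  bad <- rep(FALSE, nrow(tracks))
  if (!is.null(midline_plane)) {
    d <- (P - matrix(midline_plane$point, nrow(P), 3, byrow = TRUE)) %*%
      midline_plane$normal
    bad <- bad | as.vector(d) > 0
  }
  for (m in exclusion_masks) {
    if (!identical(m$type, "box")) stop("unsupported mask type: ", m$type)
    inside <- P[, 1] > m$min[1] & P[, 1] < m$max[1] &
      P[, 2] > m$min[2] & P[, 2] < m$max[2] &
      P[, 3] > m$min[3] & P[, 3] < m$max[3]
    if (!is.null(m$frames))
      inside <- inside & tracks$frame >= m$frames[1] & tracks$frame <= m$frames[2]
    bad <- bad | inside
  }
  bad_ids <- unique(tracks$track_id[bad])
  out <- tracks[!(tracks$track_id %in% bad_ids), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- bad_ids
  out
}

#' Track-duration versus start-position control
#'
#' Pearson correlation between track duration and track start AP position.
#' A strong correlation would confound neighbour-exchange gradients (short
#' tracks in one region inflate apparent new-neighbour counts), so the
#' expectation for a clean dataset is |r| near 0.
#'
#' @param tracks A [track_set()] (>= 3 tracks); AP is the `x_um` column.
#' @param frame_interval Minutes per frame (durations reported in minutes).
#' @return List `r`, `p`, `n`, `constant` (TRUE when durations have zero
#'   variance, in which case r is reported as 0 and p as NA).
#' @export
track_qc_duration_vs_position <- function(tracks, frame_interval = 1) {
  agg <- do.call(rbind, lapply(split(tracks, tracks$track_id), function(tr) {
    data.frame(duration = (max(tr$frame) - min(tr$frame)) * frame_interval,
               start_ap = tr$x_um[which.min(tr$frame)])
  }))
  if (nrow(agg) < 3L) stop("need at least 3 tracks")
  if (stats::sd(agg$duration) == 0 || stats::sd(agg$start_ap) == 0)
    return(list(r = 0, p = NA_real_, n = nrow(agg), constant = TRUE))
  ct <- stats::cor.test(agg$start_ap, agg$duration, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(agg), constant = FALSE)
}
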