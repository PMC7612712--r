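#' Tracker configuration
#'
#' Parameters of the frame-to-frame linker: the tracking regime used for
#' PSM nuclei is autoregressive motion with gap size 3 and max distance
#' 5 um (6 um for faster-moving movies).
#'
#' @param max_distance Gating radius in micrometres (> 0): candidate links
#'   farther than this from the predicted position are forbidden.
#' @param gap_size Maximum number of consecutive missed frames a track end
#'   is held open for; the search radius grows linearly with the gap.
#' @param motion_model `"autoregressive"` (damped-velocity prediction) or
#'   `"nearest"` (zero-velocity prediction).
#' @param ar_damping Velocity damping factor in [0, 1] for the
#'   autoregressive prediction.
#' @return List of class `tracker_config`.
#' @export
tracker_config <- function(max_distance = 5, gap_size = 3,
                           motion_model = c("autoregressive", "nearest"),
                           ar_damping = 0.5) {
  motion_model <- match.arg(motion_model)
  stopifnot(max_distance > 0, gap_size >= 0,
            ar_damping >= 0, ar_damping <= 1)
  structure(list(max_distance = max_distance, gap_size = as.integer(gap_size),
                 motion_model = motion_model, ar_damping = ar_damping),
            class = "tracker_config")
}

#' Link detected spots into tracks
#'
#' Frame-to-frame linking by globally optimal one-to-one assignment between
#' predicted track positions and observed spots, approximating the
#' autoregressive-motion tracking regime: the prediction for an open track
#' is its last position plus `ar_damping` times its last velocity
#' (times the number of elapsed frames).  Candidates farther than
#' `max_distance * (gap + 1)` from the prediction are forbidden; unmatched
#' track ends are held open for up to `gap_size` frames.  The result is
#' deterministic and invariant to the order of the input spot records
#' (spots are canonically sorted internally); assignment-cost ties resolve
#' to the lower track id.
#'
#' @param spots Spot table (`spot_id, frame, x_um, y_um, z_um`); `(frame,
#'   spot_id)` must be unique.
#' @param config A [tracker_config()].
#' @param frame_interval Minutes per frame, stored in the output `t_min`.
#' @return A [track_set()].
#' @export
link_tracks <- function(spots, config = tracker_config(), frame_interval = 1) {
  stopifnot(inherits(config, "tracker_config"))
  if (anyDuplicated(spots[, c("frame", "spot_id")]))
    stop("duplicate (frame, spot_id) records")
  if (nrow(spots) == 0L)
    return(track_set(data.frame(track_id = integer(0), frame = integer(0),
                                x_um = numeric(0), y_um = numeric(0),
                                z_um = numeric(0))))
  # canonical order for permutation invariance
  spots <- spots[order(spots$frame, spots$x_um, spots$y_um, spots$z_um,
                       spots$spot_id), , drop = FALSE]
  frames <- sort(unique(spots$frame))
  BIG <- 1e9

  tracks <- list()   # each: id, pos, vel, last_frame, gap, rows (list of df rows)
  next_id <- 1L
  out <- list()

  open_new <- function(P, f) {
    for (r in seq_len(nrow(P))) {
      tracks[[length(tracks) + 1L]] <<- list(
        id = next_id, pos = P[r, ], vel = c(0, 0, 0), last_frame = f, gap = 0L)
      out[[length(out) + 1L]] <<- data.frame(
        track_id = next_id, frame = f, x_um = P[r, 1], y_um = P[r, 2],
        z_um = P[r, 3])
      next_id <<- next_id + 1L
    }
  }

  first <- TRUE
  for (f in frames) {
    P <- as.matrix(spots[spots$frame == f, c("x_um", "y_um", "z_um"),
                         drop = FALSE])
    if (first) { open_new(P, f); first <- FALSE; next }

    nT <- length(tracks); nS <- nrow(P)
    if (nT == 0L) { open_new(P, f); next }

    pred <- matrix(NA_real_, nT, 3L)
    gate <- numeric(nT)
    for (i in seq_len(nT)) {
      tr <- tracks[[i]]
      dt <- f - tr$last_frame
      damp <- if (config$motion_model == "autoregressive") config$ar_damping else 0
      pred[i, ] <- tr$pos + damp * tr$vel * dt
      gate[i] <- config$max_distance * dt   # radius grows linearly with gap
    }
    D <- sqrt(outer(rowSums(pred^2), rowSums(P^2), "+") - 2 * pred %*% t(P))
    D[is.na(D) | D < 0] <- 0
    ALT <- max(gate) + 1e-6

    n <- nT + nS
    C <- matrix(BIG, n, n)
    ids <- vapply(tracks, `[[`, integer(1), "id")
    cost <- D + outer(ids, rep(1, nS)) * 1e-9  # tie-break toward lower id
    cost[D > gate] <- BIG
    C[seq_len(nT), seq_len(nS)] <- cost
    C[cbind(seq_len(nT), nS + seq_len(nT))] <- ALT      # track unmatched
    C[cbind(nT + seq_len(nS), seq_len(nS))] <- ALT      # spot -> new track
    C[nT + seq_len(nS), nS + seq_len(nT)] <- 0          # dummy-dummy
    assign <- lap_solve(C)

    matched_spots <- rep(FALSE, nS)
    keep <- logical(nT)
    for (i in seq_len(nT)) {
      j <- assign[i]
      tr <- tracks[[i]]
      if (j <= nS && C[i, j] < BIG) {
        dt <- f - tr$last_frame
        newpos <- P[j, ]
        tracks[[i]] <- list(id = tr$id, pos = newpos,
                            vel = (newpos - tr$pos) / dt,
                            last_frame = f, gap = 0L)
        out[[length(out) + 1L]] <- data.frame(
          track_id = tr$id, frame = f, x_um = newpos[1], y_um = newpos[2],
          z_um = newpos[3])
        matched_spots[j] <- TRUE
        keep[i] <- TRUE
      } else {
        tracks[[i]]$gap <- f - tr$last_frame
        keep[i] <- tracks[[i]]$gap <= config$gap_size
      }
    }
    tracks <- tracks[keep]
    if (any(!matched_spots))
      open_new(P[!matched_spots, , drop = FALSE], f)
  }
  res <- do.call(rbind, out)
  track_set(res, frame_interval = frame_interval)
}

#' Fraction of ground-truth links recovered by a tracker
#'
#' Matches estimated detections to ground-truth positions by proximity
#' (within `tol` micrometres at the same frame) and scores the fraction of
#' ground-truth frame-to-frame links -- consecutive observations of the
#' same true cell no farther apart than `max_gap + 1` frames -- whose two
#' endpoint detections exist and carry the same estimated track id.
#'
#' @param est Estimated [track_set()].
#' @param truth Ground-truth [track_set()].
#' @param tol Matching tolerance in micrometres.
#' @param max_gap Maximum frame gap for a link to count.
#' @return List `recall`, `n_links`, `n_matched`.
#' @export
track_link_recall <- function(est, truth, tol = 1, max_gap = 3) {
  key <- function(f, x, y, z) paste(f, round(x / tol), round(y / tol),
                                    round(z / tol))
  est_id <- new.env(hash = TRUE)
  # exact grid cells claim first; neighbour cells only fill empty slots, so
  # a detection at the query position always wins over a nearby one
  for (r in seq_len(nrow(est))) {
    k <- key(est$frame[r], est$x_um[r], est$y_um[r], est$z_um[r])
    est_id[[k]] <- est$track_id[r]
  }
  for (r in seq_len(nrow(est))) {
    for (kx in -1:1) for (ky in -1:1) for (kz in -1:1) {
      if (kx == 0 && ky == 0 && kz == 0) next
      k <- paste(est$frame[r],
                 round(est$x_um[r] / tol) + kx,
                 round(est$y_um[r] / tol) + ky,
                 round(est$z_um[r] / tol) + kz)
      if (is.null(est_id[[k]])) est_id[[k]] <- est$track_id[r]
    }
  }
  lookup <- function(f, x, y, z) {
    v <- est_id[[key(f, x, y, z)]]
    if (is.null(v)) NA_integer_ else v
  }
  n_links <- 0L; n_matched <- 0L
  for (tr in split(truth, truth$track_id)) {
    tr <- tr[order(tr$frame), ]
    if (nrow(tr) < 2L) next
    for (r in seq_len(nrow(tr) - 1L)) {
      if (tr$frame[r + 1L] - tr$frame[r] > max_gap + 1L) next
      n_links <- n_links + 1L
      a <- lookup(tr$frame[r], tr$x_um[r], tr$y_um[r], tr$z_um[r])
      b <- lookup(tr$frame[r + 1L], tr$x_um[r + 1L], tr$y_um[r + 1L],
                  tr$z_um[r + 1L])
      if (!is.na(a) && !is.na(b) && a == b) n_matched <- n_matched + 1L
    }
  }
  list(recall = if (n_links) n_matched / n_links else NA_real_,
       n_links = n_links, n_matched = n_matched)
}
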