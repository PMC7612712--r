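#' Moving reference frames
#'
#' A reference-frame trajectory is a set of keyframes, each holding an
#' origin (micrometres, world coordinates) and three orthonormal axes
#' mapped to the anatomical axes x = AP, y = DV, z = ML.  Keyframes are
#' interpolated to every movie frame: origins linearly, rotations on the
#' shortest arc (unit-quaternion spherical interpolation, which keeps the
#' intermediate axes orthonormal).  How a commercial tracking suite
#' interpolates rotation between manually placed frames is not documented;
#' slerp is the constant-angular-velocity reading of "linear interpolation"
#' and is the convention adopted here.
#'
#' Sign conventions: +AP points anterior, +DV dorsal, +ML lateral (away
#' from the midline).
#'
#' @param frame Integer vector of keyframe frame indices, strictly
#'   increasing.
#' @param origin n x 3 matrix of keyframe origins.
#' @param axes List of n 3x3 matrices; column i of each is the i-th axis
#'   (AP, DV, ML) expressed in world coordinates.  Axes deviating from
#'   orthonormality by less than 1e-3 are re-orthonormalised (nearest
#'   rotation); larger deviations are an error.
#' @return An object of class `ref_keyframes`.
#' @export
ref_keyframes <- function(frame, origin, axes) {
  origin <- as.matrix(origin)
  stopifnot(length(frame) == nrow(origin), length(axes) == length(frame),
            ncol(origin) == 3L)
  if (any(diff(frame) <= 0)) stop("keyframe frames must be strictly increasing")
  axes <- lapply(seq_along(axes), function(i) {
    R <- as.matrix(axes[[i]])
    dev <- max(abs(crossprod(R) - diag(3)))
    if (dev > 1e-3)
      stop(sprintf("keyframe %d axes deviate from orthonormality by %.2g (> 1e-3)",
                   frame[i], dev))
    if (dev > 1e-6) {
      sv <- svd(R)
      R <- sv$u %*% t(sv$v)
    }
    if (det(R) < 0) stop(sprintf("keyframe %d axes are left-handed", frame[i]))
    R
  })
  structure(list(frame = as.integer(frame), origin = origin, axes = axes),
            class = "ref_keyframes")
}

# ---- quaternion helpers (unit quaternions, w-first) ----

rot_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
           (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
           0.25 * s, (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

quat_to_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

quat_slerp <- function(q0, q1, t) {
  d <- sum(q0 * q1)
  if (d < 0) { q1 <- -q1; d <- -d }  # shortest arc
  if (d > 1 - 1e-10) {
    q <- (1 - t) * q0 + t * q1
    return(q / sqrt(sum(q^2)))
  }
  th <- acos(min(1, d))
  (sin((1 - t) * th) * q0 + sin(t * th) * q1) / sin(th)
}

#' Interpolate reference-frame keyframes to every movie frame
#'
#' Origins are linearly interpolated; rotations by shortest-arc quaternion
#' slerp.  Frames before the first / after the last keyframe are clamped to
#' the nearest keyframe.  At keyframe frames the keyframe transform is
#' reproduced exactly.
#'
#' @param keyframes A [ref_keyframes()] object.
#' @param frames Integer frames to interpolate at; defaults to every frame
#'   spanned by the keyframes.
#' @return An object of class `frame_trajectory`: list with `frame`,
#'   `origin` (n x 3) and `axes` (list of 3x3 rotation matrices).
#' @export
interpolate_frames <- function(keyframes,
                               frames = seq(min(keyframes$frame), max(keyframes$frame))) {
  stopifnot(inherits(keyframes, "ref_keyframes"))
  kf <- keyframes$frame
  quats <- lapply(keyframes$axes, rot_to_quat)
  origin <- matrix(NA_real_, length(frames), 3L)
  axes <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    f <- frames[i]
    if (f <= kf[1L]) {
      origin[i, ] <- keyframes$origin[1L, ]; axes[[i]] <- keyframes$axes[[1L]]
    } else if (f >= kf[length(kf)]) {
      n <- length(kf)
      origin[i, ] <- keyframes$origin[n, ]; axes[[i]] <- keyframes$axes[[n]]
    } else {
      j <- findInterval(f, kf)
      t <- (f - kf[j]) / (kf[j + 1L] - kf[j])
      origin[i, ] <- (1 - t) * keyframes$origin[j, ] + t * keyframes$origin[j + 1L, ]
      axes[[i]] <- if (t == 0) keyframes$axes[[j]]
        else if (t == 1) keyframes$axes[[j + 1L]]
        else quat_to_rot(quat_slerp(quats[[j]], quats[[j + 1L]], t))
    }
  }
  structure(list(frame = as.integer(frames), origin = origin, axes = axes),
            class = "frame_trajectory")
}

frame_index <- function(traj, frames) {
  idx <- match(frames, traj$frame)
  # clamp outside the covered range
  idx[is.na(idx) & frames < traj$frame[1L]] <- 1L
  idx[is.na(idx) & frames > traj$frame[length(traj$frame)]] <- length(traj$frame)
  if (anyNA(idx)) stop("trajectory does not cover all track frames")
  idx
}

#' Transform tracks into local AP/DV/ML coordinates
#'
#' Applies `p_local = R' (p_world - origin)` per frame, where `R` holds the
#' frame's axes as columns.  Removes the global drift and rotation of the
#' tissue so that downstream statistics see anatomical coordinates
#' (x = AP, y = DV, z = ML).
#'
#' @param tracks A track data.frame (see [track_set()]).
#' @param traj A `frame_trajectory` from [interpolate_frames()], covering
#'   all track frames (frames outside the span are clamped).
#' @return Tracks with identical schema, coordinates replaced by local
#'   AP/DV/ML values; attribute `coords` set to `"local"`.
#' @export
transform_to_local <- function(tracks, traj) {
  stopifnot(inherits(traj, "frame_trajectory"))
  idx <- frame_index(traj, tracks$frame)
  P <- as.matrix(tracks[, c("x_um", "y_um", "z_um")])
  out <- P
  for (i in unique(idx)) {
    sel <- idx == i
    out[sel, ] <- (P[sel, , drop = FALSE] -
                     matrix(traj$origin[i, ], sum(sel), 3, byrow = TRUE)) %*%
      traj$axes[[i]]
  }
  tracks[, c("x_um", "y_um", "z_um")] <- out
  attr(tracks, "coords") <- "local"
  tracks
}

#' Transform local-coordinate tracks back to world coordinates
#'
#' Inverse of [transform_to_local()]: `p_world = R p_local + origin`.  Used
#' by the simulator to inject a known global rigid motion.
#'
#' @inheritParams transform_to_local
#' @return Tracks in world coordinates (`coords` attribute `"world"`).
#' @export
transform_to_world <- function(tracks, traj) {
  stopifnot(inherits(traj, "frame_trajectory"))
  idx <- frame_index(traj, tracks$frame)
  P <- as.matrix(tracks[, c("x_um", "y_um", "z_um")])
  out <- P
  for (i in unique(idx)) {
    sel <- idx == i
    out[sel, ] <- P[sel, , drop = FALSE] %*% t(traj$axes[[i]]) +
      matrix(traj$origin[i, ], sum(sel), 3, byrow = TRUE)
  }
  tracks[, c("x_um", "y_um", "z_um")] <- out
  attr(tracks, "coords") <- "world"
  tracks
}

#' Per-track displacement relative to a moving landmark
#'
#' Displacement of each cell along an anatomical axis over a time window,
#' minus the displacement of a reference landmark (tailbud tip, posterior
#' notochord end, or the posterior boundary of the start-of-movie nascent
#' somite) along the same axis over the same window.  Whether cells appear
#' to move "anteriorly" or "posteriorly" depends entirely on the landmark
#' chosen, so the landmark is an explicit input.
#'
#' @param tracks Track data.frame in local AP/DV/ML coordinates.
#' @param landmark Data.frame with columns `frame`, `x_um`, `y_um`, `z_um`
#'   giving the landmark trajectory in the same coordinates.
#' @param axis `"AP"`, `"DV"` or `"ML"`.
#' @param window_min Window length in minutes.
#' @param frame_interval Minutes per frame.
#' @return Data.frame `(track_id, start_position, displacement)`; tracks
#'   shorter than the window are excluded and listed in the
#'   `excluded` attribute.
#' @export
relative_displacement <- function(tracks, landmark, axis = c("AP", "DV", "ML"),
                                  window_min, frame_interval) {
  axis <- match.arg(axis)
  ax <- c(AP = "x_um", DV = "y_um", ML = "z_um")[[axis]]
  wf <- round(window_min / frame_interval)
  ids <- unique(tracks$track_id)
  res <- vector("list", length(ids)); excl <- character(0)
  for (i in seq_along(ids)) {
    tr <- tracks[tracks$track_id == ids[i], ]
    f0 <- min(tr$frame); f1 <- f0 + wf
    if (!(f1 %in% tr$frame)) { excl <- c(excl, as.character(ids[i])); next }
    p0 <- tr[[ax]][tr$frame == f0]; p1 <- tr[[ax]][tr$frame == f1]
    l0 <- landmark[[ax]][landmark$frame == f0]
    l1 <- landmark[[ax]][landmark$frame == f1]
    if (length(l0) != 1L || length(l1) != 1L)
      stop("landmark trajectory must cover the track window")
    res[[i]] <- data.frame(track_id = ids[i], start_position = p0,
                           displacement = (p1 - p0) - (l1 - l0))
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(track_id = character(0), start_position = numeric(0),
                      displacement = numeric(0))
  attr(out, "excluded") <- excl
  out
}

#' Read / write reference-frame keyframes as JSON
#'
#' @param keyframes A [ref_keyframes()] object.
#' @param path File path.
#' @export
write_keyframes_json <- function(keyframes, path) {
  payload <- lapply(seq_along(keyframes$frame), function(i) list(
    frame = keyframes$frame[i],
    origin = keyframes$origin[i, ],
    axes = keyframes$axes[[i]]
  ))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_keyframes_json
#' @export
read_keyframes_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  ref_keyframes(
    frame = vapply(payload, function(k) as.integer(k$frame), integer(1)),
    origin = do.call(rbind, lapply(payload, function(k) as.numeric(k$origin))),
    axes = lapply(payload, function(k) {
      A <- k$axes
      if (is.matrix(A)) A else matrix(unlist(A), 3, 3, byrow = TRUE)
    })
  )
}
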