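#' Simulation configuration
#'
#' Parameters of the synthetic compacting-extending half-PSM.  The
#' geometry is a straight, axis-aligned box whose stage-dependent length,
#' heights and widths follow the reference trendlines
#' ([psm_reference_trendlines()]); the curved tail of the real embryo is
#' represented only through the injected global drift/rotation, since all
#' downstream statistics are frame-relative.  Tissue length is derived as
#' volume divided by the mean of the posterior and anterior cross-section
#' areas (the published length trendline being unusable, see
#' [psm_reference_trendlines()]).
#'
#' @param stage_start,stage_end Integer somite stages (start < end).
#' @param frame_interval Minutes per frame.
#' @param somite_period Minutes between somite formations.
#' @param n_cells_initial Starting PSM cell count; defaults to the
#'   cell-number trendline at `stage_start`.
#' @param motility_posterior,motility_anterior Isotropic random-step scale
#'   (micrometres per square-root minute) at the posterior (AP fraction 0)
#'   and anterior (fraction 1) ends; the per-frame step s.d. per axis is
#'   `motility(u) * sqrt(frame_interval)`.  Posterior must be >= anterior
#'   (the tissue-fluidity gradient).
#' @param convergence_slope_dv,convergence_intercept_dv Coefficients of the
#'   DV displacement-per-120-min field (see [psm_reference_fields()]);
#'   used by [simulate_convergence_tracks()].
#' @param convergence_slope_ml,convergence_intercept_ml ML field
#'   coefficients.
#' @param noise_r2_dv,noise_r2_ml Target coefficient of determination of
#'   the displacement fields, strictly between 0 and 1; field noise
#'   variance is sized analytically as
#'   `var_signal * (1 - R2) / R2`.
#' @param cell_volume_mean_by_stage Named numeric vector mapping somite
#'   stage to mean cell volume (cubic micrometres).
#' @param cell_volume_cv Coefficient of variation of cell volumes.
#' @param drift_amplitude Per-keyframe s.d. of the injected global
#'   translation random walk (micrometres); 0 disables drift.
#' @param rotation_amplitude Per-keyframe s.d. of the injected global
#'   rotation random walk (degrees); 0 disables rotation.
#' @param intercalation_rate Directional-intercalation rate (degrees per
#'   minute by which nearest-neighbour pair vectors are actively rotated
#'   toward alignment with the AP axis).  0 (the default) gives the
#'   non-directional null; positive values are the positive control.
#' @param psm_boundary_frac AP fraction of the posterior/anterior PSM
#'   boundary (progenitor-domain limit).
#' @param seed Integer seed; all stochastic draws flow from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(stage_start = 16L, stage_end = 26L,
                       frame_interval = 2, somite_period = 30,
                       n_cells_initial = NULL,
                       motility_posterior = 0.4, motility_anterior = 0.1,
                       convergence_slope_dv = -0.10,
                       convergence_intercept_dv = -0.67,
                       convergence_slope_ml = -0.08,
                       convergence_intercept_ml = 0.45,
                       noise_r2_dv = 0.20, noise_r2_ml = 0.08,
                       cell_volume_mean_by_stage = c("18" = 367, "26" = 220),
                       cell_volume_cv = 0.2,
                       drift_amplitude = 2, rotation_amplitude = 2,
                       intercalation_rate = 0,
                       psm_boundary_frac = 0.5,
                       seed = 1L) {
  cfg <- list(stage_start = as.integer(stage_start),
              stage_end = as.integer(stage_end),
              frame_interval = frame_interval, somite_period = somite_period,
              n_cells_initial = n_cells_initial,
              motility_posterior = motility_posterior,
              motility_anterior = motility_anterior,
              convergence_slope_dv = convergence_slope_dv,
              convergence_intercept_dv = convergence_intercept_dv,
              convergence_slope_ml = convergence_slope_ml,
              convergence_intercept_ml = convergence_intercept_ml,
              noise_r2_dv = noise_r2_dv, noise_r2_ml = noise_r2_ml,
              cell_volume_mean_by_stage = cell_volume_mean_by_stage,
              cell_volume_cv = cell_volume_cv,
              drift_amplitude = drift_amplitude,
              rotation_amplitude = rotation_amplitude,
              intercalation_rate = intercalation_rate,
              psm_boundary_frac = psm_boundary_frac,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  err <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) err <<- c(err, msg)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk(num1(cfg$stage_start) && num1(cfg$stage_end) &&
        cfg$stage_start < cfg$stage_end, "stage_start must be < stage_end")
  chk(num1(cfg$frame_interval) && cfg$frame_interval > 0,
      "frame_interval must be > 0")
  chk(num1(cfg$somite_period) && cfg$somite_period > 0,
      "somite_period must be > 0")
  if (num1(cfg$frame_interval) && num1(cfg$somite_period))
    chk(abs(cfg$somite_period / cfg$frame_interval -
              round(cfg$somite_period / cfg$frame_interval)) < 1e-9,
        "somite_period must be a multiple of frame_interval")
  chk(num1(cfg$motility_posterior) && num1(cfg$motility_anterior) &&
        cfg$motility_posterior >= 0 && cfg$motility_anterior >= 0 &&
        cfg$motility_posterior >= cfg$motility_anterior,
      "motility_posterior must be >= motility_anterior >= 0")
  for (f in c("noise_r2_dv", "noise_r2_ml"))
    chk(num1(cfg[[f]]) && cfg[[f]] > 0 && cfg[[f]] < 1,
        paste(f, "must lie strictly between 0 and 1"))
  chk(num1(cfg$cell_volume_cv) && cfg$cell_volume_cv >= 0,
      "cell_volume_cv must be >= 0")
  chk(is.numeric(cfg$cell_volume_mean_by_stage) &&
        length(cfg$cell_volume_mean_by_stage) >= 1 &&
        all(cfg$cell_volume_mean_by_stage > 0),
      "cell_volume_mean_by_stage must be positive")
  chk(num1(cfg$drift_amplitude) && cfg$drift_amplitude >= 0,
      "drift_amplitude must be >= 0")
  chk(num1(cfg$rotation_amplitude) && cfg$rotation_amplitude >= 0,
      "rotation_amplitude must be >= 0")
  chk(num1(cfg$intercalation_rate) && cfg$intercalation_rate >= 0,
      "intercalation_rate must be >= 0")
  chk(num1(cfg$psm_boundary_frac) && cfg$psm_boundary_frac > 0 &&
        cfg$psm_boundary_frac < 1,
      "psm_boundary_frac must lie strictly between 0 and 1")
  if (!is.null(cfg$n_cells_initial))
    chk(num1(cfg$n_cells_initial) && cfg$n_cells_initial >= 10,
        "n_cells_initial must be >= 10")
  if (length(err)) stop(paste(err, collapse = "; "))
  invisible(TRUE)
}

#' Stage-dependent box geometry of the half-PSM
#'
#' Heights and widths from the cross-section trendlines; length derived as
#' `volume / mean(cross-section areas)`.
#'
#' @param stage Somite stage (may be fractional).
#' @param tl Trendline set, by default [psm_reference_trendlines()].
#' @return List `L, H_post, W_post, H_ant, W_ant, A_post, A_ant, V,
#'   somite_length`.
#' @export
box_geometry <- function(stage, tl = psm_reference_trendlines()) {
  H_post <- evaluate_trendline(tl$height_posterior, stage)
  W_post <- evaluate_trendline(tl$width_posterior, stage)
  H_ant <- evaluate_trendline(tl$height_anterior, stage)
  W_ant <- evaluate_trendline(tl$width_anterior, stage)
  Ls <- evaluate_trendline(tl$somite_length, stage)
  V <- evaluate_trendline(tl$psm_volume, stage)
  if (any(c(H_post, W_post, H_ant, W_ant, Ls) <= 0))
    stop(sprintf("trendlines imply non-positive dimensions at stage %g", stage))
  A_post <- H_post * W_post
  A_ant <- H_ant * W_ant
  list(L = V / ((A_post + A_ant) / 2),
       H_post = H_post, W_post = W_post, H_ant = H_ant, W_ant = W_ant,
       A_post = A_post, A_ant = A_ant, V = V, somite_length = Ls)
}

reflect_into <- function(x, lo, hi) {
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  lo + ifelse(y > span, 2 * span - y, y)
}

# Directional-intercalation displacement: for each cell, rotate the vector
# to its nearest neighbour by delta_deg toward +/-90 degrees elevation
# (alignment with the AP axis), displacing both ends symmetrically.
# Returns an n x 3 displacement matrix (micrometres).
intercalation_step <- function(P, delta_deg) {
  n <- nrow(P)
  nn <- integer(n)
  for (ii in seq_len(n)) {
    d <- sqrt(colSums((t(P) - P[ii, ])^2))
    d[ii] <- Inf
    nn[ii] <- which.min(d)
  }
  done <- rep(FALSE, n)
  delta <- delta_deg * pi / 180
  disp <- matrix(0, n, 3L)
  for (ii in seq_len(n)) {
    jj <- nn[ii]
    if (done[ii] || done[jj]) next
    vec <- P[jj, ] - P[ii, ]
    nrm <- sqrt(sum(vec^2)); if (nrm == 0) next
    a <- vec[1L]; tv <- vec[2:3]; tn <- sqrt(sum(tv^2))
    th <- atan2(abs(a), tn)
    th2 <- min(pi / 2, th + delta)
    sa <- if (a != 0) sign(a) else 1
    tdir <- if (tn > 0) tv / tn else c(1, 0)
    vec2 <- c(sa * nrm * sin(th2), nrm * cos(th2) * tdir)
    dd <- (vec2 - vec) / 2
    disp[jj, ] <- disp[jj, ] + dd
    disp[ii, ] <- disp[ii, ] - dd
    done[ii] <- TRUE; done[jj] <- TRUE
  }
  disp
}

#' Simulate a compacting-extending half-PSM with ground-truth tracks
#'
#' Generates a synthetic tissue whose per-stage dimensions, volume and
#' PSM cell count follow the reference trendlines, populated with cells
#' that move by (i) the affine compaction flow mapping the stage-t box to
#' the stage-t+dt box -- which implements the DV/ML convergence and AP
#' rescaling of the tissue -- plus (ii) isotropic random steps whose scale
#' declines linearly from posterior to anterior (the fluidity gradient),
#' plus optionally (iii) an active directional-intercalation term (positive
#' control).  Every `somite_period` minutes the anterior-most slab, of
#' length given by the nascent-somite length trendline, is reassigned to a
#' new somite and frozen; cell additions (divisions) or exits are applied
#' at each somite event so the PSM count stays on the cell-number
#' trendline.  A global rigid drift/rotation, built from keyframes placed
#' every 5 frames and interpolated exactly as [interpolate_frames()] does,
#' is applied last and recorded.
#'
#' Tissue-frame conventions: +x anterior (AP), y dorsoventral centred on
#' 0, z mediolateral with the midline at z = 0.  The anterior PSM boundary
#' starts at x = 0 and successive somites occupy decreasing x as the
#' tailbud retreats posteriorly.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_bundle`: `tracks` (ground-truth gap-free
#'   tracks in tissue coordinates), `tracks_world` (same tracks with the
#'   injected rigid motion applied), `keyframes` and `frames` (the injected
#'   motion), `stage_series`, `geometry` (per-frame tip/boundary/length),
#'   `landmarks` (tailbud tip, notochord end, start-of-movie nascent-somite
#'   boundary trajectories), `label_sets`, `somite_assignments`,
#'   `additions`, `exited`, `config`.
#' @export
simulate_tissue <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  tl <- psm_reference_trendlines()
  # fail early if any requested stage implies non-positive dimensions
  for (s in seq(config$stage_start, config$stage_end)) box_geometry(s, tl)

  set.seed(config$seed)
  fi <- config$frame_interval
  fps <- as.integer(round(config$somite_period / fi))  # frames per somite
  n_som <- config$stage_end - config$stage_start
  F_last <- n_som * fps

  n0 <- if (is.null(config$n_cells_initial))
    max(10L, round(evaluate_trendline(tl$psm_cells, config$stage_start)))
  else as.integer(config$n_cells_initial)

  # ---- injected rigid motion (keyframes every 5 frames) ----
  kf_frames <- unique(c(seq(0L, F_last, by = 5L), F_last))
  nk <- length(kf_frames)
  if (config$drift_amplitude > 0) {
    steps <- matrix(stats::rnorm(3L * (nk - 1L), 0, config$drift_amplitude),
                    ncol = 3L)
    origins <- rbind(0, apply(steps, 2L, cumsum))
  } else origins <- matrix(0, nk, 3L)
  axes <- vector("list", nk)
  axes[[1L]] <- diag(3)
  for (i in seq_len(nk - 1L)) {
    if (config$rotation_amplitude > 0) {
      ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
      ang <- stats::rnorm(1, 0, config$rotation_amplitude) * pi / 180
      K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                  3, 3, byrow = TRUE)
      Rstep <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
      axes[[i + 1L]] <- axes[[i]] %*% Rstep
    } else axes[[i + 1L]] <- axes[[i]]
  }
  keyframes <- ref_keyframes(kf_frames, origins, axes)
  traj <- interpolate_frames(keyframes, frames = 0:F_last)

  # ---- cell state ----
  id <- seq_len(n0)
  u <- stats::runif(n0)
  v <- stats::runif(n0) - 0.5
  w <- stats::runif(n0)
  region <- rep(0L, n0)            # 0 = psm, -1 = exited, >0 = somite index
  fx <- fy <- fz <- rep(NA_real_, n0)  # frozen world coords
  start_frame <- rep(0L, n0)
  next_id <- n0 + 1L
  additions <- integer(0); exited <- integer(0)

  geom_L <- function(f) {
    # current PSM length: within a somite interval, interpolate from the
    # post-cut length at the last event to the pre-cut length at the next
    k <- min(max(0L, f - 1L) %/% fps, n_som - 1L)
    s0 <- config$stage_start + k
    s1 <- s0 + 1L
    tfrac <- (f - k * fps) / fps
    g1 <- box_geometry(s1, tl)
    (1 - tfrac) * box_geometry(s0, tl)$L +
      tfrac * (g1$L + g1$somite_length)
  }

  rec <- vector("list", F_last + 1L)
  ss_rows <- vector("list", n_som + 1L)
  geo_rows <- matrix(NA_real_, F_last + 1L, 4L)  # tip, boundary, L, stage
  b_cur <- 0

  world_psm <- function(sel, L_cur, s_cont) {
    g <- box_geometry(s_cont, tl)
    Hu <- g$H_post + (g$H_ant - g$H_post) * u[sel]
    Wu <- g$W_post + (g$W_ant - g$W_post) * u[sel]
    cbind(b_cur - (1 - u[sel]) * L_cur, v[sel] * Hu, w[sel] * Wu)
  }

  record_stage <- function(s, somite_cells, somite_volume) {
    g <- box_geometry(s, tl)
    n_psm <- sum(region == 0L)
    data.frame(stage = s, psm_length = g$L, psm_cells = n_psm,
               psm_volume = g$V,
               somite_length = if (is.na(somite_cells)) NA_real_ else g$somite_length,
               somite_cells = somite_cells, somite_volume = somite_volume,
               height_posterior = g$H_post, width_posterior = g$W_post,
               height_anterior = g$H_ant, width_anterior = g$W_ant,
               density = n_psm / g$V)
  }
  ss_rows[[1L]] <- record_stage(config$stage_start, NA_real_, NA_real_)

  for (f in 0:F_last) {
    s_cont <- config$stage_start + f / fps
    L_cur <- geom_L(f)

    if (f > 0) {
      psm <- which(region == 0L)
      g <- box_geometry(s_cont, tl)
      # motility: isotropic random step, AP-graded scale (world um)
      sdv <- (config$motility_posterior +
                (config$motility_anterior - config$motility_posterior) *
                u[psm]) * sqrt(fi)
      if (any(sdv > 0)) {
        Hu <- g$H_post + (g$H_ant - g$H_post) * u[psm]
        Wu <- g$W_post + (g$W_ant - g$W_post) * u[psm]
        u[psm] <- reflect_into(u[psm] + stats::rnorm(length(psm), 0, sdv) / L_cur, 0, 1)
        v[psm] <- reflect_into(v[psm] + stats::rnorm(length(psm), 0, sdv) / Hu, -0.5, 0.5)
        w[psm] <- reflect_into(w[psm] + stats::rnorm(length(psm), 0, sdv) / Wu, 0, 1)
      }
      if (config$intercalation_rate > 0 && length(psm) >= 2L) {
        P <- world_psm(psm, L_cur, s_cont)
        disp <- intercalation_step(P, config$intercalation_rate * fi)
        Hu <- g$H_post + (g$H_ant - g$H_post) * u[psm]
        Wu <- g$W_post + (g$W_ant - g$W_post) * u[psm]
        u[psm] <- reflect_into(u[psm] + disp[, 1L] / L_cur, 0, 1)
        v[psm] <- reflect_into(v[psm] + disp[, 2L] / Hu, -0.5, 0.5)
        w[psm] <- reflect_into(w[psm] + disp[, 3L] / Wu, 0, 1)
      }

      # somite event when f hits a somite boundary
      if (f %% fps == 0L) {
        s_new <- config$stage_start + f %/% fps
        g_new <- box_geometry(s_new, tl)
        L_pre <- g_new$L + g_new$somite_length   # == geom_L at this frame
        u_cut <- g_new$L / L_pre
        psm <- which(region == 0L)
        slab <- psm[u[psm] > u_cut]
        if (length(slab)) {
          W <- world_psm(slab, L_pre, s_new)
          fx[slab] <- W[, 1L]; fy[slab] <- W[, 2L]; fz[slab] <- W[, 3L]
          region[slab] <- s_new
        }
        keepers <- setdiff(psm, slab)
        # rescale AP fraction to the shortened PSM; rescale v/w so that the
        # world DV/ML positions are continuous across the cut (the local
        # cross-section H(u), W(u) changes meaning when u is rescaled)
        u_old <- u[keepers]
        u_new <- u_old / u_cut
        H_old <- g_new$H_post + (g_new$H_ant - g_new$H_post) * u_old
        H_new <- g_new$H_post + (g_new$H_ant - g_new$H_post) * u_new
        W_old <- g_new$W_post + (g_new$W_ant - g_new$W_post) * u_old
        W_new <- g_new$W_post + (g_new$W_ant - g_new$W_post) * u_new
        u[keepers] <- u_new
        v[keepers] <- reflect_into(v[keepers] * H_old / H_new, -0.5, 0.5)
        w[keepers] <- reflect_into(w[keepers] * W_old / W_new, 0, 1)
        A_cut <- {
          Hc <- g_new$H_post + (g_new$H_ant - g_new$H_post) * u_cut
          Wc <- g_new$W_post + (g_new$W_ant - g_new$W_post) * u_cut
          Hc * Wc
        }
        som_vol <- g_new$somite_length * (A_cut + g_new$A_ant) / 2
        b_cur <- b_cur - g_new$somite_length
        L_cur <- g_new$L

        # keep the PSM count on the cell-number trendline:
        # deficits are filled by divisions (uniform placement), surpluses
        # leave the paraxial mesoderm (fin-mesenchyme-like exit)
        target <- max(10L, round(evaluate_trendline(tl$psm_cells, s_new)))
        n_psm <- length(keepers)
        if (n_psm < target) {
          n_add <- target - n_psm
          idn <- seq(next_id, length.out = n_add)
          id <- c(id, idn)
          u <- c(u, stats::runif(n_add))
          v <- c(v, stats::runif(n_add) - 0.5)
          w <- c(w, stats::runif(n_add))
          region <- c(region, rep(0L, n_add))
          fx <- c(fx, rep(NA_real_, n_add)); fy <- c(fy, rep(NA_real_, n_add))
          fz <- c(fz, rep(NA_real_, n_add))
          start_frame <- c(start_frame, rep(f, n_add))
          additions <- c(additions, idn)
          next_id <- next_id + n_add
        } else if (n_psm > target) {
          drop_idx <- sample(keepers, n_psm - target)
          W <- world_psm(drop_idx, L_cur, s_new)
          fx[drop_idx] <- W[, 1L]; fy[drop_idx] <- W[, 2L]; fz[drop_idx] <- W[, 3L]
          region[drop_idx] <- -1L
          exited <- c(exited, id[drop_idx])
        }
        ss_rows[[f %/% fps + 1L]] <- record_stage(s_new, length(slab), som_vol)
      }
    }

    psm <- which(region == 0L)
    X <- matrix(NA_real_, length(id), 3L)
    if (length(psm)) X[psm, ] <- world_psm(psm, L_cur, s_cont)
    frozen <- which(region != 0L)
    X[frozen, ] <- cbind(fx[frozen], fy[frozen], fz[frozen])
    rec[[f + 1L]] <- cbind(frame = f, id = id, X, region = region)
    geo_rows[f + 1L, ] <- c(b_cur - L_cur, b_cur, L_cur, s_cont)
  }

  M <- do.call(rbind, rec)
  region_lab <- ifelse(M[, "region"] == 0L, "psm",
                       ifelse(M[, "region"] == -1L, "exited",
                              paste0("somite_", M[, "region"])))
  tracks <- track_set(data.frame(
    track_id = as.integer(M[, "id"]), frame = as.integer(M[, "frame"]),
    t_min = M[, "frame"] * fi,
    x_um = M[, 3L], y_um = M[, 4L], z_um = M[, 5L],
    region = region_lab, stringsAsFactors = FALSE))
  attr(tracks, "coords") <- "local"
  tracks_world <- transform_to_world(tracks, traj)

  geometry <- data.frame(frame = 0:F_last, tip = geo_rows[, 1L],
                         boundary = geo_rows[, 2L], length = geo_rows[, 3L],
                         stage = geo_rows[, 4L])
  landmarks <- list(
    tailbud_tip = data.frame(frame = geometry$frame, x_um = geometry$tip,
                             y_um = 0, z_um = 0),
    notochord_end = data.frame(frame = geometry$frame,
                               x_um = geometry$tip +
                                 config$psm_boundary_frac * geometry$length,
                               y_um = 0, z_um = 0),
    nascent_somite_boundary = data.frame(frame = geometry$frame, x_um = 0,
                                         y_um = 0, z_um = 0))

  final_region <- region
  names(final_region) <- id
  structure(list(
    tracks = tracks, tracks_world = tracks_world,
    keyframes = keyframes, frames = traj,
    stage_series = do.call(rbind, ss_rows),
    geometry = geometry, landmarks = landmarks,
    label_sets = list(),
    somite_assignments = ifelse(final_region == 0L, "psm",
                                ifelse(final_region == -1L, "exited",
                                       paste0("somite_", final_region))),
    additions = additions, exited = exited,
    frame_interval = fi, n_frames = F_last + 1L,
    config = config), class = "sim_bundle")
}

#' Photolabel a dorsoventral stripe of PSM cells
#'
#' Labels every PSM cell whose AP position at the label frame lies within
#' a stripe centred at `ap_fraction` of the PSM length (0 = posterior end,
#' 1 = anterior boundary), spanning the full DV extent.  The label is
#' registered in `bundle$label_sets`.
#'
#' @param bundle A [simulate_tissue()] bundle.
#' @param ap_fraction Stripe centre as a fraction of PSM length, in [0, 1].
#' @param stripe_width Stripe AP width in micrometres.
#' @param frame Frame at which the label is applied.
#' @param name Label name; autogenerated when NULL.
#' @return The bundle with the new label in `label_sets`.
#' @export
make_photolabel <- function(bundle, ap_fraction, stripe_width, frame = 0L,
                            name = NULL) {
  stopifnot(inherits(bundle, "sim_bundle"),
            ap_fraction >= 0, ap_fraction <= 1, stripe_width > 0)
  geo <- bundle$geometry[bundle$geometry$frame == frame, ]
  x_c <- geo$tip + ap_fraction * geo$length
  at <- bundle$tracks[bundle$tracks$frame == frame &
                        bundle$tracks$region == "psm", ]
  ids <- at$track_id[abs(at$x_um - x_c) <= stripe_width / 2]
  if (length(ids) == 0L)
    warning("photolabel stripe lies outside the tissue: empty label")
  if (is.null(name))
    name <- sprintf("label_ap%.2f_f%d", ap_fraction, frame)
  bundle$label_sets[[name]] <- ids
  bundle
}

#' Measure the deformation of a photolabel between two frames
#'
#' Bounding AP length and DV height of the labelled cells at the two
#' frames, passed through [photolabel_deformation()].
#'
#' @param bundle A [simulate_tissue()] bundle.
#' @param ids Labelled cell ids (e.g. an entry of `bundle$label_sets`).
#' @param frame0,frame1 Measurement frames.
#' @return A `photolabel_measurement` row.
#' @export
label_deformation <- function(bundle, ids, frame0 = 0L,
                              frame1 = max(bundle$tracks$frame)) {
  ext <- function(f) {
    at <- bundle$tracks[bundle$tracks$frame == f &
                          bundle$tracks$track_id %in% ids, ]
    if (nrow(at) < 2L) stop("label has fewer than 2 cells at frame ", f)
    c(len = diff(range(at$x_um)), hei = diff(range(at$y_um)),
      mid = mean(at$x_um))
  }
  e0 <- ext(frame0); e1 <- ext(frame1)
  geo <- bundle$geometry[bundle$geometry$frame == frame0, ]
  photolabel_deformation(length_t0 = e0[["len"]], height_t0 = e0[["hei"]],
                         length_t1 = e1[["len"]], height_t1 = e1[["hei"]],
                         ap_position_norm = (e0[["mid"]] - geo$tip) / geo$length)
}

#' Sample cell volumes for a somite stage
#'
#' Draws from a normal distribution truncated at zero, with mean linearly
#' interpolated between the configured stage anchors and standard
#' deviation `cv * mean`.
#'
#' @param stage Somite stage; must lie within the anchor range.
#' @param n Number of draws (> 0).
#' @param mean_by_stage Named numeric vector of stage -> mean volume
#'   (cubic micrometres).
#' @param cv Coefficient of variation; 0 gives the stage mean exactly.
#' @param seed Optional seed.
#' @return Numeric vector of n positive volumes.
#' @export
sample_cell_volumes <- function(stage, n, mean_by_stage = c("18" = 367,
                                                            "26" = 220),
                                cv = 0.2, seed = NULL) {
  if (n <= 0) stop("n must be positive")
  stages <- as.numeric(names(mean_by_stage))
  if (stage < min(stages) || stage > max(stages))
    stop(sprintf("stage %g outside the configured mapping [%g, %g]",
                 stage, min(stages), max(stages)))
  m <- if (length(stages) == 1L) mean_by_stage[[1L]]
    else stats::approx(stages, mean_by_stage, xout = stage)$y
  if (!is.null(seed)) set.seed(seed)
  if (cv == 0) return(rep(m, n))
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(n, m, cv * m)
    out <- c(out, draw[draw > 0])
  }
  out[seq_len(n)]
}

#' Simulate posterior-PSM convergence-field tracks
#'
#' Generates per-track displacements over a window from the linear
#' convergence field `displacement = slope * start + intercept + noise`,
#' with the noise variance sized analytically from the target coefficient
#' of determination: `var_noise = slope^2 * var(start) * (1 - R2) / R2`.
#' Start positions are uniform over the posterior-PSM extent of the axis.
#' Returned as a minimal two-frame track set so the regression runs on the
#' same code path as real tracks.
#'
#' @param n Number of tracks.
#' @param slope,intercept Field coefficients (displacement in micrometres
#'   per `window_min` as a function of start position).
#' @param r2 Target R-squared, strictly between 0 and 1.
#' @param window_min Window in minutes.
#' @param frame_interval Minutes per frame.
#' @param axis `"DV"` or `"ML"`.
#' @param half_range Half-extent of start positions about the midline
#'   (micrometres).
#' @param seed Optional seed.
#' @return List `tracks` (a [track_set()]), `truth` (the generating
#'   coefficients), `frame_interval`.
#' @export
simulate_convergence_tracks <- function(n, slope, intercept, r2,
                                        window_min = 120, frame_interval = 2,
                                        axis = c("DV", "ML"),
                                        half_range = 55, seed = NULL) {
  axis <- match.arg(axis)
  stopifnot(r2 > 0, r2 < 1, n >= 3)
  if (!is.null(seed)) set.seed(seed)
  x0 <- stats::runif(n, -half_range, half_range)
  var_x <- (2 * half_range)^2 / 12
  sd_noise <- sqrt(slope^2 * var_x * (1 - r2) / r2)
  disp <- slope * x0 + intercept + stats::rnorm(n, 0, sd_noise)
  wf <- round(window_min / frame_interval)
  mk <- function(frame, pos) {
    df <- data.frame(track_id = seq_len(n), frame = frame,
                     x_um = 30, y_um = 0, z_um = 0)
    if (axis == "DV") df$y_um <- pos else df$z_um <- pos
    df
  }
  tracks <- track_set(rbind(mk(0L, x0), mk(wf, x0 + disp)),
                      frame_interval = frame_interval)
  list(tracks = tracks,
       truth = list(slope = slope, intercept = intercept, r2 = r2,
                    sd_noise = sd_noise),
       frame_interval = frame_interval)
}

#' Simulate a posterior-PSM cell cloud moving under convergence fields
#'
#' The non-directional-rearrangement construction used for the
#' angle-change null and its positive control: cells fill a static
#' posterior-PSM-sized box and move by isotropic random steps plus the
#' explicit linear DV/ML convergence displacement fields (a
#' position-dependent drift, which by construction carries no information
#' about pair orientation and hence no directional intercalation).
#' With `intercalation_rate > 0`, nearest-neighbour pair vectors are
#' additionally rotated toward alignment with the AP axis -- the positive
#' control in which the parallel/perpendicular angle-change comparison
#' must separate.
#'
#' Distinct from [simulate_tissue()], whose DV/ML convergence arises from
#' the trendline-driven compaction of the whole tissue: here the box does
#' not deform globally, isolating rearrangement from tissue-scale
#' extension.
#'
#' @param n Number of cells.
#' @param box Length-3 box dimensions (AP length, DV height, ML width) in
#'   micrometres; defaults to the posterior half-PSM at stage 16.
#' @param window_min Duration to simulate (minutes).
#' @param frame_interval Minutes per frame.
#' @param motility Isotropic random-step scale (micrometres per
#'   square-root minute).
#' @param slope_dv,intercept_dv,slope_ml,intercept_ml Convergence-field
#'   coefficients (displacement per `field_window` minutes as a linear
#'   function of position; DV position centred on the midline, ML
#'   position 0 at the midline).
#' @param field_window Minutes over which the field coefficients are
#'   expressed.
#' @param intercalation_rate Degrees per minute of active pair alignment;
#'   0 for the null.
#' @param seed Optional seed.
#' @return A [track_set()] covering frames 0 .. window_min/frame_interval.
#' @export
simulate_field_cloud <- function(n = 1348, box = c(130, 110, 56),
                                 window_min = 60, frame_interval = 2,
                                 motility = 0.4,
                                 slope_dv = -0.10, intercept_dv = -0.67,
                                 slope_ml = -0.08, intercept_ml = 0.45,
                                 field_window = 120,
                                 intercalation_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fi <- frame_interval
  nf <- round(window_min / fi)
  P <- cbind(stats::runif(n, 0, box[1]),
             stats::runif(n, -box[2] / 2, box[2] / 2),
             stats::runif(n, 0, box[3]))
  out <- vector("list", nf + 1L)
  out[[1L]] <- data.frame(track_id = seq_len(n), frame = 0L,
                          x_um = P[, 1], y_um = P[, 2], z_um = P[, 3])
  for (f in seq_len(nf)) {
    P <- P + matrix(stats::rnorm(3 * n, 0, motility * sqrt(fi)), ncol = 3L)
    P[, 2] <- P[, 2] + (slope_dv * P[, 2] + intercept_dv) * fi / field_window
    P[, 3] <- P[, 3] + (slope_ml * P[, 3] + intercept_ml) * fi / field_window
    if (intercalation_rate > 0)
      P <- P + intercalation_step(P, intercalation_rate * fi)
    P[, 1] <- reflect_into(P[, 1], 0, box[1])
    P[, 2] <- reflect_into(P[, 2], -box[2] / 2, box[2] / 2)
    P[, 3] <- reflect_into(P[, 3], 0, box[3])
    out[[f + 1L]] <- data.frame(track_id = seq_len(n), frame = f,
                                x_um = P[, 1], y_um = P[, 2], z_um = P[, 3])
  }
  track_set(do.call(rbind, out), frame_interval = fi)
}

#' Write a simulation bundle to a directory
#'
#' Tracks as CSV (`track_id, frame, t_min, x_um, y_um, z_um, region`),
#' reference-frame keyframes as JSON, the stage series as CSV and label
#' sets as JSON.
#'
#' @param bundle A [simulate_tissue()] bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tracks_csv(bundle$tracks, file.path(dir, "tracks_local.csv"))
  write_tracks_csv(bundle$tracks_world, file.path(dir, "tracks_world.csv"))
  write_keyframes_json(bundle$keyframes, file.path(dir, "keyframes.json"))
  utils::write.csv(bundle$stage_series, file.path(dir, "stage_series.csv"),
                   row.names = FALSE)
  jsonlite::write_json(bundle$label_sets, file.path(dir, "labels.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(dir)
}
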