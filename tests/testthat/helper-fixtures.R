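# Shared fixtures, built once per test run.

# Default-condition bundle (stages 16-26), reused across files via a cache.
.fixture_env <- new.env(parent = emptyenv())

default_bundle <- function() {
  if (is.null(.fixture_env$bundle))
    .fixture_env$bundle <- simulate_tissue(sim_config(seed = 101L))
  .fixture_env$bundle
}

# Small fast bundle for kinematic checks.
small_bundle <- function(...) {
  simulate_tissue(sim_config(stage_start = 16L, stage_end = 18L,
                             n_cells_initial = 400, seed = 202L, ...))
}

# Rectangle polygon (width w along x, height h along y), centred at (cx, cy).
rect_poly <- function(w, h, cx = 0, cy = 0) {
  cbind(cx + c(-w, w, w, -w) / 2, cy + c(-h, -h, h, h) / 2)
}

# Regular polygon approximating a circle.
circle_poly <- function(r, n = 64) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(r * cos(th), r * sin(th))
}

# Box-shaped contour stack: rectangles along z.
box_stack <- function(w, h, z = 0:10) {
  contour_stack(lapply(z, function(zz) list(z = zz, xy = rect_poly(w, h))))
}

# Two-frame track set from start/end position matrices.
two_frame_tracks <- function(P0, P1, f1 = 30L) {
  track_set(rbind(
    data.frame(track_id = seq_len(nrow(P0)), frame = 0L,
               x_um = P0[, 1], y_um = P0[, 2], z_um = P0[, 3]),
    data.frame(track_id = seq_len(nrow(P0)), frame = f1,
               x_um = P1[, 1], y_um = P1[, 2], z_um = P1[, 3])))
}

# Rotation matrix about axis k (1 = x, 2 = y, 3 = z) by angle degrees.
rot3 <- function(axis, deg) {
  a <- deg * pi / 180
  R <- diag(3)
  i <- setdiff(1:3, axis)
  R[i[1], i[1]] <- cos(a); R[i[2], i[2]] <- cos(a)
  R[i[1], i[2]] <- -sin(a); R[i[2], i[1]] <- sin(a)
  R
}
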