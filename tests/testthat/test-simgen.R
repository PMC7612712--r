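test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(stage_start = 16L, stage_end = 17L,
                    n_cells_initial = 120, seed = 9L)
  b1 <- simulate_tissue(cfg)
  b2 <- simulate_tissue(cfg)
  expect_identical(b1$tracks, b2$tracks)
  expect_identical(b1$tracks_world, b2$tracks_world)
  expect_identical(b1$stage_series, b2$stage_series)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(stage_start = 20, stage_end = 18), "stage_start")
  expect_error(sim_config(frame_interval = 0), "frame_interval")
  expect_error(sim_config(motility_posterior = 0.1, motility_anterior = 0.4),
               "motility_posterior")
  expect_error(sim_config(noise_r2_dv = 1.2), "noise_r2_dv")
  expect_error(sim_config(psm_boundary_frac = 0), "psm_boundary_frac")
  # trendlines imply non-positive anterior width beyond stage 38
  expect_error(simulate_tissue(sim_config(stage_start = 36L, stage_end = 40L)),
               "stage")
})

test_that("with motility, drift and rotation off, cells follow the compaction flow", {
  b <- simulate_tissue(sim_config(stage_start = 16L, stage_end = 18L,
                                  n_cells_initial = 300,
                                  motility_posterior = 0, motility_anterior = 0,
                                  drift_amplitude = 0, rotation_amplitude = 0,
                                  seed = 5L))
  tr <- b$tracks
  ids <- with(tr, intersect(track_id[frame == 0], track_id[frame == max(frame)]))
  t0 <- tr[tr$frame == 0 & tr$track_id %in% ids, ]
  t1 <- tr[tr$frame == max(tr$frame) & tr$track_id %in% ids, ]
  t1 <- t1[match(t0$track_id, t1$track_id), ]
  # the flow is monotone along each axis: orderings are preserved
  expect_equal(order(t0$x_um), order(t1$x_um))
  expect_true(all(sign(t0$y_um) == sign(t1$y_um) | t0$y_um == 0))
  # world and drift-free tracks coincide when no rigid motion is injected
  expect_equal(b$tracks_world$x_um, b$tracks$x_um, tolerance = 1e-12)
})

test_that("stage series tracks the reference trendlines and compacts", {
  b <- default_bundle()
  ss <- b$stage_series
  tl <- psm_reference_trendlines()
  # heights/widths and volume follow the trendlines (within 5%)
  for (f in c("height_posterior", "width_posterior",
              "height_anterior", "width_anterior")) {
    expect_lt(max(abs(ss[[f]] / evaluate_trendline(tl[[f]], ss$stage) - 1)), 0.05)
  }
  expect_lt(max(abs(ss$psm_volume /
                      evaluate_trendline(tl$psm_volume, ss$stage) - 1)), 0.05)
  # PSM cell count on the cell-number trendline (within 5%)
  expect_lt(max(abs(ss$psm_cells /
                      evaluate_trendline(tl$psm_cells, ss$stage) - 1)), 0.05)
  # compaction: volume strictly decreasing, density monotonically rising
  expect_true(all(diff(ss$psm_volume) < 0))
  expect_true(all(diff(ss$density) > 0))
  # the density increase over the simulated span is substantial (~80%-order,
  # per the count and volume trendlines)
  inc <- ss$density[nrow(ss)] / ss$density[1] - 1
  expect_gt(inc, 0.6)
  expect_lt(inc, 1.3)
})

test_that("cell count is conserved frame by frame as PSM + somites + exited", {
  b <- small_bundle()
  n0 <- sum(b$tracks$frame == 0)
  for (f in unique(b$tracks$frame)) {
    at <- b$tracks[b$tracks$frame == f, ]
    added <- sum(b$additions %in% at$track_id)
    expect_equal(nrow(at), n0 + added)
    # each id appears exactly once per frame and in exactly one region
    expect_false(anyDuplicated(at$track_id) > 0)
  }
  # somite assignment covers every cell
  expect_setequal(names(b$somite_assignments),
                  as.character(unique(b$tracks$track_id)))
})

test_that("photolabel stripes span the tissue correctly", {
  b <- default_bundle()
  geo <- b$geometry[b$geometry$frame == 0, ]
  # stripe wider than the tissue labels every PSM cell
  b_all <- make_photolabel(b, 0.5, stripe_width = 3 * geo$length, name = "all")
  psm0 <- b$tracks[b$tracks$frame == 0 & b$tracks$region == "psm", ]
  expect_setequal(b_all$label_sets$all, psm0$track_id)
  # posterior-most vs anterior-most stripes are disjoint
  b2 <- make_photolabel(b, 0, 30, name = "post")
  b2 <- make_photolabel(b2, 1, 30, name = "ant")
  expect_length(intersect(b2$label_sets$post, b2$label_sets$ant), 0)
  # a stripe outside the tissue warns and yields an empty label
  expect_warning(make_photolabel(b, 0, 1e-9, name = "nil"), "empty")
})

test_that("posterior photolabels deform more than anterior ones over 120 min", {
  b <- default_bundle()
  b <- make_photolabel(b, 0.15, 30, name = "post")
  b <- make_photolabel(b, 0.85, 30, name = "ant")
  f120 <- round(120 / b$frame_interval)
  post <- label_deformation(b, b$label_sets$post, 0, f120)
  ant <- label_deformation(b, b$label_sets$ant, 0, f120)
  expect_gt(post$ratio_fold_change, ant$ratio_fold_change)
  expect_lt(post$ap_position_norm, ant$ap_position_norm)
})

test_that("rendered nuclei images peak at the nuclei and round-trip detection", {
  one <- render_nuclei_image(matrix(c(10, 11, 9), 1), voxel_size = 1,
                             origin = c(0, 0, 0), fov = c(20, 20, 18))
  peak <- which(one$stack == max(one$stack), arr.ind = TRUE)[1, ]
  peak_um <- (peak - 0.5)  # voxel centres at (i - 0.5) um
  expect_true(all(abs(peak_um - c(10, 11, 9)) <= 0.5))

  none <- render_nuclei_image(matrix(numeric(0), 0, 3), voxel_size = 1,
                              origin = c(0, 0, 0), fov = c(10, 10, 10))
  expect_true(all(none$stack == 0))
  expect_error(render_nuclei_image(matrix(c(1, 1, 1), 1), voxel_size = 0),
               "positive")

  # 100 nuclei >= 8 um apart: detection recall >= 0.99
  pos <- as.matrix(expand.grid(x = seq(5, 75, 10), y = seq(5, 75, 10),
                               z = seq(5, 35, 15)))[1:100, ]
  img <- render_nuclei_image(pos, voxel_size = 1, origin = c(0, 0, 0),
                             fov = c(80, 80, 40))
  sp <- detect_spots(img)
  d <- vapply(seq_len(nrow(pos)), function(i)
    min(sqrt((sp$x_um - pos[i, 1])^2 + (sp$y_um - pos[i, 2])^2 +
               (sp$z_um - pos[i, 3])^2)), numeric(1))
  expect_gte(mean(d < 1), 0.99)
})

test_that("convergence-track generator embeds the configured field", {
  sim <- simulate_convergence_tracks(2000, slope = -0.1, intercept = -0.67,
                                     r2 = 0.2, seed = 3)
  fit <- convergence_regression(sim$tracks, axis = "DV", window_min = 120,
                                frame_interval = 2)
  expect_lt(abs(fit$slope - (-0.1)), 0.02)
  expect_lt(abs(fit$intercept - (-0.67)), 0.5)
  expect_lt(abs(fit$r2 - 0.2), 0.08)
})
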