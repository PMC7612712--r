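test_that("spot detection localises blobs and merges sub-diameter doublets", {
  one <- render_nuclei_image(matrix(c(10, 9, 11), 1), voxel_size = 1,
                             origin = c(0, 0, 0), fov = c(20, 18, 22))
  sp <- detect_spots(one)
  expect_equal(nrow(sp), 1L)
  expect_lt(sqrt(sum((c(sp$x_um, sp$y_um, sp$z_um) - c(10, 9, 11))^2)), 0.5)

  # two blobs 8 um apart resolve into two spots
  two <- render_nuclei_image(rbind(c(10, 10, 10), c(18, 10, 10)),
                             voxel_size = 1, origin = c(0, 0, 0),
                             fov = c(28, 20, 20))
  expect_equal(nrow(detect_spots(two)), 2L)

  # two blobs 2 um apart (below the 4 um diameter) merge into one detection
  close2 <- render_nuclei_image(rbind(c(10, 10, 10), c(12, 10, 10)),
                                voxel_size = 1, origin = c(0, 0, 0),
                                fov = c(22, 20, 20))
  expect_equal(nrow(detect_spots(close2)), 1L)

  # empty image -> empty table; invalid voxels rejected
  expect_equal(nrow(detect_spots(array(0, c(8, 8, 8)))), 0L)
  expect_error(detect_spots(array(1, c(4, 4, 4)), voxel_size = -1), "positive")
})

test_that("detection handles anisotropic voxels", {
  img <- render_nuclei_image(rbind(c(15, 15, 10), c(15, 15, 20)),
                             voxel_size = c(1, 1, 2), origin = c(0, 0, 0),
                             fov = c(30, 30, 30))
  sp <- detect_spots(img)
  expect_equal(nrow(sp), 2L)
  expect_lt(max(abs(sort(sp$z_um) - c(10, 20))), 1)
})

test_that("stationary spots and gaps link into continuous tracks", {
  sp <- do.call(rbind, lapply(0:9, function(f)
    data.frame(spot_id = 1:2, frame = f, x_um = c(0, 20), y_um = 0, z_um = 0)))
  tr <- link_tracks(sp, tracker_config())
  expect_equal(length(unique(tr$track_id)), 2L)
  expect_equal(as.integer(table(tr$track_id)), c(10L, 10L))

  # a spot missing for 2 consecutive frames is bridged (gap size 3)
  sp_gap <- sp[!(sp$frame %in% 4:5 & sp$spot_id == 1), ]
  tr_gap <- link_tracks(sp_gap, tracker_config(gap_size = 3))
  expect_equal(length(unique(tr_gap$track_id)), 2L)
  durs <- tapply(tr_gap$frame, tr_gap$track_id, function(f) max(f) - min(f))
  expect_true(all(durs == 9))
  # with gap closing disabled the track fragments
  tr_nogap <- link_tracks(sp_gap, tracker_config(gap_size = 0))
  expect_gt(length(unique(tr_nogap$track_id)), 2L)

  expect_error(link_tracks(rbind(sp, sp[1, ]), tracker_config()), "duplicate")
})

test_that("no track contains a gap exceeding the configured gap size", {
  set.seed(21)
  sp <- do.call(rbind, lapply(0:19, function(f) {
    keep <- runif(30) > 0.1
    data.frame(spot_id = (1:30)[keep], frame = f,
               x_um = (1:30)[keep] * 10 + rnorm(sum(keep), 0, 0.3),
               y_um = rnorm(sum(keep), 0, 0.3), z_um = 0)
  }))
  tr <- link_tracks(sp, tracker_config(max_distance = 4, gap_size = 2))
  gaps <- tapply(tr$frame, tr$track_id, function(f) max(diff(sort(f))) - 1)
  expect_true(all(unlist(gaps) <= 2))
})

test_that("crossing spots: autoregressive prediction keeps identities, nearest swaps", {
  sp <- do.call(rbind, lapply(0:7, function(f)
    data.frame(spot_id = 1:2, frame = f,
               x_um = c(f * 3, 21 - f * 3), y_um = 0, z_um = 0)))
  ar <- link_tracks(sp, tracker_config(max_distance = 6,
                                       motion_model = "autoregressive",
                                       ar_damping = 1))
  nn <- link_tracks(sp, tracker_config(max_distance = 6,
                                       motion_model = "nearest"))
  end_x <- function(tr, id) tr$x_um[tr$track_id == id & tr$frame == 7]
  expect_equal(end_x(ar, 1L), 21)   # identity preserved through the crossing
  expect_equal(end_x(nn, 1L), 0)    # nearest-neighbour model swaps
})

test_that("the detection + linking pipeline is invariant to record order", {
  set.seed(31)
  sp <- do.call(rbind, lapply(0:8, function(f)
    data.frame(spot_id = 1:15, frame = f,
               x_um = (1:15) * 8 + rnorm(15, 0, 0.5),
               y_um = rnorm(15, 0, 0.5), z_um = rnorm(15, 0, 0.5))))
  tr1 <- link_tracks(sp, tracker_config())
  tr2 <- link_tracks(sp[sample(nrow(sp)), ], tracker_config())
  expect_identical(tr1, tr2)
})

test_that("tracker recall exceeds 90% on synthetic tracks with 5% dropouts", {
  b <- simulate_tissue(sim_config(stage_start = 16L, stage_end = 17L,
                                  n_cells_initial = 300,
                                  drift_amplitude = 0, rotation_amplitude = 0,
                                  seed = 4L))
  tr <- b$tracks[b$tracks$frame <= 12, ]
  set.seed(8)
  keep <- runif(nrow(tr)) > 0.05
  sp <- data.frame(spot_id = tr$track_id[keep], frame = tr$frame[keep],
                   x_um = tr$x_um[keep], y_um = tr$y_um[keep],
                   z_um = tr$z_um[keep])
  est <- link_tracks(sp, tracker_config(max_distance = 5, gap_size = 3))
  # linking accuracy is scored over detected endpoints: links whose endpoint
  # was dropped cannot be recovered by any linker (gap closure instead
  # bridges the surrounding chain, which these links exercise)
  rc <- track_link_recall(est, track_set(tr[keep, ]), tol = 0.5)
  expect_gte(rc$recall, 0.9)
})

test_that("paraxial selection removes midline crossers and mask visitors", {
  mk <- function(id, zs) data.frame(track_id = id, frame = seq_along(zs) - 1,
                                    x_um = 10, y_um = 0, z_um = zs)
  tr <- track_set(rbind(mk(1, c(5, 2, -1)),    # crosses the z=0 midline
                        mk(2, c(5, 5, 5)),     # stays paraxial
                        mk(3, c(5, 0, 5))))    # touches the plane exactly
  sel <- select_paraxial_tracks(tr, midline_plane = list(point = c(0, 0, 0),
                                                         normal = c(0, 0, -1)))
  expect_setequal(unique(sel$track_id), c(2, 3))  # boundary contact retained

  # notochord-like box mask: strict interior test
  mask <- list(type = "box", min = c(0, -2, 3), max = c(20, 2, 7))
  tr2 <- track_set(rbind(mk(1, c(10, 10, 10)),  # inside (y=0, z=5 interior)
                         mk(2, c(20, 20, 20))))
  tr2$z_um <- c(5, 5, 5, 9, 9, 9)
  sel2 <- select_paraxial_tracks(tr2, exclusion_masks = list(mask))
  expect_setequal(unique(sel2$track_id), 2)
  # a track touching the mask surface is retained
  tr3 <- track_set(mk(1, c(3, 3, 3)))
  expect_equal(unique(select_paraxial_tracks(tr3,
                exclusion_masks = list(mask))$track_id), 1)
})

test_that("track duration shows no spurious correlation with start position", {
  # constructed gradient: durations increase along AP -> strong correlation
  tr <- do.call(rbind, lapply(1:30, function(i)
    data.frame(track_id = i, frame = 0:(2 + i), x_um = i * 10,
               y_um = 0, z_um = 0)))
  qc <- track_qc_duration_vs_position(track_set(tr))
  expect_gt(qc$r, 0.9)

  # uniform durations: flagged, r reported as 0
  tr2 <- do.call(rbind, lapply(1:10, function(i)
    data.frame(track_id = i, frame = 0:5, x_um = i, y_um = 0, z_um = 0)))
  qc2 <- track_qc_duration_vs_position(track_set(tr2))
  expect_true(qc2$constant)
  expect_equal(qc2$r, 0)

  # default simulation truncated to 60-min windows at random offsets:
  # duration is unrelated to start AP position
  b <- default_bundle()
  tr <- b$tracks[b$tracks$region == "psm", ]
  set.seed(77)
  wf <- round(60 / b$frame_interval)
  ids <- sample(unique(tr$track_id), 300)
  trunc <- do.call(rbind, lapply(ids, function(id) {
    tt <- tr[tr$track_id == id, ]
    if (nrow(tt) < 5) return(NULL)
    f0 <- sample(seq(min(tt$frame), max(tt$frame) - 4), 1)
    tt[tt$frame >= f0 & tt$frame <= f0 + sample(4:wf, 1), ]
  }))
  qc3 <- track_qc_duration_vs_position(track_set(trunc),
                                       frame_interval = b$frame_interval)
  expect_lt(abs(qc3$r), 0.2)
})
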