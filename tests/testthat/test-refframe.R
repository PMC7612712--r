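test_that("keyframe interpolation: origins linear, rotations on the shortest arc", {
  # identical keyframes: identity motion at all frames
  kf <- ref_keyframes(c(0L, 10L), rbind(c(1, 2, 3), c(1, 2, 3)),
                      list(diag(3), diag(3)))
  tj <- interpolate_frames(kf)
  expect_equal(tj$origin[4, ], c(1, 2, 3))
  expect_equal(tj$axes[[7]], diag(3))

  # origin linearly interpolated: (0,0,0) at f0, (10,0,0) at f5 -> (4,0,0) at f2
  kf2 <- ref_keyframes(c(0L, 5L), rbind(c(0, 0, 0), c(10, 0, 0)),
                       list(diag(3), diag(3)))
  tj2 <- interpolate_frames(kf2)
  expect_equal(tj2$origin[tj2$frame == 2, ], c(4, 0, 0))

  # 90-degree rotation about ML: 45 degrees at the midpoint, axes orthonormal
  R90 <- rot3(3, 90)
  kf3 <- ref_keyframes(c(0L, 10L), rbind(c(0, 0, 0), c(0, 0, 0)),
                       list(diag(3), R90))
  tj3 <- interpolate_frames(kf3)
  mid <- tj3$axes[[which(tj3$frame == 5)]]
  expect_equal(mid, rot3(3, 45), tolerance = 1e-10)
  for (A in tj3$axes)
    expect_lt(max(abs(crossprod(A) - diag(3))), 1e-6)
  # keyframe frames reproduce the keyframe rotation exactly
  expect_equal(tj3$axes[[which(tj3$frame == 10)]], R90, tolerance = 1e-12)
})

test_that("keyframe axes are validated and gently re-orthonormalised", {
  slightly_off <- diag(3) + matrix(1e-5, 3, 3)
  kf <- ref_keyframes(0L, rbind(c(0, 0, 0)), list(slightly_off))
  expect_lt(max(abs(crossprod(kf$axes[[1]]) - diag(3))), 1e-10)
  badly_off <- diag(3) + matrix(0.1, 3, 3)
  expect_error(ref_keyframes(0L, rbind(c(0, 0, 0)), list(badly_off)),
               "orthonormality")
  expect_error(ref_keyframes(c(3L, 3L), rbind(c(0, 0, 0), c(0, 0, 0)),
                             list(diag(3), diag(3))), "strictly increasing")
})

test_that("track normalisation removes exactly the injected rigid motion", {
  set.seed(11)
  tr <- track_set(data.frame(track_id = rep(1:20, each = 11),
                             frame = rep(0:10, 20),
                             x_um = rnorm(220, 50, 10),
                             y_um = rnorm(220), z_um = rnorm(220)))
  # identity trajectory: unchanged
  id_tj <- interpolate_frames(ref_keyframes(c(0L, 10L),
                                            rbind(c(0, 0, 0), c(0, 0, 0)),
                                            list(diag(3), diag(3))))
  expect_equal(transform_to_local(tr, id_tj)$x_um, tr$x_um)

  # pure translation removed exactly
  tt <- interpolate_frames(ref_keyframes(c(0L, 10L),
                                         rbind(c(0, 0, 0), c(30, -10, 5)),
                                         list(diag(3), diag(3))))
  drifted <- transform_to_world(tr, tt)
  expect_equal(transform_to_local(drifted, tt)$x_um, tr$x_um, tolerance = 1e-9)

  # full drift + rotation round trip through the simulator to 1e-6 um
  b <- small_bundle()
  back <- transform_to_local(b$tracks_world, b$frames)
  err <- max(abs(as.matrix(back[, c("x_um", "y_um", "z_um")]) -
                   as.matrix(b$tracks[, c("x_um", "y_um", "z_um")])))
  expect_lt(err, 1e-6)
})

test_that("relative displacement subtracts the landmark and flips with the reference", {
  lm_static <- data.frame(frame = 0:30, x_um = 0, y_um = 0, z_um = 0)
  lm_moving <- data.frame(frame = 0:30, x_um = -2 * (0:30), y_um = 0, z_um = 0)
  still <- track_set(data.frame(track_id = 1, frame = 0:30,
                                x_um = 5, y_um = 0, z_um = 0))
  # static everything: zero
  r0 <- relative_displacement(still, lm_static, "AP", 30, 1)
  expect_equal(r0$displacement, 0)
  # static cell, moving landmark: minus the landmark displacement
  r1 <- relative_displacement(still, lm_moving, "AP", 30, 1)
  expect_equal(r1$displacement, 60)
  # tracks shorter than the window are excluded and reported
  short <- track_set(data.frame(track_id = 1:2, frame = c(0, 0),
                                x_um = 0, y_um = 0, z_um = 0))
  r2 <- relative_displacement(short, lm_static, "AP", 30, 1)
  expect_equal(nrow(r2), 0)
  expect_length(attr(r2, "excluded"), 2)
})

test_that("AP displacement sign flips between tailbud-tip and nascent-somite references", {
  b <- default_bundle()
  tr <- b$tracks[b$tracks$region == "psm", ]
  wf <- 60
  tip <- relative_displacement(tr, b$landmarks$tailbud_tip, "AP",
                               wf, b$frame_interval)
  som <- relative_displacement(tr, b$landmarks$nascent_somite_boundary, "AP",
                               wf, b$frame_interval)
  # relative to the retreating tailbud tip almost all cells displace anteriorly
  expect_gt(mean(tip$displacement > 0), 0.9)
  # relative to the fixed start-of-movie nascent-somite boundary almost all
  # cells displace posteriorly
  expect_gt(mean(som$displacement < 0), 0.9)
})

test_that("keyframes survive a JSON round trip", {
  kf <- ref_keyframes(c(0L, 5L, 12L),
                      rbind(c(0, 0, 0), c(3, 1, -2), c(5, 5, 5)),
                      list(diag(3), rot3(1, 20), rot3(2, 50)))
  path <- withr::local_tempfile(fileext = ".json")
  write_keyframes_json(kf, path)
  back <- read_keyframes_json(path)
  expect_equal(back$frame, kf$frame)
  expect_equal(back$origin, kf$origin, ignore_attr = TRUE)
  for (i in 1:3) expect_equal(back$axes[[i]], kf$axes[[i]], tolerance = 1e-12)
})
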