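test_that("k-nearest neighbourhoods match a brute-force oracle", {
  # 3 collinear cells at 0, 1, 3: the middle cell's 1-NN is the cell at 0
  pos <- data.frame(id = 1:3, x = c(0, 1, 3), y = 0, z = 0)
  expect_equal(knn_neighbourhood(pos, 2, 1), 1)
  # k = n - 1 returns all other cells
  expect_setequal(knn_neighbourhood(pos, 1, 2), c(2, 3))
  expect_error(knn_neighbourhood(pos, 1, 3), "k \\+ 1")

  # random 50-cell cloud, k = 10: agree with an exhaustive sort
  set.seed(12)
  P <- data.frame(id = 1:50, x = rnorm(50), y = rnorm(50), z = rnorm(50))
  for (target in c(1, 25, 50)) {
    d <- sqrt((P$x - P$x[target])^2 + (P$y - P$y[target])^2 +
                (P$z - P$z[target])^2)
    oracle <- P$id[order(d, P$id)]
    oracle <- oracle[oracle != target][1:10]
    expect_equal(knn_neighbourhood(P, target, 10), oracle)
  }
})

test_that("neighbour exchange counts transits and respects its bounds", {
  # static configuration: all counts zero
  static <- do.call(rbind, lapply(0:10, function(f)
    data.frame(track_id = 1:8, frame = f, x_um = (1:8) * 5,
               y_um = 0, z_um = 0)))
  ex <- neighbour_exchange(track_set(static), k = 2, window_min = 10,
                           frame_interval = 1)
  expect_true(all(ex$count == 0))

  # 5-cell 1D construction: cell 4 transits cell 1's 2-neighbourhood at the
  # middle frame and leaves again; cumulative counts it, endpoint does not
  pos_t <- list(c(0, 1, 2, 10, 50), c(0, 1, 2, 1.5, 50), c(0, 1, 2, 10, 50))
  tr <- track_set(do.call(rbind, lapply(0:2, function(f)
    data.frame(track_id = 1:5, frame = f, x_um = pos_t[[f + 1]],
               y_um = 0, z_um = 0))))
  cum <- neighbour_exchange(tr, k = 2, window_min = 2, frame_interval = 1,
                            mode = "cumulative_entrants", cells = 1)
  endp <- neighbour_exchange(tr, k = 2, window_min = 2, frame_interval = 1,
                             mode = "endpoint_difference", cells = 1)
  expect_equal(cum$count, 1L)
  expect_equal(endp$count, 0L)

  # endpoint-mode bound: 0 <= count <= n_cells - k
  set.seed(5)
  rnd <- track_set(do.call(rbind, lapply(0:6, function(f)
    data.frame(track_id = 1:12, frame = f, x_um = rnorm(12, 0, 3),
               y_um = rnorm(12, 0, 3), z_um = rnorm(12, 0, 3)))))
  exr <- neighbour_exchange(rnd, k = 4, window_min = 6, frame_interval = 1,
                            mode = "endpoint_difference")
  expect_true(all(exr$count >= 0 & exr$count <= 12 - 4))
  expect_error(neighbour_exchange(rnd, k = 4, window_min = 0.2,
                                  frame_interval = 1), "window")
})

test_that("posterior cells exchange more neighbours than anterior cells", {
  b <- default_bundle()
  tr <- b$tracks
  t0 <- tr[tr$frame == 0 & tr$region == "psm", ]
  qs <- stats::quantile(t0$x_um, c(1 / 3, 2 / 3))
  post <- sort(t0$track_id[t0$x_um <= qs[1]])[1:150]
  ant <- sort(t0$track_id[t0$x_um >= qs[2]])[1:150]
  ex <- neighbour_exchange(tr, k = 10, window_min = 60,
                           frame_interval = b$frame_interval,
                           cells = c(post, ant))
  m_post <- mean(ex$count[ex$track_id %in% as.character(post)])
  m_ant <- mean(ex$count[ex$track_id %in% as.character(ant)])
  expect_gt(m_post, m_ant)
  expect_gt(m_post / m_ant, 1.5)  # the fluidity gradient is ~2-fold
})

test_that("pair elevation angles follow the axis conventions", {
  o <- c(0, 0, 0)
  expect_equal(pair_elevation_angle(o, c(5, 0, 0)), 90)   # pure AP separation
  expect_equal(pair_elevation_angle(o, c(-5, 0, 0)), 90)
  expect_equal(pair_elevation_angle(o, c(0, 3, 0)), 0)    # pure DV separation
  expect_equal(pair_elevation_angle(o, c(0, 0, 7)), 0)    # pure ML separation
  expect_equal(pair_elevation_angle(o, c(2, 2, 0)), 45)   # equal AP and DV
  expect_equal(pair_elevation_angle(o, c(2, -2, 0)), -45) # sign from DV
  expect_error(pair_elevation_angle(o, o), "zero-length")
})

test_that("angle changes are exact under a rigid in-plane rotation", {
  set.seed(3)
  P0 <- cbind(runif(40, 0, 60), runif(40, -20, 20), runif(40, 0, 20))
  P1 <- P0 %*% t(rot3(3, 30))   # rigid 30-degree rotation in the AP-DV plane
  rec <- angle_change_analysis(two_frame_tracks(P0, P1), window_min = 30,
                               frame_interval = 1)
  # the projected pair angle of every pair rotates by exactly 30 degrees
  expect_true(all(abs(abs(rec$change) - 30) < 1e-9))
  # no motion: all changes zero
  rec0 <- angle_change_analysis(two_frame_tracks(P0, P0), window_min = 30,
                                frame_interval = 1)
  expect_true(all(rec0$change == 0))
  # pairs are unordered-deduplicated
  expect_false(any(duplicated(t(apply(cbind(rec$id_a, rec$id_b), 1, sort)))))
})

test_that("KS comparison matches the ECDF oracle and the reference implementation", {
  # identical samples: D = 0, p = 1
  same <- compare_angle_distributions(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$d, 0)
  expect_equal(same$p, 1)
  # disjoint samples: D = 1
  expect_equal(compare_angle_distributions(list(a = 1:3, b = 4:6))$d, 1)

  # random small samples: D equals the exhaustive ECDF maximum difference,
  # p equals the asymptotic two-sided reference value
  set.seed(9)
  for (i in 1:10) {
    a <- rnorm(sample(5:40, 1)); b <- rnorm(sample(5:40, 1), 0.4)
    r <- compare_angle_distributions(list(a = a, b = b))
    grid <- c(a, b)
    D_oracle <- max(vapply(grid, function(t) abs(mean(a <= t) - mean(b <= t)),
                           numeric(1)))
    expect_equal(r$d, D_oracle, tolerance = 1e-12)
    ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
    expect_equal(r$d, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(r$p, ref$p.value, tolerance = 1e-4)
  }
  expect_error(compare_angle_distributions(list(a = numeric(0), b = 1:3)),
               "non-empty")
})

test_that("the angle-change null holds under convergence fields without intercalation", {
  # position-dependent DV/ML drift carries no pair-orientation information:
  # the parallel/perpendicular comparison must not reject in >= 90% of seeds
  rejections <- vapply(1:30, function(s) {
    tr <- simulate_field_cloud(n = 450, seed = s)
    ks <- compare_angle_distributions(
      angle_change_analysis(tr, window_min = 60, frame_interval = 2))
    ks$p < 0.05
  }, logical(1))
  expect_lte(mean(rejections), 0.1)
})

test_that("imposed directional intercalation separates the angle distributions", {
  rejections <- vapply(1:8, function(s) {
    tr <- simulate_field_cloud(n = 450, intercalation_rate = 2,
                               seed = 400 + s)
    ks <- compare_angle_distributions(
      angle_change_analysis(tr, window_min = 60, frame_interval = 2))
    ks$p < 0.05
  }, logical(1))
  expect_true(all(rejections))
})

test_that("convergence regression recovers fields exactly and under noise", {
  # zero displacements: slope and intercept both zero
  P0 <- cbind(rep(10, 10), seq(-20, 20, length.out = 10), 0)
  fit0 <- convergence_regression(two_frame_tracks(P0, P0, f1 = 60L),
                                 axis = "DV", window_min = 60,
                                 frame_interval = 1)
  expect_equal(fit0$slope, 0)
  expect_equal(fit0$intercept, 0)

  # noise-free field y = -0.1 x - 0.67 recovered exactly
  y0 <- seq(-50, 50, length.out = 25)
  P0 <- cbind(30, y0, 0)
  P1 <- cbind(30, y0 + (-0.1 * y0 - 0.67), 0)
  fit <- convergence_regression(two_frame_tracks(P0, P1, f1 = 60L),
                                axis = "DV", window_min = 60,
                                frame_interval = 1)
  expect_equal(fit$slope, -0.1, tolerance = 1e-12)
  expect_equal(fit$intercept, -0.67, tolerance = 1e-12)
  expect_equal(fit$r2, 1)

  # sampling distribution at the published design: n = 1161, R2 = 0.2 ->
  # recovered slope within +/-0.03 of the true slope in >= 95% of seeds
  hits <- vapply(1:30, function(s) {
    sim <- simulate_convergence_tracks(1161, -0.1, -0.67, 0.2, seed = 600 + s)
    f <- convergence_regression(sim$tracks, axis = "DV", window_min = 120,
                                frame_interval = 2)
    abs(f$slope - (-0.1)) <= 0.03
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("track statistics are invariant under injected global rigid motion", {
  b <- small_bundle()
  local_back <- transform_to_local(b$tracks_world, b$frames)
  tr0 <- b$tracks[b$tracks$region == "psm", ]
  tr1 <- local_back[local_back$region == "psm", ]

  ex0 <- neighbour_exchange(tr0, k = 5, window_min = 20,
                            frame_interval = b$frame_interval,
                            cells = sort(unique(tr0$track_id))[1:80])
  ex1 <- neighbour_exchange(tr1, k = 5, window_min = 20,
                            frame_interval = b$frame_interval,
                            cells = sort(unique(tr1$track_id))[1:80])
  expect_equal(ex0$count, ex1$count)

  a0 <- angle_change_analysis(tr0, window_min = 30,
                              frame_interval = b$frame_interval)
  a1 <- angle_change_analysis(tr1, window_min = 30,
                              frame_interval = b$frame_interval)
  expect_equal(a0$change, a1$change, tolerance = 1e-6)
  k0 <- compare_angle_distributions(a0)
  k1 <- compare_angle_distributions(a1)
  expect_equal(k0$d, k1$d, tolerance = 1e-9)
})
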