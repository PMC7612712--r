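#!/usr/bin/env Rscript
# Track statistics: reference-frame normalisation, landmark-relative AP
# displacement, the neighbourhood-exchange fluidity gradient, the
# neighbour-pair angle-change analysis with its KS null and intercalation
# positive control, and the DV/ML convergence regressions.

library(compext)

out_dir <- "results/04_track_statistics"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

b <- simulate_tissue(sim_config(seed = 1L))
fi <- b$frame_interval

## Moving-reference-frame normalisation removes the injected rigid motion
back <- transform_to_local(b$tracks_world, b$frames)
err <- max(abs(as.matrix(back[, c("x_um", "y_um", "z_um")]) -
                 as.matrix(b$tracks[, c("x_um", "y_um", "z_um")])))
message(sprintf("Drift/rotation round trip: max error %.2g um", err))

## AP displacement depends on the landmark chosen
tr <- b$tracks[b$tracks$region == "psm", ]
for (lm in c("tailbud_tip", "nascent_somite_boundary")) {
  rd <- relative_displacement(tr, b$landmarks[[lm]], "AP", 60, fi)
  message(sprintf("vs %-24s %2.0f%% of cells displace anteriorly over 60 min",
                  lm, 100 * mean(rd$displacement > 0)))
}

## Neighbourhood exchange: posterior cells mix more (k = 10, 60 min)
t0 <- tr[tr$frame == 0, ]
qs <- quantile(t0$x_um, c(1 / 3, 2 / 3))
post <- sort(t0$track_id[t0$x_um <= qs[1]])[1:150]
ant <- sort(t0$track_id[t0$x_um >= qs[2]])[1:150]
# the candidate cloud keeps somite-frozen cells: a neighbour that segments
# into a somite stays in place and must not count as an exchange
ex <- neighbour_exchange(b$tracks, k = 10, window_min = 60,
                         frame_interval = fi, cells = c(post, ant))
ex$zone <- ifelse(ex$track_id %in% as.character(post), "posterior", "anterior")
agg <- aggregate(count ~ zone, ex, mean)
print(agg, row.names = FALSE)
message(sprintf("Posterior/anterior exchange ratio: %.2f",
                agg$count[agg$zone == "posterior"] /
                  agg$count[agg$zone == "anterior"]))
utils::write.csv(ex, file.path(out_dir, "neighbour_exchange.csv"),
                 row.names = FALSE)

## Angle-change analysis on the tissue (reported) and the field-cloud null
ang <- angle_change_analysis(tr, window_min = 60, frame_interval = fi)
utils::write.csv(ang, file.path(out_dir, "angle_pairs.csv"), row.names = FALSE)
ks_tissue <- compare_angle_distributions(ang)
message(sprintf("Full tissue pairs (n = %d): KS D = %.3f, p = %.3g",
                nrow(ang), ks_tissue$d, ks_tissue$p))

cloud <- simulate_field_cloud(n = 450, seed = 2L)
ks_null <- compare_angle_distributions(
  angle_change_analysis(cloud, window_min = 60, frame_interval = 2))
message(sprintf("Convergence-field null:  KS D = %.3f, p = %.3f (no intercalation)",
                ks_null$d, ks_null$p))
pos <- simulate_field_cloud(n = 450, intercalation_rate = 2, seed = 2L)
ks_pos <- compare_angle_distributions(
  angle_change_analysis(pos, window_min = 60, frame_interval = 2))
message(sprintf("Intercalation control:   KS D = %.3f, p = %.2g (rejected)",
                ks_pos$d, ks_pos$p))

## DV and ML convergence regressions at the published design
for (ax in c("DV", "ML")) {
  f <- psm_reference_fields()[[ax]]
  sim <- simulate_convergence_tracks(f$n, f$slope, f$intercept, f$r2,
                                     window_min = f$window_min,
                                     frame_interval = fi, axis = ax,
                                     seed = 10 + match(ax, c("DV", "ML")))
  fit <- convergence_regression(sim$tracks, axis = ax,
                                window_min = f$window_min,
                                frame_interval = fi)
  message(sprintf("%s convergence: y = %.3f x %+.2f (R2 = %.2f, n = %d)",
                  ax, fit$slope, fit$intercept, fit$r2, fit$n))
}
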