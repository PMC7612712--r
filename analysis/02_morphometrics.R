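#!/usr/bin/env Rscript
# Tissue-scale morphometrics: the worked examples computed from the published
# stage-trendline equations, trendline refits of the simulated stage series,
# and the photolabel deformation gradient.

library(compext)

out_dir <- "results/02_morphometrics"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
tl <- psm_reference_trendlines()

## Density increase over stages 16-30 (the "~80%" figure)
inc <- 100 * (evaluate_trendline(tl$density, 30) /
                evaluate_trendline(tl$density, 16) - 1)
message(sprintf("Density trendline increase 16 -> 30: %.1f%%", inc))

## Mean decline of the four PSM height/width trendlines ("~50%")
dims <- c("height_posterior", "width_posterior",
          "height_anterior", "width_anterior")
dec <- vapply(dims, function(d)
  100 * (1 - evaluate_trendline(tl[[d]], 30) /
           evaluate_trendline(tl[[d]], 16)), numeric(1))
message(sprintf("Mean H/W decline 16 -> 30: %.1f%% (range %.1f-%.1f%%)",
                mean(dec), min(dec), max(dec)))

## Cumulative paraxial reconstruction (cells: "~+10%"; volume decreasing)
cum_cells <- cumulative_paraxial(tl$psm_cells, tl$somite_cells, 16, 32)
cum_vol <- cumulative_paraxial(tl$psm_volume, tl$somite_volume, 16, 32)
message(sprintf("Cumulative paraxial cell number 16 -> 32: %+.1f%%",
                100 * (cum_cells$cumulative[17] / cum_cells$cumulative[1] - 1)))
message(sprintf("Cumulative paraxial volume 16 -> 32: %+.1f%% (monotone decrease: %s)",
                100 * (cum_vol$cumulative[17] / cum_vol$cumulative[1] - 1),
                all(diff(cum_vol$cumulative) < 0)))
utils::write.csv(cum_cells, file.path(out_dir, "cumulative_cells.csv"),
                 row.names = FALSE)
utils::write.csv(cum_vol, file.path(out_dir, "cumulative_volume.csv"),
                 row.names = FALSE)

## Refit trendlines to the simulated stage series (AIC family selection)
ss <- utils::read.csv("results/01_simulate/stage_series.csv")
refits <- data.frame(
  quantity = c("psm_cells", "psm_volume", "density"),
  t(vapply(c("psm_cells", "psm_volume", "density"), function(q) {
    m <- fit_trendline(ss$stage, ss[[q]])
    c(form = m$form, a = format(m$a, digits = 6),
      b = format(m$b, digits = 6), r2 = round(m$r2, 4))
  }, character(4))))
print(refits, row.names = FALSE)
utils::write.csv(refits, file.path(out_dir, "trendline_refits.csv"),
                 row.names = FALSE)

## Photolabel deformation: posterior stripes converge-extend, anterior do not
b <- simulate_tissue(sim_config(seed = 1L))
rows <- lapply(seq(0.1, 0.9, 0.2), function(fr) {
  b2 <- make_photolabel(b, fr, 30, name = "stripe")
  f120 <- round(120 / b$frame_interval)
  label_deformation(b2, b2$label_sets$stripe, 0, f120)
})
lab <- do.call(rbind, rows)
print(lab[, c("ap_position_norm", "ratio_fold_change")], row.names = FALSE)
fit <- fit_trendline(lab$ap_position_norm, lab$ratio_fold_change)
message(sprintf("Fold-change vs position: %s fit, slope %.2f (negative = posterior deforms more)",
                fit$form, fit$a))
utils::write.csv(lab, file.path(out_dir, "photolabel_deformation.csv"),
                 row.names = FALSE)

## Cell-volume comparison between stages (18SS vs 26SS, n = 25 cells each)
a <- sample_cell_volumes(18, 25, cv = 0.2, seed = 18)
bb <- sample_cell_volumes(26, 25, cv = 0.2, seed = 26)
tt <- compare_cell_volumes(a, bb)
message(sprintf("Cell volumes 18SS (mean %.0f) vs 26SS (mean %.0f): t = %.2f, p = %.2g",
                tt$mean_a, tt$mean_b, tt$t, tt$p))
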