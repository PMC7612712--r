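#!/usr/bin/env Rscript
# End-to-end reproducible benchmark: simulate -> measure -> normalise ->
# statistics, with a machine-readable JSON report and acceptance-check
# booleans.

library(compext)

report <- run_benchmark(sim_config(seed = 1L),
                        out_dir = "results/05_benchmark")
message(sprintf("density increase (simulated span): %.1f%%",
                report$density_increase_pct))
message(sprintf("cumulative paraxial cell number:   %+.1f%%",
                report$cumulative_cell_increase_pct))
message(sprintf("DV slope %.3f / ML slope %.3f",
                report$convergence$DV$fit$slope,
                report$convergence$ML$fit$slope))
message("checks:")
for (k in names(report$checks))
  message(sprintf("  %-38s %s", k, report$checks[[k]]))
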