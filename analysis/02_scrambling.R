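#!/usr/bin/env Rscript
# Stage 2: quantify lipid scrambling in the stage-1 trajectories. Snapshots
# every 10 ns are assigned to leaflets by phosphate position relative to the
# membrane center; the trace reports the instantaneous scrambled-lipid count
# (with a 200 ns running average, as the reference analyses plot) and the
# cumulative transition events that define the per-microsecond rate.
# A barrier scan documents the Kramers-like rate suppression.

suppressMessages(library(scramblekit))
dir.create("results", showWarnings = FALSE)

analyse <- function(name, n_lipids, n_protein = 0) {
  path <- file.path("results", paste0(name, ".sktrj"))
  if (!file.exists(path)) stop("run analysis/01_simulate.R first (missing ",
                               path, ")")
  top <- system_topology(c(rep("PO4", n_lipids), rep("BB", n_protein)),
                         c(rep("POPC", n_lipids), rep("PROT", n_protein)),
                         seq_len(n_lipids + n_protein))
  traj <- read_trajectory(path, top)
  tr <- scrambling_trace(traj, interval = 10, smoothing_window = 200)
  utils::write.table(as.data.frame(tr),
                     file.path("results", paste0(name, "_trace.tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  r <- scrambling_rate(tr, seed = 11)
  cat(sprintf("%-12s events %4d  rate %6.2f events/us  (95%% CI %.2f-%.2f)\n",
              name, r$events, r$rate, r$ci[1], r$ci[2]))
  r
}

r_plain <- analyse("proteinless", 290)
r_groove <- analyse("groove", 64, n_protein = 12)

# Barrier dependence: flip events drop steeply with barrier height at fixed
# diffusion and temperature (desk-scale analogue of the rate suppression in
# the high-barrier membranes).
scan <- do.call(rbind, lapply(c(5, 10, 20), function(B) {
  sc <- membrane_scenario(paste0("scan", B), 100,
                          potential = flipflop_potential(B),
                          duration = 2000, snapshot_interval = 10, seed = 33)
  tr <- scrambling_trace(simulate_unbiased(sc), interval = 10)
  data.frame(barrier_kJmol = B,
             events = tr$cumulative_events[nrow(tr)],
             rate_per_us = scrambling_rate(tr)$rate)
}))
utils::write.table(scan, "results/barrier_rate_scan.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
cat("barrier scan (events over 2 us, 100 lipids):\n")
print(scan, row.names = FALSE)
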