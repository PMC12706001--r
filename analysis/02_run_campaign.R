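#!/usr/bin/env Rscript
# Runs the desk-scale simulation campaign: 2 tail states x 3 initial
# positions x 10 seeds x 1e5 Langevin steps (the scaled-down analogue of
# the full 20-seed, 3e7-step protocol).  Takes roughly 10-15 minutes on
# one CPU.  Writes the per-trajectory manifest and center-of-geometry
# series under results/, and the campaign object (with contact
# accumulators) under scratch/ for the downstream scripts.
library(dynlattice)
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

args <- commandArgs(trailingOnly = TRUE)
base_seed <- if (length(args) >= 1) as.integer(args[1]) else 1L

camp <- run_campaign(n_seeds = 10, base_seed = base_seed)
print(camp)
write.csv(camp$manifest, "results/campaign_manifest.csv",
          row.names = FALSE)

com <- do.call(rbind, lapply(seq_along(camp$trajectories), function(k) {
  tr <- camp$trajectories[[k]]
  data.frame(run = k, state = tr$metadata$tail_state,
             position = tr$metadata$position_id,
             seed = tr$metadata$seed, step = tr$steps,
             x = tr$com_low[, 1], y = tr$com_low[, 2],
             z = tr$com_low[, 3])
}))
write.csv(com, "results/com_series.csv", row.names = FALSE)
saveRDS(camp, "scratch/campaign.rds")
cat("manifest, COM series -> results/; campaign object -> scratch/\n")
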