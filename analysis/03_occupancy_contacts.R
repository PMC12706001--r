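#!/usr/bin/env Rscript
# Trajectory statistics of the campaign produced by 02_run_campaign.R:
# binding-site occupancy heatmaps (per initial position and summed) with
# burn-in exclusion, the overflow proportion per tail state with a
# bootstrap CI, the Y-vs-dY differential contact map, and the
# leading-head order statistic.
library(dynlattice)
dir.create("results", showWarnings = FALSE)
camp <- readRDS("scratch/campaign.rds")
grid <- camp$grid
bi <- camp$params$burn_in_steps

state_trajs <- function(st)
  Filter(function(t) t$metadata$tail_state == st, camp$trajectories)

rows <- list()
for (st in c("Y", "dY")) {
  trs <- state_trajs(st)
  occ <- occupancy(trs, grid, burn_in = bi)
  ov <- overflow_proportion(trs, grid, burn_in = bi, boot_seed = 7)
  cat("==", st, "lattice ==\n")
  print(occ)
  cat(sprintf("overflow %.1f%% (95%% CI %.1f-%.1f), n = %d\n\n",
              ov$percent, ov$ci[1], ov$ci[2], ov$n))
  g <- occ$summed_grid
  rows[[st]] <- data.frame(state = st, row = rep(0:2, 3),
                           col = rep(0:2, each = 3),
                           frequency = as.vector(g),
                           overflow_percent = ov$percent)
  write.csv(as.data.frame(occ$summed_grid),
            sprintf("results/occupancy_summed_%s.csv", st))
  lead <- vapply(trs, leading_head_fraction, axis = c(1, 0, 0),
                 burn_in = bi, FUN.VALUE = 1)
  cat(sprintf("mean leading-head fraction (%s): %.2f\n\n", st,
              mean(lead)))
}
write.csv(do.call(rbind, rows), "results/occupancy_long.csv",
          row.names = FALSE)

dm <- diff_contact_map(camp$contacts$dY, camp$contacts$Y)
write.csv(as.data.frame(dm$delta), "results/diff_contact_map.csv")
tail_cols <- grepl("^T_", colnames(dm$delta))
cat(sprintf("differential contacts (dY - Y): E-hook mean %+.4f, body mean %+.4f\n",
            mean(dm$delta[, tail_cols]), mean(dm$delta[, !tail_cols])))
ord <- order(abs(dm$delta), decreasing = TRUE)[1:10]
idx <- arrayInd(ord, dim(dm$delta))
cat("strongest changes upon detyrosination:\n")
for (k in seq_len(10))
  cat(sprintf("  %-10s %-16s %+.3f\n", rownames(dm$delta)[idx[k, 1]],
              colnames(dm$delta)[idx[k, 2]], dm$delta[ord[k]]))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  d <- do.call(rbind, rows)
  p <- ggplot(d, aes(factor(col), factor(row), fill = frequency)) +
    geom_tile() +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                         midpoint = median(d$frequency)) +
    facet_wrap(~state) +
    labs(x = "lateral site", y = "axial site (toward minus end)",
         title = "Low-affinity head occupancy, summed over positions") +
    theme_minimal()
  ggsave("results/occupancy_heatmap.png", p, width = 7, height = 3.2,
         dpi = 150)
  cat("heatmap figure -> results/occupancy_heatmap.png\n")
}
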