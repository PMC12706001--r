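#!/usr/bin/env Rscript
# Regenerates the small plain-text fixtures shipped under inst/extdata/.
# Both are synthetic stand-ins with known ground truth:
#  - synthetic_dimer_configurations.json: 43 motor dimers on five doublet
#    axes whose class composition (7, 11, 13, 12) of Configurations
#    1/2/3/other reproduces the printed one-decimal percentages
#    (16.3 / 25.6 / 30.2 / 27.9).
#  - synthetic_psm_table.csv: a peptide-spectrum-match table generated at
#    tyrosinated fraction 0.337 and glutamylation fraction 0.0635.
library(dynlattice)

out_dir <- file.path("inst", "extdata")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

classes <- rep(c("1", "2", "3", "other"), c(7, 11, 13, 12))
set.seed(43)
classes <- sample(classes)
per_doublet <- c(9, 9, 9, 8, 8)
doublets <- list()
k <- 0
for (d in seq_along(per_doublet)) {
  n <- per_doublet[d]
  cls <- classes[(k + 1):(k + n)]
  k <- k + n
  axis_len <- 900
  s <- seq(60, axis_len - 60, length.out = n)
  heads <- do.call(rbind, lapply(seq_len(n), function(i) {
    base <- c(s[i], 4, 12)
    off <- switch(cls[i],
                  "1" = c(8, -3.5, 0), "2" = c(0, -3.5, 0),
                  "3" = c(-8, -3.5, 0), "other" = c(6, 0, 0))
    rbind(
      data.frame(head_id = 2 * i - 1, x = base[1], y = base[2],
                 z = base[3], tubule = "A", dimer_id = i),
      data.frame(head_id = 2 * i, x = base[1] + off[1],
                 y = base[2] + off[2], z = base[3] + off[3],
                 tubule = "A", dimer_id = i))
  }))
  doublets[[d]] <- list(
    doublet_id = sprintf("synthetic_doublet_%d", d),
    polarity = 1,
    outward_normal = c(0, 0, 1),
    axis = cbind(x = c(0, axis_len), y = 0, z = 0),
    heads = heads,
    true_classes = cls)
}
jsonlite::write_json(doublets,
                     file.path(out_dir, "synthetic_dimer_configurations.json"),
                     digits = NA, auto_unbox = TRUE)

tab <- gen_psm_table(frac_Y = 0.337, frac_glu = 0.0635, n_records = 1500,
                     seed = 20250927)
write.csv(tab, file.path(out_dir, "synthetic_psm_table.csv"),
          row.names = FALSE)
cat("fixtures written to", out_dir, "\n")
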