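#!/usr/bin/env Rscript
# Stage 4 — spatial phylogenetics. Stacks the focal-species distribution
# maps into assemblages and maps SR, PD, RPD and PE (raw and 0-1
# scaled).

source("analysis/00_common.R")

p <- get_pipeline()

for (m in c("SR", "PD", "RPD", "PE")) {
  write_raster(p$diversity[[m]], sprintf("results/%s.asc", tolower(m)))
  write_raster(p$diversity$scaled[[m]],
               sprintf("results/%s_scaled.asc", tolower(m)))
}
write.csv(p$cell_table, "results/cell_table.csv", row.names = FALSE)

core <- p$world$core$values == 1
sr <- p$diversity$SR$values
message(sprintf("mean richness: %.1f inside core vs %.1f outside",
                mean(sr[core], na.rm = TRUE),
                mean(sr[!core], na.rm = TRUE)))
message(sprintf("PE sums to %.4f = occurring subtree length",
                sum(p$diversity$PE$values, na.rm = TRUE)))
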