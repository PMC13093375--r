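#!/usr/bin/env Rscript
# Stage 3 — forest and climate stability. Stacks the thresholded
# indicator hindcasts into the stability surface, delineates nested
# refugia, and compares the strictest class with the planted core.

source("analysis/00_common.R")

p <- get_pipeline()

write_raster(p$stability$normalized, "results/forest_stability.asc")
write_raster(p$distance, "results/distance_to_refugium.asc")
for (f in names(p$refugia))
  write_raster(p$refugia[[f]],
               sprintf("results/refugia_%s.asc", gsub("\\.", "", f)))
write_raster(p$climate_stability$BIO1$stability,
             "results/temp_stability.asc")
write_raster(p$climate_stability$BIO12$stability,
             "results/precip_stability.asc")

sizes <- vapply(p$refugia, function(m) sum(m$values == 1, na.rm = TRUE),
                numeric(1))
message("refugia cells by species fraction (tau = ",
        p$parameters$tau, " of ", p$world$config$T, " slices):")
print(sizes)
message(sprintf("Jaccard(strictest refugia, planted core) = %.3f",
                mask_jaccard(p$refugia[["0.95"]], p$world$core)))
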