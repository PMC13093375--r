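#!/usr/bin/env Rscript
# Stage 2 — niche models. Fits the ridge-logistic maximum-entropy-style
# model for every species, applies the record-count and AUC screens, and
# reports each model's 95% minimum-occurrence threshold.

source("analysis/00_common.R")

p <- get_pipeline()

models <- do.call(rbind, lapply(p$models, function(m)
  data.frame(species = m$species, status = m$status,
             n_presence = m$n_presence,
             auc = if (is.null(m$auc)) NA else m$auc,
             threshold = if (is.null(m$threshold)) NA else m$threshold)))
write.csv(models, "results/enm_models.csv", row.names = FALSE)

message(sprintf("fitted %d models: %d accepted, %d rejected by AUC, %d by records",
                nrow(models), sum(models$status == "accepted"),
                sum(models$status == "rejected_auc"),
                sum(models$status == "rejected_records")))
message(sprintf("AUC range among accepted models: %.3f - %.3f",
                min(models$auc[models$status == "accepted"]),
                max(models$auc[models$status == "accepted"])))
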