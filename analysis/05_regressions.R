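#!/usr/bin/env Rscript
# Stage 5 — spatial regressions. Collinearity screen, the univariate
# OLS/SLX battery contrasting contemporary and past predictors, the
# contemporary-vs-past multivariate comparison, stepwise AIC subset
# selection, and the distance-decay fits.

source("analysis/00_common.R")

p <- get_pipeline()

screen <- p$regressions$screen
write.csv(round(screen$matrix, 3), "results/predictor_correlations.csv")
message(sprintf("max |r| among predictors: %.2f (%d pair(s) above 0.7)",
                max(abs(screen$matrix[upper.tri(screen$matrix)])),
                nrow(screen$flagged)))

uv <- summarize_univariate(p)
write.csv(uv, "results/univariate_regressions.csv", row.names = FALSE)
for (m in unique(uv$metric)) {
  d <- uv[uv$metric == m, ]
  top <- d[which.max(d$ols_r2), ]
  message(sprintf("%-4s best univariate predictor: %s (coef %.2f, R2 %.2f)",
                  m, top$predictor, top$ols_coef, top$ols_r2))
}

mv <- summarize_multivariate(p)
write.csv(mv, "results/multivariate_regressions.csv", row.names = FALSE)
past_r2 <- unique(mv[mv$set == "past" & mv$model == "OLS", c("metric", "r2")])
cont_r2 <- unique(mv[mv$set == "contemporary" & mv$model == "OLS",
                     c("metric", "r2")])
message("multivariate OLS R2, past vs contemporary variable sets:")
print(merge(past_r2, cont_r2, by = "metric",
            suffixes = c("_past", "_contemporary")))

sw <- do.call(rbind, lapply(names(p$regressions$stepwise), function(m)
  data.frame(metric = m,
             selected = paste(p$regressions$stepwise[[m]]$selected,
                              collapse = "+"),
             r2 = p$regressions$stepwise[[m]]$result$r2)))
write.csv(sw, "results/stepwise_selection.csv", row.names = FALSE)

dd <- summarize_distance_decay(p)
write.csv(dd, "results/distance_decay.csv", row.names = FALSE)
message("distance-decay standardized OLS slopes:")
print(dd[, c("metric", "ols_slope", "ols_p")])
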