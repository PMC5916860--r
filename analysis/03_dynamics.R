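#!/usr/bin/env Rscript
# Stage 3: growth-pattern comparison and dynamic characteristics.
#
# Fits power, exponential and sigmoidal-logistic laws to the treatment-mean
# FIL expansion curves (compared by R^2 and AIC), then quantifies every
# plant's dynamics as RGR (shape: LA, LP, EA, ED) and ACR (color: G, NRI,
# DGCI, ExG, ExR) over the 3-day (P1..P7) and 6-day (P1'..P3') interval
# schemes.

library(riceleafdyn)

features <- read.csv("results/cohort/features.csv", stringsAsFactors = FALSE)

fits <- rbind(growth_fit_report(features, "LA", "FIL"),
              growth_fit_report(features, "LP", "FIL"))
write.csv(fits, "results/growth_fits.csv", row.names = FALSE)
cat("growth-model comparison (FIL):\n")
print(fits[, c("treatment", "characteristic", "model", "r2", "aic", "selected")],
      digits = 4)
sel <- fits[fits$selected, ]
cat(sprintf("\nselected model: %s in %d/%d treatment x characteristic cells\n",
            names(sort(table(sel$model), decreasing = TRUE))[1],
            max(table(sel$model)), nrow(sel)))

schedule <- sort(unique(features$dat))
for (sp in c(3, 6)) {
  scheme <- build_interval_scheme(schedule, sp)
  dyn <- dynamic_features(features, scheme)
  write.csv(dyn, sprintf("results/dyn%d.csv", sp), row.names = FALSE)
  cat(sprintf("%d-day intervals: %d periods (%s), %d plant-period rows\n",
              sp, nrow(scheme), paste(scheme$id, collapse = " "), nrow(dyn)))
}
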