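#!/usr/bin/env Rscript
# Stage 5: SVM diagnosis of the four N levels from the dynamic
# characteristics, for every single period, every cumulative time-ordered
# combination (P1P2, P1P2P3, ...), each leaf position and the FIL + 3rd
# combination, evaluated by resubstitution (training) and leave-one-out
# (validation) accuracy.

library(riceleafdyn)

dyn <- list(`3d` = read.csv("results/dyn3.csv", stringsAsFactors = FALSE),
            `6d` = read.csv("results/dyn6.csv", stringsAsFactors = FALSE))
schedule <- seq(20, 44, by = 3)
attr(dyn$`3d`, "scheme") <- build_interval_scheme(schedule, 3)
attr(dyn$`6d`, "scheme") <- build_interval_scheme(schedule, 6)

grid <- evaluate_grid(dyn)
write.csv(grid$report, "results/diagnosis.csv", row.names = FALSE)
best_pos <- best_position_summary(grid$report)
write.csv(best_pos, "results/best_position.csv", row.names = FALSE)
jsonlite::write_json(grid$confusions, "results/confusions.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

ok <- grid$report[grid$report$note == "", ]
cat(sprintf("evaluated %d data-set x position models (n per model up to %d)\n",
            nrow(ok), max(ok$n_used)))
best <- ok[which.max(ok$validation_acc), ]
cat(sprintf("best LOOCV validation: %.1f%% (training %.1f%%) for %s, %s, %s\n",
            100 * best$validation_acc, 100 * best$training_acc,
            best$positions, best$data_set, best$spacing))
cat("\nbest single-position choice per data set (head):\n")
print(head(best_pos, 10))
cat("\ncombined early data sets on the FIL vs late 3rd-leaf sets:\n")
show <- ok[ok$positions %in% c("FIL", "3rd", "FIL+3rd") & !ok$single, ]
print(show[order(-show$validation_acc),
           c("spacing", "data_set", "positions", "training_acc", "validation_acc")][1:10, ])
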