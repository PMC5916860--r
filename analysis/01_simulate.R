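#!/usr/bin/env Rscript
# Stage 1: simulate the two-season scanning campaign.
#
# The cohort mirrors the study design: 4 ammonium-nitrate levels (N1 = 0 to
# N4 = 114.30 mg/L) x 5 replicate plants x 2 years, leaves scanned every
# 3 days from DAT 20 to DAT 44 at 4 positions (FIL, 1st, 2nd, 3rd). The
# full cohort uses the generator's analytic ground truth (fast); a handful
# of scans are also rendered to PNG so the extraction stage can be
# validated on real rasters (see 02_extract_features.R).

library(riceleafdyn)

SEED <- 20140520
cfg <- experiment_config(master_seed = SEED)

dir.create("results/cohort", recursive = TRUE, showWarnings = FALSE)
ex <- generate_experiment(cfg, render = FALSE)
write.csv(ex$truth, "results/cohort/truth.csv", row.names = FALSE)
write.csv(ex$features, "results/cohort/features.csv", row.names = FALSE)

cat(sprintf("cohort: %d observations (%d missing through 3rd-leaf senescence)\n",
            nrow(ex$truth), sum(ex$truth$missing)))
la44 <- subset(ex$truth, dat == 44 & leaf_position == "FIL" & !missing)
cat("mean FIL area at DAT 44 by treatment (cm^2):\n")
print(round(tapply(la44$la, la44$treatment, mean), 2))
ed38 <- subset(ex$truth, dat == 38 & leaf_position == "3rd" & !missing)
cat("mean 3rd-leaf etiolation degree at DAT 38 by treatment:\n")
print(round(tapply(ed38$ed, ed38$treatment, mean), 3))

# a small rendered subset (one plant per treatment, 3rd leaf + FIL) for the
# extraction validation; scans go under scratch/ (regenerable rasters)
demo_cfg <- experiment_config(replicates = 1, years = 1, dpi = 100,
                              master_seed = SEED)
demo <- generate_experiment(demo_cfg, out_dir = "scratch/demo_scans",
                            render = TRUE)
cat(sprintf("rendered %d demo scans to scratch/demo_scans/\n",
            sum(!demo$truth$missing)))
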