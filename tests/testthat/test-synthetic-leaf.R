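test_that("plant parameter sampling is deterministic and exact at zero CV", {
  prof <- default_treatment_profiles()$N2
  a <- sample_plant_parameters(prof, seed = 123)
  b <- sample_plant_parameters(prof, seed = 123)
  expect_identical(a, b)
  c <- sample_plant_parameters(prof, seed = 124)
  expect_false(identical(a$leaves, c$leaves))

  exact <- sample_plant_parameters(prof, seed = 5, cv = 0)
  expect_equal(exact$leaves$FIL$A, prof$area_A)
  expect_equal(exact$leaves$FIL$k, prof$area_k)
  expect_equal(exact$leaves$FIL$t0, prof$area_t0)
  expect_equal(exact$base_rgb, prof$base_rgb)
  expect_equal(exact$front_speed, prof$front_speed)

  expect_error(sample_plant_parameters(prof, seed = 1, cv = -0.1), "cv")
})

test_that("lognormal plant variability realizes the configured CV", {
  prof <- default_treatment_profiles()$N3
  A <- vapply(seq_len(1000), function(s)
    sample_plant_parameters(prof, seed = s, cv = 0.1)$leaves$FIL$A, 0)
  cv_hat <- stats::sd(A) / mean(A)
  expect_gt(cv_hat, 0.08)
  expect_lt(cv_hat, 0.12)
  # mean-preserving parameterization
  expect_equal(mean(A), prof$area_A, tolerance = 0.02)
})

test_that("rendered blade area follows the logistic law (midpoint check)", {
  cfg <- experiment_config(dpi = 100, noise_sd = 0, master_seed = 1)
  prof <- default_treatment_profiles()$N4
  p <- sample_plant_parameters(prof, seed = 2, cv = 0, plant_id = "mid")
  obs <- render_leaf_image(p, dat = prof$area_t0, "FIL", cfg)
  expect_equal(obs$truth$la, prof$area_A / 2, tolerance = 0.02)
  expect_equal(obs$truth$la_analytic, prof$area_A / 2, tolerance = 1e-12)
})

test_that("etiolation truth is stronger under N deficiency on the 3rd leaf", {
  cfg <- experiment_config(dpi = 100, noise_sd = 0, master_seed = 1)
  profs <- default_treatment_profiles()
  p1 <- sample_plant_parameters(profs$N1, seed = 3, cv = 0)
  p4 <- sample_plant_parameters(profs$N4, seed = 3, cv = 0)
  t1 <- render_leaf_image(p1, 38, "3rd", cfg)$truth
  t4 <- render_leaf_image(p4, 38, "3rd", cfg)$truth
  expect_gt(t1$ed, t4$ed)
  expect_gt(t1$ed, 0.3)
})

test_that("rendering is reproducible: zero noise gives bit-identical images", {
  cfg <- experiment_config(dpi = 100, noise_sd = 0, master_seed = 1)
  p <- sample_plant_parameters(default_treatment_profiles()$N2, seed = 9)
  a <- render_leaf_image(p, 26, "1st", cfg)
  b <- render_leaf_image(p, 26, "1st", cfg)
  expect_identical(a$image$pixels, b$image$pixels)
  # and with noise, the derived per-observation seed keeps it reproducible
  cfg$noise_sd <- 2
  expect_identical(render_leaf_image(p, 26, "1st", cfg)$image$pixels,
                   render_leaf_image(p, 26, "1st", cfg)$image$pixels)
})

test_that("cohort bookkeeping: counts, senescence missingness, determinism", {
  cfg <- experiment_config(treatments = no_senescence_profiles(),
                           replicates = 5, years = 1, master_seed = 11)
  ex <- generate_experiment(cfg, render = FALSE)
  # 4 treatments x 5 plants x 9 DATs x 4 positions, no senescence
  expect_equal(nrow(ex$truth), 720)
  expect_equal(sum(ex$truth$missing), 0)
  expect_equal(nrow(ex$features), 720)

  profs <- default_treatment_profiles()
  for (nm in names(profs)) profs[[nm]]$senescence_dat <- 34
  cfg2 <- experiment_config(treatments = profs, replicates = 2, years = 1,
                            master_seed = 11)
  ex2 <- generate_experiment(cfg2, render = FALSE)
  third_late <- ex2$truth$leaf_position == "3rd" & ex2$truth$dat >= 35
  expect_true(all(ex2$truth$missing[third_late]))
  expect_true(all(ex2$truth$reason[third_late] == "senesced"))
  expect_false(any(ex2$truth$missing[!third_late]))

  ex3 <- generate_experiment(cfg2, render = FALSE)
  expect_identical(ex2$truth, ex3$truth)
  expect_identical(ex2$features, ex3$features)
})

test_that("ground truth satisfies its own invariants", {
  ex <- small_cohort(seed = 21, replicates = 3,
                     positions = c("FIL", "1st", "2nd", "3rd"))
  tr <- ex$truth[!ex$truth$missing, ]
  expect_true(all(tr$ea <= tr$la + 1e-12))
  expect_true(all(abs(tr$ed - tr$ea / tr$la) < 1e-9))
  expect_true(all(tr$ed >= 0 & tr$ed <= 1))
  # LA non-decreasing in DAT for every plant x position
  key <- paste(tr$plant_id, tr$leaf_position)
  for (k in unique(key)) {
    sub <- tr[key == k, ]
    sub <- sub[order(sub$dat), ]
    expect_true(all(diff(sub$la) >= -1e-9))
  }
  # ED non-decreasing on the 3rd leaf
  third <- tr[tr$leaf_position == "3rd", ]
  for (p in unique(third$plant_id)) {
    sub <- third[third$plant_id == p, ]
    sub <- sub[order(sub$dat), ]
    expect_true(all(diff(sub$ed) >= -1e-9))
  }
})

test_that("mean final leaf area increases with nitrogen supply", {
  ex <- small_cohort(seed = 33, replicates = 5, positions = "FIL")
  last <- ex$truth[ex$truth$dat == 44 & !ex$truth$missing, ]
  m <- tapply(last$la, last$treatment, mean)
  expect_true(all(diff(m[c("N1", "N2", "N3", "N4")]) > 0))
})

test_that("senesced observations are flagged, not rendered", {
  cfg <- experiment_config(dpi = 100, master_seed = 1)
  prof <- default_treatment_profiles()$N1 # senescence_dat = 38
  p <- sample_plant_parameters(prof, seed = 4, cv = 0)
  obs <- render_leaf_image(p, 41, "3rd", cfg)
  expect_true(is_missing_observation(obs))
  expect_equal(obs$reason, "senesced")
  expect_false(is_missing_observation(render_leaf_image(p, 38, "3rd", cfg)))
})
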