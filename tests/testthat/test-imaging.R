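test_that("leaf segmentation recovers a known blob and rejects empty scenes", {
  img <- uniform_image(200, 300, WHITE_BG, dpi = 300)
  truth <- ellipse_mask(200, 300, 150, 100, 90, 40)
  img <- paint(img, truth, GREEN_110)
  mask <- segment_leaf(img)
  expect_lt(abs(sum(mask) - sum(truth)) / sum(truth), 0.01)

  expect_error(segment_leaf(uniform_image(50, 50, WHITE_BG)),
               class = "rld_no_leaf")

  # two blobs, one much larger: only the larger is kept
  img2 <- uniform_image(200, 300, WHITE_BG)
  big <- ellipse_mask(200, 300, 100, 100, 60, 40)
  small <- ellipse_mask(200, 300, 270, 30, 8, 8)
  img2 <- paint(paint(img2, big, GREEN_110), small, YELLOW_50)
  m2 <- segment_leaf(img2)
  expect_true(all(m2[big]))
  expect_false(any(m2[small]))
})

test_that("area calibration follows pixel size exactly", {
  mask <- rect_mask(120, 120, 11:110, 11:110) # 10,000 px
  expect_equal(measure_area(mask, 300), 10000 * (2.54 / 300)^2)
  expect_equal(measure_area(mask, 300), 0.71685, tolerance = 1e-4)
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_equal(measure_area(one, 254), 1e-4)
  expect_error(measure_area(matrix(FALSE, 5, 5), 300), class = "rld_zero_area")
})

test_that("perimeter matches closed forms for square and disk", {
  sq <- rect_mask(120, 120, 11:110, 11:110)
  expect_equal(measure_perimeter(sq, 300), 4 * 100 * 2.54 / 300,
               tolerance = 0.02)
  dk <- disk_mask(120, 50)
  # with dpi = 2.54 one pixel is 1 cm, so the result is in pixel units
  expect_equal(measure_perimeter(dk, 2.54), 2 * pi * 50, tolerance = 0.03)
  expect_error(measure_perimeter(matrix(FALSE, 3, 3), 300),
               class = "rld_zero_area")
})

test_that("shape measures are rotation invariant on re-rendered outlines", {
  m0 <- lance_mask(400, 400, angle = 0)
  m90 <- lance_mask(400, 400, angle = 90)
  m37 <- lance_mask(400, 400, angle = 37)
  p0 <- measure_perimeter(m0, 100)
  expect_equal(measure_perimeter(m90, 100), p0, tolerance = 0.01)
  expect_equal(measure_perimeter(m37, 100), p0, tolerance = 0.01)
  expect_equal(measure_area(m37, 100), measure_area(m0, 100), tolerance = 0.015)
})

test_that("etiolation segmentation finds the yellow tip fraction", {
  img <- uniform_image(100, 500, WHITE_BG, dpi = 300)
  leaf <- rect_mask(100, 500, 31:70, 51:450) # 400 px long blade
  distal <- rect_mask(100, 500, 31:70, 351:450) # distal 25%
  img <- paint(paint(img, leaf, GREEN_110), distal, YELLOW_50)
  stopifnot(hue_of(GREEN_110) > 100, hue_of(YELLOW_50) < 55)
  et <- segment_etiolation(img, leaf, hue_cut = 75)
  ea_la <- sum(et) / sum(leaf)
  expect_lt(abs(ea_la - 0.25), 0.03)

  green_only <- paint(uniform_image(100, 500, WHITE_BG), leaf, GREEN_110)
  expect_equal(sum(segment_etiolation(green_only, leaf)), 0)
  expect_equal(sum(segment_etiolation(img, leaf, hue_cut = 0)), 0)
})

test_that("etiolation degree is the etiolated area fraction", {
  expect_equal(etiolation_degree(25, 100), 0.25)
  expect_equal(etiolation_degree(0, 3), 0)
  expect_equal(etiolation_degree(7, 7), 1)
  expect_error(etiolation_degree(1, 0), class = "rld_zero_area")
  expect_error(etiolation_degree(2, 1), class = "rld_invariant_violation")
})

test_that("tip third selects the tapered end and is rotation equivariant", {
  m <- lance_mask(200, 400, len = 300, thick = 30, tip = 60, angle = 0)
  tt <- tip_third(m)
  # the tip is on the right: selected pixels sit in the right part of the axis
  cols_sel <- which(tt, arr.ind = TRUE)[, 2]
  cols_all <- which(m, arr.ind = TRUE)[, 2]
  expect_gt(min(cols_sel), stats::quantile(cols_all, 0.6))
  expect_gt(mean(cols_sel), mean(cols_all))

  # equivariance: tip third of the rotated mask ~ rotated tip third
  m37 <- lance_mask(200, 400, len = 300, thick = 30, tip = 60, angle = 37)
  tt37 <- tip_third(m37)
  # compare areas and axis-side placement rather than exact pixels
  expect_equal(sum(tt37) / sum(m37), sum(tt) / sum(m), tolerance = 0.05)
  idx <- which(m37, arr.ind = TRUE)
  sel <- which(tt37, arr.ind = TRUE)
  axis <- prcomp(idx)$rotation[, 1]
  if (axis[2] < 0) axis <- -axis # orient toward increasing column
  s_all <- as.matrix(idx) %*% axis
  s_sel <- as.matrix(sel) %*% axis
  # selected pixels occupy one extreme third of the axis extent
  third_cut <- min(s_all) + 2 / 3 * diff(range(s_all))
  frac_distal <- mean(s_sel >= third_cut)
  expect_gt(max(frac_distal, 1 - frac_distal), 0.98)

  expect_warning(tip_third(rect_mask(50, 50, 11:40, 11:40)),
                 class = "rld_tip_ambiguous")
})

test_that("region mean color is the arithmetic channel mean", {
  img <- uniform_image(10, 10, c(100, 150, 50))
  expect_equal(mean_rgb(img, matrix(TRUE, 10, 10)), c(100, 150, 50))
  img2 <- uniform_image(10, 10, c(0, 0, 0))
  img2 <- paint(img2, rect_mask(10, 10, 1:5, 1:10), c(200, 100, 50))
  expect_equal(mean_rgb(img2, matrix(TRUE, 10, 10)), c(100, 50, 25))
  expect_error(mean_rgb(img, matrix(FALSE, 10, 10)), class = "rld_zero_area")
})

test_that("color indices match their definitions", {
  ci <- color_indices(100, 150, 50)
  expect_equal(ci$NRI, 1 / 3)
  expect_equal(ci$NGI, 0.5)
  expect_equal(ci$NBI, 1 / 6)
  expect_equal(ci$ExG, 0.5)
  expect_equal(ci$ExR, 1.4 / 3 - 0.5)
  expect_equal(ci$G, 150)

  gray <- color_indices(80, 80, 80)
  expect_equal(gray$NRI, 1 / 3)
  expect_equal(gray$ExG, 0)
  expect_equal(gray$ExR, 1.4 / 3 - 1 / 3)

  expect_error(color_indices(0, 0, 0), class = "rld_division_by_zero")
})

test_that("chromatic coordinates are scale invariant and sum to one", {
  set.seed(7)
  for (i in 1:25) {
    rgb <- stats::runif(3, 5, 250)
    c1 <- color_indices(rgb[1], rgb[2], rgb[3])
    expect_equal(c1$NRI + c1$NGI + c1$NBI, 1, tolerance = 1e-12)
    expect_equal(c1$ExG, 3 * c1$NGI - 1, tolerance = 1e-12)
    s <- stats::runif(1, 0.05, 1)
    c2 <- color_indices(s * rgb[1], s * rgb[2], s * rgb[3])
    for (f in c("NRI", "NGI", "NBI", "ExR", "ExG")) {
      expect_equal(c1[[f]], c2[[f]], tolerance = 1e-12)
    }
  }
})

test_that("dark green color index follows the HSB formula", {
  expect_equal(dgci(0, 255, 0), 1 / 3)     # hue 120, S 1, B 1
  expect_equal(dgci(255, 255, 0), 0)       # hue 60, S 1, B 1
  # negative hue term allowed below 60 degrees
  expect_lt(dgci(255, 128, 0), 0.2)
  expect_error(dgci(128, 128, 128), class = "rld_achromatic")
})

test_that("full extraction matches generator ground truth on rendered leaves", {
  cfg <- experiment_config(dpi = 100, noise_sd = 2, master_seed = 5)
  profs <- default_treatment_profiles()

  p_fil <- sample_plant_parameters(profs$N3, seed = 41, plant_id = "fil")
  obs <- render_leaf_image(p_fil, 29, "FIL", cfg)
  f <- extract_features(obs$image)
  expect_equal(f$region_tag, "whole_leaf")
  expect_true(is.na(f$EA) && is.na(f$ED))
  expect_equal(f$LA, obs$truth$la, tolerance = 0.01)
  expect_equal(f$LP, obs$truth$lp, tolerance = 0.03)
  expect_equal(f$G, obs$truth$mean_rgb[2], tolerance = 2 / obs$truth$mean_rgb[2])

  errs <- replicate(12, NA_real_)
  ed_errs <- errs
  set.seed(99)
  seeds <- sample.int(10000, 12)
  for (i in seq_along(seeds)) {
    lev <- sample(names(profs), 1)
    p <- sample_plant_parameters(profs[[lev]], seed = seeds[i])
    dat <- sample(seq(26, min(38, p$senescence_dat), by = 3), 1)
    o <- render_leaf_image(p, dat, "3rd", cfg)
    ft <- extract_features(o$image)
    expect_equal(ft$region_tag, "tip_third")
    errs[i] <- abs(ft$LA - o$truth$la) / o$truth$la
    ed_errs[i] <- abs(ft$ED - o$truth$ed)
    expect_equal(ft$LP, o$truth$lp, tolerance = 0.03)
    rgb_hat <- c(ft$NRI, ft$NGI, ft$NBI) * (ft$G / ft$NGI)
    expect_equal(rgb_hat[2], o$truth$tip_rgb[2], tolerance = 3 / o$truth$tip_rgb[2])
  }
  expect_lt(stats::median(errs), 0.01)
  expect_lt(stats::median(ed_errs), 0.03)
})

test_that("batch extraction keeps one row per measurable scan", {
  cfg <- experiment_config(replicates = 1, years = 1, dpi = 60,
                           schedule = c(20, 23, 26), positions = c("FIL", "3rd"),
                           master_seed = 8)
  ex <- generate_experiment(cfg, render = TRUE)
  expect_equal(length(ex$images), sum(!ex$truth$missing))
  fb <- extract_features_batch(ex$images)
  expect_equal(nrow(fb$features), length(ex$images))
  expect_null(fb$skipped)

  # an all-background "scan" is skipped with a reason, not an error
  blank <- uniform_image(60, 60, WHITE_BG, dpi = 60)
  blank$meta <- list(plant_id = "none", dat = 20, leaf_position = "FIL")
  fb2 <- extract_features_batch(c(ex$images[1], list(blank)))
  expect_equal(nrow(fb2$features), 1)
  expect_equal(fb2$skipped$reason, "no_leaf_found")
})

test_that("round-tripping a scan through PNG preserves the measurements", {
  cfg <- experiment_config(dpi = 100, master_seed = 3)
  p <- sample_plant_parameters(default_treatment_profiles()$N2, seed = 6)
  obs <- render_leaf_image(p, 32, "3rd", cfg)
  tmp <- withr::local_tempfile(fileext = ".png")
  png::writePNG(obs$image$pixels / 255, tmp)
  back <- read_leaf_image(tmp, dpi = 100,
                          meta = list(leaf_position = "3rd", plant_id = "x",
                                      treatment = "N2", dat = 32))
  expect_equal(back$pixels, obs$image$pixels, tolerance = 1e-8)
  f1 <- extract_features(obs$image)
  f2 <- extract_features(back)
  expect_equal(f1$LA, f2$LA)
  expect_equal(f1$DGCI, f2$DGCI, tolerance = 1e-6)
})
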