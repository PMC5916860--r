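#' Treatment profiles for the four hydroponic nitrogen levels
#'
#' Returns the default generating parameters for the four ammonium-nitrate
#' treatments (N1 = 0, N2 = 57.20, N3 = 85.70, N4 = 114.30 mg/L): extreme
#' deficiency up to normal supply. Higher N gives a larger asymptotic blade
#' area, a faster expansion rate, a darker green base color, a slower
#' senescence color drift, later tip-yellowing onset and a slower etiolation
#' front on the oldest (3rd) leaf.
#'
#' The numeric defaults are generator choices calibrated to produce
#' rice-like blade sizes (asymptotic areas of roughly 12-30 cm^2) and the
#' qualitative treatment ordering observed in hydroponic N-stress trials;
#' they are not measurements.
#'
#' @param effect_scale multiplier on the between-treatment differences: every
#'   numeric parameter is pulled toward its across-treatment mean by
#'   `effect_scale` (1 = defaults, 0 = all treatments identical). Used to
#'   study how diagnosis accuracy responds to effect size.
#' @return a named list of four `treatment_profile` lists (N1..N4).
#' @export
default_treatment_profiles <- function(effect_scale = 1) {
  stopifnot(is.numeric(effect_scale), length(effect_scale) == 1, effect_scale >= 0)
  levels <- c("N1", "N2", "N3", "N4")
  prof <- list(
    n_conc = c(0, 57.20, 85.70, 114.30),
    area_A = c(12, 18, 24, 30),       # asymptotic blade area, cm^2
    area_k = c(0.25, 0.32, 0.38, 0.45), # logistic rate, 1/day
    area_t0 = c(29, 28, 27.5, 27),    # inflection DAT of the youngest leaf
    aspect = c(12, 12, 12, 12),       # blade length : max width
    base_r = c(95, 80, 70, 60),       # healthy green, darker with more N
    base_g = c(150, 138, 128, 118),
    base_b = c(65, 55, 48, 40),
    drift_r = c(1.8, 1.2, 0.8, 0.5),  # senescence color drift, units/day
    drift_g = c(1.2, 0.8, 0.55, 0.35),
    drift_b = c(0.20, 0.15, 0.10, 0.07),
    etiolation_onset = c(22, 26, 30, 34), # DAT tip yellowing starts, 3rd leaf
    front_speed = c(0.040, 0.028, 0.018, 0.010), # leaf-length fraction/day
    senescence_dat = c(38, 41, 44, 44)  # 3rd leaf missing after this DAT
  )
  if (effect_scale != 1) {
    keep <- c("n_conc", "senescence_dat") # labels and missingness design stay fixed
    for (nm in setdiff(names(prof), keep)) {
      m <- mean(prof[[nm]])
      prof[[nm]] <- pmax(m + effect_scale * (prof[[nm]] - m), 0)
    }
  }
  out <- lapply(seq_along(levels), function(i) {
    structure(list(
      n_level = levels[i],
      n_conc = prof$n_conc[i],
      area_A = prof$area_A[i],
      area_k = prof$area_k[i],
      area_t0 = prof$area_t0[i],
      aspect = prof$aspect[i],
      base_rgb = c(prof$base_r[i], prof$base_g[i], prof$base_b[i]),
      rgb_drift = c(prof$drift_r[i], prof$drift_g[i], prof$drift_b[i]),
      yellow_rgb = c(205, 180, 60),   # etiolated tissue, hue ~ 50 degrees
      etiolation_onset = prof$etiolation_onset[i],
      front_speed = prof$front_speed[i],
      senescence_dat = prof$senescence_dat[i]
    ), class = "treatment_profile")
  })
  names(out) <- levels
  out
}

#' Experiment configuration for the synthetic cohort
#'
#' Describes one simulated scanning campaign: which treatments, how many
#' replicate plants, the scan schedule in days after transplanting (DAT),
#' the leaf positions scanned, and the rendering settings.
#'
#' @param treatments named list of treatment profiles
#'   (default [default_treatment_profiles()]).
#' @param replicates replicate plants per treatment (default 5).
#' @param years number of experiment years pooled (default 2, the pooled
#'   two-season design).
#' @param schedule strictly increasing DAT vector (default every 3 days,
#'   DAT 20 to 44).
#' @param positions leaf positions scanned, newest first.
#' @param dpi scanner resolution (default 300).
#' @param noise_sd additive Gaussian pixel noise, 0-255 scale.
#' @param bg_rgb near-white scanner background color.
#' @param param_cv plant-to-plant lognormal coefficient of variation.
#' @param feature_noise_cv multiplicative measurement noise on shape
#'   features in analytic-truth mode.
#' @param rgb_noise_sd additive noise on region-mean RGB in analytic-truth
#'   mode, 0-255 scale.
#' @param master_seed integer master seed; every observation's randomness is
#'   derived from it.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(treatments = default_treatment_profiles(),
                              replicates = 5,
                              years = 2,
                              schedule = seq(20, 44, by = 3),
                              positions = c("FIL", "1st", "2nd", "3rd"),
                              dpi = 300,
                              noise_sd = 2,
                              bg_rgb = c(245, 245, 242),
                              param_cv = 0.10,
                              feature_noise_cv = 0.02,
                              rgb_noise_sd = 1,
                              master_seed = 1L) {
  if (any(diff(schedule) <= 0)) stop("schedule must be strictly increasing")
  if (replicates < 1) stop("replicates must be >= 1")
  if (dpi <= 0) stop("dpi must be positive")
  structure(list(
    treatments = treatments, replicates = as.integer(replicates),
    years = as.integer(years), schedule = schedule, positions = positions,
    dpi = dpi, noise_sd = noise_sd, bg_rgb = bg_rgb, param_cv = param_cv,
    feature_noise_cv = feature_noise_cv, rgb_noise_sd = rgb_noise_sd,
    master_seed = as.integer(master_seed)
  ), class = "experiment_config")
}

# Leaf positions and their fixed developmental offsets relative to the
# treatment profile: the first incomplete leaf (FIL) is the youngest and is
# still expanding over DAT 20-44; the 3rd fully expanded leaf is the oldest,
# essentially full-size, and the one that etiolates and senesces.
position_offsets <- function() {
  data.frame(
    position = c("FIL", "1st", "2nd", "3rd"),
    t0_shift = c(0, -6, -10, -14),
    A_mult = c(1.00, 1.00, 0.95, 0.90),
    stringsAsFactors = FALSE
  )
}

# Lognormal draw with exact mean `m` and coefficient of variation `cv`.
rlnorm_cv <- function(n, m, cv) {
  if (cv == 0 || m == 0) return(rep(m, n))
  s <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, log(m) - s^2 / 2, s))
}

#' Realize one plant's parameters from a treatment profile
#'
#' Plant-to-plant variability is lognormal around the profile values with a
#' common coefficient of variation (color parameters use half that CV), so
#' all realized parameters stay positive and have mean equal to the profile
#' value. Per-leaf logistic parameters are then derived with fixed
#' developmental offsets per position.
#'
#' @param profile a `treatment_profile`.
#' @param seed integer seed; identical seed and profile give identical output.
#' @param cv coefficient of variation (default 0.10; 0 reproduces the
#'   profile exactly).
#' @param plant_id identifier stored with the parameters.
#' @return a `plant_params` list with per-position logistic parameters and
#'   realized color/etiolation parameters.
#' @export
sample_plant_parameters <- function(profile, seed, cv = 0.10, plant_id = "plant") {
  if (!is.numeric(cv) || cv < 0) stop("cv must be >= 0")
  with_seed(seed, {
    A <- rlnorm_cv(1, profile$area_A, cv)
    k <- rlnorm_cv(1, profile$area_k, cv)
    t0 <- rlnorm_cv(1, profile$area_t0, cv / 3)
    aspect <- rlnorm_cv(1, profile$aspect, cv / 2)
    base_rgb <- vapply(profile$base_rgb, function(v) rlnorm_cv(1, v, cv / 2), 0)
    drift <- vapply(profile$rgb_drift, function(v) rlnorm_cv(1, v, cv), 0)
    yellow <- vapply(profile$yellow_rgb, function(v) rlnorm_cv(1, v, cv / 4), 0)
    onset <- rlnorm_cv(1, profile$etiolation_onset, cv / 3)
    fspeed <- min(rlnorm_cv(1, profile$front_speed, cv), 1)
    off <- position_offsets()
    leaves <- lapply(seq_len(nrow(off)), function(i) {
      list(A = A * off$A_mult[i], k = k, t0 = t0 + off$t0_shift[i])
    })
    names(leaves) <- off$position
    structure(list(
      plant_id = plant_id,
      treatment = profile$n_level,
      leaves = leaves,
      aspect = aspect,
      base_rgb = base_rgb,
      rgb_drift = drift,
      yellow_rgb = yellow,
      etiolation_onset = onset,
      front_speed = fspeed,
      senescence_dat = profile$senescence_dat,
      rng_seed = as.integer(seed)
    ), class = "plant_params")
  })
}

## ---- blade geometry -------------------------------------------------------
## The blade is a symmetric lanceolate outline: half-width
## h(u) = (W/2) * g(u), u in [0,1] along the axis, with a beta-shaped profile
## g(u) = u^a (1-u)^b / max. With b > a the u = 1 end tapers harder and is
## the tip. Length L and max width W are solved so the enclosed area matches
## the logistic law exactly, with a fixed length:width ratio.

.blade_a <- 0.4
.blade_b <- 1.2

blade_profile <- function(u) {
  gmax <- (.blade_a / (.blade_a + .blade_b))^.blade_a *
    (.blade_b / (.blade_a + .blade_b))^.blade_b
  ifelse(u <= 0 | u >= 1, 0, u^.blade_a * (1 - u)^.blade_b / gmax)
}

# integral of blade_profile over [0,1]: area = L * W * blade_area_factor()
blade_area_factor <- function() {
  gmax <- (.blade_a / (.blade_a + .blade_b))^.blade_a *
    (.blade_b / (.blade_a + .blade_b))^.blade_b
  beta(.blade_a + 1, .blade_b + 1) / gmax
}

# fraction of blade area distal to axis fraction u0 (toward the tip, u = 1)
blade_distal_area_frac <- function(u0) {
  u0 <- pmin(pmax(u0, 0), 1)
  1 - stats::pbeta(u0, .blade_a + 1, .blade_b + 1)
}

# blade length and max width (cm) for a target area (cm^2) and aspect ratio
blade_dims <- function(area, aspect) {
  L <- sqrt(area * aspect / blade_area_factor())
  list(L = L, W = L / aspect)
}

# analytic outline perimeter (cm) by dense arc-length quadrature
blade_perimeter_analytic <- function(area, aspect) {
  d <- blade_dims(area, aspect)
  u <- seq(0, 1, length.out = 4001)
  x <- u * d$L
  y <- 0.5 * d$W * blade_profile(u)
  2 * sum(sqrt(diff(x)^2 + diff(y)^2))
}

logistic_area <- function(A, k, t0, dat) A / (1 + exp(-k * (dat - t0)))

# etiolation front position as a fraction of leaf length from the tip
etiolation_fraction <- function(params, dat, position) {
  if (position != "3rd" || dat < params$etiolation_onset) return(0)
  min(max(params$front_speed * (dat - params$etiolation_onset), 0), 1)
}

healthy_rgb_at <- function(params, dat) {
  pmin(pmax(params$base_rgb + params$rgb_drift * (dat - 20), 0), 255)
}

#' Render one synthetic leaf scan with ground truth
#'
#' Draws a lanceolate blade on a near-white scanner background. Blade area
#' follows the logistic law `A / (1 + exp(-k (dat - t0)))` for the leaf's
#' position; on the 3rd leaf past the etiolation onset, tissue distal to the
#' advancing front is rendered yellow (hue around 50 degrees) with a 2-pixel
#' linear color transition. Ground truth (areas, perimeter, region-mean
#' colors) is measured from the rendered masks with the same conventions the
#' extractor uses, so extraction tests isolate extraction error; the
#' analytic polygon area and perimeter are reported alongside.
#'
#' @param params a `plant_params` object.
#' @param dat day after transplanting; must not precede the schedule start
#'   used for color drift (DAT 20).
#' @param position one of `"FIL"`, `"1st"`, `"2nd"`, `"3rd"`.
#' @param cfg an `experiment_config` (rendering settings are read from it).
#' @param angle optional blade rotation in degrees (counter-clockwise).
#' @return a list with `image` (a `leaf_image`) and `truth` (ground-truth
#'   list), or a [missing_observation()] when the leaf has senesced.
#' @export
render_leaf_image <- function(params, dat, position, cfg, angle = 0) {
  stopifnot(position %in% names(params$leaves))
  if (position == "3rd" && dat > params$senescence_dat) {
    return(missing_observation("senesced",
      plant_id = params$plant_id, dat = dat, leaf_position = position))
  }
  lp <- params$leaves[[position]]
  area <- logistic_area(lp$A, lp$k, lp$t0, dat)
  dims <- blade_dims(area, params$aspect)
  px <- 2.54 / cfg$dpi # cm per pixel
  Lpx <- dims$L / px
  Wpx <- dims$W / px
  margin <- 6
  th <- angle * pi / 180
  # bounding box of the rotated axis-aligned blade box
  corners_x <- c(0, Lpx, Lpx, 0)
  corners_y <- c(-Wpx / 2, -Wpx / 2, Wpx / 2, Wpx / 2)
  rx <- corners_x * cos(th) - corners_y * sin(th)
  ry <- corners_x * sin(th) + corners_y * cos(th)
  w_img <- ceiling(diff(range(rx))) + 2 * margin
  h_img <- ceiling(diff(range(ry))) + 2 * margin
  x0 <- margin - min(rx)
  y0 <- margin - min(ry)

  xs <- matrix(rep(seq_len(w_img) - 0.5, each = h_img), h_img, w_img) - x0
  ys <- matrix(rep(seq_len(h_img) - 0.5, times = w_img), h_img, w_img) - y0
  s <- xs * cos(th) + ys * sin(th)   # axis coordinate, base 0 -> tip Lpx
  v <- -xs * sin(th) + ys * cos(th)  # transverse coordinate
  u <- s / Lpx
  inside <- u > 0 & u < 1 & abs(v) <= 0.5 * Wpx * blade_profile(pmin(pmax(u, 0), 1))

  f <- etiolation_fraction(params, dat, position)
  front_u <- 1 - f
  healthy <- healthy_rgb_at(params, dat)
  yellow <- params$yellow_rgb

  color <- array(0, dim = c(h_img, w_img, 3))
  for (ch in 1:3) color[, , ch] <- cfg$bg_rgb[ch]
  if (any(inside)) {
    if (f <= 0) {
      wgt <- rep(0, sum(inside))
    } else if (f >= 1) {
      wgt <- rep(1, sum(inside))
    } else {
      d_px <- (s[inside] - front_u * Lpx) # distance past the front, px
      wgt <- pmin(pmax(d_px / 2 + 0.5, 0), 1) # 2-px linear transition
    }
    for (ch in 1:3) {
      plane <- color[, , ch]
      plane[inside] <- healthy[ch] * (1 - wgt) + yellow[ch] * wgt
      color[, , ch] <- plane
    }
  }

  etio <- inside & (u >= front_u) & f > 0
  tip_third <- inside & (u >= 2 / 3)

  mask_num <- matrix(as.numeric(inside), h_img, w_img)
  la_px <- sum(inside)
  truth <- list(
    la = la_px * px^2,
    la_analytic = area,
    lp = marching_squares_length(box_smooth3(mask_num)) * px,
    lp_analytic = blade_perimeter_analytic(area, params$aspect),
    ea = sum(etio) * px^2,
    ed = if (la_px > 0) sum(etio) / la_px else 0,
    mean_rgb = vapply(1:3, function(ch) mean(color[, , ch][inside]), 0),
    tip_rgb = vapply(1:3, function(ch) mean(color[, , ch][tip_third]), 0),
    leaf_mask = inside,
    etiolated_mask = etio,
    tip_third_mask = tip_third
  )

  if (cfg$noise_sd > 0) {
    noise_seed <- derive_seed(params$rng_seed, paste("noise", dat, position))
    color <- with_seed(noise_seed,
      color + array(stats::rnorm(length(color), 0, cfg$noise_sd), dim = dim(color)))
  }
  pixels <- round(pmin(pmax(color, 0), 255))

  img <- structure(list(
    pixels = pixels,
    dpi = cfg$dpi,
    meta = list(plant_id = params$plant_id, treatment = params$treatment,
                dat = dat, leaf_position = position)
  ), class = "leaf_image")
  list(image = img, truth = truth)
}

#' @export
print.leaf_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<leaf_image %dx%d px, %g dpi, %s %s DAT %s>\n",
              d[1], d[2], x$dpi, x$meta$plant_id %||% "?",
              x$meta$leaf_position %||% "?", x$meta$dat %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Analytic (formula-based) ground truth for one observation; used by the
# fast truth-only cohort mode where no raster is produced.
analytic_truth <- function(params, dat, position) {
  lp <- params$leaves[[position]]
  area <- logistic_area(lp$A, lp$k, lp$t0, dat)
  f <- etiolation_fraction(params, dat, position)
  ed <- blade_distal_area_frac(1 - f)
  if (f <= 0) ed <- 0
  a3 <- blade_distal_area_frac(2 / 3)           # tip-third area fraction
  e3 <- if (f <= 0) 0 else blade_distal_area_frac(max(2 / 3, 1 - f))
  healthy <- healthy_rgb_at(params, dat)
  yellow <- params$yellow_rgb
  list(
    la = area,
    lp = blade_perimeter_analytic(area, params$aspect),
    ea = area * ed,
    ed = ed,
    mean_rgb = healthy * (1 - ed) + yellow * ed,
    tip_rgb = (healthy * (a3 - e3) + yellow * e3) / a3
  )
}

# One feature row (same schema as the extractor's output) from analytic
# truth plus measurement noise.
truth_feature_row <- function(params, dat, position, cfg) {
  tr <- analytic_truth(params, dat, position)
  seed <- derive_seed(params$rng_seed, paste("meas", dat, position))
  with_seed(seed, {
    la <- tr$la * rlnorm_cv(1, 1, cfg$feature_noise_cv)
    lpv <- tr$lp * rlnorm_cv(1, 1, cfg$feature_noise_cv)
    ea <- if (tr$ea > 0) tr$ea * rlnorm_cv(1, 1, cfg$feature_noise_cv) else 0
    region_rgb <- if (position == "FIL") tr$mean_rgb else tr$tip_rgb
    region_rgb <- pmin(pmax(region_rgb + stats::rnorm(3, 0, cfg$rgb_noise_sd), 0), 255)
  })
  ed <- min(ea / la, 1)
  idx <- color_indices(region_rgb[1], region_rgb[2], region_rgb[3])
  dg <- tryCatch(dgci(region_rgb[1], region_rgb[2], region_rgb[3]),
                 rld_achromatic = function(e) NA_real_)
  hsb <- rgb_to_hsb(region_rgb[1], region_rgb[2], region_rgb[3])
  data.frame(
    plant_id = params$plant_id, treatment = params$treatment,
    dat = dat, leaf_position = position,
    LA = la, LP = lpv,
    EA = if (position == "3rd") ea else NA_real_,
    ED = if (position == "3rd") ed else NA_real_,
    G = idx$G, NRI = idx$NRI, NGI = idx$NGI, NBI = idx$NBI,
    ExR = idx$ExR, ExG = idx$ExG, DGCI = dg,
    Hue = hsb$h, Saturation = hsb$s, Brightness = hsb$v,
    region_tag = if (position == "FIL") "whole_leaf" else "tip_third",
    qc_flags = "", stringsAsFactors = FALSE
  )
}

#' Generate a synthetic scanning campaign
#'
#' Simulates every plant x DAT x leaf-position observation of the configured
#' cohort. In rendered mode each observation is a PNG-writable leaf scan plus
#' mask-measured ground truth; in analytic-truth mode (`render = FALSE`) the
#' ground truth is computed from the generating formulas and returned
#' directly as a feature table with light measurement noise, which is fast
#' enough for large simulation studies of the downstream statistics.
#' Observations of the 3rd leaf past its senescence DAT are recorded as
#' missing, mirroring the loss of old leaves late in the campaign.
#'
#' @param cfg an [experiment_config()].
#' @param out_dir optional directory; when given, images are written as PNG
#'   under `out_dir/images/` with `meta.csv` and `truth.csv` alongside.
#' @param render if `TRUE` (default) rasterize every leaf; if `FALSE` use
#'   analytic ground truth only.
#' @param keep_images in rendered mode without `out_dir`, keep the
#'   `leaf_image` objects in memory (default `TRUE` when `out_dir` is NULL).
#' @return a `leaf_experiment` list: `truth` (one row per observation,
#'   missing ones flagged), `features` (analytic mode only), `images`
#'   (rendered in-memory mode only), `meta`, and `cfg`.
#' @export
generate_experiment <- function(cfg, out_dir = NULL, render = TRUE,
                                keep_images = is.null(out_dir)) {
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  }
  truth_rows <- list()
  feat_rows <- list()
  meta_rows <- list()
  images <- list()
  for (year in seq_len(cfg$years)) {
    for (lev in names(cfg$treatments)) {
      profile <- cfg$treatments[[lev]]
      for (rep_i in seq_len(cfg$replicates)) {
        plant_id <- sprintf("Y%d_%s_P%02d", year, lev, rep_i)
        pseed <- derive_seed(cfg$master_seed, plant_id)
        params <- sample_plant_parameters(profile, pseed, cv = cfg$param_cv,
                                          plant_id = plant_id)
        for (dat in cfg$schedule) {
          for (pos in cfg$positions) {
            key <- paste(plant_id, dat, pos, sep = "_")
            senesced <- pos == "3rd" && dat > params$senescence_dat
            if (senesced) {
              truth_rows[[key]] <- data.frame(
                plant_id = plant_id, treatment = lev, year = year, dat = dat,
                leaf_position = pos, missing = TRUE, reason = "senesced",
                la = NA_real_, la_analytic = NA_real_, lp = NA_real_,
                lp_analytic = NA_real_, ea = NA_real_, ed = NA_real_,
                r_mean = NA_real_, g_mean = NA_real_, b_mean = NA_real_,
                tip_r = NA_real_, tip_g = NA_real_, tip_b = NA_real_,
                stringsAsFactors = FALSE)
              next
            }
            if (render) {
              obs <- render_leaf_image(params, dat, pos, cfg)
              tr <- obs$truth
              truth_rows[[key]] <- data.frame(
                plant_id = plant_id, treatment = lev, year = year, dat = dat,
                leaf_position = pos, missing = FALSE, reason = "",
                la = tr$la, la_analytic = tr$la_analytic, lp = tr$lp,
                lp_analytic = tr$lp_analytic, ea = tr$ea, ed = tr$ed,
                r_mean = tr$mean_rgb[1], g_mean = tr$mean_rgb[2],
                b_mean = tr$mean_rgb[3], tip_r = tr$tip_rgb[1],
                tip_g = tr$tip_rgb[2], tip_b = tr$tip_rgb[3],
                stringsAsFactors = FALSE)
              if (!is.null(out_dir)) {
                fn <- file.path("images", paste0(key, ".png"))
                png::writePNG(obs$image$pixels / 255, file.path(out_dir, fn))
                meta_rows[[key]] <- data.frame(
                  image_path = fn, plant_id = plant_id, treatment = lev,
                  year = year, dat = dat, leaf_position = pos, dpi = cfg$dpi,
                  stringsAsFactors = FALSE)
              } else if (keep_images) {
                obs$image$meta$year <- year
                images[[key]] <- obs$image
              }
            } else {
              tr <- analytic_truth(params, dat, pos)
              truth_rows[[key]] <- data.frame(
                plant_id = plant_id, treatment = lev, year = year, dat = dat,
                leaf_position = pos, missing = FALSE, reason = "",
                la = tr$la, la_analytic = tr$la, lp = tr$lp,
                lp_analytic = tr$lp, ea = tr$ea, ed = tr$ed,
                r_mean = tr$mean_rgb[1], g_mean = tr$mean_rgb[2],
                b_mean = tr$mean_rgb[3], tip_r = tr$tip_rgb[1],
                tip_g = tr$tip_rgb[2], tip_b = tr$tip_rgb[3],
                stringsAsFactors = FALSE)
              fr <- truth_feature_row(params, dat, pos, cfg)
              fr$year <- year
              feat_rows[[key]] <- fr
            }
          }
        }
      }
    }
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  features <- if (length(feat_rows)) {
    f <- do.call(rbind, feat_rows)
    rownames(f) <- NULL
    f
  } else NULL
  meta <- if (length(meta_rows)) {
    m <- do.call(rbind, meta_rows)
    rownames(m) <- NULL
    m
  } else NULL
  if (!is.null(out_dir)) {
    csv_write(truth, file.path(out_dir, "truth.csv"))
    if (!is.null(meta)) csv_write(meta, file.path(out_dir, "meta.csv"))
  }
  structure(list(truth = truth, features = features, images = images,
                 meta = meta, cfg = cfg),
            class = "leaf_experiment")
}
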