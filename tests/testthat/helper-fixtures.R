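# Fixtures are built in code: uniform/blob images, tiny cohorts, and
# independent brute-force oracles for the statistics under test.

# a leaf_image filled with one color
uniform_image <- function(h, w, rgb, dpi = 300) {
  px <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) px[, , ch] <- rgb[ch]
  leaf_image(px, dpi = dpi)
}

# paint a mask region of an image with a color
paint <- function(img, mask, rgb) {
  for (ch in 1:3) {
    plane <- img$pixels[, , ch]
    plane[mask] <- rgb[ch]
    img$pixels[, , ch] <- plane
  }
  img
}

ellipse_mask <- function(h, w, cx, cy, rx, ry) {
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), times = w), h, w)
  ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1
}

disk_mask <- function(n, r) {
  ellipse_mask(n, n, (n + 1) / 2, (n + 1) / 2, r, r)
}

rect_mask <- function(h, w, rows, cols) {
  m <- matrix(FALSE, h, w)
  m[rows, cols] <- TRUE
  m
}

# rectangle with a triangular tip on the right, optionally rotated; returns
# the mask rendered on an (h x w) grid around its center
lance_mask <- function(h, w, len = 300, thick = 30, tip = 60, angle = 0) {
  th <- angle * pi / 180
  # half-integer centers so shape edges never coincide with pixel centers
  xs <- matrix(rep(seq_len(w), each = h), h, w) - (w / 2 + 0.25)
  ys <- matrix(rep(seq_len(h), times = w), h, w) - (h / 2 + 0.25)
  x <- xs * cos(th) + ys * sin(th)
  y <- -xs * sin(th) + ys * cos(th)
  body <- x >= -len / 2 & x <= len / 2 - tip & abs(y) <= thick / 2
  tri <- x > len / 2 - tip & x <= len / 2 &
    abs(y) <= thick / 2 * (len / 2 - x) / tip
  body | tri
}

# colors used in imaging fixtures: green hue ~110 deg, yellow hue ~50 deg
GREEN_110 <- c(60, 140, 40)
YELLOW_50 <- c(205, 180, 60)
WHITE_BG <- c(245, 245, 242)

# hue of an rgb triple, degrees
hue_of <- function(rgb) rgb_to_hsb(rgb[1], rgb[2], rgb[3])$h

# independent one-way ANOVA oracle: explicit sums of squares
bf_anova_f <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  all_v <- unlist(groups)
  gm <- mean(all_v)
  k <- length(groups)
  n <- length(all_v)
  ssb <- sum(sapply(groups, function(g) length(g) * (mean(g) - gm)^2))
  ssw <- sum(sapply(groups, function(g) sum((g - mean(g))^2)))
  (ssb / (k - 1)) / (ssw / (n - k))
}

# four gaussian clusters in p dimensions, separation in sd units
cluster_dataset <- function(n_per = 10, sep = 6, p = 4, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(0:3, function(k)
    matrix(stats::rnorm(n_per * p, mean = sep * k), n_per, p)))
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = factor(rep(paste0("N", 1:4), each = n_per)),
       dropped_rows = character())
}

# small truth-only cohort for downstream statistics tests
small_cohort <- function(seed = 1, replicates = 4, years = 1,
                         positions = c("FIL", "3rd"), effect_scale = 1, ...) {
  cfg <- experiment_config(
    treatments = default_treatment_profiles(effect_scale),
    replicates = replicates, years = years, positions = positions,
    master_seed = seed, ...)
  generate_experiment(cfg, render = FALSE)
}

# profiles with senescence disabled
no_senescence_profiles <- function(...) {
  profs <- default_treatment_profiles(...)
  for (nm in names(profs)) profs[[nm]]$senescence_dat <- Inf
  profs
}
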