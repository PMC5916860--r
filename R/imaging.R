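#' Construct a leaf image object
#'
#' @param pixels numeric array `height x width x 3`, channel values 0-255.
#' @param dpi scanner resolution in dots per inch.
#' @param meta named list of acquisition metadata (plant_id, treatment, dat,
#'   leaf_position, ...).
#' @return a `leaf_image`.
#' @export
leaf_image <- function(pixels, dpi, meta = list()) {
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 3, dpi > 0,
            dim(pixels)[1] >= 3, dim(pixels)[2] >= 3)
  structure(list(pixels = pixels, dpi = dpi, meta = meta), class = "leaf_image")
}

#' Read a leaf scan from a PNG or TIFF file
#'
#' @param path image file path (`.png`, `.tif`/`.tiff`).
#' @param dpi resolution the scan was acquired at.
#' @param meta named metadata list.
#' @return a `leaf_image` with 0-255 channel values.
#' @export
read_leaf_image <- function(path, dpi, meta = list()) {
  img <- EBImage::readImage(path)
  px <- EBImage::imageData(img)
  if (length(dim(px)) == 2) px <- array(rep(px, 3), dim = c(dim(px), 3))
  if (dim(px)[3] > 3) px <- px[, , 1:3] # drop alpha
  # EBImage stores x (width) as the first dimension; transpose to rows = y
  px <- aperm(px, c(2, 1, 3)) * 255
  leaf_image(px, dpi = dpi, meta = meta)
}

# EBImage works on width-major matrices; these helpers hop between the
# package's row-major masks and EBImage objects.
as_ebi <- function(m) EBImage::Image(t(m))
from_ebi <- function(img) t(EBImage::imageData(img))

#' Segment the leaf from its scanner background
#'
#' Pixels are scored by their RGB distance from the modal background color
#' (estimated from the image border), thresholded (Otsu by default), and the
#' largest connected component is kept with its holes filled.
#'
#' @param img a `leaf_image` with a near-uniform bright background.
#' @param threshold `"otsu"` or a fixed numeric cut on the normalized
#'   color distance in \[0, 1\].
#' @param min_area minimum component size in pixels below which
#'   no leaf is deemed present.
#' @return logical matrix (the leaf mask).
#' @export
segment_leaf <- function(img, threshold = "otsu", min_area = 100) {
  px <- img$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  border <- rbind(
    cbind(1, seq_len(w)), cbind(h, seq_len(w)),
    cbind(seq_len(h), 1), cbind(seq_len(h), w))
  bg <- vapply(1:3, function(ch) stats::median(px[, , ch][border]), 0)
  dist <- sqrt((px[, , 1] - bg[1])^2 + (px[, , 2] - bg[2])^2 +
                 (px[, , 3] - bg[3])^2) / (255 * sqrt(3))
  thr <- if (identical(threshold, "otsu")) {
    EBImage::otsu(as_ebi(dist), range = c(0, 1))
  } else {
    as.numeric(threshold)
  }
  fg <- dist > thr
  if (!any(fg)) stop_no_leaf()
  lab <- EBImage::bwlabel(as_ebi(matrix(as.numeric(fg), h, w)))
  counts <- table(EBImage::imageData(lab)[EBImage::imageData(lab) > 0])
  if (!length(counts) || max(counts) < min_area) stop_no_leaf()
  biggest <- as.integer(names(counts)[which.max(counts)])
  comp <- EBImage::imageData(lab) == biggest
  comp <- EBImage::fillHull(EBImage::Image(comp * 1))
  from_ebi(comp) > 0.5
}

#' Leaf area from a mask
#'
#' Pixel count calibrated to cm^2 via the scan resolution:
#' `LA = n_pixels * (2.54 / dpi)^2`.
#'
#' @param mask logical pixel mask.
#' @param dpi resolution in dots per inch.
#' @return area in cm^2.
#' @export
measure_area <- function(mask, dpi) {
  n <- sum(mask)
  if (n == 0) stop_zero_area()
  n * (2.54 / dpi)^2
}

#' Leaf perimeter from a mask
#'
#' Length of the sub-pixel 0.5 iso-contour (marching squares with linear
#' interpolation) of the lightly smoothed mask, calibrated to cm. Smoothing
#' with a 3x3 box filter before contouring removes the staircase bias that
#' makes boundary-pixel counting overestimate oblique edges.
#'
#' @param mask logical pixel mask (one connected component expected).
#' @param dpi resolution in dots per inch.
#' @param smooth smooth the mask before contouring (default `TRUE`).
#' @return perimeter in cm.
#' @export
measure_perimeter <- function(mask, dpi, smooth = TRUE) {
  if (!any(mask)) stop_zero_area()
  field <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (smooth) field <- box_smooth3(field)
  marching_squares_length(field) * 2.54 / dpi
}

#' Segment etiolated (yellowed) tissue within the leaf
#'
#' Etiolated pixels are leaf pixels whose HSV hue lies in `[0, hue_cut)`
#' degrees — the red-through-yellow side of green. Achromatic pixels
#' (saturation below 0.05) are non-etiolated by convention.
#'
#' @param img a `leaf_image`.
#' @param leaf logical leaf mask from [segment_leaf()].
#' @param hue_cut hue threshold in degrees (default 75, the yellow side of
#'   green).
#' @return logical mask of etiolated pixels (subset of `leaf`).
#' @export
segment_etiolation <- function(img, leaf, hue_cut = 75) {
  out <- matrix(FALSE, nrow(leaf), ncol(leaf))
  if (!any(leaf) || hue_cut <= 0) return(out)
  idx <- which(leaf)
  hsb <- rgb_to_hsb(img$pixels[, , 1][idx], img$pixels[, , 2][idx],
                    img$pixels[, , 3][idx])
  et <- !is.na(hsb$h) & hsb$s >= 0.05 & hsb$h < hue_cut
  out[idx[et]] <- TRUE
  out
}

#' Degree of leaf etiolation
#'
#' The etiolated fraction of the blade, `ED = EA / LA`.
#'
#' @param EA etiolated area.
#' @param LA total leaf area (same units as `EA`).
#' @return ED, dimensionless in \[0, 1\].
#' @export
etiolation_degree <- function(EA, LA) {
  if (LA <= 0) stop_zero_area("LA must be positive")
  if (EA < 0 || EA > LA) stop_invariant("EA must lie in [0, LA]")
  EA / LA
}

#' Distal (tip) third of a leaf mask
#'
#' The mask is trisected along its principal axis; pixels projecting onto
#' the distal third of the axis extent are returned. The tip end is the end
#' with the smaller mean transverse width over the outer 10% of the axis
#' length. For nearly isotropic masks (axis aspect ratio below 1.2) the tip
#' is ambiguous: a `rld_tip_ambiguous` warning is raised and the end with
#' the greater axis coordinate is used.
#'
#' @param mask logical single-component mask.
#' @return logical mask of the tip third.
#' @export
tip_third <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop_zero_area()
  xy <- cbind(idx[, 2], idx[, 1]) # x = column, y = row
  ctr <- colMeans(xy)
  cxy <- sweep(xy, 2, ctr)
  ev <- eigen(stats::cov(cxy), symmetric = TRUE)
  axis <- ev$vectors[, 1]
  # fix the sign convention: axis points toward +x (ties: +y)
  if (axis[1] < 0 || (axis[1] == 0 && axis[2] < 0)) axis <- -axis
  aspect <- sqrt(ev$values[1] / max(ev$values[2], .Machine$double.eps))
  s <- cxy %*% axis
  v <- cxy %*% c(-axis[2], axis[1])
  rng <- range(s)
  extent <- diff(rng)
  if (aspect < 1.2) {
    warn_tip_ambiguous()
    tip_high <- TRUE
  } else {
    band <- 0.10 * extent
    lo <- s <= rng[1] + band
    hi <- s >= rng[2] - band
    width_lo <- mean(abs(v[lo]))
    width_hi <- mean(abs(v[hi]))
    tip_high <- width_hi <= width_lo
  }
  sel <- if (tip_high) s >= rng[2] - extent / 3 else s <= rng[1] + extent / 3
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  out[idx[sel, , drop = FALSE]] <- TRUE
  out
}

#' Mean RGB over a region
#'
#' @param img a `leaf_image`.
#' @param region logical mask of the region.
#' @return numeric length-3 vector of channel means (0-255 scale).
#' @export
mean_rgb <- function(img, region) {
  if (!any(region)) stop_zero_area()
  vapply(1:3, function(ch) mean(img$pixels[, , ch][region]), 0)
}

#' RGB color indices
#'
#' The chromatic coordinates and excess indices commonly used for
#' vegetation color: `NRI = R/(R+G+B)` (NGI and NBI analogous),
#' `ExR = 1.4 NRI - NGI`, `ExG = 2 NGI - NRI - NBI`, plus the raw green
#' channel mean `G`.
#'
#' @param r,g,b channel values (any common positive scale).
#' @return list with `G`, `NRI`, `NGI`, `NBI`, `ExR`, `ExG`.
#' @export
color_indices <- function(r, g, b) {
  tot <- r + g + b
  if (tot <= 0) stop_division_by_zero()
  nri <- r / tot
  ngi <- g / tot
  nbi <- b / tot
  list(G = g, NRI = nri, NGI = ngi, NBI = nbi,
       ExR = 1.4 * nri - ngi, ExG = 2 * ngi - nri - nbi)
}

#' Dark green color index
#'
#' `DGCI = ((Hue - 60)/60 + (1 - Saturation) + (1 - Brightness)) / 3` with
#' hue in degrees (red = 0) and saturation/brightness in \[0, 1\]. Higher
#' values indicate darker green; hues below 60 degrees give negative hue
#' terms, which are not clamped.
#'
#' @param r,g,b channel values on the 0-255 scale.
#' @return DGCI (scalar).
#' @export
dgci <- function(r, g, b) {
  hsb <- rgb_to_hsb(r, g, b)
  if (is.na(hsb$h) || hsb$s < 0.05) stop_achromatic()
  ((hsb$h - 60) / 60 + (1 - hsb$s) + (1 - hsb$v)) / 3
}

#' Extract all leaf characteristics from one scan
#'
#' Runs segmentation and computes the full characteristic set: shape (LA,
#' LP, and for the 3rd leaf EA and ED) and color (G, NRI, NGI, NBI, ExR,
#' ExG, DGCI). Color indices are computed from the region-mean RGB
#' (mean-then-index); the region is the whole leaf for the still-uniform
#' first incomplete leaf (FIL) and the distal third for fully expanded
#' leaves, whose tip responds to nitrogen stress first.
#'
#' @param img a `leaf_image` whose `meta$leaf_position` is one of `"FIL"`,
#'   `"1st"`, `"2nd"`, `"3rd"`.
#' @param hue_cut etiolation hue threshold in degrees.
#' @param threshold background threshold passed to [segment_leaf()].
#' @param per_pixel if `TRUE`, average per-pixel indices over the region
#'   instead of computing indices from the mean RGB.
#' @return one-row `data.frame` of features (schema shared with the
#'   analytic-truth generator), or a [missing_observation()] when no leaf is
#'   found.
#' @export
extract_features <- function(img, hue_cut = 75, threshold = "otsu",
                             per_pixel = FALSE) {
  meta <- img$meta
  pos <- meta$leaf_position %||% "FIL"
  qc <- character()
  leaf <- tryCatch(segment_leaf(img, threshold = threshold),
                   rld_no_leaf = function(e) NULL)
  if (is.null(leaf)) {
    return(missing_observation("no_leaf_found",
      plant_id = meta$plant_id, dat = meta$dat, leaf_position = pos))
  }
  la <- measure_area(leaf, img$dpi)
  lp <- measure_perimeter(leaf, img$dpi)
  if (pos == "3rd") {
    etio <- segment_etiolation(img, leaf, hue_cut = hue_cut)
    ea <- if (any(etio)) measure_area(etio, img$dpi) else 0
    ed <- etiolation_degree(min(ea, la), la)
  } else {
    ea <- NA_real_
    ed <- NA_real_
  }
  region <- if (pos == "FIL") {
    leaf
  } else {
    withCallingHandlers(tip_third(leaf), rld_tip_ambiguous = function(w) {
      qc <<- c(qc, "tip_ambiguous")
      invokeRestart("muffleWarning")
    })
  }
  m <- mean_rgb(img, region)
  if (per_pixel) {
    ridx <- which(region)
    rr <- img$pixels[, , 1][ridx]; gg <- img$pixels[, , 2][ridx]; bb <- img$pixels[, , 3][ridx]
    tot <- rr + gg + bb
    ok <- tot > 0
    idx <- list(G = mean(gg), NRI = mean(rr[ok] / tot[ok]), NGI = mean(gg[ok] / tot[ok]),
                NBI = mean(bb[ok] / tot[ok]))
    idx$ExR <- 1.4 * idx$NRI - idx$NGI
    idx$ExG <- 2 * idx$NGI - idx$NRI - idx$NBI
  } else {
    idx <- color_indices(m[1], m[2], m[3])
  }
  dg <- tryCatch(dgci(m[1], m[2], m[3]), rld_achromatic = function(e) {
    qc <<- c(qc, "achromatic_region")
    NA_real_
  })
  hsb <- rgb_to_hsb(m[1], m[2], m[3])
  data.frame(
    plant_id = meta$plant_id %||% NA_character_,
    treatment = meta$treatment %||% NA_character_,
    dat = meta$dat %||% NA_real_,
    leaf_position = pos,
    LA = la, LP = lp, EA = ea, ED = ed,
    G = idx$G, NRI = idx$NRI, NGI = idx$NGI, NBI = idx$NBI,
    ExR = idx$ExR, ExG = idx$ExG, DGCI = dg,
    Hue = hsb$h, Saturation = hsb$s, Brightness = hsb$v,
    region_tag = if (pos == "FIL") "whole_leaf" else "tip_third",
    qc_flags = paste(qc, collapse = ";"),
    stringsAsFactors = FALSE
  )
}

#' Extract features for a batch of scans
#'
#' Applies [extract_features()] to a list of `leaf_image` objects or to an
#' image directory with its metadata table. Failed observations become rows
#' of the returned `skipped` table instead of aborting the batch.
#'
#' @param images list of `leaf_image` objects, or a directory path.
#' @param meta metadata `data.frame` (columns `image_path`, `plant_id`,
#'   `treatment`, `year`, `dat`, `leaf_position`, `dpi`) when `images` is a
#'   directory.
#' @param ... passed to [extract_features()].
#' @return list with `features` (one row per measured leaf) and `skipped`.
#' @export
extract_features_batch <- function(images, meta = NULL, ...) {
  rows <- list()
  skipped <- list()
  push <- function(img, year) {
    res <- extract_features(img, ...)
    if (is_missing_observation(res)) {
      skipped[[length(skipped) + 1L]] <<- data.frame(
        plant_id = res$meta$plant_id %||% NA_character_,
        dat = res$meta$dat %||% NA_real_,
        leaf_position = res$meta$leaf_position %||% NA_character_,
        reason = res$reason, stringsAsFactors = FALSE)
    } else {
      res$year <- year
      rows[[length(rows) + 1L]] <<- res
    }
  }
  if (is.character(images)) {
    stopifnot(!is.null(meta))
    for (i in seq_len(nrow(meta))) {
      img <- read_leaf_image(file.path(images, meta$image_path[i]),
                             dpi = meta$dpi[i],
                             meta = as.list(meta[i, c("plant_id", "treatment",
                                                      "dat", "leaf_position")]))
      push(img, meta$year[i])
    }
  } else {
    for (img in images) push(img, img$meta$year %||% 1L)
  }
  list(
    features = if (length(rows)) do.call(rbind, rows) else NULL,
    skipped = if (length(skipped)) do.call(rbind, skipped) else NULL
  )
}
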