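# Internal numeric helpers shared by the imaging and synthesis code.

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream. `seed` must stay below 2^31 - 1.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed and a string key, stable across
# sessions (no dependence on the RNG itself).
derive_seed <- function(master, key) {
  h <- 0
  for (ch in utf8ToInt(paste0(key))) h <- (h * 31 + ch) %% 2147480000
  as.integer((as.numeric(master) * 7919 + h) %% 2147480000) + 1L
}

#' Convert RGB (0-255) to hue/saturation/brightness
#'
#' Hue is in degrees with red at 0, saturation and brightness in \[0, 1\]
#' (the "brightness" is HSV value, max of the scaled channels). For an
#' achromatic color (max = min) the hue is returned as `NA`.
#'
#' @param r,g,b channel values on the 0-255 scale (vectors allowed).
#' @return a list with numeric vectors `h` (degrees), `s`, `v`.
#' @export
rgb_to_hsb <- function(r, g, b) {
  hsv <- grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 255)
  h <- hsv[1, ] * 360
  s <- hsv[2, ]
  h[s == 0] <- NA_real_
  list(h = unname(h), s = unname(s), v = unname(hsv[3, ]))
}

# 3x3 box filter with zero padding; used to smooth a binary mask before
# extracting the 0.5 iso-contour (reduces staircase bias on oblique edges).
box_smooth3 <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  p <- matrix(0, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  s <- p[1:nr, 1:nc] + p[1:nr, 2:(nc + 1L)] + p[1:nr, 3:(nc + 2L)] +
    p[2:(nr + 1L), 1:nc] + p[2:(nr + 1L), 2:(nc + 1L)] + p[2:(nr + 1L), 3:(nc + 2L)] +
    p[3:(nr + 2L), 1:nc] + p[3:(nr + 2L), 2:(nc + 1L)] + p[3:(nr + 2L), 3:(nc + 2L)]
  s / 9
}

# Total length (in pixel units) of the 0.5 iso-contour of a scalar field,
# by marching squares with linear interpolation along cell edges. Saddle
# cells use the two-segment resolution. The field is zero-padded so closed
# regions touching the border still yield closed contours.
marching_squares_length <- function(field) {
  nr <- nrow(field)
  nc <- ncol(field)
  f <- matrix(0, nr + 2L, nc + 2L)
  f[2:(nr + 1L), 2:(nc + 1L)] <- field
  a <- f[-(nr + 2L), -(nc + 2L)] # top-left corner of each cell
  b <- f[-(nr + 2L), -1L]        # top-right
  cc <- f[-1L, -1L]              # bottom-right
  d <- f[-1L, -(nc + 2L)]        # bottom-left
  idx <- 1L + (a >= 0.5) + 2L * (b >= 0.5) + 4L * (cc >= 0.5) + 8L * (d >= 0.5)

  interp <- function(v1, v2) {
    t <- (0.5 - v1) / (v2 - v1)
    t[!is.finite(t)] <- 0.5
    t
  }
  xt <- interp(a, b)  # crossing on top edge, fraction from left
  yr <- interp(b, cc) # right edge, fraction from top
  xb <- interp(d, cc) # bottom edge, fraction from left
  yl <- interp(a, d)  # left edge, fraction from top
  seg <- function(x1, y1, x2, y2) sqrt((x1 - x2)^2 + (y1 - y2)^2)

  top_left  <- seg(xt, 0, 0, yl)
  top_right <- seg(xt, 0, 1, yr)
  bot_right <- seg(xb, 1, 1, yr)
  bot_left  <- seg(xb, 1, 0, yl)
  left_right <- seg(0, yl, 1, yr)
  top_bot    <- seg(xt, 0, xb, 1)

  len <- matrix(0, nrow(idx), ncol(idx))
  pick <- function(case, v) len[idx == case] <<- v[idx == case]
  pick(2L, top_left)              # a
  pick(3L, top_right)             # b
  pick(4L, left_right)            # a b
  pick(5L, bot_right)             # c
  pick(6L, top_left + bot_right)  # a c (saddle)
  pick(7L, top_bot)               # b c
  pick(8L, bot_left)              # a b c
  pick(9L, bot_left)              # d
  pick(10L, top_bot)              # a d
  pick(11L, top_right + bot_left) # b d (saddle)
  pick(12L, bot_right)            # a b d
  pick(13L, left_right)           # c d
  pick(14L, top_right)            # a c d
  pick(15L, top_left)             # b c d
  sum(len)
}

# Min-max scaler fitted on a training design matrix; constant columns map
# to 0.5 so they carry no information but stay finite.
fit_minmax <- function(x) {
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  list(lo = lo, range = hi - lo)
}

apply_minmax <- function(scaler, x) {
  out <- sweep(x, 2, scaler$lo, "-")
  rng <- scaler$range
  const <- rng <= 0
  rng[const] <- 1
  out <- sweep(out, 2, rng, "/")
  out[, const] <- 0.5
  out
}

csv_write <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
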