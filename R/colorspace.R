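#' Colour constants used by the channel decomposition
#'
#' Returns the fixed conversion constants: the sRGB-primaries RGB to XYZ
#' matrix rescaled so that RGB white maps exactly onto the D65 whitepoint
#' (X_w, Y_w, Z_w) = (95.04, 100.00, 108.89), the NTSC YIQ matrix whose
#' luminance row is (0.299, 0.587, 0.114), and the CIELAB linear-segment
#' threshold (6/29)^3.
#'
#' @return A list with elements `whitepoint`, `rgb_to_xyz`, `yiq` and
#'   `lab_f_threshold`.
#' @export
color_constants <- function() {
  wp <- c(95.04, 100.00, 108.89)
  m <- matrix(c(
    0.4124564, 0.3575761, 0.1804375,
    0.2126729, 0.7151522, 0.0721750,
    0.0193339, 0.1191920, 0.9503041), nrow = 3, byrow = TRUE)
  # scale each row so (1,1,1) maps exactly to the whitepoint
  m <- m * (wp / rowSums(m))
  yiq <- matrix(c(
    0.299,     0.587,     0.114,
    0.595716, -0.274453, -0.321263,
    0.211456, -0.522591,  0.311135), nrow = 3, byrow = TRUE)
  list(whitepoint = wp, rgb_to_xyz = m, yiq = yiq,
       lab_f_threshold = (6 / 29)^3)
}

#' Convert an RGB image to gray-scale (NTSC luminance)
#'
#' Gray = 0.299 R + 0.587 G + 0.114 B, i.e. the luminance row of the YIQ
#' matrix, so the gray channel is identical to the Y channel.
#'
#' @param img An H x W x 3 array with values in \[0, 1\].
#' @return An H x W matrix in \[0, 1\].
#' @export
rgb_to_gray <- function(img) {
  check_rgb_image(img)
  d <- dim(img)
  matrix(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3],
         d[1], d[2])
}

#' Convert an RGB image to CIELAB
#'
#' Two-stage conversion: a linear RGB to XYZ map (see [color_constants()]),
#' then the standard CIELAB cube-root compression with linear segment below
#' (6/29)^3, normalised by the D65 whitepoint. RGB is not gamma-linearised
#' before the matrix by default (`linearize = FALSE`); set `linearize = TRUE`
#' for an sRGB decode first.
#'
#' @param img H x W x 3 RGB array in \[0, 1\].
#' @param constants Conversion constants, see [color_constants()].
#' @param linearize If `TRUE`, apply the sRGB electro-optical transfer
#'   function before the linear matrix. Default `FALSE`.
#' @return A list with matrices `L` (0..100), `A`, `B` (signed).
#' @export
rgb_to_lab <- function(img, constants = color_constants(), linearize = FALSE) {
  check_rgb_image(img)
  d <- dim(img)
  rgb <- matrix(img, ncol = 3)
  if (linearize) {
    rgb <- ifelse(rgb <= 0.04045, rgb / 12.92, ((rgb + 0.055) / 1.055)^2.4)
  }
  xyz <- rgb %*% t(constants$rgb_to_xyz)
  xyz <- sweep(xyz, 2, constants$whitepoint, "/")
  thr <- constants$lab_f_threshold
  f <- function(t) ifelse(t > thr, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
  fx <- f(xyz[, 1]); fy <- f(xyz[, 2]); fz <- f(xyz[, 3])
  list(L = matrix(116 * fy - 16, d[1], d[2]),
       A = matrix(500 * (fx - fy), d[1], d[2]),
       B = matrix(200 * (fy - fz), d[1], d[2]))
}

#' Convert an RGB image to HSI
#'
#' I = (R+G+B)/3; S = 1 - min(R,G,B)/I for I > 0, else 0; H from the
#' standard arccos formula, rescaled to \[0, 1\] (full turn = 1). Hue is
#' undefined for achromatic pixels (S = 0) and is set to 0 there.
#'
#' @param img H x W x 3 RGB array in \[0, 1\].
#' @return A list with matrices `H`, `S`, `I`.
#' @export
rgb_to_hsi <- function(img) {
  check_rgb_image(img)
  d <- dim(img)
  r <- as.vector(img[, , 1]); g <- as.vector(img[, , 2]); b <- as.vector(img[, , 3])
  i <- (r + g + b) / 3
  mn <- pmin(r, g, b)
  s <- ifelse(i > 0, 1 - mn / i, 0)
  num <- 0.5 * ((r - g) + (r - b))
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  h <- ifelse(den > 0, acos(pmin(pmax(num / den, -1), 1)), 0)
  h <- ifelse(b > g, 2 * pi - h, h)
  h <- h / (2 * pi)
  h[s == 0] <- 0
  list(H = matrix(h, d[1], d[2]), S = matrix(s, d[1], d[2]),
       I = matrix(i, d[1], d[2]))
}

#' Convert an RGB image to YIQ (and back)
#'
#' Linear NTSC map; `yiq_to_rgb` is its exact matrix inverse, so the
#' round-trip is the identity up to floating point.
#'
#' @param img H x W x 3 RGB array in \[0, 1\].
#' @param constants Conversion constants, see [color_constants()].
#' @return For `rgb_to_yiq`, a list with matrices `Y`, `I`, `Q`; for
#'   `yiq_to_rgb`, an H x W x 3 RGB array.
#' @export
rgb_to_yiq <- function(img, constants = color_constants()) {
  check_rgb_image(img)
  d <- dim(img)
  yiq <- matrix(img, ncol = 3) %*% t(constants$yiq)
  list(Y = matrix(yiq[, 1], d[1], d[2]),
       I = matrix(yiq[, 2], d[1], d[2]),
       Q = matrix(yiq[, 3], d[1], d[2]))
}

#' @param yiq A list with matrices `Y`, `I`, `Q` as returned by
#'   [rgb_to_yiq()].
#' @rdname rgb_to_yiq
#' @export
yiq_to_rgb <- function(yiq, constants = color_constants()) {
  d <- dim(yiq$Y)
  m <- cbind(as.vector(yiq$Y), as.vector(yiq$I), as.vector(yiq$Q))
  rgb <- m %*% t(solve(constants$yiq))
  array(rgb, c(d[1], d[2], 3))
}

#' Split an RGB image into the 13 single-channel images of the pipeline
#'
#' Decomposes the image into gray + RGB + CIELAB + HSI + YIQ channels. Each
#' channel is independently min-max rescaled to \[0, 1\] so that one
#' receptive-field set trained on gray-scale patches can encode every
#' channel; a constant channel maps to all zeros. The returned order is
#' frozen and part of the pipeline contract:
#' `gray, R, G, B, L, A, Bstar, H, S, I, Y, Istar, Q`
#' (`Bstar`/`Istar` disambiguate CIELAB B from RGB B and YIQ I from HSI I).
#'
#' @inheritParams rgb_to_lab
#' @return A named list of 13 H x W matrices, each in \[0, 1\].
#' @export
split_channels <- function(img, constants = color_constants(),
                           linearize = FALSE) {
  check_rgb_image(img)
  lab <- rgb_to_lab(img, constants, linearize)
  hsi <- rgb_to_hsi(img)
  yiq <- rgb_to_yiq(img, constants)
  raw <- list(
    gray = rgb_to_gray(img),
    R = img[, , 1], G = img[, , 2], B = img[, , 3],
    L = lab$L, A = lab$A, Bstar = lab$B,
    H = hsi$H, S = hsi$S, I = hsi$I,
    Y = yiq$Y, Istar = yiq$I, Q = yiq$Q)
  lapply(raw, minmax01)
}

# Frozen grouping of the 12 colour channels into their four colour spaces,
# in the tie-breaking order used by the entropy selection.
channel_groups <- function() {
  list(RGB = c("R", "G", "B"),
       CIELAB = c("L", "A", "Bstar"),
       HSI = c("H", "S", "I"),
       YIQ = c("Y", "Istar", "Q"))
}
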