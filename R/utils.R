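#' @keywords internal
"_PACKAGE"

# Rescale to [0, 1]; a constant input maps to all zeros so that downstream
# histogram and entropy code never divides by a zero range.
minmax01 <- function(x) {
  rng <- range(x)
  if (!all(is.finite(rng))) stop("non-finite values in input")
  if (rng[2] == rng[1]) return(array(0, dim = dim(x) %||% length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reflecting (mirror) index into 1..n for out-of-range i, used for border
# padding during dense patch extraction.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * (n - 1L)
  j <- (i - 1L) %% period
  j <- ifelse(j >= n, period - j, j)
  j + 1L
}

# Bilinear upsampling of a matrix computed on a regular pixel grid
# (rows gy, cols gx of the target image) back to the full H x W raster.
upsample_bilinear <- function(m, gy, gx, height, width) {
  stopifnot(nrow(m) == length(gy), ncol(m) == length(gx))
  interp_axis <- function(targets, knots) {
    # for each target coordinate, bracketing knot indices and weight
    k <- findInterval(targets, knots, all.inside = TRUE)
    k <- pmin(k, length(knots) - 1L)
    if (length(knots) == 1L) {
      return(list(lo = rep(1L, length(targets)), hi = rep(1L, length(targets)),
                  w = rep(0, length(targets))))
    }
    w <- (targets - knots[k]) / (knots[k + 1L] - knots[k])
    w <- pmin(pmax(w, 0), 1)
    list(lo = k, hi = k + 1L, w = w)
  }
  ay <- interp_axis(seq_len(height), gy)
  ax <- interp_axis(seq_len(width), gx)
  top <- m[ay$lo, ax$lo, drop = FALSE] * (1 - ay$w) + m[ay$hi, ax$lo, drop = FALSE] * ay$w
  bot <- m[ay$lo, ax$hi, drop = FALSE] * (1 - ay$w) + m[ay$hi, ax$hi, drop = FALSE] * ay$w
  sweep(top, 2, 1 - ax$w, "*") + sweep(bot, 2, ax$w, "*")
}

# Laplacian (double-exponential) deviates, location 0, scale b.
rlaplace <- function(n, b = 1) {
  u <- stats::runif(n) - 0.5
  -b * sign(u) * log(1 - 2 * abs(u))
}

check_rgb_image <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("expected an H x W x 3 RGB array")
  if (!all(is.finite(img))) stop("non-finite pixel values")
  if (min(img) < 0 || max(img) > 1)
    stop("RGB values must lie in [0, 1] (divide 8-bit input by 255)")
  invisible(img)
}
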