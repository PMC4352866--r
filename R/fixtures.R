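#' Synthetic 1/f-spectrum ("pink noise") gray-scale images
#'
#' White Gaussian noise is shaped in the frequency domain so that the
#' amplitude spectrum falls off as `1/f^exponent` (exponent 1 approximates
#' the ensemble statistics of natural scenes), inverse-transformed and
#' min-max normalised to \[0, 1\]. Pure function of `(n, size, exponent,
#' seed)`.
#'
#' @param n Number of images.
#' @param size Image side in pixels (>= 32 recommended).
#' @param exponent Spectral exponent (0 = white noise, 1 = natural-like).
#' @param seed Integer seed.
#' @return A list of `n` size x size matrices in \[0, 1\].
#' @export
make_pink_noise_images <- function(n, size = 128, exponent = 1, seed = 1) {
  set.seed(seed)
  fr <- c(0:(size %/% 2), -((size - size %/% 2 - 1):1)) / size
  f2 <- outer(fr^2, fr^2, "+")
  amp <- 1 / sqrt(f2)^exponent
  amp[1, 1] <- 0                      # kill DC; mean handled by normalisation
  lapply(seq_len(n), function(i) {
    wn <- matrix(stats::rnorm(size * size), size, size)
    shaped <- Re(stats::fft(stats::fft(wn) * amp, inverse = TRUE)) / size^2
    minmax01(shaped)
  })
}

#' Pop-out scene with known ground truth
#'
#' A background carrying achromatic 1/f ("natural-statistics") luminance
#' texture with one square target region of a distinct colour; the mask
#' marks the target pixels exactly. With `contrast = 0` the target is
#' identical to the background (the no-signal control).
#'
#' @param size Image side in pixels.
#' @param target_frac Target area as a fraction of the image (default 0.04).
#' @param contrast Colour contrast of the target in \[0, 1\]; 0 disables it.
#' @param texture_sd Standard deviation of the background luminance texture.
#' @param seed Integer seed (target position, colours, texture).
#' @return A list with `image` (H x W x 3 RGB array in \[0, 1\]) and `mask`
#'   (logical H x W matrix).
#' @export
make_popout_scene <- function(size = 96, target_frac = 0.04, contrast = 1,
                              texture_sd = 0.05, seed = 1) {
  set.seed(seed)
  tside <- max(2L, round(size * sqrt(target_frac)))
  if (tside >= size) stop("target does not fit inside the image")
  bg <- stats::runif(3, 0.3, 0.6)
  # target colour: push the channels apart from the background colour
  dir <- stats::rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  tgt <- pmin(pmax(bg + contrast * 0.45 * dir, 0), 1)
  y0 <- sample.int(size - tside + 1L, 1L)
  x0 <- sample.int(size - tside + 1L, 1L)
  # achromatic 1/f luminance texture, matching the training ensemble
  tex <- make_pink_noise_images(1, size = size, exponent = 1,
                                seed = sample.int(.Machine$integer.max, 1))[[1]]
  tex <- (tex - mean(tex)) / stats::sd(tex) * texture_sd
  img <- array(0, c(size, size, 3))
  mask <- matrix(FALSE, size, size)
  mask[y0:(y0 + tside - 1L), x0:(x0 + tside - 1L)] <- TRUE
  for (c in 1:3) {
    plane <- matrix(bg[c], size, size)
    plane[mask] <- tgt[c]
    img[, , c] <- pmin(pmax(plane + tex, 0), 1)
  }
  list(image = img, mask = mask)
}

#' Patches generated from a known sparse Gabor dictionary
#'
#' Builds a random dictionary of `K` unit-norm, zero-mean Gabor atoms and
#' synthesises patches as sparse combinations: `s` atoms per patch with
#' Laplacian-distributed coefficients, plus Gaussian pixel noise of standard
#' deviation `sigma`. Returns both the patches and the generating
#' dictionary, enabling dictionary-recovery tests of the network training.
#'
#' @param n Number of patches.
#' @param side Patch side in pixels (default 10).
#' @param K Dictionary size (default 64).
#' @param s Non-zero coefficients per patch (default 3).
#' @param sigma Additive Gaussian noise SD (default 0.01).
#' @param seed Integer seed.
#' @return A list with `patches` (n x side^2) and `dictionary`
#'   (K x side^2, unit-norm rows).
#' @export
make_sparse_patch_set <- function(n, side = 10, K = 64, s = 3, sigma = 0.01,
                                  seed = 1) {
  set.seed(seed)
  D <- .random_gabor_dictionary(K, side)
  coefs <- matrix(0, n, K)
  for (i in seq_len(n)) {
    sel <- sample.int(K, s)
    coefs[i, sel] <- rlaplace(s, b = 1)
  }
  patches <- coefs %*% D
  if (sigma > 0) patches <- patches + matrix(stats::rnorm(n * side^2,
                                                          sd = sigma),
                                             n, side^2)
  list(patches = patches, dictionary = D, coefficients = coefs)
}

.random_gabor_dictionary <- function(K, side) {
  D <- matrix(0, K, side * side)
  xs <- seq_len(side) - (side + 1) / 2
  grid_x <- matrix(xs, side, side, byrow = TRUE)
  grid_y <- matrix(xs, side, side)
  for (k in seq_len(K)) {
    th <- stats::runif(1, 0, pi)
    freq <- stats::runif(1, 0.12, 0.35)          # cycles / pixel
    phase <- stats::runif(1, 0, 2 * pi)
    sd_env <- stats::runif(1, side / 8, side / 4)
    cx <- stats::runif(1, -side / 6, side / 6)
    cy <- stats::runif(1, -side / 6, side / 6)
    xr <- (grid_x - cx) * cos(th) + (grid_y - cy) * sin(th)
    yr <- -(grid_x - cx) * sin(th) + (grid_y - cy) * cos(th)
    g <- exp(-(xr^2 + 0.8 * yr^2) / (2 * sd_env^2)) *
      cos(2 * pi * freq * xr + phase)
    g <- g - mean(g)
    nrm <- sqrt(sum(g^2))
    if (nrm < 1e-8) {
      g <- g + stats::rnorm(length(g), sd = 1e-3)
      g <- g - mean(g)
      nrm <- sqrt(sum(g^2))
    }
    D[k, ] <- as.vector(g) / nrm
  }
  D
}

#' Greedy one-to-one matching of learned filters to a dictionary
#'
#' Matches learned receptive fields (rows of `learned`) to true dictionary
#' atoms by absolute Pearson correlation, greedily assigning the globally
#' best remaining pair first; each atom and each filter is used at most
#' once. Used to score dictionary recovery.
#'
#' @param learned Matrix of learned filters (rows).
#' @param dictionary Matrix of generating atoms (rows).
#' @param threshold Absolute correlation above which an atom counts as
#'   recovered (default 0.8).
#' @return A list with `recovered` (fraction of atoms recovered), `matches`
#'   (data frame: atom, filter, abs_cor).
#' @export
match_dictionary <- function(learned, dictionary, threshold = 0.8) {
  stopifnot(ncol(learned) == ncol(dictionary))
  cmat <- abs(stats::cor(t(dictionary), t(learned)))
  cmat[!is.finite(cmat)] <- 0
  natom <- nrow(dictionary)
  matches <- data.frame(atom = integer(), filter = integer(),
                        abs_cor = numeric())
  free_a <- rep(TRUE, natom); free_f <- rep(TRUE, nrow(learned))
  for (step in seq_len(min(natom, nrow(learned)))) {
    sub <- cmat
    sub[!free_a, ] <- -1; sub[, !free_f] <- -1
    best <- arrayInd(which.max(sub), dim(sub))
    matches <- rbind(matches, data.frame(atom = best[1], filter = best[2],
                                         abs_cor = sub[best]))
    free_a[best[1]] <- FALSE; free_f[best[2]] <- FALSE
  }
  list(recovered = sum(matches$abs_cor > threshold) / natom,
       matches = matches)
}
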