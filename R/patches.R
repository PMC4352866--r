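#' Sample square patches from a set of channel images
#'
#' Draws `n` patches of side `side` uniformly over images and valid top-left
#' positions, and vectorises each patch into a row. Reproducible given
#' `seed`.
#'
#' @param images A list of numeric matrices (channel images), each at least
#'   `side` x `side`.
#' @param n Number of patches.
#' @param side Patch side in pixels (default 14, giving 196-dimensional
#'   stimuli).
#' @param seed Integer seed.
#' @return An `n` x `side^2` matrix, one vectorised patch per row.
#' @export
sample_patches <- function(images, n, side = 14, seed = 1) {
  if (is.matrix(images)) images <- list(images)
  for (im in images) {
    if (nrow(im) < side || ncol(im) < side)
      stop("image smaller than the requested patch side")
  }
  set.seed(seed)
  idx <- sample.int(length(images), n, replace = TRUE)
  out <- matrix(0, n, side * side)
  for (p in seq_len(n)) {
    im <- images[[idx[p]]]
    y <- sample.int(nrow(im) - side + 1L, 1L)
    x <- sample.int(ncol(im) - side + 1L, 1L)
    out[p, ] <- as.vector(im[y:(y + side - 1L), x:(x + side - 1L)])
  }
  out
}

#' Mean-centre and ZCA-whiten a patch matrix
#'
#' Computes the symmetric (ZCA) whitening transform of the patch covariance
#' with an eigenvalue floor, so that the whitened sample covariance is the
#' identity on well-conditioned input. The transform (mean vector, whitening
#' and de-whitening matrices) is stored for reuse at inference time.
#'
#' Components with eigenvalues below `eps_rel * max(eigenvalue)` are floored;
#' with `var_retain < 1`, trailing components beyond that cumulative variance
#' fraction are projected out entirely (weight 0) rather than amplified —
#' useful when patches live on a low-dimensional subspace plus small noise,
#' as sparse-dictionary fixtures do.
#'
#' @param pm An `n` x `p` patch matrix (rows are patches).
#' @param eps_rel Relative eigenvalue floor.
#' @param var_retain Fraction of total variance to whiten; the remainder is
#'   suppressed. Default 1 (whiten everything).
#' @return A list with `patches` (whitened matrix) and `whitener` (list with
#'   `mean`, `w` whitening matrix, `dw` de-whitening matrix).
#' @export
whiten_patches <- function(pm, eps_rel = 1e-10, var_retain = 1) {
  stopifnot(is.matrix(pm))
  if (nrow(pm) <= ncol(pm))
    warning("fewer patches than patch dimensions; covariance is singular")
  mu <- colMeans(pm)
  xc <- sweep(pm, 2, mu)
  cv <- crossprod(xc) / (nrow(pm) - 1)
  if (max(diag(cv)) == 0) stop("zero-variance input: degenerate covariance")
  e <- eigen(cv, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  eps <- eps_rel * max(lam)
  scl <- 1 / sqrt(lam + eps)
  if (var_retain < 1) {
    keep <- cumsum(lam) / sum(lam) <= var_retain
    keep[1] <- TRUE
    scl[!keep] <- 0
  }
  w <- e$vectors %*% (scl * t(e$vectors))
  dw <- e$vectors %*% (sqrt(lam + eps) * t(e$vectors))
  whitener <- list(mean = mu, w = w, dw = dw)
  list(patches = apply_whitener(pm, whitener), whitener = whitener)
}

#' Apply (or invert) a stored whitening transform
#'
#' @param pm Patch matrix, rows are patches.
#' @param whitener A whitener as stored by [whiten_patches()].
#' @return The transformed patch matrix.
#' @export
apply_whitener <- function(pm, whitener) {
  sweep(pm, 2, whitener$mean) %*% whitener$w
}

#' @rdname apply_whitener
#' @export
unapply_whitener <- function(pm, whitener) {
  sweep(pm %*% whitener$dw, 2, whitener$mean, "+")
}

# Dense (stride-able) extraction of the side x side patch centred at each
# grid pixel, with reflecting border padding. Returns the patch matrix plus
# the grid coordinates, for later bilinear upsampling.
extract_patches_grid <- function(ch, side, stride = 1L) {
  h <- nrow(ch); w <- ncol(ch)
  off <- (side - 1L) %/% 2L
  gy <- seq.int(1L, h, by = stride)
  gx <- seq.int(1L, w, by = stride)
  # padded image via reflecting indices
  ridx <- reflect_index(seq.int(1L - off, h + (side - 1L - off)), h)
  cidx <- reflect_index(seq.int(1L - off, w + (side - 1L - off)), w)
  pad <- ch[ridx, cidx, drop = FALSE]
  npos <- length(gy) * length(gx)
  X <- matrix(0, npos, side * side)
  k <- 0L
  for (dc in seq_len(side)) {
    for (dr in seq_len(side)) {
      k <- k + 1L
      X[, k] <- as.vector(pad[gy + (dr - 1L), gx + (dc - 1L), drop = FALSE])
    }
  }
  list(x = X, gy = gy, gx = gx, height = h, width = w, stride = stride)
}
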