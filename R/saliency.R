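#' Histogram probability model of neuron responses
#'
#' Builds, for each response dimension independently, an equal-width
#' histogram over that dimension's observed range (default 1000 bins) from
#' which the probability of any observed response can be read off. Add-eps
#' smoothing bounds the self-information: the probability of a value falling
#' in bin b is `(count_b + eps) / (n + eps * bins)`. A degenerate dimension
#' (all responses identical) collapses to a single bin with probability 1.
#'
#' @param rm A `"v1_response_map"` or a plain n x K response matrix.
#' @param bins Number of histogram bins (default 1000).
#' @param eps Additive smoothing per bin (default 1).
#' @return An object of class `"v1_prob_model"` (type `"histogram"`).
#' @export
fit_histogram_model <- function(rm, bins = 1000, eps = 1) {
  x <- if (inherits(rm, "v1_response_map")) rm$counts else rm
  stopifnot(is.matrix(x), nrow(x) >= 1)
  if (bins < 1) stop("bins must be >= 1")
  K <- ncol(x)
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  probs <- vector("list", K)
  n <- nrow(x)
  for (k in seq_len(K)) {
    if (hi[k] == lo[k]) {
      probs[[k]] <- 1
    } else {
      idx <- .bin_index(x[, k], lo[k], hi[k], bins)
      cnt <- tabulate(idx, nbins = bins)
      probs[[k]] <- (cnt + eps) / (n + eps * bins)
    }
  }
  structure(list(type = "histogram", K = K, bins = bins, eps = eps,
                 lo = lo, hi = hi, probs = probs),
            class = "v1_prob_model")
}

.bin_index <- function(v, lo, hi, bins) {
  idx <- floor((v - lo) / (hi - lo) * bins) + 1L
  pmin(pmax(idx, 1L), bins)
}

#' Generalized Gaussian probability model of neuron responses
#'
#' Fits, per response dimension, a generalized Gaussian distribution
#' `f(x) = beta / (2 alpha Gamma(1/beta)) exp(-(|x - mu| / alpha)^beta)` by
#' moment matching: the shape `beta` solves the mean-absolute-deviation /
#' variance ratio `sigma^2 / m1^2 = Gamma(1/beta) Gamma(3/beta) /
#' Gamma(2/beta)^2` (Laplacian beta = 1, Gaussian beta = 2), the scale
#' `alpha` comes from the variance and `mu` is the sample mean.
#' Probabilities are evaluated as density times the bin width of an
#' equal-width grid with `bins` cells, so histogram and GGD models are
#' interchangeable in the saliency computation. A zero-variance dimension
#' falls back to the degenerate histogram rule (p = 1).
#'
#' @inheritParams fit_histogram_model
#' @return An object of class `"v1_prob_model"` (type `"ggd"`).
#' @export
fit_ggd_model <- function(rm, bins = 1000) {
  x <- if (inherits(rm, "v1_response_map")) rm$counts else rm
  stopifnot(is.matrix(x))
  K <- ncol(x)
  pars <- matrix(NA_real_, K, 3, dimnames = list(NULL, c("mu", "alpha", "beta")))
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  for (k in seq_len(K)) {
    v <- x[, k]
    if (hi[k] == lo[k]) next
    mu <- mean(v)
    sdv <- stats::sd(v)
    m1 <- mean(abs(v - mu))
    pars[k, ] <- c(mu, NA, NA)
    b <- .ggd_shape_from_ratio(sdv^2 / m1^2)
    a <- sdv * sqrt(gamma(1 / b) / gamma(3 / b))
    pars[k, ] <- c(mu, a, b)
  }
  structure(list(type = "ggd", K = K, bins = bins, pars = pars,
                 lo = lo, hi = hi),
            class = "v1_prob_model")
}

# Invert rho(beta) = Gamma(1/b) Gamma(3/b) / Gamma(2/b)^2 (monotone
# decreasing in b) for the observed variance / MAD^2 ratio.
.ggd_shape_from_ratio <- function(rho) {
  f <- function(b) gamma(1 / b) * gamma(3 / b) / gamma(2 / b)^2 - rho
  lo <- 0.1; hi <- 20
  if (f(lo) < 0) return(lo)
  if (f(hi) > 0) return(hi)
  stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
}

#' GGD density
#'
#' @param x Numeric vector.
#' @param mu,alpha,beta Location, scale (> 0) and shape (> 0).
#' @export
dggd <- function(x, mu = 0, alpha = 1, beta = 2) {
  beta / (2 * alpha * gamma(1 / beta)) * exp(-(abs(x - mu) / alpha)^beta)
}

# Probability of each observed response under the model, per dimension.
.model_prob <- function(pm, v, k) {
  if (pm$type == "histogram") {
    pr <- pm$probs[[k]]
    if (length(pr) == 1) return(rep(1, length(v)))
    return(pr[.bin_index(v, pm$lo[k], pm$hi[k], pm$bins)])
  }
  if (any(is.na(pm$pars[k, ]))) return(rep(1, length(v)))
  width <- (pm$hi[k] - pm$lo[k]) / pm$bins
  p <- dggd(v, pm$pars[k, "mu"], pm$pars[k, "alpha"], pm$pars[k, "beta"]) * width
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Self-information saliency map
#'
#' The saliency of a pixel is the summed self-information of its neuron
#' responses, `S(x, y) = sum_k -log p_k(r_k(x, y))` (natural log), treating
#' the response dimensions as independent. Rare responses — those falling in
#' sparsely populated histogram bins — mark salient locations.
#'
#' @param rm A `"v1_response_map"`.
#' @param pm A `"v1_prob_model"` fitted on `rm` (or on a reference
#'   ensemble).
#' @return A saliency matrix at the response-grid resolution, with
#'   attributes `gy`, `gx`, `height`, `width` preserved for upsampling.
#' @export
self_information_map <- function(rm, pm) {
  stopifnot(inherits(rm, "v1_response_map"), inherits(pm, "v1_prob_model"))
  if (pm$K != ncol(rm$counts))
    stop("probability model and response map have different dimensions")
  s <- numeric(nrow(rm$counts))
  for (k in seq_len(pm$K)) {
    s <- s - log(.model_prob(pm, rm$counts[, k], k))
  }
  out <- matrix(s, length(rm$gy), length(rm$gx))
  attr(out, "gy") <- rm$gy; attr(out, "gx") <- rm$gx
  attr(out, "height") <- rm$height; attr(out, "width") <- rm$width
  out
}

#' Shannon entropy of a saliency map
#'
#' The map is min-max normalised to \[0, 1\], quantised to `m` integer
#' levels, and the Shannon entropy (natural log) of the level histogram is
#' returned. A constant map has entropy 0; a map using all `m` levels
#' equally often attains the maximum `log(m)`. Low entropy indicates a
#' concentrated focus against a suppressed background, which is what the
#' channel selection rewards.
#'
#' @param sm A numeric saliency matrix.
#' @param m Number of quantisation levels (default 256).
#' @return The entropy in nats.
#' @export
map_entropy <- function(sm, m = 256) {
  stopifnot(all(is.finite(sm)))
  rng <- range(sm)
  if (rng[1] == rng[2]) return(0)
  v <- (sm - rng[1]) / (rng[2] - rng[1])
  lev <- round(v * (m - 1))
  p <- tabulate(lev + 1L, nbins = m)
  p <- p[p > 0] / length(lev)
  -sum(p * log(p))
}

#' Entropy-based selection and fusion of saliency sub-maps
#'
#' From each colour space the sub-map with the lowest entropy is selected
#' (ties go to the first channel in the frozen order). The four selected
#' maps and the gray-scale map are min-max normalised and linearly combined
#' with normalised reciprocal-entropy weights
#' `O_j = (1 / entropy_j) / sum_i (1 / entropy_i)`; the fused map is min-max
#' normalised to \[0, 1\]. Degenerate rule: if any selected entropy is 0,
#' that map receives weight 1 if unique, otherwise the zero-entropy maps
#' share the weight uniformly.
#'
#' @param gray_map Saliency sub-map of the gray-scale channel.
#' @param space_maps A list of 4 colour spaces, each a list of 3 saliency
#'   sub-maps in the frozen channel order (see [split_channels()]).
#' @param m Quantisation level for [map_entropy()].
#' @return A list with `map` (fused, in \[0, 1\]), `weights` (length 5,
#'   sums to 1, order: gray then the four spaces), `entropies` (all 13),
#'   `selected` (winning channel index per space).
#' @export
select_and_combine <- function(gray_map, space_maps, m = 256) {
  stopifnot(length(space_maps) == 4)
  dims <- dim(gray_map)
  sel_maps <- list(gray = gray_map)
  sel_ent <- c(gray = map_entropy(gray_map, m))
  all_ent <- list(gray = sel_ent[["gray"]])
  selected <- integer(0)
  for (sname in names(space_maps)) {
    maps <- space_maps[[sname]]
    stopifnot(length(maps) == 3)
    for (mp in maps) stopifnot(identical(dim(mp), dims))
    ents <- vapply(maps, map_entropy, numeric(1), m = m)
    all_ent[[sname]] <- ents
    win <- which.min(ents)          # ties: first in frozen order
    selected[sname] <- win
    sel_maps[[sname]] <- maps[[win]]
    sel_ent[sname] <- ents[win]
  }
  if (any(sel_ent == 0)) {
    w <- as.numeric(sel_ent == 0)
    w <- w / sum(w)
  } else {
    w <- (1 / sel_ent) / sum(1 / sel_ent)
  }
  fused <- matrix(0, dims[1], dims[2])
  for (j in seq_along(sel_maps)) {
    fused <- fused + w[j] * minmax01(sel_maps[[j]])
  }
  list(map = minmax01(fused), weights = unname(w), entropies = all_ent,
       selected = selected)
}

#' End-to-end saliency map of a colour image
#'
#' Runs the full pipeline: split the RGB image into 13 channels
#' ([split_channels()]), compute a neuron response map for each channel
#' ([compute_response_map()]), fit a per-channel probability model of the
#' responses and turn them into self-information sub-maps
#' ([self_information_map()]), then select the lowest-entropy sub-map per
#' colour space and fuse with reciprocal-entropy weights
#' ([select_and_combine()]). Deterministic given its inputs.
#'
#' @param img An H x W x 3 RGB array in \[0, 1\].
#' @param net A fitted [v1net()].
#' @param bins Histogram bins for the probability model (default 1000).
#' @param prob_model `"hist"` (default) or `"ggd"`.
#' @param stride Response-grid stride; sub-maps are computed on the grid and
#'   the fused map is bilinearly upsampled back to the image size.
#' @param m Entropy quantisation levels (default 256).
#' @param smooth_sigma Optional Gaussian blur (pixels) of the final map;
#'   0 (default) disables it.
#' @param eps Histogram smoothing, see [fit_histogram_model()].
#' @param keep_submaps Also return the 13 per-channel sub-maps (default
#'   `FALSE`).
#' @return An object of class `"v1_saliency"`: list with `map` (H x W in
#'   \[0, 1\]), `weights`, `entropies`, `selected` and (optionally)
#'   `submaps`.
#' @export
compute_saliency <- function(img, net, bins = 1000,
                             prob_model = c("hist", "ggd"),
                             stride = 1L, m = 256, smooth_sigma = 0,
                             eps = 1, keep_submaps = FALSE) {
  prob_model <- match.arg(prob_model)
  check_rgb_image(img)
  chans <- split_channels(img)
  submaps <- lapply(chans, function(ch) {
    rm <- compute_response_map(ch, net, stride = stride)
    pm <- if (prob_model == "hist") fit_histogram_model(rm, bins, eps)
          else fit_ggd_model(rm, bins)
    self_information_map(rm, pm)
  })
  groups <- channel_groups()
  space_maps <- lapply(groups, function(chn) submaps[chn])
  comb <- select_and_combine(submaps$gray, space_maps, m = m)
  final <- comb$map
  if (stride > 1) {
    a <- submaps$gray
    final <- minmax01(upsample_bilinear(final, attr(a, "gy"), attr(a, "gx"),
                                        attr(a, "height"), attr(a, "width")))
  }
  if (smooth_sigma > 0) final <- minmax01(.gauss_blur(final, smooth_sigma))
  structure(list(map = final, weights = comb$weights,
                 entropies = comb$entropies, selected = comb$selected,
                 stride = stride, prob_model = prob_model,
                 submaps = if (keep_submaps) submaps),
            class = "v1_saliency")
}

#' @export
print.v1_saliency <- function(x, ...) {
  cat(sprintf("v1 saliency map: %d x %d, model %s, stride %d\n",
              nrow(x$map), ncol(x$map), x$prob_model, x$stride))
  sel <- names(x$selected)
  cat("selected channels:",
      paste(sprintf("%s[%d]", sel, x$selected), collapse = ", "), "\n")
  cat("fusion weights:",
      paste(sprintf("%.3f", x$weights), collapse = ", "), "\n")
  invisible(x)
}

# Separable Gaussian blur with reflecting borders.
.gauss_blur <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  conv1 <- function(mat) {
    n <- nrow(mat)
    out <- matrix(0, n, ncol(mat))
    for (j in -r:r) {
      out <- out + k[j + r + 1] * mat[reflect_index(seq_len(n) + j, n), ,
                                      drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(m))))
}
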