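#' Encode whitened patches as spike counts
#'
#' Simulates `T` leaky integrate-and-fire steps for every patch (row of
#' `x`). At each step the membrane potential of neuron i is updated as
#' `u_i <- (1 - eta) u_i + eta (Q_i . x - sum_j W_ij s_j)`, where `s_j` are
#' the spikes emitted at the previous step; a neuron spikes and resets to 0
#' when `u_i` exceeds its threshold. The returned spike counts are the
#' neuron responses. Fully deterministic given its inputs.
#'
#' @param x Matrix of whitened patches (rows) or a single patch vector.
#' @param Q K x p feedforward weight matrix (receptive fields).
#' @param W K x K non-negative lateral inhibition matrix, zero diagonal.
#' @param theta Length-K vector of positive firing thresholds.
#' @param n_steps Number of LIF steps `T` (>= 1).
#' @param eta Leak/update rate in (0, 1].
#' @return An n x K matrix of non-negative integer spike counts.
#' @export
encode_patches <- function(x, Q, W, theta, n_steps = 50, eta = 0.2) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (n_steps < 1) stop("n_steps must be >= 1")
  stopifnot(ncol(x) == ncol(Q), length(theta) == nrow(Q))
  n <- nrow(x); K <- nrow(Q)
  drive <- x %*% t(Q)                      # n x K, constant over time
  th <- matrix(theta, n, K, byrow = TRUE)
  u <- matrix(0, n, K)
  s <- matrix(0, n, K)
  counts <- matrix(0L, n, K)
  any_spikes <- FALSE
  for (t in seq_len(n_steps)) {
    inh <- if (any_spikes) s %*% W else 0
    u <- (1 - eta) * u + eta * (drive - inh)
    fired <- u > th
    counts <- counts + fired
    u[fired] <- 0
    s <- fired + 0
    any_spikes <- any(fired)
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Fit a spiking sparse-coding network of model V1 neurons
#'
#' Learns Gabor-like receptive fields from image patches with a
#' single-population spiking network trained by local plasticity rules
#' (SAILnet-style): Hebbian/anti-Hebbian lateral inhibition
#' `dW_ij = alpha (n_i n_j - p^2)` (clipped at W >= 0, zero diagonal), an
#' Oja-like feedforward rule `dQ_i = beta n_i (x - n_i Q_i)`, and a
#' homeostatic threshold rule `dtheta_i = gamma (n_i - p)` that drives every
#' neuron's mean spike count per patch towards the target rate `p`.
#' The two factors shaped by these rules are response sparseness and the
#' error between each patch and its reconstruction from spike counts.
#'
#' Patches are mean-centred and ZCA-whitened before training unless
#' `whiten = FALSE` (in which case `x` must already be whitened); the
#' whitening transform is stored in the fitted object and reused when the
#' network encodes new images.
#'
#' @param x An n x p matrix of vectorised image patches (see
#'   [sample_patches()]), p = `side^2`.
#' @param K Number of neurons (default 128).
#' @param n_steps LIF steps per patch presentation (default 50).
#' @param eta LIF leak/update rate (default 0.2).
#' @param p Target mean spike count per patch per neuron; default
#'   `0.05 * n_steps` (= 2.5 at the defaults, i.e. a 5% firing probability
#'   per step).
#' @param alpha,beta,gamma Learning rates for W, Q and theta.
#' @param epochs Passes over the patch set; `epochs = 0` returns the
#'   untrained (random-Q) network, useful as a baseline.
#' @param batch_size Patches per update.
#' @param seed Integer seed (weight initialisation and patch shuffling).
#' @param whiten Whiten `x` internally (default `TRUE`).
#' @param eps_rel,var_retain Whitening options, see [whiten_patches()].
#' @param q_bound Divergence guard: training aborts if any |Q| exceeds it.
#' @return An object of class `"v1net"`: list with `Q`, `W`, `theta`,
#'   `whitener`, `gain` (least-squares reconstruction gain), `config`,
#'   `history` (per-epoch mean rate and relative reconstruction error) and
#'   `eval_sample` (a stored whitened subset used by [residuals.v1net()]).
#' @examples
#' imgs <- make_pink_noise_images(n = 4, size = 48, seed = 1)
#' pm <- sample_patches(imgs, n = 1500, side = 8, seed = 1)
#' net <- v1net(pm, K = 12, epochs = 3, seed = 1)
#' net
#' @export
v1net <- function(x, K = 128, n_steps = 50, eta = 0.2, p = 0.05 * n_steps,
                  alpha = 0.1, beta = 0.01, gamma = 0.02,
                  epochs = 20, batch_size = 100, seed = 1,
                  whiten = TRUE, eps_rel = 1e-10, var_retain = 1,
                  q_bound = 100) {
  stopifnot(is.matrix(x), K >= 1, n_steps >= 1, p > 0,
            alpha > 0, beta > 0, gamma > 0, epochs >= 0)
  side <- sqrt(ncol(x))
  if (whiten) {
    wh <- whiten_patches(x, eps_rel = eps_rel, var_retain = var_retain)
    xw <- wh$patches
    whitener <- wh$whitener
  } else {
    xw <- x
    whitener <- list(mean = rep(0, ncol(x)), w = diag(ncol(x)),
                     dw = diag(ncol(x)))
  }
  n <- nrow(xw); pdim <- ncol(xw)
  set.seed(seed)
  Q <- matrix(stats::rnorm(K * pdim), K, pdim)
  Q <- Q / sqrt(rowSums(Q^2))
  W <- matrix(0, K, K)
  theta <- rep(1, K)
  eval_idx <- seq_len(min(500L, n))
  xeval <- xw[eval_idx, , drop = FALSE]
  # epoch 0: the untrained network, as the baseline for training progress
  n0 <- encode_patches(xeval, Q, W, theta, n_steps, eta)
  history <- data.frame(epoch = 0L, mean_rate = mean(n0),
                        recon_error = .recon_error(xeval, n0, Q))
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    rate_acc <- 0; nb <- 0L
    for (start in seq.int(1L, n, by = batch_size)) {
      sel <- ord[start:min(start + batch_size - 1L, n)]
      xb <- xw[sel, , drop = FALSE]
      m <- nrow(xb)
      ns <- encode_patches(xb, Q, W, theta, n_steps, eta)
      # local plasticity updates
      W <- W + alpha * (crossprod(ns) / m - p^2)
      diag(W) <- 0
      W[W < 0] <- 0
      Q <- Q + beta * (crossprod(ns, xb) / m - colMeans(ns^2) * Q)
      theta <- pmax(theta + gamma * (colMeans(ns) - p), 1e-4)
      if (max(abs(Q)) > q_bound)
        stop("training diverged: |Q| exceeded ", q_bound,
             "; reduce the learning rates")
      rate_acc <- rate_acc + mean(ns)
      nb <- nb + 1L
    }
    ne <- encode_patches(xeval, Q, W, theta, n_steps, eta)
    history <- rbind(history, data.frame(
      epoch = ep, mean_rate = rate_acc / nb,
      recon_error = .recon_error(xeval, ne, Q)))
  }
  ne <- encode_patches(xeval, Q, W, theta, n_steps, eta)
  rec <- ne %*% Q
  gain <- sum(xeval * rec) / max(sum(rec * rec), .Machine$double.eps)
  structure(list(
    Q = Q, W = W, theta = theta, whitener = whitener, gain = gain,
    config = list(K = K, side = side, patch_dim = pdim, n_steps = n_steps,
                  eta = eta, p = p, alpha = alpha, beta = beta,
                  gamma = gamma, epochs = epochs, batch_size = batch_size,
                  seed = seed),
    history = history, eval_sample = xeval),
    class = "v1net")
}

.recon_error <- function(xw, counts, Q) {
  rec <- counts %*% Q
  g <- sum(xw * rec) / max(sum(rec * rec), .Machine$double.eps)
  sqrt(sum((xw - g * rec)^2) / max(sum(xw^2), .Machine$double.eps))
}

#' Train a V1 network on synthetic natural-statistics images
#'
#' Convenience wrapper: generates 1/f ("pink") noise images, samples and
#' whitens patches, and fits [v1net()] with the standard configuration
#' (14 x 14 patches, 128 neurons).
#'
#' @param n_patches Number of training patches (default 50000).
#' @param n_images Number of synthetic images to sample from.
#' @param image_size Side of the synthetic images.
#' @param side Patch side (default 14).
#' @param seed Integer seed.
#' @param ... Further arguments passed to [v1net()].
#' @return A fitted `"v1net"` object.
#' @export
train_v1_network <- function(n_patches = 50000, n_images = 20,
                             image_size = 128, side = 14, seed = 1, ...) {
  imgs <- make_pink_noise_images(n = n_images, size = image_size, seed = seed)
  pm <- sample_patches(imgs, n = n_patches, side = side, seed = seed + 1)
  v1net(pm, seed = seed + 2, ...)
}

#' @export
print.v1net <- function(x, ...) {
  cfg <- x$config
  cat("Spiking sparse-coding V1 network\n")
  cat(sprintf("  %d neurons, %d x %d patches (%d-dimensional stimuli)\n",
              cfg$K, cfg$side, cfg$side, cfg$patch_dim))
  h <- x$history
  cat(sprintf("  trained %d epochs; final mean rate %.3f (target %.3f), relative reconstruction error %.3f\n",
              max(h$epoch), h$mean_rate[nrow(h)], cfg$p, h$recon_error[nrow(h)]))
  invisible(x)
}

#' @export
summary.v1net <- function(object, ...) {
  out <- list(config = object$config, history = object$history,
              theta = summary(object$theta),
              w_density = mean(object$W[upper.tri(object$W)] > 0))
  class(out) <- "summary.v1net"
  out
}

#' @export
print.summary.v1net <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("v1net: K = %d neurons, patch %d x %d, T = %d LIF steps, eta = %.2f, target rate p = %.2f spikes/patch\n",
              cfg$K, cfg$side, cfg$side, cfg$n_steps, cfg$eta, cfg$p))
  cat(sprintf("lateral inhibition density: %.1f%% of pairs\n",
              100 * x$w_density))
  cat("thresholds:\n"); print(x$theta)
  cat("training history (last 5 epochs):\n")
  print(utils::tail(x$history, 5), row.names = FALSE)
  invisible(x)
}

#' Receptive fields of a fitted network
#'
#' Returns the learned receptive fields as a K x p matrix. With
#' `space = "pixel"` the rows are de-whitened back to pixel space, which is
#' the form to inspect visually or to compare against a generating
#' dictionary; `space = "whitened"` returns the raw feedforward weights Q.
#'
#' @param object A fitted `"v1net"`.
#' @param space `"pixel"` or `"whitened"`.
#' @param ... Unused.
#' @export
coef.v1net <- function(object, space = c("pixel", "whitened"), ...) {
  space <- match.arg(space)
  if (space == "whitened") return(object$Q)
  # de-whiten the direction of each RF (drop the mean offset: RFs are
  # contrast patterns, not images)
  object$Q %*% object$whitener$dw
}

#' Mosaic plot of learned receptive fields
#'
#' @param x A fitted `"v1net"`.
#' @param n_show How many receptive fields to draw (default up to 64).
#' @param ... Unused.
#' @export
plot.v1net <- function(x, n_show = min(64L, x$config$K), ...) {
  side <- x$config$side
  rf <- coef(x, space = "pixel")
  nc <- ceiling(sqrt(n_show)); nr <- ceiling(n_show / nc)
  op <- graphics::par(mfrow = c(nr, nc), mar = c(0.2, 0.2, 0.2, 0.2))
  on.exit(graphics::par(op))
  for (i in seq_len(n_show)) {
    m <- matrix(rf[i, ], side, side)
    graphics::image(t(m[side:1, ]), axes = FALSE,
                    col = grDevices::gray.colors(64))
  }
  invisible(x)
}

#' Reconstruction residuals of a fitted network
#'
#' Encodes patches with the network and returns the residual between each
#' whitened patch and its reconstruction `gain * counts %*% Q`. With no
#' `patches` argument, the stored evaluation subset of the training patches
#' is used.
#'
#' @param object A fitted `"v1net"`.
#' @param patches Optional raw patch matrix (will be whitened with the
#'   stored transform).
#' @param ... Unused.
#' @return A matrix of residuals in whitened space, with attribute
#'   `"relative_error"` (Frobenius-norm ratio).
#' @export
residuals.v1net <- function(object, patches = NULL, ...) {
  xw <- if (is.null(patches)) object$eval_sample
        else apply_whitener(patches, object$whitener)
  cfg <- object$config
  counts <- encode_patches(xw, object$Q, object$W, object$theta,
                           cfg$n_steps, cfg$eta)
  res <- xw - object$gain * (counts %*% object$Q)
  attr(res, "relative_error") <- sqrt(sum(res^2) / max(sum(xw^2),
                                                       .Machine$double.eps))
  res
}

#' Save or load a fitted network
#'
#' Thin RDS-based serialisation of `"v1net"` objects with a schema version
#' tag.
#'
#' @param object A fitted `"v1net"`.
#' @param path File path.
#' @export
write_v1net <- function(object, path) {
  stopifnot(inherits(object, "v1net"))
  object$schema <- "v1net-1"
  saveRDS(object, path)
  invisible(path)
}

#' @rdname write_v1net
#' @export
read_v1net <- function(path) {
  object <- readRDS(path)
  if (!inherits(object, "v1net") || !identical(object$schema, "v1net-1"))
    stop("not a serialized v1net object")
  object
}
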