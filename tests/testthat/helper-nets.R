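# Shared fitted networks, trained once per test run and memoised.
.net_cache <- new.env(parent = emptyenv())

# Small network on 1/f-noise patches: fast, used by unit tests.
tiny_net <- function() {
  if (is.null(.net_cache$tiny)) {
    imgs <- make_pink_noise_images(n = 4, size = 64, seed = 41)
    pm <- sample_patches(imgs, n = 3000, side = 8, seed = 42)
    .net_cache$tiny <- v1net(pm, K = 24, epochs = 4, seed = 43)
  }
  .net_cache$tiny
}

# Hand-built single-neuron network with an identity whitener, for toys.
toy_net <- function(q, theta = 1, n_steps = 50, eta = 0.2, gain = 1) {
  pdim <- length(q)
  side <- as.integer(sqrt(pdim))
  structure(list(
    Q = matrix(q, 1, pdim), W = matrix(0, 1, 1), theta = theta,
    whitener = list(mean = rep(0, pdim), w = diag(pdim), dw = diag(pdim)),
    gain = gain,
    config = list(K = 1L, side = side, patch_dim = pdim, n_steps = n_steps,
                  eta = eta, p = 1, alpha = 0.1, beta = 0.01, gamma = 0.02,
                  epochs = 0, batch_size = 100, seed = 1),
    history = data.frame(epoch = 0L, mean_rate = NA_real_,
                         recon_error = NA_real_),
    eval_sample = matrix(0, 1, pdim)),
    class = "v1net")
}

# Full-scale networks for the acceptance checks (trained lazily, shared
# across acceptance blocks).
acceptance_pink_net <- function() {
  if (is.null(.net_cache$pink)) {
    imgs <- make_pink_noise_images(n = 12, size = 128, seed = 21)
    pm <- sample_patches(imgs, n = 20000, side = 14, seed = 22)
    .net_cache$pink <- v1net(pm, K = 128, epochs = 12, seed = 23)
  }
  .net_cache$pink
}

acceptance_dict_run <- function() {
  if (is.null(.net_cache$dict)) {
    sp <- make_sparse_patch_set(n = 20000, side = 10, K = 64, s = 3,
                                sigma = 0.01, seed = 11)
    net <- v1net(sp$patches, K = 128, p = 0.3, epochs = 30, seed = 12,
                 var_retain = 0.999)
    .net_cache$dict <- list(fixture = sp, net = net,
                            match = match_dictionary(coef(net),
                                                     sp$dictionary))
  }
  .net_cache$dict
}

excess_kurtosis <- function(v) {
  m <- mean(v); s2 <- mean((v - m)^2)
  if (s2 == 0) return(NA_real_)
  mean((v - m)^4) / s2^2 - 3
}
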