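test_that("LIF encoding matches a scalar reference simulation", {
  # independent single-neuron oracle
  lif1 <- function(d, theta, n_steps, eta) {
    u <- 0; n <- 0
    for (t in seq_len(n_steps)) {
      u <- (1 - eta) * u + eta * d
      if (u > theta) { n <- n + 1; u <- 0 }
    }
    n
  }
  q <- c(0.5, -0.3, 0.2, 0.1)
  x <- c(2, -1, 0.5, 3)
  for (theta in c(0.05, 0.3, 0.9)) {
    for (eta in c(0.1, 0.2, 0.5)) {
      got <- encode_patches(x, matrix(q, 1), matrix(0, 1, 1), theta,
                            n_steps = 50, eta = eta)
      expect_equal(as.integer(got), lif1(sum(q * x), theta, 50, eta),
                   ignore_attr = TRUE)
    }
  }
  # counts grow with simulation length under constant suprathreshold drive
  c10 <- encode_patches(x, matrix(q, 1), matrix(0, 1, 1), 0.05, n_steps = 10)
  c80 <- encode_patches(x, matrix(q, 1), matrix(0, 1, 1), 0.05, n_steps = 80)
  expect_gt(c80[1], c10[1])
  expect_error(encode_patches(x, matrix(q, 1), matrix(0, 1, 1), 1,
                              n_steps = 0), "n_steps")
})

test_that("zero input produces zero spikes and thresholds act monotonically", {
  set.seed(13)
  Q <- matrix(rnorm(8 * 16), 8, 16)
  W <- matrix(0, 8, 8)
  x <- matrix(rnorm(5 * 16), 5, 16)
  expect_true(all(encode_patches(matrix(0, 3, 16), Q, W, rep(0.5, 8)) == 0))
  lo <- encode_patches(x, Q, W, rep(0.2, 8))
  hi <- encode_patches(x, Q, W, rep(0.8, 8))
  expect_true(all(hi <= lo))
  expect_true(all(lo >= 0))
  expect_true(all(lo == floor(lo)))
  # determinism
  expect_identical(encode_patches(x, Q, W, rep(0.3, 8)),
                   encode_patches(x, Q, W, rep(0.3, 8)))
})

test_that("lateral inhibition between duplicate neurons lowers joint counts", {
  set.seed(14)
  q <- rnorm(9)
  Q <- rbind(q, q)
  x <- 1.2 * q / sum(q^2)        # moderate drive: Q . x = 1.2 per neuron
  free <- encode_patches(x, Q, matrix(0, 2, 2), rep(0.5, 2))
  Wm <- matrix(c(0, 50, 50, 0), 2, 2)
  inhib <- encode_patches(x, Q, Wm, rep(0.5, 2))
  expect_gt(sum(free), 0)
  expect_lt(sum(inhib), sum(free))
})

test_that("training is reproducible, homeostatic, and guards divergence", {
  imgs <- make_pink_noise_images(n = 2, size = 48, seed = 51)
  pm <- sample_patches(imgs, n = 1500, side = 8, seed = 52)
  net1 <- v1net(pm, K = 16, epochs = 4, seed = 53)
  net2 <- v1net(pm, K = 16, epochs = 4, seed = 53)
  expect_identical(net1$Q, net2$Q)
  expect_identical(net1$theta, net2$theta)
  h <- net1$history
  expect_lt(abs(h$mean_rate[nrow(h)] - net1$config$p) / net1$config$p, 0.25)
  # W stays non-negative with a zero diagonal
  expect_true(all(net1$W >= 0))
  expect_true(all(diag(net1$W) == 0))
  expect_true(all(net1$theta > 0))
  expect_error(v1net(pm, K = 16, epochs = 4, beta = 5, seed = 53),
               "diverged")
})

test_that("reconstruction recovers the identity-dictionary limit and the mean patch", {
  # orthonormal Q, no inhibition, responses used as exact coefficients
  pdim <- 16
  Q <- diag(pdim)[1:8, ]
  net <- toy_net(rep(0, pdim))
  net$Q <- Q; net$W <- matrix(0, 8, 8); net$theta <- rep(1, 8)
  net$config$K <- 8L
  coefs <- matrix(rnorm(3 * 8), 3, 8)
  expect_equal(reconstruct(coefs, net), coefs %*% Q, tolerance = 1e-12)
  # zero responses reconstruct the (whitener) mean patch
  net$whitener$mean <- rep(0.5, pdim)
  expect_equal(as.vector(reconstruct(rep(0, 8), net)), rep(0.5, pdim))
  expect_error(reconstruct(matrix(0, 2, 5), net), "dimension")
})

test_that("training on structured patches tightens reconstruction versus a random net", {
  sp <- make_sparse_patch_set(n = 6000, side = 8, K = 24, s = 3,
                              sigma = 0.01, seed = 61)
  trained <- v1net(sp$patches, K = 48, p = 0.5, epochs = 8, seed = 62,
                   var_retain = 0.999)
  random <- v1net(sp$patches, K = 48, p = 0.5, epochs = 0, seed = 62,
                  var_retain = 0.999)
  err_t <- attr(residuals(trained, sp$patches), "relative_error")
  err_r <- attr(residuals(random, sp$patches), "relative_error")
  expect_lt(err_t, err_r)
  expect_gt(trained$history$recon_error[1], tail(trained$history$recon_error, 1))
})

test_that("response maps are translation-invariant on constant input and equivariant under flips", {
  net <- tiny_net()
  ch <- matrix(0.5, 18, 18)
  rm <- compute_response_map(ch, net)
  expect_identical(nrow(rm$counts), 18L * 18L)
  expect_equal(ncol(rm$counts), net$config$K)
  expect_true(all(rm$counts == rep(rm$counts[1, ], each = nrow(rm$counts))))
  # flip equivariance with a single asymmetric receptive field (odd side)
  q <- as.vector(outer(seq(-1, 1, length.out = 7),
                       seq(-0.5, 1, length.out = 7)))
  tnet <- toy_net(q, theta = 0.05)
  qf <- as.vector(matrix(q, 7, 7)[, 7:1])   # horizontally flipped RF
  tnet_f <- toy_net(qf, theta = 0.05)
  set.seed(63)
  im <- matrix(runif(20 * 20), 20, 20)
  r <- matrix(compute_response_map(im, tnet)$counts, 20, 20)
  rf <- matrix(compute_response_map(im[, 20:1], tnet_f)$counts, 20, 20)
  expect_identical(r, rf[, 20:1])
})

test_that("response histograms on natural-statistics input are sparse and heavy-tailed", {
  net <- tiny_net()
  imgs <- make_pink_noise_images(n = 2, size = 48, seed = 71)
  pm <- sample_patches(imgs, n = 1500, side = 8, seed = 72)
  ct <- encode_patches(apply_whitener(pm, net$whitener), net$Q, net$W,
                       net$theta)
  exk <- apply(ct, 2, excess_kurtosis)
  expect_gt(mean(exk > 0, na.rm = TRUE), 0.9)
  expect_gt(mean(ct == 0), 0.3)   # zero-peaked
})

test_that("fitted networks serialise and round-trip through RDS", {
  net <- tiny_net()
  path <- tempfile(fileext = ".rds")
  write_v1net(net, path)
  back <- read_v1net(path)
  expect_identical(back$Q, net$Q)
  expect_identical(back$config, net$config)
  saveRDS(list(1), path)
  expect_error(read_v1net(path), "v1net")
})
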