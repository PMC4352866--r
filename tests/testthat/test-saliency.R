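fake_rm <- function(counts) {
  # wrap a plain response matrix as a 1-row-per-pixel response map
  structure(list(counts = counts, gy = seq_len(nrow(counts)), gx = 1L,
                 height = nrow(counts), width = 1L, stride = 1L,
                 K = ncol(counts), channel_tag = "toy"),
            class = "v1_response_map")
}

test_that("histogram model reproduces hand counts and normalises", {
  pm <- fit_histogram_model(matrix(c(0, 0, 0, 1)), bins = 2, eps = 0)
  expect_equal(pm$probs[[1]], c(0.75, 0.25))
  # degenerate dimension collapses to probability one
  pmd <- fit_histogram_model(matrix(5, 10, 1), bins = 1000)
  expect_equal(pmd$probs[[1]], 1)
  set.seed(30)
  x <- matrix(rpois(600, 3), 200, 3)
  pms <- fit_histogram_model(x, bins = 10, eps = 1)
  for (k in 1:3) expect_equal(sum(pms$probs[[k]]), 1)
  expect_error(fit_histogram_model(x, bins = 0), "bins")
})

test_that("self-information maps follow the histogram probabilities exactly", {
  # all pixels share one response vector: every dimension degenerate
  rm0 <- fake_rm(matrix(rep(c(2L, 7L), each = 6), 6, 2))
  pm0 <- fit_histogram_model(rm0)
  expect_true(all(self_information_map(rm0, pm0) == 0))
  # ten pixels, one unique in one dimension, two bins, no smoothing
  v <- c(rep(0L, 9), 1L)
  rm1 <- fake_rm(matrix(v))
  pm1 <- fit_histogram_model(rm1, bins = 2, eps = 0)
  s <- self_information_map(rm1, pm1)
  expect_equal(as.vector(s), c(rep(-log(0.9), 9), -log(0.1)))
  # shift invariance: histogram edges move with the data
  rm2 <- fake_rm(matrix(v + 5L))
  pm2 <- fit_histogram_model(rm2, bins = 2, eps = 0)
  expect_equal(as.vector(self_information_map(rm2, pm2)), as.vector(s))
  expect_error(self_information_map(rm1, fit_histogram_model(matrix(0:5, 3, 2))),
               "dimension")
  # self-information is non-negative and additive over dimensions
  set.seed(31)
  rm3 <- fake_rm(matrix(rpois(60, 2), 30, 2))
  pm3 <- fit_histogram_model(rm3, bins = 5)
  s3 <- self_information_map(rm3, pm3)
  expect_true(all(s3 >= 0))
  s_each <- sapply(1:2, function(k) {
    self_information_map(fake_rm(rm3$counts[, k, drop = FALSE]),
                         fit_histogram_model(rm3$counts[, k, drop = FALSE],
                                             bins = 5))
  })
  expect_equal(as.vector(s3), rowSums(s_each))
})

test_that("GGD moment fit recovers Gaussian and Laplacian shapes", {
  set.seed(32)
  g <- matrix(rnorm(1e5, mean = 2, sd = 3))
  fg <- fit_ggd_model(g)
  expect_lt(abs(fg$pars[1, "beta"] - 2), 0.3)
  expect_equal(unname(fg$pars[1, "mu"]), mean(g))
  u <- runif(1e5) - 0.5
  lap <- matrix(-sign(u) * log(1 - 2 * abs(u)))
  fl <- fit_ggd_model(lap)
  expect_lt(abs(fl$pars[1, "beta"] - 1), 0.3)
  # zero-variance dimension falls back to the degenerate rule
  fz <- fit_ggd_model(cbind(g[1:50], 3))
  s <- self_information_map(fake_rm(cbind(g[1:50], 3)), fz)
  expect_true(all(is.finite(s)))
})

test_that("map entropy has its exact degenerate, uniform and two-level values", {
  expect_equal(map_entropy(matrix(0.4, 5, 5)), 0)
  m <- 256
  u <- matrix(rep(seq(0, 1, length.out = m), 4))
  expect_equal(map_entropy(u, m = m), log(m), tolerance = 1e-12)
  two <- matrix(c(rep(0, 90), rep(1, 10)))
  expect_equal(map_entropy(two), -(0.9 * log(0.9) + 0.1 * log(0.1)),
               tolerance = 1e-12)
  # brute-force enumeration oracle on maps with few distinct values
  set.seed(33)
  for (rep in 1:10) {
    vals <- sort(runif(sample(2:5, 1)))
    mp <- matrix(sample(vals, 30, replace = TRUE), 5, 6)
    lev <- round((mp - min(mp)) / (max(mp) - min(mp)) * 255)
    p <- table(lev) / length(lev)
    expect_equal(map_entropy(mp), -sum(p * log(p)))
  }
  # monotone rescaling leaves the level frequencies untouched
  mp <- matrix(sample(c(0.1, 0.4, 0.9), 40, replace = TRUE), 8, 5)
  expect_equal(map_entropy(exp(mp)), map_entropy(mp), tolerance = 1e-9)
  expect_equal(map_entropy(mp^3), map_entropy(mp), tolerance = 1e-9)
})

test_that("entropy selection picks per-space minima and weights by reciprocal entropy", {
  set.seed(34)
  base <- matrix(runif(100), 10, 10)          # high entropy
  peaky <- matrix(0, 10, 10); peaky[5, 5] <- 1 # low entropy
  spaces <- lapply(1:4, function(i) list(base, peaky, base))
  names(spaces) <- c("RGB", "CIELAB", "HSI", "YIQ")
  res <- select_and_combine(base, spaces)
  expect_true(all(res$selected == 2))
  for (sname in names(spaces)) {
    ents <- sapply(spaces[[sname]], map_entropy)
    expect_lte(ents[res$selected[sname]], min(ents))
  }
  expect_equal(sum(res$weights), 1, tolerance = 1e-12)
  # weight ratio equals the inverse entropy ratio
  e_gray <- map_entropy(base); e_sel <- map_entropy(peaky)
  expect_equal(res$weights[1] / res$weights[2], e_sel / e_gray,
               tolerance = 1e-12)
  # identical maps everywhere: perfect symmetry, one fifth each
  same <- lapply(1:4, function(i) list(base, base, base))
  names(same) <- names(spaces)
  res2 <- select_and_combine(base, same)
  expect_equal(res2$weights, rep(0.2, 5))
  # zero-entropy winners take all the weight
  const <- matrix(0.5, 10, 10)
  res3 <- select_and_combine(const, same)
  expect_equal(res3$weights, c(1, 0, 0, 0, 0))
  res4 <- select_and_combine(const, lapply(same, function(x)
    list(const, base, base)))
  expect_equal(res4$weights, rep(0.2, 5))
  expect_true(all(res3$map >= 0 & res3$map <= 1))
})

test_that("the full pipeline highlights a pop-out region deterministically", {
  net <- tiny_net()
  sc <- make_popout_scene(size = 48, target_frac = 0.06, seed = 81)
  sal1 <- compute_saliency(sc$image, net, stride = 2)
  sal2 <- compute_saliency(sc$image, net, stride = 2)
  expect_identical(sal1$map, sal2$map)
  expect_identical(dim(sal1$map), dim(sc$mask))
  expect_true(all(sal1$map >= 0 & sal1$map <= 1))
  expect_equal(sum(sal1$weights), 1, tolerance = 1e-9)
  expect_gt(mean(sal1$map[sc$mask]), mean(sal1$map[!sc$mask]))
  # uniform image: no structure, near-constant map
  flat <- array(0.5, c(48, 48, 3))
  salf <- compute_saliency(flat, net, stride = 2)
  expect_lt(max(salf$map) - min(salf$map), 0.1)
  # GGD probability model runs through the same pipeline
  salg <- compute_saliency(sc$image, net, stride = 4, prob_model = "ggd")
  expect_true(all(is.finite(salg$map)))
})

test_that("entropy selection beats unselected channels on pop-out scenes", {
  net <- tiny_net()
  wins <- 0L; trials <- 0L
  for (i in 1:5) {
    sc <- make_popout_scene(size = 48, target_frac = 0.06, seed = 200 + i)
    sal <- compute_saliency(sc$image, net, stride = 2, keep_submaps = TRUE)
    auc_final <- auc_score(sal$map, sc$mask)
    groups <- v1saliency:::channel_groups()
    for (sname in names(groups)) {
      losers <- setdiff(seq_len(3), sal$selected[sname])
      for (l in losers) {
        sub <- sal$submaps[[groups[[sname]][l]]]
        up <- v1saliency:::upsample_bilinear(sub, attr(sub, "gy"),
                                             attr(sub, "gx"), 48, 48)
        trials <- trials + 1L
        wins <- wins + (auc_final > auc_score(up, sc$mask))
      }
    }
  }
  expect_gt(wins / trials, 0.7)
})
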