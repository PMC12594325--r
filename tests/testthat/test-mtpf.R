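# Texture priors: Laplacian edge, LBP, Gabor bank, prior stack, compression,
# attention fusion, pyramid pooling, MMD.

test_that("Laplacian kernel and edge map behave as specified", {
  # the exact 3x3 kernel: centre 4, four-neighbours -1, corners 0
  expect_equal(kidneyct:::LAPLACIAN_KERNEL,
               matrix(c(0, -1, 0, -1, 4, -1, 0, -1, 0), 3, 3))
  expect_equal(sum(kidneyct:::LAPLACIAN_KERNEL), 0)
  # constant image -> all zeros (kernel sums to zero, replicate padding)
  expect_true(all(abs(laplacian_edge(matrix(0.37, 9, 9))) < 1e-12))
  # unit impulse at the centre: 4 at centre, -1 at the 4-neighbours
  img <- matrix(0, 7, 7); img[4, 4] <- 1
  e <- laplacian_edge(img)
  expect_equal(e[4, 4], 4)
  expect_equal(c(e[3, 4], e[5, 4], e[4, 3], e[4, 5]), rep(-1, 4))
  e[3:5, 3:5] <- 0
  expect_true(all(e == 0))
  # output keeps the spatial size
  expect_equal(dim(laplacian_edge(fixture_image(12))), c(12L, 12L))
  expect_error(laplacian_edge(matrix(0, 2, 2)), "3x3")
})

test_that("LBP codes: constant image, local maximum, explicit pattern", {
  # constant image: ties count as 1, so every code is 2^P - 1
  expect_true(all(lbp_encode(matrix(0.5, 8, 8), P = 8, R = 1) == 255))
  # centre strictly above all neighbours -> code 0 (P=8, R=1)
  img <- matrix(1, 7, 7); img[4, 4] <- 9
  expect_equal(lbp_encode(img, 8, 1)[4, 4], 0)
  # explicit 3x3 pattern, enumerated with the documented ordering
  pat <- matrix(1, 5, 5)
  pat[2:4, 2:4] <- matrix(c(5, 1, 1, 1, 3, 1, 1, 1, 9), 3, 3, byrow = TRUE)
  expect_equal(lbp_encode(pat, 8, 1)[3, 3], lbp_oracle(pat, 8, 1)[3, 3])
  # codes bounded and scaling maps to [0,1]
  codes <- lbp_encode(fixture_image(16), 8, 1)
  expect_true(all(codes >= 0 & codes <= 255))
  scaled <- lbp_encode(fixture_image(16), 8, 1, scale = TRUE)
  expect_equal(scaled, codes / 255)
  # guards
  expect_error(lbp_encode(fixture_image(16), P = 2), "at least 4")
  expect_error(lbp_encode(fixture_image(16), P = 30), "overflow")
  expect_error(lbp_encode(matrix(0, 3, 3), P = 8, R = 1), "larger")
})

test_that("vectorized LBP equals the per-pixel enumeration oracle", {
  withr::with_seed(21, {
    for (i in 1:50) {
      img <- matrix(runif(256), 16, 16)
      expect_identical(lbp_encode(img, 8, 1), lbp_oracle(img, 8, 1))
    }
    # a non-integer radius exercises the bilinear sampling throughout
    img <- matrix(runif(256), 16, 16)
    expect_equal(lbp_encode(img, 8, 2), lbp_oracle(img, 8, 2))
  })
})

test_that("Gabor kernels match the closed form", {
  cfg <- gabor_config(sigma = 3, gamma = 0.5, size = 15)
  k <- gabor_kernel(cfg, lambda = 6, theta = 0)
  half <- 8 # centre index
  # origin value 1 at phase 0
  expect_equal(k[half, half], 1)
  # even symmetry at phase 0: G(x, y) = G(-x, -y)
  expect_equal(k, k[15:1, 15:1])
  # theta = 0, point (x, y) = (lambda/2, 0) -> -exp(-lambda^2 / (8 sigma^2))
  lam <- 6
  expect_equal(k[half, half + lam / 2], -exp(-lam^2 / (8 * 3^2)),
               tolerance = 1e-12)
  # configuration guards
  expect_error(gabor_config(size = 14), "odd")
  expect_error(gabor_config(wavelengths = numeric(0)), "at least one")
  expect_error(gabor_kernel(cfg, lambda = -2, theta = 0), "positive")
})

test_that("Gabor bank responses: zero input, constant input, linearity", {
  cfg <- gabor_config()
  z <- gabor_bank_responses(matrix(0, 10, 10), cfg)
  expect_true(all(z == 0))
  expect_equal(dim(z)[3], length(cfg$wavelengths) * length(cfg$orientations))
  # constant image: interior equals c * sum(kernel)
  cimg <- matrix(0.4, 41, 41)
  r <- gabor_bank_responses(cimg, cfg)
  k1 <- gabor_kernel(cfg, cfg$wavelengths[1], cfg$orientations[1])
  expect_lt(abs(r[21, 21, 1] - 0.4 * sum(k1)), 1e-12)
  # linearity within 1e-5
  withr::with_seed(4, {
    x <- matrix(runif(144), 12, 12); y <- matrix(runif(144), 12, 12)
    rx <- gabor_bank_responses(x, cfg)
    ry <- gabor_bank_responses(y, cfg)
    rxy <- gabor_bank_responses(2 * x + 3 * y, cfg)
    expect_equal(rxy, 2 * rx + 3 * ry, tolerance = 1e-5)
  })
})

test_that("prior stack has the documented channel order and geometry", {
  img <- fixture_image(16)
  st <- build_prior_stack(img, P = 8, R = 1, cfg = gabor_config())
  expect_equal(dim(st), c(16L, 16L, 10L)) # 2 + 2 * 4
  expect_equal(dimnames(st)[[3]][1:2], c("edge", "lbp"))
  expect_equal(st[, , 1], laplacian_edge(img))
  expect_equal(st[, , 2], lbp_encode(img, 8, 1, scale = TRUE))
  expect_equal(st[, , 3], gabor_bank_responses(img)[, , 1])
  # deterministic: identical inputs give bit-identical stacks
  expect_identical(st, build_prior_stack(img, 8, 1, gabor_config()))
})

test_that("prior compression applies conv + GELU as configured", {
  img <- fixture_image(12)
  st <- build_prior_stack(img)
  p <- compress_params(in_channels = 10, out_channels = 5, seed = 2)
  out <- compress_priors(st, p)
  expect_equal(dim(out), c(12L, 12L, 5L))
  # zero weights and bias give GELU(0) = 0
  p0 <- p; p0$weight[] <- 0; p0$bias[] <- 0
  expect_true(all(compress_priors(st, p0) == 0))
  # identity kernel on a single channel: GELU ~ identity for large inputs
  big <- array(5 + matrix(runif(64), 8, 8), c(8, 8, 1))
  pid <- compress_params(1, 1)
  pid$weight[] <- 0; pid$weight[2, 2, 1, 1] <- 1; pid$bias[] <- 0
  out_id <- compress_priors(big, pid)
  expect_equal(as.numeric(out_id), as.numeric(big), tolerance = 1e-3)
  expect_error(compress_priors(st, compress_params(3, 5)), "channels")
})

test_that("attention fusion gates and combines channels as specified", {
  withr::with_seed(8, {
    feats <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
    priors <- array(rnorm(12 * 12 * 3), c(12, 12, 3))
  })
  p <- attention_params(channels = 4, prior_channels = 3, seed = 3)
  # zero gate weights give alpha = beta = 0.5
  p0 <- p; p0$w_alpha[] <- 0; p0$w_beta[] <- 0
  r0 <- attention_fuse(feats, priors, p0)
  expect_equal(r0$alpha, rep(0.5, 4))
  expect_equal(r0$beta, rep(0.5, 4))
  # zero priors: fused = alpha (.) F
  pz <- p; pz$proj_weight[] <- 0; pz$proj_bias[] <- 0
  rz <- attention_fuse(feats, array(0, c(12, 12, 3)), pz)
  expect_equal(rz$fused, sweep(feats, 3, rz$alpha, "*"))
  # gates always in (0,1) and shapes preserved
  r <- attention_fuse(feats, priors, p)
  expect_true(all(r$alpha > 0 & r$alpha < 1 & r$beta > 0 & r$beta < 1))
  expect_equal(dim(r$fused), dim(feats))
  # hand-computed 2-channel toy
  f2 <- array(1, c(2, 2, 2)); f2[, , 2] <- 2
  t2 <- array(3, c(2, 2, 2)); t2[, , 2] <- 4
  ph <- attention_params(2, 2)
  ph$proj_weight <- diag(2); ph$proj_bias <- c(0, 0)
  ph$w_alpha <- matrix(0, 2, 2); ph$w_beta <- matrix(0, 2, 2)
  rh <- attention_fuse(f2, t2, ph)
  expect_equal(rh$fused[1, 1, ], 0.5 * c(1, 2) + 0.5 * c(3, 4))
})

test_that("pyramid pooling sums three pooled-and-upsampled grids", {
  # constant input c -> constant 3c
  expect_equal(pyramid_pool(matrix(0.3, 8, 8)), matrix(0.9, 8, 8))
  # shape preservation
  x <- array(runif(8 * 8 * 2), c(8, 8, 2))
  expect_equal(dim(pyramid_pool(x)), dim(x))
  # 4x4 hand example: scale 1 = global mean; scale 4 = identity
  m <- matrix(as.numeric(1:16), 4, 4)
  got <- pyramid_pool(m)
  q <- matrix(0, 4, 4) # scale-2: 2x2 block means, upsampled
  for (bi in 0:1) for (bj in 0:1) {
    q[bi * 2 + 1:2, bj * 2 + 1:2] <- mean(m[bi * 2 + 1:2, bj * 2 + 1:2])
  }
  expect_equal(got, mean(m) + q + m)
  # global mean is tripled (all scales average-pool)
  withr::with_seed(5, y <- matrix(runif(64), 8, 8))
  expect_equal(mean(pyramid_pool(y)), 3 * mean(y), tolerance = 1e-6)
  expect_error(pyramid_pool(matrix(0, 3, 3)), "at least")
})

test_that("MMD: zero on identical samples, nonnegative, singleton closed form", {
  withr::with_seed(10, a <- matrix(rnorm(30), 10, 3))
  expect_equal(mmd_loss(a, a), 0)
  expect_equal(mmd_loss(a, a[sample(10), , drop = FALSE]), 0) # multiset
  withr::with_seed(11, b <- matrix(rnorm(24, mean = 1), 8, 3))
  expect_gte(mmd_loss(a, b), 0)
  # singleton samples with the linear kernel: ||x - y||^2
  x <- matrix(c(1, 2, 3), 1); y <- matrix(c(2, 0, 3), 1)
  expect_equal(mmd_loss(x, y, kernel = "linear"), sum((x - y)^2))
  # degenerate bandwidth falls back with a warning
  expect_warning(mmd_loss(matrix(1, 3, 1), matrix(1, 2, 1)), "bandwidth")
  expect_error(mmd_loss(matrix(1, 2, 2), matrix(1, 2, 3)), "dimensionality")
  expect_error(mmd_loss(matrix(0, 0, 2), matrix(1, 2, 2)), "non-empty")
})

test_that("kernel-trick MMD equals the explicit double-sum oracle", {
  withr::with_seed(12, {
    for (i in 1:10) {
      n <- sample(3:20, 1); m <- sample(3:20, 1); d <- sample(1:4, 1)
      a <- matrix(rnorm(n * d), n, d)
      b <- matrix(rnorm(m * d, mean = 0.5), m, d)
      h <- 1.3
      expect_equal(mmd_loss(a, b, bandwidth = h), max(mmd_oracle(a, b, h), 0),
                   tolerance = 1e-8)
    }
  })
})

test_that("MMD gradients match finite differences", {
  withr::with_seed(13, {
    a <- matrix(rnorm(12), 6, 2)
    b <- matrix(rnorm(10, mean = 1), 5, 2)
  })
  g <- kidneyct:::mmd_rbf_grad(a, b)
  # the analytic gradient holds the median-heuristic bandwidth fixed, so
  # compare against finite differences at that fixed bandwidth
  d2 <- kidneyct:::pairwise_sqdist(rbind(a, b), rbind(a, b))
  h <- median(sqrt(d2[upper.tri(d2)]))
  eps <- 1e-6
  for (i in c(1, 4)) for (j in 1:2) {
    ap <- a; ap[i, j] <- ap[i, j] + eps
    am <- a; am[i, j] <- am[i, j] - eps
    num <- (mmd_loss(ap, b, bandwidth = h) - mmd_loss(am, b, bandwidth = h)) /
      (2 * eps)
    expect_equal(g$da[i, j], num, tolerance = 1e-5)
  }
  bp <- b; bp[2, 1] <- bp[2, 1] + eps
  bm <- b; bm[2, 1] <- bm[2, 1] - eps
  num <- (mmd_loss(a, bp, bandwidth = h) - mmd_loss(a, bm, bandwidth = h)) /
    (2 * eps)
  expect_equal(g$db[2, 1], num, tolerance = 1e-5)
})
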