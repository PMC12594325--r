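# Adaptive dual-window enhancement: window transform, projection, views,
# gated fusion, multi-scale features, histogram constraint.

test_that("window transform matches its closed form and fixed points", {
  # centre maps to exactly 0.5 for any width/sharpness
  expect_equal(window_transform(0.3, wl = 0.3, ww = 0.7, alpha = 3), 0.5)
  expect_equal(window_transform(c(0.5, 0.5), wl = 0.5, ww = 0.1, alpha = 9),
               c(0.5, 0.5))
  # tanh saturation far from the centre
  expect_lt(abs(window_transform(0.5 + 10 * 0.2 / 1, 0.5, 0.2, 1) - 1), 1e-8)
  expect_lt(abs(window_transform(0.5 - 10 * 0.2 / 1, 0.5, 0.2, 1) - 0), 1e-8)
  # x = wl + ww at alpha = 1 -> (tanh(1) + 1) / 2
  expect_equal(window_transform(0.75, wl = 0.25, ww = 0.5, alpha = 1),
               (tanh(1) + 1) / 2, tolerance = 1e-12)
  expect_equal(window_transform(0.75, wl = 0.25, ww = 0.5, alpha = 1),
               0.8807971, tolerance = 1e-7)
})

test_that("window transform is strictly increasing and maps into (0,1)", {
  grid <- seq(0, 1, length.out = 1000)
  y <- window_transform(grid, wl = 0.4, ww = 0.3, alpha = 2)
  expect_true(all(diff(y) > 0))
  expect_true(all(y > 0 & y < 1))
})

test_that("window transform validates its inputs", {
  expect_error(window_transform(0.5, 0.5, ww = 0, alpha = 1), "positive")
  expect_error(window_transform(0.5, 0.5, ww = -1, alpha = 1), "positive")
  expect_error(window_transform(0.5, 0.5, ww = 1, alpha = 0), "positive")
  expect_error(window_transform(c(0.5, NA), 0.5, 1, 1), "non-finite")
  expect_error(window_transform(c(0.5, Inf), 0.5, 1, 1), "non-finite")
})

test_that("window transform gradients match finite differences", {
  x <- matrix(seq(0.05, 0.95, length.out = 25), 5, 5)
  wl <- 0.4; ww <- 0.3; alpha <- 2; eps <- 1e-6
  g <- kidneyct:::window_transform_grads(x, wl, ww, alpha)
  expect_equal(g$y, window_transform(x, wl, ww, alpha))
  num <- function(f) (f(eps) - f(-eps)) / (2 * eps)
  dwl <- num(function(e) sum(window_transform(x, wl + e, ww, alpha)))
  dww <- num(function(e) sum(window_transform(x, wl, ww + e, alpha)))
  dal <- num(function(e) sum(window_transform(x, wl, ww, alpha + e)))
  expect_equal(sum(g$dwl), dwl, tolerance = 1e-3)
  expect_equal(sum(g$dww), dww, tolerance = 1e-3)
  expect_equal(sum(g$dalpha), dal, tolerance = 1e-3)
  expect_true(all(is.finite(g$dwl)) && any(g$dwl != 0))
})

test_that("projection clips into bounds, keeps interior points, is idempotent", {
  p <- window_params(wl1 = 0.5, ww1 = 0.5, wl2 = 0.75, ww2 = 0.35)
  expect_identical(project_window_params(p), p) # interior: unchanged
  p$wl1 <- p$wl_bounds[2] + 10
  p$ww2 <- p$ww_bounds[1] / 2
  q <- project_window_params(p)
  expect_equal(q$wl1, p$wl_bounds[2])
  expect_equal(q$ww2, p$ww_bounds[1])
  # idempotence on 1000 random draws
  withr::with_seed(7, {
    for (i in 1:1000) {
      r <- window_params(wl1 = runif(1, -2, 2), ww1 = runif(1, 0.01, 3),
                         wl2 = runif(1, -2, 2), ww2 = runif(1, 0.01, 3))
      once <- project_window_params(r)
      expect_identical(project_window_params(once), once)
      expect_true(once$wl1 >= r$wl_bounds[1] && once$wl1 <= r$wl_bounds[2])
      expect_true(once$ww2 >= r$ww_bounds[1] && once$ww2 <= r$ww_bounds[2])
    }
  })
})

test_that("window_params rejects invalid bounds and parameters", {
  expect_error(window_params(wl_bounds = c(0.9, 0.1)), "interval")
  expect_error(window_params(ww_bounds = c(-0.1, 1)), "interval")
  expect_error(window_params(ww1 = -1), "positive")
  expect_error(window_params(alpha = 0), "positive")
})

test_that("dual window views: symmetry, equality, and monotone ramps", {
  img <- fixture_image(16)
  p <- window_params()
  v <- dual_window_views(img, p)
  expect_identical(dim(v$x1), dim(img))
  expect_identical(dim(v$x2), dim(img))
  # identical pairs give identical views
  p_same <- window_params(wl1 = 0.4, ww1 = 0.3, wl2 = 0.4, ww2 = 0.3)
  v_same <- dual_window_views(img, p_same)
  expect_equal(v_same$x1, v_same$x2)
  # swapping the pairs swaps the views
  p_swap <- window_params(wl1 = p$wl2, ww1 = p$ww2, wl2 = p$wl1, ww2 = p$ww1)
  v_swap <- dual_window_views(img, p_swap)
  expect_equal(v_swap$x1, v$x2)
  expect_equal(v_swap$x2, v$x1)
  # monotone ramp input stays monotone in both views
  ramp <- matrix(rep(seq(0, 1, length.out = 16), each = 16), 16, 16)
  vr <- dual_window_views(ramp, p)
  expect_true(all(diff(vr$x1[1, ]) > 0))
  expect_true(all(diff(vr$x2[1, ]) > 0))
})

test_that("gated fusion is a per-pixel convex combination of the views", {
  img <- fixture_image(16)
  v <- dual_window_views(img, window_params())
  # equal views: fusion returns them unchanged regardless of the gate
  v_eq <- structure(list(x1 = v$x1, x2 = v$x1), class = "view_pair")
  f_eq <- gated_fusion(v_eq, fusion_gate(c(3, -2), 1))
  expect_equal(f_eq$fused, v$x1)
  # large positive pre-activation forces Z -> 1, X* -> x1
  f_sat <- gated_fusion(v, fusion_gate(c(0, 0), 50))
  expect_equal(f_sat$fused, v$x1, tolerance = 1e-8)
  # constant example: Z = 0.5, x1 = 0.2, x2 = 0.6 -> 0.4
  v_const <- structure(list(x1 = matrix(0.2, 4, 4), x2 = matrix(0.6, 4, 4)),
                       class = "view_pair")
  f_const <- gated_fusion(v_const, fusion_gate())
  expect_equal(f_const$fused, matrix(0.4, 4, 4))
  expect_equal(f_const$gate_map, matrix(0.5, 4, 4))
  # convexity on random gates and inputs
  withr::with_seed(3, {
    for (i in 1:20) {
      g <- fusion_gate(rnorm(2), rnorm(1))
      f <- gated_fusion(v, g)
      lo <- pmin(v$x1, v$x2); hi <- pmax(v$x1, v$x2)
      expect_true(all(f$fused >= lo - 1e-6 & f$fused <= hi + 1e-6))
      expect_true(all(f$gate_map > 0 & f$gate_map < 1))
    }
  })
  # misaligned views are rejected
  bad <- structure(list(x1 = matrix(0, 4, 4), x2 = matrix(0, 5, 5)),
                   class = "view_pair")
  expect_error(gated_fusion(bad), "aligned")
})

test_that("multi-scale features: zero kernels, delta kernel, linearity", {
  img <- fixture_image(16)
  p <- multiscale_params(out_channels = 3, seed = 5)
  # all-zero kernels give zero output
  p0 <- p
  for (k in names(p0$kernels)) p0$kernels[[k]][] <- 0
  expect_true(all(multiscale_features(img, p0) == 0))
  # centred delta on the k=3 branch replicates the input per channel
  pd <- p0
  pd$kernels$k3[2, 2, 1, ] <- 1
  fd <- multiscale_features(img, pd)
  for (ch in 1:3) expect_equal(fd[, , ch], img)
  # bias-free linearity: f(2x) = 2 f(x)
  f1 <- multiscale_features(img, p)
  f2 <- multiscale_features(2 * img, p)
  expect_equal(f2, 2 * f1, tolerance = 1e-10)
  expect_equal(dim(f1), c(16L, 16L, 3L))
})

test_that("soft histograms are normalized and the loss is a divergence", {
  x <- fixture_image(16)
  h <- soft_histogram(x, 64, 1 / 64)
  expect_equal(sum(h), 1, tolerance = 1e-6)
  expect_true(all(h >= 0))
  # equal images give zero loss
  v <- dual_window_views(x, window_params())
  f <- v$x1
  v_eq <- structure(list(x1 = f, x2 = f), class = "view_pair")
  expect_equal(histogram_match_loss(f, v_eq), 0, tolerance = 1e-12)
  # lambda1 = 1 and X* = x1 gives zero regardless of x2
  cfg1 <- histogram_config(lambda1 = 1, lambda2 = 0)
  expect_equal(histogram_match_loss(v$x1, v, cfg1), 0, tolerance = 1e-12)
  # nonnegative on arbitrary inputs
  expect_gte(histogram_match_loss(v$x2, v), 0)
  # invalid lambdas rejected
  expect_error(histogram_config(lambda1 = 0.7, lambda2 = 0.5), "sum to 1")
})

test_that("soft histogram at bin centres reduces to the hard histogram", {
  # two-level image with values exactly at bin centres: the triangular
  # kernel assigns all mass to the containing bin, so the soft histogram
  # equals hard binning and the loss equals the hard-histogram L2 oracle
  n_bins <- 8
  centers <- (seq_len(n_bins) - 0.5) / n_bins
  img <- matrix(c(rep(centers[2], 8), rep(centers[6], 8)), 4, 4)
  h <- soft_histogram(img, n_bins, 1 / n_bins)
  hard <- tabulate(findInterval(img, seq(0, 1, by = 1 / n_bins),
                                rightmost.closed = TRUE), n_bins) / length(img)
  expect_equal(h, hard, tolerance = 1e-12)
  # loss against a uniform two-level mixture computed by hand
  x1 <- matrix(centers[2], 4, 4)
  x2 <- matrix(centers[6], 4, 4)
  views <- structure(list(x1 = x1, x2 = x2), class = "view_pair")
  cfg <- histogram_config(n_bins = n_bins, bandwidth = 1 / n_bins)
  # H(X*) = (1/2, 1/2) on bins 2 and 6; mixture = same -> loss 0
  expect_equal(histogram_match_loss(img, views, cfg), 0, tolerance = 1e-12)
  # all-x1 fused image vs the mixture: loss = (1-1/2)^2 + (0-1/2)^2 = 1/2
  expect_equal(histogram_match_loss(x1, views, cfg), 0.5, tolerance = 1e-12)
})

test_that("soft-histogram gradient closure matches finite differences", {
  withr::with_seed(11, x <- runif(40, 0.1, 0.9))
  v <- kidneyct:::soft_histogram_vjp(x, 16, 1 / 16)
  expect_equal(v$p, soft_histogram(x, 16, 1 / 16))
  dp <- rnorm(16)
  g <- v$vjp(dp)
  eps <- 1e-7
  for (i in c(1, 7, 23)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    num <- (sum(dp * soft_histogram(xp, 16, 1 / 16)) -
            sum(dp * soft_histogram(xm, 16, 1 / 16))) / (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-5)
  }
})
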