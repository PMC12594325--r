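# Classifier assembly, forward contracts, losses, training loop mechanics.

test_that("configs validate their fields", {
  expect_error(model_config(num_classes = 1), "at least 2")
  expect_error(model_config(depths = c(1, 1)), "four")
  expect_error(model_config(input_size = 100), "divisible by 32")
  expect_error(model_config(lambda_hist = -1), "nonnegative")
  expect_error(train_config(epochs = 0), "at least 1")
  expect_error(train_config(split = c(0.5, 0.2, 0.2)), "sum to 1")
  tiny <- model_config(preset = "tiny")
  expect_equal(tiny$depths, c(1L, 1L, 2L, 1L))
  expect_equal(tiny$dim, 24L)
  expect_equal(tiny$input_size, 64L)
})

test_that("the classifier maps batches to logits with the right geometry", {
  cfg <- model_config(num_classes = 4, preset = "tiny")
  model <- build_classifier(cfg, seed = 1)
  withr::with_seed(2, batch <- array(runif(64 * 64 * 2), c(64, 64, 2)))
  fwd <- forward_pipeline(model, batch, keep_intermediates = TRUE)
  expect_equal(dim(fwd$logits), c(4L, 2L))
  # intermediates follow the documented geometry (stage dims double,
  # spatial halves; fusion at stage-3 output)
  ints <- fwd$intermediates
  expect_equal(dim(ints$xstar), c(1L, 64L, 64L, 2L))
  expect_equal(dim(ints$stages[[1]]), c(24L, 16L, 16L, 2L))
  expect_equal(dim(ints$stages[[3]]), c(96L, 4L, 4L, 2L))
  expect_equal(dim(ints$stages[[4]]), c(192L, 2L, 2L, 2L))
  expect_equal(dim(ints$priors), c(10L, 64L, 64L, 2L))
  expect_equal(dim(ints$fused_features), c(96L, 4L, 4L, 2L))
  expect_true(all(ints$gate > 0 & ints$gate < 1))
  # aux losses are nonnegative
  expect_gte(fwd$aux$hist, 0)
  expect_gte(fwd$aux$mmd, 0)
})

test_that("forward pass validates its input", {
  model <- build_classifier(fixture_model_config(), seed = 1)
  expect_error(forward_pipeline(model, array(0.5, c(32, 32, 1))), "expects")
  expect_error(forward_pipeline(model, array(1.5, c(64, 64, 1))),
               "normalized")
  expect_error(forward_pipeline(model, array(-0.2, c(64, 64, 1))),
               "normalized")
})

test_that("identical seeds give bit-identical models and forward passes", {
  cfg <- fixture_model_config()
  m1 <- build_classifier(cfg, seed = 5)
  m2 <- build_classifier(cfg, seed = 5)
  expect_identical(kidneyct:::snapshot_params(m1),
                   kidneyct:::snapshot_params(m2))
  withr::with_seed(1, batch <- array(runif(64 * 64 * 2), c(64, 64, 2)))
  f1 <- forward_pipeline(m1, batch)
  f2 <- forward_pipeline(m1, batch)
  expect_identical(f1$logits, f2$logits) # evaluation determinism
  m3 <- build_classifier(cfg, seed = 6)
  expect_false(identical(kidneyct:::snapshot_params(m1),
                         kidneyct:::snapshot_params(m3)))
})

test_that("parameter count equals the hand-summed per-layer arithmetic", {
  cfg <- model_config(num_classes = 2, preset = "tiny")
  model <- build_classifier(cfg, seed = 1)
  d <- 24
  block <- function(c) {
    (49 * c + c) +            # depthwise 7x7 + bias
      2 * c +                 # layernorm
      (c * 4 * c + 4 * c) +   # pointwise expand + bias
      2 * 4 * c +             # GRN
      (4 * c * c + c)         # pointwise project + bias
  }
  expected <- 5 +                                   # wl/ww pairs + alpha
    3 +                                             # gate w, b
    32 * (9 + 25 + 49) +                            # multi-scale banks
    (16 * 32 * d + d) + 2 * d +                     # stem conv + LN
    block(d) + block(2 * d) + 2 * block(4 * d) + block(8 * d) +
    (2 * d * 4 * d + 2 * d) + 2 * d +               # downsample 1 (conv+LN)
    (4 * d * 8 * d + 4 * d) + 4 * d +               # downsample 2
    (8 * d * 16 * d + 8 * d) + 8 * d +              # downsample 3
    (9 * 10 * 16 + 16) +                            # prior compression
    (16 * 4 * d + 4 * d) +                          # prior projection
    2 * (4 * d)^2 +                                 # attention gates
    (8 * d * 2 + 2)                                 # head
  expect_equal(count_params(model), expected)
})

test_that("total loss composes cross-entropy with weighted aux terms", {
  logits <- matrix(c(2, 0), 2, 1)
  # zero weights reduce to cross-entropy
  tl0 <- total_loss(logits, 1L, list(hist = 5, mmd = 9), c(0, 0))
  expect_equal(tl0$total, log(1 + exp(-2)))
  # the documented hand example
  tl <- total_loss(logits, 1L, list(hist = 0.5, mmd = 0.2), c(0.1, 0.01))
  expect_equal(tl$total, log(1 + exp(-2)) + 0.05 + 0.002, tolerance = 1e-12)
  expect_error(total_loss(logits, 1L, list(hist = 0, mmd = 0), c(-1, 0)),
               "nonnegative")
})

test_that("gradients reach the window parameters through the pipeline", {
  cfg <- fixture_model_config(lambda_hist = 0, lambda_mmd = 0,
                              use_mtpf = FALSE)
  model <- build_classifier(cfg, seed = 7)
  withr::with_seed(3, batch <- array(runif(64 * 64 * 2), c(64, 64, 2)))
  labels <- c(1L, 2L)
  fwd <- forward_pipeline(model, batch)
  tl <- total_loss(fwd$logits, labels, fwd$aux, c(0, 0))
  kidneyct:::module_list_zero(kidneyct:::flatten_modules(model$modules))
  model_backward(model, fwd, tl$dlogits)
  win <- model$modules$adwe_win
  eps <- 1e-5
  for (nm in c("wl1", "ww1", "wl2", "ww2", "alpha")) {
    g <- as.numeric(win$gr[[nm]])
    expect_true(is.finite(g) && g != 0)
    p <- win$par[[nm]]
    win$par[[nm]] <- p + eps
    f1 <- total_loss(forward_pipeline(model, batch)$logits, labels,
                     list(hist = 0, mmd = 0), c(0, 0))$total
    win$par[[nm]] <- p - eps
    f2 <- total_loss(forward_pipeline(model, batch)$logits, labels,
                     list(hist = 0, mmd = 0), c(0, 0))$total
    win$par[[nm]] <- p
    num <- (f1 - f2) / (2 * eps)
    expect_lt(abs(g - num) / max(abs(num), 1e-10), 1e-3)
  }
})

test_that("training is reproducible, bounded, and annealed", {
  ds <- generate_dataset(24, seed = 3, task = "binary")
  cfg <- fixture_model_config()
  tc <- train_config(epochs = 3, batch_size = 8, lr = 1e-3, seed = 21)
  f1 <- train_classifier(build_classifier(cfg, seed = 2), ds, tc)
  f2 <- train_classifier(build_classifier(cfg, seed = 2), ds, tc)
  expect_identical(f1$history, f2$history) # seeded end-to-end
  # cosine endpoint: final-epoch lr is (numerically) zero
  expect_lt(f1$history$lr[3], 1e-3 * 1e-6 + 1e-15)
  expect_equal(f1$history$lr[1], 1e-3)
  # window parameters stay inside their bounds after every epoch
  w <- model_window_params(f1$model)
  expect_true(w$wl1 >= w$wl_bounds[1] && w$wl1 <= w$wl_bounds[2])
  expect_true(w$ww2 >= w$ww_bounds[1] && w$ww2 <= w$ww_bounds[2])
  # history is a tidy per-epoch tibble
  expect_equal(tidy(f1)$epoch, 1:3)
  expect_equal(glance(f1)$epochs, 3)
  expect_error(train_classifier(build_classifier(cfg, 1),
                                list(images = array(0, c(64, 64, 0)),
                                     labels = integer(0)), tc), "empty")
})

test_that("ablation flags rewire the model as documented", {
  ds <- generate_dataset(16, seed = 13, task = "binary")
  variants <- list(
    baseline = c(FALSE, FALSE), adwe = c(TRUE, FALSE),
    mtpf = c(FALSE, TRUE), full = c(TRUE, TRUE))
  reports <- lapply(variants, function(v) {
    cfg <- fixture_model_config(use_adwe = v[1], use_mtpf = v[2])
    model <- build_classifier(cfg, seed = 3)
    fwd <- forward_pipeline(model, ds$images[, , 1:4],
                            keep_intermediates = TRUE)
    list(cfg = cfg, fwd = fwd)
  })
  # baseline: no ADWE gate/hist, no MTPF aux
  expect_null(reports$baseline$fwd$intermediates$gate)
  expect_equal(reports$baseline$fwd$aux$hist, 0)
  expect_equal(reports$baseline$fwd$aux$mmd, 0)
  # +ADWE only: hist active, mmd off
  expect_gt(reports$adwe$fwd$aux$hist, 0)
  expect_equal(reports$adwe$fwd$aux$mmd, 0)
  # +MTPF only: priors active without the dual-window front end
  expect_equal(reports$mtpf$fwd$aux$hist, 0)
  expect_false(is.null(reports$mtpf$fwd$intermediates$priors))
  # full: both constraint losses alive
  expect_gt(reports$full$fwd$aux$hist, 0)
  expect_gte(reports$full$fwd$aux$mmd, 0)
  # all four emit comparable logits
  for (r in reports) expect_equal(dim(r$fwd$logits), c(2L, 4L))
})

test_that("training pressure moves the high-density window toward the hyperdense range", {
  # Window-separable data: the two classes are uniform fields at 0.5 and
  # 0.9, so class membership is visible only above an intensity threshold.
  # With the high-density window initialized below that threshold and an
  # informative (linear-probe) head, descent on the cross-entropy must
  # push wl2 upward, toward the hyperdense range.
  k <- asNamespace("kidneyct")
  withr::with_seed(1, {
    n <- 16
    imgs <- array(rep(rep(c(0.5, 0.9), each = n / 2), each = 64 * 64),
                  c(64, 64, n))
    imgs <- imgs + array(runif(length(imgs), -0.02, 0.02), dim(imgs))
  })
  labs <- rep(1:2, each = 8)
  cfg <- fixture_model_config(window = window_params(wl2 = 0.45, ww2 = 0.2),
                              lambda_hist = 0, lambda_mmd = 0,
                              use_mtpf = FALSE)
  model <- build_classifier(cfg, seed = 11)
  f <- extract_features(model, imgs)
  yy <- ifelse(labs == 2, 1, -1)
  w <- solve(crossprod(f) + diag(ncol(f)), crossprod(f, yy))
  model$modules$head$par$w <- rbind(-as.numeric(w) / 2, as.numeric(w) / 2)
  model$modules$head$par$b <- c(0, 0)
  fwd <- forward_pipeline(model, imgs)
  tl <- total_loss(fwd$logits, labs, fwd$aux, c(0, 0))
  expect_gt(mean(apply(fwd$logits, 2, which.max) == labs), 0.6)
  k$module_list_zero(k$flatten_modules(model$modules))
  model_backward(model, fwd, tl$dlogits)
  # negative gradient: gradient descent increases wl2
  expect_lt(model$modules$adwe_win$gr$wl2, 0)
})

test_that("predictions are probabilities consistent across batch sizes", {
  model <- build_classifier(fixture_model_config(), seed = 9)
  withr::with_seed(4, imgs <- array(runif(64 * 64 * 5), c(64, 64, 5)))
  p1 <- predict_classifier(model, imgs, batch_size = 2)
  p2 <- predict_classifier(model, imgs, batch_size = 5)
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_equal(rowSums(p1), rep(1, 5), tolerance = 1e-12)
  expect_true(all(p1 >= 0 & p1 <= 1))
})
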