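# End-to-end classifier: ADWE enhancement -> ConvNeXtV2-style backbone with
# MTPF texture fusion -> classification head, trained with cross-entropy plus
# histogram-matching and MMD auxiliary losses. The forward and backward
# passes are written out explicitly; see nn.R for the layer primitives.

#' Model configuration
#'
#' Architecture and loss configuration. The default mirrors a
#' ConvNeXtV2-Tiny backbone (stage depths `[3,3,9,3]`, embedding dim 96,
#' 224x224 inputs); `preset = "tiny"` selects the desk-scale test preset
#' (depths `[1,1,2,1]`, dim 24, 64x64 inputs) used throughout the test
#' suite.
#'
#' @param num_classes Number of target classes (>= 2).
#' @param depths Integer vector of four stage depths.
#' @param dim Embedding dimension of stage 1 (doubling per stage).
#' @param input_size Square input size in pixels; must be divisible by 32.
#' @param ms_channels Output channels of the ADWE multi-scale convolution.
#' @param compress_channels Channels of the compressed texture priors.
#' @param lbp_p,lbp_r LBP neighbour count and radius for the prior stack.
#' @param gabor A [gabor_config()].
#' @param hist A [histogram_config()].
#' @param lambda_hist,lambda_mmd Auxiliary loss weights (>= 0).
#' @param window Initial [window_params()].
#' @param mmd_max_locations Maximum spatial locations sampled per batch for
#'   the MMD constraint.
#' @param use_adwe,use_mtpf Ablation switches. With `use_adwe = FALSE` the
#'   input passes through a single fixed window (level 0.5, width 1) and the
#'   histogram constraint is dropped; with `use_mtpf = FALSE` the texture
#'   branch, pyramid pooling and MMD constraint are dropped.
#' @param preset `"full"` or `"tiny"`.
#' @return An object of class `model_config`.
#' @export
model_config <- function(num_classes = 2,
                         depths = c(3, 3, 9, 3),
                         dim = 96,
                         input_size = 224,
                         ms_channels = 32,
                         compress_channels = 16,
                         lbp_p = 8, lbp_r = 1,
                         gabor = gabor_config(),
                         hist = histogram_config(),
                         lambda_hist = 0.1,
                         lambda_mmd = 0.01,
                         window = window_params(),
                         mmd_max_locations = 256,
                         use_adwe = TRUE,
                         use_mtpf = TRUE,
                         preset = c("full", "tiny")) {
  preset <- match.arg(preset)
  if (preset == "tiny" && missing(depths)) depths <- c(1, 1, 2, 1)
  if (preset == "tiny" && missing(dim)) dim <- 24
  if (preset == "tiny" && missing(input_size)) input_size <- 64
  if (num_classes < 2) stop_input("num_classes must be at least 2")
  if (length(depths) != 4 || any(depths < 1)) {
    stop_input("depths must be four positive integers")
  }
  if (input_size %% 32 != 0) {
    stop_input("input_size must be divisible by 32 (four downsampling stages)")
  }
  if (lambda_hist < 0 || lambda_mmd < 0) {
    stop_input("auxiliary loss weights must be nonnegative")
  }
  structure(list(
    num_classes = as.integer(num_classes), depths = as.integer(depths),
    dim = as.integer(dim), input_size = as.integer(input_size),
    ms_channels = as.integer(ms_channels),
    compress_channels = as.integer(compress_channels),
    lbp_p = lbp_p, lbp_r = lbp_r, gabor = gabor, hist = hist,
    lambda_hist = lambda_hist, lambda_mmd = lambda_mmd,
    window = window, mmd_max_locations = as.integer(mmd_max_locations),
    use_adwe = isTRUE(use_adwe), use_mtpf = isTRUE(use_mtpf),
    preset = preset
  ), class = "model_config")
}

#' Training configuration
#'
#' Defaults follow the full-scale training recipe (AdamW, initial learning
#' rate 1e-4, weight decay 1e-5, batch size 32, 100 epochs, cosine-annealed
#' learning rate, 7:1.5:1.5 split). Desk-scale smoke runs use fewer epochs
#' and a larger learning rate appropriate for a from-scratch tiny model.
#'
#' @param epochs Number of training epochs (>= 1).
#' @param batch_size Minibatch size.
#' @param lr Initial (peak) learning rate.
#' @param weight_decay AdamW weight-decay coefficient.
#' @param warmup_epochs Linear learning-rate warmup over this many initial
#'   epochs before the cosine decay (0 = plain cosine).
#' @param split Train/validation/test fractions, summing to 1.
#' @param augment An [augment_spec()] applied to training images, or `NULL`.
#' @param seed Global seed fanned out to shuffling and augmentation.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 100, batch_size = 32, lr = 1e-4,
                         weight_decay = 1e-5, warmup_epochs = 0,
                         split = c(train = 0.7, val = 0.15, test = 0.15),
                         augment = NULL, seed = 42) {
  if (epochs < 1) stop_input("epochs must be at least 1")
  if (warmup_epochs < 0 || warmup_epochs >= epochs) {
    stop_input("warmup_epochs must lie in [0, epochs)")
  }
  if (abs(sum(split) - 1) > 1e-9) stop_input("split fractions must sum to 1")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr = lr, weight_decay = weight_decay,
                 warmup_epochs = as.integer(warmup_epochs),
                 split = split,
                 augment = augment, seed = as.integer(seed)),
            class = "train_config")
}

#' Build the classifier
#'
#' Assembles the ADWE front end, the four-stage ConvNeXtV2-style backbone,
#' the MTPF texture branch (fused at the stage-3 output, followed by pyramid
#' pooling), and the global-average-pool + linear head. Initialisation is
#' fully determined by `seed`.
#'
#' @param cfg A [model_config()].
#' @param seed Initialisation seed.
#' @return An object of class `kct_model`.
#' @export
build_classifier <- function(cfg = model_config(), seed = 1) {
  stopifnot(inherits(cfg, "model_config"))
  m <- new.env(parent = emptyenv())
  m$cfg <- cfg
  dims <- cfg$dim * c(1L, 2L, 4L, 8L)
  with_seed(derive_seed(seed, "init"), {
    mods <- list()
    if (cfg$use_adwe) {
      w0 <- project_window_params(cfg$window)
      mods$adwe_win <- new_module("adwe_win", list(
        wl1 = w0$wl1, ww1 = w0$ww1, wl2 = w0$wl2, ww2 = w0$ww2,
        alpha = w0$alpha))
      mods$adwe_gate <- new_module("adwe_gate", list(w = c(0, 0), b = 0))
      for (k in c(3L, 5L, 7L)) {
        mods[[paste0("ms", k)]] <-
          layer_conv2d(1L, cfg$ms_channels, k, pad = (k - 1L) %/% 2L,
                       bias = FALSE, init_sd = 0.05)
      }
      # residual-style structured init: channel 1 of the k=3 bank starts as
      # the identity, so the enhanced image passes through unchanged at
      # initialization and the backbone sees raw contrast from step one
      mods$ms3$par$w[, , 1L, 1L] <- 0
      mods$ms3$par$w[2L, 2L, 1L, 1L] <- 1
      stem_in <- cfg$ms_channels
    } else {
      stem_in <- 1L
    }
    mods$stem_conv <- layer_conv2d(stem_in, dims[1], 4L, stride = 4L, pad = 0L)
    mods$stem_ln <- layer_layernorm(dims[1])
    for (s in 1:4) {
      for (b in seq_len(cfg$depths[s])) {
        mods[[sprintf("stage%d_block%d", s, b)]] <- convnext_block(dims[s])
      }
      if (s < 4) {
        mods[[sprintf("ds%d_ln", s)]] <- layer_layernorm(dims[s])
        mods[[sprintf("ds%d_conv", s)]] <-
          layer_conv2d(dims[s], dims[s + 1], 2L, stride = 2L, pad = 0L)
      }
    }
    if (cfg$use_mtpf) {
      ct <- 2L + length(cfg$gabor$wavelengths) * length(cfg$gabor$orientations)
      mods$mtpf_compress <- layer_conv2d(ct, cfg$compress_channels, 3L,
                                         pad = 1L, init_sd = 0.05)
      mods$mtpf_proj <- layer_pointwise(cfg$compress_channels, dims[3],
                                        init_sd = 0.05)
      mods$mtpf_attn <- new_module("mtpf_attn", list(
        w_alpha = matrix(rnorm(dims[3]^2, sd = 0.05), dims[3], dims[3]),
        w_beta = matrix(rnorm(dims[3]^2, sd = 0.05), dims[3], dims[3])))
    }
    mods$head <- layer_linear(dims[4], cfg$num_classes)
    m$modules <- mods
  })
  m$dims <- dims
  m$bounds <- list(wl = cfg$window$wl_bounds, ww = cfg$window$ww_bounds)
  class(m) <- "kct_model"
  m
}

#' @export
print.kct_model <- function(x, ...) {
  cat(sprintf(
    "<kct_model> %d classes, depths [%s], dim %d, input %dx%d (ADWE: %s, MTPF: %s)\n",
    x$cfg$num_classes, paste(x$cfg$depths, collapse = ","), x$cfg$dim,
    x$cfg$input_size, x$cfg$input_size,
    ifelse(x$cfg$use_adwe, "on", "off"), ifelse(x$cfg$use_mtpf, "on", "off")))
  cat(sprintf("  trainable parameters: %s\n",
              format(count_params(x), big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters
#'
#' @param model A `kct_model`.
#' @return Integer parameter count.
#' @export
count_params <- function(model) {
  sum(vapply(flatten_modules(model$modules),
             function(m) sum(vapply(m$par, length, 1L)), 1L))
}

# Current learnable window parameters as a window_params object.
#' Extract the model's current window parameters
#'
#' @param model A `kct_model` built with ADWE enabled.
#' @return A [window_params()] object reflecting the learned values.
#' @export
model_window_params <- function(model) {
  if (is.null(model$modules$adwe_win)) stop_input("model was built without ADWE")
  p <- model$modules$adwe_win$par
  window_params(p$wl1, p$ww1, p$wl2, p$ww2, p$alpha,
                wl_bounds = model$bounds$wl, ww_bounds = model$bounds$ww)
}

# Batched texture prior stack for (1,H,W,N) enhanced images -> (Ct,H,W,N).
prior_stack_batch <- function(xs, cfg) {
  d <- dim(xs)
  H <- d[2]; W <- d[3]; N <- d[4]
  kernels <- list(LAPLACIAN_KERNEL)
  for (lambda in cfg$gabor$wavelengths) {
    for (theta in cfg$gabor$orientations) {
      kernels <- c(kernels, list(gabor_kernel(cfg$gabor, lambda, theta)))
    }
  }
  ct <- 1L + length(kernels)
  out <- array(0, c(ct, H, W, N))
  # channel 1: Laplacian edge; channel 2: scaled LBP; 3..: Gabor responses
  out[1, , , ] <- conv2d_fwd_cpp(xs, array(kernels[[1]], c(3, 3, 1, 1)),
                                 numeric(0), 1L, 1L, 1L, 1L)
  denom <- 2^cfg$lbp_p - 1
  for (n in seq_len(N)) {
    img <- matrix(xs[1, , , n], H, W)
    out[2, , , n] <- lbp_encode_cpp(img, as.integer(cfg$lbp_p),
                                    as.numeric(cfg$lbp_r)) / denom
  }
  for (i in seq_along(kernels)[-1]) {
    k <- kernels[[i]]
    out[1L + i, , , ] <- conv2d_fwd_cpp(
      xs, array(k, c(nrow(k), ncol(k), 1, 1)), numeric(0),
      1L, (nrow(k) - 1L) %/% 2L, 1L, 1L)
  }
  out
}

# Pyramid pooling on (C,H,W,N) with cached operator matrices.
pyramid_ops <- function(H, W, scales = c(1, 2, 4)) {
  ops <- lapply(scales, function(s) {
    list(MH = nearest_up_matrix(s, H) %*% adaptive_avg_matrix(H, s),
         MW = nearest_up_matrix(s, W) %*% adaptive_avg_matrix(W, s))
  })
  ops
}

pyramid_fwd_chwn <- function(x, ops) {
  acc <- 0
  for (op in ops) {
    acc <- acc + apply_matrix_dim(apply_matrix_dim(x, op$MH, 2L), op$MW, 3L)
  }
  acc
}

pyramid_bwd_chwn <- function(dy, ops) {
  acc <- 0
  for (op in ops) {
    acc <- acc + apply_matrix_dim(apply_matrix_dim(dy, t(op$MH), 2L), t(op$MW), 3L)
  }
  acc
}

# Broadcast a (C,N) matrix over spatial dims of a (C,H,W,N) array.
bcast_cn <- function(v, d) {
  aperm(array(v, c(d[1], d[4], d[2], d[3])), c(1L, 3L, 4L, 2L))
}

sum_hw_cn <- function(a) {
  d <- dim(a)
  matrix(colSums(matrix(aperm(a, c(2L, 3L, 1L, 4L)), d[2] * d[3])), d[1], d[4])
}

# Squared-MMD (RBF, biased V-statistic) with gradients w.r.t. both samples.
# a, b: numeric matrices n x d / m x d.
mmd_rbf_grad <- function(a, b) {
  n <- nrow(a); m <- nrow(b)
  x <- rbind(a, b)
  d2 <- pairwise_sqdist(x, x)
  dd <- sqrt(pmax(d2[upper.tri(d2)], 0))
  h <- median(dd)
  if (!is.finite(h) || h <= 0) h <- 1
  K <- exp(-d2 / (2 * h^2))
  ia <- seq_len(n); ib <- n + seq_len(m)
  val <- mean(K[ia, ia, drop = FALSE]) + mean(K[ib, ib, drop = FALSE]) -
    2 * mean(K[ia, ib, drop = FALSE])
  if (val <= 0) {
    return(list(value = 0, da = a * 0, db = b * 0))
  }
  # d/du exp(-||u-v||^2/(2h^2)) = K * (v - u) / h^2
  Kaa <- K[ia, ia, drop = FALSE]; Kbb <- K[ib, ib, drop = FALSE]
  Kab <- K[ia, ib, drop = FALSE]
  da <- (2 / n^2) * (Kaa %*% a - rowSums(Kaa) * a) / h^2 -
    (2 / (n * m)) * (Kab %*% b - rowSums(Kab) * a) / h^2
  db <- (2 / m^2) * (Kbb %*% b - rowSums(Kbb) * b) / h^2 -
    (2 / (n * m)) * (t(Kab) %*% a - colSums(Kab) * b) / h^2
  list(value = val, da = da, db = db)
}

#' Forward pass of the full pipeline
#'
#' Runs window views, gated fusion, multi-scale features, the backbone
#' stages, MTPF fusion and pyramid pooling, and the classification head.
#' Auxiliary losses are computed alongside. Deterministic in evaluation
#' mode; the MMD location subsample is drawn from `sample_seed` when
#' supplied (training passes a per-step seed).
#'
#' @param model A `kct_model`.
#' @param batch H x W x N array (or H x W matrix) of `[0,1]` intensities.
#' @param keep_intermediates If `TRUE`, the returned cache exposes X1, X2,
#'   the gate map Z, X*, the prior tensor T, compressed priors T', and the
#'   fused features F*.
#' @param sample_seed Seed for the MMD location subsample (`NULL` =
#'   deterministic first locations).
#' @return List with `logits` (K x N), `aux` (`hist`, `mmd`), and `cache`
#'   (pipeline intermediates, needed by [model_backward()]).
#' @export
forward_pipeline <- function(model, batch, keep_intermediates = FALSE,
                             sample_seed = NULL) {
  cfg <- model$cfg
  if (is.matrix(batch)) batch <- array(batch, c(dim(batch), 1L))
  d <- dim(batch)
  if (d[1] != cfg$input_size || d[2] != cfg$input_size) {
    stop_input("batch is %dx%d but the model expects %dx%d",
               d[1], d[2], cfg$input_size, cfg$input_size)
  }
  if (min(batch) < -1e-6 || max(batch) > 1 + 1e-6) {
    stop_input("batch intensities must be normalized to [0, 1]")
  }
  N <- d[3]
  x <- array(batch, c(1L, d[1], d[2], N))
  # silence R CMD check-style lints for locals assigned conditionally
  mods <- model$modules
  cache <- new.env(parent = emptyenv())
  cache$N <- N

  if (cfg$use_adwe) {
    p <- mods$adwe_win$par
    wt1 <- window_transform_grads(x, p$wl1, p$ww1, p$alpha)
    wt2 <- window_transform_grads(x, p$wl2, p$ww2, p$alpha)
    gw <- mods$adwe_gate$par
    pre <- gw$w[1] * wt1$y + gw$w[2] * wt2$y + gw$b
    z <- sigmoid(pre)
    xs <- z * wt1$y + (1 - z) * wt2$y
    f0 <- mods$ms3$fwd(xs) + mods$ms5$fwd(xs) + mods$ms7$fwd(xs)
    cache$wt1 <- wt1; cache$wt2 <- wt2; cache$z <- z; cache$xs <- xs
  } else {
    xs <- (tanh(2 * (x - 0.5)) + 1) / 2 # fixed single window
    f0 <- xs
    cache$xs <- xs
  }

  h <- mods$stem_ln$fwd(mods$stem_conv$fwd(f0))
  stage_out <- list()
  for (s in 1:4) {
    for (b in seq_len(cfg$depths[s])) {
      h <- mods[[sprintf("stage%d_block%d", s, b)]]$fwd(h)
    }
    stage_out[[s]] <- h
    if (s == 3 && cfg$use_mtpf) {
      f3 <- h
      dd <- dim(f3)
      tt <- prior_stack_batch(cache$xs, cfg)
      tpre <- mods$mtpf_compress$fwd(tt)
      tcomp <- gelu(tpre)
      cache$tpre <- tpre
      tr <- resize_bilinear_chwn(tcomp, dd[2], dd[3])
      tp <- mods$mtpf_proj$fwd(tr)
      gap_t <- gap_fwd(tp); gap_f <- gap_fwd(f3)
      aw <- mods$mtpf_attn$par
      alpha <- sigmoid(aw$w_alpha %*% gap_t)
      beta <- sigmoid(aw$w_beta %*% gap_f)
      fstar <- f3 * bcast_cn(alpha, dd) + tp * bcast_cn(beta, dd)
      pops <- pyramid_ops(dd[2], dd[3])
      h <- pyramid_fwd_chwn(fstar, pops)
      # MMD between per-location channel means of T' and X* intensities
      nloc <- dim(tcomp)[2] * dim(tcomp)[3] * N
      nsamp <- min(cfg$mmd_max_locations, nloc)
      locs <- if (is.null(sample_seed)) seq_len(nsamp) else {
        with_seed(sample_seed, sample.int(nloc, nsamp))
      }
      cc <- dim(tcomp)[1]
      tmat <- matrix(tcomp, cc) # C x (H*W*N)
      a <- matrix(colMeans(tmat[, locs, drop = FALSE]), ncol = 1)
      b <- matrix(as.numeric(cache$xs)[locs], ncol = 1)
      mmd <- mmd_rbf_grad(a, b)
      cache$tt <- tt; cache$tcomp <- tcomp; cache$tr <- tr; cache$tp <- tp
      cache$gap_t <- gap_t; cache$gap_f <- gap_f
      cache$alpha <- alpha; cache$beta <- beta
      cache$f3 <- f3; cache$fstar <- fstar; cache$pops <- pops
      cache$mmd <- mmd; cache$locs <- locs
    }
    if (s < 4) {
      h <- mods[[sprintf("ds%d_conv", s)]]$fwd(mods[[sprintf("ds%d_ln", s)]]$fwd(h))
    }
  }
  cache$stage_out <- stage_out
  g <- gap_fwd(h)
  cache$f4_dim <- dim(h)
  logits <- mods$head$fwd(g)

  hist_loss <- 0
  if (cfg$use_adwe) {
    hc <- cfg$hist
    vjps <- vector("list", N)
    for (n in seq_len(N)) {
      vs <- soft_histogram_vjp(cache$xs[1, , , n], hc$n_bins, hc$bandwidth)
      v1 <- soft_histogram_vjp(cache$wt1$y[1, , , n], hc$n_bins, hc$bandwidth)
      v2 <- soft_histogram_vjp(cache$wt2$y[1, , , n], hc$n_bins, hc$bandwidth)
      q <- hc$lambda1 * v1$p + hc$lambda2 * v2$p
      hist_loss <- hist_loss + sum((vs$p - q)^2)
      vjps[[n]] <- list(vs = vs, v1 = v1, v2 = v2, diff = vs$p - q)
    }
    hist_loss <- hist_loss / N
    cache$hist_vjps <- vjps
  }
  mmd_val <- if (cfg$use_mtpf) cache$mmd$value else 0

  out <- list(logits = logits,
              aux = list(hist = hist_loss, mmd = mmd_val),
              cache = cache)
  if (keep_intermediates) {
    out$intermediates <- list(
      x1 = if (cfg$use_adwe) cache$wt1$y else NULL,
      x2 = if (cfg$use_adwe) cache$wt2$y else NULL,
      gate = if (cfg$use_adwe) cache$z else NULL,
      xstar = cache$xs,
      priors = if (cfg$use_mtpf) cache$tt else NULL,
      compressed = if (cfg$use_mtpf) cache$tcomp else NULL,
      fused_features = if (cfg$use_mtpf) cache$fstar else NULL,
      stages = stage_out)
  }
  out
}

#' Backward pass of the full pipeline
#'
#' Backpropagates `dlogits` (plus the weighted auxiliary-loss gradients)
#' through the pipeline, accumulating parameter gradients in the model's
#' modules. Optionally records the gradient arriving at each backbone stage
#' output (used by Grad-CAM).
#'
#' @param model A `kct_model`.
#' @param fwd Result of [forward_pipeline()] on the same batch.
#' @param dlogits Gradient of the scalar loss w.r.t. the logits (K x N).
#' @param lambda_hist,lambda_mmd Weights applied to the auxiliary-loss
#'   gradients (default: the model configuration's weights).
#' @param record_stage_grads If `TRUE`, returns gradients at stage outputs.
#' @return Invisibly, a list with `stage_grads` when recorded.
#' @export
model_backward <- function(model, fwd, dlogits,
                           lambda_hist = model$cfg$lambda_hist,
                           lambda_mmd = model$cfg$lambda_mmd,
                           record_stage_grads = FALSE) {
  cfg <- model$cfg
  mods <- model$modules
  cache <- fwd$cache
  N <- cache$N
  stage_grads <- if (record_stage_grads) vector("list", 4L) else NULL

  dg <- mods$head$bwd(dlogits)
  dh <- gap_bwd(dg, cache$f4_dim)
  for (s in 4:1) {
    if (s < 4) {
      dh <- mods[[sprintf("ds%d_ln", s)]]$bwd(mods[[sprintf("ds%d_conv", s)]]$bwd(dh))
    }
    if (s == 3 && cfg$use_mtpf) {
      # dh is the gradient at the pyramid output
      dfstar <- pyramid_bwd_chwn(dh, cache$pops)
      dd <- dim(cache$f3)
      df3 <- dfstar * bcast_cn(cache$alpha, dd)
      dtp <- dfstar * bcast_cn(cache$beta, dd)
      dalpha <- sum_hw_cn(dfstar * cache$f3)
      dbeta <- sum_hw_cn(dfstar * cache$tp)
      aw <- mods$mtpf_attn$par
      dpre_a <- dalpha * cache$alpha * (1 - cache$alpha)
      dpre_b <- dbeta * cache$beta * (1 - cache$beta)
      mods$mtpf_attn$gr$w_alpha <- mods$mtpf_attn$gr$w_alpha +
        dpre_a %*% t(cache$gap_t)
      mods$mtpf_attn$gr$w_beta <- mods$mtpf_attn$gr$w_beta +
        dpre_b %*% t(cache$gap_f)
      dtp <- dtp + gap_bwd(crossprod(aw$w_alpha, dpre_a), dim(cache$tp))
      df3 <- df3 + gap_bwd(crossprod(aw$w_beta, dpre_b), dd)
      dtr <- mods$mtpf_proj$bwd(dtp)
      dtcomp <- resize_bilinear_chwn_adj(dtr, dim(cache$tcomp)[2],
                                         dim(cache$tcomp)[3])
      # MMD gradient into T' (channel-mean at sampled locations) and X*
      if (lambda_mmd > 0 && cache$mmd$value > 0) {
        cc <- dim(cache$tcomp)[1]
        dmat <- matrix(0, cc, length(cache$tcomp) / cc)
        dmat[, cache$locs] <- rep(lambda_mmd * cache$mmd$da / cc,
                                  each = cc)
        dtcomp <- dtcomp + array(dmat, dim(cache$tcomp))
        dxs_mmd <- numeric(length(cache$xs))
        dxs_mmd[cache$locs] <- lambda_mmd * cache$mmd$db
        cache$dxs_extra <- array(dxs_mmd, dim(cache$xs))
      }
      # GELU after the compression conv; the prior stack itself is a fixed
      # (non-differentiable) branch, so the input gradient is discarded
      mods$mtpf_compress$bwd(dtcomp * gelu_grad(cache$tpre))
      dh <- df3
    }
    if (record_stage_grads) stage_grads[[s]] <- dh
    for (b in rev(seq_len(cfg$depths[s]))) {
      dh <- mods[[sprintf("stage%d_block%d", s, b)]]$bwd(dh)
    }
  }
  df0 <- mods$stem_conv$bwd(mods$stem_ln$bwd(dh))

  if (cfg$use_adwe) {
    dxs <- mods$ms3$bwd(df0) + mods$ms5$bwd(df0) + mods$ms7$bwd(df0)
    dx1 <- array(0, dim(dxs)); dx2 <- array(0, dim(dxs))
    if (!is.null(cache$dxs_extra)) dxs <- dxs + cache$dxs_extra
    if (lambda_hist > 0) {
      for (n in seq_len(N)) {
        v <- cache$hist_vjps[[n]]
        dp <- 2 * v$diff * lambda_hist / N
        dxs[1, , , n] <- dxs[1, , , n] + v$vs$vjp(dp)
        dx1[1, , , n] <- dx1[1, , , n] +
          v$v1$vjp(-dp * model$cfg$hist$lambda1)
        dx2[1, , , n] <- dx2[1, , , n] +
          v$v2$vjp(-dp * model$cfg$hist$lambda2)
      }
    }
    # gate
    z <- cache$z
    x1 <- cache$wt1$y; x2 <- cache$wt2$y
    dz <- dxs * (x1 - x2)
    dpre <- dz * z * (1 - z)
    gw <- mods$adwe_gate$par
    mods$adwe_gate$gr$w <- mods$adwe_gate$gr$w +
      c(sum(dpre * x1), sum(dpre * x2))
    mods$adwe_gate$gr$b <- mods$adwe_gate$gr$b + sum(dpre)
    dx1 <- dx1 + dxs * z + dpre * gw$w[1]
    dx2 <- dx2 + dxs * (1 - z) + dpre * gw$w[2]
    # window transforms
    wt1 <- cache$wt1; wt2 <- cache$wt2
    gw2 <- mods$adwe_win$gr
    gw2$wl1 <- gw2$wl1 + sum(dx1 * wt1$dwl)
    gw2$ww1 <- gw2$ww1 + sum(dx1 * wt1$dww)
    gw2$wl2 <- gw2$wl2 + sum(dx2 * wt2$dwl)
    gw2$ww2 <- gw2$ww2 + sum(dx2 * wt2$dww)
    gw2$alpha <- gw2$alpha + sum(dx1 * wt1$dalpha) + sum(dx2 * wt2$dalpha)
    mods$adwe_win$gr <- gw2
  }
  invisible(list(stage_grads = stage_grads))
}

#' Composite training loss
#'
#' `cross-entropy + lambda_hist * hist + lambda_mmd * mmd`.
#'
#' @param logits K x N logit matrix.
#' @param labels Integer class labels in `1..K`.
#' @param aux List with elements `hist` and `mmd` (both >= 0).
#' @param weights Numeric `c(lambda_hist, lambda_mmd)`, nonnegative.
#' @return List with `total`, `ce`, and the weighted aux terms.
#' @export
total_loss <- function(logits, labels, aux = list(hist = 0, mmd = 0),
                       weights = c(0.1, 0.01)) {
  if (any(weights < 0)) stop_input("loss weights must be nonnegative")
  ce <- cross_entropy(logits, labels)
  list(total = ce$loss + weights[1] * aux$hist + weights[2] * aux$mmd,
       ce = ce$loss, hist = weights[1] * aux$hist, mmd = weights[2] * aux$mmd,
       dlogits = ce$dlogits)
}

snapshot_params <- function(model) {
  lapply(flatten_modules(model$modules), function(m) m$par)
}

restore_params <- function(model, snap) {
  mods <- flatten_modules(model$modules)
  for (i in seq_along(mods)) mods[[i]]$par <- snap[[i]]
  invisible(model)
}

project_model_windows <- function(model) {
  w <- model$modules$adwe_win
  if (is.null(w)) return(invisible(model))
  b <- model$bounds
  w$par$wl1 <- min(max(w$par$wl1, b$wl[1]), b$wl[2])
  w$par$wl2 <- min(max(w$par$wl2, b$wl[1]), b$wl[2])
  w$par$ww1 <- min(max(w$par$ww1, b$ww[1]), b$ww[2])
  w$par$ww2 <- min(max(w$par$ww2, b$ww[1]), b$ww[2])
  invisible(model)
}

#' Train the classifier
#'
#' AdamW with a per-epoch cosine-annealed learning rate; the window
#' parameters are projected back into their bounds after every optimizer
#' step. Keeps the parameter snapshot with the best validation accuracy.
#' Fully reproducible under `cfg$seed`.
#'
#' @param model A `kct_model` from [build_classifier()].
#' @param data List with `images` (H x W x n array), `labels` (factor or
#'   integer), and optionally `split` (factor with levels train/val/test);
#'   without a split, all samples train and validation reuses the training
#'   set. [generate_dataset()] returns this shape.
#' @param cfg A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return An object of class `kct_fit`: the trained model, a per-epoch
#'   `history` tibble, and the best-validation checkpoint (already restored
#'   into the model).
#' @export
train_classifier <- function(model, data, cfg = train_config(),
                             verbose = FALSE) {
  stopifnot(inherits(model, "kct_model"), inherits(cfg, "train_config"))
  labels <- as.integer(as.factor(data$labels))
  n <- length(labels)
  if (n == 0) stop_input("dataset is empty")
  if (max(labels) > model$cfg$num_classes) {
    stop_input("data has %d classes but the model expects %d",
               max(labels), model$cfg$num_classes)
  }
  split <- data$split %||% factor(rep("train", n), levels = c("train", "val", "test"))
  idx_train <- which(split == "train")
  idx_val <- which(split == "val")
  if (length(idx_val) == 0) idx_val <- idx_train
  if (length(idx_train) == 0) stop_input("training split is empty")

  flat <- flatten_modules(model$modules)
  opt <- adamw_new(flat, lr = cfg$lr, weight_decay = cfg$weight_decay)
  history <- vector("list", cfg$epochs)
  best <- list(acc = -Inf, snap = snapshot_params(model), epoch = 0L)

  step <- 0L
  wu <- cfg$warmup_epochs %||% 0L
  for (epoch in seq_len(cfg$epochs)) {
    lr <- if (epoch <= wu) {
      cfg$lr * epoch / (wu + 1)
    } else {
      cosine_lr(epoch - wu, cfg$epochs - wu, cfg$lr)
    }
    ord <- with_seed(derive_seed(cfg$seed, "train", epoch), sample(idx_train))
    ep_loss <- 0; ep_ce <- 0; ep_hist <- 0; ep_mmd <- 0; ep_n <- 0
    ep_correct <- 0
    for (start in seq(1, length(ord), by = cfg$batch_size)) {
      ids <- ord[start:min(start + cfg$batch_size - 1, length(ord))]
      imgs <- data$images[, , ids, drop = FALSE]
      if (!is.null(cfg$augment)) {
        for (j in seq_along(ids)) {
          imgs[, , j] <- augment(imgs[, , j], cfg$augment,
                                 derive_seed(cfg$seed, "augment",
                                             epoch * 100003L + ids[j]))
        }
      }
      step <- step + 1L
      fwd <- forward_pipeline(model, imgs,
                              sample_seed = derive_seed(cfg$seed, "train",
                                                        1000000L + step))
      tl <- total_loss(fwd$logits, labels[ids], fwd$aux,
                       c(model$cfg$lambda_hist, model$cfg$lambda_mmd))
      if (!is.finite(tl$total)) {
        stop_input("training diverged at epoch %d (loss=%g, ce=%g)",
                   epoch, tl$total, tl$ce)
      }
      module_list_zero(flat)
      model_backward(model, fwd, tl$dlogits)
      opt <- adamw_step(opt, lr)
      project_model_windows(model)
      nb <- length(ids)
      ep_loss <- ep_loss + tl$total * nb
      ep_ce <- ep_ce + tl$ce * nb
      ep_hist <- ep_hist + tl$hist * nb
      ep_mmd <- ep_mmd + tl$mmd * nb
      ep_correct <- ep_correct + sum(apply(fwd$logits, 2, which.max) == labels[ids])
      ep_n <- ep_n + nb
    }
    val_probs <- predict_classifier(model, data$images[, , idx_val, drop = FALSE],
                                    batch_size = cfg$batch_size)
    val_pred <- max.col(val_probs)
    val_acc <- mean(val_pred == labels[idx_val])
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, lr = lr, loss = ep_loss / ep_n, ce = ep_ce / ep_n,
      hist_loss = ep_hist / ep_n, mmd_loss = ep_mmd / ep_n,
      train_acc = ep_correct / ep_n, val_acc = val_acc)
    if (val_acc >= best$acc) { # ties prefer the later (better-trained) epoch
      best <- list(acc = val_acc, snap = snapshot_params(model), epoch = epoch)
    }
    if (verbose) {
      message(sprintf(
        "epoch %3d  lr %.2e  loss %.4f  train_acc %.3f  val_acc %.3f",
        epoch, lr, ep_loss / ep_n, ep_correct / ep_n, val_acc))
    }
  }
  restore_params(model, best$snap)
  structure(list(model = model, history = do.call(rbind, history),
                 best_epoch = best$epoch, best_val_acc = best$acc,
                 train_cfg = cfg),
            class = "kct_fit")
}

#' @export
print.kct_fit <- function(x, ...) {
  cat(sprintf("<kct_fit> %d epochs; best val accuracy %.4f at epoch %d\n",
              nrow(x$history), x$best_val_acc, x$best_epoch))
  invisible(x)
}

#' Predict class probabilities
#'
#' @param model A trained `kct_model`.
#' @param images H x W x n array (or single H x W matrix) in `[0, 1]`.
#' @param batch_size Forward-pass batch size.
#' @return n x K matrix of class probabilities.
#' @export
predict_classifier <- function(model, images, batch_size = 32) {
  if (is.matrix(images)) images <- array(images, c(dim(images), 1L))
  n <- dim(images)[3]
  out <- matrix(0, n, model$cfg$num_classes)
  for (start in seq(1, n, by = batch_size)) {
    ids <- start:min(start + batch_size - 1, n)
    fwd <- forward_pipeline(model, images[, , ids, drop = FALSE])
    out[ids, ] <- t(softmax_cols(fwd$logits))
  }
  out
}
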