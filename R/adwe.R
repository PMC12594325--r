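# Adaptive dual-window enhancement (ADWE).
#
# CT windowing is usually a fixed affine clip on Hounsfield units; here it is
# a smooth, learnable transform f(x) = (tanh(alpha * (x - wl) / ww) + 1) / 2
# so that window level (wl), window width (ww) and sharpness (alpha) can be
# optimised by gradient descent. Two windows run in parallel — a soft-tissue
# ("parenchymal") window and a high-density window — and a per-pixel sigmoid
# gate blends them. Intensities are on the normalized [0,1] scale (8-bit
# sources divided by 255), not raw HU.

#' Learnable dual-window parameters
#'
#' Container for the two (window level, window width) pairs, the shared
#' sharpness scale, and the box constraints used by
#' [project_window_params()]. Defaults place window 1 over the soft-tissue
#' (parenchymal) range and window 2 over the hyperdense range of a
#' `[0,1]`-normalized CT slice.
#'
#' @param wl1,ww1 Level and width of the parenchymal window.
#' @param wl2,ww2 Level and width of the high-density window.
#' @param alpha Sharpness of the tanh mapping (shared by both windows);
#'   larger values approach a hard intensity clip.
#' @param wl_bounds,ww_bounds Closed intervals `c(lo, hi)` that the levels
#'   and widths are projected into after each optimiser step.
#' @return An object of class `window_params`.
#' @examples
#' p <- window_params()
#' project_window_params(p)
#' @export
window_params <- function(wl1 = 0.25, ww1 = 0.50, wl2 = 0.75, ww2 = 0.35,
                          alpha = 2.0,
                          wl_bounds = c(0.05, 0.95),
                          ww_bounds = c(0.05, 1.50)) {
  if (length(wl_bounds) != 2 || wl_bounds[2] <= wl_bounds[1]) {
    stop_input("wl_bounds must be an interval c(a, b) with b > a")
  }
  if (length(ww_bounds) != 2 || ww_bounds[2] <= ww_bounds[1] || ww_bounds[1] <= 0) {
    stop_input("ww_bounds must be an interval c(c, d) with d > c > 0")
  }
  if (ww1 <= 0 || ww2 <= 0) stop_input("window widths must be strictly positive")
  if (alpha <= 0) stop_input("alpha must be strictly positive")
  structure(
    list(wl1 = wl1, ww1 = ww1, wl2 = wl2, ww2 = ww2, alpha = alpha,
         wl_bounds = wl_bounds, ww_bounds = ww_bounds),
    class = "window_params"
  )
}

#' @export
print.window_params <- function(x, ...) {
  cat(sprintf(
    "<window_params> wl1=%.3f ww1=%.3f | wl2=%.3f ww2=%.3f | alpha=%.3f\n",
    x$wl1, x$ww1, x$wl2, x$ww2, x$alpha))
  cat(sprintf("  wl in [%.2f, %.2f], ww in [%.2f, %.2f]\n",
              x$wl_bounds[1], x$wl_bounds[2], x$ww_bounds[1], x$ww_bounds[2]))
  invisible(x)
}

#' Differentiable window transform
#'
#' Smooth windowing `f(x) = (tanh(alpha * (x - wl) / ww) + 1) / 2`. The
#' output lies strictly in (0, 1), is strictly increasing in `x`, and equals
#' exactly 0.5 at `x = wl`.
#'
#' @param image Numeric vector, matrix or array of finite intensities.
#' @param wl,ww Window level and width (`ww > 0`).
#' @param alpha Sharpness scale (`alpha > 0`).
#' @return Transformed intensities with the same shape as `image`.
#' @examples
#' window_transform(c(0.2, 0.25, 0.3), wl = 0.25, ww = 0.5, alpha = 2)
#' @export
window_transform <- function(image, wl, ww, alpha) {
  if (!is.numeric(ww) || ww <= 0) stop_input("ww must be strictly positive")
  if (!is.numeric(alpha) || alpha <= 0) stop_input("alpha must be strictly positive")
  check_image(image)
  (tanh(alpha * (image - wl) / ww) + 1) / 2
}

# Forward + local partials of the window transform, for backprop.
window_transform_grads <- function(image, wl, ww, alpha) {
  u <- alpha * (image - wl) / ww
  th <- tanh(u)
  sech2 <- 1 - th^2
  list(
    y = (th + 1) / 2,
    dx = sech2 * alpha / (2 * ww),
    dwl = -sech2 * alpha / (2 * ww),
    dww = -sech2 * u / (2 * ww),
    dalpha = sech2 * (image - wl) / (2 * ww)
  )
}

#' Project window parameters onto their feasible box
#'
#' Clips each window level into `wl_bounds` and each width into `ww_bounds`.
#' Applied after every optimiser step during training so learned windows stay
#' physically reasonable. Idempotent.
#'
#' @param params A [window_params()] object.
#' @return The projected `window_params`.
#' @export
project_window_params <- function(params) {
  stopifnot(inherits(params, "window_params"))
  a <- params$wl_bounds[1]; b <- params$wl_bounds[2]
  cc <- params$ww_bounds[1]; d <- params$ww_bounds[2]
  params$wl1 <- min(max(params$wl1, a), b)
  params$wl2 <- min(max(params$wl2, a), b)
  params$ww1 <- min(max(params$ww1, cc), d)
  params$ww2 <- min(max(params$ww2, cc), d)
  params
}

#' Generate the dual window views
#'
#' Applies the two learned windows to the same image, producing the
#' parenchymal view `x1` and the high-density view `x2`.
#'
#' @param image Numeric matrix (H x W) of `[0,1]` intensities.
#' @param params A [window_params()] object (already projected).
#' @return An object of class `view_pair`: list with elements `x1`, `x2`.
#' @export
dual_window_views <- function(image, params) {
  stopifnot(inherits(params, "window_params"))
  structure(
    list(x1 = window_transform(image, params$wl1, params$ww1, params$alpha),
         x2 = window_transform(image, params$wl2, params$ww2, params$alpha)),
    class = "view_pair"
  )
}

#' Fusion gate parameters
#'
#' The gate is a 1x1 convolution over the channel-concatenated views followed
#' by a sigmoid: `Z = sigmoid(w[1]*x1 + w[2]*x2 + b)` per pixel.
#'
#' @param weight Numeric length-2 vector of gate weights.
#' @param bias Scalar gate bias.
#' @return An object of class `fusion_gate`.
#' @export
fusion_gate <- function(weight = c(0, 0), bias = 0) {
  stopifnot(length(weight) == 2, length(bias) == 1)
  structure(list(weight = as.numeric(weight), bias = as.numeric(bias)),
            class = "fusion_gate")
}

#' Gated fusion of the two window views
#'
#' Computes the per-pixel gate `Z` and the convex combination
#' `X* = Z * x1 + (1 - Z) * x2`, so every fused pixel lies between the two
#' views at that pixel.
#'
#' @param views A `view_pair` from [dual_window_views()].
#' @param gate A [fusion_gate()].
#' @return List with `fused` (the enhanced image X*) and `gate_map` (Z).
#' @export
gated_fusion <- function(views, gate = fusion_gate()) {
  stopifnot(inherits(views, "view_pair"), inherits(gate, "fusion_gate"))
  if (!identical(dim(views$x1), dim(views$x2)) ||
      length(views$x1) != length(views$x2)) {
    stop_input("view pair is not spatially aligned")
  }
  z <- sigmoid(gate$weight[1] * views$x1 + gate$weight[2] * views$x2 + gate$bias)
  list(fused = z * views$x1 + (1 - z) * views$x2, gate_map = z)
}

#' Multi-scale convolution parameters
#'
#' One bias-free kernel bank per receptive field k in \{3, 5, 7\}, mapping a
#' single-channel enhanced image to `out_channels` feature maps. The three
#' branches use same-padding so their outputs sum elementwise.
#'
#' @param out_channels Number of output feature channels.
#' @param in_channels Number of input channels (1 for the fused image).
#' @param init_sd Standard deviation of the normal initialiser.
#' @param seed Seed for the initialisation.
#' @return An object of class `multiscale_params` with element `kernels`,
#'   a named list of (k, k, in, out) arrays for k = 3, 5, 7.
#' @export
multiscale_params <- function(out_channels = 32, in_channels = 1,
                              init_sd = 0.05, seed = 1) {
  kernels <- with_seed(seed, {
    ks <- lapply(c(3L, 5L, 7L), function(k) {
      array(rnorm(k * k * in_channels * out_channels, sd = init_sd),
            c(k, k, in_channels, out_channels))
    })
    names(ks) <- c("k3", "k5", "k7")
    ks
  })
  structure(list(kernels = kernels, out_channels = out_channels,
                 in_channels = in_channels), class = "multiscale_params")
}

#' Multi-scale feature extraction
#'
#' `F = sum_k (W_k * X*)` over kernel sizes 3, 5 and 7 with zero same-padding
#' (cross-correlation, bias-free), capturing local detail and broader
#' structure simultaneously. Linear in the input.
#'
#' @param fused Numeric matrix (H x W), typically the gated-fusion output.
#' @param params A [multiscale_params()] object.
#' @return An H x W x out_channels array.
#' @export
multiscale_features <- function(fused, params) {
  stopifnot(inherits(params, "multiscale_params"))
  check_image(fused, "fused")
  x <- as_chwn(fused)
  if (dim(x)[1] != params$in_channels) {
    stop_input("input has %d channels but params expect %d",
               dim(x)[1], params$in_channels)
  }
  acc <- NULL
  for (k in c(3L, 5L, 7L)) {
    w <- params$kernels[[paste0("k", k)]]
    y <- conv2d_fwd_cpp(x, w, numeric(0), 1L, (k - 1L) %/% 2L, 0L, 1L)
    acc <- if (is.null(acc)) y else acc + y
  }
  from_chwn(acc)
}

#' Histogram-matching constraint configuration
#'
#' @param lambda1,lambda2 Nonnegative mixture weights, summing to 1.
#' @param n_bins Number of histogram bins over (0, 1).
#' @param bandwidth Width of the triangular soft-binning kernel; defaults to
#'   the bin width.
#' @return An object of class `histogram_config`.
#' @export
histogram_config <- function(lambda1 = 0.5, lambda2 = 0.5, n_bins = 64,
                             bandwidth = 1 / n_bins) {
  if (abs(lambda1 + lambda2 - 1) > 1e-6 || lambda1 < 0 || lambda2 < 0) {
    stop_input("lambda1 and lambda2 must be nonnegative and sum to 1")
  }
  if (n_bins < 2) stop_input("n_bins must be at least 2")
  if (bandwidth <= 0) stop_input("bandwidth must be positive")
  structure(list(lambda1 = lambda1, lambda2 = lambda2, n_bins = n_bins,
                 bandwidth = bandwidth), class = "histogram_config")
}

#' Soft (differentiable) histogram
#'
#' Triangular-kernel binning over (0, 1): bin j with centre c_j receives
#' weight `max(0, 1 - |x - c_j| / bandwidth)` from each pixel; the histogram
#' is normalized to sum to 1.
#'
#' @param x Numeric values (any shape) in `[0, 1]`.
#' @param n_bins Number of bins.
#' @param bandwidth Kernel width.
#' @return Numeric vector of length `n_bins` summing to 1.
#' @export
soft_histogram <- function(x, n_bins = 64, bandwidth = 1 / n_bins) {
  centers <- (seq_len(n_bins) - 0.5) / n_bins
  w <- pmax(1 - abs(outer(as.numeric(x), centers, "-")) / bandwidth, 0)
  h <- colSums(w)
  s <- sum(h)
  if (s <= 0) return(rep(1 / n_bins, n_bins))
  h / s
}

#' Histogram-matching loss
#'
#' Squared L2 distance between the soft histogram of the fused image and the
#' lambda-weighted mixture of the two views' histograms. Zero iff the two
#' normalized histograms coincide; used as an auxiliary training loss so the
#' fused representation preserves the gray-level statistics of both windows.
#'
#' @param fused Fused image X*.
#' @param views The `view_pair` the fusion was computed from.
#' @param cfg A [histogram_config()].
#' @return Nonnegative scalar.
#' @export
histogram_match_loss <- function(fused, views, cfg = histogram_config()) {
  stopifnot(inherits(views, "view_pair"), inherits(cfg, "histogram_config"))
  p <- soft_histogram(fused, cfg$n_bins, cfg$bandwidth)
  q <- cfg$lambda1 * soft_histogram(views$x1, cfg$n_bins, cfg$bandwidth) +
    cfg$lambda2 * soft_histogram(views$x2, cfg$n_bins, cfg$bandwidth)
  sum((p - q)^2)
}

# Soft histogram with gradient plumbing: returns the normalized histogram and
# a closure mapping d(loss)/d(histogram) to d(loss)/d(x).
soft_histogram_vjp <- function(x, n_bins, bandwidth) {
  centers <- (seq_len(n_bins) - 0.5) / n_bins
  xv <- as.numeric(x)
  diff <- outer(xv, centers, "-")
  w <- pmax(1 - abs(diff) / bandwidth, 0)
  h <- colSums(w)
  s <- sum(h)
  p <- h / s
  dw <- -sign(diff) / bandwidth * (w > 0) # d w_ij / d x_i
  list(p = p, vjp = function(dp) {
    # p = h / s, s = sum(h): d p_j / d h_k = (delta_jk - p_j) / s
    dh <- (dp - sum(dp * p)) / s
    as.numeric(dw %*% dh)
  })
}
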