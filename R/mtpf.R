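# Multi-scale texture prior fusion (MTPF).
#
# Three classic texture descriptors are computed on the enhanced image and
# injected into the backbone: a Laplacian edge map (lesion boundaries), local
# binary pattern codes (homogeneous cyst texture vs irregular tumor texture),
# and a bank of even-symmetric Gabor responses (high-frequency stone detail
# vs low-frequency soft tissue). The stack is compressed by a small learnable
# convolution, fused with backbone features through channel attention, and
# pyramid-pooled. A maximum-mean-discrepancy constraint keeps the compressed
# priors statistically aligned with the enhanced image.

LAPLACIAN_KERNEL <- matrix(c(0, -1, 0, -1, 4, -1, 0, -1, 0), 3, 3)

# Convolve a single-channel matrix with a fixed kernel, replicate padding.
conv_replicate <- function(image, kernel) {
  k <- nrow(kernel)
  x <- as_chwn(image)
  w <- array(kernel, c(k, k, 1L, 1L))
  from_chwn(conv2d_fwd_cpp(x, w, numeric(0), 1L, (k - 1L) %/% 2L, 1L, 1L))
}

#' Laplacian edge map
#'
#' Convolution (cross-correlation; the kernel is symmetric) with the 3x3
#' Laplacian kernel — centre 4, four-neighbours -1, corners 0 — using
#' replicate padding. Constant regions map to exactly zero.
#'
#' @param image Single-channel numeric matrix, at least 3x3.
#' @return Edge-response matrix of the same size.
#' @export
laplacian_edge <- function(image) {
  check_image(image)
  if (!is.matrix(image) || nrow(image) < 3 || ncol(image) < 3) {
    stop_input("image must be a matrix of at least 3x3")
  }
  conv_replicate(image, LAPLACIAN_KERNEL)
}

#' Local binary pattern codes
#'
#' Per-pixel code `sum_k s(I_k - I_p) * 2^k` over `P` neighbours on a circle
#' of radius `R`, with `s(z) = 1` for `z >= 0` (ties count as 1). Neighbour
#' `k = 0` sits at angle 0 (east) and angles increase counter-clockwise;
#' off-grid positions are sampled with bilinear interpolation and borders
#' replicate. Codes lie in `[0, 2^P - 1]`.
#'
#' @param image Single-channel numeric matrix larger than `2R + 1` per side.
#' @param P Number of sampled neighbours (4..24).
#' @param R Circle radius in pixels.
#' @param scale If `TRUE`, divide codes by `2^P - 1` so they lie in `[0, 1]`.
#' @return Matrix of LBP codes.
#' @export
lbp_encode <- function(image, P = 8, R = 1, scale = FALSE) {
  check_image(image)
  if (P < 4) stop_input("P must be at least 4")
  if (P > 24) stop_input("P > 24 would overflow the integer code range")
  if (R < 1) stop_input("R must be at least 1")
  if (!is.matrix(image) || min(dim(image)) <= 2 * R + 1) {
    stop_input("image must be larger than 2R + 1 per side")
  }
  codes <- lbp_encode_cpp(image, as.integer(P), as.numeric(R))
  if (scale) codes / (2^P - 1) else codes
}

#' Gabor bank configuration
#'
#' Even-symmetric (cosine-phase) Gabor bank: S wavelengths x O orientations.
#' The Gaussian envelope scale defaults to `0.56 * lambda` (roughly one
#' octave bandwidth).
#'
#' @param wavelengths Wavelengths lambda in pixels.
#' @param orientations Orientations theta in radians, in `[0, pi)`.
#' @param phase Phase offset phi.
#' @param sigma Envelope scale in pixels, or `NULL` for `0.56 * lambda`.
#' @param gamma Spatial aspect ratio.
#' @param size Odd kernel size in pixels.
#' @return An object of class `gabor_config`.
#' @export
gabor_config <- function(wavelengths = c(4, 8),
                         orientations = c(0, pi / 4, pi / 2, 3 * pi / 4),
                         phase = 0, sigma = NULL, gamma = 0.5, size = 15) {
  if (size %% 2 == 0) stop_input("Gabor kernel size must be odd")
  if (length(wavelengths) == 0 || length(orientations) == 0) {
    stop_input("Gabor bank must contain at least one wavelength and orientation")
  }
  if (any(wavelengths <= 0)) stop_input("wavelengths must be positive")
  if (!is.null(sigma) && any(sigma <= 0)) stop_input("sigma must be positive")
  if (any(orientations < 0 | orientations >= pi)) {
    stop_input("orientations must lie in [0, pi)")
  }
  structure(list(wavelengths = wavelengths, orientations = orientations,
                 phase = phase, sigma = sigma, gamma = gamma, size = size),
            class = "gabor_config")
}

#' Single Gabor kernel
#'
#' `G(x, y) = exp(-(x'^2 + gamma^2 y'^2) / (2 sigma^2)) * cos(2 pi x' / lambda + phi)`
#' with `x' = x cos(theta) + y sin(theta)`, `y' = -x sin(theta) + y cos(theta)`,
#' evaluated on the integer grid centred at the origin (x horizontal,
#' y vertical).
#'
#' @param cfg A [gabor_config()] (supplies phase, gamma, size and the sigma
#'   rule).
#' @param lambda Wavelength in pixels.
#' @param theta Orientation in radians.
#' @return A `size` x `size` numeric matrix (rows = y, columns = x).
#' @export
gabor_kernel <- function(cfg, lambda, theta) {
  stopifnot(inherits(cfg, "gabor_config"))
  if (lambda <= 0) stop_input("lambda must be positive")
  sigma <- cfg$sigma %||% (0.56 * lambda)
  half <- (cfg$size - 1) / 2
  xs <- matrix(rep(-half:half, each = cfg$size), cfg$size, cfg$size)
  ys <- matrix(rep(-half:half, times = cfg$size), cfg$size, cfg$size)
  xp <- xs * cos(theta) + ys * sin(theta)
  yp <- -xs * sin(theta) + ys * cos(theta)
  exp(-(xp^2 + cfg$gamma^2 * yp^2) / (2 * sigma^2)) *
    cos(2 * pi * xp / lambda + cfg$phase)
}

#' Gabor bank responses
#'
#' One same-size convolution response per (wavelength, orientation) pair,
#' replicate padding, wavelength-major channel order.
#'
#' @param image Single-channel numeric matrix.
#' @param cfg A [gabor_config()].
#' @return H x W x (S*O) array; `dimnames[[3]]` labels each channel.
#' @export
gabor_bank_responses <- function(image, cfg = gabor_config()) {
  stopifnot(inherits(cfg, "gabor_config"))
  check_image(image)
  S <- length(cfg$wavelengths); O <- length(cfg$orientations)
  out <- array(0, c(dim(image), S * O))
  labs <- character(S * O)
  ch <- 1L
  for (lambda in cfg$wavelengths) {
    for (theta in cfg$orientations) {
      out[, , ch] <- conv_replicate(image, gabor_kernel(cfg, lambda, theta))
      labs[ch] <- sprintf("gabor_l%g_t%.2f", lambda, theta)
      ch <- ch + 1L
    }
  }
  dimnames(out) <- list(NULL, NULL, labs)
  out
}

#' Build the texture prior stack
#'
#' Concatenates, in this fixed channel order: (1) the Laplacian edge map,
#' (2) the LBP code map scaled to `[0, 1]`, and (3) the Gabor responses in
#' wavelength-major order. Channel count is `2 + S*O`.
#'
#' @param image Single-channel numeric matrix (typically the ADWE-fused X*).
#' @param P,R LBP neighbour count and radius.
#' @param cfg A [gabor_config()].
#' @return An H x W x (2 + S*O) array of class `prior_stack` with channel
#'   labels in `dimnames[[3]]`.
#' @export
build_prior_stack <- function(image, P = 8, R = 1, cfg = gabor_config()) {
  gab <- gabor_bank_responses(image, cfg)
  out <- array(0, c(dim(image), 2L + dim(gab)[3]))
  out[, , 1] <- laplacian_edge(image)
  out[, , 2] <- lbp_encode(image, P, R, scale = TRUE)
  out[, , 3:dim(out)[3]] <- gab
  dimnames(out) <- list(NULL, NULL, c("edge", "lbp", dimnames(gab)[[3]]))
  class(out) <- c("prior_stack", class(out))
  out
}

#' Compression parameters for the prior stack
#'
#' A 3x3 convolution (with bias) followed by GELU, reducing the texture
#' channels to a compact representation.
#'
#' @param in_channels Number of prior channels (2 + S*O).
#' @param out_channels Compressed channel count.
#' @param init_sd Initialiser standard deviation.
#' @param seed Initialisation seed.
#' @return An object of class `compress_params` with `weight`
#'   (3, 3, in, out) and `bias` (out).
#' @export
compress_params <- function(in_channels = 10, out_channels = 16,
                            init_sd = 0.05, seed = 1) {
  w <- with_seed(seed, array(rnorm(9 * in_channels * out_channels, sd = init_sd),
                             c(3L, 3L, in_channels, out_channels)))
  structure(list(weight = w, bias = numeric(out_channels)),
            class = "compress_params")
}

#' Compress the texture prior stack
#'
#' `T' = GELU(W_t * T + b_t)` with a 3x3 zero-padded convolution.
#'
#' @param stack H x W x C_t prior stack from [build_prior_stack()].
#' @param params A [compress_params()] object.
#' @return H x W x out_channels array.
#' @export
compress_priors <- function(stack, params) {
  stopifnot(inherits(params, "compress_params"))
  d <- dim(stack)
  if (d[3] != dim(params$weight)[3]) {
    stop_input("stack has %d channels but params expect %d",
               d[3], dim(params$weight)[3])
  }
  x <- as_chwn(unclass(stack))
  y <- conv2d_fwd_cpp(x, params$weight, params$bias, 1L, 1L, 0L, 1L)
  from_chwn(gelu(y))
}

#' Channel-attention fusion parameters
#'
#' @param channels Backbone feature channel count C_f.
#' @param prior_channels Compressed prior channel count.
#' @param init_sd Initialiser standard deviation for the gate weights.
#' @param seed Initialisation seed.
#' @return An object of class `attention_params` with square gate matrices
#'   `w_alpha`, `w_beta` (C_f x C_f) and a 1x1 projection
#'   (`proj_weight` C_f x prior_channels, `proj_bias` C_f).
#' @export
attention_params <- function(channels, prior_channels,
                             init_sd = 0.05, seed = 1) {
  with_seed(seed, {
    structure(list(
      w_alpha = matrix(rnorm(channels^2, sd = init_sd), channels, channels),
      w_beta = matrix(rnorm(channels^2, sd = init_sd), channels, channels),
      proj_weight = matrix(rnorm(channels * prior_channels, sd = init_sd),
                           channels, prior_channels),
      proj_bias = numeric(channels)
    ), class = "attention_params")
  })
}

#' Attention-gated fusion of priors into backbone features
#'
#' The compressed priors are bilinearly resized to the backbone feature's
#' spatial grid and linearly projected to its channel count, then fused by
#' channel gates: `alpha = sigmoid(W_alpha GAP(T'))`,
#' `beta = sigmoid(W_beta GAP(F))`, `F* = alpha (.) F + beta (.) T'` with
#' per-channel broadcasting.
#'
#' @param features H' x W' x C_f backbone feature array.
#' @param priors H x W x C_p compressed prior array.
#' @param params An [attention_params()] object.
#' @return List with `fused` (H' x W' x C_f), `alpha`, `beta`.
#' @export
attention_fuse <- function(features, priors, params) {
  stopifnot(inherits(params, "attention_params"))
  df <- dim(features)
  if (df[3] != nrow(params$w_alpha)) {
    stop_input("feature channels (%d) do not match attention params (%d)",
               df[3], nrow(params$w_alpha))
  }
  tp <- as_chwn(priors)
  tp <- resize_bilinear_chwn(tp, df[1], df[2])
  # 1x1 projection to C_f channels
  tm <- params$proj_weight %*% matrix(tp, dim(tp)[1]) + params$proj_bias
  tproj <- from_chwn(array(tm, c(df[3], df[1], df[2], 1L)))
  gap_t <- apply(tproj, 3, mean)
  gap_f <- apply(features, 3, mean)
  alpha <- sigmoid(as.numeric(params$w_alpha %*% gap_t))
  beta <- sigmoid(as.numeric(params$w_beta %*% gap_f))
  fused <- sweep(features, 3, alpha, "*") + sweep(tproj, 3, beta, "*")
  list(fused = fused, alpha = alpha, beta = beta)
}

#' Pyramid pooling
#'
#' `F_ms = sum_{s in {1,2,4}} Upsample_s(Pool_s(F*))` with adaptive average
#' pooling to an s x s grid and nearest-neighbour upsampling back to the
#' input resolution. A constant input c therefore maps to the constant 3c.
#'
#' @param x H x W x C feature array (or H x W matrix), H, W >= 4.
#' @param scales Pooling grid sizes.
#' @return Array of the same shape as `x`.
#' @export
pyramid_pool <- function(x, scales = c(1, 2, 4)) {
  was_mat <- is.matrix(x)
  if (was_mat) x <- array(x, c(dim(x), 1L))
  d <- dim(x)
  if (d[1] < max(scales) || d[2] < max(scales)) {
    stop_input("input must be at least %dx%d", max(scales), max(scales))
  }
  xc <- as_chwn(x)
  acc <- 0
  for (s in scales) {
    PH <- adaptive_avg_matrix(d[1], s); UH <- nearest_up_matrix(s, d[1])
    PW <- adaptive_avg_matrix(d[2], s); UW <- nearest_up_matrix(s, d[2])
    y <- apply_matrix_dim(xc, UH %*% PH, 2L)
    y <- apply_matrix_dim(y, UW %*% PW, 3L)
    acc <- acc + y
  }
  out <- from_chwn(acc)
  if (was_mat && !is.matrix(out)) out <- out[, , 1]
  out
}

#' Maximum mean discrepancy (squared, biased V-statistic)
#'
#' Kernel two-sample statistic between the rows of `a` (n x d) and `b`
#' (m x d). With the RBF kernel the bandwidth defaults to the median pairwise
#' distance across the pooled sample (falling back to 1 with a warning if the
#' median is zero); with the linear kernel the statistic reduces to
#' `||mean(a) - mean(b)||^2`. Clamped at zero against floating-point error;
#' exactly zero for identical multisets.
#'
#' @param a,b Numeric matrices (or vectors, treated as single-column) with
#'   the same number of columns.
#' @param kernel `"rbf"` or `"linear"`.
#' @param bandwidth RBF bandwidth h (kernel `exp(-||u-v||^2 / (2 h^2))`), or
#'   `NULL` for the median heuristic.
#' @return Nonnegative scalar.
#' @export
mmd_loss <- function(a, b, kernel = c("rbf", "linear"), bandwidth = NULL) {
  kernel <- match.arg(kernel)
  if (is.vector(a)) a <- matrix(a, ncol = 1)
  if (is.vector(b)) b <- matrix(b, ncol = 1)
  if (nrow(a) < 1 || nrow(b) < 1) stop_input("samples must be non-empty")
  if (ncol(a) != ncol(b)) stop_input("samples must have the same dimensionality")
  if (kernel == "linear") {
    return(sum((colMeans(a) - colMeans(b))^2))
  }
  n <- nrow(a); m <- nrow(b)
  x <- rbind(a, b)
  d2 <- pairwise_sqdist(x, x)
  if (is.null(bandwidth)) {
    dd <- sqrt(pmax(d2[upper.tri(d2)], 0))
    bandwidth <- median(dd)
    if (!is.finite(bandwidth) || bandwidth <= 0) {
      warning("median pairwise distance is zero; falling back to bandwidth 1")
      bandwidth <- 1
    }
  }
  K <- exp(-d2 / (2 * bandwidth^2))
  ia <- seq_len(n); ib <- n + seq_len(m)
  v <- mean(K[ia, ia, drop = FALSE]) + mean(K[ib, ib, drop = FALSE]) -
    2 * mean(K[ia, ib, drop = FALSE])
  max(v, 0)
}

pairwise_sqdist <- function(a, b) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * a %*% t(b)
  pmax(d2, 0)
}
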