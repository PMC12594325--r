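# Shared fixtures and small oracles used across test files.

# Deterministic test image: smooth ramp plus localized bright blob.
fixture_image <- function(n = 32, seed = 1) {
  withr::with_seed(seed, {
    ramp <- matrix(rep(seq(0.1, 0.7, length.out = n), each = n), n, n)
    blob <- outer(seq_len(n), seq_len(n), function(i, j) {
      0.25 * exp(-((i - n / 3)^2 + (j - n / 2)^2) / 8)
    })
    pmin(ramp + blob + matrix(runif(n * n, 0, 0.02), n, n), 1)
  })
}

# O(n^2) per-pixel LBP oracle matching the documented sampling convention:
# neighbour k = 0 east, counter-clockwise, bilinear interpolation, replicate
# borders, ties count as 1.
lbp_oracle <- function(img, P = 8, R = 1) {
  H <- nrow(img); W <- ncol(img)
  clampi <- function(v, lo, hi) min(max(v, lo), hi)
  bilinear <- function(r, c) {
    r0 <- floor(r); c0 <- floor(c)
    tr <- r - r0; tc <- c - c0
    r0c <- clampi(r0, 1, H); r1c <- clampi(r0 + 1, 1, H)
    c0c <- clampi(c0, 1, W); c1c <- clampi(c0 + 1, 1, W)
    # same clamped-point / constant-patch reduction as the implementation,
    # so exact ties are preserved
    if (img[r0c, c0c] == img[r0c, c1c] && img[r0c, c0c] == img[r1c, c0c] &&
        img[r0c, c0c] == img[r1c, c1c]) return(img[r0c, c0c])
    if (r0c == r1c && c0c == c1c) return(img[r0c, c0c])
    if (r0c == r1c) return((1 - tc) * img[r0c, c0c] + tc * img[r0c, c1c])
    if (c0c == c1c) return((1 - tr) * img[r0c, c0c] + tr * img[r1c, c0c])
    (1 - tr) * (1 - tc) * img[r0c, c0c] + (1 - tr) * tc * img[r0c, c1c] +
      tr * (1 - tc) * img[r1c, c0c] + tr * tc * img[r1c, c1c]
  }
  out <- matrix(0, H, W)
  for (r in seq_len(H)) {
    for (cc in seq_len(W)) {
      code <- 0
      for (k in 0:(P - 1)) {
        theta <- 2 * pi * k / P
        dr <- -R * sin(theta); dc <- R * cos(theta)
        if (abs(dr - round(dr)) < 1e-9) dr <- round(dr)
        if (abs(dc - round(dc)) < 1e-9) dc <- round(dc)
        v <- bilinear(r + dr, cc + dc)
        if (v >= img[r, cc]) code <- code + 2^k
      }
      out[r, cc] <- code
    }
  }
  out
}

# Brute-force pairwise-concordance AUC with half credit for ties.
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Explicit double-sum squared-MMD oracle over Gram entries (RBF kernel).
mmd_oracle <- function(a, b, h) {
  krn <- function(u, v) exp(-sum((u - v)^2) / (2 * h^2))
  n <- nrow(a); m <- nrow(b)
  saa <- 0; sbb <- 0; sab <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) saa <- saa + krn(a[i, ], a[j, ])
  for (i in seq_len(m)) for (j in seq_len(m)) sbb <- sbb + krn(b[i, ], b[j, ])
  for (i in seq_len(n)) for (j in seq_len(m)) sab <- sab + krn(a[i, ], b[j, ])
  saa / n^2 + sbb / m^2 - 2 * sab / (n * m)
}

# O(n^2) silhouette oracle (double loop over points).
silhouette_oracle <- function(x, y) {
  n <- nrow(x)
  d <- function(i, j) sqrt(sum((x[i, ] - x[j, ])^2))
  mean(sapply(seq_len(n), function(i) {
    own <- setdiff(which(y == y[i]), i)
    if (length(own) == 0) return(0)
    a <- mean(sapply(own, function(j) d(i, j)))
    b <- min(sapply(setdiff(unique(y), y[i]), function(cl) {
      mean(sapply(which(y == cl), function(j) d(i, j)))
    }))
    (b - a) / max(a, b)
  }))
}

# Tiny model config used in the model-level tests (fast to build and run).
fixture_model_config <- function(...) {
  model_config(num_classes = 2, depths = c(1, 1, 1, 1), dim = 8,
               input_size = 64, ms_channels = 4, compress_channels = 4,
               mmd_max_locations = 64, preset = "tiny", ...)
}
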