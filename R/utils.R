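# Shared numeric helpers: activations, seeding, interpolation/pooling
# matrices, and (C,H,W,N) array plumbing.

sigmoid <- function(x) 1 / (1 + exp(-x))

# Exact (erf-based) GELU and its derivative.
gelu <- function(x) x * pnorm(x)
gelu_grad <- function(x) pnorm(x) + x * dnorm(x)

clamp01 <- function(x) pmin(pmax(x, 0), 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

check_image <- function(image, arg = "image") {
  if (!is.numeric(image)) stop_input("%s must be numeric", arg)
  if (anyNA(image) || any(!is.finite(image))) {
    stop_input("%s contains non-finite values", arg)
  }
  invisible(image)
}

# Run code under a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards. All randomness in the package funnels through
# this so that one global seed fans out reproducibly.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seeds below 2^31, one per (seed, stream, index).
derive_seed <- function(seed, stream, index = 0L) {
  h <- (as.double(seed) * 48271 + match(stream, c(
    "data", "init", "augment", "noise", "train", "embed", "other"
  )) * 16807 + as.double(index) * 69621) %% 2147483629
  as.integer(h) + 1L
}

# --- linear resampling operators -------------------------------------------
# All resizing/pooling is expressed as separable row/column matrices so the
# backward pass is just the transpose.

# Bilinear interpolation matrix mapping `n_in` samples to `n_out`
# (half-pixel-centre convention).
bilinear_matrix <- function(n_in, n_out) {
  M <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * n_in / n_out - 0.5
    i0 <- floor(src)
    t <- src - i0
    a <- min(max(i0, 0), n_in - 1)
    b <- min(max(i0 + 1, 0), n_in - 1)
    M[i, a + 1] <- M[i, a + 1] + (1 - t)
    M[i, b + 1] <- M[i, b + 1] + t
  }
  M
}

# Adaptive average pooling matrix to `s` bins.
adaptive_avg_matrix <- function(n_in, s) {
  M <- matrix(0, s, n_in)
  for (i in seq_len(s)) {
    from <- floor((i - 1) * n_in / s) + 1
    to <- ceiling(i * n_in / s)
    M[i, from:to] <- 1 / (to - from + 1)
  }
  M
}

# Nearest-neighbour upsampling matrix from `s` bins back to `n_out`.
nearest_up_matrix <- function(s, n_out) {
  M <- matrix(0, n_out, s)
  for (i in seq_len(n_out)) {
    M[i, floor((i - 1) * s / n_out) + 1] <- 1
  }
  M
}

# Apply matrix M along dimension `dim` (2 = H, 3 = W) of a (C,H,W,N) array.
apply_matrix_dim <- function(x, M, dim) {
  d <- dim(x)
  perm <- switch(dim - 1L, c(2L, 1L, 3L, 4L), c(3L, 1L, 2L, 4L))
  inv <- switch(dim - 1L, c(2L, 1L, 3L, 4L), c(2L, 3L, 1L, 4L))
  xp <- aperm(x, perm)
  m <- M %*% matrix(xp, nrow = d[dim])
  dd <- d[perm]
  dd[1] <- nrow(M)
  aperm(array(m, dd), inv)
}

# Bilinear resize of a (C,H,W,N) array; returns the resized array. The
# adjoint (for backprop) reuses the transposed matrices.
resize_bilinear_chwn <- function(x, H2, W2) {
  d <- dim(x)
  x <- apply_matrix_dim(x, bilinear_matrix(d[2], H2), 2L)
  apply_matrix_dim(x, bilinear_matrix(d[3], W2), 3L)
}

resize_bilinear_chwn_adj <- function(dy, H1, W1) {
  d <- dim(dy)
  dy <- apply_matrix_dim(dy, t(bilinear_matrix(H1, d[2])), 2L)
  apply_matrix_dim(dy, t(bilinear_matrix(W1, d[3])), 3L)
}

# Convert a user-facing (H,W) matrix or (H,W,C) array into (C,H,W,1).
as_chwn <- function(image) {
  if (is.matrix(image)) {
    return(array(aperm(array(image, c(dim(image), 1L)), c(3L, 1L, 2L)),
                 c(1L, dim(image), 1L)))
  }
  d <- dim(image)
  array(aperm(image, c(3L, 1L, 2L)), c(d[3], d[1], d[2], 1L))
}

# Convert (C,H,W,1) back to (H,W) matrix (C = 1) or (H,W,C) array.
from_chwn <- function(x) {
  d <- dim(x)
  if (d[1] == 1L) {
    matrix(x[1L, , , 1L], d[2], d[3])
  } else {
    aperm(array(x[, , , 1L], d[1:3]), c(2L, 3L, 1L))
  }
}
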