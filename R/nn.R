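# Minimal layer framework with explicit forward/backward passes.
#
# Every layer is an environment holding `par` (named list of parameter
# arrays), `gr` (matching gradient accumulators), `fwd(x)` and `bwd(dy)`.
# Feature maps are (C, H, W, N) arrays. The backward pass of each layer is
# verified against central finite differences in the test suite.

new_module <- function(type, par = list()) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$par <- par
  e$gr <- lapply(par, function(p) array(0, dim(p) %||% length(p)))
  class(e) <- "kct_module"
  e
}

zero_grads <- function(mod) {
  mod$gr <- lapply(mod$par, function(p) {
    if (is.null(dim(p))) numeric(length(p)) else array(0, dim(p))
  })
  invisible(mod)
}

module_list_zero <- function(mods) {
  for (m in mods) zero_grads(m)
  invisible(mods)
}

# --- convolution ------------------------------------------------------------

layer_conv2d <- function(cin, cout, k, stride = 1L, pad = (k - 1L) %/% 2L,
                         pad_mode = 0L, groups = 1L, bias = TRUE,
                         init_sd = 0.02) {
  par <- list(w = array(rnorm(k * k * (cin %/% groups) * cout, sd = init_sd),
                        c(k, k, cin %/% groups, cout)))
  if (bias) par$b <- numeric(cout)
  m <- new_module("conv2d", par)
  m$stride <- as.integer(stride); m$pad <- as.integer(pad)
  m$pad_mode <- as.integer(pad_mode); m$groups <- as.integer(groups)
  m$fwd <- function(x) {
    m$x <- x
    conv2d_fwd_cpp(x, m$par$w, m$par$b %||% numeric(0),
                   m$stride, m$pad, m$pad_mode, m$groups)
  }
  m$bwd <- function(dy) {
    r <- conv2d_bwd_cpp(m$x, m$par$w, dy, m$stride, m$pad, m$pad_mode, m$groups)
    m$gr$w <- m$gr$w + r$dw
    if (!is.null(m$par$b)) m$gr$b <- m$gr$b + r$db
    r$dx
  }
  m
}

# --- pointwise (1x1) channel mixing ----------------------------------------

layer_pointwise <- function(cin, cout, bias = TRUE, init_sd = 0.02) {
  par <- list(w = matrix(rnorm(cout * cin, sd = init_sd), cout, cin))
  if (bias) par$b <- numeric(cout)
  m <- new_module("pointwise", par)
  m$fwd <- function(x) {
    d <- dim(x)
    m$xm <- matrix(x, d[1])
    m$din <- d
    y <- m$par$w %*% m$xm
    if (!is.null(m$par$b)) y <- y + m$par$b
    array(y, c(nrow(m$par$w), d[2], d[3], d[4]))
  }
  m$bwd <- function(dy) {
    dym <- matrix(dy, nrow(m$par$w))
    m$gr$w <- m$gr$w + dym %*% t(m$xm)
    if (!is.null(m$par$b)) m$gr$b <- m$gr$b + rowSums(dym)
    array(crossprod(m$par$w, dym), m$din)
  }
  m
}

# --- layer normalization over channels (per spatial position) --------------

layer_layernorm <- function(c_dim, eps = 1e-6) {
  m <- new_module("layernorm", list(gamma = rep(1, c_dim), beta = numeric(c_dim)))
  m$eps <- eps
  m$fwd <- function(x) {
    d <- dim(x)
    xm <- matrix(x, d[1])
    mu <- colMeans(xm)
    xc <- sweep(xm, 2, mu)
    v <- colMeans(xc^2)
    inv <- 1 / sqrt(v + m$eps)
    xhat <- sweep(xc, 2, inv, "*")
    m$xhat <- xhat; m$inv <- inv; m$din <- d
    array(m$par$gamma * xhat + m$par$beta, d)
  }
  m$bwd <- function(dy) {
    d <- m$din
    dym <- matrix(dy, d[1])
    m$gr$gamma <- m$gr$gamma + rowSums(dym * m$xhat)
    m$gr$beta <- m$gr$beta + rowSums(dym)
    dxh <- dym * m$par$gamma
    t1 <- colMeans(dxh)
    t2 <- colMeans(dxh * m$xhat)
    dx <- sweep(dxh, 2, t1) - sweep(m$xhat, 2, t2, "*")
    array(sweep(dx, 2, m$inv, "*"), d)
  }
  m
}

# --- GELU -------------------------------------------------------------------

layer_gelu <- function() {
  m <- new_module("gelu")
  m$fwd <- function(x) { m$x <- x; gelu(x) }
  m$bwd <- function(dy) dy * gelu_grad(m$x)
  m
}

# --- global response normalization (ConvNeXtV2) -----------------------------
# gx[c,n] = ||x[c,,,n]||_2, nu = gx / (mean_c gx + eps),
# y = gamma * x * nu + beta + x. gamma, beta start at zero (identity).

layer_grn <- function(c_dim, eps = 1e-6) {
  m <- new_module("grn", list(gamma = numeric(c_dim), beta = numeric(c_dim)))
  m$eps <- eps
  sum_hw <- function(a, d) {
    # sum over H, W of a (C,H,W,N) array -> (C, N) matrix
    matrix(colSums(matrix(aperm(a, c(2L, 3L, 1L, 4L)), d[2] * d[3])), d[1], d[4])
  }
  expand_cn <- function(v, d) {
    # broadcast a (C,N) matrix over H, W
    aperm(array(v, c(d[1], d[4], d[2], d[3])), c(1L, 3L, 4L, 2L))
  }
  m$fwd <- function(x) {
    d <- dim(x)
    gx <- sqrt(sum_hw(x^2, d))
    mg <- colMeans(gx) + m$eps
    nu <- sweep(gx, 2, mg, "/")
    m$x <- x; m$gx <- gx; m$mg <- mg; m$nu <- nu; m$din <- d
    nux <- x * expand_cn(nu, d)
    m$nux <- nux
    m$par$gamma * nux + m$par$beta + x
  }
  m$bwd <- function(dy) {
    d <- m$din
    m$gr$gamma <- m$gr$gamma + rowSums(matrix(dy * m$nux, d[1]))
    m$gr$beta <- m$gr$beta + rowSums(matrix(dy, d[1]))
    g <- m$par$gamma
    # direct path: dy * (gamma * nu + 1)
    dx <- dy * (expand_cn(sweep(m$nu, 1, g, "*"), d) + 1)
    # path through nu: S[c,n] = sum_hw dy * gamma * x
    S <- sum_hw(dy * (g * m$x), d)
    C <- d[1]
    term <- sweep(sweep(S, 2, m$mg, "/"), 2,
                  colSums(S * m$gx) / (C * m$mg^2), "-")
    inv_gx <- ifelse(m$gx > 0, 1 / m$gx, 0)
    dx + m$x * expand_cn(term * inv_gx, d)
  }
  m
}

# --- dense layer on (C, N) matrices -----------------------------------------

layer_linear <- function(cin, cout, bias = TRUE, init_sd = 0.02) {
  par <- list(w = matrix(rnorm(cout * cin, sd = init_sd), cout, cin))
  if (bias) par$b <- numeric(cout)
  m <- new_module("linear", par)
  m$fwd <- function(x) {
    m$x <- x
    y <- m$par$w %*% x
    if (!is.null(m$par$b)) y <- y + m$par$b
    y
  }
  m$bwd <- function(dy) {
    m$gr$w <- m$gr$w + dy %*% t(m$x)
    if (!is.null(m$par$b)) m$gr$b <- m$gr$b + rowSums(dy)
    crossprod(m$par$w, dy)
  }
  m
}

# --- global average pooling (C,H,W,N) -> (C,N) ------------------------------

gap_fwd <- function(x) {
  d <- dim(x)
  matrix(colSums(matrix(aperm(x, c(2L, 3L, 1L, 4L)), d[2] * d[3])),
         d[1], d[4]) / (d[2] * d[3])
}

gap_bwd <- function(dy, d) {
  aperm(array(dy / (d[2] * d[3]), c(d[1], d[4], d[2], d[3])), c(1L, 3L, 4L, 2L))
}

# --- ConvNeXtV2 block -------------------------------------------------------
# x + pw2(GRN(GELU(pw1(LN(dwconv7x7(x))))))

convnext_block <- function(c_dim) {
  m <- new_module("convnext_block")
  m$sub <- list(
    dw = layer_conv2d(c_dim, c_dim, 7L, pad = 3L, groups = c_dim),
    ln = layer_layernorm(c_dim),
    pw1 = layer_pointwise(c_dim, 4L * c_dim),
    act = layer_gelu(),
    grn = layer_grn(4L * c_dim),
    pw2 = layer_pointwise(4L * c_dim, c_dim)
  )
  m$fwd <- function(x) {
    h <- x
    for (s in m$sub) h <- s$fwd(h)
    x + h
  }
  m$bwd <- function(dy) {
    dh <- dy
    for (s in rev(m$sub)) dh <- s$bwd(dh)
    dy + dh
  }
  m
}

# --- softmax cross-entropy --------------------------------------------------

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# logits: (K, N); labels: integer vector in 1..K. Returns mean CE and the
# gradient w.r.t. logits.
cross_entropy <- function(logits, labels) {
  p <- softmax_cols(logits)
  n <- ncol(logits)
  idx <- cbind(labels, seq_len(n))
  loss <- -mean(log(pmax(p[idx], 1e-300)))
  dp <- p
  dp[idx] <- dp[idx] - 1
  list(loss = loss, dlogits = dp / n, probs = p)
}

# Flatten all modules (recursing into composite blocks) for the optimizer.
flatten_modules <- function(mods) {
  out <- list()
  for (m in mods) {
    if (!is.null(m$sub)) out <- c(out, flatten_modules(m$sub))
    if (length(m$par)) out <- c(out, list(m))
  }
  out
}
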