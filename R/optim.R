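# AdamW with decoupled weight decay, over the flattened module list, plus
# the per-epoch cosine-annealing learning-rate schedule.

adamw_new <- function(modules, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 1e-5) {
  state <- lapply(modules, function(m) {
    lapply(m$par, function(p) list(m = p * 0, v = p * 0))
  })
  list(modules = modules, state = state, lr = lr, beta1 = beta1,
       beta2 = beta2, eps = eps, weight_decay = weight_decay, t = 0L)
}

adamw_step <- function(opt, lr = opt$lr) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  bc1 <- 1 - b1^opt$t; bc2 <- 1 - b2^opt$t
  for (i in seq_along(opt$modules)) {
    mod <- opt$modules[[i]]
    for (nm in names(mod$par)) {
      g <- mod$gr[[nm]]
      st <- opt$state[[i]][[nm]]
      st$m <- b1 * st$m + (1 - b1) * g
      st$v <- b2 * st$v + (1 - b2) * g^2
      opt$state[[i]][[nm]] <- st
      upd <- (st$m / bc1) / (sqrt(st$v / bc2) + opt$eps)
      mod$par[[nm]] <- mod$par[[nm]] - lr * (upd + opt$weight_decay * mod$par[[nm]])
    }
  }
  opt
}

#' Cosine-annealed learning rate
#'
#' Per-epoch schedule `lr0 * 0.5 * (1 + cos(pi * (epoch - 1) / (epochs - 1)))`,
#' decaying from the initial rate to exactly zero at the final epoch.
#'
#' @param epoch Current epoch (1-based).
#' @param epochs Total number of epochs.
#' @param lr0 Initial learning rate.
#' @return The learning rate for `epoch`.
#' @export
cosine_lr <- function(epoch, epochs, lr0) {
  if (epochs <= 1) return(lr0)
  lr0 * 0.5 * (1 + cos(pi * (epoch - 1) / (epochs - 1)))
}
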