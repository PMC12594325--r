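# The desk-scale smoke-run recipe, shared by the test suite and the
# acceptance script so both exercise identical study conditions.

#' Deterministic sub-seed derivation
#'
#' Fans one integer seed out into independent, reproducible child seeds
#' (all below 2^31) for the package's separate randomness consumers.
#'
#' @param seed Base integer seed.
#' @param index Child index.
#' @return An integer seed.
#' @export
derive_seed_public <- function(seed, index = 0L) {
  derive_seed(seed, "other", index)
}

#' Training configuration for desk-scale smoke runs
#'
#' The tiny-preset smoke recipe: 5 epochs at batch size 2 with peak
#' learning rate 2e-3, one warmup epoch, then cosine decay. A from-scratch
#' tiny model sees only a few hundred optimiser steps in five epochs, so
#' the batch size is small (more steps per epoch) and the learning rate
#' sits an order of magnitude above the full-scale recipe's 1e-4.
#'
#' @param seed Global seed.
#' @param epochs,batch_size,lr,warmup_epochs Overridable recipe fields.
#' @return A [train_config()].
#' @export
smoke_train_config <- function(seed = 1, epochs = 5, batch_size = 2,
                               lr = 2e-3, warmup_epochs = 1) {
  if (warmup_epochs >= epochs) warmup_epochs <- 0
  train_config(epochs = epochs, batch_size = batch_size, lr = lr,
               warmup_epochs = warmup_epochs,
               weight_decay = 1e-5, seed = seed)
}
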