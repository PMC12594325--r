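# Grad-CAM: gradient-weighted class activation mapping on the backbone
# stage outputs, for visual verification that the classifier attends to
# lesion regions rather than background.

#' Grad-CAM heatmap
#'
#' Backpropagates the target-class logit to the chosen backbone stage
#' output, global-average-pools the gradient per channel to obtain channel
#' weights, forms the rectified weighted sum of activations, normalizes to
#' `[0, 1]`, and bilinearly upsamples to the input size. An all-zero map
#' (nothing positively supports the class at that layer) is returned as
#' zeros with a warning.
#'
#' @param model A trained `kct_model`.
#' @param image H x W matrix in `[0, 1]`.
#' @param target_class Class index (1..K); defaults to the predicted class.
#' @param layer One of `"stage1"`..`"stage4"` (default: the last backbone
#'   stage).
#' @return H x W heatmap in `[0, 1]`.
#' @export
grad_cam <- function(model, image, target_class = NULL, layer = "stage4") {
  stopifnot(is.matrix(image))
  si <- match(layer, paste0("stage", 1:4))
  if (is.na(si)) stop_input("unknown layer '%s' (use stage1..stage4)", layer)
  fwd <- forward_pipeline(model, image, keep_intermediates = TRUE)
  if (is.null(target_class)) target_class <- which.max(fwd$logits[, 1])
  if (target_class < 1 || target_class > nrow(fwd$logits)) {
    stop_input("target_class out of range")
  }
  dlogits <- matrix(0, nrow(fwd$logits), 1)
  dlogits[target_class, 1] <- 1
  flat <- flatten_modules(model$modules)
  module_list_zero(flat)
  bk <- model_backward(model, fwd, dlogits, lambda_hist = 0, lambda_mmd = 0,
                       record_stage_grads = TRUE)
  module_list_zero(flat) # discard the probe gradients
  acts <- fwd$intermediates$stages[[si]] # (C, h, w, 1)
  grads <- bk$stage_grads[[si]]
  weights <- gap_fwd(grads)[, 1] # channel importance
  cam <- apply(acts[, , , 1, drop = FALSE] * weights, c(2, 3), sum)
  cam <- pmax(cam, 0)
  if (max(cam) == 0) {
    warning("Grad-CAM map is identically zero for this class/layer")
    return(matrix(0, nrow(image), ncol(image)))
  }
  cam <- cam / max(cam)
  up <- resize_bilinear_chwn(array(cam, c(1, dim(cam), 1)),
                             nrow(image), ncol(image))
  hm <- pmax(matrix(up[1, , , 1], nrow(image), ncol(image)), 0)
  hm / max(hm) # renormalize: upsampling smooths the peak slightly
}
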