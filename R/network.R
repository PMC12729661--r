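# Model assembly, hybrid Dice + BCE loss, prediction and checkpoints.

#' Build the segmentation model
#'
#' Assembles the five-stage state-space encoder, one edge-enhanced skip
#' module per skip level, the pyramid-attention bottleneck and the
#' context-aggregation decoder. Weight initialization is fully determined
#' by `config$seed`.
#'
#' @param config a `run_config` (see [default_run_config()],
#'   [test_profile_config()]).
#' @return an `emaseg_model` object.
#' @export
build_model <- function(config = default_run_config()) {
  config <- validate_run_config(config)
  withr::with_seed(config$seed, {
    enc <- encoder_init(base = as.integer(config$base_channels),
                        depths = as.integer(config$stage_depths))
    ch <- enc$channels
    msee <- lapply(ch[1:4], msee_init)
    bdim <- config$input_size %/% 32L
    pools <- c(1L, 3L, 5L, 7L)
    pools <- pools[pools <= bdim]
    parm <- parm_init(ch[5], pool_sizes = pools)
    dec <- decoder_init(ch, use_gcad = isTRUE(config$use_gcad))
    structure(list(encoder = enc, msee = msee, parm = parm, decoder = dec,
                   config = config), class = "emaseg_model")
  })
}

# full forward pass on an (S, S) pixel matrix -> logits node (S, S, 1)
model_forward_ag <- function(model, px, training = TRUE) {
  x <- ag_const(gray_to_3ch(px))
  pyr <- encoder_fwd(model$encoder, x)
  bn <- parm_fwd(model$parm, pyr[[5]])
  decoder_fwd(model$decoder, model$msee, pyr[1:4], bn, training = training)
}

#' Hybrid segmentation loss: Dice + binary cross-entropy
#'
#' `L_dice = 1 - 2 sum(g p) / (sum(g) + sum(p))` (with 1e-5 smoothing added
#' to numerator and denominator so empty masks are well defined) and
#' `L_bce = -mean(g log p + (1-g) log(1-p))` with probabilities clipped to
#' `[1e-7, 1 - 1e-7]`. The total is their unweighted sum.
#'
#' @param probabilities predicted foreground probabilities in `[0, 1]`.
#' @param labels 0/1 ground-truth labels, same shape.
#' @return list with `l_dice`, `l_bce`, `l_total`.
#' @export
total_loss <- function(probabilities, labels) {
  if (length(probabilities) != length(labels))
    err_validation("probabilities and labels must have the same shape")
  if (!is.null(dim(probabilities)) && !is.null(dim(labels)) &&
      !all(dim(probabilities) == dim(labels)))
    err_validation("probabilities and labels must have the same shape")
  g <- as.numeric(labels); p <- as.numeric(probabilities)
  eps <- 1e-7; sm <- 1e-5
  pc <- pmin(pmax(p, eps), 1 - eps)
  l_dice <- 1 - (2 * sum(g * p) + sm) / (sum(g) + sum(p) + sm)
  l_bce <- -mean(g * log(pc) + (1 - g) * log(1 - pc))
  list(l_dice = l_dice, l_bce = l_bce, l_total = l_dice + l_bce)
}

# autodiff version from logits (numerically stable BCE via softplus)
loss_ag <- function(logits, labels) {
  g <- ag_const(array(as.numeric(labels), dim = dim(logits$v)))
  p <- ag_sigmoid(logits)
  sm <- 1e-5
  num <- ag_add(ag_scale(ag_sum(ag_mul(g, p)), 2), ag_const(sm))
  den <- ag_add(ag_add(ag_sum(g), ag_sum(p)), ag_const(sm))
  dice <- ag_sub(ag_const(1), ag_mul(num, ag_op(1 / den$v, list(den),
                  function(gr) list(-gr / den$v^2))))
  # bce = mean(softplus(z) - g z)
  bce <- ag_mean(ag_sub(ag_softplus(logits), ag_mul(g, logits)))
  list(dice = dice, bce = bce, total = ag_add(dice, bce))
}

#' Predict a binary mask for a frame
#'
#' The frame is resized to the model input size, passed through the
#' network, thresholded (default 0.5 on the sigmoid probability), and the
#' mask is resized back to the frame's native grid with nearest-neighbour
#' interpolation.
#'
#' @param model an `emaseg_model`.
#' @param frame an [ultrasound_frame()].
#' @param threshold probability threshold in `[0, 1]`.
#' @return a [binary_mask()] aligned to the input frame.
#' @export
predict_mask <- function(model, frame, threshold = 0.5) {
  if (!inherits(model, "emaseg_model")) err_validation("not an emaseg model")
  pf <- preprocess(frame, model$config$input_size)
  logits <- with_no_grad(model_forward_ag(model, pf$pixels, training = FALSE)$v)
  prob <- 1 / (1 + exp(-logits[, , 1]))
  m <- (prob >= threshold) * 1L
  m <- resize_nearest_matrix(m, nrow(frame$pixels), ncol(frame$pixels))
  binary_mask(m, id = frame$id)
}

#' Save model weights and configuration to a checkpoint file
#'
#' @param model an `emaseg_model`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  params <- collect_params(model)
  vals <- lapply(params, function(p) p$v)
  saveRDS(list(config = unclass(model$config), values = vals,
               n_params = count_parameters(model)), path)
  invisible(path)
}

#' Load a model from a checkpoint file
#'
#' @param path checkpoint file written by [save_checkpoint()].
#' @return an `emaseg_model`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) err_io(paste("checkpoint not found:", path))
  ck <- readRDS(path)
  model <- build_model(do.call(default_run_config, ck$config[
    setdiff(names(ck$config), "augment")]))
  params <- collect_params(model)
  if (length(params) != length(ck$values))
    err_validation("checkpoint incompatible with configuration")
  for (i in seq_along(params)) {
    if (!identical(dim(params[[i]]$v) %||% length(params[[i]]$v),
                   dim(ck$values[[i]]) %||% length(ck$values[[i]])))
      err_validation("checkpoint incompatible with configuration")
    params[[i]]$v <- ck$values[[i]]
  }
  model
}
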