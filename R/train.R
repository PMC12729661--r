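# Data augmentation and the training loop.

#' Default augmentation policy
#'
#' Geometric transforms (applied identically to frame and mask; the mask is
#' nearest-resampled so it stays binary): rotation within +/-30 degrees
#' (p = 0.2), scaling 0.7-1.4 (p = 0.2), elastic deformation (p = 0.2).
#' Intensity transforms (frame only): brightness x0.75-1.25 (p = 0.15),
#' contrast x0.75-1.25 (p = 0.15), additive Gaussian noise with sigma drawn
#' from 0-0.1 (p = 0.1). Augmentation is a training-time operation only.
#'
#' @param ... named overrides.
#' @return an `augment_policy` list.
#' @export
default_augment_policy <- function(...) {
  pol <- list(p_rotate = 0.2, rotate_deg = 30,
              p_scale = 0.2, scale_range = c(0.7, 1.4),
              p_elastic = 0.2, elastic_alpha = 10, elastic_sigma = 8,
              p_brightness = 0.15, brightness_range = c(0.75, 1.25),
              p_contrast = 0.15, contrast_range = c(0.75, 1.25),
              p_noise = 0.1, noise_sigma_max = 0.1)
  pol <- utils::modifyList(pol, list(...))
  bad <- vapply(pol[grep("^p_", names(pol))],
                function(p) p < 0 || p > 1, logical(1))
  if (any(bad)) err_validation("augmentation probabilities must lie in [0, 1]")
  structure(pol, class = "augment_policy")
}

# bilinear sample of matrix m at fractional (rows, cols); replicate border
sample_bilinear <- function(m, rr, cc) {
  H <- nrow(m); W <- ncol(m)
  rr <- as.vector(rr); cc <- as.vector(cc)
  r0 <- floor(rr); c0 <- floor(cc)
  fr <- rr - r0; fc <- cc - c0
  cl <- function(v, n) pmin(pmax(v, 1L), n)
  at <- function(r, c) m[cbind(r, c)]
  out <- at(cl(r0, H), cl(c0, W)) * (1 - fr) * (1 - fc) +
    at(cl(r0, H), cl(c0 + 1, W)) * (1 - fr) * fc +
    at(cl(r0 + 1, H), cl(c0, W)) * fr * (1 - fc) +
    at(cl(r0 + 1, H), cl(c0 + 1, W)) * fr * fc
  matrix(out, H, W)
}

sample_nearest <- function(m, rr, cc) {
  H <- nrow(m); W <- ncol(m)
  idx <- cbind(pmin(pmax(round(as.vector(rr)), 1L), H),
               pmin(pmax(round(as.vector(cc)), 1L), W))
  matrix(m[idx], H, W)
}

#' Augment a frame/mask pair
#'
#' Geometric transforms move frame and mask through the same coordinate
#' map; intensity transforms touch the frame only. Deterministic given the
#' seed; with all probabilities zero this is the identity.
#'
#' @param frame an [ultrasound_frame()].
#' @param mask the paired [binary_mask()].
#' @param policy an [default_augment_policy()] list.
#' @param seed integer seed.
#' @return list `(frame, mask)`.
#' @export
augment_sample <- function(frame, mask, policy = default_augment_policy(),
                           seed = 1L) {
  if (!all(dim(frame$pixels) == dim(mask$labels)))
    err_validation("frame and mask shapes differ")
  withr::with_seed(seed, {
    px <- frame$pixels; lb <- mask$labels
    H <- nrow(px); W <- ncol(px)
    angle <- if (stats::runif(1) < policy$p_rotate)
      stats::runif(1, -policy$rotate_deg, policy$rotate_deg) * pi / 180 else 0
    scl <- if (stats::runif(1) < policy$p_scale)
      stats::runif(1, policy$scale_range[1], policy$scale_range[2]) else 1
    elastic <- stats::runif(1) < policy$p_elastic
    if (angle != 0 || scl != 1 || elastic) {
      cy <- (H + 1) / 2; cx <- (W + 1) / 2
      R <- matrix(rep(seq_len(H), W), H) - cy
      C <- matrix(rep(seq_len(W), each = H), H) - cx
      # inverse map: rotate by -angle, scale by 1/scl
      ca <- cos(angle); sa <- sin(angle)
      rr <- (ca * R - sa * C) / scl + cy
      cc <- (sa * R + ca * C) / scl + cx
      if (elastic) {
        dmr <- gauss_blur_mat(matrix(stats::rnorm(H * W), H), policy$elastic_sigma)
        dmc <- gauss_blur_mat(matrix(stats::rnorm(H * W), H), policy$elastic_sigma)
        nrm <- max(max(abs(dmr)), max(abs(dmc)), 1e-9)
        rr <- rr + policy$elastic_alpha * dmr / nrm
        cc <- cc + policy$elastic_alpha * dmc / nrm
      }
      px <- sample_bilinear(px, rr, cc)
      lb <- sample_nearest(lb, rr, cc)
    }
    if (stats::runif(1) < policy$p_brightness)
      px <- px * stats::runif(1, policy$brightness_range[1], policy$brightness_range[2])
    if (stats::runif(1) < policy$p_contrast) {
      cf <- stats::runif(1, policy$contrast_range[1], policy$contrast_range[2])
      px <- (px - mean(px)) * cf + mean(px)
    }
    if (stats::runif(1) < policy$p_noise)
      px <- px + stats::rnorm(length(px), sd = stats::runif(1, 0, policy$noise_sigma_max))
    px <- pmin(pmax(px, 0), 1)
    list(frame = ultrasound_frame(px, frame$spacing_mm, id = frame$id),
         mask = binary_mask(lb * 1L, id = mask$id))
  })
}

load_pair <- function(row, input_size) {
  fr <- load_frame(row$image_path, c(row$row_mm_per_px, row$col_mm_per_px))
  mk <- load_mask(row$mask_path)
  fr <- preprocess(fr, input_size)
  mk <- binary_mask(resize_nearest_matrix(mk$labels, input_size, input_size),
                    id = mk$id)
  list(frame = fr, mask = mk)
}

dsc_of <- function(pred, gt) {
  tp <- sum(pred == 1L & gt == 1L)
  (2 * tp) / max(2 * tp + sum(pred != gt), 1)
}

#' Train the segmentation model
#'
#' AdamW (constant learning rate, no schedule or early stopping) on the
#' hybrid Dice+BCE loss, with gradient accumulation over each mini-batch.
#' Per-epoch mean train loss, validation loss and validation DSC are
#' recorded; the checkpoint with the best validation DSC is kept (the final
#' state when there is no validation set).
#'
#' @param config a `run_config`.
#' @param manifest manifest CSV path or data frame (see [read_manifest()]).
#' @param split optional `split_spec`; by default a 7:2:1 split seeded from
#'   `config$seed`.
#' @param out_dir if given, `history.csv` and `best.ckpt` are written there.
#' @param max_steps optional cap on the number of optimizer steps.
#' @param verbose print per-epoch progress.
#' @return list with `model` (best), `history` (data frame), `steps`.
#' @export
train_model <- function(config, manifest, split = NULL, out_dir = NULL,
                        max_steps = Inf, verbose = FALSE) {
  config <- validate_run_config(config)
  man <- if (is.character(manifest)) read_manifest(manifest) else manifest
  if (is.null(split)) split <- split_dataset(man$id, seed = config$seed)
  tr <- man[man$id %in% split$train_ids, , drop = FALSE]
  va <- man[man$id %in% split$val_ids, , drop = FALSE]
  if (nrow(tr) == 0L) err_validation("empty training split")
  model <- build_model(config)
  params <- collect_params(model)
  opt <- adamw_init(params, lr = config$learning_rate,
                    weight_decay = config$weight_decay)
  pairs <- lapply(seq_len(nrow(tr)), function(i) load_pair(tr[i, ], config$input_size))
  vpairs <- lapply(seq_len(nrow(va)), function(i) load_pair(va[i, ], config$input_size))
  hist <- list(); steps <- 0L
  best <- list(dsc = -Inf, values = NULL)
  aug_counter <- 0L
  for (ep in seq_len(config$epochs)) {
    if (steps >= max_steps) break
    ord <- withr::with_seed(config$seed + ep, sample(length(pairs)))
    ep_losses <- c()
    i <- 1L
    while (i <= length(ord) && steps < max_steps) {
      bidx <- ord[i:min(i + config$batch_size - 1L, length(ord))]
      i <- i + config$batch_size
      zero_grads(params)
      bl <- 0
      for (j in bidx) {
        aug_counter <- aug_counter + 1L
        s <- augment_sample(pairs[[j]]$frame, pairs[[j]]$mask, config$augment,
                            seed = (config$seed * 131L + aug_counter) %% .Machine$integer.max)
        logits <- model_forward_ag(model, s$frame$pixels, training = TRUE)
        ls <- loss_ag(logits, s$mask$labels)
        ag_backward(ag_scale(ls$total, 1 / length(bidx)))
        bl <- bl + ls$total$v / length(bidx)
      }
      opt <- adamw_step(opt)
      steps <- steps + 1L
      ep_losses <- c(ep_losses, bl)
    }
    val_loss <- NA_real_; val_dsc <- NA_real_
    if (length(vpairs) > 0L) {
      vl <- vd <- c()
      for (vp in vpairs) {
        logits <- with_no_grad(model_forward_ag(model, vp$frame$pixels,
                                                training = FALSE)$v)
        prob <- 1 / (1 + exp(-logits[, , 1]))
        lv <- total_loss(prob, vp$mask$labels)
        vl <- c(vl, lv$l_total)
        vd <- c(vd, dsc_of((prob >= config$threshold) * 1L, vp$mask$labels))
      }
      val_loss <- mean(vl); val_dsc <- mean(vd)
      if (val_dsc >= best$dsc) {
        best$dsc <- val_dsc
        best$values <- lapply(params, function(p) p$v)
      }
    }
    hist[[ep]] <- data.frame(epoch = ep, train_loss = mean(ep_losses),
                             val_loss = val_loss, val_dsc = val_dsc)
    if (verbose) log_msg("INFO", sprintf(
      "epoch %d: train %.4f val %.4f dsc %.4f (%d steps)",
      ep, mean(ep_losses), val_loss, val_dsc, steps))
  }
  if (!is.null(best$values)) {
    for (k in seq_along(params)) params[[k]]$v <- best$values[[k]]
  }
  history <- do.call(rbind, hist)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(history, file.path(out_dir, "history.csv"), row.names = FALSE)
    save_checkpoint(model, file.path(out_dir, "best.ckpt"))
  }
  list(model = model, history = history, steps = steps)
}
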