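#' Soft Dice loss
#'
#' `1 - (2 * sum(p * y) + s) / (sum(p) + sum(y) + s)` with smoothing
#' `s = 1e-6`; differentiable in the probabilities.
#'
#' @param prob probability map.
#' @param truth binary mask of identical shape.
#' @param smooth smoothing constant.
#' @return scalar loss.
#' @export
dice_loss <- function(prob, truth, smooth = 1e-6) {
  if (!identical(dim(prob), dim(truth)))
    stop("dice_loss: shape mismatch", call. = FALSE)
  num <- 2 * sum(prob * truth) + smooth
  den <- sum(prob) + sum(truth) + smooth
  1 - num / den
}

dice_loss_grad <- function(prob, truth, smooth = 1e-6) {
  num <- 2 * sum(prob * truth) + smooth
  den <- sum(prob) + sum(truth) + smooth
  -(2 * truth * den - num) / den^2
}

#' Training configuration
#'
#' AdamW semantics: adaptive moment estimates with decoupled weight decay.
#' Defaults follow the reference training schedule (learning rate 1e-5,
#' epsilon 1e-9, weight decay 1e-6, up to 600 epochs, batch size 64, early
#' stopping after 10 non-improving validation epochs, L2 regularization of
#' 1e-6 on convolution kernels).
#'
#' @param learning_rate initial learning rate.
#' @param epsilon optimizer epsilon.
#' @param weight_decay decoupled weight decay.
#' @param max_epochs epoch cap.
#' @param batch_size minibatch size.
#' @param patience consecutive non-improving validation epochs tolerated.
#' @param l2_kernel_weight L2 penalty weight on convolution kernels.
#' @param beta1,beta2 moment decay rates.
#' @param lr_multipliers optional named per-parameter-group learning-rate
#'   multipliers for layer-wise fine-tuning, e.g. `c(enc1 = 0.1)`; groups
#'   are matched by parameter-name prefix. Default: uniform fine-tuning.
#' @param seed RNG seed controlling shuffling, dropout and augmentation.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-5, epsilon = 1e-9,
                         weight_decay = 1e-6, max_epochs = 600L,
                         batch_size = 64L, patience = 10L,
                         l2_kernel_weight = 1e-6, beta1 = 0.9,
                         beta2 = 0.999, lr_multipliers = NULL, seed = 1L) {
  if (patience >= max_epochs)
    stop("train config error: patience must be < max_epochs", call. = FALSE)
  if (any(c(learning_rate, epsilon) <= 0) || weight_decay < 0)
    stop("train config error: rates must be positive", call. = FALSE)
  structure(list(learning_rate = learning_rate, epsilon = epsilon,
                 weight_decay = weight_decay,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 l2_kernel_weight = l2_kernel_weight,
                 beta1 = beta1, beta2 = beta2,
                 lr_multipliers = lr_multipliers, seed = as.integer(seed)),
            class = "train_config")
}

#' Epoch at which early stopping fires
#'
#' Training halts when the validation loss fails to improve for `patience`
#' consecutive epochs (strict improvement over the best loss so far).
#'
#' @param val_losses per-epoch validation losses observed so far.
#' @param patience tolerated consecutive non-improving epochs.
#' @return the 1-based epoch index at which training halts, or `NA` if the
#'   criterion has not fired.
#' @export
early_stopping_epoch <- function(val_losses, patience) {
  best <- Inf; bad <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) {
      best <- val_losses[e]
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= patience) return(e)
    }
  }
  NA_integer_
}

is_kernel_param <- function(nm) grepl("\\.W$", nm)

validation_loss <- function(model, val) {
  losses <- vapply(seq_along(val$x), function(i) {
    dice_loss(seg_forward(model, val$x[[i]])$prob, val$y[[i]] * 1)
  }, numeric(1))
  mean(losses)
}

#' Train a segmentation model
#'
#' Minibatch AdamW on the soft Dice loss with early stopping on the
#' validation loss; the weights from the best validation epoch are
#' returned. Deterministic for a fixed `config$seed`.
#'
#' @param model a [build_model()] model.
#' @param train,val datasets: `list(x = <list of matrices>, y = <list of
#'   binary matrices>)`, in preprocessed coordinates.
#' @param config a [train_config()].
#' @param augment optional [augment_config()] applied on the fly to
#'   training samples.
#' @param verbose print per-epoch losses.
#' @return list with `model` (best-validation weights), `history`
#'   (data.frame of per-epoch train/validation loss), `stopped_epoch` and
#'   `best_epoch`.
#' @export
train_model <- function(model, train, val, config = train_config(),
                        augment = NULL, verbose = FALSE) {
  if (!length(train$x) || !length(val$x))
    stop("empty dataset", call. = FALSE)
  if (length(train$x) != length(train$y))
    stop("train images and masks differ in length", call. = FALSE)
  cfg <- config
  p <- model$params
  mstate <- lapply(p, function(a) a * 0)
  vstate <- lapply(p, function(a) a * 0)
  kernel <- vapply(names(p), is_kernel_param, logical(1))
  lr_mult <- rep(1, length(p))
  if (!is.null(cfg$lr_multipliers)) {
    for (g in names(cfg$lr_multipliers)) {
      hit <- startsWith(names(p), g)
      lr_mult[hit] <- cfg$lr_multipliers[[g]]
    }
  }
  step <- 0L
  hist_tr <- numeric(0); hist_val <- numeric(0)
  best <- Inf; best_params <- p; best_epoch <- 0L
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(length(train$x))
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      ep_loss <- 0
      for (b in batches) {
        grads <- NULL
        bl <- 0
        for (i in b) {
          xi <- train$x[[i]]; yi <- train$y[[i]] * 1
          if (!is.null(augment)) {
            a <- stochastic_augment(xi, augment, yi)
            xi <- a$image; yi <- a$mask
          }
          model$params <- p
          fw <- seg_forward(model, xi, training = TRUE, keep_cache = TRUE)
          bl <- bl + dice_loss(fw$prob, yi)
          dp <- dice_loss_grad(fw$prob, yi) / length(b)
          gi <- seg_backward(model, fw$cache, dp)
          grads <- if (is.null(grads)) gi else
            mapply(`+`, grads, gi, SIMPLIFY = FALSE)
        }
        ep_loss <- ep_loss + bl
        step <- step + 1L
        bc1 <- 1 - cfg$beta1^step
        bc2 <- 1 - cfg$beta2^step
        for (j in seq_along(p)) {
          g <- grads[[j]]
          if (kernel[j] && cfg$l2_kernel_weight > 0)
            g <- g + 2 * cfg$l2_kernel_weight * p[[j]]
          mstate[[j]] <- cfg$beta1 * mstate[[j]] + (1 - cfg$beta1) * g
          vstate[[j]] <- cfg$beta2 * vstate[[j]] + (1 - cfg$beta2) * g^2
          upd <- (mstate[[j]] / bc1) /
            (sqrt(vstate[[j]] / bc2) + cfg$epsilon)
          lr <- cfg$learning_rate * lr_mult[j]
          p[[j]] <- p[[j]] - lr * upd - lr * cfg$weight_decay * p[[j]]
        }
      }
      model$params <- p
      vl <- validation_loss(model, val)
      hist_tr <- c(hist_tr, ep_loss / length(train$x))
      hist_val <- c(hist_val, vl)
      if (verbose)
        message(sprintf("epoch %d: train %.4f val %.4f", epoch,
                        hist_tr[epoch], vl))
      if (vl < best) {
        best <- vl
        best_params <- p
        best_epoch <- epoch
      }
      if (!is.na(early_stopping_epoch(hist_val, cfg$patience))) break
    }
  })
  model$params <- best_params
  list(model = model,
       history = data.frame(epoch = seq_along(hist_val),
                            train_loss = hist_tr, val_loss = hist_val),
       stopped_epoch = length(hist_val), best_epoch = best_epoch)
}

same_architecture <- function(a, b) {
  identical(a$config[c("init_filters", "n_levels", "blocks_per_level",
                       "conv_kernel", "norm_groups")],
            b$config[c("init_filters", "n_levels", "blocks_per_level",
                       "conv_kernel", "norm_groups")])
}

#' Initialize a model from a pretrained model (transfer learning)
#'
#' Copies the pretrained weights into an architecturally identical model
#' instead of random initialization: encoder weights always, decoder and
#' head weights by default (`include_decoder = FALSE` gives the
#' encoder-only mode). Layer-wise fine-tuning is available through
#' `lr_multipliers` in [train_config()].
#'
#' @param model target model.
#' @param pretrained source model (e.g. trained on calcification phantoms).
#' @param include_decoder also copy decoder and head weights.
#' @return `model` with transferred weights.
#' @export
transfer_init <- function(model, pretrained, include_decoder = TRUE) {
  if (!same_architecture(model, pretrained))
    stop("transfer error: architectures differ", call. = FALSE)
  take <- if (include_decoder) names(model$params) else
    grep("^(stem|enc)", names(model$params), value = TRUE)
  model$params[take] <- pretrained$params[take]
  model
}

#' Predict a fibrous-cap mask for one preprocessed frame
#'
#' @param model trained `seg_model`.
#' @param frame preprocessed, normalized polar frame matching the model's
#'   `input_size` (raw-shaped input is rejected).
#' @param threshold probability threshold (default from the model config).
#' @return logical mask with `space = "shifted"`, plus the probability map
#'   in attribute `prob`.
#' @export
predict_mask <- function(model, frame, threshold = NULL) {
  if (inherits(frame, "polar_pullback")) {
    if (!frame$preprocessed)
      stop("predict error: pullback is not preprocessed", call. = FALSE)
    frame <- frame$frames[, , 1]
  }
  if (!identical(as.integer(dim(frame)), model$input_size))
    stop("predict error: expected a preprocessed ", model$input_size[1],
         " x ", model$input_size[2], " frame", call. = FALSE)
  threshold <- threshold %||% model$config$threshold
  prob <- seg_forward(model, frame)$prob
  mask <- prob >= threshold
  attr(mask, "space") <- "shifted"
  attr(mask, "prob") <- prob
  mask
}

#' @export
predict.seg_model <- function(object, frame, threshold = NULL, ...) {
  predict_mask(object, frame, threshold)
}

#' Plurality vote over an ensemble of masks
#'
#' Per pixel, the majority label across the input masks; ties are resolved
#' to negative (conservative toward false positives, consistent with the
#' postprocessing intent).
#'
#' @param masks list of binary masks of identical shape.
#' @return logical matrix.
#' @export
ensemble_vote <- function(masks) {
  if (!length(masks)) stop("ensemble_vote: no masks", call. = FALSE)
  d <- dim(masks[[1]])
  for (m in masks)
    if (!identical(dim(m), d))
      stop("ensemble_vote: shape mismatch", call. = FALSE)
  s <- Reduce(`+`, lapply(masks, function(m) (m != 0) * 1))
  out <- s > length(masks) / 2
  attr(out, "space") <- attr(masks[[1]], "space")
  out
}

model_arch_hash <- function(model) {
  js <- jsonlite::toJSON(model$config[order(names(model$config))],
                         auto_unbox = TRUE)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}

#' Save / load a model checkpoint
#'
#' Serialized weights with an architecture-hash header; loading verifies
#' the hash.
#'
#' @param model a `seg_model`.
#' @param path checkpoint path.
#' @return `load_model` returns the model.
#' @export
save_model <- function(model, path) {
  saveRDS(list(arch_hash = model_arch_hash(model), config = model$config,
               input_size = model$input_size, params = model$params),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  model <- structure(list(config = obj$config, input_size = obj$input_size,
                          params = obj$params), class = "seg_model")
  if (!identical(model_arch_hash(model), obj$arch_hash))
    stop("checkpoint error: architecture hash mismatch", call. = FALSE)
  model
}
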