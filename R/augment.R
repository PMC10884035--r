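#' Augmentation configuration
#'
#' Two complementary schemes: loss-free spiral rotation offsets applied to
#' raw pullbacks (the helical A-line stream is re-framed at shifted starting
#' angles, creating new frames without interpolation), and stochastic
#' flip/intensity augmentation applied to preprocessed images.
#'
#' @param n_offsets number of spiral offset copies (default 6; the original
#'   pullback is not counted).
#' @param offset_increment A-lines per offset step (default 80).
#' @param flip_prob probability of reversing the theta axis.
#' @param intensity_scale_factor half-width of the multiplicative intensity
#'   jitter; factors are drawn from `[1 - f, 1 + f]`.
#' @param intensity_scale_prob probability of applying the scale jitter.
#' @param intensity_shift_factor half-width of the additive intensity
#'   jitter, drawn from `[-f, f]`.
#' @param intensity_shift_prob probability of applying the shift jitter.
#' @param seed seed for materialized augmentation runs.
#' @return object of class `augment_config`.
#' @export
augment_config <- function(n_offsets = 6L, offset_increment = 80L,
                           flip_prob = 0.10,
                           intensity_scale_factor = 0.1,
                           intensity_scale_prob = 0.20,
                           intensity_shift_factor = 0.1,
                           intensity_shift_prob = 0.20,
                           seed = 1L) {
  probs <- c(flip_prob, intensity_scale_prob, intensity_shift_prob)
  if (any(probs < 0) || any(probs > 1))
    stop("augment config error: probabilities must lie in [0, 1]",
         call. = FALSE)
  if (n_offsets < 0 || offset_increment < 1)
    stop("augment config error: invalid offset settings", call. = FALSE)
  structure(list(n_offsets = as.integer(n_offsets),
                 offset_increment = as.integer(offset_increment),
                 flip_prob = flip_prob,
                 intensity_scale_factor = intensity_scale_factor,
                 intensity_scale_prob = intensity_scale_prob,
                 intensity_shift_factor = intensity_shift_factor,
                 intensity_shift_prob = intensity_shift_prob,
                 seed = as.integer(seed)),
            class = "augment_config")
}

#' Loss-free spiral rotation offsets of a raw pullback
#'
#' All raw polar frames are concatenated along theta into one large 2-D
#' array (the continuous helical acquisition); for offset k the array is
#' re-framed starting at A-line `k * offset_increment`, wrapping circularly
#' across the pullback end so every copy keeps the full frame count and the
#' multiset of A-lines is preserved. Masks, when provided, are re-framed
#' identically.
#'
#' @param pullback a raw [polar_pullback()] (preprocessed input is an
#'   order-of-operations error).
#' @param config an [augment_config()].
#' @param masks optional raw-coordinate label array matching the frames.
#' @return list of `n_offsets` elements, each `list(pullback, masks)`
#'   (`masks` `NULL` when not supplied).
#' @export
spiral_offsets <- function(pullback, config = augment_config(),
                           masks = NULL) {
  stopifnot(inherits(pullback, "polar_pullback"))
  if (pullback$preprocessed)
    stop("spiral offsets must be applied before preprocessing", call. = FALSE)
  W <- pullback$n_alines; nf <- pullback$n_frames
  total <- W * nf
  if (config$n_offsets * config$offset_increment >= total)
    stop("augment config error: offsets exceed the concatenated pullback",
         call. = FALSE)
  big <- matrix(pullback$frames, pullback$r_size, total)
  bigm <- if (!is.null(masks)) matrix(masks * 1, dim(masks)[1], total)
  lapply(seq_len(config$n_offsets), function(k) {
    off <- k * config$offset_increment
    idx <- ((seq_len(total) - 1L + off) %% total) + 1L
    pb <- polar_pullback(array(big[, idx], c(pullback$r_size, W, nf)),
                         pixel_size_r = pullback$pixel_size_r,
                         frame_pitch = pullback$frame_pitch,
                         preprocessed = FALSE)
    mk <- if (!is.null(bigm))
      array(bigm[, idx] > 0.5, c(dim(masks)[1], W, nf))
    list(pullback = pb, masks = mk)
  })
}

#' Stochastic flip/intensity augmentation of a preprocessed image
#'
#' With `flip_prob`, the theta axis is reversed; with
#' `intensity_scale_prob`, intensities are multiplied by a factor drawn
#' uniformly from `[1 - f, 1 + f]`; with `intensity_shift_prob`, an offset
#' drawn uniformly from `[-f, f]` is added. The result is clipped to
#' `[0, 1]`. Spatial transforms are applied identically to the mask. Draws
#' come from the caller's RNG stream, so results are deterministic under a
#' fixed seed.
#'
#' @param image normalized preprocessed image in `[0, 1]`.
#' @param config an [augment_config()].
#' @param mask optional label matrix, flipped in sync.
#' @return augmented image, or `list(image, mask)` when a mask is given.
#' @export
stochastic_augment <- function(image, config = augment_config(),
                               mask = NULL) {
  if (min(image) < 0 || max(image) > 1)
    stop("stochastic_augment expects a normalized image in [0, 1]",
         call. = FALSE)
  W <- ncol(image)
  if (runif(1) < config$flip_prob) {
    image <- image[, W:1, drop = FALSE]
    if (!is.null(mask)) mask <- mask[, W:1, drop = FALSE]
  }
  if (runif(1) < config$intensity_scale_prob)
    image <- image * runif(1, 1 - config$intensity_scale_factor,
                           1 + config$intensity_scale_factor)
  if (runif(1) < config$intensity_shift_prob)
    image <- image + runif(1, -config$intensity_shift_factor,
                           config$intensity_shift_factor)
  image <- pmin(pmax(image, 0), 1)
  if (is.null(mask)) image else list(image = image, mask = mask)
}
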