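#' Polar-domain IVOCT pullback container
#'
#' A pullback is a stack of polar frames indexed (r, theta, frame): rows are
#' radial samples along each A-line, columns are A-lines (catheter rotation),
#' slices are frames along the pullback. Intensities are stored in `[0, 1]`.
#'
#' @param frames numeric 3-D array `(r_size, n_alines, n_frames)`; a single
#'   matrix is promoted to a one-frame stack.
#' @param pixel_size_r radial pixel size, micrometres.
#' @param frame_pitch frame-to-frame spacing, millimetres.
#' @param preprocessed logical flag; `TRUE` once the five-step preprocessing
#'   chain has been applied (frames then have 200 radial samples by default).
#' @return an object of class `polar_pullback`.
#' @export
polar_pullback <- function(frames, pixel_size_r = 5, frame_pitch = 0.2,
                           preprocessed = FALSE) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("frames must be a (r_size x n_alines x n_frames) array",
         call. = FALSE)
  if (any(!is.finite(frames)))
    stop("frames must be finite", call. = FALSE)
  structure(list(frames = frames,
                 r_size = dim(frames)[1], n_alines = dim(frames)[2],
                 n_frames = dim(frames)[3],
                 pixel_size_r = pixel_size_r, frame_pitch = frame_pitch,
                 preprocessed = isTRUE(preprocessed)),
            class = "polar_pullback")
}

#' @export
print.polar_pullback <- function(x, ...) {
  cat(sprintf("polar_pullback: %d frame(s) of %d x %d (r x theta), %s\n",
              x$n_frames, x$r_size, x$n_alines,
              if (x$preprocessed) "preprocessed" else "raw"))
  cat(sprintf("  pixel_size_r = %g um, frame_pitch = %g mm\n",
              x$pixel_size_r, x$frame_pitch))
  invisible(x)
}

pullback_meta_fields <- c("r_size", "n_alines", "n_frames", "pixel_size_r",
                          "frame_pitch", "preprocessed", "bits_per_sample")

#' Write / read a pullback as a multi-frame TIFF with a JSON sidecar
#'
#' Intensities are quantized to 16-bit; a further write/read cycle is then
#' bit-identical. The sidecar (`<path>.json`) records geometry and encoding.
#'
#' @param pullback a [polar_pullback()].
#' @param path output path for the TIFF (the sidecar adds `.json`).
#' @return `write_pullback` returns `path` invisibly; `read_pullback`
#'   returns a [polar_pullback()].
#' @export
write_pullback <- function(pullback, path) {
  stopifnot(inherits(pullback, "polar_pullback"))
  fr <- lapply(seq_len(pullback$n_frames),
               function(f) pullback$frames[, , f])
  tiff::writeTIFF(fr, path, bits.per.sample = 16L, compression = "none")
  meta <- list(r_size = pullback$r_size, n_alines = pullback$n_alines,
               n_frames = pullback$n_frames,
               pixel_size_r = pullback$pixel_size_r,
               frame_pitch = pullback$frame_pitch,
               preprocessed = pullback$preprocessed,
               bits_per_sample = 16L)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_pullback
#' @export
read_pullback <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("format error: missing metadata sidecar ", sidecar, call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  missing <- setdiff(pullback_meta_fields, names(meta))
  if (length(missing))
    stop("format error: metadata missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  fr <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(fr)) fr <- list(fr)
  dims <- vapply(fr, function(m) dim(m)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("format error: frames of unequal size in stack", call. = FALSE)
  if (dims[1, 1] != meta$r_size || dims[2, 1] != meta$n_alines ||
      length(fr) != meta$n_frames)
    stop("format error: stack shape does not match metadata", call. = FALSE)
  arr <- array(unlist(fr), c(dims[1, 1], dims[2, 1], length(fr)))
  polar_pullback(arr, pixel_size_r = meta$pixel_size_r,
                 frame_pitch = meta$frame_pitch,
                 preprocessed = meta$preprocessed)
}

#' Write / read a binary mask stack as multi-frame TIFF
#'
#' @param mask logical/binary array `(r x theta x frames)` or matrix.
#' @param path TIFF path.
#' @return `read_mask_stack` returns a logical array.
#' @export
write_mask_stack <- function(mask, path) {
  if (is.matrix(mask)) mask <- array(mask, c(dim(mask), 1L))
  fr <- lapply(seq_len(dim(mask)[3]), function(f) (mask[, , f] != 0) * 1)
  tiff::writeTIFF(fr, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' @rdname write_mask_stack
#' @export
read_mask_stack <- function(path) {
  fr <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(fr)) fr <- list(fr)
  array(unlist(fr) > 0.5, c(dim(fr[[1]])[1], dim(fr[[1]])[2], length(fr)))
}

#' Convert a polar frame to a Cartesian display image
#'
#' Resamples an (r, theta) frame onto an (x, y) raster about the catheter
#' centre. One Cartesian pixel equals one radial pixel; theta = 0 maps to the
#' +x axis. Display-only: the optional log transform `log(1 + k I)/log(1 + k)`
#' is never fed back into analysis.
#'
#' @param frame polar intensity matrix (r x theta).
#' @param out_size side length of the square output (default `2 * nrow`).
#' @param interp `"bilinear"` for intensities, `"nearest"` for masks.
#' @param log_display apply the display log transform.
#' @param log_k gain of the log transform.
#' @return square numeric matrix.
#' @export
to_cartesian <- function(frame, out_size = 2L * nrow(frame),
                         interp = c("bilinear", "nearest"),
                         log_display = FALSE, log_k = 50) {
  interp <- match.arg(interp)
  if (any(!is.finite(frame))) stop("frame must be finite", call. = FALSE)
  H <- nrow(frame); W <- ncol(frame)
  ctr <- (out_size + 1) / 2
  xs <- matrix(rep(seq_len(out_size), each = out_size), out_size) - ctr
  ys <- matrix(rep(seq_len(out_size), out_size), out_size) - ctr
  r <- sqrt(xs^2 + ys^2)
  th <- atan2(ys, xs) %% (2 * pi)
  al <- th / (2 * pi) * W            # fractional A-line index, 0-based
  r <- as.vector(r); al <- as.vector(al)
  inside <- r <= (H - 1)
  out <- matrix(0, out_size, out_size)
  if (interp == "nearest") {
    i <- pmin(H - 1, round(r)) + 1
    j <- (round(al) %% W) + 1
    out[inside] <- frame[cbind(i[inside], j[inside])]
  } else {
    i0 <- pmin(H - 1, floor(r)); i1 <- pmin(H - 1, i0 + 1); a <- r - i0
    j0 <- floor(al) %% W; j1 <- (j0 + 1) %% W; bfr <- al - floor(al)
    v <- (1 - a) * ((1 - bfr) * frame[cbind(i0 + 1, j0 + 1)] +
                      bfr * frame[cbind(i0 + 1, j1 + 1)]) +
      a * ((1 - bfr) * frame[cbind(i1 + 1, j0 + 1)] +
             bfr * frame[cbind(i1 + 1, j1 + 1)])
    out[inside] <- v[inside]
  }
  if (log_display) out <- log1p(log_k * out) / log1p(log_k)
  out
}

#' Export a Cartesian overlay PNG with the mask in green
#'
#' @param frame polar intensity matrix.
#' @param mask binary polar mask of the same shape.
#' @param path output PNG path.
#' @param log_display,log_k display log transform, see [to_cartesian()].
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(frame, mask, path, log_display = TRUE,
                              log_k = 50) {
  img <- to_cartesian(frame, log_display = log_display, log_k = log_k)
  mc <- to_cartesian((mask != 0) * 1, interp = "nearest") > 0.5
  rgb <- array(img, c(dim(img), 3))
  rgb[, , 1][mc] <- rgb[, , 1][mc] * 0.3
  rgb[, , 2][mc] <- pmin(1, 0.6 + 0.4 * rgb[, , 2][mc])
  rgb[, , 3][mc] <- rgb[, , 3][mc] * 0.3
  png::writePNG(rgb, path)
  invisible(path)
}
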