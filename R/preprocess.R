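#' Detect the guidewire shadow band of a polar frame
#'
#' The metal guidewire occludes the beam and leaves a contiguous (modulo the
#' theta wrap) band of A-lines with near-zero depth-summed intensity. A-lines
#' whose depth-averaged intensity falls below `deficit` times the frame
#' median are grouped into wrapped runs; the run with the lowest mean whose
#' width lies in `width_range` is returned.
#'
#' @param frame raw polar frame (r x theta).
#' @param width_range admissible band widths in A-lines.
#' @param deficit required intensity deficit relative to the median
#'   depth-averaged A-line intensity (0.5 = at least 50 percent darker).
#' @return integer vector of occluded A-line indices (1-based, sorted);
#'   empty when no band qualifies (e.g. uniform frames).
#' @export
detect_guidewire <- function(frame, width_range = c(10L, 60L),
                             deficit = 0.5) {
  s <- colMeans(frame)
  n <- length(s)
  if (max(s) - min(s) < 1e-12) return(integer(0))
  low <- s < deficit * median(s)
  if (!any(low) || all(low)) return(integer(0))
  # wrapped runs of low columns: rotate so position 1 is not low
  start <- which(!low)[1]
  rot <- c(low[start:n], low[seq_len(start - 1)])
  r <- rle(rot)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  best <- NULL; best_mean <- Inf
  for (k in which(r$values)) {
    idx <- ((begins[k]:ends[k]) + start - 2L) %% n + 1L
    if (length(idx) < width_range[1] || length(idx) > width_range[2]) next
    m <- mean(s[idx])
    if (m < best_mean) {
      best_mean <- m
      best <- idx
    }
  }
  if (is.null(best)) integer(0) else sort(best)
}

#' Segment the lumen boundary of a polar frame
#'
#' Scores each radial position with a step-edge filter (mean intensity just
#' abluminal minus just luminal) and extracts the per-A-line boundary by
#' dynamic programming with an L1 smoothness penalty, treating theta as
#' circular. Guidewire A-lines contribute a flat cost and are then linearly
#' interpolated from their neighbours across the wrap.
#'
#' @param frame raw polar frame.
#' @param guidewire_alines indices from [detect_guidewire()].
#' @param lambda smoothness penalty per pixel of radial jump between
#'   neighbouring A-lines (intensity units).
#' @param edge_halfwin half-window of the step-edge filter, pixels.
#' @param min_intensity frames whose maximum is below this are rejected as
#'   having no detectable lumen.
#' @return list with `boundary` (0-based radial index of the lumen surface
#'   per A-line; equals the pixel-shift amount) and `guidewire_alines`.
#' @export
segment_lumen <- function(frame, guidewire_alines = integer(0),
                          lambda = 0.05, edge_halfwin = 5L,
                          min_intensity = 0.05) {
  H <- nrow(frame); W <- ncol(frame)
  if (max(frame) < min_intensity)
    stop("no detectable lumen: frame is dark", call. = FALSE)
  w <- edge_halfwin
  csp <- rbind(0, apply(frame, 2, cumsum))        # csp[i+1, ] = cumsum to row i
  rr <- seq_len(H)
  after <- (csp[pmin(rr + w, H + 1), , drop = FALSE] -
              csp[rr, , drop = FALSE]) / w
  before <- (csp[rr, , drop = FALSE] -
               csp[pmax(rr - w, 0) + 1, , drop = FALSE]) / w
  cost <- -(after - before)
  if (length(guidewire_alines)) cost[, guidewire_alines] <- 0
  b <- as.integer(cpp_dp_boundary(cost, lambda, TRUE))
  if (length(guidewire_alines))
    b <- interp_circular(b, guidewire_alines)
  list(boundary = b, guidewire_alines = guidewire_alines)
}

# Linear interpolation of integer-valued samples across bad indices on a
# circular domain.
interp_circular <- function(v, bad) {
  n <- length(v)
  good <- setdiff(seq_len(n), bad)
  if (!length(good)) return(v)
  # unroll: interpolate on index line with wrapped anchors on both sides
  xg <- c(good - n, good, good + n)
  yg <- rep(v[good], 3)
  as.integer(round(approx(xg, yg, xout = seq_len(n))$y))
}

#' Pixel-shift A-lines so the lumen surface sits at radial index zero
#'
#' Column `j` of the output is column `j` of the input shifted left (toward
#' r = 0) by `boundary[j]` pixels; vacated deep pixels are zero-filled. The
#' returned shift record equals the boundary and inverts the map on all
#' retained pixels.
#'
#' @param frame polar frame (r x theta).
#' @param boundary 0-based lumen boundary per A-line (from
#'   [segment_lumen()]), or a list as returned by it.
#' @return list with `frame` (shifted) and `shift` (per-A-line left shift).
#' @export
pixel_shift <- function(frame, boundary) {
  if (is.list(boundary)) boundary <- boundary$boundary
  H <- nrow(frame); W <- ncol(frame)
  if (length(boundary) != W)
    stop("boundary must have one entry per A-line", call. = FALSE)
  if (any(boundary < 0L) || any(boundary >= H))
    stop("boundary index out of range", call. = FALSE)
  out <- matrix(0, H, W)
  for (j in seq_len(W)) {
    b <- boundary[j]
    if (b == 0L) out[, j] <- frame[, j]
    else out[seq_len(H - b), j] <- frame[(b + 1L):H, j]
  }
  list(frame = out, shift = as.integer(boundary))
}

#' Invert a pixel shift on all retained pixels
#'
#' @param frame shifted frame.
#' @param shift per-A-line shift record from [pixel_shift()].
#' @return frame in raw radial coordinates (vacated luminal pixels zero).
#' @export
unshift <- function(frame, shift) {
  H <- nrow(frame); W <- ncol(frame)
  out <- matrix(0, H, W)
  for (j in seq_len(W)) {
    b <- shift[j]
    if (b == 0L) out[, j] <- frame[, j]
    else out[(b + 1L):H, j] <- frame[seq_len(H - b), j]
  }
  out
}

#' Apply a shift record to a binary mask (image/label synchrony)
#'
#' @param mask binary matrix in raw coordinates.
#' @param shift per-A-line shift record.
#' @return shifted mask with attributes `space = "shifted"` and
#'   `shift_record`.
#' @export
shift_mask <- function(mask, shift) {
  out <- pixel_shift(mask * 1, shift)$frame > 0.5
  attr(out, "space") <- "shifted"
  attr(out, "shift_record") <- as.integer(shift)
  out
}

#' Crop a frame to the first `depth` radial pixels
#'
#' @param frame polar frame.
#' @param depth retained radial extent (200 pixels ~ 1 mm at 5 um/pixel).
#' @return frame of `depth` rows; theta size unchanged.
#' @export
crop_depth <- function(frame, depth = 200L) {
  if (nrow(frame) < depth)
    stop("crop error: frame has fewer than ", depth, " radial pixels",
         call. = FALSE)
  frame[seq_len(depth), , drop = FALSE]
}

gaussian_kernel2d <- function(kernel = 7L, sigma = 1) {
  off <- seq_len(kernel) - (kernel + 1) / 2
  k <- exp(-outer(off^2, off^2, "+") / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian noise filtering of a polar frame
#'
#' 2-D Gaussian convolution truncated to a `kernel x kernel` window. The
#' theta axis is treated circularly (acquisition geometry); the r axis uses
#' mirror padding.
#'
#' @param frame polar frame.
#' @param kernel odd window size (default 7).
#' @param sigma standard deviation in pixels (default 1).
#' @return filtered frame, same shape.
#' @export
smooth_frame <- function(frame, kernel = 7L, sigma = 1) {
  if (any(!is.finite(frame))) stop("frame must be finite", call. = FALSE)
  h <- (kernel - 1L) %/% 2L
  H <- nrow(frame); W <- ncol(frame)
  padded <- frame[c(h:1, seq_len(H), H:(H - h + 1L)), , drop = FALSE]
  jj <- c(W - h + seq_len(h), seq_len(W), seq_len(h))
  padded <- padded[, jj, drop = FALSE]
  k <- gaussian_kernel2d(kernel, sigma)
  x <- array(padded, c(dim(padded), 1L))
  out <- cpp_conv2d_fwd(x, matrix(k, kernel * kernel, 1), 0, kernel, 1L, 0L)
  matrix(out, H, W)
}

#' Five-step preprocessing of a raw pullback
#'
#' Per frame: guidewire-shadow detection, lumen segmentation, zeroing of the
#' occluded A-lines (the "black strip"), pixel-shifting so every A-line
#' starts at the lumen surface, depth cropping, and Gaussian smoothing.
#' Intensities are then min-max normalized to `[0, 1]` over the whole
#' pullback.
#'
#' @param pullback a raw [polar_pullback()].
#' @param depth radial crop depth (default 200).
#' @param kernel,sigma Gaussian filter parameters.
#' @param lumen_backend function `(frame, guidewire_alines)` returning a
#'   lumen boundary list; defaults to [segment_lumen()]. A learned model can
#'   be plugged in here.
#' @param guidewire_width_range,guidewire_deficit passed to
#'   [detect_guidewire()].
#' @return list with `pullback` (preprocessed, `depth x n_alines` frames),
#'   `boundaries` (n_alines x n_frames matrix of 0-based lumen indices),
#'   `shifts` (identical to `boundaries`; the per-frame shift records) and
#'   `guidewire` (per-frame A-line index sets).
#' @export
preprocess_pullback <- function(pullback, depth = 200L, kernel = 7L,
                                sigma = 1, lumen_backend = NULL,
                                guidewire_width_range = c(10L, 60L),
                                guidewire_deficit = 0.5) {
  stopifnot(inherits(pullback, "polar_pullback"))
  if (pullback$preprocessed)
    stop("pullback is already preprocessed", call. = FALSE)
  if (is.null(lumen_backend)) lumen_backend <- segment_lumen
  nf <- pullback$n_frames; W <- pullback$n_alines
  out <- array(0, c(depth, W, nf))
  boundaries <- matrix(0L, W, nf)
  gw <- vector("list", nf)
  for (f in seq_len(nf)) {
    fr <- pullback$frames[, , f]
    g <- detect_guidewire(fr, guidewire_width_range, guidewire_deficit)
    lb <- lumen_backend(fr, g)
    if (length(g)) fr[, g] <- 0
    sh <- pixel_shift(fr, lb$boundary)
    out[, , f] <- smooth_frame(crop_depth(sh$frame, depth), kernel, sigma)
    boundaries[, f] <- sh$shift
    gw[[f]] <- g
  }
  rng <- range(out)
  if (diff(rng) > 0) out <- (out - rng[1]) / diff(rng)
  list(pullback = polar_pullback(out, pixel_size_r = pullback$pixel_size_r,
                                 frame_pitch = pullback$frame_pitch,
                                 preprocessed = TRUE),
       boundaries = boundaries, shifts = boundaries, guidewire = gw)
}

#' Transform a raw-coordinate mask stack with preprocessing shift records
#'
#' @param mask_stack logical array in raw coordinates.
#' @param shifts n_alines x n_frames shift matrix from
#'   [preprocess_pullback()].
#' @param depth radial crop depth.
#' @return logical array in shifted coordinates (`space` attribute set).
#' @export
preprocess_mask <- function(mask_stack, shifts, depth = 200L) {
  if (is.matrix(mask_stack))
    mask_stack <- array(mask_stack, c(dim(mask_stack), 1L))
  nf <- dim(mask_stack)[3]
  out <- array(FALSE, c(depth, dim(mask_stack)[2], nf))
  for (f in seq_len(nf)) {
    m <- shift_mask(mask_stack[, , f], shifts[, f])
    out[, , f] <- crop_depth(m * 1, depth) > 0.5
  }
  attr(out, "space") <- "shifted"
  out
}
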