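#' Euclidean disk structuring element
#'
#' @param radius disk radius in pixels; offsets with `dx^2 + dy^2 <=
#'   radius^2` are included.
#' @return binary matrix of size `2 * radius + 1`.
#' @export
disk_kernel <- function(radius = 3L) {
  off <- -radius:radius
  (outer(off^2, off^2, "+") <= radius^2) * 1
}

#' Morphological cleanup of a predicted cap mask
#'
#' Opening with a disk-shaped structuring element (radius 3 by default)
#' removes spotty false positives, then holes - background components not
#' 4-connected to the radial borders - are filled. The theta axis is
#' treated circularly throughout, so lesions straddling the theta = 0 seam
#' are neither split nor opened at the seam; the fill border is defined on
#' the r axis only.
#'
#' @param mask binary matrix (r x theta).
#' @param radius opening disk radius.
#' @param connectivity hole-filling pixel connectivity (4, the only
#'   supported rule).
#' @param wrap_theta treat theta circularly.
#' @return cleaned logical mask (attributes preserved).
#' @export
open_and_fill <- function(mask, radius = 3L, connectivity = 4L,
                          wrap_theta = TRUE) {
  if (!all(mask %in% c(0, 1)) && !is.logical(mask))
    stop("postprocess error: mask must be binary", call. = FALSE)
  if (connectivity != 4L)
    stop("postprocess error: only 4-connectivity is supported",
         call. = FALSE)
  atts <- attributes(mask)[c("space", "shift_record")]
  m <- (mask != 0) * 1
  H <- nrow(m); W <- ncol(m)
  r <- radius
  # pad by 2r: background beyond the r borders, circular wrap in theta
  # (the eroded pixels that dilation reads up to r outside the crop need
  # their own full r-neighbourhood)
  p <- 2L * r
  jj <- (((-p + 1L):(W + p) - 1L) %% W) + 1L
  padded <- rbind(matrix(0, p, W + 2L * p),
                  m[, jj, drop = FALSE],
                  matrix(0, p, W + 2L * p))
  kern <- disk_kernel(r)
  opened <- EBImage::dilate(EBImage::erode(padded, kern), kern)
  opened <- matrix(as.numeric(opened), nrow(padded), ncol(padded))
  opened <- opened[p + seq_len(H), p + seq_len(W), drop = FALSE] > 0.5
  out <- cpp_fill_holes(opened, wrap_theta)
  out <- matrix(as.logical(out), H, W)
  for (nm in names(atts))
    if (!is.null(atts[[nm]])) attr(out, nm) <- atts[[nm]]
  out
}

#' Postprocess every frame of a mask stack
#'
#' @param mask_stack logical array (r x theta x frames).
#' @inheritParams open_and_fill
#' @return cleaned logical array.
#' @export
postprocess_stack <- function(mask_stack, radius = 3L, connectivity = 4L,
                              wrap_theta = TRUE) {
  if (is.matrix(mask_stack))
    return(open_and_fill(mask_stack, radius, connectivity, wrap_theta))
  out <- mask_stack
  for (f in seq_len(dim(mask_stack)[3]))
    out[, , f] <- open_and_fill(mask_stack[, , f], radius, connectivity,
                                wrap_theta)
  out
}
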