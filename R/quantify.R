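#' Per-A-line fibrous-cap thickness
#'
#' Thickness along A-line `j` is the radial span of the cap column,
#' `(abluminal index - luminal index + 1) * pixel_size_r`, measured in the
#' pixel-shifted (preprocessed) coordinate space; A-lines without cap are
#' `NA` and excluded from means.
#'
#' @param mask binary mask matrix (r x theta) or stack (r x theta x
#'   frames) in shifted coordinates; masks whose `space` attribute is
#'   `"raw"` are rejected.
#' @param pixel_size_r radial pixel size, micrometres.
#' @return n_frames x n_alines matrix of thickness in micrometres.
#' @export
aline_thickness <- function(mask, pixel_size_r = 5) {
  space <- attr(mask, "space") %||% "shifted"
  if (identical(space, "raw"))
    stop("thickness error: mask is in raw coordinates; apply the shift ",
         "record first", call. = FALSE)
  if (is.matrix(mask)) mask <- array(mask, c(dim(mask), 1L))
  nf <- dim(mask)[3]; W <- dim(mask)[2]
  out <- matrix(NA_real_, nf, W)
  for (f in seq_len(nf)) {
    m <- mask[, , f] != 0
    cols <- which(colSums(m) > 0)
    for (j in cols) {
      r <- range(which(m[, j]))
      out[f, j] <- (r[2] - r[1] + 1) * pixel_size_r
    }
  }
  out
}

# Runs of TRUE on a circular index set; returns a list of 1-based index
# vectors, merging runs across the theta seam.
wrap_runs <- function(v) {
  n <- length(v)
  if (!any(v)) return(list())
  if (all(v)) return(list(seq_len(n)))
  start <- which(!v)[1]
  rot <- c(v[start:n], v[seq_len(start - 1L)])
  r <- rle(rot)
  ends <- cumsum(r$lengths); begins <- ends - r$lengths + 1L
  lapply(which(r$values), function(k)
    sort(((begins[k]:ends[k]) + start - 2L) %% n + 1L))
}

#' Cross-sectional cap area of one frame
#'
#' Sum of polar area elements `r * dr * dtheta` over mask pixels, with `r`
#' the pixel's true radial distance from the catheter centre restored via
#' the pixel-shift record (polar pixel area grows with r, so naive pixel
#' counting would bias the area).
#'
#' @param mask binary mask matrix in shifted coordinates.
#' @param shift_record per-A-line shift (lumen boundary index); taken from
#'   the mask's `shift_record` attribute when missing.
#' @param pixel_size_r radial pixel size, micrometres.
#' @return area in mm^2.
#' @export
fc_area <- function(mask, shift_record = NULL, pixel_size_r = 5) {
  shift_record <- shift_record %||% attr(mask, "shift_record")
  if (is.null(shift_record))
    stop("area error: missing shift record", call. = FALSE)
  W <- ncol(mask)
  if (length(shift_record) != W)
    stop("area error: shift record length mismatch", call. = FALSE)
  px <- which(mask != 0, arr.ind = TRUE)
  if (!nrow(px)) return(0)
  ridx <- shift_record[px[, 2]] + px[, 1] - 1  # 0-based true radial index
  dr <- pixel_size_r / 1000
  dth <- 2 * pi / W
  sum((ridx + 0.5) * dr^2 * dth)
}

#' Longitudinal (luminal) cap surface area
#'
#' Per frame, the luminal arc length subtended by the cap (computed at the
#' lumen radius) times the frame pitch, summed over frames.
#'
#' @param mask_stack binary array (r x theta x frames) in shifted space.
#' @param lumen_boundary n_alines x n_frames matrix of 0-based lumen
#'   indices.
#' @param pixel_size_r radial pixel size, micrometres.
#' @param frame_pitch frame spacing, mm.
#' @return surface area in mm^2, with per-frame values in attribute
#'   `per_frame`.
#' @export
surface_area <- function(mask_stack, lumen_boundary, pixel_size_r = 5,
                         frame_pitch = 0.2) {
  if (is.matrix(mask_stack))
    mask_stack <- array(mask_stack, c(dim(mask_stack), 1L))
  nf <- dim(mask_stack)[3]; W <- dim(mask_stack)[2]
  dth <- 2 * pi / W
  per <- vapply(seq_len(nf), function(f) {
    cols <- which(colSums(mask_stack[, , f] != 0) > 0)
    if (!length(cols)) return(0)
    r_mm <- lumen_boundary[cols, f] * pixel_size_r / 1000
    sum(dth * r_mm * frame_pitch)
  }, numeric(1))
  structure(sum(per), per_frame = per)
}

#' Lesion-level morphometric summary
#'
#' Cap regions are theta-wrapping connected components per frame, linked
#' across consecutive frames when their angular extents overlap. Per
#' lesion: mean and minimum thickness over defined A-lines, per-frame and
#' maximum arc angle (`A-line count * 360 / n_alines` degrees), per-frame
#' and total cross-sectional area, luminal surface area, longitudinal
#' length (`frame span * frame_pitch`), and the TCFA flag (minimum
#' thickness strictly below the threshold).
#'
#' @param mask_stack binary array in shifted coordinates.
#' @param thickness n_frames x n_alines thickness matrix from
#'   [aline_thickness()].
#' @param geometry list with `pixel_size_r` (um), `frame_pitch` (mm),
#'   `lumen_boundary` and `shifts` (both n_alines x n_frames).
#' @param tcfa_threshold_um thin-cap threshold, micrometres (default 65).
#' @return list with data.frames `lesions` and `per_frame`.
#' @export
region_summary <- function(mask_stack, thickness, geometry,
                           tcfa_threshold_um = 65) {
  if (is.matrix(mask_stack))
    mask_stack <- array(mask_stack, c(dim(mask_stack), 1L))
  nf <- dim(mask_stack)[3]; W <- dim(mask_stack)[2]
  regions <- list()
  for (f in seq_len(nf)) {
    present <- colSums(mask_stack[, , f] != 0) > 0
    for (cols in wrap_runs(present))
      regions[[length(regions) + 1L]] <- list(frame = f, cols = cols)
  }
  empty <- list(lesions = data.frame(), per_frame = data.frame())
  if (!length(regions)) return(empty)
  # union-find linking across consecutive frames on angular overlap
  parent <- seq_along(regions)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_along(regions)) {
    for (j in seq_along(regions)) {
      if (regions[[j]]$frame != regions[[i]]$frame + 1L) next
      if (length(intersect(regions[[i]]$cols, regions[[j]]$cols))) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_along(regions), find, integer(1))
  ids <- match(roots, sort(unique(roots)))
  pf <- do.call(rbind, lapply(seq_along(regions), function(i) {
    rg <- regions[[i]]
    th <- thickness[rg$frame, rg$cols]
    th <- th[!is.na(th)]
    sub <- mask_stack[, , rg$frame] * 0
    sub[, rg$cols] <- mask_stack[, rg$cols, rg$frame]
    data.frame(lesion = ids[i], frame = rg$frame,
               n_alines = length(rg$cols),
               arc_deg = length(rg$cols) * 360 / W,
               mean_thickness_um = if (length(th)) mean(th) else NA_real_,
               min_thickness_um = if (length(th)) min(th) else NA_real_,
               area_mm2 = fc_area(sub, geometry$shifts[, rg$frame],
                                  geometry$pixel_size_r))
  }))
  dth <- 2 * pi / W
  lesions <- do.call(rbind, lapply(sort(unique(ids)), function(id) {
    sel <- which(ids == id)
    frames <- vapply(regions[sel], `[[`, integer(1), "frame")
    th_all <- unlist(lapply(regions[sel], function(rg)
      thickness[rg$frame, rg$cols]))
    th_all <- th_all[!is.na(th_all)]
    surf <- sum(vapply(sel, function(i) {
      rg <- regions[[i]]
      r_mm <- geometry$lumen_boundary[rg$cols, rg$frame] *
        geometry$pixel_size_r / 1000
      sum(dth * r_mm * geometry$frame_pitch)
    }, numeric(1)))
    mn <- if (length(th_all)) min(th_all) else NA_real_
    data.frame(lesion = id, frame_start = min(frames),
               frame_end = max(frames),
               length_mm = (max(frames) - min(frames) + 1L) *
                 geometry$frame_pitch,
               mean_thickness_um = if (length(th_all)) mean(th_all)
               else NA_real_,
               min_thickness_um = mn,
               max_arc_deg = max(pf$arc_deg[pf$lesion == id]),
               area_mm2 = sum(pf$area_mm2[pf$lesion == id]),
               surface_area_mm2 = surf,
               tcfa = isTRUE(mn < tcfa_threshold_um))
  }))
  list(lesions = lesions, per_frame = pf)
}

#' Cap-thickness heatmap over the unrolled vessel
#'
#' @param mask_stack binary array in shifted space, or a precomputed
#'   thickness matrix.
#' @param pixel_size_r radial pixel size, micrometres.
#' @return n_frames x n_alines thickness matrix (um, `NA` where no cap).
#' @export
thickness_heatmap <- function(mask_stack, pixel_size_r = 5) {
  if (is.array(mask_stack) &&
      (is.logical(mask_stack) || all(mask_stack %in% c(0, 1))))
    return(aline_thickness(mask_stack, pixel_size_r))
  mask_stack
}

#' Export / read a thickness surface mesh (ASCII PLY)
#'
#' Vertices lie on a cylinder of the given lumen radius, one per (frame,
#' A-line), with cap thickness as a per-vertex scalar (0 where no cap).
#'
#' @param heatmap n_frames x n_alines thickness matrix.
#' @param path output PLY path.
#' @param lumen_radius_mm cylinder radius for the mesh.
#' @param frame_pitch frame spacing, mm.
#' @return `read_thickness_ply` returns a data.frame with columns x, y, z,
#'   thickness.
#' @export
write_thickness_ply <- function(heatmap, path, lumen_radius_mm = 1.5,
                                frame_pitch = 0.2) {
  nf <- nrow(heatmap); W <- ncol(heatmap)
  th <- 2 * pi * (seq_len(W) - 1) / W
  verts <- do.call(rbind, lapply(seq_len(nf), function(f) {
    cbind(x = lumen_radius_mm * cos(th), y = lumen_radius_mm * sin(th),
          z = (f - 1) * frame_pitch,
          thickness = ifelse(is.na(heatmap[f, ]), 0, heatmap[f, ]))
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(verts)),
               "property float x", "property float y", "property float z",
               "property float thickness", "end_header"), con)
  write.table(format(verts, trim = TRUE, scientific = FALSE), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_thickness_ply
#' @export
read_thickness_ply <- function(path) {
  lines <- readLines(path)
  hdr_end <- which(lines == "end_header")[1]
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  dat <- read.table(text = lines[(hdr_end + 1):(hdr_end + nv)])
  names(dat) <- c("x", "y", "z", "thickness")
  dat
}

#' Bland-Altman agreement analysis
#'
#' @param x,y paired measurements (same length, >= 2 pairs).
#' @return list with `bias` (mean difference x - y), `sd` of differences,
#'   `limits` (bias +/- 1.96 sd) and `fraction_within` the limits.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop("bland_altman: need >= 2 pairs", call. = FALSE)
  d <- x - y
  bias <- mean(d)
  s <- sd(d)
  limits <- bias + c(-1.96, 1.96) * s
  list(bias = bias, sd = s, limits = limits,
       fraction_within = mean(d >= limits[1] & d <= limits[2]))
}

#' Coefficient of variation
#'
#' Population standard deviation divided by the mean (so repeats
#' `c(90, 110)` give CV 0.1); `NA` (flagged undefined) for zero mean. For a
#' matrix, repeats are rows and the CV is computed per column (attribute).
#'
#' @param x numeric vector of repeated measurements, or matrix with one
#'   column per attribute.
#' @return scalar or per-attribute named vector.
#' @export
coefficient_of_variation <- function(x) {
  if (is.matrix(x) || is.data.frame(x))
    return(apply(as.matrix(x), 2, coefficient_of_variation))
  m <- mean(x)
  if (isTRUE(all.equal(m, 0))) return(NA_real_)
  sqrt(mean((x - m)^2)) / m
}
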