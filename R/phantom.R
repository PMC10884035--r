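#' Configuration for synthetic polar IVOCT phantoms
#'
#' Defines the acquisition geometry and tissue-appearance parameters of the
#' phantom generator. Defaults mirror a frequency-domain IVOCT system: raw
#' frames of 968 radial samples by 448 A-lines, ~5 um radial pixel pitch and
#' a 0.2 mm frame pitch (36 mm/s pullback at 180 fps).
#'
#' The tissue model is piecewise-constant mean reflectance per class with
#' exponential depth attenuation and multiplicative gamma-distributed
#' speckle. A fibrous cap is rendered as a signal-rich layer at the lumen
#' surface overlying a signal-poor lipid pool; the guidewire casts a
#' near-zero-intensity angular shadow band.
#'
#' @param n_frames number of frames in the pullback.
#' @param r_size radial samples per A-line (>= 200).
#' @param n_alines A-lines (columns) per frame.
#' @param pixel_size_r radial pixel size in micrometres.
#' @param frame_pitch frame-to-frame spacing in millimetres.
#' @param lumen_radius_range range (mm) for the mean lumen radius.
#' @param cap_thickness_range range (um) for cap thickness draws.
#' @param lipid_arc_range range (degrees) of the lesion's angular extent;
#'   `c(0, 0)` generates a lesion-free pullback.
#' @param guidewire_width_range range (A-lines) of the shadow band width.
#' @param speckle_contrast speckle contrast (sd/mean of the multiplicative
#'   noise); 0 disables speckle.
#' @param intensity_levels named mean reflectances in (0,1) for classes
#'   `background`, `wall`, `cap`, `lipid`, `calc`, `calc_border`.
#' @param attenuation_mm depth attenuation coefficient (1/mm) applied to
#'   tissue below the lumen surface.
#' @param seed master seed; all randomness derives deterministically from it.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(n_frames = 8L,
                           r_size = 968L,
                           n_alines = 448L,
                           pixel_size_r = 5,
                           frame_pitch = 0.2,
                           lumen_radius_range = c(0.8, 1.6),
                           cap_thickness_range = c(60, 140),
                           lipid_arc_range = c(60, 180),
                           guidewire_width_range = c(10L, 60L),
                           speckle_contrast = 0.25,
                           intensity_levels = c(background = 0.02,
                                                wall = 0.45, cap = 0.70,
                                                lipid = 0.12, calc = 0.08,
                                                calc_border = 0.80),
                           attenuation_mm = 1.5,
                           seed = 1L) {
  cfg <- list(n_frames = as.integer(n_frames), r_size = as.integer(r_size),
              n_alines = as.integer(n_alines), pixel_size_r = pixel_size_r,
              frame_pitch = frame_pitch,
              lumen_radius_range = lumen_radius_range,
              cap_thickness_range = cap_thickness_range,
              lipid_arc_range = lipid_arc_range,
              guidewire_width_range = as.integer(guidewire_width_range),
              speckle_contrast = speckle_contrast,
              intensity_levels = intensity_levels,
              attenuation_mm = attenuation_mm, seed = as.integer(seed))
  validate_phantom_config(cfg)
  class(cfg) <- "phantom_config"
  cfg
}

validate_phantom_config <- function(cfg) {
  if (cfg$r_size < 200L)
    stop("phantom config error: r_size must be >= 200", call. = FALSE)
  if (cfg$n_alines < 1L)
    stop("phantom config error: n_alines must be >= 1", call. = FALSE)
  if (cfg$n_frames < 1L)
    stop("phantom config error: n_frames must be >= 1", call. = FALSE)
  if (any(cfg$cap_thickness_range <= 0))
    stop("phantom config error: cap_thickness_range must be positive",
         call. = FALSE)
  if (any(!is.finite(cfg$speckle_contrast)) || cfg$speckle_contrast < 0)
    stop("phantom config error: speckle_contrast must be finite, >= 0",
         call. = FALSE)
  need <- c("background", "wall", "cap", "lipid", "calc", "calc_border")
  if (!all(need %in% names(cfg$intensity_levels)))
    stop("phantom config error: intensity_levels must name ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(!is.finite(cfg$intensity_levels)) || any(cfg$intensity_levels < 0))
    stop("phantom config error: intensity_levels must be finite, >= 0",
         call. = FALSE)
  if (any(cfg$lipid_arc_range < 0) || any(cfg$lipid_arc_range > 360))
    stop("phantom config error: lipid_arc_range must lie in [0, 360]",
         call. = FALSE)
  # lumen + cap + lipid pool must fit the radial field of view
  max_b <- max(cfg$lumen_radius_range) * 1000 / cfg$pixel_size_r
  max_t <- max(cfg$cap_thickness_range) / cfg$pixel_size_r
  if (max_b * 1.15 + max_t + 350 / cfg$pixel_size_r >= cfg$r_size)
    stop("phantom config error: lumen radius plus lesion depth exceeds the ",
         "radial field of view", call. = FALSE)
  invisible(cfg)
}

# Smoothly varying per-A-line lumen boundary (pixels, 0-based), one column
# per frame.
phantom_lumen_profile <- function(cfg) {
  th <- 2 * pi * (seq_len(cfg$n_alines) - 1) / cfg$n_alines
  base_mm <- runif(1, cfg$lumen_radius_range[1], cfg$lumen_radius_range[2])
  a1 <- runif(1, 0.02, 0.08); p1 <- runif(1, 0, 2 * pi)
  a2 <- runif(1, 0.01, 0.05); p2 <- runif(1, 0, 2 * pi)
  drift <- runif(1, -0.03, 0.03)
  base_px <- base_mm * 1000 / cfg$pixel_size_r
  sapply(seq_len(cfg$n_frames), function(f) {
    z <- (f - 1) / max(1L, cfg$n_frames - 1L)
    prof <- base_px * (1 + a1 * sin(th + p1) + a2 * sin(2 * th + p2) +
                         drift * z)
    as.integer(round(prof))
  })
}

# Wrapped A-line index set of width w centred at c0 (1-based).
wrap_band <- function(c0, w, n) {
  idx <- (c0 - (w %/% 2)) + seq_len(w) - 1L
  sort(unique(((idx - 1L) %% n) + 1L))
}

phantom_scaffold <- function(cfg) {
  n <- cfg$n_alines
  gw_w <- if (diff(range(cfg$guidewire_width_range)) == 0)
    cfg$guidewire_width_range[1] else
      sample(cfg$guidewire_width_range[1]:cfg$guidewire_width_range[2], 1)
  gw_c0 <- sample.int(n, 1)
  arc_deg <- runif(1, cfg$lipid_arc_range[1], cfg$lipid_arc_range[2])
  arc_w <- as.integer(round(arc_deg / 360 * n))
  lesion_c <- NA_integer_
  if (arc_w > 0) {
    gw_band <- wrap_band(gw_c0, gw_w + 4L, n)
    for (i in 1:200) {
      cand <- sample.int(n, 1)
      if (!any(wrap_band(cand, arc_w, n) %in% gw_band)) {
        lesion_c <- cand
        break
      }
    }
    if (is.na(lesion_c)) lesion_c <- cand  # overlap removed via mask later
  }
  # smooth cap-thickness field (um), exact on the configured range
  t_lo <- cfg$cap_thickness_range[1]; t_hi <- cfg$cap_thickness_range[2]
  tp1 <- runif(1, 0, 2 * pi); tp2 <- runif(1, 0, 2 * pi)
  tf <- runif(1, 0.5, 2)
  list(gw_w = gw_w, gw_c0 = gw_c0, arc_w = arc_w,
       lesion_c = lesion_c, t_lo = t_lo, t_hi = t_hi,
       tp1 = tp1, tp2 = tp2, tf = tf,
       lipid_depth_px = as.integer(round(runif(1, 150, 300) /
                                           cfg$pixel_size_r)))
}

# Thickness (um) along theta for one frame: a smooth field mapped into the
# configured range.
phantom_thickness_um <- function(scaf, cfg, frame) {
  th <- 2 * pi * (seq_len(cfg$n_alines) - 1) / cfg$n_alines
  z <- (frame - 1) / max(1L, cfg$n_frames - 1L)
  u <- 0.5 + 0.35 * sin(th + scaf$tp1) + 0.15 * sin(scaf$tf * 2 * pi * z +
                                                      scaf$tp2)
  u <- pmin(1, pmax(0, u))
  scaf$t_lo + u * (scaf$t_hi - scaf$t_lo)
}

# Substream seed for frame f, independent of the frame count so each
# frame is reproducible on its own.
frame_substream <- function(seed, f) {
  as.integer(((as.double(seed) %% 2147483647) * 69621 + f * 476211) %%
               2147483647) + 1L
}

render_phantom <- function(cfg, lesion_class = c("fc", "calcification")) {
  lesion_class <- match.arg(lesion_class)
  with_seed(cfg$seed, {
    boundary <- phantom_lumen_profile(cfg)        # n_alines x n_frames
    scaf <- phantom_scaffold(cfg)
    frame_seeds <- vapply(seq_len(cfg$n_frames), frame_substream,
                          integer(1), seed = cfg$seed)
    H <- cfg$r_size; W <- cfg$n_alines; nf <- cfg$n_frames
    lv <- cfg$intensity_levels
    pix_mm <- cfg$pixel_size_r / 1000
    k_speckle <- if (cfg$speckle_contrast > 0)
      1 / cfg$speckle_contrast^2 else Inf
    frames <- array(0, c(H, W, nf))
    fc_mask <- array(FALSE, c(H, W, nf))
    thick <- matrix(NA_real_, nf, W)
    gw_list <- vector("list", nf)
    lesion_cols <- if (scaf$arc_w > 0)
      wrap_band(scaf$lesion_c, scaf$arc_w, W) else integer(0)
    gw_centre <- scaf$gw_c0
    for (f in seq_len(nf)) {
      with_seed(frame_seeds[f], {
        b <- boundary[, f]
        if (f > 1L)                    # slow angular drift of the wire
          gw_centre <- ((gw_centre - 1L + sample(-2:2, 1)) %% W) + 1L
        gw <- wrap_band(gw_centre, scaf$gw_w, W)
        gw_list[[f]] <- gw
        depth <- outer(0:(H - 1), b, "-")        # H x W radial depth (px)
        lvl <- matrix(lv["wall"], H, W)
        lvl[depth < 0] <- lv["background"]
        t_um <- phantom_thickness_um(scaf, cfg, f)
        t_px <- pmax(1L, as.integer(round(t_um / cfg$pixel_size_r)))
        tcol <- integer(W)
        tcol[lesion_cols] <- t_px[lesion_cols]
        tmat <- matrix(tcol, H, W, byrow = TRUE)
        if (lesion_class == "fc") {
          in_cap <- depth >= 0 & depth < tmat & tmat > 0
          in_lip <- depth >= tmat & depth < tmat + scaf$lipid_depth_px &
            tmat > 0
          lvl[in_lip] <- lv["lipid"]
          lvl[in_cap] <- lv["cap"]
          lesion_px <- in_cap
        } else {
          # sharply delineated low-backscatter body with a bright border
          in_body <- depth >= 3 & depth < 3 + tmat & tmat > 0
          rim <- depth >= 1 & depth < 3 & tmat > 0 |
            (depth >= 3 + tmat & depth < 5 + tmat & tmat > 0)
          edge_cols <- if (length(lesion_cols))
            lesion_cols[!(((lesion_cols %% W) + 1L) %in% lesion_cols &
                            (((lesion_cols - 2L) %% W) + 1L) %in% lesion_cols)]
          else integer(0)
          if (length(edge_cols)) {
            em <- matrix(FALSE, H, W)
            em[, edge_cols] <- depth[, edge_cols, drop = FALSE] >= 1 &
              depth[, edge_cols, drop = FALSE] < 5 + tmat[, edge_cols,
                                                          drop = FALSE]
            rim <- rim | (em & tmat > 0)
          }
          lvl[in_body] <- lv["calc"]
          lvl[rim & !in_body] <- lv["calc_border"]
          lesion_px <- (in_body | rim) & tmat > 0
        }
        img <- lvl * exp(-cfg$attenuation_mm * pmax(depth, 0) * pix_mm)
        if (is.finite(k_speckle))
          img <- img * matrix(rgamma(H * W, shape = k_speckle,
                                     rate = k_speckle), H, W)
        img[, gw] <- img[, gw] * 0.02
        frames[, , f] <- pmin(1, pmax(0, img))
        lesion_px[, gw] <- FALSE
        fc_mask[, , f] <- lesion_px
        counts <- colSums(lesion_px)
        tk <- rep(NA_real_, W)
        tk[counts > 0] <- counts[counts > 0] * cfg$pixel_size_r
        thick[f, ] <- tk
      })
    }
    pb <- polar_pullback(frames, pixel_size_r = cfg$pixel_size_r,
                         frame_pitch = cfg$frame_pitch, preprocessed = FALSE)
    truth <- structure(list(lumen_boundary = boundary,
                            guidewire_alines = gw_list,
                            fc_mask_raw = fc_mask,
                            thickness_truth = thick,
                            lesion_class = lesion_class),
                       class = "phantom_truth")
    list(pullback = pb, truth = truth)
  })
}

#' Generate a synthetic fibrous-cap pullback with ground truth
#'
#' Renders a polar-domain pullback containing a circular-ish lumen, a dark
#' guidewire shadow band, and (unless the lesion arc is zero) a signal-rich
#' fibrous cap overlying a signal-poor lipid pool, corrupted by
#' multiplicative speckle. Output is deterministic for a fixed seed; each
#' frame uses its own derived substream.
#'
#' @param config a [phantom_config()].
#' @return list with elements `pullback` (a `polar_pullback`) and `truth`
#'   (lumen boundary in pixels per A-line and frame, guidewire A-line sets,
#'   raw-coordinate cap mask, per-frame/per-A-line cap thickness in um with
#'   `NA` where no cap, and the lesion class).
#' @export
generate_pullback <- function(config) {
  validate_phantom_config(config)
  render_phantom(config, "fc")
}

#' Generate a synthetic calcification pullback (transfer-learning source)
#'
#' Same scaffolding as [generate_pullback()] but the lesion is rendered as a
#' sharply delineated low-backscatter body with a bright border, the
#' appearance of calcified plaque, the source task used to pretrain the
#' segmentation network before fine-tuning on fibrous caps.
#'
#' @inheritParams generate_pullback
#' @return as [generate_pullback()], with `lesion_class = "calcification"`.
#' @export
generate_calcific_pullback <- function(config) {
  validate_phantom_config(config)
  render_phantom(config, "calcification")
}
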