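#' Default end-to-end run configuration
#'
#' Aggregates every stage's parameters with the reference defaults: crop
#' depth 200, Gaussian kernel 7 / sigma 1, 6 spiral offsets of 80 A-lines,
#' flip probability 0.10, intensity scale/shift 0.1 at 20 percent, 16
#' initial filters, dropout 0.2, learning rate 1e-5, epsilon 1e-9, weight
#' decay 1e-6, up to 600 epochs at batch size 64 with patience 10, opening
#' radius 3 with 4-connectivity, and a 65 um TCFA threshold.
#'
#' @param out_dir output directory for run artifacts.
#' @param seed master seed.
#' @param stages pipeline stages to execute, in order.
#' @param ... overrides for nested entries, e.g.
#'   `phantom = phantom_config(n_frames = 20)`.
#' @return list of class `run_config`.
#' @export
default_run_config <- function(out_dir = tempfile("fibrocap_run_"),
                               seed = 1L,
                               stages = c("simulate", "preprocess", "train",
                                          "predict", "quantify",
                                          "evaluate"), ...) {
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = stages,
    phantom = phantom_config(seed = seed),
    preprocess = list(depth = 200L, kernel = 7L, sigma = 1),
    augment = augment_config(seed = seed),
    model = seg_model_config(),
    train = train_config(seed = seed),
    split = c(train = 0.6, validation = 0.2, test = 0.2),
    postprocess = list(radius = 3L, connectivity = 4L),
    quantify = list(tcfa_threshold_um = 65),
    transfer = list(enabled = FALSE, include_decoder = TRUE)
  )
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  class(cfg) <- "run_config"
  cfg
}

pipeline_stage_order <- c("simulate", "augment", "preprocess", "pretrain",
                          "train", "predict", "quantify", "evaluate")

pipeline_deps <- list(augment = "simulate", preprocess = "simulate",
                      train = "preprocess", predict = "train",
                      quantify = "predict", evaluate = "predict")

validate_stages <- function(stages) {
  unknown <- setdiff(stages, pipeline_stage_order)
  if (length(unknown))
    stop("pipeline error: unknown stage(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  pos <- match(stages, pipeline_stage_order)
  if (is.unsorted(pos))
    stop("pipeline error: stages out of order; required order is ",
         paste(pipeline_stage_order, collapse = " -> "), call. = FALSE)
  for (s in stages) {
    need <- pipeline_deps[[s]]
    if (!is.null(need) && !all(need %in% stages))
      stop("pipeline error: stage '", s, "' requires '",
           paste(setdiff(need, stages), collapse = ", "), "'",
           call. = FALSE)
  }
  invisible(stages)
}

config_hash <- function(cfg) {
  js <- jsonlite::toJSON(cfg[setdiff(names(cfg), "out_dir")],
                         auto_unbox = TRUE, digits = 12, force = TRUE)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}

# Deterministic frame split into train/validation/test.
split_frames <- function(n, fractions, seed) {
  ord <- with_seed(seed, sample.int(n))
  n_tr <- max(1L, floor(fractions[1] * n))
  n_va <- max(1L, floor(fractions[2] * n))
  n_tr <- min(n_tr, n - n_va - 1L)
  list(train = sort(ord[seq_len(n_tr)]),
       validation = sort(ord[n_tr + seq_len(n_va)]),
       test = sort(ord[(n_tr + n_va + 1L):n]))
}

#' Run the fibrous-cap pipeline end to end
#'
#' Executes the requested stages in order (simulate, augment, preprocess,
#' pretrain, train, predict, quantify, evaluate) on a synthetic pullback,
#' writing artifacts and a reproducibility manifest (config hash, seed,
#' package version, per-stage outputs) to `config$out_dir`. Deterministic
#' stages reproduce bitwise under an identical config and seed.
#'
#' @param config a [default_run_config()].
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = default_run_config()) {
  stopifnot(inherits(config, "run_config"))
  stages <- validate_stages(config$stages)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- list()
  res <- list()
  seeds <- derive_seeds(config$seed, 8L)

  if ("simulate" %in% stages) {
    sim <- generate_pullback(config$phantom)
    res$simulate <- sim
    f <- file.path(config$out_dir, "raw_pullback.tif")
    write_pullback(sim$pullback, f)
    write_mask_stack(sim$truth$fc_mask_raw,
                     file.path(config$out_dir, "truth_mask_raw.tif"))
    outputs$simulate <- c("raw_pullback.tif", "truth_mask_raw.tif")
  }

  if ("augment" %in% stages) {
    res$augment <- spiral_offsets(res$simulate$pullback, config$augment,
                                  masks = res$simulate$truth$fc_mask_raw)
    outputs$augment <- sprintf("spiral offset copies: %d",
                               length(res$augment))
  }

  if ("preprocess" %in% stages) {
    pp <- preprocess_pullback(res$simulate$pullback,
                              depth = config$preprocess$depth,
                              kernel = config$preprocess$kernel,
                              sigma = config$preprocess$sigma)
    pp$masks <- preprocess_mask(res$simulate$truth$fc_mask_raw, pp$shifts,
                                config$preprocess$depth)
    if (!is.null(res$augment)) {
      pp$extra <- lapply(res$augment, function(a) {
        e <- preprocess_pullback(a$pullback,
                                 depth = config$preprocess$depth,
                                 kernel = config$preprocess$kernel,
                                 sigma = config$preprocess$sigma)
        e$masks <- preprocess_mask(a$masks, e$shifts,
                                   config$preprocess$depth)
        e
      })
    }
    res$preprocess <- pp
    write_pullback(pp$pullback,
                   file.path(config$out_dir, "preprocessed.tif"))
    write.csv(data.frame(frame = rep(seq_len(ncol(pp$shifts)),
                                     each = nrow(pp$shifts)),
                         aline = rep(seq_len(nrow(pp$shifts)),
                                     ncol(pp$shifts)),
                         shift_px = as.vector(pp$shifts)),
              file.path(config$out_dir, "shift_records.csv"),
              row.names = FALSE)
    outputs$preprocess <- c("preprocessed.tif", "shift_records.csv")
  }

  input_size <- c(config$preprocess$depth, config$phantom$n_alines)

  if ("pretrain" %in% stages) {
    calc_cfg <- config$phantom
    calc_cfg$seed <- seeds[2]
    calc <- generate_calcific_pullback(calc_cfg)
    cpp <- preprocess_pullback(calc$pullback,
                               depth = config$preprocess$depth,
                               kernel = config$preprocess$kernel,
                               sigma = config$preprocess$sigma)
    cmasks <- preprocess_mask(calc$truth$fc_mask_raw, cpp$shifts,
                              config$preprocess$depth)
    nf <- cpp$pullback$n_frames
    sp <- split_frames(nf, config$split, seeds[3])
    ds <- function(idx) list(
      x = lapply(idx, function(f) cpp$pullback$frames[, , f]),
      y = lapply(idx, function(f) cmasks[, , f]))
    pre_model <- build_model(config$model, input_size, seed = seeds[4])
    res$pretrain <- train_model(pre_model, ds(sp$train), ds(sp$validation),
                                config$train)
    save_model(res$pretrain$model,
               file.path(config$out_dir, "pretrained_model.rds"))
    outputs$pretrain <- "pretrained_model.rds"
  }

  if ("train" %in% stages) {
    pp <- res$preprocess
    nf <- pp$pullback$n_frames
    sp <- split_frames(nf, config$split, seeds[3])
    xs <- lapply(sp$train, function(f) pp$pullback$frames[, , f])
    ys <- lapply(sp$train, function(f) pp$masks[, , f])
    if (!is.null(pp$extra)) {
      for (e in pp$extra) {
        xs <- c(xs, lapply(sp$train, function(f) e$pullback$frames[, , f]))
        ys <- c(ys, lapply(sp$train, function(f) e$masks[, , f]))
      }
    }
    model <- build_model(config$model, input_size, seed = seeds[5])
    if (isTRUE(config$transfer$enabled)) {
      if (is.null(res$pretrain))
        stop("pipeline error: transfer requested without 'pretrain' stage",
             call. = FALSE)
      model <- transfer_init(model, res$pretrain$model,
                             config$transfer$include_decoder)
    }
    res$train <- train_model(
      model, list(x = xs, y = ys),
      list(x = lapply(sp$validation, function(f) pp$pullback$frames[, , f]),
           y = lapply(sp$validation, function(f) pp$masks[, , f])),
      config$train)
    res$split <- sp
    save_model(res$train$model, file.path(config$out_dir, "model.rds"))
    write.csv(res$train$history,
              file.path(config$out_dir, "training_history.csv"),
              row.names = FALSE)
    outputs$train <- c("model.rds", "training_history.csv")
  }

  if ("predict" %in% stages) {
    pp <- res$preprocess
    test_idx <- res$split$test
    masks <- lapply(test_idx, function(f)
      predict_mask(res$train$model, pp$pullback$frames[, , f]))
    masks <- lapply(masks, open_and_fill,
                    radius = config$postprocess$radius,
                    connectivity = config$postprocess$connectivity)
    stack <- array(FALSE, c(input_size, length(masks)))
    for (i in seq_along(masks)) stack[, , i] <- masks[[i]]
    attr(stack, "space") <- "shifted"
    res$predict <- list(test_idx = test_idx, masks = stack)
    write_mask_stack(stack,
                     file.path(config$out_dir, "predicted_masks.tif"))
    outputs$predict <- "predicted_masks.tif"
  }

  if ("quantify" %in% stages) {
    pp <- res$preprocess
    test_idx <- res$predict$test_idx
    thick <- aline_thickness(res$predict$masks,
                             config$phantom$pixel_size_r)
    geom <- list(pixel_size_r = config$phantom$pixel_size_r,
                 frame_pitch = config$phantom$frame_pitch,
                 lumen_boundary = pp$boundaries[, test_idx, drop = FALSE],
                 shifts = pp$shifts[, test_idx, drop = FALSE])
    summ <- region_summary(res$predict$masks, thick, geom,
                           config$quantify$tcfa_threshold_um)
    res$quantify <- list(thickness = thick, summary = summ)
    tl <- data.frame(frame = rep(test_idx, each = ncol(thick)),
                     aline = rep(seq_len(ncol(thick)), length(test_idx)),
                     thickness_um = as.vector(t(thick)))
    write.csv(tl, file.path(config$out_dir, "thickness.csv"),
              row.names = FALSE)
    if (nrow(summ$lesions))
      write.csv(summ$lesions, file.path(config$out_dir, "lesions.csv"),
                row.names = FALSE)
    outputs$quantify <- c("thickness.csv",
                          if (nrow(summ$lesions)) "lesions.csv")
  }

  if ("evaluate" %in% stages) {
    pp <- res$preprocess
    test_idx <- res$predict$test_idx
    total <- structure(list(TP = 0, TN = 0, FP = 0, FN = 0),
                       class = "confusion_counts")
    for (i in seq_along(test_idx)) {
      f <- test_idx[i]
      excl <- matrix(FALSE, input_size[1], input_size[2])
      gw <- res$preprocess$guidewire[[f]]
      if (length(gw)) excl[, gw] <- TRUE
      total <- add_confusion(total,
                             confusion(res$predict$masks[, , i],
                                       pp$masks[, , f], exclude = excl))
    }
    met <- seg_metrics(total)
    res$evaluate <- list(counts = total, metrics = met)
    write.csv(data.frame(metric = names(unclass(met)),
                         value = unlist(unclass(met))),
              file.path(config$out_dir, "metrics.csv"), row.names = FALSE)
    outputs$evaluate <- "metrics.csv"
  }

  manifest <- list(config_hash = config_hash(config),
                   seed = config$seed,
                   package_version =
                     as.character(utils::packageVersion("fibrocap")),
                   stages = stages,
                   config = config[setdiff(names(config), "out_dir")],
                   outputs = outputs)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 12, force = TRUE,
                       pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
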