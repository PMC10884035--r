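#' Pixel-wise confusion counts
#'
#' @param pred,truth binary masks of identical shape.
#' @param exclude optional logical mask of pixels excluded from evaluation
#'   (e.g. the guidewire band, which carries no tissue truth).
#' @return list of class `confusion_counts` with TP, TN, FP, FN.
#' @export
confusion <- function(pred, truth, exclude = NULL) {
  if (!identical(dim(pred), dim(truth)))
    stop("confusion: shape mismatch", call. = FALSE)
  p <- pred != 0; t <- truth != 0
  if (!is.null(exclude)) {
    keep <- !(exclude != 0)
    p <- p[keep]; t <- t[keep]
  }
  structure(list(TP = sum(p & t), TN = sum(!p & !t),
                 FP = sum(p & !t), FN = sum(!p & t)),
            class = "confusion_counts")
}

add_confusion <- function(a, b) {
  structure(list(TP = a$TP + b$TP, TN = a$TN + b$TN,
                 FP = a$FP + b$FP, FN = a$FN + b$FN),
            class = "confusion_counts")
}

#' Segmentation metrics from confusion counts
#'
#' PPV = TP/(TP+FP), NPV = TN/(TN+FN), sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), accuracy = (TP+TN)/total, Dice =
#' 2TP/(2TP+FP+FN). Ratios with zero denominator are reported as `NA`
#' (undefined), never as 0.
#'
#' @param counts a [confusion()] result.
#' @return list of class `metrics_report`.
#' @export
seg_metrics <- function(counts) {
  r <- function(num, den) if (den == 0) NA_real_ else num / den
  with(counts, structure(list(
    ppv = r(TP, TP + FP), npv = r(TN, TN + FN),
    sensitivity = r(TP, TP + FN), specificity = r(TN, TN + FP),
    accuracy = r(TP + TN, TP + TN + FP + FN),
    dice = r(2 * TP, 2 * TP + FP + FN)),
    class = "metrics_report"))
}

#' Pullback-level cross-validation split
#'
#' Partitions pullback ids into `n_folds` groups; each fold assigns one
#' rotation of groups to training/validation/testing in the requested
#' fractions. Test groups are pairwise disjoint across folds and their
#' union covers all pullbacks; no pullback appears in two sub-groups of
#' one fold.
#'
#' @param ids pullback identifiers (>= `n_folds`).
#' @param n_folds number of folds (default 5).
#' @param fractions train/validation/test fractions; must be multiples of
#'   `1 / n_folds` with a test fraction of exactly `1 / n_folds`.
#' @param seed shuffling seed.
#' @return list of folds, each `list(train, validation, test)` of ids.
#' @export
crossval_split <- function(ids, n_folds = 5L,
                           fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  if (length(ids) < n_folds)
    stop("crossval error: need at least ", n_folds, " pullbacks",
         call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("crossval error: fractions must sum to 1", call. = FALSE)
  ng <- fractions * n_folds
  if (any(abs(ng - round(ng)) > 1e-9) || round(ng[3]) != 1L)
    stop("crossval error: fractions incompatible with n_folds (test ",
         "fraction must equal 1/n_folds)", call. = FALSE)
  ng <- as.integer(round(ng))
  shuffled <- with_seed(seed, sample(ids))
  groups <- split(shuffled, rep(seq_len(n_folds),
                                length.out = length(ids)))
  lapply(seq_len(n_folds), function(i) {
    test_g <- i
    val_g <- ((i - 1L + seq_len(ng[2])) %% n_folds) + 1L
    train_g <- setdiff(seq_len(n_folds), c(test_g, val_g))
    list(train = unname(unlist(groups[train_g])),
         validation = unname(unlist(groups[val_g])),
         test = unname(unlist(groups[test_g])))
  })
}

#' Held-out evaluation with a plurality-vote ensemble
#'
#' Each frame is predicted by every model, the per-pixel plurality vote is
#' taken, masks are optionally postprocessed, and confusion counts are
#' pooled over the set.
#'
#' @param models list of trained models (e.g. the five fold models).
#' @param frames list of preprocessed frames.
#' @param truths list of matching truth masks.
#' @param threshold probability threshold (model default when `NULL`).
#' @param postprocess apply [open_and_fill()] to the voted mask.
#' @param exclude optional list of per-frame exclusion masks.
#' @return list with `metrics`, pooled `counts` and `per_frame` counts.
#' @export
evaluate_heldout <- function(models, frames, truths, threshold = NULL,
                             postprocess = TRUE, exclude = NULL) {
  if (!length(models)) stop("evaluate error: no models", call. = FALSE)
  total <- structure(list(TP = 0, TN = 0, FP = 0, FN = 0),
                     class = "confusion_counts")
  per_frame <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    masks <- lapply(models, predict_mask, frame = frames[[i]],
                    threshold = threshold)
    voted <- ensemble_vote(masks)
    if (postprocess) voted <- open_and_fill(voted)
    cc <- confusion(voted, truths[[i]],
                    exclude = if (!is.null(exclude)) exclude[[i]])
    per_frame[[i]] <- cc
    total <- add_confusion(total, cc)
  }
  list(metrics = seg_metrics(total), counts = total,
       per_frame = per_frame)
}
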