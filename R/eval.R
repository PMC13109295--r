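# Instance-segmentation evaluation (IoU matching, AP@IoU) and
# generated-image fidelity (foreground mean absolute error).

#' Intersection-over-union of two binary masks
#'
#' @param a,b 0/1 matrices of identical shape.
#' @return `|a & b| / |a | b|` in `[0, 1]`; 0 when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("shape mismatch", call. = FALSE)
  inter <- sum(a > 0 & b > 0)
  union <- sum(a > 0 | b > 0)
  if (union == 0) 0 else inter / union
}

#' Greedily match predicted to ground-truth instances
#'
#' Predictions are visited in order of descending score (ties by lower
#' prediction index); each is matched to the still-unmatched ground-truth
#' mask of highest IoU, provided that IoU reaches the threshold (IoU ties
#' by lower ground-truth index). Deterministic.
#'
#' @param pred_masks list of 0/1 matrices.
#' @param scores numeric vector, one per prediction (default all 1).
#' @param gt_masks list of 0/1 matrices.
#' @param tau IoU threshold in (0, 1].
#' @return a `match_result`: data frame `pairs` (pred, gt, iou), integer
#'   vectors `unmatched_pred` / `unmatched_gt`, and `tau`.
#' @export
match_instances <- function(pred_masks, gt_masks, tau = 0.5,
                            scores = rep(1, length(pred_masks))) {
  stopifnot(tau > 0, tau <= 1, length(scores) == length(pred_masks))
  np <- length(pred_masks); ng <- length(gt_masks)
  order_p <- order(-scores, seq_len(np))
  gt_free <- rep(TRUE, ng)
  pairs <- list()
  matched_p <- logical(np)
  for (p in order_p) {
    if (!ng) break
    ious <- vapply(seq_len(ng), function(g) {
      if (gt_free[g]) mask_iou(pred_masks[[p]], gt_masks[[g]]) else -1
    }, numeric(1))
    g_best <- which.max(ious)  # which.max takes the first (lowest id) tie
    if (ious[g_best] >= tau) {
      pairs[[length(pairs) + 1L]] <-
        data.frame(pred = p, gt = g_best, iou = ious[g_best])
      gt_free[g_best] <- FALSE
      matched_p[p] <- TRUE
    }
  }
  structure(list(
    pairs = if (length(pairs)) do.call(rbind, pairs) else
      data.frame(pred = integer(), gt = integer(), iou = numeric()),
    unmatched_pred = which(!matched_p),
    unmatched_gt = which(gt_free),
    tau = tau), class = "match_result")
}

# normalize the flexible preds/gts argument into a list of per-image sets
.as_image_sets <- function(x, with_scores) {
  one <- function(s) {
    if (is.list(s) && !is.null(s$masks)) {
      list(masks = s$masks,
           scores = s$scores %||% rep(1, length(s$masks)))
    } else {
      list(masks = s, scores = rep(1, length(s)))
    }
  }
  if (!length(x)) return(list(list(masks = list(), scores = numeric())))
  if (is.list(x) && !is.null(x$masks)) return(list(one(x)))
  if (is.list(x) && is.matrix(x[[1]])) return(list(one(x)))
  lapply(x, one)
}

#' Average precision at an IoU threshold
#'
#' Two variants of AP over one or more images (instances pooled across
#' images by default):
#' * `"precision"`: 100 x matched predictions / total predictions — AP
#'   read as the percentage of correctly predicted instances.
#' * `"coco"`: 101-point interpolated average precision over the pooled
#'   score-ranked prediction list, x 100.
#'
#' @param preds predictions: a list of 0/1 mask matrices, a list with
#'   `masks` and `scores`, or a list of such per-image sets.
#' @param gts ground truth in the same layouts (scores ignored).
#' @param tau IoU threshold in (0, 1].
#' @param variant `"precision"` or `"coco"`.
#' @return AP in `[0, 100]` (0, with a warning, for the precision variant
#'   with no predictions).
#' @seealso [eval_report()] for the full per-image report.
#' @export
ap_at_iou <- function(preds, gts, tau = 0.5,
                      variant = c("precision", "coco")) {
  variant <- match.arg(variant)
  pred_sets <- .as_image_sets(preds, TRUE)
  gt_sets <- .as_image_sets(gts, FALSE)
  stopifnot(length(pred_sets) == length(gt_sets))

  all_scores <- numeric()
  all_correct <- logical()
  n_gt <- 0L
  n_pred <- 0L
  n_matched <- 0L
  for (i in seq_along(pred_sets)) {
    ps <- pred_sets[[i]]; gs <- gt_sets[[i]]
    mr <- match_instances(ps$masks, gs$masks, tau, scores = ps$scores)
    n_gt <- n_gt + length(gs$masks)
    n_pred <- n_pred + length(ps$masks)
    n_matched <- n_matched + nrow(mr$pairs)
    correct <- seq_along(ps$masks) %in% mr$pairs$pred
    all_scores <- c(all_scores, ps$scores)
    all_correct <- c(all_correct, correct)
  }

  if (variant == "precision") {
    if (n_pred == 0) {
      warning("no predictions: precision-variant AP undefined, reporting 0")
      return(0)
    }
    return(100 * n_matched / n_pred)
  }
  # coco: precision/recall curve over the pooled ranked list
  if (n_gt == 0 || n_pred == 0) return(0)
  ord <- order(-all_scores, seq_along(all_scores))
  tp <- cumsum(all_correct[ord])
  fp <- cumsum(!all_correct[ord])
  recall <- tp / n_gt
  precision <- tp / (tp + fp)
  # monotone envelope, then 101-point interpolation
  for (i in rev(seq_along(precision))[-1]) {
    precision[i] <- max(precision[i], precision[i + 1])
  }
  rpts <- seq(0, 1, by = 0.01)
  interp <- vapply(rpts, function(r) {
    ok <- recall >= r - 1e-12
    if (any(ok)) max(precision[ok]) else 0
  }, numeric(1))
  100 * mean(interp)
}

#' Recall at an IoU threshold
#'
#' Companion to the precision-variant AP: 100 x matched ground-truth
#' instances / total ground-truth instances, pooled across images.
#'
#' @inheritParams ap_at_iou
#' @return recall in `[0, 100]`.
#' @export
recall_at_iou <- function(preds, gts, tau = 0.5) {
  pred_sets <- .as_image_sets(preds, TRUE)
  gt_sets <- .as_image_sets(gts, FALSE)
  n_gt <- 0L; n_matched <- 0L
  for (i in seq_along(pred_sets)) {
    mr <- match_instances(pred_sets[[i]]$masks, gt_sets[[i]]$masks, tau,
                          scores = pred_sets[[i]]$scores)
    n_gt <- n_gt + length(gt_sets[[i]]$masks)
    n_matched <- n_matched + nrow(mr$pairs)
  }
  if (n_gt == 0) return(0)
  100 * n_matched / n_gt
}

#' Foreground mean absolute error
#'
#' Average absolute pixel difference between two images over the
#' foreground region only, on the 0-255 scale. The foreground is taken
#' from ground truth (typically the union of ground-truth leaf masks),
#' never from predictions.
#'
#' @param generated,reference H x W x 3 arrays of identical shape.
#' @param foreground 0/1 matrix; must contain at least one pixel.
#' @return mean of `|generated - reference|` over channels at foreground
#'   pixels.
#' @export
foreground_mae <- function(generated, reference, foreground) {
  if (!identical(dim(generated), dim(reference))) {
    stop("shape mismatch", call. = FALSE)
  }
  if (!all(dim(foreground) == dim(generated)[1:2])) {
    stop("foreground mask shape mismatch", call. = FALSE)
  }
  sel <- foreground > 0
  if (!any(sel)) stop("empty foreground", call. = FALSE)
  diffs <- abs(generated - reference)
  mean(vapply(seq_len(dim(generated)[3]), function(ch) {
    mean(diffs[, , ch][sel])
  }, numeric(1)))
}

#' Evaluate predicted against ground-truth COCO annotations
#'
#' Loads two COCO JSON files, matches instances per image at each
#' threshold, and reports pooled AP (both variants), recall, and the
#' per-image match tables.
#'
#' @param pred_path,gt_path COCO annotation files (images are not read).
#' @param taus IoU thresholds.
#' @param variant default AP variant reported as `ap`.
#' @return an `eval_report` list: one entry per threshold with `ap`,
#'   `ap_precision`, `ap_coco`, `recall`, `per_image` (matched /
#'   predicted / gt counts), plus the `variant` used.
#' @export
eval_report <- function(pred_path, gt_path, taus = c(0.5, 0.75),
                        variant = c("precision", "coco")) {
  variant <- match.arg(variant)
  preds <- read_coco(pred_path, load_images = FALSE)
  gts <- read_coco(gt_path, load_images = FALSE)
  gt_ids <- vapply(gts, function(r) as.character(r$image_id), character(1))
  pred_ids <- vapply(preds, function(r) as.character(r$image_id),
                     character(1))
  pred_sets <- lapply(gt_ids, function(id) {
    i <- match(id, pred_ids)
    if (is.na(i)) list(masks = list(), scores = numeric())
    else {
      sc <- preds[[i]]$scores
      sc[is.na(sc)] <- 1
      list(masks = preds[[i]]$masks, scores = sc)
    }
  })
  gt_sets <- lapply(gts, function(r) list(masks = r$masks))

  out <- lapply(taus, function(tau) {
    per_image <- do.call(rbind, lapply(seq_along(gt_ids), function(i) {
      mr <- match_instances(pred_sets[[i]]$masks, gt_sets[[i]]$masks, tau,
                            scores = pred_sets[[i]]$scores)
      data.frame(image_id = gt_ids[i], matched = nrow(mr$pairs),
                 predicted = length(pred_sets[[i]]$masks),
                 gt = length(gt_sets[[i]]$masks))
    }))
    list(tau = tau,
         ap = ap_at_iou(pred_sets, gt_sets, tau, variant),
         ap_precision = ap_at_iou(pred_sets, gt_sets, tau, "precision"),
         ap_coco = ap_at_iou(pred_sets, gt_sets, tau, "coco"),
         recall = recall_at_iou(pred_sets, gt_sets, tau),
         per_image = per_image)
  })
  structure(list(thresholds = out, variant = variant),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("instance-segmentation evaluation (variant:", x$variant, ")\n")
  for (t in x$thresholds) {
    cat(sprintf("  AP@%d: %.2f (precision %.2f, coco %.2f, recall %.2f)\n",
                round(100 * t$tau), t$ap, t$ap_precision, t$ap_coco,
                t$recall))
  }
  invisible(x)
}
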