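# Multi-label evaluation metrics.
#
# Average precision follows the non-interpolated definition: samples are
# ranked by descending score (ties broken by sample index, stable) and AP is
# the mean, over the positive samples, of the precision at each positive's
# rank. mAP averages AP over classes; classes without positives are excluded
# with a warning (AP is undefined at zero positives). Thresholded metrics
# (precision/recall/F1/accuracy) apply a 0.5 cut on sigmoid-transformed
# scores; weighted variants average per-class values with weights
# proportional to class support.

#' Average precision of one class
#'
#' @param scores Numeric vector of real-valued scores (higher = more
#'   positive).
#' @param labels Binary vector of the same length.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(scores, labels) {
  if (length(scores) != length(labels)) stop_thanet("length mismatch")
  if (!all(labels %in% c(0, 1))) stop_thanet("labels must be 0/1")
  npos <- sum(labels)
  if (npos == 0) stop_thanet("average precision undefined: no positives")
  ord <- order(-scores, seq_along(scores)) # ties broken by sample index
  rel <- labels[ord]
  prec <- cumsum(rel) / seq_along(rel)
  sum(prec * rel) / npos
}

#' Mean average precision over classes
#'
#' @param scores `N x C` score matrix.
#' @param labels `N x C` binary matrix.
#' @return Unweighted mean of per-class APs over classes that have at least
#'   one positive; classes without positives are dropped with a warning.
#' @export
mean_average_precision <- function(scores, labels) {
  stopifnot(all(dim(scores) == dim(labels)))
  has_pos <- colSums(labels) > 0
  if (!any(has_pos)) stop_thanet("no class has positive labels")
  if (!all(has_pos)) {
    warning(sum(!has_pos), " class(es) without positives excluded from mAP",
            call. = FALSE)
  }
  aps <- vapply(which(has_pos), function(k) {
    average_precision(scores[, k], labels[, k])
  }, numeric(1))
  mean(aps)
}

#' Confusion counts of a binary prediction
#' @param pred Binary prediction vector.
#' @param labels Binary truth vector.
#' @return Named vector `c(tp, tn, fp, fn)`.
#' @export
confusion_counts <- function(pred, labels) {
  c(tp = sum(pred == 1 & labels == 1), tn = sum(pred == 0 & labels == 0),
    fp = sum(pred == 1 & labels == 0), fn = sum(pred == 0 & labels == 1))
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2PR / (P + R)`; defined as 0 when `P + R = 0`. Accepts
#' percentages or proportions (returned on the same scale).
#'
#' @param precision,recall Precision and recall values.
#' @return F1 on the input scale.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Precision, recall and F1 from confusion counts
#'
#' Ratios with undefined denominators are reported as 0 with a warning.
#'
#' @param counts Named vector from [confusion_counts()] (needs `tp`, `fp`,
#'   `fn`).
#' @return Named vector `c(precision, recall, f1)`.
#' @export
prf1 <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]; fn <- counts[["fn"]]
  if (tp + fp == 0) {
    warning("precision undefined (no predicted positives); reporting 0",
            call. = FALSE)
    p <- 0
  } else p <- tp / (tp + fp)
  if (tp + fn == 0) {
    warning("recall undefined (no true positives); reporting 0",
            call. = FALSE)
    r <- 0
  } else r <- tp / (tp + fn)
  c(precision = p, recall = r, f1 = f1_score(p, r))
}

#' Accuracy from confusion counts
#' @param counts Named vector with `tp`, `tn`, `fp`, `fn`.
#' @return `(tp + tn) / total`.
#' @export
accuracy <- function(counts) {
  tot <- sum(counts[c("tp", "tn", "fp", "fn")])
  if (tot == 0) stop_thanet("accuracy undefined on zero samples")
  (counts[["tp"]] + counts[["tn"]]) / tot
}

#' Support-weighted precision, recall and F1
#'
#' Per-class thresholded metrics averaged with weights equal to class
#' support over total support.
#'
#' @param scores `N x C` real score matrix (logits).
#' @param labels `N x C` binary matrix.
#' @param threshold Decision threshold on sigmoid-transformed scores.
#' @return Named vector `c(precision, recall, f1)` (weighted).
#' @export
weighted_prf1 <- function(scores, labels, threshold = 0.5) {
  pred <- (stats::plogis(scores) >= threshold) * 1
  support <- colSums(labels)
  if (sum(support) == 0) stop_thanet("no positive labels in any class")
  per <- t(vapply(seq_len(ncol(labels)), function(k) {
    suppressWarnings(prf1(confusion_counts(pred[, k], labels[, k])))
  }, numeric(3)))
  w <- support / sum(support)
  c(precision = sum(w * per[, 1]), recall = sum(w * per[, 2]),
    f1 = sum(w * per[, 3]))
}

#' Full evaluation of multi-label predictions
#'
#' @param scores `N x C` logit matrix.
#' @param labels `N x C` binary matrix.
#' @param threshold Decision threshold on sigmoid scores.
#' @param label_names Class names (defaults to [complication_labels()] when
#'   `C == 7`).
#' @return A `metrics_report`: list with `per_class` (data frame: support,
#'   AP, precision, recall, F1, accuracy per class), `map`, `weighted`
#'   (P/R/F1), `macro` (P/R/F1), `threshold`, `n`.
#' @export
evaluate_predictions <- function(scores, labels, threshold = 0.5,
                                 label_names = NULL) {
  stopifnot(all(dim(scores) == dim(labels)))
  C <- ncol(scores)
  if (is.null(label_names)) {
    label_names <- if (C == 7) complication_labels()
                   else paste0("class", seq_len(C))
  }
  pred <- (stats::plogis(scores) >= threshold) * 1
  per <- lapply(seq_len(C), function(k) {
    cnt <- confusion_counts(pred[, k], labels[, k])
    pr <- suppressWarnings(prf1(cnt))
    ap <- if (sum(labels[, k]) > 0) {
      average_precision(scores[, k], labels[, k])
    } else NA_real_
    data.frame(label = label_names[k], support = sum(labels[, k]), ap = ap,
               precision = pr[["precision"]], recall = pr[["recall"]],
               f1 = pr[["f1"]], accuracy = accuracy(cnt))
  })
  per <- do.call(rbind, per)
  w <- suppressWarnings(weighted_prf1(scores, labels, threshold))
  structure(list(
    per_class = per,
    map = suppressWarnings(mean_average_precision(scores, labels)),
    weighted = w,
    macro = c(precision = mean(per$precision), recall = mean(per$recall),
              f1 = mean(per$f1)),
    threshold = threshold, n = nrow(scores)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("n = %d | mAP %.3f | weighted P %.3f R %.3f F1 %.3f\n",
              x$n, x$map, x$weighted[["precision"]], x$weighted[["recall"]],
              x$weighted[["f1"]]))
  print(x$per_class, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a metrics report to JSON
#' @param report A `metrics_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       dataframe = "rows", digits = NA)
  invisible(path)
}

#' No-skill mAP baseline by simulation
#'
#' Estimates the mAP a random scorer achieves on a given label matrix by
#' averaging over simulated standard-normal score draws; the multi-label
#' chance level depends on class prevalences, so it is simulated rather than
#' assumed.
#'
#' @param labels `N x C` binary matrix.
#' @param n_sim Simulation draws.
#' @param seed Integer seed.
#' @return Mean mAP of random scores.
#' @export
noskill_map <- function(labels, n_sim = 200, seed = 1) {
  with_seed(seed, {
    mean(vapply(seq_len(n_sim), function(i) {
      sc <- matrix(stats::rnorm(length(labels)), nrow(labels), ncol(labels))
      suppressWarnings(mean_average_precision(sc, labels))
    }, numeric(1)))
  })
}
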