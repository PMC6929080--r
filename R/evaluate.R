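#' Root-mean-square error
#'
#' @param pred,truth Equal-length numeric vectors.
#' @return `sqrt(mean((pred - truth)^2))`.
#' @export
rmse <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  if (length(pred) == 0L) stop("empty vectors")
  sqrt(mean((pred - truth)^2))
}

#' Mean absolute error
#'
#' @inheritParams rmse
#' @return `mean(abs(pred - truth))`.
#' @export
mae <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  if (length(pred) == 0L) stop("empty vectors")
  mean(abs(pred - truth))
}

#' Per-column error between a predicted and a reference curve
#'
#' Row differences over the shared column span feed RMSE and MAE; columns
#' outside the overlap are excluded and counted.
#'
#' @param pred,truth [layer_curve()] objects with overlapping spans.
#' @return Named vector `c(rmse, mae)` with attribute `n_excluded`.
#' @export
curve_error <- function(pred, truth) {
  shared <- intersect(pred$cols, truth$cols)
  if (length(shared) == 0L) stop("curves share no columns")
  dp <- curve_row_at(pred, shared)
  dt <- curve_row_at(truth, shared)
  out <- c(rmse = rmse(dp, dt), mae = mae(dp, dt))
  attr(out, "n_excluded") <-
    length(union(pred$cols, truth$cols)) - length(shared)
  out
}

#' Confusion matrix and classification rates
#'
#' @param predicted,truth Character vectors of class labels
#'   (`"two_layers"` / `"three_layers"`).
#' @param positive The positive class; images showing all three layers by
#'   default.
#' @return List with `confusion` (TP/FP/TN/FN), `accuracy`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`; rates with a zero denominator are `NaN`.
#' @export
classification_metrics <- function(predicted, truth,
                                   positive = "three_layers") {
  if (length(predicted) != length(truth)) stop("length mismatch")
  known <- c("two_layers", "three_layers")
  bad <- setdiff(unique(c(predicted, truth)), known)
  if (length(bad) > 0) stop("unknown class label: ", bad[1])
  tp <- sum(predicted == positive & truth == positive)
  fp <- sum(predicted == positive & truth != positive)
  tn <- sum(predicted != positive & truth != positive)
  fn <- sum(predicted != positive & truth == positive)
  rate <- function(a, b) if (a + b == 0) NaN else a / (a + b)
  list(confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
       accuracy = (tp + tn) / length(truth),
       sensitivity = rate(tp, fn),
       specificity = rate(tn, fp),
       ppv = rate(tp, fp),
       npv = rate(tn, fn))
}

#' Area under the ROC curve
#'
#' Mann-Whitney pairwise formulation: the probability that a random positive
#' scores above a random negative, ties counted one half.
#'
#' @param scores Numeric confidence scores (higher favors the positive
#'   class).
#' @param truth Class labels.
#' @param positive The positive class label.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, truth, positive = "three_layers") {
  if (length(scores) != length(truth)) stop("length mismatch")
  pos <- truth == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate segmentations against phantom ground truth
#'
#' Aggregates per-curve RMSE/MAE (overall and per scenario), layer-count
#' classification rates and the ROC AUC of the distinctness confidence
#' score over a list of results.
#'
#' @param results List of `oct_segmentation` objects (or `NULL` for failed
#'   images).
#' @param truths Matching list of `ground_truth` objects.
#' @return An `eval_report` list: `rmse`, `mae`, `per_scenario`, `confusion`
#'   and rates, `auc`, `n`, `n_failed`. Errors are in pixels.
#' @export
evaluate_results <- function(results, truths) {
  if (length(results) != length(truths)) stop("length mismatch")
  n <- length(results)
  scen <- vapply(truths, function(t) t$scenario, character(1))
  pred_class <- vapply(results, function(r)
    if (is.null(r)) "two_layers" else r$layers$region_class, character(1))
  true_class <- vapply(truths, function(t)
    if (t$layer_count == 3L) "three_layers" else "two_layers", character(1))
  scores <- vapply(results, function(r)
    if (is.null(r)) 0 else r$layers$confidence, numeric(1))

  errs <- lapply(seq_len(n), function(i) {
    r <- results[[i]]; t <- truths[[i]]
    if (is.null(r)) return(NULL)
    pairs <- c("scl_outer", "cornea",
               if (!is.null(r$layers$scl_inner) &&
                   !is.null(t$curves$scl_inner)) "scl_inner")
    diffs <- unlist(lapply(pairs, function(nm) {
      pr <- r$layers[[nm]]; tr <- t$curves[[nm]]
      if (is.null(pr) || is.null(tr)) return(numeric(0))
      shared <- intersect(pr$cols, tr$cols)
      if (length(shared) == 0L) return(numeric(0))
      curve_row_at(pr, shared) - curve_row_at(tr, shared)
    }))
    diffs
  })
  pooled <- unlist(errs)
  per_scen <- lapply(split(seq_len(n), scen), function(idx) {
    d <- unlist(errs[idx])
    if (length(d) == 0L) return(c(rmse = NaN, mae = NaN))
    c(rmse = sqrt(mean(d^2)), mae = mean(abs(d)))
  })
  cm <- classification_metrics(pred_class, true_class)
  auc <- tryCatch(roc_auc(scores, true_class), error = function(e) NaN)
  structure(c(list(
    rmse = if (length(pooled)) sqrt(mean(pooled^2)) else NaN,
    mae = if (length(pooled)) mean(abs(pooled)) else NaN,
    per_scenario = per_scen, auc = auc, n = n,
    n_failed = sum(vapply(results, is.null, logical(1)))), cm),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  cat(sprintf("  segmentation: RMSE %.3f px, MAE %.3f px (n=%d, failed=%d)\n",
              x$rmse, x$mae, x$n, x$n_failed))
  for (s in names(x$per_scenario))
    cat(sprintf("    %-8s RMSE %7.3f  MAE %7.3f\n", s,
                x$per_scenario[[s]]["rmse"], x$per_scenario[[s]]["mae"]))
  cat(sprintf("  classification: acc %.4f sens %.4f spec %.4f ppv %.4f npv %.4f\n",
              x$accuracy, x$sensitivity, x$specificity, x$ppv, x$npv))
  cat(sprintf("  AUC %.4f; confusion TP=%d FP=%d TN=%d FN=%d\n", x$auc,
              x$confusion["TP"], x$confusion["FP"], x$confusion["TN"],
              x$confusion["FN"]))
  invisible(x)
}
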