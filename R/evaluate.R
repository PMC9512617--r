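# Evaluation: confusion matrix, support-weighted F1, accuracy, and the
# channel-correlation analysis behind axis-wise picture construction.

#' Confusion matrix from true and predicted labels
#'
#' @param y_true,y_pred Equal-length label vectors; every value must belong
#'   to `classes`.
#' @param classes Class label set (default: sorted union of observed labels).
#' @return Integer matrix of class `confusion_matrix`, rows = true class,
#'   columns = predicted class.
#' @export
confusion_matrix <- function(y_true, y_pred,
                             classes = sort(unique(c(y_true, y_pred)))) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  bad <- setdiff(unique(c(y_true, y_pred)), classes)
  if (length(bad))
    stop("label(s) outside the class set: ", paste(bad, collapse = ", "))
  cm <- unclass(as.matrix(table(factor(y_true, classes),
                                factor(y_pred, classes))))
  storage.mode(cm) <- "integer"
  dimnames(cm) <- list(as.character(classes), as.character(classes))
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Support-weighted F1 score
#'
#' `F = sum_i w_i * 2 P_i R_i / (P_i + R_i)` over the classes, where `P_i`
#' is column precision, `R_i` row recall, and `w_i` the class's share of the
#' true samples (or uniform weights). A class with `P_i + R_i = 0`
#' contributes 0.
#'
#' @param cm A [confusion_matrix].
#' @param weights `"support"` (default) or `"uniform"`.
#' @param exclude Optional class labels to drop from the sum (e.g. the NULL
#'   class); weights are renormalized over the remaining classes.
#' @return Score in `[0, 1]`; 1 exactly when `cm` is diagonal with every
#'   included class present.
#' @export
weighted_f1 <- function(cm, weights = c("support", "uniform"),
                        exclude = NULL) {
  weights <- match.arg(weights)
  if (sum(cm) == 0) stop("empty confusion matrix")
  pc <- per_class_metrics(cm)
  keep <- !(rownames(cm) %in% exclude)
  if (!any(keep)) stop("no classes left after exclusion")
  w <- if (weights == "support") pc$support[keep] / sum(pc$support[keep])
       else rep(1 / sum(keep), sum(keep))
  sum(w * pc$f1[keep])
}

per_class_metrics <- function(cm) {
  support <- rowSums(cm)
  predicted <- colSums(cm)
  tp <- diag(cm)
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  data.frame(class = rownames(cm), support = as.integer(support),
             precision = precision, recall = recall, f1 = f1,
             row.names = NULL)
}

#' Overall accuracy
#'
#' @param cm A [confusion_matrix].
#' @return Fraction of correctly classified samples (trace over total).
#' @export
accuracy <- function(cm) {
  if (sum(cm) == 0) stop("empty confusion matrix")
  sum(diag(cm)) / sum(cm)
}

#' Evaluation report
#'
#' @param y_true,y_pred Label vectors (see [confusion_matrix]).
#' @param classes Class label set.
#' @return An object of class `evaluation_report` with the confusion matrix,
#'   per-class precision/recall/F1, support-weighted F1, and accuracy;
#'   printing gives a structured text table.
#' @export
evaluation_report <- function(y_true, y_pred,
                              classes = sort(unique(c(y_true, y_pred)))) {
  cm <- confusion_matrix(y_true, y_pred, classes)
  structure(list(confusion = cm, per_class = per_class_metrics(cm),
                 weighted_f1 = weighted_f1(cm), accuracy = accuracy(cm)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation over", sum(x$confusion), "windows\n\n")
  pc <- x$per_class
  pc$precision <- round(pc$precision, 4)
  pc$recall <- round(pc$recall, 4)
  pc$f1 <- round(pc$f1, 4)
  print(pc, row.names = FALSE)
  cat(sprintf("\nweighted F1: %.4f\naccuracy:    %.4f\n",
              x$weighted_f1, x$accuracy))
  cat("\nConfusion matrix (rows = true):\n")
  print(unclass(x$confusion))
  invisible(x)
}

#' Channel-correlation analysis of a recording
#'
#' Computes absolute Pearson correlations for (a) same-axis channel pairs
#' across positions and (b) cross-axis pairs within a position, with the
#' fraction of weakly correlated pairs (`|r|` below the threshold) per
#' group. Same-axis cross-position correlation exceeding cross-axis
#' correlation is the premise behind grouping channels into per-axis
#' pictures. Constant channels are excluded with a warning.
#'
#' @param rec An [mp_recording] with at least 3 samples.
#' @param threshold Weak-correlation threshold on `|r|` (default 0.3).
#' @return An object of class `axis_correlation_report`: data frames
#'   `same_axis` and `cross_axis` (pair, `abs_r`), per-group `mean_abs_r`
#'   and `weak_fraction`, and the threshold.
#' @export
axis_correlation_report <- function(rec, threshold = 0.3) {
  if (nrow(rec$channels) < 3L) stop("need at least 3 samples per channel")
  sds <- apply(rec$channels, 2L, stats::sd)
  if (all(sds == 0)) stop("all channels are constant; correlations undefined")
  if (any(sds == 0))
    warning("excluding constant channel(s): ",
            paste(colnames(rec$channels)[sds == 0], collapse = ", "))
  ok <- function(nm) sds[nm] > 0
  pos <- rec$layout$positions
  axes <- c("x", "y", "z")
  same <- list(); cross <- list()
  for (a in axes) for (i in seq_along(pos)) {
    for (j in seq_along(pos)) if (i < j) {
      c1 <- paste(pos[i], a, sep = "_"); c2 <- paste(pos[j], a, sep = "_")
      if (ok(c1) && ok(c2))
        same[[length(same) + 1L]] <- data.frame(
          pair = paste(c1, c2, sep = " ~ "), axis = a,
          abs_r = abs(stats::cor(rec$channels[, c1], rec$channels[, c2])))
    }
  }
  for (p in pos) for (ai in 1:2) for (aj in seq.int(ai + 1L, 3L)) {
    c1 <- paste(p, axes[ai], sep = "_"); c2 <- paste(p, axes[aj], sep = "_")
    if (ok(c1) && ok(c2))
      cross[[length(cross) + 1L]] <- data.frame(
        pair = paste(c1, c2, sep = " ~ "), position = p,
        abs_r = abs(stats::cor(rec$channels[, c1], rec$channels[, c2])))
  }
  same <- do.call(rbind, same); cross <- do.call(rbind, cross)
  grp <- function(df) if (is.null(df)) c(mean_abs_r = NA_real_,
                                         weak_fraction = NA_real_)
    else c(mean_abs_r = mean(df$abs_r),
           weak_fraction = mean(df$abs_r < threshold))
  structure(list(same_axis = same, cross_axis = cross,
                 summary = rbind(same_axis = grp(same),
                                 cross_axis = grp(cross)),
                 threshold = threshold),
            class = "axis_correlation_report")
}

#' @export
print.axis_correlation_report <- function(x, ...) {
  cat("Channel correlation analysis (weak: |r| <", x$threshold, ")\n")
  print(round(x$summary, 4))
  invisible(x)
}
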