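#' Observed-vs-identified confusion matrix
#'
#' Rows are observed (annotated) classes, columns identified (predicted)
#' classes: `x[i, j]` counts the epochs observed as class i and identified
#' as class j.
#'
#' @param observed,identified equal-length label vectors.
#' @param classes ordered class set; defaults to the sorted union of the
#'   labels appearing in either vector.
#' @return K x K integer matrix of class `confusion_matrix` with dimnames
#'   `observed`/`identified` and an `N` attribute (total count).
#' @export
#' @examples
#' confusion_matrix(c("a", "a", "b"), c("a", "b", "b"))
confusion_matrix <- function(observed, identified, classes = NULL) {
  observed <- as.character(observed)
  identified <- as.character(identified)
  if (length(observed) != length(identified))
    stop("observed and identified must have equal length")
  if (is.null(classes)) classes <- sort(unique(c(observed, identified)))
  if (!all(observed %in% classes) || !all(identified %in% classes))
    stop("labels outside the declared class set")
  x <- table(factor(observed, levels = classes),
             factor(identified, levels = classes))
  x <- matrix(as.integer(x), nrow = length(classes),
              dimnames = list(observed = classes, identified = classes))
  attr(x, "N") <- sum(x)
  class(x) <- c("confusion_matrix", class(x))
  x
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows observed, columns identified), N =",
      attr(x, "N"), "\n")
  print(unclass(x))
  invisible(x)
}

#' Per-class one-vs-rest metrics from a confusion matrix
#'
#' For each class, TP/TN/FP/FN are the one-vs-rest counts and the four
#' proportions follow the evaluation equations: accuracy
#' (TP+TN)/(TP+TN+FP+FN), precision TP/(TP+FP), sensitivity TP/(TP+FN), and
#' specificity. Specificity has two modes: `"as_printed"` (the default)
#' computes TN/(TN+FN), reproducing the printed equation; `"standard"`
#' computes the conventional TN/(TN+FP). Metrics with a zero denominator are
#' returned as `NA` (undefined), except sensitivity with TP = 0 and FN > 0,
#' which is a true 0.
#'
#' @param cm a [confusion_matrix()].
#' @param mode `"as_printed"` or `"standard"` specificity denominator.
#' @return data.frame, one row per class: class, TP, TN, FP, FN, accuracy,
#'   precision, sensitivity, specificity.
#' @export
class_metrics <- function(cm, mode = c("as_printed", "standard")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- attr(cm, "N")
  classes <- rownames(cm)
  tp <- diag(unclass(cm))
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- n - tp - fn - fp
  ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  spec_den <- if (mode == "as_printed") tn + fn else tn + fp
  data.frame(
    class = classes,
    TP = as.integer(tp), TN = as.integer(tn),
    FP = as.integer(fp), FN = as.integer(fn),
    accuracy = ratio(tp + tn, rep(n, length(tp))),
    precision = ratio(tp, tp + fp),
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, spec_den),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Overall (micro-averaged) accuracy
#'
#' The proportion of epochs on the confusion-matrix diagonal, trace(x)/N.
#'
#' @param cm a [confusion_matrix()].
#' @return proportion in `[0, 1]`.
#' @export
overall_accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- attr(cm, "N")
  if (n == 0) stop("empty confusion matrix")
  sum(diag(unclass(cm))) / n
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement,
#' kappa = (N * sum_i x_ii - sum_i x_i+ x_+i) / (N^2 - sum_i x_i+ x_+i),
#' with the Fleiss interpretation bands: above 0.75 excellent, 0.40-0.75
#' fair to good, below 0.40 poor.
#'
#' @param cm a [confusion_matrix()].
#' @return list of class `kappa_result`: `kappa`, `interpretation`, and the
#'   observed/expected agreements `p_o`, `p_e`. Degenerate marginals
#'   (expected agreement 1) yield `kappa = NA` with interpretation
#'   `"undefined"`.
#' @export
cohen_kappa <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- attr(cm, "N")
  if (n == 0) stop("empty confusion matrix")
  x <- unclass(cm)
  marg <- sum(as.numeric(rowSums(x)) * as.numeric(colSums(x)))
  p_o <- sum(diag(x)) / n
  p_e <- marg / n^2
  if (n^2 == marg) {
    k <- NA_real_
    interp <- "undefined"
  } else {
    k <- (n * sum(diag(x)) - marg) / (n^2 - marg)
    interp <- kappa_interpretation(k)
  }
  structure(list(kappa = k, interpretation = interp, p_o = p_o, p_e = p_e),
            class = "kappa_result")
}

#' Interpret a kappa value on the Fleiss bands
#'
#' @param kappa numeric kappa value.
#' @return `"excellent"` (> 0.75), `"fair-to-good"` (0.40-0.75) or
#'   `"poor"` (< 0.40).
#' @export
kappa_interpretation <- function(kappa) {
  ifelse(is.na(kappa), "undefined",
         ifelse(kappa > 0.75, "excellent",
                ifelse(kappa >= 0.40, "fair-to-good", "poor")))
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa: %s (%s); p_o = %.4f, p_e = %.4f\n",
              format(x$kappa, digits = 4), x$interpretation, x$p_o, x$p_e))
  invisible(x)
}

#' Intra-rater reliability between two annotation tracks
#'
#' Cohen's kappa of the two per-second label sequences over the seconds both
#' tracks cover, with the class set being the union of the labels observed
#' in either track.
#'
#' @param track1,track2 data.frames with `second` and `behaviour` columns.
#' @return a `kappa_result`, see [cohen_kappa()].
#' @export
intra_rater_kappa <- function(track1, track2) {
  common <- intersect(track1$second, track2$second)
  if (!length(common)) stop("tracks cover disjoint seconds")
  a <- normalise_label(track1$behaviour[match(common, track1$second)])
  b <- normalise_label(track2$behaviour[match(common, track2$second)])
  cohen_kappa(confusion_matrix(a, b, classes = sort(unique(c(a, b)))))
}

#' Write per-class metrics as TSV / a confusion matrix as labelled CSV
#'
#' @param metrics data.frame from [class_metrics()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_tsv <- function(metrics, path) {
  utils::write.table(metrics, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metrics_tsv
#' @param cm a [confusion_matrix()].
#' @export
write_confusion_csv <- function(cm, path) {
  write.csv(as.data.frame(unclass(cm)), path, row.names = TRUE)
  invisible(path)
}
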