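#' Agreement and classification metrics
#'
#' All figures of merit are derived from a confusion matrix of frame counts
#' (reference in rows, prediction in columns). Cohen's kappa is the primary
#' chance-corrected agreement score; for a binary carrying task it has the
#' closed form
#' \deqn{\kappa = \frac{2(tp \cdot tn - fn \cdot fp)}
#'   {(tp+fp)(fp+tn) + (tp+fn)(fn+tn)}}
#' which coincides with the general multi-class definition
#' \eqn{(p_o - p_e)/(1 - p_e)}. Precision, recall and F1 are one-vs-rest and
#' reported as percentages; weighted summaries use the annotated class
#' proportions as weights.
#'
#' @name metrics
NULL

#' Confusion matrix from frame labels
#'
#' Counts only frames valid in both tracks (out-of-screen or disagreement
#' frames carry no label and are discarded).
#'
#' @param pred predicted labels: a `ch_frame_labels` or integer/character
#'   vector.
#' @param ref reference labels of the same length and scheme.
#' @param classes class names (required for bare vectors; taken from the
#'   scheme otherwise).
#' @return a K x K matrix of class `ch_confusion` (reference rows,
#'   prediction columns).
#' @export
confusion <- function(pred, ref, classes = NULL) {
  if (inherits(pred, "ch_frame_labels") && inherits(ref, "ch_frame_labels")) {
    if (pred$n != ref$n) stop("pred and ref have different lengths")
    if (!identical(pred$scheme$name, ref$scheme$name)) {
      stop(sprintf("scheme mismatch: '%s' vs '%s'",
                   pred$scheme$name, ref$scheme$name))
    }
    classes <- ref$scheme$classes
    ok <- pred$valid & ref$valid
    p <- pred$class_idx[ok]; r <- ref$class_idx[ok]
  } else {
    if (is.null(classes)) {
      classes <- sort(unique(c(pred, ref)))
    }
    p <- match(pred, classes); r <- match(ref, classes)
    ok <- !is.na(p) & !is.na(r)
    p <- p[ok]; r <- r[ok]
  }
  if (!length(p)) stop("no evaluable frames (all masked)")
  k <- length(classes)
  cm <- matrix(tabulate(r + k * (p - 1L), nbins = k * k), k, k,
               dimnames = list(reference = classes, prediction = classes))
  structure(cm, class = c("ch_confusion", "matrix"))
}

#' Build a confusion matrix from counts
#' @param counts K x K matrix (reference rows, prediction columns).
#' @param classes optional class names.
#' @export
as_confusion <- function(counts, classes = NULL) {
  cm <- as.matrix(counts)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  if (any(cm < 0)) stop("confusion counts must be non-negative")
  if (sum(cm) <= 0) stop("confusion matrix has zero total")
  if (is.null(classes)) {
    classes <- rownames(cm)
    if (is.null(classes)) classes <- paste0("class", seq_len(nrow(cm)))
  }
  dimnames(cm) <- list(reference = classes, prediction = classes)
  structure(cm, class = c("ch_confusion", "matrix"))
}

## tp/tn/fp/fn for a binary matrix; positive class "carry" when present,
## otherwise the second class.
binary_cells <- function(cm, positive = NULL) {
  if (nrow(cm) != 2L) stop("binary accessors require a 2x2 confusion matrix")
  classes <- rownames(cm)
  if (is.null(positive)) {
    positive <- if ("carry" %in% classes) "carry" else classes[2]
  }
  pos <- match(positive, classes)
  neg <- 3L - pos
  list(tp = cm[pos, pos], tn = cm[neg, neg],
       fp = cm[neg, pos], fn = cm[pos, neg])
}

#' Cohen's kappa, binary closed form
#'
#' @param cm a 2x2 `ch_confusion` (or matrix), positive class `"carry"`.
#' @param positive optional positive-class name.
#' @return kappa in `[-1, 1]`; `NA` with a warning when the denominator is
#'   degenerate (e.g. all counts in one row and column).
#' @export
kappa_binary <- function(cm, positive = NULL) {
  cells <- binary_cells(cm, positive)
  tp <- cells$tp; tn <- cells$tn; fp <- cells$fp; fn <- cells$fn
  den <- (tp + fp) * (fp + tn) + (tp + fn) * (fn + tn)
  if (den <= 0) {
    warning("kappa undefined: degenerate confusion matrix (zero denominator)")
    return(NA_real_)
  }
  2 * (tp * tn - fn * fp) / den
}

#' Cohen's kappa, general multi-class form
#'
#' \eqn{(p_o - p_e)/(1 - p_e)} with observed agreement \eqn{p_o} the
#' diagonal fraction and expected agreement \eqn{p_e} the sum of products of
#' the row and column marginal fractions. For a 2x2 matrix this equals
#' [kappa_binary()] exactly.
#'
#' @param cm a `ch_confusion` or square count matrix.
#' @export
kappa_multiclass <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  if (n <= 0) stop("confusion matrix has zero total")
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - pe) < 1e-15) {
    warning("kappa undefined: expected agreement is 1")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Overall accuracy (percent)
#' @param cm a `ch_confusion` or square count matrix.
#' @export
accuracy <- function(cm) {
  cm <- as.matrix(cm)
  100 * sum(diag(cm)) / sum(cm)
}

#' One-vs-rest precision, recall and F1 for one class (percent)
#'
#' Division by zero (no predicted or no actual positives) yields 0 with a
#' `degenerate` flag instead of NaN.
#'
#' @param cm a `ch_confusion` or square count matrix.
#' @param class class name or index.
#' @return named list: `precision`, `recall`, `f1` (percent), `degenerate`.
#' @export
prf <- function(cm, class) {
  cm <- as.matrix(cm)
  k <- if (is.character(class)) match(class, rownames(cm)) else as.integer(class)
  if (is.na(k) || k < 1L || k > nrow(cm)) stop("class not present in matrix")
  tp <- cm[k, k]
  fp <- sum(cm[-k, k])
  fn <- sum(cm[k, -k])
  degenerate <- FALSE
  precision <- if (tp + fp > 0) tp / (tp + fp) else { degenerate <- TRUE; 0 }
  recall <- if (tp + fn > 0) tp / (tp + fn) else { degenerate <- TRUE; 0 }
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    degenerate <- TRUE; 0
  }
  list(precision = 100 * precision, recall = 100 * recall, f1 = 100 * f1,
       degenerate = degenerate)
}

#' F1 from precision and recall percentages
#'
#' Harmonic mean on the percent scale; convenience for checking tabulated
#' precision/recall/F1 triples.
#'
#' @param precision,recall percentages.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Matthews correlation coefficient (binary)
#'
#' Provided as an optional extra; model selection and reporting in this
#' package use kappa.
#'
#' @param cm 2x2 confusion matrix.
#' @param positive optional positive-class name.
#' @export
mcc <- function(cm, positive = NULL) {
  cells <- binary_cells(cm, positive)
  tp <- cells$tp; tn <- cells$tn; fp <- cells$fp; fn <- cells$fn
  den <- sqrt((tp + fp)) * sqrt((tp + fn)) * sqrt((tn + fp)) * sqrt((tn + fn))
  if (den <= 0) {
    warning("MCC undefined: degenerate confusion matrix")
    return(NA_real_)
  }
  (tp * tn - fp * fn) / den
}

#' Full metric report for a confusion matrix
#'
#' @param cm a `ch_confusion` or square count matrix.
#' @param proportions per-class annotated fractions used as weights for the
#'   weighted averages; defaults to the reference (row) marginals. Must sum
#'   to 1 over the classes.
#' @return object of class `ch_metric_report`: `kappa`, `accuracy`,
#'   per-class data.frame (`proportion`, `precision`, `recall`, `f1`),
#'   `weighted` and `unweighted` precision/recall/F1 averages.
#' @export
metric_report <- function(cm, proportions = NULL) {
  cm <- as.matrix(cm)
  classes <- rownames(cm)
  if (is.null(classes)) classes <- paste0("class", seq_len(nrow(cm)))
  if (is.null(proportions)) {
    proportions <- rowSums(cm) / sum(cm)
  } else {
    if (length(proportions) != nrow(cm)) {
      stop("`proportions` length must match the number of classes")
    }
    if (abs(sum(proportions) - 1) > 1e-6) {
      stop("`proportions` must sum to 1")
    }
  }
  per <- lapply(seq_len(nrow(cm)), function(k) prf(cm, k))
  tab <- data.frame(class = classes,
                    proportion = as.numeric(proportions),
                    precision = vapply(per, `[[`, numeric(1), "precision"),
                    recall = vapply(per, `[[`, numeric(1), "recall"),
                    f1 = vapply(per, `[[`, numeric(1), "f1"))
  wavg <- function(v) sum(tab$proportion * v)
  structure(list(
    kappa = kappa_multiclass(cm), accuracy = accuracy(cm), per_class = tab,
    weighted = list(precision = wavg(tab$precision), recall = wavg(tab$recall),
                    f1 = wavg(tab$f1)),
    unweighted = list(precision = mean(tab$precision),
                      recall = mean(tab$recall), f1 = mean(tab$f1)),
    degenerate = any(vapply(per, `[[`, logical(1), "degenerate")),
    confusion = cm), class = "ch_metric_report")
}

#' @export
print.ch_metric_report <- function(x, ...) {
  cat(sprintf("Accuracy: %.1f%%   kappa: %.2f\n", x$accuracy, x$kappa))
  tab <- x$per_class
  tab$proportion <- sprintf("%.1f", 100 * tab$proportion)
  tab$precision <- sprintf("%.1f", tab$precision)
  tab$recall <- sprintf("%.1f", tab$recall)
  tab$f1 <- sprintf("%.1f", tab$f1)
  print(tab, row.names = FALSE)
  cat(sprintf("W avg  P/R/F1: %.1f / %.1f / %.1f\n",
              x$weighted$precision, x$weighted$recall, x$weighted$f1))
  cat(sprintf("UW avg P/R/F1: %.1f / %.1f / %.1f\n",
              x$unweighted$precision, x$unweighted$recall, x$unweighted$f1))
  invisible(x)
}
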