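#' Flat multiclass classification metrics
#'
#' Builds the confusion matrix (rows = truth, columns = prediction) and
#' derives accuracy, per-class precision/recall/F1, their unweighted macro
#' averages, and the Matthews correlation coefficient. For two classes the
#' MCC is the familiar
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; for more classes
#' the standard multiclass generalization
#' `(c*s - sum(p_k t_k)) / sqrt((s^2 - sum(p_k^2)) (s^2 - sum(t_k^2)))`
#' is used, which reduces to the binary formula at two classes. Zero
#' denominators (a class never predicted, a degenerate confusion matrix)
#' yield 0 and are recorded in the `notes` attribute.
#'
#' @param true_labels,predicted_labels Equal-length label vectors.
#' @param label_order Optional class ordering; defaults to the sorted union.
#' @return A `confusion_summary`: list with `table` (count matrix),
#'   `by_class` tibble, and overall `accuracy`, `macro_precision`,
#'   `macro_recall`, `macro_f1`, `mcc`. Has [tidy()] and [glance()] methods.
#' @export
#' @examples
#' flat_metrics(c("a", "a", "b"), c("a", "b", "b"))
flat_metrics <- function(true_labels, predicted_labels, label_order = NULL) {
  if (length(true_labels) == 0) stop("empty input", call. = FALSE)
  stopifnot(length(true_labels) == length(predicted_labels))
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (is.null(label_order)) {
    label_order <- sort(unique(c(true_labels, predicted_labels)))
  }
  bad <- setdiff(c(true_labels, predicted_labels), label_order)
  if (length(bad) > 0) {
    stop("labels outside label_order: ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  f <- function(x) factor(x, levels = label_order)
  cm <- table(truth = f(true_labels), prediction = f(predicted_labels))
  cm <- unclass(cm)

  notes <- character()
  tp <- diag(cm)
  pred_tot <- colSums(cm)
  true_tot <- rowSums(cm)
  precision <- ifelse(pred_tot > 0, tp / pred_tot, 0)
  if (any(pred_tot == 0)) {
    notes <- c(notes, paste0("precision set to 0 for never-predicted class: ",
                             paste(label_order[pred_tot == 0], collapse = ", ")))
  }
  recall <- ifelse(true_tot > 0, tp / true_tot, 0)
  if (any(true_tot == 0)) {
    notes <- c(notes, paste0("recall set to 0 for absent class: ",
                             paste(label_order[true_tot == 0], collapse = ", ")))
  }
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)

  s <- sum(cm)
  c_ <- sum(tp)
  denom <- sqrt(s^2 - sum(pred_tot^2)) * sqrt(s^2 - sum(true_tot^2))
  if (denom == 0) {
    mcc <- 0
    notes <- c(notes, "MCC denominator zero; MCC set to 0")
  } else {
    mcc <- (c_ * s - sum(pred_tot * true_tot)) / denom
  }

  structure(
    list(table = cm,
         by_class = tibble::tibble(class = label_order,
                                   precision = unname(precision),
                                   recall = unname(recall),
                                   f1 = unname(f1),
                                   support = unname(true_tot)),
         accuracy = c_ / s,
         macro_precision = mean(precision),
         macro_recall = mean(recall),
         macro_f1 = mean(f1),
         mcc = mcc,
         notes = notes),
    class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat("<confusion_summary>", nrow(x$table), "classes,", sum(x$table),
      "records\n")
  cat(sprintf("  accuracy %.4f | macro-F1 %.4f | MCC %.4f\n",
              x$accuracy, x$macro_f1, x$mcc))
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' @rdname flat_metrics
#' @param x A `confusion_summary`.
#' @param ... Unused.
#' @export
tidy.confusion_summary <- function(x, ...) x$by_class

#' @rdname flat_metrics
#' @export
glance.confusion_summary <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, macro_precision = x$macro_precision,
                 macro_recall = x$macro_recall, macro_f1 = x$macro_f1,
                 mcc = x$mcc, n = sum(x$table))
}

#' Binary MCC from confusion counts
#'
#' @param tp,tn,fp,fn Confusion-matrix counts.
#' @return The Matthews correlation coefficient; 0 when any denominator
#'   factor is 0.
#' @export
#' @examples
#' mcc_binary(40, 45, 5, 10)  # ~0.7006
mcc_binary <- function(tp, tn, fp, fn) {
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / denom
}

#' Hierarchical precision, recall and F-measure
#'
#' For each sequence `i`, `P_i` is the ancestor-closed set of the most
#' specific predicted label and `T_i` the ancestor-closed set of the true
#' label; then `hP = sum |P_i ∩ T_i| / sum |P_i|`,
#' `hR = sum |P_i ∩ T_i| / sum |T_i|`, and `hF` their harmonic mean.
#' Over-specific predictions lower only hP, under-specific ones only hR.
#' The universal root label is excluded from both sets by default (every
#' sequence shares it, so including it inflates both metrics);
#' `include_root = TRUE` restores the strict ancestor-closed sets.
#'
#' @param pred_paths,true_paths Either lists of root-first label paths or
#'   vectors of most-specific labels (expanded through the taxonomy). Ids
#'   are matched positionally.
#' @param tax A `te_taxonomy`; every path must be valid in it.
#' @param include_root Keep the root in `P_i`/`T_i` (default `FALSE`).
#' @return A `hier_eval` list: `hP`, `hR`, `hF`, and a per-sequence tibble
#'   (`n_pred`, `n_true`, `n_common`).
#' @export
#' @examples
#' tax <- default_taxonomy()
#' hier_metrics("LTR", "Gypsy", tax)  # hP 1, hR 2/3, hF 0.8
hier_metrics <- function(pred_paths, true_paths, tax, include_root = FALSE) {
  stopifnot(inherits(tax, "te_taxonomy"))
  as_sets <- function(paths) {
    if (!is.list(paths)) paths <- as.list(paths)
    lapply(paths, function(p) {
      p <- as.character(p)
      tip <- p[length(p)]
      full <- ancestors(tax, tip)
      # accept the root-first path with or without the universal root
      if (length(p) > 1 && !identical(p, full) && !identical(p, full[-1])) {
        stop("path not in taxonomy: ", paste(p, collapse = "/"), call. = FALSE)
      }
      if (include_root) full else setdiff(full, tax$root)
    })
  }
  P <- as_sets(pred_paths)
  T_ <- as_sets(true_paths)
  stopifnot(length(P) == length(T_))
  per <- tibble::tibble(
    n_pred = lengths(P),
    n_true = lengths(T_),
    n_common = mapply(function(p, t) length(intersect(p, t)), P, T_))
  hP <- if (sum(per$n_pred) > 0) sum(per$n_common) / sum(per$n_pred) else 0
  hR <- if (sum(per$n_true) > 0) sum(per$n_common) / sum(per$n_true) else 0
  hF <- if (hP + hR > 0) 2 * hP * hR / (hP + hR) else 0
  structure(list(hP = hP, hR = hR, hF = hF, per_sequence = per),
            class = "hier_eval")
}

#' @export
print.hier_eval <- function(x, ...) {
  cat(sprintf("<hier_eval> hP %.4f | hR %.4f | hF %.4f | n = %d\n",
              x$hP, x$hR, x$hF, nrow(x$per_sequence)))
  invisible(x)
}

#' @rdname hier_metrics
#' @param x A `hier_eval`.
#' @param ... Unused.
#' @export
glance.hier_eval <- function(x, ...) {
  tibble::tibble(hP = x$hP, hR = x$hR, hF = x$hF, n = nrow(x$per_sequence))
}

#' Write a metrics report as TSV
#'
#' One `metric<TAB>value` row per overall metric; for a `confusion_summary`
#' the labelled confusion matrix is appended to `<path>.matrix.tsv`.
#'
#' @param x A `confusion_summary` or `hier_eval`.
#' @param path Output TSV path.
#' @return The report tibble, invisibly.
#' @export
write_metrics <- function(x, path) {
  gl <- glance(x)
  report <- tibble::tibble(metric = names(gl), value = as.numeric(gl[1, ]))
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (inherits(x, "confusion_summary")) {
    utils::write.table(as.data.frame(unclass(x$table)),
                       paste0(path, ".matrix.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  invisible(report)
}
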