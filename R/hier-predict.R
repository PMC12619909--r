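#' Top-down threshold-stopped hierarchical prediction
#'
#' Starting at the taxonomy root, each query is handed to the classifier of
#' the current parent node; if the highest child probability is at least
#' `threshold` the query descends into that child (lexicographically first
#' child on exact ties), otherwise the traversal terminates and the current
#' node is the predicted label ("nonmandatory leaf-node prediction": a
#' sequence may be classified at any level). Traversal also stops at leaves,
#' and — flagged as `"model_missing"` — at reachable parent nodes without a
#' classifier. Internal nodes with a single child are passed through without
#' a classifier (confidence 1, no attention record).
#'
#' @param records Featurized query tibble (see [featurize()]), one row per
#'   sequence.
#' @param classifiers Named list, parent label -> `node_classifier` (or
#'   [mock_node_classifier()]).
#' @param tax A `te_taxonomy`.
#' @param threshold Stopping threshold in `(0, 1]` (default 0.60): descent
#'   happens iff the maximum child probability is `>= threshold`.
#' @return A tibble of prediction paths, one row per query: `id`, `label`
#'   (deepest assigned label), `path` (list of root-first label vectors),
#'   `stop_level` (number of edges descended), `confidences`,
#'   `alpha_cnn`, `alpha_rnn` (list columns, one entry per descent),
#'   `stopped_at_leaf`, `status` (`"ok"` or `"model_missing"`), `threshold`.
#' @export
predict_topdown <- function(records, classifiers, tax, threshold = 0.60) {
  stopifnot(inherits(tax, "te_taxonomy"),
            is.numeric(threshold), threshold > 0, threshold <= 1)
  n <- nrow(records)
  # cache per-node predictions for all queries (each node model is queried
  # once for the full batch; the traversal then just reads rows)
  node_cache <- new.env(parent = emptyenv())
  get_node_probs <- function(node) {
    if (!is.null(node_cache[[node]])) return(node_cache[[node]])
    clf <- classifiers[[node]]
    if (is.null(clf)) return(NULL)
    pr <- node_predict(clf, records)
    kids <- taxonomy_children(tax, node)
    if (is.null(colnames(pr$probs))) colnames(pr$probs) <- kids
    node_cache[[node]] <- pr
    pr
  }

  out <- purrr::map_dfr(seq_len(n), function(i) {
    path <- tax$root
    confs <- numeric(); a_c <- numeric(); a_r <- numeric()
    status <- "ok"; at_leaf <- FALSE
    repeat {
      node <- path[length(path)]
      kids <- taxonomy_children(tax, node)
      if (length(kids) == 0) { at_leaf <- TRUE; break }
      if (length(kids) == 1) {  # pass-through node: no classifier needed
        path <- c(path, kids)
        confs <- c(confs, 1); a_c <- c(a_c, NA_real_); a_r <- c(a_r, NA_real_)
        next
      }
      pr <- get_node_probs(node)
      if (is.null(pr)) { status <- "model_missing"; break }
      p <- pr$probs[i, ]
      best <- max(p)
      if (best < threshold) break
      winners <- names(p)[p == best]
      child <- sort(winners)[1]
      path <- c(path, child)
      confs <- c(confs, best)
      a_c <- c(a_c, pr$alpha[i, 1]); a_r <- c(a_r, pr$alpha[i, 2])
    }
    depth <- length(path) - 1L
    tibble::tibble(id = records$id[i], label = path[length(path)],
                   path = list(path), stop_level = depth,
                   confidences = list(confs),
                   alpha_cnn = list(a_c), alpha_rnn = list(a_r),
                   stopped_at_leaf = at_leaf, status = status,
                   threshold = threshold)
  })
  class(out) <- c("te_predictions", class(out))
  out
}

#' Run the top-down prediction over a threshold grid
#'
#' @param records Featurized query tibble.
#' @param classifiers Named list of node classifiers.
#' @param tax A `te_taxonomy`.
#' @param grid Ascending thresholds in `(0, 1]`; default the 0.50-0.95 grid
#'   in steps of 0.05.
#' @return A `te_predictions` tibble stacking one prediction set per
#'   threshold (distinguished by the `threshold` column). For a fixed query,
#'   paths at higher thresholds are prefixes of paths at lower ones.
#' @export
threshold_sweep <- function(records, classifiers, tax,
                            grid = seq(0.50, 0.95, by = 0.05)) {
  if (length(grid) == 0) stop("empty threshold grid", call. = FALSE)
  stopifnot(all(grid > 0), all(grid <= 1), !is.unsorted(grid))
  out <- purrr::map_dfr(grid, function(th) {
    predict_topdown(records, classifiers, tax, threshold = th)
  })
  class(out) <- c("te_predictions", class(out))
  out
}

#' Attention-dominance summary of prediction paths
#'
#' For each group of sequences, the fraction whose attention leaned on the
#' global CNN branch (`alpha_cnn > alpha_rnn`), on the local RNN branch, or
#' on neither (`|alpha_cnn - alpha_rnn| <= tie_tol`). Each sequence is
#' summarized by the attention weights of its deepest descent (the most
#' specific decision taken). The three fractions sum to 1 per group.
#'
#' @param paths A `te_predictions` tibble carrying attention traces.
#' @param grouping Column name in `paths` to group by (e.g. `"label"`), or a
#'   vector with one group per row of `paths`; default one overall group.
#' @param tie_tol Tie tolerance on `|alpha_cnn - alpha_rnn|` (default 1e-6).
#' @return Tibble with `group`, `n`, `cnn_dominant`, `rnn_dominant`, `equal`.
#'   Groups with no attention-carrying sequences are omitted with a warning.
#' @export
summarize_attention <- function(paths, grouping = NULL, tie_tol = 1e-6) {
  stopifnot(all(c("alpha_cnn", "alpha_rnn") %in% names(paths)))
  last_or_na <- function(v) {
    v <- v[!is.na(v)]
    if (length(v)) v[length(v)] else NA_real_
  }
  ac <- vapply(paths$alpha_cnn, last_or_na, 0)
  ar <- vapply(paths$alpha_rnn, last_or_na, 0)
  grp <- if (is.null(grouping)) rep("all", nrow(paths))
  else if (length(grouping) == 1 && grouping %in% names(paths)) paths[[grouping]]
  else grouping
  df <- tibble::tibble(group = as.character(grp), ac = ac, ar = ar)
  keep <- !is.na(df$ac)
  dropped <- setdiff(unique(df$group), unique(df$group[keep]))
  if (length(dropped) > 0) {
    warning("group(s) without attention traces omitted: ",
            paste(dropped, collapse = ", "))
  }
  df <- df[keep, ]
  out <- df |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      cnn_dominant = mean(.data$ac - .data$ar > tie_tol),
      rnn_dominant = mean(.data$ar - .data$ac > tie_tol),
      equal = mean(abs(.data$ac - .data$ar) <= tie_tol),
      .groups = "drop")
  class(out) <- c("te_attention_summary", class(out))
  out
}

#' Write predictions to the tabular interchange format
#'
#' One row per query and threshold: `sequence_id`, `predicted_path` (labels
#' joined by `/`), `stop_level`, `confidence` and the attention weights as
#' `;`-joined per-level values, and `threshold`. Row order equals input
#' order.
#'
#' @param paths A `te_predictions` tibble.
#' @param path Output TSV file.
#' @return The written tibble, invisibly.
#' @export
write_predictions <- function(paths, path) {
  join <- function(l) vapply(l, function(v) paste(signif(v, 6), collapse = ";"), "")
  flat <- tibble::tibble(
    sequence_id = paths$id,
    predicted_path = vapply(paths$path, paste, "", collapse = "/"),
    stop_level = paths$stop_level,
    confidence = join(paths$confidences),
    alpha_cnn = join(paths$alpha_cnn),
    alpha_rnn = join(paths$alpha_rnn),
    threshold = paths$threshold)
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(flat)
}

#' Plot a threshold sweep
#'
#' @param object A `te_predictions` tibble from [threshold_sweep()].
#' @param true_paths Optional named list (id -> true root-first label path);
#'   when supplied, hierarchical precision/recall/F are drawn per threshold,
#'   otherwise the mean predicted depth.
#' @param tax Taxonomy (required with `true_paths`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.te_predictions <- function(object, true_paths = NULL, tax = NULL, ...) {
  if (!is.null(true_paths)) {
    stopifnot(!is.null(tax))
    df <- purrr::map_dfr(unique(object$threshold), function(th) {
      sub <- object[object$threshold == th, ]
      hm <- hier_metrics(stats::setNames(sub$path, sub$id),
                         true_paths[sub$id], tax)
      tibble::tibble(threshold = th, hP = hm$hP, hR = hm$hR, hF = hm$hF)
    })
    df <- tidyr::pivot_longer(df, c("hP", "hR", "hF"),
                              names_to = "metric", values_to = "value")
    ggplot2::ggplot(df, ggplot2::aes(.data$threshold, .data$value,
                                     colour = .data$metric)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "stopping threshold", y = "hierarchical metric") +
      ggplot2::theme_minimal()
  } else {
    df <- object |>
      dplyr::group_by(.data$threshold) |>
      dplyr::summarise(mean_depth = mean(.data$stop_level), .groups = "drop")
    ggplot2::ggplot(df, ggplot2::aes(.data$threshold, .data$mean_depth)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "stopping threshold", y = "mean predicted depth") +
      ggplot2::theme_minimal()
  }
}

#' Plot an attention-dominance summary
#'
#' @param object A `te_attention_summary` from [summarize_attention()].
#' @param ... Unused.
#' @return A stacked-bar ggplot of branch dominance per group.
#' @export
autoplot.te_attention_summary <- function(object, ...) {
  df <- tidyr::pivot_longer(object, c("cnn_dominant", "rnn_dominant", "equal"),
                            names_to = "dominance", values_to = "fraction")
  ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$fraction,
                                   fill = .data$dominance)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of sequences") +
    ggplot2::theme_minimal()
}
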