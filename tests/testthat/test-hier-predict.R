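# featurization is irrelevant for mocked classifiers, but predict_topdown
# takes the same records shape as the real pipeline
mock_records <- function(ids) {
  tibble::tibble(id = ids,
                 kmer = replicate(length(ids), numeric(16), simplify = FALSE),
                 onehot = replicate(length(ids), matrix(0L, 4, 4),
                                    simplify = FALSE))
}

test_that("traversal stops where the best probability falls below threshold", {
  tax <- default_taxonomy()
  clfs <- list(
    TE = mock_node_classifier("TE", c(ClassI = 0.95, ClassII = 0.05)),
    ClassI = mock_node_classifier("ClassI", c(LTR = 0.90, nonLTR = 0.10)),
    LTR = mock_node_classifier("LTR", c(Copia = 0.57, Gypsy = 0.23,
                                        `Bel-Pao` = 0.10, ERV = 0.10)))
  out <- predict_topdown(mock_records("te1"), clfs, tax, threshold = 0.60)
  expect_identical(out$path[[1]], c("TE", "ClassI", "LTR"))
  expect_identical(out$label, "LTR")
  expect_false(out$stopped_at_leaf)
  expect_identical(out$status, "ok")
  expect_length(out$confidences[[1]], 2)          # one entry per descent
  expect_true(all(out$confidences[[1]] >= 0.60))  # only accepted descents
})

test_that("a confident chain reaches the leaf", {
  tax <- default_taxonomy()
  clfs <- list(
    TE = mock_node_classifier("TE", c(ClassI = 0.20, ClassII = 0.80)),
    ClassII = mock_node_classifier("ClassII", c(TIR = 0.85, Helitron = 0.10,
                                                Maverick = 0.05)),
    TIR = mock_node_classifier("TIR", c(hAT = 0.70, TcMar = 0.10, MULE = 0.05,
                                        PIF = 0.05, CACTA = 0.05,
                                        Merlin = 0.025, P = 0.025)))
  out <- predict_topdown(mock_records("te2"), clfs, tax, threshold = 0.60)
  expect_identical(out$path[[1]], c("TE", "ClassII", "TIR", "hAT"))
  expect_true(out$stopped_at_leaf)
})

test_that("an unreachable threshold yields the bare root", {
  tax <- default_taxonomy()
  clfs <- list(TE = mock_node_classifier("TE", c(ClassI = 0.9, ClassII = 0.1)))
  out <- predict_topdown(mock_records("q"), clfs, tax, threshold = 0.999)
  expect_identical(out$path[[1]], "TE")
  expect_identical(out$stop_level, 0L)
})

test_that("a missing classifier halts the traversal with a flag", {
  tax <- default_taxonomy()
  clfs <- list(TE = mock_node_classifier("TE", c(ClassI = 0.9, ClassII = 0.1)))
  out <- predict_topdown(mock_records("q"), clfs, tax, threshold = 0.60)
  expect_identical(out$label, "ClassI")
  expect_identical(out$status, "model_missing")
})

test_that("exact ties descend into the lexicographically first child", {
  tax <- load_taxonomy(list(r = c("b", "a")))
  clfs <- list(r = mock_node_classifier("r", c(b = 0.5, a = 0.5)))
  out <- predict_topdown(mock_records("q"), clfs, tax, threshold = 0.5)
  expect_identical(out$label, "a")
})

test_that("traversal matches the brute-force rule oracle on random tables", {
  grid <- seq(0.50, 0.95, by = 0.05)
  for (case in 1:12) {
    tax <- random_taxonomy(sample(6:25, 1), 100 + case)
    ids <- paste0("q", 1:6)
    tab <- random_prob_table(tax, ids, 200 + case)
    clfs <- lapply(names(tab), function(node) {
      mock_node_classifier(node, tab[[node]])
    })
    names(clfs) <- names(tab)
    swept <- threshold_sweep(mock_records(ids), clfs, tax, grid)
    expect_identical(nrow(swept), length(grid) * length(ids))
    for (th in grid) {
      sub <- swept[swept$threshold == th, ]
      for (j in seq_along(ids)) {
        expect_identical(
          sub$path[[j]],
          oracle_topdown(tax, function(node, id) tab[[node]][id, ],
                         ids[j], th))
      }
    }
    # monotonicity: higher threshold never deepens a path, and each higher
    # path is a prefix of the lower one
    for (id in ids) {
      dd <- swept[swept$id == id, ]
      depths <- dd$stop_level[order(dd$threshold)]
      expect_true(all(diff(depths) <= 0))
      paths <- dd$path[order(dd$threshold)]
      for (j in seq_along(paths)[-1]) {
        expect_identical(paths[[j]],
                         paths[[j - 1]][seq_along(paths[[j]])])
      }
    }
  }
})

test_that("replaying recorded probabilities reproduces every path", {
  tax <- random_taxonomy(15, 77)
  ids <- paste0("s", 1:8)
  tab <- random_prob_table(tax, ids, 78)
  clfs <- lapply(names(tab), function(n) mock_node_classifier(n, tab[[n]]))
  names(clfs) <- names(tab)
  out <- predict_topdown(mock_records(ids), clfs, tax, threshold = 0.55)
  for (j in seq_along(ids)) {
    expect_identical(out$path[[j]],
                     oracle_topdown(tax, function(node, id) tab[[node]][id, ],
                                    ids[j], 0.55))
    # every path is a valid root-first chain of taxonomy edges
    p <- out$path[[j]]
    expect_identical(p[1], tax$root)
    if (length(p) > 1) {
      for (e in 2:length(p)) {
        expect_identical(unname(tax$parent[p[e]]), p[e - 1])
      }
    }
  }
})

test_that("empty threshold grids are refused", {
  tax <- default_taxonomy()
  expect_error(threshold_sweep(mock_records("q"), list(), tax, numeric()),
               "empty")
})

test_that("attention summaries partition sequences by dominant branch", {
  paths <- tibble::tibble(
    id = c("a", "b", "c"),
    label = c("x", "x", "y"),
    alpha_cnn = list(0.5, c(0.9, 0.7), 0.2),
    alpha_rnn = list(0.5, c(0.1, 0.3), 0.8))
  s <- summarize_attention(paths)
  expect_equal(s$cnn_dominant + s$rnn_dominant + s$equal, 1, tolerance = 1e-9)
  expect_equal(s$cnn_dominant, 1 / 3)
  expect_equal(s$rnn_dominant, 1 / 3)
  expect_equal(s$equal, 1 / 3)
  by_label <- summarize_attention(paths, "label")
  expect_equal(sort(by_label$group), c("x", "y"))
  expect_equal(by_label$cnn_dominant[by_label$group == "x"], 0.5)
})

test_that("all-equal traces give equal fraction one", {
  paths <- tibble::tibble(id = "a", alpha_cnn = list(c(0.5, 0.5)),
                          alpha_rnn = list(c(0.5, 0.5)))
  expect_equal(summarize_attention(paths)$equal, 1)
})

test_that("groups without attention traces are omitted with a warning", {
  paths <- tibble::tibble(id = c("a", "b"), label = c("x", "y"),
                          alpha_cnn = list(0.7, NA_real_),
                          alpha_rnn = list(0.3, NA_real_))
  expect_warning(s <- summarize_attention(paths, "label"), "omitted")
  expect_identical(s$group, "x")
})

test_that("prediction TSV export writes one row per query in input order", {
  tax <- default_taxonomy()
  clfs <- list(TE = mock_node_classifier("TE", c(ClassI = 0.9, ClassII = 0.1)))
  out <- predict_topdown(mock_records(c("z2", "a1")), clfs, tax, 0.95)
  tmp <- tempfile(fileext = ".tsv")
  write_predictions(out, tmp)
  got <- utils::read.delim(tmp)
  expect_identical(got$sequence_id, c("z2", "a1"))
  expect_identical(got$predicted_path, c("TE", "TE"))
})
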