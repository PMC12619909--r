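tiny_model <- function(seed = 3, n_out = 3, dropout = 0) {
  build_node_classifier("P", paste0("c", seq_len(n_out)), k = 2, L = 5,
                        seed = seed, conv_channels = c(2, 3, 2),
                        gru_units = c(3, 2), dense_units = 4,
                        dropout = dropout)
}

tiny_batch <- function(B = 4, seed = 1) {
  set.seed(seed)
  Xg <- matrix(stats::runif(B * 16), B, 16)
  Xl <- array(0, c(B, 4, 10))
  for (b in seq_len(B)) for (t in 1:10) Xl[b, sample(4, 1), t] <- 1
  list(Xg = Xg, Xl = Xl)
}

test_that("construction contract: output size, determinism, refusals", {
  m <- build_node_classifier("TIR",
                             c("hAT", "TcMar", "MULE", "PIF", "CACTA",
                               "Merlin", "P"),
                             k = 3, L = 20, seed = 1,
                             conv_channels = c(4, 4, 4), gru_units = c(4, 4),
                             dense_units = 8)
  expect_identical(ncol(m$params$out_W), 7L)
  m2 <- build_node_classifier("TIR",
                              c("hAT", "TcMar", "MULE", "PIF", "CACTA",
                                "Merlin", "P"),
                              k = 3, L = 20, seed = 1,
                              conv_channels = c(4, 4, 4), gru_units = c(4, 4),
                              dense_units = 8)
  expect_identical(m$params, m2$params)
  expect_error(build_node_classifier("X", "only_one"), "at least 2")
})

test_that("the dense-layer parameter count follows the shape arithmetic", {
  m <- build_node_classifier("n", c("a", "b"), k = 4, L = 10, seed = 1,
                             conv_channels = c(4, 8, 16), gru_units = c(3, 2),
                             dense_units = 12)
  td <- tidy(m)
  flat_len <- (4^4 / 8) * 16  # three halvings of 4^k, last block channels
  expect_identical(td$n_parameters[td$term == "dense_g_W"],
                   as.integer(flat_len * 12))
  expect_identical(td$n_parameters[td$term == "dense_g_b"], 12L)
  expect_identical(glance(m)$n_parameters, sum(td$n_parameters))
})

test_that("analytic gradients match finite differences everywhere", {
  m <- tiny_model()
  b <- tiny_batch()
  Y <- diag(3)[sample(1:3, 4, replace = TRUE), ]
  fwd <- hierTE:::nn_forward(m, b$Xg, b$Xl, train = FALSE)
  expect_equal(rowSums(fwd$probs), rep(1, 4), tolerance = 1e-9)
  g <- hierTE:::nn_backward(m, fwd, b$Xg, b$Xl, Y)
  loss_fn <- function(model) {
    f <- hierTE:::nn_forward(model, b$Xg, b$Xl, train = FALSE)
    hierTE:::ce_loss(f$probs, Y)
  }
  eps <- 1e-6
  set.seed(99)
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    for (i in sample(length(p), min(4, length(p)))) {
      mp <- m; mp$params[[nm]][i] <- p[i] + eps
      mm <- m; mm$params[[nm]][i] <- p[i] - eps
      num <- (loss_fn(mp) - loss_fn(mm)) / (2 * eps)
      expect_equal(as.numeric(g[[nm]])[i], num, tolerance = 1e-4,
                   label = paste("grad", nm, i))
    }
  }
})

test_that("attention fusion is a softmax-weighted convex combination", {
  # symmetry: identical inputs share the weight equally
  h <- stats::rnorm(8)
  out <- attention_fuse(h, h, stats::rnorm(8))
  expect_equal(unname(out$weights), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(out$context, h, tolerance = 1e-12)
  # weights always sum to one and context stays inside the segment
  set.seed(13)
  for (i in 1:20) {
    a <- stats::rnorm(16); b <- stats::rnorm(16); w <- stats::rnorm(16)
    out <- attention_fuse(a, b, w)
    expect_equal(sum(out$weights), 1, tolerance = 1e-6)
    expect_true(all(out$weights > 0 & out$weights < 1))
    lo <- pmin(a, b); hi <- pmax(a, b)
    expect_true(all(out$context >= lo - 1e-12 & out$context <= hi + 1e-12))
  }
  expect_error(attention_fuse(c(1, NaN), c(1, 2), c(1, 1)), "non-finite")
})

test_that("attention fusion matches hand arithmetic on a 2-d toy", {
  h_cnn <- c(1, -1); h_rnn <- c(0.5, 2); w <- c(0.3, 0.7)
  e_c <- tanh(0.3 * 1 + 0.7 * -1)   # tanh(-0.4)
  e_r <- tanh(0.3 * 0.5 + 0.7 * 2)  # tanh(1.55)
  a_c <- exp(e_c) / (exp(e_c) + exp(e_r))
  out <- attention_fuse(h_cnn, h_rnn, w)
  expect_equal(unname(out$weights[1]), a_c, tolerance = 1e-9)
  expect_equal(out$context, a_c * h_cnn + (1 - a_c) * h_rnn, tolerance = 1e-9)
})

test_that("predict_proba returns normalized rows and honours child order", {
  m <- tiny_model()
  recs <- tibble::tibble(
    id = paste0("q", 1:3),
    kmer = replicate(3, {v <- stats::runif(16); v / sum(v)}, simplify = FALSE),
    onehot = replicate(3, one_hot(random_seq(10)), simplify = FALSE))
  pp <- predict_proba(m, recs)
  pm <- as.matrix(pp[m$child_labels])
  expect_equal(rowSums(pm), rep(1, 3), tolerance = 1e-6)
  expect_true(all(pm >= 0))
  # zeroed output layer -> exactly uniform probabilities
  m0 <- m
  m0$params$out_W[] <- 0; m0$params$out_b[] <- 0
  pm0 <- as.matrix(predict_proba(m0, recs)[m0$child_labels])
  expect_equal(unname(pm0), matrix(1 / 3, 3, 3), tolerance = 1e-12)
  # permuting child labels together with the output head permutes columns
  perm <- c(3, 1, 2)
  mp <- m
  mp$child_labels <- m$child_labels[perm]
  mp$params$out_W <- m$params$out_W[, perm]
  mp$params$out_b <- m$params$out_b[perm]
  ppm <- predict_proba(mp, recs)
  expect_equal(as.matrix(ppm[m$child_labels]), pm, tolerance = 1e-12)
  # dimension mismatches are named
  bad <- recs
  bad$kmer <- lapply(bad$kmer, function(v) v[1:8])
  expect_error(predict_proba(m, bad), "dimension mismatch")
})

test_that("training refuses degenerate label sets and epochs = 0 is a no-op", {
  m <- tiny_model(n_out = 2)
  recs <- tibble::tibble(
    id = paste0("q", 1:6),
    class = rep("c1", 6),
    kmer = replicate(6, {v <- stats::runif(16); v / sum(v)}, simplify = FALSE),
    onehot = replicate(6, one_hot(random_seq(10)), simplify = FALSE))
  expect_error(train_node_classifier(m, recs, epochs = 1),
               "absent from training data: c2")
  recs$class <- rep(c("c1", "c2"), 3)
  m0 <- train_node_classifier(m, recs, epochs = 0)
  expect_identical(m0$params, m$params)
  expect_identical(nrow(m0$log), 0L)
})

test_that("a planted-motif toy is learned to perfect training accuracy", {
  # two classes separated by a planted 7-mer at a fixed interior position
  set.seed(4)
  mk <- function(with_motif) {
    s <- random_seq(60)
    if (with_motif) substr(s, 20, 26) <- "ACGTACG"
    s
  }
  seqs <- c(replicate(10, mk(TRUE)), replicate(10, mk(FALSE)))
  recs <- tibble::tibble(id = paste0("q", 1:20),
                         class = rep(c("pos", "neg"), each = 10),
                         seq = seqs)
  recs <- featurize(recs, k = 3, L = 30)
  m <- build_node_classifier("n", c("neg", "pos"), k = 3, L = 30, seed = 2,
                             conv_channels = c(4, 8, 8), gru_units = c(8, 4),
                             dense_units = 16, dropout = 0.2, lr = 3e-3)
  m <- train_node_classifier(m, recs, epochs = 30, batch_size = 8,
                             validation_split = 0, seed = 2)
  pp <- predict_proba(m, recs)
  pred <- m$child_labels[max.col(as.matrix(pp[m$child_labels]),
                                 ties.method = "first")]
  expect_identical(pred, recs$class)
  # training reduced the loss from its initial value
  m_init <- build_node_classifier("n", c("neg", "pos"), k = 3, L = 30,
                                  seed = 2, conv_channels = c(4, 8, 8),
                                  gru_units = c(8, 4), dense_units = 16,
                                  dropout = 0.2)
  tens <- hierTE:::records_to_tensors(recs)
  Y <- diag(2)[as.integer(factor(recs$class, levels = c("neg", "pos"))), ]
  f0 <- hierTE:::nn_forward(m_init, tens$Xg, tens$Xl, train = FALSE)
  expect_lt(utils::tail(m$log$train_loss, 1), hierTE:::ce_loss(f0$probs, Y))
  # same seed, same data -> identical trajectory
  m2 <- build_node_classifier("n", c("neg", "pos"), k = 3, L = 30, seed = 2,
                              conv_channels = c(4, 8, 8), gru_units = c(8, 4),
                              dense_units = 16, dropout = 0.2, lr = 3e-3)
  m2 <- train_node_classifier(m2, recs, epochs = 30, batch_size = 8,
                              validation_split = 0, seed = 2)
  expect_identical(m$log, m2$log)
})

test_that("cross-validation folds are a stratified deterministic partition", {
  labels <- rep(c("a", "b"), each = 50)
  f1 <- hierTE:::make_folds(labels, 5, seed = 7)
  f2 <- hierTE:::make_folds(labels, 5, seed = 7)
  expect_identical(f1, f2)
  for (fold in 1:5) {
    expect_identical(sum(labels == "a" & f1 == fold), 10L)
    expect_identical(sum(labels == "b" & f1 == fold), 10L)
  }
  expect_setequal(unique(f1), 1:5)
  expect_error(hierTE:::make_folds(c("a", "a", "b"), 2, 1), "fewer than")
})
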