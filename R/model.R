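#' Build an untrained node classifier
#'
#' Constructs the attention-fused hybrid network attached to one parent node
#' of the taxonomy. The global branch encodes the `4^k` k-mer frequency vector
#' with three convolution + max-pooling blocks (64/128/256 kernels by
#' default), flattens, and maps to a 128-unit dense layer; the local branch
#' runs the one-hot both-end matrix through two stacked GRU layers (128 and 64
#' units), flattens the full output sequence, applies dropout, and maps to a
#' 128-unit dense layer. A learned attention projection scores the two branch
#' vectors, softmax-normalizes the scores into weights `(alpha_cnn,
#' alpha_rnn)`, and the softmax output layer acts on the convex-combination
#' context vector. ReLU is used in all hidden layers and dropout 0.5 in the
#' fully connected layers. All parameters are initialized reproducibly
#' (Glorot-uniform) from `seed`.
#'
#' Single-branch ablation variants (`branches = "global"` or `"local"`) skip
#' the fusion and classify from the remaining branch's dense output.
#'
#' @param parent_label Taxonomy node this classifier sits on.
#' @param child_labels Ordered character vector of the node's children
#'   (at least 2); the output dimension.
#' @param k k-mer word size of the global input (default 7).
#' @param L per-end length of the local input in bp (default 600).
#' @param seed Integer seed for parameter initialization.
#' @param branches `c("global", "local")` (default, fused), or one of the two.
#' @param conv_channels Kernel counts of the three convolutional blocks.
#' @param kernel_width Convolution kernel width (odd; default 3, stride 1,
#'   same padding; pooling is width/stride 2).
#' @param gru_units Units of the two stacked GRU layers.
#' @param dense_units Width of each branch's dense layer (default 128).
#' @param dropout Dropout rate in the fully connected layers (default 0.5).
#' @param lr Default Adam learning rate carried by the model (default 5e-4).
#' @return A `node_classifier` object.
#' @export
build_node_classifier <- function(parent_label, child_labels, k = 7, L = 600,
                                  seed = 1,
                                  branches = c("global", "local"),
                                  conv_channels = c(64, 128, 256),
                                  kernel_width = 3,
                                  gru_units = c(128, 64),
                                  dense_units = 128,
                                  dropout = 0.5,
                                  lr = 5e-4) {
  child_labels <- as.character(child_labels)
  if (length(child_labels) < 2) {
    stop("a node classifier needs at least 2 child labels; got ",
         length(child_labels), call. = FALSE)
  }
  branches <- match.arg(branches, c("global", "local"), several.ok = TRUE)
  stopifnot(k >= 2, L >= 1, kernel_width %% 2 == 1, length(gru_units) == 2,
            length(conv_channels) == 3)
  l <- 4^k
  if (l %% 8 != 0) stop("4^k must be divisible by the three pooling layers")
  n_out <- length(child_labels)
  T_ <- 2L * L

  old <- .Random.seed_safe()
  set.seed(seed)
  on.exit(.Random.seed_restore(old), add = TRUE)

  p <- list()
  if ("global" %in% branches) {
    cin <- c(1, conv_channels[1], conv_channels[2])
    for (i in 1:3) {
      lim <- sqrt(6 / (kernel_width * cin[i] + kernel_width * conv_channels[i]))
      p[[paste0("conv", i, "_W")]] <-
        array(stats::runif(kernel_width * cin[i] * conv_channels[i], -lim, lim),
              c(kernel_width, cin[i], conv_channels[i]))
      p[[paste0("conv", i, "_b")]] <- numeric(conv_channels[i])
    }
    flat_g <- (l / 8) * conv_channels[3]
    p$dense_g_W <- glorot(flat_g, dense_units)
    p$dense_g_b <- numeric(dense_units)
  }
  if ("local" %in% branches) {
    dims <- c(4, gru_units)
    for (i in 1:2) {
      for (g in c("z", "r", "h")) {
        p[[paste0("gru", i, "_W", g)]] <- glorot(dims[i], dims[i + 1])
        p[[paste0("gru", i, "_U", g)]] <- glorot(dims[i + 1], dims[i + 1])
        p[[paste0("gru", i, "_b", g)]] <- numeric(dims[i + 1])
      }
    }
    p$dense_l_W <- glorot(T_ * gru_units[2], dense_units)
    p$dense_l_b <- numeric(dense_units)
  }
  if (length(branches) == 2) {
    p$att_w <- as.numeric(glorot(dense_units, 1))
  }
  p$out_W <- glorot(dense_units, n_out)
  p$out_b <- numeric(n_out)

  structure(
    list(parent_label = parent_label, child_labels = child_labels,
         k = k, L = L, branches = branches,
         conv_channels = conv_channels, kernel_width = kernel_width,
         gru_units = gru_units, dense_units = dense_units,
         dropout = dropout, lr = lr, seed = seed,
         params = p, trained = FALSE, log = empty_training_log()),
    class = "node_classifier")
}

empty_training_log <- function() {
  tibble::tibble(epoch = integer(), train_loss = numeric(),
                 val_loss = numeric(), val_accuracy = numeric())
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.node_classifier <- function(x, ...) {
  cat("<node_classifier>", x$parent_label, "->",
      paste(x$child_labels, collapse = ", "), "\n")
  cat("  branches:", paste(x$branches, collapse = "+"),
      "| k =", x$k, "| L =", x$L,
      "|", format(sum(vapply(x$params, length, 0L)), big.mark = ","),
      "parameters |", if (x$trained) "trained" else "untrained", "\n")
  invisible(x)
}

# ---- forward / backward ----------------------------------------------------

nn_forward <- function(model, Xg, Xl, train = FALSE) {
  p <- model$params
  cache <- list()
  B <- if ("global" %in% model$branches) nrow(Xg) else dim(Xl)[1]
  h_g <- h_l <- NULL

  if ("global" %in% model$branches) {
    # frequencies are O(4^-k); rescale each profile to fold-enrichment over
    # the uniform expectation (mean ~1) so conv activations start
    # well-conditioned (also normalizes raw-count input)
    rs <- rowSums(Xg)
    rs[rs == 0] <- 1
    A <- array((Xg / rs) * 4^model$k, c(B, ncol(Xg), 1))
    for (i in 1:3) {
      Z <- conv1d_forward(A, p[[paste0("conv", i, "_W")]], p[[paste0("conv", i, "_b")]])
      mask <- Z > 0
      R <- Z * mask
      pl <- pool2_forward(R)
      cache[[paste0("blk", i)]] <- list(A = A, mask = mask, left = pl$left,
                                        len = dim(R)[2])
      A <- pl$P
    }
    flat_g <- matrix(A, B)
    zg <- dense_forward(flat_g, p$dense_g_W, p$dense_g_b)
    mg <- zg > 0
    hg_act <- zg * mg
    dmask_g <- if (train) dropout_mask(B, ncol(hg_act), model$dropout) else NULL
    h_g <- if (is.null(dmask_g)) hg_act else hg_act * dmask_g
    cache$flat_g <- flat_g; cache$mask_g <- mg; cache$dmask_g <- dmask_g
    cache$pooled_dim <- dim(A)
  }

  if ("local" %in% model$branches) {
    fw1 <- gru_layer_forward(Xl, p, "gru1")
    fw2 <- gru_layer_forward(fw1$H, p, "gru2")
    flat_l <- matrix(fw2$H, B)
    dmask_l <- if (train) dropout_mask(B, ncol(flat_l), model$dropout) else NULL
    drop_l <- if (is.null(dmask_l)) flat_l else flat_l * dmask_l
    zl <- dense_forward(drop_l, p$dense_l_W, p$dense_l_b)
    ml <- zl > 0
    h_l <- zl * ml
    cache$fw1 <- fw1; cache$fw2 <- fw2; cache$flat_l <- flat_l
    cache$dmask_l <- dmask_l; cache$drop_l <- drop_l; cache$mask_l <- ml
  }

  if (length(model$branches) == 2) {
    att <- attention_forward(h_g, h_l, p$att_w)
    ctx <- att$context
    alpha <- att$alpha
    cache$att <- att; cache$h_g <- h_g; cache$h_l <- h_l
  } else {
    ctx <- if ("global" %in% model$branches) h_g else h_l
    alpha <- matrix(NA_real_, B, 2)
  }
  logits <- dense_forward(ctx, p$out_W, p$out_b)
  probs <- softmax_rows(logits)
  colnames(probs) <- model$child_labels
  colnames(alpha) <- c("alpha_cnn", "alpha_rnn")
  cache$ctx <- ctx
  list(probs = probs, alpha = alpha, cache = cache)
}

attention_forward <- function(h_g, h_l, w) {
  u_c <- as.numeric(h_g %*% w); u_r <- as.numeric(h_l %*% w)
  e_c <- tanh(u_c); e_r <- tanh(u_r)
  m <- pmax(e_c, e_r)
  a_c <- exp(e_c - m); a_r <- exp(e_r - m)
  s <- a_c + a_r
  a_c <- a_c / s; a_r <- a_r / s
  context <- h_g * a_c + h_l * a_r
  list(context = context, alpha = cbind(a_c, a_r),
       e_c = e_c, e_r = e_r)
}

nn_backward <- function(model, fwd, Xg, Xl, Y) {
  p <- model$params
  cache <- fwd$cache
  B <- nrow(fwd$probs)
  g <- list()

  dlogits <- (fwd$probs - Y) / B
  g$out_W <- crossprod(cache$ctx, dlogits)
  g$out_b <- colSums(dlogits)
  dctx <- dlogits %*% t(p$out_W)

  if (length(model$branches) == 2) {
    att <- cache$att
    a_c <- att$alpha[, 1]; a_r <- att$alpha[, 2]
    h_g <- cache$h_g; h_l <- cache$h_l
    da_c <- rowSums(dctx * h_g); da_r <- rowSums(dctx * h_l)
    dh_g <- dctx * a_c; dh_l <- dctx * a_r
    de_c <- a_c * a_r * (da_c - da_r)
    du_c <- de_c * (1 - att$e_c^2)
    du_r <- -de_c * (1 - att$e_r^2)
    g$att_w <- as.numeric(crossprod(h_g, du_c) + crossprod(h_l, du_r))
    dh_g <- dh_g + outer(du_c, p$att_w)
    dh_l <- dh_l + outer(du_r, p$att_w)
  } else if ("global" %in% model$branches) {
    dh_g <- dctx
  } else {
    dh_l <- dctx
  }

  if ("global" %in% model$branches) {
    if (!is.null(cache$dmask_g)) dh_g <- dh_g * cache$dmask_g
    dzg <- dh_g * cache$mask_g
    g$dense_g_W <- crossprod(cache$flat_g, dzg)
    g$dense_g_b <- colSums(dzg)
    dA <- array(dzg %*% t(p$dense_g_W), cache$pooled_dim)
    for (i in 3:1) {
      blk <- cache[[paste0("blk", i)]]
      dR <- pool2_backward(dA, blk$left, blk$len)
      dZ <- dR * blk$mask
      cb <- conv1d_backward(blk$A, p[[paste0("conv", i, "_W")]], dZ)
      g[[paste0("conv", i, "_W")]] <- cb$dW
      g[[paste0("conv", i, "_b")]] <- cb$db
      dA <- cb$dA
    }
  }

  if ("local" %in% model$branches) {
    dzl <- dh_l * cache$mask_l
    g$dense_l_W <- crossprod(cache$drop_l, dzl)
    g$dense_l_b <- colSums(dzl)
    ddrop <- dzl %*% t(p$dense_l_W)
    if (!is.null(cache$dmask_l)) ddrop <- ddrop * cache$dmask_l
    dH2 <- array(ddrop, c(B, model$gru_units[2], 2L * model$L))
    b2 <- gru_layer_backward(cache$fw1$H, cache$fw2, p, "gru2", dH2)
    b1 <- gru_layer_backward(Xl, cache$fw1, p, "gru1", b2$dX)
    g <- c(g, b2$grads, b1$grads)
  }
  g
}

ce_loss <- function(probs, Y) {
  -mean(log(pmax(rowSums(probs * Y), 1e-12)))
}

# ---- attention as a standalone operation -----------------------------------

#' Attention fusion of the two branch feature vectors
#'
#' Scores each branch vector `h_s` with a shared learned projection,
#' `e_s = tanh(w . h_s)`, softmax-normalizes the two scalar scores into
#' weights `alpha_s`, and returns the context vector
#' `c = alpha_cnn * h_cnn + alpha_rnn * h_rnn` — a coordinatewise convex
#' combination of the branch features. Identical branch inputs therefore give
#' `alpha = (0.5, 0.5)` and a context equal to the input.
#'
#' @param h_cnn,h_rnn Numeric vectors of equal length (or matrices with one
#'   row per sample).
#' @param w Numeric projection vector of the same length.
#' @return List with `context` (same shape as the inputs) and `weights`
#'   (`alpha_cnn`, `alpha_rnn`; one row per sample for matrix input).
#' @export
#' @examples
#' h <- rnorm(8)
#' attention_fuse(h, h, rnorm(8))$weights  # 0.5 / 0.5
attention_fuse <- function(h_cnn, h_rnn, w) {
  vec_in <- is.null(dim(h_cnn))
  if (vec_in) { h_cnn <- rbind(h_cnn); h_rnn <- rbind(h_rnn) }
  if (!all(is.finite(h_cnn)) || !all(is.finite(h_rnn))) {
    stop("non-finite branch features passed to attention fusion", call. = FALSE)
  }
  stopifnot(ncol(h_cnn) == ncol(h_rnn), length(w) == ncol(h_cnn))
  att <- attention_forward(h_cnn, h_rnn, as.numeric(w))
  weights <- att$alpha
  colnames(weights) <- c("alpha_cnn", "alpha_rnn")
  if (vec_in) {
    list(context = as.numeric(att$context), weights = drop(weights))
  } else {
    list(context = att$context, weights = weights)
  }
}

# ---- tensors from featurized records ---------------------------------------

records_to_tensors <- function(records) {
  stopifnot(all(c("kmer", "onehot") %in% names(records)))
  list(Xg = do.call(rbind, records$kmer),
       Xl = onehot_to_cube(records$onehot))
}

check_feature_dims <- function(model, records) {
  lk <- length(records$kmer[[1]])
  if ("global" %in% model$branches && lk != 4^model$k) {
    stop("feature dimension mismatch: model expects k-mer vector of length ",
         4^model$k, " (k=", model$k, "), got ", lk, call. = FALSE)
  }
  nr <- nrow(records$onehot[[1]])
  if ("local" %in% model$branches && nr != 2 * model$L) {
    stop("feature dimension mismatch: model expects one-hot matrix with ",
         2 * model$L, " rows (L=", model$L, "), got ", nr, call. = FALSE)
  }
}

# ---- training --------------------------------------------------------------

#' Train a node classifier
#'
#' Minimizes categorical cross-entropy with Adam (learning rate 5e-4 by
#' default). A stratified validation split drives early stopping on
#' validation loss; the parameters of the best epoch are restored. All
#' randomness (shuffling, dropout, validation split) is governed by `seed`.
#'
#' @param model A `node_classifier` from [build_node_classifier()].
#' @param records Featurized tibble (see [featurize()]) with a `class` column
#'   holding each record's child-of-parent label; every child label of the
#'   model must be present.
#' @param epochs Maximum training epochs (default 100). `epochs = 0` returns
#'   the model unchanged with an empty log.
#' @param batch_size Minibatch size (default 32).
#' @param lr Adam learning rate (default: the model's `lr`).
#' @param validation_split Fraction held out for early stopping (default 0.1;
#'   0 disables validation and early stopping).
#' @param patience Early-stopping patience in epochs (default 5).
#' @param seed Integer seed.
#' @param verbose Print per-epoch progress.
#' @return The trained model; `$log` holds the per-epoch training record.
#' @export
train_node_classifier <- function(model, records, epochs = 100,
                                  batch_size = 32, lr = model$lr,
                                  validation_split = 0.1, patience = 5,
                                  seed = 1, verbose = FALSE) {
  stopifnot(inherits(model, "node_classifier"), "class" %in% names(records))
  if (epochs == 0) { model$log <- empty_training_log(); return(model) }
  cls <- as.character(records$class)
  missing_cls <- setdiff(model$child_labels, cls)
  if (length(missing_cls) > 0) {
    stop("child class absent from training data: ",
         paste(missing_cls, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(cls, model$child_labels)
  if (length(bad) > 0) {
    stop("records carry labels that are not children of ", model$parent_label,
         ": ", paste(bad, collapse = ", "), call. = FALSE)
  }
  check_feature_dims(model, records)

  old <- .Random.seed_safe()
  set.seed(seed)
  on.exit(.Random.seed_restore(old), add = TRUE)

  tens <- records_to_tensors(records)
  n <- length(cls)
  y <- factor(cls, levels = model$child_labels)
  Y <- diag(length(model$child_labels))[as.integer(y), , drop = FALSE]

  if (validation_split > 0) {
    val_idx <- unlist(lapply(split(seq_len(n), y), function(ix) {
      nv <- max(1, round(length(ix) * validation_split))
      sample(ix, nv)
    }), use.names = FALSE)
  } else val_idx <- integer()
  tr_idx <- setdiff(seq_len(n), val_idx)

  state <- adam_init(model$params)
  log <- empty_training_log()
  best_loss <- Inf; best_params <- model$params; wait <- 0L

  for (ep in seq_len(epochs)) {
    ord <- sample(tr_idx)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1, length(ord), by = batch_size)) {
      ix <- ord[start:min(start + batch_size - 1, length(ord))]
      Xg <- tens$Xg[ix, , drop = FALSE]
      Xl <- tens$Xl[ix, , , drop = FALSE]
      fwd <- nn_forward(model, Xg, Xl, train = TRUE)
      ep_loss <- ep_loss + ce_loss(fwd$probs, Y[ix, , drop = FALSE])
      nb <- nb + 1L
      grads <- nn_backward(model, fwd, Xg, Xl, Y[ix, , drop = FALSE])
      upd <- adam_step(model$params, grads, state, lr)
      model$params <- upd$params; state <- upd$state
    }
    if (length(val_idx) > 0) {
      vf <- nn_forward(model,
                       tens$Xg[val_idx, , drop = FALSE],
                       tens$Xl[val_idx, , , drop = FALSE], train = FALSE)
      vl <- ce_loss(vf$probs, Y[val_idx, , drop = FALSE])
      va <- mean(max.col(vf$probs, ties.method = "first") == as.integer(y)[val_idx])
    } else { vl <- NA_real_; va <- NA_real_ }
    log <- dplyr::bind_rows(log, tibble::tibble(
      epoch = ep, train_loss = ep_loss / nb, val_loss = vl, val_accuracy = va))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val_loss %s", ep, ep_loss / nb,
                      ifelse(is.na(vl), "-", sprintf("%.4f", vl))))
    }
    if (!is.na(vl)) {
      if (vl < best_loss - 1e-6) {
        best_loss <- vl; best_params <- model$params; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
  }
  if (length(val_idx) > 0) model$params <- best_params
  model$trained <- TRUE
  model$log <- log
  model
}

# ---- prediction ------------------------------------------------------------

#' Class probabilities (and attention weights) for featurized records
#'
#' Runs the node classifier on precomputed feature pairs. Probabilities over
#' the model's child labels sum to 1 per record; the attention weights say
#' how much the prediction leaned on the global (CNN) versus local (RNN)
#' branch (NA for single-branch models).
#'
#' @param model A `node_classifier`.
#' @param records Featurized tibble (see [featurize()]); feature dimensions
#'   must match the model's `k` and `L`.
#' @param batch Chunk size for prediction (memory control; default 128).
#' @return Tibble with `id`, one probability column per child label,
#'   `alpha_cnn`, `alpha_rnn`.
#' @export
predict_proba <- function(model, records, batch = 128) {
  stopifnot(inherits(model, "node_classifier"))
  check_feature_dims(model, records)
  tens <- records_to_tensors(records)
  n <- nrow(records)
  probs <- matrix(NA_real_, n, length(model$child_labels))
  alpha <- matrix(NA_real_, n, 2)
  for (start in seq(1, n, by = batch)) {
    ix <- start:min(start + batch - 1, n)
    fwd <- nn_forward(model, tens$Xg[ix, , drop = FALSE],
                      tens$Xl[ix, , , drop = FALSE], train = FALSE)
    probs[ix, ] <- fwd$probs
    alpha[ix, ] <- fwd$alpha
  }
  colnames(probs) <- model$child_labels
  out <- tibble::as_tibble(probs)
  out <- dplyr::bind_cols(tibble::tibble(id = records$id), out)
  out$alpha_cnn <- alpha[, 1]
  out$alpha_rnn <- alpha[, 2]
  out
}

# Internal dispatch used by the hierarchical traversal: returns
# list(probs = matrix[n, children], alpha = matrix[n, 2]).
node_predict <- function(clf, records) UseMethod("node_predict")

#' @export
node_predict.node_classifier <- function(clf, records) {
  pp <- predict_proba(clf, records)
  list(probs = as.matrix(pp[clf$child_labels]),
       alpha = cbind(pp$alpha_cnn, pp$alpha_rnn))
}

#' A mock node classifier emitting fixed probabilities
#'
#' Testing and pipeline-mocking utility: stands in for a trained
#' `node_classifier` in [predict_topdown()] and returns prescribed
#' probabilities instead of running the network.
#'
#' @param parent_label Taxonomy node.
#' @param probs Either a named probability vector over the node's children
#'   (used for every query), a matrix with one named row per query id, or a
#'   `function(id)` returning a named vector.
#' @param alpha Attention-weight pair reported per query (default 0.5/0.5).
#' @return A `mock_node_classifier`.
#' @export
mock_node_classifier <- function(parent_label, probs, alpha = c(0.5, 0.5)) {
  structure(list(parent_label = parent_label, probs = probs, alpha = alpha),
            class = "mock_node_classifier")
}

#' @export
node_predict.mock_node_classifier <- function(clf, records) {
  ids <- records$id
  one <- function(id) {
    p <- if (is.function(clf$probs)) clf$probs(id)
    else if (is.matrix(clf$probs)) clf$probs[id, ]
    else clf$probs
    p
  }
  pm <- do.call(rbind, lapply(ids, one))
  rownames(pm) <- NULL
  list(probs = pm, alpha = matrix(rep(clf$alpha, each = length(ids)),
                                  length(ids), 2))
}

# ---- cross-validation ------------------------------------------------------

make_folds <- function(labels, folds, seed) {
  old <- .Random.seed_safe()
  set.seed(seed)
  on.exit(.Random.seed_restore(old), add = TRUE)
  assign <- integer(length(labels))
  for (cl in unique(labels)) {
    ix <- which(labels == cl)
    if (length(ix) < folds) {
      stop("class '", cl, "' has ", length(ix), " records, fewer than ",
           folds, " folds", call. = FALSE)
    }
    assign[sample(ix)] <- rep_len(seq_len(folds), length(ix))
  }
  assign
}

#' Stratified k-fold cross-validation of a node classifier
#'
#' Assigns records to folds stratified by class, trains a fresh classifier on
#' each training portion, and evaluates flat metrics on the held-out fold.
#'
#' @param records Featurized tibble with a `class` column.
#' @param folds Number of folds (default 5).
#' @param seed Seed for fold assignment and training.
#' @param build_args List of arguments to [build_node_classifier()]
#'   (`parent_label`, `child_labels`, `k`, `L`, architecture overrides).
#' @param train_args List of arguments to [train_node_classifier()].
#' @return Tibble with one row per fold (`fold`, `n_val`, `accuracy`,
#'   `macro_f1`, `mcc`); the fold assignment is attached as attribute
#'   `"folds"`, and `summary` (mean and sd rows) as attribute `"summary"`.
#' @export
crossvalidate <- function(records, folds = 5, seed = 1,
                          build_args = list(), train_args = list()) {
  stopifnot("class" %in% names(records))
  cls <- as.character(records$class)
  fold_of <- make_folds(cls, folds, seed)
  child_labels <- build_args$child_labels %||% sort(unique(cls))
  res <- purrr::map_dfr(seq_len(folds), function(f) {
    tr <- records[fold_of != f, ]
    va <- records[fold_of == f, ]
    ba <- utils::modifyList(
      list(parent_label = build_args$parent_label %||% "node",
           child_labels = child_labels, seed = seed + f),
      build_args[setdiff(names(build_args), c("parent_label", "child_labels"))])
    mdl <- do.call(build_node_classifier, ba)
    mdl <- do.call(train_node_classifier,
                   c(list(model = mdl, records = tr, seed = seed + f),
                     train_args))
    pp <- predict_proba(mdl, va)
    pred <- child_labels[max.col(as.matrix(pp[child_labels]), ties.method = "first")]
    cm <- flat_metrics(va$class, pred, child_labels)
    gl <- glance(cm)
    tibble::tibble(fold = f, n_val = nrow(va), accuracy = gl$accuracy,
                   macro_f1 = gl$macro_f1, mcc = gl$mcc)
  })
  summ <- tibble::tibble(
    stat = c("mean", "sd"),
    accuracy = c(mean(res$accuracy), stats::sd(res$accuracy)),
    macro_f1 = c(mean(res$macro_f1), stats::sd(res$macro_f1)),
    mcc = c(mean(res$mcc), stats::sd(res$mcc)))
  attr(res, "folds") <- fold_of
  attr(res, "summary") <- summ
  res
}

# ---- broom-style methods ---------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-layer parameter summary of a node classifier
#'
#' @param x A `node_classifier`.
#' @param ... Unused.
#' @return Tibble with `term` (parameter name), `dims`, `n_parameters`.
#' @export
tidy.node_classifier <- function(x, ...) {
  tibble::tibble(
    term = names(x$params),
    dims = unname(vapply(x$params, function(p) {
      paste(dim(p) %||% length(p), collapse = "x")
    }, "")),
    n_parameters = unname(vapply(x$params, length, 0L)))
}

#' One-row summary of a node classifier
#'
#' @param x A `node_classifier`.
#' @param ... Unused.
#' @return Tibble with parent label, output size, feature sizes, parameter
#'   count, training status and (when trained) final losses.
#' @export
glance.node_classifier <- function(x, ...) {
  tibble::tibble(
    parent_label = x$parent_label,
    n_children = length(x$child_labels),
    branches = paste(x$branches, collapse = "+"),
    k = x$k, L = x$L,
    n_parameters = sum(vapply(x$params, length, 0L)),
    trained = x$trained,
    epochs_trained = nrow(x$log),
    final_train_loss = if (nrow(x$log)) utils::tail(x$log$train_loss, 1) else NA_real_,
    best_val_loss = if (nrow(x$log) && !all(is.na(x$log$val_loss)))
      min(x$log$val_loss, na.rm = TRUE) else NA_real_)
}

#' Training-curve plot for a node classifier
#'
#' @param object A trained `node_classifier`.
#' @param ... Unused.
#' @return A ggplot of training/validation loss by epoch.
#' @export
autoplot.node_classifier <- function(object, ...) {
  stopifnot(nrow(object$log) > 0)
  df <- tidyr::pivot_longer(object$log, c("train_loss", "val_loss"),
                            names_to = "series", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = paste("Training:", object$parent_label),
                  x = "epoch", y = "categorical cross-entropy") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
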