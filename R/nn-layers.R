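# Internal layer primitives for the node classifiers. Every forward op
# returns what its backward pass needs; gradients are hand-derived and
# verified by finite differences in the test suite.
#
# Activation layouts:
#   global branch: (batch, length, channels) arrays; matrix(A, B * len) gives
#     the (B*len) x C view used for the channel matmuls
#   local branch: (batch, dim, time) cubes matching the C++ GRU kernels

conv_offsets <- function(kw) seq_len(kw) - (kw + 1L) %/% 2L

# 1-D convolution, stride 1, zero ("same") padding, expressed as a sum of
# offset-shifted channel matmuls: out[,t,] = sum_o A[,t+o,] %*% W[o,,] + b
conv1d_forward <- function(A, W, b) {
  dm <- dim(A); B <- dm[1]; len <- dm[2]; cin <- dm[3]
  kw <- dim(W)[1]; cout <- dim(W)[3]
  Zm <- matrix(rep(b, each = B * len), B * len, cout)
  for (j in seq_len(kw)) {
    o <- conv_offsets(kw)[j]
    tt <- max(1, 1 - o):min(len, len - o)
    As <- array(0, c(B, len, cin))
    As[, tt, ] <- A[, tt + o, ]
    Zm <- Zm + matrix(As, B * len, cin) %*% matrix(W[j, , ], cin, cout)
  }
  array(Zm, c(B, len, cout))
}

conv1d_backward <- function(A, W, dZ) {
  dm <- dim(A); B <- dm[1]; len <- dm[2]; cin <- dm[3]
  kw <- dim(W)[1]; cout <- dim(W)[3]
  dZm <- matrix(dZ, B * len, cout)
  dA <- array(0, dim(A))
  dW <- array(0, dim(W))
  for (j in seq_len(kw)) {
    o <- conv_offsets(kw)[j]
    tt <- max(1, 1 - o):min(len, len - o)
    As <- array(0, c(B, len, cin))
    As[, tt, ] <- A[, tt + o, ]
    dW[j, , ] <- crossprod(matrix(As, B * len, cin), dZm)
    dAs <- array(dZm %*% t(matrix(W[j, , ], cin, cout)), c(B, len, cin))
    dA[, tt + o, ] <- dA[, tt + o, , drop = FALSE] + dAs[, tt, , drop = FALSE]
  }
  list(dA = dA, dW = dW, db = colSums(dZm))
}

relu <- function(x) { x[x < 0] <- 0; x }

# max pooling, width = stride = 2 (even lengths by construction: 4^k halves
# cleanly through three blocks for every k >= 3); ties keep the left element
pool2_forward <- function(A) {
  dm <- dim(A); len <- dm[2]
  i1 <- seq(1, len, by = 2); i2 <- i1 + 1
  A1 <- A[, i1, , drop = FALSE]; A2 <- A[, i2, , drop = FALSE]
  left <- A1 >= A2
  list(P = A1 * left + A2 * !left, left = left)
}

pool2_backward <- function(dP, left, len) {
  dm <- dim(dP)
  dA <- array(0, c(dm[1], len, dm[3]))
  i1 <- seq(1, len, by = 2)
  dA[, i1, ] <- dP * left
  dA[, i1 + 1, ] <- dP * !left
  dA
}

dense_forward <- function(X, W, b) X %*% W + rep(b, each = nrow(X))

# inverted dropout: scaling at train time, identity at prediction time
dropout_mask <- function(n_row, n_col, rate) {
  if (rate <= 0) return(NULL)
  matrix((stats::runif(n_row * n_col) >= rate) / (1 - rate), n_row, n_col)
}

onehot_to_cube <- function(onehot_list) {
  B <- length(onehot_list)
  T_ <- nrow(onehot_list[[1]])
  X <- array(0, c(B, 4L, T_))
  for (b in seq_len(B)) X[b, , ] <- t(onehot_list[[b]])
  X
}

gru_layer_forward <- function(X, p, prefix) {
  .gru_forward(X,
               p[[paste0(prefix, "_Wz")]], p[[paste0(prefix, "_Uz")]], p[[paste0(prefix, "_bz")]],
               p[[paste0(prefix, "_Wr")]], p[[paste0(prefix, "_Ur")]], p[[paste0(prefix, "_br")]],
               p[[paste0(prefix, "_Wh")]], p[[paste0(prefix, "_Uh")]], p[[paste0(prefix, "_bh")]])
}

gru_layer_backward <- function(X, fw, p, prefix, dH) {
  g <- .gru_backward(X, fw$H, fw$Z, fw$R, fw$Hc, fw$UhH,
                     p[[paste0(prefix, "_Wz")]], p[[paste0(prefix, "_Uz")]],
                     p[[paste0(prefix, "_Wr")]], p[[paste0(prefix, "_Ur")]],
                     p[[paste0(prefix, "_Wh")]], p[[paste0(prefix, "_Uh")]],
                     dH)
  grads <- g[-1]
  names(grads) <- paste0(prefix, "_", sub("^d", "", names(grads)))
  list(dX = g$dX, grads = grads)
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    dim(g) <- dim(state$m[[nm]])  # C++ rowvec gradients arrive as 1 x n
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    upd <- lr * mhat / (sqrt(vhat) + eps)
    dim(upd) <- dim(params[[nm]])
    params[[nm]] <- params[[nm]] - upd
  }
  list(params = params, state = state)
}
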