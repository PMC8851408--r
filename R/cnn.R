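# A small convolutional network for grayscale activity-map classification,
# implemented directly on BLAS matrix products (im2col). Architecture:
# repeated [3x3 valid conv -> ReLU -> 2x2 max-pool] blocks, then a dense
# block with ReLU and inverted dropout, a linear output layer, softmax and
# categorical cross-entropy, trained with Adam and L2 weight decay.
#
# Activation layout: a batch of feature maps is a matrix with
# `H*W*B` rows (spatial position fastest, image index slowest) and one
# column per channel; im2col and pooling are pure row-index gathers, so
# every FLOP-heavy step is a single matrix product.

#' CNN architecture and training protocol configuration
#'
#' Defaults encode the full-scale protocol: three convolutional layers of
#' 128 3x3 kernels with ReLU and 2x2 max-pooling, a dense block of four
#' fully connected layers (three hidden layers of 128 nodes plus the
#' 5-node output), Adam at learning rate 0.001 with categorical
#' cross-entropy, 20% dropout, L2 regularization lambda = 7e-4, batch size
#' 32, 25 epochs, and 90-10 train-test then 90-10 train-validation splits.
#' That width is expensive on a single CPU; [cnn_config_desk()] is the
#' reduced configuration used throughout the package's own tests.
#'
#' @param input_side Square input image side (pixels) fed to the network.
#' @param conv_filters Kernels per convolutional layer.
#' @param dense_units Hidden fully-connected layer widths.
#' @param n_classes Output classes.
#' @param learning_rate,dropout,l2,batch_size,epochs Training protocol.
#' @param test_frac,val_frac Held-out fractions (test split first, then
#'   validation from the remaining training data).
#' @param max_downsample Cap on the block-mean downsampling factor when
#'   preparing activity maps; larger maps are center-cropped first (see
#'   [prepare_cnn_input()]).
#' @return List of class `cnn_config`.
#' @export
cnn_config <- function(input_side = 64L, conv_filters = c(128L, 128L, 128L),
                       dense_units = c(128L, 128L, 128L), n_classes = 5L,
                       learning_rate = 0.001, dropout = 0.20, l2 = 7e-4,
                       batch_size = 32L, epochs = 25L,
                       test_frac = 0.10, val_frac = 0.10,
                       max_downsample = 4L) {
  cfg <- as.list(environment())
  side <- input_side
  for (i in seq_along(conv_filters)) {
    side <- side - 2L            # 3x3 valid conv
    if (side < 2L) stop("input_side too small for the conv stack")
    side <- side %/% 2L          # 2x2 pool
  }
  cfg$final_side <- side
  structure(cfg, class = "cnn_config")
}

#' @rdname cnn_config
#' @export
cnn_config_desk <- function(...) {
  cnn_config(input_side = 48L, conv_filters = c(16L, 32L, 32L),
             dense_units = c(64L, 64L), max_downsample = 3L, ...)
}

# ---- index plumbing ------------------------------------------------------

# in-image gather indices for 3x3 valid conv: (H'W', 9)
conv_indices <- function(H, W) {
  Hp <- H - 2L; Wp <- W - 2L
  yp <- rep(seq_len(Hp), Wp)
  xp <- rep(seq_len(Wp), each = Hp)
  idx <- matrix(0L, Hp * Wp, 9L)
  k <- 0L
  for (dx in 0:2) for (dy in 0:2) {
    k <- k + 1L
    idx[, k] <- (xp + dx - 1L) * H + (yp + dy)   # linear index (col-1)*H + row
  }
  idx
}

# in-image gather indices for 2x2/stride-2 max pool: (H2W2, 4)
pool_indices <- function(H, W) {
  H2 <- H %/% 2L; W2 <- W %/% 2L
  y2 <- rep(seq_len(H2), W2)
  x2 <- rep(seq_len(W2), each = H2)
  idx <- matrix(0L, H2 * W2, 4L)
  j <- 0L
  for (dx in 0:1) for (dy in 0:1) {
    j <- j + 1L
    idx[, j] <- (2L * x2 - 2L + dx) * H + (2L * y2 - 1L + dy)
  }
  idx
}

# expand in-image indices to a batch: rows of the (HW*B, C) activation
batch_rows <- function(idx_col, HW, B) {
  as.vector(outer(idx_col, (seq_len(B) - 1L) * HW, "+"))
}

# geometry + gather tables for one batch size, memoized per model
cnn_plan <- function(config, B) {
  H <- config$input_side
  plan <- list()
  for (l in seq_along(config$conv_filters)) {
    ci <- conv_indices(H, H)
    Hp <- H - 2L
    pi_ <- pool_indices(Hp, Hp)
    plan[[l]] <- list(
      H = H, Hp = Hp, H2 = Hp %/% 2L,
      conv_rows = lapply(seq_len(9L), function(k)
        batch_rows(ci[, k], H * H, B)),
      pool_rows = lapply(seq_len(4L), function(j)
        batch_rows(pi_[, j], Hp * Hp, B)))
    H <- Hp %/% 2L
  }
  plan
}

# ---- forward / backward --------------------------------------------------

cnn_init <- function(config, rng) {
  he <- function(nin, nout) matrix(rng$rnorm(nin * nout, 0, sqrt(2 / nin)),
                                   nin, nout)
  params <- list(conv_W = list(), conv_b = list(),
                 dense_W = list(), dense_b = list())
  c_in <- 1L
  for (l in seq_along(config$conv_filters)) {
    c_out <- config$conv_filters[l]
    params$conv_W[[l]] <- he(9L * c_in, c_out)
    params$conv_b[[l]] <- numeric(c_out)
    c_in <- c_out
  }
  d_in <- config$final_side^2 * c_in
  widths <- c(config$dense_units, config$n_classes)
  for (l in seq_along(widths)) {
    params$dense_W[[l]] <- he(d_in, widths[l])
    params$dense_b[[l]] <- numeric(widths[l])
    d_in <- widths[l]
  }
  params
}

# X: (B, input_side^2) matrix of flattened images (column-major pixels).
cnn_forward <- function(params, config, plan, X, train = FALSE,
                        drop_masks = NULL) {
  B <- nrow(X)
  nL <- length(config$conv_filters)
  A <- matrix(as.vector(t(X)), ncol = 1L)   # (HW*B, 1), pos fastest
  cache <- list(conv = vector("list", nL))
  c_in <- 1L
  for (l in seq_len(nL)) {
    pl <- plan[[l]]
    Col <- do.call(cbind, lapply(pl$conv_rows, function(r)
      A[r, , drop = FALSE]))
    Z <- Col %*% params$conv_W[[l]]
    Z <- sweep(Z, 2L, params$conv_b[[l]], "+")
    relu_mask <- Z > 0
    Ar <- Z * relu_mask
    # max pool
    P <- lapply(pl$pool_rows, function(r) Ar[r, , drop = FALSE])
    M <- P[[1L]]; jmax <- matrix(1L, nrow(M), ncol(M))
    for (j in 2:4) {
      upd <- P[[j]] > M
      M[upd] <- P[[j]][upd]
      jmax[upd] <- j
    }
    cache$conv[[l]] <- list(Col = Col, relu_mask = relu_mask, jmax = jmax,
                            in_rows = nrow(A), c_in = c_in)
    A <- M
    c_in <- ncol(A)
  }
  # flatten (H2W2*B, C) -> (B, H2W2*C)
  HW <- plan[[nL]]$H2^2
  Fmat <- matrix(aperm(array(A, c(HW, B, c_in)), c(2L, 1L, 3L)), nrow = B)
  cache$flat_dims <- c(HW, B, c_in)
  nD <- length(params$dense_W)
  cache$dense <- vector("list", nD)
  H_ <- Fmat
  for (l in seq_len(nD)) {
    Z <- H_ %*% params$dense_W[[l]]
    Z <- sweep(Z, 2L, params$dense_b[[l]], "+")
    if (l < nD) {
      relu_mask <- Z > 0
      Zr <- Z * relu_mask
      dm <- NULL
      if (train && config$dropout > 0) {
        dm <- if (is.null(drop_masks)) NULL else drop_masks[[l]]
        Zr <- Zr * dm
      }
      cache$dense[[l]] <- list(input = H_, relu_mask = relu_mask, drop = dm)
      H_ <- Zr
    } else {
      cache$dense[[l]] <- list(input = H_)
      H_ <- Z
    }
  }
  logits <- H_
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  list(probs = probs, cache = cache)
}

cnn_backward <- function(params, config, plan, fwd, Y_onehot) {
  B <- nrow(Y_onehot)
  grads <- list(conv_W = list(), conv_b = list(),
                dense_W = list(), dense_b = list())
  dZ <- (fwd$probs - Y_onehot) / B
  nD <- length(params$dense_W)
  for (l in rev(seq_len(nD))) {
    cc <- fwd$cache$dense[[l]]
    grads$dense_W[[l]] <- crossprod(cc$input, dZ) +
      2 * config$l2 * params$dense_W[[l]]
    grads$dense_b[[l]] <- colSums(dZ)
    if (l > 1L) {
      dH <- dZ %*% t(params$dense_W[[l]])
      cp <- fwd$cache$dense[[l - 1L]]
      if (!is.null(cp$drop)) dH <- dH * cp$drop
      dZ <- dH * cp$relu_mask
    } else {
      dF <- dZ %*% t(params$dense_W[[1L]])
    }
  }
  # unflatten (B, HW*C) -> (HW*B, C)
  fd <- fwd$cache$flat_dims
  dA <- matrix(aperm(array(dF, c(fd[2], fd[1], fd[3])), c(2L, 1L, 3L)),
               ncol = fd[3])
  nL <- length(config$conv_filters)
  for (l in rev(seq_len(nL))) {
    pl <- plan[[l]]
    cc <- fwd$cache$conv[[l]]
    # pool backward: route each pooled gradient to its argmax position
    dAr <- matrix(0, nrow(cc$relu_mask), ncol(cc$relu_mask))
    for (j in 1:4) {
      sel <- cc$jmax == j
      contrib <- dA * sel
      r <- pl$pool_rows[[j]]
      dAr[r, ] <- dAr[r, ] + contrib
    }
    dZc <- dAr * cc$relu_mask
    grads$conv_W[[l]] <- crossprod(cc$Col, dZc) +
      2 * config$l2 * params$conv_W[[l]]
    grads$conv_b[[l]] <- colSums(dZc)
    if (l > 1L) {
      dCol <- dZc %*% t(params$conv_W[[l]])
      c_in <- cc$c_in
      dA <- matrix(0, cc$in_rows, c_in)
      for (k in 1:9) {
        r <- pl$conv_rows[[k]]
        dA[r, ] <- dA[r, ] + dCol[, ((k - 1L) * c_in + 1L):(k * c_in),
                                  drop = FALSE]
      }
    }
  }
  grads
}

cnn_loss <- function(params, config, probs, Y_onehot) {
  ce <- -mean(log(pmax(rowSums(probs * Y_onehot), 1e-12)))
  l2 <- config$l2 * (sum(vapply(params$conv_W, function(w) sum(w^2),
                                numeric(1))) +
                     sum(vapply(params$dense_W, function(w) sum(w^2),
                                numeric(1))))
  ce + l2
}

# Adam update (in place on the params list); state carries first/second
# moments per parameter tensor.
adam_step <- function(params, grads, state, config) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  state$t <- state$t + 1L
  lr_t <- config$learning_rate *
    sqrt(1 - b2^state$t) / (1 - b1^state$t)
  for (grp in c("conv_W", "conv_b", "dense_W", "dense_b")) {
    for (l in seq_along(params[[grp]])) {
      g <- grads[[grp]][[l]]
      key <- paste0(grp, l)
      if (is.null(state$m[[key]])) {
        state$m[[key]] <- g * 0
        state$v[[key]] <- g * 0
      }
      state$m[[key]] <- b1 * state$m[[key]] + (1 - b1) * g
      state$v[[key]] <- b2 * state$v[[key]] + (1 - b2) * g^2
      params[[grp]][[l]] <- params[[grp]][[l]] -
        lr_t * state$m[[key]] / (sqrt(state$v[[key]]) + eps)
    }
  }
  list(params = params, state = state)
}

cnn_predict_probs <- function(model, X) {
  config <- model$config
  B <- nrow(X)
  plan <- cnn_plan(config, B)
  cnn_forward(model$params, config, plan, X, train = FALSE)$probs
}
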