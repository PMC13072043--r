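#' Two-layer graph convolutional classifier
#'
#' Forward model on the normalized adjacency `A` (written `Ã` in the graph
#' literature):
#' \deqn{H^1 = ReLU(\tilde{A} X W^0),\quad H^2 = ReLU(\tilde{A} H^1 W^1),
#'       \quad \hat{y} = softmax(H^2 W^2)}
#' with inverted dropout on both hidden layers during training. Trained
#' transductively by Adam on masked categorical cross-entropy with early
#' stopping on validation accuracy. Gradients are analytic (hand-derived
#' backprop); [gcn_gradients()] exposes them for finite-difference
#' verification.
#'
#' @name gcn_model
NULL

#' Initialize GCN parameters (Glorot uniform)
#'
#' @param d input feature dimension.
#' @param h hidden units per layer (default 256).
#' @param C number of classes (default 4).
#' @param dropout_p dropout probability in `[0, 0.5]` (default 0.3).
#' @param seed init seed.
#' @return a `gcn_params` object with `W0` (d x h), `W1` (h x h),
#'   `W2` (h x C).
#' @export
init_params <- function(d, h = 256L, C = 4L, dropout_p = 0.3, seed = 42L) {
  stopifnot(d >= 1, h >= 1, C >= 2)
  if (dropout_p < 0 || dropout_p > 0.5) {
    stopf("dropout_p must lie in [0, 0.5]")
  }
  glorot <- function(fin, fout) {
    lim <- sqrt(6 / (fin + fout))
    matrix(stats::runif(fin * fout, -lim, lim), fin, fout)
  }
  with_seed(derive_seed(seed, 5L), {
    structure(list(W0 = glorot(d, h), W1 = glorot(h, h), W2 = glorot(h, C),
                   hidden_dim = as.integer(h), n_classes = as.integer(C),
                   dropout_p = dropout_p, init_seed = as.integer(seed)),
              class = "gcn_params")
  })
}

#' @export
print.gcn_params <- function(x, ...) {
  cat(sprintf("<gcn_params> %d -> %d -> %d -> %d, dropout %.3g\n",
              nrow(x$W0), x$hidden_dim, x$hidden_dim, x$n_classes,
              x$dropout_p))
  invisible(x)
}

#' One graph convolution
#'
#' `ReLU(A H W)` when `activate`, else `A H W`.
#' @param A_norm normalized adjacency (sparse or dense).
#' @param H node embedding matrix.
#' @param W weight matrix.
#' @param activate apply ReLU (default TRUE).
#' @return propagated matrix.
#' @export
gcn_layer <- function(A_norm, H, W, activate = TRUE) {
  if (ncol(A_norm) != nrow(H) || ncol(H) != nrow(W)) {
    stopf("dimension mismatch: A %dx%d, H %dx%d, W %dx%d",
          nrow(A_norm), ncol(A_norm), nrow(H), ncol(H), nrow(W), ncol(W))
  }
  Z <- as.matrix(A_norm %*% H) %*% W
  if (activate) pmax(Z, 0) else Z
}

.softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# full forward pass with caches for backprop; dropout masks drawn from the
# current RNG stream when training
.gcn_forward <- function(graph, params, training = FALSE) {
  A <- graph$A_norm
  p <- if (training) params$dropout_p else 0
  Z0 <- as.matrix(A %*% graph$X) %*% params$W0
  H1 <- pmax(Z0, 0)
  M1 <- if (p > 0) {
    matrix(stats::rbinom(length(H1), 1, 1 - p), nrow(H1)) / (1 - p)
  } else 1
  D1 <- H1 * M1
  Z1 <- as.matrix(A %*% D1) %*% params$W1
  H2 <- pmax(Z1, 0)
  M2 <- if (p > 0) {
    matrix(stats::rbinom(length(H2), 1, 1 - p), nrow(H2)) / (1 - p)
  } else 1
  D2 <- H2 * M2
  S <- D2 %*% params$W2
  list(P = .softmax_rows(S), Z0 = Z0, D1 = D1, M1 = M1, Z1 = Z1, D2 = D2,
       M2 = M2)
}

#' Forward pass: class probabilities per node
#'
#' Deterministic when `training = FALSE`; with `training = TRUE` dropout
#' masks are drawn from the current RNG stream (seed the caller for
#' reproducibility).
#'
#' @param graph a `graph_dataset`.
#' @param params `gcn_params`.
#' @param training apply dropout (default FALSE).
#' @return `N x C` matrix of row-stochastic probabilities.
#' @export
gcn_forward <- function(graph, params, training = FALSE) {
  if (!inherits(graph, "graph_dataset")) stopf("graph must be a graph_dataset")
  .gcn_forward(graph, params, training)$P
}

#' Masked categorical cross-entropy
#'
#' Mean over masked nodes of `-log` probability of the true class.
#' Probabilities below `1e-12` at the true class are clamped with a warning.
#'
#' @param probs row-stochastic probability matrix.
#' @param labels integer classes (1-based) or factor.
#' @param mask logical vector of nodes entering the loss.
#' @return nonnegative scalar.
#' @export
cross_entropy <- function(probs, labels, mask = rep(TRUE, nrow(probs))) {
  if (is.factor(labels)) labels <- as.integer(labels)
  idx <- which(mask)
  if (!length(idx)) stopf("empty mask")
  if (anyNA(labels[idx])) stopf("labels undefined on masked nodes")
  p <- probs[cbind(idx, labels[idx])]
  if (any(p < 1e-12)) {
    warnf("clamping %d zero probabilities at 1e-12", sum(p < 1e-12))
    p <- pmax(p, 1e-12)
  }
  -mean(log(p))
}

# labels as integer vector; NA outside masks tolerated
.int_labels <- function(graph) {
  if (is.factor(graph$labels)) as.integer(graph$labels) else
    as.integer(graph$labels)
}

#' Analytic gradients of the masked cross-entropy
#'
#' Returns loss and gradients for `W0`, `W1`, `W2` at fixed dropout masks
#' (no dropout unless `training`). Exposed as a hook so the test-suite can
#' verify backprop against central finite differences.
#'
#' @param graph a `graph_dataset`.
#' @param params `gcn_params`.
#' @param mask logical vector of nodes entering the loss (default training
#'   mask).
#' @param training draw dropout masks (default FALSE).
#' @return list `loss`, `gW0`, `gW1`, `gW2`.
#' @export
gcn_gradients <- function(graph, params, mask = graph$train_mask,
                          training = FALSE) {
  y <- .int_labels(graph)
  fw <- .gcn_forward(graph, params, training)
  idx <- which(mask)
  nm <- length(idx)
  if (!nm) stopf("empty mask")
  P <- fw$P
  loss <- -mean(log(pmax(P[cbind(idx, y[idx])], 1e-12)))
  dS <- matrix(0, nrow(P), ncol(P))
  dS[idx, ] <- P[idx, , drop = FALSE] / nm
  dS[cbind(idx, y[idx])] <- dS[cbind(idx, y[idx])] - 1 / nm
  A <- graph$A_norm
  gW2 <- crossprod(fw$D2, dS)
  dD2 <- dS %*% t(params$W2)
  dZ1 <- dD2 * fw$M2 * (fw$Z1 > 0)
  AdZ1 <- as.matrix(A %*% dZ1)            # A symmetric: t(A) == A
  gW1 <- crossprod(fw$D1, AdZ1)
  dD1 <- AdZ1 %*% t(params$W1)
  dZ0 <- dD1 * fw$M1 * (fw$Z0 > 0)
  AdZ0 <- as.matrix(A %*% dZ0)
  gW0 <- crossprod(graph$X, AdZ0)
  list(loss = loss, gW0 = gW0, gW1 = gW1, gW2 = gW2)
}

#' Training configuration
#'
#' Defaults follow the reference training recipe: Adam, learning rate 1e-3,
#' at most 20 epochs, early-stopping patience 3 on validation accuracy
#' (strict improvement), minibatches of 16 training nodes per step (loss
#' masked to the chunk; the graph forward pass always spans all nodes, so no
#' edges are severed). `batch_size = NULL` trains full-batch.
#'
#' @param learning_rate Adam step size (default 1e-3).
#' @param max_epochs epoch cap (default 20).
#' @param patience epochs without strict validation improvement before
#'   stopping (default 3).
#' @param batch_size training nodes per gradient step (default 16; NULL =
#'   full batch).
#' @param beta1,beta2,eps Adam moment decay constants (conventional
#'   defaults).
#' @param seed seed for dropout masks and minibatch shuffling.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, max_epochs = 20L,
                         patience = 3L, batch_size = 16L,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         seed = 42L) {
  if (patience > max_epochs) stopf("patience must be <= max_epochs")
  if (learning_rate <= 0) stopf("learning_rate must be > 0")
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = if (is.null(batch_size)) NULL
                              else as.integer(batch_size),
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 seed = as.integer(seed)), class = "train_config")
}

.adam_init <- function(params, keys = c("W0", "W1", "W2")) {
  st <- list(t = 0)
  for (k in keys) {
    st[[paste0("m_", k)]] <- params[[k]] * 0
    st[[paste0("v_", k)]] <- params[[k]] * 0
  }
  st
}

.adam_step <- function(params, grads, st, cfg, keys = c("W0", "W1", "W2")) {
  st$t <- st$t + 1
  for (k in keys) {
    g <- grads[[paste0("g", k)]]
    st[[paste0("m_", k)]] <- cfg$beta1 * st[[paste0("m_", k)]] +
      (1 - cfg$beta1) * g
    st[[paste0("v_", k)]] <- cfg$beta2 * st[[paste0("v_", k)]] +
      (1 - cfg$beta2) * g^2
    mhat <- st[[paste0("m_", k)]] / (1 - cfg$beta1^st$t)
    vhat <- st[[paste0("v_", k)]] / (1 - cfg$beta2^st$t)
    params[[k]] <- params[[k]] - cfg$learning_rate * mhat /
      (sqrt(vhat) + cfg$eps)
  }
  list(params = params, state = st)
}

.masked_accuracy <- function(probs, labels, mask) {
  idx <- which(mask)
  pred <- max.col(probs[idx, , drop = FALSE], ties.method = "first")
  mean(pred == labels[idx])
}

#' Train the GCN transductively
#'
#' Adam on masked cross-entropy over training nodes; after every epoch the
#' validation accuracy is evaluated (dropout off) and training stops when it
#' has not strictly improved for `patience` consecutive epochs or at
#' `max_epochs`. The returned parameters are the snapshot with the best
#' validation accuracy.
#'
#' @param graph a `graph_dataset` with non-empty train and val masks.
#' @param params optional initial `gcn_params` (default: Glorot init seeded
#'   by `cfg$seed`, hidden 256).
#' @param cfg a [train_config()].
#' @return list `params` (best snapshot), `history` (data.frame epoch /
#'   loss / val_acc), `stopped_epoch`, `best_epoch`, `best_val_acc`.
#' @export
train_gcn <- function(graph, params = NULL, cfg = train_config()) {
  if (!any(graph$train_mask)) stopf("empty training mask")
  if (!any(graph$val_mask)) stopf("empty validation mask")
  y <- .int_labels(graph)
  if (is.null(params)) {
    lv <- graph$class_names %||% levels(graph$labels)
    params <- init_params(ncol(graph$X), 256L,
                          if (length(lv)) length(lv) else 4L,
                          seed = cfg$seed)
  }
  st <- .adam_init(params)
  train_idx <- which(graph$train_mask)
  hist_loss <- numeric(0); hist_val <- numeric(0)
  best_val <- -Inf; best_params <- params; best_epoch <- 0L
  stall <- 0L; stopped <- cfg$max_epochs
  with_seed(derive_seed(cfg$seed, 6L), {
    for (epoch in seq_len(cfg$max_epochs)) {
      chunks <- if (is.null(cfg$batch_size)) list(train_idx) else {
        sh <- train_idx[sample.int(length(train_idx))]
        split(sh, ceiling(seq_along(sh) / cfg$batch_size))
      }
      ep_loss <- 0
      for (ch in chunks) {
        mask <- logical(nrow(graph$X)); mask[ch] <- TRUE
        gr <- gcn_gradients(graph, params, mask = mask, training = TRUE)
        if (!is.finite(gr$loss)) {
          stopf("divergence at epoch %d (non-finite loss)", epoch)
        }
        up <- .adam_step(params, gr, st, cfg)
        params <- up$params; st <- up$state
        ep_loss <- ep_loss + gr$loss * length(ch)
      }
      hist_loss <- c(hist_loss, ep_loss / length(train_idx))
      probs <- gcn_forward(graph, params, training = FALSE)
      val_acc <- .masked_accuracy(probs, y, graph$val_mask)
      hist_val <- c(hist_val, val_acc)
      if (val_acc > best_val) {
        best_val <- val_acc; best_params <- params; best_epoch <- epoch
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      if (stall >= cfg$patience) { stopped <- epoch; break }
      stopped <- epoch
    }
  })
  list(params = best_params,
       history = data.frame(epoch = seq_along(hist_loss), loss = hist_loss,
                            val_acc = hist_val),
       stopped_epoch = stopped, best_epoch = best_epoch,
       best_val_acc = best_val)
}

#' Predict test-node classes and confidences
#'
#' Argmax class and maximal probability per node; ties break toward the
#' lower class index. Test labels are never read.
#'
#' @param graph a `graph_dataset`.
#' @param params trained `gcn_params`.
#' @param nodes node indices to report (default the test mask).
#' @return list `labels` (factor), `confidence` (numeric), `probs`.
#' @export
predict_gcn <- function(graph, params, nodes = which(graph$test_mask)) {
  probs <- gcn_forward(graph, params, training = FALSE)
  pr <- probs[nodes, , drop = FALSE]
  cls <- max.col(pr, ties.method = "first")
  lv <- graph$class_names %||% levels(graph$labels)
  list(labels = factor(lv[cls], levels = lv),
       confidence = pr[cbind(seq_along(cls), cls)],
       probs = pr)
}
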