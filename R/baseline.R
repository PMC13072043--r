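#' Dense (CNN-only) baseline classifier
#'
#' A two-hidden-layer perceptron (512 -> 256 -> C units, ReLU, softmax) on
#' the raw embeddings — the "feature extractor plus dense head" control arm
#' against which the graph model is compared. Shares the optimizer and
#' early-stopping contract of [train_gcn()] so accuracy differences reflect
#' the graph, not the training protocol.
#'
#' @param features N x d embedding matrix.
#' @param labels factor / integer labels (needed on train and val rows).
#' @param masks list with `train_mask`, `val_mask` (and optionally
#'   `test_mask`).
#' @param cfg a [train_config()].
#' @param hidden hidden layer sizes, default `c(512, 256)`.
#' @param dropout_p inverted dropout on both hidden layers during training
#'   (default 0.3, the shared training-configuration value, so the
#'   comparison against the graph model isolates the graph rather than the
#'   regularization).
#' @return list `model` (weights, hidden dims), `history`, `stopped_epoch`,
#'   `best_epoch`, `best_val_acc`.
#' @export
dense_baseline_train <- function(features, labels, masks,
                                 cfg = train_config(),
                                 hidden = c(512L, 256L), dropout_p = 0.3) {
  if (!any(masks$train_mask)) stopf("empty training mask")
  if (!any(masks$val_mask)) stopf("empty validation mask")
  X <- as.matrix(features)
  if (is.factor(labels)) {
    lv <- levels(labels); y <- as.integer(labels)
  } else {
    lv <- as.character(sort(unique(labels[!is.na(labels)])))
    y <- as.integer(factor(labels, levels = lv))
  }
  C <- length(lv)
  d <- ncol(X)
  glorot <- function(fin, fout) {
    lim <- sqrt(6 / (fin + fout))
    matrix(stats::runif(fin * fout, -lim, lim), fin, fout)
  }
  with_seed(derive_seed(cfg$seed, 7L), {
    W <- list(W0 = glorot(d, hidden[1]), W1 = glorot(hidden[1], hidden[2]),
              W2 = glorot(hidden[2], C))
    st <- .adam_init(W)
    fwd <- function(Xb, training = FALSE) {
      p <- if (training) dropout_p else 0
      H1 <- pmax(Xb %*% W$W0, 0)
      M1 <- if (p > 0) matrix(stats::rbinom(length(H1), 1, 1 - p),
                              nrow(H1)) / (1 - p) else 1
      D1 <- H1 * M1
      H2 <- pmax(D1 %*% W$W1, 0)
      M2 <- if (p > 0) matrix(stats::rbinom(length(H2), 1, 1 - p),
                              nrow(H2)) / (1 - p) else 1
      D2 <- H2 * M2
      list(P = .softmax_rows(D2 %*% W$W2), H1 = H1, M1 = M1, D1 = D1,
           H2 = H2, M2 = M2, D2 = D2)
    }
    train_idx <- which(masks$train_mask)
    hist_loss <- numeric(0); hist_val <- numeric(0)
    best_val <- -Inf; bestW <- W; best_epoch <- 0L
    stall <- 0L; stopped <- cfg$max_epochs
    for (epoch in seq_len(cfg$max_epochs)) {
      chunks <- if (is.null(cfg$batch_size)) list(train_idx) else {
        sh <- train_idx[sample.int(length(train_idx))]
        split(sh, ceiling(seq_along(sh) / cfg$batch_size))
      }
      ep_loss <- 0
      for (ch in chunks) {
        Xb <- X[ch, , drop = FALSE]
        fw <- fwd(Xb, training = TRUE)
        nm <- length(ch)
        loss <- -mean(log(pmax(fw$P[cbind(seq_len(nm), y[ch])], 1e-12)))
        if (!is.finite(loss)) stopf("divergence at epoch %d", epoch)
        dS <- fw$P / nm
        dS[cbind(seq_len(nm), y[ch])] <- dS[cbind(seq_len(nm), y[ch])] -
          1 / nm
        gW2 <- crossprod(fw$D2, dS)
        dH2 <- (dS %*% t(W$W2)) * fw$M2 * (fw$H2 > 0)
        gW1 <- crossprod(fw$D1, dH2)
        dH1 <- (dH2 %*% t(W$W1)) * fw$M1 * (fw$H1 > 0)
        gW0 <- crossprod(Xb, dH1)
        up <- .adam_step(W, list(gW0 = gW0, gW1 = gW1, gW2 = gW2), st, cfg)
        W <- up$params; st <- up$state
        ep_loss <- ep_loss + loss * nm
      }
      hist_loss <- c(hist_loss, ep_loss / length(train_idx))
      val_idx <- which(masks$val_mask)
      val_acc <- mean(max.col(fwd(X[val_idx, , drop = FALSE])$P,
                              ties.method = "first") == y[val_idx])
      hist_val <- c(hist_val, val_acc)
      if (val_acc > best_val) {
        best_val <- val_acc; bestW <- W; best_epoch <- epoch; stall <- 0L
      } else stall <- stall + 1L
      if (stall >= cfg$patience) { stopped <- epoch; break }
      stopped <- epoch
    }
    list(model = structure(list(weights = bestW, hidden = hidden,
                                class_names = lv), class = "dense_model"),
         history = data.frame(epoch = seq_along(hist_loss),
                              loss = hist_loss, val_acc = hist_val),
         stopped_epoch = stopped, best_epoch = best_epoch,
         best_val_acc = best_val)
  })
}

#' Predict with the dense baseline
#'
#' @param model a `dense_model` from [dense_baseline_train()].
#' @param features N x d matrix.
#' @return list `labels` (factor), `confidence`, `probs`.
#' @export
dense_baseline_predict <- function(model, features) {
  W <- model$weights
  H1 <- pmax(as.matrix(features) %*% W$W0, 0)
  H2 <- pmax(H1 %*% W$W1, 0)
  P <- .softmax_rows(H2 %*% W$W2)
  cls <- max.col(P, ties.method = "first")
  list(labels = factor(model$class_names[cls], levels = model$class_names),
       confidence = P[cbind(seq_along(cls), cls)], probs = P)
}
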