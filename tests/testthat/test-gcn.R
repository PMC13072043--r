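# small graph shared across tests
make_graph <- function(noise = 0.05, overlap = 0, n = c(10L, 10L, 10L, 10L),
                       seed = 11L, k = 4L, tau = 0.4) {
  tab <- tiny_table(n, 16L, noise, overlap, seed)
  sp <- make_split(tab$labels, 0.25, 0.2, seed = seed)
  list(tab = tab, sp = sp,
       graph = build_graph(tab, sp, graph_config(k = k, tau = tau,
                                                 seed = seed)))
}

test_that("Glorot init is bounded, seeded and shape-consistent", {
  p <- init_params(20L, 8L, 4L, seed = 5L)
  expect_identical(p, init_params(20L, 8L, 4L, seed = 5L))
  expect_false(identical(p$W0, init_params(20L, 8L, 4L, seed = 6L)$W0))
  expect_true(all(abs(p$W0) <= sqrt(6 / 28)))
  expect_true(all(abs(p$W1) <= sqrt(6 / 16)))
  expect_equal(dim(p$W2), c(8L, 4L))
  expect_error(init_params(4L, 4L, 4L, dropout_p = 0.9), "dropout")
})

test_that("gcn_layer matches the dense propagation oracle", {
  # identity propagation leaves nonnegative input unchanged
  H <- matrix(abs(rnorm(12)), 4, 3)
  expect_equal(gcn_layer(Matrix::Diagonal(4), H, diag(3)), H,
               ignore_attr = TRUE)
  # all-negative pre-activation -> zeros
  expect_true(all(gcn_layer(Matrix::Diagonal(4), -H, diag(3)) == 0))
  # random 5-node instance vs brute-force product
  with_seed(2, {
    A <- matrix(runif(25), 5, 5); A <- (A + t(A)) / 2
    Hh <- matrix(rnorm(15), 5, 3); W <- matrix(rnorm(6), 3, 2)
    expect_lt(max(abs(gcn_layer(A, Hh, W, activate = FALSE) - A %*% Hh %*% W)),
              1e-12)
    expect_lt(max(abs(gcn_layer(A, Hh, W) - pmax(A %*% Hh %*% W, 0))), 1e-12)
  })
  expect_error(gcn_layer(diag(3), matrix(0, 4, 2), diag(2)), "mismatch")
})

test_that("forward produces distributions and honours dropout contracts", {
  gg <- make_graph()
  p <- init_params(16L, 8L, 4L, dropout_p = 0.3, seed = 1L)
  probs <- gcn_forward(gg$graph, p)
  expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-9)
  # inference path is deterministic
  expect_identical(probs, gcn_forward(gg$graph, p))
  # dropout disabled: training == inference
  p0 <- init_params(16L, 8L, 4L, dropout_p = 0, seed = 1L)
  expect_identical(gcn_forward(gg$graph, p0, training = TRUE),
                   gcn_forward(gg$graph, p0))
})

test_that("cross-entropy matches closed forms and the elementwise oracle", {
  onehot <- diag(4)[c(1, 2, 3), ]
  expect_equal(cross_entropy(pmax(onehot, 1e-15), c(1L, 2L, 3L)), 0,
               tolerance = 1e-10)
  unif <- matrix(0.25, 3, 4)
  expect_equal(cross_entropy(unif, c(1L, 4L, 2L)), log(4), tolerance = 1e-12)
  with_seed(4, {
    P <- matrix(runif(12), 3, 4); P <- P / rowSums(P)
    y <- c(2L, 1L, 4L)
    # direct double-sum evaluation of the loss definition
    oracle <- -sum(vapply(1:3, function(i) log(P[i, y[i]]), numeric(1))) / 3
    expect_equal(cross_entropy(P, y), oracle, tolerance = 1e-12)
  })
  expect_warning(cross_entropy(rbind(c(0, 1, 0, 0)), 1L), "clamp")
})

test_that("analytic gradients agree with central finite differences", {
  tab <- tiny_table(c(2L, 2L, 1L, 1L), dim = 16L, seed = 13L)
  sp <- list(train_mask = rep(c(TRUE, FALSE), c(4L, 2L)),
             val_mask = c(rep(FALSE, 4L), TRUE, FALSE),
             test_mask = c(rep(FALSE, 5L), TRUE))
  g <- suppressWarnings(build_graph(tab, sp, graph_config(k = 2L, tau = -1)))
  p <- init_params(16L, 4L, 4L, dropout_p = 0, seed = 3L)
  gr <- gcn_gradients(g, p, mask = g$train_mask)
  for (w in c("W0", "W1", "W2")) {
    gn <- numeric_gradient(g, p, w, g$train_mask)
    rel <- max(abs(gr[[paste0("g", w)]] - gn)) / max(abs(gn))
    expect_lt(rel, 1e-5)
  }
})

test_that("training learns separable clusters and is deterministic", {
  gg <- make_graph(n = rep(40L, 4), seed = 17L, k = 6L)
  cfg <- train_config(seed = 99L)
  fit <- train_gcn(gg$graph, init_params(16L, 256L, 4L, seed = 99L), cfg)
  expect_gte(fit$best_val_acc, 0.95)
  # training loss trends downward over the first epochs
  first <- fit$history$loss[seq_len(min(5, nrow(fit$history)))]
  expect_lt(first[length(first)], first[1])
  # bit-identical repeat under the same seed
  fit2 <- train_gcn(gg$graph, init_params(16L, 256L, 4L, seed = 99L), cfg)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$params, fit2$params)
})

test_that("early stopping halts after `patience` flat epochs", {
  gg <- make_graph()
  # learning rate so small that validation accuracy cannot move
  cfg <- train_config(learning_rate = 1e-15, patience = 1L, seed = 1L)
  fit <- train_gcn(gg$graph, init_params(16L, 8L, 4L, dropout_p = 0,
                                         seed = 1L), cfg)
  expect_equal(fit$stopped_epoch, 2L)
  expect_equal(fit$best_epoch, 1L)
  expect_error(train_gcn(gg$graph, cfg = train_config(patience = 5L,
                                                      max_epochs = 3L)),
               "patience")
})

test_that("prediction uses argmax with lower-index ties, label-blind", {
  gg <- make_graph(seed = 23L)
  p <- init_params(16L, 8L, 4L, seed = 2L)
  pred <- predict_gcn(gg$graph, p)
  probs <- gcn_forward(gg$graph, p)[which(gg$graph$test_mask), , drop = FALSE]
  expect_equal(as.integer(pred$labels),
               apply(probs, 1, which.max))
  expect_equal(pred$confidence, apply(probs, 1, max))
  # tie row resolves to the lower class index
  fake <- gg$graph
  expect_equal(max.col(rbind(rep(0.25, 4)), ties.method = "first"), 1L)
})

test_that("forward with identity adjacency and identity-like weights reduces
           to a linear softmax on X", {
  tab <- tiny_table(c(3L, 3L, 3L, 3L), 8L, seed = 31L)
  n <- nrow(tab$vectors)
  es <- add_self_loops(edge_set(n_nodes = n))
  g <- structure(list(X = pmax(tab$vectors, 0), edges = es,
                      A_norm = normalize_adjacency(es),
                      labels = tab$labels,
                      train_mask = rep(TRUE, n), val_mask = rep(FALSE, n),
                      test_mask = rep(FALSE, n),
                      class_names = levels(tab$labels)),
                 class = "graph_dataset")
  W2 <- with_seed(1, matrix(rnorm(32), 8, 4))
  p <- structure(list(W0 = diag(8), W1 = diag(8), W2 = W2,
                      hidden_dim = 8L, n_classes = 4L, dropout_p = 0,
                      init_seed = 0L), class = "gcn_params")
  probs <- gcn_forward(g, p)
  manual <- exp(pmax(g$X, 0) %*% W2)
  manual <- manual / rowSums(manual)
  expect_equal(probs, manual, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("dense baseline trains, records its architecture and is seeded", {
  tab <- tiny_table(c(15L, 15L, 15L, 15L), seed = 37L)
  sp <- make_split(tab$labels, 0.25, 0.2, seed = 37L)
  cfg <- train_config(seed = 7L)
  fit <- dense_baseline_train(tab$vectors, tab$labels, sp, cfg,
                              hidden = c(512L, 256L))
  expect_equal(fit$model$hidden, c(512L, 256L))
  expect_gte(fit$best_val_acc, 0.95)
  fit2 <- dense_baseline_train(tab$vectors, tab$labels, sp, cfg)
  expect_identical(fit$model$weights, fit2$model$weights)
  pred <- dense_baseline_predict(fit$model,
                                 tab$vectors[sp$test_mask, , drop = FALSE])
  expect_gte(mean(pred$labels == tab$labels[sp$test_mask]), 0.9)
})

test_that("checkpoints round-trip weights at full precision", {
  p <- init_params(6L, 4L, 4L, seed = 8L)
  f <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(p, f, graph_fingerprint = "abc123")
  q <- load_checkpoint(f)
  expect_equal(q$W0, p$W0, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(q$W2, p$W2, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(q$hidden_dim, p$hidden_dim)
})
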