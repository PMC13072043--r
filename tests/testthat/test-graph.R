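test_that("cosine similarity matches hand-derived values", {
  expect_equal(cosine_similarity(c(2, 5, 1), c(2, 5, 1)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 0), c(1, 1)), sqrt(2) / 2,
               tolerance = 1e-12)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero")
})

test_that("thresholded knn edges follow the enumeration and tie-break rules", {
  # three nodes where only the (1,2) pair exceeds tau
  X <- rbind(c(1, 0.02), c(1, -0.02), c(0, 1))
  cfg <- graph_config(k = 2L, tau = 0.75)
  es <- build_knn_edges(X, cfg)
  df <- as.data.frame(es)
  expect_setequal(paste(df$src, df$dst), c("1 2", "2 1"))

  # strict threshold: tau = 1 and distinct directions -> empty
  es2 <- build_knn_edges(X, graph_config(k = 2L, tau = 1))
  expect_length(es2$src, 0L)

  # all identical: ties at rank k resolve toward lower node index
  Xid <- matrix(1, 5, 3)
  expect_warning(es3 <- build_knn_edges(Xid, graph_config(k = 10L, tau = 0)),
                 "capping")
  df3 <- as.data.frame(es3)
  # every ordered pair is present (k capped at 4 neighbours)
  expect_equal(nrow(df3), 20L)
  es4 <- build_knn_edges(Xid, graph_config(k = 2L, tau = 0))
  df4 <- as.data.frame(es4)
  # node 5 chooses neighbours 1 and 2 (lowest indices); symmetrization
  # cannot add more links to node 5 because nobody else selects it
  expect_setequal(df4$dst[df4$src == 5], c(1L, 2L))
})

test_that("self-loops are complete, idempotent and preserving", {
  es <- edge_set(1L, 2L, "knn", 3L)
  with_loops <- add_self_loops(es)
  df <- as.data.frame(with_loops)
  expect_true(all(paste(1:3, 1:3) %in% paste(df$src, df$dst)))
  expect_true("1 2" %in% paste(df$src, df$dst))
  expect_equal(as.data.frame(add_self_loops(with_loops)), df)
})

test_that("class edges only touch same-label training nodes", {
  labels <- c("a", "a", "a", "b", "b", "b", "b", NA)
  train <- c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  cfg <- graph_config(class_edges_per_node = 2L, seed = 1L)
  es <- add_class_edges(labels, train, cfg)
  df <- as.data.frame(es)
  expect_true(all(df$provenance == "class_aware"))
  expect_true(all(train[df$src] & train[df$dst]))
  expect_true(all(labels[df$src] == labels[df$dst]))

  # zero budget -> empty
  es0 <- add_class_edges(labels, train, graph_config(class_edges_per_node = 0L))
  expect_length(es0$src, 0L)

  # two-node class with budget 3 -> exactly the one symmetric pair
  es2 <- add_class_edges(c("x", "x"), c(TRUE, TRUE),
                         graph_config(class_edges_per_node = 3L))
  expect_setequal(paste(es2$src, es2$dst), c("1 2", "2 1"))

  # singleton class warns and contributes nothing
  expect_warning(es3 <- add_class_edges(c("x", "y", "y"), rep(TRUE, 3),
                                        graph_config()), "single")
  expect_true(all(c(es3$src, es3$dst) %in% 2:3))
})

test_that("symmetric normalization matches hand and dense oracles", {
  # identity graph
  es <- add_self_loops(edge_set(n_nodes = 3L))
  expect_equal(as.matrix(normalize_adjacency(es)), diag(3),
               ignore_attr = TRUE)

  # 2-node full graph: every entry 1/2
  es2 <- add_self_loops(symmetrize_edges(edge_set(1L, 2L, "knn", 2L)))
  expect_equal(as.matrix(normalize_adjacency(es2)),
               matrix(0.5, 2, 2), ignore_attr = TRUE)

  # random 6-node graph against the dense D^(-1/2) A D^(-1/2) oracle
  X <- with_seed(3, matrix(rnorm(6 * 4), 6, 4))
  cfg <- graph_config(k = 3L, tau = -1)
  es3 <- add_self_loops(build_knn_edges(X, cfg))
  expect_lt(max(abs(as.matrix(normalize_adjacency(es3)) -
                      dense_graph_oracle(X, 3L, -1))), 1e-12)

  expect_error(normalize_adjacency(edge_set(1L, 1L, "self_loop", 2L)),
               "zero-degree")
})

test_that("raising tau never adds a knn edge (monotonicity)", {
  X <- with_seed(9, matrix(rnorm(12 * 5), 12, 5))
  taus <- c(-0.5, 0, 0.3, 0.6, 0.9)
  prev <- NULL
  for (tau in taus) {
    es <- build_knn_edges(X, graph_config(k = 4L, tau = tau))
    cur <- paste(es$src, es$dst)
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("build_graph produces a consistent transductive dataset", {
  tab <- tiny_table()
  sp <- make_split(tab$labels, 0.25, 0.2, seed = 3L)
  g <- build_graph(tab, sp, graph_config(k = 4L, tau = 0.5, seed = 5L))
  n <- nrow(tab$vectors)
  # conservation: every node in exactly one mask
  expect_equal(sum(g$train_mask) + sum(g$val_mask) + sum(g$test_mask), n)
  # symmetry of the finalized adjacency
  expect_true(Matrix::isSymmetric(g$A_norm))
  # every node has its self-loop (degree >= 1)
  expect_true(all(Matrix::diag(g$A_norm) > 0))
  # labels blanked on test nodes
  expect_true(all(is.na(g$labels[g$test_mask])))
  # no test-test edges and no class edges at test nodes
  df <- as.data.frame(g$edges)
  both_test <- g$test_mask[df$src] & g$test_mask[df$dst] & df$src != df$dst
  expect_false(any(both_test))
  at_test <- (g$test_mask[df$src] | g$test_mask[df$dst]) &
    df$provenance == "class_aware"
  expect_false(any(at_test))
  # same-class knn fraction exceeds cross-class fraction on synthetic data
  knn <- df[df$provenance == "knn" &
              !g$test_mask[df$src] & !g$test_mask[df$dst], ]
  lab <- as.character(tab$labels)
  expect_gt(mean(lab[knn$src] == lab[knn$dst]), 0.5)
})

test_that("test attachment is label-blind and similarity-driven", {
  tab <- tiny_table(seed = 21L)
  n <- nrow(tab$vectors)
  tr <- embedding_table(tab$vectors[1:30, ], ids = tab$ids[1:30],
                        labels = tab$labels[1:30],
                        class_names = levels(tab$labels))
  te_vec <- tab$vectors[31:40, ]
  te <- embedding_table(te_vec, ids = tab$ids[31:40],
                        labels = tab$labels[31:40],
                        class_names = levels(tab$labels))
  g1 <- attach_test_nodes(tr, te, graph_config(k = 3L))
  # permuted / removed test labels -> identical adjacency
  te_perm <- embedding_table(te_vec, ids = te$ids,
                             labels = rev(as.character(te$labels)),
                             class_names = levels(tab$labels))
  te_null <- embedding_table(te_vec, ids = te$ids)
  g2 <- attach_test_nodes(tr, te_perm, graph_config(k = 3L))
  g3 <- attach_test_nodes(tr, te_null, graph_config(k = 3L))
  expect_identical(as.matrix(g1$A_norm), as.matrix(g2$A_norm))
  expect_identical(as.matrix(g1$A_norm), as.matrix(g3$A_norm))
  expect_identical(g1$train_mask, g2$train_mask)

  # a test node identical to a training node picks it as top neighbour
  te_dup <- embedding_table(tr$vectors[7, , drop = FALSE], ids = "dup")
  g4 <- attach_test_nodes(tr, te_dup, graph_config(k = 1L))
  df <- as.data.frame(g4$edges)
  test_id <- 31L
  nb <- df$dst[df$src == test_id & df$dst != test_id]
  expect_equal(nb, 7L)

  # a far-away test node (all similarities below tau) still receives its
  # k nearest neighbours: the threshold does not apply at inference
  far <- matrix(with_seed(99, rnorm(ncol(tr$vectors))), 1)
  far <- far - tcrossprod(rep(1, 1), colMeans(tr$vectors)) * 5
  g5 <- attach_test_nodes(tr, embedding_table(far, ids = "far"),
                          graph_config(k = 3L, tau = 0.75))
  df5 <- as.data.frame(g5$edges)
  deg <- sum(df5$src == 31L & df5$dst != 31L)
  expect_equal(deg, 3L)

  expect_error(attach_test_nodes(te_null, te, graph_config()), "labelled")
})

test_that("small pipelines match the dense oracle end to end", {
  # a focused version of the acceptance sweep: 10 random instances
  for (r in 1:10) {
    with_seed(100 + r, {
      n <- sample(5:20, 1)
      X <- matrix(rnorm(n * 6), n, 6)
      k <- sample(2:4, 1)
      tau <- runif(1, -0.5, 0.5)
      es <- add_self_loops(build_knn_edges(X, graph_config(k = k, tau = tau)))
      expect_lt(max(abs(as.matrix(normalize_adjacency(es)) -
                          dense_graph_oracle(X, k, tau))), 1e-12)
    })
  }
})
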