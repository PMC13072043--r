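#' Dataset-level similarity graphs
#'
#' One node per image. Edges come from three sources: (i) a self-loop on
#' every node, (ii) thresholded cosine k-nearest-neighbour links
#' (`similarity > tau` AND within the top-k), and (iii) optional class-aware
#' links sampled between same-label training nodes. The binary adjacency is
#' symmetrically normalized, `D^(-1/2) A D^(-1/2)`, before entering the GCN.
#' Test nodes attach through feature similarity alone — their labels are
#' never read.
#'
#' @name graph_build
NULL

#' Graph construction configuration
#'
#' @param k neighbours per node (default 10; the threshold `tau` remains the
#'   binding filter).
#' @param tau cosine similarity threshold in `[-1, 1]` (default 0.75).
#' @param class_edges_per_node same-class training links sampled per
#'   training node (default 3).
#' @param use_class_edges enable class-aware links (default TRUE).
#' @param seed seed for class-edge sampling.
#' @return a `graph_config` list.
#' @export
graph_config <- function(k = 10L, tau = 0.75, class_edges_per_node = 3L,
                         use_class_edges = TRUE, seed = 42L) {
  if (k < 1L) stopf("k must be >= 1")
  if (tau < -1 || tau > 1) stopf("tau must lie in [-1, 1]")
  if (class_edges_per_node < 0L) stopf("class_edges_per_node must be >= 0")
  structure(list(k = as.integer(k), tau = tau,
                 class_edges_per_node = as.integer(class_edges_per_node),
                 use_class_edges = isTRUE(use_class_edges),
                 seed = as.integer(seed)),
            class = "graph_config")
}

#' Construct an edge set
#'
#' Ordered 1-based node-index pairs with per-edge provenance
#' (`self_loop`, `knn`, `class_aware`).
#'
#' @param src,dst integer node indices.
#' @param provenance character vector (recycled).
#' @param n_nodes total node count.
#' @return an `edge_set`.
#' @export
edge_set <- function(src = integer(0), dst = integer(0),
                     provenance = character(0), n_nodes) {
  src <- as.integer(src); dst <- as.integer(dst)
  if (length(src) != length(dst)) stopf("src/dst length mismatch")
  if (length(src) && (min(c(src, dst)) < 1L || max(c(src, dst)) > n_nodes)) {
    stopf("edge indices out of range [1, %d]", n_nodes)
  }
  provenance <- rep_len(as.character(provenance),
                        length.out = length(src))
  structure(list(src = src, dst = dst, provenance = provenance,
                 n_nodes = as.integer(n_nodes)), class = "edge_set")
}

#' @export
as.data.frame.edge_set <- function(x, ...) {
  data.frame(src = x$src, dst = x$dst, provenance = x$provenance)
}

#' @export
print.edge_set <- function(x, ...) {
  cat(sprintf("<edge_set> %d directed pairs over %d nodes (%s)\n",
              length(x$src), x$n_nodes,
              paste(sprintf("%s=%d", names(table(x$provenance)),
                            table(x$provenance)), collapse = ", ")))
  invisible(x)
}

# drop duplicate ordered pairs, keeping the first provenance seen
.dedupe_edges <- function(es) {
  key <- (as.double(es$src) - 1) * es$n_nodes + as.double(es$dst)
  keep <- !duplicated(key)
  edge_set(es$src[keep], es$dst[keep], es$provenance[keep], es$n_nodes)
}

#' Combine edge sets over the same node universe
#' @param ... `edge_set` objects.
#' @return deduplicated `edge_set`.
#' @export
merge_edges <- function(...) {
  sets <- list(...)
  n <- unique(vapply(sets, function(e) e$n_nodes, integer(1)))
  if (length(n) != 1L) stopf("edge sets span different node counts")
  .dedupe_edges(edge_set(unlist(lapply(sets, `[[`, "src")),
                         unlist(lapply(sets, `[[`, "dst")),
                         unlist(lapply(sets, `[[`, "provenance")), n))
}

#' Symmetrize an edge set
#'
#' Adds `(j, i)` for every `(i, j)`; self-pairs untouched.
#' @param es an `edge_set`.
#' @return symmetric `edge_set`.
#' @export
symmetrize_edges <- function(es) {
  .dedupe_edges(edge_set(c(es$src, es$dst), c(es$dst, es$src),
                         c(es$provenance, es$provenance), es$n_nodes))
}

#' Cosine similarity of two vectors
#'
#' `u . v / (||u|| ||v||)`; errors on zero-norm input.
#' @param u,v numeric vectors of equal length.
#' @return value in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stopf("cosine similarity undefined for zero vector")
  min(max(sum(u * v) / (nu * nv), -1), 1)
}

# row-normalized cosine similarity matrix between X rows and Y rows
.cosine_matrix <- function(X, Y = X) {
  nx <- sqrt(rowSums(X^2)); ny <- sqrt(rowSums(Y^2))
  if (any(nx == 0) || any(ny == 0)) {
    stopf("cosine similarity undefined for zero-norm rows")
  }
  S <- tcrossprod(X / nx, Y / ny)
  S[S > 1] <- 1; S[S < -1] <- -1
  S
}

#' Thresholded cosine-KNN edges
#'
#' For each querying node, links to its at most `k` most similar candidate
#' nodes whose similarity strictly exceeds `tau` (both conditions enforced).
#' Ties at rank k break toward the lower node index. The directed result is
#' symmetrized; self-pairs are excluded (self-loops are added separately).
#'
#' @param X feature matrix (rows = nodes).
#' @param cfg a [graph_config()].
#' @param candidate_mask logical vector marking allowed neighbours (default
#'   all); querying nodes default to the candidates themselves.
#' @param query_idx integer indices of querying nodes (default the
#'   candidates).
#' @return symmetric `edge_set` with provenance `"knn"`.
#' @export
build_knn_edges <- function(X, cfg, candidate_mask = NULL, query_idx = NULL) {
  n <- nrow(X)
  candidate_mask <- candidate_mask %||% rep(TRUE, n)
  cand <- which(candidate_mask)
  query_idx <- query_idx %||% cand
  if (!length(cand)) stopf("no candidate nodes")
  k <- cfg$k
  if (k >= length(cand)) {
    warnf("k = %d >= %d candidates; capping at %d", k, length(cand),
          length(cand) - 1L)
  }
  S <- .cosine_matrix(X[query_idx, , drop = FALSE],
                      X[cand, , drop = FALSE])
  src <- integer(0); dst <- integer(0)
  for (qi in seq_along(query_idx)) {
    i <- query_idx[qi]
    sims <- S[qi, ]
    pool <- which(cand != i & sims > cfg$tau)
    if (!length(pool)) next
    ord <- pool[order(-sims[pool], cand[pool])]
    sel <- ord[seq_len(min(k, length(ord)))]
    src <- c(src, rep(i, length(sel)))
    dst <- c(dst, cand[sel])
  }
  symmetrize_edges(edge_set(src, dst, "knn", n))
}

#' Add self-loops
#'
#' Ensures `(i, i)` for every node; idempotent; existing edges preserved.
#' @param es an `edge_set`.
#' @param n_nodes optional override of the node count.
#' @return `edge_set` including all self-loops.
#' @export
add_self_loops <- function(es, n_nodes = es$n_nodes) {
  merge_edges(es, edge_set(seq_len(n_nodes), seq_len(n_nodes), "self_loop",
                           n_nodes))
}

#' Sampled class-aware training edges
#'
#' For each training node, links to `class_edges_per_node` seeded uniformly
#' sampled distinct same-class training nodes (capped by availability;
#' singleton classes contribute nothing, with a warning). Non-training nodes
#' are never touched. Result is symmetrized.
#'
#' @param labels labels (defined wherever `train_mask` is TRUE).
#' @param train_mask logical vector.
#' @param cfg a [graph_config()].
#' @return symmetric `edge_set` with provenance `"class_aware"`.
#' @export
add_class_edges <- function(labels, train_mask, cfg) {
  n <- length(labels)
  budget <- cfg$class_edges_per_node
  if (budget == 0L) return(edge_set(n_nodes = n))
  labels <- as.character(labels)
  if (anyNA(labels[train_mask])) stopf("training labels must be defined")
  src <- integer(0); dst <- integer(0)
  with_seed(derive_seed(cfg$seed, 4L), {
    for (cl in unique(labels[train_mask])) {
      members <- which(train_mask & labels == cl)
      if (length(members) < 2L) {
        warnf("class '%s' has a single training member; no class edges", cl)
        next
      }
      for (i in members) {
        pool <- setdiff(members, i)
        m <- min(budget, length(pool))
        sel <- if (length(pool) == 1L) pool else sample(pool, m)
        src <- c(src, rep(i, m)); dst <- c(dst, sel)
      }
    }
  })
  symmetrize_edges(edge_set(src, dst, "class_aware", n))
}

#' Symmetrically normalized adjacency
#'
#' Builds the binary adjacency from the (finalized, self-looped) edge set
#' and returns the sparse `D^(-1/2) A D^(-1/2)`.
#'
#' @param es an `edge_set` (must give every node degree >= 1).
#' @param n_nodes optional override.
#' @return sparse symmetric `Matrix`.
#' @export
normalize_adjacency <- function(es, n_nodes = es$n_nodes) {
  es <- .dedupe_edges(es)
  A <- Matrix::sparseMatrix(i = es$src, j = es$dst, x = 1,
                            dims = c(n_nodes, n_nodes))
  if (!Matrix::isSymmetric(A)) stopf("edge set must be symmetric (finalize first)")
  deg <- Matrix::rowSums(A)
  if (any(deg == 0)) {
    stopf("zero-degree node(s): %s (add self-loops first)",
          paste(utils::head(which(deg == 0)), collapse = ", "))
  }
  dinv <- 1 / sqrt(deg)
  Matrix::Diagonal(x = dinv) %*% A %*% Matrix::Diagonal(x = dinv)
}

#' Assemble a graph dataset from features, labels and masks
#'
#' KNN edges are built among labelled (train + validation) nodes with the
#' `tau` threshold; test nodes attach to their `k` most similar labelled
#' nodes unconditionally (never to each other) — at inference the threshold
#' does not apply, so every test node receives a full neighbourhood.
#' Class-aware edges are sampled among training nodes only. Test labels are
#' never read.
#'
#' @param table an [embedding_table()] (labels needed on train/val rows).
#' @param split list with `train_mask`, `val_mask`, `test_mask`.
#' @param cfg a [graph_config()].
#' @return a `graph_dataset`: `X`, `edges`, `A_norm`, `labels`,
#'   `train_mask`, `val_mask`, `test_mask`, `class_names`.
#' @export
build_graph <- function(table, split, cfg = graph_config()) {
  stopifnot(inherits(table, "embedding_table"))
  X <- table$vectors
  n <- nrow(X)
  train <- split$train_mask
  val <- split$val_mask %||% rep(FALSE, n)
  test <- split$test_mask %||% rep(FALSE, n)
  if (any(train & val) || any(train & test) || any(val & test)) {
    stopf("masks must be disjoint")
  }
  if (!all(train | val | test)) stopf("masks must cover every node")
  labelled <- train | val
  if (!any(labelled)) stopf("no labelled nodes")
  labels <- table$labels
  if (is.null(labels) || anyNA(labels[labelled])) {
    stopf("labels required on train/validation nodes")
  }
  # blind the graph to test labels by construction
  labels[test] <- NA
  es <- build_knn_edges(X, cfg, candidate_mask = labelled)
  if (any(test)) {
    es <- merge_edges(es, .attach_edges(X, which(labelled), which(test), cfg))
  }
  if (cfg$use_class_edges && cfg$class_edges_per_node > 0L) {
    es <- merge_edges(es, add_class_edges(labels, train, cfg))
  }
  es <- add_self_loops(es)
  structure(list(X = X, edges = es, A_norm = normalize_adjacency(es),
                 labels = factor(labels, levels = levels(table$labels)),
                 train_mask = train, val_mask = val, test_mask = test,
                 class_names = levels(table$labels), ids = table$ids),
            class = "graph_dataset")
}

# test-node attachment: plain top-k by cosine similarity, no threshold —
# at inference the reference design links each test sample to its k nearest
# training samples regardless of threshold or labels, so no test node is
# ever isolated (an isolated node would receive no message passing)
.attach_edges <- function(X, labelled_idx, test_idx, cfg) {
  S <- .cosine_matrix(X[test_idx, , drop = FALSE],
                      X[labelled_idx, , drop = FALSE])
  src <- integer(0); dst <- integer(0)
  k <- min(cfg$k, length(labelled_idx))
  for (ti in seq_along(test_idx)) {
    sims <- S[ti, ]
    sel <- order(-sims, labelled_idx)[seq_len(k)]
    src <- c(src, rep(test_idx[ti], k))
    dst <- c(dst, labelled_idx[sel])
  }
  symmetrize_edges(edge_set(src, dst, "knn", nrow(X)))
}

#' Attach unlabelled test nodes to a training graph
#'
#' Convenience wrapper combining a labelled training table and an unlabelled
#' test table into one transductive `graph_dataset`. Test labels, if
#' present, are ignored by construction.
#'
#' @param train_table labelled [embedding_table()].
#' @param test_table [embedding_table()] (labels ignored).
#' @param cfg a [graph_config()].
#' @return a `graph_dataset` (train mask = training rows, test mask = test
#'   rows).
#' @export
attach_test_nodes <- function(train_table, test_table, cfg = graph_config()) {
  stopifnot(inherits(train_table, "embedding_table"),
            inherits(test_table, "embedding_table"))
  if (is.null(train_table$labels) || anyNA(train_table$labels)) {
    stopf("training table must be fully labelled")
  }
  n_tr <- nrow(train_table$vectors)
  n_te <- nrow(test_table$vectors)
  combined <- embedding_table(
    rbind(train_table$vectors, test_table$vectors),
    ids = c(paste0("tr_", train_table$ids), paste0("te_", test_table$ids)),
    labels = c(as.character(train_table$labels), rep(NA, n_te)),
    class_names = levels(train_table$labels))
  build_graph(combined,
              list(train_mask = c(rep(TRUE, n_tr), rep(FALSE, n_te)),
                   val_mask = rep(FALSE, n_tr + n_te),
                   test_mask = c(rep(FALSE, n_tr), rep(TRUE, n_te))),
              cfg)
}

#' @export
print.graph_dataset <- function(x, ...) {
  cat(sprintf(
    "<graph_dataset> %d nodes (%d train / %d val / %d test), %d features\n",
    nrow(x$X), sum(x$train_mask), sum(x$val_mask), sum(x$test_mask),
    ncol(x$X)))
  print(x$edges)
  invisible(x)
}
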