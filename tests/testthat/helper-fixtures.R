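# Shared fixtures and independent oracles. Oracles are deliberately written
# as naive dense/loop implementations so they share no code path with the
# package internals they check.

# small labelled synthetic table for graph/GCN tests
tiny_table <- function(n_per_class = c(10L, 10L, 10L, 10L), dim = 16L,
                       noise_sd = 0.05, overlap = 0, seed = 11L) {
  sample_embeddings(synthetic_config(
    n_per_class = n_per_class, dim = dim, noise_sd = noise_sd,
    overlap_pairs = list(list(a = 1L, b = 2L, overlap = overlap)),
    seed = seed))
}

# dense brute-force oracle: thresholded cosine KNN + self-loops + symmetric
# normalization, all via explicit loops on a dense matrix
dense_graph_oracle <- function(X, k, tau) {
  n <- nrow(X)
  S <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    S[i, j] <- sum(X[i, ] * X[j, ]) /
      (sqrt(sum(X[i, ]^2)) * sqrt(sum(X[j, ]^2)))
  }
  A <- matrix(0, n, n)
  for (i in 1:n) {
    cand <- setdiff(1:n, i)
    cand <- cand[S[i, cand] > tau]
    if (length(cand)) {
      ord <- cand[order(-S[i, cand], cand)]
      sel <- ord[seq_len(min(k, length(ord)))]
      A[i, sel] <- 1
    }
  }
  A <- pmax(A, t(A))        # symmetrize
  diag(A) <- 1              # self-loops
  D <- rowSums(A)
  t(t(A / sqrt(D)) / sqrt(D))
}

# naive bilinear sampler for one output pixel (half-pixel centres, clamped)
bilinear_point_oracle <- function(plane, oy, ox, out_h, out_w) {
  H <- nrow(plane); W <- ncol(plane)
  yc <- (oy - 0.5) * H / out_h - 0.5
  xc <- (ox - 0.5) * W / out_w - 0.5
  y0 <- min(max(floor(yc), 0), H - 1); y1 <- min(y0 + 1, H - 1)
  x0 <- min(max(floor(xc), 0), W - 1); x1 <- min(x0 + 1, W - 1)
  wy <- min(max(yc - y0, 0), 1); wx <- min(max(xc - x0, 0), 1)
  (1 - wy) * (1 - wx) * plane[y0 + 1, x0 + 1] +
    (1 - wy) * wx * plane[y0 + 1, x1 + 1] +
    wy * (1 - wx) * plane[y1 + 1, x0 + 1] +
    wy * wx * plane[y1 + 1, x1 + 1]
}

# central finite differences of the masked cross-entropy wrt one weight
# matrix, probing every entry
numeric_gradient <- function(graph, params, which, mask, eps = 1e-5) {
  W <- params[[which]]
  out <- W * 0
  for (i in seq_along(W)) {
    pp <- params; pp[[which]][i] <- W[i] + eps
    lp <- cross_entropy(gcn_forward(graph, pp), graph$labels, mask)
    pm <- params; pm[[which]][i] <- W[i] - eps
    lm <- cross_entropy(gcn_forward(graph, pm), graph$labels, mask)
    out[i] <- (lp - lm) / (2 * eps)
  }
  out
}

# deterministic uniform image array in [0, 255]
toy_image <- function(h, w, seed = 3L) {
  with_seed(seed, array(runif(h * w * 3, 0, 255), c(h, w, 3)))
}
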