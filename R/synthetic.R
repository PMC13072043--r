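#' Synthetic embedding generator
#'
#' Emulates the statistical structure the graph pipeline assumes: four class
#' clusters of unit-norm prototype directions with isotropic Gaussian noise,
#' one pair of classes (glioma/meningioma by default) pulled closer together
#' to mimic their overlapping radiological appearance, and the no-tumour
#' cluster left well separated. Class proportions default to the training
#' distribution of the public brain-tumour MRI benchmark
#' (1321/1339/1457/1595), scaled to 400 samples.
#'
#' @name synthetic_data
NULL

#' Synthetic generator configuration
#'
#' @param n_per_class integer vector of 4 class sizes. Default
#'   `c(92, 94, 102, 112)` (benchmark training proportions scaled to 400 by
#'   largest remainder).
#' @param dim embedding dimension (2048 by convention; tests use 32).
#' @param prototype_separation pairwise angular distance (radians) between
#'   cluster prototypes; default `pi/3` (cosine 0.5).
#' @param overlap_pairs list of `list(a=, b=, overlap=)` entries; each pair
#'   of prototypes is interpolated toward its midpoint by `overlap` in
#'   `[0, 1]` (1 makes them identical). Default pulls classes 1 and 2
#'   (glioma, meningioma) together by 0.3.
#' @param noise_sd per-coordinate Gaussian noise sd (> 0); default 0.1.
#' @param class_names character vector of 4 class names.
#' @param seed integer RNG seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_per_class = c(92L, 94L, 102L, 112L),
                             dim = 2048L,
                             prototype_separation = pi / 3,
                             overlap_pairs = list(list(a = 1L, b = 2L,
                                                       overlap = 0.3)),
                             noise_sd = 0.1,
                             class_names = c("glioma", "meningioma",
                                             "pituitary", "notumor"),
                             seed = 42L) {
  if (length(n_per_class) != 4L || any(n_per_class < 1L)) {
    stopf("n_per_class must be 4 counts >= 1")
  }
  if (noise_sd <= 0) stopf("noise_sd must be > 0")
  if (prototype_separation < 0) stopf("prototype_separation must be >= 0")
  for (p in overlap_pairs) {
    if (p$overlap < 0 || p$overlap > 1) stopf("extra overlap must be in [0,1]")
    if (p$a == p$b || p$a > 4 || p$b > 4) stopf("invalid overlap pair")
  }
  structure(list(n_per_class = as.integer(n_per_class), dim = as.integer(dim),
                 prototype_separation = prototype_separation,
                 overlap_pairs = overlap_pairs, noise_sd = noise_sd,
                 class_names = class_names, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate the four class prototype vectors
#'
#' Builds four unit-norm vectors whose pairwise cosines all equal
#' `cos(prototype_separation)` (Gram-matrix square root mapped through a
#' seeded random orthonormal basis), then interpolates each `overlap_pairs`
#' entry toward its midpoint and renormalizes. Deterministic given the seed.
#'
#' @param cfg a [synthetic_config()].
#' @return 4 x dim matrix of unit-norm prototypes.
#' @export
generate_prototypes <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (cfg$dim < 4L) stopf("dim must be >= 4")
  rho <- cos(cfg$prototype_separation)
  if (rho <= -1 / 3) stopf("prototype_separation too large for 4 vectors")
  G <- matrix(rho, 4, 4); diag(G) <- 1
  eg <- eigen(G, symmetric = TRUE)
  S <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0))) %*% t(eg$vectors)
  Q <- with_seed(derive_seed(cfg$seed, 1L), {
    qr.Q(qr(matrix(stats::rnorm(cfg$dim * 4L), cfg$dim, 4L)))
  })
  P <- S %*% t(Q)  # 4 x dim, Gram(P) = G
  for (pair in cfg$overlap_pairs) {
    g <- pair$overlap / 2
    pa <- P[pair$a, ]; pb <- P[pair$b, ]
    na <- (1 - g) * pa + g * pb
    nb <- (1 - g) * pb + g * pa
    P[pair$a, ] <- na / sqrt(sum(na^2))
    P[pair$b, ] <- nb / sqrt(sum(nb^2))
  }
  rownames(P) <- cfg$class_names
  P
}

#' Sample a labelled synthetic embedding table
#'
#' Each class-`c` row is `prototype_c + N(0, noise_sd^2 I)`; class counts are
#' exactly `n_per_class` and rows are shuffled by a seeded permutation.
#'
#' @param cfg a [synthetic_config()].
#' @return an [embedding_table()] with labels.
#' @export
sample_embeddings <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  P <- generate_prototypes(cfg)
  n <- sum(cfg$n_per_class)
  with_seed(derive_seed(cfg$seed, 2L), {
    X <- matrix(NA_real_, n, cfg$dim)
    lab <- character(n)
    row <- 1L
    for (c in 1:4) {
      nc <- cfg$n_per_class[c]
      noise <- matrix(stats::rnorm(nc * cfg$dim, sd = cfg$noise_sd), nc,
                      cfg$dim)
      X[row:(row + nc - 1L), ] <- matrix(P[c, ], nc, cfg$dim,
                                         byrow = TRUE) + noise
      lab[row:(row + nc - 1L)] <- cfg$class_names[c]
      row <- row + nc
    }
    perm <- sample.int(n)
    embedding_table(X[perm, , drop = FALSE],
                    ids = sprintf("synth_%05d", seq_len(n)),
                    labels = lab[perm], class_names = cfg$class_names)
  })
}

# per-stratum integer allocation: floor + largest remainder, ties to the
# lower class index
.allocate <- function(counts, frac, total) {
  exact <- counts * frac
  base <- floor(exact)
  short <- total - sum(base)
  if (short > 0) {
    ord <- order(-(exact - base), seq_along(counts))
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  } else if (short < 0) {
    ord <- order(exact - base, seq_along(counts))
    take <- ord[base[ord] > 0][seq_len(-short)]
    base[take] <- base[take] - 1
  }
  as.integer(base)
}

#' Stratified train/validation/test split
#'
#' `test_fraction` applies to the full table; `val_fraction` to the post-test
#' remainder (the usual "validation split of the training data" convention).
#' Per-class counts are allocated by largest remainder so each stratum is
#' within one sample of the requested proportion; membership within a class
#' is a seeded random draw.
#'
#' @param labels factor/character labels for every row.
#' @param test_fraction,val_fraction fractions in (0, 1) with
#'   `test + val * (1 - test) < 1`.
#' @param seed integer seed.
#' @return list of logical vectors `train_mask`, `val_mask`, `test_mask`
#'   (disjoint, covering all rows).
#' @export
make_split <- function(labels, test_fraction = 0.2, val_fraction = 0.2,
                       seed = 42L) {
  labels <- factor(labels)
  if (anyNA(labels)) stopf("labels must be defined for every row")
  if (test_fraction <= 0 || test_fraction >= 1 ||
      val_fraction <= 0 || val_fraction >= 1) {
    stopf("fractions must lie in (0, 1)")
  }
  if (test_fraction + val_fraction >= 1) {
    stopf("test_fraction + val_fraction must leave a training remainder")
  }
  n <- length(labels)
  counts <- as.integer(table(labels))
  if (any(counts < 3L)) {
    stopf("stratification error: every class needs at least 3 samples")
  }
  n_test <- .allocate(counts, test_fraction, round(n * test_fraction))
  rem <- counts - n_test
  n_val <- .allocate(rem, val_fraction, round(sum(rem) * val_fraction))
  if (any(rem - n_val < 1L)) {
    stopf("stratification error: a class has no training samples left")
  }
  train <- val <- test <- logical(n)
  with_seed(derive_seed(seed, 3L), {
    for (c in seq_along(levels(labels))) {
      idx <- which(labels == levels(labels)[c])
      idx <- idx[sample.int(length(idx))]
      test[idx[seq_len(n_test[c])]] <- TRUE
      val[idx[n_test[c] + seq_len(n_val[c])]] <- TRUE
      train[idx[(n_test[c] + n_val[c] + 1L):length(idx)]] <- TRUE
    }
  })
  list(train_mask = train, val_mask = val, test_mask = test)
}
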