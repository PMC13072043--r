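#' Save an embedding table
#'
#' TSV layout: header `id<TAB>label<TAB>v1..vd`; values are written with 17
#' significant digits so a round trip reproduces doubles exactly. HDF5 layout
#' (requires the `rhdf5` package): datasets `vectors`, `ids`, `labels`.
#'
#' @param table an [embedding_table()].
#' @param path output file.
#' @param format `"tsv"` or `"hdf5"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
save_feature_table <- function(table, path, format = NULL) {
  stopifnot(inherits(table, "embedding_table"))
  format <- format %||% .guess_format(path)
  if (format == "tsv") {
    d <- ncol(table$vectors)
    labels <- if (is.null(table$labels)) rep(NA_character_,
                                             nrow(table$vectors))
              else as.character(table$labels)
    num <- matrix(sprintf("%.17g", table$vectors), nrow(table$vectors), d)
    lines <- c(
      paste(c("id", "label", paste0("v", seq_len(d))), collapse = "\t"),
      vapply(seq_len(nrow(num)), function(i) {
        paste(c(table$ids[i], labels[i], num[i, ]), collapse = "\t")
      }, character(1)))
    writeLines(lines, path)
  } else if (format == "hdf5") {
    .need_rhdf5()
    if (file.exists(path)) file.remove(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(table$vectors, path, "vectors")
    rhdf5::h5write(table$ids, path, "ids")
    if (!is.null(table$labels)) {
      rhdf5::h5write(as.character(table$labels), path, "labels")
      rhdf5::h5write(levels(table$labels), path, "class_names")
    }
    rhdf5::h5closeAll()
  } else stopf("unknown format '%s'", format)
  invisible(path)
}

#' Load an embedding table saved by [save_feature_table()]
#'
#' @param path input file.
#' @param format `"tsv"` or `"hdf5"`; default guessed from the extension.
#' @param class_names optional label vocabulary; unknown labels error.
#' @return an [embedding_table()].
#' @export
load_feature_table <- function(path, format = NULL, class_names = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  format <- format %||% .guess_format(path)
  if (format == "tsv") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) < 2L) stopf("empty feature table: %s", path)
    header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    d <- length(header) - 2L
    if (d < 1L) stopf("malformed feature table header")
    cells <- strsplit(lines[-1], "\t", fixed = TRUE)
    nfield <- lengths(cells)
    if (any(nfield != length(header))) {
      stopf("ragged rows in %s (expected %d fields, found %s)", path,
            length(header), paste(unique(nfield[nfield != length(header)]),
                                  collapse = "/"))
    }
    m <- do.call(rbind, cells)
    vec <- suppressWarnings(matrix(as.numeric(m[, -(1:2), drop = FALSE]),
                                   nrow(m), d))
    if (any(is.na(vec))) stopf("non-numeric cell in feature columns of %s",
                               path)
    labels <- m[, 2]
    labels[labels == "NA"] <- NA
    if (all(is.na(labels))) labels <- NULL
    embedding_table(vec, ids = m[, 1], labels = labels,
                    class_names = class_names)
  } else if (format == "hdf5") {
    .need_rhdf5()
    ls <- rhdf5::h5ls(path)$name
    vec <- rhdf5::h5read(path, "vectors")
    ids <- as.character(rhdf5::h5read(path, "ids"))
    labels <- if ("labels" %in% ls) as.character(rhdf5::h5read(path, "labels"))
              else NULL
    if (is.null(class_names) && "class_names" %in% ls) {
      class_names <- as.character(rhdf5::h5read(path, "class_names"))
    }
    rhdf5::h5closeAll()
    embedding_table(vec, ids = ids, labels = labels,
                    class_names = class_names)
  } else stopf("unknown format '%s'", format)
}

.guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("h5", "hdf5")) "hdf5" else "tsv"
}

.need_rhdf5 <- function() {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    stopf("HDF5 feature tables require the 'rhdf5' package; use format='tsv'")
  }
}

#' Export an edge set as TSV (0-based indices)
#'
#' Columns `src`, `dst`, `provenance`.
#' @param edges an [edge_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edges <- function(edges, path) {
  df <- as.data.frame(edges)
  df$src <- df$src - 1L
  df$dst <- df$dst - 1L
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a sparse adjacency in coordinate text format (0-based)
#'
#' Columns `i`, `j`, `value`, one nonzero per line.
#' @param A a sparse `Matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(A, path) {
  tri <- Matrix::summary(methods::as(A, "TsparseMatrix"))
  df <- data.frame(i = tri$i - 1L, j = tri$j - 1L,
                   value = sprintf("%.17g", tri$x))
  df <- df[order(df$i, df$j), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Save / load a GCN checkpoint (single JSON file)
#'
#' Stores the three weight matrices, the architecture and dropout settings,
#' the init seed and an optional graph-config fingerprint at full precision.
#'
#' @param params a `gcn_params` object.
#' @param path output file.
#' @param graph_fingerprint optional [config_hash()] of the graph config.
#' @return `path` (save) or `gcn_params` (load).
#' @export
save_checkpoint <- function(params, path, graph_fingerprint = NULL) {
  stopifnot(inherits(params, "gcn_params"))
  obj <- list(W0 = params$W0, W1 = params$W1, W2 = params$W2,
              hidden_dim = params$hidden_dim, n_classes = params$n_classes,
              dropout_p = params$dropout_p, init_seed = params$init_seed,
              graph_fingerprint = graph_fingerprint)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- list(W0 = as.matrix(obj$W0), W1 = as.matrix(obj$W1),
            W2 = as.matrix(obj$W2),
            hidden_dim = as.integer(obj$hidden_dim),
            n_classes = as.integer(obj$n_classes),
            dropout_p = obj$dropout_p,
            init_seed = as.integer(obj$init_seed))
  class(p) <- "gcn_params"
  p
}
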