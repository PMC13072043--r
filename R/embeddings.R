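#' Embedding tables and the image-to-embedding front end
#'
#' Images enter the pipeline as `H x W x 3` arrays with pixel values in
#' `[0, 255]`, are standardized to the 299 x 299 RGB resolution expected by
#' the InceptionV3 backbone family, and are mapped to fixed-length feature
#' vectors (2048-d by convention) by a pluggable backbone. Everything
#' downstream consumes only the resulting embedding table, so precomputed or
#' synthetic embeddings can replace the image path entirely.
#'
#' @name embeddings
NULL

#' Construct an embedding table
#'
#' The central container: an `N x d` matrix of per-image feature vectors plus
#' image identifiers and (optionally) class labels.
#'
#' @param vectors numeric matrix, one row per image.
#' @param ids character vector of unique image identifiers (default
#'   `img_000001`, ...).
#' @param labels optional factor/character vector of class labels, `NA`
#'   allowed (e.g. for unlabeled test images).
#' @param class_names optional character vector fixing the label levels.
#' @return an object of class `embedding_table` with elements `vectors`,
#'   `ids`, `labels`.
#' @export
embedding_table <- function(vectors, ids = NULL, labels = NULL,
                            class_names = NULL) {
  vectors <- as.matrix(vectors)
  storage.mode(vectors) <- "double"
  if (nrow(vectors) < 1L) stopf("embedding table must have at least one row")
  if (any(!is.finite(vectors))) {
    stopf("embedding vectors contain NaN/Inf entries")
  }
  if (is.null(ids)) ids <- sprintf("img_%06d", seq_len(nrow(vectors)))
  ids <- as.character(ids)
  if (length(ids) != nrow(vectors)) stopf("ids must align 1:1 with rows")
  if (anyDuplicated(ids)) stopf("image ids must be unique")
  if (!is.null(labels)) {
    if (length(labels) != nrow(vectors)) {
      stopf("labels must align 1:1 with rows")
    }
    labels <- if (is.null(class_names)) factor(labels) else {
      bad <- setdiff(unique(as.character(labels[!is.na(labels)])), class_names)
      if (length(bad)) stopf("unknown label(s): %s", paste(bad, collapse = ", "))
      factor(labels, levels = class_names)
    }
  }
  structure(list(vectors = vectors, ids = ids, labels = labels),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> %d images x %d features\n",
              nrow(x$vectors), ncol(x$vectors)))
  if (!is.null(x$labels)) {
    tab <- table(x$labels, useNA = "ifany")
    cat("labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
dim.embedding_table <- function(x) dim(x$vectors)

#' Bilinear resize of an image array
#'
#' Half-pixel-centre convention (the default of mainstream image stacks),
#' clamped at the borders.
#'
#' @param img numeric array `H x W x C` (or `H x W` matrix).
#' @param out_h,out_w target spatial dimensions.
#' @return resized array.
#' @export
bilinear_resize <- function(img, out_h, out_w) {
  if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
  d <- dim(img)
  if (d[1] < 1L || d[2] < 1L) stopf("zero-sized image")
  sy <- d[1] / out_h
  sx <- d[2] / out_w
  # source coordinates of output pixel centres
  yc <- (seq_len(out_h) - 0.5) * sy - 0.5
  xc <- (seq_len(out_w) - 0.5) * sx - 0.5
  y0 <- pmin(pmax(floor(yc), 0), d[1] - 1)
  x0 <- pmin(pmax(floor(xc), 0), d[2] - 1)
  y1 <- pmin(y0 + 1, d[1] - 1)
  x1 <- pmin(x0 + 1, d[2] - 1)
  wy <- pmin(pmax(yc - y0, 0), 1)
  wx <- pmin(pmax(xc - x0, 0), 1)
  out <- array(0, c(out_h, out_w, d[3]))
  for (ch in seq_len(d[3])) {
    plane <- img[, , ch]
    a <- plane[cbind(rep(y0 + 1, out_w), rep(x0 + 1, each = out_h))]
    b <- plane[cbind(rep(y0 + 1, out_w), rep(x1 + 1, each = out_h))]
    cc <- plane[cbind(rep(y1 + 1, out_w), rep(x0 + 1, each = out_h))]
    dd <- plane[cbind(rep(y1 + 1, out_w), rep(x1 + 1, each = out_h))]
    wyr <- rep(wy, out_w)
    wxr <- rep(wx, each = out_h)
    v <- (1 - wyr) * (1 - wxr) * a + (1 - wyr) * wxr * b +
      wyr * (1 - wxr) * cc + wyr * wxr * dd
    out[, , ch] <- matrix(v, out_h, out_w)
  }
  out
}

#' Standardize a raw image for the backbone
#'
#' Reorders channels to RGB, bilinearly resizes to 299 x 299 and applies the
#' backbone normalization map. The default (`"inception"`) is the linear map
#' of `[0, 255]` onto `[-1, 1]` used by the InceptionV3 family; the
#' alternative `"imagenet"` convention divides by 255 then standardizes each
#' channel by the usual ImageNet means/sds.
#'
#' Already-standardized inputs (flagged by [preprocess_image()] itself) are
#' returned unchanged, making the operation idempotent.
#'
#' @param img `H x W x 3` numeric array with values in `[0, 255]`, or the
#'   result of a previous call.
#' @param channel_order `"RGB"` or `"BGR"` describing the input ordering.
#' @param normalization `"inception"` (default) or `"imagenet"`.
#' @param source_id optional identifier carried along as an attribute.
#' @return 299 x 299 x 3 array with attribute `standardized = TRUE`.
#' @export
preprocess_image <- function(img, channel_order = c("RGB", "BGR"),
                             normalization = c("inception", "imagenet"),
                             source_id = NULL) {
  if (isTRUE(attr(img, "standardized"))) return(img)
  channel_order <- match.arg(channel_order)
  normalization <- match.arg(normalization)
  if (length(dim(img)) != 3L || dim(img)[3] != 3L) {
    stopf("expected a 3-channel H x W x 3 image, got dims [%s]",
          paste(dim(img), collapse = ", "))
  }
  if (dim(img)[1] < 1L || dim(img)[2] < 1L) stopf("zero-sized image")
  img <- img * 1.0
  if (channel_order == "BGR") img <- img[, , c(3L, 2L, 1L), drop = FALSE]
  out <- bilinear_resize(img, 299L, 299L)
  if (normalization == "inception") {
    out <- out / 127.5 - 1
  } else {
    mu <- c(0.485, 0.456, 0.406)
    sd <- c(0.229, 0.224, 0.225)
    for (ch in 1:3) out[, , ch] <- (out[, , ch] / 255 - mu[ch]) / sd[ch]
  }
  attr(out, "standardized") <- TRUE
  if (!is.null(source_id)) attr(out, "source_id") <- source_id
  out
}

#' Define a feature-extraction backbone
#'
#' The backbone is a contract, not a bundled network: any function mapping a
#' list of standardized 299 x 299 x 3 arrays to an `N x output_dim` matrix
#' qualifies. The InceptionV3-with-global-average-pooling extractor of the
#' reference pipeline is one such adapter (requiring the user's own weights);
#' the fixtures below keep the package download-free.
#'
#' @param embed function `list of images -> N x output_dim matrix`.
#' @param output_dim positive integer embedding dimension.
#' @param name optional label.
#' @return object of class `backbone`.
#' @export
backbone <- function(embed, output_dim, name = "custom") {
  stopifnot(is.function(embed), output_dim >= 1)
  structure(list(embed = embed, output_dim = as.integer(output_dim),
                 name = name), class = "backbone")
}

# 12 rotation-free summary statistics of one standardized image
.image_stats <- function(img) {
  unlist(lapply(1:3, function(ch) {
    v <- as.vector(img[, , ch])
    c(mean(v), stats::sd(v), stats::quantile(v, c(0.25, 0.75), names = FALSE))
  }))
}

#' Deterministic fixture backbone: random projection of pixel statistics
#'
#' Computes 12 per-channel summary statistics per image and multiplies by a
#' fixed seeded Gaussian projection to `output_dim` dimensions. Deterministic
#' for a fixed seed; used throughout the test-suite in place of a pretrained
#' CNN.
#'
#' @param output_dim embedding dimension (default 2048).
#' @param seed projection seed.
#' @return a [backbone()].
#' @export
projection_backbone <- function(output_dim = 2048L, seed = 1L) {
  proj <- with_seed(seed, matrix(stats::rnorm(12 * output_dim), 12, output_dim))
  backbone(function(imgs) {
    stats <- t(vapply(imgs, .image_stats, numeric(12)))
    stats %*% proj
  }, output_dim, name = sprintf("projection(seed=%d)", seed))
}

#' Trivial fixture backbone: per-channel means
#' @return a 3-d [backbone()] whose embedding is the per-channel mean.
#' @export
channel_mean_backbone <- function() {
  backbone(function(imgs) {
    t(vapply(imgs, function(im) vapply(1:3, function(ch) mean(im[, , ch]),
                                       numeric(1)), numeric(3)))
  }, 3L, name = "channel_mean")
}

#' Extract embeddings from standardized images
#'
#' Applies the backbone batch-wise. Images that fail validation or whose
#' embedding is non-finite are skipped with a warning (quality-control
#' contract) and excluded from the table; row order otherwise follows input
#' order.
#'
#' @param imgs list of standardized images ([preprocess_image()] output).
#' @param bb a [backbone()].
#' @param ids optional identifiers (defaults to attributes or positions).
#' @param labels optional labels aligned with `imgs`.
#' @param batch_size images per backbone call (progress is reported per
#'   batch via `message`).
#' @return an [embedding_table()].
#' @export
extract_embeddings <- function(imgs, bb, ids = NULL, labels = NULL,
                               batch_size = 32L) {
  if (!inherits(bb, "backbone")) stopf("`bb` must be a backbone()")
  if (length(imgs) == 0L) stopf("no input images: empty table")
  if (is.null(ids)) {
    ids <- vapply(seq_along(imgs), function(i) {
      attr(imgs[[i]], "source_id") %||% sprintf("img_%06d", i)
    }, character(1))
  }
  ok <- rep(TRUE, length(imgs))
  for (i in seq_along(imgs)) {
    im <- imgs[[i]]
    valid <- is.array(im) && length(dim(im)) == 3L &&
      all(dim(im) == c(299L, 299L, 3L)) && all(is.finite(im))
    if (!valid) {
      warnf("skipping unreadable/corrupt image '%s'", ids[i])
      ok[i] <- FALSE
    }
  }
  keep <- which(ok)
  if (!length(keep)) stopf("no valid images after quality control")
  n <- length(keep)
  out <- matrix(NA_real_, n, bb$output_dim)
  starts <- seq(1L, n, by = batch_size)
  for (s in starts) {
    idx <- s:min(s + batch_size - 1L, n)
    emb <- bb$embed(imgs[keep[idx]])
    if (!is.matrix(emb) || ncol(emb) != bb$output_dim ||
        nrow(emb) != length(idx)) {
      stopf("backbone contract violation: expected %d x %d output",
            length(idx), bb$output_dim)
    }
    out[idx, ] <- emb
    message(sprintf("embedded %d/%d images", max(idx), n))
  }
  embedding_table(out, ids = ids[keep],
                  labels = if (is.null(labels)) NULL else labels[keep])
}

#' Read one PNG/JPEG image as a raw `H x W x 3` array in `[0, 255]`
#'
#' Requires the `png`/`jpeg` packages; greyscale images are replicated to 3
#' channels.
#'
#' @param path image file.
#' @return numeric array with attribute `source_id`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = {
      if (!requireNamespace("png", quietly = TRUE)) {
        stopf("reading PNG requires the 'png' package")
      }
      png::readPNG(path)
    },
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE)) {
        stopf("reading JPEG requires the 'jpeg' package")
      }
      jpeg::readJPEG(path)
    },
    stopf("unsupported image format '%s'", ext)
  )
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]  # drop alpha
  px <- px * 255
  attr(px, "source_id") <- basename(path)
  px
}

#' Embed a class-labelled image directory
#'
#' Expects the `<root>/<class>/image.png` layout; every image is
#' preprocessed and embedded.
#'
#' @param root directory whose sub-directories are class names.
#' @param bb a [backbone()].
#' @param channel_order,normalization passed to [preprocess_image()].
#' @return an [embedding_table()] with labels from directory names.
#' @export
embed_image_dir <- function(root, bb, channel_order = "RGB",
                            normalization = "inception") {
  classes <- list.dirs(root, recursive = FALSE, full.names = FALSE)
  if (!length(classes)) stopf("no class sub-directories under %s", root)
  files <- character(0); labels <- character(0)
  for (cl in classes) {
    f <- list.files(file.path(root, cl), pattern = "\\.(png|jpe?g)$",
                    ignore.case = TRUE, full.names = TRUE)
    files <- c(files, f)
    labels <- c(labels, rep(cl, length(f)))
  }
  imgs <- lapply(files, function(p) {
    tryCatch(preprocess_image(read_image(p), channel_order = channel_order,
                              normalization = normalization,
                              source_id = basename(p)),
             error = function(e) structure(NA, source_id = basename(p)))
  })
  extract_embeddings(imgs, bb, ids = basename(files), labels = labels)
}
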