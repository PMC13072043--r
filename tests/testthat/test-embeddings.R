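test_that("preprocess_image standardizes, swaps channels and normalizes", {
  # upper bound of the [-1, 1] map
  white <- array(255, c(299, 299, 3))
  out <- preprocess_image(white)
  expect_equal(dim(out), c(299, 299, 3))
  expect_true(all(out == 1))

  # BGR input: blue plane must land in channel 3 at +1, red plane at -1
  bgr <- array(0, c(10, 10, 3))
  bgr[, , 1] <- 255  # blue first in BGR ordering
  out <- preprocess_image(bgr, channel_order = "BGR")
  expect_lt(max(abs(out[, , 1] + 1)), 1e-12)  # R plane at -1
  expect_lt(max(abs(out[, , 3] - 1)), 1e-12)  # B plane at +1

  # idempotence via the standardized flag
  expect_identical(preprocess_image(out), out)

  # error contracts
  expect_error(preprocess_image(array(1, c(5, 5, 1))), "3-channel")
  expect_error(preprocess_image(array(1, c(0, 5, 3))), "zero-sized")
})

test_that("bilinear resize matches an independent per-pixel oracle", {
  checker <- outer(1:600, 1:600, function(i, j) ((i %/% 25) + (j %/% 25)) %% 2)
  img <- array(rep(checker * 255, 3), c(600, 600, 3))
  out <- bilinear_resize(img, 299, 299)
  probes <- rbind(c(1, 1), c(1, 299), c(299, 1), c(299, 299),
                  with_seed(5, cbind(sample(299, 25, TRUE),
                                     sample(299, 25, TRUE))))
  for (r in seq_len(nrow(probes))) {
    expect_equal(out[probes[r, 1], probes[r, 2], 2],
                 bilinear_point_oracle(checker * 255, probes[r, 1],
                                       probes[r, 2], 299, 299),
                 tolerance = 1e-12)
  }
})

test_that("extract_embeddings honours the backbone contract and skips", {
  imgs <- lapply(1:3, function(i) preprocess_image(toy_image(20, 20, i)))
  bb <- channel_mean_backbone()
  tab <- suppressMessages(extract_embeddings(imgs, bb))
  expect_equal(dim(tab$vectors), c(3L, 3L))
  # fixture definition: row i equals per-channel means of image i
  expect_equal(tab$vectors[2, ],
               vapply(1:3, function(ch) mean(imgs[[2]][, , ch]), numeric(1)),
               tolerance = 1e-12)

  # one corrupt image: skipped with a warning, 2 rows survive in order
  imgs2 <- list(imgs[[1]], structure(NA, source_id = "bad"), imgs[[3]])
  expect_warning(tab2 <- suppressMessages(extract_embeddings(imgs2, bb)),
                 "corrupt")
  expect_equal(nrow(tab2$vectors), 2L)
  expect_equal(tab2$vectors[1, ], tab$vectors[1, ])
  expect_equal(tab2$vectors[2, ], tab$vectors[3, ])

  # constant backbone: all rows identical
  const_bb <- backbone(function(l) matrix(7, length(l), 2), 2L)
  tab3 <- suppressMessages(extract_embeddings(imgs, const_bb))
  expect_true(all(tab3$vectors == 7))

  expect_error(suppressMessages(extract_embeddings(list(), bb)), "empty")
  bad_bb <- backbone(function(l) matrix(0, length(l), 5), 3L)
  expect_error(suppressMessages(extract_embeddings(imgs, bad_bb)),
               "contract")
})

test_that("projection backbone is deterministic and dimension-true", {
  imgs <- lapply(1:2, function(i) preprocess_image(toy_image(15, 18, i)))
  bb <- projection_backbone(32L, seed = 9L)
  e1 <- suppressMessages(extract_embeddings(imgs, bb))
  e2 <- suppressMessages(extract_embeddings(imgs, projection_backbone(32L, 9L)))
  expect_identical(e1$vectors, e2$vectors)
  expect_equal(ncol(e1$vectors), 32L)
})

test_that("feature tables round-trip through tsv and hdf5", {
  tab <- embedding_table(matrix(c(pi, exp(1), 1/3, 2/7, 1e-300, 123456.789,
                                  -4.5e-7, 0, 1, 2, 3, 4), 3, 4),
                         ids = c("a", "b", "c"),
                         labels = c("glioma", NA, "notumor"),
                         class_names = c("glioma", "meningioma",
                                         "pituitary", "notumor"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  save_feature_table(tab, tsv)
  back <- load_feature_table(tsv, class_names = levels(tab$labels))
  expect_identical(back$vectors, tab$vectors)  # %.17g is exact for doubles
  expect_identical(back$ids, tab$ids)
  expect_identical(as.character(back$labels), as.character(tab$labels))

  h5 <- withr::local_tempfile(fileext = ".h5")
  save_feature_table(tab, h5)
  back5 <- load_feature_table(h5)
  expect_identical(back5$vectors, tab$vectors)
  expect_identical(levels(back5$labels), levels(tab$labels))

  # malformed inputs
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tlabel\tv1\tv2", "a\tglioma\t1.0\toops"), bad)
  expect_error(load_feature_table(bad), "non-numeric")
  writeLines(c("id\tlabel\tv1\tv2", "a\tglioma\t1.0"), bad)
  expect_error(load_feature_table(bad), "ragged")
  writeLines(character(0), bad)
  expect_error(load_feature_table(bad), "empty")
})

test_that("embedding_table enforces its invariants", {
  expect_error(embedding_table(matrix(c(1, NaN), 1, 2)), "NaN")
  expect_error(embedding_table(matrix(1, 2, 2), ids = c("x", "x")), "unique")
  expect_error(embedding_table(matrix(1, 2, 2), labels = c("a", "zzz"),
                               class_names = c("a", "b")), "unknown label")
})
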