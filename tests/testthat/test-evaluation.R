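# Metric oracles and evaluation artifacts.

test_that("confusion matches hand tallies", {
  expect_equal(confusion(c(1, 2, 3), c(1, 2, 3), 3), diag(c(1L, 1L, 1L)))
  cm <- confusion(c(1, 1, 2), c(1, 2, 2), 3)
  expect_equal(cm[1, 1], 1L); expect_equal(cm[1, 2], 1L)
  expect_equal(cm[2, 2], 1L); expect_equal(sum(cm), 3L)
  expect_error(confusion(c(1, 4), c(1, 1), 3))
  expect_error(confusion(c(1, 2), c(1), 3))
})

test_that("confusion row sums equal true-class frequencies (random oracle)", {
  set.seed(51)
  for (i in 1:20) {
    n_class <- sample(c(3, 6), 1)
    true <- sample(n_class, 50, replace = TRUE)
    pred <- sample(n_class, 50, replace = TRUE)
    cm <- confusion(true, pred, n_class)
    expect_equal(rowSums(cm), as.numeric(tabulate(true, n_class)))
    expect_equal(colSums(cm), as.numeric(tabulate(pred, n_class)))
  }
})

test_that("normalize_rows yields row-stochastic matrices with zero-row convention", {
  expect_equal(normalize_rows(matrix(c(5, 0, 0, 5), 2, byrow = TRUE)),
               diag(2))
  expect_equal(normalize_rows(matrix(c(1, 1, 0, 0), 2, byrow = TRUE)),
               matrix(c(0.5, 0.5, 0, 0), 2, byrow = TRUE))
  set.seed(52)
  m <- matrix(sample(0:9, 36, TRUE), 6)
  rs <- rowSums(normalize_rows(m))
  expect_true(all(abs(rs[rowSums(m) > 0] - 1) < 1e-12))
})

test_that("metrics match closed-form and brute-force values", {
  # TP=8, FP=2, FN=8 for class 1
  cm <- matrix(c(8, 2, 0, 8, 0, 0, 0, 0, 0), 3)  # column-major
  r <- metrics(cm)
  expect_equal(r$precision[1], 0.8)
  expect_equal(r$recall[1], 0.5)
  expect_equal(r$f_score[1], 2 * 0.8 * 0.5 / 1.3)
  # perfect diagonal
  p <- metrics(diag(c(3, 4, 5)))
  expect_equal(p$accuracy, 1)
  expect_equal(p$precision, rep(1, 3))
  expect_equal(p$f_score, rep(1, 3))
  # hand-filled 3x3
  cm2 <- matrix(c(5, 1, 0,
                  2, 6, 1,
                  0, 1, 4), 3, byrow = TRUE)
  r2 <- metrics(cm2)
  expect_equal(r2$accuracy, 15 / 20)
  expect_equal(r2$precision[2], 6 / (6 + 1 + 1))
  expect_equal(r2$recall[2], 6 / 9)
})

test_that("metrics against brute-force tallies on 100 random label vectors", {
  set.seed(53)
  for (i in 1:100) {
    n_class <- sample(c(3, 6), 1)
    n <- sample(20:60, 1)
    true <- sample(n_class, n, replace = TRUE)
    pred <- sample(n_class, n, replace = TRUE)
    cm <- confusion(true, pred, n_class)
    r <- metrics(cm)
    expect_equal(r$accuracy, mean(true == pred))
    for (c in seq_len(n_class)) {
      tp <- sum(true == c & pred == c)
      fp <- sum(true != c & pred == c)
      fn <- sum(true == c & pred != c)
      expect_equal(r$precision[c], if (tp + fp == 0) 0 else tp / (tp + fp))
      expect_equal(r$recall[c], if (tp + fn == 0) 0 else tp / (tp + fn))
    }
    # micro-consistency
    expect_equal(sum(diag(cm)), sum(true == pred))
  }
})

test_that("metrics(confusion(x, x)) is all ones", {
  set.seed(54)
  x <- sample(3, 30, replace = TRUE)
  r <- metrics(confusion(x, x, 3))
  expect_equal(r$accuracy, 1)
  expect_equal(r$recall, rep(1, 3))
})

test_that("label_matrix stacks rows, exports CSV and a color raster", {
  labs <- list(c(1, 1, 2, 3, 3), c(1, 2, 2, 3, 3))
  lm <- label_matrix(labs, 3)
  expect_equal(dim(lm), c(2, 5))
  csv <- file.path(tempdir(), "lm.csv"); png <- file.path(tempdir(), "lm.png")
  on.exit(unlink(c(csv, png)), add = TRUE)
  label_matrix(labs, 3, csv = csv, png = png, scale = 2)
  back <- as.matrix(utils::read.csv(csv, header = FALSE))
  dimnames(back) <- NULL
  expect_equal(back, lm)
  img <- png::readPNG(png)
  expect_equal(dim(img), c(4, 10, 3))
  # every class maps to a distinct color
  pal6 <- apply(grDevices::col2rgb(mitostage:::stage_palette(6)), 2,
                paste, collapse = ",")
  expect_equal(length(unique(pal6)), 6)
  expect_error(label_matrix(list(c(1, 2), c(1, 2, 3)), 3))
})

test_that("embed_pca orders components and handles rank deficiency", {
  set.seed(55)
  x <- cbind(rnorm(50, sd = 5), rnorm(50, sd = 2), rnorm(50, sd = 0.3),
             rnorm(50, sd = 0.1))
  pr <- embed_pca(x, labels = rep(1:2, 25))
  expect_equal(ncol(pr$scores), 3)
  expect_true(all(diff(pr$explained_variance) <= 1e-12))
  # axis-aligned data: PC1 recovers the highest-variance axis up to sign
  expect_gt(abs(cor(pr$scores[, 1], x[, 1])), 0.95)
  # rank-2 data: PC3 variance ~ 0
  y2 <- cbind(rnorm(30), rnorm(30))
  y <- cbind(y2, y2 %*% matrix(c(1, 2, -1, 0.5), 2))
  pr2 <- embed_pca(y)
  expect_lt(pr2$explained_variance[3], 1e-10)
  expect_error(embed_pca(x[1:3, ]))
  expect_error(embed_pca(x[, 1:2]))
})

test_that("segmentation threshold and IoU behave on trivial cases", {
  tr <- array(0.9, c(4, 4, 3))
  expect_equal(segment_by_threshold(tr, 0.5), matrix(1, 4, 4))
  expect_equal(segment_by_threshold(array(0.1, c(4, 4, 3)), 0.5),
               matrix(0, 4, 4))
  expect_error(segment_by_threshold(tr, 1.2))
  a <- matrix(c(1, 1, 0, 0), 2); b <- matrix(c(1, 0, 1, 0), 2)
  expect_equal(mask_iou(a, a), 1)
  expect_equal(mask_iou(a, b), 1 / 3)
  expect_equal(mask_iou(a * 0, a * 0), 1)
  expect_error(mask_iou(a, matrix(0, 3, 3)))
})

test_that("embedding silhouette rewards separated classes", {
  set.seed(56)
  sep <- rbind(matrix(rnorm(60, 0), 20), matrix(rnorm(60, 8), 20))
  mixed <- matrix(rnorm(120), 40)
  labs <- rep(1:2, each = 20)
  expect_gt(embedding_silhouette(sep, labs), 0.7)
  expect_gt(embedding_silhouette(sep, labs),
            embedding_silhouette(mixed, labs))
  expect_error(embedding_silhouette(sep, rep(1, 40)))
})

test_that("evaluate_model pools frames across sequences", {
  cfg <- sim_config("three_class", frame_size = 64, sequence_length = 6,
                    seed = 1)
  seqs <- lapply(1:2, function(i) generate_sequence(cfg, seed = 60 + i))
  m <- build_base_model(frame_spec(64), base_spec(conv_channels = c(4L, 4L, 8L),
                                                  decoder_channels = c(4L, 4L, 3L),
                                                  head_filters = 8L,
                                                  fc_hidden = 8L),
                        3L, seed = 61)
  ev <- evaluate_model(m, seqs)
  expect_equal(sum(ev$confusion), 12)
  expect_equal(ev$metrics$accuracy,
               mean(unlist(ev$predictions) == unlist(ev$true)))
})
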