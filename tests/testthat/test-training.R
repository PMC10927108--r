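# Relabel/remap protocol, augmentation, learning-rate schedule, and the
# training loop plumbing.

test_that("relabel_recovery matches hand-computed outputs", {
  # post-mitosis starts at frame 7; K = 3 keeps frames 7-9, relabels 10-12
  lab <- c(1, 1, 1, 2, 2, 2, 3, 3, 3, 3, 3, 3)
  expect_equal(relabel_recovery(lab, 3), c(1, 1, 1, 2, 2, 2, 3, 3, 3, 1, 1, 1))
  # K larger than the post-mitotic run: unchanged
  expect_equal(relabel_recovery(lab, 10), lab)
  # no post-mitosis: unchanged
  expect_equal(relabel_recovery(c(1, 1, 2, 2), 2), c(1, 1, 2, 2))
  # K = 0 relabels the whole run
  expect_equal(relabel_recovery(c(2, 3, 3), 0), c(2, 1, 1))
  expect_error(relabel_recovery(c(3, 2, 1), 2))
  expect_error(relabel_recovery(c(1, 2, 4), 2))
})

test_that("remap_predictions matches hand-computed outputs", {
  # trailing interphase after the last mitosis becomes post-mitosis
  expect_equal(remap_predictions(c(1, 1, 2, 2, 3, 1, 1)),
               c(1, 1, 2, 2, 3, 3, 3))
  # interphase between mitosis runs is also after-last-mitosis only
  expect_equal(remap_predictions(c(1, 2, 1, 2, 1)), c(1, 2, 1, 2, 3))
  # no mitosis predicted: unchanged
  expect_equal(remap_predictions(c(1, 1, 1)), c(1, 1, 1))
  # non-interphase predictions after mitosis are untouched
  expect_equal(remap_predictions(c(2, 3, 1, 3)), c(2, 3, 3, 3))
})

test_that("relabel -> remap round-trip restores monotone labels", {
  set.seed(41)
  for (i in 1:200) {
    d1 <- sample(1:10, 1); d2 <- sample(1:6, 1); d3 <- sample(1:12, 1)
    lab <- rep(1:3, c(d1, d2, d3))
    K <- sample(0:14, 1)
    rel <- relabel_recovery(lab, K)
    # a perfect predictor of the relabeled stream, remapped, recovers the
    # original annotation
    expect_equal(remap_predictions(rel), lab)
  }
})

test_that("lr schedule drops by the factor every lr_drop_iteration steps", {
  cfg <- train_config("base", optimizer = "sgd")  # lr 0.01
  expect_equal(lr_at(0, cfg), 0.01)
  expect_equal(lr_at(2499, cfg), 0.01)
  expect_equal(lr_at(2500, cfg), 0.001)
  expect_equal(lr_at(5000, cfg), 1e-4)
})

test_that("train_config defaults follow the reference table per model kind", {
  te <- train_config("time_encoded")
  expect_equal(te$optimizer, "adam")
  expect_equal(te$batch, 4L); expect_equal(te$lr, 0.001)
  expect_equal(te$lambda_wt, 0.1)
  # SGD keeps the reference learning rates: 0.01 for the from-scratch base
  # model, 0.001 otherwise
  bs <- train_config("base", optimizer = "sgd")
  expect_equal(bs$lr, 0.01); expect_equal(bs$lambda_wt, 0.01)
  expect_equal(train_config("time_encoded", optimizer = "sgd")$lr, 0.001)
  expect_equal(train_config("base")$lr, 0.001)
  fc <- train_config("frame_classifier")
  expect_equal(fc$batch, 64L); expect_equal(fc$lr, 0.001)
  expect_equal(te$lr_drop_iteration, 2500L)
  expect_equal(te$train_test_ratio, 0.85)
})

test_that("augmentation applies one shared transform to frames and masks", {
  cfg <- sim_config("three_class", frame_size = 64, sequence_length = 12,
                    seed = 1)
  s <- generate_sequence(cfg, seed = 7)
  a <- augment_sequence(s, seed = 99)
  tf <- attr(a, "transform")
  expect_true(tf$k %in% 0:3 && tf$flip %in% c("none", "h", "v"))
  expect_identical(a$labels, s$labels)
  # frames and masks undergo the same transform: masked intensities invariant
  for (t in c(1, 6, 12)) {
    expect_equal(sort(a$frames[, , t][a$masks[, , t] > 0]),
                 sort(s$frames[, , t][s$masks[, , t] > 0]))
    expect_equal(sum(a$masks[, , t]), sum(s$masks[, , t]))
  }
  # deterministic given the seed
  b <- augment_sequence(s, seed = 99)
  expect_identical(a$frames, b$frames)
})

test_that("identity transform leaves the sequence unchanged", {
  cfg <- sim_config("three_class", frame_size = 64, sequence_length = 8,
                    seed = 1)
  s <- generate_sequence(cfg, seed = 8)
  a <- augment_sequence(s, k = 0, flip = "none")
  expect_equal(a$frames, s$frames)
})

test_that("a short recurrent training run reduces the total loss", {
  cfg <- sim_config("three_class", frame_size = 64, sequence_length = 8,
                    seed = 1)
  data <- generate_dataset(5, cfg, seed = 11)
  m <- build_base_model(frame_spec(64), base_spec(conv_channels = c(4L, 8L, 8L),
                                                  decoder_channels = c(8L, 4L, 3L),
                                                  head_filters = 8L,
                                                  fc_hidden = 8L),
                        3L, seed = 11)
  tc <- train_config("base", epochs = 3, relabel_k = 3, seed = 11,
                     augment = FALSE)
  tr <- train_model(m, data, tc)
  h <- tr$history
  expect_equal(nrow(h), 3 * 1)  # 4 train seqs, batch 4 -> 1 iter/epoch
  expect_lt(h$l_tot[nrow(h)], h$l_tot[1])
  expect_equal(nrow(tr$validation), 3)
  # trained parameters moved
  expect_false(identical(tr$model$params$head$fc2$W, m$params$head$fc2$W))
})

test_that("frame classifier training runs and logs per-iteration history", {
  cfg <- sim_config("three_class", frame_size = 64, sequence_length = 6,
                    seed = 1)
  data <- generate_dataset(4, cfg, seed = 12)
  m <- build_frame_classifier(frame_spec(64),
                              backbone_spec(stage_channels = c(4L, 8L, 16L, 32L)),
                              3L, seed = 12)
  tc <- train_config("frame_classifier", batch = 18, epochs = 2, seed = 12)
  tr <- train_model(m, data, tc)
  expect_equal(nrow(tr$history), 2)  # 3 seqs x 6 frames = 18 images -> 1 iter
  expect_true(all(is.finite(tr$history$l_cls)))
})

test_that("training is deterministic under a fixed seed", {
  cfg <- sim_config("three_class", frame_size = 64, sequence_length = 6,
                    seed = 1)
  data <- generate_dataset(4, cfg, seed = 13)
  mk <- function() build_base_model(frame_spec(64),
                                    base_spec(conv_channels = c(4L, 4L, 8L),
                                              decoder_channels = c(4L, 4L, 3L),
                                              head_filters = 8L, fc_hidden = 8L),
                                    3L, seed = 13)
  tc <- train_config("base", epochs = 1, seed = 13)
  a <- train_model(mk(), data, tc)
  b <- train_model(mk(), data, tc)
  expect_identical(a$history, b$history)
  expect_identical(a$model$params, b$model$params)
})

test_that("predict_sequence returns per-frame labels with remapping", {
  m <- build_base_model(frame_spec(32), base_spec(conv_channels = c(4L, 4L, 8L),
                                                  decoder_channels = c(4L, 4L, 3L),
                                                  head_filters = 8L,
                                                  fc_hidden = 8L),
                        3L, seed = 14)
  frames <- lapply(1:5, function(t) matrix(runif(32 * 32, 0, 255), 32, 32))
  p <- predict_sequence(m, frames)
  expect_length(p, 5)
  expect_true(all(p %in% 1:3))
  expect_identical(p, remap_predictions(predict_sequence(m, frames,
                                                         remap = FALSE)))
})
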