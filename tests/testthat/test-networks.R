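# Shape contracts and structural properties of the three model families.

test_that("reduced time-encoded model maps 64x64 to the contracted shapes", {
  m <- build_time_encoded_model(frame_spec(64), reduced_backbone_spec(), 3L,
                                seed = 1)
  frames <- lapply(1:2, function(t) matrix(runif(64 * 64, 0, 255), 64, 64))
  out <- forward_sequence(m, frames)
  expect_equal(dim(out$features[[1]]), c(2, 2, 64))      # 64 / 32 = 2
  expect_equal(dim(out$tracks[[1]]), c(64, 64, 3))       # full resolution
  expect_equal(dim(out$scores), c(2, 3))
  expect_true(all(out$scores >= 0 & out$scores <= 1))
  expect_true(all(out$tracks[[1]] >= 0 & out$tracks[[1]] <= 1))
})

test_that("x32 arithmetic holds over randomized valid reduced specs", {
  set.seed(21)
  for (i in 1:4) {
    c1 <- sample(c(4L, 8L), 1)
    sc <- c1 * c(1L, 2L, 4L, 8L)
    hw <- 32L * sample(2:4, 1)
    m <- build_time_encoded_model(frame_spec(hw),
                                  backbone_spec(stage_channels = sc),
                                  n_class = 3L, seed = i)
    out <- forward_sequence(m, list(matrix(runif(hw * hw, 0, 255), hw, hw)))
    expect_equal(dim(out$features[[1]]), c(hw / 32, hw / 32, sc[4]))
    expect_equal(dim(out$tracks[[1]]), c(hw, hw, 3))
  }
})

test_that("full-scale spec maps 3x224x224 to 512x7x7 features and 3x224x224 tracks", {
  m <- build_time_encoded_model(frame_spec(224), backbone_spec(), 3L, seed = 2)
  out <- forward_sequence(m, list(matrix(runif(224 * 224, 0, 255), 224, 224)))
  expect_equal(dim(out$features[[1]]), c(7, 7, 512))
  expect_equal(dim(out$tracks[[1]]), c(224, 224, 3))
  # decoder channel plan 256/128/64/3, head conv 1024 filters
  expect_equal(dim(m$params$dec$t1$W)[3], 256)
  expect_equal(dim(m$params$dec$t4$W)[3], 3)
  expect_equal(dim(m$params$head$conv$W)[4], 1024)
})

test_that("invalid frame/backbone combinations are rejected", {
  expect_error(build_time_encoded_model(frame_spec(60), reduced_backbone_spec()))
  expect_error(build_time_encoded_model(frame_spec(32), reduced_backbone_spec()))
  expect_error(backbone_spec(stage_channels = c(8L, 16L, 32L, 64L),
                             gru_channels = c(8L, 16L, 32L)))
})

test_that("frame classifier output is independent of frame order", {
  m <- build_frame_classifier(frame_spec(64), reduced_backbone_spec(), 3L,
                              seed = 3)
  set.seed(22)
  f1 <- matrix(runif(64 * 64, 0, 255), 64, 64)
  f2 <- matrix(runif(64 * 64, 0, 255), 64, 64)
  a <- forward_sequence(m, list(f1, f2))
  b <- forward_sequence(m, list(f2, f1))
  expect_equal(a$scores[1, ], b$scores[2, ], tolerance = 1e-12)
  expect_null(a$tracks)
})

test_that("recurrent model output depends on history; classifier's does not", {
  cfg <- sim_config("three_class", frame_size = 64, sequence_length = 20,
                    seed = 1)
  s <- generate_sequence(cfg, seed = 31)
  te <- build_time_encoded_model(frame_spec(64), reduced_backbone_spec(), 3L,
                                 seed = 4)
  t_last <- dim(s$frames)[3]
  full <- forward_sequence(te, s)
  only_last <- forward_sequence(te, list(s$frames[, , t_last]))
  expect_gt(max(abs(full$scores[t_last, ] - only_last$scores[1, ])), 1e-8)
})

test_that("base model respects its x8 downscale and three GRU scales", {
  m <- build_base_model(frame_spec(64), base_spec(), 3L, seed = 5)
  out <- forward_sequence(m, list(matrix(runif(64 * 64, 0, 255), 64, 64)))
  expect_equal(dim(out$features[[1]]), c(8, 8, 64))
  expect_equal(dim(out$tracks[[1]]), c(64, 64, 3))
  expect_true(all(c("gru1", "gru2", "gru3") %in% names(m$params)))
})

test_that("weight initialisation is seeded and reproducible", {
  a <- build_time_encoded_model(frame_spec(64), reduced_backbone_spec(), 3L,
                                seed = 9)
  b <- build_time_encoded_model(frame_spec(64), reduced_backbone_spec(), 3L,
                                seed = 9)
  expect_identical(a$params$head$fc2$W, b$params$head$fc2$W)
})

test_that("model checkpoints round-trip", {
  m <- build_base_model(frame_spec(32), base_spec(), 3L, seed = 6)
  path <- file.path(tempdir(), "ckpt.rds")
  on.exit(unlink(c(path, paste0(path, ".json"))), add = TRUE)
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m$params, m2$params)
  expect_true(file.exists(paste0(path, ".json")))
  fr <- list(matrix(runif(32 * 32, 0, 255), 32, 32))
  expect_equal(forward_sequence(m, fr)$scores, forward_sequence(m2, fr)$scores)
})
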