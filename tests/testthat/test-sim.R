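# Synthetic mitosis time-lapse generator.

cfg3 <- sim_config("three_class", frame_size = 64, sequence_length = 30,
                   seed = 1)
cfg6 <- sim_config("six_class", frame_size = 64, sequence_length = 20,
                   seed = 1)

test_that("generation is deterministic under a fixed seed", {
  a <- generate_sequence(cfg3, seed = 5)
  b <- generate_sequence(cfg3, seed = 5)
  expect_identical(a$frames, b$frames)
  expect_identical(a$labels, b$labels)
  c <- generate_sequence(cfg3, seed = 6)
  expect_false(identical(a$frames, c$frames))
})

test_that("frames are 8-bit gray levels of the configured size", {
  s <- generate_sequence(cfg3, seed = 2)
  expect_equal(dim(s$frames), c(64, 64, 30))
  expect_true(all(s$frames >= 0 & s$frames <= 255))
  expect_true(all(s$frames == round(s$frames)))
})

test_that("three-class labels are monotone 1 -> 2 -> 3 and cover all stages", {
  for (seed in 1:8) {
    s <- generate_sequence(cfg3, seed = seed)
    expect_true(all(diff(s$labels) >= 0))
    expect_setequal(unique(s$labels), 1:3)
  }
})

test_that("six-class labels are monotone and cover all six stages", {
  for (seed in 1:5) {
    s <- generate_sequence(cfg6, seed = seed)
    expect_true(all(diff(s$labels) >= 0))
    expect_setequal(unique(s$labels), 1:6)
  }
})

test_that("center-cell mask is non-empty and disjoint from distractors", {
  for (seed in 1:5) {
    s <- generate_sequence(cfg3, seed = seed)
    for (t in seq_len(dim(s$frames)[3])) {
      expect_gt(sum(s$masks[, , t]), 0)
      expect_equal(sum(s$masks[, , t] & s$distractors[, , t]), 0)
    }
  }
})

test_that("schedule durations fall in the configured ranges and sum to length", {
  for (seed in 1:10) {
    sc <- sample_schedule(cfg3, seed = seed)
    expect_equal(sum(sc$durations), cfg3$sequence_length)
    expect_equal(length(sc$labels), cfg3$sequence_length)
    rr <- cfg3$stage_duration_ranges
    expect_true(sc$durations[2] >= rr$mitosis[1] &&
                sc$durations[2] <= rr$mitosis[2])
  }
})

test_that("recovered post-mitotic frames resemble interphase more than mitosis", {
  # the deliberate ambiguity: late post-mitotic frames decondense back toward
  # interphase appearance, so their masked mean intensity drops to near the
  # interphase level and away from the bright condensed mitotic level
  s <- generate_sequence(cfg3, seed = 9)
  stage <- vapply(seq_len(30), function(t) {
    mean(s$frames[, , t][s$masks[, , t] > 0])
  }, numeric(1))
  inter <- mean(stage[s$labels == 1])
  mito <- mean(stage[s$labels == 2])
  last_post <- max(which(s$labels == 3))
  expect_lt(abs(stage[last_post] - inter), abs(stage[last_post] - mito))
})

test_that("dataset split is disjoint and respects the ratio", {
  d <- generate_dataset(10, cfg3, seed = 3, ratio = 0.85)
  expect_s3_class(d, "mitosis_split")
  expect_equal(length(d$train), round(0.85 * 10))
  expect_equal(length(d$train) + length(d$test), 10)
  # disjointness: no train frame stack equals a test frame stack
  for (tr in d$train) for (te in d$test) {
    expect_false(identical(tr$frames, te$frames))
  }
})

test_that("write/read dataset round-trips frames, masks and labels", {
  dir <- file.path(tempdir(), "ds_roundtrip")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  # 8 sequences -> 7 train / 1 test, so both splits are non-empty
  d <- generate_dataset(8, cfg3, seed = 4)
  write_dataset(d, dir)
  d2 <- read_dataset(dir)
  expect_equal(length(d2$train), length(d$train))
  expect_equal(d2$train[[1]]$frames, d$train[[1]]$frames)
  expect_equal(d2$train[[1]]$labels, d$train[[1]]$labels)
  expect_equal(d2$test[[1]]$masks * 1, d$test[[1]]$masks * 1)
})

test_that("render_frame exposes per-frame image, mask and distractor layers", {
  sc <- sample_schedule(cfg3, seed = 5)
  f <- render_frame(sc, 10, cfg3, seed = 5)
  expect_equal(dim(f$image), c(64, 64))
  expect_true(all(f$mask %in% c(0, 1)))
  expect_true(all(f$image >= 0 & f$image <= 255))
})

test_that("config validation", {
  expect_error(sim_config("three_class", frame_size = 16))
  expect_error(generate_dataset(1, cfg3))
})
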