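# Synthetic single-cell mitosis time-lapse generator. Sequences emulate the
# structure the classifier assumes: a fixed stage order, stage-dependent
# nuclear morphology (decondensed ellipse -> condensation -> metaphase plate
# -> two separating masses -> decondensing daughters -> recovery toward
# interphase appearance), a centered tracked cell plus off-center distractor
# nuclei, and additive Gaussian imaging noise. Rendering is
# parametric-geometric, not physics-based: it creates stage-separable
# appearance plus the deliberate ambiguity between interphase and recovered
# post-mitotic frames that only temporal context can resolve.

default_duration_ranges <- function(mode, sequence_length) {
  if (mode == "three_class") {
    base <- list(interphase = c(25, 35), mitosis = c(12, 20),
                 post_mitosis = c(40, 50))
    f <- sequence_length / 90
  } else {
    base <- list(interphase = c(8, 14), prophase = c(3, 6),
                 prometaphase = c(4, 7), metaphase = c(5, 9),
                 anaphase = c(3, 5), telophase = c(6, 10))
    f <- sequence_length / 40
  }
  lapply(base, function(r) pmax(1L, as.integer(round(r * f))))
}

#' Configuration of the synthetic mitosis generator
#'
#' @param mode `"three_class"` (interphase, mitosis, post-mitosis; the
#'   90-frame regime) or `"six_class"` (interphase plus the five mitotic
#'   phases; the 40-frame regime).
#' @param frame_size square frame edge in pixels (>= 32), default 96.
#' @param sequence_length frames per sequence; defaults to 90 (three-class)
#'   or 40 (six-class).
#' @param stage_duration_ranges named list of integer `c(min, max)` frame
#'   ranges per stage; defaults scale the canonical regimes to
#'   `sequence_length`. The interphase run absorbs the rounding so durations
#'   always sum to `sequence_length`.
#' @param n_distractors integer range `c(min, max)` of off-center distractor
#'   nuclei per sequence.
#' @param noise_sd Gaussian image noise standard deviation in gray levels.
#' @param recovery_onset integer range: frames after the start of the
#'   post-mitotic run at which the tracked daughter regains interphase-like
#'   appearance; default scales the 15--20 frame onset of the 90-frame regime
#'   proportionally (three-class mode only).
#' @param seed optional integer seed stored with the config.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(mode = c("three_class", "six_class"),
                       frame_size = 96L,
                       sequence_length = NULL,
                       stage_duration_ranges = NULL,
                       n_distractors = c(2L, 4L),
                       noise_sd = 8,
                       recovery_onset = NULL,
                       seed = NULL) {
  mode <- match.arg(mode)
  if (frame_size < 32) stop("sim_config: frame_size must be >= 32")
  if (is.null(sequence_length)) {
    sequence_length <- if (mode == "three_class") 90L else 40L
  }
  sequence_length <- as.integer(sequence_length)
  if (is.null(stage_duration_ranges)) {
    stage_duration_ranges <- default_duration_ranges(mode, sequence_length)
  }
  if (any(vapply(stage_duration_ranges, function(r) r[2] < r[1] || r[1] < 1,
                 logical(1)))) {
    stop("sim_config: every stage duration range must be non-empty")
  }
  if (sequence_length < sum(vapply(stage_duration_ranges, `[`, numeric(1), 1))) {
    stop("sim_config: sequence_length smaller than the sum of minimum stage durations")
  }
  if (is.null(recovery_onset)) {
    recovery_onset <- pmax(3L, as.integer(round(c(15, 20) * sequence_length / 90)))
  }
  if (length(n_distractors) == 1) n_distractors <- rep(n_distractors, 2)
  structure(
    list(mode = mode, frame_size = as.integer(frame_size),
         sequence_length = sequence_length,
         stage_duration_ranges = stage_duration_ranges,
         n_distractors = as.integer(n_distractors),
         noise_sd = noise_sd,
         recovery_onset = as.integer(recovery_onset),
         seed = seed),
    class = "sim_config")
}

n_stages <- function(config) if (config$mode == "three_class") 3L else 6L

#' Sample a per-frame stage schedule
#'
#' Stage durations are drawn uniformly from the configured ranges; the
#' interphase run is then adjusted so the total equals `sequence_length`
#' (shrinking later stages toward their minima only if required). Stages
#' always appear in the fixed biological order, each as one contiguous run,
#' so the label vector is non-decreasing.
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return an object of class `stage_schedule` with element `labels`.
#' @export
sample_schedule <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  rng <- config$stage_duration_ranges
  L <- config$sequence_length
  with_seed(seed, {
    mins <- vapply(rng, `[`, numeric(1), 1)
    durs <- vapply(rng, function(r) {
      if (r[1] == r[2]) r[1] else sample(seq.int(r[1], r[2]), 1)
    }, numeric(1))
    others <- durs[-1]
    excess <- sum(others) + mins[1] - L
    while (excess > 0) {
      i <- which.max(others - mins[-1])
      if (others[i] <= mins[-1][i]) break
      take <- min(excess, others[i] - mins[-1][i])
      others[i] <- others[i] - take
      excess <- excess - take
    }
    durs[-1] <- others
    durs[1] <- L - sum(others)
    labels <- rep.int(seq_along(durs), durs)
    structure(list(labels = as.integer(labels),
                   durations = as.integer(durs),
                   mode = config$mode),
              class = "stage_schedule")
  })
}

# --- rendering -------------------------------------------------------------

# Map a frame of a schedule to a morphological phase plus progress in (0, 1].
# `onset` is the recovery onset in frames after the post-mitotic run start.
phase_at <- function(schedule, t, onset) {
  lab <- schedule$labels
  l <- lab[t]
  run_start <- min(which(lab == l))
  idx <- t - run_start + 1L
  len <- sum(lab == l)
  prog <- idx / len
  if (schedule$mode == "six_class") {
    phase <- c("interphase", "prophase", "prometaphase", "metaphase",
               "anaphase", "telophase")[l]
    return(list(phase = phase, prog = prog, idx = idx))
  }
  if (l == 1L) return(list(phase = "interphase", prog = prog, idx = idx))
  if (l == 2L) {
    b1 <- ceiling(0.3 * len); b2 <- ceiling(0.6 * len)
    if (idx <= b1) return(list(phase = "prophase", prog = idx / max(1, b1), idx = idx))
    if (idx <= b2) return(list(phase = "prometaphase", prog = (idx - b1) / max(1, b2 - b1), idx = idx))
    return(list(phase = "metaphase", prog = (idx - b2) / max(1, len - b2), idx = idx))
  }
  n_ana <- min(2L, len)
  n_tel <- min(3L, max(0L, len - n_ana))
  if (idx <= n_ana) return(list(phase = "anaphase", prog = idx / n_ana, idx = idx))
  if (idx <= n_ana + n_tel) {
    return(list(phase = "telophase", prog = (idx - n_ana) / n_tel, idx = idx))
  }
  if (idx >= onset) return(list(phase = "recovered", prog = 1, idx = idx))
  q <- (idx - n_ana - n_tel) / max(1, onset - n_ana - n_tel)
  list(phase = "post_recovering", prog = min(1, q), idx = idx)
}

# Soft-edged rotated ellipse: returns intensity weight in [0, 1] and the
# hard footprint (normalised radius <= 1).
ellipse_field <- function(grid, cx, cy, a, b, theta) {
  xr <- (grid$X - cx) * cos(theta) + (grid$Y - cy) * sin(theta)
  yr <- -(grid$X - cx) * sin(theta) + (grid$Y - cy) * cos(theta)
  d <- sqrt((xr / a)^2 + (yr / b)^2)
  w <- pmin(1, pmax(0, (1.05 - d) / 0.15))
  list(w = w, mask = d <= 1, xr = xr, yr = yr)
}

cell_texture <- function(ef, tex) {
  1 + tex$amp * sin(tex$w1 * ef$xr + tex$p1) * sin(tex$w2 * ef$yr + tex$p2)
}

# Static per-sequence scene: cell geometry, texture phases, division axis,
# recovery onset, distractor layout. Everything random is drawn here so that
# frames are a deterministic function of (scene, t) plus per-frame noise.
make_scene <- function(config, seed = NULL) {
  n <- config$frame_size
  with_seed(seed, {
    k <- if (config$n_distractors[1] == config$n_distractors[2]) {
      config$n_distractors[1]
    } else {
      sample(seq.int(config$n_distractors[1], config$n_distractors[2]), 1)
    }
    distr <- if (k > 0) lapply(seq_len(k), function(i) {
      ang <- runif(1, 0, 2 * pi)
      dist <- runif(1, 0.46 * n, 0.62 * n)
      list(cx = (n + 1) / 2 + dist * cos(ang),
           cy = (n + 1) / 2 + dist * sin(ang),
           a = 0.11 * n * runif(1, 0.8, 1.1),
           b = 0.085 * n * runif(1, 0.8, 1.1),
           theta = runif(1, 0, pi),
           intensity = runif(1, 140, 175),
           vx = runif(1, -0.06, 0.06), vy = runif(1, -0.06, 0.06),
           tex = list(amp = 0.12, w1 = runif(1, 0.15, 0.35),
                      w2 = runif(1, 0.15, 0.35),
                      p1 = runif(1, 0, 2 * pi), p2 = runif(1, 0, 2 * pi)))
    }) else list()
    list(
      n = n, cx = (n + 1) / 2, cy = (n + 1) / 2,
      a0 = 0.16 * n * runif(1, 0.9, 1.1),
      b0 = 0.12 * n * runif(1, 0.9, 1.1),
      theta0 = runif(1, 0, pi),
      tex = list(amp = 0.15, w1 = runif(1, 0.15, 0.35),
                 w2 = runif(1, 0.15, 0.35),
                 p1 = runif(1, 0, 2 * pi), p2 = runif(1, 0, 2 * pi)),
      speckles = list(u = runif(6, -0.6, 0.6), v = runif(6, -0.6, 0.6),
                      amp = runif(6, 60, 90)),
      theta_div = runif(1, 0, pi),
      track_side = sample(c(-1, 1), 1),
      onset = if (config$recovery_onset[1] == config$recovery_onset[2]) {
        config$recovery_onset[1]
      } else {
        sample(seq.int(config$recovery_onset[1], config$recovery_onset[2]), 1)
      },
      distractors = distr,
      noise_seed = sample.int(2147483000L, 1))
  })
}

# Intensity field + footprint of the tracked cell for one phase.
draw_center_cell <- function(scene, grid, ph) {
  n <- scene$n; cx <- scene$cx; cy <- scene$cy
  blob <- function(cxx, cyy, a, b, theta, I, tex_amp = 0.05, speck = FALSE,
                   tex = scene$tex) {
    ef <- ellipse_field(grid, cxx, cyy, a, b, theta)
    txx <- tex; txx$amp <- tex_amp
    f <- I * ef$w * cell_texture(ef, txx)
    if (speck) {
      for (i in seq_along(scene$speckles$u)) {
        sx <- cxx + scene$speckles$u[i] * a * cos(theta) -
                    scene$speckles$v[i] * b * sin(theta)
        sy <- cyy + scene$speckles$u[i] * a * sin(theta) +
                    scene$speckles$v[i] * b * cos(theta)
        bump <- scene$speckles$amp[i] *
          exp(-(((grid$X - sx)^2 + (grid$Y - sy)^2) / (2 * (0.045 * n)^2)))
        f <- f + bump * ef$mask
      }
    }
    list(f = f, mask = ef$mask)
  }
  interph <- function() blob(cx, cy, scene$a0, scene$b0, scene$theta0, 160,
                             tex_amp = scene$tex$amp)
  dirx <- cos(scene$theta_div); diry <- sin(scene$theta_div)
  sep_max <- 0.12 * n
  two <- function(sep, a, b, I, sister_extra = 0, track_off = NULL,
                  mask_both = TRUE, decond = 0) {
    s <- scene$track_side
    # tracked daughter position (possibly re-centered), sister moves away
    tx <- if (is.null(track_off)) s * sep * dirx else track_off * s * sep_max * dirx
    ty <- if (is.null(track_off)) s * sep * diry else track_off * s * sep_max * diry
    sx <- -s * (sep + sister_extra) * dirx
    sy <- -s * (sep + sister_extra) * diry
    at <- a + decond * (scene$a0 - a); bt <- b + decond * (scene$b0 - b)
    It <- I + decond * (160 - I)
    amp <- 0.05 + decond * (scene$tex$amp - 0.05)
    b1 <- blob(cx + tx, cy + ty, at, bt, scene$theta0, It, tex_amp = amp)
    b2 <- blob(cx + sx, cy + sy, a, b, scene$theta_div + pi / 2, I)
    m <- if (mask_both) b1$mask | b2$mask else b1$mask
    list(f = pmax(b1$f, b2$f), mask = m,
         sister = if (mask_both) NULL else b2$mask)
  }
  switch(ph$phase,
    interphase = ,
    recovered = interph(),
    prophase = blob(cx, cy, scene$a0 * 0.95, scene$b0 * 0.95, scene$theta0,
                    150, tex_amp = 0.18, speck = TRUE),
    prometaphase = blob(cx, cy, 0.09 * n, 0.085 * n, scene$theta0, 215),
    metaphase = blob(cx, cy, 0.115 * n, 0.045 * n, scene$theta_div + pi / 2, 230),
    anaphase = two(sep = ph$prog * sep_max, a = 0.07 * n, b = 0.06 * n,
                   I = 215, mask_both = TRUE),
    telophase = two(sep = sep_max, a = 0.075 * n, b = 0.065 * n, I = 190,
                    sister_extra = ph$prog * 0.18 * n,
                    track_off = max(0, 1 - ph$prog), mask_both = FALSE,
                    decond = if (identical(ph$mode6, TRUE)) ph$decond else 0),
    post_recovering = two(sep = sep_max, a = 0.075 * n, b = 0.065 * n,
                          I = 190, sister_extra = 0.18 * n, track_off = 0,
                          mask_both = FALSE, decond = ph$prog),
    stop("unknown phase"))
}

render_frame_scene <- function(scene, schedule, t, config, add_noise = TRUE) {
  n <- scene$n
  grid <- list(X = matrix(rep(seq_len(n), times = n), n, n),
               Y = matrix(rep(seq_len(n), each = n), n, n))
  ph <- phase_at(schedule, t, scene$onset)
  if (schedule$mode == "six_class" && ph$phase == "telophase") {
    # recenter over the first frames, then decondense toward interphase
    len_idx <- ph$idx
    ph$mode6 <- TRUE
    ph$decond <- max(0, min(1, (len_idx - 3) / 5))
    ph$prog <- min(1, len_idx / 3)
  }
  cc <- draw_center_cell(scene, grid, ph)
  img <- matrix(15, n, n)  # constant background level
  img <- pmax(img, cc$f)
  clutter <- matrix(FALSE, n, n)
  for (d in scene$distractors) {
    ef <- ellipse_field(grid, d$cx + d$vx * (t - 1), d$cy + d$vy * (t - 1),
                        d$a, d$b, d$theta)
    img <- pmax(img, d$intensity * ef$w * cell_texture(ef, d$tex))
    clutter <- clutter | ef$mask
  }
  sister <- if (!is.null(cc$sister)) cc$sister else matrix(FALSE, n, n)
  if (add_noise && config$noise_sd > 0) {
    img <- img + with_seed(derive_seed(scene$noise_seed, t),
                           matrix(rnorm(n * n, sd = config$noise_sd), n, n))
  }
  img <- round(pmin(pmax(img, 0), 255))
  list(image = img, mask = cc$mask, distractors = clutter, sister = sister)
}

#' Render one frame of a synthetic mitosis sequence
#'
#' Renders the tracked center cell with the morphology of the stage active at
#' frame `t` (soft-textured decondensed ellipse in interphase, condensed
#' speckles in prophase, compact blob in prometaphase, elongated plate in
#' metaphase, two separating masses in anaphase, a re-centering daughter in
#' telophase, decondensation back to interphase appearance after the recovery
#' onset), plus off-center distractor nuclei and Gaussian noise. The mask
#' covers only the tracked cell, never distractors.
#'
#' @param schedule a [sample_schedule()] result.
#' @param t frame index in `1..sequence_length`.
#' @param config the [sim_config()] used for the schedule.
#' @param seed integer seed fixing the scene (cell geometry, distractor
#'   layout) and the frame noise.
#' @param scene optional precomputed scene (internal use).
#' @return list with `image` (frame_size x frame_size matrix, integer gray
#'   levels 0--255), `mask` (logical matrix, tracked cell footprint) and
#'   `distractors` (logical matrix, union of distractor footprints).
#' @export
render_frame <- function(schedule, t, config, seed = NULL, scene = NULL) {
  stopifnot(inherits(schedule, "stage_schedule"))
  if (t < 1 || t > length(schedule$labels)) {
    stop("render_frame: frame index out of range")
  }
  if (is.null(scene)) scene <- make_scene(config, seed)
  render_frame_scene(scene, schedule, t, config)
}

#' Generate one synthetic cell sequence
#'
#' @param config a [sim_config()].
#' @param seed integer seed; the full sequence (schedule, scene, noise) is a
#'   deterministic function of `(config, seed)`.
#' @return an object of class `cell_sequence`: `frames` and `masks` arrays of
#'   dim `(frame_size, frame_size, T)`, `distractors` array, per-frame
#'   `labels`, and `meta` (config echo plus seed).
#' @export
generate_sequence <- function(config, seed = NULL) {
  schedule <- sample_schedule(config, seed = if (is.null(seed)) NULL else derive_seed(seed, 1L))
  scene <- make_scene(config, seed = if (is.null(seed)) NULL else derive_seed(seed, 2L))
  n <- config$frame_size
  Tn <- config$sequence_length
  frames <- array(0, c(n, n, Tn))
  masks <- array(FALSE, c(n, n, Tn))
  distr <- array(FALSE, c(n, n, Tn))
  for (t in seq_len(Tn)) {
    fr <- render_frame_scene(scene, schedule, t, config)
    frames[, , t] <- fr$image
    masks[, , t] <- fr$mask
    distr[, , t] <- fr$distractors
  }
  structure(list(frames = frames, masks = masks, distractors = distr,
                 labels = schedule$labels, schedule = schedule,
                 meta = list(config = config, seed = seed,
                             recovery_onset = scene$onset)),
            class = "cell_sequence")
}

#' Generate a reproducible train/test dataset of synthetic sequences
#'
#' Sequences are independently seeded from the master seed by a counter-based
#' scheme, so the dataset is a deterministic function of
#' `(n_sequences, config, seed)`.
#'
#' @param n_sequences number of sequences (>= 2).
#' @param config a [sim_config()].
#' @param seed master integer seed.
#' @param ratio train fraction; `round(ratio * n_sequences)` sequences go to
#'   the training split, the rest to the disjoint test split.
#' @return an object of class `mitosis_split` with elements `train`, `test`,
#'   `ratio`.
#' @export
generate_dataset <- function(n_sequences, config, seed = 1L, ratio = 0.85) {
  if (n_sequences < 2) stop("generate_dataset: n_sequences must be >= 2")
  seqs <- lapply(seq_len(n_sequences), function(i) {
    generate_sequence(config, seed = derive_seed(seed, 100L + i))
  })
  ord <- with_seed(derive_seed(seed, 99L), sample.int(n_sequences))
  ntrain <- round(ratio * n_sequences)
  structure(list(train = seqs[ord[seq_len(ntrain)]],
                 test = seqs[ord[setdiff(seq_len(n_sequences), seq_len(ntrain))]],
                 ratio = ratio,
                 config = config, seed = seed),
            class = "mitosis_split")
}

#' @export
print.mitosis_split <- function(x, ...) {
  cat(sprintf("mitosis_split: %d train / %d test sequences (%s, %dx%d px, %d frames)\n",
              length(x$train), length(x$test), x$config$mode,
              x$config$frame_size, x$config$frame_size,
              x$config$sequence_length))
  invisible(x)
}

# --- directory layout reader/writer ---------------------------------------

#' Write one sequence to a directory
#'
#' Layout: `frames/` and `masks/` as numbered 8-bit grayscale PNGs,
#' `labels.csv` (frame_index, stage_label) and `meta.json`.
#'
#' @param s a `cell_sequence`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_sequence <- function(s, dir) {
  dir.create(file.path(dir, "frames"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  Tn <- dim(s$frames)[3]
  for (t in seq_len(Tn)) {
    png::writePNG(s$frames[, , t] / 255,
                  file.path(dir, "frames", sprintf("f%04d.png", t)))
    png::writePNG(s$masks[, , t] * 1,
                  file.path(dir, "masks", sprintf("m%04d.png", t)))
  }
  write.csv(data.frame(frame_index = seq_len(Tn), stage_label = s$labels),
            file.path(dir, "labels.csv"), row.names = FALSE)
  meta <- s$meta
  if (!is.null(meta$config)) meta$config <- unclass(meta$config)
  meta$config$stage_duration_ranges <- lapply(meta$config$stage_duration_ranges, as.integer)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read one sequence from a directory written by [write_sequence()]
#'
#' @param dir sequence directory.
#' @return a `cell_sequence`.
#' @export
read_sequence <- function(dir) {
  ff <- sort(list.files(file.path(dir, "frames"), full.names = TRUE))
  mf <- sort(list.files(file.path(dir, "masks"), full.names = TRUE))
  frames <- sapply(ff, function(p) round(png::readPNG(p) * 255), simplify = "array")
  masks <- sapply(mf, function(p) png::readPNG(p) > 0.5, simplify = "array")
  dimnames(frames) <- NULL
  dimnames(masks) <- NULL
  lab <- read.csv(file.path(dir, "labels.csv"))
  meta <- if (file.exists(file.path(dir, "meta.json"))) {
    jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  } else list()
  structure(list(frames = frames, masks = masks,
                 labels = as.integer(lab$stage_label), meta = meta),
            class = "cell_sequence")
}

#' Write a dataset to a directory of images, labels and metadata
#'
#' One directory per sequence: `frames/` as numbered 8-bit grayscale PNGs,
#' `masks/` as a parallel PNG set, `labels.csv` (frame_index, stage_label)
#' and `meta.json`. A `mitosis_split` is written under `train/` and `test/`
#' subdirectories. Any user-supplied real data in the same layout is accepted
#' by [read_dataset()].
#'
#' @param x a `mitosis_split` or a list of `cell_sequence` objects.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_dataset <- function(x, dir) {
  if (inherits(x, "mitosis_split")) {
    for (split in c("train", "test")) {
      for (i in seq_along(x[[split]])) {
        write_sequence(x[[split]][[i]],
                       file.path(dir, split, sprintf("seq_%04d", i)))
      }
    }
  } else {
    for (i in seq_along(x)) {
      write_sequence(x[[i]], file.path(dir, sprintf("seq_%04d", i)))
    }
  }
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir dataset directory. If it contains `train/` and `test/`
#'   subdirectories a `mitosis_split` is returned, otherwise a list of
#'   sequences.
#' @return a `mitosis_split` or list of `cell_sequence` objects.
#' @export
read_dataset <- function(dir) {
  if (!dir.exists(dir)) stop("read_dataset: directory does not exist: ", dir)
  if (dir.exists(file.path(dir, "train"))) {
    rd <- function(sub) {
      dirs <- sort(list.dirs(file.path(dir, sub), recursive = FALSE))
      lapply(dirs, read_sequence)
    }
    structure(list(train = rd("train"), test = rd("test"), ratio = NA_real_),
              class = "mitosis_split")
  } else {
    dirs <- sort(list.dirs(dir, recursive = FALSE))
    lapply(dirs, read_sequence)
  }
}
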