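# The three model families:
#  * time_encoded     — residual backbone with ConvGRUs at the outputs of the
#                       three stages whose widths match the GRU widths, plus
#                       a tracking decoder and a classification head;
#  * frame_classifier — the same residual backbone and head, no recurrence,
#                       no decoder: every frame is processed independently;
#  * base             — a shallow three-conv backbone with a ConvGRU at each
#                       of its three scales and a three-layer tracking
#                       decoder.

#' Frame specification
#'
#' @param h0,w0 input spatial dimensions in pixels.
#' @param channels_in input channels fed to the network: 3 (grayscale
#'   replicated to RGB) for the residual models, 1 or 3 for the base model.
#' @return an object of class `frame_spec`.
#' @export
frame_spec <- function(h0, w0 = h0, channels_in = 3L) {
  structure(list(h0 = as.integer(h0), w0 = as.integer(w0),
                 channels_in = as.integer(channels_in)),
            class = "frame_spec")
}

#' Backbone specification for the residual models
#'
#' The full-scale configuration uses stage widths 64/128/256/512 with ConvGRU
#' widths 128/256/512 and a total spatial downscale of 32 (stem stride 2,
#' stem max-pool, and strides 2 in stages 2--4). Reduced configurations keep
#' the same arithmetic with narrower widths for CPU-scale experiments.
#'
#' @param stage_channels four stage widths (default 64, 128, 256, 512).
#' @param gru_channels three ConvGRU widths; must equal
#'   `stage_channels[2:4]` since each GRU sits at the output of the stage
#'   whose width it matches.
#' @param blocks_per_stage residual blocks per stage (2; two 3x3
#'   convolutions each).
#' @param gru_kernel ConvGRU spatial kernel (odd).
#' @param head_filters filters of the classification-head convolution
#'   (default `2 * stage_channels[4]`, i.e. 1024 at full scale).
#' @param fc_hidden width of the hidden fully-connected layer.
#' @param decoder_channels channels of the four transpose convolutions
#'   (default `stage_channels[4] / 2, / 4, / 8, 3`, i.e. 256, 128, 64, 3 at
#'   full scale).
#' @return an object of class `backbone_spec`.
#' @export
backbone_spec <- function(stage_channels = c(64L, 128L, 256L, 512L),
                          gru_channels = stage_channels[2:4],
                          blocks_per_stage = 2L,
                          gru_kernel = 3L,
                          head_filters = 2L * stage_channels[4],
                          fc_hidden = max(16L, head_filters %/% 4L),
                          decoder_channels = NULL) {
  stage_channels <- as.integer(stage_channels)
  gru_channels <- as.integer(gru_channels)
  if (length(stage_channels) != 4) stop("backbone_spec: four stage widths required")
  if (!identical(gru_channels, stage_channels[2:4])) {
    stop("backbone_spec: gru_channels must match stage_channels[2:4]")
  }
  if (is.null(decoder_channels)) {
    decoder_channels <- c(pmax(2L, stage_channels[4] %/% c(2L, 4L, 8L)), 3L)
  }
  structure(list(stage_channels = stage_channels,
                 gru_channels = gru_channels,
                 blocks_per_stage = as.integer(blocks_per_stage),
                 gru_kernel = as.integer(gru_kernel),
                 downscale = 32L,
                 head_filters = as.integer(head_filters),
                 fc_hidden = as.integer(fc_hidden),
                 decoder_channels = as.integer(decoder_channels)),
            class = "backbone_spec")
}

#' Reduced backbone specification for CPU-scale experiments
#'
#' Stage widths 8/16/32/64 with ConvGRU widths 16/32/64, the desk-scale
#' counterpart of the full 64--512 configuration.
#' @export
reduced_backbone_spec <- function() {
  backbone_spec(stage_channels = c(8L, 16L, 32L, 64L))
}

check_frame_backbone <- function(fs, bs) {
  if (fs$h0 %% bs$downscale != 0 || fs$w0 %% bs$downscale != 0) {
    stop("frame dims must be divisible by the backbone downscale (",
         bs$downscale, ")")
  }
  if (fs$h0 %/% bs$downscale < 2 || fs$w0 %/% bs$downscale < 2) {
    stop("frame too small: the feature map must be at least 2x2 for the head max-pool")
  }
}

backbone_params <- function(fs, bs) {
  sc <- bs$stage_channels
  list(stem = list(conv = conv_param(3L, fs$channels_in, sc[1], stride = 2L)),
       stage1 = stage_param(sc[1], sc[1], 1L),
       stage2 = stage_param(sc[1], sc[2], 2L),
       stage3 = stage_param(sc[2], sc[3], 2L),
       stage4 = stage_param(sc[3], sc[4], 2L))
}

head_params_for <- function(fs, bs, n_class) {
  hf <- fs$h0 %/% bs$downscale
  wf <- fs$w0 %/% bs$downscale
  flat <- (hf %/% 2L) * (wf %/% 2L) * bs$head_filters
  head_param(bs$stage_channels[4], bs$head_filters, flat, bs$fc_hidden, n_class)
}

#' Build the time-encoded residual model
#'
#' Residual backbone (stem + four stages of two residual blocks) with
#' convolutional GRUs at the outputs of the three stages whose widths match
#' the GRU widths, a four-layer transpose-convolution tracking decoder with a
#' sigmoid output (a final non-learned bilinear x2 resize bridges the
#' backbone's x32 stride), and a classification head (3x3 convolution, 2x2
#' max-pool, flatten, two fully-connected layers ending in `n_class` sigmoid
#' units). The flattened post-max-pool head activations are the embeddings
#' used for PCA visualisation.
#'
#' @param fs a [frame_spec()].
#' @param bs a [backbone_spec()].
#' @param n_class number of stages to predict.
#' @param seed optional seed for weight initialisation.
#' @return an object of class `mitostage_model`.
#' @export
build_time_encoded_model <- function(fs, bs = backbone_spec(), n_class = 3L,
                                     seed = NULL) {
  check_frame_backbone(fs, bs)
  params <- with_seed(seed, {
    p <- backbone_params(fs, bs)
    p$gru2 <- conv_gru_params(bs$gru_channels[1], bs$gru_kernel)
    p$gru3 <- conv_gru_params(bs$gru_channels[2], bs$gru_kernel)
    p$gru4 <- conv_gru_params(bs$gru_channels[3], bs$gru_kernel)
    dec <- decoder_param(bs$stage_channels[4], bs$decoder_channels)
    names(dec) <- paste0("t", seq_along(dec))
    p$dec <- dec
    p$head <- head_params_for(fs, bs, n_class)
    p
  })
  structure(list(kind = "time_encoded", frame_spec = fs, backbone_spec = bs,
                 n_class = as.integer(n_class), params = params),
            class = "mitostage_model")
}

#' Build the frame-independent residual classifier baseline
#'
#' The standard 18-layer residual classifier: the same stem and four residual
#' stages as the time-encoded model but without recurrence or decoder; each
#' frame is processed independently of every other frame. `pretrained = TRUE`
#' is an optional hook for externally supplied weights (a `params` list of
#' matching shape); random He initialisation is the tested path.
#'
#' @inheritParams build_time_encoded_model
#' @param pretrained `FALSE` (random init) or a params list to load.
#' @return an object of class `mitostage_model`.
#' @export
build_frame_classifier <- function(fs, bs = backbone_spec(), n_class = 3L,
                                   pretrained = FALSE, seed = NULL) {
  check_frame_backbone(fs, bs)
  params <- with_seed(seed, {
    p <- backbone_params(fs, bs)
    p$head <- head_params_for(fs, bs, n_class)
    p
  })
  if (is.list(pretrained)) params <- pretrained
  structure(list(kind = "frame_classifier", frame_spec = fs,
                 backbone_spec = bs, n_class = as.integer(n_class),
                 params = params),
            class = "mitostage_model")
}

#' Specification of the shallow base model
#'
#' @param conv_channels widths of the three strided backbone convolutions;
#'   each is followed by a ConvGRU of the same width (information is
#'   propagated at three scales).
#' @param decoder_channels channels of the three transpose convolutions
#'   (last is 3).
#' @param head_filters,fc_hidden classification head sizes.
#' @param gru_kernel ConvGRU kernel size.
#' @return an object of class `base_spec`.
#' @export
base_spec <- function(conv_channels = c(16L, 32L, 64L),
                      decoder_channels = c(32L, 16L, 3L),
                      head_filters = 128L, fc_hidden = 32L,
                      gru_kernel = 3L) {
  structure(list(conv_channels = as.integer(conv_channels),
                 decoder_channels = as.integer(decoder_channels),
                 head_filters = as.integer(head_filters),
                 fc_hidden = as.integer(fc_hidden),
                 gru_kernel = as.integer(gru_kernel),
                 downscale = 8L),
            class = "base_spec")
}

#' Build the shallow base model
#'
#' A configurable shallow variant: three strided convolutions with a ConvGRU
#' after each (time information propagated at three scales), a three-layer
#' transpose-convolution tracking decoder with sigmoid output, and the same
#' classification head design as the deeper model. Accepts 1- or 3-channel
#' input (96x96 grayscale by default).
#'
#' @param fs a [frame_spec()] (dims divisible by 8).
#' @param bs a [base_spec()].
#' @inheritParams build_time_encoded_model
#' @return an object of class `mitostage_model`.
#' @export
build_base_model <- function(fs, bs = base_spec(), n_class = 3L, seed = NULL) {
  if (fs$h0 %% bs$downscale != 0 || fs$w0 %% bs$downscale != 0) {
    stop("frame dims must be divisible by ", bs$downscale)
  }
  cc <- bs$conv_channels
  params <- with_seed(seed, {
    p <- list(conv1 = conv_param(3L, fs$channels_in, cc[1], stride = 2L),
              gru1 = conv_gru_params(cc[1], bs$gru_kernel),
              conv2 = conv_param(3L, cc[1], cc[2], stride = 2L),
              gru2 = conv_gru_params(cc[2], bs$gru_kernel),
              conv3 = conv_param(3L, cc[2], cc[3], stride = 2L),
              gru3 = conv_gru_params(cc[3], bs$gru_kernel))
    dec <- decoder_param(cc[3], bs$decoder_channels)
    names(dec) <- paste0("t", seq_along(dec))
    p$dec <- dec
    hf <- fs$h0 %/% bs$downscale; wf <- fs$w0 %/% bs$downscale
    flat <- (hf %/% 2L) * (wf %/% 2L) * bs$head_filters
    p$head <- head_param(cc[3], bs$head_filters, flat, bs$fc_hidden, n_class)
    p
  })
  structure(list(kind = "base", frame_spec = fs, base_spec = bs,
                 n_class = as.integer(n_class), params = params),
            class = "mitostage_model")
}

#' @export
print.mitostage_model <- function(x, ...) {
  np <- sum(rapply(x$params, length, how = "unlist"))
  cat(sprintf("mitostage_model <%s>: %dx%d input, %d classes, %s parameters\n",
              x$kind, x$frame_spec$h0, x$frame_spec$w0, x$n_class,
              format(np, big.mark = ",")))
  invisible(x)
}

# --- input handling --------------------------------------------------------

# Accepts a cell_sequence, an (H, W, T) array or a list of matrices; returns
# a list of (H, W, channels_in) arrays scaled to [0, 1] (grayscale content
# replicated across channels).
frames_as_input <- function(frames, channels_in) {
  if (inherits(frames, "cell_sequence")) frames <- frames$frames
  if (is.array(frames) && length(dim(frames)) == 3) {
    frames <- lapply(seq_len(dim(frames)[3]), function(t) frames[, , t])
  }
  if (!is.list(frames) || length(frames) == 0) {
    stop("expected a non-empty sequence of frames")
  }
  lapply(frames, function(m) {
    v <- m / 255
    array(rep(v, channels_in), c(dim(m), channels_in))
  })
}

# --- per-frame forward passes ----------------------------------------------

te_frame_f <- function(params, x, h) {
  st <- stem_f(params$stem, x)
  s1 <- stage_f(params$stage1, st$out)
  s2 <- stage_f(params$stage2, s1$out)
  g2 <- gru_step_cache(params$gru2, s2$out, h$h2)
  s3 <- stage_f(params$stage3, g2$h)
  g3 <- gru_step_cache(params$gru3, s3$out, h$h3)
  s4 <- stage_f(params$stage4, g3$h)
  g4 <- gru_step_cache(params$gru4, s4$out, h$h4)
  dec <- decoder_f(params$dec, g4$h, upsample = TRUE)
  hd <- head_f(params$head, g4$h)
  list(features = g4$h, track = dec$track, scores = hd$scores,
       embedding = hd$embedding,
       h = list(h2 = g2$h, h3 = g3$h, h4 = g4$h),
       cache = list(st = st$cache, s1 = s1$cache, s2 = s2$cache, g2 = g2,
                    s3 = s3$cache, g3 = g3, s4 = s4$cache, g4 = g4,
                    dec = dec$cache, head = hd$cache))
}

fc_frame_f <- function(params, x) {
  st <- stem_f(params$stem, x)
  s1 <- stage_f(params$stage1, st$out)
  s2 <- stage_f(params$stage2, s1$out)
  s3 <- stage_f(params$stage3, s2$out)
  s4 <- stage_f(params$stage4, s3$out)
  hd <- head_f(params$head, s4$out)
  list(features = s4$out, scores = hd$scores, embedding = hd$embedding,
       cache = list(st = st$cache, s1 = s1$cache, s2 = s2$cache,
                    s3 = s3$cache, s4 = s4$cache, head = hd$cache))
}

base_frame_f <- function(params, x, h) {
  a1 <- conv_f(params$conv1, x); r1 <- a1 * (a1 > 0)
  g1 <- gru_step_cache(params$gru1, r1, h$h1)
  a2 <- conv_f(params$conv2, g1$h); r2 <- a2 * (a2 > 0)
  g2 <- gru_step_cache(params$gru2, r2, h$h2)
  a3 <- conv_f(params$conv3, g2$h); r3 <- a3 * (a3 > 0)
  g3 <- gru_step_cache(params$gru3, r3, h$h3)
  dec <- decoder_f(params$dec, g3$h, upsample = FALSE)
  hd <- head_f(params$head, g3$h)
  list(features = g3$h, track = dec$track, scores = hd$scores,
       embedding = hd$embedding,
       h = list(h1 = g1$h, h2 = g2$h, h3 = g3$h),
       cache = list(x = x, a1pos = a1 > 0, g1 = g1, a2pos = a2 > 0, g2 = g2,
                    a3pos = a3 > 0, g3 = g3, dec = dec$cache,
                    head = hd$cache))
}

zero_states <- function(model) {
  fs <- model$frame_spec
  if (model$kind == "time_encoded") {
    sc <- model$backbone_spec$stage_channels
    list(h2 = array(0, c(fs$h0 / 8, fs$w0 / 8, sc[2])),
         h3 = array(0, c(fs$h0 / 16, fs$w0 / 16, sc[3])),
         h4 = array(0, c(fs$h0 / 32, fs$w0 / 32, sc[4])))
  } else {
    cc <- model$base_spec$conv_channels
    list(h1 = array(0, c(fs$h0 / 2, fs$w0 / 2, cc[1])),
         h2 = array(0, c(fs$h0 / 4, fs$w0 / 4, cc[2])),
         h3 = array(0, c(fs$h0 / 8, fs$w0 / 8, cc[3])))
  }
}

#' Run a model over a sequence of frames
#'
#' GRU hidden states are reset at the sequence start, so outputs at frame `t`
#' depend only on frames `<= t` (causality). For the frame-independent
#' classifier every frame is processed in isolation and no tracking output
#' exists.
#'
#' @param model a `mitostage_model`.
#' @param frames a `cell_sequence`, an `(H, W, T)` array of gray levels
#'   0--255, or a list of matrices.
#' @param keep_cache internal flag: retain the per-frame caches needed for
#'   backpropagation.
#' @return list with `features` (per-frame backbone output feature maps),
#'   `tracks` (per-frame sigmoid reconstructions; `NULL` for the frame
#'   classifier), `scores` (T x n_class matrix of per-class sigmoid
#'   probabilities; rows need not sum to 1) and `embeddings` (T x d matrix of
#'   flattened post-max-pool head activations).
#' @export
forward_sequence <- function(model, frames, keep_cache = FALSE) {
  stopifnot(inherits(model, "mitostage_model"))
  xs <- frames_as_input(frames, model$frame_spec$channels_in)
  Tn <- length(xs)
  feats <- vector("list", Tn)
  tracks <- if (model$kind != "frame_classifier") vector("list", Tn) else NULL
  scores <- matrix(0, Tn, model$n_class)
  emb <- NULL
  caches <- if (keep_cache) vector("list", Tn) else NULL
  h <- if (model$kind != "frame_classifier") zero_states(model) else NULL
  for (t in seq_len(Tn)) {
    o <- switch(model$kind,
                time_encoded = te_frame_f(model$params, xs[[t]], h),
                frame_classifier = fc_frame_f(model$params, xs[[t]]),
                base = base_frame_f(model$params, xs[[t]], h))
    if (model$kind != "frame_classifier") h <- o$h
    feats[[t]] <- o$features
    if (!is.null(tracks)) tracks[[t]] <- o$track
    scores[t, ] <- o$scores
    if (is.null(emb)) emb <- matrix(0, Tn, length(o$embedding))
    emb[t, ] <- o$embedding
    if (keep_cache) caches[[t]] <- o$cache
  }
  list(features = feats, tracks = tracks, scores = scores, embeddings = emb,
       caches = caches)
}

# --- sequence backward passes ----------------------------------------------

# dscore_pre[[t]]: gradient wrt the pre-sigmoid class scores;
# dtrack_pre[[t]]: gradient wrt the pre-sigmoid tracking output (NULL to
# skip the decoder). Returns the accumulated parameter gradients.
te_backward_sequence <- function(model, caches, dscore_pre, dtrack_pre) {
  p <- model$params
  Tn <- length(caches)
  h0 <- zero_states(model)
  dh2 <- h0$h2 * 0; dh3 <- h0$h3 * 0; dh4 <- h0$h4 * 0
  gtot <- NULL
  for (t in rev(seq_len(Tn))) {
    cc <- caches[[t]]
    hb <- head_b(p$head, cc$head, dscore_pre[[t]])
    dh4t <- dh4 + hb$dx
    gdec <- NULL
    if (!is.null(dtrack_pre)) {
      db <- decoder_b(p$dec, cc$dec, dtrack_pre[[t]])
      dh4t <- dh4t + db$dx
      gdec <- db$grads
    }
    gb4 <- gru_step_bw(p$gru4, cc$g4, dh4t)
    dh4 <- gb4$dh_prev
    sb4 <- stage_b(p$stage4, cc$s4, gb4$dx)
    gb3 <- gru_step_bw(p$gru3, cc$g3, dh3 + sb4$dx)
    dh3 <- gb3$dh_prev
    sb3 <- stage_b(p$stage3, cc$s3, gb3$dx)
    gb2 <- gru_step_bw(p$gru2, cc$g2, dh2 + sb3$dx)
    dh2 <- gb2$dh_prev
    sb2 <- stage_b(p$stage2, cc$s2, gb2$dx)
    sb1 <- stage_b(p$stage1, cc$s1, sb2$dx)
    stb <- stem_b(p$stem, cc$st, sb1$dx)
    gt <- list(stem = stb$grads, stage1 = sb1$grads, stage2 = sb2$grads,
               stage3 = sb3$grads, stage4 = sb4$grads,
               gru2 = gb2$grads, gru3 = gb3$grads, gru4 = gb4$grads,
               head = hb$grads)
    if (!is.null(gdec)) gt$dec <- gdec
    gtot <- acc_grads(gtot, gt)
  }
  gtot
}

fc_frame_b <- function(model, cache, dscore_pre) {
  p <- model$params
  hb <- head_b(p$head, cache$head, dscore_pre)
  sb4 <- stage_b(p$stage4, cache$s4, hb$dx)
  sb3 <- stage_b(p$stage3, cache$s3, sb4$dx)
  sb2 <- stage_b(p$stage2, cache$s2, sb3$dx)
  sb1 <- stage_b(p$stage1, cache$s1, sb2$dx)
  stb <- stem_b(p$stem, cache$st, sb1$dx)
  list(stem = stb$grads, stage1 = sb1$grads, stage2 = sb2$grads,
       stage3 = sb3$grads, stage4 = sb4$grads, head = hb$grads)
}

base_backward_sequence <- function(model, caches, dscore_pre, dtrack_pre) {
  p <- model$params
  Tn <- length(caches)
  z <- zero_states(model)
  dh1 <- z$h1; dh2 <- z$h2; dh3 <- z$h3
  gtot <- NULL
  for (t in rev(seq_len(Tn))) {
    cc <- caches[[t]]
    hb <- head_b(p$head, cc$head, dscore_pre[[t]])
    dh3t <- dh3 + hb$dx
    gdec <- NULL
    if (!is.null(dtrack_pre)) {
      db <- decoder_b(p$dec, cc$dec, dtrack_pre[[t]])
      dh3t <- dh3t + db$dx
      gdec <- db$grads
    }
    gb3 <- gru_step_bw(p$gru3, cc$g3, dh3t)
    dh3 <- gb3$dh_prev
    dr3 <- gb3$dx * cc$a3pos
    c3 <- conv_b(p$conv3, cc$g2$h, dr3)
    gb2 <- gru_step_bw(p$gru2, cc$g2, dh2 + c3$dx)
    dh2 <- gb2$dh_prev
    dr2 <- gb2$dx * cc$a2pos
    c2 <- conv_b(p$conv2, cc$g1$h, dr2)
    gb1 <- gru_step_bw(p$gru1, cc$g1, dh1 + c2$dx)
    dh1 <- gb1$dh_prev
    dr1 <- gb1$dx * cc$a1pos
    c1 <- conv_b(p$conv1, cc$x, dr1)
    gt <- list(conv1 = c1$grads, gru1 = gb1$grads, conv2 = c2$grads,
               gru2 = gb2$grads, conv3 = c3$grads, gru3 = gb3$grads,
               head = hb$grads)
    if (!is.null(gdec)) gt$dec <- gdec
    gtot <- acc_grads(gtot, gt)
  }
  gtot
}

# --- checkpoints -----------------------------------------------------------

#' Save a model checkpoint
#'
#' Writes the serialized weights plus a JSON sidecar (`<path>.json`)
#' recording the full specification, so checkpoints are self-describing.
#'
#' @param model a `mitostage_model`.
#' @param path file path for the weights.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  spec <- list(kind = model$kind,
               frame_spec = unclass(model$frame_spec),
               n_class = model$n_class)
  spec[[if (model$kind == "base") "base_spec" else "backbone_spec"]] <-
    unclass(if (model$kind == "base") model$base_spec else model$backbone_spec)
  jsonlite::write_json(spec, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Load a model checkpoint written by [save_model()]
#' @param path file path.
#' @return a `mitostage_model`.
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "mitostage_model"))
  m
}
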