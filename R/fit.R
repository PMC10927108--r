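# Classic modelling front-end: one fitting function returning a classed
# object with print / summary / predict / plot / simulate methods.

#' Fit a mitosis stage classifier to a dataset split
#'
#' Builds the requested model, trains it with [train_model()], and evaluates
#' it on the held-out test split. This is the high-level entry point; the
#' lower-level pieces ([build_time_encoded_model()], [train_model()],
#' [evaluate_model()]) remain available for custom workflows.
#'
#' @param data a `mitosis_split` from [generate_dataset()] or
#'   [read_dataset()].
#' @param model `"time_encoded"` (recurrent residual model),
#'   `"frame_classifier"` (frame-independent residual baseline) or `"base"`
#'   (shallow recurrent model).
#' @param backbone a [backbone_spec()] / [base_spec()]; defaults to
#'   [reduced_backbone_spec()] for the residual models (CPU-scale) and
#'   [base_spec()] for the base model.
#' @param config a [train_config()]; defaults to the reference
#'   hyperparameters for the chosen model kind.
#' @param seed seed controlling weight initialisation and the training
#'   stream.
#' @param verbose print per-epoch progress.
#' @return an object of class `mitostage_fit` with elements `model`
#'   (trained `mitostage_model`), `history`, `validation`, `evaluation`
#'   (test-split [evaluate_model()] report), `config`, `data_meta`, `call`.
#' @export
mitostage_fit <- function(data,
                          model = c("time_encoded", "frame_classifier", "base"),
                          backbone = NULL, config = NULL, seed = NULL,
                          verbose = FALSE) {
  model <- match.arg(model)
  if (!inherits(data, "mitosis_split")) {
    stop("mitostage_fit: `data` must be a mitosis_split (see generate_dataset)")
  }
  if (length(data$train) == 0 || length(data$test) == 0) {
    stop("mitostage_fit: both splits must be non-empty")
  }
  s1 <- data$train[[1]]
  h0 <- dim(s1$frames)[1]; w0 <- dim(s1$frames)[2]
  n_class <- if (max(s1$labels) > 3) 6L else 3L
  if (is.null(config)) config <- train_config(model)
  if (!is.null(seed)) config$seed <- seed
  m <- switch(model,
    time_encoded = {
      bs <- if (is.null(backbone)) reduced_backbone_spec() else backbone
      build_time_encoded_model(frame_spec(h0, w0), bs, n_class, seed = seed)
    },
    frame_classifier = {
      bs <- if (is.null(backbone)) reduced_backbone_spec() else backbone
      build_frame_classifier(frame_spec(h0, w0), bs, n_class, seed = seed)
    },
    base = {
      bs <- if (is.null(backbone)) base_spec() else backbone
      build_base_model(frame_spec(h0, w0), bs, n_class, seed = seed)
    })
  tr <- train_model(m, data, config, verbose = verbose)
  ev <- evaluate_model(tr$model, data$test)
  structure(list(model = tr$model, history = tr$history,
                 validation = tr$validation, evaluation = ev,
                 config = config,
                 data_meta = list(n_train = length(data$train),
                                  n_test = length(data$test),
                                  frame_size = c(h0, w0),
                                  n_frames = dim(s1$frames)[3],
                                  sim_config = data$config),
                 call = match.call()),
            class = "mitostage_fit")
}

#' @export
print.mitostage_fit <- function(x, ...) {
  cat("mitostage_fit\n")
  cat("  model:        ", x$model$kind, sprintf("(%d classes)\n", x$model$n_class))
  cat("  trained on:   ", x$data_meta$n_train, "sequences x",
      x$data_meta$n_frames, "frames,",
      paste(x$data_meta$frame_size, collapse = "x"), "px\n")
  cat("  epochs:       ", x$config$epochs,
      sprintf("(%d iterations)\n", nrow(x$history)))
  cat(sprintf("  test accuracy: %.4f (%d sequences)\n",
              x$evaluation$metrics$accuracy, x$data_meta$n_test))
  invisible(x)
}

#' @export
summary.mitostage_fit <- function(object, ...) {
  m <- object$evaluation$metrics
  out <- list(
    kind = object$model$kind,
    n_class = object$model$n_class,
    accuracy = m$accuracy,
    per_class = data.frame(class = seq_len(object$model$n_class),
                           precision = m$precision, recall = m$recall,
                           f_score = m$f_score),
    mean_f_score = m$mean_f_score,
    normalized_confusion = object$evaluation$normalized,
    final_loss = object$history$l_tot[nrow(object$history)],
    final_val_accuracy =
      object$validation$val_accuracy[nrow(object$validation)])
  class(out) <- "summary.mitostage_fit"
  out
}

#' @export
print.summary.mitostage_fit <- function(x, ...) {
  cat(sprintf("%s model, %d classes\n", x$kind, x$n_class))
  cat(sprintf("pooled test accuracy: %.4f   mean F-score: %.4f\n",
              x$accuracy, x$mean_f_score))
  cat("per-class metrics:\n")
  print(x$per_class, row.names = FALSE, digits = 4)
  cat("row-normalized confusion matrix (rows = true class):\n")
  print(round(x$normalized_confusion, 3))
  cat(sprintf("final training loss: %.4f   final validation accuracy: %.4f\n",
              x$final_loss, x$final_val_accuracy))
  invisible(x)
}

#' Predict from a fitted mitosis stage classifier
#'
#' @param object a `mitostage_fit`.
#' @param newdata a `cell_sequence`, an `(H, W, T)` array, a list of frame
#'   matrices, or a list of `cell_sequence`s.
#' @param type `"class"` (per-frame stage labels, with three-class
#'   remapping), `"prob"` (per-frame per-class sigmoid scores), `"track"`
#'   (per-frame tracking reconstructions) or `"embedding"`.
#' @param ... unused.
#' @return per `type`; a list of such results when `newdata` is a list of
#'   sequences.
#' @export
predict.mitostage_fit <- function(object, newdata,
                                  type = c("class", "prob", "track",
                                           "embedding"), ...) {
  type <- match.arg(type)
  if (is.list(newdata) && !inherits(newdata, "cell_sequence") &&
      length(newdata) > 0 && inherits(newdata[[1]], "cell_sequence")) {
    return(lapply(newdata, function(s)
      predict.mitostage_fit(object, s, type = type)))
  }
  if (type == "class") {
    return(predict_sequence(object$model, newdata))
  }
  out <- forward_sequence(object$model, newdata)
  switch(type, prob = out$scores, track = out$tracks,
         embedding = out$embeddings)
}

#' Plot a fitted mitosis stage classifier
#'
#' `type = "loss"` draws the per-iteration training losses; `"confusion"`
#' draws the row-normalized confusion matrix of the test split; `"labels"`
#' draws the predicted label matrix of the test split as colored bands.
#'
#' @param x a `mitostage_fit`.
#' @param type one of `"loss"`, `"confusion"`, `"labels"`.
#' @param ... passed to the underlying base-graphics calls.
#' @export
plot.mitostage_fit <- function(x, type = c("loss", "confusion", "labels"),
                               ...) {
  type <- match.arg(type)
  if (type == "loss") {
    h <- x$history
    graphics::plot(h$iteration, h$l_tot, type = "l", xlab = "iteration",
                   ylab = "loss", main = "training loss", ...)
    if (!is.null(h$l_track)) {
      graphics::lines(h$iteration, h$l_track, lty = 2)
      graphics::lines(h$iteration, h$l_cls, lty = 3)
      graphics::legend("topright", c("total", "tracking", "classification"),
                       lty = 1:3, bty = "n")
    }
  } else if (type == "confusion") {
    cm <- x$evaluation$normalized
    n <- nrow(cm)
    graphics::image(seq_len(n), seq_len(n), t(cm[n:1, , drop = FALSE]),
                    col = grDevices::gray.colors(32, start = 1, end = 0.2),
                    axes = FALSE, xlab = "predicted", ylab = "true",
                    main = "normalized confusion", ...)
    graphics::axis(1, seq_len(n)); graphics::axis(2, seq_len(n), rev(seq_len(n)))
    for (i in seq_len(n)) for (j in seq_len(n)) {
      graphics::text(j, n + 1 - i, sprintf("%.2f", cm[i, j]))
    }
  } else {
    preds <- x$evaluation$predictions
    lm <- do.call(rbind, preds)
    pal <- stage_palette(x$model$n_class)
    graphics::image(seq_len(ncol(lm)), seq_len(nrow(lm)),
                    t(lm[nrow(lm):1, , drop = FALSE]),
                    col = pal, zlim = c(1, x$model$n_class),
                    xlab = "frame", ylab = "trajectory",
                    main = "predicted label matrix", axes = FALSE, ...)
    graphics::axis(1); graphics::axis(2)
  }
  invisible(x)
}

#' Simulate new sequences from the generator configuration of a fit
#'
#' Draws `nsim` fresh synthetic sequences from the same simulator
#' configuration the training data came from.
#'
#' @param object a `mitostage_fit`.
#' @param nsim number of sequences.
#' @param seed seed for the generator.
#' @param ... unused.
#' @return list of `cell_sequence` objects.
#' @export
simulate.mitostage_fit <- function(object, nsim = 1, seed = NULL, ...) {
  cfg <- object$data_meta$sim_config
  if (is.null(cfg)) stop("simulate: the fit carries no simulator configuration")
  if (is.null(seed)) seed <- sample.int(1e6, 1)
  lapply(seq_len(nsim), function(i)
    generate_sequence(cfg, seed = derive_seed(seed, i)))
}
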