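# Metrics and result artifacts: accuracy, normalized confusion matrix,
# per-class precision/recall/F-score, label matrices (CSV + color raster),
# PCA embedding projections, and threshold segmentation of tracker output.

#' Confusion matrix
#'
#' `counts[i, j]` is the number of frames with true class `i` predicted as
#' class `j`: rows are the true class, columns the predicted class, so the
#' per-class true positives lie on the diagonal.
#'
#' @param true,pred integer label vectors of equal length, values in
#'   `1..n_class`.
#' @param n_class number of classes.
#' @return an `n_class` x `n_class` integer matrix.
#' @export
confusion <- function(true, pred, n_class) {
  if (length(true) != length(pred)) stop("confusion: unequal lengths")
  if (!all(true %in% seq_len(n_class)) || !all(pred %in% seq_len(n_class))) {
    stop("confusion: label out of range 1..n_class")
  }
  cm <- matrix(0L, n_class, n_class)
  for (i in seq_along(true)) {
    cm[true[i], pred[i]] <- cm[true[i], pred[i]] + 1L
  }
  cm
}

#' Row-normalize a confusion matrix
#'
#' Each nonzero row is divided by its sum (so the diagonal reads as per-class
#' recall); all-zero rows stay zero.
#'
#' @param cm a confusion matrix.
#' @return a row-stochastic matrix.
#' @export
normalize_rows <- function(cm) {
  rs <- rowSums(cm)
  rs[rs == 0] <- 1
  cm / rs
}

#' Metrics from a confusion matrix
#'
#' Per-class precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and F-score
#' `2*p*r/(p+r)` (convention: 0 when the denominator is 0), plus pooled
#' accuracy `trace/total` and the across-class means.
#'
#' @param cm a confusion matrix (rows = true class).
#' @return list with `accuracy`, `precision`, `recall`, `f_score` (per-class
#'   vectors) and `mean_precision`, `mean_recall`, `mean_f_score`.
#' @export
metrics <- function(cm) {
  total <- sum(cm)
  if (total <= 0) stop("metrics: empty confusion matrix")
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(a, b) ifelse(b == 0, 0, a / b)
  p <- safe_div(tp, tp + fp)
  r <- safe_div(tp, tp + fn)
  f <- safe_div(2 * p * r, p + r)
  list(accuracy = sum(tp) / total,
       precision = p, recall = r, f_score = f,
       mean_precision = mean(p), mean_recall = mean(r),
       mean_f_score = mean(f))
}

stage_palette <- function(n_class) {
  if (n_class == 3) {
    c("#00a651", "#ec008c", "#ed1c24")      # green, magenta, red
  } else if (n_class == 6) {
    c("#00a651", "#fff200", "#f7941d",      # green, yellow, orange
      "#92278f", "#0072bc", "#ed1c24")      # violet, blue, red
  } else {
    grDevices::hcl.colors(n_class, "Dark 3")
  }
}

#' Label matrix: per-trajectory stage labels over time
#'
#' Stacks per-sequence label vectors into a matrix (rows = cell trajectories,
#' columns = frame index) and optionally exports it as CSV plus a
#' color-mapped raster PNG (3-class: green/magenta/red for interphase,
#' mitosis, post-mitosis; 6-class: green/yellow/orange/violet/blue/red).
#'
#' @param labels_list list of equal-length per-frame label vectors.
#' @param n_class number of classes.
#' @param csv,png optional output paths.
#' @param scale integer pixel size of each matrix cell in the PNG.
#' @return the label matrix (invisibly when files are written).
#' @export
label_matrix <- function(labels_list, n_class, csv = NULL, png = NULL,
                         scale = 4L) {
  lens <- vapply(labels_list, length, integer(1))
  if (length(unique(lens)) != 1) stop("label_matrix: ragged rows")
  lm <- do.call(rbind, lapply(labels_list, as.integer))
  if (!all(lm %in% seq_len(n_class))) stop("label_matrix: label out of range")
  if (!is.null(csv)) {
    utils::write.table(lm, csv, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }
  if (!is.null(png)) {
    pal <- stage_palette(n_class)
    rgbv <- grDevices::col2rgb(pal) / 255
    big <- lm[rep(seq_len(nrow(lm)), each = scale),
              rep(seq_len(ncol(lm)), each = scale), drop = FALSE]
    img <- array(0, c(dim(big), 3))
    for (ch in 1:3) img[, , ch] <- matrix(rgbv[ch, big], nrow(big), ncol(big))
    png::writePNG(img, png)
  }
  if (is.null(csv) && is.null(png)) lm else invisible(lm)
}

#' Project embeddings onto their first three principal components
#'
#' Mean-centered PCA (no scaling) of the per-frame embedding vectors. Returns
#' the first three component scores per frame with the stage labels and the
#' explained-variance ratios (ordered decreasing by construction).
#'
#' @param embeddings numeric matrix, one row per frame (>= 4 rows, >= 3
#'   columns).
#' @param labels per-frame stage labels (optional).
#' @return list with `scores` (n x 3 matrix), `labels` and
#'   `explained_variance` (ratios for the first three components).
#' @export
embed_pca <- function(embeddings, labels = NULL) {
  embeddings <- as.matrix(embeddings)
  if (nrow(embeddings) < 4) stop("embed_pca: at least 4 samples required")
  if (ncol(embeddings) < 3) stop("embed_pca: dimension must be >= 3")
  pc <- stats::prcomp(embeddings, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  list(scores = pc$x[, 1:3, drop = FALSE],
       labels = labels,
       explained_variance = (ev / sum(ev))[1:3])
}

#' Silhouette score of 3-PC embedding projections by stage label
#'
#' Mean silhouette width of the first-three-principal-component scores
#' grouped by true stage, a scalar measure of how well the stages separate
#' in the embedding space.
#'
#' @param embeddings per-frame embedding matrix.
#' @param labels per-frame stage labels (at least two distinct values).
#' @return mean silhouette width in the interval -1 to 1.
#' @export
embedding_silhouette <- function(embeddings, labels) {
  pr <- embed_pca(embeddings, labels)
  if (length(unique(labels)) < 2) {
    stop("embedding_silhouette: at least two classes required")
  }
  sil <- cluster::silhouette(as.integer(labels), stats::dist(pr$scores))
  mean(sil[, "sil_width"])
}

#' Segment the tracking output by an intensity threshold
#'
#' Binary mask: mean over the channels of the sigmoid tracking output
#' compared against the threshold.
#'
#' @param track `(H, W, C)` tracking output in the interval 0 to 1.
#' @param threshold fraction in (0, 1).
#' @return binary `(H, W)` matrix.
#' @export
segment_by_threshold <- function(track, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) {
    stop("segment_by_threshold: threshold must be in (0, 1)")
  }
  m <- apply(track, c(1, 2), mean)
  (m >= threshold) * 1
}

#' Intersection over union of two binary masks
#'
#' @param a,b binary matrices of equal shape. An empty union yields IoU 1.
#' @return scalar in the interval 0 to 1.
#' @export
mask_iou <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask_iou: shape mismatch")
  a <- a > 0; b <- b > 0
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Evaluate a model on a list of test sequences
#'
#' Predicts per-frame stages for every sequence (with the three-class
#' remapping of [remap_predictions()] by default), pools all frames, and
#' returns the confusion matrix, its row-normalized form and the
#' [metrics()] report, plus the per-sequence predictions.
#'
#' @param model a `mitostage_model`.
#' @param seqs list of `cell_sequence` objects with ground-truth labels.
#' @param remap apply trailing-interphase remapping (three-class only).
#' @return list with `confusion`, `normalized`, `metrics`, `predictions`,
#'   `true`.
#' @export
evaluate_model <- function(model, seqs, remap = model$n_class == 3L) {
  preds <- lapply(seqs, function(s) predict_sequence(model, s, remap = remap))
  true <- lapply(seqs, function(s) as.integer(s$labels))
  cm <- confusion(unlist(true), unlist(preds), model$n_class)
  list(confusion = cm, normalized = normalize_rows(cm), metrics = metrics(cm),
       predictions = preds, true = true)
}
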