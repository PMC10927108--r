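# End-to-end pipeline (simulate -> train -> predict -> evaluate) with a
# hashed artifact manifest, plus the command-line front-end used by the
# inst/cli/mitostage script.

write_metrics_json <- function(ev, path) {
  m <- ev$metrics
  jsonlite::write_json(
    list(accuracy = m$accuracy,
         precision = m$precision, recall = m$recall, f_score = m$f_score,
         mean_precision = m$mean_precision, mean_recall = m$mean_recall,
         mean_f_score = m$mean_f_score),
    path, auto_unbox = TRUE, digits = NA)
  path
}

write_evaluation_artifacts <- function(fit_or_ev, model, seqs, dir) {
  ev <- if (inherits(fit_or_ev, "mitostage_fit")) fit_or_ev$evaluation else fit_or_ev
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_metrics_json(ev, file.path(dir, "metrics.json"))
  utils::write.table(ev$confusion, file.path(dir, "confusion.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  n_class <- nrow(ev$confusion)
  label_matrix(ev$predictions, n_class,
               csv = file.path(dir, "labels_pred.csv"),
               png = file.path(dir, "labels_pred.png"))
  label_matrix(ev$true, n_class,
               csv = file.path(dir, "labels_true.csv"),
               png = file.path(dir, "labels_true.png"))
  # embedding projection of the pooled test frames
  embs <- do.call(rbind, lapply(seqs, function(s)
    forward_sequence(model, s)$embeddings))
  labs <- unlist(lapply(seqs, function(s) s$labels))
  pr <- embed_pca(embs, labs)
  utils::write.csv(data.frame(pc1 = pr$scores[, 1], pc2 = pr$scores[, 2],
                              pc3 = pr$scores[, 3], label = labs),
                   file.path(dir, "embedding.csv"), row.names = FALSE)
  grDevices::png(file.path(dir, "embedding.png"), 480, 480)
  graphics::plot(pr$scores[, 1], pr$scores[, 2],
                 col = stage_palette(n_class)[labs], pch = 19,
                 xlab = "PC1", ylab = "PC2", main = "embedding projection")
  grDevices::dev.off()
  invisible(dir)
}

#' Run the full pipeline into a run directory
#'
#' Simulates a dataset, trains a model, predicts on the test split and writes
#' every evaluation artifact (metrics JSON, confusion CSV, label-matrix CSV +
#' PNG, embedding CSV + PNG, training history CSV, model checkpoint) plus a
#' `manifest.json` listing each written file with its MD5 hash. With
#' `repeats > 1` the whole run is repeated under derived seeds and the pooled
#' test accuracies are aggregated as mean and standard deviation in
#' `summary.json`.
#'
#' @param out_dir run directory (created).
#' @param model model kind as in [mitostage_fit()].
#' @param sim a [sim_config()] (its `seed` field is overridden per repeat).
#' @param n_sequences dataset size.
#' @param config a [train_config()]; defaults per model kind.
#' @param backbone optional backbone/base spec override.
#' @param seed master seed; every RNG consumer receives a seed derived from
#'   it.
#' @param repeats number of independent seeded repetitions.
#' @param verbose print progress.
#' @return list with `fits` (one `mitostage_fit` per repeat), `summary`
#'   (mean/sd accuracy) and `manifest` (file -> MD5 map), invisibly.
#' @export
run_pipeline <- function(out_dir, model = "time_encoded",
                         sim = sim_config("three_class", frame_size = 64,
                                          sequence_length = 30),
                         n_sequences = 20, config = NULL, backbone = NULL,
                         seed = 1L, repeats = 1L, verbose = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fits <- vector("list", repeats)
  accs <- numeric(repeats)
  for (r in seq_len(repeats)) {
    rseed <- derive_seed(seed, r)
    rdir <- if (repeats == 1) out_dir else file.path(out_dir, sprintf("rep%02d", r))
    dir.create(rdir, recursive = TRUE, showWarnings = FALSE)
    data <- generate_dataset(n_sequences, sim, seed = rseed)
    write_dataset(data, file.path(rdir, "data"))
    fit <- mitostage_fit(data, model = model, backbone = backbone,
                         config = config, seed = rseed, verbose = verbose)
    utils::write.csv(fit$history, file.path(rdir, "history.csv"),
                     row.names = FALSE)
    save_model(fit$model, file.path(rdir, "model.rds"))
    write_evaluation_artifacts(fit, fit$model, data$test,
                               file.path(rdir, "eval"))
    fits[[r]] <- fit
    accs[r] <- fit$evaluation$metrics$accuracy
  }
  summ <- list(model = model, repeats = repeats, seed = seed,
               accuracy_mean = mean(accs),
               accuracy_sd = if (repeats > 1) stats::sd(accs) else 0)
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "manifest.json"))
  manifest <- as.list(tools::md5sum(files))
  names(manifest) <- substring(names(manifest), nchar(out_dir) + 2)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(fits = fits, summary = summ, manifest = manifest))
}

# --- command-line front-end -------------------------------------------------

cli_parse_flags <- function(args) {
  flags <- list()
  pos <- character()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- substring(a, 3)
      if (i < length(args) && !startsWith(args[i + 1], "--")) {
        flags[[key]] <- args[i + 1]
        i <- i + 2L
      } else {
        flags[[key]] <- "true"
        i <- i + 1L
      }
    } else {
      pos <- c(pos, a)
      i <- i + 1L
    }
  }
  list(flags = flags, pos = pos)
}

cli_load_config <- function(path) {
  if (is.null(path)) return(list())
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

num_or <- function(x, default) if (is.null(x)) default else as.numeric(x)
int_or <- function(x, default) if (is.null(x)) default else as.integer(x)
chr_or <- function(x, default) if (is.null(x)) default else as.character(x)

cli_sim_config <- function(opt) {
  sim_config(mode = chr_or(opt$mode, "three_class"),
             frame_size = int_or(opt$frame_size, 64L),
             sequence_length = int_or(opt$sequence_length, 30L),
             noise_sd = num_or(opt$noise_sd, 8))
}

cli_train_config <- function(opt, model) {
  cfg <- train_config(model)
  for (nm in c("batch", "lr", "lambda_wt", "epochs", "momentum",
               "relabel_k", "lr_drop_factor", "lr_drop_iteration",
               "train_test_ratio")) {
    if (!is.null(opt[[nm]])) cfg[[nm]] <- as.numeric(opt[[nm]])
  }
  cfg$batch <- as.integer(cfg$batch)
  cfg$epochs <- as.integer(cfg$epochs)
  cfg$lr_drop_iteration <- as.integer(cfg$lr_drop_iteration)
  if (!is.null(opt$no_augment)) cfg$augment <- FALSE
  cfg
}

cli_backbone <- function(opt, model) {
  if (model == "base") return(base_spec())
  if (is.null(opt$full_scale)) reduced_backbone_spec() else backbone_spec()
}

#' Command-line entry point
#'
#' Sub-commands: `simulate` (writes a dataset split), `train` (data dir +
#' optional YAML/JSON config -> checkpoint + history CSV), `predict`
#' (checkpoint + sequence dir -> labels CSV), `evaluate` (checkpoint + data
#' dir -> metrics JSON, confusion CSV, label-matrix and embedding images) and
#' `run` (the full [run_pipeline()], `--repeats` aggregating mean/sd).
#' Every command accepts `--seed`. Flags override config-file fields.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    p <- cli_parse_flags(args)
    cmd <- if (length(p$pos)) p$pos[1] else "help"
    opt <- utils::modifyList(cli_load_config(p$flags$config), p$flags)
    seed <- int_or(opt$seed, 1L)
    switch(cmd,
      simulate = {
        out <- chr_or(opt$out, stop("simulate: --out required"))
        cfg <- cli_sim_config(opt)
        data <- generate_dataset(int_or(opt$n_sequences, 20L), cfg,
                                 seed = seed,
                                 ratio = num_or(opt$train_test_ratio, 0.85))
        write_dataset(data, out)
        message("wrote dataset to ", out)
      },
      train = {
        ddir <- chr_or(opt$data, stop("train: --data required"))
        if (!dir.exists(ddir)) stop("data directory does not exist: ", ddir)
        out <- chr_or(opt$out, stop("train: --out required"))
        model <- chr_or(opt$model, "time_encoded")
        data <- read_dataset(ddir)
        fit <- mitostage_fit(data, model = model,
                             backbone = cli_backbone(opt, model),
                             config = cli_train_config(opt, model),
                             seed = seed,
                             verbose = !is.null(opt$verbose))
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        save_model(fit$model, file.path(out, "model.rds"))
        utils::write.csv(fit$history, file.path(out, "history.csv"),
                         row.names = FALSE)
        utils::write.csv(fit$validation, file.path(out, "validation.csv"),
                         row.names = FALSE)
        message(sprintf("trained %s: test accuracy %.4f", model,
                        fit$evaluation$metrics$accuracy))
      },
      predict = {
        m <- load_model(chr_or(opt$model_path, stop("predict: --model_path required")))
        sdir <- chr_or(opt$data, stop("predict: --data required"))
        if (!dir.exists(sdir)) stop("sequence directory does not exist: ", sdir)
        s <- read_sequence(sdir)
        pred <- predict_sequence(m, s)
        out <- chr_or(opt$out, stop("predict: --out required"))
        utils::write.csv(data.frame(frame_index = seq_along(pred),
                                    stage_label = pred),
                         out, row.names = FALSE)
        message("wrote predictions to ", out)
      },
      evaluate = {
        m <- load_model(chr_or(opt$model_path, stop("evaluate: --model_path required")))
        ddir <- chr_or(opt$data, stop("evaluate: --data required"))
        if (!dir.exists(ddir)) stop("data directory does not exist: ", ddir)
        data <- read_dataset(ddir)
        seqs <- if (inherits(data, "mitosis_split")) data$test else data
        ev <- evaluate_model(m, seqs)
        out <- chr_or(opt$out, stop("evaluate: --out required"))
        write_evaluation_artifacts(ev, m, seqs, out)
        message(sprintf("accuracy %.4f; artifacts in %s",
                        ev$metrics$accuracy, out))
      },
      run = {
        out <- chr_or(opt$out, stop("run: --out required"))
        run_pipeline(out,
                     model = chr_or(opt$model, "time_encoded"),
                     sim = cli_sim_config(opt),
                     n_sequences = int_or(opt$n_sequences, 20L),
                     config = cli_train_config(opt,
                                               chr_or(opt$model, "time_encoded")),
                     backbone = cli_backbone(opt, chr_or(opt$model, "time_encoded")),
                     seed = seed,
                     repeats = int_or(opt$repeats, 1L),
                     verbose = !is.null(opt$verbose))
        message("run complete; manifest in ", file.path(out, "manifest.json"))
      },
      {
        message("usage: mitostage <simulate|train|predict|evaluate|run> [--flags]")
        message("common flags: --seed --out --data --model --config --repeats")
      })
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
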