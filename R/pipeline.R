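# End-to-end experiment runner: synth -> mix -> featurize -> reduce ->
# train -> classify -> evaluate, all seeded from one config.

#' Experiment configuration
#'
#' All randomness in a run is derived from `seed` through named sub-seeds
#' (corpus, training frames, cross-validation folds, masker segments), so a
#' config reproduces its run bit-exactly.
#'
#' @param seed master seed.
#' @param feature_set one of the seven feature set names (default `"gt14"`).
#' @param frame_ms frame length (default 8).
#' @param train_snr_db training SNR against speech-shaped noise (default +10;
#'   training always uses SSN).
#' @param test_snrs_db babble SNRs for testing (default `+20 ... -10` dB;
#'   testing always uses babble, mirroring the mismatched-noise design).
#' @param include_quiet evaluate on clean tokens too (default TRUE).
#' @param reduction `"none"`, `"pca"` or `"kpca"`.
#' @param threshold eigenvalue threshold for the reduction (default 0.01,
#'   relative).
#' @param grid a [grid_search_spec()].
#' @param corpus a [corpus_spec()].
#' @param specs per-group envelope specs (default [default_envelope_specs()]).
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1, feature_set = "gt14", frame_ms = 8,
                       train_snr_db = 10,
                       test_snrs_db = c(20, 15, 10, 5, 0, -5, -10),
                       include_quiet = TRUE,
                       reduction = c("none", "pca", "kpca"), threshold = 0.01,
                       grid = grid_search_spec(),
                       corpus = corpus_spec(),
                       specs = default_envelope_specs()) {
  reduction <- match.arg(reduction)
  feature_set <- match.arg(feature_set, FEATURE_SETS)
  structure(list(seed = as.integer(seed), feature_set = feature_set,
                 frame_ms = frame_ms, train_snr_db = train_snr_db,
                 test_snrs_db = test_snrs_db, include_quiet = include_quiet,
                 reduction = reduction, threshold = threshold, grid = grid,
                 corpus = corpus, specs = specs),
            class = "run_config")
}

# Tiny FNV-1a hash of the deparsed config, for artifact provenance.
config_hash <- function(cfg) {
  bytes <- utf8ToInt(paste(deparse(cfg), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run a full classification experiment
#'
#' Generates the synthetic corpus, builds the clean + SSN training set,
#' optionally fits a reduction model (frozen at test time), grid-searches and
#' trains the SVM, then classifies every test token by majority vote in quiet
#' and at each babble SNR.
#'
#' @param cfg a [run_config()].
#' @param out_dir optional directory: writes `metrics.csv`,
#'   `confusion_<condition>.csv` and `manifest.json` (config snapshot + hash).
#' @param verbose print progress (default FALSE).
#' @return object of class `fricshape_run`: `metrics` data.frame (condition,
#'   snr_db, accuracy, n), named list `confusions`, the `model`, `reducer`,
#'   `config` and its `hash`.
#' @export
run_experiment <- function(cfg = run_config(), out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  cs <- cfg$corpus
  cs$seed <- child_seed(cfg$seed, 11)
  say("generating corpus (%d tokens/group/split)", cs$n_tokens_per_group)
  corpus <- generate_corpus(cfg$specs, cs)
  fs <- cs$fs
  bank <- if (cfg$feature_set %in% c("gt14", "gt24")) gammatone_bank(fs = fs)

  say("building training set (clean + SSN at %+d dB)", cfg$train_snr_db)
  ts <- build_training_set(corpus$train, cfg$feature_set, cfg$train_snr_db,
                           seed = child_seed(cfg$seed, 12),
                           frame_ms = cfg$frame_ms, bank = bank)
  reducer <- NULL
  Xtr <- ts$features
  if (cfg$reduction != "none") {
    reducer <- if (cfg$reduction == "pca") {
      fit_pca(Xtr, threshold = cfg$threshold)
    } else {
      fit_kpca(Xtr, threshold = cfg$threshold)
    }
    Xtr <- project(reducer, Xtr)
    say("%s reduction: %d -> %d dimensions", cfg$reduction,
        ncol(ts$features), ncol(Xtr))
  }
  grid <- cfg$grid
  grid$seed <- child_seed(cfg$seed, 13)
  say("grid search over %d x %d points, %d-fold CV",
      length(grid$C_grid), length(grid$gamma_grid), grid$folds)
  model <- train_svm(Xtr, ts$labels, grid, feature_set = cfg$feature_set)
  say("chosen C = %g, gamma = %g (CV accuracy %.1f%%)",
      model$C, model$gamma, 100 * model$cv_accuracy)

  test_tokens <- corpus$test
  truth <- vapply(test_tokens, function(t) t$group, character(1))
  max_len <- max(vapply(test_tokens, function(t) length(t$samples), integer(1)))
  babble <- synthesize_babble(max_len / fs + 1,
                              noise_spec("babble", fs = fs,
                                         seed = child_seed(cfg$seed, 14)))
  conditions <- character(0)
  snrs <- numeric(0)
  if (cfg$include_quiet) { conditions <- "quiet"; snrs <- NA_real_ }
  conditions <- c(conditions, sprintf("babble_%+ddB", cfg$test_snrs_db))
  snrs <- c(snrs, cfg$test_snrs_db)

  metrics <- data.frame(condition = conditions, snr_db = snrs,
                        accuracy = NA_real_, n = length(test_tokens))
  confusions <- list()
  for (ci in seq_along(conditions)) {
    pred <- character(length(test_tokens))
    for (i in seq_along(test_tokens)) {
      tok <- test_tokens[[i]]
      if (!is.na(snrs[ci])) {
        tok <- mix_at_snr(tok, babble, snrs[ci],
                          seed = child_seed(cfg$seed, 20000L + ci * 1000L + i))
      }
      pred[i] <- as.character(classify_token(model, tok, reducer, bank,
                                             cfg$frame_ms)$group)
    }
    cm <- score_run(truth, pred)
    metrics$accuracy[ci] <- cm$accuracy
    confusions[[conditions[ci]]] <- cm
    say("%-14s accuracy %.1f%%", conditions[ci], 100 * cm$accuracy)
  }

  run <- structure(list(metrics = metrics, confusions = confusions,
                        model = model, reducer = reducer, config = cfg,
                        hash = config_hash(cfg)),
                   class = "fricshape_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.fricshape_run <- function(x, ...) {
  cat(sprintf("<fricshape_run %s: %s features, reduction = %s>\n",
              x$hash, x$config$feature_set, x$config$reduction))
  m <- x$metrics
  m$accuracy <- sprintf("%.1f%%", 100 * m$accuracy)
  print(m, row.names = FALSE)
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(run$metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  for (cond in names(run$confusions)) {
    write.csv(run$confusions[[cond]]$row_percent,
              file.path(out_dir, sprintf("confusion_%s.csv", cond)))
  }
  snapshot <- list(hash = run$hash, config = unclass(run$config),
                   C = run$model$C, gamma = run$model$gamma)
  snapshot$config$grid <- unclass(snapshot$config$grid)
  snapshot$config$corpus <- unclass(snapshot$config$corpus)
  snapshot$config$specs <- lapply(snapshot$config$specs, unclass)
  jsonlite::write_json(snapshot, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
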