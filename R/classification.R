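# One-vs-one C-SVC with RBF kernel (SMO solver in src/core.cpp), seeded
# cross-validated grid search, and majority-vote token decoding.

#' Grid-search specification
#'
#' Defaults follow the usual coarse grid for RBF C-SVCs:
#' `C = 2^(-5, -3, ..., 15)`, `gamma = 2^(-15, -13, ..., 3)`, 5-fold CV.
#'
#' @param C_grid positive penalty values.
#' @param gamma_grid positive RBF bandwidth values.
#' @param folds number of cross-validation folds (>= 2).
#' @param seed seed for the fold assignment.
#' @return list of class `grid_search_spec`.
#' @export
grid_search_spec <- function(C_grid = 2^seq(-5, 15, by = 2),
                             gamma_grid = 2^seq(-15, 3, by = 2),
                             folds = 5, seed = 1) {
  stopifnot(length(C_grid) >= 1, all(C_grid > 0),
            length(gamma_grid) >= 1, all(gamma_grid > 0), folds >= 2)
  structure(list(C_grid = sort(C_grid), gamma_grid = sort(gamma_grid),
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "grid_search_spec")
}

# Fit the three pairwise binary SVMs on standardized features.
ovo_fit <- function(X, y_int, C, gamma, n_classes = 3) {
  pairs <- utils::combn(n_classes, 2)
  models <- vector("list", ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1, p]; b <- pairs[2, p]
    idx <- which(y_int == a | y_int == b)
    Xp <- X[idx, , drop = FALSE]
    yp <- ifelse(y_int[idx] == a, 1, -1)
    K <- cpp_rbf_kernel(Xp, Xp, gamma)
    sol <- cpp_smo(K, yp, C)
    sv <- which(sol$alpha > 1e-10)
    models[[p]] <- list(pos = a, neg = b,
                        sv = Xp[sv, , drop = FALSE],
                        coef = sol$alpha[sv] * yp[sv],
                        rho = sol$rho, gamma = gamma)
  }
  models
}

# Decision values [n x n_pairs] and derived votes/margins for one-vs-one.
ovo_decision <- function(models, X, n_classes = 3) {
  n <- nrow(X)
  votes <- matrix(0, n, n_classes)
  margin <- matrix(0, n, n_classes)
  dec <- matrix(0, n, length(models))
  for (p in seq_along(models)) {
    m <- models[[p]]
    f <- as.numeric(cpp_rbf_kernel(X, m$sv, m$gamma) %*% m$coef) - m$rho
    dec[, p] <- f
    pos_win <- f >= 0
    votes[, m$pos] <- votes[, m$pos] + pos_win
    votes[, m$neg] <- votes[, m$neg] + !pos_win
    margin[, m$pos] <- margin[, m$pos] + f
    margin[, m$neg] <- margin[, m$neg] - f
  }
  list(votes = votes, margin = margin, decision = dec)
}

# Argmax of votes with deterministic tie-breaking: largest summed one-vs-one
# decision margin, then lowest class index.
ovo_predict_int <- function(models, X, n_classes = 3) {
  d <- ovo_decision(models, X, n_classes)
  apply_ties <- function(i) {
    v <- d$votes[i, ]
    cand <- which(v == max(v))
    if (length(cand) > 1) {
      mg <- d$margin[i, cand]
      cand <- cand[mg == max(mg)]
    }
    cand[1]
  }
  vapply(seq_len(nrow(X)), apply_ties, integer(1))
}

scale_apply <- function(scaler, X) {
  sweep(sweep(X, 2, scaler$center), 2, scaler$scale, "/")
}

#' Train the 3-class RBF SVM with cross-validated grid search
#'
#' Features are z-scored (fit on the training data only). For every `(C,
#' gamma)` grid point a seeded stratified k-fold cross-validation accuracy is
#' computed with one-vs-one C-SVCs; the maximizing pair (ties: smallest C,
#' then smallest gamma) is refit on all rows.
#'
#' @param features numeric matrix, rows = training frames.
#' @param labels factor or character vector over `FRIC_GROUPS`.
#' @param grid a [grid_search_spec()].
#' @param feature_set name of the feature set (metadata).
#' @return object of class `classifier_model`: pairwise SVMs, chosen `C` and
#'   `gamma`, the scaler, the CV accuracy table and class labels.
#' @export
train_svm <- function(features, labels, grid = grid_search_spec(),
                      feature_set = NA_character_) {
  X <- as.matrix(features)
  labels <- factor(as.character(labels), levels = FRIC_GROUPS)
  if (anyNA(labels)) stop("labels outside the three fricative groups")
  counts <- table(labels)
  if (any(counts == 0)) {
    stop("every class must be present in the training set")
  }
  if (any(counts < grid$folds)) {
    stop("need at least `folds` samples per class")
  }
  scaler <- list(center = colMeans(X), scale = apply(X, 2, stats::sd))
  if (all(scaler$scale < 1e-12)) stop("all feature dimensions are degenerate")
  scaler$scale[scaler$scale < 1e-12] <- 1
  Xs <- scale_apply(scaler, X)
  y_int <- as.integer(labels)

  # stratified seeded fold assignment
  fold <- integer(length(y_int))
  with_seed(grid$seed, for (cl in seq_along(levels(labels))) {
    idx <- which(y_int == cl)
    fold[idx] <- sample(rep_len(seq_len(grid$folds), length(idx)))
  })

  cv <- expand.grid(C = grid$C_grid, gamma = grid$gamma_grid)
  cv$accuracy <- NA_real_
  for (g in seq_along(grid$gamma_grid)) {
    gamma <- grid$gamma_grid[g]
    for (ci in seq_along(grid$C_grid)) {
      C <- grid$C_grid[ci]
      correct <- 0L
      for (f in seq_len(grid$folds)) {
        tr <- fold != f
        models <- ovo_fit(Xs[tr, , drop = FALSE], y_int[tr], C, gamma)
        pred <- ovo_predict_int(models, Xs[!tr, , drop = FALSE])
        correct <- correct + sum(pred == y_int[!tr])
      }
      cv$accuracy[cv$C == C & cv$gamma == gamma] <- correct / length(y_int)
    }
  }
  best <- cv[order(-cv$accuracy, cv$C, cv$gamma), ][1, ]
  models <- ovo_fit(Xs, y_int, best$C, best$gamma)
  structure(list(svms = models, C = best$C, gamma = best$gamma,
                 scaler = scaler, classes = FRIC_GROUPS,
                 feature_set = feature_set, cv_table = cv,
                 cv_accuracy = best$accuracy),
            class = "classifier_model")
}

#' @export
print.classifier_model <- function(x, ...) {
  cat(sprintf("<classifier_model: %s features, C = %g, gamma = %g, CV acc = %.1f%%>\n",
              x$feature_set, x$C, x$gamma, 100 * x$cv_accuracy))
  invisible(x)
}

#' Predict group labels for a feature matrix
#'
#' @param object a [train_svm()] model.
#' @param newdata numeric matrix of (already projected, unscaled) features.
#' @param ... unused.
#' @return list with factor `labels`, vote matrix and summed margin matrix.
#' @export
predict.classifier_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$scaler$center)) {
    stop("feature dimension does not match the trained model")
  }
  Xs <- scale_apply(object$scaler, X)
  d <- ovo_decision(object$svms, Xs)
  pred <- ovo_predict_int(object$svms, Xs)
  list(labels = factor(object$classes[pred], levels = object$classes),
       votes = d$votes, margin = d$margin)
}

#' Build the training set: clean + SSN-corrupted random frames
#'
#' For each token, one seeded random 8-ms frame is drawn from the clean
#' waveform and one from an SSN-corrupted copy (default +10 dB SNR), and the
#' configured feature set is computed for both.
#'
#' @param tokens list of [phone_token()] objects.
#' @param feature_set feature set name (default `"gt14"`).
#' @param ssn_snr_db training SNR against speech-shaped noise (default +10).
#' @param seed master seed; per-token sub-seeds are derived from it.
#' @param frame_ms frame length (default 8).
#' @param bank optional [gammatone_bank()] reused across frames.
#' @return list with `features` matrix (2 rows per token), factor `labels`
#'   and the `feature_set`.
#' @export
build_training_set <- function(tokens, feature_set = "gt14", ssn_snr_db = 10,
                               seed = 1, frame_ms = 8, bank = NULL) {
  stopifnot(length(tokens) > 0)
  fs <- tokens[[1]]$fs
  if (is.null(bank) && feature_set %in% c("gt14", "gt24")) {
    bank <- gammatone_bank(fs = fs)
  }
  max_len <- max(vapply(tokens, function(t) length(t$samples), integer(1)))
  ssn <- generate_ssn(max_len / fs + 0.5,
                      noise_spec("ssn", fs = fs, seed = child_seed(seed, 0)))
  feats <- vector("list", 2 * length(tokens))
  labs <- character(2 * length(tokens))
  for (i in seq_along(tokens)) {
    tok <- tokens[[i]]
    noisy <- mix_at_snr(tok, ssn, ssn_snr_db, seed = child_seed(seed, 2 * i))
    f_clean <- frame_token(tok, frame_ms, "random_one",
                           seed = child_seed(seed, 2 * i + 1))
    f_noisy <- frame_token(noisy, frame_ms, "random_one",
                           seed = child_seed(seed, 2 * i + 1))
    feats[[2 * i - 1]] <- compute_frame_features(f_clean[1, ], fs, feature_set, bank)
    feats[[2 * i]] <- compute_frame_features(f_noisy[1, ], fs, feature_set, bank)
    labs[c(2 * i - 1, 2 * i)] <- tok$group
  }
  list(features = do.call(rbind, feats),
       labels = factor(labs, levels = FRIC_GROUPS),
       feature_set = feature_set)
}

#' Classify a token by majority vote over its 8-ms frames
#'
#' Every non-overlapping 8-ms frame is featurized, optionally projected
#' through a frozen reduction model, standardized with the model's scaler and
#' labeled by the SVM. The token label is the modal frame label; ties break
#' by the largest summed one-vs-one decision margin, then the lowest class
#' index.
#'
#' @param model a [train_svm()] model.
#' @param token a [phone_token()].
#' @param reducer optional [fit_pca()]/[fit_kpca()] model.
#' @param bank optional [gammatone_bank()].
#' @param frame_ms frame length (default 8).
#' @return list with `group` (factor level) and `frame_labels`.
#' @export
classify_token <- function(model, token, reducer = NULL, bank = NULL,
                           frame_ms = 8) {
  fs <- token$fs
  feature_set <- model$feature_set
  if (is.null(bank) && feature_set %in% c("gt14", "gt24")) {
    bank <- gammatone_bank(fs = fs)
  }
  frames <- frame_token(token, frame_ms, "all")
  F <- t(apply(frames, 1, compute_frame_features, fs = fs,
               feature_set = feature_set, bank = bank))
  if (nrow(frames) == 1) F <- matrix(F, nrow = 1)
  if (!is.null(reducer)) F <- project(reducer, F)
  pred <- predict(model, F)
  tab <- tabulate(as.integer(pred$labels), nbins = length(model$classes))
  cand <- which(tab == max(tab))
  if (length(cand) > 1) {
    mg <- colSums(pred$margin[, cand, drop = FALSE])
    cand <- cand[mg == max(mg)]
  }
  list(group = factor(model$classes[cand[1]], levels = model$classes),
       frame_labels = pred$labels)
}
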