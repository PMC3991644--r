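# Scoring: overall accuracy, row-normalized confusion matrices, the
# Kruskal-Wallis feature screen and the Bernoulli confidence-interval bound.

#' Score a classification run
#'
#' @param true_groups,predicted_groups equal-length label vectors over
#'   `FRIC_GROUPS`.
#' @return list of class `confusion_matrix`: `counts` (3x3, rows = truth),
#'   `row_percent`, `accuracy`. Rows absent from the truth get 0 percent and
#'   are flagged in attribute `empty_rows`.
#' @export
score_run <- function(true_groups, predicted_groups) {
  truth <- factor(as.character(true_groups), levels = FRIC_GROUPS)
  pred <- factor(as.character(predicted_groups), levels = FRIC_GROUPS)
  if (length(truth) != length(pred)) stop("label sequences differ in length")
  if (length(truth) == 0) stop("empty label sequences")
  if (anyNA(truth) || anyNA(pred)) stop("labels outside the three groups")
  counts <- unclass(table(truth, pred))
  rs <- rowSums(counts)
  row_percent <- 100 * counts / ifelse(rs == 0, 1, rs)
  out <- list(counts = counts, row_percent = row_percent,
              accuracy = sum(diag(counts)) / sum(counts))
  attr(out, "empty_rows") <- FRIC_GROUPS[rs == 0]
  class(out) <- "confusion_matrix"
  out
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("Overall accuracy: %.1f%%\n", 100 * x$accuracy))
  cat("Row-normalized confusion matrix (%):\n")
  print(round(x$row_percent, 1))
  invisible(x)
}

#' Kruskal-Wallis rank test
#'
#' Rank-based H statistic with tie correction; the p-value uses the
#' chi-square approximation with `k - 1` degrees of freedom. Identical
#' values in all groups give `H = 0`, `p = 1`.
#'
#' @param values_by_group list of numeric vectors, one per group.
#' @return list with `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(values_by_group) {
  stopifnot(is.list(values_by_group), length(values_by_group) >= 2)
  sizes <- lengths(values_by_group)
  if (any(sizes < 1)) stop("each group needs at least one value")
  x <- unlist(values_by_group, use.names = FALSE)
  N <- length(x)
  if (N < 3) stop("need at least 3 values in total")
  r <- rank(x)
  g <- rep(seq_along(values_by_group), sizes)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (N + 1) / 2)^2))
  ties <- table(x)
  tie_corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (tie_corr <= 0) {
    H <- 0
  } else {
    H <- H / tie_corr
  }
  df <- length(values_by_group) - 1
  list(H = H, p = if (H == 0) 1 else pchisq(H, df, lower.tail = FALSE), df = df)
}

#' Width of the normal-approximation 95% Bernoulli confidence interval
#'
#' `width = 100 * 2 * 1.96 * sqrt(p * (1 - p) / n)` percentage points.
#'
#' @param p success proportion, strictly inside (0, 1). Vectorized.
#' @param n number of trials.
#' @return CI width in percentage points.
#' @export
bernoulli_ci_width <- function(p, n) {
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly inside (0, 1)")
  stopifnot(n >= 1)
  100 * 2 * 1.96 * sqrt(p * (1 - p) / n)
}

#' Feature screening report: per-group medians and Kruskal-Wallis p-values
#'
#' For every token one seeded random 8-ms frame is analyzed on clean speech
#' and the six knowledge-based features (M1-M4, peak P, slope S) are
#' computed. The report gives the median per group and the Kruskal-Wallis
#' p-value per feature.
#'
#' @param tokens list of [phone_token()] objects covering all three groups.
#' @param seed seed for the per-token frame draws.
#' @param frame_ms frame length (default 8).
#' @return data.frame with columns `feature`, `NONSIB`, `ALV`, `PAL`, `p`.
#' @export
feature_screening_report <- function(tokens, seed = 1, frame_ms = 8) {
  groups <- vapply(tokens, function(t) t$group, character(1))
  if (!all(FRIC_GROUPS %in% groups)) stop("all three groups must be present")
  vals <- t(vapply(seq_along(tokens), function(i) {
    tok <- tokens[[i]]
    fr <- frame_token(tok, frame_ms, "random_one", seed = child_seed(seed, i))
    s <- magnitude_spectrum(fr[1, ], tok$fs)
    c(spectral_moments(s), P = spectral_peak(s), S = spectral_slope(s))
  }, numeric(6)))
  colnames(vals) <- c("M1", "M2", "M3", "M4", "P", "S")
  out <- data.frame(feature = colnames(vals),
                    NONSIB = NA_real_, ALV = NA_real_, PAL = NA_real_,
                    p = NA_real_)
  for (j in seq_len(ncol(vals))) {
    by_group <- split(vals[, j], factor(groups, levels = FRIC_GROUPS))
    out[j, FRIC_GROUPS] <- vapply(by_group, median, numeric(1))
    out$p[j] <- kruskal_wallis(by_group)$p
  }
  out
}
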