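# Linear PCA and kernel PCA with eigenvalue-threshold dimension selection.
# Models are fit on training features and applied frozen to test features.

# Stable descending eigenvalue order with deterministic sign fixing: the
# largest-magnitude loading of each component is made positive.
fix_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

select_m <- function(eigenvalues, threshold, threshold_type) {
  cut <- if (threshold_type == "relative") threshold * sum(pmax(eigenvalues, 0))
         else threshold
  max(1L, sum(eigenvalues > cut))
}

#' Fit linear PCA
#'
#' Column means are removed, the covariance matrix (1/l normalization, a sum
#' over the dataset) is eigen-decomposed, and the retained dimension `m` is
#' the number of eigenvalues exceeding the threshold (at least 1).
#'
#' @param X numeric matrix, rows = observations.
#' @param threshold eigenvalue threshold; with `threshold_type = "relative"`
#'   (default) an eigenvalue is retained when it exceeds `threshold` times
#'   the eigenvalue sum (default 0.01).
#' @param threshold_type `"relative"` or `"absolute"`.
#' @return object of class `fric_pca`: `train_mean`, `components`
#'   (orthonormal columns), `eigenvalues` (descending), `m`, `threshold`.
#' @export
fit_pca <- function(X, threshold = 0.01,
                    threshold_type = c("relative", "absolute")) {
  threshold_type <- match.arg(threshold_type)
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2, all(is.finite(X)))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / nrow(X)
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  if (sum(ev) <= 1e-12 * ncol(X)) stop("rank-0 data: all rows are identical")
  V <- fix_signs(e$vectors)
  m <- select_m(ev, threshold, threshold_type)
  structure(list(kind = "LDR", train_mean = mu, components = V,
                 eigenvalues = ev, m = m, threshold = threshold,
                 threshold_type = threshold_type),
            class = "fric_pca")
}

# Kernel evaluation between row sets for the supported kernel specs.
kernel_matrix <- function(kernel, X, Y) {
  if (kernel$type == "linear") return(tcrossprod(X, Y))
  if (kernel$type == "rbf") return(cpp_rbf_kernel(X, Y, kernel$gamma))
  stop("unknown kernel type: ", kernel$type)
}

#' Median pairwise-distance RBF bandwidth heuristic
#'
#' `gamma = 1 / (2 * median(dist)^2)` over the pairwise Euclidean distances
#' of the training rows (subsampled to at most 500 rows).
#'
#' @param X numeric matrix.
#' @return scalar gamma.
#' @export
median_heuristic_gamma <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) > 500) X <- X[seq(1, nrow(X), length.out = 500), , drop = FALSE]
  d <- stats::dist(X)
  m <- stats::median(d[d > 0])
  if (!is.finite(m) || m == 0) return(1)
  1 / (2 * m^2)
}

#' Fit kernel PCA
#'
#' The kernel matrix K over training rows is centered in feature space,
#' `G = K - 1K - K1 + 1K1` with `1` the l-by-l matrix of entries 1/l, and
#' eigen-decomposed. Dual coefficients are normalized so that projections
#' have unit self-consistency (with a linear kernel the projections equal
#' standard PCA projections up to component sign). Eigenvalues are reported
#' on the covariance scale (Gram eigenvalues divided by l) so the threshold
#' rule matches [fit_pca()].
#'
#' @param X numeric training matrix.
#' @param kernel list: `list(type = "rbf", gamma = NULL)` (gamma defaults to
#'   the median heuristic) or `list(type = "linear")`.
#' @param threshold,threshold_type as in [fit_pca()].
#' @return object of class `fric_kpca`: stored training rows, dual
#'   coefficients `alpha`, kernel spec, centering statistics, `eigenvalues`,
#'   `m`.
#' @export
fit_kpca <- function(X, kernel = list(type = "rbf", gamma = NULL),
                     threshold = 0.01,
                     threshold_type = c("relative", "absolute")) {
  threshold_type <- match.arg(threshold_type)
  X <- as.matrix(X)
  l <- nrow(X)
  stopifnot(l >= 2, all(is.finite(X)))
  if (kernel$type == "rbf" && is.null(kernel$gamma)) {
    kernel$gamma <- median_heuristic_gamma(X)
  }
  K <- kernel_matrix(kernel, X, X)
  row_mean <- rowMeans(K)
  tot_mean <- mean(K)
  G <- K - outer(row_mean, rep(1, l)) - outer(rep(1, l), row_mean) + tot_mean
  G <- (G + t(G)) / 2
  e <- eigen(G, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values), 1)) {
    stop("kernel matrix is not positive semidefinite")
  }
  ev <- pmax(e$values, 0)
  if (sum(ev) <= 1e-12 * l) stop("rank-0 data: all rows are identical")
  keep <- which(ev > 1e-12 * max(ev))
  V <- fix_signs(e$vectors[, keep, drop = FALSE])
  alpha <- sweep(V, 2, sqrt(ev[keep]), "/")   # unit-norm feature-space axes
  ev_cov <- ev / l
  m <- select_m(ev_cov[keep], threshold, threshold_type)
  structure(list(kind = "NLDR", X_train = X, alpha = alpha, kernel = kernel,
                 K_row_mean = row_mean, K_tot_mean = tot_mean,
                 eigenvalues = ev_cov, m = m, threshold = threshold,
                 threshold_type = threshold_type),
            class = "fric_kpca")
}

#' Project feature vectors through a fitted reduction model
#'
#' @param model a [fit_pca()] or [fit_kpca()] model.
#' @param x numeric vector (one observation) or matrix (rows).
#' @return projection matrix with `model$m` columns (a vector input returns a
#'   1-row matrix).
#' @export
project <- function(model, x) UseMethod("project")

#' @export
project.fric_pca <- function(model, x) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != length(model$train_mean)) stop("feature dimension mismatch")
  sweep(X, 2, model$train_mean) %*%
    model$components[, seq_len(model$m), drop = FALSE]
}

#' @export
project.fric_kpca <- function(model, x) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != ncol(model$X_train)) stop("feature dimension mismatch")
  Kt <- kernel_matrix(model$kernel, X, model$X_train)  # [n_test x l]
  Kt <- Kt - matrix(model$K_row_mean, nrow(Kt), ncol(Kt), byrow = TRUE) -
    rowMeans(Kt) + model$K_tot_mean
  Kt %*% model$alpha[, seq_len(model$m), drop = FALSE]
}

#' Serialize a reduction model to a portable JSON file
#'
#' @param model a `fric_pca` or `fric_kpca` model.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_projection_model <- function(model, path) {
  obj <- unclass(model)
  obj$schema <- "fricshape-projection-1"
  obj$class <- class(model)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a serialized reduction model
#'
#' @param path JSON path written by [write_projection_model()].
#' @return the restored model object.
#' @export
read_projection_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "fricshape-projection-1")) {
    stop("unrecognized projection model schema")
  }
  cls <- obj$class
  obj$schema <- NULL
  obj$class <- NULL
  for (f in c("components", "alpha", "X_train")) {
    if (!is.null(obj[[f]]) && !is.matrix(obj[[f]])) {
      obj[[f]] <- as.matrix(obj[[f]])
    }
  }
  structure(obj, class = cls)
}
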