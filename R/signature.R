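#' Fit a z-score scaler on training data
#'
#' Per-feature mean and standard deviation (denominator n - 1). Columns
#' with zero variance or any non-finite value are dropped and recorded in
#' the `dropped` field so they never enter selection.
#'
#' @param X numeric matrix or data.frame of raw features (rows = subjects).
#' @return A `z_scaler`: list with `center`, `scale`, `features`,
#'   `dropped`.
#' @export
fit_scaler <- function(X) {
  X <- as.matrix(X)
  ok_finite <- apply(X, 2, function(c) all(is.finite(c)))
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  keep <- ok_finite & is.finite(sdv) & sdv > 0
  structure(list(center = mu[keep], scale = sdv[keep],
                 features = colnames(X)[keep],
                 dropped = colnames(X)[!keep]),
            class = "z_scaler")
}

#' Apply a fitted scaler
#'
#' @param scaler a `z_scaler`.
#' @param X raw feature matrix containing at least the scaler's features.
#' @return z-scored matrix restricted to the scaler's feature set.
#' @export
apply_scaler <- function(scaler, X) {
  X <- as.matrix(X)
  miss <- setdiff(scaler$features, colnames(X))
  if (length(miss))
    stop("missing features: ", paste(head(miss, 3), collapse = ", "),
         call. = FALSE)
  sweep(sweep(X[, scaler$features, drop = FALSE], 2, scaler$center),
        2, scaler$scale, "/")
}

#' Gaussian LASSO by cyclic coordinate descent
#'
#' Minimises `(1/2n) ||y - b0 - X b||^2 + lambda * ||b||_1` by cyclic
#' coordinate descent with soft-thresholding, converging when the largest
#' absolute coefficient change in a sweep falls below `tol`. Deterministic
#' given inputs. Columns are used as supplied (callers z-score them);
#' the intercept is the mean of `y`.
#'
#' @param X standardized n x p feature matrix.
#' @param y numeric response (0/1 labels for classification use).
#' @param lambda penalty, a scalar or decreasing grid (warm starts).
#' @param tol convergence tolerance on coefficient changes.
#' @param maxit maximum sweeps per lambda.
#' @return For scalar lambda: list with `beta` (named), `intercept`,
#'   `lambda`. For a grid: list with `beta` (p x n_lambda), `intercept`,
#'   `lambda`.
#' @export
lasso_fit <- function(X, y, lambda, tol = 1e-7, maxit = 10000L) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("non-finite entries in X or y", call. = FALSE)
  if (nrow(X) < 2L || length(unique(y)) < 2L)
    stop("need at least two rows and both classes present", call. = FALSE)
  lambda <- as.numeric(lambda)
  fit <- cpp_lasso_path(X, as.numeric(y), lambda, tol, as.integer(maxit))
  rownames(fit$beta) <- colnames(X)
  if (length(lambda) == 1L)
    list(beta = setNames(fit$beta[, 1], colnames(X)),
         intercept = fit$intercept, lambda = lambda)
  else
    list(beta = fit$beta, intercept = fit$intercept, lambda = lambda)
}

#' The lambda that zeroes all coefficients
#'
#' `lambda_max = max_j |x_j' (y - mean(y))| / n`.
#'
#' @inheritParams lasso_fit
#' @return Scalar.
#' @export
lasso_lambda_max <- function(X, y) {
  X <- as.matrix(X)
  max(abs(crossprod(X, y - mean(y)))) / nrow(X)
}

#' Default lambda grid
#'
#' 100 log-spaced values from `lambda_max` down to `1e-4 * lambda_max`.
#'
#' @inheritParams lasso_fit
#' @param n_lambda grid size.
#' @param min_ratio smallest lambda as a fraction of `lambda_max`.
#' @return Decreasing numeric vector.
#' @export
lasso_lambda_grid <- function(X, y, n_lambda = 100L, min_ratio = 1e-4) {
  lmax <- lasso_lambda_max(X, y)
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
}

stratified_folds <- function(y, k, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  fold
}

#' Select lambda by stratified ten-fold cross-validation
#'
#' Minimises the mean cross-validated squared prediction error over the
#' lambda grid ("min" rule, default); the one-standard-error rule picks the
#' largest lambda within one SE of the minimum. Fold assignment is
#' stratified by class and seeded, so the selection is reproducible.
#'
#' @inheritParams lasso_fit
#' @param folds number of CV folds.
#' @param lambda_grid decreasing penalty grid (default
#'   [lasso_lambda_grid]).
#' @param seed fold-assignment seed.
#' @param rule `"min"` or `"1se"`.
#' @return List: `lambda` (selected), `cv_mse`, `cv_se`, `lambda_grid`,
#'   `rule`.
#' @export
cv_select_lambda <- function(X, y, folds = 10L, lambda_grid = NULL,
                             seed = 1L, rule = c("min", "1se")) {
  rule <- match.arg(rule)
  X <- as.matrix(X); y <- as.numeric(y)
  if (nrow(X) < folds) stop("fewer rows than folds", call. = FALSE)
  if (is.null(lambda_grid)) lambda_grid <- lasso_lambda_grid(X, y)
  fold <- stratified_folds(y, folds, seed)
  if (any(vapply(seq_len(folds),
                 function(f) length(unique(y[fold == f])) < 2L, logical(1))))
    stop("a fold lost one class; use fewer folds", call. = FALSE)
  errs <- matrix(NA_real_, length(y), length(lambda_grid))
  for (f in seq_len(folds)) {
    tr <- fold != f
    fit <- lasso_fit(X[tr, , drop = FALSE], y[tr], lambda_grid)
    pred <- sweep(X[!tr, , drop = FALSE] %*% fit$beta, 2, -fit$intercept)
    errs[!tr, ] <- (y[!tr] - pred)^2
  }
  mse <- colMeans(errs)
  se <- apply(errs, 2, sd) / sqrt(nrow(errs))
  best <- which.min(mse)
  lam <- if (rule == "min") lambda_grid[best] else
    lambda_grid[which(mse <= mse[best] + se[best])[1]]
  list(lambda = lam, cv_mse = mse, cv_se = se, lambda_grid = lambda_grid,
       rule = rule)
}

#' Build a radiomics signature from a LASSO fit
#'
#' Keeps the features with nonzero coefficients, in decreasing order of
#' absolute coefficient.
#'
#' @param fit a scalar-lambda [lasso_fit] result.
#' @param scaler the `z_scaler` fitted on the training data.
#' @return A `radiomics_signature`: list with `features`, `coefficients`,
#'   `lambda`, `intercept`, `scaler`.
#' @export
build_signature <- function(fit, scaler = NULL) {
  nz <- which(fit$beta != 0)
  ord <- nz[order(-abs(fit$beta[nz]))]
  structure(list(features = names(fit$beta)[ord],
                 coefficients = unname(fit$beta[ord]),
                 lambda = fit$lambda, intercept = fit$intercept,
                 scaler = scaler),
            class = "radiomics_signature")
}

#' @export
print.radiomics_signature <- function(x, ...) {
  cat(sprintf("<radiomics_signature: %d features, lambda = %.4g>\n",
              length(x$features), x$lambda))
  for (i in seq_along(x$features))
    cat(sprintf("  %+.5f x %s\n", x$coefficients[i], x$features[i]))
  invisible(x)
}

#' Score subjects with a signature
#'
#' `score = sum_i coef_i * z_i` over the signature's named features
#' (intercept excluded, matching the linear-combination form in which
#' radiomics signatures are reported). If the signature carries a scaler,
#' raw features are z-scored with it first; otherwise `X` must already be
#' z-scored.
#'
#' @param signature a `radiomics_signature`.
#' @param X feature matrix (or single named vector).
#' @return Numeric score per row.
#' @export
score_signature <- function(signature, X) {
  if (is.null(dim(X))) X <- matrix(X, 1, dimnames = list(NULL, names(X)))
  X <- as.matrix(X)
  miss <- setdiff(signature$features, colnames(X))
  if (length(miss))
    stop("missing features: ", paste(miss, collapse = ", "), call. = FALSE)
  Z <- if (!is.null(signature$scaler)) {
    sc <- signature$scaler
    i <- match(signature$features, sc$features)
    sweep(sweep(X[, signature$features, drop = FALSE], 2, sc$center[i]),
          2, sc$scale[i], "/")
  } else X[, signature$features, drop = FALSE]
  drop(Z %*% signature$coefficients)
}

#' Fit the full signature workflow on a training table
#'
#' z-scores the features, drops undefined (non-finite / zero-variance)
#' columns, selects lambda by stratified ten-fold CV unless a fixed value
#' is given, fits the LASSO at that lambda, and packages the result.
#'
#' @param X raw feature matrix (rows = training subjects).
#' @param y 0/1 labels (1 = PD).
#' @param lambda `"cv"` (default) or a fixed penalty.
#' @param seed CV fold seed.
#' @param rule CV selection rule, `"min"` or `"1se"`.
#' @return A `radiomics_signature`.
#' @export
fit_signature <- function(X, y, lambda = "cv", seed = 1L, rule = "min") {
  scaler <- fit_scaler(X)
  Z <- apply_scaler(scaler, X)
  y <- as.numeric(y)
  lam <- if (identical(lambda, "cv"))
    cv_select_lambda(Z, y, seed = seed, rule = rule)$lambda
  else as.numeric(lambda)
  fit <- lasso_fit(Z, y, lam)
  build_signature(fit, scaler)
}

#' The published five-feature PD signature
#'
#' The reference signature for discriminating Parkinson's disease from
#' normal controls on spatially normalised DAT-SPECT:
#' `-0.00863 * ih_median_putamen - 0.18100 * dzm_zdnu_3D_putamen
#'  - 0.02485 * ngl_dcnu_3D_putamen - 0.00001 * ngl_dcnu_norm_3D_putamen
#'  - 0.05259 * szm_lzlge_3D_CRpallidum`, selected at lambda = 0.0967.
#' It was derived on patient data, so it ships without z-score parameters:
#' supply a scaler fitted on your own cohort, or z-scored features.
#'
#' @return A `radiomics_signature` without a scaler.
#' @export
published_pd_signature <- function() {
  structure(list(
    features = c("ih_median_putamen", "dzm_zdnu_3D_putamen",
                 "ngl_dcnu_3D_putamen", "ngl_dcnu_norm_3D_putamen",
                 "szm_lzlge_3D_CRpallidum"),
    coefficients = c(-0.00863, -0.18100, -0.02485, -0.00001, -0.05259),
    lambda = 0.0967, intercept = NA_real_, scaler = NULL),
    class = "radiomics_signature")
}

#' Save / load a signature as JSON
#'
#' @param signature a `radiomics_signature`.
#' @param path JSON file path.
#' @export
write_signature <- function(signature, path) {
  obj <- list(features = signature$features,
              coefficients = signature$coefficients,
              lambda = signature$lambda, intercept = signature$intercept)
  if (!is.null(signature$scaler))
    obj$scaler <- list(features = signature$scaler$features,
                       center = unname(signature$scaler$center),
                       scale = unname(signature$scaler$scale))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  scaler <- NULL
  if (!is.null(obj$scaler))
    scaler <- structure(list(center = setNames(obj$scaler$center,
                                               obj$scaler$features),
                             scale = setNames(obj$scaler$scale,
                                              obj$scaler$features),
                             features = obj$scaler$features,
                             dropped = character(0)),
                        class = "z_scaler")
  structure(list(features = obj$features, coefficients = obj$coefficients,
                 lambda = obj$lambda, intercept = obj$intercept,
                 scaler = scaler),
            class = "radiomics_signature")
}
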