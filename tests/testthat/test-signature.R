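test_that("LASSO matches the soft-threshold closed form on an orthonormal design", {
  set.seed(21)
  n <- 4
  Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  X <- sqrt(n) * Q             # X'X = n I, so each penalised update is exact
  y <- rnorm(4, sd = 2)
  b_ols <- drop(crossprod(X, y - mean(y))) / n
  for (lam in c(0.05, 0.2, 0.6)) {
    fit <- lasso_fit(X, y, lam, tol = 1e-10)
    expected <- sign(b_ols) * pmax(abs(b_ols) - lam, 0)
    expect_equal(unname(fit$beta), expected, tolerance = 1e-8)
  }
})

test_that("all coefficients vanish at and above lambda_max", {
  set.seed(22)
  X <- scale(matrix(rnorm(30 * 8), 30, 8))
  y <- rbinom(30, 1, 0.5)
  lmax <- lasso_lambda_max(X, y)
  # at lambda_max itself the solution is zero up to float rounding of the
  # threshold; strictly above it is exactly zero
  expect_lt(max(abs(lasso_fit(X, y, lmax)$beta)), 1e-10)
  expect_true(all(lasso_fit(X, y, lmax * (1 + 1e-12))$beta == 0))
  expect_true(all(lasso_fit(X, y, lmax * 1.5)$beta == 0))
  expect_gt(sum(lasso_fit(X, y, lmax * 0.5)$beta != 0), 0)
})

test_that("unpenalised fit agrees with ordinary least squares", {
  set.seed(23)
  X <- matrix(rnorm(40 * 4), 40, 4)
  X <- scale(X)
  y <- rnorm(40)
  fit <- lasso_fit(X, y, 0, tol = 1e-12)
  ols <- coef(lm(y ~ X))
  expect_equal(unname(fit$beta), unname(ols[-1]), tolerance = 1e-6)
  expect_equal(fit$intercept, unname(ols[1]), tolerance = 1e-6)
})

test_that("coordinate descent agrees with an independent LASSO solver", {
  skip_if_not_installed("glmnet")
  set.seed(24)
  X <- scale(matrix(rnorm(60 * 25), 60, 25))
  y <- as.numeric(rbinom(60, 1, 0.4))
  lam <- 0.5 * lasso_lambda_max(X, y)
  fit <- lasso_fit(X, y, lam, tol = 1e-10)
  g <- glmnet::glmnet(X, y, family = "gaussian", lambda = lam,
                      standardize = FALSE, thresh = 1e-14)
  expect_equal(unname(fit$beta), as.vector(g$beta), tolerance = 1e-5)
})

test_that("the L1 norm shrinks monotonically along the lambda path", {
  set.seed(25)
  X <- scale(matrix(rnorm(50 * 20), 50, 20))
  y <- as.numeric(rbinom(50, 1, 0.5))
  grid <- lasso_lambda_grid(X, y, n_lambda = 40)
  path <- lasso_fit(X, y, grid)
  l1 <- colSums(abs(path$beta))
  expect_true(all(diff(l1) > -1e-9))  # grid is decreasing, norms grow
})

test_that("cross-validated lambda selection is reproducible and sane", {
  set.seed(26)
  n <- 100; p <- 50
  X <- scale(matrix(rnorm(n * p), n, p))
  y <- rep(c(0, 1), each = n / 2)
  a <- cv_select_lambda(X, y, seed = 7)
  b <- cv_select_lambda(X, y, seed = 7)
  expect_identical(a$lambda, b$lambda)
  # pure-noise labels: lambda lands at or near the top of the grid
  pos <- vapply(1:5, function(s) {
    set.seed(300 + s)
    Xs <- scale(matrix(rnorm(n * p), n, p))
    cv <- cv_select_lambda(Xs, sample(y), seed = s)
    which(cv$lambda_grid == cv$lambda)
  }, numeric(1))
  expect_gte(mean(pos <= 20), 0.6)
})

test_that("a dominant true predictor survives CV-selected shrinkage", {
  hits <- 0
  for (s in 1:20) {
    set.seed(400 + s)
    n <- 100; p <- 50
    X <- scale(matrix(rnorm(n * p), n, p))
    y <- as.numeric(X[, 3] + rnorm(n, 0, 0.3) > 0)
    cv <- cv_select_lambda(X, y, seed = s)
    fit <- lasso_fit(X, y, cv$lambda)
    if (fit$beta[3] != 0) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("signature scoring is the stated linear combination", {
  sig <- published_pd_signature()
  z1 <- setNames(rep(1, 5), sig$features)
  expect_equal(score_signature(sig, z1), sum(sig$coefficients))
  expect_equal(sum(sig$coefficients), -0.26708)  # sum of printed values
  z0 <- setNames(rep(0, 5), sig$features)
  expect_equal(score_signature(sig, z0), 0)
  expect_error(score_signature(sig, c(ih_median_putamen = 1)),
               "missing features")
})

test_that("published signature has the five printed coefficients", {
  sig <- published_pd_signature()
  expect_equal(sig$features,
               c("ih_median_putamen", "dzm_zdnu_3D_putamen",
                 "ngl_dcnu_3D_putamen", "ngl_dcnu_norm_3D_putamen",
                 "szm_lzlge_3D_CRpallidum"))
  expect_equal(sig$coefficients,
               c(-0.00863, -0.18100, -0.02485, -0.00001, -0.05259))
  expect_equal(sig$lambda, 0.0967)
  expect_true(all(sig$coefficients != 0))
})

test_that("scores are invariant to affine feature rescaling when refit", {
  set.seed(27)
  n <- 30; p <- 10
  X <- matrix(rnorm(n * p, 100, 15), n, p,
              dimnames = list(NULL, paste0("f", 1:p)))
  y <- as.numeric(rbinom(n, 1, 0.5))
  s1 <- fit_signature(X, y, lambda = 0.05)
  X2 <- sweep(sweep(X, 2, runif(p, 0.5, 2), "*"), 2, runif(p, -5, 5), "+")
  s2 <- fit_signature(X2, y, lambda = 0.05)
  expect_equal(score_signature(s1, X), score_signature(s2, X2),
               tolerance = 1e-6)
})

test_that("zero-variance and undefined columns never enter selection", {
  set.seed(28)
  X <- cbind(matrix(rnorm(40), 20, 2), const = 1, bad = NA_real_)
  colnames(X) <- c("a", "b", "const", "bad")
  sc <- fit_scaler(X)
  expect_setequal(sc$dropped, c("const", "bad"))
  expect_setequal(sc$features, c("a", "b"))
})

test_that("signatures round-trip through JSON", {
  set.seed(29)
  X <- matrix(rnorm(200), 20, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  y <- rep(c(0, 1), 10)
  sig <- fit_signature(X, y, lambda = 0.02)
  f <- tempfile(fileext = ".json")
  write_signature(sig, f)
  sig2 <- read_signature(f)
  expect_equal(sig2$features, sig$features)
  expect_equal(sig2$coefficients, sig$coefficients)
  expect_equal(score_signature(sig2, X), score_signature(sig, X))
  unlink(f)
})
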