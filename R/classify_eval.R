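#' Stratified train/test split
#'
#' Splits subject ids into train and test sets at the given ratio within
#' each class, so the class proportions are preserved to within one
#' subject. Deterministic under the seed.
#'
#' @param ids subject identifiers.
#' @param groups class label per id (e.g. `"NC"`/`"PD"`).
#' @param train_frac training fraction (default 0.7, the 7:3 split).
#' @param seed RNG seed.
#' @return List with `train` and `test` id vectors.
#' @export
stratified_split <- function(ids, groups, train_frac = 0.7, seed = 1L) {
  stopifnot(length(ids) == length(groups))
  if (train_frac <= 0 || train_frac >= 1)
    stop("train fraction must be in (0, 1)", call. = FALSE)
  tab <- table(groups)
  if (length(tab) < 2L || any(tab < 2L))
    stop("each class needs at least 2 members", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  train <- unlist(lapply(names(tab), function(cls) {
    x <- ids[groups == cls]
    sample(x, round(train_frac * length(x)))
  }), use.names = FALSE)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  list(train = train, test = setdiff(ids, train))
}

#' AUC as the Mann-Whitney U probability
#'
#' Probability that a positive subject scores above a negative one, with
#' ties counted one half.
#'
#' @param scores numeric decision scores.
#' @param labels 0/1 (or two-level) class labels; the larger level is
#'   positive.
#' @return AUC in `[0, 1]`.
#' @export
auc_mw <- function(scores, labels) {
  y <- as.integer(factor(labels)) - 1L
  if (length(unique(y)) < 2L)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong placement values: for each positive, the fraction of negatives it
# beats (ties half), and vice versa.
delong_placements <- function(scores, labels) {
  y <- as.integer(factor(labels)) - 1L
  sp <- scores[y == 1L]; sn <- scores[y == 0L]
  v10 <- vapply(sp, function(s) mean((s > sn) + 0.5 * (s == sn)), numeric(1))
  v01 <- vapply(sn, function(s) mean((sp > s) + 0.5 * (sp == s)), numeric(1))
  list(auc = mean(v10), v10 = v10, v01 = v01)
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors over the same subjects using the
#' DeLong placement-value covariance; two-sided normal p-value. Identical
#' score vectors give z = 0, p = 1.
#'
#' @param scores_a,scores_b paired decision scores.
#' @param labels class labels (shared).
#' @return List: `auc_a`, `auc_b`, `z`, `p`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(scores_b))
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  m <- length(pa$v10); n <- length(pa$v01)
  # a class with a single member has no estimable placement variance;
  # the covariance contribution degenerates to zero
  safe_cov <- function(a, b) {
    if (length(a) < 2L) matrix(0, 2, 2) else var(cbind(a, b))
  }
  s10 <- safe_cov(pa$v10, pb$v10)
  s01 <- safe_cov(pa$v01, pb$v01)
  S <- s10 / m + s01 / n
  v <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  d <- pa$auc - pb$auc
  if (v <= 0) {
    z <- if (abs(d) < 1e-12) 0 else sign(d) * Inf
  } else z <- d / sqrt(v)
  list(auc_a = pa$auc, auc_b = pb$auc, z = z,
       p = if (is.infinite(z)) 0 else 2 * stats::pnorm(-abs(z)))
}

#' DeLong confidence interval for one AUC
#'
#' `AUC +/- z * SE` with the DeLong standard error, truncated to `[0, 1]`.
#' A degenerate SE (perfect separation with no score variation) collapses
#' the interval to the point estimate.
#'
#' @param scores decision scores.
#' @param labels class labels.
#' @param level confidence level.
#' @return Named numeric: `auc`, `lo`, `hi`, `se`.
#' @export
delong_ci <- function(scores, labels, level = 0.95) {
  pl <- delong_placements(scores, labels)
  sv <- function(x) if (length(x) < 2L) 0 else var(x)
  se <- sqrt(sv(pl$v10) / length(pl$v10) + sv(pl$v01) / length(pl$v01))
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(auc = pl$auc, lo = max(0, pl$auc - z * se),
    hi = min(1, pl$auc + z * se), se = se)
}

#' Optimal cut-off by Youden's J on training data
#'
#' Scans midpoints between adjacent distinct training scores (plus outer
#' sentinels) and picks the threshold maximising J = sensitivity +
#' specificity - 1; ties take the lower threshold. The positive
#' orientation (whether PD scores high or low) is fixed from the training
#' group means and returned so test evaluation uses the same rule.
#'
#' @param scores training decision scores.
#' @param labels training labels (positive = second factor level, e.g.
#'   `"PD"`).
#' @return List: `threshold`, `direction` (+1 if positives score high),
#'   `J`.
#' @export
optimal_cutoff <- function(scores, labels) {
  y <- as.integer(factor(labels)) - 1L
  if (length(unique(y)) < 2L) stop("both classes required", call. = FALSE)
  if (length(unique(scores)) < 2L)
    stop("cut-off undefined: all scores equal", call. = FALSE)
  dir <- if (mean(scores[y == 1L]) >= mean(scores[y == 0L])) 1 else -1
  s <- dir * scores
  u <- sort(unique(s))
  cand <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  J <- vapply(cand, function(th) {
    sens <- mean(s[y == 1L] > th)
    spec <- mean(s[y == 0L] <= th)
    sens + spec - 1
  }, numeric(1))
  best <- which(J == max(J))[1]  # ties: lower threshold
  list(threshold = cand[best] * dir, direction = dir, J = max(J))
}

#' Confusion metrics at a fixed cut-off
#'
#' @param cutoff result of [optimal_cutoff] (or a list with `threshold`
#'   and `direction`).
#' @param scores test decision scores.
#' @param labels test labels.
#' @return Named numeric: `sensitivity`, `specificity`, `accuracy` in
#'   percent.
#' @export
confusion_at <- function(cutoff, scores, labels) {
  y <- as.integer(factor(labels)) - 1L
  s <- cutoff$direction * scores
  th <- cutoff$direction * cutoff$threshold
  pred <- as.integer(s > th)
  c(sensitivity = 100 * mean(pred[y == 1L] == 1L),
    specificity = 100 * mean(pred[y == 0L] == 0L),
    accuracy = 100 * mean(pred == y))
}

#' Wilcoxon rank-sum p-value for a group difference
#'
#' Two-sided; exact for small untied samples, normal approximation with
#' tie correction otherwise (the standard `wilcox.test` behaviour).
#' Completely tied data give p = 1.
#'
#' @param a,b numeric samples.
#' @return p-value.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  if (length(unique(c(a, b))) == 1L) return(1)
  suppressWarnings(stats::wilcox.test(a, b)$p.value)
}

#' Bonferroni correction
#'
#' @param p raw p-values.
#' @param m number of comparisons (default `length(p)`).
#' @return Adjusted p-values, capped at 1.
#' @export
bonferroni <- function(p, m = length(p)) pmin(1, p * m)

# --- classifiers ------------------------------------------------------

#' Fit one of the four reference classifiers
#'
#' The models and hyperparameters follow the reference configuration:
#' SVM with cubic polynomial kernel (cost 1, kernel scale 1), 1-nearest
#' neighbour with Euclidean (Minkowski exponent 2) distance, LDA without
#' shrinkage, and a decision tree with minimum leaf size 1 and minimum
#' split size 10. Each model exposes a continuous decision score so ROC
#' analysis is possible: SVM and LDA use the signed distance to the
#' decision boundary, the tree uses the leaf positive-class fraction, and
#' 1-NN uses the signed difference between the distance to the nearest
#' negative and nearest positive training neighbour (a documented scoring
#' rule, since a raw 1-NN vote is binary).
#'
#' @param kind `"SVM"`, `"KNN"`, `"LDA"` or `"DecisionTree"`.
#' @param X training feature matrix.
#' @param y training labels (factor; second level = positive).
#' @return A `striatal_classifier` with a [decision_score] method.
#' @export
fit_classifier <- function(kind = c("SVM", "KNN", "LDA", "DecisionTree"),
                           X, y) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  y <- factor(y)
  stopifnot(nlevels(y) == 2L)
  model <- switch(kind,
    SVM = e1071::svm(X, y, kernel = "polynomial", degree = 3, gamma = 1,
                     coef0 = 1, cost = 1, scale = FALSE),
    KNN = list(X = X, y = y),
    LDA = MASS::lda(X, grouping = y),
    DecisionTree = {
      df <- data.frame(y = y, X)
      rpart::rpart(y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(minbucket = 1,
                                                  minsplit = 10, cp = 0,
                                                  xval = 0))
    })
  structure(list(kind = kind, model = model, levels = levels(y),
                 features = colnames(X)),
            class = "striatal_classifier")
}

#' Continuous decision score of a fitted classifier
#'
#' Higher scores favour the positive (second) class.
#'
#' @param object a `striatal_classifier`.
#' @param X feature matrix of new subjects.
#' @return Numeric score per row.
#' @export
decision_score <- function(object, X) {
  X <- as.matrix(X)[, object$features, drop = FALSE]
  pos <- object$levels[2]
  switch(object$kind,
    SVM = {
      dv <- attr(predict(object$model, X, decision.values = TRUE),
                 "decision.values")
      # orient: column name is "lev1/lev2"; positive margin favours the
      # class named first
      if (startsWith(colnames(dv)[1], pos)) drop(dv) else -drop(dv)
    },
    KNN = {
      tr <- object$model$X
      ispos <- object$model$y == pos
      d2 <- outer(rowSums(X^2), rowSums(tr^2), `+`) - 2 * X %*% t(tr)
      d2[d2 < 0] <- 0
      dpos <- sqrt(apply(d2[, ispos, drop = FALSE], 1, min))
      dneg <- sqrt(apply(d2[, !ispos, drop = FALSE], 1, min))
      dneg - dpos
    },
    LDA = {
      pr <- predict(object$model, X)
      drop(pr$posterior[, pos])
    },
    DecisionTree = {
      pr <- predict(object$model, data.frame(X), type = "prob")
      drop(pr[, pos])
    })
}

#' Train the reference classifiers and evaluate on test sets
#'
#' For each model kind and each feature set (radiomics signature alone,
#' `SUR_putamen` alone, and the combination) trains on the training rows
#' and reports AUC with DeLong 95% CI per test set, plus the DeLong
#' p-value comparing SUR-alone with the combination on the same test
#' subjects.
#'
#' @param data data.frame with columns `group` (NC/PD), `set`
#'   (`"train"`, or a test-set name), `signature_score`, `SUR_putamen`.
#' @param kinds classifier kinds to fit.
#' @return data.frame: one row per model x feature set x test set with
#'   `auc`, `lo`, `hi`, and `p_sur_vs_combo`.
#' @export
train_and_evaluate <- function(data,
                               kinds = c("SVM", "KNN", "LDA",
                                         "DecisionTree")) {
  stopifnot(all(c("group", "set", "signature_score", "SUR_putamen") %in%
                  names(data)))
  data <- data[stats::complete.cases(
    data[, c("group", "set", "signature_score", "SUR_putamen")]), ]
  y <- factor(data$group, levels = c("NC", "PD"))
  fsets <- list(signature = "signature_score",
                SUR_putamen = "SUR_putamen",
                combination = c("signature_score", "SUR_putamen"))
  tr <- data$set == "train"
  test_sets <- setdiff(unique(data$set), "train")
  out <- list()
  for (kind in kinds) {
    scores <- lapply(fsets, function(cols) {
      fit <- fit_classifier(kind, as.matrix(data[tr, cols, drop = FALSE]),
                            y[tr])
      decision_score(fit, as.matrix(data[, cols, drop = FALSE]))
    })
    for (ts in test_sets) {
      sel <- data$set == ts
      dl <- delong_test(scores$SUR_putamen[sel], scores$combination[sel],
                        y[sel])
      for (fs in names(fsets)) {
        ci <- delong_ci(scores[[fs]][sel], y[sel])
        out[[length(out) + 1L]] <- data.frame(
          model = kind, features = fs, test_set = ts,
          auc = ci[["auc"]], lo = ci[["lo"]], hi = ci[["hi"]],
          p_sur_vs_combo = dl$p)
      }
    }
  }
  do.call(rbind, out)
}

#' ROC evaluation of the continuous indices
#'
#' Mirrors the semi-quantitative/signature evaluation layout: per index and
#' test set, Wilcoxon group-difference p, AUC with DeLong 95% CI, and
#' sensitivity/specificity/accuracy at the training-set Youden cut-off.
#'
#' @param data data.frame with `group`, `set`, and the index columns.
#' @param indices character vector of index column names.
#' @return data.frame, one row per index x test set.
#' @export
evaluate_indices <- function(data, indices) {
  y <- factor(data$group, levels = c("NC", "PD"))
  tr <- data$set == "train"
  test_sets <- setdiff(unique(data$set), "train")
  out <- list()
  for (ix in indices) {
    v <- data[[ix]]
    ok <- is.finite(v)
    cut <- optimal_cutoff(v[tr & ok], y[tr & ok])
    for (ts in test_sets) {
      sel <- data$set == ts & ok
      # orient by the training-set group means so an index that is *lower*
      # in PD is scored in its discriminative direction
      ci <- delong_ci(cut$direction * v[sel], y[sel])
      cm <- confusion_at(cut, v[sel], y[sel])
      out[[length(out) + 1L]] <- data.frame(
        index = ix, test_set = ts,
        p_wilcoxon = wilcoxon_rank_sum(v[sel][y[sel] == "NC"],
                                       v[sel][y[sel] == "PD"]),
        auc = ci[["auc"]], lo = ci[["lo"]], hi = ci[["hi"]],
        cutoff = cut$threshold,
        sensitivity = cm[["sensitivity"]],
        specificity = cm[["specificity"]],
        accuracy = cm[["accuracy"]])
    }
  }
  do.call(rbind, out)
}
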