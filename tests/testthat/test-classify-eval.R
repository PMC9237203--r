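test_that("stratified split preserves class proportions and is seeded", {
  ids <- sprintf("S%03d", 1:320)
  groups <- rep(c("NC", "PD"), c(81, 239))
  sp <- stratified_split(ids, groups, 0.7, seed = 5)
  g <- setNames(groups, ids)
  expect_equal(sum(g[sp$train] == "NC"), 57)
  expect_equal(sum(g[sp$train] == "PD"), 167)
  expect_equal(sum(g[sp$test] == "NC"), 24)
  expect_equal(sum(g[sp$test] == "PD"), 72)
  expect_length(intersect(sp$train, sp$test), 0)
  sp2 <- stratified_split(ids, groups, 0.7, seed = 5)
  expect_identical(sp, sp2)
  expect_false(identical(sp, stratified_split(ids, groups, 0.7, seed = 6)))
  expect_error(stratified_split(ids, groups, 1), "in \\(0, 1\\)")
  expect_error(stratified_split(c("a", "b"), c("NC", "PD"), 0.5),
               "at least 2")
})

test_that("AUC equals the pair-counting probability", {
  expect_equal(auc_mw(c(1, 3, 2, 4), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc_mw(c(1, 2, 9, 10), c(0, 0, 1, 1)), 1)
  expect_equal(auc_mw(rep(2, 6), rep(c(0, 1), 3)), 0.5)
  expect_error(auc_mw(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC agrees with ROC trapezoid integration on fuzzed inputs", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(10:60, 1)
    scores <- sample(round(rnorm(n), sample(0:2, 1)))  # induce ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(auc_mw(scores, labels),
                 oracle_auc_trapezoid(scores, labels), tolerance = 1e-12)
  }
})

test_that("label swap maps AUC to its complement and keeps DeLong |z|", {
  set.seed(32)
  s1 <- rnorm(40); s2 <- rnorm(40) + s1 / 2
  y <- rbinom(40, 1, 0.5)
  expect_equal(auc_mw(s1, y), 1 - auc_mw(s1, 1 - y), tolerance = 1e-12)
  d1 <- delong_test(s1, s2, y)
  d2 <- delong_test(s1, s2, 1 - y)
  expect_equal(abs(d1$z), abs(d2$z), tolerance = 1e-10)
})

test_that("DeLong test on identical scores is exactly null", {
  set.seed(33)
  s <- rnorm(30); y <- rbinom(30, 1, 0.5)
  d <- delong_test(s, s, y)
  expect_equal(d$z, 0)
  expect_equal(d$p, 1)
})

test_that("DeLong agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(34)
  y <- rbinom(60, 1, 0.5)
  s1 <- rnorm(60) + y; s2 <- rnorm(60) + 0.5 * y
  d <- delong_test(s1, s2, y)
  pr <- pROC::roc.test(pROC::roc(y, s1, quiet = TRUE, direction = "<"),
                       pROC::roc(y, s2, quiet = TRUE, direction = "<"),
                       method = "delong", paired = TRUE)
  expect_equal(d$p, pr$p.value, tolerance = 1e-8)
  ci <- delong_ci(s1, y)
  pci <- as.numeric(pROC::ci.auc(pROC::roc(y, s1, quiet = TRUE,
                                           direction = "<"),
                                 method = "delong"))
  expect_equal(unname(ci[c("lo", "auc", "hi")]), pci, tolerance = 1e-8)
})

test_that("DeLong p matches a bootstrap oracle on a fixed 10-subject set", {
  # frozen paired scores for 5 NC and 5 PD subjects
  y <- c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1)
  sa <- c(0.1, 0.4, 0.35, 0.8, 0.25, 0.7, 0.9, 0.6, 0.95, 0.5)
  sb <- c(0.2, 0.3, 0.5, 0.6, 0.1, 0.4, 0.8, 0.55, 0.85, 0.45)
  d <- delong_test(sa, sb, y)
  set.seed(35)
  n_boot <- 20000
  dauc <- replicate(n_boot, {
    i0 <- sample(which(y == 0), 5, replace = TRUE)
    i1 <- sample(which(y == 1), 5, replace = TRUE)
    i <- c(i0, i1)
    auc_mw(sa[i], y[i]) - auc_mw(sb[i], y[i])
  })
  z_boot <- (d$auc_a - d$auc_b) / sd(dauc)
  p_boot <- 2 * pnorm(-abs(z_boot))
  expect_equal(d$p, p_boot, tolerance = 0.02)
})

test_that("Bonferroni correction multiplies and caps at one", {
  expect_equal(bonferroni(0.02, 4), 0.08)
  expect_equal(bonferroni(0.4, 4), 1)
  expect_equal(bonferroni(c(0.01, 0.5)), c(0.02, 1))
})

test_that("Youden cut-off picks the boundary between separable groups", {
  scores <- c(1, 2, 3, 4, 5, 6)
  labels <- rep(c("NC", "PD"), each = 3)
  cut <- optimal_cutoff(scores, labels)
  expect_gt(cut$threshold, 3)
  expect_lt(cut$threshold, 4)
  expect_equal(cut$J, 1)
  cm <- confusion_at(cut, c(0.5, 1.5, 2.5, 4.5, 5.5, 6.5), labels)
  expect_equal(unname(cm), c(100, 100, 100))  # equally separable test set
  expect_error(optimal_cutoff(rep(1, 4), c("NC", "NC", "PD", "PD")),
               "all scores equal")
})

test_that("cut-off orientation follows the training group means", {
  # PD scores *lower*: orientation must flip
  scores <- c(6, 5, 4, 3, 2, 1)
  labels <- rep(c("NC", "PD"), each = 3)
  cut <- optimal_cutoff(scores, labels)
  expect_equal(cut$direction, -1)
  cm <- confusion_at(cut, scores, labels)
  expect_equal(unname(cm), c(100, 100, 100))
})

test_that("Wilcoxon rank-sum behaves as specified", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(wilcoxon_rank_sum(rep(2, 5), rep(2, 7)), 1)
  set.seed(36)
  expect_lt(wilcoxon_rank_sum(rnorm(200), rnorm(200) + 2), 1e-3)
})

test_that("all four classifiers separate linearly separable data", {
  set.seed(37)
  n <- 40
  X <- rbind(matrix(rnorm(n, -3, 0.5), n / 2, 2),
             matrix(rnorm(n, 3, 0.5), n / 2, 2))
  colnames(X) <- c("u", "v")
  y <- factor(rep(c("NC", "PD"), each = n / 2))
  Xt <- rbind(matrix(rnorm(20, -3, 0.5), 10, 2),
              matrix(rnorm(20, 3, 0.5), 10, 2))
  colnames(Xt) <- c("u", "v")
  yt <- rep(c("NC", "PD"), each = 10)
  for (k in c("SVM", "KNN", "LDA", "DecisionTree")) {
    fit <- fit_classifier(k, X, y)
    expect_equal(auc_mw(decision_score(fit, Xt), yt), 1)
  }
})

test_that("permuted labels give chance-level AUCs", {
  set.seed(38)
  aucs <- replicate(20, {
    n <- 160
    X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("u", "v")))
    y <- factor(rep(c("NC", "PD"), each = n / 2))
    tr <- sample(n, n / 2)
    fit <- fit_classifier("LDA", X[tr, ], y[tr])
    auc_mw(decision_score(fit, X[-tr, ]), y[-tr])
  })
  expect_true(all(aucs > 0.3 & aucs < 0.7))
  expect_gt(mean(aucs > 0.35 & aucs < 0.65), 0.8)
})

test_that("DeLong p-values are uniform under a permutation null", {
  set.seed(39)
  y <- rep(c(0, 1), each = 30)
  ps <- replicate(200, {
    s1 <- rnorm(60); s2 <- rnorm(60)
    delong_test(s1, s2, y)$p
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
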