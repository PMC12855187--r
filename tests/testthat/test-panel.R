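table3_means <- function(group) {
  p <- psa_group_params()
  if (group == "HC") p$mean_hc else p$mean_psa
}

test_that("the published panel separates the two group mean vectors across the 0.38 cutoff", {
  panel <- published_panel()
  expect_equal(panel$intercept, -61.645)
  expect_equal(panel$threshold, 0.38)
  hc <- as.data.frame(t(table3_means("HC")))
  psa <- as.data.frame(t(table3_means("PsA")))
  s_hc <- score_fixed_panel(hc, panel)
  s_psa <- score_fixed_panel(psa, panel)
  # frozen from independent arithmetic: logit(HC) = 2.6779, logit(PsA) = -2.2617
  expect_equal(qlogis(s_hc$P), 2.677884, tolerance = 1e-6)
  expect_equal(qlogis(s_psa$P), -2.261746, tolerance = 1e-6)
  expect_gt(s_hc$P, 0.38)
  expect_lt(s_psa$P, 0.38)
  expect_equal(s_hc$call, "HC")
  expect_equal(s_psa$call, "other")
})

test_that("the fixed-panel scorer is a pure monotone function of its inputs", {
  panel <- published_panel()
  base <- as.data.frame(t(table3_means("PsA")))
  up <- base; up$leucine <- up$leucine + 1
  expect_gt(score_fixed_panel(up, panel)$P, score_fixed_panel(base, panel)$P)
  # zero coefficients give P = 0.5 everywhere
  null_panel <- list(intercept = 0,
                     coefficients = setNames(rep(0, 9), names(panel$coefficients)),
                     threshold = 0.38, positive_class = "HC")
  expect_equal(score_fixed_panel(base, null_panel)$P, 0.5)
  expect_error(score_fixed_panel(base[, setdiff(colnames(base), "leucine")],
                                 panel), "missing panel")
})

test_that("the IRLS logistic fit matches glm on well-conditioned data", {
  set.seed(4)
  n <- 120
  X <- data.frame(m1 = rnorm(n), m2 = rnorm(n))
  eta <- -0.3 + 1.2 * X$m1 - 0.8 * X$m2
  y <- ifelse(runif(n) < plogis(eta), "HC", "PsA")
  fit <- fit_logistic_panel(X, y, positive = "HC")
  ref <- glm(I(y == "HC") ~ m1 + m2, data = X, family = binomial())
  expect_equal(unname(fit$intercept), unname(coef(ref)[1]), tolerance = 1e-4)
  expect_equal(unname(fit$coefficients), unname(coef(ref)[-1]),
               tolerance = 1e-4)
  expect_false(fit$separated)
  # MLE score equation: fitted probabilities sum to the positive count
  expect_equal(sum(fit$fitted), sum(y == "HC"), tolerance = 1e-6)
})

test_that("complete separation is detected and still returns finite coefficients", {
  X <- data.frame(m = c(1, 2, 3, 10, 11, 12))
  y <- c("PsA", "PsA", "PsA", "HC", "HC", "HC")
  fit <- fit_logistic_panel(X, y, positive = "HC")
  expect_true(fit$separated)
  expect_true(all(is.finite(c(fit$intercept, fit$coefficients))))
  expect_equal(fit$auc, 1)
  expect_error(fit_logistic_panel(data.frame(m = rep(1, 6)), y), "constant")
})

test_that("balanced symmetric single-predictor data yields a near-zero intercept at x = 0", {
  X <- data.frame(m = c(-3, -2, -1, 1, 2, 3, -3, -2, -1, 1, 2, 3))
  y <- rep(c("a", "b"), each = 6)
  # classes overlap symmetrically: P(0) must be 0.5
  X$m[y == "b"] <- -X$m[y == "b"]
  fit <- fit_logistic_panel(X, y, positive = "b")
  expect_equal(fit$intercept, 0, tolerance = 1e-6)
})

test_that("ROC curve has the required shape and equals the rank statistic", {
  expect_equal(roc_curve(c(1, 2, 3, 11, 12, 13),
                         c("n", "n", "n", "p", "p", "p"),
                         positive = "p")$auc, 1)
  set.seed(14)
  big <- roc_curve(rnorm(2000), rep(c("n", "p"), 1000), positive = "p")
  expect_equal(big$auc, 0.5, tolerance = 0.05)
  for (i in 1:8) {
    scores <- sample(1:6, 30, replace = TRUE)  # heavy ties
    labels <- sample(c("n", "p"), 30, replace = TRUE, prob = c(0.5, 0.5))
    if (length(unique(labels)) < 2) next
    rc <- roc_curve(scores, labels, positive = "p")
    expect_equal(rc$points$fpr[1], 0); expect_equal(rc$points$tpr[1], 0)
    expect_equal(rc$points$fpr[nrow(rc$points)], 1)
    expect_equal(rc$points$tpr[nrow(rc$points)], 1)
    expect_true(all(diff(rc$points$fpr) >= 0))
    expect_true(all(diff(rc$points$tpr) >= 0))
    # AUC/U identity, ties counted half
    u <- mann_whitney(scores[labels == "p"], scores[labels == "n"])$U
    expect_equal(rc$auc, u / (sum(labels == "p") * sum(labels == "n")),
                 tolerance = 1e-12)
  }
  expect_error(roc_curve(1:4, rep("p", 4)), "two classes")
})

test_that("relabeling classes reflects the AUC around one half", {
  set.seed(24)
  scores <- rnorm(40); labels <- rep(c("n", "p"), 20)
  a1 <- roc_curve(scores, labels, positive = "p")$auc
  a2 <- roc_curve(scores, labels, positive = "n")$auc
  expect_equal(a1 + a2, 1, tolerance = 1e-12)
})

test_that("DeLong interval matches the pROC reference and contains the AUC", {
  skip_if_not_installed("pROC")
  set.seed(34)
  scores <- c(rnorm(30), rnorm(35, 1))
  labels <- rep(c("n", "p"), c(30, 35))
  ci <- auc_ci(scores, labels, positive = "p")
  ref <- suppressMessages(pROC::ci.auc(pROC::roc(
    response = labels, predictor = scores, levels = c("n", "p"),
    direction = "<", quiet = TRUE), method = "delong"))
  expect_equal(ci[1], as.numeric(ref[1]), tolerance = 1e-6)
  expect_equal(ci[2], as.numeric(ref[3]), tolerance = 1e-6)
  auc <- roc_curve(scores, labels, positive = "p")$auc
  expect_true(ci[1] <= auc && auc <= ci[2])
})

test_that("confidence intervals are wider at smaller sample sizes", {
  set.seed(44)
  width <- function(n) {
    median(replicate(15, {
      scores <- c(rnorm(n), rnorm(n, 1))
      labels <- rep(c("n", "p"), each = n)
      diff(auc_ci(scores, labels, positive = "p"))
    }))
  }
  expect_gt(width(10), width(100))
})

test_that("degenerate AUC falls back to a bootstrap interval with a warning", {
  scores <- c(1:6, 11:16)
  labels <- rep(c("n", "p"), each = 6)
  expect_warning(ci <- auc_ci(scores, labels, positive = "p", seed = 3),
                 "bootstrap")
  # fully separated data stays separated in every stratified resample, so
  # the percentile interval legitimately collapses at 1
  expect_true(ci[1] >= 0 && ci[2] <= 1 && ci[1] <= ci[2])
})

test_that("Monte-Carlo CV is honest about overfitting and permutation p hits its floor", {
  sim <- simulate_cohort(seed = 55)
  rel <- relative_concentrations(sim$concentrations)
  sig <- significant_metabolites()
  val <- cv_and_permute(rel[, sig], sim$cohort$group, positive = "HC",
                        n_cv = 30, n_perm = 60, seed = 6)
  expect_lte(val$cv_auc_mean, val$resub_auc + 0.02)
  expect_equal(val$perm_p, 1 / 61)  # strong signal: attainable floor
  # reproducible under the seed
  val2 <- cv_and_permute(rel[, sig], sim$cohort$group, positive = "HC",
                         n_cv = 30, n_perm = 60, seed = 6)
  expect_equal(val$cv_auc, val2$cv_auc)
})

test_that("signal-free data yields an unremarkable permutation p", {
  set.seed(64)
  ps <- replicate(8, {
    X <- data.frame(m1 = rnorm(30), m2 = rnorm(30))
    y <- rep(c("a", "b"), 15)
    cv_and_permute(X, y, positive = "b", n_cv = 10, n_perm = 40,
                   seed = sample.int(1e6, 1))$perm_p
  })
  expect_gt(median(ps), 0.05)
})
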