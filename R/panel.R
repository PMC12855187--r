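#' Fit a logistic biomarker panel
#'
#' Maximum-likelihood logistic regression fitted by iteratively reweighted
#' least squares with a tiny ridge (1e-8) on the slope coefficients for
#' numerical stability at small n. Predictors are standardized internally and
#' coefficients back-transformed to the input scale. Complete or
#' quasi-complete separation is detected (all fitted probabilities pinned to
#' the class labels) and reported via the `separated` flag; coefficients are
#' still returned under the ridge.
#'
#' @param conc samples x metabolites table restricted to the panel predictors.
#' @param labels two-class label vector.
#' @param positive class coded y = 1 (default `"HC"` if present, else the
#'   second sorted class).
#' @param ridge ridge penalty on standardized slopes (default 1e-8).
#' @param max_iter,tol IRLS iteration control.
#' @return object of class `panel_model`: `intercept`, `coefficients`,
#'   `positive_class`, `threshold` (Youden-optimal on the training ROC),
#'   `fitted` (P per sample), `roc`, `auc`, `auc_ci`, `separated`.
#' @export
fit_logistic_panel <- function(conc, labels, positive = NULL, ridge = 1e-8,
                               max_iter = 100, tol = 1e-10) {
  X <- as.matrix(conc)
  if (is.null(positive))
    positive <- if ("HC" %in% labels) "HC" else NULL
  cls <- code_classes(labels, positive = positive)
  d <- cls$d
  if (min(table(d)) < 2) stop("need at least 2 samples per class")
  const <- which(apply(X, 2, stats::sd) == 0)
  if (length(const) > 0)
    stop("constant predictor(s): ", paste(colnames(X)[const], collapse = ", "))
  ctr <- colMeans(X); scl <- apply(X, 2, stats::sd)
  Z <- cbind(1, sweep(sweep(X, 2, ctr, "-"), 2, scl, "/"))
  pen <- diag(c(0, rep(ridge, ncol(X))))
  beta <- c(stats::qlogis(mean(d)), rep(0, ncol(X)))
  dev_old <- Inf
  for (it in seq_len(max_iter)) {
    eta <- as.vector(Z %*% beta)
    mu <- stats::plogis(eta)
    wts <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (d - mu) / wts
    beta <- solve(crossprod(Z, wts * Z) + pen, crossprod(Z, wts * z))
    mu_new <- stats::plogis(as.vector(Z %*% beta))
    dev <- -2 * sum(d * log(pmax(mu_new, 1e-300)) +
                    (1 - d) * log(pmax(1 - mu_new, 1e-300)))
    if (abs(dev - dev_old) < tol * (abs(dev) + 0.1)) break
    dev_old <- dev
  }
  beta <- as.vector(beta)
  slopes <- beta[-1] / scl
  intercept <- beta[1] - sum(slopes * ctr)
  fitted <- stats::plogis(intercept + as.vector(X %*% slopes))
  separated <- all(abs(d - fitted) < 1e-4)
  roc <- roc_curve(fitted, labels, positive = cls$classes["positive"])
  ci <- delong_ci(fitted, d, roc$auc)
  j <- roc$points$tpr - roc$points$fpr
  thr <- roc$points$threshold[which.max(j)]
  structure(list(intercept = intercept,
                 coefficients = stats::setNames(slopes, colnames(X)),
                 positive_class = unname(cls$classes["positive"]),
                 threshold = min(max(thr, 1e-6), 1 - 1e-6),
                 fitted = fitted, roc = roc, auc = roc$auc, auc_ci = ci,
                 separated = separated, deviance = dev, iterations = it),
            class = "panel_model")
}

#' @export
print.panel_model <- function(x, ...) {
  cat(sprintf("Logistic panel (%d metabolites, positive class = %s)\n",
              length(x$coefficients), x$positive_class))
  cat(sprintf("  AUC = %.3f (95%% CI %.3f-%.3f), threshold = %.3f%s\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$threshold,
              if (x$separated) "  [complete separation]" else ""))
  invisible(x)
}

#' Load the published nine-metabolite panel fixture
#'
#' The printed panel coefficients, intercept and 0.38 decision threshold ship
#' as a JSON fixture; healthy controls are the y = 1 class (confirmed by
#' evaluating the formula at the two group mean vectors).
#'
#' @param path fixture file (default: bundled).
#' @return list with `intercept`, `coefficients`, `threshold`,
#'   `positive_class`.
#' @export
published_panel <- function(path = system.file("extdata", "panel_psa_hc.json",
                                           package = "psametab")) {
  fx <- jsonlite::read_json(path, simplifyVector = TRUE)
  fx$coefficients <- unlist(fx$coefficients)
  fx
}

#' Score samples with a fixed-coefficient logistic panel
#'
#' Pure function of the inputs: P = plogis(intercept + sum(beta * x)); a
#' sample is called positive when P >= threshold.
#'
#' @param conc samples x metabolites table containing every panel metabolite.
#' @param panel a fixture list as returned by [published_panel()], or a
#'   `panel_model`.
#' @param threshold decision cutoff on P (default: the panel's own).
#' @return data.frame with `sample_id`, `P`, `call` (positive-class name or
#'   `"other"`).
#' @export
score_fixed_panel <- function(conc, panel = published_panel(), threshold = NULL) {
  beta <- if (inherits(panel, "panel_model")) panel$coefficients
          else panel$coefficients
  intercept <- panel$intercept
  pos <- panel$positive_class
  if (is.null(threshold)) threshold <- panel$threshold
  missing_met <- setdiff(names(beta), colnames(conc))
  if (length(missing_met) > 0)
    stop("missing panel metabolite(s): ", paste(missing_met, collapse = ", "),
         " (required: ", paste(names(beta), collapse = ", "), ")")
  X <- as.matrix(conc[, names(beta), drop = FALSE])
  P <- stats::plogis(intercept + as.vector(X %*% beta))
  data.frame(sample_id = if (is.null(rownames(conc)))
               seq_len(nrow(conc)) else rownames(conc),
             P = P, call = ifelse(P >= threshold, pos, "other"),
             stringsAsFactors = FALSE)
}

#' Empirical ROC curve and AUC
#'
#' Curve over all unique score thresholds (plus sentinels), with the trapezoid
#' AUC; tied scores produce diagonal segments so the AUC equals the
#' Mann-Whitney rank statistic U/(n1*n2) exactly, ties counted half.
#'
#' @param scores numeric scores, higher = more positive-like.
#' @param labels two-class labels.
#' @param positive class treated as positive (default second sorted class).
#' @return object of class `roc_curve`: `points` (threshold, fpr, tpr),
#'   `auc`, class counts.
#' @export
roc_curve <- function(scores, labels, positive = NULL) {
  cls <- code_classes(labels, positive = positive)
  d <- cls$d
  if (length(unique(d)) < 2) stop("both classes must be present")
  n1 <- sum(d == 1); n0 <- sum(d == 0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(tt) sum(scores >= tt & d == 1) / n1, numeric(1))
  fpr <- vapply(thr, function(tt) sum(scores >= tt & d == 0) / n0, numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
                 auc = auc, n_positive = n1, n_negative = n0,
                 positive_class = unname(cls$classes["positive"])),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: AUC = %.3f (%d positive / %d negative, positive = %s)\n",
              x$auc, x$n_positive, x$n_negative, x$positive_class))
  invisible(x)
}

#' Confidence interval for an AUC
#'
#' DeLong placement-variance interval by default; a stratified percentile
#' bootstrap (2000 replicates) is available and is used automatically, with a
#' warning, when the point AUC is degenerate (0 or 1) and the DeLong variance
#' collapses.
#'
#' @param scores,labels,positive as in [roc_curve()].
#' @param method `"delong"` or `"bootstrap"`.
#' @param level confidence level (default 0.95).
#' @param n_boot bootstrap replicates.
#' @param seed seed for the bootstrap.
#' @return length-2 numeric vector `c(lo, hi)`, clamped to [0, 1].
#' @export
auc_ci <- function(scores, labels, positive = NULL,
                   method = c("delong", "bootstrap"), level = 0.95,
                   n_boot = 2000, seed = NULL) {
  method <- match.arg(method)
  cls <- code_classes(labels, positive = positive)
  d <- cls$d
  if (min(sum(d == 1), sum(d == 0)) < 5)
    stop("need at least 5 samples per class for a CI")
  auc <- roc_curve(scores, labels, positive = cls$classes["positive"])$auc
  if (method == "delong" && (auc == 0 || auc == 1)) {
    warning("degenerate AUC; falling back to stratified bootstrap CI")
    method <- "bootstrap"
  }
  if (method == "delong") {
    ci <- delong_ci(scores, d, auc, level)
  } else {
    ci <- local_seed(seed, {
      i1 <- which(d == 1); i0 <- which(d == 0)
      reps <- vapply(seq_len(n_boot), function(b) {
        idx <- c(sample(i1, replace = TRUE), sample(i0, replace = TRUE))
        roc_curve(scores[idx], labels[idx],
                  positive = cls$classes["positive"])$auc
      }, numeric(1))
      stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                      names = FALSE)
    })
  }
  pmin(pmax(ci, 0), 1)
}

# DeLong placement-variance CI; degenerate AUC gives a zero-width variance
# and the interval collapses onto the point estimate.
delong_ci <- function(scores, d, auc, level = 0.95) {
  xs <- scores[d == 1]; ys <- scores[d == 0]
  psi <- outer(xs, ys, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(psi); v01 <- colMeans(psi)
  v <- stats::var(v10) / length(xs) + stats::var(v01) / length(ys)
  z <- stats::qnorm(1 - (1 - level) / 2)
  pmin(pmax(auc + c(-1, 1) * z * sqrt(v), 0), 1)
}

#' Monte-Carlo cross-validation and label-permutation guard for a panel
#'
#' The "100-fold cross-validation" of the discovery workflow is interpreted as
#' 100 stratified Monte-Carlo 2:1 train/test splits (a literal 100-fold scheme
#' is impossible at n = 62): the panel is refitted on each training split and
#' the AUC measured on the held-out third. The permutation guard refits the
#' panel on label-shuffled data and reports
#' p = (1 + #\{permuted AUC >= observed\}) / (n_perm + 1).
#'
#' @param conc samples x metabolites table.
#' @param labels two-class labels.
#' @param positive positive class (see [fit_logistic_panel()]).
#' @param n_cv number of Monte-Carlo splits (>= 10).
#' @param n_perm number of label permutations.
#' @param train_frac training fraction of each split (default 2/3).
#' @param seed integer seed.
#' @return list with `cv_auc` (vector), `cv_auc_mean`, `resub_auc`,
#'   `perm_auc` (vector), `perm_p`.
#' @export
cv_and_permute <- function(conc, labels, positive = NULL, n_cv = 100,
                           n_perm = 1000, train_frac = 2 / 3, seed = NULL) {
  if (n_cv < 10) stop("n_cv must be at least 10")
  X <- as.data.frame(conc)
  cls <- code_classes(labels, positive = positive)
  pos <- cls$classes["positive"]
  resub <- fit_logistic_panel(X, labels, positive = pos)
  local_seed(seed, {
    idx_by_class <- split(seq_along(labels), labels)
    one_split <- function() {
      tr <- unlist(lapply(idx_by_class, function(ix)
        sample(ix, max(2, round(train_frac * length(ix))))))
      te <- setdiff(seq_along(labels), tr)
      if (length(unique(labels[te])) < 2) return(NA_real_)
      fit <- fit_logistic_panel(X[tr, , drop = FALSE], labels[tr],
                                positive = pos)
      sc <- score_fixed_panel(X[te, , drop = FALSE], fit, threshold = 0.5)
      roc_curve(sc$P, labels[te], positive = pos)$auc
    }
    cv_auc <- numeric(0)
    while (length(cv_auc) < n_cv) {
      a <- one_split()
      if (!is.na(a)) cv_auc <- c(cv_auc, a)
    }
    perm_auc <- vapply(seq_len(n_perm), function(i) {
      fit_logistic_panel(X, sample(labels), positive = pos)$auc
    }, numeric(1))
    list(cv_auc = cv_auc, cv_auc_mean = mean(cv_auc),
         resub_auc = resub$auc, perm_auc = perm_auc,
         perm_p = (1 + sum(perm_auc >= resub$auc)) / (n_perm + 1))
  })
}
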