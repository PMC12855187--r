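#' Fit a two-class OPLS-DA model
#'
#' Orthogonal projections to latent structures discriminant analysis, fitted
#' by the orthogonal-signal-correction NIPALS iteration: for each orthogonal
#' component, the loading of a provisional predictive component is split into
#' its class-correlated and class-orthogonal parts, the orthogonal part is
#' normalized into a weight vector, and the corresponding score/loading pair
#' is deflated from X; one predictive PLS component is then fitted on the
#' filtered matrix. With a single response column the NIPALS inner loop
#' converges in one pass, so the fit is fully deterministic.
#'
#' The class label is coded as a single centered dummy column; `R2X` is the
#' cumulative fraction of X-variation captured by all extracted components
#' (predictive plus orthogonal) and `R2Y` the fraction of class-variation
#' explained by the predictive component.
#'
#' @param X centered (typically Pareto-scaled) samples x variables matrix.
#' @param y two-class factor/character/logical vector, >= 3 samples per class.
#' @param n_orthogonal number of orthogonal components to remove (default 1).
#' @return object of class `opls_model` with predictive `w`, `p`, `t`, `c`,
#'   orthogonal `W_o`, `P_o`, `T_o`, `R2X_cum`, `R2Y_cum`, `Q2_cum` (NA until
#'   cross-validated), class coding, and fitted values.
#' @export
fit_oplsda <- function(X, y, n_orthogonal = 1) {
  X <- as.matrix(X)
  cls <- code_classes(y)
  tab <- table(cls$d)
  if (length(tab) < 2) stop("y must contain two classes")
  if (min(tab) < 3) stop("need at least 3 samples per class")
  if (max(abs(colMeans(X))) > 1e-6 * max(stats::sd(X), 1e-12))
    stop("X must be column-centered (e.g. Pareto-scaled) before fitting")
  yc <- cls$d - mean(cls$d)
  SSX <- sum(X^2)
  SSY <- sum(yc^2)
  Xf <- X
  p_vars <- ncol(X)
  W_o <- P_o <- matrix(0, p_vars, 0)
  T_o <- matrix(0, nrow(X), 0)
  r2x_parts <- numeric(0)
  for (a in seq_len(n_orthogonal)) {
    w <- crossprod(Xf, yc) / sum(yc^2)
    w <- w / sqrt(sum(w^2))
    tt <- Xf %*% w
    p <- crossprod(Xf, tt) / sum(tt^2)
    wo <- p - as.numeric(crossprod(w, p)) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12) {
      warning("no orthogonal variation left after ", a - 1,
              " component(s); stopping early")
      break
    }
    wo <- wo / nwo
    to <- Xf %*% wo
    po <- crossprod(Xf, to) / sum(to^2)
    Xf <- Xf - to %*% t(po)
    W_o <- cbind(W_o, wo); P_o <- cbind(P_o, po); T_o <- cbind(T_o, to)
    r2x_parts <- c(r2x_parts, sum(to^2) * sum(po^2) / SSX)
  }
  w <- crossprod(Xf, yc) / sum(yc^2)
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) stop("predictive weight vector degenerate (no covariance with y)")
  w <- w / nw
  tt <- Xf %*% w
  p <- crossprod(Xf, tt) / sum(tt^2)
  cc <- as.numeric(crossprod(tt, yc) / sum(tt^2))
  fitted <- as.vector(tt) * cc
  r2x_pred <- sum(tt^2) * sum(p^2) / SSX
  structure(list(
    w = as.vector(w), p = as.vector(p), t = as.vector(tt), c = cc,
    W_o = W_o, P_o = P_o, T_o = T_o,
    n_predictive = 1L, n_orthogonal = ncol(W_o),
    R2X_cum = r2x_pred + sum(r2x_parts),
    R2Y_cum = 1 - sum((yc - fitted)^2) / SSY,
    Q2_cum = NA_real_,
    SSX = SSX, SSY = SSY,
    classes = cls$classes, y_dummy = cls$d, y_center = mean(cls$d),
    fitted = fitted, variables = colnames(X)),
    class = "opls_model")
}

# Code a two-class label vector as a 0/1 dummy (second sorted level = 1).
code_classes <- function(y, positive = NULL) {
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2) stop("y must contain exactly two classes")
  positive <- if (is.null(positive)) classes[2] else unname(positive)
  if (!positive %in% classes) stop("positive class '", positive, "' not in y")
  list(d = as.numeric(y == positive),
       classes = c(negative = setdiff(classes, positive), positive = positive))
}

#' Predict class scores for new samples from an OPLS-DA model
#'
#' Orthogonal components are removed from the new data in fitting order, then
#' the predictive score and the centered-dummy prediction are computed.
#'
#' @param object fitted `opls_model`.
#' @param newdata matrix on the same (scaled) variable space as the training X.
#' @param ... unused.
#' @return list with `score` (predictive t), `yhat` (centered-dummy scale),
#'   `class` (predicted labels at the 0 decision point).
#' @export
predict.opls_model <- function(object, newdata, ...) {
  Xn <- as.matrix(newdata)
  if (object$n_orthogonal > 0) {
    for (a in seq_len(object$n_orthogonal)) {
      to <- Xn %*% object$W_o[, a]
      Xn <- Xn - to %*% t(object$P_o[, a])
    }
  }
  tt <- as.vector(Xn %*% object$w)
  yhat <- tt * object$c
  cls <- ifelse(yhat + object$y_center > 0.5,
                object$classes["positive"], object$classes["negative"])
  list(score = tt, yhat = yhat, class = unname(cls))
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf("OPLS-DA model: %dP + %dO components (%s vs %s)\n",
              x$n_predictive, x$n_orthogonal,
              x$classes["negative"], x$classes["positive"]))
  cat(sprintf("  R2X(cum) = %.3f  R2Y(cum) = %.3f  Q2(cum) = %s\n",
              x$R2X_cum, x$R2Y_cum,
              ifelse(is.na(x$Q2_cum), "not cross-validated",
                     sprintf("%.3f", x$Q2_cum))))
  invisible(x)
}

# Deterministic round-robin fold assignment within class, by input order.
assign_folds <- function(y, folds) {
  f <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    f[idx] <- rep_len(seq_len(folds), length(idx))
  }
  f
}

#' Cross-validated predictive ability (Q2) of an OPLS-DA model
#'
#' Q2 = 1 - PRESS/SS over held-out predictions from a deterministic K-fold
#' scheme (folds assigned round-robin within class by input order). The whole
#' model, including the scaling, is refitted on each training fold and applied
#' to the held-out samples.
#'
#' @param X raw (unscaled) samples x variables matrix.
#' @param y two-class labels.
#' @param n_orthogonal orthogonal components.
#' @param folds number of folds (default 7).
#' @param scaling `"pareto"`, `"unit"` or `"center"`.
#' @return list with `Q2`, `press`, `ss`, `predictions` (held-out yhat on the
#'   dummy scale), `folds`.
#' @export
cross_validate_oplsda <- function(X, y, n_orthogonal = 1, folds = 7,
                                  scaling = "pareto") {
  X <- as.matrix(X)
  if (folds < 2) stop("folds must be >= 2")
  cls <- code_classes(y)
  d <- cls$d
  fold_id <- assign_folds(as.character(y), folds)
  dhat <- rep(NA_real_, length(y))
  for (k in sort(unique(fold_id))) {
    tr <- fold_id != k
    if (length(unique(d[tr])) < 2)
      stop("fold ", k, " leaves a single class in training; use fewer folds")
    sc <- pareto_scale(X[tr, , drop = FALSE], method = scaling)
    fit <- fit_oplsda(sc$scaled, y[tr], n_orthogonal = n_orthogonal)
    Xte <- apply_scaling(X[!tr, , drop = FALSE], sc$model)
    pr <- predict(fit, Xte)
    dhat[!tr] <- pr$yhat + fit$y_center
  }
  ss <- sum((d - mean(d))^2)
  press <- sum((d - dhat)^2)
  list(Q2 = 1 - press / ss, press = press, ss = ss,
       predictions = dhat, folds = fold_id)
}

#' Permutation validation of an OPLS-DA model
#'
#' Repeatedly shuffles the class labels while keeping X fixed, refits the
#' model and its cross-validation, and records the absolute correlation of
#' each permuted label vector with the original alongside the permuted R2Y
#' and Q2. Least-squares lines of R2Y and Q2 against the label correlation
#' (the unpermuted model is included at correlation 1) give the R2 and Q2
#' intercepts; a Q2 intercept below 0.05 is the usual validity criterion.
#'
#' @param X raw samples x variables matrix.
#' @param y two-class labels.
#' @param n_orthogonal,folds,scaling model specification, as in
#'   [cross_validate_oplsda()].
#' @param n_perm number of permutations (>= 20; 500 in routine use).
#' @param seed integer seed for the permutations.
#' @return object of class `permutation_summary`: per-permutation table
#'   (`correlation`, `R2Y`, `Q2`, first row = unpermuted model),
#'   `R2_intercept`, `Q2_intercept`, fitted line coefficients, `n_failed`.
#' @export
permutation_test <- function(X, y, n_orthogonal = 1, folds = 7,
                             scaling = "pareto", n_perm = 500, seed = NULL) {
  if (n_perm < 20) stop("n_perm must be at least 20")
  X <- as.matrix(X)
  d <- code_classes(y)$d
  dc <- d - mean(d)
  fit_one <- function(yy) {
    sc <- pareto_scale(X, method = scaling)
    fit <- fit_oplsda(sc$scaled, yy, n_orthogonal = n_orthogonal)
    cv <- cross_validate_oplsda(X, yy, n_orthogonal = n_orthogonal,
                                folds = folds, scaling = scaling)
    c(R2Y = fit$R2Y_cum, Q2 = cv$Q2)
  }
  orig <- fit_one(y)
  local_seed(seed, {
    rows <- vector("list", n_perm)
    n_failed <- 0L
    for (i in seq_len(n_perm)) {
      yp <- sample(y)
      dp <- code_classes(yp)$d - mean(code_classes(yp)$d)
      rr <- abs(stats::cor(dp, dc))
      res <- tryCatch(fit_one(yp), error = function(e) NULL)
      if (is.null(res)) { n_failed <- n_failed + 1L; next }
      rows[[i]] <- c(correlation = rr, res)
    }
    if (n_failed > 0)
      warning(n_failed, " permutation(s) failed to fit and were skipped")
    perm <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    tab <- rbind(c(correlation = 1, orig), perm)
    tab <- as.data.frame(tab)
    fit_r2 <- stats::lm(R2Y ~ correlation, data = tab)
    fit_q2 <- stats::lm(Q2 ~ correlation, data = tab)
    structure(list(table = tab,
                   R2_intercept = unname(stats::coef(fit_r2)[1]),
                   Q2_intercept = unname(stats::coef(fit_q2)[1]),
                   R2_line = stats::coef(fit_r2), Q2_line = stats::coef(fit_q2),
                   n_permutations = nrow(tab) - 1L, n_failed = n_failed),
              class = "permutation_summary")
  })
}

#' @export
print.permutation_summary <- function(x, ...) {
  cat(sprintf("Permutation test (%d permutations):\n", x$n_permutations))
  cat(sprintf("  R2 intercept = %.3f   Q2 intercept = %.3f %s\n",
              x$R2_intercept, x$Q2_intercept,
              ifelse(x$Q2_intercept < 0.05, "(valid model criterion met)",
                     "(Q2 intercept >= 0.05: possible overfit)")))
  invisible(x)
}

#' Variable importance in the projection (VIP)
#'
#' Predictive-component VIP: for a single predictive component this reduces to
#' `sqrt(p) * |w_j|` for unit-norm weights, so the mean squared VIP is exactly
#' 1. Variables with VIP > 1 are flagged as important for class separation.
#'
#' @param model fitted `opls_model`.
#' @return data.frame (class `vip_table`) with `variable`, `vip`, `selected`.
#' @export
vip <- function(model) {
  if (!inherits(model, "opls_model")) stop("model must be a fitted opls_model")
  p_vars <- length(model$w)
  v <- sqrt(p_vars) * abs(model$w) / sqrt(sum(model$w^2))
  out <- data.frame(
    variable = if (is.null(model$variables))
      sprintf("V%d", seq_len(p_vars)) else model$variables,
    vip = v, selected = v > 1, stringsAsFactors = FALSE)
  class(out) <- c("vip_table", "data.frame")
  out
}
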