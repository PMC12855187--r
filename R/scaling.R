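#' Pareto scaling of a data matrix
#'
#' Mean-centers every column and divides it by the square root of its sample
#' standard deviation (n-1 denominator), the usual chemometrics compromise
#' between raw and unit-variance data: after scaling, each column's variance
#' equals its original standard deviation, so abundant features are damped
#' without letting noise features dominate. Zero-variance columns become
#' all-zero and are flagged.
#'
#' @param X numeric matrix or data.frame (samples x variables), >= 2 rows.
#' @param method `"pareto"` (default), `"unit"` (autoscaling), or `"center"`.
#' @return list with `scaled` (matrix) and `model` (class `scaling_model`:
#'   `center`, `scale`, `method`, `zero_variance` flags), invertible via
#'   [invert_scaling()].
#' @export
pareto_scale <- function(X, method = c("pareto", "unit", "center")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("Pareto scaling needs at least 2 rows")
  ctr <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  zero <- sds <= 0
  scl <- switch(method,
                pareto = sqrt(sds),
                unit   = sds,
                center = rep(1, length(sds)))
  scl[zero] <- 1   # flagged columns are centered only (all zero anyway)
  model <- structure(list(center = ctr, scale = scl, method = method,
                          zero_variance = zero, sds = sds,
                          variables = colnames(X)),
                     class = "scaling_model")
  list(scaled = apply_scaling(X, model), model = model)
}

#' Apply a fitted scaling model to new data
#' @param X matrix with the same columns as the training data.
#' @param model a `scaling_model` from [pareto_scale()].
#' @return scaled matrix.
#' @export
apply_scaling <- function(X, model) {
  stopifnot(inherits(model, "scaling_model"))
  X <- as.matrix(X)
  sweep(sweep(X, 2, model$center, "-"), 2, model$scale, "/")
}

#' Invert a scaling transform
#' @param S scaled matrix.
#' @param model the `scaling_model` used to produce it.
#' @return matrix on the original scale.
#' @export
invert_scaling <- function(S, model) {
  stopifnot(inherits(model, "scaling_model"))
  sweep(sweep(as.matrix(S), 2, model$scale, "*"), 2, model$center, "+")
}
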