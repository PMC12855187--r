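#' Spearman rank correlation with confidence interval
#'
#' r is the Pearson correlation of midranks. The two-sided p-value is exact
#' (permutation distribution) for n <= 10 without ties, and otherwise uses the
#' t approximation on n - 2 degrees of freedom. The confidence interval uses
#' the Fisher z transform with the Spearman-specific standard error
#' sqrt(1.06 / (n - 3)).
#'
#' @param x,y paired numeric vectors, n >= 4.
#' @param level confidence level (default 0.95).
#' @return list with `r`, `p`, `ci` (lo, hi), `n`, `method`.
#' @export
spearman_cor <- function(x, y, level = 0.95) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant variable")
  r <- stats::cor(rank(x), rank(y))
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  exact <- n <= 10 && !ties
  p <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = exact,
                    alternative = "two.sided")$p.value)
  z <- atanh(min(max(r, -1 + 1e-12), 1 - 1e-12))
  se <- sqrt(1.06 / (n - 3))
  q <- stats::qnorm(1 - (1 - level) / 2)
  ci <- tanh(z + c(-1, 1) * q * se)
  list(r = r, p = min(p, 1), ci = ci, n = n,
       method = if (exact) "exact" else "t approximation")
}

#' Correlate a metabolite panel with the DAPSA disease-activity score
#'
#' Spearman correlation of each listed metabolite against the DAPSA score,
#' restricted to PsA samples with a recorded score. Output order follows the
#' input metabolite order.
#'
#' @param conc samples x metabolites table.
#' @param cohort cohort data.frame with `sample_id`, `group`, `dapsa`.
#' @param metabolites metabolite names to correlate (default: the nine
#'   significant panel metabolites present in `conc`).
#' @param level confidence level.
#' @return data.frame (class `correlation_result`): `metabolite`, `r`,
#'   `ci_lo`, `ci_hi`, `p`, `n`.
#' @export
correlate_panel <- function(conc, cohort,
                            metabolites = intersect(significant_metabolites(),
                                                    colnames(conc)),
                            level = 0.95) {
  conc <- as.data.frame(conc)
  missing_met <- setdiff(metabolites, colnames(conc))
  if (length(missing_met) > 0)
    stop("metabolites not in table: ", paste(missing_met, collapse = ", "))
  idx <- which(cohort$group == "PsA" & !is.na(cohort$dapsa))
  if (length(idx) == 0) stop("no PsA samples with a DAPSA score")
  dapsa <- cohort$dapsa[idx]
  rows <- lapply(metabolites, function(m) {
    s <- spearman_cor(conc[[m]][idx], dapsa, level = level)
    data.frame(metabolite = m, r = s$r, ci_lo = s$ci[1], ci_hi = s$ci[2],
               p = s$p, n = s$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("correlation_result", "data.frame")
  out
}
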