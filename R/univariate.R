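#' Relative metabolite concentrations
#'
#' Normalizes each sample's metabolite vector to its own total and rescales to
#' percent, so every row sums to 100. This is the working scale of the whole
#' tabular pipeline (the default generator parameters are already expressed on
#' it, which is why the group mean vectors sum to ~100); the operation is
#' idempotent.
#'
#' @param raw samples x metabolites table of non-negative concentrations.
#' @return table of the same shape; rows sum to 100.
#' @export
relative_concentrations <- function(raw) {
  X <- as.matrix(raw)
  if (any(X < 0)) stop("concentrations must be non-negative")
  totals <- rowSums(X)
  bad <- which(totals <= 0)
  if (length(bad) > 0)
    stop("zero total concentration for sample(s): ",
         paste(rownames(X)[bad], collapse = ", "))
  out <- 100 * X / totals
  as.data.frame(out)
}

#' Mann-Whitney U test for a two-group comparison
#'
#' Rank-sum test with midrank ties. The two-sided p-value is exact (by
#' enumeration) when both groups have at most 8 observations and there are no
#' ties, and otherwise uses the normal approximation with tie and continuity
#' corrections.
#'
#' @param x,y numeric observation vectors for the two groups (>= 2 each).
#' @return list with `U` (statistic for `x`), `p` (two-sided), `method`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 observations")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) <= 8 && length(y) <= 8
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; input order is preserved.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return adjusted p-values (elementwise >= input, capped at 1).
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Univariate group comparison over a metabolite panel
#'
#' For each metabolite: group means and SDs, Mann-Whitney U with two-sided
#' p-value, and BH-adjusted p across the tested family (by default the full
#' metabolite set handed in, mirroring a VIP-preselected panel). The
#' significance flag follows the reporting convention of the discovery study:
#' raw p < 0.05 with adjusted p <= 0.05.
#'
#' @param conc samples x metabolites table (relative concentrations).
#' @param groups group label per sample (two classes).
#' @param metabolites columns to test (default: all).
#' @param alpha significance level (default 0.05).
#' @return data.frame with per-metabolite summaries, class
#'   `univariate_result`.
#' @export
univariate_table <- function(conc, groups, metabolites = colnames(conc),
                             alpha = 0.05) {
  conc <- as.data.frame(conc)
  missing_met <- setdiff(metabolites, colnames(conc))
  if (length(missing_met) > 0)
    stop("metabolites not in table: ", paste(missing_met, collapse = ", "))
  cls <- sort(unique(as.character(groups)))
  if (length(cls) != 2) stop("groups must contain exactly two classes")
  g1 <- groups == cls[1]
  rows <- lapply(metabolites, function(m) {
    x1 <- conc[[m]][g1]; x2 <- conc[[m]][!g1]
    mw <- mann_whitney(x1, x2)
    data.frame(metabolite = m,
               mean_1 = mean(x1), sd_1 = stats::sd(x1),
               mean_2 = mean(x2), sd_2 = stats::sd(x2),
               U = mw$U, p = mw$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:5] <- c(paste0("mean_", cls[1]), paste0("sd_", cls[1]),
                       paste0("mean_", cls[2]), paste0("sd_", cls[2]))
  out$p_adj <- bh_adjust(out$p)
  out$significant <- out$p < alpha & out$p_adj <= alpha
  class(out) <- c("univariate_result", "data.frame")
  out
}
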