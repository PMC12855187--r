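#' Default cohort parameters for the PsA / HC simulation
#'
#' Group means and standard deviations of the 13 serum metabolites retained by
#' VIP selection in the reference PsA-vs-HC study, on the relative-concentration
#' scale (each metabolite as a percentage of the total quantified pool, so the
#' group mean vectors sum to ~100). These parameterize the synthetic cohort
#' generator; the metabolite-metabolite correlation is exchangeable with
#' coefficient `rho` because no covariance information is available for the
#' original cohort.
#'
#' @param rho exchangeable metabolite-metabolite correlation (default 0.1).
#' @param correlation optional full 13x13 correlation matrix overriding `rho`;
#'   must be symmetric positive definite with unit diagonal.
#' @return An object of class `group_params`: list with `metabolites`,
#'   `mean_psa`, `sd_psa`, `mean_hc`, `sd_hc`, `correlation`.
#' @export
psa_group_params <- function(rho = 0.1, correlation = NULL) {
  tab <- data.frame(
    metabolite = c("2-aminobutyrate", "alanine", "anserine", "glucose",
                   "glutamine", "glycylproline", "isoleucine", "leucine",
                   "methionine", "serine", "threonate", "tryptophan", "valine"),
    mean_psa = c(1.911, 7.010, 2.509, 52.43, 9.739, 4.353, 1.500, 2.601,
                 0.6879, 5.2170, 6.601, 1.252, 4.189),
    sd_psa   = c(0.314, 1.416, 0.739, 5.242, 2.817, 1.801, 0.245, 0.470,
                 0.207, 0.914, 1.109, 0.239, 0.837),
    mean_hc  = c(1.900, 8.402, 2.753, 48.340, 11.080, 3.411, 1.688, 3.124,
                 0.8190, 6.008, 6.412, 1.349, 4.769),
    sd_hc    = c(0.273, 1.499, 0.635, 3.514, 1.618, 1.127, 0.294, 0.508,
                 0.130, 0.729, 0.997, 0.217, 0.781),
    stringsAsFactors = FALSE
  )
  p <- nrow(tab)
  if (is.null(correlation)) {
    correlation <- matrix(rho, p, p)
    diag(correlation) <- 1
  }
  dimnames(correlation) <- list(tab$metabolite, tab$metabolite)
  obj <- structure(
    list(metabolites = tab$metabolite,
         mean_psa = stats::setNames(tab$mean_psa, tab$metabolite),
         sd_psa   = stats::setNames(tab$sd_psa, tab$metabolite),
         mean_hc  = stats::setNames(tab$mean_hc, tab$metabolite),
         sd_hc    = stats::setNames(tab$sd_hc, tab$metabolite),
         correlation = correlation),
    class = "group_params"
  )
  validate_group_params(obj)
  obj
}

validate_group_params <- function(params) {
  stopifnot(inherits(params, "group_params"))
  p <- length(params$metabolites)
  if (any(params$sd_psa <= 0) || any(params$sd_hc <= 0))
    stop("all standard deviations must be positive")
  R <- params$correlation
  if (!is.matrix(R) || nrow(R) != p || ncol(R) != p)
    stop("correlation must be a ", p, "x", p, " matrix")
  if (max(abs(R - t(R))) > 1e-10)
    stop("correlation matrix must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-10)
    stop("correlation matrix must have unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12)
    stop("correlation matrix is not positive definite (min eigenvalue ",
         format(min(ev)), ")")
  invisible(params)
}

#' Link between DAPSA disease activity and metabolite concentrations
#'
#' Specifies the rank correlations imposed between the simulated DAPSA score
#' of active-PsA patients and selected metabolites, and the marginal DAPSA
#' distribution: a left-truncated normal above the active-disease floor of 14,
#' with parent parameters solved so the truncated mean and SD match the
#' cohort's observed 25.2 (10.4).
#'
#' @param target_spearman named numeric vector of target Spearman correlations
#'   (defaults: alanine 0.384, leucine 0.487).
#' @param dapsa_mean,dapsa_sd target mean and SD of the truncated DAPSA
#'   distribution.
#' @param dapsa_floor exclusive lower bound (active disease cutoff).
#' @return object of class `dapsa_link`.
#' @export
dapsa_link <- function(target_spearman = c(alanine = 0.384, leucine = 0.487),
                       dapsa_mean = 25.2, dapsa_sd = 10.4, dapsa_floor = 14) {
  if (any(abs(target_spearman) >= 1))
    stop("target Spearman correlations must lie strictly inside (-1, 1)")
  if (dapsa_mean <= dapsa_floor)
    stop("dapsa_mean must exceed dapsa_floor")
  if (dapsa_sd <= 0) stop("dapsa_sd must be positive")
  structure(list(target_spearman = target_spearman,
                 dapsa_mean = dapsa_mean, dapsa_sd = dapsa_sd,
                 dapsa_floor = dapsa_floor),
            class = "dapsa_link")
}

#' The nine panel metabolites significant in both VIP and univariate screens
#' @return character vector of metabolite names.
#' @export
significant_metabolites <- function() {
  c("alanine", "glucose", "glutamine", "glycylproline", "isoleucine",
    "leucine", "methionine", "serine", "valine")
}
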