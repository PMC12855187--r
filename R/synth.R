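#' @importFrom stats rnorm dnorm pnorm qnorm setNames sd cor quantile
NULL

# Evaluate expr with a locally-seeded RNG, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Generate synthetic metabolite concentration tables for two groups
#'
#' Draws per-sample metabolite vectors from group-specific multivariate
#' Gaussians (means/SDs from `params`, common correlation structure),
#' truncated at zero by redrawing any sample with a negative entry. At the
#' default parameters the truncation mass is negligible, so sample moments
#' converge to the configured means and SDs.
#'
#' @param params a [psa_group_params()] object.
#' @param n_psa,n_hc group sizes (defaults 29 and 33, the study cohort).
#' @param seed integer seed; identical seeds give identical tables.
#' @return list with `concentrations` (samples x metabolites data.frame,
#'   rownames = sample ids) and `cohort` (data.frame `sample_id`, `group`).
#' @export
generate_concentrations <- function(params = psa_group_params(),
                                    n_psa = 29, n_hc = 33, seed = NULL) {
  validate_group_params(params)
  if (n_psa < 2 || n_hc < 2) stop("need at least 2 samples per group")
  local_seed(seed, {
    draw_group <- function(n, mu, sigma, R) {
      Sigma <- diag(sigma) %*% R %*% diag(sigma)
      X <- MASS::mvrnorm(n, mu = mu, Sigma = Sigma)
      X <- matrix(X, nrow = n)
      bad <- which(apply(X, 1, function(r) any(r < 0)))
      iter <- 0
      while (length(bad) > 0 && iter < 1000) {
        X[bad, ] <- matrix(MASS::mvrnorm(length(bad), mu = mu, Sigma = Sigma),
                           nrow = length(bad))
        bad <- bad[apply(X[bad, , drop = FALSE], 1, function(r) any(r < 0))]
        iter <- iter + 1
      }
      if (length(bad) > 0) stop("could not draw non-negative samples")
      X
    }
    Xp <- draw_group(n_psa, params$mean_psa, params$sd_psa, params$correlation)
    Xh <- draw_group(n_hc, params$mean_hc, params$sd_hc, params$correlation)
    X <- rbind(Xp, Xh)
    colnames(X) <- params$metabolites
    ids <- c(sprintf("PsA_%02d", seq_len(n_psa)), sprintf("HC_%02d", seq_len(n_hc)))
    rownames(X) <- ids
    cohort <- data.frame(sample_id = ids,
                         group = rep(c("PsA", "HC"), c(n_psa, n_hc)),
                         stringsAsFactors = FALSE)
    list(concentrations = as.data.frame(X), cohort = cohort)
  })
}

# Solve parent (mu, sigma) of a normal left-truncated at `floor` so the
# truncated distribution has the requested mean and SD. Parameterized by the
# standardized truncation point alpha = (floor - mu)/sigma, for which the
# SD/(mean - floor) ratio is monotone; solved by uniroot, then mu and sigma
# follow in closed form from the truncated-normal moment identities.
solve_truncnorm <- function(mean_target, sd_target, floor) {
  ratio <- sd_target / (mean_target - floor)
  if (!is.finite(ratio) || ratio <= 0 || ratio >= 1)
    stop("infeasible truncated-normal target: need 0 < sd/(mean - floor) < 1")
  mills <- function(a) dnorm(a) / pnorm(a, lower.tail = FALSE)
  f <- function(a) {
    lam <- mills(a)
    d <- lam - a
    sqrt(pmax(1 - lam * d, 0)) / d - ratio
  }
  a <- stats::uniroot(f, c(-10, 10), tol = 1e-12)$root
  lam <- mills(a)
  sigma <- (mean_target - floor) / (lam - a)
  mu <- floor - a * sigma
  list(mu = mu, sigma = sigma, alpha = a)
}

# Quantile function of the normal(mu, sigma) left-truncated at `floor`.
qtruncnorm_left <- function(u, mu, sigma, floor) {
  p0 <- pnorm((floor - mu) / sigma)
  qnorm(p0 + u * (1 - p0)) * sigma + mu
}

#' Attach simulated DAPSA scores to the PsA arm of a synthetic cohort
#'
#' DAPSA is generated through a Gaussian copula: a latent standard normal is
#' drawn conditionally on the standardized (latent) scores of the linked
#' metabolites so that its Pearson correlation with each equals
#' `2*sin(pi*r_s/6)` (the exact Spearman-to-Pearson conversion for bivariate
#' Gaussian copulas), then mapped through the quantile function of a
#' left-truncated normal whose parent parameters are solved numerically so the
#' truncated distribution has the configured mean and SD above the floor.
#' Healthy controls receive `NA`.
#'
#' @param cohort cohort data.frame from [generate_concentrations()].
#' @param conc concentration data.frame from [generate_concentrations()].
#' @param link a [dapsa_link()] object.
#' @param params the [psa_group_params()] used to generate `conc` (supplies
#'   the PsA means/SDs used to standardize the linked metabolites, and their
#'   correlation block).
#' @param seed integer seed.
#' @return `cohort` with a `dapsa` column (NA for HC; all PsA values > floor).
#' @export
generate_dapsa <- function(cohort, conc, link = dapsa_link(),
                           params = psa_group_params(), seed = NULL) {
  stopifnot(is.data.frame(cohort), is.data.frame(conc))
  psa_idx <- which(cohort$group == "PsA")
  if (length(psa_idx) == 0) stop("cohort contains no PsA samples")
  met <- names(link$target_spearman)
  missing_met <- setdiff(met, colnames(conc))
  if (length(missing_met) > 0)
    stop("linked metabolites absent from concentration table: ",
         paste(missing_met, collapse = ", "))
  rho <- 2 * sin(pi * link$target_spearman / 6)   # latent Pearson targets
  R_ll <- params$correlation[met, met, drop = FALSE]
  b <- solve(R_ll, rho)
  resid_var <- 1 - sum(b * rho)
  if (resid_var <= 0) {
    worst <- met[which.max(abs(rho))]
    stop("infeasible joint correlation: latent matrix not positive definite ",
         "(offending target involves '", worst, "')")
  }
  cal <- solve_truncnorm(link$dapsa_mean, link$dapsa_sd, link$dapsa_floor)
  local_seed(seed, {
    Z <- sweep(sweep(as.matrix(conc[psa_idx, met, drop = FALSE]), 2,
                     params$mean_psa[met], "-"),
               2, params$sd_psa[met], "/")
    w <- as.vector(Z %*% b) + sqrt(resid_var) * rnorm(length(psa_idx))
    dapsa <- qtruncnorm_left(pnorm(w), cal$mu, cal$sigma, link$dapsa_floor)
    cohort$dapsa <- NA_real_
    cohort$dapsa[psa_idx] <- dapsa
    cohort
  })
}

#' Load the multiplet library used by the spectrum renderer
#'
#' The library is a plain TSV shipped with the package (editable by the user):
#' one row per multiplet with columns `metabolite`, `center_ppm`, `rel_area`,
#' `width_ppm`. Rows named `TSP` and `WATER` describe the chemical-shift
#' reference peak at 0.00 ppm and the residual-water band. Chemical shifts are
#' approximate literature values; downstream code relies only on internal
#' consistency of the library, never on literature exactness.
#'
#' @param path library TSV (default: the bundled file).
#' @param jitter_sd per-sample, per-multiplet position jitter SD in ppm
#'   (emulates pH-dependent shift variation).
#' @param noise_sd additive Gaussian baseline noise SD (intensity units).
#' @return object of class `spectral_library`.
#' @export
spectral_library <- function(path = system.file("extdata", "spectral_library.tsv",
                                                package = "psametab"),
                             jitter_sd = 0.005, noise_sd = 0.5) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("metabolite", "center_ppm", "rel_area", "width_ppm")
  if (!all(need %in% colnames(tab)))
    stop("spectral library must have columns: ", paste(need, collapse = ", "))
  if (any(tab$center_ppm < 0 | tab$center_ppm > 8.6))
    stop("multiplet centers must lie within 0.00-8.60 ppm")
  if (any(tab$rel_area <= 0)) stop("multiplet areas must be positive")
  special <- tab$metabolite %in% c("TSP", "WATER")
  structure(list(multiplets = tab[!special, , drop = FALSE],
                 tsp = tab[tab$metabolite == "TSP", , drop = FALSE],
                 water = tab[tab$metabolite == "WATER", , drop = FALSE],
                 jitter_sd = jitter_sd, noise_sd = noise_sd),
            class = "spectral_library")
}

#' Render synthetic 1D NMR spectra from a concentration table
#'
#' Each sample's spectrum is a sum of Lorentzian multiplets whose integrated
#' area is proportional to that sample's metabolite concentration, with
#' per-sample Gaussian position jitter on every multiplet (the pH effect), a
#' fixed TSP reference peak at 0.00 ppm, a broad residual-water band inside
#' 4.70-5.20 ppm, and additive Gaussian noise.
#'
#' @param conc samples x metabolites data.frame.
#' @param lib a [spectral_library()].
#' @param n_points number of axis points over 0.00-8.60 ppm (>= 2048).
#' @param seed integer seed.
#' @return a [spectrum_set()].
#' @export
render_spectra <- function(conc, lib = spectral_library(), n_points = 8192,
                           seed = NULL) {
  stopifnot(inherits(lib, "spectral_library"))
  if (n_points < 2048) stop("n_points must be at least 2048")
  missing_met <- setdiff(colnames(conc), unique(lib$multiplets$metabolite))
  if (length(missing_met) > 0)
    stop("no spectral library entry for: ", paste(missing_met, collapse = ", "))
  ppm <- seq(0, 8.6, length.out = n_points)
  n <- nrow(conc)
  mult <- lib$multiplets[lib$multiplets$metabolite %in% colnames(conc), ,
                         drop = FALSE]
  lorentz <- function(x, center, area, width) {
    hw <- width / 2
    (area / pi) * hw / ((x - center)^2 + hw^2)
  }
  local_seed(seed, {
    Y <- matrix(0, nrow = n, ncol = n_points)
    for (s in seq_len(n)) {
      y <- numeric(n_points)
      jit <- rnorm(nrow(mult), 0, lib$jitter_sd)
      for (m in seq_len(nrow(mult))) {
        a <- conc[s, mult$metabolite[m]] * mult$rel_area[m]
        if (a > 0)
          y <- y + lorentz(ppm, mult$center_ppm[m] + jit[m], a, mult$width_ppm[m])
      }
      if (nrow(lib$tsp) > 0)
        y <- y + lorentz(ppm, lib$tsp$center_ppm, lib$tsp$rel_area,
                         lib$tsp$width_ppm)
      if (nrow(lib$water) > 0) {
        # presaturation residual: Gaussian, so the band stays localized
        # inside the excluded window instead of spreading Lorentzian tails
        # across the whole spectrum
        sdw <- lib$water$width_ppm / (2 * sqrt(2 * log(2)))
        y <- y + lib$water$rel_area *
          stats::dnorm(ppm, lib$water$center_ppm, sdw)
      }
      if (lib$noise_sd > 0) y <- y + rnorm(n_points, 0, lib$noise_sd)
      Y[s, ] <- y
    }
    rownames(Y) <- rownames(conc)
    spectrum_set(ppm, Y)
  })
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper chaining [generate_concentrations()],
#' [generate_dapsa()] and optionally [render_spectra()], with per-stage seeds
#' derived deterministically from one global seed.
#'
#' @param params,link,lib generator parameter objects.
#' @param n_psa,n_hc group sizes.
#' @param spectra render spectra as well? (slower)
#' @param seed global integer seed.
#' @return list of class `synthetic_cohort`: `cohort`, `concentrations`,
#'   `spectra` (or NULL), `seed`, `params`, `link`.
#' @export
simulate_cohort <- function(params = psa_group_params(), link = dapsa_link(),
                            lib = spectral_library(), n_psa = 29, n_hc = 33,
                            spectra = FALSE, seed = 1) {
  seeds <- derive_seeds(seed, c("concentrations", "dapsa", "spectra"))
  gen <- generate_concentrations(params, n_psa, n_hc, seed = seeds["concentrations"])
  cohort <- generate_dapsa(gen$cohort, gen$concentrations, link, params,
                           seed = seeds["dapsa"])
  spec <- if (spectra)
    render_spectra(gen$concentrations, lib, seed = seeds["spectra"]) else NULL
  structure(list(cohort = cohort, concentrations = gen$concentrations,
                 spectra = spec, seed = seed, params = params, link = link),
            class = "synthetic_cohort")
}

# Stable per-stage seeds below 2^31, derived from a global seed and stage name.
derive_seeds <- function(seed, stages) {
  out <- vapply(stages, function(s) {
    h <- sum(utf8ToInt(s) * seq_along(utf8ToInt(s)))
    (as.integer(seed) %% 100000L) * 20011L + (h %% 19993L)
  }, numeric(1))
  setNames(as.integer(out %% 2^31), stages)
}
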