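#' Pipeline configuration
#'
#' Collects all stage parameters and the global seed for [run_pipeline()].
#' Per-stage seeds are derived deterministically from the global seed and the
#' stage name, so any stage can be re-run in isolation with identical output.
#'
#' @param seed global integer seed.
#' @param n_psa,n_hc simulated group sizes.
#' @param spectra run the spectral branch (render, bucket, normalize) or work
#'   on the concentration table directly.
#' @param bucket_width,looseness,region bucketing parameters (ppm).
#' @param exclude water-exclusion window `c(lo, hi)` in ppm.
#' @param scaling `"pareto"`, `"unit"` or `"center"`.
#' @param n_orthogonal,folds,n_perm_opls OPLS-DA stage parameters.
#' @param alpha univariate significance level.
#' @param n_cv,n_perm_panel panel-validation parameters.
#' @param out optional output directory; when set, [run_pipeline()] writes
#'   every intermediate artifact plus a JSON manifest there.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, n_psa = 29, n_hc = 33, spectra = TRUE,
                            bucket_width = 0.04, looseness = 0.5,
                            region = c(0.80, 8.50), exclude = c(4.70, 5.20),
                            scaling = "pareto", n_orthogonal = 1, folds = 7,
                            n_perm_opls = 500, alpha = 0.05, n_cv = 100,
                            n_perm_panel = 1000, out = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full discovery pipeline on a synthetic cohort
#'
#' Chains every stage of the workflow: cohort simulation, optional spectrum
#' rendering with intelligent bucketing / water exclusion / total-area
#' normalization, Pareto scaling, OPLS-DA with cross-validation, permutation
#' validation and VIP scoring, univariate Mann-Whitney + BH testing on
#' relative concentrations, the logistic ROC panel with Monte-Carlo CV and
#' permutation guard on the univariate-significant metabolites, Spearman
#' correlation of those metabolites with DAPSA, and metabolite-set
#' over-representation with the pathway network. Deterministic given the
#' config.
#'
#' @param config a [pipeline_config()].
#' @param params,link,lib generator parameter objects.
#' @return list of class `pipeline_result` with each stage's output.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         params = psa_group_params(), link = dapsa_link(),
                         lib = spectral_library()) {
  seeds <- derive_seeds(config$seed,
                        c("simulate", "oplsda", "panel", "enrich"))
  cohort_data <- simulate_cohort(params, link, lib, config$n_psa, config$n_hc,
                                 spectra = config$spectra,
                                 seed = seeds["simulate"])
  conc <- cohort_data$concentrations
  groups <- cohort_data$cohort$group

  buckets <- NULL
  if (config$spectra) {
    buckets <- intelligent_bucket(cohort_data$spectra,
                                  nominal_width = config$bucket_width,
                                  looseness = config$looseness,
                                  region = config$region)
    buckets <- exclude_region(buckets, config$exclude[1], config$exclude[2])
    buckets <- normalize_total_area(buckets)
    X <- buckets$values
  } else {
    X <- as.matrix(conc)
  }

  sc <- pareto_scale(X, method = config$scaling)
  opls <- fit_oplsda(sc$scaled, groups, n_orthogonal = config$n_orthogonal)
  cv <- cross_validate_oplsda(X, groups, n_orthogonal = config$n_orthogonal,
                              folds = config$folds, scaling = config$scaling)
  opls$Q2_cum <- cv$Q2
  perm <- permutation_test(X, groups, n_orthogonal = config$n_orthogonal,
                           folds = config$folds, scaling = config$scaling,
                           n_perm = config$n_perm_opls, seed = seeds["oplsda"])
  vip_tab <- vip(opls)

  rel <- relative_concentrations(conc)
  uni <- univariate_table(rel, groups, alpha = config$alpha)
  sig <- uni$metabolite[uni$p < config$alpha]

  panel <- valid <- corr <- NULL
  if (length(sig) >= 2) {
    panel <- fit_logistic_panel(rel[, sig, drop = FALSE], groups,
                                positive = "HC")
    valid <- cv_and_permute(rel[, sig, drop = FALSE], groups, positive = "HC",
                            n_cv = config$n_cv, n_perm = config$n_perm_panel,
                            seed = seeds["panel"])
    corr <- correlate_panel(rel, cohort_data$cohort, metabolites = sig)
  }
  enr <- if (length(sig) >= 1) hypergeometric_ora(sig) else NULL
  net <- if (!is.null(enr)) pathway_network(enr) else NULL

  result <- structure(
    list(config = config, cohort = cohort_data$cohort, concentrations = conc,
         buckets = buckets, scaling = sc$model, oplsda = opls,
         cross_validation = cv, permutation = perm, vip = vip_tab,
         relative = rel, univariate = uni, significant = sig, panel = panel,
         panel_validation = valid, dapsa_correlation = corr,
         enrichment = enr, network = net),
    class = "pipeline_result")
  if (!is.null(config$out)) write_pipeline(result, config$out)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Discovery pipeline result\n")
  cat(sprintf("  cohort: %d PsA / %d HC\n", sum(x$cohort$group == "PsA"),
              sum(x$cohort$group == "HC")))
  if (!is.null(x$buckets))
    cat(sprintf("  buckets: %d (after water exclusion)\n",
                ncol(x$buckets$values)))
  cat(sprintf("  OPLS-DA: R2X %.3f  R2Y %.3f  Q2 %.3f  (Q2 intercept %.3f)\n",
              x$oplsda$R2X_cum, x$oplsda$R2Y_cum, x$oplsda$Q2_cum,
              x$permutation$Q2_intercept))
  cat(sprintf("  significant metabolites (raw p < %.2g): %s\n",
              x$config$alpha, paste(x$significant, collapse = ", ")))
  if (!is.null(x$panel))
    cat(sprintf("  panel AUC: %.3f (CV mean %.3f, permutation p %.3g)\n",
                x$panel$auc, x$panel_validation$cv_auc_mean,
                x$panel_validation$perm_p))
  invisible(x)
}

# ---- writers / readers ------------------------------------------------------

#' Write the cohort and concentration tables as TSV
#'
#' @param cohort cohort data.frame (`sample_id`, `group`, optional `dapsa`).
#' @param conc samples x metabolites table.
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
write_cohort_tables <- function(cohort, conc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "cohort.tsv")
  p2 <- file.path(dir, "concentrations.tsv")
  utils::write.table(cohort, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = rownames(conc), conc,
                                check.names = FALSE),
                     p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Read a concentration table written by [write_cohort_tables()]
#' @param path TSV path with a `sample_id` column.
#' @return samples x metabolites data.frame with sample ids as rownames.
#' @export
read_concentrations <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(tab)) stop("missing 'sample_id' column")
  if (anyDuplicated(tab$sample_id) > 0) stop("duplicated sample ids")
  rownames(tab) <- tab$sample_id
  tab$sample_id <- NULL
  num <- vapply(tab, is.numeric, logical(1))
  if (!all(num))
    stop("non-numeric concentration column(s): ",
         paste(colnames(tab)[!num], collapse = ", "))
  tab
}

#' Write spectra as a wide TSV (first column ppm, one column per sample)
#' @param spectra a [spectrum_set()].
#' @param path output file.
#' @export
write_spectra <- function(spectra, path) {
  stopifnot(inherits(spectra, "spectrum_set"))
  tab <- data.frame(ppm = spectra$ppm, t(spectra$intensities),
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read spectra from the wide TSV written by [write_spectra()]
#' @param path input file.
#' @return a [spectrum_set()].
#' @export
read_spectra <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  if (colnames(tab)[1] != "ppm") stop("first column must be 'ppm'")
  spectrum_set(tab$ppm, t(as.matrix(tab[, -1, drop = FALSE])))
}

#' Write a bucket table with boundary metadata header lines
#'
#' Boundaries and excluded regions are recorded in `#`-prefixed header lines
#' at full precision, so a write/read round trip is lossless.
#'
#' @param buckets a `bucket_table`.
#' @param path output TSV.
#' @export
write_buckets <- function(buckets, path) {
  stopifnot(inherits(buckets, "bucket_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# boundaries\t%s",
                     paste(format(buckets$boundaries, digits = 17),
                           collapse = "\t")), con)
  writeLines(sprintf("# normalized\t%s", buckets$normalized), con)
  for (r in buckets$excluded_regions)
    writeLines(sprintf("# excluded\t%.17g\t%.17g", r[1], r[2]), con)
  utils::write.table(data.frame(sample_id = rownames(buckets$values),
                                buckets$values, check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a bucket table written by [write_buckets()]
#' @param path input TSV.
#' @return a `bucket_table`.
#' @export
read_buckets <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  bline <- strsplit(sub("^# boundaries\t", "", hdr[grep("boundaries", hdr)]),
                    "\t")[[1]]
  boundaries <- as.numeric(bline)
  normalized <- as.logical(sub("^# normalized\t", "",
                               hdr[grep("normalized", hdr)]))
  excl <- lapply(grep("excluded", hdr, value = TRUE), function(h)
    as.numeric(strsplit(h, "\t")[[1]][2:3]))
  tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  if (anyDuplicated(tab$sample_id) > 0) stop("duplicated sample ids")
  V <- as.matrix(tab[, -1, drop = FALSE])
  rownames(V) <- tab$sample_id
  structure(list(boundaries = boundaries, values = V,
                 normalized = normalized, excluded_regions = excl),
            class = "bucket_table")
}

# Write every pipeline artifact plus a manifest with checksums.
write_pipeline <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort_tables(result$cohort, result$concentrations, dir)
  if (!is.null(result$buckets))
    write_buckets(result$buckets, file.path(dir, "buckets.tsv"))
  utils::write.table(result$univariate, file.path(dir, "univariate.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$vip, file.path(dir, "vip.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$dapsa_correlation))
    utils::write.table(result$dapsa_correlation,
                       file.path(dir, "dapsa_correlation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$enrichment))
    utils::write.table(result$enrichment[, setdiff(colnames(result$enrichment),
                                                   "members_hit")],
                       file.path(dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    seed = result$config$seed,
    oplsda = list(components = sprintf("%dP + %dO", result$oplsda$n_predictive,
                                       result$oplsda$n_orthogonal),
                  R2X = result$oplsda$R2X_cum, R2Y = result$oplsda$R2Y_cum,
                  Q2 = result$oplsda$Q2_cum,
                  R2_intercept = result$permutation$R2_intercept,
                  Q2_intercept = result$permutation$Q2_intercept,
                  vip_variant = "predictive-component VIP"),
    significant = result$significant,
    panel = if (!is.null(result$panel)) list(
      auc = result$panel$auc, auc_ci = result$panel$auc_ci,
      cv_auc_mean = result$panel_validation$cv_auc_mean,
      perm_p = result$panel_validation$perm_p,
      coefficients = as.list(result$panel$coefficients),
      intercept = result$panel$intercept,
      threshold = result$panel$threshold))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- setdiff(list.files(dir), "manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("psametab")),
    seed = result$config$seed,
    files = lapply(files, function(f) list(
      name = f, md5 = unname(tools::md5sum(file.path(dir, f))))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
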