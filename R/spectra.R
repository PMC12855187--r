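#' Construct a multi-sample spectrum set
#'
#' @param ppm strictly increasing chemical-shift axis (ppm), shared by all
#'   samples.
#' @param intensities samples x points numeric matrix; rownames are sample ids.
#' @return object of class `spectrum_set`.
#' @export
spectrum_set <- function(ppm, intensities) {
  intensities <- as.matrix(intensities)
  if (length(ppm) != ncol(intensities))
    stop("length(ppm) must equal ncol(intensities)")
  if (any(diff(ppm) <= 0)) stop("ppm axis must be strictly increasing")
  if (anyNA(intensities)) stop("intensities must not contain missing values")
  if (is.null(rownames(intensities)))
    rownames(intensities) <- sprintf("S%03d", seq_len(nrow(intensities)))
  structure(list(ppm = as.numeric(ppm), intensities = intensities,
                 sample_ids = rownames(intensities)),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat("spectrum_set:", nrow(x$intensities), "samples,",
      length(x$ppm), "points,",
      sprintf("%.2f-%.2f ppm\n", min(x$ppm), max(x$ppm)))
  invisible(x)
}

# Trapezoidal integral of each sample over [a, b], with intensities linearly
# interpolated at the exact interval endpoints so that adjacent intervals
# sharing a boundary tile the full-region integral exactly.
trapz_interval <- function(ppm, Y, a, b) {
  inside <- which(ppm > a & ppm < b)
  interp <- function(x0) {
    if (x0 <= ppm[1]) return(Y[, 1])
    if (x0 >= ppm[length(ppm)]) return(Y[, ncol(Y)])
    i <- findInterval(x0, ppm)
    w <- (x0 - ppm[i]) / (ppm[i + 1] - ppm[i])
    (1 - w) * Y[, i] + w * Y[, i + 1]
  }
  xs <- c(a, ppm[inside], b)
  ys <- cbind(interp(a), Y[, inside, drop = FALSE], interp(b))
  dx <- diff(xs)
  as.vector((ys[, -ncol(ys), drop = FALSE] + ys[, -1, drop = FALSE]) %*% dx) / 2
}

#' Intelligent (minimum-seeking) spectral bucketing
#'
#' Nominal bucket boundaries are laid out every `nominal_width` ppm across the
#' integration region; each interior boundary is then relocated to the local
#' minimum of the reference spectrum (the pointwise mean across samples)
#' within +/- `looseness * nominal_width / 2` of its nominal position, so a
#' peak whose position jitters between samples stays integrated within a
#' single bucket. Region endpoints are fixed. With the defaults (0.04 ppm,
#' 50% looseness) bucket widths are guaranteed to lie in [0.02, 0.06] ppm.
#' Argmin ties are broken toward the nominal position; a flat search window
#' keeps the exact nominal boundary.
#'
#' @param spectra a [spectrum_set()].
#' @param nominal_width nominal bucket width in ppm.
#' @param looseness allowed fractional deviation of each boundary (in [0, 1)).
#' @param region integration region `c(lo, hi)` in ppm.
#' @return object of class `bucket_table`: `boundaries`, `values`
#'   (samples x buckets matrix of trapezoidal integrals), `normalized`,
#'   `excluded_regions`.
#' @export
intelligent_bucket <- function(spectra, nominal_width = 0.04, looseness = 0.5,
                               region = c(0.80, 8.50)) {
  stopifnot(inherits(spectra, "spectrum_set"))
  if (looseness < 0 || looseness >= 1)
    stop("looseness must lie in [0, 1)")
  ppm <- spectra$ppm
  if (region[1] < min(ppm) || region[2] > max(ppm))
    stop("integration region must lie inside the ppm axis")
  if (diff(region) < nominal_width)
    stop("region narrower than one nominal bucket width")
  n_full <- floor(diff(region) / nominal_width + 1e-9)
  rem <- diff(region) - n_full * nominal_width
  nominal <- region[1] + nominal_width * seq(0, n_full)
  frozen <- integer(0)
  if (rem > 1e-9) {
    if (rem < nominal_width * (1 - looseness) - 1e-12) {
      # remainder too narrow to stand alone: merge into the final bucket,
      # freezing its left boundary so the merged width stays below
      # nominal * (2 - looseness)
      nominal[n_full + 1] <- region[2]
      frozen <- n_full
    } else {
      # remainder becomes its own trailing bucket with fixed boundaries
      nominal <- c(nominal, region[2])
      frozen <- n_full + 1
    }
  }
  # reference spectrum: pointwise mean across samples
  ref <- colMeans(spectra$intensities)
  half_window <- looseness * nominal_width / 2
  boundaries <- nominal
  for (k in setdiff(seq(2, length(nominal) - 1), frozen)) {
    idx <- which(abs(ppm - nominal[k]) <= half_window + 1e-12)
    if (length(idx) == 0) next
    vals <- ref[idx]
    if (max(vals) - min(vals) < 1e-12 * max(abs(vals), 1)) next  # flat window
    cand <- idx[vals <= min(vals) + 0]
    boundaries[k] <- ppm[cand[which.min(abs(ppm[cand] - nominal[k]))]]
  }
  if (any(diff(boundaries) <= 0))
    stop("degenerate boundaries; reduce looseness")
  V <- sapply(seq_len(length(boundaries) - 1), function(k)
    trapz_interval(ppm, spectra$intensities, boundaries[k], boundaries[k + 1]))
  V <- matrix(V, nrow = nrow(spectra$intensities),
              dimnames = list(spectra$sample_ids, NULL))
  colnames(V) <- sprintf("B%.3f_%.3f", boundaries[-length(boundaries)],
                         boundaries[-1])
  structure(list(boundaries = boundaries, values = V, normalized = FALSE,
                 excluded_regions = list()),
            class = "bucket_table")
}

#' @export
print.bucket_table <- function(x, ...) {
  w <- diff(x$boundaries)
  cat("bucket_table:", nrow(x$values), "samples x", ncol(x$values), "buckets;",
      sprintf("widths %.3f-%.3f ppm;", min(w), max(w)),
      if (x$normalized) "normalized" else "raw integrals", "\n")
  if (length(x$excluded_regions) > 0)
    cat("  excluded:", paste(vapply(x$excluded_regions, function(r)
      sprintf("%.2f-%.2f", r[1], r[2]), character(1)), collapse = ", "), "ppm\n")
  invisible(x)
}

#' Bucket widths in ppm
#' @param buckets a `bucket_table`.
#' @return numeric vector of widths matching the columns of `values`.
#' @export
bucket_widths <- function(buckets) {
  stopifnot(inherits(buckets, "bucket_table"))
  w <- diff(buckets$boundaries)
  # after exclusion, columns are a subset; recover widths from column names
  if (length(w) != ncol(buckets$values)) {
    parts <- strsplit(sub("^B", "", colnames(buckets$values)), "_")
    w <- vapply(parts, function(p) as.numeric(p[2]) - as.numeric(p[1]),
                numeric(1))
  }
  w
}

# Bucket intervals (lo, hi) parsed from column names; exact to 3 decimals.
bucket_intervals <- function(buckets) {
  parts <- strsplit(sub("^B", "", colnames(buckets$values)), "_")
  data.frame(lo = vapply(parts, function(p) as.numeric(p[1]), numeric(1)),
             hi = vapply(parts, function(p) as.numeric(p[2]), numeric(1)))
}

#' Drop buckets overlapping a spectral region
#'
#' Removes every bucket whose ppm interval intersects the open interval
#' `(lo, hi)`; used to discard the residual-water region (default
#' 4.70-5.20 ppm) before normalization.
#'
#' @param buckets a `bucket_table`.
#' @param lo,hi region bounds in ppm.
#' @return the filtered `bucket_table`, with the region recorded in
#'   `excluded_regions`.
#' @export
exclude_region <- function(buckets, lo = 4.70, hi = 5.20) {
  stopifnot(inherits(buckets, "bucket_table"))
  if (lo >= hi) stop("lo must be less than hi")
  iv <- bucket_intervals(buckets)
  keep <- !(iv$lo < hi & iv$hi > lo)
  buckets$values <- buckets$values[, keep, drop = FALSE]
  buckets$excluded_regions <- c(buckets$excluded_regions, list(c(lo, hi)))
  buckets
}

#' Normalize each sample to unit total bucket area
#'
#' Divides every sample's bucket vector by its own sum, removing
#' between-sample differences in overall concentration/receiver gain.
#'
#' @param buckets a `bucket_table`.
#' @return the normalized `bucket_table` (rows sum to 1).
#' @export
normalize_total_area <- function(buckets) {
  stopifnot(inherits(buckets, "bucket_table"))
  totals <- rowSums(buckets$values)
  bad <- which(totals <= 0)
  if (length(bad) > 0)
    stop("non-positive total area for sample(s): ",
         paste(rownames(buckets$values)[bad], collapse = ", "))
  buckets$values <- buckets$values / totals
  buckets$normalized <- TRUE
  buckets
}
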