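# Band-restricted coherence areas, their log transform, group comparison and
# correlation analyses.
#
# Band bin assignment: the alpha (5-15 Hz) and beta (15-35 Hz) bands share
# the 15 Hz endpoint; to prevent double counting, a band marked
# `right_open = TRUE` (the alpha default via `coherence_band_areas`) sums
# integer-Hz bins in [lo, hi) while the closed form sums [lo, hi].

#' Coherence area over a frequency band
#'
#' Sums per-bin coherence over the bins inside `band` and reports the base-10
#' logarithm, the conventional symmetrising transform for coherence areas.
#'
#' @param est A `spectral_estimate` or `pooled_coherence`.
#' @param band Two-element numeric `(lo_hz, hi_hz)`.
#' @param right_open If `TRUE`, sum bins in `[lo, hi)`; if `FALSE` (default)
#'   in `[lo, hi]`.
#' @return A `band_area` with fields `band`, `n_bins`, `area` and `log_area`
#'   (`NA` with an `undefined` flag when the area is zero).
#' @export
band_area <- function(est, band, right_open = FALSE) {
  if (length(band) != 2L || band[1] >= band[2]) {
    stop("`band` must be an increasing (lo, hi) pair in Hz", call. = FALSE)
  }
  freqs <- est$freqs
  coh <- est$coherence
  sel <- if (right_open) freqs >= band[1] & freqs < band[2]
         else freqs >= band[1] & freqs <= band[2]
  if (!any(sel)) stop("band contains no estimated frequency bins", call. = FALSE)
  area <- sum(coh[sel])
  structure(
    list(band = as.numeric(band), n_bins = sum(sel), area = area,
         log_area = if (area > 0) log10(area) else NA_real_,
         undefined = area <= 0),
    class = "band_area")
}

#' @export
print.band_area <- function(x, ...) {
  cat(sprintf("<band_area> %g-%g Hz (%d bins): area %.4f, log10 %s\n",
              x$band[1], x$band[2], x$n_bins, x$area,
              if (x$undefined) "undefined" else sprintf("%.3f", x$log_area)))
  invisible(x)
}

#' Alpha- and beta-band coherence areas for one estimate
#'
#' Convenience wrapper returning both standard bands with the shared 15 Hz
#' boundary assigned to the beta band only (alpha summed over `[5, 15)`,
#' beta over `[15, 35]`).
#'
#' @param est A `spectral_estimate` or `pooled_coherence`.
#' @param config An [analysis_config()] supplying the band edges.
#' @return Named list with `band_area` elements `alpha` and `beta`.
#' @export
coherence_band_areas <- function(est, config = analysis_config()) {
  list(alpha = band_area(est, config$alpha_band, right_open = TRUE),
       beta = band_area(est, config$beta_band, right_open = FALSE))
}

#' Compare log coherence areas between two groups
#'
#' Two-sample Student's t-test on log10 band areas, reporting group means and
#' standard errors. Records with undefined logs (zero area) are excluded with
#' an explicit count rather than silently imputed.
#'
#' @param groupA,groupB Lists of `band_area` objects (or numeric vectors of
#'   log areas), at least 2 defined values per group.
#' @return List with `t`, `df`, `p`, per-group `mean`, `se`, `n` and
#'   `n_excluded`.
#' @export
compare_band_areas <- function(groupA, groupB) {
  extract <- function(g) {
    if (is.numeric(g)) return(g)
    vapply(g, function(b) b$log_area, numeric(1))
  }
  a <- extract(groupA); b <- extract(groupB)
  n_excl <- sum(is.na(a)) + sum(is.na(b))
  if (n_excl > 0) {
    warning(sprintf("%d record(s) with undefined log area excluded", n_excl))
  }
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 defined log areas", call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean = c(A = mean(a), B = mean(b)),
       se = c(A = stats::sd(a) / sqrt(length(a)),
              B = stats::sd(b) / sqrt(length(b))),
       n = c(A = length(a), B = length(b)),
       n_excluded = n_excl)
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length `>= 3` with nonzero variance.
#' @return List with `r` and two-sided `p`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate input: zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
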