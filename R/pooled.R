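# Group-level inference: pooled coherence, pooled cumulant density, and the
# per-frequency chi-squared difference-of-coherence test between two groups.
#
# Pooling operates on normalised per-record coherencies
# c_i(k) = f_xy,i(k) / sqrt(f_xx,i(k) * f_yy,i(k)), weighted by segment
# counts: c_pool = sum_i L_i c_i / sum_i L_i.  Working on coherencies rather
# than raw spectra makes records with different power scales commensurate,
# consistent with unit-variance preprocessing; spectra-sum pooling is kept
# behind a switch for sensitivity analysis.

coherency_of <- function(est, full = FALSE) {
  f <- if (full) est$full else est
  denom <- sqrt(f$f_xx * f$f_yy)
  out <- f$f_xy
  out[denom > 0] <- out[denom > 0] / denom[denom > 0]
  out[denom <= 0] <- 0 + 0i
  out
}

check_common_axis <- function(estimates) {
  if (length(estimates) == 0L) stop("empty estimate list", call. = FALSE)
  f0 <- estimates[[1]]$freqs
  T0 <- estimates[[1]]$T
  for (e in estimates) {
    if (!inherits(e, "spectral_estimate")) {
      stop("all elements must be spectral_estimate objects", call. = FALSE)
    }
    if (e$T != T0 || length(e$freqs) != length(f0) ||
        max(abs(e$freqs - f0)) > 1e-9) {
      stop("estimates have mismatched frequency axes", call. = FALSE)
    }
  }
  invisible(f0)
}

#' Pooled coherence across records
#'
#' Segment-weighted complex average of per-record coherencies; pooled
#' coherence is the squared modulus of the average, with the confidence limit
#' computed at the total segment count. Like individual coherence it is a
#' bounded measure of linear association on [0, 1], interpreted at the level
#' of the pooled population of records.
#'
#' @param estimates List of `spectral_estimate` objects on a common frequency
#'   axis.
#' @param method `"coherency"` (default; normalised per-record coherencies)
#'   or `"spectra"` (segment-weighted sums of raw spectra; sensitivity
#'   analysis only).
#' @return A `pooled_coherence` with `freqs`, `coherence`, `coherency`
#'   (complex), `total_segments`, `n_records`, `coh_cl`.
#' @export
pool_coherence <- function(estimates, method = c("coherency", "spectra")) {
  method <- match.arg(method)
  check_common_axis(estimates)
  Ls <- vapply(estimates, function(e) e$L, numeric(1))
  totL <- sum(Ls)
  alpha <- estimates[[1]]$alpha
  if (method == "coherency") {
    acc <- 0 + 0i; acc_full <- 0 + 0i
    for (i in seq_along(estimates)) {
      acc <- acc + Ls[i] * coherency_of(estimates[[i]])
      acc_full <- acc_full + Ls[i] * coherency_of(estimates[[i]], full = TRUE)
    }
    cpool <- acc / totL
    cpool_full <- acc_full / totL
  } else {
    sxx <- 0; syy <- 0; sxy <- 0 + 0i; sxyf <- 0 + 0i; sxxf <- 0; syyf <- 0
    for (e in estimates) {
      sxx <- sxx + e$L * e$f_xx; syy <- syy + e$L * e$f_yy
      sxy <- sxy + e$L * e$f_xy
      sxxf <- sxxf + e$L * e$full$f_xx; syyf <- syyf + e$L * e$full$f_yy
      sxyf <- sxyf + e$L * e$full$f_xy
    }
    denom <- sqrt(sxx * syy)
    cpool <- ifelse(denom > 0, sxy / denom, 0 + 0i)
    denf <- sqrt(sxxf * syyf)
    cpool_full <- ifelse(denf > 0, sxyf / denf, 0 + 0i)
  }
  structure(
    list(freqs = estimates[[1]]$freqs,
         coherence = pmin(Mod(cpool)^2, 1),
         coherency = cpool,
         coherency_full = cpool_full,
         T = estimates[[1]]$T, fs = estimates[[1]]$fs,
         total_segments = totL, n_records = length(estimates),
         alpha = alpha, coh_cl = 1 - alpha^(1 / (totL - 1))),
    class = "pooled_coherence")
}

#' @export
print.pooled_coherence <- function(x, ...) {
  cat(sprintf(
    "<pooled_coherence> %d records, %d total segments; 95%% limit %.5f\n",
    x$n_records, x$total_segments, x$coh_cl))
  invisible(x)
}

#' Pooled cumulant density
#'
#' Inverse transform of the segment-weighted pooled coherency (the same
#' normalised basis as [pool_coherence()]), with a flat independence-null
#' confidence band at the total segment count: each coherency bin has null
#' second moment `1/sum(L)`, giving lag-constant variance
#' `1/(T * sum(L))` for the pooled cumulant.
#'
#' @param estimates List of `spectral_estimate` objects on a common axis.
#' @param max_lag_s Lag half-range in seconds (default 0.25).
#' @return A `cumulant_density`.
#' @export
pool_cumulant <- function(estimates, max_lag_s = 0.25) {
  pc <- pool_coherence(estimates)
  var_q <- 1 / (pc$T * pc$total_segments)
  cumulant_from_cross(pc$coherency_full / pc$T, pc$fs, max_lag_s, var_q,
                      pc$alpha)
}

#' Chi-squared difference-of-coherence test between two groups
#'
#' Per-frequency nonparametric comparison of pooled coherence between two
#' groups of records. Each group's pooled coherency modulus is variance-
#' stabilised as `z_g = atanh(|c_pool,g|)`, whose large-sample variance under
#' pooling is `1/(2 * sum L_i)`; with weights `w_g = 2 * sum L_i` the
#' statistic `chi2 = sum_g w_g (z_g - z_bar_w)^2` is chi-squared with
#' `groups - 1` degrees of freedom at frequencies where coherence is nonzero.
#' No correction for multiple testing across frequencies is applied; each bin
#' is compared with the per-frequency 95% critical value.
#'
#' @param groupA,groupB Non-empty lists of `spectral_estimate` objects on a
#'   common frequency axis.
#' @param alpha Significance level for the per-frequency threshold.
#' @return A `coherence_difference` with `freqs`, `chi2`, `df`, `threshold`,
#'   `significant`, and the two `pooled_coherence` objects.
#' @export
chi2_difference_test <- function(groupA, groupB, alpha = 0.05) {
  if (length(groupA) == 0L || length(groupB) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  check_common_axis(c(groupA, groupB))
  pools <- list(pool_coherence(groupA), pool_coherence(groupB))
  eps <- 1e-12
  z <- lapply(pools, function(p) atanh(pmin(Mod(p$coherency), 1 - eps)))
  w <- vapply(pools, function(p) 2 * p$total_segments, numeric(1))
  zbar <- (w[1] * z[[1]] + w[2] * z[[2]]) / sum(w)
  chi2 <- w[1] * (z[[1]] - zbar)^2 + w[2] * (z[[2]] - zbar)^2
  df <- 1L
  thr <- stats::qchisq(1 - alpha, df)
  structure(
    list(freqs = pools[[1]]$freqs, chi2 = chi2, df = df, threshold = thr,
         significant = chi2 > thr,
         pooledA = pools[[1]], pooledB = pools[[2]]),
    class = "coherence_difference")
}

#' @export
print.coherence_difference <- function(x, ...) {
  sel <- x$freqs >= 1 & x$freqs <= 60
  cat(sprintf(
    "<coherence_difference> df=%d, 95%% threshold %.2f; %d of %d 1-60 Hz bins differ\n",
    x$df, x$threshold, sum(x$significant[sel]), sum(sel)))
  invisible(x)
}
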