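#' Construct a FRAP trace
#'
#' A fluorescence recovery after photobleaching trace: `n_prebleach`
#' pre-bleach scans establishing the reference intensity, followed by the
#' post-bleach recovery series.
#'
#' @param times time points in minutes, strictly increasing.
#' @param intensities fluorescence intensities (arbitrary units), same
#'   length as `times`.
#' @param n_prebleach number of leading pre-bleach points (>= 1).
#' @param roi_diameter bleached region-of-interest diameter in micrometers
#'   (metadata).
#' @param zone free-text label of the sampled zone (e.g. root tip).
#' @param normalized whether the trace is already normalized (pre-bleach
#'   mean 1, time zero at first post-bleach frame); set by
#'   [normalize_trace()].
#' @return An object of class `frap_trace`.
#' @export
frap_trace <- function(times, intensities, n_prebleach = 3,
                       roi_diameter = NA_real_, zone = NA_character_,
                       normalized = FALSE) {
  if (length(times) != length(intensities)) {
    abort("'times' and 'intensities' must have equal length")
  }
  if (!all(is.finite(times)) || !all(is.finite(intensities))) {
    abort("FRAP trace contains non-finite values")
  }
  if (any(diff(times) <= 0)) abort("'times' must be strictly increasing")
  if (!is_count(n_prebleach)) abort("'n_prebleach' must be >= 1")
  if (length(times) < n_prebleach + 1L) {
    abort("trace must extend beyond the pre-bleach scans")
  }
  pre_mean <- mean(intensities[seq_len(n_prebleach)])
  if (intensities[n_prebleach + 1L] >= pre_mean) {
    abort("first post-bleach intensity (%.4g) is not below the pre-bleach mean (%.4g)",
          intensities[n_prebleach + 1L], pre_mean)
  }
  structure(
    list(times = as.numeric(times), intensities = as.numeric(intensities),
         n_prebleach = as.integer(n_prebleach), roi_diameter = roi_diameter,
         zone = zone, normalized = isTRUE(normalized)),
    class = "frap_trace"
  )
}

#' @export
print.frap_trace <- function(x, ...) {
  cat(sprintf("<frap_trace> %d points (%d pre-bleach), t %.3g..%.3g min%s\n",
              length(x$times), x$n_prebleach, min(x$times), max(x$times),
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Normalize a FRAP trace to its pre-bleach intensity
#'
#' Divides intensities by the mean of the pre-bleach scans, so the
#' pre-bleach level becomes 1, and re-zeroes time at the first post-bleach
#' frame. When a reference trace from an unbleached region is supplied, the
#' trace is first corrected for acquisition bleaching by pointwise division
#' with the reference (itself scaled to its own pre-bleach mean).
#' Normalization is idempotent.
#'
#' @param trace a [frap_trace].
#' @param reference optional numeric vector (same length) or `frap_trace`
#'   from an unbleached region, used for acquisition-bleaching correction.
#' @return A normalized [frap_trace].
#' @export
normalize_trace <- function(trace, reference = NULL) {
  if (!inherits(trace, "frap_trace")) abort("'trace' must be a frap_trace")
  intens <- trace$intensities
  npre <- trace$n_prebleach
  if (!is.null(reference)) {
    ref <- if (inherits(reference, "frap_trace")) reference$intensities else reference
    if (length(ref) != length(intens)) {
      abort("reference trace length (%d) differs from trace length (%d)",
            length(ref), length(intens))
    }
    if (any(ref <= 0)) abort("reference trace must be strictly positive")
    intens <- intens / (ref / mean(ref[seq_len(npre)]))
  }
  pre_mean <- mean(intens[seq_len(npre)])
  if (pre_mean <= 0) abort("pre-bleach mean is not positive; cannot normalize")
  frap_trace(times = trace$times - trace$times[npre + 1L],
             intensities = intens / pre_mean,
             n_prebleach = npre, roi_diameter = trace$roi_diameter,
             zone = trace$zone, normalized = TRUE)
}

#' Fit single-exponential FRAP recovery
#'
#' Least-squares fit of the post-bleach recovery of a normalized trace to
#' \deqn{F(t) = F_0 + A (1 - e^{-k t})} reporting the mobile fraction
#' `Mf = A / (1 - F0)` (the recovered share of the bleached fluorescence),
#' the halftime `t_half = ln 2 / k`, and the coefficient of determination on
#' the post-bleach points. One recovery component is the minimal model
#' behind a single mobile fraction and halftime; optimization uses bounded
#' Levenberg-Marquardt least squares with `k` in (0, 10] per minute and `A`
#' in [0, 1.5], initialized from the observed recovery span and the time at
#' which half the span is reached.
#'
#' @param trace a [frap_trace]; normalized internally if needed (see
#'   [normalize_trace()]).
#' @param fix_f0 fix the bleach floor `F0` at the first post-bleach sample
#'   (default, more stable at sparse sampling) or co-fit it.
#' @return An object of class `frap_fit` with elements `mobile_fraction`,
#'   `t_half` (minutes), `rate` (`k`, per minute), `f0`, `plateau`
#'   (`F0 + A`), `r_squared`, `converged`, `n_points`, and `warning`
#'   (diagnostics, e.g. when the halftime exceeds half the observation
#'   window and the asymptote is extrapolated). A failed optimization
#'   returns `converged = FALSE` with `NA` parameters rather than an error.
#'   A flat post-bleach trace is an immobile cell: `Mf = 0`, no rate.
#' @export
fit_recovery <- function(trace, fix_f0 = TRUE) {
  if (!inherits(trace, "frap_trace")) abort("'trace' must be a frap_trace")
  if (!trace$normalized) trace <- normalize_trace(trace)
  post <- seq.int(trace$n_prebleach + 1L, length(trace$times))
  tt <- trace$times[post]
  yy <- trace$intensities[post]
  if (length(tt) < 5L) abort("at least 5 post-bleach points are required")
  if (!all(is.finite(yy))) abort("non-finite intensities in trace")

  f0_first <- yy[1L]
  span_obs <- mean(tail(yy, 3L)) - f0_first
  out <- list(mobile_fraction = NA_real_, t_half = NA_real_, rate = NA_real_,
              f0 = f0_first, plateau = NA_real_, r_squared = NA_real_,
              converged = FALSE, n_points = length(tt), warning = NA_character_,
              fix_f0 = fix_f0)
  class(out) <- "frap_fit"

  rsq <- function(fitted) {
    ss_res <- sum((yy - fitted)^2)
    ss_tot <- sum((yy - mean(yy))^2)
    if (ss_tot == 0) {
      if (ss_res <= .Machine$double.eps * length(yy)) 1 else NA_real_
    } else {
      1 - ss_res / ss_tot
    }
  }

  # immobile limit: nothing recovers, the constant fit is the model
  if (abs(span_obs) < 1e-9 || sd(yy) == 0) {
    out$mobile_fraction <- 0
    out$plateau <- f0_first
    out$r_squared <- rsq(rep(mean(yy), length(yy)))
    out$converged <- TRUE
    return(out)
  }

  a0 <- min(max(span_obs, 1e-3), 1.5)
  half_idx <- which(yy - f0_first >= a0 / 2)
  t_half0 <- if (length(half_idx)) max(tt[half_idx[1L]], tt[2L] / 2) else max(tt) / 2
  k0 <- min(max(log(2) / t_half0, 1e-3), 10)

  fit <- if (fix_f0) {
    f0 <- f0_first
    try(minpack.lm::nlsLM(
      yy ~ f0 + A * (1 - exp(-k * tt)),
      start = list(A = a0, k = k0),
      lower = c(A = 0, k = 1e-6), upper = c(A = 1.5, k = 10),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  } else {
    try(minpack.lm::nlsLM(
      yy ~ F0 + A * (1 - exp(-k * tt)),
      start = list(F0 = f0_first, A = a0, k = k0),
      lower = c(F0 = 0, A = 0, k = 1e-6), upper = c(F0 = 1, A = 1.5, k = 10),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  }
  if (inherits(fit, "try-error")) {
    out$warning <- sprintf("optimizer failed: %s",
                           conditionMessage(attr(fit, "condition")))
    return(out)
  }
  cf <- coef(fit)
  f0_hat <- if (fix_f0) f0_first else unname(cf["F0"])
  a_hat <- unname(cf["A"])
  k_hat <- unname(cf["k"])
  out$f0 <- f0_hat
  out$plateau <- f0_hat + a_hat
  out$rate <- k_hat
  out$t_half <- log(2) / k_hat
  out$mobile_fraction <- if (f0_hat < 1) a_hat / (1 - f0_hat) else NA_real_
  out$r_squared <- rsq(f0_hat + a_hat * (1 - exp(-k_hat * tt)))
  out$converged <- TRUE
  if (out$t_half > max(tt) / 2) {
    out$warning <- paste("halftime exceeds half the observation window;",
                         "plateau and mobile fraction are extrapolated",
                         "(wide confidence)")
  }
  out
}

#' @export
print.frap_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "<frap_fit> Mf = %.3f, t_half = %.3g min (k = %.3g /min), F0 = %.3f, R^2 = %.4f\n",
      x$mobile_fraction, x$t_half, x$rate, x$f0, x$r_squared))
    if (!is.na(x$warning)) cat("  note:", x$warning, "\n")
  } else {
    cat("<frap_fit> not converged:", x$warning, "\n")
  }
  invisible(x)
}
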