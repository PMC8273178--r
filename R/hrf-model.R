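# Two-Gaussian-pulse model of the block-averaged BOLD response.
#
# The averaged response to a 15 s stimulation block, sampled at 13 grid
# times 0, 2.5, ..., 30 s, is modelled as the integral over the trailing
# 15 s window of two Gaussian pulses (a positive activation pulse and a
# negative undershoot pulse), gated by the Heaviside step at stimulus
# onset, plus a per-condition linear drift.

#' The standard 13-point block time grid
#'
#' @return Numeric vector `seq(0, 30, by = 2.5)` (seconds).
#' @export
time_grid <- function() seq(0, 30, by = 2.5)

#' Temporal parameters shared across conditions
#'
#' Centers (`T1 < T2`, seconds) and widths (`alpha1`, `alpha2` > 0, seconds)
#' of the positive and negative Gaussian pulses. One set is shared by all
#' four chroma conditions of a joint fit.
#'
#' @param T1,T2 Pulse centers, s.
#' @param alpha1,alpha2 Pulse standard deviations, s.
#' @return An object of class `hrf_temporal_params`.
#' @export
hrf_temporal_params <- function(T1 = 6, T2 = 16, alpha1 = 2.5, alpha2 = 4) {
  if (!(alpha1 > 0 && alpha2 > 0)) stop("alpha1, alpha2 must be > 0", call. = FALSE)
  if (!(T1 < T2)) stop("T1 must be < T2", call. = FALSE)
  structure(list(T1 = T1, T2 = T2, alpha1 = alpha1, alpha2 = alpha2),
    class = "hrf_temporal_params"
  )
}

#' Per-condition response parameters
#'
#' Pulse intensities (`a1 > 0`, `a2 < 0`) and linear-drift slope/offset for
#' one chroma condition.
#'
#' @param a1 Positive pulse intensity.
#' @param a2 Negative pulse intensity.
#' @param b Drift slope, percent signal change per second.
#' @param d Offset, percent signal change.
#' @param condition Chroma condition label.
#' @return An object of class `condition_params`.
#' @export
condition_params <- function(a1, a2, b = 0, d = 0, condition = "/0") {
  if (!(a1 > 0)) stop("a1 must be > 0", call. = FALSE)
  if (!(a2 < 0)) stop("a2 must be < 0", call. = FALSE)
  check_chroma(condition)
  structure(list(a1 = a1, a2 = a2, b = b, d = d, condition = condition),
    class = "condition_params"
  )
}

#' Gaussian pulse integral over a Heaviside-gated window
#'
#' Computes `integral over [max(lower, 0), max(upper, 0)] of
#' exp(-(tau - T)^2 / (2 alpha^2)) dtau` in closed form via the Gaussian CDF;
#' the clamp at zero implements the Heaviside gate at stimulus onset.
#'
#' @param T Pulse center, s.
#' @param alpha Pulse width, s (> 0).
#' @param lower,upper Window bounds, s (`lower <= upper`).
#' @return The (dimensionless time-integrated) window area in seconds.
#' @export
#' @examples
#' pulse_window_integral(6, 2, 0, 15)
pulse_window_integral <- function(T, alpha, lower, upper) {
  if (!all(alpha > 0)) stop("alpha must be > 0", call. = FALSE)
  if (any(upper < lower)) stop("lower must be <= upper", call. = FALSE)
  lo <- pmax(lower, 0)
  up <- pmax(upper, 0)
  alpha * sqrt(2 * pi) *
    (stats::pnorm((up - T) / alpha) - stats::pnorm((lo - T) / alpha))
}

#' Model block response on the time grid
#'
#' `ModelR(t) = a1 * I1(t) + a2 * I2(t) + b t + d`, where `Ik(t)` is the
#' [pulse_window_integral()] of pulse k over the trailing window
#' `[t - 15, t]` (Heaviside-clamped at 0).
#'
#' @param temporal A [hrf_temporal_params()].
#' @param cond A [condition_params()] (or any list with `a1`, `a2`, `b`, `d`).
#' @param times Sample times, s; defaults to [time_grid()].
#' @param window_s Stimulation-block duration, s.
#' @return Numeric vector of model responses (percent signal change).
#' @export
model_response <- function(temporal, cond, times = time_grid(),
                           window_s = 15) {
  i1 <- pulse_window_integral(temporal$T1, temporal$alpha1, times - window_s, times)
  i2 <- pulse_window_integral(temporal$T2, temporal$alpha2, times - window_s, times)
  cond$a1 * i1 + cond$a2 * i2 + cond$b * times + cond$d
}

#' Relative squared-error objective of a joint fit
#'
#' The error value is the sum over conditions and grid points of
#' `((R - ModelR) / ModelR)^2`. Near-zero model denominators (absolute value
#' below `eps`) are clamped to `+/- eps` and counted.
#'
#' @param observed,fitted Numeric matrices (13 x 4: grid points x chroma
#'   conditions), or vectors/lists coercible to such.
#' @param eps Denominator guard, percent signal change.
#' @param warn Emit a warning when any denominator is clamped.
#' @return The error value, with attribute `n_clamped`.
#' @export
error_value <- function(observed, fitted, eps = 1e-3, warn = TRUE) {
  r <- as.matrix(as.data.frame(observed))
  m <- as.matrix(as.data.frame(fitted))
  if (!identical(dim(r), dim(m))) {
    stop("observed and fitted responses must have identical shape",
      call. = FALSE
    )
  }
  small <- abs(m) < eps
  denom <- m
  denom[small] <- ifelse(m[small] >= 0, eps, -eps)
  n_clamped <- sum(small)
  if (n_clamped > 0 && warn) {
    warning(sprintf(
      "%d model value(s) below %g %% signal change clamped in EV denominator",
      n_clamped, eps
    ), call. = FALSE)
  }
  ev <- sum(((r - m) / denom)^2)
  attr(ev, "n_clamped") <- n_clamped
  ev
}

#' Block-averaged BOLD time courses for one fit
#'
#' Container for the four per-condition averaged time courses consumed by
#' [fit_joint_hrf()]: a 13 x 4 matrix with chroma conditions as columns.
#'
#' @param responses 13 x 4 numeric matrix (or data frame) of percent signal
#'   change, columns named by chroma condition.
#' @param n_blocks Blocks averaged per condition.
#' @param times Sample times; defaults to [time_grid()].
#' @return An object of class `bold_timecourses`.
#' @export
bold_timecourses <- function(responses, n_blocks = 54L,
                             times = time_grid()) {
  m <- as.matrix(responses)
  if (is.null(colnames(m))) colnames(m) <- chroma_levels()
  check_chroma(colnames(m))
  if (nrow(m) != length(times)) {
    stop("responses must have one row per grid time (", length(times), ")",
      call. = FALSE
    )
  }
  if (ncol(m) != 4L) stop("four chroma conditions are required", call. = FALSE)
  m <- m[, chroma_levels(), drop = FALSE]
  structure(
    list(responses = m, n_blocks = as.integer(n_blocks), times = times),
    class = "bold_timecourses"
  )
}

#' @export
print.bold_timecourses <- function(x, ...) {
  cat(sprintf(
    "BOLD block time courses: %d time points x %d conditions (%d blocks averaged)\n",
    nrow(x$responses), ncol(x$responses), x$n_blocks
  ))
  invisible(x)
}
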