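# Cumulative-Gaussian psychometric analysis of 2AFC contrast discrimination.
#
# The probability of judging the test grating as higher-contrast is modelled
# as the Gaussian CDF of the test contrast, P(x) = Phi((x - mu) / sigma):
# mu is the contrast of subjective equality (50% point) and sigma, the
# standard deviation of the fitted distribution, is read through signal
# detection theory as inversely proportional to the effective luminance
# signal-to-noise ratio, so 1/sigma serves as the sensitivity index.

#' Aggregate 2AFC trials into response-rate tables
#'
#' Discards the first `discard_first_sessions` sessions (learning effect)
#' and tallies, per chroma condition and test-contrast level, the number of
#' trials and of "test judged higher" responses.
#'
#' @param trials Data frame with columns `subject`, `session`, `chroma`,
#'   `test_contrast`, `response` (logical or 0/1; optionally `order`).
#' @param discard_first_sessions Sessions dropped from the start of each
#'   subject's data.
#' @return A data frame with columns `subject`, `chroma`, `test_contrast`,
#'   `n_trials`, `n_chose_test`, `proportion`.
#' @export
aggregate_rates <- function(trials, discard_first_sessions = 2L) {
  need <- c("subject", "session", "chroma", "test_contrast", "response")
  if (!all(need %in% names(trials))) {
    stop("trials must have columns ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  check_chroma(unique(trials$chroma))
  keep <- trials$session > discard_first_sessions
  if (!any(keep)) stop("no trials retained after discarding sessions",
    call. = FALSE
  )
  t2 <- trials[keep, ]
  agg <- stats::aggregate(
    cbind(n_trials = 1L, n_chose_test = as.integer(t2$response)) ~
      subject + chroma + test_contrast,
    data = t2, FUN = sum
  )
  agg <- agg[order(agg$subject, agg$chroma, agg$test_contrast), ]
  agg$proportion <- agg$n_chose_test / agg$n_trials
  rownames(agg) <- NULL
  agg
}

#' Fit the cumulative-Gaussian psychometric function
#'
#' Estimates `(mu, sigma)` of `P(x) = Phi((x - mu) / sigma)`, with no lapse
#' parameter. The default is trialwise maximum likelihood (Bernoulli
#' likelihood on the per-level counts); `"ls"` minimises squared error on
#' the observed proportions. `sigma` is constrained to `[1e-4, 1]`; fits at
#' the boundary (e.g. degenerate data with all responses identical) are
#' flagged rather than failed.
#'
#' @param rates A rate table from [aggregate_rates()] (one subject and one
#'   chroma condition), or any data frame with `test_contrast`, `n_trials`,
#'   `n_chose_test`.
#' @param method `"ml"` or `"ls"`.
#' @param sigma_bounds Lower/upper bounds on sigma (contrast units).
#' @return An object of class `psychometric_fit`: `mu`, `sigma`,
#'   `sensitivity` (= 1/sigma), `method`, `logLik` (ML) or `rss` (LS),
#'   `n_trials`, flags `converged` and `boundary`.
#' @export
#' @examples
#' x <- seq(0.34, 0.66, length.out = 9)
#' rates <- data.frame(
#'   test_contrast = x, n_trials = 200,
#'   n_chose_test = rbinom(9, 200, pnorm(x, 0.5, 0.05))
#' )
#' fit_psychometric(rates)
fit_psychometric <- function(rates, method = c("ml", "ls"),
                             sigma_bounds = c(1e-4, 1)) {
  method <- match.arg(method)
  need <- c("test_contrast", "n_trials", "n_chose_test")
  if (!all(need %in% names(rates))) {
    stop("rates must have columns ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  x <- rates$test_contrast
  n <- rates$n_trials
  k <- rates$n_chose_test
  if (length(unique(x)) < 3L) {
    stop("at least 3 distinct contrast levels are required", call. = FALSE)
  }
  p_obs <- k / n
  degenerate <- all(k == 0) || all(k == n)

  # moment-style start: interpolate the 50% point, slope from the spread
  mu0 <- tryCatch(
    stats::approx(p_obs, x, xout = 0.5, ties = mean)$y,
    error = function(e) NA_real_
  )
  if (!is.finite(mu0)) mu0 <- stats::weighted.mean(x, w = n)
  sigma0 <- diff(range(x)) / 4

  nll <- function(par) {
    p <- stats::pnorm((x - par[1]) / par[2])
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(k * log(p) + (n - k) * log(1 - p))
  }
  rss_fn <- function(par) {
    sum((p_obs - stats::pnorm((x - par[1]) / par[2]))^2)
  }
  obj <- if (method == "ml") nll else rss_fn
  span <- diff(range(x))
  opt <- stats::optim(c(mu0, sigma0), obj,
    method = "L-BFGS-B",
    lower = c(min(x) - 2 * span, sigma_bounds[1]),
    upper = c(max(x) + 2 * span, sigma_bounds[2]),
    control = list(maxit = 500L, factr = 1e4)
  )
  boundary <- degenerate ||
    abs(opt$par[2] - sigma_bounds[1]) < 1e-12 ||
    abs(opt$par[2] - sigma_bounds[2]) < 1e-12
  if (boundary) {
    warning("psychometric fit at the sigma boundary; data may be degenerate",
      call. = FALSE
    )
  }
  structure(
    list(
      mu = opt$par[1], sigma = opt$par[2],
      sensitivity = 1 / opt$par[2],
      method = method,
      logLik = if (method == "ml") -opt$value else NA_real_,
      rss = if (method == "ls") opt$value else rss_fn(opt$par),
      n_trials = sum(n),
      converged = opt$convergence == 0L,
      boundary = boundary
    ),
    class = "psychometric_fit"
  )
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "Cumulative-Gaussian fit (%s): mu = %.4f, sigma = %.4f (1/sigma = %.2f), n = %d%s\n",
    toupper(x$method), x$mu, x$sigma, x$sensitivity, x$n_trials,
    if (x$boundary) " [boundary]" else ""
  ))
  invisible(x)
}

#' Predicted response probability of a fitted psychometric function
#'
#' @param object A [psychometric_fit].
#' @param newdata Numeric vector of test contrasts.
#' @param ... Unused.
#' @return Probabilities `Phi((x - mu) / sigma)`.
#' @export
predict.psychometric_fit <- function(object, newdata, ...) {
  stats::pnorm((newdata - object$mu) / object$sigma)
}

#' Contrast at a criterion probability
#'
#' The discrimination threshold at a criterion level (e.g. 75%):
#' `mu + sigma * qnorm(criterion)`.
#'
#' @param fit A [psychometric_fit] (or any list with `mu`, `sigma`).
#' @param criterion Probability strictly between 0 and 1.
#' @return Contrast (Michelson fraction).
#' @export
threshold_at_criterion <- function(fit, criterion = 0.75) {
  if (any(criterion <= 0 | criterion >= 1)) {
    stop("criterion must lie strictly between 0 and 1", call. = FALSE)
  }
  fit$mu + fit$sigma * stats::qnorm(criterion)
}

#' Flag subjects with outlying psychometric spread
#'
#' Computes each subject's mean sigma across the four chroma conditions and
#' flags those exceeding `factor` times the cohort median as excluded (the
#' rule that removed the one subject whose mean sigma of 0.35 stood apart
#' from a 0.05-0.12 cohort).
#'
#' @param sigmas Data frame with columns `subject`, `chroma`, `sigma`, or a
#'   named vector of per-subject mean sigmas.
#' @param factor Exclusion threshold as a multiple of the cohort median.
#' @return A data frame with `subject`, `mean_sigma`, `threshold`, `margin`
#'   and logical `excluded`.
#' @export
exclude_subjects <- function(sigmas, factor = 3) {
  if (is.data.frame(sigmas)) {
    ms <- tapply(sigmas$sigma, sigmas$subject, mean)
  } else {
    ms <- sigmas
  }
  if (length(ms) < 3L) stop("at least 3 subjects are required", call. = FALSE)
  thr <- factor * stats::median(ms)
  out <- data.frame(
    subject = names(ms), mean_sigma = as.numeric(ms),
    threshold = thr, margin = as.numeric(ms) - thr,
    excluded = as.numeric(ms) > thr,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
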