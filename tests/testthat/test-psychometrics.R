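test_that("aggregation discards early sessions and tallies cells correctly", {
  obs <- paper_like_observer_config(1L, seed = 4)
  trials <- simulate_2afc(obs)
  rates <- aggregate_rates(trials)
  expect_true(all(rates$n_trials == 10L))
  expect_equal(nrow(rates), 4L * 9L)
  expect_true(all(rates$proportion == rates$n_chose_test / rates$n_trials))

  # order invariance
  shuffled <- trials[sample(nrow(trials)), ]
  expect_equal(aggregate_rates(shuffled), rates)

  toy <- data.frame(
    subject = "a", session = 3, chroma = "/0",
    test_contrast = 0.5, response = c(1, 1, 1, 0)
  )
  expect_equal(aggregate_rates(toy)$proportion, 0.75)
  expect_error(
    aggregate_rates(toy, discard_first_sessions = 5),
    "no trials retained"
  )
})

test_that("the fitted curve passes through 0.5 at mu", {
  x <- seq(0.34, 0.66, length.out = 9)
  rates <- data.frame(
    test_contrast = x, n_trials = 50,
    n_chose_test = round(50 * pnorm((x - 0.5) / 0.06))
  )
  fit <- fit_psychometric(rates)
  expect_equal(predict(fit, fit$mu), 0.5)
  expect_equal(threshold_at_criterion(fit, 0.5), fit$mu)
})

test_that("a simulated observer's mu and sigma are recovered within 10%", {
  x <- seq(0.34, 0.66, length.out = 9)
  set.seed(1234)
  k <- rbinom(9, 200, pnorm((x - 0.5) / 0.05))
  rates <- data.frame(test_contrast = x, n_trials = 200, n_chose_test = k)
  for (method in c("ml", "ls")) {
    fit <- fit_psychometric(rates, method = method)
    expect_equal(fit$mu, 0.50, tolerance = 0.10)
    expect_equal(fit$sigma, 0.05, tolerance = 0.10)
    expect_equal(fit$sensitivity, 1 / fit$sigma)
  }
})

test_that("trialwise ML agrees with probit regression (independent oracle)", {
  x <- seq(0.34, 0.66, length.out = 9)
  set.seed(77)
  k <- rbinom(9, 120, pnorm((x - 0.52) / 0.07))
  rates <- data.frame(test_contrast = x, n_trials = 120, n_chose_test = k)
  fit <- fit_psychometric(rates, method = "ml")
  glm_fit <- glm(cbind(n_chose_test, n_trials - n_chose_test) ~ test_contrast,
    family = binomial("probit"), data = rates
  )
  mu_glm <- -coef(glm_fit)[[1]] / coef(glm_fit)[[2]]
  sigma_glm <- 1 / coef(glm_fit)[[2]]
  expect_equal(fit$mu, mu_glm, tolerance = 1e-3)
  expect_equal(fit$sigma, sigma_glm, tolerance = 1e-3)
})

test_that("translating the contrast axis shifts mu and preserves sigma", {
  x <- seq(0.34, 0.66, length.out = 9)
  p <- pnorm((x - 0.5) / 0.06)
  rates <- data.frame(test_contrast = x, n_trials = 1000, n_chose_test = 1000 * p)
  shifted <- rates
  shifted$test_contrast <- x + 0.1
  f0 <- fit_psychometric(rates, method = "ls")
  f1 <- fit_psychometric(shifted, method = "ls")
  expect_equal(f1$mu - f0$mu, 0.1, tolerance = 1e-6)
  expect_equal(f1$sigma, f0$sigma, tolerance = 1e-6)
})

test_that("ML and LS agree on sigma for clean proportion tables", {
  x <- seq(0.34, 0.66, length.out = 9)
  p <- pnorm((x - 0.48) / 0.08)
  rates <- data.frame(
    test_contrast = x, n_trials = 500,
    n_chose_test = round(500 * p)
  )
  ml <- fit_psychometric(rates, method = "ml")
  ls <- fit_psychometric(rates, method = "ls")
  expect_equal(ml$sigma, ls$sigma, tolerance = 0.05)
})

test_that("degenerate response data produce a flagged boundary fit", {
  x <- seq(0.34, 0.66, length.out = 9)
  rates <- data.frame(test_contrast = x, n_trials = 10, n_chose_test = 10)
  expect_warning(fit <- fit_psychometric(rates), "boundary")
  expect_true(fit$boundary)
  expect_gt(fit$sigma, 0)
  expect_error(
    fit_psychometric(data.frame(
      test_contrast = c(0.4, 0.5), n_trials = 5, n_chose_test = 2
    )),
    "3 distinct"
  )
})

test_that("criterion thresholds follow the Gaussian quantile closed form", {
  fit <- list(mu = 0.50, sigma = 0.05)
  thr <- threshold_at_criterion(fit, 0.75)
  expect_equal(thr, 0.50 + 0.05 * qnorm(0.75), tolerance = 1e-12)
  oracle <- bisect_gaussian_quantile(0.75, 0.50, 0.05)
  expect_equal(thr, oracle, tolerance = 1e-8)
  lo <- threshold_at_criterion(fit, 0.25)
  expect_equal((lo + thr) / 2, fit$mu, tolerance = 1e-12)
  expect_error(threshold_at_criterion(fit, 1), "criterion")
})

test_that("the exclusion rule isolates the outlying subject of the cohort", {
  cohort <- c(seq(0.05, 0.12, length.out = 9), 0.35)
  names(cohort) <- sprintf("S%02d", 1:10)
  res <- exclude_subjects(cohort)
  expect_identical(res$subject[res$excluded], "S10")
  expect_equal(sum(res$excluded), 1L)

  homogeneous <- setNames(seq(0.05, 0.12, length.out = 9), paste0("H", 1:9))
  expect_false(any(exclude_subjects(homogeneous)$excluded))
  expect_false(any(exclude_subjects(cohort, factor = 10)$excluded))
  expect_error(exclude_subjects(c(a = 1, b = 2)), "3 subjects")
})

test_that("sigma recovery is unbiased at the study's design scale", {
  # 9 levels x 10 trials, 100 seeded replicates; wide tolerance at this n
  x <- seq(0.34, 0.66, length.out = 9)
  true_sigma <- 0.08
  set.seed(2024)
  sigmas <- replicate(100, {
    k <- rbinom(9, 10, pnorm((x - 0.5) / true_sigma))
    fit <- suppressWarnings(fit_psychometric(
      data.frame(test_contrast = x, n_trials = 10, n_chose_test = k)
    ))
    fit$sigma
  })
  expect_equal(mean(sigmas), true_sigma, tolerance = 0.15)
})

test_that("the sensitivity index is antitone in the true sigma", {
  x <- seq(0.34, 0.66, length.out = 9)
  set.seed(9)
  sens <- vapply(c(0.04, 0.08, 0.16), function(s) {
    k <- rbinom(9, 400, pnorm((x - 0.5) / s))
    fit_psychometric(
      data.frame(test_contrast = x, n_trials = 400, n_chose_test = k)
    )$sensitivity
  }, numeric(1))
  expect_true(all(diff(sens) < 0))
})
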