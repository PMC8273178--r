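test_that("schedules satisfy their multiplicity invariants for many seeds", {
  for (seed in 1:100) {
    sch <- schedule_fmri(seed = seed)
    per_run <- table(
      sch$blocks$run[sch$blocks$block > 0],
      sch$blocks$condition[sch$blocks$block > 0]
    )
    expect_true(all(per_run == 3L))
    expect_equal(sum(sch$blocks$block == 0), 18L)
  }
})

test_that("the full experiment yields 54 blocks per condition, 216 total", {
  sch <- schedule_fmri(seed = 7)
  sch$runs$excluded[] <- FALSE
  rb <- retained_blocks(sch)
  expect_equal(as.numeric(table(rb$condition)), rep(54, 4))
  expect_equal(nrow(rb), 216L)
  excl <- mark_runs_excluded(sch, 5L)
  expect_equal(as.numeric(table(retained_blocks(excl)$condition)), rep(51, 4))
})

test_that("awareness exclusion follows the more-than-three-errors rule", {
  sch <- schedule_fmri(seed = 1)
  expect_identical(sch$runs$excluded, sch$runs$awareness_errors > 3L)
  # at the default error rate, accuracy across a cohort is near 98.7%
  acc <- vapply(1:20, function(s) {
    sc <- schedule_fmri(seed = s)
    1 - sum(sc$runs$awareness_errors) / (18 * 13)
  }, numeric(1))
  expect_equal(mean(acc), 0.987, tolerance = 0.005)
})

test_that("noise-free simulation reproduces the model response exactly", {
  truth <- paper_like_bold_truth(1L, noise_sd = 0, seed = 2)[[1]]
  tc <- simulate_bold(truth, subject = 1)
  for (ch in chroma_levels()) {
    expect_equal(
      tc$responses[, ch],
      model_response(truth$temporal, truth$per_condition[[ch]]),
      ignore_attr = TRUE
    )
  }
  expect_equal(tc$n_blocks, 54L)
})

test_that("simulation is a pure function of config and seed", {
  truth <- paper_like_bold_truth(1L, seed = 6)[[1]]
  expect_identical(
    simulate_bold(truth, subject = 1)$responses,
    simulate_bold(truth, subject = 1)$responses
  )
  expect_false(identical(
    simulate_bold(truth, subject = 1)$responses,
    simulate_bold(truth, subject = 2)$responses
  ))
  obs <- paper_like_observer_config(2L, seed = 3)
  expect_identical(simulate_2afc(obs), simulate_2afc(obs))
})

test_that("54-block averaging shrinks the noise by sqrt(54)", {
  truth <- paper_like_bold_truth(1L, noise_sd = 1.5, seed = 8)[[1]]
  sch <- schedule_fmri(seed = 4)
  sch$runs$excluded[] <- FALSE
  noiseless <- truth
  noiseless$noise_sd <- 0
  clean <- simulate_bold(noiseless, sch, subject = 1)
  devs <- sapply(1:50, function(r) {
    cfg <- truth
    cfg$seed <- derive_seed(71L, r)
    tc <- simulate_bold(cfg, sch, level = "block", subject = 1)
    as.numeric(tc$responses - clean$responses)
  })
  expect_equal(sd(devs), 1.5 / sqrt(54), tolerance = 0.2)
})

test_that("a far-suprathreshold observer responds correctly almost surely", {
  tp <- data.frame(
    subject = "S01", chroma = chroma_levels(), mu = 0.5, sigma = 0.01
  )
  cfg <- observer_config(tp,
    n_sessions = 625L,
    contrasts = 0.5 + 10 * 0.01, seed = 13
  )
  trials <- simulate_2afc(cfg)
  expect_equal(nrow(trials), 625L * 4L)
  expect_gte(mean(trials$response), 0.999)
})

test_that("every session presents all 36 conditions once", {
  obs <- paper_like_observer_config(1L, seed = 10)
  trials <- simulate_2afc(obs)
  for (sess in c(1, 6, 12)) {
    s <- trials[trials$session == sess, ]
    expect_equal(nrow(s), 36L)
    expect_equal(nrow(unique(s[c("chroma", "test_contrast")])), 36L)
  }
  expect_true(all(trials$isi_ms >= 1000 & trials$isi_ms <= 2000))
})

test_that("simulate -> aggregate -> fit recovers sigma within 10% at scale", {
  tp <- data.frame(
    subject = "S01", chroma = chroma_levels(),
    mu = 0.5, sigma = c(0.08, 0.11, 0.07, 0.078)
  )
  cfg <- observer_config(tp, n_sessions = 202L, seed = 21)
  trials <- simulate_2afc(cfg)
  rates <- aggregate_rates(trials) # 200 retained trials per level
  for (ch in chroma_levels()) {
    cell <- rates[rates$chroma == ch, ]
    fit <- fit_psychometric(cell)
    expect_equal(fit$sigma, tp$sigma[tp$chroma == ch], tolerance = 0.10)
  }
})

test_that("config constructors validate their fields", {
  tp <- data.frame(subject = "a", chroma = "/0", mu = 0.5, sigma = 0.1)
  expect_error(observer_config(transform(tp, sigma = -1)), "sigma")
  expect_error(observer_config(tp, lapse = 0.9), "lapse")
  truth <- paper_like_bold_truth(1L)[[1]]
  expect_error(
    bold_sim_config(truth$temporal, truth$per_condition, noise_sd = -1),
    "noise_sd"
  )
  expect_error(
    bold_sim_config(truth$temporal, truth$per_condition, ar1 = 1),
    "ar1"
  )
})
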