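test_that("RECIST rules classify diameters as specified", {
  expect_equal(recist_classify(50, 9), "CR")
  expect_equal(recist_classify(50, 34), "PR")   # 32% decrease
  expect_equal(recist_classify(50, 36), "SD")   # 28% decrease
  expect_equal(recist_classify(20, 24.5), "SD") # +22.5% but only +4.5 mm
  expect_equal(recist_classify(20, 26), "PD")   # +30% and +6 mm
  # CR takes priority even when the PD conditions hold numerically
  expect_equal(recist_classify(4, 9.5), "CR")
  expect_equal(recist_classify(30, c(9, 20, 29, 37)),
               c("CR", "PR", "SD", "PD"))
})

test_that("product-limit curve matches hand calculations", {
  p <- pfs_curve(c(2, 5, NA, NA), c(NA, NA, NA, NA), trial_end = 10)
  expect_equal(pfs_at(p, c(1, 2, 4.9, 5, 10)), c(100, 75, 75, 50, 50))

  pc <- pfs_curve(c(2, 5, NA, NA), c(NA, NA, 3, NA), trial_end = 10)
  expect_equal(pfs_at(pc, c(2, 5)), c(75, 37.5))

  flat <- pfs_curve(rep(NA, 5), rep(NA, 5), trial_end = 12)
  expect_equal(pfs_at(flat, 12), 100)

  expect_error(pfs_curve(c(2, NA), c(1, NA), trial_end = 5), "both")
})

test_that("pfs_curve equals the product-limit oracle on random cohorts", {
  set.seed(2024)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    ev <- rexp(n, 0.1)
    cn <- rexp(n, 0.07)
    end <- 15
    event_times <- ifelse(ev <= pmin(cn, end), ev, NA)
    censor_times <- ifelse(is.na(event_times), pmin(cn, end), NA)
    ours <- pfs_curve(event_times, censor_times, end)
    time_obs <- pmin(ev, cn, end)
    status <- as.integer(!is.na(event_times))
    km <- survival::survfit(survival::Surv(time_obs, status) ~ 1)
    at_events <- summary(km, times = ours$time[-1])$surv
    expect_equal(ours$survival[-1], at_events * 100, tolerance = 1e-10)
  }
})

test_that("survival is non-increasing, bounded, and starts at 100", {
  set.seed(77)
  ev <- rexp(40, 0.2); cn <- rexp(40, 0.1)
  event_times <- ifelse(ev <= pmin(cn, 10), ev, NA)
  censor_times <- ifelse(is.na(event_times), pmin(cn, 10), NA)
  p <- pfs_curve(event_times, censor_times, 10)
  expect_equal(p$survival[1], 100)
  expect_true(all(diff(p$survival) <= 0))
  expect_true(all(p$survival >= 0 & p$survival <= 100))
})

test_that("virtual populations honour their CVs and are median-preserving", {
  tgi <- quick_tgi()
  spec0 <- population_spec(tgi, list(), n_patients = 5)
  pop0 <- sample_population(spec0)
  expect_true(all(pop0$t_double == tgi$t_double))

  spec <- population_spec(tgi, list(kc50 = 0.4, t_double = 0.15),
                          n_patients = 10000)
  set.seed(31)
  pop <- sample_population(spec)
  expect_equal(sd(pop$kc50) / mean(pop$kc50), 0.4, tolerance = 0.05)
  expect_equal(sd(pop$t_double) / mean(pop$t_double), 0.15,
               tolerance = 0.05)
  expect_equal(median(pop$kc50), tgi$kc50, tolerance = 0.05)
  expect_true(all(pop$kc50 > 0))
})

test_that("exponential dropout sampling has the right moments", {
  expect_true(all(is.infinite(censor_sample(0, 5))))
  x <- censor_sample(0.02, 10000, seed = 8)
  expect_equal(mean(x), 50, tolerance = 0.03)
  expect_identical(censor_sample(0.02, 100, seed = 8),
                   censor_sample(0.02, 100, seed = 8))
})

test_that("trials are reproducible and abort-safe", {
  cfg <- default_config("trial_tdm1_ph2")
  cfg$trial$n_patients <- 8L
  r1 <- run_trial(cfg, seed = 5, her2_receptors_per_cell = 2e4)
  r2 <- run_trial(cfg, seed = 5, her2_receptors_per_cell = 2e4)
  expect_identical(r1$patients, r2$patients)
  expect_identical(r1$pfs, r2$pfs)
  expect_s3_class(r1$pfs, "pfs_curve")
  expect_true(all(r1$patients$event_time[r1$patients$event] <=
                    cfg$trial$duration, na.rm = TRUE))
})

test_that("a potently killed single patient has no progression events", {
  cfg <- default_config("trial_tdm1_ph2")
  cfg$trial$n_patients <- 1L
  cfg$trial$dropout_rate <- 0
  cfg <- set_params(cfg, list("tgi.kc50" = 1))   # essentially maximal kill
  cfg$trial$cv <- list()
  res <- run_trial(cfg, seed = 2)
  expect_equal(res$summary$n_events, 0)
  expect_equal(tail(res$pfs$survival, 1), 100)
})
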