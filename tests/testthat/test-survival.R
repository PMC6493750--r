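test_that("surv_data validates its inputs", {
  expect_error(surv_data(numeric(0), integer(0)), "at least one")
  expect_error(surv_data(c(1, -2), c(1, 1)), "positive")
  expect_error(surv_data(c(1, 2), c(1, 2)), "0/1")
})

test_that("km_curve reproduces hand-computed product-limit values", {
  # three deaths, no censoring
  km <- km_curve(surv_data(c(1, 2, 3), c(1, 1, 1)))
  expect_equal(km$curve$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$median, 2)

  # censoring in the middle: S(1) = 2/3, S(3) = 2/3 * (1 - 1/1) = 0
  km2 <- km_curve(surv_data(c(1, 2, 3), c(1, 0, 1)))
  expect_equal(km2$curve$survival[km2$curve$time == 1], 2 / 3)
  expect_equal(km2$curve$survival[km2$curve$time == 3], 0)

  # single censored subject: no events, median not reached
  km3 <- km_curve(surv_data(5, 0))
  expect_equal(sum(km3$curve$n_event), 0)
  expect_true(is.na(km3$median))
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(18)
  for (k in 1:20) {
    t <- round(rexp(sample(5:60, 1), 1 / 30), 1) + 0.1
    km <- km_curve(surv_data(t, rep(1, length(t))))
    emp <- vapply(km$curve$time, function(x) mean(t > x), numeric(1))
    expect_equal(km$curve$survival, emp)
    # against an independent product-limit accumulation
    want <- oracle_km(t, rep(1, length(t)))
    expect_equal(km$curve$survival, want$survival)
  }
})

test_that("km quartiles use the smallest-time-below convention", {
  km <- km_curve(surv_data(c(10, 20, 30, 40), rep(1, 4)))
  expect_equal(km$q25, 10)   # S(10) = 0.75
  expect_equal(km$median, 20)
  expect_equal(km$q75, 30)
})

test_that("log-rank matches the hand-computed O/E/V table", {
  a <- surv_data(c(1, 2), c(1, 1), "a")
  b <- surv_data(c(3, 4), c(1, 1), "b")
  lr <- log_rank(a, b)
  # by hand over event times 1..4: O_A = 2, E_A = 1/2 + 1/3,
  # V = 1/4 + 2/9, statistic = (2 - 5/6)^2 / (17/36) = 49/17
  expect_equal(lr$statistic, 49 / 17, tolerance = 1e-12)
  expect_equal(lr$df, 1L)
  expect_equal(lr$p_value, pchisq(49 / 17, 1, lower.tail = FALSE))

  ident <- log_rank(surv_data(c(2, 4, 6), c(1, 1, 0), "x"),
                    surv_data(c(2, 4, 6), c(1, 1, 0), "y"))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)

  # symmetric in group order
  lr_ba <- log_rank(b, a)
  expect_equal(lr_ba$statistic, lr$statistic)
})

test_that("log-rank has power against separated exponentials", {
  set.seed(19)
  hits <- 0
  for (k in 1:100) {
    a <- surv_data(rexp(200, 1 / 20), rep(1, 200), "a")
    b <- surv_data(rexp(200, 1 / 40), rep(1, 200), "b")
    if (log_rank(a, b)$p_value < 0.001) hits <- hits + 1
  }
  expect_gte(hits, 99)
})

test_that("summaries report deaths-only mean and lethality", {
  s <- summarize_survival(surv_data(c(10, 20, 30), c(1, 1, 1)))
  expect_equal(s$mean, 20)
  expect_equal(s$median, 20)
  expect_equal(s$sem, 10 / sqrt(3))

  s2 <- summarize_survival(surv_data(c(10, 10, 40, 40), rep(1, 4)),
                           lethality_at = 24)
  expect_equal(s2$lethality$percent_dead, 50)

  s3 <- summarize_survival(surv_data(5, 0))
  expect_true(is.na(s3$mean))
  expect_equal(s3$n_censored, 1)
})

test_that("summaries agree with direct recomputation on random datasets", {
  set.seed(20)
  for (k in 1:100) {
    n <- sample(4:40, 1)
    t <- round(rexp(n, 1 / 30), 1) + 0.1
    e <- rbinom(n, 1, 0.7)
    if (!any(e == 1)) e[1] <- 1
    s <- summarize_survival(surv_data(t, e), lethality_at = c(12, 30))
    expect_equal(s$mean, mean(t[e == 1]))
    if (sum(e) > 1) expect_equal(s$sem, sd(t[e == 1]) / sqrt(sum(e)))
    # median by the stated convention, from an independent product-limit
    o <- oracle_km(t, e)
    hit <- o$time[o$survival <= 0.5 + 1e-12]
    want_med <- if (length(hit)) min(hit) else NA_real_
    expect_equal(s$median, want_med)
    for (i in 1:2) {
      tt <- c(12, 30)[i]
      denom <- sum(t >= tt | (e == 1 & t <= tt))
      expect_equal(s$lethality$percent_dead[i],
                   100 * sum(e == 1 & t <= tt) / denom)
    }
  }
})

test_that("power-law fits recover exact coefficients on noiseless data", {
  x <- c(0.25, 0.5, 0.75, 1)
  fit <- fit_power_law(x, 10.503 * x^-1.394)
  expect_equal(fit$a, 10.503, tolerance = 1e-9)
  expect_equal(fit$b, -1.394, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  flat <- fit_power_law(c(1, 2, 4), c(33, 33, 33))
  expect_equal(flat$b, 0)
  expect_equal(flat$a, 33)
  expect_equal(flat$r_squared, 1)

  two <- fit_power_law(c(0.5, 2), c(40, 10))
  expect_equal(two$r_squared, 1)
  expect_equal(predict_median(two, c(0.5, 2)), c(40, 10))

  set.seed(21)
  for (k in 1:25) {
    a <- runif(1, 0.1, 100); b <- runif(1, -3, 3)
    doses <- sort(runif(sample(3:8, 1), 0.05, 5))
    f <- fit_power_law(doses, a * doses^b)
    expect_equal(f$a, a, tolerance = 1e-6)
    expect_equal(f$b, b, tolerance = 1e-6)
  }

  expect_error(fit_power_law(c(1, -1), c(2, 2)), "positive")
  expect_error(fit_power_law(1, 2), "at least 2")
})

test_that("equivalent dose inverts the model and scales sensitivity", {
  fit <- dose_response_fit(10.503, -1.394)
  expect_equal(signif(equivalent_dose(fit, 36), 3), 0.413)
  expect_equal(equivalent_dose(fit, fit$a), 1)
  for (x0 in c(0.1, 0.5, 2))
    expect_equal(equivalent_dose(fit, predict_median(fit, x0)), x0,
                 tolerance = 1e-12)

  expect_equal(relative_sensitivity(fit, 0.25, 36), 65.3, tolerance = 0.01)
  expect_equal(relative_sensitivity(fit, 0.25, predict_median(fit, 0.25)), 0)
  # doubling the equivalent dose doubles the excess sensitivity to 100%
  x2 <- predict_median(fit, 0.5)
  expect_equal(relative_sensitivity(fit, 0.25, x2), 100)

  expect_error(equivalent_dose(dose_response_fit(10, 0), 5), "flat")
  expect_error(equivalent_dose(fit, -3), "positive")
})
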