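obj_df <- function(rows, cols) {
  n <- length(rows)
  data.frame(arena = rep(1L, n), time_h = rep(0, n), area = rep(400, n),
             centroid_row = rows, centroid_col = cols,
             bbox_height = rep(10, n), bbox_width = rep(40, n),
             mean_intensity = rep(60, n))
}

test_that("match_objects pairs nearest centroids and reports leftovers", {
  m <- match_objects(obj_df(10, 10), obj_df(10, 10))
  expect_equal(nrow(m$pairs), 1)
  expect_equal(m$pairs$displacement, 0)

  m2 <- match_objects(obj_df(10, 10), obj_df(13, 14))
  expect_equal(m2$pairs$displacement, 5)  # 3-4-5 triangle

  # 2 objects vs 1: nearest pair matched, the other is a disappearance
  m3 <- match_objects(obj_df(c(10, 40), c(10, 10)), obj_df(38, 12))
  expect_equal(nrow(m3$pairs), 1)
  expect_equal(m3$pairs$prev_idx, 2)
  expect_equal(m3$disappearances, 1)
  expect_equal(length(m3$appearances), 0)

  # against the exhaustive minimal-assignment oracle on 2-vs-1 cases
  set.seed(14)
  for (k in 1:25) {
    prev <- matrix(runif(4, 0, 100), 2)
    curr <- matrix(runif(2, 0, 100), 1)
    m4 <- match_objects(obj_df(prev[, 1], prev[, 2]),
                        obj_df(curr[, 1], curr[, 2]))
    want <- oracle_assignment(prev, curr)
    expect_equal(m4$pairs$prev_idx, unname(want[, "prev_idx"]))
  }

  empty <- obj_df(numeric(0), numeric(0))
  m5 <- match_objects(empty, obj_df(5, 5))
  expect_equal(nrow(m5$pairs), 0)
  expect_equal(m5$appearances, 1)
})

test_that("global shift compensation acts only on an arena consensus", {
  near_zero <- data.frame(arena = 1:6, drow = rnorm(6, 0, 0.2),
                          dcol = rnorm(6, 0, 0.2))
  near_zero$displacement <- sqrt(near_zero$drow^2 + near_zero$dcol^2)
  c0 <- compensate_global_shift(near_zero)
  expect_false(c0$flagged)
  expect_equal(c0$vectors, near_zero)

  # a uniform (10, 0) added to every arena is recognised and inverted
  set.seed(15)
  base <- data.frame(arena = 1:8, drow = c(rnorm(6, 0, 0.5), 9, -8),
                     dcol = c(rnorm(6, 0, 0.5), 2, 5))
  shifted <- base
  shifted$drow <- shifted$drow + 10
  shifted$displacement <- sqrt(shifted$drow^2 + shifted$dcol^2)
  cs <- compensate_global_shift(shifted)
  expect_true(cs$flagged)
  expect_equal(cs$shift[1], 10, tolerance = 0.5)
  expect_equal(cs$vectors$drow, base$drow + 10 - cs$shift[1],
               tolerance = 1e-9)

  # one arena moving on its own must not trigger compensation
  solo <- data.frame(arena = 1:6, drow = c(10, 0, 0, 0, 0, 0),
                     dcol = 0, displacement = c(10, 0, 0, 0, 0, 0))
  expect_false(compensate_global_shift(solo)$flagged)

  # fewer than 3 populated arenas: nothing to agree on
  two <- data.frame(arena = 1:2, drow = 10, dcol = 0, displacement = 10)
  expect_false(compensate_global_shift(two)$flagged)
})

test_that("moving_count uses a strict threshold and counts topology changes", {
  expect_equal(moving_count(7.0), 0L)           # exactly 7 px is not movement
  expect_equal(moving_count(7.000001), 1L)
  expect_equal(moving_count(c(8, 2)), 1L)
  expect_equal(moving_count(numeric(0), n_appear = 0, n_disappear = 1), 1L)
  # capped at the larger object count of the pair
  expect_equal(moving_count(c(8, 9), n_appear = 1, n_disappear = 1,
                            n_prev = 3, n_curr = 3), 3L)
})

test_that("occupancy classification takes the modal count in the window", {
  expect_equal(classify_occupancy(rep(1, 11), 0:10)$class, "1")
  expect_equal(classify_occupancy(c(1, 1, 2, 1, 1, 1, 1, 1, 1, 1, 1),
                                  0:10)$class, "1")
  expect_equal(classify_occupancy(c(1, 1, 2, 2, 9, 9), c(0, 2, 4, 6, 8, 20),
                                  window_h = 10)$class, "2")  # tie -> larger
  occ <- classify_occupancy(c(4, 4, 5, 4, 4, 4, 4, 4, 4, 4, 4), 0:10)
  expect_equal(occ$class, "4+")
  expect_warning(classify_occupancy(c(1, 1, 1), 0:2, window_h = 10),
                 "longer than")
})

test_that("call_death follows the quiescence rule on the worked examples", {
  r1 <- call_death(c(1, 1, 1, 0, 0, 0, 0, 0, 0), 0:8)
  expect_equal(r1$status, "dead")
  expect_equal(r1$time_h, 2)

  r2 <- call_death(rep(1, 9), 0:8)
  expect_equal(r2$status, "censored")
  expect_equal(r2$time_h, 8)

  # single late blip is spurious (< confirm_m)
  r3 <- call_death(c(1, 1, 1, 0, 0, 0, 0, 0, 1, 0, 0, 0, 0), 0:12)
  expect_equal(r3$status, "dead")
  expect_equal(r3$time_h, 2)

  # short quiet run does not kill; confirmed movement re-anchors
  r4 <- call_death(c(1, 1, 1, 0, 0, 1, 1, 0, 0, 0, 0, 0), 0:11)
  expect_equal(r4$status, "dead")
  expect_equal(r4$time_h, 6)

  # confirm_m = 1: any late movement resets the call
  r5 <- call_death(c(1, 1, 1, 0, 0, 0, 0, 0, 1, 0, 0, 0, 0), 0:12,
                   confirm_m = 1)
  expect_equal(r5$time_h, 8)

  # confirmed movement after quiescence, then too-short tail: censored
  r6 <- call_death(c(1, 0, 0, 0, 0, 0, 1, 1, 0, 0), 0:9)
  expect_equal(r6$status, "censored")

  # all-quiet occupied arena: death at the first time point
  r7 <- call_death(rep(0, 9), 0:8)
  expect_equal(r7$status, "dead")
  expect_equal(r7$time_h, 0)

  expect_warning(r8 <- call_death(c(1, 0), 0:1), "shorter")
  expect_equal(r8$status, "censored")

  # statuses driven by occupancy class
  expect_equal(call_death(rep(1, 9), 0:8, occupancy = "0")$status, "empty")
  expect_equal(call_death(rep(1, 9), 0:8, occupancy = "4+")$status, "excluded")
  expect_true(call_death(rep(1, 9), 0:8, occupancy = "2")$multi_occupancy)
})

test_that("quiescence is converted to frames via the sampling interval", {
  # half-hour sampling: 4 h of quiet needs 8 frames
  counts <- c(1, 1, rep(0, 7))
  t_half <- seq(0, by = 0.5, length.out = 9)
  expect_equal(call_death(counts, t_half)$status, "censored")
  expect_equal(call_death(c(1, 1, rep(0, 8)),
                          seq(0, by = 0.5, length.out = 10))$status, "dead")
})

test_that("backward-pass death calling equals the forward-rule oracle", {
  set.seed(16)
  for (k in 1:400) {
    n <- sample(6:40, 1)
    counts <- random_moving_counts(n)
    confirm <- sample(1:3, 1)
    got <- call_death(counts, seq_len(n) - 1, confirm_m = confirm)
    want <- oracle_call_death(counts, seq_len(n) - 1, confirm_m = confirm)
    expect_equal(got$status, want$status)
    if (want$status == "dead") expect_equal(got$time_h, want$time)
  }
})

test_that("compute_yield reproduces the reported arithmetic", {
  expect_equal(round(compute_yield(9153, capacity = 13300), 1), 68.8)
  expect_equal(compute_yield(0, capacity = 50), 0)
  expect_equal(compute_yield(50, capacity = 50), 100)
  calls <- data.frame(status = c("dead", "censored", "empty", "excluded"))
  expect_equal(compute_yield(calls, capacity = 4), 50)
  expect_error(compute_yield(10, capacity = 0), "capacity")
})

test_that("occupancy_summary tabulates class percentages", {
  s <- occupancy_summary(c("1", "1", "2", "0", "4+"))
  expect_equal(s$n, c(1, 2, 1, 0, 1))
  expect_equal(s$percent[s$class == "1"], 40)
})

test_that("arena results are invariant to object-row permutation", {
  cfg <- sim_config(n_arenas = 4, frames = 16, arena_px = c(126, 456),
                    occupancy_probs = c(0, 0.6, 0.4, 0, 0),
                    survival_dist = list(name = "fixed", times = 6),
                    debris_rate = 0, bubble_rate = 0, seed = 23)
  sim <- generate_experiment(cfg)
  objects <- detect_stack(sim$series, sim$regions)
  base <- vitality_from_objects(objects, sim$series$times, sim$regions)
  set.seed(1)
  shuffled <- objects[sample(nrow(objects)), ]
  again <- vitality_from_objects(shuffled, sim$series$times, sim$regions)
  expect_equal(again$calls, base$calls)
  expect_equal(again$moving_counts, base$moving_counts)
})

test_that("statuses partition the arenas (censoring conservation)", {
  cfg <- sim_config(n_arenas = 10, frames = 16,
                    occupancy_probs = c(0.3, 0.4, 0.2, 0.05, 0.05),
                    survival_dist = list(name = "fixed", times = 6),
                    debris_rate = 0.3, bubble_rate = 0.3, seed = 29)
  sim <- generate_experiment(cfg)
  regions <- sim$regions
  regions$excluded[2] <- TRUE
  res <- score_stack(sim$series, regions)
  expect_equal(nrow(res$calls), 10)
  expect_true(all(res$calls$status %in%
                  c("dead", "censored", "excluded", "empty")))
  expect_equal(sum(table(res$calls$status)), 10)
  expect_equal(res$calls$status[2], "excluded")
  expect_equal(res$calls$flags[2], "user_excluded")
})

test_that("pipeline KM median agrees with the generating distribution", {
  # three replicate arrays, pooled; the true median 40 ln 2 must lie in the
  # Brookmeyer-Crowley 95% CI of the pooled Kaplan-Meier median
  calls <- list(); truth_t <- numeric(); truth_e <- integer()
  for (s in 1:3) {
    cfg <- sim_config(n_arenas = 12, frames = 72,
                      occupancy_probs = c(0, 1, 0, 0, 0),
                      debris_rate = 0, bubble_rate = 0, seed = s)
    sim <- generate_experiment(cfg)
    res <- score_stack(sim$series, sim$regions)
    calls[[s]] <- res$calls
    d <- sim$truth$animals$death_time_h
    truth_t <- c(truth_t, ifelse(is.na(d), 71, d))
    truth_e <- c(truth_e, as.integer(!is.na(d)))
  }
  sdat <- calls_to_surv_data(do.call(rbind, calls))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = sdat)
  q <- stats::quantile(fit, probs = 0.5)
  lo <- if (is.na(q$lower)) 0 else q$lower
  up <- if (is.na(q$upper)) Inf else q$upper
  expect_gte(40 * log(2), lo)
  expect_lte(40 * log(2), up)
  # and the recovered median equals the ground-truth sample median within
  # one sampling interval
  km_truth <- km_curve(surv_data(truth_t, truth_e))
  expect_lte(abs(km_curve(sdat)$median - km_truth$median), 1)
})

test_that("frameshift compensation restores exact recovery; disabling it hurts", {
  sim <- fixed_death_shift_sim()
  expd <- expected_calls(sim$truth, sim$series$times)
  on <- score_stack(sim$series, sim$regions, compensate_shifts = TRUE)
  off <- score_stack(sim$series, sim$regions, compensate_shifts = FALSE)
  expect_true(any(on$shift_flags))
  expect_equal(on$calls$time_h, expd$time_h)
  n_on <- sum(on$calls$time_h == expd$time_h)
  n_off <- sum(off$calls$time_h == expd$time_h)
  expect_lt(n_off, n_on)   # regression guard: compensation matters
})
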