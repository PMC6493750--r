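# Shared simulation fixtures, built in code. The full-array runs are
# expensive, so they are computed lazily once per test session and only
# their scored results (not the pixel stacks) are cached.

.sim_cache <- new.env(parent = emptyenv())

match_against_truth <- function(calls, truth, times, quiescent_h = 4) {
  expd <- expected_calls(truth, times, quiescent_h = quiescent_h)
  cmp <- merge(calls, expd, by = "arena", suffixes = c("", ".exp"))
  ok <- (cmp$status == cmp$status.exp) &
    (cmp$status != "dead" | abs(cmp$time_h - cmp$time_h.exp) <= 1)
  list(matched = sum(ok), total = nrow(cmp), mismatches = cmp[!ok, ])
}

# Full 50-arena, 72-frame array at defaults (movement mean 12 px), no
# debris/bubbles; optionally with late global frameshift events.
full_array_recovery <- function(with_shifts = FALSE) {
  key <- if (with_shifts) "shifted" else "clean"
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  shifts <- if (with_shifts)
    data.frame(frame = c(59, 66), drow = c(10, 0), dcol = c(0, -9)) else NULL
  cfg <- sim_config(debris_rate = 0, bubble_rate = 0,
                    global_shift_events = shifts, seed = 7)
  sim <- generate_experiment(cfg)
  res <- score_stack(sim$series, sim$regions, compensate_shifts = TRUE)
  out <- list(calls = res$calls,
              shift_flags = res$shift_flags,
              pair_times = res$pair_times,
              recovery = match_against_truth(res$calls, sim$truth,
                                             sim$series$times),
              truth = sim$truth, times = sim$series$times)
  rm(sim, res); gc(verbose = FALSE)
  .sim_cache[[key]] <- out
  out
}

# Small deterministic array: every arena holds one worm that dies at a
# fixed time, with one global frameshift two hours after death.
fixed_death_shift_sim <- function() {
  if (!is.null(.sim_cache$fixed_shift)) return(.sim_cache$fixed_shift)
  cfg <- sim_config(
    n_arenas = 10, frames = 48, occupancy_probs = c(0, 1, 0, 0, 0),
    survival_dist = list(name = "fixed", times = 30),
    debris_rate = 0, bubble_rate = 0,
    global_shift_events = data.frame(frame = 33, drow = 10, dcol = 0),
    seed = 3)
  .sim_cache$fixed_shift <- generate_experiment(cfg)
  .sim_cache$fixed_shift
}

random_moving_counts <- function(n) {
  # mixes plausible life histories with pure noise series
  kind <- sample(3, 1)
  if (kind == 1) {
    d <- sample(0:n, 1)
    counts <- c(rep(1, d), rep(0, n - d))
  } else if (kind == 2) {
    counts <- rbinom(n, 1, runif(1, 0.1, 0.9))
  } else {
    counts <- sample(0:2, n, replace = TRUE, prob = c(0.6, 0.3, 0.1))
  }
  counts
}
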