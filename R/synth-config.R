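#' Configuration for the synthetic scanner-stack generator
#'
#' Bundles every knob of the simulator with validation. Defaults emulate the
#' real acquisition geometry and the occupancy statistics observed when
#' loading the chips: hourly scans at 3200 dpi (~7.9 um/px, so a ~1 mm
#' adult covers ~1000 px and each 0.99 x 3.6 mm arena is ~126 x 456 px), a
#' 2-column array of 50 arenas, and a loading distribution of roughly
#' 38.8% empty / 50.5% single / 9.2% double / 1.2% triple / 0.3% "4+"
#' arenas.
#'
#' @param n_arenas number of arenas (default 50).
#' @param arena_px `(height, width)` of one arena in pixels.
#' @param frames number of scans.
#' @param frame_interval hours between scans (default 1).
#' @param occupancy_probs probability vector over occupancies 0,1,2,3,4+;
#'   must sum to 1.
#' @param survival_dist death-time distribution: `list(name = "exponential",
#'   mean = )`, `list(name = "weibull", shape = , scale = )`, or
#'   `list(name = "fixed", times = )` (hours).
#' @param movement_px `(mean, sd)` of the per-frame centroid displacement of
#'   a live worm, pixels.
#' @param worm_area_px target rendered worm area in pixels (default 1000;
#'   must exceed the detection size filter to be detectable).
#' @param fade_after_death opacity decay rate per hour after death; 0 keeps
#'   full contrast (rod-like death), larger values emulate the progressive
#'   loss of opacity of matricidal "bagging".
#' @param debris_rate expected static sub-threshold objects per arena
#'   (Poisson).
#' @param bubble_rate expected static supra-threshold objects per arena
#'   (Poisson); these inflate apparent occupancy, exercising the "4+"
#'   exclusion.
#' @param global_shift_events whole-frame translations emulating physical
#'   disturbance of the chip: a data frame (or list of length-3 vectors)
#'   with columns `frame` (1-based index of the first affected frame),
#'   `drow`, `dcol` (pixels). Shifts persist and accumulate.
#' @param noise_sd additive Gaussian noise, gray levels.
#' @param background_level,worm_level background and worm gray levels
#'   (0-255); worms are darker than background.
#' @param seed integer seed; the entire simulation is reproducible from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_arenas = 50L,
                       arena_px = c(126L, 456L),
                       frames = 72L,
                       frame_interval = 1,
                       occupancy_probs = c(0.388, 0.505, 0.092, 0.012, 0.003),
                       survival_dist = list(name = "exponential", mean = 40),
                       movement_px = c(mean = 12, sd = 2),
                       worm_area_px = 1000,
                       fade_after_death = 0,
                       debris_rate = 0.1,
                       bubble_rate = 0.01,
                       global_shift_events = NULL,
                       noise_sd = 2,
                       background_level = 200,
                       worm_level = 60,
                       seed = 1L) {
  stop_if(!is_count(n_arenas) || n_arenas < 1, "`n_arenas` must be a positive count")
  stop_if(length(arena_px) != 2L || any(arena_px < 8),
          "`arena_px` must be (height, width), each >= 8")
  stop_if(!is_count(frames) || frames < 2, "`frames` must be a count >= 2")
  stop_if(!is_number(frame_interval) || frame_interval <= 0,
          "`frame_interval` must be > 0")
  stop_if(length(occupancy_probs) != 5L || any(occupancy_probs < 0) ||
          abs(sum(occupancy_probs) - 1) > 1e-8,
          "`occupancy_probs` must be 5 non-negative values summing to 1")
  validate_survival_dist(survival_dist)
  stop_if(length(movement_px) != 2L || any(movement_px < 0),
          "`movement_px` must be (mean, sd), both >= 0")
  stop_if(!is_number(worm_area_px) || worm_area_px < 20,
          "`worm_area_px` must be >= 20")
  stop_if(!is_number(fade_after_death) || fade_after_death < 0,
          "`fade_after_death` must be >= 0")
  stop_if(!is_number(debris_rate) || debris_rate < 0, "`debris_rate` must be >= 0")
  stop_if(!is_number(bubble_rate) || bubble_rate < 0, "`bubble_rate` must be >= 0")
  if (!is.null(global_shift_events)) {
    if (!is.data.frame(global_shift_events))
      global_shift_events <- as.data.frame(do.call(
        rbind, lapply(global_shift_events, function(e) {
          stop_if(length(e) != 3L, "each shift event is (frame, drow, dcol)")
          stats::setNames(as.numeric(e), c("frame", "drow", "dcol"))
        })))
    stop_if(!all(c("frame", "drow", "dcol") %in% names(global_shift_events)),
            "`global_shift_events` needs columns frame, drow, dcol")
    stop_if(any(global_shift_events$frame < 2) ||
            any(global_shift_events$frame > frames),
            "shift event frames must lie in 2..frames")
  }
  stop_if(!is_number(noise_sd) || noise_sd < 0, "`noise_sd` must be >= 0")
  stop_if(!is_number(background_level) || !is_number(worm_level) ||
          background_level < 0 || background_level > 255 ||
          worm_level < 0 || worm_level > 255,
          "gray levels must lie in [0, 255]")
  stop_if(worm_level >= background_level,
          "`worm_level` must be darker (smaller) than `background_level`")
  stop_if(!is_count(seed), "`seed` must be a non-negative integer")
  structure(list(
    n_arenas = as.integer(n_arenas), arena_px = as.integer(arena_px),
    frames = as.integer(frames), frame_interval = frame_interval,
    occupancy_probs = occupancy_probs, survival_dist = survival_dist,
    movement_px = stats::setNames(as.numeric(movement_px), c("mean", "sd")),
    worm_area_px = worm_area_px, fade_after_death = fade_after_death,
    debris_rate = debris_rate, bubble_rate = bubble_rate,
    global_shift_events = global_shift_events, noise_sd = noise_sd,
    background_level = background_level, worm_level = worm_level,
    seed = as.integer(seed)), class = "sim_config")
}

validate_survival_dist <- function(dist) {
  stop_if(!is.list(dist) || is.null(dist$name),
          "`survival_dist` must be a list with a `name`")
  switch(dist$name,
    exponential = {
      scale <- dist$mean %||% (1 / dist$rate)
      stop_if(!is_number(scale) || scale <= 0,
              "exponential needs a positive `mean` (or `rate`)")
    },
    weibull = {
      stop_if(!is_number(dist$shape) || dist$shape <= 0 ||
              !is_number(dist$scale) || dist$scale <= 0,
              "weibull needs positive `shape` and `scale`")
    },
    fixed = {
      stop_if(is.null(dist$times) || any(dist$times < 0),
              "fixed needs non-negative `times`")
    },
    stop("unknown survival distribution: ", dist$name, call. = FALSE))
  invisible(dist)
}

#' Sample ground-truth death times
#'
#' Draws `n` death times (hours) from a named survival distribution.
#' `fixed` passes the listed times through (recycled to length `n`), which
#' pins ground truth exactly in tests.
#'
#' @param n number of animals.
#' @param dist distribution spec, see [sim_config()].
#' @param seed optional integer seed; `NULL` draws from the current RNG
#'   stream.
#' @return numeric vector of `n` non-negative death times in hours.
#' @export
sample_death_times <- function(n, dist, seed = NULL) {
  stop_if(!is_count(n), "`n` must be a non-negative count")
  validate_survival_dist(dist)
  if (n == 0L) return(numeric(0))
  with_seed(seed, switch(dist$name,
    exponential = rexp(n, rate = 1 / (dist$mean %||% (1 / dist$rate))),
    weibull = rweibull(n, shape = dist$shape, scale = dist$scale),
    fixed = rep_len(as.numeric(dist$times), n)))
}
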