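disc_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  as.matrix(g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE])
}

#' Draw a worm-shaped pixel blob
#'
#' Builds a worm posture as a thickened random-walk polyline: a heading
#' random walk (sinusoid-like, gentle curvature) stamped with a disc of the
#' worm's half-width at ~1.5 px intervals until the union of stamped pixels
#' reaches the target area. Growing until the area target is met makes the
#' rendered area insensitive to self-overlap from curvature, and the random
#' posture makes bounding-box dimensions vary between frames the way a
#' crawling animal's do.
#'
#' Draws from the current RNG stream.
#'
#' @param area target pixel area.
#' @param width worm body width in pixels; default scales with `area` to
#'   keep an adult-like ~12:1 aspect.
#' @param turn_sd heading change per step, radians.
#' @param max_extent soft bound (pixels) on how far the body may reach from
#'   its starting point; the walk is steered back toward its start when it
#'   approaches this radius, so postures fit inside a known box.
#' @return integer matrix of (drow, dcol) pixel offsets, re-centred so the
#'   blob's pixel centroid is within half a pixel of the origin.
#' @keywords internal
#' @export
worm_posture <- function(area, width = max(3, round(sqrt(area / 12))),
                         turn_sd = 0.2, max_extent = Inf) {
  radius <- width / 2
  half <- ceiling(sqrt(area)) + as.integer(area / width) + 2L * ceiling(radius)
  if (is.finite(max_extent))
    half <- min(half, as.integer(max_extent) + 2L * ceiling(radius))
  side <- 2L * half + 1L
  origin <- c(half + 1, half + 1)
  canvas <- matrix(FALSE, side, side)
  disc <- disc_offsets(radius)
  pos <- origin
  heading <- runif(1, 0, 2 * pi)
  count <- 0L
  max_steps <- as.integer(10 * area / width) + 50L
  steer_r <- min(max_extent - radius - 2, half - 2 * radius - 2)
  for (step in seq_len(max_steps)) {
    px_r <- round(pos[1]) + disc[, 1]
    px_c <- round(pos[2]) + disc[, 2]
    ok <- px_r >= 1 & px_r <= side & px_c >= 1 & px_c <= side
    idx <- cbind(px_r[ok], px_c[ok])
    new <- !canvas[idx]
    canvas[idx[new, , drop = FALSE]] <- TRUE
    count <- count + sum(new)
    if (count >= area) break
    heading <- heading + rnorm(1, 0, turn_sd)
    # steer back toward the start when nearing the allowed reach
    if (sqrt(sum((pos - origin)^2)) > steer_r)
      heading <- atan2(origin[1] - pos[1], origin[2] - pos[2]) + rnorm(1, 0, 0.3)
    pos <- pos + 1.5 * c(sin(heading), cos(heading))
  }
  px <- which(canvas, arr.ind = TRUE)
  ctr <- colMeans(px)
  off <- cbind(px[, 1] - round(ctr[1]), px[, 2] - round(ctr[2]))
  storage.mode(off) <- "integer"
  colnames(off) <- c("drow", "dcol")
  off
}

#' Render one arena frame from object states
#'
#' Paints each object (worm, debris, or bubble) as its pixel-offset blob at
#' its current centroid onto a constant background, then adds Gaussian
#' noise last. Objects reaching past the arena bounds are clipped with a
#' warning. Rendering is deterministic for a fixed seed.
#'
#' @param state list of objects, each a list with `offsets` (n x 2 integer
#'   matrix of pixel offsets), `centroid` (`(row, col)`, may be fractional),
#'   and `level` (gray level).
#' @param dim arena `(height, width)` in pixels.
#' @param background_level background gray level.
#' @param noise_sd additive Gaussian noise sd in gray levels (applied last).
#' @param seed optional seed for the noise draw; `NULL` uses the current
#'   RNG stream.
#' @return numeric matrix `dim[1]` x `dim[2]`, gray levels 0-255.
#' @export
render_arena_frame <- function(state, dim, background_level = 200,
                               noise_sd = 0, seed = NULL) {
  img <- matrix(background_level, dim[1], dim[2])
  for (obj in state) {
    ctr <- obj$centroid
    mu <- colMeans(obj$offsets)
    px_r <- obj$offsets[, 1] + as.integer(round(ctr[1] - mu[1]))
    px_c <- obj$offsets[, 2] + as.integer(round(ctr[2] - mu[2]))
    ok <- px_r >= 1 & px_r <= dim[1] & px_c >= 1 & px_c <= dim[2]
    if (!all(ok))
      warning("object at (", round(ctr[1]), ", ", round(ctr[2]),
              ") clipped at arena bounds", call. = FALSE)
    img[cbind(px_r[ok], px_c[ok])] <- obj$level
  }
  if (noise_sd > 0)
    img <- with_seed(seed,
                     clip_gray(img + rnorm(length(img), 0, noise_sd)))
  img
}

# Sample a displacement step that keeps the centroid inside [lo, hi] bounds.
# Retries the direction so the commanded step length is preserved; falls
# back to clamping only when the box is too tight for any direction.
step_centroid <- function(ctr, dist_px, lo, hi) {
  for (k in seq_len(25L)) {
    ang <- runif(1, 0, 2 * pi)
    cand <- ctr + dist_px * c(sin(ang), cos(ang))
    if (all(cand >= lo) && all(cand <= hi)) return(cand)
  }
  pmin(pmax(ctr + dist_px * c(sin(ang), cos(ang)), lo), hi)
}

#' Generate a synthetic experiment with ground truth
#'
#' Simulates a full scanner run of one array: arenas laid out in a
#' 2-column grid, each loaded with 0-4 worms per the occupancy
#' distribution, plus optional static debris (below the detection size
#' filter) and bubbles (above it). Live worms re-posture and displace their
#' centroid by the movement distribution between consecutive frames; from
#' the first frame at or past an animal's death time its blob freezes
#' (optionally fading). Global shift events translate entire frames,
#' persistently and cumulatively, emulating physical disturbance of the
#' chip. Noise is added last. Everything is reproducible from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return a list with
#'   * `series`: a [frame_series()] of rendered frames;
#'   * `truth`: ground truth with `arenas` (arena, occupancy), `animals`
#'     (arena, animal, death_time_h, alive_at_end), `shifts` (per-frame
#'     cumulative applied translation), and static `artifacts`;
#'   * `config`: the input configuration;
#'   * `regions`: the arena regions used for layout (as from
#'     [build_grid()]).
#' @export
generate_experiment <- function(cfg) {
  stop_if(!inherits(cfg, "sim_config"), "`cfg` must be a sim_config")
  with_seed(cfg$seed, generate_experiment_impl(cfg))
}

generate_experiment_impl <- function(cfg) {
  layout <- c(ceiling(cfg$n_arenas / 2), min(2L, cfg$n_arenas))
  if (prod(layout) != cfg$n_arenas) layout <- c(cfg$n_arenas, 1L)
  H <- layout[1] * cfg$arena_px[1]; W <- layout[2] * cfg$arena_px[2]
  spec <- grid_spec(c(1, 1, H, W), n_arenas = cfg$n_arenas, layout = layout)
  regions <- build_grid(spec)
  times <- (seq_len(cfg$frames) - 1) * cfg$frame_interval
  end_t <- times[cfg$frames]

  # --- per-arena contents -------------------------------------------------
  occ <- sample(0:4, cfg$n_arenas, replace = TRUE, prob = cfg$occupancy_probs)
  animals <- list(); arts <- list()
  worms <- vector("list", cfg$n_arenas)
  static <- vector("list", cfg$n_arenas)
  aw <- cfg$arena_px
  # postures are steered to fit a known reach so blobs stay inside arenas
  ext_limit <- max(10, floor(min(aw) / 2) - 14)
  new_posture <- function() {
    for (k in 1:4) {
      off <- worm_posture(cfg$worm_area_px, max_extent = ext_limit)
      if (max(abs(off)) <= ext_limit + 4) return(off)
    }
    off
  }
  ext <- ext_limit + 6
  lo <- pmin(c(ext + 1, ext + 1), aw / 2)
  hi <- pmax(aw - ext, aw / 2)
  for (a in seq_len(cfg$n_arenas)) {
    n_w <- occ[a]
    ws <- vector("list", n_w)
    if (n_w > 0) {
      deaths <- sample_death_times(n_w, cfg$survival_dist)
      for (j in seq_len(n_w)) {
        ctr <- c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]))
        ws[[j]] <- list(offsets = new_posture(), centroid = ctr,
                        death = deaths[j], lo = lo, hi = hi)
      }
      animals[[a]] <- data.frame(
        arena = a, animal = seq_len(n_w),
        death_time_h = ifelse(deaths <= end_t, deaths, NA_real_),
        alive_at_end = deaths > end_t)
    }
    worms[[a]] <- ws
    n_d <- rpois(1, cfg$debris_rate)
    n_b <- rpois(1, cfg$bubble_rate)
    st <- list()
    for (k in seq_len(n_d)) {
      a_px <- runif(1, 30, max(40, min(250, cfg$worm_area_px / 4)))
      off <- worm_posture(a_px, width = 6, turn_sd = 0.5)
      ctr <- c(runif(1, 15, aw[1] - 15), runif(1, 15, aw[2] - 15))
      st <- c(st, list(list(offsets = off, centroid = ctr,
                            level = cfg$worm_level, kind = "debris")))
    }
    for (k in seq_len(n_b)) {
      a_px <- runif(1, 400, 1200)
      off <- disc_offsets(sqrt(a_px / pi))
      ctr <- c(runif(1, 25, aw[1] - 25), runif(1, 25, aw[2] - 25))
      st <- c(st, list(list(offsets = off, centroid = ctr,
                            level = (cfg$worm_level + cfg$background_level) / 2,
                            kind = "bubble")))
    }
    static[[a]] <- st
    if (length(st))
      arts[[a]] <- data.frame(
        arena = a,
        kind = vapply(st, `[[`, character(1), "kind"),
        row = vapply(st, function(s) s$centroid[1], numeric(1)),
        col = vapply(st, function(s) s$centroid[2], numeric(1)),
        area = vapply(st, function(s) nrow(s$offsets), numeric(1)))
  }

  # --- cumulative global shifts -------------------------------------------
  shift_r <- integer(cfg$frames); shift_c <- integer(cfg$frames)
  ev <- cfg$global_shift_events
  if (!is.null(ev)) for (i in seq_len(nrow(ev))) {
    sel <- seq_len(cfg$frames) >= ev$frame[i]
    shift_r[sel] <- shift_r[sel] + as.integer(ev$drow[i])
    shift_c[sel] <- shift_c[sel] + as.integer(ev$dcol[i])
  }

  # --- render frames ------------------------------------------------------
  frames <- vector("list", cfg$frames)
  for (fi in seq_len(cfg$frames)) {
    frame <- matrix(cfg$background_level, H, W)
    for (a in seq_len(cfg$n_arenas)) {
      state <- static[[a]]
      for (wm in worms[[a]]) {
        lvl <- cfg$worm_level
        if (times[fi] >= wm$death && cfg$fade_after_death > 0) {
          contrast <- (cfg$background_level - cfg$worm_level) *
            exp(-cfg$fade_after_death * (times[fi] - wm$death))
          lvl <- cfg$background_level - contrast
        }
        state <- c(state, list(list(offsets = wm$offsets,
                                    centroid = wm$centroid, level = lvl)))
      }
      if (length(state)) {
        sub <- render_arena_frame(state, aw,
                                  background_level = cfg$background_level)
        reg <- regions[a, ]
        frame[reg$row_start:(reg$row_stop - 1),
              reg$col_start:(reg$col_stop - 1)] <- sub
      }
    }
    if (shift_r[fi] != 0 || shift_c[fi] != 0)
      frame <- shift_image(frame, c(shift_r[fi], shift_c[fi]),
                           fill = cfg$background_level)
    if (cfg$noise_sd > 0)
      frame <- clip_gray(frame + rnorm(length(frame), 0, cfg$noise_sd))
    frames[[fi]] <- frame

    # advance live worms into the next frame
    if (fi < cfg$frames) {
      for (a in seq_len(cfg$n_arenas)) {
        for (j in seq_along(worms[[a]])) {
          wm <- worms[[a]][[j]]
          if (times[fi] < wm$death) {
            d <- max(0, rnorm(1, cfg$movement_px["mean"], cfg$movement_px["sd"]))
            wm$centroid <- step_centroid(wm$centroid, d, wm$lo, wm$hi)
            wm$offsets <- new_posture()
            worms[[a]][[j]] <- wm
          }
        }
      }
    }
  }

  animals_df <- if (length(animals)) do.call(rbind, animals[!vapply(
    animals, is.null, logical(1))]) else
    data.frame(arena = integer(), animal = integer(),
               death_time_h = numeric(), alive_at_end = logical())
  rownames(animals_df) <- NULL
  arts_df <- if (length(arts)) do.call(rbind, arts[!vapply(
    arts, is.null, logical(1))]) else NULL

  list(series = frame_series(frames, times, source = "synthetic"),
       truth = list(arenas = data.frame(arena = seq_len(cfg$n_arenas),
                                        occupancy = occ),
                    animals = animals_df,
                    shifts = data.frame(frame = seq_len(cfg$frames),
                                        drow = shift_r, dcol = shift_c),
                    artifacts = arts_df),
       config = cfg,
       regions = regions)
}

#' Write a simulated experiment to disk
#'
#' Saves the rendered stack as a multi-page 8-bit TIFF plus a JSON sidecar
#' manifest carrying the configuration, frame times, and ground truth.
#'
#' @param sim result of [generate_experiment()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tif <- file.path(dir, "stack.tif")
  man <- file.path(dir, "manifest.json")
  tiff::writeTIFF(lapply(sim$series$frames, function(f) round(f) / 255), tif,
                  bits.per.sample = 8L)
  cfg <- sim$config
  cfg$global_shift_events <- if (is.null(cfg$global_shift_events)) NULL else
    as.data.frame(cfg$global_shift_events)
  jsonlite::write_json(
    list(config = unclass(cfg), times = sim$series$times, truth = sim$truth),
    man, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(stack = tif, manifest = man))
}

#' Load a simulated experiment written by [write_simulation()]
#'
#' @param dir directory containing `stack.tif` and `manifest.json`.
#' @return a list with `series`, `truth`, and `config` (config returned as
#'   a plain list).
#' @export
load_simulation <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  series <- load_frame_series(file.path(dir, "stack.tif"),
                              times = as.numeric(man$times),
                              source = "synthetic")
  list(series = series, truth = man$truth, config = man$config)
}

#' Expected death calls implied by simulation ground truth
#'
#' Translates ground-truth death times into the calls an ideal scorer
#' would make under the quiescence rule with the series' sampling. A death
#' between two scans is observable only at the later scan (the last frame
#' pair showing movement), and a death within the final `quiescent_h`
#' hours cannot accumulate a qualifying quiet run before the series ends,
#' so such animals are expected to be censored -- exactly as a real
#' experiment scores them.
#'
#' @param truth the `truth` element of [generate_experiment()].
#' @param times frame times in hours.
#' @param quiescent_h quiescence used by the scorer (default 4).
#' @return data frame: `arena`, `status` (`dead`/`censored`/`empty`/
#'   `excluded`), `time_h` (expected called death time, NA otherwise).
#' @export
expected_calls <- function(truth, times, quiescent_h = 4) {
  n <- length(times)
  m <- n - 1L
  q <- as.integer(ceiling(quiescent_h / median(diff(times))))
  one <- function(a) {
    occ <- truth$arenas$occupancy[truth$arenas$arena == a]
    if (occ == 0) return(data.frame(arena = a, status = "empty",
                                    time_h = NA_real_))
    if (occ >= 4) return(data.frame(arena = a, status = "excluded",
                                    time_h = NA_real_))
    an <- truth$animals[truth$animals$arena == a, ]
    call_t <- 0
    for (i in seq_len(nrow(an))) {
      if (an$alive_at_end[i])
        return(data.frame(arena = a, status = "censored", time_h = times[n]))
      d <- an$death_time_h[i]
      jstar <- if (any(times[seq_len(m)] < d))
        max(which(times[seq_len(m)] < d)) else 0L
      if (m - jstar < q)  # quiet tail too short to confirm
        return(data.frame(arena = a, status = "censored", time_h = times[n]))
      call_t <- max(call_t, times[if (jstar >= 1) jstar + 1L else 2L])
    }
    data.frame(arena = a, status = "dead", time_h = call_t)
  }
  out <- do.call(rbind, lapply(truth$arenas$arena, one))
  rownames(out) <- NULL
  out
}
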