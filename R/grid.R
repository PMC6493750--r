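#' Specify the arena grid of an array
#'
#' A chip array is a rectangular block of identical arenas (50 by default,
#' in 2 columns). The grid specification carries the pixel bounds of the
#' array in the aligned frame, the layout, and exclusions: whole arenas the
#' user rules out (clogged channels and the like), and per-arena time
#' windows to drop from analysis when image quality was lost.
#'
#' All rectangles use 1-based, half-open pixel intervals `[start, stop)` so
#' regions tile exactly with no off-by-one overlap.
#'
#' @param bounds length-4 integer vector `(row_start, col_start, height,
#'   width)` of the array block in the aligned frame.
#' @param n_arenas total number of arenas (default 50).
#' @param layout length-2 integer `(rows, cols)` of arenas;
#'   `rows * cols` must equal `n_arenas`. Default: 2 columns.
#' @param exclude_arenas integer vector of arena indices (1-based) excluded
#'   from analysis.
#' @param exclude_windows data frame with columns `arena`, `t_start_h`,
#'   `t_end_h`: per-arena time intervals to mask before vitality analysis.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(bounds, n_arenas = 50L, layout = NULL,
                      exclude_arenas = integer(),
                      exclude_windows = NULL) {
  stop_if(length(bounds) != 4L || !is.numeric(bounds),
          "`bounds` must be (row_start, col_start, height, width)")
  bounds <- as.integer(bounds)
  stop_if(bounds[3] <= 0 || bounds[4] <= 0, "bounds height/width must be positive")
  stop_if(!is_count(n_arenas) || n_arenas < 1, "`n_arenas` must be a positive count")
  if (is.null(layout)) {
    stop_if(n_arenas %% 2L != 0L,
            "`n_arenas` not divisible by 2; give `layout` explicitly")
    layout <- c(n_arenas / 2L, 2L)
  }
  layout <- as.integer(layout)
  stop_if(length(layout) != 2L || prod(layout) != n_arenas,
          "`layout` rows * cols must equal `n_arenas`")
  stop_if(layout[1] > bounds[3] || layout[2] > bounds[4],
          "more arenas than pixels in bounds")
  exclude_arenas <- as.integer(exclude_arenas)
  stop_if(length(exclude_arenas) && (min(exclude_arenas) < 1 ||
                                     max(exclude_arenas) > n_arenas),
          "`exclude_arenas` indices must lie in 1..n_arenas")
  if (!is.null(exclude_windows)) {
    stop_if(!is.data.frame(exclude_windows) ||
            !all(c("arena", "t_start_h", "t_end_h") %in% names(exclude_windows)),
            "`exclude_windows` needs columns arena, t_start_h, t_end_h")
    stop_if(nrow(exclude_windows) > 0 &&
            (min(exclude_windows$arena) < 1 || max(exclude_windows$arena) > n_arenas),
            "`exclude_windows` arena indices out of range")
  }
  structure(list(bounds = bounds, n_arenas = as.integer(n_arenas),
                 layout = layout, exclude_arenas = exclude_arenas,
                 exclude_windows = exclude_windows),
            class = "grid_spec")
}

#' Build per-arena regions from a grid specification
#'
#' Tiles the bounds with `n_arenas` rectangles in row-major order from the
#' top-left. When the bounds are not exactly divisible, cell sizes differ by
#' at most 1 px, with the remainder assigned deterministically to the last
#' cells of each row/column. Excluded arenas are flagged, not removed, so
#' arena indices keep their longitudinal identity.
#'
#' @param spec a [grid_spec()].
#' @return a data frame of class `arena_regions`: one row per arena with
#'   columns `arena`, `row_start`, `row_stop`, `col_start`, `col_stop`
#'   (half-open `[start, stop)`), and `excluded`.
#' @export
build_grid <- function(spec) {
  stop_if(!inherits(spec, "grid_spec"), "`spec` must be a grid_spec")
  splits <- function(start, extent, n) {
    base <- extent %/% n; rem <- extent %% n
    sizes <- rep(base, n)
    if (rem > 0) sizes[(n - rem + 1):n] <- base + 1L  # remainder to last cells
    stops <- start + cumsum(sizes)
    cbind(start = stops - sizes, stop = stops)
  }
  r <- splits(spec$bounds[1], spec$bounds[3], spec$layout[1])
  c_ <- splits(spec$bounds[2], spec$bounds[4], spec$layout[2])
  grid <- expand.grid(col_block = seq_len(spec$layout[2]),
                      row_block = seq_len(spec$layout[1]))  # row-major
  out <- data.frame(
    arena = seq_len(spec$n_arenas),
    row_start = r[grid$row_block, "start"],
    row_stop = r[grid$row_block, "stop"],
    col_start = c_[grid$col_block, "start"],
    col_stop = c_[grid$col_block, "stop"])
  out$excluded <- out$arena %in% spec$exclude_arenas
  class(out) <- c("arena_regions", "data.frame")
  out
}

#' Crop one arena sub-image from a frame
#'
#' @param frame numeric matrix (aligned frame).
#' @param region one row of the data frame returned by [build_grid()] (or
#'   any list with `row_start`, `row_stop`, `col_start`, `col_stop`).
#' @return the sub-image covering exactly `[row_start, row_stop) x
#'   [col_start, col_stop)`.
#' @export
crop_arena <- function(frame, region) {
  stop_if(region$row_start < 1 || region$col_start < 1 ||
          region$row_stop - 1 > nrow(frame) || region$col_stop - 1 > ncol(frame) ||
          region$row_stop <= region$row_start || region$col_stop <= region$col_start,
          "arena region [", region$row_start, ",", region$row_stop, ") x [",
          region$col_start, ",", region$col_stop, ") outside frame ",
          nrow(frame), " x ", ncol(frame))
  frame[region$row_start:(region$row_stop - 1),
        region$col_start:(region$col_stop - 1), drop = FALSE]
}

#' Flag arena-frames with anomalous overall intensity
#'
#' Automatic quality control: an arena-frame whose mean intensity deviates
#' from that arena's series median by more than `n_sd` standard deviations
#' is flagged, emulating manual exclusion of timepoints where image quality
#' was lost through clogging. The standard deviation is estimated robustly
#' (median absolute deviation, scaled to be consistent with the sd of a
#' normal series) so that the outlying frames being hunted cannot inflate
#' the threshold and mask themselves.
#'
#' @param series a [frame_series()].
#' @param regions regions from [build_grid()].
#' @param n_sd deviation threshold in standard deviations (default 5).
#' @return logical matrix, arenas x frames; `TRUE` = flagged.
#' @export
qc_flag_frames <- function(series, regions, n_sd = 5) {
  means <- vapply(series$frames, function(f)
    vapply(seq_len(nrow(regions)), function(i)
      mean(crop_arena(f, regions[i, ])), numeric(1)),
    numeric(nrow(regions)))
  means <- matrix(means, nrow = nrow(regions))
  flags <- matrix(FALSE, nrow(regions), length(series$frames))
  for (i in seq_len(nrow(regions))) {
    s <- stats::mad(means[i, ])
    if (!is.finite(s) || s == 0) next
    flags[i, ] <- abs(means[i, ] - median(means[i, ])) > n_sd * s
  }
  flags
}

#' Per-arena exclusion mask over frames
#'
#' Combines whole-arena exclusions and per-arena time windows from the
#' grid spec into an arenas x frames logical mask (`TRUE` = excluded).
#'
#' @param spec a [grid_spec()].
#' @param times frame times in hours.
#' @return logical matrix, arenas x frames.
#' @export
exclusion_mask <- function(spec, times) {
  mask <- matrix(FALSE, spec$n_arenas, length(times))
  mask[spec$exclude_arenas, ] <- TRUE
  w <- spec$exclude_windows
  if (!is.null(w)) for (i in seq_len(nrow(w))) {
    mask[w$arena[i], times >= w$t_start_h[i] & times <= w$t_end_h[i]] <- TRUE
  }
  mask
}
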