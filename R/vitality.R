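#' Match objects between adjacent frames of one arena
#'
#' Greedy nearest-centroid matching: candidate pairs are ranked by
#' Euclidean centroid distance and accepted smallest-first, each object
#' used at most once. Objects left over are returned as appearances (new in
#' the current frame) or disappearances (gone from the previous frame).
#'
#' @param prev,curr `worm_objects` data frames (rows may be empty) from
#'   adjacent frames of the same arena.
#' @return a list with `pairs` (data frame: `prev_idx`, `curr_idx`,
#'   `displacement`, `drow`, `dcol`), `appearances`, and `disappearances`
#'   (integer row indices into `curr` / `prev`).
#' @export
match_objects <- function(prev, curr) {
  np <- NROW(prev); nc <- NROW(curr)
  pairs <- data.frame(prev_idx = integer(), curr_idx = integer(),
                      displacement = numeric(), drow = numeric(),
                      dcol = numeric())
  if (np > 0 && nc > 0) {
    dr <- outer(curr$centroid_row, prev$centroid_row, "-")
    dc <- outer(curr$centroid_col, prev$centroid_col, "-")
    d <- sqrt(dr^2 + dc^2)
    ord <- order(d)
    used_p <- logical(np); used_c <- logical(nc)
    for (k in ord) {
      ci <- (k - 1L) %% nc + 1L
      pi <- (k - 1L) %/% nc + 1L
      if (used_p[pi] || used_c[ci]) next
      used_p[pi] <- TRUE; used_c[ci] <- TRUE
      pairs <- rbind(pairs, data.frame(
        prev_idx = pi, curr_idx = ci, displacement = d[ci, pi],
        drow = dr[ci, pi], dcol = dc[ci, pi]))
      if (all(used_p) || all(used_c)) break
    }
  }
  list(pairs = pairs,
       appearances = setdiff(seq_len(nc), pairs$curr_idx),
       disappearances = setdiff(seq_len(np), pairs$prev_idx))
}

#' Detect and remove a global frameshift from one frame pair
#'
#' A physical disturbance of the chip translates the whole image between
#' two scans, which mimics movement in every arena simultaneously. If more
#' than `agree_frac` of the arenas that contain matched objects show
#' displacement vectors within `min_shift` px of the pooled median vector,
#' and that median vector is itself at least `min_shift` px long, the
#' median vector is subtracted from every matched displacement and the
#' frame pair is flagged. With fewer than 3 populated arenas there is no
#' basis for a consensus and nothing is done.
#'
#' @param vectors data frame with columns `arena`, `drow`, `dcol`: one row
#'   per matched pair across all arenas of one frame pair.
#' @param agree_frac minimum fraction of populated arenas that must agree
#'   with the median vector (default 0.5).
#' @param min_shift minimum shift magnitude to act on, px (default 3).
#' @return a list with `vectors` (corrected `drow`/`dcol` plus recomputed
#'   `displacement`), `shift` (the removed `(drow, dcol)`, `c(0, 0)` if
#'   none), and `flagged` (logical).
#' @export
compensate_global_shift <- function(vectors, agree_frac = 0.5, min_shift = 3) {
  out <- list(vectors = vectors, shift = c(0, 0), flagged = FALSE)
  if (NROW(vectors) == 0) return(out)
  per_arena <- aggregate(vectors[, c("drow", "dcol")],
                         by = list(arena = vectors$arena), FUN = mean)
  if (nrow(per_arena) < 3) return(out)
  med <- c(median(per_arena$drow), median(per_arena$dcol))
  if (sqrt(sum(med^2)) < min_shift) return(out)
  dev <- sqrt((per_arena$drow - med[1])^2 + (per_arena$dcol - med[2])^2)
  if (mean(dev < min_shift) <= agree_frac) return(out)
  vectors$drow <- vectors$drow - med[1]
  vectors$dcol <- vectors$dcol - med[2]
  vectors$displacement <- sqrt(vectors$drow^2 + vectors$dcol^2)
  list(vectors = vectors, shift = med, flagged = TRUE)
}

#' Count moving worms in one arena for one frame pair
#'
#' A matched object counts as moving when its (compensated) centroid
#' displacement is strictly greater than `move_threshold` px. Appearances
#' and disappearances each count as one moving worm -- a worm crossing
#' pillar shadows can fragment or vanish from segmentation, and treating
#' any topology change as motion avoids premature death calls. The count is
#' capped at the larger object count of the pair.
#'
#' @param displacements numeric vector of matched pair displacements, px.
#' @param n_appear,n_disappear counts of unmatched objects.
#' @param move_threshold movement threshold in pixels (default 7); a
#'   displacement of exactly the threshold is not movement.
#' @param n_prev,n_curr object counts of the two frames (for the cap);
#'   defaults derived from the other arguments.
#' @return integer moving-worm count.
#' @export
moving_count <- function(displacements, n_appear = 0L, n_disappear = 0L,
                         move_threshold = 7,
                         n_prev = length(displacements) + n_disappear,
                         n_curr = length(displacements) + n_appear) {
  n <- sum(displacements > move_threshold) + n_appear + n_disappear
  as.integer(min(n, max(n_prev, n_curr)))
}

#' Classify arena occupancy from the initial assessment window
#'
#' The resident count of an arena is the modal detected object count over
#' the frames of the first `window_h` hours, with ties broken toward the
#' larger count. Arenas whose class is "4+" typically contain bubbles or
#' debris and are excluded from analysis downstream.
#'
#' @param counts integer vector of detected object counts per frame.
#' @param times frame times in hours (same length).
#' @param window_h assessment window length in hours (default 10).
#' @return a list with `class` (`"0"`, `"1"`, `"2"`, `"3"`, or `"4+"`),
#'   `count` (the modal count, 4 meaning 4 or more), and `window_h`.
#' @export
classify_occupancy <- function(counts, times, window_h = 10) {
  stop_if(length(counts) != length(times), "`counts`/`times` length mismatch")
  sel <- times <= window_h
  if (max(times) < window_h) {
    warning("occupancy window (", window_h, " h) longer than series (",
            max(times), " h); using all frames", call. = FALSE)
    sel <- rep(TRUE, length(times))
  }
  w <- pmin(counts[sel], 4L)
  tab <- table(w)
  best <- as.integer(names(tab)[tab == max(tab)])
  cls <- max(best)  # ties toward the larger count
  list(class = if (cls >= 4) "4+" else as.character(cls),
       count = cls, window_h = window_h)
}

#' Call time of death from a moving-count series
#'
#' Time of death is the last time point with observed movement before a
#' quiescent run of at least `quiescent_h` hours with no movement. To avoid
#' spurious death calls from stray late movement (segmentation flicker, a
#' nudge of the chip), movement observed after a qualifying quiescent run
#' only reinstates "alive" when it is confirmed by at least `confirm_m`
#' consecutive moving frames; shorter blips are ignored. Animals whose
#' movement record never ends in a qualifying quiescent run are censored at
#' the final time point.
#'
#' Implemented as a backward pass from the final frame: walk back to the
#' last confirmed movement, then locate the earliest qualifying quiescent
#' run after it. This is equivalent to the forward reading of the rule
#' (verified property-style against a brute-force forward oracle).
#'
#' @param counts integer moving-count series.
#' @param times frame times in hours (same length as `counts`).
#' @param quiescent_h quiescence needed to call death, hours (default 4);
#'   converted to frames via the series' median interval (ceiling), so
#'   sub-hourly series work.
#' @param confirm_m consecutive moving frames needed to confirm late
#'   movement (default 2; 1 means any movement resets the call).
#' @param occupancy occupancy class from [classify_occupancy()] (`"0"`
#'   gives status `empty`, `"4+"` gives `excluded`).
#' @param arena arena index stamped on the result.
#' @return a one-row data frame (class `death_call`): `arena`, `status`
#'   (`dead`, `censored`, `excluded`, or `empty`), `time_h` (death time if
#'   dead, censor time if censored, else `NA`), `occupancy`,
#'   `multi_occupancy` (TRUE for classes 2-3: the call then marks when the
#'   last resident stops moving).
#' @export
call_death <- function(counts, times, quiescent_h = 4, confirm_m = 2,
                       occupancy = "1", arena = NA_integer_) {
  stop_if(length(counts) != length(times), "`counts`/`times` length mismatch")
  stop_if(!is_number(quiescent_h) || quiescent_h <= 0, "`quiescent_h` must be > 0")
  stop_if(!is_count(confirm_m) || confirm_m < 1, "`confirm_m` must be >= 1")
  res <- function(status, t) {
    structure(data.frame(arena = as.integer(arena), status = status,
                         time_h = t, occupancy = occupancy,
                         multi_occupancy = occupancy %in% c("2", "3")),
              class = c("death_call", "data.frame"))
  }
  if (identical(occupancy, "0")) return(res("empty", NA_real_))
  if (identical(occupancy, "4+")) return(res("excluded", NA_real_))

  n <- length(counts)
  dt <- median(diff(times))
  q <- as.integer(ceiling(quiescent_h / dt))
  if (n < q) {
    warning("series shorter than the quiescence window; censoring",
            call. = FALSE)
    return(res("censored", times[n]))
  }

  moving <- counts > 0
  r <- rle(moving)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L

  # backward pass: locate the last confirmed movement run
  conf <- which(r$values & r$lengths >= confirm_m)
  from <- if (length(conf)) starts[max(conf)] else 1L

  # earliest qualifying quiescent run at/after it
  quiet <- which(!r$values & r$lengths >= q & starts >= from)
  if (length(quiet) == 0L) return(res("censored", times[n]))
  run_start <- starts[min(quiet)]

  last_move <- if (run_start > 1L && any(moving[seq_len(run_start - 1L)]))
    max(which(moving[seq_len(run_start - 1L)])) else NA_integer_
  res("dead", if (is.na(last_move)) times[1] else times[last_move])
}

#' Experimental yield of an array
#'
#' Yield measures loading and retention efficacy: the number of animals
#' with a usable endpoint (a death call, or identified alive at the end and
#' censored) relative to the arena capacity.
#'
#' @param calls either a `death_call` data frame (statuses are counted) or
#'   a single number of scored arenas.
#' @param capacity arenas per array (default 50).
#' @param n_arrays number of arrays pooled (default 1); total capacity is
#'   `capacity * n_arrays`.
#' @return yield in percent (0-100); print with one decimal as reported.
#' @examples
#' compute_yield(9153, capacity = 13300)  # 68.8
#' @export
compute_yield <- function(calls, capacity = 50, n_arrays = 1) {
  stop_if(!is_number(capacity) || capacity <= 0, "`capacity` must be > 0")
  scored <- if (is.data.frame(calls))
    sum(calls$status %in% c("dead", "censored")) else as.numeric(calls)
  100 * scored / (capacity * n_arrays)
}

#' Occupancy class summary
#'
#' Tabulates occupancy classes over arenas and reports the percentage of
#' each class, as used to characterise loading efficiency.
#'
#' @param classes character vector of occupancy classes (`"0"`..`"3"`,
#'   `"4+"`), e.g. the `occupancy` column of death calls.
#' @return data frame with `class`, `n`, `percent`.
#' @export
occupancy_summary <- function(classes) {
  lev <- c("0", "1", "2", "3", "4+")
  tab <- table(factor(classes, levels = lev))
  data.frame(class = lev, n = as.integer(tab),
             percent = 100 * as.integer(tab) / length(classes))
}
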