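#' Vitality analysis of detected objects
#'
#' Converts per-arena object timelines into per-frame-pair moving counts,
#' occupancy classes, and death calls. Adjacent frames of each arena are
#' matched by nearest centroid; matched displacement vectors are pooled
#' across arenas per frame pair to detect and remove global frameshifts
#' (when enabled); counts of moving objects then feed the quiescence rule.
#'
#' Arena-frames masked by `exclude` (user exclusion windows or automatic
#' QC) are dropped from that arena's timeline; whole arenas flagged in
#' `regions$excluded` are reported with status `excluded`.
#'
#' @param objects a `worm_objects` data frame (e.g. from [detect_stack()]).
#' @param times frame times in hours for the full series.
#' @param regions arena regions from [build_grid()] (supplies arena ids and
#'   user exclusions); alternatively pass `n_arenas`.
#' @param n_arenas number of arenas when `regions` is not given.
#' @param move_threshold movement threshold, px (default 7, strict).
#' @param quiescent_h,confirm_m death-call parameters, see [call_death()].
#' @param occupancy_window_h assessment window for [classify_occupancy()].
#' @param compensate_shifts detect and remove global frameshifts
#'   (default TRUE).
#' @param agree_frac,min_shift frameshift consensus parameters, see
#'   [compensate_global_shift()].
#' @param exclude optional arenas x frames logical mask (TRUE = drop that
#'   arena-frame).
#' @return a list of class `vitality_result`:
#'   * `calls`: death-call data frame (one row per arena);
#'   * `object_counts`: arenas x frames matrix of detected object counts;
#'   * `moving_counts`: arenas x (frames-1) matrix of moving-worm counts,
#'     column `j` describing the pair ending at `times[j+1]` (NA where the
#'     pair was not evaluated);
#'   * `pair_times`: times of the pair-ending frames;
#'   * `shift_flags`: per frame pair, was a global shift removed;
#'   * `shifts`: the removed median vectors (rows match `pair_times`).
#' @export
vitality_from_objects <- function(objects, times, regions = NULL,
                                  n_arenas = NULL,
                                  move_threshold = 7, quiescent_h = 4,
                                  confirm_m = 2, occupancy_window_h = 10,
                                  compensate_shifts = TRUE, agree_frac = 0.5,
                                  min_shift = 3, exclude = NULL) {
  if (is.null(n_arenas)) {
    stop_if(is.null(regions), "give `regions` or `n_arenas`")
    n_arenas <- nrow(regions)
  }
  nf <- length(times)
  stop_if(nf < 2, "need at least 2 frames")
  fidx <- match(round(objects$time_h, 9), round(times, 9))
  stop_if(anyNA(fidx) && nrow(objects) > 0,
          "object times do not line up with the series times")

  # per arena x frame object tables
  cell <- vector("list", n_arenas * nf)
  dim(cell) <- c(n_arenas, nf)
  if (nrow(objects) > 0) {
    grp <- split(seq_len(nrow(objects)),
                 list(arena = objects$arena, frame = fidx), drop = TRUE)
    for (g in names(grp)) {
      ij <- as.integer(strsplit(g, ".", fixed = TRUE)[[1]])
      cell[[ij[1], ij[2]]] <- objects[grp[[g]], , drop = FALSE]
    }
  }
  counts <- matrix(vapply(seq_along(cell),
                          function(i) NROW(cell[[i]]), integer(1)),
                   n_arenas, nf)
  valid <- matrix(TRUE, n_arenas, nf)
  if (!is.null(exclude)) valid <- valid & !exclude
  counts[!valid] <- NA_integer_

  # match adjacent frames per arena, pool vectors per frame pair
  moving <- matrix(NA_integer_, n_arenas, nf - 1)
  shift_flags <- logical(nf - 1)
  shifts <- matrix(0, nf - 1, 2, dimnames = list(NULL, c("drow", "dcol")))
  for (j in seq_len(nf - 1)) {
    matches <- vector("list", n_arenas)
    vecs <- list()
    for (a in seq_len(n_arenas)) {
      if (!valid[a, j] || !valid[a, j + 1]) next
      m <- match_objects(cell[[a, j]], cell[[a, j + 1]])
      matches[[a]] <- m
      if (nrow(m$pairs) > 0)
        vecs[[length(vecs) + 1L]] <- data.frame(arena = a, m$pairs)
    }
    vecs <- if (length(vecs)) do.call(rbind, vecs) else
      data.frame(arena = integer(), prev_idx = integer(),
                 curr_idx = integer(), displacement = numeric(),
                 drow = numeric(), dcol = numeric())
    if (compensate_shifts) {
      comp <- compensate_global_shift(vecs, agree_frac = agree_frac,
                                      min_shift = min_shift)
      vecs <- comp$vectors
      shift_flags[j] <- comp$flagged
      shifts[j, ] <- comp$shift
    }
    for (a in seq_len(n_arenas)) {
      m <- matches[[a]]
      if (is.null(m)) next
      disp <- vecs$displacement[vecs$arena == a]
      moving[a, j] <- moving_count(
        disp, n_appear = length(m$appearances),
        n_disappear = length(m$disappearances),
        move_threshold = move_threshold,
        n_prev = NROW(cell[[a, j]]), n_curr = NROW(cell[[a, j + 1]]))
    }
  }

  # occupancy + death call per arena
  user_excluded <- if (!is.null(regions)) regions$excluded else
    rep(FALSE, n_arenas)
  calls <- vector("list", n_arenas)
  pair_times <- times[-1]
  for (a in seq_len(n_arenas)) {
    if (isTRUE(user_excluded[a])) {
      calls[[a]] <- data.frame(arena = a, status = "excluded",
                               time_h = NA_real_, occupancy = NA_character_,
                               multi_occupancy = FALSE, flags = "user_excluded")
      next
    }
    cf <- which(!is.na(counts[a, ]))
    if (length(cf) == 0) {
      calls[[a]] <- data.frame(arena = a, status = "excluded",
                               time_h = NA_real_, occupancy = NA_character_,
                               multi_occupancy = FALSE, flags = "qc")
      next
    }
    occ <- classify_occupancy(counts[a, cf], times[cf],
                              window_h = occupancy_window_h)
    mv <- which(!is.na(moving[a, ]))
    if (occ$class %in% c("0", "4+") || length(mv) == 0) {
      cl <- call_death(integer(0), numeric(0), occupancy = occ$class,
                       arena = a)
      if (!occ$class %in% c("0", "4+"))
        cl <- data.frame(arena = a, status = "censored",
                         time_h = max(times), occupancy = occ$class,
                         multi_occupancy = occ$class %in% c("2", "3"))
    } else {
      cl <- call_death(moving[a, mv], pair_times[mv],
                       quiescent_h = quiescent_h, confirm_m = confirm_m,
                       occupancy = occ$class, arena = a)
    }
    cl$flags <- ""
    calls[[a]] <- as.data.frame(cl)
  }
  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL
  structure(list(calls = calls, object_counts = counts,
                 moving_counts = moving, pair_times = pair_times,
                 shift_flags = shift_flags, shifts = shifts),
            class = "vitality_result")
}

#' @export
print.vitality_result <- function(x, ...) {
  tab <- table(x$calls$status)
  cat("<vitality_result> ", nrow(x$calls), " arenas: ",
      paste(names(tab), as.integer(tab), sep = "=", collapse = ", "),
      "; yield ", sprintf("%.1f%%", compute_yield(x$calls,
                                                  capacity = nrow(x$calls))),
      "\n", sep = "")
  invisible(x)
}

#' Score a frame series end to end
#'
#' Detection plus vitality analysis: thresholds and measures objects in
#' every arena of every frame ([detect_stack()]), then derives moving
#' counts and death calls ([vitality_from_objects()]).
#'
#' @param series a [frame_series()].
#' @param regions arena regions from [build_grid()].
#' @param min_area,method,threshold,polarity,min_contrast detection
#'   parameters, see [binarize()].
#' @param exclude optional arenas x frames exclusion mask.
#' @param ... vitality parameters passed to [vitality_from_objects()].
#' @return a `vitality_result` (see [vitality_from_objects()]) with the
#'   detected `objects` attached.
#' @export
score_stack <- function(series, regions, min_area = 300, method = "otsu",
                        threshold = NULL, polarity = "dark_objects",
                        min_contrast = 20, exclude = NULL, ...) {
  objects <- detect_stack(series, regions, min_area = min_area,
                          method = method, threshold = threshold,
                          polarity = polarity, min_contrast = min_contrast,
                          exclude = exclude)
  res <- vitality_from_objects(objects, series$times, regions = regions,
                               exclude = exclude, ...)
  res$objects <- objects
  res
}

#' Write the moving-count matrix as TSV
#'
#' Rows are arenas, columns frame times (the later frame of each pair),
#' mirroring the "number of moving worms in each arena at each timepoint"
#' text output of the original processing chain.
#'
#' @param result a `vitality_result`.
#' @param file output path.
#' @export
write_moving_counts <- function(result, file) {
  m <- result$moving_counts
  df <- data.frame(arena = seq_len(nrow(m)), m, check.names = FALSE)
  names(df)[-1] <- sprintf("%.1f", result$pair_times)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write death calls as CSV
#'
#' @param calls the `calls` data frame of a `vitality_result`.
#' @param file output path.
#' @export
write_death_calls <- function(calls, file) {
  out <- calls
  out$time_h <- ifelse(is.na(out$time_h), "", sprintf("%.1f", out$time_h))
  write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
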