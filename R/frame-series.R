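#' Construct a frame series
#'
#' A frame series is the raw observable of a scanner run: an ordered set of
#' grayscale frames of identical shape with elapsed times in hours. Times are
#' re-expressed relative to the first frame, so `times[1]` is always 0.
#'
#' Images throughout the package are numeric matrices indexed `[row, col]`
#' (1-based, origin top-left) with gray levels on a 0-255 scale.
#'
#' @param frames list of numeric matrices of equal dimensions.
#' @param times numeric vector of acquisition times in hours, strictly
#'   increasing, same length as `frames`. Absolute times are allowed; they
#'   are shifted so the first frame is at 0.
#' @param source optional character identifier (scanner/array).
#' @return an object of class `frame_series` with elements `frames`,
#'   `times`, and `source`.
#' @export
frame_series <- function(frames, times, source = NA_character_) {
  stop_if(!is.list(frames) || length(frames) == 0L,
          "`frames` must be a non-empty list of matrices")
  stop_if(length(times) != length(frames),
          "`times` (", length(times), ") and `frames` (", length(frames),
          ") lengths differ")
  stop_if(anyNA(times), "`times` contains missing values")
  stop_if(any(diff(times) <= 0), "`times` must be strictly increasing")
  dims <- vapply(frames, function(f) {
    stop_if(!is.matrix(f) || !is.numeric(f), "each frame must be a numeric matrix")
    dim(f)
  }, integer(2))
  stop_if(any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]),
          "all frames must have identical dimensions")
  structure(
    list(frames = frames, times = as.numeric(times - times[1]),
         source = source),
    class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_series> %d frames of %d x %d px, %.1f h span (%s)\n",
              length(x$frames), d[1], d[2], max(x$times),
              ifelse(is.na(x$source), "unnamed", x$source)))
  invisible(x)
}

#' @export
length.frame_series <- function(x) length(x$frames)

#' Load a timestamped frame series from TIFF files
#'
#' Accepts either a single multi-page TIFF or a set of single-frame TIFFs
#' (a directory or an explicit vector of paths). Pixel values are rescaled
#' to gray levels 0-255 regardless of the files' bit depth.
#'
#' Timestamps are resolved in a fixed precedence order so runs are
#' scriptable and deterministic:
#' 1. a sidecar table (`times` as a CSV path or data frame with columns
#'    `file` and `time`, ISO-8601 or numeric hours);
#' 2. an ISO-8601-like stamp embedded in each filename
#'    (`YYYY-MM-DD[T_ ]HH[:]MM[[:]SS]` or compact `YYYYMMDDHHMMSS`);
#' 3. the TIFF `DateTime` tag.
#'
#' Frames are sorted by time whatever the lexical order of the inputs.
#'
#' @param path a multi-page TIFF file, a directory containing `.tif`/`.tiff`
#'   files, or a character vector of TIFF paths.
#' @param times optional sidecar: a CSV path, a data frame with columns
#'   `file` (filename or 1-based page number) and `time`, or a bare numeric
#'   vector of hours (one per frame/page, in file/page order).
#' @param source optional series identifier.
#' @return a [frame_series()].
#' @export
load_frame_series <- function(path, times = NULL, source = NA_character_) {
  sidecar <- read_sidecar_times(times)
  if (length(path) == 1L && dir.exists(path)) {
    path <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                            full.names = TRUE))
    stop_if(length(path) == 0L, "no TIFF files found in directory")
  }
  for (p in path) stop_if(!file.exists(p), "cannot read TIFF: ", p)

  if (length(path) == 1L) {
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                      error = function(e)
                        stop("unreadable TIFF: ", path, " (", conditionMessage(e),
                             ")", call. = FALSE))
    if (!is.list(pages)) pages <- list(pages)
    frames <- lapply(pages, tiff_to_gray)
    keys <- as.character(seq_along(frames))
    tags <- vapply(pages, function(p) {
      dt <- attr(p, "date.time")
      if (is.null(dt)) NA_character_ else as.character(dt)
    }, character(1))
    tvec <- resolve_times(keys, tags, sidecar, label = path)
  } else {
    frames <- vector("list", length(path))
    tags <- character(length(path))
    for (i in seq_along(path)) {
      img <- tryCatch(tiff::readTIFF(path[i], info = TRUE),
                      error = function(e)
                        stop("unreadable TIFF: ", path[i], " (",
                             conditionMessage(e), ")", call. = FALSE))
      dt <- attr(img, "date.time")
      tags[i] <- if (is.null(dt)) NA_character_ else as.character(dt)
      frames[[i]] <- tiff_to_gray(img)
    }
    tvec <- resolve_times(basename(path), tags, sidecar, label = path)
  }

  stop_if(anyNA(tvec), "missing timestamp for: ",
          paste(path[is.na(tvec)][1], collapse = ", "))
  stop_if(anyDuplicated(tvec) > 0, "duplicate timestamps in series")
  ord <- order(tvec)
  frame_series(frames[ord], tvec[ord], source = source)
}

# First TIFF sample plane, rescaled from [0,1] to gray levels 0-255.
tiff_to_gray <- function(img) {
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img * 255
}

read_sidecar_times <- function(times) {
  if (is.null(times)) return(NULL)
  if (is.numeric(times)) return(times)
  if (is.character(times) && length(times) == 1L) {
    stop_if(!file.exists(times), "sidecar timestamp file not found: ", times)
    times <- read.csv(times, stringsAsFactors = FALSE)
  }
  stop_if(!is.data.frame(times) || !all(c("file", "time") %in% names(times)),
          "sidecar table must have columns `file` and `time`")
  times
}

parse_time_value <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  suppressWarnings(num <- as.numeric(x))
  if (all(!is.na(num))) return(num)
  t <- as.POSIXct(x, tz = "UTC",
                  tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                 "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                                 "%Y:%m:%d %H:%M:%S", "%Y%m%d%H%M%S"),
                  optional = TRUE)
  as.numeric(t) / 3600
}

filename_time <- function(fn) {
  m <- regmatches(fn, regexpr(
    "\\d{4}-\\d{2}-\\d{2}[T_ -]\\d{2}[:.]?\\d{2}([:.]?\\d{2})?", fn))
  if (length(m) == 0L) m <- regmatches(fn, regexpr("\\d{14}", fn))
  if (length(m) == 0L) return(NA_real_)
  digits <- gsub("\\D", "", m)            # YYYYMMDDHHMM[SS]
  if (nchar(digits) == 12L) digits <- paste0(digits, "00")
  t <- as.POSIXct(digits, tz = "UTC", format = "%Y%m%d%H%M%S")
  as.numeric(t) / 3600
}

resolve_times <- function(keys, tags, sidecar, label = "") {
  n <- length(keys)
  if (is.numeric(sidecar)) {
    stop_if(length(sidecar) != n, "sidecar provides ", length(sidecar),
            " times for ", n, " frames")
    return(as.numeric(sidecar))
  }
  if (is.data.frame(sidecar)) {
    idx <- match(keys, as.character(sidecar$file))
    stop_if(anyNA(idx), "sidecar table missing entry for: ",
            keys[is.na(idx)][1])
    return(parse_time_value(sidecar$time[idx]))
  }
  tvec <- vapply(keys, filename_time, numeric(1), USE.NAMES = FALSE)
  fallback <- is.na(tvec) & !is.na(tags)
  if (any(fallback)) tvec[fallback] <- parse_time_value(tags[fallback])
  tvec
}
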