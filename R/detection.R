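#' Threshold an arena image into a worm-candidate mask
#'
#' Converts a grayscale arena crop to a binary foreground mask. Worms absorb
#' the scanner's transillumination, so the default polarity treats pixels
#' darker than the threshold as candidates. Otsu's threshold is computed per
#' arena per frame: the scanner's residual exposure gradient across the bed
#' makes a single global threshold unsafe, whereas within one ~1 x 4 mm
#' arena the gradient is negligible.
#'
#' An image without an object carries no evidence to split on: a constant
#' input yields an empty mask, and when the two classes Otsu separates
#' differ by less than `min_contrast` gray levels the "foreground" is just
#' the dark tail of sensor noise (which, thresholded near its median,
#' percolates into arbitrarily large connected blobs), so the mask is
#' empty as well.
#'
#' @param image numeric matrix, gray levels 0-255.
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param threshold gray level for `method = "fixed"`.
#' @param polarity `"dark_objects"` (foreground below threshold, default) or
#'   `"light_objects"`.
#' @param min_contrast minimum separation of the Otsu class means (gray
#'   levels) required to accept the split (default 20); ignored for
#'   `method = "fixed"`.
#' @return logical matrix, `TRUE` = candidate foreground.
#' @export
binarize <- function(image, method = c("otsu", "fixed"), threshold = NULL,
                     polarity = c("dark_objects", "light_objects"),
                     min_contrast = 20) {
  method <- match.arg(method)
  polarity <- match.arg(polarity)
  stop_if(!is.matrix(image) || !is.numeric(image), "`image` must be a numeric matrix")
  rng <- range(image)
  if (method == "otsu") {
    if (rng[1] == rng[2]) return(matrix(FALSE, nrow(image), ncol(image)))
    threshold <- EBImage::otsu(image, range = c(0, 255), levels = 256L)
    lo <- image[image < threshold]; hi <- image[image >= threshold]
    if (!length(lo) || !length(hi) || mean(hi) - mean(lo) < min_contrast)
      return(matrix(FALSE, nrow(image), ncol(image)))
  } else {
    stop_if(is.null(threshold) || !is_number(threshold),
            "`threshold` is required for method = \"fixed\"")
    if (threshold < rng[1] || threshold > rng[2])
      warning("fixed threshold ", threshold, " outside image value range [",
              signif(rng[1], 4), ", ", signif(rng[2], 4), "]", call. = FALSE)
  }
  if (polarity == "dark_objects") image < threshold else image > threshold
}

#' Measure worm-like objects in a binary mask
#'
#' Labels 8-connected components (thin diagonal worm segments must not
#' fragment), removes everything too small to be a worm, and measures each
#' surviving object: area, centroid (mean of member pixel coordinates,
#' 1-based), and bounding box. The size rule keeps `area >= min_area`:
#' objects strictly smaller than the threshold are removed.
#'
#' @param mask logical or 0/1 matrix.
#' @param min_area minimum object area in pixels (default 300, user
#'   adjustable for other stages or strains).
#' @param image optional grayscale matrix matching `mask`, used to record
#'   each object's mean intensity.
#' @param arena optional arena index stamped on each object.
#' @param time_h optional frame time in hours stamped on each object.
#' @return a data frame (class `worm_objects`), one row per object, sorted
#'   by centroid row then column: `arena`, `time_h`, `area`,
#'   `centroid_row`, `centroid_col`, `bbox_height`, `bbox_width`,
#'   `mean_intensity`.
#' @export
detect_objects <- function(mask, min_area = 300, image = NULL,
                           arena = NA_integer_, time_h = NA_real_) {
  stop_if(!is.matrix(mask), "`mask` must be a matrix")
  stop_if(!is_number(min_area) || min_area < 0, "`min_area` must be >= 0")
  storage.mode(mask) <- "integer"
  lab <- .label_components8(mask)
  st <- lab$stats
  keep <- st$area >= min_area
  st <- st[keep, , drop = FALSE]
  mi <- rep(NA_real_, nrow(st))
  if (!is.null(image) && nrow(st) > 0) {
    sums <- tapply(image[lab$labels > 0], lab$labels[lab$labels > 0], sum)
    mi <- as.numeric(sums[as.character(st$label)]) / st$area
  }
  out <- data.frame(
    arena = rep(as.integer(arena), nrow(st)),
    time_h = rep(as.numeric(time_h), nrow(st)),
    area = st$area,
    centroid_row = st$centroid_row,
    centroid_col = st$centroid_col,
    bbox_height = st$row_max - st$row_min + 1L,
    bbox_width = st$col_max - st$col_min + 1L,
    mean_intensity = mi)
  out <- out[order(out$centroid_row, out$centroid_col), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("worm_objects", "data.frame")
  out
}

empty_worm_objects <- function() {
  detect_objects(matrix(0L, 1, 1), min_area = 0)[0, ]
}

#' Detect objects in every arena of every frame
#'
#' Runs [binarize()] + [detect_objects()] over each (arena, frame) cell of
#' a series: the per-arena crop is thresholded independently and its
#' objects measured in arena-local coordinates.
#'
#' @param series a [frame_series()].
#' @param regions regions from [build_grid()].
#' @param min_area,method,threshold,polarity,min_contrast passed to
#'   [binarize()] /
#'   [detect_objects()].
#' @param exclude optional arenas x frames logical mask (`TRUE` = skip).
#' @return a `worm_objects` data frame covering the whole series.
#' @export
detect_stack <- function(series, regions, min_area = 300,
                         method = "otsu", threshold = NULL,
                         polarity = "dark_objects", min_contrast = 20,
                         exclude = NULL) {
  res <- vector("list", length(series$frames) * nrow(regions))
  k <- 0L
  for (fi in seq_along(series$frames)) {
    f <- series$frames[[fi]]
    for (ai in seq_len(nrow(regions))) {
      if (isTRUE(regions$excluded[ai])) next
      if (!is.null(exclude) && isTRUE(exclude[ai, fi])) next
      crop <- crop_arena(f, regions[ai, ])
      m <- binarize(crop, method = method, threshold = threshold,
                    polarity = polarity, min_contrast = min_contrast)
      obj <- detect_objects(m, min_area = min_area, image = crop,
                            arena = regions$arena[ai],
                            time_h = series$times[fi])
      if (nrow(obj)) { k <- k + 1L; res[[k]] <- obj }
    }
  }
  out <- if (k > 0) do.call(rbind, res[seq_len(k)]) else empty_worm_objects()
  rownames(out) <- NULL
  class(out) <- c("worm_objects", "data.frame")
  out
}
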