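#' Rigid (similarity) transforms between image coordinate systems
#'
#' A `rigid_transform` maps points `p = (row, col)` to `s * R %*% p + t`,
#' where `R` is a rotation by `rotation` radians, `t = translation` in
#' pixels, and `s` an optional uniform scale (1 for a pure rigid motion).
#' Chips sit at a slightly different angle on each scanner, so aligning
#' frames to the grid's coordinate system needs rotation + translation;
#' scale absorbs small dpi differences when enabled.
#'
#' @param rotation rotation angle in radians (counter-clockwise in
#'   (row, col) coordinates).
#' @param translation length-2 numeric, pixel offset (drow, dcol).
#' @param scale uniform scale factor, must be > 0.
#' @return an object of class `rigid_transform`.
#' @seealso [estimate_rigid_transform()], [apply_transform()]
#' @export
rigid_transform <- function(rotation = 0, translation = c(0, 0), scale = 1) {
  stop_if(!is_number(rotation), "`rotation` must be a single finite number")
  stop_if(length(translation) != 2L || !is.numeric(translation),
          "`translation` must be length-2 numeric")
  stop_if(!is_number(scale) || scale <= 0, "`scale` must be > 0")
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 scale = scale),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf(
    "<rigid_transform> rotation %.6g rad, translation (%.6g, %.6g), scale %.6g\n",
    x$rotation, x$translation[1], x$translation[2], x$scale))
  if (!is.null(attr(x, "rms"))) cat(sprintf("  fit residual RMS %.3g px\n",
                                            attr(x, "rms")))
  invisible(x)
}

rotation_matrix <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

#' Apply a rigid transform to points
#'
#' @param t a [rigid_transform()].
#' @param pts n x 2 matrix of (row, col) points.
#' @return n x 2 matrix of transformed points.
#' @export
transform_points <- function(t, pts) {
  pts <- rbind(pts)
  t$scale * pts %*% t(rotation_matrix(t$rotation)) +
    matrix(t$translation, nrow(pts), 2, byrow = TRUE)
}

#' Invert a rigid transform
#'
#' @param t a [rigid_transform()].
#' @return the inverse `rigid_transform`; composing the two is the identity.
#' @export
invert_transform <- function(t) {
  Rinv <- t(rotation_matrix(t$rotation))
  rigid_transform(rotation = -t$rotation,
                  translation = as.numeric(-(Rinv %*% t$translation) / t$scale),
                  scale = 1 / t$scale)
}

#' Estimate a rigid transform from reference point pairs
#'
#' Least-squares rigid (rotation + translation, optionally + uniform scale)
#' fit mapping `src` onto `dst`, by 2-D orthogonal Procrustes: centre both
#' point sets, take the SVD of the cross-covariance, and constrain the
#' orthogonal factor to a proper rotation. With two or more non-coincident
#' reference points marked on both the chip and the target grid this
#' corrects small deviations in the chip/scanner angle.
#'
#' @param src,dst n x 2 matrices (or data frames) of matched (row, col)
#'   points, n >= 2.
#' @param allow_scale if `TRUE`, fit a similarity (uniform scale) instead of
#'   a pure rigid motion.
#' @return a [rigid_transform()] with attribute `rms`, the root-mean-square
#'   residual of `transform_points(fit, src) - dst` in pixels.
#' @examples
#' src <- cbind(c(0, 10, 0), c(0, 0, 10))
#' estimate_rigid_transform(src, src + rep(c(5, -3), each = 3))
#' @export
estimate_rigid_transform <- function(src, dst, allow_scale = FALSE) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  stop_if(ncol(src) != 2L || ncol(dst) != 2L, "points must be n x 2")
  stop_if(nrow(src) != nrow(dst), "`src` and `dst` must pair up")
  stop_if(nrow(src) < 2L, "at least 2 point pairs are required")
  stop_if(all(apply(src, 2, function(v) diff(range(v))) == 0),
          "reference points are coincident; transform is degenerate")

  mu_s <- colMeans(src); mu_d <- colMeans(dst)
  A <- sweep(src, 2, mu_s); B <- sweep(dst, 2, mu_d)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, d))
  R <- sv$v %*% D %*% t(sv$u)          # dst ~ R %*% src
  s <- if (allow_scale) sum(diag(D) * sv$d) / sum(A^2) else 1
  theta <- atan2(R[2, 1], R[1, 1])
  tr <- mu_d - s * as.numeric(R %*% mu_s)
  fit <- rigid_transform(rotation = theta, translation = tr, scale = s)
  res <- transform_points(fit, src) - dst
  attr(fit, "rms") <- sqrt(mean(rowSums(res^2)))
  fit
}

#' Resample an image under a rigid transform
#'
#' Moves image content by the transform: the output pixel at `p` takes the
#' (bilinearly interpolated) input value at `t^-1(p)`, so features end up at
#' `transform_points(t, feature)`. Regions mapped from outside the input are
#' filled with the median border intensity (configurable), which avoids
#' creating spurious dark objects along frame edges.
#'
#' @param image numeric matrix, gray levels 0-255.
#' @param t a [rigid_transform()].
#' @param fill fill value for out-of-bounds regions; default the median of
#'   the image's border pixels.
#' @return a numeric matrix of the same dimensions.
#' @export
apply_transform <- function(image, t, fill = NULL) {
  stop_if(!is.matrix(image) || !is.numeric(image), "`image` must be a numeric matrix")
  stop_if(!inherits(t, "rigid_transform"), "`t` must be a rigid_transform")
  if (abs(t$rotation) < 1e-12 && t$scale == 1 &&
      all(abs(t$translation - round(t$translation)) < 1e-12)) {
    return(shift_image(image, round(t$translation),
                       fill = fill %||% border_median(image)))
  }
  if (is.null(fill)) fill <- border_median(image)
  R <- t$scale * rotation_matrix(t$rotation)
  # EBImage::affine maps output = input %*% m convention on (row, col, 1)
  m <- rbind(t(R), t$translation)
  out <- EBImage::affine(image, m, filter = "bilinear", bg.col = fill)
  matrix(as.numeric(out), nrow(image), ncol(image))
}

border_median <- function(image) {
  nr <- nrow(image); nc <- ncol(image)
  median(c(image[1, ], image[nr, ], image[, 1], image[, nc]))
}

# Integer-pixel translation without interpolation.
shift_image <- function(image, shift, fill = 0) {
  dr <- as.integer(shift[1]); dc <- as.integer(shift[2])
  nr <- nrow(image); nc <- ncol(image)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dr
  src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  out[which(ok_r), which(ok_c)] <- image[src_r[ok_r], src_c[ok_c]]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
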