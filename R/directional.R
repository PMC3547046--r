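#' Signed directional intensity difference at one pixel
#'
#' The elementary center-vs-ring comparison behind the directional score
#' stack: the intensity at `(row, col)` minus the intensity at the point a
#' distance `r` away along orientation `alpha`.  Angles follow the image
#' convention with x along columns and y up, so the ring point is
#' `(row - r*sin(alpha), col + r*cos(alpha))`, rounded to the nearest
#' pixel (no interpolation: at multiples of 45 degrees with integer radii
#' the offsets are near-integers already).
#'
#' @param img Numeric matrix.
#' @param row,col Center pixel, 1-based.
#' @param r Radius in pixels.
#' @param alpha Orientation in degrees.
#' @return The signed difference `img[center] - img[ring point]`.
#' @export
directional_difference <- function(img, row, col, r, alpha) {
  stopifnot(is.matrix(img))
  if (row < 1 || row > nrow(img) || col < 1 || col > ncol(img))
    stop("center (", row, ",", col, ") out of bounds")
  a <- alpha * pi / 180
  r2 <- row - round(r * sin(a))
  c2 <- col + round(r * cos(a))
  if (r2 < 1 || r2 > nrow(img) || c2 < 1 || c2 > ncol(img))
    stop("ring point (", r2, ",", c2, ") out of bounds; ",
         "use directional_scores() for mirror-extended evaluation")
  img[row, col] - img[r2, c2]
}

#' Directional difference score stack
#'
#' For every pixel and each of 8 orientations spaced 45 degrees apart over
#' the full circle, computes signed differences between the pixel and the
#' points on L equidistant concentric rings (radii 1..L) along that
#' orientation, then aggregates the L differences with the median, max or
#' mean.  Eight score images of the same size as the input are returned;
#' borders are handled by mirror extension, and a constant input yields an
#' all-zero stack.  These scores complement the wavelet magnitudes with a
#' cheap, signed, per-pixel measure of oriented local contrast.
#'
#' @param img Numeric matrix, normally the [average_intensity()] image.
#' @param L Ring count / largest radius in pixels, default 5.
#' @param aggregator One of `"median"`, `"max"`, `"mean"`.
#' @return Object of class `directional_scores`: list of 8 matrices
#'   (orientations 0, 45, ..., 315 degrees, attribute `orientation`),
#'   with the aggregator name attached.
#' @examples
#' ramp <- matrix(rep(1:16, each = 16), 16, 16, byrow = TRUE)
#' s <- directional_scores(ramp, L = 5, aggregator = "median")
#' s[[1]][8, 8]  # -3: median of {-1,...,-5} along 0 degrees
#' @export
directional_scores <- function(img, L = 5L,
                               aggregator = c("median", "max", "mean")) {
  stopifnot(is.matrix(img), L >= 1L)
  aggregator <- match.arg(aggregator)
  n <- nrow(img); m <- ncol(img)
  ext <- mirror_extend(img, L)
  alphas <- (0:7) * 45
  scores <- vector("list", 8L)
  for (j in seq_len(8L)) {
    a <- alphas[j] * pi / 180
    diffs <- vector("list", L)
    for (k in seq_len(L)) {
      dr <- -round(k * sin(a))
      dc <- round(k * cos(a))
      diffs[[k]] <- img - ext[(1 + L + dr):(n + L + dr),
                              (1 + L + dc):(m + L + dc), drop = FALSE]
    }
    scores[[j]] <- aggregate_planes(diffs, aggregator)
  }
  attr(scores, "orientation") <- alphas
  attr(scores, "aggregator") <- aggregator
  class(scores) <- "directional_scores"
  scores
}

# elementwise aggregation of a list of equally sized matrices
aggregate_planes <- function(planes, aggregator) {
  switch(aggregator,
    max  = Reduce(pmax, planes),
    mean = Reduce(`+`, planes) / length(planes),
    median = {
      arr <- array(unlist(planes), dim = c(dim(planes[[1]]), length(planes)))
      apply(arr, c(1, 2), stats::median)
    })
}

# whole-sample mirror extension by p pixels on every side
mirror_extend <- function(img, p) {
  n <- nrow(img); m <- ncol(img)
  ri <- c(p:1, 1:n, n:(n - p + 1L))
  ci <- c(p:1, 1:m, m:(m - p + 1L))
  img[ri, ci, drop = FALSE]
}

#' @export
print.directional_scores <- function(x, ...) {
  cat("Directional difference scores (", attr(x, "aggregator"), "), 8 x ",
      nrow(x[[1]]), "x", ncol(x[[1]]), "\n", sep = "")
  invisible(x)
}
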