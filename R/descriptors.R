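#' Per-pixel feature maps F1-F4
#'
#' Assembles the per-pixel attribute stack whose region covariances are
#' the texture descriptors.  Mappings F1, F2 and F3 are 15-dimensional:
#' the averaged intensity, the six dual-tree subband magnitudes and the
#' eight directional scores aggregated with the median (F1), max (F2) or
#' mean (F3).  F4 is the classical 5-dimensional intensity-plus-derivative
#' mapping: intensity, absolute first and second derivatives along columns
#' and rows (central differences, mirror boundaries).  Pixel coordinates
#' are deliberately excluded: subwindows are sampled all over the image,
#' so absolute position carries no class information here.
#'
#' @param avg Averaged intensity image ([average_intensity()]).
#' @param mags Six-magnitude list from [subband_magnitudes()]
#'   (unused by F4).
#' @param scores A `directional_scores` stack whose aggregator matches
#'   the mapping (median for F1, max for F2, mean for F3; unused by F4).
#' @param mapping One of `"F1"`, `"F2"`, `"F3"`, `"F4"`.
#' @return Object of class `feature_map`: list with `planes` (list of d
#'   matrices), `d`, and `mapping`.
#' @export
feature_map <- function(avg, mags = NULL, scores = NULL,
                        mapping = c("F1", "F2", "F3", "F4")) {
  mapping <- match.arg(mapping)
  stopifnot(is.matrix(avg))
  if (mapping == "F4") {
    planes <- c(list(avg), derivative_planes(avg))
  } else {
    if (is.null(mags) || is.null(scores))
      stop(mapping, " needs both subband magnitudes and directional scores")
    expected <- c(F1 = "median", F2 = "max", F3 = "mean")[[mapping]]
    got <- attr(scores, "aggregator")
    if (!identical(got, expected))
      stop(mapping, " uses the ", expected,
           " aggregator, but scores were built with ", got)
    all_planes <- c(list(avg), mags, unclass(scores)[1:8])
    sizes <- vapply(all_planes, dim, integer(2))
    if (any(sizes[1, ] != nrow(avg)) || any(sizes[2, ] != ncol(avg)))
      stop("feature planes are not aligned: sizes differ")
    planes <- all_planes
  }
  structure(list(planes = planes, d = length(planes), mapping = mapping),
            class = "feature_map")
}

# |dI/dx|, |dI/dy|, |d2I/dx2|, |d2I/dy2| by central differences on the
# mirror-extended image (x = columns, y = rows)
derivative_planes <- function(img) {
  e <- mirror_extend(img, 1L)
  n <- nrow(img); m <- ncol(img)
  xm <- e[2:(n + 1), 1:m]; xp <- e[2:(n + 1), 3:(m + 2)]
  ym <- e[1:n, 2:(m + 1)]; yp <- e[3:(n + 2), 2:(m + 1)]
  list(abs((xp - xm) / 2), abs((yp - ym) / 2),
       abs(xp - 2 * img + xm), abs(yp - 2 * img + ym))
}

#' Region covariance descriptor of a subwindow
#'
#' The d x d sample covariance (divisor n-1) of the per-pixel feature
#' vectors inside a square subwindow: a compact, illumination-tolerant
#' texture signature of the region.
#'
#' @param fm A `feature_map`.
#' @param window A `subwindow` (see [sample_subwindows()]) or a list with
#'   0-based `row0`, `col0` and size `M`.
#' @return Object of class `cov_descriptor`: list with `matrix` (d x d),
#'   `normalized` (FALSE), `mapping`, `window`.
#' @export
region_covariance <- function(fm, window) {
  stopifnot(inherits(fm, "feature_map"))
  r <- window$row0; c0 <- window$col0; M <- window$M
  nr <- nrow(fm$planes[[1]]); nc <- ncol(fm$planes[[1]])
  if (r < 0 || c0 < 0 || r + M > nr || c0 + M > nc)
    stop("subwindow [", r, ",", r + M, ") x [", c0, ",", c0 + M,
         ") outside the ", nr, "x", nc, " feature grid")
  if (M * M < 2) stop("degenerate region: fewer than 2 pixels")
  ri <- (r + 1):(r + M); ci <- (c0 + 1):(c0 + M)
  Z <- vapply(fm$planes, function(p) as.vector(p[ri, ci]),
              numeric(M * M))
  C <- stats::cov(Z)
  dimnames(C) <- NULL
  structure(list(matrix = (C + t(C)) / 2, normalized = FALSE,
                 mapping = fm$mapping, window = window),
            class = "cov_descriptor")
}

#' Normalize a covariance descriptor to correlations
#'
#' Divides each off-diagonal entry by the product of the corresponding
#' standard deviations, turning it into a correlation; entries whose
#' variances fall below `eps` are set to 0.  The diagonal keeps the raw
#' variances, so the diagonal-only ablation still reads feature variances
#' off the normalized descriptor.  Off-diagonals become invariant to
#' positive rescaling of any feature plane, which absorbs contrast and
#' illumination differences between images.
#'
#' @param cd A plain `cov_descriptor`.
#' @param eps Variance guard, default 1e-12.
#' @return The normalized `cov_descriptor`.
#' @export
normalize_covariance <- function(cd, eps = 1e-12) {
  stopifnot(inherits(cd, "cov_descriptor"))
  if (cd$normalized) stop("descriptor is already normalized")
  C <- cd$matrix
  v <- diag(C)
  s <- sqrt(pmax(v, 0))
  denom <- outer(s, s)
  R <- ifelse(outer(v > eps, v > eps, `&`) & denom > 0, C / denom, 0)
  diag(R) <- v
  cd$matrix <- (R + t(R)) / 2
  cd$normalized <- TRUE
  cd
}

#' Vectorize a symmetric descriptor
#'
#' Stacks the upper triangle (diagonal included) in row-major order into a
#' vector of length d(d+1)/2 -- 120 for the 15-dimensional mappings, 15
#' for F4 -- the representation fed to the SVM.
#'
#' @param cd A `cov_descriptor`.
#' @param tol Symmetry tolerance.
#' @return Numeric vector with attributes `mapping` and `normalized`.
#' @export
vectorize_descriptor <- function(cd, tol = 1e-8) {
  stopifnot(inherits(cd, "cov_descriptor"))
  M <- cd$matrix
  if (max(abs(M - t(M))) > tol) stop("descriptor matrix is not symmetric")
  v <- t(M)[lower.tri(M, diag = TRUE)]  # row-major upper triangle
  attr(v, "mapping") <- cd$mapping
  attr(v, "normalized") <- cd$normalized
  v
}

#' Diagonal-only descriptor vector
#'
#' The ablated representation: just the d feature variances, discarding
#' all cross-feature structure.  Used to quantify how much of the
#' discriminative power lives in the covariances proper.
#'
#' @inheritParams vectorize_descriptor
#' @return Numeric vector of length d.
#' @export
diagonal_descriptor <- function(cd) {
  stopifnot(inherits(cd, "cov_descriptor"))
  v <- diag(cd$matrix)
  attr(v, "mapping") <- cd$mapping
  attr(v, "normalized") <- cd$normalized
  v
}

#' @export
print.cov_descriptor <- function(x, ...) {
  d <- nrow(x$matrix)
  cat(if (x$normalized) "Normalized region" else "Region",
      "covariance descriptor, d =", d,
      paste0("(", x$mapping, ")"), "\n")
  invisible(x)
}

#' @export
print.feature_map <- function(x, ...) {
  cat("Feature map ", x$mapping, ": d = ", x$d, ", ",
      nrow(x$planes[[1]]), "x", ncol(x$planes[[1]]), "\n", sep = "")
  invisible(x)
}
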