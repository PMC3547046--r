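#' Two-dimensional dual-tree complex wavelet transform
#'
#' Decomposes a grayscale image with two parallel, maximally decimated
#' separable wavelet trees whose filters form an approximate Hilbert pair
#' (see [dt_filter_bank()]).  Running both trees along rows and columns
#' gives four real separable transforms; adding and subtracting the
#' corresponding detail subbands yields, per level, six complex detail
#' subbands that are directionally selective at orientations
#' +15, +45, +75, -75, -45 and -15 degrees, plus four real approximation
#' subbands -- 16 real bands in all.  Decimation halves each dimension per
#' level (odd sizes are mirror-padded, so level-l bands measure
#' \code{ceiling(dim / 2^l)}).  Boundaries are handled by symmetric
#' (mirror) extension throughout.
#'
#' @param img Numeric matrix of intensities (rows x cols).
#' @param levels Decomposition depth, default 2.
#' @param fb A `dt_filter_bank`; defaults to the 14-tap Q-shift bank.
#' @return An object of class `dtcwt_pyramid`: list with `levels`,
#'   `detail` (per level, a list of six complex matrices ordered by
#'   orientation +15, +45, +75, -75, -45, -15 degrees), `approx` (per
#'   level, four real lowpass bands for the tree combinations AA, AB, BA,
#'   BB) and `dim`, the input size.
#' @seealso [subband_magnitudes()], [average_intensity()]
#' @examples
#' pyr <- dtcwt2d(matrix(runif(64^2), 64), levels = 2)
#' dim(pyr$detail[[2]][[1]])  # 16 x 16
#' @export
dtcwt2d <- function(img, levels = 2L, fb = dt_filter_bank()) {
  stopifnot(is.matrix(img), is.numeric(img))
  if (levels < 1L) stop("'levels' must be >= 1")
  if (min(dim(img)) < 2^levels)
    stop("image of size ", nrow(img), "x", ncol(img),
         " is too small for a depth-", levels, " decomposition")
  # four approximation surfaces, one per (row tree, col tree) combination
  A <- list(img, img, img, img)  # order: AA, AB, BA, BB
  tree_of <- rbind(c(1L, 1L), c(1L, 2L), c(2L, 1L), c(2L, 2L))
  detail <- vector("list", levels)
  approx <- vector("list", levels)
  for (l in seq_len(levels)) {
    fl <- if (l == 1L) fb$level1 else fb$level2
    bands <- vector("list", 4L)
    for (k in 1:4) {
      i <- tree_of[k, 1L]; j <- tree_of[k, 2L]
      bands[[k]] <- separable_level(A[[k]], fl[[i]], fl[[j]])
      A[[k]] <- bands[[k]]$ll
    }
    detail[[l]] <- combine_oriented(bands)
    approx[[l]] <- lapply(bands, `[[`, "ll")
  }
  structure(list(levels = levels, detail = detail, approx = approx,
                 dim = dim(img), qshift = attr(fb, "qshift")),
            class = "dtcwt_pyramid")
}

# one separable analysis level: row-tree filters along dim 1, col-tree
# filters along dim 2
separable_level <- function(X, ftr_row, ftr_col) {
  lo <- fb_decim(X, ftr_row$h0)
  hi <- fb_decim(X, ftr_row$h1)
  list(ll = t(fb_decim(t(lo), ftr_col$h0)),
       lh = t(fb_decim(t(lo), ftr_col$h1)),
       hl = t(fb_decim(t(hi), ftr_col$h0)),
       hh = t(fb_decim(t(hi), ftr_col$h1)))
}

# Convolve the columns of X with h under symmetric extension and decimate
# by 2, keeping the window for output sample k centred at input row 2k - 1/2.
# Odd row counts are mirror-padded to even first, so nrow(out) = ceil(n/2).
fb_decim <- function(X, h) {
  if (nrow(X) %% 2L == 1L) X <- X[c(seq_len(nrow(X)), nrow(X)), , drop = FALSE]
  n <- nrow(X); L <- length(h); p <- L
  g <- rev(h)  # convolution, not correlation
  Xe <- X[c(p:1, 1:n, n:(n - p + 1L)), , drop = FALSE]
  ks <- seq_len(n %/% 2L)
  base <- 2L * ks + L %/% 2L - 1L
  out <- matrix(0, length(ks), ncol(X))
  for (t in seq_len(L)) out <- out + g[t] * Xe[base + t, , drop = FALSE]
  out
}

# Add/subtract the four separable detail bands into six oriented complex
# subbands.  bands is the list (AA, AB, BA, BB) from separable_level().
# The (sum, difference) pairing below isolates the positive- and
# negative-frequency quadrants; the output order is fixed to
# +15, +45, +75, -75, -45, -15 degrees (calibrated against oriented
# sinusoidal gratings; see the package tests).
combine_oriented <- function(bands) {
  s2 <- sqrt(2)
  cx <- function(d) {
    w11 <- bands[[1L]][[d]]; w22 <- bands[[4L]][[d]]
    w12 <- bands[[2L]][[d]]; w21 <- bands[[3L]][[d]]
    list(p = ((w11 - w22) + 1i * (w12 + w21)) / s2,
         m = ((w11 + w22) + 1i * (w21 - w12)) / s2)
  }
  lh <- cx("lh"); hl <- cx("hl"); hh <- cx("hh")
  list(hl$p, hh$p, lh$p, lh$m, hh$m, hl$m)
}

#' Orientations of the six dual-tree detail subbands, in degrees.
#' @export
dtcwt_orientations <- function() c(15, 45, 75, -75, -45, -15)

#' Oriented subband magnitudes
#'
#' Extracts the six complex-coefficient magnitude images
#' \eqn{|w| = \sqrt{w_r^2 + w_i^2}} at one pyramid level (default the
#' second, whose bands share the grid of [average_intensity()]).
#'
#' @param pyr A `dtcwt_pyramid`.
#' @param level Pyramid level, default 2.
#' @return List of six nonnegative matrices, orientation order
#'   +15, +45, +75, -75, -45, -15 degrees, with attribute `orientation`.
#' @export
subband_magnitudes <- function(pyr, level = 2L) {
  stopifnot(inherits(pyr, "dtcwt_pyramid"))
  if (level < 1L || level > pyr$levels)
    stop("level ", level, " out of range: pyramid has ", pyr$levels, " levels")
  mags <- lapply(pyr$detail[[level]], Mod)
  attr(mags, "orientation") <- dtcwt_orientations()
  mags
}

#' Quarter-resolution averaged intensity image
#'
#' Lowpass-filters the image through two dyadic stages of the tree-A/tree-A
#' approximation path and rescales so a constant image of value c maps to
#' the constant c.  The result is the image actually classified: all
#' per-pixel features are aligned to its grid, which is the input
#' downsampled by 4 in both directions.
#'
#' @inheritParams dtcwt2d
#' @return Numeric matrix of size `ceiling(dim(img)/4)`.
#' @examples
#' avg <- average_intensity(matrix(0.5, 64, 64))
#' range(avg)  # 0.5 0.5
#' @export
average_intensity <- function(img, fb = dt_filter_bank()) {
  stopifnot(is.matrix(img), is.numeric(img))
  if (min(dim(img)) < 4L) stop("image must be at least 4 x 4")
  a1 <- fb$level1[[1L]]; a2 <- fb$level2[[1L]]
  g1 <- sum(a1$h0); g2 <- sum(a2$h0)
  X <- t(fb_decim(t(fb_decim(img, a1$h0)), a1$h0))
  X <- t(fb_decim(t(fb_decim(X, a2$h0)), a2$h0))
  X / (g1^2 * g2^2)
}

#' @export
print.dtcwt_pyramid <- function(x, ...) {
  cat("2-D dual-tree complex wavelet pyramid (", x$qshift, ")\n", sep = "")
  cat("  input ", x$dim[1], "x", x$dim[2], ", ", x$levels, " level(s)\n",
      sep = "")
  for (l in seq_len(x$levels))
    cat("  level ", l, ": 6 complex detail + 4 approx bands, ",
        nrow(x$detail[[l]][[1]]), "x", ncol(x$detail[[l]][[1]]), "\n",
        sep = "")
  invisible(x)
}
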