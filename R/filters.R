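#' Dual-tree analysis filter bank
#'
#' Loads the analysis filters used by the two parallel wavelet trees.
#' Level 1 always uses the Farras nearly-symmetric orthonormal pair, whose
#' tree-B lowpass is the tree-A lowpass delayed by one sample.  Levels two
#' and above use a Q-shift pair: tree B is the time reverse of tree A, so
#' the two lowpass filters are offset by approximately half a sample, which
#' makes the iterated wavelets of the two trees an approximate Hilbert
#' transform pair.  Highpass filters are derived from the lowpass by the
#' quadrature-mirror rule \code{h1[n] = (-1)^n h0[N-1-n]}.
#'
#' @param qshift Name of the shipped Q-shift coefficient set for levels
#'   \eqn{\ge 2}: `"qshift14"` (14-tap, default) or `"qshift10"` (10-tap).
#' @return An object of class `dt_filter_bank`: a list with elements
#'   `level1` and `level2`, each a list of two trees with components
#'   `h0` (lowpass) and `h1` (highpass), plus the attribute `qshift` naming
#'   the coefficient set.
#' @examples
#' fb <- dt_filter_bank()
#' sum(fb$level2[[1]]$h0^2)  # orthonormal: 1
#' @export
dt_filter_bank <- function(qshift = c("qshift14", "qshift10")) {
  qshift <- match.arg(qshift)
  dir <- system.file("extdata", "filters", package = "cellcov")
  far <- as.matrix(utils::read.table(file.path(dir, "farras_level1.txt"),
                                     comment.char = "#"))
  q <- utils::read.table(file.path(dir, paste0(qshift, ".txt")),
                         comment.char = "#")[[1]]
  fb <- list(
    level1 = list(make_tree(far[, 1]), make_tree(far[, 2])),
    level2 = list(make_tree(q), make_tree(rev(q)))
  )
  attr(fb, "qshift") <- qshift
  class(fb) <- "dt_filter_bank"
  fb
}

make_tree <- function(h0) list(h0 = h0, h1 = qmf_filter(h0))

# quadrature mirror: h1[n] = (-1)^n h0[N-1-n].  The published lowpass
# coefficients are rounded to 8 decimals, so the alternating sum is only
# ~1e-9; recentre the highpass so it annihilates constants exactly.
qmf_filter <- function(h0) {
  h1 <- rev(h0) * (-1)^(seq_along(h0) - 1)
  h1 - mean(h1)
}

#' @export
print.dt_filter_bank <- function(x, ...) {
  cat("Dual-tree analysis filter bank\n")
  cat("  level 1 : Farras pair,", length(x$level1[[1]]$h0), "taps\n")
  cat("  level 2+:", attr(x, "qshift"), "pair,",
      length(x$level2[[1]]$h0), "taps\n")
  invisible(x)
}
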