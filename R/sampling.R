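#' Constrained random subwindow sampling
#'
#' Draws square subwindows uniformly on the averaged-image grid by
#' rejection sampling, accepting a window only when (a) more than half of
#' its pixels are foreground and (b) its intensity variance exceeds the
#' variance of the whole averaged image.  The first constraint keeps the
#' descriptors on cell material; the second favours textured regions over
#' flat ones.  Windows may overlap.  Sampling is reproducible given the
#' seed.
#'
#' @param avg Averaged intensity image.
#' @param mask An `fg_mask` on the same grid (see [downsample_mask()]).
#' @param M Window side in averaged-grid pixels (about 4M at full
#'   resolution), default 32.
#' @param N Number of windows to accept, default 20.
#' @param seed Integer seed.
#' @param max_attempts Proposal budget before giving up, default
#'   `10000 * N`.
#' @return Object of class `subwindow_set`: list with `windows` (each a
#'   `subwindow` with 0-based `row0`, `col0` and side `M`), `seed`, and
#'   the measured `acceptance_rate`.
#' @export
sample_subwindows <- function(avg, mask, M = 32L, N = 20L, seed = 1L,
                              max_attempts = 10000L * N) {
  stopifnot(is.matrix(avg), inherits(mask, "fg_mask"),
            all(dim(avg) == dim(mask$mask)))
  if (M > min(dim(avg)))
    stop("window side ", M, " exceeds the ", nrow(avg), "x", ncol(avg),
         " averaged grid")
  if (N < 1L) stop("N must be >= 1")
  vthr <- stats::var(as.vector(avg))
  msum <- cumsum2d(mask$mask * 1)
  vsum <- cumsum2d(avg)
  v2sum <- cumsum2d(avg * avg)
  npix <- M * M
  accepted <- list()
  tried <- 0L
  with_seed(seed, {
    while (length(accepted) < N && tried < max_attempts) {
      batch <- min(1024L, max_attempts - tried)
      r0 <- sample.int(nrow(avg) - M + 1L, batch, replace = TRUE) - 1L
      c0 <- sample.int(ncol(avg) - M + 1L, batch, replace = TRUE) - 1L
      tried <- tried + batch
      for (b in seq_len(batch)) {
        fgfrac <- box_sum(msum, r0[b], c0[b], M) / npix
        if (fgfrac <= 0.5) next
        s1 <- box_sum(vsum, r0[b], c0[b], M)
        s2 <- box_sum(v2sum, r0[b], c0[b], M)
        wvar <- (s2 - s1 * s1 / npix) / (npix - 1)
        if (wvar <= vthr) next
        accepted[[length(accepted) + 1L]] <-
          structure(list(row0 = r0[b], col0 = c0[b], M = M,
                         foreground_fraction = fgfrac, variance = wvar),
                    class = "subwindow")
        if (length(accepted) == N) break
      }
    }
  })
  if (length(accepted) < N)
    stop(sprintf(paste0("sampling exhausted: %d/%d windows accepted after ",
                        "%d proposals (acceptance rate %.4f)"),
                 length(accepted), N, tried, length(accepted) / tried))
  structure(list(windows = accepted, M = M, seed = seed,
                 acceptance_rate = N / tried),
            class = "subwindow_set")
}

# summed-area table with a zero top row / left column
cumsum2d <- function(X) {
  S <- apply(apply(X, 2, cumsum), 1, cumsum)  # t(cumsum rows) of colsums
  rbind(0, cbind(0, t(S)))
}

# sum of X over the half-open window [r0, r0+M) x [c0, c0+M), 0-based
box_sum <- function(S, r0, c0, M) {
  S[r0 + M + 1L, c0 + M + 1L] - S[r0 + 1L, c0 + M + 1L] -
    S[r0 + M + 1L, c0 + 1L] + S[r0 + 1L, c0 + 1L]
}

# uniform top-left proposals, exposed for distributional checks
draw_proposals <- function(n, dims, M, seed) {
  with_seed(seed, {
    list(row0 = sample.int(dims[1] - M + 1L, n, replace = TRUE) - 1L,
         col0 = sample.int(dims[2] - M + 1L, n, replace = TRUE) - 1L)
  })
}

#' @export
print.subwindow_set <- function(x, ...) {
  cat("Subwindow set: ", length(x$windows), " windows of side ", x$M,
      sprintf(" (seed %d, acceptance rate %.3f)\n", x$seed,
              x$acceptance_rate), sep = "")
  invisible(x)
}
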