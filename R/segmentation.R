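#' Two-component Gaussian mixture fit by EM
#'
#' Models the pixel intensity histogram as a mixture of two Gaussians --
#' background (low variance) and foreground (high variance, since cell
#' regions contain values both above and below the background level) --
#' and fits it with expectation-maximization.  Initialization splits the
#' sample at its median, with equal weights; the log-likelihood is
#' non-decreasing across iterations and the fit stops when the improvement
#' drops below `tol` or after `max_iter` iterations.  Images larger than
#' `subsample` pixels are subsampled (seeded) before fitting.
#'
#' @param img Numeric matrix of intensities.
#' @param seed Integer seed, used only when subsampling kicks in.
#' @param tol Log-likelihood convergence tolerance, default 1e-6.
#' @param max_iter Iteration cap, default 200.
#' @param subsample Pixel budget for fitting, default 1e6.
#' @return Object of class `gmm2`: `weights`, `means`, `variances` (all
#'   length 2), `log_likelihood` (per-iteration vector), `n_iterations`.
#' @export
fit_gmm2 <- function(img, seed = 1L, tol = 1e-6, max_iter = 200L,
                     subsample = 1e6) {
  stopifnot(is.matrix(img))
  x <- as.vector(img)
  if (length(unique(x)) < 2L)
    stop("degenerate input: fewer than 2 distinct intensity values")
  if (length(x) > subsample)
    x <- with_seed(seed, sample(x, subsample))
  med <- stats::median(x)
  lo <- x[x <= med]; hi <- x[x > med]
  if (length(hi) == 0L) { hi <- max(x); lo <- x[x < max(x)] }
  vfloor <- 1e-8
  w <- c(0.5, 0.5)
  mu <- c(mean(lo), mean(hi))
  v <- pmax(c(stats::var(lo), stats::var(hi)), vfloor)
  if (!is.finite(v[1])) v[1] <- vfloor
  if (!is.finite(v[2])) v[2] <- vfloor
  ll <- numeric(0)
  for (it in seq_len(max_iter)) {
    # E step in log space for numerical safety
    l1 <- log(w[1]) + stats::dnorm(x, mu[1], sqrt(v[1]), log = TRUE)
    l2 <- log(w[2]) + stats::dnorm(x, mu[2], sqrt(v[2]), log = TRUE)
    m <- pmax(l1, l2)
    den <- m + log(exp(l1 - m) + exp(l2 - m))
    ll <- c(ll, sum(den))
    g1 <- exp(l1 - den)
    # M step
    n1 <- sum(g1); n2 <- length(x) - n1
    w <- c(n1, n2) / length(x)
    mu <- c(sum(g1 * x) / n1, sum((1 - g1) * x) / n2)
    v <- pmax(c(sum(g1 * (x - mu[1])^2) / n1,
                sum((1 - g1) * (x - mu[2])^2) / n2), vfloor)
    if (it > 1L && ll[it] - ll[it - 1L] < tol) break
  }
  structure(list(weights = w, means = mu, variances = v,
                 log_likelihood = ll, n_iterations = length(ll)),
            class = "gmm2")
}

#' @export
print.gmm2 <- function(x, ...) {
  cat("Two-component Gaussian mixture (EM,", x$n_iterations, "iterations)\n")
  cat(sprintf("  comp %d: weight %.3f, mean %.4f, sd %.4f\n",
              1:2, x$weights, x$means, sqrt(x$variances)), sep = "")
  invisible(x)
}

#' Foreground mask from a fitted mixture
#'
#' Assigns every pixel to the component with the higher posterior; the
#' higher-variance component is labelled foreground (cells spread both
#' above and below the background level, so the foreground is the wide
#' component, not the bright one).  On an exact posterior tie, or when the
#' variances tie, the lower-index component is treated as background.
#'
#' @param img Numeric matrix.
#' @param gmm A fitted `gmm2`.
#' @return Object of class `fg_mask`: logical matrix `mask` plus
#'   `foreground_fraction`.
#' @export
segment_foreground <- function(img, gmm) {
  stopifnot(is.matrix(img), inherits(gmm, "gmm2"))
  fg <- if (gmm$variances[2] >= gmm$variances[1]) 2L else 1L
  bg <- 3L - fg
  lf <- log(gmm$weights[fg]) +
    stats::dnorm(img, gmm$means[fg], sqrt(gmm$variances[fg]), log = TRUE)
  lb <- log(gmm$weights[bg]) +
    stats::dnorm(img, gmm$means[bg], sqrt(gmm$variances[bg]), log = TRUE)
  m <- lf > lb  # ties go to background
  new_fg_mask(m)
}

new_fg_mask <- function(m) {
  structure(list(mask = m, foreground_fraction = mean(m)),
            class = "fg_mask")
}

#' Morphological refinement of a foreground mask
#'
#' Binary closing with a square structuring element (fills thin gaps and
#' holes inside cells), followed by median filtering (removes speckle).
#'
#' @param mask An `fg_mask`.
#' @param closing_k,median_k Odd kernel sizes in pixels (defaults 5, 9).
#' @return The refined `fg_mask`.
#' @export
refine_mask <- function(mask, closing_k = 5L, median_k = 9L) {
  stopifnot(inherits(mask, "fg_mask"))
  if (closing_k %% 2L == 0L || median_k %% 2L == 0L)
    stop("kernel sizes must be odd")
  m <- mask$mask * 1
  img <- EBImage::Image(t(m))     # EBImage stores x (= columns) first
  if (closing_k > 1L)
    img <- EBImage::closing(img, EBImage::makeBrush(closing_k, "box"))
  if (median_k > 1L)
    img <- EBImage::medianFilter(img, (median_k - 1L) %/% 2L)
  new_fg_mask(t(EBImage::imageData(img)) > 0.5)
}

#' Select refinement kernels by segmentation quality
#'
#' Scores each candidate (closing, median) kernel pair by an explicit
#' uniformity/contrast criterion on the refined mask: the absolute
#' foreground-background mean difference normalized by the pooled standard
#' deviation, minus `lambda` times the within-region variance fraction.
#' Candidates yielding an empty foreground or background are skipped;
#' ties keep the earliest candidate.
#'
#' @param img Numeric matrix.
#' @param mask The unrefined `fg_mask`.
#' @param candidates List of `c(closing_k, median_k)` pairs; default the
#'   grid {3,5,7} x {5,9,15}.
#' @param lambda Weight of the uniformity penalty, default 1.
#' @return List with `closing_k`, `median_k`, `score`, and the refined
#'   `mask`.
#' @export
select_kernels <- function(img, mask,
                           candidates = default_kernel_candidates(),
                           lambda = 1) {
  stopifnot(is.matrix(img), inherits(mask, "fg_mask"),
            length(candidates) >= 1L)
  best <- NULL
  for (cand in candidates) {
    ref <- refine_mask(mask, cand[1], cand[2])
    sc <- segmentation_score(img, ref$mask, lambda)
    if (is.na(sc)) next
    if (is.null(best) || sc > best$score + 1e-12)
      best <- list(closing_k = cand[1], median_k = cand[2],
                   score = sc, mask = ref)
  }
  if (is.null(best))
    stop("every candidate produced an empty foreground or background")
  best
}

default_kernel_candidates <- function() {
  out <- list()
  for (ck in c(3L, 5L, 7L)) for (mk in c(5L, 9L, 15L))
    out[[length(out) + 1L]] <- c(ck, mk)
  out
}

# contrast minus lambda * within-region variance fraction; NA when one
# region is empty
segmentation_score <- function(img, m, lambda = 1) {
  nf <- sum(m); nb <- length(m) - nf
  if (nf == 0L || nb == 0L) return(NA_real_)
  f <- img[m]; b <- img[!m]
  vf <- if (nf > 1L) stats::var(f) else 0
  vb <- if (nb > 1L) stats::var(b) else 0
  pooled <- (nf * vf + nb * vb) / (nf + nb)
  vt <- stats::var(as.vector(img))
  contrast <- abs(mean(f) - mean(b)) / sqrt(max(pooled, 1e-12))
  contrast - lambda * pooled / max(vt, 1e-12)
}

#' Downsample a mask to the averaged-image grid
#'
#' Reduces a full-resolution mask by 4 in each direction with a majority
#' vote: an averaged-grid cell is foreground when at least half of its
#' 4 x 4 block is.  Edge blocks of images whose size is not a multiple of
#' 4 are padded by replication.
#'
#' @param mask An `fg_mask` at full resolution.
#' @param dim_out Target dimensions, normally `ceiling(dim(img)/4)`.
#' @return An `fg_mask` on the averaged grid.
#' @export
downsample_mask <- function(mask, dim_out = ceiling(dim(mask$mask) / 4)) {
  m <- mask$mask
  H <- 4L * dim_out[1]; W <- 4L * dim_out[2]
  ri <- pmin(seq_len(H), nrow(m)); ci <- pmin(seq_len(W), ncol(m))
  mp <- m[ri, ci, drop = FALSE] * 1
  block <- matrix(0, dim_out[1], dim_out[2])
  for (i in 0:3) for (j in 0:3)
    block <- block + mp[seq(1L + i, H, by = 4L), seq(1L + j, W, by = 4L)]
  new_fg_mask(block >= 8)
}

#' @export
print.fg_mask <- function(x, ...) {
  cat("Foreground mask ", nrow(x$mask), "x", ncol(x$mask),
      sprintf(", %.1f%% foreground\n", 100 * x$foreground_fraction),
      sep = "")
  invisible(x)
}
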