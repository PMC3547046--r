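# Shared fixtures and independent oracles.  Oracles are deliberately
# naive (double loops, no vectorization) so they stay independent of the
# implementation paths they check.

# sinusoidal grating whose stripes run along theta (degrees; x = columns,
# y = -rows)
make_grating <- function(theta_deg, freq, n = 128, amp = 0.4, mid = 0.5) {
  th <- theta_deg * pi / 180
  r <- matrix(0:(n - 1), n, n)
  cc <- matrix(0:(n - 1), n, n, byrow = TRUE)
  mid + amp * sin(2 * pi * freq * (-cc * sin(th) - r * cos(th)))
}

# f(row, col) = col (a horizontal ramp)
make_col_ramp <- function(n = 32) matrix(rep(seq_len(n), each = n), n, n,
                                         byrow = FALSE)

# brute-force directional score at a single pixel: loop over rings,
# mirror-extending indices by reflection
oracle_directional_score <- function(img, row, col, alpha_deg, L,
                                     aggregator) {
  # symmetric extension with the edge sample duplicated, matching the
  # documented boundary rule
  reflect <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  a <- alpha_deg * pi / 180
  d <- numeric(L)
  for (k in seq_len(L)) {
    r2 <- reflect(row - round(k * sin(a)), nrow(img))
    c2 <- reflect(col + round(k * cos(a)), ncol(img))
    d[k] <- img[row, col] - img[r2, c2]
  }
  switch(aggregator, median = median(d), max = max(d), mean = mean(d))
}

oracle_score_plane <- function(img, alpha_deg, L, aggregator) {
  out <- img * 0
  for (i in seq_len(nrow(img)))
    for (j in seq_len(ncol(img)))
      out[i, j] <- oracle_directional_score(img, i, j, alpha_deg, L,
                                            aggregator)
  out
}

# naive per-pixel covariance accumulation over a window (0-based corner);
# rectangular regions allowed so tiny hand cases can use it too
oracle_region_cov <- function(planes, row0, col0, M, Mc = M) {
  d <- length(planes)
  n <- M * Mc
  Z <- matrix(0, n, d)
  k <- 0
  for (i in (row0 + 1):(row0 + M))
    for (j in (col0 + 1):(col0 + Mc)) {
      k <- k + 1
      for (f in seq_len(d)) Z[k, f] <- planes[[f]][i, j]
    }
  mu <- colSums(Z) / n
  C <- matrix(0, d, d)
  for (k in seq_len(n)) C <- C + tcrossprod(Z[k, ] - mu)
  C / (n - 1)
}

# rebuild a symmetric matrix from its row-major upper triangle
unvectorize <- function(v, d) {
  M <- matrix(0, d, d)
  k <- 0
  for (i in seq_len(d)) for (j in i:d) {
    k <- k + 1
    M[i, j] <- v[k]; M[j, i] <- v[k]
  }
  M
}

# random feature map for descriptor tests
random_feature_map <- function(d = 5, n = 16, seed = 1) {
  set.seed(seed)
  planes <- lapply(seq_len(d), function(i) matrix(rnorm(n * n), n, n))
  fm <- cellcov::feature_map(planes[[1]], mapping = "F4")
  fm$planes <- planes
  fm$d <- d
  fm
}

# single-tree critically sampled real DWT with the same (matched) filters:
# the shift-variance baseline for the dual-tree comparison
single_tree_mags <- function(img, fb = dt_filter_bank()) {
  l1 <- cellcov:::separable_level(img, fb$level1[[1]], fb$level1[[1]])
  l2 <- cellcov:::separable_level(l1$ll, fb$level2[[1]], fb$level2[[1]])
  lapply(l2[c("lh", "hl", "hh")], abs)
}

stack_l2 <- function(lst) sqrt(sum(vapply(lst, function(m) sum(m^2),
                                          numeric(1))))

rel_field_change <- function(a, b) {
  stack_l2(Map(`-`, a, b)) / stack_l2(a)
}

write_tmp_png <- function(img, name = "img.png") {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()),
                    name)
  png::writePNG(img, path)
  path
}

# balanced toy manifest data frame (no files on disk)
toy_manifest <- function(n_class = 3, k = 4) {
  labs <- rep(LETTERS[seq_len(n_class)], each = k)
  cellcov:::as_manifest(data.frame(
    path = sprintf("%s_%d.png", labs, sequence(rep(k, n_class))),
    label = labs, magnification = "20x", stringsAsFactors = FALSE))
}
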