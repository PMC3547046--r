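test_that("feature maps have the documented composition", {
  img <- make_grating(45, 0.18, 64)
  avg <- average_intensity(img)
  mags <- subband_magnitudes(dtcwt2d(img), 2)
  med <- directional_scores(avg, 5, "median")
  fm <- feature_map(avg, mags, med, "F1")
  expect_equal(fm$d, 15)                    # 1 + 6 + 8
  expect_identical(fm$planes[[1]], avg)
  expect_identical(fm$planes[[3]], mags[[2]])
  expect_identical(fm$planes[[8]], med[[1]])
  # aggregator / mapping mismatch is refused
  expect_error(feature_map(avg, mags, med, "F2"), "max")
  expect_error(feature_map(avg, mags, directional_scores(avg, 5, "mean"),
                           "F1"), "median")

  f4 <- feature_map(matrix(0.3, 16, 16), mapping = "F4")
  expect_equal(f4$d, 5)
  for (k in 2:5) expect_true(all(f4$planes[[k]] == 0))
  ramp <- make_col_ramp(16)
  f4r <- feature_map(ramp, mapping = "F4")
  core <- 3:14
  expect_true(all(f4r$planes[[2]][core, core] == 1))  # |d/dcol| of ramp
  expect_true(all(f4r$planes[[4]][core, core] == 0))  # |d2/dcol2|
})

test_that("region covariance matches the naive accumulation oracle", {
  # hand case: two distinct feature vectors (0,0) and (2,2), divisor n-1
  toy <- list(matrix(c(0, 2), 1, 2), matrix(c(0, 2), 1, 2))
  expect_equal(oracle_region_cov(toy, 0, 0, M = 1, Mc = 2),
               matrix(2, 2, 2), tolerance = 1e-14, ignore_attr = TRUE)

  set.seed(42)
  for (rep in 1:50) {
    fm <- random_feature_map(d = 5, n = 16, seed = rep)
    r0 <- sample(0:8, 1); c0 <- sample(0:8, 1)
    cd <- region_covariance(fm, list(row0 = r0, col0 = c0, M = 8))
    expect_lt(max(abs(cd$matrix - oracle_region_cov(fm$planes, r0, c0, 8))),
              1e-10)
    ev <- eigen(cd$matrix, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)  # positive semidefinite
  }

  fm <- random_feature_map()
  expect_error(region_covariance(fm, list(row0 = 12, col0 = 0, M = 8)),
               "outside")
  # constant features give the zero matrix
  cfm <- fm; cfm$planes <- lapply(cfm$planes, function(p) p * 0 + 2)
  z <- region_covariance(cfm, list(row0 = 0, col0 = 0, M = 4))
  expect_true(all(z$matrix == 0))
})

test_that("covariance is invariant to constant feature offsets", {
  fm <- random_feature_map(d = 4, n = 16, seed = 9)
  fm2 <- fm
  fm2$planes[[2]] <- fm2$planes[[2]] + 7.3
  w <- list(row0 = 2, col0 = 3, M = 10)
  expect_lt(max(abs(region_covariance(fm, w)$matrix -
                    region_covariance(fm2, w)$matrix)), 1e-10)
})

test_that("normalization yields correlations and keeps variances", {
  # perfectly correlated planes
  fm <- random_feature_map(d = 2, n = 8, seed = 2)
  fm$planes[[2]] <- 3 * fm$planes[[1]]
  cd <- normalize_covariance(region_covariance(fm,
                                               list(row0 = 0, col0 = 0,
                                                    M = 8)))
  expect_equal(cd$matrix[1, 2], 1, tolerance = 1e-12)

  z <- structure(list(matrix = matrix(0, 3, 3), normalized = FALSE,
                      mapping = "F1", window = NULL),
                 class = "cov_descriptor")
  expect_true(all(normalize_covariance(z)$matrix == 0))

  set.seed(31)
  for (rep in 1:100) {
    fm <- random_feature_map(d = 6, n = 12, seed = 100 + rep)
    w <- list(row0 = sample(0:4, 1), col0 = sample(0:4, 1), M = 8)
    cd <- region_covariance(fm, w)
    nc <- normalize_covariance(cd)
    off <- nc$matrix[upper.tri(nc$matrix)]
    expect_true(all(off >= -1 - 1e-12 & off <= 1 + 1e-12))
    expect_equal(diag(nc$matrix), diag(cd$matrix))
  }
  expect_error(normalize_covariance(nc), "already")
})

test_that("normalized off-diagonals ignore positive feature rescaling", {
  fm <- random_feature_map(d = 5, n = 16, seed = 77)
  fm2 <- fm
  fm2$planes[[3]] <- 0.02 * fm2$planes[[3]]
  fm2$planes[[5]] <- 40 * fm2$planes[[5]]
  w <- list(row0 = 1, col0 = 2, M = 12)
  a <- normalize_covariance(region_covariance(fm, w))$matrix
  b <- normalize_covariance(region_covariance(fm2, w))$matrix
  diag(a) <- diag(b) <- 0
  expect_lt(max(abs(a - b)), 1e-10)
})

test_that("vectorization is the row-major upper triangle and invertible", {
  M <- matrix(c(1, 2, 2, 5), 2)
  cd <- structure(list(matrix = M, normalized = FALSE, mapping = "F4",
                       window = NULL), class = "cov_descriptor")
  expect_equal(as.numeric(vectorize_descriptor(cd)), c(1, 2, 5))

  fm <- random_feature_map(d = 15, n = 16, seed = 4)
  cd15 <- region_covariance(fm, list(row0 = 0, col0 = 0, M = 12))
  v <- vectorize_descriptor(cd15)
  expect_length(v, 120)
  expect_equal(unvectorize(as.numeric(v), 15), cd15$matrix)

  bad <- cd
  bad$matrix[1, 2] <- 99
  expect_error(vectorize_descriptor(bad), "symmetric")
})

test_that("diagonal descriptors read off the variances", {
  cd <- structure(list(matrix = diag(1:15), normalized = TRUE,
                       mapping = "F1", window = NULL),
                  class = "cov_descriptor")
  expect_equal(as.numeric(diagonal_descriptor(cd)), 1:15)
  z <- structure(list(matrix = matrix(0, 4, 4), normalized = FALSE,
                      mapping = "F4", window = NULL),
                 class = "cov_descriptor")
  expect_equal(as.numeric(diagonal_descriptor(z)), rep(0, 4))
})
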