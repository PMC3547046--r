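# small synthetic setup shared by the classification tests
small_setup <- function(n_images = 2, seed = 3) {
  spec <- synthetic_spec(n_images = n_images, image_size = 128, seed = seed)
  dir <- file.path(tempdir(), sprintf("cellcov-small-%d-%d", n_images, seed))
  man <- if (file.exists(file.path(dir, "manifest.csv")))
    load_manifest(file.path(dir, "manifest.csv"))
  else synthetic_dataset(spec, dir)
  cfg <- cellcov_config(window_size = 16, n_windows = 6, seed = 1)
  list(man = man, cfg = cfg)
}

test_that("image signatures have N x d(d+1)/2 bookkeeping and determinism", {
  s <- small_setup()
  img <- load_image(file.path(s$man$base_dir, s$man$entries$path[1]))
  sig <- image_signature(img, s$cfg, seed = 2)
  expect_equal(dim(sig), c(6, 120))
  expect_identical(sig, image_signature(img, s$cfg, seed = 2))

  cfg4 <- cellcov_config(window_size = 16, n_windows = 6, mapping = "F4")
  expect_equal(dim(image_signature(img, cfg4, seed = 2)), c(6, 15))

  cfgd <- cellcov_config(window_size = 16, n_windows = 6,
                         diagonal_only = TRUE)
  expect_equal(dim(image_signature(img, cfgd, seed = 2)), c(6, 15))
})

test_that("the SVM separates separable clusters and is deterministic", {
  set.seed(21)
  x <- rbind(matrix(rnorm(100 * 4, 0), ncol = 4),
             matrix(rnorm(100 * 4, 3), ncol = 4))
  y <- rep(c("a", "b"), each = 100)
  m <- cellcov_train(x, y)
  pred <- predict(m$svm, scale(x, m$center, m$scale))
  expect_equal(mean(pred == y), 1)
  m2 <- cellcov_train(x, y)
  probe <- matrix(rnorm(50 * 4, 1.5), ncol = 4)
  expect_identical(predict(m$svm, scale(probe, m$center, m$scale)),
                   predict(m2$svm, scale(probe, m2$center, m2$scale)))
  expect_error(cellcov_train(x, rep("a", 200)), "2 classes")
  xna <- x; xna[1, 1] <- NA
  expect_error(cellcov_train(xna, y), "NA")
})

test_that("random labels give chance-level held-out accuracy", {
  set.seed(8)
  accs <- replicate(20, {
    x <- matrix(rnorm(120 * 6), ncol = 6)
    y <- sample(rep(c("a", "b"), each = 60))
    m <- cellcov_train(x[1:80, ], y[1:80])
    mean(as.character(predict(m$svm,
                              scale(x[81:120, ], m$center,
                                    m$scale))) == y[81:120])
  })
  expect_equal(mean(accs), 0.5, tolerance = 0.1)
})

test_that("majority voting and margin tie-breaks label images", {
  set.seed(5)
  x <- rbind(matrix(rnorm(60 * 4, 0), ncol = 4),
             matrix(rnorm(60 * 4, 3), ncol = 4))
  y <- rep(c("a", "b"), each = 60)
  m <- cellcov_train(x, y)

  sig_a <- matrix(rnorm(8 * 4, 0), ncol = 4)
  pa <- predict_image(m, sig_a)
  expect_equal(pa$label, "a")
  expect_equal(as.integer(pa$votes["a"]), 8)
  expect_equal(sum(pa$votes), 8)

  # forced 2-2 vote tie: winner must match the summed decision margins
  sig_t <- rbind(matrix(rnorm(2 * 4, 0), ncol = 4),
                 matrix(rnorm(2 * 4, 3), ncol = 4))
  pt <- predict_image(m, sig_t)
  expect_equal(sum(pt$votes), 4)
  if (max(pt$votes) == 2) {
    top <- names(pt$votes)[pt$votes == 2]
    expect_equal(pt$label, top[which.max(pt$margins[top])])
  }
  expect_error(predict_image(m, sig_a[0, , drop = FALSE]), "empty")
  expect_error(predict_image(m, matrix(0, 2, 7)), "length")
})

test_that("fold plans are leave-one-image-per-class partitions", {
  man <- toy_manifest(14, 20)
  plan <- fold_plan(man)
  expect_equal(plan$n_folds, 20)
  expect_true(all(vapply(plan$folds, function(f) length(f$test),
                         integer(1)) == 14))
  # disjoint and covering
  all_test <- sort(unlist(lapply(plan$folds, `[[`, "test")))
  expect_equal(unname(all_test), seq_len(280))
  for (f in plan$folds) {
    expect_length(intersect(f$test, f$train), 0)
    expect_equal(length(unique(man$entries$label[f$test])), 14)
  }
  plan2 <- fold_plan(toy_manifest(2, 2))
  expect_equal(plan2$n_folds, 2)

  unb <- man
  unb$entries <- unb$entries[-1, ]
  expect_error(fold_plan(unb), "unbalanced")
})

test_that("cross-validation never leaks test vectors into training", {
  s <- small_setup()
  cv <- cellcov_crossval(s$man, s$cfg)
  expect_equal(cv$mean_accuracy, mean(cv$per_fold_accuracy),
               tolerance = 1e-12)
  expect_equal(sum(cv$confusion), nrow(s$man$entries))

  # instrument the standardization: train-fold statistics only
  sigs <- lapply(seq_len(nrow(s$man$entries)), function(i) {
    p <- file.path(s$man$base_dir, s$man$entries$path[i])
    image_signature(load_image(p), s$cfg,
                    seed = cellcov:::derive_seed(s$cfg$seed, i))
  })
  plan <- fold_plan(s$man)
  f <- plan$folds[[1]]
  xtr <- do.call(rbind, sigs[f$train])
  m <- cellcov_train(xtr, rep(s$man$entries$label[f$train],
                              each = s$cfg$n_windows))
  expect_equal(m$center, colMeans(xtr))
  xall <- do.call(rbind, sigs)
  expect_false(isTRUE(all.equal(m$center, colMeans(xall))))

  # label renaming leaves accuracies untouched
  ren <- s$man
  ren$entries$label <- chartr("ABCD", "WXYZ",
                              toupper(substr(ren$entries$label, 5, 5)))
  cv2 <- cellcov_crossval(ren, s$cfg, signatures = sigs)
  cv1 <- cellcov_crossval(s$man, s$cfg, signatures = sigs)
  expect_equal(cv2$per_fold_accuracy, cv1$per_fold_accuracy)
  expect_identical(cv1$per_fold_accuracy, cv$per_fold_accuracy)
})

test_that("trained models survive a save/load round trip", {
  set.seed(2)
  x <- rbind(matrix(rnorm(40 * 3, 0), ncol = 3),
             matrix(rnorm(40 * 3, 2.5), ncol = 3))
  m <- cellcov_train(x, rep(c("u", "v"), each = 40),
                     cfg = cellcov_config())
  f <- file.path(withr::local_tempdir(), "model.rds")
  save_model(m, f)
  m2 <- load_model(f)
  sig <- matrix(rnorm(4 * 3), ncol = 3)
  expect_identical(predict_image(m, sig)$label,
                   predict_image(m2, sig)$label)
})
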