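#' Extract the descriptor signature of one image
#'
#' Runs the full per-image feature pipeline: dual-tree decomposition and
#' subband magnitudes, quarter-resolution averaging, EM foreground
#' segmentation with morphological refinement, constrained random
#' subwindow sampling, and one vectorized (normalized) covariance
#' descriptor per subwindow.
#'
#' @param img Grayscale intensity matrix from [load_image()].
#' @param cfg A [cellcov_config()].
#' @param seed Seed for segmentation subsampling and window sampling;
#'   defaults to `cfg$seed`.
#' @return Numeric matrix with `cfg$n_windows` rows (one descriptor
#'   vector per subwindow) and attribute `windows`.
#' @export
image_signature <- function(img, cfg = cellcov_config(), seed = cfg$seed) {
  stopifnot(is.matrix(img), inherits(cfg, "cellcov_config"))
  fb <- dt_filter_bank(cfg$filter_set)
  avg <- average_intensity(img, fb)

  gmm <- fit_gmm2(img, seed = seed)
  raw <- segment_foreground(img, gmm)
  refined <- if (cfg$select_kernels)
    select_kernels(img, raw)$mask
  else refine_mask(raw, cfg$closing_k, cfg$median_k)
  maskq <- downsample_mask(refined, dim(avg))

  if (cfg$mapping == "F4") {
    fm <- feature_map(avg, mapping = "F4")
  } else {
    pyr <- dtcwt2d(img, cfg$levels, fb)
    mags <- subband_magnitudes(pyr, cfg$levels)
    agg <- c(F1 = "median", F2 = "max", F3 = "mean")[[cfg$mapping]]
    sc <- directional_scores(avg, L = cfg$radius, aggregator = agg)
    fm <- feature_map(avg, mags, sc, mapping = cfg$mapping)
  }

  sw <- sample_subwindows(avg, maskq, M = cfg$window_size,
                          N = cfg$n_windows, seed = seed)
  vecs <- lapply(sw$windows, function(w) {
    cd <- region_covariance(fm, w)
    if (cfg$normalized) cd <- normalize_covariance(cd)
    if (cfg$diagonal_only) diagonal_descriptor(cd)
    else vectorize_descriptor(cd)
  })
  sig <- do.call(rbind, vecs)
  attr(sig, "windows") <- sw$windows
  sig
}

#' Train the subwindow SVM
#'
#' Fits a one-vs-one multiclass support vector machine with an RBF kernel
#' on descriptor vectors.  Vectors are standardized per dimension with
#' statistics computed from the training set only; the statistics travel
#' with the model so prediction applies the identical transform.
#'
#' @param x Numeric matrix of descriptor vectors (rows = subwindows).
#' @param labels Class label per row.
#' @param cost SVM cost C, default 10.
#' @param gamma RBF width; default `1 / ncol(x)`.
#' @param cfg Optional `cellcov_config` snapshot to embed.
#' @return Object of class `cellcov_model`.
#' @export
cellcov_train <- function(x, labels, cost = 10, gamma = NULL, cfg = NULL) {
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  if (anyNA(x)) stop("descriptor vectors contain NA")
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("training needs at least 2 classes")
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  xs <- scale(x, center = ctr, scale = scl)
  fit <- e1071::svm(xs, labels, type = "C-classification",
                    kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
  structure(list(svm = fit, center = ctr, scale = scl,
                 classes = levels(labels), cost = cost, gamma = gamma,
                 d = ncol(x), config = cfg),
            class = "cellcov_model")
}

#' Classify an image signature by majority voting
#'
#' Each subwindow descriptor is classified independently; the image takes
#' the modal label.  Vote ties are broken by the largest summed one-vs-one
#' decision margin, then lexicographically.
#'
#' @param model A `cellcov_model`.
#' @param signature Matrix from [image_signature()].
#' @return Object of class `cellcov_prediction`: `label`, `votes`
#'   (histogram over classes), `subwindow_labels`, `margins`.
#' @export
predict_image <- function(model, signature) {
  stopifnot(inherits(model, "cellcov_model"), is.matrix(signature))
  if (nrow(signature) == 0L) stop("empty signature")
  if (ncol(signature) != model$d)
    stop("descriptor length ", ncol(signature),
         " does not match the model (", model$d, ")")
  xs <- scale(signature, center = model$center, scale = model$scale)
  pred <- stats::predict(model$svm, xs, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  margins <- ovo_class_margins(dv, model$classes)
  votes <- table(factor(as.character(pred), levels = model$classes))
  top <- names(votes)[votes == max(votes)]
  label <- if (length(top) == 1L) top
  else {
    mt <- margins[top]
    cand <- names(mt)[mt == max(mt)]
    sort(cand)[1L]
  }
  structure(list(label = label, votes = votes,
                 subwindow_labels = as.character(pred), margins = margins),
            class = "cellcov_prediction")
}

# fold one-vs-one decision values ("A/B" columns, positive favours A)
# into per-class summed margins
ovo_class_margins <- function(dv, classes) {
  margins <- stats::setNames(numeric(length(classes)), classes)
  for (j in seq_len(ncol(dv))) {
    pair <- strsplit(colnames(dv)[j], "/", fixed = TRUE)[[1L]]
    s <- sum(dv[, j])
    margins[pair[1L]] <- margins[pair[1L]] + s
    margins[pair[2L]] <- margins[pair[2L]] - s
  }
  margins
}

#' @export
print.cellcov_prediction <- function(x, ...) {
  cat("Predicted label:", x$label, "\n")
  cat("Votes:", paste(names(x$votes), as.integer(x$votes), sep = ":",
                      collapse = " "), "\n")
  invisible(x)
}

#' Leave-one-image-per-class fold plan
#'
#' With K images per class, builds K disjoint folds; fold i tests on the
#' i-th image (in manifest order) of every class simultaneously and trains
#' on the rest.
#'
#' @param manifest A `dataset_manifest` with balanced classes.
#' @return Object of class `cv_fold_plan`: `folds` (each with `test` and
#'   `train` row indices into the manifest) and `n_folds`.
#' @export
fold_plan <- function(manifest) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  counts <- table(manifest$entries$label)
  if (length(unique(as.integer(counts))) != 1L)
    stop("unbalanced classes: ",
         paste(names(counts), as.integer(counts), sep = "=",
               collapse = ", "))
  K <- as.integer(counts[1L])
  if (K < 2L)
    stop("cross-validation needs at least 2 images per class, got ", K)
  by_class <- split(seq_len(nrow(manifest$entries)),
                    manifest$entries$label)
  folds <- lapply(seq_len(K), function(i) {
    test <- sort(vapply(by_class, `[[`, integer(1), i))
    list(test = test, train = setdiff(seq_len(nrow(manifest$entries)),
                                      test))
  })
  structure(list(folds = folds, n_folds = K), class = "cv_fold_plan")
}

#' Cross-validated image classification
#'
#' Runs the full protocol: one signature per image (seeded per image),
#' then for every fold of the leave-one-image-per-class plan an SVM is
#' trained on the training images' subwindow descriptors (standardization
#' statistics from the training fold only) and each test image is labelled
#' by majority vote over its subwindows.
#'
#' @param manifest A balanced `dataset_manifest`.
#' @param cfg A [cellcov_config()].
#' @param signatures Optional precomputed list of signatures (one per
#'   manifest row), e.g. to compare descriptor variants without redoing
#'   feature extraction.
#' @param verbose Print per-fold progress?
#' @return Object of class `cellcov_cv`: `per_fold_accuracy`,
#'   `mean_accuracy`, `confusion` (true x predicted), `predictions`,
#'   `config`.
#' @export
cellcov_crossval <- function(manifest, cfg = cellcov_config(),
                             signatures = NULL, verbose = FALSE) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  plan <- fold_plan(manifest)
  entries <- manifest$entries
  if (is.null(signatures)) {
    signatures <- lapply(seq_len(nrow(entries)), function(i) {
      p <- entries$path[i]
      if (!file.exists(p)) p <- file.path(manifest$base_dir, entries$path[i])
      image_signature(load_image(p), cfg, seed = derive_seed(cfg$seed, i))
    })
  }
  stopifnot(length(signatures) == nrow(entries))
  classes <- sort(unique(entries$label))
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(true = classes, predicted = classes))
  per_fold <- numeric(plan$n_folds)
  predictions <- character(nrow(entries))
  for (f in seq_len(plan$n_folds)) {
    fold <- plan$folds[[f]]
    xtr <- do.call(rbind, signatures[fold$train])
    ytr <- rep(entries$label[fold$train],
               vapply(signatures[fold$train], nrow, integer(1)))
    model <- cellcov_train(xtr, ytr, cost = cfg$svm_cost,
                           gamma = cfg$svm_gamma, cfg = cfg)
    ok <- logical(length(fold$test))
    for (t in seq_along(fold$test)) {
      i <- fold$test[t]
      pr <- predict_image(model, signatures[[i]])
      predictions[i] <- pr$label
      ok[t] <- pr$label == entries$label[i]
      confusion[entries$label[i], pr$label] <-
        confusion[entries$label[i], pr$label] + 1L
    }
    per_fold[f] <- mean(ok)
    if (verbose)
      message(sprintf("fold %2d/%d: accuracy %.3f", f, plan$n_folds,
                      per_fold[f]))
  }
  structure(list(per_fold_accuracy = per_fold,
                 mean_accuracy = mean(per_fold),
                 confusion = confusion,
                 predictions = predictions,
                 n_folds = plan$n_folds,
                 config = cfg),
            class = "cellcov_cv")
}

#' @export
print.cellcov_cv <- function(x, ...) {
  cat(sprintf(
    "%d-fold leave-one-image-per-class CV: mean image accuracy %.1f%%\n",
    x$n_folds, 100 * x$mean_accuracy))
  cat("Per-fold: ", paste(sprintf("%.2f", x$per_fold_accuracy),
                          collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.cellcov_cv <- function(object, ...) {
  print(object)
  cat("\nConfusion matrix (true x predicted):\n")
  print(object$confusion)
  cat("\n")
  print(object$config)
  invisible(object)
}

#' @export
plot.cellcov_cv <- function(x, ...) {
  cm <- x$confusion
  graphics::image(seq_len(ncol(cm)), seq_len(nrow(cm)),
                  t(cm[rev(seq_len(nrow(cm))), , drop = FALSE]),
                  axes = FALSE, xlab = "predicted", ylab = "true",
                  main = sprintf("Mean accuracy %.1f%%",
                                 100 * x$mean_accuracy), ...)
  graphics::axis(1, seq_len(ncol(cm)), colnames(cm), las = 2)
  graphics::axis(2, seq_len(nrow(cm)), rev(rownames(cm)), las = 1)
  graphics::box()
  invisible(x)
}

#' @export
print.cellcov_model <- function(x, ...) {
  cat("cellcov subwindow SVM (RBF): ", length(x$classes), " classes, d = ",
      x$d, ", C = ", x$cost, ", gamma = ", signif(x$gamma, 3), "\n",
      sep = "")
  cat("Support vectors:", nrow(x$svm$SV), "\n")
  invisible(x)
}

#' @export
summary.cellcov_model <- function(object, ...) {
  print(object)
  cat("Classes:", paste(object$classes, collapse = ", "), "\n")
  if (!is.null(object$config)) print(object$config)
  invisible(object)
}

#' Predict the class of images or signatures
#'
#' @param object A `cellcov_model`.
#' @param newdata A signature matrix, a list of signature matrices, or a
#'   grayscale image matrix to be processed with the embedded config.
#' @param seed Seed used when `newdata` is a raw image.
#' @param ... Unused.
#' @return A `cellcov_prediction` (or a list of them).
#' @export
predict.cellcov_model <- function(object, newdata, seed = NULL, ...) {
  if (is.list(newdata) && !is.data.frame(newdata))
    return(lapply(newdata, function(s) predict_image(object, s)))
  stopifnot(is.matrix(newdata))
  if (ncol(newdata) == object$d) return(predict_image(object, newdata))
  cfg <- object$config
  if (is.null(cfg)) stop("model carries no config; pass a signature matrix")
  sig <- image_signature(newdata, cfg,
                         seed = if (is.null(seed)) cfg$seed else seed)
  predict_image(object, sig)
}
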