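#' Load a microscopy image as a grayscale intensity matrix
#'
#' Reads PNG, JPEG or TIFF, converts color inputs to luma
#' (0.299 R + 0.587 G + 0.114 B) and rescales integer ranges so that
#' intensities lie in \[0, 1\].  Images smaller than 64 x 64 are rejected:
#' the two-level decomposition plus quarter-resolution windowing needs
#' room to work with.
#'
#' @param path File path.
#' @param min_size Minimum accepted side length, default 64.
#' @return Numeric matrix (rows x cols) of intensities in \[0, 1\].
#' @export
load_image <- function(path, min_size = 64L) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  img <- tryCatch(suppressWarnings(EBImage::readImage(path)),
                  error = function(e)
                    stop("cannot decode ", path, ": ", conditionMessage(e)))
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 3L) {
    nch <- dim(a)[3]
    a <- if (nch >= 3L)
      0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    else a[, , 1]
  }
  m <- t(a)  # EBImage stores x (columns) first
  m <- pmin(pmax(m, 0), 1)
  if (nrow(m) < min_size || ncol(m) < min_size)
    stop("image ", path, " is ", nrow(m), "x", ncol(m),
         "; at least ", min_size, "x", min_size, " required")
  m
}

#' Write a grayscale matrix as an 8-bit PNG
#'
#' @param img Matrix in \[0, 1\].
#' @param path Output path.
#' @export
write_gray_png <- function(img, path) {
  stopifnot(is.matrix(img))
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Load a dataset manifest
#'
#' Reads a CSV with columns `path`, `label`, `magnification` describing a
#' labelled image collection.  Paths must be unique, every class needs at
#' least two images (the cross-validation protocol cannot run otherwise),
#' and magnification must be one of 10x, 20x, 40x.
#'
#' @param path Manifest CSV path.
#' @param base_dir Optional directory against which relative image paths
#'   are resolved; defaults to the manifest's directory.
#' @return Object of class `dataset_manifest`: data frame `entries` plus
#'   `class_count`.
#' @export
load_manifest <- function(path, base_dir = dirname(path)) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("manifest is empty: ", path)
  need <- c("path", "label", "magnification")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "))
  as_manifest(df[need], base_dir = base_dir)
}

as_manifest <- function(df, base_dir = ".") {
  bad_mag <- setdiff(unique(df$magnification), c("10x", "20x", "40x"))
  if (length(bad_mag))
    stop("unknown magnification value(s): ", paste(bad_mag, collapse = ", "))
  if (anyDuplicated(df$path))
    stop("duplicate image path(s): ",
         paste(unique(df$path[duplicated(df$path)]), collapse = ", "))
  counts <- table(df$label)
  lone <- names(counts)[counts < 2L]
  if (length(lone))
    stop("class(es) with fewer than 2 images: ",
         paste(lone, collapse = ", "))
  structure(list(entries = df, class_count = length(counts),
                 base_dir = base_dir),
            class = "dataset_manifest")
}

#' Write a dataset manifest
#' @param manifest A `dataset_manifest`.
#' @param path Output CSV path.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  utils::write.csv(manifest$entries, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat("Dataset manifest: ", nrow(x$entries), " images, ",
      x$class_count, " classes\n", sep = "")
  print(table(x$entries$label))
  invisible(x)
}

#' Pipeline run configuration
#'
#' Collects every tunable of the classification pipeline.  `window_size`
#' and the sampling count live on the averaged (quarter-resolution) grid,
#' so the default 32 corresponds to roughly 128 pixels at full
#' resolution.
#'
#' @param levels Dual-tree decomposition depth (2).
#' @param radius Largest directional-difference ring, in pixels (5).
#' @param window_size Subwindow side on the averaged grid (32).
#' @param n_windows Subwindows per image (20).
#' @param mapping Feature mapping, `"F1"`..`"F4"`.
#' @param normalized Use correlation-normalized descriptors? (TRUE)
#' @param diagonal_only Feed only feature variances to the SVM? (FALSE)
#' @param svm_cost RBF-SVM cost C (10).
#' @param svm_gamma RBF width; `NULL` means 1/descriptor-length.
#' @param filter_set Q-shift coefficient set name.
#' @param closing_k,median_k Mask refinement kernels (5, 9).
#' @param select_kernels Pick kernels by segmentation score instead?
#'   (FALSE)
#' @param seed Base seed for all stochastic steps.
#' @return Object of class `cellcov_config` (a validated list).
#' @export
cellcov_config <- function(levels = 2L, radius = 5L, window_size = 32L,
                           n_windows = 20L,
                           mapping = c("F1", "F2", "F3", "F4"),
                           normalized = TRUE, diagonal_only = FALSE,
                           svm_cost = 10, svm_gamma = NULL,
                           filter_set = c("qshift14", "qshift10"),
                           closing_k = 5L, median_k = 9L,
                           select_kernels = FALSE, seed = 1L) {
  mapping <- match.arg(mapping)
  filter_set <- match.arg(filter_set)
  stopifnot(levels >= 1L, radius >= 1L, window_size >= 2L, n_windows >= 1L,
            svm_cost > 0, is.null(svm_gamma) || svm_gamma > 0)
  structure(list(levels = as.integer(levels), radius = as.integer(radius),
                 window_size = as.integer(window_size),
                 n_windows = as.integer(n_windows), mapping = mapping,
                 normalized = isTRUE(normalized),
                 diagonal_only = isTRUE(diagonal_only),
                 svm_cost = svm_cost, svm_gamma = svm_gamma,
                 filter_set = filter_set,
                 closing_k = as.integer(closing_k),
                 median_k = as.integer(median_k),
                 select_kernels = isTRUE(select_kernels),
                 seed = as.integer(seed)),
            class = "cellcov_config")
}

#' Read / write a flat key = value configuration file
#' @param path Config file path.
#' @return For `read_config`, a `cellcov_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  eq <- regexpr("=", lines, fixed = TRUE)
  if (any(eq < 1L)) stop("malformed config line(s): ",
                         paste(lines[eq < 1L], collapse = "; "))
  vals <- stats::setNames(trimws(substring(lines, eq + 1L)),
                          trimws(substr(lines, 1L, eq - 1L)))
  vals <- vals[nzchar(vals)]  # empty value means "use the default"
  args <- list()
  for (nm in names(vals)) {
    v <- vals[[nm]]
    args[[nm]] <- if (nm %in% c("mapping", "filter_set")) v
      else if (nm %in% c("normalized", "diagonal_only", "select_kernels"))
        toupper(v) %in% c("TRUE", "T", "1", "YES")
      else as.numeric(v)
  }
  if (!is.null(args$svm_gamma) && is.na(args$svm_gamma)) args$svm_gamma <- NULL
  do.call(cellcov_config, args)
}

#' @rdname read_config
#' @param cfg A `cellcov_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "cellcov_config"))
  vals <- unclass(cfg)
  vals$svm_gamma <- if (is.null(vals$svm_gamma)) "" else vals$svm_gamma
  writeLines(paste0(names(vals), " = ", unlist(vals)), path)
  invisible(path)
}

#' @export
print.cellcov_config <- function(x, ...) {
  cat("cellcov run configuration\n")
  cat("  mapping ", x$mapping,
      if (x$normalized) " (normalized)" else " (plain)",
      if (x$diagonal_only) ", diagonal only" else "", "\n", sep = "")
  cat("  levels ", x$levels, ", radius ", x$radius,
      ", windows ", x$n_windows, " x ", x$window_size, "^2 (avg grid)\n",
      sep = "")
  cat("  SVM C = ", x$svm_cost, ", gamma = ",
      if (is.null(x$svm_gamma)) "1/d" else x$svm_gamma,
      ", filters ", x$filter_set, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Persist / restore a trained model
#'
#' The model artifact embeds its `cellcov_config`, so a restored model
#' reproduces the exact feature pipeline it was trained with.
#'
#' @param model A `cellcov_model`.
#' @param path Destination file.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "cellcov_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "cellcov_model")) stop(path, " is not a cellcov model")
  m
}
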