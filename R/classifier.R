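# Supervised per-pixel tissue classification into the five classes:
# background, tumour positive, tumour negative, stroma, lymphocytes.
#
# The commercial pattern-recognition step this replaces is an
# undisclosed texture classifier; here each pixel carries colour
# (RGB), stain (deconvolved hematoxylin/DAB OD) and texture (windowed
# mean / SD / entropy of each OD channel) features, and a linear
# discriminant is fitted on class-balanced sampled pixels.

FEATURE_NAMES <- c("r", "g", "b", "h_od", "d_od",
                   "h_mean", "h_sd", "h_ent",
                   "d_mean", "d_sd", "d_ent")

#' Per-pixel colour, stain and texture features
#'
#' Computes, for every pixel: raw RGB (scaled to `[0, 1]`), deconvolved
#' hematoxylin and DAB OD, and the local mean, standard deviation and
#' entropy of each OD channel over a square window (edges reflected).
#'
#' @param image 8-bit RGB array.
#' @param window odd window side length in pixels, at least 3.
#' @return numeric matrix with one row per pixel (column-major pixel
#'   order) and `length(FEATURE_NAMES)` columns; attribute `dim_hw`
#'   records the raster size.
#' @export
extract_features <- function(image, window = 9L) {
  assert_rgb_image(image)
  window <- as.integer(window)
  if (is.na(window) || window < 3L || window %% 2L == 0L) {
    stop("`window` must be an odd integer >= 3", call. = FALSE)
  }
  r <- window %/% 2L
  od <- deconvolve_stains(image)
  h <- od$hematoxylin; d <- od$dab
  f <- cbind(
    r = as.vector(image[, , 1]) / 255,
    g = as.vector(image[, , 2]) / 255,
    b = as.vector(image[, , 3]) / 255,
    h_od = as.vector(h),
    d_od = as.vector(d),
    h_mean = as.vector(box_mean(h, r)),
    h_sd = as.vector(box_sd(h, r)),
    h_ent = as.vector(box_entropy(h, r)),
    d_mean = as.vector(box_mean(d, r)),
    d_sd = as.vector(box_sd(d, r)),
    d_ent = as.vector(box_entropy(d, r))
  )
  attr(f, "dim_hw") <- dim(image)[1:2]
  f
}

#' Train the five-class per-pixel tissue classifier
#'
#' Samples annotated pixels balanced across classes (the majority
#' class is down-sampled to the per-class budget) and fits a linear
#' discriminant on the feature stack. Training is deterministic given
#' the seed.
#'
#' @param images list of 8-bit RGB arrays.
#' @param annotations list of label masks (integer matrices over the
#'   five class codes) or generator `truth` lists with a `class_mask`.
#' @param window feature window (odd, >= 3).
#' @param n_per_class pixel budget per class (default 2000).
#' @param seed sampling seed.
#' @return a `classifier_model`.
#' @export
train_classifier <- function(images, annotations, window = 9L,
                             n_per_class = 2000L, seed = 1L) {
  if (length(images) != length(annotations) || length(images) == 0L) {
    stop("`images` and `annotations` must be non-empty lists of equal length",
         call. = FALSE)
  }
  masks <- lapply(annotations, function(a) {
    if (is.list(a) && !is.null(a$class_mask)) a$class_mask else a
  })
  present <- sort(unique(unlist(lapply(masks, function(m) unique(as.vector(m))))))
  missing <- setdiff(TISSUE_LABELS, present)
  if (length(missing) > 0L) {
    stop("annotations are missing class(es): ",
         paste(TISSUE_CLASS_NAMES[match(missing, TISSUE_LABELS)],
               collapse = ", "),
         call. = FALSE)
  }
  feats <- lapply(images, extract_features, window = window)
  X <- do.call(rbind, feats)
  y <- unlist(lapply(masks, as.vector))
  sel <- with_seed(seed, {
    unlist(lapply(TISSUE_LABELS, function(cl) {
      idx <- which(y == cl)
      if (length(idx) > n_per_class) sort(sample(idx, n_per_class)) else idx
    }))
  })
  fit <- MASS::lda(x = X[sel, , drop = FALSE],
                   grouping = factor(y[sel], levels = TISSUE_LABELS))
  structure(list(
    fit = fit,
    window = as.integer(window),
    feature_names = FEATURE_NAMES,
    n_train = table(factor(y[sel], levels = TISSUE_LABELS)),
    seed = as.integer(seed)
  ), class = "classifier_model")
}

#' @export
print.classifier_model <- function(x, ...) {
  cat("Per-pixel tissue classifier (LDA),", length(x$feature_names),
      "features, window", x$window, "\n")
  cat("Training pixels per class:",
      paste(sprintf("%s=%d", TISSUE_CLASS_NAMES, as.integer(x$n_train)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Classify every pixel of a core image
#'
#' @param image 8-bit RGB array.
#' @param model a [train_classifier()] model.
#' @return a `tissue_map`: integer `labels` matrix plus per-class pixel
#'   `counts`. Posterior ties are broken toward the lowest class label.
#' @export
classify_tissue <- function(image, model) {
  if (!inherits(model, "classifier_model")) {
    stop("`model` must be a trained classifier_model", call. = FALSE)
  }
  f <- extract_features(image, model$window)
  if (!identical(colnames(f), model$feature_names)) {
    stop("feature stack does not match the model's feature specification",
         call. = FALSE)
  }
  post <- stats::predict(model$fit, f)$posterior
  lab_idx <- max.col(post, ties.method = "first")
  labels <- matrix(TISSUE_LABELS[lab_idx], nrow = attr(f, "dim_hw")[1],
                   ncol = attr(f, "dim_hw")[2])
  counts <- tabulate(lab_idx, nbins = length(TISSUE_LABELS))
  names(counts) <- TISSUE_CLASS_NAMES
  structure(list(labels = labels, counts = counts), class = "tissue_map")
}

#' @export
print.tissue_map <- function(x, ...) {
  cat("Tissue map", nrow(x$labels), "x", ncol(x$labels), "px:\n")
  print(x$counts)
  invisible(x)
}

#' Pixel accuracy of a tissue map against ground truth
#'
#' @param predicted a `tissue_map` or label matrix.
#' @param truth a generator `truth` list or label matrix.
#' @return list with `accuracy` (matching pixels / total) and
#'   `confusion` (rows = truth, columns = prediction).
#' @export
evaluate_pixel_accuracy <- function(predicted, truth) {
  p <- tissue_labels_matrix(predicted)
  t_ <- if (is.list(truth) && !is.null(truth$class_mask)) truth$class_mask
        else truth
  if (!all(dim(p) == dim(t_))) {
    stop("predicted and truth dimensions differ", call. = FALSE)
  }
  lv <- TISSUE_LABELS
  confusion <- table(
    truth = factor(as.vector(t_), levels = lv, labels = TISSUE_CLASS_NAMES),
    predicted = factor(as.vector(p), levels = lv,
                       labels = TISSUE_CLASS_NAMES)
  )
  list(accuracy = sum(diag(confusion)) / sum(confusion),
       confusion = confusion)
}

#' Save / load a classifier model
#'
#' The model is serialized to a single portable file; a reloaded model
#' reproduces predictions exactly.
#'
#' @param model a `classifier_model`.
#' @param path file path.
#' @return `save_classifier` returns `path` invisibly;
#'   `load_classifier` returns the model.
#' @export
save_classifier <- function(model, path) {
  if (!inherits(model, "classifier_model")) {
    stop("`model` must be a classifier_model", call. = FALSE)
  }
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "classifier_model")) {
    stop("file does not contain a classifier_model", call. = FALSE)
  }
  model
}
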