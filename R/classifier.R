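#' Train a random-forest pixel classifier from sparse labels
#'
#' Supervised pixel classification in the spirit of interactive-learning
#' segmentation tools: the user supplies sparse labelled regions of two
#' classes (`entity` = BMU or pore, `background` = everything else) on one or
#' more training images; a 100-tree random forest is fitted on the multiscale
#' feature bank of [compute_feature_stack()]. At least 10 labelled regions
#' per class per training image are required.
#'
#' @param images list of [sem_image()] (or matrices): the training images.
#' @param labels data.frame with columns `image` (index into `images`),
#'   `region_id`, `class` (`"entity"` or `"background"`), `row`, `col`.
#' @param seed integer seed; training is deterministic given the seed.
#' @param n_trees number of trees (default 100).
#' @param scales feature scales, passed to [compute_feature_stack()].
#' @param min_regions minimum labelled regions per class per image
#'   (default 10).
#' @return object of class `pixel_classifier` with the fitted forest, the
#'   feature configuration, per-class label counts and the out-of-bag pixel
#'   accuracy (`oob_accuracy`).
#' @export
train_pixel_classifier <- function(images, labels, seed = 1L,
                                   n_trees = 100L,
                                   scales = c(0.7, 1.0, 1.6, 3.5, 5.0),
                                   min_regions = 10L) {
  if (inherits(images, "sem_image") || is.matrix(images)) images <- list(images)
  need <- c("image", "region_id", "class", "row", "col")
  if (!is.data.frame(labels) || !all(need %in% names(labels))) {
    stop("labels must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  classes <- c("entity", "background")
  for (cl in classes) {
    if (!any(labels$class == cl)) {
      stop("no labels supplied for class '", cl, "'", call. = FALSE)
    }
  }
  for (i in unique(labels$image)) {
    li <- labels[labels$image == i, ]
    for (cl in classes) {
      nreg <- length(unique(li$region_id[li$class == cl]))
      if (nreg < min_regions) {
        stop(sprintf("image %s has %d labelled region(s) for class '%s'; at least %d are required",
                     i, nreg, cl, min_regions), call. = FALSE)
      }
    }
  }
  xs <- list(); ys <- list()
  for (i in unique(labels$image)) {
    img <- images[[i]]
    m <- if (inherits(img, "sem_image")) img$pixels else img
    stack <- compute_feature_stack(m, scales)
    li <- labels[labels$image == i, ]
    idx <- li$row + (li$col - 1L) * nrow(m)
    xs[[length(xs) + 1L]] <- features_as_table(stack, idx)
    ys[[length(ys) + 1L]] <- li$class
  }
  x <- do.call(rbind, xs)
  y <- factor(unlist(ys), levels = classes)
  fit <- ranger::ranger(x = x, y = y, num.trees = n_trees,
                        probability = TRUE, seed = as.integer(seed),
                        num.threads = 1L)
  structure(list(forest = fit, scales = scales, classes = classes,
                 n_labels = table(y), seed = as.integer(seed),
                 oob_accuracy = 1 - fit$prediction.error),
            class = "pixel_classifier")
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf("<pixel_classifier> %d trees, %d training pixels (%s), OOB accuracy %.3f\n",
              x$forest$num.trees, sum(x$n_labels),
              paste(sprintf("%s: %d", names(x$n_labels), x$n_labels),
                    collapse = ", "),
              x$oob_accuracy))
  invisible(x)
}

#' Predict an entity mask with a trained pixel classifier
#'
#' Classifies every pixel by majority class probability (ties go to
#' background) and returns a binary mask; optionally also the per-pixel
#' entity probability map.
#'
#' @param classifier a [train_pixel_classifier()] result.
#' @param image a [sem_image()] or matrix.
#' @param return_prob also return the probability map.
#' @return logical matrix (`TRUE` = entity) with attributes
#'   `provenance = "classifier"`; if `return_prob`, a list
#'   `(mask, probability)`.
#' @export
predict_mask <- function(classifier, image, return_prob = FALSE) {
  if (!inherits(classifier, "pixel_classifier")) {
    stop("classifier must be a trained pixel_classifier", call. = FALSE)
  }
  m <- if (inherits(image, "sem_image")) image$pixels else image
  stack <- compute_feature_stack(m, classifier$scales)
  p <- stats::predict(classifier$forest, data = features_as_table(stack),
                      num.threads = 1L)$predictions
  prob <- matrix(p[, "entity"], nrow(m), ncol(m))
  mask <- prob > 0.5
  attr(mask, "provenance") <- "classifier"
  if (return_prob) list(mask = mask, probability = prob) else mask
}

#' Binarize images at their common mean gray value
#'
#' Computes a single global threshold — the mean intensity over all supplied
#' images (batch mode, the default) or per image — and binarizes each image:
#' a pixel is white (crystalline phase) iff its intensity is strictly greater
#' than the threshold; ties go to black.
#'
#' @param images a [sem_image()], matrix, or a list of them.
#' @param per_image if `TRUE`, threshold each image at its own mean instead
#'   of the batch mean.
#' @return list with `masks` (list of logical matrices, attribute
#'   `threshold_value` on each) and `threshold` (the batch threshold, or a
#'   vector in per-image mode).
#' @export
binarize_mean_threshold <- function(images, per_image = FALSE) {
  if (inherits(images, "sem_image") || is.matrix(images)) images <- list(images)
  if (length(images) == 0L) stop("empty input set", call. = FALSE)
  mats <- lapply(images, function(im)
    if (inherits(im, "sem_image")) im$pixels else im)
  if (per_image) {
    thr <- vapply(mats, mean, numeric(1))
  } else {
    tot <- sum(vapply(mats, sum, numeric(1)))
    n <- sum(vapply(mats, length, numeric(1)))
    thr <- rep(tot / n, length(mats))
  }
  masks <- lapply(seq_along(mats), function(i) {
    mk <- mats[[i]] > thr[i]
    attr(mk, "provenance") <- "mean-threshold"
    attr(mk, "threshold_value") <- thr[i]
    mk
  })
  list(masks = masks,
       threshold = if (per_image) thr else thr[1])
}

#' Percent area covered by white pixels
#'
#' `100 * white / total`, excluding pixels under an optional exclusion mask
#' (fractures, dirt, scratches). This is the (minimum) percent area covered
#' by crystalline phases when applied to mean-threshold masks.
#'
#' @param mask logical matrix.
#' @param exclusion optional logical matrix of pixels to omit.
#' @return coverage in percent.
#' @export
coverage <- function(mask, exclusion = NULL) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  keep <- rep(TRUE, length(mask))
  if (!is.null(exclusion)) {
    if (!identical(dim(exclusion), dim(mask))) {
      stop("exclusion mask shape mismatch", call. = FALSE)
    }
    keep <- !as.logical(exclusion)
  }
  n <- sum(keep)
  if (n == 0L) stop("all pixels excluded", call. = FALSE)
  100 * sum(as.logical(mask)[keep]) / n
}
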