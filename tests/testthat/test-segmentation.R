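test_that("feature stack has 1 + 5 families x 5 scales features", {
  img <- matrix(runif(32 * 32), 32, 32)
  fs <- compute_feature_stack(img)
  expect_identical(dim(fs)[3], 26L)
  expect_true(all(is.finite(fs)))
  expect_error(compute_feature_stack(img, scales = c(1, -2)), "scales")
})

test_that("constant images carry no gradient, Laplacian or tensor response", {
  fs <- compute_feature_stack(matrix(0.4, 24, 24))
  deriv <- grep("gradmag|log|structure|hessian", dimnames(fs)[[3]])
  expect_lt(max(abs(fs[, , deriv])), 1e-9)
  smoothed <- grep("smooth|raw", dimnames(fs)[[3]])
  expect_equal(max(abs(fs[, , smoothed] - 0.4)), 0, tolerance = 1e-9)
})

test_that("gradient magnitude peaks on a step edge", {
  img <- cbind(matrix(0, 32, 16), matrix(1, 32, 16))
  fs <- compute_feature_stack(img, scales = c(0.7, 1.0))
  gm <- fs[, , "gradmag_s0.7"]
  peak_col <- which.max(colMeans(gm))
  expect_true(abs(peak_col - 16.5) <= 1)
})

test_that("training enforces at least 10 labelled regions per class", {
  img <- rbind(matrix(0.2, 16, 32), matrix(0.8, 16, 32))
  lab9 <- data.frame(image = 1L,
                     region_id = rep(1:9, each = 2),
                     class = "entity",
                     row = rep(17:25, each = 2), col = c(1:18))
  lab_bg <- data.frame(image = 1L, region_id = 100 + rep(1:10, each = 2),
                       class = "background",
                       row = rep(1:10, each = 2), col = c(1:20))
  expect_error(train_pixel_classifier(img, rbind(lab9, lab_bg)),
               "at least 10")
  expect_error(train_pixel_classifier(img, lab_bg), "entity")
})

two_phase_fixture <- function(noise = 0, seed = 1) {
  # bottom half bright (entity), top half dark; labels away from the edge
  set.seed(seed)
  img <- rbind(matrix(0.2, 20, 40), matrix(0.8, 20, 40)) +
    matrix(rnorm(800, 0, noise), 40, 40)
  img <- pmin(pmax(img, 0), 1)
  lab <- rbind(
    data.frame(image = 1L, region_id = 1:12, class = "entity",
               row = 24 + (1:12), col = 3 * (1:12)),
    data.frame(image = 1L, region_id = 101:112, class = "background",
               row = 2 + (1:12), col = 3 * (1:12)))
  list(img = img, lab = lab, truth = rbind(matrix(FALSE, 20, 40),
                                           matrix(TRUE, 20, 40)))
}

test_that("intensity-separable phases are classified almost perfectly", {
  fx <- two_phase_fixture()
  clf <- train_pixel_classifier(fx$img, fx$lab, seed = 7L)
  mask <- predict_mask(clf, fx$img)
  # equivalence with the optimal intensity threshold (here: the true phases)
  expect_gte(mean(mask == fx$truth), 0.99)
  # resubstitution accuracy on the labelled pixels themselves
  lab_idx <- cbind(fx$lab$row, fx$lab$col)
  expect_gte(mean(mask[lab_idx] == (fx$lab$class == "entity")), 0.95)
  expect_identical(attr(mask, "provenance"), "classifier")
})

test_that("prediction is deterministic and refuses untrained input", {
  fx <- two_phase_fixture(noise = 0.05)
  clf1 <- train_pixel_classifier(fx$img, fx$lab, seed = 3L)
  clf2 <- train_pixel_classifier(fx$img, fx$lab, seed = 3L)
  expect_identical(predict_mask(clf1, fx$img), predict_mask(clf2, fx$img))
  expect_error(predict_mask(list(), fx$img), "trained")
})

test_that("a blank image after two-phase training is all background", {
  fx <- two_phase_fixture()
  clf <- train_pixel_classifier(fx$img, fx$lab, seed = 2L)
  blank <- matrix(0.2, 40, 40)
  expect_false(any(predict_mask(clf, blank)))
})

test_that("classifier recovers synthetic ground truth (IoU >= 0.8)", {
  cfg <- synthetic_config(canvas_size = c(160L, 160L), n_bmu = 70L, seed = 9L)
  g <- generate_microstructure_image(cfg)
  lab <- labels_from_truth(g$truth, "bmu", n_regions = 15L, seed = 10L)
  clf <- train_pixel_classifier(g$image, lab, seed = 11L)
  mask <- predict_mask(clf, g$image)
  expect_gte(mask_iou(mask, g$truth$bmu_mask > 0L,
                      exclude = g$truth$artifact_mask), 0.80)
})

test_that("mean-gray binarization follows the batch-mean contract", {
  half <- rbind(matrix(0, 4, 8), matrix(1, 4, 8))
  bt <- binarize_mean_threshold(half)
  expect_equal(bt$threshold, 0.5)
  expect_equal(coverage(bt$masks[[1]]), 50)
  # constant image: strict inequality leaves no white pixels
  expect_equal(sum(binarize_mean_threshold(matrix(0.3, 5, 5))$masks[[1]]), 0L)
  # 4x4 example: threshold is the image mean, 8 pixels exceed it
  m <- matrix(rep(c(0.1, 0.5, 0.1, 0.5, 0.2, 0.6, 0.2, 0.6,
                    0.3, 0.7, 0.3, 0.7, 0.4, 0.8, 0.4, 0.8), 1), 4, 4)
  bt <- binarize_mean_threshold(m)
  expect_equal(bt$threshold, mean(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8)))
  expect_equal(sum(bt$masks[[1]]), 8L)
  expect_error(binarize_mean_threshold(list()), "empty")
})

test_that("batch thresholding pools all images; per-image mode does not", {
  a <- matrix(0.2, 4, 4); b <- matrix(0.8, 4, 4)
  batch <- binarize_mean_threshold(list(a, b))
  expect_equal(batch$threshold, 0.5)
  expect_equal(sum(batch$masks[[1]]), 0L)   # dark image all black
  expect_equal(sum(batch$masks[[2]]), 16L)  # bright image all white
  per <- binarize_mean_threshold(list(a, b), per_image = TRUE)
  expect_equal(sum(per$masks[[2]]), 0L)     # own mean -> no pixel exceeds
})

test_that("batch binarization is invariant to joint affine rescaling", {
  set.seed(5)
  imgs <- list(matrix(runif(64), 8, 8), matrix(runif(64), 8, 8))
  base <- binarize_mean_threshold(imgs)$masks
  resc <- binarize_mean_threshold(lapply(imgs, function(m) 0.4 * m + 0.21))$masks
  expect_identical(unname(base[[1]] == TRUE), unname(resc[[1]] == TRUE))
  expect_identical(unname(base[[2]] == TRUE), unname(resc[[2]] == TRUE))
})

test_that("coverage is exact arithmetic and monotone in white pixels", {
  expect_equal(coverage(matrix(TRUE, 3, 4)), 100)
  expect_equal(coverage(matrix(FALSE, 3, 4)), 0)
  m <- matrix(FALSE, 3, 4); m[1, 1:3] <- TRUE
  expect_equal(coverage(m), 25)
  m2 <- m; m2[2, 1] <- TRUE
  expect_gte(coverage(m2), coverage(m))
  # exclusion: omitted pixels leave the denominator
  excl <- matrix(FALSE, 3, 4); excl[1, 1] <- TRUE
  expect_equal(coverage(m, excl), 100 * 2 / 11)
  expect_error(coverage(m, matrix(TRUE, 3, 4)), "excluded")
})

test_that("warm-grown batches show higher mean-threshold coverage", {
  # extreme-group contrast at reduced canvas; the full six-level ladder
  # correlation is exercised by the end-to-end acceptance run
  # many small tail entities: keeps the per-image coverage variance low at
  # this reduced canvas while preserving the temperature scaling mechanism
  imgs <- list(); temps <- rep(c(1, 15), each = 3)
  for (i in seq_along(temps)) {
    g <- generate_microstructure_image(
      synthetic_config(canvas_size = c(160L, 160L), n_bmu = 70L,
                       tail_fraction = 0.15, bmu_tail_base = 0.03,
                       bmu_tail_scale_slope = 0.01,
                       temperature = temps[i], artifact_rate = 0,
                       seed = 70L + i))
    imgs[[i]] <- g$image
  }
  bt <- binarize_mean_threshold(imgs)
  cov <- vapply(bt$masks, coverage, numeric(1))
  expect_gt(mean(cov[temps == 15]), mean(cov[temps == 1]))
})
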