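#' Simulate a temperature-ladder culturing experiment
#'
#' Generates synthetic SEM images with ground truth for every combination of
#' culturing temperature and specimen, mirroring the six-level laboratory
#' design (1, 3, 6, 9, 12, 15 degrees C). Per-image seeds are derived
#' deterministically from `seed`.
#'
#' @param temperatures culturing temperatures in degrees C.
#' @param n_specimens specimens per temperature.
#' @param seed master seed.
#' @param config base [synthetic_config()]; its `temperature` and `seed` are
#'   overridden per image.
#' @return list of entries `(temperature, specimen_id, image, truth, config)`.
#' @export
simulate_temperature_ladder <- function(temperatures = c(1, 3, 6, 9, 12, 15),
                                        n_specimens = 3L, seed = 1L,
                                        config = synthetic_config()) {
  out <- list()
  for (ti in seq_along(temperatures)) {
    for (s in seq_len(n_specimens)) {
      img_seed <- (abs(as.integer(seed)) * 1009L + ti * 101L + s) %% 2147483647L
      cfg <- utils::modifyList(config,
                               list(temperature = temperatures[ti],
                                    seed = img_seed))
      class(cfg) <- "synthetic_config"
      sid <- sprintf("T%02d-S%d", round(temperatures[ti]), s)
      g <- generate_microstructure_image(cfg, specimen_id = sid)
      out[[length(out) + 1L]] <- list(temperature = temperatures[ti],
                                      specimen_id = sid, image = g$image,
                                      truth = g$truth, config = cfg)
    }
  }
  out
}

#' Derive sparse training labels from ground truth
#'
#' Emulates the sparse user labelling of interactive pixel classification:
#' samples `n_regions` small labelled regions per class (entity vs
#' background) from the ground-truth masks of one synthetic image. Artifact
#' pixels are never labelled (a user would not annotate dirt as either
#' class). Regions are 3x3 patches restricted to class-pure pixels.
#'
#' @param truth ground-truth list from [generate_microstructure_image()].
#' @param kind `"bmu"` or `"pore"`: which mask defines the entity class.
#' @param n_regions labelled regions per class (>= 10).
#' @param seed sampling seed.
#' @param image_index value for the `image` column of the returned labels.
#' @return label data.frame for [train_pixel_classifier()].
#' @export
labels_from_truth <- function(truth, kind = c("bmu", "pore"),
                              n_regions = 15L, seed = 1L, image_index = 1L) {
  kind <- match.arg(kind)
  entity <- truth[[paste0(kind, "_mask")]] > 0L
  forbid <- truth$artifact_mask
  background <- !entity & !forbid
  entity <- entity & !forbid
  d <- dim(entity)
  # half the background regions hug entity boundaries (as a user labelling
  # boundary context would), half lie in open background
  near <- t(EBImage::imageData(EBImage::dilate(
    EBImage::Image(t(entity)), EBImage::makeBrush(7, "box")))) > 0 & background
  with_seed(seed, {
    sample_regions <- function(classmask, class, id_offset, nearmask = NULL) {
      cand <- which(classmask)
      if (!is.null(nearmask) && any(nearmask)) {
        n_near <- min(n_regions %/% 2L, sum(nearmask))
        centers <- c(sample(which(nearmask), n_near),
                     sample(setdiff(cand, which(nearmask)),
                            n_regions - n_near))
      } else {
        centers <- sample(cand, n_regions)
      }
      out <- list()
      for (i in seq_along(centers)) {
        r0 <- ((centers[i] - 1L) %% d[1]) + 1L
        c0 <- ((centers[i] - 1L) %/% d[1]) + 1L
        rr <- pmin(pmax((r0 - 1L):(r0 + 1L), 1L), d[1])
        cc <- pmin(pmax((c0 - 1L):(c0 + 1L), 1L), d[2])
        patch <- expand.grid(row = unique(rr), col = unique(cc))
        pure <- classmask[cbind(patch$row, patch$col)]
        patch <- patch[pure, , drop = FALSE]
        out[[i]] <- data.frame(image = image_index,
                               region_id = id_offset + i, class = class,
                               row = patch$row, col = patch$col)
      }
      do.call(rbind, out)
    }
    rbind(sample_regions(entity, "entity", 0L),
          sample_regions(background, "background", n_regions,
                         nearmask = near))
  })
}

#' Intersection-over-union of two binary masks
#'
#' @param pred,truth logical matrices.
#' @param exclude optional logical matrix of pixels to ignore (e.g.
#'   artifacts).
#' @return IoU in `[0, 1]` (1 when both masks are empty).
#' @export
mask_iou <- function(pred, truth, exclude = NULL) {
  p <- as.logical(pred); t <- as.logical(truth)
  keep <- if (is.null(exclude)) rep(TRUE, length(p)) else !as.logical(exclude)
  inter <- sum(p & t & keep)
  uni <- sum((p | t) & keep)
  if (uni == 0L) 1 else inter / uni
}

#' Run the full proxy pipeline on a simulated ladder
#'
#' Trains one BMU and one pore pixel classifier on a subset of the ladder's
#' images (labels derived from ground truth), segments every image, measures
#' particles (excluding artifact pixels), computes batch mean-threshold
#' coverage, and assembles the proxy statistics: pooled top-N subsets per
#' temperature group, Spearman correlations, and linear/exponential
#' calibration models for BMU and pore sizes, plus segmentation IoU per
#' image.
#'
#' @param ladder result of [simulate_temperature_ladder()].
#' @param seed seed for label sampling and classifier training.
#' @param top_n extreme-subset size (default 15).
#' @param min_pixels minimum particle size in pixels (default 3).
#' @param train_idx indices of ladder entries used for classifier training
#'   (default: one specimen at the lowest, middle and highest temperature).
#' @param n_label_regions labelled regions per class per training image.
#' @return list: `records` (pooled particle table), `coverage` (per-image
#'   data.frame), `iou` (per-image data.frame with `iou_bmu`, `iou_pore`),
#'   `report` (see [proxy_report()]), `classifiers`, `threshold`.
#' @export
run_proxy_pipeline <- function(ladder, seed = 1L, top_n = 15L,
                               min_pixels = 3L, train_idx = NULL,
                               n_label_regions = 15L) {
  temps <- vapply(ladder, `[[`, numeric(1), "temperature")
  if (is.null(train_idx)) {
    train_idx <- c(which.min(temps),
                   which.min(abs(temps - stats::median(temps))),
                   which.max(temps))
    train_idx <- unique(train_idx)
  }
  train_images <- lapply(ladder[train_idx], `[[`, "image")
  make_labels <- function(kind) {
    do.call(rbind, lapply(seq_along(train_idx), function(i) {
      labels_from_truth(ladder[[train_idx[i]]]$truth, kind = kind,
                        n_regions = n_label_regions,
                        seed = seed + 31L * i, image_index = i)
    }))
  }
  clf_bmu <- train_pixel_classifier(train_images, make_labels("bmu"),
                                    seed = seed)
  clf_pore <- train_pixel_classifier(train_images, make_labels("pore"),
                                     seed = seed + 1L)
  records <- list(); iou <- list()
  for (i in seq_along(ladder)) {
    e <- ladder[[i]]
    stack <- compute_feature_stack(e$image, clf_bmu$scales)
    feats <- features_as_table(stack)
    pm <- function(clf) {
      p <- stats::predict(clf$forest, data = feats, num.threads = 1L)$predictions
      matrix(p[, "entity"] > 0.5, nrow(e$image$pixels), ncol(e$image$pixels))
    }
    mask_b <- pm(clf_bmu)
    mask_p <- pm(clf_pore)
    excl <- e$truth$artifact_mask
    iou[[i]] <- data.frame(specimen_id = e$specimen_id,
                           temperature = e$temperature,
                           iou_bmu = mask_iou(mask_b, e$truth$bmu_mask > 0L,
                                              exclude = excl),
                           iou_pore = mask_iou(mask_p, e$truth$pore_mask > 0L,
                                               exclude = excl))
    meas <- function(mask, kind) {
      measure_particles(label_components(mask, 8L), e$image$pixel_area,
                        min_pixels = min_pixels, exclusion = excl,
                        kind = kind, specimen_id = e$specimen_id,
                        temperature = e$temperature)
    }
    records[[i]] <- rbind(meas(mask_b, "bmu"), meas(mask_p, "pore"))
  }
  records <- do.call(rbind, records)
  bt <- binarize_mean_threshold(lapply(ladder, `[[`, "image"))
  cov_df <- do.call(rbind, lapply(seq_along(ladder), function(i) {
    data.frame(specimen_id = ladder[[i]]$specimen_id,
               temperature = ladder[[i]]$temperature,
               coverage_pct = coverage(bt$masks[[i]],
                                       ladder[[i]]$truth$artifact_mask))
  }))
  list(records = records, coverage = cov_df, iou = do.call(rbind, iou),
       report = proxy_report(records, cov_df, top_n = top_n),
       classifiers = list(bmu = clf_bmu, pore = clf_pore),
       threshold = bt$threshold)
}

#' Assemble the proxy statistics report
#'
#' From a pooled particle table: per-temperature top-N subsets for BMUs and
#' pores, Spearman correlations of the pooled top-N areas against group
#' temperature, linear and exponential calibration models per kind, pairwise
#' two-sample Kolmogorov-Smirnov comparisons between temperature groups, and
#' (optionally) the coverage-temperature correlation.
#'
#' @param records particle table with `kind`, `area_um2`, `specimen_id`,
#'   `temperature`.
#' @param coverage_df optional per-image coverage table
#'   (`temperature`, `coverage_pct`).
#' @param top_n extreme-subset size.
#' @return list with per-kind entries (`top`, `spearman`, `linear`,
#'   `exponential`, `ks`) and `coverage_spearman`.
#' @export
proxy_report <- function(records, coverage_df = NULL, top_n = 15L) {
  per_kind <- function(kind) {
    rk <- records[records$kind == kind, , drop = FALSE]
    if (nrow(rk) == 0L) return(NULL)
    groups <- split(rk, rk$temperature)
    top <- do.call(rbind, lapply(groups, function(g)
      suppressWarnings(top_n_largest(g, top_n))))
    rownames(top) <- NULL
    sc <- spearman_cor(top$area_um2, top$temperature)
    lin <- fit_linear(top$temperature, top$area_um2)
    expf <- fit_exponential(top$temperature, top$area_um2)
    tt <- sort(unique(rk$temperature))
    ks <- list()
    for (i in seq_along(tt)) {
      for (j in seq_along(tt)) {
        if (i < j) {
          k <- ks_two_sample(groups[[as.character(tt[i])]]$area_um2,
                             groups[[as.character(tt[j])]]$area_um2)
          ks[[length(ks) + 1L]] <- data.frame(t1 = tt[i], t2 = tt[j],
                                              D = k$D, p = k$p)
        }
      }
    }
    list(top = top, spearman = sc, linear = lin, exponential = expf,
         ks = do.call(rbind, ks))
  }
  cov_sc <- if (!is.null(coverage_df)) {
    spearman_cor(coverage_df$coverage_pct, coverage_df$temperature)
  } else NULL
  list(bmu = per_kind("bmu"), pore = per_kind("pore"),
       coverage_spearman = cov_sc, top_n = top_n)
}
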