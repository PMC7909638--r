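test_that("connectivity follows the textbook definitions", {
  m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE; m[2, 2] <- TRUE
  expect_identical(label_components(m, 8L)$n_components, 1L)
  expect_identical(label_components(m, 4L)$n_components, 2L)
  expect_identical(label_components(matrix(FALSE, 3, 3))$n_components, 0L)
  # 4x4 checkerboard under 4-connectivity: every white square is isolated
  cb <- outer(1:4, 1:4, function(r, c) (r + c) %% 2 == 0)
  expect_identical(label_components(cb, 4L)$n_components, 8L)
  expect_error(label_components(cb, 6L), "connectivity")
})

test_that("labelling agrees with EBImage on 4-connectivity", {
  for (s in 1:10) {
    set.seed(s)
    m <- matrix(runif(900) < 0.4, 30, 30)
    mine <- label_components(m, 4L)
    ebi <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(m)))))
    expect_identical(mine$n_components, as.integer(max(ebi)))
    expect_identical(sort(tabulate(mine$labels[mine$labels > 0])),
                     sort(tabulate(ebi[ebi > 0])))
  }
})

test_that("pixel counts are conserved between components and background", {
  set.seed(3)
  m <- matrix(runif(400) < 0.35, 20, 20)
  lab <- label_components(m, 8L)
  expect_identical(sum(tabulate(lab$labels[lab$labels > 0])) + sum(!m),
                   400L)
})

test_that("areas come out in both pixels and um^2", {
  m <- matrix(FALSE, 6, 6); m[2, 2] <- m[3, 2] <- m[3, 3] <- TRUE  # L-shape
  rec <- measure_particles(label_components(m), pixel_area = 3e-4)
  expect_identical(nrow(rec), 1L)
  expect_equal(rec$area_um2, 0.0009)
  expect_identical(rec$area_px, 3L)
  expect_error(measure_particles(label_components(m), pixel_area = 0),
               "pixel_area")
})

test_that("components at or below two pixels are excluded", {
  m <- matrix(FALSE, 8, 8)
  m[1, 1:2] <- TRUE            # 2 px -> dropped
  m[5, 1:4] <- TRUE            # 4 px -> kept
  rec <- measure_particles(label_components(m), pixel_area = 3e-4)
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$area_px, 4L)
  expect_identical(attr(rec, "n_dropped_small"), 1L)
  # configurable threshold keeps it
  rec2 <- measure_particles(label_components(m), 3e-4, min_pixels = 1L)
  expect_identical(nrow(rec2), 2L)
})

test_that("components under the exclusion mask are dropped", {
  m <- matrix(FALSE, 8, 8); m[1:3, 1] <- TRUE; m[5:7, 5] <- TRUE
  excl <- matrix(FALSE, 8, 8); excl[2, 1] <- TRUE
  rec <- measure_particles(label_components(m), 3e-4, exclusion = excl)
  expect_identical(nrow(rec), 1L)
  expect_equal(rec$centroid_col, 5)
  expect_identical(attr(rec, "n_dropped_excluded"), 1L)
})

test_that("a rasterized disk is round to within 5%", {
  m <- disk_mask(20L)
  rec <- measure_particles(label_components(m), 3e-4)
  expect_gte(rec$elongation, 1.0)
  expect_lte(rec$elongation, 1.05)
})

test_that("elongation matches the brute-force moment oracle", {
  set.seed(11)
  checked <- 0L
  for (i in 1:200) {
    px <- random_pixel_set(sample(3:40, 1))
    want <- elongation_oracle(px[, 1], px[, 2])
    got <- camtherm:::elongation_from_moments(px[, 1], px[, 2])
    if (is.na(want)) {
      expect_true(got$degenerate)
    } else {
      checked <- checked + 1L
      expect_equal(got$elongation, want, tolerance = 1e-9)
    }
  }
  expect_gt(checked, 150L)
})

test_that("degenerate single-file components fall back to pixel count", {
  m <- matrix(FALSE, 8, 8); m[3, 2:6] <- TRUE  # 5-px line
  rec <- measure_particles(label_components(m), 3e-4)
  expect_true(rec$degenerate)
  expect_equal(rec$elongation, 5)
})

test_that("measurements are invariant to translation and 90-degree rotation", {
  set.seed(21)
  m <- matrix(FALSE, 24, 24)
  m[4:9, 5:7] <- TRUE; m[15:17, 10:18] <- TRUE
  base <- measure_particles(label_components(m), 3e-4)
  shifted <- matrix(FALSE, 24, 24)
  shifted[(4:9) + 5, (5:7) + 3] <- TRUE; shifted[(15:17) + 5, (10:18) + 3] <- TRUE
  rot <- t(m)[ncol(m):1, ]
  for (variant in list(shifted, rot)) {
    v <- measure_particles(label_components(variant), 3e-4)
    expect_equal(sort(v$area_um2), sort(base$area_um2))
    expect_equal(sort(v$elongation), sort(base$elongation), tolerance = 1e-9)
  }
})

test_that("Feret elongation is a sane sensitivity alternative", {
  m <- matrix(FALSE, 30, 30); m[10:12, 5:25] <- TRUE  # 3 x 21 bar
  mom <- measure_particles(label_components(m), 3e-4, method = "moment")
  fer <- measure_particles(label_components(m), 3e-4, method = "feret")
  expect_gt(fer$elongation, 3)
  expect_gt(mom$elongation, 3)
  round_rec <- measure_particles(label_components(disk_mask(15L)), 3e-4,
                                 method = "feret")
  expect_lt(round_rec$elongation, 1.2)
})

test_that("specimen summaries report count, max and percentiles", {
  rec <- data.frame(area_um2 = c(1, 2, 3), specimen_id = "S1")
  s <- summarize_specimen(rec, region_area = 100)
  expect_identical(s$n, 3L)
  expect_equal(s$max_area_um2, 3)
  expect_equal(s$p50, 2)
  one <- summarize_specimen(data.frame(area_um2 = 7, specimen_id = "S1"))
  expect_true(all(unlist(one[c("p50", "p90", "p99", "p99.9")]) == 7))
  empty <- summarize_specimen(data.frame(area_um2 = numeric(),
                                         specimen_id = character()))
  expect_identical(empty$n, 0L)
  expect_error(summarize_specimen(data.frame(area_um2 = 1:2,
                                             specimen_id = c("A", "B"))),
               "one specimen")
})

test_that("measured maxima track the generator's truth", {
  g <- generate_microstructure_image(synthetic_config(canvas_size = c(192L, 192L),
                                                      n_bmu = 100L, noise_sd = 0,
                                                      artifact_rate = 0,
                                                      seed = 33L))
  rec <- measure_particles(label_components(g$truth$bmu_mask > 0L),
                           g$config$pixel_area)
  truth_max <- max(g$truth$truth_table$area_um2[g$truth$truth_table$kind == "bmu"])
  expect_lt(abs(max(rec$area_um2) - truth_max) / truth_max, 0.15)
})
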