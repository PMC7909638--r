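test_that("config validation rejects non-finite and out-of-range parameters", {
  expect_error(synthetic_config(pixel_area = 0), "pixel_area")
  expect_error(synthetic_config(pixel_area = NA_real_), "non-finite")
  expect_error(synthetic_config(temperature = Inf), "non-finite")
  expect_error(synthetic_config(tail_fraction = 1.2), "tail_fraction")
  expect_error(synthetic_config(bmu_tail_base = -1), "bmu_tail_base")
  expect_error(synthetic_config(noise_sd = -0.1), "noise_sd")
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- synthetic_config(seed = 11L)
  expect_identical(sample_bmu_population(cfg), sample_bmu_population(cfg))
  g1 <- generate_microstructure_image(cfg)
  g2 <- generate_microstructure_image(cfg)
  expect_identical(g1$image$pixels, g2$image$pixels)
  expect_identical(g1$truth$bmu_mask, g2$truth$bmu_mask)
  expect_identical(g1$truth$truth_table, g2$truth$truth_table)
  # different seed changes the draw
  g3 <- generate_microstructure_image(synthetic_config(seed = 12L))
  expect_false(identical(g1$image$pixels, g3$image$pixels))
  # and the caller's RNG stream is untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(sample_bmu_population(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("only the upper size tail responds to temperature", {
  # with the tail component active, the maximum BMU size is larger at 15 C
  # than at 1 C in nearly all paired draws
  wins <- 0L
  for (s in 1:100) {
    lo <- sample_bmu_population(synthetic_config(temperature = 1,
                                                 tail_fraction = 0.02,
                                                 seed = s))
    hi <- sample_bmu_population(synthetic_config(temperature = 15,
                                                 tail_fraction = 0.02,
                                                 seed = 1000L + s))
    wins <- wins + (max(hi$area_um2) > max(lo$area_um2))
  }
  expect_gte(wins, 95L)
  # with tail_fraction = 0 the size distribution is temperature-invariant
  lo <- sample_bmu_population(synthetic_config(temperature = 1, n_bmu = 500L,
                                               tail_fraction = 0, seed = 5L))
  hi <- sample_bmu_population(synthetic_config(temperature = 15, n_bmu = 500L,
                                               tail_fraction = 0, seed = 6L))
  expect_gt(ks_two_sample(lo$area_um2, hi$area_um2)$p, 0.05)
})

test_that("rendered entities match their intended pixel areas", {
  # single 3.0 um^2 BMU at the native pixel size must cover 10,000 px
  cfg <- synthetic_config(canvas_size = c(384L, 384L), n_bmu = 1L,
                          tail_fraction = 0, bulk_size_log_mean = log(3),
                          bulk_size_log_sd = 1e-9, pore_density = 0,
                          noise_sd = 0, artifact_rate = 0, seed = 3L)
  g <- generate_microstructure_image(cfg)
  expect_equal(sum(g$truth$bmu_mask > 0L), 10000L,
               tolerance = 0.15 * 10000)  # rasterization tolerance
  expect_equal(g$truth$truth_table$area_px, 10000L)
  # under the default config, every placed entity >= 10 px is within 15%
  g <- generate_microstructure_image(synthetic_config(seed = 8L))
  tt <- g$truth$truth_table
  intended_px <- round(tt$area_um2 / g$config$pixel_area)
  big <- intended_px >= 10L
  expect_true(all(abs(tt$area_px[big] - intended_px[big]) /
                    intended_px[big] <= 0.15))
})

test_that("masks and truth table stay consistent", {
  g <- generate_microstructure_image(synthetic_config(seed = 21L))
  tt <- g$truth$truth_table
  for (kind in c("bmu", "pore")) {
    mask <- g$truth[[paste0(kind, "_mask")]]
    ids_mask <- sort(unique(mask[mask > 0L]))
    ids_tt <- sort(tt$mask_id[tt$kind == kind])
    expect_identical(ids_mask, ids_tt)
    cnt <- tabulate(mask[mask > 0L])
    expect_identical(cnt[tt$mask_id[tt$kind == kind]],
                     tt$area_px[tt$kind == kind])
  }
})

test_that("pores lie parallel to the growth front", {
  g <- generate_microstructure_image(synthetic_config(seed = 31L,
                                                      pore_density = 1.5))
  po <- g$truth$truth_table$orientation_deg[g$truth$truth_table$kind == "pore"]
  expect_gt(length(po), 5L)
  expect_lt(stats::sd(po), 15)
  expect_true(all(abs(po) < 35))
})

test_that("pooled BMU sizes keep a heavy small-size bulk", {
  b <- sample_bmu_population(synthetic_config(seed = 42L))
  e <- size_ecdf(b$area_um2)
  expect_gt(e$quantile(0.999) / stats::median(b$area_um2), 5)
})

test_that("mean of the 15 largest areas is non-decreasing in temperature", {
  for (s in 1:3) {
    m15 <- vapply(c(1, 3, 6, 9, 12, 15), function(t) {
      b <- sample_bmu_population(synthetic_config(temperature = t, seed = s))
      mean(sort(b$area_um2, decreasing = TRUE)[1:15])
    }, numeric(1))
    expect_true(all(diff(m15) >= 0))
  }
})

test_that("overcrowded configurations are rejected with the offending densities", {
  cfg <- synthetic_config(canvas_size = c(64L, 64L), n_bmu = 4000L)
  expect_error(generate_microstructure_image(cfg), "n_bmu")
  expect_error(generate_microstructure_image(cfg), "overcrowded")
})

test_that("Mn/Ca profiles are two-level with a recorded changepoint", {
  s <- generate_mnca_profile(500, 4, n_pre = 5, n_post = 7, noise_cv = 0,
                             seed = 1L)
  expect_identical(s$mnca, rep(c(500, 4), c(5, 7)))
  expect_identical(attr(s, "true_changepoint"), 6L)
  expect_error(generate_mnca_profile(-1, 4, 5, 5), "pre_level")
  expect_error(generate_mnca_profile(500, 4, 2, 5), "n_pre")
  s1 <- generate_mnca_profile(500, 4, 5, 5, noise_cv = 0.5, seed = 9L)
  s2 <- generate_mnca_profile(500, 4, 5, 5, noise_cv = 0.5, seed = 9L)
  expect_identical(s1$mnca, s2$mnca)
  # noisy laboratory zones stay centred on their level: pooled median over
  # 100 seeds within 20% of 4.26 umol/mol
  post <- unlist(lapply(1:100, function(s) {
    p <- generate_mnca_profile(502.39, 4.26, 10, 10, noise_cv = 0.5, seed = s)
    p$mnca[11:20]
  }))
  expect_lt(abs(stats::median(post) - 4.26) / 4.26, 0.2)
})
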