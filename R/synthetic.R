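#' Configuration for the synthetic microstructure generator
#'
#' Builds a validated configuration describing one synthetic SEM backscatter
#' image of crossed-acicular (CA) shell microstructure. The generative model
#' follows the empirical structure of the proxy: a temperature-invariant bulk
#' of very small biomineral units (BMUs, lognormal), plus a small "tail"
#' component of large BMUs whose characteristic size grows linearly with
#' temperature; pores are elongated parallel to the growth front (image
#' vertical) and their sizes scale exponentially with temperature. Gray values
#' emulate topography: bright BMU plateaus, intermediate soft rims, dark
#' inter-crystalline background, darkest pores.
#'
#' @param canvas_size integer vector (rows, cols) of the image raster.
#' @param pixel_area area of one pixel in um^2 (default 0.0003).
#' @param temperature culturing temperature in degrees C.
#' @param n_bmu number of BMUs drawn for the image.
#' @param bulk_size_log_mean,bulk_size_log_sd lognormal parameters (um^2) of
#'   the temperature-invariant small-BMU bulk.
#' @param tail_fraction fraction of BMUs drawn from the temperature-scaled
#'   large component, in `[0, 1]`.
#' @param bmu_tail_base,bmu_tail_scale_slope the large-BMU component has
#'   lognormal median `bmu_tail_base + bmu_tail_scale_slope * temperature`
#'   (um^2 and um^2 per degree C).
#' @param tail_size_log_sd lognormal sigma of the large-BMU component.
#' @param pore_density expected pores per um^2 of canvas.
#' @param pore_base_size lognormal median pore size (um^2) at 0 degrees C.
#' @param pore_growth_rate exponential temperature scaling of pore sizes
#'   (1 / degree C); the default is the two-point solve through the proxy's
#'   endpoint pore means, log(10.13 / 0.68) / 14.
#' @param pore_size_log_sd lognormal sigma of pore sizes.
#' @param dip_angle_mean,dip_angle_sd BMU long-axis orientation modes at
#'   +/- `dip_angle_mean` degrees off the growth front (image vertical), with
#'   Gaussian spread `dip_angle_sd`.
#' @param pore_angle_sd Gaussian spread (degrees) of pore orientations about
#'   the growth-front axis.
#' @param gray_levels named numeric vector with entries `plateau`, `rim`,
#'   `background`, `pore`, all in `[0, 1]`.
#' @param noise_sd standard deviation of additive Gaussian imaging noise.
#' @param artifact_rate expected number of dirt/scratch artifacts per image.
#' @param seed integer seed; identical (config, seed) gives bit-identical
#'   output.
#'
#' @return an object of class `synthetic_config` (a named list).
#' @export
synthetic_config <- function(canvas_size = c(320L, 320L),
                             pixel_area = 0.0003,
                             temperature = 9,
                             n_bmu = 280L,
                             bulk_size_log_mean = log(0.012),
                             bulk_size_log_sd = 0.8,
                             tail_fraction = 0.03,
                             bmu_tail_base = 0.12,
                             bmu_tail_scale_slope = 0.04,
                             tail_size_log_sd = 0.25,
                             pore_density = 0.7,
                             pore_base_size = 0.004,
                             pore_growth_rate = log(10.13 / 0.68) / 14,
                             pore_size_log_sd = 0.8,
                             dip_angle_mean = 35,
                             dip_angle_sd = 8,
                             pore_angle_sd = 7,
                             gray_levels = c(plateau = 0.85, rim = 0.62,
                                             background = 0.35, pore = 0.10),
                             noise_sd = 0.05,
                             artifact_rate = 1,
                             seed = 1L) {
  cfg <- list(canvas_size = as.integer(canvas_size),
              pixel_area = pixel_area, temperature = temperature,
              n_bmu = as.integer(n_bmu),
              bulk_size_log_mean = bulk_size_log_mean,
              bulk_size_log_sd = bulk_size_log_sd,
              tail_fraction = tail_fraction,
              bmu_tail_base = bmu_tail_base,
              bmu_tail_scale_slope = bmu_tail_scale_slope,
              tail_size_log_sd = tail_size_log_sd,
              pore_density = pore_density, pore_base_size = pore_base_size,
              pore_growth_rate = pore_growth_rate,
              pore_size_log_sd = pore_size_log_sd,
              dip_angle_mean = dip_angle_mean, dip_angle_sd = dip_angle_sd,
              pore_angle_sd = pore_angle_sd,
              gray_levels = gray_levels, noise_sd = noise_sd,
              artifact_rate = artifact_rate, seed = as.integer(seed))
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

validate_synthetic_config <- function(cfg) {
  num <- cfg[!(names(cfg) %in% c("canvas_size", "gray_levels"))]
  bad <- names(num)[!vapply(num, function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))]
  if (length(bad)) {
    stop("non-finite or non-scalar config parameter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(cfg$canvas_size) != 2L || any(cfg$canvas_size < 16L)) {
    stop("canvas_size must be two integers >= 16", call. = FALSE)
  }
  check_scalar(cfg$pixel_area, "pixel_area", positive = TRUE)
  if (cfg$tail_fraction < 0 || cfg$tail_fraction > 1) {
    stop("tail_fraction must lie in [0, 1]", call. = FALSE)
  }
  for (f in c("bmu_tail_base", "pore_base_size")) {
    check_scalar(cfg[[f]], f, positive = TRUE)
  }
  for (f in c("bulk_size_log_sd", "tail_size_log_sd", "pore_size_log_sd",
              "dip_angle_sd", "pore_angle_sd", "noise_sd", "pore_density",
              "artifact_rate", "bmu_tail_scale_slope")) {
    if (cfg[[f]] < 0) stop(f, " must be >= 0", call. = FALSE)
  }
  gl <- cfg$gray_levels
  if (!all(c("plateau", "rim", "background", "pore") %in% names(gl)) ||
      any(gl < 0) || any(gl > 1)) {
    stop("gray_levels must name plateau/rim/background/pore in [0, 1]",
         call. = FALSE)
  }
  invisible(cfg)
}

# -- population sampling (no RNG seeding here; callers wrap in with_seed) -----

.sample_bmu <- function(cfg) {
  n <- cfg$n_bmu
  if (n == 0L) {
    return(data.frame(entity_id = integer(), kind = character(),
                      area_um2 = numeric(), orientation_deg = numeric(),
                      elongation = numeric(), center_row = numeric(),
                      center_col = numeric(), component = character(),
                      stringsAsFactors = FALSE))
  }
  is_tail <- stats::runif(n) < cfg$tail_fraction
  size <- numeric(n)
  size[!is_tail] <- stats::rlnorm(sum(!is_tail), cfg$bulk_size_log_mean,
                                  cfg$bulk_size_log_sd)
  if (any(is_tail)) {
    scale <- cfg$bmu_tail_base + cfg$bmu_tail_scale_slope * cfg$temperature
    size[is_tail] <- stats::rlnorm(sum(is_tail), log(scale),
                                   cfg$tail_size_log_sd)
  }
  side <- sample(c(-1, 1), n, replace = TRUE)
  orient <- side * cfg$dip_angle_mean + stats::rnorm(n, 0, cfg$dip_angle_sd)
  elong <- stats::runif(n, 2, 4)
  data.frame(entity_id = seq_len(n), kind = "bmu", area_um2 = size,
             orientation_deg = orient, elongation = elong,
             center_row = stats::runif(n, 1, cfg$canvas_size[1]),
             center_col = stats::runif(n, 1, cfg$canvas_size[2]),
             component = ifelse(is_tail, "tail", "bulk"),
             stringsAsFactors = FALSE)
}

.sample_pores <- function(cfg) {
  area_um2 <- prod(cfg$canvas_size) * cfg$pixel_area
  n <- stats::rpois(1L, cfg$pore_density * area_um2)
  if (n == 0L) {
    out <- .sample_bmu(utils::modifyList(cfg, list(n_bmu = 0L)))
    return(out)
  }
  size <- stats::rlnorm(n, log(cfg$pore_base_size), cfg$pore_size_log_sd) *
    exp(cfg$pore_growth_rate * cfg$temperature)
  data.frame(entity_id = seq_len(n), kind = "pore", area_um2 = size,
             orientation_deg = stats::rnorm(n, 0, cfg$pore_angle_sd),
             elongation = stats::runif(n, 2, 5),
             center_row = stats::runif(n, 1, cfg$canvas_size[1]),
             center_col = stats::runif(n, 1, cfg$canvas_size[2]),
             component = "pore", stringsAsFactors = FALSE)
}

#' Sample a synthetic BMU population
#'
#' Draws per-entity specifications (size, orientation, elongation, proposed
#' center) from the bulk-plus-scaled-tail mixture without rendering an image.
#' Sizes of the bulk component are independent of temperature; only the tail
#' component scales with it.
#'
#' @param config a [synthetic_config()].
#' @return data.frame with columns `entity_id`, `kind`, `area_um2`,
#'   `orientation_deg`, `elongation`, `center_row`, `center_col`, `component`.
#' @export
sample_bmu_population <- function(config) {
  validate_synthetic_config(config)
  with_seed(config$seed, .sample_bmu(config))
}

#' @rdname sample_bmu_population
#' @export
sample_pore_population <- function(config) {
  validate_synthetic_config(config)
  with_seed(config$seed, .sample_pores(config))
}

# -- rasterization ------------------------------------------------------------

# Pixels of an ellipse of `npx` pixels, elongation e, orientation theta
# (degrees off the image vertical), centered at (r0, c0). Selects exactly the
# npx pixels with the smallest elliptical quadratic form, so the rendered area
# equals the intended pixel area. Returns NULL when the bounding box does not
# fit inside the canvas.
ellipse_pixels <- function(r0, c0, npx, elong, theta_deg, dim) {
  a <- sqrt(npx * elong / pi)   # semi-major, px
  b <- sqrt(npx / (pi * elong)) # semi-minor, px
  th <- theta_deg * pi / 180
  u <- c(cos(th), sin(th))      # long axis: theta = 0 -> along rows (vertical)
  mr <- ceiling(sqrt((a * u[1])^2 + (b * u[2])^2)) + 1L
  mc <- ceiling(sqrt((a * u[2])^2 + (b * u[1])^2)) + 1L
  r0 <- round(r0); c0 <- round(c0)
  if (r0 - mr < 1L || r0 + mr > dim[1] || c0 - mc < 1L || c0 + mc > dim[2]) {
    return(NULL)
  }
  rr <- (r0 - mr):(r0 + mr)
  cc <- (c0 - mc):(c0 + mc)
  dr <- rep(rr - r0, times = length(cc))
  dc <- rep(cc - c0, each = length(rr))
  du <- dr * u[1] + dc * u[2]
  dv <- -dr * u[2] + dc * u[1]
  q <- (du / a)^2 + (dv / b)^2
  ord <- order(q, dr, dc)[seq_len(min(npx, length(q)))]
  cbind(row = dr[ord] + r0, col = dc[ord] + c0)
}

# mark a 3x3 halo around pixels in a logical occupancy matrix
stamp_halo <- function(occ, px) {
  d <- dim(occ)
  for (dr in -1:1) {
    for (dc in -1:1) {
      r <- pmin(pmax(px[, 1] + dr, 1L), d[1])
      c <- pmin(pmax(px[, 2] + dc, 1L), d[2])
      occ[cbind(r, c)] <- TRUE
    }
  }
  occ
}

place_entities <- function(specs, cfg, occ, max_tries = 80L) {
  d <- cfg$canvas_size
  mask <- matrix(0L, d[1], d[2])
  placed <- logical(nrow(specs))
  area_px <- integer(nrow(specs))
  if (nrow(specs)) {
    ord <- order(-specs$area_um2)
    next_id <- 0L
    ids <- integer(nrow(specs))
    for (i in ord) {
      npx <- max(1L, round(specs$area_um2[i] / cfg$pixel_area))
      ok <- FALSE
      r0 <- specs$center_row[i]; c0 <- specs$center_col[i]
      for (try in seq_len(max_tries)) {
        px <- ellipse_pixels(r0, c0, npx, specs$elongation[i],
                             specs$orientation_deg[i], d)
        if (!is.null(px) && !any(occ[px])) { ok <- TRUE; break }
        r0 <- stats::runif(1, 1, d[1]); c0 <- stats::runif(1, 1, d[2])
      }
      if (ok) {
        next_id <- next_id + 1L
        ids[i] <- next_id
        mask[px] <- next_id
        occ <- stamp_halo(occ, px)
        placed[i] <- TRUE
        area_px[i] <- nrow(px)
      }
    }
    specs$mask_id <- ids
  } else {
    specs$mask_id <- integer(0)
  }
  specs$placed <- placed
  specs$area_px <- area_px
  list(specs = specs, mask = mask, occ = occ)
}

draw_artifacts <- function(cfg, img, artifact_mask) {
  n <- stats::rpois(1L, cfg$artifact_rate)
  d <- dim(img)
  if (n > 0) {
    for (i in seq_len(n)) {
      if (stats::runif(1) < 0.5) { # scratch: bright thin line
        p0 <- c(stats::runif(1, 1, d[1]), stats::runif(1, 1, d[2]))
        ang <- stats::runif(1, 0, pi)
        len <- stats::runif(1, 0.3, 0.9) * min(d)
        t <- seq(-len / 2, len / 2, by = 0.5)
        r <- pmin(pmax(round(p0[1] + t * cos(ang)), 1L), d[1])
        c <- pmin(pmax(round(p0[2] + t * sin(ang)), 1L), d[2])
        px <- unique(cbind(r, c))
        img[px] <- 0.95
        artifact_mask[px] <- TRUE
      } else { # dirt: dark blob
        npx <- round(stats::runif(1, 30, 150))
        px <- ellipse_pixels(stats::runif(1, 12, d[1] - 12),
                             stats::runif(1, 12, d[2] - 12),
                             npx, stats::runif(1, 1, 2),
                             stats::runif(1, -90, 90), d)
        if (!is.null(px)) {
          img[px] <- 0.05
          artifact_mask[px] <- TRUE
        }
      }
    }
  }
  list(img = img, artifact_mask = artifact_mask)
}

# interior/rim split of one labelled entity: rim = pixels with a 4-neighbor
# outside the entity footprint
rim_pixels <- function(mask, id_px) {
  d <- dim(mask)
  r <- id_px[, 1]; c <- id_px[, 2]
  id <- mask[id_px]
  nb_same <- function(dr, dc) {
    rr <- r + dr; cc <- c + dc
    inside <- rr >= 1L & rr <= d[1] & cc >= 1L & cc <= d[2]
    out <- logical(length(r))
    out[inside] <- mask[cbind(rr[inside], cc[inside])] == id[inside]
    out
  }
  same <- nb_same(1L, 0L) & nb_same(-1L, 0L) & nb_same(0L, 1L) & nb_same(0L, -1L)
  !same
}

#' Generate a synthetic SEM microstructure image with ground truth
#'
#' Renders the BMU and pore populations of a [synthetic_config()] onto a gray
#' level canvas: BMUs as bright anisotropic plateaus with darker soft rims,
#' pores as dark blobs elongated along the growth-front axis (image vertical),
#' plus Gaussian imaging noise and optional bright-scratch / dark-dirt
#' artifacts. Entities are placed without overlap (1-px halo), large first;
#' entities that cannot be placed are dropped and counted. The rendered pixel
#' area of every placed entity equals its intended area rounded to whole
#' pixels.
#'
#' @param config a [synthetic_config()].
#' @param specimen_id specimen label attached to the image.
#' @return list with elements `image` (a [sem_image()]), `truth` (list:
#'   `bmu_mask`, `pore_mask` integer label rasters; `artifact_mask` logical;
#'   `truth_table` per-entity data.frame; `n_dropped`), and `config`.
#' @export
generate_microstructure_image <- function(config, specimen_id = "synthetic") {
  validate_synthetic_config(config)
  cfg <- config
  d <- cfg$canvas_size
  npx_canvas <- prod(d)
  # analytic expectation of entity pixels under the config (deterministic)
  lnorm_mean <- function(mu, s) exp(mu + s^2 / 2)
  tail_scale <- cfg$bmu_tail_base + cfg$bmu_tail_scale_slope * cfg$temperature
  e_bmu <- cfg$n_bmu *
    ((1 - cfg$tail_fraction) * lnorm_mean(cfg$bulk_size_log_mean,
                                          cfg$bulk_size_log_sd) +
     cfg$tail_fraction * lnorm_mean(log(tail_scale), cfg$tail_size_log_sd))
  e_pore <- cfg$pore_density * npx_canvas * cfg$pixel_area *
    lnorm_mean(log(cfg$pore_base_size), cfg$pore_size_log_sd) *
    exp(cfg$pore_growth_rate * cfg$temperature)
  expected_px <- (e_bmu + e_pore) / cfg$pixel_area
  if (expected_px > 0.6 * npx_canvas) {
    stop(sprintf(paste0("overcrowded configuration: expected entity pixels ",
                        "(%.0f) exceed 60%% of the canvas (%d px); reduce ",
                        "n_bmu (%d) and/or pore_density (%g) or entity sizes"),
                 expected_px, npx_canvas, cfg$n_bmu, cfg$pore_density),
         call. = FALSE)
  }
  out <- with_seed(cfg$seed, {
    bmu <- .sample_bmu(cfg)
    pore <- .sample_pores(cfg)
    # pores first: they are rare and size-biased placement failures of the
    # largest pores would distort the upper size tail that carries the signal
    occ <- matrix(FALSE, d[1], d[2])
    pp <- place_entities(pore, cfg, occ)
    pb <- place_entities(bmu, cfg, pp$occ)
    gl <- cfg$gray_levels
    img <- matrix(gl[["background"]], d[1], d[2])
    # BMUs: plateau interior + rim ring
    bpx <- which(pb$mask > 0L, arr.ind = TRUE)
    if (nrow(bpx)) {
      rim <- rim_pixels(pb$mask, bpx)
      img[bpx[!rim, , drop = FALSE]] <- gl[["plateau"]]
      img[bpx[rim, , drop = FALSE]] <- gl[["rim"]]
    }
    img[pp$mask > 0L] <- gl[["pore"]]
    artifact_mask <- matrix(FALSE, d[1], d[2])
    art <- draw_artifacts(cfg, img, artifact_mask)
    img <- art$img
    rendered <- sum(pb$mask > 0L | pp$mask > 0L)
    if (rendered > 0.9 * npx_canvas) {
      stop(sprintf("rendered occupancy %.0f%% exceeds 90%%: n_bmu = %d, pore_density = %g",
                   100 * rendered / npx_canvas, cfg$n_bmu, cfg$pore_density),
           call. = FALSE)
    }
    if (cfg$noise_sd > 0) {
      img <- img + stats::rnorm(npx_canvas, 0, cfg$noise_sd)
    }
    img <- quantize16(img)
    tt <- rbind(pb$specs, pp$specs)
    list(img = img, bmu_mask = pb$mask, pore_mask = pp$mask,
         artifact_mask = art$artifact_mask,
         truth_table = tt[tt$placed,
                          c("entity_id", "kind", "area_um2", "area_px",
                            "orientation_deg", "elongation", "component",
                            "mask_id")],
         n_dropped = sum(!tt$placed))
  })
  image <- sem_image(out$img, pixel_area = cfg$pixel_area,
                     specimen_id = specimen_id,
                     temperature = cfg$temperature, kind_hint = "etched")
  list(image = image,
       truth = list(bmu_mask = out$bmu_mask, pore_mask = out$pore_mask,
                    artifact_mask = out$artifact_mask,
                    truth_table = out$truth_table,
                    n_dropped = out$n_dropped),
       config = cfg)
}

#' Generate a synthetic two-level Mn/Ca transect
#'
#' Produces an ordered Mn/Ca series with an abrupt changepoint between a high
#' field-growth level and a low laboratory-growth level, with multiplicative
#' lognormal noise (median of each zone equals its level).
#'
#' @param pre_level,post_level zone medians in umol/mol; both must be > 0.
#' @param n_pre,n_post number of laser spots per zone (each >= 3).
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed integer seed.
#' @param specimen_id specimen label.
#' @param spot_spacing spacing of spot midpoints in um (default 85).
#' @return an [mnca_series()] with attribute `true_changepoint`
#'   (`n_pre + 1`, the first laboratory-zone spot).
#' @export
generate_mnca_profile <- function(pre_level, post_level, n_pre, n_post,
                                  noise_cv = 0, seed = 1L,
                                  specimen_id = "synthetic",
                                  spot_spacing = 85) {
  check_scalar(pre_level, "pre_level", positive = TRUE)
  check_scalar(post_level, "post_level", positive = TRUE)
  if (n_pre < 3 || n_post < 3) stop("n_pre and n_post must be >= 3", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  n <- n_pre + n_post
  sdlog <- sqrt(log(1 + noise_cv^2))
  vals <- with_seed(seed, {
    level <- rep(c(pre_level, post_level), c(n_pre, n_post))
    if (sdlog > 0) level * exp(stats::rnorm(n, 0, sdlog)) else level
  })
  s <- mnca_series(specimen_id = specimen_id,
                   position = seq_len(n) * spot_spacing,
                   mnca = vals)
  attr(s, "true_changepoint") <- as.integer(n_pre) + 1L
  s
}
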