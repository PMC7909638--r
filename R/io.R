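#' Calibrated SEM image container
#'
#' A 2-D grayscale raster with intensities in `[0, 1]` (gray value as a proxy
#' for surface topography) plus the pixel-size calibration and specimen
#' metadata. Pixel coordinates are (row, col), row-major, with the growth
#' front along the image vertical.
#'
#' @param pixels numeric matrix with values in `[0, 1]`.
#' @param pixel_area area of one pixel in um^2; must be > 0.
#' @param specimen_id specimen label.
#' @param temperature culturing temperature in degrees C, or `NA` if unknown.
#' @param kind_hint `"etched"` (BMU imaging) or `"polished"` (pore imaging),
#'   or `NA`.
#' @return object of class `sem_image`.
#' @export
sem_image <- function(pixels, pixel_area, specimen_id = NA_character_,
                      temperature = NA_real_, kind_hint = NA_character_) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("pixels must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1) {
    stop("intensities must lie in [0, 1]", call. = FALSE)
  }
  check_scalar(pixel_area, "pixel_area", positive = TRUE)
  structure(list(pixels = pixels, pixel_area = pixel_area,
                 specimen_id = specimen_id, temperature = temperature,
                 kind_hint = kind_hint),
            class = "sem_image")
}

#' @export
print.sem_image <- function(x, ...) {
  cat(sprintf("<sem_image> %d x %d px, pixel_area %g um^2 (%.1f um^2 field), specimen %s, T = %s C\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_area,
              prod(dim(x$pixels)) * x$pixel_area,
              x$specimen_id, format(x$temperature)))
  invisible(x)
}

#' Read a grayscale SEM image
#'
#' Reads an 8- or 16-bit grayscale TIFF or PNG and rescales intensities to
#' `[0, 1]` by dividing by the bit-depth maximum.
#'
#' @param path file path.
#' @param pixel_area pixel calibration in um^2 (required).
#' @inheritParams sem_image
#' @return a [sem_image()].
#' @export
read_sem_image <- function(path, pixel_area, specimen_id = NA_character_,
                           temperature = NA_real_, kind_hint = NA_character_) {
  if (missing(pixel_area)) {
    stop("pixel_area (um^2 per pixel) is required to calibrate the image",
         call. = FALSE)
  }
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 3L) {
    if (dim(a)[3] > 1L && !all(a[, , 1] == a[, , 2])) {
      stop("RGB input: convert the image to grayscale before reading",
           call. = FALSE)
    }
    a <- a[, , 1]
  }
  # EBImage stores (x, y); internal convention is (row, col)
  sem_image(t(a), pixel_area = pixel_area, specimen_id = specimen_id,
            temperature = temperature, kind_hint = kind_hint)
}

#' Write a SEM image as 16-bit grayscale TIFF
#'
#' Intensities are quantized onto the 16-bit grid, so a write/read roundtrip
#' of generator output is bit-identical.
#'
#' @param image a [sem_image()] or numeric matrix in `[0, 1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sem_image <- function(image, path) {
  m <- if (inherits(image, "sem_image")) image$pixels else image
  EBImage::writeImage(EBImage::Image(t(m)), path, type = "tiff",
                      bits.per.sample = 16L)
  invisible(path)
}

#' Read / write integer label masks as 16-bit TIFF
#'
#' Label ids (0 = background) are stored as `id / 65535` gray values, which is
#' lossless for up to 65535 labels.
#'
#' @param mask integer matrix of labels.
#' @param path file path.
#' @return `read_label_mask`: integer matrix; `write_label_mask`: `path`.
#' @export
write_label_mask <- function(mask, path) {
  if (max(mask) > 65535L) stop("more than 65535 labels", call. = FALSE)
  EBImage::writeImage(EBImage::Image(t(mask) / 65535), path, type = "tiff",
                      bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  a <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(a)) == 3L) a <- a[, , 1]
  m <- t(a)
  storage.mode(m) <- "double"
  out <- round(m * 65535)
  storage.mode(out) <- "integer"
  out
}

particle_required_cols <- c("entity_id", "kind", "area_um2", "area_px",
                            "elongation", "specimen_id", "temperature")

#' Read and write per-entity particle tables
#'
#' Particle tables carry one row per measured entity (BMU or pore) with its
#' area in both pixels and um^2, elongation, and specimen/temperature
#' grouping. CSV is the canonical format; XLSX is supported read-only (via
#' readxl) for deposited-style inputs. Unknown columns are preserved. Rows
#' whose pixel area falls below the analysis threshold (`min_pixels`) are not
#' dropped but flagged in attribute `below_threshold` and a warning is
#' raised, mirroring the rule that only particles larger than two pixels
#' enter the analysis.
#'
#' @param path CSV or XLSX file.
#' @param min_pixels analysis threshold in pixels (default 3, i.e. strictly
#'   more than two pixels).
#' @param col_map optional named character vector mapping this package's
#'   column names to the file's column names, e.g.
#'   `c(area_um2 = "Area")`.
#' @return data.frame of particle records with attribute `below_threshold`
#'   (logical vector).
#' @export
read_particle_table <- function(path, min_pixels = 3L, col_map = NULL) {
  ext <- tolower(tools::file_ext(path))
  df <- if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading XLSX requires the readxl package", call. = FALSE)
    }
    as.data.frame(readxl::read_excel(path), stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (!is.null(col_map)) {
    for (ours in names(col_map)) {
      i <- match(col_map[[ours]], names(df))
      if (!is.na(i)) names(df)[i] <- ours
    }
  }
  if (nrow(df) == 0L) {
    warning("empty particle table: ", path, call. = FALSE)
    return(df)
  }
  if (!"area_um2" %in% names(df)) {
    stop("missing area column: expected header 'area_um2' (um^2 per entity)",
         call. = FALSE)
  }
  if ("area_px" %in% names(df)) {
    below <- df$area_px < min_pixels
    if (any(below)) {
      warning(sum(below), " row(s) at or below the analysis threshold (",
              "area_px < ", min_pixels, "); flagged, not dropped",
              call. = FALSE)
    }
  } else {
    below <- rep(NA, nrow(df))
  }
  bad_elong <- "elongation" %in% names(df) &
    any(stats::na.omit(df$elongation) < 1)
  if (isTRUE(bad_elong)) {
    warning("rows with elongation < 1 violate the record invariant",
            call. = FALSE)
  }
  attr(df, "below_threshold") <- below
  df
}

#' @param records data.frame of particle records (as from
#'   [measure_particles()]).
#' @rdname read_particle_table
#' @export
write_particle_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read Mn/Ca transects
#'
#' Reads a table of laser-ablation spots (one row per spot: `specimen_id`,
#' `position`, `mnca` in umol/mol) and returns one ordered [mnca_series()]
#' per specimen. Rows with non-positive Mn/Ca are rejected with a message;
#' duplicate positions within a specimen are an error.
#'
#' @param path CSV or XLSX file.
#' @param col_map optional named character vector mapping `specimen_id`,
#'   `position`, `mnca` to the file's column names.
#' @return named list of [mnca_series()].
#' @export
read_mnca_table <- function(path, col_map = NULL) {
  ext <- tolower(tools::file_ext(path))
  df <- if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading XLSX requires the readxl package", call. = FALSE)
    }
    as.data.frame(readxl::read_excel(path), stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (!is.null(col_map)) {
    for (ours in names(col_map)) {
      i <- match(col_map[[ours]], names(df))
      if (!is.na(i)) names(df)[i] <- ours
    }
  }
  need <- c("specimen_id", "position", "mnca")
  if (!all(need %in% names(df))) {
    stop("Mn/Ca table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- !is.finite(df$mnca) | df$mnca <= 0
  if (any(bad)) {
    warning(sum(bad), " row(s) with non-positive Mn/Ca rejected", call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  out <- lapply(split(df, df$specimen_id), function(s) {
    s <- s[order(s$position), , drop = FALSE]
    if (anyDuplicated(s$position)) {
      stop("duplicate spot positions for specimen ", s$specimen_id[1],
           call. = FALSE)
    }
    mnca_series(specimen_id = s$specimen_id[1], position = s$position,
                mnca = s$mnca)
  })
  out[order(names(out))]
}

#' Write a flat TOML-style key = value configuration echo
#'
#' @param config named list (e.g. a [synthetic_config()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config_echo <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    sprintf("%s = %s", k, paste(format(v, digits = 15), collapse = ", "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# parse a flat key = value config file into a named list of numerics/strings
read_config_echo <- function(path) {
  lines <- grep("=", readLines(path), fixed = TRUE, value = TRUE)
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    k <- trimws(kv[1])
    v <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(v, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[k]] <- if (anyNA(num)) parts else num
  }
  out
}
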