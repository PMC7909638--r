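#' Label connected components of a binary mask
#'
#' Assigns a unique id to every maximal connected set of white pixels.
#' 8-connectivity (diagonals connect) is the default, as is standard for
#' bright blob analysis; 4-connectivity is available. Labels are assigned in
#' raster-scan order of each component's first pixel, so labelling is
#' deterministic.
#'
#' @param mask logical (or 0/1) matrix.
#' @param connectivity 8 (default) or 4.
#' @return list with `labels` (integer matrix, 0 = background) and
#'   `n_components`.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask))
  if (!connectivity %in% c(4L, 8L)) {
    stop("connectivity must be 4 or 8", call. = FALSE)
  }
  w <- as.logical(mask)
  dim(w) <- dim(mask)
  nr <- nrow(w)
  idx <- which(w)
  lab <- matrix(0L, nrow(w), ncol(w))
  if (length(idx) == 0L) return(list(labels = lab, n_components = 0L))
  rank <- integer(length(w))
  rank[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% nr) + 1L
  offs <- list(down = list(1L, r < nr),      # linear-index offset, validity
               right = list(nr, TRUE))
  if (connectivity == 8L) {
    offs$downright <- list(nr + 1L, r < nr)
    offs$upright <- list(nr - 1L, r > 1L)
  }
  edges <- list()
  for (o in offs) {
    nb <- idx + o[[1]]
    ok <- o[[2]] & nb >= 1L & nb <= length(w)
    ok[ok] <- w[nb[ok]]
    if (any(ok)) edges[[length(edges) + 1L]] <- rbind(rank[idx[ok]], rank[nb[ok]])
  }
  g <- igraph::make_graph(as.integer(do.call(cbind, c(edges, list(matrix(integer(0), 2))))),
                          n = length(idx), directed = FALSE)
  memb <- igraph::components(g)$membership
  # relabel components in raster order of first occurrence (idx is sorted)
  relabel <- integer(max(memb))
  first <- !duplicated(memb)
  relabel[memb[first]] <- seq_len(sum(first))
  lab[idx] <- relabel[memb]
  list(labels = lab, n_components = max(relabel))
}

# second-central-moment summary for one pixel set; point-mass convention
pixel_moments <- function(rows, cols) {
  n <- length(rows)
  rbar <- sum(rows) / n
  cbar <- sum(cols) / n
  m20 <- sum((rows - rbar)^2) / n
  m02 <- sum((cols - cbar)^2) / n
  m11 <- sum((rows - rbar) * (cols - cbar)) / n
  tr2 <- (m20 + m02) / 2
  disc <- sqrt(((m20 - m02) / 2)^2 + m11^2)
  list(centroid = c(rbar, cbar), lambda1 = tr2 + disc, lambda2 = tr2 - disc)
}

# elongation (major/minor axis ratio of the moment-equivalent ellipse) for
# one pixel set; degenerate (collinear) sets get elongation = pixel count
elongation_from_moments <- function(rows, cols, tol = 1e-12) {
  mom <- pixel_moments(rows, cols)
  if (mom$lambda2 <= tol * max(mom$lambda1, 1)) {
    list(elongation = length(rows), degenerate = TRUE)
  } else {
    list(elongation = sqrt(mom$lambda1 / mom$lambda2), degenerate = FALSE)
  }
}

# Feret-based elongation: max pairwise distance / min caliper width over the
# convex hull (sensitivity-check alternative to moment axes)
elongation_feret <- function(rows, cols) {
  pts <- unique(cbind(rows, cols))
  if (nrow(pts) < 3L) return(list(elongation = nrow(pts), degenerate = TRUE))
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  d2 <- as.matrix(stats::dist(hp))
  len <- max(d2) + 1  # +1: pixels have unit extent
  nh <- nrow(hp)
  width <- Inf
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    e <- hp[j, ] - hp[i, ]
    nrm <- sqrt(sum(e^2))
    if (nrm < 1e-12) next
    dist_to_edge <- abs((hp[, 1] - hp[i, 1]) * e[2] -
                        (hp[, 2] - hp[i, 2]) * e[1]) / nrm
    width <- min(width, max(dist_to_edge))
  }
  if (!is.finite(width) || width < 1e-9) {
    return(list(elongation = nrow(pts), degenerate = TRUE))
  }
  list(elongation = len / (width + 1), degenerate = FALSE)
}

#' Measure particles in a labelled raster
#'
#' Computes per-component area (pixels and um^2), centroid and elongation
#' (major/minor axis ratio of the second-central-moment equivalent ellipse;
#' Feret calipers available as a sensitivity mode). Components smaller than
#' `min_pixels` (default 3: strictly more than two pixels) or overlapping the
#' exclusion mask are dropped; drop counts are attached as attributes.
#' Degenerate single-file components (zero minor moment) get
#' `elongation = pixel count` and `degenerate = TRUE`.
#'
#' @param labeled result of [label_components()], or an integer label matrix.
#' @param pixel_area um^2 per pixel; must be > 0.
#' @param min_pixels minimum component size in pixels.
#' @param exclusion optional logical matrix marking artifacts to omit.
#' @param method `"moment"` (default) or `"feret"`.
#' @param kind,specimen_id,temperature metadata copied onto every record.
#' @return data.frame of particle records (`entity_id`, `kind`, `area_um2`,
#'   `area_px`, `elongation`, `degenerate`, `centroid_row`, `centroid_col`,
#'   `specimen_id`, `temperature`) with attributes `n_dropped_small`,
#'   `n_dropped_excluded`.
#' @export
measure_particles <- function(labeled, pixel_area, min_pixels = 3L,
                              exclusion = NULL,
                              method = c("moment", "feret"),
                              kind = "bmu", specimen_id = NA_character_,
                              temperature = NA_real_) {
  method <- match.arg(method)
  check_scalar(pixel_area, "pixel_area", positive = TRUE)
  lab <- if (is.list(labeled)) labeled$labels else labeled
  stopifnot(is.matrix(lab))
  idx <- which(lab > 0L)
  empty <- data.frame(entity_id = integer(), kind = character(),
                      area_um2 = numeric(), area_px = integer(),
                      elongation = numeric(), degenerate = logical(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      specimen_id = character(), temperature = numeric(),
                      stringsAsFactors = FALSE)
  if (length(idx) == 0L) {
    attr(empty, "n_dropped_small") <- 0L
    attr(empty, "n_dropped_excluded") <- 0L
    return(empty)
  }
  ids <- lab[idx]
  rows <- ((idx - 1L) %% nrow(lab)) + 1L
  cols <- ((idx - 1L) %/% nrow(lab)) + 1L
  npx <- tabulate(ids)
  excluded_ids <- integer(0)
  if (!is.null(exclusion)) {
    if (!identical(dim(exclusion), dim(lab))) {
      stop("exclusion mask shape mismatch", call. = FALSE)
    }
    excluded_ids <- unique(ids[as.logical(exclusion)[idx]])
  }
  all_ids <- which(npx > 0L)
  keep_ids <- setdiff(all_ids[npx[all_ids] >= min_pixels], excluded_ids)
  n_small <- sum(npx[all_ids] < min_pixels & !(all_ids %in% excluded_ids))
  if (length(keep_ids) == 0L) {
    attr(empty, "n_dropped_small") <- n_small
    attr(empty, "n_dropped_excluded") <- length(excluded_ids)
    return(empty)
  }
  keep <- ids %in% keep_ids
  by_id <- split(seq_along(ids)[keep], ids[keep])
  recs <- lapply(by_id, function(ii) {
    r <- rows[ii]; c <- cols[ii]
    el <- if (method == "moment") elongation_from_moments(r, c)
          else elongation_feret(r, c)
    data.frame(entity_id = ids[ii[1]], area_px = length(ii),
               elongation = el$elongation, degenerate = el$degenerate,
               centroid_row = mean(r), centroid_col = mean(c))
  })
  out <- do.call(rbind, recs)
  out <- out[order(out$entity_id), , drop = FALSE]
  rownames(out) <- NULL
  out <- data.frame(entity_id = out$entity_id, kind = kind,
                    area_um2 = out$area_px * pixel_area,
                    area_px = out$area_px, elongation = out$elongation,
                    degenerate = out$degenerate,
                    centroid_row = out$centroid_row,
                    centroid_col = out$centroid_col,
                    specimen_id = specimen_id, temperature = temperature,
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped_small") <- n_small
  attr(out, "n_dropped_excluded") <- length(excluded_ids)
  out
}

#' Per-specimen particle summary
#'
#' @param records particle records of one specimen.
#' @param region_area analysed region area in um^2 (optional).
#' @param probs percentiles to report.
#' @return one-row data.frame: count, max area, requested percentiles,
#'   analysed region area.
#' @export
summarize_specimen <- function(records, region_area = NA_real_,
                               probs = c(0.5, 0.9, 0.99, 0.999)) {
  if (nrow(records) > 0 && length(unique(records$specimen_id)) > 1L) {
    stop("records must share one specimen", call. = FALSE)
  }
  out <- data.frame(specimen_id = if (nrow(records)) records$specimen_id[1]
                                  else NA_character_,
                    n = nrow(records),
                    max_area_um2 = if (nrow(records)) max(records$area_um2)
                                   else NA_real_,
                    region_area_um2 = region_area)
  for (p in probs) {
    out[[sprintf("p%g", 100 * p)]] <-
      if (nrow(records)) sort_index_quantile(records$area_um2, p) else NA_real_
  }
  out
}

# order-statistic quantile: value at rank ceiling(p * n) of the sorted sample
sort_index_quantile <- function(x, p) {
  s <- sort(x)
  s[max(1L, ceiling(p * length(s)))]
}
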