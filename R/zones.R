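#' Ordered Mn/Ca transect of one specimen
#'
#' @param specimen_id specimen label.
#' @param position strictly increasing spot positions (spot index or um along
#'   the growth axis).
#' @param mnca Mn/Ca per spot in umol/mol; all values must be > 0.
#' @return object of class `mnca_series`.
#' @export
mnca_series <- function(specimen_id, position, mnca) {
  if (length(position) != length(mnca)) {
    stop("position and mnca must have equal length", call. = FALSE)
  }
  if (any(diff(position) <= 0)) {
    stop("positions must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(mnca)) || any(mnca <= 0)) {
    stop("mnca values must be positive", call. = FALSE)
  }
  structure(list(specimen_id = specimen_id, position = position, mnca = mnca),
            class = "mnca_series")
}

#' @export
print.mnca_series <- function(x, ...) {
  cat(sprintf("<mnca_series> %s: %d spots, Mn/Ca %.3g-%.3g umol/mol\n",
              x$specimen_id, length(x$mnca), min(x$mnca), max(x$mnca)))
  invisible(x)
}

# inner quartile range
iqr1 <- function(x) unname(diff(stats::quantile(x, c(0.25, 0.75))))

#' Detect the field-to-laboratory changepoint in a Mn/Ca transect
#'
#' Searches the single changepoint that minimizes the summed absolute
#' deviation from the segment medians (binary segmentation on a robust L1
#' cost), equivalent to maximizing the between-segment contrast. Because the
#' laboratory tanks held oxygen-rich water, the laboratory zone must show the
#' *lower* Mn/Ca level: if the detected second segment is not a decrease the
#' split is flagged `no_lab_zone_signature` (also for constant series).
#'
#' @param series an [mnca_series()] (or numeric vector), length >= 6.
#' @param min_segment minimum spots per zone (default 3).
#' @return object of class `zone_split`: `changepoint` (index of the first
#'   laboratory-zone spot), `position` (its coordinate), `pre_median`,
#'   `pre_iqr`, `post_median`, `post_iqr`, `flag` (`"ok"` or
#'   `"no_lab_zone_signature"`), `specimen_id`.
#' @export
detect_changepoint <- function(series, min_segment = 3L) {
  x <- if (inherits(series, "mnca_series")) series$mnca else series
  n <- length(x)
  if (n < 6L) stop("series too short: need at least 6 spots", call. = FALSE)
  ks <- seq(min_segment + 1L, n - min_segment + 1L)  # first index of zone 2
  cost <- vapply(ks, function(k) {
    pre <- x[seq_len(k - 1L)]
    post <- x[k:n]
    sum(abs(pre - stats::median(pre))) + sum(abs(post - stats::median(post)))
  }, numeric(1))
  k <- ks[which.min(cost)]
  pre <- x[seq_len(k - 1L)]
  post <- x[k:n]
  flag <- if (stats::median(post) < stats::median(pre)) "ok"
          else "no_lab_zone_signature"
  structure(list(changepoint = k,
                 position = if (inherits(series, "mnca_series"))
                   series$position[k] else k,
                 pre_median = stats::median(pre), pre_iqr = iqr1(pre),
                 post_median = stats::median(post), post_iqr = iqr1(post),
                 flag = flag,
                 specimen_id = if (inherits(series, "mnca_series"))
                   series$specimen_id else NA_character_),
            class = "zone_split")
}

#' @export
print.zone_split <- function(x, ...) {
  cat(sprintf("<zone_split> %s: changepoint at spot %d [%s]; pre %.4g +/- %.3g, post %.4g +/- %.3g (median +/- 1 IQR)\n",
              x$specimen_id, x$changepoint, x$flag,
              x$pre_median, x$pre_iqr, x$post_median, x$post_iqr))
  invisible(x)
}

#' Pooled per-zone Mn/Ca summary across specimens
#'
#' Pools all spots of each zone across specimens (default) or averages the
#' per-specimen zone medians, and reports median and one inner quartile
#' range per zone.
#'
#' @param series_list list of [mnca_series()].
#' @param splits list of matching [detect_changepoint()] results.
#' @param pooled pool spots across specimens (default) rather than averaging
#'   per-specimen medians.
#' @return data.frame with one row per zone (`field`, `laboratory`):
#'   `median`, `iqr`, `n`.
#' @export
zone_summary <- function(series_list, splits, pooled = TRUE) {
  if (length(series_list) != length(splits)) {
    stop("series_list and splits must match", call. = FALSE)
  }
  pre <- list(); post <- list()
  for (i in seq_along(series_list)) {
    x <- series_list[[i]]$mnca
    k <- splits[[i]]$changepoint
    if (k < 2L || k > length(x)) stop("invalid split", call. = FALSE)
    pre[[i]] <- x[seq_len(k - 1L)]
    post[[i]] <- x[k:length(x)]
  }
  summarize <- function(zones) {
    if (pooled) {
      v <- unlist(zones)
      c(median = stats::median(v), iqr = iqr1(v), n = length(v))
    } else {
      med <- vapply(zones, stats::median, numeric(1))
      c(median = mean(med), iqr = mean(vapply(zones, iqr1, numeric(1))),
        n = length(unlist(zones)))
    }
  }
  out <- rbind(field = summarize(pre), laboratory = summarize(post))
  data.frame(zone = rownames(out), median = out[, "median"],
             iqr = out[, "iqr"], n = as.integer(out[, "n"]),
             row.names = NULL)
}
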