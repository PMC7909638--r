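#' Empirical cumulative distribution function with quantile queries
#'
#' Right-continuous step ECDF of entity sizes, plus an order-statistic
#' quantile accessor (`quantile_fun(p)` returns the sorted value at rank
#' `ceiling(p * n)`), matching the sort-and-index definition.
#'
#' @param values numeric vector, `n >= 1`.
#' @return list of class `size_ecdf`: `fun` (the step function), `quantile`
#'   (function of p), `sorted`, `n`.
#' @export
size_ecdf <- function(values) {
  if (length(values) < 1L) stop("empty sample", call. = FALSE)
  s <- sort(values)
  structure(list(fun = stats::ecdf(values),
                 quantile = function(p) vapply(p, function(pp)
                   s[max(1L, ceiling(pp * length(s)))], numeric(1)),
                 sorted = s, n = length(s)),
            class = "size_ecdf")
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |F_a - F_b|` computed directly from the two ECDFs evaluated at
#' every pooled observation; the two-sided asymptotic p-value comes from
#' [stats::ks.test()].
#'
#' @param a,b numeric samples, each with at least 2 observations.
#' @return list `(D, p, n_a, n_b)`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  sa <- sort(a); sb <- sort(b)
  pts <- c(sa, sb)
  fa <- findInterval(pts, sa) / length(sa)
  fb <- findInterval(pts, sb) / length(sb)
  D <- max(abs(fa - fb))
  p <- suppressWarnings(stats::ks.test(a, b, exact = FALSE)$p.value)
  list(D = D, p = p, n_a = length(a), n_b = length(b))
}

#' Largest-N subset of a temperature group
#'
#' Returns the `n` largest entities by area, pooled across the group's
#' specimens. Ties at the selection boundary are broken deterministically by
#' (specimen id, entity id). If the group holds fewer than `n` records, all
#' are returned with a warning.
#'
#' @param records particle records (data.frame with `area_um2`; optionally
#'   `kind`, `specimen_id`, `entity_id`).
#' @param n subset size (default 15); must be > 0.
#' @param kind optional filter (`"bmu"` or `"pore"`).
#' @return data.frame of the selected records, largest first.
#' @export
top_n_largest <- function(records, n = 15L, kind = NULL) {
  if (n <= 0) stop("n must be > 0", call. = FALSE)
  if (!is.null(kind) && "kind" %in% names(records)) {
    records <- records[records$kind == kind, , drop = FALSE]
  }
  if (nrow(records) == 0L) stop("empty group", call. = FALSE)
  sid <- if ("specimen_id" %in% names(records)) records$specimen_id else ""
  eid <- if ("entity_id" %in% names(records)) records$entity_id else
    seq_len(nrow(records))
  ord <- order(-records$area_um2, sid, eid)
  if (nrow(records) < n) {
    warning(sprintf("group has only %d record(s); returning all", nrow(records)),
            call. = FALSE)
    n <- nrow(records)
  }
  out <- records[ord[seq_len(n)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; two-sided asymptotic
#' p-value; no multiple-testing correction. `r_squared` is the square of r.
#'
#' @param x,y paired numeric vectors, `n >= 3`.
#' @return list `(r, r_squared, p, n)`; `r` is `NA` (with a warning) when
#'   either variable has zero variance.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("x and y must be paired with n >= 3", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("zero variance: Spearman correlation undefined", call. = FALSE)
    return(list(r = NA_real_, r_squared = NA_real_, p = NA_real_,
                n = length(x)))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  r <- unname(ct$estimate)
  list(r = r, r_squared = r^2, p = ct$p.value, n = length(x))
}

#' Correlation to temperature as a function of subset size
#'
#' For each candidate subset size `n`, pools the `n` largest entities of each
#' temperature group and computes the Spearman correlation between their
#' areas and the group temperatures. The correlation typically decreases as
#' the subset grows, because only the upper size tail carries the
#' temperature signal.
#'
#' @param records pooled particle records with columns `area_um2`,
#'   `temperature` (and optionally `kind`).
#' @param n_values subset sizes to evaluate.
#' @param kind optional filter.
#' @return data.frame `(n, spearman_r, p, n_pairs)`.
#' @export
threshold_sensitivity <- function(records, n_values = c(15L, 50L, 150L, 500L),
                                  kind = NULL) {
  if (!is.null(kind) && "kind" %in% names(records)) {
    records <- records[records$kind == kind, , drop = FALSE]
  }
  groups <- split(records, records$temperature)
  if (length(groups) < 2L) stop("need at least 2 temperature groups", call. = FALSE)
  out <- lapply(n_values, function(n) {
    sub <- do.call(rbind, lapply(groups, function(g)
      suppressWarnings(top_n_largest(g, n))))
    sc <- spearman_cor(sub$area_um2, sub$temperature)
    data.frame(n = n, spearman_r = sc$r, p = sc$p, n_pairs = sc$n)
  })
  do.call(rbind, out)
}
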