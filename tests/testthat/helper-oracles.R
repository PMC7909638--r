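# Independent brute-force oracles used across the suite. These deliberately
# take the slow, obvious route so they share no code with the implementation.

# KS statistic: evaluate both ECDFs at every pooled observation by counting.
ks_oracle <- function(a, b) {
  pts <- c(a, b)
  d <- 0
  for (t in pts) {
    fa <- sum(a <= t) / length(a)
    fb <- sum(b <= t) / length(b)
    d <- max(d, abs(fa - fb))
  }
  d
}

# Moment-ellipse elongation via an explicit per-pixel loop and LAPACK eigen.
elongation_oracle <- function(rows, cols) {
  n <- length(rows)
  rbar <- 0; cbar <- 0
  for (i in seq_len(n)) { rbar <- rbar + rows[i]; cbar <- cbar + cols[i] }
  rbar <- rbar / n; cbar <- cbar / n
  m20 <- 0; m02 <- 0; m11 <- 0
  for (i in seq_len(n)) {
    m20 <- m20 + (rows[i] - rbar)^2
    m02 <- m02 + (cols[i] - cbar)^2
    m11 <- m11 + (rows[i] - rbar) * (cols[i] - cbar)
  }
  ev <- eigen(matrix(c(m20, m11, m11, m02) / n, 2, 2), symmetric = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev, 1)) return(NA_real_)  # degenerate
  sqrt(max(ev) / min(ev))
}

# random connected-ish pixel set (unique pixels on a small grid)
random_pixel_set <- function(n, grid = 15L) {
  stopifnot(n <= grid * grid)
  lin <- sample.int(grid * grid, n)
  cbind(row = ((lin - 1L) %% grid) + 1L, col = ((lin - 1L) %/% grid) + 1L)
}

# rasterized disk mask
disk_mask <- function(radius, pad = 3L) {
  n <- 2L * (radius + pad) + 1L
  ctr <- radius + pad + 1L
  m <- matrix(FALSE, n, n)
  for (r in seq_len(n)) for (c in seq_len(n)) {
    if ((r - ctr)^2 + (c - ctr)^2 <= radius^2) m[r, c] <- TRUE
  }
  m
}

# population-level particle table for a temperature ladder (no rendering)
ladder_population_records <- function(seed, temperatures = c(1, 3, 6, 9, 12, 15),
                                      n_specimens = 3L, ...) {
  recs <- list()
  for (ti in seq_along(temperatures)) {
    for (s in seq_len(n_specimens)) {
      cfg <- synthetic_config(temperature = temperatures[ti],
                              seed = (seed * 1009 + ti * 101 + s) %% 2147483647,
                              ...)
      b <- sample_bmu_population(cfg)
      p <- sample_pore_population(cfg)
      keep <- c("entity_id", "kind", "area_um2")
      df <- rbind(b[, keep], p[, keep])
      df$specimen_id <- sprintf("T%02d-S%d", round(temperatures[ti]), s)
      df$temperature <- temperatures[ti]
      recs[[length(recs) + 1L]] <- df
    }
  }
  do.call(rbind, recs)
}
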