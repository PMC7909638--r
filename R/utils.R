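#' @keywords internal
"_PACKAGE"

# Run code under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so generators behave as pure functions
# of (config, seed).
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

# Mirror-pad a matrix by k pixels on every side (border handling by reflection).
pad_reflect <- function(m, k) {
  stopifnot(is.matrix(m), k >= 1, k < nrow(m), k < ncol(m))
  ri <- c(rev(seq_len(k) + 1L), seq_len(nrow(m)), nrow(m) - seq_len(k))
  ci <- c(rev(seq_len(k) + 1L), seq_len(ncol(m)), ncol(m) - seq_len(k))
  m[ri, ci, drop = FALSE]
}

crop_center <- function(m, k, nr, nc) {
  m[k + seq_len(nr), k + seq_len(nc), drop = FALSE]
}

check_scalar <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    stop(sprintf("%s must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("%s must be > 0", name), call. = FALSE)
  }
  invisible(x)
}

# Quantize intensities onto the 16-bit grid used by the TIFF writers, so that a
# write/read roundtrip is bit-identical.
quantize16 <- function(m) {
  round(pmin(pmax(m, 0), 1) * 65535) / 65535
}
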