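#' Multiscale per-pixel feature bank
#'
#' Computes the feature stack used by the pixel classifier: the raw intensity
#' plus, at each smoothing scale sigma, (1) the Gaussian-smoothed intensity,
#' (2) the gradient magnitude, (3) the Laplacian of Gaussian, (4) the largest
#' eigenvalue of the structure tensor and (5) the largest (by magnitude)
#' eigenvalue of the Hessian — capturing intensity, texture, gradients and
#' edges. With the default 5-scale ladder this yields 1 + 5 x 5 = 26 features
#' per pixel. Image borders are handled by mirror reflection.
#'
#' @param image a [sem_image()] or numeric matrix.
#' @param scales smoothing scales sigma in pixels; all must be > 0.
#' @return numeric array `(rows, cols, features)` with named feature slices.
#' @export
compute_feature_stack <- function(image,
                                  scales = c(0.7, 1.0, 1.6, 3.5, 5.0)) {
  m <- if (inherits(image, "sem_image")) image$pixels else image
  stopifnot(is.matrix(m))
  if (any(!is.finite(scales)) || any(scales <= 0)) {
    stop("scales must be positive and finite", call. = FALSE)
  }
  nr <- nrow(m); nc <- ncol(m)
  k <- min(ceiling(4 * max(scales)) + 2L, nr - 1L, nc - 1L)
  pad <- pad_reflect(m, k)
  nfeat <- 1L + 5L * length(scales)
  out <- array(NA_real_, dim = c(nr, nc, nfeat))
  nm <- character(nfeat)
  out[, , 1] <- m
  nm[1] <- "raw"
  j <- 1L
  for (s in scales) {
    sm <- ebi_gblur(pad, s)
    gr <- shift_mat(sm, 1L, 0L); gl <- shift_mat(sm, -1L, 0L)
    gd <- shift_mat(sm, 0L, 1L); gu <- shift_mat(sm, 0L, -1L)
    gx <- (gr - gl) / 2    # derivative along rows
    gy <- (gd - gu) / 2    # derivative along cols
    dxx <- gr - 2 * sm + gl
    dyy <- gd - 2 * sm + gu
    dxy <- (shift_mat(sm, 1L, 1L) - shift_mat(sm, 1L, -1L) -
            shift_mat(sm, -1L, 1L) + shift_mat(sm, -1L, -1L)) / 4
    gradmag <- sqrt(gx^2 + gy^2)
    logf <- dxx + dyy
    # structure tensor: gaussian-integrated outer product of the gradient
    jxx <- ebi_gblur(gx * gx, s)
    jyy <- ebi_gblur(gy * gy, s)
    jxy <- ebi_gblur(gx * gy, s)
    st_big <- (jxx + jyy) / 2 + sqrt(((jxx - jyy) / 2)^2 + jxy^2)
    tr2 <- (dxx + dyy) / 2
    disc <- sqrt(((dxx - dyy) / 2)^2 + dxy^2)
    h1 <- tr2 + disc
    h2 <- tr2 - disc
    hess_big <- ifelse(abs(h1) >= abs(h2), h1, h2)
    feats <- list(smooth = sm, gradmag = gradmag, log = logf,
                  structure = st_big, hessian = hess_big)
    for (f in names(feats)) {
      j <- j + 1L
      out[, , j] <- crop_center(feats[[f]], k, nr, nc)
      nm[j] <- sprintf("%s_s%g", f, s)
    }
  }
  dimnames(out) <- list(NULL, NULL, nm)
  stopifnot(all(is.finite(out)))
  out
}

# gaussian blur on a plain matrix via EBImage (operates on padded images, so
# EBImage's own boundary handling never reaches real pixels)
ebi_gblur <- function(m, sigma) {
  EBImage::imageData(EBImage::gblur(EBImage::Image(m), sigma = sigma))
}

# shift a matrix by (dr, dc) with edge replication (only used on padded data)
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

features_as_table <- function(stack, idx = NULL) {
  d <- dim(stack)
  x <- matrix(stack, nrow = d[1] * d[2], ncol = d[3])
  colnames(x) <- dimnames(stack)[[3]]
  if (!is.null(idx)) x <- x[idx, , drop = FALSE]
  as.data.frame(x)
}
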