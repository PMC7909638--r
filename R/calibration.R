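#' Calibration models between entity size and temperature
#'
#' `fit_linear` fits `S = alpha + beta * T` by ordinary least squares;
#' `fit_exponential` fits `S = a * exp(b * T)` by nonlinear least squares
#' (Levenberg-Marquardt), initialized from the log-linear fit (or a two-point
#' estimate when non-positive areas preclude the log initialization).
#' Both report parameter standard errors from the fit covariance, the
#' Spearman rank correlation of the data (with its square), the regression
#' r-squared, and residual diagnostics: a sign-runs test of the residuals and
#' the negativity of predictions over 0-16 degrees C — the criteria under
#' which a linear pore model fails while the exponential one does not.
#'
#' @param temperatures,areas paired numeric vectors; at least 3 distinct
#'   temperatures.
#' @return object of class `calibration_model`: `kind`, `coef` (named
#'   `alpha`/`beta` or `a`/`b`), `se`, `vcov`, `spearman_r`, `spearman_r2`,
#'   `model_r2`, `p_value` (of the rank correlation), `n`, `residuals`,
#'   `fitted`, `diagnostics` (`runs_p`, `n_runs`, `min_prediction_0_16`,
#'   `negative_predictions`), and the data.
#' @export
fit_linear <- function(temperatures, areas) {
  check_calibration_input(temperatures, areas)
  fit <- stats::lm(areas ~ temperatures)
  cf <- stats::coef(fit)
  names(cf) <- c("alpha", "beta")
  vc <- suppressWarnings(stats::vcov(fit))  # summary.lm warns on perfect fits
  dimnames(vc) <- list(names(cf), names(cf))
  new_calibration_model("linear", cf, vc, temperatures, areas,
                        fitted = unname(stats::fitted(fit)),
                        model_r2 = suppressWarnings(summary(fit)$r.squared))
}

#' @rdname fit_linear
#' @export
fit_exponential <- function(temperatures, areas) {
  check_calibration_input(temperatures, areas)
  if (stats::var(areas) == 0) {
    # degenerate flat response: S = mean(areas) * exp(0 * T)
    cf <- c(a = mean(areas), b = 0)
    vc <- matrix(0, 2, 2, dimnames = list(names(cf), names(cf)))
    return(new_calibration_model("exponential", cf, vc, temperatures, areas,
                                 fitted = areas, model_r2 = NA_real_))
  }
  start <- exp_start(temperatures, areas)
  fit <- minpack.lm::nlsLM(areas ~ a * exp(b * temperatures),
                           start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  vc <- stats::vcov(fit)
  fitted <- unname(stats::fitted(fit))
  ss_res <- sum((areas - fitted)^2)
  ss_tot <- sum((areas - mean(areas))^2)
  new_calibration_model("exponential", cf, vc, temperatures, areas,
                        fitted = fitted,
                        model_r2 = 1 - ss_res / ss_tot)
}

check_calibration_input <- function(temperatures, areas) {
  if (length(temperatures) != length(areas)) {
    stop("temperatures and areas must be paired", call. = FALSE)
  }
  if (length(unique(temperatures)) < 3L) {
    stop("at least 3 distinct temperatures are required", call. = FALSE)
  }
  if (any(!is.finite(temperatures)) || any(!is.finite(areas))) {
    stop("non-finite calibration data", call. = FALSE)
  }
  invisible(NULL)
}

# starting values for the exponential fit: log-linear regression, falling
# back to a two-point solve through the group means at the extreme
# temperatures when areas are not all positive
exp_start <- function(temperatures, areas) {
  if (all(areas > 0)) {
    lf <- stats::lm(log(areas) ~ temperatures)
    list(a = exp(unname(stats::coef(lf)[1])), b = unname(stats::coef(lf)[2]))
  } else {
    two_point_exponential(temperatures, areas)
  }
}

# closed-form exponential through the mean areas at the lowest and highest
# temperature: b = log(S_hi / S_lo) / (T_hi - T_lo)
two_point_exponential <- function(temperatures, areas) {
  tl <- min(temperatures); th <- max(temperatures)
  sl <- mean(areas[temperatures == tl]); sh <- mean(areas[temperatures == th])
  if (sl <= 0 || sh <= 0) return(list(a = max(mean(areas), 1e-6), b = 0.1))
  b <- log(sh / sl) / (th - tl)
  list(a = sl * exp(-b * tl), b = b)
}

new_calibration_model <- function(kind, cf, vc, temperatures, areas, fitted,
                                  model_r2) {
  res <- areas - fitted
  sc <- suppressWarnings(spearman_cor(areas, temperatures))
  grid <- seq(0, 16, by = 0.25)
  pred_grid <- forward_model(kind, cf, grid)
  structure(list(kind = kind, coef = cf, se = sqrt(diag(vc)), vcov = vc,
                 spearman_r = sc$r, spearman_r2 = sc$r_squared,
                 model_r2 = model_r2, p_value = sc$p, n = length(areas),
                 residuals = res, fitted = fitted,
                 temperatures = temperatures, areas = areas,
                 diagnostics = c(runs_test(res),
                                 list(min_prediction_0_16 = min(pred_grid),
                                      negative_predictions = any(pred_grid < 0)))),
            class = "calibration_model")
}

forward_model <- function(kind, cf, t) {
  if (kind == "linear") cf[["alpha"]] + cf[["beta"]] * t
  else cf[["a"]] * exp(cf[["b"]] * t)
}

# Wald-Wolfowitz runs test on residual signs (normal approximation);
# operationalizes "non-randomly distributed residuals"
runs_test <- function(res) {
  s <- sign(res)
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0); n <- n1 + n2
  runs <- if (n > 0) 1L + sum(diff(s) != 0) else 0L
  if (n1 == 0L || n2 == 0L || n < 3L) {
    return(list(n_runs = runs, runs_p = NA_real_))
  }
  mu <- 2 * n1 * n2 / n + 1
  sigma2 <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  z <- (runs - mu) / sqrt(sigma2)
  list(n_runs = runs, runs_p = 2 * stats::pnorm(-abs(z)))
}

#' @export
print.calibration_model <- function(x, ...) {
  eq <- if (x$kind == "linear") {
    sprintf("S = %.4g + %.4g T", x$coef[["alpha"]], x$coef[["beta"]])
  } else {
    sprintf("S = %.4g exp(%.4g T)", x$coef[["a"]], x$coef[["b"]])
  }
  cat(sprintf("<calibration_model: %s> %s (n = %d)\n", x$kind, eq, x$n))
  cat(sprintf("  Spearman r = %.3f (r^2 = %.3f, p = %.3g); regression r^2 = %.3f\n",
              x$spearman_r, x$spearman_r2, x$p_value, x$model_r2))
  cat(sprintf("  residual sign-runs p = %.3g; negative predictions on [0,16] C: %s\n",
              x$diagnostics$runs_p, x$diagnostics$negative_predictions))
  invisible(x)
}

#' Model prediction with a +/- 2 SE band
#'
#' @param object a [fit_linear()] / [fit_exponential()] model.
#' @param temperature temperatures at which to evaluate the fit.
#' @param ... unused.
#' @return data.frame `(temperature, fit, se, lower, upper)` where the band
#'   is fit +/- 2 standard errors (delta method from the parameter
#'   covariance).
#' @export
predict.calibration_model <- function(object, temperature, ...) {
  cf <- object$coef
  fit <- forward_model(object$kind, cf, temperature)
  gr <- if (object$kind == "linear") {
    cbind(1, temperature)
  } else {
    cbind(exp(cf[["b"]] * temperature),
          cf[["a"]] * temperature * exp(cf[["b"]] * temperature))
  }
  se <- sqrt(rowSums((gr %*% object$vcov) * gr))
  data.frame(temperature = temperature, fit = fit, se = se,
             lower = fit - 2 * se, upper = fit + 2 * se)
}

#' Invert a calibration model: temperature from entity size
#'
#' Inverts the fitted size-temperature model and propagates the +/- 2 SE
#' prediction band into a temperature interval. Predictions falling outside
#' the calibrated range (1-15 degrees C) are returned with
#' `extrapolated = TRUE`.
#'
#' @param model a `calibration_model`.
#' @param area entity size (um^2); must be > 0 for exponential models.
#' @param range calibrated temperature range.
#' @return data.frame `(area, temperature, lower, upper, extrapolated)`.
#' @export
predict_temperature <- function(model, area, range = c(1, 15)) {
  stopifnot(inherits(model, "calibration_model"))
  cf <- model$coef
  invert <- function(s) {
    if (model$kind == "linear") {
      if (cf[["beta"]] == 0) return(NA_real_)
      (s - cf[["alpha"]]) / cf[["beta"]]
    } else {
      if (s <= 0 || cf[["b"]] == 0) return(NA_real_)
      log(s / cf[["a"]]) / cf[["b"]]
    }
  }
  band_root <- function(s, side) {
    f <- function(t) {
      pr <- predict.calibration_model(model, t)
      (if (side == "lower") pr$upper else pr$lower) - s
    }
    lo <- -20; hi <- 40
    if (is.na(f(lo)) || is.na(f(hi)) || f(lo) * f(hi) > 0) return(NA_real_)
    stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
  }
  out <- lapply(area, function(s) {
    if (model$kind == "exponential" && s <= 0) {
      stop("area must be > 0 for exponential model inversion", call. = FALSE)
    }
    t0 <- invert(s)
    data.frame(area = s, temperature = t0,
               lower = band_root(s, "lower"), upper = band_root(s, "upper"),
               extrapolated = is.na(t0) || t0 < range[1] || t0 > range[2])
  })
  do.call(rbind, out)
}
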