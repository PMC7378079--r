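#' Normalize and truncate a DSF melting curve
#'
#' SYPRO-Orange-type melt curves rise through the unfolding transition and
#' then decline as the dye-bound aggregates fall apart; the decline breaks
#' the Boltzmann form, so points after the global fluorescence maximum are
#' dropped before fitting. The retained segment is min-max normalized to
#' \[0, 1\] (the Boltzmann fit is invariant to this affine rescaling, so
#' normalization only stabilizes the optimizer and makes baselines
#' comparable across wells).
#'
#' @param curve Data frame with columns `temperature` (degrees C, strictly
#'   increasing) and `fluorescence` (RFU).
#' @return The truncated, normalized curve (same columns).
#' @export
normalize_melt <- function(curve) {
  curve <- tibble::as_tibble(curve)
  if (!all(c("temperature", "fluorescence") %in% names(curve))) {
    abort("Melt curve needs columns temperature and fluorescence",
          class = "fretscreen_error_format")
  }
  if (is.unsorted(curve$temperature, strictly = TRUE)) {
    abort("Temperatures must be strictly increasing",
          class = "fretscreen_error_validation")
  }
  if (diff(range(curve$fluorescence)) == 0) {
    abort("Constant fluorescence: no melting transition",
          class = "fretscreen_error_no_transition")
  }
  peak <- which.max(curve$fluorescence)
  if (peak == 1) {
    abort("Fluorescence maximum at the first point: no melting transition",
          class = "fretscreen_error_no_transition")
  }
  kept <- curve[seq_len(peak), ]
  rng <- range(kept$fluorescence)
  kept$fluorescence <- (kept$fluorescence - rng[1]) / (rng[2] - rng[1])
  kept
}

#' Fit a Boltzmann sigmoid to a melting curve
#'
#' Fits \deqn{y = b_{low} + \frac{b_{high} - b_{low}}{1 + e^{(T_m - T)/k}}}
#' to a normalized, truncated melt curve; Tm is the inflection (midpoint
#' of the baselines) and k the transition width in degrees C.
#'
#' @param curve Data frame with `temperature` and `fluorescence` columns;
#'   normalized and truncated with [normalize_melt()] unless
#'   `normalize = FALSE`.
#' @param normalize Apply [normalize_melt()] first (default).
#' @return An object of class `melt_fit`: `tm`, `slope`,
#'   `baseline_low`, `baseline_high`, `rss`, `n`, `converged`. Supports
#'   [tidy()], [glance()] and [ggplot2::autoplot()].
#' @export
fit_melt <- function(curve, normalize = TRUE) {
  if (normalize) curve <- normalize_melt(curve)
  curve <- tibble::as_tibble(curve)
  if (nrow(curve) < 15) {
    abort("Need at least 15 points to fit a melting transition",
          class = "fretscreen_error_validation")
  }
  y <- curve$fluorescence
  tt <- curve$temperature
  mid <- (max(y) + min(y)) / 2
  tm0 <- tt[which.min(abs(y - mid))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      fluorescence ~ bl + (bh - bl) / (1 + exp((tm - temperature) / k)),
      data = curve,
      start = list(bl = min(y), bh = max(y), tm = tm0, k = 2),
      lower = c(-Inf, -Inf, min(tt), 1e-3),
      upper = c(Inf, Inf, max(tt), diff(range(tt))),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    abort("Boltzmann fit did not converge", class = "fretscreen_error_fit")
  }
  cf <- coef(fit)
  structure(list(tm = cf[["tm"]], slope = cf[["k"]],
                 baseline_low = cf[["bl"]], baseline_high = cf[["bh"]],
                 rss = sum(resid(fit)^2), n = nrow(curve),
                 converged = TRUE, data = curve),
            class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("Boltzmann melt fit: Tm = %.2f C (width %.2f C), RSS = %.3g on %d points\n",
              x$tm, x$slope, x$rss, x$n))
  invisible(x)
}

#' @rdname fit_melt
#' @param x,object A `melt_fit` object.
#' @param ... Unused.
#' @export
tidy.melt_fit <- function(x, ...) {
  tibble::tibble(term = c("tm", "slope", "baseline_low", "baseline_high"),
                 estimate = c(x$tm, x$slope, x$baseline_low, x$baseline_high))
}

#' @rdname fit_melt
#' @export
glance.melt_fit <- function(x, ...) {
  tibble::tibble(tm = x$tm, slope = x$slope, rss = x$rss, n = x$n,
                 converged = x$converged)
}

#' @rdname fit_melt
#' @export
autoplot.melt_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble::tibble(temperature = seq(min(d$temperature),
                                           max(d$temperature), by = 0.1))
  grid$fluorescence <- object$baseline_low +
    (object$baseline_high - object$baseline_low) /
    (1 + exp((object$tm - grid$temperature) / object$slope))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$temperature,
                                  y = .data$fluorescence)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, colour = "#b2182b") +
    ggplot2::geom_vline(xintercept = object$tm, linetype = "dotted") +
    ggplot2::labs(x = "Temperature (°C)", y = "Normalized fluorescence",
                  title = sprintf("Tm = %.2f °C", object$tm)) +
    ggplot2::theme_minimal()
}

#' Thermal shift between a compound and a no-compound control
#'
#' Replicate melting curves are fitted independently; the shift is the
#' difference of group mean Tm values, with the standard deviation
#' propagated as sqrt(sd_sample^2 + sd_control^2) from the replicate SDs
#' (reported as NA when either group has a single fit).
#'
#' @param sample_fits,control_fits Lists of `melt_fit` objects (or numeric
#'   vectors of Tm values), one element per replicate.
#' @return One-row tibble: `delta_tm`, `sd`, `tm_sample`, `tm_control`,
#'   `n_sample`, `n_control`.
#' @export
delta_tm <- function(sample_fits, control_fits) {
  tm_of <- function(fits, label) {
    if (is.numeric(fits)) tms <- fits
    else if (inherits(fits, "melt_fit")) tms <- fits$tm
    else tms <- vapply(fits, function(f) f$tm, 0)
    if (length(tms) == 0) {
      abort(paste0("Empty ", label, " group"),
            class = "fretscreen_error_validation")
    }
    tms
  }
  tm_s <- tm_of(sample_fits, "sample")
  tm_c <- tm_of(control_fits, "control")
  sd_s <- if (length(tm_s) > 1) sd(tm_s) else NA_real_
  sd_c <- if (length(tm_c) > 1) sd(tm_c) else NA_real_
  tibble::tibble(
    delta_tm = mean(tm_s) - mean(tm_c),
    sd = if (is.na(sd_s) || is.na(sd_c)) NA_real_ else sqrt(sd_s^2 + sd_c^2),
    tm_sample = mean(tm_s), tm_control = mean(tm_c),
    n_sample = length(tm_s), n_control = length(tm_c))
}
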