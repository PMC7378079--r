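#' Fit a variable-slope sigmoidal dose-response curve
#'
#' Four-parameter logistic fit
#' \deqn{y = bottom + \frac{top - bottom}{1 + (x / IC_{50})^{h}}}
#' by least squares, the standard "sigmoidal dose-response with variable
#' slope". Responses may be raw rFRET (descending with concentration) or
#' percent inhibition (ascending); the orientation is auto-detected from
#' the data and recorded. Anchor controls placed beyond the series (the
#' no-compound and fully-disrupted controls, conventionally 2 log-units
#' outside the titrated range) enter as ordinary data points.
#'
#' @param data Data frame with columns `concentration` (molar, positive)
#'   and `response`; replicates as repeated rows.
#' @param range_factor The fit is flagged unreliable when the IC50 lands
#'   outside the tested concentration range extended by this factor.
#' @return An object of class `ic50_fit`: `ic50`, `hill_slope`, `top`,
#'   `bottom` (with `top > bottom`; `direction` records whether response
#'   falls or rises with concentration), Wald `ci_95` per parameter,
#'   `converged`, `unreliable`, `rss`, `n`. Supports [tidy()], [glance()]
#'   and [ggplot2::autoplot()].
#' @export
fit_ic50 <- function(data, range_factor = 100) {
  data <- tibble::as_tibble(data)
  if (!all(c("concentration", "response") %in% names(data))) {
    abort("fit_ic50 needs columns concentration and response",
          class = "fretscreen_error_format")
  }
  if (any(data$concentration <= 0)) {
    abort("Concentrations must be positive (place anchors at finite points)",
          class = "fretscreen_error_domain")
  }
  conc <- sort(unique(data$concentration))
  if (length(conc) < 5 || log10(max(conc) / min(conc)) < 2) {
    abort("Need >= 5 concentrations spanning >= 2 log units",
          class = "fretscreen_error_validation")
  }

  x <- data$concentration
  y <- data$response
  span <- diff(range(y))
  means <- tapply(y, x, mean)
  descending <- unname(means[1] > means[length(means)])
  if (span == 0 || sd(y) < 1e-12 * max(abs(y), 1)) {
    return(ic50_fit_obj(NA, NA, NA, NA, NULL, FALSE, TRUE, NA, nrow(data),
                        data, descending = NA))
  }

  # parameterize left/right asymptotes; h > 0, left = y(x -> 0)
  left0 <- unname(means[1])
  right0 <- unname(means[length(means)])
  mid <- (left0 + right0) / 2
  lx50 <- log10(x[which.min(abs(y - mid))])
  residual_fn <- function(p) {
    y - (p[["right"]] + (p[["left"]] - p[["right"]]) /
           (1 + (x / 10^p[["lic50"]])^p[["h"]]))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(left = left0, right = right0, lic50 = lx50, h = 1),
      fn = residual_fn,
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4) {
    return(ic50_fit_obj(NA, NA, NA, NA, NULL, FALSE, TRUE, NA, nrow(data),
                        data, descending))
  }
  cf <- coef(fit)
  ic50 <- 10^cf[["lic50"]]
  hill <- cf[["h"]]
  left <- cf[["left"]]; right <- cf[["right"]]
  # normalize so hill > 0; flipping h swaps the asymptote roles
  if (hill < 0) {
    hill <- -hill
    tmp <- left; left <- right; right <- tmp
  }
  top <- max(left, right)
  bottom <- min(left, right)
  descending <- left > right

  ci <- tryCatch({
    se <- summary(fit)$coefficients[, "Std. Error"]
    z <- stats::qnorm(0.975)
    tibble::tibble(
      term = c("ic50", "hill_slope", "top", "bottom"),
      conf.low = c(10^(cf[["lic50"]] - z * se[["lic50"]]),
                   cf[["h"]] - z * se[["h"]],
                   NA, NA),
      conf.high = c(10^(cf[["lic50"]] + z * se[["lic50"]]),
                    cf[["h"]] + z * se[["h"]],
                    NA, NA))
  }, error = function(e) NULL)

  unreliable <- ic50 < min(conc) / range_factor || ic50 > max(conc) * range_factor
  ic50_fit_obj(ic50, hill, top, bottom, ci, TRUE, unreliable,
               fit$deviance, nrow(data), data, descending)
}

ic50_fit_obj <- function(ic50, hill, top, bottom, ci, converged, unreliable,
                         rss, n, data, descending) {
  structure(list(ic50 = ic50, hill_slope = hill, top = top, bottom = bottom,
                 ci_95 = ci, converged = converged, unreliable = unreliable,
                 rss = rss, n = n, data = data,
                 direction = if (is.na(descending)) NA_character_
                             else if (descending) "descending" else "ascending"),
            class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat("Sigmoidal dose-response fit (variable slope)\n")
  if (!x$converged) {
    cat("  did not converge\n")
    return(invisible(x))
  }
  cat(sprintf("  IC50 = %.4g   hill = %.3f   [%.4g, %.4g] (%s)\n",
              x$ic50, x$hill_slope, x$bottom, x$top, x$direction))
  if (x$unreliable) cat("  WARNING: flagged unreliable\n")
  invisible(x)
}

#' @rdname fit_ic50
#' @param x,object An `ic50_fit` object.
#' @param ... Unused.
#' @export
tidy.ic50_fit <- function(x, ...) {
  out <- tibble::tibble(
    term = c("ic50", "hill_slope", "top", "bottom"),
    estimate = c(x$ic50, x$hill_slope, x$top, x$bottom))
  if (!is.null(x$ci_95)) out <- dplyr::left_join(out, x$ci_95, by = "term")
  out
}

#' @rdname fit_ic50
#' @export
glance.ic50_fit <- function(x, ...) {
  tibble::tibble(ic50 = x$ic50, hill_slope = x$hill_slope, top = x$top,
                 bottom = x$bottom, rss = x$rss, n = x$n,
                 converged = x$converged, unreliable = x$unreliable,
                 direction = x$direction)
}

#' @rdname fit_ic50
#' @export
autoplot.ic50_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble::tibble(concentration = 10^seq(log10(min(d$concentration)),
                                                log10(max(d$concentration)),
                                                length.out = 200))
  left <- if (identical(object$direction, "descending")) object$top else object$bottom
  right <- if (identical(object$direction, "descending")) object$bottom else object$top
  grid$response <- right + (left - right) /
    (1 + (grid$concentration / object$ic50)^object$hill_slope)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$concentration, y = .data$response)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, colour = "#b2182b") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Concentration (M)", y = "Response",
                  title = sprintf("IC50 = %.3g M", object$ic50)) +
    ggplot2::theme_minimal()
}

#' Exact ternary competitive-binding equilibrium
#'
#' Solves the coupled mass-action equilibria D + A <-> DA (dissociation
#' constant `kd_probe`) and D + I <-> DI (`ki`) under conservation of the
#' donor, acceptor and inhibitor totals. Writing d for free donor, the
#' bound species are DA = d A / (Kd + d) and DI = d I / (Ki + d), and the
#' donor balance d (1 + A/(Kd + d) + I/(Ki + d)) = D is monotone in d, so
#' the system reduces to damped one-dimensional root finding on \[0, D\].
#' Mass balance is verified to 1e-10 relative on every call.
#'
#' @param donor_total,acceptor_total Probe totals (molar).
#' @param kd_probe Donor-acceptor dissociation constant (molar).
#' @param ki Donor-inhibitor dissociation constant (molar); `Inf` for a
#'   non-binder.
#' @param inhibitor_total Total inhibitor concentration(s), molar;
#'   vectorized.
#' @return Tibble with one row per `inhibitor_total`: free species
#'   (`donor_free`, `acceptor_free`, `inhibitor_free`) and complexes
#'   (`complex_da`, `complex_di`), molar.
#' @export
competition_equilibrium <- function(donor_total, acceptor_total, kd_probe,
                                    ki, inhibitor_total) {
  if (any(c(donor_total, acceptor_total, kd_probe, inhibitor_total) < 0) ||
      any(ki < 0)) {
    abort("Concentrations and constants must be non-negative",
          class = "fretscreen_error_domain")
  }
  solve_one <- function(I) {
    D <- donor_total; A <- acceptor_total
    if (D == 0) {
      return(c(d = 0, a = A, i = I, da = 0, di = 0))
    }
    balance <- function(d) {
      d * (1 + A / (kd_probe + d) + if (is.finite(ki)) I / (ki + d) else 0) - D
    }
    root <- uniroot(balance, lower = 0, upper = D,
                    tol = .Machine$double.eps * max(D, 1e-300))
    d <- root$root
    # polish with Newton steps; the balance is smooth and monotone
    for (k in 1:3) {
      g <- balance(d)
      slope <- 1 + A * kd_probe / (kd_probe + d)^2 +
        if (is.finite(ki)) I * ki / (ki + d)^2 else 0
      d_new <- d - g / slope
      if (is.finite(d_new) && d_new >= 0 && d_new <= D) d <- d_new
    }
    da <- d * A / (kd_probe + d)
    di <- if (is.finite(ki)) d * I / (ki + d) else 0
    res <- abs(d + da + di - D) / max(D, .Machine$double.xmin)
    if (res > 1e-10) {
      abort(sprintf(paste0("Equilibrium solver failed mass balance ",
                           "(relative residual %.3g) for D=%g A=%g Kd=%g ",
                           "Ki=%g I=%g"), res, D, A, kd_probe, ki, I),
            class = "fretscreen_error_numeric")
    }
    c(d = d, a = A - da, i = I - di, da = da, di = di)
  }
  m <- t(vapply(inhibitor_total, solve_one, numeric(5)))
  tibble::tibble(inhibitor_total = inhibitor_total,
                 donor_free = unname(m[, "d"]),
                 acceptor_free = unname(m[, "a"]),
                 inhibitor_free = unname(m[, "i"]),
                 complex_da = unname(m[, "da"]),
                 complex_di = unname(m[, "di"]))
}

#' Convert a fitted IC50 to an inhibition constant Ki
#'
#' The primary conversion inverts the exact ternary equilibrium: it finds
#' the Ki at which [competition_equilibrium()] predicts a 50% loss of the
#' probe complex DA at `inhibitor_total = ic50`. At the probe
#' concentrations typical here (donor 50 nM, acceptor 100 nM, Kd 35 nM)
#' ligand depletion is substantial, which biases the classical
#' Cheng-Prusoff approximation
#' \eqn{K_i = IC_{50} / (1 + A_{tot} / K_d)}; that value is reported
#' alongside for comparison with the common convention.
#'
#' @param ic50 Fitted IC50 (molar), or an [fit_ic50()] object.
#' @param donor_total,acceptor_total,kd_probe Probe parameters (molar).
#' @param interval Log10 bracket (molar) searched for Ki.
#' @return One-row tibble: `ki` (exact inversion), `ki_cheng_prusoff`,
#'   `ic50`.
#' @export
ic50_to_ki <- function(ic50, donor_total, acceptor_total, kd_probe,
                       interval = c(-12, 0)) {
  if (inherits(ic50, "ic50_fit")) {
    if (!ic50$converged) {
      abort("IC50 fit did not converge", class = "fretscreen_error_fit")
    }
    ic50 <- ic50$ic50
  }
  if (ic50 <= 0) {
    abort("ic50 must be positive", class = "fretscreen_error_domain")
  }
  da0 <- bound_complex(donor_total, acceptor_total, kd_probe)
  target <- function(log_ki) {
    eq <- competition_equilibrium(donor_total, acceptor_total, kd_probe,
                                  10^log_ki, ic50)
    eq$complex_da - da0 / 2
  }
  f_lo <- target(interval[1])
  f_hi <- target(interval[2])
  if (sign(f_lo) == sign(f_hi)) {
    abort("No Ki in the search bracket reproduces 50% complex loss at ic50",
          class = "fretscreen_error_inversion")
  }
  root <- uniroot(target, lower = interval[1], upper = interval[2],
                  tol = 1e-12)
  tibble::tibble(ki = 10^root$root,
                 ki_cheng_prusoff = ic50 / (1 + acceptor_total / kd_probe),
                 ic50 = ic50)
}
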