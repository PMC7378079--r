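#' Fit a dissociation constant to a FRET titration
#'
#' Least-squares fit of the saturation model
#' \deqn{EmFRET(A) = EmFRET_{max} \cdot \frac{[DA](D, A, K_d)}{D}}
#' over (Kd, EmFRETmax), where \[DA\] is the exact 1:1 ligand-depletion
#' complex concentration ([bound_complex()]). The sensitized emission is
#' normalized per donor inside the fit so the plateau parameter is
#' donor-independent. Replicate points are fit jointly (pooled), preserving
#' the error structure for the confidence interval.
#'
#' For fixed Kd the model is linear in EmFRETmax, so the fit reduces to a
#' one-dimensional optimization of the profiled residual sum of squares
#' over log Kd, which is fast and has no convergence failures away from
#' degenerate data.
#'
#' @param data Data frame with columns `acceptor_total` and `emfret`, and
#'   either a `donor_total` column or the `donor_total` argument. Replicates
#'   appear as repeated acceptor concentrations.
#' @param donor_total Fixed donor concentration (same unit as
#'   `acceptor_total`); overridden by a `donor_total` column.
#' @param ci Compute the profile-likelihood confidence interval for Kd.
#' @param level Confidence level (default 0.95).
#' @param kd_limits Log10 search limits for Kd, in the concentration unit
#'   of the data. The defaults span 1e-4 to 1e7 times a typical acceptor
#'   concentration, i.e. far beyond any identifiable value.
#' @return An object of class `kd_fit`: point estimates `kd` and
#'   `emfret_max`, `kd_ci` (profile-likelihood bounds with open-end flags),
#'   `rss`, `n` and the data. Supports [tidy()], [glance()] and
#'   [ggplot2::autoplot()].
#' @seealso [profile_likelihood_ci()]
#' @export
fit_kd <- function(data, donor_total = NULL, ci = TRUE, level = 0.95,
                   kd_limits = NULL) {
  data <- tibble::as_tibble(data)
  if (!all(c("acceptor_total", "emfret") %in% names(data))) {
    abort("fit_kd needs columns acceptor_total and emfret",
          class = "fretscreen_error_format")
  }
  if (!"donor_total" %in% names(data)) {
    if (is.null(donor_total)) {
      abort("Supply donor_total (column or argument)",
            class = "fretscreen_error_format")
    }
    data$donor_total <- donor_total
  }
  if (any(data$donor_total <= 0)) {
    abort("donor_total must be positive", class = "fretscreen_error_domain")
  }
  n_conc <- length(unique(data$acceptor_total))
  if (n_conc < 6) {
    abort("Need at least 6 distinct acceptor concentrations",
          class = "fretscreen_error_validation")
  }

  y <- data$emfret
  if (all(y == 0)) {
    abort("All EmFRET values are zero; Kd is unidentifiable",
          class = "fretscreen_error_fit")
  }

  unreliable <- FALSE
  means <- dplyr::summarise(dplyr::group_by(data, .data$acceptor_total),
                            m = mean(.data$emfret), .groups = "drop")
  means <- dplyr::arrange(means, .data$acceptor_total)
  if (nrow(means) >= 3 && all(diff(means$m) < 0)) {
    warn("EmFRET decreases monotonically with acceptor; fit and CI unreliable")
    unreliable <- TRUE
  }

  scale_conc <- max(data$acceptor_total)
  if (is.null(kd_limits)) {
    kd_limits <- log10(scale_conc) + c(-4, 7)
  }

  rss_fun <- kd_rss_closure(data)
  opt <- optimize(function(lk) rss_fun(10^lk)$rss,
                  interval = kd_limits, tol = 1e-9)
  kd_hat <- 10^opt$minimum
  at <- rss_fun(kd_hat)

  fit <- structure(list(
    kd = kd_hat, emfret_max = at$emax, rss = at$rss, n = length(y),
    kd_ci = NULL, level = level, unreliable = unreliable,
    kd_limits = kd_limits, data = data, converged = TRUE),
    class = "kd_fit")

  if (ci) {
    fit$kd_ci <- profile_likelihood_ci(data, fit, level = level)
  }
  fit
}

# Profiled RSS: for fixed kd, emfret_max is the linear least-squares solution.
kd_rss_closure <- function(data) {
  D <- data$donor_total
  A <- data$acceptor_total
  y <- data$emfret
  function(kd) {
    f <- bound_complex(D, A, kd) / D
    ss <- sum(f^2)
    emax <- if (ss > 0) sum(f * y) / ss else 0
    list(rss = sum((y - emax * f)^2), emax = emax)
  }
}

#' Profile-likelihood confidence interval for a fitted Kd
#'
#' Kd is profiled over a log-spaced grid (default 201 points spanning
#' 0.01x to 100x the point estimate); at each grid value the plateau
#' parameter is re-optimized (closed form). Under the Gaussian-error
#' likelihood with profiled variance, the log-likelihood is
#' -n/2 * log(RSS), and the interval bounds sit where it drops by
#' qchisq(level, 1) / 2 (1.92 for 95%) below the optimum. Bounds are
#' refined by bisection between bracketing grid points to 1e-3 relative
#' tolerance; a bound not bracketed within the grid is reported at the
#' grid edge and flagged open (typical for unsaturated weak-binder
#' titrations).
#'
#' @param data The titration data passed to [fit_kd()] (with
#'   `donor_total` column resolved).
#' @param fit A `kd_fit` object.
#' @param level Confidence level.
#' @param grid_points,span Profile grid resolution and half-width
#'   (in factors of the point estimate).
#' @return A one-row tibble: `lower`, `upper`, `level`, `lower_open`,
#'   `upper_open`.
#' @export
profile_likelihood_ci <- function(data, fit, level = 0.95,
                                  grid_points = 201, span = 100) {
  data <- tibble::as_tibble(data)
  if (!"donor_total" %in% names(data)) data$donor_total <- fit$data$donor_total
  rss_fun <- kd_rss_closure(data)
  n <- nrow(data)
  rss_floor <- .Machine$double.xmin
  ll <- function(kd) -n / 2 * log(max(rss_fun(kd)$rss, rss_floor))

  ll_hat <- ll(fit$kd)
  drop <- qchisq(level, df = 1) / 2
  threshold <- ll_hat - drop

  grid <- 10^seq(log10(fit$kd / span), log10(fit$kd * span),
                 length.out = grid_points)
  llg <- vapply(grid, ll, 0)

  locate <- function(side) {
    idx <- if (side == "lower") which(grid < fit$kd) else which(grid > fit$kd)
    if (side == "lower") idx <- rev(idx)
    # walk outward from the optimum until the likelihood falls through the cut
    for (i in idx) {
      if (llg[i] < threshold) {
        inner <- if (side == "lower") grid[i + 1] else grid[i - 1]
        outer <- grid[i]
        root <- bisect_log(function(kd) ll(kd) - threshold, inner, outer)
        return(list(bound = root, open = FALSE))
      }
    }
    list(bound = if (side == "lower") grid[1] else grid[length(grid)],
         open = TRUE)
  }
  lo <- locate("lower")
  up <- locate("upper")
  tibble::tibble(lower = lo$bound, upper = up$bound, level = level,
                 lower_open = lo$open, upper_open = up$open)
}

# Bisection on log10 scale to 1e-3 relative tolerance; f(inner) and f(outer)
# must straddle zero.
bisect_log <- function(f, inner, outer, rel_tol = 1e-3) {
  a <- log10(inner); b <- log10(outer)
  fa <- f(10^a)
  while (abs(10^a - 10^b) > rel_tol * 10^pmin(a, b)) {
    mid <- (a + b) / 2
    if (sign(f(10^mid)) == sign(fa)) a <- mid else b <- mid
  }
  10^((a + b) / 2)
}

#' @export
print.kd_fit <- function(x, ...) {
  cat("FRET binding fit (1:1 ligand-depletion model)\n")
  cat(sprintf("  Kd         = %.4g", x$kd))
  if (!is.null(x$kd_ci)) {
    cat(sprintf("  [%s%.4g, %.4g%s] (%d%% profile likelihood)",
                if (x$kd_ci$lower_open) "<" else "", x$kd_ci$lower,
                x$kd_ci$upper, if (x$kd_ci$upper_open) ">" else "",
                round(100 * x$level)))
  }
  cat("\n")
  cat(sprintf("  EmFRET_max = %.4g\n  RSS = %.4g on %d points\n",
              x$emfret_max, x$rss, x$n))
  if (x$unreliable) cat("  WARNING: flagged unreliable\n")
  invisible(x)
}

#' @rdname fit_kd
#' @param x A `kd_fit` object.
#' @param ... Unused.
#' @export
tidy.kd_fit <- function(x, ...) {
  tibble::tibble(
    term = c("kd", "emfret_max"),
    estimate = c(x$kd, x$emfret_max),
    conf.low = c(if (is.null(x$kd_ci)) NA_real_ else x$kd_ci$lower, NA_real_),
    conf.high = c(if (is.null(x$kd_ci)) NA_real_ else x$kd_ci$upper, NA_real_))
}

#' @rdname fit_kd
#' @export
glance.kd_fit <- function(x, ...) {
  tibble::tibble(kd = x$kd, emfret_max = x$emfret_max, rss = x$rss,
                 n = x$n, unreliable = x$unreliable,
                 ci_lower_open = !is.null(x$kd_ci) && x$kd_ci$lower_open,
                 ci_upper_open = !is.null(x$kd_ci) && x$kd_ci$upper_open)
}

#' @rdname fit_kd
#' @param object A `kd_fit` object.
#' @export
autoplot.kd_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble::tibble(
    acceptor_total = seq(min(d$acceptor_total), max(d$acceptor_total),
                         length.out = 200),
    donor_total = d$donor_total[1])
  grid$emfret <- object$emfret_max *
    bound_complex(grid$donor_total, grid$acceptor_total, object$kd) /
    grid$donor_total
  ggplot2::ggplot(d, ggplot2::aes(x = .data$acceptor_total, y = .data$emfret)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, colour = "#2166ac") +
    ggplot2::labs(x = "Total acceptor concentration",
                  y = "EmFRET (RFU)",
                  title = sprintf("Kd = %.3g", object$kd)) +
    ggplot2::theme_minimal()
}
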