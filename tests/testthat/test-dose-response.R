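test_that("the 4PL fit recovers exact logistic data and its midpoint", {
  conc <- 10^seq(-7, -3, 0.5)
  y <- 0 + (100 - 0) / (1 + (conc / 1e-5)^1)
  f <- fit_ic50(tibble::tibble(concentration = conc, response = y))
  expect_equal(f$ic50, 1e-5, tolerance = 1e-6)
  expect_equal(f$hill_slope, 1, tolerance = 1e-6)
  expect_equal(f$top, 100, tolerance = 1e-6)
  expect_equal(f$bottom, 0, tolerance = 1e-4)
  expect_equal(f$direction, "descending")
  # model midpoint identity: y(ic50) = (top + bottom) / 2
  mid <- f$bottom + (f$top - f$bottom) / (1 + (f$ic50 / f$ic50)^f$hill_slope)
  expect_equal(mid, (f$top + f$bottom) / 2)

  # ascending orientation (percent inhibition) is detected
  fa <- fit_ic50(tibble::tibble(concentration = conc, response = 100 - y))
  expect_equal(fa$ic50, 1e-5, tolerance = 1e-6)
  expect_equal(fa$direction, "ascending")
  expect_gt(fa$top, fa$bottom)
})

test_that("degenerate dose-response inputs are flagged or rejected", {
  conc <- 10^seq(-7, -3, 0.5)
  flat <- fit_ic50(tibble::tibble(concentration = conc, response = 50))
  expect_false(flat$converged)
  expect_true(flat$unreliable)

  expect_error(fit_ic50(tibble::tibble(concentration = c(1e-6, 2e-6, 3e-6),
                                       response = c(1, 2, 3))),
               class = "fretscreen_error_validation")
  expect_error(fit_ic50(tibble::tibble(concentration = c(0, conc),
                                       response = c(0, seq_along(conc)))),
               class = "fretscreen_error_domain")
})

test_that("ic50_fit exposes broom-style and plotting methods", {
  sim <- simulate_dose_response(20e-6, cv = 0.02, seed = 5)
  f <- fit_ic50(sim$data)
  expect_true(f$converged)
  td <- tidy(f)
  expect_setequal(td$term, c("ic50", "hill_slope", "top", "bottom"))
  expect_true(td$conf.low[td$term == "ic50"] < f$ic50)
  expect_s3_class(autoplot(f), "ggplot")
  expect_equal(glance(f)$n, nrow(sim$data))
})

test_that("the ternary equilibrium conserves mass and hits its limits", {
  D <- 100e-9; A <- 200e-9; kd <- 35e-9
  eq <- competition_equilibrium(D, A, kd, 20e-6,
                                c(0, 1e-6, 20e-6, 1e-4, 1e-2))
  # conservation of all three totals to 1e-10 relative
  expect_equal(eq$donor_free + eq$complex_da + eq$complex_di,
               rep(D, 5), tolerance = 1e-10)
  expect_equal(eq$acceptor_free + eq$complex_da, rep(A, 5),
               tolerance = 1e-10)
  expect_equal(eq$inhibitor_free + eq$complex_di, eq$inhibitor_total,
               tolerance = 1e-10)
  # no inhibitor reduces to the two-species closed form
  expect_equal(eq$complex_da[1], bound_complex(D, A, kd), tolerance = 1e-12)
  # DA strictly decreasing in inhibitor
  expect_true(all(diff(eq$complex_da) < 0))
  # non-binder leaves the probe untouched
  eq_inf <- competition_equilibrium(D, A, kd, Inf, 1e-3)
  expect_equal(eq_inf$complex_da, bound_complex(D, A, kd), tolerance = 1e-12)
  # DA increasing in ki at fixed inhibitor
  da_by_ki <- vapply(c(1e-7, 1e-6, 1e-5, 1e-4), function(ki) {
    competition_equilibrium(D, A, kd, ki, 20e-6)$complex_da
  }, 0)
  expect_true(all(diff(da_by_ki) > 0))
})

test_that("the equilibrium solver matches the cubic polyroot oracle", {
  set.seed(11)
  for (i in 1:50) {
    D <- 10^runif(1, -8.5, -6); A <- 10^runif(1, -8.5, -6)
    kd <- 10^runif(1, -9, -6); ki <- 10^runif(1, -7, -4)
    I <- 10^runif(1, -7, -3)
    da <- competition_equilibrium(D, A, kd, ki, I)$complex_da
    expect_equal(da, oracle_competition_da(D, A, kd, ki, I),
                 tolerance = 1e-8)
  }
})

test_that("ic50_to_ki inverts the forward simulation across potencies", {
  for (ki in c(0.1, 1, 10, 100) * 1e-6) {
    sim <- simulate_dose_response(ki, cv = 0)
    f <- fit_ic50(sim$data)
    out <- ic50_to_ki(f, donor_total = 50e-9, acceptor_total = 100e-9,
                      kd_probe = 35e-9)
    expect_equal(out$ki, ki, tolerance = 0.01)
  }
})

test_that("exact inversion approaches Cheng-Prusoff for a dilute probe", {
  # acceptor far below Kd: no depletion, the approximation becomes exact
  D <- 0.05e-9; A <- 0.1e-9; kd <- 35e-9
  sim <- simulate_dose_response(5e-6, donor_total = D, acceptor_total = A,
                                kd_probe = kd, cv = 0)
  f <- fit_ic50(sim$data)
  out <- ic50_to_ki(f, D, A, kd)
  expect_equal(out$ki, out$ki_cheng_prusoff, tolerance = 0.02)
})

test_that("the ic50 to ki mapping is monotone", {
  kis <- vapply(c(1e-6, 1e-5, 1e-4), function(ic) {
    ic50_to_ki(ic, 50e-9, 100e-9, 35e-9)$ki
  }, 0)
  expect_true(all(diff(kis) > 0))
})
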