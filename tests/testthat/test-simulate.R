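test_that("generators are pure functions of configuration and seed", {
  s1 <- simulate_screen(library = compound_library(
    n_inactive = 30, n_inhibitor_a = 2, n_inhibitor_b = 1, n_blue = 2,
    n_green = 1, n_shifted = 1, n_quencher = 1), seed = 5)
  s2 <- simulate_screen(library = compound_library(
    n_inactive = 30, n_inhibitor_a = 2, n_inhibitor_b = 1, n_blue = 2,
    n_green = 1, n_shifted = 1, n_quencher = 1), seed = 5)
  expect_identical(tibble::as_tibble(s1$assay_a$assay),
                   tibble::as_tibble(s2$assay_a$assay))
  expect_identical(tibble::as_tibble(s1$assay_b$pre),
                   tibble::as_tibble(s2$assay_b$pre))

  t1 <- simulate_titration(sim_config(seed = 3))
  t2 <- simulate_titration(sim_config(seed = 3))
  expect_identical(tibble::as_tibble(t1$plate), tibble::as_tibble(t2$plate))

  m1 <- simulate_melt_curves(tm = 50, seed = 7)
  m2 <- simulate_melt_curves(tm = 50, seed = 7)
  expect_identical(m1, m2)
})

test_that("generator calls do not disturb the caller's RNG stream", {
  set.seed(123)
  a <- runif(1)
  set.seed(123)
  invisible(simulate_titration(sim_config(seed = 99)))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("a competitive compound at zero dose equals the compound-free well", {
  cfg <- sim_config(seed = 1)
  cmp <- compound_library(n_inactive = 0, n_inhibitor_a = 1,
                          n_inhibitor_b = 0, n_blue = 0, n_green = 0,
                          n_shifted = 0, n_quencher = 0)
  with_cmp <- simulate_well(cfg, compound = cmp, compound_conc = 0, seed = 31)
  without <- simulate_well(cfg, compound = NULL, seed = 31)
  expect_equal(with_cmp$intensity, without$intensity, tolerance = 1e-12)
})

test_that("the signal model responds to binding as designed", {
  cfg <- sim_config(noise = zero_noise())
  reads <- simulate_well(cfg)
  expect_equal(nrow(reads), 5)
  # a GdnHCl positive control loses sensitized emission at (410, 527)
  pos <- simulate_well(cfg, role = "positive_control")
  i <- function(r, ex, em) r$intensity[r$excitation_nm == ex &
                                         r$emission_nm == em]
  expect_lt(i(pos, 410, 527), i(reads, 410, 527))
  expect_gt(i(pos, 410, 477), i(reads, 410, 477))  # donor dequench
  expect_error(simulate_well(cfg, channels = tibble::tibble()),
               class = "fretscreen_error_validation")
})

test_that("titration truth records the generating parameters", {
  sim <- simulate_titration(sim_config(kd_pair = 8.2e-9,
                                       noise = zero_noise()))
  expect_equal(sim$truth$kd, 8.2e-9)
  # plateau: E * exD(430) * emA(527) * brightness_A * D_nM
  expect_equal(sim$truth$emfret_max, 0.25 * 0.8 * 1 * 15 * 100)
  expect_error(simulate_titration(sim_config(), acceptor_totals = 1e-7),
               class = "fretscreen_error_config")
  expect_error(simulate_titration(sim_config(), replicates = 0),
               class = "fretscreen_error_config")
})

test_that("melt and screen generators validate their configuration", {
  expect_error(simulate_melt_curves(tm = 10), class = "fretscreen_error_config")
  expect_error(simulate_melt_curves(tm = 94, delta_tm = 5),
               class = "fretscreen_error_config")
  expect_error(simulate_melt_curves(tm = 50, replicates = 0),
               class = "fretscreen_error_config")
  expect_error(simulate_screen(library = compound_library(n_inactive = 2000)),
               class = "fretscreen_error_config")
  expect_error(simulate_dose_response(1e-6, concentrations = c(-1, 1)),
               class = "fretscreen_error_config")
})

test_that("an all-inactive library yields no exclusions and no hits", {
  zn <- zero_noise()
  sim <- simulate_screen(
    library = compound_library(n_inactive = 40, n_inhibitor_a = 0,
                               n_inhibitor_b = 0, n_blue = 0, n_green = 0,
                               n_shifted = 0, n_quencher = 0),
    config_a = sim_config(noise = zn), config_b = sam_config(noise = zn),
    seed = 3)
  scr <- run_screen(sim$assay_a, sim$assay_b)
  expect_equal(sum(scr$summary$n_excluded_total), 0)
  expect_equal(sum(scr$summary$n_hits), 0)
})

test_that("dose-response truth carries the exact half-displacement point", {
  sim <- simulate_dose_response(20e-6, cv = 0)
  da0 <- bound_complex(50e-9, 100e-9, 35e-9)
  da_at <- competition_equilibrium(50e-9, 100e-9, 35e-9, 20e-6,
                                   sim$truth$ic50)$complex_da
  expect_equal(da_at / da0, 0.5, tolerance = 1e-8)
  # anchors sit 2 log-units outside the series with anchor responses
  expect_equal(min(sim$data$concentration), 10^-7.5 / 100)
  expect_equal(max(sim$data$concentration), 10^-2.5 * 100)
  low <- sim$data$response[sim$data$concentration == min(sim$data$concentration)]
  expect_equal(unique(low), 0)
})
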