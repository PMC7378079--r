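test_that("rFRET is the 527/477 intensity ratio with guard rails", {
  wells <- tibble::tibble(well = "A1", role = "sample")
  mk <- function(i477, i527) {
    fret_plate(wells, tibble::tibble(
      well = "A1", excitation_nm = 410, emission_nm = c(477, 527),
      intensity = c(i477, i527)), format = 96)
  }
  expect_equal(plate_rfret(mk(1, 2))$rfret, 2)
  expect_error(plate_rfret(mk(0, 1)),
               class = "fretscreen_error_undefined_ratio")

  only477 <- fret_plate(wells, tibble::tibble(
    well = "A1", excitation_nm = 410, emission_nm = 477, intensity = 1),
    format = 96)
  expect_error(plate_rfret(only477),
               class = "fretscreen_error_missing_channel")
  expect_error(plate_rfret(mk(1, 2), excitation = 430),
               class = "fretscreen_error_missing_channel")
})

test_that("a bound FRET pair has higher rFRET than donor plus free acceptor", {
  cfg <- sim_config(noise = zero_noise())
  bound <- simulate_well(cfg, role = "sample")
  unbound <- simulate_well(cfg, role = "positive_control")
  rf <- function(reads) {
    i <- function(ex, em) reads$intensity[reads$excitation_nm == ex &
                                            reads$emission_nm == em]
    (i(410, 527) - cfg$blank) / (i(410, 477) - cfg$blank)
  }
  expect_gt(rf(bound), rf(unbound))
  expect_gt(rf(bound) / rf(unbound), 1.5)

  # with zero transfer efficiency the ratio no longer depends on binding
  cfg0 <- sim_config(transfer_efficiency = 0, noise = zero_noise())
  expect_equal(rf(simulate_well(cfg0, role = "sample")),
               rf(simulate_well(cfg0, role = "positive_control")))
})

test_that("bleed-through coefficients come from single-fluorophore wells", {
  donor_only <- tibble::tibble(
    well = "A1", excitation_nm = c(430, 430),
    emission_nm = c(477, 527), intensity = c(100, 10))
  acceptor_only <- tibble::tibble(
    well = "B1", excitation_nm = c(430, 477),
    emission_nm = c(527, 527), intensity = c(5, 50))
  cal <- calibrate_bleedthrough(donor_only, acceptor_only)
  expect_equal(cal$alpha, 0.10)
  expect_equal(cal$beta, 0.10)

  bad <- acceptor_only; bad$intensity[2] <- 0
  expect_error(calibrate_bleedthrough(donor_only, bad),
               class = "fretscreen_error_calibration")
})

test_that("calibration recovers the generating spectral coefficients", {
  # defaults encode alpha = em527/em477 = 0.25, beta = ex430/ex477 = 0.08
  sim <- simulate_titration(sim_config(noise = zero_noise()))
  corr <- subtract_blanks(sim$plate)
  df <- tibble::as_tibble(corr)
  cal <- calibrate_bleedthrough(
    dplyr::filter(df, donor_conc > 0, acceptor_conc == 0, role != "blank"),
    dplyr::filter(df, donor_conc == 0, acceptor_conc > 0, role != "blank"))
  expect_equal(cal$alpha, 0.25, tolerance = 0.01)
  expect_equal(cal$beta, 0.08, tolerance = 0.01)
})

test_that("EmFRET unmixing subtracts both contamination terms", {
  reads <- tibble::tibble(
    well = "A1",
    excitation_nm = c(430, 430, 477),
    emission_nm = c(527, 477, 527),
    intensity = c(100, 200, 300))
  coeffs <- list(alpha = 0.1, beta = 0.1)
  expect_equal(compute_emfret(reads, coeffs)$emfret, 100 - 20 - 30)

  expect_error(compute_emfret(reads[1:2, ], coeffs),
               class = "fretscreen_error_missing_channel")
})

test_that("EmFRET of single-fluorophore wells vanishes under own calibration", {
  sim <- simulate_titration(sim_config(noise = zero_noise()))
  corr <- subtract_blanks(sim$plate)
  df <- tibble::as_tibble(corr)
  donor_only <- dplyr::filter(df, donor_conc > 0, acceptor_conc == 0,
                              role != "blank")
  acceptor_only <- dplyr::filter(df, donor_conc == 0, acceptor_conc > 0,
                                 role != "blank")
  cal <- calibrate_bleedthrough(donor_only, acceptor_only)
  expect_equal(compute_emfret(donor_only, cal)$emfret,
               rep(0, length(unique(donor_only$well))), tolerance = 1e-8)
  expect_equal(compute_emfret(acceptor_only, cal)$emfret,
               rep(0, length(unique(acceptor_only$well))), tolerance = 1e-8)
})

test_that("bound_complex matches hand values and limits", {
  expect_equal(bound_complex(100, 100, 0), 100)   # zero-Kd: DA = min(D, A)
  expect_equal(bound_complex(100, 0, 50), 0)
  da <- bound_complex(100, 200, 100)
  expect_equal(da, 58.5786, tolerance = 1e-5)
  # back-substitution: free-species product over complex returns Kd
  expect_equal((100 - da) * (200 - da) / da, 100, tolerance = 1e-10)
  expect_error(bound_complex(-1, 1, 1), class = "fretscreen_error_domain")
})

test_that("bound_complex agrees with the root-finding oracle to 1e-10", {
  set.seed(101)
  for (i in 1:1000) {
    D <- 10^runif(1, -1, 4); A <- 10^runif(1, -1, 4)
    kd <- 10^runif(1, -2, 5)
    closed <- bound_complex(D, A, kd)
    expect_equal(closed, oracle_bound_complex(D, A, kd),
                 tolerance = 1e-10)
  }
})

test_that("bound_complex is monotone and has the correct limits", {
  set.seed(7)
  D <- 10^runif(50, 0, 3); A <- 10^runif(50, 0, 3); kd <- 10^runif(50, 0, 3)
  eps <- 1e-6
  expect_true(all(bound_complex(D, A * (1 + eps), kd) >=
                    bound_complex(D, A, kd)))
  expect_true(all(bound_complex(D * (1 + eps), A, kd) >=
                    bound_complex(D, A, kd)))
  expect_true(all(bound_complex(D, A, kd * (1 + eps)) <=
                    bound_complex(D, A, kd)))
  # saturation: A >> D, kd gives DA -> D
  expect_equal(bound_complex(10, 1e9, 1), 10, tolerance = 1e-6)
  # dilute limit: D*A << kd^2 gives DA ~ D*A/kd within 1%
  expect_equal(bound_complex(1, 2, 1000), 1 * 2 / 1000, tolerance = 0.01)
})
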