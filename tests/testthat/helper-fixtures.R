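# Small in-code fixtures and independent oracles shared across tests.

# Four-well toy plate with one well per role and two channels.
toy_plate <- function() {
  wells <- tibble::tibble(
    well = c("A1", "A2", "A3", "A4"),
    role = c("sample", "negative_control", "positive_control", "blank"),
    compound_id = c("CMP1", NA, NA, NA),
    compound_conc = c(1e-5, NA, NA, NA),
    donor_conc = c(1e-7, 1e-7, 1e-7, NA),
    acceptor_conc = c(2e-7, 2e-7, 2e-7, NA))
  reads <- tidyr::crossing(well = wells$well,
                           tibble::tibble(excitation_nm = c(410, 410),
                                          emission_nm = c(477, 527))) |>
    dplyr::distinct() |>
    dplyr::mutate(intensity = c(100, 80, 120, 95, 110, 30, 10, 10))
  fret_plate(wells, reads, plate_id = "toy", format = 96)
}

# Independent equilibrium oracle for the two-species complex: 1-D root
# finding on free donor from the donor mass balance.
oracle_bound_complex <- function(D, A, kd) {
  if (D == 0 || A == 0) return(0)
  if (kd == 0) return(min(D, A))
  bal <- function(d) d + d * A / (kd + d) - D
  d <- uniroot(bal, lower = 0, upper = D, tol = D * 1e-15)$root
  d * A / (kd + d)
}

# Independent ternary-equilibrium oracle: the free-donor cubic
# d(Kd+d)(Ki+d) + A d(Ki+d) + I d(Kd+d) - D(Kd+d)(Ki+d) = 0
# solved by polyroot (companion-matrix eigenvalues), then DA = dA/(Kd+d).
oracle_competition_da <- function(D, A, kd, ki, I) {
  # expand into c0 + c1 d + c2 d^2 + c3 d^3
  c3 <- 1
  c2 <- kd + ki + A + I - D
  c1 <- kd * ki + A * ki + I * kd - D * (kd + ki)
  c0 <- -D * kd * ki
  roots <- polyroot(c(c0, c1, c2, c3))
  real <- Re(roots[abs(Im(roots)) < 1e-8 * max(abs(roots))])
  d <- real[real >= -1e-12 * D & real <= D * (1 + 1e-12)]
  stopifnot(length(d) >= 1)
  d <- max(min(d[1], D), 0)
  d * A / (kd + d)
}

# melt-fit helpers: split a simulate_melt_curves() tibble into per-curve
# fits by condition
melt_fits_by_condition <- function(curves, cond) {
  split_curves <- split(dplyr::filter(curves, condition == cond),
                        dplyr::filter(curves, condition == cond)$replicate)
  lapply(split_curves, function(d) {
    fit_melt(dplyr::select(d, temperature, fluorescence))
  })
}
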