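#' Per-well ratiometric FRET signal
#'
#' rFRET is the acceptor-emission to donor-emission intensity ratio under
#' donor excitation: I(ex, 527 nm) / I(ex, 477 nm), computed after blank
#' subtraction. The default excitation is 410 nm; the parallel 430 nm
#' readout used by the screening discrepancy filter is selected with
#' `excitation = 430`.
#'
#' @param plate A blank-corrected [fret_plate] (or any data frame with
#'   columns `well`, `role`, `excitation_nm`, `emission_nm`, `intensity`).
#' @param excitation Donor excitation wavelength (nm), 410 or 430.
#' @param donor_em,acceptor_em Emission wavelengths (nm) of the donor and
#'   acceptor channels.
#' @return A tibble with one row per well: `well`, `role`, `compound_id`,
#'   `rfret`, `donor_intensity`, `acceptor_intensity`.
#' @export
plate_rfret <- function(plate, excitation = 410, donor_em = 477,
                        acceptor_em = 527) {
  df <- dplyr::filter(tibble::as_tibble(plate),
                      .data$excitation_nm == excitation,
                      .data$emission_nm %in% c(donor_em, acceptor_em),
                      .data$role != "blank")
  if (nrow(df) == 0) {
    abort(paste0("No reads at excitation ", excitation, " nm"),
          class = "fretscreen_error_missing_channel")
  }
  wide <- tidyr::pivot_wider(
    dplyr::select(df, "well", "role", "compound_id", "emission_nm", "intensity"),
    names_from = "emission_nm", values_from = "intensity",
    names_prefix = "em")
  dn <- paste0("em", donor_em)
  an <- paste0("em", acceptor_em)
  if (!all(c(dn, an) %in% names(wide)) || anyNA(wide[[dn]]) || anyNA(wide[[an]])) {
    abort(paste0("Wells lack reads in one of the rFRET emission channels (",
                 donor_em, "/", acceptor_em, " nm)"),
          class = "fretscreen_error_missing_channel")
  }
  if (any(wide[[dn]] <= 0)) {
    abort(paste0("Non-positive donor intensity in well(s): ",
                 paste(head(wide$well[wide[[dn]] <= 0], 5), collapse = ", ")),
          class = "fretscreen_error_undefined_ratio")
  }
  tibble::tibble(
    well = wide$well, role = wide$role, compound_id = wide$compound_id,
    rfret = wide[[an]] / wide[[dn]],
    donor_intensity = wide[[dn]], acceptor_intensity = wide[[an]])
}

#' Calibrate spectral bleed-through coefficients
#'
#' The sensitized-emission correction needs two instrument/fluorophore
#' constants: `alpha`, the donor bleed-through into the acceptor emission
#' channel (I(430, 527) / I(430, 477) in donor-only wells), and `beta`, the
#' acceptor direct-excitation ratio (I(430, 527) / I(477, 527) in
#' acceptor-only wells). Both are means over the supplied calibration wells.
#'
#' @param donor_only,acceptor_only Blank-corrected reads (long format) for
#'   donor-only and acceptor-only calibration wells.
#' @return A one-row tibble: `alpha`, `beta`, `n_donor_wells`,
#'   `n_acceptor_wells`.
#' @export
calibrate_bleedthrough <- function(donor_only, acceptor_only) {
  ratio_per_well <- function(reads, num_ch, den_ch, label) {
    wide <- tidyr::pivot_wider(
      dplyr::select(tibble::as_tibble(reads), "well", "excitation_nm",
                    "emission_nm", "intensity"),
      names_from = c("excitation_nm", "emission_nm"),
      values_from = "intensity", names_sep = "_")
    if (!all(c(num_ch, den_ch) %in% names(wide))) {
      abort(paste0("Calibration wells lack required channels for ", label),
            class = "fretscreen_error_missing_channel")
    }
    if (any(wide[[den_ch]] <= 0)) {
      abort(paste0("Zero/negative denominator intensity calibrating ", label),
            class = "fretscreen_error_calibration")
    }
    wide[[num_ch]] / wide[[den_ch]]
  }
  alpha <- ratio_per_well(donor_only, "430_527", "430_477", "alpha")
  beta <- ratio_per_well(acceptor_only, "430_527", "477_527", "beta")
  tibble::tibble(alpha = mean(alpha), beta = mean(beta),
                 n_donor_wells = length(alpha),
                 n_acceptor_wells = length(beta))
}

#' Sensitized FRET emission after spectral unmixing
#'
#' Three-channel linear unmixing of the FRET emission:
#' EmFRET = I(430, 527) - alpha * I(430, 477) - beta * I(477, 527),
#' removing donor bleed-through and acceptor direct excitation from the
#' acceptor-emission read under donor excitation. Values can be negative
#' for non-interacting pairs (noise).
#'
#' @param reads Blank-corrected reads (long format) containing the three
#'   channels (430, 477), (430, 527) and (477, 527) for each well.
#' @param coeffs Bleed-through coefficients from [calibrate_bleedthrough()]
#'   (anything with elements `alpha` and `beta`).
#' @return A tibble with one row per well: `well`, `emfret`.
#' @export
compute_emfret <- function(reads, coeffs) {
  wide <- tidyr::pivot_wider(
    dplyr::select(tibble::as_tibble(reads), "well", "excitation_nm",
                  "emission_nm", "intensity"),
    names_from = c("excitation_nm", "emission_nm"),
    values_from = "intensity", names_sep = "_")
  need <- c("430_527", "430_477", "477_527")
  if (!all(need %in% names(wide)) || anyNA(wide[need])) {
    abort("EmFRET needs reads at (430,477), (430,527) and (477,527)",
          class = "fretscreen_error_missing_channel")
  }
  tibble::tibble(
    well = wide$well,
    emfret = wide$`430_527` - coeffs$alpha[1] * wide$`430_477` -
      coeffs$beta[1] * wide$`477_527`)
}

#' Equilibrium concentration of a 1:1 complex with ligand depletion
#'
#' Exact two-species binding isotherm (the "quadratic" or tight-binding
#' solution): for total donor D, total acceptor A and dissociation constant
#' Kd, the complex concentration is
#' \deqn{DA = \frac{(D + A + K_d) - \sqrt{(D + A + K_d)^2 - 4 D A}}{2}.}
#' Unlike the dilute approximation D*A/Kd, this remains valid when the
#' protein concentrations are comparable to Kd, as they are in these
#' assays (50 nM - 1.1 uM vs Kd of 8 nM - 2.6 uM). Computed in the
#' numerically stable form 2*D*A / (b + sqrt(b^2 - 4*D*A)).
#'
#' @param donor_total,acceptor_total,kd Non-negative concentrations
#'   (any single consistent unit). Vectorized.
#' @return Complex concentration, in the input unit; always within
#'   \[0, min(D, A)\].
#' @export
bound_complex <- function(donor_total, acceptor_total, kd) {
  if (any(donor_total < 0 | acceptor_total < 0 | kd < 0)) {
    abort("bound_complex requires non-negative concentrations",
          class = "fretscreen_error_domain")
  }
  b <- donor_total + acceptor_total + kd
  disc <- b^2 - 4 * donor_total * acceptor_total
  disc <- pmax(disc, 0)  # guard tiny negative from rounding at kd = 0, D = A
  denom <- b + sqrt(disc)
  ifelse(denom == 0, 0, 2 * donor_total * acceptor_total / denom)
}
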