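#' Extract an EmFRET titration series from a plate
#'
#' Runs the full spectral pipeline on a titration plate: blank
#' subtraction, bleed-through calibration from the donor-only wells
#' (acceptor concentration 0) and acceptor-only wells (donor
#' concentration 0), then three-channel unmixing ([compute_emfret()]) for
#' every well containing donor. The zero point of the acceptor ladder is
#' part of the series (its EmFRET is zero up to noise).
#'
#' @param plate A titration [fret_plate] with reads at (430,477),
#'   (430,527) and (477,527), e.g. from [simulate_titration()].
#' @param coeffs Optional [calibrate_bleedthrough()] result; calibrated
#'   from the plate's own single-fluorophore wells when `NULL`.
#' @return Tibble ready for [fit_kd()]: `donor_total`, `acceptor_total`,
#'   `emfret`, one row per well.
#' @export
emfret_titration <- function(plate, coeffs = NULL) {
  corrected <- subtract_blanks(plate)
  df <- tibble::as_tibble(corrected)
  donor_only <- dplyr::filter(df, .data$role != "blank",
                              .data$donor_conc > 0, .data$acceptor_conc == 0)
  acceptor_only <- dplyr::filter(df, .data$role != "blank",
                                 .data$donor_conc == 0, .data$acceptor_conc > 0)
  if (is.null(coeffs)) {
    if (nrow(donor_only) == 0 || nrow(acceptor_only) == 0) {
      abort("Plate lacks donor-only or acceptor-only calibration wells",
            class = "fretscreen_error_calibration")
    }
    coeffs <- calibrate_bleedthrough(donor_only, acceptor_only)
  }
  series_wells <- dplyr::filter(df, .data$role != "blank",
                                .data$donor_conc > 0)
  em <- compute_emfret(series_wells, coeffs)
  meta <- dplyr::distinct(
    dplyr::select(series_wells, "well", "donor_total" = "donor_conc",
                  "acceptor_total" = "acceptor_conc"))
  out <- dplyr::left_join(em, meta, by = "well")
  dplyr::select(out, "donor_total", "acceptor_total", "emfret")
}
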