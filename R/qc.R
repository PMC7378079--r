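#' Summarize control wells of a plate
#'
#' Aggregates per-well rFRET values of the negative controls (intact FRET
#' pair, 0% inhibition) and positive controls (chaotrope-disrupted pair,
#' 100% inhibition) into the statistics used by [zprime()] and
#' [percent_inhibition()]. Sample standard deviations (n - 1 denominator)
#' are used.
#'
#' @param rfret_tbl Per-well rFRET tibble from [plate_rfret()] (columns
#'   `role`, `rfret`).
#' @return One-row tibble: `mean_neg`, `sd_neg`, `n_neg`, `mean_pos`,
#'   `sd_pos`, `n_pos`.
#' @export
control_stats <- function(rfret_tbl) {
  neg <- rfret_tbl$rfret[rfret_tbl$role == "negative_control"]
  pos <- rfret_tbl$rfret[rfret_tbl$role == "positive_control"]
  if (length(neg) < 2 || length(pos) < 2) {
    abort("Need at least 2 negative and 2 positive control wells",
          class = "fretscreen_error_qc")
  }
  tibble::tibble(mean_neg = mean(neg), sd_neg = sd(neg), n_neg = length(neg),
                 mean_pos = mean(pos), sd_pos = sd(pos), n_pos = length(pos))
}

#' Z'-factor screening-window statistic
#'
#' Z' = 1 - 3 (sd_pos + sd_neg) / |mean_neg - mean_pos|. Values above 0.5
#' indicate an excellent assay window; the statistic is at most 1 (zero
#' variance) and unbounded below.
#'
#' @param controls Control statistics (one-row data frame or list with
#'   `mean_neg`, `sd_neg`, `mean_pos`, `sd_pos`), e.g. from
#'   [control_stats()].
#' @return The Z'-factor (dimensionless scalar).
#' @export
zprime <- function(controls) {
  window <- abs(controls$mean_neg[1] - controls$mean_pos[1])
  if (window == 0) {
    abort("Z' undefined: control means are equal",
          class = "fretscreen_error_undefined")
  }
  1 - 3 * (controls$sd_pos[1] + controls$sd_neg[1]) / window
}

#' Percent inhibition relative to plate controls
#'
#' Linear normalization of an rFRET signal to the control anchors:
#' 100 * (mean_neg - rfret) / (mean_neg - mean_pos), so the negative
#' control (intact pair) maps to 0% and the positive control (disrupted
#' pair) to 100%. Values outside \[0, 100\] are reported as-is.
#'
#' @param rfret_sample rFRET value(s); vectorized.
#' @inheritParams zprime
#' @return Percent inhibition, same length as `rfret_sample`.
#' @export
percent_inhibition <- function(rfret_sample, controls) {
  window <- controls$mean_neg[1] - controls$mean_pos[1]
  if (window == 0) {
    abort("Percent inhibition undefined: control means are equal",
          class = "fretscreen_error_undefined")
  }
  100 * (controls$mean_neg[1] - rfret_sample) / window
}

#' Plate-level quality control
#'
#' Computes rFRET for all control wells, aggregates control statistics and
#' the Z'-factor, and checks it against a pass threshold (default 0.5, the
#' conventional cutoff for an excellent assay).
#'
#' @param plate A blank-corrected [fret_plate] with at least two negative
#'   and two positive control wells.
#' @param threshold Z' pass threshold.
#' @param excitation Donor excitation wavelength used for rFRET.
#' @return One-row tibble: `zprime`, `pass`, plus the [control_stats()]
#'   columns.
#' @export
qc_plate <- function(plate, threshold = 0.5, excitation = 410) {
  rf <- plate_rfret(plate, excitation = excitation)
  stats <- control_stats(rf)
  z <- zprime(stats)
  dplyr::bind_cols(tibble::tibble(zprime = z, pass = z >= threshold), stats)
}
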