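#' Compound-interference filters
#'
#' The validatory screen triages compounds through three stages before hit
#' calling; each stage has a vectorized predicate returning TRUE where the
#' measurement should be excluded.
#'
#' * `filter_autofluorescence()`: strong intrinsic fluorescence in the
#'   compound pre-read (compound-only wells measured at 410 nm excitation
#'   before the FRET pair is added). Excludes when the intensity exceeds
#'   `fold_threshold` times the plate background in either emission channel
#'   (strictly more than, following the "more than 5 times" rule).
#' * `filter_fret_deviation()`: assay-well fluorescence (FRET pair present,
#'   410 nm excitation) deviating by more than `rel_threshold` (default
#'   30%) above or below the negative-control fluorescence in either
#'   emission channel, indicating optical interference with the
#'   measurement.
#' * `filter_dual_excitation()`: apparent inhibition differing by more than
#'   `diff_threshold` percentage points between the 410 nm and 430 nm
#'   excitation readouts; interfering fluorophores are usually excited
#'   unequally at the two wavelengths, while genuine inhibition is not.
#' * `filter_pan_assay()`: signal reduction of at least
#'   `reduction_threshold` percent simultaneously in both parallel assays
#'   (each assay's 410 nm inhibition), indicating non-specific disruption,
#'   aggregation or quenching. `NA` in the partner assay (compound not
#'   evaluable there) never excludes.
#'
#' Stage thresholds are strict inequalities (`>`); the pan-assay reduction
#' threshold and the hit threshold are inclusive (`>=`).
#'
#' @param fluor_477,fluor_527 Compound pre-read intensities (RFU).
#' @param background_477,background_527 Pre-read plate background (RFU),
#'   must be positive.
#' @param fold_threshold Background-fold cutoff (default 5).
#' @param sample_477,sample_527 Assay-well intensities with FRET pair (RFU).
#' @param control_477,control_527 Negative-control intensities (RFU),
#'   must be positive.
#' @param rel_threshold Relative deviation cutoff (default 0.30).
#' @param inhibition_410,inhibition_430 Apparent percent inhibition at the
#'   two excitations.
#' @param diff_threshold Inhibition-difference cutoff in percentage points
#'   (default 10).
#' @param inhibition_this,inhibition_other Percent inhibition (410 nm) in
#'   the reported assay and in the parallel assay.
#' @param reduction_threshold Simultaneous signal-reduction cutoff in
#'   percent (default 20, matching the hit threshold).
#' @return Logical vector: TRUE = excluded by this filter.
#' @name interference_filters
NULL

#' @rdname interference_filters
#' @export
filter_autofluorescence <- function(fluor_477, fluor_527,
                                    background_477, background_527,
                                    fold_threshold = 5) {
  if (any(background_477 <= 0) || any(background_527 <= 0)) {
    abort("Pre-read background must be positive",
          class = "fretscreen_error_config")
  }
  fluor_477 > fold_threshold * background_477 |
    fluor_527 > fold_threshold * background_527
}

#' @rdname interference_filters
#' @export
filter_fret_deviation <- function(sample_477, sample_527,
                                  control_477, control_527,
                                  rel_threshold = 0.30) {
  if (any(control_477 <= 0) || any(control_527 <= 0)) {
    abort("Control intensities must be positive",
          class = "fretscreen_error_config")
  }
  abs(sample_477 - control_477) / control_477 > rel_threshold |
    abs(sample_527 - control_527) / control_527 > rel_threshold
}

#' @rdname interference_filters
#' @export
filter_dual_excitation <- function(inhibition_410, inhibition_430,
                                   diff_threshold = 10) {
  abs(inhibition_410 - inhibition_430) > diff_threshold
}

#' @rdname interference_filters
#' @export
filter_pan_assay <- function(inhibition_this, inhibition_other,
                             reduction_threshold = 20) {
  !is.na(inhibition_other) &
    inhibition_this >= reduction_threshold &
    inhibition_other >= reduction_threshold
}

#' Call hits among filter survivors
#'
#' A compound is a hit when it survived every interference filter
#' (`excluded_by == "none"`) and its 410 nm inhibition reaches the hit
#' threshold (inclusive: 20% or higher by default, a deliberately low
#' limit to retain weak binders).
#'
#' @param results Per-compound screen results (columns `excluded_by`,
#'   `inhibition_410`).
#' @param hit_threshold Percent inhibition cutoff.
#' @return `results` with the `is_hit` column set.
#' @export
call_hits <- function(results, hit_threshold = 20) {
  dplyr::mutate(results,
                is_hit = .data$excluded_by == "none" &
                  .data$inhibition_410 >= hit_threshold)
}

# Per-assay measurement table: pre-read fluorescence, assay intensities and
# apparent inhibition at both excitations, plus stage-1/2 flags.
screen_assay <- function(pre_plate, assay_plate, fold_threshold = 5,
                         rel_threshold = 0.30, diff_threshold = 10) {
  pre <- tibble::as_tibble(pre_plate)
  pre_bg <- dplyr::filter(pre, .data$role == "blank", .data$excitation_nm == 410)
  if (nrow(pre_bg) == 0) {
    abort("Pre-read plate has no blank wells for background",
          class = "fretscreen_error_config")
  }
  bg <- dplyr::summarise(dplyr::group_by(pre_bg, .data$emission_nm),
                         bg = mean(.data$intensity), .groups = "drop")
  bg477 <- bg$bg[bg$emission_nm == 477]
  bg527 <- bg$bg[bg$emission_nm == 527]

  pre_cmp <- dplyr::filter(pre, !is.na(.data$compound_id),
                           .data$excitation_nm == 410)
  pre_wide <- tidyr::pivot_wider(
    dplyr::select(pre_cmp, "compound_id", "emission_nm", "intensity"),
    names_from = "emission_nm", values_from = "intensity",
    names_prefix = "fluor_", values_fn = mean)

  corrected <- subtract_blanks(assay_plate)
  df <- tibble::as_tibble(corrected)
  ctrl <- dplyr::filter(df, .data$role == "negative_control",
                        .data$excitation_nm == 410)
  ctrl_m <- dplyr::summarise(dplyr::group_by(ctrl, .data$emission_nm),
                             m = mean(.data$intensity), .groups = "drop")
  ctrl477 <- ctrl_m$m[ctrl_m$emission_nm == 477]
  ctrl527 <- ctrl_m$m[ctrl_m$emission_nm == 527]

  smp <- dplyr::filter(df, !is.na(.data$compound_id), .data$excitation_nm == 410)
  smp_wide <- tidyr::pivot_wider(
    dplyr::select(smp, "compound_id", "emission_nm", "intensity"),
    names_from = "emission_nm", values_from = "intensity",
    names_prefix = "sample_", values_fn = mean)

  inhibition_at <- function(ex) {
    rf <- plate_rfret(corrected, excitation = ex)
    stats <- control_stats(rf)
    cmp <- dplyr::filter(rf, !is.na(.data$compound_id))
    agg <- dplyr::summarise(dplyr::group_by(cmp, .data$compound_id),
                            rfret = mean(.data$rfret), .groups = "drop")
    agg[[paste0("inhibition_", ex)]] <- percent_inhibition(agg$rfret, stats)
    dplyr::select(agg, "compound_id", dplyr::all_of(paste0("inhibition_", ex)))
  }

  out <- purrr::reduce(
    list(pre_wide, smp_wide, inhibition_at(410), inhibition_at(430)),
    dplyr::left_join, by = "compound_id")

  dplyr::mutate(
    out,
    strong_autofluorescence = filter_autofluorescence(
      .data$fluor_477, .data$fluor_527, bg477, bg527, fold_threshold),
    fret_fluor_deviation = filter_fret_deviation(
      .data$sample_477, .data$sample_527, ctrl477, ctrl527, rel_threshold),
    dual_excitation_discrepancy = filter_dual_excitation(
      .data$inhibition_410, .data$inhibition_430, diff_threshold))
}

#' Run the two-assay validatory screen
#'
#' Applies the interference cascade in screening order -- stage 1:
#' autofluorescence and FRET-pair fluorescence deviation (reported as one
#' "fluorescence" stage, with the two sub-flags retained); stage 2:
#' dual-excitation discrepancy; stage 3: pan-assay signal reduction across
#' the two parallel assays, evaluated only on compounds surviving stages
#' 1-2 within the assay being reported -- then calls hits. Each excluded
#' compound is attributed to the first stage that triggers, so the stage
#' counts partition the exclusions.
#'
#' @param assay_a,assay_b Per-assay input: a list with elements `pre`
#'   (compound pre-read [fret_plate]) and `assay` (FRET-pair plate measured
#'   at 410 and 430 nm excitation).
#' @param fold_threshold,rel_threshold,diff_threshold,pan_threshold
#'   Filter thresholds, see [interference_filters].
#' @param hit_threshold Hit cutoff in percent inhibition (inclusive).
#' @return An object of class `fret_screen`: `$results` (one row per
#'   compound per assay, with both inhibitions, individual filter flags,
#'   `excluded_by` and `is_hit`) and `$summary` (one [screen_summary()] row
#'   per assay).
#' @export
run_screen <- function(assay_a, assay_b, fold_threshold = 5,
                       rel_threshold = 0.30, diff_threshold = 10,
                       pan_threshold = 20, hit_threshold = 20) {
  res_a <- screen_assay(assay_a$pre, assay_a$assay, fold_threshold,
                        rel_threshold, diff_threshold)
  res_b <- screen_assay(assay_b$pre, assay_b$assay, fold_threshold,
                        rel_threshold, diff_threshold)
  if (nrow(res_a) == 0 || nrow(res_b) == 0) {
    abort("Empty compound library", class = "fretscreen_error_validation")
  }
  mismatch <- c(setdiff(res_a$compound_id, res_b$compound_id),
                setdiff(res_b$compound_id, res_a$compound_id))
  if (length(mismatch)) {
    abort(paste0("Compound libraries differ between assays: ",
                 paste(head(mismatch, 10), collapse = ", ")),
          class = "fretscreen_error_reconciliation")
  }

  attribute <- function(this, other) {
    this <- dplyr::left_join(
      this,
      dplyr::select(other, "compound_id", other_inhibition = "inhibition_410"),
      by = "compound_id")
    this <- dplyr::mutate(
      this,
      stage1 = .data$strong_autofluorescence | .data$fret_fluor_deviation,
      stage2 = !.data$stage1 & .data$dual_excitation_discrepancy,
      survivor = !.data$stage1 & !.data$stage2,
      pan_assay = .data$survivor & filter_pan_assay(
        .data$inhibition_410, .data$other_inhibition, pan_threshold),
      excluded_by = dplyr::case_when(
        .data$stage1 ~ "fluorescence",
        .data$stage2 ~ "dual_excitation",
        .data$pan_assay ~ "pan_assay",
        TRUE ~ "none"))
    call_hits(dplyr::select(this, -"stage1", -"stage2", -"survivor",
                            -"other_inhibition"),
              hit_threshold = hit_threshold)
  }

  out_a <- attribute(res_a, res_b)
  out_b <- attribute(res_b, res_a)
  results <- dplyr::bind_rows(A = out_a, B = out_b, .id = "assay")

  summary <- dplyr::bind_rows(
    dplyr::mutate(summarize_screen(out_a), assay = "A", .before = 1),
    dplyr::mutate(summarize_screen(out_b), assay = "B", .before = 1))

  structure(list(results = results, summary = summary,
                 thresholds = list(fold = fold_threshold, rel = rel_threshold,
                                   diff = diff_threshold, pan = pan_threshold,
                                   hit = hit_threshold)),
            class = "fret_screen")
}

#' @export
print.fret_screen <- function(x, ...) {
  cat("Two-assay FRET interference screen\n")
  print(x$summary)
  invisible(x)
}

#' Screen accounting summary
#'
#' Builds the exclusion/hit accounting block from stage-wise counts. The
#' three stage counts must partition the exclusions (each compound is
#' attributed to the first stage that triggered), so the total is their
#' sum. Percentages are formatted as printed in screening reports:
#' exclusion percentages to 1 decimal, hit rates to 2 decimals, both with
#' round-half-even.
#'
#' @param n_screened Number of compounds screened.
#' @param n_excluded_fluor,n_excluded_dual,n_excluded_pan Stage-wise
#'   exclusion counts (fluorescence criteria; dual-excitation discrepancy;
#'   pan-assay).
#' @param n_hits Number of hits among the survivors.
#' @return One-row tibble with the counts, `n_excluded_total`, and
#'   formatted percentage strings `pct_excluded_fluor`, `pct_excluded_dual`,
#'   `pct_excluded_pan`, `pct_excluded_total` and `pct_hits`.
#' @export
screen_summary <- function(n_screened, n_excluded_fluor, n_excluded_dual,
                           n_excluded_pan, n_hits) {
  total <- n_excluded_fluor + n_excluded_dual + n_excluded_pan
  if (n_hits > n_screened - total) {
    abort("More hits than surviving compounds",
          class = "fretscreen_error_validation")
  }
  pct <- function(count, digits) {
    paste0(formatC(round(100 * count / n_screened, digits),
                   format = "f", digits = digits), "%")
  }
  tibble::tibble(
    n_screened = n_screened,
    n_excluded_fluor = n_excluded_fluor,
    n_excluded_dual = n_excluded_dual,
    n_excluded_pan = n_excluded_pan,
    n_excluded_total = total,
    n_hits = n_hits,
    pct_excluded_fluor = pct(n_excluded_fluor, 1),
    pct_excluded_dual = pct(n_excluded_dual, 1),
    pct_excluded_pan = pct(n_excluded_pan, 1),
    pct_excluded_total = pct(total, 1),
    pct_hits = pct(n_hits, 2))
}

#' @describeIn screen_summary Accounting computed from a per-compound
#'   results table (columns `excluded_by`, `is_hit`).
#' @param results Per-compound results for one assay.
#' @export
summarize_screen <- function(results) {
  screen_summary(
    n_screened = nrow(results),
    n_excluded_fluor = sum(results$excluded_by == "fluorescence"),
    n_excluded_dual = sum(results$excluded_by == "dual_excitation"),
    n_excluded_pan = sum(results$excluded_by == "pan_assay"),
    n_hits = sum(results$is_hit))
}

#' Write the per-compound screen report
#'
#' One CSV row per compound (inhibition at both excitations, each filter
#' flag, the first triggering filter and hit status) plus a JSON summary
#' sidecar with per-filter exclusion counts and formatted percentages.
#'
#' @param results Per-compound results for one assay (as in
#'   `run_screen()$results` filtered to one assay), non-empty.
#' @param path Output CSV path; the summary is written next to it with a
#'   `_summary.json` suffix.
#' @return Invisibly, a list with the `csv` and `json` paths.
#' @export
write_screen_report <- function(results, path) {
  if (is.null(results) || nrow(results) == 0) {
    abort("Empty screen results", class = "fretscreen_error_validation")
  }
  cols <- intersect(
    c("assay", "compound_id", "inhibition_410", "inhibition_430",
      "strong_autofluorescence", "fret_fluor_deviation",
      "dual_excitation_discrepancy", "pan_assay", "excluded_by", "is_hit"),
    names(results))
  ok <- tryCatch({
    readr::write_csv(dplyr::select(results, dplyr::all_of(cols)), path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    abort(paste0("Cannot write report to ", path),
          class = "fretscreen_error_io")
  }
  json_path <- sub("\\.csv$", "", path)
  json_path <- paste0(json_path, "_summary.json")
  summ <- summarize_screen(results)
  jsonlite::write_json(as.list(summ), json_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(csv = path, json = json_path))
}

#' Scatter plot of screen inhibition by compound
#'
#' Mirrors the usual validatory-screen figure: per-compound 410 nm
#' inhibition, colored by triage outcome, with the hit threshold drawn as
#' a dotted line.
#'
#' @param results Per-compound results for one assay.
#' @param hit_threshold Hit cutoff to draw.
#' @return A ggplot object.
#' @export
plot_screen <- function(results, hit_threshold = 20) {
  results$status <- dplyr::case_when(
    results$is_hit ~ "hit",
    results$excluded_by != "none" ~ "excluded",
    TRUE ~ "inactive")
  results$index <- seq_len(nrow(results))
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$index, y = .data$inhibition_410,
                               colour = .data$status)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::geom_hline(yintercept = hit_threshold, linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(hit = "#b2182b",
                                            excluded = "grey60",
                                            inactive = "#2166ac")) +
    ggplot2::labs(x = "Compound", y = "Inhibition at 410 nm (%)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
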