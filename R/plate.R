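#' Construct a FRET plate object
#'
#' A plate is stored in long format: one row per fluorescence read, i.e. per
#' (well, excitation, emission) triple, with the well annotation (role,
#' compound, protein concentrations) repeated on every read of that well.
#' This channel-explicit layout avoids any ambiguity between the three
#' excitation wavelengths (410/430/477 nm) used across the assay.
#'
#' @param wells Data frame with columns `well`, `role` (one of `sample`,
#'   `negative_control`, `positive_control`, `blank`), and optionally
#'   `compound_id`, `compound_conc`, `donor_conc`, `acceptor_conc` (molar).
#' @param reads Data frame with columns `well`, `excitation_nm`,
#'   `emission_nm`, `intensity`.
#' @param plate_id Identifier string.
#' @param format Plate format (96, 384 or 1536). `NULL` picks the smallest
#'   standard format containing all well coordinates.
#' @param assay_label Free-text assay label (e.g. "ARC4-TBM").
#' @return A tibble of class `fret_plate`, one row per read, with attributes
#'   `plate_id`, `plate_format` and `assay_label`.
#' @export
fret_plate <- function(wells, reads, plate_id = "plate1", format = NULL,
                       assay_label = "") {
  wells <- tibble::as_tibble(wells)
  reads <- tibble::as_tibble(reads)

  need_wells <- c("well", "role")
  need_reads <- c("well", "excitation_nm", "emission_nm", "intensity")
  missing_w <- setdiff(need_wells, names(wells))
  missing_r <- setdiff(need_reads, names(reads))
  if (length(missing_w) || length(missing_r)) {
    abort(paste0("Missing required columns: ",
                 paste(c(missing_w, missing_r), collapse = ", ")),
          class = "fretscreen_error_format")
  }

  for (col in c("compound_id")) {
    if (!col %in% names(wells)) wells[[col]] <- NA_character_
  }
  for (col in c("compound_conc", "donor_conc", "acceptor_conc")) {
    if (!col %in% names(wells)) wells[[col]] <- NA_real_
  }

  roles <- c("sample", "negative_control", "positive_control", "blank")
  bad_role <- setdiff(unique(wells$role), roles)
  if (length(bad_role)) {
    abort(paste0("Unknown well role(s): ", paste(bad_role, collapse = ", ")),
          class = "fretscreen_error_validation")
  }

  if (anyDuplicated(wells$well)) {
    abort("Duplicated wells in plate map", class = "fretscreen_error_duplication")
  }
  dup <- duplicated(reads[c("well", "excitation_nm", "emission_nm")])
  if (any(dup)) {
    offenders <- unique(reads$well[dup])
    abort(paste0("Duplicated (well, channel) reads: ",
                 paste(head(offenders, 5), collapse = ", ")),
          class = "fretscreen_error_duplication")
  }

  only_reads <- setdiff(reads$well, wells$well)
  only_map <- setdiff(wells$well, reads$well)
  if (length(only_reads) || length(only_map)) {
    abort(paste0(
      "Wells do not match between measurements and plate map. ",
      if (length(only_reads)) paste0("Measured but unmapped: ",
                                     paste(head(only_reads, 5), collapse = ", "), ". "),
      if (length(only_map)) paste0("Mapped but unmeasured: ",
                                   paste(head(only_map, 5), collapse = ", "))),
      class = "fretscreen_error_validation")
  }

  if (is.null(format)) {
    format <- Find(function(f) all(well_in_format(wells$well, f)),
                   c(96, 384, 1536))
    if (is.null(format)) {
      abort("Well coordinates fit no standard plate format",
            class = "fretscreen_error_validation")
    }
  } else {
    bad <- wells$well[!well_in_format(wells$well, format)]
    if (length(bad)) {
      abort(paste0("Well coordinates outside ", format, "-well format: ",
                   paste(head(bad, 5), collapse = ", ")),
            class = "fretscreen_error_validation")
    }
  }

  if (any(wells$role == "blank" &
          (!is.na(wells$donor_conc) & wells$donor_conc > 0 |
           !is.na(wells$acceptor_conc) & wells$acceptor_conc > 0))) {
    abort("Blank wells must not declare protein concentrations",
          class = "fretscreen_error_validation")
  }
  neg <- c("donor_conc", "acceptor_conc", "compound_conc")
  if (any(unlist(wells[neg]) < 0, na.rm = TRUE)) {
    abort("Concentrations must be non-negative",
          class = "fretscreen_error_validation")
  }

  out <- dplyr::left_join(reads, wells, by = "well")
  out <- dplyr::select(out, "well", "role", "compound_id", "compound_conc",
                       "donor_conc", "acceptor_conc",
                       "excitation_nm", "emission_nm", "intensity")
  structure(out,
            class = c("fret_plate", class(tibble::tibble())),
            plate_id = plate_id, plate_format = as.integer(format),
            assay_label = assay_label)
}

#' Read a plate from measurement and plate-map files
#'
#' The measurement file is the canonical long format with columns
#' `well`, `excitation_nm`, `emission_nm`, `intensity`; the plate map has
#' `well`, `role` and optional compound/concentration columns. Both CSV and
#' TSV are accepted (delimiter sniffed from the header line).
#'
#' @param measurement_file Path to the measurement table.
#' @param plate_map_file Path to the plate map.
#' @inheritParams fret_plate
#' @return A [fret_plate] object.
#' @export
read_plate <- function(measurement_file, plate_map_file, plate_id = NULL,
                       format = NULL, assay_label = "") {
  reads <- read_delim_auto(measurement_file)
  wells <- read_delim_auto(plate_map_file)
  if (is.null(plate_id)) {
    plate_id <- tools::file_path_sans_ext(basename(measurement_file))
  }
  fret_plate(wells, reads, plate_id = plate_id, format = format,
             assay_label = assay_label)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "fretscreen_error_io")
  }
  header <- readLines(path, n = 1)
  delim <- if (grepl("\t", header)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

#' Write a plate back to measurement and plate-map files
#'
#' Inverse of [read_plate()]; the two CSVs round-trip losslessly through
#' [read_plate()].
#'
#' @param plate A [fret_plate].
#' @param measurement_file,plate_map_file Output paths.
#' @return Invisibly, the two paths.
#' @export
write_plate <- function(plate, measurement_file, plate_map_file) {
  reads <- dplyr::select(tibble::as_tibble(plate), "well", "excitation_nm",
                         "emission_nm", "intensity")
  wells <- dplyr::distinct(
    dplyr::select(tibble::as_tibble(plate), "well", "role", "compound_id",
                  "compound_conc", "donor_conc", "acceptor_conc"))
  readr::write_csv(reads, measurement_file)
  readr::write_csv(wells, plate_map_file)
  invisible(c(measurement_file, plate_map_file))
}

plate_wells <- function(plate) {
  dplyr::distinct(
    dplyr::select(tibble::as_tibble(plate), "well", "role", "compound_id",
                  "compound_conc", "donor_conc", "acceptor_conc"))
}

#' Subtract blank fluorescence per channel
#'
#' For every (excitation, emission) channel, the mean intensity over all
#' blank wells is subtracted from every non-blank well. Blank wells are left
#' untouched. Negative corrected intensities are kept (with a warning) under
#' the default policy; pass `floor` to clamp them instead.
#'
#' @param plate A [fret_plate] with at least one blank well per channel.
#' @param floor `NULL` (default) to keep negative corrected intensities, or
#'   a numeric floor (typically 0) to clamp them.
#' @return The blank-corrected plate.
#' @export
subtract_blanks <- function(plate, floor = NULL) {
  df <- tibble::as_tibble(plate)
  blanks <- dplyr::filter(df, .data$role == "blank")
  if (nrow(blanks) == 0) {
    abort("No blank wells on plate; blank subtraction impossible",
          class = "fretscreen_error_missing_blank")
  }
  blank_means <- dplyr::summarise(
    dplyr::group_by(blanks, .data$excitation_nm, .data$emission_nm),
    .blank_mean = mean(.data$intensity), .groups = "drop")

  channels <- dplyr::distinct(df, .data$excitation_nm, .data$emission_nm)
  uncovered <- dplyr::anti_join(channels, blank_means,
                                by = c("excitation_nm", "emission_nm"))
  if (nrow(uncovered)) {
    abort(paste0("Channels without blank reads: ",
                 paste(paste0("(", uncovered$excitation_nm, ",",
                              uncovered$emission_nm, ")"), collapse = " ")),
          class = "fretscreen_error_missing_blank")
  }

  out <- dplyr::left_join(df, blank_means,
                          by = c("excitation_nm", "emission_nm"))
  corrected <- ifelse(out$role == "blank", out$intensity,
                      out$intensity - out$.blank_mean)
  n_neg <- sum(corrected < 0 & out$role != "blank")
  if (n_neg > 0) {
    if (is.null(floor)) {
      warn(paste0(n_neg, " blank-corrected intensities are negative"))
    } else {
      corrected <- ifelse(out$role != "blank", pmax(corrected, floor), corrected)
    }
  }
  out$intensity <- corrected
  out$.blank_mean <- NULL
  attributes_from(out, plate)
}

attributes_from <- function(df, plate) {
  structure(tibble::as_tibble(df),
            class = c("fret_plate", class(tibble::tibble())),
            plate_id = attr(plate, "plate_id"),
            plate_format = attr(plate, "plate_format"),
            assay_label = attr(plate, "assay_label"))
}

#' @export
print.fret_plate <- function(x, ...) {
  n_wells <- length(unique(x$well))
  cat(sprintf("<fret_plate> %s (%d-well format, %s): %d wells, %d reads\n",
              attr(x, "plate_id"), attr(x, "plate_format"),
              if (nzchar(attr(x, "assay_label"))) attr(x, "assay_label") else "unlabelled",
              n_wells, nrow(x)))
  NextMethod()
}
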