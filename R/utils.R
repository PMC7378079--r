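#' @importFrom rlang abort warn .data :=
#' @importFrom stats qchisq sd setNames uniroot optimize coef vcov resid
#' @importFrom utils head
NULL

# Standard plate geometries: rows x columns
PLATE_FORMATS <- list(
  `96`   = c(rows = 8L,  cols = 12L),
  `384`  = c(rows = 16L, cols = 24L),
  `1536` = c(rows = 32L, cols = 48L)
)

# Row labels A..Z then AA, AB, ... (1536-well readers label rows 27-32 AA-AF)
plate_row_labels <- function(n) {
  stopifnot(n <= 52)
  c(LETTERS, paste0("A", LETTERS))[seq_len(n)]
}

#' Enumerate well identifiers for a plate format
#'
#' Row-major well ids ("A1", "A2", ...) for a standard 96-, 384- or
#' 1536-well plate.
#'
#' @param format Plate format: 96, 384 or 1536.
#' @return Character vector of well ids, row-major order.
#' @export
well_ids <- function(format = 384) {
  geom <- plate_geometry(format)
  rows <- plate_row_labels(geom[["rows"]])
  as.vector(t(outer(rows, seq_len(geom[["cols"]]), paste0)))
}

plate_geometry <- function(format) {
  key <- as.character(format)
  if (!key %in% names(PLATE_FORMATS)) {
    abort(paste0("Unknown plate format: ", format, " (use 96, 384 or 1536)"),
          class = "fretscreen_error_validation")
  }
  PLATE_FORMATS[[key]]
}

# Split well ids into (row label, column number); invalid ids -> NA row
parse_wells <- function(well) {
  m <- regmatches(well, regexec("^([A-Z]{1,2})([0-9]{1,2})$", well))
  row <- vapply(m, function(x) if (length(x) == 3) x[2] else NA_character_, "")
  col <- vapply(m, function(x) if (length(x) == 3) as.integer(x[3]) else NA_integer_, 1L)
  tibble::tibble(row = row, col = col)
}

#' Check well coordinates against a plate format
#'
#' @param well Character vector of well ids such as "A1" or "AF48".
#' @param format Plate format: 96, 384 or 1536.
#' @return Logical vector, TRUE where the coordinate exists on the plate.
#' @export
well_in_format <- function(well, format = 384) {
  geom <- plate_geometry(format)
  rows <- plate_row_labels(geom[["rows"]])
  parsed <- parse_wells(toupper(well))
  !is.na(parsed$row) & parsed$row %in% rows &
    !is.na(parsed$col) & parsed$col >= 1L & parsed$col <= geom[["cols"]]
}

# Run expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}
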