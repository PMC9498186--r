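#' Column contract of the measurement table
#'
#' Fixed column set of the per-image measurement CSV, in order.
#'
#' @return Character vector of column names.
#' @export
measurement_columns <- function() {
  c("image_id", "group",
    "area_whole_mm2", "area_cystic_mm2", "area_solid_mm2", "area_ratio",
    "mean_whole", "mean_cystic", "mean_solid",
    "sd_whole", "sd_cystic", "sd_solid",
    "density_whole", "density_cystic", "density_solid",
    "lobule_count", "parenchyma_mean", "parenchyma_sd")
}

#' Coerce lesion measurements to a data frame
#'
#' @param records A single `lesion_measurement`, a list of them, or a data
#'   frame already in the column contract.
#' @return Data frame with the columns of [measurement_columns()].
#' @export
measurements_to_df <- function(records) {
  if (is.data.frame(records)) {
    missing_cols <- setdiff(measurement_columns(), names(records))
    if (length(missing_cols)) {
      stop(sprintf("measurement data frame lacks column(s): %s",
                   paste(missing_cols, collapse = ", ")), call. = FALSE)
    }
    return(records[measurement_columns()])
  }
  if (inherits(records, "lesion_measurement")) records <- list(records)
  stopifnot(is.list(records), length(records) >= 1L)
  rows <- lapply(records, function(r) {
    stopifnot(inherits(r, "lesion_measurement"))
    as.data.frame(r[measurement_columns()], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write per-image measurements to CSV
#'
#' One row per image, fixed column set ([measurement_columns()]), UTF-8.
#' Numeric values are written with enough digits that a round-trip through
#' [read_measurements()] reproduces them to at least 6 significant digits;
#' missing metrics (no solid part, no parenchyma block) are empty cells,
#' never zeros.
#'
#' @param records See [measurements_to_df()]; must be non-empty.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  df <- measurements_to_df(records)
  if (nrow(df) < 1L) stop("no measurement records to write", call. = FALSE)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), NA_character_, formatC(x, digits = 10, format = "g"))
  })
  utf8_write_csv(df, path)
  invisible(path)
}

utf8_write_csv <- function(df, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, na = "")
}

#' Read a measurement CSV written by [write_measurements()]
#'
#' @param path CSV path.
#' @return Data frame in the column contract, empty cells as `NA`.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop(sprintf("measurement file not found: '%s'", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(image_id = "character", group = "character"),
                        encoding = "UTF-8")
  measurements_to_df(df)
}
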