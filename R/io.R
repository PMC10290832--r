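# Data readers/writers and the bundled Surat Thani wind-speed dataset.

#' Read grouped samples from a CSV file
#'
#' Expects a header row with columns `group` and `value` (UTF-8, decimal
#' dot), one observation per row.  Groups are returned in order of first
#' appearance.
#'
#' @param path path to a readable CSV file.
#' @return a named list of numeric vectors, one per group.
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) input_error(sprintf("file not found: %s", path))
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) input_error(sprintf("cannot parse %s: %s",
                                                         path, conditionMessage(e))))
  if (!all(c("group", "value") %in% names(df)))
    input_error(sprintf("%s: required columns 'group' and 'value' not found", path))
  if (nrow(df) == 0L) input_error(sprintf("%s: no data rows", path))
  val <- suppressWarnings(as.numeric(df$value))
  bad <- which(!is.finite(val) | val <= 0)
  if (length(bad) > 0L)
    input_error(sprintf("%s: non-numeric or non-positive value at data row %d",
                        path, bad[1L]))
  groups <- unique(as.character(df$group))
  out <- lapply(groups, function(g) val[df$group == g])
  names(out) <- groups
  for (g in groups) {
    if (length(out[[g]]) < 2L)
      input_error(sprintf("%s: group '%s' has fewer than 2 observations", path, g))
  }
  out
}

#' Monthly wind-speed data from three districts of Surat Thani province
#'
#' Ten years (2010-2019) of monthly wind speeds (m/s) recorded by weather
#' stations in Khiri Rat Nikhom, Koh Samui and Kanchanadit, 50 observations
#' per district, bundled with the package.
#'
#' @return a named list of three numeric vectors of length 50.
#' @examples
#' wind <- surat_thani_wind()
#' sapply(wind, length)
#' @export
surat_thani_wind <- function() {
  path <- system.file("extdata", "surat_thani_wind.csv", package = "weibullcm")
  if (!nzchar(path)) input_error("bundled dataset not found; is the package installed?")
  read_samples(path)
}

#' Write result records to JSON or CSV
#'
#' Numeric fields are rounded to 6 significant digits.  Existing files are
#' overwritten.
#'
#' @param records a data frame, or a list of named lists (records).
#' @param path output file path.
#' @param format `"json"` (array of records) or `"csv"` (flat table).
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (is.data.frame(records)) {
    df <- records
  } else if (is.list(records)) {
    df <- if (length(records) == 0L) data.frame() else
      do.call(rbind, lapply(records, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  } else input_error("records must be a data frame or a list of records")
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], signif, digits = 6L)
  ok <- tryCatch({
    if (format == "json") {
      jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
    } else {
      utils::write.csv(df, path, row.names = FALSE)
    }
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) input_error(sprintf("cannot write to %s", path))
  invisible(path)
}
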