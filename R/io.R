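#' Write / read a collection catalog CSV
#'
#' Plain CSV with header, columns plate_id, well, mutant_id,
#' control_class, k_per_h, lag_h, occupied; wells as letter+number
#' (A1..H12).
#'
#' @param catalog Catalog data frame.
#' @param path CSV path.
#' @return `read_catalog` returns the catalog data frame.
#' @export
write_catalog <- function(catalog, path) {
  cols <- c("plate_id", "well", "mutant_id", "control_class",
            "k_per_h", "lag_h", "occupied")
  missing <- setdiff(cols, names(catalog))
  if (length(missing)) stop("catalog lacks columns: ",
                            paste(missing, collapse = ", "))
  utils::write.csv(catalog[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  key <- paste(df$plate_id, df$well)
  if (anyDuplicated(key)) stop("duplicate (plate_id, well) keys in catalog")
  df$occupied <- as.logical(df$occupied)
  df
}

#' Write / read an acquisition log CSV
#'
#' Sidecar log mapping image files to acquisition times (hours since
#' assay start); the analysis reads timestamps from this log rather
#' than from image metadata.
#'
#' @param log Data frame with columns path, timestamp_h.
#' @param path CSV path.
#' @return `read_acquisition_log` returns the log data frame.
#' @export
write_acquisition_log <- function(log, path) {
  stopifnot(all(c("path", "timestamp_h") %in% names(log)))
  utils::write.csv(log[, c("path", "timestamp_h")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_acquisition_log
#' @export
read_acquisition_log <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
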