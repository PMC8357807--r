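#' Well addresses of a 96-well plate
#'
#' Standard row-major addresses A1..A12, B1..B12, ..., H12 (8 rows A-H,
#' 12 columns).
#'
#' @return Character vector of length 96.
#' @export
well_names <- function() {
  as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
}

#' Split well addresses into grid coordinates
#'
#' @param well Character vector of addresses such as "A1" or "H12".
#' @return Data frame with columns `row` (1-8, A = 1) and `col` (1-12).
#' @export
well_to_grid <- function(well) {
  row <- match(substr(well, 1, 1), LETTERS[1:8])
  col <- as.integer(substring(well, 2))
  bad <- is.na(row) | is.na(col) | col < 1 | col > 12
  if (any(bad)) {
    stop("invalid well address: ", paste(well[bad], collapse = ", "))
  }
  data.frame(row = row, col = col)
}

#' @rdname well_to_grid
#' @param row,col Grid coordinates (row 1-8, col 1-12).
#' @export
grid_to_well <- function(row, col) {
  stopifnot(all(row >= 1 & row <= 8), all(col >= 1 & col <= 12))
  paste0(LETTERS[row], col)
}

# Clip numeric values into [lo, hi].
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Luminance (simple channel mean) of an h x w x 3 image array on 0..255.
luminance <- function(img) (img[, , 1] + img[, , 2] + img[, , 3]) / 3
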