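# Code 128 barcode symbology (code set B), used to label synthetic plates
# and to decode plate identity from photographs. Implemented here because
# no barcode package is available for R; the widths table below is the
# canonical 107-symbol table (values 0-106). Each entry gives the widths
# (in modules, 1-4) of alternating bar/space elements; symbols 0-105 are
# 6 elements / 11 modules, the stop symbol (106) is 7 elements / 13
# modules.

CODE128_WIDTHS <- c(
  "212222", "222122", "222221", "121223", "121322", "131222", "122213",
  "122312", "132212", "221213", "221312", "231212", "112232", "122132",
  "122231", "113222", "123122", "123221", "223211", "221132", "221231",
  "213212", "223112", "312131", "311222", "321122", "321221", "312212",
  "322112", "322211", "212123", "212321", "232121", "111323", "131123",
  "131321", "112313", "132113", "132311", "211313", "231113", "231311",
  "112133", "112331", "132131", "113123", "113321", "133121", "313121",
  "211331", "231131", "213113", "213311", "213131", "311123", "311321",
  "331121", "312113", "312311", "332111", "314111", "221411", "431111",
  "111224", "111422", "121124", "121421", "141122", "141221", "112214",
  "112412", "122114", "122411", "142112", "142211", "241211", "221114",
  "413111", "241112", "134111", "111242", "121142", "121241", "114212",
  "124112", "124211", "411212", "421112", "421211", "212141", "214121",
  "412121", "111143", "111341", "131141", "114113", "114311", "411113",
  "411311", "113141", "114131", "311141", "411131", "211412", "211214",
  "211232", "2331112"
)

CODE128_START_B <- 104L
CODE128_STOP <- 106L

# Reverse lookup: widths string -> symbol value (0-based).
.code128_lookup <- local({
  env <- new.env(parent = emptyenv())
  for (i in seq_along(CODE128_WIDTHS)) {
    assign(CODE128_WIDTHS[i], i - 1L, envir = env)
  }
  env
})

code128_symbol_values <- function(payload) {
  codes <- utf8ToInt(payload) - 32L
  if (any(codes < 0L | codes > 94L)) {
    stop("payload contains characters outside Code 128 set B")
  }
  codes
}

#' Encode a string as a Code 128 (set B) module sequence
#'
#' @param payload Character scalar; printable ASCII (codes 32-126).
#' @return Integer vector of module colors (1 = bar/black, 0 = space),
#'   including start symbol, data, checksum and stop symbol, without
#'   quiet zones.
#' @keywords internal
code128_encode <- function(payload) {
  stopifnot(is.character(payload), length(payload) == 1L, nzchar(payload))
  values <- code128_symbol_values(payload)
  checksum <- (CODE128_START_B +
    sum(values * seq_along(values))) %% 103L
  symbols <- c(CODE128_START_B, values, checksum, CODE128_STOP)
  modules <- integer(0)
  for (s in symbols) {
    widths <- as.integer(strsplit(CODE128_WIDTHS[s + 1L], "")[[1]])
    colors <- rep(c(1L, 0L), length.out = length(widths))
    modules <- c(modules, rep(colors, widths))
  }
  modules
}

# Decode one row of run lengths. `runs` is an rle-style list with
# `values` (logical, TRUE = dark) and `lengths`. Returns the payload
# string plus the pixel extent of the symbol sequence, or NULL if no
# valid barcode is present in this row.
code128_decode_runs <- function(values, lengths) {
  dark_idx <- which(values)
  starts <- cumsum(c(1L, lengths))[seq_along(lengths)]
  for (i in dark_idx) {
    # need at least start + checksum + stop = 6 + 6 + 7 runs
    if (i + 18L > length(lengths)) break
    sym <- read_symbol(lengths, i, 6L, 11)
    if (is.null(sym) || !(sym %in% c(103L, 104L, 105L))) next
    res <- decode_from_start(values, lengths, i, starts)
    if (!is.null(res)) return(res)
  }
  NULL
}

read_symbol <- function(lengths, at, n_elem, n_modules) {
  if (at + n_elem - 1L > length(lengths)) return(NULL)
  runs <- lengths[at:(at + n_elem - 1L)]
  module <- sum(runs) / n_modules
  widths <- round(runs / module)
  if (any(widths < 1L | widths > 4L) || sum(widths) != n_modules) {
    return(NULL)
  }
  key <- paste(widths, collapse = "")
  val <- get0(key, envir = .code128_lookup, inherits = FALSE)
  val
}

decode_from_start <- function(values, lengths, start_at, starts) {
  start_sym <- read_symbol(lengths, start_at, 6L, 11)
  if (is.null(start_sym) || start_sym != CODE128_START_B) return(NULL)
  at <- start_at + 6L
  syms <- integer(0)
  repeat {
    stop_sym <- read_symbol(lengths, at, 7L, 13)
    if (!is.null(stop_sym) && stop_sym == CODE128_STOP) {
      at <- at + 7L
      break
    }
    sym <- read_symbol(lengths, at, 6L, 11)
    if (is.null(sym)) return(NULL)
    syms <- c(syms, sym)
    at <- at + 6L
    if (at > length(lengths) || length(syms) > 64L) return(NULL)
  }
  if (length(syms) < 2L) return(NULL)
  data_vals <- syms[-length(syms)]
  checksum <- syms[length(syms)]
  expect <- (CODE128_START_B + sum(data_vals * seq_along(data_vals))) %% 103L
  if (checksum != expect) return(NULL)
  payload <- intToUtf8(data_vals + 32L)
  x_first <- starts[start_at]
  x_last <- starts[at - 1L] + lengths[at - 1L] - 1L
  list(payload = payload, x_start = x_first, x_end = x_last)
}

# Scan an image (h x w x 3, 0..255) for a Code 128 barcode. Scans every
# `stride`-th row; returns the payload, horizontal pixel extent, and the
# row range over which the same payload decoded, or NULL.
scan_barcode <- function(img, stride = 4L, threshold = 128) {
  lum <- luminance(img)
  h <- nrow(lum)
  hits <- list()
  for (y in seq(1L, h, by = stride)) {
    dark <- lum[y, ] < threshold
    r <- rle(dark)
    res <- code128_decode_runs(r$values, r$lengths)
    if (!is.null(res)) {
      hits[[length(hits) + 1L]] <- c(
        y = y, x_start = res$x_start, x_end = res$x_end,
        payload = res$payload
      )
    }
  }
  if (length(hits) == 0L) return(NULL)
  payloads <- vapply(hits, function(h) h[["payload"]], character(1))
  payload <- names(sort(table(payloads), decreasing = TRUE))[1]
  keep <- hits[payloads == payload]
  ys <- vapply(keep, function(h) as.numeric(h[["y"]]), numeric(1))
  list(
    payload = payload,
    x_start = as.numeric(keep[[1]][["x_start"]]),
    x_end = as.numeric(keep[[1]][["x_end"]]),
    y_range = range(ys),
    ambiguous = length(unique(payloads)) > 1L
  )
}
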