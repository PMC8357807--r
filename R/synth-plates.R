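# Synthetic plate-photograph generator. Emulates macroscope images of
# 96-well assay plates: a Code 128 barcode strip with two registration
# marks along the top edge, and an 8 x 12 grid of well discs whose color
# follows the dye-oxidation kinetic model. Ground truth accompanies
# every rendered image so the full decode -> locate -> sample -> score
# chain can be tested against known values.

#' Plate image geometry
#'
#' Pixel layout shared by the renderer and the decoder: image size, well
#' grid origin/pitch/radius, barcode placement and module size, and the
#' offsets of the two registration marks relative to the barcode ends.
#' The decoder re-derives well-center positions from the decoded barcode
#' span and the mark centroids by a two-point similarity transform, so
#' the absolute placement here is a rendering convention, not a
#' requirement on input images.
#'
#' @param image_width,image_height Image size in pixels.
#' @param grid_x0,grid_y0 Center of well A1 in pixels.
#' @param pitch Well-to-well spacing in pixels.
#' @param well_radius Rendered well disc radius in pixels.
#' @param barcode_x,barcode_y0,barcode_y1 Barcode left edge and row band.
#' @param module_width Width of one barcode module in pixels.
#' @param mark_radius Registration-mark disc radius in pixels.
#' @param mark_offset_left,mark_offset_right Horizontal offsets of the
#'   left/right mark centers from the first/last bar of the barcode.
#' @param background RGB background color (0-255).
#' @return A `plate_geometry` list.
#' @export
plate_geometry <- function(image_width = 560L, image_height = 440L,
                           grid_x0 = 70, grid_y0 = 130, pitch = 36,
                           well_radius = 13,
                           barcode_x = 140L, barcode_y0 = 20L,
                           barcode_y1 = 60L, module_width = 2L,
                           mark_radius = 9,
                           mark_offset_left = -60,
                           mark_offset_right = 60,
                           background = c(255, 255, 255)) {
  stopifnot(well_radius > 0, pitch > 2 * well_radius, module_width >= 1)
  g <- list(
    image_width = as.integer(image_width),
    image_height = as.integer(image_height),
    grid_x0 = grid_x0, grid_y0 = grid_y0, pitch = pitch,
    well_radius = well_radius,
    barcode_x = as.integer(barcode_x), barcode_y0 = as.integer(barcode_y0),
    barcode_y1 = as.integer(barcode_y1),
    module_width = as.integer(module_width),
    mark_radius = mark_radius,
    mark_offset_left = mark_offset_left,
    mark_offset_right = mark_offset_right,
    background = background
  )
  class(g) <- "plate_geometry"
  g
}

#' Specify a synthetic assay plate
#'
#' @param plate_id Barcode payload (printable ASCII, Code 128 set B).
#' @param layout Data frame with one row per well: columns `well`,
#'   `mutant_id`, `control_class` (one of `"blank_no_cell"`,
#'   `"quasi_wild_type"`, `"test_mutant"`), `k_per_h` (oxidation rate,
#'   1/h), `lag_h` (lag, hours), `occupied` (logical). See
#'   [plate_layout()].
#' @param geometry A [plate_geometry()].
#' @return A `plate_spec` list.
#' @export
plate_spec <- function(plate_id, layout, geometry = plate_geometry()) {
  stopifnot(is.character(plate_id), length(plate_id) == 1L, nzchar(plate_id))
  required <- c("well", "mutant_id", "control_class", "k_per_h", "lag_h",
                "occupied")
  if (!all(required %in% names(layout))) {
    stop("layout must have columns: ", paste(required, collapse = ", "))
  }
  if (!setequal(layout$well, well_names()) ||
      nrow(layout) != 96L) {
    stop("layout must contain each of the 96 wells A1..H12 exactly once")
  }
  if (!all(layout$control_class %in%
             c("blank_no_cell", "quasi_wild_type", "test_mutant"))) {
    stop("unknown control_class in layout")
  }
  if (any(!is.finite(layout$k_per_h)) || any(layout$k_per_h < 0)) {
    stop("k_per_h must be finite and >= 0")
  }
  blank_bad <- layout$control_class == "blank_no_cell" & layout$k_per_h != 0
  if (any(blank_bad)) {
    stop("blank_no_cell wells must have k_per_h = 0")
  }
  # rendered plate must fit: grid plus barcode inside the image
  n_modules <- length(code128_encode(plate_id))
  bar_w <- n_modules * geometry$module_width
  right_edge <- geometry$barcode_x + bar_w + geometry$mark_offset_right +
    geometry$mark_radius
  grid_right <- geometry$grid_x0 + 11 * geometry$pitch + geometry$well_radius
  grid_bottom <- geometry$grid_y0 + 7 * geometry$pitch + geometry$well_radius
  if (right_edge >= geometry$image_width - 2 ||
      grid_right >= geometry$image_width - 2 ||
      grid_bottom >= geometry$image_height - 2 ||
      geometry$barcode_x + geometry$mark_offset_left -
        geometry$mark_radius <= 2) {
    stop("image_size too small to place the well grid and barcode")
  }
  structure(list(plate_id = plate_id,
                 layout = layout[order(match(layout$well, well_names())), ],
                 geometry = geometry),
            class = "plate_spec")
}

#' Build a plate layout with planted phenotypes
#'
#' Convenience constructor for 96-well layouts: named control wells plus
#' test mutants with per-class oxidation rates.
#'
#' @param mutant_ids Character vector of 96 mutant identifiers (blanks
#'   may use placeholder ids).
#' @param control_class Character vector of 96 control classes, parallel
#'   to `mutant_ids`.
#' @param k_per_h,lag_h Numeric vectors (length 96 or 1) of kinetic
#'   parameters.
#' @param occupied Logical vector (length 96 or 1).
#' @return Data frame suitable for [plate_spec()].
#' @export
plate_layout <- function(mutant_ids, control_class, k_per_h, lag_h = 0,
                         occupied = TRUE) {
  data.frame(
    well = well_names(),
    mutant_id = mutant_ids,
    control_class = control_class,
    k_per_h = rep_len(k_per_h, 96L),
    lag_h = rep_len(lag_h, 96L),
    occupied = rep_len(occupied, 96L),
    stringsAsFactors = FALSE
  )
}

#' Dye-oxidation kinetic model
#'
#' Single-exponential decay of normalized yellow intensity after a lag:
#' `y(t) = y0 * exp(-k * max(0, t - lag))`. This is the forward model
#' standing in for AHDS_red -> AQDS_ox dye chemistry (orange fades to
#' clear as the dye is oxidized).
#'
#' @param y0 Initial yellow intensity in (0, 1].
#' @param noise_sd Gaussian noise on the intensity scale, applied per
#'   well before color rendering.
#' @param channel_noise_sd Gaussian noise per RGB channel (0-255 units),
#'   applied per pixel and clipped to the channel range.
#' @return An `oxidation_kinetics` list.
#' @export
oxidation_kinetics <- function(y0 = 1, noise_sd = 0.02,
                               channel_noise_sd = 2) {
  stopifnot(y0 > 0, y0 <= 1, noise_sd >= 0, channel_noise_sd >= 0)
  structure(list(y0 = y0, noise_sd = noise_sd,
                 channel_noise_sd = channel_noise_sd),
            class = "oxidation_kinetics")
}

#' True yellow intensity under the kinetic model
#'
#' @param k Oxidation rate, 1/h.
#' @param t Time since assay start, hours.
#' @param lag Lag before decay starts, hours.
#' @param y0 Initial intensity.
#' @return `y0 * exp(-k * max(0, t - lag))`, vectorized over any
#'   argument.
#' @export
kinetic_intensity <- function(k, t, lag = 0, y0 = 1) {
  y0 * exp(-k * pmax(0, t - lag))
}

# Place the nominal (unjittered) feature positions for a spec: barcode
# first/last bar x, mark centers, well centers. All in the geometry's
# pixel frame.
nominal_positions <- function(spec) {
  g <- spec$geometry
  n_modules <- length(code128_encode(spec$plate_id))
  bar_x0 <- g$barcode_x
  bar_x1 <- g$barcode_x + n_modules * g$module_width - 1L
  bar_yc <- (g$barcode_y0 + g$barcode_y1) / 2
  marks <- rbind(
    c(bar_x0 + g$mark_offset_left, bar_yc),
    c(bar_x1 + g$mark_offset_right, bar_yc)
  )
  grid <- well_to_grid(well_names())
  wells <- cbind(
    x = g$grid_x0 + (grid$col - 1) * g$pitch,
    y = g$grid_y0 + (grid$row - 1) * g$pitch
  )
  list(bar_x0 = bar_x0, bar_x1 = bar_x1, bar_yc = bar_yc,
       marks = marks, wells = wells)
}

# Draw a filled disc of `color` (length-3, 0..255) into img at center
# (cx, cy) with radius r. Returns the modified image.
draw_disc <- function(img, cx, cy, r, color) {
  h <- dim(img)[1]; w <- dim(img)[2]
  x0 <- max(1L, floor(cx - r)); x1 <- min(w, ceiling(cx + r))
  y0 <- max(1L, floor(cy - r)); y1 <- min(h, ceiling(cy + r))
  xs <- x0:x1; ys <- y0:y1
  dx2 <- (xs - cx)^2
  dy2 <- (ys - cy)^2
  mask <- outer(dy2, dx2, "+") <= r^2
  for (ch in 1:3) {
    plane <- img[ys, xs, ch]
    plane[mask] <- color[ch]
    img[ys, xs, ch] <- plane
  }
  img
}

render_barcode_strip <- function(img, spec, dx, dy) {
  g <- spec$geometry
  modules <- code128_encode(spec$plate_id)
  pix <- rep(modules, each = g$module_width)
  x0 <- g$barcode_x + dx
  xs <- x0:(x0 + length(pix) - 1L)
  ys <- (g$barcode_y0 + dy):(g$barcode_y1 + dy)
  dark <- xs[pix == 1L]
  for (ch in 1:3) img[ys, dark, ch] <- 0
  img
}

#' Render a synthetic assay-plate photograph
#'
#' Produces an 8-bit RGB image of a 96-well AHDS_red oxidation plate at
#' time `t`: each well disc is drawn in the display color
#' `W0 + y(t) * (Y0 - W0)` for that well's kinetic parameters, with
#' optional intensity and per-channel pixel noise; the plate barcode and
#' registration marks are rendered at the configured edge. The whole
#' plate is translated by a small random jitter (as a camera would not
#' frame identically every time) so grid localization is exercised.
#'
#' @param spec A [plate_spec()].
#' @param kinetics An [oxidation_kinetics()].
#' @param t Time since assay start, hours (>= 0).
#' @param seed Integer seed; identical spec/kinetics/t/seed give
#'   bit-identical output.
#' @param jitter_px Maximum absolute translation jitter in pixels.
#' @return List with `image` (height x width x 3 array, 0-255) and
#'   `truth` (data frame: plate_id, well, mutant_id, control_class,
#'   k_per_h, lag_h, occupied, y_true, y_drawn, r, g, b).
#' @export
render_plate_image <- function(spec, kinetics = oxidation_kinetics(),
                               t, seed = NULL, jitter_px = 6L) {
  stopifnot(inherits(spec, "plate_spec"), t >= 0)
  if (!is.null(seed)) set.seed(seed)
  g <- spec$geometry
  refs <- reference_colors()
  img <- array(0, dim = c(g$image_height, g$image_width, 3))
  for (ch in 1:3) img[, , ch] <- g$background[ch]

  dx <- if (jitter_px > 0) sample(-jitter_px:jitter_px, 1L) else 0L
  dy <- if (jitter_px > 0) sample(-jitter_px:jitter_px, 1L) else 0L

  img <- render_barcode_strip(img, spec, dx, dy)
  pos <- nominal_positions(spec)
  for (m in 1:2) {
    img <- draw_disc(img, pos$marks[m, 1] + dx, pos$marks[m, 2] + dy,
                     g$mark_radius, c(0, 0, 0))
  }

  lay <- spec$layout
  y_true <- kinetic_intensity(lay$k_per_h, t, lay$lag_h, kinetics$y0)
  y_drawn <- y_true
  if (kinetics$noise_sd > 0) {
    y_drawn <- y_true + stats::rnorm(96L, 0, kinetics$noise_sd)
  }
  colors <- display_color(y_drawn, refs)
  for (i in seq_len(96L)) {
    img <- draw_disc(img, pos$wells[i, 1] + dx, pos$wells[i, 2] + dy,
                     g$well_radius, colors[i, ])
  }
  if (kinetics$channel_noise_sd > 0) {
    img <- clip(img + stats::rnorm(length(img), 0,
                                   kinetics$channel_noise_sd), 0, 255)
  }
  truth <- data.frame(
    plate_id = spec$plate_id, well = lay$well, mutant_id = lay$mutant_id,
    control_class = lay$control_class, k_per_h = lay$k_per_h,
    lag_h = lay$lag_h, occupied = lay$occupied,
    y_true = y_true, y_drawn = y_drawn,
    r = colors[, 1], g = colors[, 2], b = colors[, 3],
    stringsAsFactors = FALSE
  )
  list(image = img, truth = truth)
}

#' Render a synthetic growth (storage) plate photograph
#'
#' Emulates images of 96-well storage plates used for growth QC: wells
#' that are catalogued occupied and actually grew are rendered turbid;
#' blank-media wells are rendered clear. Planted events perturb the
#' catalog expectation: `contamination` wells are catalogued empty but
#' rendered turbid, `failures` are catalogued occupied but rendered
#' clear.
#'
#' @param spec A [plate_spec()]; `layout$occupied` is the catalogued
#'   occupancy.
#' @param contamination Character vector of wells (must be catalogued
#'   empty) that show growth.
#' @param failures Character vector of wells (must be catalogued
#'   occupied) that failed to grow.
#' @param seed Integer seed.
#' @param turbid_color,blank_color RGB colors of grown and blank wells.
#' @param channel_noise_sd Per-pixel channel noise (0-255 units).
#' @param jitter_px Translation jitter in pixels.
#' @return List with `image` and `truth` (data frame: plate_id, well,
#'   occupied, grown).
#' @export
render_growth_plate <- function(spec, contamination = character(0),
                                failures = character(0), seed = NULL,
                                turbid_color = c(196, 189, 164),
                                blank_color = c(250, 246, 235),
                                channel_noise_sd = 2, jitter_px = 6L) {
  stopifnot(inherits(spec, "plate_spec"))
  if (length(intersect(contamination, failures)) > 0L) {
    stop("contamination and failures sets overlap")
  }
  lay <- spec$layout
  occ <- stats::setNames(lay$occupied, lay$well)
  if (length(contamination) && any(occ[contamination])) {
    stop("contamination wells must be catalogued empty")
  }
  if (length(failures) && any(!occ[failures])) {
    stop("failure wells must be catalogued occupied")
  }
  if (!is.null(seed)) set.seed(seed)
  g <- spec$geometry
  img <- array(0, dim = c(g$image_height, g$image_width, 3))
  for (ch in 1:3) img[, , ch] <- g$background[ch]
  dx <- if (jitter_px > 0) sample(-jitter_px:jitter_px, 1L) else 0L
  dy <- if (jitter_px > 0) sample(-jitter_px:jitter_px, 1L) else 0L
  img <- render_barcode_strip(img, spec, dx, dy)
  pos <- nominal_positions(spec)
  for (m in 1:2) {
    img <- draw_disc(img, pos$marks[m, 1] + dx, pos$marks[m, 2] + dy,
                     g$mark_radius, c(0, 0, 0))
  }
  grown <- (lay$occupied & !(lay$well %in% failures)) |
    (lay$well %in% contamination)
  for (i in seq_len(96L)) {
    col <- if (grown[i]) turbid_color else blank_color
    img <- draw_disc(img, pos$wells[i, 1] + dx, pos$wells[i, 2] + dy,
                     g$well_radius, col)
  }
  if (channel_noise_sd > 0) {
    img <- clip(img + stats::rnorm(length(img), 0, channel_noise_sd),
                0, 255)
  }
  truth <- data.frame(plate_id = spec$plate_id, well = lay$well,
                      occupied = lay$occupied, grown = grown,
                      stringsAsFactors = FALSE)
  list(image = img, truth = truth)
}

#' Read or write a plate image as PNG
#'
#' Lossless 8-bit RGB PNG; JPEG would corrupt color scoring and is not
#' supported.
#'
#' @param img height x width x 3 array on 0-255.
#' @param path File path.
#' @return `read_plate_image` returns the image array on 0-255.
#' @export
write_plate_image <- function(img, path) {
  png::writePNG(img / 255, target = path)
  invisible(path)
}

#' @rdname write_plate_image
#' @export
read_plate_image <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 2L) {
    arr <- array(rep(arr, 3L), dim = c(dim(arr), 3L))
  }
  arr[, , 1:3, drop = FALSE] * 255
}
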