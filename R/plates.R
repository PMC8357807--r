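# Plate-photograph ingestion: barcode decoding, registration-mark grid
# localization, well-center color sampling, and growth-plate QC against
# the collection catalog.

#' Decode a plate photograph
#'
#' Scans the image for a Code 128 barcode (trying the upright and
#' 180-degree-rotated orientations), then localizes the two
#' registration-mark discs flanking the barcode by center-of-mass of
#' dark pixels in windows placed from the decoded barcode span. The two
#' mark centroids, matched to their nominal positions in the plate
#' geometry, define a similarity transform (rotation + scale +
#' translation) used to predict well centers.
#'
#' @param image height x width x 3 array on 0-255, or a path to a PNG.
#' @param geometry A [plate_geometry()] describing the nominal layout.
#' @param timestamp_h Optional acquisition time (hours since assay
#'   start), carried through to samples.
#' @return A `plate_image_record` list: `decoded_plate_id` (NA on
#'   failure), `mark_centroids` (2 x 2 matrix, x/y), `rotated_180`,
#'   `transform` (complex a, b with pixel = a * nominal + b),
#'   `quality_flags` (character vector), `timestamp_h`, and the
#'   (possibly rotated) `image`.
#' @export
decode_plate <- function(image, geometry = plate_geometry(),
                         timestamp_h = NA_real_) {
  if (is.character(image)) image <- read_plate_image(image)
  if (length(dim(image)) != 3L || dim(image)[3] < 3L) {
    stop("image must be an 8-bit RGB raster (h x w x 3)")
  }
  rec <- list(decoded_plate_id = NA_character_,
              mark_centroids = NULL, rotated_180 = FALSE,
              transform = NULL, quality_flags = character(0),
              timestamp_h = timestamp_h, image = image,
              geometry = geometry)
  class(rec) <- "plate_image_record"

  bc <- scan_barcode(image)
  rotated <- FALSE
  if (is.null(bc)) {
    flipped <- image[rev(seq_len(dim(image)[1])),
                     rev(seq_len(dim(image)[2])), , drop = FALSE]
    bc <- scan_barcode(flipped)
    if (!is.null(bc)) {
      image <- flipped
      rotated <- TRUE
    }
  }
  if (is.null(bc)) {
    rec$quality_flags <- "barcode_unreadable"
    return(rec)
  }
  rec$image <- image
  rec$rotated_180 <- rotated
  rec$decoded_plate_id <- bc$payload
  if (isTRUE(bc$ambiguous)) {
    rec$quality_flags <- c(rec$quality_flags, "barcode_ambiguous")
  }

  bar_yc <- mean(bc$y_range)
  r <- geometry$mark_radius
  win <- ceiling(2.5 * r)
  left <- mark_centroid(image, bc$x_start + geometry$mark_offset_left,
                        bar_yc, win)
  right <- mark_centroid(image, bc$x_end + geometry$mark_offset_right,
                         bar_yc, win)
  if (is.null(left) || is.null(right)) {
    rec$quality_flags <- c(rec$quality_flags, "marks_not_found")
    return(rec)
  }
  cent <- rbind(left, right)
  dimnames(cent) <- list(c("left", "right"), c("x", "y"))
  rec$mark_centroids <- cent

  # similarity transform nominal -> pixel from the two mark points
  spec_like <- list(plate_id = bc$payload, geometry = geometry)
  class(spec_like) <- "plate_spec"
  pos <- nominal_positions(spec_like)
  nom <- complex(real = pos$marks[, 1], imaginary = pos$marks[, 2])
  obs <- complex(real = cent[, 1], imaginary = cent[, 2])
  a <- (obs[2] - obs[1]) / (nom[2] - nom[1])
  b <- obs[1] - a * nom[1]
  rec$transform <- list(a = a, b = b)
  rec
}

# Center of mass of dark pixels in a square window centered at (cx, cy).
# Returns c(x, y) at sub-pixel precision, or NULL if too few dark
# pixels.
mark_centroid <- function(image, cx, cy, win, threshold = 128,
                          min_pixels = 10L) {
  h <- dim(image)[1]; w <- dim(image)[2]
  xs <- max(1L, floor(cx - win)):min(w, ceiling(cx + win))
  ys <- max(1L, floor(cy - win)):min(h, ceiling(cy + win))
  lum <- (image[ys, xs, 1] + image[ys, xs, 2] + image[ys, xs, 3]) / 3
  dark <- lum < threshold
  if (sum(dark) < min_pixels) return(NULL)
  wt <- clip((threshold - lum) / threshold, 0, 1) * dark
  sx <- sum(outer(rep(1, length(ys)), xs) * wt) / sum(wt)
  sy <- sum(outer(ys, rep(1, length(xs))) * wt) / sum(wt)
  c(sx, sy)
}

# Map nominal pixel coordinates through a record's similarity transform.
apply_transform <- function(transform, xy) {
  z <- complex(real = xy[, 1], imaginary = xy[, 2]) * transform$a +
    transform$b
  cbind(x = Re(z), y = Im(z))
}

#' Sample well-center colors from a decoded plate image
#'
#' Predicts the 96 well centers from the record's registration
#' transform and averages RGB over a disc of radius
#' `radius_frac * pitch` at each center (mean well-center color). The
#' white-referenced transform `C' = C - W0` accompanies each sample.
#'
#' @param record A [decode_plate()] result with a valid transform.
#' @param radius_frac Sampling-disc radius as a fraction of well pitch.
#' @param refs A [reference_colors()].
#' @return Data frame with one row per well A1..H12: plate_id, well,
#'   timestamp_h, r, g, b, r_prime, g_prime, b_prime, n_pixels.
#' @export
sample_wells <- function(record, radius_frac = 0.3,
                         refs = reference_colors()) {
  stopifnot(inherits(record, "plate_image_record"))
  if (radius_frac <= 0) stop("radius_frac must be > 0")
  if (is.null(record$transform)) {
    stop("record has no registration transform (flags: ",
         paste(record$quality_flags, collapse = ", "), ")")
  }
  geometry <- record$geometry %||% plate_geometry()
  spec_like <- list(plate_id = record$decoded_plate_id,
                    geometry = geometry)
  class(spec_like) <- "plate_spec"
  pos <- nominal_positions(spec_like)
  centers <- apply_transform(record$transform, pos$wells)
  img <- record$image
  h <- dim(img)[1]; w <- dim(img)[2]
  r <- radius_frac * geometry$pitch
  if (any(centers[, 1] - r < 1 | centers[, 1] + r > w |
          centers[, 2] - r < 1 | centers[, 2] + r > h)) {
    stop("predicted well grid exceeds image bounds for plate ",
         record$decoded_plate_id)
  }
  out <- data.frame(plate_id = record$decoded_plate_id,
                    well = well_names(), timestamp_h = record$timestamp_h,
                    r = NA_real_, g = NA_real_, b = NA_real_,
                    n_pixels = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(96L)) {
    cx <- centers[i, 1]; cy <- centers[i, 2]
    xs <- floor(cx - r):ceiling(cx + r)
    ys <- floor(cy - r):ceiling(cy + r)
    mask <- outer((ys - cy)^2, (xs - cx)^2, "+") <= r^2
    n <- sum(mask)
    for (ch in 1:3) {
      plane <- img[ys, xs, ch]
      out[i, c("r", "g", "b")[ch]] <- mean(plane[mask])
    }
    out$n_pixels[i] <- n
  }
  out$r_prime <- out$r - refs$W0[1]
  out$g_prime <- out$g - refs$W0[2]
  out$b_prime <- out$b - refs$W0[3]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Growth-plate QC against the collection catalog
#'
#' Scores each well's turbidity as the Euclidean RGB distance from a
#' blank-media reference color and compares growth calls with the
#' catalog's occupancy: growth in a catalogued-empty well is a
#' `contamination` event; no growth in a catalogued-occupied well is a
#' `growth_failure` event. When the plate has at least
#' `min_blank_wells` catalogued-empty wells, the blank reference and
#' threshold (mean + 3 SD of blank turbidity scores) are estimated from
#' them; otherwise the supplied `blank_ref` color and `fallback_threshold`
#' are used.
#'
#' @param record A decoded `plate_image_record`.
#' @param catalog Collection catalog data frame (plate_id, well,
#'   occupied, ...).
#' @param k_sd Threshold multiplier on the blank-score SD.
#' @param blank_ref Fallback blank-media RGB reference.
#' @param fallback_threshold Fallback absolute distance threshold, also
#'   the upper bound on the estimated threshold.
#' @param min_threshold Lower bound on the estimated threshold (RGB
#'   distance units), keeping it above photometric noise.
#' @param min_blank_wells Minimum catalogued-empty wells needed to
#'   estimate the reference from the plate itself.
#' @return List of class `qc_report`: `wells` (data frame well,
#'   occupied, turbidity, grown), `events` (data frame plate_id, well,
#'   event), `threshold`.
#' @export
qc_growth_plate <- function(record, catalog, k_sd = 3,
                            blank_ref = c(250, 246, 235),
                            fallback_threshold = 60,
                            min_threshold = 10,
                            min_blank_wells = 3L) {
  stopifnot(inherits(record, "plate_image_record"))
  plate_id <- record$decoded_plate_id
  cat_plate <- catalog[catalog$plate_id == plate_id, ]
  if (nrow(cat_plate) == 0L) {
    stop("plate ", plate_id, " not present in the collection catalog")
  }
  occ <- stats::setNames(cat_plate$occupied, cat_plate$well)
  if (anyNA(occ[well_names()])) {
    stop("catalog entry missing for some wells of plate ", plate_id)
  }
  samples <- sample_wells(record)
  rgb <- as.matrix(samples[, c("r", "g", "b")])
  occupied <- unname(occ[samples$well])

  blanks <- which(!occupied)
  if (length(blanks) >= min_blank_wells) {
    ref <- colMeans(rgb[blanks, , drop = FALSE])
    score <- sqrt(rowSums(sweep(rgb, 2L, ref)^2))
    thr <- mean(score[blanks]) + k_sd * stats::sd(score[blanks])
    # keep the threshold inside a sane band: well above pixel noise
    # (blank wells are photometrically tight, so mean + 3 SD can land
    # below 1 RGB unit) and, since a planted contamination inflates the
    # blank SD, never above the absolute fallback, so gross growth is
    # never hidden
    thr <- clip(thr, min_threshold, fallback_threshold)
  } else {
    ref <- blank_ref
    score <- sqrt(rowSums(sweep(rgb, 2L, ref)^2))
    thr <- fallback_threshold
  }
  grown <- score > thr
  wells <- data.frame(plate_id = plate_id, well = samples$well,
                      occupied = occupied, turbidity = score,
                      grown = grown, stringsAsFactors = FALSE)
  ev_cont <- wells$well[!wells$occupied & wells$grown]
  ev_fail <- wells$well[wells$occupied & !wells$grown]
  event_wells <- c(ev_cont, ev_fail)
  events <- data.frame(
    plate_id = rep(plate_id, length(event_wells)),
    well = event_wells,
    event = c(rep("contamination", length(ev_cont)),
              rep("growth_failure", length(ev_fail))),
    stringsAsFactors = FALSE
  )
  structure(list(wells = wells, events = events, threshold = thr),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Growth-plate QC:", nrow(x$wells), "wells,",
      nrow(x$events), "event(s)\n")
  if (nrow(x$events) > 0L) print(x$events)
  invisible(x)
}

#' Ingest a series of plate photographs
#'
#' Decodes and samples every image listed in an acquisition log,
#' skipping (with a message) images whose barcode cannot be read;
#' absence of data never fabricates a phenotype.
#'
#' @param paths Image paths (PNG).
#' @param timestamps_h Acquisition times, hours since assay start,
#'   parallel to `paths`.
#' @param geometry A [plate_geometry()].
#' @return List: `samples` (row-bound [sample_wells()] frames),
#'   `skipped` (data frame path, flags).
#' @export
ingest_plate_images <- function(paths, timestamps_h,
                                geometry = plate_geometry()) {
  stopifnot(length(paths) == length(timestamps_h))
  samples <- list(); skipped <- list()
  for (i in seq_along(paths)) {
    rec <- decode_plate(paths[i], geometry, timestamps_h[i])
    if (is.na(rec$decoded_plate_id) || is.null(rec$transform)) {
      message("skipping unreadable image: ", paths[i], " (",
              paste(rec$quality_flags, collapse = ", "), ")")
      skipped[[length(skipped) + 1L]] <-
        data.frame(path = paths[i],
                   flags = paste(rec$quality_flags, collapse = ";"),
                   stringsAsFactors = FALSE)
      next
    }
    rec$geometry <- geometry
    samples[[length(samples) + 1L]] <- sample_wells(rec)
  }
  list(
    samples = if (length(samples)) do.call(rbind, samples) else NULL,
    skipped = if (length(skipped)) do.call(rbind, skipped)
      else data.frame(path = character(0), flags = character(0))
  )
}
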