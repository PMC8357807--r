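# Normalized yellow-intensity scoring and hit calling. The screen's
# readout is the fading of the orange AHDS_red dye as it is oxidized to
# the clear AQDS_ox form; well color is projected onto the white-to-
# saturated-yellow axis to give a single dimensionless intensity y, with
# y = 1 for a fully yellow (reduced) well and y = 0 for a clear
# (oxidized) well.

#' Reference colors for yellow-intensity scoring
#'
#' The saturated yellow reference Y0 = (225, 153, 0) is the most
#' saturated yellow observed in the assay imagery; the white reference
#' W0 = (255, 255, 255) is a fully clear well. Both are expressed
#' relative to white: `Y0_prime = Y0 - W0 = (-30, -102, -255)`, with
#' squared norm 76329.
#'
#' @param Y0,W0 RGB triples on 0-255.
#' @return A `reference_colors` list with `Y0`, `W0`, `Y0_prime` and
#'   `Y0_prime_sq` (the squared norm).
#' @export
reference_colors <- function(Y0 = c(225, 153, 0), W0 = c(255, 255, 255)) {
  stopifnot(length(Y0) == 3L, length(W0) == 3L,
            all(Y0 >= 0 & Y0 <= 255), all(W0 >= 0 & W0 <= 255))
  Y0p <- Y0 - W0
  structure(list(Y0 = Y0, W0 = W0, Y0_prime = Y0p,
                 Y0_prime_sq = sum(Y0p^2)),
            class = "reference_colors")
}

#' Normalized yellow intensity of a well color
#'
#' Projects a well color onto the white-to-yellow axis:
#' `y = (C - W0) . (Y0 - W0) / |Y0 - W0|^2`. Values are not clipped:
#' off-axis colors (stains, condensation) can fall slightly outside
#' \[0, 1\] and clipping would hide that QC signal. The blue channel
#' dominates the score (coefficient 255/76329 per unit, vs 30/76329 for
#' red), reflecting that nearly all redox information is in the blue
#' channel.
#'
#' @param C RGB triple (0-255), or an n x 3 matrix of colors.
#' @param refs A [reference_colors()].
#' @return Dimensionless intensity, length n.
#' @export
yellow_intensity <- function(C, refs = reference_colors()) {
  if (is.null(dim(C))) {
    stopifnot(length(C) == 3L)
    C <- matrix(C, nrow = 1L)
  }
  if (any(C < 0 | C > 255)) stop("RGB channels must be in [0, 255]")
  Cp <- sweep(C, 2L, refs$W0)
  as.vector(Cp %*% refs$Y0_prime) / refs$Y0_prime_sq
}

#' Display color for a yellow intensity
#'
#' Inverse of [yellow_intensity()] on the white-yellow segment:
#' `W0 + y * (Y0 - W0)`. Used to reconstruct the colored-circle
#' time-series strips and to render synthetic wells.
#'
#' @param y Intensity vector.
#' @param refs A [reference_colors()].
#' @return n x 3 matrix of RGB colors, clipped to 0-255 for display.
#' @export
display_color <- function(y, refs = reference_colors()) {
  cols <- outer(y, refs$Y0_prime) +
    matrix(refs$W0, length(y), 3L, byrow = TRUE)
  clip(cols, 0, 255)
}

#' Build intensity traces from well samples and a catalog
#'
#' Joins per-image well color samples (module plates output) to the
#' collection catalog and scores each sample, giving a tidy per-well
#' intensity time series. Wells sharing a `mutant_id` across plates or
#' within a plate are treated as replicates.
#'
#' @param samples Data frame with columns plate_id, well, timestamp_h,
#'   r, g, b (as written by [sample_wells()] over an image series).
#' @param catalog Data frame with columns plate_id, well, mutant_id,
#'   control_class (a collection catalog).
#' @param acceptor Electron acceptor label ("fumarate" or "nitrate")
#'   attached to the trace.
#' @param refs A [reference_colors()].
#' @return Data frame: mutant_id, acceptor, control_class, plate_id,
#'   well, replicate, timestamp_h, y.
#' @export
build_traces <- function(samples, catalog, acceptor, refs = reference_colors()) {
  stopifnot(acceptor %in% c("fumarate", "nitrate"))
  key <- paste(samples$plate_id, samples$well)
  ckey <- paste(catalog$plate_id, catalog$well)
  idx <- match(key, ckey)
  if (anyNA(idx)) {
    miss <- unique(key[is.na(idx)])
    stop("wells missing from catalog: ", paste(utils::head(miss, 5L),
                                               collapse = ", "))
  }
  y <- yellow_intensity(as.matrix(samples[, c("r", "g", "b")]), refs)
  out <- data.frame(
    mutant_id = catalog$mutant_id[idx],
    acceptor = acceptor,
    control_class = catalog$control_class[idx],
    plate_id = samples$plate_id,
    well = samples$well,
    replicate = key,
    timestamp_h = samples$timestamp_h,
    y = y,
    stringsAsFactors = FALSE
  )
  out[order(out$mutant_id, out$replicate, out$timestamp_h), ]
}

# Replicate-mean trace for one mutant: average y across replicates at
# each timestamp.
replicate_mean_trace <- function(trace) {
  agg <- stats::aggregate(y ~ timestamp_h, data = trace, FUN = mean)
  agg[order(agg$timestamp_h), ]
}

#' Interpolate a replicate-mean trace at display marks
#'
#' Linearly interpolates the replicate-averaged yellow intensity at the
#' requested hours (the colored-circle strips show 0-4 h) and
#' reconstructs the display color for each mark.
#'
#' @param trace Data frame for one mutant with columns replicate,
#'   timestamp_h, y.
#' @param marks Hours at which to interpolate.
#' @param refs A [reference_colors()].
#' @return Data frame: timestamp_h, y, r, g, b, extrapolated.
#' @export
interpolate_trace <- function(trace, marks = 0:4,
                              refs = reference_colors()) {
  if (nrow(trace) == 0L) stop("empty trace")
  m <- replicate_mean_trace(trace)
  if (nrow(m) < 2L) stop("need at least two timepoints to interpolate")
  outside <- marks < min(m$timestamp_h) | marks > max(m$timestamp_h)
  y <- stats::approx(m$timestamp_h, m$y, xout = marks, rule = 2)$y
  cols <- display_color(y, refs)
  data.frame(timestamp_h = marks, y = y,
             r = cols[, 1], g = cols[, 2], b = cols[, 3],
             extrapolated = outside)
}

#' Oxidation rate from the linear portion of an intensity curve
#'
#' Operationalizes "linear fit to the linear portion": the
#' replicate-mean curve is restricted to the window where y lies within
#' \[20%, 80%\] of its own dynamic range, and an ordinary least-squares
#' line is fitted there. The absolute slope is reported as the rate.
#'
#' @param trace Data frame for one mutant (columns replicate,
#'   timestamp_h, y).
#' @param window Lower/upper fractions of the dynamic range defining
#'   the fit window.
#' @param min_range Dynamic range below which the trace is declared
#'   flat (`no_decline`).
#' @return List: `rate` (intensity/h, >= 0), `window_h` (fit window
#'   bounds in hours, NA if flat), `n_points`, `flag` ("ok" or
#'   "no_decline").
#' @export
fit_oxidation_rate <- function(trace, window = c(0.2, 0.8),
                               min_range = 0.1) {
  m <- replicate_mean_trace(trace)
  if (nrow(m) < 4L) stop("need >= 4 timepoints to fit an oxidation rate")
  rng <- max(m$y) - min(m$y)
  if (rng < min_range) {
    return(list(rate = 0, window_h = c(NA_real_, NA_real_),
                n_points = 0L, flag = "no_decline"))
  }
  lo <- min(m$y) + window[1] * rng
  hi <- min(m$y) + window[2] * rng
  keep <- m$y >= lo & m$y <= hi
  if (sum(keep) < 2L) {
    # steep curves can skip the central band; take the two points
    # bracketing the half-range crossing instead
    half <- min(m$y) + 0.5 * rng
    i <- which(m$y <= half)[1]
    keep <- rep(FALSE, nrow(m))
    keep[max(1L, i - 1L):i] <- TRUE
  }
  fit <- stats::lm(y ~ timestamp_h, data = m[keep, ])
  list(rate = abs(unname(stats::coef(fit)[2])),
       window_h = range(m$timestamp_h[keep]),
       n_points = sum(keep), flag = "ok")
}

# First time the replicate-mean trace crosses halfway through its own
# dynamic range (linear interpolation between bracketing observations).
# Returns NA if the trace never crosses or is flat (range < min_range).
trace_t50 <- function(m, min_range = 0.1) {
  y0 <- m$y[1]
  ymin <- min(m$y)
  rng <- y0 - ymin
  if (rng < min_range) return(NA_real_)
  half <- y0 - 0.5 * rng
  below <- which(m$y <= half)
  below <- below[below > 1L]
  if (length(below) == 0L) return(NA_real_)
  i <- below[1]
  t0 <- m$timestamp_h[i - 1L]; t1 <- m$timestamp_h[i]
  v0 <- m$y[i - 1L]; v1 <- m$y[i]
  if (v0 == v1) return(t1)
  t0 + (v0 - half) / (v0 - v1) * (t1 - t0)
}

#' Call slowed / eliminated mutants against quasi-wild-type controls
#'
#' For each mutant, the replicate-mean yellow-intensity trace gives a
#' half-oxidation time t50 (first crossing of half its dynamic range).
#' The null distribution of t50 comes from the run's quasi-wild-type
#' controls: a mutant is `slowed` if its t50 exceeds the control mean by
#' more than `k_sd` control standard deviations, `eliminated` if it
#' never crosses within the observation window, `normal` otherwise.
#' Wells flagged `growth_failure` by plate QC are excluded
#' (`excluded_growth_failure`) so growth failures cannot masquerade as
#' oxidation phenotypes.
#'
#' @param traces Data frame from [build_traces()] (one acceptor).
#' @param qc_events Optional QC event data frame (plate_id, well,
#'   event) from [qc_growth_plate()].
#' @param k_sd Control-referenced threshold in control SDs.
#' @param min_controls Minimum number of quasi-wild-type control traces
#'   required to form the null.
#' @param min_range Dynamic range below which a trace counts as never
#'   declining.
#' @return Data frame: mutant_id, acceptor, control_class, status,
#'   t50_h, rate_per_h, plus attribute `control_t50` (mean, sd, n).
#' @export
call_hits <- function(traces, qc_events = NULL, k_sd = 3,
                      min_controls = 8L, min_range = 0.1) {
  stopifnot(length(unique(traces$acceptor)) == 1L)
  excluded_wells <- character(0)
  if (!is.null(qc_events) && nrow(qc_events) > 0L) {
    gf <- qc_events[qc_events$event == "growth_failure", ]
    excluded_wells <- paste(gf$plate_id, gf$well)
  }
  split_by <- split(traces, traces$mutant_id)
  ctrl_t50 <- c()
  for (tr in split_by) {
    if (tr$control_class[1] == "quasi_wild_type") {
      for (rep_tr in split(tr, tr$replicate)) {
        if (paste(rep_tr$plate_id[1], rep_tr$well[1]) %in% excluded_wells) {
          next
        }
        t50 <- trace_t50(replicate_mean_trace(rep_tr), min_range)
        if (!is.na(t50)) ctrl_t50 <- c(ctrl_t50, t50)
      }
    }
  }
  if (length(ctrl_t50) < min_controls) {
    stop("need >= ", min_controls, " quasi-wild-type control traces to ",
         "form the null distribution (have ", length(ctrl_t50), ")")
  }
  thr <- mean(ctrl_t50) + k_sd * stats::sd(ctrl_t50)
  calls <- lapply(split_by, function(tr) {
    wells <- unique(paste(tr$plate_id, tr$well))
    usable <- tr[!(paste(tr$plate_id, tr$well) %in% excluded_wells), ]
    if (nrow(usable) == 0L) {
      return(data.frame(mutant_id = tr$mutant_id[1],
                        acceptor = tr$acceptor[1],
                        control_class = tr$control_class[1],
                        status = "excluded_growth_failure",
                        t50_h = NA_real_, rate_per_h = NA_real_,
                        stringsAsFactors = FALSE))
    }
    m <- replicate_mean_trace(usable)
    t50 <- trace_t50(m, min_range)
    rate <- tryCatch(fit_oxidation_rate(usable, min_range = min_range)$rate,
                     error = function(e) NA_real_)
    status <- if (is.na(t50)) "eliminated"
      else if (t50 > thr) "slowed" else "normal"
    data.frame(mutant_id = tr$mutant_id[1], acceptor = tr$acceptor[1],
               control_class = tr$control_class[1], status = status,
               t50_h = t50, rate_per_h = rate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  attr(out, "control_t50") <- c(mean = mean(ctrl_t50),
                                sd = stats::sd(ctrl_t50),
                                n = length(ctrl_t50),
                                threshold = thr)
  out
}

#' Partition hits across the two electron-acceptor assays
#'
#' A mutant is a hit in an assay iff its status is `slowed` or
#' `eliminated`. The partition reports mutants hit only with fumarate,
#' only with nitrate, and in both assays; excluded mutants never enter
#' the partition.
#'
#' @param fumarate_calls,nitrate_calls Call data frames from
#'   [call_hits()].
#' @return List of class `hit_partition`: `fumarate_only`,
#'   `nitrate_only`, `both` (character vectors) and `counts` (named
#'   vector with the three counts and `total`).
#' @export
partition_hits <- function(fumarate_calls, nitrate_calls) {
  is_hit <- function(calls) {
    calls$mutant_id[calls$status %in% c("slowed", "eliminated")]
  }
  fum <- unique(is_hit(fumarate_calls))
  nit <- unique(is_hit(nitrate_calls))
  only_in_one <- union(
    setdiff(fumarate_calls$mutant_id, nitrate_calls$mutant_id),
    setdiff(nitrate_calls$mutant_id, fumarate_calls$mutant_id)
  )
  if (length(only_in_one) > 0L) {
    warning(length(only_in_one),
            " mutant(s) present in only one assay; counted there only")
  }
  part <- list(
    fumarate_only = sort(setdiff(fum, nit)),
    nitrate_only = sort(setdiff(nit, fum)),
    both = sort(intersect(fum, nit))
  )
  part$counts <- c(
    fumarate_only = length(part$fumarate_only),
    nitrate_only = length(part$nitrate_only),
    both = length(part$both),
    total = length(part$fumarate_only) + length(part$nitrate_only) +
      length(part$both)
  )
  class(part) <- "hit_partition"
  part
}

#' @export
print.hit_partition <- function(x, ...) {
  cat("Hit partition across electron-acceptor assays\n")
  cat(sprintf("  fumarate only: %d\n", x$counts[["fumarate_only"]]))
  cat(sprintf("  nitrate only:  %d\n", x$counts[["nitrate_only"]]))
  cat(sprintf("  both assays:   %d\n", x$counts[["both"]]))
  cat(sprintf("  total hits:    %d\n", x$counts[["total"]]))
  invisible(x)
}

#' Triage hits into functional categories
#'
#' Counts hit mutants per annotated functional category; mutants with
#' no annotation fall into the `unknown` bucket, which feeds the
#' downstream electrochemical-validation shortlist.
#'
#' @param partition A [partition_hits()] result.
#' @param annotations Data frame with columns mutant_id, category.
#' @return List: `table` (data frame category/count, sorted by count),
#'   `unknown` (character vector of unknown-category hit mutants).
#' @export
triage_categories <- function(partition, annotations) {
  hits <- c(partition$fumarate_only, partition$nitrate_only,
            partition$both)
  cat_of <- stats::setNames(annotations$category, annotations$mutant_id)
  cats <- unname(cat_of[hits])
  cats[is.na(cats) | cats == ""] <- "unknown"
  tab <- as.data.frame(table(category = cats),
                       responseName = "count",
                       stringsAsFactors = FALSE)
  tab <- tab[order(-tab$count, tab$category), ]
  rownames(tab) <- NULL
  list(table = tab, unknown = sort(hits[cats == "unknown"]))
}
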