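# Synthetic potentiostat traces with known ground truth: chrono-
# amperometry (steady cathodic plateau with a respiratory-inhibitor
# step to the abiotic level) and cyclic voltammetry (sigmoidal redox
# wave on a capacitive baseline, with forward/reverse hysteresis).

#' Specify a synthetic chronoamperometry trace
#'
#' The noiseless trace sits exactly at `baseline_current` up to
#' `inhibitor_time - 3 * step_sharpness`, relaxes smoothly (half-cosine)
#' to `abiotic_current`, and sits exactly at `abiotic_current` from
#' `inhibitor_time + 3 * step_sharpness` onward. Cathodic currents are
#' negative by convention.
#'
#' @param poised_potential_mV Working-electrode potential, mV vs SHE.
#' @param baseline_current Pre-inhibitor steady current, A.
#' @param abiotic_current Post-inhibitor residual current, A.
#' @param inhibitor_time Inhibitor (Antimycin A) addition time, s. May
#'   exceed `duration`, giving a step-free trace.
#' @param step_sharpness Half-width scale of the transition, s.
#' @param noise_sd Additive Gaussian current noise, A.
#' @param sample_interval Sampling interval, s.
#' @param duration Trace duration, s.
#' @return A `ca_trace_spec` list.
#' @export
ca_trace_spec <- function(poised_potential_mV = -378,
                          baseline_current = -10e-6,
                          abiotic_current = -2e-6,
                          inhibitor_time = 600,
                          step_sharpness = 10,
                          noise_sd = 0.05e-6,
                          sample_interval = 1,
                          duration = 1200) {
  stopifnot(sample_interval > 0, step_sharpness > 0, noise_sd >= 0,
            duration > 0)
  structure(as.list(environment()), class = "ca_trace_spec")
}

#' Simulate a chronoamperometry trace
#'
#' @param spec A [ca_trace_spec()].
#' @param seed Integer seed; identical spec + seed give bit-identical
#'   output.
#' @return A `ca_trace`: data frame (time_s, current_A) with attributes
#'   `inhibitor_time_s`, `poised_potential_mV`, `spec`.
#' @export
simulate_ca_trace <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "ca_trace_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- ceiling(spec$duration / spec$sample_interval)
  t <- seq_len(n) * spec$sample_interval
  tau <- spec$step_sharpness
  t0 <- spec$inhibitor_time - 3 * tau
  t1 <- spec$inhibitor_time + 3 * tau
  s <- ifelse(t <= t0, 0,
              ifelse(t >= t1, 1, (1 - cos(pi * (t - t0) / (t1 - t0))) / 2))
  # assign the plateau levels directly so they are exact in floating
  # point; only the transition interpolates
  current <- spec$baseline_current +
    (spec$abiotic_current - spec$baseline_current) * s
  current[s == 0] <- spec$baseline_current
  current[s == 1] <- spec$abiotic_current
  if (spec$noise_sd > 0) {
    current <- current + stats::rnorm(n, 0, spec$noise_sd)
  }
  out <- data.frame(time_s = t, current_A = current)
  attr(out, "inhibitor_time_s") <-
    if (spec$inhibitor_time < spec$duration) spec$inhibitor_time else NA_real_
  attr(out, "poised_potential_mV") <- spec$poised_potential_mV
  attr(out, "spec") <- spec
  class(out) <- c("ca_trace", "data.frame")
  out
}

#' Specify a synthetic cyclic-voltammetry scan
#'
#' Each branch's noiseless current is
#' `capacitive_offset + wave_amplitude * plogis((E - inflection) / wave_width_mV)`
#' where the forward-branch inflection is `formal_potential_mV -
#' hysteresis_mV / 2` and the reverse-branch inflection is
#' `formal_potential_mV + hysteresis_mV / 2`, so the mean of the two
#' branch inflections recovers the formal potential exactly.
#'
#' @param formal_potential_mV Formal (midpoint) potential, mV vs SHE.
#' @param wave_amplitude Wave amplitude, A (negative for a cathodic
#'   wave).
#' @param wave_width_mV Logistic width of the wave, mV (> 0).
#' @param hysteresis_mV Forward/reverse inflection offset, mV.
#' @param capacitive_offset Constant capacitive baseline, A.
#' @param noise_sd Additive Gaussian current noise, A.
#' @param scan_lo_mV,scan_hi_mV Scan bounds, mV vs SHE.
#' @param step_mV Potential grid spacing, mV (> 0).
#' @return A `cv_scan_spec` list.
#' @export
cv_scan_spec <- function(formal_potential_mV = -50,
                         wave_amplitude = -5e-6,
                         wave_width_mV = 30,
                         hysteresis_mV = 20,
                         capacitive_offset = -0.5e-6,
                         noise_sd = 0.1e-6,
                         scan_lo_mV = -322, scan_hi_mV = 222,
                         step_mV = 2) {
  if (wave_width_mV <= 0) stop("wave_width_mV must be > 0")
  if (step_mV <= 0) stop("step_mV must be > 0")
  if (!(scan_lo_mV < formal_potential_mV &&
        formal_potential_mV < scan_hi_mV)) {
    stop("formal_potential_mV must lie strictly inside the scan bounds")
  }
  structure(as.list(environment()), class = "cv_scan_spec")
}

#' Simulate a cyclic-voltammetry scan
#'
#' @param spec A [cv_scan_spec()].
#' @param seed Integer seed.
#' @return A `cv_scan` list: `forward` (data frame potential_mV_SHE,
#'   current_A, potentials descending), `reverse` (ascending), `spec`.
#' @export
simulate_cv_scan <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cv_scan_spec"))
  if (!is.null(seed)) set.seed(seed)
  grid <- seq(spec$scan_lo_mV, spec$scan_hi_mV, by = spec$step_mV)
  branch <- function(E, inflection) {
    i <- spec$capacitive_offset + spec$wave_amplitude *
      stats::plogis((E - inflection) / spec$wave_width_mV)
    if (spec$noise_sd > 0) i <- i + stats::rnorm(length(E), 0, spec$noise_sd)
    data.frame(potential_mV_SHE = E, current_A = i)
  }
  fwd <- branch(rev(grid), spec$formal_potential_mV - spec$hysteresis_mV / 2)
  rev_ <- branch(grid, spec$formal_potential_mV + spec$hysteresis_mV / 2)
  structure(list(forward = fwd, reverse = rev_, spec = spec),
            class = "cv_scan")
}

#' Simulate per-well intensity traces for a whole screen
#'
#' Trace-level forward model of a multi-plate AHDS_red oxidation run:
#' each plate carries quasi-wild-type controls, no-cell blanks and test
#' mutants; planted `slowed` and `eliminated` mutants get reduced or
#' zero oxidation rates. Intensity noise is drawn i.i.d. per
#' observation. This bypasses image rendering; the image chain is
#' exercised by [render_plate_image()] round-trips.
#'
#' @param n_plates Number of 96-well plates.
#' @param n_slowed,n_eliminated Planted hit counts (assigned to the
#'   first test-mutant wells in randomized positions).
#' @param k_normal,k_slowed Oxidation rates (1/h) of normal and slowed
#'   mutants; eliminated mutants have k = 0.
#' @param controls_per_plate,blanks_per_plate Quasi-wild-type and
#'   no-cell blank wells per plate.
#' @param timepoints_h Imaging times, hours.
#' @param noise_sd Intensity noise SD per observation.
#' @param acceptor Acceptor label for the traces.
#' @param seed Integer seed.
#' @return List: `traces` (as [build_traces()] output), `truth` (data
#'   frame mutant_id, control_class, k_per_h, planted_status),
#'   `catalog`.
#' @export
simulate_screen <- function(n_plates = 4L, n_slowed = 10L,
                            n_eliminated = 6L, k_normal = 1.0,
                            k_slowed = 0.2, controls_per_plate = 4L,
                            blanks_per_plate = 2L,
                            timepoints_h = seq(0, 40, by = 1),
                            noise_sd = 0.02,
                            acceptor = "fumarate", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_wells <- 96L * n_plates
  n_ctrl <- controls_per_plate * n_plates
  n_blank <- blanks_per_plate * n_plates
  n_test <- n_wells - n_ctrl - n_blank
  stopifnot(n_slowed + n_eliminated <= n_test)

  per_plate <- lapply(seq_len(n_plates), function(p) {
    cls <- c(rep("quasi_wild_type", controls_per_plate),
             rep("blank_no_cell", blanks_per_plate),
             rep("test_mutant", 96L - controls_per_plate -
                   blanks_per_plate))
    data.frame(plate_id = sprintf("PLATE-%03d", p), well = well_names(),
               control_class = sample(cls), stringsAsFactors = FALSE)
  })
  catalog <- do.call(rbind, per_plate)
  is_test <- catalog$control_class == "test_mutant"
  catalog$mutant_id <- NA_character_
  catalog$mutant_id[is_test] <- sprintf("SO_%04d", seq_len(sum(is_test)))
  catalog$mutant_id[catalog$control_class == "quasi_wild_type"] <-
    sprintf("QWT_%03d", seq_len(sum(catalog$control_class ==
                                      "quasi_wild_type")))
  catalog$mutant_id[catalog$control_class == "blank_no_cell"] <-
    sprintf("BLANK_%03d", seq_len(sum(catalog$control_class ==
                                        "blank_no_cell")))
  catalog$occupied <- catalog$control_class != "blank_no_cell"

  planted <- sample(catalog$mutant_id[is_test], n_slowed + n_eliminated)
  slowed_ids <- planted[seq_len(n_slowed)]
  elim_ids <- setdiff(planted, slowed_ids)
  catalog$k_per_h <- ifelse(catalog$control_class == "blank_no_cell", 0,
                            k_normal)
  catalog$k_per_h[catalog$mutant_id %in% slowed_ids] <- k_slowed
  catalog$k_per_h[catalog$mutant_id %in% elim_ids] <- 0
  catalog$lag_h <- 0

  nt <- length(timepoints_h)
  y_true <- kinetic_intensity(rep(catalog$k_per_h, each = nt),
                              rep(timepoints_h, times = nrow(catalog)))
  y <- y_true + stats::rnorm(length(y_true), 0, noise_sd)
  traces <- data.frame(
    mutant_id = rep(catalog$mutant_id, each = nt),
    acceptor = acceptor,
    control_class = rep(catalog$control_class, each = nt),
    plate_id = rep(catalog$plate_id, each = nt),
    well = rep(catalog$well, each = nt),
    replicate = rep(paste(catalog$plate_id, catalog$well), each = nt),
    timestamp_h = rep(timepoints_h, times = nrow(catalog)),
    y = y,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    mutant_id = catalog$mutant_id,
    control_class = catalog$control_class,
    k_per_h = catalog$k_per_h,
    planted_status = ifelse(catalog$mutant_id %in% slowed_ids, "slowed",
                            ifelse(catalog$mutant_id %in% elim_ids,
                                   "eliminated", "normal")),
    stringsAsFactors = FALSE
  )
  list(traces = traces, truth = truth, catalog = catalog)
}

#' Simulate replicate biological currents for a set of strains
#'
#' @param strain_means Named numeric vector of true biological currents
#'   (A) per strain.
#' @param sd Replicate SD, A.
#' @param n_rep Replicates per strain.
#' @param mode `"cathodic"` or `"anodic"`, metadata only.
#' @param seed Integer seed.
#' @return Data frame: strain_id, mode, replicate_id,
#'   biological_current_A.
#' @export
simulate_strain_currents <- function(strain_means, sd = 0.5e-6,
                                     n_rep = 4L, mode = "cathodic",
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  strains <- names(strain_means)
  stopifnot(!is.null(strains), n_rep >= 1L)
  data.frame(
    strain_id = rep(strains, each = n_rep),
    mode = mode,
    replicate_id = rep(seq_len(n_rep), times = length(strains)),
    biological_current_A = rep(strain_means, each = n_rep) +
      stats::rnorm(length(strains) * n_rep, 0, sd),
    stringsAsFactors = FALSE
  )
}

#' Write / read potentiostat trace CSVs
#'
#' CA traces are stored as (time_s, current_A); CV scans as
#' (potential_mV_SHE, current_A, branch) with branch in
#' forward/reverse.
#'
#' @param trace,scan Objects from [simulate_ca_trace()] /
#'   [simulate_cv_scan()] (or data frames of the same shape).
#' @param path CSV path.
#' @return Readers return the corresponding object.
#' @export
write_ca_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace)[, c("time_s", "current_A")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ca_csv
#' @param inhibitor_time_s Inhibitor-addition time for the read trace
#'   (CSV carries no metadata).
#' @export
read_ca_csv <- function(path, inhibitor_time_s = NA_real_) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "current_A") %in% names(df)))
  attr(df, "inhibitor_time_s") <- inhibitor_time_s
  class(df) <- c("ca_trace", "data.frame")
  df
}

#' @rdname write_ca_csv
#' @export
write_cv_csv <- function(scan, path) {
  df <- rbind(
    cbind(scan$forward, branch = "forward"),
    cbind(scan$reverse, branch = "reverse")
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cv_csv
#' @export
read_cv_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("potential_mV_SHE", "current_A", "branch") %in%
                  names(df)))
  structure(list(forward = df[df$branch == "forward",
                              c("potential_mV_SHE", "current_A")],
                 reverse = df[df$branch == "reverse",
                              c("potential_mV_SHE", "current_A")],
                 spec = NULL),
            class = "cv_scan")
}
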