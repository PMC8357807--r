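# Potentiostat record analysis: steady-state and biological currents
# from chronoamperometry, midpoint potentials from cyclic voltammetry,
# and strain-level statistics (type-II ANOVA + Tukey HSD vs wild type).

#' Steady-state current of a chronoamperometry segment
#'
#' Arithmetic mean of the final `window` current samples.
#'
#' @param trace A `ca_trace` (data frame with time_s, current_A).
#' @param window Number of final points to average (default 100).
#' @return Current in A.
#' @export
steady_state_current <- function(trace, window = 100L) {
  n <- nrow(trace)
  if (n < window) {
    stop("trace has ", n, " samples; need at least ", window,
         " for the final-", window, "-point average")
  }
  mean(trace$current_A[(n - window + 1L):n])
}

#' Biological current from an inhibitor-step chronoamperogram
#'
#' Difference of the pre- and post-inhibitor steady-state currents,
#' each computed by the final-100-point rule relative to its own
#' segment end. A settling margin of `settle_s` is excluded on both
#' sides of the addition so the transition itself never enters either
#' steady-state window. With cathodic currents negative, a
#' cathode-active strain yields a negative biological current.
#'
#' @param trace A `ca_trace`; the inhibitor time is taken from
#'   `inhibitor_time_s` or the trace attribute.
#' @param inhibitor_time_s Inhibitor addition time, s.
#' @param window Points averaged per segment.
#' @param settle_s Settling margin after inhibitor addition, s.
#' @return Biological current in A (pre minus post).
#' @export
biological_current <- function(trace, inhibitor_time_s = NULL,
                               window = 100L, settle_s = 60) {
  if (is.null(inhibitor_time_s)) {
    inhibitor_time_s <- attr(trace, "inhibitor_time_s")
  }
  if (is.null(inhibitor_time_s) || is.na(inhibitor_time_s)) {
    stop("inhibitor addition time unknown; supply inhibitor_time_s ",
         "(or set it in the trace metadata)")
  }
  pre <- trace[trace$time_s < inhibitor_time_s - settle_s, , drop = FALSE]
  post <- trace[trace$time_s > inhibitor_time_s + settle_s, , drop = FALSE]
  if (nrow(pre) < window || nrow(post) < window) {
    stop("need >= ", window, " samples strictly before the inhibitor ",
         "addition and after the settling margin (have ", nrow(pre),
         " / ", nrow(post), ")")
  }
  steady_state_current(pre, window) - steady_state_current(post, window)
}

#' Midpoint potential from a cyclic-voltammetry scan
#'
#' Implements the smoothing-spline/derivative procedure: for each
#' branch, current-vs-potential inside the analysis bounds is smoothed
#' with a cubic smoothing spline (`stats::smooth.spline`, `spar`
#' defaulting to 0.70), evaluated on a uniform 1 mV grid, differentiated
#' by centered finite differences, and the potential of maximum
#' derivative magnitude taken as the branch inflection. The midpoint
#' potential is the mean of the forward and reverse inflections. If a
#' branch's derivative peaks at the edge of the analysis range the wave
#' is truncated (or absent) and no midpoint is reported for that scan
#' (`edge_inflection` flag).
#'
#' @param scan A `cv_scan` (forward/reverse data frames).
#' @param spar Smoothing parameter passed to [stats::smooth.spline()].
#' @param bounds Analysis range in mV vs SHE (default the +222 to -322
#'   window).
#' @param grid_mV Evaluation grid spacing, mV.
#' @param edge_margin_mV Distance from a bound within which a
#'   derivative peak counts as an edge inflection.
#' @return List: `midpoint_mV`, `forward_inflection_mV`,
#'   `reverse_inflection_mV`, `flags` (character vector).
#' @export
estimate_midpoint <- function(scan, spar = 0.70, bounds = c(-322, 222),
                              grid_mV = 1, edge_margin_mV = 5) {
  stopifnot(inherits(scan, "cv_scan") || is.list(scan))
  bounds <- sort(bounds)
  branch_inflection <- function(df) {
    df <- df[df$potential_mV_SHE >= bounds[1] &
               df$potential_mV_SHE <= bounds[2], , drop = FALSE]
    if (nrow(df) < 20L) {
      stop("branch has fewer than 20 points inside the analysis range")
    }
    E <- df$potential_mV_SHE
    if (is.unsorted(E) && is.unsorted(rev(E))) {
      stop("branch potentials are not monotone")
    }
    ord <- order(E)
    fit <- stats::smooth.spline(E[ord], df$current_A[ord], spar = spar)
    grid <- seq(max(bounds[1], min(E)), min(bounds[2], max(E)),
                by = grid_mV)
    i_hat <- stats::predict(fit, grid)$y
    dI <- (i_hat[-(1:2)] - i_hat[1:(length(i_hat) - 2L)]) /
      (grid[-(1:2)] - grid[1:(length(grid) - 2L)])
    dE <- grid[-c(1L, length(grid))]
    peak <- which.max(abs(dI))
    list(E = dE[peak],
         at_edge = dE[peak] <= min(dE) + edge_margin_mV ||
           dE[peak] >= max(dE) - edge_margin_mV)
  }
  fwd <- branch_inflection(scan$forward)
  rev_ <- branch_inflection(scan$reverse)
  flags <- character(0)
  if (fwd$at_edge || rev_$at_edge) flags <- c(flags, "edge_inflection")
  midpoint <- if (length(flags) == 0L) mean(c(fwd$E, rev_$E)) else NA_real_
  if (length(flags) > 0L) {
    warning("derivative maximum at analysis-range edge; wave truncated ",
            "or absent, no midpoint reported")
  }
  list(midpoint_mV = midpoint, forward_inflection_mV = fwd$E,
       reverse_inflection_mV = rev_$E, flags = flags)
}

#' Summarize replicate biological currents per strain
#'
#' @param currents Data frame with columns strain_id,
#'   biological_current_A (one row per replicate), optionally mode.
#' @param min_replicates Strains with fewer replicates are dropped with
#'   a warning (uncertainty needs at least three replicates).
#' @return Data frame: strain_id, n, mean_A, sd_A.
#' @export
summarize_strain_currents <- function(currents, min_replicates = 3L) {
  sp <- split(currents, currents$strain_id)
  too_few <- names(sp)[vapply(sp, nrow, 0L) < min_replicates]
  if (length(too_few) > 0L) {
    warning("excluding strain(s) with < ", min_replicates,
            " replicates: ", paste(too_few, collapse = ", "))
    sp <- sp[!(names(sp) %in% too_few)]
  }
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(strain_id = d$strain_id[1], n = nrow(d),
               mean_A = mean(d$biological_current_A),
               sd_A = stats::sd(d$biological_current_A),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Compare strain currents to a reference by ANOVA and Tukey HSD
#'
#' Fits a one-factor linear model (current ~ strain), runs a type-II
#' analysis of variance ([car::Anova]), and compares every strain with
#' the reference strain by Tukey's honestly-significant-difference
#' test. Strains with Tukey-adjusted p < `alpha` and mean current
#' magnitude below the reference are flagged as reduced-uptake
#' phenotypes.
#'
#' @param currents Replicate-level data frame (strain_id,
#'   biological_current_A).
#' @param reference Reference strain id (wild type).
#' @param alpha Significance level for flagging.
#' @param min_replicates Minimum replicates per strain.
#' @return List of class `strain_comparison`: `anova` (car::Anova
#'   table), `f_value`, `p_value`, `tukey` (data frame strain_id,
#'   diff_A, p_adj, flagged), `summary` (per-strain summary),
#'   `reference`.
#' @export
compare_strains <- function(currents, reference = "WT", alpha = 0.05,
                            min_replicates = 3L) {
  summ <- summarize_strain_currents(currents, min_replicates)
  if (nrow(summ) < 2L) stop("need at least two strains with enough replicates")
  if (!(reference %in% summ$strain_id)) {
    stop("reference strain '", reference, "' not present")
  }
  keep <- currents[currents$strain_id %in% summ$strain_id, ]
  keep$strain_id <- factor(keep$strain_id)
  # fit on the microamp scale: F and p are scale-invariant, and
  # ampere-scale residual sums of squares underflow numerical checks
  keep$current_uA <- keep$biological_current_A * 1e6
  fit <- stats::lm(current_uA ~ strain_id, data = keep)
  an <- car::Anova(fit, type = 2)
  aov_fit <- stats::aov(current_uA ~ strain_id, data = keep)
  tuk <- stats::TukeyHSD(aov_fit)$strain_id
  # extract contrasts involving the reference
  pairs <- strsplit(rownames(tuk), "-", fixed = TRUE)
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    if (!(reference %in% p)) return(NULL)
    other <- setdiff(p, reference)
    if (length(other) != 1L) return(NULL)
    # TukeyHSD reports (first - second); orient as other - reference
    diff <- if (p[1] == other) tuk[i, "diff"] else -tuk[i, "diff"]
    diff <- diff * 1e-6  # back to amperes
    data.frame(strain_id = other, diff_A = unname(diff),
               p_adj = unname(tuk[i, "p adj"]), stringsAsFactors = FALSE)
  })
  tukey <- do.call(rbind, rows)
  ref_mean <- summ$mean_A[summ$strain_id == reference]
  strain_mean <- summ$mean_A[match(tukey$strain_id, summ$strain_id)]
  tukey$flagged <- tukey$p_adj < alpha &
    abs(strain_mean) < abs(ref_mean)
  structure(list(
    anova = an,
    f_value = an[["F value"]][1],
    p_value = an[["Pr(>F)"]][1],
    tukey = tukey, summary = summ, reference = reference
  ), class = "strain_comparison")
}

#' @export
print.strain_comparison <- function(x, ...) {
  cat("Strain comparison vs", x$reference, "\n")
  cat(sprintf("  type-II ANOVA: F = %.3f, Pr(>F) = %.3g\n",
              x$f_value, x$p_value))
  flagged <- x$tukey$strain_id[x$tukey$flagged]
  cat("  reduced-uptake strains:",
      if (length(flagged)) paste(flagged, collapse = ", ") else "none",
      "\n")
  invisible(x)
}

#' Convert electrode-referenced potentials to the SHE scale
#'
#' Potentiostat hardware commonly reports vs Ag/AgCl; analyses here use
#' mV vs SHE throughout.
#'
#' @param potential_mV Measured potentials, mV.
#' @param offset_mV Reference-electrode offset to add (e.g. +197 for
#'   Ag/AgCl in saturated KCl at 25 C).
#' @return Potentials in mV vs SHE.
#' @export
to_she_mV <- function(potential_mV, offset_mV) potential_mV + offset_mV
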