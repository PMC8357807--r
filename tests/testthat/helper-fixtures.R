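# Shared fixture builders; everything is generated in code.

# A standard 96-well assay layout: 4 quasi-wild-type controls, 2 no-cell
# blanks, 90 test mutants at rate k_test (optionally with named planted
# rates by well).
demo_layout <- function(k_test = 1, planted = NULL) {
  cls <- c(rep("quasi_wild_type", 4), rep("blank_no_cell", 2),
           rep("test_mutant", 90))
  lay <- plate_layout(
    mutant_ids = sprintf("M%03d", 1:96),
    control_class = cls,
    k_per_h = ifelse(cls == "blank_no_cell", 0, k_test)
  )
  if (!is.null(planted)) {
    idx <- match(names(planted), lay$well)
    stopifnot(!anyNA(idx), all(lay$control_class[idx] == "test_mutant"))
    lay$k_per_h[idx] <- planted
  }
  lay
}

demo_spec <- function(plate_id = "PLATE-001", ...) {
  plate_spec(plate_id, demo_layout(...))
}

# Build call_hits-style data frames directly, for partition tests.
make_calls <- function(mutants, hit_mutants, acceptor) {
  status <- rep("normal", length(mutants))
  status[mutants %in% hit_mutants] <- "slowed"
  data.frame(
    mutant_id = mutants,
    acceptor = rep(acceptor, length(mutants)),
    control_class = rep("test_mutant", length(mutants)),
    status = status,
    t50_h = rep(NA_real_, length(mutants)),
    rate_per_h = rep(NA_real_, length(mutants)),
    stringsAsFactors = FALSE
  )
}

# Exact noiseless trace data frame for one mutant from the kinetic
# model.
kinetic_trace <- function(k, times = seq(0, 8, by = 0.5), lag = 0,
                          y0 = 1, mutant_id = "M1",
                          acceptor = "fumarate",
                          control_class = "test_mutant") {
  data.frame(
    mutant_id = mutant_id, acceptor = acceptor,
    control_class = control_class, plate_id = "P1", well = "A1",
    replicate = "P1 A1", timestamp_h = times,
    y = kinetic_intensity(k, times, lag, y0),
    stringsAsFactors = FALSE
  )
}
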