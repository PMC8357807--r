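test_that("kinetic model is monotone and respects blanks", {
  t <- seq(0, 10, by = 0.25)
  y_active <- kinetic_intensity(1.0, t)
  expect_true(all(diff(y_active) < 0))
  expect_equal(kinetic_intensity(0, t), rep(1, length(t)))
  # closed form: k = 1/h, lag 0, y0 = 1 at t = 1 h
  expect_equal(kinetic_intensity(1.0, 1), exp(-1))
  # lag delays but does not reshape the decay
  expect_equal(kinetic_intensity(0.7, 3, lag = 2),
               kinetic_intensity(0.7, 1))
})

test_that("plate_spec enforces its invariants", {
  lay <- demo_layout()
  expect_s3_class(plate_spec("P-1", lay), "plate_spec")
  bad <- lay; bad$k_per_h[5] <- -1
  expect_error(plate_spec("P-1", bad), "finite and >= 0")
  bad <- lay; bad$k_per_h[bad$control_class == "blank_no_cell"] <- 0.5
  expect_error(plate_spec("P-1", bad), "blank_no_cell")
  bad <- lay[-1, ]
  expect_error(plate_spec("P-1", bad), "96 wells")
  # geometry too small to hold grid + barcode
  expect_error(
    plate_spec("P-1", lay, plate_geometry(image_width = 300L)),
    "too small"
  )
})

test_that("rendered well colors encode the kinetic intensity", {
  spec <- demo_spec()
  kin <- oxidation_kinetics(noise_sd = 0, channel_noise_sd = 0)
  r <- render_plate_image(spec, kin, t = 1, seed = 1)
  rec <- decode_plate(r$image)
  s <- sample_wells(rec)
  y <- yellow_intensity(as.matrix(s[, c("r", "g", "b")]))
  expect_equal(y, r$truth$y_true, tolerance = 1e-6)
  # blanks stay saturated yellow, actives have faded to e^-1
  blanks <- r$truth$control_class == "blank_no_cell"
  expect_equal(unname(y[blanks]), rep(1, sum(blanks)), tolerance = 1e-6)
  expect_equal(unname(y[!blanks]), rep(exp(-1), sum(!blanks)),
               tolerance = 1e-6)
})

test_that("rendering is deterministic in the seed", {
  spec <- demo_spec()
  kin <- oxidation_kinetics()
  a <- render_plate_image(spec, kin, t = 2, seed = 99)
  b <- render_plate_image(spec, kin, t = 2, seed = 99)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
  c <- render_plate_image(spec, kin, t = 2, seed = 100)
  expect_false(identical(a$image, c$image))
})

test_that("growth plate rejects inconsistent planted sets", {
  lay <- demo_layout()
  lay$occupied <- c(rep(TRUE, 90), rep(FALSE, 6))
  spec <- plate_spec("GP-1", lay)
  expect_error(render_growth_plate(spec, contamination = "A1"),
               "catalogued empty")
  expect_error(render_growth_plate(spec, failures = "H12"),
               "catalogued occupied")
  expect_error(
    render_growth_plate(spec, contamination = "H12", failures = "H12"),
    "overlap"
  )
})

test_that("noiseless CA trace hits its plateaus exactly", {
  sp <- ca_trace_spec(noise_sd = 0)
  tr <- simulate_ca_trace(sp)
  expect_equal(nrow(tr), ceiling(sp$duration / sp$sample_interval))
  pre <- tr$current_A[tr$time_s <= sp$inhibitor_time - 3 * sp$step_sharpness]
  post <- tr$current_A[tr$time_s >= sp$inhibitor_time + 3 * sp$step_sharpness]
  expect_true(all(pre == sp$baseline_current))
  expect_true(all(post == sp$abiotic_current))
})

test_that("CA trace without inhibitor has no step", {
  sp <- ca_trace_spec(noise_sd = 0, inhibitor_time = 5000,
                      duration = 1200)
  tr <- simulate_ca_trace(sp)
  expect_true(all(tr$current_A == sp$baseline_current))
  expect_true(is.na(attr(tr, "inhibitor_time_s")))
  # trace is flat relative to its own tail
  head_ss <- mean(tr$current_A[1:100])
  expect_equal(steady_state_current(tr) - head_ss, 0)
})

test_that("CV branches honor the hysteresis invariant", {
  sp <- cv_scan_spec(formal_potential_mV = -50, hysteresis_mV = 20,
                     noise_sd = 0)
  scan <- simulate_cv_scan(sp)
  expect_true(all(diff(scan$forward$potential_mV_SHE) < 0))
  expect_true(all(diff(scan$reverse$potential_mV_SHE) > 0))
  # noiseless branch current matches offset + amplitude * logistic
  infl_f <- -50 - 10
  expected <- sp$capacitive_offset + sp$wave_amplitude *
    plogis((scan$forward$potential_mV_SHE - infl_f) / sp$wave_width_mV)
  expect_equal(scan$forward$current_A, expected)
  expect_error(cv_scan_spec(wave_width_mV = -1), "wave_width_mV")
  expect_error(cv_scan_spec(formal_potential_mV = 500), "inside")
})

test_that("synthetic screen plants exactly the requested truth", {
  sim <- simulate_screen(n_plates = 2L, n_slowed = 4L,
                         n_eliminated = 3L, seed = 42)
  expect_equal(sum(sim$truth$planted_status == "slowed"), 4L)
  expect_equal(sum(sim$truth$planted_status == "eliminated"), 3L)
  expect_equal(nrow(sim$catalog), 192L)
  # identical seed reproduces bit-identically
  sim2 <- simulate_screen(n_plates = 2L, n_slowed = 4L,
                          n_eliminated = 3L, seed = 42)
  expect_identical(sim$traces, sim2$traces)
})

test_that("trace CSVs round-trip", {
  tr <- simulate_ca_trace(ca_trace_spec(), seed = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_ca_csv(tr, f)
  back <- read_ca_csv(f, inhibitor_time_s = 600)
  expect_equal(back$current_A, tr$current_A, tolerance = 1e-12)
  scan <- simulate_cv_scan(cv_scan_spec(), seed = 1)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cv_csv(scan, f2)
  back2 <- read_cv_csv(f2)
  expect_equal(back2$forward$current_A, scan$forward$current_A,
               tolerance = 1e-12)
  expect_equal(back2$reverse$potential_mV_SHE,
               scan$reverse$potential_mV_SHE)
})
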