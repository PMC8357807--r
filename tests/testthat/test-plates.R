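test_that("decode recovers plate identity across random specs", {
  set.seed(7)
  ids <- replicate(6, paste0("PL-", paste(sample(c(LETTERS, 0:9), 6,
                                                 replace = TRUE),
                                          collapse = "")))
  for (i in seq_along(ids)) {
    spec <- demo_spec(plate_id = ids[i])
    r <- render_plate_image(spec, oxidation_kinetics(), t = 1,
                            seed = 1000 + i)
    rec <- decode_plate(r$image)
    expect_identical(rec$decoded_plate_id, ids[i])
    expect_false("barcode_unreadable" %in% rec$quality_flags)
  }
})

test_that("180-degree-rotated images decode and sample identically", {
  spec <- demo_spec()
  r <- render_plate_image(spec, oxidation_kinetics(), t = 1, seed = 5)
  up <- decode_plate(r$image)
  flipped <- r$image[rev(seq_len(dim(r$image)[1])),
                     rev(seq_len(dim(r$image)[2])), ]
  down <- decode_plate(flipped)
  expect_identical(down$decoded_plate_id, spec$plate_id)
  expect_true(down$rotated_180)
  su <- sample_wells(up)
  sd_ <- sample_wells(down)
  expect_equal(sd_[, c("r", "g", "b")], su[, c("r", "g", "b")],
               tolerance = 1e-9)
})

test_that("blank image yields barcode_unreadable, not an exception", {
  img <- array(255, dim = c(100, 200, 3))
  rec <- decode_plate(img)
  expect_true("barcode_unreadable" %in% rec$quality_flags)
  expect_true(is.na(rec$decoded_plate_id))
  expect_error(sample_wells(rec), "no registration transform")
})

test_that("missing image file raises an I/O error", {
  expect_error(decode_plate(file.path(tempdir(), "nope.png")))
})

test_that("well sampling is exact on uniform wells and emits A1..H12 once", {
  spec <- demo_spec()
  kin <- oxidation_kinetics(noise_sd = 0, channel_noise_sd = 0)
  r <- render_plate_image(spec, kin, t = 0, seed = 2)
  rec <- decode_plate(r$image)
  s <- sample_wells(rec)
  expect_identical(s$well, well_names())
  expect_identical(anyDuplicated(s$well), 0L)
  expect_true(all(s$n_pixels >= 100L))
  # uniform saturated-yellow wells sample to exactly (225, 153, 0)
  active <- r$truth$control_class != "blank_no_cell"
  expect_equal(s$r, rep(225, 96))
  expect_equal(s$g, rep(153, 96))
  expect_equal(s$b, rep(0, 96))
  # white-reference transform reconstructs C exactly
  expect_equal(s$r_prime + 255, s$r)
  expect_equal(s$g_prime + 255, s$g)
  expect_equal(s$b_prime + 255, s$b)
})

test_that("channel noise averages out at the CLT rate", {
  lay <- plate_layout(sprintf("M%03d", 1:96), "test_mutant", k_per_h = 1)
  spec <- plate_spec("PLATE-001", lay)
  kin <- oxidation_kinetics(noise_sd = 0, channel_noise_sd = 2)
  # t = 0.5 h keeps every channel interior so boundary clipping cannot
  # bias the disc means
  r <- render_plate_image(spec, kin, t = 0.5, seed = 3)
  rec <- decode_plate(r$image)
  s <- sample_wells(rec)
  expect_true(all(s$n_pixels >= 100L))
  tol <- 4 * 2 / sqrt(min(s$n_pixels))  # 4 sigma over 96 wells
  for (ch in c("r", "g", "b")) {
    truthv <- r$truth[[ch]]
    expect_true(all(abs(s[[ch]] - truthv) < tol))
  }
})

test_that("zero sampling radius is rejected", {
  spec <- demo_spec()
  r <- render_plate_image(spec, oxidation_kinetics(), t = 1, seed = 4)
  rec <- decode_plate(r$image)
  expect_error(sample_wells(rec, radius_frac = 0), "radius_frac")
})

test_that("growth QC recovers planted events exactly", {
  lay <- demo_layout()
  lay$occupied <- rep(c(TRUE, FALSE), c(88, 8))
  spec <- plate_spec("GP-7", lay)
  catalog <- cbind(lay, plate_id = "GP-7")

  fails <- c("A3", "B5", "C7", "D9", "E11")
  gp <- render_growth_plate(spec, failures = fails, seed = 11)
  rec <- decode_plate(gp$image)
  qc <- qc_growth_plate(rec, catalog)
  expect_setequal(qc$events$well[qc$events$event == "growth_failure"],
                  fails)
  expect_equal(sum(qc$events$event == "contamination"), 0L)

  # one contaminated catalogued-empty well
  cont_well <- lay$well[!lay$occupied][1]
  gp2 <- render_growth_plate(spec, contamination = cont_well, seed = 12)
  qc2 <- qc_growth_plate(decode_plate(gp2$image), catalog)
  expect_identical(qc2$events$well[qc2$events$event == "contamination"],
                   cont_well)

  # clean plate: no events, any seed
  for (s in 1:3) {
    gp3 <- render_growth_plate(spec, seed = s)
    qc3 <- qc_growth_plate(decode_plate(gp3$image), catalog)
    expect_equal(nrow(qc3$events), 0L)
  }
})

test_that("fully occupied and fully failed plates are handled", {
  lay <- demo_layout()
  lay$occupied <- TRUE
  spec <- plate_spec("GP-8", lay)
  catalog <- cbind(lay, plate_id = "GP-8")
  gp <- render_growth_plate(spec, seed = 1)
  qc <- qc_growth_plate(decode_plate(gp$image), catalog)
  expect_equal(nrow(qc$events), 0L)
  # every well failed
  gp2 <- render_growth_plate(spec, failures = lay$well, seed = 2)
  qc2 <- qc_growth_plate(decode_plate(gp2$image), catalog)
  expect_equal(sum(qc2$events$event == "growth_failure"), 96L)
})

test_that("QC requires the plate in the catalog", {
  spec <- demo_spec("GP-9")
  gp <- render_growth_plate(spec, seed = 1)
  rec <- decode_plate(gp$image)
  catalog <- cbind(demo_layout(), plate_id = "OTHER")
  expect_error(qc_growth_plate(rec, catalog), "not present")
})

test_that("image PNG round-trip preserves scoring to 8-bit precision", {
  spec <- demo_spec()
  r <- render_plate_image(spec, oxidation_kinetics(), t = 1, seed = 21)
  f <- withr::local_tempfile(fileext = ".png")
  write_plate_image(r$image, f)
  back <- read_plate_image(f)
  expect_equal(dim(back), dim(r$image))
  expect_true(max(abs(back - r$image)) <= 0.5 + 1e-9)
  rec <- decode_plate(f)
  expect_identical(rec$decoded_plate_id, spec$plate_id)
})

test_that("ingest skips unreadable images and keeps the rest", {
  spec <- demo_spec()
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "t0.png")
  p2 <- file.path(dir, "blank.png")
  write_plate_image(render_plate_image(spec, oxidation_kinetics(),
                                       t = 0, seed = 1)$image, p1)
  write_plate_image(array(255, dim = c(100, 200, 3)), p2)
  res <- suppressMessages(
    ingest_plate_images(c(p1, p2), c(0, 1))
  )
  expect_equal(nrow(res$samples), 96L)
  expect_equal(nrow(res$skipped), 1L)
  expect_match(res$skipped$flags, "barcode_unreadable")
})
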