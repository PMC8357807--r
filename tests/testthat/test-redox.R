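test_that("yellow intensity matches the reference-color anchors", {
  expect_identical(yellow_intensity(c(225, 153, 0)), 1)
  expect_identical(yellow_intensity(c(255, 255, 255)), 0)
  # hand arithmetic: C' = (-15, -51, -127),
  # dot = 450 + 5202 + 32385 = 38037, |Y0'|^2 = 76329
  expect_equal(yellow_intensity(c(240, 204, 128)), 38037 / 76329)
  refs <- reference_colors()
  expect_equal(refs$Y0_prime, c(-30, -102, -255))
  expect_equal(refs$Y0_prime_sq, 76329)
  expect_error(yellow_intensity(c(-1, 0, 0)), "\\[0, 255\\]")
})

test_that("affine display-color round trip holds to machine precision", {
  y <- seq(0, 1, length.out = 1001)
  cols <- display_color(y)
  expect_equal(yellow_intensity(cols), y, tolerance = 1e-12)
})

test_that("blue channel dominates the score", {
  base <- c(120, 120, 120)
  dy_r <- yellow_intensity(base + c(1, 0, 0)) - yellow_intensity(base)
  dy_b <- yellow_intensity(base + c(0, 0, 1)) - yellow_intensity(base)
  expect_equal(dy_r, -30 / 76329)
  expect_equal(dy_b, -255 / 76329)
  expect_gt(abs(dy_b) / abs(dy_r), 8)
})

test_that("trace interpolation is linear and replicate-averaged", {
  tr <- kinetic_trace(0, times = c(0, 2))
  tr$y <- c(1, 0)
  out <- interpolate_trace(tr, marks = 1)
  expect_equal(out$y, 0.5)
  # a mark at an observation returns it unchanged
  out2 <- interpolate_trace(tr, marks = 2)
  expect_equal(out2$y, 0)
  # two replicates average before interpolation
  tr2 <- rbind(kinetic_trace(0, times = c(0, 1, 2)),
               kinetic_trace(0, times = c(0, 1, 2)))
  tr2$replicate <- rep(c("r1", "r2"), each = 3)
  tr2$y <- c(1, 0.4, 0, 1, 0.6, 0)
  out3 <- interpolate_trace(tr2, marks = 1)
  expect_equal(out3$y, 0.5)
  # display color is reconstructed from the interpolated intensity
  expect_equal(unlist(out3[, c("r", "g", "b")], use.names = FALSE),
               as.vector(display_color(0.5)))
  expect_error(interpolate_trace(tr[0, ]), "empty trace")
})

test_that("oxidation rate is exact on a linear decline", {
  tr <- kinetic_trace(0, times = 0:4)
  tr$y <- 1 - 0.25 * tr$timestamp_h
  fit <- fit_oxidation_rate(tr)
  expect_equal(fit$rate, 0.25)
  expect_identical(fit$flag, "ok")
})

test_that("flat traces report no decline", {
  tr <- kinetic_trace(0, times = 0:5)
  fit <- fit_oxidation_rate(tr)
  expect_equal(fit$rate, 0)
  expect_identical(fit$flag, "no_decline")
})

test_that("rate fit matches a brute-force OLS oracle on its window", {
  tr <- kinetic_trace(1.0, times = seq(0, 4, by = 0.25))
  fit <- fit_oxidation_rate(tr)
  # independent oracle: re-derive the window from the definition and
  # compute the OLS slope from first principles
  y <- tr$y; t <- tr$timestamp_h
  rng <- max(y) - min(y)
  keep <- y >= min(y) + 0.2 * rng & y <= min(y) + 0.8 * rng
  tw <- t[keep]; yw <- y[keep]
  slope <- sum((tw - mean(tw)) * (yw - mean(yw))) /
    sum((tw - mean(tw))^2)
  expect_equal(fit$rate, abs(slope), tolerance = 1e-12)
  expect_equal(fit$window_h, range(tw))
})

test_that("hit calling separates planted classes and excludes QC failures", {
  sim <- simulate_screen(n_plates = 2L, n_slowed = 5L,
                         n_eliminated = 4L, seed = 77)
  calls <- call_hits(sim$traces)
  merged <- merge(calls, sim$truth, by = "mutant_id")
  # every planted eliminated mutant is called eliminated
  expect_true(all(merged$status[merged$planted_status == "eliminated" &
                                  merged$control_class.x ==
                                    "test_mutant"] == "eliminated"))
  # every planted slowed mutant is called slowed
  expect_true(all(merged$status[merged$planted_status == "slowed"] ==
                    "slowed"))
  # blanks never oxidize
  expect_true(all(merged$status[merged$control_class.x ==
                                  "blank_no_cell"] == "eliminated"))
  # a planted hit whose well fails growth QC is excluded
  victim <- sim$truth$mutant_id[sim$truth$planted_status == "slowed"][1]
  vwell <- sim$catalog[sim$catalog$mutant_id == victim, ]
  qc_events <- data.frame(plate_id = vwell$plate_id, well = vwell$well,
                          event = "growth_failure")
  calls2 <- call_hits(sim$traces, qc_events = qc_events)
  expect_identical(calls2$status[calls2$mutant_id == victim],
                   "excluded_growth_failure")
  part <- partition_hits(calls2, calls2)
  expect_false(victim %in% unlist(part[c("fumarate_only",
                                         "nitrate_only", "both")]))
})

test_that("hit calling refuses to run without enough controls", {
  sim <- simulate_screen(n_plates = 1L, controls_per_plate = 4L,
                         n_slowed = 1L, n_eliminated = 1L, seed = 1)
  expect_error(call_hits(sim$traces), "quasi-wild-type control")
})

test_that("hit set is monotone in the calling threshold", {
  sim <- simulate_screen(n_plates = 2L, seed = 31)
  hits_at <- function(k) {
    calls <- call_hits(sim$traces, k_sd = k)
    sum(calls$status %in% c("slowed", "eliminated"))
  }
  h <- vapply(c(1, 2, 3, 5), hits_at, 0)
  expect_true(all(diff(h) <= 0))
})

test_that("partition set algebra is exact on planted truth", {
  mutants <- sprintf("SO_%04d", 1:40)
  fum_hits <- c(mutants[1:5], mutants[20:26])   # 5 only + 7 both
  nit_hits <- c(mutants[10:12], mutants[20:26]) # 3 only + 7 both
  part <- partition_hits(make_calls(mutants, fum_hits, "fumarate"),
                         make_calls(mutants, nit_hits, "nitrate"))
  expect_equal(unname(part$counts["fumarate_only"]), 5L)
  expect_equal(unname(part$counts["nitrate_only"]), 3L)
  expect_equal(unname(part$counts["both"]), 7L)
  expect_equal(unname(part$counts["total"]), 15L)
  expect_setequal(part$both, mutants[20:26])
  # conservation: assay hit totals decompose through the partition
  expect_equal(length(fum_hits),
               unname(part$counts["fumarate_only"] + part$counts["both"]))
  expect_equal(length(nit_hits),
               unname(part$counts["nitrate_only"] + part$counts["both"]))
  # pairwise disjoint
  expect_length(intersect(part$fumarate_only, part$nitrate_only), 0)
  expect_length(intersect(part$fumarate_only, part$both), 0)
})

test_that("empty call lists give an empty partition", {
  empty <- make_calls(character(0), character(0), "fumarate")
  part <- partition_hits(empty, empty)
  expect_equal(unname(part$counts["total"]), 0L)
})

test_that("a mutant missing from one assay warns and counts once", {
  a <- make_calls(c("m1", "m2"), "m1", "fumarate")
  b <- make_calls("m2", "m2", "nitrate")
  expect_warning(part <- partition_hits(a, b), "only one assay")
  expect_identical(part$fumarate_only, "m1")
  expect_identical(part$nitrate_only, "m2")
})

test_that("category triage conserves counts and buckets the unannotated", {
  mutants <- sprintf("SO_%04d", 1:30)
  part <- partition_hits(make_calls(mutants, mutants[1:10], "fumarate"),
                         make_calls(mutants, mutants[6:20], "nitrate"))
  set.seed(4)
  ann <- data.frame(
    mutant_id = mutants[1:15],
    category = sample(c("fumarate reductase", "nitrate reductase",
                        "menaquinone"), 15, replace = TRUE)
  )
  tri <- triage_categories(part, ann)
  expect_equal(sum(tri$table$count), unname(part$counts["total"]))
  expect_setequal(tri$unknown, mutants[16:20])
  # single-category annotation collapses to one row
  ann2 <- data.frame(mutant_id = mutants,
                     category = "fumarate reductase")
  tri2 <- triage_categories(part, ann2)
  expect_identical(nrow(tri2$table), 1L)
})
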