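test_that("noise-free simulation reproduces the forward model exactly", {
  plan <- tiny_plan()
  arr <- tiny_array()
  k <- study_kernel()
  nf <- compute_delivery_dose(plan, arr, NULL, k)
  sim <- simulate_delivery(plan, arr, k, truth_state(), noise_off(),
                           seed = 5)
  expect_identical(sim, nf)
})

test_that("simulated deliveries are seed-deterministic", {
  plan <- tiny_plan()
  arr <- tiny_array()
  k <- study_kernel()
  a <- simulate_delivery(plan, arr, k, truth_state(), noise_model(), 123)
  b <- simulate_delivery(plan, arr, k, truth_state(), noise_model(), 123)
  c <- simulate_delivery(plan, arr, k, truth_state(), noise_model(), 124)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("delivery noise matches its configured budget", {
  plan <- tiny_plan()
  arr <- tiny_array()
  k <- study_kernel()
  nm <- noise_model()
  nf <- compute_delivery_dose(plan, arr, NULL, k)
  on <- which(nf > 0.1 * max(nf))
  sims <- sapply(1:500, function(s) {
    simulate_delivery(plan, arr, k, truth_state(), nm, s,
                      noise_free = nf)[on]
  })
  rel_sd <- apply(sims / nf[on], 1, stats::sd)
  # per-delivery factors: output 0.5 percent and diode 0.5 percent
  expected <- sqrt(nm$output_delivery_sd^2 + nm$diode_delivery_sd^2)
  expect_lt(abs(mean(rel_sd) - expected) / expected, 0.2)
})

test_that("placement truth is bounded by the stated accuracy", {
  arr <- study_array()
  pl <- beampathqa:::draw_placement_truth(arr, noise_model(), 77)
  expect_identical(dim(pl), c(1386L, 3L))
  expect_true(all(abs(pl) <= 0.5))
  expect_gt(stats::sd(pl), 0.15) # close to the 0.25 mm per-axis SD
  expect_lt(stats::sd(pl), 0.35)
})

test_that("campaigns share day factors within a day and truth throughout", {
  plan <- tiny_plan()
  arr <- tiny_array()
  k <- study_kernel()
  # isolate day-level factors: no per-delivery noise
  nm <- noise_model(output_day_sd = 0.01, output_delivery_sd = 0,
                    diode_total_sd = 0.01, diode_delivery_sd = 0,
                    placement_sd_mm = 0)
  camp <- simulate_constancy_campaign(plan, arr, k, nm, seed = 9)
  # same-day repeats are identical without per-delivery noise
  for (i in 2:5) expect_identical(camp$sameday[[i]], camp$sameday[[1]])
  # different days differ
  expect_false(identical(camp$baseline[[1]], camp$baseline[[2]]))
  expect_identical(nrow(camp$manifest), 12L)
  expect_identical(camp$truth$shift, c(0, 0, 0))
})

test_that("baseline averaging converges to the noise-free dose", {
  plan <- tiny_plan()
  arr <- tiny_array()
  k <- study_kernel()
  camp <- simulate_constancy_campaign(plan, arr, k, noise_model(),
                                      seed = 21)
  nf <- compute_delivery_dose(plan, arr, camp$truth$placements, k)
  b <- compute_baseline(camp$baseline)
  on <- which(nf > 0.1 * max(nf))
  # per-delivery budget ~1.6 percent across days; the mean of 6 tracks
  # the truth within ~3 SD / sqrt(6) for almost all diodes
  total_sd <- sqrt(0.01^2 + 0.005^2 + 0.01^2)
  viol <- abs(b$dose[on] / nf[on] - 1) > 3 * total_sd / sqrt(6) +
    3 * total_sd # day factors do not average like iid per-diode noise
  expect_lt(mean(viol), 0.02)
})

test_that("campaign manifests round-trip through JSON", {
  plan <- tiny_plan()
  arr <- tiny_array()
  camp <- simulate_constancy_campaign(plan, arr, study_kernel(),
                                      noise_model(), seed = 4,
                                      test_shift = c(0, 0, 1.4))
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(camp$manifest, f, dataframe = "rows", digits = NA)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$shift_z[back$role == "test"], 1.4)
  expect_equal(back$seed, camp$manifest$seed)
})

test_that("the noise-free pipeline reports exactly zero errors", {
  camp <- simulate_constancy_campaign(study_plan(), study_array(),
                                      study_kernel(), noise_off(),
                                      seed = 3)
  rep <- analyze_campaign(camp, study_curves(), study_lut())
  expect_true(all(rep$per_diode$delta_mm == 0))
  expect_identical(rep$summary$rms_mm, 0)
  expect_identical(rep$summary$max_abs_mm, 0)
  expect_true(rep$summary$within_tolerance)
})

test_that("recovered shifts grow with the introduced drift and never
           overshoot the expected envelope", {
  means <- vapply(c(0.4, 1.4), function(d) {
    run_shift_campaign(d, seed = 606)$summary$mean_abs_mm
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  expect_lt(means[1], 1.1 * 0.4)
  expect_lt(means[2], 1.1 * 1.4)
  # the estimator is exact in the introduced direction: inverting the
  # true-direction curve at the noise-free RPD recovers the drift
  d <- 0.8
  camp <- simulate_constancy_campaign(study_plan(), study_array(),
                                      study_kernel(), noise_off(),
                                      seed = 1, test_shift = c(0, 0, d))
  baseline <- compute_baseline(camp$baseline)
  rpd <- compute_rpd(camp$test, baseline, study_lut())
  si <- vapply(names(rpd), function(kk) {
    crv <- get_curve(study_curves(), as.integer(kk), "SI")
    inv <- invert_curve(crv, rpd[[kk]])
    if (inv$solvable) inv$abs_mm else NA_real_
  }, numeric(1))
  si <- si[is.finite(si)]
  expect_gt(length(si), 30)
  expect_equal(median(si), d, tolerance = 0.05)
})

test_that("single-beam shift measurements verify the correlation curves", {
  lut <- study_lut()
  beams <- lut$table$beam_id[order(-lut$table$signal)][1:2]
  tab <- verify_curves(study_plan(), study_array(), study_kernel(), lut,
                       beams)
  expect_identical(nrow(tab), as.integer(2 * 3 * 5))
  zero <- tab[tab$shift_mm == 0, ]
  expect_true(all(zero$measured_percent == 0))
  expect_true(all(zero$predicted_percent == 0))
  # noise-free: measured and curve-predicted changes agree within the
  # interpolation error inside +/- 1 mm
  expect_lt(max(tab$discrepancy_percent), 0.1)
  expect_error(
    verify_curves(study_plan(), study_array(), study_kernel(), lut,
                  "nope"),
    "no matched diode"
  )
})

test_that("a penumbra diode's dose change flips sign with the shift", {
  arr <- tiny_array()
  p0 <- diode_position(arr, 0)
  # beam axis offset 2.5 mm in +y from diode 0: the diode sits on the
  # penumbra slope, so opposite AP shifts move it into/out of the field
  beams <- data.frame(
    id = "B001", sx = p0[1] + 800, sy = p0[2] + 2.5, sz = p0[3],
    dx = -1, dy = 0, dz = 0, cone_mm = 5, mu = 50,
    stringsAsFactors = FALSE
  )
  plan <- beampathqa:::new_qa_plan(beams, "penumbra-beam",
                                   isocenter = c(0, p0[2] + 2.5, p0[3]))
  lut <- structure(
    list(table = data.frame(beam_id = "B001", diode = 0L, signal = 1,
                            stringsAsFactors = FALSE),
         threshold_fraction = 0.1, threshold_ref = "global",
         threshold = 0.1,
         exclusions = data.frame(kind = character(), id = character(),
                                 reason = character())),
    class = "beam_diode_lut"
  )
  tab <- verify_curves(plan, arr, study_kernel(), lut, "B001",
                       shifts_mm = c(-1, 1))
  ap <- tab[tab$direction == "AP", ]
  expect_lt(prod(ap$measured_percent), 0)
  expect_lt(max(tab$discrepancy_percent), 0.1)
})
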