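test_that("baseline averaging behaves like an arithmetic mean", {
  d1 <- c(98, 50); d2 <- c(102, 50)
  b <- compute_baseline(list(d1, d2))
  expect_equal(b$dose, c(100, 50))
  expect_identical(b$n_deliveries, 2L)
  expect_equal(compute_baseline(list(d2, d1))$dose, b$dose)
  expect_equal(compute_baseline(list(d1, d1))$dose, d1)
  expect_error(compute_baseline(list(d1, c(1, 2, 3))), "mismatched")
  expect_error(compute_baseline(list(d1)), "at least 2")
})

test_that("RPD maps are exact percent differences on LUT diodes", {
  b <- compute_baseline(list(c(100, 200, 0), c(100, 200, 0)))
  expect_warning(r0 <- compute_rpd(c(100, 200, 0), b), "non-positive")
  expect_equal(as.numeric(r0[1:2]), c(0, 0))
  expect_warning(r <- compute_rpd(c(102, 204, 5), b), "non-positive")
  expect_equal(as.numeric(r), c(2, 2))
  # linearity in the measurement
  m1 <- c(103, 190, 0); m2 <- c(99, 210, 0)
  suppressWarnings({
    r1 <- compute_rpd(m1, b); r2 <- compute_rpd(m2, b)
  })
  expect_equal(as.numeric(r1 - r2), 100 * (m1[1:2] - m2[1:2]) / b$dose[1:2])
})

test_that("placement choice falls back to nominal for zero scatter", {
  cs <- linear_curve_set()
  lut <- structure(
    list(table = data.frame(beam_id = c("B1", "B2"), diode = 0:1,
                            signal = c(1, 1), stringsAsFactors = FALSE),
         threshold_fraction = 0.1, threshold_ref = "global",
         threshold = 1,
         exclusions = data.frame(kind = character(), id = character(),
                                 reason = character())),
    class = "beam_diode_lut"
  )
  d <- c(10, 20)
  plut <- build_placement_lut(list(d, d, d, d, d), cs, lut)
  expect_identical(nrow(plut$table), 2L)
  expect_true(all(plut$table$placement == "nominal"))
  expect_true(all(plut$table$delta_mm == 0))
  # scale invariance: doubling all deliveries changes nothing
  dd <- lapply(list(c(10, 21), c(10.2, 20), c(9.9, 20.4), c(10, 20),
                    c(10.1, 19.8)), identity)
  p1 <- build_placement_lut(dd, cs, lut)
  p2 <- build_placement_lut(lapply(dd, `*`, 2), cs, lut)
  expect_equal(p1$table, p2$table, tolerance = 1e-12)
})

test_that("margin branches can cancel an RPD equal to the margin", {
  cs <- linear_curve_set()
  rpd <- structure(c(`0` = 1.0), beam_id = "B1", class = "rpd_map")
  rep <- position_errors(rpd, cs, NULL, margin_percent = 1.0)
  expect_equal(rep$per_diode$delta_mm, 0) # branch RPD - 1 percent hits 0
  expect_identical(rep$per_diode$branch, -1)
})

test_that("zero margin reproduces the plain direction-minimum step", {
  cs <- linear_curve_set()
  rpd <- structure(c(`0` = 3.0, `1` = -2.4), beam_id = c("B1", "B2"),
                   class = "rpd_map")
  rep <- position_errors(rpd, cs, NULL, margin_percent = 0)
  manual <- vapply(c(0, 1), function(d) {
    crvs <- lapply(c(AP = "AP", SI = "SI", LR = "LR"), function(dir) {
      get_curve(cs, d, dir)
    })
    min_direction_error(crvs, rpd[[as.character(d)]])$delta_mm
  }, numeric(1))
  expect_equal(rep$per_diode$delta_mm, manual, tolerance = 1e-12)
  # steepest direction wins for the linear synthetic curves
  expect_identical(rep$per_diode$direction, c("SI", "AP"))
  expect_equal(rep$per_diode$delta_mm, c(3 / 20, -2.4 / 10),
               tolerance = 1e-12)
})

test_that("larger margins never hurt while below the RPD magnitude", {
  cs <- linear_curve_set()
  rpd <- structure(c(`0` = 4.0, `1` = -6.0), beam_id = c("B1", "B2"),
                   class = "rpd_map")
  margins <- c(0, 1, 2, 3.9)
  prev <- NULL
  for (m in margins) { # all margins <= min |rpd|
    rep <- position_errors(rpd, cs, NULL, margin_percent = m)
    if (!is.null(prev)) expect_true(all(rep$per_diode$abs_mm <= prev + 1e-12))
    prev <- rep$per_diode$abs_mm
  }
})

test_that("report summaries are internally consistent", {
  rep <- run_shift_campaign(0.8, seed = 314)
  tab <- rep$per_diode
  s <- rep$summary
  expect_equal(s$rms_mm, sqrt(mean(tab$delta_mm^2)), tolerance = 1e-12)
  expect_equal(s$mean_abs_mm, mean(abs(tab$delta_mm)), tolerance = 1e-12)
  expect_equal(s$max_abs_mm, max(abs(tab$delta_mm)))
  expect_gte(s$max_abs_mm, s$rms_mm)
  expect_identical(s$n, nrow(tab))
  expect_identical(s$n_unsolvable, sum(!tab$solvable))
})

test_that("reproducibility errors scale with the SD multiplier", {
  cs <- linear_curve_set()
  lut <- structure(
    list(table = data.frame(beam_id = c("B1", "B2"), diode = 0:1,
                            signal = c(1, 1), stringsAsFactors = FALSE),
         threshold_fraction = 0.1, threshold_ref = "global",
         threshold = 1,
         exclusions = data.frame(kind = character(), id = character(),
                                 reason = character())),
    class = "beam_diode_lut"
  )
  d0 <- c(10, 20)
  zero <- reproducibility_errors(list(d0, d0, d0, d0, d0), cs, NULL, lut,
                                 k = 1)
  expect_equal(zero$summary$rms_mm, 0)
  expect_equal(zero$summary$max_abs_mm, 0)
  dd <- list(c(10, 21), c(10.2, 20), c(9.9, 20.4), c(10, 20),
             c(10.1, 19.8))
  r1 <- reproducibility_errors(dd, cs, NULL, lut, k = 1)
  r2 <- reproducibility_errors(dd, cs, NULL, lut, k = 2)
  # linear curves are monotone, so 2-SD errors dominate 1-SD errors
  expect_true(all(r2$per_diode$abs_mm >= r1$per_diode$abs_mm - 1e-12))
  expect_equal(r2$per_diode$abs_mm, 2 * r1$per_diode$abs_mm,
               tolerance = 1e-9)
})

test_that("drift detection combines the null percentile and RMS criteria", {
  rep <- run_shift_campaign(0, seed = 11)
  nr <- study_null()
  v <- detect_systematic_shift(rep, nr$mean_abs_mm)
  expect_identical(v$detected, v$by_mean || v$by_rms)
  # the null reference calibrates itself to about a 5 percent rate
  q95 <- attr(nr, "mean_abs_q95")
  rate <- mean(nr$mean_abs_mm > q95)
  expect_lte(rate, 0.08)
  # an infinite percentile disables the mean criterion only
  v_inf <- detect_systematic_shift(rep, list(mean_abs_q95 = Inf))
  expect_false(v_inf$by_mean)
  expect_identical(v_inf$detected, v_inf$by_rms)
  expect_error(detect_systematic_shift(rep, NULL), "simulate")
})
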