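test_that("shift grid has the canonical 17-point structure", {
  g <- build_shift_grid()
  s <- g$shift_mm
  expect_length(s, 17L)
  expect_equal(s, sort(-s)) # symmetric about zero
  expect_true(0 %in% s)
  inner <- s[abs(s) <= 1]
  expect_equal(diff(inner), rep(0.25, 8))
  outer <- sort(abs(s[abs(s) > 1]))
  expect_equal(outer, rep(2:5, each = 2))
  expect_false(is.unsorted(s, strictly = TRUE))
})

test_that("curve sets carry 21 curves per diode with exact zero at origin", {
  plan <- tiny_plan()
  arr <- tiny_array()
  sig <- per_beam_signals(plan, arr, study_kernel())
  lut <- build_beam_diode_lut(sig)
  cs <- build_curve_set(plan, arr, study_kernel(), lut$table$diode)
  expect_gt(length(cs$curves), 0)
  for (cc in cs$curves) {
    expect_identical(dim(cc), c(17L, 3L, 7L))
    expect_true(all(is.finite(cc)))
    expect_equal(as.numeric(cc[9, , ]), rep(0, 21), tolerance = 1e-12)
  }
})

test_that("curves are invariant to rescaling all beam MUs", {
  plan <- axis_beam_plan()
  arr <- tiny_array()
  cs1 <- build_curve_set(plan, arr, study_kernel(), 0L)
  plan2 <- plan
  plan2$beams$mu <- plan2$beams$mu * 2
  cs2 <- build_curve_set(plan2, arr, study_kernel(), 0L)
  expect_equal(cs1$curves, cs2$curves, tolerance = 1e-12)
  # and bit-reproducible
  cs3 <- build_curve_set(plan, arr, study_kernel(), 0L)
  expect_identical(cs1$curves, cs3$curves)
})

test_that("on-axis entrance diode: along-beam direction flat, lateral steep", {
  # beam travels along -x through diode 0, so LR is the along-beam
  # (depth) direction and AP/SI cross the field edge
  cs <- build_curve_set(axis_beam_plan(), tiny_array(), study_kernel(), 0L)
  lr <- get_curve(cs, 0, "LR")
  ap <- get_curve(cs, 0, "AP")
  si <- get_curve(cs, 0, "SI")
  expect_lt(max(abs(lr$percent)), 8) # inverse-square + attenuation only
  expect_gt(max(abs(ap$percent)), 50) # crosses the penumbra by 5 mm
  expect_gt(max(abs(si$percent)), 50)
  # near the origin every direction is gentle (flat core)
  small <- abs(cs$shift_mm) <= 0.5
  expect_lt(max(abs(ap$percent[small])), 1)
  expect_lt(max(abs(si$percent[small])), 1)
})

test_that("curve building from a sampled SI dose grid matches the kernel", {
  plan <- axis_beam_plan()
  arr <- tiny_array()
  k <- study_kernel()
  p0 <- diode_position(arr, 0)
  # fine local grid covering all placements and +/-5 mm shifts
  g3 <- rasterize_dose_grid(plan, k, origin = p0 - 6.5,
                            spacing = c(0.25, 0.25, 0.25),
                            dim = c(53, 53, 53))
  cs_grid <- build_curve_set_from_grid(g3, arr, 0L)
  cs_kern <- build_curve_set(plan, arr, k, 0L)
  # SI shifts leave the attenuation geometry invariant, so the static
  # field sampled by the grid route is exact up to interpolation error
  si_g <- cs_grid$curves[["0"]][, "SI", ]
  si_k <- cs_kern$curves[["0"]][, "SI", ]
  expect_lt(max(abs(si_g - si_k)), 0.5)
})

test_that("piecewise-linear interpolation matches a two-point oracle", {
  crv <- random_curve()
  expect_equal(interpolate_curve(crv, crv$shift_mm), crv$percent,
               tolerance = 1e-12)
  # linear segment midpoint
  lin <- make_curve(3 * build_shift_grid()$shift_mm)
  expect_equal(interpolate_curve(lin, 0.125), 0.375, tolerance = 1e-12)
  set.seed(42)
  for (i in 1:5) {
    crv <- random_curve()
    dl <- stats::runif(1000, -5, 5)
    seg <- findInterval(dl, crv$shift_mm, rightmost.closed = TRUE)
    x1 <- crv$shift_mm[seg]; x2 <- crv$shift_mm[seg + 1]
    y1 <- crv$percent[seg]; y2 <- crv$percent[seg + 1]
    oracle <- y1 + (dl - x1) * (y2 - y1) / (x2 - x1)
    expect_equal(interpolate_curve(crv, dl), oracle, tolerance = 1e-12)
  }
  expect_error(interpolate_curve(crv, 5.5), "extrapolation refused")
})

test_that("inversion honours closed forms and flags unreachable targets", {
  lin <- make_curve(4 * build_shift_grid()$shift_mm) # slope 4 %/mm
  expect_equal(invert_curve(lin, 0)$delta_mm, 0)
  r <- invert_curve(lin, 6)
  expect_true(r$solvable)
  expect_equal(r$delta_mm, 1.5, tolerance = 1e-12)
  # unreachable: slope 4 curve spans +/-20 percent
  r2 <- invert_curve(lin, 50)
  expect_false(r2$solvable)
  expect_equal(abs(r2$delta_mm), 5) # nearest value sits at the end node
  # tie between +d and -d resolves to the negative root
  sym <- make_curve(-abs(build_shift_grid()$shift_mm))
  expect_equal(invert_curve(sym, -2)$delta_mm, -2)
})

test_that("inverting a curve's own value is a right inverse", {
  cs <- study_curves()
  keys <- names(cs$curves)[1:5]
  for (kk in keys) {
    crv <- get_curve(cs, as.integer(kk), "SI")
    for (dl in c(-3, -0.75, 0.5, 2)) {
      target <- interpolate_curve(crv, dl)
      inv <- invert_curve(crv, target)
      expect_true(inv$solvable)
      expect_lt(abs(interpolate_curve(crv, inv$delta_mm) - target), 1e-9)
      expect_lte(abs(inv$delta_mm), abs(dl) + 1e-12)
    }
  }
})

test_that("inversion agrees with a 0.001 mm brute-force scan", {
  set.seed(99)
  for (i in 1:100) {
    crv <- random_curve()
    rng <- range(crv$percent)
    rpd <- stats::runif(1, rng[1] - 2, rng[2] + 2)
    got <- invert_curve(crv, rpd)
    want <- brute_invert(crv, rpd)
    expect_equal(got$solvable, want$solvable)
    expect_lt(abs(got$abs_mm - want$abs_mm), 0.002)
  }
})

test_that("the direction minimum discards flat, insensitive directions", {
  g <- build_shift_grid()$shift_mm
  flat <- make_curve(0.005 * g) # |C| < 0.03 percent everywhere
  steep <- make_curve(10 * g)
  mid <- make_curve(2 * g)
  res <- min_direction_error(list(AP = flat, SI = steep, LR = mid), 1)
  expect_identical(res$direction, "SI")
  expect_equal(res$delta_mm, 0.1, tolerance = 1e-9)
  # order invariance
  res2 <- min_direction_error(list(LR = mid, AP = flat, SI = steep), 1)
  expect_identical(res2[c("delta_mm", "direction")],
                   res[c("delta_mm", "direction")])
  # zero difference means zero error in some direction
  res0 <- min_direction_error(list(AP = flat, SI = steep, LR = mid), 0)
  expect_equal(res0$abs_mm, 0)
})

test_that("low curve sensitivity is measured and logged, not hidden", {
  cs <- study_curves()
  expect_length(cs$sensitivity, length(cs$curves))
  expect_true(all(cs$sensitivity > 0))
  # most selected diodes respond at percent-per-mm level near zero
  expect_gt(stats::median(cs$sensitivity), 1)
  # a diode in a beam's flat core violates the precondition -> logged
  expect_message(
    build_curve_set(axis_beam_plan(), tiny_array(), study_kernel(), 0L),
    "sensitivity below 1"
  )
})
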