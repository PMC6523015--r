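# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = .fx, inherits = FALSE)) {
    assign(name, builder(), envir = .fx)
  }
  get(name, envir = .fx)
}

# --- full-size study fixtures (the default QA configuration) ---------

study_array <- function() fx("array", function() build_arccheck_geometry())

study_plan <- function() {
  fx("plan", function() generate_body_path_plan(116, seed = 20190419))
}

study_kernel <- function() fx("kernel", function() cone_kernel())

study_signals <- function() {
  fx("signals", function() {
    per_beam_signals(study_plan(), study_array(), study_kernel())
  })
}

study_lut <- function() {
  fx("lut", function() {
    exclude_opposing(build_beam_diode_lut(study_signals()), study_plan(),
                     study_signals())
  })
}

study_curves <- function() {
  fx("curves", function() {
    build_curve_set(study_plan(), study_array(), study_kernel(),
                    study_lut()$table$diode)
  })
}

study_null <- function() {
  fx("null", function() {
    simulate_null_reference(study_plan(), study_array(), study_kernel(),
                            noise_model(), study_curves(), study_lut(),
                            n_seeds = 100, seed = 424242)
  })
}

# --- small fixtures for unit tests -----------------------------------

tiny_array <- function() {
  fx("tiny_array", function() build_arccheck_geometry(120, 105, 210))
}

tiny_plan <- function() {
  fx("tiny_plan", function() generate_body_path_plan(20, seed = 7))
}

# a single lateral beam whose central axis passes exactly through
# diode 0 of the tiny array (at (105, 0, -105))
axis_beam_plan <- function() {
  fx("axis_beam_plan", function() {
    arr <- tiny_array()
    p0 <- diode_position(arr, 0)
    beams <- data.frame(
      id = "B001", sx = p0[1] + 800, sy = p0[2], sz = p0[3],
      dx = -1, dy = 0, dz = 0, cone_mm = 5, mu = 50,
      stringsAsFactors = FALSE
    )
    beampathqa:::new_qa_plan(beams, "axis-beam", isocenter = c(0, p0[2], p0[3]))
  })
}

# synthetic curve set with exactly linear curves (percent = slope * mm)
# for diodes 0 and 1; handy for closed-form checks
linear_curve_set <- function(slopes = list(
                               `0` = c(AP = 2, SI = 20, LR = 5),
                               `1` = c(AP = 10, SI = 4, LR = 1))) {
  g <- build_shift_grid()
  placements <- rownames(enumerate_placements())
  curves <- lapply(slopes, function(sl) {
    cc <- array(NA_real_, dim = c(17, 3, 7),
                dimnames = list(format(g$shift_mm), g$directions,
                                placements))
    for (d in g$directions) {
      for (p in placements) cc[, d, p] <- sl[[d]] * g$shift_mm
    }
    cc
  })
  baseline <- rep(1, length(curves))
  names(baseline) <- names(curves)
  structure(
    list(shift_mm = g$shift_mm, directions = g$directions,
         placements = placements, curves = curves,
         baseline_dose = baseline,
         provenance = list(plan = "synthetic", source = "synthetic")),
    class = "curve_set"
  )
}

make_curve <- function(percent, shift_mm = build_shift_grid()$shift_mm) {
  structure(list(shift_mm = shift_mm, percent = percent),
            class = "correlation_curve")
}

# random continuous piecewise-linear curve with C(0) = 0
random_curve <- function() {
  g <- build_shift_grid()$shift_mm
  y <- cumsum(stats::rnorm(17, sd = 3))
  y <- y - y[g == 0]
  make_curve(y, g)
}

# independent brute-force inversion oracle: 0.001 mm scan of the
# piecewise-linear interpolant
brute_invert <- function(curve, rpd) {
  dg <- seq(-5, 5, by = 0.001)
  cv <- stats::approx(curve$shift_mm, curve$percent, xout = dg,
                      ties = "ordered")$y
  y <- cv - rpd
  cross <- which(y[-length(y)] * y[-1] <= 0)
  if (length(cross)) {
    # root localized to one scan step; linear refinement inside it
    y1 <- y[cross]; y2 <- y[cross + 1]
    frac <- ifelse(y2 == y1, 0, y1 / (y1 - y2))
    roots <- dg[cross] + 0.001 * frac
    return(list(abs_mm = min(abs(roots)), solvable = TRUE))
  }
  resid <- abs(y)
  cand <- dg[resid == min(resid)]
  list(abs_mm = min(abs(cand)), solvable = FALSE)
}

run_shift_campaign <- function(shift_z, seed, noise = noise_model()) {
  camp <- simulate_constancy_campaign(study_plan(), study_array(),
                                      study_kernel(), noise, seed,
                                      test_shift = c(0, 0, shift_z))
  analyze_campaign(camp, study_curves(), study_lut())
}
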