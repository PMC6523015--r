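# Synthetic delivery generator: emulates the measurement campaign
# (baseline deliveries on separate days, same-day repeats, test
# deliveries with introduced alignment shifts) under a stated noise
# budget, so the whole pipeline is testable without a machine.

#' Measurement noise model
#'
#' Multiplicative lognormal factors with small stated SDs
#' (indistinguishable from Gaussian at this scale):
#' a machine output factor per day (`output_day_sd`, default 1%) and
#' per delivery within a day (`output_delivery_sd`, default 0.5%), and
#' a per-diode response factor split into a per-day component and a
#' per-delivery component such that the total per-diode budget is
#' `diode_total_sd` (default 1%, the published diode dose-consistency
#' budget; the 0.5% linearity bound is treated as contained in that
#' budget rather than modeled as a dose-dependent bias).  Diode
#' placement errors are drawn per axis from
#' a truncated normal (SD `placement_sd_mm`, hard-bounded at
#' `placement_max_mm`), fixed once per phantom.
#'
#' @param output_day_sd day-to-day machine output SD (fraction).
#' @param output_delivery_sd within-day output SD (fraction).
#' @param diode_total_sd total per-diode response SD across days
#'   (fraction).
#' @param diode_delivery_sd per-delivery component of the diode SD
#'   (fraction); the per-day component is
#'   `sqrt(diode_total_sd^2 - diode_delivery_sd^2)`.
#' @param linearity_bound recorded diode linearity bound (fraction);
#'   informational — already folded into `diode_total_sd`.
#' @param placement_sd_mm per-axis placement error SD (mm).
#' @param placement_max_mm per-axis truncation bound (mm).
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(output_day_sd = 0.01, output_delivery_sd = 0.005,
                        diode_total_sd = 0.01,
                        diode_delivery_sd = 0.005,
                        linearity_bound = 0.005,
                        placement_sd_mm = 0.25, placement_max_mm = 0.5) {
  pars <- c(output_day_sd, output_delivery_sd, diode_total_sd,
            diode_delivery_sd, linearity_bound, placement_sd_mm,
            placement_max_mm)
  if (any(!is.finite(pars)) || any(pars < 0)) {
    vstop("all noise parameters must be finite and >= 0")
  }
  if (diode_delivery_sd > diode_total_sd) {
    vstop("diode_delivery_sd cannot exceed diode_total_sd")
  }
  structure(
    list(
      output_day_sd = output_day_sd,
      output_delivery_sd = output_delivery_sd,
      diode_total_sd = diode_total_sd,
      diode_delivery_sd = diode_delivery_sd,
      diode_day_sd = sqrt(diode_total_sd^2 - diode_delivery_sd^2),
      linearity_bound = linearity_bound,
      placement_sd_mm = placement_sd_mm,
      placement_max_mm = placement_max_mm
    ),
    class = "noise_model"
  )
}

#' All-off noise model
#'
#' @return a `noise_model` with every SD and placement error zero.
#' @export
noise_off <- function() {
  noise_model(0, 0, 0, 0, 0, 0, 0)
}

#' Truth state of a simulated campaign
#'
#' @param shift global alignment-center shift of the array (mm).
#' @param placements optional `count x 3` matrix of true per-diode
#'   placement offsets (mm).
#' @param beam_shifts optional `n_beams x 3` matrix of per-beam
#'   pointing-error translations (mm).
#' @return an object of class `truth_state`.
#' @export
truth_state <- function(shift = c(0, 0, 0), placements = NULL,
                        beam_shifts = NULL) {
  structure(
    list(shift = as_point3(shift, "shift"), placements = placements,
         beam_shifts = beam_shifts),
    class = "truth_state"
  )
}

# truncated normal per axis via inverse-CDF; exact hard bound
draw_placement_truth <- function(array, noise, seed) {
  n <- array$count
  if (noise$placement_sd_mm == 0 || noise$placement_max_mm == 0) {
    return(matrix(0, n, 3))
  }
  with_seed(seed, {
    lo <- stats::pnorm(-noise$placement_max_mm, sd = noise$placement_sd_mm)
    hi <- stats::pnorm(noise$placement_max_mm, sd = noise$placement_sd_mm)
    u <- stats::runif(3L * n, lo, hi)
    matrix(stats::qnorm(u, sd = noise$placement_sd_mm), n, 3)
  })
}

lognorm_factors <- function(n, sd) {
  if (sd == 0) rep(1, n) else exp(stats::rnorm(n, 0, sd))
}

#' Simulate one delivery
#'
#' Computes the noise-free delivery dose under the truth state (global
#' shift, true placements, per-beam pointing errors), then applies a
#' global output factor and per-diode response factors (lognormal with
#' the model's per-delivery SDs).  Day-level factors, shared by all
#' deliveries of one day, may be passed in; [simulate_constancy_campaign()]
#' manages them.  Deterministic given the seed.
#'
#' @param plan a `qa_plan`.
#' @param array a `diode_array`.
#' @param kernel a [cone_kernel()].
#' @param truth a [truth_state()].
#' @param noise a [noise_model()].
#' @param seed integer seed for the delivery-level factors.
#' @param day_factors optional list with scalar `output` and vector
#'   `diode` (length `count`) day-level factors; default all ones.
#' @param noise_free optional precomputed noise-free dose vector for
#'   this truth (performance cache).
#' @return numeric dose vector of length `array$count`.
#' @export
simulate_delivery <- function(plan, array, kernel, truth = truth_state(),
                              noise = noise_model(), seed = 1L,
                              day_factors = NULL, noise_free = NULL) {
  stopifnot(inherits(truth, "truth_state"), inherits(noise, "noise_model"))
  if (is.null(noise_free)) {
    noise_free <- compute_delivery_dose(
      plan, array, truth$placements, kernel,
      global_shift = truth$shift, beam_shifts = truth$beam_shifts
    )
  }
  f <- with_seed(seed, {
    list(out = lognorm_factors(1L, noise$output_delivery_sd),
         diode = lognorm_factors(array$count, noise$diode_delivery_sd))
  })
  day_out <- if (is.null(day_factors)) 1 else day_factors$output
  day_diode <- if (is.null(day_factors)) 1 else day_factors$diode
  noise_free * day_out * f$out * day_diode * f$diode
}

draw_day_factors <- function(array, noise, seed) {
  with_seed(seed, {
    list(output = lognorm_factors(1L, noise$output_day_sd),
         diode = lognorm_factors(array$count, noise$diode_day_sd))
  })
}

#' Simulate a full constancy-test campaign
#'
#' Emulates the physical measurement schedule: `n_baseline` deliveries
#' on separate days (baseline set), `n_sameday` consecutive deliveries
#' on one day (placement/reproducibility set), and one test delivery on
#' its own day with an introduced alignment shift.  The phantom's true
#' diode placement offsets are drawn once and shared by every delivery;
#' each day has its own output and diode day-factors.  One master seed
#' spawns all substreams; the manifest records the truth.
#'
#' @param plan a `qa_plan`.
#' @param array a `diode_array`.
#' @param kernel a [cone_kernel()].
#' @param noise a [noise_model()].
#' @param seed master integer seed.
#' @param n_baseline number of baseline deliveries (default 6).
#' @param n_sameday number of same-day repeats (default 5).
#' @param test_shift introduced alignment shift for the test delivery
#'   (mm), default none.
#' @return an object of class `campaign`: list with `baseline` (list of
#'   dose vectors), `sameday` (list), `test` (vector), `truth`
#'   (`truth_state`), and `manifest` (data frame: label, day, role,
#'   seed, shift components).
#' @export
simulate_constancy_campaign <- function(plan, array, kernel,
                                        noise = noise_model(), seed = 1L,
                                        n_baseline = 6L, n_sameday = 5L,
                                        test_shift = c(0, 0, 0)) {
  n_baseline <- as.integer(n_baseline)
  n_sameday <- as.integer(n_sameday)
  stopifnot(n_baseline >= 2L, n_sameday >= 3L)
  test_shift <- as_point3(test_shift, "test_shift")

  n_days <- n_baseline + 2L # baseline days, same-day day, test day
  n_deliv <- n_baseline + n_sameday + 1L
  seeds <- spawn_seeds(seed, 1L + n_days + n_deliv)
  placements <- draw_placement_truth(array, noise, seeds[1])
  day_seeds <- seeds[1L + seq_len(n_days)]
  del_seeds <- seeds[1L + n_days + seq_len(n_deliv)]

  truth0 <- truth_state(shift = c(0, 0, 0), placements = placements)
  truth1 <- truth_state(shift = test_shift, placements = placements)
  nf0 <- compute_delivery_dose(plan, array, placements, kernel)
  nf1 <- if (all(test_shift == 0)) {
    nf0
  } else {
    compute_delivery_dose(plan, array, placements, kernel,
                          global_shift = test_shift)
  }

  manifest <- list()
  baseline <- vector("list", n_baseline)
  for (i in seq_len(n_baseline)) {
    df <- draw_day_factors(array, noise, day_seeds[i])
    baseline[[i]] <- simulate_delivery(
      plan, array, kernel, truth0, noise, del_seeds[i],
      day_factors = df, noise_free = nf0
    )
    manifest[[length(manifest) + 1L]] <- data.frame(
      label = sprintf("baseline-%02d", i), day = i, role = "baseline",
      seed = del_seeds[i], shift_x = 0, shift_y = 0, shift_z = 0,
      stringsAsFactors = FALSE
    )
  }
  sameday <- vector("list", n_sameday)
  df_same <- draw_day_factors(array, noise, day_seeds[n_baseline + 1L])
  for (i in seq_len(n_sameday)) {
    k <- n_baseline + i
    sameday[[i]] <- simulate_delivery(
      plan, array, kernel, truth0, noise, del_seeds[k],
      day_factors = df_same, noise_free = nf0
    )
    manifest[[length(manifest) + 1L]] <- data.frame(
      label = sprintf("sameday-%02d", i), day = n_baseline + 1L,
      role = "sameday", seed = del_seeds[k],
      shift_x = 0, shift_y = 0, shift_z = 0, stringsAsFactors = FALSE
    )
  }
  df_test <- draw_day_factors(array, noise, day_seeds[n_days])
  test <- simulate_delivery(
    plan, array, kernel, truth1, noise, del_seeds[n_deliv],
    day_factors = df_test, noise_free = nf1
  )
  manifest[[length(manifest) + 1L]] <- data.frame(
    label = "test-01", day = n_days, role = "test",
    seed = del_seeds[n_deliv], shift_x = test_shift[1],
    shift_y = test_shift[2], shift_z = test_shift[3],
    stringsAsFactors = FALSE
  )

  structure(
    list(baseline = baseline, sameday = sameday, test = test,
         truth = truth1, manifest = do.call(rbind, manifest)),
    class = "campaign"
  )
}

#' Run the full analysis pipeline on a simulated campaign
#'
#' Baseline averaging, placement LUT from the same-day repeats, RPD of
#' the test delivery, and the margin position-error step.
#'
#' @param campaign a [simulate_constancy_campaign()] result.
#' @param curves a `curve_set`.
#' @param lut a `beam_diode_lut`.
#' @param margin_percent margin in percentage points (default 1).
#' @return a `position_error_report`.
#' @export
analyze_campaign <- function(campaign, curves, lut, margin_percent = 1.0) {
  stopifnot(inherits(campaign, "campaign"))
  baseline <- compute_baseline(campaign$baseline)
  plut <- build_placement_lut(campaign$sameday, curves, lut)
  rpd <- compute_rpd(campaign$test, baseline, lut)
  position_errors(rpd, curves, plut, margin_percent)
}

#' Null reference distribution for drift detection
#'
#' Simulates `n_seeds` complete no-shift campaigns under the given
#' noise model and runs the full pipeline on each, returning the
#' per-seed summary statistics.  The 95th percentile of `mean_abs_mm`
#' is the detection threshold used by [detect_systematic_shift()].
#'
#' @param plan,array,kernel,noise,curves,lut study fixtures.
#' @param n_seeds number of null simulations (default 100).
#' @param seed master seed; spawns one sub-seed per simulation.
#' @param margin_percent margin for [position_errors()].
#' @return data frame with `seed`, `mean_abs_mm`, `rms_mm`,
#'   `max_abs_mm`; attribute `mean_abs_q95`.
#' @export
simulate_null_reference <- function(plan, array, kernel,
                                    noise = noise_model(), curves, lut,
                                    n_seeds = 100L, seed = 1L,
                                    margin_percent = 1.0) {
  seeds <- spawn_seeds(seed, n_seeds)
  rows <- lapply(seeds, function(s) {
    camp <- simulate_constancy_campaign(plan, array, kernel, noise, s)
    rep <- analyze_campaign(camp, curves, lut, margin_percent)
    data.frame(seed = s, mean_abs_mm = rep$summary$mean_abs_mm,
               rms_mm = rep$summary$rms_mm,
               max_abs_mm = rep$summary$max_abs_mm)
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_abs_q95") <- stats::quantile(out$mean_abs_mm, 0.95,
                                               names = FALSE)
  out
}

#' Verify correlation curves by single-beam shift measurements
#'
#' Emulates the physical curve-verification experiment: delivery is
#' "stopped" at selected beams, a pointing shift of the robot is
#' introduced along each direction, and the matched diode's measured
#' percent dose change is compared with the prediction of the
#' single-beam correlation curve.  A robot/beam translation by `v` is
#' equivalent to an array translation by `-v`, so the curve is
#' evaluated at `-shift`.
#'
#' @param plan a `qa_plan`.
#' @param array a `diode_array`.
#' @param kernel a [cone_kernel()].
#' @param lut a `beam_diode_lut` matching beams to diodes.
#' @param beam_ids beams to verify (must be in the LUT).
#' @param shifts_mm numeric vector of introduced shifts (mm), within
#'   +/- 2 mm.
#' @param noise a [noise_model()]; default off (the comparison is then
#'   exact up to curve interpolation).
#' @param seed seed for the noisy variant.
#' @return data frame with `beam_id`, `diode`, `direction`, `shift_mm`,
#'   `measured_percent`, `predicted_percent`, `discrepancy_percent`.
#' @export
verify_curves <- function(plan, array, kernel, lut, beam_ids,
                          shifts_mm = c(-1, -0.5, 0, 0.5, 1),
                          noise = noise_off(), seed = 1L) {
  stopifnot(inherits(lut, "beam_diode_lut"))
  if (any(abs(shifts_mm) > 2)) vstop("shifts_mm must be within +/- 2 mm")
  rows <- list()
  seeds <- spawn_seeds(seed, length(beam_ids) * length(BPQ_DIRECTIONS) *
                         length(shifts_mm))
  si <- 0L
  for (bid in beam_ids) {
    r <- match(bid, lut$table$beam_id)
    if (is.na(r)) vstop("beam %s has no matched diode in the LUT", bid)
    d <- lut$table$diode[r]
    ib <- match(bid, plan$beams$id)
    sub <- plan
    sub$beams <- plan$beams[ib, , drop = FALSE]
    curves1 <- build_curve_set(sub, array, kernel, d)
    ref <- compute_delivery_dose(sub, array, NULL, kernel)[d + 1L]
    for (dir in BPQ_DIRECTIONS) {
      crv <- get_curve(curves1, d, dir)
      u <- direction_unit(dir)
      for (sh in shifts_mm) {
        si <- si + 1L
        meas_nf <- compute_delivery_dose(
          sub, array, NULL, kernel,
          beam_shifts = matrix(sh * u, 1, 3)
        )[d + 1L]
        fac <- with_seed(seeds[si], {
          lognorm_factors(1L, noise$output_delivery_sd) *
            lognorm_factors(1L, noise$diode_delivery_sd)
        })
        measured <- 100 * (meas_nf * fac - ref) / ref
        predicted <- interpolate_curve(crv, -sh)
        rows[[length(rows) + 1L]] <- data.frame(
          beam_id = bid, diode = d, direction = dir, shift_mm = sh,
          measured_percent = measured, predicted_percent = predicted,
          discrepancy_percent = abs(measured - predicted),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}
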