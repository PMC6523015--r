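# The position-error pipeline: baseline, relative-percent-difference
# (RPD) maps, placement lookup from same-day repeats, the margin step,
# summary statistics and drift detection.

as_delivery_matrix <- function(deliveries) {
  if (is.list(deliveries)) {
    lens <- vapply(deliveries, length, integer(1))
    if (length(unique(lens)) != 1L) {
      vstop("deliveries have mismatched lengths (%s)",
            paste(unique(lens), collapse = ", "))
    }
    deliveries <- do.call(rbind, lapply(deliveries, as.numeric))
  }
  if (!is.matrix(deliveries)) vstop("deliveries must be a list or matrix")
  deliveries
}

#' Average repeated deliveries into a baseline
#'
#' @param deliveries list of per-diode dose vectors (equal length) or a
#'   matrix with one delivery per row; at least 2 deliveries.
#' @return an object of class `baseline`: list with `dose` (per-diode
#'   mean), `n_deliveries`, `labels`.
#' @export
compute_baseline <- function(deliveries) {
  m <- as_delivery_matrix(deliveries)
  if (nrow(m) < 2L) vstop("a baseline needs at least 2 deliveries")
  structure(
    list(dose = colMeans(m), n_deliveries = nrow(m),
         labels = rownames(m)),
    class = "baseline"
  )
}

#' Relative percent difference of a measurement against the baseline
#'
#' `RPD = 100 * (M - B) / B` per selected diode, where `M` is the
#' measured dose and `B` the baseline mean.  Diodes whose baseline is
#' not positive are dropped with a warning.
#'
#' @param measurement per-diode dose vector.
#' @param baseline a [compute_baseline()] result (or per-diode vector).
#' @param lut a `beam_diode_lut` restricting the map to selected
#'   diodes; `NULL` keeps all diodes.
#' @return an object of class `rpd_map`: named numeric vector of
#'   percent differences (names = 0-based diode indices), with
#'   attribute `beam_id` when a LUT is supplied.
#' @export
compute_rpd <- function(measurement, baseline, lut = NULL) {
  b <- if (inherits(baseline, "baseline")) baseline$dose else as.numeric(baseline)
  m <- as.numeric(measurement)
  if (length(m) != length(b)) {
    vstop("measurement (%d) and baseline (%d) lengths differ",
          length(m), length(b))
  }
  if (is.null(lut)) {
    idx <- seq_along(b) - 1L
    beam <- rep(NA_character_, length(idx))
  } else {
    stopifnot(inherits(lut, "beam_diode_lut"))
    idx <- lut$table$diode
    beam <- lut$table$beam_id
  }
  ok <- b[idx + 1L] > 0
  if (any(!ok)) {
    vwarn("%d diode(s) dropped from RPD map: non-positive baseline",
          sum(!ok))
  }
  idx <- idx[ok]
  beam <- beam[ok]
  rpd <- 100 * (m[idx + 1L] - b[idx + 1L]) / b[idx + 1L]
  names(rpd) <- as.character(idx)
  structure(rpd, beam_id = beam, class = "rpd_map")
}

curves3_for <- function(curveset, diode, placement) {
  out <- lapply(BPQ_DIRECTIONS, function(d) {
    get_curve(curveset, diode, d, placement)
  })
  names(out) <- BPQ_DIRECTIONS
  out
}

# per-diode percent scatter of same-day repeats: 100 * SD / mean
sameday_scatter <- function(deliveries) {
  m <- as_delivery_matrix(deliveries)
  if (nrow(m) < 3L) {
    vstop("same-day placement analysis needs at least 3 deliveries")
  }
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd) # sample SD (n-1 denominator)
  list(mean = mu, s_percent = ifelse(mu > 0, 100 * sdv / mu, NA_real_))
}

#' Choose a placement hypothesis per diode from same-day repeats
#'
#' For each selected diode, computes the percent scatter
#' `s = 100 * SD / mean` over the same-day repeat deliveries (sample
#' SD), inverts the three-direction minimum position error under each
#' of the 7 placement hypotheses at `rpd = s`, and records the
#' placement giving the smallest absolute error (ties -> nominal).
#' Under the assumption that consecutive same-setup deliveries are
#' highly reproducible, this absorbs part of the diode placement
#' uncertainty into the curve choice.
#'
#' @param same_day_deliveries list/matrix of >= 3 same-day dose
#'   vectors.
#' @param curves a `curve_set` containing all 7 placements.
#' @param lut a `beam_diode_lut`.
#' @return an object of class `placement_lut`: data frame with `diode`,
#'   `placement`, `s_percent`, `delta_mm`.
#' @export
build_placement_lut <- function(same_day_deliveries, curves, lut) {
  stopifnot(inherits(curves, "curve_set"), inherits(lut, "beam_diode_lut"))
  sc <- sameday_scatter(same_day_deliveries)
  rows <- lapply(lut$table$diode, function(d) {
    mu <- sc$mean[d + 1L]
    if (!is.finite(mu) || mu <= 0) {
      vwarn("diode %d dropped from placement LUT: zero mean dose", d)
      return(NULL)
    }
    if (is.null(curves$curves[[as.character(d)]])) {
      vwarn("diode %d dropped from placement LUT: no curves", d)
      return(NULL)
    }
    s <- sc$s_percent[d + 1L]
    res <- lapply(curves$placements, function(p) {
      min_direction_error(curves3_for(curves, d, p), s)
    })
    a <- vapply(res, `[[`, numeric(1), "abs_mm")
    best <- which(a == min(a))
    # ties -> nominal if it participates, else first in canonical order
    pick <- if (1L %in% best) 1L else best[1]
    data.frame(diode = d, placement = curves$placements[pick],
               s_percent = s, delta_mm = res[[pick]]$delta_mm,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  structure(list(table = tab), class = "placement_lut")
}

#' @export
print.placement_lut <- function(x, ...) {
  cat(sprintf("<placement_lut> %d diodes (%d non-nominal)\n",
              nrow(x$table), sum(x$table$placement != "nominal")))
  invisible(x)
}

placement_for <- function(placement_lut, diode) {
  if (is.null(placement_lut)) return("nominal")
  i <- match(diode, placement_lut$table$diode)
  if (is.na(i)) "nominal" else placement_lut$table$placement[i]
}

new_report <- function(per_diode, tolerance_mm = 0.5) {
  d <- per_diode$delta_mm
  summary <- list(
    n = length(d),
    mean_abs_mm = mean(abs(d)),
    sd_abs_mm = stats::sd(abs(d)),
    rms_mm = sqrt(mean(d^2)),
    max_abs_mm = max(abs(d)),
    n_unsolvable = sum(!per_diode$solvable),
    tolerance_mm = tolerance_mm,
    within_tolerance = sqrt(mean(d^2)) <= tolerance_mm
  )
  structure(list(per_diode = per_diode, summary = summary),
            class = "position_error_report")
}

#' @export
print.position_error_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0(
      "<position_error_report> %d diodes\n",
      "  mean |delta| %.3f mm (SD %.3f), RMS %.3f mm, max %.3f mm\n",
      "  %d unsolvable inversion(s); RMS tolerance %.1f mm: %s\n"
    ),
    s$n, s$mean_abs_mm, s$sd_abs_mm, s$rms_mm, s$max_abs_mm,
    s$n_unsolvable, s$tolerance_mm,
    if (s$within_tolerance) "PASS" else "OUT OF TOLERANCE"
  ))
  invisible(x)
}

#' Position errors from an RPD map with the uncertainty margin
#'
#' The final estimation step: for every selected diode, the measured
#' RPD is evaluated under three branches — `RPD - margin`, `RPD`,
#' `RPD + margin` (margin 1 percentage point by default, covering diode
#' dose consistency/linearity and daily output constancy) — each
#' inverted through the three-direction minimum at the diode's chosen
#' placement; the branch of smallest absolute shift wins (ties prefer
#' the unmargined branch).  The joint minimum over direction x branch
#' is reported per diode together with mean/SD/RMS/max summaries and
#' the 0.5 mm RMS tolerance verdict.
#'
#' @param rpd_map a [compute_rpd()] result.
#' @param curves a `curve_set`.
#' @param placement_lut a [build_placement_lut()] result, or `NULL` for
#'   nominal placements.
#' @param margin_percent margin in percentage points (>= 0, default 1).
#' @param tolerance_mm RMS action threshold, mm (default 0.5).
#' @return a `position_error_report`: list with data frame `per_diode`
#'   (`diode`, `beam_id`, `rpd_percent`, `branch` in -1/0/+1,
#'   `direction`, `placement`, `delta_mm`, `abs_mm`, `solvable`) and
#'   `summary`.
#' @export
position_errors <- function(rpd_map, curves, placement_lut = NULL,
                            margin_percent = 1.0, tolerance_mm = 0.5) {
  stopifnot(inherits(curves, "curve_set"))
  if (!is.finite(margin_percent) || margin_percent < 0) {
    vstop("margin_percent must be >= 0")
  }
  diodes <- as.integer(names(rpd_map))
  beams <- attr(rpd_map, "beam_id")
  branches <- if (margin_percent > 0) c(0, -1, 1) else 0
  rows <- lapply(seq_along(diodes), function(i) {
    d <- diodes[i]
    if (is.null(curves$curves[[as.character(d)]])) {
      vwarn("diode %d skipped: not present in curve set", d)
      return(NULL)
    }
    p <- placement_for(placement_lut, d)
    c3 <- curves3_for(curves, d, p)
    res <- lapply(branches, function(br) {
      min_direction_error(c3, rpd_map[[i]] + br * margin_percent)
    })
    a <- vapply(res, `[[`, numeric(1), "abs_mm")
    pick <- which.min(a) # first minimum: branch order (0, -1, +1)
    data.frame(
      diode = d, beam_id = if (is.null(beams)) NA_character_ else beams[i],
      rpd_percent = rpd_map[[i]], branch = branches[pick],
      direction = res[[pick]]$direction, placement = p,
      delta_mm = res[[pick]]$delta_mm, abs_mm = res[[pick]]$abs_mm,
      solvable = res[[pick]]$solvable, stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(tab) || nrow(tab) == 0L) vstop("no diodes could be analyzed")
  rownames(tab) <- NULL
  new_report(tab, tolerance_mm)
}

#' Reproducibility position errors from same-day repeats
#'
#' Converts the same-day percent scatter `s` of each selected diode
#' into a position error by inverting `k * s` (k = 1 or 2, the 1-SD and
#' 2-SD analyses) through the three-direction minimum at the chosen
#' placement.  Summarizes as in [position_errors()].
#'
#' @param same_day_deliveries list/matrix of >= 3 same-day dose vectors.
#' @param curves a `curve_set`.
#' @param placement_lut placement choices (or `NULL` for nominal).
#' @param lut a `beam_diode_lut`.
#' @param k SD multiplier, 1 or 2.
#' @param tolerance_mm RMS action threshold, mm.
#' @return a `position_error_report`.
#' @export
reproducibility_errors <- function(same_day_deliveries, curves,
                                   placement_lut = NULL, lut, k = 1,
                                   tolerance_mm = 0.5) {
  stopifnot(k %in% c(1, 2), inherits(lut, "beam_diode_lut"))
  sc <- sameday_scatter(same_day_deliveries)
  idx <- lut$table$diode
  ok <- is.finite(sc$s_percent[idx + 1L]) & sc$mean[idx + 1L] > 0
  if (any(!ok)) vwarn("%d diode(s) dropped: zero mean dose", sum(!ok))
  idx <- idx[ok]
  rpd <- k * sc$s_percent[idx + 1L]
  names(rpd) <- as.character(idx)
  attr(rpd, "beam_id") <- lut$table$beam_id[ok]
  class(rpd) <- "rpd_map"
  position_errors(rpd, curves, placement_lut, margin_percent = 0,
                  tolerance_mm = tolerance_mm)
}

#' Systematic-drift verdict for a constancy report
#'
#' Declares a drift "detected" when the report's mean absolute position
#' error exceeds the 95th percentile of the null distribution (mean
#' absolute errors from no-shift simulations) OR the report RMS exceeds
#' the clinical tolerance.  Both criteria and thresholds are recorded
#' in the verdict.
#'
#' @param report a `position_error_report`.
#' @param null_reference numeric vector of null-simulation mean
#'   absolute errors (>= 20 values recommended; typically 100 seeds),
#'   or a list with element `mean_abs_q95`.
#' @param rms_tolerance_mm RMS criterion, mm (default 0.5).
#' @return list with `detected`, `mean_abs_mm`, `null_q95_mm`,
#'   `by_mean`, `rms_mm`, `rms_tolerance_mm`, `by_rms`.
#' @export
detect_systematic_shift <- function(report, null_reference,
                                    rms_tolerance_mm = 0.5) {
  stopifnot(inherits(report, "position_error_report"))
  if (missing(null_reference) || is.null(null_reference)) {
    vstop(paste0("null_reference is required: run simulate_null_reference()",
                 " (CLI: `simulate null`) to build it"))
  }
  q95 <- if (is.list(null_reference)) {
    null_reference$mean_abs_q95
  } else {
    stats::quantile(as.numeric(null_reference), 0.95, names = FALSE,
                    type = 7)
  }
  by_mean <- is.finite(q95) && report$summary$mean_abs_mm > q95
  by_rms <- report$summary$rms_mm > rms_tolerance_mm
  list(
    detected = by_mean || by_rms,
    mean_abs_mm = report$summary$mean_abs_mm, null_q95_mm = q95,
    by_mean = by_mean, rms_mm = report$summary$rms_mm,
    rms_tolerance_mm = rms_tolerance_mm, by_rms = by_rms
  )
}
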