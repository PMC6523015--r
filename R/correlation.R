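# Correlation curves: per-diode sampled functions C(delta) of percent
# dose change versus a rigid phantom shift delta along one clinical
# direction, for each of the 7 placement hypotheses; and their
# piecewise-linear interpolation and inversion back to a shift.

#' The canonical shift grid
#'
#' Shifts from -5 to +5 mm with 0.25 mm spacing inside [-1, 1] mm and
#' 1 mm spacing outside — 17 values per direction, shared by the three
#' clinical directions AP, SI and LR.  Because the zero shift is common
#' to all directions, sampling the grid requires
#' `3 * 16 + 1 = 49` distinct dose calculations.
#'
#' @return an object of class `shift_grid`: list with `shift_mm`
#'   (length 17), `directions` (`c("AP","SI","LR")`), and
#'   `n_dose_calculations` (49).
#' @export
build_shift_grid <- function() {
  s <- c(-5, -4, -3, -2, -1, -0.75, -0.5, -0.25, 0,
         0.25, 0.5, 0.75, 1, 2, 3, 4, 5)
  structure(
    list(
      shift_mm = s,
      directions = BPQ_DIRECTIONS,
      n_dose_calculations = length(BPQ_DIRECTIONS) * (length(s) - 1L) + 1L
    ),
    class = "shift_grid"
  )
}

#' @export
print.shift_grid <- function(x, ...) {
  cat(sprintf(
    "<shift_grid> %d shifts per direction x %d directions (%d dose calculations)\n",
    length(x$shift_mm), length(x$directions), x$n_dose_calculations
  ))
  invisible(x)
}

new_curve <- function(shift_mm, percent, diode = NA_integer_,
                      direction = NA_character_,
                      placement = NA_character_) {
  structure(
    list(shift_mm = shift_mm, percent = as.numeric(percent),
         diode = diode, direction = direction, placement = placement),
    class = "correlation_curve"
  )
}

#' Build the correlation-curve set for selected diodes
#'
#' For every requested diode, every direction (AP/SI/LR) and every one
#' of the 7 placement hypotheses, evaluates the noise-free full-plan
#' dose `D(delta)` with the whole array rigidly shifted by `delta`
#' along the direction (diode evaluated at nominal + placement +
#' shift), and stores the percent change
#' `C(delta) = 100 * (D(delta) - D(0)) / D(0)` on the shift grid.
#' Exactly 21 curves (3 directions x 7 placements) result per diode.
#' Diodes with zero baseline dose under the nominal placement are
#' skipped with a warning.
#'
#' Curves are ratios, so they are invariant to rescaling all beam MUs,
#' and the build is fully deterministic.
#'
#' @param plan a `qa_plan`.
#' @param array a `diode_array`.
#' @param kernel a [cone_kernel()].
#' @param diodes integer vector of 0-based diode indices (non-empty).
#' @param grid a [build_shift_grid()] result.
#' @return an object of class `curve_set`: list with `shift_mm`,
#'   `directions`, `placements`, `curves` (named list, one
#'   `17 x 3 x 7` array per diode, dimnames shift/direction/placement),
#'   `baseline_dose` (named numeric, D(0) per diode at nominal
#'   placement) and `provenance`.
#' @export
build_curve_set <- function(plan, array, kernel, diodes,
                            grid = build_shift_grid()) {
  stopifnot(inherits(plan, "qa_plan"), inherits(array, "diode_array"),
            inherits(grid, "shift_grid"))
  diodes <- unique(check_diode_index(array, diodes))
  if (length(diodes) == 0L) vstop("diodes must be non-empty")

  s <- grid$shift_mm
  ns <- length(s)
  dirs <- grid$directions
  plc <- enumerate_placements()
  npl <- nrow(plc)
  ndi <- length(diodes)

  # evaluate per (direction, shift): the whole phantom — diodes and the
  # attenuating cylinder — translates rigidly by the shift, so each
  # shift vector has its own cylinder center
  base_pts <- array$positions[diodes + 1L, , drop = FALSE]
  plc_idx <- rep(seq_len(npl), each = ndi)
  pts0 <- base_pts[rep(seq_len(ndi), npl), , drop = FALSE] +
    plc[plc_idx, , drop = FALSE] # (diode x placement) rows
  dd <- array(NA_real_, dim = c(ns, length(dirs), npl, ndi))
  for (j in seq_along(dirs)) {
    u <- direction_unit(dirs[j])
    for (si in seq_len(ns)) {
      g <- s[si] * u
      dose <- colSums(beam_dose_matrix(plan, sweep(pts0, 2, g, `+`),
                                       kernel, cyl_center = g[1:2]))
      dd[si, j, , ] <- t(matrix(dose, nrow = ndi))
    }
  }

  i0 <- which(s == 0)
  curves <- vector("list", ndi)
  names(curves) <- as.character(diodes)
  baseline <- numeric(ndi)
  names(baseline) <- as.character(diodes)
  keep <- logical(ndi)
  for (k in seq_len(ndi)) {
    d0 <- dd[i0, 1, 1, k] # nominal placement, zero shift
    baseline[k] <- d0
    if (!is.finite(d0) || d0 <= 0) {
      vwarn("diode %d skipped: zero dose under nominal placement",
            diodes[k])
      next
    }
    cc <- array(NA_real_, dim = c(ns, length(dirs), npl),
                dimnames = list(format(s), dirs, rownames(plc)))
    for (p in seq_len(npl)) {
      dp0 <- dd[i0, 1, p, k] # this placement's own zero-shift dose
      if (!is.finite(dp0) || dp0 <= 0) {
        vwarn("diode %d placement %s skipped: zero baseline dose",
              diodes[k], rownames(plc)[p])
        next
      }
      for (j in seq_along(dirs)) {
        cc[, j, p] <- 100 * (dd[, j, p, k] - dp0) / dp0
      }
    }
    curves[[k]] <- cc
    keep[k] <- TRUE
  }
  curves <- curves[keep]
  # sensitivity precondition: each diode should respond to sub-mm
  # shifts in at least one direction (>= 1 percent per mm near zero);
  # violations are logged, not removed
  i1 <- which(s == -0.25)
  i2 <- which(s == 0.25)
  sensitivity <- vapply(curves, function(cc) {
    max(abs(cc[i2, , "nominal"] - cc[i1, , "nominal"]) / 0.5)
  }, numeric(1))
  low <- names(sensitivity)[sensitivity < 1]
  if (length(low)) {
    message(sprintf(
      "curve sensitivity below 1 %%/mm near zero for diode(s): %s",
      paste(low, collapse = ", ")
    ))
  }
  structure(
    list(
      shift_mm = s, directions = dirs, placements = rownames(plc),
      curves = curves, baseline_dose = baseline[keep],
      sensitivity = sensitivity,
      provenance = list(plan = plan$label, source = "kernel")
    ),
    class = "curve_set"
  )
}

#' Build correlation curves by sampling a static dose grid
#'
#' Like [build_curve_set()] but takes doses from a rasterized 3D dose
#' grid instead of direct kernel evaluation: a rigid array shift by
#' `delta` is realized by sampling the static dose field at the
#' shifted diode position (the workflow of extracting shifted diode
#' doses from one exported dose distribution).  This static-field view
#' is exact for shifts along the phantom axis (SI), where the
#' attenuation geometry is invariant; for lateral (AP/LR) shifts it
#' omits the small change of the intra-phantom path length that the
#' kernel route includes.  Used to cross-check the kernel path against
#' the grid-sampling path.
#'
#' @param grid3d a `dose_grid` covering all shifted diode positions.
#' @param array a `diode_array`.
#' @param diodes diode indices (0-based).
#' @param grid a [build_shift_grid()].
#' @return a `curve_set` (provenance source `"grid"`).
#' @export
build_curve_set_from_grid <- function(grid3d, array, diodes,
                                      grid = build_shift_grid()) {
  stopifnot(inherits(grid3d, "dose_grid"), inherits(array, "diode_array"))
  diodes <- unique(check_diode_index(array, diodes))
  s <- grid$shift_mm
  ns <- length(s)
  dirs <- grid$directions
  plc <- enumerate_placements()
  npl <- nrow(plc)
  ndi <- length(diodes)
  base_pts <- array$positions[diodes + 1L, , drop = FALSE]
  dir_units <- t(vapply(dirs, direction_unit, numeric(3)))
  combos <- expand.grid(si = seq_len(ns), di = seq_along(dirs),
                        pi = seq_len(npl), ki = seq_len(ndi),
                        KEEP.OUT.ATTRS = FALSE)
  pts <- base_pts[combos$ki, , drop = FALSE] +
    plc[combos$pi, , drop = FALSE] +
    dir_units[combos$di, , drop = FALSE] * s[combos$si]
  dose <- sample_dose_grid(grid3d, pts)
  dd <- array(dose, dim = c(ns, length(dirs), npl, ndi))
  i0 <- which(s == 0)
  curves <- vector("list", ndi)
  names(curves) <- as.character(diodes)
  baseline <- numeric(ndi)
  names(baseline) <- as.character(diodes)
  keep <- logical(ndi)
  for (k in seq_len(ndi)) {
    d0 <- dd[i0, 1, 1, k]
    baseline[k] <- d0
    if (!is.finite(d0) || d0 <= 0) {
      vwarn("diode %d skipped: zero dose at nominal position", diodes[k])
      next
    }
    cc <- array(NA_real_, dim = c(ns, length(dirs), npl),
                dimnames = list(format(s), dirs, rownames(plc)))
    for (p in seq_len(npl)) {
      dp0 <- dd[i0, 1, p, k]
      if (!is.finite(dp0) || dp0 <= 0) next
      for (j in seq_along(dirs)) {
        cc[, j, p] <- 100 * (dd[, j, p, k] - dp0) / dp0
      }
    }
    curves[[k]] <- cc
    keep[k] <- TRUE
  }
  structure(
    list(shift_mm = s, directions = dirs, placements = rownames(plc),
         curves = curves[keep], baseline_dose = baseline[keep],
         provenance = list(plan = NA_character_, source = "grid")),
    class = "curve_set"
  )
}

#' Extract one correlation curve from a curve set
#'
#' @param curveset a `curve_set`.
#' @param diode diode index (0-based).
#' @param direction `"AP"`, `"SI"` or `"LR"`.
#' @param placement placement label, default `"nominal"`.
#' @return a `correlation_curve` (list with `shift_mm`, `percent`).
#' @export
get_curve <- function(curveset, diode, direction, placement = "nominal") {
  stopifnot(inherits(curveset, "curve_set"))
  key <- as.character(as.integer(diode))
  cc <- curveset$curves[[key]]
  if (is.null(cc)) vstop("diode %s not in curve set", key)
  direction <- match.arg(direction, curveset$directions)
  placement <- match.arg(placement, curveset$placements)
  new_curve(curveset$shift_mm, cc[, direction, placement],
            diode = as.integer(diode), direction = direction,
            placement = placement)
}

#' Piecewise-linear interpolation of a correlation curve
#'
#' @param curve a `correlation_curve` (or any list with `shift_mm` and
#'   `percent`).
#' @param delta shift(s) in mm, each within the curve's range
#'   (`[-5, 5]` for the canonical grid); extrapolation is refused.
#' @return interpolated percent value(s).
#' @export
interpolate_curve <- function(curve, delta) {
  s <- curve$shift_mm
  if (any(delta < min(s) - 1e-12 | delta > max(s) + 1e-12)) {
    vstop("delta outside the curve range [%g, %g]; extrapolation refused",
          min(s), max(s))
  }
  stats::approx(s, curve$percent, xout = pmin(pmax(delta, min(s)), max(s)),
                method = "linear", ties = "ordered")$y
}

#' Invert a correlation curve at a measured percent difference
#'
#' Finds all roots of `C(delta) = rpd` on the piecewise-linear
#' interpolant of the sampled curve and returns the root of smallest
#' absolute value (ties broken toward the negative root).  If no root
#' exists, returns the grid shift minimizing `|C(delta) - rpd|` and
#' flags the result unsolvable.
#'
#' @param curve a `correlation_curve`.
#' @param rpd_percent measured relative percent difference.
#' @return list with `delta_mm` (signed), `abs_mm`, `solvable`
#'   (logical), and `residual_percent` (`|C(delta) - rpd|`, 0 when
#'   solvable).
#' @export
invert_curve <- function(curve, rpd_percent) {
  s <- curve$shift_mm
  y <- curve$percent - rpd_percent
  n <- length(s)
  roots <- s[y == 0] # exact node roots
  y1 <- y[-n]; y2 <- y[-1]
  cross <- which(y1 * y2 < 0)
  if (length(cross)) {
    roots <- c(roots, s[cross] + (0 - y1[cross]) *
                 (s[cross + 1] - s[cross]) / (y2[cross] - y1[cross]))
  }
  # segments lying entirely on the target value: every point is a root;
  # the minimal-|delta| representative is the endpoint nearer zero (or
  # zero itself if the segment straddles it)
  flat <- which(y1 == 0 & y2 == 0)
  if (length(flat)) {
    roots <- c(roots, ifelse(s[flat] <= 0 & s[flat + 1] >= 0, 0,
                             ifelse(abs(s[flat]) < abs(s[flat + 1]),
                                    s[flat], s[flat + 1])))
  }
  if (length(roots)) {
    a <- abs(roots)
    best <- roots[a == min(a)]
    delta <- if (length(best) > 1L) min(best) else best
    return(list(delta_mm = delta, abs_mm = abs(delta), solvable = TRUE,
                residual_percent = 0))
  }
  # no root: |linear - rpd| on each segment is minimized at a node
  resid <- abs(y)
  best <- which(resid == min(resid))
  sb <- s[best]
  a <- abs(sb)
  cand <- sb[a == min(a)]
  delta <- if (length(cand) > 1L) min(cand) else cand
  list(delta_mm = delta, abs_mm = abs(delta), solvable = FALSE,
       residual_percent = min(resid))
}

#' Minimum position error over the three directions
#'
#' Inverts the AP, SI and LR curves of one diode (at one placement
#' hypothesis) against the same measured percent difference and returns
#' the direction achieving the smallest absolute shift.  Directions
#' whose curves have no root participate with their flagged nearest
#' minimizer; since flat (insensitive) directions then yield large
#' shifts, the minimum naturally discards them.  Ties are broken by the
#' more negative signed shift, then alphabetically by direction, so the
#' result is invariant to the order of the input curves.
#'
#' @param curves3 named list of three `correlation_curve`s with names
#'   `AP`, `SI`, `LR` (any order).
#' @param rpd_percent measured relative percent difference.
#' @return list with `delta_mm`, `abs_mm`, `direction`, `solvable`.
#' @export
min_direction_error <- function(curves3, rpd_percent) {
  if (!setequal(names(curves3), BPQ_DIRECTIONS)) {
    vstop("curves3 must be named AP, SI, LR")
  }
  inv <- lapply(BPQ_DIRECTIONS, function(d) invert_curve(curves3[[d]],
                                                         rpd_percent))
  names(inv) <- BPQ_DIRECTIONS
  a <- vapply(inv, `[[`, numeric(1), "abs_mm")
  dl <- vapply(inv, `[[`, numeric(1), "delta_mm")
  ties <- which(a == min(a))
  if (length(ties) > 1L) {
    ties <- ties[dl[ties] == min(dl[ties])]
    ties <- ties[order(names(ties))]
  }
  pick <- ties[1]
  list(delta_mm = dl[[pick]], abs_mm = a[[pick]],
       direction = BPQ_DIRECTIONS[pick], solvable = inv[[pick]]$solvable)
}
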