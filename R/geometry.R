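# Surrogate geometry of the cylindrical diode array and the shared
# patient coordinate frame.
#
# Frame convention (used everywhere in the package): LR along +x (toward
# patient left), AP along +y (toward anterior), SI along +z (toward
# superior); right-handed; origin at the array's geometric (alignment)
# center; all lengths in mm.

#' Build the helical diode-array geometry
#'
#' Constructs a surrogate model of a cylindrical diode-array QA phantom:
#' `count` diodes on a single-start helix wrapped on a cylinder of the
#' given radius and length.  Diode `k` (0-based) sits at axial coordinate
#' `z_k = -length/2 + k * length/(count-1)` and helix angle
#' `theta_k = k * dtheta`, with `dtheta` chosen so that the spacing
#' between consecutive diodes along the helix is approximately
#' `spacing_mm` (10 mm by default, the array's nominal detector pitch).
#' The defaults reproduce the commercial array's published envelope:
#' 1386 diodes on a 21 cm diameter x 21 cm long shell.
#'
#' The vendor's exact layout is proprietary; this surrogate preserves
#' the quantities the constancy method depends on (diode count,
#' cylindrical shell, ~1 cm resolution) without claiming hardware
#' fidelity.  Construction is fully deterministic.
#'
#' @param count number of diodes (>= 2).
#' @param radius_mm cylinder radius in mm.
#' @param length_mm cylinder length in mm.
#' @param spacing_mm target nearest-neighbour spacing along the helix, mm.
#' @return An object of class `diode_array`: list with `count`,
#'   `radius_mm`, `length_mm`, integer vector `index` (0-based), numeric
#'   vectors `theta` (rad) and a `count x 3` matrix `positions` with
#'   columns `x`, `y`, `z` (mm).
#' @export
#' @examples
#' arr <- build_arccheck_geometry()
#' arr$count
build_arccheck_geometry <- function(count = 1386L, radius_mm = 105,
                                    length_mm = 210, spacing_mm = 10) {
  count <- as.integer(count)
  if (is.na(count) || count < 2L) vstop("count must be an integer >= 2")
  if (!is.finite(radius_mm) || radius_mm <= 0) {
    vstop("radius_mm must be > 0 (got %s)", format(radius_mm))
  }
  if (!is.finite(length_mm) || length_mm <= 0) {
    vstop("length_mm must be > 0 (got %s)", format(length_mm))
  }
  if (!is.finite(spacing_mm) || spacing_mm <= 0) {
    vstop("spacing_mm must be > 0")
  }
  k <- seq_len(count) - 1L
  dz <- length_mm / (count - 1L)
  # degenerate case (very few diodes): the axial step alone exceeds the
  # target spacing, so the "helix" collapses to a straight axial line
  dtheta <- if (spacing_mm <= dz) 0 else {
    sqrt(spacing_mm^2 - dz^2) / radius_mm
  }
  theta <- k * dtheta
  z <- -length_mm / 2 + k * dz
  positions <- cbind(
    x = radius_mm * cos(theta),
    y = radius_mm * sin(theta),
    z = z
  )
  structure(
    list(
      count = count, radius_mm = radius_mm, length_mm = length_mm,
      spacing_mm = spacing_mm, index = as.integer(k), theta = theta,
      positions = positions
    ),
    class = "diode_array"
  )
}

#' @export
print.diode_array <- function(x, ...) {
  cat(sprintf(
    "<diode_array> %d diodes on a %.0f mm radius x %.0f mm cylinder (helix)\n",
    x$count, x$radius_mm, x$length_mm
  ))
  invisible(x)
}

check_diode_index <- function(array, index) {
  index <- as.integer(index)
  if (any(is.na(index)) || any(index < 0L) || any(index >= array$count)) {
    vstop(
      "unknown diode index %s (array has indices 0..%d)",
      paste(index[is.na(index) | index < 0L | index >= array$count],
        collapse = ", "
      ), array$count - 1L
    )
  }
  index
}

#' Enumerate the placement hypotheses for a diode
#'
#' Each diode's true position is known only to within the array's stated
#' 0.5 mm placement accuracy.  The method therefore carries seven
#' placement hypotheses per diode: the nominal lattice position plus a
#' 0.5 mm offset along each signed axis.
#'
#' @param index diode index (0-based); recorded in the result attribute.
#' @return A `7 x 3` numeric matrix of offset vectors (mm) with rows
#'   named `"nominal"`, `"+x"`, `"-x"`, `"+y"`, `"-y"`, `"+z"`, `"-z"`
#'   (in that stable order) and attribute `diode` = `index`.
#' @export
enumerate_placements <- function(index = 0L) {
  off <- rbind(
    nominal = c(0, 0, 0),
    `+x` = c(0.5, 0, 0), `-x` = c(-0.5, 0, 0),
    `+y` = c(0, 0.5, 0), `-y` = c(0, -0.5, 0),
    `+z` = c(0, 0, 0.5), `-z` = c(0, 0, -0.5)
  )
  colnames(off) <- c("x", "y", "z")
  attr(off, "diode") <- as.integer(index)
  off
}

placement_offset <- function(placement) {
  if (is.character(placement)) {
    placement <- match.arg(placement, BPQ_PLACEMENTS)
    return(enumerate_placements()[placement, ])
  }
  as_point3(placement, "placement offset")
}

#' Position of a diode under a placement hypothesis
#'
#' @param array a `diode_array`.
#' @param index diode index (0-based).
#' @param placement a placement label (see [enumerate_placements()]) or a
#'   numeric length-3 offset vector in mm.  Default `"nominal"`.
#' @return numeric length-3 point (mm).
#' @export
diode_position <- function(array, index, placement = "nominal") {
  stopifnot(inherits(array, "diode_array"))
  index <- check_diode_index(array, index)
  array$positions[index + 1L, ] + placement_offset(placement)
}

#' Serialize / deserialize a diode array to JSON
#'
#' Positions are written to 6 decimal places; `geometry_from_json`
#' restores an equivalent `diode_array` object.
#'
#' @param array a `diode_array`.
#' @param path output / input file path.
#' @return `geometry_to_json` returns `path` invisibly;
#'   `geometry_from_json` returns a `diode_array`.
#' @export
geometry_to_json <- function(array, path) {
  stopifnot(inherits(array, "diode_array"))
  obj <- list(
    format = "bpq-geometry", version = 1L,
    count = array$count, radius_mm = array$radius_mm,
    length_mm = array$length_mm, spacing_mm = array$spacing_mm,
    x = as.numeric(fmt_num(array$positions[, "x"])),
    y = as.numeric(fmt_num(array$positions[, "y"])),
    z = as.numeric(fmt_num(array$positions[, "z"]))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname geometry_to_json
#' @export
geometry_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "bpq-geometry")) {
    vstop("%s is not a bpq-geometry file", path)
  }
  arr <- build_arccheck_geometry(
    obj$count, obj$radius_mm, obj$length_mm,
    spacing_mm = obj$spacing_mm
  )
  # stored positions are authoritative (6-decimal rounding)
  arr$positions <- cbind(x = obj$x, y = obj$y, z = obj$z)
  arr
}
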