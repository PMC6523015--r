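# Parametric small-cone dose kernel.
#
# Stands in for the treatment planning system so that correlation
# curves and simulated measurements share one forward model.  The form
# — flat core + Gaussian penumbra, inverse-square, exponential
# attenuation along the intra-phantom chord — is the simplest model
# with the one property the constancy method needs: steep, smooth dose
# gradients at the edge of a 5 mm cone, so sub-mm shifts produce
# percent-level dose changes.

#' Construct a small-cone dose kernel
#'
#' Dose at point P from a beam with source S, unit direction u and
#' monitor units MU is
#' `MU * rate * (ref/d)^2 * P(r * ref/d) * exp(-mu_mm * t)`, where
#' `d = |P - S|`, `r` is the perpendicular distance of P from the beam
#' central axis, `P(rho)` is a radial profile equal to 1 inside the
#' flat core (radius `cone_mm/2` at the 800 mm reference distance) and
#' falling off as a Gaussian with `sigma_mm` beyond it, and `t` is the
#' chord length of the source-to-point ray inside the phantom cylinder
#' before reaching the point.  Points behind the source get zero dose.
#'
#' @param rate reference dose rate on axis at `ref_mm`, relative units
#'   per MU.
#' @param core_mm default flat-core radius at `ref_mm` (mm); used when a
#'   beam does not carry its own cone size.
#' @param sigma_mm penumbra Gaussian sigma at `ref_mm` (mm); the default
#'   0.8 mm gives roughly a 2 mm 80-20 penumbra, typical of a 5 mm cone.
#' @param mu_mm effective linear attenuation coefficient in the phantom
#'   (1/mm).
#' @param ref_mm inverse-square and cone-definition reference distance
#'   (mm).
#' @param phantom_radius_mm radius of the attenuating phantom cylinder
#'   (mm); the default 133 mm approximates the outer shell of the
#'   commercial array.
#' @return an object of class `cone_kernel`.
#' @export
cone_kernel <- function(rate = 1, core_mm = 2.5, sigma_mm = 0.8,
                        mu_mm = 0.005, ref_mm = 800,
                        phantom_radius_mm = 133) {
  pars <- c(rate = rate, core_mm = core_mm, sigma_mm = sigma_mm,
            mu_mm = mu_mm, ref_mm = ref_mm,
            phantom_radius_mm = phantom_radius_mm)
  if (any(!is.finite(pars)) || any(pars <= 0)) {
    vstop("all kernel parameters must be finite and > 0")
  }
  structure(as.list(pars), class = "cone_kernel")
}

#' @export
print.cone_kernel <- function(x, ...) {
  cat(sprintf(
    "<cone_kernel> core %g mm, sigma %g mm, mu %g /mm, ref %g mm\n",
    x$core_mm, x$sigma_mm, x$mu_mm, x$ref_mm
  ))
  invisible(x)
}

# Chord length (mm) of the ray S + s*u inside the infinite cylinder
# (x - cx)^2 + (y - cy)^2 = R^2, accumulated from the entry point up to
# the target point at distance d along the ray.  Vectorized over rows
# of u/d.  `center` is the cylinder axis position in the x-y plane: the
# phantom translates rigidly with the diode array.
chord_length <- function(src, u, d, R, center = c(0, 0)) {
  sx <- src[1] - center[1]
  sy <- src[2] - center[2]
  a <- u[, 1]^2 + u[, 2]^2
  b <- 2 * (sx * u[, 1] + sy * u[, 2])
  c0 <- sx^2 + sy^2 - R^2
  t <- numeric(length(d))
  # rays parallel to the cylinder axis: inside for their whole length
  par_in <- a < 1e-14
  if (any(par_in)) t[par_in] <- if (c0 <= 0) d[par_in] else 0
  gen <- !par_in
  if (any(gen)) {
    disc <- b[gen]^2 - 4 * a[gen] * c0
    hit <- disc > 0
    s1 <- s2 <- numeric(sum(gen))
    sq <- sqrt(pmax(disc, 0))
    s1 <- (-b[gen] - sq) / (2 * a[gen])
    s2 <- (-b[gen] + sq) / (2 * a[gen])
    tt <- pmax(pmin(d[gen], s2) - pmax(s1, 0), 0)
    tt[!hit] <- 0
    t[gen] <- tt
  }
  t
}

# Dose from a single beam at a matrix of points (n x 3).  `beam` is a
# list/one-row data frame with source, direction, cone_mm, mu.
beam_dose_at_points <- function(source, direction, cone_mm, mu, points,
                                kernel, cyl_center = c(0, 0)) {
  pts <- matrix(as.numeric(points), ncol = 3)
  v <- sweep(pts, 2, source)
  d <- sqrt(rowSums(v^2))
  d[d == 0] <- .Machine$double.eps
  zax <- as.numeric(v %*% direction)
  rperp <- sqrt(pmax(d^2 - zax^2, 0))
  core <- if (is.null(cone_mm) || is.na(cone_mm)) kernel$core_mm else cone_mm / 2
  rho <- rperp * kernel$ref_mm / d
  prof <- ifelse(rho <= core, 1,
                 exp(-(rho - core)^2 / (2 * kernel$sigma_mm^2)))
  t <- chord_length(source, v / d, d, kernel$phantom_radius_mm, cyl_center)
  dose <- mu * kernel$rate * (kernel$ref_mm / d)^2 * prof *
    exp(-kernel$mu_mm * t)
  dose[zax <= 0] <- 0
  dose
}

beam_row <- function(plan, i) {
  b <- plan$beams[i, ]
  list(
    id = b$id, source = c(b$sx, b$sy, b$sz),
    direction = c(b$dx, b$dy, b$dz), cone_mm = b$cone_mm, mu = b$mu
  )
}

#' Dose at a point from one beam
#'
#' @param beam a list with `source` (mm), unit `direction`, `cone_mm`
#'   and `mu` — e.g. one element of a plan via the internal accessor, or
#'   built by hand.
#' @param point numeric length-3 point (mm).
#' @param kernel a [cone_kernel()].
#' @return dose in relative units; exactly 0 (with attribute
#'   `behind = TRUE`) for points behind the source plane.
#' @export
dose_at_point <- function(beam, point, kernel) {
  point <- as_point3(point)
  d <- beam_dose_at_points(beam$source, beam$direction, beam$cone_mm,
                           beam$mu, matrix(point, nrow = 1), kernel)
  zax <- sum((point - beam$source) * beam$direction)
  out <- d[1]
  if (zax <= 0) attr(out, "behind") <- TRUE
  out
}

#' Per-beam dose matrix at a set of points
#'
#' @param plan a `qa_plan`.
#' @param points `n x 3` matrix of points (mm).
#' @param kernel a [cone_kernel()].
#' @param beam_shifts optional `n_beams x 3` matrix of rigid beam
#'   translation vectors (mm) — each beam's source is displaced by its
#'   row, direction unchanged (a pointing/path error).
#' @param cyl_center x-y position of the phantom cylinder axis (mm);
#'   follows the array under a global shift.
#' @return `n_beams x n` matrix of doses, rownames = beam ids.
#' @export
beam_dose_matrix <- function(plan, points, kernel, beam_shifts = NULL,
                             cyl_center = c(0, 0)) {
  stopifnot(inherits(plan, "qa_plan"), inherits(kernel, "cone_kernel"))
  pts <- matrix(as.numeric(points), ncol = 3)
  nb <- nrow(plan$beams)
  if (!is.null(beam_shifts)) {
    beam_shifts <- matrix(as.numeric(beam_shifts), ncol = 3)
    stopifnot(nrow(beam_shifts) == nb)
  }
  out <- matrix(0, nrow = nb, ncol = nrow(pts),
                dimnames = list(plan$beams$id, NULL))
  for (i in seq_len(nb)) {
    b <- beam_row(plan, i)
    src <- b$source
    if (!is.null(beam_shifts)) src <- src + beam_shifts[i, ]
    out[i, ] <- beam_dose_at_points(src, b$direction, b$cone_mm, b$mu,
                                    pts, kernel, cyl_center)
  }
  out
}

#' Noise-free delivery dose at every diode
#'
#' Sums [dose_at_point()] over all beams of the plan, evaluated at each
#' diode's nominal position plus its placement offset plus a global
#' rigid shift of the whole array (a phantom-frame translation, e.g. an
#' alignment-center drift).
#'
#' @param plan a `qa_plan`.
#' @param array a `diode_array`.
#' @param placements optional `count x 3` matrix of per-diode offset
#'   vectors (mm); `NULL` means nominal.
#' @param kernel a [cone_kernel()].
#' @param global_shift length-3 rigid array translation (mm).
#' @param beam_shifts optional per-beam translation matrix, see
#'   [beam_dose_matrix()].
#' @return numeric vector of length `array$count` (relative dose units).
#' @export
compute_delivery_dose <- function(plan, array, placements = NULL, kernel,
                                  global_shift = c(0, 0, 0),
                                  beam_shifts = NULL) {
  stopifnot(inherits(array, "diode_array"))
  global_shift <- as_point3(global_shift, "global_shift")
  pts <- array$positions
  if (!is.null(placements)) {
    placements <- matrix(as.numeric(placements), ncol = 3)
    stopifnot(nrow(placements) == array$count)
    pts <- pts + placements
  }
  pts <- sweep(pts, 2, global_shift, `+`)
  colSums(beam_dose_matrix(plan, pts, kernel, beam_shifts,
                           cyl_center = global_shift[1:2]))
}
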