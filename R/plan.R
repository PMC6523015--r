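# The isocentric body-path QA plan: many small-cone beams aimed at the
# alignment center from a shell of source positions.

default_workspace <- function() {
  list(polar_deg = c(0, 110), azimuth_deg = c(0, 360), sad_mm = c(700, 900))
}

new_qa_plan <- function(beams, label, isocenter = c(0, 0, 0)) {
  stopifnot(is.data.frame(beams))
  if (anyDuplicated(beams$id)) vstop("beam ids must be unique")
  d <- as.matrix(beams[, c("dx", "dy", "dz")])
  norms <- sqrt(rowSums(d^2))
  if (any(abs(norms - 1) > 1e-12)) vstop("beam directions must be unit vectors")
  s <- as.matrix(beams[, c("sx", "sy", "sz")])
  sad <- sqrt(rowSums(sweep(s, 2, isocenter)^2))
  aim <- sweep(s + d * sad, 2, isocenter)
  if (any(sqrt(rowSums(aim^2)) > 1e-6)) {
    vstop("all beams must be aimed at the isocenter")
  }
  if (any(beams$mu <= 0)) vstop("MU must be positive")
  structure(
    list(label = label, isocenter = as_point3(isocenter, "isocenter"),
         beams = beams),
    class = "qa_plan"
  )
}

#' @export
print.qa_plan <- function(x, ...) {
  cat(sprintf(
    "<qa_plan> '%s': %d beams, cone %g mm, %g MU each\n",
    x$label, nrow(x$beams), x$beams$cone_mm[1], x$beams$mu[1]
  ))
  invisible(x)
}

#' Generate an isocentric body-path QA plan
#'
#' Draws `n_beams` source positions quasi-uniformly (seeded uniform
#' sampling, uniform in solid angle) over a spherical shell sector and
#' aims every beam at the isocenter.  The sector — the "workspace" —
#' emulates a body-path traversal that never fires through the couch:
#' polar angle is measured from the +y (anterior) axis, so the default
#' `polar_deg = c(0, 110)` keeps sources anterior and lateral, reaching
#' slightly below the lateral plane but never posterior.  Source-to-axis
#' distance (SAD) is drawn uniformly in `sad_mm` (default 700-900 mm,
#' centred on the 800 mm cone-definition distance).
#'
#' All beams carry a 5 mm nominal cone (diameter defined at 800 mm from
#' the source) and 50 MU by default, matching the standard constancy-QA
#' plan of 116 body-path beams at 50 MU each.  The same seed always
#' yields the identical plan.
#'
#' @param n_beams number of beams (>= 1); default 116.
#' @param seed integer seed for the source sampler.
#' @param workspace list with numeric ranges `polar_deg` (degrees from
#'   +y), `azimuth_deg`, and `sad_mm`.
#' @param cone_mm nominal cone diameter at 800 mm, mm.
#' @param mu monitor units per beam.
#' @param isocenter plan isocenter (mm), default the frame origin.
#' @param label plan label.
#' @return A `qa_plan`: list with `label`, `isocenter`, and data frame
#'   `beams` (`id`, source `sx sy sz`, unit direction `dx dy dz`,
#'   `cone_mm`, `mu`).
#' @export
generate_body_path_plan <- function(n_beams = 116L, seed = 1L,
                                    workspace = default_workspace(),
                                    cone_mm = 5, mu = 50,
                                    isocenter = c(0, 0, 0),
                                    label = NULL) {
  n_beams <- as.integer(n_beams)
  if (is.na(n_beams) || n_beams < 1L) vstop("n_beams must be >= 1")
  w <- utils::modifyList(default_workspace(), workspace)
  if (diff(range(w$polar_deg)) <= 0 && n_beams > 1L ||
      any(w$sad_mm <= 0) || diff(range(w$sad_mm)) < 0 ||
      diff(range(w$polar_deg)) < 0) {
    vstop("workspace is empty or invalid")
  }
  isocenter <- as_point3(isocenter, "isocenter")
  if (is.null(label)) label <- sprintf("body-path-%d-seed%d", n_beams, seed)

  pol <- sort(w$polar_deg) * pi / 180
  azi <- sort(w$azimuth_deg) * pi / 180
  u <- with_seed(seed, {
    # uniform in solid angle over the sector: cos(polar) uniform
    cth <- stats::runif(n_beams, cos(pol[2]), cos(pol[1]))
    phi <- stats::runif(n_beams, azi[1], azi[2])
    sad <- stats::runif(n_beams, w$sad_mm[1], w$sad_mm[2])
    sth <- sqrt(pmax(0, 1 - cth^2))
    list(
      # polar axis is +y (anterior); azimuth sweeps the x-z plane
      dirs = cbind(sth * cos(phi), cth, sth * sin(phi)),
      sad = sad
    )
  })
  src <- sweep(u$dirs * u$sad, 2, isocenter, `+`)
  dirs <- -u$dirs
  beams <- data.frame(
    id = sprintf("B%03d", seq_len(n_beams)),
    sx = src[, 1], sy = src[, 2], sz = src[, 3],
    dx = dirs[, 1], dy = dirs[, 2], dz = dirs[, 3],
    cone_mm = cone_mm, mu = mu,
    stringsAsFactors = FALSE
  )
  new_qa_plan(beams, label, isocenter)
}

#' Two-beam orthogonal fixture plan
#'
#' A trivial plan of two orthogonal beams (anterior and left-lateral),
#' in the style of a simplified two-field alignment check.  Provided as
#' a test fixture only.
#'
#' @param sad_mm source-to-axis distance, mm.
#' @param cone_mm cone diameter at 800 mm, mm.
#' @param mu monitor units per beam.
#' @return a `qa_plan` with two beams.
#' @export
two_field_plan <- function(sad_mm = 800, cone_mm = 60, mu = 200) {
  beams <- data.frame(
    id = c("AP", "LAT"),
    sx = c(0, sad_mm), sy = c(sad_mm, 0), sz = c(0, 0),
    dx = c(0, -1), dy = c(-1, 0), dz = c(0, 0),
    cone_mm = cone_mm, mu = mu,
    stringsAsFactors = FALSE
  )
  new_qa_plan(beams, "two-field")
}

#' Find opposing or closely opposing beam pairs
#'
#' Returns every unordered pair of beams whose directions are
#' anti-parallel to within `angle_tol_deg` — i.e. the angle between
#' `d_i` and `-d_j` is at most the tolerance.  Diodes shared by such
#' pairs see entrance and exit doses whose shift responses cancel or
#' exaggerate each other, so they are excluded from the analysis.
#'
#' @param plan a `qa_plan`.
#' @param angle_tol_deg opposition tolerance in degrees, in (0, 30].
#' @return data frame with columns `id1`, `id2`, `angle_deg` (the angle
#'   between `d_i` and `-d_j`); zero rows if none.
#' @export
opposing_pairs <- function(plan, angle_tol_deg = 5) {
  stopifnot(inherits(plan, "qa_plan"))
  if (!is.finite(angle_tol_deg) || angle_tol_deg <= 0 || angle_tol_deg > 30) {
    vstop("angle_tol_deg must be in (0, 30]")
  }
  d <- as.matrix(plan$beams[, c("dx", "dy", "dz")])
  n <- nrow(d)
  out <- data.frame(id1 = character(), id2 = character(),
                    angle_deg = numeric(), stringsAsFactors = FALSE)
  if (n < 2L) return(out)
  cosang <- -tcrossprod(d) # cos of angle(d_i, -d_j)
  cosang <- pmax(pmin(cosang, 1), -1) # matrix-preserving clamp
  ang <- acos(cosang) * 180 / pi
  hit <- which(upper.tri(ang) & ang <= angle_tol_deg, arr.ind = TRUE)
  if (nrow(hit)) {
    out <- data.frame(
      id1 = plan$beams$id[hit[, 1]],
      id2 = plan$beams$id[hit[, 2]],
      angle_deg = ang[hit],
      stringsAsFactors = FALSE
    )
    out <- out[order(out$id1, out$id2), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Serialize / deserialize a QA plan to JSON
#'
#' @param plan a `qa_plan`.
#' @param path file path.
#' @return `plan_to_json` returns `path` invisibly; `plan_from_json`
#'   returns a `qa_plan`.
#' @export
plan_to_json <- function(plan, path) {
  stopifnot(inherits(plan, "qa_plan"))
  b <- plan$beams
  obj <- list(
    format = "bpq-plan", version = 1L, label = plan$label,
    isocenter = plan$isocenter,
    beams = lapply(seq_len(nrow(b)), function(i) {
      list(
        id = b$id[i],
        source = as.numeric(fmt_num(c(b$sx[i], b$sy[i], b$sz[i]))),
        direction = as.numeric(fmt_num(c(b$dx[i], b$dy[i], b$dz[i]), 9L)),
        cone_mm = b$cone_mm[i], mu = b$mu[i]
      )
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname plan_to_json
#' @export
plan_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "bpq-plan")) vstop("%s is not a bpq-plan file", path)
  iso <- as.numeric(unlist(obj$isocenter))
  rows <- lapply(obj$beams, function(bb) {
    s <- as.numeric(unlist(bb$source))
    # re-derive the direction from the aiming constraint so that the
    # 6-decimal source rounding cannot break the isocentric invariant
    d <- unit3(iso - s)
    data.frame(
      id = bb$id, sx = s[1], sy = s[2], sz = s[3],
      dx = d[1], dy = d[2], dz = d[3],
      cone_mm = bb$cone_mm, mu = bb$mu, stringsAsFactors = FALSE
    )
  })
  new_qa_plan(do.call(rbind, rows), obj$label, iso)
}
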