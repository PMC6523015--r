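# Readers/writers for every artifact the pipeline touches.  All
# writers use fixed float formatting and fixed key order so the same
# inputs always produce byte-identical files.

MEAS_FORMAT <- "ACMEAS"
MEAS_VERSION <- 1L

#' Write / read a measurement file
#'
#' The plain-text measurement dialect (`.acmeas.txt`): a commented
#' header (format/version, delivery label, timestamp, plan id, diode
#' count) followed by one `index value` row per diode, doses to 6
#' decimals.  Reads are strict: version, row count and non-negativity
#' are validated with line-numbered errors; out-of-order indices are
#' accepted, re-sorted and warned about.
#'
#' @param dose numeric per-diode dose vector (relative units).
#' @param path file path.
#' @param label delivery label.
#' @param plan_id plan identifier.
#' @param timestamp ISO-8601 string recorded in the header; pass a
#'   fixed value for byte-deterministic output.
#' @return `write_measurement` returns `path` invisibly;
#'   `read_measurement` returns the dose vector with attributes
#'   `label`, `plan_id`, `timestamp`.
#' @export
write_measurement <- function(dose, path, label = "delivery",
                              plan_id = "unknown",
                              timestamp = "1970-01-01T00:00:00Z") {
  dose <- as.numeric(dose)
  if (any(!is.finite(dose)) || any(dose < 0)) {
    vstop("dose values must be finite and non-negative")
  }
  header <- c(
    sprintf("# %s %d", MEAS_FORMAT, MEAS_VERSION),
    sprintf("# label: %s", label),
    sprintf("# timestamp: %s", timestamp),
    sprintf("# plan: %s", plan_id),
    sprintf("# diodes: %d", length(dose))
  )
  body <- sprintf("%d %s", seq_along(dose) - 1L, fmt_num(dose))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_measurement
#' @export
read_measurement <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 6L) vstop("%s: truncated file (%d lines)", path,
                                length(lines))
  hd <- lines[1]
  m <- regmatches(hd, regexec("^# (\\S+) (\\d+)$", hd))[[1]]
  if (length(m) != 3L || m[2] != MEAS_FORMAT) {
    vstop("%s line 1: not an %s file", path, MEAS_FORMAT)
  }
  if (as.integer(m[3]) != MEAS_VERSION) {
    vstop("%s line 1: unknown version %s (supported: %d)", path, m[3],
          MEAS_VERSION)
  }
  get_field <- function(key) {
    pat <- sprintf("^# %s: (.*)$", key)
    hit <- grep(pat, lines[1:5], value = TRUE)
    if (!length(hit)) vstop("%s: missing header field '%s'", path, key)
    sub(pat, "\\1", hit[1])
  }
  label <- get_field("label")
  timestamp <- get_field("timestamp")
  plan_id <- get_field("plan")
  n <- as.integer(get_field("diodes"))
  body <- lines[-(1:5)]
  body <- body[nzchar(body)]
  if (length(body) != n) {
    vstop("%s: expected %d diode rows, found %d", path, n, length(body))
  }
  parts <- strsplit(body, "\\s+")
  bad <- which(vapply(parts, length, integer(1)) != 2L)
  if (length(bad)) {
    vstop("%s line %d: malformed row '%s'", path, 5L + bad[1],
          body[bad[1]])
  }
  idx <- as.integer(vapply(parts, `[[`, character(1), 1L))
  val <- as.numeric(vapply(parts, `[[`, character(1), 2L))
  if (any(is.na(idx)) || any(is.na(val))) {
    i <- which(is.na(idx) | is.na(val))[1]
    vstop("%s line %d: non-numeric row '%s'", path, 5L + i, body[i])
  }
  if (any(val < 0)) {
    i <- which(val < 0)[1]
    vstop("%s line %d: negative dose %g", path, 5L + i, val[i])
  }
  if (!setequal(idx, seq_len(n) - 1L)) {
    vstop("%s: diode indices are not 0..%d", path, n - 1L)
  }
  if (is.unsorted(idx)) {
    vwarn("%s: diode indices out of order; re-sorted", path)
    val <- val[order(idx)]
  }
  structure(val, label = label, plan_id = plan_id, timestamp = timestamp)
}

#' Write / read a dose grid container
#'
#' JSON container (`.dosegrid.json`) with an explicit header
#' (dimensions, origin mm, spacing mm, axis order, scale factor) and an
#' x-fastest flattened value payload.  Values are stored as
#' `payload * scale`; the reader applies the scale.
#'
#' @param grid a `dose_grid`.
#' @param path file path.
#' @param scale stored-value scale factor (default 1).
#' @return `write_dose_grid` returns `path` invisibly; `read_dose_grid`
#'   a `dose_grid`.
#' @export
write_dose_grid <- function(grid, path, scale = 1) {
  stopifnot(inherits(grid, "dose_grid"))
  if (!is.finite(scale) || scale <= 0) vstop("scale must be > 0")
  obj <- list(
    format = "bpq-dosegrid", version = 1L,
    dimensions = grid$dim, origin_mm = grid$origin,
    spacing_mm = grid$spacing, axis_order = "xyz-x-fastest",
    scale = scale,
    values = as.numeric(fmt_num(as.numeric(grid$values) / scale))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dose_grid
#' @export
read_dose_grid <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "bpq-dosegrid")) {
    vstop("%s is not a bpq-dosegrid file", path)
  }
  if (is.null(obj$spacing_mm) || is.null(obj$origin_mm)) {
    vstop("%s: missing spacing_mm/origin_mm header", path)
  }
  if (any(obj$spacing_mm <= 0)) vstop("%s: non-positive spacing", path)
  if (!identical(obj$axis_order, "xyz-x-fastest")) {
    vstop("%s: unsupported axis_order '%s'", path, obj$axis_order)
  }
  dims <- as.integer(obj$dimensions)
  if (length(obj$values) != prod(dims)) {
    vstop("%s: payload length %d != product of dimensions %d", path,
          length(obj$values), prod(dims))
  }
  dose_grid(array(obj$values * obj$scale, dim = dims),
            obj$origin_mm, obj$spacing_mm)
}

#' Save / load a correlation-curve set as JSON
#'
#' The shift grid is stored once; per diode, direction and placement an
#' array of percent values to 6 decimals.
#'
#' @param curveset a `curve_set`.
#' @param path file path.
#' @return `save_curves` returns `path` invisibly; `load_curves` a
#'   `curve_set`.
#' @export
save_curves <- function(curveset, path) {
  stopifnot(inherits(curveset, "curve_set"))
  diodes <- names(curveset$curves)
  obj <- list(
    format = "bpq-curves", version = 1L,
    shift_mm = curveset$shift_mm,
    directions = curveset$directions,
    placements = curveset$placements,
    provenance = curveset$provenance,
    baseline_dose = as.numeric(fmt_num(curveset$baseline_dose)),
    diodes = as.integer(diodes),
    percent = lapply(diodes, function(d) {
      cc <- curveset$curves[[d]]
      lapply(curveset$directions, function(dir) {
        lapply(curveset$placements, function(p) {
          as.numeric(fmt_num(cc[, dir, p]))
        })
      })
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_curves
#' @export
load_curves <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "bpq-curves")) {
    vstop("%s is not a bpq-curves file", path)
  }
  if (as.integer(obj$version) != 1L) {
    vstop("%s: curve schema version %s not supported (expected 1)",
          path, format(obj$version))
  }
  s <- as.numeric(unlist(obj$shift_mm))
  ns <- length(s)
  directions <- as.character(unlist(obj$directions))
  placements <- as.character(unlist(obj$placements))
  diodes <- as.integer(unlist(obj$diodes))
  obj$directions <- directions
  obj$placements <- placements
  curves <- list()
  for (k in seq_along(diodes)) {
    cc <- array(NA_real_, dim = c(ns, length(directions),
                                  length(placements)),
                dimnames = list(format(s), directions, placements))
    for (j in seq_along(directions)) {
      for (p in seq_along(placements)) {
        v <- as.numeric(unlist(obj$percent[[k]][[j]][[p]]))
        if (length(v) != ns) {
          vstop("%s: curve payload length %d != %d shift samples", path,
                length(v), ns)
        }
        cc[, j, p] <- v
      }
    }
    curves[[as.character(diodes[k])]] <- cc
  }
  baseline <- as.numeric(unlist(obj$baseline_dose))
  names(baseline) <- as.character(diodes)
  structure(
    list(shift_mm = s, directions = obj$directions,
         placements = obj$placements, curves = curves,
         baseline_dose = baseline,
         provenance = as.list(obj$provenance)),
    class = "curve_set"
  )
}

#' Save / load the beam-diode lookup table as JSON
#'
#' @param lut a `beam_diode_lut`.
#' @param path file path.
#' @return `save_lut` returns `path` invisibly; `load_lut` a
#'   `beam_diode_lut`.
#' @export
save_lut <- function(lut, path) {
  stopifnot(inherits(lut, "beam_diode_lut"))
  obj <- list(
    format = "bpq-lut", version = 1L,
    threshold_fraction = lut$threshold_fraction,
    threshold_ref = lut$threshold_ref,
    table = lapply(seq_len(nrow(lut$table)), function(i) {
      list(beam_id = lut$table$beam_id[i], diode = lut$table$diode[i],
           signal = as.numeric(fmt_num(lut$table$signal[i])))
    }),
    exclusions = lapply(seq_len(nrow(lut$exclusions)), function(i) {
      list(kind = lut$exclusions$kind[i], id = lut$exclusions$id[i],
           reason = lut$exclusions$reason[i])
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_lut
#' @export
load_lut <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "bpq-lut")) vstop("%s is not a bpq-lut file",
                                               path)
  tab <- if (length(obj$table)) {
    do.call(rbind, lapply(obj$table, function(e) {
      data.frame(beam_id = e$beam_id, diode = as.integer(e$diode),
                 signal = as.numeric(e$signal), stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(beam_id = character(), diode = integer(),
               signal = numeric(), stringsAsFactors = FALSE)
  }
  if (anyDuplicated(tab$beam_id)) {
    vstop("%s: duplicate beam id in LUT", path)
  }
  if (anyDuplicated(tab$diode)) {
    vstop("%s: duplicate diode in LUT", path)
  }
  excl <- if (length(obj$exclusions)) {
    do.call(rbind, lapply(obj$exclusions, function(e) {
      data.frame(kind = e$kind, id = as.character(e$id),
                 reason = e$reason, stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(kind = character(), id = character(),
               reason = character(), stringsAsFactors = FALSE)
  }
  structure(
    list(table = tab, threshold_fraction = obj$threshold_fraction,
         threshold_ref = obj$threshold_ref, threshold = NULL,
         exclusions = excl),
    class = "beam_diode_lut"
  )
}

#' Save / load the placement lookup table as JSON
#'
#' @param placement_lut a `placement_lut`.
#' @param path file path.
#' @return `save_placement_lut` returns `path` invisibly;
#'   `load_placement_lut` a `placement_lut`.
#' @export
save_placement_lut <- function(placement_lut, path) {
  stopifnot(inherits(placement_lut, "placement_lut"))
  tab <- placement_lut$table
  obj <- list(
    format = "bpq-placement-lut", version = 1L,
    table = lapply(seq_len(nrow(tab)), function(i) {
      list(diode = tab$diode[i], placement = tab$placement[i],
           s_percent = as.numeric(fmt_num(tab$s_percent[i])),
           delta_mm = as.numeric(fmt_num(tab$delta_mm[i])))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_placement_lut
#' @export
load_placement_lut <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "bpq-placement-lut")) {
    vstop("%s is not a bpq-placement-lut file", path)
  }
  tab <- do.call(rbind, lapply(obj$table, function(e) {
    data.frame(diode = as.integer(e$diode), placement = e$placement,
               s_percent = as.numeric(e$s_percent),
               delta_mm = as.numeric(e$delta_mm), stringsAsFactors = FALSE)
  }))
  structure(list(table = tab), class = "placement_lut")
}

#' Write a position-error report
#'
#' Writes the per-diode table as CSV (`<prefix>.report.csv`) and the
#' summary, with optional detection verdict, as JSON
#' (`<prefix>.summary.json`).
#'
#' @param report a `position_error_report`.
#' @param prefix output path prefix.
#' @param verdict optional [detect_systematic_shift()] verdict.
#' @return named character vector of the two paths, invisibly.
#' @export
write_report <- function(report, prefix, verdict = NULL) {
  stopifnot(inherits(report, "position_error_report"))
  csv <- paste0(prefix, ".report.csv")
  js <- paste0(prefix, ".summary.json")
  tab <- report$per_diode
  num <- vapply(tab, is.numeric, logical(1)) &
    !vapply(tab, is.integer, logical(1))
  tab[num] <- lapply(tab[num], function(x) fmt_num(x))
  utils::write.csv(tab, csv, row.names = FALSE, quote = FALSE)
  obj <- c(list(format = "bpq-summary", version = 1L), report$summary)
  if (!is.null(verdict)) obj$verdict <- verdict
  jsonlite::write_json(obj, js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, summary = js))
}
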