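# Beam <-> diode assignment: one high-signal diode per beam, with
# threshold, cross-talk (multi-beam) and opposing-beam exclusions.

#' Noise-free per-beam diode signals
#'
#' Computes each individual beam's dose at every diode of the array,
#' replacing the physical beam/detector synchronization (movie file +
#' console video) with a direct per-beam forward computation.  By
#' linearity, these rows sum to the full-plan delivery vector.
#'
#' @param plan a `qa_plan`.
#' @param array a `diode_array`.
#' @param kernel a [cone_kernel()].
#' @return `n_beams x count` matrix of doses, rownames = beam ids.
#' @export
per_beam_signals <- function(plan, array, kernel) {
  stopifnot(inherits(array, "diode_array"))
  beam_dose_matrix(plan, array$positions, kernel)
}

#' Build the beam-to-diode lookup table
#'
#' Implements the selection criteria of the constancy method: per beam,
#' the candidate diode is the one with the maximum signal among diodes
#' at or above the signal threshold; any diode responding above
#' threshold to two or more beams is excluded entirely (cross-talk
#' would mix the beams' shift responses); beams with no above-threshold
#' responder, or none left after exclusions, drop out.  All exclusions
#' are logged with reasons.
#'
#' The 10% threshold is referenced, by default, to the global maximum
#' single-beam single-diode signal; `threshold_ref = "per-beam"`
#' references each beam's own maximum instead.
#'
#' @param signals `n_beams x n_diodes` matrix from
#'   [per_beam_signals()].
#' @param threshold_fraction fraction in (0, 1), default 0.10.
#' @param threshold_ref `"global"` (default) or `"per-beam"`.
#' @return an object of class `beam_diode_lut`: list with data frame
#'   `table` (`beam_id`, `diode`, `signal`), `threshold_fraction`,
#'   `threshold_ref`, `threshold` (absolute value(s)), and data frame
#'   `exclusions` (`kind` in diode/beam, `id`, `reason` in
#'   multi-beam/sub-threshold/no-signal/opposing-pair).
#' @export
build_beam_diode_lut <- function(signals, threshold_fraction = 0.10,
                                 threshold_ref = c("global", "per-beam")) {
  stopifnot(is.matrix(signals))
  threshold_ref <- match.arg(threshold_ref)
  if (!is.finite(threshold_fraction) || threshold_fraction <= 0 ||
      threshold_fraction >= 1) {
    vstop("threshold_fraction must be in (0, 1)")
  }
  nb <- nrow(signals)
  beam_ids <- rownames(signals)
  if (is.null(beam_ids)) beam_ids <- sprintf("B%03d", seq_len(nb))
  thr <- if (threshold_ref == "global") {
    rep(threshold_fraction * max(signals), nb)
  } else {
    threshold_fraction * apply(signals, 1, max)
  }

  above <- signals >= thr & signals > 0
  excl <- data.frame(kind = character(), id = character(),
                     reason = character(), stringsAsFactors = FALSE)

  # diodes responding above threshold to >= 2 beams: excluded entirely
  resp_count <- colSums(above)
  multi <- which(resp_count >= 2L)
  if (length(multi)) {
    excl <- rbind(excl, data.frame(
      kind = "diode", id = as.character(multi - 1L),
      reason = "multi-beam", stringsAsFactors = FALSE
    ))
  }
  usable <- above
  usable[, multi] <- FALSE

  rows <- vector("list", nb)
  for (i in seq_len(nb)) {
    cand <- which(usable[i, ])
    if (!length(cand)) {
      reason <- if (max(signals[i, ]) <= 0) {
        "no-signal"
      } else if (!any(above[i, ])) {
        "sub-threshold"
      } else {
        "multi-beam"
      }
      excl <- rbind(excl, data.frame(
        kind = "beam", id = beam_ids[i], reason = reason,
        stringsAsFactors = FALSE
      ))
      next
    }
    best <- cand[which.max(signals[i, cand])]
    rows[[i]] <- data.frame(
      beam_id = beam_ids[i], diode = best - 1L,
      signal = signals[i, best], stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(tab)) {
    tab <- data.frame(beam_id = character(), diode = integer(),
                      signal = numeric(), stringsAsFactors = FALSE)
  }
  if (anyDuplicated(tab$diode)) {
    vstop("internal error: a diode was selected for two beams")
  }
  structure(
    list(table = tab, threshold_fraction = threshold_fraction,
         threshold_ref = threshold_ref, threshold = thr,
         exclusions = excl),
    class = "beam_diode_lut"
  )
}

#' @export
print.beam_diode_lut <- function(x, ...) {
  cat(sprintf(
    "<beam_diode_lut> %d beam-diode pairs (%d exclusions logged)\n",
    nrow(x$table), nrow(x$exclusions)
  ))
  invisible(x)
}

#' Remove lookup-table entries hit by opposing beams
#'
#' Drops every entry whose diode receives an above-threshold signal
#' from any beam opposing (anti-parallel within `angle_tol_deg`) its
#' matched beam: entrance/exit dose changes of such pairs cancel or
#' exaggerate the inverted position error.  A monotone filter — the
#' result is always a subset of the input.
#'
#' @param lut a `beam_diode_lut`.
#' @param plan the `qa_plan` the LUT was built from.
#' @param signals the [per_beam_signals()] matrix used to build it.
#' @param angle_tol_deg opposition tolerance, degrees (default 5).
#' @return the filtered `beam_diode_lut` with removals logged.
#' @export
exclude_opposing <- function(lut, plan, signals, angle_tol_deg = 5) {
  stopifnot(inherits(lut, "beam_diode_lut"), inherits(plan, "qa_plan"))
  opp <- opposing_pairs(plan, angle_tol_deg)
  if (nrow(lut$table) == 0L || nrow(opp) == 0L) return(lut)
  beam_ids <- rownames(signals)
  thr <- lut$threshold
  names(thr) <- beam_ids
  drop <- logical(nrow(lut$table))
  for (r in seq_len(nrow(lut$table))) {
    b <- lut$table$beam_id[r]
    d <- lut$table$diode[r]
    opps <- c(opp$id2[opp$id1 == b], opp$id1[opp$id2 == b])
    if (!length(opps)) next
    sig <- signals[opps, d + 1L]
    if (any(sig >= thr[opps] & sig > 0)) drop[r] <- TRUE
  }
  if (any(drop)) {
    lut$exclusions <- rbind(lut$exclusions, data.frame(
      kind = "beam", id = lut$table$beam_id[drop],
      reason = "opposing-pair", stringsAsFactors = FALSE
    ))
    lut$table <- lut$table[!drop, , drop = FALSE]
    rownames(lut$table) <- NULL
  }
  lut
}
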