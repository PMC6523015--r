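# Internal helpers shared across modules.

vstop <- function(...) stop(sprintf(...), call. = FALSE)

vwarn <- function(...) warning(sprintf(...), call. = FALSE)

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global random-number stream set from `seed`, then
#' restores the previous stream, so seeded simulation helpers do not
#' perturb the caller's RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Derive independent sub-seeds from one master seed
#'
#' @param seed master integer seed.
#' @param n number of sub-seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n))
}

# Canonical direction labels and their unit vectors in the patient frame:
# LR along +x (patient left), AP along +y (anterior), SI along +z (superior).
BPQ_DIRECTIONS <- c("AP", "SI", "LR")

BPQ_PLACEMENTS <- c("nominal", "+x", "-x", "+y", "-y", "+z", "-z")

#' Unit vector of a clinical direction label
#'
#' @param direction one of `"AP"`, `"SI"`, `"LR"`.
#' @return numeric length-3 unit vector (x, y, z) in mm-frame coordinates.
#' @export
direction_unit <- function(direction) {
  switch(match.arg(direction, BPQ_DIRECTIONS),
    AP = c(0, 1, 0),
    SI = c(0, 0, 1),
    LR = c(1, 0, 0)
  )
}

as_point3 <- function(x, what = "point") {
  x <- as.numeric(x)
  if (length(x) != 3L || any(!is.finite(x))) {
    vstop("%s must be a finite numeric vector of length 3", what)
  }
  x
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) vstop("cannot normalize a zero vector")
  v / n
}

fmt_num <- function(x, digits = 6L) {
  # fixed-format numbers so writers are byte-deterministic
  sprintf(paste0("%.", digits, "f"), x)
}
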