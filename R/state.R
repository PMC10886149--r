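#' State of one release vessel
#'
#' The model tracks free glucose P, total dextrin S (the sum of the
#' susceptible and resistant pools), the susceptible proportion WS = SS/S,
#' the enzyme activity concentration E and the liquid volume V.  The pool
#' concentrations follow as SS = WS * S and SR = (1 - WS) * S.
#'
#' @param P free glucose, g/L (>= 0).
#' @param S total dextrin, g/L (>= 0).
#' @param WS susceptible proportion of the dextrin, in `[0, 1]`.
#' @param E enzyme activity concentration, U/L (>= 0).
#' @param V liquid volume, L (> 0).
#'
#' @return an object of class `release_state` (a named list).
#' @export
#' @examples
#' s <- release_state(P = 0, S = 30, WS = 0.464, E = 10, V = 0.011)
#' susceptible_substrate(s)
#' resistant_substrate(s)
release_state <- function(P = 0, S = 0, WS = 0.464, E = 0, V = 0.010) {
  s <- list(P = P, S = S, WS = WS, E = E, V = V)
  validate_release_state(s)
  structure(s, class = "release_state")
}

validate_release_state <- function(s) {
  stopifnot(
    s$P >= 0, s$S >= 0, s$E >= 0,
    s$WS >= 0, s$WS <= 1,
    s$V > 0
  )
  invisible(s)
}

#' @rdname release_state
#' @param state a `release_state` object.
#' @return `susceptible_substrate()` and `resistant_substrate()` return the
#'   concentrations SS and SR in g/L.
#' @export
susceptible_substrate <- function(state) state$WS * state$S

#' @rdname release_state
#' @export
resistant_substrate <- function(state) (1 - state$WS) * state$S

#' @export
print.release_state <- function(x, ...) {
  cat(sprintf(
    "Release state: P = %.4g g/L, S = %.4g g/L (WS = %.3f), E = %.4g U/L, V = %.4g L\n",
    x$P, x$S, x$WS, x$E, x$V))
  invisible(x)
}

# internal: state <-> numeric vector used by the integrator
# (6th slot is the cumulative dilution-free glucose release)
state_to_vector <- function(state, Rcum = 0) {
  c(P = state$P, S = state$S, WS = state$WS, E = state$E, V = state$V,
    Rcum = Rcum)
}

vector_to_state <- function(y) {
  structure(list(P = max(0, y[[1]]), S = max(0, y[[2]]),
                 WS = min(1, max(0, y[[3]])), E = max(0, y[[4]]),
                 V = y[[5]]),
            class = "release_state")
}
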