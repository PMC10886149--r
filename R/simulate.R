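# Piecewise ODE integration between discrete liquid-handling events.
#
# The integration is segmented at every event time: the solver is stopped,
# the volume-dependent states are recomputed from the mixing mass balance
# (apply_bolus / apply_sample), and the solver is restarted from the
# post-event state.  Events are never located by root-finding.
#
# The engine integrates a *group* of vessels that share the same clock in a
# single stacked ODE system (6 states per vessel, identical kinetic
# parameters), which is what makes simultaneous multi-experiment fitting
# affordable; simulating one design is the n = 1 special case.

.release_parms <- function(params, variant, n = 1L) {
  c(n, params$kS, params$kR, params$K, params$nu, params$r_evap,
    params$k_single, params$KiP, params$KiS, variant_code(variant), .ws_eps)
}

# Integrate a group of vessels over [0, t_end].
#  y0: n x 6 matrix (rows = vessels, cols P,S,WS,E,V,Rcum)
#  designs: list of experiment_design (events applied per vessel)
#  out_times: requested output times (must include 0); recorded values at an
#    event time are the pre-event (left-limit) states
# Returns an n x length(out_times) x 6 array.
.integrate_group <- function(y0, designs, out_times, params, variant,
                             rtol, atol) {
  n <- nrow(y0)
  parms <- .release_parms(params, variant, n)
  t_end <- max(out_times)

  ev_times <- sort(unique(unlist(lapply(designs, event_times))))
  # events at t = 0 are applied to the initial state before integration
  for (i in seq_len(n)) {
    if (any(event_times(designs[[i]]) == 0)) {
      st <- apply_events_at(vector_to_state(y0[i, ]), designs[[i]], 0)
      y0[i, 1:5] <- unlist(st, use.names = FALSE)
    }
  }
  boundaries <- sort(unique(c(0, ev_times[ev_times > 0 & ev_times < t_end], t_end)))

  out <- array(NA_real_, dim = c(n, length(out_times), 6))
  y <- as.numeric(t(y0))
  record <- function(row, times_idx) {
    # row: solver output row (time + 6n states) at one of out_times
    m <- matrix(row[-1], nrow = n, byrow = TRUE)
    out[, times_idx, ] <<- m
  }

  for (k in seq_len(length(boundaries) - 1)) {
    a <- boundaries[k]; b <- boundaries[k + 1]
    inner <- out_times[out_times > a & out_times < b]
    seg_times <- unique(c(a, inner, b))
    sol <- deSolve::lsoda(y = y, times = seg_times, func = "enzfeed_derivs",
                          parms = parms, dllname = "enzfeed",
                          initfunc = "enzfeed_initmod",
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop(sprintf("ODE solver failed in segment [%g, %g] h", a, b))
    # record requested times in (a, b]; a itself only for the first
    # segment (later segment starts are post-event states and must not
    # overwrite the pre-event value recorded by the previous segment)
    lo <- if (k == 1) a - 1e-12 else a
    for (tt in out_times[out_times > lo & out_times <= b]) {
      ri <- which(abs(sol[, 1] - tt) < 1e-12)[1]
      record(sol[ri, ], which(out_times == tt))
    }
    y <- as.numeric(sol[nrow(sol), -1])
    # clip solver round-off and apply the events scheduled at b
    ym <- matrix(y, nrow = n, byrow = TRUE)
    ym[, c(1, 2, 4)][ym[, c(1, 2, 4)] < 0] <- 0
    ym[, 3] <- pmin(1, pmax(0, ym[, 3]))
    if (b < t_end || any(ev_times == t_end)) {
      for (i in seq_len(n)) {
        if (any(event_times(designs[[i]]) == b)) {
          st <- apply_events_at(vector_to_state(ym[i, ]), designs[[i]], b)
          ym[i, 1:5] <- unlist(st, use.names = FALSE)
        }
      }
    }
    y <- as.numeric(t(ym))
  }
  out
}

#' Simulate one release experiment
#'
#' Integrates the release ODE system piecewise between the design's
#' handling events.  At every bolus or sample the integration is stopped,
#' the volume-dependent states are recomputed from the mixing mass balance,
#' and the integration is restarted.  Values reported at an event time are
#' the pre-event (left-limit) states, matching the convention that a sample
#' is drawn before liquid is added.
#'
#' @param design an [experiment_design()].
#' @param params a [release_parameters()].
#' @param variant kinetic variant tag, see [model_variants()].
#' @param times output time grid, h; defaults to 201 points over the
#'   horizon.  Event times are always included.
#' @param use_compiled integrate with the compiled right-hand side (the
#'   default) or with the R reference implementation [release_rhs()]; both
#'   agree to solver tolerance.
#' @return an object of class `release_trajectory`: a list with elements
#'   `states` (data frame with columns `time_h`, `P_gL`, `S_gL`, `WS`,
#'   `SS_gL`, `SR_gL`, `E_UL`, `V_L`, `Rcum_gL`), `events`, `params`,
#'   `variant`.  `Rcum_gL` is the cumulative dilution-free glucose released
#'   by the reaction, used for mass-ledger checks and feed-rate auditing.
#' @export
#' @examples
#' d <- experiment_design(release_state(S = 30, WS = 0.464, E = 10, V = 0.011),
#'                        horizon = 30)
#' traj <- simulate_release(d, release_parameters())
#' head(as.data.frame(traj))
simulate_release <- function(design, params, variant = "two_substrate",
                             times = NULL, use_compiled = TRUE) {
  stopifnot(inherits(design, "experiment_design"))
  variant <- match.arg(variant, model_variants())
  validate_release_parameters(params)
  if (is.null(times)) times <- seq(0, design$horizon, length.out = 201)
  times <- sort(unique(c(0, times, event_times(design))))
  times <- times[times <= design$horizon]

  y0 <- matrix(state_to_vector(design$initial_state), nrow = 1)
  if (use_compiled) {
    arr <- .integrate_group(y0, list(design), times, params, variant,
                            design$rtol, design$atol)
    states <- arr[1, , ]
  } else {
    states <- .integrate_single_r(y0[1, ], design, times, params, variant)
  }
  df <- data.frame(
    time_h = times,
    P_gL = pmax(0, states[, 1]),
    S_gL = pmax(0, states[, 2]),
    WS = pmin(1, pmax(0, states[, 3])),
    E_UL = pmax(0, states[, 4]),
    V_L = states[, 5],
    Rcum_gL = states[, 6]
  )
  df$SS_gL <- df$WS * df$S_gL
  df$SR_gL <- (1 - df$WS) * df$S_gL
  df <- df[, c("time_h", "P_gL", "S_gL", "WS", "SS_gL", "SR_gL",
               "E_UL", "V_L", "Rcum_gL")]
  structure(list(states = df, events = design$events, params = params,
                 variant = variant, design = design),
            class = "release_trajectory")
}

# R-path integration (single design) against the reference release_rhs();
# used to validate the compiled right-hand side.
.integrate_single_r <- function(y0, design, out_times, params, variant) {
  rhs <- function(t, y, parms) {
    st <- vector_to_state(y)
    d <- release_rhs(st, params, variant)
    reac <- if (variant_is_two_substrate(variant)) {
      sum(release_rates(st, params))
    } else {
      variant_rate(st, params, variant)
    }
    list(c(unname(d), params$nu * reac))
  }
  t_end <- max(out_times)
  ev <- event_times(design)
  st <- vector_to_state(y0)
  if (any(ev == 0)) st <- apply_events_at(st, design, 0)
  y <- c(unlist(st, use.names = FALSE), y0[6])
  boundaries <- sort(unique(c(0, ev[ev > 0 & ev < t_end], t_end)))
  out <- matrix(NA_real_, nrow = length(out_times), ncol = 6)
  for (k in seq_len(length(boundaries) - 1)) {
    a <- boundaries[k]; b <- boundaries[k + 1]
    seg_times <- unique(c(a, out_times[out_times > a & out_times < b], b))
    sol <- deSolve::lsoda(y, seg_times, rhs, parms = NULL,
                          rtol = design$rtol, atol = design$atol)
    lo <- if (k == 1) a - 1e-12 else a
    for (tt in out_times[out_times > lo & out_times <= b]) {
      ri <- which(abs(sol[, 1] - tt) < 1e-12)[1]
      out[which(out_times == tt), ] <- sol[ri, -1]
    }
    y <- as.numeric(sol[nrow(sol), -1])
    if (any(ev == b)) {
      st <- apply_events_at(vector_to_state(y), design, b)
      y <- c(unlist(st, use.names = FALSE), y[6])
    }
  }
  out
}

#' @export
print.release_trajectory <- function(x, ...) {
  df <- x$states
  cat(sprintf("Release trajectory (%s): %d time points over %.3g h, %d event(s)\n",
              x$variant, nrow(df), max(df$time_h), length(x$events)))
  cat(sprintf("  final: P = %.3f g/L, S = %.3f g/L, WS = %.3f, E = %.2f U/L\n",
              df$P_gL[nrow(df)], df$S_gL[nrow(df)], df$WS[nrow(df)],
              df$E_UL[nrow(df)]))
  invisible(x)
}

#' @export
as.data.frame.release_trajectory <- function(x, ...) x$states

#' Interpolate glucose from a trajectory
#'
#' Linear interpolation of the simulated free-glucose concentration at
#' arbitrary times within the trajectory span.
#'
#' @param trajectory a `release_trajectory` (or cultivation trajectory).
#' @param times times, h.
#' @return numeric vector of glucose concentrations, g/L.
#' @export
trajectory_glucose <- function(trajectory, times) {
  df <- trajectory$states
  if (any(times < min(df$time_h) - 1e-9 | times > max(df$time_h) + 1e-9))
    stop("requested times outside the trajectory span")
  stats::approx(df$time_h, df$P_gL, xout = times, rule = 2)$y
}
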