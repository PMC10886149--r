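#' Default stock concentrations for bolus additions
#'
#' Stock solutions typical for the robotic cultivation facility: 3000 U/L
#' glucoamylase, 150 g/L maltodextrin and 600 g/L D-glucose; pH-control
#' reagents and water carry no modelled species (stock 0) and act as pure
#' dilution.
#'
#' @param species one of `"enzyme"`, `"dextrin"`, `"glucose"`, `"base"`,
#'   `"acid"`, `"water"`.
#' @return stock concentration in g/L (U/L for enzyme).
#' @export
default_stock <- function(species) {
  species <- match.arg(species, c("enzyme", "dextrin", "glucose",
                                  "base", "acid", "water"))
  switch(species, enzyme = 3000, dextrin = 150, glucose = 600, 0)
}

#' Liquid-handling events
#'
#' `bolus_event()` describes an instantaneous, well-mixed liquid addition;
#' `sample_event()` an instantaneous removal (a sample leaves concentrations
#' unchanged and only reduces the volume).
#'
#' @param time event time, h (>= 0).
#' @param species added species, see [default_stock()].
#' @param volume added (resp. removed) volume, L (> 0).
#' @param stock stock concentration of the added species, g/L or U/L.
#' @param ws_fraction for dextrin additions: susceptible proportion of the
#'   added stock (fresh stock replenishes the susceptible pool with its
#'   initial proportion WS0).  Ignored for other species.
#' @return an event object (classes `bolus_event` / `sample_event`, both
#'   `handling_event`).
#' @export
#' @examples
#' bolus_event(6, "dextrin", 4e-5)
#' sample_event(2, 2e-4)
bolus_event <- function(time, species, volume, stock = default_stock(species),
                        ws_fraction = 0.464) {
  species <- match.arg(species, c("enzyme", "dextrin", "glucose",
                                  "base", "acid", "water"))
  stopifnot(time >= 0, volume > 0, stock >= 0,
            ws_fraction >= 0, ws_fraction <= 1)
  structure(list(time = time, type = "bolus", species = species,
                 volume = volume, stock = stock, ws_fraction = ws_fraction),
            class = c("bolus_event", "handling_event"))
}

#' @rdname bolus_event
#' @export
sample_event <- function(time, volume) {
  stopifnot(time >= 0, volume > 0)
  structure(list(time = time, type = "sample", species = NA_character_,
                 volume = volume, stock = NA_real_, ws_fraction = NA_real_),
            class = c("sample_event", "handling_event"))
}

#' Apply a bolus addition to a state
#'
#' Ideal instantaneous mixing: the volume increases by the bolus volume and
#' every concentration is recomputed from the per-species mass balance
#' `C' = (C V + C_stock v) / (V + v)`, where the stock concentration is
#' non-zero only for the added species.  Added dextrin is split between the
#' pools with the stock's susceptible fraction, so
#' `SS' = (SS V + ws_fraction * stock * v) / V'` and `WS' = SS'/S'`.
#'
#' @param state a [release_state()].
#' @param event a [bolus_event()].
#' @return the post-bolus `release_state`.
#' @export
#' @examples
#' s <- release_state(S = 40, WS = 0.3, V = 0.010)
#' apply_bolus(s, bolus_event(0, "dextrin", 4e-5, stock = 150, ws_fraction = 0.464))
apply_bolus <- function(state, event) {
  validate_release_state(state)
  stopifnot(inherits(event, "bolus_event"))
  V <- state$V
  v <- event$volume
  Vp <- V + v
  f <- V / Vp

  P <- state$P * f
  S <- state$S * f
  SS <- susceptible_substrate(state) * f
  E <- state$E * f

  added <- event$stock * v / Vp
  if (event$species == "glucose") {
    P <- P + added
  } else if (event$species == "enzyme") {
    E <- E + added
  } else if (event$species == "dextrin") {
    S <- S + added
    SS <- SS + event$ws_fraction * added
  }
  WS <- if (S > 0) SS / S else state$WS

  structure(list(P = P, S = S, WS = min(1, max(0, WS)), E = E, V = Vp),
            class = "release_state")
}

#' Apply a sample removal to a state
#'
#' Removal from a well-mixed vessel: concentrations are unchanged, the
#' volume decreases by the sample volume.
#'
#' @param state a [release_state()].
#' @param event a [sample_event()].
#' @return the post-sampling `release_state`.
#' @export
apply_sample <- function(state, event) {
  validate_release_state(state)
  stopifnot(inherits(event, "sample_event"))
  if (event$volume >= state$V)
    stop("sample volume (", event$volume, " L) must be smaller than the vessel volume (",
         state$V, " L)")
  state$V <- state$V - event$volume
  state
}

#' Experiment design: initial state, event schedule and horizon
#'
#' Container describing one vessel run: the initial state, a time-ordered
#' list of handling events and the simulation horizon, plus solver
#' tolerances.
#'
#' @param initial_state a [release_state()].
#' @param events list of [bolus_event()] / [sample_event()] objects; sorted
#'   by time internally (events sharing a timestamp keep their listed order).
#' @param horizon simulation horizon, h.
#' @param rtol,atol relative/absolute solver tolerances.
#' @param id optional experiment identifier (used to match measurements).
#' @return an object of class `experiment_design`.
#' @export
experiment_design <- function(initial_state, events = list(), horizon,
                              rtol = 1e-8, atol = 1e-10, id = NULL) {
  validate_release_state(initial_state)
  stopifnot(horizon > 0, rtol > 0, atol > 0)
  if (length(events)) {
    stopifnot(all(vapply(events, inherits, logical(1), "handling_event")))
    times <- vapply(events, `[[`, numeric(1), "time")
    if (any(times > horizon)) stop("all event times must be <= horizon")
    events <- events[order(times)]  # stable: ties keep listed order
  }
  structure(list(initial_state = initial_state, events = events,
                 horizon = horizon, rtol = rtol, atol = atol, id = id),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("Experiment design%s: horizon %.3g h, %d event(s)\n",
              if (is.null(x$id)) "" else paste0(" '", x$id, "'"),
              x$horizon, length(x$events)))
  print(x$initial_state)
  invisible(x)
}

# internal: event times of a design (numeric(0) when none)
event_times <- function(design) {
  vapply(design$events, `[[`, numeric(1), "time")
}

# internal: apply all events scheduled at one timestamp, in listed order
apply_events_at <- function(state, design, time) {
  for (ev in design$events[event_times(design) == time]) {
    state <- if (ev$type == "bolus") apply_bolus(state, ev)
             else apply_sample(state, ev)
  }
  state
}

#' Bolus volume realizing a target concentration increment
#'
#' Inverts the mixing mass balance: the volume `v` of stock at
#' concentration `C_stock` that raises the vessel concentration from `C` to
#' `C + C_add` after dilution is `v = V (C_target - C) / (C_stock -
#' C_target)`.  Used both for planned enzyme additions and for expressing
#' dextrin/glucose additions as concentration increments.
#'
#' @param V vessel volume, L.
#' @param C current concentration of the species.
#' @param C_add desired post-mixing concentration increment.
#' @param C_stock stock concentration (must exceed `C + C_add`).
#' @return volume to add, L.
#' @export
bolus_volume_for <- function(V, C, C_add, C_stock) {
  C_target <- C + C_add
  if (C_add < 0) stop("concentration increment must be >= 0")
  if (C_add == 0) return(0)
  if (C_target >= C_stock)
    stop("target concentration ", C_target, " is unreachable with stock ", C_stock)
  V * (C_target - C) / (C_stock - C_target)
}
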