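# Macro-kinetic E. coli growth model coupled to the enzymatic release
# kinetics.  The growth side follows the standard overflow-metabolism
# family for aerobic E. coli: Monod glucose uptake, a critical specific
# uptake rate above which the excess is fermented to acetate, acetate
# re-consumption when uptake capacity is spare, constant yields, an oxygen
# balance with kLa transfer to the dissolved-oxygen tension (DOT), and
# first-order product formation with reduced uptake capacity after
# induction.  All coefficients are illustrative defaults to be calibrated
# per strain/process; the release-side parameters are the fitted kinetics.

#' Growth-model parameters
#'
#' @param qS_max maximal specific glucose uptake rate, g/(g h).  With the
#'   default yield the implied maximal growth rate is
#'   `Y_XS * qS_max = 0.7 1/h`.
#' @param Ks glucose affinity constant, g/L.
#' @param Y_XS biomass yield on oxidized glucose, g/g.
#' @param Y_XS_of biomass yield on overflow-metabolized glucose, g/g
#'   (lower than `Y_XS`).
#' @param qS_crit critical specific uptake above which overflow sets in,
#'   g/(g h).
#' @param Y_AS acetate yield on overflow glucose, g/g.
#' @param qA_max maximal specific acetate re-uptake rate, g/(g h).
#' @param KA acetate affinity constant, g/L.
#' @param Y_XA biomass yield on acetate, g/g.
#' @param Y_OS oxygen demand of oxidative glucose metabolism, g O2 / g
#'   glucose.
#' @param Y_OA oxygen demand of acetate metabolism, g O2 / g acetate.
#' @param kLa volumetric oxygen-transfer coefficient, 1/h.
#' @param DO_star dissolved-oxygen solubility at 100 % air saturation, g/L.
#' @param f_ind factor by which the uptake capacity is reduced after
#'   induction (metabolic load of recombinant production), in `[0, 1]`.
#' @param q_prod specific product-formation rate after induction, g/(g h).
#' @param mu_max reference maximal specific growth rate, 1/h (used for
#'   reporting setpoints as fractions; default 0.7).
#' @return an object of class `growth_parameters`.
#' @export
growth_parameters <- function(qS_max = 1.4, Ks = 0.05, Y_XS = 0.5,
                              Y_XS_of = 0.15, qS_crit = 0.8, Y_AS = 0.4,
                              qA_max = 0.2, KA = 0.1, Y_XA = 0.4,
                              Y_OS = 0.5, Y_OA = 1.0, kLa = 800,
                              DO_star = 7.5e-3, f_ind = 0.45,
                              q_prod = 0.05, mu_max = 0.7) {
  gp <- list(qS_max = qS_max, Ks = Ks, Y_XS = Y_XS, Y_XS_of = Y_XS_of,
             qS_crit = qS_crit, Y_AS = Y_AS, qA_max = qA_max, KA = KA,
             Y_XA = Y_XA, Y_OS = Y_OS, Y_OA = Y_OA, kLa = kLa,
             DO_star = DO_star, f_ind = f_ind, q_prod = q_prod,
             mu_max = mu_max)
  stopifnot(all(unlist(gp) > 0), f_ind <= 1)
  structure(gp, class = "growth_parameters")
}

#' State of a cultivation vessel
#'
#' Extends [release_state()] with biomass, acetate, dissolved-oxygen
#' tension and recombinant product.
#'
#' @param X biomass, g/L.
#' @param A acetate, g/L.
#' @param DOT dissolved-oxygen tension, % air saturation, in `[0, 100]`.
#' @param Prod recombinant product, g/L.
#' @inheritParams release_state
#' @return an object of class `culture_state`.
#' @export
culture_state <- function(X = 0, P = 0, S = 0, WS = 0.464, E = 0,
                          V = 0.010, A = 0, DOT = 100, Prod = 0) {
  stopifnot(X >= 0, A >= 0, DOT >= 0, DOT <= 100, Prod >= 0)
  rs <- release_state(P = P, S = S, WS = WS, E = E, V = V)
  structure(c(list(X = X), unclass(rs), list(A = A, DOT = DOT, Prod = Prod)),
            class = "culture_state")
}

# culture state vector order used by the integrator
.culture_names <- c("X", "P", "S", "WS", "E", "V", "A", "DOT", "Prod", "Rcum")

#' Right-hand side of the coupled cultivation model
#'
#' Combines the enzymatic glucose source `nu (rS + rR)` with Monod uptake
#' `qS X`, overflow acetate formation above the critical uptake rate,
#' acetate re-consumption, an oxygen balance driving DOT, and post-induction
#' product formation with reduced uptake capacity.  With `X = 0` the
#' equations reduce exactly to the cell-free release dynamics.
#'
#' @param state a [culture_state()].
#' @param gp a [growth_parameters()].
#' @param rp a [release_parameters()].
#' @param induced logical: has induction occurred?
#' @return named numeric vector of derivatives for
#'   (X, P, S, WS, E, V, A, DOT, Prod).
#' @export
growth_rhs <- function(state, gp, rp, induced = FALSE) {
  rel <- release_rhs(release_state(P = state$P, S = state$S, WS = state$WS,
                                   E = state$E, V = state$V), rp)
  rates <- release_rates(release_state(P = state$P, S = state$S,
                                       WS = state$WS, E = state$E,
                                       V = state$V), rp)
  release <- rp$nu * sum(rates)
  dil <- -rp$r_evap / state$V

  qS <- gp$qS_max * (if (induced) gp$f_ind else 1) * state$P / (state$P + gp$Ks)
  qS_ox <- min(qS, gp$qS_crit)
  qS_of <- qS - qS_ox
  # acetate re-uptake only with spare oxidative capacity
  spare <- max(0, 1 - qS / gp$qS_crit)
  qA <- gp$qA_max * state$A / (state$A + gp$KA) * spare
  mu <- gp$Y_XS * qS_ox + gp$Y_XS_of * qS_of + gp$Y_XA * qA
  q_prod <- if (induced) gp$q_prod else 0
  OUR <- (gp$Y_OS * qS_ox + gp$Y_OA * qA) * state$X

  c(dX = mu * state$X - dil * state$X,
    dP = release - qS * state$X - dil * state$P,
    dS = rel[["dS"]],
    dWS = rel[["dWS"]],
    dE = rel[["dE"]],
    dV = rel[["dV"]],
    dA = (gp$Y_AS * qS_of - qA) * state$X - dil * state$A,
    dDOT = gp$kLa * (100 - state$DOT) - OUR * 100 / gp$DO_star,
    dProd = q_prod * state$X - dil * state$Prod)
}

# bolus/sample application on the culture state: release-side species via
# the release-model rules; X, A, Prod are diluted like any dissolved or
# suspended species; DOT is an intensive sensor signal, unchanged.
.apply_event_culture <- function(y, ev) {
  st <- release_state(P = y[["P"]], S = y[["S"]], WS = y[["WS"]],
                      E = y[["E"]], V = y[["V"]])
  if (ev$type == "bolus") {
    f <- st$V / (st$V + ev$volume)
    st2 <- apply_bolus(st, ev)
    y[["X"]] <- y[["X"]] * f
    y[["A"]] <- y[["A"]] * f
    y[["Prod"]] <- y[["Prod"]] * f
  } else {
    st2 <- apply_sample(st, ev)
  }
  y[c("P", "S", "WS", "E", "V")] <-
    unlist(st2, use.names = FALSE)
  y
}

#' Simulate a cultivation under a feed plan
#'
#' Piecewise integration of [growth_rhs()] with the planned enzyme/dextrin
#' boluses (and any design events) applied between segments, and an
#' induction-time switch of the growth parameters.
#'
#' @param initial_state a [culture_state()] at feed start.
#' @param rp a [release_parameters()].
#' @param gp a [growth_parameters()].
#' @param plan a [plan_feed()] result (its bolus events are applied), or a
#'   list of handling events.
#' @param horizon simulation horizon, h (defaults to the plan's schedule
#'   horizon).
#' @param induction_h induction time, h; `Inf` for no induction.
#' @param times output grid (defaults to 5-min spacing).
#' @param rtol,atol solver tolerances.
#' @return a `culture_trajectory`: list with `states` (data frame with
#'   columns `time_h`, `X_gL`, `P_gL`, `S_gL`, `WS`, `E_UL`, `V_L`,
#'   `A_gL`, `DOT_pct`, `Prod_gL`, `Rcum_gL`) and `events`.
#' @export
simulate_cultivation <- function(initial_state, rp, gp, plan,
                                 horizon = NULL, induction_h = Inf,
                                 times = NULL, rtol = 1e-6, atol = 1e-8) {
  stopifnot(inherits(initial_state, "culture_state"))
  events <- if (inherits(plan, "feed_plan")) plan$events else plan
  if (is.null(horizon)) {
    if (!inherits(plan, "feed_plan"))
      stop("horizon must be given when 'plan' is a plain event list")
    horizon <- plan$schedule$horizon
  }
  if (is.null(times)) times <- seq(0, horizon, by = 1 / 12)
  ev_times <- vapply(events, `[[`, numeric(1), "time")
  times <- sort(unique(c(0, times, ev_times,
                         if (is.finite(induction_h)) induction_h)))
  times <- times[times <= horizon]

  y <- unlist(initial_state, use.names = FALSE)
  names(y) <- .culture_names[1:9]
  y <- c(y, Rcum = 0)

  rhs <- function(t, y, parms) {
    st <- stats::setNames(as.list(pmax(y[1:9], c(0, 0, 0, 0, 0, -Inf, 0, 0, 0))),
                          .culture_names[1:9])
    st$WS <- min(1, st$WS)
    st$DOT <- min(100, st$DOT)
    class(st) <- "culture_state"
    d <- growth_rhs(st, gp, rp, induced = parms$induced)
    reac <- rp$nu * sum(release_rates(release_state(
      P = st$P, S = st$S, WS = st$WS, E = st$E, V = st$V), rp))
    list(c(unname(d), reac))
  }

  boundaries <- sort(unique(c(0, ev_times[ev_times > 0 & ev_times < horizon],
                              if (is.finite(induction_h) && induction_h < horizon)
                                induction_h,
                              horizon)))
  # events at t = 0
  for (ev in events[ev_times == 0]) y <- .apply_event_culture(y, ev)

  out <- matrix(NA_real_, nrow = length(times), ncol = 10)
  for (k in seq_len(length(boundaries) - 1)) {
    a <- boundaries[k]; b <- boundaries[k + 1]
    induced <- is.finite(induction_h) && a >= induction_h
    seg_times <- unique(c(a, times[times > a & times < b], b))
    sol <- deSolve::lsoda(y, seg_times, rhs, parms = list(induced = induced),
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop(sprintf("cultivation solver failed in segment [%g, %g] h", a, b))
    lo <- if (k == 1) a - 1e-12 else a
    for (tt in times[times > lo & times <= b]) {
      ri <- which(abs(sol[, 1] - tt) < 1e-12)[1]
      out[which(times == tt), ] <- sol[ri, -1]
    }
    y <- as.numeric(sol[nrow(sol), -1])
    names(y) <- .culture_names
    y[c(1, 2, 3, 5, 7, 9)] <- pmax(0, y[c(1, 2, 3, 5, 7, 9)])
    y[4] <- min(1, max(0, y[4]))
    for (ev in events[ev_times == b]) y <- .apply_event_culture(y, ev)
  }

  df <- data.frame(time_h = times, X_gL = out[, 1], P_gL = pmax(0, out[, 2]),
                   S_gL = pmax(0, out[, 3]), WS = pmin(1, pmax(0, out[, 4])),
                   E_UL = pmax(0, out[, 5]), V_L = out[, 6],
                   A_gL = pmax(0, out[, 7]), DOT_pct = out[, 8],
                   Prod_gL = pmax(0, out[, 9]), Rcum_gL = out[, 10])
  structure(list(states = df, events = events, induction_h = induction_h,
                 gp = gp, rp = rp),
            class = "culture_trajectory")
}

#' @export
print.culture_trajectory <- function(x, ...) {
  df <- x$states
  n <- nrow(df)
  cat(sprintf("Cultivation trajectory: %d points over %.3g h, %d event(s)\n",
              n, max(df$time_h), length(x$events)))
  cat(sprintf("  final: X = %.2f g/L, P = %.3f g/L, A = %.3f g/L, DOT = %.1f %%, product = %.2f g/L\n",
              df$X_gL[n], df$P_gL[n], df$A_gL[n], df$DOT_pct[n], df$Prod_gL[n]))
  invisible(x)
}

#' @export
as.data.frame.culture_trajectory <- function(x, ...) x$states

#' Observed specific growth rate from a biomass series
#'
#' Slope of the least-squares line through `ln X` versus time over a
#' window, the standard estimator of the specific growth rate from biomass
#' measurements.
#'
#' @param time_h sampling times, h.
#' @param X biomass concentrations, g/L (all > 0 within the window).
#' @param window numeric length-2: time window `[from, to]` (default: all
#'   points).
#' @return estimated specific growth rate, 1/h.
#' @export
#' @examples
#' t <- 0:6
#' observed_mu(t, 3 * exp(0.1 * t))  # 0.1
observed_mu <- function(time_h, X, window = range(time_h)) {
  keep <- time_h >= window[1] & time_h <= window[2]
  t <- time_h[keep]; x <- X[keep]
  if (length(t) < 3) stop("need at least 3 points in the window")
  if (any(x <= 0)) stop("biomass must be positive within the window")
  unname(stats::coef(stats::lm(log(x) ~ t))[2])
}

#' Biomass estimate from the ammonia dosing ledger
#'
#' During pH-controlled growth on ammonium, base consumption tracks
#' nitrogen assimilation, so the cumulative ammonia added gives an
#' independent biomass estimate: moles of NH3 added times a configurable
#' nitrogen-to-biomass factor.
#'
#' @param base_events list of [bolus_event()]s with `species = "base"`.
#' @param molarity molar concentration of the base stock, mol/L (default
#'   7 M ammonia).
#' @param g_biomass_per_mol_N grams of biomass formed per mole of
#'   assimilated nitrogen (default 14.007 / 0.123: E. coli is ~12.3 % N by
#'   mass).
#' @return data frame `time_h`, `X_est_g` (cumulative biomass estimate,
#'   grams).
#' @export
biomass_from_base <- function(base_events, molarity = 7,
                              g_biomass_per_mol_N = 14.007 / 0.123) {
  if (!length(base_events))
    return(data.frame(time_h = numeric(0), X_est_g = numeric(0)))
  stopifnot(all(vapply(base_events, function(e)
    inherits(e, "bolus_event") && e$species == "base", logical(1))))
  tm <- vapply(base_events, `[[`, numeric(1), "time")
  vol <- vapply(base_events, `[[`, numeric(1), "volume")
  o <- order(tm)
  data.frame(time_h = tm[o],
             X_est_g = cumsum(vol[o] * molarity) * g_biomass_per_mol_N)
}

#' Convert optical density to biomass concentration
#'
#' Linear conversion with the facility's calibration factor (0.37 g/L
#' biomass per OD600 unit); `od_from_biomass()` is its inverse.
#'
#' @param od600 optical density at 600 nm.
#' @param factor g/L biomass per OD600 unit.
#' @return biomass, g/L (resp. OD600).
#' @export
biomass_from_od <- function(od600, factor = 0.37) od600 * factor

#' @rdname biomass_from_od
#' @param X biomass, g/L.
#' @export
od_from_biomass <- function(X, factor = 0.37) X / factor
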