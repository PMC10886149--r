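# Synthetic experiment designs and noisy measurement sets emulating the
# study conditions of the cell-free release campaign (data set 1: 24
# mini-bioreactor runs, 11 mL, 30 h, factorial levels of initial dextrin,
# glucose and enzyme, with mid-run dextrin/glucose additions at 6 h) and
# the fed-batch campaigns (data sets 2 and 3).

#' Additive Gaussian measurement-noise model
#'
#' Observations are the simulated glucose plus independent Gaussian noise,
#' truncated at zero.  The glucose analyzer's precision is not a published
#' constant; 0.2 g/L is the package default for synthetic studies.
#'
#' @param sigma noise standard deviation, g/L (>= 0).
#' @param seed integer seed.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(sigma = 0.2, seed = 1L) {
  stopifnot(sigma >= 0)
  structure(list(sigma = sigma, seed = as.integer(seed)),
            class = "noise_model")
}

# factor levels of the cell-free release campaign
.ds1_levels <- list(D0 = c(15, 30), G0 = c(0, 3.75, 7.5, 15),
                    E0 = c(10, 20), Dadd = c(0, 5.25, 10.5),
                    Gadd = c(0, 3.75, 7.5))

#' Cell-free release experiment designs (data set 1)
#'
#' Returns the 24 experiment designs of the model-calibration campaign:
#' 11 mL initial volume, 30 h horizon, initial dextrin D0 in \{15, 30\},
#' glucose G0 in \{0, 3.75, 7.5, 15\} g/L and enzyme E0 in \{10, 20\} U/L,
#' with dextrin/glucose additions (Dadd in \{0, 5.25, 10.5\}, Gadd in
#' \{0, 3.75, 7.5\} g/L) applied at 6 h to part of the runs.  The exact
#' run-by-run allocation is a deterministic choice covering every factor
#' level: the 16-run full factorial of (D0, G0, E0) without additions,
#' plus 8 runs carrying the non-zero addition patterns.
#'
#' Additions are expressed as net concentration increments and converted
#' to stock volumes (150 g/L dextrin, 600 g/L glucose) via the dilution
#' mass balance.  Sampling is on a 2 h grid; by default the 200 uL sample
#' removals are not inserted as events (they leave concentrations
#' unchanged and perturb later dilution only at the sub-percent level on
#' 11 mL); set `include_sampling = TRUE` for closed-loop realism.
#'
#' @param WS0 susceptible fraction of fresh dextrin stock used for the
#'   addition events.
#' @param include_sampling insert 200 uL [sample_event()]s at the sampling
#'   times.
#' @param horizon horizon, h.
#' @param sample_every sampling interval, h.
#' @return named list of 24 [experiment_design()] objects
#'   (`ds1_01` ... `ds1_24`), each carrying a `condition` attribute with
#'   the factor levels.
#' @export
dataset1_designs <- function(WS0 = 0.464, include_sampling = FALSE,
                             horizon = 30, sample_every = 2) {
  lev <- .ds1_levels
  base <- expand.grid(D0 = lev$D0, E0 = lev$E0, G0 = lev$G0,
                      KEEP.OUT.ATTRS = FALSE)
  base$Dadd <- 0
  base$Gadd <- 0
  extra <- data.frame(
    D0 = rep(lev$D0, each = 4),
    E0 = rep(lev$E0, 4),
    G0 = rep(c(0, 7.5), 4),
    Dadd = c(5.25, 10.5, 5.25, 10.5, 0, 0, 10.5, 5.25),
    Gadd = c(0, 0, 3.75, 7.5, 3.75, 7.5, 7.5, 3.75)
  )
  cond <- rbind(base, extra)
  stopifnot(nrow(cond) == 24)

  sample_times <- seq(sample_every, horizon, by = sample_every)
  designs <- vector("list", nrow(cond))
  for (i in seq_len(nrow(cond))) {
    ci <- cond[i, ]
    V0 <- 0.011
    events <- list()
    if (ci$Dadd > 0) {
      v <- bolus_volume_for(V0, ci$D0, ci$Dadd, default_stock("dextrin"))
      events <- c(events, list(bolus_event(6, "dextrin", v,
                                           ws_fraction = WS0)))
    }
    if (ci$Gadd > 0) {
      v <- bolus_volume_for(V0, ci$G0, ci$Gadd, default_stock("glucose"))
      events <- c(events, list(bolus_event(6, "glucose", v)))
    }
    if (include_sampling) {
      events <- c(events, lapply(sample_times, sample_event, volume = 2e-4))
    }
    d <- experiment_design(
      release_state(P = ci$G0, S = ci$D0, WS = WS0, E = ci$E0, V = V0),
      events = events, horizon = horizon,
      id = sprintf("ds1_%02d", i))
    attr(d, "condition") <- as.list(ci)
    designs[[i]] <- d
  }
  names(designs) <- vapply(designs, `[[`, character(1), "id")
  designs
}

#' @rdname dataset1_designs
#' @return `dataset1_sampling_times()` returns the default 2 h sampling
#'   grid used for measurement generation.
#' @export
dataset1_sampling_times <- function(horizon = 30, sample_every = 2) {
  seq(sample_every, horizon, by = sample_every)
}

# condition table of the fed-batch campaigns
.ds23_conditions <- function() {
  data.frame(
    condition = c(1:8, 9:13),
    dataset = c(rep(2L, 8), rep(3L, 5)),
    feed_method = c("bolus", "bolus", "enzymatic", "enzymatic",
                    "enzymatic_two_additions", "enzymatic_two_additions",
                    "enzymatic", "enzymatic",
                    "enzymatic", "enzymatic", "enzymatic_two_additions",
                    "enzymatic", "enzymatic"),
    mu_set_pre = c(0.18, 0.21, 0.18, 0.21, 0.18, 0.21, 0.18, 0.21,
                   0.14, 0.21, 0.25, 0.14, 0.21),
    mu_set_post = c(0.09, 0.11, 0.09, 0.11, 0.09, 0.11, 0.09, 0.11,
                    0.07, 0.11, 0.12, 0.07, 0.11),
    G0 = c(5, 5, 5, 5, 5, 5, 0, 0, 5, 5, 5, 0, 0),
    D0 = c(2, 2, 40, 40, 40, 40, 40, 40, 40, 40, 80, 40, 40),
    cells = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE,
              TRUE, TRUE, TRUE, FALSE, FALSE)
  )
}

#' Fed-batch experiment designs (data sets 2 and 3)
#'
#' Triplicated conditions of the two fed-batch cultivation campaigns:
#' bolus-fed controls, enzymatic-feed conditions at different
#' growth-rate setpoints (switched to a reduced setpoint at induction,
#' 6 h after feed start) and cell-free release controls.  Initial volume
#' 10 mL.  Returns design descriptors (initial state, setpoint schedule,
#' feed method) from which a feed plan can be built with [plan_feed()].
#'
#' @param which data set, 2 or 3.
#' @param WS0 susceptible fraction for the initial dextrin.
#' @param feed_h length of the feeding phase, h (6 h exponential phase +
#'   4 h induction phase by default).
#' @return list of design descriptors, one per replicate: each a list with
#'   `id`, `condition`, `feed_method`, `cells`, `design` (an
#'   [experiment_design()] at feed start) and `schedule` (a
#'   [setpoint_schedule()]).
#' @export
dataset23_designs <- function(which, WS0 = 0.464, feed_h = 10) {
  stopifnot(which %in% c(2, 3))
  tab <- .ds23_conditions()
  tab <- tab[tab$dataset == which, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(tab))) {
    ci <- tab[i, ]
    for (rep_i in 1:3) {
      id <- sprintf("ds%d_c%02d_r%d", which, ci$condition, rep_i)
      design <- experiment_design(
        release_state(P = ci$G0, S = ci$D0, WS = WS0, E = 0, V = 0.010),
        horizon = feed_h, id = id)
      schedule <- setpoint_schedule(
        data.frame(start_h = c(0, 6),
                   mu_set = c(ci$mu_set_pre, ci$mu_set_post)),
        dt = 1/6, horizon = feed_h, induction_h = 6)
      out[[id]] <- list(id = id, condition = ci$condition,
                        feed_method = ci$feed_method,
                        mu_set_pre = ci$mu_set_pre,
                        mu_set_post = ci$mu_set_post,
                        cells = ci$cells, design = design,
                        schedule = schedule)
    }
  }
  out
}

#' Generate noisy glucose measurements from a trajectory
#'
#' Samples the simulated glucose at the given times and adds truncated
#' Gaussian noise; reproducible per seed.
#'
#' @param trajectory a `release_trajectory` (or `culture_trajectory`).
#' @param times sampling times, h, within the trajectory span.
#' @param noise a [noise_model()].
#' @param experiment_id identifier for the resulting measurement rows.
#' @return a [measurement_set()] data frame.
#' @export
generate_measurements <- function(trajectory, times,
                                  noise = noise_model(),
                                  experiment_id = "exp1") {
  sim <- trajectory_glucose(trajectory, times)
  set.seed(noise$seed)
  obs <- pmax(0, sim + stats::rnorm(length(sim), 0, noise$sigma))
  measurement_set(experiment_id = rep(experiment_id, length(times)),
                  time_h = times, glucose_gL = obs, sd = noise$sigma)
}

#' Simulate the full cell-free campaign and generate its measurements
#'
#' Convenience wrapper for the package's core calibration loop: builds the
#' 24 designs of [dataset1_designs()], simulates each with the given
#' parameters and collects noisy glucose observations on the sampling
#' grid.  Per-experiment seeds are derived deterministically from `seed`.
#'
#' @param params a [release_parameters()] (the generating truth).
#' @param sigma measurement noise, g/L.
#' @param seed integer master seed.
#' @param variant generating kinetic variant.
#' @param ... passed to [dataset1_designs()].
#' @return list with `designs` (the 24 designs) and `data` (one
#'   [measurement_set()] covering all experiments).
#' @export
simulate_dataset1 <- function(params = release_parameters(), sigma = 0.2,
                              seed = 1L, variant = "two_substrate", ...) {
  designs <- dataset1_designs(WS0 = params$WS0, ...)
  times <- dataset1_sampling_times()
  sets <- vector("list", length(designs))
  for (i in seq_along(designs)) {
    traj <- simulate_release(designs[[i]], params, variant, times = times)
    sets[[i]] <- generate_measurements(
      traj, times, noise_model(sigma, seed = seed * 1000L + i),
      experiment_id = designs[[i]]$id)
  }
  data <- do.call(rbind, sets)
  class(data) <- c("measurement_set", "data.frame")
  list(designs = designs, data = data)
}
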