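# File I/O: structured configs (YAML/JSON) for parameters, designs and
# schedules; tidy delimited text for trajectories, measurements, feed
# plans and comparison tables.  Every tabular output carries a comment
# header recording the package version and, where applicable, the seed,
# so a run can be reproduced from its artifacts.

.enzfeed_header <- function(seed = NULL, extra = NULL) {
  h <- sprintf("# enzfeed %s",
               as.character(utils::packageVersion("enzfeed")))
  if (!is.null(seed)) h <- paste0(h, " seed=", seed)
  if (!is.null(extra)) h <- paste0(h, " ", extra)
  h
}

.write_tsv <- function(df, path, seed = NULL, extra = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.enzfeed_header(seed, extra), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Read and write release parameters
#'
#' Parameters are serialized as a flat key-value block, YAML or JSON by
#' file extension.
#'
#' @param params a [release_parameters()].
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return `read_parameters()` returns a `release_parameters` object.
#' @export
write_parameters <- function(params, path) {
  validate_release_parameters(params)
  x <- lapply(unclass(params), function(v) if (is.infinite(v)) ".inf" else v)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(unclass(params), path, auto_unbox = TRUE,
                         digits = NA)
  } else {
    yaml::write_yaml(x, path, precision = 12)
  }
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  x <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
       else yaml::read_yaml(path)
  x <- lapply(x, function(v) {
    if (is.character(v) && v %in% c(".inf", "Inf", ".Inf")) Inf else as.numeric(v)
  })
  do.call(release_parameters, x)
}

#' Read and write experiment designs
#'
#' A design is serialized as a YAML (or JSON) document with the initial
#' state, solver settings and the event table.
#'
#' @param design an [experiment_design()].
#' @param path file path.
#' @return `read_design()` returns an `experiment_design`.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "experiment_design"))
  ev <- lapply(design$events, function(e)
    list(time = e$time, type = e$type, species = e$species,
         volume = e$volume, stock = e$stock, ws_fraction = e$ws_fraction))
  x <- list(id = design$id,
            initial_state = unclass(design$initial_state),
            horizon = design$horizon, rtol = design$rtol,
            atol = design$atol, events = ev)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    yaml::write_yaml(x, path, precision = 12)
  }
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  x <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = FALSE)
       else yaml::read_yaml(path)
  events <- lapply(x$events, function(e) {
    if (e$type == "bolus") {
      bolus_event(e$time, e$species, e$volume, stock = e$stock,
                  ws_fraction = if (is.null(e$ws_fraction) ||
                                    is.na(e$ws_fraction)) 0.464
                                else e$ws_fraction)
    } else {
      sample_event(e$time, e$volume)
    }
  })
  experiment_design(do.call(release_state, x$initial_state),
                    events = events, horizon = x$horizon,
                    rtol = x$rtol, atol = x$atol, id = x$id)
}

#' Read and write measurement sets
#'
#' Delimited text with columns `experiment_id`, `time_h`, `glucose_gL`,
#' `sd`.
#'
#' @param data a [measurement_set()] data frame.
#' @param path file path.
#' @param seed optional seed recorded in the file header.
#' @return `read_measurements()` returns a `measurement_set`.
#' @export
write_measurements <- function(data, path, seed = NULL) {
  .write_tsv(as.data.frame(data), path, seed = seed)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  df <- .read_tsv(path)
  measurement_set(df$experiment_id, df$time_h, df$glucose_gL,
                  sd = if ("sd" %in% names(df)) df$sd else NA_real_)
}

#' Write a trajectory as tidy delimited text
#'
#' Columns `time_h`, `P_gL`, `S_gL`, `WS`, `SS_gL`, `SR_gL`, `E_UL`,
#' `V_L` (plus the growth observables for cultivation trajectories).
#'
#' @param trajectory a `release_trajectory` or `culture_trajectory`.
#' @param path file path.
#' @return `read_trajectory()` returns the states data frame.
#' @export
write_trajectory <- function(trajectory, path) {
  .write_tsv(trajectory$states, path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) .read_tsv(path)

#' Write a feed plan (feed-calculator table)
#'
#' The deliverable for manual or automated execution: one row per grid
#' time with the target rate, the enzyme increment and the stock volumes
#' to pipette.
#'
#' @param plan a [plan_feed()] result.
#' @param path file path.
#' @param cumulate merge additions closer than `cumulate` hours into the
#'   earliest action of the group (for manual pipetting); `0` leaves the
#'   grid untouched.
#' @return invisibly, the written table.
#' @export
write_feed_plan <- function(plan, path, cumulate = 0) {
  stopifnot(inherits(plan, "feed_plan"))
  tab <- plan$plan
  if (cumulate > 0) {
    grp <- floor(tab$time_h / cumulate + 1e-9)
    tab <- do.call(rbind, lapply(split(tab, grp), function(g)
      data.frame(time_h = g$time_h[1],
                 r_target = g$r_target[1],
                 r_current = g$r_current[1],
                 E_add_UL = sum(g$E_add_UL),
                 enzyme_uL = sum(g$enzyme_uL),
                 dextrin_uL = sum(g$dextrin_uL))))
    rownames(tab) <- NULL
  }
  .write_tsv(tab, path)
  invisible(tab)
}

#' Write a fit result as a JSON report
#'
#' @param fit a `release_fit` from [fit_local()] or [fit_global()].
#' @param path file path.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "release_fit"))
  x <- list(variant = fit$variant,
            estimates = as.list(fit$estimates),
            sd = as.list(fit$sd),
            rss = fit$rss, nfev = fit$nfev,
            seed = if (is.na(fit$seed)) NULL else fit$seed,
            parameters = lapply(unclass(fit$parameters),
                                function(v) if (is.infinite(v)) "Inf" else v))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Write a variant-comparison table
#'
#' Delimited text mirroring the model-selection table: one row per
#' variant with its label and residual sum of squared errors.
#'
#' @param comparison a [compare_variants()] result.
#' @param path file path.
#' @export
write_comparison <- function(comparison, path) {
  stopifnot(inherits(comparison, "variant_comparison"))
  .write_tsv(comparison$table, path, seed = comparison$seed)
}

#' Read and write setpoint schedules
#'
#' YAML/JSON document with the phase table (`start_h`, `mu_set`), the grid
#' interval, horizon and induction time.
#'
#' @param schedule a [setpoint_schedule()].
#' @param path file path.
#' @return `read_schedule()` returns a `setpoint_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "setpoint_schedule"))
  x <- list(phases = lapply(seq_len(nrow(schedule$phases)), function(i)
              as.list(schedule$phases[i, ])),
            dt = schedule$dt, horizon = schedule$horizon,
            induction_h = if (is.na(schedule$induction_h)) NULL
                          else schedule$induction_h)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    yaml::write_yaml(x, path, precision = 12)
  }
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  x <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = FALSE)
       else yaml::read_yaml(path)
  phases <- do.call(rbind, lapply(x$phases, function(p)
    data.frame(start_h = p$start_h, mu_set = p$mu_set)))
  setpoint_schedule(phases, dt = x$dt, horizon = x$horizon,
                    induction_h = if (is.null(x$induction_h)) NA_real_
                                  else x$induction_h)
}
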