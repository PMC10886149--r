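# Simultaneous multi-experiment parameter estimation.
#
# All experiments are fitted at once: a single residual vector concatenates
# (simulated - observed) glucose over every experiment and sampling time.
# The global search is a self-adaptive differential evolution over box
# bounds; the local stage is bounded Levenberg-Marquardt least squares
# (minpack.lm), which also supplies linearized standard deviations.

#' Assemble a measurement set
#'
#' A measurement set is a plain data frame with columns `experiment_id`,
#' `time_h`, `glucose_gL` and optionally `sd`; this helper validates and
#' normalizes one.
#'
#' @param experiment_id experiment identifiers (character).
#' @param time_h sampling times, h.
#' @param glucose_gL observed free glucose, g/L (>= 0).
#' @param sd optional measurement standard deviations, g/L.
#' @return a `data.frame` of class `measurement_set`.
#' @export
measurement_set <- function(experiment_id, time_h, glucose_gL, sd = NA_real_) {
  stopifnot(length(time_h) == length(glucose_gL),
            all(glucose_gL >= 0), all(time_h >= 0))
  df <- data.frame(experiment_id = as.character(experiment_id),
                   time_h = time_h, glucose_gL = glucose_gL, sd = sd)
  class(df) <- c("measurement_set", "data.frame")
  df
}

# designs keyed by experiment id
.designs_by_id <- function(designs) {
  if (is.null(names(designs)) || any(names(designs) == "")) {
    ids <- vapply(designs, function(d) {
      if (is.null(d$id)) stop("designs must be named or carry an 'id'")
      as.character(d$id)
    }, character(1))
    names(designs) <- ids
  }
  designs
}

# Precompute everything that does not change between objective evaluations.
.fit_context <- function(designs, data, weighted = FALSE) {
  designs <- .designs_by_id(designs)
  ids <- unique(data$experiment_id)
  missing <- setdiff(ids, names(designs))
  if (length(missing))
    stop("no design for experiment(s): ", paste(missing, collapse = ", "))
  designs <- designs[ids]

  all_meas <- sort(unique(data$time_h))
  all_ev <- sort(unique(unlist(lapply(designs, event_times))))
  out_times <- sort(unique(c(0, all_meas, all_ev)))
  out_times <- out_times[out_times <= max(all_meas)]

  meas_idx <- vector("list", length(ids))
  obs <- numeric(0)
  wts <- numeric(0)
  for (i in seq_along(ids)) {
    di <- data[data$experiment_id == ids[i], , drop = FALSE]
    bad <- di$time_h > designs[[i]]$horizon
    if (any(bad))
      stop("measurements beyond the design horizon for ", ids[i])
    meas_idx[[i]] <- match(di$time_h, out_times)
    obs <- c(obs, di$glucose_gL)
    w <- if (weighted && !all(is.na(di$sd))) 1 / di$sd else rep(1, nrow(di))
    wts <- c(wts, w)
  }
  y0 <- t(vapply(designs, function(d) state_to_vector(d$initial_state),
                 numeric(6)))
  list(ids = ids, designs = designs, out_times = out_times,
       meas_idx = meas_idx, obs = obs, wts = wts, y0 = y0,
       rtol = designs[[1]]$rtol, atol = designs[[1]]$atol)
}

# WS0 is an initial-condition parameter: each candidate value resets the
# initial susceptible proportion of every experiment and the susceptible
# fraction of any added dextrin stock.
.ctx_apply_ws0 <- function(ctx, WS0) {
  ctx$y0[, 3] <- WS0
  ctx$designs <- lapply(ctx$designs, function(d) {
    d$events <- lapply(d$events, function(e) {
      if (e$type == "bolus" && identical(e$species, "dextrin"))
        e$ws_fraction <- WS0
      e
    })
    d
  })
  ctx
}

.ctx_residuals <- function(ctx, params, variant) {
  if (variant_is_two_substrate(variant)) ctx <- .ctx_apply_ws0(ctx, params$WS0)
  arr <- tryCatch(
    .integrate_group(ctx$y0, ctx$designs, ctx$out_times, params, variant,
                     ctx$rtol, ctx$atol),
    error = function(e) stop("simulation failed (", conditionMessage(e),
                             ") for experiment set ",
                             paste(ctx$ids, collapse = ","), call. = FALSE))
  sim <- unlist(lapply(seq_along(ctx$ids),
                       function(i) arr[i, ctx$meas_idx[[i]], 1]))
  (sim - ctx$obs) * ctx$wts
}

#' Residual sum of squares of a parameter set
#'
#' Simulates every experiment with the given parameters and variant and
#' returns the sum over all experiments and sampling times of the squared
#' glucose residuals (simulated minus observed).
#'
#' For two-substrate variants `params$WS0` is an initial-condition
#' parameter: it overrides the initial susceptible proportion stored in
#' each design and the susceptible fraction of added dextrin stock, so
#' that WS0 can be estimated alongside the catalytic constants.
#'
#' @param params a [release_parameters()].
#' @param designs list of [experiment_design()] objects, named by experiment
#'   id (or carrying `id` fields) matching `data$experiment_id`.
#' @param data a [measurement_set()] data frame.
#' @param variant kinetic variant tag.
#' @param weighted if `TRUE` and `data$sd` is available, residuals are
#'   divided by the per-point standard deviation.
#' @return scalar RSS (g/L)^2.
#' @export
release_rss <- function(params, designs, data, variant = "two_substrate",
                        weighted = FALSE) {
  ctx <- .fit_context(designs, data, weighted)
  sum(.ctx_residuals(ctx, params, variant)^2)
}

.default_bounds <- function(free) {
  lower <- c(kS = 1e-5, kR = 1e-5, k_single = 1e-5, WS0 = 0,
             KiP = 0.1, KiS = 0.1)
  upper <- c(kS = 1, kR = 1, k_single = 1, WS0 = 1,
             KiP = 1000, KiS = 1000)
  list(lower = lower[free], upper = upper[free])
}

.params_with <- function(base, free, values) {
  base[free] <- as.list(values)
  structure(base, class = "release_parameters")
}

.make_fit_result <- function(variant, params, free, estimates, sds, rss,
                             nfev, seed = NA_integer_, message = "") {
  structure(list(variant = variant, parameters = params, free = free,
                 estimates = estimates, sd = sds, rss = rss, nfev = nfev,
                 seed = seed, message = message),
            class = "release_fit")
}

#' @export
print.release_fit <- function(x, ...) {
  cat(sprintf("Fit of variant '%s': RSS = %.6g (%d residual evaluations)\n",
              x$variant, x$rss, x$nfev))
  for (nm in x$free) {
    sd <- x$sd[[nm]]
    cat(sprintf("  %-9s = %.6g%s\n", nm, x$estimates[[nm]],
                if (is.finite(sd)) sprintf("  (sd %.3g, %.2f%%)", sd,
                                           100 * sd / abs(x$estimates[[nm]]))
                else ""))
  }
  invisible(x)
}

#' Local (Levenberg-Marquardt) parameter fit
#'
#' Bounded nonlinear least squares from a starting point, minimizing
#' [release_rss()] over the listed free parameters.  Standard deviations
#' are the usual linearized values at the optimum,
#' `sqrt(diag(RSS/(n-p) * (J'J)^-1))`.
#'
#' @param start a [release_parameters()] supplying the starting values of
#'   the free parameters and the fixed values of all others (K is fixed by
#'   default: at working dextrin concentrations it is not identifiable).
#' @inheritParams release_rss
#' @param free names of the parameters to estimate; defaults to the
#'   variant's canonical free set ([variant_free_parameters()]).
#' @param lower,upper named bounds for the free parameters; default bounds
#'   span the literature range (catalytic constants 1e-5..1 g/(U h), WS0 in
#'   0..1, inhibition constants 0.1..1000 g/L).
#' @return a `release_fit` object: variant tag, fitted parameter set,
#'   per-parameter estimates and standard deviations, final RSS and
#'   evaluation count.
#' @export
fit_local <- function(start, designs, data, variant = "two_substrate",
                      free = variant_free_parameters(variant),
                      lower = NULL, upper = NULL, weighted = FALSE) {
  variant <- match.arg(variant, model_variants())
  validate_release_parameters(start)
  b <- .default_bounds(free)
  if (!is.null(lower)) b$lower[names(lower)] <- lower
  if (!is.null(upper)) b$upper[names(upper)] <- upper
  par0 <- unlist(start[free])
  if (any(par0 < b$lower - 1e-12) || any(par0 > b$upper + 1e-12))
    stop("starting values must lie within the bounds")

  ctx <- .fit_context(designs, data, weighted)
  fn <- function(p) .ctx_residuals(ctx, .params_with(start, free, p), variant)
  fit <- minpack.lm::nls.lm(par = par0, lower = unname(b$lower),
                            upper = unname(b$upper), fn = fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-12, ptol = 1e-12))
  est <- stats::setNames(as.numeric(fit$par), free)
  rss <- sum(fit$fvec^2)
  sds <- rep(NA_real_, length(free))
  names(sds) <- free
  sds_try <- tryCatch({
    co <- summary(fit)$coefficients
    stats::setNames(co[, "Std. Error"], free)
  }, error = function(e) NULL)
  if (!is.null(sds_try)) sds <- sds_try
  if (fit$info == 0)
    warning("local fit did not converge: ", fit$message, " (RSS ", rss, ")")
  .make_fit_result(variant, .params_with(start, free, est), free, est, sds,
                   rss, length(fit$rsstrace),
                   message = fit$message)
}

# Self-adaptive differential evolution (jDE scheme: per-member F and CR,
# regenerated with probability 0.1 each generation) over box bounds.
# Deterministic for a given seed.
.de_optimize <- function(fn, lower, upper, population = 20,
                         generations = 200, seed = NULL, fold = identity) {
  if (!is.null(seed)) set.seed(seed)
  d <- length(lower)
  stopifnot(length(upper) == d, all(is.finite(lower)), all(is.finite(upper)),
            population >= 4)
  pop <- sapply(seq_len(d), function(j)
    stats::runif(population, lower[j], upper[j]))
  pop <- matrix(pop, nrow = population)
  folded <- apply(pop, 1, function(x) pmin(pmax(fold(x), lower), upper))
  pop <- if (d == 1) matrix(folded, ncol = 1) else t(folded)
  fvals <- apply(pop, 1, fn)
  Fv <- rep(0.5, population)
  CRv <- rep(0.9, population)
  for (g in seq_len(generations)) {
    for (i in seq_len(population)) {
      Fi <- if (stats::runif(1) < 0.1) 0.1 + 0.9 * stats::runif(1) else Fv[i]
      CRi <- if (stats::runif(1) < 0.1) stats::runif(1) else CRv[i]
      r <- sample(seq_len(population)[-i], 3)
      v <- pop[r[1], ] + Fi * (pop[r[2], ] - pop[r[3], ])
      v <- pmin(pmax(v, lower), upper)
      jrand <- sample.int(d, 1)
      cross <- stats::runif(d) < CRi
      cross[jrand] <- TRUE
      u <- ifelse(cross, v, pop[i, ])
      u <- pmin(pmax(fold(u), lower), upper)
      fu <- fn(u)
      if (fu <= fvals[i]) {
        pop[i, ] <- u
        fvals[i] <- fu
        Fv[i] <- Fi
        CRv[i] <- CRi
      }
    }
  }
  best <- which.min(fvals)
  list(par = pop[best, ], value = fvals[best],
       nfev = population * (generations + 1))
}

# The two-pool model is invariant under relabelling the pools:
# (kS, kR, WS0) and (kR, kS, 1 - WS0) produce identical trajectories.
# The canonical labelling has the susceptible pool as the fast one
# (kS >= kR); folding candidates onto that half-space removes the
# mirrored optimum from the global search.
.canonicalize_pools <- function(params) {
  if (params$kS < params$kR) {
    tmp <- params$kS
    params$kS <- params$kR
    params$kR <- tmp
    params$WS0 <- 1 - params$WS0
  }
  params
}

#' Global (differential evolution) parameter fit
#'
#' Self-adaptive differential evolution (population 20, 200 generations by
#' default) over finite box bounds, followed by a [fit_local()] polish from
#' the best population member.  Deterministic for a given seed.
#'
#' @inheritParams fit_local
#' @param params a [release_parameters()] supplying the fixed (non-free)
#'   parameter values.
#' @param population,generations DE population size and generation count.
#' @param seed integer seed for the stochastic search (mandatory).
#' @param polish run the local polish (default `TRUE`).
#' @return a `release_fit` object (see [fit_local()]); its `seed` field
#'   records the seed.
#' @export
fit_global <- function(designs, data, variant = "two_substrate",
                       free = variant_free_parameters(variant),
                       params = release_parameters(),
                       lower = NULL, upper = NULL,
                       population = 20, generations = 200, seed,
                       polish = TRUE, weighted = FALSE) {
  variant <- match.arg(variant, model_variants())
  if (missing(seed)) stop("a seed is required for the global fit")
  b <- .default_bounds(free)
  if (!is.null(lower)) b$lower[names(lower)] <- lower
  if (!is.null(upper)) b$upper[names(upper)] <- upper

  ctx <- .fit_context(designs, data, weighted)
  canonical <- variant_is_two_substrate(variant) &&
    all(c("kS", "kR", "WS0") %in% free)
  fn <- function(p) sum(.ctx_residuals(ctx, .params_with(params, free, p),
                                       variant)^2)
  fold <- if (canonical) {
    i_kS <- match("kS", free); i_kR <- match("kR", free)
    i_WS <- match("WS0", free)
    function(p) {
      if (p[i_kS] < p[i_kR]) {
        p[c(i_kS, i_kR)] <- p[c(i_kR, i_kS)]
        p[i_WS] <- 1 - p[i_WS]
      }
      p
    }
  } else identity
  de <- .de_optimize(fn, unname(b$lower), unname(b$upper),
                     population = population, generations = generations,
                     seed = seed, fold = fold)
  start <- .params_with(params, free, pmin(pmax(de$par, b$lower), b$upper))
  if (canonical) {
    start <- .canonicalize_pools(start)
    start[free] <- pmin(pmax(unlist(start[free]), b$lower), b$upper)
  }
  if (polish) {
    out <- fit_local(start, designs, data, variant, free,
                     lower = b$lower, upper = b$upper, weighted = weighted)
    # keep the better of DE best and polished optimum (polish can only help
    # numerically, but guard against pathological steps)
    if (out$rss > de$value + 1e-12) {
      est <- stats::setNames(de$par, free)
      out <- .make_fit_result(variant, start, free, est,
                              stats::setNames(rep(NA_real_, length(free)), free),
                              de$value, de$nfev)
    }
    out$nfev <- out$nfev + de$nfev
  } else {
    est <- stats::setNames(de$par, free)
    out <- .make_fit_result(variant, start, free, est,
                            stats::setNames(rep(NA_real_, length(free)), free),
                            de$value, de$nfev)
  }
  out$seed <- seed
  out
}

#' Compare kinetic variants by residual sum of squares
#'
#' Runs one global+local fit per variant on the same measurement set and
#' tabulates the resulting RSS values in the canonical variant order, from
#' the single-substrate family to the two-substrate family.
#'
#' @inheritParams fit_global
#' @param variants variant tags to fit (default: all seven).
#' @return an object of class `variant_comparison`: a list with `table`
#'   (data frame: `variant`, `label`, `rss`, `n_free`) and `fits` (named
#'   list of `release_fit` objects; a variant whose fit fails is recorded
#'   with `NA` RSS rather than aborting the comparison).
#' @export
compare_variants <- function(designs, data, variants = model_variants(),
                             params = release_parameters(),
                             population = 20, generations = 200, seed,
                             weighted = FALSE) {
  variants <- match.arg(variants, model_variants(), several.ok = TRUE)
  variants <- model_variants()[model_variants() %in% variants]
  fits <- stats::setNames(vector("list", length(variants)), variants)
  for (v in variants) {
    fits[[v]] <- tryCatch(
      fit_global(designs, data, variant = v, params = params,
                 population = population, generations = generations,
                 seed = seed, weighted = weighted),
      error = function(e) structure(list(variant = v, rss = NA_real_,
                                         message = conditionMessage(e)),
                                    class = "release_fit_failure"))
  }
  tab <- data.frame(
    variant = variants,
    label = vapply(variants, variant_label, character(1)),
    rss = vapply(fits, function(f) if (inherits(f, "release_fit")) f$rss
                 else NA_real_, numeric(1)),
    n_free = vapply(variants, function(v) length(variant_free_parameters(v)),
                    integer(1)),
    row.names = NULL
  )
  structure(list(table = tab, fits = fits, seed = seed),
            class = "variant_comparison")
}

#' @export
print.variant_comparison <- function(x, ...) {
  cat("Model-variant comparison (residual sum of squared errors)\n")
  tab <- x$table
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-60s %s\n", tab$label[i],
                ifelse(is.na(tab$rss[i]), "failed",
                       formatC(tab$rss[i], digits = 4, format = "g"))))
  invisible(x)
}
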