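#' Population state over the size mesh
#'
#' A population is the vector of female abundances per length bin plus a
#' day counter.  Abundances are continuous (the projection is
#' deterministic; no demographic stochasticity).
#'
#' @param abundance Non-negative numeric vector, one entry per grid bin.
#' @param day Integer day index (>= 0).
#' @param grid The [size_grid()] the abundances refer to.
#' @return An object of class `"population_state"`.
#' @export
population_state <- function(abundance, grid, day = 0L) {
  stopifnot(inherits(grid, "size_grid"),
            is.numeric(abundance), length(abundance) == grid$n_bins,
            all(is.finite(abundance)), all(abundance >= 0), day >= 0)
  structure(list(abundance = as.numeric(abundance), day = as.integer(day),
                 grid = grid),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("population state at day %d: total %.4g females over %d bins\n",
              x$day, sum(x$abundance), x$grid$n_bins))
  invisible(x)
}

#' Project the population one day forward
#'
#' Left-multiplies the abundance vector by the daily kernel matrix and
#' increments the day counter.
#'
#' @param state A [population_state()].
#' @param kernel A [build_kernel()] result sharing the state's grid.
#' @return The next day's `"population_state"`.
#' @export
project_one_day <- function(state, kernel) {
  stopifnot(inherits(state, "population_state"), inherits(kernel, "deb_kernel"))
  if (!identical(state$grid$breaks, kernel$grid$breaks))
    stop("state and kernel use different size grids")
  population_state(drop(kernel$matrix %*% state$abundance), state$grid,
                   state$day + 1L)
}

#' Size-selective constant-effort harvesting rule
#'
#' Every `interval_days` days, a fixed `fraction` of the adults larger
#' than a threshold is removed.  The threshold is relative: it equals
#' `threshold_ratio` times the current abundance-weighted mean length of
#' all adults, mirroring a protocol in which the largest adults are
#' removed and the realized ratio of mean harvested length to mean adult
#' length was 1.0235.
#'
#' @param interval_days Days between harvests (default 8).
#' @param fraction Proportion of above-threshold adults removed, in
#'   \[0, 1\] (default 0.5).
#' @param threshold_ratio Harvest threshold as a multiple of the mean
#'   adult length (default 1.0235).
#' @param enabled Logical; a disabled rule leaves populations untouched.
#' @return An object of class `"harvest_rule"`.
#' @export
harvest_rule <- function(interval_days = 8, fraction = 0.5,
                         threshold_ratio = 1.0235, enabled = TRUE) {
  stopifnot(interval_days >= 1, interval_days == round(interval_days),
            fraction >= 0, fraction <= 1, threshold_ratio > 0)
  structure(list(interval_days = as.integer(interval_days),
                 fraction = fraction, threshold_ratio = threshold_ratio,
                 enabled = isTRUE(enabled)),
            class = "harvest_rule")
}

#' Apply one harvesting event to a population
#'
#' Adults are the bins with midpoint at or above the current maturation
#' length `L_p(EY)`.  Bins with midpoint above `threshold_ratio` times the
#' abundance-weighted mean adult length lose `fraction` of their
#' abundance; everything else is untouched.  With no adults (or a
#' disabled rule) the state is returned unchanged.  Note that with all
#' adult mass in a single bin nothing is ever harvested: a bin's midpoint
#' cannot exceed `threshold_ratio > 1` times itself.
#'
#' @param state A [population_state()].
#' @param rule A [harvest_rule()].
#' @param EY Feeding level of the day (sets the adult threshold).
#' @param params A [deb_params()] object.
#' @return The harvested `"population_state"` (same day).
#' @export
apply_harvest <- function(state, rule, EY, params) {
  stopifnot(inherits(state, "population_state"), inherits(rule, "harvest_rule"))
  if (!rule$enabled || rule$fraction == 0) return(state)
  x <- state$grid$midpoints
  adult <- x >= maturation_length(EY, params)
  n_ad <- state$abundance * adult
  tot <- sum(n_ad)
  if (tot <= 0) return(state)
  mean_L <- sum(n_ad * x) / tot
  take <- adult & x > rule$threshold_ratio * mean_L
  ab <- state$abundance
  ab[take] <- ab[take] * (1 - rule$fraction)
  population_state(ab, state$grid, state$day)
}

#' Stage-structured census of a population state
#'
#' Partitions the abundance vector into the three census stages: eggs
#' (bins with midpoint at or below `egg_cutoff`; the model has no
#' explicit egg stage, so the newborn bins stand in for it), adults (bins
#' at or above the maturation length `L_p(EY)`) and juveniles (the rest).
#' Alternatively, `egg_mode = "production"` reports the day's egg
#' production `sum(R(L) * N(L))` as the egg count, leaving the newborn
#' bins with the juveniles.
#'
#' Because maturation is plastic, the maturation length can fall below
#' the egg cutoff (even below the birth length) at low feeding levels; in
#' that case adult status takes precedence and the egg and juvenile
#' classes may be empty.  The cutoff is validated only against the
#' maturation length of a fully fed population (`L_p` at `EY = 1`), the
#' static upper reference.
#'
#' @param state A [population_state()].
#' @param EY Feeding level of the day.
#' @param params A [deb_params()] object.
#' @param egg_cutoff Upper length bound of the egg class (mm); must be
#'   positive and below the maturation length at `EY = 1`.
#' @param egg_mode `"cutoff"` (default) or `"production"`.
#' @return Named list: `day`, `eggs`, `juveniles`, `adults`, `total`
#'   (total is always the summed abundance vector).
#' @export
stage_counts <- function(state, EY, params, egg_cutoff = 0.2,
                         egg_mode = c("cutoff", "production")) {
  egg_mode <- match.arg(egg_mode)
  x <- state$grid$midpoints
  Lp <- maturation_length(EY, params)
  if (egg_mode == "cutoff" && egg_cutoff >= maturation_length(1, params))
    stop("'egg_cutoff' must be below the maturation length at EY = 1 (",
         signif(maturation_length(1, params), 4), " mm)")
  if (egg_mode == "cutoff" && egg_cutoff <= 0)
    stop("'egg_cutoff' must be positive")
  ab <- state$abundance
  adult <- x >= Lp
  if (egg_mode == "cutoff") {
    egg <- !adult & x <= egg_cutoff
    eggs <- sum(ab[egg])
    juveniles <- sum(ab[!adult & !egg])
  } else {
    eggs <- sum(fecundity(x, EY, params) * ab)
    juveniles <- sum(ab[!adult])
  }
  list(day = state$day, eggs = eggs, juveniles = juveniles,
       adults = sum(ab[adult]), total = sum(ab))
}

#' Log stochastic population growth rate from a totals series
#'
#' The mean of the one-step log growth ratios,
#' `mean(log(N[t + 1] / N[t]))`, which by telescoping equals
#' `log(N_end / N_start) / (n - 1)`.
#'
#' @param totals Positive numeric vector of population totals at equal
#'   spacing (length >= 2).
#' @return The mean one-step log growth rate.
#' @export
log_stochastic_growth_rate <- function(totals) {
  stopifnot(is.numeric(totals), length(totals) >= 2L)
  if (any(!is.finite(totals)) || any(totals <= 0))
    stop("population extinct or totals invalid: all totals must be positive")
  mean(diff(log(totals)))
}

#' Simulate the 148-day harvesting experiment
#'
#' Reproduces the simulated experimental protocol: 20 founder adults are
#' placed in the bin nearest the ultimate length of the acclimation
#' feeding level, the population runs 31 acclimation days at `EY_mid`,
#' then 148 experimental days driven by the daily expansion of the food
#' series (2 rods = `EY_low`, 8 rods = `EY_high`).  A census is recorded
#' every 4th experimental day (37 censuses), and on every 8th
#' experimental day an enabled harvest rule removes large adults after
#' the census.  The log stochastic growth rate is computed from the daily
#' totals of the experimental window.
#'
#' @param food A [food_series()] of 4-day blocks.
#' @param EY_low,EY_high Feeding levels for the 2- and 8-rod rations.
#' @param EY_mid Feeding level of the 5-rod acclimation/control ration
#'   (default midpoint).
#' @param params A [deb_params()] object.
#' @param grid A [size_grid()].
#' @param rule A [harvest_rule()] (default: disabled).
#' @param n_founders Number of founder adults.
#' @param acclimation_days Length of the acclimation period.
#' @param egg_cutoff,egg_mode Passed to [stage_counts()].
#' @param survivor_weighted_fecundity Passed to [build_kernel()].
#' @param init `"founders"` (default: all founders in the bin nearest
#'   `Linf(EY_mid)`) or `"uniform_adults"` (spread over adult bins).
#' @return An object of class `"deb_sim"`: list with `censuses` (a 37-row
#'   data frame: day, eggs, juveniles, adults, total), `daily_totals`
#'   (length 149: experimental days 0..148), `log_lambda_s`, `tau`,
#'   `mean_log_counts`, and the settings used.
#' @examples
#' sim <- run_experiment_simulation(constant_series(), EY_low = 0.25,
#'                                  EY_high = 0.45,
#'                                  grid = size_grid(n_bins = 60))
#' sim
#' @export
run_experiment_simulation <- function(food, EY_low, EY_high,
                                      EY_mid = (EY_low + EY_high) / 2,
                                      params = deb_params(),
                                      grid = size_grid(params),
                                      rule = harvest_rule(enabled = FALSE),
                                      n_founders = 20, acclimation_days = 31,
                                      egg_cutoff = 0.2,
                                      egg_mode = c("cutoff", "production"),
                                      survivor_weighted_fecundity = FALSE,
                                      init = c("founders", "uniform_adults")) {
  egg_mode <- match.arg(egg_mode)
  init <- match.arg(init)
  stopifnot(inherits(food, "food_series"))
  daily_EY <- expand_to_daily(food, EY_low, EY_high, EY_mid)
  n_exp <- length(daily_EY)

  kcache <- new.env(parent = emptyenv())
  get_kernel <- function(ey) {
    key <- sprintf("%.12g", ey)
    if (is.null(kcache[[key]]))
      kcache[[key]] <- build_kernel(ey, grid, params,
                                    survivor_weighted_fecundity)
    kcache[[key]]
  }

  ab <- numeric(grid$n_bins)
  if (init == "founders") {
    ib <- which.min(abs(grid$midpoints - ultimate_length(EY_mid, params)))
    ab[ib] <- n_founders
  } else {
    adult <- grid$midpoints >= maturation_length(EY_mid, params)
    ab[adult] <- n_founders / sum(adult)
  }
  state <- population_state(ab, grid)

  for (d in seq_len(acclimation_days))
    state <- project_one_day(state, get_kernel(EY_mid))

  # experimental window: day counter restarts at 0
  state <- population_state(state$abundance, grid, 0L)
  daily_totals <- numeric(n_exp + 1L)
  daily_totals[1L] <- sum(state$abundance)
  censuses <- vector("list", n_exp %/% 4L)
  for (d in seq_len(n_exp)) {
    ey <- daily_EY[d]
    state <- project_one_day(state, get_kernel(ey))
    daily_totals[d + 1L] <- sum(state$abundance)
    if (d %% 4L == 0L)
      censuses[[d %/% 4L]] <- stage_counts(state, ey, params, egg_cutoff,
                                           egg_mode)
    if (rule$enabled && d %% rule$interval_days == 0L)
      state <- apply_harvest(state, rule, ey, params)
  }
  censuses <- do.call(rbind, lapply(censuses, as.data.frame))

  # mean log count per stage over censuses with positive counts; empty
  # stages (possible at low feeding levels, where the plastic maturation
  # length undercuts the egg cutoff) are excluded and tallied in n_zero
  counts <- as.matrix(censuses[c("eggs", "juveniles", "adults")])
  mean_log_counts <- apply(counts, 2L, function(v)
    if (any(v > 0)) mean(log(v[v > 0])) else -Inf)
  attr(mean_log_counts, "n_zero") <- colSums(counts == 0)
  structure(list(censuses = censuses, daily_totals = daily_totals,
                 log_lambda_s = log_stochastic_growth_rate(daily_totals),
                 tau = n_exp,
                 mean_log_counts = mean_log_counts,
                 final_state = state,
                 settings = list(colour = attr(food, "colour"),
                                 EY_low = EY_low, EY_high = EY_high,
                                 EY_mid = EY_mid, rule = rule,
                                 egg_cutoff = egg_cutoff, egg_mode = egg_mode,
                                 n_founders = n_founders,
                                 acclimation_days = acclimation_days,
                                 survivor_weighted_fecundity =
                                   survivor_weighted_fecundity)),
            class = "deb_sim")
}

#' @export
print.deb_sim <- function(x, ...) {
  s <- x$settings
  cat(sprintf("DEB-IPM experiment simulation (%s noise, harvest %s)\n",
              s$colour, if (s$rule$enabled) "on" else "off"))
  cat(sprintf("  EY low/high/mid: %.3g / %.3g / %.3g\n",
              s$EY_low, s$EY_high, s$EY_mid))
  cat(sprintf("  tau = %d days, %d censuses\n", x$tau, nrow(x$censuses)))
  cat(sprintf("  log lambda_s = %.5f\n", x$log_lambda_s))
  cat(sprintf("  mean log counts: eggs %.3f, juveniles %.3f, adults %.3f\n",
              x$mean_log_counts[["eggs"]], x$mean_log_counts[["juveniles"]],
              x$mean_log_counts[["adults"]]))
  invisible(x)
}

#' @export
summary.deb_sim <- function(object, ...) {
  print(object)
  cat("\ncensus table (first and last rows):\n")
  cs <- object$censuses
  print(utils::head(cs, 3L), row.names = FALSE)
  cat("  ...\n")
  print(utils::tail(cs, 3L), row.names = FALSE)
  invisible(object)
}

#' @export
plot.deb_sim <- function(x, log = "y", ...) {
  cs <- x$censuses
  graphics::matplot(cs$day, cs[c("eggs", "juveniles", "adults")],
                    type = "l", lty = 1, col = c(3, 4, 2), log = log,
                    xlab = "experimental day", ylab = "females per stage",
                    main = sprintf("%s noise, harvest %s", x$settings$colour,
                                   if (x$settings$rule$enabled) "on" else "off"),
                    ...)
  graphics::legend("topleft", c("eggs", "juveniles", "adults"),
                   lty = 1, col = c(3, 4, 2), bty = "n")
  invisible(x)
}

#' Export a simulated census table
#'
#' Writes the census records of a [run_experiment_simulation()] result as
#' tab-separated text (day, eggs, juveniles, adults, total) under a
#' comment header carrying the run settings, readable back with
#' [utils::read.table()].
#'
#' @param sim A `"deb_sim"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_simulation <- function(sim, path) {
  stopifnot(inherits(sim, "deb_sim"))
  s <- sim$settings
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# deb_sim colour=%s harvest=%s EY_low=%g EY_high=%g EY_mid=%g log_lambda_s=%.8f tau=%d",
    s$colour, s$rule$enabled, s$EY_low, s$EY_high, s$EY_mid,
    sim$log_lambda_s, sim$tau), con)
  utils::write.table(format(sim$censuses, digits = 10), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
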