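#' Log stochastic growth rate along a prescribed feeding-level sequence
#'
#' Projects a population through an arbitrary daily feeding-level
#' sequence, renormalizing the structure vector each day and accumulating
#' one-step log growth increments (the numerically stable route to
#' `log(lambda_s)`).  An enabled harvest rule is applied on every
#' `interval_days`-th day; its loss is part of that day's increment.
#'
#' @param daily_EY Numeric vector of feeding levels, one per day.
#' @param params A [deb_params()] object.
#' @param grid A [size_grid()].
#' @param rule A [harvest_rule()] or `NULL` (no harvesting).
#' @param burn_in Number of leading days whose increments are discarded
#'   (transient of the population structure).
#' @param initial Initial abundance vector (default one individual per
#'   bin).
#' @param survivor_weighted_fecundity Passed to [build_kernel()].
#' @return The mean one-step log growth rate over the `length(daily_EY) -
#'   burn_in` retained days, with attribute `"tau"`.
#' @export
lambda_s_sequence <- function(daily_EY, params = deb_params(),
                              grid = size_grid(params), rule = NULL,
                              burn_in = 0, initial = rep(1, grid$n_bins),
                              survivor_weighted_fecundity = FALSE) {
  n <- length(daily_EY)
  stopifnot(n > burn_in, length(initial) == grid$n_bins, all(initial >= 0),
            sum(initial) > 0)
  harvesting <- !is.null(rule) && rule$enabled
  kcache <- new.env(parent = emptyenv())
  v <- initial / sum(initial)
  r <- numeric(n)
  for (t in seq_len(n)) {
    ey <- daily_EY[t]
    key <- sprintf("%.12g", ey)
    if (is.null(kcache[[key]]))
      kcache[[key]] <- build_kernel(ey, grid, params,
                                    survivor_weighted_fecundity)$matrix
    v <- drop(kcache[[key]] %*% v)
    if (harvesting && t %% rule$interval_days == 0L) {
      st <- apply_harvest(population_state(v, grid), rule, ey, params)
      v <- st$abundance
    }
    tot <- sum(v)
    if (!is.finite(tot) || tot <= 0)
      stop("population extinct at day ", t, " of the sequence")
    r[t] <- log(tot)
    v <- v / tot
  }
  keep <- r[(burn_in + 1L):n]
  structure(mean(keep), tau = length(keep))
}

#' Long-run stochastic growth rate in a Markov environment
#'
#' Samples a daily feeding-level sequence of length `length` from the
#' two-state chain, starts from one individual in each size bin, discards
#' the first `burn_in` daily growth increments and averages the rest.
#' The defaults (3000 days, 500 discarded, so `tau = 2500`) give a
#' between-seed standard deviation of `log(lambda_s)` below 0.01.
#'
#' @param env A [markov_environment()].
#' @param params A [deb_params()] object.
#' @param grid A [size_grid()].
#' @param rule A [harvest_rule()] or `NULL`.
#' @param length Days simulated.
#' @param burn_in Days discarded.
#' @param seed Optional integer seed for the environment sequence.
#' @param survivor_weighted_fecundity Passed to [build_kernel()].
#' @return `log(lambda_s)` with attribute `"tau"`.
#' @examples
#' env <- markov_environment(0.5, 0.5)
#' stochastic_lambda(env, grid = size_grid(n_bins = 60), length = 600,
#'                   burn_in = 100, seed = 1)
#' @export
stochastic_lambda <- function(env, params = deb_params(),
                              grid = size_grid(params), rule = NULL,
                              length = 3000, burn_in = 500, seed = NULL,
                              survivor_weighted_fecundity = FALSE) {
  stopifnot(inherits(env, "markov_env"), length > burn_in)
  daily_EY <- sample_markov_sequence(env, length, seed)
  lambda_s_sequence(daily_EY, params, grid, rule, burn_in,
                    survivor_weighted_fecundity = survivor_weighted_fecundity)
}

#' Stochastic growth rate over a grid of Markov switching probabilities
#'
#' Computes `log(lambda_s)` for every combination of the daily switching
#' probabilities `p` (good to bad) and `q` (bad to good), annotated with
#' the chain autocorrelation `rho = 1 - p - q` and good-state frequency
#' `f = q / (p + q)`.  Each cell draws its environment sequence from a
#' sub-seed derived from `seed` and the cell index, so two calls with the
#' same `seed` (e.g. harvested vs unharvested) see identical environments.
#'
#' @param p_values,q_values Switching probabilities to cross.
#' @param params A [deb_params()] object.
#' @param grid A [size_grid()].
#' @param rule A [harvest_rule()] or `NULL`.
#' @param EY_good,EY_bad Feeding levels of the two states.
#' @param length,burn_in Days simulated / discarded per cell.
#' @param seed Optional integer seed.
#' @param survivor_weighted_fecundity Passed to [build_kernel()].
#' @return A data frame of class `"stochastic_grid"` with columns `p`,
#'   `q`, `rho`, `f`, `log_lambda_s`.
#' @export
stochastic_grid <- function(p_values, q_values, params = deb_params(),
                            grid = size_grid(params), rule = NULL,
                            EY_good = 0.60, EY_bad = 0.15,
                            length = 3000, burn_in = 500, seed = NULL,
                            survivor_weighted_fecundity = FALSE) {
  cells <- expand.grid(p = p_values, q = q_values, KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(k) {
    env <- markov_environment(cells$p[k], cells$q[k], EY_good, EY_bad)
    st <- markov_stats(env)
    ll <- stochastic_lambda(env, params, grid, rule, length, burn_in,
                            seed = sub_seed(seed, k),
                            survivor_weighted_fecundity =
                              survivor_weighted_fecundity)
    data.frame(p = env$p, q = env$q, rho = st$rho, f = st$f,
               log_lambda_s = as.numeric(ll))
  })
  out <- do.call(rbind, res)
  class(out) <- c("stochastic_grid", "data.frame")
  out
}

#' @export
plot.stochastic_grid <- function(x, ...) {
  pv <- sort(unique(x$p)); qv <- sort(unique(x$q))
  z <- matrix(NA_real_, length(pv), length(qv))
  z[cbind(match(x$p, pv), match(x$q, qv))] <- x$log_lambda_s
  graphics::contour(pv, qv, z, xlab = "p (good to bad)",
                    ylab = "q (bad to good)",
                    main = "log stochastic growth rate", ...)
  graphics::abline(a = 0, b = 1, lty = 3)
  invisible(x)
}

# the perturbable life-history parameters: each entry is perturbed
# multiplicatively; rb_scale stands in for a proportional change of the
# von Bertalanffy growth rate, lp_coeff for the maturity threshold
elasticity_parameters <- c("L_b", "lp_coeff", "L_m", "R_m", "rb_scale",
                           "kappa", "mu")

perturb_params <- function(params, name, delta) {
  vals <- unclass(params)
  if (!name %in% names(vals)) stop("unknown parameter '", name, "'")
  vals[[name]] <- vals[[name]] * (1 + delta)
  do.call(deb_params, vals)
}

#' Elasticity of the stochastic growth rate to life-history parameters
#'
#' Perturbs each parameter by a proportion `delta` (default 1%) and
#' recomputes `lambda_s = exp(log lambda_s)` along the *same* environment
#' sequence (common random numbers), giving the forward-difference
#' elasticity `e = (lambda_s' - lambda_s) / (delta * lambda_s)`.  The
#' growth rate is perturbed through its multiplicative scale `rb_scale`
#' and the maturity threshold through its coefficient `lp_coeff`; the
#' discretization grid is held fixed across perturbations.
#'
#' @param env A [markov_environment()].
#' @param params A [deb_params()] object.
#' @param grid A [size_grid()].
#' @param rule A [harvest_rule()] or `NULL`.
#' @param delta Proportional perturbation (default 0.01).
#' @param parameters Which parameters to perturb (default: length at
#'   birth, maturity coefficient, maximum length, maximum fecundity,
#'   growth-rate scale, allocation fraction, mortality).
#' @param length,burn_in Days simulated / discarded.
#' @param seed Optional integer seed (fixes the common environment
#'   sequence).
#' @param survivor_weighted_fecundity Passed to [build_kernel()].
#' @return A data frame of class `"elasticity_table"` with columns
#'   `parameter`, `elasticity`, plus attributes `log_lambda_s` (base run)
#'   and `argmax` (parameter with the largest absolute elasticity).
#' @export
elasticity <- function(env, params = deb_params(), grid = size_grid(params),
                       rule = NULL, delta = 0.01,
                       parameters = elasticity_parameters,
                       length = 3000, burn_in = 500, seed = NULL,
                       survivor_weighted_fecundity = FALSE) {
  stopifnot(inherits(env, "markov_env"), delta != 0)
  daily_EY <- sample_markov_sequence(env, length, seed)
  base_ll <- lambda_s_sequence(daily_EY, params, grid, rule, burn_in,
                               survivor_weighted_fecundity =
                                 survivor_weighted_fecundity)
  base_lam <- exp(as.numeric(base_ll))
  e <- vapply(parameters, function(nm) {
    pp <- perturb_params(params, nm, delta)
    ll <- lambda_s_sequence(daily_EY, pp, grid, rule, burn_in,
                            survivor_weighted_fecundity =
                              survivor_weighted_fecundity)
    (exp(as.numeric(ll)) - base_lam) / (delta * base_lam)
  }, numeric(1))
  out <- data.frame(parameter = parameters, elasticity = unname(e))
  attr(out, "log_lambda_s") <- as.numeric(base_ll)
  attr(out, "argmax") <- parameters[which.max(abs(e))]
  class(out) <- c("elasticity_table", "data.frame")
  out
}

#' Elasticity analysis across a grid of Markov environments
#'
#' Runs [elasticity()] in every `(p, q)` cell and reports, per cell, the
#' full elasticity set and the parameter with the largest absolute
#' elasticity (the cell's most influential life-history trait).
#'
#' @inheritParams stochastic_grid
#' @param delta,parameters Passed to [elasticity()].
#' @return A data frame with one row per cell and parameter (`p`, `q`,
#'   `rho`, `f`, `log_lambda_s`, `parameter`, `elasticity`, `argmax`).
#' @export
elasticity_grid <- function(p_values, q_values, params = deb_params(),
                            grid = size_grid(params), rule = NULL,
                            EY_good = 0.60, EY_bad = 0.15, delta = 0.01,
                            parameters = elasticity_parameters,
                            length = 3000, burn_in = 500, seed = NULL,
                            survivor_weighted_fecundity = FALSE) {
  cells <- expand.grid(p = p_values, q = q_values, KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(k) {
    env <- markov_environment(cells$p[k], cells$q[k], EY_good, EY_bad)
    st <- markov_stats(env)
    et <- elasticity(env, params, grid, rule, delta, parameters,
                     length, burn_in, seed = sub_seed(seed, k),
                     survivor_weighted_fecundity =
                       survivor_weighted_fecundity)
    data.frame(p = env$p, q = env$q, rho = st$rho, f = st$f,
               log_lambda_s = attr(et, "log_lambda_s"),
               parameter = et$parameter, elasticity = et$elasticity,
               argmax = attr(et, "argmax"))
  })
  do.call(rbind, res)
}

#' Cross-level feeding-level sweep of the simulated experiment
#'
#' Runs the full experiment simulation for every pairwise combination of
#' low and high feeding levels, for each noise colour and harvesting
#' option, recording the log stochastic growth rate and the mean
#' log-transformed stage counts over the experimental period.  The same
#' food series (one per colour, shared across cells and harvest options)
#' drive all runs, as in the experimental design.
#'
#' @param EY_low_values Low feeding levels (2-rod ration).
#' @param EY_high_values High feeding levels (8-rod ration).
#' @param colours Noise colours to run; any of `"constant"`, `"blue"`,
#'   `"white"`, `"red"`.
#' @param harvest Logical vector of harvesting options to run.
#' @param params A [deb_params()] object.
#' @param grid A [size_grid()].
#' @param rule The [harvest_rule()] used when harvesting is on.
#' @param series Optional named list of [food_series()] per colour;
#'   defaults to a seeded white series recoloured by spectral mimicry.
#' @param seed Optional integer seed for the default series.
#' @param ... Further arguments to [run_experiment_simulation()].
#' @return A data frame of class `"crosslevel_sweep"`: one row per
#'   `(EY_low, EY_high, colour, harvest)` with `log_lambda_s`,
#'   `mean_log_eggs`, `mean_log_juveniles`, `mean_log_adults` and an
#'   `extinct` flag.
#' @export
crosslevel_sweep <- function(EY_low_values = seq(0.10, 0.35, by = 0.01),
                             EY_high_values = seq(0.36, 0.60, by = 0.01),
                             colours = c("blue", "white", "red"),
                             harvest = c(FALSE, TRUE),
                             params = deb_params(), grid = size_grid(params),
                             rule = harvest_rule(), series = NULL,
                             seed = NULL, ...) {
  stopifnot(all(EY_low_values < min(EY_high_values)))
  if (is.null(series)) series <- default_series_set(colours, seed)
  if (!all(colours %in% names(series)))
    stop("'series' must supply a food series for every colour")
  rows <- list()
  for (lo in EY_low_values) for (hi in EY_high_values) {
    for (col in colours) for (h in harvest) {
      r <- rule
      r$enabled <- h
      sim <- tryCatch(
        run_experiment_simulation(series[[col]], EY_low = lo, EY_high = hi,
                                  params = params, grid = grid, rule = r, ...),
        error = function(e) NULL)
      rows[[length(rows) + 1L]] <- if (is.null(sim)) {
        data.frame(EY_low = lo, EY_high = hi, colour = col, harvest = h,
                   log_lambda_s = NA_real_, mean_log_eggs = NA_real_,
                   mean_log_juveniles = NA_real_, mean_log_adults = NA_real_,
                   extinct = TRUE)
      } else {
        m <- sim$mean_log_counts
        data.frame(EY_low = lo, EY_high = hi, colour = col, harvest = h,
                   log_lambda_s = sim$log_lambda_s,
                   mean_log_eggs = m[["eggs"]],
                   mean_log_juveniles = m[["juveniles"]],
                   mean_log_adults = m[["adults"]],
                   extinct = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "series") <- series
  class(out) <- c("crosslevel_sweep", "data.frame")
  out
}

default_series_set <- function(colours, seed = NULL) {
  out <- list()
  white <- make_white_series(seed = seed)
  for (col in colours)
    out[[col]] <- switch(col,
                         constant = constant_series(),
                         white = white,
                         blue = recolour_series(white, "blue",
                                                seed = sub_seed(seed, 1L)),
                         red = recolour_series(white, "red",
                                               seed = sub_seed(seed, 2L)),
                         stop("unknown colour '", col, "'"))
  out
}

#' @export
plot.crosslevel_sweep <- function(x, colour = x$colour[1],
                                  harvest = FALSE,
                                  metric = "log_lambda_s", ...) {
  sub <- x[x$colour == colour & x$harvest == harvest, ]
  lo <- sort(unique(sub$EY_low)); hi <- sort(unique(sub$EY_high))
  z <- matrix(NA_real_, length(lo), length(hi))
  z[cbind(match(sub$EY_low, lo), match(sub$EY_high, hi))] <- sub[[metric]]
  graphics::contour(lo, hi, z, xlab = "EY low", ylab = "EY high",
                    main = sprintf("%s (%s noise, harvest %s)", metric,
                                   colour, if (harvest) "on" else "off"),
                    ...)
  invisible(x)
}

#' Stratified BCa bootstrap confidence interval
#'
#' Bias-corrected and accelerated (BCa) bootstrap interval for a
#' statistic of a set of values, resampling within strata (stratum sizes
#' preserved), as used to attach confidence intervals to per-tube census
#' summaries.  The resampling machinery is [boot::boot()]; the interval
#' is [boot::boot.ci()] of type `"bca"`.  A degenerate bootstrap
#' distribution (zero variance) collapses to a point interval and is
#' flagged.
#'
#' @param values Numeric vector of observations.
#' @param strata Optional factor of stratum labels (e.g. replicate tube);
#'   default puts everything in one stratum, giving the ordinary BCa
#'   interval.
#' @param statistic Function of a numeric vector (default [mean()]).
#' @param n_resamples Number of bootstrap resamples (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional integer seed.
#' @return An object of class `"ci_record"`: list with `estimate`,
#'   `lower`, `upper`, `conf`, `n_resamples`, `strata_sizes`,
#'   `degenerate`.
#' @examples
#' ci <- bootstrap_bca(rnorm(30), strata = gl(3, 10), seed = 1)
#' ci
#' @export
bootstrap_bca <- function(values, strata = NULL, statistic = mean,
                          n_resamples = 1000, conf = 0.95, seed = NULL) {
  stopifnot(is.numeric(values), length(values) >= 2L)
  if (is.null(strata)) strata <- rep(1L, length(values))
  strata <- as.factor(strata)
  if (length(strata) != length(values))
    stop("'strata' must label every value")
  if (any(table(strata) < 2L))
    stop("every stratum needs at least 2 values for resampling")
  est <- statistic(values)
  bt <- with_seed(seed,
                  boot::boot(values,
                             statistic = function(d, i) statistic(d[i]),
                             R = n_resamples, strata = strata))
  degenerate <- stats::var(bt$t[, 1L]) == 0
  if (degenerate) {
    lower <- upper <- est
  } else {
    ci <- boot::boot.ci(bt, conf = conf, type = "bca")
    lower <- ci$bca[1L, 4L]
    upper <- ci$bca[1L, 5L]
  }
  structure(list(estimate = est, lower = lower, upper = upper, conf = conf,
                 n_resamples = n_resamples,
                 strata_sizes = as.integer(table(strata)),
                 degenerate = degenerate),
            class = "ci_record")
}

#' @export
print.ci_record <- function(x, ...) {
  cat(sprintf("%.0f%% BCa interval: %.5g [%.5g, %.5g]%s\n", 100 * x$conf,
              x$estimate, x$lower, x$upper,
              if (x$degenerate) " (degenerate: point interval)" else ""))
  cat(sprintf("  %d resamples, strata sizes: %s\n", x$n_resamples,
              paste(x$strata_sizes, collapse = ", ")))
  invisible(x)
}

#' Does a predicted value (or interval) overlap an observed interval?
#'
#' The cross-level consistency check: a model prediction is consistent
#' with an observation when it falls inside the observed confidence
#' interval (closed at the endpoints); two intervals are consistent when
#' they overlap.
#'
#' @param observed A `"ci_record"` (or list with `lower`/`upper`).
#' @param predicted A single value, or a `"ci_record"`/list with
#'   `lower`/`upper` for interval-vs-interval overlap.
#' @return `TRUE` (consistent) or `FALSE`.
#' @export
overlap_test <- function(observed, predicted) {
  stopifnot(!is.null(observed$lower), !is.null(observed$upper))
  if (is.numeric(predicted) && length(predicted) == 1L)
    return(predicted >= observed$lower && predicted <= observed$upper)
  stopifnot(!is.null(predicted$lower), !is.null(predicted$upper))
  predicted$lower <= observed$upper && predicted$upper >= observed$lower
}

#' Compare model predictions with an observed census table
#'
#' For every treatment (colour x harvest) present in the observed table,
#' computes the tube-stratified BCa interval of the observed mean
#' log-transformed female count of each stage and tests whether the
#' model-predicted mean log count falls inside it.
#'
#' @param observed A census table (see [read_census_table()]) of observed
#'   mixed-sex counts; converted to female counts internally via the
#'   half-female convention (all counts halved).
#' @param predictions Data frame with columns `colour`, `harvest`,
#'   `stage`, `predicted` (mean log female counts), e.g. assembled from
#'   [run_experiment_simulation()] results.
#' @param n_resamples,conf,seed Passed to [bootstrap_bca()].
#' @return `predictions` augmented with `estimate`, `lower`, `upper`,
#'   `consistent`.
#' @export
compare_to_observed <- function(observed, predictions, n_resamples = 1000,
                                conf = 0.95, seed = NULL) {
  fem <- as_female_counts(observed)
  out <- predictions
  out$estimate <- out$lower <- out$upper <- NA_real_
  out$consistent <- NA
  for (i in seq_len(nrow(out))) {
    sub <- fem[fem$colour == out$colour[i] & fem$harvest == out$harvest[i], ]
    if (!nrow(sub)) next
    vals <- sub[[out$stage[i]]]
    keep <- vals > 0
    ci <- bootstrap_bca(log(vals[keep]), strata = factor(sub$tube[keep]),
                        n_resamples = n_resamples, conf = conf,
                        seed = sub_seed(seed, i))
    out$estimate[i] <- ci$estimate
    out$lower[i] <- ci$lower
    out$upper[i] <- ci$upper
    out$consistent[i] <- overlap_test(ci, out$predicted[i])
  }
  out
}
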