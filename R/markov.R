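#' Two-state Markov chain environment
#'
#' Daily environmental regime switching between a good state (feeding
#' level `EY_good`) and a bad state (`EY_bad`).  `p` is the daily
#' probability of switching good-to-bad and `q` of switching bad-to-good,
#' so the transition matrix (columns = current state good, bad) is
#' `rbind(c(1 - p, q), c(p, 1 - q))`.  The chain's lag-1 autocorrelation
#' is `rho = 1 - p - q` (positive: red, sluggish environments; negative:
#' blue, fast-flickering ones) and the stationary frequency of the good
#' state is `f = q / (p + q)`.
#'
#' @param p Daily probability good to bad, in \[0, 1\].
#' @param q Daily probability bad to good, in \[0, 1\].
#' @param EY_good,EY_bad Feeding levels of the two states,
#'   `EY_bad < EY_good`.  Defaults are the extreme feeding levels of the
#'   stationarity band explored in the cross-level analysis.
#' @return An object of class `"markov_env"`.
#' @examples
#' env <- markov_environment(0.1, 0.3)
#' markov_stats(env)
#' @export
markov_environment <- function(p, q, EY_good = 0.60, EY_bad = 0.15) {
  stopifnot(is.numeric(p), is.numeric(q), length(p) == 1L, length(q) == 1L,
            p >= 0, p <= 1, q >= 0, q <= 1)
  check_EY(c(EY_good, EY_bad))
  if (EY_bad >= EY_good) stop("'EY_bad' must be below 'EY_good'")
  structure(list(p = p, q = q, EY_good = EY_good, EY_bad = EY_bad),
            class = "markov_env")
}

#' @export
print.markov_env <- function(x, ...) {
  cat(sprintf("two-state Markov environment: p = %.3g, q = %.3g\n", x$p, x$q))
  cat(sprintf("  EY good/bad: %.3g / %.3g\n", x$EY_good, x$EY_bad))
  cat(sprintf("  autocorrelation rho = %.4g", 1 - x$p - x$q))
  if (x$p + x$q > 0)
    cat(sprintf(", good-state frequency f = %.4g", x$q / (x$p + x$q)))
  cat("\n")
  invisible(x)
}

#' Autocorrelation and good-state frequency of a Markov environment
#'
#' @param env A [markov_environment()].
#' @return Named list with `rho = 1 - p - q` and `f = q / (p + q)` (`f` is
#'   `NA` with a warning when `p = q = 0`, where the chain never moves).
#' @export
markov_stats <- function(env) {
  stopifnot(inherits(env, "markov_env"))
  f <- if (env$p + env$q > 0) env$q / (env$p + env$q) else {
    warning("good-state frequency is undefined for p = q = 0")
    NA_real_
  }
  list(rho = 1 - env$p - env$q, f = f)
}

#' Sample a daily feeding-level sequence from a Markov environment
#'
#' Simulates the state chain for `length` days from a uniformly random
#' initial state and maps states to feeding levels.
#'
#' @param env A [markov_environment()].
#' @param length Number of days (>= 1).
#' @param seed Optional integer seed.
#' @return Numeric vector of daily feeding levels with attribute
#'   `"states"` (1 = good, 2 = bad).
#' @export
sample_markov_sequence <- function(env, length, seed = NULL) {
  stopifnot(inherits(env, "markov_env"), length >= 1)
  n <- as.integer(length)
  states <- with_seed(seed, {
    s <- integer(n)
    s[1L] <- sample(1:2, 1L)
    if (n > 1L) {
      u <- stats::runif(n - 1L)
      for (t in 2L:n) {
        switch_prob <- if (s[t - 1L] == 1L) env$p else env$q
        s[t] <- if (u[t - 1L] < switch_prob) 3L - s[t - 1L] else s[t - 1L]
      }
    }
    s
  })
  structure(ifelse(states == 1L, env$EY_good, env$EY_bad), states = states)
}
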