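#' Two-valued experimental food time series
#'
#' The feeding experiment runs over 37 four-day blocks (148 days); in each
#' block the populations receive either 2 (bad state) or 8 (good state)
#' yeast rods per day.  `food_series()` wraps a rods-per-block vector with
#' its colour label; `make_white_series()` draws the uncoloured (white)
#' series as a uniformly random arrangement of `n_high` eights and `n_low`
#' twos.  The default 20/17 composition is the unique one whose mean
#' (5.24) and sample variance (9.19, denominator n-1) match the design
#' targets at two decimals.
#'
#' A constant control series (5 rods per block, the series mean) is
#' allowed under `colour = "constant"`.
#'
#' @param rods Integer vector of rods per 4-day block; values in {2, 8}
#'   (or all 5 for the constant control).
#' @param colour One of `"white"`, `"blue"`, `"red"`, `"constant"`.
#' @param n_high,n_low Number of 8-rod and 2-rod blocks (must sum to 37).
#' @param n_steps Series length in blocks.
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `"food_series"`: integer vector with
#'   attribute `colour`.
#' @examples
#' w <- make_white_series(seed = 1)
#' mean(w); var(as.numeric(w))
#' @export
food_series <- function(rods, colour = c("white", "blue", "red", "constant")) {
  colour <- match.arg(colour)
  rods <- as.integer(rods)
  if (colour == "constant") {
    if (!all(rods == 5L)) stop("a constant series must be 5 rods throughout")
  } else if (!all(rods %in% c(2L, 8L))) {
    stop("food series values must be 2 or 8 rods")
  }
  structure(rods, colour = colour, class = "food_series")
}

#' @rdname food_series
#' @export
make_white_series <- function(n_high = 20, n_low = 17, n_steps = 37,
                              seed = NULL) {
  if (n_high + n_low != n_steps)
    stop("'n_high' + 'n_low' must equal 'n_steps' (", n_steps, ")")
  rods <- with_seed(seed, sample(rep(c(8L, 2L), c(n_high, n_low))))
  food_series(rods, "white")
}

#' @rdname food_series
#' @export
constant_series <- function(n_steps = 37) {
  food_series(rep(5L, n_steps), "constant")
}

#' @export
print.food_series <- function(x, ...) {
  cat(sprintf("food series (%s): %d blocks of 4 days\n",
              attr(x, "colour"), length(x)))
  cat("  rods:", paste(unclass(x), collapse = " "), "\n")
  if (length(unique(unclass(x))) > 1L)
    cat(sprintf("  mean %.4f, sample variance %.4f, lag-1 autocorrelation %.4f\n",
                mean(x), stats::var(as.numeric(x)), lag1_autocorr(x)))
  invisible(x)
}

#' Sample lag-1 autocorrelation
#'
#' The standard sample estimator: lagged products of deviations from the
#' overall series mean, divided by the total sum of squared deviations.
#' This is the statistic used to label a series blue (negative), white
#' (near zero) or red (positive).
#'
#' @param x Numeric series of length at least 3, not constant.
#' @return The lag-1 autocorrelation in `[-1, 1]`.
#' @examples
#' lag1_autocorr(rep(c(1, -1), 10))  # -1: perfect alternation
#' @export
lag1_autocorr <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3L) stop("series must have length >= 3")
  d <- x - mean(x)
  ss <- sum(d^2)
  if (ss == 0) stop("lag-1 autocorrelation is undefined for a constant series")
  sum(d[-n] * d[-1L]) / ss
}

#' Recolour a series by spectral mimicry
#'
#' Returns the permutation of `values` whose rank order matches the rank
#' order of `surrogate`: the largest value goes where the surrogate is
#' largest, and so on.  Because the output is a permutation, the value
#' multiset -- and with it the mean, minimum, maximum and variance -- is
#' preserved exactly; only the temporal arrangement (the spectrum) changes.
#' Rank ties in the two-valued food series are broken by original index
#' order.
#'
#' @param values A [food_series()] or numeric vector.
#' @param surrogate Numeric vector of the same length whose rank order
#'   carries the desired autocorrelation structure (e.g. an AR(1) draw).
#' @return The rearranged series (class preserved for `food_series`).
#' @seealso [recolour_series()], [optimise_autocorrelation()]
#' @export
spectral_mimicry <- function(values, surrogate) {
  if (length(values) != length(surrogate))
    stop("'values' and 'surrogate' must have the same length")
  out <- values
  # place sorted values at the positions ranked by the surrogate
  out[order(surrogate, seq_along(surrogate))] <-
    values[order(values, seq_along(values))]
  out
}

#' Blue/red recolouring of a white food series
#'
#' Convenience wrapper: draws a first-order autoregressive surrogate with
#' coefficient `+ar_coef` (red) or `-ar_coef` (blue) and applies
#' [spectral_mimicry()].  The AR(1) surrogate gives the qualitative noise
#' colour; [optimise_autocorrelation()] certifies the extreme attainable
#' autocorrelations.
#'
#' @param series A [food_series()] (typically white).
#' @param colour `"blue"` or `"red"`.
#' @param ar_coef Magnitude of the AR(1) coefficient in (0, 1).
#' @param seed Optional integer seed.
#' @return A `"food_series"` with the requested colour label.
#' @export
recolour_series <- function(series, colour = c("blue", "red"), ar_coef = 0.95,
                            seed = NULL) {
  colour <- match.arg(colour)
  stopifnot(ar_coef > 0, ar_coef < 1)
  phi <- if (colour == "red") ar_coef else -ar_coef
  sur <- with_seed(seed,
                   as.numeric(stats::arima.sim(list(ar = phi), length(series))))
  food_series(spectral_mimicry(unclass(series), sur), colour)
}

#' Extreme attainable lag-1 autocorrelation of a series
#'
#' Searches the permutations of `series` for the minimum (blue limit) or
#' maximum (red limit) lag-1 autocorrelation by pairwise-swap
#' hill-climbing from rank-matched starts (an alternating surrogate for
#' minimization, a sorted-block arrangement for maximization, plus random
#' restarts).  For series of length 8 or less the search is exhaustive
#' over distinct arrangements.
#'
#' @param series A [food_series()] or numeric vector.
#' @param direction `"minimize"` or `"maximize"`.
#' @param n_restarts Number of seeded random restarts on top of the
#'   deterministic starts.
#' @param seed Optional integer seed.
#' @return The best permutation found, with its autocorrelation as
#'   attribute `"rho"`.
#' @export
optimise_autocorrelation <- function(series,
                                     direction = c("minimize", "maximize"),
                                     n_restarts = 10, seed = NULL) {
  direction <- match.arg(direction)
  x <- as.numeric(series)
  n <- length(x)
  sgn <- if (direction == "minimize") 1 else -1
  score <- function(v) sgn * lag1_autocorr(v)

  if (n <= 8L) {
    best <- exhaustive_best_arrangement(x, score)
  } else {
    climb <- function(v) {
      repeat {
        improved <- FALSE
        for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
          if (v[i] == v[j]) next
          w <- v; w[c(i, j)] <- w[c(j, i)]
          if (score(w) < score(v)) { v <- w; improved <- TRUE }
        }
        if (!improved) return(v)
      }
    }
    starts <- list(
      spectral_mimicry(x, rep_len(c(1, -1), n)),           # alternating
      spectral_mimicry(x, seq_len(n)),                     # sorted block
      spectral_mimicry(x, rev(seq_len(n))))
    starts <- c(starts, with_seed(seed, replicate(n_restarts, sample(x),
                                                 simplify = FALSE)))
    cands <- lapply(starts, climb)
    best <- cands[[which.min(vapply(cands, score, numeric(1)))]]
  }

  out <- if (inherits(series, "food_series"))
    food_series(best, if (direction == "minimize") "blue" else "red")
  else best
  attr(out, "rho") <- lag1_autocorr(best)
  out
}

# exhaustive search over distinct arrangements of a (possibly tied) series
exhaustive_best_arrangement <- function(x, score) {
  vals <- sort(x)
  perms <- unique_permutations(vals)
  best <- perms[[1L]]; bs <- score(best)
  for (p in perms[-1L]) {
    s <- score(p)
    if (s < bs) { best <- p; bs <- s }
  }
  best
}

unique_permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (v in unique(x)) {
    i <- match(v, x)
    for (rest in unique_permutations(x[-i])) out[[length(out) + 1L]] <- c(v, rest)
  }
  out
}

#' Map rods per day to feeding levels and expand blocks to days
#'
#' `rods_to_feeding()` translates the experimental rations into feeding
#' levels: 2 rods (bad) to `EY_low`, 8 rods (good) to `EY_high`, and the
#' 5-rod control/acclimation ration to `EY_mid` (by default the midpoint,
#' since the control ration equals the series mean and its feeding-level
#' equivalent is a modelling assumption).  `expand_to_daily()` repeats
#' each 4-day block value for its `days_per_step` days, producing the
#' daily feeding-level sequence driving the projection.
#'
#' @param rods Integer vector with values in {2, 5, 8}.
#' @param EY_low,EY_high,EY_mid Feeding levels in (0, 1].
#' @param series A [food_series()].
#' @param days_per_step Days per block (default 4).
#' @return `rods_to_feeding()`: numeric vector of feeding levels.
#'   `expand_to_daily()`: numeric vector of daily feeding levels of length
#'   `length(series) * days_per_step`, with attribute `colour`.
#' @examples
#' expand_to_daily(constant_series(), EY_low = 0.25, EY_high = 0.45)[1:5]
#' @export
rods_to_feeding <- function(rods, EY_low, EY_high,
                            EY_mid = (EY_low + EY_high) / 2) {
  check_EY(c(EY_low, EY_high, EY_mid))
  if (!all(rods %in% c(2L, 5L, 8L)))
    stop("rod counts must be 2, 5 or 8")
  unname(c(`2` = EY_low, `5` = EY_mid, `8` = EY_high)[as.character(rods)])
}

#' @rdname rods_to_feeding
#' @export
expand_to_daily <- function(series, EY_low, EY_high,
                            EY_mid = (EY_low + EY_high) / 2,
                            days_per_step = 4) {
  ey <- rods_to_feeding(unclass(series), EY_low, EY_high, EY_mid)
  structure(rep(ey, each = days_per_step),
            colour = attr(series, "colour") %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read or write a food series as two-column delimited text
#'
#' The file holds one row per 4-day block (`step`, `rods`) with a comment
#' header carrying the colour label and the realized lag-1
#' autocorrelation.
#'
#' @param series A [food_series()].
#' @param path File path.
#' @return `write_food_series()` returns `path` invisibly;
#'   `read_food_series()` returns a `"food_series"`.
#' @export
write_food_series <- function(series, path) {
  stopifnot(inherits(series, "food_series"))
  rho <- if (length(unique(unclass(series))) > 1L)
    sprintf("%.6f", lag1_autocorr(series)) else "NA"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# food_series colour=%s rho=%s",
                       attr(series, "colour"), rho),
               "step\trods",
               sprintf("%d\t%d", seq_along(series), unclass(series))), con)
  invisible(path)
}

#' @rdname write_food_series
#' @export
read_food_series <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "# food_series"))
    stop("'", path, "' does not look like a food series file")
  colour <- sub(".*colour=(\\S+).*", "\\1", hdr)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L)
  food_series(tab$rods, colour)
}
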