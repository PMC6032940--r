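#' Generate a synthetic observed census table
#'
#' Emulates the structure of the laboratory harvesting experiment:
#' treatments (noise colour x harvesting) each replicated across `n_tubes`
#' population tubes, censused every 4th day over the 148-day experimental
#' window.  The underlying truth per treatment is a single deterministic
#' [run_experiment_simulation()] trajectory (food series are identical
#' among replicate tubes, as in the experimental design); observed counts
#' are mixed-sex (female counts doubled, the half-female convention read
#' back by [as_female_counts()]), perturbed per tube with multiplicative
#' lognormal observation noise (counting/visibility error proportional to
#' abundance; `noise_model = "poisson"` is available as an alternative)
#' and rounded to integers.
#'
#' `drop_tube = TRUE` removes the last tube of the last treatment,
#' emulating a replicate lost during a census, to exercise
#' unbalanced-strata bootstrap paths.
#'
#' @param params A [deb_params()] object.
#' @param EY_low,EY_high,EY_mid True feeding levels of the rations.
#' @param colours Treatment colours; subset of `"constant"`, `"blue"`,
#'   `"white"`, `"red"`.
#' @param harvest Logical vector of harvesting treatments.
#' @param n_tubes Replicate tubes per treatment (default 3).
#' @param noise_sd Standard deviation of the lognormal observation noise
#'   on the log scale (default 0.2; 0 gives identical, noise-free tubes).
#' @param noise_model `"lognormal"` (default) or `"poisson"`.
#' @param drop_tube Drop one replicate to create unbalanced strata.
#' @param grid,rule Passed to [run_experiment_simulation()].
#' @param seed Optional integer seed; tubes get deterministic sub-seeds.
#' @param ... Further arguments to [run_experiment_simulation()].
#' @return A data frame of class `"census_table"` with columns `colour`,
#'   `harvest`, `tube`, `day`, `eggs`, `juveniles`, `adults` (integer
#'   mixed-sex counts), and attribute `"truth"`: the list of noise-free
#'   `"deb_sim"` objects per treatment.
#' @examples
#' tab <- generate_study(colours = "white", harvest = FALSE, noise_sd = 0,
#'                       grid = size_grid(n_bins = 60), seed = 1)
#' head(tab)
#' @export
generate_study <- function(params = deb_params(), EY_low = 0.25,
                           EY_high = 0.45,
                           EY_mid = (EY_low + EY_high) / 2,
                           colours = c("constant", "blue", "white", "red"),
                           harvest = c(FALSE, TRUE), n_tubes = 3,
                           noise_sd = 0.2,
                           noise_model = c("lognormal", "poisson"),
                           drop_tube = FALSE, grid = size_grid(params),
                           rule = harvest_rule(), seed = NULL, ...) {
  noise_model <- match.arg(noise_model)
  stopifnot(n_tubes >= 1, noise_sd >= 0)
  colours <- match.arg(colours, several.ok = TRUE)
  series <- default_series_set(colours, seed)
  truth <- list()
  rows <- list()
  k <- 0L
  for (col in colours) for (h in harvest) {
    r <- rule
    r$enabled <- h
    sim <- run_experiment_simulation(series[[col]], EY_low = EY_low,
                                     EY_high = EY_high, EY_mid = EY_mid,
                                     params = params, grid = grid, rule = r,
                                     ...)
    trt <- sprintf("%s_%s", col, if (h) "harvested" else "unharvested")
    truth[[trt]] <- sim
    female <- as.matrix(sim$censuses[c("eggs", "juveniles", "adults")])
    for (tube in seq_len(n_tubes)) {
      k <- k + 1L
      obs <- 2 * female # mixed-sex counts under a 1:1 sex ratio
      if (noise_sd > 0 || noise_model == "poisson") {
        obs <- with_seed(sub_seed(seed, k), {
          if (noise_model == "lognormal") {
            obs * exp(matrix(stats::rnorm(length(obs), 0, noise_sd),
                             nrow(obs), ncol(obs)))
          } else {
            obs[] <- stats::rpois(length(obs), obs)
            obs
          }
        })
      }
      obs <- round(obs)
      rows[[k]] <- data.frame(colour = col, harvest = h, tube = tube,
                              day = sim$censuses$day,
                              eggs = as.integer(obs[, "eggs"]),
                              juveniles = as.integer(obs[, "juveniles"]),
                              adults = as.integer(obs[, "adults"]))
    }
  }
  out <- do.call(rbind, rows)
  if (drop_tube) {
    last <- out$colour == out$colour[nrow(out)] &
      out$harvest == out$harvest[nrow(out)] & out$tube == n_tubes
    if (n_tubes < 2L) stop("cannot drop a tube from a single-tube study")
    out <- out[!last, ]
  }
  rownames(out) <- NULL
  attr(out, "truth") <- truth
  attr(out, "series") <- series
  class(out) <- c("census_table", "data.frame")
  out
}

#' Convert observed mixed-sex counts to model-comparable female counts
#'
#' Applies the half-female convention: half of all observed eggs,
#' juveniles and adults are assumed female, so all counts are halved.
#'
#' @param table A census table of observed mixed-sex counts.
#' @return The table with `eggs`, `juveniles`, `adults` halved (numeric).
#' @export
as_female_counts <- function(table) {
  for (col in c("eggs", "juveniles", "adults"))
    table[[col]] <- table[[col]] / 2
  table
}

census_columns <- c("colour", "harvest", "tube", "day",
                    "eggs", "juveniles", "adults")

#' Read or write an observed census table
#'
#' Census tables are comma-separated text with the fixed header
#' `colour,harvest,tube,day,eggs,juveniles,adults`: one row per tube and
#' census day, counts as non-negative mixed-sex integers, days on the
#' 4-day census schedule within the 148-day experimental window.
#' Validation failures name the offending rows.
#'
#' @param table A `"census_table"` (for writing).
#' @param path File path.
#' @return `read_census_table()` returns a validated `"census_table"`;
#'   `write_census_table()` returns `path` invisibly.
#' @export
read_census_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(tab), census_columns))
    stop("census table must have columns: ",
         paste(census_columns, collapse = ", "))
  validate_census_table(tab)
  class(tab) <- c("census_table", "data.frame")
  tab
}

#' @rdname read_census_table
#' @export
write_census_table <- function(table, path) {
  stopifnot(all(census_columns %in% names(table)))
  validate_census_table(table)
  utils::write.csv(as.data.frame(table)[census_columns], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_census_table <- function(tab) {
  if (!nrow(tab)) return(invisible(tab)) # empty table: valid, no treatments
  bad_day <- which(!(tab$day %in% seq(0L, 148L, by = 4L)))
  if (length(bad_day))
    stop("rows with days off the 4-day census schedule (0..148): ",
         paste(utils::head(bad_day, 5L), collapse = ", "))
  counts <- as.matrix(tab[c("eggs", "juveniles", "adults")])
  bad_neg <- which(apply(counts < 0 | !is.finite(counts), 1L, any))
  if (length(bad_neg))
    stop("rows with negative or non-finite counts: ",
         paste(utils::head(bad_neg, 5L), collapse = ", "))
  bad_int <- which(apply(counts != round(counts), 1L, any))
  if (length(bad_int))
    stop("rows with non-integer counts: ",
         paste(utils::head(bad_int, 5L), collapse = ", "))
  invisible(tab)
}

#' Estimate the log stochastic growth rate from a census table
#'
#' Telescoping estimator over each tube's total counts: the mean
#' one-step log growth ratio between consecutive censuses divided by the
#' census spacing, i.e. `log(N_end / N_start) / (days elapsed)`.  The
#' mixed-sex factor cancels in the ratio.
#'
#' @param table A census table.
#' @return Data frame with one row per (colour, harvest, tube) and the
#'   per-day `log_lambda_s` estimate.
#' @export
estimate_lambda_s <- function(table) {
  key <- interaction(table$colour, table$harvest, table$tube, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(table)), key), function(idx) {
    sub <- table[idx, ][order(table$day[idx]), ]
    tot <- sub$eggs + sub$juveniles + sub$adults
    span <- sub$day[nrow(sub)] - sub$day[1L]
    data.frame(colour = sub$colour[1L], harvest = sub$harvest[1L],
               tube = sub$tube[1L],
               log_lambda_s = log(tot[length(tot)] / tot[1L]) / span)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
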