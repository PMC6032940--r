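#' Derived DEB rates at a given feeding level
#'
#' The feeding level `EY` is a dimensionless gut-fullness proxy for
#' environmental quality, ranging over (0, 1].  Three quantities derive
#' from it: the ultimate length (von Bertalanffy asymptote)
#' `Linf = L_m * EY`; the length at maturity `L_p = lp_coeff * Linf`
#' (maturation is plastic: poorly fed individuals mature at smaller
#' sizes); and the von Bertalanffy growth rate
#' `rB = rb_scale / (rb_c0 - rb_c1 * Linf)`, which increases with feeding
#' level.
#'
#' @param EY Feeding level, in (0, 1].
#' @param params A [deb_params()] object.
#' @return A length (mm) for `ultimate_length()` and `maturation_length()`;
#'   a rate (per day) for `vb_growth_rate()`.
#' @examples
#' p <- deb_params()
#' ultimate_length(1, p)    # 1.008 mm
#' maturation_length(1, p)  # 0.539 * 1.008
#' vb_growth_rate(1, p)
#' @export
ultimate_length <- function(EY, params) {
  check_EY(EY)
  params$L_m * EY
}

#' @rdname ultimate_length
#' @export
maturation_length <- function(EY, params) {
  params$lp_coeff * ultimate_length(EY, params)
}

#' @rdname ultimate_length
#' @export
vb_growth_rate <- function(EY, params) {
  denom <- params$rb_c0 - params$rb_c1 * ultimate_length(EY, params)
  if (any(denom <= 0))
    stop("non-positive growth-rate denominator: rb_c0 - rb_c1 * Linf must be > 0")
  params$rb_scale / denom
}

check_EY <- function(EY) {
  if (!is.numeric(EY) || any(!is.finite(EY)) || any(EY <= 0) || any(EY > 1))
    stop("feeding level 'EY' must lie in (0, 1]")
  invisible(EY)
}

#' Vital-rate functions of the DEB-IPM
#'
#' The four daily vital rates that make up the projection kernel, for a
#' female of length `L` (mm) at feeding level `EY`:
#'
#' * `survival_prob()`: `exp(-mu)` while maintenance can be met
#'   (`L <= L_m * EY / kappa`), 0 above that starvation bound.
#' * `growth_mean()`: expected next-day length
#'   `L * exp(-rB) + (1 - exp(-rB)) * Linf`; individuals above the
#'   asymptote shrink towards it.
#' * `growth_sd()`: standard deviation of next-day length,
#'   `(1 - exp(-rB)) * L_m * sigma_Y`; independent of current length.
#' * `growth_density()`: Gaussian transition density for growing from
#'   `L` to `L_next` (per mm).
#' * `fecundity()`: female offspring per day,
#'   `EY * R_m * L^2 / L_m^2` for mature, non-starving individuals
#'   (`L_p <= L <= L_m * EY / kappa`), otherwise 0.
#'
#' All functions are vectorized over `L` (and `L_next`).
#'
#' @param L,L_next Body length(s), mm.
#' @param EY Feeding level in (0, 1].
#' @param params A [deb_params()] object.
#' @return Numeric vector: a probability, a length (mm), a density
#'   (per mm), or an offspring rate (per day).
#' @examples
#' p <- deb_params()
#' survival_prob(0.5, 0.5, p)   # exp(-0.03)
#' fecundity(1.008, 1, p)       # 16 female eggs per day
#' growth_mean(0.166, 1, p)
#' @export
survival_prob <- function(L, EY, params) {
  check_EY(EY)
  stopifnot(all(L > 0))
  bound <- params$L_m * EY / params$kappa
  ifelse(L <= bound, exp(-params$mu), 0)
}

#' @rdname survival_prob
#' @export
growth_mean <- function(L, EY, params) {
  rB <- vb_growth_rate(EY, params)
  L * exp(-rB) + (1 - exp(-rB)) * ultimate_length(EY, params)
}

#' @rdname survival_prob
#' @export
growth_sd <- function(EY, params) {
  rB <- vb_growth_rate(EY, params)
  (1 - exp(-rB)) * params$L_m * params$sigma_Y
}

#' @rdname survival_prob
#' @export
growth_density <- function(L_next, L, EY, params) {
  sd <- growth_sd(EY, params)
  if (sd <= 0)
    stop("growth_sd is zero: use the degenerate single-bin assignment instead")
  stats::dnorm(L_next, mean = growth_mean(L, EY, params), sd = sd)
}

#' @rdname survival_prob
#' @export
fecundity <- function(L, EY, params) {
  check_EY(EY)
  stopifnot(all(L > 0))
  Lp <- maturation_length(EY, params)
  bound <- params$L_m * EY / params$kappa
  ifelse(L >= Lp & L <= bound, EY * params$R_m * L^2 / params$L_m^2, 0)
}

#' Discretization mesh over the body-length domain
#'
#' The length domain runs from `0.9 * L_b` to `L_m` by default: the lower
#' margin leaves room for the small Gaussian growth mass that falls just
#' below the birth length, while offspring themselves enter exactly at
#' `L_b`.  The midpoint rule is used throughout, with the bin midpoints as
#' mesh points.
#'
#' @param params A [deb_params()] object (sets the default bounds).
#' @param n_bins Number of bins (default 200; more bins change results
#'   negligibly).
#' @param lower,upper Domain bounds (mm).
#' @return An object of class `"size_grid"`: list with `lower`, `upper`,
#'   `n_bins`, `midpoints`, `bin_width`, `breaks`.
#' @examples
#' g <- size_grid(deb_params())
#' range(g$midpoints); g$bin_width
#' @export
size_grid <- function(params = deb_params(), n_bins = 200,
                      lower = 0.9 * params$L_b, upper = params$L_m) {
  stopifnot(is.numeric(n_bins), length(n_bins) == 1L, n_bins >= 2,
            n_bins == round(n_bins), lower > 0, lower < upper)
  dx <- (upper - lower) / n_bins
  breaks <- lower + dx * (0:n_bins)
  g <- structure(list(lower = lower, upper = upper, n_bins = as.integer(n_bins),
                      midpoints = lower + dx * (seq_len(n_bins) - 0.5),
                      bin_width = dx, breaks = breaks),
                 class = "size_grid")
  if (is.na(bin_index(params$L_b, g)))
    stop("grid does not contain the birth length 'L_b'")
  g
}

#' @export
print.size_grid <- function(x, ...) {
  cat(sprintf("size grid: %d bins on [%.4f, %.4f] mm (width %.5f mm)\n",
              x$n_bins, x$lower, x$upper, x$bin_width))
  invisible(x)
}

# index of the bin whose half-open interval [break_i, break_{i+1}) holds L;
# the top break is closed so upper-boundary mass is kept
bin_index <- function(L, grid) {
  i <- findInterval(L, grid$breaks, rightmost.closed = TRUE)
  i[i < 1L | i > grid$n_bins] <- NA_integer_
  i
}

#' Offspring-size distribution column
#'
#' Probability distribution over grid bins of the lengths of offspring
#' produced by a parent of length `L_parent`.  Immature parents
#' (`L_parent < L_p(EY)`) return an all-zero column.  With the default
#' `sigma_Lb = 0`, offspring length is exactly `L_b` and the column is a
#' unit mass in the bin containing `L_b` (an exact assignment, not a
#' numerically evaluated delta); with `sigma_Lb > 0` the column is a
#' discretized Gaussian renormalized to sum to 1.
#'
#' @param L_parent Parent length (mm).
#' @param EY Feeding level in (0, 1].
#' @param grid A [size_grid()].
#' @param params A [deb_params()] object.
#' @return Numeric vector of length `grid$n_bins` summing to 1 (mature
#'   parent) or 0 (immature parent).
#' @export
offspring_column <- function(L_parent, EY, grid, params) {
  out <- numeric(grid$n_bins)
  if (L_parent < maturation_length(EY, params)) return(out)
  ib <- bin_index(params$L_b, grid)
  if (is.na(ib)) stop("birth length 'L_b' lies outside the grid")
  if (params$sigma_Lb <= 0) {
    out[ib] <- 1
  } else {
    d <- stats::dnorm(grid$midpoints, mean = params$L_b, sd = params$sigma_Lb)
    s <- sum(d)
    if (s <= 0) stop("offspring-size distribution has no mass on the grid")
    out <- d / s
  }
  out
}

#' Build the discretized daily projection kernel
#'
#' Discretization of the DEB-IPM over the grid at feeding level `EY`.
#' Writing `x_j` for the mesh points, the transition matrix is
#' `A = F + P` with survival/growth part
#' `P[i, j] = [Phi((b_{i+1} - m_j)/s) - Phi((b_i - m_j)/s)] * S(x_j)`
#' and fecundity part `F[i, j] = D_j[i] * R(x_j)`.  Here the source
#' dimension uses the midpoint rule (vital rates evaluated at `x_j`),
#' while the growth transition integrates the Gaussian of mean
#' `m_j = growth_mean(x_j)` and s.d. `s = growth_sd` exactly over each
#' destination bin `[b_i, b_{i+1})` via normal CDF differences, and `D_j`
#' is the [offspring_column()] of parent bin `j` (a probability vector).
#' Destination-bin integration is essential here: the daily growth s.d.
#' (about 0.002-0.024 mm) can be narrower than a bin, where sampling the
#' density at bin midpoints fabricates or destroys probability mass.
#' With CDF differences each column's growth mass sums to the survival
#' probability exactly, up to the mass truncated at the domain boundary.
#'
#' Gaussian growth mass falling outside the domain is truncated, not
#' renormalized (the loss is below 0.1% for the default parameters);
#' renormalizing would silently inflate survival.  With `sigma_Y = 0`
#' growth is deterministic and each column's survival mass is assigned
#' exactly to the bin containing the mean next-day length.
#'
#' `survivor_weighted_fecundity` multiplies the fecundity part by the
#' parental survival probability `S(x_j)`, encoding the reading that only
#' surviving adults reproduce; the default leaves fecundity unweighted,
#' the literal form of the projection equation.  The two variants differ
#' by under `exp(-mu)`, about 3% for the default mortality.
#'
#' @param EY Feeding level in (0, 1].
#' @param grid A [size_grid()].
#' @param params A [deb_params()] object.
#' @param survivor_weighted_fecundity Logical flag (default `FALSE`).
#' @return An object of class `"deb_kernel"`: list with `matrix`,
#'   `survival_part`, `fecundity_part` (all `n_bins x n_bins`), `EY`,
#'   `grid`, `params`, `survivor_weighted_fecundity`.
#' @seealso [lambda1()], [project_one_day()], [write_kernel()]
#' @examples
#' p <- deb_params()
#' g <- size_grid(p, n_bins = 50)
#' K <- build_kernel(0.36, g, p)
#' lambda1(K)
#' @export
build_kernel <- function(EY, grid, params,
                         survivor_weighted_fecundity = FALSE) {
  check_EY(EY)
  stopifnot(inherits(grid, "size_grid"), inherits(params, "deb_params"))
  n <- grid$n_bins
  x <- grid$midpoints

  S <- survival_prob(x, EY, params)
  gm <- growth_mean(x, EY, params)
  gs <- growth_sd(EY, params)
  if (gs > 0) {
    # (n+1) x n matrix of Phi((b_i - m_j)/s), differenced over breaks
    P <- stats::pnorm(outer(grid$breaks, gm, `-`) / gs)
    G <- P[-1L, , drop = FALSE] - P[-(n + 1L), , drop = FALSE]
    surv_part <- sweep(G, 2L, S, `*`)
  } else {
    # deterministic growth: all of a column's surviving mass lands in the
    # bin holding the mean next-day length (evicted if outside the domain)
    surv_part <- matrix(0, n, n)
    ib <- bin_index(gm, grid)
    keep <- !is.na(ib)
    surv_part[cbind(ib[keep], which(keep))] <- S[keep]
  }

  R <- fecundity(x, EY, params)
  if (survivor_weighted_fecundity) R <- R * S
  Lp <- maturation_length(EY, params)
  Dcol <- offspring_column(max(x[1], Lp), EY, grid, params) # mature template
  fec_part <- outer(Dcol, R, `*`)

  structure(list(matrix = surv_part + fec_part,
                 survival_part = surv_part,
                 fecundity_part = fec_part,
                 EY = EY, grid = grid, params = params,
                 survivor_weighted_fecundity = survivor_weighted_fecundity),
            class = "deb_kernel")
}

#' @export
print.deb_kernel <- function(x, ...) {
  cat(sprintf("DEB-IPM daily kernel: %d x %d, EY = %.4g%s\n",
              x$grid$n_bins, x$grid$n_bins, x$EY,
              if (x$survivor_weighted_fecundity) ", survivor-weighted fecundity" else ""))
  cat(sprintf("  dominant eigenvalue: %.6f\n", lambda1(x)))
  invisible(x)
}

#' Dominant eigenvalue of a projection kernel
#'
#' The asymptotic daily population growth rate in a constant environment
#' at the kernel's feeding level.
#'
#' @param kernel A [build_kernel()] result or a plain square matrix.
#' @return The dominant eigenvalue (real part; the Perron root of a
#'   non-negative matrix is real).
#' @export
lambda1 <- function(kernel) {
  A <- if (inherits(kernel, "deb_kernel")) kernel$matrix else kernel
  ev <- eigen(A, only.values = TRUE)$values
  Re(ev[which.max(Mod(ev))])
}

#' Feeding level at which the population is stationary
#'
#' Scans a fine grid of constant feeding levels for the sign change of
#' `lambda1 - 1` and refines the crossing by bisection.  If several
#' crossings exist on the interval (the eigenvalue is not monotone in
#' `EY` because the maturation threshold moves with the feeding level),
#' the lowest is returned with a warning listing the others.
#'
#' @param params A [deb_params()] object.
#' @param grid A [size_grid()]; defaults to the 200-bin mesh.
#' @param interval Feeding-level search interval.
#' @param survivor_weighted_fecundity Passed to [build_kernel()].
#' @param scan_points Number of initial scan points.
#' @param tol Bisection tolerance on the feeding level.
#' @return The equilibrium feeding level (lowest crossing), with the full
#'   set of crossings as attribute `"crossings"`.
#' @export
equilibrium_feeding <- function(params = deb_params(), grid = size_grid(params),
                                interval = c(0.05, 0.95),
                                survivor_weighted_fecundity = FALSE,
                                scan_points = 46, tol = 1e-4) {
  f <- function(ey) lambda1(build_kernel(ey, grid, params,
                                         survivor_weighted_fecundity)) - 1
  ey <- seq(interval[1], interval[2], length.out = scan_points)
  v <- vapply(ey, f, numeric(1))
  sgn <- sign(v)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (!length(idx)) {
    if (any(v == 0)) return(ey[which(v == 0)][1])
    stop("no eigenvalue crossing of 1 on the interval [",
         interval[1], ", ", interval[2], "]")
  }
  roots <- vapply(idx, function(i)
    stats::uniroot(f, c(ey[i], ey[i + 1]), tol = tol)$root, numeric(1))
  if (length(roots) > 1)
    warning("multiple stationarity crossings found: ",
            paste(signif(roots, 4), collapse = ", "),
            "; returning the lowest")
  structure(roots[1], crossings = roots)
}

#' Export or import a kernel matrix as delimited text
#'
#' Writes the full transition matrix as tab-separated values with a
#' comment header recording the feeding level, bin count and domain
#' bounds, so a kernel can be inspected or reused outside R.
#'
#' @param kernel A `"deb_kernel"` object.
#' @param path Output/input file path.
#' @return `write_kernel()` returns `path` invisibly; `read_kernel()`
#'   returns a list with `matrix` and the header fields `EY`, `n_bins`,
#'   `lower`, `upper`.
#' @export
write_kernel <- function(kernel, path) {
  stopifnot(inherits(kernel, "deb_kernel"))
  g <- kernel$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# deb_kernel EY=%.10g n_bins=%d lower=%.10g upper=%.10g",
                     kernel$EY, g$n_bins, g$lower, g$upper), con)
  utils::write.table(kernel$matrix, con, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "# deb_kernel"))
    stop("'", path, "' does not look like an exported kernel")
  fields <- strsplit(sub("^# deb_kernel ", "", hdr), " ")[[1]]
  kv <- strsplit(fields, "=")
  meta <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2L)),
                          vapply(kv, `[`, "", 1L))
  m <- as.matrix(utils::read.table(path, sep = "\t", skip = 1L))
  dimnames(m) <- NULL
  if (nrow(m) != meta[["n_bins"]] || ncol(m) != meta[["n_bins"]])
    stop("kernel dimensions do not match the header")
  list(matrix = m, EY = meta[["EY"]], n_bins = as.integer(meta[["n_bins"]]),
       lower = meta[["lower"]], upper = meta[["upper"]])
}
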