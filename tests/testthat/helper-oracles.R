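# Independent oracles, deliberately coded on different paths from the
# package internals.

# dominant eigenvalue by power iteration (oracle for eigen())
power_lambda <- function(A, iters = 500, tol = 1e-12) {
  v <- rep(1, nrow(A))
  lam <- 0
  for (i in seq_len(iters)) {
    w <- A %*% v
    lam_new <- sum(w) / sum(v)
    v <- w / sum(w)
    if (abs(lam_new - lam) < tol) break
    lam <- lam_new
  }
  lam
}

# kernel entries recomputed from scratch (double loop, scalar arithmetic,
# destination bins integrated by CDF differences), for the
# oracle-equivalence check
oracle_kernel <- function(EY, grid, params, weighted = FALSE) {
  n <- grid$n_bins
  x <- grid$midpoints
  b <- grid$breaks
  Linf <- params$L_m * EY
  Lp <- params$lp_coeff * Linf
  rB <- params$rb_scale / (params$rb_c0 - params$rb_c1 * Linf)
  sd <- (1 - exp(-rB)) * params$L_m * params$sigma_Y
  bound <- params$L_m * EY / params$kappa
  ibirth <- max(which(b <= params$L_b))
  A <- matrix(0, n, n)
  for (j in seq_len(n)) {
    S <- if (x[j] <= bound) exp(-params$mu) else 0
    m <- x[j] * exp(-rB) + (1 - exp(-rB)) * Linf
    R <- if (x[j] >= Lp && x[j] <= bound)
      EY * params$R_m * x[j]^2 / params$L_m^2 else 0
    if (weighted) R <- R * S
    for (i in seq_len(n)) {
      A[i, j] <- (stats::pnorm(b[i + 1], m, sd) - stats::pnorm(b[i], m, sd)) * S
      if (i == ibirth) A[i, j] <- A[i, j] + R
    }
  }
  A
}

small_grid <- function(n = 60, params = deb_params()) size_grid(params, n_bins = n)
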