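# Independent brute-force oracles used to freeze expected values. These
# deliberately avoid the package's own code paths.

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

# Interval-union total time on a 0.001-s grid.
grid_union_time <- function(bouts, window = 300, step = 0.001) {
  if (length(bouts) == 0 || nrow(bouts) == 0) return(0)
  grid <- seq(step / 2, window - step / 2, by = step)
  covered <- rep(FALSE, length(grid))
  for (i in seq_len(nrow(bouts))) {
    covered <- covered | (grid > bouts[i, 1] & grid < bouts[i, 2])
  }
  sum(covered) * step
}

# Exhaustive two-sample mean-difference randomization: exact two-sided
# tail proportion over all C(n, nx) assignments.
oracle_exact_two_sample <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  t_obs <- mean(x) - mean(y)
  cmb <- utils::combn(length(pooled), nx)
  t_all <- apply(cmb, 2, function(ix) mean(pooled[ix]) - mean(pooled[-ix]))
  mean(abs(t_all) >= abs(t_obs) - 1e-12)
}

# Exhaustive stratified LI-contrast randomization: enumerate every
# reassignment of the naive pool and, independently, the trained pool.
oracle_exact_li_contrast <- function(na_a, tr_a, na_b, tr_b) {
  li <- function(na, tr) 100 * (1 - mean(tr) / mean(na))
  t_obs <- li(na_a, tr_a) - li(na_b, tr_b)
  na_pool <- c(na_a, na_b)
  tr_pool <- c(tr_a, tr_b)
  na_cmb <- utils::combn(length(na_pool), length(na_a))
  tr_cmb <- utils::combn(length(tr_pool), length(tr_a))
  t_all <- c()
  for (i in seq_len(ncol(na_cmb))) {
    naa <- na_pool[na_cmb[, i]]
    nab <- na_pool[-na_cmb[, i]]
    if (mean(naa) <= 0 || mean(nab) <= 0) next  # LI undefined: excluded
    for (j in seq_len(ncol(tr_cmb))) {
      t_all <- c(t_all, li(naa, tr_pool[tr_cmb[, j]]) -
                   li(nab, tr_pool[-tr_cmb[, j]]))
    }
  }
  mean(abs(t_all) >= abs(t_obs) - 1e-12)
}

# Brute-force exact Mann-Whitney two-sided p by enumerating all rank
# assignments (tie-free data).
oracle_exact_mwu <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  cmb <- utils::combn(length(pooled), nx)
  u_all <- apply(cmb, 2, function(ix) sum(r[ix]) - nx * (nx + 1) / 2)
  lo <- mean(u_all <= u_obs)
  hi <- mean(u_all >= u_obs)
  min(1, 2 * min(lo, hi))
}

# Hypergeometric upper-tail P(X >= k) as an explicit sum of exact ratios.
oracle_hyper_tail <- function(k, K, n, N) {
  if (k <= 0) return(1)
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Brute-force Venn region counts via a per-element membership table.
oracle_venn <- function(sets) {
  universe <- unique(unlist(sets))
  nm <- names(sets)
  out <- list()
  for (g in universe) {
    sig <- vapply(sets, function(s) g %in% s, logical(1))
    key <- paste(nm[sig], collapse = "&")
    out[[key]] <- c(out[[key]], g)
  }
  vapply(out, length, integer(1))
}

# Simple beta-layer CI sample matching the generator's contract, for null
# simulations that must not depend on the generator under test.
oracle_beta_ci <- function(n, mean_pct = 50, conc = 10) {
  mu <- mean_pct / 100
  100 * stats::rbeta(n, mu * conc, (1 - mu) * conc)
}
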