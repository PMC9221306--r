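# T-maze olfactory preference. The unit of analysis is the replicate (one
# T-maze run of ~15 males), not the individual fly; V is the percentage of
# flies attracted (non-repulsed) by the odorant arm.

#' Olfactory preference index
#'
#' `V(%) = 100 * n_odor / n_total`: the percentage of flies in the odorant
#' arm of the T-maze at the end of the choice period. Vectorized.
#'
#' @param n_odor Flies counted in the odorant tube.
#' @param n_total Total flies in the replicate (must be >= 1).
#' @return V as a percentage in `[0, 100]`.
#' @examples
#' preference_index(5, 15)
#' @export
preference_index <- function(n_odor, n_total) {
  if (any(!is.finite(n_odor)) || any(!is.finite(n_total))) {
    stop("counts must be finite", call. = FALSE)
  }
  if (any(n_total < 1)) stop("n_total must be at least 1", call. = FALSE)
  if (any(n_odor < 0) || any(n_odor > n_total)) {
    stop("n_odor must lie in [0, n_total]", call. = FALSE)
  }
  100 * n_odor / n_total
}

#' Mann-Whitney U test (exact or tie-corrected normal approximation)
#'
#' `U` counts pairs `(x_i, y_j)` with `x_i > y_j`, plus half the tied
#' pairs. In exact mode (the automatic choice for tie-free samples with at
#' most `exact_threshold` rank arrangements) the two-sided p-value comes
#' from the exact null distribution of U; exact mode refuses tied data and
#' falls back to the approximation with a message. Approximate mode uses
#' the normal approximation with midrank tie correction of the variance
#' and a continuity correction.
#'
#' @param x,y Non-empty numeric samples.
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @param exact_threshold Largest `choose(n + m, n)` handled exactly in
#'   auto mode (default 20000).
#' @return A list with `U`, `p` (two-sided, in `(0, 1]`) and `method`.
#' @examples
#' mwu_test(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
mwu_test <- function(x, y, mode = c("auto", "exact", "approx"),
                     exact_threshold = 20000) {
  mode <- match.arg(mode)
  if (length(x) == 0L || length(y) == 0L) {
    stop("samples must be non-empty", call. = FALSE)
  }
  nx <- length(x)
  ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(pooled) > 0L

  want_exact <- switch(mode,
                       exact = TRUE,
                       approx = FALSE,
                       auto = !ties && choose(nx + ny, nx) <= exact_threshold)
  if (want_exact && ties) {
    message("mwu_test: ties present, exact mode unavailable; falling back to the tie-corrected normal approximation")
    want_exact <- FALSE
  }
  if (want_exact) {
    u_int <- round(u)
    p <- if (u_int > nx * ny / 2) {
      stats::pwilcox(u_int - 1, nx, ny, lower.tail = FALSE)
    } else {
      stats::pwilcox(u_int, nx, ny)
    }
    return(list(U = u, p = min(2 * p, 1), method = "exact"))
  }
  n <- nx + ny
  tie_tab <- table(pooled)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 <= 0) {
    # all pooled values identical: the null is symmetric and degenerate
    return(list(U = u, p = 1, method = "approx"))
  }
  z <- u - nx * ny / 2
  if (abs(z) < .STAT_TOL) {
    p <- 1
  } else {
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- min(2 * stats::pnorm(-abs(z)), 1)
  }
  list(U = u, p = p, method = "approx")
}

#' Read an olfactory replicate CSV
#'
#' Expected header: `replicate_id,genotype,n_odor,n_total`. The preference
#' index `v` is computed per replicate.
#'
#' @param path Path to the CSV file.
#' @return A tibble with `replicate_id`, `genotype`, `n_odor`, `n_total`,
#'   `v`.
#' @export
read_olfactory <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(replicate_id = "character",
                                       genotype = "character"))
  need <- c("replicate_id", "genotype", "n_odor", "n_total")
  if (!identical(names(df), need)) {
    stop("malformed olfactory header: expected ",
         paste(need, collapse = ","), call. = FALSE)
  }
  out <- tibble::as_tibble(df)
  out$v <- preference_index(out$n_odor, out$n_total)
  out
}

#' Per-genotype olfactory summary with Mann-Whitney tests vs control
#'
#' Summarizes the distribution of the preference index V per genotype
#' (replicate-level median, quartiles, n) and compares each experimental
#' genotype with the control by [mwu_test()]. Genotypes with fewer than 2
#' replicates are reported untested.
#'
#' @param replicates Tibble with at least `genotype`, `n_odor`, `n_total`
#'   (e.g. from [read_olfactory()] or [generate_olfactory()]).
#' @param control Control genotype label (must be present).
#' @param mode Mann-Whitney mode passed to [mwu_test()].
#' @return A tibble with one row per genotype: `genotype`, `n`,
#'   `v_median`, `v_q1`, `v_q3`, `U`, `p` (NA for the control itself and
#'   for untested genotypes) and `tested`.
#' @export
olfactory_report <- function(replicates, control, mode = "auto") {
  if (!control %in% replicates$genotype) {
    stop("control genotype '", control, "' not present", call. = FALSE)
  }
  v <- preference_index(replicates$n_odor, replicates$n_total)
  gts <- unique(replicates$genotype)
  gts <- c(control, setdiff(gts, control))
  v_ctrl <- v[replicates$genotype == control]
  rows <- lapply(gts, function(g) {
    vg <- v[replicates$genotype == g]
    q <- stats::quantile(vg, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    testable <- !identical(g, control) && length(vg) >= 2L &&
      length(v_ctrl) >= 2L
    if (testable) {
      mw <- mwu_test(vg, v_ctrl, mode = mode)
      u_stat <- mw$U
      p <- mw$p
    } else {
      u_stat <- NA_real_
      p <- NA_real_
    }
    tibble::tibble(genotype = g, n = length(vg), v_median = q[2L],
                   v_q1 = q[1L], v_q3 = q[3L], U = u_stat, p = p,
                   tested = testable)
  })
  do.call(rbind, rows)
}
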