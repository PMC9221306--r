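# Two-sided randomization tests for the courtship-suppression paradigm.
#
# The inferential quantity throughout is alpha_R, the directly computed
# probability of rejecting the null hypothesis of no group difference under
# random relabelling. In sampled mode alpha_R = (b + 1) / (m + 1), where b
# counts permuted statistics with |T_perm| >= |T_obs| among m random
# relabellings — the add-one correction keeps sampled p-values strictly
# positive and the test valid. In exhaustive mode alpha_R is the exact tail
# proportion over all label assignments. Ties |T_perm| = |T_obs| within
# 1e-12 count as extreme.

.STAT_TOL <- 1e-12

.draw_seed <- function(seed) {
  if (is.null(seed)) sample.int(2147483646L, 1L) else as.integer(seed)
}

.new_rand_result <- function(statistic, alpha, n_perm, scheme, exhaustive,
                             seed, n_redrawn = 0L) {
  structure(list(statistic_observed = statistic, alpha_R = alpha,
                 n_perm = n_perm, scheme = scheme, exhaustive = exhaustive,
                 seed = seed, n_redrawn = n_redrawn),
            class = "rand_test_result")
}

#' @export
print.rand_test_result <- function(x, ...) {
  cat(sprintf("Two-sided randomization test (%s%s)\n", x$scheme,
              if (x$exhaustive) ", exhaustive" else ", sampled"))
  cat(sprintf("  T observed = %.6g\n  alpha_R    = %.6g  (%d %s)\n",
              x$statistic_observed, x$alpha_R, x$n_perm,
              if (x$exhaustive) "assignments" else "permutations"))
  if (!x$exhaustive) cat(sprintf("  seed       = %d\n", x$seed))
  if (x$n_redrawn > 0L) cat(sprintf("  redrawn    = %d\n", x$n_redrawn))
  invisible(x)
}

#' Learning index from naive and trained CI samples
#'
#' `LI = (1 - CI_tr / CI_na) * 100`, where `CI_na` and `CI_tr` are the mean
#' courtship indices of independent naive and trained male samples. LI is 0
#' when training leaves courtship unchanged, 100 at complete suppression,
#' and negative when trained males court more than naive ones; it is
#' undefined when the naive males did not court at all.
#'
#' @param ci_na,ci_tr Numeric vectors of per-male CI percentages for the
#'   naive and trained cohorts.
#' @return An object of class `learning_result`: a list with
#'   `ci_na_mean`, `ci_tr_mean`, `li`, `n_na`, `n_tr`.
#' @examples
#' learning_index(c(60, 60), c(15, 15))$li  # 75
#' @export
learning_index <- function(ci_na, ci_tr) {
  if (length(ci_na) == 0L || length(ci_tr) == 0L) {
    stop("both CI samples must be non-empty", call. = FALSE)
  }
  m_na <- mean(ci_na)
  m_tr <- mean(ci_tr)
  if (m_na <= 0) {
    stop("LI undefined: naive males did not court (mean CI_na = 0)",
         call. = FALSE)
  }
  structure(list(ci_na_mean = m_na, ci_tr_mean = m_tr,
                 li = 100 * (1 - m_tr / m_na),
                 n_na = length(ci_na), n_tr = length(ci_tr)),
            class = "learning_result")
}

#' @export
print.learning_result <- function(x, ...) {
  cat(sprintf("LI = %.2f  (CI_na = %.2f, n = %d; CI_tr = %.2f, n = %d)\n",
              x$li, x$ci_na_mean, x$n_na, x$ci_tr_mean, x$n_tr))
  invisible(x)
}

# Sampled permutation mean-differences: reassigns pooled values to groups of
# size nx / ny, m times; returns the vector of permuted statistics.
.perm_mean_diffs <- function(pooled, nx, m) {
  n <- length(pooled)
  ny <- n - nx
  total <- sum(pooled)
  idx <- vapply(seq_len(m), function(i) sample.int(n, nx), integer(nx))
  sx <- colSums(matrix(pooled[idx], nrow = nx))
  sx / nx - (total - sx) / ny
}

# All C(n, nx) assignment mean-differences.
.all_mean_diffs <- function(pooled, nx) {
  n <- length(pooled)
  ny <- n - nx
  total <- sum(pooled)
  cmb <- utils::combn(n, nx)
  sx <- colSums(matrix(pooled[cmb], nrow = nx))
  sx / nx - (total - sx) / ny
}

#' Two-sample sampled randomization test
#'
#' Tests the null of no difference between two independent samples (e.g.
#' trained vs naive CIs of one strain) with the statistic
#' `T = mean(x) - mean(y)`. Group labels of the pooled values are randomly
#' reassigned preserving group sizes; `alpha_R` is the two-sided rejection
#' probability. When the number of distinct assignments
#' `choose(nx + ny, nx)` does not exceed `exhaustive_threshold` (and
#' `exhaustive = "auto"`), the full enumeration is used and the result is
#' flagged exhaustive.
#'
#' @param x,y Numeric samples, each of size at least 2.
#' @param n_perm Number of sampled permutations (default 10000).
#' @param seed Integer seed recorded in the result; drawn at random when
#'   `NULL`.
#' @param exhaustive `"auto"` (enumerate when small enough), `"never"`
#'   (always sample) or `"always"` (enumerate or fail).
#' @param exhaustive_threshold Largest assignment count enumerated in auto
#'   mode (default 10000).
#' @return A `rand_test_result` (see [print.rand_test_result()]).
#' @export
randomization_two_sample <- function(x, y, n_perm = 10000, seed = NULL,
                                     exhaustive = c("auto", "never", "always"),
                                     exhaustive_threshold = 10000) {
  exhaustive <- match.arg(exhaustive)
  if (length(x) < 2L || length(y) < 2L) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  if (n_perm < 1L) stop("n_perm must be at least 1", call. = FALSE)
  t_obs <- mean(x) - mean(y)
  pooled <- c(x, y)
  n_assign <- choose(length(pooled), length(x))
  do_exact <- switch(exhaustive,
                     auto = n_assign <= exhaustive_threshold,
                     never = FALSE,
                     always = TRUE)
  if (do_exact) {
    if (n_assign > 2e5) {
      stop("too many assignments to enumerate; use sampled mode",
           call. = FALSE)
    }
    t_perm <- .all_mean_diffs(pooled, length(x))
    alpha <- mean(abs(t_perm) >= abs(t_obs) - .STAT_TOL)
    return(.new_rand_result(t_obs, alpha, as.integer(n_assign),
                            "two_sample", TRUE, NA_integer_))
  }
  seed <- .draw_seed(seed)
  set.seed(seed)
  t_perm <- .perm_mean_diffs(pooled, length(x), n_perm)
  b <- sum(abs(t_perm) >= abs(t_obs) - .STAT_TOL)
  .new_rand_result(t_obs, (b + 1) / (n_perm + 1), as.integer(n_perm),
                   "two_sample", FALSE, seed)
}

#' Exhaustive two-sample randomization probability
#'
#' Exact tail proportion of assignments with `|T| >= |T_obs|` over all
#' `choose(nx + ny, nx)` relabellings; ties count as extreme. The default
#' statistic is the difference of means; any two-argument statistic can be
#' supplied (evaluated per assignment, slower). Serves as the internal
#' oracle for the sampled test, whose `alpha_R` converges to this value as
#' `n_perm` grows.
#'
#' @param x,y Numeric samples.
#' @param statistic Optional `function(x, y)` returning a scalar.
#' @return The exact probability in `(0, 1]`.
#' @export
exact_randomization <- function(x, y, statistic = NULL) {
  n_assign <- choose(length(x) + length(y), length(x))
  if (n_assign > 2e5) {
    stop("more than 200000 assignments; use the sampled randomization test",
         call. = FALSE)
  }
  pooled <- c(x, y)
  nx <- length(x)
  if (is.null(statistic)) {
    t_obs <- mean(x) - mean(y)
    t_perm <- .all_mean_diffs(pooled, nx)
  } else {
    t_obs <- statistic(x, y)
    cmb <- utils::combn(length(pooled), nx)
    t_perm <- apply(cmb, 2L, function(ix) {
      statistic(pooled[ix], pooled[-ix])
    })
  }
  mean(abs(t_perm) >= abs(t_obs) - .STAT_TOL)
}

# Stratified LI-contrast permutation core. Strata are the naive and trained
# pools; occasion/strain labels are shuffled within each stratum
# independently and training status is never exchanged. Permutations whose
# relabelled naive mean is zero (LI undefined) are redrawn and counted.
.rand_li_contrast <- function(na_a, tr_a, na_b, tr_b, n_perm, seed, scheme) {
  for (s in list(na_a, tr_a, na_b, tr_b)) {
    if (length(s) == 0L) stop("all four CI samples must be non-empty",
                              call. = FALSE)
  }
  if (mean(na_a) <= 0 || mean(na_b) <= 0) {
    stop("LI undefined: a naive sample has mean CI 0", call. = FALSE)
  }
  if (n_perm < 1L) stop("n_perm must be at least 1", call. = FALSE)
  li <- function(na, tr) 100 * (1 - mean(tr) / mean(na))
  t_obs <- li(na_a, tr_a) - li(na_b, tr_b)

  seed <- .draw_seed(seed)
  set.seed(seed)
  na_pool <- c(na_a, na_b)
  tr_pool <- c(tr_a, tr_b)
  n_na_a <- length(na_a)
  n_tr_a <- length(tr_a)

  draw <- function(m) {
    na_idx <- vapply(seq_len(m), function(i) sample.int(length(na_pool), n_na_a),
                     integer(n_na_a))
    tr_idx <- vapply(seq_len(m), function(i) sample.int(length(tr_pool), n_tr_a),
                     integer(n_tr_a))
    na_sa <- colSums(matrix(na_pool[na_idx], nrow = n_na_a)) / n_na_a
    na_sb <- (sum(na_pool) - na_sa * n_na_a) / (length(na_pool) - n_na_a)
    tr_sa <- colSums(matrix(tr_pool[tr_idx], nrow = n_tr_a)) / n_tr_a
    tr_sb <- (sum(tr_pool) - tr_sa * n_tr_a) / (length(tr_pool) - n_tr_a)
    list(t = (100 * (1 - tr_sa / na_sa)) - (100 * (1 - tr_sb / na_sb)),
         bad = na_sa <= .STAT_TOL | na_sb <= .STAT_TOL)
  }

  res <- draw(n_perm)
  t_perm <- res$t
  bad <- res$bad
  n_redrawn <- 0L
  rounds <- 0L
  while (any(bad)) {
    rounds <- rounds + 1L
    if (rounds > 1000L) {
      stop("could not draw valid permutations (naive means keep collapsing to 0)",
           call. = FALSE)
    }
    n_redrawn <- n_redrawn + sum(bad)
    rep_res <- draw(sum(bad))
    t_perm[bad] <- rep_res$t
    bad[bad] <- rep_res$bad
  }
  if (n_redrawn > 0.01 * n_perm) {
    warning(sprintf("%d of %d permutations redrawn (degenerate naive means)",
                    n_redrawn, n_perm), call. = FALSE)
  }
  b <- sum(abs(t_perm) >= abs(t_obs) - .STAT_TOL)
  .new_rand_result(t_obs, (b + 1) / (n_perm + 1), as.integer(n_perm),
                   scheme, FALSE, seed, n_redrawn)
}

.as_ci_pair <- function(g, what) {
  if (!is.list(g) || is.null(g$ci_na) || is.null(g$ci_tr)) {
    stop(sprintf("'%s' must be a list with elements ci_na and ci_tr", what),
         call. = FALSE)
  }
  g
}

#' Between-strain learning-index contrast by stratified randomization
#'
#' Tests `T = LI_A - LI_B` between two strains measured at the same time
#' point. Under the null the strain label is exchangeable within a training
#' condition, so the permutation shuffles strain labels among the naive
#' males and, independently, among the trained males; training status is
#' never permuted (naive and trained cohorts are independent samples, not a
#' pairing). Permutations producing a naive group mean of zero (LI
#' undefined) are redrawn and counted; more than 1% redrawn raises a
#' warning.
#'
#' @param group_a,group_b Lists with numeric elements `ci_na` and `ci_tr`.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed; drawn at random when `NULL`.
#' @return A `rand_test_result` with scheme `"li_contrast"`.
#' @export
randomization_li_contrast <- function(group_a, group_b, n_perm = 10000,
                                      seed = NULL) {
  a <- .as_ci_pair(group_a, "group_a")
  b <- .as_ci_pair(group_b, "group_b")
  .rand_li_contrast(a$ci_na, a$ci_tr, b$ci_na, b$ci_tr, n_perm, seed,
                    "li_contrast")
}

#' Retention contrast: delayed vs immediate learning index
#'
#' Tests whether the learning index measured at a delayed time point
#' differs from the one immediately after training within the same strain:
#' `T = LI_delayed - LI_immediate`. Identical stratified machinery to
#' [randomization_li_contrast()] with the occasion (immediate/delayed)
#' label permuted within the naive and trained strata.
#'
#' @param immediate,delayed Lists with numeric elements `ci_na`, `ci_tr`
#'   for the immediate and delayed tests.
#' @inheritParams randomization_li_contrast
#' @return A `rand_test_result` with scheme `"retention"`.
#' @export
retention_contrast <- function(immediate, delayed, n_perm = 10000,
                               seed = NULL) {
  i <- .as_ci_pair(immediate, "immediate")
  d <- .as_ci_pair(delayed, "delayed")
  .rand_li_contrast(d$ci_na, d$ci_tr, i$ci_na, i$ci_tr, n_perm, seed,
                    "retention")
}
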