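# Learning index and the two-sided randomization machinery.

test_that("learning_index follows LI = (1 - CI_tr/CI_na) * 100", {
  expect_equal(learning_index(c(40, 60), c(40, 60))$li, 0)
  expect_equal(learning_index(c(40, 60), c(0, 0))$li, 100)
  r <- learning_index(c(55, 65), c(10, 20))  # means 60 and 15
  expect_equal(r$li, 75)
  expect_equal(r$n_na, 2)
  expect_equal(r$ci_tr_mean, 15)
  # higher trained courtship than naive gives a negative LI
  expect_lt(learning_index(c(30, 30), c(40, 50))$li, 0)
  expect_error(learning_index(c(0, 0), c(10, 20)), "undefined")
  expect_error(learning_index(numeric(0), 1), "non-empty")
})

test_that("LI strictly decreases as trained courtship increases", {
  na <- c(40, 50, 60)
  lis <- vapply(seq(5, 60, by = 5),
                function(m) learning_index(na, c(m, m))$li, numeric(1))
  expect_true(all(diff(lis) < 0))
})

test_that("two-sample randomization reproduces hand-enumerated cases", {
  # identical constant samples: every |T_perm| >= |T_obs| = 0
  r <- randomization_two_sample(c(5, 5), c(5, 5), exhaustive = "always")
  expect_equal(r$alpha_R, 1)
  expect_true(r$exhaustive)
  # x={0,0}, y={1,1}: of the 6 assignments only the 2 extremes give |T|=1
  expect_equal(randomization_two_sample(c(0, 0), c(1, 1),
                                        exhaustive = "always")$alpha_R, 2 / 6)
  expect_equal(exact_randomization(c(1, 2), c(10, 11)), 2 / 6)
  # one-vs-one: both assignments give |T| = 1
  expect_equal(exact_randomization(c(1), c(2)), 1)
  expect_error(exact_randomization(rnorm(15), rnorm(15)), "200000")
  expect_error(randomization_two_sample(c(1), c(2, 3)), "at least 2")
  expect_error(randomization_two_sample(c(1, 2), c(2, 3), n_perm = 0),
               "n_perm")
})

test_that("exhaustive alpha_R matches the independent enumeration oracle", {
  set.seed(2024)
  for (i in 1:10) {
    nx <- sample(3:5, 1)
    ny <- sample(3:5, 1)
    x <- round(runif(nx, 0, 100), 1)
    y <- round(runif(ny, 0, 100) + 20, 1)
    expect_equal(randomization_two_sample(x, y, exhaustive = "always")$alpha_R,
                 oracle_exact_two_sample(x, y))
    expect_equal(exact_randomization(x, y), oracle_exact_two_sample(x, y))
  }
})

test_that("sampled alpha_R converges to the exhaustive value", {
  set.seed(11)
  x <- round(runif(4, 0, 100), 1)
  y <- round(runif(4, 20, 120), 1)
  exact <- exact_randomization(x, y)
  # 3 vs 3 and 4 vs 4 sampled runs stay within the binomial 3-sigma band
  n_perm <- 10000
  band <- 3 * sqrt(exact * (1 - exact) / n_perm) + 1 / n_perm
  ok <- vapply(1:200, function(s) {
    a <- randomization_two_sample(x, y, n_perm = n_perm, seed = s,
                                  exhaustive = "never")$alpha_R
    abs(a - exact) <= band
  }, logical(1))
  expect_gte(mean(ok), 0.99)
  # high-precision convergence check
  a5 <- randomization_two_sample(x, y, n_perm = 1e5, seed = 99,
                                 exhaustive = "never")$alpha_R
  expect_lt(abs(a5 - exact), 0.005)
})

test_that("alpha_R is a valid two-sided probability with the stated invariances", {
  set.seed(5)
  for (i in 1:10) {
    x <- runif(5, 0, 100)
    y <- runif(6, 0, 100)
    a_xy <- randomization_two_sample(x, y, n_perm = 500, seed = i,
                                     exhaustive = "never")$alpha_R
    expect_gt(a_xy, 0)
    expect_lte(a_xy, 1)
    # exchanging the groups flips the sign of T but not alpha_R (exact in
    # exhaustive mode; sampled mode draws different permutations)
    expect_equal(randomization_two_sample(x, y, exhaustive = "always")$alpha_R,
                 randomization_two_sample(y, x, exhaustive = "always")$alpha_R)
    # shifting every CI by a constant leaves the test unchanged
    a_sh <- randomization_two_sample(x + 17, y + 17, n_perm = 500, seed = i,
                                     exhaustive = "never")$alpha_R
    expect_equal(a_xy, a_sh)
    # exhaustive invariances hold exactly too
    expect_equal(exact_randomization(x, y), exact_randomization(y, x))
  }
})

test_that("seeded randomization results are bit-reproducible", {
  x <- runif(8, 0, 100)
  y <- runif(8, 0, 100)
  r1 <- randomization_two_sample(x, y, n_perm = 1000, seed = 31,
                                 exhaustive = "never")
  r2 <- randomization_two_sample(x, y, n_perm = 1000, seed = 31,
                                 exhaustive = "never")
  expect_identical(r1$alpha_R, r2$alpha_R)
  expect_equal(r1$seed, 31)
})

test_that("LI contrast: identical groups give T = 0 and alpha_R = 1", {
  g <- list(ci_na = c(50, 60, 45), ci_tr = c(20, 15, 25))
  r <- randomization_li_contrast(g, g, n_perm = 500, seed = 4)
  expect_equal(r$statistic_observed, 0)
  expect_equal(r$alpha_R, 1)
  expect_equal(r$scheme, "li_contrast")
})

test_that("LI contrast matches the exhaustive stratified oracle at small n", {
  set.seed(7)
  for (i in 1:4) {
    a <- list(ci_na = round(runif(2, 40, 90), 1),
              ci_tr = round(runif(2, 5, 40), 1))
    b <- list(ci_na = round(runif(2, 40, 90), 1),
              ci_tr = round(runif(2, 30, 80), 1))
    exact <- oracle_exact_li_contrast(a$ci_na, a$ci_tr, b$ci_na, b$ci_tr)
    sampled <- randomization_li_contrast(a, b, n_perm = 10000,
                                         seed = 100 + i)$alpha_R
    expect_lt(abs(sampled - exact), 0.02)
  }
})

test_that("retention contrast shares the stratified machinery", {
  g <- list(ci_na = c(50, 60, 45), ci_tr = c(20, 15, 25))
  r <- retention_contrast(g, g, n_perm = 500, seed = 12)
  expect_equal(r$alpha_R, 1)
  expect_equal(r$scheme, "retention")
  set.seed(21)
  imm <- list(ci_na = round(runif(2, 40, 90), 1),
              ci_tr = round(runif(2, 5, 30), 1))
  del <- list(ci_na = round(runif(2, 40, 90), 1),
              ci_tr = round(runif(2, 40, 85), 1))
  exact <- oracle_exact_li_contrast(del$ci_na, del$ci_tr, imm$ci_na,
                                    imm$ci_tr)
  sampled <- retention_contrast(imm, del, n_perm = 10000, seed = 13)$alpha_R
  expect_lt(abs(sampled - exact), 0.02)
})

test_that("planted phenotype profiles separate under the LI contrast", {
  profs <- builtin_profiles()
  n_sig_ctrl_vs_flat <- 0
  for (s in 1:20) {
    ctrl <- list(ci_na = r_ci_sample(profs$control, "0", "naive", 20,
                                     seed = 4 * s),
                 ci_tr = r_ci_sample(profs$control, "0", "trained", 20,
                                     seed = 4 * s + 1))
    flat <- list(ci_na = r_ci_sample(profs$cbs_like, "0", "naive", 20,
                                     seed = 4 * s + 2),
                 ci_tr = r_ci_sample(profs$cbs_like, "0", "trained", 20,
                                     seed = 4 * s + 3))
    a <- randomization_li_contrast(flat, ctrl, n_perm = 1000,
                                   seed = s)$alpha_R
    n_sig_ctrl_vs_flat <- n_sig_ctrl_vs_flat + (a < 0.05)
  }
  expect_gte(n_sig_ctrl_vs_flat, 19)
})

test_that("li_timecourse lays out one analysed row per strain x timepoint", {
  cfg <- synth_config(n_males_per_group = 15, seed = 2026)
  groups <- aggregate_groups(generate_ethograms(cfg))
  tc <- li_timecourse(groups, control_strains = "control", n_perm = 400,
                      seed = 55)
  expect_equal(nrow(tc), 9)  # 3 strains x 3 timepoints
  expect_setequal(unique(tc$status), "ok")

  ctrl <- tc[tc$strain == "control", ]
  expect_true(all(ctrl$alpha_within < 0.05))   # learns at every time point
  expect_true(all(ctrl$flags %in% ""))         # no flags vs itself

  cbs <- tc[tc$strain == "cbs_like", ]
  expect_true(all(abs(cbs$li) < 40))           # LI near 0, no learning
  expect_true(all(grepl("\\*", cbs$flags)))    # flagged vs control everywhere

  cse <- tc[tc$strain == "cse_like", ]
  expect_lt(cse$alpha_retention[cse$timepoint == "8"], 0.05)
  expect_match(cse$flags[cse$timepoint == "8"], "#")

  # empty input gives an empty table with the same schema
  empty <- li_timecourse(groups[0, ], control_strains = "control")
  expect_equal(nrow(empty), 0)
  expect_true(all(c("li", "alpha_within", "alpha_vs_control",
                    "alpha_retention", "flags", "status") %in%
                    colnames(empty)))
})

test_that("li_timecourse reports untestable groups instead of failing", {
  cfg <- synth_config(n_males_per_group = 8, seed = 3)
  groups <- aggregate_groups(generate_ethograms(cfg))
  # drop the trained cohort of one strain/timepoint
  drop <- groups$strain == "cse_like" & groups$timepoint == "2" &
    groups$condition == "trained"
  tc <- li_timecourse(groups[!drop, ], control_strains = "control",
                      n_perm = 200, seed = 8)
  row <- tc[tc$strain == "cse_like" & tc$timepoint == "2", ]
  expect_equal(row$status, "not_testable")
  expect_true(is.na(row$li))
})
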