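test_that("Yates-corrected chi-square reproduces published cohort contrasts", {
  # zygosity x ancestry, bacterial vaginosis, current smoking
  expect_equal(chi2_yates(matrix(c(168, 48, 76, 40), 2))$statistic, 5.21,
               tolerance = 0.005 / 5.21)
  expect_equal(chi2_yates(matrix(c(213, 65, 19, 18), 2))$statistic, 9.48,
               tolerance = 0.005 / 9.48)
  expect_equal(chi2_yates(matrix(c(142, 64, 71, 13), 2))$statistic, 6.66,
               tolerance = 0.005 / 6.66)
})

test_that("the continuity correction never increases the statistic", {
  set.seed(50)
  for (rep in 1:20) {
    tab <- matrix(rpois(4, 40) + 1, 2)
    y <- chi2_yates(tab)$statistic
    raw <- chi2_yates(tab, correct = FALSE)$statistic
    expect_lte(y, raw + 1e-12)
  }
})

test_that("chi-square is invariant to simultaneous row and column swaps", {
  tab <- matrix(c(168, 48, 76, 40), 2)
  expect_equal(chi2_yates(tab)$statistic,
               chi2_yates(tab[2:1, 2:1])$statistic)
  expect_error(chi2_yates(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("Welch t from summaries reproduces the published BMI contrast", {
  got <- welch_t(26.84, 6.74, 212, 30.95, 7.02, 77)
  expect_equal(abs(got$t), 4.45, tolerance = 0.005 / 4.45)
  expect_lt(got$p_value, 0.001)
})

test_that("Welch t matches the algebraic formula and is antisymmetric", {
  set.seed(51)
  for (rep in 1:10) {
    m <- rnorm(2, 10, 3); s <- runif(2, 0.5, 4); n <- sample(5:200, 2)
    got <- welch_t(m[1], s[1], n[1], m[2], s[2], n[2])
    se2 <- s[1]^2 / n[1] + s[2]^2 / n[2]
    t_ref <- (m[1] - m[2]) / sqrt(se2)
    df_ref <- se2^2 / ((s[1]^2 / n[1])^2 / (n[1] - 1) +
                       (s[2]^2 / n[2])^2 / (n[2] - 1))
    expect_equal(got$t, t_ref, tolerance = 1e-12)
    expect_equal(got$df, df_ref, tolerance = 1e-12)
    expect_equal(got$p_value, 2 * pt(-abs(t_ref), df_ref), tolerance = 1e-12)
    flipped <- welch_t(m[2], s[2], n[2], m[1], s[1], n[1])
    expect_equal(flipped$t, -got$t)
    expect_equal(flipped$p_value, got$p_value)
  }
  same <- welch_t(5, 1, 10, 5, 1, 10)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
})

test_that("cohort summary matches sort-based oracles per stratum", {
  set.seed(52)
  sp <- cohort_spec(n_mz = 40, n_dz = 30, seed = 99)
  meta <- generate_cohort(sp)$metadata
  summ <- summarize_cohort(meta)
  age <- summ$continuous[summ$continuous$variable == "age", ]
  for (i in 1:2) {
    x <- meta$age[meta$ancestry == age$ancestry[i]]
    expect_equal(age$median[i], stats::median(x))
    expect_equal(age$q1[i], unname(stats::quantile(x, 0.25)))
    expect_equal(age$q3[i], unname(stats::quantile(x, 0.75)))
    expect_equal(age$mean[i], mean(x))
    expect_equal(age$sd[i], stats::sd(x))
  }
  zyg <- summ$categorical[summ$categorical$variable == "zygosity", ]
  expect_equal(sum(zyg$count), nrow(meta))

  # all-identical values give zero spread
  meta2 <- meta; meta2$age <- 30
  summ2 <- summarize_cohort(meta2)
  age2 <- summ2$continuous[summ2$continuous$variable == "age", ]
  expect_equal(age2$sd, c(0, 0))
  expect_equal(age2$q3 - age2$q1, c(0, 0))
})
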