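test_that("implied covariance follows the biometrical expectations", {
  expect_equal(implied_covariance(1, 0, 1, "MZ"), matrix(c(2, 1, 1, 2), 2))
  expect_equal(implied_covariance(1, 0, 1, "DZ"),
               matrix(c(2, 0.5, 0.5, 2), 2))
  # common environment is zygosity-invariant
  expect_equal(implied_covariance(0, 0.7, 0.3, "MZ"),
               implied_covariance(0, 0.7, 0.3, "DZ"))
})

test_that("log-likelihood matches the standard bivariate normal and a brute-force oracle", {
  one <- twin_pairs(mz = rbind(c(0, 0)), dz = NULL)
  expect_equal(twin_loglik(0, 0, 1, 0, one), -log(2 * pi))

  set.seed(40)
  tp <- latent_twin_pairs(7, 9, 0.5, 0.2, 0.8)
  for (par in list(c(0.5, 0.2, 0.8, 0), c(0.3, 0, 1.1, 0.2),
                   c(-0.1, 0.4, 0.9, -0.3))) {
    expect_equal(twin_loglik(par[1], par[2], par[3], par[4], tp),
                 brute_loglik(par[1], par[2], par[3], par[4],
                              tp$mz, tp$dz),
                 tolerance = 1e-10)
  }
  # non-positive-definite implied covariance yields the -Inf sentinel
  expect_identical(twin_loglik(-2, 0, 0.1, 0, tp), -Inf)
  expect_identical(twin_loglik(1, 0, -2, 0, tp), -Inf)
})

test_that("log-likelihood is exchangeable in within-pair order", {
  set.seed(41)
  tp <- latent_twin_pairs(6, 6, 0.4, 0.1, 0.6)
  swapped <- twin_pairs(mz = tp$mz[, 2:1], dz = tp$dz[, 2:1])
  expect_equal(twin_loglik(0.4, 0.1, 0.6, 0.1, tp),
               twin_loglik(0.4, 0.1, 0.6, 0.1, swapped))
  fit1 <- twin_ace(tp, "AE")
  fit2 <- twin_ace(swapped, "AE")
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-6)
})

test_that("AE fit reproduces the closed form on exact-moment data", {
  tp <- twin_pairs(mz = exact_moment_pairs(1, 0.6),
                   dz = exact_moment_pairs(1, 0.3))
  fit <- twin_ace(tp, "AE")
  expect_equal(unname(fit$coefficients[c("a2", "e2", "mu")]),
               c(0.6, 0.4, 0), tolerance = 1e-5)
  expect_equal(unname(fit$standardized["A"]), 0.6, tolerance = 1e-5)
  # the saturated per-zygosity likelihood is attained (perfect fit)
  g <- grid_fit(tp, "AE")
  expect_lt(abs(fit$loglik - g$loglik), 1e-3)
})

test_that("equal twin covariances force the genetic component to zero", {
  tp <- twin_pairs(mz = exact_moment_pairs(1, 0.5),
                   dz = exact_moment_pairs(1, 0.5))
  fit <- twin_ace(tp, "ACE")
  expect_equal(unname(fit$coefficients["a2"]), 0, tolerance = 1e-4)
  expect_equal(unname(fit$coefficients["c2"]), 0.5, tolerance = 1e-4)
  expect_equal(unname(fit$coefficients["e2"]), 0.5, tolerance = 1e-4)
})

test_that("ML estimates agree with an exhaustive grid-search oracle", {
  set.seed(42)
  for (rep in 1:3) {
    tp <- latent_twin_pairs(sample(8:20, 1), sample(8:20, 1),
                            0.4, 0, 0.6, mu = 0.5)
    for (model in c("AE", "E")) {
      fit <- twin_ace(tp, model)
      g <- grid_fit(tp, model)
      for (nm in names(g$par)) {
        est <- if (nm == "mu") fit$coefficients["mu"] else fit$coefficients[nm]
        expect_lt(abs(est - g$par[[nm]]), 2 * g$resolution[[nm]] + 1e-6)
      }
      expect_gte(fit$loglik, g$loglik - 1e-6)
    }
  }
})

test_that("standardization reproduces published-style arithmetic and sums to one", {
  std <- standardize(c(a2 = 0.1428, c2 = 0, e2 = 0.2683), "AE")
  expect_equal(unname(std["A"]), 0.3473, tolerance = 5e-4 / 0.3473)
  expect_equal(unname(std["E"]), 0.6527, tolerance = 5e-4 / 0.6527)
  expect_equal(sum(std), 1, tolerance = 1e-12)

  std2 <- standardize(c(a2 = 0.0455, c2 = 0, e2 = 0.2213), "AE")
  expect_equal(unname(std2["A"]), 0.1706, tolerance = 5e-4 / 0.1706)

  expect_equal(unname(standardize(c(a2 = 0.5, c2 = 0, e2 = 0.5), "AE")),
               c(0.5, 0.5))
  # signed proportions still sum to one under the direct parameterization
  std3 <- standardize(c(a2 = -0.0168, c2 = 0, e2 = 0.1187), "AE")
  expect_equal(sum(std3), 1, tolerance = 1e-12)
  expect_lt(std3["A"], 0)
  expect_error(standardize(c(a2 = -1, c2 = 0, e2 = 0.5), "AE"), "positive")
})

test_that("model ladder respects nesting and the AIC identity", {
  set.seed(43)
  tp <- latent_twin_pairs(60, 60, 0.3, 0.2, 0.5)
  fits <- lapply(c(ACE = "ACE", AE = "AE", CE = "CE", E = "E"),
                 function(m) twin_ace(tp, m))
  expect_gte(fits$ACE$loglik, fits$AE$loglik - 1e-6)
  expect_gte(fits$ACE$loglik, fits$CE$loglik - 1e-6)
  expect_gte(fits$AE$loglik, fits$E$loglik - 1e-6)
  expect_gte(fits$CE$loglik, fits$E$loglik - 1e-6)
  for (f in fits) {
    expect_identical(f$aic, -2 * f$loglik + 2 * f$n_params)
    expect_equal(sum(f$standardized), 1, tolerance = 1e-8)
  }
  expect_identical(vapply(fits, function(f) f$n_params, integer(1)),
                   c(ACE = 4L, AE = 3L, CE = 3L, E = 2L))
})

test_that("likelihood-ratio comparison gives the chi-square machinery", {
  set.seed(44)
  tp <- latent_twin_pairs(50, 50, 0.4, 0, 0.6)
  ae <- twin_ace(tp, "AE")
  e <- twin_ace(tp, "E")
  cmp <- compare_models(ae, e)
  expect_equal(cmp$lr_stat, 2 * (ae$loglik - e$loglik))
  expect_identical(cmp$df, 1L)
  expect_equal(cmp$delta_aic, e$aic - ae$aic)
  expect_equal(cmp$p_value, pchisq(cmp$lr_stat, 1, lower.tail = FALSE))

  # identical logliks -> zero statistic, p = 1
  expect_equal(lrt_pvalue(0, 1), 1)
  # quantile identity and the published-style p-value
  expect_equal(lrt_pvalue(3.8415, 1), 0.05, tolerance = 1e-4 / 0.05)
  expect_equal(lrt_pvalue(5.5944, 1), 0.0180, tolerance = 1e-4 / 0.018)

  ce <- twin_ace(tp, "CE")
  expect_error(compare_models(ae, ce), "not nested")
  expect_error(compare_models(e, ae), "not nested")
})

test_that("path parameterization constrains variances to be nonnegative", {
  # negative MZ covariance pushes the unconstrained A estimate negative
  tp <- twin_pairs(mz = exact_moment_pairs(1, -0.3),
                   dz = exact_moment_pairs(1, 0))
  direct <- twin_ace(tp, "AE", parameterization = "direct")
  path <- twin_ace(tp, "AE", parameterization = "path")
  expect_lt(direct$coefficients["a2"], 0)
  expect_gte(path$coefficients["a2"], 0)
  expect_gte(direct$loglik, path$loglik - 1e-6)
})

test_that("profile intervals bracket the estimate and tighten with n", {
  set.seed(45)
  tp <- latent_twin_pairs(100, 100, 0.4, 0, 0.6)
  fit <- twin_ace(tp, "AE")
  ci <- confint(fit)
  expect_true(all(ci[, "lower"] < ci[, "upper"]))
  expect_true(all(ci[, "lower"] <= fit$coefficients[c("a2", "e2")]))
  expect_true(all(ci[, "upper"] >= fit$coefficients[c("a2", "e2")]))
  expect_gt(ci["e2", "lower"], 0)  # e2 strictly positive

  # profile deviance at the reported bounds equals the chi-square quantile
  for (p in c("a2", "e2"))
    for (b in 1:2)
      expect_equal(twinbiome:::profile_deviance(fit, p, ci[p, b]),
                   qchisq(0.95, 1), tolerance = 1e-3)

  set.seed(45)
  tp_big <- latent_twin_pairs(1000, 1000, 0.4, 0, 0.6)
  ci_big <- confint(twin_ace(tp_big, "AE"), parm = "a2")
  expect_lt(diff(ci_big[1, ]), diff(ci["a2", ]))

  # the cheap Wald alternative roughly agrees at this sample size
  w <- confint(fit, parm = "a2", method = "wald")
  expect_equal(unname(w[1, ]), unname(ci["a2", ]), tolerance = 0.25)
})

test_that("heritability test reports the AE heritability with its LRT p-value", {
  set.seed(46)
  tp <- latent_twin_pairs(2000, 2000, 0.35, 0, 0.65)
  ht <- heritability_test(tp)
  expect_equal(ht$h2, unname(ht$fits$AE$standardized["A"]))
  want <- compare_models(ht$fits$AE, ht$fits$E)
  expect_equal(ht$p_value, want$p_value)
  expect_named(ht$fits, c("ACE", "AE", "CE", "E"))
  expect_equal(nrow(ht$comparisons), 4L)
  # moment-based cross-check agrees at this size
  expect_equal(ht$falconer, ht$h2, tolerance = 0.05 / ht$h2)
})

test_that("degenerate inputs fail loudly", {
  flat <- twin_pairs(mz = matrix(1, 5, 2), dz = matrix(1, 5, 2))
  expect_error(twin_ace(flat, "AE"), "zero phenotypic variance")
  tiny <- twin_pairs(mz = rbind(c(0, 1)), dz = rbind(c(0, 1)))
  expect_error(twin_ace(tiny, "AE"), "at least 2")
})

test_that("simulate and residuals are consistent with the fitted model", {
  set.seed(47)
  tp <- latent_twin_pairs(200, 200, 0.4, 0, 0.6)
  fit <- twin_ace(tp, "AE")
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_identical(sims[[1]]$stats$mz$n, fit$n_mz)
  refit <- twin_ace(sims[[1]], "AE")
  expect_equal(refit$coefficients["a2"], fit$coefficients["a2"],
               tolerance = 0.15)
  r <- residuals(fit)
  expect_identical(dim(r), c(400L, 2L))
  expect_equal(mean(r), 0, tolerance = 0.1)
  expect_equal(stats::sd(as.vector(r)), 1, tolerance = 0.1)
})
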