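test_that("arcsine square root hits its closed-form anchor points", {
  expect_identical(asin_sqrt(0), 0)
  expect_equal(asin_sqrt(1), pi / 2)
  expect_equal(asin_sqrt(0.5), pi / 4)
  expect_equal(inv_asin_sqrt(pi / 4), 0.5)
  expect_identical(inv_asin_sqrt(0), 0)
})

test_that("transform round-trips and is strictly monotone", {
  set.seed(30)
  p <- runif(1000)
  expect_lt(max(abs(inv_asin_sqrt(asin_sqrt(p)) - p)), 1e-12)
  sorted <- sort(p)
  expect_true(all(diff(asin_sqrt(sorted)) > 0))
})

test_that("boundary spillover is clamped but genuine violations error", {
  expect_identical(asin_sqrt(-1e-12), 0)
  expect_equal(asin_sqrt(1 + 1e-12), pi / 2)
  expect_error(asin_sqrt(-0.01), "outside")
  expect_error(asin_sqrt(1.01), "outside")
  # simulated phenotypes outside the range are clamped before inversion
  expect_identical(inv_asin_sqrt(-0.3), 0)
  expect_equal(inv_asin_sqrt(2.0), 1)
})
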