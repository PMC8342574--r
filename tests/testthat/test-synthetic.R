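test_that("identical spec and seed give identical cohorts", {
  sp <- cohort_spec(n_mz = 25, n_dz = 20, n_noise_taxa = 10, seed = 77)
  a <- generate_cohort(sp)
  b <- generate_cohort(sp)
  expect_identical(a$taxa$counts, b$taxa$counts)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth$phenotypes, b$truth$phenotypes)
  c <- generate_cohort(cohort_spec(n_mz = 25, n_dz = 20, n_noise_taxa = 10,
                                   seed = 78))
  expect_false(identical(a$taxa$counts, c$taxa$counts))
})

test_that("generated tables satisfy the count and proportion invariants", {
  sp <- cohort_spec(n_mz = 30, n_dz = 30, n_noise_taxa = 15, seed = 5)
  coh <- generate_cohort(sp)
  expect_true(all(coh$taxa$counts >= 0))
  expect_true(all(rowSums(coh$taxa$counts) <= coh$taxa$total_reads))
  pr <- to_proportions(coh$taxa)
  expect_true(all(pr$proportions >= 0 & pr$proportions <= 1))
  expect_true(all(rowSums(pr$proportions) <= 1 + 1e-9))
  # singleton emission: 5% of pairs lose one member's sample
  n_expected <- 2L * 60L - 3L  # floor(0.05 * 60) singletons
  expect_identical(length(coh$taxa$sample_ids), n_expected)
})

test_that("vanishing unique environment collapses within-pair differences", {
  sp <- cohort_spec(n_mz = 40, n_dz = 40, a2 = 0, c2 = 0, e2 = 1e-4,
                    singleton_frac = 0, seed = 6)
  coh <- generate_cohort(sp)
  y <- coh$truth$phenotypes$y
  d <- y[seq(1, length(y), 2)] - y[seq(2, length(y), 2)]
  expect_lt(max(abs(d)), 0.1)
})

test_that("twin correlations match the generating model's moments", {
  rs <- vapply(1:4, function(seed) {
    sp <- cohort_spec(n_mz = 3000, n_dz = 3000, a2 = 0.4 * 0.04, c2 = 0,
                      e2 = 0.6 * 0.04, n_noise_taxa = 3,
                      singleton_frac = 0, seed = seed)
    tp <- twinbiome:::cohort_twin_pairs(generate_cohort(sp))
    c(cor(tp$mz[, 1], tp$mz[, 2]), cor(tp$dz[, 1], tp$dz[, 2]))
  }, numeric(2))
  expect_equal(mean(rs[1, ]), 0.4, tolerance = 0.03 / 0.4)
  expect_equal(mean(rs[2, ]), 0.2, tolerance = 0.03 / 0.2)
  expect_true(all(rs[1, ] > rs[2, ]))
})

test_that("boundary clamping censors under 1% of draws at default settings", {
  coh <- generate_cohort(cohort_spec(seed = 9))
  y <- coh$truth$phenotypes$y
  expect_lt(mean(y < 0 | y > pi / 2), 0.01)
})

test_that("depths are overdispersed and exercise the 5000-read screen", {
  sp <- cohort_spec(n_mz = 200, n_dz = 200, seed = 10)
  coh <- generate_cohort(sp)
  expect_gt(sum(coh$taxa$total_reads < 5000), 0)
  expect_gt(sum(coh$taxa$total_reads >= 5000), 0)
  # variance well above Poisson at this mean
  expect_gt(stats::var(as.numeric(coh$taxa$total_reads)),
            5 * mean(coh$taxa$total_reads))
})

test_that("cohort files round-trip through the io readers", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(cohort_spec(n_mz = 10, n_dz = 10,
                                     n_noise_taxa = 5, seed = 11))
  paths <- write_cohort(coh, dir)
  tab <- read_taxa_table(paths["taxa"], "counts")
  expect_equal(tab$counts, coh$taxa$counts)
  meta <- read_metadata(paths["metadata"])
  expect_identical(meta$participant_id, coh$metadata$participant_id)
  truth <- read.delim(paths["truth"], header = FALSE)
  expect_equal(truth$V2[truth$V1 == "h2"], coh$truth$h2, tolerance = 1e-9)
})

test_that("a single-replicate harness equals that replicate's raw fit", {
  sp <- cohort_spec(n_mz = 60, n_dz = 60, n_noise_taxa = 3, seed = 12)
  rh <- recovery_harness(sp, replicates = 1)
  tp <- twinbiome:::cohort_twin_pairs(generate_cohort(sp))
  ae <- twin_ace(tp, "AE")
  expect_equal(rh$summary$mean_h2, unname(ae$standardized["A"]))
  expect_equal(rh$replicates$p_value,
               compare_models(ae, twin_ace(tp, "E"))$p_value)
  expect_equal(rh$summary$rmse, abs(rh$summary$bias))
})
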