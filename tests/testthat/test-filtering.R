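props_table <- function(m) {
  twinbiome:::new_taxa_table(sprintf("s%02d", seq_len(nrow(m))),
                             colnames(m), proportions = m)
}

test_that("prevalence and abundance thresholds are inclusive and joint", {
  m <- matrix(0, 10, 2, dimnames = list(NULL, c("edge", "ubiquitous_low")))
  m[1:2, "edge"] <- 0.15             # >= 0.10 in exactly 2/10 subjects
  m[, "ubiquitous_low"] <- 0.05      # everywhere, but never reaches 0.10
  tab <- props_table(m)
  expect_identical(select_taxa(tab, filter_spec(0.20, 0.10)), "edge")

  # disjoint reading admits the low-abundance taxon once it peaks anywhere
  m[1, "ubiquitous_low"] <- 0.10
  expect_setequal(select_taxa(props_table(m), filter_spec(0.20, 0.10),
                              mode = "disjoint"),
                  c("edge", "ubiquitous_low"))
})

test_that("empty selection warns and returns an empty vector", {
  m <- matrix(0.001, 5, 2, dimnames = list(NULL, c("a", "b")))
  expect_warning(out <- select_taxa(props_table(m), filter_spec(0.5, 0.5)),
                 "no taxa")
  expect_identical(out, character(0))
})

test_that("selection matches the brute-force double loop on sparse tables", {
  set.seed(20)
  for (rep in 1:10) {
    tab <- random_sparse_props(50, 30)
    for (spec in list(filter_spec(0.20, 0.10), filter_spec(expanded = TRUE))) {
      got <- tryCatch(select_taxa(tab, spec), warning = function(w) character(0))
      want <- brute_select_taxa(tab$proportions, spec$min_subject_frac,
                                spec$min_within_prop)
      expect_identical(got, want)
    }
  }
})

test_that("relaxing either threshold never shrinks the selection", {
  set.seed(21)
  tab <- random_sparse_props(40, 25)
  base <- tryCatch(select_taxa(tab, filter_spec(0.20, 0.10)),
                   warning = function(w) character(0))
  for (spec in list(filter_spec(0.10, 0.10), filter_spec(0.20, 0.05),
                    filter_spec(0.025, 0.01))) {
    wider <- tryCatch(select_taxa(tab, spec), warning = function(w) character(0))
    expect_true(all(base %in% wider))
  }
  # the all-pass spec selects every taxon (0 >= 0 holds everywhere)
  expect_identical(select_taxa(tab, filter_spec(0, 0)), tab$taxon_names)
})

test_that("selection is invariant to subject and taxon ordering", {
  set.seed(22)
  tab <- random_sparse_props(30, 20)
  base <- select_taxa(tab, filter_spec(0.1, 0.05))
  perm_s <- sample(nrow(tab$proportions))
  perm_t <- sample(ncol(tab$proportions))
  shuffled <- twinbiome:::new_taxa_table(
    tab$sample_ids[perm_s], tab$taxon_names[perm_t],
    proportions = tab$proportions[perm_s, perm_t])
  expect_setequal(select_taxa(shuffled, filter_spec(0.1, 0.05)), base)
})
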