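#' Analysis configuration
#'
#' Collects the tunable settings of the end-to-end pipeline. Every field
#' has the default used for the primary analysis; [load_config()] reads
#' the same fields from a flat YAML file.
#'
#' @param min_reads Read-depth screen (samples with fewer total reads are
#'   dropped; inclusive threshold).
#' @param min_subject_frac,min_within_prop Taxa filter thresholds (see
#'   [select_taxa()]); the primary screen is 20% of subjects at a 10%
#'   within-subject proportion.
#' @param filter_mode `"joint"` or `"disjoint"` prevalence rule.
#' @param filter_scope `"pooled"` (filter once on the whole analysis
#'   population) or `"stratum"` (filter within each ancestry stratum).
#' @param strata Ancestry levels to analyze; `NULL` = every level with at
#'   least 2 pairs of each zygosity.
#' @param age_cutoff Optional sensitivity cutoff in years: participants
#'   older than the cutoff are removed (retain `age <= age_cutoff`) and
#'   pairs broken by the removal are excluded. `NULL` = no age filter.
#' @param parameterization Passed to [twin_ace()].
#' @param ci Compute profile-likelihood intervals for the AE components.
#' @param conf_level Confidence level for those intervals.
#' @param denominator Proportion denominator, `"total"` or `"assigned"`
#'   (see [to_proportions()]).
#' @param seed Seed recorded in the run log (the analysis itself is
#'   deterministic).
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(min_reads = 5000,
                            min_subject_frac = 0.20,
                            min_within_prop = 0.10,
                            filter_mode = "joint",
                            filter_scope = "pooled",
                            strata = NULL,
                            age_cutoff = NULL,
                            parameterization = "direct",
                            ci = TRUE,
                            conf_level = 0.95,
                            denominator = "total",
                            seed = 1L) {
  stopifnot(min_reads >= 0, is.null(age_cutoff) || age_cutoff > 0)
  out <- as.list(environment())
  class(out) <- "analysis_config"
  out
}

#' Read an analysis configuration from YAML
#'
#' Flat key-value YAML; unknown keys are an error, absent keys keep their
#' defaults. Arguments passed through `...` override the file.
#'
#' @param path Path to a YAML file (or `NULL` for pure defaults).
#' @param ... Overrides, as in [analysis_config()].
#' @return An `analysis_config`.
#' @export
load_config <- function(path = NULL, ...) {
  vals <- if (!is.null(path)) yaml::read_yaml(path) else list()
  dots <- list(...)
  vals[names(dots)] <- dots
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  do.call(analysis_config, vals)
}

#' Age-based sensitivity subset
#'
#' Retains participants whose age is at most `age_cutoff` years
#' ("removing women older than" the cutoff). Participants with missing
#' age are excluded with a warning. Downstream pair assembly then drops
#' any pair broken by the removal.
#'
#' @param records Metadata data frame.
#' @param age_cutoff Age in years; `Inf` is the identity.
#' @return The filtered records, with attribute `"n_age_removed"`.
#' @export
sensitivity_subset <- function(records, age_cutoff) {
  stopifnot(age_cutoff > 0)
  if (!"age" %in% names(records)) stop("metadata has no 'age' column")
  age <- as.numeric(records$age)
  if (anyNA(age))
    warning("excluding ", sum(is.na(age)), " participant(s) with missing age")
  keep <- !is.na(age) & age <= age_cutoff
  out <- records[keep, , drop = FALSE]
  attr(out, "n_age_removed") <- sum(!keep)
  out
}

#' Run the end-to-end heritability pipeline
#'
#' Executes the full analysis: depth screen, proportion computation,
#' complete-pair assembly (optionally after an age-based sensitivity
#' subset), prevalence/abundance taxa selection, arcsine-square-root
#' transformation, and a per-(taxon x ancestry stratum) heritability test
#' over the full ACE/AE/CE/E model ladder. Strata with fewer than 2 pairs
#' of either zygosity are skipped with a logged warning.
#'
#' Three reports are written to `out_dir`:
#' * `table2.tsv` — one row per taxon x stratum x AE component with
#'   unstandardized and standardized estimates, profile intervals, the
#'   heritability and its AE-vs-E p-value (plus a Bonferroni-adjusted
#'   column for transparency; the per-test alpha of 0.05 is the decision
#'   rule).
#' * `nested_models.tsv` — the ACE/AE/CE/E ladder per taxon x stratum
#'   with log-likelihood, AIC and the likelihood-ratio drop tests.
#' * `table1.tsv` — cohort characteristics by ancestry with
#'   Yates-corrected chi-square and Welch t tests.
#' * `run.log` — participant and sample accounting for every filter.
#'
#' Outputs contain no timestamps; re-running on identical inputs and
#' configuration reproduces them byte-for-byte.
#'
#' @param taxa Path to a counts-dialect taxa TSV, or a `taxa_count_table`.
#' @param metadata Path to a metadata CSV, or a data frame.
#' @param config An [analysis_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with `table2`, `nested`, `cohort`, `taxa_selected`
#'   and the accounting `log` lines.
#' @export
run_pipeline <- function(taxa, metadata, config = analysis_config(),
                         out_dir) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.character(taxa)) taxa <- read_taxa_table(taxa, dialect = "counts")
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  metadata <- validate_metadata(metadata)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  log_lines <- character(0)
  logmsg <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  n_input <- length(taxa$sample_ids)
  logmsg("input: %d samples, %d taxa, %d participants in metadata",
         n_input, length(taxa$taxon_names), nrow(metadata))

  n_age_removed <- 0L
  if (!is.null(config$age_cutoff)) {
    metadata <- sensitivity_subset(metadata, config$age_cutoff)
    n_age_removed <- attr(metadata, "n_age_removed")
    logmsg("age filter (<= %g years): removed %d participant(s)",
           config$age_cutoff, n_age_removed)
  }

  taxa_f <- depth_filter(taxa, min_reads = config$min_reads)
  logmsg("depth filter (>= %g reads): %d of %d samples retained (%d removed)",
         config$min_reads, length(taxa_f$sample_ids), n_input,
         attr(taxa_f, "n_removed"))

  props <- to_proportions(taxa_f, denominator = config$denominator)
  cohort <- assemble_pairs(metadata, props$sample_ids)
  n_singleton <- attr(cohort, "singletons_excluded")
  logmsg("pair assembly: %d complete pairs (%d MZ, %d DZ); %d singleton(s) excluded",
         nrow(cohort), sum(cohort$zygosity == "MZ"),
         sum(cohort$zygosity == "DZ"), n_singleton)

  members <- c(cohort$member_1, cohort$member_2)
  props_analysis <- new_taxa_table(
    sample_ids = props$sample_ids[props$sample_ids %in% members],
    taxon_names = props$taxon_names,
    proportions = props$proportions[props$sample_ids %in% members, ,
                                    drop = FALSE])

  strata <- config$strata
  if (is.null(strata)) strata <- sort(unique(cohort$ancestry))
  fspec <- filter_spec(config$min_subject_frac, config$min_within_prop)

  select_for <- function(tab) {
    tryCatch(select_taxa(tab, fspec, mode = config$filter_mode),
             warning = function(w) character(0))
  }
  taxa_selected <- if (config$filter_scope == "pooled")
    select_for(props_analysis) else NULL

  table2 <- list(); nested <- list()
  for (stratum in strata) {
    sub <- cohort[cohort$ancestry == stratum, , drop = FALSE]
    if (sum(sub$zygosity == "MZ") < 2L || sum(sub$zygosity == "DZ") < 2L) {
      logmsg("stratum '%s': skipped (fewer than 2 pairs of each zygosity)",
             stratum)
      next
    }
    smembers <- c(sub$member_1, sub$member_2)
    sprops <- props_analysis$proportions[
      props_analysis$sample_ids %in% smembers, , drop = FALSE]
    sel <- if (config$filter_scope == "pooled") taxa_selected
    else select_for(new_taxa_table(sample_ids = rownames(sprops),
                                   taxon_names = props$taxon_names,
                                   proportions = sprops))
    logmsg("stratum '%s': %d pairs, %d taxa selected", stratum, nrow(sub),
           length(sel))
    for (taxon in sel) {
      y <- asin_sqrt(props_analysis$proportions[, taxon])
      names(y) <- props_analysis$sample_ids
      m <- cbind(y[sub$member_1], y[sub$member_2])
      tp <- twin_pairs(mz = m[sub$zygosity == "MZ", , drop = FALSE],
                       dz = m[sub$zygosity == "DZ", , drop = FALSE])
      ht <- tryCatch(
        heritability_test(tp, parameterization = config$parameterization,
                          ci = config$ci, conf_level = config$conf_level),
        error = function(e) {
          logmsg("stratum '%s', taxon '%s': fit failed (%s)", stratum,
                 taxon, conditionMessage(e))
          NULL
        })
      if (is.null(ht)) next
      table2[[length(table2) + 1L]] <- table2_rows(taxon, stratum, ht)
      nested[[length(nested) + 1L]] <- nested_rows(taxon, stratum, ht)
    }
  }

  table2 <- if (length(table2)) do.call(rbind, table2) else empty_table2()
  nested <- if (length(nested)) do.call(rbind, nested) else empty_nested()
  if (nrow(table2)) {
    n_tests <- length(unique(paste(table2$taxon, table2$ancestry)))
    table2$p_bonferroni <- pmin(table2$p_value * n_tests, 1)
  } else table2$p_bonferroni <- numeric(0)

  summ <- summarize_cohort(
    metadata[metadata$participant_id %in% members, , drop = FALSE],
    ancestry_levels = if (length(strata) >= 2L) strata[1:2]
    else unique(metadata$ancestry)[1:2])

  write_tsv <- function(df, name) {
    utils::write.table(format_report(df), file.path(out_dir, name),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_tsv(table2, "table2.tsv")
  write_tsv(nested, "nested_models.tsv")
  write_tsv(table1_report(summ), "table1.tsv")
  writeLines(log_lines, file.path(out_dir, "run.log"))

  invisible(list(table2 = table2, nested = nested, cohort = cohort,
                 taxa_selected = taxa_selected, summary = summ,
                 log = log_lines,
                 accounting = c(input = nrow(metadata) + n_age_removed,
                                age_removed = n_age_removed,
                                singleton_removed = n_singleton)))
}

# round numeric report columns to a fixed precision so identical analyses
# serialize identically across platforms
format_report <- function(df) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]])) df[[j]] <- signif(df[[j]], 10)
  df
}

table2_rows <- function(taxon, stratum, ht) {
  ae <- ht$fits$AE
  comp <- c("A", "E")
  unst <- unname(ae$coefficients[c("a2", "e2")])
  ci <- ht$ci
  data.frame(taxon = taxon, ancestry = stratum, model = "AE",
             component = comp,
             standardized = unname(ae$standardized[comp]),
             unstandardized = unst,
             ci_low = if (!is.null(ci)) ci[c("a2", "e2"), "lower"]
             else NA_real_,
             ci_high = if (!is.null(ci)) ci[c("a2", "e2"), "upper"]
             else NA_real_,
             h2 = ht$h2, p_value = ht$p_value,
             stringsAsFactors = FALSE, row.names = NULL)
}

empty_table2 <- function() {
  data.frame(taxon = character(0), ancestry = character(0),
             model = character(0), component = character(0),
             standardized = numeric(0), unstandardized = numeric(0),
             ci_low = numeric(0), ci_high = numeric(0), h2 = numeric(0),
             p_value = numeric(0), stringsAsFactors = FALSE)
}

nested_rows <- function(taxon, stratum, ht) {
  fits <- ht$fits
  base <- data.frame(
    taxon = taxon, ancestry = stratum,
    model = names(fits),
    n_params = vapply(fits, function(f) f$n_params, integer(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  cmp <- ht$comparisons
  base$lr_vs <- c(NA, "ACE", "ACE", "AE")
  base$lr_stat <- c(NA,
                    cmp$lr_stat[cmp$full == "ACE" & cmp$reduced == "AE"],
                    cmp$lr_stat[cmp$full == "ACE" & cmp$reduced == "CE"],
                    cmp$lr_stat[cmp$full == "AE" & cmp$reduced == "E"])
  base$df <- c(NA, 1L, 1L, 1L)
  base$p_value <- c(NA,
                    cmp$p_value[cmp$full == "ACE" & cmp$reduced == "AE"],
                    cmp$p_value[cmp$full == "ACE" & cmp$reduced == "CE"],
                    cmp$p_value[cmp$full == "AE" & cmp$reduced == "E"])
  base
}

empty_nested <- function() {
  data.frame(taxon = character(0), ancestry = character(0),
             model = character(0), n_params = integer(0),
             loglik = numeric(0), aic = numeric(0), lr_vs = character(0),
             lr_stat = numeric(0), df = integer(0), p_value = numeric(0),
             stringsAsFactors = FALSE)
}

table1_report <- function(summ) {
  cont <- summ$continuous
  cat_ <- summ$categorical
  rows <- list()
  if (!is.null(cont) && nrow(cont))
    rows[[1L]] <- data.frame(variable = cont$variable,
                             ancestry = cont$ancestry,
                             level = NA_character_,
                             count = NA_real_,
                             mean = cont$mean, sd = cont$sd,
                             median = cont$median,
                             statistic = cont$t, p_value = cont$p_value,
                             stringsAsFactors = FALSE)
  if (!is.null(cat_) && nrow(cat_))
    rows[[2L]] <- data.frame(variable = cat_$variable,
                             ancestry = cat_$ancestry, level = cat_$level,
                             count = cat_$count,
                             mean = NA_real_, sd = NA_real_,
                             median = NA_real_,
                             statistic = cat_$chisq, p_value = cat_$p_value,
                             stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(variable = character(0), ancestry = character(0),
                      level = character(0), count = numeric(0),
                      mean = numeric(0), sd = numeric(0),
                      median = numeric(0), statistic = numeric(0),
                      p_value = numeric(0), stringsAsFactors = FALSE)
  out
}
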