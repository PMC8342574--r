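#' Specification for a synthetic twin cohort
#'
#' Parameters of the data-generating model used to emulate a twin
#' vaginal-microbiome study. On the arcsine-square-root scale each
#' participant's focal-taxon phenotype is `y = mu + A + C + E` with
#' additive-genetic deviation `A` perfectly correlated within MZ pairs and
#' correlated 0.5 within DZ pairs, common-environment deviation `C` shared
#' within every pair, and unique-environment deviation `E` independent.
#' The phenotype is mapped to a proportion by `sin(y)^2` (clamped to
#' \[0, pi/2\] first — mild boundary censoring), sparse nuisance taxa
#' share part of the remaining read mass, and per-sample depths follow an
#' overdispersed negative-binomial law so that some samples fall below a
#' 5000-read screen.
#'
#' Defaults mirror a two-ancestry twin cohort of 108 MZ and 58 DZ pairs
#' with heritability a2/(a2+c2+e2) = 0.347 for the focal taxon, 266 sparse
#' nuisance taxa, and a 5% singleton rate. The default total latent
#' variance is 0.04 (sd 0.2 on a range of pi/2), calibrated so that
#' boundary clamping censors under 1% of draws and the latent ACE
#' decomposition survives the back-transform essentially intact;
#' standardized components are scale-free, so this choice does not affect
#' heritability truth values.
#'
#' @param n_mz,n_dz Twin-pair counts by zygosity.
#' @param a2,c2,e2 True variance components (transformed scale).
#' @param mu True grand mean (transformed scale, radians).
#' @param n_noise_taxa Number of sparse nuisance taxa.
#' @param sparsity Per-sample presence probability of each nuisance taxon.
#' @param mean_depth Expected reads per sample.
#' @param depth_dispersion Negative-binomial size parameter (smaller =
#'   more overdispersed).
#' @param singleton_frac Fraction of pairs emitted with only one member's
#'   sample (exercises singleton exclusion).
#' @param p_european Probability a pair is labelled European ancestry.
#' @param focal_taxon Name of the heritable focal taxon.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_mz = 108L, n_dz = 58L,
                        a2 = 0.347 * 0.04, c2 = 0, e2 = 0.653 * 0.04,
                        mu = pi / 4,
                        n_noise_taxa = 266L, sparsity = 0.15,
                        mean_depth = 20000, depth_dispersion = 5,
                        singleton_frac = 0.05, p_european = 122 / 166,
                        focal_taxon = "Lactobacillus_crispatus",
                        seed = 1L) {
  stopifnot(n_mz >= 0L, n_dz >= 0L, a2 >= 0, c2 >= 0, e2 > 0,
            n_noise_taxa >= 0L, sparsity > 0, sparsity <= 1,
            mean_depth > 0, depth_dispersion > 0,
            singleton_frac >= 0, singleton_frac < 1,
            p_european >= 0, p_european <= 1)
  out <- as.list(environment())
  class(out) <- "cohort_spec"
  out
}

#' Generate a synthetic twin cohort
#'
#' Draws a complete synthetic dataset from a [cohort_spec()]: a
#' sample-by-taxon read-count table (focal taxon plus sparse nuisance
#' taxa, with per-sample total reads), a participant metadata table
#' (pair id, zygosity, ancestry, age, BMI, bacterial-vaginosis and smoking
#' status, pH), and a truth record holding the generating parameters and
#' latent phenotypes. Identical spec and seed give identical output.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `synthetic_cohort`: list with `taxa` (a
#'   `taxa_count_table`), `metadata` (data frame) and `truth`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_mz + spec$n_dz
  if (n == 0L) stop("spec generates no pairs")
  zyg <- rep(c("MZ", "DZ"), c(spec$n_mz, spec$n_dz))
  pair_id <- sprintf("P%04d", seq_len(n))
  ancestry <- ifelse(stats::runif(n) < spec$p_european, "European", "African")

  # latent decomposition: MZ co-twins share A fully, DZ half
  sa <- sqrt(spec$a2); sc <- sqrt(spec$c2); se <- sqrt(spec$e2)
  A1 <- sa * stats::rnorm(n)
  A2 <- ifelse(zyg == "MZ", A1,
               0.5 * A1 + sqrt(0.75) * sa * stats::rnorm(n))
  C <- sc * stats::rnorm(n)
  y1 <- spec$mu + A1 + C + se * stats::rnorm(n)
  y2 <- spec$mu + A2 + C + se * stats::rnorm(n)

  ids <- c(rbind(paste0(pair_id, "-A"), paste0(pair_id, "-B")))
  y <- c(rbind(y1, y2))
  ns <- 2L * n
  p_focal <- inv_asin_sqrt(y)

  depth <- stats::rnbinom(ns, size = spec$depth_dispersion,
                          mu = spec$mean_depth)
  depth <- pmax(depth, 1L)

  k <- spec$n_noise_taxa
  taxon_names <- c(spec$focal_taxon,
                   if (k > 0L) sprintf("taxon_%03d", seq_len(k)))
  # per-sample taxon probabilities: focal, sparse nuisance taxa over a
  # fraction of the non-focal mass, remainder unassigned
  assigned_frac <- stats::runif(ns, 0.5, 0.9)
  probs <- matrix(0, ns, k + 1L)
  probs[, 1L] <- p_focal
  if (k > 0L) {
    present <- matrix(stats::runif(ns * k) < spec$sparsity, ns, k)
    g <- matrix(stats::rgamma(ns * k, shape = 0.5, rate = 1), ns, k) * present
    gsum <- rowSums(g)
    scale <- ifelse(gsum > 0, (1 - p_focal) * assigned_frac / gsum, 0)
    probs[, -1L] <- g * scale
  }
  # exact multinomial draw by sequential conditional binomials,
  # vectorized across samples
  counts <- matrix(0, ns, k + 1L, dimnames = list(ids, taxon_names))
  remaining <- depth
  mass_left <- rep(1, ns)
  for (j in seq_len(k + 1L)) {
    p_j <- ifelse(mass_left > 0, pmin(probs[, j] / mass_left, 1), 0)
    counts[, j] <- stats::rbinom(ns, remaining, p_j)
    remaining <- remaining - counts[, j]
    mass_left <- pmax(mass_left - probs[, j], 0)
  }

  # emit a fraction of pairs as singletons: one member's sample is dropped
  n_single <- floor(spec$singleton_frac * n)
  keep <- rep(TRUE, ns)
  if (n_single > 0L) {
    sp <- sample(n, n_single)
    keep[2L * sp - (stats::runif(n_single) < 0.5)] <- FALSE
  }
  taxa <- new_taxa_table(sample_ids = ids[keep],
                         taxon_names = taxon_names,
                         counts = counts[keep, , drop = FALSE],
                         total_reads = depth[keep])

  anc_i <- rep(ancestry, each = 2L)
  bmi_mean <- ifelse(anc_i == "European", 26.84, 30.95)
  bmi_sd <- ifelse(anc_i == "European", 6.74, 7.02)
  metadata <- data.frame(
    participant_id = ids,
    pair_id = rep(pair_id, each = 2L),
    zygosity = rep(zyg, each = 2L),
    ancestry = anc_i,
    age = round(pmin(pmax(stats::rnorm(ns, 39.4, 13.8), 18), 78)),
    bmi = round(pmin(pmax(stats::rnorm(ns, bmi_mean, bmi_sd), 17), 50), 1),
    bacterial_vaginosis = sample(c("no", "yes", "not_sure"), ns,
                                 replace = TRUE, prob = c(0.85, 0.12, 0.03)),
    current_smoking = sample(c("no", "yes"), ns, replace = TRUE,
                             prob = c(0.72, 0.28)),
    ph = round(pmin(pmax(stats::rnorm(ns, 5.0, 1.1), 4), 7), 1),
    stringsAsFactors = FALSE
  )

  truth <- list(a2 = spec$a2, c2 = spec$c2, e2 = spec$e2, mu = spec$mu,
                h2 = spec$a2 / (spec$a2 + spec$c2 + spec$e2),
                seed = spec$seed,
                phenotypes = data.frame(participant_id = ids, y = y,
                                        stringsAsFactors = FALSE))
  out <- list(taxa = taxa, metadata = metadata, truth = truth, spec = spec)
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic twin cohort: %d MZ + %d DZ pairs, %d samples, %d taxa (seed %d)\n",
    x$spec$n_mz, x$spec$n_dz, length(x$taxa$sample_ids),
    length(x$taxa$taxon_names), x$spec$seed))
  cat(sprintf("  truth: a2 = %.4g, c2 = %.4g, e2 = %.4g, mu = %.4g (h2 = %.3f)\n",
              x$truth$a2, x$truth$c2, x$truth$e2, x$truth$mu, x$truth$h2))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes the taxa table (TSV, counts dialect), the metadata (CSV) and a
#' key-value sidecar with the generating truth, in exactly the dialects
#' [read_taxa_table()] and [read_metadata()] consume.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the files written, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  taxa_path <- file.path(dir, "taxa.tsv")
  meta_path <- file.path(dir, "metadata.csv")
  truth_path <- file.path(dir, "truth.txt")
  write_taxa_table(cohort$taxa, taxa_path)
  utils::write.csv(cohort$metadata, meta_path, row.names = FALSE,
                   quote = FALSE)
  tr <- cohort$truth
  writeLines(sprintf("%s\t%.10g",
                     c("a2", "c2", "e2", "mu", "h2", "seed"),
                     c(tr$a2, tr$c2, tr$e2, tr$mu, tr$h2, tr$seed)),
             truth_path)
  invisible(c(taxa = taxa_path, metadata = meta_path, truth = truth_path))
}

#' Parameter-recovery harness
#'
#' Runs the full analysis chain (generate, depth-screen, proportions, pair
#' assembly, transform, ACE-family fits) on `replicates` independent
#' synthetic cohorts drawn from `spec` (replicate `r` uses seed
#' `spec$seed + r - 1`) and summarizes how well the heritability estimator
#' recovers the generating truth: bias and RMSE of the standardized A
#' estimate, the alpha = 0.05 rejection rate of the AE-versus-E
#' likelihood-ratio test, and (optionally) empirical coverage of the
#' profile-likelihood interval for `a2`.
#'
#' @param spec A [cohort_spec()].
#' @param replicates Number of replicate cohorts.
#' @param ci Also compute the profile interval for `a2` each replicate and
#'   report its empirical coverage of the generating value (slower).
#' @param min_reads Depth screen applied each replicate.
#' @param conf_level Level of the profile interval when `ci = TRUE`.
#' @return An object of class `recovery_summary`: list with `replicates`
#'   (per-replicate data frame: `h2_hat`, `p_value`, `covered`) and
#'   `summary` (bias, rmse, rejection rate, coverage).
#' @export
recovery_harness <- function(spec, replicates = 100L, ci = FALSE,
                             min_reads = 5000, conf_level = 0.95) {
  stopifnot(inherits(spec, "cohort_spec"), replicates >= 1L)
  rows <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    sp <- spec
    sp$seed <- spec$seed + r - 1L
    coh <- generate_cohort(sp)
    tp <- cohort_twin_pairs(coh, min_reads = min_reads)
    ae <- twin_ace(tp, model = "AE")
    e <- twin_ace(tp, model = "E")
    cmp <- compare_models(ae, e)
    covered <- NA
    if (ci) {
      band <- confint(ae, parm = "a2", level = conf_level)
      covered <- is.finite(band[1L]) && is.finite(band[2L]) &&
        band[1L] <= spec$a2 && spec$a2 <= band[2L]
    }
    rows[[r]] <- data.frame(h2_hat = unname(ae$standardized["A"]),
                            a2_hat = unname(ae$coefficients["a2"]),
                            p_value = cmp$p_value, covered = covered)
  }
  reps <- do.call(rbind, rows)
  h2_true <- spec$a2 / (spec$a2 + spec$c2 + spec$e2)
  out <- list(
    replicates = reps,
    truth = list(a2 = spec$a2, h2 = h2_true),
    summary = list(
      mean_h2 = mean(reps$h2_hat),
      bias = mean(reps$h2_hat) - h2_true,
      rmse = sqrt(mean((reps$h2_hat - h2_true)^2)),
      rejection_rate = mean(reps$p_value < 0.05),
      coverage = if (ci) mean(reps$covered) else NA_real_))
  class(out) <- "recovery_summary"
  out
}

#' @export
print.recovery_summary <- function(x, digits = 4, ...) {
  s <- x$summary
  cat(sprintf("recovery over %d replicates (true h2 = %.4f):\n",
              nrow(x$replicates), x$truth$h2))
  cat(sprintf("  mean h2_hat = %.*f  bias = %+.*f  rmse = %.*f\n",
              digits, s$mean_h2, digits, s$bias, digits, s$rmse))
  cat(sprintf("  LRT rejection rate (alpha = 0.05) = %.3f\n",
              s$rejection_rate))
  if (!is.na(s$coverage))
    cat(sprintf("  profile-CI coverage of a2 = %.3f\n", s$coverage))
  invisible(x)
}

# Run a synthetic cohort through the standard preprocessing chain and
# return the focal taxon's transformed phenotypes as twin_pairs (pooled
# over ancestry: the generator draws one set of components).
cohort_twin_pairs <- function(cohort, min_reads = 5000) {
  taxa <- depth_filter(cohort$taxa, min_reads = min_reads)
  props <- to_proportions(taxa)
  pairs <- assemble_pairs(cohort$metadata, props$sample_ids)
  y <- asin_sqrt(props$proportions[, cohort$spec$focal_taxon])
  names(y) <- props$sample_ids
  m <- cbind(y[pairs$member_1], y[pairs$member_2])
  twin_pairs(mz = m[pairs$zygosity == "MZ", , drop = FALSE],
             dz = m[pairs$zygosity == "DZ", , drop = FALSE])
}
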