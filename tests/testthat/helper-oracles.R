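# Independent oracles and fixture builders shared across test files.

# Four pairs whose ML sample moments are exactly mean 0, variance `v`,
# covariance `cv`: pairs (a,a), (-a,-a), (b,-b), (-b,b) with
# a^2 = v + cv, b^2 = v - cv.
exact_moment_pairs <- function(v = 1, cv = 0) {
  a <- sqrt(v + cv)
  b <- sqrt(v - cv)
  rbind(c(a, a), c(-a, -a), c(b, -b), c(-b, b))
}

# Brute-force bivariate normal log-likelihood via explicit 2x2 inverse and
# determinant, pair by pair (independent of the package's sufficient-
# statistic path).
brute_loglik <- function(a2, c2, e2, mu, mz, dz) {
  one <- function(m, sig) {
    if (is.null(m) || nrow(m) == 0L) return(0)
    det <- sig[1, 1] * sig[2, 2] - sig[1, 2] * sig[2, 1]
    if (!is.finite(det) || det <= 0 || sig[1, 1] <= 0) return(-Inf)
    i11 <- sig[2, 2] / det; i22 <- sig[1, 1] / det; i12 <- -sig[1, 2] / det
    d1 <- m[, 1] - mu; d2 <- m[, 2] - mu
    q <- i11 * d1^2 + 2 * i12 * d1 * d2 + i22 * d2^2
    sum(-log(2 * pi) - 0.5 * log(det) - 0.5 * q)
  }
  v <- a2 + c2 + e2
  one(mz, matrix(c(v, a2 + c2, a2 + c2, v), 2)) +
    one(dz, matrix(c(v, a2 / 2 + c2, a2 / 2 + c2, v), 2))
}

# Coarse-then-refined exhaustive grid search over the model's free
# parameters; independent ML oracle for small datasets. Returns the grid
# optimum and the final per-parameter resolution.
grid_fit <- function(data, model = "AE", n_grid = 11L, rounds = 6L) {
  mz <- data$mz; dz <- data$dz
  y <- c(mz, dz)
  v0 <- stats::var(y) * (length(y) - 1) / length(y)
  ranges <- list(mu = mean(y) + c(-1, 1) * 2 * sqrt(v0 / length(y)) * 4)
  if (model %in% c("ACE", "AE")) ranges$a2 <- c(-v0, 2 * v0)
  if (model %in% c("ACE", "CE")) ranges$c2 <- c(-v0, 2 * v0)
  ranges$e2 <- c(v0 * 1e-3, 2.5 * v0)
  best <- NULL
  for (r in seq_len(rounds)) {
    grids <- lapply(ranges, function(rg) seq(rg[1], rg[2], length.out = n_grid))
    pts <- as.matrix(expand.grid(grids))
    ll <- apply(pts, 1, function(p) {
      a2 <- if ("a2" %in% names(ranges)) p[["a2"]] else 0
      c2 <- if ("c2" %in% names(ranges)) p[["c2"]] else 0
      brute_loglik(a2, c2, p[["e2"]], p[["mu"]], mz, dz)
    })
    best <- pts[which.max(ll), ]
    # shrink each range around the incumbent
    for (nm in names(ranges)) {
      w <- diff(ranges[[nm]]) / (n_grid - 1)
      lo <- best[[nm]] - 1.5 * w
      hi <- best[[nm]] + 1.5 * w
      if (nm == "e2") lo <- max(lo, v0 * 1e-6)
      ranges[[nm]] <- c(lo, hi)
    }
  }
  res <- vapply(ranges, function(rg) diff(rg) / (n_grid - 1), numeric(1))
  list(par = best, loglik = max(ll), resolution = res)
}

# Brute-force double-loop taxa selection oracle.
brute_select_taxa <- function(props, min_subject_frac, min_within_prop) {
  keep <- character(0)
  for (j in seq_len(ncol(props))) {
    hits <- 0L
    for (i in seq_len(nrow(props)))
      if (props[i, j] >= min_within_prop) hits <- hits + 1L
    if (hits / nrow(props) >= min_subject_frac)
      keep <- c(keep, colnames(props)[j])
  }
  keep
}

# Random sparse proportion table for filtering tests.
random_sparse_props <- function(n_subj, n_taxa, p_present = 0.3) {
  m <- matrix(0, n_subj, n_taxa,
              dimnames = list(sprintf("s%03d", seq_len(n_subj)),
                              sprintf("t%03d", seq_len(n_taxa))))
  for (i in seq_len(n_subj)) {
    present <- which(stats::runif(n_taxa) < p_present)
    if (length(present)) {
      w <- stats::rgamma(length(present), 0.4)
      m[i, present] <- w / sum(w) * stats::runif(1, 0.3, 1)
    }
  }
  new_taxa_table(sample_ids = rownames(m), taxon_names = colnames(m),
                 proportions = m)
}

# Latent-scale twin pairs drawn straight from the ACE covariance structure
# (no proportion/count round trip); independent of generate_cohort.
latent_twin_pairs <- function(n_mz, n_dz, a2, c2, e2, mu = 0) {
  draw <- function(n, rg) {
    A1 <- rnorm(n, sd = sqrt(a2))
    A2 <- rg * A1 + sqrt(1 - rg^2) * rnorm(n, sd = sqrt(a2))
    C <- rnorm(n, sd = sqrt(c2))
    cbind(mu + A1 + C + rnorm(n, sd = sqrt(e2)),
          mu + A2 + C + rnorm(n, sd = sqrt(e2)))
  }
  twin_pairs(mz = draw(n_mz, 1), dz = draw(n_dz, 0.5))
}

# Small metadata table: n_pairs complete pairs plus singleton participants.
make_metadata <- function(n_pairs = 3L, n_singletons = 0L,
                          zygosity = rep(c("MZ", "DZ"), length.out = n_pairs),
                          ancestry = rep("European", n_pairs)) {
  pid <- sprintf("P%02d", seq_len(n_pairs + n_singletons))
  rows <- data.frame(
    participant_id = c(paste0(rep(pid[seq_len(n_pairs)], each = 2), c("-A", "-B")),
                       if (n_singletons) paste0(pid[n_pairs + seq_len(n_singletons)], "-A")),
    pair_id = c(rep(pid[seq_len(n_pairs)], each = 2),
                if (n_singletons) pid[n_pairs + seq_len(n_singletons)]),
    zygosity = c(rep(zygosity, each = 2),
                 if (n_singletons) rep("MZ", n_singletons)),
    ancestry = c(rep(ancestry, each = 2),
                 if (n_singletons) rep("European", n_singletons)),
    age = 30,
    stringsAsFactors = FALSE)
  rows
}
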