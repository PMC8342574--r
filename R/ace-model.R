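#' Paired twin phenotypes
#'
#' Bundles the transformed phenotype values of monozygotic (MZ) and
#' dizygotic (DZ) twin pairs into the data object the variance-component
#' models consume. Each input is a two-column matrix (one row per pair);
#' the likelihood is exchangeable in the two columns, so within-pair
#' ordering is immaterial.
#'
#' @param mz,dz Numeric matrices with two columns (or `NULL` / zero rows if
#'   a zygosity group is absent). Rows with any missing value are dropped
#'   with a warning: the models use complete pairs only.
#' @return An object of class `twin_pairs` with elements `mz`, `dz` and
#'   precomputed sufficient statistics.
#' @examples
#' tp <- twin_pairs(mz = cbind(rnorm(5), rnorm(5)),
#'                  dz = cbind(rnorm(5), rnorm(5)))
#' tp
#' @export
twin_pairs <- function(mz, dz) {
  clean <- function(m, lab) {
    if (is.null(m) || length(m) == 0L) return(matrix(numeric(0), 0L, 2L))
    m <- as.matrix(m)
    if (ncol(m) != 2L) stop(lab, " pairs must have exactly two columns")
    cc <- stats::complete.cases(m)
    if (!all(cc)) {
      warning("dropping ", sum(!cc), " incomplete ", lab, " pair(s)")
      m <- m[cc, , drop = FALSE]
    }
    storage.mode(m) <- "double"
    m
  }
  mz <- clean(mz, "MZ")
  dz <- clean(dz, "DZ")
  out <- list(mz = mz, dz = dz,
              stats = list(mz = pair_suffstats(mz), dz = pair_suffstats(dz)))
  class(out) <- "twin_pairs"
  out
}

# Sufficient statistics for an exchangeable bivariate normal likelihood:
# the log-likelihood of n pairs depends on the data only through
# n, sum(y1+y2), sum(y1^2+y2^2) and sum(y1*y2).
pair_suffstats <- function(m) {
  list(n = nrow(m),
       s1 = sum(m),
       s2 = sum(m^2),
       s12 = if (nrow(m)) sum(m[, 1L] * m[, 2L]) else 0)
}

#' @export
print.twin_pairs <- function(x, ...) {
  cat(sprintf("twin pairs: %d MZ, %d DZ\n", x$stats$mz$n, x$stats$dz$n))
  invisible(x)
}

#' Implied twin-pair covariance matrix
#'
#' The biometrical expectation for the 2x2 phenotype covariance of a twin
#' pair: additive-genetic variance `a2` is fully shared by MZ co-twins and
#' half-shared by DZ co-twins, common-environment variance `c2` is fully
#' shared by both, and unique-environment variance `e2` (which absorbs
#' measurement error) is unshared. Diagonals are `a2 + c2 + e2`;
#' off-diagonals are `a2 + c2` (MZ) or `a2/2 + c2` (DZ).
#'
#' @param a2,c2,e2 Variance components on the phenotype scale.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return A symmetric 2x2 numeric matrix.
#' @examples
#' implied_covariance(1, 0, 1, "MZ")
#' implied_covariance(1, 0, 1, "DZ")
#' @export
implied_covariance <- function(a2, c2, e2, zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  v <- a2 + c2 + e2
  cv <- if (zygosity == "MZ") a2 + c2 else 0.5 * a2 + c2
  matrix(c(v, cv, cv, v), 2L, 2L)
}

# Log-likelihood of all pairs for given components and mean, computed in
# O(1) from sufficient statistics. Returns -Inf when an implied covariance
# is not positive-definite (optimizer-safe sentinel).
twin_loglik_stats <- function(a2, c2, e2, mu, stats) {
  v <- a2 + c2 + e2
  ll <- 0
  for (z in c("mz", "dz")) {
    st <- stats[[z]]
    if (st$n == 0L) next
    cv <- if (z == "mz") a2 + c2 else 0.5 * a2 + c2
    det <- v^2 - cv^2
    if (!is.finite(det) || v <= 0 || det <= 0) return(-Inf)
    sd2 <- st$s2 - 2 * mu * st$s1 + 2 * st$n * mu^2
    sd12 <- st$s12 - mu * st$s1 + st$n * mu^2
    q <- (v * sd2 - 2 * cv * sd12) / det
    ll <- ll - st$n * log(2 * pi) - st$n / 2 * log(det) - q / 2
  }
  ll
}

#' Twin-model log-likelihood at given parameter values
#'
#' Sum over pairs of the bivariate normal log-density with mean
#' `(mu, mu)` and the zygosity-appropriate [implied_covariance()]. Mainly
#' useful for diagnostics and cross-checks; [twin_ace()] maximizes it.
#'
#' @param a2,c2,e2 Variance components.
#' @param mu Grand mean.
#' @param data A [twin_pairs()] object.
#' @return The log-likelihood; `-Inf` if an implied covariance is not
#'   positive-definite.
#' @export
twin_loglik <- function(a2, c2, e2, mu, data) {
  stopifnot(inherits(data, "twin_pairs"))
  twin_loglik_stats(a2, c2, e2, mu, data$stats)
}

# --- parameter packing --------------------------------------------------
# direct: variance components enter as unbounded reals (a2, c2 may go
#   negative, as unstandardized twin-model point estimates sometimes do);
#   e2 > 0 is enforced through an internal log transform.
# path:   a2 = a^2, c2 = c^2 via unbounded path coefficients, constraining
#   the genetic and shared-environment variances to be nonnegative.
model_free <- function(model) {
  switch(model,
         ACE = c("a2", "c2"),
         AE = "a2",
         CE = "c2",
         E = character(0))
}

theta_to_comp <- function(theta, model, parameterization) {
  theta <- unname(theta)
  free <- model_free(model)
  a2 <- c2 <- 0
  i <- 2L
  if ("a2" %in% free) {
    a2 <- if (parameterization == "path") theta[i]^2 else theta[i]
    i <- i + 1L
  }
  if ("c2" %in% free) {
    c2 <- if (parameterization == "path") theta[i]^2 else theta[i]
    i <- i + 1L
  }
  c(mu = theta[1L], a2 = a2, c2 = c2, e2 = exp(theta[i]))
}

comp_to_theta <- function(mu, a2, c2, e2, model, parameterization) {
  free <- model_free(model)
  th <- unname(mu)
  a2 <- unname(a2); c2 <- unname(c2); e2 <- unname(e2)
  if ("a2" %in% free)
    th <- c(th, if (parameterization == "path") sqrt(max(a2, 1e-8)) else a2)
  if ("c2" %in% free)
    th <- c(th, if (parameterization == "path") sqrt(max(c2, 1e-8)) else c2)
  c(th, log(max(e2, 1e-10)))
}

# Moment-based estimates: grand mean, per-zygosity ML variances and
# covariances, and the classical method-of-moments component solutions.
moment_estimates <- function(stats) {
  n <- stats$mz$n + stats$dz$n
  mu <- (stats$mz$s1 + stats$dz$s1) / (2 * n)
  mom <- function(st) {
    if (st$n == 0L) return(c(var = NA_real_, cov = NA_real_))
    c(var = (st$s2 - 2 * mu * st$s1 + 2 * st$n * mu^2) / (2 * st$n),
      cov = (st$s12 - mu * st$s1 + st$n * mu^2) / st$n)
  }
  mz <- mom(stats$mz); dz <- mom(stats$dz)
  vtot <- mean(c(mz["var"], dz["var"]), na.rm = TRUE)
  list(mu = mu, vtot = vtot, mz = mz, dz = dz,
       a2 = 2 * (mz[["cov"]] - dz[["cov"]]),
       c2 = 2 * dz[["cov"]] - mz[["cov"]])
}

#' Fit an ACE-family twin variance-component model by maximum likelihood
#'
#' Fits the classical biometrical twin model: the phenotype covariance of a
#' twin pair is decomposed into additive-genetic (A), common-environment
#' (C) and unique-environment (E) variance, exploiting the expected genetic
#' correlation of 1 within MZ pairs and 1/2 within DZ pairs. The full
#' likelihood (bivariate normal per pair, a single grand mean shared across
#' twin order and zygosity) is maximized numerically with deterministic
#' multi-start optimization.
#'
#' Under the default `"direct"` parameterization `a2` and `c2` are
#' unbounded, so small true components can yield negative point estimates
#' and confidence bounds — informative about sampling noise near zero. The
#' `"path"` parameterization squares path coefficients, constraining
#' `a2, c2 >= 0`; likelihood-ratio tests of components on that boundary are
#' then conservative (no boundary-mixture correction is applied).
#'
#' @param data A [twin_pairs()] object.
#' @param model `"ACE"`, `"AE"`, `"CE"` or `"E"` — which components are
#'   free; omitted components are fixed at zero.
#' @param parameterization `"direct"` (unbounded `a2`, `c2`) or `"path"`
#'   (nonnegative via squared path coefficients).
#' @param n_starts Number of deterministic optimizer starts (moment-based
#'   start plus fixed perturbations).
#' @return An object of class `twin_ace` with components `coefficients`
#'   (`mu`, `a2`, `c2`, `e2`), `standardized` (included components divided
#'   by total variance), `loglik`, `n_params`, `aic`, `converged`, `model`,
#'   `parameterization`, `data`.
#' @seealso [confint.twin_ace()] for profile-likelihood intervals,
#'   [anova.twin_ace()] for likelihood-ratio comparison,
#'   [heritability_test()] for the full model ladder.
#' @examples
#' set.seed(1)
#' tp <- twin_pairs(mz = matrix(rnorm(200), ncol = 2),
#'                  dz = matrix(rnorm(200), ncol = 2))
#' fit <- twin_ace(tp, model = "AE")
#' summary(fit)
#' @export
twin_ace <- function(data, model = c("ACE", "AE", "CE", "E"),
                     parameterization = c("direct", "path"),
                     n_starts = 5L) {
  model <- match.arg(model)
  parameterization <- match.arg(parameterization)
  stopifnot(inherits(data, "twin_pairs"))
  st <- data$stats
  n_pairs <- st$mz$n + st$dz$n
  if (model %in% c("ACE", "AE")) {
    if (st$mz$n < 2L || st$dz$n < 2L)
      stop("models with an A component need at least 2 MZ and 2 DZ pairs")
  } else if (n_pairs < 2L) {
    stop("at least 2 pairs are required")
  }
  mom <- moment_estimates(st)
  if (!is.finite(mom$vtot) || mom$vtot <= 0)
    stop("degenerate data: zero phenotypic variance")

  negll <- function(theta) {
    cp <- theta_to_comp(theta, model, parameterization)
    -twin_loglik_stats(cp["a2"], cp["c2"], cp["e2"], cp["mu"], st)
  }

  v <- mom$vtot
  a0 <- min(max(mom$a2, -0.5 * v, na.rm = TRUE), 1.5 * v)
  c0 <- min(max(mom$c2, -0.5 * v, na.rm = TRUE), 1.5 * v)
  if (!is.finite(a0)) a0 <- 0.3 * v
  if (!is.finite(c0)) c0 <- 0.2 * v
  e0 <- max(v - max(a0, 0) - max(c0, 0), 0.1 * v)
  starts <- list(
    c(mu = mom$mu, a2 = a0, c2 = c0, e2 = e0),
    c(mu = mom$mu, a2 = 0.3 * v, c2 = 0.3 * v, e2 = 0.4 * v),
    c(mu = mom$mu, a2 = 0.05 * v, c2 = 0.05 * v, e2 = 0.9 * v),
    c(mu = mom$mu, a2 = 0.8 * v, c2 = 0.05 * v, e2 = 0.15 * v),
    c(mu = mom$mu, a2 = 0.1 * v, c2 = 0.6 * v, e2 = 0.3 * v)
  )[seq_len(max(1L, min(n_starts, 5L)))]

  best <- NULL
  for (s in starts) {
    th0 <- comp_to_theta(s["mu"], s["a2"], s["c2"], s["e2"],
                         model, parameterization)
    if (!is.finite(negll(th0))) next
    o <- stats::optim(th0, negll, method = "Nelder-Mead",
                      control = list(reltol = 1e-8, maxit = 1000L))
    o <- stats::optim(o$par, negll, method = "BFGS",
                      control = list(reltol = 1e-12, maxit = 500L))
    if (is.null(best) || o$value < best$value - 1e-12) best <- o
  }
  if (is.null(best))
    stop("optimization failed from every start")

  cp <- theta_to_comp(best$par, model, parameterization)
  k <- length(best$par)
  ll <- -best$value
  fit <- list(
    coefficients = cp,
    standardized = standardize(cp[c("a2", "c2", "e2")], model),
    loglik = ll,
    n_params = k,
    aic = -2 * ll + 2 * k,
    converged = best$convergence == 0L,
    model = model,
    parameterization = parameterization,
    theta = best$par,
    data = data,
    n_mz = st$mz$n,
    n_dz = st$dz$n
  )
  class(fit) <- "twin_ace"
  fit
}

#' Standardize variance components
#'
#' Divides each component included in the model by the total fitted
#' variance, yielding the proportions of phenotypic variance attributed to
#' each source (standardized A is the narrow-sense heritability). Under the
#' direct parameterization a component can be negative, so standardized
#' values are signed but still sum to one.
#'
#' @param components Named numeric vector with elements `a2`, `c2`, `e2`
#'   (extra elements such as `mu` are ignored).
#' @param model Model label; only the components the model includes enter
#'   the total and the output.
#' @return Named numeric vector of proportions (names `A`, `C`, `E` as
#'   included), summing to 1.
#' @examples
#' standardize(c(a2 = 0.1428, c2 = 0, e2 = 0.2683), "AE")
#' @export
standardize <- function(components, model = "ACE") {
  free <- c(model_free(model), "e2")
  vals <- components[free]
  tot <- sum(vals)
  if (!is.finite(tot) || tot <= 0)
    stop("total variance must be positive to standardize")
  out <- vals / tot
  names(out) <- toupper(substr(free, 1L, 1L))
  out
}

#' @export
print.twin_ace <- function(x, digits = 4, ...) {
  cat(sprintf("Twin %s model (%s parameterization), ML fit\n",
              x$model, x$parameterization))
  cat(sprintf("  %d MZ pairs, %d DZ pairs; logLik = %.*f, AIC = %.*f\n",
              x$n_mz, x$n_dz, digits, x$loglik, digits, x$aic))
  comp <- x$coefficients
  free <- c(model_free(x$model), "e2")
  tab <- data.frame(
    unstandardized = comp[free],
    standardized = unname(x$standardized),
    row.names = toupper(substr(free, 1L, 1L)))
  print(round(tab, digits))
  cat(sprintf("  mean = %.*f\n", digits, comp["mu"]))
  if (!x$converged) cat("  WARNING: optimizer did not converge\n")
  invisible(x)
}

#' @export
coef.twin_ace <- function(object, ...) object$coefficients

#' @export
logLik.twin_ace <- function(object, ...) {
  structure(object$loglik, df = object$n_params, class = "logLik")
}

#' @export
summary.twin_ace <- function(object, conf_level = 0.95, ci = TRUE, ...) {
  ci_tab <- if (ci) confint(object, level = conf_level) else NULL
  out <- list(fit = object, ci = ci_tab, conf_level = conf_level)
  class(out) <- "summary.twin_ace"
  out
}

#' @export
print.summary.twin_ace <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  if (!is.null(x$ci)) {
    cat(sprintf("Profile-likelihood %g%% intervals (unstandardized):\n",
                100 * x$conf_level))
    print(round(x$ci, digits))
  }
  invisible(x)
}

#' Residuals of a twin model fit
#'
#' Whitened within-pair residuals: each pair's deviation from the grand
#' mean is premultiplied by the inverse Cholesky factor of its implied
#' covariance, so under the model the residuals are approximately iid
#' standard normal.
#'
#' @param object A `twin_ace` fit.
#' @param ... Unused.
#' @return Numeric matrix with two columns and one row per pair, MZ pairs
#'   first.
#' @export
residuals.twin_ace <- function(object, ...) {
  cp <- object$coefficients
  out <- lapply(c("MZ", "DZ"), function(z) {
    m <- if (z == "MZ") object$data$mz else object$data$dz
    if (nrow(m) == 0L) return(m)
    sig <- implied_covariance(cp["a2"], cp["c2"], cp["e2"], z)
    d <- sweep(m, 2L, cp["mu"])
    t(solve(t(chol(sig)), t(d)))
  })
  res <- rbind(out[[1L]], out[[2L]])
  rownames(res) <- NULL
  res
}

#' Simulate twin pairs from a fitted model
#'
#' @param object A `twin_ace` fit.
#' @param nsim Number of replicate datasets.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A list of [twin_pairs()] objects (length `nsim`), each with the
#'   fitted model's pair counts and parameter values.
#' @export
simulate.twin_ace <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  cp <- object$coefficients
  lapply(seq_len(nsim), function(i) {
    draw <- function(n, z) {
      if (n == 0L) return(NULL)
      sig <- implied_covariance(max(cp["a2"], 0), max(cp["c2"], 0),
                                cp["e2"], z)
      r <- chol(sig)
      zmat <- matrix(stats::rnorm(2L * n), n, 2L)
      sweep(zmat %*% r, 2L, -cp["mu"])
    }
    twin_pairs(mz = draw(object$n_mz, "MZ"), dz = draw(object$n_dz, "DZ"))
  })
}

#' Plot a twin model fit
#'
#' Scatter of co-twin phenotypes by zygosity with the fitted implied
#' correlation in each panel title. A steeper MZ than DZ resemblance is the
#' visual signature of additive-genetic variance.
#'
#' @param x A `twin_ace` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.twin_ace <- function(x, ...) {
  cp <- x$coefficients
  op <- graphics::par(mfrow = c(1L, 2L))
  on.exit(graphics::par(op))
  for (z in c("MZ", "DZ")) {
    m <- if (z == "MZ") x$data$mz else x$data$dz
    sig <- implied_covariance(cp["a2"], cp["c2"], cp["e2"], z)
    r <- sig[1L, 2L] / sig[1L, 1L]
    graphics::plot(m[, 1L], m[, 2L], xlab = "twin 1", ylab = "twin 2",
                   main = sprintf("%s pairs (implied r = %.2f)", z, r), ...)
    graphics::abline(0, 1, lty = 2L)
  }
  invisible(x)
}
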