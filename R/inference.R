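#' Profile-likelihood confidence intervals for variance components
#'
#' For each free variance component the profile deviance
#' `2 * (logLik_max - logLik_profile)` is traced as the component is fixed
#' on a grid while all other parameters are re-optimized; the interval
#' endpoints are where the deviance crosses the chi-square(1) quantile for
#' `level` (3.8415 at 95%). Under the direct parameterization lower bounds
#' on `a2` and `c2` may be negative; `e2` is always strictly positive.
#' `method = "wald"` gives the cheaper normal-approximation interval from
#' the numerical Hessian instead.
#'
#' @param object A `twin_ace` fit.
#' @param parm Components to profile (subset of the model's free variance
#'   components); defaults to all.
#' @param level Confidence level.
#' @param method `"profile"` (default) or `"wald"`.
#' @param ... Unused.
#' @return Matrix with one row per component and columns `lower`, `upper`.
#' @export
confint.twin_ace <- function(object, parm = NULL, level = 0.95,
                             method = c("profile", "wald"), ...) {
  method <- match.arg(method)
  free <- c(model_free(object$model), "e2")
  if (is.null(parm)) parm <- free
  parm <- match.arg(parm, free, several.ok = TRUE)
  if (method == "wald") return(wald_ci(object, parm, level))
  thresh <- stats::qchisq(level, df = 1L)
  out <- t(vapply(parm, function(p) profile_ci_one(object, p, thresh),
                  numeric(2L)))
  colnames(out) <- c("lower", "upper")
  out
}

# Profile deviance for one component fixed at `value`: re-optimize the
# remaining parameters from the MLE (warm start).
profile_deviance <- function(object, comp, value) {
  st <- object$data$stats
  model <- object$model
  par <- object$parameterization
  if (comp == "e2" && value <= 0) return(Inf)
  if (par == "path" && comp %in% c("a2", "c2") && value < 0) return(Inf)
  free_other <- setdiff(c(model_free(model), "e2"), comp)
  cp_hat <- object$coefficients
  pack <- function(cp) {
    th <- cp["mu"]
    for (f in free_other) {
      v <- cp[f]
      th <- c(th, switch(f,
                         a2 = if (par == "path") sqrt(max(v, 1e-8)) else v,
                         c2 = if (par == "path") sqrt(max(v, 1e-8)) else v,
                         e2 = log(max(v, 1e-10))))
    }
    th
  }
  unpack <- function(th) {
    cp <- c(mu = th[[1L]], a2 = 0, c2 = 0, e2 = 0)
    i <- 2L
    for (f in free_other) {
      cp[f] <- switch(f,
                      a2 = if (par == "path") th[i]^2 else th[i],
                      c2 = if (par == "path") th[i]^2 else th[i],
                      e2 = exp(th[i]))
      i <- i + 1L
    }
    cp[comp] <- value
    cp
  }
  negll <- function(th) {
    cp <- unpack(th)
    -twin_loglik_stats(cp["a2"], cp["c2"], cp["e2"], cp["mu"], st)
  }
  th0 <- pack(cp_hat)
  if (!is.finite(negll(th0))) {
    # fixed value may make the MLE warm start infeasible; retreat to a
    # conservative interior start
    cp0 <- cp_hat
    cp0["e2"] <- max(cp_hat["e2"], abs(value) + 0.1 * sum(abs(cp_hat[-1L])))
    th0 <- pack(cp0)
    if (!is.finite(negll(th0))) return(Inf)
  }
  o <- stats::optim(th0, negll, method = "Nelder-Mead",
                    control = list(reltol = 1e-12, maxit = 3000L))
  if (length(th0) > 1L)
    o <- stats::optim(o$par, negll, method = "BFGS",
                      control = list(reltol = 1e-12, maxit = 200L))
  2 * (o$value - (-object$loglik))
}

profile_ci_one <- function(object, comp, thresh) {
  est <- object$coefficients[[comp]]
  scale <- max(sum(abs(object$coefficients[c("a2", "c2", "e2")])) * 0.1,
               abs(est) * 0.25, 1e-6)
  bound <- function(dir) {
    lo_allowed <- if (comp == "e2") 1e-12
                  else if (object$parameterization == "path") 0
                  else -Inf
    x_prev <- est
    d_prev <- 0
    step <- scale
    for (i in 1:60) {
      x <- est + dir * step
      if (dir < 0 && x < lo_allowed) x <- lo_allowed
      d <- profile_deviance(object, comp, x)
      if (is.finite(d) && d >= thresh) {
        r <- tryCatch(
          stats::uniroot(function(v) profile_deviance(object, comp, v) - thresh,
                         lower = min(x_prev, x), upper = max(x_prev, x),
                         tol = scale * 1e-6)$root,
          error = function(e) NA_real_)
        return(r)
      }
      if (dir < 0 && x <= lo_allowed) return(lo_allowed)  # boundary inside CI
      x_prev <- x
      d_prev <- d
      step <- step * 1.7
    }
    warning("profile bound search for ", comp, " did not bracket; ",
            "reporting NA")
    NA_real_
  }
  c(bound(-1), bound(1))
}

wald_ci <- function(object, parm, level) {
  st <- object$data$stats
  model <- object$model
  par <- object$parameterization
  negll <- function(theta) {
    cp <- theta_to_comp(theta, model, par)
    -twin_loglik_stats(cp["a2"], cp["c2"], cp["e2"], cp["mu"], st)
  }
  H <- stats::optimHess(object$theta, negll)
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_,
                                                     nrow(H), ncol(H)))
  free <- c(model_free(model), "e2")
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- t(vapply(parm, function(p) {
    i <- match(p, free) + 1L
    est <- object$coefficients[[p]]
    se_th <- sqrt(V[i, i])
    # delta method through the internal transform
    g <- switch(p,
                e2 = est,                       # d exp(t)/dt = e2
                if (par == "path") 2 * sqrt(max(est, 0)) else 1)
    se <- se_th * abs(g)
    c(est - z * se, est + z * se)
  }, numeric(2L)))
  colnames(out) <- c("lower", "upper")
  out
}

#' Likelihood-ratio comparison of nested twin models
#'
#' Drops components in turn and registers the decline in fit: the
#' likelihood-ratio statistic `2 * (logLik_full - logLik_reduced)` is
#' referred to a central chi-square with degrees of freedom equal to the
#' difference in free parameter count, and the change in AIC
#' (`AIC_reduced - AIC_full`) is reported alongside.
#'
#' @param object The full-model `twin_ace` fit.
#' @param reduced A `twin_ace` fit of a model nested in `object`'s.
#' @param ... Unused.
#' @return A one-row data frame of class `twin_ace_anova` with columns
#'   `full`, `reduced`, `lr_stat`, `df`, `p_value`, `delta_aic`.
#' @export
anova.twin_ace <- function(object, reduced, ...) {
  compare_models(object, reduced)
}

#' @rdname anova.twin_ace
#' @param full The full-model fit.
#' @export
compare_models <- function(full, reduced) {
  stopifnot(inherits(full, "twin_ace"), inherits(reduced, "twin_ace"))
  nesting <- list(ACE = c("AE", "CE", "E"), AE = "E", CE = "E",
                  E = character(0))
  if (!reduced$model %in% nesting[[full$model]])
    stop("model ", reduced$model, " is not nested in ", full$model)
  lr <- 2 * (full$loglik - reduced$loglik)
  if (lr < -1e-6)
    stop("reduced model fits better than full (LR = ", signif(lr, 4),
         "): optimization failure")
  lr <- max(lr, 0)
  df <- full$n_params - reduced$n_params
  out <- data.frame(full = full$model, reduced = reduced$model,
                    lr_stat = lr, df = df,
                    p_value = lrt_pvalue(lr, df),
                    delta_aic = reduced$aic - full$aic,
                    stringsAsFactors = FALSE)
  class(out) <- c("twin_ace_anova", "data.frame")
  out
}

#' Upper-tail chi-square p-value for a likelihood-ratio statistic
#'
#' @param lr_stat Likelihood-ratio statistic (nonnegative).
#' @param df Degrees of freedom (parameter difference).
#' @return The p-value `P(chisq_df >= lr_stat)`.
#' @examples
#' lrt_pvalue(3.8415, 1)  # 0.05
#' @export
lrt_pvalue <- function(lr_stat, df = 1L) {
  stopifnot(lr_stat >= -1e-8, df >= 1L)
  stats::pchisq(max(lr_stat, 0), df = df, lower.tail = FALSE)
}

#' @export
print.twin_ace_anova <- function(x, digits = 4, ...) {
  cat(sprintf("LRT %s vs %s: chisq = %.*f, df = %d, p = %.4g, dAIC = %.*f\n",
              x$full, x$reduced, digits, x$lr_stat, x$df, x$p_value,
              digits, x$delta_aic))
  invisible(x)
}

#' Heritability test for one phenotype
#'
#' Fits the full nested ladder of twin models (ACE, AE, CE, E) and reports
#' the narrow-sense heritability as the standardized A component of the AE
#' model, with significance from the AE-versus-E likelihood-ratio test
#' (df = 1). The AE model is the reporting model because shared-environment
#' variance is rarely separable from additive-genetic variance at typical
#' twin-cohort sizes; the complete ladder is retained for model-comparison
#' reporting.
#'
#' @param data A [twin_pairs()] object.
#' @param parameterization Passed to [twin_ace()].
#' @param ci Compute profile-likelihood 95% intervals for the AE
#'   components.
#' @param conf_level Confidence level for the intervals.
#' @return An object of class `heritability_test`: list with `h2`
#'   (standardized A from AE), `p_value` (AE vs E), `fits` (named list of
#'   the four fits), `comparisons` (nested-model LRT table), `falconer`
#'   (moment-based `2 * (r_MZ - r_DZ)` cross-check) and optionally `ci`.
#' @export
heritability_test <- function(data, parameterization = c("direct", "path"),
                              ci = FALSE, conf_level = 0.95) {
  parameterization <- match.arg(parameterization)
  fits <- lapply(c(ACE = "ACE", AE = "AE", CE = "CE", E = "E"),
                 function(m) twin_ace(data, model = m,
                                      parameterization = parameterization))
  comparisons <- rbind(compare_models(fits$ACE, fits$AE),
                       compare_models(fits$ACE, fits$CE),
                       compare_models(fits$AE, fits$E),
                       compare_models(fits$CE, fits$E))
  ae_e <- comparisons[comparisons$full == "AE" & comparisons$reduced == "E", ]
  out <- list(h2 = unname(fits$AE$standardized["A"]),
              p_value = ae_e$p_value,
              fits = fits,
              comparisons = comparisons,
              falconer = falconer_h2(data),
              ci = if (ci) confint(fits$AE, level = conf_level) else NULL)
  class(out) <- "heritability_test"
  out
}

#' @export
print.heritability_test <- function(x, digits = 4, ...) {
  cat(sprintf("Narrow-sense heritability (standardized A, AE model): %.*f\n",
              digits, x$h2))
  cat(sprintf("AE vs E likelihood-ratio test: p = %.4g\n", x$p_value))
  cat(sprintf("Falconer moment estimate 2(r_MZ - r_DZ): %.*f\n",
              digits, x$falconer))
  cat("\nNested-model comparisons:\n")
  print(as.data.frame(x$comparisons), digits = digits)
  if (!is.null(x$ci)) {
    cat("\nAE component intervals (unstandardized):\n")
    print(round(x$ci, digits))
  }
  invisible(x)
}

#' Falconer moment estimate of heritability
#'
#' The classical `h2 = 2 * (r_MZ - r_DZ)` estimator, with each twin
#' correlation computed as the Pearson correlation on double-entered pairs
#' (each pair contributes both orderings, making the estimate
#' order-invariant). Used as an independent cross-check on the
#' maximum-likelihood estimate.
#'
#' @param data A [twin_pairs()] object with at least 2 pairs per zygosity.
#' @return The moment-based heritability estimate.
#' @export
falconer_h2 <- function(data) {
  stopifnot(inherits(data, "twin_pairs"))
  de_cor <- function(m) {
    if (nrow(m) < 2L) return(NA_real_)
    stats::cor(c(m[, 1L], m[, 2L]), c(m[, 2L], m[, 1L]))
  }
  2 * (de_cor(data$mz) - de_cor(data$dz))
}
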