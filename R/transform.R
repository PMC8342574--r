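#' Arcsine-square-root transform of proportions
#'
#' The variance-stabilizing transform `y = arcsin(sqrt(p))` maps a
#' proportion in \[0, 1\] to a phenotype in \[0, pi/2\] radians; it is the
#' scale on which the twin variance-component models are fit. Values within
#' `tol` of the boundary (floating-point spillover from upstream division)
#' are clamped; values further outside raise an error.
#'
#' @param p Numeric vector of proportions.
#' @param tol Clamp tolerance for values marginally outside \[0, 1\].
#' @return Numeric vector on the arcsine-square-root scale (radians).
#' @export
asin_sqrt <- function(p, tol = 1e-9) {
  bad <- p < -tol | p > 1 + tol
  if (any(bad, na.rm = TRUE))
    stop("proportion outside [0, 1]: ", p[which(bad)[1L]])
  asin(sqrt(pmin(pmax(p, 0), 1)))
}

#' Inverse arcsine-square-root transform
#'
#' Maps an arcsine-square-root phenotype back to a proportion via
#' `sin(y)^2`. Simulated phenotypes may stray outside \[0, pi/2\]; they are
#' clamped to the range before inversion, so the result is always a valid
#' proportion (mild boundary censoring, the simulator's documented
#' contract).
#'
#' @param y Numeric vector on the transformed scale (radians).
#' @return Numeric vector of proportions in \[0, 1\].
#' @export
inv_asin_sqrt <- function(y) {
  sin(pmin(pmax(y, 0), pi / 2))^2
}
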