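#' Select analyzable taxa by prevalence and abundance
#'
#' Microbiome taxa tables are sparse: most taxa are absent from most
#' samples and carry too little covariance information for a
#' variance-component fit. `select_taxa()` keeps a taxon when its
#' proportion reaches `min_within_prop` in at least a fraction
#' `min_subject_frac` of subjects (both thresholds inclusive). The primary
#' screen used for heritability estimation is 20% of subjects at a
#' within-subject proportion of 10%; an expanded screen of 2.5% / 1% is
#' available via [filter_spec()].
#'
#' Under the default joint rule a subject counts toward prevalence only
#' when the taxon reaches `min_within_prop` in that subject. The disjoint
#' alternative (`mode = "disjoint"`) counts any nonzero occurrence toward
#' prevalence and requires the abundance threshold to be met in at least
#' one subject anywhere; it admits taxa that are near-absent in most
#' carriers and is provided for comparison only.
#'
#' @param table A `taxa_proportion_table`.
#' @param spec A [filter_spec()].
#' @param mode `"joint"` (default) or `"disjoint"`; see Details.
#' @return Character vector of selected taxon names, in input column order.
#' @export
select_taxa <- function(table, spec = filter_spec(), mode = c("joint", "disjoint")) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "taxa_proportion_table"))
  p <- table$proportions
  if (nrow(p) == 0L) stop("empty proportion table")
  n <- nrow(p)
  if (mode == "joint") {
    frac_hit <- colSums(p >= spec$min_within_prop) / n
    sel <- frac_hit >= spec$min_subject_frac
  } else {
    prev <- colSums(p > 0) / n
    sel <- prev >= spec$min_subject_frac &
      apply(p, 2L, max) >= spec$min_within_prop
  }
  out <- table$taxon_names[sel]
  if (!length(out)) warning("no taxa pass the filter")
  out
}

#' Taxa filter thresholds
#'
#' @param min_subject_frac Minimum fraction of subjects (in \[0, 1\]) in
#'   which the taxon must reach `min_within_prop`.
#' @param min_within_prop Minimum within-subject proportion (in \[0, 1\]).
#' @param expanded Use the expanded screen (2.5% of subjects at 1%
#'   proportion) instead of the primary 20% / 10% screen.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(min_subject_frac = 0.20, min_within_prop = 0.10,
                        expanded = FALSE) {
  if (expanded) {
    min_subject_frac <- 0.025
    min_within_prop <- 0.01
  }
  stopifnot(min_subject_frac >= 0, min_subject_frac <= 1,
            min_within_prop >= 0, min_within_prop <= 1)
  structure(list(min_subject_frac = min_subject_frac,
                 min_within_prop = min_within_prop),
            class = "filter_spec")
}
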