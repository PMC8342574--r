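#' Read a sample-by-taxon abundance table
#'
#' Reads a tab-separated species-level abundance table of the kind produced
#' by 16S read-classification pipelines: one row per sample, one column per
#' taxon, and (for the counts dialect) a `total_reads` column holding the
#' per-sample sequencing depth. Unassigned reads are permitted, so taxon
#' counts may sum to less than `total_reads`.
#'
#' @param path Path to a UTF-8 TSV file. The counts dialect has header
#'   `sample_id`, `total_reads`, then taxon names; the proportions dialect
#'   omits `total_reads`.
#' @param dialect `"counts"` for integer read counts plus totals,
#'   `"proportions"` for values already on the \[0, 1\] scale.
#' @return An object of class `taxa_table`: a list with `sample_ids`,
#'   `taxon_names`, a numeric samples-by-taxa matrix (`counts` or
#'   `proportions`), and for the counts dialect `total_reads`.
#' @seealso [depth_filter()], [to_proportions()], [write_taxa_table()]
#' @export
read_taxa_table <- function(path, dialect = c("counts", "proportions")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("taxa table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = NA,
                          fileEncoding = "UTF-8")
  if (ncol(df) < 2L || names(df)[1L] != "sample_id")
    stop("malformed taxa table: first column must be 'sample_id'")
  if (dialect == "counts") {
    if (names(df)[2L] != "total_reads")
      stop("counts dialect requires a 'total_reads' second column")
    mat <- as.matrix(df[, -(1:2), drop = FALSE])
    storage.mode(mat) <- "double"
    tab <- new_taxa_table(sample_ids = as.character(df$sample_id),
                          taxon_names = colnames(mat),
                          counts = mat,
                          total_reads = as.numeric(df$total_reads))
  } else {
    mat <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(mat) <- "double"
    tab <- new_taxa_table(sample_ids = as.character(df$sample_id),
                          taxon_names = colnames(mat),
                          proportions = mat)
  }
  tab
}

# Construct and validate a taxa_table; shared by the reader and simulator.
new_taxa_table <- function(sample_ids, taxon_names, counts = NULL,
                           proportions = NULL, total_reads = NULL) {
  stopifnot(xor(is.null(counts), is.null(proportions)))
  mat <- if (is.null(counts)) proportions else counts
  dimnames(mat) <- list(sample_ids, taxon_names)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(taxon_names))
    stop("duplicate taxon name: ",
         paste(unique(taxon_names[duplicated(taxon_names)]), collapse = ", "))
  bad <- which(mat < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("malformed input: negative value at sample '%s', taxon '%s'",
                 sample_ids[bad[1L, 1L]], taxon_names[bad[1L, 2L]]))
  if (is.null(counts)) {
    bad <- which(mat > 1, arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop(sprintf("proportion > 1 at sample '%s', taxon '%s'",
                   sample_ids[bad[1L, 1L]], taxon_names[bad[1L, 2L]]))
    rs <- rowSums(mat)
    if (any(rs > 1 + 1e-6))
      stop("proportions in sample '", sample_ids[which.max(rs)],
           "' sum to more than 1")
    out <- list(sample_ids = sample_ids, taxon_names = taxon_names,
                proportions = mat)
    class(out) <- c("taxa_proportion_table", "taxa_table")
  } else {
    if (length(total_reads) != length(sample_ids))
      stop("total_reads must have one entry per sample")
    if (any(total_reads < 0)) stop("malformed input: negative total_reads")
    over <- rowSums(mat) > total_reads + 1e-6
    if (any(over))
      stop("taxon counts exceed total_reads for sample '",
           sample_ids[which(over)[1L]], "'")
    names(total_reads) <- sample_ids
    out <- list(sample_ids = sample_ids, taxon_names = taxon_names,
                counts = mat, total_reads = total_reads)
    class(out) <- c("taxa_count_table", "taxa_table")
  }
  out
}

#' Write a taxa table to TSV
#'
#' Inverse of [read_taxa_table()]; writes the same dialect the object holds.
#'
#' @param table A `taxa_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxa_table <- function(table, path) {
  if (inherits(table, "taxa_count_table")) {
    df <- data.frame(sample_id = table$sample_ids,
                     total_reads = unname(table$total_reads),
                     check.names = FALSE)
    df <- cbind(df, as.data.frame(table$counts, check.names = FALSE))
  } else {
    df <- data.frame(sample_id = table$sample_ids, check.names = FALSE)
    df <- cbind(df, as.data.frame(table$proportions, check.names = FALSE))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.taxa_table <- function(x, ...) {
  kind <- if (inherits(x, "taxa_count_table")) "counts" else "proportions"
  cat(sprintf("taxa table (%s): %d samples x %d taxa\n",
              kind, length(x$sample_ids), length(x$taxon_names)))
  invisible(x)
}

#' Screen samples by sequencing depth
#'
#' Keeps only samples whose total read count reaches `min_reads`
#' (inclusive). Low-depth samples carry unreliable proportion estimates, so
#' a depth screen (conventionally 5000 reads for vaginal 16S surveys) is
#' applied before any proportion is computed. By default the screen uses the
#' per-sample `total_reads` (all reads, assigned or not); set
#' `assigned_only = TRUE` to screen on taxonomically assigned reads instead.
#'
#' @param table A `taxa_count_table`.
#' @param min_reads Minimum depth; samples with `total_reads >= min_reads`
#'   are retained.
#' @param assigned_only Screen on the row sum of assigned taxon counts
#'   rather than `total_reads`.
#' @return The filtered `taxa_count_table`, with attribute `"n_removed"`.
#' @export
depth_filter <- function(table, min_reads = 5000, assigned_only = FALSE) {
  stopifnot(inherits(table, "taxa_count_table"), min_reads >= 0)
  depth <- if (assigned_only) rowSums(table$counts) else table$total_reads
  keep <- depth >= min_reads
  if (!any(keep))
    stop("depth filter removed every sample (min_reads = ", min_reads, ")")
  out <- new_taxa_table(sample_ids = table$sample_ids[keep],
                        taxon_names = table$taxon_names,
                        counts = table$counts[keep, , drop = FALSE],
                        total_reads = unname(table$total_reads[keep]))
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Convert read counts to proportions
#'
#' Divides each taxon count by the sample's sequencing depth. The default
#' denominator is `total_reads` (including unassigned reads), which is
#' robust to truncation of the taxon list; `denominator = "assigned"`
#' renormalizes over the listed taxa instead.
#'
#' @param table A `taxa_count_table`.
#' @param denominator `"total"` (per-sample total reads) or `"assigned"`
#'   (sum of listed taxon counts).
#' @return A `taxa_proportion_table`.
#' @export
to_proportions <- function(table, denominator = c("total", "assigned")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(table, "taxa_count_table"))
  den <- if (denominator == "total") unname(table$total_reads)
         else rowSums(table$counts)
  zero <- den <= 0
  if (any(zero))
    stop("zero total reads for sample '",
         table$sample_ids[which(zero)[1L]], "': cannot form proportions")
  new_taxa_table(sample_ids = table$sample_ids,
                 taxon_names = table$taxon_names,
                 proportions = table$counts / den)
}

#' Read twin participant metadata
#'
#' Reads a CSV with columns `participant_id`, `pair_id`, `zygosity`
#' (MZ/DZ), `ancestry`, `age`, and any additional covariate columns (BMI,
#' bacterial vaginosis status, smoking, pH, ...). Empty fields are missing.
#'
#' @param path Path to the CSV file.
#' @return A data frame of validated participant records.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = c("", "NA"), fileEncoding = "UTF-8")
  validate_metadata(df)
}

validate_metadata <- function(df) {
  need <- c("participant_id", "pair_id", "zygosity", "ancestry")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metadata missing required column(s): ", paste(miss, collapse = ", "))
  df$participant_id <- as.character(df$participant_id)
  df$pair_id <- as.character(df$pair_id)
  if (anyDuplicated(df$participant_id))
    stop("duplicate participant_id in metadata")
  bad <- !df$zygosity %in% c("MZ", "DZ")
  if (any(bad))
    stop("zygosity must be 'MZ' or 'DZ'; offending participant: ",
         df$participant_id[which(bad)[1L]])
  sizes <- table(df$pair_id)
  if (any(sizes > 2L))
    stop("pair_id '", names(sizes)[which(sizes > 2L)[1L]],
         "' has more than two members")
  zyg_per_pair <- tapply(df$zygosity, df$pair_id,
                         function(z) length(unique(z)))
  if (any(zyg_per_pair > 1L))
    stop("discordant zygosity labels within pair_id '",
         names(zyg_per_pair)[which(zyg_per_pair > 1L)[1L]], "'")
  df
}

#' Assemble complete twin pairs
#'
#' Joins participant metadata to the set of samples that survived the depth
#' screen and keeps only pairs in which both members have a retained
#' sample. Members of incomplete pairs (singletons) are counted and
#' excluded: a twin model needs the within-pair covariance, which a lone
#' member cannot supply. Member order within a pair is canonical
#' (lexicographic by participant id), so the result does not depend on
#' input row order.
#'
#' @param records Metadata data frame (see [read_metadata()]).
#' @param phenotype_samples Character vector of retained sample/participant
#'   ids (samples are identified by participant id).
#' @return An object of class `twin_cohort`: a data frame of pairs
#'   (`pair_id`, `zygosity`, `ancestry`, `member_1`, `member_2`) with
#'   attribute `"singletons_excluded"`.
#' @export
assemble_pairs <- function(records, phenotype_samples) {
  records <- validate_metadata(records)
  present <- records[records$participant_id %in% phenotype_samples, ,
                     drop = FALSE]
  n_members <- table(present$pair_id)
  complete <- names(n_members)[n_members == 2L]
  singletons <- sum(n_members == 1L)
  keep <- present[present$pair_id %in% complete, , drop = FALSE]
  keep <- keep[order(keep$pair_id, keep$participant_id), , drop = FALSE]
  i1 <- seq(1L, nrow(keep), by = 2L)
  pairs <- data.frame(
    pair_id = keep$pair_id[i1],
    zygosity = keep$zygosity[i1],
    ancestry = keep$ancestry[i1],
    member_1 = keep$participant_id[i1],
    member_2 = keep$participant_id[i1 + 1L],
    stringsAsFactors = FALSE
  )
  if (nrow(pairs)) {
    anc2 <- keep$ancestry[i1 + 1L]
    mism <- pairs$ancestry != anc2
    # rare in practice; keep the pair but flag the label conflict
    if (any(mism, na.rm = TRUE))
      warning("ancestry labels differ within pair(s): ",
              paste(pairs$pair_id[which(mism)], collapse = ", "))
  }
  rownames(pairs) <- NULL
  class(pairs) <- c("twin_cohort", "data.frame")
  attr(pairs, "singletons_excluded") <- singletons
  pairs
}

#' @export
print.twin_cohort <- function(x, ...) {
  cat(sprintf("twin cohort: %d complete pairs (%d MZ, %d DZ), %d singleton(s) excluded\n",
              nrow(x), sum(x$zygosity == "MZ"), sum(x$zygosity == "DZ"),
              attr(x, "singletons_excluded")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}
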