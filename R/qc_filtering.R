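# Two-stage quality filtering: a length filter on raw sequences before
# clustering, and fragment/metal-binding-site checks on aligned cluster
# representatives before phylogenetics.

#' Filter protein records by sequence length
#'
#' Bounds are inclusive: a sequence is kept iff
#' `min_len <= length <= max_len`. Defaults (100-1000 aa) are
#' configuration, not biology: they bracket the plausible size range of
#' single-domain CA proteins and should be tuned to the input source.
#'
#' @param records A [protein_records()] data.frame.
#' @param min_len,max_len Inclusive length bounds (residues).
#' @return A list with `kept`, `removed` (both data.frames) and `report`
#'   (per-class counts: n_in, n_kept, n_removed).
#' @export
filter_by_length <- function(records, min_len = 100L, max_len = 1000L) {
  stopifnot(min_len > 0L, min_len <= max_len)
  ok <- records$length >= min_len & records$length <= max_len
  kept <- records[ok, , drop = FALSE]
  removed <- records[!ok, , drop = FALSE]
  classes <- sort(unique(records$ca_class))
  report <- data.frame(
    ca_class = classes,
    n_in = vapply(classes, function(c) sum(records$ca_class == c), 0L),
    n_kept = vapply(classes, function(c) sum(kept$ca_class == c), 0L),
    n_removed = vapply(classes, function(c) sum(removed$ca_class == c), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
  list(kept = kept, removed = removed, report = report)
}

#' Remove fragmentary rows from an alignment
#'
#' A row is removed iff its non-gap residue count is strictly below
#' `min_fraction` times the alignment length; rows at exactly the bound
#' are kept. The operation is idempotent.
#'
#' @param msa Named character vector of equal-length aligned rows
#'   (gap = `-`).
#' @param min_fraction Minimum retained fraction of the alignment length
#'   (default 0.75).
#' @return A list with `kept_ids` and `removed_ids`.
#' @export
filter_alignment_fragments <- function(msa, min_fraction = 0.75) {
  stopifnot(length(msa) > 0L, min_fraction > 0, min_fraction <= 1)
  len <- unique(nchar(msa))
  if (length(len) != 1L) stop("ragged alignment: rows differ in length")
  resid <- nchar(gsub("-", "", msa, fixed = TRUE))
  keep <- resid >= min_fraction * len
  list(kept_ids = names(msa)[keep], removed_ids = names(msa)[!keep])
}

#' Construct a metal-binding motif specification
#'
#' @param ca_class One of `alpha`, `beta`, `gamma`.
#' @param required_sites A list of `list(column=, residues=)` entries:
#'   1-based alignment columns (strictly increasing) and the residue set
#'   accepted at each.
#' @return A `ca_motif_spec` list.
#' @export
motif_spec <- function(ca_class, required_sites) {
  stopifnot(ca_class %in% CA_CLASSES, length(required_sites) > 0L)
  cols <- vapply(required_sites, function(s) as.integer(s$column), 0L)
  if (any(diff(cols) <= 0L)) stop("motif columns must be strictly increasing")
  for (s in required_sites)
    if (length(s$residues) == 0L) stop("allowed residue set must be nonempty")
  structure(list(ca_class = ca_class, required_sites = required_sites),
            class = "ca_motif_spec")
}

#' Check an aligned row for required metal-binding residues
#'
#' @param msa_row A single aligned sequence (string, gaps as `-`).
#' @param motif A [motif_spec()] object; columns index the alignment.
#' @return `TRUE` iff every required site carries an allowed residue.
#' @export
check_metal_binding <- function(msa_row, motif) {
  stopifnot(inherits(motif, "ca_motif_spec"))
  cols <- vapply(motif$required_sites, function(s) as.integer(s$column), 0L)
  if (any(cols > nchar(msa_row)))
    stop("motif column beyond alignment length")
  res <- substring(msa_row, cols, cols)
  all(mapply(function(r, s) r %in% s$residues,
             res, motif$required_sites))
}

#' Account for a before/after filtering step
#'
#' Given counts before filtering and counts removed, reports retained
#' counts and the percentage removed (one decimal), the arithmetic used
#' in filter-accounting summaries.
#'
#' @param n_before Named or plain integer vector of input counts.
#' @param n_removed Counts removed (same length/names).
#' @return A data.frame with `n_before`, `n_removed`, `n_retained`,
#'   `pct_removed`.
#' @export
filter_accounting <- function(n_before, n_removed) {
  stopifnot(length(n_before) == length(n_removed),
            all(n_removed <= n_before), all(n_removed >= 0))
  data.frame(class = if (is.null(names(n_before)))
               as.character(seq_along(n_before)) else names(n_before),
             n_before = as.integer(n_before),
             n_removed = as.integer(n_removed),
             n_retained = as.integer(n_before - n_removed),
             pct_removed = round(100 * n_removed / n_before, 1),
             row.names = NULL, stringsAsFactors = FALSE)
}
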