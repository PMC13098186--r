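# Center-star multiple alignment. Each member is aligned pairwise to the
# cluster representative (the center) by global dynamic programming, and
# the pairwise alignments are merged under the "once a gap, always a
# gap" rule. Deterministic and adequate for clusters whose members
# already share at least the clustering threshold of identity.

#' Center-star multiple sequence alignment of a cluster
#'
#' @param seqs Named character vector of member sequences.
#' @param center_id Id of the center (representative) sequence; defaults
#'   to the longest member (ties: id ascending).
#' @param ... Scoring scheme passed to [pairwise_identity()].
#' @return Named character vector of equal-length aligned rows, in the
#'   input order; ungapping any row yields its source sequence.
#' @export
center_star_align <- function(seqs, center_id = NULL, ...) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  if (length(seqs) == 1L) return(seqs)
  if (is.null(center_id)) {
    ord <- order(-nchar(seqs), names(seqs))
    center_id <- names(seqs)[ord[1L]]
  }
  stopifnot(center_id %in% names(seqs))
  center <- seqs[[center_id]]
  others <- setdiff(names(seqs), center_id)
  master <- strsplit(center, "")[[1]]
  rows <- list()
  rows[[center_id]] <- master
  for (id in others) {
    pa <- pairwise_identity(center, seqs[[id]], details = TRUE, ...)
    ac <- strsplit(pa$aligned_a, "")[[1]]
    am <- strsplit(pa$aligned_b, "")[[1]]
    merged <- .merge_into_master(master, ac, am)
    if (length(merged$insert_at) > 0L)
      rows <- lapply(rows, .insert_gaps, at = merged$insert_at)
    master <- merged$master
    rows[[id]] <- merged$member_row
  }
  out <- vapply(rows, paste, "", collapse = "")
  out[names(seqs)]
}

# master and ac both ungap to the center sequence; walk them in parallel
# producing the merged master, the member row in merged coordinates, and
# the (pre-insertion) positions at which existing rows need new gaps.
.merge_into_master <- function(master, ac, am) {
  i <- 1L; j <- 1L
  n <- length(master); m <- length(ac)
  new_master <- character(n + m)
  member <- character(n + m)
  insert_at <- integer(0)
  k <- 0L
  while (i <= n || j <= m) {
    k <- k + 1L
    mi <- if (i <= n) master[i] else NULL
    aj <- if (j <= m) ac[j] else NULL
    if (!is.null(mi) && !is.null(aj) &&
        ((mi != "-" && aj != "-") || (mi == "-" && aj == "-"))) {
      new_master[k] <- mi; member[k] <- am[j]
      i <- i + 1L; j <- j + 1L
    } else if (!is.null(mi) && (is.null(aj) || (mi == "-" && aj != "-"))) {
      new_master[k] <- mi; member[k] <- "-"
      i <- i + 1L
    } else {
      # gap only in ac (or master exhausted): existing rows need a gap
      new_master[k] <- "-"; member[k] <- am[j]
      insert_at <- c(insert_at, i)
      j <- j + 1L
    }
  }
  list(master = new_master[seq_len(k)], member_row = member[seq_len(k)],
       insert_at = insert_at)
}

# insert gaps into a row (character vector) before the given original
# positions; positions may repeat and refer to pre-insertion coordinates
.insert_gaps <- function(row, at) {
  n <- length(row)
  counts <- tabulate(at, nbins = n + 1L)
  out <- character(n + length(at))
  k <- 0L
  for (i in seq_len(n + 1L)) {
    if (counts[i] > 0L) {
      out[k + seq_len(counts[i])] <- "-"
      k <- k + counts[i]
    }
    if (i <= n) { k <- k + 1L; out[k] <- row[i] }
  }
  out
}

#' Remove gap-rich columns from an alignment
#'
#' Retains columns whose gap fraction is at most `max_gap_fraction`;
#' row order is preserved. Idempotent. The default 0.9 removes only
#' insertion columns carried by a small minority of rows.
#'
#' @param msa Named character vector of equal-length aligned rows.
#' @param max_gap_fraction Maximum tolerated per-column gap fraction.
#' @return The trimmed alignment (named character vector).
#' @export
trim_columns <- function(msa, max_gap_fraction = 0.9) {
  stopifnot(max_gap_fraction > 0, max_gap_fraction <= 1)
  len <- unique(nchar(msa))
  if (length(len) != 1L) stop("ragged alignment: rows differ in length")
  mat <- do.call(rbind, strsplit(msa, ""))
  gapfrac <- colMeans(mat == "-")
  keep <- gapfrac <= max_gap_fraction
  if (!any(keep))
    stop("all columns removed; raise max_gap_fraction")
  out <- apply(mat[, keep, drop = FALSE], 1L, paste, collapse = "")
  stats::setNames(out, names(msa))
}
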