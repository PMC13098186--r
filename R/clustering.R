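# Greedy centroid clustering at an amino-acid identity threshold,
# CD-HIT-style: sequences are sorted (length descending, id ascending),
# the first unassigned sequence seeds a cluster and becomes its
# representative, and each remaining sequence joins the first existing
# representative it matches at or above the threshold.

#' Pairwise global-alignment identity between two protein sequences
#'
#' Identity is defined as matched columns divided by alignment length of
#' an optimal Needleman-Wunsch global alignment (gap columns count
#' against identity), under a configurable match/mismatch/linear-gap
#' scoring scheme. Among equal-score alignments the reported one is
#' canonical (diagonal preferred, then gap-in-second, then gap-in-first).
#'
#' @param seq_a,seq_b Nonempty amino-acid strings.
#' @param match,mismatch,gap Scoring scheme (defaults 1/-1/-1).
#' @param details If `TRUE`, return the full alignment list (score,
#'   identity, matches, alignment_length, aligned strings).
#' @return Identity in `[0,1]`, or the detail list.
#' @export
pairwise_identity <- function(seq_a, seq_b, match = 1, mismatch = -1,
                              gap = -1, details = FALSE) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  res <- .nw_align_cpp(seq_a, seq_b, match, mismatch, gap)
  if (details) res else res$identity
}

#' Greedy identity-threshold clustering of protein records
#'
#' Deterministic given input: records are ordered by length descending
#' then id ascending; each sequence joins the first representative with
#' identity at or above `threshold`, else seeds a new cluster with itself
#' as representative. Representatives of different clusters are not
#' guaranteed to be mutually below the threshold (greedy semantics).
#'
#' @param records A [protein_records()] data.frame, all of one CA class.
#' @param threshold Identity threshold in `(0, 1]` (default 0.5).
#' @param kmer_screen If `TRUE`, skip the alignment against a
#'   representative sharing no 3-mer with the query (a speed heuristic,
#'   off by default; at the identity levels this pipeline clusters at,
#'   it does not alter results, which the test suite verifies).
#' @param ... Passed to [pairwise_identity()] (scoring scheme).
#' @return A data.frame with one row per member: `cluster_id`,
#'   `representative_id`, `member_id`, `ca_class`, `size`.
#' @export
greedy_cluster <- function(records, threshold = 0.5, kmer_screen = FALSE,
                           ...) {
  stopifnot(threshold > 0, threshold <= 1)
  if (nrow(records) == 0L)
    return(data.frame(cluster_id = character(0), representative_id = character(0),
                      member_id = character(0), ca_class = character(0),
                      size = integer(0), stringsAsFactors = FALSE))
  if (length(unique(records$ca_class)) > 1L)
    stop("greedy_cluster requires records of a single ca_class; got: ",
         paste(unique(records$ca_class), collapse = ", "))
  ord <- order(-records$length, records$sequence_id)
  ids <- records$sequence_id[ord]
  seqs <- records$sequence[ord]
  kmers <- function(s) {
    if (nchar(s) < 3L) return(s)
    unique(substring(s, 1:(nchar(s) - 2L), 3:nchar(s)))
  }
  rep_ids <- character(0); rep_seqs <- character(0)
  rep_kmers <- list()
  qk <- if (kmer_screen) lapply(seqs, kmers) else NULL
  assign <- integer(length(ids))
  for (i in seq_along(ids)) {
    placed <- FALSE
    for (k in seq_along(rep_ids)) {
      if (kmer_screen && !any(qk[[i]] %in% rep_kmers[[k]])) next
      if (pairwise_identity(rep_seqs[k], seqs[i], ...) >= threshold) {
        assign[i] <- k; placed <- TRUE; break
      }
    }
    if (!placed) {
      rep_ids <- c(rep_ids, ids[i]); rep_seqs <- c(rep_seqs, seqs[i])
      if (kmer_screen) rep_kmers[[length(rep_ids)]] <- kmers(seqs[i])
      assign[i] <- length(rep_ids)
    }
  }
  cls <- records$ca_class[1L]
  out <- data.frame(
    cluster_id = sprintf("%s_cl%04d", cls, assign),
    representative_id = rep_ids[assign],
    member_id = ids,
    ca_class = cls, stringsAsFactors = FALSE)
  sizes <- table(out$cluster_id)
  out$size <- as.integer(sizes[out$cluster_id])
  out[order(out$cluster_id, out$member_id), , drop = FALSE]
}

#' Cluster protein records per CA class
#'
#' Runs [greedy_cluster()] separately within each class and binds the
#' results.
#'
#' @inheritParams greedy_cluster
#' @return Combined cluster membership data.frame.
#' @export
cluster_by_class <- function(records, threshold = 0.5, ...) {
  parts <- lapply(split(records, records$ca_class), greedy_cluster,
                  threshold = threshold, ...)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Census of cluster sizes
#'
#' @param clusters A membership data.frame from [greedy_cluster()].
#' @param min_size Minimum cluster size of interest (default 3).
#' @return A list: `n_clusters`, `n_clusters_ge_min`,
#'   `n_sequences_in_ge_min`.
#' @export
cluster_size_census <- function(clusters, min_size = 3L) {
  stopifnot(min_size >= 1L)
  sizes <- table(clusters$cluster_id)
  qual <- sizes[sizes >= min_size]
  list(n_clusters = length(sizes),
       n_clusters_ge_min = length(qual),
       n_sequences_in_ge_min = as.integer(sum(qual)))
}
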