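# Position-specific profile models built from cluster alignments and
# scored against ORFs by local Viterbi dynamic programming, in bits.
# The architecture is Plan7-like: match states with estimated emissions,
# insert states emitting at background, silent delete states, free local
# entry/exit at any match state.

.default_transitions <- function() {
  log2(c(MM = 0.90, MI = 0.05, MD = 0.05,
         IM = 0.60, II = 0.40,
         DM = 0.60, DD = 0.40))
}

#' Build a profile model from a cluster alignment
#'
#' Match states are the alignment columns with gap fraction below
#' `max_match_gap` (default 0.5). Match emissions are residue counts
#' plus a pseudocount, normalized over the 20-letter alphabet; scores
#' are log-odds against the background in bits (log base 2).
#'
#' @param msa Named character vector of aligned rows.
#' @param profile_id Identifier (typically the cluster id).
#' @param pseudocount Additive pseudocount per residue (default 0.5).
#' @param background Background residue frequencies (default uniform
#'   1/20), named by [CA_ALPHABET].
#' @param min_rows Minimum number of rows required (default 3, the
#'   cluster-size cutoff for model building).
#' @param max_match_gap Columns with at least this gap fraction become
#'   insert, not match, columns.
#' @return A `ca_profile` list: `profile_id`, `match_columns`,
#'   `emissions` (20 x M probabilities), `log_odds` (bits),
#'   `background`, `transitions` (log2 probabilities), `n_rows`,
#'   `consensus`.
#' @export
build_profile <- function(msa, profile_id = "profile", pseudocount = 0.5,
                          background = NULL, min_rows = 3L,
                          max_match_gap = 0.5) {
  if (length(msa) < min_rows)
    stop("profile refused: ", length(msa), " row(s) < min_rows = ", min_rows)
  len <- unique(nchar(msa))
  if (length(len) != 1L) stop("ragged alignment: rows differ in length")
  if (is.null(background))
    background <- stats::setNames(rep(1 / 20, 20), CA_ALPHABET)
  stopifnot(abs(sum(background) - 1) < 1e-8)
  mat <- do.call(rbind, strsplit(msa, ""))
  gapfrac <- colMeans(mat == "-")
  match_cols <- which(gapfrac < max_match_gap)
  if (length(match_cols) == 0L) stop("no match columns (all gap-rich)")
  M <- length(match_cols)
  emis <- matrix(0, nrow = 20, ncol = M, dimnames = list(CA_ALPHABET, NULL))
  for (k in seq_len(M)) {
    col <- mat[, match_cols[k]]
    col <- col[col %in% CA_ALPHABET]
    counts <- table(factor(col, levels = CA_ALPHABET))
    p <- (as.numeric(counts) + pseudocount)
    emis[, k] <- p / sum(p)
  }
  log_odds <- log2(emis / background)
  consensus <- paste(CA_ALPHABET[apply(emis, 2L, which.max)], collapse = "")
  structure(list(profile_id = profile_id,
                 match_columns = match_cols,
                 emissions = emis,
                 log_odds = log_odds,
                 background = background,
                 transitions = .default_transitions(),
                 n_rows = length(msa),
                 consensus = consensus),
            class = "ca_profile")
}

#' Score a sequence against a profile (local Viterbi, bits)
#'
#' Residues outside the 20-letter alphabet (e.g. `X`) are scored
#' background-neutral (0 bits), not rejected.
#'
#' @param profile A `ca_profile` from [build_profile()].
#' @param orf_sequence Nonempty amino-acid string.
#' @return Best local-path log-odds score in bits.
#' @export
score_sequence <- function(profile, orf_sequence) {
  stopifnot(inherits(profile, "ca_profile"))
  if (!nzchar(orf_sequence)) stop("empty ORF sequence")
  idx <- match(strsplit(toupper(orf_sequence), "")[[1]], CA_ALPHABET) - 1L
  idx[is.na(idx)] <- -1L
  tr <- profile$transitions
  .profile_viterbi_cpp(profile$log_odds, idx,
                       tr[["MM"]], tr[["MI"]], tr[["MD"]],
                       tr[["IM"]], tr[["II"]],
                       tr[["DM"]], tr[["DD"]])
}

#' Build profiles for all sufficiently large clusters
#'
#' Aligns each qualifying cluster with [center_star_align()] (seeded on
#' the cluster representative), trims gap-rich columns, and builds a
#' profile.
#'
#' @param clusters Membership data.frame from [greedy_cluster()].
#' @param records The [protein_records()] the clusters index into.
#' @param min_size Minimum cluster size to model (default 3).
#' @param max_gap_fraction Column-trim threshold (see [trim_columns()]).
#' @param ... Passed to [build_profile()].
#' @return Named list of `ca_profile` objects, keyed by cluster id.
#' @export
build_profiles <- function(clusters, records, min_size = 3L,
                           max_gap_fraction = 0.9, ...) {
  out <- list()
  for (cid in sort(unique(clusters$cluster_id))) {
    mem <- clusters[clusters$cluster_id == cid, ]
    if (nrow(mem) < min_size) next
    seqs <- stats::setNames(
      records$sequence[match(mem$member_id, records$sequence_id)],
      mem$member_id)
    if (anyNA(seqs)) stop("cluster ", cid, " references unknown sequences")
    msa <- center_star_align(seqs, center_id = mem$representative_id[1L])
    msa <- trim_columns(msa, max_gap_fraction)
    out[[cid]] <- build_profile(msa, profile_id = cid,
                                min_rows = min_size, ...)
  }
  out
}

#' Score every ORF against every profile
#'
#' @param profiles Named list of `ca_profile` objects.
#' @param orfs Named character vector of ORF sequences.
#' @param dataset_id Dataset label attached to the output rows.
#' @return A long data.frame: `dataset_id`, `orf_id`, `profile_id`,
#'   `score` (all pairs, unfiltered).
#' @export
scan_orfs <- function(profiles, orfs, dataset_id = "dataset") {
  stopifnot(length(profiles) > 0L, length(orfs) > 0L)
  grid <- expand.grid(orf_id = names(orfs), profile_id = names(profiles),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$score <- mapply(function(o, p) score_sequence(profiles[[p]], orfs[[o]]),
                       grid$orf_id, grid$profile_id, USE.NAMES = FALSE)
  data.frame(dataset_id = dataset_id, grid, stringsAsFactors = FALSE)
}

#' Filter scores and assign each ORF to its best profile
#'
#' Retains, per ORF, only its maximum-scoring profile, and only when
#' that score reaches `min_score` (inclusive). Ties are broken by
#' profile id ascending. With `hit_policy = "best_orf_per_profile"` the
#' alternative reading is applied: per dataset and profile, only the
#' highest-scoring ORF above threshold is retained.
#'
#' @param scores Long data.frame from [scan_orfs()] (possibly several
#'   datasets bound together).
#' @param min_score Inclusive score threshold in bits (default 50).
#' @param hit_policy `"best_profile_per_orf"` (default) or
#'   `"best_orf_per_profile"`.
#' @return A data.frame of retained hits: `dataset_id`, `orf_id`,
#'   `profile_id`, `score`.
#' @export
assign_best_hits <- function(scores, min_score = 50,
                             hit_policy = c("best_profile_per_orf",
                                            "best_orf_per_profile")) {
  hit_policy <- match.arg(hit_policy)
  if (nrow(scores) == 0L) return(scores)
  if (hit_policy == "best_profile_per_orf") {
    ord <- order(scores$dataset_id, scores$orf_id,
                 -scores$score, scores$profile_id)
    s <- scores[ord, , drop = FALSE]
    best <- s[!duplicated(s[, c("dataset_id", "orf_id")]), , drop = FALSE]
  } else {
    ord <- order(scores$dataset_id, scores$profile_id,
                 -scores$score, scores$orf_id)
    s <- scores[ord, , drop = FALSE]
    best <- s[!duplicated(s[, c("dataset_id", "profile_id")]), , drop = FALSE]
  }
  out <- best[best$score >= min_score, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialize a profile (or list of profiles) to versioned JSON
#'
#' @param profiles A `ca_profile` or named list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles_json <- function(profiles, path) {
  if (inherits(profiles, "ca_profile")) profiles <- list(profiles)
  ser <- lapply(profiles, function(p) list(
    profile_id = p$profile_id,
    match_columns = p$match_columns,
    emissions = apply(p$emissions, 2L, identity, simplify = FALSE),
    background = as.list(p$background),
    transitions = as.list(p$transitions),
    n_rows = p$n_rows,
    consensus = p$consensus))
  jsonlite::write_json(list(format = "ca_profile", version = 1L,
                            profiles = ser),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read profiles serialized by [write_profiles_json()]
#'
#' @param path Path to the JSON file.
#' @return Named list of `ca_profile` objects.
#' @export
read_profiles_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "ca_profile"))
    stop("not a profile JSON file: ", path)
  out <- list()
  for (nm in names(obj$profiles)) {
    pr <- obj$profiles[[nm]]
    emis <- pr$emissions
    if (is.list(emis)) emis <- do.call(cbind, emis)    # M columns of 20
    else if (is.matrix(emis)) emis <- t(emis)          # parsed as M x 20
    else emis <- matrix(emis, ncol = 1L)               # single match state
    rownames(emis) <- CA_ALPHABET
    bg <- unlist(pr$background)[CA_ALPHABET]
    p <- structure(list(profile_id = pr$profile_id,
                        match_columns = as.integer(pr$match_columns),
                        emissions = emis,
                        log_odds = log2(emis / bg),
                        background = bg,
                        transitions = unlist(pr$transitions),
                        n_rows = pr$n_rows,
                        consensus = pr$consensus),
                   class = "ca_profile")
    out[[p$profile_id]] <- p
  }
  out
}
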