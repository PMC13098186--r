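# Independent reference implementations used as oracles. These are
# deliberately naive (exhaustive enumeration, plain loops) and share no
# code with the package internals they check.

# Enumerate every global alignment of two short strings; returns a
# data.frame of (score, matches, length) over all alignments.
enumerate_alignments <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  out <- list()
  rec <- function(i, j, score, matches, len) {
    if (i > length(va) && j > length(vb)) {
      out[[length(out) + 1L]] <<- c(score, matches, len)
      return(invisible())
    }
    if (i <= length(va) && j <= length(vb)) {
      hit <- va[i] == vb[j]
      rec(i + 1L, j + 1L, score + if (hit) match else mismatch,
          matches + hit, len + 1L)
    }
    if (i <= length(va)) rec(i + 1L, j, score + gap, matches, len + 1L)
    if (j <= length(vb)) rec(i, j + 1L, score + gap, matches, len + 1L)
  }
  rec(1L, 1L, 0, 0L, 0L)
  m <- do.call(rbind, out)
  data.frame(score = m[, 1], matches = m[, 2], length = m[, 3])
}

# Naive greedy clustering with the same ordering/assignment rules:
# full identity matrix first, then a plain assignment loop.
greedy_cluster_oracle <- function(records, threshold) {
  ord <- order(-records$length, records$sequence_id)
  ids <- records$sequence_id[ord]
  seqs <- records$sequence[ord]
  n <- length(ids)
  idm <- matrix(1, n, n)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      idm[i, j] <- idm[j, i] <- pairwise_identity(seqs[i], seqs[j])
    }
  }
  reps <- integer(0)
  assign <- integer(n)
  for (i in seq_len(n)) {
    assign[i] <- 0L
    for (r in reps) {
      if (idm[r, i] >= threshold) { assign[i] <- match(r, reps); break }
    }
    if (assign[i] == 0L) { reps <- c(reps, i); assign[i] <- length(reps) }
  }
  stats::setNames(assign, ids)
}

# Exhaustive best-local-path enumeration for a profile: start at any
# match state/position, move between matches directly, via insert runs,
# or via delete runs, exit freely after any match.
profile_score_oracle <- function(profile, seq) {
  lo <- profile$log_odds
  tr <- profile$transitions
  M <- ncol(lo)
  x <- match(strsplit(toupper(seq), "")[[1]], CA_ALPHABET)
  L <- length(x)
  emit <- function(k, i) if (is.na(x[i])) 0 else lo[x[i], k]
  best <- -Inf
  dfs <- function(k, i, sc) {
    best <<- max(best, sc)
    if (k < M && i < L)  # direct match -> match
      dfs(k + 1L, i + 1L, sc + tr[["MM"]] + emit(k + 1L, i + 1L))
    if (k < M) {         # insert run of length g, then next match
      g <- 1L
      while (i + g + 1L <= L) {
        cost <- tr[["MI"]] + (g - 1L) * tr[["II"]] + tr[["IM"]]
        dfs(k + 1L, i + g + 1L, sc + cost + emit(k + 1L, i + g + 1L))
        g <- g + 1L
      }
    }
    if (i < L) {         # delete run skipping d match states
      d <- 1L
      while (k + d + 1L <= M) {
        cost <- tr[["MD"]] + (d - 1L) * tr[["DD"]] + tr[["DM"]]
        dfs(k + d + 1L, i + 1L, sc + cost + emit(k + d + 1L, i + 1L))
        d <- d + 1L
      }
    }
  }
  for (i in seq_len(L)) for (k in seq_len(M)) dfs(k, i, emit(k, i))
  best
}

# Brute-force lowest-common-rank: deepest rank with a unique non-missing
# value and no conflict at any shallower rank.
lcr_oracle <- function(member_genome_ids, genomes) {
  idx <- match(member_genome_ids, genomes$genome_id)
  conflict_at <- function(r) {
    v <- unique(genomes[[r]][idx])
    v <- v[!is.na(v)]
    length(v) > 1L
  }
  unique_at <- function(r) {
    v <- unique(genomes[[r]][idx])
    v <- v[!is.na(v)]
    if (length(v) == 1L) v else NA_character_
  }
  res <- list(rank = "ROOT", taxon = "ROOT")
  for (d in rev(seq_along(CA_RANKS))) {
    r <- CA_RANKS[d]
    tx <- unique_at(r)
    if (is.na(tx)) next
    shallower <- CA_RANKS[seq_len(d - 1L)]
    if (!any(vapply(shallower, conflict_at, TRUE))) {
      res <- list(rank = r, taxon = tx)
      break
    }
  }
  res
}

# random protein string
rand_seq <- function(n) paste(sample(CA_ALPHABET, n, TRUE), collapse = "")

# mean pairwise identity over sampled pairs of a sequence set
mean_pairwise_identity <- function(seqs, n_pairs = 200L) {
  stopifnot(length(seqs) >= 2L)
  picks <- replicate(n_pairs, sample(length(seqs), 2L))
  mean(apply(picks, 2L, function(p)
    pairwise_identity(seqs[[p[1]]], seqs[[p[2]]])))
}

# adjusted Rand index between two labelings (closed form)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}
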