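toy_profile <- function(rows, ...) {
  build_profile(stats::setNames(rows, sprintf("r%d", seq_along(rows))), ...)
}

test_that("center-star alignment is rectangular and ungaps to sources", {
  two <- c(a = "MKCHCAR", b = "MKCHCAR")
  msa <- center_star_align(two)
  expect_identical(unname(msa), c("MKCHCAR", "MKCHCAR"))

  seqs <- c(a = "MKCHC", b = "MKHC")
  msa2 <- center_star_align(seqs)
  expect_identical(length(unique(nchar(msa2))), 1L)
  expect_identical(sum(strsplit(paste(msa2, collapse = ""), "")[[1]] == "-"),
                   1L)
  for (id in names(seqs))
    expect_identical(gsub("-", "", msa2[[id]]), seqs[[id]])
  expect_gte(nchar(msa2[1L]), max(nchar(seqs)))
})

test_that("center-star handles many members around a representative", {
  set.seed(8)
  anc <- rand_seq(40L)
  seqs <- stats::setNames(c(anc, vapply(1:6, function(i) {
    v <- strsplit(anc, "")[[1]]
    if (i %% 2 == 0) v <- v[-sample(40L, 2L)]
    paste(v, collapse = "")
  }, "")), sprintf("m%d", 0:6))
  msa <- center_star_align(seqs, center_id = "m0")
  expect_identical(length(unique(nchar(msa))), 1L)
  for (id in names(seqs))
    expect_identical(gsub("-", "", msa[[id]]), unname(seqs[[id]]))
})

test_that("gap-rich column trimming is idempotent and bounded", {
  msa <- c(a = "AC-E", b = "AC-E", c = "ACDE", d = "-C-E")
  tr <- trim_columns(msa, 0.5)
  expect_identical(unname(tr), c("ACE", "ACE", "ACE", "-CE"))
  expect_identical(trim_columns(tr, 0.5), tr)
  gapfree <- c(a = "ACDE", b = "ACDE", c = "ACDE")
  expect_identical(trim_columns(gapfree, 0.5), gapfree)
  allgap <- c(a = "--", b = "--", c = "AC")
  expect_error(trim_columns(allgap, 0.3), "raise max_gap_fraction")
})

test_that("profile emissions follow the pseudocount formula", {
  p0 <- toy_profile(c("MKH", "MKH", "MKH"), pseudocount = 0)
  expect_identical(ncol(p0$emissions), 3L)
  expect_identical(unname(p0$emissions["M", 1L]), 1)
  expect_identical(unname(p0$emissions["K", 2L]), 1)
  # one-column toy with pseudocount: unobserved residue log-odds
  p <- toy_profile(c("M", "M", "M"), pseudocount = 0.5)
  expected_unobs <- (0.5) / (3 + 20 * 0.5)
  expect_equal(unname(p$emissions["A", 1L]), expected_unobs)
  expect_equal(unname(p$log_odds["A", 1L]),
               log2(expected_unobs / (1 / 20)))
  expect_equal(unname(colSums(p$emissions)), 1)
})

test_that("gap-rich columns are excluded from match states", {
  msa <- c(a = "M-KH", b = "M-KH", c = "MAKH", d = "M-KH", e = "M-KH")
  p <- build_profile(msa, min_rows = 3L)
  expect_identical(p$match_columns, c(1L, 3L, 4L))
  expect_error(build_profile(msa[1:2], min_rows = 3L), "min_rows")
})

test_that("Viterbi scoring equals exhaustive path enumeration", {
  set.seed(9)
  for (i in 1:60) {
    M <- sample(2:5, 1L)
    rows <- replicate(3L, rand_seq(M))
    p <- toy_profile(rows, pseudocount = 0.4)
    orf <- rand_seq(sample(2:8, 1L))
    expect_equal(score_sequence(p, orf), profile_score_oracle(p, orf),
                 tolerance = 1e-9, info = paste("case", i))
  }
})

test_that("a profile scores its consensus above any point mutant", {
  set.seed(10)
  rows <- rep(rand_seq(15L), 3L)
  p <- toy_profile(rows)
  cons <- p$consensus
  s0 <- score_sequence(p, cons)
  v <- strsplit(cons, "")[[1]]
  for (pos in c(1L, 7L, 15L)) {
    for (r in setdiff(CA_ALPHABET, v[pos])[c(1L, 10L)]) {
      mut <- v; mut[pos] <- r
      expect_gte(s0, score_sequence(p, paste(mut, collapse = "")))
    }
  }
})

test_that("unknown residues are scored background-neutral, not rejected", {
  rows <- rep("MKHC", 3L)
  p <- toy_profile(rows)
  expect_no_error(s <- score_sequence(p, "MXHC"))
  expect_lt(s, score_sequence(p, "MKHC"))
})

test_that("best-hit assignment keeps one best profile per ORF", {
  sc <- data.frame(dataset_id = "d1",
                   orf_id = c("o1", "o1", "o2", "o3", "o3"),
                   profile_id = c("p1", "p2", "p1", "p2", "p1"),
                   score = c(60, 55, 49.9, 50, 50))
  hits <- assign_best_hits(sc, 50)
  expect_identical(hits$orf_id, c("o1", "o3"))
  expect_identical(hits$profile_id, c("p1", "p1")) # tie at 50 -> p1 first
  expect_identical(nrow(hits[hits$orf_id == "o2", ]), 0L)
})

test_that("assignment is invariant to score-row permutation", {
  set.seed(11)
  sc <- expand.grid(dataset_id = "d1", orf_id = sprintf("o%02d", 1:8),
                    profile_id = sprintf("p%d", 1:4),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sc$score <- runif(nrow(sc), 40, 70)
  h1 <- assign_best_hits(sc, 50)
  h2 <- assign_best_hits(sc[sample(nrow(sc)), ], 50)
  expect_identical(h1, h2)
  expect_lte(max(table(h1$orf_id)), 1L)
})

test_that("the best-ORF-per-profile policy keeps one ORF per profile", {
  sc <- data.frame(dataset_id = "d1",
                   orf_id = c("o1", "o2", "o1", "o2"),
                   profile_id = c("p1", "p1", "p2", "p2"),
                   score = c(60, 70, 80, 55))
  hits <- assign_best_hits(sc, 50, hit_policy = "best_orf_per_profile")
  expect_identical(hits[order(hits$profile_id), ]$orf_id, c("o2", "o1"))
})

test_that("profiles round-trip through JSON serialization", {
  set.seed(12)
  rows <- replicate(4L, rand_seq(12L))
  p <- toy_profile(rows, profile_id = "beta_cl0001")
  f <- tempfile(fileext = ".json")
  write_profiles_json(list(beta_cl0001 = p), f)
  back <- read_profiles_json(f)
  expect_identical(names(back), "beta_cl0001")
  expect_equal(back[[1L]]$emissions, p$emissions)
  orf <- rand_seq(15L)
  expect_equal(score_sequence(back[[1L]], orf), score_sequence(p, orf))
})

test_that("profiles assign held-out descendants to their true cluster", {
  cfg <- sim_config(seed = 41L,
                    n_genomes_per_group = c(Bacteria = 30L, Archaea = 0L,
                                            Fungi = 15L, Algae = 0L),
                    n_ancestors_per_class = 3L)
  s <- simulate_sequences(simulate_genomes(cfg), cfg)
  recs <- s$proteins
  truth <- s$truth$true_cluster_of
  set.seed(13)
  held <- unlist(lapply(split(recs$sequence_id, truth[recs$sequence_id]),
                        function(ids) if (length(ids) >= 5L)
                          sample(ids, 1L) else character(0)))
  train <- recs[!recs$sequence_id %in% held, ]
  cl <- cluster_by_class(train, 0.5)
  prof <- build_profiles(cl, train, 3L)
  # cluster -> dominant true ancestor
  anc_of_cluster <- vapply(split(cl$member_id, cl$cluster_id), function(m)
    names(which.max(table(truth[m]))), "")
  ok <- 0L
  for (h in held) {
    seq <- recs$sequence[recs$sequence_id == h]
    scores <- vapply(prof, score_sequence, 0, orf_sequence = seq)
    best <- names(prof)[order(-scores, names(prof))][1L]
    if (identical(anc_of_cluster[[best]], unname(truth[[h]]))) ok <- ok + 1L
  }
  expect_gte(ok / length(held), 0.95)
})
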