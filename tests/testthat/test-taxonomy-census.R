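toy_genomes <- function() {
  data.frame(
    genome_id = sprintf("g%d", 1:6),
    group = c("Fungi", "Fungi", "Fungi", "Bacteria", "Archaea", "Fungi"),
    cultured = TRUE,
    Superkingdom = c("Eukaryota", "Eukaryota", "Eukaryota", "Bacteria",
                     "Archaea", "Eukaryota"),
    Phylum = c("Ascomycota", "Ascomycota", "Ascomycota", "Proteo",
               "Eury", "Basidio"),
    Class = c("Sordariomycetes", NA, "Leotiomycetes", "Gamma", "Methano",
              "Agarico"),
    Order = c("Hypocreales", NA, NA, "Pseudo", NA, NA),
    Family = c("Nectriaceae", NA, NA, NA, NA, NA),
    Genus = c("Fusarium", NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE)
}

test_that("LCR walks to the deepest agreeing rank", {
  g <- toy_genomes()
  expect_identical(compute_lcr("g1", g),
                   list(rank = "Genus", taxon = "Fusarium"))
  expect_identical(compute_lcr(c("g4", "g5"), g),
                   list(rank = "ROOT", taxon = "ROOT"))
  # missing ranks are non-informative, not agreement-breaking
  expect_identical(compute_lcr(c("g1", "g2", "g3"), g),
                   list(rank = "Phylum", taxon = "Ascomycota"))
  expect_error(compute_lcr("nope", g), "unknown genome")
})

test_that("LCR equals the brute-force oracle on all small clusters", {
  g <- toy_genomes()
  ids <- g$genome_id
  for (k in 1:6) {
    combos <- utils::combn(ids, k)
    for (j in seq_len(ncol(combos))) {
      mem <- combos[, j]
      expect_identical(compute_lcr(mem, g), lcr_oracle(mem, g),
                       info = paste(mem, collapse = ","))
    }
  }
})

test_that("conservation by rank is cumulative and monotone", {
  # cumulative rule: percent at rank r counts clusters whose LCR is at
  # r or deeper, so {Genus, Phylum, ROOT, Class} gives 3/4 down to Class
  got <- conservation_by_rank(c("Genus", "Phylum", "ROOT", "Class"))
  expect_identical(unname(got),
                   c(75, 75, 50, 25, 25, 25))
  expect_identical(unname(conservation_by_rank(rep("Genus", 5L))),
                   rep(100, 6L))
  expect_identical(unname(conservation_by_rank(rep("ROOT", 4L))),
                   rep(0, 6L))
  expect_length(conservation_by_rank(character(0)), 0L)
  set.seed(14)
  for (i in 1:20) {
    ranks <- sample(c("ROOT", CA_RANKS), 15L, replace = TRUE)
    v <- conservation_by_rank(ranks)
    expect_true(all(diff(v) <= 0))
  }
})

test_that("presence census reproduces ratio arithmetic", {
  # 1250 of 1269 fungal genomes -> 98.5%
  expect_identical(ratio_pct(1250, 1269), 98.5)
  g <- data.frame(genome_id = sprintf("g%d", 1:10),
                  group = rep(c("Fungi", "Bacteria"), each = 5L),
                  cultured = rep(c(TRUE, FALSE), 5L),
                  Superkingdom = NA, Phylum = NA, Class = NA,
                  Order = NA, Family = NA, Genus = NA,
                  stringsAsFactors = FALSE)
  r <- protein_records(c("s1", "s2", "s3"), c("g1", "g2", "g6"),
                       c("beta", "beta", "gamma"),
                       c("MKL", "MKL", "MKL"))
  cen <- genome_presence_census(r, g)
  fungi_all <- cen[cen$group == "Fungi" & cen$ca_class == "all", ]
  expect_identical(fungi_all$n_with_ca, 2L)
  expect_identical(fungi_all$pct_with_ca, 40)
  none <- genome_presence_census(r[0L, ], g)
  pop <- none[none$n_genomes > 0L, ]
  expect_true(all(pop$pct_with_ca == 0))
  expect_true(all(is.na(none$pct_with_ca[none$n_genomes == 0L])))
  cult <- genome_presence_census(r, g, cultured_only = TRUE)
  expect_identical(cult[cult$group == "all" & cult$ca_class == "all",
                        "n_genomes"], 5L)
})

test_that("synthetic presence percentages match generator ground truth", {
  cfg <- sim_config(seed = 51L)
  g <- simulate_genomes(cfg)
  s <- simulate_sequences(g, cfg)
  cen <- genome_presence_census(s$proteins, g$genomes)
  ct <- g$copy_table
  with_ca <- unique(ct$genome_id[ct$n_copies > 0L])
  for (grp in CA_GROUPS) {
    gids <- g$genomes$genome_id[g$genomes$group == grp]
    expected <- ratio_pct(sum(gids %in% with_ca), length(gids))
    got <- cen$pct_with_ca[cen$group == grp & cen$ca_class == "all"]
    expect_identical(got, expected, info = grp)
  }
})

test_that("copy statistics cover carriers only, with sample SD", {
  g <- toy_genomes()
  r <- protein_records(sprintf("s%d", 1:6),
                       c("g1", "g2", "g2", "g2", "g2", "g4"),
                       rep("beta", 6L), rep("MKL", 6L))
  cs <- copy_number_stats(r, g)
  beta_all <- cs$stats[cs$stats$group == "all" &
                         cs$stats$ca_class == "beta", ]
  # carriers: g1 = 1, g2 = 4, g4 = 1
  expect_identical(beta_all$copy_mean, 2)
  expect_identical(beta_all$copy_min, 1L)
  expect_identical(beta_all$copy_max, 4L)
  expect_equal(beta_all$copy_sd, sd(c(1, 4, 1)))
  single <- cs$stats[cs$stats$group == "Bacteria" &
                       cs$stats$ca_class == "beta", ]
  expect_identical(single$copy_sd, 0)
  expect_true(single$single_genome)
})

test_that("synthetic copy means recover the configured rate", {
  cfg <- sim_config(seed = 61L,
                    n_genomes_per_group = c(Bacteria = 0L, Archaea = 0L,
                                            Fungi = 120L, Algae = 0L),
                    zero_ca_fraction = c(Bacteria = 0, Archaea = 0,
                                         Fungi = 0, Algae = 0))
  g <- simulate_genomes(cfg)
  s <- simulate_sequences(g, cfg)
  cs <- copy_number_stats(s$proteins, g$genomes)
  got <- cs$stats[cs$stats$group == "Fungi" & cs$stats$ca_class == "gamma", ]
  rate <- cfg$copy_rate["Fungi", "gamma"]
  se <- sqrt(rate / got$n_carriers)
  expect_lt(abs(got$copy_mean - rate), 3 * se)
})

test_that("class combinations partition each group's genomes", {
  g <- toy_genomes()
  r <- protein_records(sprintf("s%d", 1:3), c("g1", "g1", "g5"),
                       c("beta", "gamma", "gamma"), rep("MKL", 3L))
  cc <- class_combinations(r, g)
  fungi <- cc[cc$group == "Fungi", ]
  expect_identical(fungi$n_genomes[fungi$combination == "beta+gamma"], 1L)
  expect_identical(fungi$n_genomes[fungi$combination == "none"], 3L)
  expect_identical(sum(fungi$n_genomes), 4L)
  arch <- cc[cc$group == "Archaea", ]
  expect_identical(arch$n_genomes[arch$combination == "gamma"], 1L)
  expect_identical(sum(cc$n_genomes), nrow(g))
})

test_that("archaea generated without alpha stay out of alpha cells", {
  cfg <- sim_config(seed = 71L)  # default alpha rate for Archaea is 0
  g <- simulate_genomes(cfg)
  s <- simulate_sequences(g, cfg)
  cc <- class_combinations(s$proteins, g$genomes)
  arch <- cc[cc$group == "Archaea", ]
  alpha_cells <- grepl("alpha", arch$combination)
  expect_true(all(arch$n_genomes[alpha_cells] == 0L))
})
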