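toy_datasets <- function() {
  data.frame(dataset_id = sprintf("d%d", 1:6),
             environment = rep(c("terrestrial:soil", "aquatic/marine",
                                 "air"), each = 2L),
             datatype = "metagenome",
             study_id = sprintf("st%d", 1:6),
             stringsAsFactors = FALSE)
}

toy_hits <- function() {
  data.frame(dataset_id = c("d1", "d1", "d2", "d3", "d5"),
             orf_id = sprintf("o%d", 1:5),
             profile_id = c("p1", "p1", "p1", "p2", "p2"),
             score = 60, stringsAsFactors = FALSE)
}

test_that("hit counting fills the environment-by-profile matrix", {
  cm <- count_hits(toy_hits(), toy_datasets())
  expect_identical(cm$by_profile["terrestrial:soil", "p1"], 3L)
  expect_identical(cm$by_profile["aquatic/marine", "p2"], 1L)
  expect_identical(sum(cm$by_profile), nrow(toy_hits()))
  bad <- toy_hits(); bad$dataset_id[1L] <- "zzz"
  expect_error(count_hits(bad, toy_datasets()), "zzz")
})

test_that("rollups conserve the grand total", {
  roll <- c(p1 = "beta", p2 = "gamma")
  cm <- count_hits(toy_hits(), toy_datasets(), rollup = roll)
  expect_identical(sum(cm$by_group), sum(cm$by_profile))
  expect_identical(cm$by_group[, "beta"],
                   cm$by_profile[, "p1"])
  expect_error(count_hits(toy_hits(), toy_datasets(),
                          rollup = c(p1 = "beta")), "p2")
})

test_that("a soil-exclusive cluster only accrues soil hits", {
  cfg <- sim_config(seed = 81L,
                    n_genomes_per_group = c(Bacteria = 20L, Archaea = 0L,
                                            Fungi = 10L, Algae = 0L),
                    n_datasets_per_environment = c(
                      "terrestrial:soil" = 2L, "aquatic/marine" = 2L),
                    orfs_per_dataset = 30L)
  s <- simulate_sequences(simulate_genomes(cfg), cfg)
  anc <- unique(s$truth$true_cluster_of)[1L]
  m <- simulate_metagenomes(s, cfg, env_of_ancestor =
                              stats::setNames("terrestrial:soil", anc))
  src <- stats::setNames(s$truth$true_cluster_of[m$truth$orf_source],
                         names(m$truth$orf_source))
  hits <- data.frame(
    dataset_id = sub("\\|.*$", "", names(src)),
    orf_id = names(src), profile_id = unname(src), score = 100,
    stringsAsFactors = FALSE)
  cm <- count_hits(hits, m$datasets)
  soil_col <- cm$by_profile[, anc]
  nonsoil <- setdiff(rownames(cm$by_profile), "terrestrial:soil")
  expect_true(all(soil_col[nonsoil] == 0L))
  expect_gt(soil_col[["terrestrial:soil"]], 0L)
})

test_that("abundance scaling follows the printed formula", {
  z <- normalize_abundance(0, 0.5, 10)
  expect_identical(z$transformed, -5)
  v <- normalize_abundance(10, 0.25, 50)
  expect_equal(v$scaled, 0.8)
  expect_equal(v$transformed, log10(0.8 + 1e-5))
  # linear in hits before the log
  expect_equal(normalize_abundance(20, 0.25, 50)$scaled, 2 * v$scaled)
  # monotone in hits, antitone in group size
  expect_gt(normalize_abundance(11, 0.25, 50)$transformed, v$transformed)
  expect_lt(normalize_abundance(10, 0.25, 60)$transformed, v$transformed)
  expect_error(normalize_abundance(1, 0, 10), "env_study_fraction")
  expect_error(normalize_abundance(1, 0.5, 0), "no genomes")
})

test_that("per-environment fractions sum to one where hits exist", {
  m <- matrix(c(6L, 3L, 1L, 0L, 0L, 0L), nrow = 2L, byrow = TRUE,
              dimnames = list(c("terrestrial:soil", "air"),
                              c("gamma", "beta", "alpha")))
  fr <- class_fraction_by_environment(m)
  soil <- fr[fr$environment == "terrestrial:soil", ]
  expect_equal(soil$fraction, c(0.6, 0.3, 0.1))
  air <- fr[fr$environment == "air", ]
  expect_true(all(air$no_hits))
  expect_identical(sum(air$fraction), 0)
})

test_that("specificity intersections partition the selected union", {
  m <- matrix(0L, nrow = 3L, ncol = 4L,
              dimnames = list(c("terrestrial:soil", "aquatic/marine", "air"),
                              sprintf("p%d", 1:4)))
  m["terrestrial:soil", "p1"] <- 5L               # soil only
  m["terrestrial:soil", "p2"] <- 3L
  m["aquatic/marine", "p2"] <- 2L                 # soil & aquatic
  m["aquatic/marine", "p3"] <- 4L                 # aquatic only
  m["air", "p4"] <- 1L                            # air only
  sp <- environment_specificity(m, top_n = 10L)
  expect_identical(sum(sp$intersections$n_profiles),
                   nrow(sp$selected))
  mem <- stats::setNames(sp$selected$membership, sp$selected$profile_id)
  expect_identical(mem[["p1"]], "terrestrial:soil")
  expect_identical(mem[["p2"]], "terrestrial:soil&aquatic/marine")
  expect_identical(mem[["p4"]], "air")
})

test_that("specificity is invariant to dataset/profile ordering", {
  set.seed(15)
  m <- matrix(rpois(21L, 2), nrow = 3L,
              dimnames = list(c("air", "terrestrial:soil", "aquatic/marine"),
                              sprintf("p%d", 1:7)))
  a <- environment_specificity(m, top_n = 2L)
  perm <- m[sample(3L), sample(7L)]
  b <- environment_specificity(perm, top_n = 2L)
  expect_identical(a$selected[order(a$selected$profile_id), ],
                   b$selected[order(b$selected$profile_id), ],
                   ignore_attr = TRUE)
})

test_that("coverage summary reports the documented percentages", {
  ds <- toy_datasets()
  hits <- data.frame(dataset_id = c("d1", "d2"), orf_id = c("o1", "o2"),
                     profile_id = c("p1", "p2"), score = 60,
                     stringsAsFactors = FALSE)
  profs <- sprintf("p%d", 1:20)
  hits17 <- data.frame(dataset_id = "d1", orf_id = sprintf("o%d", 1:17),
                       profile_id = sprintf("p%d", 1:17), score = 60,
                       stringsAsFactors = FALSE)
  cov <- coverage_summary(hits17, profs, ds)
  expect_identical(cov$pct_profiles_with_hit, 85)
  cov2 <- coverage_summary(hits, c("p1", "p2"), ds)
  expect_identical(cov2$pct_profiles_with_hit, 100)
})

test_that("size-independent hits give near-zero rank correlation", {
  set.seed(16)
  profs <- sprintf("p%03d", 1:200)
  sizes <- stats::setNames(sample(3:50, 200L, TRUE), profs)
  hits <- data.frame(dataset_id = "d1",
                     orf_id = sprintf("o%d", 1:2000),
                     profile_id = sample(profs, 2000L, TRUE),
                     score = 60, stringsAsFactors = FALSE)
  ds <- data.frame(dataset_id = "d1", environment = "air",
                   datatype = "metagenome", study_id = "s1",
                   stringsAsFactors = FALSE)
  cov <- coverage_summary(hits, profs, ds, sizes)
  expect_lt(abs(cov$size_hit_correlation), 0.2)
})
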