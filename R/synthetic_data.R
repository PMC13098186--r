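# Synthetic study generator. Emulates, at desk scale, the structure of a
# large public-genome CA survey: four organism groups with group- and
# class-specific copy-number behaviour, protein families diverged from
# per-cluster ancestors so that within-family identity sits above and
# between-family identity below the clustering threshold, class-specific
# metal-binding residues that are never mutated, nested taxonomies, and
# environment-labelled ORF sets of true CA proteins plus
# composition-preserving decoys.

#' Build and validate a simulation configuration
#'
#' Defaults define the study conditions used throughout the package's
#' tests: group sizes down-sampled from a genomes+MAGs survey while
#' keeping every group large enough to exercise, per-group zero-CA
#' fractions matching the survey's presence percentages, and class copy
#' rates giving fungi/algae CA-rich genomes, gamma-dominated archaea with
#' no alpha, and mostly single-copy bacteria.
#'
#' @param seed Integer seed; fixed seed implies byte-identical outputs.
#' @param n_genomes_per_group Named integer vector over
#'   Bacteria/Archaea/Fungi/Algae.
#' @param zero_ca_fraction Named numeric vector: per-group probability
#'   that a genome carries no CA at all.
#' @param copy_rate Numeric matrix (groups x classes): mean CA copies per
#'   CA-capable genome, Poisson-distributed per class.
#' @param cultured_fraction Named numeric vector: per-group probability a
#'   genome derives from a cultured organism rather than a MAG.
#' @param n_ancestors_per_class Ancestral (true-cluster) sequences per
#'   CA class.
#' @param within_divergence Fraction of non-motif positions mutated in
#'   each descendant of an ancestor (0-1).
#' @param between_divergence Fraction of non-motif positions mutated
#'   between ancestors of a class (0-1); must exceed `within_divergence`.
#' @param seq_length Ancestor length in residues.
#' @param lineage_depth_profile Named integer vector (Phylum..Genus):
#'   number of child taxa per parent taxon at each rank.
#' @param missing_rank_fraction Probability an assigned rank cell is
#'   blanked to missing.
#' @param n_datasets_per_environment Named integer vector over the seven
#'   environment categories.
#' @param orfs_per_dataset ORFs per simulated dataset.
#' @param decoy_fraction Fraction of each dataset's ORFs that are
#'   residue-shuffled decoys (0-1).
#' @param truncate_fraction Fraction of true CA ORFs emitted truncated.
#' @param truncate_keep Fraction of residues kept when truncating.
#' @param env_exclusive_fraction Fraction of ancestors restricted to a
#'   single (randomly chosen) environment.
#' @param conservation_depth_weights Named weights over `ROOT` and the
#'   six ranks: the distribution from which each ancestor's taxonomic
#'   restriction depth is drawn. An ancestor restricted at rank r only
#'   acquires members inside one taxon at r, so cluster lowest common
#'   ranks are at least that deep; the default gives a survey-like
#'   declining conservation gradient. The first ancestor of each class
#'   is always unrestricted so every genome has an eligible ancestor.
#' @param motifs Named list per class of `list(positions=, residues=)`:
#'   metal-binding residues held invariant by the mutation process.
#' @param indels If `TRUE`, descendants additionally receive short indels
#'   (exercises alignment code; identity is no longer analytically
#'   predictable).
#' @return A validated list of class `ca_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genomes_per_group = c(Bacteria = 120L, Archaea = 24L,
                                               Fungi = 40L, Algae = 16L),
                       zero_ca_fraction = c(Bacteria = 0.31, Archaea = 0.52,
                                            Fungi = 0.015, Algae = 0.69),
                       copy_rate = NULL,
                       cultured_fraction = c(Bacteria = 0.65, Archaea = 0.39,
                                             Fungi = 1.0, Algae = 1.0),
                       n_ancestors_per_class = 6L,
                       within_divergence = 0.10,
                       between_divergence = 0.80,
                       seq_length = 180L,
                       lineage_depth_profile = c(Phylum = 3L, Class = 2L,
                                                 Order = 2L, Family = 2L,
                                                 Genus = 2L),
                       missing_rank_fraction = 0.05,
                       n_datasets_per_environment = stats::setNames(
                         rep(3L, length(CA_ENVIRONMENTS)), CA_ENVIRONMENTS),
                       orfs_per_dataset = 60L,
                       decoy_fraction = 0.5,
                       truncate_fraction = 0.1,
                       truncate_keep = 0.6,
                       env_exclusive_fraction = 0,
                       conservation_depth_weights = c(
                         ROOT = 0.05, Superkingdom = 0.17, Phylum = 0.18,
                         Class = 0.11, Order = 0.12, Family = 0.12,
                         Genus = 0.25),
                       motifs = default_motifs(),
                       indels = FALSE) {
  if (is.null(copy_rate)) {
    copy_rate <- rbind(Bacteria = c(alpha = 0.2, beta = 1.0, gamma = 1.0),
                       Archaea  = c(alpha = 0.0, beta = 0.5, gamma = 1.2),
                       Fungi    = c(alpha = 1.0, beta = 3.1, gamma = 6.2),
                       Algae    = c(alpha = 3.6, beta = 3.3, gamma = 9.3))
  }
  cfg <- list(seed = as.integer(seed),
              n_genomes_per_group = n_genomes_per_group,
              zero_ca_fraction = zero_ca_fraction,
              copy_rate = copy_rate,
              cultured_fraction = cultured_fraction,
              n_ancestors_per_class = as.integer(n_ancestors_per_class),
              within_divergence = within_divergence,
              between_divergence = between_divergence,
              seq_length = as.integer(seq_length),
              lineage_depth_profile = lineage_depth_profile,
              missing_rank_fraction = missing_rank_fraction,
              n_datasets_per_environment = n_datasets_per_environment,
              orfs_per_dataset = as.integer(orfs_per_dataset),
              decoy_fraction = decoy_fraction,
              truncate_fraction = truncate_fraction,
              truncate_keep = truncate_keep,
              env_exclusive_fraction = env_exclusive_fraction,
              conservation_depth_weights = conservation_depth_weights,
              motifs = motifs,
              indels = isTRUE(indels))
  class(cfg) <- "ca_sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param cfg A `ca_sim_config` list.
#' @return `cfg`, invisibly; errors name the offending field.
#' @export
validate_sim_config <- function(cfg) {
  chk_named <- function(x, names_need, field) {
    if (!all(names_need %in% names(x)))
      stop("field ", field, " must be named over: ",
           paste(names_need, collapse = ", "))
    if (any(is.na(x)) || any(x < 0))
      stop("field ", field, " must be nonnegative")
  }
  chk_named(cfg$n_genomes_per_group, CA_GROUPS, "n_genomes_per_group")
  chk_named(cfg$zero_ca_fraction, CA_GROUPS, "zero_ca_fraction")
  chk_named(cfg$cultured_fraction, CA_GROUPS, "cultured_fraction")
  if (any(cfg$zero_ca_fraction > 1)) stop("field zero_ca_fraction must be in [0,1]")
  if (!is.matrix(cfg$copy_rate) ||
      !all(CA_GROUPS %in% rownames(cfg$copy_rate)) ||
      !all(CA_CLASSES %in% colnames(cfg$copy_rate)))
    stop("field copy_rate must be a groups x classes matrix")
  if (any(cfg$copy_rate < 0)) stop("field copy_rate must be nonnegative")
  if (cfg$n_ancestors_per_class < 1) stop("field n_ancestors_per_class must be >= 1")
  if (cfg$within_divergence < 0 || cfg$within_divergence > 1)
    stop("field within_divergence must be in [0,1]")
  if (cfg$between_divergence < 0 || cfg$between_divergence > 1)
    stop("field between_divergence must be in [0,1]")
  if (cfg$within_divergence >= cfg$between_divergence)
    stop("field within_divergence must be < between_divergence")
  if (cfg$seq_length < 1) stop("field seq_length must be positive")
  for (cls in names(cfg$motifs)) {
    pos <- cfg$motifs[[cls]]$positions
    if (any(pos > cfg$seq_length))
      stop("field seq_length too short to contain motif positions for class ", cls)
  }
  if (cfg$decoy_fraction < 0 || cfg$decoy_fraction > 1)
    stop("field decoy_fraction must be in [0,1]")
  w <- cfg$conservation_depth_weights
  if (!all(c("ROOT", CA_RANKS) %in% names(w)) || any(w < 0) || sum(w) <= 0)
    stop("field conservation_depth_weights must be nonnegative weights over ",
         "ROOT and all six ranks")
  if (length(cfg$n_datasets_per_environment) < 1)
    stop("field n_datasets_per_environment: at least one environment required")
  if (any(cfg$n_datasets_per_environment < 0))
    stop("field n_datasets_per_environment must be nonnegative")
  invisible(cfg)
}

#' Read a simulation configuration from a YAML file
#'
#' Accepts the flat-key YAML written by [run_ca_pipeline()] (or written
#' by hand); unnamed fields fall back to the [sim_config()] defaults.
#'
#' @param path Path to a YAML file.
#' @return A validated `ca_sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0L)
    stop("unknown config field(s): ", paste(extra, collapse = ", "))
  to_named <- function(x) if (is.list(x)) unlist(x) else x
  for (f in c("n_genomes_per_group", "zero_ca_fraction",
              "cultured_fraction", "lineage_depth_profile",
              "n_datasets_per_environment", "conservation_depth_weights"))
    if (!is.null(raw[[f]])) raw[[f]] <- to_named(raw[[f]])
  if (!is.null(raw$copy_rate)) {
    cr <- do.call(cbind, lapply(raw$copy_rate, unlist))
    raw$copy_rate <- cr[CA_GROUPS, , drop = FALSE]
  }
  if (!is.null(raw$motifs))
    raw$motifs <- lapply(raw$motifs, function(m)
      list(positions = as.integer(unlist(m$positions)),
           residues = as.character(unlist(m$residues))))
  do.call(sim_config, raw)
}

#' Default metal-binding motif positions per CA class
#'
#' Positions are coordinates in the ungapped ancestor sequence. The
#' residue sets mirror the canonical zinc-coordination chemistry of each
#' class: three histidines for the alpha and gamma classes, a
#' cysteine-histidine-cysteine triad for the beta class.
#'
#' @param seq_length Unused; kept for symmetry with [sim_config()].
#' @return Named list per class with `positions` and `residues`.
#' @export
default_motifs <- function(seq_length = 180L) {
  list(alpha = list(positions = c(40L, 60L, 80L), residues = c("H", "H", "H")),
       beta  = list(positions = c(30L, 50L, 90L), residues = c("C", "H", "C")),
       gamma = list(positions = c(35L, 55L, 75L), residues = c("H", "H", "H")))
}

.random_protein <- function(n, alphabet = CA_ALPHABET) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# substitute a `divergence` fraction of positions, never touching `keep`
.mutate_seq <- function(seq, divergence, keep = integer(0)) {
  v <- strsplit(seq, "")[[1]]
  free <- setdiff(seq_along(v), keep)
  n_mut <- rbinom(1L, length(free), divergence)
  if (n_mut > 0L) {
    at <- sample(free, n_mut)
    v[at] <- vapply(v[at], function(r) sample(setdiff(CA_ALPHABET, r), 1L), "")
  }
  paste(v, collapse = "")
}

.apply_indels <- function(seq, n_events = 1L, max_len = 3L) {
  v <- strsplit(seq, "")[[1]]
  for (i in seq_len(n_events)) {
    len <- sample(max_len, 1L)
    if (runif(1) < 0.5 && length(v) > len + 1L) {
      at <- sample(length(v) - len, 1L)
      v <- v[-(at:(at + len - 1L))]
    } else {
      at <- sample(length(v), 1L)
      v <- append(v, sample(CA_ALPHABET, len, replace = TRUE), after = at)
    }
  }
  paste(v, collapse = "")
}

# nested taxonomy: each rank partitions the one above; taxon names are
# path-encoded, so equality at a rank implies equality at all shallower
# ranks
.make_lineage_pool <- function(group, profile) {
  sk <- switch(group, Bacteria = "Bacteria", Archaea = "Archaea",
               Fungi = "Eukaryota", Algae = "Eukaryota")
  pool <- list()
  ranks <- names(profile)
  expand <- function(prefix, parent_name, depth) {
    if (depth > length(ranks)) {
      pool[[length(pool) + 1L]] <<- prefix
      return(invisible())
    }
    r <- ranks[depth]
    for (i in seq_len(profile[[r]])) {
      nm <- paste0(parent_name, "_", tolower(substr(r, 1L, 1L)), i)
      expand(c(prefix, stats::setNames(nm, r)), nm, depth + 1L)
    }
  }
  expand(character(0), substr(group, 1L, 4L), 1L)
  lapply(pool, function(p) c(Superkingdom = sk, p))
}

#' Simulate genomes with group-specific CA copy numbers
#'
#' Each genome is CA-capable with probability `1 - zero_ca_fraction` for
#' its group; capable genomes draw per-class copy counts from Poisson
#' distributions with the configured group-by-class means (a
#' zero-inflated Poisson overall). Lineages are drawn from a nested
#' taxonomy in which each rank partitions the one above.
#'
#' @param config A [sim_config()] object.
#' @return A list with `genomes` (taxonomy data.frame), `copy_table`
#'   (genome_id, ca_class, n_copies for capable genomes), and `truth`
#'   (per-genome capability flags).
#' @export
simulate_genomes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  rows <- list(); copies <- list()
  for (g in CA_GROUPS) {
    n <- config$n_genomes_per_group[[g]]
    if (n == 0L) next
    lineages <- .make_lineage_pool(g, config$lineage_depth_profile)
    for (i in seq_len(n)) {
      gid <- sprintf("%s_g%04d", tolower(g), i)
      lin <- lineages[[sample(length(lineages), 1L)]]
      blank <- names(lin)[-1][runif(length(lin) - 1L) < config$missing_rank_fraction]
      lin[blank] <- NA_character_
      capable <- runif(1) >= config$zero_ca_fraction[[g]]
      cultured <- runif(1) < config$cultured_fraction[[g]]
      cc <- if (capable) {
        stats::setNames(rpois(length(CA_CLASSES),
                              config$copy_rate[g, CA_CLASSES]), CA_CLASSES)
      } else stats::setNames(rep(0L, length(CA_CLASSES)), CA_CLASSES)
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = gid, group = g, cultured = cultured,
        capable = capable, t(lin), stringsAsFactors = FALSE)
      copies[[length(copies) + 1L]] <- data.frame(
        genome_id = gid, ca_class = CA_CLASSES, n_copies = as.integer(cc),
        stringsAsFactors = FALSE)
    }
  }
  genomes <- do.call(rbind, rows)
  truth <- list(ca_capable = stats::setNames(genomes$capable, genomes$genome_id))
  genomes$capable <- NULL
  list(genomes = genomes,
       copy_table = do.call(rbind, copies),
       truth = truth)
}

#' Simulate CA protein sequences descending from per-cluster ancestors
#'
#' Ancestors of a class are generated by mutating a class base sequence
#' at `between_divergence` of non-motif positions; each genome copy is a
#' descendant mutated at `within_divergence` of non-motif positions.
#' Metal-binding motif residues are never mutated. Substitution-only by
#' default, so pairwise identities are analytically predictable.
#'
#' @param genomes_sim Output of [simulate_genomes()].
#' @param config A [sim_config()] object.
#' @return A list with `proteins` (a [protein_records()] data.frame),
#'   `ancestors` (named list per class of ancestor sequences), and
#'   `truth` (`true_cluster_of`, `true_lcr_of`).
#' @export
simulate_sequences <- function(genomes_sim, config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  L <- config$seq_length
  ancestors <- list()
  for (cls in CA_CLASSES) {
    motif <- config$motifs[[cls]]
    base <- strsplit(.random_protein(L), "")[[1]]
    base[motif$positions] <- motif$residues
    base <- paste(base, collapse = "")
    anc <- stats::setNames(vapply(seq_len(config$n_ancestors_per_class),
      function(i) .mutate_seq(base, config$between_divergence,
                              keep = motif$positions), ""),
      sprintf("%s_anc%02d", cls, seq_len(config$n_ancestors_per_class)))
    ancestors[[cls]] <- anc
  }
  # designate a taxonomic restriction per ancestor (conservation control);
  # the first ancestor of each class stays unrestricted
  genomes <- genomes_sim$genomes
  w <- config$conservation_depth_weights[c("ROOT", CA_RANKS)]
  anchors <- list()
  for (cls in CA_CLASSES) {
    for (a in seq_along(ancestors[[cls]])) {
      aid <- names(ancestors[[cls]])[a]
      r <- if (a == 1L) "ROOT" else sample(names(w), 1L, prob = w)
      taxon <- NA_character_
      if (r != "ROOT") {
        pool <- genomes[[r]][!is.na(genomes[[r]])]
        if (length(pool) == 0L) r <- "ROOT" else taxon <- sample(pool, 1L)
      }
      anchors[[aid]] <- list(rank = r, taxon = taxon)
    }
  }
  ct <- genomes_sim$copy_table
  ct <- ct[ct$n_copies > 0L, , drop = FALSE]
  recs <- vector("list", sum(ct$n_copies))
  true_cluster <- character(0)
  k <- 0L
  gidx <- match(ct$genome_id, genomes$genome_id)
  for (i in seq_len(nrow(ct))) {
    cls <- ct$ca_class[i]
    motif <- config$motifs[[cls]]
    aids <- names(ancestors[[cls]])
    lin <- genomes[gidx[i], ]
    eligible <- aids[vapply(aids, function(a) {
      an <- anchors[[a]]
      an$rank == "ROOT" ||
        (!is.na(lin[[an$rank]]) && lin[[an$rank]] == an$taxon)
    }, TRUE)]
    if (length(eligible) == 0L) eligible <- aids[1L]
    for (j in seq_len(ct$n_copies[i])) {
      k <- k + 1L
      anc_id <- eligible[sample.int(length(eligible), 1L)]
      s <- .mutate_seq(ancestors[[cls]][[anc_id]], config$within_divergence,
                       keep = motif$positions)
      if (config$indels) s <- .apply_indels(s)
      sid <- sprintf("%s|%s|c%03d", ct$genome_id[i], cls, k)
      recs[[k]] <- data.frame(sequence_id = sid, genome_id = ct$genome_id[i],
                              ca_class = cls, sequence = s,
                              stringsAsFactors = FALSE)
      true_cluster[sid] <- anc_id
    }
  }
  proteins <- if (k > 0L) {
    df <- do.call(rbind, recs[seq_len(k)])
    protein_records(df$sequence_id, df$genome_id, df$ca_class, df$sequence)
  } else {
    protein_records(character(0), character(0), character(0), character(0))
  }
  true_lcr <- .truth_lcr(true_cluster, proteins, genomes_sim$genomes)
  list(proteins = proteins, ancestors = ancestors,
       truth = list(true_cluster_of = true_cluster, true_lcr_of = true_lcr,
                    ancestor_anchor = anchors))
}

# ground-truth LCR per ancestor, by direct rank walk over member lineages
.truth_lcr <- function(true_cluster, proteins, genomes) {
  lin <- genomes[match(proteins$genome_id, genomes$genome_id),
                 c("Superkingdom", CA_RANKS[-1])]
  out <- list()
  for (anc in unique(true_cluster)) {
    members <- names(true_cluster)[true_cluster == anc]
    sub <- lin[proteins$sequence_id %in% members, , drop = FALSE]
    res <- c(rank = "ROOT", taxon = "ROOT")
    for (r in CA_RANKS) {
      vals <- unique(sub[[r]][!is.na(sub[[r]])])
      if (length(vals) == 1L) res <- c(rank = r, taxon = vals)
      else if (length(vals) > 1L) break
    }
    out[[anc]] <- res
  }
  out
}

#' Simulate environment-labelled metagenome ORF sets
#'
#' Each dataset receives true CA ORFs (sampled, possibly truncated
#' descendants) and decoy ORFs (residue-shuffled true sequences, so
#' composition is preserved and only position-specific signal
#' discriminates). A configurable fraction of ancestors can be made
#' exclusive to one environment.
#'
#' @param sequences_sim Output of [simulate_sequences()].
#' @param config A [sim_config()] object.
#' @param env_of_ancestor Optional named character vector restricting
#'   specific ancestors to specific environments (overrides the random
#'   exclusivity draw).
#' @return A list with `datasets` (data.frame), `orfs` (named list:
#'   dataset_id to named sequence vector), and `truth` (`true_env_of`,
#'   `true_ca_orfs`, `orf_source`, `env_of_ancestor`).
#' @export
simulate_metagenomes <- function(sequences_sim, config, env_of_ancestor = NULL) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  proteins <- sequences_sim$proteins
  if (nrow(proteins) == 0L) stop("no CA proteins to sample ORFs from")
  true_cluster <- sequences_sim$truth$true_cluster_of
  envs <- names(config$n_datasets_per_environment)
  if (is.null(env_of_ancestor)) {
    anc_ids <- unique(true_cluster)
    n_excl <- round(config$env_exclusive_fraction * length(anc_ids))
    env_of_ancestor <- stats::setNames(rep(NA_character_, length(anc_ids)), anc_ids)
    if (n_excl > 0L)
      env_of_ancestor[sample(anc_ids, n_excl)] <- sample(envs, n_excl, TRUE)
  }
  ds_rows <- list(); orfs <- list()
  true_env <- character(0); true_ca <- character(0); src <- character(0)
  d <- 0L
  for (e in envs) {
    for (i in seq_len(config$n_datasets_per_environment[[e]])) {
      d <- d + 1L
      did <- sprintf("ds%03d", d)
      ds_rows[[d]] <- data.frame(
        dataset_id = did, environment = e,
        datatype = if (runif(1) < 0.8) "metagenome" else "metatranscriptome",
        study_id = sprintf("study%03d", d), stringsAsFactors = FALSE)
      true_env[did] <- e
      n_decoy <- round(config$orfs_per_dataset * config$decoy_fraction)
      n_true <- config$orfs_per_dataset - n_decoy
      restrict <- env_of_ancestor[true_cluster[proteins$sequence_id]]
      eligible <- proteins$sequence_id[is.na(restrict) | restrict == e]
      seqs <- character(0)
      if (n_true > 0L && length(eligible) > 0L) {
        pick <- sample(eligible, n_true, replace = TRUE)
        s <- proteins$sequence[match(pick, proteins$sequence_id)]
        trunc <- runif(n_true) < config$truncate_fraction
        s[trunc] <- substr(s[trunc], 1L,
                           pmax(10L, floor(nchar(s[trunc]) * config$truncate_keep)))
        ids <- sprintf("%s|orf%04d", did, seq_len(n_true))
        names(s) <- ids
        seqs <- c(seqs, s)
        true_ca <- c(true_ca, ids)
        src[ids] <- pick
      }
      if (n_decoy > 0L) {
        tmpl <- sample(proteins$sequence, n_decoy, replace = TRUE)
        s <- vapply(tmpl, function(x)
          paste(sample(strsplit(x, "")[[1]]), collapse = ""), "")
        ids <- sprintf("%s|orf%04d", did, n_true + seq_len(n_decoy))
        names(s) <- ids
        seqs <- c(seqs, s)
      }
      orfs[[did]] <- seqs
    }
  }
  list(datasets = do.call(rbind, ds_rows), orfs = orfs,
       truth = list(true_env_of = true_env, true_ca_orfs = true_ca,
                    orf_source = src, env_of_ancestor = env_of_ancestor))
}

#' Run the full synthetic-study generator
#'
#' Chains [simulate_genomes()], [simulate_sequences()], and
#' [simulate_metagenomes()]; optionally writes all standard files
#' (per-class protein FASTA, taxonomy TSV, dataset TSV, per-dataset ORF
#' FASTA, ground-truth JSON) to `out_dir`.
#'
#' @param config A [sim_config()] object.
#' @param out_dir Optional output directory.
#' @return A list with `genomes`, `copy_table`, `proteins`, `ancestors`,
#'   `datasets`, `orfs`, and a merged `truth` list.
#' @export
simulate_ca_study <- function(config = sim_config(), out_dir = NULL) {
  g <- simulate_genomes(config)
  s <- simulate_sequences(g, config)
  m <- simulate_metagenomes(s, config)
  truth <- c(g$truth, s$truth, m$truth)
  res <- list(genomes = g$genomes, copy_table = g$copy_table,
              proteins = s$proteins, ancestors = s$ancestors,
              datasets = m$datasets, orfs = m$orfs, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (cls in CA_CLASSES) {
      p <- res$proteins[res$proteins$ca_class == cls, ]
      if (nrow(p) > 0L)
        write_fasta(stats::setNames(p$sequence, p$sequence_id),
                    file.path(out_dir, paste0("proteins_", cls, ".faa")))
    }
    tax <- res$genomes
    names(tax) <- c("genome_id", "group", "cultured", tolower(CA_RANKS))
    write_tsv(tax, file.path(out_dir, "taxonomy.tsv"))
    write_tsv(res$datasets, file.path(out_dir, "datasets.tsv"))
    orf_dir <- file.path(out_dir, "orfs")
    dir.create(orf_dir, showWarnings = FALSE)
    for (did in names(res$orfs))
      write_fasta(res$orfs[[did]], file.path(orf_dir, paste0(did, ".faa")))
    truth_out <- truth
    truth_out$true_lcr_of <- lapply(truth_out$true_lcr_of, as.list)
    write_json(truth_out, file.path(out_dir, "ground_truth.json"))
  }
  res
}
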