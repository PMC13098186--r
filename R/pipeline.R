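# End-to-end orchestration on synthetic data: simulate -> qc -> cluster
# -> census -> profiles -> scan -> environment statistics -> phylogeny.
# Stages communicate only via files under the output directory, so each
# stage is independently replaceable with real data, and a manifest of
# checksums makes determinism checkable.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full census pipeline on synthetic data
#'
#' Generates a synthetic study, filters it, clusters per class, computes
#' the census tables, builds profiles, scans all simulated datasets,
#' computes environment abundance/specificity tables, builds per-class
#' neighbor-joining guide trees of cluster representatives (distance =
#' 1 - identity) and runs the fungal PD contribution test on the
#' combined representative set, then writes a run manifest with MD5
#' checksums of every output.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param min_len,max_len Length-filter bounds.
#' @param threshold Clustering identity threshold.
#' @param min_size Cluster-size cutoff for profiles and conservation.
#' @param min_score Bit-score threshold for retained hits.
#' @param top_n Top-N profiles per environment for the specificity table.
#' @param n_rand Randomizations for the PD test.
#' @return The run manifest (list), invisibly; all outputs are files
#'   under `out_dir`.
#' @export
run_ca_pipeline <- function(config = sim_config(), out_dir,
                            min_len = 100L, max_len = 1000L,
                            threshold = 0.5, min_size = 3L,
                            min_score = 50, top_n = 10L, n_rand = 199L) {
  if (threshold <= 0 || threshold > 1)
    stop("invalid config: clustering threshold must be in (0, 1]")
  validate_sim_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_line <- function(...) message("[ca-census] ", ...)

  sim <- .stage("simulate", simulate_ca_study(config, out_dir))
  log_line("simulate: ", nrow(sim$genomes), " genomes, ",
           nrow(sim$proteins), " proteins, ", nrow(sim$datasets),
           " datasets")

  qc <- .stage("qc", filter_by_length(sim$proteins, min_len, max_len))
  write_tsv(qc$report, file.path(out_dir, "qc_report.tsv"))
  log_line("qc: ", nrow(qc$kept), " kept / ", nrow(qc$removed), " removed")

  clusters <- .stage("cluster", cluster_by_class(qc$kept, threshold))
  write_tsv(clusters, file.path(out_dir, "clusters.tsv"))
  log_line("cluster: ", length(unique(clusters$cluster_id)), " clusters")

  cen <- .stage("census", census_table(qc$kept, clusters, sim$genomes,
                                       min_size))
  census_dir <- file.path(out_dir, "census")
  dir.create(census_dir, showWarnings = FALSE)
  write_tsv(cen$lcr, file.path(census_dir, "lcr.tsv"))
  write_tsv(cen$conservation, file.path(census_dir, "conservation.tsv"))
  write_tsv(cen$presence, file.path(census_dir, "presence.tsv"))
  write_tsv(cen$presence_cultured,
            file.path(census_dir, "presence_cultured.tsv"))
  write_tsv(cen$copy_stats, file.path(census_dir, "copies.tsv"))
  write_tsv(class_combinations(qc$kept, sim$genomes),
            file.path(census_dir, "class_combinations.tsv"))
  log_line("census: conservation Superkingdom ",
           cen$conservation[1L, "all"], "%")

  profiles <- .stage("profiles",
                     build_profiles(clusters, qc$kept, min_size))
  write_profiles_json(profiles, file.path(out_dir, "profiles.json"))
  log_line("profiles: ", length(profiles), " models")

  scans <- .stage("scan", {
    do.call(rbind, lapply(names(sim$orfs), function(did)
      scan_orfs(profiles, sim$orfs[[did]], did)))
  })
  hits <- assign_best_hits(scans, min_score)
  write_tsv(hits, file.path(out_dir, "hits.tsv"))
  log_line("scan: ", nrow(hits), " retained hits of ", nrow(scans),
           " scored pairs")

  envdir <- file.path(out_dir, "env")
  dir.create(envdir, showWarnings = FALSE)
  env <- .stage("envstats", {
    class_of <- stats::setNames(
      clusters$ca_class[match(names(profiles), clusters$cluster_id)],
      names(profiles))
    counts <- count_hits(hits, sim$datasets, rollup = class_of)
    lcr_group <- stats::setNames(cen$lcr$taxon, cen$lcr$cluster_id)
    tax_sizes <- .lcr_group_sizes(cen$lcr, sim$genomes)
    gcounts <- count_hits(hits, sim$datasets, rollup = lcr_group)
    abt <- abundance_table(gcounts$by_group, sim$datasets, tax_sizes)
    write_tsv(abt, file.path(envdir, "abundance.tsv"))
    write_tsv(class_fraction_by_environment(counts$by_group),
              file.path(envdir, "fractions.tsv"))
    spec <- environment_specificity(counts$by_profile, top_n,
                                    profile_groups = lcr_group)
    write_tsv(spec$intersections, file.path(envdir, "intersections.tsv"))
    sizes <- table(clusters$cluster_id)
    cov <- coverage_summary(hits, names(profiles), sim$datasets,
                            stats::setNames(as.integer(sizes), names(sizes)))
    write_json(cov[c("pct_datasets_with_hit", "pct_profiles_with_hit",
                     "size_hit_correlation")],
               file.path(envdir, "coverage.json"))
    cov
  })
  log_line("envstats: ", env$pct_profiles_with_hit, "% profiles with hits")

  phylo <- .stage("phylo", .representative_pd_stage(
    clusters, qc$kept, sim$genomes, min_size, n_rand, config$seed, out_dir))
  if (!is.null(phylo))
    log_line("phylo: fungal PD contribution p = ", phylo$p_value)

  manifest <- .stage("manifest", {
    cfg_file <- file.path(out_dir, "config.yaml")
    yaml::write_yaml(.config_as_yamlable(config), cfg_file)
    files <- sort(list.files(out_dir, recursive = TRUE, full.names = TRUE))
    files <- files[basename(files) != "manifest.json"]
    sums <- tools::md5sum(files)
    names(sums) <- sub(paste0("^", out_dir, "/?"), "", names(sums))
    m <- list(tool = "cacensus",
              version = as.character(utils::packageVersion("cacensus")),
              seed = config$seed,
              config_md5 = unname(tools::md5sum(cfg_file)),
              timestamp = format(Sys.time(), tz = "UTC"),
              checksums = as.list(sums))
    write_json(m, file.path(out_dir, "manifest.json"))
    m
  })
  invisible(manifest)
}

.config_as_yamlable <- function(config) {
  cfg <- unclass(config)
  cr <- config$copy_rate
  cfg$copy_rate <- lapply(stats::setNames(colnames(cr), colnames(cr)),
                          function(cl)
                            as.list(stats::setNames(cr[, cl], rownames(cr))))
  # yaml drops names on atomic vectors; named maps survive as lists
  for (f in c("n_genomes_per_group", "zero_ca_fraction",
              "cultured_fraction", "lineage_depth_profile",
              "n_datasets_per_environment", "conservation_depth_weights"))
    cfg[[f]] <- as.list(cfg[[f]])
  cfg
}

# genomes per LCR taxon label (Superkingdom fallback "ROOT" -> all)
.lcr_group_sizes <- function(lcr, genomes) {
  labs <- unique(lcr$taxon)
  sizes <- vapply(labs, function(t) {
    if (t == "ROOT") nrow(genomes)
    else max(1L, sum(vapply(CA_RANKS, function(r)
      sum(genomes[[r]] == t, na.rm = TRUE), 0L)))
  }, 0L)
  stats::setNames(sizes, labs)
}

# NJ guide tree over cluster representatives (distance = 1 - identity),
# then PD and the fungal-contribution randomization test
.representative_pd_stage <- function(clusters, records, genomes, min_size,
                                     n_rand, seed, out_dir) {
  sizes <- table(clusters$cluster_id)
  big <- names(sizes)[sizes >= min_size]
  reps <- unique(clusters[clusters$cluster_id %in% big,
                          c("cluster_id", "representative_id")])
  if (nrow(reps) < 4L) return(NULL)
  seqs <- records$sequence[match(reps$representative_id,
                                 records$sequence_id)]
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(reps$cluster_id, reps$cluster_id))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    d[i, j] <- d[j, i] <- 1 - pairwise_identity(seqs[i], seqs[j])
  tree <- ape::nj(stats::as.dist(d))
  tree$edge.length[tree$edge.length < 0] <- 0
  write_newick(tree, file.path(out_dir, "representatives.nwk"))
  fungal_genomes <- genomes$genome_id[genomes$group == "Fungi"]
  has_fungal <- vapply(reps$cluster_id, function(cid) {
    mem <- clusters$member_id[clusters$cluster_id == cid]
    any(records$genome_id[match(mem, records$sequence_id)] %in%
          fungal_genomes)
  }, TRUE)
  focal <- reps$cluster_id[has_fungal]
  if (length(focal) == 0L || length(focal) > n - 2L) return(NULL)
  res <- pd_contribution_test(tree, focal, n_rand = n_rand, seed = seed)
  write_json(res[c("pd_total", "pd_focal", "delta", "p_value",
                   "n_randomizations", "seed")],
             file.path(out_dir, "pd_test.json"))
  res
}
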