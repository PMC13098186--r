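# Lowest-common-rank (LCR) assignment, taxonomic-conservation-by-rank
# statistics, genome presence and copy-number census, and CA-class
# co-occurrence counts.

#' Percentage with a documented rounding rule
#'
#' The package-wide ratio rule for census percentages:
#' `100 * n / total`, rounded to `digits` decimals (default 1).
#'
#' @param n Numerator count.
#' @param total Denominator count.
#' @param digits Decimals to round to.
#' @return The rounded percentage (NA when `total` is 0).
#' @export
ratio_pct <- function(n, total, digits = 1L) {
  ifelse(total > 0, round(100 * n / total, digits), NA_real_)
}

#' Lowest common rank of a cluster
#'
#' Walks the rank ladder from Superkingdom down to Genus, keeping the
#' deepest rank at which all members with a non-missing value agree.
#' Missing values are non-informative: they neither anchor nor break
#' agreement, but at least one member must carry a value for a rank to
#' count. Members spanning multiple Superkingdoms give `ROOT`.
#'
#' @param member_genome_ids Genome ids of the cluster members.
#' @param genomes Taxonomy data.frame (see [read_taxonomy()]).
#' @return A list with `rank` and `taxon` (both `"ROOT"` at the root).
#' @export
compute_lcr <- function(member_genome_ids, genomes) {
  idx <- match(member_genome_ids, genomes$genome_id)
  if (anyNA(idx))
    stop("cluster references unknown genome: ",
         member_genome_ids[is.na(idx)][1L])
  rank <- "ROOT"; taxon <- "ROOT"
  for (r in CA_RANKS) {
    vals <- unique(genomes[[r]][idx])
    vals <- vals[!is.na(vals)]
    if (length(vals) == 1L) { rank <- r; taxon <- vals }
    else if (length(vals) > 1L) break
  }
  list(rank = rank, taxon = taxon)
}

#' LCR assignments for every cluster
#'
#' @param clusters Membership data.frame from [greedy_cluster()].
#' @param records The matching [protein_records()].
#' @param genomes Taxonomy data.frame.
#' @return A data.frame: `cluster_id`, `ca_class`, `size`, `rank`,
#'   `taxon`.
#' @export
compute_lcr_table <- function(clusters, records, genomes) {
  ids <- sort(unique(clusters$cluster_id))
  rows <- lapply(ids, function(cid) {
    mem <- clusters[clusters$cluster_id == cid, ]
    gids <- records$genome_id[match(mem$member_id, records$sequence_id)]
    if (anyNA(gids)) stop("cluster ", cid, " references unknown sequences")
    lcr <- compute_lcr(gids, genomes)
    data.frame(cluster_id = cid, ca_class = mem$ca_class[1L],
               size = nrow(mem), rank = lcr$rank, taxon = lcr$taxon,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Conservation-by-rank percentages
#'
#' Percent of clusters conserved at each rank, where "conserved at rank
#' r" means the LCR is at r or deeper. The result is monotonically
#' non-increasing from Superkingdom to Genus.
#'
#' @param lcr_ranks Character vector of LCR ranks (one per cluster;
#'   `"ROOT"` allowed). Typically restricted to clusters with at least
#'   three members before calling.
#' @param digits Rounding for the percentages.
#' @return Named numeric vector over [CA_RANKS] (empty input gives an
#'   empty vector).
#' @export
conservation_by_rank <- function(lcr_ranks, digits = 1L) {
  n <- length(lcr_ranks)
  if (n == 0L) return(stats::setNames(numeric(0), character(0)))
  depth <- match(lcr_ranks, CA_RANKS, nomatch = 0L) # ROOT -> 0
  out <- vapply(seq_along(CA_RANKS), function(d)
    ratio_pct(sum(depth >= d), n, digits), 0)
  stats::setNames(out, CA_RANKS)
}

# per-genome per-class copy counts implied by a set of protein records
.copy_counts <- function(records, genomes) {
  idx <- match(records$genome_id, genomes$genome_id)
  if (anyNA(idx))
    stop("sequence references unknown genome: ",
         records$genome_id[is.na(idx)][1L])
  out <- expand.grid(genome_id = genomes$genome_id,
                     ca_class = CA_CLASSES,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab <- table(records$genome_id, records$ca_class)
  out$n_copies <- 0L
  hit <- out$genome_id %in% rownames(tab) & out$ca_class %in% colnames(tab)
  out$n_copies[hit] <- as.integer(tab[cbind(out$genome_id[hit],
                                            out$ca_class[hit])])
  out
}

#' Genome presence census per stratum and class
#'
#' Counts and percentages of genomes carrying at least one CA, per
#' organism group (plus `"all"`) and per class (plus `"all"`), for all
#' genomes and optionally for the cultured-only stratum.
#'
#' @param records [protein_records()] after QC.
#' @param genomes Taxonomy data.frame.
#' @param cultured_only If `TRUE`, restrict to cultured genomes.
#' @param digits Percentage rounding (default 1).
#' @return A data.frame: `group`, `ca_class`, `n_genomes`,
#'   `n_with_ca`, `pct_with_ca`.
#' @export
genome_presence_census <- function(records, genomes, cultured_only = FALSE,
                                   digits = 1L) {
  if (cultured_only) genomes <- genomes[genomes$cultured, , drop = FALSE]
  records <- records[records$genome_id %in% genomes$genome_id, , drop = FALSE]
  groups <- c("all", CA_GROUPS)
  classes <- c("all", CA_CLASSES)
  rows <- list()
  for (g in groups) {
    gset <- if (g == "all") genomes$genome_id else
      genomes$genome_id[genomes$group == g]
    for (cl in classes) {
      rset <- if (cl == "all") records else
        records[records$ca_class == cl, , drop = FALSE]
      with_ca <- length(intersect(gset, unique(rset$genome_id)))
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, ca_class = cl, n_genomes = length(gset),
        n_with_ca = with_ca,
        pct_with_ca = ratio_pct(with_ca, length(gset), digits),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Copy-number statistics per stratum and class
#'
#' Statistics are computed only over genomes carrying at least one copy
#' of the relevant class; the SD is the sample SD (n-1), reported as 0
#' with `single_genome = TRUE` when only one carrier exists.
#'
#' @param records [protein_records()] after QC.
#' @param genomes Taxonomy data.frame.
#' @return A list with `stats` (group x class mean/sd/min/max over
#'   carriers) and `histogram` (group, ca_class, n_copies, n_genomes,
#'   pct_of_genomes) supporting percent-of-genomes copy-number curves.
#' @export
copy_number_stats <- function(records, genomes) {
  cc <- .copy_counts(records, genomes)
  cc$group <- genomes$group[match(cc$genome_id, genomes$genome_id)]
  totals <- cc[cc$ca_class == CA_CLASSES[1L], c("genome_id", "group")]
  all_counts <- stats::aggregate(n_copies ~ genome_id + group, cc, sum)
  all_counts$ca_class <- "all"
  cc <- rbind(cc[, c("genome_id", "group", "ca_class", "n_copies")],
              all_counts[, c("genome_id", "group", "ca_class", "n_copies")])
  rows <- list(); hist_rows <- list()
  for (g in c("all", CA_GROUPS)) {
    sub_g <- if (g == "all") cc else cc[cc$group == g, , drop = FALSE]
    n_total <- if (g == "all") nrow(totals) else sum(totals$group == g)
    for (cl in c("all", CA_CLASSES)) {
      x <- sub_g$n_copies[sub_g$ca_class == cl]
      carriers <- x[x >= 1L]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, ca_class = cl, n_carriers = length(carriers),
        copy_mean = if (length(carriers)) mean(carriers) else NA_real_,
        copy_sd = if (length(carriers) > 1L) stats::sd(carriers)
                  else if (length(carriers) == 1L) 0 else NA_real_,
        single_genome = length(carriers) == 1L,
        copy_min = if (length(carriers)) min(carriers) else NA_integer_,
        copy_max = if (length(carriers)) max(carriers) else NA_integer_,
        stringsAsFactors = FALSE)
      if (length(carriers)) {
        h <- table(carriers)
        hist_rows[[length(hist_rows) + 1L]] <- data.frame(
          group = g, ca_class = cl,
          n_copies = as.integer(names(h)),
          n_genomes = as.integer(h),
          pct_of_genomes = ratio_pct(as.integer(h), n_total),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(stats = do.call(rbind, rows), histogram = do.call(rbind, hist_rows))
}

#' CA-class presence combinations per organism group
#'
#' Counts, per group, the genomes in each of the seven non-empty
#' presence combinations of the alpha/beta/gamma classes, plus `none`;
#' the eight cells sum to the group total.
#'
#' @param records [protein_records()] after QC.
#' @param genomes Taxonomy data.frame.
#' @return A data.frame: `group`, `combination`, `n_genomes`.
#' @export
class_combinations <- function(records, genomes) {
  cc <- .copy_counts(records, genomes)
  pres <- stats::reshape(cc, idvar = "genome_id", timevar = "ca_class",
                         direction = "wide")
  names(pres) <- sub("^n_copies\\.", "", names(pres))
  combo <- apply(pres[, CA_CLASSES] > 0L, 1L, function(v) {
    if (!any(v)) "none" else paste(CA_CLASSES[v], collapse = "+")
  })
  grp <- genomes$group[match(pres$genome_id, genomes$genome_id)]
  combos <- c("alpha", "beta", "gamma", "alpha+beta", "alpha+gamma",
              "beta+gamma", "alpha+beta+gamma", "none")
  rows <- list()
  for (g in CA_GROUPS) {
    tab <- table(factor(combo[grp == g], levels = combos))
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, combination = combos, n_genomes = as.integer(tab),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Assemble a survey-style census table
#'
#' One call bundling sequence counts, cluster census, genome presence,
#' copy-number statistics, and conservation by rank for a set of
#' records, clusters, and genomes.
#'
#' @param records [protein_records()] after QC.
#' @param clusters Membership data.frame.
#' @param genomes Taxonomy data.frame.
#' @param min_size Cluster-size cutoff for the conservation statistics.
#' @return A list of data.frames: `sequences`, `clusters`, `presence`,
#'   `presence_cultured`, `copy_stats`, `conservation`.
#' @export
census_table <- function(records, clusters, genomes, min_size = 3L) {
  lcr <- compute_lcr_table(clusters, records, genomes)
  cons <- list()
  for (cl in c("all", CA_CLASSES)) {
    sub <- lcr[lcr$size >= min_size, ]
    if (cl != "all") sub <- sub[sub$ca_class == cl, ]
    cons[[cl]] <- conservation_by_rank(sub$rank)
  }
  cons_df <- data.frame(rank = CA_RANKS,
                        do.call(cbind, cons), row.names = NULL,
                        check.names = FALSE)
  seq_counts <- as.data.frame(table(ca_class = records$ca_class),
                              stringsAsFactors = FALSE)
  names(seq_counts)[2L] <- "n_sequences"
  clus_rows <- lapply(c("all", CA_CLASSES), function(cl) {
    sub <- if (cl == "all") clusters else
      clusters[clusters$ca_class == cl, , drop = FALSE]
    cen <- cluster_size_census(sub, min_size)
    data.frame(ca_class = cl, n_clusters = cen$n_clusters,
               n_clusters_ge_min = cen$n_clusters_ge_min,
               n_sequences_in_ge_min = cen$n_sequences_in_ge_min,
               stringsAsFactors = FALSE)
  })
  cn <- copy_number_stats(records, genomes)
  list(sequences = seq_counts,
       clusters = do.call(rbind, clus_rows),
       presence = genome_presence_census(records, genomes),
       presence_cultured = genome_presence_census(records, genomes,
                                                  cultured_only = TRUE),
       copy_stats = cn$stats,
       conservation = cons_df,
       lcr = lcr)
}
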