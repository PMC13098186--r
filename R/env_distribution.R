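# Environment-level abundance and specificity of profile hits: raw
# count matrices and rollups, study-proportion/taxon-size scaling with a
# log10 transform, per-environment class fractions, top-N environment
# intersections, and coverage summaries.

#' Count retained hits per environment and profile
#'
#' @param hits Retained-hit data.frame from [assign_best_hits()].
#' @param datasets Dataset table (see [read_datasets()]).
#' @param rollup Optional named character vector mapping `profile_id`
#'   to a coarser label (clade, class, or LCR-derived tax group); when
#'   given, a rolled-up matrix is returned alongside.
#' @return A list with `by_profile` (environment x profile count
#'   matrix) and, when requested, `by_group` (environment x label);
#'   rollups conserve totals.
#' @export
count_hits <- function(hits, datasets, rollup = NULL) {
  orphan <- setdiff(unique(hits$dataset_id), datasets$dataset_id)
  if (length(orphan) > 0L)
    stop("hits reference unknown dataset id(s): ",
         paste(orphan, collapse = ", "))
  env <- datasets$environment[match(hits$dataset_id, datasets$dataset_id)]
  envs <- sort(unique(datasets$environment))
  profs <- sort(unique(hits$profile_id))
  by_profile <- table(factor(env, levels = envs),
                      factor(hits$profile_id, levels = profs))
  by_profile <- matrix(as.integer(by_profile), nrow = length(envs),
                       dimnames = list(envs, profs))
  out <- list(by_profile = by_profile)
  if (!is.null(rollup)) {
    miss <- setdiff(profs, names(rollup))
    if (length(miss) > 0L)
      stop("rollup missing profile id(s): ", paste(miss, collapse = ", "))
    lab <- rollup[profs]
    groups <- sort(unique(lab))
    by_group <- vapply(groups, function(g)
      rowSums(by_profile[, lab == g, drop = FALSE]),
      numeric(length(envs)))
    out$by_group <- matrix(as.integer(by_group), nrow = length(envs),
                           dimnames = list(envs, groups))
  }
  out
}

#' Scale and log-transform a raw hit count
#'
#' `P = raw_hits / env_study_fraction` corrects for unequal numbers of
#' studies per ecosystem; dividing by the taxonomic group size `T`
#' (genomes in the group) corrects for unequal genome representation.
#' The transform is `log10(P/T + 1e-5)`, so zero hits map to exactly -5.
#'
#' @param raw_hits Nonnegative hit count(s).
#' @param env_study_fraction Share of studies in the environment,
#'   in `(0, 1]`.
#' @param tax_group_size Number of genomes in the taxonomic group
#'   (must be >= 1).
#' @return A list with `scaled` and `transformed` (vectors).
#' @export
normalize_abundance <- function(raw_hits, env_study_fraction, tax_group_size) {
  if (any(raw_hits < 0)) stop("raw_hits must be nonnegative")
  if (any(env_study_fraction <= 0) || any(env_study_fraction > 1))
    stop("env_study_fraction must be in (0, 1]")
  if (any(tax_group_size < 1))
    stop("tax group with no genomes cannot be normalized")
  scaled <- (raw_hits / env_study_fraction) / tax_group_size
  list(scaled = scaled, transformed = log10(scaled + 1e-5))
}

#' Long-format abundance table with scaling and transform
#'
#' Applies [normalize_abundance()] per (environment x group) cell of a
#' rolled-up count matrix.
#'
#' @param by_group Environment x group count matrix (see
#'   [count_hits()]).
#' @param datasets Dataset table; study fractions are the per-
#'   environment share of distinct `study_id`s.
#' @param tax_group_sizes Named vector: genomes per group label.
#' @return A long data.frame: `environment`, `tax_group`, `raw`,
#'   `scaled`, `transformed`.
#' @export
abundance_table <- function(by_group, datasets, tax_group_sizes) {
  envs <- rownames(by_group)
  studies <- tapply(datasets$study_id, datasets$environment,
                    function(x) length(unique(x)))
  frac <- studies[envs] / sum(studies)
  rows <- list()
  for (e in envs) {
    for (g in colnames(by_group)) {
      if (!g %in% names(tax_group_sizes))
        stop("no genome count for tax group: ", g)
      nm <- normalize_abundance(by_group[e, g], frac[[e]],
                                tax_group_sizes[[g]])
      rows[[length(rows) + 1L]] <- data.frame(
        environment = e, tax_group = g, raw = by_group[e, g],
        scaled = nm$scaled, transformed = nm$transformed,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Per-environment hit fractions per class or clade
#'
#' @param by_group Environment x label count matrix.
#' @return A data.frame: `environment`, `label`, `n_hits`, `fraction`;
#'   fractions sum to 1 per environment with hits, and an all-zero
#'   environment is flagged with `no_hits = TRUE`.
#' @export
class_fraction_by_environment <- function(by_group) {
  rows <- list()
  for (e in rownames(by_group)) {
    tot <- sum(by_group[e, ])
    rows[[length(rows) + 1L]] <- data.frame(
      environment = e, label = colnames(by_group),
      n_hits = as.integer(by_group[e, ]),
      fraction = if (tot > 0) as.numeric(by_group[e, ] / tot) else 0,
      no_hits = tot == 0L, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Environment-specificity intersections of top profiles
#'
#' Selects, per environment, the `top_n` profiles by raw hits (ties by
#' profile id ascending), takes their union, assigns each selected
#' profile its environment membership set (every environment where it
#' has at least one raw hit), and groups profiles by identical
#' membership sets -- the construction behind upset-style intersection
#' plots.
#'
#' @param by_profile Environment x profile count matrix.
#' @param top_n Number of top profiles per environment (default 10).
#' @param profile_groups Optional named vector (profile id to label,
#'   e.g. LCR phylum) for the composition column.
#' @return A list with `intersections` (data.frame: `membership`,
#'   `n_profiles`, `composition`), `selected` (per-profile membership
#'   table), and `set_sizes` (per-environment hit totals over selected
#'   profiles).
#' @export
environment_specificity <- function(by_profile, top_n = 10L,
                                    profile_groups = NULL) {
  stopifnot(top_n >= 1L)
  selected <- character(0)
  for (e in rownames(by_profile)) {
    cnt <- by_profile[e, ]
    cnt <- cnt[cnt > 0L]
    if (length(cnt) == 0L) next
    ord <- order(-cnt, names(cnt))
    selected <- union(selected, names(cnt)[ord][seq_len(min(top_n,
                                                            length(cnt)))])
  }
  selected <- sort(selected)
  membership <- vapply(selected, function(p)
    paste(rownames(by_profile)[by_profile[, p] > 0L], collapse = "&"), "")
  sel_tab <- data.frame(profile_id = selected, membership = membership,
                        stringsAsFactors = FALSE)
  if (!is.null(profile_groups))
    sel_tab$group <- profile_groups[selected]
  inter <- lapply(split(sel_tab, sel_tab$membership), function(d) {
    data.frame(membership = d$membership[1L], n_profiles = nrow(d),
               composition = if (!is.null(profile_groups))
                 paste(sort(table(d$group), decreasing = TRUE) |>
                         (\(t) paste0(names(t), ":", t))(), collapse = ",")
               else "", stringsAsFactors = FALSE)
  })
  inter <- do.call(rbind, inter)
  rownames(inter) <- NULL
  set_sizes <- vapply(rownames(by_profile), function(e)
    sum(by_profile[e, selected, drop = FALSE]), 0)
  list(intersections = inter, selected = sel_tab, set_sizes = set_sizes)
}

#' Coverage summary of a scan
#'
#' Percent of datasets with any retained hit, percent of profiles with
#' any retained hit, the distribution of hits per profile, and the
#' Spearman rank correlation between cluster size and hit count (the
#' size-independence check).
#'
#' @param hits Retained-hit data.frame.
#' @param profile_ids All scanned profile ids (the universe).
#' @param datasets Dataset table (the dataset universe).
#' @param cluster_sizes Optional named vector: members per profile id.
#' @return A list: `pct_datasets_with_hit`, `pct_profiles_with_hit`,
#'   `hits_per_profile`, `size_hit_correlation` (NA without sizes).
#' @export
coverage_summary <- function(hits, profile_ids, datasets,
                             cluster_sizes = NULL) {
  hit_profiles <- unique(hits$profile_id)
  hit_datasets <- unique(hits$dataset_id)
  hpp <- stats::setNames(integer(length(profile_ids)), profile_ids)
  tab <- table(hits$profile_id)
  hpp[names(tab)] <- as.integer(tab)
  rho <- NA_real_
  if (!is.null(cluster_sizes)) {
    cs <- cluster_sizes[profile_ids]
    rho <- suppressWarnings(stats::cor(cs, hpp, method = "spearman"))
  }
  list(pct_datasets_with_hit = ratio_pct(length(hit_datasets),
                                         nrow(datasets)),
       pct_profiles_with_hit = ratio_pct(length(hit_profiles),
                                         length(profile_ids)),
       hits_per_profile = hpp,
       size_hit_correlation = rho)
}
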