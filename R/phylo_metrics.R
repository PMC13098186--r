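# Tree post-processing and diversity statistics: support-based node
# collapsing into polytomies, long-branch flagging, Faith-style
# phylogenetic diversity (PD), and a randomization test for the PD
# contribution of a focal tip set.

#' Collapse poorly supported nodes into polytomies
#'
#' Every internal (non-root) edge whose child node's support is strictly
#' below `threshold_percent` is contracted; a node at exactly the
#' threshold is retained. On contraction the collapsed edge's length is
#' added to each child's branch, preserving all root-to-tip distances.
#' Nodes without a support value are kept by default.
#'
#' @param tree An [ape::phylo] with a `node.support` vector (see
#'   [read_newick()]).
#' @param threshold_percent Support threshold in `(0, 100]`.
#' @param missing_support `"keep"` (default) or `"collapse"` for nodes
#'   carrying no numeric support.
#' @return The collapsed tree (re-parsed, with `node.support`).
#' @export
collapse_low_support <- function(tree, threshold_percent = 95,
                                 missing_support = c("keep", "collapse")) {
  missing_support <- match.arg(missing_support)
  stopifnot(threshold_percent > 0, threshold_percent <= 100)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  sup <- tree$node.support
  if (is.null(sup)) sup <- rep(NA_real_, tree$Nnode)
  kids_of <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  collapse_node <- function(v) {
    s <- sup[v - ntip]
    if (is.na(s)) missing_support == "collapse" else s < threshold_percent
  }
  recurse_child <- function(v, len) {
    if (v <= ntip)
      return(paste0(tree$tip.label[v], ":", format(len, digits = 15)))
    edges <- kids_of[[as.character(v)]]
    if (v != root && collapse_node(v)) {
      parts <- unlist(lapply(edges, function(e)
        recurse_child(tree$edge[e, 2L], tree$edge.length[e] + len)))
      return(parts)
    }
    parts <- unlist(lapply(edges, function(e)
      recurse_child(tree$edge[e, 2L], tree$edge.length[e])))
    s <- sup[v - ntip]
    lab <- if (is.na(s)) "" else format(s, trim = TRUE)
    paste0("(", paste(parts, collapse = ","), ")", lab, ":",
           format(len, digits = 15))
  }
  root_edges <- kids_of[[as.character(root)]]
  parts <- unlist(lapply(root_edges, function(e)
    recurse_child(tree$edge[e, 2L], tree$edge.length[e])))
  s <- sup[1L]
  lab <- if (is.na(s)) "" else format(s, trim = TRUE)
  parse_newick(paste0("(", paste(parts, collapse = ","), ")", lab, ";"))
}

#' Flag tips on exceptionally long terminal branches
#'
#' A tip is flagged when its terminal branch length exceeds
#' `median + k * MAD` of all terminal branch lengths (MAD with the
#' usual 1.4826 consistency constant). The rule, and the default
#' `k = 5`, are configuration: only the outcome of long-branch
#' exclusion is standard, not any particular statistic.
#'
#' @param tree An [ape::phylo] with branch lengths.
#' @param k Multiplier on the MAD (default 5).
#' @return Character vector of flagged tip labels (empty, with a
#'   warning, for trees with fewer than 4 tips).
#' @export
flag_long_branches <- function(tree, k = 5) {
  stopifnot(k > 0)
  ntip <- length(tree$tip.label)
  if (ntip < 4L) {
    warning("fewer than 4 tips; no long-branch flags")
    return(character(0))
  }
  term <- tree$edge[, 2L] <= ntip
  len <- tree$edge.length[term]
  tip <- tree$tip.label[tree$edge[term, 2L]]
  cut <- stats::median(len) + k * stats::mad(len)
  sort(tip[len > cut])
}

#' Phylogenetic diversity of a tree or tip subset
#'
#' For the whole tree, PD is the sum of all branch lengths. For a tip
#' subset, PD is the sum of branch lengths of the minimal subtree
#' connecting the subset (crown convention: the edge above the
#' subset's connecting node is excluded unless `include_root = TRUE`).
#'
#' @param tree An [ape::phylo] with branch lengths.
#' @param tips `NULL`/`"ALL"` for the whole tree, else a character
#'   vector of at least two tip labels.
#' @param include_root Include the root-ward path above the subset's
#'   most recent common ancestor.
#' @return PD as a single number.
#' @export
phylogenetic_diversity <- function(tree, tips = NULL, include_root = FALSE) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (is.null(tips) || identical(tips, "ALL"))
    return(sum(tree$edge.length))
  ntip <- length(tree$tip.label)
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) stop("unknown tip label: ", tips[is.na(idx)][1L])
  if (length(idx) < 2L)
    stop("PD of a single tip is undefined; supply at least two tips")
  n_sub <- length(idx)
  count <- integer(ntip + tree$Nnode)
  count[idx] <- 1L
  tr <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(tr$edge)))
    count[tr$edge[e, 1L]] <- count[tr$edge[e, 1L]] + count[tr$edge[e, 2L]]
  below <- count[tr$edge[, 2L]]
  keep <- below >= 1L & (below < n_sub | include_root)
  sum(tr$edge.length[keep])
}

#' Randomization test for the PD contribution of a focal tip set
#'
#' The observed statistic is `PD(ALL) - PD(ALL minus focal)`: the
#' diversity lost when the focal tips (e.g. all fungal sequences) are
#' removed. The null distribution re-draws `n_rand` uniformly random
#' tip sets of the focal size; the p-value uses the add-one correction
#' `p = (1 + #(null >= observed)) / (1 + n_rand)` so it is never zero.
#'
#' @param tree An [ape::phylo] with branch lengths.
#' @param focal_tips Nonempty proper subset of tip labels (at most
#'   `Ntip - 2`, so the remainder still has a defined PD).
#' @param n_rand Number of randomizations (default 999).
#' @param seed Integer seed; results are bit-exact given the seed.
#' @return A list of class `ca_pd_result`: `pd_total`, `pd_focal`
#'   (crown PD of the focal set, NA for a single focal tip), `delta`,
#'   `p_value`, `n_randomizations`, `seed`, `null` (the null draws).
#' @export
pd_contribution_test <- function(tree, focal_tips, n_rand = 999L, seed = 1L) {
  stopifnot(n_rand >= 1L)
  ntip <- length(tree$tip.label)
  focal_tips <- unique(focal_tips)
  if (length(focal_tips) == 0L) stop("focal_tips must be nonempty")
  if (anyNA(match(focal_tips, tree$tip.label)))
    stop("unknown focal tip label")
  if (length(focal_tips) > ntip - 2L)
    stop("focal set must leave at least two non-focal tips")
  pd_total <- phylogenetic_diversity(tree)
  drop_stat <- function(drop) {
    rest <- setdiff(tree$tip.label, drop)
    pd_total - phylogenetic_diversity(tree, rest)
  }
  observed <- drop_stat(focal_tips)
  set.seed(seed)
  null <- vapply(seq_len(n_rand), function(i)
    drop_stat(sample(tree$tip.label, length(focal_tips))), 0)
  p <- (1 + sum(null >= observed)) / (1 + n_rand)
  structure(list(pd_total = pd_total,
                 pd_focal = if (length(focal_tips) >= 2L)
                   phylogenetic_diversity(tree, focal_tips) else NA_real_,
                 delta = observed,
                 p_value = p,
                 n_randomizations = n_rand,
                 seed = seed,
                 null = null),
            class = "ca_pd_result")
}
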