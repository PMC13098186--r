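#' Read a Newick tree with node support values
#'
#' Parses a Newick file (via \pkg{ape}) and interprets numeric internal
#' node labels as support values. Supports are normalized to a 0--100
#' percent scale: files storing fractional supports (e.g. `0.95`) are
#' handled by `support_scale = "fraction"`, which multiplies by 100. The
#' default expects percent-scale supports as produced by ultrafast
#' bootstrapping.
#'
#' @param path Path to a Newick file.
#' @param support_scale `"percent"` (default) or `"fraction"`.
#' @return An [ape::phylo] object with an added numeric `node.support`
#'   vector (NA where a node carries no numeric label).
#' @export
read_newick <- function(path, support_scale = c("percent", "fraction")) {
  support_scale <- match.arg(support_scale)
  if (!file.exists(path)) stop("Newick file not found: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse error in ", path,
                                            ": ", conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error in ", path)
  .attach_supports(tree, support_scale)
}

#' Parse a Newick string (not a file)
#'
#' @inheritParams read_newick
#' @param text A Newick string.
#' @return An [ape::phylo] object with `node.support`.
#' @export
parse_newick <- function(text, support_scale = c("percent", "fraction")) {
  support_scale <- match.arg(support_scale)
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("Newick parse error")
  .attach_supports(tree, support_scale)
}

.attach_supports <- function(tree, support_scale) {
  ns <- rep(NA_real_, tree$Nnode)
  if (!is.null(tree$node.label)) {
    suppressWarnings(v <- as.numeric(tree$node.label))
    ns <- v
  }
  if (support_scale == "fraction") ns <- ns * 100
  tree$node.support <- ns
  tree
}

#' Write a tree to Newick, carrying supports as node labels
#'
#' The round trip `read_newick()` then `write_newick()` preserves
#' topology, branch lengths, and supports.
#'
#' @param tree An [ape::phylo] object, optionally with `node.support`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (!is.null(tree$node.support)) {
    lab <- ifelse(is.na(tree$node.support), "",
                  format(tree$node.support, trim = TRUE))
    tree$node.label <- lab
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}
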