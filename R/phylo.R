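# Branch-length statistics on rooted phylogenies: root-to-tip distances
# and the fraction of total branch length attributable to a tagged tip set
# (e.g. the genomes recovered from a single community), in two readings:
# clade-exclusive edges or terminal branches only.

#' Parse a newick string into a validated phylo tree
#'
#' Thin, validating wrapper around `ape::read.tree`.  Rejects unbalanced
#' parentheses (reporting the offending position) and duplicate tip
#' labels; missing branch lengths are set to 0 with a warning.  A bare
#' single-tip string such as `"A:5;"` is accepted.  Unrooted (basal
#' multifurcation) trees are kept with the basal node treated as the root,
#' with a warning.
#'
#' @param text A newick string.
#' @return An `ape` `phylo` object.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  depth <- 0L
  chars <- strsplit(text, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) stop(sprintf("unbalanced ')' at position %d", i))
  }
  if (depth != 0L) {
    stop(sprintf("unbalanced '(': %d unclosed at end of string", depth))
  }
  if (!grepl("\\(", text)) text <- sub("^([^;]+);?$", "(\\1);", text)
  tree <- tryCatch(ape::read.tree(text = text), error = function(e) NULL)
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("could not parse newick string")
  }
  if (anyDuplicated(tree$tip.label)) {
    stop(sprintf("duplicate tip label(s): %s",
                 paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                       collapse = ", ")))
  }
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; all set to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warning("missing branch lengths set to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths are not allowed")
  if (!ape::is.rooted(tree)) {
    warning("tree is unrooted; treating its basal node as the root")
  }
  tree
}

#' Root-to-tip path lengths
#'
#' Sum of branch lengths along the unique path from the root to each tip.
#'
#' @param tree A rooted `phylo` tree with branch lengths.
#' @return Named numeric vector, one distance per tip.
#' @export
root_to_tip <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  d <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  names(d) <- tree$tip.label
  d
}

#' Fraction of total branch length attributable to a tip set
#'
#' In `"exclusive"` mode, an edge contributes when every tip descending
#' from it belongs to `tips` (the branch length exclusive to the tagged
#' clade(s), including their internal edges); in `"tip_only"` mode only
#' the terminal branches of the tagged tips contribute.  Both sums are
#' divided by the total branch length of the tree.  Exclusive mode always
#' gives at least the tip-only value.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param tips Character vector of tip labels (subset of the tree's tips).
#' @param mode `"exclusive"` or `"tip_only"`.
#' @return A fraction in \[0, 1\] (0 for an empty tip set; 0 with a
#'   warning for a tree of zero total length).
#' @export
branch_fraction <- function(tree, tips, mode = c("exclusive", "tip_only")) {
  stopifnot(inherits(tree, "phylo"))
  mode <- match.arg(mode)
  tips <- as.character(tips)
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown tip label(s): %s", paste(unknown, collapse = ", ")))
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  total <- sum(tree$edge.length)
  if (total == 0) {
    warning("tree has zero total branch length; fraction reported as 0")
    return(0)
  }
  if (length(tips) == 0L) return(0)
  tip_idx <- match(tips, tree$tip.label)
  child <- tree$edge[, 2L]
  if (mode == "tip_only") {
    contrib <- tree$edge.length[child %in% tip_idx]
  } else {
    # an edge counts when the tip set below its child node is within `tips`
    desc <- phangorn::Descendants(tree, child, type = "tips")
    inside <- vapply(desc, function(s) all(s %in% tip_idx), logical(1))
    contrib <- tree$edge.length[inside]
  }
  sum(contrib) / total
}
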