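#' Coerce to a rooted binary species tree
#'
#' Accepts an `ape::phylo` object or a Newick string (for example
#' `"(Anj,(Apj,(Sp,Lv)));"`). The tree must be rooted and binary and its
#' tips are the species labels used in expression tables. Branch lengths
#' are optional; stage-conservation scoring uses the topology only.
#'
#' @param tree A `phylo` object or a Newick string.
#' @param species Optional character vector of species to retain; the tree
#'   is pruned to these tips with the topology among them preserved.
#' @return A rooted binary `phylo` object.
#' @export
species_tree <- function(tree, species = NULL) {
  if (is.character(tree) && length(tree) == 1L) {
    tree <- ape::read.tree(text = tree)
    if (is.null(tree)) stop_config("could not parse Newick string")
  }
  if (!inherits(tree, "phylo")) {
    stop_config("`tree` must be a phylo object or a Newick string")
  }
  if (anyDuplicated(tree$tip.label)) stop_config("duplicated tip labels")
  if (!is.null(species)) {
    missing <- setdiff(species, tree$tip.label)
    if (length(missing) > 0L) {
      stop_config("species not in tree: %s", paste(missing, collapse = ", "))
    }
    tree <- ape::keep.tip(tree, species)
  }
  if (length(tree$tip.label) < 2L) stop_config("tree must have >= 2 tips")
  if (!ape::is.rooted(tree)) stop_config("tree must be rooted")
  if (!ape::is.binary(tree)) stop_config("tree must be binary")
  tree
}

# Nested-list view of a phylo object; children kept in newick (cladewise)
# order so that combination enumeration is deterministic.
tree_structure <- function(phy) {
  ntip <- length(phy$tip.label)
  build <- function(node) {
    if (node <= ntip) {
      return(list(leaf = TRUE, species = phy$tip.label[node]))
    }
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    list(leaf = FALSE, left = build(kids[1]), right = build(kids[2]))
  }
  build(ntip + 1L)
}

# Leaf labels in left-to-right (newick) order.
tree_leaf_order <- function(phy) {
  node <- tree_structure(phy)
  rec <- function(n) if (n$leaf) n$species else c(rec(n$left), rec(n$right))
  rec(node)
}
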