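#' Parse a rooted binary species tree
#'
#' Reads a newick string (or file) with [ape::read.tree()], checks that
#' the tree is rooted and binary (the family algorithm needs a left/right
#' split at every internal node), and assigns deterministic internal node
#' ids `N1, N2, ...` in pre-order (root = `N1`, children visited in the
#' order they appear in the newick). Leaves keep their labels as ids.
#'
#' @param newick A newick string, or a path to a newick file.
#' @param focal_clade The focal clade: either a character vector of >= 2
#'   leaf names (resolved to their MRCA), a single leaf name, or an
#'   internal node id such as `"N3"`.
#' @param strains Optional character vector of strain names that must
#'   match the leaf set exactly (typically `genome_set$strains`).
#' @return A `species_tree`: list with `phylo` (the ape tree), `ids`
#'   (node ids indexed by ape node number), `parent`, `children`,
#'   `leaves_under`, `branch_length` (length of the edge *entering* each
#'   node, NA at the root), `depth`, `preorder`, `postorder`,
#'   `is_leaf` (all keyed by node id), and `focal_root`.
#' @export
parse_species_tree <- function(newick, focal_clade, strains = NULL) {
  phy <- if (file.exists(newick) && !grepl("\\(", newick)) {
    ape::read.tree(newick)
  } else {
    ape::read.tree(text = newick)
  }
  if (is.null(phy)) stop("could not parse newick input")
  if (!ape::is.rooted(phy)) stop("species tree must be rooted")
  if (!ape::is.binary(phy)) {
    stop("species tree must be binary: polytomies are not supported ",
         "(the family algorithm requires a left/right split at each node)")
  }
  if (anyDuplicated(phy$tip.label)) stop("leaf names must be unique")
  if (!is.null(strains) && !setequal(phy$tip.label, strains)) {
    stop("tree leaves do not match strain names; missing from tree: ",
         paste(setdiff(strains, phy$tip.label), collapse = ","),
         "; extra in tree: ",
         paste(setdiff(phy$tip.label, strains), collapse = ","))
  }
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  root_num <- ntip + 1L
  kids <- split(phy$edge[, 2], phy$edge[, 1])  # preserves edge order
  ## pre-order traversal with deterministic internal ids
  ids <- character(ntip + nnode)
  ids[seq_len(ntip)] <- phy$tip.label
  preorder_nums <- integer(0)
  stack <- root_num
  next_internal <- 1L
  while (length(stack)) {
    nd <- stack[1]
    stack <- stack[-1]
    preorder_nums <- c(preorder_nums, nd)
    if (nd > ntip) {
      ids[nd] <- sprintf("N%d", next_internal)
      next_internal <- next_internal + 1L
      stack <- c(kids[[as.character(nd)]], stack)  # depth-first, left first
    }
  }
  parent <- setNames(rep(NA_character_, ntip + nnode), ids)
  branch_length <- setNames(rep(NA_real_, ntip + nnode), ids)
  for (e in seq_len(nrow(phy$edge))) {
    child <- phy$edge[e, 2]
    parent[ids[child]] <- ids[phy$edge[e, 1]]
    if (!is.null(phy$edge.length)) {
      branch_length[ids[child]] <- phy$edge.length[e]
    }
  }
  children <- lapply(seq_len(ntip + nnode), function(nd) {
    if (nd <= ntip) character(0) else ids[kids[[as.character(nd)]]]
  })
  names(children) <- ids
  is_leaf <- setNames(seq_len(ntip + nnode) <= ntip, ids)
  ## leaves under each node, and depth (edges from root)
  preorder <- ids[preorder_nums]
  postorder <- rev(preorder)
  leaves_under <- setNames(vector("list", length(ids)), ids)
  for (id in postorder) {
    leaves_under[[id]] <- if (is_leaf[id]) id else
      unlist(lapply(children[[id]], function(ch) leaves_under[[ch]]),
             use.names = FALSE)
  }
  depth <- setNames(integer(length(ids)), ids)
  for (id in preorder) {
    depth[id] <- if (is.na(parent[id])) 0L else depth[parent[id]] + 1L
  }
  tree <- structure(list(
    phylo = phy, ids = ids, parent = parent, children = children,
    leaves_under = leaves_under, branch_length = branch_length,
    depth = depth, preorder = preorder, postorder = postorder,
    is_leaf = is_leaf, focal_root = NA_character_), class = "species_tree")
  tree$focal_root <- resolve_node(tree, focal_clade)
  tree
}

## Resolve a clade designation (leaf set, leaf, or node id) to a node id.
resolve_node <- function(tree, spec) {
  if (length(spec) > 1) return(tree_mrca(tree, spec))
  if (spec %in% names(tree$parent)) return(spec)
  stop("unknown node or leaf: ", spec)
}

#' Most recent common ancestor of a set of strains
#'
#' @param tree A `species_tree`.
#' @param strains Non-empty character vector of leaf names.
#' @return The id of the lowest node whose subtree contains all the given
#'   strains; `tree_mrca(tree, "X")` is the leaf `"X"` itself.
#' @export
tree_mrca <- function(tree, strains) {
  strains <- unique(strains)
  if (!length(strains)) stop("empty strain set")
  bad <- setdiff(strains, names(tree$is_leaf)[tree$is_leaf])
  if (length(bad)) stop("unknown strain(s): ", paste(bad, collapse = ","))
  if (length(strains) == 1L) return(strains)
  ## walk up from the first strain until the subtree covers all of them
  node <- strains[1]
  while (!all(strains %in% tree$leaves_under[[node]])) {
    node <- tree$parent[node]
  }
  unname(node)
}

## Is `anc` an ancestor of (or equal to) `node`?
tree_is_ancestor <- function(tree, anc, node) {
  while (!is.na(node)) {
    if (node == anc) return(TRUE)
    node <- tree$parent[node]
  }
  FALSE
}

## Internal (non-leaf) nodes in pre-order.
internal_nodes <- function(tree) {
  tree$preorder[!tree$is_leaf[tree$preorder]]
}

#' @export
print.species_tree <- function(x, ...) {
  cat(sprintf("species_tree: %d leaves, %d internal nodes, focal root %s (%s)\n",
              sum(x$is_leaf), sum(!x$is_leaf), x$focal_root,
              paste(x$leaves_under[[x$focal_root]], collapse = ",")))
  invisible(x)
}

#' Default 11-taxon validation tree
#'
#' A rooted binary tree with a ladder-like focal clade of nine strains
#' (`A`--`I`) and two successively deeper outgroups (`J`, `K`), used for
#' simulation-based validation of the pipeline. Branch lengths are in the
#' simulator's time units (event rates and the substitution rate are per
#' unit branch length); total tree length is about 2.24.
#'
#' @return A `species_tree` with `focal_root = ` MRCA of `A`--`I`.
#' @export
validation_tree <- function() {
  nwk <- paste0("(((((((((A:0.1,B:0.1):0.08,C:0.1):0.08,(D:0.1,E:0.1):0.08)",
                ":0.08,F:0.1):0.08,G:0.1):0.08,H:0.1):0.08,I:0.1):0.08,",
                "J:0.25):0.1,K:0.35);")
  parse_species_tree(nwk, focal_clade = LETTERS[1:9])
}
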