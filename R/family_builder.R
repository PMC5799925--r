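## Tree-aware gene families.
##
## Families are built by visiting the species tree's internal nodes in
## pre-order. At each node, genes of the strains under the left child
## form group 1 and genes under the right child form group 2 (genes of
## strains outside the node's subtree are ignored, as are genes already
## placed in a family). For each unclustered gene the most similar
## unclustered gene in the opposite group (by raw score) proposes a seed;
## seeds are processed in order of decreasing similarity, and each seed
## whose two genes are still unclustered founds a family that then grows
## by single-linkage: an unclustered gene from either group joins when
## some link to a current member has (possibly synteny-boosted) raw score
## at least the seed score AND clears the norm-score and synteny floors.
## The same floors gate seed formation: only links that pass them count
## as evidence of descent from a common ancestor within the tree.
## Genes left over after all nodes become singleton families at their
## leaf. Every family records the MRCA of its member strains.

#' Generate family seeds at a tree node
#'
#' @param tree A `species_tree`.
#' @param node An internal node id.
#' @param genomes A `genome_set`.
#' @param pairs Scored candidate pairs (needs `raw`).
#' @param unclustered Character vector of still-unclustered gene ids
#'   (default: all genes).
#' @return A `data.table` with columns `g1`, `g2` (gene ids, `g1 < g2`)
#'   and `score`, sorted by decreasing score with ties broken by
#'   `(g1, g2)`.
#' @export
generate_seeds <- function(tree, node, genomes, pairs,
                           unclustered = genomes$genes$gene_id) {
  if (tree$is_leaf[node]) stop("seeds are generated at internal nodes only")
  kids <- tree$children[[node]]
  left <- tree$leaves_under[[kids[1]]]
  right <- tree$leaves_under[[kids[2]]]
  strain_of <- setNames(genomes$genes$strain, genomes$genes$gene_id)
  keep <- pairs$g1 %in% unclustered & pairs$g2 %in% unclustered
  p <- pairs[keep]
  s1 <- strain_of[p$g1]; s2 <- strain_of[p$g2]
  cross <- (s1 %in% left & s2 %in% right) | (s1 %in% right & s2 %in% left)
  p <- p[cross]
  if (!nrow(p)) {
    return(data.table(g1 = character(0), g2 = character(0),
                      score = numeric(0)))
  }
  long <- rbindlist(list(p[, .(g = g1, partner = g2, raw)],
                         p[, .(g = g2, partner = g1, raw)]))
  setorder(long, g, -raw, partner)
  best <- long[, .(partner = partner[1], score = raw[1]), by = g]
  pk <- pair_key(best$g, best$partner)
  seeds <- unique(data.table(g1 = pk$g1, g2 = pk$g2, score = best$score))
  setorder(seeds, -score, g1, g2)
  seeds[]
}

#' Build tree-aware gene families
#'
#' @param genomes A `genome_set`.
#' @param tree A `species_tree`.
#' @param pairs Fully scored candidate pairs (`raw`, `norm`, `core_syn`,
#'   `local_syn`), as produced by [score_genomes()].
#' @param config Optional configuration; see [default_config()]
#'   (`family_*` entries).
#' @return A `gi_families` object: list with `families` (a `data.table`
#'   with `family_id`, `mrca`, `founding_node`, `n_genes`, `seed_g1`,
#'   `seed_g2`, `seed_score`; seed columns are `NA` for singletons) and
#'   `membership` (`gene_id` -> `family_id`; a partition of all genes).
#' @export
build_families <- function(genomes, tree, pairs, config = NULL) {
  cfg <- as_config(config)
  genes <- genomes$genes
  strain_of <- setNames(genes$strain, genes$gene_id)
  ## effective link score: raw plus synteny bonus when both synteny
  ## measures are high; eligibility from the three floors
  p <- copy(pairs)
  p[, eff := pmin(1, raw + ifelse(core_syn >= cfg$family_bonus_core &
                                  local_syn >= cfg$family_bonus_local,
                                  cfg$family_bonus, 0))]
  p[, elig := norm >= cfg$family_norm_floor &
        core_syn >= cfg$family_core_syn_floor &
        local_syn >= cfg$family_local_syn_floor]
  long <- rbindlist(list(
    p[, .(g = g1, partner = g2, raw, eff, elig)],
    p[, .(g = g2, partner = g1, raw, eff, elig)]))
  adj <- split(long, by = "g", keep.by = FALSE)
  ## Links below the floors are not usable evidence of common descent
  ## within the tree, for seeding just as for member addition: this is
  ## the role the external-search significance cutoff plays upstream.
  seed_pairs <- p[elig == TRUE]
  unclustered <- setNames(rep(TRUE, nrow(genes)), genes$gene_id)
  fam_rows <- list()
  members_of <- list()
  next_id <- 1L
  for (node in internal_nodes(tree)) {
    node_strains <- tree$leaves_under[[node]]
    ucl <- names(unclustered)[unclustered]
    ucl <- ucl[strain_of[ucl] %in% node_strains]
    if (length(ucl) < 2) next
    seeds <- generate_seeds(tree, node, genomes, seed_pairs,
                            unclustered = ucl)
    for (si in seq_len(nrow(seeds))) {
      a <- seeds$g1[si]; b <- seeds$g2[si]
      if (!unclustered[a] || !unclustered[b]) next
      seed_score <- seeds$score[si]
      members <- c(a, b)
      unclustered[members] <- FALSE
      frontier <- members
      while (length(frontier)) {
        new_members <- character(0)
        for (mgene in frontier) {
          ed <- adj[[mgene]]
          if (is.null(ed)) next
          cand <- ed[elig & eff >= seed_score, partner]
          cand <- cand[unclustered[cand] & strain_of[cand] %in% node_strains]
          if (length(cand)) {
            cand <- unique(cand)
            unclustered[cand] <- FALSE
            new_members <- c(new_members, cand)
          }
        }
        members <- c(members, new_members)
        frontier <- new_members
      }
      fam_rows[[next_id]] <- data.table(
        family_id = next_id, founding_node = node,
        mrca = tree_mrca(tree, unique(unname(strain_of[members]))),
        n_genes = length(members),
        seed_g1 = a, seed_g2 = b, seed_score = seed_score)
      members_of[[next_id]] <- sort(members)
      next_id <- next_id + 1L
    }
  }
  ## leftovers: singleton families at their own leaf
  for (gid in sort(names(unclustered)[unclustered])) {
    fam_rows[[next_id]] <- data.table(
      family_id = next_id, founding_node = unname(strain_of[gid]),
      mrca = unname(strain_of[gid]), n_genes = 1L,
      seed_g1 = NA_character_, seed_g2 = NA_character_,
      seed_score = NA_real_)
    members_of[[next_id]] <- gid
    next_id <- next_id + 1L
  }
  families <- rbindlist(fam_rows)
  membership <- data.table(
    gene_id = unlist(members_of, use.names = FALSE),
    family_id = rep(families$family_id, families$n_genes))
  obj <- list(families = families, membership = membership)
  class(obj) <- "gi_families"
  obj
}

#' @export
print.gi_families <- function(x, ...) {
  cat(sprintf("gi_families: %d families over %d genes (%d singletons)\n",
              nrow(x$families), nrow(x$membership),
              sum(x$families$n_genes == 1L)))
  invisible(x)
}

#' Write families as TSV
#'
#' Columns: `family_id`, `mrca`, `founding_node`, `seed_score`,
#' `gene_ids` (comma-separated, sorted).
#'
#' @param families A `gi_families`.
#' @param path Output file.
#' @export
write_families_tsv <- function(families, path) {
  mem <- families$membership[order(gene_id),
                             .(gene_ids = paste(sort(gene_id), collapse = ",")),
                             by = family_id]
  out <- merge(families$families[, .(family_id, mrca, founding_node,
                                     seed_score)],
               mem, by = "family_id")
  setorder(out, family_id)
  fwrite(out, path, sep = "\t")
  invisible(path)
}
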