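## Islands: groups of same-MRCA families inferred to have been adjacent
## in their common ancestor, i.e. to have arrived in one horizontal
## transfer event (or to be one ancestral core block).
##
## Adjacency evolution is modeled as a binary presence-of-adjacency
## character: moving an adjacent pair apart costs one event, bringing a
## non-adjacent pair together costs one. The rearrangement score of two
## islands is cost(root non-adjacent) - cost(root adjacent), computed by
## fixed-root small parsimony over the subtree below the shared MRCA with
## missing observations as wildcards; it is bounded by [-2, 2] on a
## binary tree. Islands are merged greedily while the best score exceeds
## the threshold, over successive rounds that relax the adjacency gap.

#' Observed adjacency state of two island ends in a strain
#'
#' @param endI,endJ Vectors of gene indices (positions in gene order) of
#'   the two end families' genes in the strain, as lists keyed by
#'   replicon id.
#' @param gap Allowed number of intervening genes (0 = strictly
#'   consecutive).
#' @return `"adjacent"`, `"non-adjacent"`, or `"missing"`.
#' @keywords internal
adjacency_state <- function(endI, endJ, gap) {
  if (!length(endI) || !length(endJ)) return("missing")
  for (rep_id in intersect(names(endI), names(endJ))) {
    for (i in endI[[rep_id]]) {
      if (any(abs(endJ[[rep_id]] - i) - 1L <= gap)) return("adjacent")
    }
  }
  "non-adjacent"
}

#' Observed adjacency state of two families in a strain
#'
#' `"missing"` if either family has no gene in the strain; `"adjacent"`
#' if some gene of one family and some gene of the other lie on the same
#' replicon with at most `gap` intervening genes; `"non-adjacent"`
#' otherwise.
#'
#' @param famI,famJ Family ids.
#' @param strain Strain name.
#' @param genomes A `genome_set`.
#' @param families A `gi_families`.
#' @param gap Allowed intervening genes.
#' @return A character state.
#' @export
observed_adjacency_state <- function(famI, famJ, strain, genomes, families,
                                     gap = 0L) {
  pos <- family_positions(genomes, families)
  adjacency_state(pos[[strain]][[as.character(famI)]],
                  pos[[strain]][[as.character(famJ)]], gap)
}

## pos[[strain]][[family_id]] = list(replicon -> integer vector of
## gene-order indices).
family_positions <- function(genomes, families) {
  g <- merge(genomes$genes[, .(gene_id, strain, replicon_id, index)],
             families$membership, by = "gene_id")
  out <- list()
  for (s in unique(g$strain)) {
    gs <- g[strain == s]
    out[[s]] <- lapply(split(gs, by = "family_id", keep.by = TRUE),
                       function(d) split(d$index, d$replicon_id))
    names(out[[s]]) <- as.character(unique(gs$family_id))
  }
  out
}

## Fixed-root small parsimony cost on the subtree below `node` for a
## binary character with states adjacent (1) / non-adjacent (2).
## `states`: named character vector over the leaves under `node` with
## values "adjacent"/"non-adjacent"/"missing" (missing = wildcard).
## Returns c(cost_adjacent, cost_non_adjacent) for the two root states.
sankoff_costs <- function(tree, node, states) {
  leaf_cost <- function(st) {
    switch(st,
           adjacent = c(0, Inf),
           `non-adjacent` = c(Inf, 0),
           missing = c(0, 0),
           stop("bad adjacency state: ", st))
  }
  rec <- function(nd) {
    if (tree$is_leaf[nd]) return(leaf_cost(states[[nd]]))
    kid_costs <- lapply(tree$children[[nd]], rec)
    vapply(1:2, function(s) {
      sum(vapply(kid_costs, function(kc) {
        min(kc[s], kc[3 - s] + 1)
      }, numeric(1)))
    }, numeric(1))
  }
  if (tree$is_leaf[node]) {
    ## degenerate subtree: the observation sits at the fixed root itself
    lc <- leaf_cost(states[[node]])
    return(pmin(lc, rev(lc) + 1))
  }
  rec(node)
}

#' Rearrangement score from observed adjacency states
#'
#' `cost(root non-adjacent) - cost(root adjacent)` by fixed-root small
#' parsimony on the subtree below `node`; positive values favor
#' ancestral adjacency. Bounded by `[-2, 2]` on a binary tree.
#'
#' @param tree A `species_tree`.
#' @param node The shared MRCA node id.
#' @param states Named character vector over the leaves under `node`:
#'   `"adjacent"`, `"non-adjacent"` or `"missing"`.
#' @return Numeric score.
#' @export
rearrangement_score_states <- function(tree, node, states) {
  costs <- sankoff_costs(tree, node, states)
  costs[2] - costs[1]
}

## All four end pairings of two islands. Pairing codes give which end of
## each island is glued: "LF" = I's last family next to J's first, etc.
## Returns list(score, pairing) with the maximum score and the first
## argmax in the fixed order LF, LL, FF, FL.
island_pair_score <- function(isl_i, isl_j, tree, node, pos, gap) {
  leaves <- tree$leaves_under[[node]]
  ends_i <- list(F = isl_i$fams[1], L = isl_i$fams[length(isl_i$fams)])
  ends_j <- list(F = isl_j$fams[1], L = isl_j$fams[length(isl_j$fams)])
  pairings <- c("LF", "LL", "FF", "FL")
  best_score <- -Inf; best_pairing <- NULL
  for (pg in pairings) {
    fi <- ends_i[[substr(pg, 1, 1)]]
    fj <- ends_j[[substr(pg, 2, 2)]]
    states <- vapply(leaves, function(s) {
      adjacency_state(pos[[s]][[as.character(fi)]],
                      pos[[s]][[as.character(fj)]], gap)
    }, character(1))
    names(states) <- leaves
    sc <- rearrangement_score_states(tree, node, states)
    if (sc > best_score) { best_score <- sc; best_pairing <- pg }
  }
  list(score = best_score, pairing = best_pairing)
}

## Concatenate family orders according to the winning end pairing, so the
## glued ends are internal neighbors of the merged order.
merge_orders <- function(fams_i, fams_j, pairing) {
  switch(pairing,
         LF = c(fams_i, fams_j),
         LL = c(fams_i, rev(fams_j)),
         FF = c(rev(fams_i), fams_j),
         FL = c(fams_j, fams_i))
}

#' Group families into islands
#'
#' Families are partitioned by MRCA node; within each group, one
#' single-family island per family is created, then islands are merged
#' greedily: in each relaxation round (adjacency gap allowances from
#' `merge_gap_schedule`), the best-scoring island pair is merged while
#' its rearrangement score exceeds `merge_threshold` (ties broken by the
#' smallest island-id pair), concatenating family orders according to the
#' winning end pairing. Islands with different MRCAs are never merged.
#'
#' @param genomes A `genome_set`.
#' @param tree A `species_tree`.
#' @param families A `gi_families`.
#' @param config Optional configuration (`merge_threshold`,
#'   `merge_gap_schedule`).
#' @return A `gi_islands` object: list with `islands` (a `data.table`
#'   with `island_id`, `mrca`, `n_families`, `classification`, `branch`)
#'   and `fams` (list of ordered family-id vectors keyed by island id),
#'   plus the `families` object it was built from.
#' @export
merge_islands <- function(genomes, tree, families, config = NULL) {
  cfg <- as_config(config)
  pos <- family_positions(genomes, families)
  fam_dt <- families$families
  out_islands <- list()
  for (node in unique(fam_dt$mrca)) {
    fams_here <- fam_dt[mrca == node, family_id]
    islands <- lapply(fams_here, function(f) list(id = f, fams = f))
    names(islands) <- as.character(fams_here)
    if (length(islands) > 1) {
      for (gap in sort(unique(as.integer(cfg$merge_gap_schedule)))) {
        islands <- merge_round(islands, tree, node, pos, gap,
                               cfg$merge_threshold)
        if (length(islands) == 1) break
      }
    }
    out_islands <- c(out_islands, lapply(islands, function(isl) {
      list(mrca = node, fams = isl$fams)
    }))
  }
  ## deterministic island ids: order groups by tree pre-order, then by
  ## smallest member family id
  ord <- order(match(vapply(out_islands, `[[`, character(1), "mrca"),
                     tree$preorder),
               vapply(out_islands, function(i) min(i$fams), numeric(1)))
  out_islands <- out_islands[ord]
  ids <- sprintf("isl%04d", seq_along(out_islands))
  obj <- list(
    islands = data.table(
      island_id = ids,
      mrca = vapply(out_islands, `[[`, character(1), "mrca"),
      n_families = vapply(out_islands, function(i) length(i$fams),
                          integer(1))),
    fams = setNames(lapply(out_islands, `[[`, "fams"), ids),
    families = families)
  class(obj) <- "gi_islands"
  classify_islands(obj, tree)
}

## One relaxation round of greedy merging at a fixed gap allowance.
## Candidate pairs are limited to islands with adjacency evidence (the
## score can only be positive if some strain observes the ends adjacent);
## after a merge only the merged island's scores change.
merge_round <- function(islands, tree, node, pos, gap, threshold) {
  repeat {
    cand <- candidate_pairs(islands, node, pos, gap)
    if (!nrow(cand)) break
    scores <- vector("list", nrow(cand))
    for (i in seq_len(nrow(cand))) {
      scores[[i]] <- island_pair_score(islands[[cand$i[i]]],
                                       islands[[cand$j[i]]],
                                       tree, node, pos, gap)
    }
    cand[, `:=`(score = vapply(scores, `[[`, numeric(1), "score"),
                pairing = vapply(scores, `[[`, character(1), "pairing"))]
    repeat {
      live <- cand[score > threshold]
      if (!nrow(live)) break
      setorder(live, -score, i, j)
      wi <- live$i[1]; wj <- live$j[1]
      merged <- list(
        id = min(islands[[wi]]$id, islands[[wj]]$id),
        fams = merge_orders(islands[[wi]]$fams, islands[[wj]]$fams,
                            live$pairing[1]))
      islands[[wi]] <- NULL
      islands[[wj]] <- NULL
      islands[[as.character(merged$id)]] <- merged
      if (length(islands) == 1) return(islands)
      ## drop stale pairs, rescore pairs involving the merged island
      cand <- cand[i != wi & j != wi & i != wj & j != wj]
      newc <- candidate_pairs(islands, node, pos, gap,
                              only = as.character(merged$id))
      if (nrow(newc)) {
        sc <- vector("list", nrow(newc))
        for (k in seq_len(nrow(newc))) {
          sc[[k]] <- island_pair_score(islands[[newc$i[k]]],
                                       islands[[newc$j[k]]],
                                       tree, node, pos, gap)
        }
        newc[, `:=`(score = vapply(sc, `[[`, numeric(1), "score"),
                    pairing = vapply(sc, `[[`, character(1), "pairing"))]
        cand <- rbindlist(list(cand, newc))
      }
    }
    break
  }
  islands
}

## Island pairs whose end families have genes within `gap` intervening
## genes in at least one strain. Keys `i`, `j` are island list names with
## as.numeric(i) < as.numeric(j); `only` restricts to pairs involving one
## island.
candidate_pairs <- function(islands, node, pos, gap, only = NULL) {
  keys <- names(islands)
  end_fams <- lapply(islands, function(isl) {
    unique(c(isl$fams[1], isl$fams[length(isl$fams)]))
  })
  ## map end family id -> island key
  fam2isl <- data.table(
    fam = as.character(unlist(end_fams, use.names = FALSE)),
    isl = rep(keys, lengths(end_fams)))
  found <- list()
  for (s in names(pos)) {
    ps <- pos[[s]]
    present <- fam2isl[fam %in% names(ps)]
    if (nrow(present) < 2) next
    ## flatten: one row per (gene position) of an end family
    rows <- present[, {
      byrep <- ps[[fam]]
      data.table(replicon = rep(names(byrep), lengths(byrep)),
                 idx = unlist(byrep, use.names = FALSE))
    }, by = .(fam, isl)]
    setorder(rows, replicon, idx)
    for (rep_id in unique(rows$replicon)) {
      rr <- rows[replicon == rep_id]
      n <- nrow(rr)
      for (a in seq_len(n)) {
        b <- a + 1L
        while (b <= n && rr$idx[b] - rr$idx[a] - 1L <= gap) {
          if (rr$isl[a] != rr$isl[b]) {
            found[[length(found) + 1L]] <- c(rr$isl[a], rr$isl[b])
          }
          b <- b + 1L
        }
      }
    }
  }
  if (!length(found)) {
    return(data.table(i = character(0), j = character(0)))
  }
  dt <- as.data.table(do.call(rbind, found))
  setnames(dt, c("i", "j"))
  swap <- as.numeric(dt$i) > as.numeric(dt$j)
  tmp <- dt$i[swap]; dt[swap, i := j]; dt[swap, j := tmp]
  dt <- unique(dt)
  if (!is.null(only)) dt <- dt[i == only | j == only]
  dt[]
}

#' Classify islands as core or branch-specific insertions
#'
#' An island whose MRCA lies inside the focal clade (at or below the
#' focal root) is an insertion on the branch entering its MRCA node;
#' any other island is core relative to the focal clade. An island with
#' MRCA exactly at the focal root is an insertion on the branch entering
#' the focal clade (it is absent from the outgroups).
#'
#' @param islands A `gi_islands`.
#' @param tree A `species_tree`.
#' @return `islands` with `classification` (`"core"`/`"insertion"`) and
#'   `branch` (MRCA node id for insertions, `NA` for core) columns set.
#' @export
classify_islands <- function(islands, tree) {
  isl <- islands$islands
  inside <- vapply(isl$mrca, function(nd) {
    tree_is_ancestor(tree, tree$focal_root, nd)
  }, logical(1))
  isl[, classification := ifelse(inside, "insertion", "core")]
  isl[, branch := ifelse(inside, mrca, NA_character_)]
  islands$islands <- isl
  islands
}

#' @export
print.gi_islands <- function(x, ...) {
  cat(sprintf("gi_islands: %d islands (%d insertion, %d core) over %d families\n",
              nrow(x$islands), sum(x$islands$classification == "insertion"),
              sum(x$islands$classification == "core"),
              sum(x$islands$n_families)))
  invisible(x)
}

#' Write islands as TSV
#'
#' Columns: `island_id`, `mrca`, `classification`, `branch`,
#' `family_ids` (ordered, comma-separated), and per-strain gene spans
#' (`strain:replicon:start-end`, semicolon-separated).
#'
#' @param islands A `gi_islands`.
#' @param genomes A `genome_set`.
#' @param path Output file.
#' @export
write_islands_tsv <- function(islands, genomes, path) {
  gm <- merge(genomes$genes, islands$families$membership, by = "gene_id")
  isl <- islands$islands
  spans <- vapply(isl$island_id, function(iid) {
    fams <- islands$fams[[iid]]
    gg <- gm[family_id %in% fams]
    if (!nrow(gg)) return("")
    sp <- gg[, .(lo = min(start), hi = max(end)), by = .(strain, replicon_id)]
    setorder(sp, strain, replicon_id)
    paste(sprintf("%s:%s:%d-%d", sp$strain, sp$replicon_id, sp$lo, sp$hi),
          collapse = ";")
  }, character(1))
  out <- copy(isl)
  out[, family_ids := vapply(island_id, function(iid) {
    paste(islands$fams[[iid]], collapse = ",")
  }, character(1))]
  out[, spans := spans]
  fwrite(out, path, sep = "\t")
  invisible(path)
}
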