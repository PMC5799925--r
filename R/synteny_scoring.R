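## Neighborhood synteny scores.
##
## Two measures of neighborhood conservation are attached to each
## candidate pair: a broad "core synteny" score over a window of
## conservative core genes, and a "local synteny" score over all genes in
## a small window, matched greedily by normalized similarity.

## For each gene: core-set ids of the nearest `window` core genes on each
## side (same replicon, focal gene excluded, truncated at replicon ends).
## Returns a list keyed by gene_id.
core_neighborhoods <- function(genomes, cores, window) {
  core_of <- setNames(cores$core_set, cores$gene_id)
  genes <- genomes$genes
  out <- setNames(vector("list", nrow(genes)), genes$gene_id)
  by_rep <- split(seq_len(nrow(genes)),
                  paste(genes$strain, genes$replicon_id, sep = "\r"))
  for (rows in by_rep) {
    ids <- genes$gene_id[rows][order(genes$index[rows])]
    cs <- unname(core_of[ids])          # NA for non-core genes
    core_pos <- which(!is.na(cs))
    for (i in seq_along(ids)) {
      below <- core_pos[core_pos < i]
      above <- core_pos[core_pos > i]
      take <- c(tail(below, window), head(above, window))
      out[[ids[i]]] <- cs[take]
    }
  }
  out
}

## Gene ids within W positions of each gene (same replicon, excl. self).
local_neighborhoods <- function(genomes, W) {
  genes <- genomes$genes
  out <- setNames(vector("list", nrow(genes)), genes$gene_id)
  by_rep <- split(seq_len(nrow(genes)),
                  paste(genes$strain, genes$replicon_id, sep = "\r"))
  for (rows in by_rep) {
    ids <- genes$gene_id[rows][order(genes$index[rows])]
    n <- length(ids)
    for (i in seq_len(n)) {
      lo <- max(1L, i - W); hi <- min(n, i + W)
      out[[ids[i]]] <- ids[setdiff(lo:hi, i)]
    }
  }
  out
}

#' Core synteny scores for candidate pairs
#'
#' Each gene's core neighborhood is the nearest `core_synteny_window`
#' conservative core genes on each side of it on its replicon (so up to
#' 20 core genes at the default of 10 per side). The directional score
#' A to B is the number of core ortholog sets shared between the two
#' neighborhoods divided by the number of core genes in A's neighborhood;
#' the reported score is the mean of the two directions and lies in
#' `[0, 1]`. A neighborhood with zero core genes (short contig)
#' contributes a directional score of 0.
#'
#' @param genomes A `genome_set`.
#' @param pairs Candidate pairs (`g1`, `g2`).
#' @param cores Core sets from [find_conservative_cores()].
#' @param config Optional configuration (`core_synteny_window`).
#' @return `pairs` with a `core_syn` column added.
#' @export
compute_core_synteny <- function(genomes, pairs, cores, config = NULL) {
  cfg <- as_config(config)
  nb <- core_neighborhoods(genomes, cores, cfg$core_synteny_window)
  pairs <- copy(pairs)
  n <- nrow(pairs)
  sc <- numeric(n)
  warned <- FALSE
  for (i in seq_len(n)) {
    na <- nb[[pairs$g1[i]]]; nbv <- nb[[pairs$g2[i]]]
    if (!length(na) || !length(nbv)) {
      if (!warned) {
        gi_warn("gene with an empty core neighborhood: directional core ",
                "synteny taken as 0")
        warned <- TRUE
      }
    }
    shared_ab <- sum(na %in% nbv)
    shared_ba <- sum(nbv %in% na)
    dab <- if (length(na)) shared_ab / length(na) else 0
    dba <- if (length(nbv)) shared_ba / length(nbv) else 0
    sc[i] <- (dab + dba) / 2
  }
  pairs[, core_syn := sc]
  pairs[]
}

#' Core synteny score for a single gene pair
#'
#' @param geneA,geneB Gene ids.
#' @inheritParams compute_core_synteny
#' @return Score in `[0, 1]`.
#' @export
compute_core_synteny_score <- function(geneA, geneB, genomes, cores,
                                       config = NULL) {
  p <- data.table(g1 = geneA, g2 = geneB)
  compute_core_synteny(genomes, p, cores, config)$core_syn
}

## Greedy without-replacement matching of neighbor pairs by descending
## norm score; rows must be pre-sorted by (-norm, na_gene, nb_gene).
## Returns sum of the up-to-T best matched scores / T.
greedy_local_score <- function(na_gene, nb_gene, norm, T) {
  used_a <- character(0); used_b <- character(0)
  total <- 0; taken <- 0L
  for (i in seq_along(norm)) {
    if (taken >= T) break
    if (na_gene[i] %in% used_a || nb_gene[i] %in% used_b) next
    used_a <- c(used_a, na_gene[i]); used_b <- c(used_b, nb_gene[i])
    total <- total + norm[i]; taken <- taken + 1L
  }
  total / T
}

#' Local synteny scores for candidate pairs
#'
#' For genes A and B, take all genes within `local_synteny_window` (W)
#' positions on either side of each. Neighbor pairs across the two
#' windows that have a normalized score are matched greedily without
#' replacement in order of descending norm score (ties broken by gene
#' ids); the local synteny score is the sum of the up-to-`T` best matched
#' scores divided by `T` (missing matches contribute 0). The matching is
#' deliberately greedy, not optimal.
#'
#' @param genomes A `genome_set`.
#' @param pairs Candidate pairs with `norm` scores (see
#'   [compute_norm_scores()]).
#' @param config Optional configuration (`local_synteny_window`,
#'   `local_synteny_top`).
#' @return `pairs` with a `local_syn` column added.
#' @export
compute_local_synteny <- function(genomes, pairs, config = NULL) {
  cfg <- as_config(config)
  W <- cfg$local_synteny_window; T <- cfg$local_synteny_top
  nb <- local_neighborhoods(genomes, W)
  pairs <- copy(pairs)
  pairs[, pair_id := .I]
  ## neighbor map as a long table: gene -> each of its window neighbors
  nb_dt <- data.table(gene = rep(names(nb), lengths(nb)),
                      neighbor = unlist(nb, use.names = FALSE))
  if (!"norm" %in% names(pairs)) stop("pairs must carry norm scores")
  norms <- pairs[!is.na(norm), .(g1, g2, norm)]
  cand <- pairs[, .(g1, g2, pair_id)]
  ## scored cross pairs (x, y): x in N(A) iff A in N(x); expand each
  ## scored pair to the candidate pairs whose windows contain it, in
  ## chunks so the (scored pair x window x window) intermediate stays
  ## bounded regardless of genome count.
  expand <- function(chunk, xcol, ycol) {
    dtx <- merge(chunk, nb_dt, by.x = xcol, by.y = "gene",
                 allow.cartesian = TRUE)
    setnames(dtx, "neighbor", "A")
    dty <- merge(dtx, nb_dt, by.x = ycol, by.y = "gene",
                 allow.cartesian = TRUE)
    setnames(dty, "neighbor", "B")
    dty
  }
  chunk_size <- 2500L
  starts <- seq(1L, max(nrow(norms), 1L), by = chunk_size)
  pieces <- vector("list", length(starts))
  for (ci in seq_along(starts)) {
    rows <- starts[ci]:min(starts[ci] + chunk_size - 1L, nrow(norms))
    chunk <- norms[rows]
    ## both orientations: (g1 near A, g2 near B) and (g2 near A, g1 near B)
    e1 <- expand(chunk, "g1", "g2")[, .(A, B, na_gene = g1, nb_gene = g2,
                                        norm)]
    e2 <- expand(chunk, "g2", "g1")[, .(A, B, na_gene = g2, nb_gene = g1,
                                        norm)]
    ee <- rbindlist(list(e1, e2))
    pk <- pair_key(ee$A, ee$B)
    swapped <- ee$A > ee$B
    ee[, `:=`(A = pk$g1, B = pk$g2)]
    tmp <- ee$na_gene[swapped]
    ee[swapped, na_gene := nb_gene]
    ee[swapped, nb_gene := tmp]
    ## keep only rows for actual candidate pairs (A,B)
    pieces[[ci]] <- merge(ee, cand, by.x = c("A", "B"),
                          by.y = c("g1", "g2"))
  }
  ee <- unique(rbindlist(pieces))
  setorder(ee, pair_id, -norm, na_gene, nb_gene)
  sc <- ee[, .(local_syn = greedy_local_score(na_gene, nb_gene, norm, T)),
           by = pair_id]
  pairs[, local_syn := 0]
  pairs[sc, on = "pair_id", local_syn := i.local_syn]
  pairs[, pair_id := NULL]
  pairs[]
}

#' Local synteny score for a single gene pair
#'
#' @param geneA,geneB Gene ids.
#' @param genomes A `genome_set`.
#' @param pairs Scored candidate pairs with `norm`.
#' @param config Optional configuration.
#' @return The local synteny score (a real number; 0 when no neighbor
#'   pair has a score).
#' @export
compute_local_synteny_score <- function(geneA, geneB, genomes, pairs,
                                        config = NULL) {
  one <- data.table(g1 = min(geneA, geneB), g2 = max(geneA, geneB))
  withnorm <- merge(one, pairs[, .(g1, g2, norm)], by = c("g1", "g2"),
                    all.x = TRUE)
  full <- rbindlist(list(withnorm, pairs[, .(g1, g2, norm)]))
  full <- unique(full, by = c("g1", "g2"))
  compute_local_synteny(genomes, full, config)[g1 == one$g1 & g2 == one$g2,
                                               local_syn]
}
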