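## Independent oracles used to freeze expected values. These deliberately
## share no code with the package implementation: plain dynamic
## programming, exhaustive enumeration, and full rescans instead of the
## package's vectorized / indexed paths.

## Affine-gap global alignment score by the Gotoh recursion, with a gap
## of length L costing open + (L-1)*ext.
oracle_global_align <- function(a, b, mat, open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes a)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes b)
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -open - (i - 1) * ext
  for (j in seq_len(m)) Iy[1, j + 1] <- -open - (j - 1) * ext
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[av[i], bv[j]]
      M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open, Ix[i, j + 1] - ext,
                              Iy[i, j + 1] - open)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open, Iy[i + 1, j] - ext,
                              Ix[i + 1, j] - open)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

## Raw score via the oracle aligner and the package's floor/ceiling
## definitions computed from first principles.
oracle_raw_score <- function(a, b, mat, open = 11, ext = 1) {
  self <- function(p) {
    aa <- strsplit(p, "")[[1]]
    sum(mat[cbind(aa, aa)])
  }
  la <- nchar(a); lb <- nchar(b)
  flo <- -2 * open - ext * ((la - 1) + (lb - 1))
  ceil <- if (la < lb) self(a) else if (lb < la) self(b) else
    min(self(a), self(b))
  g <- oracle_global_align(a, b, mat, open, ext)
  min(1, max(0, (g - flo) / (ceil - flo)))
}

## Fixed-root parsimony cost by exhaustive enumeration over all internal
## node states (and all states of missing leaves) in the subtree below
## `node`. States: "adjacent"/"non-adjacent"; `states` is a named vector
## over the leaves under `node` ("missing" = unconstrained).
oracle_parsimony_cost <- function(tree, node, states, root_state) {
  stopifnot(!tree$is_leaf[node])
  subtree_nodes <- function(nd) {
    if (tree$is_leaf[nd]) return(nd)
    c(nd, unlist(lapply(tree$children[[nd]], subtree_nodes)))
  }
  nodes <- subtree_nodes(node)
  leaves <- nodes[tree$is_leaf[nodes]]
  internals <- setdiff(nodes, leaves)
  free <- c(setdiff(internals, node), leaves[states[leaves] == "missing"])
  fixed <- setNames(rep(NA_character_, length(nodes)), nodes)
  fixed[node] <- root_state
  for (lf in leaves) {
    if (states[[lf]] != "missing") fixed[lf] <- states[[lf]]
  }
  vals <- c("adjacent", "non-adjacent")
  best <- Inf
  n_free <- length(free)
  for (mask in seq_len(2^n_free) - 1L) {
    assign_ <- fixed
    if (n_free > 0) {
      bits <- as.integer(intToBits(mask))[seq_len(n_free)]
      assign_[free] <- vals[bits + 1L]
    }
    cost <- 0L
    for (nd in setdiff(nodes, node)) {
      par <- tree$parent[nd]
      if (assign_[nd] != assign_[par]) cost <- cost + 1L
    }
    best <- min(best, cost)
  }
  best
}

oracle_rearrangement_score <- function(tree, node, states) {
  oracle_parsimony_cost(tree, node, states, "non-adjacent") -
    oracle_parsimony_cost(tree, node, states, "adjacent")
}

## Brute-force tree-aware single-linkage families: materializes groups,
## seeds and acceptance tests with full rescans of the score table at
## every step. For instances of a few dozen genes only.
oracle_build_families <- function(genomes, tree, pairs, cfg) {
  genes <- genomes$genes
  strain_of <- setNames(genes$strain, genes$gene_id)
  score <- function(x, y, col) {
    r <- pairs[(pairs$g1 == x & pairs$g2 == y) |
               (pairs$g1 == y & pairs$g2 == x), ]
    if (nrow(r) == 0) return(NA_real_)
    r[[col]][1]
  }
  eff_score <- function(x, y) {
    raw <- score(x, y, "raw")
    if (is.na(raw)) return(NA_real_)
    if (!is.na(score(x, y, "core_syn")) &&
        score(x, y, "core_syn") >= cfg$family_bonus_core &&
        score(x, y, "local_syn") >= cfg$family_bonus_local) {
      raw <- min(1, raw + cfg$family_bonus)
    }
    raw
  }
  eligible <- function(x, y) {
    n <- score(x, y, "norm")
    if (is.na(n)) return(FALSE)
    n >= cfg$family_norm_floor &&
      score(x, y, "core_syn") >= cfg$family_core_syn_floor &&
      score(x, y, "local_syn") >= cfg$family_local_syn_floor
  }
  unclustered <- setNames(rep(TRUE, nrow(genes)), genes$gene_id)
  fams <- list()
  internals <- tree$preorder[!tree$is_leaf[tree$preorder]]
  for (node in internals) {
    kids <- tree$children[[node]]
    left <- tree$leaves_under[[kids[1]]]
    right <- tree$leaves_under[[kids[2]]]
    repeat_outer <- TRUE
    ## seeds over currently unclustered genes
    g1s <- names(unclustered)[unclustered & strain_of[names(unclustered)] %in% left]
    g2s <- names(unclustered)[unclustered & strain_of[names(unclustered)] %in% right]
    seed_list <- list()
    for (x in c(g1s, g2s)) {
      other <- if (strain_of[x] %in% left) g2s else g1s
      best_raw <- -Inf; best_partner <- NULL
      for (y in sort(other)) {
        r <- score(x, y, "raw")
        if (!is.na(r) && eligible(x, y) && r > best_raw) {
          best_raw <- r; best_partner <- y
        }
      }
      if (!is.null(best_partner)) {
        pair <- sort(c(x, best_partner))
        seed_list[[paste(pair, collapse = "|")]] <-
          list(g1 = pair[1], g2 = pair[2], score = best_raw)
      }
    }
    if (!length(seed_list)) next
    sdt <- do.call(rbind, lapply(seed_list, function(s) {
      data.frame(g1 = s$g1, g2 = s$g2, score = s$score)
    }))
    sdt <- sdt[order(-sdt$score, sdt$g1, sdt$g2), ]
    for (k in seq_len(nrow(sdt))) {
      a <- sdt$g1[k]; b <- sdt$g2[k]; sc <- sdt$score[k]
      if (!unclustered[a] || !unclustered[b]) next
      members <- c(a, b)
      unclustered[members] <- FALSE
      changed <- TRUE
      while (changed) {
        changed <- FALSE
        pool <- names(unclustered)[unclustered &
                                   strain_of[names(unclustered)] %in%
                                     c(left, right)]
        for (cand in sort(pool)) {
          for (mem in members) {
            ef <- eff_score(cand, mem)
            if (!is.na(ef) && ef >= sc && eligible(cand, mem)) {
              members <- c(members, cand)
              unclustered[cand] <- FALSE
              changed <- TRUE
              break
            }
          }
        }
      }
      fams[[length(fams) + 1L]] <- sort(members)
    }
  }
  for (gid in sort(names(unclustered)[unclustered])) {
    fams[[length(fams) + 1L]] <- gid
  }
  fams
}

## Canonical form of a gene partition for comparison.
canonical_partition <- function(member_lists) {
  unname(sort(vapply(member_lists, function(m) paste(sort(m), collapse = ","),
                     character(1))))
}
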