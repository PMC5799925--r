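## Hand-built family layouts. `layout` is a list strain -> vector of
## family ids in gene order (NA = gene outside any tracked family gets a
## fresh singleton family); builds a genome_set and gi_families with one
## gene per family occurrence.
make_family_layout <- function(layout, tree) {
  set.seed(31)
  rows <- list()
  mem <- list()
  extra <- 1000L
  for (s in names(layout)) {
    fams <- layout[[s]]
    n <- length(fams)
    prots <- replicate(n, rand_prot(20))
    nt <- 3L * nchar(prots) + 3L
    starts <- cumsum(c(100L, head(nt + 100L, -1L)))
    ids <- sprintf("%s_%05d", s, seq_len(n))
    rows[[s]] <- data.table::data.table(
      gene_id = ids, strain = s, replicon_id = paste0(s, "_chr"),
      index = seq_len(n) - 1L, start = starts, end = starts + nt,
      strand = "+", protein = prots)
    for (i in seq_len(n)) {
      fid <- fams[i]
      if (is.na(fid)) { fid <- extra; extra <- extra + 1L }
      mem[[length(mem) + 1L]] <- data.table::data.table(
        gene_id = ids[i], family_id = as.integer(fid))
    }
  }
  genomes <- new_genome_set(data.table::rbindlist(rows))
  membership <- data.table::rbindlist(mem)
  strain_of <- setNames(genomes$genes$strain, genomes$genes$gene_id)
  fam_ids <- sort(unique(membership$family_id))
  families <- data.table::rbindlist(lapply(fam_ids, function(fid) {
    strains <- unique(unname(strain_of[membership[family_id == fid,
                                                  gene_id]]))
    data.table::data.table(
      family_id = fid, founding_node = tree_mrca(tree, strains),
      mrca = tree_mrca(tree, strains),
      n_genes = nrow(membership[family_id == fid]),
      seed_g1 = NA_character_, seed_g2 = NA_character_,
      seed_score = NA_real_)
  }))
  out <- structure(list(families = families, membership = membership),
                   class = "gi_families")
  out$genomes <- genomes
  out
}

cherry3 <- function() parse_species_tree("((A:1,B:1):1,C:1);",
                                         focal_clade = c("A", "B"))

test_that("observed adjacency state counts intervening genes against the gap", {
  tr <- cherry3()
  ## strain A: f1 at index 7, f2 at index 8, f3 at index 10
  layout <- list(A = c(rep(NA, 7), 1, 2, NA, 3), B = c(1, 2, 3))
  fx <- make_family_layout(layout, tr)
  expect_equal(observed_adjacency_state(1, 2, "A", fx$genomes, fx, gap = 0),
               "adjacent")
  ## indices 8 and 10: one intervening gene
  expect_equal(observed_adjacency_state(2, 3, "A", fx$genomes, fx, gap = 0),
               "non-adjacent")
  expect_equal(observed_adjacency_state(2, 3, "A", fx$genomes, fx, gap = 1),
               "adjacent")
  ## indices 7 and 10: two intervening genes
  expect_equal(observed_adjacency_state(1, 3, "A", fx$genomes, fx, gap = 1),
               "non-adjacent")
  expect_equal(observed_adjacency_state(1, 3, "A", fx$genomes, fx, gap = 2),
               "adjacent")
  ## family absent from the strain -> missing
  expect_equal(observed_adjacency_state(1, 2, "C", fx$genomes, fx, gap = 0),
               "missing")
})

test_that("cherry rearrangement scores match the enumeration oracle", {
  tr <- cherry3()
  node <- tree_mrca(tr, c("A", "B"))
  cases <- list(
    list(states = c(A = "adjacent", B = "adjacent"), expected = 2),
    list(states = c(A = "adjacent", B = "non-adjacent"), expected = 0),
    list(states = c(A = "non-adjacent", B = "non-adjacent"), expected = -2),
    list(states = c(A = "missing", B = "adjacent"), expected = 1),
    list(states = c(A = "missing", B = "missing"), expected = 0))
  for (cs in cases) {
    got <- rearrangement_score_states(tr, node, cs$states)
    expect_equal(got, cs$expected, info = paste(cs$states, collapse = "/"))
    expect_equal(got, oracle_rearrangement_score(tr, node, cs$states),
                 info = paste("oracle", paste(cs$states, collapse = "/")))
  }
})

test_that("fixed-root parsimony equals exhaustive enumeration on trees up to 6 leaves", {
  topologies <- c(
    "((A:1,B:1):1,(C:1,D:1):1);",
    "(((A:1,B:1):1,C:1):1,D:1);",
    "((((A:1,B:1):1,C:1):1,D:1):1,E:1);",
    "(((A:1,B:1):1,(C:1,D:1):1):1,(E:1,F:1):1);")
  vals <- c("adjacent", "non-adjacent", "missing")
  set.seed(909)
  for (nwk in topologies) {
    tr <- parse_species_tree(nwk, focal_clade = c("A", "B"))
    internal <- tr$preorder[!tr$is_leaf[tr$preorder]]
    for (i in 1:20) {
      node <- sample(internal, 1)
      leaves <- tr$leaves_under[[node]]
      states <- setNames(sample(vals, length(leaves), replace = TRUE),
                         leaves)
      got <- rearrangement_score_states(tr, node, states)
      expect_equal(got, oracle_rearrangement_score(tr, node, states),
                   info = paste(nwk, node, paste(states, collapse = "/")))
      ## the score bound holds on every input
      expect_gte(got, -2); expect_lte(got, 2)
    }
  }
})

test_that("consecutive families in both leaves of a cherry merge into one ordered island", {
  tr <- cherry3()
  layout <- list(A = c(1, 2, 3), B = c(1, 2, 3), C = c(NA, NA, NA))
  fx <- make_family_layout(layout, tr)
  isl <- merge_islands(fx$genomes, tr, fx)
  node <- tree_mrca(tr, c("A", "B"))
  merged <- isl$islands[mrca == node]
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$n_families, 3L)
  fams <- isl$fams[[merged$island_id]]
  expect_true(identical(fams, c(1L, 2L, 3L)) ||
              identical(fams, c(3L, 2L, 1L)))
})

test_that("islands with no adjacency evidence stay separate", {
  tr <- cherry3()
  ## f1 and f2 are far apart in both strains (> max gap allowance)
  layout <- list(A = c(1, rep(NA, 8), 2), B = c(1, rep(NA, 8), 2),
                 C = c(NA, NA))
  fx <- make_family_layout(layout, tr)
  isl <- merge_islands(fx$genomes, tr, fx)
  node <- tree_mrca(tr, c("A", "B"))
  expect_equal(nrow(isl$islands[mrca == node]), 2L)
})

test_that("a one-gene interruption is bridged in the gap-1 relaxation round", {
  tr <- cherry3()
  ## f1 and f2 separated by one strain-specific gene in both leaves
  layout <- list(A = c(1, NA, 2), B = c(1, NA, 2), C = c(NA))
  fx <- make_family_layout(layout, tr)
  node <- tree_mrca(tr, c("A", "B"))
  ## at gap 0 they are non-adjacent in both strains: score -2, no merge
  expect_equal(observed_adjacency_state(1, 2, "A", fx$genomes, fx, gap = 0),
               "non-adjacent")
  cfg0 <- default_config(); cfg0$merge_gap_schedule <- 0L
  isl0 <- merge_islands(fx$genomes, tr, fx, cfg0)
  expect_equal(nrow(isl0$islands[mrca == node]), 2L)
  ## the default schedule reaches gap 1 and merges them
  isl <- merge_islands(fx$genomes, tr, fx)
  expect_equal(nrow(isl$islands[mrca == node]), 1L)
})

test_that("merging conserves the family multiset and never mixes MRCAs", {
  fx <- make_hgt_fixture()
  res <- detect_islands(fx$genomes, fx$tree)
  isl <- res$islands
  all_fams <- sort(unlist(isl$fams, use.names = FALSE))
  expect_equal(all_fams, sort(res$families$families$family_id))
  for (iid in isl$islands$island_id) {
    fams <- isl$fams[[iid]]
    mrcas <- res$families$families[family_id %in% fams, unique(mrca)]
    expect_equal(mrcas, isl$islands[island_id == iid, mrca])
  }
})

test_that("classification separates core islands from branch insertions", {
  tr <- cherry3()
  node_ab <- tree_mrca(tr, c("A", "B"))
  layout <- list(A = c(1, 10), B = c(1, 10), C = c(1))
  fx <- make_family_layout(layout, tr)
  isl <- merge_islands(fx$genomes, tr, fx)
  ## family 1 spans all strains -> MRCA at root -> core
  root_isl <- isl$islands[mrca == "N1"]
  expect_true(all(root_isl$classification == "core"))
  expect_true(all(is.na(root_isl$branch)))
  ## family 10 only in A,B -> MRCA = focal root -> insertion on the
  ## branch entering the focal clade
  ab_isl <- isl$islands[mrca == node_ab]
  expect_true(all(ab_isl$classification == "insertion"))
  expect_true(all(ab_isl$branch == node_ab))
  ## leaf-specific singletons -> insertion on the terminal branch
  leafy <- isl$islands[mrca == "A"]
  expect_true(all(leafy$classification == "insertion"))
  expect_true(all(leafy$branch == "A"))
})
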