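## Hand-built instances: genomes via make_genomes, scores via
## manual_pairs (norm/synteny default to comfortably passing values so
## individual links can be degraded selectively).

test_that("seed generation pairs each gene with its best cross-group partner", {
  gs <- make_genomes(list(A = c("MKLVW", "MPPPW"), B = c("MKLVW", "MPPPW")))
  tr <- parse_species_tree("(A:1,B:1);", focal_clade = "A")
  ## a1-b1 strong, a2 has no candidate partner at all
  pairs <- manual_pairs("A_00001", "B_00001", raw = 0.9)
  seeds <- generate_seeds(tr, "N1", gs, pairs)
  expect_equal(nrow(seeds), 1L)
  expect_equal(seeds$g1, "A_00001")
  expect_equal(seeds$g2, "B_00001")
  expect_equal(seeds$score, 0.9)
  ## two seeds are ordered by descending score
  pairs2 <- rbind(manual_pairs("A_00001", "B_00001", raw = 0.7),
                  manual_pairs("A_00002", "B_00002", raw = 0.9))
  seeds2 <- generate_seeds(tr, "N1", gs, pairs2)
  expect_equal(seeds2$score, c(0.9, 0.7))
  ## the same pair proposed from both directions yields one seed
  expect_equal(nrow(seeds2), 2L)
})

test_that("orthologs across the clade form one family at the root", {
  gs <- make_trio()
  tr <- trio_tree()
  sc <- score_genomes(gs)
  fams <- build_families(gs, tr, sc$pairs)
  expect_equal(nrow(fams$families), 12L)
  expect_true(all(fams$families$mrca == "N1"))
  expect_true(all(fams$families$n_genes == 3L))
  ## partition: every gene in exactly one family
  expect_setequal(fams$membership$gene_id, gs$genes$gene_id)
  expect_equal(anyDuplicated(fams$membership$gene_id), 0L)
})

test_that("a pair present only inside the focal clade founds a family at its MRCA", {
  ## genes 1..3 in all strains; gene 4 only in A and B
  set.seed(17)
  base <- replicate(3, rand_prot(60))
  isl <- rand_prot(60)
  gs <- make_genomes(list(
    A = c(vapply(base, function(p) mutate_prot(p, 2), character(1)), isl),
    B = c(vapply(base, function(p) mutate_prot(p, 2), character(1)),
          mutate_prot(isl, 1)),
    C = vapply(base, function(p) mutate_prot(p, 4), character(1))))
  tr <- trio_tree()
  sc <- score_genomes(gs)
  fams <- build_families(gs, tr, sc$pairs)
  fam_ab <- fams$membership[gene_id == "A_00004", family_id]
  expect_setequal(fams$membership[family_id == fam_ab, gene_id],
                  c("A_00004", "B_00004"))
  expect_equal(fams$families[family_id == fam_ab, mrca], "N2")
  expect_equal(fams$families[family_id == fam_ab, founding_node], "N2")
})

test_that("a translocated homolog below the core synteny floor is excluded", {
  gs <- make_genomes(list(A = c("MKLVW", "MPPPW"), B = c("MKLVW", "MPPPW")))
  tr <- parse_species_tree("(A:1,B:1);", focal_clade = "A")
  cfg <- default_config()
  ## b1 is a fine ortholog of a1; b2 is a strong match to a1 too but has
  ## no core synteny (translocated copy)
  pairs <- rbind(
    manual_pairs("A_00001", "B_00001", raw = 0.9),
    manual_pairs("A_00001", "B_00002", raw = 0.95, core_syn = 0.0),
    manual_pairs("A_00002", "B_00002", raw = 0.2, core_syn = 0.0))
  fams <- build_families(gs, tr, pairs, cfg)
  f_a1 <- fams$membership[gene_id == "A_00001", family_id]
  expect_setequal(fams$membership[family_id == f_a1, gene_id],
                  c("A_00001", "B_00001"))
  ## matches the brute-force single-linkage oracle on the same instance
  oracle <- oracle_build_families(gs, tr, pairs, cfg)
  mem <- split(fams$membership$gene_id, fams$membership$family_id)
  expect_equal(canonical_partition(mem), canonical_partition(oracle))
})

test_that("the synteny bonus can lift a link over the seed score", {
  gs <- make_genomes(list(A = c("MKLVW", "MPPPW", "MCCCW"),
                          B = c("MKLVW", "MPPPW", "MCCCW")))
  tr <- parse_species_tree("(A:1,B:1);", focal_clade = "A")
  cfg <- default_config()
  ## seed a1-b1 at 0.9; a2's only link is 0.85 < seed, but high synteny
  ## adds the 0.1 bonus -> 0.95 >= 0.9, so it joins; a3's identical-raw
  ## link has poor synteny, gets no bonus, stays out
  pairs <- rbind(
    manual_pairs("A_00001", "B_00001", raw = 0.9),
    manual_pairs("A_00001", "B_00002", raw = 0.85,
                 core_syn = 0.9, local_syn = 2),
    manual_pairs("A_00001", "B_00003", raw = 0.85,
                 core_syn = 0.3, local_syn = 0.5))
  fams <- build_families(gs, tr, pairs, cfg)
  f1 <- fams$membership[gene_id == "A_00001", family_id]
  mem <- fams$membership[family_id == f1, gene_id]
  expect_true("B_00002" %in% mem)
  expect_false("B_00003" %in% mem)
})

test_that("build_families matches the brute-force oracle on random instances", {
  tr <- parse_species_tree("((A:1,B:1):1,(C:1,D:1):1);",
                           focal_clade = c("A", "B"))
  cfg <- default_config()
  set.seed(808)
  for (rep in 1:8) {
    n_per <- sample(2:5, 1)
    prots <- lapply(c(A = "A", B = "B", C = "C", D = "D"), function(s) {
      replicate(n_per, rand_prot(12))
    })
    gs <- make_genomes(prots)
    ids <- gs$genes$gene_id
    strain_of <- setNames(gs$genes$strain, gs$genes$gene_id)
    grid <- data.table::CJ(g1 = ids, g2 = ids)[g1 < g2]
    grid <- grid[strain_of[g1] != strain_of[g2]]
    ## sparse random score table
    grid <- grid[runif(.N) < 0.6]
    grid[, raw := round(runif(.N), 3)]
    grid[, norm := round(runif(.N, -4, 3), 2)]
    grid[, core_syn := round(runif(.N), 2)]
    grid[, local_syn := round(runif(.N, -1, 3), 2)]
    fams <- build_families(gs, tr, grid, cfg)
    oracle <- oracle_build_families(gs, tr, grid, cfg)
    mem <- split(fams$membership$gene_id, fams$membership$family_id)
    expect_equal(canonical_partition(mem), canonical_partition(oracle),
                 info = paste("instance", rep))
  }
})

test_that("families partition the genes and respect the founding subtree", {
  fx <- make_hgt_fixture()
  sc <- score_genomes(fx$genomes)
  fams <- build_families(fx$genomes, fx$tree, sc$pairs)
  ## partition
  expect_setequal(fams$membership$gene_id, fx$genomes$genes$gene_id)
  expect_equal(anyDuplicated(fams$membership$gene_id), 0L)
  ## tree-consistency: member strains within the founding node's subtree
  strain_of <- setNames(fx$genomes$genes$strain, fx$genomes$genes$gene_id)
  for (fid in fams$families$family_id) {
    node <- fams$families[family_id == fid, founding_node]
    strains <- unique(strain_of[fams$membership[family_id == fid, gene_id]])
    expect_true(all(strains %in% fx$tree$leaves_under[[node]]))
    ## MRCA at-or-below the founding node
    expect_true(phyloGI:::tree_is_ancestor(
      fx$tree, node, fams$families[family_id == fid, mrca]))
  }
  ## determinism: identical inputs -> identical families
  fams2 <- build_families(fx$genomes, fx$tree, sc$pairs)
  expect_identical(fams$families, fams2$families)
  expect_identical(fams$membership, fams2$membership)
})

test_that("leftover genes become singleton families at their leaf", {
  gs <- make_genomes(list(A = c("MKLVW", "MPPPW"), B = c("MKLVW")))
  tr <- parse_species_tree("(A:1,B:1);", focal_clade = "A")
  pairs <- manual_pairs("A_00001", "B_00001", raw = 0.9)
  fams <- build_families(gs, tr, pairs)
  single <- fams$families[n_genes == 1L]
  expect_equal(nrow(single), 1L)
  expect_equal(single$mrca, "A")
  expect_true(is.na(single$seed_score))
})
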