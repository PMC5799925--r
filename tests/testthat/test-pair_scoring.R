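BL62 <- phyloGI:::substitution_matrix("BLOSUM62")

test_that("raw score of a protein against an identical copy is exactly 1", {
  set.seed(101)
  for (len in c(5, 37, 120)) {
    p <- rand_prot(len)
    expect_identical(compute_raw_score(p, p), 1)
  }
})

test_that("raw score matches an independent Gotoh DP oracle", {
  ## fixed case frozen from the oracle: MKLVW vs MKIVW, BLOSUM62, 11/1
  expect_equal(oracle_global_align("MKLVW", "MKIVW", BL62), 27)
  expect_equal(compute_raw_score("MKLVW", "MKIVW"),
               (27 + 30) / (29 + 30))   # a = -30, b = 29
  expect_equal(compute_raw_score("MKLVW", "MKIVW"),
               oracle_raw_score("MKLVW", "MKIVW", BL62))
  ## randomized cases including indels and length differences
  set.seed(202)
  for (i in 1:15) {
    a <- rand_prot(sample(5:40, 1))
    b <- if (i %% 3 == 0) rand_prot(sample(5:40, 1)) else {
      ## derived homolog: substitutions plus an indel
      m <- mutate_prot(a, sample(1:3, 1))
      paste0(substr(m, 1, nchar(m) - sample(0:3, 1)), "")
    }
    expect_equal(compute_raw_score(a, b), oracle_raw_score(a, b, BL62),
                 info = paste(a, b))
  }
})

test_that("raw score is symmetric and clamped to [0, 1]", {
  set.seed(303)
  for (i in 1:10) {
    a <- rand_prot(sample(5:60, 1)); b <- rand_prot(sample(5:60, 1))
    r1 <- compute_raw_score(a, b); r2 <- compute_raw_score(b, a)
    expect_identical(r1, r2)
    expect_gte(r1, 0); expect_lte(r1, 1)
  }
  expect_error(compute_raw_score("", "MK"), "empty")
})

test_that("candidate k-mer prefilter keeps homologs, drops noise, stays cross-strain", {
  set.seed(404)
  shared <- rand_prot(100)
  gs <- make_genomes(list(
    A = c(shared, rand_prot(100), rand_prot(100)),
    B = c(shared, rand_prot(100))))
  pairs <- find_candidate_pairs(gs)
  strain_of <- setNames(gs$genes$strain, gs$genes$gene_id)
  ## identical 100-aa proteins retained
  expect_true(nrow(pairs[g1 == "A_00001" & g2 == "B_00001"]) == 1)
  ## independent random sequences rejected, and genuinely dissimilar by
  ## the full-alignment oracle (the all-gap floor keeps even unrelated
  ## pairs somewhat above zero; identical pairs sit at 1)
  expect_false(any(pairs$g1 == "A_00002" & pairs$g2 == "B_00002"))
  p2 <- gs$genes[gs$genes$gene_id %in% c("A_00002", "B_00002"), protein]
  expect_lt(oracle_raw_score(p2[1], p2[2], BL62), 0.35)
  ## never a same-strain pair (A has two random paralogs of itself below)
  expect_true(all(strain_of[pairs$g1] != strain_of[pairs$g2]))
})

test_that("prefilter passes every simulator-derived homolog pair", {
  ## homologs at ~60% identity -- well below the divergence the
  ## simulator produces between the farthest strains -- must pass
  set.seed(505)
  base <- replicate(6, rand_prot(80))
  far <- vapply(base, function(p) mutate_prot(p, 32), character(1))
  gs <- make_genomes(list(A = base, B = far))
  pairs <- find_candidate_pairs(gs)
  for (k in seq_along(base)) {
    expect_true(nrow(pairs[g1 == sprintf("A_%05d", k) &
                           g2 == sprintf("B_%05d", k)]) == 1,
                info = paste("homolog pair", k))
  }
})

test_that("conservative cores are all-around unique best reciprocal hits", {
  gs <- make_trio()
  sc <- find_candidate_pairs(gs)
  sc <- compute_raw_scores(gs, sc)
  cores <- find_conservative_cores(gs, sc)
  ## one near-identical ortholog per strain, all mutual best
  expect_equal(length(unique(cores$core_set)), 12L)
  expect_true(all(table(cores$core_set) == 3L))
  ## positional homologs end up in the same set
  pos_of <- setNames(gs$genes$index, gs$genes$gene_id)
  same_pos <- cores[, length(unique(pos_of[gene_id])) == 1L, by = core_set]$V1
  expect_true(all(same_pos))
})

test_that("a gene missing from one strain yields no core set", {
  set.seed(606)
  base <- replicate(3, rand_prot(60))
  gs <- make_genomes(list(
    A = vapply(base, function(p) mutate_prot(p, 1), character(1)),
    B = vapply(base, function(p) mutate_prot(p, 1), character(1)),
    C = vapply(base[1:2], function(p) mutate_prot(p, 2), character(1))))
  sc <- compute_raw_scores(gs, find_candidate_pairs(gs))
  cores <- find_conservative_cores(gs, sc)
  ## gene 3 absent in C: only two sets remain
  expect_equal(length(unique(cores$core_set)), 2L)
  expect_false(any(cores$gene_id %in% c("A_00003", "B_00003")))
})

test_that("cores match brute-force enumeration when a best hit crosses paralog groups", {
  ## 3 strains x 2 paralog groups; craft raw scores so that one cross
  ## hit's best partner is in the wrong group
  prots <- c("MKLVW", "MKIVW", "MMMVW")
  gs <- make_genomes(list(A = prots, B = prots, C = prots))
  ids <- gs$genes$gene_id
  grid <- data.table::CJ(g1 = ids, g2 = ids)[g1 < g2]
  strain_of <- setNames(gs$genes$strain, gs$genes$gene_id)
  grid <- grid[strain_of[g1] != strain_of[g2]]
  para <- setNames(rep(1:3, 3), ids)          # paralog group by position
  grid[, raw := ifelse(para[g1] == para[g2], 0.9, 0.2)]
  ## poison: a cross-group hit that outscores the within-group ones,
  ## breaking mutual-best for groups 1 and 2 (scores are symmetric)
  grid[g1 == "A_00002" & g2 == "C_00001", raw := 0.95]
  cores <- find_conservative_cores(gs, grid)
  ## brute force: enumerate all one-per-strain tuples, check mutual
  ## unique best
  raw_of <- function(x, y) {
    r <- grid[(g1 == x & g2 == y) | (g1 == y & g2 == x), raw]
    if (length(r)) r else NA_real_
  }
  is_best <- function(x, y) {
    others <- ids[strain_of[ids] == strain_of[y] & ids != y]
    ry <- raw_of(x, y)
    !is.na(ry) && all(vapply(others, function(o) {
      ro <- raw_of(x, o); is.na(ro) || ro < ry
    }, logical(1)))
  }
  tuples <- data.table::CJ(a = ids[1:3], b = ids[4:6], c = ids[7:9])
  ok <- apply(tuples, 1, function(tp) {
    all(combn(tp, 2, function(xy) {
      is_best(xy[1], xy[2]) && is_best(xy[2], xy[1])
    }))
  })
  expected <- sort(apply(tuples[ok], 1, paste, collapse = ","))
  got <- sort(vapply(split(cores$gene_id, cores$core_set),
                     function(m) paste(sort(m), collapse = ","),
                     character(1)))
  expect_equal(unname(got), unname(expected))
  ## the poison breaks mutual-best for groups 1 and 2; group 3 survives
  expect_false("A_00001,B_00001,C_00001" %in% got)
  expect_false("A_00002,B_00002,C_00002" %in% got)
  expect_true("A_00003,B_00003,C_00003" %in% got)
})

test_that("strain pair statistics use the population standard deviation", {
  gs <- make_genomes(list(A = c("MKLVW", "MKIVW"), B = c("MKLVW", "MKIVW")))
  cores <- data.table::data.table(
    core_set = c(1L, 1L, 2L, 2L),
    gene_id = c("A_00001", "B_00001", "A_00002", "B_00002"),
    strain = c("A", "B", "A", "B"))
  mkpairs <- function(r1, r2) data.table::data.table(
    g1 = c("A_00001", "A_00002"), g2 = c("B_00001", "B_00002"),
    raw = c(r1, r2))
  st <- compute_strain_pair_stats(cores, mkpairs(0.8, 0.9))
  expect_equal(st$m, 0.85)
  expect_equal(st$s, 0.05)
  ## degenerate spread is fatal and names the strain pair
  expect_error(compute_strain_pair_stats(cores, mkpairs(0.7, 0.7)), "A-B")
  ## three-score case
  cores3 <- rbind(cores, data.table::data.table(
    core_set = 3L, gene_id = c("A_00003", "B_00003"), strain = c("A", "B")))
  p3 <- rbind(mkpairs(0.6, 0.8),
              data.table::data.table(g1 = "A_00003", g2 = "B_00003",
                                     raw = 1.0))
  st3 <- compute_strain_pair_stats(cores3, p3)
  expect_equal(st3$m, 0.8)
  expect_equal(st3$s, sqrt(0.08 / 3))
  ## fewer than two sets cannot anchor a normalization
  expect_error(compute_strain_pair_stats(cores[core_set == 1L],
                                         mkpairs(0.8, 0.9)),
               "at least 2")
})

test_that("norm scores are z-scores of the raw score", {
  stats <- data.table::data.table(strain1 = "A", strain2 = "B",
                                  m = 0.8, s = 0.05, n_core = 10L)
  pr <- data.table::data.table(
    g1 = c("A_1", "A_2", "A_3"), g2 = c("B_1", "B_2", "B_3"),
    strain1 = "A", strain2 = "B", raw = c(0.8, 0.9, 0.75))
  out <- compute_norm_scores(pr, stats)
  expect_equal(out$norm, c(0, 2, -1))
})

test_that("norm scores over core pairs have mean 0 and unit SD by construction", {
  gs <- make_trio()
  sc <- score_genomes(gs)
  cores <- sc$cores
  cp <- cores[cores, on = "core_set", allow.cartesian = TRUE][strain < i.strain]
  pk <- phyloGI:::pair_key(cp$gene_id, cp$i.gene_id)
  cp[, `:=`(g1 = pk$g1, g2 = pk$g2)]
  core_pairs <- merge(cp, sc$pairs[, .(g1, g2, norm)], by = c("g1", "g2"))
  by_sp <- split(core_pairs$norm, paste(core_pairs$strain,
                                        core_pairs$i.strain))
  for (v in by_sp) {
    expect_equal(mean(v), 0, tolerance = 1e-9)
    expect_equal(sqrt(mean((v - mean(v))^2)), 1, tolerance = 1e-9)
  }
})

test_that("raw scores are identical whether computed serially or in parallel", {
  gs <- make_trio()
  pairs <- find_candidate_pairs(gs)
  cfg2 <- default_config(); cfg2$workers <- 2L
  serial <- compute_raw_scores(gs, pairs)
  par <- compute_raw_scores(gs, pairs, cfg2)
  expect_identical(serial$raw, par$raw)
})
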