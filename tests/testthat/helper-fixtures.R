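## Programmatic fixtures: tiny genome sets and scored pair tables built
## in code under fixed seeds.

AA <- c("A","R","N","D","C","Q","E","G","H","I",
        "L","K","M","F","P","S","T","W","Y","V")

rand_prot <- function(len) paste(sample(AA, len, replace = TRUE),
                                 collapse = "")

## n point substitutions at deterministic positions (requires set.seed
## by the caller).
mutate_prot <- function(p, n_sub) {
  aa <- strsplit(p, "")[[1]]
  pos <- sample(seq_along(aa), n_sub)
  for (i in pos) aa[i] <- sample(AA[AA != aa[i]], 1)
  paste(aa, collapse = "")
}

## Build a genome_set from a named list: strain -> character vector of
## proteins in gene order (one linear replicon per strain), or strain ->
## named list of replicons.
make_genomes <- function(strain_prots, intergenic = 100L) {
  rows <- list()
  for (s in names(strain_prots)) {
    reps <- strain_prots[[s]]
    if (!is.list(reps)) reps <- list(chr = reps)
    gnum <- 0L
    for (r in names(reps)) {
      prots <- reps[[r]]
      nt <- 3L * nchar(prots) + 3L
      starts <- cumsum(c(intergenic, head(nt + intergenic, -1L)))
      rows[[paste(s, r)]] <- data.table::data.table(
        gene_id = sprintf("%s_%05d", s, gnum + seq_along(prots)),
        strain = s, replicon_id = paste0(s, "_", r),
        index = seq_along(prots) - 1L,
        start = starts, end = starts + nt,
        strand = "+", protein = prots)
      gnum <- gnum + length(prots)
    }
  }
  new_genome_set(data.table::rbindlist(rows))
}

## A clean 3-strain fixture: `n_core` well-conserved single-copy genes
## per strain in the same order, with a few substitutions between
## strains. Returns the genome_set; gene k of each strain is homologous
## to gene k of the others.
make_trio <- function(n_core = 12, len = 60, seed = 42) {
  set.seed(seed)
  base <- replicate(n_core, rand_prot(len))
  prots <- list(
    A = vapply(base, function(p) mutate_prot(p, 2), character(1)),
    B = vapply(base, function(p) mutate_prot(p, 2), character(1)),
    C = vapply(base, function(p) mutate_prot(p, 4), character(1)))
  make_genomes(prots)
}

trio_tree <- function() parse_species_tree("((A:0.1,B:0.1):0.1,C:0.2);",
                                           focal_clade = c("A", "B"))

## Small scored-pairs table for hand-built cases: every cross-strain
## pair of homologs (same position) gets the given scores.
manual_pairs <- function(g1, g2, raw, norm = 0, core_syn = 1,
                         local_syn = 2) {
  pk <- phyloGI:::pair_key(g1, g2)
  data.table::data.table(g1 = pk$g1, g2 = pk$g2, raw = raw, norm = norm,
                         core_syn = core_syn, local_syn = local_syn)
}

## GenBank text for a tiny 2-record file used by the parser tests.
tiny_genbank <- function(path) {
  txt <- c(
    "LOCUS       repA  1200 bp    DNA    linear  BCT",
    "DEFINITION  toy genome.",
    "FEATURES             Location/Qualifiers",
    "     source          1..1200",
    '                     /organism="toy"',
    "     CDS             101..160",
    '                     /locus_tag="t1"',
    '                     /product="alpha"',
    '                     /translation="MKLVWAAAKLMNPQRSTVWY"',
    "     CDS             complement(201..260)",
    '                     /locus_tag="t2"',
    '                     /product="beta"',
    '                     /translation="MKIVWAAAKLMNPQRSTVWY"',
    "     CDS             301..360",
    '                     /locus_tag="t3"',
    '                     /product="pseudo, no translation"',
    "     CDS             join(401..430,441..470)",
    '                     /locus_tag="t4"',
    '                     /product="gamma"',
    '                     /translation="MMMMWAAAKLMNPQRSTVWY"',
    "ORIGIN",
    "//",
    "LOCUS       repB  600 bp    DNA    linear  BCT",
    "FEATURES             Location/Qualifiers",
    "     CDS             11..70",
    '                     /locus_tag="t5"',
    '                     /product="delta"',
    '                     /translation="MCCCWAAAKLMNPQRSTVWY"',
    "ORIGIN",
    "//")
  writeLines(txt, path)
  path
}

## Simulated cherry with one deterministic HGT block: returns a list with
## genomes, tree, and the block's position, built by hand (not via the
## simulator) so the expected island is known exactly.
make_hgt_fixture <- function(n_core = 24, block = 5, len = 60, seed = 7) {
  set.seed(seed)
  base <- replicate(n_core, rand_prot(len))
  island <- replicate(block, rand_prot(len))
  at <- n_core %/% 2
  with_island <- function(core, isl) c(head(core, at), isl,
                                       tail(core, -at))
  prots <- list(
    A = with_island(vapply(base, function(p) mutate_prot(p, 2),
                           character(1)),
                    vapply(island, function(p) mutate_prot(p, 1),
                           character(1))),
    B = with_island(vapply(base, function(p) mutate_prot(p, 2),
                           character(1)),
                    vapply(island, function(p) mutate_prot(p, 1),
                           character(1))),
    C = vapply(base, function(p) mutate_prot(p, 4), character(1)),
    D = vapply(base, function(p) mutate_prot(p, 5), character(1)))
  genomes <- make_genomes(prots)
  tree <- parse_species_tree("(((A:0.1,B:0.1):0.1,C:0.15):0.1,D:0.3);",
                             focal_clade = c("A", "B", "C"))
  list(genomes = genomes, tree = tree, island_at = at, block = block,
       n_core = n_core)
}

## Small simulation config scaled for fast tests.
test_sim_config <- function(seed = 1, ...) {
  cfg <- default_config()
  cfg$sim_root_genes <- 60L
  cfg$sim_protein_len <- 60L
  cfg$sim_seed <- as.integer(seed)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}
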