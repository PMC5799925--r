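#' Find candidate cross-strain gene pairs
#'
#' Default backend: a shared amino-acid k-mer prefilter. Two genes from
#' different strains become a candidate pair when they share at least
#' `kmer_min_shared` distinct k-mers of length `kmer_k`. The filter is a
#' cheap stand-in for a local-alignment search step: it only decides
#' which pairs get full scores, and is deliberately permissive (homologs
#' down to ~50% identity pass comfortably at the defaults).
#'
#' @param genomes A `genome_set`.
#' @param config Optional (partial) configuration list; see
#'   [default_config()] (`kmer_k`, `kmer_min_shared`).
#' @return A `data.table` with columns `g1`, `g2` (gene ids, `g1 < g2`,
#'   always from different strains) and `shared_kmers`.
#' @export
find_candidate_pairs <- function(genomes, config = NULL) {
  cfg <- as_config(config)
  if (length(genomes$strains) < 2) stop("need at least two strains")
  k <- cfg$kmer_k
  genes <- genomes$genes
  kmers <- lapply(genes$protein, function(p) {
    n <- nchar(p)
    if (n < k) return(character(0))
    unique(substring(p, 1:(n - k + 1L), k:n))
  })
  idx <- data.table(
    kmer = unlist(kmers, use.names = FALSE),
    gene = rep(genes$gene_id, lengths(kmers)),
    strain = rep(genes$strain, lengths(kmers)))
  setkey(idx, kmer)
  hits <- idx[idx, on = "kmer", allow.cartesian = TRUE][strain < i.strain]
  pairs <- hits[, .N, by = .(g1 = gene, g2 = i.gene)]
  pairs <- pairs[N >= cfg$kmer_min_shared]
  pk <- pair_key(pairs$g1, pairs$g2)
  pairs[, `:=`(g1 = pk$g1, g2 = pk$g2)]
  setnames(pairs, "N", "shared_kmers")
  setorder(pairs, g1, g2)
  pairs[]
}

#' Candidate pairs via an external protein search tool
#'
#' Adapter with the same contract as [find_candidate_pairs()], using
#' NCBI `blastp` with an E-value cutoff instead of the built-in k-mer
#' prefilter. Requires `makeblastdb` and `blastp` on the PATH.
#'
#' @param genomes A `genome_set`.
#' @param evalue E-value threshold (default `1e-8`).
#' @return A `data.table` with columns `g1`, `g2` (`g1 < g2`,
#'   cross-strain only).
#' @export
find_candidate_pairs_blast <- function(genomes, evalue = 1e-8) {
  if (Sys.which("blastp") == "" || Sys.which("makeblastdb") == "") {
    stop("external search backend unavailable (blastp/makeblastdb not on ",
         "PATH); use the built-in k-mer backend find_candidate_pairs()")
  }
  td <- tempfile("blastdb")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  fa <- file.path(td, "prot.fa")
  aa <- Biostrings::AAStringSet(setNames(genomes$genes$protein,
                                         genomes$genes$gene_id))
  Biostrings::writeXStringSet(aa, fa)
  system2("makeblastdb", c("-in", fa, "-dbtype", "prot"),
          stdout = FALSE, stderr = FALSE)
  out <- file.path(td, "hits.tsv")
  system2("blastp", c("-query", fa, "-db", fa, "-outfmt", "6",
                      "-evalue", format(evalue, scientific = TRUE),
                      "-out", out), stdout = FALSE, stderr = FALSE)
  hits <- fread(out, header = FALSE, select = 1:2,
                col.names = c("g1", "g2"))
  strain_of <- setNames(genomes$genes$strain, genomes$genes$gene_id)
  hits <- hits[strain_of[g1] != strain_of[g2]]
  pk <- pair_key(hits$g1, hits$g2)
  hits[, `:=`(g1 = pk$g1, g2 = pk$g2)]
  hits <- unique(hits[, .(g1, g2)])
  setorder(hits, g1, g2)
  hits[]
}

## Per-gene self-alignment score: sum of diagonal substitution values.
self_scores <- function(proteins, mat) {
  vapply(proteins, function(p) {
    aa <- strsplit(p, "", fixed = TRUE)[[1]]
    sum(mat[cbind(aa, aa)])
  }, numeric(1), USE.NAMES = FALSE)
}

substitution_matrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Raw similarity scores for candidate gene pairs
#'
#' The raw score rescales the global affine-gap alignment score `g` of
#' two proteins to `[0, 1]`: `raw = (g - a) / (b - a)`, where `b` is the
#' ceiling (the self-alignment score of the shorter protein, i.e. the sum
#' of diagonal substitution values) and `a` is the floor (the score of an
#' all-gap alignment: two opened gaps, one per sequence, so
#' `a = -2*gap_open - gap_extend*((lenA-1) + (lenB-1))` with gap costs in
#' the open + (L-1)*extend convention). Values are clamped to `[0, 1]`.
#'
#' @param genomes A `genome_set`.
#' @param pairs A `data.table` with columns `g1`, `g2` as returned by
#'   [find_candidate_pairs()].
#' @param config Optional configuration (`subst_matrix`, `gap_open`,
#'   `gap_extend`, `workers`).
#' @return `pairs` with columns `strain1`, `strain2` and `raw` added.
#' @export
compute_raw_scores <- function(genomes, pairs, config = NULL) {
  cfg <- as_config(config)
  genes <- genomes$genes
  mat <- substitution_matrix(cfg$subst_matrix)
  self <- self_scores(genes$protein, mat)
  names(self) <- genes$gene_id
  lens <- setNames(nchar(genes$protein), genes$gene_id)
  prot <- setNames(genes$protein, genes$gene_id)
  strain_of <- setNames(genes$strain, genes$gene_id)
  pairs <- copy(pairs)
  pairs[, `:=`(strain1 = strain_of[g1], strain2 = strain_of[g2])]
  la <- unname(lens[pairs$g1]); lb <- unname(lens[pairs$g2])
  a <- -2 * cfg$gap_open - cfg$gap_extend * ((la - 1) + (lb - 1))
  b <- ifelse(la < lb, self[pairs$g1],
       ifelse(lb < la, self[pairs$g2],
              pmin(self[pairs$g1], self[pairs$g2])))
  b <- unname(b)
  if (any(b <= a)) stop("degenerate pair: ceiling <= floor (zero-length protein?)")
  g <- alignment_scores(prot[pairs$g1], prot[pairs$g2], cfg)
  pairs[, raw := pmin(1, pmax(0, (g - a) / (b - a)))]
  pairs[]
}

## Vectorized global alignment scores; chunked, optionally parallel.
## Biostrings charges open + L*extend for a gap of length L, so passing
## gapOpening = open - extend reproduces the open + (L-1)*extend
## convention used throughout this package.
alignment_scores <- function(pa, pb, cfg) {
  mat <- substitution_matrix(cfg$subst_matrix)
  n <- length(pa)
  chunk_size <- 2000L
  starts <- seq(1L, n, by = chunk_size)
  score_chunk <- function(s) {
    i <- s:min(s + chunk_size - 1L, n)
    Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(pa[i]), Biostrings::AAStringSet(pb[i]),
      substitutionMatrix = mat,
      gapOpening = cfg$gap_open - cfg$gap_extend,
      gapExtension = cfg$gap_extend,
      type = "global", scoreOnly = TRUE)
  }
  res <- if (cfg$workers > 1L) {
    parallel::mclapply(starts, score_chunk, mc.cores = cfg$workers)
  } else {
    lapply(starts, score_chunk)
  }
  unlist(res, use.names = FALSE)
}

#' Raw score between two protein sequences
#'
#' Scalar convenience wrapper around the raw-score construction used by
#' [compute_raw_scores()]; see there for the formula.
#'
#' @param pA,pB Non-empty amino-acid strings.
#' @param config Optional configuration (`subst_matrix`, `gap_open`,
#'   `gap_extend`).
#' @return Raw score in `[0, 1]`.
#' @export
compute_raw_score <- function(pA, pB, config = NULL) {
  cfg <- as_config(config)
  if (!nzchar(pA) || !nzchar(pB)) stop("empty protein sequence")
  mat <- substitution_matrix(cfg$subst_matrix)
  sa <- self_scores(pA, mat); sb <- self_scores(pB, mat)
  la <- nchar(pA); lb <- nchar(pB)
  a <- -2 * cfg$gap_open - cfg$gap_extend * ((la - 1) + (lb - 1))
  b <- if (la < lb) sa else if (lb < la) sb else min(sa, sb)
  if (b <= a) stop("degenerate pair: ceiling <= floor")
  g <- alignment_scores(pA, pB, cfg)
  min(1, max(0, (g - a) / (b - a)))
}

#' Conservative core ortholog sets (all-around best reciprocal hits)
#'
#' Finds every maximal gene set with exactly one member per strain in
#' which each member is the unique best raw-score hit of every other
#' member within its strain. These very conservative ortholog sets anchor
#' score normalization and the core synteny score.
#'
#' @param genomes A `genome_set`.
#' @param pairs A `data.table` with `g1`, `g2`, `raw` (from
#'   [compute_raw_scores()]).
#' @return A `data.table` with columns `core_set` (integer id), `gene_id`
#'   and `strain`; zero rows if no set qualifies.
#' @export
find_conservative_cores <- function(genomes, pairs) {
  strains <- genomes$strains
  strain_of <- setNames(genomes$genes$strain, genomes$genes$gene_id)
  long <- rbindlist(list(
    pairs[, .(g = g1, partner = g2, pstrain = strain_of[g2], raw)],
    pairs[, .(g = g2, partner = g1, pstrain = strain_of[g1], raw)]))
  ## unique best hit per (gene, other strain); ties disqualify
  setorder(long, g, pstrain, -raw, partner)
  top <- long[, {
    mx <- raw[1]
    if (.N > 1 && raw[2] == mx) list(partner = NA_character_)
    else list(partner = partner[1])
  }, by = .(g, pstrain)]
  best <- new.env(parent = emptyenv())
  apply_rows <- top[!is.na(partner)]
  keys <- paste(apply_rows$g, apply_rows$pstrain, sep = "\r")
  for (i in seq_len(nrow(apply_rows))) {
    assign(keys[i], apply_rows$partner[i], envir = best)
  }
  get_best <- function(g, s) {
    k <- paste(g, s, sep = "\r")
    if (exists(k, envir = best, inherits = FALSE))
      get(k, envir = best, inherits = FALSE) else NA_character_
  }
  ref <- strains[1]
  ref_genes <- sort(genomes$genes[strain == ref, gene_id])
  sets <- list()
  for (rg in ref_genes) {
    tuple <- c(rg, vapply(strains[-1], function(s) get_best(rg, s),
                          character(1)))
    if (anyNA(tuple)) next
    names(tuple) <- strains
    ok <- TRUE
    for (x in tuple) {
      for (s in strains) {
        if (s == strain_of[x]) next
        if (!identical(get_best(x, s), unname(tuple[s]))) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) sets[[length(sets) + 1L]] <- tuple
  }
  if (!length(sets)) {
    return(data.table(core_set = integer(0), gene_id = character(0),
                      strain = character(0)))
  }
  data.table(
    core_set = rep(seq_along(sets), each = length(strains)),
    gene_id = unlist(sets, use.names = FALSE),
    strain = rep(strains, times = length(sets)))
}

#' Per-strain-pair normalization statistics
#'
#' For each unordered strain pair, the mean `m` and population standard
#' deviation `s` of raw scores over the conservative core ortholog pairs.
#'
#' @param cores Core sets from [find_conservative_cores()].
#' @param pairs Scored pairs (`g1`, `g2`, `raw`).
#' @return A `data.table` with `strain1`, `strain2` (`strain1 < strain2`),
#'   `m`, `s`, `n_core`.
#' @export
compute_strain_pair_stats <- function(cores, pairs) {
  if (nrow(cores) == 0 || length(unique(cores$core_set)) < 2) {
    stop("need at least 2 conservative core sets to normalize scores ",
         "(found ", length(unique(cores$core_set)), ")")
  }
  core_pairs <- cores[cores, on = "core_set",
                      allow.cartesian = TRUE][strain < i.strain]
  pk <- pair_key(core_pairs$gene_id, core_pairs$i.gene_id)
  core_pairs[, `:=`(g1 = pk$g1, g2 = pk$g2)]
  core_pairs <- merge(core_pairs[, .(strain1 = strain, strain2 = i.strain,
                                     g1, g2)],
                      pairs[, .(g1, g2, raw)], by = c("g1", "g2"))
  stats <- core_pairs[, .(m = mean(raw),
                          s = sqrt(mean((raw - mean(raw))^2)),
                          n_core = .N),
                      by = .(strain1, strain2)]
  bad <- stats[s <= 0]
  if (nrow(bad)) {
    stop("zero raw-score spread over core orthologs for strain pair(s): ",
         paste(sprintf("%s-%s", bad$strain1, bad$strain2), collapse = ", "),
         "; cannot normalize")
  }
  setorder(stats, strain1, strain2)
  stats[]
}

#' Normalized (z-scored) similarity scores
#'
#' `norm = (raw - m) / s` using the strain pair's core-gene statistics;
#' a norm score may be negative or exceed 1.
#'
#' @param pairs Scored pairs with `strain1`, `strain2`, `raw`.
#' @param stats Output of [compute_strain_pair_stats()].
#' @return `pairs` with a `norm` column added.
#' @export
compute_norm_scores <- function(pairs, stats) {
  pairs <- copy(pairs)
  pk <- pair_key(pairs$strain1, pairs$strain2)
  pairs[, `:=`(.s1 = pk$g1, .s2 = pk$g2)]
  pairs[stats, on = c(.s1 = "strain1", .s2 = "strain2"),
        norm := (raw - i.m) / i.s]
  if (anyNA(pairs$norm)) {
    miss <- unique(pairs[is.na(norm), .(.s1, .s2)])
    stop("missing normalization stats for strain pair(s): ",
         paste(sprintf("%s-%s", miss$.s1, miss$.s2), collapse = ", "))
  }
  pairs[, c(".s1", ".s2") := NULL]
  pairs[]
}
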