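#' Compute all similarity and synteny scores
#'
#' Runs the scoring stage: candidate pairs (k-mer prefilter), raw
#' alignment scores, conservative core ortholog sets, per-strain-pair
#' normalization, normalized scores, and the two synteny scores.
#'
#' @param genomes A `genome_set`.
#' @param config Optional configuration; see [default_config()].
#' @return A `score_graph`: list with `pairs` (a `data.table` with `g1`,
#'   `g2`, `raw`, `norm`, `core_syn`, `local_syn`), `cores`
#'   (conservative core sets), and `stats` (per-strain-pair m, s).
#' @export
score_genomes <- function(genomes, config = NULL) {
  cfg <- as_config(config)
  gi_log("scoring: candidate pairs (k-mer prefilter)")
  pairs <- find_candidate_pairs(genomes, cfg)
  gi_log(sprintf("scoring: %d candidate pairs; raw alignment scores",
                 nrow(pairs)))
  pairs <- compute_raw_scores(genomes, pairs, cfg)
  gi_log("scoring: conservative core ortholog sets")
  cores <- find_conservative_cores(genomes, pairs)
  gi_log(sprintf("scoring: %d core sets; normalization",
                 length(unique(cores$core_set))))
  stats <- compute_strain_pair_stats(cores, pairs)
  pairs <- compute_norm_scores(pairs, stats)
  gi_log("scoring: core synteny")
  pairs <- compute_core_synteny(genomes, pairs, cores, cfg)
  gi_log("scoring: local synteny")
  pairs <- compute_local_synteny(genomes, pairs, cfg)
  obj <- list(pairs = pairs, cores = cores, stats = stats)
  class(obj) <- "score_graph"
  obj
}

#' @export
print.score_graph <- function(x, ...) {
  cat(sprintf("score_graph: %d scored cross-strain pairs, %d conservative core sets\n",
              nrow(x$pairs), length(unique(x$cores$core_set))))
  invisible(x)
}

#' Detect genomic islands in a set of genomes
#'
#' In-memory pipeline: scoring, tree-aware family building, island
#' assembly and classification.
#'
#' @param genomes A `genome_set`.
#' @param tree A `species_tree` whose leaves match the strains.
#' @param config Optional configuration.
#' @return A `gi_result`: list with `islands` (classified `gi_islands`),
#'   `families`, `scores`, `genomes`, `tree`, `config`.
#' @export
detect_islands <- function(genomes, tree, config = NULL) {
  cfg <- as_config(config)
  if (!setequal(names(tree$is_leaf)[tree$is_leaf], genomes$strains)) {
    stop("tree leaves do not match genome strains")
  }
  scores <- score_genomes(genomes, cfg)
  gi_log("families: tree-aware clustering")
  families <- build_families(genomes, tree, scores$pairs, cfg)
  gi_log(sprintf("families: %d families; island assembly",
                 nrow(families$families)))
  islands <- merge_islands(genomes, tree, families, cfg)
  gi_log(sprintf("islands: %d islands (%d insertions)",
                 nrow(islands$islands),
                 sum(islands$islands$classification == "insertion")))
  res <- list(islands = islands, families = families, scores = scores,
              genomes = genomes, tree = tree, config = cfg)
  class(res) <- "gi_result"
  res
}

#' @export
print.gi_result <- function(x, ...) {
  print(x$genomes); print(x$families); print(x$islands)
  invisible(x)
}

#' Run the full pipeline from files
#'
#' Loads genomes and the species tree, runs [detect_islands()], and
#' writes `families.tsv`, `islands.tsv`, `scores.tsv` and a
#' classification report into `out_dir`. Outputs are deterministic for
#' identical inputs and configuration, regardless of worker count. On any
#' stage failure, partial outputs are removed and the error names the
#' stage.
#'
#' @param genome_paths Character vector of GenBank files (one strain
#'   each).
#' @param tree_newick Newick string or file for the rooted binary species
#'   tree.
#' @param focal_clade Focal clade designation (leaf names or node id);
#'   see [parse_species_tree()].
#' @param out_dir Output directory.
#' @param config Optional configuration.
#' @return A `gi_result`, invisibly.
#' @export
run_pipeline <- function(genome_paths, tree_newick, focal_clade, out_dir,
                         config = NULL) {
  cfg <- as_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- file.path(out_dir, c("families.tsv", "islands.tsv",
                                  "scores.tsv", "classification.txt"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      suppressWarnings(file.remove(outputs[file.exists(outputs)]))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  genomes <- stage("load", load_genomes(genome_paths))
  tree <- stage("load", parse_species_tree(tree_newick, focal_clade,
                                           strains = genomes$strains))
  res <- stage("detect", detect_islands(genomes, tree, cfg))
  stage("write", {
    write_families_tsv(res$families, outputs[1])
    write_islands_tsv(res$islands, res$genomes, outputs[2])
    export_score_graph(res$scores, outputs[3])
    writeLines(classification_report(res), outputs[4])
  })
  invisible(res)
}

#' Export the score graph as TSV
#'
#' Deterministic row order (sorted by gene ids): columns `g1`, `g2`,
#' `raw`, `norm`, `core_syn`, `local_syn`.
#'
#' @param scores A `score_graph`.
#' @param path Output file.
#' @export
export_score_graph <- function(scores, path) {
  out <- scores$pairs[, .(g1, g2, raw, norm, core_syn, local_syn)]
  setorder(out, g1, g2)
  fwrite(out, path, sep = "\t")
  invisible(path)
}

## Human-readable per-branch summary of insertions.
classification_report <- function(res) {
  isl <- res$islands$islands
  lines <- c("Island classification summary",
             sprintf("  strains: %s", paste(res$genomes$strains,
                                            collapse = ", ")),
             sprintf("  focal clade root: %s", res$tree$focal_root),
             sprintf("  islands: %d total, %d core, %d insertions",
                     nrow(isl), sum(isl$classification == "core"),
                     sum(isl$classification == "insertion")),
             "", "Insertions per branch (branch = node the edge enters):")
  ins <- isl[classification == "insertion"]
  for (nd in res$tree$preorder) {
    k <- sum(ins$branch == nd)
    if (k > 0) {
      lines <- c(lines, sprintf("  %-8s %3d island(s), %d family(ies)",
                                nd, k, sum(ins[branch == nd, n_families])))
    }
  }
  lines
}
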