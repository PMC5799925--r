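## Result writers (BED / GFF3 / FASTA) and text query reports.

## Contiguous gene runs of each island in one strain, with island
## metadata. Returns a data.table: island_id, replicon_id, start, end,
## mrca, classification, branch (one row per run).
island_runs_for_strain <- function(islands, genomes, strain_name) {
  if (!strain_name %in% genomes$strains) {
    stop("unknown strain: ", strain_name, " (known: ",
         paste(genomes$strains, collapse = ", "), ")")
  }
  isl <- islands$islands
  empty <- data.table(island_id = character(0), replicon_id = character(0),
                      start = integer(0), end = integer(0),
                      mrca = character(0), classification = character(0),
                      branch = character(0))
  if (!nrow(isl)) return(empty)
  fam_isl <- data.table(
    family_id = unlist(islands$fams, use.names = FALSE),
    label = rep(names(islands$fams),
                vapply(islands$fams, length, integer(1))))
  g <- merge(genomes$genes[strain == strain_name,
                           .(gene_id, strain, replicon_id, index, start, end)],
             islands$families$membership, by = "gene_id")
  g <- merge(g, fam_isl, by = "family_id")
  if (!nrow(g)) return(empty)
  iv <- runs_to_intervals(g)[, run_id := NULL][]
  setnames(iv, "label", "island_id")
  out <- merge(iv[, .(island_id, replicon_id, start, end)],
               isl[, .(island_id, mrca, classification, branch)],
               by = "island_id")
  setorder(out, replicon_id, start, island_id)
  out
}

## Deterministic island colors: a fixed palette cycled by island rank,
## with a reserved color (black) for islands whose MRCA is at or above
## `old_node` ("old" islands, typically the core blocks).
island_colors <- function(islands, tree, old_node = NULL) {
  palette <- c("#E41A1C", "#377EB8", "#4DAF4A", "#984EA3", "#FF7F00",
               "#A65628", "#F781BF", "#1B9E77", "#66A61E", "#E6AB02")
  isl <- islands$islands
  old <- if (is.null(old_node) || !nzchar(old_node)) {
    isl$classification == "core"
  } else {
    vapply(isl$mrca, function(nd) tree_is_ancestor(tree, nd, old_node),
           logical(1))
  }
  cols <- palette[(seq_len(nrow(isl)) - 1L) %% length(palette) + 1L]
  cols[old] <- "#000000"
  setNames(cols, isl$island_id)
}

#' Export islands as BED or GFF3 for a genome browser
#'
#' One record per island per contiguous gene run in the strain. BED is
#' 0-based half-open with the island id as name and two extra columns
#' after the strand (branch, color); GFF3 is 1-based inclusive with
#' feature type `genomic_island` and attributes `ID`, `mrca`, `branch`
#' and `color`. Islands whose MRCA is at or above `old_node` (default:
#' all core-classified islands) share a single reserved color.
#'
#' @param islands A classified `gi_islands`.
#' @param genomes A `genome_set`.
#' @param strain Strain to export.
#' @param format `"BED"` or `"GFF3"`.
#' @param path Output file.
#' @param tree The `species_tree` (needed to resolve `old_node`).
#' @param old_node Optional node id; islands with MRCA at or above it get
#'   the reserved color.
#' @return `path`, invisibly.
#' @export
export_annotations <- function(islands, genomes, strain, format, path,
                               tree = NULL, old_node = NULL) {
  format <- toupper(format)
  runs <- island_runs_for_strain(islands, genomes, strain)
  cols <- if (!is.null(tree)) island_colors(islands, tree, old_node) else
    setNames(rep("#808080", nrow(islands$islands)),
             islands$islands$island_id)
  branch_of <- function(b) ifelse(is.na(b), "core", b)
  if (format == "BED") {
    lines <- c(sprintf("# BED (0-based half-open): islands of strain %s",
                       strain),
               "# chrom\tstart\tend\tname\tscore\tstrand\tbranch\tcolor")
    if (nrow(runs)) {
      lines <- c(lines, sprintf("%s\t%d\t%d\t%s\t0\t.\t%s\t%s",
                                runs$replicon_id, runs$start, runs$end,
                                runs$island_id, branch_of(runs$branch),
                                cols[runs$island_id]))
    }
    writeLines(lines, path)
  } else if (format == "GFF3") {
    if (nrow(runs)) {
      gr <- GenomicRanges::GRanges(
        seqnames = runs$replicon_id,
        ranges = IRanges::IRanges(start = runs$start + 1L, end = runs$end),
        strand = "*",
        type = "genomic_island",
        ID = runs$island_id,
        mrca = runs$mrca,
        branch = branch_of(runs$branch),
        color = unname(cols[runs$island_id]))
      rtracklayer::export(gr, path, format = "GFF3")
    } else {
      writeLines("##gff-version 3", path)
    }
  } else {
    stop("unknown format: ", format, " (use BED or GFF3)")
  }
  invisible(path)
}

#' Export conservative core gene sets as FASTA
#'
#' One unaligned FASTA per core ortholog set (named `coreNNNN.fa`), with
#' headers `>strain gene_id`; these per-set protein files are the input
#' for external alignment and tree building.
#'
#' @param cores Core sets from [find_conservative_cores()].
#' @param genomes A `genome_set`.
#' @param dir Output directory.
#' @return Character vector of file paths (empty, with a warning, when
#'   there are no core sets).
#' @export
export_core_gene_sets <- function(cores, genomes, dir) {
  if (!nrow(cores)) {
    gi_warn("no conservative core sets to export")
    return(character(0))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prot <- setNames(genomes$genes$protein, genomes$genes$gene_id)
  paths <- character(0)
  for (cs in sort(unique(cores$core_set))) {
    members <- cores[core_set == cs]
    setorder(members, strain)
    aa <- Biostrings::AAStringSet(setNames(
      prot[members$gene_id],
      sprintf("%s %s", members$strain, members$gene_id)))
    p <- file.path(dir, sprintf("core%04d.fa", cs))
    Biostrings::writeXStringSet(aa, p)
    paths <- c(paths, p)
  }
  paths
}

#' Text report on a node, gene, or family
#'
#' `kind = "node"`: all islands with that MRCA and their gene contents
#' per strain. `kind = "gene"`: the gene's family, island, MRCA and
#' branch. `kind = "family"`: members, raw scores to the founding seed,
#' island membership.
#'
#' @param result A `gi_result` from [detect_islands()]/[run_pipeline()].
#' @param kind `"node"`, `"gene"` or `"family"`.
#' @param key Node id, gene id, or family id.
#' @return Character vector of report lines (also printed).
#' @export
query_report <- function(result, kind = c("node", "gene", "family"), key) {
  kind <- match.arg(kind)
  islands <- result$islands
  families <- result$families
  genes <- result$genomes$genes
  isl_of_fam <- data.table(
    family_id = unlist(islands$fams, use.names = FALSE),
    island_id = rep(names(islands$fams),
                    vapply(islands$fams, length, integer(1))))
  lines <- switch(kind,
    node = {
      if (!key %in% names(result$tree$is_leaf)) {
        stop("unknown node: ", key, "; valid nodes: ",
             paste(result$tree$preorder, collapse = ", "))
      }
      isl <- islands$islands[mrca == key]
      hd <- sprintf("Islands with MRCA %s: %d", key, nrow(isl))
      if (!nrow(isl[classification == "insertion"])) {
        hd <- c(hd, "no insertion islands at this node")
      }
      body <- character(0)
      for (iid in isl$island_id) {
        fams <- islands$fams[[iid]]
        gg <- merge(genes, families$membership[family_id %in% fams],
                    by = "gene_id")
        body <- c(body,
                  sprintf("island %s (%s): families %s", iid,
                          isl[island_id == iid, classification],
                          paste(fams, collapse = ",")),
                  sprintf("  %s: %s", unique(gg$strain),
                          vapply(unique(gg$strain), function(s) {
                            paste(sort(gg[strain == s, gene_id]),
                                  collapse = ",")
                          }, character(1))))
      }
      c(hd, body)
    },
    gene = {
      if (!key %in% genes$gene_id) {
        stop("unknown gene: ", key)
      }
      fid <- families$membership[gene_id == key, family_id]
      fam <- families$families[family_id == fid]
      iid <- isl_of_fam[family_id == fid, island_id]
      isl <- islands$islands[island_id == iid]
      c(sprintf("gene %s (strain %s)", key,
                genes[gene_id == key, strain]),
        sprintf("  family: %d (MRCA %s)", fid, fam$mrca),
        sprintf("  island: %s (%s%s)", iid, isl$classification,
                ifelse(isl$classification == "insertion",
                       sprintf(", on branch into %s", isl$branch),
                       "")))
    },
    family = {
      fid <- as.integer(key)
      if (!fid %in% families$families$family_id) {
        stop("unknown family: ", key)
      }
      fam <- families$families[family_id == fid]
      members <- sort(families$membership[family_id == fid, gene_id])
      iid <- isl_of_fam[family_id == fid, island_id]
      seed_lines <- if (!is.na(fam$seed_g1)) {
        sc <- result$scores$pairs
        vapply(members, function(gid) {
          r1 <- sc[(g1 == gid & g2 == fam$seed_g1) |
                   (g2 == gid & g1 == fam$seed_g1), raw]
          r2 <- sc[(g1 == gid & g2 == fam$seed_g2) |
                   (g2 == gid & g1 == fam$seed_g2), raw]
          sprintf("  %s: raw to seed %s / %s",
                  gid,
                  ifelse(length(r1), sprintf("%.3f", max(r1)), "-"),
                  ifelse(length(r2), sprintf("%.3f", max(r2)), "-"))
        }, character(1))
      } else {
        sprintf("  %s (singleton)", members)
      }
      c(sprintf("family %d: %d gene(s), MRCA %s, island %s",
                fid, fam$n_genes, fam$mrca, iid),
        sprintf("  seed: %s - %s (score %s)",
                ifelse(is.na(fam$seed_g1), "-", fam$seed_g1),
                ifelse(is.na(fam$seed_g2), "-", fam$seed_g2),
                ifelse(is.na(fam$seed_score), "-",
                       sprintf("%.3f", fam$seed_score))),
        seed_lines)
    })
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}

#' Export gene annotations as GFF3 (round-trip of input coordinates)
#'
#' Writes every gene of a strain as a GFF3 `CDS` record; coordinates are
#' converted back from the internal 0-based half-open convention to
#' GFF3's 1-based inclusive, reproducing the original GenBank
#' coordinates.
#'
#' @param genomes A `genome_set`.
#' @param strain Strain to export.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_genes_gff3 <- function(genomes, strain, path) {
  g <- genomes$genes[genomes$genes$strain == strain]
  if (!nrow(g)) stop("unknown strain: ", strain)
  gr <- GenomicRanges::GRanges(
    seqnames = g$replicon_id,
    ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
    strand = g$strand,
    type = "CDS", phase = 0L, ID = g$gene_id, locus_tag = g$locus_tag)
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}
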