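#' Load annotated genomes from GenBank files
#'
#' Each file is one strain (possibly with several records/scaffolds).
#' Every CDS feature carrying a `/translation` qualifier becomes a gene;
#' CDS without a translation (e.g. pseudogenes) are skipped with a
#' warning. Gene order per replicon follows coordinate order, and GenBank
#' 1-based inclusive coordinates are converted to the internal 0-based
#' half-open convention. Replicons are treated as linear: gene adjacency
#' never crosses a replicon boundary and there is no circular wrap.
#'
#' @param paths Character vector of GenBank file paths.
#' @param strain_names Optional character vector (same length as `paths`)
#'   overriding the default strain name (the filename stem).
#' @return A `genome_set`: list with `genes` (a `data.table` with columns
#'   `gene_id`, `strain`, `replicon_id`, `index`, `start`, `end`,
#'   `strand`, `protein`, `locus_tag`, `product`) and `strains`.
#' @export
load_genomes <- function(paths, strain_names = NULL) {
  if (is.null(strain_names)) {
    strain_names <- tools::file_path_sans_ext(basename(paths))
  }
  stopifnot(length(strain_names) == length(paths))
  if (anyDuplicated(strain_names)) stop("duplicate strain names")
  all_genes <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    recs <- read_genbank_records(paths[i])
    strain <- strain_names[i]
    rows <- list()
    n_skipped <- 0L
    for (rec in recs) {
      for (ft in rec$features) {
        if (ft$key != "CDS") next
        tr <- ft$qualifiers[["translation"]]
        if (is.null(tr) || !is.character(tr) || !nzchar(tr)) {
          n_skipped <- n_skipped + 1L
          next
        }
        loc <- parse_genbank_location(ft$location)
        if (is.null(loc)) {
          n_skipped <- n_skipped + 1L
          next
        }
        rows[[length(rows) + 1L]] <- data.table(
          strain = strain, replicon_id = rec$replicon,
          start = loc$start1 - 1, end = loc$end1, strand = loc$strand,
          protein = gsub("\\s", "", tr),
          locus_tag = as.character(ft$qualifiers[["locus_tag"]] %||% NA),
          product = as.character(ft$qualifiers[["product"]] %||% NA))
      }
    }
    if (n_skipped > 0) {
      gi_warn(sprintf("%s: skipped %d CDS feature(s) without a usable translation/location",
                      strain, n_skipped))
    }
    if (!length(rows)) {
      stop("no usable genes (CDS with /translation) in strain ", strain)
    }
    dt <- rbindlist(rows)
    setorder(dt, replicon_id, start, end)
    dt[, index := seq_len(.N) - 1L, by = replicon_id]
    all_genes[[i]] <- dt
  }
  genes <- rbindlist(all_genes)
  genes[, gene_id := sprintf("%s_%05d", strain, seq_len(.N)), by = strain]
  stopifnot(!anyDuplicated(genes$gene_id), all(genes$start < genes$end),
            all(nzchar(genes$protein)))
  new_genome_set(genes)
}

#' Construct a genome set from a gene table
#'
#' Low-level constructor used by [load_genomes()], the simulator, and
#' tests. Validates the genome-set invariants (unique gene ids, start <
#' end, consecutive 0-based indices per replicon, non-empty proteins).
#'
#' @param genes A data.frame/data.table with columns `gene_id`, `strain`,
#'   `replicon_id`, `index`, `start`, `end`, `strand`, `protein` and
#'   optionally `locus_tag`, `product`.
#' @return A `genome_set` object.
#' @export
new_genome_set <- function(genes) {
  genes <- as.data.table(genes)
  if (!"locus_tag" %in% names(genes)) genes[, locus_tag := gene_id]
  if (!"product" %in% names(genes)) genes[, product := "hypothetical protein"]
  if (anyDuplicated(genes$gene_id)) stop("gene ids not globally unique")
  if (any(genes$start >= genes$end)) stop("gene with start >= end")
  if (any(!nzchar(genes$protein))) stop("empty protein sequence")
  idx_ok <- genes[, all(sort(index) == seq_len(.N) - 1L),
                  by = .(strain, replicon_id)]$V1
  if (!all(idx_ok)) stop("replicon indices must be consecutive from 0")
  setorder(genes, strain, replicon_id, index)
  obj <- list(genes = genes, strains = sort(unique(genes$strain)))
  class(obj) <- "genome_set"
  obj
}

#' @export
print.genome_set <- function(x, ...) {
  cat(sprintf("genome_set: %d strains, %d genes, %d replicons\n",
              length(x$strains), nrow(x$genes),
              nrow(unique(x$genes[, .(strain, replicon_id)]))))
  invisible(x)
}
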