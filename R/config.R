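#' Default run configuration
#'
#' Returns the full parameter set used by the pipeline and simulator as a
#' named list. Every entry has a documented default; a run configuration
#' round-trips through [write_config()] / [read_config()].
#'
#' @details Parameter groups:
#' \describe{
#'   \item{Candidate filter}{`kmer_k` (amino-acid k-mer length, 4),
#'     `kmer_min_shared` (minimum shared distinct k-mers for a cross-strain
#'     pair to become a candidate, 2).}
#'   \item{Alignment}{`subst_matrix` ("BLOSUM62"), `gap_open` (11),
#'     `gap_extend` (1). Gap costs follow the open + (L-1)*extend
#'     convention for a gap of length L.}
#'   \item{Synteny}{`core_synteny_window` (conservative core genes per
#'     side, 10 -- i.e. a neighborhood of up to 20 core genes),
#'     `local_synteny_window` W (genes per side, 10),
#'     `local_synteny_top` T (top matched pairs averaged, 4).}
#'   \item{Family building}{`family_norm_floor` (-2), `family_core_syn_floor`
#'     (0.25), `family_local_syn_floor` (-2): minimum normalized score /
#'     core synteny / local synteny for a gene to join a family.
#'     `family_bonus_core` (0.5) and `family_bonus_local` (1.0): synteny
#'     levels above which a link's raw score gets `family_bonus` (0.1)
#'     added (capped at 1) before comparison with the seed score.}
#'   \item{Island merging}{`merge_threshold` (0; merge while the best
#'     rearrangement score is strictly greater), `merge_gap_schedule`
#'     (allowed intervening-gene counts for the adjacency relaxation
#'     rounds, `0:5`).}
#'   \item{Simulator}{`sim_root_genes` (300), per-unit-branch-length event
#'     rates `sim_hgt_rate` (17), `sim_del_rate` (35), `sim_dup_rate`
#'     (17), `sim_inv_rate` (4); size ranges `sim_hgt_size` (2-51),
#'     `sim_del_size` (1-50), `sim_dup_size` (1-48), `sim_inv_size`
#'     (5-147) with truncated-geometric means `sim_hgt_size_mean` (4.4),
#'     `sim_del_size_mean` (3.5), `sim_dup_size_mean` (2.8),
#'     `sim_inv_size_mean` (15); `sim_protein_len` (mean protein length,
#'     100 aa; lengths drawn uniformly in 0.5-1.5x the mean),
#'     `sim_subst_rate` (per-site substitutions per unit branch length,
#'     0.3), `sim_intergenic` (nt between consecutive genes, 100),
#'     `sim_seed` (mandatory RNG seed, default 1).}
#'   \item{Misc}{`workers` (1), `export_old_node` ("" = color islands
#'     whose MRCA is outside the focal clade with the reserved color).}
#' }
#'
#' @return Named list of parameters.
#' @export
default_config <- function() {
  list(
    ## candidate pair filter
    kmer_k            = 4L,
    kmer_min_shared   = 2L,
    ## alignment / raw score
    subst_matrix      = "BLOSUM62",
    gap_open          = 11,
    gap_extend        = 1,
    ## synteny windows
    core_synteny_window = 10L,
    local_synteny_window = 10L,
    local_synteny_top = 4L,
    ## family formation
    family_norm_floor      = -2,
    family_core_syn_floor  = 0.25,
    family_local_syn_floor = -2,
    family_bonus_core      = 0.5,
    family_bonus_local     = 1.0,
    family_bonus           = 0.1,
    ## island merging
    merge_threshold    = 0,
    merge_gap_schedule = 0:5,
    ## simulator
    sim_root_genes    = 300L,
    sim_hgt_rate      = 17,
    sim_del_rate      = 35,
    sim_dup_rate      = 17,
    sim_inv_rate      = 4,
    sim_hgt_size      = c(2L, 51L),
    sim_del_size      = c(1L, 50L),
    sim_dup_size      = c(1L, 48L),
    sim_inv_size      = c(5L, 147L),
    sim_hgt_size_mean = 4.4,
    sim_del_size_mean = 3.5,
    sim_dup_size_mean = 2.8,
    sim_inv_size_mean = 15,
    sim_protein_len   = 100L,
    sim_subst_rate    = 0.3,
    sim_intergenic    = 100L,
    sim_seed          = 1L,
    ## misc
    workers           = 1L,
    export_old_node   = ""
  )
}

#' Read / write a key=value configuration file
#'
#' Plain `key = value` text; vectors are comma-separated; `#` starts a
#' comment. Unknown keys are an error, so typos fail early. Values are
#' coerced to the type of the corresponding [default_config()] entry.
#'
#' @param path File path.
#' @param config Named list as from [default_config()].
#' @return `read_config()` returns a full config list (defaults overlaid
#'   with the file's entries); `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- default_config()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) stop("malformed config line: ", ln)
    kv <- regmatches(ln, regexpr("=", ln, fixed = TRUE), invert = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    if (!key %in% names(cfg)) stop("unknown config key: ", key)
    proto <- cfg[[key]]
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    cfg[[key]] <- if (is.numeric(proto)) {
      if (!length(parts)) stop("empty value for numeric key: ", key)
      v <- as.numeric(parts)
      if (is.integer(proto)) as.integer(v) else v
    } else if (!length(parts)) {
      ""
    } else {
      parts
    }
  }
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    sprintf("%s = %s", k, paste(config[[k]], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

## Merge user-supplied partial config over defaults.
as_config <- function(config = NULL) {
  cfg <- default_config()
  if (is.null(config)) return(cfg)
  bad <- setdiff(names(config), names(cfg))
  if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
  cfg[names(config)] <- config
  cfg
}
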