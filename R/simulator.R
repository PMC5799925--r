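## Clade genome evolution simulator.
##
## A root genome of random proteins evolves down a branch-length species
## tree. Along each branch, per-type event counts are Poisson in
## rate * branch length; events (horizontal transfer of novel genes,
## contiguous deletion, duplication to a new position, inversion) are
## applied in random order at uniform positions, then every protein
## accumulates residue substitutions. Leaves are emitted as genomes with
## synthetic coordinates, together with a truth log of every event and a
## per-gene origin label (root ancestry or the originating transfer
## event), so pipeline predictions can be scored against ground truth.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

random_protein <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

## Truncated-geometric event size on [lo, hi] with approximate mean
## `mean_size` (lo + geometric tail, capped at hi).
sample_size <- function(lo, hi, mean_size) {
  extra_mean <- max(mean_size - lo, 1e-9)
  p <- 1 / (1 + extra_mean)
  min(hi, lo + rgeom(1L, p))
}

#' Sample evolutionary events for one branch
#'
#' Independent Poisson counts per event type with mean
#' `rate * branch_length`; sizes drawn from truncated geometric
#' distributions within the configured ranges; the combined event list is
#' returned in random order of application. Positions are resolved later,
#' against the genome as it mutates.
#'
#' @param branch_length Nonnegative branch length.
#' @param config Optional configuration (`sim_*_rate`, `sim_*_size`,
#'   `sim_*_size_mean`).
#' @return A list of events, each `list(type, size)` with `type` in
#'   `hgt`, `del`, `dup`, `inv`.
#' @export
sample_events <- function(branch_length, config = NULL) {
  cfg <- as_config(config)
  types <- c("hgt", "del", "dup", "inv")
  rates <- c(cfg$sim_hgt_rate, cfg$sim_del_rate, cfg$sim_dup_rate,
             cfg$sim_inv_rate)
  ranges <- list(cfg$sim_hgt_size, cfg$sim_del_size, cfg$sim_dup_size,
                 cfg$sim_inv_size)
  means <- c(cfg$sim_hgt_size_mean, cfg$sim_del_size_mean,
             cfg$sim_dup_size_mean, cfg$sim_inv_size_mean)
  events <- list()
  for (t in seq_along(types)) {
    n <- rpois(1L, rates[t] * branch_length)
    for (i in seq_len(n)) {
      events[[length(events) + 1L]] <- list(
        type = types[t],
        size = sample_size(ranges[[t]][1], ranges[[t]][2], means[t]))
    }
  }
  if (length(events) > 1) events <- events[sample.int(length(events))]
  events
}

#' Evolve protein sequences along a branch
#'
#' Residue-level change follows a Jukes-Cantor-type jump chain over the
#' 20 amino acids: each site experiences a Poisson(`rate *
#' branch_length`) number of substitution events, and each event replaces
#' the residue with a uniform draw among the other 19. A site therefore
#' differs from its start with probability close to
#' `1 - exp(-rate * branch_length)` on short branches, and identity
#' saturates at the equilibrium value 1/20 on long ones (closed form:
#' `P(same) = 1/20 + (19/20) * exp(-(20/19) * rate * branch_length)`).
#'
#' @param proteins Character vector of amino-acid strings.
#' @param branch_length Branch length.
#' @param rate Per-site substitution rate per unit branch length.
#' @return Character vector of evolved proteins.
#' @export
evolve_sequence <- function(proteins, branch_length, rate) {
  lambda <- rate * branch_length
  if (lambda <= 0) return(proteins)
  vapply(proteins, function(pr) {
    aa <- strsplit(pr, "", fixed = TRUE)[[1]]
    k <- rpois(length(aa), lambda)
    for (i in which(k > 0L)) {
      for (j in seq_len(k[i])) {
        aa[i] <- sample(AA20[AA20 != aa[i]], 1L)
      }
    }
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate genome evolution over a species tree
#'
#' @param tree A `species_tree` with positive branch lengths.
#' @param config Optional configuration; see [default_config()]
#'   (`sim_*` entries; `sim_seed` seeds all randomness).
#' @return A `sim_result`: list with `genomes` (a `genome_set` over the
#'   tree's leaves, one linear replicon per strain), `truth` (a
#'   `data.table` of events: `event_id`, `type`, `branch` (the node the
#'   edge enters), `size` (realized gene count), `tokens`), `origins`
#'   (`strain`, `replicon_id`, `index`, `gene_id`, `origin`; `origin` is
#'   `"root"` or an `hgt` event id), and `tree`.
#' @export
simulate_clade <- function(tree, config = NULL) {
  cfg <- as_config(config)
  if (any(is.na(tree$branch_length[tree$preorder[-1]])) ||
      any(tree$branch_length[tree$preorder[-1]] <= 0)) {
    stop("simulator requires positive branch lengths on every edge")
  }
  set.seed(as.integer(cfg$sim_seed))
  lenmean <- cfg$sim_protein_len
  n0 <- cfg$sim_root_genes
  lens <- pmax(30L, as.integer(round(runif(n0, 0.5 * lenmean,
                                           1.5 * lenmean))))
  root <- data.table(
    token = seq_len(n0),
    protein = vapply(lens, random_protein, character(1)),
    origin = "root", strand = "+")
  env <- new.env(parent = emptyenv())
  env$next_token <- n0 + 1L
  env$hgt_counter <- 0L
  env$truth <- list()
  leaf_states <- list()
  walk <- function(node, state) {
    for (child in tree$children[[node]]) {
      cs <- evolve_branch(state, child, tree$branch_length[child], cfg, env)
      if (tree$is_leaf[child]) leaf_states[[child]] <<- cs
      else walk(child, cs)
    }
  }
  walk(tree$preorder[1], root)
  ## emit leaf genomes with synthetic coordinates
  gap <- cfg$sim_intergenic
  gene_rows <- list()
  origin_rows <- list()
  for (s in names(leaf_states)) {
    st <- leaf_states[[s]]
    n <- nrow(st)
    nt_len <- 3L * nchar(st$protein) + 3L
    starts <- cumsum(c(gap, head(nt_len + gap, -1L)))
    dt <- data.table(
      gene_id = sprintf("%s_%05d", s, seq_len(n)),
      strain = s, replicon_id = paste0(s, "_chr"),
      index = seq_len(n) - 1L,
      start = starts, end = starts + nt_len,
      strand = st$strand, protein = st$protein,
      locus_tag = sprintf("%s_%05d", s, seq_len(n)),
      product = "hypothetical protein")
    gene_rows[[s]] <- dt
    origin_rows[[s]] <- data.table(
      strain = s, replicon_id = dt$replicon_id, index = dt$index,
      gene_id = dt$gene_id, origin = st$origin)
  }
  truth <- if (length(env$truth)) rbindlist(env$truth) else
    data.table(event_id = character(0), type = character(0),
               branch = character(0), size = integer(0),
               tokens = character(0))
  res <- list(genomes = new_genome_set(rbindlist(gene_rows)),
              truth = truth,
              origins = rbindlist(origin_rows),
              tree = tree)
  class(res) <- "sim_result"
  res
}

## Apply one branch: sampled events in random order, then substitutions.
evolve_branch <- function(state, child, bl, cfg, env) {
  events <- sample_events(bl, cfg)
  for (ev in events) {
    n <- nrow(state)
    if (ev$type == "hgt") {
      env$hgt_counter <- env$hgt_counter + 1L
      eid <- sprintf("hgt%04d", env$hgt_counter)
      k <- ev$size
      lens <- pmax(30L, as.integer(round(runif(k, 0.5 * cfg$sim_protein_len,
                                               1.5 * cfg$sim_protein_len))))
      block <- data.table(
        token = seq.int(env$next_token, length.out = k),
        protein = vapply(lens, random_protein, character(1)),
        origin = eid, strand = "+")
      env$next_token <- env$next_token + k
      pos <- sample.int(n + 1L, 1L) - 1L   # gap position 0..n
      state <- insert_block(state, block, pos)
      env$truth[[length(env$truth) + 1L]] <- data.table(
        event_id = eid, type = "hgt", branch = child, size = k,
        tokens = paste(block$token, collapse = ","))
    } else if (ev$type == "del") {
      from <- sample.int(n, 1L)
      to <- min(n, from + ev$size - 1L)
      if (to - from + 1L >= n) {
        stop("simulated genome shrank to zero genes on the branch into ",
             child, "; lower sim_del_rate or sim_del_size_mean")
      }
      removed <- state$token[from:to]
      state <- state[-(from:to)]
      env$truth[[length(env$truth) + 1L]] <- data.table(
        event_id = sprintf("del%05d", length(env$truth) + 1L),
        type = "del", branch = child, size = to - from + 1L,
        tokens = paste(removed, collapse = ","))
    } else if (ev$type == "dup") {
      from <- sample.int(n, 1L)
      to <- min(n, from + ev$size - 1L)
      block <- state[from:to]
      k <- nrow(block)
      block <- copy(block)
      block[, token := seq.int(env$next_token, length.out = k)]
      env$next_token <- env$next_token + k
      ## insertion gap outside the interior of the source block
      allowed <- setdiff(0:n, seq.int(from, to - 1L))
      pos <- allowed[sample.int(length(allowed), 1L)]
      state <- insert_block(state, block, pos)
      env$truth[[length(env$truth) + 1L]] <- data.table(
        event_id = sprintf("dup%05d", length(env$truth) + 1L),
        type = "dup", branch = child, size = k,
        tokens = paste(block$token, collapse = ","))
    } else {                               # inversion
      from <- sample.int(n, 1L)
      to <- min(n, from + ev$size - 1L)
      seg <- state[from:to]
      seg <- seg[rev(seq_len(nrow(seg)))]
      seg[, strand := ifelse(strand == "+", "-", "+")]
      state <- rbindlist(list(
        if (from > 1L) state[1:(from - 1L)] else NULL,
        seg,
        if (to < n) state[(to + 1L):n] else NULL))
      env$truth[[length(env$truth) + 1L]] <- data.table(
        event_id = sprintf("inv%05d", length(env$truth) + 1L),
        type = "inv", branch = child, size = to - from + 1L,
        tokens = paste(seg$token, collapse = ","))
    }
  }
  state <- copy(state)
  state[, protein := evolve_sequence(protein, bl, cfg$sim_subst_rate)]
  state
}

insert_block <- function(state, block, pos) {
  n <- nrow(state)
  rbindlist(list(
    if (pos > 0L) state[1:pos] else NULL,
    block,
    if (pos < n) state[(pos + 1L):n] else NULL))
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result: %d strains, %d genes; %d events (%s)\n",
              length(x$genomes$strains), nrow(x$genomes$genes),
              nrow(x$truth),
              paste(sprintf("%s=%d", names(table(x$truth$type)),
                            as.integer(table(x$truth$type))),
                    collapse = ", ")))
  invisible(x)
}

#' Write a simulation to disk
#'
#' One GenBank file per leaf strain (feature annotation with
#' translations; consumed directly by [load_genomes()]), plus
#' `truth_events.tsv` (the event log) and `gene_origins.tsv` (per-gene
#' origin labels keyed by strain/replicon/gene-order index).
#'
#' @param sim A `sim_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in sim$genomes$strains) {
    write_genbank(sim$genomes$genes[strain == s],
                  file.path(dir, paste0(s, ".gbk")))
  }
  fwrite(sim$truth, file.path(dir, "truth_events.tsv"), sep = "\t")
  fwrite(sim$origins, file.path(dir, "gene_origins.tsv"), sep = "\t")
  invisible(dir)
}
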