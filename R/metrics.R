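## Base-wise evaluation of island predictions.
##
## Truth and predictions are both reduced to nucleotide interval sets per
## leaf genome. A truth interval is the span (first gene start to last
## gene end) of a maximal run of consecutive genes sharing one horizontal
## transfer event as origin; a predicted interval is the span of a
## maximal run of consecutive genes belonging to one predicted insertion
## island. The headline metrics require the predicted island to sit on
## the same tree branch as the true event.

runs_to_intervals <- function(dt) {
  ## dt: strain, replicon_id, index, start, end, label  (one row per gene)
  setorder(dt, strain, replicon_id, label, index)
  dt[, run_id := cumsum(c(1L, diff(index) != 1L)),
     by = .(strain, replicon_id, label)]
  dt[, .(start = min(start), end = max(end)),
     by = .(strain, replicon_id, label, run_id)]
}

#' Nucleotide labelings of truth events and predicted islands
#'
#' @param sim A `sim_result`.
#' @param focal_only Keep only events on branches inside the focal clade
#'   (at or below the tree's focal root). Insertions on outgroup branches
#'   or above the focal root are outside the method's scope -- it
#'   classifies such material as core by construction, since the
#'   outgroups exist precisely to polarize core against inserted genes --
#'   so they are not part of the ground truth by default.
#' @return A `data.table` with `strain`, `replicon_id`, `label` (event
#'   id), `branch`, `start`, `end` — one row per maximal run of
#'   consecutive genes sharing a transfer-event origin in a leaf genome.
#' @export
truth_labeling <- function(sim, focal_only = TRUE) {
  g <- merge(sim$genomes$genes[, .(strain, replicon_id, index, start, end)],
             sim$origins[, .(strain, replicon_id, index, origin)],
             by = c("strain", "replicon_id", "index"))
  g <- g[origin != "root"]
  if (!nrow(g)) {
    return(data.table(strain = character(0), replicon_id = character(0),
                      label = character(0), branch = character(0),
                      start = integer(0), end = integer(0)))
  }
  setnames(g, "origin", "label")
  iv <- runs_to_intervals(g)[, run_id := NULL][]
  ev <- unique(sim$truth[type == "hgt", .(label = event_id, branch)])
  if (focal_only) {
    focal <- vapply(ev$branch, function(nd) {
      tree_is_ancestor(sim$tree, sim$tree$focal_root, nd)
    }, logical(1))
    ev <- ev[focal]
  }
  merge(iv, ev, by = "label")
}

#' Nucleotide labeling of predicted insertion islands
#'
#' @param islands A `gi_islands` (classified).
#' @param genomes A `genome_set`.
#' @return A `data.table` with `strain`, `replicon_id`, `label` (island
#'   id), `branch`, `start`, `end` — one row per maximal run of
#'   consecutive genes of an insertion island in a strain.
#' @export
predicted_labeling <- function(islands, genomes) {
  ins <- islands$islands[classification == "insertion"]
  if (!nrow(ins)) {
    return(data.table(strain = character(0), replicon_id = character(0),
                      label = character(0), branch = character(0),
                      start = integer(0), end = integer(0)))
  }
  fam_isl <- data.table(
    family_id = unlist(islands$fams[ins$island_id], use.names = FALSE),
    label = rep(ins$island_id,
                vapply(islands$fams[ins$island_id], length, integer(1))))
  g <- merge(genomes$genes[, .(gene_id, strain, replicon_id, index,
                               start, end)],
             islands$families$membership, by = "gene_id")
  g <- merge(g, fam_isl, by = "family_id")
  iv <- runs_to_intervals(g)[, run_id := NULL][]
  merge(iv, ins[, .(label = island_id, branch)], by = "label")
}

iranges_of <- function(dt) {
  IRanges::reduce(IRanges::IRanges(start = dt$start + 1L, end = dt$end))
}

#' Base-wise true positive rate and positive predictive value
#'
#' A nucleotide is a true positive when it lies in a true transfer-event
#' interval and in a predicted insertion-island interval assigned to the
#' same branch. `TPR = TP / all truly-island nucleotides`;
#' `PPV = TP / all nucleotides inside predicted insertion islands`
#' (core-classified islands are not part of the denominator). With
#' `branch_agnostic = TRUE` the branch-match requirement is dropped
#' (diagnostic variant).
#'
#' @param truth Output of [truth_labeling()].
#' @param predicted Output of [predicted_labeling()].
#' @param branch_agnostic Drop the same-branch requirement.
#' @return List with `tpr`, `ppv` (either may be `NA` with a warning when
#'   its denominator is empty), `tp`, `truth_bases`, `predicted_bases`.
#' @export
basewise_confusion <- function(truth, predicted, branch_agnostic = FALSE) {
  key_cols <- if (branch_agnostic) c("strain", "replicon_id") else
    c("strain", "replicon_id", "branch")
  truth_bases <- 0; pred_bases <- 0; tp <- 0
  for (ss in split(truth, by = c("strain", "replicon_id"))) {
    truth_bases <- truth_bases + sum(IRanges::width(iranges_of(ss)))
  }
  for (ss in split(predicted, by = c("strain", "replicon_id"))) {
    pred_bases <- pred_bases + sum(IRanges::width(iranges_of(ss)))
  }
  tkeys <- unique(truth[, ..key_cols])
  for (i in seq_len(nrow(tkeys))) {
    tt <- truth[tkeys[i], on = key_cols]
    pp <- predicted[tkeys[i], on = key_cols, nomatch = NULL]
    if (!nrow(pp)) next
    tp <- tp + sum(IRanges::width(
      IRanges::intersect(iranges_of(tt), iranges_of(pp))))
  }
  tpr <- if (truth_bases > 0) tp / truth_bases else {
    gi_warn("no truly-island nucleotides: TPR undefined"); NA_real_
  }
  ppv <- if (pred_bases > 0) tp / pred_bases else {
    gi_warn("no predicted insertion nucleotides: PPV undefined"); NA_real_
  }
  list(tpr = tpr, ppv = ppv, tp = tp, truth_bases = truth_bases,
       predicted_bases = pred_bases)
}

#' Fraction of true islands overlapped by exactly one predicted island
#'
#' A true island is the leaf-genome footprint of one transfer event in
#' one strain (possibly several intervals after rearrangement). The
#' fraction counts footprints overlapped (>= 1 shared nucleotide) by
#' exactly one predicted insertion island; footprints with zero
#' overlapping predictions count against the fraction.
#'
#' @param truth Output of [truth_labeling()].
#' @param predicted Output of [predicted_labeling()].
#' @return Fraction in `[0, 1]`, or `NA` (with a warning) when there are
#'   no true islands.
#' @export
single_island_fraction <- function(truth, predicted) {
  if (!nrow(truth)) {
    gi_warn("no true islands: single-island fraction undefined")
    return(NA_real_)
  }
  feet <- split(truth, by = c("label", "strain"), drop = TRUE)
  n_single <- 0L
  for (ft in feet) {
    pp <- predicted[strain == ft$strain[1]]
    if (nrow(pp)) {
      fr <- iranges_of(ft)
      hit <- vapply(split(pp, by = "label"), function(pl) {
        pr <- IRanges::IRanges(pl$start + 1L, pl$end)
        sum(IRanges::width(IRanges::intersect(fr, IRanges::reduce(pr)))) > 0
      }, logical(1))
      if (sum(hit) == 1L) n_single <- n_single + 1L
    }
  }
  n_single / length(feet)
}

#' Coverage of literature validation ranges by predicted islands
#'
#' For each validation range (a nucleotide interval on a strain's
#' replicon): `base_coverage` = covered bases / range length;
#' `in_single_island` = whether exactly one predicted island overlaps the
#' range; `extra_coverage` = bases of overlapping islands outside the
#' range divided by the range length.
#'
#' @param ranges A data.frame with `strain`, `replicon_id`, `start`,
#'   `end` (0-based half-open).
#' @param predicted Output of [predicted_labeling()] (or any interval
#'   table with `strain`, `replicon_id`, `label`, `start`, `end`).
#' @return A `data.table` with one row per range plus the three metrics,
#'   and attributes `summary` (means over ranges).
#' @export
range_coverage <- function(ranges, predicted) {
  ranges <- as.data.table(ranges)
  if (any(ranges$end <= ranges$start)) stop("empty validation range")
  out <- vector("list", nrow(ranges))
  for (i in seq_len(nrow(ranges))) {
    rg <- ranges[i]
    rr <- IRanges::IRanges(rg$start + 1L, rg$end)
    pp <- predicted[strain == rg$strain & replicon_id == rg$replicon_id]
    overl <- character(0)
    cov <- 0L; extra <- 0L
    if (nrow(pp)) {
      by_isl <- split(pp, by = "label")
      hit <- vapply(by_isl, function(pl) {
        sum(IRanges::width(IRanges::intersect(
          rr, iranges_of(pl)))) > 0
      }, logical(1))
      overl <- names(by_isl)[hit]
      if (length(overl)) {
        union_iv <- iranges_of(pp[label %in% overl])
        cov <- sum(IRanges::width(IRanges::intersect(rr, union_iv)))
        extra <- sum(IRanges::width(IRanges::setdiff(union_iv, rr)))
      }
    }
    out[[i]] <- data.table(
      rg, base_coverage = cov / IRanges::width(rr),
      n_islands = length(overl),
      in_single_island = length(overl) == 1L,
      extra_coverage = extra / IRanges::width(rr))
  }
  res <- rbindlist(out)
  attr(res, "summary") <- list(
    base_coverage = res[, sum(base_coverage * (end - start)) / sum(end - start)],
    in_single_island = mean(res$in_single_island),
    extra_coverage = mean(res$extra_coverage))
  res
}

#' Per-branch base-wise TPR and PPV
#'
#' Splits the base-wise confusion by tree branch: for each branch, TPR
#' over the truth intervals of events on that branch, and PPV over the
#' predicted insertion intervals assigned to it (the style of per-branch
#' accuracy annotation used on validation trees).
#'
#' @param truth Output of [truth_labeling()].
#' @param predicted Output of [predicted_labeling()].
#' @return A `data.table` with `branch`, `tpr`, `ppv`, `truth_bases`,
#'   `predicted_bases` (one row per branch seen in either table; rates
#'   are `NA` where the denominator is empty).
#' @export
per_branch_confusion <- function(truth, predicted) {
  branches <- union(unique(truth$branch), unique(predicted$branch))
  out <- lapply(sort(branches), function(b) {
    res <- suppressWarnings(
      basewise_confusion(truth[branch == b], predicted[branch == b]))
    data.table(branch = b, tpr = res$tpr, ppv = res$ppv,
               truth_bases = res$truth_bases,
               predicted_bases = res$predicted_bases)
  })
  rbindlist(out)
}

#' Evaluate pipeline predictions against simulator truth
#'
#' Convenience wrapper: computes the base-wise confusion (branch-aware
#' and branch-agnostic) and the single-island fraction for a pipeline
#' result on a simulated clade.
#'
#' @param sim A `sim_result`.
#' @param islands A classified `gi_islands` computed on the simulated
#'   genomes.
#' @param genomes Optional `genome_set` the islands were computed on
#'   (defaults to `sim$genomes`; pass the reloaded set when the pipeline
#'   ran on files written by [write_sim()]).
#' @return List with `tpr`, `ppv`, `single_island_fraction`,
#'   `tpr_any_branch`, `ppv_any_branch`, and the labelings.
#' @export
evaluate_predictions <- function(sim, islands, genomes = sim$genomes) {
  tl <- truth_labeling(sim)
  pl <- predicted_labeling(islands, genomes)
  strict <- basewise_confusion(tl, pl)
  loose <- basewise_confusion(tl, pl, branch_agnostic = TRUE)
  list(tpr = strict$tpr, ppv = strict$ppv,
       single_island_fraction = single_island_fraction(tl, pl),
       tpr_any_branch = loose$tpr, ppv_any_branch = loose$ppv,
       truth_bases = strict$truth_bases,
       predicted_bases = strict$predicted_bases,
       truth = tl, predicted = pl)
}
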