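---
title: "Phylogeny-aware genomic island inference: models and methods"
author: "phyloGI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogeny-aware genomic island inference: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Every protein-coding gene in a clade of closely related bacteria has one
of two origins: it descends from the clade's most recent common ancestor
(a *core* gene), or it arrived later by horizontal transfer. Genes that
arrive together in one transfer event form a *genomic island*: a
contiguous block in the recipient genome, present in exactly the strains
descended from the recipient lineage, and absent from the outgroups.

phyloGI takes a set of annotated genomes (GenBank), a rooted binary
species tree whose leaves are the strains, and a designated *focal
clade* (the subtree under study; the remaining leaves are outgroups used
to polarize core against inserted material). It infers, for each gene,
which origin it has, groups horizontally acquired genes into islands,
and assigns each island to the tree branch on which it inserted.
Islands whose family ancestry predates the focal clade are reported as
core. The three stages are:

1. **Scoring.** Cross-strain candidate gene pairs receive a *raw* score
   (a rescaled global alignment score), a *norm* score (the raw score
   z-scored against the distribution over very conservative single-copy
   orthologs for that strain pair), and two neighborhood-conservation
   scores (*core synteny* over a window of conservative core genes and
   *local synteny* over all neighbors).
2. **Family building.** A species-tree-aware seeded single-linkage
   clustering, processed from the root downwards, so that every family
   corresponds to descent from one ancestral gene *within* the tree;
   deeper homology is deliberately split into separate families.
3. **Island assembly.** Families sharing an MRCA are merged when a
   parsimony *rearrangement score* supports their adjacency in that
   ancestor, over rounds of progressively relaxed adjacency.

### Score definitions

For proteins $p_A, p_B$ with global affine-gap alignment score $g$,

$$\text{raw} = \frac{g - a}{b - a}, \qquad
  a = -2\,o - e\,\bigl((\ell_A - 1) + (\ell_B - 1)\bigr), \qquad
  b = \text{self-score of the shorter protein},$$

where $o$ and $e$ are the gap-open and gap-extend penalties (a gap of
length $L$ costs $o + (L-1)e$), $a$ is the score of the all-gap
alignment (each sequence opposite one long gap), and $b$ is the sum of
diagonal substitution-matrix values of the shorter sequence. The raw
score is clamped to $[0,1]$; identical proteins score exactly 1. When
the two proteins have equal length we take $b$ as the smaller of the two
self-scores, which keeps the score symmetric and keeps $g \le b$ in
practice.

Normalization uses *conservative core genes*: ortholog sets with exactly
one member per strain in which every member is the unique best
raw-score hit of every other (all-around best reciprocal hits). For
each strain pair, $m$ and $s$ are the mean and population standard
deviation of raw scores over these core pairs, and
$\text{norm} = (\text{raw} - m)/s$. By construction the norm scores of
the core pairs themselves have mean 0 and unit SD, which makes one
threshold meaningful across strain pairs at different distances.

The **core synteny score** of genes $A$ and $B$ compares the core-set
identities of the nearest `core_synteny_window` (default 10)
conservative core genes on each side of each gene — up to 20 in total.
Each direction divides the number of shared core sets by the size of
that gene's own core neighborhood; the reported score is the mean of
the two directions, which removes the dependence on argument order and
equals the one-directional value whenever both neighborhoods hold the
full window. A neighborhood with no core genes (possible on very short
contigs) contributes 0 with a warning.

The **local synteny score** takes all genes within
`local_synteny_window` (default $W = 10$) positions of each gene, and
matches scored cross-neighborhood pairs greedily without replacement in
order of decreasing norm score; the score is the sum of the up-to-$T$
(default 4) best matched scores divided by $T$, with missing matches
contributing 0. The matching is deliberately greedy rather than
optimal — the test suite pins this down with a $2 \times 2$ case where
the greedy and the optimal matchings differ — because determinism and
speed matter more here than the exact value of an internal score.

### Family building

Internal nodes are visited in pre-order. At a node, group 1 holds the
not-yet-clustered genes of the strains under the left child, group 2
those under the right child; genes of strains outside the node's
subtree are ignored. Every gene proposes its best raw-score partner in
the opposite group; the de-duplicated proposals are *seeds*, processed
in order of decreasing score. A seed whose genes are both still
unclustered founds a family, which grows by single linkage: an
unclustered gene of either group joins if some link to a current member
has raw score at least the seed score *after* an optional synteny bonus
(`family_bonus`, default 0.1, added when the link's core synteny
$\ge$ `family_bonus_core` = 0.5 and local synteny $\ge$
`family_bonus_local` = 1.0, capped at 1), and the link clears three
floors: norm $\ge$ `family_norm_floor` (default $-2$), core synteny
$\ge$ `family_core_syn_floor` (default 0.25), local synteny $\ge$
`family_local_syn_floor` (default $-2$).

Two design choices deserve emphasis:

* **Seeds must clear the same floors as member links.** The candidate
  k-mer prefilter is intentionally permissive, so the score graph
  contains links between unrelated proteins whose raw scores are small
  but nonzero (the all-gap floor construction keeps even unrelated
  pairs above zero). A floor-free seed drawn from such a link would
  found a family at a too-high tree node with a near-zero seed score,
  and single linkage would then absorb entire true islands into it.
  Requiring every link that founds or extends a family to pass the norm
  and synteny floors is the package's analog of the significance cutoff
  an external search tool would apply before any scores exist. In our
  validation runs this single rule is the difference between a working
  and a broken method.
* **Only cross-strain links exist.** Within-strain paralogs join
  families only through cross-strain links; the synteny floors keep
  translocated or duplicated copies in other strains from riding into a
  family on sequence similarity alone, so each insertion location forms
  its own family — and hence its own island.

After all nodes are processed, each remaining gene becomes a singleton
family at its own leaf — these carry strain-specific insertions. Every
family records the MRCA of its member strains; this node determines the
island grouping and the final classification.

### Island assembly and the rearrangement score

Adjacency evolution is modeled as a single binary character — "are the
two blocks adjacent?" — with unit cost per gain or loss. For two
islands with the same MRCA, each of the four end pairings is scored by
fixed-root small parsimony on the subtree below the MRCA: tips are
labeled adjacent / non-adjacent by observation (at most `gap`
intervening genes counts as adjacent), tips where either island is
absent are wildcards, and

$$\text{rearrangement score} =
  \text{cost}(\text{root non-adjacent}) - \text{cost}(\text{root adjacent}).$$

The score of the island pair is the maximum over the four pairings, and
the winning pairing dictates the concatenation order on merge (either
island may be reversed; ancestral order has no orientation). On a
binary tree the score lies in $[-2, 2]$: changing the root state can
save or cost at most one event on each of the two child edges. The test
suite proves the implementation against exhaustive enumeration of all
internal state assignments on trees up to six leaves. When the MRCA is
a leaf the "subtree" is that single strain and the score reduces to
$\pm 1$ (or 0 when missing).

Merging is greedy within each MRCA group: repeatedly merge the
best-scoring pair while the best score exceeds `merge_threshold`
(default 0, i.e. strictly positive evidence), ties broken by the
smallest island-id pair; then relax the adjacency allowance through
`merge_gap_schedule` (default gaps 0–5) and repeat. Because a pair's
score depends only on the two islands' end families, only scores
involving the merged island are recomputed, and candidate pairs are
restricted to islands with adjacency evidence in at least one strain — a
score can only be positive with at least one adjacent observation.

Islands whose MRCA is at or below the focal root are insertions on the
branch entering their MRCA; an island whose MRCA *is* the focal root is
an insertion on the branch entering the focal clade (it is absent from
the outgroups, and it is precisely presence in an outgroup that makes a
family core). All other islands are core.

## The simulator: what it emulates, and what it does not

`simulate_clade()` grows a root genome of random proteins down the tree.
Per branch, event counts are Poisson with mean rate × branch length per
type; events are applied in uniformly shuffled order at uniform
positions: horizontal transfer inserts a block of novel random genes,
deletion removes a contiguous block, duplication copies a block to a new
position (outside the source block's interior), inversion reverses a
block and flips strands. Residues then evolve by a Jukes–Cantor-type
jump chain on the 20 amino acids: each site experiences a Poisson
number of substitution events, each replacing the residue uniformly
among the other 19, so identity decays to the equilibrium value 1/20 on
long branches.

Defaults are chosen to mirror, at reduced scale, the event regime of an
enteric-bacteria clade: 300-gene root genomes on an 11-taxon tree
(ladder-like focal clade `A`–`I`, outgroups `J`, `K`, total tree length
≈ 2.24) with rates 17 : 35 : 17 : 4 (HGT : deletion : duplication :
inversion) per unit branch length — about 37, 77, 37 and 9 expected
events per run, i.e. the same events-per-root-gene densities as a
full-size clade with ~4000-gene genomes and roughly 495/1009/494/125
events. Event sizes are truncated geometric within the ranges 2–51
(HGT), 1–50 (deletion), 1–48 (duplication) and 5–147 (inversion) genes.
The size *ranges* match what a full-scale run exhibits; the geometric
shape (means ≈ 4.4, 3.5, 2.8 and 15 genes) is the package's own choice,
made once, for two reasons: small events dominate real indel spectra,
and a mean-25-gene uniform deletion distribution at realistic per-gene
deletion densities would turn the genome over several times per lineage,
leaving no conservative core genes — at which point normalization, and
the method itself, are impossible. With these means, gene gains balance
losses in expectation (stationary genome size) and roughly 40% of root
genes survive clade-wide.

What the simulator deliberately does **not** emulate: nucleotide-level
sequence (genes carry synthetic coordinates with fixed 100-nt
intergenic spacing), codon structure, rate heterogeneity across sites
or genes, insertion hotspots, repeated insertion of similar islands
(novel HGT genes are always fresh random sequences, so the pipeline is
never asked to distinguish re-insertions — a documented limitation of
the method itself), plasmids, or multi-replicon genomes. A passing
validation run therefore shows that the machinery correctly recovers
islands under the model's own assumptions — clean orthology, preserved
gene order between events — not that it is robust to compositional
artifacts or assembly noise in real data.

## The validation experiment and its metrics

`run_validation_experiment()` simulates clades on the validation tree,
writes the leaves as GenBank, reloads them through the standard input
path, runs the full pipeline, and scores base-wise: a nucleotide is a
true positive when it lies both in a true island footprint and in a
predicted insertion island assigned to the *same branch*. Because a
single 300-gene clade carries only a few dozen transfer events, the
experiment pools three independently simulated clades (seeds derived
from the one given) and computes every metric over the pooled
nucleotides and footprints — roughly 120 events in total — so the
estimate does not hinge on whether one unlucky large event lands on a
deep internal branch. TPR divides
by all truly-island nucleotides, PPV by all nucleotides in predicted
insertion islands (core islands are excluded from the denominator; a
diagnostic branch-agnostic variant is also computed). The
single-island fraction is the share of per-strain event footprints
overlapped by exactly one predicted island, with zero-overlap footprints
counting against it. Ground truth is restricted to events on focal-clade
branches: an insertion on an outgroup branch is, to this method, core
material by definition — outgroups exist precisely to make that call —
so counting such events would measure the scope of the question, not
the quality of the answer. The acceptance suite runs this experiment at
the 300-gene scale (a few minutes per clade on one CPU) and checks
TPR >= 0.85, PPV >= 0.51 and single-island fraction >= 0.83 -- the
accuracy bar the method is expected to clear under these study
conditions.

PPV is the metric that stays furthest from 1, for a structural reason:
duplications create blocks that are genuinely new at their location and
absent from outgroups. Sequence alone cannot distinguish them from
horizontal acquisitions, and the method classifies them as insertions.
This failure mode is inherent to the model, not to the implementation.

## Numerical and determinism choices

* Alignment uses BLOSUM62 with gap open 11 / extend 1 (standard protein
  search defaults; configurable). Biostrings charges gaps as
  $o' + Le$, so the package passes $o' = o - e$ to realize the
  $o + (L-1)e$ convention used in the score definitions; the test suite
  verifies exact agreement with an independently written Gotoh dynamic
  program.
* The candidate prefilter counts shared amino-acid 4-mers
  (`kmer_min_shared` = 2). It is a superset filter: pairs below ~50%
  identity may be lost, which is far more divergent than anything the
  within-clade model expects to matter.
* All tie-breaks are deterministic and documented at the site of use:
  seed ordering by (score desc, gene ids), greedy matching by (norm
  desc, gene ids), merge order by (score desc, island ids), equal-length
  raw-score ceiling by the smaller self-score. Identical inputs and
  configuration give byte-identical outputs for any worker count; the
  only parallelism is over chunks of the pure raw-score computation.
* Degenerate inputs fail loudly rather than silently: a strain with no
  translated CDS, a non-binary or mismatching tree, fewer than two
  conservative core sets, zero raw-score spread between a strain pair
  (all fatal with named culprits); zero denominators in the evaluation
  metrics yield `NA` with a warning, never 0.
* The simulator requires an explicit seed (`sim_seed`) and is
  bit-reproducible given one.

## Known limitations

* Islands inserted repeatedly at one hotspot are merged into single
  events; synteny cannot separate them.
* Accuracy declines on deep internal branches, where subsequent
  deletions can pull a family's observed MRCA below the true insertion
  branch (and its branch assignment with it). The same mechanism splits
  islands: when different families of one insertion end up with
  different observed MRCAs they can never rejoin, so one event is
  reported as several islands on several branches. In our simulations
  this cross-branch splitting accounts for essentially all multiply-hit
  island footprints; same-MRCA fragments are reliably merged.
* Very large clades (dozens of strains) are outside the tested regime.
* Plasmids and assemblies worse than scaffold level violate the
  gene-order assumptions and are unsupported.
* The GenBank reader covers the feature dialect the pipeline needs
  (CDS with `/translation`, simple/complement/join locations); it is
  not a general-purpose GenBank parser.
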