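---
title: "Discriminating reticulate allopolyploidy from nested genome duplication"
author: "allorigin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating reticulate allopolyploidy from nested genome duplication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

A polyploid genome can reach high ploidy by two very different routes.
Under a *nested whole-genome duplication* (WGD) history, an octoploid's
four subgenomes are two sister-pairs of duplicates, each pair nested
inside one lineage of an earlier duplication. Under *reticulate
allopolyploidization*, the four subgenomes descend from four distinct
diploid progenitors that were brought together by successive
hybridizations (two allotetraploids merging into an allooctoploid).
The two histories make sharply different predictions that can be read
off a genome and its relatives:

1. **Anchor gene trees.** Take syntenic gene sets at an exact
   1:2:4 copy ratio across a diploid outgroup, a related tetraploid and
   the octoploid. Rooted on the outgroup, the WGD history predicts the
   shape `(O,((T1,(Pa,Pb)),(T2,(Pc,Pd))))` — octoploid copies form
   cherries under each tetraploid copy — while the reticulate history
   predicts `(O,((((T1,Pa),Pb),(T2,Pc)),Pd))` — each tetraploid
   subgenome is sister to the octoploid subgenome that shares its
   progenitor. Counting canonical rooted topologies over thousands of
   anchor trees (a topology census) discriminates the models.
2. **Subgenome-specific k-mers.** Progenitors accumulate private
   repeats between their divergence and the hybridization that fused
   them (the divergence–hybridization period). Differential repetitive
   k-mers therefore phase chromosomes into subgenomes, and windows
   enriched for another subgenome's k-mers reveal homoeologous
   exchanges.
3. **LTR insertion ages.** A retrotransposon's two terminal repeats
   are identical at insertion; their Jukes–Cantor divergence `K` dates
   the insertion as `T = K / (2 mu)`. The symmetric 95% percentile
   interval of subgenome-specific insertion ages estimates each
   progenitor's divergence–hybridization window; progenitors that
   hybridized together share a window.
4. **Ks-ratio dating.** Under rate constancy, the median synonymous
   divergence of a lineage pair scales linearly with time, so
   `T = Ks / Ks(calibration) * T(calibration)` dates each split from a
   single calibrated one (7.7 MY by default).

`allorigin` implements this entire inference chain *and* a synthetic
genome generator with known truth, so every stage can be validated by
parameter recovery rather than by eye.

## The generator

`scenario_spec()` fixes a complete study design; `simulate_scenario()`
realizes it deterministically from its seed. The default scenario is a
reticulate history: four progenitors (A–D) plus an outgroup radiate at
4.7–7.3 MY (root at the 7.7 MY calibration split); B and D fuse at
0.91 MY; A and C fuse at 0.7 MY; the tetraploid species separates from
the AC stock at 0.66 MY; AC and BD fuse into the octoploid at 0.44 MY;
three homoeologous exchanges (each 15% of a chromosome, the proportion
a multi-megabase exchange occupies on a chromosome-scale assembly)
occur after 0.44 MY. The `autopolyploid` model instead nests two duplications
(7.2 and 4.0 MY) inside the tetraploid's sister lineage with
speciation at 5.0 MY.

```{r}
library(allorigin)
sim <- simulate_scenario(scenario_spec(seed = 1))
sim
```

Sequences evolve under Jukes–Cantor at `subst_rate` = 0.005
substitutions/site/MY, applied as the exact per-site transition
probability `3/4 (1 - exp(-4 d / 3))` so that multiple hits are modeled
and the closed-form expectation is testable. Gene families (default
200 at the 1:2:4 ratio plus 30 single-copy, 900 bp, collinear order
shared across subgenomes) are planted in non-overlapping slots; repeat
motifs (250 bp, 60 copies/chromosome) and LTR elements (200 bp terminal
repeats, 400 bp internal, 20/chromosome) are private per subgenome and
inserted at ages drawn uniformly from that subgenome's
divergence–hybridization window. Exchanges copy the donor's segment —
backbone, repeats, LTR elements and gene copies — as of the exchange
time, after which both copies diverge independently; the truth tables
record every feature with its origin.

Desk-test scale: chromosomes are 3 x 500 kb per subgenome and analysis
windows 12.5 kb with a 5-window minimum exchange length, preserving
the 1 Mb-window / 5 Mb-minimum ratio used at genome scale while
keeping exchanges a minority of their host chromosome, as they are on
real assemblies. All of these are parameters, not constants.

What the generator deliberately does *not* emulate: indels and
alignment uncertainty, strand, gene conversion, incomplete lineage
sorting (gene trees depart from the species tree only through
substitution noise and exchanges), TE superfamily structure, shared
pre-speciation TE insertions between the tetraploid and octoploid
copies of the same subgenome, and fractionation beyond explicit
`copy_loss` events. Passing tests therefore demonstrate that the
inference chain is correct and well-calibrated under its own model
assumptions — not that it is robust to every artifact of real
assemblies.

## Stage-by-stage notes

**Orthogroups** (`build_orthogroups`): candidate pairs must share 30
exact CDS 10-mers (cheap prefilter), then are scored by local protein
alignment (BLOSUM62, gap open 10 / extend 0.5); pairs with >= 40%
identity over >= 50% of the shorter protein in both directions become
edges and connected components are orthogroups. Thresholded reciprocal
hits — not strict best hits — are used because a tetraploid gene has
four octoploid homologs but only one *best* hit, and best-hit edges
would splinter the families the anchor ratio needs.

**Collinear blocks** (`chain_collinear_blocks`): dynamic-programming
chaining in gene-rank space, `score(i) = match + max(0, score(j) -
gap * rank gaps)` over predecessors increasing on both axes (both
orientations searched; gaps capped at 25 ranks; blocks need >= 5
pairs; tandem arrays are collapsed first). On instances small enough
to enumerate every monotone chain, the DP is verified to find the
optimum. Anchor groups are connected components of block pair edges
filtered to the exact per-genome copy ratio, so a single missing or
surplus copy excludes a family.

**Trees** (`align_progressive`, `jc_distance_matrix`, `nj_tree`,
`bootstrap_support`, `quartet_species_tree`): alignment delegates to
MAFFT; the simulator emits gap-free equal-length homologs, for which
the alignment is the identity, so the census pipeline aligns only when
lengths differ. Distance trees use the JC formula with a saturation
cap (`p >= 0.75` maps to distance 5.0 with a warning) and
neighbor-joining, which recovers additive topologies exactly — a
deliberate, documented substitution for likelihood inference that
keeps the census deterministic and fast; the module boundary accepts
any tree producer. Bootstrap supports resample columns (or whole
codons) and count recovered bipartitions. The species-tree summary
scores every unrooted topology (n <= 8) by shared induced quartets
against the gene trees and returns the exhaustive optimum.

**Census** (`census`): trees are rooted on the outgroup and reduced to
canonical strings (children sorted by their smallest contained role),
so sibling order cannot split a class. Classes are tagged by
membership in the enumerated model-predicted sets (6 WGD shapes, 48
reticulate shapes over concrete subgenome labels); multifurcating
trees can never match and fall to `other`. The verdict is the tag of
the plurality class.

**Phasing** (`phase_subgenomes`): canonical k-mers (default k = 15,
odd so no k-mer equals its own reverse complement; ambiguous bases
break k-mers) are counted in C++ and kept only at genome-wide count
>= 10 (repetitive k-mers). After an unevenness prefilter
(max/median fold >= 2 across chromosomes), chromosomes are clustered
by k-means on per-bp-normalized, standardized vectors (best of 10
restarts, canonical relabeling: largest cluster first). Specific
k-mer sets per cluster require a >= 2-fold margin over the runner-up
cluster. Window enrichment uses the exact hypergeometric upper tail
(drawing a window's specific-k-mer occurrences from the genome-wide
pool) with Benjamini–Hochberg FDR at alpha = 0.05 across all
window-by-subgenome tests; "significant enrichment" needs a concrete
test to be reproducible, so an exact, enumerable one was chosen and
made configurable. Exchange segments are maximal runs of
discordantly-enriched windows (one interior unlabeled window may be
bridged; labeled windows always break runs) of at least 5 windows;
after a first pass, called segments are masked and the specific sets
recomputed once, so exchanged repeats cannot contaminate the
subgenome-specific sets — enrichment is always evaluated on the
unmasked sequence. Borderline single-window discordances remain
visible in the window table for manual review.

**Dating** (`ltr_insertion_ages`, `divergence_hybridization_window`,
`ng86_ka_ks`, `ks_ratio_dating`): LTR detection is out of scope —
elements enter via annotation. The LTR rate `mu` (subs/site/year) has
no default because no defensible universal value exists; the pipeline
on synthetic data uses the generator's own rate. Ka/Ks uses NG86
(per-codon site fractions averaged over both sequences; differences
averaged over mutational paths, stop-codon paths excluded; JC
correction), rather than a codon-frequency ML model: the downstream
inference consumes only *ratios of median Ks*, which NG86 preserves
under the generator's uniform-rate model. Stop codons arising from
unconstrained simulated evolution are masked pairwise before Ks
computation. Medians, not means, summarize each lineage pair.

## Numerical and degenerate-input choices

* JC saturation (`p >= 0.75`): distances capped at 5.0, LTR ages and
  Ks reported `NA` with warnings, keeping matrices finite and the
  affected records identifiable.
* k-means ties: clusters renamed by size then by alphabetically first
  member, so the partition is reproducible under its seed.
* Exchange donor: modal enriched label of the run.
* Interval-to-subgenome assignment: midpoint rule, documented for
  intervals straddling a boundary.
* Empty inputs: empty gene tables give empty orthogroup partitions;
  empty block sets give empty anchor sets; zero bootstrap replicates
  give a plain tree; an empty Ks set reports "no peak".

## Problem sizes

The shipped tests and the acceptance script run the default scenario
(10.5 Mb across the three genomes, 230 families) over 10-seed sweeps
for the census, phasing, exchange and LTR-window checks, and smaller
24-family scenarios for unit tests. These sizes were chosen so that a
full validation sweep completes on one CPU core in minutes while
keeping every statistical check comfortably away from its decision
boundary.

## Known limitations

* The census assumes the anchor's role map (which copy belongs to
  which subgenome) is known; on real data it comes from the phasing
  stage, so phasing errors propagate to the census.
* NJ on JC distances can misplace copies when internal branches are
  a handful of substitutions long; the census absorbs this as `other`
  classes rather than misclassifying models, but very recent
  radiations will dilute the plurality fraction.
* Ks-ratio dating of very recent splits (< ~1 MY at default gene
  lengths) is quantization-limited: a 900 bp gene holds only ~200
  synonymous sites, so the median Ks step size is comparable to the
  signal. The deep radiation splits are the reliable targets.
* Read placement uses unique exact k-mer matches; reads wholly inside
  young repeats remain unplaced and are reported as such.
* Chromosome assignment works from whole-chromosome k-mer profiles, so
  an exchange approaching half of its host chromosome makes the host's
  profile genuinely intermediate and k-means can place it with the
  donor's cluster. Exchanges of the size seen on real assemblies (a
  few percent to ~15% of a chromosome) are well inside the safe
  regime; recipients of larger transfers should be inspected via the
  window table.
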