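# allorigin

Subgenome-aware inference of how a polyploid genome came to be: did an
octoploid arise by **nested whole-genome duplication** (WGD) within one
lineage, or by **reticulate allopolyploidization** — several diverged
diploid progenitors fused step-wise through hybrid tetraploids? The two
histories leave different fingerprints, and `allorigin` reads all of
them:

* **Anchor-gene topology census.** Syntenic gene sets at an exact
  1:2:4 copy ratio (diploid outgroup : tetraploid : octoploid) are
  extracted from orthogroups and collinear blocks, turned into rooted
  gene trees, and counted by canonical topology. Nested WGD predicts
  `(O,((T1,(Pa,Pb)),(T2,(Pc,Pd))))`; reticulate allopolyploidy predicts
  `(O,((((T1,Pa),Pb),(T2,Pc)),Pd))`. The plurality class is the
  verdict.
* **k-mer subgenome phasing.** Differential repetitive k-mers —
  repeats amplified privately during each progenitor's
  divergence-to-hybridization window — cluster chromosomes into
  subgenomes (k-means), and per-window hypergeometric enrichment with
  BH-FDR flags homoeologous exchanges (runs of discordant windows at a
  minimum length, echoing a 5 Mb cutoff at 1 Mb windows).
* **LTR retrotransposon dating.** The two terminal repeats of an LTR
  element are identical at insertion, so their Jukes–Cantor divergence
  `K` dates it: `T = K / (2 mu)`. Symmetric 95% percentile intervals of
  subgenome-specific insertion ages bound each progenitor's
  divergence–hybridization window.
* **Ks-ratio dating.** With median synonymous divergence (NG86) and a
  calibrated split, `T = Ks / Ks(calibration) x 7.7 MY` dates every
  lineage pair under rate constancy.
* **A truth-bearing simulator.** `simulate_scenario()` generates the
  whole species complex — outgroup, tetraploid, octoploid with four
  subgenomes, planted gene families, repeat/LTR bursts, homoeologous
  exchanges — with exact truth tables, so every stage above is
  validated by parameter recovery.

Intended users: comparative genomicists studying polyploid origins who
want the inference chain as composable, testable R functions rather
than a pipeline of external binaries.

## A worked example

```r
library(allorigin)

sim <- simulate_scenario(scenario_spec(seed = 1))
cen <- census(anchor_gene_trees(sim), default_roles())
cen
#> Topology census over 200 gene trees
#>    163 ( 81.5%) reticulate-model (O,((((P1,T1),P2),(P3,T2)),P4))
#>     11 (  5.5%) other            (O,((((P1,P3),T2),(P2,T1)),P4))
#>     11 (  5.5%) other            (O,((((P1,T1),(P2,P3)),T2),P4))
#>      9 (  4.5%) other            (O,((((P1,P2),T1),(P3,T2)),P4))
#>      4 (  2.0%) reticulate-model (O,(((P1,T1),(P2,(P3,T2))),P4))
#>      2 (  1.0%) other            (O,((((P1,T1),(P3,T2)),P2),P4))
#> Plurality class model: reticulate-model
```

81% of the anchor gene trees recover exactly the planted reticulate
topology — tetraploid/octoploid ortholog cherries `(T,P)` rather than
octoploid duplicate cherries `(P,P)` — so the census favors the
reticulate model, as it should for this scenario.

```r
part <- phase_subgenomes(sim$genomes$oct, seed = 1)
part$exchanges
#>        chrom  start    end host donor n_windows length
#> 1 oct_C_chr1 150000 212500   S3    S2         5  62500
#> 2 oct_B_chr2  50000 125000   S2    S1         6  75000
```

The phasing recovers all twelve chromosome assignments and calls two
of the three planted exchanges with correct donors (cluster S2 is
subgenome B, etc.) and boundaries within one window; the third planted
segment is split by two feature-empty 12.5 kb windows and falls under
the minimum run length on this seed — across a 10-seed sweep the
recall is 0.93 at perfect precision. Dating closes the loop:

```r
cal <- median(ks_between_copies(sim, "tet_A", "out"), na.rm = TRUE)
ks_ab <- median(ks_between_copies(sim, "tet_A", "oct_B"), na.rm = TRUE)
ks_ratio_dating(ks_ab, cal)   # A-B split, planted at 4.7 MY
#> [1] 4.093784
```

The full chain — simulate, synteny, trees, census, phase, date, with
TSV/Newick outputs, a Markdown report and a reproducibility manifest —
runs as one call:

```r
res <- run_pipeline(default_run_config(outdir = "run1", seed = 1))
```

or from a shell via `inst/scripts/run-pipeline.R`.

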