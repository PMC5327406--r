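# locusdrift

Diagnosing gene loss, locus disruption, and accelerated evolution of
"salvaged" genes across a species phylogeny.

## The problem

Even deeply conserved genes can vanish from individual genomes. The motivating
case is the axon-guidance receptor gene *DCC* in birds: its multi-gene locus
was disrupted independently in several avian lineages (Galliformes,
Passeriformes), leaving each gene of the affected segment either **lost**,
**salvaged** (surviving on an isolated scaffold outside its ancestral
syntenic context, and evolving measurably faster afterwards), or **retained**
in the conserved gene order. Distinguishing the three outcomes from genomic
evidence — and not being fooled by the near-identical paralog *Neogenin* —
takes several coordinated analyses. `locusdrift` implements that inference
chain as a tidyverse-style R package for comparative genomicists:

* a **tiered detection cascade** (annotation lookup → translated affine-gap
  Smith–Waterman search of assemblies at a relaxed bit-score floor →
  read-level search with greedy contig assembly, paralog filtering and
  orthology verification: global identity > 75%, or for fast evolvers with
  JC69-corrected divergence $d = -\frac34\log(1-\frac43\hat p) > 0.4$, a
  best-hit majority vote over a labelled protein panel with ≥ 20 aligned
  residues);
* **synteny analysis on signed gene orders**: synteny-block decomposition,
  inversion and breakpoint detection, per-gene fate classification and the
  maximal *disrupted segment*;
* **substitution mapping**: gap trimming, pairwise percent
  identity/similarity, Fitch-parsimony ancestral reconstruction with
  deterministic tie-breaks, and BLOSUM62-based labelling of substitutions as
  conservative or non-conservative;
* **rate comparison**: per-gene maximum-likelihood branch lengths on a fixed
  topology (Felsenstein pruning, JC69/K80), root-to-tip distances from the
  ingroup stem, and the normality-gated two-sample test
  (D'Agostino–Pearson omnibus gate, then equal-variance t or Mann–Whitney U)
  of salvaged versus intact-locus genes;
* a **locus-evolution simulator** with a ground-truth event log (branch
  disruptions, inverted intervals, lost/salvaged sets, rate multipliers),
  used to validate every stage end-to-end.

Fixtures transcribed from published comparative maps of the avian *DCC*
locus (31-gene reference order, Galliformes gene orders and detection
matrix) ship with the package and provide the worked example.

## Worked example

```r
library(locusdrift)

# chicken gene order vs the 31-gene reference locus
report <- fixture_disruption_report("chicken")
report
#> <disruption_report> species chicken
#>   7 blocks, 1 inversion(s), 1 breakpoint(s)
#>   fates: lost=12, retained_in_locus=14, salvaged=5 
#>   largest disrupted segment: [8, 24] (17 genes)

fixture_counts()
#> $disrupted_segment_genes
#> [1] 17
#> $undetected_all_galliformes
#> [1] 10
#> $salvaged_all_galliformes
#> [1] 5
#> $n_reference_genes
#> [1] 31
```

Reading: in chicken the reference locus decomposes into an intact upstream
flank, an inverted downstream flank and five isolated salvage scaffolds; the
17 consecutive reference genes from *CCDC68* to *MYO5B* (positions 8–24) have
no retained representative — the disrupted segment. Across the four
Galliformes, 10 of those genes are undetected everywhere and 5 (*DYNAP*,
*MBD2*, *ME2*, *SMAD4*, *SKA1*) are salvaged in all four.

A synthetic end-to-end run with one forced disruption and a 3-fold
post-salvage rate multiplier:

```r
cfg <- sim_config(locus = default_locus(n_genes = 12, length_nt = 900),
                  flank_genes = 3, disruption_branches = "galliformes",
                  inversion_interval = c(4, 9), rho = 3, seed = 2)
rep <- run_pipeline(run_config(sim = cfg))
rep
#> <run_report>
#>   seed 2, config hash ab20bb55eed409b8a61bdfc400ed2261
#>   detection: 72 records, 68 detected
#>   synteny reports for 6 species
#>   salvaged vs intact rates: mann_whitney test, p = 0.009524
#>   recovery: fate_accuracy = 1.000, precision = 1.000, recall = 1.000, root_to_tip_within_10pct = 0.632, median_rel_error = 0.074
```

The recovery block compares every call against the simulator's truth log:
all 72 presence calls and all gene fates are correct, and the salvaged
genes' root-to-tip distances are significantly inflated in the disrupted
clade (Mann–Whitney on per-gene means, 4 salvaged vs 6 flank genes,
p = 0.0095). Root-to-tip recovery tightens from ~63% of tips within 10%
at these 900-nt genes to ≥ 95% at the 5-kb gene length used in the
validation experiments.

`autoplot()` methods draw the presence/absence matrix, the per-gene rate
table, and the block structure of a disruption report; `tidy()`/`glance()`
turn reports, fits and comparisons into tibbles.

## Package tour

| area | functions |
|---|---|
| simulator | `sim_config()`, `simulate_locus()`, `evolve_sequence()`, `apply_inversion()`, `fragment_reads()`, `write_sim()`, `truth_root_to_tip()` |
| detection | `pipeline_thresholds()`, `call_gene_status()`, `local_align()`, `translate_six_frames()`, `pssm_build()`/`pssm_scan()`, `greedy_assemble()`, `paralog_filter()`, `verify_ortholog()`, `presence_matrix()` |
| synteny | `extract_locus()`, `map_to_reference()`, `find_blocks()`, `detect_inversions()`, `count_breakpoints()`, `classify_fates()` |
| substitution maps | `aligned_set()`, `strip_gap_columns()`, `percent_identity()`, `percent_similarity()`, `reconstruct_ancestor()`, `map_substitutions()` |
| rates | `pruning_loglik()`, `fit_branch_lengths()`, `root_to_tip()`, `rate_table()`, `dagostino_pearson()`, `compare_groups()`, `compare_rate_groups()` |
| orchestration | `run_config()`, `run_pipeline()`, `load_fixture()`, `fixture_disruption_report()`, `fixture_counts()` |

The methods vignette (`vignettes/locus-disruption-methods.Rmd`) documents the
models, thresholds, tie-breaks, simulator assumptions and their limits.
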