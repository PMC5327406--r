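---
title: "Diagnosing gene loss, locus disruption and rate shifts of salvaged genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing gene loss, locus disruption and rate shifts of salvaged genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locusdrift)
```

## The problem

A gene that is "highly conserved" across vertebrates can nevertheless be
missing from individual genomes. The textbook example this package is built
around is the axon-guidance receptor gene *DCC* in birds: the multi-gene
chromosomal neighbourhood that contains *DCC* was broken up independently in
several avian lineages, with three distinct outcomes per gene:

* **lost** — no trace of the gene in annotation, assembly, raw reads or
  transcriptome;
* **salvaged** — the gene survives, but relocated outside its ancestral
  syntenic context (empirically: on scaffolds carrying only one or two
  genes), and tends to accumulate substitutions faster afterwards;
* **retained in locus** — the gene stays embedded in the conserved gene
  order.

Deciding between these outcomes from genomic evidence requires several
independent analyses that this package implements as composable functions:
a tiered detection cascade, a synteny/rearrangement analysis on signed gene
orders, substitution mapping against a reconstructed ancestor, and a
root-to-tip substitution-rate comparison. A locus-evolution simulator with a
ground-truth event log ties everything together: every claim the test-suite
makes about recovery is measured against the simulator's truth.

## The detection cascade

`call_gene_status()` decides presence/absence of one gene in one species in
three tiers, stopping at the first tier whose evidence survives
verification:

1. **annotation** — name lookup in the species' gene-order table; the
   annotated sequence must still pass orthology verification.
2. **assembly** — translated search: the bait protein is aligned
   (affine-gap Smith–Waterman, BLOSUM62, gap cost `11 + L`) against all six
   reading frames of every assembly sequence. A hit qualifies when its
   bit score (Karlin–Altschul normalisation, `lambda = 0.267`, `K = 0.041`)
   reaches `relaxed_min_bitscore` (default 25 bits). The bit-score floor is
   a deterministic stand-in for a very permissive E-value cut-off, which is
   not meaningful on databases this small.
3. **reads** — reads sharing an exact 16-mer with the bait are aligned to
   it (match +1 / mismatch −1, gap `5 + 2L`), assembled with a greedy
   overlap merger (merge while overlap ≥ 20 nt and identity ≥ 0.97), and
   filtered against the paralog bait; surviving contigs are verified.

Both search tiers use exact-word seeding (protein word 6, nucleotide word
16) before dynamic programming — the same seed-and-extend idea BLAST is
built on; without it the translated search is quadratic in database size.

**Verification** (`verify_ortholog()`) mirrors how orthology is confirmed
in comparative screens. A candidate is accepted outright when its global
nucleotide identity to the reference ortholog exceeds 75% (identity is
computed over aligned columns with terminal gaps excluded; when candidate
and reference have equal length the ungapped comparison *is* that
alignment). Otherwise the JC69-corrected divergence
$d = -\tfrac{3}{4}\log(1 - \tfrac{4}{3}\hat p)$ is estimated; candidates
beyond 0.4 substitutions/site (the "fast evolver" regime) can still be
accepted, but only by best-hit consistency: all six frame translations are
aligned against a labelled protein panel, and the top-5 hits must vote for
the target family, with at least 20 aligned residues. Panel hits qualify at
`panel_min_bitscore` (default 40 bits), deliberately stricter than the
tier-2 screening floor: the vote re-creates "consistently annotated top
database hits", and annotated hits are solid homologies, never
borderline-random scores — over a six-frame-by-panel search space, random
alignments regularly reach the permissive 25-bit screening floor but stay
far below 40 bits.
The divergence here is the pairwise corrected distance to the nearest
reference ortholog, not a re-estimated tree branch — a deliberate
simplification for the single-candidate setting. Ambiguities the analyst
would resolve by eye are resolved by fixed tie-breaks (score descending,
then lexicographic id) so the cascade is fully deterministic.

**The paralog trap.** The headline gene has an ancient paralog of high
similarity (*DCC*/*Neogenin*-like). Two safeguards keep the paralog from
masquerading as the missing target: read-derived contigs whose best local
alignment to the paralog bait is longer than 40 nt *and* more than 95%
identical are discarded before verification, and the verification panel
contains the paralog family, so paralog-derived candidates lose the
best-hit vote. The 95%/40-nt rule uses local-alignment (blastn-style)
semantics; whether the original screens used local or global identity is
not documented, and local is the safer reading.

## Synteny, inversions and gene fates

The locus is treated as a signed permutation: `map_to_reference()` places
each reference gene in a target genome, `find_blocks()` decomposes the
placements into maximal runs of preserved adjacency with consistent
orientation, and `detect_inversions()` reports the inverted blocks.
Adjacency deliberately ignores intervening non-reference genes: the
comparison is between orthologs only. Block decomposition of a signed
permutation with one inversion yields the classic
*prefix–inverted–suffix* pattern, and a property test checks that a single
injected inversion is always recovered exactly.

`classify_fates()` then labels every reference gene:

* `lost` when no tier detected it;
* `salvaged` when it was detected but sits on a scaffold carrying at most
  `max_salvage_block` (default 2) reference genes — the operational version
  of "found on scaffolds with only one or two genes" — or was detected only
  at a sequence tier with no placement at all;
* `retained_in_locus` otherwise.

The **disrupted segment** is every maximal run of consecutive reference
genes none of which is retained; ties are reported longest first. On the
bundled fixtures (hand transcriptions of published comparative maps of the
avian *DCC* locus; see `inst/extdata/transcription_note.md`) the chicken
order yields a 17-gene disrupted segment from *CCDC68* to *MYO5B*, 10 of
the 17 segment genes are undetected in all four Galliformes, and 5 genes
(*DYNAP*, *MBD2*, *ME2*, *SMAD4*, *SKA1*) are salvaged in all four —
`fixture_counts()` recomputes all three numbers.

## Substitution mapping

`reconstruct_ancestor()` infers an ancestral sequence by Fitch parsimony
with a deterministic tie-break (majority state among the column's tip
states, then highest summed BLOSUM62 similarity, then alphabetical). This
is a deliberate deviation from likelihood-based ancestral reconstruction:
parsimony is self-contained and exhaustively testable (the suite checks the
parsimony cost against a brute-force minimum over all internal assignments
for trees up to six tips), and on the shallow, high-identity alignments
this analysis targets the two approaches rarely disagree; the output object
records the method. `map_substitutions()` labels each ancestor/descendant
column `identical`, `conservative` (BLOSUM62 score strictly positive — the
boundary is not standardised, and zero counts as non-conservative here),
`nonconservative`, or `indel`. `percent_identity()` and
`percent_similarity()` use aligned columns where both rows carry a residue;
similarity additionally counts positive-scoring mismatches, so it is never
below identity. Default gap trimming removes every column containing a gap
(`any_gap`), matching the practice of trimming indel regions before
scoring.

## Rates: root-to-tip distances and the group comparison

`fit_branch_lengths()` estimates maximum-likelihood branch lengths on a
*fixed* topology (topology inference is out of scope — species
relationships are an input) by Felsenstein pruning under JC69 (default;
K80 with configurable kappa available) with uniform base frequencies,
pattern compression and per-node rescaling. Each branch is optimised by
Brent search within `[1e-8, 10]`; sweeps repeat until the log-likelihood
gain drops below `1e-6` (at most 100 sweeps, flagged if not converged).
Partial likelihoods above and below the focal branch are recomputed before
every one-dimensional optimisation, so the log-likelihood is monotone
non-decreasing — asserted per sweep in the tests, and the optimum matches
an independent implementation (phangorn) to numerical precision.

The rate statistic is the **root-to-tip distance**. Under a reversible
model the two branches meeting at the root are confounded (only their sum
is identifiable — the "pulley principle", also verified in the tests), so
the pipeline measures from the **ingroup stem node** (where the outgroup
attaches): the identifiable proxy for the outgroup/ingroup common
ancestor. `root_to_tip()` measures from the root by default for plain
trees and from the stem with `from = "ingroup"`.

`compare_groups()` reproduces the normality-gated test choice used in the
original statistical analysis: both groups are tested with the
D'Agostino–Pearson omnibus test (implemented from the published skewness
and kurtosis z-transforms; it requires n ≥ 8, and matches an independent
reference implementation to 1e-8 on frozen samples); if both pass at
alpha = 0.05 an unpaired two-tailed equal-variance t-test is used
("assuming equal standard error" is read as the pooled-variance t-test),
otherwise a two-sided Mann–Whitney U test (exact when both n ≤ 20 without
ties, normal approximation with tie correction otherwise). Groups with
fewer than 3 values are rejected outright, mirroring the original
exclusion rule.

**Grouping.** `compare_rate_groups()` collapses the rate table to one
value per gene (the mean root-to-tip over the species set being compared)
before testing. Genes evolve independently in the generative model, so
per-gene values are independent sample units; per-species values of one
gene are not (they share tree paths). The pipeline compares salvaged
against retained genes *within the disrupted clade's tips*, which makes
the two groups exchangeable under the null hypothesis of no rate shift.

## The simulator and what passing tests mean

`simulate_locus()` generates the study conditions end to end: uniform
random root sequences per gene (codon structure is not enforced — the rate
analysis is nucleotide-level), indel-free evolution under JC69/K80 down a
fixed bird-like tree, disruption events on designated branches (inversion
of a locus interval, then per-gene loss with probability `p_loss` or
relocation to an isolated scaffold with probability `p_salvage`),
post-salvage rate multiplication by `rho`, an always-present diverged
paralog of the target gene, and uniform-error shotgun reads. A single RNG
stream in a documented order (pre-order over branches, event decision
first, then genes in locus order) makes identical configurations
byte-identical. Defaults, chosen once as a realistic regime for this kind
of comparative screen:

* ingroup of six species, clock-like with 0.15 expected substitutions/site
  from stem to tip at base rate 1, plus a distant outgroup (0.30 on its own
  stem). The clock-like ingroup makes root-to-tip depth exchangeable
  across tips, which is what lets the null group comparison be calibrated.
* per-gene base rate 0.5 — conserved coding genes evolve well below the
  neutral rate; this keeps distant ingroup orthologs near 85–90%
  nucleotide identity, the regime the 75% verification rule assumes.
* `rho = 3`, `p_loss = 0.5`, paralog divergence 0.4 substitutions/site,
  reads of 100 nt at 5-fold coverage with 0.5% uniform error.

The recovery experiments in the test-suite run twenty replicates of a
20-gene locus with 5-kb genes and one forced disruption on the galliform
stem, checking perfect fate recovery, detection precision/recall,
root-to-tip recovery within 10% for ≥ 90% of tips, and ≥ 90% power of the
salvaged-vs-intact comparison; 200 further replicates at `rho = 1`
(12 genes of 300 nt — type-I error is size-free) check that the comparison
rejects at the nominal 5% level. These sizes are the package's chosen
experimental design, balancing statistical resolution against runtime.

What the simulator deliberately does **not** emulate — and hence what
passing tests do not establish about real data: indels and alignment error
(real screens must align first; the simulator is indel-free so alignment
is trivial), codon structure and selection (no dN/dS), rate heterogeneity
across sites, GC/composition bias, assembly fragmentation and chimerism,
paired-end reads, and annotation errors in the input gene-order tables.
The fixtures bridge part of that gap: they are transcriptions of real
published locus maps, and the headline counts are recomputed from them,
not from simulations.

## Numerical and degenerate-input choices

* Smith–Waterman tie-breaks: diagonal > up > left in the traceback; best
  cell by score, then smallest query, then smallest target index. Scores
  of empty/all-negative problems floor at 0 with an empty alignment.
* Greedy assembly merges by highest overlap identity, then longest
  overlap, then lexicographic read ids; mismatched overlap columns take
  the left read's base. Zero reads give zero contigs.
* `evolve_sequence(t = 0)` is the identity; saturation tends to 3/4
  differing sites (tested against the binomial envelope).
* Branch lengths of identical sequences collapse to the lower bound
  `1e-8`; `optimize()` is warm-started from the previous sweep's value
  with a fallback to the full interval when the optimum hugs the window
  edge.
* Fitch treats gaps and ambiguity codes as missing data (the tip
  contributes the full alphabet).
* All TSV coordinates are 1-based inclusive; alignment intervals in
  `local_alignment` objects are 0-based half-open.
* Fixtures are checksum-verified on load; a tampered file is an error, not
  a warning.

## Known limitations

The greedy assembler is deliberately minimal (no error correction, no
reverse-complement handling) — it recovers candidate fragments, not
isoforms. The PSSM scanner has no insert/delete states and is not a
profile HMM. E-value statistics are replaced by a raw bit floor. The
best-hit consistency vote uses a bundled panel rather than a comprehensive
protein database, so its power depends on the panel's coverage. Branch
lengths are estimated per gene with no shrinkage across genes; very short
alignments give noisy root-to-tip values, which is why the group
comparison collapses to per-gene means and excludes groups with fewer
than three genes.

## A worked example

```{r example, eval = FALSE}
library(locusdrift)

# fixture analysis: chicken vs the 31-gene reference locus
report <- fixture_disruption_report("chicken")
report
glance(report)

# the three headline counts
fixture_counts()

# a synthetic end-to-end run with one forced disruption
cfg <- sim_config(
  locus = default_locus(n_genes = 12, length_nt = 900),
  flank_genes = 3,
  disruption_branches = "galliformes",
  inversion_interval = c(4, 9),
  rho = 3, seed = 2
)
rep <- run_pipeline(run_config(sim = cfg))
rep
autoplot(rep$presence_matrix)
```
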