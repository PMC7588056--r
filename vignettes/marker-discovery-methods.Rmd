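---
title: "Methods: plastid marker-region discovery by neutrality scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plastid marker-region discovery by neutrality scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastidscan)
```

## The problem

Whole-plastome phylogenies of closely related plant species (for example
congeneric *Iris*) resolve clades that single-locus barcodes such as
*matK* cannot. Sequencing and aligning complete plastomes for every new
accession is expensive, so one wants a small set of short plastid regions
whose variation alone recapitulates the whole-plastome species tree. This
package implements a selection procedure for such regions, together with
the population-genetic and molecular-evolution statistics it relies on,
and a synthetic plastome simulator that provides ground truth so the whole
pipeline can be validated without any external data.

The procedure is:

1. scan a whole-plastome multiple alignment with sliding windows,
   computing nucleotide diversity (pi) and Tajima's D;
2. decompose the alignment into well-aligned blocks (gap-density runs) and
   keep the blocks with Tajima's D above a neutrality threshold
   (default D > -0.5);
3. concatenate the selected blocks and extract the gap-free segregating
   sites into a taxa-by-sites genotype matrix;
4. build distance trees (neighbor joining on Hamming or Tamura–Nei
   distances; UPGMA for the clustering view) with a site-resampling
   bootstrap, and compare them to a reference species tree by
   Robinson–Foulds distance;
5. independently, classify species pairs by the modal value of their
   per-gene synonymous substitution rate (Ks) distribution over a shared
   set of single-copy plastid genes.

## Statistics

**Tajima's D.** For `n` sequences with `S` segregating sites and mean
pairwise difference count `pi`,

\[ D = \frac{\pi - S/a_1}{\sqrt{e_1 S + e_2 S (S-1)}} \]

with the standard constants \(a_1 = \sum_{i<n} 1/i\), etc. All
components are exposed (`tajimas_d()` returns `a1..e2`, `var_d`, both the
count-scale `pi` and `pi` per site) so every value is auditable. Two
conventions matter and are fixed as follows:

* *Gaps.* The default policy removes any column containing `-`, `N` or
  `?` before counting (sites are counted "excluding gaps"); `N` is
  treated exactly like a gap. A `pairwise` policy is available.
* *S = 0.* D is reported as undefined, never as 0. A window with no
  variation carries no evidence of neutrality, and coding it as 0 would
  let empty windows pass the neutrality filter.

When the outgroup is included in the alignment — as it is by default,
matching how such scans are run in practice — its long pendant branch
contributes many rare alleles, shifting D negative genome-wide. The
selected regions are precisely those that stay above the threshold despite
this shift.

**NG86 Ks.** Synonymous and nonsynonymous sites are counted per codon as
the expected fraction of the nine single-nucleotide changes that preserve
the amino acid (standard code; changes into stop codons count as
nonsynonymous). For codon pairs differing at several positions, the
difference counts are averaged over all minimal mutational pathways,
excluding pathways that pass through a stop codon; if every pathway is
blocked, all are used rather than discarding the pair. Rates are
Jukes–Cantor corrected, \(K_s = -\tfrac34 \ln(1 - \tfrac43 p_s)\), and a
pair is flagged invalid when \(p_s \ge 3/4\). A 64x64 pathway table is
precomputed once, which makes all-vs-all matrices over dozens of genes
cheap.

**Modal Ks.** The divergence proxy for a species pair is the peak of its
per-gene Ks distribution, not its mean, because orthology errors and
rate-shifted genes contaminate the tail. Two peak estimators are
provided. The histogram estimator (bin width 0.005 Ks units anchored at
0, leftmost bin on ties) is transparent and appropriate for large gene
sets. With typical plastid gene sets (~57 genes per pair), however, a
fixed 0.005 bin holds only a handful of values and the argmax is
dominated by sampling noise; the all-vs-all matrix therefore defaults to
a Gaussian KDE mode with Terrell's oversmoothing bandwidth
\(1.144\,\hat\sigma\,n^{-1/5}\), a deliberately conservative rule that
suits locating the single peak of a unimodal distribution from a few
dozen points. Both estimators are available everywhere; the choice is a
parameter and is echoed into reports.

**Tamura–Nei distance.** `tn93_distance()` implements the closed form
from the two transition proportions (within purines and within
pyrimidines) and the transversion proportion, with base frequencies
pooled over the pairwise-complete sites of the two sequences. Degenerate
compositions (a missing purine or pyrimidine class) zero the
corresponding term; non-positive logarithm arguments flag the pair as
saturated and report a declared cap (default 5 substitutions/site)
instead of an infinite or undefined distance.

**Trees.** Neighbor joining and UPGMA are used as the tree builders. The
reference analyses this package mirrors used a maximum-likelihood search
for the final figure; on segregating-site genotype matrices of this size
the ML and distance topologies coincide, the quantity being scored is
topology recapitulation (RF = 0), and distance methods are deterministic
and dependency-light, so ML search is deliberately out of scope. Taxa are
sorted lexicographically before agglomeration, so ties break
reproducibly; negative NJ branch lengths are clamped to zero with the
clamped deficit recorded. Bootstrap supports resample genotype columns
with replacement; each replicate derives its own seed from the master
seed, so extending `n_reps` never reshuffles earlier replicates.

## The synthetic plastome simulator

The simulator is first-class, tested code: it defines the conditions
under which the pipeline's claims are validated.

**Species tree.** `simulate_species_tree()` builds an ultrametric binary
ingroup of `n_clades` monophyletic clades (clade crowns below 45% of the
ingroup depth, the backbone above it) and attaches one outgroup whose
pendant branch is 1.5x the ingroup depth. Defaults mirror a
17-taxon, 4-clade study design at ingroup depth 0.05 substitutions/site.

**Alignment.** `evolve_alignment()` drops mutations onto the tree region
by region; each mutation rewrites one column in the clade below the
chosen branch. The mechanism is mutation placement, not a full
substitution-model simulation, because the property being emulated is the
site-frequency spectrum, which is determined by where on the tree
variants arise:

* *Constrained regions* place a fraction `terminal_bias` (default 0.95)
  of mutations uniformly on terminal branches. Terminal placement makes
  singletons, and a singleton excess drives D strongly negative — these
  regions emulate the bulk of the plastome, where the scan should reject.
* *Neutral regions* place a fraction `internal_bias` (default 0.75) of
  mutations on internal branches in proportion to branch length, the rest
  on all branches in proportion to branch length. Purely
  length-proportional placement on a species tree with a long outgroup
  pendant edge would itself produce a singleton excess (mean D near
  -1.8), which would contradict the construct these regions emulate:
  marker regions that retain clade-shared, intermediate-frequency
  variants. The default 0.75 was calibrated analytically, before any
  end-to-end evaluation, by equating the expected per-mutation pairwise
  difference contribution \(E[c(n-c)]/\binom n2\) (where `c` is the
  number of tips below the drawn branch) with the Watterson expectation
  \(1/a_1\) — the defining balance of a Tajima-neutral spectrum — over
  simulated trees of the default shape; 0.70 balances exactly and 0.75
  leaves a small positive margin.

Mutation counts per region are Poisson with mean `length x rate`, where
`rate` is the expected number of mutations per column over the whole tree
(defaults 0.08 for constrained and 0.05 for neutral regions, i.e. a
moderately conserved ~150 kb plastome scaled to the ~50 kb test
alignments). The default region layout intersperses five neutral islands
(20% of columns) in a constrained background, mirroring a genome in
which a handful of short regions pass the filter. Optional all-gap
separator columns at region joins (`boundary_gap`) let the gap-density
block decomposition recover the region boundaries, standing in for the
alignment-block structure that a whole-genome aligner produces; random
per-column gap injection (`gap_rate`) exercises the gap-handling paths.

**Codon genes.** `evolve_codon_genes()` evolves stop-free codon sequences
along the same tree with separate synonymous and nonsynonymous rates: a
specific synonymous neighbor substitution occurs at rate `syn_rate/3` per
unit branch length, so expected pairwise Ks grows linearly with tree path
length. Defaults are 57 genes of 300 codons (the mean plastid single-copy
protein gene is roughly 300–350 codons), `syn_rate = 2` and
`nonsyn_rate = 0.4` (Ka/Ks = 0.2, a typical plastid purifying regime).
Pairs whose expected raw synonymous difference proportion exceeds 0.74
are flagged, since the Jukes–Cantor correction degenerates there.

**What the simulator does not emulate.** No among-site rate
heterogeneity, no indel evolution (gaps are injected, not evolved), no
recombination, no IR-mediated structural change, and mutation placement
rather than an explicit substitution process. Passing tests on synthetic
data therefore demonstrate that the statistics and the selection logic
behave as designed under a controlled site-frequency contrast — not that
any particular real plastome alignment contains regions passing the
filter.

## Plastome records and curation

GenBank flat files are parsed with coordinates converted once, at the I/O
boundary, to 0-based half-open; everything downstream uses that single
convention. CDS curation follows submission-style rules: genes whose
spliced CDS is off-frame or lacks a start/stop are flagged removed;
internal stop codons are masked to `NNN`; duplicated gene names are
flagged multi-copy. Accepted start codons default to `{ATG, GTG}` (GTG
initiation occurs in plastid genes) and are configurable. The shared
single-copy filter keeps genes present exactly once in every species with
no `N` anywhere, in deterministic alphabetical order; gene names are
matched case-insensitively with locus-tag suffixes stripped, since
annotation dialects vary.

Quadripartite detection finds the longest pair of disjoint, exactly
reverse-complementary repeats on the circular sequence by k-mer
seed-and-extend (k capped at 24), deduplicating seeds of the same repeat
through the invariant sum of their coordinates. The longer single-copy
gap is labelled LSC, the shorter SSC, and the copy following the LSC is
IRb by convention. Ties between equal-length maximal pairs resolve to the
pair with the smaller start coordinate, so results are deterministic; the
result is invariant under rotation of the circular sequence.

## Numerical and policy choices

* Window scan defaults: window 500, step 100 columns,
  `max_gap_fraction` 0.2, `min_usable` 100. Block collection: minimum
  length 150 columns, per-column gap fraction at most 0.1. These are
  recorded in output headers; the scan source material never states its
  windowing, so these are declared package defaults, not inherited
  values.
* The D threshold is strictly `D > -0.5`. The symmetric variant
  (`|D| < 0.5`) is available via `upper_threshold` and off by default.
* Undefined-D blocks are never selectable.
* All randomness flows through explicit `seed` arguments; the global RNG
  state of the caller is saved and restored, and fixed seeds give
  byte-identical FASTA/JSON/report outputs (timestamps and output paths
  are excluded from reports for this reason).
* Validation scale: the package's own end-to-end checks run 20 replicates
  of the 17-taxon, 4-clade, 50 kb alignment design and 10 replicates of
  the 57-gene Ks design; these sizes keep each property estimate stable
  (binomial s.e. below ~7 points) while the whole suite stays fast.

## Interfaces

`run_pipeline()` orchestrates the stages from a validated configuration
(`validate_config()`, YAML or list, unknown keys rejected, all
violations reported at once) and persists every intermediate artifact —
window TSV, block BEDs, genotype TSV, newick trees, truth JSON/BED in
synthetic mode, and a machine-readable JSON report whose counts are
re-derivable from the artifacts. The exported functions are the
interface; this is an analysis package, and R users compose the stages
directly (see the README for a worked example).

## Known limitations

* Real-data mode consumes a precomputed whole-plastome alignment; the
  package neither aligns genomes nor annotates them.
* Tajima's D across species violates the single-population sampling
  assumptions of the test; as in the source analyses, D is used here as a
  descriptive filter statistic for allele-frequency shape, not as a
  hypothesis test.
* The NG86 estimator is the counting method with JC correction; no
  maximum-likelihood codon model is provided.
* Modal-Ks nearest neighbors are a heuristic classification; ties and
  near-ties among close congeners (the very cases such analyses flag as
  "problematic species complexes") remain ambiguous by construction.
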