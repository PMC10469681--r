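---
title: "clademark: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{clademark: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clademark)
```

`clademark` packages the computational core of a MAG-based clade
reclassification: marker-gene curation over gene trees, supermatrix
assembly, identity-threshold group delineation, pathway and antioxidant
profiling, abundance estimation, and a simplified ancestral gene-content
reconstruction. This vignette explains the models and rules, the
parameters that matter, what the synthetic-data generators do and do not
emulate, and the design decisions taken where several readings were
possible.

## Marker-gene curation

The screen consumes gene families — per-genome copy counts, a multiple
alignment, a gene tree — plus genome metadata, and applies four filters
in a fixed order, recording each family's *first* failing rule:

1. **Eligibility.** Only genomes with completeness strictly above
   `completeness_min` (default 85%) participate. The strict inequality
   mirrors the usual "completeness > 85%" phrasing of MAG quality
   cutoffs: a genome at exactly the threshold is excluded.
2. **Single copy and occupancy.** A family is discarded if any eligible
   genome carries two or more copies, or if fewer than `occupancy_min`
   (default 0.5) of the eligible genomes carry it at all. "Single copy
   in every genome" is ambiguous for incomplete MAGs — absence may be a
   binning artifact — so strict single-copy and occupancy are separate
   dials: `occupancy_min = 1` gives the full-occupancy reading,
   `0.5` the "discard if harboured by less than half" reading.
3. **Monophyly.** The focal clade's gene copies must be monophyletic in
   the family's gene tree. Monophyly is defined on the *unrooted* tree
   via bipartitions (single-gene trees rarely carry a defensible root;
   a rooted input is treated as unrooted). Families with fewer than two
   focal copies pass vacuously, with a logged note — monophyly of one
   leaf is undefined-but-true.
4. **Contamination.** Published screens often discard a gene when the
   focal sequences "cluster with" particular contaminant lineages — a
   judgement usually made by eye. We formalise it with the *minimal
   spanning side*: the smallest edge-bipartition side containing every
   focal copy. If that side contains any leaf from an excluded clade,
   the family is discarded. A stricter reading (additionally requiring
   focal monophyly) is what the combined filters 3 + 4 give.

Surviving alignments are restricted to eligible genomes, columns with
strictly more than `max_gap_frac` (default 5%) gaps are removed — at
exactly 5% a column is kept, the literal "more than" — and the blocks
are concatenated, gap-filling genomes absent from a family. Partition
intervals are reported 1-based inclusive, matching the RAxML
`GENE, name = start-end` convention of the partition file writer.

## Group delineation

16S-style records below 700 ungapped bases are excluded (a 700 bp record
passes). Identity is computed on aligned columns where neither sequence
has a gap, which also drops terminal-gap columns; we fix this
alignment-column definition because the alternative (k-mer identity)
depends on tool internals, and the inputs of interest are already
aligned. Unaligned input is an error rather than silently pairwise
aligned.

Greedy centroid clustering processes sequences in decreasing ungapped
length (ties broken by id) and joins the first centroid with identity at
least `rep_cluster` (default 0.99) — the common centroid-clustering
order, documented because tool-exact behaviour of the usual
implementations is not reproduced. Groups among the representatives are
connected components of the graph linking pairs with identity strictly
above `intra_min` (0.97). Pairs of distinct groups with identity at or
above `inter_max` (0.91) fall into the ambiguous 91–97% band, for which
published threshold pairs give no rule; we flag them `unresolved`
instead of forcing a merge. Queries take the best representative's group
when identity exceeds `intra_min`, else `unassigned` with the best
identity reported.

## Pathway and antioxidant profiling

A pathway is `present` when strictly more than half of its genes are
present — for an even gene count that means at least n/2 + 1, e.g. 5 of
8 — and otherwise `partial` when at least two subunits of its key
cluster are present (the "more than one subunit of cdhABCDE" rule for
the Wood–Ljungdahl pathway), else `absent`. Calls are ordered
(`absent < partial < present`) and provably monotone: adding a gene
never demotes a call. Genes absent from the annotation matrix count as
zero with a logged list, since absence-of-evidence is routine for
incomplete MAGs.

Pathway definitions ship as editable JSON
(`inst/extdata/pathways.json`). The default Wood–Ljungdahl gene list
(fwdB, ftr, mch, mtd + cdhABCDE) is a placeholder for whatever gene set
an annotation pipeline associates with the pathway; the cdhABCDE key
cluster is the fixed, meaningful part. The antioxidant panel is the four
archaeal oxidative-stress genes (superoxide reductase, rubredoxin,
rubrerythrin, bcp-2); categories are `none-detected` (0 of 4, the
strictly-anaerobic candidate), `minimal` (1), `partial` (2–3), `full`
(4).

## Abundance and environmental correlation

RPKM is `mapped / ((length/10^3) * (total/10^6))`. Some papers write the
unscaled `mapped / (length x size)`; the kb/million constants change
only the units, and every downstream use here (ranking, correlation) is
scale-invariant. "Metagenome size" is taken as total reads; passing
total bases instead simply changes the `total` argument's units.
Per-sample outputs are the raw read fraction `mapped/total` and the
RPKM-normalised share, which sums to one over genomes and corrects the
length bias of raw counts. Spearman correlations use average ranks with
the t-approximation p-value, or a seeded permutation null recommended
below ~10 samples, with Benjamini–Hochberg adjustment across
parameters.

## Ancestral gene content

The reconstruction is deliberately a desk-scale stand-in for full
gene-tree/species-tree reconciliation: it works on presence/absence
profiles only, so **a transfer is indistinguishable from an independent
gain**, and no donor–recipient inference is attempted.

*Fitch parsimony* returns the minimum change count and one optimal
labeling; ambiguous nodes resolve to absence (state 0), a conservative
tie-break that avoids inflating ancestral gene content. *The two-state
Markov model* has gain rate g (0→1) and loss rate l (1→0) per
branch-length unit, root prior defaulting to the stationary probability
g/(g+l), and uses Felsenstein pruning with the analytic 2×2 transition
matrix; zero-length branches get the identity matrix. Marginal
posteriors come from a standard up/down pass; per-branch expected events
are posterior *endpoint-transition* probabilities (the probability the
branch starts absent and ends present, or vice versa), not expected
event counts along the branch — the distinction matters only on long
branches. Rates are estimated by Nelder–Mead on the log-rate scale
(relative tolerance 1e-6), which in practice converges on these 2-D
smooth likelihoods without a preliminary grid. Posterior thresholds for
declaring a gene "present at an ancestor" are left to the user; the
package reports probabilities.

## Synthetic data: what is and is not emulated

All generators are bit-reproducible under a seed and restore the
caller's RNG state.

* **Species trees** are Yule radiations grafted onto a Yule backbone, so
  every named clade is monophyletic by construction; depth is rescaled
  to an expected root-to-tip substitutions/site (default 0.75).
* **Gene families** evolve by a birth–death-within-species-tree process:
  duplications split a lineage in place, losses end it, and transfers
  copy it to a uniformly chosen other branch — the *undated* fallback,
  since the simulated trees carry no time calibration and undated
  reconciliation is the relevant comparison point. With all rates zero
  the gene tree is exactly congruent with the species tree. Expected
  duplication counts follow the closed-form branching expectation
  (lineages multiply as e^(rate·length)), which the tests use as an
  independent oracle.
* **Sequences** evolve under JC69 only; richer models would not change
  what the screens exercise.
* **16S-style sets** plant intra-group identity 0.98 and inter-group
  0.88 (the defaults bracket the usual >97% / <91% thresholds) using
  the JC expected-identity inversion; records are 5'-anchored partials
  with ungapped lengths uniform in [650, width], so the 700 bp filter
  is exercised and any two records always share comparable columns.
* **Annotation matrices** give each genome its group's signature genes,
  optionally thinned gene-by-gene with retention probability
  completeness/100 — the simplest model that makes completeness
  thresholds consequential.
* **Read counts** are per-sample multinomials with probability
  proportional to abundance × genome length.

Not emulated: read-level sequencing (FASTQ), assembly and binning
artifacts, chimeras, alignment error, rate heterogeneity across sites
and lineages, and real 16S primer chemistry. Passing tests therefore
show the *procedures* are correct under their stated models, not that
the thresholds are optimal for any particular real dataset.

## Numerical choices and edge cases

* JC distance is undefined at p ≥ 0.75; the default is an error naming
  the pair, with an `Inf` option.
* Neighbor joining delegates to the standard implementation; negative
  branch lengths (possible off additive inputs) are clamped to zero
  with a warning. On additive matrices path lengths reproduce the input
  to 1e-9.
* Newick writing keeps 10 significant digits, so round-trips preserve
  branch lengths to better than 1e-9; missing branch lengths read as 0;
  a tree is unrooted iff its root has at least three children.
* An all-lineages-lost gene family is an empty family, not an error;
  an all-gap trimmed alignment warns and is excluded with its own
  verdict reason.
* Zero comparable columns between two sequences is always an error that
  names the pair.

## Validation design and problem sizes

Every nontrivial primitive is checked against an independent oracle:
monophyly and minimal spanning sides against exhaustive edge enumeration
(100 random trees of up to 12 leaves), Fitch against the exhaustive
labeling minimum (200 cases up to 6 leaves), pruning log-likelihoods
against full enumeration (agreement well below 1e-8), Spearman against
explicit average ranks. Recovery tests use 50 additive matrices for NJ,
20 seeds for group delineation, a 100-family planted screen (60
vertical, 40 disrupted at duplication 0.3 / transfer 0.6), 10^6-read
multinomials, 500 simulated binary profiles for expected branch events,
and 1000-site JC alignments. The end-to-end demonstration
(`runDemo`) simulates an eight-group focal phylum (3 genomes per group,
30 marker families, 48 16S-style records, 4 abundance samples) with the
Wood–Ljungdahl signature planted in the three root-proximal groups and
antioxidant panels planted as none / rubrerythrin-only / three-of-four /
full, and verifies the profile output reproduces exactly that structure.
These sizes complete in a few minutes on a single core and leave the
Monte-Carlo checks well-powered (3-standard-error bands).

## Known limitations

* Group delineation can split a planted group in rare draws where a
  realized representative-pair identity falls below the 0.97 link
  threshold; the flagged-band design reports, rather than repairs, such
  cases.
* The contamination screen inherits the arbitrariness of any
  formalisation of "clusters with": a single stray excluded-clade leaf
  inside the minimal spanning side discards the family.
* The gene-flux module reconstructs presence/absence only; copy-number
  dynamics and transfer routes are out of its scope by design.
* Greedy clustering reproduces the common centroid heuristic, not any
  specific tool's tie-breaking; results can differ from tool output at
  the margins.
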