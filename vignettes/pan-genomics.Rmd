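---
title: "Methods: pan-genome inference, whole-genome metrics and core-gene phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-genome inference, whole-genome metrics and core-gene phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(panforge)
```

This vignette documents the models and procedures implemented in
`panforge`, the parameters that matter, the design choices made where the
design was genuinely open, and what the synthetic-data validation does and
does not establish about behaviour on real data.

## The analysis chain

For a panel of conspecific bacterial genomes the package runs, in order:

1. **Gene-call reconciliation** (when raw predictor output is the input).
   Prokaryotic gene callers usually agree on a gene's stop codon and
   disagree on its start, so calls sharing strand and stop-side coordinate
   are merged into one model taking the longest extent; calls seen by a
   single predictor are retained, trading a few false positives for fewer
   false negatives.
2. **Ortholog families.** All-vs-all protein search, reciprocal best hits
   (RBHs) per genome pair, then two-stage clustering: single-linkage
   connected components of the pooled RBH graph, followed by Markov
   clustering within each component.
3. **Presence/absence matrix.** One row per strain, one column per family;
   genes excluded by the minimum cluster size re-enter as prevalence-1
   columns so strain-unique genes are counted.
4. **Rarefaction and openness.** Core/pan/new-gene counts under permuted
   genome-addition orders; Heaps-law fit to the new-gene medians.
5. **Whole-genome metrics.** Fragment-based ANI and POCP, species
   classification, complete-linkage clustering of metric matrices.
6. **Core-gene phylogeny.** Concatenation of single-copy core families,
   gap-column stripping, SNP distances, neighbour-joining with bootstrap,
   outgroup rooting.
7. **Replicon profiling.** Marker- and homology-based contig assignment,
   reference-cluster presence calls, per-replicon functional count
   matrices.

## The similarity search and its constants

The internal engine performs local (Smith–Waterman) alignment under
BLOSUM62 with affine gaps, open 11 / extend 1, via
`Biostrings::pairwiseAlignment()`. Raw scores are converted to bit scores
and e-values with the standard Karlin–Altschul constants for that scoring
system (λ = 0.267, K = 0.041):

* bit = (λ·S − ln K) / ln 2
* E = K·m·n·e^(−λS), with n the subject proteome's total residue count.

Hits are gated only by percent identity (≥40), query coverage (≥50 % of
the query's full length) and bit score (≥50 for orthology, ≥60 for
annotation transfer); the e-value is reported but does not gate ortholog
hits. Identity is computed over the aligned region including internal
gaps, the convention of tabular search output.

Aligning every pair of proteins is quadratic, so the engine seeds
candidate pairs by shared amino-acid 6-mers — the same idea as word
seeding in BLAST-family tools. At the divergences relevant here (≤ 15 %
amino-acid distance between family members) a shared 6-mer is essentially
guaranteed; at the 40 %-identity threshold floor a borderline hit between
two *unrelated-looking* sequences can in principle be missed, which is why
`exhaustive = TRUE` exists and is used in the oracle-backed tests. An
external search engine can be substituted by supplying its tabular output
in the `SimilarityHit` column contract.

## Reciprocal best hits and two-stage clustering

For a genome pair, `(a, b)` is an RBH iff each is the other's unique best
hit; "best" is highest bit score with ties broken by higher identity and
then lexicographic subject id, making the result deterministic. RBH edges
are weighted by the mean of the two directed bit scores (the sources fix
only the inflation value, not the edge weighting; bit-score weighting is
the documented, configurable default).

Markov clustering runs within each connected component on the
column-stochastic adjacency with self-loops (loop weight = the node's
maximum incident edge weight — loops are required for convergence and this
is the conventional choice), expansion power 2 and inflation 3.
Convergence is declared when the largest entry change drops below 1e-6, or
after 100 iterations. Attractors (non-zero diagonal) define clusters; a
node attracted by several clusters is assigned to the one holding most of
its column mass, ties to the lexicographically smallest attractor.
Clusters below the minimum size (2) become singletons. On graphs whose
components are cliques the procedure reduces exactly to connected
components, which is one of the tested invariants.

Quartet-based paralogy discrimination is deliberately **not**
implemented; the contract is RBH + two-stage clustering. Multi-copy genes
are retained and binarised in the matrix.

## Rarefaction and the Heaps fit

Genome-addition orders are sampled uniformly with replacement from the N!
permutations (1000 by default; an explicit order list can force exhaustive
enumeration on small panels, which the tests exploit). Medians — not
means — summarise the per-k distributions. The openness fit is OLS of
log10(new) on log10(k) over k ∈ [2, N]: new(1) is the first genome's full
complement, not a discovery increment, so it is excluded by default; the
fitted range is explicit in the output because reasonable analyses may
trim further leading points. α = −slope; α < 1 (strictly, with a 1e-9
numerical guard at the boundary) calls the pan-genome open. The fit is
scale-equivariant: rescaling the medians moves κ, never α.

Quantiles everywhere (e.g. per-replicon gene-count summaries) use linear
interpolation between order statistics (R's default type 7), which is why
fractional medians like 47.5 can arise on even-sized panels.

## ANI and POCP

ANI follows the classic fragment protocol: the query genome is cut into
consecutive 1020-nt fragments (a trailing fragment is kept if ≥100 nt —
this tail rule is not specified by the protocol's sources and is
configurable), each fragment is aligned to the other genome with `blastn`
(reward 1 / penalty −1, gap x-dropoff 150, no dusting, e ≤ 1e-15), and a
fragment is retained when its best hit reaches ≥30 % identity over ≥70 %
of the fragment length. The directed ANI is the mean identity of retained
fragments and the reported ANI averages the two directions (whether the
original analyses averaged or reported one direction is not documented;
the mean is the default and both directed values are always in the
output). Fewer than 10 retained fragments in either direction flags the
value unreliable rather than suppressing it. The species boundary is an
inclusive 95 %.

POCP is ((C1 + C2)/(T1 + T2))·100 with Ci the count of genome i's
proteins having ≥1 hit in the other proteome at e ≤ 1e-5, identity ≥40 %
and alignable region >50 % of the query protein's full length. The
formula is symmetric by construction and the implementation preserves
that exactly.

Metric matrices are clustered by complete linkage on Euclidean distances
between similarity rows (not on 100 − ANI); this affects dendrogram
heights, not the merge order, and matches how such heatmaps are usually
drawn.

## Core-gene phylogeny

Only families with exactly one member in every strain enter the
concatenation (multi-copy or partial families are dropped with a recorded
count), in sorted-family-id order so every strain concatenates
identically. Alignment is a pluggable engine: the internal engine handles
the already-colinear equal-length case (the synthetic panel's family
copies never need gaps); MAFFT is wired in for ragged input, and any
external aligner can be used through FASTA round-tripping. After
alignment, every column containing at least one gap is removed, and SNP
distances are counted on the gap-free columns (case-insensitive; any
non-identical symbol pair counts). Both amino-acid and nucleotide
concatenations are supported; the alphabet is recorded in the result.

Maximum-likelihood inference is out of scope by design: the internal tree
engine is neighbour joining on the SNP (or any) distance matrix, with
NJ's occasional negative branch lengths clamped to zero and the deficit
moved to the adjacent branch so path lengths are approximately preserved.
Bootstrap supports resample alignment columns with replacement, rebuild
the tree per replicate, and report the percentage of replicates containing
each internal bipartition of the full-data tree. Rooting places the root
on the outgroup's pendant edge; a display-only flag can shorten the drawn
root branch without ever altering Newick distances.

## Replicon assignment and functional profiling

The full supplementary protocol behind marker-based replicon assignment is
not available, so the implemented rule is a documented reconstruction:
contigs carrying a repA-type marker gene (repA/repE/parA) at ≥93 %
identity over ≥90 % of the marker's length are called repA-type
megaplasmid; remaining contigs take the reference class with the greatest
merged homology coverage of the contig; a contig whose best class covers
less than 20 % stays unassigned. The homology floor is not derivable from
any source and is documented as a default, not an inference; marker
searches are nucleotide-level (the quoted identity range 79–100 % spans
values only meaningful for nucleotide comparisons). All three thresholds
are arguments.

Reference-cluster (e.g. exopolysaccharide cluster) presence is called per
gene by annotation transfer against the cluster's proteins and at cluster
level by an inclusive threshold of matched genes (default 18); the
per-gene vector and observed gene order are emitted rather than any
hard-coded sub-grouping, so downstream groupings remain possible. The
LPXTG sorting-signal scan requires the L-P-x-T-G pattern to begin within
the C-terminal 50 residues — the original detection method is unavailable,
but sortase-substrate biology places the motif near the C-terminus; the
window is configurable. Bacteriocin profiling via annotation transfer
against a user-supplied reference FASTA is possible but is not equivalent
to HMM-based detection, and is documented as such.

## The synthetic panel generator

The generator emulates exactly what the downstream statistics consume: a
panel of N strains sharing `n_core` families, accessory families at
configured prevalences, `n_unique_per_genome` strain-private genes, a
chromosome / repA-megaplasmid / other-megaplasmid / small-plasmid replicon
architecture, and star-wise nucleotide divergence: each family descends
from one ancestral coding sequence and every strain's copy is mutated
independently at the per-site substitution rate, so expected pairwise
identity is ≈ (1 − r)² per site and stays analytic. Genes are random
codon strings with fixed start/stop codons; mutations that would create an
internal stop (or destroy the terminal stop) are reverted to the ancestral
codon so proteomes remain clean equal-length ORFs — a negligible bias at
the rates used (≲5 % of mutated codons). Replicons are gene
concatenations with 100-nt spacers; each family carries one ancestral
spacer that mutates per strain like the genes, and gene order and strand
are fixed across strains, because rearrangement simulation is a non-goal
and colinear genomes are what make fragment-based ANI behave as it does on
real conspecific assemblies.

Defaults chosen once and held fixed: mean gene length 250 codons (typical
bacterial coding genes run ~750–900 nt); allocation of families to
replicon classes mirrors the empirical pattern that core genes are
overwhelmingly chromosomal while accessory and unique genes are enriched
on the megaplasmid and small plasmids (core 90/10/0/0,
accessory 35/45/0/20, unique 30/40/0/30 across
chromosome/repA-megaplasmid/other-megaplasmid/small-plasmid); every strain
has one chromosome, one repA-type megaplasmid and one small plasmid unless
a per-strain plan says otherwise. An allocation that sends a family to a
replicon class some carrying strain lacks is a configuration error, not a
silent reassignment.

**What passing on synthetic panels shows — and what it does not.** The
generator produces clean ORFs, star-shaped divergence, no rearrangements,
no assembly fragmentation or contamination, and no true paralogy. Exact
recovery (adjusted Rand index 1.0 at 2 % divergence) therefore validates
the machinery — thresholds, RBH logic, clustering, matrix bookkeeping —
not robustness to fragmented assemblies, domain shuffling, or recent
paralogs, which real panels contain.

## Problem sizes and numerical choices

The validation suite exercises a 12-genome panel (300 core families,
accessory prevalences 2/6/11 with 40/40/20 families, 15 unique genes per
strain, 2 % substitution rate), 1000-permutation rarefactions, Heaps
recovery over 100 noisy replicates, 200-kb genomes for ANI calibration
and 50-kb genomes for the rate-monotonicity sweep, and 100-replicate
bootstraps; these sizes were chosen as the smallest that make the
statistics sharp (e.g. exact core recovery, binomial noise on ANI well
under the 0.3-point tolerance).

Numerical conventions collected in one place: MCL convergence 1e-6 / 100
iterations with entries below 1e-12 pruned between iterations; Heaps
openness boundary guarded at 1e-9; proportions validated to 1e-9;
deterministic tie-breaks everywhere (lexicographic ids after score and
identity); all random processes consume an explicit integer seed, and the
generator restores the caller's RNG state.

## Known limitations

* The seeded search is a heuristic; near the 40 %-identity floor a
  diverged borderline hit can be missed unless `exhaustive = TRUE`.
* NJ is a distance method; for publication-grade phylogenies export the
  stripped alignment and use an ML engine, then re-import the Newick.
* Fragment ANI shells out to `blastn`; the PATH must provide BLAST+.
* The replicon-assignment rule is a reconstruction with configurable
  thresholds, not a re-implementation of an published protocol.
* E-values from the internal engine use the subject proteome as the
  database; comparing them across databases of very different size is
  not meaningful.
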