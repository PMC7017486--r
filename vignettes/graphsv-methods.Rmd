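---
title: "Genotyping structural variants on a variation graph: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping structural variants on a variation graph: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `graphsv`, the parameters
that matter, the numerical and design decisions taken where several
reasonable choices existed, and what the simulation-based validation does
and does not establish.

## The graph model

A variation graph is a bidirected sequence graph: nodes carry DNA (1 bp to
`max_node_len`, default 1024 bp), and edges connect node *sides* (left or
right end), so a walk may traverse a node in either orientation.
`build_graph()` embeds a VCF catalog into the reference:

* coordinates are 0-based half-open internally; VCF input is 1-based;
* reference contigs are split at every variant breakpoint, and segments
  longer than `max_node_len` are split left-to-right (the cap keeps the
  seed index and coverage vectors well-conditioned; its exact value only
  changes the node decomposition, not any spelled sequence);
* a deletion contributes a bypass edge, an insertion new node(s), an
  inversion two edges into the reverse orientation of the existing
  reference segment (no sequence duplication), and any other explicit
  replacement allele new node(s) carrying the ALT core;
* each allele of each VCF record is annotated as a walk anchored on the
  reference nodes flanking the record's breakpoint-union interval, so that
  a multi-allelic record's alleles all span the same interval.

Explicit alleles are reduced to a minimal core by trimming the shared
suffix then the shared prefix. An explicit inversion is recognised *before*
trimming — equal-length alleles whose padding-stripped sequences are exact
reverse complements — because trimming can slide the interval when segment
end bases coincide by chance. Two equivalent normalized representations of
the same indel (when flanking bases repeat) are both accepted; downstream
matching is representation-tolerant by construction.

Variants that cannot be anchored (breakpoints at the very first or last
reference base) are rejected with an error; catalogs produced by the
simulator always leave flanking sequence. Overlapping records embed jointly
as long as each allele can be anchored; allele combinations that cannot be
spelled as one walk are dropped at traversal-enumeration time rather than
at construction.

## Snarls

The unit of genotyping is the snarl, defined by two criteria on a pair of
sides `{x, y}`: separation (cutting the edges incident to the opposite
sides `x'` and `y'` disconnects a component `X` containing `x` and `y`) and
minimality (no side `z` of `X` forms such a pair with `x`, and likewise
with `y`). The printed definition leaves the connectivity model implicit,
and a literal reading fails on the simplest bubble (nothing is removed when
the boundary's outer sides have no edges). The package therefore fixes the
following operational formalization, chosen to reproduce the intended
behaviour on bubbles, chained bubbles, and nested sites:

> In the side graph (vertices = node sides; edges = node-traversal edges
> `s — s'` plus adjacency edges), remove **all** edges incident to `x'` and
> `y'`. The pair is separable iff the component `X` of `x` contains `y` and
> every side of `X` other than `x` and `y` retains at least one adjacency
> edge — i.e. `X` is internally closed and the only ways in or out are
> through `x` and `y`.

`find_snarls()` prunes candidates to sides with adjacency degree ≥ 2: a
degree-1 side's only separable partner is its sole neighbour (the trivial
snarl between mutually single-edged sides, enumerated analytically), so
non-trivial boundaries must branch. Small graphs (≤ 200 sides) are searched
exhaustively over all side pairs instead; the test suite checks both code
paths against an independent brute-force implementation of the definition.
Canonical orientation puts the boundary with the smaller reference
coordinate first; one level of nesting is recorded via component
containment. Genotyping uses top-level snarls whose boundary nodes both lie
on a reference path, with variant containment decided on breakpoint
intervals (stable under node splitting).

## Read mapping and the coverage index

The mapper is deliberately simple plumbing: exact k-mer seeds (default
`k = 16`; within-node k-mers forward, junction-spanning k-mers in both
orientations so reverse-strand and inversion-crossing placements are
discoverable), then banded affine-gap alignment (match +1, mismatch −4,
gap open −6, gap extend −1; band `2 + ⌈0.1·read length⌉`) of the read
against candidate graph walks, bounded at 64 walks per seed cluster
(overflow ⇒ MAPQ 0). Candidates anchored on the forward reference path are
scored against the cached contig sequence first and fall back to walk
enumeration only when the linear alignment is imperfect, which is what
keeps desk-scale mapping fast in R. Two placements are the same placement
when they cover the same oriented step footprint; keys are canonicalized
under walk reversal, since a walk and its reverse complement describe one
physical placement. MAPQ is `min(60, 10·(s_best − s_second))`, 60 for a
unique placement, 0 on ties. Reads scoring below 40% of their length are
reported unmapped.

`compute_pack()` makes one pass over the alignments and counts, for every
node base and edge, the reads of MAPQ ≥ 5 covering it. Soft behaviour at
the edges of the definition: read deletions do not cover the skipped graph
bases; read insertions add no coverage; each mate counts as one read; an
edge is counted when the alignment covers at least one base on each side of
the junction. Counting is order-independent by construction.

## Genotyping

For each top-level snarl the Cartesian product of contained-variant alleles
is rendered as walks from boundary to boundary. Above 500,000 combinations,
alleles with average support below 1 are dropped per variant (always
keeping the reference allele and the best-supported allele); a site still
over the bound is skipped as a no-call.

A traversal's *support* is the average over its interior node bases and all
traversed edges (`traversal_support()`). Boundary nodes are excluded: they
are shared by every traversal and would only dilute the signal. For
*ranking* traversals the genotyper goes one step further and averages over
elements not shared by **all** candidate traversals of the snarl, falling
back to all elements when nothing distinguishes. For deletions and
insertions this is identical to the plain average. For inversions it is
essential: the reference and inverted traversals share every interior node
(coverage counts are orientation-less), so their plain averages nearly
coincide and every inversion would be called heterozygous; restricted to
the distinguishing elements, the four breakpoint edges carry the evidence
and hom-ref/het/hom-alt separate cleanly. This is the package's resolution
of an averaging rule whose exact operands are not published.

The calling rules are applied in order with strict inequalities:
homozygous when `s1 > min_support` (default 1) and `s1 > B·s2`
(default `B = 6`); else heterozygous when `s2 > min_support`; else — a case
the two printed rules leave open — homozygous for the best traversal when
it alone is supported; else no-call. Ties in support break
deterministically: reference-allele traversals first, then lexicographic
allele vectors. The genotype quality is
`GQ = round(10·log10((s1+s2)·min(1, s1/(B·s2)) + 1))` — an arbitrary but
monotone-in-support score; the evaluation module only thresholds it, so any
monotone choice yields the same ranking behaviour. `DP` is the rounded sum
of the two top supports and `AD` the rounded support of the traversal(s)
carrying each allele.

## SV benchmarking

`normalize()` splits multi-allelics, right- then left-trims, infers types
from allele lengths, and recognises explicit inversions by locally aligning
the reverse complement of the ALT to the REF (> 80% of the shorter sequence
aligned, both sequences > 10 bp). Matching follows the standard two-track
procedure: reciprocal overlap for deletions and inversions (candidates at
RO ≥ 0.10 and size > 1 bp; a record is covered when the union of its
candidates covers > 50% of it — union rather than single best partner, so
fragmented representations still match), and Smith-Waterman alignment of
inserted sequences for insertion pairs at most 20 bp apart (per-record
aligned proportion ≥ 50%; with several candidates the maximum proportion
counts; the proportion counts the record's bases spanned by the optimal
local alignment). Smith-Waterman scores are match +1, mismatch −1, gap open
−3, gap extend −1 (not published; any sensible local scheme separates the
matched/unmatched regimes these thresholds test). Strictness follows the
printed wording exactly: `> 50%` coverage for DEL/INV, `≥ 50%` for INS,
`≥ 10%` RO. Records under 50 bp are never counted as TP/FP/FN but still
contribute coverage when larger than 1 bp. The 90%-coverage replicate is
`eval_options(min_coverage = 0.9)`.

Genotype-level evaluation first merges heterozygous fragments closer than
20 bp (skipping pairs that are ≥ 80% reciprocal duplicates, which instead
collapse into a homozygous record), then evaluates het and hom strata
separately and sums the counts. Region filtering keeps records with at
least half of their reference span (the insertion point for insertions)
inside the region set — the published analyses name their region sets but
not the inclusion rule, so this is the package's choice. PR curves
re-evaluate at every distinct call quality (QUAL, else GQ), reporting the
maximum F1 and the trapezoidal area over recall; insertion alignments are
memoised across thresholds.

## The simulation model

`sim_config()` encodes the study conditions: 1000 SVs per type separated by
at least a 500 bp buffer, genotypes uniform over hom-ref/het/hom-alt for 3
samples, read depths 1, 3, 7, 10, 13, 20×, 150 bp paired-end reads
(fragments ~ Normal(400, 50)), and breakpoint errors of 1–10 bp (deletions
and inversions shift one or both ends; insertions shift or lose flanking
sequence, with REF/ALT recomputed from the genome so perturbed records stay
internally consistent). The SV size distribution of the source catalog is
not published as a table, so the generator uses a stand-in mixture with the
right qualitative shape: 60% log-uniform on [50, 1000] bp, 30%
Normal(300, 30) truncated at 50 bp (the mobile-element-like peak), 10%
log-uniform on [1, 10] kb; it is configurable. Sequencing error is a
parametric substitution-only model at 0.2% per base (the published
experiment trained an error model on real reads; training data is out of
scope here). The genome is uniform random ACGT on one contig, auto-sized to
fit the requested catalog plus buffers.

What this emulates well: breakpoint-accurate and breakpoint-perturbed
catalogs, zygosity recovery from relative path support, depth titration.
What it does not: repeats and segmental duplications (a uniform random
genome is maximally mappable, so real-data mapping ambiguity is
under-represented), indel sequencing errors, GC and coverage biases,
overlapping/nested variant clusters, and catalogs with wrong or missing
alleles. Passing the simulated validation therefore demonstrates
correctness of the machinery under its stated assumptions, not real-data
performance.

## Validation scale and determinism

The test suite replicates the validation at desk scale, chosen so the whole
suite runs comfortably on one CPU: snarl-search equivalence on 200 random
variant graphs of up to 30 nodes against the exhaustive oracle; the
simulation experiment with 50 SVs per type (~320 kb genome, one sample) at
20× for exact and perturbed catalogs; the depth trend with 25 SVs per type
at 1/3/20× over three seeds, compared on seed-averaged maximum F1; and the
evaluation identities on 1000 randomized interval configurations. At this
scale the experiment reaches presence-F1 of 1.0 for all three SV types at
20× with exact breakpoints and stays within 0.1 under 1–10 bp breakpoint
errors, mirroring the published robustness claim. Every stochastic step
takes an explicit seed and sub-seeds derive arithmetically from it, so all
pipelines are bit-reproducible; ties anywhere are broken deterministically.

## Known limitations

* Ploidy is fixed at 2; no multi-sample joint calling.
* Novel-variant discovery (graph augmentation from read alignments) and
  haplotype-index-aware mapping are out of scope; the mapper is a stand-in
  adequate for desk-scale experiments, not a competitive aligner.
* The pack index ignores base qualities.
* Overlapping catalog records genotype jointly within one snarl; truly
  contradictory allele combinations are silently dropped from the
  traversal set rather than reported per-record.
* The linear-time cactus-decomposition algorithms used by production
  pangenome toolkits for snarl finding are replaced by a definition-driven
  search; it is quadratic in branching sides and meant for desk-scale
  graphs.
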