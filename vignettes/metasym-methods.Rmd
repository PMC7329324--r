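---
title: "Methods: symbiont metagenome binning, strain variation, and BGC family analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: symbiont metagenome binning, strain variation, and BGC family analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`metasym` analyses host-associated bacterial symbiont communities — the
motivating system being the gill endosymbionts of shipworms, intracellular
gammaproteobacteria whose genomes carry unusually many biosynthetic gene
clusters (BGCs). This vignette documents the models behind each stage, the
parameters that matter, what the synthetic-data generators do and do not
emulate, and the design decisions taken where more than one reasonable
formalisation existed.

## 1. Fragment-based gANI and alignment fraction

**Model.** Genome average nucleotide identity is computed fragment-wise:
the query (a genome or a metagenome bin) is cut into consecutive
fragments of `fragment_bp` (default 1000 bp; trailing pieces under 200 bp
are not aligned but stay in the AF denominator). Each fragment is placed
on the reference by exact k-mer seeding (`seed_k = 16`) on both strands;
the diagonal with most seed hits is evaluated by gapless comparison, and
the best placement per fragment wins. A fragment *maps* when its placement
covers at least 70% of the fragment at 70% identity or better
(`min_fragment_cov`, `min_fragment_ident`). Then

- gANI = length-weighted mean identity of mapped fragments,
- AF = mapped fragment bp / total query bp.

**Assumptions.** Gapless extension is exact for substitution-only
divergence, which is what distinguishes closely related strains of one
symbiont species; at the 0–12% divergences this pipeline discriminates, a
16-mer exact seed occurs in essentially every 1 kb fragment
(expected ≥ 0.9^16 × 985 ≈ 180 seeds at 10% divergence). Genuine
rearrangements and indels reduce AF rather than corrupting gANI, which is
the desired failure direction for the assignment rule. This fragment
formulation needs no gene calls; on substitution-only data it converges to
gene-based gANI definitions.

**Thresholds.** Bin assignment requires AF > 0.5 *and* gANI > 0.9 (strict
inequalities, read literally from the rule's statement); among passing
references the maximal gANI wins, ties broken by larger AF then
lexicographic reference id, so assignment is a total order. Conspecificity
is gANI ≥ 0.95. The 70%/70% fragment-mapping thresholds are implementation
choices to exclude spurious placements and are exposed as arguments.
Aggregate gANI over a group of bins is Σ(gANI·len)/Σ len with len the
total bin size — the length-normalised summary used when many bins of one
species map to one reference.

**Bacterial-bin rule.** A bin is bacterial when coding density > 0.5 and
the bacterial fraction of its per-gene taxonomy labels is ≥ 0.60. Gene
taxonomy is injected (`contig_bin(gene_taxa = ...)`), not computed: the
upstream database search is out of scope. Whether unassigned genes belong
in the denominator is genuinely ambiguous; the default counts classified
genes only (`denominator = "classified"`), with `"all"` available.

## 2. Read mapping and community composition

The mapping contract is explicit rather than delegated to an external
mapper: a read maps to a reference iff its best placement contains an
exact match of ≥ `min_exact_seed` (22) bp, at most `max_subs` (15)
substitutions and at most `max_indel` (80) indel bp. Seeds are exact
22-mers; extension is gapless first, and only when the gapless diagonal
exceeds the substitution cap is a banded *global-local* alignment tried
(the whole read against a reference window), so substitutions can never be
clipped away at read ends. Best reference = fewest mismatches, then fewest
indel bp, then lexicographic id — deterministic under any input order.
Composition percentages are reads per species / total reads × 100;
species under `minor_floor` (0.5%) pool into a `"minor"` category
mirroring the gray "minor, sporadic, unidentified strains" slice of
stacked composition plots.

## 3. Marker-gene strain windows

The marker (a single-copy gene such as gyrB, typically ~2 kb) is tiled
with non-overlapping `window_bp = 50` windows. A read contributes to every
window its alignment fully covers; its bases over the window form the
window-restricted haplotype string. Partial-overlap reads are skipped per
window to avoid composite variants from ragged edges; `min_overlap_bp`
sets the minimum width a (possibly short trailing) window must have to be
profiled. Variants with fewer than `min_support = 2` reads are dropped as
sequencing noise — a deliberately mild floor, configurable for deeper
data.

`min_strains` is the maximum number of surviving variants in any window: a
*lower bound* on strain number, tight exactly when some window contains
discriminating sites for every strain pair and coverage suffices (≈ 50×
per window in practice). The mixture estimator pools variant-frequency
ranks across polymorphic windows and takes the median per rank,
renormalised. It is an estimator, not an identity: it assumes the same
strains dominate every window (no within-gene recombination) and its
per-window sampling error is binomial, so with w polymorphic windows of
coverage c its precision scales like 1/√(w·c). Edge windows of the marker
are covered only by reads aligned flush with the marker ends and may fall
under `min_support` at moderate coverage; interior windows carry the
signal.

## 4. BGC classes, similarity network, and GCFs

Only well-characterised product classes are networked: PKSs, NRPSs,
siderophores, terpenes, homoserine lactones, thiopeptides, and their
hybrids. Labels are canonicalised (lower case, "homoserine lactone" →
`hserlactone`) and matched as substrings so `t1pks` and `nrps-t1pks`
qualify.

All-vs-all protein comparison runs as one batched blastp call
(single-threaded for determinism). Two tiers of per-gene hits are used:

- *loose* — identity ≥ 30%, both coverages ≥ 25%: a stand-in for the
  multi-gene comparison tool's defaults, defining shared-gene counts;
- *strict* — identity ≥ 60%, both coverages ≥ 80%: the refinement filter
  for valid hits.

A directional cluster-to-cluster hit needs `min_shared = 3` loose-tier
query genes with subject homologs and scores
`shared · (1 + synteny)`, where synteny is the longest common subsequence
of the hit order divided by the shared count. The exact score of the
original multi-gene comparison tool is not published; this stand-in is
documented and has the same monotone behaviour (more homologs in conserved
order → higher score), and the network builder would accept externally
computed hits in its place.

Edges: bidirectional hits are reliable. A single-directional hit —
typically a metagenomic fragment against a full-length cluster — is
retained iff the *truncated member* (defined as the member with fewer
genes, since truncation here arises from assembly fragmentation) has
`s ≥ max(n − 2, 1)` strict-tier gene hits in the partner, `n` being its
gene count. The floor of 1 handles degenerate n ≤ 2, where n − 2 would
demand nothing. GCFs are connected components, numbered by descending
size then lexicographic smallest member — a reproducible formalisation of
what is otherwise a manual network-viewer grouping; edge weights and
types are exported (GraphML/SIF) so manual review remains possible.

## 5. Occurrence and fragment collapse

Core biosynthetic proteins of a GCF come from its largest member: the
`is_core`-flagged genes, or failing that the member's proteins with
strict-tier homologs in at least half the members. They are searched with
tblastn against each specimen assembly; hits must exceed 50% query
coverage and 90% amino-acid identity (strict inequalities). Identity is
computed over the aligned span at the protein level; alignments running
through in-frame stops are not reported as single hits.

Occurrence counts per (GCF, specimen) are distinct evidence loci: network
member BGCs of that specimen plus tblastn hit clusters (hits within
`locus_gap = 10 kb` on one contig merge) that do not overlap a member
locus. BGC records carry optional locus coordinates for exactly this
deduplication; without coordinates a member counts as its own locus.
Per-species values divide summed counts by the species' specimen number,
so 1 means "in every specimen once" and values above 1 indicate multiple
subtype loci.

Collapse: each metagenome BGC is assigned to its best-scoring reference
BGC. Within one (specimen, reference) group, fragments whose hit ranges on
the reference gene order are disjoint merge into one underlying cluster
(complementary pieces of a split cluster); overlapping ranges stay
separate (genuinely distinct copies). Merging is first-fit over fragments
sorted by range start with lexicographic tie-breaks — deterministic, and
conservative in never merging across references or specimens. The
inflation factor (matched metagenome BGCs / matched unique clusters)
generalises the observation that fragmentation roughly doubles raw BGC
counts; `estimate_total_unique()` divides any total by the *measured*
inflation rather than hard-coding 2×.

## 6. The synthetic-data module

The generators produce every input class with machine-readable ground
truth: substitution-only genome mutation (so expected identity is exactly
1 − d and mismatch counts equal the mutation log), weighted fragment bins
with per-contig provenance, uniform-start reads on both strands with
per-base substitution errors and a read-level truth table, marker strain
mixtures from explicit SNP sets, BGC families with terminal-contiguous
truncation (mimicking contig-edge fragmentation) and bounded protein
divergence, and complementary fragmentations of clusters for the collapse
estimator. All are deterministic given `seed` and leave the session RNG
untouched.

What they do *not* emulate — and what passing tests therefore cannot
show — includes indels and rearrangements, sequencing-quality profiles and
chimeras, paired-end structure, compositional bias of real proteins
(generated proteins are uniform over the 20-letter alphabet, which makes
spurious homology even rarer than in real data), repeat-rich trans-AT PKS
assembly pathologies, and any real taxonomy. Results on real data depend
additionally on assembly and binning quality, which are out of scope
(bins arrive as given).

Default study conditions used by the tests and the acceptance script are
the package's own choices at desk scale: 100 kb genomes for the
divergence sweep (d ∈ {0, 0.02, 0.05, 0.10}), 20 bins over 4 references
within 2% divergence plus a 12% outgroup, a 60/25/15 three-species
mixture of 10,000 125-bp reads at 1% error, 2,000 marker reads for 70/30
and 50/30/20 strain mixtures, 8 planted families (3–6 variants each,
truncation ≤ 40%, protein divergence ≤ 10%) with 10 unrelated singletons,
and 30 reference clusters fragmented into 75 pieces. These sizes keep
every stage comfortably within a single-CPU desk run while leaving the
statistical checks (binomial 3·SE bands, ±2 percentage points, ARI ≥
0.95, ±15% estimates) well powered.

## 7. Numerical choices and degenerate inputs

- Coordinates are 0-based half-open internally only at arithmetic
  boundaries; all user-facing positions are 1-based inclusive, matching
  GenBank/BLAST conventions.
- Ambiguity codes other than N are rejected at parse; N sites are never
  mutated and k-mers containing N never seed.
- Empty inputs error early (`compute_ani` on an empty query, zero reads in
  `composition`, empty profile in `summarize_strains`); "no evidence"
  cases return well-defined empties with warnings (no ANI results →
  `UNASSIGNED`, no reads on a marker → empty profile, empty interchange
  file → empty list).
- gANI is reported as missing (`NA`) when no fragment maps, and such
  results are excluded from aggregation; aggregation over zero defined
  members errors.
- All cross-reference and cross-variant orderings (assignment, read
  mapping, collapse, GCF numbering) end in lexicographic tie-breaks, so
  every stage is a deterministic function of its inputs and seed.

## 8. Known limitations

- The ANI placement is single-diagonal; true indels shift AF down rather
  than being aligned through. That is acceptable for the assignment rule
  but makes `compute_ani` unsuitable as a general-purpose aligner.
- `min_strains` is a lower bound; strains without discriminating sites in
  any single window are invisible, and phasing across windows is not
  attempted.
- The synteny-weighted score is a stand-in; absolute score values are not
  comparable with the original multi-gene comparison tool, only their
  ordering behaviour is analogous.
- GCF = connected component can chain distinct families through
  intermediate members in principle; on the divergences tested this does
  not occur, but dense real datasets may warrant reviewing exported edge
  weights before interpreting a large component as one family.
- The collapse first-fit merge is exact for complementary fragments and
  conservative otherwise; adversarial overlapping fragmentations could
  over-count, never under-count, unique clusters.
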