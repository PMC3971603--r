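---
title: "Methods: de novo OTU assembly for protein-coding barcodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: de novo OTU assembly for protein-coding barcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Microbial community profiling with protein-coding barcodes (such as the
cpn60 universal target) amplifies a standardized gene region with
broad-range primers and sequences the amplicon pool. The raw reads must be
aggregated into operational taxonomic units (OTUs) before any ecological
interpretation. `otuforge` takes the *de novo assembly* route: OTUs are
consensus sequences assembled from the reads themselves, with no reference
database in the loop, so novel organisms form OTUs just as readily as
well-known ones. Reference sets enter only optionally — for chimera
screening, reading-frame identification and quality evaluation.

The package implements the full chain: primer trimming, assembly (two
engines), read-to-OTU abundance by mapping, split-end chimera screening,
collapse of nucleotide OTUs to non-redundant peptide OTUs, rarefaction,
quality metrics, and exports for downstream ecology tools — plus a seeded
synthetic-community simulator that provides per-read ground truth, so the
whole pipeline can be validated end-to-end in software alone.

# Primer removal, twice

PCR primers are removed at two points. Before assembly, `trim_primers()`
searches each read terminus (anchored, primer length + 3 bases of slack —
amplicon primers sit at read ends, and a global scan would create false
internal trims) allowing 2 mismatches, with IUPAC degeneracies honoured
and reads shorter than 50 bases after trimming discarded (below that, a
100 bp overlap is impossible). After assembly, `sweep_otu_primers()` runs
the same anchored search over the OTU consensus ends with a wider
allowance (4 mismatches): roughly one read in several thousand carries
three or more errors inside its primer copy, escapes the read-level pass,
and would otherwise extend its contig with a low-depth primer overhang
that frameshifts the translation. Sweeping assembled sequences as well as
reads is the classic primer/vector-cleaner practice.

# The two assembly engines

## Greedy overlap-layout-consensus (OLC)

`olc_assemble()` detects pairwise read overlaps — dovetail or containment,
on either strand — and merges reads greedily in decreasing score order
(score = overlap length × percent identity; ties broken lexicographically
by read-id pair). Overlap detection is gapless (offset-based): the
simulator's default error model is substitution-only, 454-style
homopolymer errors are out of scope, and a gapless scan admits an exact
brute-force oracle over all offsets, which the tests exploit. The two
governing parameters are the ones practitioners actually sweep:

* `min_overlap_len` (bases, default 100) — the recommended minimum for
  ~550 bp barcode amplicons; raising it makes assembly stricter and
  strands more reads.
* `min_overlap_identity` (percent, default 90).

Consensus is a per-column weighted majority vote (quality-weighted when
qualities are present, read-count otherwise), with ties resolved to the
lexicographically smallest base for bit-reproducibility. Every read is
tracked to exactly one OTU or listed unassembled; contigs with fewer than
`min_reads_per_otu` (default 2) reads are dissolved — a single read is not
a consensus.

**The haplotype-conflict merge guard.** Two community members can be 96%
identical while being distinct organisms; read-level overlaps between them
pass a 90% identity threshold, so naive greedy merging would collapse
them. Before committing any merge — read into contig or contig into
contig — the assembler compares the two sides' majority calls over the
implied overlap and counts disagreeing columns. The merge is vetoed when
disagreements exceed `max(max_merge_conflicts, merge_conflict_rate ×
overlap length)` (defaults: floor 1, rate 0.02). The rate threshold sits
between the sequencing-error scale (~0.5% of columns disagree when a
noisy read meets its own template's consensus) and the divergence of the
closest distinct templates the overlap-identity threshold admits (4–10%),
so error variation is absorbed while near-identical members stay
separate. The guard applies equally to single reads, which is what stops
a rare member's reads from being absorbed one-by-one into its
96%-identical partner's deeper contig; the occasional read it rejects
outright ends up unassembled, visible in the tracking table.

## De Bruijn graph (DBG)

`dbg_assemble()` builds a canonical k-mer graph (a k-mer and its reverse
complement are one node) and emits maximal unbranched paths after the
usual cleaning: k-mers below `min_kmer_count` (default 2) dropped,
dead-end tips shorter than `tip_max_len` (default `2k`) clipped, and
simple two-path bubbles whose branches align at `bubble_pop_identity`
percent or better (default 98) popped in favour of the higher-coverage
branch. With k = 31 a single-SNP bubble spans 61 columns (98.4% identity),
so sequencing-error bubbles pop at the default while more divergent
parallel paths survive.

Read tracking is deliberately absent from this engine: distilling reads
into k-mers forfeits the read-to-contig relation, which is precisely why
the mapping module exists. On communities whose members share long
identical stretches (common at 90%+ pairwise identity) a pure unitig graph
fragments into shared and member-specific pieces rather than full-length
members; resolving such paths needs read-path threading, which is out of
scope. The package treats DBG under-resolution as a property to
demonstrate — the test suite asserts the *trend* (more truth-matched
contigs as k grows from 10 to 31, never more members than OLC resolves),
not a specific count.

# Read mapping and abundance

`map_reads()` aligns every read end-to-end against every OTU on both
strands with an exact affine semi-global dynamic program (match +1,
mismatch −1, gap open −2, gap extend −1; OTU ends free). The best hit is
chosen by maximal identity, then maximal aligned columns, then smallest
OTU id with '+' before '−' — a fully deterministic tie-break, with ties
counted in the output so ambiguous placements can be audited. A read is
unmapped when its best identity falls below `min_identity` (default 90) or
its aligned columns below `min_aligned_len` (default 50).

For large instances the mapper first runs a k-mer seeded gapless prescreen
(16-mers, stride 8) to shortlist candidate (OTU, strand) pairs; every
candidate within 5 identity points of the best prescreen hit receives the
full dynamic program, and reads with no adequate seed fall back to the
exhaustive scan. Small instances always take the exhaustive path. The
shortlist is a performance device, not a semantic one: the test suite
asserts agreement between the seeded and exhaustive paths on simulated
data, and agreement of the exhaustive path with an independent full-DP
oracle on random instances.

`count_abundance()` tabulates assignments into an OTU × library matrix and
maintains the conservation invariant — per library, column sum plus
unmapped equals the input read count — which every later stage
(chimera removal, dereplication, peptide collapse) preserves.
`downsample_abundance()` rarefies every library's mapped profile, without
replacement, to the smallest library's depth under a caller-supplied seed.

# Chimera screening (split-end test)

PCR chimeras join segments of two parent templates. `c3_classify()`
extracts the first and last 150 bases (`end_len`) of each OTU and finds
each end's best-matching reference set by local alignment. Non-chimeric
verdicts require a shared reference carrying both ends on the same strand
with the 5′ end strictly upstream of the 3′ end — the package's
operationalization of "matching in the expected orientations", which the
method's description leaves informal. Three deliberate design points:

* Ties at an end's best score are kept as a *set*, and chimerism requires
  the two sets to be disjoint; near-identical reference entries (common in
  non-redundant barcode collections) therefore cannot trigger false
  chimera calls.
* An end with no match at `min_end_identity` (default 60, the low end of
  the validation community's identity envelope) makes the verdict
  *indeterminate*, never chimeric: novelty is not evidence of chimerism,
  and the screen is skippable outright (`skip_chimera`) for communities
  poorly represented in any reference.
* Removal moves the chimeric OTU's reads to the unmapped tally rather
  than remapping them, keeping conservation exact.

# Reference identity screening

`watered_blast_identity()` is the two-stage search used wherever a
sequence is compared against a reference set: candidates are short-listed
by shared 8-mer count (top 20), then scored by exact Smith–Waterman local
alignment on both strands. Candidates are ranked by the optimal alignment
*score*, and the reported identity is computed over that alignment's
columns. Ranking by raw identity would be degenerate — any unrelated
reference sharing one short exact word attains a "100%" local alignment a
few bases long — so score ranks and identity reports. Ties at the maximal
score are returned as a set.

# Translation and peptide OTUs

Protein-coding barcodes carry signal at two levels; the pipeline emits
both. Nucleotide OTUs are first dereplicated at 100% identity
(byte-identical, reverse-complement identical, or exact containment merged
into the longest representative, abundances summed). Each survivor's
reading frame is identified by scoring all six conceptual translations
against a protein reference with local BLOSUM62 alignment (gap open −11,
extend −1) — raw score with a floor of 50 rather than E-values, since OTU
sets are small and exhaustive scoring is deterministic; below the floor,
or with no reference, the frame containing the longest open reading frame
is used. Identical peptides are then collapsed into peptide OTUs whose
per-library abundance is the sum over member nucleotide OTUs. OTUs whose
best translation still contains an internal stop are frameshift artifacts;
they are excluded from peptide space by default (toggleable) and reported,
with the excluded counts moved to unmapped so totals reconcile. In the
validation community this stage is what merges the synonymous pair: 20
nucleotide OTUs, 19 peptide OTUs.

# The synthetic community simulator

`generate_community()` emulates the structure of the cpn60 validation
community: `n = 20` coding sequences of 552 bp whose pairwise nucleotide
identities span 60–96%, with the top pair differing only by synonymous
third-position substitutions so its peptides are identical. Members are
derived from one random ancestor coding sequence by a ladder of
per-member substitution loads; the realized identity matrix is then
nudged site-by-site (never creating an in-frame stop) until both ends of
the envelope are attained to within half a percentage point — the ±1
point tolerance in the contract acknowledges discreteness at finite
length. The synonymous twin is built by exactly
`round((1 − identity_max/100) · L)` third-position synonymous changes, so
the envelope maximum is attained by construction. With only two members a
single pair cannot attain both ends of a non-degenerate envelope; the
generator places it at the maximum.

`simulate_reads()` draws each read's member from the community's
proportions (default: a geometric series with ratio 0.85 — the validation
community's abundances are known to be uneven but unpublished, so this is
a stand-in, chosen once), takes the read from the 5′ or 3′ end of the
primer-flanked amplicon (fraction `frac_5prime`, default 0.5, mirroring a
two-ended amplicon sequencing design), and applies i.i.d. substitution
errors (default 0.5%). Read lengths are normal with mean 400 bp and sd
40 bp — the scale of later-generation 454 chemistry, chosen so that 5′ and
3′ reads of a ~550 bp target overlap well beyond the 100 bp minimum
overlap. Chimeric reads (optional, default off) join a prefix of one
member to the suffix of another at a uniform breakpoint in the central
half of the template, guaranteeing both 150 bp ends fall on different
parents. Indels are supported but off by default; flowgram/homopolymer
error structure is not modelled. Qualities are a constant Phred 30.

What passing tests on these simulations do *not* show: robustness to
homopolymer indels, chimera rates interacting with assembly (chimeric
reads are simulated but the validation runs use rate 0, as in a clean
template mixture), PCR amplification bias, or contaminating off-target
sequence. The simulator's ground truth labels every read with its source
member, which is what makes exact sensitivity/specificity and
compositional-error computations possible.

# Evaluation metrics

* **Per-OTU sensitivity/specificity** (`otu_sn_sp()`): with target `t` =
  the OTU's nearest reference, sensitivity = fraction of `t`'s reads
  captured by the OTU, specificity = fraction of the OTU's reads truly
  from `t`; zero denominators yield flagged `NA`s, never errors.
* **Compositional error** (`compare_profiles()`): the figure-of-merit
  "total error" of an assembly is not formally defined in the method
  literature this package follows; the implemented, normative metric here
  is the total variation distance `0.5 · Σ|p̂ − p|` between the
  mapped-read member profile and the realized truth profile — the
  standard bounded-[0, 1] compositional error. Members are credited as
  recovered when some OTU's best reference hit includes them at ≥ 97%
  identity (the package's chosen threshold for "an expected OTU").
  The unmapped fraction is reported separately.

# Determinism

Every stochastic step takes an explicit integer seed (simulator,
down-sampling, pipeline configuration) and restores the caller's RNG
state. All tie-breaks — consensus bases, merge order, mapping, contig
ordering, canonical orientation (the lexicographically smaller strand) —
are specified deterministically, so `run_pipeline()` is a pure function of
(inputs, configuration, seed), which the manifest of md5 checksums it
returns makes checkable. One consequence of ancestor-derived communities:
all members share most terminal bases, so canonical orientation tends to
agree across an entire community; this is cosmetic.

# Problem sizes used in the validation suite

The packaged tests validate the full-scale experiment — 20 members,
552 bp, ~5,000 reads at 0.5% substitution error, five simulation seeds —
for member recovery and peptide collapse, and the parameter sweeps
(minimum overlap 100–350 bp; k = 10–31) on one fixed read set. Unit and
property tests use smaller communities (2–8 members, 300–450 bp, a few
hundred reads) where brute-force oracles are affordable; oracle
equivalence for overlap detection, mapping and reference screening runs on
hundreds of random small instances per engine. These sizes are the
package's chosen validation design.

# Known limitations

* The OLC engine's gapless overlap model is blind to indel errors; with
  `indel_rate > 0` in the simulator, overlap identities degrade and
  assembly quality falls off faster than a gapped assembler's would.
* The DBG engine does no read-path threading, so communities with long
  shared stretches fragment (see above); it also emits no isoform-like
  variants.
* The mapper is exact but quadratic per read-OTU pair; it is sized for
  amplicon problems (10²–10³ OTUs of ~10³ bases), not metagenome-scale
  references.
* Translation uses the standard genetic code only.
* SFF ingestion is out of scope; reads enter as FASTQ (or FASTA via the
  reference reader), converted upstream.
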