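---
title: "Methods: hybrid assembly of quadripartite plastomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid assembly of quadripartite plastomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cpkit)
```

This vignette is the package's own account of the models and procedures
it implements, the parameters that matter, the design choices made where
the design was genuinely open, and what the synthetic-data tests do and
do not demonstrate about real data.

## The problem

Plastomes are circular DNA molecules with a conserved quadripartite
layout — LSC · IRA · SSC · IRB, where IRB is a near-exact reverse
complement of IRA and each IR is tens of kilobases.  Two practical
consequences drive everything in this package:

1. **Rotation and strand are arbitrary.**  A circular assembly can start
   anywhere on either strand; assemblies are only comparable after a
   canonicalization convention.
2. **The IRs break assemblers.**  Short-read assemblers emit a single
   copy of the repeat (the graph collapses), and long-read assemblers
   tend to break contigs at the repeat boundaries, leaving terminal
   redundancies.

The package implements the computational stages that repair both
failure modes: merging/circularizing long-read draft contigs, polishing
the circle with accurate short reads, and reference-guided scaffolding
that restores the second IR copy from a collapsed short-read assembly —
plus the up-front read extraction, the structure/census reporting, and
small phylogeny utilities used when comparing the resulting genomes.

## Read classification

A WGS read is classified from its alignments to a panel of reference cp
genomes (the alignments are inputs, in a 12-column PAF-style table; the
identity of a record is $I = M/L$ with $M$ exact-match bases and $L$ the
span on the reference).  For long reads, records with less than
`min_record_query_bp` (500 bp) aligned are discarded and the remaining
*query intervals are unioned* before totaling, so overlapping records —
common when a read spans an IR present in every panel genome — are
counted once.  The read is accepted iff the union is at least
`min_total_query_bp` (1 kb) *and* `min_query_fraction` (80 %) of the
read length.  For short reads, each mate of a pair must carry one block
of at least `pair_min_block_bp` (100 bp).  Strand is ignored; alignments
to different panel genomes count toward the same union.

Short-read quality trimming enforces the rule "every base ≥ Phred
`trim_min_quality` (20), read length ≥ `trim_min_length` (100)": ends
are trimmed first, then the read is cut at the first failing internal
base keeping the longer fragment (left fragment on ties), iterating
until clean.  The iteration is our pinning of an under-specified rule:
a single cut can leave failing bases behind, which would contradict the
per-base guarantee the thresholds express.

Raising any threshold can only shrink the accepted set; the test suite
asserts this monotonicity and checks every decision against an
independent brute-force evaluation of the written rules.

## Overlap detection, merging, circularization

All overlap machinery shares one primitive: exact k-mer anchoring on a
diagonal (candidate offsets voted by shared k-mers), followed by
verification.  Suffix–prefix overlaps between contigs are verified by
edit distance (`utils::adist`), so indel-bearing candidates still score
correctly; a candidate overlap of length $L$ is accepted when
$1 - d_\mathrm{edit}/L \ge$ `min_identity` (0.95) and
$L \ge$ `min_overlap_bp` (500).  Merging walks the overlap graph
greedily by descending overlap length (ties broken lexicographically) —
exact in practice for the handful of contigs a plastome yields, and
auditable.  Contigs contained in another contig are dropped as
redundancy.  An edge that would close a cycle is skipped and reported:
a circular genome's contig chain necessarily suggests a cycle, and the
skipped (weakest) junction reappears as the terminal redundancy that
`circularize()` trims.  Where overlap identities are below 1, overlap
bases are taken from the longer contig; the polisher is the error-fixing
stage, so the merger stays simple and deterministic.

`circularize()` finds the longest prefix/suffix self-match (same
anchoring + verification), trims the suffix copy, and marks the sequence
circular.  A terminal overlap longer than half the contig is refused as
degenerate (a tandem artifact rather than a circle).  Verification by
edit distance is only attempted for candidates up to half the contig
length; longer candidates are recognized by their k-mer support alone,
which keeps the degenerate check from costing quadratic time.

## Polishing

The polisher is a plurality-with-threshold pileup consensus — the
contract (fix SNPs and small indels using accurate short reads), not a
reimplementation of any specific tool's evidence model.  Reads are
aligned by the built-in aligner:

* verbatim occurrences on either strand are found by exact multi-pattern
  matching against the doubled sequence (circular coordinates, so reads
  wrap the origin);
* every additional k-mer-seeded candidate location is reconstructed as
  either a gapless alignment or a single-indel alignment (gap size up to
  `max_indel_bp`, split position chosen to maximize matches with ties
  broken leftmost, so indels are left-normalized and their evidence
  piles onto the same columns);
* candidates neither model explains fall back to a banded
  `Biostrings::pairwiseAlignment`, and are dropped unless they align
  nearly full length.

Placing reads at *all* near-exact locations is deliberate and matters in
the IRs: a read drawn from one repeat copy that disagrees with the draft
would otherwise match the other copy exactly and carry its evidence
there, leaving draft errors inside a repeat systematically
uncorrectable.  With both placements reported, every read covering
either copy supports the true base at both, and the plurality rule
corrects the error.

Edits are called per column at depth ≥ `min_depth` (5) when the
plurality allele (a base, a spanning deletion, or an inserted string)
differs from the draft with support ≥ `min_support_fraction` (0.7; a
column exactly at the threshold is accepted).  Adjacent deletion columns
merge into one multi-base deletion; indels longer than `max_indel_bp`
(10) are ignored.  Edits apply in descending position order, and
polishing iterates (default one round; the round loop stops at the first
edit-free round), so a partially corrected indel converges.

## Reference-guided scaffolding with IR restoration

Contigs are anchored on a canonical reference by shared-k-mer diagonals
with mismatch-tolerant extension (substitution-only, which matches the
fragment sources the stage is built for), keeping every placement with
span ≥ `min_anchor_bp` (500) and identity ≥ `min_identity` (0.95).  A
contig from inside the IR anchors at both copies on opposite strands; a
contig overlapping the IR partially yields a partial placement covering
just the homologous segment.  Selection is greedy by
identity × aligned-length, accepting any placement that covers enough
still-uncovered reference — which is exactly how a single collapsed IR
contig ends up instantiated at both repeats, the second time
reverse-complemented.  A contig placed twice with essentially the same
query interval (Jaccard ≥ 0.8) is only tolerated when both placements
lie ≥ 80 % inside the IR intervals; that span-fraction rule makes
"IR-homologous" testable.

Joins between neighbours come from reference coordinates: positive
differences are suffix–prefix overlaps (verified before bases are
emitted once), negative ones are gaps filled with N at the
reference-estimated size — the transparent choice, and visible in the
output.  The layout is complete when every reference base is covered or
inside a gap ≤ `max_gap_bp` (5000); incomplete layouts are an error
listing the uncovered intervals, never a silently truncated genome.

## Structure detection and canonicalization

The detector seeds shared k-mers between the doubled genome and its
reverse complement, clusters them by diagonal, and extends each seeded
run outward.  Two numerical choices deserve note:

* In any quadripartite genome the two IR hit-runs fall on the *same*
  diagonal (the IRA·SSC·IRB segment is palindromic about the SSC
  midpoint), so runs separated by more than 100 bp are seeded
  separately, and a seed whose overall mismatch rate exceeds the
  tolerance is restarted from its longest clean stretch.  Without this,
  a small SSC would bridge the two runs into one bogus candidate.
* Extension across a mismatch is only accepted when a 20-base lookahead
  window keeps at least 15 matches and the running mismatch rate stays
  within `max_mismatch_rate` (0.01); boundaries are then trimmed to the
  outermost matching base.  A pure running-rate rule would walk far into
  random flanking sequence, because one chance match (probability 1/4
  per base) resets the trailing trim while the global rate stays low.

The highest-scoring disjoint, oppositely oriented pair ≥ `min_ir_bp`
(1000) defines the repeats; the larger single-copy arc is the LSC, and
IRA is *defined* as the IR copy immediately following the LSC — a
positional convention, since the genome itself does not name its
copies.  `canonicalize()` rotates the genome to start at the LSC and, of
the two strand choices, emits the lexicographically smaller sequence: a
deterministic, data-free orientation rule (homology to a published
genome would require external data).  The canonical sequence is still
flagged circular — canonicalization fixes rotation and strand, it does
not linearize the molecule — so structure detection composes with it.
Unequal IR lengths are possible (extension is maximal independently at
each boundary) and the asymmetric trailing bases are assigned to the
single-copy neighbours; `ir_mismatches` records the substitution
differences between IRA and the reverse complement of IRB along the
detection diagonal.

Region GC excludes N from the denominator so gap fill does not dilute
composition; the IR figure is reported for both copies concatenated
(the conventional single figure) alongside the per-copy values.

## Annotation census and phylogeny utilities

The census consumes an annotation table (gene, functional system, copy
count — annotation *generation* is out of scope) and tallies copies per
system plus the copy-number spectrum; its invariants
(`copies = n1 + 2·n2 + 3·n3`, `distinct = n1 + n2 + n3`) are asserted in
tests.  rRNA and tRNA gene counts are annotated separately and added by
`gene_totals()`.

`p_distance()` counts substitutions per comparable column (both symbols
in A/C/G/T; gaps and N excluded from numerator and denominator).
`collapse_short_branches()` contracts internal branches strictly shorter
than the threshold (default 2×10⁻⁴ substitutions/bp; "shorter than"
means strict, so a boundary-length branch survives and threshold 0 is
the identity); leaf branches are never contracted, so the leaf set is
preserved.  `clade_report()` finds the maximal clades whose branches are
all below the threshold.  By default *terminal branches count too*: the
clades this summarizes are groups of near-identical samples, whose
terminal branches are short by definition, and under an internal-only
reading any two-leaf cherry would qualify trivially no matter how long
its terminal branches.  The internal-only reading remains available via
`all_branches = FALSE`.

## The synthetic-data module

The generators define the study conditions for every test.  The default
toy genome is a faithful scale-down of a sweetpotato-type plastome —
LSC 20 kb, IRs 6 kb, SSC 3 kb (real: ≈87/31/12 kb) — with region GC
targets 0.3614/0.4057/0.3220 taken from the real genome's reported
composition, and exact IRs unless a divergence count is requested.  Two
generator details exist to keep truth and detection coherent:

* the single-copy bases flanking each IR boundary are constrained so the
  repeats are *maximal exactly at the generated boundaries* (otherwise a
  chance match would legitimately extend the maximal repeat and the
  recorded truth would be wrong);
* requested IR divergence sites are kept 30 bp clear of the repeat edges
  (an edge substitution would shorten the maximal repeat and silently
  change the truth intervals).

Long reads default to 30× coverage, 3 kb mean length, and indel-biased
errors (insertion + deletion rates exceeding substitutions, mirroring
nanopore-style data); short pairs default to 30×, 150 bp reads, 400 ±
40 bp inserts, constant Phred 40 with an optional 3'-decay model for
exercising the trimmer.  The draft-contig generator reproduces the
IR-boundary break pattern with a terminal redundancy at each junction
(default 2 kb on the toy scale, emulating the ~20 kb redundancy seen at
full scale); the collapsed-contig generator deletes IRB and fragments
the rest at seeded positions (kept 800 bp from the IR boundaries and
600 bp apart, so every fragment remains anchorable), with 50 bp terminal
overlaps.  Background "nuclear" reads in the WGS mixture come from a
random genome: the classifier contract concerns the alignment rules, not
biological homology edge cases.

What passing these tests shows — and does not.  The round trips
demonstrate that the pipeline logic is lossless under its stated
assumptions: error-free contig sequence for the exactness claims,
substitution-only noise for the tolerance claims, uniform read sampling,
no chimeric reads, a single organelle.  Real data adds homopolymer
errors, coverage bias, nuclear insertions of plastid DNA and
mitochondrial cross-homology, none of which the generators model; on
real data the stages still apply but exactness becomes a best case, not
a guarantee.

## Problem sizes and determinism

The test suite and the acceptance script use the 35 kb toy genome for
the two end-to-end round trips (five seeds each), a 5.6 kb genome for
the 20-seed polisher recovery study (20 SNPs + 5 indels of 1–3 bp at
30×), 2.8 kb genomes for the exhaustive inverted-repeat oracle and the
100-transformation canonicalization invariance check, and 50-read
batches for classifier/oracle agreement — sizes chosen so each property
is measured across many seeds in seconds on a laptop.  Every generator
is a pure function of its spec and seed (`withr::with_seed`), so all
outputs are byte-identical per seed; every pipeline stage is
deterministic given its inputs.

## Known limitations

* The scaffolder's anchoring is substitution-tolerant but not
  indel-tolerant; contigs with indel errors against the reference will
  anchor in pieces.  (The merger and polisher are indel-aware.)
* The polisher assumes isolated edits; two indels closer together than a
  read length fall back to the banded aligner, and dense error clusters
  may not resolve in one round.
* Classification consumes alignments; it does not produce them (any
  mapper's output converted to the PAF-style table works), and
  multi-mapping flags are not modelled — the table is taken at face
  value.
* Only the census of an annotation table is computed; gene annotation
  and multiple sequence alignment are inputs from external tools, as is
  maximum-likelihood tree inference.
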