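---
title: "Methods: split-read CNV breakpoints and mechanism classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: split-read CNV breakpoints and mechanism classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

cnvbreak detects copy-number variants (CNVs) — deletions, insertions and
tandem duplications of at least 25 bp — at single-nucleotide breakpoint
resolution from long single-end shotgun reads, and then reads the mutational
mechanism off the junction sequence. The 25 bp floor is the conventional
lower limit separating CNVs from ordinary indels in compact insect genomes;
it is a parameter (`min_size`) everywhere it appears.

The mechanistic readout rests on four signals:

* **Breakpoint class.** Junctions are blunt (no shared sequence, no added
  bases), microhomology-bearing (>= 2 bp of identity between the event's
  interior and the adjacent exterior sequence), complex (untemplated bases
  at the junction), or complex with microhomology. Blunt ends are the
  classic non-homologous end-joining (NHEJ) outcome; short microhomology is
  compatible with microhomology-mediated end joining (MMEJ) and
  replication-based repair; very long identity (> 20 bp) is the scale at
  which single-strand annealing (SSA) becomes plausible.
* **Flank homology.** SSA and non-allelic homologous recombination (NAHR)
  leave high-identity repeats flanking the event. Two published filters are
  applied: >= 30 bp at >= 98% identity (SSA scale, "type I") and >= 200 bp
  at >= 95% (NAHR scale, "type II").
* **Insertion origin.** An insertion is a tandem duplication (a full-length
  nearby copy), a repeat expansion (phase-consistent extension of a 1-6 bp
  flanking tract), or filler DNA (no full-length source — the signature of
  untemplated synthesis during end joining). For filler, short (>= 7 bp)
  exact matches to the +/- 30-120 bp neighborhood, on both strands,
  quantify how much of the insertion could have been copied locally;
  coordinate-shuffled pseudo-insertions give the chance expectation.
* **Non-B DNA.** Z-DNA tracts, G-quadruplex motifs and inverted / mirror /
  direct repeats are predicted natively and their enrichment in 50 bp
  breakpoint windows (25 bp inside + 25 bp outside the CNV) is tested
  against 10x coordinate-shuffled controls with Fisher's exact test;
  225 bp spans (25 in + 200 out) feed positional histograms.

# Coordinates

All intervals are 1-based and closed, the R/Bioconductor convention, and
the package converts at format boundaries (BED is written 0-based
half-open). Insertions are zero-width events anchored at `start == end ==
pos`, the reference base immediately 5' of the insertion point. Junction
ambiguity (microhomology lets a breakpoint shift) is always resolved to the
leftmost representation, both in the caller and in the simulator's truth
ledger, so coordinates compare exactly.

# The split-read caller

Reads are anchored by exact k-mers (default `k = 20`) at their first and
last `k` bases, in both orientations, and extended inward with a greedy
gapless extension that accepts a mismatch only when the next 8 bases match
and the running mismatch count stays within `ceil(0.05 * length)`. The
look-ahead stops extension from bleeding through a breakpoint on lucky
isolated matches, which would otherwise blur exact junction coordinates;
isolated sequencing errors are still crossed. A read becomes:

* *concordant* — one full-length block (excluded from split analysis);
* *split* — two blocks separated by a reference gap (deletion; any
  unaligned read bases in between are junction-inserted bases), a read gap
  with contiguous reference (insertion), or blocks in flipped reference
  order (tandem duplication);
* *ambiguous* (tied best placements; logged and excluded) or *unmapped*.

Overlapping block reconciliation trims the left block, which together with
maximal backward extension of the right block yields the leftmost junction.
Insertions are only detectable when contained in a read with both anchors
in flanking sequence — an intrinsic limit of split-read calling, not an
enforced rule; with 105 bp reads the practical ceiling is roughly 60 bp.

Calls then pass a conservative filter chain: >= 2 distinct supporting reads;
not all supports sharing one alignment start (the PCR-duplicate rule:
duplicates share an exact start and may vary at the end); junctions >= 10 bp
from every supporting read's ends; breakpoints inside the euchromatin mask;
and < 80% of the affected sequence covered by TE annotation (TE
polymorphisms are a separate mutational process). Every discarded group is
logged with its failing filter. Alignments are also importable/exportable
as 21-column PSL so an external gapped aligner can stand in for the native
mapper.

# Microhomology geometries and the 2 bp rule

For a deletion of segment S with 5' flank P and 3' flank F:

* type I (mechanistically capable): `max(lcp(S, F), lcs(S, P))` — one copy
  of the shared stretch lies inside the event, one outside;
* type II (chance control): the longest k with the k bases entering the
  junction equal to the k bases leaving it (`suffix_k(P) == prefix_k(F)`);
* type III (chance control): the longest k with `prefix_k(S) ==
  suffix_k(P)`, a geometry that cannot mediate the event.

Insertions use the inserted sequence as S. The controls calibrate how much
identity arises by chance at a junction: `microhomology_excess_test()`
counts, for each k, junctions with type I >= k against the pooled controls
and applies a two-proportion test (type I on n junctions vs controls on
2n), returning the smallest significant k. The 2 bp minimum used by
`classify_breakpoint()` reflects that calibration logic; both the minimum
and the 20 bp long-identity threshold are arguments. The type II/III
schematics admit more than one reading; these definitions are this
package's declared interpretation and are isolated in one function so they
can be swapped.

Identity is measured as max(prefix, suffix) match, not a sum: a junction
shifted through k ambiguous bases has microhomology k, matching standard
breakpoint-ambiguity usage. Events at chromosome edges are measured over
the available flank and flagged.

# Polarization

Calls are polarized against an outgroup genome under parsimony. The region
is located by an exact junction-adjacent 20-mer (with a mismatch-tolerant
and 3'-side fallback); both allele probes — reference allele with the
segment, derived allele without it (plus any junction-inserted bases) — are
aligned to the outgroup window (`Biostrings::pairwiseAlignment`,
global-local) and the higher percent identity decides. Quality gates:
best identity >= 70% and an identity margin >= 0.5 between alleles,
otherwise UNPOLARIZED. The probe window is 500 bp per side; smaller events
give smaller identity margins between the probes (roughly size / (2 x 500 +
size)), which is why the margin threshold is kept well below the ~2.4%
margin of the smallest (25 bp) events. Insertion calls mirror the deletion
states (INSERTION_IN_STRAIN / DELETION_IN_REFERENCE); a five-state enum
rather than three, so both call kinds polarize symmetrically.

# Recurrence and complexity

Calls are grouped by reference overlap (with 500 bp of slack). A region is
*recurrent* when it holds >= 2 distinct junctions across >= 2 strains —
independent overlapping mutations in different individuals. It is *complex*
when one strain carries >= 2 distinct junctions within 500 bp — the
footprint of a single multi-break event; the slack default covers the
82-325 bp junction spacings this phenomenon shows in flies.

# Homology scanning

`find_homology()` is ungapped: on every diagonal of the comparison matrix
it finds the longest window with identity >= the threshold (exact, by
integer prefix-sum search), reporting matches / columns as identity. The
published filters are substitution-dominated at these scales (30 bp / 98%
allows no mismatch until 50 bp; 200 bp / 95% allows scattered
substitutions), and the simulator implants substitution-mutated repeats, so
an affine-gap engine would add machinery without changing any tested
quantity; this trade-off is deliberate and documented here. Hits wholly
explained by the two pieces covering the same genomic positions (imprecise
mode lets flanks overlap the CNV) are removed as self-hits; a k-mer-based
low-complexity score annotates repetitive hits but never filters them.

Flank extraction: precise mode takes 200 bp per side; imprecise
(array-style) mode reaches 500 bp outward and 25% of the CNV length inward
past each nominal breakpoint. Note a geometric consequence verified in the
tests: a 250 bp repeat pair can only produce a 200 bp aligned run when the
flanks are wide enough to hold both copies, i.e. in imprecise mode.

# Non-B DNA detectors

Perfect-arm definitions keep every detector exactly decidable against
brute-force enumeration, which the tests exploit (each detector is compared
with an independent oracle on randomly generated sequences, with planted
exemplars to guarantee non-trivial cases):

| class | definition | default minima |
|---|---|---|
| ZDNA | alternating purine/pyrimidine steps from {GC, CG, GT, TG, AC, CA} | tract >= 10 bp |
| G4 | four G-runs >= 3 with loops of 1-7 bp, either strand | — |
| INVERTED_REPEAT | perfect arms, reverse-complement | arm >= 10, spacer <= 8 |
| MIRROR_REPEAT | perfect arms, reversed | arm >= 10, spacer <= 8 |
| DIRECT_REPEAT | perfect unit repeated | unit >= 10, spacer <= 8 |

Overlapping candidates of a class (per strand for G4) merge into maximal
intervals. These thresholds follow common non-B database conventions; none
is asserted as canonical, all live in `nonb_config()`, and the tests pin
the defaults. A-phased and short tandem repeats are omitted; the class enum
is extensible. Ambiguous bases are masked with pseudo-random sentinel
letters (deterministic) so runs of ambiguity can never align into a motif.

# The synthetic-data generator

The generator is the package's ground truth. Defaults mirror the study
design it emulates: nine strains, 105 bp mean reads (length from a normal,
sd 15, truncated to [50, 2 x mean]; the source technology's mean read size
is the only published figure, so the spread is a declared choice), ~0.2x
per-strain coverage when emulating sparse data, uniform read starts, both
strands, substitution errors at a configurable rate (no homopolymer error
model). Chromosomes are i.i.d. bases at a requested GC (0.42 as the
fly-like default); euchromatin masks exclude configurable chromosome ends;
TE annotation is interval-only.

Implanted signatures are written into the reference so that every signature
is verifiable from sequence alone: forced microhomology copies the k bases
following the deletion onto the segment start (and breaks the k+1
extension); blunt events force zero type-I identity; junction-extra bases
are forced unabsorbable into either flank (first extra base differs from
the segment's first base, last from its last — the minimal constraints that
keep the junction representation unique); filler insertions are verified
absent from the reference at full length by exhaustive search; NAHR-style
events write a repeat pair at the stated length and identity around the
deletion; repeat expansions write a two-unit tract adjacent to the
insertion. Implant sites are >= 1 kb apart and clear of mask edges. The
truth ledger stores left-aligned coordinates, and generation is
byte-reproducible from its seeds.

Because real genomes carry a non-B motif background that i.i.d. sequence
lacks almost entirely, `generate_genome(nonb_per_kb = ...)` can plant
exemplar motifs at a chosen density; around 0.8/kb reproduces the few-percent
motif-positive rate per short window that real euchromatin shows, and is
used in the enrichment-calibration simulations.

The outgroup derives from the reference with a `share` fraction of events
carrying the derived allele and substitutions applied at the requested
divergence outside 20 bp junction-adjacent guard zones — so polarization
failures reflect logic, not simulated noise; divergence sensitivity can be
probed separately by corrupting the outgroup.

What passing these simulations does *not* show: tolerance to real 454
homopolymer indel errors, TE-family sequence confusion, heterozygosity
(strains are haploid inbred lines here), or reference bias in diverged
regions. The generator's reads are uniform; real libraries are not.

# Problem sizes in the checks

The acceptance-level checks run at sizes chosen to make their statistics
meaningful while staying desk-scale: a 320-event deletion cohort (class mix
35/41/22/2%, sizes log-uniform 25-500 bp, nine strains, 10x pooled
error-free coverage) for recovery and class-frequency checks; a 60-event
insertion cohort with 1.2 kb error-free reads so that insertions up to
500 bp fit within reads (read length is the binding constraint on insertion
recovery, and the mean read length is a free simulation parameter); 1000
random instances per oracle-equivalence suite; 200 replicates of ~450
breakpoint regions with 10x controls for null calibration on a 20 Mb
motif-bearing genome — large enough that sampled regions essentially never
overlap, since overlapping regions share sequence and would violate the
exact test's independence assumption by construction, a crowding artifact
rather than a property of the method; 100 replicates of the 447-region /
4470-control planted-enrichment configuration for power; and 400 deletions
with a 2.5% NAHR-flanked fraction plus 1000 blunt events for the
homology-scan recovery and false-positive checks.

# Known limitations

* The native mapper handles at most one large gap per read and keeps only
  unique-best alignments (ties are logged, not rescued); multi-mapping
  reads in repeat-rich genomes therefore reduce support rather than create
  calls. PSL import exists precisely so a heavier aligner can be swapped in.
* Insertions longer than the reads are invisible; tandem duplications
  shorter than the reads surface as insertions of the duplicated segment
  (the two descriptions are sequence-equivalent; the caller reports the
  insertion form).
* `find_homology()` does not model indels inside homology tracts.
* Mechanism labels are evidence classes, not pathway assignments: blunt vs
  microhomology vs complex constrains, but does not uniquely identify,
  NHEJ / MMEJ / replication-based repair.
* Fisher's exact test is conservative at small counts; the enrichment
  machinery reports full 2x2 tables so users can choose their own test.

# A worked call, end to end

```{r, eval = FALSE}
library(cnvbreak)
g0 <- generate_genome(1, 60000, gc = 0.45, seed = 7)
imp <- implant_cnvs(g0, list(cnv_spec("deletion", 40, sig_microhomology(5))),
                    strains = paste0("s", 1:3), seed = 2)
reads <- simulate_reads(imp$strains, coverage = 12, seed = 3)
al <- map_reads(reads, imp$reference)
sig <- detect_split_signatures(al, 25, reads = reads)
calls <- cluster_and_filter(sig, imp$reference)
measure_microhomology(calls[1, ], imp$reference)$type_I  # 5, as implanted
```
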