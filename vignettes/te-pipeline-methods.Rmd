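---
title: "Methods: repeat discovery, characterization and the planted-truth benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat discovery, characterization and the planted-truth benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the model
behind each stage, the tunable parameters and why their defaults are what
they are, the numerical decisions taken where the design was genuinely
open, what the synthetic benchmark does and does not demonstrate, and the
known limitations.

## The discovery model

Dispersed TE families reveal themselves as off-diagonal local alignments
in a genome self-comparison. `selfAlignGenome()` delegates the raw local
alignment to BLAST+ megablast (the package treats the aligner as an
engine behind a fixed hit contract; any tool producing query/subject
footprints with identity and score can be adapted) and then applies the
pipeline's semantics:

* hits must exceed **94% identity** with both footprints **≥ 400 nt** —
  the classic setting for recovering intact, recently active copies while
  ignoring ancient rubble;
* the trivial self-diagonal is removed (same scaffold, footprints
  overlapping more than half the shorter);
* each alignment is kept once, as a canonical unordered pair.

Footprints are condensed into *piles* by transitive interval union
(`GenomicRanges::reduce`). A pile whose footprint is covered > 80% by
hits that begin and end inside the same pile is flagged *tandem* — that
is the signature of a satellite/tandem array, a repeat class this
pipeline deliberately does not annotate — and excluded from family
calling. The 0.8 coverage fraction is a declared default: intra-element
LTR-to-LTR hits also land inside one pile but cover only a small fraction
of it, so genuine LTR elements do not trip the flag.

Families are connected components over piles, with an edge when some
hit's two footprints each cover ≥ 90% ("globally alignable" copies, the
`covFrac` parameter) of their piles, subject to ≥ 3 members, each
> 400 nt. The 0.90 linkage fraction mirrors the downstream 90/90
clustering; it is configurable because the upstream literature never
states its internal value. A consequence worth knowing: 5'-truncated
copies whose lengths differ by more than ~10% do not satisfy the mutual
coverage test against full-length copies, so heavily truncated copies are
left out of the family (they are "non-intact" in the discovery sense) —
family-level recovery relies on the untruncated copies.

## Clustering

`clusterSequences()` builds single-linkage clusters with an edge when the
best local alignment has identity > 0.90 over ≥ 0.90 of the **shorter**
sequence. The coverage denominator was the one genuinely open choice:
measuring on the shorter sequence lets fragments join the family of
their full-length relatives, which is the entire point of grouping
"sequences with different sizes" into one family. Components of size < 3
are reported as unclustered rather than forced into clusters.

`relaxedLinkPass()` re-compares cluster consensus sequences in six-frame
translated space (tblastx) at identity thresholds 0.35/0.50/0.75/0.90
over ≥ 50% of the shorter consensus. A single hit set is thresholded, so
the link sets are nested by construction. The top threshold is 0.90 by
default but exposed, since 0.95 is an equally defensible upper rung.

## Progressive alignment, consensus, centroid

`progressiveAlign()` is a longest-first progressive profile aligner: the
two longest members are aligned first and every further member is aligned
onto the running profile (profile–profile Gotoh in C++, column scores
weighted by base frequencies, `match = 100`, `mismatch = -100`,
`gapopen = -500`, `gapextend = -50`, *free terminal gaps*). Free terminal
gaps are the load-bearing choice: clusters routinely mix full-length
elements with 5'- or 3'-truncated copies, and a fragment must be able to
sit flush inside the profile without paying the very large opening
penalty at its ends. The `center` parameter is retained on
`AlignerParams` for interface parity with MUSCLE-style parameterizations
but the internal aligner places gaps by the affine model alone.
De-gapping any row always reproduces the input member exactly; a helper
`trimAlignmentEnds()` can clip ragged ends (> 80% gaps) for display, but
it is **off** in the pipeline because trimming removes residues and
breaks that round-trip.

`buildConsensus()` implements the majority rule per column over the
*spanning* rows: a row spans a column when its sequence has started and
not yet ended there, so terminal gap runs do not vote, while internal
gaps vote as deletion states (and drop the column when they win). Keeping
every column where a residue wins among spanning rows — no matter how few
rows span it — yields the longest possible consensus; positions spanned by
fewer than half of all rows are lowercased as low-confidence. Where no
residue exceeds 50% of the spanning rows the plurality base is emitted,
alphabetical on ties, always lowercase: the tie rule is a declared
decision (flagging low confidence by case rather than inventing IUPAC
output).

`selectCentroid()` maximizes the row sum of the all-to-all local
alignment score matrix (BLAST bitscores, symmetrized, or a user-supplied
matrix); ties break to the longest member, then the smallest id, making
the choice order-independent.

## Structural signatures

Inverted and direct repeats come from a BLAST self-comparison of each
sequence (minus-strand hits are inverted repeats, off-diagonal plus
hits direct repeats), with three layers of post-processing that are the
package's own:

* **Significance.** Fixed arm-length/identity floors cannot separate
  real short arms on sub-kilobase elements from chance matches on long
  sequences, so candidate arms are gated by the aligner's length-adaptive
  e-value (default ceiling `1e-3`). Two corrections apply. For
  *adjacent-arm (palindromic) hits* the aligner's e-value is
  systematically overconfident — the 2n columns of a self-reverse-
  complement alignment contain only n independent base pairs — so their
  significance is recomputed as a pair-based binomial expectation.
  Short *terminal* arms get a dedicated anchored scan: walking inward
  from the two sequence corners, scoring +1/-1 and stopping at the score
  maximum, removes the positional search space entirely, so a 15-nt arm
  with a substitution or two is significant on a 500-nt element while
  remaining undetectable-by-chance on random sequence (binomial bound
  ≤ 1e-4).
* **Endpoint refinement.** Local alignment trims diverged boundary
  positions, so detected endpoints stop short of the biological boundary.
  A paired outward walk (+1 match / -1 mismatch, endpoint at the farthest
  running maximum) recovers balanced mismatch tails; inward walks use
  strict improvement so they cannot wander into the interior on net-zero
  noise. The definitive length floor for direct repeats is applied after
  refinement.
* **Geometry.** Palindromic (arms near-contiguous, covering ≥ 80% of the
  sequence) takes precedence over terminal (arm 1 starting in the first
  10%, arm 2 ending in the last 10%), else subterminal. The "first
  10% / last 10%" reading is the only geometrically meaningful version of
  the terminal rule.

ORFs are stop-to-stop segments in all six frames with no start-codon
requirement — degenerate TE copies routinely lose their starts, and the
reported quantity is "the largest ORF", which stop-bounded segments
measure cleanly. PPT detection looks for the longest A/G run ≥ 8 nt
within 20 nt upstream of the 3' LTR; PBS detection for an exact
reverse-complement match ≥ 8 nt to the 3'-terminal 18 nt of a supplied
tRNA within 20 nt downstream of the 5' LTR. Those run/window constants
are declared defaults (the upstream tool chain never published its own)
and all configurable.

## Homology annotation and classification

`searchLibrary()` runs blastn / tblastx / blastx as the library molecule
dictates; a hit is *positive* for annotation exactly when its e-value is
below 1e-15 (strict). The 11-field best-match summary (e-value, best
match, score, extent, length, % identity, % match length, first residue
of match, first residue of sequence, number of segments, orientation)
follows the classic spreadsheet layout.

`classifyCluster()` is a first-match ladder: non-TE (only rRNA/host
positives) → class I LTR (direct-repeat pair, or LTR-diagnostic protein
sets Peptidase_A17/RVE, or a known-LTR hit) → class I non-LTR (RVT /
polyprotein / known-NLTR positives without direct repeats) → class II
(terminal IRs plus transposase or known-class-II hit) → MITE (TIRs
matching a known family's arms at ≥ 0.80 identity, consensus < 800 nt,
largest ORF < 300 nt) → MITE-like novel (TIRs or palindromic termini, no
positive TE hit, only small ORFs) → repeat without signature. One
deliberate refinement: reverse transcriptase alone is *not* LTR
evidence — both retrotransposon orders carry RT, and it is the
LTR-specific integrase/protease domains (or the direct repeats
themselves) that diagnose the LTR order; RT without direct repeats reads
as non-LTR. Every label carries an evidence list naming the features that
fired, and the activity indicators (identical within-element LTRs, large
domain-bearing ORF, expression-library hit) are reported as flags only —
activity is always "putative".

Element types use canonical coverage bands full ≥ 0.90 / fragment
[0.10, 0.90) / remnant < 0.10; the 0.90 band (rather than a literal
"100% match") absorbs alignment slop at element ends. Solo-LTRs are
consensus sequences matching a family's LTR arm at ≥ 0.80 identity over
≥ 0.80 of the arm while being no longer than 1.5 × the arm — a full
element fails the length test.

## Evolutionary statistics

`pDistance()` uses pairwise deletion of gap/N columns and reports the
population standard deviation over pairs. `neiGojobori()` implements
NG86 site counting with equal-pathway averaging (pathways through stop
codons excluded; mutations *to* stops counted as nonsynonymous; codon
pairs containing gaps, N, or stops excluded pairwise) and Jukes–Cantor
correction, averaged over all sequence pairs; the correction is flagged
undefined at p ≥ 3/4 and the ratio reported as NA when dS = 0. The
64 × 64 codon-pair tables are enumerated once per session and memoized.
The reading frame is taken from gap-free alignment blocks (the frame of
the cluster's longest ORF when projected cleanly). `tajimaD()` uses the
standard constants from the sample size, treats a site as segregating
when ≥ 2 unambiguous bases occur, and takes significance from the
beta-distribution approximation on the (Dmin, Dmax) support, two-sided at
0.05 — the approximation originally proposed alongside the statistic.

## The synthetic benchmark

`simulateGenome()` plants TE families with exact truth into i.i.d.
background sequence. The background choice matters: under an i.i.d.
model, chance 400-bp matches at 94% identity are effectively impossible,
so any discovery output is attributable to the planted copies. Element
templates mirror the structures the pipeline looks for: LTR elements are
`LTR – PBS – pol cassette (RT + integrase tags) – PPT – LTR`; non-LTR
elements carry an RT cassette and a poly-A tail and 5'-truncate with
geometric lengths (each copy truncated with probability 0.5, matching
the observation that real non-LTR clusters mix full-length and truncated
copies); class II elements are transposase cassettes between TIRs; MITEs
inherit the outer portion of a donor family's TIR around an unrelated
interior — the structure reported for real MITE/master-element pairs.
ORF cassettes are reverse-translated with random synonymous codons from
synthetic 60-aa protein tags bundled under `inst/extdata/protein_tags/`
(clearly labeled synthetic stand-ins for curated TE protein subsets).
The RT tag comes in two lineage variants — one embedded in LTR-style
cassettes, one in non-LTR-style — reflecting the real divergence of the
two RT lineages; without that distinction, reverse-translating a single
tag would leave the two orders ~75% identical at the nucleotide level,
an artifact real libraries do not show.

The default benchmark (`defaultBenchmarkSpecs()`) is 12 families in a
2-Mb genome at 1% per-copy substitution: three LTR families (one
planting half its copies as solo LTRs, with a 500-nt arm so solos clear
the 400-nt discovery floor), three truncating non-LTR families, three
TIR families and three MITEs riding the TIR families' arms — roughly
135 kb of planted repeat, a realistic density for a repeat-poor genome
slice. `runBenchmark()` runs the whole pipeline against libraries built
from the simulation's own ancestral elements and scores family recall /
precision, copy-level F1 (reciprocal-overlap ≥ 0.5 matching) and
classification accuracy (cluster (class, order) versus the label implied
by the majority planted family among its members).

**What passing does and does not show.** The benchmark exercises every
stage under controlled truth, but its background has no compositional
bias, no nested insertions, no segmental duplications and no
assembly artifacts; its families are island copies of a single ancestor
rather than nested bursts. Recall and accuracy on it bound the
pipeline's algorithmic behavior, not its performance on real
heterochromatin.

Parameter-recovery simulators validate the statistics end to end:
`simulateCodonEvolution()` evolves a star phylogeny with nonsynonymous
proposals thinned by ω (so the realized rate ratio is ω by
construction), and `simulateNeutralAlignment()` is a standard
infinite-sites coalescent. The shipped configurations — ω = 0.2 recovery
within ±0.05 over 50 replicates of 10 × 300 codons, and a mean neutral
D within ±0.15 of zero over 200 replicates at n = 10 — are sized to keep
the whole validation suite a few minutes on one CPU while holding the
Monte-Carlo error comfortably inside the stated bands.

## Degenerate inputs and tie-breaks (summary)

* Duplicate FASTA ids, gap characters in unaligned input, empty files:
  hard errors. Non-ACGTN residues normalize to N with a logged count;
  N never votes as a match anywhere.
* Singleton clusters: the aligner refuses them; the caller treats the
  single member as its own consensus.
* Consensus ties: plurality base, alphabetical, lowercased.
* Centroid ties: longest member, then smallest id.
* Tajima's D at S = 0: NaN with `significant = FALSE`. Nei–Gojobori at
  dS = 0: ratio NA with a reason string.
* All orderings (clusters, members, hit tables) are canonically sorted,
  so every stage is deterministic and order-independent; `emitDatabase()`
  output is byte-reproducible.

## Known limitations

* Tandem arrays, pseudo-satellites and terminal-repeat-only discovery
  modes are out of scope; tandem piles are flagged and dropped.
* Heavily 5'-truncated copies are excluded from dispersed families by the
  mutual-coverage rule (by design — they are recovered at the clustering
  stage only when within ~10% of another member's length).
* Helitrons and subclass-2 mechanisms are not structurally detected; a
  Helitron would classify only through a known-element library hit.
* E-values come from the BLAST+ engine (or explicit binomial bounds for
  the anchored/palindromic cases); they are decision thresholds here,
  not calibrated against any other engine's values.
* The dN/dS frame projection requires a reasonably gap-free alignment
  block; clusters of wildly different fragments may report no dN/dS.
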