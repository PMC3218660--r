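---
title: "Discovering fusion transcripts from paired-end RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering fusion transcripts from paired-end RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pefusion)
```

## The problem

A fusion transcript joins mRNA from two genes. Paired-end (PE) RNA-seq
detects them through *inter-transcript pairs*: fragments whose two sequenced
ends map to different genes. The difficulty is that many processes other
than a genuine fusion produce such pairs — misalignment between homologous
sequences, reads in repeats, random ligation of unrelated cDNA fragments
during library preparation, residual ribosomal RNA, and PCR
over-amplification of a single chimeric molecule. `pefusion` implements the
complete workflow: detect candidate gene pairs from aligned PE reads, remove
artifact classes with a cascade of seven filters, score the survivors with
supportive-pairs statistics, and resolve the exact junction sequence with a
tiled junction library. A seeded synthetic-data generator produces genomes,
annotations and labelled reads so every stage is testable without external
data.

## Composite gene models

All per-gene coordinate work happens on the *composite model*: the union of
the exonic intervals of all of a gene's isoforms. It is the finest
annotation-derived coordinate system in which an exonic genomic position has
a unique transcript-like offset without choosing an isoform. Internally all
intervals are 0-based and half-open; GTF input/output converts from the
1-based closed convention.

```{r composite}
exons <- tibble::tibble(
  gene_id = "g1", tx_id = c("t1", "t1", "t2"), chrom = "chr1", strand = "+",
  start = c(100L, 300L, 150L), end = c(200L, 400L, 350L)
)
composite_models(gene_models(exons))
```

Single ends are classified against the composite blocks as `exon` (fully
inside a block), `boundary` (straddling a block edge, e.g. retained introns
or pre-mRNA), `junction` (spliced alignment with every block exonic) or
`intron`. An end overlapping several genes is assigned to the gene with the
larger exonic overlap; an exact tie goes to the lexicographically smaller
gene identifier and is flagged, so the choice is deterministic and visible.

## Detection

`detect_candidates()` assigns every quality-passing, uniquely-mapped pair to
`intra` (both ends one gene — the normal transcriptome), `inter` (two genes
— a potential fusion supporter) or `unassigned` (an end unmapped or outside
any gene). Unmapped ends keep their sequence: the junction resolver aligns
them later. Candidates are keyed by *unordered* gene pair, because PE
connectivity alone cannot tell which partner is upstream; orientation is
resolved only at the junction stage.

## The filtration cascade

Seven filters address the artifact classes. The repeat filter works at read
level and runs first: supporters with an end overlapping a repeat interval
are pruned from every candidate. All remaining filters are candidate-level
predicates evaluated on that common pruned state, and a candidate is kept
iff every applicable filter keeps it; since the predicates do not modify
shared state, their order cannot change the kept set (the suite checks this
by permutation).

* **Paralogs** — a user-supplied unordered pair table (e.g. derived from an
  ortholog/paralog database) discards candidates whose partners are
  homologous at gene scale.
* **Small-scale similarity** — two steps. A fast step matches each
  supporting read end-to-end against the partner gene's composite sequence
  allowing up to 3 substitutions; a side hit-fraction above 1% discards.
  Survivors get a refined ungapped local-similarity search; a hit needs 75%
  of the read length matched, again with a 1% side-fraction threshold. The
  fractions are counted per gene side, the stricter of the two readings of
  a pooled threshold.
* **Repeats** — see above; a candidate left without supporters is discarded.
* **Abnormal insert size** — the library-preparation random-pairing filter,
  described below.
* **Ribosomal** — reads with 75% local similarity to a ribosomal library
  count as hits; a candidate with more than 10% hits is a likely rRNA
  contamination chimera compounded by misalignment.
* **Expression consistency** — chimeric signal (supporting ends per covered
  minimal-fragment nucleotide) must not exceed the smaller of the two
  genes' signals (single ends per composite nucleotide): a real fusion
  cannot out-express both parents. Comparing against the *minimum* is the
  conservative reading.
* **PCR** — supporter footprints must independently cover at least the read
  size plus `p = 5` nucleotides on *both* gene sides. Coverage is the
  length of the union of footprints, not a hull, so a pile of identical
  reads plus one distant read cannot fake breadth.

### The abnormal insert-size filter

Size selection makes true cDNA fragments approximately one length
(default 300 ± 20 nt here). For an intra-gene pair the insert size — the
outer span of the two ends in composite coordinates — therefore
concentrates near the fragment size; pairs fully contained in exons define
this *intra-transcript distribution* (multi-isoform composites shift it
slightly upward, because a fragment spanning a skipped exon spans the
skipped block too).

A chimeric candidate has no known transcript, only the *minimal fusion
transcript fragment*: per gene, the smallest composite interval containing
all chimeric footprints. A real fusion's supporters all come from within
one fragment length of the junction, so their spans on the concatenated
fragment look like normal inserts; random pairing joins arbitrary positions
of both genes and produces much larger spans. The filter computes the
median chimeric span and an add-one resampling p-value — the probability
that the median of `k` draws from the intra distribution reaches the
observed median — and discards below `alpha = 0.01` (a sample with an
unusually tight insert distribution may warrant a smaller `alpha`; it is a
config knob). Candidates with only intronic supporters have no defined
fragment and pass unscored.

Two geometric quantities are not observable from PE data and are resolved
in the candidate's favour:

* which edge of each gene's covered region faces the junction — the span
  is evaluated under the four edge combinations and the one minimizing the
  median span is used (a fixed genomic-order concatenation would reject
  real fusions whose breakpoint happens to sit at the other hull edge, for
  instance on minus-strand genes);
* the anchor itself — the raw hull edge is set by the single most extreme
  footprint, so one stray background supporter between two well-expressed
  genes shifts every span by a constant, and with many supporters the
  median-of-`k` test is sharp enough to reject a real fusion over a
  15-nt shift. The junction-facing anchor is therefore the 98th-percentile
  footprint edge (a type-1 quantile, so nothing is trimmed below ~50
  supporters and the small-`k` arithmetic is exact).

## Scoring

With `m_i` supporting pairs out of `N` mapped pairs,

$$\mathrm{SPER}_i = \frac{m_i}{N}\times 10^6, \qquad
\langle \mathrm{SPER}_i\rangle = \frac{m_A\, m_B}{N^2}\times 10^6, \qquad
\mathrm{DASPER}_i = \mathrm{SPER}_i - \langle \mathrm{SPER}_i\rangle,$$

where `m_A`, `m_B` are the genes' single-end counts (including the chimeric
ends themselves — a deliberately conservative expectation). The expected
value is the random-joining null: the chance that a randomly ligated pair
lands on genes A and B is proportional to the product of their single-end
mapping probabilities, so DASPER demotes chimeras between highly expressed
genes. `RESPER_i` is `SPER_i` divided by the mean SPER over the sample's
`M` candidates; its mean is exactly 1 and it is fragment-size independent,
hence better for cross-sample comparison. `M` is taken over the
*post-filter* kept set (the stabler choice where the definition is open).
`LSPER` (pairs per mean partner RPKM) is reported as a diagnostic only:
with monoallelic fusions parent-gene expression need not track the fusion.
The default report order is descending DASPER, with RESPER ordering
available; ties break by DASPER and then gene-pair identifier.

Candidates are typed `inter` (different chromosomes), `intra`, and — when no
third gene's span intersects the interval between the two genes —
`read-through` (same strand) or `cis` (opposite strands). The cis
definition implies read-throughs are same-strand, which is adopted; an
intervening gene counts regardless of its strand.

## Junction-sequence resolution

PE pairs bracket a junction but never contain it; the exact sequence comes
from single ends. For a surviving candidate the *breakpoint regions* are
the composite blocks intersected by chimeric footprints plus any
directly-supported intronic intervals, each extended by 150-nt flanks and
merged. Region sequences follow each gene's transcriptional sense, so a
junction element reads upstream-into-downstream like the fusion transcript.

Tiles of length `read_length − min_overlap` (26 nt for 36-nt reads and a
10-nt overlap) are spaced 1 nt apart over both regions; the library is
every cross pairing in both orientations — `n_A × n_B × 2` elements of
twice the tile length, guaranteeing any aligned read overlaps both genes by
at least `min_overlap`. The library is kept lazy (tile counts plus an
element accessor): a thousand tiles a side is already two million elements
and materialising them would be pointless.

The matcher is exact: because the tile is shorter than the read, any
read/element alignment crosses the junction, splitting the read into a
prefix that must match a window ending at the upstream tile's right edge
and a suffix matching from the downstream tile's left edge. Enumerating
splits and matching the parts against the two regions reproduces the
brute-force `≤ max_mismatches` window scan exactly (oracle-tested), at a
fraction of the cost; a provably safe exact k-mer screen (seed length =
the worst-case guaranteed exact run of a matching read) drops hopeless
reads first.

Element support counts each read once, and only at its best-scoring
element(s): a read crossing the true junction also matches one-shifted
elements with one extra mismatch, and counting those would let phantom
junctions tie the real one. The best-supported element is called only when
its read starts are uniform across the valid offsets — a
Kolmogorov–Smirnov test against the discrete uniform when support reaches
10 (pass at p ≥ 0.05, orientations assessed separately), otherwise a
heuristic demanding at least `n = 4` reads at `m = 2` distinct starts
(values are configurable; the thresholds are design choices where none are
prescribed). Exact ties are all reported and flagged ambiguous; among equal
calls those landing on annotated exon edges list first, since validated
fusion breakpoints overwhelmingly lie on exon boundaries. An optional scan
discards junctions whose element matches elsewhere in the genome at 75%
identity.

## The synthetic-data generator

`simulate_dataset()` builds the whole study: random-sequence chromosomes
carrying 200 non-overlapping genes (4–7 exons of 120–260 nt, introns
200–800 nt, two isoforms — the second skips an internal exon), log-normal
expression, size-selected fragments (300 ± 20 nt), 36-nt reads at 50,000
pairs, and uniform per-base substitution errors (0.001). The fusion joins
the 5′ exons of one well-expressed gene to the 3′ exons of another at exon
boundaries, expressed at `F = 0.5` of the upstream wild-type allele —
mirroring the highly expressed driver fusions that motivate the method.
Junction-spanning ends are emitted unmapped with their sequence retained,
as a genomic aligner would leave them.

Each artifact class is implanted with a truth label: random inter-transcript
pairs drawn independently per end with probability proportional to
expression (exactly the ⟨SPER⟩ null, concentrated on a deliberately "hot"
gene pair), one chimeric fragment amplified 50×, rRNA-derived read pairs
misassigned to a fixed gene pair, reads from a homologous decoy gene (a
structural copy at 2% divergence, listed in the paralog table) with one end
emitted at the homolog's coordinates, and chimeras planted inside a repeat
interval. All randomness flows from one seed through fixed per-stage
offsets, so toggling one class does not perturb the others and outputs are
byte-identical across runs.

Choices that matter and why:

* **200 genes.** With very few genes each gene's single-end probability is
  so large that the quadratic ⟨SPER⟩ null swamps any real support and
  DASPER cannot rank a true fusion first — an artifact of a toy
  transcriptome, not of the method. Two hundred genes is the smallest
  background where the score regime resembles a real transcriptome while a
  full sample still simulates in seconds.
* **Breakpoints at exon boundaries, without edge microhomology.** Validated
  breakpoints sit on exon boundaries, so that is the default placement
  (uniform placement is available). If the base after the upstream
  breakpoint happened to equal the first downstream base, the junction
  would only be defined up to the homology length and "exact recovery"
  would be ill-posed; the generator substitutes the (intronic) adjacent
  bases when needed, leaving every transcript sequence untouched.
* **What the generator does not model:** indels and gapped alignment,
  quality scores, position-dependent error profiles, coverage bias along
  transcripts, alternative expression between isoforms, or genuinely
  repetitive sequence content (the repeat track is positional). Passing
  tests therefore demonstrate the pipeline's logic and statistics, not
  robustness to every property of real libraries.

## Numerical and scale choices

The test suite runs minutes-scale problems: shared fixtures use ~6,000
pairs over 60 genes, and the end-to-end recovery suite runs twenty seeded
samples at the full 50,000-pair, 200-gene conditions with one fusion at
`F = 0.5` and all artifact classes enabled, asserting the fusion ranks
first by DASPER in at least 80% of runs and that the called breakpoint
equals the implanted coordinate. Resampling uses 10,000 draws with the
add-one estimator and a configurable seed; counts are coerced to double
before forming `m_A · m_B`, which overflows integers on realistic inputs;
degenerate inputs (no candidates, all-zero SPER, empty intra distribution,
zero-length regions) raise early, named errors rather than propagating
NaNs.

## Limitations

Only substitution alignments are considered, so breakpoints hidden behind
indels within a read escape the matcher. Fusions whose partners overlap the
same locus, three-way fusions, and candidates supported purely by intronic
reads (kept, but unscoreable by the insert-size filter) are out of scope.
The expectation behind DASPER ignores the fragment-size constraint between
ends, which the source method itself calls very conservative.
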