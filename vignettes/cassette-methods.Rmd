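---
title: "Methods: junction-read quantification of cassette-exon skipping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: junction-read quantification of cassette-exon skipping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cassette)
```

## The measurement problem

A cassette exon is an internal exon that the spliceosome can either include
in or exclude from the mature mRNA. The motivating system is exon 6 of the
vertebrate D2-family dopamine receptor genes: a short exon (24–33 codons)
encoding part of the third cytoplasmic loop, bounded on both sides by
phase-0 introns. Because both flanking introns splice between codons,
skipping (or genomic deletion) of the exon leaves the reading frame intact —
the structural precondition that makes this exon evolutionarily labile.

Quantifying inclusion vs. skipping across dozens of species from public
RNA-Seq has two obstacles: libraries differ enormously in depth, and reads
retrieved by sequence matching can be artifactual (chimeric inserts, PCR
strand-switches, vector carry-over). The package addresses the first with a
per-library β-actin control and an explicit depth diagnostic, and the second
with a per-read identity classifier.

## Junction queries and perfect-match counting

Each splice junction is probed with a 30-nt query: the last 15 nt of the
upstream exon joined to the first 15 nt of the downstream exon
(`design_ejrna()`; `flank = 15` is tunable). Fifteen per side is long
enough to make random 30-mer matches vanishingly unlikely (a specific
30-mer occurs by chance once per ~10^18 nt) yet short enough that real
reads routinely span it.

A read supports a junction iff it contains the query exactly — 30/30
identities, no gaps — on either strand (`strand_mode = "both"`, since
public libraries have unknown strandedness). Counting is read-level: a read
increments a query's count at most once. The scan is an indexed
multi-pattern search (Biostrings `PDict`); the test suite holds it equal to
a naive per-read, per-query substring scan, and every reported match
re-verifies by extracting the 30-mer at its offset.

This criterion is deliberately all-or-nothing. One substitution anywhere in
the 30-mer discards the read, which costs sensitivity but buys an
essentially zero false-positive rate and makes counts comparable across
species without alignment-score tuning.

## Read-identity QC

Every matched read is classified (`classify_reads()`) by how much of it the
expected isoform transcript explains:

1. The junction match fixes a unique register between read and transcript.
   If the whole read lies within the transcript at that register and
   differs by at most `max_subs = 5` scattered substitutions, the read is
   `clean`. The bound of 5 reflects what legitimate reads show in practice
   (sequencing errors, often near read starts; RT errors; allelic
   polymorphism).
2. Otherwise the match is extended outward without gaps until a run of
   `stop_run = 3` consecutive mismatches, the substitution budget, or a
   sequence end. The unexplained leftover (if at least
   `min_leftover = 20` nt — shorter fragments cannot be identified
   confidently) is searched by exact 16-nt seeds, either strand, against
   reference sets in priority order: vector/barcode pool, the same gene's
   transcripts (`rearranged_same_gene` — wrong strand, wrong region, or
   gap-separated), other transcripts of the same species, then foreign
   sequences. No hit, or a too-short leftover, yields
   `unidentified_short`.

The priority order runs from the most specific contamination source to the
least; when several sets hit, the call is flagged `multi_hit` so ambiguous
reads are visible. One boundary case is ours by construction: a read
collinear with the expected transcript but exceeding `max_subs` has no
foreign leftover to identify, and is labelled `rearranged_same_gene` with
an "excess divergence" note so the category set stays a partition.
`stop_run = 3` is a numerical choice: at a chimera breakpoint the mismatch
density jumps to ~75%, so three consecutive mismatches locate the boundary
to within a few bases while never triggering inside a clean read at
realistic error rates.

`qc_summary()` reports counts, rounded integer percentages (half away from
zero), and the mean read length (total nt / reads, rounded).

## Normalization, presence, and depth

Counts are normalized as `log10(n / n_actb)` against the same library's
β-actin junction count (`normalized_expression()`); a zero control count
invalidates the library (hard error), and a zero gene count is reported as
absent (`NA`) rather than −∞, so plots simply omit the bar. Species with
several junction variants per isoform class are aggregated by cassette
containment into L and S subtotals (`aggregate_isoforms()`), which
conserves the total: L + S equals the sum over all of the gene's junction
queries.

Presence is operational: `raw_count >= min_reads`, default 1, because a
perfect 30-mer match is already strong evidence and the survey treats
single-read detections as real while reporting raw counts for stricter
reanalysis. Presence calls are monotone in `min_reads`.

`depth_report()` guards against the obvious confound — deeper libraries
detecting more isoforms — by reporting the rank-biserial correlation
between library depth (total Actb reads) and S-presence. We chose
rank-biserial over the Pearson point-biserial because it is exactly 0 under
independence or constant depth and exactly 1 when presence is confined to
the deeper half of species, which makes the diagnostic's extremes readable.

The skipping proportion is estimated with a length normalization:
junction-spanning starts number `len − 29` on either isoform, but a read's
start is uniform over `L_tx − len + 1` positions, so raw count ratios
overshoot toward the shorter (skipping) isoform. `
estimate_skipping_fraction()` weights each count by `L_tx − r̄ + 1` before
forming the ratio, which removes the first-order bias.

## Intron anchors and the exon-deletion signature

`map_intron_to_alignment()` expresses each coding intron as (alignment
column, phase). Phase-0 introns fall between codons and anchor between
residue columns (reported at the preceding residue's column); phase-1/2
introns anchor at the column of the codon they interrupt. Residue-to-column
mapping skips gaps, so anchors ignore all-gap columns outside the anchored
span.

Intron conservation (`conserved_intron_pairs()`) demands the identical
column and identical phase — no intron-sliding tolerance by default
(`slack = 0`), because the homology argument rests on exact
coincidence; a `slack` parameter exists for ragged alignments. Domain-level
equivalence is annotation, not a filter.

`detect_exon_loss_signature()` encodes the deletion-by-recombination
pattern: gene A shows two phase-0 anchors flanking the cassette exon, gene
B's row is gapped across the exon's columns (`gap_fraction = 1` by
default; relaxable), and gene B shows exactly one phase-0 anchor at the
fused position. Anything else is `retained` (exon present in both, flanks
paired) or `no_signature` (e.g. a fused intron of the wrong phase).

## Conservation profile

`column_net_score()` implements the pairwise column score: 2 per identity,
1 per conservative substitution, 0 for anything else including any gap;
the identity score is elevated to 3 if and only if the column is identical,
gap-free, across all rows; the net score is the mean over all unordered
pairs. `window_scan()` averages net scores over 30-column windows advancing
one column, reporting each window at its center (for even length w, center
= start + w/2 — fixed so plots are bit-reproducible). Profiles run in
alignment columns; `ref_row` adds residue numbering of a chosen reference
sequence for plotting against structural annotations.

The conservative-substitution groups are not part of the scoring rule's
definition, so the default uses the common strong classes {ILMV} {FWY}
{DENQ} {HKR} {AGPST} {C} and the argument accepts any alternative scheme;
at fixture scale the qualitative profile shape is insensitive to the
choice.

## Parsimony scenarios

`min_changes()` is a Sankoff dynamic program over the rooted tree
(multifurcations handled directly, no arbitrary resolution), minimized over
root states; on binary trees it coincides with Fitch, and the tests pin it
to phangorn and to exhaustive enumeration. The two constrained scenarios
are the biologically meaningful extremes for a complex character:
`scenario_gains_no_losses()` (loss forbidden — the count of maximal
all-present clades) and `scenario_losses_given_root_gain()` (single gain at
an ancestral node, no regain — the count of maximal all-absent clades
below it). Only event counts are contracted; optimal reconstructions need
not be unique. On the shipped 20-tip tetrapod fixture the counts are 4, 4
and 6: four convergent gains beat one ancestral gain plus six losses.

## The simulator: what it emulates, and what it does not

`simulate_gene_fixture()` builds, deterministically per seed, a target gene
whose 6th of 8 exons is a cassette of 24–33 codons flanked by phase-0
introns (both configurable — setting flank phases (0,1) produces the
frameshift-on-skipping control used in tests), plus a 6-exon β-actin-like
control gene assayed at its exon 3|4 junction. Exons are drawn at 40–80
codons, so transcripts land near real D2-receptor mRNA coding lengths
(~1.3 kb).

`simulate_reads()` draws reads per species: half from the control gene
(`control_weight = 0.5`, a typical housekeeping-vs-target abundance ratio
at the junction level), the rest split between inclusion and skipping
transcripts at the species' proportion `pi_s`; read lengths are normal with
mean 108 nt and sd 12, truncated to [30, transcript length] — 108 nt being
the empirical mean of the survey this emulates; starts are uniform;
substitutions are iid at `error_rate = 0.005`, a typical short-read
substitution rate. A `chimera_fraction = 0.03` of the junction-spanning
reads is replaced by constructed artifacts across the five QC categories,
each keeping an intact junction 30-mer plus genuine flanking sequence —
matching the empirical observation that artifact reads still carry enough
perfectly matched sequence to be retrieved and attributed. The fraction
applies to junction-spanning reads (not all reads) because the 3% artifact
rate is a property of the retrieved read set. Appended artifact content is
forced to mismatch the transcript continuation within its first 3 bases so
breakpoints are always detectable; without this, a rare chance agreement
could blur a truth label.

Species-level scenarios come from a status table
(`scenario_from_table()`); the shipped 29-row table encodes the survey's
presence pattern (12 species expressing both isoforms: ranid frogs,
squamates, most birds, and placental/marsupial mammals in the fixture tree,
plus 17 fish and tetrapod species with the long isoform only).
`pi_s_present = 0.3` is our choice for "both isoforms clearly expressed" —
the short isoform is consistently the minority species in brain tissue —
and depth tiers (5,000/10,000/20,000 reads per library) are assigned
cyclically, independent of presence, mirroring the observation that
detection is not depth-limited.

Deliberately not modelled: indels (the counting criterion is gap-free, so
indels could only deflate counts), base-quality scores, positional or GC
coverage bias, paired ends, and multi-library batch structure. Passing
tests on this generator therefore demonstrate correctness of the counting,
classification and inference machinery under a faithful but idealized read
model — not robustness to alignment-scale artifacts real libraries may
add.

## Numerical and interface choices

- Coordinates are 1-based inclusive throughout, the native convention of
  the R/Bioconductor sequence stack; GFF3 I/O therefore needs no coordinate
  conversion at the boundary.
- Introns lying wholly in untranslated regions get an `NA` phase sentinel,
  never 0, and are excluded from anchoring.
- Integer percentages (identity, QC fractions) round half away from zero.
- `log10` of a zero count is `NA` ("absent"), not −∞.
- Ties and degenerate inputs fail loudly: zero control reads, unmapped
  queries, missing tip states, single-row alignments and width-exceeding
  windows are all hard errors rather than silent defaults.
- Test and acceptance problem sizes — libraries of 5,000–20,000 reads,
  50,000 reads for parameter recovery, 10^4-read oracle comparisons, the
  20-tip exhaustive enumeration — were chosen as the smallest sizes at
  which binomial expectations separate cleanly from their 4σ bounds.

## Limitations

The pipeline quantifies exactly one cassette exon per gene against exactly
one control gene per species; multi-exon events, mutually exclusive exons
and intron retention are out of scope. Perfect-match counting undercounts
in proportion to `(1 - ε)^30` at per-base error ε and is not meant for
expression estimation in TPM-like units. The exon-deletion signature test
presumes a trustworthy protein alignment; it does not build one. Parsimony
counts are unweighted and unrooted hypotheses about process — they compare
scenario event counts, not likelihoods.
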