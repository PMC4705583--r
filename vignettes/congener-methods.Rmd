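---
title: "Methods: guided assembly and comparative analysis of congeneric genomes"
author: "congener package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: guided assembly and comparative analysis of congeneric genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(congener)
```

## What the package does

`congener` implements the computational core of a reference-assisted
("guided") genome assembly workflow and the comparative analyses that
typically follow when a new genome is built against the chromosome-level
assembly of a closely related species: mate-pair-based contig bridging and
gap filling, scaffold-to-chromosome placement, inter-chromosomal
rearrangement screening, single-nucleotide-change (SNC) and InDel calling
with effect classification, and transposable-element (TE) age landscapes.

Every analysis is validated against synthetic data with complete planted
truth. The synthetic-data module is first-class, tested code: it generates
a reference genome, a diverged congener genome, tiered paired-end
libraries, and a truth set from which the derived genome can be rebuilt
byte for byte.

## The synthetic study system

The generator emulates the sequencing design of a typical short-read
genome project within a genus:

* **Genome**: by default 2 Mb in 8 equally sized chromosomes at 35 % GC,
  with i.i.d. bases. Real fish genomes are two orders of magnitude larger
  and have compositional structure (isochores, repeats); the desk-scale
  genome preserves the algorithmic difficulty that matters here (unique vs
  repeated k-mers, insert-size geometry, coordinate bookkeeping around
  indels) while keeping the full test suite in the minutes range. The
  2 Mb / 8-chromosome size is also what the recovery analyses below use.
* **Divergence between species**: point mutations at 1 per 100 bp and
  InDels at 1 per 1000 bp by default, matching the low end of the 1-per-50
  to 1-per-100 range observed between congeneric fish species. Transitions
  are drawn twice as often as transversions, which both reflects real
  substitution spectra and makes the Kimura p and q estimates genuinely
  different, so the two-parameter correction is actually exercised. InDel
  lengths are uniform on 1..10 bp; short-read data says little about the
  true spectrum, so a simple explicit model is preferred over a fitted
  one.
* **Structural variation**: inter-chromosomal rearrangements are planted
  as cut-and-paste translocations of at least 25 kb between distinct
  (source, destination) chromosome pairs. Later events never cut into an
  earlier event's segment (overlap leads to a re-draw); stacked events
  would otherwise silently split a planted segment below any detection
  threshold and the truth set would no longer describe what is in the
  genome.
* **Libraries**: a 30x short-insert fragment library (300 ± 30 bp, reads
  pointing inward, "FR") plus 17x 3 kb and 5x 8 kb mate-pair libraries
  (reads pointing outward, "RF"), 100 bp reads — the tiered
  300 bp-to-8 kb design that assisted assembly expects. Reads are
  error-free by default; a uniform per-base substitution error rate is
  available. Quality-score models, PCR duplicates and coverage biases are
  deliberately out of scope, and there is no heterozygosity: the sequenced
  lines the workflow targets are inbred, so the variant model is a
  substitution/InDel event model, not a genotype model.

Determinism: every draw goes through R's Mersenne-Twister generator seeded
from the configuration seed plus a fixed per-operation offset, so any
object can be regenerated in isolation on any platform.

What passing these tests shows — and what it does not: recovery rates on
this synthetic system demonstrate that the algorithms are implemented
correctly under their stated assumptions (unique sequence, uniform
coverage, known library geometry). They do not predict performance on real
data with repeat families, coverage dropouts and chimeric reads.

## Read mapping

Alignments come either from external SAM files (parsed by `read_sam()`)
or from the built-in seed-and-extend mapper, which indexes target k-mers
(default k = 25, five seed offsets per orientation) and extends each
candidate diagonal with an ungapped X-drop scan (match +1, mismatch −3,
X-drop 12). Reads whose best placement does not beat the runner-up for the
same part of the read by a score margin of 5 are discarded as ambiguous;
complementary split placements (the two sides of an indel) do not compete.

Two details matter for calling accuracy downstream:

* **Clean flanks.** An aligned window must end in eight consecutive
  matches on each side; otherwise it is trimmed. Without this, a read
  whose X-drop extension coasts a few coincidentally matching bases past
  an indel junction deposits systematic mismatches into the pileup.
* **Indel rescue with junction refinement.** A clipped 3' tail (or 5'
  head) of at least 18 bases that re-aligns at a diagonal shift of up to
  ±15 with at most ~1 mismatch is accepted as evidence of a short indel.
  The junction is then refined to the split point minimising total
  mismatches across the two diagonals. All cost-tied split positions are
  treated as an ambiguity zone: the left segment ends at the leftmost
  optimum, the right segment starts at the rightmost, and the zone between
  them contributes no pileup evidence. This keeps homopolymer-shifted
  junctions from piling systematic false substitutions while still
  anchoring the indel observation at a consistent (leftmost-normalised)
  coordinate.

## Insert-size models and pair filtering

For each library the insert histogram of properly oriented pairs is
smoothed with a 10 bp moving sum; the contiguous non-zero region around
the largest smoothed peak is the dominant mode, and the selected range is
the central 99 % interval (0.5 and 99.5 percentiles) of inserts within
that mode. This resolves "the tightest range or the 99th percentile" into
one deterministic rule that collapses to a point for degenerate
histograms and ignores minor contaminating modes. A pair is retained iff
its orientation matches the library and its insert falls in the selected
range; the two rejection counts are reported separately.

## Bridging and gap filling

A pair supports the bridge across a scaffold gap iff one mate lies
entirely in the contig left of the gap and the other in the contig
immediately right of it, each with an exact match of at least 30 bases,
and the implied fragment spans the gap. Bridges need 3 supporting pairs
by default (joins between scaffolds need 5); these small integers are
chosen to be testable by construction and err on the permissive side for
error-free data. The gap estimate is the median of (library insert center
− left flank − right flank) over supporting pairs.

Filling walks a 30-mer graph built only from reads mapped within one
large-library insert (8 kb) of the gap plus the unmapped mates of those
reads — unmapped mates are where the missing sequence lives. The walk
starts from the left flank's terminal 30-mer and must have a **unique**
successor at every step until it reaches the right flank's initial 30-mer.
There is no heuristic tie-breaking: a branch is an explicit
`unfilled_ambiguous` status, a dead end after progress is `partial`, and
exceeding the 5000 bp cap (10 extension iterations) is
`unfilled_too_long`. Only bridged gaps are attempted. The package's
position is that a wrong fill is worse than an honest failure status;
exactness of successful fills is asserted, not approximated, in the test
suite.

## Anchor mapping, placement and rearrangements

Genome-vs-genome alignment uses MUM-style unique-k-mer seeding (k = 20)
with same-diagonal run merging, then chains colinear anchors when
consecutive anchors are at most 500 bp apart on both sequences, keeping
clusters with at least 400 matched bases. It is a stand-in for a
general-purpose whole-genome aligner, adequate because only the cluster
thresholds are analytically meaningful here. Cluster identity counts
anchor bases as matches and compares equal-length inter-anchor gaps base
by base (unequal gaps, i.e. indels, are excluded).

A scaffold is placed on the chromosome with the greatest summed matched
bases; if the runner-up is within 10 % the assignment is ambiguous and
the scaffold is reported unplaced rather than guessed. Orientation is the
majority strand; ordering along the chromosome uses the median cluster
coordinate; AGP output places 100 bp N gaps between scaffolds (a
conventional placeholder value — the true inter-scaffold distance is
unknown).

The rearrangement rule is deliberately strict: an event requires at least
20 kb of aligned sequence on **each** of two chromosomes from a single
contig. The weaker reading ("20 kb total, split across two chromosomes")
admits false positives from modest paralogous alignments; the strict
reading is the one the recovery analysis validates (5 of 5 planted
≥ 25 kb translocations found, zero events on a translocation-free
control). In that analysis the derived chromosomes themselves serve as
the "de novo contigs": re-fragmenting them at random positions could
split a planted segment below 20 kb on one side, which would test the
fragmenter rather than the rule.

## Variant calling and effects

Calling is pileup-based with explicit thresholds: depth ≥ 3, alternate
allele fraction ≥ 0.2, and a one-sided binomial tail
P(X ≥ alt_depth | n = depth, ε = 0.01) < 0.1. The binomial tail against a
fixed error rate re-specifies the published tool's p-value in a
transparent, testable form while keeping the two printed thresholds
(minimum coverage 3, p-value cutoff 0.1) meaningful. Because the compared
genomes are effectively haploid (inbred lines), a position cannot be both
substituted and deleted: SNC evidence inside a span supported by at least
two indel observations is masked as junction artefact. InDel observations
of the same type and length within 3 bp are clustered before testing.

Effect classification annotates every (variant, nearby transcript)
combination — one variant can count several times, once per affected
transcript, which is also how the summary table arithmetic works. Coding
SNCs are translated with the standard genetic code
(synonymous / non-synonymous / stop gained / stop lost / start lost);
coding InDels are frame shifts unless their length is a multiple of three
(codon InDel); intronic positions within 2 bp of an exon boundary are
splice sites; positions within 5 kb of a transcript are
upstream/downstream. The 5 kb and 2 bp windows are the defaults of the
annotation tools this summarisation format comes from. Deletions removing
a whole exon are `exon_deleted`; deletions longer than 1 % of their
chromosome are `chromosome_large_deletion`. High impact comprises splice
site, start lost, stop gained, stop lost, frame shift, exon deleted and
large chromosomal deletion. A "rare amino acid" category is not
implemented — it requires an external amino-acid frequency database — and
classification of every possible coding SNC is tested against an
exhaustive translation oracle rather than spot examples.

## TE landscapes

Repeat hits come from RepeatMasker `.out` files. Hits shorter than 80 bp
or below 80 % identity to their library consensus are discarded (both
boundaries inclusive for retention). Genome coverage is a per-position
union; where hits of different superfamilies overlap, the position is
assigned to the longer hit, and the Total row counts every covered
position once.

Copy age uses the Kimura two-parameter distance
K = −½ ln(1 − 2p − q) − ¼ ln(1 − 2q), with p the transition
(purine↔purine, pyrimidine↔pyrimidine) and q the transversion proportion
over gap-free aligned columns — the standard assignment. Landscapes
accumulate covered bases into integer K×100 bins on a 0–50 axis with an
explicit overflow bin. The recovery analysis plants copies at 1–20 %
divergence with the 2:1 transition bias and requires the median estimated
K within 15 % of the mutation-count-corrected truth; at 20 % divergence
the K2P estimate sits ~2.5 % above it, dominated by the repeat-mutation
correction, not estimation noise.

The spider table compares log10 genome and transcriptome percentages per
superfamily and flags families over- or under-represented in the
transcriptome by at least two-fold; zero percentages are flagged `absent`
because their logarithm is undefined.

## Numerical and degenerate-input choices

* All internal coordinates are 0-based half-open; conversions happen only
  in the IO layer, so each format rule (SAM/AGP/VCF 1-based, RepeatMasker
  inclusive ends) is applied exactly once and round-trips are identities.
* An N-run of ≥ 10 inside a scaffold defines a gap; shorter N-runs are
  sequence. The gap definition must be concrete for bridging to be
  testable.
* Empty inputs produce empty (header-only) outputs, not errors; unplaced
  scaffolds are always reported, never dropped.
* A variant whose stated reference allele disagrees with the genome is a
  hard error: silent repair would desynchronise truth sets from calls.
* Kimura distances outside the domain (2p + q ≥ 1 or 2q ≥ 1) are NA with
  a warning, never clamped.

## Known limitations

* The mapper is ungapped-with-rescue: it recovers InDels up to ~15 bp
  (search window) and calls them from junction observations; longer or
  clustered InDels, and InDels within ~18 bp of a read end, lose
  sensitivity (about 90–95 % InDel recovery at the default settings, vs
  > 99 % for SNCs).
* The k-mer gap filler requires unique successors, so it cannot fill
  through perfect repeats longer than k − 1 = 29 bp; such gaps end as
  `unfilled_ambiguous` by design.
* Anchor mapping assumes mostly-unique sequence; on repeat-dense real
  genomes the unique-k-mer seed density drops and placement would need a
  repeat-aware aligner.
* The effect classifier annotates against transferred gene models as
  given; it does not attempt to repair models whose CDS length is not a
  multiple of three (they are flagged on import instead).

## Reproducing the recovery numbers

```{r, eval = FALSE}
# gap-fill recovery at the study conditions
cfg <- sim_config(seed = 101)
ref <- simulate_reference(cfg)
fs <- fragment_scaffolds(ref, gap_count = 100, seed = 101)
prs <- simulate_pairs(ref, cfg)
rt <- as_read_table(prs)
aln <- map_reads(fs$scaffolds, rt)
pa <- pair_alignments(aln, rt)
models <- lapply(tiered_libraries(), function(l) build_insert_model(pa, l))
filt <- do.call(rbind, lapply(models, function(m) filter_pairs(pa, m)))
bridges <- find_bridges(fs$scaffolds, filt, models)
fills <- fill_gaps(bridges, fs$scaffolds, rt, aln)
table(fills$status)
```

The full set of headline numbers is recomputed by
`scripts/acceptance.R`; the test suite asserts each one at its stated
threshold.
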