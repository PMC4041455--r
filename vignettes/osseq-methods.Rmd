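---
title: "Probe design, capture QC and breakpoint assembly with osseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probe design, capture QC and breakpoint assembly with osseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osseq)
library(dplyr)
```

## The assay this package models

In oligonucleotide-selective sequencing, target enrichment happens on the
sequencing flow cell itself. A pool of 101-mer "primer probes" is grafted
onto the P7 primer lawn; each probe consists of a 5' target-specific 40-mer,
a universal read-primer segment (37 bases by default) and a 24-base segment
complementary to the P7 lawn primer. A single-adapter fragment library is
hybridized to the probe field; captured strands are copied by polymerase
extension from the probe and clustered in place. Read 1 then sequences
genomic target, while Read 2 reads through the synthetic probe itself — so
the first 40 bases of Read 2 identify, exactly, which probe captured each
fragment. That bookkeeping trick drives everything downstream: per-probe
yield accounting, on-target classification, and the grouping of reads
around candidate structural-variant breakpoints.

`osseq` implements the full computational stack around this chemistry:

1. a k-mer mapability index with a mismatch margin (`classify_positions()`),
2. constraint-based probe placement for exons/loci, SNPs and breakpoints
   (`design_for_interval()`, `design_for_snp()`, `design_for_breakpoint()`),
3. Read-2-indexed capture QC (`assign_probe()`, `classify_on_target()`,
   `per_probe_yield()`, `roi_coverage()`, `naive_af_call()`),
4. probe-grouped local assembly and split-alignment validation of exact
   breakpoints (`assemble_locus()`, `validate_contig()`,
   `call_breakpoints()`), and
5. a deterministic simulator (`simulate_genome()`, `implant_variants()`,
   `simulate_capture()`) that generates genomes, variant genomes, mixtures
   and capture-chemistry read pairs with full provenance, so the stack is
   testable end to end on synthetic data.

All internal coordinates are 0-based, half-open; conversion to 1-based
happens only at file boundaries (BED, SAM, VCF).

## k-mer mapability and the uniqueness margin

Probe specificity is carried almost entirely by the terminal 20 bases at
the extension end of the 40-mer, so candidate anchors are screened against
a per-position mapability track. For every position admitting a full
k-mer (k = 20 by default) we count occurrences on both strands — an
occurrence of a k-mer on the reverse strand is an occurrence of its reverse
complement on the forward strand, and a palindromic k-mer is counted once
per physical site. Positions are labelled:

* `UNIQUE_D1`: exactly one exact site, and no *other* site matches within
  `margin_mismatches` substitutions on either strand;
* `UNIQUE_STRICT`: exact-unique, but a second site lies within the margin;
* `REPETITIVE`: more than one exact site;
* `AMBIGUOUS`: the window contains `N`.

Designs require `UNIQUE_D1`, i.e. a second genomic site must need at least
`margin + 1` edits to bind the probe end. The literature on this assay
describes the production filter both as "one to two mismatches" and as
"edit distance of 1"; since those are not the same filter, the margin is a
parameter with default 1 (a second site must differ by at least two bases),
and "edit" is interpreted as substitution-only Hamming distance — the
neighbor-enumeration index (3k neighbors per k-mer per margin step, hashed
against exact counts) would not extend cleanly to indels, and the
brute-force oracle in the test-suite uses the same metric.

The implementation enumerates Hamming neighborhoods in compiled code but is
contractually equal to an all-pairs scan; the test-suite checks this
equivalence on genomes up to a few kilobases for k in {8, 20} and margins
0–2, plus reverse-complement symmetry and margin monotonicity.

## Probe placement rules

A candidate anchor is a 40-base genomic footprint plus a strand. A `+`
probe's synthesized 40-mer equals the forward reference at its anchor and
extension proceeds toward increasing coordinates; a `-` probe carries the
reverse complement and extends toward decreasing coordinates. "Terminal"
bases (the last 20 for uniqueness, the last 10 for SNP exclusion) are at
the extension-proximal end of the synthesized oligo. The assay's
description places the excluded SNP zone at "the last 10 bases on the 5'
side" while also calling that end the one critical for hybridization and
extension — on the synthesized oligo the target 40-mer *is* the 5' end, and
its extension-proximal terminus is where a mismatched SNP would abort
priming, so the extension end is the zone this package protects.

`candidate_passes_filters()` evaluates, and reports jointly:

| rule | default | code |
|---|---|---|
| GC fraction of the 40-mer | 0.30–0.65 inclusive | `GC_RANGE` |
| terminal 20-mer margin-unique | margin 1 | `KMER_NOT_UNIQUE` |
| no known SNP under terminal bases | last 10 | `SNP_IN_TERMINAL_10` |
| no `REPETITIVE` k-mer start adjacent on the extension side | 20 b | `REPEAT_ADJACENT` |
| no `N` in the anchor | — | `CONTAINS_N` |

The 20-base repeat-adjacency window is this package's operationalization of
"not immediately adjacent to highly repetitive sequence": no width is
published, and 20 bases shields the extension-proximal region that the
uniqueness rule already treats as critical.

Placement geometry per target class:

* **Interval targets** get one upstream `+` probe and one downstream `-`
  probe whose extension-proximal ends sit 100–200 bases outside the target
  (so extension reads into it from both sides), plus — for targets longer
  than the 200-base tile spacing — probes on both strands at nominal
  positions every 200 bases. Each nominal tile is searched within ±30
  bases; the passing candidate closest to the nominal position wins, ties
  to the smaller coordinate, which makes catalogs byte-reproducible.
* **SNP targets** get one probe per strand, anchored 100–200 bases away so
  extension reads across the site; the targeted SNP can never fall under a
  probe's terminal bases because anchors never overlap it.
* **Breakpoint targets** get four probes per breakpoint, two per flank on
  opposing strands, 150–300 bases from the putative junction, extension
  oriented toward it.

A window with no passing candidate produces a `DesignGap` record (with the
searched window and reason), never an error; a window clipped away by a
contig boundary is a gap with reason `OUTSIDE_GENOME`. The acceptance
suite verifies both soundness (every emitted probe re-passes the filters)
and completeness (a slot is filled if and only if exhaustive enumeration
of every anchor in the window finds a passing candidate).

## Capture QC

`assign_probe()` matches the first 20 bases of Read 2 against the catalog's
40-mer prefixes, tolerating one mismatch by default; the unique best hit
wins and ties are unassigned. Twenty bases suffice because catalogs are
built with unique terminal 20-mers; full-40 matching is
`prefix_len = 40`. No mismatch tolerance is prescribed for this step; one mismatch keeps ~2% of reads with a prefix
sequencing error assignable without risking collisions in catalogs of this
size.

`classify_on_target()` encodes the distance conventions: a read is on
target when it aligns to its probe's chromosome, in the expected
orientation, within 1000 bases of the anchor's extension-proximal end
(distance measured to the near end of the alignment). Because captures are
occasionally recovered beyond 1 kb while inserts beyond 1.5 kb are treated
as off-target, reads in (1000, 1500] are additionally flagged `gray`;
default metrics follow the 1 kb convention and the flag lets callers count
the gray zone as on-target explicitly. The expected orientation falls out
of the chemistry: Read 1 is primed from the adapter at the far fragment
end and reads back toward the probe, so it aligns on the strand *opposite*
the probe, downstream of a `+` anchor (and mirror-image for `-`).

`per_probe_yield()` counts on-target reads per probe (zeros included) and
reports the capture rate (probes with ≥ 1 on-target read) and the one-log
uniformity: the fraction of probes whose yield lies within a factor of ten
of the median yield over all probes — a scale-free number, which the tests
verify by invariance under rescaling.

`roi_coverage()` builds regions of interest as probe anchors ±50 bases,
merged, and computes per-base depth counting only Read 1 alignments that do
not overlap their own probe's footprint, so synthetic probe sequence never
inflates coverage. `naive_af_call()` applies the fixed pileup thresholds
(depth ≥ 10, allele fraction ≥ 0.15, mean base quality ≥ 25 — arithmetic
mean of Phred scores) and always reports the allele fraction; it is a
thresholds re-implementation, not a statistical caller.

## The simulator: what it emulates and what it does not

`simulate_capture()` draws library fragments with Normal(500, 100) lengths
(the fragmentation peak the protocol targets; the spread is a package
choice as no deviation is published), uniform start positions, from each
source genome in proportion to its mixture weight. A fragment is eligible
for a probe when it fully contains the probe's anchor in that source's
coordinate frame — anchors are lifted through each source's variant lift
map, and an anchor disrupted by a variant cannot capture. Eligible
fragments are captured with the probe's efficiency: fixed, or drawn
log-normally with mean 0.049 (reflecting the assay's reported ~4.9%
capture of available targets in a 20 h hybridization) and CV 0.5.

Read geometry follows the single-adapter chemistry. The probe is extended
to the fragment end on its extension side; Read 1 is primed from the
ligated adapter at that fragment end and reads back toward the probe.
Read start positions are therefore randomly distributed over the captured
span — which is what makes breakpoint recovery possible at all, since
breakpoint probes sit 150–300 bases from the junction and 80-base reads
could never span it if they always began at the probe edge. A fragment
ending close to the anchor yields a Read 1 overlapping the probe
footprint, which exercises the ROI-coverage exclusion rule. Read 2 is the
synthetic probe 40-mer followed by adjacent genomic sequence when
`read2_len > 40`; defaults are 80 × 40.

Errors are independent per-base substitutions at rate 0.001; qualities are
constant Phred 35. The simulator does **not** model GC-dependent capture
bias, PCR duplication, indel sequencing errors, quality decay along the
read, chimeric fragments, or allele dropout from variants under the probe
anchor (eligibility is by coordinates, not sequence identity). Passing
tests therefore demonstrate algorithmic correctness under clean Illumina-
like noise, not robustness to every artifact of real libraries. Every
output is deterministic given the config seed, and each read carries full
provenance (source genome, fragment, probe), from which truth SAM records
are emitted directly — no aligner is required anywhere in the test chain.

Mixtures are simulated as weighted sources: a spike at mass fraction `s`
contributes its two haplotypes at `s/2` each, so a heterozygous
spike-unique site has expected allele fraction `s/2` and a homozygous one
`s`. Following the depth convention of the mixture experiments, detection
rates are evaluated only at sites with depth ≥ 100. For the acceptance
check of proportionality, each site's observed fraction is compared with
its binomial 3-sigma band; since a 3-sigma band is *expected* to fail ~0.3%
of the time, the suite requires the observed exception rate across all
site-checks to stay below 2% and the pooled fraction per spike to sit
inside its own 3-sigma band — a contract that is tight but not vacuously
flaky.

## Breakpoint resolution

Upstream candidate filtering (`filter_sv_candidates()`) reproduces the
discovery-side rules: support ≥ 20 reads in a single tumor or ≥ 10 in each
of two; absence from the matched normal; sex plausibility (no Y
involvement in a female); anchors ≥ 20 bases and outside a repeat mask.

For targeted resolution, reads are grouped per rearrangement locus via
their Read-2 probe assignment (`build_locus_groups()`), then filtered
(`filter_reads_for_assembly()`): mean base quality must exceed 25
(interpreted as the read-mean of Phred scores), reads containing
sequencing primer 2 (`AGATCGGAAGAGCGGT`) or its reverse complement are
removed to prevent adapter contigs, and reads that match the reference are
eliminated. Reference matching is deliberately *tolerant* — a read counts
as matching when some location on either strand carries it with at most 3
substitutions, found by pigeonhole seeding (4 exact 20-mer seeds located
with Biostrings, then Hamming verification). Exact matching would be
wrong here: an alignment-based workflow removes reads that *align* to the
reference, and an aligner happily places a read with one sequencing error,
so exact-match elimination would flood the assembler with error-bearing
reference reads.

`assemble_locus()` is a compact de Bruijn assembler: k-mers (k = 19, odd,
so none are their own reverse complement) are counted in canonical form,
k-mers seen fewer than `kmer_min_count = 2` times are pruned (the
error-removal counterpart of a coverage cutoff), and maximal non-branching
paths become contigs, deduplicated across orientations. One further
cleaning step matters in practice: at a branching node, alternative edges
whose k-mer count falls below 10% of the dominant alternative are treated
as noise (`min_branch_frac`). Without it, two reads sharing the same
sequencing error — an event that becomes likely at high per-locus depth —
create a count-2 spurious branch that would split the junction unitig at
exactly the wrong place. Equal-coverage branches are never pruned, so
genuinely heterozygous junctions survive, and the gate leaves error-free
oracle read sets untouched. Contigs shorter than 50 bases or with mean
canonical-k-mer coverage below 4 are suppressed; these two gates follow
the assay's standard assembly parameters by contract; general-purpose
assemblers keep their coverage books differently in detail.

`validate_contig()` asks whether a contig is a junction: it must split as
`prefix · suffix` with each segment aligning exactly to the reference
(either strand) with anchors ≥ 20 bases — the same 20-base anchor contract
as the discovery filter — at discontinuous locations. Seeds from the
contig ends are located exactly and extended; a contig matching the
reference contiguously is rejected `FULLY_REFERENCE`; splits off the
expected chromosome are rejected `WRONG_CHROM`; a junction also derivable
from the matched normal's contigs is reported with its coordinates but
flagged `GERMLINE`/non-somatic. Microhomology at the junction makes the
split position intrinsically ambiguous: all equivalent representations
(shifts across the homology tract, plus the flip that reads the junction
from the other side) are enumerated against the reference and the
lexicographically smallest `(chrom1, pos1, chrom2, pos2, strand1,
strand2)` is reported, with the homology length recorded. Truth
coordinates from `implant_variants()` are compared in the same canonical
form, which is what makes "exact junction recovery" a well-defined test —
the canonicalization itself is property-tested against brute-force
sequence-equivalence enumeration.

A deletion of `[a, b)` validates as `(chrom, a, +, chrom, b, +)`. An
inversion of `[a, b)` produces two junctions — forward into
reverse-complement at the left edge, reverse-complement into forward at the
right — both of which canonicalize to `(a, b)` with distinguishing strand
signatures, and both of which are recovered from the same locus group.

## Problem sizes and determinism

The test-suite and the acceptance script run entirely on synthetic genomes:
3 kb genomes (20 seeds) for design/enumeration equivalence, ~1.2 kb for the
all-pairs k-mer oracle, 6 kb mixtures captured at ~150 000 fragments per
sample for allele-fraction recovery, and a 100 kb tumor/normal pair (5
somatic deletions + 2 inversions + 2 germline controls, 40% tumor
cellularity, 600 000 fragments per sample) for end-to-end breakpoint
recovery. These sizes were chosen so the full chain — including the
deliberately naive brute-force oracles — completes on a laptop-class
single core in minutes while still exercising every rule at realistic
depths (junction coverage ≥ 15×, site depths ≥ 100). All simulations are
seed-deterministic; rerunning any generator with the same seed reproduces
outputs byte for byte, which the fixture-suite test asserts via MD5
digests.

## Known limitations

* Uniqueness is substitution-only; indel-mediated cross-hybridization is
  not screened.
* The capture model ignores thermodynamics: no melting-temperature or
  GC-bias term modulates efficiency, and probe concentration rebalancing is
  out of scope.
* `validate_contig()` uses exact segment matching (suited to desk-scale
  references and assembled contigs); it does not implement a full
  mismatch-tolerant local aligner, and inter-chromosomal junctions, while
  representable, are only lightly exercised.
* The allele-fraction caller is a fixed-threshold filter with no p-value,
  strand-bias or mapping-quality model.
* Whole-genome discovery (discordant-pair calling) is consumed as candidate
  records, not reimplemented.
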