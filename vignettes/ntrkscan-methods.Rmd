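---
title: "ntrkscan: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ntrkscan: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntrkscan)
```

## The problem

*NTRK1/2/3* fusions are tumor-agnostic drug targets: a rearrangement that
places the TRK tyrosine kinase domain downstream of a partner gene's 5'
region yields a constitutively active chimeric kinase. On a DNA capture
panel the evidence for such a rearrangement is indirect — read pairs
whose two ends map implausibly far apart or to different chromosomes —
and a candidate junction is only clinically meaningful if the genomic
geometry supports a translatable, in-frame, kinase-intact transcript.
`ntrkscan` implements the full path from aligned read pairs to a
classified fusion call, plus the panel biomarkers (TMB, MSI) and the
cohort statistics used to describe fusion epidemiology.

## The caller

A read pair is **discordant** when its ends map to two chromosomes, or
to one chromosome with an *outer insert* — leftmost mapped base to
rightmost mapped base of the pair, the same quantity SAM's TLEN encodes —
strictly greater than 2000 bp. The strict inequality matters only at the
boundary and is tested there. The outer-distance definition was chosen
over inner distance because it is the convention aligners report;
nothing else in the pipeline depends on the choice.

Discordant pairs are grouped by (chromosome pair, orientation pair) and
clustered by **single linkage**: two pairs are linked when their A-side
starts and their B-side starts each differ by less than 500 bp. Linkage
is applied on both sides of the candidate junction — a one-sided rule
would merge distinct junctions sharing one locus — and on read start
positions rather than fragment midpoints, since starts are what the
records carry. Connected components make the result independent of
input order (tested by permutation and against a brute-force
pairwise-graph oracle).

Each cluster's reads are assembled by **greedy exact overlap**: the pair
of sequences (either orientation) with the longest exact suffix–prefix
overlap of at least 20 bp is merged until no merge remains. Contained
and duplicate reads are absorbed. Exact overlaps are appropriate here
because the simulator emits error-free reads; for error-bearing data the
`min_overlap` parameter would be raised and the merge predicate relaxed,
which is out of scope. When reads do not tile across the junction the
cluster assembles into one contig per locus; all terminal contigs are
therefore kept and confirmation is attempted longest-first.

**Confirmation** is a split realignment. The first and last 25 bp of the
contig are seeded in the reference (both strands, up to 2 mismatches,
restricted to windows around the cluster's loci when called from the
pipeline), the whole contig is projected onto the reference under each
placement, and the junction is placed at the split that minimises the
total mismatch count of left-part-on-locus-A plus right-part-on-locus-B.
Ties — microhomology at the junction — resolve to the leftmost split, a
deterministic convention shared by split-read callers. A contig whose
two placements coincide (it aligns end-to-end at one locus) is rejected:
it is reference-concordant, not a rearrangement. An earlier design that
extended each flank independently under the mismatch budget and then
reconciled the two edges systematically overshot the junction by a few
chance-matching bases; the joint minimisation removes that bias, and
recovery tests require the reported breakpoints within ±5 bp of the
planted truth (the residual slack covers genuine microhomology).

Finally, calls need at least **5 unique supporting pairs**, uniqueness
meaning distinct (A-start, B-start) coordinate tuples — a PCR-duplicate
style deduplication. The count is taken after deduplication and before
assembly; applying the filter at the cluster stage or the call stage
yields the same set, and monotonicity (lowering the threshold never
removes calls) is tested.

### Operating constants

| parameter | default | unit | role |
|---|---|---|---|
| `insert_threshold` | 2000 | bp | discordance cutoff (strict >) |
| `cluster_distance` | 500 | bp | single-linkage radius (strict <) |
| `min_support` | 5 | pairs | unique-pair filter (≥) |
| `min_overlap` | 20 | bp | exact assembly overlap |
| `min_flank` | 25 | bp | seed/flank length for confirmation |
| `max_mismatch` | 2 | bases | per-flank mismatch budget |

The first three are the workflow's clinical operating points; the last
three are repository defaults for the bundled assembler/realigner and
are exposed as arguments.

## Gene models, frame and classification

Gene models carry one canonical transcript each: exons in transcript
order (0-based half-open genomic intervals), full coding status, an
optional kinase-domain interval, and a hot-exon set. Reports use 1-based
exon ordinals ("exon1-5") and the emitted TSV converts breakpoints to
1-based coordinates; everything internal is 0-based half-open.

A call side with strand `+` retains the coordinates below its
breakpoint (side A) or above it (side B); `-` flips either. A junction
is **in-strand** when exactly one side contributes its gene's
transcription start — both reciprocal orientation pairs qualify, mixed
pairs join two 5' or two 3' ends and cannot transcribe through.
**In-frame** requires the retained 5'-partner coding length to be
congruent mod 3 to the coding length the NTRK gene loses upstream of its
breakpoint, so the kinase codons read through in register; non-coding
partners have undefined frame and are treated as out-of-frame.
**Kinase retention** demands the entire annotated kinase-domain interval
inside the retained NTRK segment — a breakpoint inside the domain
disqualifies the call.

Classification is then: Definite = in-strand ∧ in-frame ∧
kinase-retained; Likely = kinase-retained ∧ ¬(in-strand ∧ in-frame) ∧
(known partner ∨ hot-exon breakpoint); otherwise NotReportable.

Two curation choices deserve flags. The **hot-exon sets** (NTRK1 exons
8–17, NTRK3 exons 13–15, with an intron counting as hot when adjacent to
a hot exon) encode the recurrently rearranged regions — NTRK3
breakpoints cluster tightly in introns 13–14 while NTRK1 breakpoints
spread across introns 3–13 — but "hot" has no standard definition, so
the sets are model attributes the user can replace. The **partner
knowledge base** is a packaged ten-symbol TSV of previously reported
partners (ETV6, TPM3, LMNA, TPR, RBPMS, IRF2BP2, PHF20, AMOTL2, COL8A1,
PEAR1), matched case-insensitively and user-extensible; no external
fusion registry is bundled.

The packaged toy models mirror the real genes' chromosome assignments
(NTRK1 on a chr1-like contig, NTRK2 chr9-like, NTRK3 chr15-like, ETV6
chr12-like) with exon lengths chosen so the recurrent clinical junctions
are in frame; they are synthetic models for validation, not curated
human annotation.

## Panel metrics

**TMB** is the count of coding SNVs and indels divided by the panel's
coding footprint in megabases, reported to one decimal. Synonymous and
non-synonymous variants count alike and no driver subtraction is applied
— the simplest reading of "coding mutations per megabase". The
denominator is a parameter (`panel_coding_mb`, no default constant)
because a capture panel's footprint is assay-specific and the distinction
between total captured and coding-only megabases is a documented
ambiguity of such assays.

**MSI** is decided in two layers. Per locus: *unstable* iff the tumor
carries an allele length with ≥ 3 supporting reads absent from the
matched normal; *uncovered* below 10× in either sample. The per-locus
rule is this package's operationalisation — panel MSI assays publish the
panel threshold, not the locus rule — and both thresholds are
parameters. Per sample: MSI-H iff strictly more than 15% of evaluated
loci are unstable; *Unknown* when fewer than 20 loci could be evaluated,
modelling the small Unknown stratum real cohorts report (its true cause
is not stated in such tables; insufficient coverage is the natural
mechanism). Monotonicity (an added unstable locus never flips MSI-H to
MSS) and planted-fraction recovery across the 15% boundary are tested.

## Cohort statistics

Prevalence tables report positives, totals and a percentage rounded
**half-up to one decimal**, matching clinical-table convention (R's
default banker's rounding would print 12.65 → 12.6). Association tests
are Fisher's exact (two-sided, sum of hypergeometric probabilities not
exceeding the observed table's) with chi-square available on request;
Unknown levels are excluded pairwise. Group comparisons use the
Wilcoxon rank-sum with midrank ties. Fisher and Wilcoxon are delegated
to `stats::fisher.test()` / `stats::wilcox.test()`; the test suite
verifies both against independent enumerations (full hypergeometric
sums; all `choose(6, 3)` group assignments).

Per-fusion (41) and per-patient (40) denominators are both computed and
labelled, because one patient carries two NTRK3 fusions and published
summaries mix the two denominators. The fixture tables transcribe the
printed cohort tables; where a printed summary is inconsistent with the
printed per-patient rows (the positive-cohort median age and median TMB,
and one stratum percentage), the package reports the value recomputed
from the rows and keeps the counts authoritative. The DNA-vs-IHC
detection comparison is reported as counts (7 positive of 9 evaluated)
rather than a percentage, because the published percentage implies a
denominator the concordance table does not show.

## The synthetic-data generator

The generator emulates exactly the features the caller consumes:

* a uniform-composition random reference (≥ 2 chromosomes so
  interchromosomal events exist; GC ≈ 0.5);
* fragments of a planted fused allele, placed at staggered unique start
  coordinates straddling the junction, so every supporting pair
  satisfies the discordance predicate and reads near the junction carry
  chimeric sequence for assembly. Supporting fragments sit at the median
  insert; background fragments draw from a normal insert distribution
  (default 300 ± 30 bp, read length 100 bp — typical hybrid-capture
  values) truncated below at twice the read length, which keeps every
  background pair concordant by a wide margin (a > 2000 bp draw is a
  ~57-sigma event);
* microsatellite profiles where a planted fraction of loci gains a
  well-supported novel tumor allele and all other loci are identical to
  the normal;
* cohorts with independent per-patient fusion and MSI status at chosen
  conditional rates and tumor types drawn from the packaged pan-cancer
  frequency table.

It does **not** model sequencing errors, base qualities, PCR/optical
duplicates, mappability structure, repeats, or real human gene
annotation. Passing recovery tests therefore demonstrate the
correctness of the algorithmic chain (collection → clustering →
assembly → confirmation → filtering) under clean evidence, not
performance on real FFPE libraries, where alignment artifacts and
duplicate marking dominate the error budget.

## Determinism and problem sizes

Every generator takes an explicit seed and derives independent
sub-streams per component, so identical seeds give byte-identical
outputs and an end-to-end run writes a byte-identical summary. The test
suite and the acceptance script use desk-scale problem sizes chosen to
exercise the contracts well within interactive runtimes: 30–60 kb
chromosomes, 20-seed recovery and specificity experiments with hundreds
to thousands of background pairs, the full 572-locus MSI panel, and
exhaustive Fisher-oracle enumeration over all small contingency tables
(with random sampling of larger ones up to N = 60). One statistical
caveat is asserted deliberately loosely: under the null, Fisher's exact
test on the sparse 2×2 tables a rare-fusion cohort produces is
conservative, so the suite checks that the realized type-I rate does not
exceed the nominal 5% (plus simulation noise) rather than demanding it
equal 5%.

## Known limitations

* Single-end (split-read-only) evidence is not used; events supported
  only by soft-clips are invisible.
* Copy-number style events (deletions, duplications, inversions without
  discordant-pair signatures at the junction) are out of scope.
* One canonical transcript per gene; isoform-aware exon numbering is a
  curation problem the annotator does not attempt.
* The greedy assembler is exact-overlap and quadratic in cluster size;
  clusters are capped at 120 reads for assembly. For noisy data a
  dedicated assembler should replace it behind the same interface.
* Somatic/germline subtraction and panel-of-normals filtering are not
  implemented; the caller assumes tumor-only discordant evidence.
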