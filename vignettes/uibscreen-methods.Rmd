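---
title: "Detecting intergenic-breakpoint fusions that dysregulate cancer genes"
author: "uibscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting intergenic-breakpoint fusions that dysregulate cancer genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uibscreen)
library(data.table)
```

## The problem

Most fusion analyses of tumor whole-genome sequencing concentrate on
junctions whose two breakpoints both fall inside genes, because those are
the ones expected to produce chimeric mRNAs. But the majority of somatic
structural-variant (SV) junctions have one or both breakpoints in
intergenic space, and two consequences of such junctions matter for tumor
biology:

1. **Chimeric transcripts from gene-intergenic fusions.** When an SV
   juxtaposes an intronic breakpoint of a 5' gene with a breakpoint in
   the intergenic region *upstream* of a 3' gene, sense-to-sense, the
   transcription machinery initiated at the 5' gene's promoter can read
   through the junction and splice the 5' gene's last retained exon
   directly onto **exon 2** of the 3' gene. Exon 1 of the 3' gene is
   skipped: with no splice-acceptor signal ahead of it, the whole segment
   between the retained 5' exon and the 3' gene's exon 2 behaves as one
   intron. The result is a chimeric mRNA that DNA-level gene-gene fusion
   callers never see.
2. **Upregulation of intact mRNAs by repositioned regulatory sequence.**
   A breakpoint upstream (UIB: upstream-intergenic-breakpoint) or
   downstream (DIB) of a gene can reposition a promoter, enhancer or
   insulator and massively upregulate the intact transcript, sometimes
   from megabases away. These events recur across samples at the level of
   the target gene, not the partner locus.

`uibscreen` implements the full analysis chain for these phenomena on SV
call sets (BEDPE) paired with expression (TPM) and copy-number (discrete
GISTIC-style scores) matrices: breakend annotation and fusion
classification, the first-exon-skipping chimera model with RNA junction
verification, and a distance-ordered split-search screen for recurrent
target-dysregulating UIB/DIB fusions. A seeded cohort simulator with a
ground-truth manifest makes every stage testable without access to
protected human data.

## Breakend annotation and fusion classes

A breakend is a chromosome, a position and a **side**: `LEFT` means the
retained segment lies at coordinates below the position and is joined at
the junction to the partner breakend, `RIGHT` that it lies above. In
BEDPE input, strand `+` maps to `LEFT` and `-` to `RIGHT`. All internal
coordinates are 1-based inclusive, the GTF/`GRanges` dialect; BED and
BEDPE are converted at the I/O boundary.

Each breakend is `GENIC` (inside any gene body, exon or intron alike) or
`INTERGENIC`, and a junction is classified `GENE_GENE`,
`GENE_INTERGENIC` or `INTERGENIC_INTERGENIC` accordingly. Under a null
in which breakpoints land uniformly on the genome, the expected gene-gene
fraction is $f^2$ where $f$ is the genic fraction (union of gene bodies
over genome size); `class_proportions()` reports the observed counts
against $N f^2$ with a one-proportion test (exact binomial and normal
approximation). Gene bodies, not exon unions, define $f$, matching the
gene/intergenic dichotomy of the classification itself.

Annotation uses one canonical transcript per gene: longest total CDS,
ties broken by exonic length, then by transcript id. Exon indices are in
transcription order, so exon 1 of a `-` gene has the highest
coordinates, and "upstream" always means 5' of the transcription start
in the gene's own orientation.

## Junction orientation

Whether transcription can run from the partner side into a target gene
is a property of the two retained sides. Walking from the junction into
the retained segment at the target-side breakend moves towards lower
coordinates for `LEFT` and higher for `RIGHT`; the junction is
*transcription-concordant* for the target when that direction equals the
target's strand, and, when a 5' partner gene is specified, when the walk
additionally leaves the partner in its sense direction
(`is_transcription_concordant()`). For UIB/DIB candidate enumeration the
equivalent requirement is that the retained segment at the intergenic
breakend *faces* the gene, so that the gene stays physically joined to
the partner-side material.

## The chimera model

`predict_chimera()` applies the splicing model to a single call:

* **UIB mode** (gene-intergenic): the 5' breakpoint must be *intronic*
  in gene A; the other breakend must be upstream of a gene B within the
  chimera window; the junction must be sense-to-sense. The predicted
  donor is the 3' boundary of A's last exon before the breakpoint
  (typically exon 1 -- breakpoints concentrate in first introns, which
  are several-fold larger than later introns) and the acceptor is the 5'
  boundary of B's **exon 2**.
* **Gene-gene mode**: both breakpoints intronic, sense-to-sense; the
  acceptor is the first B exon after the breakpoint.

Exonic 5' breakpoints return no prediction: the model is defined for
intronic breaks, and such calls are left for manual review rather than
guessed at. The chimera window defaults to 100 kb -- observed UIB
distances of chimera-producing fusions fall in the tens of kb, the scale
of (first) intron sizes, while non-chimera-producing breakpoints extend
to several Mb; the cutoff is deliberately permissive and is a parameter,
not a claim that splicing stops at exactly 100 kb.

`frame_status()` classifies the predicted transcript by two quantities:
the coding length of A's retained exons and the coding length of B's
skipped prefix, both computed from CDS/exon intersections:

| status | meaning |
|---|---|
| `NON_CODING` | either gene lacks a CDS |
| `FIVE_UTR_ONLY` | A contributes no coding sequence; the product is B's intact protein from A's promoter |
| `THREE_EXON1_UTR_ORF_INTACT` | B's skipped exon(s) are pure 5' UTR; B's ORF is intact from exon 2 |
| `IN_FRAME` | both sides coding and congruent modulo 3 |
| `OUT_OF_FRAME` | both sides coding, frames incompatible |

The order matters and is part of the contract: `FIVE_UTR_ONLY` is
decided before the 3'-UTR rule, so a junction where *both* hold is
described by the 5' side (the protein is B's either way). The modulo-3
rule is validated in the test suite against hand-designed toy genes whose
spliced chimeric mRNAs are translated with `Biostrings`.

A prediction is *verified* when RNA junction evidence (per-sample split
reads at exon-exon junctions) supplies at least 3 reads at the exact
donor/acceptor pair; the tolerance defaults to 0 bp because annotation-
derived splice sites are exact in both simulation and practice, and the
read threshold reflects the signal-to-noise of junction-spanning
alignments.

## The recurrence screen

For a target gene, tumor type and mode (UIB or DIB),
`split_search_best_group()` collects the samples carrying a concordant
intergenic breakpoint within the window (default 4 Mb, a conservative
bound motivated by chromatin-contact maps in which 98% of loops span
under 2 Mb), orders them by breakpoint distance $S_1 \le \dots \le S_n$
(each sample contributes its closest breakpoint; ties break by sample
id), and evaluates every prefix group $\{S_1..S_i\}$ with a two-sided
Wilcoxon rank-sum test of target expression, choosing the split with the
smallest p-value.

Two comparison groups are implemented. The default (`"rest"`) compares
the prefix against *all remaining samples of the tumor type*; this is
the only reading under which the test measures upregulation against the
cohort background, and it is consistent with the fold filters, which are
defined against "the rest". The literal variant (`"literal"`,
`--literal-split`) compares against the remaining breakpoint-bearing
samples $\{S_{i+1}..S_n\}$ only. The rank-sum p-values are computed in
closed form (normal approximation with tie and continuity correction,
identical arithmetic to `wilcox.test(exact = FALSE)`), which makes the
scan over all splits a single ranking operation; fully tied expression
yields p = 1.

Choosing the minimum p over $n$ splits is a selection; the nominal
p-value is therefore optimistic. The result records `n_splits_tested`,
and a seeded permutation calibration (`permutations` argument) provides
an empirical p-value for the min-p statistic when wanted; it defaults to
off because the screen's decisions rest on the fold filters below, not
on the nominal p.

`apply_expression_filters()` then enforces the functional criteria:

* samples with a high-level amplification of the target (copy-number
  score 2) are excluded from the analysis -- from the positive group
  *and* from the control group, since an amplified control sample
  inflates the background mean and can mask a true fusion effect;
* each case must exceed 4-fold expression over the control median
  (pseudocount 0.1 on numerator and denominator to tolerate zeros);
* the surviving group's mean must exceed 5-fold the control mean.

An event is reported when at least `min_samples` (default 4) cases
survive. Events are labelled `CP` (chimera-producing) when any surviving
case carries a junction-verified chimera prediction for the target,
`N_CP` otherwise; cytoband-level partner recurrence and breakpoint
distance summaries (mean, maximum, fractions beyond 1 and 2 Mb) are
attached. Recurrent gene-gene fusions are screened separately
(`screen_recurrent_gene_gene()`, at least two samples sharing the
oriented gene pair), as is the simpler nearest-upstream-gene scenario
(`screen_nearest_gene()`, at least two samples with breakpoints before
the nearest upstream gene and direction-consistent expression change at
a configurable rank-sum threshold, default 0.05).

### Behaviour near the fold floor

The per-case 4-fold floor is a hard filter, and its interaction with
expression noise is worth stating precisely. Under the simulator's noise
law (multiplicative log-normal with $\sigma = 0.25$), a planted 6-fold
case falls below the floor whenever its noise draw is below about
$-2\sigma$, roughly a 1-in-40 event per case. A cohort event planted in
exactly 4 samples at 6-fold is therefore suppressed entirely whenever
any one of its cases dips -- detection of effects this close to the
floor is probabilistic by construction, in simulation and in real
cohorts alike. Effects at 10-fold and beyond are essentially never lost,
and planted events at 3-fold, or in 3 samples, are never reported at the
default thresholds. The screen's published sensitivity claims should be
read with this floor effect in mind.

## The cohort simulator

`simulate_annotation()` draws non-overlapping multi-exon genes (3-10
exons; log-normal exon and intron widths) with the transcription-first
intron enlarged 4-fold, reproducing the empirical excess of first-intron
size that concentrates breakpoints there. A configurable fraction of
genes has an entirely untranslated first exon (35%, so that every frame
status of the chimera model arises) or no CDS at all (10%). CDS lengths
are multiples of 3.

`simulate_cohort()` realizes, per planted event, breakends with sides
chosen to be junction-orientation-concordant and an SV type consistent
with the geometry (deletion-, tandem-duplication-, inversion-like
adjacencies on one chromosome; translocations across chromosomes):

* expression is `baseline(gene) x fold(if positive) x lognormal(sigma)`
  with a per-gene log-normal baseline -- simple, but sufficient for a
  rank-based screen;
* chimera-producing events place the partner breakpoint in intron 1 of a
  real partner gene and emit junction evidence (3-10 reads) at the
  model-predicted donor/acceptor; non-chimera events use intergenic
  partners and emit none;
* amplified confounders receive copy-number score 2 and elevated
  expression of a planted target *without* any SV, exercising the
  amplification-exclusion path;
* germline events appear at identical coordinates in several tumor
  samples and in the panel of normals; per-sample repeat-artifact and
  low-read-support calls exercise the ingest filters;
* background somatic SVs default to 1 per sample, which reproduces on
  the default 60 Mb toy genome the breakpoint density of real tumor WGS
  cohorts (about 50 SVs per 3 Gb genome, i.e. ~0.017 SV/Mb/sample).
  This calibration matters: because the toy genome is small, every 4 Mb
  window is a large fraction of it, and an inflated background rate
  fills the distance-ordered candidate lists with interleaved noise
  samples in a way real genomes do not.

All randomness derives from the single config seed; the annotation and
the cohort are byte-reproducible, and the ground-truth manifest records
targets, modes, samples, distances, folds and expected CP/N-CP labels.
`write_fixture_files()` / `read_cohort_dir()` round-trip everything
through plain-text formats (GTF, per-sample BEDPE, TSV matrices, UCSC
cytoband layout, BED repeats, JSON manifest).

What the simulator does **not** emulate -- and hence what green tests do
not demonstrate about real data: read-level artifacts (alignability,
mapping bias), caller-specific breakend inaccuracy, subclonal variant
allele fractions, correlated expression programs (the screen's control
groups in real cohorts contain biology, not i.i.d. noise), multiple
isoforms per gene, and copy-number states other than the discrete
amplification score.

## Numerical and design choices

* Coordinates: 1-based inclusive internally; GTF read/written 1-based,
  BED/BEDPE 0-based half-open at the boundary. Chromosome names are
  matched verbatim; a vocabulary mismatch is an explicit error listing
  both sides rather than a silent `chr`-prefix fix.
* Support filter: high-coverage call sets keep junctions with
  discordant + split reads >= 6 (the "and/or" of combined evidence);
  low-coverage call sets require >= 2 discordant and >= 1 split.
  Germline matching drops a call when both breakends match a
  panel-of-normals call within 100 bp; repeat filtering drops a call
  only when *both* breakends lie in repeats. Filters are idempotent and
  commute.
* Split-search determinism: distance ties break by sample id; the
  minimum-p split takes the smallest index on ties.
* Degenerate inputs: empty call sets are errors for `class_proportions`
  and empty results elsewhere; a constant expression vector gives p = 1;
  a missing comparison group gives no result rather than a fabricated
  one.
* Inversion adjacencies are never inferred: every call must carry
  explicit retained sides per breakend, and the simulator writes them.
* Problem sizes in the shipped tests: toy genomes of 40-100 genes on
  20-60 Mb, cohorts of 30-60 samples, 500 random split-search instances,
  200 null cohorts for calibration, exhaustive 2x2 tables up to 30
  observations. These sizes make every property checkable in minutes on
  one core while leaving each estimate comfortably away from its
  decision boundary.

## Limitations

The screen tests upregulation only in its 4 Mb form (downregulation is
covered by the nearest-upstream-gene screen); the min-p split selection
is reported with its selection bias rather than corrected by default;
CP/N-CP labels depend on the completeness of the junction evidence
table; and the cohort-scale numbers reported in the accompanying
analyses of real tumor cohorts (class fractions, recurrent event counts,
per-gene fold changes) are properties of controlled-access data that the
simulator only mirrors in regime, not in value.
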