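---
title: "Bait-and-pond candidate nomination: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bait-and-pond candidate nomination: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baitpond)
```

## The framework

Genes underlying the evolution of human intelligence are hard to pin down
directly: inter-species comparisons yield thousands of human-specific
genomic differences, almost all unrelated to cognition, while GWAS of
intelligence in human populations yield hundreds of associated loci whose
causal genes are unresolved. `baitpond` implements the intersection
strategy that combines the two axes of evidence:

* **bait** — genes located within GWAS intelligence-associated loci,
  carrying *intra*-species variation linked to cognitive phenotypes;
* **pond** — human-specific structural variations relative to the great
  apes (*inter*-species variation): STR contractions and expansions,
  insertions and deletions over 50 bp, hCONDELs (sequences conserved in
  other species but deleted in the human lineage), human-specific
  segmental duplications (HSDs, > 1 kb at > 90% similarity), inversions,
  and cross-species exon gains/losses.

A bait gene physically hit by a pond variation is a **prey gene**; prey
genes whose variation falls in exonic sequence — or which carry a
variation class admitted unconditionally (below) — become candidate
**human intelligence evolution genes** (HIEGs). Candidates are then
profiled for cerebral-cortex enrichment and cross-species neocortex
expression divergence.

The intersection is deliberately permissive: every gene in an associated
locus is bait, although typically only one gene per locus is causal, so
the candidate set knowingly contains false positives. The framework
enriches, it does not prove.

## Coordinates and the record model

All coordinates are 1-based and inclusive on both ends (the Ensembl
convention); BED input is converted on read. This convention is what the
packaged variation records verify under: for every ranged record,
`end - start + 1 == length_bp`, e.g. the 675-bp TRIOBP insertion at
37723443–37724117. One exon-gain record (PCCB, 136326325–136326385,
stated length 60) is off by one base under any consistent convention; the
span is stored as printed, the stated length is treated as authoritative,
and the row carries `length_flag = "convention-ambiguous"` rather than a
silent correction.

hCONDELs are stored as a single human anchor coordinate plus the length
of the ancestral sequence missing from the human genome: the human
footprint of a clean deletion is a point. Whether the printed anchor is
the 5′ edge or the midpoint of the deletion locus is not decidable from
the record itself; the package treats it as an anchor only (never
reconstructs an ancestral span from it), so nothing downstream depends on
that choice. Point-anchored deletions are handled identically.

## Pond admission

Size rules are applied at pond admission: insertions/deletions must
exceed 50 bp and HSDs must exceed 1 kb; rejected records are kept with a
reason, not discarded silently. STRs, hCONDELs and inversions carry no
size filter — the published definitions state none. A separate
`filter_hsd_large()` reproduces the published large-duplication subset
(> 5 kb). Admission is monotone: adding a source never removes a
previously admitted record.

## The kilobase-bucket overlap and its oracle

The operative intersection divides every coordinate by 1000 (integer
floor) and joins genes and variations whose bucket ranges intersect on
the same chromosome. Although introduced as a computational-efficiency
device, the division changes semantics: a variation up to 999 bp outside
a gene can share its bucket. Both behaviours are preserved —
`kb_bucket_overlap()` is the pipeline's method and records `within_gene`
(whether the exact spans intersect); `exact_overlap_oracle()` is the
exact interval intersection, used for verification. The invariant
`exact ⊆ bucket` holds for every bucket width and the two coincide at
width 1; the test suite checks both against an independent brute-force
pairwise oracle on random instances. Full spans are bucketed, not just
start coordinates: bucketing only starts would miss a long variation
whose tail reaches a gene, which the exact intersection would find, and
would break the containment invariant.

## Alignment validation

Candidate variations inherited from published call sets are confirmed
against ape sequence by Smith–Waterman local alignment
(match +1, mismatch −2, gap open 5, gap extend 2 — BLASTn-like scoring,
via `Biostrings::pairwiseAlignment`). A segment counts as *found* in a
target when the local alignment reaches ≥ 90% identity over ≥ 80% of the
segment length. An E-value cutoff is not used: E-values are
database-size dependent and meaningless for a pairwise desk-scale
comparison, so the identity/coverage rule stands in for "detectable with
a local BLAST"; both thresholds are arguments. What coverage constituted
"undetectable" in the original filter is unstated, so the 80% rule is a
configurable stand-in.

A case validates only if **every** supplied ape species shows the
human-specific state: for insertion-like records, both human flanks
anchor in the ape but the inserted segment is not found; for
deletion-like records, the ancestral segment is found in the ape but not
in the human sequence. Flank anchoring uses a fixed 0.9 identity so the
verdict is monotone in `min_identity`: raising it only makes ape matches
of the segment rarer, moving insertion verdicts from rejected toward
validated. Species with missing sequence are skipped with a warning;
default flank is 500 bp per side — long enough to anchor uniquely in
random sequence, short enough that each case aligns in milliseconds.

## Positional classification and the admission rule

Each prey variation is classified against *every* isoform of its gene
and the most consequential class wins:
`CDS_EXON > UTR5/UTR3 > NONCODING_EXON > INTRON > FLANK`, with the UTR
side resolved strand-aware. `FLANK` is reserved for bucket-only hits.

"Coding regions" is interpreted as exonic sequence of any isoform,
including UTRs and exons of non-coding isoforms: the published candidate
list itself admits a 3′UTR insertion (GNB5) and processed-transcript
exons (ARIH2, STAB1, TSNARE1), so a CDS-only reading would contradict
the list it is meant to reproduce. The admission rule is therefore:

1. any variation with class `CDS_EXON`, `UTR5`, `UTR3` or
   `NONCODING_EXON` admits its gene;
2. hCONDELs, HSDs and exon gains/losses admit their gene regardless of
   position (all 28 packaged hCONDELs are intronic yet admitted — their
   lineage specificity is the evidence, not their position);
3. inversions never admit a gene. This is a deliberate narrowing of
   rule 1: a multi-kilobase inversion span covers whole genes, so the
   literal exon-located rule would promote every inversion-hit gene,
   contradicting the published outcome (no inversion candidates).
   Inversions are audited instead: `check_inversion_breakpoints()`
   reports, per gene, `inside` / `at_breakpoint` / `outside` — a gene
   wholly inside an inversion is repositioned but intact, whereas a
   breakpoint inside a gene would disrupt it.

Category accounting maps exon gain/loss → `EXON_GAIN_LOSS`, hCONDEL →
`HCONDEL`, HSD → `HSD`, exon-located STRs → `STR`, and remaining
exon-located indels → `INDEL`. An insertion co-identified as an STR
expansion (`also_str`) counts under `STR`, not `INDEL` — the reading
under which the packaged records sum correctly: 2 + 28 + 1 + 8 + 4 = 43
gene×category slots over 40 unique genes, with exactly three
dual-category genes. Exon gain/loss detection compares exon sequences of
all isoforms across species with the validator's aligner: a human exon
matching no ape exon of the gene in any species is a gain; the relation
is antisymmetric under swapping the species roles.

## Expression profiling

**Cortex enrichment.** For each gene, the ratio of cerebral-cortex TPM
to the mean over all 37 panel tissues; the mean includes the cortex
itself (the stated "relative to the average in 37 tissues", read
literally — with 37 tissues the two readings differ by under 3%).
Ratio > 1 flags enrichment, > 2 strong enrichment. Strongly enriched
genes are typed into the three verbally described patterns using
configurable cutoffs: `CORTEX_RELATIVE` (weakly expressed overall: row
maximum below the median per-gene maximum), `CORTEX_DOMINANT` (cortex is
the row maximum), else `BROAD`.

**Cross-species fold change.** Mean over the focal species' neocortex
samples divided by the mean over all other species' neocortex samples
pooled equally (a single fold change per gene is reported, so per-species
detail is not reconstructable; pooling is the default, and computing per
region first is a caller-side variation on the same matrix).
Reciprocity `FC(A/B) · FC(B/A) = 1` holds exactly for positive means.

**Clustering.** Samples are clustered on 1 − Pearson distance with
average linkage. Values are `log2(x + 1)`-transformed first: Pearson on
raw TPM/RPKM is leveraged by the few highest-expressed genes
(expression is approximately log-normal), which makes merge heights —
and hence tree cuts — unstable even when clades are correct; the log
transform is the field's standard preprocessing and can be disabled.
Columns are ordered by sample label before clustering, making the result
independent of input order up to that tie-break. The clade report states
per species whether its neocortex samples are monophyletic, and per
non-neocortex tissue (cerebellum, striatum, hippocampus) whether the
tissue groups across species; `neocortex_clade_purity()` scores the
species partition of neocortex samples by adjusted Rand index.

## The synthetic-data generator

No external genomes, call sets or expression atlases are downloaded;
the generator produces every input with known ground truth.

* **Genome**: non-overlapping genes on several chromosomes, each with a
  principal coding isoform (UTRs inset in the terminal exons), a
  processed transcript whose single exon is private to an intron, and —
  for exon-gain genes — a variant isoform with an extra exon mirrored by
  ape annotations that lack it. Intergenic gaps are at least 6 kb.
* **Pond**: variations planted at requested positional classes and
  verified against the annotation; intergenic decoys placed ≥ 2 kb from
  any gene, where not even the bucket method can reach them; optional
  flank placements just outside genes exercise the bucket-only regime.
  Gene-spanning inversions keep their breakpoints intergenic.
* **GWAS**: one lead SNP per intended bait gene (plus deliberate
  duplicates from a second study, and X-linked genes the bait stage must
  drop), grouped into loci.
* **Validation cases**: for each planted indel, the ape sequence is the
  reverse edit of the human one; a configurable fraction is
  false-specific (ape carries the human state), which the validator must
  reject.
* **Expression**: log-normal baselines; multiplicative cortex effects
  (defaults: 12 genes at 4× and 11 at 1.5×, giving 23 enriched of which
  12 strongly — the shape of the published panel); additive per-species
  neocortex signatures (s.d. 2 on the log scale) against log-scale noise
  (s.d. 0.25, signal-to-noise 8); planted focal/other fold changes (one
  gene at 4.8, five at 0.25) with the species signature zeroed on those
  genes so the planted value is exact at zero noise; shared tissue
  signatures for the non-neocortical regions.

Random streams are per component (genome / pond / expression), derived
from the master seed, so changing expression parameters does not perturb
the genome. The `paper-scale` preset sizes the conditions to the
published integration — 549 bait genes in 271 loci, pond totals of
1,465/4,921 STR contractions/expansions, 11,899 insertions, 5,894
deletions, 625 inversions, 218 large HSDs, ~510 hCONDELs — with planted
prey structure (26 + 74 STR-hit genes, 144/298 insertion and 94/148
deletion genes and variations, 31 inversion-hit genes, 28 hCONDEL genes,
one HSD gene, two exon-gain genes) whose exon-located subset reproduces
the published candidate composition. Inversion and HSD decoy lengths are
scaled down (9–10 kb and 5–9 kb) to fit the synthetic intergenic space;
the published inversions ranged up to 8.4 Mb.

What the generator does **not** emulate: linkage disequilibrium and real
locus structure, recombination, phylogenetic sequence evolution
(variations are literal edits into random sequence), polymorphism within
species, alignment artefacts, and the overlap structure of real call
sets. Passing tests therefore demonstrate the correctness of the rules
and their composition, not performance on real genomes — in particular,
the genome-scale published outcomes that depend on the external call
sets (213 prey genes / 406 variations, the specific enriched genes)
are not reproduced, only their counting structure.

## Problem sizes and determinism

The default ("small") conditions are 30 autosomal genes on 3
chromosomes, 2 X-linked genes, ~260 pond records, 11 planted candidate
variations across 10 genes, and 40-gene expression matrices; a full
small-preset simulation plus pipeline runs in a few seconds, and the
paper-scale preset (549 genes, ~25,000 pond records) in well under a
minute. All generation and analysis is deterministic given the seed;
hierarchical clustering ties are broken by sample-label order.

## Known limitations

* Locus merging across studies is taken from the input locus
  identifiers; the package does not re-cluster loci, and nearest-gene
  assignments are consumed as given (the source GWAS annotations),
  never recomputed.
* The validator models clean edits; it has no model of sequencing error,
  paralogy, or segmental-duplication cross-matching, so its perfect
  panel separation is a property of clean inputs.
* Exon gain/loss calls depend on the supplied transcript sets; an exon
  missing from an incomplete ape annotation is indistinguishable from a
  true gain.
* Principal-isoform designation is read from the annotation's flags;
  no APPRIS-like scoring is performed.
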