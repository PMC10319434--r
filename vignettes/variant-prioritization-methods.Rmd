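---
title: "Methods: family-based rare-variant prioritization for recessive oocyte maturation arrest"
author: "TrioCascade authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-based rare-variant prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TrioCascade)
```

## The problem and the procedure

Primary female infertility with oocyte maturation arrest at metaphase I is,
in a subset of patients, a recessive Mendelian condition: both copies of a
gene required for meiotic progression are inactivated.  Finding such a gene
from whole-exome sequencing of a patient cohort is a filtering problem, not
a statistical one — per exome there are on the order of $10^4$–$10^5$
called variants, and a cascade of hard criteria reduces them to a handful
of candidate genes:

1. **Rarity.** Keep variants whose minor allele frequency is below 1% in
   every scanned reference database (five by default: dbSNP, the 1000
   genomes panel, EVS, ExAC, gnomAD).  A variant *absent* from every
   database passes: absence is weaker evidence than an observed common
   frequency, and truly novel pathogenic alleles are expected to be
   unobserved.  "Not observed" is therefore represented as `NA`,
   deliberately distinct from frequency 0.
2. **Functional class.** Keep exonic nonsynonymous variants (stopgain,
   missense), coding indels (frameshift or in-frame) and splice-site
   variants within 2 bp of an exon/intron boundary; drop synonymous,
   UTR, deep-intronic and intergenic calls.
3. **Recessive inheritance.** In each trio, keep (a) variants homozygous
   in the affected proband with both parents heterozygous carriers, and
   (b) gene-wise pairs of heterozygous variants compatible with a
   compound heterozygote, i.e. one allele demonstrably from each parent
   (*trans*).  Sex chromosomes are excluded.
4. **Autozygosity.** In consanguineous families, homozygous candidates
   inside runs of homozygosity (ROH) longer than 2 Mb are prioritized —
   a recessive allele identical by descent is expected inside such a run.
5. **Recurrence.** Intersect candidate genes across unrelated families
   (at least two by default).
6. **Expression.** Require the candidate gene to be expressed (TPM ≥ 1 in
   at least one oocyte stage: GV, MI or MII) in an oocyte expression
   table.  A gene absent from the table is dropped: the criterion demands
   positive evidence of expression.

One manual step of the original screens is reproduced mechanically: a
deep-intronic allele discarded at stage 2 is *rescued* when the same gene
still carries a surviving rare heterozygous loss-of-function allele in the
same patient and the two are plausible *trans* partners.  This is how a
frameshift-plus-intronic compound heterozygote survives a pipeline that
would otherwise see only one half of it.  A rescue can never re-admit a
variant that failed the rarity filter, because only stage-2 casualties are
eligible.

## Coordinate arithmetic and consequence calls

Variant characterization uses a `TranscriptModel`: forward-strand exon
intervals, genomic CDS bounds, and the spliced coding sequence.  Genomic
positions map to coding (c.) positions by exon-offset arithmetic;
intronic positions map to the nearest exonic anchor with a signed offset
(`c.21-94` is 94 bp upstream of coding position 21, on the acceptor side).
The codon index of coding position $p$ is $\lceil p/3 \rceil$; a premature
stop at codon $s$ of an $L$-residue protein removes $L - s + 1$ residues
(the replaced residue counts as lost).  Frameshift naming translates the
shifted frame from the first altered codon to the first stop, extending
into the 3' UTR sequence when provided, and reports `p.X###Yfs*N` with N
counting the first changed residue as 1; an immediate stop collapses to
nonsense-style naming.  Only this HGVS subset is implemented (`c.N`,
`c.N±off`, `c.NdelX`, `p.X###*`, `p.X###Yfs*N`) — it covers every variant
class the cascade retains; duplications, insertions and extensions are
named by position only.

The packaged MAD2L1BP transcript fixture is **synthetic**: it is built to
satisfy simultaneously all published anchor points of the real gene (the
four genomic/cDNA coordinate pairs, + strand on chromosome 6, a 306-residue
protein, arginine codons at 181 and 285, phenylalanine at 173 with a
downstream codon arrangement that makes the 1-bp deletion at c.518 read
`p.F173Sfs*4`).  It is not the real exon annotation; tests verify it
against the published coordinate pairs rather than trusting it.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `mafThreshold` | 0.01 | fraction | the "MAF below 1%" rarity rule; strict `<` |
| `spliceWindow` | 2 | bp | common exome-annotator convention for "splice site" |
| `minLengthBp` (ROH) | 2e6 | bp | ">2 Mb" rule; strictly greater on span |
| `minSites`, `hetTolerance`, `windowSites` | 25, 1, 50 | sites | conventional exome-ROH settings; configurable |
| `maxGapBp` | 5e5 | bp | site-desert limit (below) |
| `minFamilies` | 2 | families | "at least two unrelated affected women"; 3 gives the strict three-family intersection |
| `tpmMin` | 1 | TPM | "expressed" cutoff, `>=` at the boundary |

**ROH gap semantics.** The detector is a deterministic streak scan:
maximal homozygous runs tolerating at most `hetTolerance` heterozygous
calls per `windowSites`-site trailing window.  `maxGapBp` bounds the
distance between consecutive informative sites within one segment — a run
never extends across a larger site desert (the PLINK-style gap rule).  We
deliberately do *not* merge het-separated runs by physical distance: at
exome site density (one informative site per tens of kb) every pair of
adjacent runs is within half a megabase, so distance-based merging chains
across unlimited heterozygous calls and degenerates to whole-chromosome
segments.  With `hetTolerance = 0` and `maxGapBp = 0` the detector is
exactly the maximal-run scan, which is how it is property-tested.  ROH is
computed on the *pre-filter* site set; the rare subset alone is far too
sparse to support 2 Mb runs.

**Phasing policy.** Compound-het pairs with one ungenotyped parent, or an
allele carried by both parents, are retained as `phase_unknown` and ranked
below `trans_confirmed` pairs; pairs whose two alleles trace to the same
single parent are rejected as *cis*.  Unaffected siblings homozygous for a
candidate reject it under strict mode (the default) and merely warn under
lenient mode; affected siblings are never used as exclusion evidence.

**Ranking.** The final order is deterministic: shared-gene membership,
then homozygous-in-ROH (consanguineous families), homozygous, trans
compound-het, unphased compound-het; ties break by (gene, chromosome,
position), so the ranking is invariant to input order.

## The synthetic cohort generator

Since patient-level exome data for such cohorts are not publicly
deposited, validation runs on simulated trios whose statistical structure
matches what the cascade assumes:

* **Variant list scale and spectrum.** Each family's VCF carries
  `nBackgroundVariants` records (default 20,000; 130,000 in full-scale
  runs).  The emitted records follow a mixture: 93% common alleles
  (AF ~ U(0.01, 0.5)), 5% rare tail (exponential, mean 0.001, truncated
  below 0.01), 2% absent from every database.  These fractions were fixed
  once to reproduce the order of magnitude of published per-stage counts
  (a few percent of an exome's variant list survives the multi-database
  MAF filter); they are the *emitted-record* spectrum, i.e. the spectrum
  of a family's variant list, not of a population site-frequency
  spectrum.
* **Genotypes.** At each emitted site the four founder alleles are drawn
  Bernoulli(AF) conditioned on the family carrying at least one
  alternate allele (a joint-called family VCF only contains such rows);
  offspring inherit one uniformly chosen allele per parent, so emitted
  genotypes contain zero Mendelian errors by construction.  The exported
  `simulateTrioGenotypes()` is the unconditional version of the same
  model.
* **Placement.** Variants are placed by category — coding SNV, coding
  indel, splice site, intronic, UTR, intergenic — over ~300 synthetic
  multi-exon genes on three 40 Mb chromosomes.  The realized
  stopgain/missense/synonymous split of coding SNVs follows from the
  actual codon change against the generated CDS, keeping the VCF
  internally consistent with the gene models the consequence caller
  reads.
* **Autozygosity.** Consanguineous probands receive contiguous blocks
  (2.5–10 Mb) in which the maternally transmitted allele is forced
  identical in state to the paternally transmitted one (IBD sharing), so
  the proband is homozygous at every block site while transmission stays
  Mendelian.
* **Planted truth.** Scenarios plant a homozygous nonsense allele inside
  a block (consanguineous family), a *trans* frameshift + deep-intronic
  pair (10–200 bp inside an intron of the causal gene), or a homozygous
  nonsense without a block; planted alleles are absent from all frequency
  tables, and the causal gene's expression is forced ≥ 1 TPM.  A truth
  table records every planted record for end-to-end recovery checks.

What the simulator does **not** model: linkage disequilibrium between
background sites, sequencing or genotyping error beyond simple
missingness, population structure, mosaicism, and multi-nucleotide
haplotype effects.  A green test suite therefore shows the *logic* of the
cascade is correct under its own assumptions, not that it is robust to
real-data artifacts such as miscalled genotypes inside ROH or strand
misannotation.

## Numerical and degenerate-input choices

* Indel alleles are normalized (shared suffix then prefix trimmed,
  position advanced) before any frequency-table join, so differing VCF
  representations key identically.
* Multi-allelic rows decompose into one biallelic record per ALT; an
  allele equal to a *different* ALT codes as REF for that record, which
  conserves total ALT dosage across the decomposition.
* Missing genotypes are uninformative everywhere: they drop out of ROH
  scans, relax (and flag) parental-carrier checks, and make compound-het
  phase `unknown` rather than rejecting the pair.
* Empty inputs flow through: an empty PED gives an empty family list, a
  candidate-free family contributes an empty gene set, and a report with
  no candidates still renders the full per-stage trace.
* The non-applicable in-ROH stage of non-consanguineous families is `NA`
  internally and rendered `-` in reports; monotonicity checks skip it.

## Problem sizes used in the shipped checks

The test suite simulates cohorts of 3 families x 2,500 background
variants for pipeline-level checks and one 130,000-variant family for the
full-scale trace check; planted-truth recovery runs 20 seeds of the
three-scenario shared-gene cohort.  These sizes were chosen as the
smallest at which every property under test (ROH site density inside
2.5 Mb blocks, background compound-het competition, the ≥10x MAF-stage
reduction) is comfortably expressed.

## Known limitations

* One canonical transcript per gene; overlapping genes resolve to the
  first span hit.
* Consequence calls trust the model's CDS sequence; a VCF whose REF
  disagrees with the transcript sequence is not detected.
* Indels spanning an exon/intron boundary are classified by length
  arithmetic only and may be named by position only.
* The rescue path is deliberately narrow (intronic partners of surviving
  rare LoF hets) — it reproduces the published manual reconsideration,
  not a general re-ranking of discarded variants.
* External deleteriousness predictors (SIFT, PolyPhen-2, splice-site
  scores) are carried as pass-through annotations if present and never
  gate any stage.
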