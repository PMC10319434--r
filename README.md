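# TrioCascade

Family-based rare-variant prioritization for autosomal-recessive disease
gene discovery, built around the screen design used for oocyte
maturation arrest cohorts: patients with primary infertility whose
oocytes arrest at metaphase I, sequenced as trios (proband + parents) by
whole-exome sequencing.

It is aimed at genetics groups who need the *logic* of such a screen as
tested, reusable code: a filter cascade over per-family VCFs rather than
a black-box annotation service.

## The procedure

Each family's variant list (10⁴–10⁵ records) passes through a fixed
cascade:

1. **Rarity** — maximum observed MAF < 1% across five reference
   databases (dbSNP, 1000 genomes, EVS, ExAC, gnomAD); absence from all
   databases also passes ("not observed" ≠ frequency 0).
2. **Functional class** — keep stopgain, missense, coding indels and
   splice-site variants (±2 bp); drop synonymous/UTR/intronic/intergenic.
3. **Deep-intronic rescue** — a dropped intronic allele re-enters if its
   gene still carries a surviving rare heterozygous loss-of-function
   allele in the same patient and the two are plausible *trans* partners.
4. **Recessive inheritance** — homozygous-recessive (proband hom-alt,
   both parents carriers) and *trans*-configured compound heterozygotes;
   X/Y excluded.
5. **Autozygosity** — in consanguineous families, homozygous candidates
   inside runs of homozygosity > 2 Mb are prioritized.
6. **Cross-family recurrence and oocyte expression** — intersect
   candidate genes across unrelated families and require TPM ≥ 1 in at
   least one oocyte stage (GV/MI/MII).

Variant characterization uses transcript-model arithmetic: coding
position of a genomic position, codon index ⌈p/3⌉ (c.853 → codon 285),
truncated-tail length L − s + 1 (a stop at codon 285 of a 306-residue
protein removes 22 C-terminal residues), HGVS-lite cDNA/protein naming
including frameshift `fs*N` resolution and intronic offsets (`c.21-94`).

A deterministic synthetic-cohort generator (exome-scale variant lists,
Mendelian trios, autozygosity blocks, planted causal alleles with truth
files) makes every stage testable without any data download.

## Worked example

```r
library(TrioCascade)

## three simulated families: hom nonsense in ROH (consanguineous),
## frameshift + deep-intronic comp-het, hom nonsense; shared causal gene
cfg <- simulationConfig(nBackgroundVariants = 5000, seed = 7)
simulateCohort(cfg, "cohort")
rep <- runPipeline("cohort", pipelineParams(minFamilies = 3))
```

The run logs each stage per family:

```
[triocascade] F2: loaded 5002 variants
[triocascade] F2: 326 after MAF < 0.01 filter
[triocascade] F2: 24 after functional-class filter
[triocascade] F2: 1 intronic variant(s) rescued
[triocascade] F2: 1 recessive candidate(s) in 1 gene(s)
[triocascade] shared genes (>= 3 families): SIMG0080
```

and the consanguineous family's trace mirrors the cascade-summary shape
(counts are survivors per stage; the last row only applies to
consanguineous families):

```
FilterTrace [F1]
  total_variants               5001
  after_maf                    368
  after_functional             33
  after_inheritance_autosomal  4
  homozygous_only              4
  in_roh_gt2mb                 4
```

The ranked candidate list puts the planted gene first — homozygous-in-ROH
above the trans comp-het, shared-gene members above everything else:

```
  rank family_id     gene         model    phase_status in_roh      cdna protein_change
1    1        F1 SIMG0080 hom_recessive            <NA>   TRUE c.1126A>T        p.K376*
2    2        F3 SIMG0080 hom_recessive            <NA>  FALSE  c.824T>A        p.L275*
3    3        F2 SIMG0080  compound_het trans_confirmed  FALSE c.519-103           <NA>
```

Row 3 is the rescued deep-intronic allele paired in *trans* with its
frameshift partner.  `writeCandidateReport(rep, "report")` renders the
trace table, the candidate TSV (database-absent alleles print
"not found") and per-family ROH BED files.

One-off variant characterization against a gene model:

```r
m <- readTranscriptModels(
  system.file("extdata", "mad2l1bp_synthetic_model.tsv", package = "TrioCascade"),
  system.file("extdata", "mad2l1bp_synthetic_cds.fa",   package = "TrioCascade"))[[1]]
callConsequence(m, "chr6", 43608202, "C", "T")
#>       gene      transcript_id functional_class cds_pos ... codon protein_change
#> 1 MAD2L1BP MAD2L1BP_synthetic         stopgain     853 ...   285        p.R285*
```

(The packaged MAD2L1BP model is a synthetic reconstruction pinned to the
published coordinate anchors; see the methods vignette.)

A thin CLI wraps the same functions
(`exec/triocascade simulate|run|consequence|roh|summarize-clinical`).

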