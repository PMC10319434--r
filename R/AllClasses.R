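#' @import methods
#' @importClassesFrom IRanges IRanges
#' @importFrom IRanges IRanges
#' @importFrom stats rbinom runif rexp rnorm setNames
#' @importFrom utils read.table write.table read.csv write.csv head
NULL

## Genotype encoding used throughout: two integer allele matrices (sites x
## samples) with 0 = REF, 1 = ALT, NA = missing.  Zygosity and dosage are
## derived, never stored.

#' VariantSet: normalized biallelic variant calls for one family
#'
#' Container for a set of biallelic, decomposed variant records with
#' per-sample genotypes and an open annotation table.  Rows are variants
#' (sorted by chromosome then position), columns of the genotype matrices are
#' samples.  Allele values are 0 (REF), 1 (ALT) or NA (missing).
#'
#' @slot chrom character, chromosome per variant (as written in the VCF).
#' @slot pos integer, 1-based genomic position.
#' @slot ref,alt character, reference / single alternate allele (records from
#'   multi-allelic VCF rows are decomposed, one per ALT).
#' @slot id character, external identifier (e.g. rs number) or `"."`.
#' @slot alleleA,alleleB integer matrices of first/second allele per call.
#' @slot phased logical matrix, whether the call was phased (`|`) in the VCF.
#' @slot anno data.frame with one row per variant; open key-value bag where
#'   frequencies, consequence calls and filter flags attach.
#'
#' @export
setClass("VariantSet",
  representation(
    chrom = "character", pos = "integer",
    ref = "character", alt = "character", id = "character",
    alleleA = "matrix", alleleB = "matrix", phased = "matrix",
    anno = "data.frame"
  )
)

setValidity("VariantSet", function(object) {
  n <- length(object@chrom)
  msg <- character()
  if (length(object@pos) != n || length(object@ref) != n ||
      length(object@alt) != n || length(object@id) != n)
    msg <- c(msg, "field lengths differ")
  if (n > 0 && any(object@pos < 1L)) msg <- c(msg, "pos must be >= 1")
  if (n > 0 && (any(!nzchar(object@ref)) || any(!nzchar(object@alt))))
    msg <- c(msg, "ref/alt must be non-empty")
  if (n > 0 && any(object@ref == object@alt))
    msg <- c(msg, "ref must differ from alt")
  for (sl in c("alleleA", "alleleB", "phased")) {
    m <- slot(object, sl)
    if (nrow(m) != n) msg <- c(msg, sprintf("%s has wrong row count", sl))
  }
  if (!identical(colnames(object@alleleA), colnames(object@alleleB)))
    msg <- c(msg, "allele matrices disagree on samples")
  if (nrow(object@anno) != n && !(nrow(object@anno) == 0 && n == 0))
    msg <- c(msg, "anno has wrong row count")
  if (length(msg)) msg else TRUE
})

#' Pedigree: one family with affected status and consanguinity flag
#'
#' @slot familyId single string.
#' @slot samples data.frame with columns `sample_id`, `father`, `mother`
#'   (NA when unknown), `sex` (1 male, 2 female, NA unknown) and `affected`
#'   (TRUE/FALSE/NA for unknown).
#' @slot consanguineous logical flag for the family.
#'
#' @export
setClass("Pedigree",
  representation(familyId = "character", samples = "data.frame",
                 consanguineous = "logical")
)

setValidity("Pedigree", function(object) {
  s <- object@samples
  need <- c("sample_id", "father", "mother", "sex", "affected")
  if (!all(need %in% names(s))) return("samples lacks required columns")
  for (p in c("father", "mother")) {
    bad <- !is.na(s[[p]]) & !(s[[p]] %in% s$sample_id)
    if (any(bad))
      return(sprintf("dangling %s reference for sample(s): %s", p,
                     paste(s$sample_id[bad], collapse = ", ")))
  }
  if (!any(s$affected %in% TRUE))
    return("pedigree has no affected sample")
  TRUE
})

#' FrequencyTable: population allele frequencies from one database
#'
#' Absent keys mean "not observed in this database", which is distinct from
#' frequency zero: a variant missing from every database still passes the
#' rarity filter (the cascade keeps "Not found" alleles).
#'
#' @slot dbName database label (e.g. "gnomAD").
#' @slot keys character vector "chrom:pos:ref:alt" (normalized alleles).
#' @slot af numeric vector in [0, 1], parallel to `keys`.
#'
#' @export
setClass("FrequencyTable",
  representation(dbName = "character", keys = "character", af = "numeric")
)

setValidity("FrequencyTable", function(object) {
  if (length(object@keys) != length(object@af))
    return("keys and af lengths differ")
  if (anyDuplicated(object@keys))
    return("duplicate variant key in frequency table")
  if (length(object@af) && (any(object@af < 0) || any(object@af > 1)))
    return("allele frequency outside [0, 1]")
  TRUE
})

#' TranscriptModel: exon structure and coding sequence of one transcript
#'
#' Exons are stored as 1-based inclusive genomic intervals on the forward
#' strand, sorted by genomic position regardless of transcript strand; cDNA
#' numbering runs along the coding strand.
#'
#' @slot transcriptId,gene identifier strings.
#' @slot chrom chromosome name.
#' @slot strand "+" or "-".
#' @slot exons [IRanges::IRanges] of exon intervals.
#' @slot cdsStart,cdsEnd genomic bounds of the coding region (forward strand).
#' @slot cdsSequence spliced coding sequence (coding strand, `ATG..stop`) or
#'   `NA_character_` when unavailable; required for protein-level naming.
#' @slot utr3Sequence optional genomic continuation of the coding sequence
#'   (3' UTR on the coding strand) used when a frameshifted frame runs past
#'   the canonical stop.
#'
#' @export
setClass("TranscriptModel",
  representation(
    transcriptId = "character", gene = "character", chrom = "character",
    strand = "character", exons = "IRanges",
    cdsStart = "integer", cdsEnd = "integer",
    cdsSequence = "character", utr3Sequence = "character"
  )
)

setValidity("TranscriptModel", function(object) {
  ex <- object@exons
  if (!object@strand %in% c("+", "-")) return("strand must be '+' or '-'")
  if (length(ex) == 0) return("transcript needs at least one exon")
  st <- IRanges::start(ex); en <- IRanges::end(ex)
  if (is.unsorted(st, strictly = TRUE)) return("exons must be sorted")
  if (length(ex) > 1 && any(st[-1] <= en[-length(ex)]))
    return("exons overlap")
  if (object@cdsStart < st[1] || object@cdsEnd > en[length(ex)])
    return("CDS bounds outside exons")
  if (!is.na(object@cdsSequence)) {
    cs <- object@cdsSequence
    if (nchar(cs) %% 3 != 0) return("cds_sequence length not multiple of 3")
    if (substr(cs, 1, 3) != "ATG") return("cds_sequence must start with ATG")
    last <- substr(cs, nchar(cs) - 2, nchar(cs))
    if (!last %in% c("TAA", "TAG", "TGA"))
      return("cds_sequence must end with a stop codon")
    ov <- pmin(en, object@cdsEnd) - pmax(st, object@cdsStart) + 1L
    if (sum(ov[ov > 0]) != nchar(cs))
      return("cds_sequence length disagrees with coding-exon overlap")
  }
  TRUE
})

#' FilterTrace: per-stage surviving counts for one family
#'
#' Stage names mirror the published cascade summary rows: total variants,
#' after the multi-database MAF filter, after the functional-class filter,
#' candidate genes under the autosomal recessive models, homozygous-only
#' genes, and homozygous candidates inside runs of homozygosity > 2 Mb (NA
#' for non-consanguineous families, rendered "-").  Rescued variants are
#' tallied separately, never added back to earlier stages.
#'
#' @slot familyId single string.
#' @slot counts named integer vector over the fixed stage names.
#' @slot rescued integer, number of rescued (re-included) variants.
#'
#' @export
setClass("FilterTrace",
  representation(familyId = "character", counts = "integer",
                 rescued = "integer")
)

traceStages <- c("total_variants", "after_maf", "after_functional",
                 "after_inheritance_autosomal", "homozygous_only",
                 "in_roh_gt2mb")

setValidity("FilterTrace", function(object) {
  if (!identical(names(object@counts), traceStages))
    return("counts must be named by the fixed stage list")
  x <- object@counts[!is.na(object@counts)]
  if (any(x < 0)) return("counts must be nonnegative")
  if (is.unsorted(rev(x))) return("stage counts must be nonincreasing")
  TRUE
})

#' CohortReport: full output of the prioritization pipeline
#'
#' @slot traces named list of [FilterTrace-class], one per family.
#' @slot candidates data.frame of ranked candidates (rank 1 first).
#' @slot familyGenes named list of candidate gene sets per family.
#' @slot sharedGenes genes recurring in >= `min_families` families.
#' @slot rohSegments named list of per-family ROH segment data.frames.
#' @slot params the `pipelineParams()` list the run used.
#'
#' @export
setClass("CohortReport",
  representation(traces = "list", candidates = "data.frame",
                 familyGenes = "list", sharedGenes = "character",
                 rohSegments = "list", params = "list")
)
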