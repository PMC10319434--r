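#' @include AllClasses.R
NULL

#' Number of variants in a VariantSet
#' @param x a `VariantSet`.
#' @return integer count.
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' Sample identifiers carried by an object
#' @param x a `VariantSet` or `Pedigree`.
#' @return character vector of sample ids.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Canonical variant keys "chrom:pos:ref:alt"
#' @param x a `VariantSet`.
#' @return character vector of keys.
#' @export
setGeneric("variantKeys", function(x) standardGeneric("variantKeys"))

#' ALT-allele dosage per call
#' @param x a `VariantSet`.
#' @param sample sample id(s); default all samples.
#' @return integer matrix (variants x samples) of 0/1/2, NA when either
#'   allele is missing.
#' @export
setGeneric("dosage", function(x, sample = NULL) standardGeneric("dosage"))

#' Zygosity per call
#' @param x a `VariantSet`.
#' @param sample sample id(s); default all samples.
#' @return character matrix over `hom_ref`, `het`, `hom_alt`, `missing`.
#' @export
setGeneric("zygosity", function(x, sample = NULL) standardGeneric("zygosity"))

#' Variant annotations
#' @param x a `VariantSet`.
#' @return the annotation `data.frame` (one row per variant).
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' Replace variant annotations
#' @param x a `VariantSet`.
#' @param value data.frame with `nVariants(x)` rows.
#' @export
setGeneric("annotations<-",
           function(x, value) standardGeneric("annotations<-"))

#' Per-stage survivor counts of a filter trace
#' @param x a `FilterTrace` or `CohortReport`.
#' @param ... unused.
#' @return named integer vector (or list of them for a report).
#' @export
setGeneric("traceCounts", function(x, ...) standardGeneric("traceCounts"))
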