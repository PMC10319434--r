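#' @include AllGenerics.R
NULL

#' Construct a VariantSet
#'
#' Low-level constructor used by the readers and the simulator.  Records are
#' sorted by (chrom, pos, alt); multi-allelic decomposition and allele
#' normalization are the reader's job, not the constructor's.
#'
#' @param chrom,pos,ref,alt,id parallel per-variant vectors (`id` optional).
#' @param alleleA,alleleB integer matrices (variants x samples), 0 = REF,
#'   1 = ALT, NA = missing; column names are sample ids.
#' @param phased optional logical matrix, defaults to all-unphased.
#' @param anno optional annotation data.frame.
#' @return a [VariantSet-class].
#' @examples
#' gt <- matrix(c(0L, 1L), 1, 2, dimnames = list(NULL, c("P1", "M1")))
#' VariantSet("chr1", 100L, "A", "T", alleleA = gt, alleleB = gt)
#' @export
VariantSet <- function(chrom, pos, ref, alt, id = NULL,
                       alleleA, alleleB, phased = NULL, anno = NULL) {
  n <- length(chrom)
  if (is.null(id)) id <- rep(".", n)
  if (is.null(phased))
    phased <- matrix(FALSE, n, ncol(alleleA),
                     dimnames = dimnames(alleleA))
  if (is.null(anno)) anno <- data.frame(row.names = seq_len(max(n, 0L)))
  pos <- as.integer(pos)
  o <- order(chrom, pos, alt)
  x <- new("VariantSet", chrom = as.character(chrom)[o], pos = pos[o],
           ref = as.character(ref)[o], alt = as.character(alt)[o],
           id = as.character(id)[o],
           alleleA = alleleA[o, , drop = FALSE],
           alleleB = alleleB[o, , drop = FALSE],
           phased = phased[o, , drop = FALSE],
           anno = anno[o, , drop = FALSE])
  validObject(x)
  x
}

#' @describeIn nVariants number of variant records.
#' @export
setMethod("nVariants", "VariantSet", function(x) length(x@chrom))

#' @describeIn sampleIds samples genotyped in the set.
#' @export
setMethod("sampleIds", "VariantSet", function(x) colnames(x@alleleA))

#' @describeIn sampleIds samples listed in the pedigree.
#' @export
setMethod("sampleIds", "Pedigree", function(x) x@samples$sample_id)

#' @describeIn variantKeys canonical "chrom:pos:ref:alt" keys.
#' @export
setMethod("variantKeys", "VariantSet", function(x)
  paste(x@chrom, x@pos, x@ref, x@alt, sep = ":"))

#' @describeIn dosage ALT dosage matrix.
#' @export
setMethod("dosage", "VariantSet", function(x, sample = NULL) {
  a <- x@alleleA; b <- x@alleleB
  if (!is.null(sample)) {
    missing <- setdiff(sample, colnames(a))
    if (length(missing))
      stop("unknown sample(s): ", paste(missing, collapse = ", "))
    a <- a[, sample, drop = FALSE]; b <- b[, sample, drop = FALSE]
  }
  a + b
})

#' @describeIn zygosity zygosity matrix.
#' @export
setMethod("zygosity", "VariantSet", function(x, sample = NULL) {
  d <- dosage(x, sample)
  z <- matrix("missing", nrow(d), ncol(d), dimnames = dimnames(d))
  z[!is.na(d) & d == 0L] <- "hom_ref"
  z[!is.na(d) & d == 1L] <- "het"
  z[!is.na(d) & d == 2L] <- "hom_alt"
  z
})

#' @describeIn annotations annotation accessor.
#' @export
setMethod("annotations", "VariantSet", function(x) x@anno)

#' @describeIn annotations-set annotation replacement.
#' @param x a `VariantSet`.
#' @param value replacement data.frame.
#' @export
setReplaceMethod("annotations", "VariantSet", function(x, value) {
  stopifnot(is.data.frame(value), nrow(value) == nVariants(x))
  x@anno <- value
  x
})

#' Subset a VariantSet by variant index
#' @param x a `VariantSet`.
#' @param i integer or logical index over variants.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "VariantSet", function(x, i, j, ..., drop = FALSE) {
  new("VariantSet", chrom = x@chrom[i], pos = x@pos[i], ref = x@ref[i],
      alt = x@alt[i], id = x@id[i],
      alleleA = x@alleleA[i, , drop = FALSE],
      alleleB = x@alleleB[i, , drop = FALSE],
      phased = x@phased[i, , drop = FALSE],
      anno = x@anno[i, , drop = FALSE])
})

#' Variant records as a data.frame
#'
#' @param x a `VariantSet`.
#' @param annotations include annotation columns (default TRUE).
#' @return data.frame with chrom, pos, ref, alt, id and annotations.
#' @export
variantTable <- function(x, annotations = TRUE) {
  stopifnot(is(x, "VariantSet"))
  df <- data.frame(chrom = x@chrom, pos = x@pos, ref = x@ref, alt = x@alt,
                   id = x@id, stringsAsFactors = FALSE)
  if (annotations && ncol(x@anno))
    df <- cbind(df, x@anno, row.names = NULL)
  df
}

setMethod("show", "VariantSet", function(object) {
  cat(sprintf("VariantSet with %d variants x %d samples\n",
              nVariants(object), length(sampleIds(object))))
  if (length(sampleIds(object)))
    cat("  samples:", paste(head(sampleIds(object), 8), collapse = ", "),
        if (length(sampleIds(object)) > 8) "..." else "", "\n")
  if (ncol(object@anno))
    cat("  annotations:", paste(names(object@anno), collapse = ", "), "\n")
})

#' Construct a Pedigree
#'
#' @param familyId family identifier.
#' @param samples data.frame with columns `sample_id`, `father`, `mother`,
#'   `sex`, `affected` (see [Pedigree-class]).
#' @param consanguineous logical family flag.
#' @return a [Pedigree-class].
#' @export
Pedigree <- function(familyId, samples, consanguineous = FALSE) {
  samples$sample_id <- as.character(samples$sample_id)
  samples$father <- as.character(samples$father)
  samples$mother <- as.character(samples$mother)
  x <- new("Pedigree", familyId = familyId, samples = samples,
           consanguineous = isTRUE(consanguineous))
  validObject(x)
  x
}

#' @describeIn Pedigree family identifier accessor.
#' @param x a `Pedigree`.
#' @export
familyId <- function(x) x@familyId

#' @describeIn Pedigree TRUE for consanguineous families.
#' @export
isConsanguineous <- function(x) x@consanguineous

#' Affected individuals of a family
#' @param ped a `Pedigree`.
#' @return character vector of affected sample ids.
#' @export
affectedIds <- function(ped) {
  s <- ped@samples
  s$sample_id[s$affected %in% TRUE]
}

#' The proband of a family
#'
#' The first affected individual with at least one recorded parent, falling
#' back to the first affected individual.
#' @param ped a `Pedigree`.
#' @return single sample id.
#' @export
probandId <- function(ped) {
  s <- ped@samples
  aff <- s[s$affected %in% TRUE, , drop = FALSE]
  withPar <- aff[!is.na(aff$father) | !is.na(aff$mother), , drop = FALSE]
  if (nrow(withPar)) withPar$sample_id[1] else aff$sample_id[1]
}

#' Parents of an individual
#' @param ped a `Pedigree`.
#' @param id sample id.
#' @return list with elements `father` and `mother` (NA when unknown).
#' @export
parentsOf <- function(ped, id) {
  s <- ped@samples
  row <- s[s$sample_id == id, , drop = FALSE]
  if (!nrow(row)) stop("unknown sample: ", id)
  list(father = row$father[1], mother = row$mother[1])
}

#' Siblings of an individual
#' @param ped a `Pedigree`.
#' @param id sample id.
#' @param affected NULL for all siblings, TRUE/FALSE to restrict.
#' @return character vector of sibling sample ids (sharing >= 1 known parent).
#' @export
siblingsOf <- function(ped, id, affected = NULL) {
  s <- ped@samples
  p <- parentsOf(ped, id)
  share <- (!is.na(s$father) & !is.na(p$father) & s$father == p$father) |
    (!is.na(s$mother) & !is.na(p$mother) & s$mother == p$mother)
  sib <- s[share & s$sample_id != id, , drop = FALSE]
  if (isTRUE(affected)) sib <- sib[sib$affected %in% TRUE, , drop = FALSE]
  if (isFALSE(affected)) sib <- sib[sib$affected %in% FALSE, , drop = FALSE]
  sib$sample_id
}

setMethod("show", "Pedigree", function(object) {
  cat(sprintf("Pedigree %s: %d samples, %d affected%s\n",
              object@familyId, nrow(object@samples),
              sum(object@samples$affected %in% TRUE),
              if (object@consanguineous) ", consanguineous" else ""))
})

setMethod("show", "FrequencyTable", function(object) {
  cat(sprintf("FrequencyTable '%s': %d entries\n",
              object@dbName, length(object@keys)))
})

setMethod("show", "TranscriptModel", function(object) {
  cat(sprintf(
    "TranscriptModel %s (%s) %s%s: %d exons, CDS %d..%d%s\n",
    object@transcriptId, object@gene, object@chrom, object@strand,
    length(object@exons), object@cdsStart, object@cdsEnd,
    if (is.na(object@cdsSequence)) "" else
      sprintf(", %d nt CDS", nchar(object@cdsSequence))))
})

#' @describeIn traceCounts counts of one family's trace.
#' @export
setMethod("traceCounts", "FilterTrace", function(x, ...) x@counts)

#' @describeIn traceCounts named list of per-family counts.
#' @export
setMethod("traceCounts", "CohortReport", function(x, ...)
  lapply(x@traces, traceCounts))

setMethod("show", "FilterTrace", function(object) {
  cat(sprintf("FilterTrace [%s]\n", object@familyId))
  for (s in names(object@counts))
    cat(sprintf("  %-28s %s\n", s,
                ifelse(is.na(object@counts[[s]]), "-", object@counts[[s]])))
  if (object@rescued > 0)
    cat(sprintf("  %-28s %d\n", "rescued (annotated)", object@rescued))
})

setMethod("show", "CohortReport", function(object) {
  cat(sprintf("CohortReport: %d families, %d ranked candidates\n",
              length(object@traces), nrow(object@candidates)))
  if (length(object@sharedGenes))
    cat("  shared genes:", paste(object@sharedGenes, collapse = ", "), "\n")
})

#' @describeIn CohortReport ranked candidate table accessor.
#' @param x a `CohortReport`.
#' @export
candidates <- function(x) x@candidates

#' @describeIn CohortReport shared-gene set accessor.
#' @export
sharedGeneSet <- function(x) x@sharedGenes
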