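#' @include io-freq.R consequence.R
NULL

#' Parameters of the variant filter cascade
#'
#' @param mafThreshold keep variants whose maximum observed allele frequency
#'   across the scanned databases is strictly below this (default 0.01, the
#'   "MAF below 1%" rule); absence from every database also passes.
#' @param databases database labels required for the max-AF scan.
#' @param spliceWindow bp window for "splicing" calls (default 2).
#' @param rescueEnabled run the deep-intronic rescue after the functional
#'   filter (default TRUE).
#' @return validated parameter list of class `FilterParams`.
#' @export
filterParams <- function(mafThreshold = 0.01,
                         databases = defaultDatabases(),
                         spliceWindow = 2L, rescueEnabled = TRUE) {
  stopifnot(mafThreshold > 0, mafThreshold < 1, spliceWindow >= 0)
  structure(list(mafThreshold = mafThreshold, databases = databases,
                 spliceWindow = as.integer(spliceWindow),
                 rescueEnabled = isTRUE(rescueEnabled)),
            class = "FilterParams")
}

#' Annotate per-database and maximum allele frequencies
#'
#' Adds one `af_<db>` column per table (NA = not observed in that database)
#' and `max_af`, the maximum over databases where the variant is present
#' (NA when absent from all: "not observed" is distinct from frequency 0).
#'
#' @param x a [VariantSet-class].
#' @param tables list of [FrequencyTable-class].
#' @return `x` with frequency annotations.
#' @export
annotateFrequencies <- function(x, tables) {
  keys <- variantKeys(x)
  anno <- annotations(x)
  afs <- matrix(NA_real_, nVariants(x), length(tables))
  for (j in seq_along(tables)) {
    afs[, j] <- lookupFrequency(tables[[j]], keys)
    anno[[paste0("af_", tables[[j]]@dbName)]] <- afs[, j]
  }
  maxAf <- suppressWarnings(apply(afs, 1, max, na.rm = TRUE))
  maxAf[!is.finite(maxAf)] <- NA_real_
  anno$max_af <- if (nVariants(x)) maxAf else numeric(0)
  annotations(x) <- anno
  x
}

#' Maximum observed allele frequency of one variant
#'
#' @param chrom,pos,ref,alt the variant.
#' @param tables list of [FrequencyTable-class].
#' @return the maximum frequency over databases containing the variant, or
#'   NA when it is observed in none ("not observed").
#' @export
maxObservedMaf <- function(chrom, pos, ref, alt, tables) {
  norm <- normalizeAlleles(pos, ref, alt)
  key <- paste(chrom, norm$pos, norm$ref, norm$alt, sep = ":")
  vals <- vapply(tables, function(t) lookupFrequency(t, key), 0)
  vals <- vals[!is.na(vals)]
  if (!length(vals)) NA_real_ else max(vals)
}

#' Rarity filter: MAF below threshold in every scanned database
#'
#' Keeps a variant iff its maximum observed frequency is strictly below the
#' threshold or it is absent from all databases.  Requires
#' [annotateFrequencies()] first.
#'
#' @param x an annotated [VariantSet-class].
#' @param params a [filterParams()] list.
#' @return list with `variants` (surviving set) and `count`.
#' @export
filterRare <- function(x, params = filterParams()) {
  if (!"max_af" %in% names(annotations(x)))
    stop("run annotateFrequencies() before filterRare()")
  maxAf <- annotations(x)$max_af
  keep <- is.na(maxAf) | maxAf < params$mafThreshold
  list(variants = x[keep], count = sum(keep))
}

lofClasses <- c("stopgain", "frameshift_deletion", "frameshift_insertion",
                "splicing")
keptFunctionalClasses <- c("stopgain", "missense", "frameshift_deletion",
                           "frameshift_insertion", "inframe_indel",
                           "splicing")

#' Functional-class filter
#'
#' Keeps exonic nonsynonymous variants, coding indels and splice-site
#' variants; drops synonymous, intronic, UTR and intergenic classes.
#' Requires [annotateConsequences()] first.
#'
#' @param x an annotated [VariantSet-class].
#' @param params a [filterParams()] list (unused beyond validation; the
#'   class set is fixed by the cascade definition).
#' @return list with `variants` (surviving set), `count`, and `dropped`
#'   (the removed records, the pool the rescue stage may re-inspect).
#' @export
filterFunctional <- function(x, params = filterParams()) {
  cls <- annotations(x)$functional_class
  if (is.null(cls))
    stop("run annotateConsequences() before filterFunctional()")
  bad <- is.na(cls) | !(cls %in% functionalClasses)
  if (any(bad))
    stop("unclassified variant(s): ",
         paste(head(variantKeys(x)[bad], 5), collapse = ", "))
  keep <- cls %in% keptFunctionalClasses
  list(variants = x[keep], count = sum(keep), dropped = x[!keep])
}

## Parental origin of a heterozygous proband allele: "father", "mother",
## "ambiguous" (both carry or de novo), or "unknown" (a parent ungenotyped).
parentalOrigin <- function(x, proband, father, mother) {
  d <- dosage(x)
  dp <- if (!is.na(father) && father %in% colnames(d)) d[, father]
        else rep(NA_integer_, nrow(d))
  dm <- if (!is.na(mother) && mother %in% colnames(d)) d[, mother]
        else rep(NA_integer_, nrow(d))
  out <- rep("ambiguous", nrow(d))
  out[is.na(dp) | is.na(dm)] <- "unknown"
  ok <- !is.na(dp) & !is.na(dm)
  out[ok & dp >= 1 & dm == 0] <- "father"
  out[ok & dm >= 1 & dp == 0] <- "mother"
  out
}

#' Deep-intronic rescue of functionally filtered variants
#'
#' Re-includes a dropped intronic variant iff (i) it lies in a gene that
#' still carries at least one surviving rare heterozygous loss-of-function
#' variant in the same affected individual, and (ii) the two are plausible
#' trans-partners (parental origins differ, or at least one origin is
#' unknown).  This reproduces the manual "reconsidered" path by which a
#' deep-intronic allele paired with a frameshift re-enters the candidate
#' list.  Re-included variants are flagged `rescued`.  Only variants dropped
#' *after* the rarity filter are eligible, so a rescue can never re-admit a
#' common allele.
#'
#' @param dropped VariantSet removed by [filterFunctional()].
#' @param surviving VariantSet that passed it.
#' @param pedigree the family [Pedigree-class].
#' @return VariantSet of re-included variants (possibly empty) with a
#'   `rescued` annotation column set TRUE.
#' @export
applyRescueList <- function(dropped, surviving, pedigree) {
  pid <- probandId(pedigree)
  par <- parentsOf(pedigree, pid)
  sAnno <- annotations(surviving)
  sHetLof <- sAnno$functional_class %in% lofClasses &
    zygosity(surviving, pid)[, 1] == "het"
  lofGenes <- unique(sAnno$gene[sHetLof])
  lofGenes <- lofGenes[!is.na(lofGenes)]
  dAnno <- annotations(dropped)
  cand <- which(dAnno$functional_class == "intronic" &
                  dAnno$gene %in% lofGenes &
                  zygosity(dropped, pid)[, 1] == "het")
  if (!length(cand)) {
    out <- dropped[integer(0)]
    a <- annotations(out); a$rescued <- logical(0); annotations(out) <- a
    return(out)
  }
  keep <- logical(length(cand))
  dOrig <- parentalOrigin(dropped, pid, par$father, par$mother)
  sOrig <- parentalOrigin(surviving, pid, par$father, par$mother)
  for (k in seq_along(cand)) {
    i <- cand[k]
    partners <- which(sHetLof & sAnno$gene == dAnno$gene[i])
    ## trans-candidate: origins differ or either is unresolved
    keep[k] <- any(dOrig[i] %in% c("unknown", "ambiguous") |
                     sOrig[partners] %in% c("unknown", "ambiguous") |
                     sOrig[partners] != dOrig[i])
  }
  out <- dropped[cand[keep]]
  a <- annotations(out)
  a$rescued <- rep(TRUE, nVariants(out))
  annotations(out) <- a
  out
}
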