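#' @include filters.R
NULL

#' Drop X/Y variants (autosomal recessive models only)
#'
#' Accepts chromosome spellings with or without a "chr" prefix.
#'
#' @param x a [VariantSet-class].
#' @return the autosomal subset.
#' @export
filterAutosomal <- function(x) {
  bare <- toupper(sub("^chr", "", x@chrom, ignore.case = TRUE))
  x[!(bare %in% c("X", "Y"))]
}

#' Homozygous-recessive candidates in one family
#'
#' A variant is a candidate iff the affected proband is homozygous for the
#' alternate allele, every genotyped parent is heterozygous (a carrier), and
#' no genotyped *unaffected* sibling is also homozygous-alt.  Missing
#' parental genotypes relax the carrier condition and flag the candidate
#' `parents_unverified`.  Affected siblings are never used as exclusion
#' evidence (an affected sib sharing the homozygote supports, not refutes,
#' the model).  In lenient mode a homozygous unaffected sibling demotes the
#' candidate to a warning instead of rejecting it.
#'
#' @param x a [VariantSet-class].
#' @param pedigree the family [Pedigree-class].
#' @param strictSiblings reject on a hom-alt unaffected sibling (default
#'   TRUE).
#' @return data.frame of candidates: `key`, `chrom`, `pos`, `gene`,
#'   `model`, `phase_status`, `parents_unverified`, `family_id`.
#' @export
findHomozygousRecessive <- function(x, pedigree, strictSiblings = TRUE) {
  if (!length(affectedIds(pedigree)))
    stop("pedigree has no affected sample")
  pid <- probandId(pedigree)
  par <- parentsOf(pedigree, pid)
  d <- dosage(x)
  dp <- d[, pid]
  isHom <- !is.na(dp) & dp == 2L

  parentsUnverified <- rep(FALSE, nVariants(x))
  for (p in c(par$father, par$mother)) {
    if (is.na(p) || !(p %in% colnames(d))) {
      parentsUnverified <- parentsUnverified | TRUE
    } else {
      dpar <- d[, p]
      parentsUnverified <- parentsUnverified | is.na(dpar)
      isHom <- isHom & (is.na(dpar) | dpar == 1L)
    }
  }

  unaffSibs <- siblingsOf(pedigree, pid, affected = FALSE)
  unaffSibs <- intersect(unaffSibs, colnames(d))
  sibHom <- rep(FALSE, nVariants(x))
  for (s in unaffSibs) {
    ds <- d[, s]
    sibHom <- sibHom | (!is.na(ds) & ds == 2L)
  }
  if (strictSiblings) {
    isHom <- isHom & !sibHom
  } else if (any(isHom & sibHom)) {
    warning(sum(isHom & sibHom),
            " candidate(s) kept despite a homozygous unaffected sibling",
            " (lenient mode)")
  }

  idx <- which(isHom)
  anno <- annotations(x)
  data.frame(
    key = variantKeys(x)[idx], key2 = rep(NA_character_, length(idx)),
    chrom = x@chrom[idx], pos = x@pos[idx],
    gene = if ("gene" %in% names(anno)) anno$gene[idx]
           else rep(NA_character_, length(idx)),
    model = rep("hom_recessive", length(idx)),
    phase_status = rep(NA_character_, length(idx)),
    parents_unverified = parentsUnverified[idx],
    family_id = rep(familyId(pedigree), length(idx)),
    stringsAsFactors = FALSE)
}

#' Compound-heterozygous candidates in one family
#'
#' For each gene, enumerates unordered pairs of variants heterozygous in the
#' proband.  A pair whose alleles demonstrably come one from each parent is
#' `trans_confirmed`; pairs with an ungenotyped parent or an allele carried
#' by both parents are `phase_unknown` (retained, ranked below); pairs whose
#' alleles both trace to the same single parent are rejected as cis.
#'
#' @param x a [VariantSet-class] with gene annotations.
#' @param pedigree the family [Pedigree-class].
#' @return data.frame of candidates: one row per pair, `key` and `key2` the
#'   two members, plus `gene`, `model`, `phase_status`, `family_id`.
#' @export
findCompoundHet <- function(x, pedigree) {
  pid <- probandId(pedigree)
  par <- parentsOf(pedigree, pid)
  anno <- annotations(x)
  gene <- if ("gene" %in% names(anno)) anno$gene else
    rep(NA_character_, nVariants(x))
  het <- zygosity(x, pid)[, 1] == "het"
  origin <- parentalOrigin(x, pid, par$father, par$mother)
  keys <- variantKeys(x)
  rows <- list()
  for (g in unique(gene[het & !is.na(gene)])) {
    idx <- which(het & !is.na(gene) & gene == g)
    if (length(idx) < 2) next
    pairs <- utils::combn(idx, 2)
    for (c in seq_len(ncol(pairs))) {
      i <- pairs[1, c]; j <- pairs[2, c]
      oi <- origin[i]; oj <- origin[j]
      status <- if (oi == "father" && oj == "mother" ||
                    oi == "mother" && oj == "father") "trans_confirmed"
        else if (oi %in% c("father", "mother") && oi == oj) "cis"
        else "phase_unknown"
      if (status == "cis") next
      rows[[length(rows) + 1]] <- data.frame(
        key = keys[i], key2 = keys[j], chrom = x@chrom[i],
        pos = x@pos[i], gene = g, model = "compound_het",
        phase_status = status, parents_unverified = any(
          c(oi, oj) == "unknown"),
        family_id = familyId(pedigree), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(key = character(), key2 = character(),
                      chrom = character(), pos = integer(),
                      gene = character(), model = character(),
                      phase_status = character(),
                      parents_unverified = logical(),
                      family_id = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
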