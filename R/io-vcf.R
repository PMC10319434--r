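#' @include VariantSet-methods.R
NULL

#' Normalize indel alleles to their minimal left-aligned representation
#'
#' Trims the shared allele suffix, then the shared prefix (keeping at least
#' one base of each allele), adjusting the position.  Database joins require
#' canonical keys; VCF writers differ in how much flanking sequence they
#' include around indels.
#'
#' @param pos,ref,alt parallel vectors for one or more variants.
#' @return list with normalized `pos`, `ref`, `alt`.
#' @examples
#' normalizeAlleles(100L, "CTT", "CT")   # suffix-trimmed to ref "CT", alt "C"
#' normalizeAlleles(100L, "ACG", "ATG")  # prefix/suffix kept minimal: pos 101
#' @export
normalizeAlleles <- function(pos, ref, alt) {
  pos <- as.integer(pos)
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  for (i in seq_along(pos)) {
    r <- ref[i]; a <- alt[i]
    # trim common suffix
    while (nchar(r) > 1 && nchar(a) > 1 &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1, nchar(r) - 1)
      a <- substr(a, 1, nchar(a) - 1)
    }
    # trim common prefix
    while (nchar(r) > 1 && nchar(a) > 1 &&
           substr(r, 1, 1) == substr(a, 1, 1)) {
      r <- substr(r, 2, nchar(r)); a <- substr(a, 2, nchar(a))
      pos[i] <- pos[i] + 1L
    }
    ref[i] <- r; alt[i] <- a
  }
  list(pos = pos, ref = ref, alt = alt)
}

gtCodeToAlleles <- function(gt) {
  ## Map unique GT strings once; returns list(a, b, phased) integer/logical
  ## vectors with ALT-index alleles preserved (decomposition remaps later).
  u <- unique(gt)
  parse1 <- function(s) {
    phased <- grepl("|", s, fixed = TRUE)
    parts <- strsplit(s, "[/|]")[[1]]
    if (length(parts) == 1) parts <- c(parts, NA_character_)
    a <- suppressWarnings(as.integer(parts[1]))
    b <- suppressWarnings(as.integer(parts[2]))
    c(a, b, as.integer(phased))
  }
  m <- vapply(u, parse1, numeric(3))
  idx <- match(gt, u)
  list(a = as.integer(m[1, idx]), b = as.integer(m[2, idx]),
       phased = as.logical(m[3, idx]))
}

#' Read a multi-sample VCF into a VariantSet
#'
#' Wraps `VariantAnnotation::readVcf`: requires a GT FORMAT field, decomposes
#' multi-allelic rows into one biallelic record per ALT (an allele equal to a
#' *different* ALT is coded REF for that record, so ALT dosage is conserved
#' across the decomposition), normalizes indel alleles, and returns records
#' sorted by (chrom, pos).
#'
#' When a pedigree is supplied, pedigree samples absent from the VCF are
#' added with all-missing genotypes (with a warning); extra VCF samples are
#' kept and flagged in the `extraneous_samples` attribute.
#'
#' @param path VCF v4.x file (uncompressed or bgzipped).
#' @param pedigree optional [Pedigree-class] for the family.
#' @param normalize left-align/trim indel alleles (default TRUE).
#' @return a [VariantSet-class].
#' @export
readCohortVcf <- function(path, pedigree = NULL, normalize = TRUE) {
  head1 <- readLines(path, n = 1L)
  if (!startsWith(head1, "##fileformat=VCF"))
    stop("not a VCF file (missing ##fileformat header): ", path)
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  if (!"GT" %in% rownames(VariantAnnotation::geno(
        VariantAnnotation::header(vcf))))
    stop("VCF lacks a GT FORMAT field: ", path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altList <- VariantAnnotation::alt(vcf)
  nAlt <- S4Vectors::elementNROWS(altList)
  altAll <- as.character(unlist(altList))
  ids <- names(rr)
  ids[is.na(ids) | grepl("[:_]", ids)] <- "."
  gt <- VariantAnnotation::geno(vcf)$GT
  samples <- colnames(gt)
  parsed <- gtCodeToAlleles(as.vector(gt))
  aRaw <- matrix(parsed$a, nrow(gt), ncol(gt))
  bRaw <- matrix(parsed$b, nrow(gt), ncol(gt))
  phRaw <- matrix(parsed$phased, nrow(gt), ncol(gt))

  rowIdx <- rep(seq_along(nAlt), nAlt)      # source row per decomposed record
  altIdx <- unlist(lapply(nAlt, seq_len))   # which ALT this record carries
  mapAllele <- function(m) {
    out <- m[rowIdx, , drop = FALSE]
    out <- (out == altIdx) * 1L             # ALT-k -> 1, REF/other-ALT -> 0
    out
  }
  alleleA <- mapAllele(aRaw)
  alleleB <- mapAllele(bRaw)
  phased <- phRaw[rowIdx, , drop = FALSE]
  colnames(alleleA) <- colnames(alleleB) <- colnames(phased) <- samples

  chrom <- chrom[rowIdx]; pos <- pos[rowIdx]; ref <- ref[rowIdx]
  ids <- ids[rowIdx]; alt <- altAll
  keep <- alt != "" & alt != "." & !is.na(alt) & alt != ref
  if (!all(keep)) {
    chrom <- chrom[keep]; pos <- pos[keep]; ref <- ref[keep]
    alt <- alt[keep]; ids <- ids[keep]
    alleleA <- alleleA[keep, , drop = FALSE]
    alleleB <- alleleB[keep, , drop = FALSE]
    phased <- phased[keep, , drop = FALSE]
  }
  if (normalize && length(pos)) {
    norm <- normalizeAlleles(pos, ref, alt)
    pos <- norm$pos; ref <- norm$ref; alt <- norm$alt
  }

  extraneous <- character()
  if (!is.null(pedigree)) {
    pedSamples <- sampleIds(pedigree)
    absent <- setdiff(pedSamples, samples)
    if (length(absent)) {
      warning("pedigree sample(s) absent from VCF, filled as missing: ",
              paste(absent, collapse = ", "))
      for (s in absent) {
        alleleA <- cbind(alleleA, NA_integer_)
        alleleB <- cbind(alleleB, NA_integer_)
        phased <- cbind(phased, FALSE)
        colnames(alleleA)[ncol(alleleA)] <- s
        colnames(alleleB)[ncol(alleleB)] <- s
        colnames(phased)[ncol(phased)] <- s
      }
    }
    extraneous <- setdiff(samples, pedSamples)
  }
  vs <- VariantSet(chrom, pos, ref, alt, ids, alleleA, alleleB, phased)
  attr(vs, "extraneous_samples") <- extraneous
  vs
}

#' Write a VariantSet as a minimal GT-only VCF v4.2
#'
#' @param x a [VariantSet-class].
#' @param path output path.
#' @param contigs optional named integer vector of contig lengths for
#'   `##contig` header lines.
#' @return `path`, invisibly.
#' @export
writeCohortVcf <- function(x, path, contigs = NULL) {
  stopifnot(is(x, "VariantSet"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  if (is.null(contigs)) {
    for (ch in unique(x@chrom)) {
      len <- if (length(x@pos)) max(x@pos[x@chrom == ch]) + 1000L else 1000L
      writeLines(sprintf("##contig=<ID=%s,length=%d>", ch, len), con)
    }
  } else {
    for (ch in names(contigs))
      writeLines(sprintf("##contig=<ID=%s,length=%d>", ch, contigs[[ch]]),
                 con)
  }
  writeLines(paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                    "Description=\"Genotype\">"), con)
  samples <- sampleIds(x)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"), con)
  if (nVariants(x)) {
    sep <- ifelse(x@phased, "|", "/")
    fmt <- function(m) ifelse(is.na(m), ".", as.character(m))
    gtStr <- matrix(paste0(fmt(x@alleleA), sep, fmt(x@alleleB)),
                    nVariants(x), length(samples))
    lines <- paste(x@chrom, x@pos, x@id, x@ref, x@alt, ".", "PASS", ".",
                   "GT", sep = "\t")
    gtCols <- lapply(seq_len(ncol(gtStr)), function(j) gtStr[, j])
    lines <- paste(lines, do.call(paste, c(gtCols, list(sep = "\t"))),
                   sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}
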