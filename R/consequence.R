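#' @include gene-model.R
NULL

functionalClasses <- c("stopgain", "missense", "synonymous",
                       "frameshift_deletion", "frameshift_insertion",
                       "inframe_indel", "splicing", "intronic",
                       "UTR5", "UTR3", "intergenic")

## Vectorized consequence classification of variants against one transcript.
## SNVs are classified from the actual codon change read off cds_sequence;
## indels by length difference mod 3 (frameshift vs in-frame); intronic
## positions within `spliceWindow` bp of an exon boundary are "splicing".
classifyInTranscript <- function(model, pos, ref, alt, spliceWindow = 2L,
                                 flank = 5000L) {
  n <- length(pos)
  g2c <- genomicToCdna(model, pos, flank = flank)
  cls <- rep("intergenic", n)
  codon <- rep(NA_integer_, n)
  protein <- cdna <- rep(NA_character_, n)

  isIntron <- g2c$region == "intron"
  cls[isIntron & abs(g2c$intron_offset) <= spliceWindow] <- "splicing"
  cls[isIntron & abs(g2c$intron_offset) > spliceWindow] <- "intronic"
  cdna[isIntron] <- ifelse(
    is.na(g2c$cds_pos[isIntron]), NA_character_,
    paste0("c.", g2c$cds_pos[isIntron],
           sprintf("%+d", g2c$intron_offset[isIntron])))
  cls[g2c$region == "utr5"] <- "UTR5"
  cls[g2c$region == "utr3"] <- "UTR3"

  coding <- g2c$region == "coding"
  minus <- model@strand == "-"
  cds <- model@cdsSequence

  snv <- coding & nchar(ref) == 1L & nchar(alt) == 1L & ref != alt
  if (any(snv)) {
    p <- g2c$cds_pos[snv]
    altC <- if (minus) complementBase(alt[snv]) else alt[snv]
    ci <- codonIndex(p)
    if (!is.na(cds)) {
      inCodon <- (p - 1L) %% 3L + 1L
      cStart <- (ci - 1L) * 3L + 1L
      refCodon <- substring(cds, cStart, cStart + 2L)
      altCodon <- refCodon
      substr(altCodon, inCodon, inCodon) <- altC
      aaRef <- unname(GENETIC_CODE_TABLE[refCodon])
      aaAlt <- unname(GENETIC_CODE_TABLE[altCodon])
      k <- ifelse(aaAlt == "*", "stopgain",
                  ifelse(aaRef == aaAlt, "synonymous", "missense"))
      cls[snv] <- k
      codon[snv] <- ci
      refC <- substring(cds, p, p)
      cdna[snv] <- paste0("c.", p, refC, ">", altC)
      protein[snv] <- paste0("p.", aaRef, ci,
                             ifelse(aaAlt == "*", "*", aaAlt))
    } else {
      warning("cds_sequence absent for ", model@transcriptId,
              ": coding SNVs classified as missense without protein naming")
      cls[snv] <- "missense"
      codon[snv] <- ci
      refC <- if (minus) complementBase(ref[snv]) else ref[snv]
      cdna[snv] <- paste0("c.", p, refC, ">", altC)
    }
  }

  indel <- coding & (nchar(ref) != nchar(alt))
  for (i in which(indel)) {
    lenDiff <- nchar(ref[i]) - nchar(alt[i])
    fs <- (abs(lenDiff) %% 3L) != 0L
    cls[i] <- if (!fs) "inframe_indel" else
      if (lenDiff > 0) "frameshift_deletion" else "frameshift_insertion"
    res <- tryCatch(
      indelCodingCall(model, pos[i], ref[i], alt[i], fs),
      error = function(e) NULL)
    if (!is.null(res)) {
      codon[i] <- res$codon
      cdna[i] <- res$cdna
      protein[i] <- res$protein
    }
  }

  ## coding multi-nucleotide substitutions of equal length: treat as missense
  mnv <- coding & nchar(ref) == nchar(alt) & nchar(ref) > 1L
  if (any(mnv)) {
    cls[mnv] <- "missense"
    codon[mnv] <- codonIndex(g2c$cds_pos[mnv])
  }

  data.frame(gene = model@gene, transcript_id = model@transcriptId,
             functional_class = cls, cds_pos = g2c$cds_pos,
             intron_offset = g2c$intron_offset, cdna = cdna,
             codon = codon, protein_change = protein,
             stringsAsFactors = FALSE)
}

## cDNA/protein naming for a coding indel (minimal-representation alleles on
## the forward strand).
indelCodingCall <- function(model, pos, ref, alt, frameshift) {
  minus <- model@strand == "-"
  refC <- if (minus) revComp(ref) else ref
  altC <- if (minus) revComp(alt) else alt
  anchorG <- if (minus) pos + nchar(ref) - 1L else pos
  cdsAnchor <- genomicToCdna(model, anchorG)$cds_pos
  if (is.na(cdsAnchor)) stop("indel anchor outside coding sequence")
  shared <- 0L
  while (shared < min(nchar(refC), nchar(altC)) &&
         substr(refC, shared + 1, shared + 1) ==
         substr(altC, shared + 1, shared + 1))
    shared <- shared + 1L
  firstChanged <- cdsAnchor + shared
  ci <- codonIndex(firstChanged)
  deleted <- if (nchar(refC) > nchar(altC))
    substr(refC, nchar(altC) + 1L, nchar(refC)) else ""
  cdna <- if (nzchar(deleted))
    paste0("c.", firstChanged, "del", deleted) else
    paste0("c.", firstChanged)
  protein <- NA_character_
  if (!is.na(model@cdsSequence)) {
    aaRef <- GENETIC_CODE_TABLE[[substring(model@cdsSequence,
                                           (ci - 1L) * 3L + 1L,
                                           ci * 3L)]]
    if (frameshift) {
      fsres <- frameshiftNewStopOffset(model, cdsAnchor, refC, altC)
      protein <- if (isTRUE(fsres$stop_at_first))
        paste0("p.", aaRef, ci, "*")
      else paste0("p.", aaRef, ci, fsres$new_aa, "fs*",
                  ifelse(is.na(fsres$n), "?", fsres$n))
    }
  }
  list(codon = ci, cdna = cdna, protein = protein)
}

#' Call the consequence of one variant against one transcript model
#'
#' @param model a [TranscriptModel-class].
#' @param chrom,pos,ref,alt the variant (forward-strand alleles, minimal
#'   representation).
#' @param spliceWindow bp around exon/intron boundaries called "splicing"
#'   (default 2, the usual exome-annotator convention).
#' @return one-row data.frame with `gene`, `transcript_id`,
#'   `functional_class`, `cds_pos`, `intron_offset`, `cdna`, `codon`,
#'   `protein_change`.
#' @examples
#' m <- transcriptModel("tx1", "G1", "chrT", "+", 101, 130, 101, 112,
#'                      "ATGCGATGGTAA")
#' callConsequence(m, "chrT", 104, "C", "T")  # codon 2 CGA->TGA, p.R2*
#' @export
callConsequence <- function(model, chrom, pos, ref, alt,
                            spliceWindow = 2L) {
  if (chrom != model@chrom)
    stop("variant on ", chrom, " but model on ", model@chrom)
  classifyInTranscript(model, as.integer(pos), toupper(ref), toupper(alt),
                       spliceWindow = spliceWindow)
}

#' Annotate a VariantSet with gene and consequence calls
#'
#' Assigns each variant to at most one transcript (the first whose exon span
#' covers its position; one canonical transcript per gene is assumed) and
#' attaches `gene`, `transcript_id`, `functional_class`, `cds_pos`,
#' `intron_offset`, `cdna`, `codon` and `protein_change` annotation columns.
#' Variants outside every transcript span are `intergenic`.
#'
#' @param x a [VariantSet-class].
#' @param models list of [TranscriptModel-class].
#' @param spliceWindow see [callConsequence()].
#' @return `x` with consequence annotations added.
#' @export
annotateConsequences <- function(x, models, spliceWindow = 2L) {
  n <- nVariants(x)
  out <- data.frame(gene = rep(NA_character_, n),
                    transcript_id = NA_character_,
                    functional_class = "intergenic",
                    cds_pos = NA_integer_, intron_offset = NA_integer_,
                    cdna = NA_character_, codon = NA_integer_,
                    protein_change = NA_character_,
                    stringsAsFactors = FALSE)
  if (n > 0 && length(models)) {
    spans <- GenomicRanges::GRanges(
      vapply(models, function(m) m@chrom, ""),
      IRanges::IRanges(
        vapply(models, function(m) IRanges::start(m@exons)[1], 0L),
        vapply(models, function(m)
          IRanges::end(m@exons)[length(m@exons)], 0L)))
    vr <- GenomicRanges::GRanges(x@chrom, IRanges::IRanges(x@pos, x@pos))
    hits <- GenomicRanges::findOverlaps(vr, spans, select = "first")
    for (k in sort(unique(hits[!is.na(hits)]))) {
      idx <- which(!is.na(hits) & hits == k)
      res <- classifyInTranscript(models[[k]], x@pos[idx], x@ref[idx],
                                  x@alt[idx], spliceWindow = spliceWindow)
      out[idx, ] <- res[, names(out)]
    }
  }
  anno <- annotations(x)
  drop <- intersect(names(anno), names(out))
  anno <- anno[, setdiff(names(anno), drop), drop = FALSE]
  annotations(x) <- cbind(anno, out, row.names = NULL)
  x
}
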