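#' @include VariantSet-methods.R
NULL

GENETIC_CODE_TABLE <- Biostrings::GENETIC_CODE

complementBase <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

revComp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

#' Construct a TranscriptModel
#'
#' @param transcriptId,gene identifiers.
#' @param chrom chromosome name.
#' @param strand "+" or "-".
#' @param exonStarts,exonEnds 1-based inclusive genomic exon bounds on the
#'   forward strand, sorted by position.
#' @param cdsStart,cdsEnd genomic CDS bounds (forward strand).
#' @param cdsSequence spliced coding sequence on the coding strand
#'   (`ATG ... stop`), or NA.
#' @param utr3Sequence optional 3' UTR continuation on the coding strand,
#'   used when a frameshifted reading frame runs past the canonical stop.
#' @return a [TranscriptModel-class].
#' @export
transcriptModel <- function(transcriptId, gene, chrom, strand,
                            exonStarts, exonEnds, cdsStart, cdsEnd,
                            cdsSequence = NA_character_,
                            utr3Sequence = NA_character_) {
  x <- new("TranscriptModel", transcriptId = transcriptId, gene = gene,
           chrom = chrom, strand = strand,
           exons = IRanges::IRanges(as.integer(exonStarts),
                                    as.integer(exonEnds)),
           cdsStart = as.integer(cdsStart), cdsEnd = as.integer(cdsEnd),
           cdsSequence = if (is.na(cdsSequence)) NA_character_ else
             toupper(cdsSequence),
           utr3Sequence = if (is.na(utr3Sequence)) NA_character_ else
             toupper(utr3Sequence))
  validObject(x)
  x
}

## Coding segments in transcription order: genomic bounds plus the cDNA
## interval each covers.  The anchor of all coordinate arithmetic.
codingSegments <- function(model) {
  st <- IRanges::start(model@exons); en <- IRanges::end(model@exons)
  gs <- pmax(st, model@cdsStart); ge <- pmin(en, model@cdsEnd)
  keep <- gs <= ge
  gs <- gs[keep]; ge <- ge[keep]
  w <- ge - gs + 1L
  if (model@strand == "+") {
    cEnd <- cumsum(w)
    data.frame(gStart = gs, gEnd = ge,
               cStart = cEnd - w + 1L, cEnd = cEnd)
  } else {
    ord <- rev(seq_along(gs))              # transcription right-to-left
    w2 <- w[ord]
    cEnd <- cumsum(w2)
    data.frame(gStart = gs[ord], gEnd = ge[ord],
               cStart = cEnd - w2 + 1L, cEnd = cEnd)
  }
}

#' Map a genomic position to cDNA coordinates
#'
#' Exonic coding positions map to `(cds_pos, 0)`.  Intronic positions map to
#' the nearest exonic coding anchor with a signed HGVS offset: positive past
#' a donor (counted from the last base of the upstream exon), negative before
#' an acceptor (counted back from the first base of the downstream exon), so
#' `c.21-94` is 94 bp upstream of coding position 21.  Strand-aware; ties go
#' to the donor side.
#'
#' @param model a [TranscriptModel-class].
#' @param gpos 1-based genomic position(s), forward strand.
#' @param flank bp beyond the exon span still accepted (default 5000).
#' @return data.frame with columns `cds_pos`, `intron_offset`, `region`
#'   (one of coding, intron, utr5, utr3, flank).
#' @export
genomicToCdna <- function(model, gpos, flank = 5000L) {
  gpos <- as.integer(gpos)
  st <- IRanges::start(model@exons); en <- IRanges::end(model@exons)
  span <- c(st[1], en[length(en)])
  if (any(gpos < span[1] - flank | gpos > span[2] + flank))
    stop("position outside transcript span + flank for ",
         model@transcriptId)
  seg <- codingSegments(model)
  n <- length(gpos)
  cdsPos <- rep(NA_integer_, n); off <- rep(NA_integer_, n)
  region <- rep("flank", n)

  exIdx <- findInterval(gpos, st)
  inExon <- exIdx >= 1L & gpos <= en[pmax(exIdx, 1L)]
  coding <- inExon & gpos >= model@cdsStart & gpos <= model@cdsEnd
  if (any(coding)) {
    segSorted <- seg[order(seg$gStart), , drop = FALSE]
    g <- gpos[coding]
    k <- findInterval(g, segSorted$gStart)
    if (model@strand == "+") {
      cdsPos[coding] <- segSorted$cStart[k] + (g - segSorted$gStart[k])
    } else {
      cdsPos[coding] <- segSorted$cStart[k] + (segSorted$gEnd[k] - g)
    }
    off[coding] <- 0L
    region[coding] <- "coding"
  }
  utr <- inExon & !coding
  if (any(utr)) {
    g <- gpos[utr]
    if (model@strand == "+") {
      region[utr] <- ifelse(g < model@cdsStart, "utr5", "utr3")
    } else {
      region[utr] <- ifelse(g > model@cdsEnd, "utr5", "utr3")
    }
  }
  intronic <- !inExon & gpos >= span[1] & gpos <= span[2]
  if (any(intronic)) {
    g <- gpos[intronic]
    i <- findInterval(g, st)          # exon to the genomic left
    eLeft <- en[i]; sRight <- st[i + 1L]
    dLeft <- g - eLeft; dRight <- sRight - g
    cLeft <- cdnaAtEdge(model, seg, eLeft)
    cRight <- cdnaAtEdge(model, seg, sRight)
    if (model@strand == "+") {
      useDonor <- dLeft <= dRight
      cdsPos[intronic] <- ifelse(useDonor, cLeft, cRight)
      off[intronic] <- ifelse(useDonor, dLeft, -dRight)
    } else {
      useDonor <- dRight <= dLeft     # donor is the genomic-right exon edge
      cdsPos[intronic] <- ifelse(useDonor, cRight, cLeft)
      off[intronic] <- ifelse(useDonor, dRight, -dLeft)
    }
    region[intronic] <- "intron"
  }
  data.frame(cds_pos = cdsPos, intron_offset = off, region = region)
}

## cDNA coding position of an exon-edge genomic position (NA if the edge is
## untranslated).
cdnaAtEdge <- function(model, seg, g) {
  segSorted <- seg[order(seg$gStart), , drop = FALSE]
  idx <- findInterval(g, segSorted$gStart)
  ok <- idx >= 1L & g <= segSorted$gEnd[pmax(idx, 1L)] & idx <= nrow(segSorted)
  out <- rep(NA_integer_, length(g))
  if (any(ok)) {
    if (model@strand == "+") {
      out[ok] <- segSorted$cStart[idx[ok]] +
        (g[ok] - segSorted$gStart[idx[ok]])
    } else {
      out[ok] <- segSorted$cStart[idx[ok]] +
        (segSorted$gEnd[idx[ok]] - g[ok])
    }
  }
  out
}

#' Map a cDNA coordinate back to a genomic position
#'
#' Inverse of [genomicToCdna()] for coding and intronic coordinates.
#'
#' @param model a [TranscriptModel-class].
#' @param cdsPos 1-based coding position(s).
#' @param intronOffset signed offset(s); 0 for exonic (default).
#' @return integer genomic position(s), forward strand.
#' @export
cdnaToGenomic <- function(model, cdsPos, intronOffset = 0L) {
  cdsPos <- as.integer(cdsPos)
  intronOffset <- as.integer(rep(intronOffset, length.out = length(cdsPos)))
  seg <- codingSegments(model)
  k <- vapply(cdsPos, function(p) {
    w <- which(seg$cStart <= p & seg$cEnd >= p)
    if (!length(w)) stop("cds position outside coding sequence: ", p)
    w[1]
  }, 0L)
  if (model@strand == "+") {
    g0 <- seg$gStart[k] + (cdsPos - seg$cStart[k])
    as.integer(g0 + intronOffset)
  } else {
    g0 <- seg$gEnd[k] - (cdsPos - seg$cStart[k])
    as.integer(g0 - intronOffset)
  }
}

#' Render a cDNA coordinate in HGVS-lite notation
#'
#' @param cdsPos coding position(s).
#' @param intronOffset signed offset(s), 0 for exonic.
#' @return strings like `"c.853"` or `"c.21-94"`.
#' @export
formatCdna <- function(cdsPos, intronOffset = 0L) {
  intronOffset <- rep(intronOffset, length.out = length(cdsPos))
  suffix <- ifelse(is.na(intronOffset) | intronOffset == 0L, "",
                   sprintf("%+d", intronOffset))
  ifelse(is.na(cdsPos), NA_character_, paste0("c.", cdsPos, suffix))
}

#' Codon number of a coding position
#'
#' `ceiling(cds_pos / 3)`: coding position 853 falls in codon 285, 541 in
#' codon 181, 518 in codon 173.
#'
#' @param cdsPos 1-based coding position(s).
#' @return integer codon index(es).
#' @export
codonIndex <- function(cdsPos) {
  cdsPos <- as.integer(cdsPos)
  if (any(!is.na(cdsPos) & cdsPos < 1L))
    stop("cds position must be >= 1")
  as.integer(ceiling(cdsPos / 3))
}

#' Residues lost to a premature termination codon
#'
#' The residue replaced by the stop counts as lost: a stop at codon 285 of a
#' 306-residue protein removes the C-terminal 22 amino acids; at codon 181 it
#' removes 126.
#'
#' @param proteinLength wild-type protein length in amino acids.
#' @param stopCodon codon index where the premature stop arises.
#' @return integer, number of amino acids lost.
#' @export
truncatedTailLength <- function(proteinLength, stopCodon) {
  proteinLength <- as.integer(proteinLength)
  stopCodon <- as.integer(stopCodon)
  if (any(stopCodon < 1L) || any(stopCodon > proteinLength))
    stop("stop codon must lie in 1..protein_length")
  proteinLength - stopCodon + 1L
}

#' Novel-residue count of a frameshift before its new stop (fs*N)
#'
#' Translates the shifted reading frame from the first altered codon through
#' the remaining coding sequence (extended into the 3' UTR sequence when
#' available) until a stop codon.  Returns N counting the first changed
#' residue as 1, i.e. the N of `p.X###Yfs*N`; a stop arising at the first
#' novel codon returns 1 with `stop_at_first = TRUE` (nonsense-style naming
#' `p.X###*`).
#'
#' @param model a [TranscriptModel-class] with `cdsSequence`.
#' @param cdsPos first coding position affected by the indel.
#' @param ref,alt the indel alleles *on the coding strand*, minimal
#'   representation (e.g. ref "TT", alt "T" for a 1-bp deletion).
#' @return list with `n` (integer N, NA when no stop is reachable —
#'   reported as `fs*?`), `stop_at_first` flag, and `new_aa` (the residue
#'   replacing the first affected one).
#' @export
frameshiftNewStopOffset <- function(model, cdsPos, ref, alt) {
  cds <- model@cdsSequence
  if (is.na(cds)) stop("cds_sequence required for frameshift resolution")
  cdsPos <- as.integer(cdsPos)
  shared <- 0L
  while (shared < min(nchar(ref), nchar(alt)) &&
         substr(ref, shared + 1, shared + 1) ==
         substr(alt, shared + 1, shared + 1))
    shared <- shared + 1L
  firstChanged <- cdsPos + shared          # first cds base actually altered
  mutated <- paste0(substr(cds, 1, cdsPos - 1L), alt,
                    substr(cds, cdsPos + nchar(ref), nchar(cds)))
  if (!is.na(model@utr3Sequence))
    mutated <- paste0(mutated, model@utr3Sequence)
  ci <- codonIndex(min(firstChanged, nchar(cds)))
  frame <- substr(mutated, (ci - 1L) * 3L + 1L, nchar(mutated))
  nCodon <- nchar(frame) %/% 3L
  if (nCodon < 1L) return(list(n = NA_integer_, stop_at_first = FALSE,
                               new_aa = NA_character_))
  codons <- substring(frame, 3L * (seq_len(nCodon) - 1L) + 1L,
                      3L * seq_len(nCodon))
  aas <- unname(GENETIC_CODE_TABLE[codons])
  stopAt <- match("*", aas)
  newAa <- aas[1]
  if (is.na(stopAt))
    return(list(n = NA_integer_, stop_at_first = FALSE, new_aa = newAa))
  list(n = as.integer(stopAt), stop_at_first = stopAt == 1L,
       new_aa = newAa)
}

#' Read transcript models from a simplified TSV
#'
#' Columns: `transcript_id`, `gene`, `chrom`, `strand`, `exons`
#' (comma-separated `start-end` forward-strand intervals), `cds_start`,
#' `cds_end`.  Coding sequences come from a FASTA keyed by transcript id; an
#' entry named `<transcript_id>.utr3` supplies the 3' UTR continuation.
#'
#' @param path TSV file.
#' @param fasta optional FASTA of coding-strand CDS sequences.
#' @return named list of [TranscriptModel-class].
#' @export
readTranscriptModels <- function(path, fasta = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE,
                   colClasses = list(chrom = "character"))
  seqs <- NULL
  if (!is.null(fasta)) {
    ss <- Biostrings::readDNAStringSet(fasta)
    seqs <- setNames(as.character(ss), names(ss))
  }
  out <- list()
  for (i in seq_len(nrow(df))) {
    iv <- strsplit(df$exons[i], ",", fixed = TRUE)[[1]]
    bounds <- do.call(rbind, strsplit(iv, "-", fixed = TRUE))
    cdsSeq <- utr3 <- NA_character_
    if (!is.null(seqs)) {
      cdsSeq <- seqs[[df$transcript_id[i]]] %||% NA_character_
      utr3 <- seqs[[paste0(df$transcript_id[i], ".utr3")]] %||%
        NA_character_
    }
    out[[df$transcript_id[i]]] <- transcriptModel(
      df$transcript_id[i], df$gene[i], df$chrom[i], df$strand[i],
      as.integer(bounds[, 1]), as.integer(bounds[, 2]),
      df$cds_start[i], df$cds_end[i], cdsSeq, utr3)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write transcript models to the simplified TSV (+ FASTA)
#'
#' @param models list of [TranscriptModel-class].
#' @param path output TSV path.
#' @param fasta optional output FASTA path for CDS (and `.utr3`) sequences.
#' @return `path`, invisibly.
#' @export
writeTranscriptModels <- function(models, path, fasta = NULL) {
  rows <- lapply(models, function(m) {
    data.frame(transcript_id = m@transcriptId, gene = m@gene,
               chrom = m@chrom, strand = m@strand,
               exons = paste(sprintf("%d-%d", IRanges::start(m@exons),
                                     IRanges::end(m@exons)),
                             collapse = ","),
               cds_start = m@cdsStart, cds_end = m@cdsEnd,
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(fasta)) {
    seqs <- character(); nm <- character()
    for (m in models) {
      if (!is.na(m@cdsSequence)) {
        seqs <- c(seqs, m@cdsSequence); nm <- c(nm, m@transcriptId)
      }
      if (!is.na(m@utr3Sequence)) {
        seqs <- c(seqs, m@utr3Sequence)
        nm <- c(nm, paste0(m@transcriptId, ".utr3"))
      }
    }
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(setNames(seqs, nm)), fasta)
  }
  invisible(path)
}

#' Read transcript models from GFF3
#'
#' Expects gene/mRNA/exon/CDS features with `Parent` links; one mRNA per
#' model.  Requires the rtracklayer package.
#'
#' @param path GFF3 file.
#' @param fasta optional FASTA of coding-strand CDS sequences keyed by
#'   transcript id.
#' @return named list of [TranscriptModel-class].
#' @export
readTranscriptModelsGff <- function(path, fasta = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required to read GFF3 gene models")
  gr <- rtracklayer::import(path)
  seqs <- NULL
  if (!is.null(fasta)) {
    ss <- Biostrings::readDNAStringSet(fasta)
    seqs <- setNames(as.character(ss), names(ss))
  }
  mrna <- gr[gr$type == "mRNA"]
  out <- list()
  for (i in seq_along(mrna)) {
    tid <- mrna$ID[i]
    gene <- if (!is.null(mrna$gene) && !is.na(mrna$gene[i])) mrna$gene[i]
            else unlist(mrna$Parent[i])[1] %||% tid
    kidOf <- function(type) {
      k <- gr[gr$type == type &
                vapply(gr$Parent, function(p) tid %in% p, TRUE)]
      k[order(GenomicRanges::start(k))]
    }
    ex <- kidOf("exon"); cds <- kidOf("CDS")
    if (!length(ex)) ex <- cds
    out[[tid]] <- transcriptModel(
      tid, as.character(gene),
      as.character(GenomicRanges::seqnames(mrna))[i],
      as.character(GenomicRanges::strand(mrna))[i],
      GenomicRanges::start(ex), GenomicRanges::end(ex),
      min(GenomicRanges::start(cds)), max(GenomicRanges::end(cds)),
      if (!is.null(seqs)) seqs[[tid]] %||% NA_character_ else
        NA_character_)
  }
  out
}
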