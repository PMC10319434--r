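## Shared in-code fixtures for the test suite.

gtToAlleles <- function(gt) {
  ## "0/1" etc -> c(a, b); "." or "./." -> NA
  if (gt %in% c(".", "./.", ".|.")) return(c(NA_integer_, NA_integer_))
  as.integer(strsplit(gt, "[/|]")[[1]])
}

## Build a VariantSet from per-sample genotype strings.
## geno: named list sample -> character vector of "0/0","0/1","1/1","./."
makeVS <- function(chrom, pos, ref, alt, geno, anno = NULL) {
  n <- length(pos)
  samples <- names(geno)
  a <- b <- matrix(NA_integer_, n, length(samples),
                   dimnames = list(NULL, samples))
  for (s in samples) {
    parsed <- vapply(geno[[s]], gtToAlleles, integer(2))
    a[, s] <- parsed[1, ]
    b[, s] <- parsed[2, ]
  }
  VariantSet(chrom, pos, ref, alt, alleleA = a, alleleB = b, anno = anno)
}

## Standard trio pedigree: F_father x F_mother -> F_proband (affected).
makeTrioPed <- function(famId = "F1", consang = FALSE, extra = NULL) {
  s <- data.frame(
    sample_id = paste0(famId, c("_father", "_mother", "_proband")),
    father = c(NA, NA, paste0(famId, "_father")),
    mother = c(NA, NA, paste0(famId, "_mother")),
    sex = c(1L, 2L, 2L), affected = c(FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  if (!is.null(extra)) s <- rbind(s, extra)
  Pedigree(famId, s, consanguineous = consang)
}

## Toy + strand model: exon1 genomic 101..130 (coding 1..30), intron
## 131..200, exon2 genomic 201..230 (coding 31..60).
toyModelPlus <- function() {
  set.seed(42)
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  nonStop <- setdiff(all3, c("TAA", "TAG", "TGA"))
  cds <- paste0("ATG", paste(sample(nonStop, 18, replace = TRUE),
                             collapse = ""), "TAA")
  transcriptModel("toyP", "TOYP", "chrT", "+", c(101L, 201L),
                  c(130L, 230L), 101L, 230L, cds,
                  "GGGGGGTAATAATAA")
}

## Mirror-image - strand model with the same cDNA geometry.
toyModelMinus <- function() {
  set.seed(43)
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  nonStop <- setdiff(all3, c("TAA", "TAG", "TGA"))
  cds <- paste0("ATG", paste(sample(nonStop, 18, replace = TRUE),
                             collapse = ""), "TAA")
  transcriptModel("toyM", "TOYM", "chrT", "-", c(101L, 201L),
                  c(130L, 230L), 101L, 230L, cds,
                  "GGGGGGTAATAATAA")
}

## Minimal 4-codon model: CDS "ATG CGA TGG TAA" in one exon 101..112.
toyCdsModel <- function() {
  transcriptModel("toy4", "TOY4", "chrT", "+", 101L, 112L, 101L, 112L,
                  "ATGCGATGGTAA", "TAATAATAA")
}

mad2Model <- function() {
  readTranscriptModels(
    system.file("extdata", "mad2l1bp_synthetic_model.tsv",
                package = "TrioCascade"),
    system.file("extdata", "mad2l1bp_synthetic_cds.fa",
                package = "TrioCascade"))[[1]]
}

clinicalFixture <- function() {
  readClinicalTable(system.file("extdata", "clinical_oocytes.csv",
                                package = "TrioCascade"))
}

## Single-sample VariantSet encoding a zygosity string over evenly spaced
## sites (h = hom, e = het), for ROH tests.
zygosityTrack <- function(zstring, spacingBp = 1000L, chrom = "chr1",
                          sample = "S1") {
  z <- strsplit(zstring, "")[[1]]
  n <- length(z)
  a <- matrix(0L, n, 1, dimnames = list(NULL, sample))
  b <- matrix(ifelse(z == "e", 1L, 0L), n, 1,
              dimnames = list(NULL, sample))
  VariantSet(rep(chrom, n), seq_len(n) * spacingBp,
             rep("A", n), rep("T", n), alleleA = a, alleleB = b)
}

## Brute-force maximal homozygous runs (independent ROH oracle).
bruteForceRuns <- function(zstring, spacingBp = 1000L) {
  z <- strsplit(zstring, "")[[1]]
  r <- rle(z == "h")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep] * spacingBp,
             end = ends[keep] * spacingBp,
             n_sites = r$lengths[keep])
}

writeLinesTmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
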