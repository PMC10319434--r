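test_that("exonic offsets map genomic to cDNA on the plus strand", {
  m <- toyModelPlus()
  expect_equal(genomicToCdna(m, 110L),
               data.frame(cds_pos = 10L, intron_offset = 0L,
                          region = "coding"))
  ## intronic position 6 bp before the acceptor of exon 2 (coding 31)
  expect_equal(genomicToCdna(m, 195L)$cds_pos, 31L)
  expect_equal(genomicToCdna(m, 195L)$intron_offset, -6L)
  ## donor side: 3 bp past the end of exon 1 (coding 30)
  expect_equal(genomicToCdna(m, 133L)$cds_pos, 30L)
  expect_equal(genomicToCdna(m, 133L)$intron_offset, 3L)
  expect_error(genomicToCdna(m, 10L, flank = 5L), "outside")
})

test_that("cDNA mapping is strand-aware", {
  m <- toyModelMinus()
  ## exon 2 (genomic right) is transcribed first on the minus strand
  expect_equal(genomicToCdna(m, 230L)$cds_pos, 1L)
  expect_equal(genomicToCdna(m, 201L)$cds_pos, 30L)
  expect_equal(genomicToCdna(m, 130L)$cds_pos, 31L)
  expect_equal(genomicToCdna(m, 101L)$cds_pos, 60L)
  ## intron position 3 bp past the minus-strand donor (end of exon 2)
  expect_equal(genomicToCdna(m, 198L)$cds_pos, 30L)
  expect_equal(genomicToCdna(m, 198L)$intron_offset, 3L)
})

test_that("genomicToCdna and cdnaToGenomic compose to identity", {
  for (m in list(toyModelPlus(), toyModelMinus())) {
    gAll <- c(101:130, 201:230)          # every coding position
    cc <- genomicToCdna(m, gAll)
    expect_true(all(cc$region == "coding"))
    expect_equal(cdnaToGenomic(m, cc$cds_pos), gAll)
    ## intronic positions round-trip through anchor + offset
    gIntron <- 131:200
    ci <- genomicToCdna(m, gIntron)
    expect_true(all(ci$region == "intron"))
    expect_equal(cdnaToGenomic(m, ci$cds_pos, ci$intron_offset), gIntron)
  }
})

test_that("the MAD2L1BP model reproduces the published coordinate pairs", {
  m <- mad2Model()
  cds <- genomicToCdna(m, c(43608202L, 43607890L, 43607867L))$cds_pos
  expect_equal(cds, c(853L, 541L, 518L))
  ## same-exon spacing: cDNA differences equal genomic differences
  expect_equal(cds[1] - cds[2], 43608202L - 43607890L)
  expect_equal(cds[2] - cds[3], 43607890L - 43607867L)
  ## deep-intronic acceptor variant: 94 bp upstream of coding position 21
  hit <- genomicToCdna(m, 43600837L)
  expect_equal(hit$cds_pos, 21L)
  expect_equal(hit$intron_offset, -94L)
  expect_equal(formatCdna(hit$cds_pos, hit$intron_offset), "c.21-94")
})

test_that("codonIndex matches published position-codon pairs", {
  expect_equal(codonIndex(853L), 285L)
  expect_equal(codonIndex(541L), 181L)
  expect_equal(codonIndex(518L), 173L)
  expect_equal(codonIndex(c(1L, 3L, 4L)), c(1L, 1L, 2L))
  expect_error(codonIndex(0L), ">= 1")
})

test_that("codonIndex agrees with a complete-triplet count", {
  p <- 1:10000
  ## independent scan: how many complete or started triplets cover 1..x
  brute <- ((p - 1L) %/% 3L) + 1L
  expect_equal(codonIndex(p), brute)
})

test_that("truncation arithmetic counts the replaced residue as lost", {
  expect_equal(truncatedTailLength(306L, 285L), 22L)
  expect_equal(truncatedTailLength(306L, 181L), 126L)
  expect_equal(truncatedTailLength(50L, 1L), 50L)
  expect_equal(truncatedTailLength(50L, 50L), 1L)
  expect_error(truncatedTailLength(306L, 307L), "protein_length")
})

test_that("frameshift stop offsets match full re-translation", {
  bruteOracle <- function(cdsSeq, utr3, pos, ref, alt) {
    mutated <- paste0(substr(cdsSeq, 1, pos - 1), alt,
                      substr(cdsSeq, pos + nchar(ref), nchar(cdsSeq)),
                      utr3)
    shared <- 0L
    while (shared < min(nchar(ref), nchar(alt)) &&
           substr(ref, shared + 1, shared + 1) ==
           substr(alt, shared + 1, shared + 1)) shared <- shared + 1L
    ci <- ((pos + shared - 1L) %/% 3L) + 1L
    keep <- (nchar(mutated) - (ci - 1L) * 3L) %/% 3L * 3L
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(
      substr(mutated, (ci - 1L) * 3L + 1L, (ci - 1L) * 3L + keep))))
    stopAt <- regexpr("*", aa, fixed = TRUE)
    if (stopAt < 0) NA_integer_ else as.integer(stopAt)
  }
  set.seed(7)
  b <- c("A", "C", "G", "T")
  nonStop <- setdiff(as.vector(outer(outer(b, b, paste0), b, paste0)),
                     c("TAA", "TAG", "TGA"))
  for (rep in 1:25) {
    nAa <- sample(20:60, 1)
    cdsSeq <- paste0("ATG", paste(sample(nonStop, nAa - 1, TRUE),
                                  collapse = ""), "TAA")
    len <- nchar(cdsSeq)
    mdl <- transcriptModel(paste0("r", rep), "R", "chrT", "+", 101L,
                           100L + len, 101L, 100L + len, cdsSeq,
                           "GGTAATAATAA")
    p <- sample(4:(len - 9), 1)
    ref <- substr(cdsSeq, p, p + 1)
    alt <- substr(cdsSeq, p, p)
    got <- frameshiftNewStopOffset(mdl, p, ref, alt)
    want <- bruteOracle(cdsSeq, "GGTAATAATAA", p, ref, alt)
    expect_equal(got$n, want, info = sprintf("rep %d pos %d", rep, p))
    if (!is.na(want) && want == 1L) expect_true(got$stop_at_first)
  }
})

test_that("an immediate novel stop collapses to nonsense-style naming", {
  ## CDS where deleting base 4 makes codon 2 = TGA immediately:
  ## ATG | TTG | ACC ... delete base 4 (T): ATG TGA ...
  m <- transcriptModel("fs2", "FS2", "chrT", "+", 101L, 112L, 101L, 112L,
                       "ATGTTGACCTAA", "TAATAATAA")
  got <- frameshiftNewStopOffset(m, 4L, "TT", "T")
  expect_equal(got$n, 1L)
  expect_true(got$stop_at_first)
})

test_that("transcript model validity enforces CDS structure", {
  expect_error(transcriptModel("x", "X", "chr1", "+", 101L, 130L, 101L,
                               130L, "ATGAAA"),  # 6 nt, no stop
               "stop codon")
  expect_error(transcriptModel("x", "X", "chr1", "+", 101L, 130L, 90L,
                               130L, NA_character_), "CDS bounds")
  ## translating a valid model's CDS yields no internal stop
  for (m in list(toyModelPlus(), toyModelMinus(), mad2Model())) {
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(m@cdsSequence)))
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
  }
})

test_that("gene models load from GFF3 with Parent links", {
  gff <- writeLinesTmp(c(
    "##gff-version 3",
    "chrT\ttest\tgene\t101\t230\t.\t+\t.\tID=g1",
    "chrT\ttest\tmRNA\t101\t230\t.\t+\t.\tID=tx1;Parent=g1;gene=TOYG",
    "chrT\ttest\texon\t101\t130\t.\t+\t.\tID=e1;Parent=tx1",
    "chrT\ttest\texon\t201\t230\t.\t+\t.\tID=e2;Parent=tx1",
    "chrT\ttest\tCDS\t101\t130\t.\t+\t0\tID=c1;Parent=tx1",
    "chrT\ttest\tCDS\t201\t230\t.\t+\t0\tID=c2;Parent=tx1"), ".gff3")
  models <- readTranscriptModelsGff(gff)
  expect_length(models, 1)
  m <- models[["tx1"]]
  expect_equal(m@gene, "TOYG")
  expect_equal(IRanges::start(m@exons), c(101L, 201L))
  expect_equal(m@cdsStart, 101L)
  expect_equal(m@cdsEnd, 230L)
  expect_equal(genomicToCdna(m, 205L)$cds_pos, 35L)
})
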