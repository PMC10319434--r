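freqTab <- function(db, keys, af) {
  new("FrequencyTable", dbName = db, keys = keys, af = af)
}

test_that("maxObservedMaf takes the maximum over observing databases", {
  gnomad <- freqTab("gnomAD", "chr6:43608202:C:T", 3 / 248598)
  dbsnp <- freqTab("dbSNP", "chr6:43600837:G:A", 0.002)
  gnomad2 <- freqTab("gnomAD", "chr6:43600837:G:A", 0.00355)
  expect_equal(maxObservedMaf("chr6", 43608202L, "C", "T",
                              list(gnomad, dbsnp)), 3 / 248598)
  expect_equal(maxObservedMaf("chr6", 43600837L, "G", "A",
                              list(gnomad2, dbsnp)), 0.00355)
  ## absent from every database: "not observed", not zero
  expect_true(is.na(maxObservedMaf("chr6", 43607867L, "TT", "T",
                                   list(gnomad, dbsnp))))
})

test_that("filterRare keeps sub-threshold and unobserved variants", {
  vs <- makeVS(rep("chr1", 3), c(10L, 20L, 30L), rep("A", 3),
               rep("G", 3), list(S1 = rep("0/1", 3)))
  tabs <- list(freqTab("gnomAD", c("chr1:10:A:G", "chr1:20:A:G"),
                       c(0.00355, 0.02)))
  vs <- annotateFrequencies(vs, tabs)
  out <- filterRare(vs, filterParams(mafThreshold = 0.01))
  expect_equal(out$count, 2L)
  expect_setequal(out$variants@pos, c(10L, 30L))  # 0.02 removed
})

test_that("filterRare equals a direct set comprehension on 1000 variants", {
  set.seed(31)
  n <- 1000
  af <- ifelse(runif(n) < 0.3, NA, runif(n, 0, 0.05))
  vs <- makeVS(rep("chr1", n), seq_len(n) * 10L, rep("A", n),
               rep("G", n), list(S1 = rep("0/1", n)))
  present <- which(!is.na(af))
  tabs <- list(freqTab("gnomAD", variantKeys(vs)[present], af[present]))
  vs <- annotateFrequencies(vs, tabs)
  out <- filterRare(vs, filterParams(mafThreshold = 0.01))
  want <- sort(vs@pos[is.na(af) | af < 0.01])
  expect_equal(sort(out$variants@pos), want)
})

test_that("functional filter keeps the deleterious classes only", {
  cls <- c("stopgain", "synonymous", "intronic", "splicing", "missense",
           "UTR3", "frameshift_deletion", "intergenic", "inframe_indel")
  n <- length(cls)
  vs <- makeVS(rep("chr1", n), seq_len(n) * 10L, rep("A", n),
               rep("G", n), list(S1 = rep("0/1", n)),
               anno = data.frame(functional_class = cls,
                                 stringsAsFactors = FALSE))
  out <- filterFunctional(vs)
  kept <- annotations(out$variants)$functional_class
  expect_setequal(kept, c("stopgain", "splicing", "missense",
                          "frameshift_deletion", "inframe_indel"))
  expect_equal(out$count, 5L)
  dropped <- annotations(out$dropped)$functional_class
  expect_true(all(c("synonymous", "intronic", "UTR3", "intergenic")
                  %in% dropped))
})

test_that("unclassified variants abort the functional filter by name", {
  vs <- makeVS("chr1", 10L, "A", "G", list(S1 = "0/1"),
               anno = data.frame(functional_class = NA_character_))
  expect_error(filterFunctional(vs), "chr1:10:A:G")
})

test_that("rarity and functional filters commute", {
  set.seed(5)
  n <- 200
  cls <- sample(TrioCascade:::functionalClasses, n, replace = TRUE)
  af <- ifelse(runif(n) < 0.3, NA, runif(n, 0, 0.03))
  vs <- makeVS(rep("chr1", n), seq_len(n) * 10L, rep("A", n),
               rep("G", n), list(S1 = rep("0/1", n)),
               anno = data.frame(functional_class = cls,
                                 stringsAsFactors = FALSE))
  present <- which(!is.na(af))
  vs <- annotateFrequencies(
    vs, list(freqTab("gnomAD", variantKeys(vs)[present], af[present])))
  ab <- filterFunctional(filterRare(vs)$variants)$variants
  ba <- filterRare(filterFunctional(vs)$variants)$variants
  expect_equal(variantKeys(ab), variantKeys(ba))
})

## Rescue scenarios: a family with a surviving het frameshift and a
## dropped het intronic in the same gene.
rescueFixture <- function(intronFather = "0/1", intronMother = "0/0",
                          fsFather = "0/0", fsMother = "0/1") {
  ped <- makeTrioPed("F2")
  surviving <- makeVS(
    "chr1", 1000L, "TT", "T",
    list(F2_father = fsFather, F2_mother = fsMother,
         F2_proband = "0/1"),
    anno = data.frame(gene = "GENE1",
                      functional_class = "frameshift_deletion",
                      stringsAsFactors = FALSE))
  dropped <- makeVS(
    "chr1", 2000L, "G", "A",
    list(F2_father = intronFather, F2_mother = intronMother,
         F2_proband = "0/1"),
    anno = data.frame(gene = "GENE1", functional_class = "intronic",
                      stringsAsFactors = FALSE))
  list(ped = ped, surviving = surviving, dropped = dropped)
}

test_that("a trans-configured intronic partner is rescued", {
  fx <- rescueFixture()
  out <- applyRescueList(fx$dropped, fx$surviving, fx$ped)
  expect_equal(nVariants(out), 1L)
  expect_true(all(annotations(out)$rescued))
})

test_that("an intronic variant from the same parent is not rescued", {
  fx <- rescueFixture(intronFather = "0/0", intronMother = "0/1")
  out <- applyRescueList(fx$dropped, fx$surviving, fx$ped)
  expect_equal(nVariants(out), 0L)
})

test_that("a gene with only intronic variants rescues nothing", {
  fx <- rescueFixture()
  noLof <- fx$surviving[integer(0)]
  out <- applyRescueList(fx$dropped, noLof, fx$ped)
  expect_equal(nVariants(out), 0L)
})

test_that("rescue enumerates parental-origin combinations correctly", {
  gts <- c("0/0", "0/1")
  for (fF in gts) for (fM in gts) for (iF in gts) for (iM in gts) {
    fx <- rescueFixture(intronFather = iF, intronMother = iM,
                        fsFather = fF, fsMother = fM)
    out <- applyRescueList(fx$dropped, fx$surviving, fx$ped)
    fsOrig <- if (fF == "0/1" && fM == "0/0") "father"
      else if (fM == "0/1" && fF == "0/0") "mother" else "ambiguous"
    inOrig <- if (iF == "0/1" && iM == "0/0") "father"
      else if (iM == "0/1" && iF == "0/0") "mother" else "ambiguous"
    wantRescue <- !(fsOrig %in% c("father", "mother") &&
                      fsOrig == inOrig)
    expect_equal(nVariants(out) == 1L, wantRescue,
                 info = paste(fF, fM, iF, iM))
  }
})
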