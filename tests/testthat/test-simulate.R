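test_that("degenerate allele frequencies give fixed genotypes", {
  set.seed(1)
  g0 <- simulateTrioGenotypes(rep(0, 50))
  expect_true(all(unlist(g0) == 0L))
  g1 <- simulateTrioGenotypes(rep(1, 50))
  expect_true(all(unlist(g1) == 1L))
})

test_that("offspring het fraction matches Mendelian expectation", {
  set.seed(123)
  af <- 0.3
  n <- 10000L
  g <- simulateTrioGenotypes(rep(af, n))
  ## each child allele is an unconditional Bernoulli(af) draw, so
  ## P(het) = 2 af (1 - af)
  pHet <- 2 * af * (1 - af)
  childHet <- mean((g$childA + g$childB) == 1L)
  se <- sqrt(pHet * (1 - pHet) / n)
  expect_lt(abs(childHet - pHet), 3 * se)
  ## founder empirical AF converges to the generating AF
  fAf <- mean(c(g$fatherA, g$fatherB, g$motherA, g$motherB))
  seF <- sqrt(af * (1 - af) / (4 * n))
  expect_lt(abs(fAf - af), 4 * seF)
})

mendelianViolations <- function(vs, ped) {
  d <- dosage(vs)
  pid <- probandId(ped)
  par <- parentsOf(ped, pid)
  dp <- d[, pid]; df <- d[, par$father]; dm <- d[, par$mother]
  ok <- !is.na(dp) & !is.na(df) & !is.na(dm)
  ## impossible transmissions for autosomal biallelic sites
  bad <- (dp == 2L & (df == 0L | dm == 0L)) |
    (dp == 0L & (df == 2L | dm == 2L)) |
    (dp == 1L & df == 0L & dm == 0L) |
    (dp == 1L & df == 2L & dm == 2L)
  sum(bad & ok)
}

test_that("simulated trios contain zero Mendelian errors at no missingness", {
  cfg <- simulationConfig(nFamilies = 2,
                          scenarios = c("HOM_NONSENSE_IN_ROH",
                                        "COMPHET_FRAMESHIFT_PLUS_INTRONIC"),
                          nBackgroundVariants = 3000L,
                          genotypeMissingness = 0, seed = 99)
  dir <- file.path(tempdir(), "simMendel")
  simulateCohort(cfg, dir)
  peds <- readPedFile(file.path(dir, "cohort.ped"))
  for (fam in names(peds)) {
    vs <- readCohortVcf(file.path(dir, paste0(fam, ".vcf")), peds[[fam]])
    expect_equal(mendelianViolations(vs, peds[[fam]]), 0L)
  }
})

test_that("the same seed reproduces a byte-identical bundle", {
  cfg <- simulationConfig(nFamilies = 2,
                          scenarios = c("HOM_NONSENSE", "NONE"),
                          nBackgroundVariants = 800L, seed = 42)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  simulateCohort(cfg, d1)
  simulateCohort(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("a planted homozygous nonsense sits inside a >= 2.5 Mb block", {
  cfg <- simulationConfig(nFamilies = 1,
                          scenarios = "HOM_NONSENSE_IN_ROH",
                          sharedCausalGene = FALSE,
                          nBackgroundVariants = 4000L, seed = 7)
  dir <- file.path(tempdir(), "simRoh")
  res <- simulateCohort(cfg, dir)
  truth <- res$truth
  expect_equal(nrow(truth), 1L)
  expect_true(truth$in_roh)
  ped <- res$pedigrees[["F1"]]
  expect_true(isConsanguineous(ped))
  vs <- readCohortVcf(file.path(dir, "F1.vcf"), ped)
  key <- truth$keys
  i <- match(key, variantKeys(vs))
  expect_false(is.na(i))
  ## proband 1/1, both parents 0/1
  d <- dosage(vs)
  expect_equal(unname(d[i, "F1_proband"]), 2L)
  expect_equal(unname(d[i, "F1_father"]), 1L)
  expect_equal(unname(d[i, "F1_mother"]), 1L)
  ## the planted block itself is >= 2.5 Mb and covers the variant
  blocks <- res$rohBlocks[["F1"]]
  covering <- blocks$chrom == vs@chrom[i] & blocks$start <= vs@pos[i] &
    blocks$end >= vs@pos[i]
  expect_true(any(covering))
  expect_true(all(blocks$end - blocks$start + 1 >= 2.5e6))
  ## and the detector recovers a segment over the planted variant
  segs <- detectRoh(vs, "F1_proband")
  hit <- segs$chrom == vs@chrom[i] & segs$start <= vs@pos[i] &
    segs$end >= vs@pos[i]
  expect_true(any(hit))
})

test_that("the comp-het scenario plants trans alleles in one gene", {
  cfg <- simulationConfig(nFamilies = 1,
                          scenarios = "COMPHET_FRAMESHIFT_PLUS_INTRONIC",
                          sharedCausalGene = FALSE,
                          nBackgroundVariants = 1000L, seed = 13)
  dir <- file.path(tempdir(), "simCh")
  res <- simulateCohort(cfg, dir)
  keys <- strsplit(res$truth$keys, ";", fixed = TRUE)[[1]]
  expect_length(keys, 2)
  vs <- readCohortVcf(file.path(dir, "F1.vcf"),
                      res$pedigrees[["F1"]])
  i <- match(keys, variantKeys(vs))
  d <- dosage(vs)
  ## proband het for both; opposite parental origins
  expect_equal(unname(d[i, "F1_proband"]), c(1L, 1L))
  origins <- ifelse(d[i, "F1_father"] >= 1, "father", "mother")
  expect_setequal(origins, c("father", "mother"))
  ## the intronic partner is 10..200 bp inside an intron of the gene
  models <- readTranscriptModels(file.path(dir, "gene_models.tsv"),
                                 file.path(dir, "cds.fa"))
  gene <- res$truth$gene
  m <- Filter(function(x) x@gene == gene, models)[[1]]
  calls <- lapply(i, function(k)
    callConsequence(m, vs@chrom[k], vs@pos[k], vs@ref[k], vs@alt[k]))
  classes <- vapply(calls, function(x) x$functional_class, "")
  expect_setequal(classes, c("frameshift_deletion", "intronic"))
  off <- calls[[which(classes == "intronic")]]$intron_offset
  expect_true(abs(off) >= 10 && abs(off) <= 200)
})

test_that("truth files round-trip and validate keys", {
  truth <- data.frame(
    family_id = c("F1", "F2"), scenario = c("HOM_NONSENSE", "NONE"),
    keys = c("chr1:100:A:G", "scaffold_77:5:AT:A;chr2:9:G:C"),
    model = c("hom_recessive", "compound_het"),
    in_roh = c(TRUE, FALSE), gene = c("G1", "G2"),
    stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  writeTruth(truth, path)
  back <- loadTruth(path)
  expect_equal(back, truth)
  ## novel chromosome names are preserved verbatim
  expect_true(grepl("scaffold_77", back$keys[2]))
  empty <- truth[integer(0), ]
  writeTruth(empty, path)
  expect_equal(nrow(loadTruth(path)), 0L)
  bad <- writeLinesTmp(c("family_id\tscenario\tkeys\tmodel\tin_roh\tgene",
                         "F1\tX\tnot-a-key\thom_recessive\tTRUE\tG"),
                       ".tsv")
  expect_error(loadTruth(bad), "malformed")
})

test_that("contradictory configs are rejected", {
  expect_error(simulationConfig(nFamilies = 1, sharedCausalGene = TRUE),
               "at least 2")
  expect_error(simulationConfig(scenarios = "NOT_A_SCENARIO"),
               "unknown scenario")
  expect_error(simulationConfig(afMix = c(common = 0.5, rare = 0.1,
                                          absent = 0.1)), "sum to 1")
})
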