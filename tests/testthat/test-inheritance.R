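dosageToGt <- c("0/0", "0/1", "1/1")

trioVS <- function(dp, df, dm, famId = "F1", chrom = "chr1",
                   gene = "GENE1") {
  gt <- function(d) if (is.na(d)) "./." else dosageToGt[d + 1L]
  makeVS(chrom, 100L, "A", "G",
         list(gt(df), gt(dm), gt(dp)) |>
           setNames(paste0(famId, c("_father", "_mother", "_proband"))),
         anno = data.frame(gene = gene, stringsAsFactors = FALSE))
}

test_that("sex chromosomes are excluded whatever the spelling", {
  vs <- makeVS(c("chr6", "chrX", "chrY", "chr22", "X", "Y"),
               seq_len(6) * 10L, rep("A", 6), rep("G", 6),
               list(S1 = rep("0/1", 6)))
  out <- filterAutosomal(vs)
  expect_setequal(out@chrom, c("chr6", "chr22"))
  expect_equal(nVariants(filterAutosomal(vs[integer(0)])), 0L)
})

test_that("homozygous-recessive detection matches the 27-case truth table", {
  ped <- makeTrioPed("F1")
  for (dp in 0:2) for (df in 0:2) for (dm in 0:2) {
    vs <- trioVS(dp, df, dm)
    got <- findHomozygousRecessive(vs, ped)
    want <- dp == 2L && df == 1L && dm == 1L
    expect_equal(nrow(got) == 1L, want,
                 info = sprintf("proband=%d father=%d mother=%d",
                                dp, df, dm))
    if (want) {
      expect_equal(got$model, "hom_recessive")
      expect_false(got$parents_unverified)
    }
  }
})

test_that("missing parents relax the carrier check with a flag", {
  ped <- makeTrioPed("F1")
  vs <- trioVS(2L, NA, 1L)
  got <- findHomozygousRecessive(vs, ped)
  expect_equal(nrow(got), 1L)
  expect_true(got$parents_unverified)
  ## proband not hom-alt never qualifies, genotyped parents or not
  expect_equal(nrow(findHomozygousRecessive(trioVS(1L, NA, NA), ped)), 0L)
})

test_that("a homozygous unaffected sibling rejects strictly, warns leniently", {
  extra <- data.frame(sample_id = "F1_brother", father = "F1_father",
                      mother = "F1_mother", sex = 1L, affected = FALSE,
                      stringsAsFactors = FALSE)
  ped <- makeTrioPed("F1", extra = extra)
  vs <- makeVS("chr1", 100L, "A", "G",
               list(F1_father = "0/1", F1_mother = "0/1",
                    F1_proband = "1/1", F1_brother = "1/1"),
               anno = data.frame(gene = "GENE1"))
  expect_equal(nrow(findHomozygousRecessive(vs, ped,
                                            strictSiblings = TRUE)), 0L)
  expect_warning(
    got <- findHomozygousRecessive(vs, ped, strictSiblings = FALSE),
    "lenient")
  expect_equal(nrow(got), 1L)
  ## an *affected* sibling with the same homozygote is never exclusionary
  extra$affected <- TRUE
  pedAff <- makeTrioPed("F1", extra = extra)
  expect_equal(nrow(findHomozygousRecessive(vs, pedAff,
                                            strictSiblings = TRUE)), 1L)
})

test_that("compound hets phase by parental origin", {
  ped <- makeTrioPed("F2")
  vs <- makeVS(c("chr1", "chr1"), c(100L, 200L), c("TT", "G"),
               c("T", "A"),
               list(F2_father = c("0/0", "0/1"),
                    F2_mother = c("0/1", "0/0"),
                    F2_proband = c("0/1", "0/1")),
               anno = data.frame(gene = c("GENE1", "GENE1")))
  got <- findCompoundHet(vs, ped)
  expect_equal(nrow(got), 1L)
  expect_equal(got$phase_status, "trans_confirmed")
  expect_equal(got$model, "compound_het")

  ## both alleles from the mother: rejected as cis
  cis <- makeVS(c("chr1", "chr1"), c(100L, 200L), c("T", "G"),
                c("A", "A"),
                list(F2_father = c("0/0", "0/0"),
                     F2_mother = c("0/1", "0/1"),
                     F2_proband = c("0/1", "0/1")),
                anno = data.frame(gene = c("GENE1", "GENE1")))
  expect_equal(nrow(findCompoundHet(cis, ped)), 0L)

  ## ungenotyped father: retained as phase_unknown
  unk <- makeVS(c("chr1", "chr1"), c(100L, 200L), c("T", "G"),
                c("A", "A"),
                list(F2_father = c("./.", "./."),
                     F2_mother = c("0/1", "0/0"),
                     F2_proband = c("0/1", "0/1")),
                anno = data.frame(gene = c("GENE1", "GENE1")))
  gotUnk <- findCompoundHet(unk, ped)
  expect_equal(gotUnk$phase_status, "phase_unknown")
})

test_that("compound-het search equals brute-force pair enumeration", {
  ped <- makeTrioPed("F3")
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    genes <- sample(c("G1", "G2", "G3"), n, replace = TRUE)
    gtP <- sample(c("0/1", "0/0", "1/1"), n, replace = TRUE,
                  prob = c(0.6, 0.3, 0.1))
    gtF <- sample(c("0/0", "0/1"), n, replace = TRUE)
    gtM <- sample(c("0/0", "0/1"), n, replace = TRUE)
    vs <- makeVS(rep("chr2", n), seq_len(n) * 50L, rep("A", n),
                 rep("G", n),
                 list(F3_father = gtF, F3_mother = gtM, F3_proband = gtP),
                 anno = data.frame(gene = genes,
                                   stringsAsFactors = FALSE))
    got <- findCompoundHet(vs, ped)
    ## independent oracle: exhaustive scan over ordered index pairs
    keys <- variantKeys(vs)
    origin <- ifelse(gtF == "0/1" & gtM == "0/0", "father",
              ifelse(gtM == "0/1" & gtF == "0/0", "mother", "ambiguous"))
    wantPairs <- character()
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i >= j) next
      if (genes[i] != genes[j]) next
      if (gtP[i] != "0/1" || gtP[j] != "0/1") next
      oi <- origin[i]; oj <- origin[j]
      if (oi %in% c("father", "mother") && oi == oj) next  # cis
      wantPairs <- c(wantPairs, paste(sort(c(keys[i], keys[j])),
                                      collapse = "|"))
    }
    gotPairs <- if (nrow(got))
      vapply(seq_len(nrow(got)), function(r)
        paste(sort(c(got$key[r], got$key2[r])), collapse = "|"), "")
    else character()
    expect_setequal(gotPairs, wantPairs)
    ## dosage invariants: hom candidates dose 2, comp-het members dose 1
    if (nrow(got)) {
      d <- dosage(vs, "F3_proband")[, 1]
      names(d) <- keys
      expect_true(all(d[got$key] == 1L & d[got$key2] == 1L))
    }
  }
})
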