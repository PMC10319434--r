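#' @include cohort.R
NULL

## All simulator randomness flows through one explicitly seeded stream;
## the global RNG state is saved and restored.
withSeed <- function(seed, expr) {
  hasSeed <- exists(".Random.seed", envir = globalenv())
  if (hasSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hasSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

simScenarios <- c("HOM_NONSENSE_IN_ROH", "COMPHET_FRAMESHIFT_PLUS_INTRONIC",
                  "HOM_NONSENSE", "NONE")

#' Configuration of the synthetic trio-cohort generator
#'
#' The generator emits, per family, a trio VCF whose record list has the
#' statistical shape the cascade assumes: exome-scale variant counts, an
#' allele-frequency spectrum dominated by common alleles with a rare tail
#' and a configurable fraction absent from every database, Mendelian
#' transmission, autozygosity blocks in consanguineous probands, and planted
#' causal alleles per scenario.
#'
#' @param nFamilies number of trio families.
#' @param scenarios character vector (recycled/truncated to `nFamilies`)
#'   over `HOM_NONSENSE_IN_ROH`, `COMPHET_FRAMESHIFT_PLUS_INTRONIC`,
#'   `HOM_NONSENSE`, `NONE`.
#' @param sharedCausalGene plant all scenarios in one gene (>= 2 families
#'   required).
#' @param nBackgroundVariants background records per family VCF (default
#'   20000; ~130000 emulates a full-scale exome variant list).
#' @param afMix named fractions `common`, `rare`, `absent` (sum 1):
#'   common AF ~ U(0.01, 0.5); rare AF ~ Exp(mean `rareMeanAf`) truncated
#'   below 0.01; absent variants appear in no database.
#' @param rareMeanAf mean of the rare-tail AF distribution (0.001).
#' @param classMix named fractions of variant placement over `coding`,
#'   `coding_indel`, `splice`, `intronic`, `utr`, `intergenic` (sum 1).
#'   Realized consequence classes of coding SNVs (stopgain / missense /
#'   synonymous) follow from the actual codon change.
#' @param rohBlockLengthBp length range of consanguineous autozygosity
#'   blocks (default 2.5-10 Mb).
#' @param genotypeMissingness per-call missing probability (default 0).
#' @param nGenes,nChrom,chromLengthBp synthetic genome geometry.
#' @param seed integer; fully determines the output.
#' @return validated config list of class `SimulationConfig`.
#' @export
simulationConfig <- function(
    nFamilies = 3L,
    scenarios = c("HOM_NONSENSE_IN_ROH",
                  "COMPHET_FRAMESHIFT_PLUS_INTRONIC", "HOM_NONSENSE"),
    sharedCausalGene = TRUE,
    nBackgroundVariants = 20000L,
    afMix = c(common = 0.93, rare = 0.05, absent = 0.02),
    rareMeanAf = 0.001,
    classMix = c(coding = 0.10, coding_indel = 0.005, splice = 0.005,
                 intronic = 0.55, utr = 0.14, intergenic = 0.20),
    rohBlockLengthBp = c(2.5e6, 1e7),
    genotypeMissingness = 0,
    nGenes = 300L, nChrom = 3L, chromLengthBp = 4e7,
    seed = 1L) {
  scenarios <- rep(scenarios, length.out = nFamilies)
  if (!all(scenarios %in% simScenarios))
    stop("unknown scenario(s): ",
         paste(setdiff(scenarios, simScenarios), collapse = ", "))
  if (abs(sum(afMix) - 1) > 1e-8) stop("afMix must sum to 1")
  if (abs(sum(classMix) - 1) > 1e-8) stop("classMix must sum to 1")
  if (sharedCausalGene && nFamilies < 2L)
    stop("shared_causal_gene needs at least 2 families")
  if (genotypeMissingness < 0 || genotypeMissingness >= 1)
    stop("genotype missingness must be in [0, 1)")
  structure(list(
    nFamilies = as.integer(nFamilies), scenarios = scenarios,
    sharedCausalGene = isTRUE(sharedCausalGene),
    nBackgroundVariants = as.integer(nBackgroundVariants),
    afMix = afMix, rareMeanAf = rareMeanAf, classMix = classMix,
    rohBlockLengthBp = as.numeric(rohBlockLengthBp),
    genotypeMissingness = genotypeMissingness,
    nGenes = as.integer(nGenes), nChrom = as.integer(nChrom),
    chromLengthBp = as.numeric(chromLengthBp),
    seed = as.integer(seed)), class = "SimulationConfig")
}

nonStopCodons <- function() {
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  all3[!all3 %in% c("TAA", "TAG", "TGA")]
}

randomCds <- function(nAa) {
  body <- sample(nonStopCodons(), nAa - 1L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

## One synthetic multi-exon gene with a valid CDS.
randomGeneModel <- function(id, gene, chrom, geneStart) {
  nAa <- sample(150:450, 1)
  cdsLen <- 3L * (nAa + 1L)
  u5 <- sample(30:150, 1); u3 <- sample(60:300, 1)
  total <- u5 + cdsLen + u3
  nEx <- sample(3:8, 1)
  cuts <- sort(sample(seq(60L, total - 60L), nEx - 1L))
  lens <- diff(c(0L, cuts, total))
  while (any(lens < 20L)) {           # re-draw thin exons
    cuts <- sort(sample(seq(60L, total - 60L), nEx - 1L))
    lens <- diff(c(0L, cuts, total))
  }
  introns <- sample(500:8000, nEx - 1L, replace = TRUE)
  starts <- integer(nEx); ends <- integer(nEx)
  cur <- as.integer(geneStart)
  for (i in seq_len(nEx)) {
    starts[i] <- cur; ends[i] <- cur + lens[i] - 1L
    if (i < nEx) cur <- ends[i] + introns[i] + 1L
  }
  strand <- sample(c("+", "-"), 1, prob = c(0.7, 0.3))
  exonic <- unlist(mapply(seq, starts, ends, SIMPLIFY = FALSE))
  if (strand == "+") {
    lo <- exonic[u5 + 1L]; hi <- exonic[u5 + cdsLen]
  } else {
    lo <- exonic[u3 + 1L]; hi <- exonic[u3 + cdsLen]
  }
  utr3seq <- paste0(paste(sample(c("A", "C", "G", "T"), 51, replace = TRUE),
                          collapse = ""), "TAATAATAA")
  transcriptModel(id, gene, chrom, strand, starts, ends, lo, hi,
                  randomCds(nAa), utr3seq)
}

generateGeneModels <- function(config) {
  perChrom <- ceiling(config$nGenes / config$nChrom)
  slot <- floor(config$chromLengthBp / (perChrom + 1))
  models <- list()
  k <- 0L
  for (c in seq_len(config$nChrom)) {
    for (g in seq_len(perChrom)) {
      if (k >= config$nGenes) break
      k <- k + 1L
      id <- sprintf("TX%04d", k)
      gene <- sprintf("SIMG%04d", k)
      geneStart <- (g - 1L) * slot + sample.int(floor(slot / 3), 1) + 1000L
      models[[id]] <- randomGeneModel(id, gene, paste0("chr", c),
                                      geneStart)
    }
  }
  models
}

## Forward-strand reference base at a coding genomic position.
forwardBaseAt <- function(model, g) {
  p <- genomicToCdna(model, g)$cds_pos
  b <- substring(model@cdsSequence, p, p)
  if (model@strand == "-") complementBase(b) else b
}

#' Simulate trio genotypes at independent sites
#'
#' Founder (parental) alleles are i.i.d. Bernoulli(af) per site; the
#' offspring inherits one uniformly chosen allele from each parent.  Inside
#' autozygosity blocks (`autozygous` TRUE) the two offspring alleles are
#' copies of a single parental allele: the mother's transmitted allele is
#' forced identical in state to the father's transmitted one (the parents
#' share a haplotype identical by descent), so transmission stays
#' Mendelian-consistent while the offspring is homozygous at every block
#' site.
#'
#' @param af per-site allele frequencies (length n).
#' @param autozygous logical length-n mask (default all FALSE).
#' @param requireVariant condition founder draws on carrying at least one
#'   ALT allele in the family (used for emitted variant lists; default
#'   FALSE gives the unconditional model).
#' @return list of integer vectors `fatherA`, `fatherB`, `motherA`,
#'   `motherB`, `childA`, `childB` (0 = REF, 1 = ALT).
#' @export
simulateTrioGenotypes <- function(af, autozygous = NULL,
                                  requireVariant = FALSE) {
  n <- length(af)
  stopifnot(all(af >= 0 & af <= 1))
  if (is.null(autozygous)) autozygous <- rep(FALSE, n)
  if (!requireVariant) {
    founders <- matrix(rbinom(4L * n, 1L, rep(af, 4L)), n, 4L)
  } else {
    ## number of ALT alleles among 4 founder slots, conditioned >= 1
    q <- 1 - af
    pk <- cbind(4 * af * q^3, 6 * af^2 * q^2, 4 * af^3 * q, af^4)
    pk <- pk / pmax(rowSums(pk), .Machine$double.xmin)
    u <- runif(n)
    cum <- t(apply(pk, 1, cumsum))
    kAlt <- rowSums(u > cum) + 1L
    r <- matrix(runif(4L * n), n, 4L)
    rk <- matrix(0L, n, 4L)            # rank of each slot within its row
    for (a in 1:4) for (b in 1:4)
      if (a != b) rk[, a] <- rk[, a] + (r[, b] < r[, a])
    founders <- (rk < kAlt) * 1L
  }
  fatherA <- founders[, 1]; fatherB <- founders[, 2]
  motherA <- founders[, 3]; motherB <- founders[, 4]
  fromF <- runif(n) < 0.5
  fromM <- runif(n) < 0.5
  childA <- ifelse(fromF, fatherA, fatherB)
  if (any(autozygous)) {
    ## IBD sharing: mother's transmitted allele copies the father's
    transmitted <- childA[autozygous]
    motherSlotA <- fromM[autozygous]
    motherA[autozygous][motherSlotA] <- transmitted[motherSlotA]
    motherB[autozygous][!motherSlotA] <- transmitted[!motherSlotA]
  }
  childB <- ifelse(fromM, motherA, motherB)
  list(fatherA = fatherA, fatherB = fatherB, motherA = motherA,
       motherB = motherB, childA = childA, childB = childB)
}

randomBase <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

randomOtherBase <- function(ref) {
  vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
}

randomOtherBases <- function(ref) {
  bases <- c("A", "C", "G", "T")
  shift <- sample(1:3, length(ref), replace = TRUE)
  idx <- (match(ref, bases) - 1L + shift) %% 4L + 1L
  bases[idx]
}

## Forward-strand CDS bases at coding genomic positions, vectorized.
forwardBasesAt <- function(model, g) {
  p <- genomicToCdna(model, g)$cds_pos
  b <- substring(model@cdsSequence, p, p)
  if (model@strand == "-") complementBase(b) else b
}

## Draw background variant sites for one family, vectorized per gene.
## Returns data.frame with chrom, pos, ref, alt (forward strand).
drawBackgroundSites <- function(config, models, n) {
  cats <- sample(names(config$classMix), n, replace = TRUE,
                 prob = config$classMix)
  chroms <- paste0("chr", seq_len(config$nChrom))
  geneIdx <- sample(length(models), n, replace = TRUE)
  chrom <- character(n); pos <- integer(n)
  ref <- character(n); alt <- character(n)

  ## intergenic sites are gene-independent
  ig <- which(cats == "intergenic")
  if (length(ig)) {
    chrom[ig] <- sample(chroms, length(ig), replace = TRUE)
    pos[ig] <- sample.int(config$chromLengthBp, length(ig),
                          replace = TRUE)
    ref[ig] <- randomBase(length(ig))
    alt[ig] <- randomOtherBases(ref[ig])
  }

  genic <- setdiff(seq_len(n), ig)
  for (mi in unique(geneIdx[genic])) {
    m <- models[[mi]]
    seg <- codingSegments(m)
    cds <- m@cdsSequence
    nCds <- nchar(cds)
    ex <- m@exons
    nEx <- length(ex)
    idxAll <- genic[geneIdx[genic] == mi]
    chrom[idxAll] <- m@chrom
    catm <- cats[idxAll]

    j <- idxAll[catm == "coding"]
    if (length(j)) {
      p <- sample(4:(nCds - 6L), length(j), replace = TRUE)
      pos[j] <- cdnaToGenomic(m, p)
      refCds <- substring(cds, p, p)
      ref[j] <- if (m@strand == "-") complementBase(refCds) else refCds
      alt[j] <- randomOtherBases(ref[j])
    }

    j <- idxAll[catm == "coding_indel"]
    if (length(j)) {
      ## 1-bp deletion of cds base p+1, both bases in one coding segment
      wide <- which(seg$cEnd - seg$cStart >= 1L)
      sIdx <- wide[sample.int(length(wide), length(j), replace = TRUE)]
      p <- seg$cStart[sIdx] +
        floor(runif(length(j)) * (seg$cEnd[sIdx] - seg$cStart[sIdx]))
      g1 <- cdnaToGenomic(m, p)
      g2 <- cdnaToGenomic(m, p + 1L)
      anchor <- pmin(g1, g2)
      b1 <- forwardBasesAt(m, anchor)
      b2 <- forwardBasesAt(m, anchor + 1L)
      pos[j] <- anchor
      ref[j] <- paste0(b1, b2)
      alt[j] <- b1
    }

    j <- idxAll[catm == "splice"]
    if (length(j)) {
      k <- sample.int(nEx - 1L, length(j), replace = TRUE)
      pos[j] <- IRanges::end(ex)[k] + sample(1:2, length(j),
                                             replace = TRUE)
      ref[j] <- randomBase(length(j))
      alt[j] <- randomOtherBases(ref[j])
    }

    j <- idxAll[catm == "intronic"]
    if (length(j)) {
      k <- sample.int(nEx - 1L, length(j), replace = TRUE)
      lo <- IRanges::end(ex)[k] + 6L
      hi <- IRanges::start(ex)[k + 1L] - 6L
      hi <- pmax(hi, lo)
      pos[j] <- lo + floor(runif(length(j)) * (hi - lo + 1L))
      ref[j] <- randomBase(length(j))
      alt[j] <- randomOtherBases(ref[j])
    }

    j <- idxAll[catm == "utr"]
    if (length(j)) {
      leftLo <- IRanges::start(ex)[1]; leftHi <- m@cdsStart - 1L
      rightLo <- m@cdsEnd + 1L; rightHi <- IRanges::end(ex)[nEx]
      useLeft <- runif(length(j)) < 0.5 & leftHi >= leftLo
      lo <- ifelse(useLeft, leftLo, rightLo)
      hi <- ifelse(useLeft, leftHi, rightHi)
      hi <- pmax(hi, lo)
      pos[j] <- lo + floor(runif(length(j)) * (hi - lo + 1L))
      ref[j] <- randomBase(length(j))
      alt[j] <- randomOtherBases(ref[j])
    }
  }
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

drawAfSpectrum <- function(config, n) {
  tier <- sample(c("common", "rare", "absent"), n, replace = TRUE,
                 prob = config$afMix[c("common", "rare", "absent")])
  af <- numeric(n)
  af[tier == "common"] <- runif(sum(tier == "common"), 0.01, 0.5)
  nr <- sum(tier != "common")
  x <- rexp(nr, 1 / config$rareMeanAf)
  x[x >= 0.0099] <- 0.0099
  x <- pmax(x, 1e-6)
  af[tier != "common"] <- x
  list(af = af, tier = tier)
}

## Scenario planting helpers ------------------------------------------------

findStopgainSite <- function(model) {
  cds <- model@cdsSequence
  nAa <- nchar(cds) / 3 - 1
  bases <- c("A", "C", "G", "T")
  for (ci in sample(10:(nAa - 10), nAa - 19)) {
    codon <- substring(cds, (ci - 1) * 3 + 1, ci * 3)
    for (k in 1:3) for (b in bases) {
      if (b == substring(codon, k, k)) next
      mut <- codon
      substr(mut, k, k) <- b
      if (GENETIC_CODE_TABLE[[mut]] == "*") {
        p <- (ci - 1L) * 3L + k
        refCds <- substring(cds, p, p)
        g <- cdnaToGenomic(model, p)
        refF <- if (model@strand == "-") complementBase(refCds) else refCds
        altF <- if (model@strand == "-") complementBase(b) else b
        return(list(pos = g, ref = refF, alt = altF, cds_pos = p,
                    codon = ci))
      }
    }
  }
  stop("no stopgain-able codon found in ", model@transcriptId)
}

findFrameshiftSite <- function(model) {
  cds <- model@cdsSequence
  nCds <- nchar(cds)
  for (p in sample(30:(nCds - 30), 200, replace = TRUE)) {
    g <- cdnaToGenomic(model, p)
    gNext <- if (model@strand == "+") g + 1L else g - 1L
    anchorG <- min(g, gNext)
    r <- tryCatch({
      c1 <- genomicToCdna(model, anchorG)
      c2 <- genomicToCdna(model, anchorG + 1L)
      if (c1$region != "coding" || c2$region != "coding") NULL
      else {
        b1 <- forwardBaseAt(model, anchorG)
        b2 <- forwardBaseAt(model, anchorG + 1L)
        if (b1 == b2) NULL
        else list(pos = anchorG, ref = paste0(b1, b2), alt = b1)
      }
    }, error = function(e) NULL)
    if (!is.null(r)) return(r)
  }
  stop("no clean frameshift site in ", model@transcriptId)
}

findDeepIntronicSite <- function(model) {
  seg <- codingSegments(model)
  for (j in 2:nrow(seg)) {
    cFirst <- seg$cStart[j]
    for (d in sample(10:200, 50, replace = TRUE)) {
      g <- tryCatch(cdnaToGenomic(model, cFirst, -d),
                    error = function(e) NA_integer_)
      if (is.na(g)) next
      hit <- genomicToCdna(model, g)
      if (hit$region == "intron" && !is.na(hit$cds_pos) &&
          hit$cds_pos == cFirst && hit$intron_offset == -d) {
        r <- randomBase(1)
        return(list(pos = g, ref = r, alt = randomOtherBase(r),
                    offset = -d))
      }
    }
  }
  stop("no deep-intronic acceptor site in ", model@transcriptId)
}

pickCausalGene <- function(models) {
  ok <- vapply(models, function(m)
    length(m@exons) >= 3 && nchar(m@cdsSequence) >= 600, TRUE)
  cand <- which(ok)
  models[[cand[sample(length(cand), 1)]]]
}

## --------------------------------------------------------------------------

#' Generate a fully self-contained synthetic cohort bundle
#'
#' Writes, under `dir`: one trio VCF per family (`<family>.vcf`), a
#' `cohort.ped`, one frequency table per database (`freq_<db>.tsv`), shared
#' gene models (`gene_models.tsv` + `cds.fa`), an oocyte `expression.tsv`
#' and a `truth.tsv` of planted causal records.  Deterministic for a fixed
#' config seed.
#'
#' @param config a [simulationConfig()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with `dir`, `truth` (data.frame), `models`,
#'   `pedigrees` and `rohBlocks`.
#' @export
simulateCohort <- function(config, dir) {
  stopifnot(inherits(config, "SimulationConfig"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  withSeed(config$seed, simulateCohortImpl(config, dir))
}

simulateCohortImpl <- function(config, dir) {
  models <- generateGeneModels(config)
  geneOf <- vapply(models, function(m) m@gene, "")

  causal <- pickCausalGene(models)
  truthRows <- list()
  pedigrees <- list()
  rohBlocks <- list()
  freqRows <- list()     # accumulated db entries across families
  dbs <- defaultDatabases()

  for (f in seq_len(config$nFamilies)) {
    famId <- sprintf("F%d", f)
    scen <- config$scenarios[f]
    if (!config$sharedCausalGene && scen != "NONE")
      causalF <- pickCausalGene(models)
    else causalF <- causal
    consang <- scen == "HOM_NONSENSE_IN_ROH"
    father <- paste0(famId, "_father"); mother <- paste0(famId, "_mother")
    proband <- paste0(famId, "_proband")
    ped <- Pedigree(famId, data.frame(
      sample_id = c(father, mother, proband),
      father = c(NA, NA, father), mother = c(NA, NA, mother),
      sex = c(1L, 2L, 2L), affected = c(FALSE, FALSE, TRUE),
      stringsAsFactors = FALSE), consanguineous = consang)
    pedigrees[[famId]] <- ped

    sites <- drawBackgroundSites(config, models,
                                 ceiling(config$nBackgroundVariants * 1.1))
    keys <- paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = ":")
    sites <- sites[!duplicated(keys), , drop = FALSE]
    sites <- head(sites, config$nBackgroundVariants)
    nBg <- nrow(sites)
    spec <- drawAfSpectrum(config, nrow(sites))

    ## autozygosity blocks for consanguineous probands: one covering the
    ## causal gene, one elsewhere
    blocks <- NULL
    if (consang) {
      span <- c(IRanges::start(causalF@exons)[1],
                IRanges::end(causalF@exons)[length(causalF@exons)])
      len <- runif(1, config$rohBlockLengthBp[1],
                   config$rohBlockLengthBp[2])
      mid <- mean(span)
      b1 <- c(max(1, mid - len / 2), mid + len / 2)
      otherChrom <- setdiff(paste0("chr", seq_len(config$nChrom)),
                            causalF@chrom)[1]
      len2 <- runif(1, config$rohBlockLengthBp[1],
                    config$rohBlockLengthBp[2])
      s2 <- runif(1, 1, config$chromLengthBp - len2)
      blocks <- data.frame(chrom = c(causalF@chrom, otherChrom),
                           start = floor(c(b1[1], s2)),
                           end = ceiling(c(b1[2], s2 + len2)))
    }
    rohBlocks[[famId]] <- blocks
    auto <- rep(FALSE, nrow(sites))
    if (!is.null(blocks))
      for (b in seq_len(nrow(blocks)))
        auto <- auto | (sites$chrom == blocks$chrom[b] &
                          sites$pos >= blocks$start[b] &
                          sites$pos <= blocks$end[b])

    gt <- simulateTrioGenotypes(spec$af, autozygous = auto,
                                requireVariant = TRUE)
    alleleA <- cbind(gt$fatherA, gt$motherA, gt$childA)
    alleleB <- cbind(gt$fatherB, gt$motherB, gt$childB)
    colnames(alleleA) <- colnames(alleleB) <-
      c(father, mother, proband)

    ## frequency-table membership for non-absent background variants
    present <- spec$tier != "absent"
    keys <- paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = ":")
    dbProb <- c(0.75, 0.7, 0.6, 0.8, 0.9)   # last = broadest catalog
    inDb <- matrix(runif(nrow(sites) * length(dbs)), ncol = length(dbs))
    inDb <- sweep(inDb, 2, dbProb, `<`)
    inDb[rowSums(inDb) == 0L, length(dbs)] <- TRUE
    inDb[!present, ] <- FALSE
    freqRows[[length(freqRows) + 1L]] <- data.frame(
      key = rep(keys, ncol(inDb))[as.vector(inDb)],
      af = rep(spec$af, ncol(inDb))[as.vector(inDb)],
      db = rep(dbs, each = nrow(inDb))[as.vector(inDb)],
      stringsAsFactors = FALSE)

    ## plant the causal alleles (db-absent by construction)
    plant <- function(site, gA, gB) {
      sites <<- rbind(sites, data.frame(chrom = causalF@chrom,
                                        pos = site$pos, ref = site$ref,
                                        alt = site$alt))
      alleleA <<- rbind(alleleA, gA)
      alleleB <<- rbind(alleleB, gB)
      paste(causalF@chrom, site$pos, site$ref, site$alt, sep = ":")
    }
    if (scen %in% c("HOM_NONSENSE_IN_ROH", "HOM_NONSENSE")) {
      s <- findStopgainSite(causalF)
      key <- plant(s, c(0L, 0L, 1L), c(1L, 1L, 1L))  # parents het, child hom
      truthRows[[length(truthRows) + 1L]] <- data.frame(
        family_id = famId, scenario = scen, keys = key,
        model = "hom_recessive", in_roh = consang, gene = causalF@gene,
        stringsAsFactors = FALSE)
    } else if (scen == "COMPHET_FRAMESHIFT_PLUS_INTRONIC") {
      fs <- findFrameshiftSite(causalF)
      keyFs <- plant(fs, c(0L, 0L, 0L), c(0L, 1L, 1L))  # maternal
      intr <- findDeepIntronicSite(causalF)
      keyIn <- plant(intr, c(0L, 0L, 1L), c(1L, 0L, 0L)) # paternal
      truthRows[[length(truthRows) + 1L]] <- data.frame(
        family_id = famId, scenario = scen,
        keys = paste(keyFs, keyIn, sep = ";"),
        model = "compound_het", in_roh = FALSE, gene = causalF@gene,
        stringsAsFactors = FALSE)
    }

    if (config$genotypeMissingness > 0) {
      drop <- matrix(runif(nrow(alleleA) * 3L) <
                       config$genotypeMissingness, ncol = 3L)
      if (nrow(drop) > nBg)            # keep planted calls clean
        drop[(nBg + 1L):nrow(drop), ] <- FALSE
      alleleA[drop] <- NA_integer_
      alleleB[drop] <- NA_integer_
    }

    vs <- VariantSet(sites$chrom, sites$pos, sites$ref, sites$alt,
                     alleleA = alleleA, alleleB = alleleB)
    contigs <- setNames(rep(as.integer(config$chromLengthBp + 1e6),
                            config$nChrom),
                        paste0("chr", seq_len(config$nChrom)))
    writeCohortVcf(vs, file.path(dir, paste0(famId, ".vcf")),
                   contigs = contigs)
  }

  writePedFile(pedigrees, file.path(dir, "cohort.ped"))

  freq <- do.call(rbind, freqRows)
  for (db in dbs) {
    sub <- freq[freq$db == db, , drop = FALSE]
    sub <- sub[!duplicated(sub$key), , drop = FALSE]
    tab <- new("FrequencyTable", dbName = db, keys = sub$key, af = sub$af)
    writeFrequencyTable(tab, file.path(dir, paste0("freq_", db, ".tsv")))
  }

  writeTranscriptModels(models, file.path(dir, "gene_models.tsv"),
                        file.path(dir, "cds.fa"))

  genes <- sort(unique(geneOf))
  stages <- c("GV", "MI", "MII")
  low <- runif(length(genes)) < 0.25
  rows <- list()
  for (i in seq_along(genes)) {
    tpm <- if (genes[i] %in% vapply(truthRows, function(t) t$gene, ""))
      runif(3, 5, 50)
    else if (low[i]) runif(3, 0, 0.5)
    else exp(rnorm(3, log(10), 1.2))
    rows[[i]] <- data.frame(gene = genes[i], stage = stages,
                            tpm = round(tpm, 3), stringsAsFactors = FALSE)
  }
  write.table(do.call(rbind, rows), file.path(dir, "expression.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  truth <- if (length(truthRows)) do.call(rbind, truthRows) else
    data.frame(family_id = character(), scenario = character(),
               keys = character(), model = character(),
               in_roh = logical(), gene = character(),
               stringsAsFactors = FALSE)
  writeTruth(truth, file.path(dir, "truth.tsv"))

  invisible(list(dir = dir, truth = truth, models = models,
                 pedigrees = pedigrees, rohBlocks = rohBlocks))
}

#' Write / read the planted-truth table
#'
#' Variant keys use the stable `chrom:pos:ref:alt` format; compound-het
#' pairs join their two keys with `;`.
#'
#' @param truth data.frame with columns `family_id`, `scenario`, `keys`,
#'   `model`, `in_roh`, `gene`.
#' @param path TSV path.
#' @return `path` invisibly (write); the data.frame (load).
#' @export
writeTruth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTruth
#' @export
loadTruth <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE,
                   colClasses = list(keys = "character"))
  if (nrow(df)) {
    ok <- grepl("^[^:;]+:[0-9]+:[A-Za-z]+:[A-Za-z]+(;[^:;]+:[0-9]+:[A-Za-z]+:[A-Za-z]+)*$",
                df$keys)
    if (any(!ok))
      stop("malformed truth key: ", df$keys[!ok][1])
  }
  df
}
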