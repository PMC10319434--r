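#' @include simulate.R
NULL

#' Parameters of a full pipeline run
#'
#' Aggregates the per-stage thresholds: MAF < 0.01 in every scanned
#' database, splice window 2 bp, ROH > 2 Mb, expression TPM >= 1, gene
#' recurrence in >= 2 unrelated families.
#'
#' @param filter a [filterParams()] list.
#' @param roh a [rohParams()] list.
#' @param minFamilies recurrence threshold for the shared-gene stage.
#' @param tpmMin oocyte-expression cutoff.
#' @param strictSiblings reject homozygous candidates carried hom by an
#'   unaffected sibling (default TRUE).
#' @return parameter list of class `PipelineParams`.
#' @export
pipelineParams <- function(filter = filterParams(), roh = rohParams(),
                           minFamilies = 2L, tpmMin = 1,
                           strictSiblings = TRUE) {
  stopifnot(inherits(filter, "FilterParams"), inherits(roh, "ROHParams"),
            minFamilies >= 1, tpmMin >= 0)
  structure(list(filter = filter, roh = roh,
                 minFamilies = as.integer(minFamilies), tpmMin = tpmMin,
                 strictSiblings = isTRUE(strictSiblings)),
            class = "PipelineParams")
}

#' Read pipeline parameters from a flat YAML config file
#'
#' Recognized keys (all optional, defaults otherwise): `maf_threshold`,
#' `databases`, `splice_window`, `rescue_enabled`, `roh_min_length_bp`,
#' `roh_min_sites`, `roh_het_tolerance`, `roh_window_sites`,
#' `roh_max_gap_bp`, `min_families`, `tpm_min`, `strict_sibling_mode`.
#'
#' @param path YAML file.
#' @return a [pipelineParams()] list.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  g <- function(key, default) if (!is.null(cfg[[key]])) cfg[[key]] else
    default
  pipelineParams(
    filter = filterParams(
      mafThreshold = g("maf_threshold", 0.01),
      databases = unlist(g("databases", defaultDatabases())),
      spliceWindow = g("splice_window", 2L),
      rescueEnabled = g("rescue_enabled", TRUE)),
    roh = rohParams(
      minLengthBp = g("roh_min_length_bp", 2e6),
      minSites = g("roh_min_sites", 25L),
      hetTolerance = g("roh_het_tolerance", 1L),
      windowSites = g("roh_window_sites", 50L),
      maxGapBp = g("roh_max_gap_bp", 5e5)),
    minFamilies = g("min_families", 2L),
    tpmMin = g("tpm_min", 1),
    strictSiblings = g("strict_sibling_mode", TRUE))
}

## Concatenate two VariantSets (union of annotation columns, NA-filled).
concatVariantSets <- function(a, b) {
  if (nVariants(b) == 0) return(a)
  if (nVariants(a) == 0) return(b)
  stopifnot(identical(sampleIds(a), sampleIds(b)))
  aa <- annotations(a); ab <- annotations(b)
  for (col in setdiff(names(ab), names(aa)))
    aa[[col]] <- rep(NA, nVariants(a))
  for (col in setdiff(names(aa), names(ab)))
    ab[[col]] <- rep(NA, nVariants(b))
  ab <- ab[, names(aa), drop = FALSE]
  VariantSet(c(a@chrom, b@chrom), c(a@pos, b@pos), c(a@ref, b@ref),
             c(a@alt, b@alt), c(a@id, b@id),
             rbind(a@alleleA, b@alleleA), rbind(a@alleleB, b@alleleB),
             rbind(a@phased, b@phased),
             rbind(aa, ab))
}

## rbind data.frames with unequal column sets (NA-filled union).
rbindFill <- function(dfs) {
  dfs <- dfs[vapply(dfs, function(d) !is.null(d), TRUE)]
  if (!length(dfs)) return(data.frame())
  cols <- unique(unlist(lapply(dfs, names)))
  dfs <- lapply(dfs, function(d) {
    for (col in setdiff(cols, names(d)))
      d[[col]] <- rep(NA, nrow(d))
    d[, cols, drop = FALSE]
  })
  out <- do.call(rbind, dfs)
  rownames(out) <- NULL
  out
}

newFilterTrace <- function(familyId, total, afterMaf, afterFunctional,
                           afterInheritance, homOnly, inRoh, rescued) {
  counts <- c(total_variants = total, after_maf = afterMaf,
              after_functional = afterFunctional,
              after_inheritance_autosomal = afterInheritance,
              homozygous_only = homOnly, in_roh_gt2mb = inRoh)
  new("FilterTrace", familyId = familyId,
      counts = setNames(as.integer(counts), traceStages),
      rescued = as.integer(rescued))
}

pipelineLog <- function(...) message("[triocascade] ", sprintf(...))

#' Run the full prioritization cascade on a cohort directory
#'
#' Expects the bundle layout the simulator emits (and any real data coerced
#' into it): `cohort.ped`, one `<family_id>.vcf` per family,
#' `freq_<db>.tsv` frequency tables, `gene_models.tsv` (+ `cds.fa`), and
#' `expression.tsv`.  Stages run in the fixed published order: load,
#' multi-database MAF filter, functional-class filter, deep-intronic
#' rescue, autosomal recessive inheritance models, ROH annotation,
#' per-family candidate gene sets, cross-family shared genes, oocyte
#' expression filter, ranking.  Identical inputs and parameters give
#' identical reports (no randomness in the analysis path).
#'
#' @param cohortDir input directory.
#' @param params a [pipelineParams()] list.
#' @param verbose log per-stage counts via `message()` (default TRUE).
#' @return a [CohortReport-class].
#' @export
runPipeline <- function(cohortDir, params = pipelineParams(),
                        verbose = TRUE) {
  log <- if (verbose) pipelineLog else function(...) invisible()
  peds <- readPedFile(file.path(cohortDir, "cohort.ped"))
  if (!length(peds)) stop("no families in pedigree file")
  models <- readTranscriptModels(
    file.path(cohortDir, "gene_models.tsv"),
    fasta = {
      fa <- file.path(cohortDir, "cds.fa")
      if (file.exists(fa)) fa else NULL
    })
  freqFiles <- list.files(cohortDir, pattern = "^freq_.*\\.tsv$",
                          full.names = TRUE)
  dbNames <- sub("^freq_(.*)\\.tsv$", "\\1", basename(freqFiles))
  keep <- dbNames %in% params$filter$databases
  tables <- mapply(readFrequencyTable, freqFiles[keep], dbNames[keep],
                   SIMPLIFY = FALSE)
  missingDb <- setdiff(params$filter$databases, dbNames)
  if (length(missingDb))
    warning("frequency table(s) not found for: ",
            paste(missingDb, collapse = ", "))
  exprPath <- file.path(cohortDir, "expression.tsv")
  expr <- if (file.exists(exprPath)) readExpressionTable(exprPath) else
    NULL

  traces <- list(); allCands <- list(); familyGenes <- list()
  rohSegs <- list()
  for (famId in names(peds)) {
    ped <- peds[[famId]]
    vcf <- file.path(cohortDir, paste0(famId, ".vcf"))
    if (!file.exists(vcf)) stop("missing VCF for family ", famId)
    vs <- readCohortVcf(vcf, pedigree = ped)
    total <- nVariants(vs)
    log("%s: loaded %d variants", famId, total)

    vs <- annotateFrequencies(vs, tables)
    rare <- filterRare(vs, params$filter)
    log("%s: %d after MAF < %g filter", famId, rare$count,
        params$filter$mafThreshold)

    rare$variants <- annotateConsequences(rare$variants, models,
                                          params$filter$spliceWindow)
    fun <- filterFunctional(rare$variants, params$filter)
    log("%s: %d after functional-class filter", famId, fun$count)

    rescued <- if (params$filter$rescueEnabled)
      applyRescueList(fun$dropped, fun$variants, ped)
    else fun$variants[integer(0)]
    if (nVariants(rescued))
      log("%s: %d intronic variant(s) rescued", famId,
          nVariants(rescued))
    working <- concatVariantSets(fun$variants, rescued)
    if (!"rescued" %in% names(annotations(working))) {
      a <- annotations(working)
      a$rescued <- rep(FALSE, nVariants(working))
      annotations(working) <- a
    } else {
      a <- annotations(working)
      a$rescued[is.na(a$rescued)] <- FALSE
      annotations(working) <- a
    }

    auto <- filterAutosomal(working)
    hom <- findHomozygousRecessive(auto, ped, params$strictSiblings)
    comphet <- findCompoundHet(auto, ped)
    cands <- rbind(hom, comphet)
    log("%s: %d recessive candidate(s) in %d gene(s)", famId,
        nrow(cands), length(candidateGenes(cands)))

    segs <- detectRoh(vs, probandId(ped), params$roh)
    rohSegs[[famId]] <- segs
    cands <- annotateInRoh(cands, segs)

    genes <- candidateGenes(cands)
    homGenes <- candidateGenes(cands[cands$model == "hom_recessive", ,
                                     drop = FALSE])
    inRohGenes <- candidateGenes(
      cands[cands$model == "hom_recessive" & cands$in_roh, ,
            drop = FALSE])
    traces[[famId]] <- newFilterTrace(
      famId, total, rare$count, fun$count,
      length(genes), length(homGenes),
      if (isConsanguineous(ped)) length(inRohGenes) else NA_integer_,
      nVariants(rescued))
    familyGenes[[famId]] <- genes

    ## attach per-variant annotation columns for reporting
    if (nrow(cands)) {
      vt <- variantTable(auto)
      vt$key <- variantKeys(auto)
      m <- match(cands$key, vt$key)
      for (col in c("cdna", "protein_change", "functional_class",
                    grep("^af_", names(vt), value = TRUE), "max_af",
                    "rescued"))
        if (col %in% names(vt)) cands[[col]] <- vt[[col]][m]
      m2 <- match(cands$key2, vt$key)
      cands$cdna2 <- vt$cdna[m2]
      cands$functional_class2 <- vt$functional_class[m2]
      cands$rescued <- cands$rescued |
        (!is.na(m2) & vt$rescued[m2] %in% TRUE)
    }
    allCands[[famId]] <- cands
  }

  cands <- rbindFill(allCands)

  shared0 <- sharedGenes(familyGenes,
                         minFamilies = params$minFamilies)
  log("shared genes (>= %d families): %s", params$minFamilies,
      if (length(shared0)) paste(shared0, collapse = ", ") else "none")

  if (!is.null(expr) && nrow(cands)) {
    expressed <- expressionFilter(unique(cands$gene), expr,
                                  tpmMin = params$tpmMin)
    cands <- cands[cands$gene %in% expressed, , drop = FALSE]
    shared <- intersect(shared0, expressed)
    log("%d candidate(s) in expressed genes", nrow(cands))
  } else shared <- shared0

  ranked <- rankCandidates(cands, shared, peds)
  new("CohortReport", traces = traces, candidates = ranked,
      familyGenes = familyGenes, sharedGenes = shared,
      rohSegments = rohSegs,
      params = unclass(params))
}

#' Write the report files of a pipeline run
#'
#' Emits `trace.tsv` (per-stage counts, one column per family, stage rows
#' in the published cascade order, "-" for stages not applicable),
#' `candidates.tsv` (one row per ranked candidate; allele frequencies of
#' databases lacking the variant render "not found"), and per-family ROH
#' BED/TSV files.  Deterministic column order throughout.
#'
#' @param report a [CohortReport-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCandidateReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fams <- names(report@traces)
  traceDf <- data.frame(stage = traceStages, stringsAsFactors = FALSE)
  for (f in fams) {
    v <- traceCounts(report@traces[[f]])
    traceDf[[f]] <- ifelse(is.na(v), "-", as.character(v))
  }
  rescue <- vapply(report@traces, function(t) t@rescued, 0L)
  rescueRow <- as.data.frame(
    c(list(stage = "rescued_reconsidered"),
      setNames(as.list(as.character(rescue)), fams)),
    stringsAsFactors = FALSE)
  traceDf <- rbind(traceDf, rescueRow)
  write.table(traceDf, file.path(dir, "trace.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  cands <- report@candidates
  if (nrow(cands)) {
    afCols <- grep("^af_", names(cands), value = TRUE)
    for (col in afCols)
      cands[[col]] <- ifelse(is.na(cands[[col]]), "not found",
                             format(cands[[col]], digits = 4,
                                    scientific = TRUE))
    first <- intersect(
      c("rank", "family_id", "gene", "chrom", "pos", "key", "key2",
        "cdna", "cdna2", "protein_change", "functional_class",
        "functional_class2", "model", "phase_status", "in_roh",
        "rescued", "tier", afCols, "max_af"), names(cands))
    cands <- cands[, c(first, setdiff(names(cands), first)), drop = FALSE]
  }
  write.table(cands, file.path(dir, "candidates.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "-")

  for (f in fams) {
    segs <- report@rohSegments[[f]]
    if (is.null(segs)) next
    write.table(segs, file.path(dir, paste0("roh_", f, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(segs))
      writeRohBed(segs, file.path(dir, paste0("roh_", f, ".bed")))
  }
  invisible(dir)
}
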