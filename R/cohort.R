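#' @include inheritance.R roh.R
NULL

#' Read an oocyte expression table
#'
#' Long TSV with columns `gene`, `stage` (e.g. GV, MI, MII) and `tpm`.
#'
#' @param path TSV file.
#' @return data.frame with those columns.
#' @export
readExpressionTable <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("gene", "stage", "tpm")
  if (!all(need %in% names(df)))
    stop("expression table needs columns gene, stage, tpm")
  if (any(df$tpm < 0)) stop("TPM must be nonnegative")
  df
}

#' Candidate gene set of one family
#'
#' Union of genes over the homozygous-recessive and compound-het candidates.
#'
#' @param cands candidate data.frame from the inheritance stage.
#' @return character vector of gene symbols.
#' @export
candidateGenes <- function(cands) {
  sort(unique(cands$gene[!is.na(cands$gene)]))
}

#' Genes recurring across unrelated families
#'
#' @param familyGenes list of per-family candidate gene sets.
#' @param minFamilies minimum number of families a gene must appear in
#'   (default 2, "at least two unrelated affected women"; set to the number
#'   of families for a strict intersection).
#' @return character vector of shared genes.
#' @export
sharedGenes <- function(familyGenes, minFamilies = 2L) {
  if (minFamilies > length(familyGenes))
    stop("min_families exceeds the number of families")
  counts <- table(unlist(lapply(familyGenes, unique)))
  sort(names(counts)[counts >= minFamilies])
}

#' Oocyte-expression filter
#'
#' Keeps genes expressed (TPM >= `tpmMin`) in at least one oocyte stage.
#' Genes absent from the table are dropped with a warning: the criterion
#' demands positive expression evidence.
#'
#' @param genes character vector of gene symbols.
#' @param expr expression data.frame from [readExpressionTable()].
#' @param tpmMin expression cutoff (default 1, "expressed" = TPM >= 1).
#' @return the expressed subset of `genes`.
#' @export
expressionFilter <- function(genes, expr, tpmMin = 1) {
  known <- genes %in% expr$gene
  if (any(!known))
    warning(sum(!known), " gene(s) absent from the expression table, ",
            "dropped: ", paste(head(genes[!known], 5), collapse = ", "))
  maxTpm <- vapply(genes, function(g)
    if (g %in% expr$gene) max(expr$tpm[expr$gene == g]) else -Inf, 0)
  genes[known & maxTpm >= tpmMin]
}

#' Rank candidates across the cohort
#'
#' Deterministic total order: (1) membership of the cross-family shared-gene
#' set; (2) homozygous-in-ROH candidates of consanguineous families (the
#' "homozygous variants prioritized in consanguineous families" rule);
#' (3) other homozygous-recessive candidates; (4) trans-confirmed compound
#' hets; (5) phase-unknown compound hets.  Ties break by (gene, chrom, pos),
#' so the ranking is invariant to input order.
#'
#' @param cands candidate data.frame (all families, `in_roh` annotated).
#' @param shared character vector of shared genes.
#' @param pedigrees named list of [Pedigree-class] per family.
#' @return `cands` sorted with a `rank` column (1 = best) and a `tier`
#'   column naming the priority class.
#' @export
rankCandidates <- function(cands, shared, pedigrees) {
  if (!nrow(cands)) {
    cands$rank <- integer(0); cands$tier <- character(0)
    return(cands)
  }
  consang <- vapply(cands$family_id, function(f)
    isConsanguineous(pedigrees[[f]]), TRUE)
  inRoh <- if ("in_roh" %in% names(cands)) cands$in_roh else FALSE
  tier <- ifelse(cands$model == "hom_recessive" & inRoh & consang, 2L,
          ifelse(cands$model == "hom_recessive", 3L,
          ifelse(cands$phase_status %in% "trans_confirmed", 4L, 5L)))
  inShared <- cands$gene %in% shared
  o <- order(!inShared, tier, cands$gene, cands$chrom, cands$pos)
  out <- cands[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$tier <- c("shared", "hom_in_roh", "hom_recessive",
                "comphet_trans", "comphet_unphased")[tier[o] - 0L]
  out$tier[inShared[o]] <- paste0("shared+", out$tier[inShared[o]])
  rownames(out) <- NULL
  out
}

#' Read a clinical oocyte-outcome table
#'
#' CSV with columns `family_id`, `cycle`, `protocol`, `total_retrieved`,
#' `gv`, `mi`, `pb1`, `fertilized`, `cleaved` (one row per stimulation
#' cycle).  Validates that staged oocytes do not exceed the retrieved total.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
readClinicalTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("family_id", "cycle", "protocol", "total_retrieved", "gv",
            "mi", "pb1", "fertilized", "cleaved")
  if (!all(need %in% names(df)))
    stop("clinical table lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  cnt <- c("total_retrieved", "gv", "mi", "pb1", "fertilized", "cleaved")
  if (any(df[cnt] < 0)) stop("negative oocyte counts")
  bad <- df$gv + df$mi + df$pb1 > df$total_retrieved
  if (any(bad))
    stop("staged oocytes exceed total retrieved in row(s): ",
         paste(which(bad), collapse = ", "))
  df
}

#' Summarize oocyte outcomes for one family
#'
#' Sums each count column over the family's stimulation cycles and reports
#' the MI-arrest fraction (sum MI / sum retrieved; NA when no oocytes were
#' retrieved).  The fraction is derived reporting, not part of the clinical
#' table itself.
#'
#' @param clinical data.frame from [readClinicalTable()].
#' @param familyId family to summarize.
#' @return one-row data.frame with `family_id`, `n_cycles`, totals per
#'   stage, and `mi_arrest_fraction`.
#' @export
summarizeOocyteOutcomes <- function(clinical, familyId) {
  rows <- clinical[clinical$family_id == familyId, , drop = FALSE]
  if (!nrow(rows)) stop("unknown family: ", familyId)
  tot <- function(col) sum(rows[[col]])
  totalRetrieved <- tot("total_retrieved")
  data.frame(
    family_id = familyId, n_cycles = nrow(rows),
    total_retrieved = totalRetrieved, gv = tot("gv"), mi = tot("mi"),
    pb1 = tot("pb1"), fertilized = tot("fertilized"),
    cleaved = tot("cleaved"),
    mi_arrest_fraction = if (totalRetrieved > 0)
      tot("mi") / totalRetrieved else NA_real_,
    stringsAsFactors = FALSE)
}
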