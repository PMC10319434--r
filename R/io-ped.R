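#' @include VariantSet-methods.R
NULL

#' Read a PED pedigree file
#'
#' Standard 6-column PED dialect (family, individual, father, mother, sex,
#' phenotype) with an optional 7th per-family consanguinity column (0/1).
#' Phenotype 2 codes affected, 1 unaffected, 0 or -9 unknown.  Parent ids of
#' "0" mean unknown.  Tab- or whitespace-delimited; lines starting `#` are
#' skipped.
#'
#' @param path PED file.
#' @return named list of [Pedigree-class], one per family id; empty list for
#'   an empty file.
#' @export
readPedFile <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) return(list())
  fields <- strsplit(trimws(lines), "[ \t]+")
  ncols <- lengths(fields)
  if (any(ncols < 6))
    stop("PED line with fewer than 6 columns: line ",
         which(ncols < 6)[1])
  df <- as.data.frame(do.call(rbind, lapply(fields, `[`, 1:7)),
                      stringsAsFactors = FALSE)
  names(df) <- c("family", "sample_id", "father", "mother", "sex",
                 "phenotype", "consang")
  out <- list()
  for (fam in unique(df$family)) {
    d <- df[df$family == fam, , drop = FALSE]
    father <- ifelse(d$father %in% c("0", "", NA), NA_character_, d$father)
    mother <- ifelse(d$mother %in% c("0", "", NA), NA_character_, d$mother)
    sex <- suppressWarnings(as.integer(d$sex))
    sex[!sex %in% c(1L, 2L)] <- NA_integer_
    affected <- rep(NA, nrow(d))
    affected[d$phenotype == "2"] <- TRUE
    affected[d$phenotype == "1"] <- FALSE
    consang <- any(d$consang %in% "1")
    samples <- data.frame(sample_id = d$sample_id, father = father,
                          mother = mother, sex = sex, affected = affected,
                          stringsAsFactors = FALSE)
    out[[fam]] <- Pedigree(fam, samples, consanguineous = consang)
  }
  out
}

#' Write pedigrees to a PED file (6 + 1 columns)
#'
#' @param peds list of [Pedigree-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePedFile <- function(peds, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ped in peds) {
    s <- ped@samples
    pheno <- ifelse(is.na(s$affected), 0L, ifelse(s$affected, 2L, 1L))
    lines <- paste(ped@familyId, s$sample_id,
                   ifelse(is.na(s$father), "0", s$father),
                   ifelse(is.na(s$mother), "0", s$mother),
                   ifelse(is.na(s$sex), 0L, s$sex),
                   pheno, as.integer(ped@consanguineous), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}
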