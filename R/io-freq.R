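#' @include VariantSet-methods.R
NULL

#' Databases scanned by default for the rarity filter
#'
#' The five reference sources of the published cascade.
#' @export
defaultDatabases <- function()
  c("dbSNP", "1000g", "EVS", "ExAC", "gnomAD")

#' Read a population allele-frequency table
#'
#' TSV with header columns `chrom`, `pos`, `ref`, `alt` and either `af` or
#' the pair `allele_count`, `allele_number` (then `af = allele_count /
#' allele_number`, e.g. 3/248598 ~ 1.21e-5).  Alleles are normalized with
#' [normalizeAlleles()] before keying so indel representations match the
#' variant records.
#'
#' @param path TSV file.
#' @param dbName database label (defaults to the file's base name).
#' @return a [FrequencyTable-class].
#' @export
readFrequencyTable <- function(path, dbName = NULL) {
  if (is.null(dbName))
    dbName <- sub("\\.[^.]*$", "", basename(path))
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE,
                   colClasses = list(chrom = "character",
                                     ref = "character",
                                     alt = "character"))
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(df)))
    stop("frequency table lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if ("af" %in% names(df)) {
    af <- as.numeric(df$af)
  } else if (all(c("allele_count", "allele_number") %in% names(df))) {
    af <- as.numeric(df$allele_count) / as.numeric(df$allele_number)
  } else {
    stop("frequency table needs 'af' or 'allele_count'+'allele_number'")
  }
  if (any(is.na(af)) || any(af < 0) || any(af > 1))
    stop("allele frequency outside [0, 1] in ", path)
  norm <- normalizeAlleles(df$pos, df$ref, df$alt)
  keys <- paste(df$chrom, norm$pos, norm$ref, norm$alt, sep = ":")
  if (anyDuplicated(keys))
    stop("duplicate variant key in ", dbName, ": ",
         keys[duplicated(keys)][1])
  new("FrequencyTable", dbName = dbName, keys = keys, af = af)
}

#' Write a FrequencyTable to TSV
#' @param tab a [FrequencyTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFrequencyTable <- function(tab, path) {
  parts <- strsplit(tab@keys, ":", fixed = TRUE)
  df <- data.frame(chrom = vapply(parts, `[`, "", 1),
                   pos = vapply(parts, `[`, "", 2),
                   ref = vapply(parts, `[`, "", 3),
                   alt = vapply(parts, `[`, "", 4),
                   af = tab@af, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Look up one variant's frequency in one database
#'
#' @param tab a [FrequencyTable-class].
#' @param keys character vector of "chrom:pos:ref:alt" keys.
#' @return numeric vector; NA means "not observed in this database"
#'   (deliberately distinct from frequency 0).
#' @export
lookupFrequency <- function(tab, keys) {
  tab@af[match(keys, tab@keys)]
}
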