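#' @include VariantSet-methods.R
NULL

#' Parameters for runs-of-homozygosity detection
#'
#' Only the 2 Mb length threshold comes from the published cascade ("in
#' homozygous region >2 Mb", strictly greater); the remaining settings are
#' conventional exome-ROH defaults and stay configurable.
#'
#' @param minLengthBp minimum segment span in bp, strict (default 2e6).
#' @param minSites minimum informative genotyped sites per segment (25).
#' @param hetTolerance heterozygous calls tolerated per sliding window (1).
#' @param windowSites sliding-window size in sites (50).
#' @param maxGapBp maximum distance between consecutive informative sites
#'   inside one segment; larger site deserts split the run (5e5).  0
#'   disables the gap rule.
#' @return validated parameter list of class `ROHParams`.
#' @export
rohParams <- function(minLengthBp = 2e6, minSites = 25L, hetTolerance = 1L,
                      windowSites = 50L, maxGapBp = 5e5) {
  stopifnot(minLengthBp >= 0, minSites > 0, hetTolerance >= 0,
            windowSites > 0, maxGapBp >= 0, hetTolerance < windowSites)
  structure(list(minLengthBp = as.numeric(minLengthBp),
                 minSites = as.integer(minSites),
                 hetTolerance = as.integer(hetTolerance),
                 windowSites = as.integer(windowSites),
                 maxGapBp = as.numeric(maxGapBp)),
            class = "ROHParams")
}

## Greedy streak scan over one chromosome.  `het` is logical over sorted
## informative sites.  A het is absorbed into the running streak iff, after
## absorbing it, the trailing `windowSites`-site window holds at most
## `hetTolerance` het calls; otherwise the streak closes at the last hom.
## A site desert wider than `maxGapBp` (when > 0) also closes the streak.
## Returns a list of c(startIdx, endIdx) index ranges (ends are hom sites).
rohStreaks <- function(pos, het, params) {
  n <- length(pos)
  segs <- list()
  i <- 1L
  while (i <= n) {
    if (het[i]) { i <- i + 1L; next }
    start <- i
    hetIdx <- integer(0)
    j <- i + 1L
    lastHom <- i
    while (j <= n) {
      if (params$maxGapBp > 0 && pos[j] - pos[j - 1L] > params$maxGapBp)
        break
      if (!het[j]) {
        lastHom <- j
      } else {
        inWindow <- sum(hetIdx > j - params$windowSites) + 1L
        if (inWindow > params$hetTolerance) break
        hetIdx <- c(hetIdx, j)
      }
      j <- j + 1L
    }
    segs[[length(segs) + 1L]] <- c(pos[start], pos[lastHom],
                                   lastHom - start + 1L,
                                   sum(hetIdx <= lastHom))
    i <- if (j > n) j else if (het[j]) j + 1L else j
  }
  segs
}

#' Detect runs of homozygosity in one sample
#'
#' Scans sorted biallelic genotype calls for maximal homozygous streaks,
#' tolerating up to `hetTolerance` heterozygous interruptions per
#' `windowSites`-site sliding window; a distance of more than `maxGapBp`
#' between consecutive informative sites ends the streak (no segment is
#' extended across a large site desert); only segments spanning strictly
#' more than `minLengthBp` with at least `minSites` informative sites are
#' reported.  Missing calls are uninformative and skipped.  Deterministic
#' for fixed input.
#'
#' @param x a [VariantSet-class] of *all* genotyped sites (ROH needs the
#'   pre-filter site density, not the rare subset).
#' @param sample sample id to scan (e.g. the proband).
#' @param params a [rohParams()] list.
#' @return data.frame of segments: `chrom`, `start`, `end` (1-based
#'   inclusive), `n_sites`, `n_het`.
#' @export
detectRoh <- function(x, sample, params = rohParams()) {
  z <- zygosity(x, sample)[, 1]
  keep <- z != "missing"
  chrom <- x@chrom[keep]; pos <- x@pos[keep]; z <- z[keep]
  out <- list()
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    p <- pos[sel]
    if (is.unsorted(p)) stop("sites not sorted by position on ", ch)
    segs <- rohStreaks(p, z[sel] == "het", params)
    if (!length(segs)) next
    m <- do.call(rbind, segs)
    span <- m[, 2] - m[, 1] + 1
    ok <- span > params$minLengthBp & m[, 3] >= params$minSites
    if (any(ok))
      out[[ch]] <- data.frame(chrom = ch, start = m[ok, 1], end = m[ok, 2],
                              n_sites = m[ok, 3], n_het = m[ok, 4],
                              stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_sites = integer(),
                      n_het = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Flag candidates lying inside ROH segments
#'
#' Homozygous candidates get `in_roh = TRUE` when their position falls
#' within a segment; compound-het candidates are FALSE by definition (their
#' members are heterozygous).
#'
#' @param cands candidate data.frame from the inheritance stage.
#' @param segments segment data.frame from [detectRoh()].
#' @return `cands` with an `in_roh` logical column.
#' @export
annotateInRoh <- function(cands, segments) {
  inRoh <- rep(FALSE, nrow(cands))
  if (nrow(cands) && nrow(segments)) {
    homIdx <- which(cands$model == "hom_recessive")
    for (i in homIdx) {
      hit <- segments$chrom == cands$chrom[i] &
        segments$start <= cands$pos[i] & segments$end >= cands$pos[i]
      inRoh[i] <- any(hit)
    }
  }
  cands$in_roh <- inRoh
  cands
}

#' Write ROH segments as BED
#'
#' Internal coordinates are 1-based inclusive; BED is written 0-based
#' half-open at this boundary.
#'
#' @param segments data.frame from [detectRoh()].
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
writeRohBed <- function(segments, path) {
  bed <- data.frame(segments$chrom, segments$start - 1L, segments$end,
                    sprintf("ROH_%d", seq_len(nrow(segments))),
                    segments$n_sites)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
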