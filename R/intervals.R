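## Interval I/O and gap-tolerant interval algebra.
##
## Regions are GRanges, 1-based closed in memory; BED/narrowPeak files are
## 0-based half-open on disk and converted at read/write time.  Histone-mark
## peaks are unstranded, so every overlap operation here ignores strand.

#' Read genomic regions from BED or ENCODE narrowPeak
#'
#' Reads tab-separated peak files into a sorted `GRanges`. narrowPeak
#' column 10 (the summit, an offset from the region start; `-1` = absent)
#' is stored in metadata column `summit_offset`. Track, browser and `#`
#' comment lines are skipped. On-disk coordinates are interpreted as
#' 0-based half-open and converted to the in-memory 1-based convention.
#'
#' @param path Path to the file.
#' @param dialect One of `"auto"`, `"bed3"`, `"bed6"`, `"narrowPeak"`.
#'   `"auto"` infers the dialect from the column count of the first data
#'   line (3 = bed3, 6 = bed6, 10 = narrowPeak).
#' @param genome Optional named vector of chromosome lengths; when given,
#'   intervals must fit within their chromosome.
#' @param chrom_alias Optional named character vector mapping on-disk
#'   chromosome names to canonical ones (e.g. `c("1" = "chr1")`). Default
#'   is no renaming.
#' @return A sorted `GRanges` with metadata columns `name`, `score`,
#'   `summit_offset`.
#' @export
read_regions <- function(path, dialect = c("auto", "bed3", "bed6", "narrowPeak"),
                         genome = NULL, chrom_alias = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(lines) & !grepl("^(#|track\\b|browser\\b)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(.empty_regions(genome))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfld <- lengths(fields)
  if (dialect == "auto") {
    dialect <- switch(as.character(nfld[[1L]]),
      "3" = "bed3", "10" = "narrowPeak",
      if (nfld[[1L]] >= 6L) "bed6" else
        stop("cannot infer dialect from ", nfld[[1L]], " columns (line ", lineno[1L], ")")
    )
  }
  need <- c(bed3 = 3L, bed6 = 6L, narrowPeak = 10L)[[dialect]]
  bad <- which(nfld < need)
  if (length(bad) > 0L) {
    stop("line ", lineno[bad[1L]], ": expected >= ", need,
         " tab-separated fields, found ", nfld[bad[1L]])
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  chrom <- col(1L)
  start0 <- suppressWarnings(as.integer(col(2L)))
  end0 <- suppressWarnings(as.integer(col(3L)))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad) > 0L) stop("line ", lineno[bad[1L]], ": non-integer coordinate")
  bad <- which(start0 < 0L | start0 >= end0)
  if (length(bad) > 0L) {
    stop("line ", lineno[bad[1L]], ": invalid interval [", start0[bad[1L]],
         ", ", end0[bad[1L]], ")")
  }
  if (!is.null(chrom_alias)) {
    hit <- chrom %in% names(chrom_alias)
    chrom[hit] <- unname(chrom_alias[chrom[hit]])
  }
  name <- if (need >= 6L) col(4L) else rep(NA_character_, length(lines))
  name[name == "."] <- NA_character_
  score <- if (need >= 6L) suppressWarnings(as.numeric(col(5L))) else
    rep(NA_real_, length(lines))
  str <- if (need >= 6L) col(6L) else rep("*", length(lines))
  str[!str %in% c("+", "-")] <- "*"
  summit <- rep(NA_integer_, length(lines))
  if (dialect == "narrowPeak") {
    summit <- suppressWarnings(as.integer(col(10L)))
    if (anyNA(summit)) stop("line ", lineno[which(is.na(summit))[1L]],
                            ": non-integer summit (column 10)")
    summit[summit < 0L] <- NA_integer_
    off <- which(!is.na(summit) & summit >= end0 - start0)
    if (length(off) > 0L) {
      stop("line ", lineno[off[1L]], ": summit offset ", summit[off[1L]],
           " outside interval of width ", end0[off[1L]] - start0[off[1L]])
    }
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0),
                               strand = str)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(name = name, score = score,
                                               summit_offset = summit)
  if (!is.null(genome)) {
    miss <- setdiff(unique(chrom), names(genome))
    if (length(miss) > 0L) stop("chromosome(s) absent from genome: ",
                                paste(miss, collapse = ", "))
    GenomeInfoDb::seqlevels(gr) <- names(genome)
    GenomeInfoDb::seqlengths(gr) <- unname(genome)
    over <- which(end0 > genome[chrom])
    if (length(over) > 0L) stop("line ", lineno[over[1L]],
                                ": interval exceeds chromosome length")
  }
  sort(GenomeInfoDb::sortSeqlevels(gr), ignore.strand = TRUE)
}

.empty_regions <- function(genome = NULL) {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(name = character(0),
                                               score = numeric(0),
                                               summit_offset = integer(0))
  if (!is.null(genome)) {
    GenomeInfoDb::seqlevels(gr) <- names(genome)
    GenomeInfoDb::seqlengths(gr) <- unname(genome)
  }
  gr
}

#' Write genomic regions to BED, narrowPeak or TSV
#'
#' Output is sorted and deterministic; BED coordinates are written 0-based
#' half-open with LF line endings. A missing summit is written as `-1` in
#' narrowPeak.
#'
#' @param regions A `GRanges` (metadata columns `name`, `score`,
#'   `summit_offset` are used when present).
#' @param path Output path.
#' @param dialect One of `"bed6"`, `"bed3"`, `"narrowPeak"`, `"tsv"`.
#' @return Invisibly, `path`.
#' @export
write_regions <- function(regions, path,
                          dialect = c("bed6", "bed3", "narrowPeak", "tsv")) {
  dialect <- match.arg(dialect)
  gr <- sort(GenomeInfoDb::sortSeqlevels(regions), ignore.strand = TRUE)
  chrom <- as.character(GenomeInfoDb::seqnames(gr))
  start0 <- BiocGenerics::start(gr) - 1L
  end0 <- BiocGenerics::end(gr)
  mc <- S4Vectors::mcols(gr)
  getmc <- function(nm, default) {
    if (nm %in% names(mc)) mc[[nm]] else rep(default, length(gr))
  }
  name <- getmc("name", NA_character_)
  name <- ifelse(is.na(name), ".", name)
  score <- getmc("score", NA_real_)
  score_chr <- ifelse(is.na(score), "0", vapply(score, .num2chr, character(1)))
  str <- as.character(BiocGenerics::strand(gr))
  str[str == "*"] <- "."
  summit <- getmc("summit_offset", NA_integer_)
  summit_chr <- ifelse(is.na(summit), "-1", as.character(summit))
  body <- if (length(gr) == 0L) character(0) else switch(dialect,
    bed3 = paste(chrom, start0, end0, sep = "\t"),
    bed6 = paste(chrom, start0, end0, name, score_chr, str, sep = "\t"),
    narrowPeak = paste(chrom, start0, end0, name, score_chr, str,
                       score_chr, "-1", "-1", summit_chr, sep = "\t"),
    tsv = paste(chrom, start0, end0, name, score_chr, str, summit_chr,
                sep = "\t")
  )
  lines <- if (dialect == "tsv") {
    c(paste("chrom", "start", "end", "name", "score", "strand",
            "summit_offset", sep = "\t"), body)
  } else {
    body
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines) > 0L) writeLines(lines, con, sep = "\n")
  invisible(path)
}

.num2chr <- function(x) {
  if (is.na(x)) return("0")
  if (x == as.integer(x)) as.character(as.integer(x)) else as.character(x)
}

#' Merge intervals allowing a maximum gap
#'
#' Collapses intervals whose gap is at most `max_gap` base pairs into
#' single runs per chromosome. Touching intervals have gap 0 and are
#' always merged when `max_gap >= 0`.
#'
#' @param regions A `GRanges`.
#' @param max_gap Non-negative integer gap (bp) tolerated between merged
#'   intervals.
#' @return Sorted, merged `GRanges` (metadata dropped).
#' @export
merge_intervals <- function(regions, max_gap = 0) {
  if (length(max_gap) != 1L || is.na(max_gap) || max_gap < 0) {
    stop("max_gap must be a single non-negative number")
  }
  GenomicRanges::reduce(sort(regions, ignore.strand = TRUE),
                        min.gapwidth = as.integer(max_gap) + 1L,
                        ignore.strand = TRUE)
}

#' Gap-tolerant pairwise overlap test
#'
#' Two intervals overlap at `max_gap` if they lie on the same chromosome
#' and the gap between them is at most `max_gap` bp, where touching or
#' overlapping intervals have gap 0. Vectorised over pairs; strand is
#' ignored.
#'
#' @param a,b `GRanges` of equal length (or either of length 1).
#' @param max_gap Maximum tolerated gap in bp.
#' @return Logical vector.
#' @export
overlaps_with_gap <- function(a, b, max_gap = 0) {
  same <- as.character(GenomeInfoDb::seqnames(a)) ==
    as.character(GenomeInfoDb::seqnames(b))
  gap <- pmax(BiocGenerics::start(b) - BiocGenerics::end(a) - 1L,
              BiocGenerics::start(a) - BiocGenerics::end(b) - 1L, 0L)
  same & gap <= max_gap
}

#' Subset a query set by gap-tolerant overlap with a subject set
#'
#' Returns the query intervals having at least one subject interval within
#' `max_gap` bp (`invert = FALSE`), or the complement subset
#' (`invert = TRUE`). Query intervals are returned unmodified and in their
#' original order; strand is ignored.
#'
#' @param query,subject `GRanges`.
#' @param max_gap Maximum tolerated gap in bp (0 = touching still counts).
#' @param invert Return non-overlapping query intervals instead.
#' @return Subset of `query`.
#' @export
subset_by_overlap <- function(query, subject, max_gap = 0, invert = FALSE) {
  if (length(subject) == 0L) {
    return(if (invert) query else query[integer(0)])
  }
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    query, subject, maxgap = as.integer(max_gap), ignore.strand = TRUE))
  idx <- sort(unique(S4Vectors::queryHits(hits)))
  if (invert) query[setdiff(seq_along(query), idx)] else query[idx]
}

## Fail fast on "chr1" vs "1" chromosome-dialect mixing between inputs:
## a silent empty intersection is the classic failure mode.
.check_chrom_dialect <- function(grs, labels = names(grs)) {
  has_chr <- vapply(grs, function(g) {
    lv <- GenomeInfoDb::seqlevels(g)
    if (length(lv) == 0L) NA else any(startsWith(lv, "chr"))
  }, logical(1))
  has_chr <- has_chr[!is.na(has_chr)]
  if (length(unique(has_chr)) > 1L) {
    stop("chromosome-name dialect mismatch ('chr' prefix) between inputs: ",
         paste(names(has_chr)[has_chr], collapse = ", "), " vs ",
         paste(names(has_chr)[!has_chr], collapse = ", "),
         "; supply chrom_alias at read time")
  }
  invisible(TRUE)
}
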