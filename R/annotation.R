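## Promoter-window gene assignment and the gene-set overlap test used for
## bivalency resolution (H3K4me3 gain meeting H3K27me3 loss at the same
## genes).

#' Read gene models (one TSS per gene)
#'
#' From a GTF (Ensembl dialect, 1-based inclusive) the TSS of each gene is
#' the 5'-most transcript start: on `+` the minimum transcript start, on
#' `-` the maximum transcript end, converted to a 0-based position.
#' Alternatively a 4-column TSV `gene_id, chrom, tss, strand` with `tss`
#' already 0-based. Genes without transcript lines (GTF) or a defined
#' strand are skipped with a warning.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"gtf"` or `"tsv"`.
#' @return `data.frame` with columns `gene_id`, `chrom`, `tss` (0-based),
#'   `strand`, sorted by `(chrom, tss, gene_id)`.
#' @export
read_gene_models <- function(path, format = c("auto", "gtf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf"
              else "tsv"
  }
  if (format == "gtf") {
    gtf <- rtracklayer::import(path, format = "gtf")
    tx <- gtf[gtf$type == "transcript"]
    if (length(tx) == 0L) stop("no transcript features in GTF: ", path)
    str <- as.character(BiocGenerics::strand(tx))
    ok <- str %in% c("+", "-") & !is.na(tx$gene_id)
    if (!all(ok)) warning(sum(!ok), " transcript(s) without strand/gene_id skipped")
    tx <- tx[ok]
    str <- str[ok]
    gid <- as.character(tx$gene_id)
    tss0 <- ifelse(str == "+", BiocGenerics::start(tx) - 1L,
                   BiocGenerics::end(tx) - 1L)
    df <- data.frame(gene_id = gid,
                     chrom = as.character(GenomeInfoDb::seqnames(tx)),
                     tss = tss0, strand = str, stringsAsFactors = FALSE)
    parts <- split(df, df$gene_id)
    genes <- do.call(rbind, lapply(parts, function(d) {
      if (d$strand[1L] == "+") d[which.min(d$tss), ] else d[which.max(d$tss), ]
    }))
  } else {
    genes <- utils::read.table(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "tss", "strand")
    if (!all(need %in% names(genes))) {
      stop("TSV gene table needs columns: ", paste(need, collapse = ", "))
    }
    genes <- genes[, need]
    bad <- !genes$strand %in% c("+", "-")
    if (any(bad)) {
      warning(sum(bad), " gene(s) without defined strand skipped")
      genes <- genes[!bad, ]
    }
  }
  if (any(genes$tss < 0)) stop("negative TSS position")
  genes <- genes[order(genes$chrom, genes$tss, genes$gene_id), ]
  rownames(genes) <- NULL
  genes
}

## Promoter window of each gene, 0-based half-open, strand-reflected:
## + strand  [tss - upstream, tss + downstream)
## - strand  [tss - downstream + 1, tss + upstream + 1)
.promoter_windows <- function(genes, upstream, downstream) {
  plus <- genes$strand == "+"
  ws0 <- ifelse(plus, genes$tss - upstream, genes$tss - downstream + 1)
  we0 <- ifelse(plus, genes$tss + downstream, genes$tss + upstream + 1)
  ws0 <- pmax(ws0, 0)
  GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(ws0 + 1, we0))
}

## Signed, strand-aware distance of a region to a TSS: 0 when the region
## covers the TSS, negative upstream of the gene, positive downstream.
.tss_distance <- function(start0, end0, tss, strand) {
  raw <- ifelse(tss >= start0 & tss < end0, 0,
                ifelse(start0 > tss, start0 - tss, (end0 - 1) - tss))
  ifelse(strand == "-", -raw, raw)
}

#' Assign regions to genes via promoter windows
#'
#' Each region is assigned to the gene whose promoter window (default
#' 5000 bp upstream to 100 bp downstream of the TSS, strand-aware) it
#' overlaps, ties broken by smallest absolute TSS distance then
#' lexicographic `gene_id`. Regions overlapping no promoter fall back to
#' the nearest TSS on the same chromosome with `in_promoter = FALSE`, so
#' every region receives exactly one assignment (gene `NA` only when the
#' chromosome carries no gene).
#'
#' @param regions `GRanges`.
#' @param genes Gene table from [read_gene_models()].
#' @param upstream,downstream Promoter window extent in bp (defaults
#'   5000 and 100).
#' @return `data.frame`: `chrom`, `start`, `end` (0-based half-open),
#'   `gene_id`, `in_promoter`, `tss_distance`.
#' @export
annotate_regions <- function(regions, genes, upstream = 5000,
                             downstream = 100) {
  stopifnot(upstream >= 0, downstream >= 0)
  n <- length(regions)
  start0 <- BiocGenerics::start(regions) - 1L
  end0 <- BiocGenerics::end(regions)
  chrom <- as.character(GenomeInfoDb::seqnames(regions))
  out <- data.frame(chrom = chrom, start = start0, end = end0,
                    gene_id = NA_character_, in_promoter = FALSE,
                    tss_distance = NA_real_, stringsAsFactors = FALSE)
  if (n == 0L || nrow(genes) == 0L) return(out)
  prom <- .promoter_windows(genes, upstream, downstream)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(regions, prom,
                                                       ignore.strand = TRUE))
  pick_best <- function(r, gidx) {
    d <- .tss_distance(start0[r], end0[r], genes$tss[gidx], genes$strand[gidx])
    ord <- order(abs(d), genes$gene_id[gidx])
    c(gidx[ord[1L]], d[ord[1L]])
  }
  if (length(hits) > 0L) {
    byq <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
    for (qs in names(byq)) {
      r <- as.integer(qs)
      best <- pick_best(r, byq[[qs]])
      out$gene_id[r] <- genes$gene_id[best[1L]]
      out$in_promoter[r] <- TRUE
      out$tss_distance[r] <- best[2L]
    }
  }
  miss <- which(!out$in_promoter)
  if (length(miss) > 0L) {
    for (r in miss) {
      gidx <- which(genes$chrom == chrom[r])
      if (length(gidx) == 0L) next
      best <- pick_best(r, gidx)
      out$gene_id[r] <- genes$gene_id[best[1L]]
      out$tss_distance[r] <- best[2L]
    }
  }
  out
}

#' Gene set from annotated DBRs
#'
#' Unique gene ids of the assignments, optionally restricted to regions
#' overlapping a promoter window.
#'
#' @param assignments Output of [annotate_regions()].
#' @param promoter_only Drop nearest-TSS (distal) assignments.
#' @return Character vector of unique gene ids, sorted.
#' @export
gene_sets_from_dbrs <- function(assignments, promoter_only = FALSE) {
  keep <- !is.na(assignments$gene_id)
  if (promoter_only) keep <- keep & assignments$in_promoter
  sort(unique(assignments$gene_id[keep]))
}

#' Chi-squared test of gene-set overlap
#'
#' Builds the 2x2 contingency table (in A and B / A only / B only /
#' neither) over a gene universe and applies Pearson's chi-squared test on
#' 1 degree of freedom without continuity correction (upper-tail
#' p-value). Used to ask whether genes gaining H3K4me3 and genes losing
#' H3K27me3 coincide more than chance.
#'
#' @param set_a,set_b Character vectors of gene ids, both subsets of
#'   `universe` and non-empty.
#' @param universe Character vector of all eligible gene ids.
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return List: `overlap` (|A intersect B|), `statistic`, `pvalue`,
#'   `table` (the 2x2 matrix).
#' @export
overlap_chi_squared <- function(set_a, set_b, universe, correct = FALSE) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  if (length(set_a) == 0L || length(set_b) == 0L) {
    stop("both gene sets must be non-empty")
  }
  if (length(universe) < 4L) stop("universe too small")
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop("gene sets must be subsets of the universe")
  }
  a <- length(intersect(set_a, set_b))
  b <- length(set_a) - a
  cc <- length(set_b) - a
  d <- length(universe) - a - b - cc
  tab <- matrix(c(a, cc, b, d), nrow = 2,
                dimnames = list(in_a = c("yes", "no"), in_b = c("yes", "no")))
  ex <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(ex <= 0)) stop("a margin of the 2x2 table is empty")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(overlap = a, statistic = unname(ht$statistic),
       pvalue = unname(ht$p.value), table = tab)
}
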