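## Plain-text round trip for region x sample count matrices, so a
## precomputed matrix can enter the pipeline in place of fragment BEDs.

#' Write a count matrix to TSV
#'
#' Columns `chrom`, `start`, `end` (0-based half-open) followed by one
#' integer column per sample. Group labels and library sizes are stored
#' in `#group:` / `#lib_size:` header comment lines.
#'
#' @param counts A [count_matrix()] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_count_matrix <- function(counts, path) {
  stopifnot(inherits(counts, "chip_counts"))
  hdr <- c(paste0("#group: ", paste(counts$samples, counts$groups,
                                    sep = "=", collapse = "\t")),
           paste0("#lib_size: ", paste(counts$samples, counts$lib_sizes,
                                       sep = "=", collapse = "\t")))
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(counts$regions)),
                   start = BiocGenerics::start(counts$regions) - 1L,
                   end = BiocGenerics::end(counts$regions),
                   counts$counts, check.names = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, paste(colnames(df), collapse = "\t")), con, sep = "\n")
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read a count matrix written by [write_count_matrix()]
#'
#' @param path Path to the TSV.
#' @return A [count_matrix()] object.
#' @export
read_count_matrix <- function(path) {
  lines <- readLines(path)
  parse_kv <- function(prefix) {
    ln <- sub(paste0("^#", prefix, ": "), "",
              grep(paste0("^#", prefix, ":"), lines, value = TRUE)[1L])
    kv <- strsplit(strsplit(ln, "\t", fixed = TRUE)[[1L]], "=", fixed = TRUE)
    setNames(vapply(kv, `[[`, character(1), 2L),
             vapply(kv, `[[`, character(1), 1L))
  }
  groups <- parse_kv("group")
  libs <- as.numeric(parse_kv("lib_size"))
  names(libs) <- names(parse_kv("lib_size"))
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                          check.names = FALSE)
  regions <- GenomicRanges::GRanges(df$chrom,
                                    IRanges::IRanges(df$start + 1L, df$end))
  y <- as.matrix(df[, -(1:3), drop = FALSE])
  count_matrix(regions, y, groups, lib_sizes = libs)
}
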