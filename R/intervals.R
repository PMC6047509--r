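#' Genomic interval tables
#'
#' Intervals are plain data.frames with columns `chrom`, `start`, `end`
#' (0-based, half-open) and optionally `name`, `score`, `strand`
#' (`"+"`, `"-"` or `"."`). These helpers validate and convert them.
#'
#' @param chrom,start,end,name,score,strand column vectors.
#' @return data.frame of intervals.
#' @export
intervals <- function(chrom, start, end, name = NULL, score = NULL, strand = NULL) {
  if (any(start >= end)) stop("interval start must be < end")
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  if (!is.null(score)) df$score <- as.numeric(score)
  if (!is.null(strand)) {
    if (!all(strand %in% c("+", "-", "."))) stop("strand must be +, - or .")
    df$strand <- as.character(strand)
  }
  df
}

interval_midpoints <- function(iv) (iv$start + iv$end) / 2

# TRUE for each query interval that overlaps >= 1 bp of any subject interval
overlaps_any <- function(query, subject) {
  if (nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  q <- GenomicRanges::GRanges(query$chrom, IRanges::IRanges(query$start + 1, query$end))
  s <- GenomicRanges::GRanges(subject$chrom, IRanges::IRanges(subject$start + 1, subject$end))
  IRanges::overlapsAny(q, s)
}

as_granges <- function(iv) {
  gr <- GenomicRanges::GRanges(iv$chrom, IRanges::IRanges(iv$start + 1, iv$end),
                               strand = if ("strand" %in% names(iv)) {
                                 ifelse(iv$strand == ".", "*", iv$strand)
                               } else "*")
  if ("name" %in% names(iv)) gr$name <- iv$name
  if ("score" %in% names(iv)) gr$score <- iv$score
  gr
}

from_granges <- function(gr) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
  md <- S4Vectors::mcols(gr)
  if ("name" %in% names(md)) df$name <- as.character(md$name)
  if ("score" %in% names(md)) df$score <- as.numeric(md$score)
  st <- as.character(GenomicRanges::strand(gr))
  df$strand <- ifelse(st == "*", ".", st)
  df
}

#' Read / write BED interval files
#'
#' Thin wrappers around rtracklayer that convert to the package's 0-based
#' half-open data.frame convention.
#'
#' @param file path to a BED3/BED6 file.
#' @return `read_bed`: an interval data.frame.
#' @export
read_bed <- function(file) {
  from_granges(rtracklayer::import(file, format = "BED"))
}

#' @rdname read_bed
#' @param iv interval data.frame.
#' @export
write_bed <- function(iv, file) {
  rtracklayer::export(as_granges(iv), file, format = "BED")
  invisible(file)
}
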