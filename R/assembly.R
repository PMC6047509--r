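#' Binned genome assembly
#'
#' Describes the chromosomes of a genome together with a fixed bin size.
#' All coordinates in the package are 0-based, half-open (BED convention);
#' bins of a chromosome of length `L` are `[0, b), [b, 2b), ...,
#' [(n-1)b, L)` with `n = ceiling(L / b)`.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param bin_size bin width in bp.
#' @return an object of class `genome_assembly`.
#' @export
genome_assembly <- function(chrom_lengths, bin_size) {
  stopifnot(length(chrom_lengths) >= 1, !is.null(names(chrom_lengths)),
            all(nzchar(names(chrom_lengths))), !anyDuplicated(names(chrom_lengths)))
  if (any(chrom_lengths <= 0)) stop("all chromosome lengths must be > 0")
  if (bin_size <= 0) stop("bin_size must be > 0")
  nb <- as.integer(ceiling(chrom_lengths / bin_size))
  asm <- list(
    chrom_names   = names(chrom_lengths),
    chrom_lengths = as.numeric(chrom_lengths),
    bin_size      = as.numeric(bin_size),
    n_bins_chrom  = nb,
    offsets       = c(0L, cumsum(nb))[seq_along(nb)]  # global index of first bin per chrom
  )
  names(asm$chrom_lengths) <- names(asm$n_bins_chrom) <- names(asm$offsets) <- asm$chrom_names
  class(asm) <- "genome_assembly"
  asm
}

#' Total number of bins in an assembly
#' @param asm a `genome_assembly`.
#' @export
n_bins <- function(asm) sum(asm$n_bins_chrom)

#' Bin table of an assembly
#'
#' @param asm a `genome_assembly`.
#' @return data.frame with columns `chrom`, `start`, `end`, `bin`
#'   (1-based global bin index).
#' @export
bin_table <- function(asm) {
  tabs <- lapply(asm$chrom_names, function(cn) {
    n <- asm$n_bins_chrom[[cn]]
    s <- (seq_len(n) - 1) * asm$bin_size
    data.frame(chrom = cn, start = s,
               end = pmin(s + asm$bin_size, asm$chrom_lengths[[cn]]))
  })
  out <- do.call(rbind, tabs)
  out$bin <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Global bin index of a genomic position
#'
#' @param asm a `genome_assembly`.
#' @param chrom chromosome name(s).
#' @param pos 0-based bp position(s); must satisfy `0 <= pos < length`.
#' @return 1-based global bin indices.
#' @export
bin_of <- function(asm, chrom, pos) {
  ci <- match(chrom, asm$chrom_names)
  if (anyNA(ci)) stop("unknown chromosome: ", paste(unique(chrom[is.na(ci)]), collapse = ", "))
  bad <- pos < 0 | pos >= asm$chrom_lengths[ci]
  if (any(bad)) stop("position outside chromosome bounds")
  as.integer(asm$offsets[ci] + floor(pos / asm$bin_size) + 1)
}

#' Bins of a single chromosome
#' @param asm a `genome_assembly`.
#' @param chrom chromosome name.
#' @return integer vector of global bin indices.
#' @export
chrom_bins <- function(asm, chrom) {
  ci <- match(chrom, asm$chrom_names)
  if (is.na(ci)) stop("unknown chromosome: ", chrom)
  seq.int(asm$offsets[ci] + 1L, asm$offsets[ci] + asm$n_bins_chrom[ci])
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat("genome_assembly:", length(x$chrom_names), "chromosomes,",
      format(sum(x$chrom_lengths), big.mark = ","), "bp,",
      "bin_size", format(x$bin_size, big.mark = ","), "->", n_bins(x), "bins\n")
  invisible(x)
}
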