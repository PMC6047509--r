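#' CTCF motif orientation profile at TAD borders
#'
#' Counts stranded motifs in `n_bins` consecutive `bin_bp`-wide bins
#' extending from each border into its TAD. For 3' borders the bins run
#' leftward into the TAD and strand labels are swapped, so profiles from
#' both sides share the 5' orientation and can be summed: an excess of
#' forward motifs in bin 1 then reports the convergent arrangement.
#'
#' @param motifs interval data.frame with `strand` in `+`/`-` (and
#'   optionally `score`); counted at their midpoints.
#' @param borders a `border_set` with `side` annotations.
#' @param n_bins,bin_bp number and width of bins from the border.
#' @param min_score if non-NULL, keep motifs with `score > min_score`
#'   (high-confidence set; the conventional cutoff for FIMO scores is 12).
#' @return data.frame with columns `side`, `bin` (1 = at the border),
#'   `forward`, `reverse`; plus a `combined` attribute summing both sides.
#' @export
motif_orientation_profile <- function(motifs, borders, n_bins = 10,
                                      bin_bp = 1e4, min_score = NULL) {
  stopifnot(all(motifs$strand %in% c("+", "-")))
  if (!is.null(min_score)) motifs <- motifs[motifs$score > min_score, , drop = FALSE]
  mid <- interval_midpoints(motifs)
  res <- expand.grid(side = c("5p", "3p"), bin = seq_len(n_bins),
                     stringsAsFactors = FALSE)
  res$forward <- res$reverse <- 0L
  for (r in seq_len(nrow(borders))) {
    cn <- borders$chrom[r]; p <- borders$pos[r]; side <- borders$side[r]
    off <- if (side == "5p") mid - p else p - mid  # distance into the TAD
    k <- floor(off / bin_bp) + 1
    hit <- motifs$chrom == cn & k >= 1 & k <= n_bins
    if (!any(hit)) next
    st <- motifs$strand[hit]
    if (side == "3p") st <- ifelse(st == "+", "-", "+")  # mirror convention
    kk <- k[hit]
    for (b in unique(kk)) {
      row <- which(res$side == side & res$bin == b)
      res$forward[row] <- res$forward[row] + sum(kk == b & st == "+")
      res$reverse[row] <- res$reverse[row] + sum(kk == b & st == "-")
    }
  }
  comb <- stats::aggregate(cbind(forward, reverse) ~ bin, data = res, FUN = sum)
  structure(res[order(res$side, res$bin), ], combined = comb)
}

#' Motif-content enrichment of OCRs over a shifted control
#'
#' Fraction of open chromatin regions containing at least one motif,
#' compared with the same fraction after shifting every OCR by `+shift`
#' (clipped to the chromosome).
#'
#' @param ocrs interval data.frame of open chromatin regions.
#' @param motifs interval data.frame of motif matches.
#' @param assembly `genome_assembly` used for clipping shifted intervals.
#' @param shift shift in bp; default 10x the median OCR length.
#' @return named vector `c(fraction_observed, fraction_shifted, ratio)`.
#' @export
ocr_motif_enrichment <- function(ocrs, motifs, assembly,
                                 shift = 10 * stats::median(ocrs$end - ocrs$start)) {
  if (nrow(ocrs) == 0) stop("empty OCR set")
  obs <- mean(overlaps_any(ocrs, motifs))
  lens <- assembly$chrom_lengths[match(ocrs$chrom, assembly$chrom_names)]
  sh <- data.frame(chrom = ocrs$chrom,
                   start = pmin(ocrs$start + shift, lens - (ocrs$end - ocrs$start)),
                   end = pmin(ocrs$end + shift, lens))
  exp_ <- mean(overlaps_any(sh, motifs))
  c(fraction_observed = obs, fraction_shifted = exp_,
    ratio = if (exp_ > 0) obs / exp_ else Inf)
}

#' Infer nucleosome dyad positions from MNase reads
#'
#' Plus-strand reads place the dyad 73 bp (half a 147-bp nucleosomal
#' footprint) downstream of their leftmost coordinate; minus-strand reads
#' place it `length - 73` bp from theirs (-24 bp for the typical 49-nt
#' read). Centers falling outside their chromosome are dropped.
#'
#' @param reads data.frame with `chrom`, `pos` (leftmost, 0-based),
#'   `strand`, `length`, `mapq`.
#' @param assembly `genome_assembly` for bounds checking.
#' @param min_mapq keep reads with `mapq > min_mapq` (set NULL to skip).
#' @return data.frame with `chrom`, `center`.
#' @export
nucleosome_centers <- function(reads, assembly, min_mapq = 10) {
  if (!is.null(min_mapq)) reads <- reads[reads$mapq > min_mapq, , drop = FALSE]
  center <- ifelse(reads$strand == "+", reads$pos + 73,
                   reads$pos + reads$length - 73)
  lens <- assembly$chrom_lengths[match(reads$chrom, assembly$chrom_names)]
  keep <- center >= 0 & center < lens
  data.frame(chrom = reads$chrom[keep], center = center[keep],
             row.names = NULL)
}

#' Nucleosome phasing profile around binding sites
#'
#' Histogram of dyad-center offsets relative to site midpoints within
#' `+-window` bp; offsets at minus-strand sites are sign-flipped so all
#' sites share one orientation. A phased array shows peaks at regular
#' multiples of the nucleosome repeat length.
#'
#' @param centers data.frame from [nucleosome_centers()].
#' @param sites interval data.frame (stranded or not; unstranded = `+`).
#' @param window half-width in bp.
#' @return data.frame with `offset` (-window..window) and `count`.
#' @export
phasing_profile <- function(centers, sites, window = 1000) {
  offs <- integer(0)
  strand <- if ("strand" %in% names(sites)) sites$strand else rep("+", nrow(sites))
  mid <- round(interval_midpoints(sites))
  for (s in seq_len(nrow(sites))) {
    d <- centers$center[centers$chrom == sites$chrom[s]] - mid[s]
    d <- d[abs(d) <= window]
    if (strand[s] == "-") d <- -d
    offs <- c(offs, d)
  }
  data.frame(offset = -window:window,
             count = tabulate(offs + window + 1, nbins = 2 * window + 1))
}
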