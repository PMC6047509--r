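#' Per-bin scalar tracks
#'
#' A track holds one real value per bin of an assembly at a given bin size
#' (NA = missing). Used for GC content, ChIP densities, replication timing.
#'
#' @param assembly a `genome_assembly` whose `bin_size` is the track resolution.
#' @param values numeric vector, one value per bin of `assembly`.
#' @return object of class `bin_track`.
#' @export
bin_track <- function(assembly, values) {
  stopifnot(inherits(assembly, "genome_assembly"))
  if (length(values) != n_bins(assembly))
    stop("track length ", length(values), " != bin count ", n_bins(assembly))
  structure(list(assembly = assembly, values = as.numeric(values)),
            class = "bin_track")
}

#' @export
print.bin_track <- function(x, ...) {
  cat("bin_track:", n_bins(x$assembly), "bins at",
      format(x$assembly$bin_size, big.mark = ","), "bp\n")
  invisible(x)
}

#' Average a fine track into a coarser binning
#'
#' @param track a `bin_track`.
#' @param new_bin_size target resolution (multiple of the track's bin size).
#' @return a `bin_track` at the coarser resolution (mean of non-missing
#'   fine values per coarse bin).
#' @export
rebin_track <- function(track, new_bin_size) {
  asm <- track$assembly
  k <- new_bin_size / asm$bin_size
  if (k != round(k) || k < 1) stop("new_bin_size must be a multiple of the track bin size")
  asm2 <- genome_assembly(stats::setNames(asm$chrom_lengths, asm$chrom_names), new_bin_size)
  vals <- rep(NA_real_, n_bins(asm2))
  for (cn in asm$chrom_names) {
    fb <- chrom_bins(asm, cn); cb <- chrom_bins(asm2, cn)
    grp <- floor((seq_along(fb) - 1) / k) + 1
    mg <- tapply(track$values[fb], grp, function(v) mean(v, na.rm = TRUE))
    vals[cb[as.integer(names(mg))]] <- as.numeric(mg)
  }
  vals[is.nan(vals)] <- NA_real_
  bin_track(asm2, vals)
}

#' Average biological replicate tracks
#'
#' @param tracks list of `bin_track`s on the same binning.
#' @return a `bin_track` of per-bin means over replicates (NA-aware).
#' @export
average_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  vs <- vapply(tracks, function(t) t$values, numeric(n_bins(tracks[[1]]$assembly)))
  bin_track(tracks[[1]]$assembly, rowMeans(as.matrix(vs), na.rm = TRUE))
}

#' Read / write per-bin tracks as bedGraph
#'
#' @param file bedGraph path.
#' @param assembly the `genome_assembly` defining the binning.
#' @return `read_bedgraph`: a `bin_track` (bins absent from the file are NA).
#' @export
read_bedgraph <- function(file, assembly) {
  gr <- rtracklayer::import(file, format = "bedGraph")
  df <- from_granges(gr)
  vals <- rep(NA_real_, n_bins(assembly))
  vals[bin_of(assembly, df$chrom, df$start)] <- df$score
  bin_track(assembly, vals)
}

#' @rdname read_bedgraph
#' @param track a `bin_track`.
#' @export
write_bedgraph <- function(track, file) {
  bt <- bin_table(track$assembly)
  keep <- !is.na(track$values)
  gr <- GenomicRanges::GRanges(bt$chrom[keep],
                               IRanges::IRanges(bt$start[keep] + 1, bt$end[keep]),
                               score = track$values[keep])
  rtracklayer::export(gr, file, format = "bedGraph")
  invisible(file)
}
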