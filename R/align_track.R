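#' Align a per-bin track on TAD borders
#'
#' Averages a scalar track into `step`-sized bins over
#' `[-upstream, +downstream]` around every border, deeptools-style. Borders
#' whose window is truncated by a chromosome end are dropped. 3' borders are
#' mirrored so all alignments share the 5' orientation (offset increasing
#' into the TAD). With `zscore = TRUE` the track is standardized genome-wide
#' over its non-missing bins before alignment.
#'
#' @param track a `bin_track` whose resolution is <= `step`.
#' @param borders a `border_set`.
#' @param upstream,downstream window extent in bp.
#' @param step output bin width in bp.
#' @param zscore standardize the track first.
#' @return list with `offsets` (bp, window bin centers), `profile`
#'   (borders x offsets matrix), `mean` (NA-aware column means),
#'   `n_borders`; class `border_alignment`.
#' @export
align_track_on_borders <- function(track, borders, upstream = 5e5,
                                   downstream = 5e5, step = 1e4,
                                   zscore = FALSE) {
  asm <- track$assembly
  if (asm$bin_size > step) stop("track resolution must be <= step")
  vals <- track$values
  if (zscore) {
    mu <- mean(vals, na.rm = TRUE); sdv <- stats::sd(vals, na.rm = TRUE)
    if (!is.finite(sdv) || sdv == 0) stop("zero-variance track: z-scoring undefined")
    vals <- (vals - mu) / sdv
  }
  n_out <- round((upstream + downstream) / step)
  offsets <- -upstream + (seq_len(n_out) - 0.5) * step
  rows <- list()
  for (r in seq_len(nrow(borders))) {
    cn <- borders$chrom[r]; p <- borders$pos[r]
    len <- asm$chrom_lengths[[cn]]
    mirror <- identical(borders$side[r], "3p")
    lo <- if (mirror) p - downstream else p - upstream
    hi <- if (mirror) p + upstream else p + downstream
    if (lo < 0 || hi > len) next  # truncated window
    prof <- vapply(seq_len(n_out), function(k) {
      o0 <- lo + (k - 1) * step; o1 <- o0 + step
      b0 <- floor(o0 / asm$bin_size); b1 <- ceiling(o1 / asm$bin_size) - 1
      idx <- chrom_bins(asm, cn)[(b0 + 1):(b1 + 1)]
      # area weights of track bins inside [o0, o1)
      bs <- asm$bin_size
      ov <- pmin(o1, (b0:b1 + 1) * bs) - pmax(o0, (b0:b1) * bs)
      v <- vals[idx]
      ok <- !is.na(v) & ov > 0
      if (!any(ok)) return(NA_real_)
      sum(v[ok] * ov[ok]) / sum(ov[ok])
    }, numeric(1))
    if (mirror) prof <- rev(prof)
    rows[[length(rows) + 1]] <- prof
  }
  if (!length(rows)) stop("no borders with complete windows")
  profile <- do.call(rbind, rows)
  structure(list(offsets = offsets, profile = profile,
                 mean = colMeans(profile, na.rm = TRUE),
                 n_borders = nrow(profile)),
            class = "border_alignment")
}
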