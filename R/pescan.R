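# PE-SCAn: pile-up of contact submatrices centered on all pairwise anchor
# combinations, normalized by a coordinate-shifted background.

anchor_bins <- function(asm, anchors) {
  mid <- pmin(interval_midpoints(anchors),
              asm$chrom_lengths[match(anchors$chrom, asm$chrom_names)] - 1)
  data.frame(chrom = anchors$chrom, bin = bin_of(asm, anchors$chrom, mid))
}

# average the (2r+1)^2 windows at (rows bi, cols bj) over a list of pairs,
# adding each window and its transpose so the pile-up is order-symmetric
pileup_windows <- function(x, pairs, r) {
  sz <- 2 * r + 1
  acc <- matrix(0, sz, sz); wt <- matrix(0, sz, sz)
  for (p in pairs) {
    win <- x[(p[1] - r):(p[1] + r), (p[2] - r):(p[2] + r), drop = FALSE]
    for (w in list(win, t(win))) {
      ok <- !is.na(w)
      acc[ok] <- acc[ok] + w[ok]
      wt[ok] <- wt[ok] + 1
    }
  }
  out <- acc / wt
  out[wt == 0] <- NA_real_
  out
}

pescan_result <- function(mean_real, background, n_pairs, radius_bins) {
  bg_med <- stats::median(background, na.rm = TRUE)
  if (!is.finite(bg_med) || bg_med <= 0) stop("zero background median; cannot normalize")
  structure(list(radius_bins = radius_bins, mean_real = mean_real,
                 background = background, background_median = bg_med,
                 normalized = mean_real / bg_med, n_pairs = n_pairs),
            class = "hub_alignment")
}

#' @export
print.hub_alignment <- function(x, ...) {
  r <- x$radius_bins + 1
  cat("hub_alignment:", x$n_pairs, "anchor pairs, center enrichment",
      format(x$normalized[r, r], digits = 4), "\n")
  invisible(x)
}

#' PE-SCAn pile-up of intra-chromosomal anchor pairs
#'
#' For every same-chromosome anchor pair separated by more than `min_sep`
#' ("far-cis"), the `(2r+1) x (2r+1)` O/E submatrix centered on the pair is
#' averaged; the background repeats the procedure with both anchors shifted
#' by `+shift`, and the pile-up is normalized by the background median. A
#' center enrichment above 1 indicates preferential spatial clustering of
#' the anchors (e.g. super-enhancer hubs).
#'
#' @param m a `contact_matrix`.
#' @param anchors interval data.frame (anchor point = midpoint snapped to
#'   its bin).
#' @param min_sep minimum pair separation in bp.
#' @param shift background shift in bp.
#' @param radius_bins window half-size in bins.
#' @param oe optional precomputed O/E matrix for `m`.
#' @return a `hub_alignment`.
#' @export
pescan_intra <- function(m, anchors, min_sep = 5e6, shift = 1e6,
                         radius_bins = 10, oe = NULL) {
  stopifnot(inherits(m, "contact_matrix"))
  asm <- m$assembly
  r <- radius_bins
  sb <- round(shift / asm$bin_size)
  ab <- anchor_bins(asm, anchors)
  if (is.null(oe)) oe <- observed_over_expected(m)
  real <- list(); bg <- list()
  for (cn in unique(ab$chrom)) {
    bins <- sort(ab$bin[ab$chrom == cn])
    if (length(bins) < 2) next
    lo <- min(chrom_bins(asm, cn)); hi <- max(chrom_bins(asm, cn))
    cmb <- utils::combn(bins, 2)
    for (q in seq_len(ncol(cmb))) {
      bi <- cmb[1, q]; bj <- cmb[2, q]
      if ((bj - bi) * asm$bin_size <= min_sep) next
      # a pair is used only if both its real and shifted windows fit
      if (bi - r < lo || bj + sb + r > hi) next
      real[[length(real) + 1]] <- c(bi, bj)
      bg[[length(bg) + 1]] <- c(bi + sb, bj + sb)
    }
  }
  if (!length(real))
    stop("no eligible far-cis anchor pairs (separation > ", min_sep, " bp)")
  pescan_result(pileup_windows(oe, real, r), pileup_windows(oe, bg, r),
                length(real), r)
}

#' PE-SCAn pile-up of inter-chromosomal anchor pairs
#'
#' Same pile-up over all cross-chromosome anchor pairs, using raw trans
#' counts (there is no distance decay to remove between chromosomes);
#' background by shifting both anchors `+shift` along their chromosomes.
#'
#' @inheritParams pescan_intra
#' @return a `hub_alignment`.
#' @export
pescan_inter <- function(m, anchors, shift = 1e6, radius_bins = 10) {
  stopifnot(inherits(m, "contact_matrix"))
  asm <- m$assembly
  if (length(asm$chrom_names) < 2) stop("inter-chromosomal pile-up needs >= 2 chromosomes")
  r <- radius_bins
  sb <- round(shift / asm$bin_size)
  ab <- anchor_bins(asm, anchors)
  trans_mask <- outer(bin_table(asm)$chrom, bin_table(asm)$chrom, "!=")
  if (sum(m$counts[trans_mask]) == 0) stop("matrix has no trans contacts")
  x <- m$counts
  x[!trans_mask] <- NA_real_  # restrict windows to trans blocks
  lims <- lapply(stats::setNames(asm$chrom_names, asm$chrom_names),
                 function(cn) range(chrom_bins(asm, cn)))
  real <- list(); bg <- list()
  for (q1 in seq_len(nrow(ab) - 1)) for (q2 in (q1 + 1):nrow(ab)) {
    if (ab$chrom[q1] == ab$chrom[q2]) next
    bi <- ab$bin[q1]; bj <- ab$bin[q2]
    l1 <- lims[[ab$chrom[q1]]]; l2 <- lims[[ab$chrom[q2]]]
    if (bi - r < l1[1] || bi + sb + r > l1[2] ||
        bj - r < l2[1] || bj + sb + r > l2[2]) next
    real[[length(real) + 1]] <- c(bi, bj)
    bg[[length(bg) + 1]] <- c(bi + sb, bj + sb)
  }
  if (!length(real)) stop("no eligible inter-chromosomal anchor pairs")
  pescan_result(pileup_windows(x, real, r), pileup_windows(x, bg, r),
                length(real), r)
}
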