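#' Observed-over-expected normalization
#'
#' Divides each intra-chromosomal contact by the mean contact count at the
#' same bin separation, computed per chromosome over pairs in which both
#' bins are live. Distance decay is thereby removed, exposing domain and
#' compartment structure. Dead bins give NA rows/columns; inter-chromosomal
#' blocks are left untouched.
#'
#' @param m a `contact_matrix`.
#' @return a numeric matrix of the same dimension with attributes
#'   `assembly` and `what = "oe"`; cis entries are O/E values, trans entries
#'   are the raw counts.
#' @export
observed_over_expected <- function(m) {
  stopifnot(inherits(m, "contact_matrix"))
  asm <- m$assembly
  dead <- dead_bins(m)
  out <- m$counts
  for (cn in asm$chrom_names) {
    idx <- chrom_bins(asm, cn)
    if (all(dead[idx])) stop("chromosome has no covered bins: ", cn)
    blk <- m$counts[idx, idx, drop = FALSE]
    alive <- !dead[idx]
    n <- length(idx)
    oe <- matrix(NA_real_, n, n)
    for (d in 0:(n - 1)) {
      i <- seq_len(n - d); j <- i + d
      ok <- alive[i] & alive[j]
      if (!any(ok)) next
      ex <- mean(blk[cbind(i[ok], j[ok])])
      if (ex > 0) {
        v <- blk[cbind(i[ok], j[ok])] / ex
        oe[cbind(i[ok], j[ok])] <- v
        oe[cbind(j[ok], i[ok])] <- v
      }
    }
    out[idx, idx] <- oe
  }
  out[dead, ] <- NA_real_
  out[, dead] <- NA_real_
  attr(out, "assembly") <- asm
  attr(out, "what") <- "oe"
  out
}

#' Correlation matrix of an O/E block
#'
#' Entry (i, j) is the Pearson correlation between rows i and j over their
#' mutually valid (non-NA) entries — the classic checkerboard transform used
#' ahead of compartment eigenvector analysis.
#'
#' @param oe square numeric matrix, NA = masked.
#' @return square matrix in `[-1, 1]`, unit diagonal on valid rows; rows with
#'   fewer than 3 valid entries or zero variance are fully masked.
#' @export
correlation_matrix <- function(oe) {
  stopifnot(is.matrix(oe), nrow(oe) == ncol(oe))
  valid_n <- rowSums(!is.na(oe))
  sds <- apply(oe, 1, stats::sd, na.rm = TRUE)
  good <- valid_n >= 3 & !is.na(sds) & sds > 0
  if (sum(good) < 3) stop("need at least 3 valid rows")
  cc <- suppressWarnings(stats::cor(t(oe[good, good, drop = FALSE]),
                                    use = "pairwise.complete.obs"))
  cc <- (cc + t(cc)) / 2
  diag(cc) <- 1
  out <- matrix(NA_real_, nrow(oe), ncol(oe))
  out[good, good] <- cc
  out
}

#' Relative contact frequency by distance
#'
#' Pools all intra-chromosomal contacts genome-wide and reports the
#' percentage of contacts falling in each of `n_bins` exponentially
#' (geometrically) spaced distance bins between one bin size and the longest
#' chromosome. Shifts of this curve towards long distances reflect
#' large-scale compaction changes.
#'
#' @param m a `contact_matrix`.
#' @param n_bins number of distance bins.
#' @return object of class `distance_curve`: data.frame with `left`, `right`
#'   (bp bin edges) and `fraction` (percent, summing to 100).
#' @export
relative_contact_frequency <- function(m, n_bins = 50) {
  stopifnot(inherits(m, "contact_matrix"))
  asm <- m$assembly
  bs <- asm$bin_size
  # total counts per bin separation d >= 1, pooled over chromosomes
  maxd <- max(asm$n_bins_chrom) - 1
  if (maxd < 1) stop("matrix has no off-diagonal intra-chromosomal bins")
  per_d <- numeric(maxd)
  for (cn in asm$chrom_names) {
    blk <- cis_block(m, cn)
    n <- nrow(blk)
    if (n < 2) next
    for (d in 1:(n - 1)) {
      i <- seq_len(n - d)
      per_d[d] <- per_d[d] + sum(blk[cbind(i, i + d)])
    }
  }
  total <- sum(per_d)
  if (total == 0) stop("no intra-chromosomal contacts off the diagonal")
  edges <- exp(seq(log(bs), log(max(asm$chrom_lengths)), length.out = n_bins + 1))
  d_bp <- (1:maxd) * bs
  k <- findInterval(d_bp, edges, rightmost.closed = TRUE)
  k[k < 1] <- 1; k[k > n_bins] <- n_bins
  frac <- vapply(seq_len(n_bins), function(b) sum(per_d[k == b]), numeric(1)) / total * 100
  structure(data.frame(left = edges[-length(edges)], right = edges[-1],
                       fraction = frac),
            class = c("distance_curve", "data.frame"))
}

#' Quantify a 4C viewpoint profile within its TAD
#'
#' Splits the contact signal of a one-viewpoint (4C) profile into the region
#' flanking the viewpoint and the rest of the containing TAD. TAD loss
#' manifests as signal concentrating near the viewpoint at the expense of
#' the domain body.
#'
#' @param profile data.frame with columns `pos` (bp) and `signal` (>= 0),
#'   e.g. per-fragment or per-bp contact counts on the viewpoint chromosome.
#' @param tad single-row interval data.frame (the containing TAD).
#' @param viewpoint viewpoint position in bp; must lie in `tad`.
#' @param flank half-width of the flanking region (bp); signal at positions
#'   in `[viewpoint - flank, viewpoint + flank)` counts as flanking.
#' @return named numeric vector `c(flank_fraction, body_fraction)`.
#' @export
quantify_viewpoint_profile <- function(profile, tad, viewpoint, flank = 15000) {
  stopifnot(all(c("pos", "signal") %in% names(profile)), nrow(tad) == 1)
  if (viewpoint < tad$start || viewpoint >= tad$end)
    stop("viewpoint must lie inside the TAD")
  in_tad <- profile$pos >= tad$start & profile$pos < tad$end
  total <- sum(profile$signal[in_tad])
  if (total <= 0) stop("no signal within the TAD")
  in_flank <- in_tad & profile$pos >= viewpoint - flank & profile$pos < viewpoint + flank
  ff <- sum(profile$signal[in_flank]) / total
  c(flank_fraction = ff, body_fraction = 1 - ff)
}

#' Paired comparison of viewpoint flank fractions between two stages
#'
#' @param flank_a,flank_b flank fractions for the same viewpoints at two
#'   stages (equal length, paired).
#' @return the paired Wilcoxon signed-rank test (`htest`).
#' @export
compare_viewpoint_profiles <- function(flank_a, flank_b) {
  stopifnot(length(flank_a) == length(flank_b))
  stats::wilcox.test(flank_a, flank_b, paired = TRUE)
}
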