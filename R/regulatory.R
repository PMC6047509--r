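#' Classify promoters and enhancers from histone peak sets
#'
#' Promoters are H3K4me3 peaks within 2 kb (edge-to-point gap) of a TSS;
#' enhancers are H3K27ac peaks overlapping at least 1 bp of an H3K4me1 peak
#' and no H3K4me3 peak.
#'
#' @param k4me3,k27ac,k4me1 interval data.frames of peaks.
#' @param tss interval data.frame of transcription start sites (points).
#' @param tss_dist maximum peak-edge-to-TSS gap in bp.
#' @return list with `promoters` and `enhancers` interval data.frames,
#'   class `element_set`.
#' @export
classify_elements <- function(k4me3, k27ac, k4me1, tss, tss_dist = 2000) {
  tpos <- tss$start
  near_tss <- vapply(seq_len(nrow(k4me3)), function(i) {
    same <- tss$chrom == k4me3$chrom[i]
    any(same & tpos >= k4me3$start[i] - tss_dist & tpos <= k4me3$end[i] + tss_dist)
  }, logical(1))
  promoters <- k4me3[near_tss, , drop = FALSE]
  enh <- overlaps_any(k27ac, k4me1) & !overlaps_any(k27ac, k4me3)
  enhancers <- k27ac[enh, , drop = FALSE]
  rownames(promoters) <- rownames(enhancers) <- NULL
  structure(list(promoters = promoters, enhancers = enhancers),
            class = "element_set")
}

#' Observed/expected promoter-to-nearest-enhancer distance
#'
#' Observed: mean over promoters of the midpoint distance to the nearest
#' enhancer on the same chromosome. Expected: the same statistic averaged
#' over `n_shuffles` random relocations of every enhancer, uniform within a
#' `window` centered on its original midpoint (length preserved, clipped to
#' the chromosome). Negative `log2(O/E)` indicates enhancers sitting closer
#' to promoters than chance placement allows.
#'
#' @param elements an `element_set` (or list with `promoters`, `enhancers`).
#' @param assembly `genome_assembly` for clipping.
#' @param window shuffling window in bp.
#' @param n_shuffles number of random relocations (> 0).
#' @param seed RNG seed.
#' @return list with `log2_oe`, `observed_mean`, `expected_mean`,
#'   `distances` (per promoter), `n_excluded` (promoters with no enhancer
#'   on their chromosome).
#' @export
enhancer_distance_oe <- function(elements, assembly, window = 1e6,
                                 n_shuffles = 100, seed = 1) {
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  pr <- elements$promoters; en <- elements$enhancers
  if (!nrow(pr) || !nrow(en)) stop("need at least one promoter and one enhancer")
  pm <- interval_midpoints(pr); em <- interval_midpoints(en)
  nearest_mean <- function(emid) {
    d <- rep(NA_real_, nrow(pr))
    for (cn in unique(pr$chrom)) {
      pi <- which(pr$chrom == cn); ei <- which(en$chrom == cn)
      if (!length(ei)) next
      d[pi] <- vapply(pm[pi], function(x) min(abs(emid[ei] - x)), numeric(1))
    }
    d
  }
  obs <- nearest_mean(em)
  n_excluded <- sum(is.na(obs))
  lens <- assembly$chrom_lengths[match(en$chrom, assembly$chrom_names)]
  half <- (en$end - en$start) / 2
  exp_means <- with_seed(seed, vapply(seq_len(n_shuffles), function(s) {
    shuf <- stats::runif(nrow(en), em - window / 2, em + window / 2)
    shuf <- pmax(half, pmin(shuf, lens - half))
    mean(nearest_mean(shuf), na.rm = TRUE)
  }, numeric(1)))
  om <- mean(obs, na.rm = TRUE); xm <- mean(exp_means)
  list(log2_oe = log2(om / xm), observed_mean = om, expected_mean = xm,
       distances = obs, n_excluded = n_excluded)
}

#' Shannon-entropy expression-breadth classification
#'
#' Per gene, expression across samples is normalized to a probability
#' vector and its entropy `H = -sum(p * log2(p))` computed (`0 log 0 = 0`).
#' Uniform expression gives the maximum `log2(n)`; expression confined to
#' one sample gives 0. By the standard reading, high entropy means broad
#' (housekeeping) expression, so the `k` genes with the highest H are
#' classified housekeeping and the `k` lowest tissue-specific;
#' `invert = TRUE` swaps the two labels.
#'
#' @param tpm genes x samples nonnegative matrix (rownames = gene ids);
#'   all-zero rows are dropped.
#' @param k number of genes per extreme class (`<= nrow/2`).
#' @param invert swap the class labels.
#' @return data.frame with `gene`, `entropy` (bits), `class` in
#'   `{housekeeping, tissue-specific, neither}`.
#' @export
shannon_classify <- function(tpm, k = 1000, invert = FALSE) {
  stopifnot(is.matrix(tpm), ncol(tpm) >= 2)
  tpm <- tpm[rowSums(tpm) > 0, , drop = FALSE]
  if (k > nrow(tpm) / 2) stop("k must be at most half the gene count")
  h <- apply(tpm, 1, shannon_entropy)
  ord <- order(h, decreasing = TRUE)
  cls <- rep("neither", length(h))
  cls[ord[seq_len(k)]] <- if (invert) "tissue-specific" else "housekeeping"
  cls[rev(ord)[seq_len(k)]] <- if (invert) "housekeeping" else "tissue-specific"
  data.frame(gene = rownames(tpm), entropy = h, class = cls, row.names = NULL)
}

#' Shannon entropy of an expression profile
#' @param x nonnegative numeric vector (one gene across samples).
#' @return entropy in bits.
#' @export
shannon_entropy <- function(x) {
  p <- x / sum(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Feature enrichment near TAD borders
#'
#' Density of feature positions as a function of distance to the nearest
#' border, divided by the density of a background position set, with a
#' bootstrap confidence band over features.
#'
#' @param features,background data.frames with `chrom` and `pos` (bp).
#' @param borders a `border_set`.
#' @param max_dist largest distance considered (bp).
#' @param step distance bin width (bp).
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed.
#' @return data.frame with `dist_lo`, `dist_hi`, `ratio`, `lo`, `hi`
#'   (band); bins without background positions have NA ratio.
#' @export
feature_border_enrichment <- function(features, borders, background,
                                      max_dist = 5e5, step = 5e4,
                                      n_boot = 200, seed = 1) {
  if (!nrow(borders)) stop("empty border set")
  if (!nrow(features) || !nrow(background)) stop("features and background must be non-empty")
  if (nrow(features) == 1) warning("single feature: confidence band is degenerate")
  nearest_border_dist <- function(df) {
    vapply(seq_len(nrow(df)), function(i) {
      b <- borders$pos[borders$chrom == df$chrom[i]]
      if (!length(b)) return(NA_real_)
      min(abs(b - df$pos[i]))
    }, numeric(1))
  }
  edges <- seq(0, max_dist, by = step)
  nb <- length(edges) - 1
  dens <- function(d) {
    d <- d[!is.na(d) & d < max_dist]
    tabulate(pmin(floor(d / step) + 1, nb), nbins = nb) / max(length(d), 1)
  }
  fd <- nearest_border_dist(features)
  bd <- nearest_border_dist(background)
  fb <- dens(fd); bb <- dens(bd)
  ratio <- ifelse(bb > 0, fb / bb, NA_real_)
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(s) {
    rs <- dens(sample(fd, length(fd), replace = TRUE))
    ifelse(bb > 0, rs / bb, NA_real_)
  }, numeric(nb)))
  band <- apply(boots, 1, stats::quantile, probs = c(0.025, 0.975),
                na.rm = TRUE, names = FALSE)
  data.frame(dist_lo = edges[-length(edges)], dist_hi = edges[-1],
             ratio = ratio, lo = band[1, ], hi = band[2, ])
}
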