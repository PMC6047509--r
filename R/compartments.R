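#' A/B compartment eigenvector
#'
#' Per chromosome: O/E-normalize the cis block, take its correlation matrix,
#' extract the leading eigenvectors, select among the first three the one
#' whose values best correlate (absolute Pearson) with GC content, and
#' orient the sign so that bins with positive values have the higher mean
#' active-mark signal. Positive values are labelled A, negative B.
#'
#' @param m a `contact_matrix` at 100-kb resolution (use [rebin()] for finer
#'   matrices; coarse bins with under half their fine bins covered are
#'   masked there).
#' @param gc a `bin_track` of GC content on the same binning.
#' @param active a `bin_track` of active-mark (e.g. H3K4me1) density on the
#'   same binning.
#' @param n_pc how many leading eigenvectors to scan.
#' @return object of class `compartment_profile`: data.frame with `chrom`,
#'   `start`, `end`, `pc` (eigenvector value, NA where masked), `label`
#'   (`"A"`/`"B"`); attributes `selected_pc` and `gc_correlation` (named per
#'   chromosome) and `gc_correlation_genome` (Pearson r of pc vs GC over all
#'   unmasked bins).
#' @export
compartment_eigenvector <- function(m, gc, active, n_pc = 3) {
  stopifnot(inherits(m, "contact_matrix"))
  asm <- m$assembly
  if (n_bins(gc$assembly) != n_bins(asm) || n_bins(active$assembly) != n_bins(asm))
    stop("matrix, gc and active tracks must share the same binning")
  oe <- observed_over_expected(m)
  bt <- bin_table(asm)
  pc_all <- rep(NA_real_, nrow(bt))
  sel <- r_gc <- stats::setNames(rep(NA_real_, length(asm$chrom_names)), asm$chrom_names)
  for (cn in asm$chrom_names) {
    idx <- chrom_bins(asm, cn)
    if (sum(!dead_bins(m)[idx]) < 10) stop("fewer than 10 covered bins on ", cn)
    cc <- correlation_matrix(oe[idx, idx, drop = FALSE])
    good <- which(!is.na(diag(cc)))
    eg <- eigen(cc[good, good], symmetric = TRUE)
    if (sum(eg$values > 1e-10) < n_pc)
      stop("degenerate correlation matrix on ", cn, ": rank below ", n_pc)
    gcv <- gc$values[idx][good]
    rs <- vapply(seq_len(n_pc), function(k)
      suppressWarnings(stats::cor(eg$vectors[, k], gcv,
                                  use = "complete.obs")), numeric(1))
    k <- which.max(abs(rs))
    v <- eg$vectors[, k] * sqrt(eg$values[k])
    av <- active$values[idx][good]
    m_pos <- mean(av[v > 0], na.rm = TRUE); m_neg <- mean(av[v < 0], na.rm = TRUE)
    if (!is.finite(m_pos) || !is.finite(m_neg) || m_pos == m_neg)
      stop("ambiguous A/B orientation on ", cn,
           ": active-mark means equal; provide a longer active track")
    if (m_pos < m_neg) v <- -v
    pc_all[idx[good]] <- v
    sel[cn] <- k
    r_gc[cn] <- stats::cor(v, gcv, use = "complete.obs")
  }
  out <- data.frame(chrom = bt$chrom, start = bt$start, end = bt$end,
                    pc = pc_all,
                    label = ifelse(is.na(pc_all), NA_character_,
                                   ifelse(pc_all > 0, "A", "B")))
  structure(out, assembly = asm, selected_pc = sel, gc_correlation = r_gc,
            gc_correlation_genome = stats::cor(pc_all, gc$values,
                                               use = "complete.obs"),
            class = c("compartment_profile", "data.frame"))
}

#' Stratify a track by compartment label
#'
#' Summarizes a scalar track (e.g. replication timing) over A and B bins and
#' tests A > B with a one-sided Wilcoxon rank-sum test. Replicates, if
#' given as a list of tracks, are averaged first; finer tracks are averaged
#' into the profile's 100-kb binning.
#'
#' @param track a `bin_track` or a list of replicate `bin_track`s.
#' @param profile a `compartment_profile`.
#' @return list with `summary` (data.frame: label, n, q25, median, q75),
#'   `p_a_gt_b` (one-sided Wilcoxon p), class `compartment_strata`.
#' @export
stratify_by_compartment <- function(track, profile) {
  asm <- attr(profile, "assembly")
  if (is.list(track) && !inherits(track, "bin_track")) track <- average_tracks(track)
  if (track$assembly$bin_size < asm$bin_size)
    track <- rebin_track(track, asm$bin_size)
  if (n_bins(track$assembly) != nrow(profile))
    stop("track and profile binnings differ")
  v <- track$values
  a <- v[!is.na(profile$label) & profile$label == "A"]
  b <- v[!is.na(profile$label) & profile$label == "B"]
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("empty compartment class")
  qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  sm <- data.frame(label = c("A", "B"), n = c(length(a), length(b)),
                   q25 = c(qs(a)[1], qs(b)[1]), median = c(qs(a)[2], qs(b)[2]),
                   q75 = c(qs(a)[3], qs(b)[3]))
  p <- stats::wilcox.test(a, b, alternative = "greater")$p.value
  structure(list(summary = sm, p_a_gt_b = p), class = "compartment_strata")
}
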