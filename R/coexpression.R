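#' Section quality control for sectioned expression data
#'
#' Drops sections (columns) in which fewer than `min_genes` genes are
#' detected (nonzero counts). The conventional threshold for genome-scale
#' Tomo-seq data is 6,000 detected genes per section.
#'
#' @param expr genes x sections nonnegative matrix.
#' @param min_genes minimum detected-gene count per section.
#' @return the filtered matrix; attribute `detected` holds the per-section
#'   counts of the retained sections.
#' @export
qc_sections <- function(expr, min_genes = 6000) {
  stopifnot(is.matrix(expr))
  det <- colSums(expr > 0)
  keep <- det >= min_genes
  if (!any(keep)) stop("all sections fail QC (< ", min_genes, " detected genes)")
  structure(expr[, keep, drop = FALSE], detected = det[keep])
}

#' Combine p-values by Fisher's method
#'
#' `X2 = -2 * sum(log(p))` referred to a chi-square distribution with
#' `2 * length(p)` degrees of freedom.
#'
#' @param p vector of p-values in (0, 1].
#' @return list with `statistic`, `df`, `p_value`.
#' @export
fisher_combine <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) stop("no p-values to combine")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  x2 <- -2 * sum(log(p))
  list(statistic = x2, df = 2 * length(p),
       p_value = stats::pchisq(x2, df = 2 * length(p), lower.tail = FALSE))
}

#' Same-TAD enrichment of spatially co-expressed neighbour gene pairs
#'
#' For each gene distance `d` (number of intervening genes along the
#' chromosome), all gene pairs separated by `d` are formed, their Spearman
#' correlation across sections computed (average ranks for ties), and a
#' pair is "correlated" when rho exceeds `rho_threshold`. Per `d`, the
#' correlated fraction among same-TAD pairs is tested against the
#' correlated fraction among all pairs (the null probability) with a
#' one-sided exact binomial test; the per-d p-values are combined with
#' Fisher's method.
#'
#' @param expr genes x sections matrix (after [qc_sections()]); rownames
#'   are gene names.
#' @param gene_coords interval data.frame with a `name` column matching
#'   `rownames(expr)`.
#' @param tads interval data.frame of TADs (same-TAD = both gene midpoints
#'   inside one TAD).
#' @param rho_threshold Spearman threshold (conventionally 0.4, 0.5 or 0.6).
#' @param dmax largest gene distance considered.
#' @return object of class `coexpr_result`: data.frame with one row per
#'   `d` (`n_pairs`, `n_same_tad`, `frac_all`, `frac_same_tad`,
#'   `p_binomial`, `included`); attributes `combined_p`, `statistic`, `df`,
#'   `rho_threshold`, `alternative = "greater"`.
#' @export
coexpression_stratified <- function(expr, gene_coords, tads,
                                    rho_threshold = 0.5, dmax = 5) {
  stopifnot(is.matrix(expr), ncol(expr) >= 3)
  gene_coords <- gene_coords[match(rownames(expr), gene_coords$name), ]
  if (anyNA(gene_coords$chrom)) stop("gene_coords must cover all expression rows")
  tad_of <- assign_to_tads(gene_coords, tads)
  # rank-transform once; Spearman rho = Pearson on ranks
  rk <- t(apply(expr, 1, rank))
  rk <- rk - rowMeans(rk)
  ss <- sqrt(rowSums(rk^2))
  ord <- order(gene_coords$chrom, interval_midpoints(gene_coords))
  res <- data.frame(d = 0:dmax, n_pairs = 0L, n_same_tad = 0L,
                    frac_all = NA_real_, frac_same_tad = NA_real_,
                    p_binomial = NA_real_, included = FALSE)
  for (d in 0:dmax) {
    i <- ord[seq_len(length(ord) - d - 1)]
    j <- ord[seq_len(length(ord) - d - 1) + d + 1]
    same_chrom <- gene_coords$chrom[i] == gene_coords$chrom[j]
    i <- i[same_chrom]; j <- j[same_chrom]
    if (!length(i)) next
    rho <- rowSums(rk[i, , drop = FALSE] * rk[j, , drop = FALSE]) / (ss[i] * ss[j])
    correlated <- !is.na(rho) & rho > rho_threshold
    same_tad <- !is.na(tad_of[i]) & !is.na(tad_of[j]) & tad_of[i] == tad_of[j]
    row <- d + 1
    res$n_pairs[row] <- length(i)
    res$n_same_tad[row] <- sum(same_tad)
    res$frac_all[row] <- mean(correlated)
    if (sum(same_tad) == 0) next  # flagged: excluded from the combination
    res$frac_same_tad[row] <- mean(correlated[same_tad])
    x <- sum(correlated & same_tad); n <- sum(same_tad); p0 <- res$frac_all[row]
    # exact one-sided binomial tail P(X >= x); robust for p0 in {0, 1}
    res$p_binomial[row] <- if (p0 >= 1) 1 else
      stats::pbinom(x - 1, n, p0, lower.tail = FALSE)
    res$included[row] <- TRUE
  }
  if (!any(res$included)) stop("no gene distance had same-TAD pairs")
  fc <- fisher_combine(res$p_binomial[res$included])
  structure(res, combined_p = fc$p_value, statistic = fc$statistic,
            df = fc$df, rho_threshold = rho_threshold,
            alternative = "greater",
            class = c("coexpr_result", "data.frame"))
}
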