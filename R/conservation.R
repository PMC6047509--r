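#' Load and sanitize a strict one-to-one ortholog map
#'
#' Rows whose gene id appears more than once on either side are dropped
#' (only strict orthologs are informative for synteny conservation).
#'
#' @param map data.frame with columns `gene_id_a`, `chrom_a`, `start_a`,
#'   `end_a`, `gene_id_b`, `chrom_b`, `start_b`, `end_b`, or a path to such
#'   an 8-column TSV (BioMart-export column order).
#' @return the filtered data.frame; attribute `n_dropped`.
#' @export
ortholog_map <- function(map) {
  if (is.character(map)) {
    map <- as.data.frame(data.table::fread(map, header = TRUE))
  }
  need <- c("gene_id_a", "chrom_a", "start_a", "end_a",
            "gene_id_b", "chrom_b", "start_b", "end_b")
  if (!all(need %in% names(map))) stop("ortholog map must have columns: ",
                                       paste(need, collapse = ", "))
  dup <- duplicated(map$gene_id_a) | duplicated(map$gene_id_a, fromLast = TRUE) |
    duplicated(map$gene_id_b) | duplicated(map$gene_id_b, fromLast = TRUE)
  out <- map[!dup, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_dropped = sum(dup))
}

#' TAD synteny conservation from ortholog gene pairs
#'
#' Intra-TAD units are TADs; inter-TAD units are pairs of strictly adjacent
#' TADs (shared border). A gene pair (both genes inside one unit, one gene
#' per TAD for inter units) is conserved when both orthologs lie on one
#' chromosome of the comparison species within `max_dist` of each other
#' (midpoint distance). Scores are the percentage of units with at least
#' one conserved pair. Because intra and inter pair counts differ per
#' distance stratum, the larger pair class is subsampled to the smaller one
#' `n_subsample` times and the mean and sd over draws are reported.
#'
#' @param tads interval data.frame of TADs in species A.
#' @param map ortholog map (see [ortholog_map()]; applied on input).
#' @param max_dist conservation distance criterion in bp.
#' @param bin_edges distance-stratum edges in bp (pair midpoint distance in
#'   species A); the defaults give short/medium/long strata.
#' @param n_subsample number of subsampling draws.
#' @param seed RNG seed for the draws.
#' @return object of class `conservation_result`: data.frame with one row
#'   per stratum (`bin_lo`, `bin_hi`, `n_intra_pairs`, `n_inter_pairs`,
#'   `intra_score`, `intra_sd`, `inter_score`, `inter_sd`); strata empty in
#'   either class have NA scores.
#' @export
tad_conservation <- function(tads, map, max_dist = 1e6,
                             bin_edges = c(100e3, 235e3, 534e3, 1212e3),
                             n_subsample = 100, seed = 1) {
  map <- ortholog_map(map)
  mid_a <- (map$start_a + map$end_a) / 2
  mid_b <- (map$start_b + map$end_b) / 2
  gi <- assign_to_tads(data.frame(chrom = map$chrom_a, start = map$start_a,
                                  end = map$end_a), tads)
  # adjacency: consecutive TADs on a chromosome sharing a border
  ord <- order(tads$chrom, tads$start)
  adj <- list()
  for (k in seq_len(length(ord) - 1)) {
    a <- ord[k]; b <- ord[k + 1]
    if (tads$chrom[a] == tads$chrom[b] && tads$end[a] == tads$start[b])
      adj[[length(adj) + 1]] <- c(a, b)
  }
  pair_rows <- function(i, j) {
    data.frame(dist = abs(mid_a[i] - mid_a[j]),
               conserved = map$chrom_b[i] == map$chrom_b[j] &
                 abs(mid_b[i] - mid_b[j]) <= max_dist)
  }
  intra <- list(); intra_unit <- integer(0)
  for (t in unique(gi[!is.na(gi)])) {
    g <- which(gi == t)
    if (length(g) < 2) next
    cmb <- utils::combn(g, 2)
    intra[[length(intra) + 1]] <- pair_rows(cmb[1, ], cmb[2, ])
    intra_unit <- c(intra_unit, rep(t, ncol(cmb)))
  }
  inter <- list(); inter_unit <- integer(0)
  for (u in seq_along(adj)) {
    g1 <- which(gi == adj[[u]][1]); g2 <- which(gi == adj[[u]][2])
    if (!length(g1) || !length(g2)) next
    grid <- expand.grid(i = g1, j = g2)
    inter[[length(inter) + 1]] <- pair_rows(grid$i, grid$j)
    inter_unit <- c(inter_unit, rep(u, nrow(grid)))
  }
  intra <- if (length(intra)) do.call(rbind, intra) else data.frame(dist = numeric(0), conserved = logical(0))
  inter <- if (length(inter)) do.call(rbind, inter) else data.frame(dist = numeric(0), conserved = logical(0))

  # score = % of units with >= 1 conserved pair among the sampled pairs,
  # over units represented in the sample
  unit_score <- function(units, conserved) {
    if (!length(units)) return(NA_real_)
    100 * mean(vapply(split(conserved, units), any, logical(1)))
  }
  res <- data.frame(bin_lo = bin_edges[-length(bin_edges)],
                    bin_hi = bin_edges[-1])
  res$n_intra_pairs <- res$n_inter_pairs <- 0L
  res$intra_score <- res$intra_sd <- res$inter_score <- res$inter_sd <- NA_real_
  with_seed(seed, {
    for (b in seq_len(nrow(res))) {
      ii <- which(intra$dist >= res$bin_lo[b] & intra$dist < res$bin_hi[b])
      jj <- which(inter$dist >= res$bin_lo[b] & inter$dist < res$bin_hi[b])
      res$n_intra_pairs[b] <- length(ii); res$n_inter_pairs[b] <- length(jj)
      if (!length(ii) || !length(jj)) next  # stratum missing, reported as NA
      k <- min(length(ii), length(jj))
      draw <- function(idx, units, conserved) {
        vapply(seq_len(n_subsample), function(s) {
          sub <- if (length(idx) == k) idx else sample(idx, k)
          unit_score(units[sub], conserved[sub])
        }, numeric(1))
      }
      si <- draw(ii, intra_unit, intra$conserved)
      sj <- draw(jj, inter_unit, inter$conserved)
      res$intra_score[b] <- mean(si); res$intra_sd[b] <- stats::sd(si)
      res$inter_score[b] <- mean(sj); res$inter_sd[b] <- stats::sd(sj)
    }
  })
  structure(res, class = c("conservation_result", "data.frame"))
}
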