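#' Simulate auxiliary annotations correlated with the planted structure
#'
#' Generates every non-Hi-C input of the pipeline from a [synthetic_spec()]:
#' GC and replication-timing tracks correlated with the planted eigenvector,
#' an active-mark track, convergent CTCF-like motifs at the planted borders
#' plus uniform background motifs, a gene/TSS set, a TPM table with planted
#' housekeeping and tissue-specific genes, a sectioned (Tomo-seq-like)
#' expression matrix in which same-TAD neighbours share spatial profiles,
#' MNase-like reads phased around border motifs, an ortholog map to a
#' pseudo-species that breaks synteny only at TAD borders with probability
#' `break_prob`, histone-peak sets, OCRs and super-enhancer intervals at the
#' hub anchors.
#'
#' @param spec a `synthetic_spec`.
#' @param p_share probability that a gene adopts its TAD's spatial archetype
#'   in the sectioned expression matrix (background sharing is
#'   `1/n_archetypes`).
#' @param break_prob probability of a synteny break at each TAD border in
#'   the pseudo-species.
#' @param n_sections number of Tomo-seq-like sections.
#' @param n_samples number of RNA-seq samples in the TPM table.
#' @param n_archetypes size of the global pool of spatial profiles.
#' @param gene_spacing mean TSS-to-TSS distance (bp).
#' @return object of class `synthetic_truth`: a list with elements `spec`,
#'   `tads`, `borders`, `compartment` (100-kb `bin_track`), `ab_labels`,
#'   `gc`, `reptime`, `active` (100-kb `bin_track`s), `motifs`,
#'   `border_motifs`, `genes`, `tss`, `gene_tad`, `tpm`, `gene_class`,
#'   `tomoseq`, `mnase`, `nucleosome_truth`, `orthologs`, `k4me3`, `k27ac`,
#'   `k4me1`, `enhancers`, `ocrs`, `super_enhancers`.
#' @export
simulate_annotations <- function(spec, p_share = 0.8, break_prob = 0.2,
                                 n_sections = 40, n_samples = 8,
                                 n_archetypes = 10, gene_spacing = 8e4) {
  asm <- spec$assembly
  asm100 <- spec$assembly100
  tads <- planted_tads(spec)
  E <- spec$compartment_profile
  with_seed(spec$seed + 7777L, {
    gc <- bin_track(asm100, 0.40 + 0.05 * E + stats::rnorm(length(E), 0, 0.01))
    reptime <- bin_track(asm100, E + stats::rnorm(length(E), 0, 0.4))
    active <- bin_track(asm100, pmax(0, E) + stats::rnorm(length(E), 0, 0.05))

    # convergent motifs: forward just inside each TAD 5' end, reverse just
    # inside the 3' end; uniform background motifs with random strand
    fs <- tads$start + round(stats::runif(nrow(tads), 500, 8000))
    re <- tads$end - round(stats::runif(nrow(tads), 500, 8000))
    border_motifs <- rbind(
      intervals(chrom = tads$chrom, start = fs, end = fs + 19,
                score = stats::runif(nrow(tads), 13, 30), strand = "+"),
      intervals(chrom = tads$chrom, start = re - 19, end = re,
                score = stats::runif(nrow(tads), 13, 30), strand = "-"))
    n_bg <- round(sum(asm$chrom_lengths) / 2e5)
    bg_chrom <- sample(asm$chrom_names, n_bg, replace = TRUE,
                       prob = asm$chrom_lengths / sum(asm$chrom_lengths))
    bg_start <- floor(stats::runif(n_bg, 0, asm$chrom_lengths[bg_chrom] - 20))
    bg <- intervals(chrom = bg_chrom, start = bg_start, end = bg_start + 19,
                    score = stats::runif(n_bg, 5, 30),
                    strand = sample(c("+", "-"), n_bg, replace = TRUE))
    motifs <- rbind(border_motifs, bg)
    motifs <- motifs[order(motifs$chrom, motifs$start), ]
    rownames(motifs) <- NULL

    # genes: roughly evenly spaced TSSs with jitter, 10-kb bodies
    genes <- do.call(rbind, lapply(asm$chrom_names, function(cn) {
      len <- asm$chrom_lengths[[cn]]
      tss0 <- seq(gene_spacing / 2, len - 2 * gene_spacing, by = gene_spacing)
      tss0 <- tss0 + round(stats::runif(length(tss0), -0.2, 0.2) * gene_spacing)
      tss0 <- pmax(1000, pmin(tss0, len - 11000))
      intervals(chrom = cn, start = tss0, end = tss0 + 1e4,
                name = paste0(cn, "_g", seq_along(tss0)),
                strand = sample(c("+", "-"), length(tss0), replace = TRUE))
    }))
    rownames(genes) <- NULL
    gene_tad <- assign_to_tads(genes, tads)
    if (min(table(gene_tad)) < 2)
      stop("fewer than 2 genes in some TAD; decrease gene_spacing")
    tss <- intervals(chrom = genes$chrom,
                     start = ifelse(genes$strand == "-", genes$end - 1, genes$start),
                     end = ifelse(genes$strand == "-", genes$end, genes$start + 1),
                     name = genes$name, strand = genes$strand)

    # TPM table with planted expression-breadth classes
    ng <- nrow(genes)
    gene_class <- sample(c("housekeeping", "tissue-specific", "neither"), ng,
                         replace = TRUE)
    tpm <- t(vapply(gene_class, function(cl) {
      if (cl == "housekeeping") 50 * (1 + stats::rnorm(n_samples, 0, 0.05))
      else if (cl == "tissue-specific") {
        v <- rep(0.1, n_samples); v[sample(n_samples, 1)] <- 100; v
      } else stats::rlnorm(n_samples, 1, 1)
    }, numeric(n_samples)))
    tpm <- pmax(tpm, 0)
    dimnames(tpm) <- list(genes$name, paste0("sample", seq_len(n_samples)))

    # sectioned expression: per-TAD archetype from a global pool
    arch <- vapply(seq_len(n_archetypes), function(k)
      stats::dnorm(seq_len(n_sections), mean = stats::runif(1, 5, n_sections - 4), sd = 4),
      numeric(n_sections))
    arch <- sweep(arch, 2, apply(arch, 2, max), "/")
    tad_arch <- sample(n_archetypes, nrow(tads), replace = TRUE)
    gene_arch <- ifelse(stats::runif(ng) < p_share, tad_arch[gene_tad],
                        sample(n_archetypes, ng, replace = TRUE))
    tomoseq <- t(vapply(seq_len(ng), function(g)
      stats::rpois(n_sections, 5 + 100 * arch[, gene_arch[g]]), integer(n_sections)))
    dimnames(tomoseq) <- list(genes$name, paste0("section", seq_len(n_sections)))

    # MNase reads phased around border motifs (dyads at +-150 and +-300 bp)
    mm_mid <- round((border_motifs$start + border_motifs$end) / 2)
    centers <- unlist(lapply(mm_mid, function(p) p + c(-300, -150, 150, 300)))
    centers_chrom <- rep(border_motifs$chrom, each = 4)
    reads <- do.call(rbind, lapply(seq_along(centers), function(k) {
      nr <- stats::rpois(1, 15)
      if (nr == 0) return(NULL)
      strand <- sample(c("+", "-"), nr, replace = TRUE)
      data.frame(chrom = centers_chrom[k],
                 pos = ifelse(strand == "+", centers[k] - 73, centers[k] + 24),
                 strand = strand, length = 49L,
                 mapq = sample(15:42, nr, replace = TRUE))
    }))
    n_noise <- round(nrow(reads) * 0.3)
    noise_chrom <- sample(asm$chrom_names, n_noise, replace = TRUE)
    noise <- data.frame(chrom = noise_chrom,
                        pos = floor(stats::runif(n_noise, 100, asm$chrom_lengths[noise_chrom] - 100)),
                        strand = sample(c("+", "-"), n_noise, replace = TRUE),
                        length = 49L, mapq = sample(0:42, n_noise, replace = TRUE))
    mnase <- rbind(reads, noise)
    rownames(mnase) <- NULL

    # ortholog map: gene order preserved; synteny breaks only at TAD borders
    ord <- order(genes$chrom, genes$start)
    bchr <- 1L; cursor <- 1e5
    chrom_b <- character(ng); start_b <- numeric(ng)
    prev_chrom <- genes$chrom[ord[1]]; prev_tad <- gene_tad[ord[1]]
    for (k in ord) {
      if (genes$chrom[k] != prev_chrom ||
          (gene_tad[k] != prev_tad && stats::runif(1) < break_prob)) {
        bchr <- bchr + 1L; cursor <- 1e5
      }
      chrom_b[k] <- paste0("bchr", bchr)
      start_b[k] <- cursor
      cursor <- cursor + 3e4
      prev_chrom <- genes$chrom[k]; prev_tad <- gene_tad[k]
    }
    orth <- data.frame(gene_id_a = genes$name, chrom_a = genes$chrom,
                       start_a = genes$start, end_a = genes$end,
                       gene_id_b = paste0(genes$name, "_b"), chrom_b = chrom_b,
                       start_b = start_b, end_b = start_b + 1e4)

    # histone peaks / regulatory elements
    k4me3 <- intervals(chrom = tss$chrom, start = pmax(0, tss$start - 500),
                       end = tss$start + 500)
    near <- stats::runif(ng) < 0.7
    enh_start <- tss$start + round(stats::runif(ng, 1.5e4, 6e4))
    n_bg_enh <- round(ng * 0.2)
    bg_chrom2 <- sample(asm$chrom_names, n_bg_enh, replace = TRUE)
    bg_enh_start <- floor(stats::runif(n_bg_enh, 1e4, asm$chrom_lengths[bg_chrom2] - 1e4))
    enhancers <- rbind(
      intervals(chrom = tss$chrom[near], start = enh_start[near],
                end = enh_start[near] + 800),
      intervals(chrom = bg_chrom2, start = bg_enh_start, end = bg_enh_start + 800))
    k4me1 <- enhancers
    k27ac <- rbind(enhancers, k4me3)

    # OCRs: around border motifs (motif-containing) plus motif-free ones
    n_free <- nrow(border_motifs)
    free_chrom <- sample(asm$chrom_names, n_free, replace = TRUE)
    free_start <- floor(stats::runif(n_free, 1e4, asm$chrom_lengths[free_chrom] - 1e4))
    ocrs <- rbind(
      intervals(chrom = border_motifs$chrom,
                start = pmax(0, border_motifs$start - 200),
                end = border_motifs$end + 200),
      intervals(chrom = free_chrom, start = free_start, end = free_start + 439))

    ses <- intervals(chrom = spec$hub_anchors$chrom,
                     start = pmax(0, spec$hub_anchors$start - 1e4),
                     end = spec$hub_anchors$end + 1e4,
                     name = spec$hub_anchors$name)

    truth <- list(spec = spec, tads = tads, borders = tad_borders(tads),
                  compartment = bin_track(asm100, E),
                  ab_labels = ifelse(E > 0, "A", "B"),
                  gc = gc, reptime = reptime, active = active,
                  motifs = motifs, border_motifs = border_motifs,
                  genes = genes, tss = tss, gene_tad = gene_tad,
                  tpm = tpm, gene_class = gene_class, tomoseq = tomoseq,
                  gene_archetype = gene_arch,
                  mnase = mnase,
                  nucleosome_truth = data.frame(chrom = centers_chrom, center = centers),
                  orthologs = orth,
                  k4me3 = k4me3, k27ac = k27ac, k4me1 = k4me1,
                  enhancers = enhancers, ocrs = ocrs, super_enhancers = ses)
    class(truth) <- "synthetic_truth"
    truth
  })
}

# TAD index (row of `tads`) containing each interval's midpoint; NA if none
assign_to_tads <- function(iv, tads) {
  mid <- interval_midpoints(iv)
  out <- rep(NA_integer_, nrow(iv))
  for (k in seq_len(nrow(tads))) {
    hit <- iv$chrom == tads$chrom[k] & mid >= tads$start[k] & mid < tads$end[k]
    out[hit] <- k
  }
  out
}
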