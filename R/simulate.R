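# Synthetic Hi-C generator with planted TADs, compartments and hub anchors.
# The planted structure is materialized once, deterministically from the
# seed, inside synthetic_spec(); simulate_hic()/simulate_annotations() then
# only add sampling noise, so a stage series shares all positions.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Specification of a synthetic genome with planted chromatin structure
#'
#' Builds the complete blueprint for a simulated Hi-C experiment: a toy
#' genome, planted TAD boundaries, a blockwise A/B compartment eigenvector
#' at 100-kb resolution, and long-range hub anchor positions. Contact
#' intensity for bins i, j at separation d follows
#' `lambda = N/Z * d^(-alpha) * (1 + tau*[same TAD]) * (1 + kappa*E_i*E_j)
#' * (1 + eta*[both bins at hub anchors])`.
#' All planted positions are drawn deterministically from `seed`, so
#' matrices simulated from the same spec share their ground truth.
#'
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param bin_size matrix resolution (bp).
#' @param alpha distance-decay exponent (> 0).
#' @param tau,kappa,eta strengths of the TAD, compartment and hub terms
#'   (>= 0; `kappa > 1` would produce negative intensities and is rejected
#'   at simulation time).
#' @param depth expected total intra-chromosomal count. The default gives
#'   far-cis (>5 Mb) bin pairs an expected count near 1, comparable to
#'   deeply pooled developmental Hi-C maps and sufficient for pile-up
#'   statistics.
#' @param trans_fraction expected trans counts as a fraction of `depth`.
#' @param seed integer seed; the single source of all randomness.
#' @param tad_boundaries optional list (per chromosome) of boundary bp
#'   positions; default draws TAD sizes uniformly in 550 kb - 1.2 Mb, so
#'   every planted domain is wider than the default 500-kb insulation
#'   window.
#' @param compartment_profile optional numeric vector of eigenvector values
#'   per 100-kb genome bin in `[-1, 1]`; default is a block wave of
#'   amplitude 0.8 with block lengths 1.5 - 3 Mb.
#' @param hub_anchors optional interval data.frame of anchor points;
#'   default plants 6 anchors per chromosome.
#' @param hub_halfwidth bp around an anchor within which bins get the hub
#'   intensity boost.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(chrom_lengths = c(chr1 = 20e6, chr2 = 20e6),
                           bin_size = 20e3, alpha = 1,
                           tau = 1, kappa = 1, eta = 1,
                           depth = 2e7, trans_fraction = 0.2, seed = 1,
                           tad_boundaries = NULL, compartment_profile = NULL,
                           hub_anchors = NULL, hub_halfwidth = bin_size) {
  stopifnot(alpha > 0, tau >= 0, kappa >= 0, eta >= 0, depth > 0)
  asm <- genome_assembly(chrom_lengths, bin_size)
  asm100 <- genome_assembly(chrom_lengths, 1e5)
  with_seed(seed, {
    if (is.null(tad_boundaries)) {
      # boundaries on 100-kb multiples so compartment blocks (100-kb bins)
      # can switch exactly at domain borders, as they do in real genomes
      tad_boundaries <- lapply(stats::setNames(asm$chrom_names, asm$chrom_names), function(cn) {
        len <- asm$chrom_lengths[[cn]]
        pos <- c(); cur <- 0
        repeat {
          cur <- cur + stats::runif(1, 5.5e5, 1.2e6)
          if (cur > len - 1e6) break
          snap <- if (1e5 %% bin_size == 0) 1e5 else bin_size
          pos <- c(pos, round(cur / snap) * snap)
        }
        pos
      })
    }
    if (is.null(compartment_profile)) {
      # sign per TAD, flipped between consecutive TADs with probability 0.4
      # (compartment switches coincide with a subset of domain borders)
      compartment_profile <- unlist(lapply(asm$chrom_names, function(cn) {
        edges <- c(0, tad_boundaries[[cn]], asm$chrom_lengths[[cn]])
        sgn <- numeric(length(edges) - 1)
        sgn[1] <- sample(c(-0.8, 0.8), 1)
        for (k in seq_along(sgn)[-1])
          sgn[k] <- if (stats::runif(1) < 0.4) -sgn[k - 1] else sgn[k - 1]
        n100 <- asm100$n_bins_chrom[[cn]]
        mids <- (seq_len(n100) - 0.5) * 1e5
        sgn[findInterval(pmin(mids, asm$chrom_lengths[[cn]] - 1), edges)]
      }))
    }
    if (is.null(hub_anchors)) {
      # anchors live in the active (E > 0) compartment, like super-enhancers
      hub_anchors <- do.call(rbind, lapply(asm$chrom_names, function(cn) {
        len <- asm$chrom_lengths[[cn]]
        e100 <- compartment_profile[chrom_bins(asm100, cn)]
        # majority compartment of the chromosome (anchor pairs share sign)
        s <- if (sum(e100 > 0) >= sum(e100 < 0)) 1 else -1
        a_mid <- (which(e100 * s > 0) - 0.5) * 1e5
        centers <- seq(0.06 * len, 0.94 * len, length.out = 6) +
          stats::runif(6, -2e5, 2e5)
        centers <- vapply(centers, function(x) a_mid[which.min(abs(a_mid - x))],
                          numeric(1))
        centers <- floor(centers / bin_size) * bin_size + bin_size / 2
        intervals(chrom = cn, start = centers - bin_size / 2,
                  end = centers + bin_size / 2,
                  name = paste0(cn, "_hub", seq_along(centers)))
      }))
    }
  })
  if (any(abs(compartment_profile) > 1)) stop("compartment profile must lie in [-1, 1]")
  spec <- list(assembly = asm, assembly100 = asm100,
               alpha = alpha, tau = tau, kappa = kappa, eta = eta,
               depth = depth, trans_fraction = trans_fraction, seed = as.integer(seed),
               tad_boundaries = tad_boundaries,
               compartment_profile = as.numeric(compartment_profile),
               hub_anchors = hub_anchors, hub_halfwidth = hub_halfwidth)
  class(spec) <- "synthetic_spec"
  spec
}

#' Planted TADs of a synthetic spec
#' @param spec a `synthetic_spec`.
#' @return interval data.frame partitioning each chromosome at the planted
#'   boundaries.
#' @export
planted_tads <- function(spec) {
  do.call(rbind, lapply(spec$assembly$chrom_names, function(cn) {
    b <- spec$tad_boundaries[[cn]]
    edges <- c(0, b, spec$assembly$chrom_lengths[[cn]])
    intervals(chrom = cn, start = edges[-length(edges)], end = edges[-1],
              name = paste0(cn, "_tad", seq_len(length(edges) - 1)))
  }))
}

# planted eigenvector interpolated to the matrix resolution (nearest 100-kb bin)
e_at_matrix_bins <- function(spec) {
  bt <- bin_table(spec$assembly)
  mid <- pmin((bt$start + bt$end) / 2, spec$assembly$chrom_lengths[match(bt$chrom, spec$assembly$chrom_names)] - 1)
  spec$compartment_profile[bin_of(spec$assembly100, bt$chrom, mid)]
}

# per-bin TAD id (0 between no boundaries never happens: TADs partition the chromosome)
tad_id_per_bin <- function(spec) {
  bt <- bin_table(spec$assembly)
  out <- integer(nrow(bt)); base <- 0L
  for (cn in spec$assembly$chrom_names) {
    idx <- chrom_bins(spec$assembly, cn)
    out[idx] <- base + findInterval(bt$start[idx], c(0, spec$tad_boundaries[[cn]]))
    base <- max(out[idx])
  }
  out
}

hub_bin_flags <- function(spec) {
  bt <- bin_table(spec$assembly)
  flags <- rep(FALSE, nrow(bt))
  ctr <- (bt$start + bt$end) / 2
  for (r in seq_len(nrow(spec$hub_anchors))) {
    a <- spec$hub_anchors[r, ]
    am <- (a$start + a$end) / 2
    flags <- flags | (bt$chrom == a$chrom & abs(ctr - am) <= spec$hub_halfwidth)
  }
  flags
}

#' Simulate a Hi-C contact matrix from a synthetic spec
#'
#' Poisson counts around the planted intensity (see [synthetic_spec()]);
#' trans blocks receive a uniform rate with the hub boost applied to
#' anchor-anchor bin pairs. Output is exactly symmetric.
#'
#' @param spec a `synthetic_spec`.
#' @param seed optional override of `spec$seed` for the sampling noise
#'   (planted positions are unaffected).
#' @return a `contact_matrix`.
#' @export
simulate_hic <- function(spec, seed = spec$seed) {
  asm <- spec$assembly
  E <- e_at_matrix_bins(spec)
  tid <- tad_id_per_bin(spec)
  hub <- hub_bin_flags(spec)
  nb <- n_bins(asm)
  counts <- matrix(0, nb, nb)
  with_seed(seed, {
    # cis blocks: normalize so expected cis total is spec$depth
    mus <- list()
    for (cn in asm$chrom_names) {
      idx <- chrom_bins(asm, cn)
      n <- length(idx)
      d <- abs(outer(seq_len(n), seq_len(n), "-"))
      base <- ifelse(d == 0, 2, d^(-spec$alpha))
      mu <- base *
        (1 + spec$tau * outer(tid[idx], tid[idx], "==")) *
        (1 + spec$kappa * outer(E[idx], E[idx])) *
        (1 + spec$eta * outer(hub[idx], hub[idx], "&"))
      if (any(mu < 0)) stop("negative contact intensity; kappa too large for the planted eigenvector")
      mus[[cn]] <- mu
    }
    z <- sum(vapply(mus, function(m) sum(m[upper.tri(m, diag = TRUE)]), numeric(1)))
    for (cn in asm$chrom_names) {
      idx <- chrom_bins(asm, cn)
      lam <- mus[[cn]] * spec$depth / z
      n <- length(idx)
      ut <- upper.tri(lam, diag = TRUE)
      cc <- matrix(0, n, n)
      cc[ut] <- stats::rpois(sum(ut), lam[ut])
      cc <- cc + t(cc) - diag(diag(cc))
      counts[idx, idx] <- cc
    }
    # trans blocks: uniform rate + hub boost
    if (length(asm$chrom_names) > 1 && spec$trans_fraction > 0) {
      pairs <- utils::combn(asm$chrom_names, 2, simplify = FALSE)
      npair_bins <- sum(vapply(pairs, function(p)
        asm$n_bins_chrom[[p[1]]] * asm$n_bins_chrom[[p[2]]], numeric(1)))
      lam0 <- spec$depth * spec$trans_fraction / npair_bins
      for (p in pairs) {
        i1 <- chrom_bins(asm, p[1]); i2 <- chrom_bins(asm, p[2])
        lam <- lam0 * (1 + spec$eta * outer(hub[i1], hub[i2], "&"))
        blk <- matrix(stats::rpois(length(lam), lam), nrow = length(i1))
        counts[i1, i2] <- blk
        counts[i2, i1] <- t(blk)
      }
    }
  })
  contact_matrix(asm, counts)
}

#' Simulate a developmental stage series of contact matrices
#'
#' All stages share the planted boundaries, eigenvector and anchors; only
#' the structural strengths (and the Poisson noise stream) differ. The
#' canonical four-stage series mimicking a pre-ZGA / post-ZGA /
#' gastrulation / 24-hpf progression is strong / absent / weak / strong.
#'
#' @param spec a `synthetic_spec` (its tau/kappa/eta act as stage-1 baseline).
#' @param stages list of length-3 numeric vectors `(tau_mult, kappa_mult,
#'   eta_mult)` applied to the spec's strengths.
#' @return named list of `contact_matrix` objects (`stage1`, `stage2`, ...).
#' @export
stage_series <- function(spec, stages) {
  if (length(stages) < 2) stop("need at least 2 stages")
  out <- lapply(seq_along(stages), function(s) {
    mult <- stages[[s]]
    stopifnot(length(mult) == 3)
    sp <- spec
    sp$tau <- spec$tau * mult[1]; sp$kappa <- spec$kappa * mult[2]; sp$eta <- spec$eta * mult[3]
    simulate_hic(sp, seed = spec$seed + s - 1L)
  })
  names(out) <- paste0("stage", seq_along(stages))
  out
}
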