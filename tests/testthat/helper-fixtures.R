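# Shared fixtures. Expensive simulations are memoized so several test files
# can reuse them within one test run.

single_chrom_asm <- function(n, bs = 1e4) {
  genome_assembly(c(chrA = n * bs), bs)
}

# contact matrix on one chromosome from an explicit symmetric count matrix
cm_from_counts <- function(counts, bs = 1e4) {
  contact_matrix(single_chrom_asm(nrow(counts), bs), counts)
}

# random symmetric nonnegative matrix with strictly positive coverage
random_sym_counts <- function(n, seed) {
  set.seed(seed)
  x <- matrix(rpois(n * n, 5) + 1, n, n)
  x[lower.tri(x)] <- t(x)[lower.tri(x)]
  x
}

# small planted genome for module tests: 2 x 8 Mb at 20 kb
mini_spec <- function(seed = 1, ...) {
  synthetic_spec(chrom_lengths = c(chr1 = 8e6, chr2 = 8e6), depth = 1.2e6,
                 seed = seed, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

mini_truth <- function() cached("mini_truth", simulate_annotations(mini_spec(seed = 11)))
mini_matrix <- function() cached("mini_matrix", simulate_hic(mini_spec(seed = 11)))

# brute-force insulation oracle: explicit double loop over the w x w square,
# skipping dead bins
brute_insulation_raw <- function(counts, w, dead = rep(FALSE, nrow(counts))) {
  n <- nrow(counts)
  raw <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - w < 1 || i + w > n || dead[i]) next
    s <- 0; np <- 0L
    for (x in (i - w):(i - 1)) for (y in (i + 1):(i + w)) {
      if (dead[x] || dead[y]) next
      s <- s + counts[x, y]; np <- np + 1L
    }
    if (np > 0) raw[i] <- s / np
  }
  raw
}

# fraction of planted borders with a called border within +-1 bin
border_recovery <- function(spec, borders, tol_bins = 1.5) {
  planted <- unlist(spec$tad_boundaries)
  chroms <- rep(names(spec$tad_boundaries), lengths(spec$tad_boundaries))
  hit <- mapply(function(cn, p) {
    any(borders$chrom == cn &
          abs(borders$pos - p) <= tol_bins * spec$assembly$bin_size)
  }, chroms, planted)
  mean(hit)
}

# uniformly placed anchor intervals for null pile-ups
random_anchors <- function(asm, n_per_chrom, seed) {
  set.seed(seed)
  do.call(rbind, lapply(asm$chrom_names, function(cn) {
    p <- sort(runif(n_per_chrom, 1e6, asm$chrom_lengths[[cn]] - 2e6))
    intervals(chrom = cn, start = p, end = p + 100)
  }))
}

# i.i.d.-gene sectioned-expression null for the co-expression statistic:
# sparse TADs keep the same-TAD pair fraction low so the plug-in null
# probability is close to independent of the tested counts
coexpr_null_p <- function(seed, ng = 1000, ns = 8, span = 12, every = 100) {
  set.seed(seed)
  coords <- intervals(chrom = "chr1", start = (1:ng) * 1e4,
                      end = (1:ng) * 1e4 + 5e3, name = paste0("g", 1:ng))
  st <- seq(0, ng - every, by = every)
  tads <- intervals(chrom = "chr1", start = st * 1e4 + 5e3,
                    end = (st + span) * 1e4 + 5e3)
  expr <- matrix(rnorm(ng * ns), ng, dimnames = list(coords$name, NULL))
  attr(coexpression_stratified(expr, coords, tads, rho_threshold = 0.4,
                               dmax = 3), "combined_p")
}
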