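test_that("uniform matrices have identically zero normalized insulation", {
  m <- cm_from_counts(matrix(4, 40, 40))
  ins <- insulation_score(m, w = 5)
  v <- ins$normalized[!is.na(ins$normalized)]
  expect_equal(v, rep(0, length(v)))
  # masked margins: w bins at each end
  expect_true(all(is.na(ins$normalized[c(1:5, 36:40)])))
})

test_that("insulation equals the brute-force window mean, also next to dead bins", {
  cnt <- random_sym_counts(60, 7)
  cnt[23, ] <- cnt[, 23] <- 0  # dead bin
  m <- cm_from_counts(cnt)
  w <- 6
  ins <- insulation_score(m, w = w)
  brute <- brute_insulation_raw(cnt, w, dead = dead_bins(m))
  expect_equal(ins$raw, brute)
  expect_true(is.na(ins$raw[23]))
  # normalization: mean of 2^normalized equals raw/chrom-mean by construction
  ok <- !is.na(ins$raw)
  expect_equal(ins$normalized[ok], log2(ins$raw[ok] / mean(ins$raw[ok])))
})

test_that("a short chromosome is masked with a warning", {
  asm <- genome_assembly(c(tiny = 5e4, big = 6e5), 1e4)
  cnt <- random_sym_counts(65, 1)
  m <- contact_matrix(asm, cnt)
  expect_warning(ins <- insulation_score(m, w = 5), "tiny")
  expect_true(all(is.na(ins$raw[1:5])))
  expect_false(all(is.na(ins$raw[6:65])))
})

test_that("a single planted border is the insulation minimum", {
  spec <- synthetic_spec(chrom_lengths = c(chr1 = 6e6), bin_size = 2e4,
                         tad_boundaries = list(chr1 = 3e6), tau = 2,
                         kappa = 0, eta = 0, depth = 2e6, trans_fraction = 0,
                         seed = 8)
  ins <- insulation_score(simulate_hic(spec), w = 25)
  k <- which.min(ins$normalized)
  expect_lte(abs((ins$start[k] + ins$end[k]) / 2 - 3e6), 1.5 * 2e4)
})

test_that("border calling rejects monotone profiles and suppresses close minima", {
  asm <- single_chrom_asm(50)
  prof <- structure(
    data.frame(chrom = "chrA", start = (0:49) * 1e4, end = (1:50) * 1e4,
               raw = NA, normalized = seq(-2, 2, length.out = 50)),
    assembly = asm, w = 5, class = c("insulation_profile", "data.frame"))
  expect_equal(nrow(call_borders(prof, 0)), 0)
  # two minima 3 bins apart (< w): only the deeper survives
  s <- rep(0, 50)
  s[20] <- -1; s[23] <- -0.6
  prof$normalized <- s
  bd <- call_borders(prof, 0.05)
  expect_equal(nrow(bd), 1)
  expect_equal(bd$pos, 19.5 * 1e4)  # bin-20 midpoint
  expect_gt(bd$strength, 0.5)
})

test_that("most planted borders are recovered at default strength", {
  spec <- mini_spec(seed = 11)
  m <- mini_matrix()
  bd <- call_borders(insulation_score(m, 25), 0.1)
  expect_gte(border_recovery(spec, bd), 0.8)
})

test_that("border filtering drops uncovered bins, never adds, and is idempotent", {
  cnt <- random_sym_counts(30, 3)
  cnt[15, ] <- cnt[, 15] <- 0
  m <- cm_from_counts(cnt)
  bd <- border_set(chrom = rep("chrA", 3), pos = c(5.5e4, 14.5e4, 25.5e4),
                   strength = c(1, 2, 3))
  f <- filter_borders(bd, m)
  expect_equal(nrow(f), 2)
  expect_equal(attr(f, "n_removed"), 1L)
  expect_equal(f$pos, c(5.5e4, 25.5e4))
  # no dead bins: identity
  m2 <- cm_from_counts(random_sym_counts(30, 4))
  f2 <- filter_borders(bd, m2)
  expect_equal(f2$pos, bd$pos)
  # idempotence and monotonicity
  expect_equal(filter_borders(f, m)$pos, f$pos)
  expect_lte(nrow(f), nrow(bd))
  # all borders dead -> empty set with a warning
  cnt3 <- matrix(0, 30, 30); cnt3[1, 1] <- 5
  m3 <- cm_from_counts(cnt3)
  expect_warning(f3 <- filter_borders(bd, m3), "all borders")
  expect_equal(nrow(f3), 0)
})

test_that("aggregate TAD analysis is exact on uniform input and identity windows", {
  m <- cm_from_counts(matrix(6, 80, 80))
  tads <- intervals("chrA", 20e4, 40e4)  # 20-bin TAD, 40-bin window
  a <- aggregate_tads(m, tads, out_dim = 40)
  expect_equal(a$strength, 1, tolerance = 1e-9)
  expect_equal(unname(a$matrix), matrix(1, 40, 40), tolerance = 1e-9)
  # window exactly out_dim bins: resize is the identity
  oe <- observed_over_expected(m)
  idx <- 11:50  # [start - L/2, end + L/2) for the 20-bin TAD
  expect_equal(unname(a$matrix), unname(oe[idx, idx]), tolerance = 1e-9)
  # TAD whose window exits the chromosome is unusable
  expect_error(aggregate_tads(m, intervals("chrA", 0, 20e4)), "no usable")
})

test_that("ATA strength is scale-invariant and increases with planted TAD strength", {
  tads <- NULL
  strengths <- vapply(c(0, 0.5, 1), function(tau) {
    sp <- synthetic_spec(chrom_lengths = c(chr1 = 8e6), tau = tau, kappa = 0,
                         eta = 0, depth = 1e6, trans_fraction = 0, seed = 21)
    if (is.null(tads)) tads <<- planted_tads(sp)
    aggregate_tads(simulate_hic(sp, seed = 21 + tau * 10), tads)$strength
  }, numeric(1))
  expect_true(all(diff(strengths) > 0))
  expect_equal(strengths[1], 1, tolerance = 0.1)
  # uniform count scaling leaves the O/E-based strength unchanged
  m <- cm_from_counts(random_sym_counts(80, 5))
  t1 <- intervals("chrA", 20e4, 40e4)
  a1 <- aggregate_tads(m, t1, out_dim = 40)
  m5 <- contact_matrix(m$assembly, m$counts * 5)
  a5 <- aggregate_tads(m5, t1, out_dim = 40)
  expect_equal(a5$strength, a1$strength, tolerance = 1e-12)
})

test_that("track alignment on borders recovers impulses and honours orientation", {
  asm <- single_chrom_asm(200, bs = 1e4)
  bd <- border_set(chrom = rep("chrA", 2), pos = c(60e4, 140e4))
  # constant track, no z-scoring: flat curve at the constant
  const <- bin_track(asm, rep(3, 200))
  al <- align_track_on_borders(const, bd, upstream = 2e5, downstream = 2e5,
                               step = 1e4)
  expect_equal(unname(al$mean), rep(3, 40))
  expect_error(align_track_on_borders(const, bd, zscore = TRUE), "variance")
  # impulse at each border peaks at offset zero
  v <- rep(0, 200); v[c(61, 141)] <- 10  # bins containing the border bp
  imp <- bin_track(asm, v)
  al2 <- align_track_on_borders(imp, bd, upstream = 2e5, downstream = 2e5,
                                step = 1e4)
  expect_equal(which.max(al2$mean), which(al2$offsets > 0)[1])
  # a 3' border mirrors the window
  bd3 <- border_set("chrA", 140e4, side = "3p")
  v3 <- rep(0, 200); v3[139] <- 7  # impulse 2 bins before the 3' border
  al3 <- align_track_on_borders(bin_track(asm, v3), bd3, upstream = 5e4,
                                downstream = 5e4, step = 1e4)
  # into-the-TAD side must appear at positive offsets after mirroring
  expect_gt(sum(al3$mean[al3$offsets > 0]), sum(al3$mean[al3$offsets < 0]))
  # truncated windows are dropped
  bd_edge <- border_set("chrA", 5e4)
  expect_error(align_track_on_borders(const, bd_edge, upstream = 2e5,
                                      downstream = 2e5), "complete windows")
})

test_that("borders_to_tads partitions chromosomes and respects the size floor", {
  asm <- single_chrom_asm(100, bs = 1e4)
  bd <- border_set(chrom = rep("chrA", 2), pos = c(30e4, 31.5e4))
  tads <- borders_to_tads(bd, asm, min_bins = 3)
  # the 1.5-bin middle segment is dropped
  expect_equal(nrow(tads), 2)
  expect_equal(tads$start, c(0, 32e4))
  expect_equal(tads$end, c(30e4, 100e4))
})
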