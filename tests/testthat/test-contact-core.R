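test_that("bin/coordinate mapping is a bijection under 0-based half-open convention", {
  asm <- genome_assembly(c(chr1 = 95e3, chr2 = 40e3), 1e4)
  expect_equal(asm$n_bins_chrom, c(chr1 = 10L, chr2 = 4L))
  bt <- bin_table(asm)
  expect_equal(nrow(bt), 14)
  expect_equal(bt$end[10], 95e3)  # last bin clipped to chromosome length
  # every bin start maps back to its own bin
  expect_equal(bin_of(asm, bt$chrom, bt$start), bt$bin)
  expect_equal(bin_of(asm, "chr2", 39999), 14L)
  expect_error(bin_of(asm, "chr2", 40000), "outside")
  expect_error(bin_of(asm, "chrX", 0), "unknown")
  expect_error(genome_assembly(c(a = 0), 10), "> 0")
})

test_that("contact_matrix validates symmetry, sign and dead-bin bookkeeping", {
  cnt <- random_sym_counts(6, 1)
  m <- cm_from_counts(cnt)
  expect_false(any(dead_bins(m)))
  cnt2 <- cnt; cnt2[3, ] <- cnt2[, 3] <- 0
  m2 <- cm_from_counts(cnt2)
  expect_equal(which(dead_bins(m2)), 3L)
  bad <- cnt; bad[1, 2] <- bad[1, 2] + 5
  expect_error(cm_from_counts(bad), "symmetric")
  neg <- cnt; neg[1, 2] <- neg[2, 1] <- -1
  expect_error(cm_from_counts(neg), "nonnegative")
})

test_that("observed/expected equals hand-computed diagonal means", {
  # constant diagonals: the matrix is its own expected value
  n <- 8
  cnt <- outer(1:n, 1:n, function(i, j) 10 - abs(i - j))
  oe <- observed_over_expected(cm_from_counts(cnt))
  expect_equal(unname(oe[!is.na(oe)]), rep(1, sum(!is.na(oe))))
  # 4x4 with one elevated first-diagonal entry
  cnt <- matrix(1, 4, 4)
  cnt[1, 2] <- cnt[2, 1] <- 4
  cnt[2, 3] <- cnt[3, 2] <- 2
  cnt[3, 4] <- cnt[4, 3] <- 2
  oe <- observed_over_expected(cm_from_counts(cnt))
  expect_equal(oe[1, 2], 4 / ((4 + 2 + 2) / 3))
  expect_equal(oe[2, 3], 2 / (8 / 3))
})

test_that("dead bins are excluded from expected values and masked in the output", {
  cnt <- random_sym_counts(10, 2)
  dead <- cnt
  dead[4, ] <- dead[, 4] <- 0
  oe_dead <- observed_over_expected(cm_from_counts(dead))
  expect_true(all(is.na(oe_dead[4, ])))
  # expected at distance d must average only pairs avoiding bin 4
  d <- 2
  i <- setdiff(1:8, c(4, 4 - d))
  exp_d <- mean(dead[cbind(i, i + d)])
  expect_equal(oe_dead[1, 3], dead[1, 3] / exp_d)
  # an all-dead chromosome is a hard error naming the chromosome
  asm <- genome_assembly(c(ok = 3e4, gone = 3e4), 1e4)
  cnt2 <- matrix(0, 6, 6); cnt2[1:3, 1:3] <- random_sym_counts(3, 3)
  expect_error(observed_over_expected(contact_matrix(asm, cnt2)), "gone")
})

test_that("observed/expected is idempotent on valid entries", {
  for (seed in 1:5) {
    m <- cm_from_counts(random_sym_counts(12, seed))
    oe1 <- observed_over_expected(m)
    m2 <- contact_matrix(m$assembly, ifelse(is.na(oe1), 0, oe1))
    oe2 <- observed_over_expected(m2)
    ok <- !is.na(oe1) & !is.na(oe2)
    expect_equal(oe2[ok], oe1[ok], tolerance = 1e-12)
  }
})

test_that("correlation matrix matches a direct Pearson oracle and masks degenerate rows", {
  x <- rbind(c(1, 2, 3), c(2, 4, 6), c(3, 2, 1))
  cc <- correlation_matrix(x)
  expect_equal(cc[1, 2], cor(x[1, ], x[2, ]))
  expect_equal(cc[1, 3], cor(x[1, ], x[3, ]))
  expect_equal(diag(cc), rep(1, 3))
  # identical rows correlate at 1, a negated row at -1
  y <- rbind(c(1, 5, 2, 7), c(1, 5, 2, 7), -c(1, 5, 2, 7), c(2, 1, 9, 3))
  cy <- correlation_matrix(y)
  expect_equal(cy[1, 2], 1)
  expect_equal(cy[1, 3], -1)
  # zero-variance row is masked, not NaN-propagated
  z <- rbind(c(1, 1, 1, 1), c(1, 5, 2, 7), c(2, 1, 9, 3), c(5, 2, 2, 8))
  cz <- correlation_matrix(z)
  expect_true(all(is.na(cz[1, ])))
  expect_false(anyNA(cz[2:4, 2:4]))
})

test_that("correlation matrix is symmetric with unit diagonal on random inputs", {
  for (seed in 1:10) {
    set.seed(seed)
    x <- matrix(rnorm(15 * 15), 15, 15)
    cc <- correlation_matrix(x)
    expect_equal(cc, t(cc))
    expect_equal(diag(cc), rep(1, 15))
    expect_true(all(abs(cc) <= 1 + 1e-12))
  }
})

test_that("relative contact frequency matches brute-force pair enumeration", {
  m <- cm_from_counts(matrix(7, 30, 30), bs = 1e4)
  rcf <- relative_contact_frequency(m, n_bins = 12)
  expect_equal(sum(rcf$fraction), 100, tolerance = 1e-9)
  # uniform counts: fraction per bin proportional to the number of bin pairs
  # whose separation lands in the bin
  edges <- rcf$left; edges <- c(edges, rcf$right[12])
  brute <- numeric(12)
  for (i in 1:29) for (j in (i + 1):30) {
    d <- (j - i) * 1e4
    k <- min(max(findInterval(d, edges, rightmost.closed = TRUE), 1), 12)
    brute[k] <- brute[k] + 1
  }
  expect_equal(rcf$fraction, brute / sum(brute) * 100, tolerance = 1e-9)
  # scaling invariance
  rcf5 <- relative_contact_frequency(cm_from_counts(matrix(35, 30, 30), bs = 1e4), 12)
  expect_equal(rcf5$fraction, rcf$fraction, tolerance = 1e-12)
})

test_that("contacts at one-bin separation land entirely in the first distance bin", {
  cnt <- matrix(0, 20, 20)
  cnt[cbind(1:19, 2:20)] <- 3; cnt[cbind(2:20, 1:19)] <- 3
  diag(cnt) <- 1  # keep bins covered
  rcf <- relative_contact_frequency(cm_from_counts(cnt), n_bins = 10)
  expect_equal(rcf$fraction[1], 100)
  expect_error(relative_contact_frequency(cm_from_counts(diag(20) * 1)), "off the diagonal")
})

test_that("viewpoint profiles split flank and TAD-body signal correctly", {
  tad <- intervals("chr1", 1e6, 1.3e6)
  pos <- seq(1e6, 1.3e6 - 1, by = 100)  # uniform signal over the TAD
  prof <- data.frame(pos = pos, signal = 1)
  vp <- 1.15e6
  q <- quantify_viewpoint_profile(prof, tad, vp)
  expect_equal(unname(q["flank_fraction"]), 30e3 / 300e3, tolerance = 1e-6)
  expect_equal(sum(q), 1)
  # all signal inside the flank
  prof2 <- data.frame(pos = vp + seq(-14e3, 14e3, by = 1e3), signal = 2)
  expect_equal(unname(quantify_viewpoint_profile(prof2, tad, vp)["flank_fraction"]), 1)
  # signal entirely outside the TAD is an error
  prof3 <- data.frame(pos = c(5e5, 2e6), signal = 1)
  expect_error(quantify_viewpoint_profile(prof3, tad, vp), "no signal")
  expect_error(quantify_viewpoint_profile(prof, tad, 5e5), "inside")
  w <- compare_viewpoint_profiles(c(0.2, 0.3, 0.25), c(0.5, 0.65, 0.58))
  expect_s3_class(w, "htest")
})

test_that("rebinning sums counts and masks sparsely covered coarse bins", {
  cnt <- random_sym_counts(10, 4)
  m <- cm_from_counts(cnt, bs = 1e4)
  m2 <- rebin(m, 2e4)
  expect_equal(n_bins(m2$assembly), 5)
  expect_equal(sum(m2$counts), sum(cnt))
  expect_equal(m2$counts[1, 1], sum(cnt[1:2, 1:2]))
  expect_equal(m2$counts[1, 3], sum(cnt[1:2, 5:6]))
  # a coarse bin with under half its fine bins live is masked
  cnt3 <- cnt; cnt3[1, ] <- cnt3[, 1] <- 0; cnt3[2, ] <- cnt3[, 2] <- 0
  m3 <- rebin(cm_from_counts(cnt3, bs = 1e4), 2e4)
  expect_true(dead_bins(m3)[1])
  expect_error(rebin(m, 2.5e4), "multiple")
})

test_that("dense-text matrix, BED and bedGraph round-trips preserve content", {
  m <- cm_from_counts(random_sym_counts(8, 5), bs = 1e4)
  f <- tempfile(fileext = ".matrix")
  write_contact_matrix(m, f)
  m2 <- read_contact_matrix(f)
  expect_equal(m2$counts, m$counts)
  expect_equal(m2$assembly$chrom_lengths, m$assembly$chrom_lengths)

  iv <- intervals(chrom = c("chrA", "chrA"), start = c(100, 5000),
                  end = c(400, 5400), name = c("x", "y"),
                  score = c(1, 2), strand = c("+", "-"))
  fb <- tempfile(fileext = ".bed")
  write_bed(iv, fb)
  iv2 <- read_bed(fb)
  expect_equal(iv2$start, iv$start)
  expect_equal(iv2$end, iv$end)
  expect_equal(iv2$strand, iv$strand)

  tr <- bin_track(single_chrom_asm(8), c(1.5, NA, 3, 4, -1, 0, 2, 8))
  fg <- tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, fg)
  tr2 <- read_bedgraph(fg, tr$assembly)
  expect_equal(tr2$values, tr$values)
})
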