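test_that("motif orientation bins count from the border into the TAD", {
  bd <- border_set("chr1", 1e6, side = "5p")
  mot <- intervals("chr1", 1e6 + 5e3, 1e6 + 5e3 + 19, strand = "+")
  p <- motif_orientation_profile(mot, bd)
  expect_equal(p$forward[p$side == "5p" & p$bin == 1], 1)
  expect_equal(sum(p$forward) + sum(p$reverse), 1)
  # a motif upstream of a 5' border is outside the profile
  out <- intervals("chr1", 1e6 - 5e3, 1e6 - 5e3 + 19, strand = "+")
  p2 <- motif_orientation_profile(out, bd)
  expect_equal(sum(p2$forward) + sum(p2$reverse), 0)
  # 3' border: bins extend leftward, strands are swapped
  bd3 <- border_set("chr1", 2e6, side = "3p")
  rev_in <- intervals("chr1", 2e6 - 15e3, 2e6 - 15e3 + 19, strand = "-")
  p3 <- motif_orientation_profile(rev_in, bd3)
  expect_equal(p3$forward[p3$side == "3p" & p3$bin == 2], 1)
  expect_equal(sum(p3$reverse), 0)
})

test_that("planted convergent motifs give a forward excess at the border bin", {
  tr <- mini_truth()
  p <- motif_orientation_profile(tr$motifs, tr$borders, min_score = 12)
  comb <- attr(p, "combined")
  expect_gt(comb$forward[comb$bin == 1], 2 * comb$reverse[comb$bin == 1])
  # totals match a brute-force midpoint intersection count
  hi <- tr$motifs[tr$motifs$score > 12, ]
  mid <- (hi$start + hi$end) / 2
  brute <- 0L
  for (r in seq_len(nrow(tr$borders))) {
    b <- tr$borders[r, ]
    off <- if (b$side == "5p") mid - b$pos else b$pos - mid
    brute <- brute + sum(hi$chrom == b$chrom & off >= 0 & off < 1e5)
  }
  expect_equal(sum(comb$forward) + sum(comb$reverse), brute)
})

test_that("uniformly shuffled motifs show balanced orientations", {
  tr <- mini_truth()
  set.seed(99)
  asm <- tr$spec$assembly
  n <- 2000
  cn <- sample(asm$chrom_names, n, replace = TRUE)
  st <- floor(runif(n, 0, asm$chrom_lengths[cn] - 20))
  shuf <- intervals(chrom = cn, start = st, end = st + 19,
                    strand = sample(c("+", "-"), n, replace = TRUE))
  p <- motif_orientation_profile(shuf, tr$borders)
  comb <- attr(p, "combined")
  bt <- binom.test(sum(comb$forward), sum(comb$forward) + sum(comb$reverse))
  expect_gt(bt$p.value, 0.01)
})

test_that("OCR motif enrichment matches hand counts on a toy input", {
  asm <- genome_assembly(c(chr1 = 1e6), 1e4)
  ocrs <- intervals(chrom = rep("chr1", 4),
                    start = c(1e4, 11e4, 21e4, 31e4),
                    end = c(1.1e4, 11.1e4, 21.1e4, 31.1e4))
  # motifs in OCRs 1 and 2; one extra motif where shifted OCR 3 will land
  motifs <- intervals(chrom = rep("chr1", 3),
                      start = c(1.02e4, 11.02e4, 21.05e4 + 5e3),
                      end = c(1.04e4, 11.04e4, 21.07e4 + 5e3),
                      strand = c("+", "-", "+"))
  r <- ocr_motif_enrichment(ocrs, motifs, asm, shift = 5e3)
  expect_equal(unname(r["fraction_observed"]), 0.5)
  expect_equal(unname(r["fraction_shifted"]), 0.25)
  expect_equal(unname(r["ratio"]), 2)
  expect_error(ocr_motif_enrichment(ocrs[0, ], motifs, asm), "empty")
})

test_that("uniform motifs give an OCR enrichment ratio near 1", {
  tr <- mini_truth()
  set.seed(7)
  asm <- tr$spec$assembly
  n <- 5000
  cn <- sample(asm$chrom_names, n, replace = TRUE)
  st <- floor(runif(n, 0, asm$chrom_lengths[cn] - 20))
  uni <- intervals(chrom = cn, start = st, end = st + 19)
  r <- ocr_motif_enrichment(tr$ocrs, uni, asm)
  expect_gt(unname(r["ratio"]), 0.7)
  expect_lt(unname(r["ratio"]), 1.4)
})

test_that("nucleosome centers follow the footprint arithmetic", {
  asm <- genome_assembly(c(chr1 = 1e4, tiny = 50), 10)
  reads <- data.frame(chrom = c("chr1", "chr1", "tiny", "chr1"),
                      pos = c(100, 100, 0, 500),
                      strand = c("+", "-", "+", "+"),
                      length = c(49L, 49L, 30L, 49L),
                      mapq = c(30L, 30L, 30L, 5L))
  nc <- nucleosome_centers(reads, asm)
  # + read at 100 -> 173; - 49-nt read at 100 -> 76; off-contig and
  # low-mapq reads are dropped
  expect_equal(nc$center, c(173, 76))
  # a pure per-read map without drops
  ok <- data.frame(chrom = "chr1", pos = c(200, 300), strand = c("+", "-"),
                   length = 49L, mapq = 30L)
  expect_equal(nrow(nucleosome_centers(ok, asm)), 2)
})

test_that("phasing histograms peak at the planted dyad offsets", {
  tr <- mini_truth()
  nc <- nucleosome_centers(tr$mnase, tr$spec$assembly)
  ph <- phasing_profile(nc, tr$border_motifs, window = 500)
  top4 <- sort(ph$offset[order(-ph$count)][1:4])
  expect_equal(top4, c(-300, -150, 150, 300))
  # no centers near a site: zero histogram
  far <- intervals("chr1", 1, 3)
  ph0 <- phasing_profile(nc[0, ], far, window = 100)
  expect_equal(sum(ph0$count), 0)
  # minus-strand site flips the offset sign
  site <- intervals("chr1", 1000, 1020, strand = "-")
  ctr <- data.frame(chrom = "chr1", center = 1110)  # site mid 1010, offset +100
  ph1 <- phasing_profile(ctr, site, window = 200)
  expect_equal(ph1$count[ph1$offset == -100], 1)
  expect_equal(sum(ph1$count), 1)
})
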