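test_that("element classification brackets the TSS distance threshold", {
  tss <- intervals("chr1", 10e4, 10e4 + 1)
  near <- intervals("chr1", 10e4 + 1500, 10e4 + 1900)   # 1.5 kb gap
  far <- intervals("chr1", 10e4 + 2500, 10e4 + 2900)    # 2.5 kb gap
  k27 <- intervals("chr1", c(5e4, 6e4, 7e4), c(5.1e4, 6.1e4, 7.1e4))
  k1 <- intervals("chr1", c(5.05e4, 6.05e4), c(5.15e4, 6.15e4))
  es1 <- classify_elements(near, k27, k1, tss)
  expect_equal(nrow(es1$promoters), 1)
  es2 <- classify_elements(far, k27, k1, tss)
  expect_equal(nrow(es2$promoters), 0)
  # 3 K27ac peaks, 2 over K4me1, 1 of those also K4me3: exactly 1 enhancer
  k4me3 <- intervals("chr1", 5.02e4, 5.08e4)
  es3 <- classify_elements(k4me3, k27, k1, tss)
  expect_equal(nrow(es3$enhancers), 1)
  expect_equal(es3$enhancers$start, 6e4)
})

test_that("planted elements produce clustered promoter-enhancer distances", {
  tr <- mini_truth()
  es <- classify_elements(tr$k4me3, tr$k27ac, tr$k4me1, tr$tss)
  expect_gt(nrow(es$promoters), 0)
  expect_gt(nrow(es$enhancers), 0)
  # no enhancer overlaps a K4me3 peak by construction of the classification
  expect_false(any(devhic:::overlaps_any(es$enhancers, tr$k4me3)))
  r <- enhancer_distance_oe(es, tr$spec$assembly, n_shuffles = 20, seed = 1)
  expect_lt(r$log2_oe, 0)  # planted enhancers sit near their promoters
  # reproducible from the seed
  r2 <- enhancer_distance_oe(es, tr$spec$assembly, n_shuffles = 20, seed = 1)
  expect_identical(r$expected_mean, r2$expected_mean)
  expect_error(enhancer_distance_oe(es, tr$spec$assembly, n_shuffles = 0), "n_shuffles")
})

test_that("uniform enhancers give log2(O/E) near zero; window widens expected distance", {
  asm <- genome_assembly(c(chr1 = 20e6), 1e4)
  vals <- vapply(1:5, function(sd) {
    set.seed(sd)
    ps <- sort(runif(500, 1e6, 19e6)); es <- sort(runif(1500, 1e6, 19e6))
    pr <- intervals("chr1", ps, ps + 500)
    en <- intervals("chr1", es, es + 500)
    enhancer_distance_oe(list(promoters = pr, enhancers = en), asm,
                         n_shuffles = 40, seed = sd)$log2_oe
  }, numeric(1))
  expect_lt(max(abs(vals)), 0.2)
  # on a uniform background a wider shuffling window can only stretch the
  # expected nearest distance
  set.seed(9)
  ps <- sort(runif(40, 1e6, 19e6))
  pr <- intervals("chr1", ps, ps + 500)
  en <- intervals("chr1", pr$start + 2e4, pr$start + 2.05e4)
  el <- list(promoters = pr, enhancers = en)
  exps <- vapply(c(2e5, 1e6, 4e6), function(w)
    enhancer_distance_oe(el, asm, window = w, n_shuffles = 40, seed = 2)$expected_mean,
    numeric(1))
  expect_true(all(diff(exps) > 0))
})

test_that("Shannon entropy hits its closed-form landmarks", {
  expect_equal(shannon_entropy(rep(5, 4)), 2)
  expect_equal(shannon_entropy(c(3, 0, 0, 0)), 0)
  expect_equal(shannon_entropy(c(0.75, 0.25)),
               -0.75 * log2(0.75) - 0.25 * log2(0.25), tolerance = 1e-12)
  # scale and permutation invariance
  x <- c(2, 7, 1, 4, 9)
  expect_equal(shannon_entropy(x * 1000), shannon_entropy(x))
  expect_equal(shannon_entropy(rev(x)), shannon_entropy(x))
})

test_that("entropy classification separates planted breadth classes", {
  tr <- mini_truth()
  ec <- shannon_classify(tr$tpm, k = 40)
  cls <- tr$gene_class[match(ec$gene, rownames(tr$tpm))]
  expect_true(all(cls[ec$class == "housekeeping"] == "housekeeping"))
  expect_true(all(cls[ec$class == "tissue-specific"] == "tissue-specific"))
  # inversion swaps the label assignment
  ei <- shannon_classify(tr$tpm, k = 40, invert = TRUE)
  expect_true(all(ei$class[ec$class == "housekeeping"] == "tissue-specific"))
  expect_error(shannon_classify(tr$tpm, k = 1e5), "half")
  # all-zero rows are dropped before ranking
  tpm0 <- rbind(tr$tpm, zero_gene = rep(0, ncol(tr$tpm)))
  expect_false("zero_gene" %in% shannon_classify(tpm0, k = 40)$gene)
})

test_that("border enrichment is flat for background-identical features", {
  bd <- border_set(chrom = rep("chr1", 4), pos = c(2e6, 4e6, 6e6, 8e6))
  set.seed(4)
  pts <- data.frame(chrom = "chr1", pos = runif(500, 0, 10e6))
  r <- feature_border_enrichment(pts, bd, pts, max_dist = 1e6, step = 2e5)
  expect_equal(r$ratio, rep(1, nrow(r)))
  # features planted at borders dominate the first distance bin
  near <- data.frame(chrom = "chr1",
                     pos = rep(c(2e6, 4e6, 6e6, 8e6), each = 50) +
                       runif(200, -2e4, 2e4))
  r2 <- feature_border_enrichment(near, bd, pts, max_dist = 1e6, step = 2e5)
  expect_gt(r2$ratio[1], r2$ratio[nrow(r2)])
  expect_gt(r2$ratio[1], 1)
  expect_warning(
    feature_border_enrichment(near[1, ], bd, pts, max_dist = 1e6, step = 2e5),
    "single feature")
  expect_error(feature_border_enrichment(near, bd[0, ], pts), "empty border")
})
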