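test_that("compute_roi extends by pad plus half the variant length", {
  roi <- compute_roi(gi("chr1", 10000, 12000), 1000, 5e7)
  expect_equal(as.data.frame(roi), as.data.frame(gi("chr1", 8000, 14000)))
  # clipping at the chromosome start and end
  expect_equal(as.data.frame(compute_roi(gi("chr1", 500, 700), 1000, 5e7)),
               as.data.frame(gi("chr1", 0, 1800)))
  expect_equal(compute_roi(gi("chr1", 500, 700), 1000, 1750)$end, 1750)
  # odd length: e = pad + floor(L/2)
  roi2 <- compute_roi(gi("chr1", 3000, 3501), 1000, 1e6)
  expect_equal(roi2$start, 3000 - 1250)
  expect_equal(roi2$end, 3501 + 1250)
})

test_that("classify reproduces the printed minimal-evidence examples", {
  cfg <- validation_config()
  expect_equal(classify(pairs_with_quality(90), cfg)$verdict, "true_positive")
  expect_equal(classify(pairs_with_quality(c(45, 45)), cfg)$verdict,
               "true_positive")
  expect_equal(classify(pairs_with_quality(c(30, 30, 30)), cfg)$verdict,
               "true_positive")
  expect_equal(classify(pairs_with_quality(89), cfg)$verdict,
               "false_positive")
  expect_equal(classify(pairs_with_quality(c(29, 29, 29)), cfg)$verdict,
               "false_positive")
  r <- classify(pairs_with_quality(numeric(0)), cfg)
  expect_equal(r$verdict, "false_positive")
  expect_equal(r$avg_mq, 0); expect_equal(r$sum_mq, 0)
})

test_that("classify agrees with brute-force evaluation of the rule", {
  cfg <- validation_config()
  qs <- seq(0, 100, by = 10)
  for (n in 1:4) {
    combos <- utils::combn(length(qs) + n - 1, n)  # multisets via stars&bars
    sets <- apply(combos, 2, function(ix) qs[ix - seq_len(n) + 1])
    sets <- if (n == 1) matrix(sets, nrow = 1) else sets
    for (j in seq_len(ncol(sets))) {
      q <- sets[, j]
      want <- if (mean(q) >= 30 && sum(q) >= 90) "true_positive"
              else "false_positive"
      expect_identical(classify(pairs_with_quality(q), cfg)$verdict, want)
    }
  }
})

test_that("adding strong evidence never downgrades a true positive", {
  cfg <- validation_config()
  set.seed(9)
  for (i in 1:50) {
    q <- sample(30:100, sample(1:6, 1), replace = TRUE)
    if (classify(pairs_with_quality(q), cfg)$verdict != "true_positive") next
    q2 <- c(q, sample(30:100, 1))
    expect_identical(classify(pairs_with_quality(q2), cfg)$verdict,
                     "true_positive")
  }
})

test_that("select_supporting_pairs applies a strict span F-score cut", {
  v <- gi("chr1", 10000, 12000)
  pr <- pairs_from_spans("chr1", c(10000, 10500, 9800), c(12000, 11000, 12100))
  sel <- select_supporting_pairs(pr, v)
  # spans: F=1; F=2*500/2500=0.4; F=2*2000/(2000+2300)=0.930
  expect_equal(nrow(sel), 2L)
  expect_equal(sel$fscore[1], 1)
  expect_equal(sel$pair_quality, c(60, 60))
  # quality modes
  pr2 <- pairs_from_spans("chr1", 10000, 12000, mapq1 = 20, mapq2 = 60)
  expect_equal(select_supporting_pairs(pr2, v)$pair_quality, 20)
  cfg_sum <- validation_config(pair_quality_mode = "sum")
  expect_equal(select_supporting_pairs(pr2, v, cfg_sum)$pair_quality, 80)
  # inner-span mode drops pairs with no inner gap
  pr3 <- pairs_from_spans("chr1", 10000, 10150, mapq1 = 60)  # overlapping mates
  cfg_in <- validation_config(span_mode = "inner")
  expect_equal(nrow(select_supporting_pairs(pr3, v, cfg_in)), 0L)
  expect_equal(nrow(select_supporting_pairs(pr[0, ], v)), 0L)
})

test_that("extract_pairs keeps only fully contained, clean primary pairs", {
  roi <- gi("chrT", 8000, 14000)
  recs <- c(
    sam_pair("in_pair", 8101, 13801),                 # fully inside
    sam_pair("edge_pair", 8101, 13951),               # mate2 ends 14050 > 14000
    sam_pair("outside", 20001, 20501),                # elsewhere entirely
    sam_pair("secondary", 9001, 9501,
             flag1 = 99L + 256L, flag2 = 147L + 256L),
    sam_pair("dup", 9001, 9501,
             flag1 = 99L + 1024L, flag2 = 147L + 1024L))
  bam <- make_tiny_bam(recs)
  pr <- extract_pairs(bam, roi)
  expect_equal(nrow(pr), 1L)
  expect_equal(pr$m1_start, 8100)
  expect_equal(pr$m2_end, 13900)
  expect_equal(pr$outer_start, 8100)
  expect_equal(pr$outer_end, 13900)
  expect_equal(pr$inner_start, 8200)
  expect_equal(c(pr$mapq1, pr$mapq2), c(60, 60))
  # output invariant to alignments outside the ROI
  bam2 <- make_tiny_bam(sam_pair("in_pair", 8101, 13801))
  pr2 <- extract_pairs(bam2, roi)
  expect_equal(pr[names(pr2)], pr2, ignore_attr = TRUE)
  # empty region; missing chromosome
  expect_equal(nrow(extract_pairs(bam, gi("chrT", 40000, 41000))), 0L)
  expect_equal(nrow(extract_pairs(bam, gi("chrZ", 0, 1000))), 0L)
})

test_that("extract_pairs demands an index", {
  bam <- make_tiny_bam(sam_pair("p", 101, 501), index = FALSE)
  expect_error(extract_pairs(bam, gi("chrT", 0, 2000)), "indexed")
})

test_that("compute_doc measures per-bin mean coverage", {
  roi <- gi("chrT", 1000, 1500)
  bam0 <- make_tiny_bam(sam_pair("far", 50001, 50501))
  expect_equal(compute_doc(bam0, roi)$values, rep(0, 5))
  # one 100 bp read exactly tiling the second bin
  bam1 <- make_tiny_bam(sam_pair("p", 1101, 50001))
  doc <- compute_doc(bam1, roi)
  expect_equal(doc$values, c(0, 1, 0, 0, 0))
  expect_equal(doc$origin, 1000)
  expect_false(doc$range01)
})

test_that("validate_variant flags unresolvable samples and picks the best", {
  bam <- make_tiny_bam(c(sam_pair("s1", 2001, 3401, 60, 60),
                         sam_pair("s2", 2051, 3401, 60, 60)))
  v <- gi("chrT", 2000, 3500)
  manifest <- c(S1 = unname(as.character(bam)))
  r <- validate_variant(v, "S1", manifest, accession = "acc1")
  expect_equal(r$verdict, "true_positive")
  expect_equal(r$n_selected, 2L)
  expect_equal(r$avg_mq, 60)
  r2 <- validate_variant(v, "UNKNOWN", manifest)
  expect_equal(r2$verdict, "unresolvable")
  # any supporting sample suffices
  empty_bam <- make_tiny_bam(sam_pair("far", 50001, 50501))
  m2 <- c(S0 = unname(as.character(empty_bam)), S1 = unname(as.character(bam)))
  r3 <- validate_variant(v, c("S0", "S1"), m2)
  expect_equal(r3$verdict, "true_positive")
  expect_equal(r3$sample, "S1")
})
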