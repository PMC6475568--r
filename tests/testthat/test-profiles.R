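test_that("loess_smooth reproduces constants and exact linear ramps", {
  const <- binned_track("chr1", rep(0.5, 60))
  expect_equal(loess_smooth(const, 11)$values, rep(0.5, 60))
  ramp <- binned_track("chr1", seq(0, 1, length.out = 101))
  sm <- loess_smooth(ramp, 11)
  expect_equal(sm$values, ramp$values, tolerance = 1e-6)
})

test_that("loess_smooth shrinks spikes, keeps NA, validates input", {
  v <- rep(0.2, 41); v[21] <- 1
  sm <- loess_smooth(binned_track("chr1", v), 11)
  expect_lt(sm$values[21], 1)
  expect_gt(sm$values[21], 0.2)
  # missing bins are excluded from fits and stay missing
  v2 <- rep(0.4, 41); v2[c(5, 30)] <- NA
  sm2 <- loess_smooth(binned_track("chr1", v2), 11)
  expect_true(all(is.na(sm2$values[c(5, 30)])))
  expect_equal(sm2$values[-c(5, 30)], rep(0.4, 39))
  expect_error(loess_smooth(binned_track("chr1", rep(0.4, 5)), 11),
               "at least 11")
  expect_error(loess_smooth(binned_track("chr1", rep(0.4, 50)), 10),
               "odd")
  expect_error(binned_track("chr1", c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("GC threshold selection hits the stated tail quantiles", {
  grid <- seq(0, 1, by = 0.01)  # 101 values
  th <- select_gc_thresholds(grid, 0.05)
  expect_equal(unname(th["th1"]), 0.05, tolerance = 1e-8)
  expect_equal(unname(th["th2"]), 0.95, tolerance = 1e-8)
  expect_error(select_gc_thresholds(rep(0.4, 200)), "degenerate")
  expect_error(select_gc_thresholds(runif(50)), "at least 100")
  # the fraction below th1 tracks tail_fraction on continuous data
  set.seed(1)
  x <- rbeta(1e4, 5, 7)
  th <- select_gc_thresholds(x, 0.05)
  expect_lt(abs(mean(x < th["th1"]) - 0.05), 0.02)
  expect_lt(abs(mean(x > th["th2"]) - 0.05), 0.02)
})

test_that("mappability threshold excludes exact 0/1 masses", {
  vals <- c(rep(1, 7000), rep(0, 700), seq(0.5, 0.999, length.out = 2300))
  th3 <- select_mappability_threshold(vals, 0.20)
  expect_equal(th3, 0.5 + 0.8 * 0.5, tolerance = 0.01)
  expect_equal(select_mappability_threshold(c(rep(1, 200), rep(0, 50),
                                              rep(0.9, 150))), 0.9)
  expect_error(select_mappability_threshold(c(rep(1, 300), rep(0.8, 10))),
               "between 0 and 1")
})

test_that("segment_suspicious applies run, length and raw-mean rules", {
  th <- ref_thresholds()
  flat <- binned_track("chr1", rep(0.45, 50))
  expect_equal(nrow(segment_suspicious(flat, th, "gc")), 0L)
  # 7 suspicious bins = 700 bp > 500 -> one gc_low region with exact bounds
  v <- rep(0.45, 50); v[11:17] <- 0.10
  tr <- binned_track("chr1", v)
  seg <- segment_suspicious(tr, th, "gc")
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$start, 1000); expect_equal(seg$end, 1700)
  expect_equal(seg$cause, "gc_low")
  expect_equal(seg$mean_value, 0.10)
  # 5 bins = 500 bp is NOT larger than 500 bp
  v5 <- rep(0.45, 50); v5[11:15] <- 0.10
  expect_equal(nrow(segment_suspicious(binned_track("chr1", v5), th, "gc")), 0L)
  # high-GC side and mappability kind
  vh <- rep(0.45, 50); vh[11:17] <- 0.80
  expect_equal(segment_suspicious(binned_track("chr1", vh), th, "gc")$cause,
               "gc_high")
  vm <- rep(0.97, 50); vm[11:17] <- 0.5
  segm <- segment_suspicious(binned_track("chr1", vm), th, "mappability")
  expect_equal(segm$cause, "low_mappability")
  # missing bins break runs (two 3-bin halves, each <= 500 bp)
  vna <- rep(0.45, 50); vna[11:17] <- 0.10; vna[14] <- NA
  expect_equal(nrow(segment_suspicious(binned_track("chr1", vna), th, "gc")), 0L)
})

test_that("emitted regions always satisfy their invariants", {
  th <- ref_thresholds()
  set.seed(5)
  n_emitted <- 0L
  for (rep in 1:10) {
    # noisy background with planted low/high windows of random width
    v <- pmin(1, pmax(0, rnorm(400, 0.41, 0.08)))
    w <- sample(4:12, 2)
    v[101:(100 + w[1])] <- 0.08
    v[301:(300 + w[2])] <- 0.85
    tr <- binned_track("chr1", v)
    seg <- segment_suspicious(loess_smooth(tr, 11), th, "gc", raw = tr)
    n_emitted <- n_emitted + nrow(seg)
    expect_true(all(seg$end - seg$start > 500))
    expect_true(all((seg$cause == "gc_low" & seg$mean_value < th$th1) |
                      (seg$cause == "gc_high" & seg$mean_value > th$th2)))
  }
  expect_gt(n_emitted, 0L)
})

test_that("segmentation is translation-equivariant in the track origin", {
  th <- ref_thresholds()
  v <- rep(0.45, 50); v[11:17] <- 0.10
  a <- segment_suspicious(binned_track("chr1", v, origin = 0), th, "gc")
  b <- segment_suspicious(binned_track("chr1", v, origin = 2500), th, "gc")
  expect_equal(b$start, a$start + 2500)
  expect_equal(b$end, a$end + 2500)
})

test_that("planted windows are recovered within one bin; background is clean", {
  th <- ref_thresholds()
  cfg <- sim_config(seed = 11, chrom_length = 6e5, n_true_deletions = 0,
                    n_bias_artifacts = 6, map_zero_fraction = 0)
  p <- simulate_profiles(cfg)
  seg_gc <- segment_suspicious(loess_smooth(p$gc), th, "gc", raw = p$gc)
  seg_map <- segment_suspicious(loess_smooth(p$map), th, "mappability",
                                raw = p$map)
  f <- p$truth$features
  for (i in seq_len(nrow(f))) {
    regs <- if (f$cause[i] == "gc_low") seg_gc else seg_map
    j <- which(regs$start < f$end[i] & regs$end > f$start[i])
    expect_length(j, 1L)
    expect_lte(abs(regs$start[j] - f$start[i]), 100)
    expect_lte(abs(regs$end[j] - f$end[i]), 100)
  }
  expect_equal(nrow(seg_gc) + nrow(seg_map), nrow(f))
  # pure background: nothing suspicious
  cfg0 <- sim_config(seed = 12, chrom_length = 6e5, n_true_deletions = 0,
                     n_bias_artifacts = 0, map_zero_fraction = 0)
  p0 <- simulate_profiles(cfg0)
  expect_equal(nrow(segment_suspicious(loess_smooth(p0$gc), th, "gc",
                                       raw = p0$gc)), 0L)
  expect_equal(nrow(segment_suspicious(loess_smooth(p0$map), th,
                                       "mappability", raw = p0$map)), 0L)
})

test_that("build_suspicious_regions unions region lists and keeps causes", {
  g <- data.frame(chrom = "chr1", start = 0, end = 700, cause = "gc_low",
                  mean_value = 0.1)
  m <- data.frame(chrom = "chr1", start = 600, end = 1300,
                  cause = "low_mappability", mean_value = 0.5)
  none <- g[0, ]
  both <- build_suspicious_regions(g, m)
  expect_equal(as.data.frame(both$regions),
               as.data.frame(gi("chr1", 0, 1300)))
  expect_equal(nrow(both$details), 2L)
  expect_equal(as.data.frame(build_suspicious_regions(g, none)$regions),
               as.data.frame(gi("chr1", 0, 700)))
  expect_equal(nrow(build_suspicious_regions(none, none)$regions), 0L)
})

test_that("bedGraph track round-trip preserves values and geometry", {
  set.seed(2)
  tr <- binned_track("chr9", round(runif(200), 4))
  p <- tempfile(fileext = ".bedgraph")
  write_bedgraph_track(tr, p)
  back <- read_bedgraph_track(p)
  expect_named(back, "chr9")
  expect_equal(back$chr9$values, tr$values)
  expect_equal(back$chr9$bin_size, 100)
  # non-uniform bins rejected
  writeLines(c("chr1\t0\t100\t0.5", "chr1\t100\t250\t0.5"), p)
  expect_error(read_bedgraph_track(p), "not uniformly")
})
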