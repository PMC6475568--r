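test_that("generator outputs are deterministic functions of (config, seed)", {
  cfg <- small_sim_config(seed = 21)
  p1 <- simulate_profiles(cfg)
  p2 <- simulate_profiles(small_sim_config(seed = 21))
  expect_identical(p1$gc$values, p2$gc$values)
  expect_identical(p1$map$values, p2$map$values)
  expect_identical(p1$truth$features, p2$truth$features)
  f1 <- tempfile(); f2 <- tempfile()
  emit_variant_table(cfg, p1$truth, f1)
  emit_variant_table(cfg, p2$truth, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # a different seed moves the implants
  p3 <- simulate_profiles(small_sim_config(seed = 22))
  expect_false(identical(p1$truth$features$start, p3$truth$features$start))
})

test_that("config validation enforces the implant invariants", {
  expect_error(sim_config(deletion_size_range = c(400, 8000)),
               "strictly within")
  expect_error(sim_config(deletion_size_range = c(600, 10000)),
               "strictly within")
  expect_error(sim_config(chrom_length = 2e5, n_true_deletions = 10,
                          n_bias_artifacts = 10), "too short")
  # implanted features are non-overlapping and far apart
  tr <- simulate_truth(sim_config(seed = 4))
  f <- tr$features[order(tr$features$start), ]
  expect_true(all(f$start[-1] - f$end[-nrow(f)] >= 20000))
  sz <- f$end - f$start
  expect_true(all(sz[f$type == "deletion"] > 500 &
                    sz[f$type == "deletion"] < 10000))
})

test_that("profile tracks realise the stated background and implants", {
  cfg <- small_sim_config(seed = 5, deletions_biased = FALSE)
  p <- simulate_profiles(cfg)
  f <- p$truth$features
  bin <- cfg$bin_size
  expect_equal(length(p$gc$values), cfg$chrom_length / bin)
  # background GC near its stated mean; mappability mass at exactly 1
  # (measured outside the overwritten implant/repeat-block windows)
  bg <- rep(TRUE, length(p$map$values))
  for (k in seq_len(nrow(f)))
    bg[(f$start[k] / bin + 1):(f$end[k] / bin)] <- FALSE
  blk <- p$truth$repeat_blocks
  for (k in seq_len(nrow(blk)))
    bg[(blk$start[k] / bin + 1):(blk$end[k] / bin)] <- FALSE
  expect_equal(mean(p$gc$values[bg]), 0.41, tolerance = 0.02)
  expect_equal(mean(p$map$values[bg] == 1), 0.70, tolerance = 0.03)
  # exact-zero mass sits in the recorded repeat blocks only
  zero_bins <- which(p$map$values == 0)
  blk <- p$truth$repeat_blocks
  in_block <- unlist(lapply(seq_len(nrow(blk)), function(k)
    (blk$start[k] / bin + 1):(blk$end[k] / bin)))
  expect_setequal(zero_bins, in_block)
  # artifact windows carry their cause's extreme values
  for (i in which(f$type == "artifact")) {
    bins <- (f$start[i] / bin + 1):(f$end[i] / bin)
    if (f$cause[i] == "gc_low")
      expect_lt(mean(p$gc$values[bins]), 0.2)
    else
      expect_lt(mean(p$map$values[bins]), 0.6)
  }
  # unbiased deletions stay at background (specificity of the screen)
  for (i in which(f$type == "deletion")) {
    bins <- (f$start[i] / bin + 1):(f$end[i] / bin)
    expect_gt(mean(p$gc$values[bins]), 0.3)
  }
})

test_that("read-pair count matches the coverage budget within 5%", {
  cfg <- small_sim_config(seed = 6)
  truth <- simulate_truth(cfg)
  bam <- simulate_read_pairs(cfg, truth)
  n <- attr(bam, "n_pairs")
  expected <- cfg$coverage * cfg$chrom_length / (2 * cfg$read_length)
  expect_lt(abs(n - expected) / expected, 0.05)
  # and the realised depth of coverage away from implants matches the
  # closed form: fragments sampled on the shorter donor genome concentrate
  # on the non-deleted reference, so local depth = coverage * L / L_donor
  f <- truth$features
  dele <- f[f$type == "deletion", ]
  local_depth <- cfg$coverage * cfg$chrom_length /
    (cfg$chrom_length - sum(dele$end - dele$start))
  gaps <- data.frame(start = c(0, f$end), end = c(f$start, cfg$chrom_length))
  g <- gaps[which.max(gaps$end - gaps$start), ]
  mid <- round((g$start + g$end) / 2)
  doc <- compute_doc(bam, gi(cfg$chrom_name, mid - 2500, mid + 2500))
  expect_equal(mean(doc$values), local_depth, tolerance = 0.08)
})

test_that("deletions gain spanning support; artifacts and flanks stay clean", {
  for (seed in c(31, 32, 33)) {
    cfg <- small_sim_config(seed = seed)
    truth <- simulate_truth(cfg)
    bam <- simulate_read_pairs(cfg, truth)
    f <- truth$features
    for (i in seq_len(nrow(f))) {
      v <- gi(f$chrom[i], f$start[i], f$end[i])
      roi <- compute_roi(v, 1000, cfg$chrom_length)
      pr <- extract_pairs(bam, roi)
      sel <- select_supporting_pairs(pr, v)
      if (f$type[i] == "deletion") {
        expect_gte(nrow(sel), 3)
        # excision: no read maps inside a homozygous deletion
        expect_false(any(pr$m1_start < v$end & pr$m1_end > v$start))
        expect_false(any(pr$m2_start < v$end & pr$m2_end > v$start))
        # every supporting pair's inner span straddles the deletion
        expect_true(all(sel$inner_start <= v$start & sel$inner_end >= v$end))
      } else {
        # bias artifacts have zero span-matching pairs: thinned but concordant
        expect_equal(nrow(sel), 0L)
      }
    }
  }
})

test_that("mate MAPQ drops inside low-mappability artifact windows", {
  cfg <- small_sim_config(seed = 41)
  truth <- simulate_truth(cfg)
  bam <- simulate_read_pairs(cfg, truth)
  lowmap <- truth$features[truth$features$cause == "low_mappability" &
                             truth$features$type == "artifact", ]
  expect_equal(nrow(lowmap), 1L)  # causes alternate: one per pair of artifacts
  w <- lowmap[1, ]
  pr <- extract_pairs(bam, gi(w$chrom, max(0, w$start - 2000),
                              w$end + 2000))
  inside1 <- pr$m1_start < w$end & pr$m1_end > w$start
  expect_true(all(pr$mapq1[inside1] == 10))
  expect_true(all(pr$mapq1[pr$m1_end <= w$start] == 60))
})

test_that("variant table round-trips and feeds the filters as designed", {
  cfg <- sim_config(seed = 8, chrom_length = 1e6, n_true_deletions = 5,
                    n_bias_artifacts = 5)
  truth <- simulate_truth(cfg)
  path <- tempfile(fileext = ".tsv")
  emit_variant_table(cfg, truth, path, n_decoys = 5)
  v <- read_dgv_table(path)
  expect_equal(nrow(v), 15L)
  kept <- suppressMessages(filter_variants(v))
  expect_equal(nrow(kept), 10L)   # decoys rejected, implants kept
  # coordinates round-trip exactly against the truth
  m <- merge(as.data.frame(kept)[c("accession", "start", "end")],
             truth$features[c("accession", "start", "end")],
             by = "accession")
  expect_equal(m$start.x, m$start.y)
  expect_equal(m$end.x, m$end.y)
})

test_that("simulate_dataset writes a coherent dataset", {
  out <- file.path(tempdir(), "simds")
  d <- simulate_dataset(small_sim_config(seed = 13), out)
  expect_true(all(file.exists(d$gc, d$map, d$bam, d$variants,
                              d$truth_file, d$manifest)))
  expect_true(file.exists(paste0(d$bam, ".bai")))
  m <- read_manifest(d$manifest)
  expect_named(m, "SIM001")
  tr <- read_bedgraph_track(d$gc)
  expect_equal(length(tr[[1]]$values), 3000)
})
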