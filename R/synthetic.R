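# Truth-labelled synthetic inputs: binned GC/mappability tracks, paired-end
# alignment files, and DGV-style variant tables, all deterministic functions
# of (config, seed). The generator emulates the data regime the screen
# assumes: concordant pairs with a stated insert-size distribution,
# discordant pairs spanning implanted (homozygous) deletions, coverage
# valleys caused by GC/mappability bias with NO discordant support, and
# matching profile tracks and variant tables.

#' Simulation configuration
#'
#' Defaults describe a 2 Mb chromosome sequenced at 30x with a 100 bp read
#' length and a 500 +/- 50 bp insert-size distribution, GC background
#' 0.41 +/- 0.05 per 100 bp bin, and a mappability background that is exact
#' 1.0 for 70% of bins with the non-unique remainder near 0.97 and a 7%
#' exact-zero mass laid down as contiguous repeat-like blocks.
#'
#' @param seed integer seed; every simulated artefact is a deterministic
#'   function of `(config, seed)`.
#' @param chrom_name,chrom_length chromosome name and length (bases).
#' @param bin_size profile bin size in bases.
#' @param read_length,insert_mean,insert_sd,coverage paired-end library
#'   geometry (fragment length ~ Normal truncated at `2*read_length`).
#' @param gc_background_mean,gc_background_sd per-bin GC background.
#' @param n_true_deletions,n_bias_artifacts implant counts.
#' @param deletion_size_range implanted deletion sizes in bases (must stay
#'   within (500, 10000) so implants pass the screen's own filters).
#' @param artifact_size_range bias-artifact window sizes; the default floor
#'   of 1500 bp keeps artifacts out of the regime where ordinary concordant
#'   pairs span-match a sub-kb window (see the methods vignette).
#' @param artifact_coverage_factor fraction of concordant fragments retained
#'   inside bias artifacts (coverage valley depth).
#' @param artifact_gc,artifact_mappability profile values written into
#'   GC-cause / mappability-cause artifact windows.
#' @param map_one_fraction,map_zero_fraction mappability background masses
#'   at exactly 1 and exactly 0; the zero mass is realised as
#'   `map_zero_block` -bp contiguous blocks recorded in the truth object.
#' @param map_zero_block block length for the exact-zero mass (bases).
#' @param deletions_biased if `TRUE`, the implanted true deletions also get
#'   extreme profile values, so they are flagged suspicious and exercise the
#'   full suspicious-then-validated-true path; if `FALSE` (default) they
#'   stay at background and test specificity of the profile screen.
#' @param zygosity `"hom"` (default) or `"het"` (half the fragments come
#'   from a haplotype without the deletions).
#' @param sample_name sample identifier used in tables and the manifest.
#' @param min_feature_gap minimum distance between implanted features.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L, chrom_name = "chrS", chrom_length = 2e6,
                       bin_size = 100, read_length = 100, insert_mean = 500,
                       insert_sd = 50, coverage = 30,
                       gc_background_mean = 0.41, gc_background_sd = 0.05,
                       n_true_deletions = 10, n_bias_artifacts = 10,
                       deletion_size_range = c(600, 8000),
                       artifact_size_range = c(1500, 8000),
                       artifact_coverage_factor = 0.2,
                       artifact_gc = 0.15, artifact_mappability = 0.5,
                       map_one_fraction = 0.70, map_zero_fraction = 0.07,
                       map_zero_block = 5000,
                       deletions_biased = FALSE,
                       zygosity = c("hom", "het"),
                       sample_name = "SIM001",
                       min_feature_gap = 20000) {
  zygosity <- match.arg(zygosity)
  stopifnot(coverage > 0, chrom_length >= 1e5, bin_size >= 1,
            read_length >= 20, insert_mean >= 2 * read_length,
            insert_sd > 0, n_true_deletions >= 0, n_bias_artifacts >= 0,
            artifact_coverage_factor >= 0, artifact_coverage_factor <= 1)
  if (deletion_size_range[1] <= 500 || deletion_size_range[2] >= 10000)
    stop("deletion sizes must lie strictly within (500, 10000) so implants ",
         "pass the screen's own filters", call. = FALSE)
  n_feat <- n_true_deletions + n_bias_artifacts
  if (n_feat > 0) {
    slot <- chrom_length / n_feat
    if (slot < min_feature_gap + max(deletion_size_range[2],
                                     artifact_size_range[2]) + 2 * bin_size)
      stop("chromosome too short for ", n_feat, " implants at least ",
           min_feature_gap, " bases apart", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), chrom_name = chrom_name,
                 chrom_length = chrom_length, bin_size = bin_size,
                 read_length = read_length, insert_mean = insert_mean,
                 insert_sd = insert_sd, coverage = coverage,
                 gc_background_mean = gc_background_mean,
                 gc_background_sd = gc_background_sd,
                 n_true_deletions = n_true_deletions,
                 n_bias_artifacts = n_bias_artifacts,
                 deletion_size_range = deletion_size_range,
                 artifact_size_range = artifact_size_range,
                 artifact_coverage_factor = artifact_coverage_factor,
                 artifact_gc = artifact_gc,
                 artifact_mappability = artifact_mappability,
                 map_one_fraction = map_one_fraction,
                 map_zero_fraction = map_zero_fraction,
                 map_zero_block = map_zero_block,
                 deletions_biased = isTRUE(deletions_biased),
                 zygosity = zygosity, sample_name = sample_name,
                 min_feature_gap = min_feature_gap),
            class = "sim_config")
}

# snap a coordinate/length to the bin grid
.snap <- function(x, bin) round(x / bin) * bin

#' Place implanted features and fix their expected outcomes
#'
#' Deterministic given the config seed. Features (true deletions and bias
#' artifacts) are placed in disjoint slots, snapped to the bin grid, at
#' least `min_feature_gap` apart; the exact-zero mappability mass is laid
#' down as repeat-like blocks away from the features. Artifact causes (and
#' biased-deletion causes) alternate between extreme GC and low
#' mappability.
#'
#' @param config a [sim_config()].
#' @return list of class `"sim_truth"`: `features` (data.frame with
#'   accession, chrom, start, end, type, cause, expected_verdict),
#'   `repeat_blocks` ([gi()] set, possibly empty), and the `config`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_del <- config$n_true_deletions
  n_art <- config$n_bias_artifacts
  n_feat <- n_del + n_art
  bin <- config$bin_size
  feats <- NULL
  if (n_feat > 0) {
    slot <- floor(config$chrom_length / n_feat)
    type <- sample(c(rep("deletion", n_del), rep("artifact", n_art)))
    sizes <- numeric(n_feat)
    sizes[type == "deletion"] <- stats::runif(n_del,
                                              config$deletion_size_range[1],
                                              config$deletion_size_range[2])
    sizes[type == "artifact"] <- stats::runif(n_art,
                                              config$artifact_size_range[1],
                                              config$artifact_size_range[2])
    sizes <- pmax(bin, .snap(sizes, bin))
    # keep deletion sizes inside their stated range after snapping
    sizes[type == "deletion"] <- pmin(
      pmax(sizes[type == "deletion"],
           bin * ceiling(config$deletion_size_range[1] / bin)),
      bin * floor(config$deletion_size_range[2] / bin))
    margin <- config$min_feature_gap / 2
    lo <- (seq_len(n_feat) - 1) * slot + margin
    hi <- seq_len(n_feat) * slot - margin - sizes
    start <- .snap(lo + stats::runif(n_feat) * (hi - lo), bin)
    feats <- data.frame(chrom = config$chrom_name, start = start,
                        end = start + sizes, type = type,
                        stringsAsFactors = FALSE)
    # alternate causes within each class
    feats$cause <- "none"
    art_idx <- which(feats$type == "artifact")
    feats$cause[art_idx] <- rep(c("gc_low", "low_mappability"),
                                length.out = length(art_idx))
    if (config$deletions_biased) {
      del_idx <- which(feats$type == "deletion")
      feats$cause[del_idx] <- rep(c("gc_low", "low_mappability"),
                                  length.out = length(del_idx))
    }
    feats$expected_verdict <- ifelse(feats$type == "deletion",
                                     "true_positive", "false_positive")
    feats$accession <- sprintf("essv%07d", seq_len(n_feat))
    if (any(diff(feats$start) < 0) ||
        any(feats$start[-1] - feats$end[-n_feat] < config$min_feature_gap))
      stop("internal: implanted features overlap or are too close",
           call. = FALSE)
  } else {
    feats <- data.frame(chrom = character(), start = numeric(),
                        end = numeric(), type = character(),
                        cause = character(), expected_verdict = character(),
                        accession = character(), stringsAsFactors = FALSE)
  }
  # repeat-like exact-zero mappability blocks, kept clear of the implants
  blocks <- gi()
  if (config$map_zero_fraction > 0) {
    n_blocks <- max(0L, round(config$map_zero_fraction * config$chrom_length /
                                config$map_zero_block))
    placed <- list()
    tries <- 0L
    while (length(placed) < n_blocks && tries < 20000L) {
      tries <- tries + 1L
      s <- .snap(stats::runif(1, 0, config$chrom_length - config$map_zero_block),
                 bin)
      e <- s + config$map_zero_block
      gap <- config$min_feature_gap
      clash <- FALSE
      if (nrow(feats))
        clash <- any(s < feats$end + gap & e > feats$start - gap)
      if (!clash && length(placed))
        clash <- any(vapply(placed, function(b)
          s < b[2] + gap / 2 && e > b[1] - gap / 2, TRUE))
      if (!clash) placed[[length(placed) + 1L]] <- c(s, e)
    }
    if (length(placed)) {
      m <- do.call(rbind, placed)
      m <- m[order(m[, 1]), , drop = FALSE]
      blocks <- gi(config$chrom_name, m[, 1], m[, 2])
    }
  }
  structure(list(features = feats, repeat_blocks = blocks, config = config),
            class = "sim_truth")
}

#' Simulate the GC and mappability profile tracks
#'
#' GC per bin is Normal background clipped to \[0, 1\]; mappability is exact
#' 1.0 for `map_one_fraction` of bins, exact 0 inside the repeat blocks, and
#' near-0.97 otherwise. Every bias-cause window (artifacts, plus biased
#' deletions) is overwritten with the extreme value for its cause;
#' unbiased true-deletion windows stay at background, so the profile screen
#' must NOT flag them.
#'
#' @param config a [sim_config()].
#' @param truth optional [simulate_truth()] result (recomputed otherwise).
#' @return list with `gc` and `map` ([binned_track()]) and `truth`.
#' @export
simulate_profiles <- function(config, truth = simulate_truth(config)) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  set.seed(config$seed + 1L)
  bin <- config$bin_size
  nbins <- floor(config$chrom_length / bin)
  gc <- pmin(1, pmax(0, stats::rnorm(nbins, config$gc_background_mean,
                                     config$gc_background_sd)))
  u <- stats::runif(nbins)
  map <- ifelse(u < config$map_one_fraction, 1,
                pmin(0.999, pmax(0.9, stats::rnorm(nbins, 0.97, 0.008))))
  if (nrow(truth$repeat_blocks)) {
    for (k in seq_len(nrow(truth$repeat_blocks))) {
      i <- (truth$repeat_blocks$start[k] / bin + 1):(truth$repeat_blocks$end[k] / bin)
      map[i] <- 0
    }
  }
  f <- truth$features
  for (k in seq_len(nrow(f))) {
    if (f$cause[k] == "none") next
    i <- (f$start[k] / bin + 1):(f$end[k] / bin)
    if (f$cause[k] == "gc_low") {
      gc[i] <- pmin(1, pmax(0, stats::rnorm(length(i), config$artifact_gc, 0.02)))
    } else {
      map[i] <- pmin(0.85, pmax(0.05,
                                stats::rnorm(length(i), config$artifact_mappability, 0.02)))
    }
  }
  list(gc = binned_track(config$chrom_name, gc, bin),
       map = binned_track(config$chrom_name, map, bin),
       truth = truth)
}

# donor -> reference coordinate map for homozygously excised deletions
.make_donor_map <- function(dels) {
  if (nrow(dels) == 0L) return(function(d) d)
  o <- order(dels$start)
  s <- dels$start[o]; sz <- dels$end[o] - dels$start[o]
  breaks <- s - cumsum(c(0, sz[-length(sz)]))
  shift <- c(0, cumsum(sz))
  function(d) d + shift[findInterval(d, breaks) + 1]
}

#' Simulate a paired-end alignment file
#'
#' Fragments are sampled uniformly from the donor genome (the reference
#' with the implanted deletions homozygously excised), at the rate giving
#' the target reference coverage; fragment lengths are Normal truncated at
#' `2*read_length`. Mapped back to the reference, a fragment straddling a
#' deletion yields a discordant pair whose mates are pushed apart by the
#' deletion length (reads that would cross a breakpoint are dropped — in
#' reality they would be clipped or unmapped). Fragments overlapping a bias
#' artifact are thinned to `artifact_coverage_factor` but stay concordant.
#' Mate MAPQ is 60, reduced to 10 inside low-mappability artifact windows.
#' Pairs are written in FR orientation with proper flags and TLEN, then
#' coordinate-sorted and indexed.
#'
#' @param config a [sim_config()].
#' @param truth a [simulate_truth()] result.
#' @param bam_prefix output path prefix; `<bam_prefix>.bam` and its index
#'   are created.
#' @return path to the sorted, indexed BAM, with attributes `n_pairs`
#'   (pairs written) and `truth`.
#' @export
simulate_read_pairs <- function(config, truth,
                                bam_prefix = tempfile("pemscreen_sim")) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  set.seed(config$seed + 2L)
  rl <- config$read_length
  L <- config$chrom_length
  f <- truth$features
  dels <- f[f$type == "deletion", , drop = FALSE]
  arts <- f[f$type == "artifact", , drop = FALSE]
  Ld <- L - sum(dels$end - dels$start)
  dmap <- .make_donor_map(dels)

  n_frag <- round(config$coverage * L / (2 * rl))
  flen <- pmax(2 * rl, round(stats::rnorm(n_frag, config$insert_mean,
                                          config$insert_sd)))
  from_ref_hap <- if (config$zygosity == "het")
    stats::runif(n_frag) < 0.5 else rep(FALSE, n_frag)
  glen <- ifelse(from_ref_hap, L, Ld)
  d0 <- floor(stats::runif(n_frag) * (glen - flen))

  # donor mate intervals
  m1s_d <- d0; m1e_d <- d0 + rl
  m2s_d <- d0 + flen - rl; m2e_d <- d0 + flen
  # map to reference; identity for reference-haplotype fragments
  mapc <- function(x, hap) ifelse(hap, x, dmap(x))
  m1s <- mapc(m1s_d, from_ref_hap); m1e_last <- mapc(m1e_d - 1, from_ref_hap)
  m2s <- mapc(m2s_d, from_ref_hap); m2e_last <- mapc(m2e_d - 1, from_ref_hap)
  # drop reads that would cross a breakpoint (non-contiguous on reference)
  ok <- (m1e_last - m1s == rl - 1) & (m2e_last - m2s == rl - 1)

  # thin fragments overlapping bias artifacts (coverage valley, concordant)
  if (nrow(arts)) {
    out_s <- m1s; out_e <- m2s + rl
    in_art <- rep(FALSE, n_frag)
    for (k in seq_len(nrow(arts)))
      in_art <- in_art | (out_s < arts$end[k] & out_e > arts$start[k])
    ok <- ok & (!in_art | stats::runif(n_frag) < config$artifact_coverage_factor)
  }
  m1s <- m1s[ok]; m2s <- m2s[ok]
  n <- length(m1s)

  mapq1 <- rep(60L, n); mapq2 <- rep(60L, n)
  lowmap <- arts[arts$cause == "low_mappability", , drop = FALSE]
  if (nrow(lowmap)) {
    for (k in seq_len(nrow(lowmap))) {
      mapq1[m1s < lowmap$end[k] & m1s + rl > lowmap$start[k]] <- 10L
      mapq2[m2s < lowmap$end[k] & m2s + rl > lowmap$start[k]] <- 10L
    }
  }

  qname <- sprintf("frag%08d", seq_len(n))
  tlen <- m2s + rl - m1s
  cigar <- paste0(rl, "M")
  rec1 <- data.table::data.table(qname = qname, flag = 99L,
                                 rname = config$chrom_name, pos = m1s + 1,
                                 mapq = mapq1, cigar = cigar, rnext = "=",
                                 pnext = m2s + 1, tlen = tlen,
                                 seq = "*", qual = "*")
  rec2 <- data.table::data.table(qname = qname, flag = 147L,
                                 rname = config$chrom_name, pos = m2s + 1,
                                 mapq = mapq2, cigar = cigar, rnext = "=",
                                 pnext = m1s + 1, tlen = -tlen,
                                 seq = "*", qual = "*")
  sam <- paste0(bam_prefix, ".unsorted.sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", config$chrom_name, as.integer(L))),
             sam)
  data.table::fwrite(rbind(rec1, rec2), sam, sep = "\t", append = TRUE,
                     col.names = FALSE, quote = FALSE, scipen = 50)
  unsorted <- Rsamtools::asBam(sam, paste0(bam_prefix, ".unsorted"),
                               overwrite = TRUE, indexDestination = FALSE)
  sorted <- Rsamtools::sortBam(unsorted, bam_prefix)
  Rsamtools::indexBam(sorted)
  unlink(c(sam, unsorted))
  structure(sorted, n_pairs = n, truth = truth)
}

#' Emit a DGV-style supporting-variants table
#'
#' One row per implanted true deletion and per bias artifact (artifact rows
#' model depth-of-coverage miscalls), with subtype alternating
#' deletion/loss, method `"sequencing"`, and the simulated sample id; plus
#' `n_decoys` rows the screen's filters must reject (wrong subtype, wrong
#' method, oversize, empty samples). Coordinates are written 1-based
#' inclusive.
#'
#' @param config a [sim_config()].
#' @param truth a [simulate_truth()] result.
#' @param path output TSV path.
#' @param n_decoys number of decoy rows (default 5).
#' @return `path` invisibly; the written table as attribute `"table"`.
#' @export
emit_variant_table <- function(config, truth, path, n_decoys = 5) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  set.seed(config$seed + 3L)
  f <- truth$features
  n <- nrow(f)
  rows <- data.frame(
    variantaccession = f$accession, chr = f$chrom,
    start = f$start + 1, end = f$end,
    varianttype = "CNV",
    variantsubtype = rep(c("deletion", "loss"), length.out = n),
    reference = "SimStudyA_2026", method = "Sequencing",
    samples = config$sample_name, stringsAsFactors = FALSE)
  if (n_decoys > 0) {
    kinds <- rep(c("wrong_subtype", "wrong_method", "oversize",
                   "empty_samples", "wrong_type"), length.out = n_decoys)
    # park decoys in inter-feature gaps, clear of every implant
    sizes <- rep(2000, n_decoys)
    sizes[kinds == "oversize"] <- 12000
    cand <- seq(5000, config$chrom_length - 20000, by = 101)
    busy <- rbind(f[, c("start", "end")],
                  as.data.frame(truth$repeat_blocks)[, c("start", "end"),
                                                     drop = FALSE])
    free <- vapply(cand, function(s)
      !any(s < busy$end + 1000 & s + 12000 > busy$start - 1000), TRUE)
    cand <- cand[free]
    starts <- sort(sample(cand, n_decoys))
    decoys <- data.frame(
      variantaccession = sprintf("essv%07d", n + seq_len(n_decoys)),
      chr = config$chrom_name, start = starts + 1, end = starts + sizes,
      varianttype = "CNV",
      variantsubtype = ifelse(kinds == "wrong_subtype", "duplication",
                              ifelse(kinds == "wrong_type", "insertion",
                                     "deletion")),
      reference = "SimStudyA_2026",
      method = ifelse(kinds == "wrong_method", "aCGH", "Sequencing"),
      samples = ifelse(kinds == "empty_samples", "", config$sample_name),
      stringsAsFactors = FALSE)
    rows <- rbind(rows, decoys)
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  attr(path, "table") <- rows
  invisible(path)
}

#' Write the truth table
#' @param truth a [simulate_truth()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth$features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a sample manifest
#' @param samples named character vector (sample id -> alignment path).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(samples, path) {
  utils::write.table(data.frame(sample = names(samples),
                                path = unname(samples)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a complete synthetic dataset on disk
#'
#' Writes the profile bedGraphs, the sorted+indexed alignment file, the
#' DGV-style variant table, the truth table, and the manifest consumed by
#' the validation stage.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param n_decoys decoy rows in the variant table (default 5).
#' @return list with paths (`gc`, `map`, `bam`, `variants`, `truth_file`,
#'   `manifest`) plus the in-memory `truth`, `profiles` and `config`.
#' @export
simulate_dataset <- function(config, out_dir, n_decoys = 5) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- simulate_truth(config)
  prof <- simulate_profiles(config, truth)
  gc_path <- file.path(out_dir, "gc.bedgraph")
  map_path <- file.path(out_dir, "map.bedgraph")
  write_bedgraph_track(prof$gc, gc_path)
  write_bedgraph_track(prof$map, map_path)
  bam <- simulate_read_pairs(config, truth,
                             file.path(out_dir, config$sample_name))
  variants <- file.path(out_dir, "variants.tsv")
  emit_variant_table(config, truth, variants, n_decoys = n_decoys)
  truth_file <- file.path(out_dir, "truth.tsv")
  write_truth(truth, truth_file)
  manifest <- file.path(out_dir, "manifest.tsv")
  write_manifest(stats::setNames(as.character(bam), config$sample_name),
                 manifest)
  list(gc = gc_path, map = map_path, bam = as.character(bam),
       variants = variants, truth_file = truth_file, manifest = manifest,
       truth = truth, profiles = prof, config = config)
}
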