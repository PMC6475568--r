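# shared fixtures: per-base oracle, tiny SAM/BAM builders, toy DGV tables

# independent per-base membership-counting oracle for the overlap F-score
oracle_fscore <- function(ref, test) {
  if (ref$chrom != test$chrom) return(0)
  A <- seq(ref$start, ref$end - 1)
  B <- seq(test$start, test$end - 1)
  ov <- length(intersect(A, B))
  if (ov == 0) return(0)
  2 * ov / (length(A) + length(B))
}

pairs_with_quality <- function(q) data.frame(pair_quality = q)

# build a read_pairs-shaped table from outer spans (100 bp mates at the ends)
pairs_from_spans <- function(chrom, outer_start, outer_end,
                             mapq1 = 60, mapq2 = 60) {
  chrom <- rep_len(chrom, length(outer_start))
  mapq1 <- rep_len(mapq1, length(outer_start))
  mapq2 <- rep_len(mapq2, length(outer_start))
  d <- data.frame(chrom = chrom, m1_start = outer_start,
                  m1_end = outer_start + 100, m2_start = outer_end - 100,
                  m2_end = outer_end, outer_start = outer_start,
                  outer_end = outer_end, mapq1 = mapq1, mapq2 = mapq2,
                  stringsAsFactors = FALSE)
  d$inner_start <- ifelse(d$m1_end < d$m2_start, d$m1_end, NA_real_)
  d$inner_end <- ifelse(d$m1_end < d$m2_start, d$m2_start, NA_real_)
  class(d) <- c("read_pairs", class(d))
  d
}

sam_pair <- function(qname, pos1, pos2, mapq1 = 60, mapq2 = 60, rl = 100,
                     flag1 = 99L, flag2 = 147L, chrom = "chrT") {
  # pos1/pos2 are 1-based leftmost positions of the two mates
  c(paste(qname, flag1, chrom, pos1, mapq1, paste0(rl, "M"), "=", pos2,
          pos2 + rl - pos1, "*", "*", sep = "\t"),
    paste(qname, flag2, chrom, pos2, mapq2, paste0(rl, "M"), "=", pos1,
          -(pos2 + rl - pos1), "*", "*", sep = "\t"))
}

# write SAM records, convert to a sorted (optionally indexed) BAM
make_tiny_bam <- function(records, chrom = "chrT", len = 100000L,
                          index = TRUE) {
  prefix <- tempfile("tinybam")
  sam <- paste0(prefix, ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", chrom, len), records), sam)
  unsorted <- Rsamtools::asBam(sam, paste0(prefix, ".unsorted"),
                               overwrite = TRUE, indexDestination = FALSE)
  bam <- Rsamtools::sortBam(unsorted, prefix)
  if (index) Rsamtools::indexBam(bam)
  unlink(c(sam, unsorted))
  bam
}

# DGV-style table writer from a list of row vectors
write_dgv_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  header <- c("variantaccession", "chr", "start", "end", "varianttype",
              "variantsubtype", "reference", "method", "samples")
  writeLines(c(paste(header, collapse = "\t"),
               vapply(rows, paste, "", collapse = "\t")), path)
  path
}

# the five-row toy table: one survivor, four rows the filters must reject
toy_dgv_rows <- list(
  c("essv1", "chr1", "1001", "3000", "CNV", "deletion", "StudyA",
    "Sequencing", "NA18507"),
  c("essv2", "chr1", "5001", "7000", "CNV", "duplication", "StudyA",
    "Sequencing", "NA18507"),
  c("essv3", "chr1", "9001", "11000", "CNV", "deletion", "StudyA",
    "aCGH", "NA18507"),
  c("essv4", "chr1", "20001", "32000", "CNV", "deletion", "StudyA",
    "Sequencing", "NA18507"),
  c("essv5", "chr1", "40001", "41000", "CNV", "loss", "StudyA",
    "Sequencing", ""))

# small but fully featured simulation (keeps routine tests fast)
small_sim_config <- function(seed = 3, ...) {
  sim_config(seed = seed, chrom_length = 3e5, coverage = 10,
             n_true_deletions = 2, n_bias_artifacts = 2, ...)
}

ref_thresholds <- function() threshold_set(0.26, 0.59, 0.92)
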