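# Genomic-interval arithmetic and the base-level overlap F-score that drives
# both suspicious-variant flagging and paired-end validation.
#
# All intervals in this package are 0-based, half-open [start, end).
# Conversion to/from 1-based inclusive coordinates happens only at file
# boundaries (DGV tables, SAM/BAM, BED/bedGraph import/export).

#' Construct a set of genomic intervals
#'
#' @param chrom character vector of chromosome identifiers.
#' @param start integer-valued vector, 0-based inclusive start.
#' @param end integer-valued vector, 0-based exclusive end; must satisfy
#'   `end > start` element-wise (every interval covers at least one base).
#'
#' @return A `data.frame` of class `"gi"` with columns `chrom`, `start`,
#'   `end`.
#' @export
#' @examples
#' gi("chr1", 1000, 2000)
gi <- function(chrom = character(), start = numeric(), end = numeric()) {
  x <- data.frame(chrom = as.character(chrom),
                  start = as.numeric(start),
                  end = as.numeric(end),
                  stringsAsFactors = FALSE)
  validate_gi(x)
}

validate_gi <- function(x) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (any(is.na(x$start)) || any(is.na(x$end)))
    stop("interval coordinates must be non-missing", call. = FALSE)
  if (any(x$end <= x$start))
    stop("invalid interval: end must be strictly greater than start ",
         "(0-based half-open convention)", call. = FALSE)
  if (any(x$start < 0))
    stop("invalid interval: start must be >= 0", call. = FALSE)
  class(x) <- unique(c("gi", class(x)))
  x
}

#' Interval lengths in bases
#' @param x a [gi()] interval set.
#' @return numeric vector, `end - start`.
#' @export
gi_length <- function(x) x$end - x$start

# Vectorised F-score core on raw coordinate vectors (same chromosome assumed
# already handled by caller). Returns list of precision/recall/fscore vectors.
.fscore_num <- function(rs, re, ts, te) {
  inter <- pmax(0, pmin(re, te) - pmax(rs, ts))
  lr <- re - rs
  lt <- te - ts
  p <- ifelse(inter > 0, inter / lt, 0)
  r <- ifelse(inter > 0, inter / lr, 0)
  f <- ifelse(inter > 0, 2 * p * r / (p + r), 0)
  list(precision = p, recall = r, fscore = f)
}

#' Overlap F-score between a reference and a test interval
#'
#' Measures base-level overlap quality between two spans. Precision is the
#' fraction of the *test* span covered by the reference, recall the fraction
#' of the *reference* span covered by the test, and
#' `F = 2PR/(P+R)`. Intervals with no overlap (including intervals on
#' different chromosomes) score 0 on all three components. The F-score is
#' symmetric: `F(A,B) = 2|A∩B| / (|A|+|B|)`.
#'
#' @param reference,test single-interval [gi()] objects (one row each).
#' @return A list of class `"overlap_score"` with elements `precision`,
#'   `recall` and `fscore`, each in `[0, 1]`.
#' @export
#' @examples
#' fscore(gi("chr1", 0, 100), gi("chr1", 0, 50))$fscore  # 2*0.5/1.5
fscore <- function(reference, test) {
  reference <- validate_gi(reference)
  test <- validate_gi(test)
  stopifnot(nrow(reference) == 1L, nrow(test) == 1L)
  if (reference$chrom != test$chrom) {
    s <- list(precision = 0, recall = 0, fscore = 0)
  } else {
    s <- .fscore_num(reference$start, reference$end, test$start, test$end)
    s <- lapply(s, as.numeric)
  }
  structure(s, class = "overlap_score")
}

#' @export
print.overlap_score <- function(x, ...) {
  cat(sprintf("overlap score: P=%.4f R=%.4f F=%.4f\n",
              x$precision, x$recall, x$fscore))
  invisible(x)
}

#' F-score of one reference interval against each interval in a set
#'
#' Vectorised companion to [fscore()]: returns the per-interval F-score of
#' `reference` against every row of `x` (0 where chromosomes differ).
#'
#' @param reference single-row [gi()].
#' @param x a [gi()] interval set.
#' @return numeric vector of length `nrow(x)`.
#' @export
fscore_each <- function(reference, x) {
  reference <- validate_gi(reference)
  x <- validate_gi(x)
  stopifnot(nrow(reference) == 1L)
  if (nrow(x) == 0L) return(numeric(0))
  f <- .fscore_num(reference$start, reference$end, x$start, x$end)$fscore
  f[x$chrom != reference$chrom] <- 0
  f
}

#' Merge an interval set into its union
#'
#' Returns sorted, per-chromosome, non-overlapping maximal intervals covering
#' exactly the union of the input; abutting intervals (`end == start`) are
#' merged. Backed by `IRanges::reduce`.
#'
#' @param x a [gi()] interval set (may be unsorted / overlapping).
#' @return a [gi()] interval set.
#' @export
merge_intervals <- function(x) {
  x <- validate_gi(x)
  if (nrow(x) == 0L) return(gi())
  parts <- lapply(split(x, x$chrom), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(start = d$start + 1, end = d$end))
    data.frame(chrom = d$chrom[1],
               start = IRanges::start(ir) - 1,
               end = IRanges::end(ir),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts[order(names(parts))])
  rownames(out) <- NULL
  validate_gi(out)
}

#' Best single-region F-score of a reference against a region set
#'
#' Scores `reference` against every region and returns the best-scoring
#' region's overlap score (zero score if the set is empty). Regions are
#' expected to be pre-merged (non-overlapping); a variant overlapping several
#' regions is judged by the maximum single-region F-score, not by the F-score
#' against their union.
#'
#' @param reference single-row [gi()].
#' @param regions a [gi()] interval set.
#' @return list of class `"overlap_score"` with an extra element `index`
#'   (row index of the best region in `regions`, `NA` if empty/zero).
#' @export
max_fscore_against_set <- function(reference, regions) {
  f <- fscore_each(reference, regions)
  if (length(f) == 0L || max(f) == 0) {
    return(structure(list(precision = 0, recall = 0, fscore = 0,
                          index = NA_integer_),
                     class = "overlap_score"))
  }
  i <- which.max(f)
  s <- fscore(reference, regions[i, , drop = FALSE])
  s$index <- i
  s
}

#' Read a BED file as an interval set
#'
#' BED is 0-based half-open, matching the internal convention.
#' @param path path to a BED file.
#' @return a [gi()] interval set; a `name` column is kept when present.
#' @export
read_bed <- function(path) {
  g <- rtracklayer::import(path, format = "BED")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
                    start = GenomicRanges::start(g) - 1,
                    end = GenomicRanges::end(g),
                    stringsAsFactors = FALSE)
  nm <- S4Vectors::mcols(g)$name
  out <- validate_gi(out)
  if (!is.null(nm)) out$name <- as.character(nm)
  out
}

#' Write an interval set as BED
#' @param x a [gi()] interval set; optional `name` column is exported.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- validate_gi(x)
  g <- GenomicRanges::GRanges(x$chrom,
                              IRanges::IRanges(start = x$start + 1, end = x$end))
  if (!is.null(x$name)) S4Vectors::mcols(g)$name <- x$name
  rtracklayer::export(g, path, format = "BED")
  invisible(path)
}
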