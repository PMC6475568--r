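# Binned GC-content / mappability tracks: loading, local-regression
# smoothing, data-driven threshold selection, and segmentation of
# chromosomes into bias-suspicious regions.

#' Construct a binned track
#'
#' A fixed-bin-size per-chromosome value track. Bin `i` (1-based in R)
#' covers `[origin + (i-1)*bin_size, origin + i*bin_size)`. GC and
#' mappability values are fractions in `[0, 1]`; `NA` marks missing bins
#' (assembly gaps). Coverage-style tracks may opt out of the `[0, 1]`
#' range check with `range01 = FALSE`.
#'
#' @param chrom chromosome identifier.
#' @param values numeric vector of per-bin values (`NA` allowed).
#' @param bin_size bases per bin (default 100).
#' @param origin 0-based start of the first bin (default 0).
#' @param range01 enforce values in `[0, 1]`? Default `TRUE`.
#' @return list of class `"binned_track"`.
#' @export
binned_track <- function(chrom, values, bin_size = 100, origin = 0,
                         range01 = TRUE) {
  stopifnot(length(chrom) == 1L, bin_size >= 1, origin >= 0)
  values <- as.numeric(values)
  if (range01) {
    bad <- !is.na(values) & (values < 0 | values > 1)
    if (any(bad))
      stop("track values must lie in [0, 1] (", sum(bad), " offending bins)",
           call. = FALSE)
  }
  structure(list(chrom = as.character(chrom), bin_size = as.numeric(bin_size),
                 origin = as.numeric(origin), values = values,
                 range01 = isTRUE(range01)),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf("binned_track %s: %d bins of %g bp from %g (%d missing)\n",
              x$chrom, length(x$values), x$bin_size, x$origin,
              sum(is.na(x$values))))
  invisible(x)
}

# 0-based genomic interval of bins i..j (1-based bin indices)
.track_span <- function(track, i, j) {
  gi(track$chrom,
     track$origin + (i - 1) * track$bin_size,
     track$origin + j * track$bin_size)
}

.tricube <- function(u) ifelse(abs(u) < 1, (1 - abs(u)^3)^3, 0)

#' Locally weighted (LOESS-style) smoothing of a binned track
#'
#' Degree-1 locally weighted regression with tricube weights over a sliding
#' window of `window_bins` bins, evaluated at each bin centre. Missing bins
#' are excluded from every fit and remain missing in the output. For
#' interior windows with no missing values the symmetric design makes the
#' fitted centre value a fixed tricube-weighted mean, which is computed as a
#' linear filter; edge bins and windows touching missing values fall back to
#' an explicit weighted least-squares fit. Output is clipped to `[0, 1]`
#' for `range01` tracks.
#'
#' @param track a [binned_track()].
#' @param window_bins odd integer >= 3, window width in bins (default 11,
#'   i.e. ~1.1 kb at 100 bp bins; see the methods vignette for why this and
#'   not a multi-kb window).
#' @return a [binned_track()] with identical geometry.
#' @export
loess_smooth <- function(track, window_bins = 11) {
  stopifnot(inherits(track, "binned_track"))
  window_bins <- as.integer(window_bins)
  if (window_bins < 3L || window_bins %% 2L == 0L)
    stop("window_bins must be an odd integer >= 3", call. = FALSE)
  v <- track$values
  n <- length(v)
  n_ok <- sum(!is.na(v))
  if (n_ok < window_bins)
    stop("track too short to smooth: needs at least ", window_bins,
         " non-missing bins, has ", n_ok, call. = FALSE)
  h <- (window_bins - 1L) / 2L
  w <- .tricube((-h:h) / (h + 1))
  out <- rep(NA_real_, n)

  # fast path: full interior windows free of NA
  smoothed <- stats::filter(v, w / sum(w), sides = 2)
  ok <- !is.na(smoothed)
  out[ok] <- smoothed[ok]

  # slow path: edges and NA-contaminated windows, explicit WLS at centre
  redo <- which(is.na(out) & !is.na(v))
  for (i in redo) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    idx <- lo:hi
    keep <- idx[!is.na(v[idx])]
    if (length(keep) == 0L) next
    wi <- .tricube((keep - i) / (h + 1))
    x <- keep - i
    sw <- sum(wi); sx <- sum(wi * x); sxx <- sum(wi * x * x)
    sy <- sum(wi * v[keep]); sxy <- sum(wi * x * v[keep])
    det <- sw * sxx - sx * sx
    if (length(keep) >= 2L && det > 1e-12 * sw * sxx + 1e-300) {
      # fitted value at x = 0 is the intercept of the weighted line
      out[i] <- (sxx * sy - sx * sxy) / det
    } else {
      out[i] <- sy / sw
    }
  }
  out[is.na(v)] <- NA_real_
  if (track$range01) out <- pmin(1, pmax(0, out))
  binned_track(track$chrom, out, track$bin_size, track$origin,
               range01 = track$range01)
}

#' Data-driven GC thresholds from a value distribution
#'
#' Empirical quantiles such that the left and right tails each cover
#' `tail_fraction` of the distribution (default 5% per tail, as used for the
#' genome-wide GC distribution). Quantiles use the linear-interpolation
#' definition (`stats::quantile` type 7).
#'
#' @param values numeric vector of GC fractions (NA dropped).
#' @param tail_fraction per-tail area (default 0.05).
#' @return named numeric vector `c(th1, th2)` with `th1 < th2`.
#' @export
select_gc_thresholds <- function(values, tail_fraction = 0.05) {
  values <- values[!is.na(values)]
  stopifnot(tail_fraction > 0, tail_fraction < 0.5)
  if (length(values) < 100L)
    stop("need at least 100 non-missing values to place GC thresholds, have ",
         length(values), call. = FALSE)
  q <- stats::quantile(values, c(tail_fraction, 1 - tail_fraction),
                       names = FALSE, type = 7)
  if (!(q[1] < q[2]))
    stop("degenerate value distribution: lower and upper GC thresholds ",
         "coincide (", format(q[1]), ")", call. = FALSE)
  c(th1 = q[1], th2 = q[2])
}

#' Data-driven mappability threshold
#'
#' Values exactly 0 or exactly 1 (which dominate real mappability tracks)
#' are excluded; the threshold is the quantile of the remaining values whose
#' right tail covers `right_area` of their distribution (default 20%).
#'
#' @param values numeric vector of mappability scores (NA dropped).
#' @param right_area right-tail area above the threshold (default 0.20).
#' @return numeric scalar `th3`.
#' @export
select_mappability_threshold <- function(values, right_area = 0.20) {
  values <- values[!is.na(values)]
  stopifnot(right_area > 0, right_area < 1)
  keep <- values[values != 0 & values != 1]
  if (length(keep) < 100L)
    stop("need at least 100 values strictly between 0 and 1 to place the ",
         "mappability threshold, have ", length(keep), call. = FALSE)
  stats::quantile(keep, 1 - right_area, names = FALSE, type = 7)
}

#' Bundle segmentation thresholds
#'
#' @param th1,th2 GC lower/upper thresholds (`th1 < th2`).
#' @param th3 mappability threshold.
#' @return list of class `"threshold_set"`.
#' @export
threshold_set <- function(th1, th2, th3) {
  stopifnot(th1 < th2, th1 >= 0, th2 <= 1, th3 >= 0, th3 <= 1)
  structure(list(th1 = th1, th2 = th2, th3 = th3), class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("thresholds: GC < %.4f or > %.4f; mappability < %.4f\n",
              x$th1, x$th2, x$th3))
  invisible(x)
}

.violates <- function(values, cause, th) {
  switch(cause,
         gc_low = values < th$th1,
         gc_high = values > th$th2,
         low_mappability = values < th$th3,
         stop("unknown cause: ", cause))
}

#' Segment a smoothed track into suspicious regions
#'
#' Bins are marked suspicious where the smoothed value falls beyond the
#' relevant threshold (`< th1` or `> th2` for GC; `< th3` for mappability);
#' missing bins are never suspicious and break runs. Maximal runs of
#' suspicious bins form candidates; each run is refined to its longest
#' contiguous subrun of RAW-violating bins (smoothing smears shallow edges
#' outward, so the raw signal sets the boundaries), and the refined run is
#' emitted only if its span is strictly longer than `min_length` bases AND
#' the mean of the raw values over the span still violates the threshold.
#'
#' @param smoothed a [loess_smooth()]-ed [binned_track()].
#' @param thresholds a [threshold_set()].
#' @param kind `"gc"` or `"mappability"`.
#' @param raw the unsmoothed track (same geometry); defaults to `smoothed`.
#' @param min_length minimum span in bases, strict (default 500).
#' @return data.frame of class `"suspicious_regions"` with columns `chrom`,
#'   `start`, `end`, `cause` (`gc_low`/`gc_high`/`low_mappability`) and
#'   `mean_value` (raw mean over the span).
#' @export
segment_suspicious <- function(smoothed, thresholds,
                               kind = c("gc", "mappability"),
                               raw = smoothed, min_length = 500) {
  kind <- match.arg(kind)
  stopifnot(inherits(smoothed, "binned_track"), inherits(raw, "binned_track"),
            inherits(thresholds, "threshold_set"),
            length(raw$values) == length(smoothed$values),
            raw$bin_size == smoothed$bin_size, raw$origin == smoothed$origin)
  v <- smoothed$values
  flag <- if (kind == "gc") (v < thresholds$th1 | v > thresholds$th2)
          else v < thresholds$th3
  flag[is.na(flag)] <- FALSE

  out <- list()
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    i <- starts[k]; j <- ends[k]
    cause <- if (kind == "mappability") "low_mappability"
             else if (mean(v[i:j], na.rm = TRUE) < thresholds$th1) "gc_low"
             else "gc_high"
    rv <- raw$values[i:j]
    viol <- .violates(rv, cause, thresholds)
    viol[is.na(viol)] <- FALSE
    if (!any(viol)) next
    # refine to the longest contiguous raw-violating subrun: smoothing
    # smears shallow edges outward, and isolated raw crossings in the
    # smeared margin must not drag the boundary with them
    vr <- rle(viol)
    vends <- cumsum(vr$lengths)
    vstarts <- vends - vr$lengths + 1L
    cand <- which(vr$values)
    best <- cand[which.max(vr$lengths[cand])]
    i2 <- i + vstarts[best] - 1L
    j2 <- i + vends[best] - 1L
    if ((j2 - i2 + 1L) * smoothed$bin_size <= min_length) next
    m <- mean(raw$values[i2:j2], na.rm = TRUE)
    if (!isTRUE(.violates(m, cause, thresholds))) next
    span <- .track_span(smoothed, i2, j2)
    out[[length(out) + 1L]] <- data.frame(
      chrom = span$chrom, start = span$start, end = span$end,
      cause = cause, mean_value = m, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(chrom = character(), start = numeric(),
                         end = numeric(), cause = character(),
                         mean_value = numeric(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("suspicious_regions", class(res))
  res
}

#' Combine GC- and mappability-derived suspicious regions
#'
#' @param gc_regions,map_regions outputs of [segment_suspicious()] (either
#'   may be empty); additional region sets may be passed via `...`.
#' @return list with `regions` (merged union as a [gi()] set, sorted) and
#'   `details` (row-bound cause-annotated input regions).
#' @export
build_suspicious_regions <- function(gc_regions, map_regions, ...) {
  details <- do.call(rbind, c(list(as.data.frame(gc_regions),
                                   as.data.frame(map_regions)),
                              lapply(list(...), as.data.frame)))
  if (is.null(details) || nrow(details) == 0L) {
    return(list(regions = gi(),
                details = data.frame(chrom = character(), start = numeric(),
                                     end = numeric(), cause = character(),
                                     mean_value = numeric())))
  }
  details <- details[order(details$chrom, details$start, details$end), ]
  rownames(details) <- NULL
  list(regions = merge_intervals(gi(details$chrom, details$start, details$end)),
       details = details)
}

#' Read binned tracks from a bedGraph file
#'
#' Intervals must form uniform bins of `bin_size` bases (gaps become missing
#' bins; unequal bin sizes are rejected — the segmentation assumes uniform
#' bins). Returns one track per chromosome.
#'
#' @param path bedGraph path.
#' @param bin_size expected bin size (default 100).
#' @param range01 passed to [binned_track()].
#' @return named list of [binned_track()], keyed by chromosome.
#' @export
read_bedgraph_track <- function(path, bin_size = 100, range01 = TRUE) {
  g <- rtracklayer::import(path, format = "bedGraph")
  d <- data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
                  start = GenomicRanges::start(g) - 1,
                  end = GenomicRanges::end(g),
                  score = as.numeric(S4Vectors::mcols(g)$score),
                  stringsAsFactors = FALSE)
  if (nrow(d) == 0L) stop("empty bedGraph: ", path, call. = FALSE)
  if (any(d$end - d$start != bin_size))
    stop("bedGraph bins are not uniformly ", bin_size, " bp: ", path,
         call. = FALSE)
  if (any(d$start %% bin_size != 0))
    stop("bedGraph bins are not aligned to the ", bin_size, " bp grid: ",
         path, call. = FALSE)
  lapply(split(d, d$chrom), function(x) {
    x <- x[order(x$start), ]
    n <- max(x$start) / bin_size + 1
    vals <- rep(NA_real_, n)
    vals[x$start / bin_size + 1] <- x$score
    binned_track(x$chrom[1], vals, bin_size, origin = 0, range01 = range01)
  })
}

#' Write a binned track as bedGraph
#'
#' Missing bins are omitted from the file (bedGraph gaps).
#' @param track a [binned_track()].
#' @param path output path.
#' @param append append to an existing file? (used to write multi-chromosome
#'   files track by track)
#' @return `path`, invisibly.
#' @export
write_bedgraph_track <- function(track, path, append = FALSE) {
  stopifnot(inherits(track, "binned_track"))
  i <- which(!is.na(track$values))
  d <- data.table::data.table(
    chrom = track$chrom,
    start = track$origin + (i - 1) * track$bin_size,
    end = track$origin + i * track$bin_size,
    score = track$values[i])
  data.table::fwrite(d, path, sep = "\t", col.names = FALSE,
                     append = append, scipen = 50)
  invisible(path)
}

#' Write a threshold sidecar file
#' @param thresholds a [threshold_set()].
#' @param path output path (tab-separated `name value`).
#' @return `path`, invisibly.
#' @export
write_thresholds <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "threshold_set"))
  utils::write.table(
    data.frame(name = c("th1", "th2", "th3"),
               value = c(thresholds$th1, thresholds$th2, thresholds$th3)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
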