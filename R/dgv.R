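# DGV-style supporting-variant tables: parsing, the deletion filters,
# duplicate merging, and suspicious flagging by overlap with bias regions.

.dgv_required <- c("variantaccession", "chr", "start", "end", "varianttype",
                   "variantsubtype", "reference", "method", "samples")

.norm_chrom <- function(x) {
  x <- trimws(as.character(x))
  ifelse(grepl("^chr", x, ignore.case = FALSE), x, paste0("chr", x))
}

.split_samples <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", as.character(x)), ","), function(s) {
    s <- trimws(s)
    s[nzchar(s)]
  })
}

#' Read a DGV-style supporting-variants table
#'
#' Tab-separated with a header naming at least: `variantaccession`, `chr`,
#' `start`, `end`, `varianttype`, `variantsubtype`, `reference`, `method`,
#' `samples` (case-insensitive; extra columns are ignored). DGV coordinates
#' are 1-based inclusive and are converted to the internal 0-based half-open
#' convention; `samples` is split on commas; chromosome labels are
#' normalised to a leading `"chr"`. Rows with non-numeric or inverted
#' coordinates are skipped with a warning.
#'
#' @param path table path.
#' @return data.frame of class `"dgv_variants"` with columns `accession`,
#'   `chrom`, `start`, `end` (0-based half-open), `variant_type`,
#'   `variant_subtype`, `method`, `reference`, and list-columns `samples`
#'   and `merged_accessions`; attribute `n_skipped` counts dropped rows.
#' @export
read_dgv_table <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  names(raw) <- tolower(names(raw))
  missing_cols <- setdiff(.dgv_required, names(raw))
  if (length(missing_cols))
    stop("DGV table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  start1 <- suppressWarnings(as.numeric(raw$start))
  end1 <- suppressWarnings(as.numeric(raw$end))
  bad <- is.na(start1) | is.na(end1) | end1 < start1 | start1 < 1
  if (any(bad))
    warning(sum(bad), " row(s) with non-numeric or inverted coordinates ",
            "skipped", call. = FALSE)
  keep <- which(!bad)
  out <- data.frame(accession = raw$variantaccession[keep],
                    chrom = .norm_chrom(raw$chr[keep]),
                    start = start1[keep] - 1,   # 1-based incl -> 0-based half-open
                    end = end1[keep],
                    variant_type = raw$varianttype[keep],
                    variant_subtype = raw$variantsubtype[keep],
                    method = raw$method[keep],
                    reference = raw$reference[keep],
                    stringsAsFactors = FALSE)
  out$samples <- .split_samples(raw$samples[keep])
  out$merged_accessions <- as.list(out$accession)
  attr(out, "n_skipped") <- sum(bad)
  class(out) <- c("dgv_variants", class(out))
  out
}

#' Variant filter configuration
#'
#' Defaults implement the deletion screen: sequencing-derived calls of
#' subtype deletion/loss, strictly smaller than 10 kbp, with a nonempty
#' sample field.
#'
#' @param required_method_token substring the `method` field must contain,
#'   case-insensitively (default `"sequencing"`).
#' @param allowed_subtypes lower-case subtypes kept (default
#'   `c("deletion", "loss")` — the two are equivalent in DGV).
#' @param max_size strict upper size bound in bases (default 10000).
#' @param require_samples drop records with an empty sample list?
#' @return list of class `"filter_config"`.
#' @export
filter_config <- function(required_method_token = "sequencing",
                          allowed_subtypes = c("deletion", "loss"),
                          max_size = 10000, require_samples = TRUE) {
  stopifnot(max_size > 0)
  structure(list(required_method_token = tolower(required_method_token),
                 allowed_subtypes = tolower(allowed_subtypes),
                 max_size = max_size,
                 require_samples = isTRUE(require_samples)),
            class = "filter_config")
}

#' Apply the deletion-screen filters
#'
#' Keeps records whose method contains the required token
#' (case-insensitive substring), whose subtype is in the allowed set, whose
#' size is strictly below `max_size`, and (optionally) whose sample list is
#' nonempty. Input order is preserved; a per-criterion rejection tally is
#' emitted as a message.
#'
#' @param variants a `dgv_variants` table.
#' @param config a [filter_config()].
#' @return the surviving rows, same class.
#' @export
filter_variants <- function(variants, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  if (nrow(variants) == 0L) return(variants)
  ok_method <- grepl(config$required_method_token, tolower(variants$method),
                     fixed = TRUE)
  ok_subtype <- tolower(variants$variant_subtype) %in% config$allowed_subtypes
  ok_size <- (variants$end - variants$start) < config$max_size
  ok_samples <- if (config$require_samples)
    vapply(variants$samples, length, 1L) > 0 else rep(TRUE, nrow(variants))
  message(sprintf(
    "filter_variants: %d in; rejected by method=%d subtype=%d size=%d samples=%d; %d kept",
    nrow(variants), sum(!ok_method), sum(!ok_subtype), sum(!ok_size),
    sum(!ok_samples), sum(ok_method & ok_subtype & ok_size & ok_samples)))
  out <- variants[ok_method & ok_subtype & ok_size & ok_samples, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge duplicated variants
#'
#' Records sharing an identical locus (`chrom`, `start`, `end`) collapse to
#' one: the lexicographically smallest accession is retained, sample lists
#' and study labels are unioned (studies joined with `";"` in sorted order),
#' and every constituent accession is recorded in `merged_accessions`.
#' Subtype differences (deletion vs loss) do not prevent merging. Output is
#' sorted by (chrom, start, end).
#'
#' @param variants a `dgv_variants` table.
#' @return merged table, same class.
#' @export
merge_duplicates <- function(variants) {
  if (nrow(variants) == 0L) return(variants)
  key <- paste(variants$chrom, variants$start, variants$end, sep = "\r")
  parts <- lapply(split(seq_len(nrow(variants)), key), function(idx) {
    d <- variants[idx, , drop = FALSE]
    lead <- order(d$accession)[1]
    r <- d[lead, , drop = FALSE]
    r$samples <- list(sort(unique(unlist(d$samples))))
    r$reference <- paste(sort(unique(d$reference)), collapse = ";")
    r$merged_accessions <- list(sort(unique(unlist(d$merged_accessions))))
    r
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- unique(c("dgv_variants", class(out)))
  out
}

#' Flag variants suspicious by overlap with bias regions
#'
#' A variant is flagged when its best single-region F-score against the
#' suspicious-region set strictly exceeds `f_threshold` (default 0.9).
#' Flagged variants are annotated with the achieved F-score and, when
#' region cause details are available, the cause of the best-matching
#' region.
#'
#' @param variants a `dgv_variants` table.
#' @param suspicious_regions either a merged [gi()] set or the list returned
#'   by [build_suspicious_regions()] (whose `details` provide causes).
#' @param f_threshold strict F-score threshold (default 0.9).
#' @return the flagged rows with extra columns `fscore` and `cause`.
#' @export
flag_suspicious <- function(variants, suspicious_regions, f_threshold = 0.9) {
  details <- NULL
  if (is.list(suspicious_regions) && !is.data.frame(suspicious_regions) &&
      !is.null(suspicious_regions$regions)) {
    details <- suspicious_regions$details
    suspicious_regions <- suspicious_regions$regions
  }
  regions <- validate_gi(as.data.frame(suspicious_regions))
  n <- nrow(variants)
  fs <- numeric(n); cause <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    v <- gi(variants$chrom[i], variants$start[i], variants$end[i])
    s <- max_fscore_against_set(v, regions)
    fs[i] <- s$fscore
    if (!is.na(s$index) && !is.null(details) && nrow(details)) {
      # cause of the detail region best overlapping the matched region
      cs <- max_fscore_against_set(regions[s$index, , drop = FALSE],
                                   gi(details$chrom, details$start, details$end))
      if (!is.na(cs$index)) cause[i] <- details$cause[cs$index]
    }
  }
  keep <- fs > f_threshold
  out <- variants[keep, , drop = FALSE]
  out$fscore <- fs[keep]
  out$cause <- cause[keep]
  rownames(out) <- NULL
  out
}

#' Write flagged variants as TSV
#'
#' Coordinates are written back on the 1-based inclusive scale.
#' @param variants flagged `dgv_variants` (with `fscore`/`cause` columns).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_flagged_variants <- function(variants, path) {
  d <- data.frame(accession = variants$accession,
                  chrom = variants$chrom,
                  start = variants$start + 1,
                  end = variants$end,
                  size = variants$end - variants$start,
                  subtype = variants$variant_subtype,
                  reference = variants$reference,
                  samples = vapply(variants$samples, paste, "", collapse = ","),
                  fscore = if (is.null(variants$fscore)) NA_real_ else variants$fscore,
                  cause = if (is.null(variants$cause)) NA_character_ else variants$cause,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a flagged-variants TSV back
#'
#' Inverse of [write_flagged_variants()]; coordinates return to the
#' internal 0-based half-open convention.
#'
#' @param path TSV path.
#' @return a `dgv_variants`-shaped table with `fscore`/`cause` columns.
#' @export
read_flagged_variants <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- data.frame(accession = d$accession, chrom = d$chrom,
                    start = d$start - 1, end = d$end,
                    variant_type = "CNV", variant_subtype = d$subtype,
                    method = "sequencing", reference = d$reference,
                    stringsAsFactors = FALSE)
  out$samples <- .split_samples(d$samples)
  out$merged_accessions <- as.list(out$accession)
  out$fscore <- d$fscore
  out$cause <- d$cause
  class(out) <- c("dgv_variants", class(out))
  out
}

#' Read a sample-to-alignment manifest
#'
#' Two-column tab-separated file with header `sample<TAB>path` mapping
#' sample identifiers to coordinate-sorted, indexed alignment files.
#' Relative paths are resolved against the manifest's directory.
#'
#' @param path manifest path.
#' @return named character vector (names = sample ids, values = paths).
#' @export
read_manifest <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "path") %in% names(d)))
    stop("manifest must have columns 'sample' and 'path'", call. = FALSE)
  p <- ifelse(grepl("^/", d$path), d$path,
              file.path(dirname(normalizePath(path)), d$path))
  stats::setNames(p, d$sample)
}
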