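# Reporting: the results spreadsheet, per-variant diagnostic figures, and
# summary statistics (per-chromosome/sample/study tallies, the
# chromosome-length correlation, and a Gaussian-mixture fit of the
# false-positive log-size distribution).

#' Write the per-variant results spreadsheet
#'
#' One row per validated suspicious variant with the verdict and all
#' validation statistics; rows ordered deterministically by
#' (chrom, start, accession).
#'
#' @param results a `validation_results` table from [validate_variants()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_results_spreadsheet <- function(results, path) {
  cols <- c("accession", "sample", "chrom", "start", "end", "size",
            "subtype", "reference", "fscore", "n_pairs_in_roi",
            "n_selected", "avg_mq", "sum_mq", "verdict")
  d <- as.data.frame(results)[, cols, drop = FALSE]
  d <- d[order(d$chrom, d$start, d$accession), , drop = FALSE]
  d$start <- d$start + 1   # spreadsheet is 1-based inclusive
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a results spreadsheet back
#' @param path TSV written by [write_results_spreadsheet()].
#' @return data.frame with internal 0-based half-open coordinates.
#' @export
read_results_spreadsheet <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  d$start <- d$start - 1
  class(d) <- c("validation_results", class(d))
  d
}

#' Fit a Gaussian mixture by EM
#'
#' Expectation-maximisation for a `k`-component univariate Gaussian
#' mixture, initialised from a seeded k-means partition. The log-likelihood
#' is non-decreasing across iterations (asserted).
#'
#' @param x numeric vector (here: log10 variant sizes).
#' @param k number of components (default 3).
#' @param seed seed for the k-means initialisation.
#' @param max_iter,tol EM stopping controls.
#' @return list with `means`, `sds`, `weights` (each length `k`, sorted by
#'   mean), `loglik` (final), `loglik_trace`, `n_iter`.
#' @export
fit_gaussian_mixture <- function(x, k = 3, seed = 1, max_iter = 500,
                                 tol = 1e-8) {
  x <- x[is.finite(x)]
  if (length(unique(x)) < k)
    stop("need at least ", k, " distinct values to fit a ", k,
         "-component mixture", call. = FALSE)
  set.seed(seed)
  km <- suppressWarnings(stats::kmeans(x, centers = k, nstart = 10))
  mu <- as.numeric(km$centers)
  sd0 <- vapply(seq_len(k), function(j) {
    s <- stats::sd(x[km$cluster == j])
    if (is.na(s) || s < 1e-3) 1e-3 else s
  }, 0)
  w <- as.numeric(table(factor(km$cluster, levels = seq_len(k)))) / length(x)
  w <- pmax(w, 1e-6); w <- w / sum(w)
  loglik <- -Inf; trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j)
      w[j] * stats::dnorm(x, mu[j], sd0[j]), numeric(length(x)))
    rowsum_ <- pmax(rowSums(dens), 1e-300)
    ll <- sum(log(rowsum_))
    if (length(trace) && ll < trace[length(trace)] - 1e-6)
      stop("internal: EM log-likelihood decreased", call. = FALSE)
    trace <- c(trace, ll)
    if (is.finite(loglik) && abs(ll - loglik) < tol) break
    loglik <- ll
    resp <- dens / rowsum_
    nk <- pmax(colSums(resp), 1e-12)
    mu <- colSums(resp * x) / nk
    sd0 <- vapply(seq_len(k), function(j)
      sqrt(sum(resp[, j] * (x - mu[j])^2) / nk[j]), 0)
    sd0 <- pmax(sd0, 1e-3)
    w <- nk / length(x)
  }
  o <- order(mu)
  list(means = mu[o], sds = sd0[o], weights = w[o],
       loglik = trace[length(trace)], loglik_trace = trace,
       n_iter = length(trace))
}

#' Summary statistics over validation results
#'
#' Per-chromosome, per-sample and per-study tallies of suspicious variants
#' and false positives; Pearson correlation between chromosome length and
#' false-positive count; a seeded 3-component Gaussian mixture fitted to
#' log10 of the false-positive sizes (component means also reported in bp).
#' Unresolvable variants are tallied separately and excluded from verdicts.
#'
#' @param results a `validation_results` table.
#' @param chrom_lengths named numeric vector of chromosome lengths in bases
#'   (chromosomes absent from `results` count zero false positives).
#' @param mixture_seed seed for the mixture initialisation.
#' @return list of class `"pem_summary"`.
#' @export
summarize_results <- function(results, chrom_lengths = NULL,
                              mixture_seed = 1) {
  d <- as.data.frame(results)
  unresolved <- d[d$verdict == "unresolvable", , drop = FALSE]
  d <- d[d$verdict != "unresolvable", , drop = FALSE]
  fp <- d[d$verdict == "false_positive", , drop = FALSE]
  tally <- function(key) {
    ks <- sort(unique(d[[key]]))
    data.frame(level = ks,
               suspicious = as.integer(table(factor(d[[key]], levels = ks))),
               false_positive = as.integer(table(factor(fp[[key]], levels = ks))),
               stringsAsFactors = FALSE)
  }
  per_chromosome <- tally("chrom")
  per_sample <- tally("sample")
  per_study <- tally("reference")

  correlation <- list(r = NA_real_, p = NA_real_, n = 0L)
  if (!is.null(chrom_lengths)) {
    chroms <- intersect(names(chrom_lengths), unique(d$chrom))
    if (length(chroms) >= 3) {
      fp_count <- vapply(chroms, function(ch) sum(fp$chrom == ch), 0L)
      len <- as.numeric(chrom_lengths[chroms])
      if (stats::sd(len) > 0 && stats::sd(fp_count) > 0) {
        ct <- stats::cor.test(len, fp_count, method = "pearson")
        correlation <- list(r = unname(ct$estimate), p = ct$p.value,
                            n = length(chroms))
      }
    }
  }

  mixture <- NULL
  sizes <- fp$size
  if (length(unique(sizes)) >= 3) {
    mixture <- fit_gaussian_mixture(log10(sizes), k = 3, seed = mixture_seed)
    mixture$means_bp <- 10^mixture$means
  } else if (length(sizes)) {
    warning("fewer than 3 distinct false-positive sizes; mixture fit skipped",
            call. = FALSE)
  }

  structure(list(n_suspicious = nrow(d), n_false_positive = nrow(fp),
                 n_unresolvable = nrow(unresolved),
                 per_chromosome = per_chromosome, per_sample = per_sample,
                 per_study = per_study, size_log10 = log10(fp$size),
                 chromosome_length_correlation = correlation,
                 size_modality_fit = mixture),
            class = "pem_summary")
}

#' @export
print.pem_summary <- function(x, ...) {
  cat(sprintf("suspicious: %d   false positives: %d   unresolvable: %d\n",
              x$n_suspicious, x$n_false_positive, x$n_unresolvable))
  if (!is.na(x$chromosome_length_correlation$r))
    cat(sprintf("chromosome-length correlation: r=%.3f p=%.3g (n=%d)\n",
                x$chromosome_length_correlation$r,
                x$chromosome_length_correlation$p,
                x$chromosome_length_correlation$n))
  if (!is.null(x$size_modality_fit))
    cat("size modalities (bp): ",
        paste(sprintf("%.0f", x$size_modality_fit$means_bp), collapse = " / "),
        "\n", sep = "")
  invisible(x)
}

#' Write the summary as TSV + JSON
#' @param summary a [summarize_results()] object.
#' @param prefix output path prefix (writes `<prefix>_chromosome.tsv`,
#'   `<prefix>_sample.tsv`, `<prefix>_study.tsv`, `<prefix>.json`).
#' @return the JSON path, invisibly.
#' @export
write_summary <- function(summary, prefix) {
  utils::write.table(summary$per_chromosome,
                     paste0(prefix, "_chromosome.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(summary$per_sample, paste0(prefix, "_sample.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(summary$per_study, paste0(prefix, "_study.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  out <- list(
    n_suspicious = summary$n_suspicious,
    n_false_positive = summary$n_false_positive,
    n_unresolvable = summary$n_unresolvable,
    chromosome_length_correlation = summary$chromosome_length_correlation,
    size_modality_fit = if (is.null(summary$size_modality_fit)) NULL else
      summary$size_modality_fit[c("means", "sds", "weights", "means_bp",
                                  "loglik", "n_iter")])
  json <- paste0(prefix, ".json")
  jsonlite::write_json(out, json, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(json)
}

.plot_track_panel <- function(track, roi, variant, col, ylab, ylim = NULL) {
  i <- which(!is.na(track$values))
  xs <- track$origin + (i - 0.5) * track$bin_size
  keep <- xs >= roi$start & xs <= roi$end
  if (is.null(ylim)) {
    ylim <- if (track$range01) c(0, 1)
            else c(0, max(1, track$values[i][keep]) * 1.05)
  }
  graphics::plot(NA, xlim = c(roi$start, roi$end), ylim = ylim,
                 xlab = "", ylab = ylab, xaxs = "i", las = 1)
  graphics::rect(variant$start, ylim[1], variant$end, ylim[2],
                 col = grDevices::adjustcolor("green3", 0.35), border = NA)
  graphics::lines(xs[keep], track$values[i][keep], col = col, lwd = 1.2)
}

#' Diagnostic four-panel figure for one variant
#'
#' Left column: GC content, mappability and depth of coverage over the
#' region of interest, with the variant shown as a green bar. Right panel:
#' the paired-end mapping signature — one horizontal line per selected read
#' pair at its outer span, colour-graded from yellow (low pair quality) to
#' black (high). An empty right panel is the visual signature of a false
#' positive.
#'
#' @param variant single-row [gi()].
#' @param gc_track,map_track [binned_track()]s covering the ROI.
#' @param doc_profile coverage [binned_track()] from [compute_doc()].
#' @param pairs `read_pairs` table (typically the selected pairs).
#' @param path output PNG path (named by accession upstream).
#' @param roi optional explicit ROI; defaults to the DOC profile's extent.
#' @param max_quality quality mapped to black (default 60).
#' @return `path`, invisibly.
#' @export
plot_variant <- function(variant, gc_track, map_track, doc_profile, pairs,
                         path, roi = NULL, max_quality = 60) {
  variant <- validate_gi(variant)
  if (is.null(roi))
    roi <- gi(doc_profile$chrom, doc_profile$origin,
              doc_profile$origin +
                length(doc_profile$values) * doc_profile$bin_size)
  grDevices::png(path, width = 1000, height = 620)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::layout(matrix(c(1, 4, 2, 4, 3, 4), 3, 2, byrow = TRUE),
                   widths = c(1.1, 1))
  old <- graphics::par(mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(old), add = TRUE)
  .plot_track_panel(gc_track, roi, variant, "magenta", "GC content")
  .plot_track_panel(map_track, roi, variant, "red", "mappability")
  .plot_track_panel(doc_profile, roi, variant, "blue", "DOC", ylim = NULL)
  n <- nrow(pairs)
  graphics::plot(NA, xlim = c(roi$start, roi$end),
                 ylim = c(0, max(1, n) + 1), xlab = "", ylab = "read pairs",
                 xaxs = "i", yaxt = "n")
  graphics::rect(variant$start, 0, variant$end, max(1, n) + 1,
                 col = grDevices::adjustcolor("green3", 0.35), border = NA)
  if (n > 0) {
    ramp <- grDevices::colorRampPalette(c("yellow2", "black"))(101)
    q <- pairs$pair_quality
    if (is.null(q)) q <- pmin(pairs$mapq1, pairs$mapq2)
    ci <- pmin(100, pmax(0, round(100 * q / max_quality))) + 1
    ord <- order(pairs$outer_start)
    graphics::segments(pairs$outer_start[ord], seq_len(n),
                       pairs$outer_end[ord], seq_len(n),
                       col = ramp[ci[ord]], lwd = 2)
  }
  invisible(path)
}

#' Render diagnostic figures for a set of validated variants
#'
#' @param results a `validation_results` table (with its `pair_sets`
#'   attribute).
#' @param gc_tracks,map_tracks named lists of [binned_track()] per
#'   chromosome.
#' @param manifest named character vector of alignment paths.
#' @param fig_dir output directory; files are named `<accession>.png`.
#' @param config a [validation_config()] (for the ROI geometry).
#' @return character vector of figure paths, invisibly.
#' @export
plot_all_variants <- function(results, gc_tracks, map_tracks, manifest,
                              fig_dir, config = validation_config()) {
  dir.create(fig_dir, recursive = TRUE, showWarnings = FALSE)
  pair_sets <- attr(results, "pair_sets")
  d <- as.data.frame(results)
  paths <- character(0)
  for (i in seq_len(nrow(d))) {
    if (d$verdict[i] == "unresolvable") next
    v <- gi(d$chrom[i], d$start[i], d$end[i])
    bam <- manifest[[d$sample[i]]]
    targets <- Rsamtools::scanBamHeader(Rsamtools::BamFile(bam))$targets
    clen <- if (v$chrom %in% names(targets)) as.numeric(targets[[v$chrom]])
            else Inf
    roi <- compute_roi(v, pad = config$roi_pad,
                       chrom_length = max(clen, v$end))
    doc <- compute_doc(bam, roi)
    gt <- gc_tracks[[v$chrom]]; mt <- map_tracks[[v$chrom]]
    p <- file.path(fig_dir, paste0(d$accession[i], ".png"))
    plot_variant(v, gt, mt, doc, pair_sets[[d$accession[i]]], p, roi = roi)
    paths <- c(paths, p)
  }
  invisible(paths)
}
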