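# End-to-end driver: profile tracks -> suspicious regions -> DGV filtering
# and flagging -> paired-end validation -> spreadsheet, summary, figures.

#' Run the full false-positive screen
#'
#' Chains the pipeline stages: loads binned GC and mappability tracks,
#' selects data-driven thresholds from the raw value distributions, smooths
#' and segments each chromosome into suspicious regions, parses and filters
#' the variant table, merges duplicates, flags variants lying in suspicious
#' regions (F-score > `flag_f_threshold`), and validates every flagged
#' variant against the paired-end evidence in the manifest's alignment
#' files. Results, regions, thresholds and summary files are written under
#' `out_dir`.
#'
#' @param gc_path,map_path bedGraph paths for the binned GC and mappability
#'   tracks.
#' @param dgv_path DGV-style supporting-variants TSV.
#' @param manifest_path sample-to-alignment manifest (see
#'   [read_manifest()]).
#' @param out_dir output directory.
#' @param bin_size track bin size (default 100).
#' @param window_bins smoothing window (default 11 bins).
#' @param gc_tails,map_right_area threshold-selection tail areas (defaults
#'   0.05 and 0.20).
#' @param min_region_length strict minimum suspicious-segment length
#'   (default 500 bases).
#' @param flag_f_threshold strict variant-flagging F-score cut (default
#'   0.9).
#' @param filter a [filter_config()].
#' @param validation a [validation_config()].
#' @param make_figures render per-variant diagnostic figures under
#'   `out_dir/fig`? (default `FALSE`; figures are slow at scale)
#' @return list with `thresholds`, `regions`, `flagged`, `results`,
#'   `summary` and the written `paths`.
#' @export
run_pipeline <- function(gc_path, map_path, dgv_path, manifest_path, out_dir,
                         bin_size = 100, window_bins = 11, gc_tails = 0.05,
                         map_right_area = 0.20, min_region_length = 500,
                         flag_f_threshold = 0.9,
                         filter = filter_config(),
                         validation = validation_config(),
                         make_figures = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gc_tracks <- read_bedgraph_track(gc_path, bin_size = bin_size)
  map_tracks <- read_bedgraph_track(map_path, bin_size = bin_size)

  thresholds <- threshold_set(
    th1 = select_gc_thresholds(unlist(lapply(gc_tracks, `[[`, "values")),
                               gc_tails)[["th1"]],
    th2 = select_gc_thresholds(unlist(lapply(gc_tracks, `[[`, "values")),
                               gc_tails)[["th2"]],
    th3 = select_mappability_threshold(
      unlist(lapply(map_tracks, `[[`, "values")), map_right_area))
  message(sprintf("thresholds: th1=%.4f th2=%.4f th3=%.4f",
                  thresholds$th1, thresholds$th2, thresholds$th3))

  seg <- list()
  for (ch in names(gc_tracks)) {
    sm <- loess_smooth(gc_tracks[[ch]], window_bins)
    seg[[paste0(ch, ".gc")]] <-
      segment_suspicious(sm, thresholds, "gc", raw = gc_tracks[[ch]],
                         min_length = min_region_length)
  }
  for (ch in names(map_tracks)) {
    sm <- loess_smooth(map_tracks[[ch]], window_bins)
    seg[[paste0(ch, ".map")]] <-
      segment_suspicious(sm, thresholds, "mappability",
                         raw = map_tracks[[ch]],
                         min_length = min_region_length)
  }
  suspicious <- do.call(build_suspicious_regions, unname(seg))
  message(nrow(suspicious$regions), " suspicious region(s)")

  variants <- read_dgv_table(dgv_path)
  variants <- filter_variants(variants, filter)
  variants <- merge_duplicates(variants)
  flagged <- flag_suspicious(variants, suspicious,
                             f_threshold = flag_f_threshold)
  message(nrow(flagged), " suspicious variant(s) flagged for validation")

  manifest <- read_manifest(manifest_path)
  results <- validate_variants(flagged, manifest, validation)

  chrom_lengths <- vapply(gc_tracks, function(t)
    t$origin + length(t$values) * t$bin_size, 0)
  summary <- summarize_results(results, chrom_lengths)

  paths <- list(
    thresholds = write_thresholds(thresholds,
                                  file.path(out_dir, "thresholds.tsv")),
    regions = write_bed(
      if (nrow(suspicious$regions)) suspicious$regions else gi(),
      file.path(out_dir, "suspicious_regions.bed")),
    flagged = write_flagged_variants(flagged,
                                     file.path(out_dir, "flagged.tsv")),
    results = write_results_spreadsheet(results,
                                        file.path(out_dir, "results.tsv")),
    summary = write_summary(summary, file.path(out_dir, "summary")))
  if (isTRUE(make_figures) && nrow(as.data.frame(results)) > 0)
    paths$figures <- plot_all_variants(results, gc_tracks, map_tracks,
                                       manifest, file.path(out_dir, "fig"),
                                       validation)
  list(thresholds = thresholds, regions = suspicious, flagged = flagged,
       results = results, summary = summary, paths = paths)
}
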