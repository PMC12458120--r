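#' Run the full synthetic pipeline end to end
#'
#' Executes every stage in order against one simulated data set: simulate
#' (annotation, tracks, beta matrix, screen plate) -> replicate response ->
#' differential calling and width-mixture shape classification -> chromatin
#' state condensation and enrichment bias -> proximity linking, k-means
#' signal clustering and a profile matrix -> DMR calling -> screen hit
#' calling. All intermediate files are written to `out_dir` in plain-text
#' formats (bedGraph, BED, TSV), the configuration is echoed as YAML, and a
#' JSON manifest records the seed, per-stage summary counts and an MD5 of
#' every output file. With a fixed seed the run is bit-reproducible.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [sim_config()]; its `seed` drives every stage.
#' @param link_window Linking window in bp between called gains and the
#'   second-mark peaks (default 10000).
#' @param mark A [mark_config()] used for differential calling.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_demo <- function(out_dir, config = sim_config(),
                     link_window = 10000,
                     mark = mark_config("h3k27ac")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(...) file.path(out_dir, ...)
  cfg_echo <- config
  cfg_echo$chrom_lengths <- as.list(cfg_echo$chrom_lengths)
  cfg_echo$state_props <- as.list(cfg_echo$state_props)
  yaml::write_yaml(unclass(cfg_echo), path("config.yaml"))

  # --- simulate -----------------------------------------------------------
  annotation <- simulate_annotation(config)
  sim <- simulate_tracks(config)
  meth <- simulate_beta(config)
  scr <- simulate_screen(config)
  write_bed(annotation, path("annotation.bed"))
  write_bed(sim$peaks, path("peaks.bed"))
  utils::write.table(sim$truth, path("truth_peaks.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (arm in names(sim$tracks)) {
    for (r in seq_along(sim$tracks[[arm]])) {
      write_bedgraph(sim$tracks[[arm]][[r]],
                     path(sprintf("%s_rep%d.bedGraph", arm, r)))
    }
  }
  write_beta_matrix(meth$beta, path("beta.tsv"))
  utils::write.table(scr$wells, path("screen_wells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(scr$cpm, path("screen_cpm.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # --- response + differential calls -------------------------------------
  responses <- replicate_response(sim$tracks$treatment, sim$tracks$vehicle,
                                  sim$peaks)
  calls <- call_differential(responses, mark)
  mixture <- fit_width_mixture(calls$width)
  calls <- classify_shapes(calls, mixture)
  write_response_table(calls, path("calls.tsv"))
  gains <- .gr0(calls$chrom, calls$start, calls$end,
                seqlengths = config$chrom_lengths)[calls$call == "gain"]
  write_bed(gains, path("gains.bed"))

  # --- chromatin-state enrichment ----------------------------------------
  condensed <- condense_states(annotation)
  enr <- if (length(gains)) {
    enrichment_bias(overlap_enrichment(gains, condensed))
  } else NULL
  if (!is.null(enr)) {
    utils::write.table(as.data.frame(enr), path("enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- integration --------------------------------------------------------
  me1_like <- sim$peaks
  pairs <- link_within(gains, me1_like, window = link_window)
  utils::write.table(pairs, path("linked_pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  clusters <- if (nrow(pairs) >= 3) {
    cluster_by_signal(pairs, sim$tracks$vehicle[[1]], window = link_window)
  } else NULL
  if (!is.null(clusters)) {
    utils::write.table(
      data.frame(pairs, cluster = as.character(clusters$cluster)),
      path("clusters.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  pm <- profile_matrix(sim$tracks$treatment[[1]],
                       if (length(gains)) gains else sim$peaks,
                       mode = "reference_point", flank = 1000, bin = 50)
  write_profile_matrix(pm, path("profile_matrix.tsv"))

  # --- methylation --------------------------------------------------------
  deltas <- delta_beta(meth$beta, meth$groups$a, meth$groups$b)
  dmrs <- call_dmrs(deltas)
  utils::write.table(as.data.frame(dmrs), path("dmrs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_dmr_bed(dmrs, path("dmrs.bed"))

  # --- screen -------------------------------------------------------------
  wells <- normalize_wells(scr$wells)
  wells <- filter_wells(wells, scr$cpm)
  screen_res <- call_hits(wells)
  utils::write.table(screen_res$hits, path("screen_hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # --- manifest -----------------------------------------------------------
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package = "quantepi",
    version = as.character(utils::packageVersion("quantepi")),
    seed = config$seed,
    counts = list(
      peaks = length(sim$peaks),
      gains = sum(calls$call == "gain"),
      losses = sum(calls$call == "loss"),
      narrow = sum(calls$shape == "narrow"),
      broad = sum(calls$shape == "broad"),
      linked_pairs = nrow(pairs),
      dmrs = nrow(dmrs),
      screen_hits = nrow(screen_res$hits)
    ),
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files))
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(annotation = annotation, sim = sim, meth = meth,
                 screen_input = scr, calls = calls, mixture = mixture,
                 enrichment = enr, pairs = pairs, clusters = clusters,
                 profile = pm, dmrs = dmrs, screen = screen_res,
                 manifest = manifest))
}
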