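#' Segment a quantitative track into peaks
#'
#' Finds maximal runs of intervals whose signal is at least `threshold`,
#' merges runs separated by at most `merge_gap` bp, and drops runs narrower
#' than `min_width`. This is deliberately simple segmentation for tracks
#' that already carry absolute-scale signal; it is not a read-level peak
#' caller.
#'
#' @param track A `GRanges` quantitative track (see [read_bedgraph()]).
#' @param threshold Minimum signal level (efficiency units), `> 0`.
#' @param min_width Minimum peak width in bp (default 1).
#' @param merge_gap Runs separated by `<= merge_gap` bp are merged
#'   (default 0: only overlapping/adjacent runs merge).
#' @return A sorted, non-overlapping `GRanges` of peaks.
#' @export
detect_peaks <- function(track, threshold, min_width = 1L, merge_gap = 0L) {
  stopifnot(threshold > 0, min_width >= 1)
  validate_track(track)
  above <- track[S4Vectors::mcols(track)$score >= threshold]
  peaks <- GenomicRanges::reduce(above, min.gapwidth = merge_gap + 1L,
                                 ignore.strand = TRUE)
  peaks <- peaks[GenomicRanges::width(peaks) >= min_width]
  GenomicRanges::sort(peaks, ignore.strand = TRUE)
}

#' Area of a track under peaks
#'
#' The area of a peak is the sum over track intervals of
#' `value * bp overlap` (signal x bp). Bases outside track coverage
#' contribute 0, matching the interpretation of coverage-style tracks
#' where absence of an interval means no signal.
#'
#' @param track A `GRanges` quantitative track.
#' @param peaks A `GRanges` of one or more peaks.
#' @return Numeric vector of areas, one per peak.
#' @export
peak_area <- function(track, peaks) {
  if (length(peaks) == 0L) return(numeric(0))
  hits <- GenomicRanges::findOverlaps(peaks, track, ignore.strand = TRUE)
  out <- numeric(length(peaks))
  if (length(hits) > 0L) {
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    ov <- GenomicRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(peaks)[q], GenomicRanges::ranges(track)[s]))
    contrib <- ov * S4Vectors::mcols(track)$score[s]
    agg <- tapply(contrib, q, sum)
    out[as.integer(names(agg))] <- as.numeric(agg)
  }
  out
}

#' log2 fold-change in response for one replicate pairing
#'
#' The response of a peak is the ratio of its area in the treatment track to
#' its area in the vehicle track, summarised as a log2 fold-change. A
#' symmetric pseudocount (signal x bp) on both areas guards zero areas and
#' preserves the arm-swap antisymmetry of the statistic.
#'
#' @param treat,veh Treatment and vehicle `GRanges` tracks.
#' @param peaks A `GRanges` of peaks.
#' @param pseudo Pseudocount added to both areas (`> 0`, default 1).
#' @return Numeric vector `log2((area_treat + pseudo)/(area_veh + pseudo))`.
#' @export
pair_log2fc <- function(treat, veh, peaks, pseudo = 1) {
  stopifnot(pseudo > 0)
  log2((peak_area(treat, peaks) + pseudo) / (peak_area(veh, peaks) + pseudo))
}

#' Peak responses across all replicate pairings
#'
#' Each treatment replicate is compared to every vehicle replicate (the full
#' cross of pairings), and its per-peak log2 fold-changes are averaged over
#' its vehicle pairings. The overall response of a peak is the arithmetic
#' mean of those per-treatment-replicate means, and the replicate variance is
#' the unbiased sample variance of the per-replicate means (0 when there is
#' a single treatment replicate). Variability is thus assessed at the level
#' of biological replicates, not of individual pairings.
#'
#' @param treat_tracks,veh_tracks Lists of `GRanges` tracks, one per
#'   biological replicate of each arm (at least one each).
#' @param peaks A `GRanges` of (consensus) peaks.
#' @param pseudo Pseudocount forwarded to [pair_log2fc()].
#' @return A `data.frame` (class `response_table`) with columns `chrom`,
#'   `start`, `end` (0-based half-open), `width`, one `rep_mean_<i>` column
#'   per treatment replicate, `mean_log2fc`, `variance`, `n_treat`, `n_veh`.
#' @export
replicate_response <- function(treat_tracks, veh_tracks, peaks, pseudo = 1) {
  stopifnot(length(treat_tracks) >= 1, length(veh_tracks) >= 1)
  nt <- length(treat_tracks)
  if (length(peaks) == 0L) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), width = integer(0))
    for (i in seq_len(nt)) out[[paste0("rep_mean_", i)]] <- numeric(0)
    out$mean_log2fc <- numeric(0)
    out$variance <- numeric(0)
    out$n_treat <- integer(0)
    out$n_veh <- integer(0)
    class(out) <- c("response_table", "data.frame")
    return(out)
  }
  rep_means <- matrix(NA_real_, nrow = length(peaks), ncol = nt)
  for (i in seq_len(nt)) {
    pairs <- vapply(veh_tracks, function(v) {
      pair_log2fc(treat_tracks[[i]], v, peaks, pseudo)
    }, numeric(length(peaks)))
    pairs <- matrix(pairs, nrow = length(peaks))
    rep_means[, i] <- rowMeans(pairs)
  }
  overall <- rowMeans(rep_means)
  variance <- if (nt > 1) apply(rep_means, 1, stats::var) else
    rep(0, length(peaks))
  out <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(peaks)),
    start = GenomicRanges::start(peaks) - 1L,
    end = GenomicRanges::end(peaks),
    width = GenomicRanges::width(peaks),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nt)) out[[paste0("rep_mean_", i)]] <- rep_means[, i]
  out$mean_log2fc <- overall
  out$variance <- variance
  out$n_treat <- nt
  out$n_veh <- length(veh_tracks)
  class(out) <- c("response_table", "data.frame")
  out
}

#' Replicate-conserved consensus peaks
#'
#' Builds connected components of any-base-pair overlap across the
#' per-replicate peak sets; a component is conserved when it contains peaks
#' from at least `min_replicates` distinct replicates. The consensus
#' interval of a conserved component is the union span of its member peaks,
#' so downstream widths are well defined.
#'
#' @param peak_sets List of `GRanges`, one peak set per replicate.
#' @param min_replicates Number of distinct replicates a component must touch
#'   (default: all of them).
#' @return A sorted `GRanges` of consensus peaks with an `n_replicates`
#'   metadata column.
#' @export
conserve_peaks <- function(peak_sets, min_replicates = length(peak_sets)) {
  stopifnot(length(peak_sets) >= 1, min_replicates <= length(peak_sets))
  pooled <- do.call(c, lapply(peak_sets, GenomicRanges::granges))
  # min.gapwidth = 0: merge only intervals sharing >= 1 bp, never merely
  # adjacent ones (half-open intervals touching at a boundary share no base).
  components <- GenomicRanges::reduce(pooled, min.gapwidth = 0L,
                                      ignore.strand = TRUE)
  support <- vapply(peak_sets, function(ps) {
    GenomicRanges::countOverlaps(components, ps, minoverlap = 1L,
                                 ignore.strand = TRUE) > 0L
  }, logical(length(components)))
  support <- matrix(support, nrow = length(components))
  n_rep <- rowSums(support)
  out <- components[n_rep >= min_replicates]
  S4Vectors::mcols(out)$n_replicates <- n_rep[n_rep >= min_replicates]
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

#' Write a response table as TSV
#' @param responses A `response_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_response_table <- function(responses, path) {
  utils::write.table(as.data.frame(responses), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
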