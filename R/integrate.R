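#' Link peaks of one mark to the nearest peak of another within a window
#'
#' For each query (mark A) peak the nearest subject (mark B) peak by
#' edge-to-edge distance is found; a pair is emitted only when that distance
#' is at most `window` bp (e.g. H3K27ac gains within 10 kb of H3K27me1
#' signal). Overlapping intervals have distance 0. Ties between two
#' equidistant B peaks resolve to the leftmost (smallest start) for
#' determinism. With `mode = "center"` the distance is measured between
#' interval midpoints instead.
#'
#' @param peaks_a Query `GRanges` (e.g. significant H3K27ac gains).
#' @param peaks_b Subject `GRanges` (e.g. H3K27me1 peaks).
#' @param window Maximum linking distance in bp (`> 0`).
#' @param mode `"edge"` (default) or `"center"`.
#' @return A `data.frame` with one row per linked A peak: `a_index`,
#'   `a_chrom`, `a_start`, `a_end`, `b_index`, `b_start`, `b_end`,
#'   `distance`, `window` (coordinates 0-based half-open). A peaks with no
#'   B peak within the window are simply absent.
#' @export
link_within <- function(peaks_a, peaks_b, window, mode = c("edge", "center")) {
  mode <- match.arg(mode)
  stopifnot(window > 0)
  if (length(peaks_a) == 0L || length(peaks_b) == 0L) {
    return(data.frame(a_index = integer(0), a_chrom = character(0),
                      a_start = integer(0), a_end = integer(0),
                      b_index = integer(0), b_start = integer(0),
                      b_end = integer(0), distance = numeric(0),
                      window = numeric(0)))
  }
  if (mode == "edge") {
    # edge-to-edge gap computed directly so that ties are all visible and
    # can be broken deterministically (nearest-style selection is arbitrary)
    sa0 <- GenomicRanges::start(peaks_a) - 1
    ea0 <- GenomicRanges::end(peaks_a)
    sb0 <- GenomicRanges::start(peaks_b) - 1
    eb0 <- GenomicRanges::end(peaks_b)
    chra <- as.character(GenomeInfoDb::seqnames(peaks_a))
    chrb <- as.character(GenomeInfoDb::seqnames(peaks_b))
    q <- integer(0); s <- integer(0); d <- numeric(0)
    for (i in seq_along(peaks_a)) {
      same <- which(chrb == chra[i])
      if (!length(same)) next
      dd <- pmax(sb0[same] - ea0[i], sa0[i] - eb0[same], 0)
      nearest <- same[dd == min(dd)]
      q <- c(q, rep(i, length(nearest)))
      s <- c(s, nearest)
      d <- c(d, rep(min(dd), length(nearest)))
    }
  } else {
    ca <- floor((GenomicRanges::start(peaks_a) - 1 +
                 GenomicRanges::end(peaks_a)) / 2)
    cb <- floor((GenomicRanges::start(peaks_b) - 1 +
                 GenomicRanges::end(peaks_b)) / 2)
    chra <- as.character(GenomeInfoDb::seqnames(peaks_a))
    chrb <- as.character(GenomeInfoDb::seqnames(peaks_b))
    q <- integer(0); s <- integer(0); d <- numeric(0)
    for (i in seq_along(peaks_a)) {
      same <- which(chrb == chra[i])
      if (!length(same)) next
      dd <- abs(cb[same] - ca[i])
      q <- c(q, rep(i, length(same))); s <- c(s, same); d <- c(d, dd)
    }
    keepmin <- unlist(lapply(split(seq_along(q), q), function(idx) {
      idx[d[idx] == min(d[idx])]
    }), use.names = FALSE)
    q <- q[keepmin]; s <- s[keepmin]; d <- d[keepmin]
  }
  # leftmost B wins among equidistant nearest neighbours
  ord <- order(q, GenomicRanges::start(peaks_b)[s])
  q <- q[ord]; s <- s[ord]; d <- d[ord]
  first <- !duplicated(q)
  q <- q[first]; s <- s[first]; d <- d[first]
  keep <- d <= window
  data.frame(
    a_index = q[keep],
    a_chrom = as.character(GenomeInfoDb::seqnames(peaks_a))[q[keep]],
    a_start = GenomicRanges::start(peaks_a)[q[keep]] - 1L,
    a_end = GenomicRanges::end(peaks_a)[q[keep]],
    b_index = s[keep],
    b_start = GenomicRanges::start(peaks_b)[s[keep]] - 1L,
    b_end = GenomicRanges::end(peaks_b)[s[keep]],
    distance = as.numeric(d[keep]),
    window = rep(window, sum(keep)),
    stringsAsFactors = FALSE
  )
}

# mean signal of `track` in [center - window, center + window) around the
# midpoint of each interval (0-based midpoint, floor division)
.window_mean_signal <- function(track, intervals, window) {
  center0 <- floor((GenomicRanges::start(intervals) - 1 +
                    GenomicRanges::end(intervals)) / 2)
  win <- .gr0(as.character(GenomeInfoDb::seqnames(intervals)),
              pmax(center0 - window, 0), center0 + window)
  peak_area(track, win) / GenomicRanges::width(win)
}

#' Cluster linked regions by second-mark signal
#'
#' Each linked A peak is summarised by the mean B-mark signal in a window of
#' `+/- window` bp around its midpoint, and the resulting one-dimensional
#' features are partitioned with k-means (k = 3 by default). Initial centers
#' are the odd `(2i - 1) / (2k)` quantiles of the feature distribution --
#' one center per equal-mass slice -- which is deterministic and avoids
#' seeding two centers inside a single dispersed signal tier; clusters are
#' relabeled `low`/`intermediate`/`high` by ascending centroid.
#'
#' @param pairs Output of [link_within()].
#' @param track_b Quantitative `GRanges` track of the second mark.
#' @param window Half-width in bp of the signal window around each A peak.
#' @param k Number of clusters (default 3).
#' @param seed Unused (initialisation is deterministic); kept for interface
#'   uniformity.
#'
#' @return A list of class `cluster_assignment`: `cluster` (ordered factor,
#'   `low < intermediate < high` for k = 3), `centroids` (ascending),
#'   `feature` (the signal summaries), `degenerate` (`TRUE` when all
#'   features are identical, in which case all rows share one cluster).
#' @export
cluster_by_signal <- function(pairs, track_b, window, k = 3L, seed = NULL) {
  stopifnot(nrow(pairs) >= k, k >= 1)
  a_iv <- .gr0(pairs$a_chrom, pairs$a_start, pairs$a_end)
  feature <- .window_mean_signal(track_b, a_iv, window)
  labels <- if (k == 3L) c("low", "intermediate", "high") else
    paste0("cluster", seq_len(k))
  if (length(unique(feature)) == 1L) {
    return(structure(list(
      cluster = factor(rep(labels[1], length(feature)), levels = labels,
                       ordered = TRUE),
      centroids = rep(feature[1], k), feature = feature, degenerate = TRUE),
      class = "cluster_assignment"))
  }
  centers <- .quantile_centers(feature, k)
  fit <- stats::kmeans(feature, centers = matrix(centers, ncol = 1),
                       iter.max = 50L)
  ord <- order(fit$centers[, 1])
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  cl <- factor(labels[relabel[fit$cluster]], levels = labels, ordered = TRUE)
  structure(list(cluster = cl, centroids = sort(fit$centers[, 1]),
                 feature = feature, degenerate = FALSE),
            class = "cluster_assignment")
}

.quantile_centers <- function(x, k) {
  ux <- sort(unique(x))
  if (length(ux) < k) {
    stop("fewer distinct feature values (", length(ux), ") than clusters (",
         k, ")", call. = FALSE)
  }
  centers <- unique(stats::quantile(x, probs = (2 * seq_len(k) - 1) / (2 * k),
                                    names = FALSE))
  # duplicate quantiles (heavily tied data): top up with the unique values
  # farthest from the chosen centers, keeping the seeding deterministic
  while (length(centers) < k) {
    dmin <- vapply(ux, function(v) min(abs(v - centers)), numeric(1))
    centers <- c(centers, ux[which.max(dmin)])
  }
  sort(centers)
}

#' Build a signal profile matrix over queried coordinates
#'
#' Computes a regions-by-bins matrix of base-pair-weighted mean signal, in
#' the style of deepTools computeMatrix. In `reference_point` mode bins of
#' width `bin` tile `[center - flank, center + flank)` around each region
#' midpoint; in `scale_regions` mode the upstream flank, a body rescaled to
#' `body_bins` bins, and the downstream flank are laid out left to right.
#' Bins extending past chromosome bounds (when `seqlengths` are set) or
#' before position 0 are `NA` and are excluded from the per-bin average
#' profile rather than zero-filled, which avoids edge artifacts.
#'
#' @param track Quantitative `GRanges` track.
#' @param regions `GRanges` of query regions.
#' @param mode `"reference_point"` or `"scale_regions"`.
#' @param flank Flank size in bp (must be divisible by `bin`).
#' @param bin Bin width in bp.
#' @param body_bins Number of body bins (`scale_regions` mode only).
#' @return A list of class `profile_matrix`: `matrix` (regions x bins),
#'   `profile` (per-bin mean over regions, `NA`s removed), `mode`, `flank`,
#'   `bin`, `body_bins`.
#' @export
profile_matrix <- function(track, regions,
                           mode = c("reference_point", "scale_regions"),
                           flank = 1000L, bin = 50L, body_bins = 20L) {
  mode <- match.arg(mode)
  stopifnot(flank %% bin == 0, flank > 0, bin > 0)
  n_flank <- as.integer(flank / bin)
  n_regions <- length(regions)
  chrom <- as.character(GenomeInfoDb::seqnames(regions))
  sl <- GenomeInfoDb::seqlengths(regions)
  if (!length(sl)) sl <- GenomeInfoDb::seqlengths(track)
  chrom_len <- function(ch) {
    if (length(sl) && ch %in% names(sl) && !is.na(sl[[ch]])) sl[[ch]] else Inf
  }
  s0 <- GenomicRanges::start(regions) - 1L
  e0 <- GenomicRanges::end(regions)
  if (mode == "reference_point") {
    n_cols <- 2L * n_flank
    edges <- function(i) {
      center <- floor((s0[i] + e0[i]) / 2)
      left <- center - flank + bin * (seq_len(n_cols) - 1L)
      cbind(left, left + bin)
    }
  } else {
    n_cols <- 2L * n_flank + body_bins
    edges <- function(i) {
      up <- s0[i] - flank + bin * (seq_len(n_flank) - 1L)
      body_w <- (e0[i] - s0[i]) / body_bins
      body <- s0[i] + body_w * (seq_len(body_bins) - 1L)
      down <- e0[i] + bin * (seq_len(n_flank) - 1L)
      cbind(c(up, body, down), c(up + bin, body + body_w, down + bin))
    }
  }
  mat <- matrix(NA_real_, nrow = n_regions, ncol = n_cols)
  for (i in seq_len(n_regions)) {
    be <- edges(i)
    lo <- be[, 1]; hi <- be[, 2]
    ok <- lo >= 0 & hi <= chrom_len(chrom[i]) & hi > lo
    if (!any(ok)) next
    # fractional body-bin edges are handled by exact bp weighting
    mat[i, which(ok)] <- .binned_mean(track, chrom[i], lo[ok], hi[ok])
  }
  rn <- sprintf("%s:%d-%d", chrom, s0, e0)
  rownames(mat) <- make.unique(rn)
  profile <- colMeans(mat, na.rm = TRUE)
  profile[is.nan(profile)] <- NA_real_
  structure(list(matrix = mat, profile = profile, mode = mode,
                 flank = flank, bin = bin,
                 body_bins = if (mode == "scale_regions") body_bins else 0L),
            class = "profile_matrix")
}

# exact bp-weighted mean of track signal over possibly fractional 0-based
# [lo, hi) windows on one chromosome
.binned_mean <- function(track, chrom, lo, hi) {
  tr <- track[as.character(GenomeInfoDb::seqnames(track)) == chrom]
  ts <- GenomicRanges::start(tr) - 1
  te <- GenomicRanges::end(tr)
  tv <- S4Vectors::mcols(tr)$score
  vapply(seq_along(lo), function(j) {
    ov_lo <- pmax(ts, lo[j])
    ov_hi <- pmin(te, hi[j])
    w <- pmax(ov_hi - ov_lo, 0)
    sum(w * tv) / (hi[j] - lo[j])
  }, numeric(1))
}

#' Write a profile matrix as TSV
#'
#' One row per region; the header gives bin offsets relative to the
#' reference point (or bin indices in scale mode).
#'
#' @param pm A `profile_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_matrix <- function(pm, path) {
  stopifnot(inherits(pm, "profile_matrix"))
  m <- pm$matrix
  if (pm$mode == "reference_point") {
    offs <- -pm$flank + pm$bin * (seq_len(ncol(m)) - 1L)
    colnames(m) <- sprintf("bin_%d", offs)
  } else {
    colnames(m) <- sprintf("bin_%d", seq_len(ncol(m)))
  }
  df <- data.frame(region = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter a differential-expression table at fixed thresholds
#'
#' Genes are considered differentially expressed when `|log2FC| >= lfc_min`
#' and `FDR <= fdr_max` (both bounds inclusive). No model fitting happens
#' here: the table comes from an external differential-expression analysis.
#'
#' @param de_table `data.frame` with columns `gene`, `log2FC`, `FDR`.
#' @param lfc_min Minimum absolute log2 fold-change (default 1).
#' @param fdr_max Maximum FDR (default 0.01).
#' @return List with character vectors `up` and `down`.
#' @export
filter_de <- function(de_table, lfc_min = 1.0, fdr_max = 0.01) {
  stopifnot(all(c("gene", "log2FC", "FDR") %in% names(de_table)))
  up <- de_table$gene[de_table$log2FC >= lfc_min & de_table$FDR <= fdr_max]
  down <- de_table$gene[de_table$log2FC <= -lfc_min & de_table$FDR <= fdr_max]
  list(up = as.character(up), down = as.character(down))
}
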