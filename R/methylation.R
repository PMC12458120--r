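#' Per-CpG group difference of methylation beta values
#'
#' Computes, per probe, the difference of group mean beta values
#' (`group_b - group_a`); with treated samples as group B and vehicle as
#' group A, positive values are treatment-associated hypermethylation.
#'
#' @param beta A `beta_matrix` (see [read_beta_matrix()]) or a `data.frame`
#'   with `probe`, `chrom`, `pos` and sample columns.
#' @param group_a,group_b Character vectors of sample column names; both
#'   must be non-empty and present in `beta`.
#' @return `data.frame` with `probe`, `chrom`, `pos`, `delta` (in
#'   `[-1, 1]`), probes sorted by position within chromosome.
#' @export
delta_beta <- function(beta, group_a, group_b) {
  stopifnot(length(group_a) >= 1, length(group_b) >= 1)
  missing <- setdiff(c(group_a, group_b), names(beta))
  if (length(missing)) {
    stop("sample column(s) not in beta matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  a <- rowMeans(as.data.frame(beta)[, group_a, drop = FALSE])
  b <- rowMeans(as.data.frame(beta)[, group_b, drop = FALSE])
  out <- data.frame(probe = beta$probe, chrom = beta$chrom, pos = beta$pos,
                    delta = b - a, stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Call differentially methylated regions from per-probe deltas
#'
#' Scans each chromosome for maximal runs of consecutive probes that share
#' the sign of their beta difference (zero deltas break a run), with
#' adjacent run probes at most `max_gap` bp apart. A run is reported as a
#' DMR when it contains at least `min_cpgs` probes and the absolute mean
#' delta over the run is at least `min_delta` (default: at least five
#' contiguous CpGs with a mean difference of 0.20). Setting
#' `per_probe = TRUE` switches to the stricter reading in which every probe
#' in the run must individually satisfy `|delta| >= min_delta`.
#'
#' Array probes are sparse, so "contiguous" is bounded by `max_gap`:
#' an unbounded gap would merge unrelated loci into one region.
#'
#' @param deltas Output of [delta_beta()] (must be position-sorted within
#'   chromosome; unsorted input is an error).
#' @param min_cpgs Minimum probes per region (default 5).
#' @param min_delta Minimum absolute mean delta (default 0.20).
#' @param max_gap Maximum bp between consecutive probes of a run
#'   (default 1000).
#' @param per_probe Require `|delta| >= min_delta` at every probe instead of
#'   on the run mean.
#' @return `data.frame` (class `dmr_table`) with one row per DMR: `chrom`,
#'   `start`, `end` (0-based half-open span from first to last probe, end =
#'   last position + 1), `n_probes`, `mean_delta`, `direction`
#'   (`hyper`/`hypo`), `first_probe`, `last_probe`.
#' @export
call_dmrs <- function(deltas, min_cpgs = 5L, min_delta = 0.20,
                      max_gap = 1000L, per_probe = FALSE) {
  stopifnot(all(c("probe", "chrom", "pos", "delta") %in% names(deltas)))
  rows <- list()
  for (ch in unique(deltas$chrom)) {
    d <- deltas[deltas$chrom == ch, , drop = FALSE]
    if (is.unsorted(d$pos, strictly = TRUE)) {
      stop("probes on ", ch, " are not strictly position-sorted",
           call. = FALSE)
    }
    n <- nrow(d)
    if (n == 0L) next
    sgn <- sign(d$delta)
    # a new run starts at a sign change, a zero delta, or a gap > max_gap
    new_run <- c(TRUE, sgn[-1] != sgn[-n] |
                   diff(d$pos) > max_gap)
    new_run[sgn == 0] <- TRUE
    run <- cumsum(new_run)
    for (r in split(seq_len(n), run)) {
      if (sgn[r[1]] == 0) next
      if (length(r) < min_cpgs) next
      m <- mean(d$delta[r])
      admit <- if (per_probe) all(abs(d$delta[r]) >= min_delta) else
        abs(m) >= min_delta
      if (!admit) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch,
        start = d$pos[r[1]],
        end = d$pos[r[length(r)]] + 1L,
        n_probes = length(r),
        mean_delta = m,
        direction = if (m > 0) "hyper" else "hypo",
        first_probe = d$probe[r[1]],
        last_probe = d$probe[r[length(r)]],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               n_probes = integer(0), mean_delta = numeric(0),
               direction = character(0), first_probe = character(0),
               last_probe = character(0), stringsAsFactors = FALSE)
  class(out) <- c("dmr_table", "data.frame")
  out
}

#' Export DMRs as BED
#'
#' BED name is the direction and score is `1000 * |mean delta|`, capped at
#' 1000.
#'
#' @param dmrs A `dmr_table` from [call_dmrs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  gr <- .gr0(dmrs$chrom, dmrs$start, dmrs$end,
             name = dmrs$direction,
             score = pmin(1000, round(1000 * abs(dmrs$mean_delta))))
  write_bed(gr, path)
}
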