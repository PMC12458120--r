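# Builders for in-code fixtures. All coordinates are 0-based half-open,
# mirroring the on-disk convention; the helpers do the +1 shift into GRanges.

track0 <- function(chrom, start, end, value, seqlengths = NULL) {
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start + 1, end),
                               score = value)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  gr
}

iv0 <- function(chrom, start, end, ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end), ...)
}

# random non-overlapping small track on one chromosome, plus a per-base
# signal vector usable as a brute-force oracle
random_track <- function(len = 1000, n_bins = 20) {
  starts <- sort(sample.int(len - 1, n_bins))
  ends <- c(starts[-1], len)
  keep <- sample(c(TRUE, FALSE), n_bins, replace = TRUE)
  vals <- round(stats::runif(n_bins, 0, 10), 3)
  per_base <- numeric(len)
  for (i in which(keep)) {
    per_base[(starts[i] + 1):ends[i]] <- vals[i]
  }
  list(track = track0("chr1", starts[keep], ends[keep], vals[keep]),
       per_base = per_base, len = len)
}

# brute-force per-base area of a per-base vector over 0-based [s, e)
area_oracle <- function(per_base, s, e) {
  s <- max(s, 0); e <- min(e, length(per_base))
  if (e <= s) return(0)
  sum(per_base[(s + 1):e])
}

write_lines_tmp <- function(lines) {
  tf <- tempfile()
  writeLines(lines, tf)
  tf
}
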