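make_deltas <- function(delta, pos = NULL) {
  n <- length(delta)
  if (is.null(pos)) pos <- seq(100, by = 400, length.out = n)
  data.frame(probe = sprintf("cg%04d", seq_len(n)), chrom = "chr1",
             pos = pos, delta = delta, stringsAsFactors = FALSE)
}

# independent brute-force oracle for DMR calling: enumerate every candidate
# probe run, keep those that are sign-consistent within the gap bound and
# not extendable in either direction, then admit by run size and mean shift
dmr_oracle <- function(d, min_cpgs = 5, min_delta = 0.2, max_gap = 1000) {
  n <- nrow(d)
  ok_run <- function(i, j) {
    idx <- i:j
    sgns <- sign(d$delta[idx])
    if (any(sgns == 0) || length(unique(sgns)) != 1) return(FALSE)
    if (j > i && any(diff(d$pos[idx]) > max_gap)) return(FALSE)
    TRUE
  }
  out <- NULL
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (!ok_run(i, j)) next
      extendable <- (i > 1 && ok_run(i - 1, j)) ||
        (j < n && ok_run(i, j + 1))
      if (extendable) next
      if (j - i + 1 < min_cpgs) next
      m <- mean(d$delta[i:j])
      if (abs(m) < min_delta) next
      out <- rbind(out, data.frame(start = d$pos[i], end = d$pos[j] + 1,
                                   n_probes = j - i + 1, mean_delta = m))
    }
  }
  out
}
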