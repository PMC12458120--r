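test_that("peak detection thresholds, merges and drops runs as specified", {
  tr <- track0("chr1", c(0, 100, 400), c(100, 400, 1000), c(0, 5, 0))
  pk <- detect_peaks(tr, threshold = 1, min_width = 50)
  expect_equal(GenomicRanges::start(pk) - 1L, 100L)
  expect_equal(GenomicRanges::end(pk), 400L)

  two <- track0("chr1", c(100, 220), c(200, 300), c(5, 5))
  merged <- detect_peaks(two, threshold = 1, merge_gap = 50)
  expect_length(merged, 1)
  expect_equal(GenomicRanges::end(merged), 300L)
  unmerged <- detect_peaks(two, threshold = 1, merge_gap = 10)
  expect_length(unmerged, 2)

  short <- track0("chr1", 100, 130, 5)
  expect_length(detect_peaks(short, threshold = 1, min_width = 50), 0)
})

test_that("peak area equals hand arithmetic and per-base brute force", {
  tr <- track0("chr1", c(0, 100), c(100, 200), c(1.0, 3.0))
  expect_equal(peak_area(tr, iv0("chr1", 50, 150)), 200.0)
  expect_equal(peak_area(tr, iv0("chr1", 500, 600)), 0.0)
  expect_equal(peak_area(track0("chr1", 0, 1000, 2.5),
                         iv0("chr1", 100, 300)), 2.5 * 200)

  withr::with_seed(42, {
    for (i in 1:20) {
      rt <- random_track()
      s <- sample.int(rt$len - 10, 1)
      e <- s + sample.int(rt$len - s, 1)
      expect_equal(peak_area(rt$track, iv0("chr1", s, e)),
                   area_oracle(rt$per_base, s, e))
    }
  })
})

test_that("pairwise log2FC matches closed forms and pseudocount limit", {
  t2 <- track0("chr1", 0, 200, 2.0)   # area 400 over [0,200)
  t1 <- track0("chr1", 0, 200, 1.0)   # area 200
  pk <- iv0("chr1", 0, 200)
  expect_equal(pair_log2fc(t2, t1, pk, pseudo = 1e-9), 1.0, tolerance = 1e-8)
  expect_equal(pair_log2fc(t1, t1, pk), 0.0)
  t255 <- track0("chr1", 0, 1, 255)
  t0 <- track0("chr1", 0, 1, 0)
  expect_equal(pair_log2fc(t255, t0, iv0("chr1", 0, 1), pseudo = 1), 8.0)
})

test_that("responses satisfy scaling and arm-swap symmetry", {
  withr::with_seed(3, {
    rt <- random_track()
    pk <- iv0("chr1", c(100, 500), c(300, 800))
    scaled <- rt$track
    S4Vectors::mcols(scaled)$score <- S4Vectors::mcols(scaled)$score * 8
    fwd <- pair_log2fc(scaled, rt$track, pk, pseudo = 1e-12)
    expect_equal(fwd, pair_log2fc(rt$track, rt$track, pk, 1e-12) + 3,
                 tolerance = 1e-6)
    rev <- pair_log2fc(rt$track, scaled, pk, pseudo = 1e-12)
    expect_equal(rev, -fwd, tolerance = 1e-6)
  })
})

test_that("replicate cross-pairing averages, overall mean and variance", {
  # construct areas so rep1 pairings give {1.0, 1.2}, rep2 {0.8, 1.0}
  pk <- iv0("chr1", 0, 100)
  mk <- function(v) track0("chr1", 0, 100, v)
  veh <- list(mk(2^0 * 10), mk(2^-0.2 * 10))
  treat <- list(mk(2^1.0 * 10), mk(2^0.8 * 10))
  resp <- replicate_response(treat, veh, pk, pseudo = 1e-9)
  expect_equal(resp$rep_mean_1, 1.1, tolerance = 1e-6)
  expect_equal(resp$rep_mean_2, 0.9, tolerance = 1e-6)
  expect_equal(resp$mean_log2fc, 1.0, tolerance = 1e-6)
  expect_equal(resp$variance, 0.02, tolerance = 1e-6)

  single <- replicate_response(treat[1], veh[1], pk, pseudo = 1e-9)
  expect_equal(single$mean_log2fc, 1.0, tolerance = 1e-6)
  expect_equal(single$variance, 0)

  empty <- replicate_response(treat, veh, GenomicRanges::GRanges())
  expect_identical(nrow(empty), 0L)
})

test_that("noiseless 2x treatment gives overall mean exactly 1", {
  withr::with_seed(5, {
    rt <- random_track()
    doubled <- rt$track
    S4Vectors::mcols(doubled)$score <- 2 * S4Vectors::mcols(doubled)$score
    pk <- iv0("chr1", c(50, 400), c(200, 700))
    resp <- replicate_response(list(doubled, doubled), list(rt$track, rt$track),
                               pk, pseudo = 1e-12)
    expect_equal(resp$mean_log2fc, rep(1, 2), tolerance = 1e-6)
  })
})

test_that("peak conservation uses overlap components and union spans", {
  r1 <- iv0("chr1", 100, 400)
  r2 <- iv0("chr1", 350, 600)
  cons <- conserve_peaks(list(r1, r2), min_replicates = 2)
  expect_equal(GenomicRanges::start(cons) - 1L, 100L)
  expect_equal(GenomicRanges::end(cons), 600L)

  apart <- conserve_peaks(list(iv0("chr1", 100, 200), iv0("chr1", 500, 600)),
                          min_replicates = 2)
  expect_length(apart, 0)

  three <- conserve_peaks(list(iv0("chr1", 0, 100), iv0("chr1", 0, 100),
                               iv0("chr1", 0, 100)), min_replicates = 3)
  expect_length(three, 1)
  expect_equal(GenomicRanges::width(three), 100L)

  # touching half-open intervals share no base and must not merge
  touching <- conserve_peaks(list(iv0("chr1", 100, 200),
                                  iv0("chr1", 200, 300)), min_replicates = 2)
  expect_length(touching, 0)
})

test_that("peak conservation is invariant to replicate-set order", {
  withr::with_seed(9, {
    sets <- lapply(1:3, function(i) {
      s <- sort(sample.int(5000, 8)) * 10
      iv0("chr1", s, s + sample(50:300, 8, replace = TRUE))
    })
    ref <- conserve_peaks(sets, min_replicates = 2)
    for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
      alt <- conserve_peaks(sets[perm], min_replicates = 2)
      expect_identical(GenomicRanges::start(alt), GenomicRanges::start(ref))
      expect_identical(GenomicRanges::end(alt), GenomicRanges::end(ref))
    }
  })
})
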