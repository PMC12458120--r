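test_that("proximity linking uses edge distance with an inclusive window", {
  a <- iv0("chr1", 900, 1100)
  expect_equal(link_within(a, iv0("chr1", 10500, 10600), 10000)$distance,
               9400)
  expect_identical(nrow(link_within(a, iv0("chr1", 11200, 11300), 10000)),
                   0L)
  expect_equal(link_within(a, iv0("chr1", 1000, 1300), 10000)$distance, 0)

  # ties resolve to the leftmost subject peak
  b <- iv0("chr1", c(0, 1500), c(500, 2000))  # both 400 bp from a
  tie <- link_within(a, b, 10000)
  expect_equal(tie$b_start, 0)

  # translation invariance
  shift <- 12345
  moved <- link_within(iv0("chr1", 900 + shift, 1100 + shift),
                       iv0("chr1", 10500 + shift, 10600 + shift), 10000)
  expect_equal(moved$distance, 9400)
})

test_that("k-means signal clustering recovers planted tiers in order", {
  withr::with_seed(55, {
    n_per <- 30
    tiers <- rep(c(0.1, 1.0, 5.0), each = n_per)
    starts <- seq(0, by = 30000, length.out = 3 * n_per)
    ord <- sample(length(tiers))
    tiers <- tiers[ord]
    a <- iv0("chr1", starts + 14000, starts + 14400)
    b <- iv0("chr1", starts + 15000, starts + 15200)
    sig <- tiers * (1 + rnorm(length(tiers), 0, 0.05))
    track <- track0("chr1", starts + 13000, starts + 17000, pmax(sig, 0.01))
    pairs <- link_within(a, b, window = 10000)
    expect_identical(nrow(pairs), length(tiers))
    cl <- cluster_by_signal(pairs, track, window = 2000, k = 3)
    expect_true(all(diff(cl$centroids) >= 0))
    truth <- factor(c("low", "intermediate", "high")[match(tiers,
      sort(unique(tiers)))], levels = levels(cl$cluster), ordered = TRUE)
    agreement <- mean(cl$cluster == truth)
    expect_gte(agreement, 0.9)

    # determinism and degenerate handling
    cl2 <- cluster_by_signal(pairs, track, window = 2000, k = 3)
    expect_identical(cl$cluster, cl2$cluster)
    flat <- track0("chr1", 0, max(starts) + 20000, 1.0)
    dg <- cluster_by_signal(pairs, flat, window = 2000, k = 3)
    expect_true(dg$degenerate)
    expect_identical(length(unique(dg$cluster)), 1L)
    expect_error(cluster_by_signal(pairs[1:2, ], track, 2000, k = 3))
  })
})

test_that("profile matrix equals per-base brute force on fuzzed inputs", {
  withr::with_seed(77, {
    for (i in 1:25) {
      rt <- random_track(len = 4000, n_bins = 30)
      s <- sample(1200:2000, 1)
      regions <- iv0("chr1", s, s + sample(100:600, 1),
                     seqlengths = c(chr1 = 4000))
      flank <- 500; bin <- 50
      pm <- profile_matrix(rt$track, regions, "reference_point",
                           flank = flank, bin = bin)
      expect_equal(ncol(pm$matrix), 2 * flank / bin)
      s0 <- GenomicRanges::start(regions) - 1
      center <- (s0 + GenomicRanges::end(regions)) %/% 2
      for (j in seq_len(ncol(pm$matrix))) {
        lo <- center - flank + (j - 1) * bin
        expect_equal(unname(pm$matrix[1, j]),
                     area_oracle(rt$per_base, lo, lo + bin) / bin,
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("constant tracks give constant profiles; bounds become missing", {
  tr <- track0("chr1", 0, 10000, 3.5, seqlengths = c(chr1 = 10000))
  regions <- iv0("chr1", c(4000, 100), c(4400, 300),
                 seqlengths = c(chr1 = 10000))
  pm <- profile_matrix(tr, regions, "reference_point", flank = 1000,
                       bin = 50)
  expect_identical(ncol(pm$matrix), 40L)
  expect_true(all(pm$matrix[1, ] == 3.5))
  # second region's center is 200: bins left of position 0 are missing
  expect_true(anyNA(pm$matrix[2, ]))
  expect_equal(unname(pm$profile[40]), 3.5)  # NA bins excluded from profile

  sc <- profile_matrix(tr, regions[1], "scale_regions", flank = 500,
                       bin = 50, body_bins = 8)
  expect_identical(ncol(sc$matrix), 28L)
  expect_true(all(sc$matrix == 3.5))
})

test_that("DE filtering applies inclusive fold-change and FDR bounds", {
  de <- data.frame(gene = c("G1", "G2", "G3", "G4"),
                   log2FC = c(1.0, 0.9, -2.0, -1.5),
                   FDR = c(0.01, 0.001, 0.05, 0.002))
  out <- filter_de(de)
  expect_identical(out$up, "G1")
  expect_identical(out$down, "G4")
})
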