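test_that("simulated annotations tile chromosomes with exact state coverage", {
  cfg <- sim_config(seed = 4, chrom_lengths = c(chrA = 10000),
                    state_props = c(S1 = 0.5, S2 = 0.5, S3 = 0))
  ann <- simulate_annotation(cfg)
  expect_false("S3" %in% S4Vectors::mcols(ann)$name)
  cov <- tapply(GenomicRanges::width(ann), S4Vectors::mcols(ann)$name, sum)
  expect_equal(sum(cov), 10000)
  expect_equal(unname(cov[["S1"]]), 5000)
  # tiling: no gaps, no overlaps
  red <- GenomicRanges::reduce(ann)
  expect_equal(sum(GenomicRanges::width(red)), 10000)
  expect_length(red, 1)

  bad <- cfg
  bad$state_props <- c(S1 = 0.6, S2 = 0.5)
  expect_error(simulate_annotation(bad), "sum to 1")

  again <- simulate_annotation(cfg)
  expect_identical(S4Vectors::mcols(again)$name, S4Vectors::mcols(ann)$name)
  expect_identical(GenomicRanges::start(again), GenomicRanges::start(ann))
})

test_that("noiseless planted effects realize exact area ratios", {
  cfg <- sim_config(seed = 5, peak_count = 60, noise_cv = 0, gain_fc = 2.0,
                    loss_fc = 0.4, n_reps = 2L)
  sim <- simulate_tracks(cfg)
  a_t <- peak_area(sim$tracks$treatment[[1]], sim$peaks)
  a_v <- peak_area(sim$tracks$vehicle[[1]], sim$peaks)
  ratio <- a_t / a_v
  expect_equal(ratio, sim$truth$fc, tolerance = 1e-12)
  expect_true(all(sim$truth$class[abs(ratio - 2) < 1e-9] == "gain"))
})

test_that("class fractions, truth completeness and determinism hold", {
  cfg <- sim_config(seed = 6, peak_count = 100, frac_gain = 0.2,
                    frac_loss = 0.1)
  sim <- simulate_tracks(cfg)
  expect_identical(nrow(sim$truth), 100L)
  expect_identical(anyDuplicated(sim$truth$peak_id), 0L)
  expect_equal(sum(sim$truth$class == "gain"), 20)
  expect_equal(sum(sim$truth$class == "loss"), 10)
  expect_setequal(unique(sim$truth$class), c("gain", "loss", "null"))

  nullcfg <- sim_config(seed = 6, peak_count = 40, frac_gain = 0,
                        frac_loss = 0)
  expect_true(all(simulate_tracks(nullcfg)$truth$class == "null"))

  sim2 <- simulate_tracks(cfg)
  expect_identical(sim$truth, sim2$truth)
  expect_identical(
    S4Vectors::mcols(sim$tracks$treatment[[2]])$score,
    S4Vectors::mcols(sim2$tracks$treatment[[2]])$score)
})

test_that("planted peaks cannot be squeezed into an impossible genome", {
  tiny <- sim_config(seed = 7, chrom_lengths = c(chr1 = 20000),
                     peak_count = 50L)
  expect_error(simulate_tracks(tiny), "place peak")
})

test_that("simulated beta shifts are exact pre-clipping and deterministic", {
  cfg <- sim_config(seed = 8, beta_noise_sd = 0,
                    dmr_specs = list(list(start = 50L, n = 8L,
                                          delta = 0.30)))
  sim <- simulate_beta(cfg)
  d <- delta_beta(sim$beta, sim$groups$a, sim$groups$b)
  in_run <- 50:57
  bg <- setdiff(seq_len(cfg$n_cpgs), in_run)
  expect_true(all(abs(d$delta[bg]) < 1e-12))
  # exact +0.30 wherever the shift did not clip
  base <- as.data.frame(sim$beta)[in_run, sim$groups$a[1]]
  unclipped <- base + 0.30 <= 1
  expect_equal(d$delta[in_run][unclipped],
               rep(0.30, sum(unclipped)), tolerance = 1e-12)

  sim2 <- simulate_beta(cfg)
  expect_identical(as.data.frame(sim$beta), as.data.frame(sim2$beta))
  expect_error(sim_config(seed = 8, dmr_specs = list(
    list(start = 10L, n = 8L, delta = 0.2),
    list(start = 15L, n = 5L, delta = 0.2))), "overlap")
})

test_that("screen plates plant hits, toxicity and low expression as told", {
  cfg <- sim_config(seed = 9, screen_size = 5000, n_hits = 25, n_toxic = 40,
                    n_low_expr = 100)
  sim <- simulate_screen(cfg)
  expect_identical(nrow(sim$wells), 5000L)
  expect_identical(sum(sim$truth$class == "hit"), 25L)
  expect_identical(sum(sim$truth$class == "toxic"), 40L)
  expect_identical(sum(sim$truth$low_expression), 100L)
  toxic <- sim$truth$class == "toxic"
  expect_true(all(sim$wells$confluency[toxic] <
                    mean(sim$wells$confluency) - sd(sim$wells$confluency)))
  low <- sim$truth$low_expression
  expect_true(all(sim$cpm$basal[low] < 100 & sim$cpm$treated[low] < 100))
  expect_true(all(sim$cpm$basal[!low] >= 100))
  sim2 <- simulate_screen(cfg)
  expect_identical(sim$wells, sim2$wells)
  expect_error(sim_config(seed = 9, hit_effect = 0))
})
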