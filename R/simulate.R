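#' Simulation configuration
#'
#' One configuration object drives all four generators (annotation, tracks,
#' beta matrix, screen). Defaults emulate the design of a quantitative
#' ChIP study of H3K27 marks: 3 biological replicates per treatment arm,
#' peaks with a high density of short widths (~350 bp) and a broad tail
#' (~2 kb), multiplicative replicate noise with a 10% coefficient of
#' variation, an 18-state chromatin annotation condensible to 4 categories,
#' array-style beta values with planted contiguous-probe DMRs, and an
#' ~18,000-gene arrayed reporter screen with planted activating hits and
#' planted toxic genes.
#'
#' @param seed Master seed; each generator derives its own deterministic
#'   stream from it.
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param state_props Named numeric vector of per-state genome proportions
#'   (must sum to 1 within 1e-9).
#' @param seg_len Mean chromatin-segment length (bp).
#' @param peak_count Number of planted peaks.
#' @param frac_gain,frac_loss Fractions of peaks planted as gains/losses.
#' @param gain_fc,loss_fc Multiplicative treatment effects (`> 0`).
#' @param narrow_mean,narrow_cv Narrow width mode: mean bp, lognormal CV.
#' @param broad_mean,broad_cv Broad width mode: mean bp, lognormal CV.
#' @param narrow_weight Mixture weight of the narrow component.
#' @param n_reps Biological replicates per arm.
#' @param noise_cv Coefficient of variation of multiplicative (lognormal)
#'   replicate noise on peak height.
#' @param peak_height Baseline peak height (efficiency units).
#' @param background Background signal level outside peaks.
#' @param min_peak_gap Minimum bp between planted peaks.
#' @param n_cpgs Number of array probes.
#' @param probe_gap_range Range (bp) of inter-probe spacing.
#' @param beta_noise_sd Per-sample Gaussian noise SD on beta values.
#' @param n_beta_samples Samples per methylation group.
#' @param dmr_specs List of planted runs, each
#'   `list(start = probe index, n = probes, delta = signed beta shift)`;
#'   runs must not overlap.
#' @param screen_size Number of screened genes.
#' @param n_hits Planted activating hits.
#' @param hit_effect Hit effect size in null-SD units (`> 0`).
#' @param n_toxic Planted toxic (viability-reducing) genes.
#' @param n_low_expr Planted lowly expressed genes (CPM < 100 everywhere).
#' @param confluency_mean,confluency_sd Null confluency distribution (%).
#' @param score_mean,score_sd Null normalized-score distribution.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 2e6, chr2 = 2e6),
                       state_props = default_state_props(),
                       seg_len = 1500,
                       peak_count = 200L,
                       frac_gain = 0.2, frac_loss = 0.2,
                       gain_fc = 2.0, loss_fc = 0.4,
                       narrow_mean = 350, narrow_cv = 0.15,
                       broad_mean = 2000, broad_cv = 0.30,
                       narrow_weight = 0.7,
                       n_reps = 3L,
                       noise_cv = 0.10,
                       peak_height = 1.0,
                       background = 0.05,
                       min_peak_gap = 1000L,
                       n_cpgs = 2000L,
                       probe_gap_range = c(100L, 800L),
                       beta_noise_sd = 0.02,
                       n_beta_samples = 3L,
                       dmr_specs = default_dmr_specs(),
                       screen_size = 18000L,
                       n_hits = 50L,
                       hit_effect = 8,
                       n_toxic = 100L,
                       n_low_expr = 500L,
                       confluency_mean = 80, confluency_sd = 5,
                       score_mean = 20, score_sd = 4) {
  cfg <- list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
              state_props = state_props, seg_len = seg_len,
              peak_count = as.integer(peak_count),
              frac_gain = frac_gain, frac_loss = frac_loss,
              gain_fc = gain_fc, loss_fc = loss_fc,
              narrow_mean = narrow_mean, narrow_cv = narrow_cv,
              broad_mean = broad_mean, broad_cv = broad_cv,
              narrow_weight = narrow_weight,
              n_reps = as.integer(n_reps), noise_cv = noise_cv,
              peak_height = peak_height, background = background,
              min_peak_gap = as.integer(min_peak_gap),
              n_cpgs = as.integer(n_cpgs),
              probe_gap_range = probe_gap_range,
              beta_noise_sd = beta_noise_sd,
              n_beta_samples = as.integer(n_beta_samples),
              dmr_specs = dmr_specs,
              screen_size = as.integer(screen_size),
              n_hits = as.integer(n_hits), hit_effect = hit_effect,
              n_toxic = as.integer(n_toxic),
              n_low_expr = as.integer(n_low_expr),
              confluency_mean = confluency_mean,
              confluency_sd = confluency_sd,
              score_mean = score_mean, score_sd = score_sd)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Default 18-state genome proportions for the simulator
#'
#' Quiescent chromatin dominates, transcription and weak repression are
#' common, promoter and enhancer states are rare -- the qualitative shape of
#' real chromHMM segmentations of somatic cell lines.
#' @return Named numeric vector summing to 1.
#' @export
default_state_props <- function() {
  p <- c(TssA = 0.010, TssFlnk = 0.010, TssFlnkD = 0.005, TssFlnkU = 0.005,
         TssBiv = 0.005, EnhBiv = 0.010, EnhA1 = 0.010, EnhA2 = 0.010,
         EnhWk = 0.030, EnhG1 = 0.005, EnhG2 = 0.005,
         TxWk = 0.100, Tx = 0.050,
         ReprPCWk = 0.050, ReprPC = 0.020, Het = 0.050,
         `ZNF/Rpts` = 0.010, Quies = 0.615)
  p / sum(p)
}

#' Default planted methylation runs
#'
#' Includes one clearly qualifying hypermethylated run, one qualifying
#' hypomethylated run, one long moderate run, plus two decoys that fail one
#' admission criterion each: a 4-probe run (too few CpGs even at a large
#' shift) and a 6-probe run with mean shift below 0.20.
#' @return List of run specifications.
#' @export
default_dmr_specs <- function() {
  list(list(start = 101L, n = 8L, delta = 0.30),
       list(start = 301L, n = 6L, delta = -0.30),
       list(start = 501L, n = 10L, delta = 0.25),
       list(start = 701L, n = 4L, delta = 0.50),
       list(start = 901L, n = 6L, delta = 0.15))
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$peak_count >= 0, cfg$n_reps >= 1, cfg$noise_cv >= 0,
            cfg$gain_fc > 0, cfg$loss_fc > 0,
            cfg$frac_gain >= 0, cfg$frac_loss >= 0,
            cfg$frac_gain + cfg$frac_loss <= 1,
            cfg$narrow_weight >= 0, cfg$narrow_weight <= 1,
            cfg$background >= 0, cfg$peak_height > 0,
            cfg$hit_effect > 0,
            cfg$screen_size >= cfg$n_hits + cfg$n_toxic,
            all(cfg$chrom_lengths > 0))
  if (abs(sum(cfg$state_props) - 1) > 1e-9) {
    stop("state proportions must sum to 1 (got ", sum(cfg$state_props), ")",
         call. = FALSE)
  }
  for (spec in cfg$dmr_specs) {
    stopifnot(spec$n >= 1, abs(spec$delta) <= 1)
  }
  if (length(cfg$dmr_specs) > 1) {
    iv <- t(vapply(cfg$dmr_specs,
                   function(s) c(s$start, s$start + s$n - 1L), numeric(2)))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (any(iv[-1, 1] <= iv[-nrow(iv), 2])) {
      stop("planted DMR probe runs overlap", call. = FALSE)
    }
  }
  ends <- vapply(cfg$dmr_specs, function(s) s$start + s$n - 1L, numeric(1))
  if (length(ends) && max(ends) > cfg$n_cpgs) {
    stop("planted DMR run extends past the last probe", call. = FALSE)
  }
  invisible(cfg)
}

# independent deterministic stream per generator, derived from the master
# seed; constants keep derived seeds well inside 32-bit range
.stream_seed <- function(cfg, stage) {
  offs <- c(annotation = 1001L, tracks = 2003L, beta = 3005L,
            screen = 4007L)
  (cfg$seed %% 100000L) * 10000L + offs[[stage]]
}

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Simulate a chromatin-state annotation
#'
#' Tiles each chromosome with disjoint labeled segments. Per-state coverage
#' is allocated exactly as `proportion * chromosome length` (largest state
#' absorbs rounding), cut into segments of roughly `seg_len` bp, and the
#' segments are laid down in shuffled order, so coverage conservation is
#' exact and every state with positive proportion appears.
#'
#' @param config A [sim_config()].
#' @return A `GRanges` with `name` = state label and seqlengths set.
#' @export
simulate_annotation <- function(config) {
  validate_sim_config(config)
  props <- config$state_props
  if (abs(sum(props) - 1) > 1e-9) {
    stop("state proportions must sum to 1", call. = FALSE)
  }
  props <- props[props > 0]
  .with_seed(.stream_seed(config, "annotation"), {
    per_chrom <- lapply(names(config$chrom_lengths), function(ch) {
      L <- config$chrom_lengths[[ch]]
      cov <- floor(props * L)
      cov[which.max(cov)] <- cov[which.max(cov)] + (L - sum(cov))
      pieces_state <- character(0)
      pieces_len <- numeric(0)
      for (st in names(cov)) {
        if (cov[[st]] <= 0) next
        n_seg <- max(1L, round(cov[[st]] / config$seg_len))
        cuts <- sort(sample.int(cov[[st]] - 1, min(n_seg - 1, cov[[st]] - 1)))
        lens <- diff(c(0, cuts, cov[[st]]))
        pieces_state <- c(pieces_state, rep(st, length(lens)))
        pieces_len <- c(pieces_len, lens)
      }
      ord <- sample.int(length(pieces_len))
      pieces_state <- pieces_state[ord]
      pieces_len <- pieces_len[ord]
      ends <- cumsum(pieces_len)
      data.frame(chrom = ch, start = c(0, ends[-length(ends)]), end = ends,
                 name = pieces_state, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, per_chrom)
    .gr0(df$chrom, df$start, df$end, name = df$name,
         seqlengths = config$chrom_lengths)
  })
}

#' Simulate multi-replicate quantitative tracks with planted effects
#'
#' Plants `peak_count` rectangular peaks (constant height over width, which
#' keeps area ratios analytically exact) at non-overlapping positions.
#' Widths are drawn from a two-component lognormal mixture (narrow/broad).
#' Peak classes are `gain`, `loss` or `null` in the configured fractions.
#' Vehicle-arm peak heights are `peak_height` times multiplicative
#' lognormal replicate noise with the configured CV (lognormal noise keeps
#' efficiency values non-negative; its meanlog is set so the noise has mean
#' exactly 1, hence CV 0 means no noise at all); treatment-arm heights are
#' additionally multiplied by the planted fold-change (x1 for null peaks).
#' Background signal covers the rest of each chromosome.
#'
#' @param config A [sim_config()].
#' @param annotation Optional annotation (unused for placement; accepted so
#'   pipelines can thread one object through).
#' @param max_tries Placement retries per peak before giving up.
#' @return A list: `tracks` (`$vehicle` and `$treatment`, each a list of
#'   `n_reps` `GRanges` tracks), `peaks` (`GRanges` with `peak_id`), and
#'   `truth` (`data.frame`: `peak_id`, `chrom`, `start`, `end`, `width`,
#'   `class`, `fc`, `width_component`).
#' @export
simulate_tracks <- function(config, annotation = NULL, max_tries = 200L) {
  validate_sim_config(config)
  .with_seed(.stream_seed(config, "tracks"), {
    n <- config$peak_count
    comp <- ifelse(stats::runif(n) < config$narrow_weight, "narrow", "broad")
    sdlog_n <- sqrt(log(1 + config$narrow_cv^2))
    sdlog_b <- sqrt(log(1 + config$broad_cv^2))
    widths <- ifelse(
      comp == "narrow",
      stats::rlnorm(n, log(config$narrow_mean) - sdlog_n^2 / 2, sdlog_n),
      stats::rlnorm(n, log(config$broad_mean) - sdlog_b^2 / 2, sdlog_b))
    widths <- pmax(50L, round(widths))
    chroms <- names(config$chrom_lengths)
    placed <- data.frame(chrom = character(0), start = numeric(0),
                         end = numeric(0))
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        ch <- sample(chroms, 1, prob = config$chrom_lengths)
        L <- config$chrom_lengths[[ch]]
        if (L <= widths[i] + 2 * config$min_peak_gap) next
        s <- floor(stats::runif(1, config$min_peak_gap,
                                L - widths[i] - config$min_peak_gap))
        e <- s + widths[i]
        same <- placed[placed$chrom == ch, , drop = FALSE]
        if (nrow(same) == 0 ||
            all(s - config$min_peak_gap >= same$end |
                e + config$min_peak_gap <= same$start)) {
          placed <- rbind(placed, data.frame(chrom = ch, start = s, end = e))
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("could not place peak ", i, " without overlap after ",
             max_tries, " tries; reduce peak_count or widths", call. = FALSE)
      }
    }
    n_gain <- round(config$frac_gain * n)
    n_loss <- round(config$frac_loss * n)
    class <- sample(c(rep("gain", n_gain), rep("loss", n_loss),
                      rep("null", n - n_gain - n_loss)))
    fc <- ifelse(class == "gain", config$gain_fc,
                 ifelse(class == "loss", config$loss_fc, 1.0))
    sdlog <- sqrt(log(1 + config$noise_cv^2))
    noise <- function(k) {
      if (config$noise_cv == 0) rep(1, k) else
        stats::rlnorm(k, -sdlog^2 / 2, sdlog)
    }
    heights_veh <- matrix(config$peak_height * noise(n * config$n_reps),
                          nrow = n)
    heights_trt <- matrix(config$peak_height * fc * noise(n * config$n_reps),
                          nrow = n)
    ord <- order(placed$chrom, placed$start)
    build_track <- function(heights) {
      segs <- lapply(chroms, function(ch) {
        idx <- ord[placed$chrom[ord] == ch]
        L <- config$chrom_lengths[[ch]]
        ps <- placed$start[idx]; pe <- placed$end[idx]
        bg_s <- c(0, pe); bg_e <- c(ps, L)
        keep <- bg_e > bg_s
        df <- rbind(
          data.frame(chrom = ch, start = ps, end = pe, score = heights[idx]),
          if (config$background > 0)
            data.frame(chrom = ch, start = bg_s[keep], end = bg_e[keep],
                       score = config$background)
        )
        df[order(df$start), , drop = FALSE]
      })
      df <- do.call(rbind, segs)
      .gr0(df$chrom, df$start, df$end, score = df$score,
           seqlengths = config$chrom_lengths)
    }
    tracks <- list(
      vehicle = lapply(seq_len(config$n_reps),
                       function(r) build_track(heights_veh[, r])),
      treatment = lapply(seq_len(config$n_reps),
                         function(r) build_track(heights_trt[, r]))
    )
    peak_id <- sprintf("peak_%04d", seq_len(n))
    peaks <- .gr0(placed$chrom, placed$start, placed$end,
                  peak_id = peak_id, seqlengths = config$chrom_lengths)
    truth <- data.frame(peak_id = peak_id, chrom = placed$chrom,
                        start = placed$start, end = placed$end,
                        width = widths, class = class, fc = fc,
                        width_component = comp, stringsAsFactors = FALSE)
    o <- order(truth$chrom, truth$start)
    list(tracks = tracks,
         peaks = GenomicRanges::sort(peaks, ignore.strand = TRUE),
         truth = truth[o, , drop = FALSE])
  })
}

#' Simulate a methylation beta matrix with planted DMRs
#'
#' Probe positions are laid down with spacing drawn uniformly from
#' `probe_gap_range` (so consecutive probes stay within a 1 kb contiguity
#' bound). Each probe gets a baseline methylation level from a Beta(5, 5)
#' distribution; per-sample values are the baseline plus Gaussian noise,
#' clipped to `[0, 1]`. Within each planted run the group-B (treated)
#' samples are shifted by the run's delta before clipping.
#'
#' @param config A [sim_config()].
#' @return A list: `beta` (a `beta_matrix` with samples `vehA_1..n` and
#'   `treatB_1..n`), `groups` (list `a`, `b` of column names), and `truth`
#'   (`data.frame`: `run_id`, `chrom`, `start_index`, `n_probes`, `delta`,
#'   `start`, `end`, `qualifies` under the >= 5 CpG / mean 0.20 criterion).
#' @export
simulate_beta <- function(config) {
  validate_sim_config(config)
  .with_seed(.stream_seed(config, "beta"), {
    n <- config$n_cpgs
    gaps <- sample(seq(config$probe_gap_range[1], config$probe_gap_range[2]),
                   n, replace = TRUE)
    pos <- cumsum(gaps)
    baseline <- stats::rbeta(n, 5, 5)
    ns <- config$n_beta_samples
    a_names <- sprintf("vehA_%d", seq_len(ns))
    b_names <- sprintf("treatB_%d", seq_len(ns))
    shift <- numeric(n)
    for (spec in config$dmr_specs) {
      idx <- spec$start:(spec$start + spec$n - 1L)
      shift[idx] <- spec$delta
    }
    clip <- function(x) pmin(1, pmax(0, x))
    df <- data.frame(probe = sprintf("cg%07d", seq_len(n)), chrom = "chr1",
                     pos = pos, stringsAsFactors = FALSE)
    for (s in a_names) {
      df[[s]] <- clip(baseline + stats::rnorm(n, 0, config$beta_noise_sd))
    }
    for (s in b_names) {
      df[[s]] <- clip(baseline + shift +
                        stats::rnorm(n, 0, config$beta_noise_sd))
    }
    beta <- structure(df, samples = c(a_names, b_names),
                      class = c("beta_matrix", "data.frame"))
    truth <- do.call(rbind, lapply(seq_along(config$dmr_specs), function(i) {
      spec <- config$dmr_specs[[i]]
      last <- spec$start + spec$n - 1L
      data.frame(run_id = sprintf("run_%02d", i), chrom = "chr1",
                 start_index = spec$start, n_probes = spec$n,
                 delta = spec$delta, start = pos[spec$start],
                 end = pos[last] + 1L,
                 qualifies = spec$n >= 5L && abs(spec$delta) >= 0.20,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(truth)) {
      truth <- data.frame(run_id = character(0), chrom = character(0),
                          start_index = integer(0), n_probes = integer(0),
                          delta = numeric(0), start = integer(0),
                          end = integer(0), qualifies = logical(0))
    }
    list(beta = beta, groups = list(a = a_names, b = b_names), truth = truth)
  })
}

#' Simulate an arrayed reporter screen with planted hits
#'
#' Null wells draw confluency and normalized score from the configured
#' Gaussian distributions (scores floored at a small positive value and
#' converted back to raw luminescence as `score * confluency`). Planted
#' hits get a normalized score of exactly the null mean plus
#' `hit_effect` null SDs (empirical moments of the generated null wells).
#' Planted toxic genes get confluency 2.5 +/- 0.5 SD below the mean, safely
#' past a one-SD viability filter. Planted low-expression genes get CPM
#' below 100 in both expression conditions; all other genes get clearly
#' expressed CPM values.
#'
#' @param config A [sim_config()].
#' @return A list: `wells` (`data.frame`: `gene`, `rlu`, `confluency`),
#'   `cpm` (`data.frame`: `gene`, `basal`, `treated`), and `truth`
#'   (`data.frame`: `gene`, `class` in hit/toxic/null, `effect`,
#'   `low_expression`).
#' @export
simulate_screen <- function(config) {
  validate_sim_config(config)
  .with_seed(.stream_seed(config, "screen"), {
    n <- config$screen_size
    genes <- sprintf("GENE%05d", seq_len(n))
    roles <- rep("null", n)
    special <- sample.int(n, config$n_hits + config$n_toxic)
    hit_idx <- special[seq_len(config$n_hits)]
    toxic_idx <- special[config$n_hits + seq_len(config$n_toxic)]
    roles[hit_idx] <- "hit"
    roles[toxic_idx] <- "toxic"
    low_pool <- which(roles == "null")
    low_idx <- sample(low_pool, min(config$n_low_expr, length(low_pool)))
    confluency <- pmin(100, pmax(1, stats::rnorm(
      n, config$confluency_mean, config$confluency_sd)))
    confluency[toxic_idx] <- pmax(1, config$confluency_mean -
      (2.5 + stats::runif(length(toxic_idx), -0.5, 0.5)) *
        config$confluency_sd)
    # hits are activating, not toxic: give them at-least-average viability
    # so a one-SD viability filter cannot swallow a planted hit
    confluency[hit_idx] <- pmin(100, config$confluency_mean +
      abs(stats::rnorm(length(hit_idx), 0, config$confluency_sd)))
    score <- pmax(0.1, stats::rnorm(n, config$score_mean, config$score_sd))
    null_like <- setdiff(seq_len(n), hit_idx)
    mu0 <- mean(score[null_like])
    sd0 <- stats::sd(score[null_like])
    score[hit_idx] <- mu0 + config$hit_effect * sd0
    wells <- data.frame(gene = genes, rlu = score * confluency,
                        confluency = confluency, stringsAsFactors = FALSE)
    basal <- stats::rlnorm(n, log(1000), 1) + 100
    treated <- stats::rlnorm(n, log(1000), 1) + 100
    basal[low_idx] <- stats::runif(length(low_idx), 0, 99)
    treated[low_idx] <- stats::runif(length(low_idx), 0, 99)
    cpm <- data.frame(gene = genes, basal = basal, treated = treated,
                      stringsAsFactors = FALSE)
    truth <- data.frame(gene = genes, class = roles,
                        effect = ifelse(roles == "hit", config$hit_effect,
                                        NA_real_),
                        low_expression = seq_len(n) %in% low_idx,
                        stringsAsFactors = FALSE)
    list(wells = wells, cpm = cpm, truth = truth)
  })
}
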