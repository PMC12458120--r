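#' Mark-specific significance configuration
#'
#' Thresholds on the mean log2 fold-change in response, plus an optional
#' ceiling on the replicate variance. Two presets reflect how differently
#' the two H3K27 marks behave: acetylation responds strongly and is called
#' on asymmetric thresholds (gain at log2(1.5) = 0.585, loss at -1.0, no
#' variance gate); mono-methylation responds subtly and with high replicate
#' variability, so it uses symmetric +/-0.5 thresholds and additionally
#' requires the replicate variance to be at most 1.
#'
#' @param mark `"h3k27ac"`, `"h3k27me1"`, or `"custom"`.
#' @param gain Gain threshold (log2FC, `> 0`); required for `"custom"`.
#' @param loss Loss threshold (log2FC, `< 0`); required for `"custom"`.
#' @param var_max Optional variance ceiling (`> 0`), or `NULL` for no gate.
#' @return A list of class `mark_config`.
#' @examples
#' mark_config("h3k27ac")
#' mark_config("custom", gain = 1, loss = -1, var_max = 0.5)
#' @export
mark_config <- function(mark = c("h3k27ac", "h3k27me1", "custom"),
                        gain = NULL, loss = NULL, var_max = NULL) {
  mark <- match.arg(mark)
  if (mark == "h3k27ac") {
    if (is.null(gain)) gain <- 0.585
    if (is.null(loss)) loss <- -1.0
  } else if (mark == "h3k27me1") {
    if (is.null(gain)) gain <- 0.5
    if (is.null(loss)) loss <- -0.5
    if (is.null(var_max)) var_max <- 1.0
  }
  stopifnot(is.numeric(gain), is.numeric(loss), gain > 0, loss < 0)
  if (!is.null(var_max)) stopifnot(var_max > 0)
  structure(list(mark = mark, gain = gain, loss = loss, var_max = var_max),
            class = "mark_config")
}

#' Call significant gains and losses from a response table
#'
#' Pure threshold application, with all comparisons inclusive: a peak is a
#' `gain` when `mean_log2fc >= gain`, a `loss` when `mean_log2fc <= loss`,
#' otherwise `not_significant`. When the configuration carries a variance
#' ceiling, gains and losses additionally require `variance <= var_max`;
#' peaks over the ceiling are `not_significant` regardless of effect size.
#'
#' @param responses A `response_table` from [replicate_response()].
#' @param config A [mark_config()].
#' @return The response table with an added factor column `call` with levels
#'   `gain`, `loss`, `not_significant`.
#' @export
call_differential <- function(responses, config) {
  stopifnot(inherits(config, "mark_config"),
            all(c("mean_log2fc", "variance") %in% names(responses)))
  m <- responses$mean_log2fc
  call <- rep("not_significant", length(m))
  call[m >= config$gain] <- "gain"
  call[m <= config$loss] <- "loss"
  if (!is.null(config$var_max)) {
    call[responses$variance > config$var_max] <- "not_significant"
  }
  responses$call <- factor(call, levels = c("gain", "loss", "not_significant"))
  responses
}

#' Fit a two-component Gaussian mixture to peak widths
#'
#' Peak widths from quantitative ChIP tracks of broadly distributed marks
#' show a high density of short peaks (a few hundred bp) plus a tail of much
#' broader domains; a two-component Gaussian mixture on log10 width
#' separates the two. Widths are strictly positive and right-skewed, so the
#' fit is on the log scale. The EM is deterministically initialised from the
#' exact 1-D 2-means split of the sorted log-widths, which makes the fit a
#' pure function of the input (the `seed` argument is accepted for interface
#' uniformity but no randomness is used).
#'
#' @param widths Numeric vector of peak widths in bp; at least 10 values
#'   with at least 2 distinct values are required.
#' @param seed Unused; retained so all model-fitting functions share a
#'   signature.
#' @param max_iter,tol EM stopping controls.
#' @return A list of class `width_mixture` with elements `mean`, `sd`,
#'   `weight` (each length 2, component 1 = smaller mean = "narrow"),
#'   `posterior_narrow` (per input width), `loglik`, `iterations`.
#' @export
fit_width_mixture <- function(widths, seed = NULL, max_iter = 500,
                              tol = 1e-8) {
  stopifnot(is.numeric(widths), all(widths > 0))
  if (length(widths) < 10L || length(unique(widths)) < 2L) {
    stop("degenerate width distribution (need >= 10 widths, >= 2 distinct); ",
         "treat all peaks as a single shape class instead", call. = FALSE)
  }
  x <- log10(widths)
  # exact 1-D 2-means: best split point of the sorted values
  xs <- sort(x)
  n <- length(xs)
  css <- cumsum(xs); css2 <- cumsum(xs^2)
  k <- seq_len(n - 1)
  ss_left <- css2[k] - css[k]^2 / k
  ss_right <- (css2[n] - css2[k]) - (css[n] - css[k])^2 / (n - k)
  split <- which.min(ss_left + ss_right)
  mu <- c(mean(xs[1:split]), mean(xs[(split + 1):n]))
  sg <- c(stats::sd(xs[1:split]), stats::sd(xs[(split + 1):n]))
  sg[is.na(sg) | sg < 1e-3] <- 1e-3
  w <- c(split, n - split) / n
  loglik <- -Inf
  it <- 0L
  repeat {
    it <- it + 1L
    d1 <- w[1] * stats::dnorm(x, mu[1], sg[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    r1 <- d1 / tot
    if (abs(ll - loglik) < tol || it >= max_iter) {
      loglik <- ll
      break
    }
    loglik <- ll
    n1 <- sum(r1); n2 <- length(x) - n1
    mu <- c(sum(r1 * x) / n1, sum((1 - r1) * x) / n2)
    sg <- sqrt(c(sum(r1 * (x - mu[1])^2) / n1,
                 sum((1 - r1) * (x - mu[2])^2) / n2))
    sg[sg < 1e-3] <- 1e-3
    w <- c(n1, n2) / length(x)
  }
  if (mu[1] > mu[2]) { # component 1 is always the narrow (smaller-mean) one
    mu <- rev(mu); sg <- rev(sg); w <- rev(w); r1 <- 1 - r1
  }
  structure(list(mean = mu, sd = sg, weight = w, posterior_narrow = r1,
                 loglik = loglik, iterations = it),
            class = "width_mixture")
}

#' Posterior probability of the narrow component for new widths
#'
#' @param mixture A fitted [fit_width_mixture()] object.
#' @param widths Peak widths in bp.
#' @return Numeric vector of posterior probabilities of the smaller-mean
#'   (narrow) component.
#' @export
posterior_narrow <- function(mixture, widths) {
  stopifnot(inherits(mixture, "width_mixture"), all(widths > 0))
  x <- log10(widths)
  d1 <- mixture$weight[1] * stats::dnorm(x, mixture$mean[1], mixture$sd[1])
  d2 <- mixture$weight[2] * stats::dnorm(x, mixture$mean[2], mixture$sd[2])
  tot <- d1 + d2
  tot[tot == 0] <- .Machine$double.xmin
  d1 / tot
}

#' Classify peaks as narrow or broad
#'
#' A peak is `narrow` when its posterior probability under the smaller-mean
#' mixture component is at least 0.5 (a posterior of exactly 0.5 resolves to
#' `narrow`; this tie rule is part of the contract), else `broad`.
#'
#' @param calls A `data.frame` with a `width` column (typically the output
#'   of [call_differential()]).
#' @param mixture A fitted [fit_width_mixture()] object.
#' @return `calls` with added columns `posterior_narrow` and factor `shape`
#'   (`narrow`/`broad`).
#' @export
classify_shapes <- function(calls, mixture) {
  stopifnot("width" %in% names(calls))
  p <- posterior_narrow(mixture, calls$width)
  calls$posterior_narrow <- p
  calls$shape <- factor(ifelse(p >= 0.5, "narrow", "broad"),
                        levels = c("narrow", "broad"))
  calls
}
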