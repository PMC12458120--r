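#' Normalize screen wells to confluency
#'
#' Background-subtracted luminescence per percent confluency: the raw
#' readout of each siRNA well is floored at zero after subtracting the
#' media-only background, then divided by the well's confluency so the
#' score reflects per-cell reporter activity. Wells with non-positive
#' confluency cannot be normalized and are flagged invalid.
#'
#' @param wells `data.frame` with columns `gene`, `rlu` (relative
#'   luminescence units, non-negative) and `confluency` (percent).
#' @param background Media-only background RLU (`>= 0`, default 0).
#' @return The wells with added columns `score` (NA when invalid) and
#'   logical `invalid`.
#' @export
normalize_wells <- function(wells, background = 0) {
  stopifnot(all(c("gene", "rlu", "confluency") %in% names(wells)),
            background >= 0)
  invalid <- !(wells$confluency > 0)
  score <- ifelse(invalid, NA_real_,
                  pmax(wells$rlu - background, 0) / wells$confluency)
  wells$score <- score
  wells$invalid <- invalid
  wells
}

#' Apply expression and viability exclusion filters
#'
#' Two classes of wells are excluded before hit calling. Genes that are very
#' lowly or not expressed (CPM below `cpm_min` in every provided expression
#' condition) cannot give a real reactivation signal, so they are flagged
#' `low_expression`; a gene expressed in at least one condition is kept, and
#' a gene missing from the CPM table is treated as unexpressed. Genes whose
#' knockdown kills cells confound the readout, so wells whose confluency
#' falls more than `sd_mult` standard deviations below the mean confluency
#' (computed over all valid wells) are flagged `toxic`.
#'
#' @param wells Output of [normalize_wells()].
#' @param cpm_table `data.frame` with a `gene` column plus one numeric CPM
#'   column per expression condition.
#' @param cpm_min CPM threshold (default 100, exclusive: `CPM < 100` is low).
#' @param sd_mult Confluency SD multiplier (default 1).
#' @return The wells with added logical columns `low_expression`, `toxic`.
#' @export
filter_wells <- function(wells, cpm_table, cpm_min = 100, sd_mult = 1.0) {
  stopifnot("gene" %in% names(cpm_table), "score" %in% names(wells))
  cpm_cols <- setdiff(names(cpm_table), "gene")
  stopifnot(length(cpm_cols) >= 1)
  cpm <- as.matrix(cpm_table[, cpm_cols, drop = FALSE])
  low_by_gene <- apply(cpm < cpm_min, 1, all)
  names(low_by_gene) <- cpm_table$gene
  idx <- match(wells$gene, cpm_table$gene)
  wells$low_expression <- ifelse(is.na(idx), TRUE, low_by_gene[idx])
  valid <- !wells$invalid
  mu <- mean(wells$confluency[valid])
  sdv <- stats::sd(wells$confluency[valid])
  wells$toxic <- valid & wells$confluency < mu - sd_mult * sdv
  wells
}

#' Call screen hits by Z-score
#'
#' Z-scores are computed on the normalized scores of the retained wells
#' (valid, expressed, non-toxic): `z = (score - mean) / sd` with the
#' unbiased sample SD. A well is a hit when its Z-score strictly exceeds
#' `z_min`; excluded wells carry no Z-score and can never be hits.
#'
#' @param wells Output of [filter_wells()].
#' @param z_min Z-score threshold (default 4; strict inequality).
#' @return List: `wells` (with added `zscore`, NA for excluded wells, and
#'   logical `hit`), `hits` (hit rows sorted by descending Z-score).
#' @export
call_hits <- function(wells, z_min = 4.0) {
  stopifnot(all(c("score", "invalid", "low_expression", "toxic") %in%
                names(wells)))
  keep <- !wells$invalid & !wells$low_expression & !wells$toxic
  if (sum(keep) < 2L) {
    stop("need at least 2 retained wells to compute Z-scores", call. = FALSE)
  }
  mu <- mean(wells$score[keep])
  sdv <- stats::sd(wells$score[keep])
  if (sdv == 0) {
    stop("retained scores have zero standard deviation", call. = FALSE)
  }
  wells$zscore <- ifelse(keep, (wells$score - mu) / sdv, NA_real_)
  wells$hit <- !is.na(wells$zscore) & wells$zscore > z_min
  hits <- wells[wells$hit, , drop = FALSE]
  hits <- hits[order(-hits$zscore), , drop = FALSE]
  list(wells = wells, hits = hits)
}
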