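#' Default 18-state to 4-category condensation map
#'
#' The standard 18-state chromHMM vocabulary collapsed to four general
#' genomic annotation categories: Promoter (TssA, TssFlnk, TssFlnkD,
#' TssFlnkU, TssBiv), Enhancer (EnhBiv, EnhA1, EnhA2, EnhWk, EnhG1, EnhG2),
#' Genic (TxWk, Tx) and Repressive (ReprPCWk, ReprPC, Het, Quies, ZNF/Rpts).
#'
#' @return Named character vector mapping state label to category.
#' @export
chromhmm_condensation <- function() {
  c(TssA = "Promoter", TssFlnk = "Promoter", TssFlnkD = "Promoter",
    TssFlnkU = "Promoter", TssBiv = "Promoter",
    EnhBiv = "Enhancer", EnhA1 = "Enhancer", EnhA2 = "Enhancer",
    EnhWk = "Enhancer", EnhG1 = "Enhancer", EnhG2 = "Enhancer",
    TxWk = "Genic", Tx = "Genic",
    ReprPCWk = "Repressive", ReprPC = "Repressive", Het = "Repressive",
    Quies = "Repressive", `ZNF/Rpts` = "Repressive")
}

#' Condense a chromatin-state annotation into broader categories
#'
#' Replaces every state label by its category and merges runs of adjacent
#' same-category intervals, conserving total coverage exactly.
#'
#' @param annotation A `GRanges` with a `name` column of state labels
#'   (disjoint intervals tiling the genome, as from a chromHMM
#'   segmentation BED).
#' @param map Named character vector state -> category; defaults to
#'   [chromhmm_condensation()]. Every label present in the annotation must
#'   be mapped.
#' @return A `GRanges` with `name` holding the categories, adjacent
#'   same-category intervals merged.
#' @export
condense_states <- function(annotation, map = chromhmm_condensation()) {
  stopifnot(methods::is(annotation, "GRanges"),
            "name" %in% names(S4Vectors::mcols(annotation)))
  labels <- S4Vectors::mcols(annotation)$name
  unmapped <- setdiff(unique(labels), names(map))
  if (length(unmapped)) {
    stop("state label(s) not in condensation map: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  ann <- GenomicRanges::sort(annotation, ignore.strand = TRUE)
  cat <- unname(map[S4Vectors::mcols(ann)$name])
  if (length(ann) == 0L) {
    S4Vectors::mcols(ann)$name <- character(0)
    return(ann)
  }
  chrom <- as.character(GenomeInfoDb::seqnames(ann))
  s <- GenomicRanges::start(ann)
  e <- GenomicRanges::end(ann)
  # merge a run when chromosome and category repeat and intervals touch
  new_run <- c(TRUE, !(chrom[-1] == chrom[-length(chrom)] &
                       cat[-1] == cat[-length(cat)] &
                       s[-1] <= e[-length(e)] + 1L))
  run <- cumsum(new_run)
  merged <- .gr0(
    chrom = chrom[new_run],
    start = tapply(s, run, min) - 1L,
    end = tapply(e, run, max),
    name = cat[new_run]
  )
  GenomeInfoDb::seqlevels(merged) <- GenomeInfoDb::seqlevels(ann)
  GenomeInfoDb::seqlengths(merged) <- GenomeInfoDb::seqlengths(ann)
  merged
}

#' Base-pair overlap enrichment of peaks in chromatin states
#'
#' For each state `s` the fold enrichment is the fraction of peak bases
#' falling in `s` divided by the fraction of the genome annotated `s`:
#' `fold(s) = (peak bp in s / total peak bp) / (state bp / genome bp)`.
#' Enrichment is base-pair weighted rather than peak-count weighted, so a
#' broad peak spanning several states contributes to each in proportion to
#' the exact interval intersection. A state with zero genomic coverage has
#' an undefined fold and is reported `NA`.
#'
#' @param peaks A `GRanges` of peaks (total width must be positive).
#' @param annotation A labeled `GRanges` (column `name`) tiling the genome.
#' @param genome_bp Total genome size in bp; defaults to the sum of
#'   `seqlengths(annotation)` when set, else to the annotation's total
#'   coverage (exact for a tiling annotation).
#' @return A `data.frame` (class `enrichment_result`) with columns `state`,
#'   `peak_bp`, `state_bp`, `fold`, sorted by state label.
#' @export
overlap_enrichment <- function(peaks, annotation, genome_bp = NULL) {
  stopifnot(methods::is(peaks, "GRanges"),
            "name" %in% names(S4Vectors::mcols(annotation)))
  peaks <- GenomicRanges::reduce(GenomicRanges::granges(peaks),
                                 ignore.strand = TRUE)
  total_peak <- sum(as.numeric(GenomicRanges::width(peaks)))
  if (total_peak <= 0) {
    stop("peak set has zero total width", call. = FALSE)
  }
  if (is.null(genome_bp)) {
    sl <- GenomeInfoDb::seqlengths(annotation)
    genome_bp <- if (length(sl) && !anyNA(sl)) sum(as.numeric(sl)) else
      sum(as.numeric(GenomicRanges::width(annotation)))
  }
  states <- sort(unique(S4Vectors::mcols(annotation)$name))
  res <- lapply(states, function(st) {
    stateset <- annotation[S4Vectors::mcols(annotation)$name == st]
    state_bp <- sum(as.numeric(GenomicRanges::width(GenomicRanges::reduce(
      GenomicRanges::granges(stateset), ignore.strand = TRUE))))
    inter <- GenomicRanges::intersect(peaks, GenomicRanges::granges(stateset),
                                      ignore.strand = TRUE)
    peak_bp <- sum(as.numeric(GenomicRanges::width(inter)))
    fold <- if (state_bp > 0) {
      (peak_bp / total_peak) / (state_bp / genome_bp)
    } else NA_real_
    data.frame(state = st, peak_bp = peak_bp, state_bp = state_bp,
               fold = fold, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Enrichment bias: fold enrichment as a percentage of total enrichment
#'
#' Expresses each state's fold enrichment as a percentage of the sum of the
#' fold enrichments over all defined states for this peak set, so per-state
#' biases sum to 100. States absent from the genome (undefined fold) are
#' excluded from the denominator and keep an `NA` bias.
#'
#' @param result An `enrichment_result` from [overlap_enrichment()].
#' @return The result with an added `bias` column (percent).
#' @export
enrichment_bias <- function(result) {
  stopifnot(inherits(result, "enrichment_result") ||
            "fold" %in% names(result))
  defined <- !is.na(result$fold)
  if (!any(defined)) stop("no defined fold enrichments", call. = FALSE)
  total <- sum(result$fold[defined])
  if (total <= 0) stop("all fold enrichments are zero", call. = FALSE)
  result$bias <- ifelse(defined, 100 * result$fold / total, NA_real_)
  result
}
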