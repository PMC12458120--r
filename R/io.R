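#' Coordinate conventions
#'
#' On disk (bedGraph, BED) coordinates are 0-based half-open `[start, end)`,
#' the native convention of both formats. In memory all intervals are held as
#' [GenomicRanges::GRanges] objects, which are 1-based closed; the readers and
#' writers in this file perform the `start + 1` shift in both directions, so
#' round trips are exact. All other functions in the package exchange
#' `GRanges` and never see the on-disk convention.
#'
#' @name quantepi-coordinates
#' @keywords internal
NULL

# Tokenize a whitespace-delimited text file, dropping comment (#), `track`
# and `browser` lines but remembering original line numbers for error messages.
.read_genomic_lines <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|track\\b|browser\\b)", raw) & nzchar(trimws(raw))
  list(lines = raw[keep], lineno = which(keep))
}

.split_fields <- function(line) {
  strsplit(trimws(line), "[ \t]+")[[1]]
}

#' Read a bedGraph file into a quantitative track
#'
#' A quantitative track is a stepwise-constant, non-negative signal surface
#' over the genome: here, the per-interval IP efficiency of a quantitative
#' ChIP experiment. Gaps between intervals are interpreted as signal 0, not
#' as missing data. The returned object is a `GRanges` with a numeric
#' `score` column, sorted, with strictly non-overlapping intervals.
#'
#' @param path Path to a bedGraph file (`chrom start end value`, whitespace
#'   or tab delimited; `track`/`browser`/comment lines are skipped).
#' @param seqlengths Optional named integer vector of chromosome lengths to
#'   attach to the result.
#' @return A `GRanges` with a `score` metadata column.
#' @examples
#' tf <- tempfile(fileext = ".bedGraph")
#' writeLines(c("chr1 0 100 1.0", "chr1 100 200 3.0"), tf)
#' read_bedgraph(tf)
#' @export
read_bedgraph <- function(path, seqlengths = NULL) {
  parsed <- .read_genomic_lines(path)
  n <- length(parsed$lines)
  if (n == 0L) {
    gr <- GenomicRanges::GRanges(score = numeric(0))
    if (!is.null(seqlengths)) {
      GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
      GenomeInfoDb::seqlengths(gr) <- seqlengths
    }
    return(gr)
  }
  fields <- lapply(parsed$lines, .split_fields)
  bad <- which(vapply(fields, length, integer(1)) < 4L)
  if (length(bad)) {
    stop("malformed bedGraph line ", parsed$lineno[bad[1]],
         ": expected 4 fields", call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  value <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 4L)))
  bad <- which(is.na(start) | is.na(end) | is.na(value))
  if (length(bad)) {
    stop("malformed bedGraph line ", parsed$lineno[bad[1]],
         ": non-numeric field", call. = FALSE)
  }
  if (any(value < 0)) {
    stop("negative signal value at line ",
         parsed$lineno[which(value < 0)[1]], call. = FALSE)
  }
  if (any(start < 0) || any(end <= start)) {
    stop("invalid interval (need 0 <= start < end) at line ",
         parsed$lineno[which(start < 0 | end <= start)[1]], call. = FALSE)
  }
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = start + 1, end = end), score = value
  )
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  validate_track(gr)
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <-
      union(GenomeInfoDb::seqlevels(gr), names(seqlengths))
    GenomeInfoDb::seqlengths(gr) <- seqlengths[GenomeInfoDb::seqlevels(gr)]
  }
  gr
}

#' Validate quantitative-track invariants
#'
#' Checks that a `GRanges` carries a non-negative numeric `score`, is sorted,
#' and has no overlapping intervals. Called by the readers and simulators;
#' exported so user-constructed tracks can be checked too.
#'
#' @param track A `GRanges` with a `score` column.
#' @return The track, invisibly; errors describe the violated invariant.
#' @export
validate_track <- function(track) {
  stopifnot(methods::is(track, "GRanges"))
  if (!"score" %in% names(S4Vectors::mcols(track))) {
    stop("track must carry a 'score' metadata column", call. = FALSE)
  }
  sc <- S4Vectors::mcols(track)$score
  if (!is.numeric(sc) || anyNA(sc) || any(sc < 0)) {
    stop("track scores must be non-negative numbers", call. = FALSE)
  }
  ord <- GenomicRanges::order(track)
  if (!identical(ord, seq_along(track))) {
    stop("track intervals must be sorted by (chrom, start)", call. = FALSE)
  }
  if (length(track) > 1L) {
    hits <- GenomicRanges::findOverlaps(track, drop.self = TRUE,
                                        drop.redundant = TRUE)
    if (length(hits) > 0L) {
      i <- S4Vectors::queryHits(hits)[1]
      stop("track intervals overlap (e.g. interval ", i, " and ",
           S4Vectors::subjectHits(hits)[1], ")", call. = FALSE)
    }
  }
  invisible(track)
}

#' Write a quantitative track as bedGraph
#'
#' Signal is written with 6 decimal places so that write-then-read round
#' trips are bit-identical at that precision. Coordinates are emitted
#' 0-based half-open.
#'
#' @param track A `GRanges` with `score`, as returned by [read_bedgraph()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  validate_track(track)
  track <- GenomicRanges::sort(track, ignore.strand = TRUE)
  lines <- sprintf("%s\t%d\t%d\t%.6f",
                   as.character(GenomeInfoDb::seqnames(track)),
                   GenomicRanges::start(track) - 1L,
                   GenomicRanges::end(track),
                   S4Vectors::mcols(track)$score)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED3/BED4 file
#'
#' @param path Path to a BED file.
#' @param with_name If `TRUE`, require a 4th column and attach it as the
#'   `name` metadata column (used for chromatin-state labels).
#' @param seqlengths Optional named vector of chromosome lengths.
#' @return A `GRanges`, in file order, optionally with a `name` column.
#' @export
read_bed <- function(path, with_name = FALSE, seqlengths = NULL) {
  parsed <- .read_genomic_lines(path)
  n <- length(parsed$lines)
  if (n == 0L) {
    gr <- GenomicRanges::GRanges()
    if (with_name) S4Vectors::mcols(gr)$name <- character(0)
    return(gr)
  }
  fields <- lapply(parsed$lines, .split_fields)
  nf <- vapply(fields, length, integer(1))
  need <- if (with_name) 4L else 3L
  if (any(nf < need)) {
    stop("BED line ", parsed$lineno[which(nf < need)[1]], ": expected at least ",
         need, " fields", call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | end <= start)
  if (length(bad)) {
    stop("BED line ", parsed$lineno[bad[1]],
         ": invalid interval (need 0 <= start < end)", call. = FALSE)
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  if (with_name) {
    S4Vectors::mcols(gr)$name <- vapply(fields, `[[`, character(1), 4L)
  }
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <-
      union(GenomeInfoDb::seqlevels(gr), names(seqlengths))
    GenomeInfoDb::seqlengths(gr) <- seqlengths[GenomeInfoDb::seqlevels(gr)]
  }
  gr
}

#' Write intervals as BED
#'
#' Emits BED3, or BED4 when a `name` metadata column is present (or BED5 when
#' both `name` and `score` are present; scores are written as integers,
#' clamped to the BED 0-1000 range).
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  chrom <- as.character(GenomeInfoDb::seqnames(gr))
  s <- GenomicRanges::start(gr) - 1L
  e <- GenomicRanges::end(gr)
  mc <- S4Vectors::mcols(gr)
  if ("name" %in% names(mc) && "score" %in% names(mc)) {
    sc <- pmin(pmax(round(mc$score), 0L), 1000L)
    lines <- sprintf("%s\t%d\t%d\t%s\t%d", chrom, s, e, mc$name, sc)
  } else if ("name" %in% names(mc)) {
    lines <- sprintf("%s\t%d\t%d\t%s", chrom, s, e, mc$name)
  } else {
    lines <- sprintf("%s\t%d\t%d", chrom, s, e)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a typed, headered TSV against a schema
#'
#' Thin, strict wrapper used for beta tables, differential-expression tables
#' and screen plates: the header must contain every schema column and each
#' column must parse to its declared type.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param schema Named character vector mapping column name to type, one of
#'   `"character"`, `"numeric"`, `"integer"`.
#' @return A `data.frame` with the schema columns (extra columns preserved),
#'   row order as in the file.
#' @export
read_table_checked <- function(path, schema) {
  stopifnot(is.character(schema), !is.null(names(schema)))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(names(schema), names(df))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in names(schema)) {
    type <- schema[[col]]
    v <- df[[col]]
    conv <- switch(type,
      character = as.character(v),
      numeric = suppressWarnings(as.numeric(v)),
      integer = suppressWarnings(as.integer(v)),
      stop("unknown schema type: ", type, call. = FALSE)
    )
    if (type != "character" && any(is.na(conv) & !is.na(v))) {
      bad <- which(is.na(conv) & !is.na(v))[1]
      stop("column '", col, "', row ", bad, ": cannot parse '", v[bad],
           "' as ", type, call. = FALSE)
    }
    df[[col]] <- conv
  }
  df
}

#' Read a methylation beta-value table
#'
#' Expects columns `probe`, `chrom`, `pos` and one numeric column per sample.
#' Beta values are methylation fractions: 0 is fully unmethylated, 1 fully
#' methylated; any value outside `[0, 1]` is rejected. Probes are sorted by
#' `(chrom, pos)` on load and duplicate positions are an error.
#'
#' @param path Path to a TSV beta table.
#' @param samples Optional character vector naming the sample columns;
#'   defaults to every column after `probe`, `chrom`, `pos`.
#' @return A `data.frame` (class `beta_matrix`) with attributes `samples`.
#' @export
read_beta_matrix <- function(path, samples = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("probe", "chrom", "pos")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("beta table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(samples)) samples <- setdiff(names(df), need)
  if (!length(samples)) stop("beta table has no sample columns", call. = FALSE)
  for (s in samples) {
    v <- suppressWarnings(as.numeric(df[[s]]))
    if (anyNA(v)) stop("sample '", s, "': non-numeric beta value",
                       call. = FALSE)
    if (any(v < 0 | v > 1)) {
      stop("sample '", s, "': beta value outside [0, 1] at row ",
           which(v < 0 | v > 1)[1], call. = FALSE)
    }
    df[[s]] <- v
  }
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  if (anyDuplicated(df[, c("chrom", "pos")])) {
    stop("duplicate probe positions in beta table", call. = FALSE)
  }
  structure(df, samples = samples, class = c("beta_matrix", "data.frame"))
}

#' Write a beta matrix back to TSV
#' @param beta A `beta_matrix` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path) {
  utils::write.table(as.data.frame(beta), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Convenience used across modules: GRanges from 0-based half-open triples.
.gr0 <- function(chrom, start, end, ..., seqlengths = NULL) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end), ...)
  if (!is.null(seqlengths)) {
    # chromosome order follows the length map, so sorting is stable across
    # objects built from the same configuration
    GenomeInfoDb::seqlevels(gr) <-
      union(names(seqlengths), GenomeInfoDb::seqlevels(gr))
    GenomeInfoDb::seqlengths(gr) <- seqlengths[GenomeInfoDb::seqlevels(gr)]
  }
  gr
}
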