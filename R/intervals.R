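#' Genomic intervals in 0-based half-open coordinates
#'
#' All positional data inside the package uses 0-based half-open
#' (BED-style) coordinates. VCF input (1-based) is converted on read and
#' back-converted on write. `genomic_intervals()` builds and validates a
#' plain data frame of intervals; downstream code treats that data frame
#' as the interval container.
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start integer vector, 0-based inclusive starts (`>= 0`).
#' @param end integer vector, 0-based exclusive ends (`> start`).
#' @param label optional character vector of labels (e.g. a histone mark);
#'   recycled if length 1.
#' @return A `data.frame` with columns `chrom`, `start`, `end` and, when
#'   given, `label`, carrying class `genomic_intervals`.
#' @examples
#' genomic_intervals("chr1", 100, 200, label = "H3K27ac")
#' @export
genomic_intervals <- function(chrom, start, end, label = NULL) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   stringsAsFactors = FALSE)
  if (!is.null(label)) df$label <- rep_len(as.character(label), nrow(df))
  validate_intervals(df)
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

#' Validate interval invariants
#'
#' Checks `start >= 0`, `end > start` and non-empty `chrom` on any data
#' frame with those columns; used by every read path.
#'
#' @param df data frame with `chrom`, `start`, `end` columns.
#' @param context string naming the caller, used in error messages.
#' @return `df`, invisibly, if valid; otherwise an error naming the first
#'   offending row.
#' @export
validate_intervals <- function(df, context = "intervals") {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  bad <- which(is.na(df$chrom) | !nzchar(df$chrom) |
                 df$start < 0 | df$end <= df$start)
  if (length(bad)) {
    stop(sprintf("%s: invalid interval at row %d (chrom=%s start=%s end=%s)",
                 context, bad[1], df$chrom[bad[1]], df$start[bad[1]],
                 df$end[bad[1]]), call. = FALSE)
  }
  invisible(df)
}

## IRanges view of a 0-based half-open frame restricted to one chromosome.
## IRanges is closed 1-based: [start+1, end].
.iranges_of <- function(df) {
  IRanges::IRanges(start = df$start + 1L, end = df$end)
}

#' Overlap query between two interval frames
#'
#' Chromosome-aware overlap of two 0-based half-open interval frames.
#' `maxgap = 0` means touching intervals do not overlap (half-open
#' semantics are preserved exactly).
#'
#' @param query,subject data frames with `chrom`, `start`, `end`.
#' @param maxgap non-negative integer; intervals within `maxgap` bases are
#'   also reported (0 = strict overlap).
#' @return Data frame with columns `query`, `subject`: row indices of
#'   overlapping pairs.
#' @export
interval_overlaps <- function(query, subject, maxgap = 0L) {
  if (nrow(query) == 0L || nrow(subject) == 0L)
    return(data.frame(query = integer(), subject = integer()))
  res <- vector("list", 0L)
  for (ch in intersect(unique(query$chrom), unique(subject$chrom))) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    ## IRanges counts abutting ranges as gap 0; our contract is that
    ## maxgap = 0 means strict overlap, so shift by one
    hits <- IRanges::findOverlaps(.iranges_of(query[qi, , drop = FALSE]),
                                  .iranges_of(subject[si, , drop = FALSE]),
                                  maxgap = maxgap - 1L)
    res[[length(res) + 1L]] <- data.frame(
      query = qi[S4Vectors::queryHits(hits)],
      subject = si[S4Vectors::subjectHits(hits)])
  }
  if (!length(res)) return(data.frame(query = integer(), subject = integer()))
  out <- do.call(rbind, res)
  out[order(out$query, out$subject), , drop = FALSE]
}

## Length of pairwise overlap between two single intervals on one chromosome
## (0 if disjoint or on different chromosomes).
.overlap_len <- function(a_start, a_end, b_start, b_end) {
  max(0, min(a_end, b_end) - max(a_start, b_start))
}
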