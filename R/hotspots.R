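#' Gate non-coding SNVs on regulatory annotation and population absence
#'
#' Keeps a non-coding SNV iff it overlaps at least one labeled
#' regulatory interval (active promoter/enhancer histone marks, open
#' chromatin, TF binding sites) AND is absent from the population
#' variant panel. Overlap with conserved elements is recorded as an
#' annotation flag, never used as a filter.
#'
#' @param variants [somatic_variants()] frame (SNVs with
#'   `functional_class == "non_coding"` are considered; others are
#'   dropped with a note in the result attributes).
#' @param regulatory labeled interval frame.
#' @param population data frame `chrom`, `start`, `ref`, `alt` or `NULL`.
#' @param conserved interval frame or `NULL`.
#' @return Gated [somatic_variants()] frame with extra columns
#'   `region_labels` (`";"`-joined marks) and `conserved` (logical).
#' @export
gate_noncoding <- function(variants, regulatory, population = NULL,
                           conserved = NULL) {
  v <- variants[variants$var_class == "SNV" &
                  variants$functional_class == "non_coding", , drop = FALSE]
  hits <- interval_overlaps(v, regulatory)
  labels <- vapply(seq_len(nrow(v)), function(i) {
    marks <- regulatory$label[hits$subject[hits$query == i]]
    join_flags(marks)
  }, character(1))
  keep <- nzchar(labels)
  if (!is.null(population) && nrow(population)) {
    pop_keys <- paste(population$chrom, population$start, population$ref,
                      population$alt, sep = ":")
    keep <- keep & !(variant_key(v) %in% pop_keys)
  }
  out <- v[keep, , drop = FALSE]
  out$region_labels <- labels[keep]
  out$conserved <- rep(FALSE, nrow(out))
  if (!is.null(conserved) && nrow(conserved) && nrow(out)) {
    ch <- interval_overlaps(out, conserved)
    out$conserved[unique(ch$query)] <- TRUE
  }
  class(out) <- c("somatic_variants", "data.frame")
  out
}

## Complete-linkage agglomeration of 1-D positions with a strict
## diameter cut: merge the pair of clusters with the smallest merged
## diameter while that diameter stays < width. Deterministic: input is
## sorted, ties resolved toward the leftmost pair. In 1-D every cluster
## is a contiguous run, so the state is a set of [lo, hi] index ranges
## over the sorted positions.
complete_linkage_cut <- function(pos, width) {
  n <- length(pos)
  if (n == 0L) return(integer(0))
  ord <- order(pos)
  p <- pos[ord]
  ## cluster boundaries over sorted positions
  starts <- seq_len(n)
  ends <- seq_len(n)
  repeat {
    k <- length(starts)
    if (k == 1L) break
    ## merging adjacent clusters i, i+1 gives diameter p[ends[i+1]] - p[starts[i]]
    diam <- p[ends[-1]] - p[starts[-k]]
    j <- which.min(diam)
    if (diam[j] >= width) break
    starts <- starts[-(j + 1L)]
    ends <- ends[-j]
  }
  cl_sorted <- rep(seq_along(starts), ends - starts + 1L)
  cl <- integer(n)
  cl[ord] <- cl_sorted
  cl
}

#' Cluster gated non-coding variants into recurrence hotspots
#'
#' Per-chromosome complete-linkage hierarchical clustering of variant
#' positions, cut so that every cluster's maximum pairwise distance is
#' strictly smaller than `cluster_width` (the published 100 bp rule).
#' Clusters carried by fewer than `min_patients` distinct patients are
#' discarded. Variants on different chromosomes never cluster.
#'
#' @param gated [somatic_variants()] frame (typically from
#'   [gate_noncoding()]).
#' @param cluster_width strict diameter bound in bp (default 100).
#' @param min_patients minimal distinct patients per retained hotspot
#'   (default 2).
#' @return Data frame of hotspots sorted by `chrom`, `start`: columns
#'   `chrom`, `start`, `end` (position span, half-open), `n_variants`,
#'   `n_patients`, `patients`, `genes`, `region_labels`, and a
#'   list-column `members` of row indices into `gated`.
#' @export
cluster_hotspots <- function(gated, cluster_width = 100, min_patients = 2L) {
  if (!nrow(gated))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_variants = integer(),
                      n_patients = integer(), patients = character(),
                      genes = character(), region_labels = character()))
  out <- list()
  for (ch in sort(unique(gated$chrom))) {
    idx <- which(gated$chrom == ch)
    cl <- complete_linkage_cut(gated$start[idx], cluster_width)
    for (g in unique(cl)) {
      rows <- idx[cl == g]
      pats <- unique(gated$patient_id[rows])
      if (length(pats) < min_patients) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = min(gated$start[rows]),
        end = max(gated$start[rows]) + 1,
        n_variants = length(rows), n_patients = length(pats),
        patients = paste(sort(pats), collapse = ";"),
        genes = join_flags(gated$gene[rows][nzchar(gated$gene[rows])]),
        region_labels = join_flags(unlist(lapply(
          gated$region_labels[rows], split_flags))),
        stringsAsFactors = FALSE)
      out[[length(out)]]$members <- I(list(rows))
    }
  }
  if (!length(out)) return(cluster_hotspots(gated[0, , drop = FALSE]))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Gene-expression criterion for hotspot target genes
#'
#' A gene counts as expressed when `log2(FPKM) > 1`, i.e. `FPKM > 2`
#' (strict at the boundary).
#'
#' @param fpkm non-negative FPKM value(s).
#' @return Logical vector.
#' @export
expression_gate <- function(fpkm) {
  if (any(fpkm < 0)) stop("negative FPKM", call. = FALSE)
  fpkm > 2
}
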