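#' Canonical 96 trinucleotide substitution channels
#'
#' Pyrimidine-centric single-base-substitution channels in the standard
#' order: substitution class varies slowest (C>A, C>G, C>T, T>A, T>C,
#' T>G), then the 5' flank (A, C, G, T), then the 3' flank, giving
#' `A[C>A]A` first and `T[T>G]T` last.
#'
#' @return Character vector of length 96.
#' @export
sbs_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s)
    unlist(lapply(bases, function(f5)
      paste0(f5, "[", s, "]", bases)))))
}

#' Construct a signature set
#'
#' A signature set is a 96 x K non-negative matrix whose columns are
#' probability profiles over the [sbs_channels()] (each column sums to 1).
#'
#' @param matrix 96 x K non-negative matrix; rows must be the canonical
#'   channels (rownames checked when present). Columns are renormalized
#'   only if within `tol` of 1, otherwise an error is raised.
#' @param labels column labels; defaults to existing colnames.
#' @param provenance `"de_novo"`, `"reference"` or `"synthetic"`.
#' @param tol column-sum tolerance (default `1e-9` after renormalization).
#' @return Object of class `signature_set`: list with `matrix`, `labels`,
#'   `provenance`.
#' @export
signature_set <- function(matrix, labels = colnames(matrix),
                          provenance = "reference", tol = 1e-9) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != 96L)
    stop("signature matrix must have 96 rows, got ", nrow(matrix),
         call. = FALSE)
  if (!is.null(rownames(matrix)) &&
      !identical(rownames(matrix), sbs_channels()))
    stop("signature rows are not in canonical channel order", call. = FALSE)
  if (any(matrix < 0)) stop("negative signature entries", call. = FALSE)
  cs <- colSums(matrix)
  if (any(cs <= 0)) stop("all-zero signature column", call. = FALSE)
  matrix <- sweep(matrix, 2, cs, "/")
  if (any(abs(colSums(matrix) - 1) > tol))
    stop("signature columns failed to normalize", call. = FALSE)
  if (is.null(labels)) labels <- paste0("S", seq_len(ncol(matrix)))
  rownames(matrix) <- sbs_channels()
  colnames(matrix) <- labels
  structure(list(matrix = matrix, labels = labels, provenance = provenance),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat("signature_set:", length(x$labels), "signatures (", x$provenance,
      ")\n  ", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

## Subset a signature set by label or index, preserving order of `which`.
subset_signatures <- function(sigs, which) {
  idx <- if (is.character(which)) match(which, sigs$labels) else which
  if (anyNA(idx)) stop("unknown signature label", call. = FALSE)
  signature_set(sigs$matrix[, idx, drop = FALSE],
                labels = sigs$labels[idx], provenance = sigs$provenance)
}

#' Synthetic stand-in for a COSMIC-style reference signature catalog
#'
#' Builds a deterministic set of ten synthetic single-base-substitution
#' signatures with the qualitative shapes of well-known processes:
#' a CpG deamination clock (`SBS1`), APOBEC peaks at TpC (`SBS2`,
#' `SBS13`), a mismatch-repair profile (`SBS6`), two broad flat
#' signatures (`SBS5`, `SBS40`), an oxidative C>A profile (`SBS18`),
#' a T>G profile (`SBS17b`) and two additional filler processes
#' (`SBS26`, `SBS89`). These are NOT the COSMIC profiles: they are
#' synthetic stand-ins with matching labels so that matching, selection
#' and refitting can be exercised offline.
#'
#' @param seed deterministic construction seed (fixed default so the set
#'   is identical across sessions).
#' @return `signature_set` with provenance `"synthetic"`.
#' @export
make_reference_signatures <- function(seed = 20260909) {
  ch <- sbs_channels()
  sub_of <- sub(".*\\[(.*)\\].*", "\\1", ch)
  f5 <- substr(ch, 1, 1)
  f3 <- substr(ch, 7, 7)
  base <- function() rep(0.01, 96)  # small floor avoids zero-support ties
  with_rng(seed, {
    peak <- function(mask, w) { v <- base(); v[mask] <- v[mask] + w *
      stats::runif(sum(mask), 0.6, 1.4); v }
    sigs <- cbind(
      SBS1  = peak(sub_of == "C>T" & f3 == "G", 12),
      SBS2  = peak(sub_of == "C>T" & f5 == "T", 14),
      SBS5  = base() + stats::runif(96, 0, 0.6),
      SBS6  = peak(sub_of == "C>T", 2.5) + peak(sub_of == "T>C" & f5 == "A", 3) - base(),
      SBS13 = peak(sub_of == "C>G" & f5 == "T", 10) +
        peak(sub_of == "C>A" & f5 == "T", 4) - base(),
      SBS17b = peak(sub_of == "T>G" & f3 == "T", 12),
      SBS18 = peak(sub_of == "C>A", 3),
      SBS26 = peak(sub_of == "T>C", 3.5),
      SBS40 = base() + stats::runif(96, 0, 0.8),
      SBS89 = peak(sub_of == "C>A" & f5 == "A", 6) +
        peak(sub_of == "T>A" & f3 == "C", 5) - base())
    rownames(sigs) <- ch
    signature_set(sigs, provenance = "synthetic")
  })
}
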