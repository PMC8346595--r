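## Internal helpers shared across modules.

## Run `expr` under a local RNG seeded with `seed`, restoring the caller's
## RNG state afterwards. All stochastic package code funnels through this
## so one global seed drives reproducible per-stage substreams.
with_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

## Derive a bounded sub-seed from a master seed and a stage offset.
## Kept below 2^31 - 1 so it is always a valid R integer seed.
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(offset) * 12289) %% 2147483629)
}

#' Cosine similarity between two non-negative profiles
#'
#' `dot(a, b) / (|a| |b|)`; the standard similarity used throughout the
#' mutational-signature literature. Errors on zero vectors rather than
#' returning `NaN`.
#'
#' @param a,b numeric vectors of equal length.
#' @return Similarity in `[0, 1]` for non-negative inputs.
#' @examples
#' cosine_similarity(c(1, 1, 0), c(1, 0, 0)) # 1/sqrt(2)
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine_similarity: zero vector", call. = FALSE)
  sum(a * b) / (na * nb)
}

## Reverse complement for plain character bases.
rev_comp <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, NULL), function(s)
    paste(rev(s), collapse = ""), character(1)))
}
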