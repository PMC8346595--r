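## Shared fixtures, built once per test run. Everything is generated in
## code from fixed seeds; nothing binary ships with the package.

sv <- relapsetrace:::somatic_variants
vkey <- relapsetrace:::variant_key
subsig <- relapsetrace:::subset_signatures

test_ref <- make_toy_reference(1)
test_refsig <- make_reference_signatures()

## independent naive complete-linkage agglomeration (O(n^3)): merges the
## globally closest pair under the max-distance criterion, leftmost pair
## on ties, while the merged diameter stays strictly under `width`.
## Used as the clustering oracle; shares no code with the production path.
oracle_complete_linkage <- function(pos, width) {
  n <- length(pos)
  if (n == 0L) return(integer(0))
  clusters <- as.list(seq_len(n))
  repeat {
    k <- length(clusters)
    if (k == 1L) break
    best <- NULL
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      d <- max(abs(outer(pos[clusters[[i]]], pos[clusters[[j]]], "-")))
      if (is.null(best) || d < best$d) best <- list(i = i, j = j, d = d)
    }
    if (best$d >= width) break
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  out <- integer(n)
  for (g in seq_along(clusters)) out[clusters[[g]]] <- g
  out
}

## canonicalize a partition label vector for comparison
canon_partition <- function(cl) {
  m <- match(cl, unique(cl))
  split(seq_along(m), m)
}

## brute-force enumeration of all sum-rule-consistent rooted trees over
## a CCF matrix: every parent vector over all nodes, fixed root,
## acyclicity checked explicitly. Oracle for the branch-and-bound path.
oracle_trees <- function(ccf, eps = 0.05, root = which.max(rowSums(ccf))) {
  k <- nrow(ccf)
  others <- setdiff(seq_len(k), root)
  if (!length(others)) return(list(rep(NA_integer_, k)))
  grid <- expand.grid(rep(list(seq_len(k)), length(others)))
  res <- list()
  for (r in seq_len(nrow(grid))) {
    parent <- rep(NA_integer_, k)
    parent[others] <- as.integer(grid[r, ])
    if (any(parent[others] == others)) next
    ## acyclic and rooted at `root`?
    ok <- TRUE
    for (v in others) {
      seen <- integer(0); u <- v
      while (!is.na(parent[u])) {
        if (u %in% seen) { ok <- FALSE; break }
        seen <- c(seen, u); u <- parent[u]
      }
      if (!ok || u != root) { ok <- FALSE; break }
    }
    if (!ok) next
    ## sum rule at every node and timepoint
    for (i in seq_len(k)) {
      kids <- which(!is.na(parent) & parent == i)
      if (length(kids) &&
          any(colSums(ccf[kids, , drop = FALSE]) > ccf[i, ] + eps)) {
        ok <- FALSE; break
      }
    }
    if (ok) res[[length(res) + 1L]] <- parent
  }
  res
}

tree_key <- function(p) paste(ifelse(is.na(p), 0L, p), collapse = ",")
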