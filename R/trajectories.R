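#' Cancer cell fraction under the diploid copy-neutral model
#'
#' `CCF = min(1, 2 AF / purity)`: the deterministic purity adjustment
#' used throughout the clonal reconstruction (variants in copy-altered
#' regions should be excluded upstream).
#'
#' @param af allele frequency in `[0, 1]`.
#' @param purity tumor purity in `(0, 1]`.
#' @return CCF in `[0, 1]`.
#' @export
ccf_from_af <- function(af, purity) pmin(1, 2 * af / purity)

## Pivot a per-patient multi-timepoint variant frame into aligned
## alt/depth matrices (variants x timepoints) keyed by variant identity.
.pivot_counts <- function(variants, timepoints) {
  keys <- unique(variant_key(variants))
  alt <- depth <- matrix(0, length(keys), length(timepoints),
                         dimnames = list(keys, timepoints))
  for (ti in seq_along(timepoints)) {
    sub <- variants[variants$timepoint == timepoints[ti], , drop = FALSE]
    idx <- match(variant_key(sub), keys)
    alt[idx, ti] <- sub$alt_count
    depth[idx, ti] <- sub$tumor_depth
  }
  list(keys = keys, alt = alt, depth = depth)
}

## EM for a K-component binomial mixture over joint timepoints.
.binmix_em <- function(alt, depth, K, n_init = 5L, max_iter = 200L) {
  n <- nrow(alt); TT <- ncol(alt)
  af <- ifelse(depth > 0, alt / depth, 0)
  best <- NULL
  for (init in seq_len(n_init)) {
    centers <- af[sample.int(n, K), , drop = FALSE]
    p <- pmin(pmax(centers, 1e-4), 1 - 1e-4)
    pi_k <- rep(1 / K, K)
    ll_prev <- -Inf
    for (it in seq_len(max_iter)) {
      logr <- vapply(seq_len(K), function(k)
        rowSums(stats::dbinom(alt, depth, rep(p[k, ], each = n),
                              log = TRUE)) + log(pi_k[k]),
        numeric(n))
      if (n == 1L) logr <- matrix(logr, nrow = 1L)
      m <- apply(logr, 1, max)
      r <- exp(logr - m)
      rs <- rowSums(r)
      ll <- sum(m + log(rs))
      r <- r / rs
      pi_k <- colMeans(r)
      for (k in seq_len(K)) {
        wd <- colSums(r[, k] * depth)
        wa <- colSums(r[, k] * alt)
        p[k, ] <- pmin(pmax(ifelse(wd > 0, wa / wd, 1e-4), 1e-4),
                       1 - 1e-4)
      }
      if (ll - ll_prev < 1e-6 * abs(ll_prev) + 1e-9) break
      ll_prev <- ll
    }
    if (is.null(best) || ll > best$ll)
      best <- list(p = p, pi = pi_k, ll = ll,
                   assign = max.col(logr, ties.method = "first"))
  }
  best
}

#' Cluster multi-timepoint variant allele frequencies
#'
#' Fits binomial mixtures over the joint (diagnosis, relapse...) read
#' counts of one patient's somatic SNVs by EM, selects the component
#' count by BIC over `1..max_clusters`, then merges clusters smaller
#' than `min_cluster_size` into their nearest neighbour (Euclidean on
#' the CCF centroids). A deliberate, documented simplification of
#' Dirichlet-process clustering.
#'
#' @param variants per-patient [somatic_variants()] frame covering at
#'   least two timepoints (same variant keys repeated per timepoint).
#' @param purity named numeric per timepoint.
#' @param max_clusters BIC search bound (default 10).
#' @param min_cluster_size merge threshold (default 5 variants).
#' @param seed RNG seed (initialization substreams derive from it).
#' @return List of class `vaf_clusters`: `clusters` (data frame
#'   `cluster`, `size`), `ccf` (clusters x timepoints), `af_centers`,
#'   `assignments` (per variant key), `alt`, `depth`, `purity`,
#'   `timepoints`, `bic` (per K).
#' @export
cluster_vafs <- function(variants, purity, max_clusters = 10L,
                         min_cluster_size = 5L, seed = 1L) {
  tps <- intersect(c("diagnosis", "r1", "r2"), unique(variants$timepoint))
  if (length(tps) < 2L)
    stop("need variants at >= 2 timepoints", call. = FALSE)
  if (!all(tps %in% names(purity)))
    stop("purity missing for some timepoint", call. = FALSE)
  pc <- .pivot_counts(variants, tps)
  n <- nrow(pc$alt)
  with_rng(sub_seed(seed, 601), {
    fits <- list(); bic <- numeric(0)
    for (K in seq_len(min(max_clusters, n))) {
      fit <- .binmix_em(pc$alt, pc$depth, K)
      k_par <- K * length(tps) + (K - 1)
      bic[K] <- -2 * fit$ll + k_par * log(n)
      fits[[K]] <- fit
      if (K >= 3 && bic[K] > bic[K - 1] && bic[K - 1] > bic[K - 2]) break
    }
    K <- which.min(bic)
    fit <- fits[[K]]
    assign <- fit$assign
    ## merge undersized clusters into the nearest surviving centroid
    repeat {
      sizes <- tabulate(assign, nbins = K)
      small <- which(sizes > 0 & sizes < min_cluster_size)
      if (!length(small) || sum(sizes > 0) <= 1L) break
      s <- small[which.min(sizes[small])]
      others <- setdiff(which(sizes > 0), s)
      d <- apply(fit$p[others, , drop = FALSE], 1, function(q)
        sum((q - fit$p[s, ])^2))
      tgt <- others[which.min(d)]
      assign[assign == s] <- tgt
      sizes <- tabulate(assign, nbins = K)
      for (k in which(sizes > 0)) {
        wd <- colSums(pc$depth[assign == k, , drop = FALSE])
        wa <- colSums(pc$alt[assign == k, , drop = FALSE])
        fit$p[k, ] <- ifelse(wd > 0, wa / wd, 0)
      }
    }
    keep <- sort(unique(assign))
    relabel <- match(assign, keep)
    p <- fit$p[keep, , drop = FALSE]
    ccf <- t(vapply(seq_len(nrow(p)), function(k)
      ccf_from_af(p[k, ], purity[tps]), numeric(length(tps))))
    if (length(tps) == 1L) ccf <- matrix(ccf, ncol = 1L)
    colnames(ccf) <- tps
    structure(list(
      clusters = data.frame(cluster = seq_along(keep),
                            size = tabulate(relabel, length(keep))),
      ccf = ccf, af_centers = p, assignments = stats::setNames(relabel,
                                                               pc$keys),
      alt = pc$alt, depth = pc$depth, purity = purity[tps],
      timepoints = tps, bic = bic), class = "vaf_clusters")
  })
}

## All sum-rule-consistent rooted trees over cluster CCFs.
## Returns a list of parent vectors (NA at root). DFS with pairwise
## pruning (parent CCF >= child CCF - eps at every timepoint) and
## incremental child-sum checks; complete within the cap.
.consistent_trees <- function(ccf, eps = 0.05, root = NULL, cap = 20000L) {
  k <- nrow(ccf)
  if (is.null(root)) {
    tot <- rowSums(ccf)
    root <- which.max(tot)
  }
  if (k == 1L) return(list(structure(NA_integer_, root = 1L)))
  nodes <- setdiff(order(-rowSums(ccf)), root)
  res <- list()
  parent <- rep(NA_integer_, k)
  child_sum <- matrix(0, k, ncol(ccf))
  ok_pair <- function(p, c_) all(ccf[p, ] >= ccf[c_, ] - eps)
  makes_cycle <- function(p, v) {
    u <- p
    while (!is.na(u)) {
      if (u == v) return(TRUE)
      u <- parent[u]
    }
    FALSE
  }
  recurse <- function(d) {
    if (length(res) >= cap) return()
    if (d > length(nodes)) {
      res[[length(res) + 1L]] <<- parent
      return()
    }
    v <- nodes[d]
    ## any other node may serve as parent (within eps a child can have
    ## nominally higher CCF than its parent), so check cycles explicitly
    for (p in setdiff(seq_len(k), v)) {
      if (!ok_pair(p, v)) next
      if (makes_cycle(p, v)) next
      new_sum <- child_sum[p, ] + ccf[v, ]
      if (any(new_sum > ccf[p, ] + eps)) next
      parent[v] <<- p
      child_sum[p, ] <<- new_sum
      recurse(d + 1L)
      child_sum[p, ] <<- child_sum[p, ] - ccf[v, ]
      parent[v] <<- NA_integer_
    }
  }
  recurse(1L)
  lapply(res, function(pv) structure(pv, root = root))
}

## Nesting-tightness score of a tree: smaller = children sit closer
## under their parents. Used to pick a best tree deterministically.
.tree_score <- function(parent, ccf) {
  s <- 0
  for (v in which(!is.na(parent)))
    s <- s + sum(ccf[parent[v], ] - ccf[v, ])
  s
}

.best_tree <- function(trees, ccf) {
  if (!length(trees)) return(NULL)
  scores <- vapply(trees, .tree_score, numeric(1), ccf = ccf)
  cand <- which(scores == min(scores))
  if (length(cand) > 1L) {
    keys <- vapply(trees[cand], function(p)
      paste(ifelse(is.na(p), 0L, p), collapse = ","), character(1))
    cand <- cand[order(keys)][1]
  }
  trees[[cand[1]]]
}

#' Build a consensus clone tree from VAF clusters
#'
#' Enumerates every rooted tree over the mutation clusters that
#' satisfies the pigeonhole sum rule (each parent's CCF at least the
#' sum of its children's, within `eps`) at every timepoint, with the
#' root fixed to the cluster of maximal CCF. The consensus topology is
#' the candidate consistent with the most bootstrap resamples of the
#' variant-to-cluster assignment; the probability score is the fraction
#' of resamples whose own best tree matches the consensus.
#'
#' @param clusters `vaf_clusters` (or a bare CCF matrix for
#'   enumeration-only use).
#' @param eps sum-rule tolerance in absolute CCF (default 0.05).
#' @param n_boot bootstrap resamples (default 100; 0 disables).
#' @param seed RNG seed.
#' @return List of class `clone_tree_fit`: `tree` (a `clone_tree` or
#'   `NULL` when no consistent tree exists), `probability_score`,
#'   `n_consistent`, `all_trees` (parent vectors).
#' @export
build_clone_tree <- function(clusters, eps = 0.05, n_boot = 100L,
                             seed = 1L) {
  ccf <- if (is.matrix(clusters)) clusters else clusters$ccf
  sizes <- if (is.matrix(clusters)) rep(1L, nrow(ccf))
           else clusters$clusters$size
  trees <- .consistent_trees(ccf, eps)
  if (!length(trees))
    return(structure(list(tree = NULL, probability_score = 0,
                          n_consistent = 0L, all_trees = list()),
                     class = "clone_tree_fit"))
  best <- .best_tree(trees, ccf)
  score <- 1
  if (n_boot > 0L && !is.matrix(clusters) &&
      !is.null(clusters$assignments) && nrow(clusters$alt) > 1L) {
    consensus_key <- paste(ifelse(is.na(best), 0L, best), collapse = ",")
    purity <- clusters$purity
    n <- nrow(clusters$alt)
    match_count <- 0L
    consist_count <- stats::setNames(integer(length(trees)),
                                     vapply(trees, function(p)
                                       paste(ifelse(is.na(p), 0L, p),
                                             collapse = ","), character(1)))
    with_rng(sub_seed(seed, 701), {
      for (b in seq_len(n_boot)) {
        idx <- sample.int(n, n, replace = TRUE)
        a <- clusters$assignments[idx]
        ccf_b <- ccf
        for (k in seq_len(nrow(ccf))) {
          rows <- idx[a == k]
          if (!length(rows)) next
          wd <- colSums(clusters$depth[rows, , drop = FALSE])
          wa <- colSums(clusters$alt[rows, , drop = FALSE])
          ccf_b[k, ] <- ccf_from_af(ifelse(wd > 0, wa / wd, 0), purity)
        }
        trees_b <- .consistent_trees(ccf_b, eps)
        keys_b <- vapply(trees_b, function(p)
          paste(ifelse(is.na(p), 0L, p), collapse = ","), character(1))
        hit <- names(consist_count) %in% keys_b
        consist_count[hit] <- consist_count[hit] + 1L
        bb <- .best_tree(trees_b, ccf_b)
        if (!is.null(bb) &&
            paste(ifelse(is.na(bb), 0L, bb), collapse = ",") ==
            consensus_key)
          match_count <- match_count + 1L
      }
    })
    ## consensus = candidate consistent with the most resamples
    cons_key <- names(consist_count)[which.max(consist_count)]
    best <- trees[[which(names(consist_count) == cons_key)[1]]]
    score <- if (identical(cons_key, consensus_key)) match_count / n_boot
             else unname(consist_count[cons_key]) / n_boot
  }
  tps <- colnames(ccf)
  tree <- structure(list(parent = { p <- as.integer(best); p },
                         ccf = ccf, timepoints = tps,
                         n_mutations = sizes), class = "clone_tree")
  list2 <- structure(list(tree = tree, probability_score = score,
                          n_consistent = length(trees),
                          all_trees = trees), class = "clone_tree_fit")
  list2
}

## Clone-exclusive prevalence: own CCF minus the sum of the children's.
exclusive_prevalence <- function(tree) {
  excl <- tree$ccf
  for (i in seq_along(tree$parent)) {
    kids <- which(tree$parent == i)
    if (length(kids))
      excl[i, ] <- pmax(0, excl[i, ] - colSums(tree$ccf[kids, , drop = FALSE]))
  }
  excl
}

## Major clone at a timepoint: highest exclusive prevalence among clones
## present (CCF >= threshold); ties broken by larger mutation count.
.major_clone <- function(tree, tp, present = 0.05) {
  idx <- which(tree$ccf[, tp] >= present)
  if (!length(idx)) return(NA_integer_)
  excl <- exclusive_prevalence(tree)[, tp]
  idx[order(-excl[idx], -tree$n_mutations[idx])][1]
}

#' Classify the clonal evolution trajectory of one interval
#'
#' Applies the trajectory definitions to a clone tree with per-timepoint
#' CCFs. Let `M_D` be the major clone at the baseline timepoint, `M_R`
#' the major clone at relapse, and `A` the nearest ancestor-or-self of
#' `M_R` that is present (CCF at least the `present` threshold) at
#' baseline. The label is `persistent` when `A == M_D` (this includes
#' the override where the founding clone itself is the baseline major
#' clone), `rising` when `A` is a present non-major baseline subclone,
#' `founding` when `A` is the founding clone (or no non-root ancestor is
#' present at baseline), and `undetermined` when the relapse purity is
#' below `purity_min` or no consistent tree exists.
#'
#' @param fit `clone_tree_fit` from [build_clone_tree()] (or a
#'   `clone_tree`).
#' @param patient patient identifier for the call.
#' @param baseline,relapse timepoint names (defaults `"diagnosis"`,
#'   first relapse column present).
#' @param relapse_purity purity of the relapse sample (for the
#'   undetermined short-circuit); `NA` skips the check.
#' @param present CCF presence threshold (default 0.05).
#' @param purity_min minimal relapse purity (default 0.2).
#' @return List of class `trajectory_call`: `patient`, `interval`,
#'   `label`, `probability_score`, `evidence`, `reason` (for
#'   undetermined calls).
#' @export
classify_trajectory <- function(fit, patient = "P0",
                                baseline = "diagnosis", relapse = NULL,
                                relapse_purity = NA_real_,
                                present = 0.05, purity_min = 0.2) {
  tree <- if (inherits(fit, "clone_tree_fit")) fit$tree else fit
  score <- if (inherits(fit, "clone_tree_fit")) fit$probability_score
           else NA_real_
  mk <- function(label, reason = NA_character_, evidence = list()) {
    structure(list(patient = patient,
                   interval = paste0(baseline, "->",
                                     if (is.null(relapse)) "?" else relapse),
                   label = label, probability_score = score,
                   evidence = evidence, reason = reason),
              class = "trajectory_call")
  }
  if (!is.na(relapse_purity) && relapse_purity < purity_min)
    return(mk("undetermined", "low_purity"))
  if (is.null(tree)) return(mk("undetermined", "no_consistent_tree"))
  tps <- tree$timepoints
  if (is.null(relapse))
    relapse <- setdiff(tps, baseline)[1]
  if (!relapse %in% tps || !baseline %in% tps)
    stop("timepoint absent from tree: ", relapse, call. = FALSE)
  root <- which(is.na(tree$parent))
  m_d <- .major_clone(tree, baseline, present)
  m_r <- .major_clone(tree, relapse, present)
  if (is.na(m_d) || is.na(m_r))
    return(mk("undetermined", "no_present_clone"))
  ## walk up from the relapse major to the nearest baseline-present clone
  a <- m_r
  while (!is.na(a) && tree$ccf[a, baseline] < present &&
         !is.na(tree$parent[a]))
    a <- tree$parent[a]
  evidence <- list(major_baseline = m_d, major_relapse = m_r,
                   anchor = a, root = root,
                   ccf_baseline = tree$ccf[, baseline],
                   ccf_relapse = tree$ccf[, relapse])
  if (a == m_d) return(mk("persistent", evidence = evidence))
  if (a == root) return(mk("founding", evidence = evidence))
  mk("rising", evidence = evidence)
}

#' Reassign a founding call using deep targeted resequencing
#'
#' When deep (e.g. 600x) resequencing of the baseline sample detects a
#' relapse-lineage variant at or above `af_detect`, the subclone was
#' present at baseline after all and the call flips to `rising`.
#'
#' @param call `trajectory_call` with label `founding`.
#' @param deep_afs named numeric: deep baseline AF per relapse-lineage
#'   variant.
#' @param af_detect detection threshold (default 0.01).
#' @return Possibly relabeled `trajectory_call`.
#' @export
reassign_with_deep_sequencing <- function(call, deep_afs,
                                          af_detect = 0.01) {
  if (!identical(call$label, "founding"))
    stop("reassignment applies to founding calls only", call. = FALSE)
  hits <- deep_afs[!is.na(deep_afs) & deep_afs >= af_detect]
  if (length(hits)) {
    call$label <- "rising"
    call$evidence$deep_rescue <- hits
  }
  call
}

#' Trajectory from first to second relapse
#'
#' Same classification rules with `r1` as baseline and `r2` as relapse.
#'
#' @param fit `clone_tree_fit` or `clone_tree` covering `r1` and `r2`.
#' @param patient patient identifier.
#' @param ... passed to [classify_trajectory()].
#' @return `trajectory_call` for the `r1->r2` interval.
#' @export
relapse_to_relapse_trajectory <- function(fit, patient = "P0", ...) {
  tree <- if (inherits(fit, "clone_tree_fit")) fit$tree else fit
  if (is.null(tree) || !"r2" %in% tree$timepoints)
    stop("no second-relapse data", call. = FALSE)
  classify_trajectory(fit, patient, baseline = "r1", relapse = "r2", ...)
}
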