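#' Build a 96-channel mutation catalog from SNVs
#'
#' Maps every somatic SNV to its pyrimidine-centric trinucleotide
#' channel using the reference sequence for the flanking bases.
#' Purine-reference substitutions are reverse-complemented. Indels are
#' excluded. A mismatch between `ref` and the reference base raises an
#' error naming the variant.
#'
#' @param variants [somatic_variants()] frame (indels ignored).
#' @param sequences reference `DNAStringSet`.
#' @param sample_ids optional character vector fixing the row set and
#'   order of the catalog (samples without variants get zero rows).
#' @return `mutation_catalog`: list with `counts` (samples x 96 integer
#'   matrix, canonical channel columns) and `samples`.
#' @export
build_catalog <- function(variants, sequences, sample_ids = NULL) {
  snv <- variants[variants$var_class == "SNV", , drop = FALSE]
  if (is.null(sample_ids)) sample_ids <- sort(unique(snv$sample_id))
  ch <- sbs_channels()
  counts <- matrix(0L, nrow = length(sample_ids), ncol = 96L,
                   dimnames = list(sample_ids, ch))
  if (nrow(snv)) {
    tri <- vapply(seq_len(nrow(snv)), function(i)
      ref_window(sequences, snv$chrom[i], snv$start[i] - 1, snv$start[i] + 2),
      character(1))
    mid <- substr(tri, 2, 2)
    bad <- which(mid != snv$ref)
    if (length(bad))
      stop(sprintf("reference mismatch for variant %s:%d %s>%s (reference %s)",
                   snv$chrom[bad[1]], snv$start[bad[1]], snv$ref[bad[1]],
                   snv$alt[bad[1]], mid[bad[1]]), call. = FALSE)
    pur <- snv$ref %in% c("A", "G")
    tri[pur] <- rev_comp(tri[pur])
    alt <- snv$alt
    alt[pur] <- chartr("ACGT", "TGCA", alt[pur])
    channel <- paste0(substr(tri, 1, 1), "[", substr(tri, 2, 2), ">", alt,
                      "]", substr(tri, 3, 3))
    for (i in seq_along(channel)) {
      r <- match(snv$sample_id[i], sample_ids)
      c_ <- match(channel[i], ch)
      if (is.na(r) || is.na(c_))
        stop("unmapped sample or channel for variant row ", i, call. = FALSE)
      counts[r, c_] <- counts[r, c_] + 1L
    }
  }
  structure(list(counts = counts, samples = sample_ids),
            class = "mutation_catalog")
}

## One NMF run with multiplicative updates under the generalized
## Kullback-Leibler (Poisson) objective -- the standard loss for count
## catalogs in signature analysis. V (n x 96) ~ E (n x k) %*% t(S).
.nmf_once <- function(V, k, max_iter = 800L, tol = 1e-8) {
  n <- nrow(V); m <- ncol(V)
  eps <- 1e-10
  E <- matrix(stats::runif(n * k, 0.1, 1), n, k)
  S <- matrix(stats::runif(m * k, 0.1, 1), m, k)
  dev_of <- function(R) 2 * sum(ifelse(V > 0, V * log(V / R), 0) - V + R)
  dev_prev <- Inf
  for (it in seq_len(max_iter)) {
    R <- tcrossprod(E, S) + eps
    E <- E * ((V / R) %*% S) / rep(colSums(S) + eps, each = n)
    R <- tcrossprod(E, S) + eps
    S <- S * (t(V / R) %*% E) / rep(colSums(E) + eps, each = m)
    if (it %% 20L == 0L) {
      dev <- dev_of(tcrossprod(E, S) + eps)
      if (dev_prev - dev < tol * max(abs(dev_prev), 1)) break
      dev_prev <- dev
    }
  }
  R <- tcrossprod(E, S) + eps
  ## normalize signature columns, rescale exposures
  cs <- colSums(S)
  cs[cs == 0] <- 1
  list(S = sweep(S, 2, cs, "/"), E = sweep(E, 2, cs, "*"),
       rss = sum((V - R)^2), dev = dev_of(R))
}

#' De novo signature extraction by NMF
#'
#' Factorizes a mutation catalog into `k` non-negative signatures and
#' exposures with multiplicative updates under the generalized
#' Kullback-Leibler (Poisson) objective, keeping the best of
#' `n_restarts` random restarts per rank. The rank is chosen by the
#' residual elbow criterion on the residual deviance: the selected rank
#' is the largest surveyed rank whose relative improvement over the
#' previous rank is at least 3x the noise plateau (the smallest
#' surveyed improvement, i.e. what fitting one more rank of pure count
#' noise buys) and at least `elbow_threshold`. Signal ranks improve the
#' deviance by an order of magnitude more than the plateau, so the two
#' gates separate cleanly. Per-rank RSS is also reported.
#'
#' @param catalog `mutation_catalog`.
#' @param rank_range integer vector of candidate ranks (within
#'   `[2, samples - 1]`).
#' @param n_restarts random restarts per rank.
#' @param seed RNG seed (restart substreams are derived from it).
#' @param max_iter multiplicative-update iterations per restart.
#' @param elbow_threshold relative RSS improvement cutoff (default 0.05).
#' @return List with `signatures` (`signature_set`, labels `DN1..DNk`),
#'   `exposures` (samples x k), `rank`, `rss` and `deviance` (named
#'   per-rank, including the rank-1 baseline), `rel_improvement`
#'   (relative deviance improvement per rank).
#' @export
extract_de_novo <- function(catalog, rank_range = 2:5, n_restarts = 20L,
                            seed = 1L, elbow_threshold = 0.05,
                            max_iter = 800L) {
  V <- catalog$counts
  if (all(V == 0)) stop("all-zero catalog", call. = FALSE)
  if (min(rank_range) < 2L || max(rank_range) > nrow(V) - 1L)
    stop("rank_range must lie within [2, samples - 1]", call. = FALSE)
  ranks <- sort(unique(c(1L, as.integer(rank_range))))
  fits <- vector("list", length(ranks))
  names(fits) <- as.character(ranks)
  for (ri in seq_along(ranks)) {
    k <- ranks[ri]
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- with_rng(sub_seed(seed, k * 1000L + r),
                      .nmf_once(V, k, max_iter = max_iter))
      if (is.null(best) || fit$dev < best$dev) best <- fit
    }
    fits[[ri]] <- best
  }
  rss <- vapply(fits, `[[`, numeric(1), "rss")
  dev <- vapply(fits, `[[`, numeric(1), "dev")
  rel_imp <- c(NA_real_, (dev[-length(dev)] - dev[-1]) /
                 pmax(dev[-length(dev)], .Machine$double.eps))
  names(rel_imp) <- names(dev)
  ## selected rank: the elbow of the deviance curve. The noise plateau
  ## (what fitting one more rank of pure count noise buys) is
  ## self-calibrated as the smallest surveyed improvement; a rank counts
  ## as structure when its improvement is at least 3x that plateau
  ## (signal ranks sit an order of magnitude above it) and above the
  ## absolute threshold.
  imp <- rel_imp[-1]
  floor_imp <- max(elbow_threshold, 3 * min(imp))
  cand <- ranks[-1][imp >= floor_imp]
  if (!length(cand)) cand <- ranks[-1][imp >= elbow_threshold]
  sel <- if (length(cand)) max(cand) else min(rank_range)
  sel <- max(sel, min(rank_range))
  fit <- fits[[as.character(sel)]]
  deviance <- dev
  S <- fit$S
  ## deterministic column order: by total exposure, descending
  ord <- order(colSums(fit$E), decreasing = TRUE)
  S <- S[, ord, drop = FALSE]
  E <- fit$E[, ord, drop = FALSE]
  rownames(S) <- sbs_channels()
  colnames(S) <- paste0("DN", seq_len(ncol(S)))
  dimnames(E) <- list(catalog$samples, colnames(S))
  list(signatures = signature_set(S, provenance = "de_novo"),
       exposures = E, rank = sel, rss = rss, deviance = deviance,
       rel_improvement = rel_imp)
}

## Exact non-negative least squares (Lawson-Hanson active set):
## minimize |A x - b|^2 subject to x >= 0.
nnls_fit <- function(A, b, tol = 1e-10) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- rep(FALSE, n)
  w <- crossprod(A, b - A %*% x)
  iter <- 0L
  while (any(!passive & w > tol) && iter < 30L * n) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      s <- numeric(n)
      P <- which(passive)
      s[P] <- qr.coef(qr(A[, P, drop = FALSE]), b)
      s[P][is.na(s[P])] <- 0
      if (all(s[P] > tol)) { x <- s; break }
      neg <- P[s[P] <= tol]
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive[abs(x) < tol & passive] <- FALSE
      x[!passive] <- 0
    }
    w <- crossprod(A, b - A %*% x)
  }
  x
}

#' Refit exposures against a fixed signature set
#'
#' Per-sample non-negative least squares of the observed 96-channel
#' counts on the signature matrix. The reconstruction for each sample is
#' `signatures x exposures`; the per-sample cosine similarity between
#' observation and reconstruction is the standard quality measure.
#'
#' @param catalog `mutation_catalog`.
#' @param signatures `signature_set`.
#' @return List with `exposures` (samples x K, mutation counts
#'   attributed per signature), `cosines` (named per sample),
#'   `reconstruction` (samples x 96).
#' @export
refit_exposures <- function(catalog, signatures) {
  V <- catalog$counts
  S <- signatures$matrix
  E <- t(apply(V, 1, function(b) nnls_fit(S, b)))
  if (ncol(S) == 1L) E <- matrix(E, ncol = 1L)
  dimnames(E) <- list(catalog$samples, signatures$labels)
  recon <- E %*% t(S)
  cosines <- vapply(seq_len(nrow(V)), function(i) {
    if (sum(V[i, ]) == 0 || sum(recon[i, ]) == 0) return(NA_real_)
    cosine_similarity(V[i, ], recon[i, ])
  }, numeric(1))
  names(cosines) <- catalog$samples
  list(exposures = E, cosines = cosines, reconstruction = recon)
}

#' Match de novo signatures against a reference catalog
#'
#' Computes all pairwise cosine similarities between de novo and
#' reference signatures and returns the reference signatures exceeding
#' the (deliberately relaxed) threshold against any de novo signature.
#'
#' @param de_novo,reference `signature_set`s over the same channels.
#' @param threshold cosine cutoff (strict `>`, default 0.65).
#' @return List with `candidates` (character labels), `similarity`
#'   (de novo x reference matrix).
#' @export
match_to_reference <- function(de_novo, reference, threshold = 0.65) {
  if (!identical(rownames(de_novo$matrix), rownames(reference$matrix)))
    stop("channel order mismatch between signature sets", call. = FALSE)
  sim <- t(apply(de_novo$matrix, 2, function(d)
    apply(reference$matrix, 2, cosine_similarity, a = d)))
  dimnames(sim) <- list(de_novo$labels, reference$labels)
  keep <- apply(sim, 2, max) > threshold
  list(candidates = reference$labels[keep], similarity = sim)
}

## Paired two-sided t-test of per-sample cosines vs a baseline; the
## degenerate all-zero-difference case counts as perfect equivalence.
.paired_p <- function(cos_stage, cos_base) {
  d <- cos_stage - cos_base
  d <- d[!is.na(d)]
  if (!length(d) || stats::sd(d) == 0) return(1)
  stats::t.test(d)$p.value
}

#' Parsimonious reference-signature selection
#'
#' Staged reduction of matched reference candidates to the smallest set
#' reconstructing the catalog as well as the de novo signatures:
#' * stage 1: the single best-matching candidate per de novo signature;
#' * later stages: per de novo signature, add its next-best candidate
#'   from the same branch of the average-linkage dendrogram of the
#'   candidates (distance `1 - cosine`), until each de novo signature
#'   has two reference representatives;
#' * after each stage the catalog is refitted and per-sample
#'   reconstruction cosines are compared with the de novo baseline by a
#'   paired two-sided t-test; the first stage with `p > alpha` is
#'   accepted.
#'
#' @param de_novo de novo `signature_set`.
#' @param reference reference `signature_set`.
#' @param catalog `mutation_catalog`.
#' @param alpha equivalence acceptance level (default 0.05).
#' @param threshold candidate-matching cosine threshold.
#' @return List with `final` (`signature_set`), `trace` (data frame of
#'   stages: signature labels, median cosine, p-value, accepted flag),
#'   `stage_cosines` (list of per-sample cosine vectors),
#'   `baseline_cosines`.
#' @export
select_parsimonious_set <- function(de_novo, reference, catalog,
                                    alpha = 0.05, threshold = 0.65) {
  m <- match_to_reference(de_novo, reference, threshold)
  cand <- m$candidates
  if (!length(cand)) stop("no reference candidates above threshold",
                          call. = FALSE)
  sim <- m$similarity[, cand, drop = FALSE]
  base <- refit_exposures(catalog, de_novo)$cosines
  ## dendrogram over candidates (average linkage on 1 - cosine)
  branch_of <- rep(1L, length(cand))
  names(branch_of) <- cand
  if (length(cand) > 2L) {
    cmat <- matrix(1, length(cand), length(cand),
                   dimnames = list(cand, cand))
    for (i in seq_along(cand)) for (j in seq_along(cand))
      cmat[i, j] <- cosine_similarity(reference$matrix[, cand[i]],
                                      reference$matrix[, cand[j]])
    hc <- stats::hclust(stats::as.dist(1 - cmat), method = "average")
    ## branch = smallest cluster with >= 2 members containing a signature:
    ## use the pair-level merge structure via cutree over all k and pick,
    ## per candidate, the finest partition where its cluster has >= 2.
    branch_of <- vapply(seq_along(cand), function(i) {
      for (k in rev(seq_len(length(cand) - 1L))) {
        ct <- stats::cutree(hc, k = k)
        if (sum(ct == ct[i]) >= 2L) return(paste0(k, ":", ct[i]))
      }
      "1:1"
    }, character(1))
    names(branch_of) <- cand
  }
  ## ranked candidate lists per de novo signature: same-branch first,
  ## then global similarity order; ties broken by label order
  per_dn <- lapply(seq_len(nrow(sim)), function(d) {
    best <- cand[order(-sim[d, ], cand)][1]
    same_branch <- cand[branch_of == branch_of[best]]
    rest <- setdiff(cand, same_branch)
    c(same_branch[order(-sim[d, same_branch], same_branch)],
      rest[order(-sim[d, rest], rest)])
  })
  ## stage s = union over de novo signatures of their top-s ranked
  ## candidates (own branch first); duplicate sets are collapsed
  stage_sets <- list()
  for (s in seq_len(max(lengths(per_dn)))) {
    set_s <- unique(unlist(lapply(per_dn, function(p)
      p[seq_len(min(s, length(p)))])))
    if (!length(stage_sets) ||
        !identical(sort(set_s), sort(stage_sets[[length(stage_sets)]])))
      stage_sets[[length(stage_sets) + 1L]] <- set_s
  }
  trace <- data.frame(stage = seq_along(stage_sets),
                      n_signatures = lengths(stage_sets),
                      signatures = vapply(stage_sets, function(s)
                        paste(sort(s), collapse = ";"), character(1)),
                      median_cosine = NA_real_, p_value = NA_real_,
                      accepted = FALSE, stringsAsFactors = FALSE)
  stage_cos <- vector("list", length(stage_sets))
  final <- NULL
  for (si in seq_along(stage_sets)) {
    sigs <- subset_signatures(reference, sort(stage_sets[[si]]))
    fit <- refit_exposures(catalog, sigs)
    stage_cos[[si]] <- fit$cosines
    trace$median_cosine[si] <- stats::median(fit$cosines, na.rm = TRUE)
    trace$p_value[si] <- .paired_p(fit$cosines, base)
    if (trace$p_value[si] > alpha || alpha >= 1) {
      trace$accepted[si] <- TRUE
      final <- sigs
      break
    }
  }
  if (is.null(final)) {
    warning("no stage reached equivalence; returning the largest set")
    final <- subset_signatures(reference,
                               sort(stage_sets[[length(stage_sets)]]))
  }
  list(final = final, trace = trace[!is.na(trace$median_cosine), ,
                                    drop = FALSE],
       stage_cosines = stage_cos, baseline_cosines = base)
}
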