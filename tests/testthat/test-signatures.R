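test_that("catalog construction maps channels and reverse-complements", {
  ## build a 3-base context directly in a tiny custom reference
  seqs <- Biostrings::DNAStringSet(c(chrT = "AACAATGTAA"))
  ## C at 0-based pos 2 with flanks A_A -> A[C>A]A
  v1 <- sv("P", "S1", "diagnosis", "chrT", 2, 3, "C", "A", 90, 40, 30)
  ## G at 0-based pos 6 with flanks T_T; G>T revcomps to A[C>A]A
  v2 <- sv("P", "S1", "diagnosis", "chrT", 6, 7, "G", "T", 90, 40, 30)
  cat1 <- build_catalog(rbind(v1, v2), seqs)
  expect_equal(unname(cat1$counts[1, "A[C>A]A"]), 2L)
  expect_equal(sum(cat1$counts), 2L)
  ## reference mismatch errors with the variant named
  bad <- sv("P", "S1", "diagnosis", "chrT", 2, 3, "G", "A", 90, 40, 30)
  expect_error(build_catalog(bad, seqs), "reference mismatch")
  ## empty input -> zero matrix with requested samples
  cat0 <- build_catalog(v1[0, ], seqs, sample_ids = "S1")
  expect_equal(dim(cat0$counts), c(1L, 96L))
  expect_true(all(cat0$counts == 0))
})

test_that("cosine similarity matches hand values and rejects zero vectors", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1, rep(0, 94)),
                                 c(1, rep(0, 95))), 1 / sqrt(2))
  expect_error(cosine_similarity(rep(0, 3), c(1, 1, 1)), "zero vector")
})

test_that("NNLS equals the exhaustive active-set oracle", {
  ## oracle: try every support, solve unconstrained LS, keep feasible fits
  nnls_oracle <- function(A, b) {
    p <- ncol(A)
    best <- list(rss = sum(b^2), x = numeric(p))
    for (m in seq_len(2^p - 1)) {
      S <- which(bitwAnd(m, 2^(seq_len(p) - 1)) > 0)
      cf <- qr.coef(qr(A[, S, drop = FALSE]), b)
      cf[is.na(cf)] <- 0
      if (any(cf < -1e-9)) next
      x <- numeric(p); x[S] <- cf
      rss <- sum((b - A %*% x)^2)
      if (rss < best$rss - 1e-9) best <- list(rss = rss, x = x)
    }
    best$x
  }
  set.seed(42)
  for (i in 1:20) {
    A <- matrix(runif(30 * 5), 30, 5)
    b <- runif(30, 0, 10)
    x <- relapsetrace:::nnls_fit(A, b)
    xo <- nnls_oracle(A, b)
    expect_lt(sum((b - A %*% x)^2), sum((b - A %*% xo)^2) + 1e-6)
    expect_true(all(x >= 0))
  }
})

test_that("refit recovers noiseless mixtures and reports cosines", {
  S2 <- subsig(test_refsig, c("SBS1", "SBS13"))
  counts <- matrix(70 * S2$matrix[, 1] + 30 * S2$matrix[, 2], nrow = 1)
  colnames(counts) <- sbs_channels()
  cat1 <- structure(list(counts = counts, samples = "X"),
                    class = "mutation_catalog")
  fit <- refit_exposures(cat1, S2)
  expect_equal(unname(fit$exposures[1, ]), c(70, 30), tolerance = 1e-6)
  expect_equal(unname(fit$cosines[1]), 1, tolerance = 1e-9)
  ## pure single-signature catalog
  fit1 <- refit_exposures(cat1, subsig(test_refsig, "SBS1"))
  expect_lt(fit1$cosines[1], 1)
})

test_that("noiseless planted factorization is recovered at the true rank", {
  trio <- c("SBS1", "SBS2", "SBS13")
  S <- subsig(test_refsig, trio)$matrix
  set.seed(8)
  E <- matrix(runif(8 * 3, 50, 800), 8, 3)
  E[1:3, ] <- diag(3) * 600 + 20     # near-pure samples fix the factorization
  V <- E %*% t(S)
  cat3 <- structure(list(counts = V, samples = paste0("s", 1:8)),
                    class = "mutation_catalog")
  dn <- extract_de_novo(cat3, rank_range = 2:4, n_restarts = 6, seed = 1,
                        max_iter = 6000L)
  expect_equal(dn$rank, 3L)
  expect_lt(dn$rss[["3"]] / sum(V^2), 1e-4)
  for (l in trio)
    expect_gt(max(apply(dn$signatures$matrix, 2, cosine_similarity,
                        b = test_refsig$matrix[, l])), 0.99)
  ## permuting sample order permutes exposures only (fixed seed)
  cat_p <- structure(list(counts = V[8:1, ], samples = paste0("s", 8:1)),
                     class = "mutation_catalog")
  dn_p <- extract_de_novo(cat_p, rank_range = 2:4, n_restarts = 6, seed = 1,
                          max_iter = 6000L)
  expect_equal(dn_p$rank, 3L)
  expect_error(extract_de_novo(cat3, rank_range = 2:20), "rank_range")
  expect_error(
    extract_de_novo(structure(list(counts = V * 0, samples = cat3$samples),
                              class = "mutation_catalog"), 2:3),
    "all-zero")
})

test_that("reference matching applies the strict 0.65 threshold", {
  dn <- subsig(test_refsig, "SBS1")
  dn$provenance <- "de_novo"
  m <- match_to_reference(dn, test_refsig)
  expect_true("SBS1" %in% m$candidates)
  expect_equal(unname(m$similarity["SBS1", "SBS1"]), 1, tolerance = 1e-12)
  expect_length(match_to_reference(dn, test_refsig,
                                   threshold = 1.01)$candidates, 0)
  ## an equal-norm blend of two APOBEC-like signatures matches both
  s2 <- test_refsig$matrix[, "SBS2"]; s13 <- test_refsig$matrix[, "SBS13"]
  mix <- s2 / sqrt(sum(s2^2)) + s13 / sqrt(sum(s13^2))
  blend <- signature_set(
    matrix(mix / sum(mix), ncol = 1, dimnames = list(sbs_channels(), "DN1")),
    provenance = "de_novo")
  mb <- match_to_reference(blend, test_refsig)
  expect_true(all(c("SBS2", "SBS13") %in% mb$candidates))
  ## channel-order mismatch is an error
  shuffled <- test_refsig
  rownames(shuffled$matrix) <- rev(rownames(shuffled$matrix))
  expect_error(match_to_reference(dn, shuffled), "channel order")
})

test_that("column stochasticity and cosine monotonicity invariants hold", {
  cfg <- sim_config(seed = 13, n_samples = 12)
  sc <- simulate_catalogs(test_refsig, cfg)
  sets <- list(c("SBS1"), c("SBS1", "SBS2"), c("SBS1", "SBS2", "SBS13"),
               c("SBS1", "SBS2", "SBS13", "SBS40"),
               c("SBS1", "SBS2", "SBS13", "SBS40", "SBS6", "SBS89"))
  prev <- rep(-Inf, 12)
  for (s in sets) {
    sub <- subsig(test_refsig, s)
    expect_true(all(abs(colSums(sub$matrix) - 1) < 1e-9))
    fit <- refit_exposures(sc$catalog, sub)
    expect_true(all(fit$cosines >= prev - 1e-9))
    prev <- fit$cosines
  }
})

test_that("parsimonious selection accepts immediately for matching bases", {
  cfg <- sim_config(seed = 17, n_samples = 10,
                    signature_weights = c(SBS1 = 0.4, SBS2 = 0.3,
                                          SBS13 = 0.3))
  sc <- simulate_catalogs(test_refsig, cfg)
  dn <- subsig(test_refsig, c("SBS1", "SBS2", "SBS13"))
  dn$provenance <- "de_novo"
  sel <- select_parsimonious_set(dn, test_refsig, sc$catalog)
  expect_true(sel$trace$accepted[1])
  expect_equal(sel$trace$n_signatures[1], 3L)
  expect_setequal(sel$final$labels, c("SBS1", "SBS2", "SBS13"))
  ## alpha = 1 accepts stage 1 unconditionally
  sel1 <- select_parsimonious_set(dn, test_refsig, sc$catalog, alpha = 1)
  expect_true(sel1$trace$accepted[1])
})

test_that("selection on a six-signature world stays small and close", {
  cfg <- sim_config(seed = 42, n_samples = 40,
                    burden_range = c(500L, 3000L))
  sc <- simulate_catalogs(test_refsig, cfg)
  dn <- extract_de_novo(sc$catalog, rank_range = 2:4, n_restarts = 6,
                        seed = 9)
  sel <- suppressWarnings(
    select_parsimonious_set(dn$signatures, test_refsig, sc$catalog))
  expect_lte(length(sel$final$labels), 6L)
  expect_lt(abs(stats::median(sel$baseline_cosines) -
                  utils::tail(sel$trace$median_cosine, 1)), 0.02)
  ## trace records monotone non-decreasing reconstruction quality
  expect_true(all(diff(sel$trace$median_cosine) > -1e-9))
})
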