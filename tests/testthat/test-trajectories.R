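## small helper: a clone_tree built directly from a CCF matrix
mktree <- function(parent, ccf, n_mut = NULL) {
  structure(list(parent = parent, ccf = ccf,
                 timepoints = colnames(ccf),
                 n_mutations = n_mut %||% rep(100L, length(parent))),
            class = "clone_tree")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("CCF conversion clips at 1", {
  expect_equal(ccf_from_af(0.45, 0.9), 1)
  expect_equal(ccf_from_af(0.2, 0.8), 0.5)
})

test_that("VAF clustering recovers planted clusters and is deterministic", {
  cfg <- sim_config(seed = 8, depth_mean = 90)
  ## two clusters at CCF (1, 1) and (0.2, 0.9), 200 variants each
  tree <- mktree(c(NA, 1L),
                 matrix(c(1, 1, 0.2, 0.9), 2, 2, byrow = TRUE,
                        dimnames = list(NULL, c("diagnosis", "r1"))),
                 c(200L, 200L))
  sim <- simulate_variant_reads(tree, cfg,
                                purity = c(diagnosis = 0.9, r1 = 0.9),
                                seed = 8)
  cl <- cluster_vafs(sim$variants, c(diagnosis = 0.9, r1 = 0.9), seed = 4)
  expect_equal(nrow(cl$ccf), 2L)
  got <- cl$ccf[order(cl$ccf[, "diagnosis"], decreasing = TRUE), ]
  expect_lt(max(abs(got - tree$ccf)), 0.05)
  ## determinism
  cl2 <- cluster_vafs(sim$variants, c(diagnosis = 0.9, r1 = 0.9), seed = 4)
  expect_identical(cl$assignments, cl2$assignments)
  ## identical CCF everywhere collapses to one cluster
  tree1 <- mktree(NA_integer_,
                  matrix(c(1, 1), 1, 2,
                         dimnames = list(NULL, c("diagnosis", "r1"))),
                  300L)
  sim1 <- simulate_variant_reads(tree1, cfg,
                                 purity = c(diagnosis = 0.8, r1 = 0.8),
                                 seed = 5)
  cl1 <- cluster_vafs(sim1$variants, c(diagnosis = 0.8, r1 = 0.8), seed = 2)
  expect_equal(nrow(cl1$ccf), 1L)
  ## single timepoint errors
  expect_error(cluster_vafs(
    sim$variants[sim$variants$timepoint == "diagnosis", ],
    c(diagnosis = 0.9)), "2 timepoints")
})

test_that("tree enumeration matches the worked three-cluster example", {
  ccf <- matrix(c(1, 1, 0.6, 0.1, 0.3, 0.8), 3, 2, byrow = TRUE,
                dimnames = list(NULL, c("diagnosis", "r1")))
  trees <- relapsetrace:::.consistent_trees(ccf, eps = 0.05)
  expect_length(trees, 1L)
  expect_equal(unclass(trees[[1]]), c(NA, 1L, 1L), ignore_attr = TRUE)
  ## single cluster: trivial tree, score 1
  fit1 <- build_clone_tree(matrix(c(1, 1), 1, 2,
                                  dimnames = list(NULL,
                                                  c("diagnosis", "r1"))))
  expect_equal(fit1$probability_score, 1)
  expect_equal(fit1$tree$parent, NA_integer_)
})

test_that("branch-and-bound equals brute force for up to 5 clusters", {
  set.seed(123)
  for (rep in 1:40) {
    k <- sample(2:5, 1)
    tps <- 2
    ## random CCFs with a dominant root
    ccf <- rbind(rep(1, tps),
                 matrix(runif((k - 1) * tps, 0, 0.9), k - 1, tps))
    colnames(ccf) <- c("diagnosis", "r1")
    ours <- relapsetrace:::.consistent_trees(ccf, eps = 0.05)
    oracle <- oracle_trees(ccf, eps = 0.05, root = 1L)
    expect_setequal(vapply(ours, tree_key, character(1)),
                    vapply(oracle, tree_key, character(1)))
    ## every accepted tree satisfies the sum rule
    for (p in ours) {
      tr <- mktree(as.integer(p), ccf)
      expect_silent(validate_clone_tree(tr, eps = 0.0500001))
    }
  }
})

test_that("trajectory classification follows the published definitions", {
  tp2 <- c("diagnosis", "r1")
  ## persistent: diagnostic major clone's child becomes relapse major
  t_per <- mktree(c(NA, 1L, 2L),
                  matrix(c(1, 1, 0.8, 0.85, 0, 0.7), 3, 2, byrow = TRUE,
                         dimnames = list(NULL, tp2)))
  expect_equal(classify_trajectory(t_per)$label, "persistent")
  ## founding-clone-as-major override: root is diagnostic major and the
  ## relapse major is its child, absent at diagnosis
  t_ovr <- mktree(c(NA, 1L),
                  matrix(c(1, 1, 0.02, 0.9), 2, 2, byrow = TRUE,
                         dimnames = list(NULL, tp2)))
  expect_equal(classify_trajectory(t_ovr)$label, "persistent")
  ## rising: diagnostic subclone at 0.2 dominates relapse
  t_ris <- mktree(c(NA, 1L, 1L, 3L),
                  matrix(c(1, 1, 0.7, 0.02, 0.2, 0.9, 0, 0.5), 4, 2,
                         byrow = TRUE, dimnames = list(NULL, tp2)))
  expect_equal(classify_trajectory(t_ris)$label, "rising")
  ## founding: relapse major attaches to root, absent at diagnosis
  t_fnd <- mktree(c(NA, 1L, 1L),
                  matrix(c(1, 1, 0.8, 0, 0, 0.85), 3, 2, byrow = TRUE,
                         dimnames = list(NULL, tp2)))
  expect_equal(classify_trajectory(t_fnd)$label, "founding")
  ## low relapse purity short-circuits to undetermined
  u <- classify_trajectory(t_fnd, relapse_purity = 0.1)
  expect_equal(u$label, "undetermined")
  expect_equal(u$reason, "low_purity")
  ## no consistent tree feeds undetermined
  nofit <- structure(list(tree = NULL, probability_score = 0,
                          n_consistent = 0L, all_trees = list()),
                     class = "clone_tree_fit")
  expect_equal(classify_trajectory(nofit)$label, "undetermined")
})

test_that("classification is invariant to a purity-like rescaling", {
  tp2 <- c("diagnosis", "r1")
  t_ris <- mktree(c(NA, 1L, 1L),
                  matrix(c(1, 1, 0.7, 0.02, 0.2, 0.9), 3, 2, byrow = TRUE,
                         dimnames = list(NULL, tp2)))
  scaled <- t_ris
  scaled$ccf[, "r1"] <- scaled$ccf[, "r1"]    # CCF space is purity-corrected
  expect_equal(classify_trajectory(scaled)$label,
               classify_trajectory(t_ris)$label)
})

test_that("deep resequencing reassigns founding to rising", {
  tp2 <- c("diagnosis", "r1")
  t_fnd <- mktree(c(NA, 1L, 1L),
                  matrix(c(1, 1, 0.8, 0, 0, 0.85), 3, 2, byrow = TRUE,
                         dimnames = list(NULL, tp2)))
  call <- classify_trajectory(t_fnd)
  re <- reassign_with_deep_sequencing(call, c(BRINP3 = 0.02))
  expect_equal(re$label, "rising")
  expect_equal(re$evidence$deep_rescue, c(BRINP3 = 0.02))
  expect_equal(reassign_with_deep_sequencing(call, c(x = 0))$label,
               "founding")
  per <- classify_trajectory(mktree(c(NA, 1L),
    matrix(c(1, 1, 0.8, 0.9), 2, 2, byrow = TRUE,
           dimnames = list(NULL, tp2))))
  expect_error(reassign_with_deep_sequencing(per, c(x = 0.5)), "founding")
})

test_that("relapse-to-relapse classification reuses the rules on r1->r2", {
  tp3 <- c("diagnosis", "r1", "r2")
  ## r1 major persists into r2 with a new child
  t1 <- mktree(c(NA, 1L, 2L),
               matrix(c(1, 1, 1, 0.8, 0.85, 0.9, 0, 0, 0.6), 3, 3,
                      byrow = TRUE, dimnames = list(NULL, tp3)))
  expect_equal(relapse_to_relapse_trajectory(t1)$label, "persistent")
  ## r1 minor subclone dominates r2
  t2 <- mktree(c(NA, 1L, 1L),
               matrix(c(1, 1, 1, 0.1, 0.7, 0.05, 0, 0.15, 0.85), 3, 3,
                      byrow = TRUE, dimnames = list(NULL, tp3)))
  expect_equal(relapse_to_relapse_trajectory(t2)$label, "rising")
  ## missing r2 errors
  t3 <- mktree(c(NA, 1L),
               matrix(c(1, 1, 0.5, 0.6), 2, 2, byrow = TRUE,
                      dimnames = list(NULL, c("diagnosis", "r1"))))
  expect_error(relapse_to_relapse_trajectory(t3), "second-relapse")
})

test_that("bootstrap consensus scores are high for well-separated trees", {
  cfg <- sim_config(seed = 14)
  tree <- simulate_clone_tree(cfg, n_clones = 3, trajectory = "rising",
                              seed = 14)
  sim <- simulate_variant_reads(tree, cfg, seed = 14)
  cl <- cluster_vafs(sim$variants, sim$purity, max_clusters = 5, seed = 1)
  fit <- build_clone_tree(cl, n_boot = 50, seed = 1)
  expect_gte(fit$probability_score, 0.8)
  expect_silent(validate_clone_tree(fit$tree, eps = 0.0500001))
})
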