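test_that("sim_config validates weights and burdens", {
  expect_error(sim_config(signature_weights = c(SBS1 = 0.5, SBS2 = 0.4)),
               "sum to 1")
  expect_error(sim_config(burden_range = c(10L, 5L)))
  cfg <- sim_config()
  expect_equal(cfg$burden_range, c(152L, 1343L))
  expect_equal(cfg$depth_mean, 90)
})

test_that("single-signature catalogs concentrate on that signature", {
  cfg <- sim_config(seed = 2, n_samples = 3,
                    burden_range = c(1000L, 1000L),
                    signature_weights = c(SBS2 = 1))
  sc <- simulate_catalogs(test_refsig, cfg)
  for (i in 1:3)
    expect_gt(cosine_similarity(sc$catalog$counts[i, ],
                                test_refsig$matrix[, "SBS2"]), 0.98)
  expect_equal(unname(sc$exposures[1, "SBS2"]), 1000)
})

test_that("zero burden gives zero catalog rows; fixed seed is bitwise stable", {
  cfg0 <- sim_config(seed = 5, n_samples = 2, burden_range = c(0L, 0L))
  expect_true(all(simulate_catalogs(test_refsig, cfg0)$catalog$counts == 0))
  cfg <- sim_config(seed = 11, n_samples = 4)
  a <- simulate_catalogs(test_refsig, cfg)
  b <- simulate_catalogs(test_refsig, cfg)
  expect_identical(a$catalog$counts, b$catalog$counts)
  expect_identical(a$exposures, b$exposures)
})

test_that("simulated clone trees satisfy the sum rule exactly and honor the
           requested trajectory", {
  for (s in 1:8) for (tr in c("persistent", "rising", "founding")) {
    cfg <- sim_config(seed = s)
    tree <- simulate_clone_tree(cfg, trajectory = tr, seed = s)
    expect_silent(validate_clone_tree(tree, eps = 1e-9))
    ## classify directly on the generated (noise-free) tree
    call <- classify_trajectory(tree)
    expect_equal(call$label, tr,
                 info = sprintf("seed %d trajectory %s", s, tr))
  }
  ## rising with a subclone present in [0.05, 0.3] at diagnosis that
  ## dominates r1
  tree <- simulate_clone_tree(sim_config(seed = 3), n_clones = 3,
                              trajectory = "rising", seed = 3)
  expect_gte(tree$ccf[3, "diagnosis"], 0.05)
  expect_lte(tree$ccf[3, "diagnosis"], 0.3)
  expect_gt(tree$ccf[3, "r1"], max(tree$ccf[2, "r1"],
                                   1 - tree$ccf[3, "r1"]))
})

test_that("infeasible trajectory requests error", {
  cfg <- sim_config(seed = 1)
  expect_error(simulate_clone_tree(cfg, n_clones = 2, trajectory = "rising"),
               "at least 3")
  expect_error(simulate_clone_tree(cfg, n_clones = 1), "at least 2")
})

test_that("simulated read counts match the AF model", {
  ## clone prevalence 1, purity 0.9, depth 90 -> mean AF ~ 0.45
  cfg <- sim_config(seed = 9, timepoints = c("diagnosis", "r1"))
  tree <- simulate_clone_tree(cfg, n_clones = 2, trajectory = "persistent",
                              seed = 9)
  tree$ccf[2, ] <- 0            # only founding clone carries prevalence
  tree$n_mutations <- c(10000L, 10L)
  sim <- simulate_variant_reads(tree, cfg, purity = c(diagnosis = 0.9,
                                                      r1 = 0.9), seed = 9)
  root_af <- sim$variants$af[sim$variants$clone == 1 &
                               sim$variants$timepoint == "diagnosis"]
  expect_lt(abs(mean(root_af) - 0.45), 0.01)
  ## prevalence 0 at a timepoint -> no alt reads for that clone
  expect_true(all(sim$variants$alt_count[sim$variants$clone == 2] == 0))
})

test_that("default cohort AF histogram is bimodal in the published bands", {
  cfg <- sim_config(seed = 21)
  af <- unlist(lapply(1:6, function(i) {
    tree <- simulate_clone_tree(cfg, seed = 400 + i)
    sim <- simulate_variant_reads(tree, cfg, seed = 400 + i)
    sim$variants$af[sim$variants$af > 0.02]
  }))
  clonal <- mean(af >= 0.35 & af <= 0.50)
  subclonal <- mean(af >= 0.10 & af <= 0.25)
  expect_gt(clonal, 0.15)
  expect_gt(subclonal, 0.10)
})

test_that("inject_artifacts plants exactly the requested violations", {
  clean <- simulate_clean_variants(test_ref, 20, seed = 3)
  inj <- inject_artifacts(clean, test_ref,
                          rates = c(homopolymer = 5L, low_af = 3L), seed = 3)
  expect_equal(nrow(inj$variants), 28L)
  hp <- inj$truth[inj$truth$label == "homopolymer", ]
  expect_equal(nrow(hp), 5L)
  ## every homopolymer artifact lies within 1 bp of a >= 7-base run
  runs <- homopolymer_runs(test_ref$sequences)
  for (k in hp$key) {
    parts <- strsplit(k, ":")[[1]]
    pos <- as.numeric(parts[2])
    near <- runs[runs$chrom == parts[1], ]
    expect_true(any(pos >= near$start - 1 & pos < near$end + 1), info = k)
  }
  la <- inj$variants[vkey(inj$variants) %in%
                       inj$truth$key[inj$truth$label == "low_af"], ]
  expect_true(all(la$af < 0.05))
  ## zero rates: unchanged input
  expect_identical(inject_artifacts(clean, test_ref,
                                    rates = c(homopolymer = 0L))$variants,
                   clean)
  expect_error(inject_artifacts(clean, test_ref, rates = c(bogus = 1L)),
               "unknown filter rule")
})

test_that("fixture bundle is deterministic and loads through the readers", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_fixture_bundle(d1, seed = 4, n_patients = 1)
  p2 <- write_fixture_bundle(d2, seed = 4, n_patients = 1)
  for (nm in names(p1))
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]), info = nm)
  v <- read_variants(p1[["SIM_P01_diagnosis"]])
  expect_gt(nrow(v), 0L)
  expect_equal(nrow(read_regions(p1$repeats)), nrow(test_ref$repeats))
  expect_equal(nrow(read_population_vcf(p1$population)),
               nrow(test_ref$population))
  ## truth rows = clean + injected for each written sample
  truth <- utils::read.delim(p1$truth)
  tt <- table(truth$sample_id)
  expect_true(all(tt == 150 + sum(sim_config()$artifact_rates)))
})

test_that("planted exposures are recovered by refitting (catalog invariant)", {
  cfg <- sim_config(seed = 31, n_samples = 8, burden_range = c(2000L, 3000L))
  sc <- simulate_catalogs(test_refsig, cfg)
  six <- subsig(test_refsig, colnames(sc$weights)[colSums(sc$weights) > 0])
  fit <- refit_exposures(sc$catalog, six)
  frac <- fit$exposures / rowSums(fit$exposures)
  expect_lt(max(abs(frac - sc$weights[, colnames(frac)])), 0.05)
})
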