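mkv <- function(chrom = "chrS1", start = 200, ref = "A", alt = "T",
                depth = 90, alt_n = 40, gdp = 30, sample = "S0") {
  sv("P0", sample, "diagnosis", chrom, start, start + nchar(ref), ref, alt,
     depth, alt_n, gdp)
}

test_that("depth anomaly rule uses a strict 3-fold boundary", {
  prof <- chrom_depth_profile(c(chrS1 = 30))
  expect_false(filter_depth_anomaly(mkv(gdp = 95), prof))   # 95 > 90
  expect_true(filter_depth_anomaly(mkv(gdp = 90), prof))    # boundary passes
  expect_true(filter_depth_anomaly(mkv(gdp = 0), prof))
  expect_error(filter_depth_anomaly(mkv(chrom = "chrX", gdp = 10), prof),
               "absent from depth profile")
})

test_that("AF floor is strict and switches for flagged samples", {
  expect_false(filter_low_af(mkv(depth = 100, alt_n = 4)))        # 0.04
  expect_true(filter_low_af(mkv(depth = 100, alt_n = 5)))         # 0.05 passes
  expect_false(filter_low_af(mkv(depth = 100, alt_n = 7), bmt_flag = TRUE))
  expect_true(filter_low_af(mkv(depth = 100, alt_n = 10), bmt_flag = TRUE))
  expect_false(filter_low_af(mkv(depth = 100, alt_n = 7),
                             dbsnp_overlap_fraction = 0.95))
  expect_true(filter_low_af(mkv(depth = 100, alt_n = 7),
                            dbsnp_overlap_fraction = 0.90))  # not > 0.90
})

test_that("homopolymer rule fires on overlap or 1 bp flank only", {
  run <- test_ref$homopolymers[1, ]           # [start, end) 8-base run
  inside <- mkv(run$chrom, run$start + 3,
                substr(as.character(test_ref$sequences[[run$chrom]]),
                       run$start + 4, run$start + 4))
  adjacent <- mkv(run$chrom, run$start - 1,
                  substr(as.character(test_ref$sequences[[run$chrom]]),
                         run$start, run$start))
  away <- mkv(run$chrom, run$start - 10,
              substr(as.character(test_ref$sequences[[run$chrom]]),
                     run$start - 9, run$start - 9))
  f <- filter_annotation_overlaps(rbind(inside, adjacent, away),
                                  sequences = test_ref$sequences)
  expect_equal(f[[1]], "homopolymer")
  expect_equal(f[[2]], "homopolymer")
  expect_equal(f[[3]], character(0))
})

test_that("near-indel rule has a strict 5 bp boundary within the sample", {
  indel <- sv("P0", "S0", "diagnosis", "chrS1", 1000, 1002, "AC", "A",
              90, 30, 30)
  at5 <- mkv(start = 1006)   # distance 5 from the last indel base
  at6 <- mkv(start = 1007)
  other_sample <- mkv(start = 1006, sample = "S9")
  f <- filter_annotation_overlaps(rbind(at5, at6, other_sample),
                                  indels = indel)
  expect_equal(f[[1]], "near_indel")
  expect_equal(f[[2]], character(0))
  expect_equal(f[[3]], character(0))
})

test_that("population rule matches SNVs on alleles, indels by position", {
  popn <- test_ref$population[1, ]
  hit <- mkv(popn$chrom, popn$start, popn$ref, popn$alt)
  wrong_alt <- mkv(popn$chrom, popn$start, popn$ref,
                   setdiff(c("A", "C", "G", "T"),
                           c(popn$ref, popn$alt))[1])
  f <- filter_annotation_overlaps(rbind(hit, wrong_alt),
                                  population = test_ref$population)
  expect_equal(f[[1]], "population_variant")
  expect_equal(f[[2]], character(0))
  ## indel population matching tolerates 1 bp of position drift
  pop_ind <- data.frame(chrom = "chrS1", start = 5000, ref = "AAC",
                        alt = "A")
  ind <- sv("P0", "S0", "diagnosis", "chrS1", 5001, 5003, "AC", "A",
            90, 30, 30)
  f2 <- filter_annotation_overlaps(ind, population = pop_ind)
  expect_equal(f2[[1]], "population_variant")
})

test_that("cascade conserves counts, flags all rules, and is order-free", {
  clean <- simulate_clean_variants(test_ref, 188, seed = 7)
  rates <- c(depth_anomaly = 2L, low_af = 2L, repeat_overlap = 2L,
             homopolymer = 2L, near_indel = 2L, population_variant = 2L)
  inj <- inject_artifacts(clean, test_ref, rates = rates, seed = 5)
  prof <- chrom_depth_profile(c(chrS1 = 30, chrS2 = 30))
  res <- run_cascade(inj$variants, profile = prof,
                     repeats = test_ref$repeats,
                     population = test_ref$population,
                     indels = inj$indels, sequences = test_ref$sequences)
  expect_equal(nrow(res$survivors) + nrow(res$removed), nrow(inj$variants))
  expect_equal(unname(res$counts[names(rates)]), unname(rates))
  ## order independence: permuting the input permutes nothing material
  perm <- sample(nrow(inj$variants))
  res2 <- run_cascade(inj$variants[perm, ], profile = prof,
                      repeats = test_ref$repeats,
                      population = test_ref$population,
                      indels = inj$indels, sequences = test_ref$sequences)
  expect_equal(res2$counts, res$counts)
  expect_setequal(vkey(res2$survivors), vkey(res$survivors))
  ## clean-only input is the identity
  res3 <- run_cascade(clean, profile = prof, repeats = test_ref$repeats,
                      population = test_ref$population,
                      sequences = test_ref$sequences)
  expect_equal(nrow(res3$removed), 0L)
  ## empty input
  res4 <- run_cascade(clean[0, ], profile = prof)
  expect_equal(nrow(res4$survivors), 0L)
  expect_true(all(res4$counts == 0L))
})

test_that("SV filters: population overlap, coverage, gaps, DEL/DUP, whitelist", {
  svs <- structural_variants(
    sample_id = c("S1", "S1", "S1", "S1", "S2"),
    sv_type = c("DEL", "DEL", "DEL", "DUP", "DEL"),
    chrom_a = "chr1", start_a = c(1000, 50000, 20000, 21000, 80000),
    end_a = c(1001, 50001, 20001, 21001, 80001),
    chrom_b = "chr1", start_b = c(5000, 58000, 30000, 29000, 90000),
    end_b = c(5001, 58001, 30001, 29001, 90001),
    genes = c("", "", "", "", "TARP"))
  ## population DEL reciprocally overlapping the first SV by >= 50%
  pop <- structural_variants("pop", "DEL", "chr1", 1000, 1001,
                             "chr1", 4000, 4001)
  cov <- data.frame(chrom = "chr1", start = 50000, end = 60000,
                    mean_depth = 8)
  res <- filter_structural_variants(
    svs, population_svs = pop, germline_cov = cov,
    excluded_genes = c("TARP", "HLA", "IGH"))
  expect_equal(nrow(res$removed), 4L)   # pop, low_cov, DEL of the pair, gene
  expect_true(any(grepl("population", res$reasons)))
  expect_true(any(grepl("low_coverage", res$reasons)))
  expect_true(any(grepl("del_dup_overlap", res$reasons)))
  expect_true(any(grepl("excluded_gene", res$reasons)))
  ## whitelisted driver gene rescues an otherwise removed SV
  svs2 <- svs
  svs2$genes[3] <- "ETV6"
  res2 <- filter_structural_variants(svs2, population_svs = pop,
                                     germline_cov = cov,
                                     excluded_genes = "TARP",
                                     whitelist = "ETV6")
  expect_true("ETV6" %in% res2$survivors$genes)
  ## 40% reciprocal overlap is not enough
  pop40 <- structural_variants("pop", "DEL", "chr1", 3400, 3401,
                               "chr1", 7000, 7001)
  res3 <- filter_structural_variants(svs[1, ], population_svs = pop40)
  expect_equal(nrow(res3$removed), 0L)
})

test_that("replicate concordance fractions cover the union and sum to 1", {
  expect_equal(replicate_concordance(list(c("a", "b"), c("a", "b"),
                                          c("a", "b"))),
               c(in_3 = 1, in_2 = 0, in_1 = 0))
  ## union {a,b,c}: a in all three, b and c in exactly one each
  fr <- replicate_concordance(list(c("a", "b"), c("a", "c"), "a"))
  expect_equal(unname(fr), c(1 / 3, 0, 2 / 3))
  expect_equal(sum(fr), 1)
  expect_error(replicate_concordance(list("a", "b")), "three")
  expect_error(replicate_concordance(list(character(0), character(0),
                                          character(0))), "empty")
})
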