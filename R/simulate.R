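#' Simulation configuration
#'
#' The stated world of the synthetic cohort: per-sample mutation burdens
#' in the published diagnostic range (152-1343, median ~524), ~90x tumor
#' coverage, tumor purity in the blast-count range estimated for these
#' samples, signature mixtures over the six-signature set, and 2-4
#' clones per patient across diagnosis and relapse timepoints.
#'
#' @param seed master seed; every stage derives an independent substream
#'   from it.
#' @param n_samples number of catalog samples / patients.
#' @param burden_range integer `(min, max)` somatic point mutations per
#'   sample.
#' @param signature_weights named numeric mixing proportions (must sum
#'   to 1 within `1e-9`): the cohort-mean signature composition. Unless
#'   a full matrix (samples x signatures) is given, per-sample weights
#'   are drawn from a Dirichlet centred on these means (see
#'   `weight_alpha`), mirroring the strong between-patient signature
#'   heterogeneity of real cohorts.
#' @param weight_alpha Dirichlet concentration scale: per-sample
#'   weights ~ Dirichlet(`weight_alpha * K * signature_weights`).
#'   Small values give near-pure samples; `Inf` fixes every sample at
#'   the mean composition. Default 0.8 (strongly heterogeneous).
#' @param clone_count_range `(min, max)` clones per simulated tree.
#' @param timepoints subset of `c("diagnosis", "r1", "r2")`.
#' @param depth_mean expected tumor sequencing depth.
#' @param purity_range tumor purity `(min, max)`.
#' @param artifact_rates named integer counts of planted filter
#'   violations per sample (names from [cascade_rules()]).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_samples = 29L,
                       burden_range = c(152L, 1343L),
                       signature_weights = c(SBS1 = 0.25, SBS2 = 0.10,
                                             SBS6 = 0.10, SBS13 = 0.10,
                                             SBS40 = 0.35, SBS89 = 0.10),
                       weight_alpha = 0.8,
                       clone_count_range = c(3L, 4L),
                       timepoints = c("diagnosis", "r1"),
                       depth_mean = 90, purity_range = c(0.7, 0.95),
                       artifact_rates = c(depth_anomaly = 2L, low_af = 2L,
                                          repeat_overlap = 2L,
                                          homopolymer = 2L, near_indel = 2L,
                                          population_variant = 2L)) {
  if (is.matrix(signature_weights)) {
    if (any(abs(rowSums(signature_weights) - 1) > 1e-9))
      stop("signature weights must sum to 1 per sample", call. = FALSE)
  } else if (abs(sum(signature_weights) - 1) > 1e-9) {
    stop("signature weights must sum to 1", call. = FALSE)
  }
  stopifnot(burden_range[1] >= 0, burden_range[2] >= burden_range[1],
            all(timepoints %in% c("diagnosis", "r1", "r2")))
  structure(list(seed = seed, n_samples = n_samples,
                 burden_range = burden_range,
                 signature_weights = signature_weights,
                 weight_alpha = weight_alpha,
                 clone_count_range = clone_count_range,
                 timepoints = timepoints, depth_mean = depth_mean,
                 purity_range = purity_range,
                 artifact_rates = artifact_rates),
            class = "sim_config")
}

#' Simulate 96-channel mutation catalogs from a signature mixture
#'
#' Inverts the signature model: each sample's burden is drawn uniformly
#' from `burden_range` and its 96-vector multinomially with channel
#' probabilities `signatures x weights`. True exposures (burden x
#' weight) are returned for recovery tests.
#'
#' @param signatures `signature_set`.
#' @param config [sim_config()].
#' @return List with `catalog` (`mutation_catalog`), `exposures`
#'   (samples x K true counts), `weights` (samples x K matrix used).
#' @export
simulate_catalogs <- function(signatures, config = sim_config()) {
  K <- length(signatures$labels)
  W <- config$signature_weights
  fixed <- is.matrix(W)
  if (!fixed) {
    idx <- match(names(W), signatures$labels)
    if (anyNA(idx)) stop("unknown signature label in weights", call. = FALSE)
    w_full <- numeric(K)
    w_full[idx] <- W
    W <- matrix(w_full, nrow = config$n_samples, ncol = K, byrow = TRUE)
  }
  colnames(W) <- signatures$labels
  samples <- sprintf("SIM_%03d", seq_len(config$n_samples))
  with_rng(sub_seed(config$seed, 201), {
    if (!fixed && is.finite(config$weight_alpha)) {
      ## per-sample Dirichlet draw around the cohort-mean composition
      alpha <- config$weight_alpha * K * W[1, ]
      W <- t(vapply(seq_len(config$n_samples), function(i) {
        g <- ifelse(alpha > 0, stats::rgamma(K, alpha), 0)
        g / sum(g)
      }, numeric(K)))
      colnames(W) <- signatures$labels
    }
    burdens <- if (config$burden_range[2] > config$burden_range[1])
      sample(config$burden_range[1]:config$burden_range[2],
             config$n_samples, replace = TRUE)
      else rep(config$burden_range[1], config$n_samples)
    counts <- t(vapply(seq_len(config$n_samples), function(i) {
      p <- as.numeric(signatures$matrix %*% W[i, ])
      if (burdens[i] == 0) integer(96)
      else as.integer(stats::rmultinom(1, burdens[i], p))
    }, integer(96)))
    dimnames(counts) <- list(samples, sbs_channels())
    exposures <- W * burdens
    dimnames(exposures) <- list(samples, signatures$labels)
    list(catalog = structure(list(counts = counts, samples = samples),
                             class = "mutation_catalog"),
         exposures = exposures, weights = W)
  })
}

#' Construct / simulate a clone tree with per-timepoint CCFs
#'
#' Builds a rooted clone tree whose cancer-cell fractions satisfy the
#' sum rule exactly at every timepoint (each parent's CCF is at least
#' the sum of its children's). When `trajectory` is requested, the
#' prevalence pattern is drawn so that the trajectory classifier's
#' definition of that pattern holds: `persistent` (the diagnostic major
#' clone's lineage stays major at relapse), `rising` (a minor diagnostic
#' subclone becomes the relapse major), `founding` (the relapse major
#' descends only from the founding clone).
#'
#' @param config [sim_config()].
#' @param n_clones clone count including the founding clone (default:
#'   drawn from `clone_count_range`).
#' @param trajectory `NULL` or one of `"persistent"`, `"rising"`,
#'   `"founding"`.
#' @param seed optional override of the config seed.
#' @return Object of class `clone_tree`: list with `parent` (integer,
#'   `NA` for the root), `ccf` (clones x timepoints matrix),
#'   `timepoints`, `n_mutations` (per-clone cluster sizes).
#' @export
simulate_clone_tree <- function(config = sim_config(), n_clones = NULL,
                                trajectory = NULL, seed = NULL) {
  seed <- if (is.null(seed)) config$seed else seed
  tps <- config$timepoints
  if (!"diagnosis" %in% tps || !any(c("r1", "r2") %in% tps))
    stop("need diagnosis plus at least one relapse timepoint", call. = FALSE)
  with_rng(sub_seed(seed, 301), {
    if (is.null(n_clones))
      n_clones <- sample(config$clone_count_range[1]:
                           config$clone_count_range[2], 1)
    if (n_clones < 2) stop("need at least 2 clones", call. = FALSE)
    if (!is.null(trajectory) &&
        trajectory %in% c("rising", "founding") && n_clones < 3)
      stop("trajectory '", trajectory, "' needs at least 3 clones",
           call. = FALSE)
    relapse_cols <- setdiff(tps, "diagnosis")
    parent <- rep(NA_integer_, n_clones)
    ccf <- matrix(0, n_clones, length(tps), dimnames = list(NULL, tps))
    ccf[1, ] <- 1                     # founding clone
    if (is.null(trajectory))
      trajectory <- sample(c("persistent", "rising", "founding"), 1)
    if (trajectory == "persistent") {
      parent[2] <- 1L
      a_d <- stats::runif(1, 0.6, 0.9)
      if (n_clones >= 3) {
        parent[3] <- 2L
        b_r <- stats::runif(1, 0.55, 0.75)
        a_r <- min(1, b_r + stats::runif(1, 0.05, 0.15))
        ccf[2, "diagnosis"] <- a_d
        ccf[3, "diagnosis"] <- 0
        for (tp in relapse_cols) { ccf[2, tp] <- a_r; ccf[3, tp] <- b_r }
      } else {
        ccf[2, "diagnosis"] <- a_d
        for (tp in relapse_cols) ccf[2, tp] <- stats::runif(1, 0.7, 0.95)
      }
      extra_parent <- if (n_clones >= 3) 3L else 2L
    } else if (trajectory == "rising") {
      parent[2] <- 1L; parent[3] <- 1L      # 2 = dx major, 3 = riser
      m_d <- stats::runif(1, 0.55, 0.7)
      s_d <- stats::runif(1, 0.08, min(0.25, 0.95 - m_d))
      ccf[2, "diagnosis"] <- m_d
      ccf[3, "diagnosis"] <- s_d
      for (tp in relapse_cols) {
        ccf[2, tp] <- stats::runif(1, 0, 0.03)
        ccf[3, tp] <- stats::runif(1, 0.75, 0.95)
      }
      extra_parent <- 3L
    } else if (trajectory == "founding") {
      parent[2] <- 1L; parent[3] <- 1L      # 2 = dx major, 3 = relapse clone
      m_d <- stats::runif(1, 0.6, 0.85)
      ccf[2, "diagnosis"] <- m_d
      ccf[3, "diagnosis"] <- 0
      for (tp in relapse_cols) {
        ccf[2, tp] <- 0
        ccf[3, tp] <- stats::runif(1, 0.6, 0.9)
      }
      extra_parent <- 3L
    } else stop("unknown trajectory: ", trajectory, call. = FALSE)
    ## extra clones nest under the relapse lineage, new at relapse
    used <- if (trajectory == "persistent" && n_clones >= 3) 3L
            else min(3L, n_clones)
    if (n_clones > used) {
      for (k in (used + 1L):n_clones) {
        parent[k] <- extra_parent
        for (tp in relapse_cols)
          ccf[k, tp] <- stats::runif(1, 0.1, 0.5) * ccf[extra_parent, tp]
        extra_parent <- k       # chain keeps the sum rule trivially exact
      }
    }
    n_mut <- sample(100:300, n_clones, replace = TRUE)
    tree <- structure(list(parent = parent, ccf = ccf, timepoints = tps,
                           n_mutations = n_mut, trajectory = trajectory),
                      class = "clone_tree")
    validate_clone_tree(tree, eps = 1e-9)
    tree
  })
}

#' Validate the pigeonhole (sum) rule on a clone tree
#'
#' At every node and timepoint the node's CCF must be at least the sum
#' of its children's CCFs, within `eps`.
#'
#' @param tree `clone_tree`.
#' @param eps tolerance (absolute CCF).
#' @return `tree` invisibly; error on violation.
#' @export
validate_clone_tree <- function(tree, eps = 0.05) {
  n <- length(tree$parent)
  if (sum(is.na(tree$parent)) != 1L)
    stop("clone tree must have exactly one root", call. = FALSE)
  for (i in seq_len(n)) {
    kids <- which(tree$parent == i)
    if (!length(kids)) next
    csum <- colSums(tree$ccf[kids, , drop = FALSE])
    if (any(csum > tree$ccf[i, ] + eps))
      stop("sum rule violated at clone ", i, call. = FALSE)
  }
  invisible(tree)
}

#' Simulate read-count level variants from a clone tree
#'
#' Every clone contributes `n_mutations` variants; at each timepoint a
#' variant's expected allele frequency is `purity x CCF / 2` (diploid,
#' copy-neutral), its depth is Poisson around `depth_mean` and its alt
#' count binomial. At the default configuration clonal clusters produce
#' the 0.35-0.50 AF peak and subclones the 0.1-0.25 peak.
#'
#' @param tree `clone_tree`.
#' @param config [sim_config()].
#' @param patient_id patient label for the emitted variants.
#' @param purity named numeric per timepoint (default: drawn from
#'   `purity_range`).
#' @param reference optional `toy_reference`; when given, variant
#'   positions are drawn from clean reference positions with matching
#'   reference base, so the variants pass the filter cascade.
#' @param seed optional override of the config seed.
#' @return List with `variants` ([somatic_variants()] frame with extra
#'   `clone` column; one row per variant per timepoint) and `purity`.
#' @export
simulate_variant_reads <- function(tree, config = sim_config(),
                                   patient_id = "SIM_P1", purity = NULL,
                                   reference = NULL, seed = NULL) {
  seed <- if (is.null(seed)) config$seed else seed
  tps <- tree$timepoints
  with_rng(sub_seed(seed, 401), {
    if (is.null(purity)) {
      purity <- stats::runif(length(tps), config$purity_range[1],
                             config$purity_range[2])
      names(purity) <- tps
    }
    n_mut <- tree$n_mutations
    total <- sum(n_mut)
    clone_of <- rep(seq_along(n_mut), n_mut)
    if (!is.null(reference)) {
      pos <- clean_positions(reference, total)
    } else {
      pos <- data.frame(chrom = "chrS1",
                        start = sort(sample.int(10000000L, total)),
                        ref = "A", stringsAsFactors = FALSE)
    }
    alt_base <- vapply(pos$ref, function(r)
      setdiff(c("A", "C", "G", "T"), r)[sample.int(3, 1)],
      character(1), USE.NAMES = FALSE)
    out <- vector("list", length(tps))
    for (ti in seq_along(tps)) {
      tp <- tps[ti]
      af_exp <- purity[tp] * tree$ccf[clone_of, tp] / 2
      depth <- stats::rpois(total, config$depth_mean)
      alt <- stats::rbinom(total, depth, af_exp)
      v <- somatic_variants(
        patient_id = patient_id,
        sample_id = paste0(patient_id, "_", tp), timepoint = tp,
        chrom = pos$chrom, start = pos$start, end = pos$start + 1,
        ref = pos$ref, alt = alt_base,
        tumor_depth = depth, alt_count = alt, germline_depth = 30,
        callers = "callerA;callerB")
      v$clone <- clone_of
      out[[ti]] <- v
    }
    variants <- do.call(rbind, out)
    class(variants) <- c("somatic_variants", "data.frame")
    list(variants = variants, purity = purity)
  })
}

## Positions safe for clean simulated variants: outside repeats, gaps,
## regulatory edge-cases are fine; >= 3 bp from any homopolymer run;
## not a population position.
clean_positions <- function(reference, n) {
  cand <- list()
  for (ch in names(reference$sequences)) {
    len <- Biostrings::width(reference$sequences[ch])
    p <- seq(10L, len - 10L)
    bad <- rep(FALSE, length(p))
    block <- function(df, flank = 0L) {
      sub <- df[df$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(sub)))
        bad[p >= sub$start[i] - flank & p < sub$end[i] + flank] <<- TRUE
    }
    ## generous flanks so small offsets applied to a "clean" position
    ## (e.g. the near-indel construction) cannot trip another rule
    block(reference$repeats, flank = 6L); block(reference$gaps, flank = 6L)
    block(reference$homopolymers, flank = 10L)
    pop_pos <- reference$population$start[reference$population$chrom == ch]
    for (d in -6:6) bad[p %in% (pop_pos + d)] <- TRUE
    cand[[ch]] <- data.frame(chrom = ch, start = p[!bad],
                             stringsAsFactors = FALSE)
  }
  cand <- do.call(rbind, cand)
  if (n > nrow(cand)) stop("not enough clean positions", call. = FALSE)
  idx <- sort(sample.int(nrow(cand), n))
  sel <- cand[idx, , drop = FALSE]
  sel$ref <- vapply(seq_len(nrow(sel)), function(i)
    ref_window(reference$sequences, sel$chrom[i], sel$start[i],
               sel$start[i] + 1), character(1))
  rownames(sel) <- NULL
  sel
}

#' Simulate clean clonal variants for filter validation
#'
#' Draws variants from the major clone of a copy-neutral diploid tumor
#' (expected AF `purity/2`, default ~0.45) at positions guaranteed
#' clear of every planted filter feature, so that all of them pass the
#' cascade. Used by the filter-validation bundle; subclonal cohorts
#' come from [simulate_variant_reads()].
#'
#' @param reference `toy_reference`.
#' @param n number of variants.
#' @param config [sim_config()] (depth model).
#' @param purity tumor purity (default 0.9).
#' @param sample_id,patient_id,timepoint identifiers.
#' @param seed RNG seed.
#' @return [somatic_variants()] frame.
#' @export
simulate_clean_variants <- function(reference, n, config = sim_config(),
                                    purity = 0.9, sample_id = "S0",
                                    patient_id = "P0",
                                    timepoint = "diagnosis", seed = 1L) {
  with_rng(sub_seed(seed, 451), {
    pos <- clean_positions(reference, n)
    alt_base <- vapply(pos$ref, function(r)
      setdiff(c("A", "C", "G", "T"), r)[sample.int(3, 1)],
      character(1), USE.NAMES = FALSE)
    depth <- stats::rpois(n, config$depth_mean)
    ## resample low-coverage sites so the AF floor cannot trip by chance
    depth[depth < 40] <- 40L
    alt <- vapply(depth, function(d) {
      a <- stats::rbinom(1, d, purity / 2)
      while (a / d < 0.1) a <- stats::rbinom(1, d, purity / 2)
      a
    }, numeric(1))
    somatic_variants(patient_id, sample_id, timepoint, pos$chrom,
                     pos$start, pos$start + 1, pos$ref, alt_base,
                     depth, alt, germline_depth = 30,
                     callers = "callerA;callerB")
  })
}

#' Inject filter-violating artifact variants
#'
#' For each cascade rule with a positive rate, appends variants that
#' violate exactly that rule, constructed from the toy reference's
#' planted features, and returns ground-truth labels for recall/false-
#' positive accounting. Rates of zero leave the input unchanged.
#'
#' @param variants clean [somatic_variants()] frame (labels `clean`).
#' @param reference `toy_reference`.
#' @param rates named integer vector over [cascade_rules()].
#' @param sample_id sample to attach artifacts to (default: first sample
#'   in `variants`, or `"S0"`).
#' @param seed RNG seed.
#' @return List with `variants` (augmented frame), `indels` (companion
#'   indel call set used by the near-indel rule), `truth` (data frame
#'   `key`, `label`).
#' @export
inject_artifacts <- function(variants, reference,
                             rates = c(homopolymer = 2L), sample_id = NULL,
                             seed = 1L) {
  unknown <- setdiff(names(rates), cascade_rules())
  if (length(unknown))
    stop("unknown filter rule id: ", unknown[1], call. = FALSE)
  if (is.null(sample_id))
    sample_id <- if (nrow(variants)) variants$sample_id[1] else "S0"
  pid <- if (nrow(variants)) variants$patient_id[1] else "P0"
  tp <- if (nrow(variants)) variants$timepoint[1] else "diagnosis"
  truth <- data.frame(key = variant_key(variants),
                      label = rep("clean", nrow(variants)),
                      stringsAsFactors = FALSE)
  indels <- NULL
  with_rng(sub_seed(seed, 501), {
    mk <- function(chrom, start, ref, alt, depth = 90L, alt_n = 40L,
                   gdp = 30) {
      somatic_variants(pid, sample_id, tp, chrom, start,
                       start + nchar(ref), ref, alt, depth, alt_n, gdp,
                       callers = "callerA;callerB")
    }
    base_at <- function(chrom, start)
      ref_window(reference$sequences, chrom, start, start + 1)
    other <- function(b) setdiff(c("A", "C", "G", "T"), b)[sample.int(3, 1)]
    added <- list()
    pool <- clean_positions(reference, 4L * sum(rates) + 40L)
    take <- function(k) {
      idx <- sample.int(nrow(pool), k)
      out <- pool[idx, , drop = FALSE]
      pool <<- pool[-idx, , drop = FALSE]
      out
    }
    for (rule in names(rates)) {
      k <- rates[[rule]]
      if (k == 0) next
      vs <- switch(rule,
        depth_anomaly = {
          p <- take(k)
          do.call(rbind, lapply(seq_len(k), function(i)
            mk(p$chrom[i], p$start[i], p$ref[i], other(p$ref[i]),
               gdp = 500)))
        },
        low_af = {
          p <- take(k)
          do.call(rbind, lapply(seq_len(k), function(i)
            mk(p$chrom[i], p$start[i], p$ref[i], other(p$ref[i]),
               depth = 100L, alt_n = 2L)))
        },
        repeat_overlap = {
          reps <- reference$repeats
          do.call(rbind, lapply(seq_len(k), function(i) {
            r <- reps[1 + (i - 1) %% nrow(reps), ]
            pos <- r$start + 10L + i
            b <- base_at(r$chrom, pos)
            mk(r$chrom, pos, b, other(b))
          }))
        },
        homopolymer = {
          hp <- reference$homopolymers
          do.call(rbind, lapply(seq_len(k), function(i) {
            h <- hp[1 + (i - 1) %% nrow(hp), ]
            pos <- h$start - 1L          # adjacent to the run
            b <- base_at(h$chrom, pos)
            mk(h$chrom, pos, b, other(b))
          }))
        },
        near_indel = {
          p <- take(k)
          ind <- do.call(rbind, lapply(seq_len(k), function(i) {
            b <- p$ref[i]
            b2 <- base_at(p$chrom[i], p$start[i] + 1)
            mk(p$chrom[i], p$start[i], paste0(b, b2), b)   # 1 bp deletion
          }))
          ## note: this block evaluates in the function frame, so plain
          ## assignment updates the `indels` defined above
          indels <- if (is.null(indels)) ind else rbind(indels, ind)
          do.call(rbind, lapply(seq_len(k), function(i) {
            pos <- p$start[i] + 4L       # within 5 bp of the indel
            b <- base_at(p$chrom[i], pos)
            mk(p$chrom[i], pos, b, other(b))
          }))
        },
        population_variant = {
          popn <- reference$population
          do.call(rbind, lapply(seq_len(k), function(i) {
            r <- popn[((i - 1L) * 7L) %% nrow(popn) + 1L, ]
            mk(r$chrom, r$start, r$ref, r$alt)
          }))
        })
      truth <- rbind(truth, data.frame(key = variant_key(vs),
                                       label = rule,
                                       stringsAsFactors = FALSE))
      added[[rule]] <- vs
    }
    aug <- rbind(variants, do.call(rbind, added))
    if (!is.null(aug)) class(aug) <- c("somatic_variants", "data.frame")
    list(variants = if (is.null(aug)) variants else aug,
         indels = indels, truth = truth)
  })
}

#' Write a complete synthetic fixture bundle
#'
#' Materializes everything the pipeline reads: the toy reference FASTA,
#' regulatory/repeat/gap BED files, the population VCF, per-sample tumor
#' VCFs for a small simulated cohort (with planted artifacts), a sample
#' metadata TSV and a truth table. Byte-identical across runs with the
#' same seed.
#'
#' @param outdir output directory (created if needed).
#' @param seed master seed.
#' @param n_patients number of simulated patients.
#' @param config [sim_config()] for the cohort.
#' @return Invisibly, a named list of written file paths.
#' @export
write_fixture_bundle <- function(outdir, seed = 1L, n_patients = 3L,
                                 config = sim_config(seed = seed)) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outdir, 2) != 0)
    stop("unwritable output directory: ", outdir, call. = FALSE)
  ref <- make_toy_reference(seed)
  paths <- list(fasta = file.path(outdir, "reference.fa"),
                regulatory = file.path(outdir, "regulatory.bed"),
                repeats = file.path(outdir, "repeats.bed"),
                gaps = file.path(outdir, "gaps.bed"),
                population = file.path(outdir, "population.vcf"),
                meta = file.path(outdir, "samples.tsv"),
                truth = file.path(outdir, "truth.tsv"))
  Biostrings::writeXStringSet(ref$sequences, paths$fasta)
  write_regions(ref$regulatory, paths$regulatory)
  write_regions(ref$repeats, paths$repeats)
  write_regions(ref$gaps, paths$gaps)
  write_population_vcf(ref$population, paths$population)
  trajs <- c("persistent", "rising", "founding")
  meta <- list(); truth <- list()
  for (i in seq_len(n_patients)) {
    pid <- sprintf("SIM_P%02d", i)
    tr <- trajs[1 + (i - 1) %% 3]
    for (tp in config$timepoints) {
      v <- simulate_clean_variants(ref, 150L, config, sample_id =
                                     paste0(pid, "_", tp),
                                   patient_id = pid, timepoint = tp,
                                   seed = sub_seed(seed, i * 10L +
                                                     match(tp, config$timepoints)))
      inj <- inject_artifacts(v, ref, rates = config$artifact_rates,
                              seed = sub_seed(seed, i * 10L +
                                                match(tp, config$timepoints)))
      vp <- file.path(outdir, sprintf("%s_%s.vcf", pid, tp))
      write_variants(inj$variants, vp)
      paths[[sprintf("%s_%s", pid, tp)]] <- vp
      tt <- inj$truth
      tt$sample_id <- paste0(pid, "_", tp)
      truth[[length(truth) + 1L]] <- tt
      meta[[length(meta) + 1L]] <- data.frame(
        patient_id = pid, sample_id = paste0(pid, "_", tp),
        timepoint = tp, purity = 0.9,
        trajectory_truth = tr, bmt_flag = FALSE,
        dbsnp_overlap_fraction = 0, stringsAsFactors = FALSE)
    }
  }
  utils::write.table(do.call(rbind, meta), paths$meta, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(do.call(rbind, truth), paths$truth, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Write a minimal population VCF (sites only)
#'
#' @param population data frame `chrom`, `start` (0-based), `ref`, `alt`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_population_vcf <- function(population, path) {
  hdr <- c("##fileformat=VCFv4.2",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  o <- order(population$chrom, population$start)
  p <- population[o, , drop = FALSE]
  writeLines(c(hdr, sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.", p$chrom,
                            as.integer(p$start) + 1L, p$ref, p$alt)), path)
  invisible(path)
}

#' Read a sites-only population VCF
#'
#' @param path VCF path.
#' @return Data frame `chrom`, `start` (0-based), `ref`, `alt`.
#' @export
read_population_vcf <- function(path) {
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path))
  rr <- SummarizedExperiment::rowRanges(vcf)
  data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    start = BiocGenerics::start(rr) - 1L,
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = vapply(seq_along(vcf), function(i)
      as.character(VariantAnnotation::alt(vcf)[[i]][1]), character(1)),
    stringsAsFactors = FALSE)
}
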