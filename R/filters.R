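#' Filter cascade configuration
#'
#' Thresholds of the somatic SNV/indel downstream filter cascade and the
#' structural-variant filters. Defaults encode the published rules:
#' an allele-frequency floor of 5% (10% for flagged samples), a 3-fold
#' germline depth anomaly cutoff, homopolymer runs of >= 7 bases,
#' a 5 bp indel exclusion flank, a 90% dbSNP-overlap sample flag, 50%
#' reciprocal overlap for population SV matching, and 10 kb coverage
#' windows with a 10-read floor.
#'
#' @param af_min_default AF floor for unflagged samples.
#' @param af_min_flagged AF floor for samples with a bone-marrow
#'   transplant before sampling or excess dbSNP overlap.
#' @param depth_fold germline depth anomaly multiplier.
#' @param homopolymer_min_len minimal homopolymer run length.
#' @param homopolymer_flank_bp flank (bp) by which a variant interval is
#'   expanded before intersecting runs ("overlapped or flanked").
#' @param indel_flank_bp SNV-to-indel exclusion distance.
#' @param dbsnp_sample_fraction dbSNP overlap fraction above which a
#'   sample uses the flagged AF floor.
#' @param sv_reciprocal_overlap minimal reciprocal overlap with a
#'   population SV of the same type.
#' @param sv_window_bp,sv_window_min_cov germline coverage window size
#'   and minimal mean coverage.
#' @return List of class `filter_config`.
#' @export
filter_config <- function(af_min_default = 0.05, af_min_flagged = 0.10,
                          depth_fold = 3, homopolymer_min_len = 7L,
                          homopolymer_flank_bp = 1L, indel_flank_bp = 5L,
                          dbsnp_sample_fraction = 0.90,
                          sv_reciprocal_overlap = 0.50,
                          sv_window_bp = 10000L, sv_window_min_cov = 10) {
  cfg <- list(af_min_default = af_min_default,
              af_min_flagged = af_min_flagged, depth_fold = depth_fold,
              homopolymer_min_len = homopolymer_min_len,
              homopolymer_flank_bp = homopolymer_flank_bp,
              indel_flank_bp = indel_flank_bp,
              dbsnp_sample_fraction = dbsnp_sample_fraction,
              sv_reciprocal_overlap = sv_reciprocal_overlap,
              sv_window_bp = sv_window_bp,
              sv_window_min_cov = sv_window_min_cov)
  stopifnot(all(unlist(cfg) > 0),
            af_min_default <= 1, af_min_flagged <= 1,
            dbsnp_sample_fraction <= 1, sv_reciprocal_overlap <= 1)
  class(cfg) <- "filter_config"
  cfg
}

## Rule identifiers of the SNV/indel cascade, in report order.
cascade_rules <- function() {
  c("depth_anomaly", "low_af", "repeat_overlap", "homopolymer",
    "near_indel", "population_variant")
}

#' Per-chromosome germline depth profile
#'
#' @param means named numeric vector: mean germline depth per chromosome.
#' @return Object of class `chrom_depth_profile`.
#' @export
chrom_depth_profile <- function(means) {
  stopifnot(is.numeric(means), !is.null(names(means)), all(means > 0))
  structure(list(means = means), class = "chrom_depth_profile")
}

#' Germline depth anomaly filter
#'
#' Fails a variant when the germline depth at its site exceeds
#' `depth_fold` times the chromosomal mean germline depth (strictly; a
#' depth of exactly 3x the mean passes).
#'
#' @param variants [somatic_variants()] frame with `germline_depth` set.
#' @param profile [chrom_depth_profile()].
#' @param cfg [filter_config()].
#' @return Logical vector, `TRUE` = pass.
#' @export
filter_depth_anomaly <- function(variants, profile, cfg = filter_config()) {
  missing_ch <- setdiff(unique(variants$chrom), names(profile$means))
  if (length(missing_ch))
    stop("chromosome absent from depth profile: ", missing_ch[1],
         call. = FALSE)
  lim <- cfg$depth_fold * profile$means[variants$chrom]
  !(variants$germline_depth > lim)
}

#' Allele-frequency floor filter
#'
#' Fails variants with AF strictly below the floor. The floor is
#' `af_min_flagged` for samples flagged by a prior bone-marrow transplant
#' or by a dbSNP overlap fraction above `dbsnp_sample_fraction`,
#' otherwise `af_min_default`.
#'
#' @param variants [somatic_variants()] frame.
#' @param bmt_flag logical, sample-level transplant flag.
#' @param dbsnp_overlap_fraction numeric in `[0, 1]`, sample-level.
#' @param cfg [filter_config()].
#' @return Logical vector, `TRUE` = pass.
#' @export
filter_low_af <- function(variants, bmt_flag = FALSE,
                          dbsnp_overlap_fraction = 0,
                          cfg = filter_config()) {
  flagged <- isTRUE(bmt_flag) ||
    (!is.na(dbsnp_overlap_fraction) &&
       dbsnp_overlap_fraction > cfg$dbsnp_sample_fraction)
  floor_af <- if (flagged) cfg$af_min_flagged else cfg$af_min_default
  !(variants$af < floor_af)
}

#' Annotation-overlap filter rules
#'
#' Evaluates the four annotation-based rules for each variant and
#' returns every violated rule id among `repeat_overlap`, `homopolymer`,
#' `near_indel` and `population_variant`:
#' * `repeat_overlap`: the variant interval intersects a repeat region;
#' * `homopolymer`: the variant interval expanded by
#'   `homopolymer_flank_bp` intersects a single-base run of at least
#'   `homopolymer_min_len` bases in the reference;
#' * `near_indel`: an SNV lies within `indel_flank_bp` bases of an indel
#'   called in the same sample;
#' * `population_variant`: SNVs match a population record on
#'   chromosome, position and both alleles; indels match by position
#'   within 1 bp.
#'
#' @param variants [somatic_variants()] frame.
#' @param repeats interval frame of repeat regions (or `NULL`).
#' @param population data frame `chrom`, `start`, `ref`, `alt`
#'   (or `NULL`).
#' @param indels [somatic_variants()] frame of indel calls (or `NULL`).
#' @param sequences reference `DNAStringSet` (or `NULL` to skip the
#'   homopolymer rule).
#' @param cfg [filter_config()].
#' @return List (one element per variant) of character vectors of failed
#'   rule ids.
#' @export
filter_annotation_overlaps <- function(variants, repeats = NULL,
                                       population = NULL, indels = NULL,
                                       sequences = NULL,
                                       cfg = filter_config()) {
  n <- nrow(variants)
  fails <- rep(list(character(0)), n)
  add <- function(idx, rule) {
    for (i in idx) fails[[i]] <<- c(fails[[i]], rule)
    fails
  }
  if (!is.null(repeats) && nrow(repeats)) {
    hits <- interval_overlaps(variants, repeats)
    fails <- add(unique(hits$query), "repeat_overlap")
  }
  if (!is.null(sequences)) {
    runs <- homopolymer_runs(sequences, cfg$homopolymer_min_len)
    if (nrow(runs)) {
      grown <- variants
      grown$start <- pmax(0, grown$start - cfg$homopolymer_flank_bp)
      grown$end <- grown$end + cfg$homopolymer_flank_bp
      hits <- interval_overlaps(grown, runs)
      fails <- add(unique(hits$query), "homopolymer")
    }
  }
  if (!is.null(indels) && nrow(indels)) {
    snv_idx <- which(variants$var_class == "SNV")
    for (i in snv_idx) {
      same <- indels[indels$sample_id == variants$sample_id[i] &
                       indels$chrom == variants$chrom[i], , drop = FALSE]
      if (!nrow(same)) next
      d <- pmax(same$start - variants$start[i],
                variants$start[i] - (same$end - 1), 0)
      if (any(d <= cfg$indel_flank_bp)) fails <- add(i, "near_indel")
    }
  }
  if (!is.null(population) && nrow(population)) {
    pop_snv <- paste(population$chrom, population$start, population$ref,
                     population$alt, sep = ":")
    snv <- variants$var_class == "SNV"
    hit_snv <- which(snv & variant_key(variants) %in% pop_snv)
    fails <- add(hit_snv, "population_variant")
    ind_idx <- which(!snv)
    if (length(ind_idx)) {
      pop_ind <- population[nchar(population$ref) != 1 |
                              nchar(population$alt) != 1, , drop = FALSE]
      for (i in ind_idx) {
        same <- pop_ind[pop_ind$chrom == variants$chrom[i], , drop = FALSE]
        if (nrow(same) && any(abs(same$start - variants$start[i]) <= 1))
          fails <- add(i, "population_variant")
      }
    }
  }
  fails
}

#' Run the somatic SNV/indel filter cascade
#'
#' Evaluates every rule independently on every variant (the cascade is
#' order-free by construction), annotates removed variants with all
#' their failed rule ids, and reports per-rule removal counts. A variant
#' survives iff it fails no rule; survivors plus removed always equal
#' the input.
#'
#' @param variants [somatic_variants()] frame.
#' @param profile [chrom_depth_profile()] or `NULL` to skip the depth
#'   rule.
#' @param sample_flags data frame `sample_id`, `bmt_flag`,
#'   `dbsnp_overlap_fraction` (or `NULL`: all unflagged).
#' @param repeats,population,indels,sequences see
#'   [filter_annotation_overlaps()].
#' @param cfg [filter_config()].
#' @return List with `survivors`, `removed` (both [somatic_variants()]
#'   frames, `removed` carrying `filter_flags`) and `counts` (named
#'   integer removal count per rule).
#' @export
run_cascade <- function(variants, profile = NULL, sample_flags = NULL,
                        repeats = NULL, population = NULL, indels = NULL,
                        sequences = NULL, cfg = filter_config()) {
  n <- nrow(variants)
  fails <- filter_annotation_overlaps(variants, repeats, population,
                                      indels, sequences, cfg)
  if (!is.null(profile)) {
    known <- !is.na(variants$germline_depth)
    ok <- rep(TRUE, n)
    ok[known] <- filter_depth_anomaly(variants[known, , drop = FALSE],
                                      profile, cfg)
    for (i in which(!ok)) fails[[i]] <- c(fails[[i]], "depth_anomaly")
  }
  for (sid in unique(variants$sample_id)) {
    idx <- which(variants$sample_id == sid)
    bmt <- FALSE; dbf <- 0
    if (!is.null(sample_flags) && sid %in% sample_flags$sample_id) {
      row <- sample_flags[sample_flags$sample_id == sid, , drop = FALSE]
      bmt <- isTRUE(row$bmt_flag[1])
      dbf <- row$dbsnp_overlap_fraction[1]
    }
    ok <- filter_low_af(variants[idx, , drop = FALSE], bmt, dbf, cfg)
    for (i in idx[!ok]) fails[[i]] <- c(fails[[i]], "low_af")
  }
  flag_str <- vapply(fails, join_flags, character(1))
  out <- variants
  out$filter_flags <- flag_str
  keep <- !nzchar(flag_str)
  counts <- vapply(cascade_rules(), function(r)
    sum(vapply(fails, function(f) r %in% f, logical(1))), integer(1))
  list(survivors = out[keep, , drop = FALSE],
       removed = out[!keep, , drop = FALSE],
       counts = counts)
}

## Reciprocal overlap of two spans: min of the two mutual fractions.
reciprocal_overlap <- function(a_start, a_end, b_start, b_end) {
  ov <- .overlap_len(a_start, a_end, b_start, b_end)
  if (ov <= 0) return(0)
  min(ov / (a_end - a_start), ov / (b_end - b_start))
}

## Genomic span of a non-translocation SV.
sv_span <- function(svs) {
  data.frame(chrom = svs$chrom_a, start = svs$start_a, end = svs$end_b,
             stringsAsFactors = FALSE)
}

#' Structural-variant filters
#'
#' Removes a somatic SV when any of the following holds, unless one of
#' its genes is whitelisted as a known driver or fusion gene:
#' (1) reciprocal overlap >= `sv_reciprocal_overlap` with a population
#' SV of the same type; (2) its span overlaps a coverage window with
#' mean germline coverage below `sv_window_min_cov`, or an assembly gap;
#' (3) a deletion overlaps a duplication in the same sample; (4) its
#' gene set intersects the excluded-gene list (e.g. T-cell receptor,
#' HLA and immunoglobulin loci).
#'
#' @param svs [structural_variants()] frame.
#' @param population_svs [structural_variants()] frame of population
#'   variation (or `NULL`).
#' @param germline_cov data frame `chrom`, `start`, `end`, `mean_depth`
#'   of coverage windows (or `NULL`).
#' @param gaps interval frame of assembly gaps (or `NULL`).
#' @param excluded_genes,whitelist character vectors of gene symbols.
#' @param cfg [filter_config()].
#' @return List with `survivors`, `removed` and `reasons` (character,
#'   `";"`-joined per removed SV).
#' @export
filter_structural_variants <- function(svs, population_svs = NULL,
                                       germline_cov = NULL, gaps = NULL,
                                       excluded_genes = character(0),
                                       whitelist = character(0),
                                       cfg = filter_config()) {
  n <- nrow(svs)
  reasons <- rep(list(character(0)), n)
  spans <- sv_span(svs)
  intra <- svs$sv_type != "TRA"
  if (!is.null(population_svs) && nrow(population_svs)) {
    pop_spans <- sv_span(population_svs)
    for (i in which(intra)) {
      same <- which(population_svs$sv_type == svs$sv_type[i] &
                      pop_spans$chrom == spans$chrom[i])
      for (j in same) {
        if (reciprocal_overlap(spans$start[i], spans$end[i],
                               pop_spans$start[j], pop_spans$end[j]) >=
            cfg$sv_reciprocal_overlap) {
          reasons[[i]] <- c(reasons[[i]], "population")
          break
        }
      }
    }
  }
  flag_span_overlap <- function(bad, rule) {
    if (is.null(bad) || !nrow(bad)) return()
    hits <- interval_overlaps(spans[intra, , drop = FALSE], bad)
    for (i in which(intra)[unique(hits$query)])
      reasons[[i]] <<- c(reasons[[i]], rule)
  }
  if (!is.null(germline_cov))
    flag_span_overlap(
      germline_cov[germline_cov$mean_depth < cfg$sv_window_min_cov, ,
                   drop = FALSE], "low_coverage")
  flag_span_overlap(gaps, "gap")
  for (sid in unique(svs$sample_id)) {
    del <- which(svs$sample_id == sid & svs$sv_type == "DEL")
    dup <- which(svs$sample_id == sid & svs$sv_type == "DUP")
    for (i in del) for (j in dup) {
      if (spans$chrom[i] == spans$chrom[j] &&
          .overlap_len(spans$start[i], spans$end[i],
                       spans$start[j], spans$end[j]) > 0)
        reasons[[i]] <- c(reasons[[i]], "del_dup_overlap")
    }
  }
  gene_sets <- lapply(svs$genes, split_flags)
  if (length(excluded_genes)) {
    for (i in seq_len(n))
      if (length(intersect(gene_sets[[i]], excluded_genes)))
        reasons[[i]] <- c(reasons[[i]], "excluded_gene")
  }
  protected <- vapply(gene_sets, function(g)
    length(intersect(g, whitelist)) > 0, logical(1))
  reasons[protected] <- list(character(0))
  removed <- vapply(reasons, length, integer(1)) > 0
  list(survivors = svs[!removed, , drop = FALSE],
       removed = svs[removed, , drop = FALSE],
       reasons = vapply(reasons[removed], join_flags, character(1)))
}

#' Technical-replicate concordance
#'
#' Given the call sets of three technical replicate libraries, computes
#' the fractions of the union of variant keys present in all three,
#' exactly two, and exactly one replicate. The three fractions sum to 1.
#'
#' @param callsets list of exactly three [somatic_variants()] frames or
#'   character vectors of variant keys.
#' @return Named numeric vector `c(in_3, in_2, in_1)`.
#' @export
replicate_concordance <- function(callsets) {
  if (length(callsets) != 3L)
    stop("replicate_concordance needs exactly three call sets",
         call. = FALSE)
  keys <- lapply(callsets, function(x)
    unique(if (is.data.frame(x)) variant_key(x) else as.character(x)))
  u <- unique(unlist(keys))
  if (!length(u)) stop("all replicate call sets are empty", call. = FALSE)
  times <- rowSums(vapply(keys, function(k) u %in% k, logical(length(u))))
  c(in_3 = mean(times == 3), in_2 = mean(times == 2), in_1 = mean(times == 1))
}
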