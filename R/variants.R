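#' Somatic variant table
#'
#' One row per called somatic SNV or indel. Positions are 0-based
#' half-open (`start`, `end`); `af` is recomputed from `alt_count` and
#' `tumor_depth` whenever the depth is positive, so the invariant
#' `af == alt_count / tumor_depth` always holds.
#'
#' @param patient_id,sample_id,timepoint identifiers; `timepoint` one of
#'   `"diagnosis"`, `"r1"`, `"r2"`, `"remission"`.
#' @param chrom,start,end interval of the variant (0-based half-open).
#' @param ref,alt reference and alternate alleles.
#' @param tumor_depth,alt_count,germline_depth read counts.
#' @param gene gene symbol or `""`.
#' @param functional_class one of `"non_silent"`, `"silent"`,
#'   `"non_coding"`, `"unknown"`.
#' @param callers caller provenance, `";"`-separated subset of
#'   `{callerA, callerB}` per variant.
#' @param filter_flags `";"`-separated failed-rule identifiers (empty for
#'   untested/clean variants).
#' @return data frame of class `somatic_variants`.
#' @export
somatic_variants <- function(patient_id, sample_id, timepoint,
                             chrom, start, end, ref, alt,
                             tumor_depth, alt_count,
                             germline_depth = NA_real_,
                             gene = "", functional_class = "unknown",
                             callers = "callerA", filter_flags = "") {
  n <- max(length(patient_id), length(sample_id), length(timepoint),
           length(chrom), length(start), length(end), length(ref),
           length(alt), length(tumor_depth), length(alt_count))
  df <- data.frame(
    patient_id = rep_len(as.character(patient_id), n),
    sample_id = rep_len(as.character(sample_id), n),
    timepoint = rep_len(as.character(timepoint), n),
    chrom = rep_len(as.character(chrom), n),
    start = as.numeric(start), end = as.numeric(end),
    ref = as.character(ref), alt = as.character(alt),
    var_class = ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV", "indel"),
    tumor_depth = as.numeric(tumor_depth),
    alt_count = as.numeric(alt_count),
    af = ifelse(tumor_depth > 0, as.numeric(alt_count) / as.numeric(tumor_depth), 0),
    germline_depth = rep_len(as.numeric(germline_depth), n),
    gene = rep_len(as.character(gene), n),
    functional_class = rep_len(as.character(functional_class), n),
    callers = rep_len(as.character(callers), n),
    filter_flags = rep_len(as.character(filter_flags), n),
    stringsAsFactors = FALSE)
  validate_variants(df)
  class(df) <- c("somatic_variants", "data.frame")
  df
}

#' Validate somatic variant invariants
#'
#' @param df variant data frame.
#' @return `df` invisibly, or an error naming the first violating row.
#' @export
validate_variants <- function(df) {
  validate_intervals(df, "somatic_variants")
  bad_tp <- which(!df$timepoint %in% c("diagnosis", "r1", "r2", "remission"))
  if (length(bad_tp))
    stop("somatic_variants: unknown timepoint at row ", bad_tp[1], call. = FALSE)
  bad_ct <- which(df$alt_count > df$tumor_depth)
  if (length(bad_ct))
    stop("somatic_variants: alt_count > tumor_depth at row ", bad_ct[1],
         call. = FALSE)
  pos <- df$tumor_depth > 0
  if (any(abs(df$af[pos] - df$alt_count[pos] / df$tumor_depth[pos]) > 1e-9))
    stop("somatic_variants: af inconsistent with counts", call. = FALSE)
  snv <- df$var_class == "SNV"
  if (any(nchar(df$ref[snv]) != 1L | nchar(df$alt[snv]) != 1L))
    stop("somatic_variants: SNV with multi-base allele", call. = FALSE)
  invisible(df)
}

#' Structural variant table
#'
#' Breakpoint pairs for deletions, duplications, inversions and
#' translocations. Non-translocations must have both breakpoints on one
#' chromosome with `a` not after `b`.
#'
#' @param sample_id sample identifier.
#' @param sv_type one of `"DEL"`, `"DUP"`, `"INV"`, `"TRA"`.
#' @param chrom_a,start_a,end_a,chrom_b,start_b,end_b breakpoint intervals
#'   (0-based half-open).
#' @param genes `";"`-separated overlapped gene symbols per SV.
#' @return data frame of class `structural_variants`.
#' @export
structural_variants <- function(sample_id, sv_type, chrom_a, start_a, end_a,
                                chrom_b, start_b, end_b, genes = "") {
  n <- length(sv_type)
  df <- data.frame(sample_id = rep_len(as.character(sample_id), n),
                   sv_type = as.character(sv_type),
                   chrom_a = as.character(chrom_a),
                   start_a = as.numeric(start_a), end_a = as.numeric(end_a),
                   chrom_b = as.character(chrom_b),
                   start_b = as.numeric(start_b), end_b = as.numeric(end_b),
                   genes = rep_len(as.character(genes), n),
                   stringsAsFactors = FALSE)
  stopifnot(all(df$sv_type %in% c("DEL", "DUP", "INV", "TRA")))
  intra <- df$sv_type != "TRA"
  if (any(df$chrom_a[intra] != df$chrom_b[intra]))
    stop("structural_variants: non-TRA on two chromosomes", call. = FALSE)
  if (any(df$start_a[intra] > df$start_b[intra]))
    stop("structural_variants: breakpoint a after b", call. = FALSE)
  class(df) <- c("structural_variants", "data.frame")
  df
}

## Canonical variant identity key: chrom + 0-based pos + alleles.
variant_key <- function(df) {
  paste(df$chrom, df$start, df$ref, df$alt, sep = ":")
}

## Split a ";"-separated flag cell into a character vector.
split_flags <- function(x) {
  if (!nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
}

## Join flags back; stable sort keeps outputs deterministic.
join_flags <- function(x) paste(sort(unique(x)), collapse = ";")
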