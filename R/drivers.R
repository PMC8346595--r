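#' Assemble per-gene driver evidence
#'
#' Bundles the inputs of the driver rule engine for one gene: external
#' significance p-values (e.g. from recurrence/selection tools),
#' per-patient variant hits, known-driver status, and RNA evidence of
#' mutant-allele expression.
#'
#' @param gene gene symbol.
#' @param tool_p_values named numeric, p-value per external tool (may be
#'   empty).
#' @param hits data frame with one row per variant hit: columns
#'   `patient_id`, `timepoint`, `af`, `functional_class`,
#'   `rna_expressed` (logical; `NA` = not assayed).
#' @param known_driver logical: membership in the configured
#'   known-driver gene list.
#' @return List of class `gene_evidence`.
#' @export
gene_evidence <- function(gene, tool_p_values = numeric(0), hits,
                          known_driver = FALSE) {
  if (!nrow(hits)) stop("empty patient hits for gene ", gene, call. = FALSE)
  stopifnot(all(tool_p_values >= 0 & tool_p_values <= 1))
  structure(list(gene = gene, tool_p_values = tool_p_values, hits = hits,
                 known_driver = known_driver), class = "gene_evidence")
}

#' Evaluate the driver-gene rules for one gene
#'
#' A gene is called a driver when all five criteria hold:
#' (1) at least one external tool reports `p <= p_max`;
#' (2) non-silent hits recur in at least `min_patients` distinct
#' patients; (3) hits are non-silent; (4) some hit is clonal
#' (`af >= af_clonal`); (5) the mutant allele is expressed in RNA in at
#' least one carrier sample. For genes on the known-driver list only
#' criteria 3-5 are required and a single patient suffices.
#'
#' @param evidence [gene_evidence()].
#' @param p_max tool significance cutoff (default 0.05, inclusive).
#' @param af_clonal clonal AF cutoff (default 0.25, inclusive).
#' @param min_patients recurrence cutoff for novel genes (default 2).
#' @return List of class `driver_call`: `gene`, `verdict`,
#'   `criteria_met` (character subset of the five ids), `rationale`.
#' @export
evaluate_driver <- function(evidence, p_max = 0.05, af_clonal = 0.25,
                            min_patients = 2L) {
  h <- evidence$hits
  ns <- h[h$functional_class == "non_silent", , drop = FALSE]
  crit <- c(
    significance = length(evidence$tool_p_values) > 0 &&
      any(evidence$tool_p_values <= p_max),
    recurrence = length(unique(ns$patient_id)) >= min_patients,
    non_silent = nrow(ns) > 0,
    clonal_af = nrow(ns) > 0 && any(ns$af >= af_clonal),
    rna_expressed = nrow(ns) > 0 && any(ns$rna_expressed %in% TRUE))
  verdict <- if (evidence$known_driver)
    all(crit[c("non_silent", "clonal_af", "rna_expressed")])
  else all(crit)
  rationale <- sprintf(
    "%s: %s via %s path; criteria met: %s",
    evidence$gene, if (verdict) "driver" else "not a driver",
    if (evidence$known_driver) "known-driver (criteria 3-5, 1 patient sufficient)"
    else "novel-gene (criteria 1-5)",
    paste(names(crit)[crit], collapse = ", "))
  structure(list(gene = evidence$gene, verdict = verdict,
                 criteria_met = names(crit)[crit], rationale = rationale),
            class = "driver_call")
}

#' Classify driver genes by carrier timepoints
#'
#' @param calls list of [evaluate_driver()] results (only positive
#'   verdicts are classified).
#' @param variants [somatic_variants()] frame of all carrier hits.
#' @return Data frame `gene`, `classification` in
#'   `{diagnosis_only, relapse_only, both}`.
#' @export
summarize_driver_timepoints <- function(calls, variants) {
  genes <- vapply(Filter(function(c) c$verdict, calls), `[[`, character(1),
                  "gene")
  cls <- vapply(genes, function(g) {
    tps <- unique(variants$timepoint[variants$gene == g &
                                       variants$timepoint != "remission"])
    has_dx <- "diagnosis" %in% tps
    has_rel <- any(c("r1", "r2") %in% tps)
    if (has_dx && has_rel) "both"
    else if (has_dx) "diagnosis_only"
    else "relapse_only"
  }, character(1))
  data.frame(gene = genes, classification = unname(cls),
             stringsAsFactors = FALSE)
}

#' Genes with biallelic loss: deletion plus non-silent mutation
#'
#' Reports genes where one sample carries both a heterozygous deletion
#' (from an external CNA table) and a surviving non-silent mutation:
#' one allele lost, the other mutated.
#'
#' @param variants [somatic_variants()] frame (cascade survivors).
#' @param deletions data frame `sample_id`, `gene`, `zygosity`
#'   (`"het"`/`"hom"`).
#' @return Data frame `gene`, `sample_id` of biallelic hits.
#' @export
biallelic_hits <- function(variants, deletions) {
  het <- deletions[deletions$zygosity == "het", , drop = FALSE]
  ns <- variants[variants$functional_class == "non_silent" &
                   nzchar(variants$gene), , drop = FALSE]
  key_del <- paste(het$sample_id, het$gene)
  key_mut <- paste(ns$sample_id, ns$gene)
  both <- intersect(key_del, key_mut)
  if (!length(both))
    return(data.frame(gene = character(), sample_id = character()))
  parts <- strsplit(both, " ", fixed = TRUE)
  out <- data.frame(gene = vapply(parts, `[`, character(1), 2L),
                    sample_id = vapply(parts, `[`, character(1), 1L),
                    stringsAsFactors = FALSE)
  out[order(out$gene, out$sample_id), , drop = FALSE]
}

#' Default known-driver gene list
#'
#' The configurable list of genes treated as established drivers of
#' ALL, for which the single-patient shortcut applies. Users can pass
#' their own vector anywhere a known-driver list is accepted.
#'
#' @return Character vector of gene symbols.
#' @export
known_driver_genes <- function() {
  c("ARID1A", "ATRX", "BCORL1", "BIRC7", "CDKN2A", "CREBBP", "EBF1",
    "EP300", "ETV6", "EZH2", "FBXW7", "HDAC2", "HIST1H1D", "HIST1H3I",
    "HIST1H4J", "IDH1", "IKZF1", "IL7R", "KDM6A", "KRAS", "NF1",
    "NOTCH1", "NR3C1", "NRAS", "NT5C2", "PAX5", "PTEN", "PTPN11",
    "SH2B3")
}
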