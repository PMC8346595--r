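#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value with margins fixed: the sum of hypergeometric
#' probabilities of all tables no more probable than the observed one
#' (the standard exact convention). Implemented directly over the
#' hypergeometric support; a brute-force enumeration and
#' `stats::fisher.test` serve as oracles in the test suite.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @return p-value in `(0, 1]`.
#' @examples
#' fisher_exact_two_sided(matrix(c(6, 18, 18, 18), 2, byrow = TRUE))
#' @export
fisher_exact_two_sided <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0))
  if (sum(tab) == 0) stop("empty table", call. = FALSE)
  m <- sum(tab[1, ])           # row 1 total
  n <- sum(tab[2, ])           # row 2 total
  k <- sum(tab[, 1])           # column 1 total
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Tally clonal-evolution trajectories and consensus-model scores
#'
#' Counts patients per trajectory label, patients with a consensus
#' model (non-missing probability score), and scores strictly above
#' 0.8 / strictly below 0.65.
#'
#' @param meta `cohort_meta` frame (see [read_cohort_tables()]).
#' @return List with `by_label` (named integer), `n_consensus`,
#'   `n_above_0_8`, `n_below_0_65`.
#' @export
tally_trajectories <- function(meta) {
  lab <- meta$trajectory_label
  by_label <- vapply(c("persistent", "rising", "founding", "undetermined"),
                     function(l) sum(!is.na(lab) & lab == l), integer(1))
  sc <- meta$probability_score
  list(by_label = by_label,
       n_consensus = sum(!is.na(sc)),
       n_above_0_8 = sum(!is.na(sc) & sc > 0.8),
       n_below_0_65 = sum(!is.na(sc) & sc < 0.65))
}

#' Patients carrying a gene in their critical-gene list, by trajectory
#'
#' A gene counts for a patient when it appears in the critical-genes
#' cell at any timepoint (diagnosis and/or relapses).
#'
#' @param meta `cohort_meta` frame.
#' @param gene gene symbol.
#' @return Named integer vector of distinct-patient counts per
#'   trajectory label (unknown genes give zeros).
#' @export
tally_gene_by_trajectory <- function(meta, gene) {
  labels <- c("persistent", "rising", "founding", "undetermined")
  counts <- stats::setNames(integer(length(labels)), labels)
  for (i in seq_len(nrow(meta))) {
    lab <- meta$trajectory_label[i]
    if (is.na(lab) || !lab %in% labels) next
    genes <- unlist(lapply(c("diagnosis", "r1", "r2"), function(tp)
      critical_genes(meta, meta$patient_id[i], tp)))
    if (gene %in% genes) counts[lab] <- counts[lab] + 1L
  }
  counts
}

#' Genome inventory of the cohort
#'
#' Per-timepoint genome counts under the study design: every patient
#' contributes a diagnostic and a remission (germline) genome, a first
#' relapse genome, and a second relapse genome when a second-relapse
#' time is recorded.
#'
#' @param meta `cohort_meta` frame.
#' @return Named integer vector: `diagnosis`, `remission`, `r1`, `r2`,
#'   `tumor_total`, `grand_total`.
#' @export
sample_inventory <- function(meta) {
  n <- nrow(meta)
  r1 <- sum(!is.na(meta$time_to_first_relapse_months))
  r2 <- sum(!is.na(meta$time_to_second_relapse_months))
  c(diagnosis = n, remission = n, r1 = r1, r2 = r2,
    tumor_total = n + r1 + r2, grand_total = 2L * n + r1 + r2)
}

#' Mutation-burden summary per timepoint
#'
#' Median (mean of the two middle order statistics for even n) and
#' min-max range of per-sample burdens, grouped by timepoint.
#'
#' @param burdens data frame `timepoint`, `n_mutations` (one row per
#'   sample).
#' @return Data frame `timepoint`, `n`, `median`, `min`, `max`.
#' @export
burden_summary <- function(burdens) {
  tps <- intersect(c("diagnosis", "r1", "r2"), unique(burdens$timepoint))
  out <- lapply(tps, function(tp) {
    x <- burdens$n_mutations[burdens$timepoint == tp]
    if (!length(x)) {
      warning("no samples at timepoint ", tp)
      return(NULL)
    }
    data.frame(timepoint = tp, n = length(x),
               median = stats::median(x), min = min(x), max = max(x),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Render a plain-markdown cohort report
#'
#' Assembles the stage outputs into one deterministic markdown
#' document: burden table, signature attributions, hotspot table,
#' driver calls, trajectory calls and the cohort tallies. Sections are
#' included when their input is supplied; `burden` and `meta` are
#' mandatory.
#'
#' @param meta `cohort_meta` frame (mandatory).
#' @param burden output of [burden_summary()] (or `NULL`).
#' @param exposures exposure matrix (or `NULL`).
#' @param hotspots hotspot frame (or `NULL`).
#' @param drivers data frame of driver calls (or `NULL`).
#' @param trajectories data frame of trajectory calls (or `NULL`).
#' @param path optional output file.
#' @return Character vector of markdown lines (invisibly when `path`
#'   given).
#' @export
render_report <- function(meta, burden = NULL, exposures = NULL,
                          hotspots = NULL, drivers = NULL,
                          trajectories = NULL, path = NULL) {
  if (missing(meta) || is.null(meta))
    stop("missing mandatory stage output: meta", call. = FALSE)
  md_table <- function(df) {
    df <- as.data.frame(df)
    df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
    c(paste0("| ", paste(names(df), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
      vapply(seq_len(nrow(df)), function(i)
        paste0("| ", paste(vapply(df[i, ], function(x)
          if (is.numeric(x)) format(x, digits = 6) else as.character(x),
          character(1)), collapse = " | "), " |"), character(1)))
  }
  tal <- tally_trajectories(meta)
  inv <- sample_inventory(meta)
  lines <- c("# Cohort report", "",
             "## Sample inventory", "",
             paste0("- ", names(inv), ": ", inv), "",
             "## Trajectory tallies", "",
             paste0("- ", names(tal$by_label), ": ", tal$by_label),
             paste0("- consensus models: ", tal$n_consensus),
             paste0("- probability score > 0.8: ", tal$n_above_0_8),
             paste0("- probability score < 0.65 (as published): ",
                    tal$n_below_0_65), "")
  if (!is.null(burden))
    lines <- c(lines, "## Mutation burden", "", md_table(burden), "")
  if (!is.null(exposures))
    lines <- c(lines, "## Signature exposures", "",
               md_table(data.frame(sample = rownames(exposures),
                                   round(exposures, 1))), "")
  if (!is.null(hotspots))
    lines <- c(lines, "## Regulatory hotspots", "", md_table(hotspots), "")
  if (!is.null(drivers))
    lines <- c(lines, "## Driver calls", "", md_table(drivers), "")
  if (!is.null(trajectories))
    lines <- c(lines, "## Clonal trajectories", "", md_table(trajectories),
               "")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
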