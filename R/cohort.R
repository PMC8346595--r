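#' Read the cohort clinical and trajectory tables
#'
#' Parses the two delimited cohort fixtures shipped with the package (or
#' user-supplied tables with the same headers) into one per-patient
#' metadata frame. The clinical table carries subtype, risk group,
#' relapse timing and the bone-marrow-transplant flag; the trajectory
#' table carries the published consensus-model trajectory label, its
#' probability score (kept as published, never recomputed) and the
#' critical mutated genes per timepoint.
#'
#' Missing values written as any of `na`, `Na`, `NA` or an empty cell are
#' normalized to `NA`. `"#"`-prefixed lines are comments.
#'
#' @param path_t1 clinical table path (default: shipped fixture).
#' @param path_t2 trajectory table path (default: shipped fixture);
#'   `NULL` to skip.
#' @return A `cohort_meta` data frame, one row per patient, with columns
#'   `patient_id`, `immunophenotype`, `subtype_diagnosis`,
#'   `subtype_revised`, `risk_group`, `time_to_first_relapse_months`,
#'   `first_relapse_on_therapy`, `time_to_second_relapse_months`,
#'   `vital_status`, `bmt_flag`, and from the trajectory table
#'   `trajectory_label`, `probability_score`, `fusion_gene`,
#'   `genes_diagnosis`, `genes_r1`, `genes_r2` (comma-separated cells).
#' @export
read_cohort_tables <- function(path_t1 = cohort_fixture_path("table1.tsv"),
                               path_t2 = cohort_fixture_path("table2.tsv")) {
  t1 <- utils::read.delim(path_t1, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (anyDuplicated(t1$patient_id))
    stop("duplicate patient_id in clinical table: ",
         t1$patient_id[duplicated(t1$patient_id)][1], call. = FALSE)
  t1$time_to_first_relapse_months <-
    normalize_missing(t1$time_to_first_relapse_months, numeric = TRUE)
  t1$time_to_second_relapse_months <-
    normalize_missing(t1$time_to_second_relapse_months, numeric = TRUE)
  t1$bmt_flag <- as.logical(t1$bmt_after_first_relapse)
  t1$bmt_after_first_relapse <- NULL
  out <- t1
  if (!is.null(path_t2)) {
    t2 <- utils::read.delim(path_t2, comment.char = "#",
                            stringsAsFactors = FALSE)
    if (anyDuplicated(t2$patient_id))
      stop("duplicate patient_id in trajectory table: ",
           t2$patient_id[duplicated(t2$patient_id)][1], call. = FALSE)
    t2$probability_score <- normalize_missing(t2$probability_score,
                                              numeric = TRUE)
    for (col in c("fusion_gene", "genes_diagnosis", "genes_r1", "genes_r2"))
      t2[[col]] <- normalize_missing(t2[[col]])
    names(t2)[names(t2) == "trajectory"] <- "trajectory_label"
    out <- merge(t1, t2[, c("patient_id", "trajectory_label",
                            "probability_score", "fusion_gene",
                            "genes_diagnosis", "genes_r1", "genes_r2")],
                 by = "patient_id", all.x = TRUE, sort = FALSE)
  }
  out <- out[order(match(out$patient_id, t1$patient_id)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cohort_meta", "data.frame")
  out
}

#' Path to a shipped cohort fixture
#'
#' @param file fixture file name under `extdata/tables`.
#' @return Absolute path.
#' @export
cohort_fixture_path <- function(file) {
  p <- system.file("extdata", "tables", file, package = "relapsetrace")
  if (!nzchar(p)) stop("fixture not found: ", file, call. = FALSE)
  p
}

## Normalize the mixed missing-value tokens ("na", "Na", "NA", "") used in
## transcribed tables to NA; optionally coerce the remainder to numeric.
normalize_missing <- function(x, numeric = FALSE) {
  x <- as.character(x)
  x[is.na(x) | tolower(trimws(x)) %in% c("na", "")] <- NA_character_
  if (numeric) as.numeric(x) else x
}

#' Critical genes of a patient at one timepoint
#'
#' Splits the comma-separated critical-gene cell of the trajectory table.
#'
#' @param meta `cohort_meta` frame.
#' @param patient_id patient identifier.
#' @param timepoint `"diagnosis"`, `"r1"` or `"r2"`.
#' @return Character vector of gene symbols (empty if none recorded).
#' @export
critical_genes <- function(meta, patient_id, timepoint) {
  col <- switch(timepoint, diagnosis = "genes_diagnosis", r1 = "genes_r1",
                r2 = "genes_r2",
                stop("unknown timepoint: ", timepoint, call. = FALSE))
  cell <- meta[[col]][meta$patient_id == patient_id]
  if (!length(cell) || is.na(cell)) return(character(0))
  trimws(strsplit(cell, ",", fixed = TRUE)[[1]])
}
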