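#' Read somatic variants from a VCF file
#'
#' Parses a VCF 4.x file (as written by [write_variants()] or any caller
#' emitting `AD`/`DP` genotype fields for the tumor sample) into a
#' [somatic_variants()] table. 1-based VCF positions are converted to the
#' package's 0-based half-open convention. Caller provenance is taken from
#' the `CALLERS` INFO key when present; germline depth from `GDP`, gene
#' symbol from `GENE` and functional class from `FCLASS`.
#'
#' @param path VCF file path.
#' @param patient_id,sample_id,timepoint metadata applied to every record
#'   (overridden by `PID`/`SID`/`TP` INFO keys when present).
#' @return [somatic_variants()] data frame (zero rows for an empty body).
#' @export
read_variants <- function(path, patient_id = "P0", sample_id = "S0",
                          timepoint = "diagnosis") {
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path)),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  n <- length(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  if (n == 0L) {
    return(somatic_variants(character(), character(), character(),
                            character(), numeric(), numeric(),
                            character(), character(), numeric(), numeric()))
  }
  gn <- VariantAnnotation::geno(vcf)
  if (!all(c("AD", "DP") %in% names(gn)))
    stop("VCF '", path, "' lacks AD/DP genotype fields", call. = FALSE)
  ad <- gn$AD[, 1]
  alt_count <- vapply(seq_len(n), function(i) {
    x <- if (is.list(ad)) ad[[i]] else ad[i, ]
    if (length(x) < 2 || anyNA(x[1:2]))
      stop("missing AD counts at VCF line for record ", i, " in '", path,
           "'", call. = FALSE)
    as.numeric(x[2])
  }, numeric(1))
  dp <- as.numeric(gn$DP[, 1])
  if (anyNA(dp)) stop("missing DP in '", path, "'", call. = FALSE)
  info <- VariantAnnotation::info(vcf)
  pull <- function(key, default) {
    if (key %in% names(info)) {
      v <- info[[key]]
      v <- as.character(v)
      ifelse(is.na(v) | !nzchar(v), default, v)
    } else rep(default, n)
  }
  callers <- if ("CALLERS" %in% names(info)) {
    vapply(seq_len(n), function(i)
      paste(sort(unique(as.character(info$CALLERS[[i]]))), collapse = ";"),
      character(1))
  } else rep("callerA", n)
  gdp <- if ("GDP" %in% names(info)) suppressWarnings(as.numeric(info$GDP))
         else rep(NA_real_, n)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- vapply(seq_len(n), function(i)
    as.character(VariantAnnotation::alt(vcf)[[i]][1]), character(1))
  pos1 <- BiocGenerics::start(rr)        # 1-based
  start0 <- pos1 - 1
  somatic_variants(
    patient_id = pull("PID", patient_id),
    sample_id = pull("SID", sample_id),
    timepoint = pull("TP", timepoint),
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    start = start0, end = start0 + nchar(ref),
    ref = ref, alt = alt,
    tumor_depth = dp, alt_count = alt_count,
    germline_depth = gdp,
    gene = pull("GENE", ""), functional_class = pull("FCLASS", "unknown"),
    callers = callers)
}

#' Write somatic variants to a VCF file
#'
#' Inverse of [read_variants()]: emits a minimal VCF 4.2 with `AD`/`DP`
#' genotype fields for a single `TUMOR` sample and the package INFO keys
#' (`PID`, `SID`, `TP`, `GDP`, `GENE`, `FCLASS`, `CALLERS`). Coordinates
#' convert back to 1-based.
#'
#' @param variants [somatic_variants()] frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=PID,Number=1,Type=String,Description=\"Patient id\">",
    "##INFO=<ID=SID,Number=1,Type=String,Description=\"Sample id\">",
    "##INFO=<ID=TP,Number=1,Type=String,Description=\"Timepoint\">",
    "##INFO=<ID=GDP,Number=1,Type=Integer,Description=\"Germline depth at site\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=FCLASS,Number=1,Type=String,Description=\"Functional class\">",
    "##INFO=<ID=CALLERS,Number=.,Type=String,Description=\"Caller provenance\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "TUMOR", sep = "\t"))
  body <- character(0)
  if (nrow(variants)) {
    o <- order(variants$chrom, variants$start)
    v <- variants[o, , drop = FALSE]
    info <- sprintf("PID=%s;SID=%s;TP=%s%s;GENE=%s;FCLASS=%s;CALLERS=%s",
                    v$patient_id, v$sample_id, v$timepoint,
                    ifelse(is.na(v$germline_depth), "",
                           sprintf(";GDP=%d", as.integer(v$germline_depth))),
                    ifelse(nzchar(v$gene), v$gene, "."),
                    v$functional_class,
                    gsub(";", ",", v$callers, fixed = TRUE))
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s\tGT:AD:DP\t0/1:%d,%d:%d",
                    v$chrom, as.integer(v$start) + 1L, v$ref, v$alt, info,
                    as.integer(v$tumor_depth - v$alt_count),
                    as.integer(v$alt_count), as.integer(v$tumor_depth))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read labeled regions from a BED file
#'
#' BED3+ reader; BED's native 0-based half-open coordinates are kept as-is
#' (they match the package convention). A 4th column, when present, is
#' retained as `label`. Overlapping records are preserved unmerged.
#'
#' @param path BED file path.
#' @return [genomic_intervals()] data frame.
#' @export
read_regions <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines))
    return(genomic_intervals(character(), numeric(), numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_min <- min(lengths(fields))
  if (ncol_min < 3)
    stop("BED line ", which(lengths(fields) < 3)[1], " has fewer than 3 columns",
         call. = FALSE)
  chrom <- vapply(fields, `[`, character(1), 1L)
  start <- as.numeric(vapply(fields, `[`, character(1), 2L))
  end <- as.numeric(vapply(fields, `[`, character(1), 3L))
  bad <- which(is.na(start) | is.na(end) | end <= start)
  if (length(bad))
    stop("BED line ", bad[1], ": end <= start or non-numeric coordinates",
         call. = FALSE)
  label <- if (ncol_min >= 4) vapply(fields, `[`, character(1), 4L) else NULL
  genomic_intervals(chrom, start, end, label)
}

#' Write regions to a BED file
#'
#' @param regions [genomic_intervals()] frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  cols <- list(regions$chrom, format(regions$start, scientific = FALSE,
                                     trim = TRUE),
               format(regions$end, scientific = FALSE, trim = TRUE))
  if (!is.null(regions$label)) cols <- c(cols, list(regions$label))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read a reference signature matrix in COSMIC layout
#'
#' First column holds the 96 channel labels (`A[C>A]A` ... `T[T>G]T`);
#' remaining columns are one signature each. Rows are reordered into the
#' package's canonical channel order and columns are checked for
#' normalization.
#'
#' @param path TSV file path.
#' @return A `signature_set`: list with `matrix` (96 x K, columns sum to
#'   1), `labels`, `provenance`.
#' @export
read_signatures <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ch <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ch
  signature_set(m[sbs_channels(), , drop = FALSE], provenance = "reference")
}

#' Write a signature set as a COSMIC-layout TSV
#'
#' @param sigs `signature_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signatures <- function(sigs, path) {
  df <- data.frame(Type = sbs_channels(), sigs$matrix, check.names = FALSE)
  colnames(df) <- c("Type", sigs$labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
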