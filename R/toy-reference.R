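#' Build the toy reference bundle
#'
#' Constructs a small (~100 kb, two synthetic chromosomes) reference
#' world with planted, documented features: homopolymer runs of eight
#' bases (the only runs of length >= 7 in the sequence, since the
#' background is generated with runs capped at three), repeat regions,
#' assembly gaps, labeled regulatory intervals (promoter/enhancer/open
#' chromatin marks), conserved elements, and a population-variant panel.
#' Everything downstream of the filter cascade can be validated against
#' this known ground truth.
#'
#' @param seed integer seed; the bundle is a pure function of it.
#' @param chrom_len length of each of the two chromosomes.
#' @return Object of class `toy_reference`: list with `sequences`
#'   (named `DNAStringSet`), `homopolymers`, `repeats`, `gaps`,
#'   `regulatory`, `conserved` (interval frames) and `population`
#'   (data frame `chrom`, `start`, `ref`, `alt`).
#' @export
make_toy_reference <- function(seed = 1, chrom_len = 50000L) {
  chroms <- c("chrS1", "chrS2")
  bases <- c("A", "C", "G", "T")
  with_rng(sub_seed(seed, 101), {
    seqs <- lapply(chroms, function(ch) {
      ## background with homopolymer runs capped at 3
      s <- character(chrom_len)
      s[1:2] <- sample(bases, 2, replace = TRUE)
      draws <- sample(bases, chrom_len, replace = TRUE)
      alts <- sample(bases, chrom_len, replace = TRUE)
      for (i in 3:chrom_len) {
        b <- draws[i]
        if (b == s[i - 1] && b == s[i - 2]) {
          b <- alts[i]
          if (b == s[i - 1]) b <- bases[match(b, bases) %% 4 + 1]
        }
        s[i] <- b
      }
      s
    })
    names(seqs) <- chroms
    ## plant 8-base homopolymer runs at fixed offsets
    hp_starts <- c(5000L, 15000L, 25000L, 35000L, 45000L)
    hp <- do.call(rbind, lapply(chroms, function(ch)
      data.frame(chrom = ch, start = hp_starts, end = hp_starts + 8L)))
    for (i in seq_len(nrow(hp))) {
      b <- sample(bases, 1)
      idx <- (hp$start[i] + 1):(hp$end[i])
      seqs[[hp$chrom[i]]][idx] <- b
      ## guard flanks so the run is exactly 8 long
      seqs[[hp$chrom[i]]][hp$start[i]] <-
        bases[bases != b][sample.int(3, 1)]
      seqs[[hp$chrom[i]]][hp$end[i] + 1L] <-
        bases[bases != b][sample.int(3, 1)]
    }
    repeats <- genomic_intervals(
      chrom = c("chrS1", "chrS1", "chrS1", "chrS2", "chrS2"),
      start = c(8000, 20000, 40000, 9000, 26000),
      end = c(8400, 20400, 40400, 9400, 26400),
      label = "repeat")
    gaps <- genomic_intervals(chrom = c("chrS1", "chrS2"),
                              start = c(48000, 30000),
                              end = c(48500, 31000), label = "gap")
    regulatory <- genomic_intervals(
      chrom = c("chrS1", "chrS1", "chrS1", "chrS1", "chrS2", "chrS2", "chrS2"),
      start = c(1000, 2000, 10000, 22000, 3000, 12000, 18000),
      end = c(1500, 2600, 10800, 22500, 3600, 12500, 18400),
      label = c("H3K4me3", "H3K27ac", "H3K4me1", "DNase1",
                "H3K27ac", "H3K4me3", "TFBS"))
    conserved <- genomic_intervals(chrom = c("chrS1", "chrS2"),
                                   start = c(2100, 3100),
                                   end = c(2200, 3200),
                                   label = "phastCons")
    ## population panel: SNVs at positions clear of planted runs
    pop_n <- 150L
    pop_pos <- sort(sample(setdiff(seq(100L, chrom_len - 100L, by = 7L),
                                   unlist(lapply(hp_starts, function(s)
                                     (s - 10L):(s + 18L)))), pop_n))
    population <- do.call(rbind, lapply(chroms, function(ch) {
      ref <- seqs[[ch]][pop_pos + 1L]
      alt <- vapply(ref, function(r) bases[bases != r][sample.int(3, 1)],
                    character(1), USE.NAMES = FALSE)
      data.frame(chrom = ch, start = pop_pos, ref = ref, alt = alt,
                 stringsAsFactors = FALSE)
    }))
    dna <- Biostrings::DNAStringSet(vapply(seqs, paste, character(1),
                                           collapse = ""))
    names(dna) <- chroms
    structure(list(sequences = dna, homopolymers = hp, repeats = repeats,
                   gaps = gaps, regulatory = regulatory,
                   conserved = conserved, population = population,
                   seed = seed),
              class = "toy_reference")
  })
}

#' Homopolymer runs of a reference sequence
#'
#' Scans a reference for maximal single-base runs of at least
#' `min_len` bases and returns them as 0-based half-open intervals.
#' This is the scan the homopolymer filter rule consumes; on the toy
#' reference it recovers exactly the planted runs.
#'
#' @param sequences named `DNAStringSet`.
#' @param min_len minimal run length (default 7).
#' @return Interval frame with `chrom`, `start`, `end`, `label` (the
#'   repeated base).
#' @export
homopolymer_runs <- function(sequences, min_len = 7L) {
  out <- lapply(names(sequences), function(ch) {
    r <- rle(strsplit(as.character(sequences[[ch]]), NULL)[[1]])
    ends <- cumsum(r$lengths)
    keep <- r$lengths >= min_len
    if (!any(keep)) return(NULL)
    data.frame(chrom = ch, start = ends[keep] - r$lengths[keep],
               end = ends[keep], label = r$values[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(genomic_intervals(character(), numeric(), numeric(),
                             character()))
  genomic_intervals(out$chrom, out$start, out$end, out$label)
}

## Reference base(s) over a 0-based half-open window; errors when the
## window falls off the sequence.
ref_window <- function(sequences, chrom, start, end) {
  if (!chrom %in% names(sequences))
    stop("chromosome absent from reference: ", chrom, call. = FALSE)
  len <- Biostrings::width(sequences[chrom])
  if (start < 0 || end > len)
    stop("reference window unavailable: ", chrom, ":", start, "-", end,
         call. = FALSE)
  as.character(Biostrings::subseq(sequences[[chrom]], start + 1L, end))
}
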