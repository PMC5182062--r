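# Chromosome breakage sequence scanning, conservation, and strand asymmetry.

#' Scan a sequence for Cbs family motifs on both strands
#'
#' Finds every (possibly overlapping) match of the 15-bp chromosome breakage
#' sequence family `WAAACCAACCYCNHW` on either strand. Minus-strand hits are
#' reported with the C-rich strand sequence and forward-axis coordinates.
#' `N` bases never match.
#'
#' @param sequence a single DNA string.
#' @param chromosome_id identifier recorded with each hit.
#' @return data.frame of hits sorted by start: `chromosome`, `start`, `end`
#'   (1-based inclusive), `strand`, `sequence` (C-rich strand), `variant`,
#'   `n_substitutions`, `overlaps_other` (TRUE where hits overlap).
#' @examples
#' scan_cbs(paste0("ACGTACGT", "TAAACCAACCTCTTT", "ACGTACGT"), "chr")
#' @export
scan_cbs <- function(sequence, chromosome_id = "chr") {
  sequence <- toupper(sequence)
  hits <- scan_cbs_raw(sequence)
  if (nrow(hits) == 0L)
    return(data.frame(chromosome = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      sequence = character(0), variant = character(0),
                      n_substitutions = integer(0),
                      overlaps_other = logical(0)))
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  fwd_seq <- substring(sequence, hits$start, hits$start + CBS_LENGTH - 1L)
  crich <- ifelse(hits$strand == "+", fwd_seq, revcomp(fwd_seq))
  cls <- lapply(crich, classify_variant)
  out <- data.frame(
    chromosome = chromosome_id,
    start = hits$start,
    end = hits$start + CBS_LENGTH - 1L,
    strand = hits$strand,
    sequence = crich,
    variant = vapply(cls, `[[`, character(1), "variant"),
    n_substitutions = vapply(cls, `[[`, integer(1), "n_substitutions"),
    stringsAsFactors = FALSE)
  out$overlaps_other <- vapply(seq_len(nrow(out)), function(i)
    any(out$start[-i] <= out$end[i] & out$end[-i] >= out$start[i]),
    logical(1))
  rownames(out) <- NULL
  out
}

#' Scan a whole genome for Cbs motifs
#' @param genome named character vector of chromosome sequences.
#' @return row-bound [scan_cbs()] results for every chromosome.
#' @export
scan_cbs_genome <- function(genome) {
  out <- do.call(rbind, lapply(names(genome), function(chrom)
    scan_cbs(genome[[chrom]], chrom)))
  rownames(out) <- NULL
  out
}

#' Per-position information content of aligned Cbs sequences
#'
#' Computes `2 + sum_b f_b log2 f_b` at each column of the aligned hit
#' sequences (C-rich strand, optionally with equal-length flanks): 2 bits is
#' complete conservation, 0 bits no conservation. `N` characters are
#' excluded from the frequency counts.
#'
#' @param sequences character vector of equal-length aligned sequences.
#' @return numeric vector of information content (bits) per position.
#' @export
conservation_profile <- function(sequences) {
  if (length(sequences) == 0L) stop("no sequences to profile")
  w <- unique(nchar(sequences))
  if (length(w) != 1L) stop("sequences must share a common length")
  m <- do.call(rbind, strsplit(toupper(sequences), ""))
  apply(m, 2L, function(col) {
    col <- col[col %in% DNA_BASES]
    if (length(col) == 0L) return(NA_real_)
    f <- table(factor(col, levels = DNA_BASES)) / length(col)
    f <- f[f > 0]
    2 + sum(f * log2(f))
  })
}

#' Strand asymmetry of Cbs substitutions
#'
#' Counts, over all substitutions relative to the consensus (each mismatch of
#' a double-substituted variant counts separately), how many substituted
#' bases are C and how many are G on the C-rich strand, and tests the C/G
#' split against 50/50 with a one-degree-of-freedom chi-square (no continuity
#' correction).
#'
#' @param hits data.frame with a `sequence` column of C-rich strand 15-mers
#'   (e.g. from [scan_cbs()]), or a character vector of 15-mers.
#' @return list with `n_sub_to_C`, `n_sub_to_G`, `n_sub_to_AT`, `chi_square`,
#'   `p_value` (chi-square and p are `NA` when no C/G substitutions exist).
#' @export
strand_asymmetry <- function(hits) {
  seqs <- if (is.data.frame(hits)) hits$sequence else hits
  cons <- strsplit(CBS_CONSENSUS, "")[[1]]
  subs <- unlist(lapply(seqs, function(s) {
    v <- strsplit(toupper(s), "")[[1]]
    v[v != cons]
  }))
  nC <- sum(subs == "C"); nG <- sum(subs == "G")
  nAT <- sum(subs %in% c("A", "T"))
  if (nC + nG == 0L)
    return(list(n_sub_to_C = nC, n_sub_to_G = nG, n_sub_to_AT = nAT,
                chi_square = NA_real_, p_value = NA_real_))
  e <- (nC + nG) / 2
  chi <- (nC - e)^2 / e + (nG - e)^2 / e
  list(n_sub_to_C = nC, n_sub_to_G = nG, n_sub_to_AT = nAT,
       chi_square = chi,
       p_value = stats::pchisq(chi, df = 1L, lower.tail = FALSE))
}
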